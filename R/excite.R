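# Mock excited-state engine: a Stark-like linear response of the first bright
# transition to the solvent electric field at a probe point, plus weaker
# higher states at fixed offsets. Stands in for a per-snapshot excited-state
# calculation so the ensemble-spectroscopy pipeline can be exercised and
# tested at desk scale.

#' Configuration of the mock excitation model
#'
#' The first transition energy of each snapshot is
#' `E1 = e0 - stark_slope * F + Normal(0, noise_sd)` where `F` is the solvent
#' electric field of the solved embedding at `probe_point`, projected on
#' `probe_axis`. Additional states sit at `e0 + state_offsets` with
#' independent noise and no field coupling. Oscillator strengths are drawn
#' from `|Normal(strength_mean, strength_sd)|`, scaled down for the higher
#' states.
#'
#' @param e0 gas-phase (zero-field) energy of the first bright transition, eV.
#' @param stark_slope linear response of the transition to the projected
#'   field, eV per atomic unit of field. The default corresponds to an
#'   excited-state dipole change of about one atomic unit (roughly 2.4 D),
#'   typical of a push-pull dye.
#' @param probe_point where the solvent field is evaluated, Angstrom; defaults
#'   to the carbonyl acceptor of [carbonyl_solute()].
#' @param probe_axis unit 3-vector; defaults to the oxygen-to-carbon direction
#'   of the carbonyl, along which hydrogen-bond donors push the transition
#'   down in energy.
#' @param strength_mean,strength_sd oscillator-strength law.
#' @param noise_sd residual per-snapshot noise on each energy, eV.
#' @param n_states number of states per snapshot (>= 1).
#' @param state_offsets energy offsets of states 2..n relative to `e0`, eV.
#' @param seed integer seed for the noise streams.
#' @return a `mock_excitation_model` list.
#' @export
excitation_model <- function(e0 = 3.10,
                             stark_slope = 25,
                             probe_point = c(1.23, 0, 0),
                             probe_axis = c(-1, 0, 0),
                             strength_mean = 0.5,
                             strength_sd = 0.05,
                             noise_sd = 0.02,
                             n_states = 3,
                             state_offsets = c(1.6, 2.3),
                             seed = 1L) {
  if (n_states < 1) fq_abort("`n_states` must be >= 1.", "fqembed_bad_config")
  if (noise_sd < 0) fq_abort("`noise_sd` must be >= 0.", "fqembed_bad_config")
  if (length(state_offsets) < n_states - 1) {
    fq_abort("`state_offsets` must provide one offset per extra state.",
             "fqembed_bad_config")
  }
  structure(list(
    e0 = e0, stark_slope = stark_slope,
    probe_point = as.numeric(probe_point),
    probe_axis = unit3(as.numeric(probe_axis)),
    strength_mean = strength_mean, strength_sd = strength_sd,
    noise_sd = noise_sd, n_states = as.integer(n_states),
    state_offsets = state_offsets, seed = as.integer(seed)
  ), class = "mock_excitation_model")
}

#' Mock stick spectrum of one snapshot
#'
#' Evaluates the solvent field of the solved embedding at the model's probe
#' point and turns it into a per-snapshot stick spectrum (energies in eV,
#' dimensionless oscillator strengths). The noise stream is derived from the
#' model seed and the snapshot id, so ensembles are reproducible regardless of
#' evaluation order.
#'
#' @param snapshot a single-snapshot tibble (used for its id).
#' @param solution the `embedding_solution` for that snapshot's waters.
#' @param model a [excitation_model()].
#' @return a tibble with columns `snapshot_id`, `state`, `energy_ev`,
#'   `strength`, `field_au` (the projected solvent field).
#' @export
mock_excitations <- function(snapshot, solution, model = excitation_model()) {
  snap_id <- unique(snapshot$snapshot_id)
  if (length(snap_id) != 1) {
    fq_abort("`snapshot` must contain exactly one snapshot id.",
             "fqembed_bad_value")
  }
  f <- sum(solvent_field(solution, model$probe_point) * model$probe_axis)
  set.seed((model$seed + 7919L * as.integer(snap_id)) %% .Machine$integer.max)
  e <- c(model$e0 - model$stark_slope * f,
         model$e0 + model$state_offsets[seq_len(model$n_states - 1)])
  if (model$noise_sd > 0) e <- e + rnorm(model$n_states, 0, model$noise_sd)
  strengths <- abs(rnorm(model$n_states, model$strength_mean, model$strength_sd))
  if (model$n_states > 1) {
    strengths[-1] <- strengths[-1] * 0.4   # higher states weaker
  }
  if (any(e <= 0)) {
    fq_abort("mock excitation produced a non-positive energy.",
             "fqembed_bad_value")
  }
  tibble::tibble(snapshot_id = as.integer(snap_id),
                 state = seq_len(model$n_states),
                 energy_ev = e, strength = strengths, field_au = f)
}

#' Stick spectra for a whole ensemble
#'
#' Convenience wrapper: solves the embedding for every snapshot's water shell
#' and evaluates the mock excitation model on each.
#'
#' @param snapshots ensemble tibble from [generate_snapshots()].
#' @param params force-field parameters, see [fq_parameters()].
#' @param variant force-field variant.
#' @param model a [excitation_model()].
#' @param kernel_form kernel family, see [build_kernels()].
#' @param charge_scale multiplier applied to the solved charges (and dipoles)
#'   before the field evaluation; 1 leaves the solution untouched. Exposed to
#'   probe how the coupling strength propagates into band widths.
#' @return a stick tibble (all snapshots stacked).
#' @export
ensemble_excitations <- function(snapshots, params = fq_parameters("toy"),
                                 variant = "FQ",
                                 model = excitation_model(),
                                 kernel_form = "ohno",
                                 charge_scale = 1) {
  variant <- ff_variant(variant)
  config <- attr(snapshots, "config")
  solute <- if (!is.null(config)) config$solute else carbonyl_solute()
  frames <- split_snapshots(snapshots)
  purrr::map(frames, function(fr) {
    top <- water_topology(fr, params, variant)
    src <- solute_point_source(solute, top)
    sol <- solve_embedding(top, variant, src, kernel_form)
    if (charge_scale != 1) {
      sol$sites$q <- charge_scale * sol$sites$q
      if (variant_uses_dipoles(variant)) {
        sol$sites$mux <- charge_scale * sol$sites$mux
        sol$sites$muy <- charge_scale * sol$sites$muy
        sol$sites$muz <- charge_scale * sol$sites$muz
      }
    }
    mock_excitations(fr, sol, model)
  }) |> purrr::list_rbind()
}
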