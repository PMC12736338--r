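# End-to-end orchestration: generate -> cut -> solve -> excite -> broaden ->
# average -> shift, with per-stage artifacts and a JSON report.

#' Pipeline configuration
#'
#' Bundles the sub-configurations of the five workflow stages. The pipeline
#' seed governs every stochastic stage: the generator and the excitation model
#' receive seeds derived from it, so a rerun with the same configuration is
#' bit-identical.
#'
#' @param generator a [generator_config()].
#' @param variant force-field variant, see [ff_variant()].
#' @param params force-field parameter tibble, see [fq_parameters()].
#' @param kernel_form kernel family, see [build_kernels()].
#' @param excitation a [excitation_model()].
#' @param fwhm Gaussian broadening, eV.
#' @param grid spectral grid `c(min, max, step)`, eV.
#' @param window band-search window, eV; defaults to
#'   `c(e0 - 1.5, e0 + 0.5)` around the model's zero-field energy.
#' @param cut_radius spherical-cut radius, Angstrom; defaults to the
#'   generator's droplet radius.
#' @param charge_scale coupling-strength multiplier applied to the solved
#'   charges and dipoles before the excitation stage (1 = physical solution).
#' @param workspace directory for stage artifacts, or `NULL` to keep
#'   everything in memory.
#' @param seed master integer seed.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(generator = generator_config(),
                            variant = "FQ",
                            params = fq_parameters("toy"),
                            kernel_form = "ohno",
                            excitation = excitation_model(),
                            fwhm = 0.3,
                            grid = default_grid,
                            window = NULL,
                            cut_radius = NULL,
                            charge_scale = 1,
                            workspace = NULL,
                            seed = 1L) {
  variant <- ff_variant(variant)
  if (is.null(window)) {
    window <- c(excitation$e0 - 1.5, excitation$e0 + 0.5)
  }
  structure(list(
    generator = generator, variant = variant, params = params,
    kernel_form = kernel_form, excitation = excitation,
    fwhm = fwhm, grid = grid, window = window,
    cut_radius = cut_radius %||% generator$droplet_radius,
    charge_scale = charge_scale,
    workspace = workspace, seed = as.integer(seed)
  ), class = "pipeline_config")
}

#' Run the full ensemble-spectroscopy pipeline
#'
#' Executes generate, cut, solve, excite, broaden/average and shift in order,
#' writing every intermediate artifact when a workspace directory is
#' configured, and returns a report with the band maximum, the solvatochromic
#' shift relative to the model's zero-field energy, the first-band stick
#' dispersion, per-stage timings and the seeds used. Reruns with the same
#' configuration are bit-identical.
#'
#' @param config a [pipeline_config()].
#' @return a `pipeline_report` list; see [tidy.pipeline_report()].
#' @export
run_pipeline <- function(config = pipeline_config()) {
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    timings[[stage]] <<- t1 - t0
    t0 <<- t1
  }
  gen <- config$generator
  gen$seed <- config$seed
  model <- config$excitation
  model$seed <- config$seed + 1L

  snaps <- generate_snapshots(gen)
  tick("generate")
  snaps <- spherical_cut(snaps, c(0, 0, 0), config$cut_radius)
  tick("cut")

  ws <- config$workspace
  files <- character(0)
  if (!is.null(ws)) {
    for (d in c("snapshots", "solutions", "sticks", "spectra")) {
      dir.create(file.path(ws, d), recursive = TRUE, showWarnings = FALSE)
    }
    files <- c(files,
               write_xyz(snaps, file.path(ws, "snapshots", "ensemble.xyz")),
               write_molecule_map(snaps, file.path(ws, "snapshots", "map.csv")))
  }

  frames <- split_snapshots(snaps)
  sticks_list <- vector("list", length(frames))
  for (k in seq_along(frames)) {
    fr <- frames[[k]]
    top <- water_topology(fr, config$params, config$variant)
    src <- solute_point_source(gen$solute, top)
    sol <- solve_embedding(top, config$variant, src, config$kernel_form)
    if (config$charge_scale != 1) {
      sol$sites$q <- config$charge_scale * sol$sites$q
      if (variant_uses_dipoles(config$variant)) {
        for (cc in c("mux", "muy", "muz")) {
          sol$sites[[cc]] <- config$charge_scale * sol$sites[[cc]]
        }
      }
    }
    if (!is.null(ws)) {
      files <- c(files, write_solution(
        sol, file.path(ws, "solutions",
                       sprintf("solution_%03d.csv", unique(fr$snapshot_id)))))
    }
    sticks_list[[k]] <- mock_excitations(fr, sol, model)
  }
  tick("solve_excite")

  sticks <- purrr::list_rbind(sticks_list)
  if (!is.null(ws)) {
    files <- c(files, write_sticks(sticks, file.path(ws, "sticks", "sticks.csv")))
  }
  curve <- ensemble_spectrum(sticks, config$fwhm, config$grid)
  if (!is.null(ws)) {
    files <- c(files, write_curve(curve, file.path(ws, "spectra", "curve_avg.csv")))
  }
  tick("spectra")

  bmax <- band_maximum(curve, config$window)
  shift <- solvatochromic_shift(model$e0, bmax)
  e1 <- dplyr::filter(sticks, .data$state == 1)$energy_ev
  tick("shift")

  report <- structure(list(
    variant = config$variant,
    kernel_form = config$kernel_form,
    n_snapshots = length(frames),
    band_max_ev = bmax,
    e_vac_ev = model$e0,
    delta_e_ev = shift$delta_e,
    e1_mean_ev = mean(e1),
    e1_sd_ev = stats::sd(e1),
    fwhm_ev = config$fwhm,
    seed = config$seed,
    timings_s = timings,
    files = if (length(files) > 0) {
      tibble::tibble(path = unname(files), md5 = unname(tools::md5sum(files)))
    } else tibble::tibble(path = character(0), md5 = character(0)),
    sticks = sticks,
    curve = curve
  ), class = "pipeline_report")

  if (!is.null(ws)) {
    rep_json <- report[c("variant", "kernel_form", "n_snapshots",
                         "band_max_ev", "e_vac_ev", "delta_e_ev",
                         "e1_mean_ev", "e1_sd_ev", "fwhm_ev", "seed")]
    rep_json$timings_s <- as.list(timings)
    rep_json$files <- report$files
    jsonlite::write_json(rep_json, file.path(ws, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> %s, %d snapshots\n", x$variant, x$n_snapshots))
  cat(sprintf("  band maximum : %.3f eV (gas phase %.2f eV)\n",
              x$band_max_ev, x$e_vac_ev))
  cat(sprintf("  shift        : %+.3f eV\n", x$delta_e_ev))
  cat(sprintf("  E1 dispersion: %.3f eV (sd over snapshots)\n", x$e1_sd_ev))
  invisible(x)
}

#' Compare force-field variants on identical snapshots
#'
#' Runs the pipeline once per configuration. All configurations must share
#' the same master seed and snapshot count so that every variant sees the
#' identical solvent ensemble; only the embedding (and anything downstream of
#' it) differs.
#'
#' @param configs a list of [pipeline_config()]s, or a single base
#'   configuration together with `variants`.
#' @param variants optional character vector of variants; each is run on a
#'   copy of the single base configuration.
#' @param out optional CSV path for the comparison table.
#' @return a `variant_comparison` tibble: `variant`, `delta_e_ev`,
#'   `band_max_ev`, `band_width_ev` (stick dispersion of the first state).
#' @export
compare_variants <- function(configs, variants = NULL, out = NULL) {
  if (inherits(configs, "pipeline_config")) {
    if (is.null(variants)) variants <- configs$variant
    base <- configs
    configs <- lapply(variants, function(v) {
      cfg <- base
      cfg$variant <- ff_variant(v)
      cfg
    })
  }
  seeds <- vapply(configs, function(cfg) cfg$seed, integer(1))
  nsnap <- vapply(configs, function(cfg) cfg$generator$n_snapshots, integer(1))
  if (length(unique(seeds)) != 1 || length(unique(nsnap)) != 1) {
    fq_abort("configurations must share the generator seed and snapshot count.",
             "fqembed_mismatched_snapshots")
  }
  rows <- purrr::map(configs, function(cfg) {
    rep <- run_pipeline(cfg)
    tibble::tibble(variant = rep$variant,
                   delta_e_ev = rep$delta_e_ev,
                   band_max_ev = rep$band_max_ev,
                   band_width_ev = rep$e1_sd_ev)
  })
  tab <- purrr::list_rbind(rows)
  class(tab) <- c("variant_comparison", class(tab))
  if (!is.null(out)) utils::write.csv(as.data.frame(tab), out,
                                      row.names = FALSE)
  tab
}
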