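# broom-style tidiers for the package's result objects.

#' Tidy an embedding solution
#'
#' @param x an `embedding_solution` from [solve_embedding()].
#' @param ... unused.
#' @return one row per site: `site`, `element`, coordinates, `molecule_id`,
#'   solved charge `q` and dipole components (NA for the charge-only variant).
#' @export
tidy.embedding_solution <- function(x, ...) {
  x$sites
}

#' @rdname tidy.embedding_solution
#' @return for `glance()`: a one-row summary with the variant, site and
#'   molecule counts, solver residual, total charge and the largest charge and
#'   dipole magnitudes.
#' @export
glance.embedding_solution <- function(x, ...) {
  mu <- solution_dipoles(x)
  tibble::tibble(
    variant = x$variant,
    kernel_form = x$kernel_form,
    n_sites = nrow(x$sites),
    n_molecules = length(unique(x$sites$molecule_id)),
    n_constraints = length(x$multipliers),
    residual = x$residual,
    total_charge = sum(x$sites$q),
    max_abs_q = max(abs(x$sites$q)),
    max_dipole_norm = if (is.null(mu)) NA_real_ else
      max(sqrt(rowSums(mu^2)))
  )
}

#' Tidy a pipeline report
#'
#' @param x a `pipeline_report` from [run_pipeline()].
#' @param ... unused.
#' @return a one-row tibble with the variant, snapshot count, band maximum,
#'   solvatochromic shift and first-band dispersion.
#' @export
tidy.pipeline_report <- function(x, ...) {
  tibble::tibble(
    variant = x$variant,
    n_snapshots = x$n_snapshots,
    e_vac_ev = x$e_vac_ev,
    band_max_ev = x$band_max_ev,
    delta_e_ev = x$delta_e_ev,
    e1_sd_ev = x$e1_sd_ev
  )
}

#' @rdname tidy.pipeline_report
#' @export
glance.pipeline_report <- function(x, ...) tidy.pipeline_report(x)
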