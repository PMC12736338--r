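# MM topology: a tibble of polarizable sites plus charge-constraint metadata.

#' Force-field parameter sets for polarizable water sites
#'
#' Returns per-element electronegativity `chi`, chemical hardness `eta` and
#' (for dipole-carrying force fields) isotropic polarizability `alpha`, all in
#' atomic units. The `"toy"` set is a self-consistent, numerically
#' well-conditioned parameterization used throughout the package's tests and
#' examples; it is not a literature water model. Named templates
#' (`"FQa"`, `"FQb"`, `"FQc"`, `"FQFmu"`) are returned with `NA` placeholders:
#' the published values live in the original parameterization papers and must
#' be filled in by the user before solving.
#'
#' @param set one of `"toy"`, `"FQa"`, `"FQb"`, `"FQc"`, `"FQFmu"`.
#' @return a tibble with columns `element`, `chi`, `eta`, `alpha` and a
#'   `placeholder` flag.
#' @export
fq_parameters <- function(set = "toy") {
  set <- match.arg(set, c("toy", "FQa", "FQb", "FQc", "FQFmu"))
  if (set == "toy") {
    return(tibble::tibble(
      element = c("O", "H"),
      chi   = c(0.18, 0.00),
      eta   = c(0.60, 0.70),
      alpha = c(6.00, 1.00),
      placeholder = FALSE
    ))
  }
  # templates only: values deliberately NA, to be supplied from the literature
  tibble::tibble(
    element = c("O", "H"),
    chi = NA_real_, eta = NA_real_,
    alpha = if (set == "FQFmu") NA_real_ else NA_real_,
    placeholder = TRUE
  )
}

#' Force-field variant labels
#'
#' `"FQ"` carries fluctuating charges only, with one total-charge constraint
#' per molecule. `"FQFMU"` adds induced point dipoles on every site.
#' `"FQFMU_CT"` keeps the dipoles but replaces the per-molecule constraints by
#' a single total-system constraint, allowing charge flow between solvent
#' molecules.
#'
#' @param variant character, partial-matched against the three labels.
#' @return the normalized variant string.
#' @export
ff_variant <- function(variant = c("FQ", "FQFMU", "FQFMU_CT")) {
  match.arg(toupper(variant[1]), c("FQ", "FQFMU", "FQFMU_CT"))
}

variant_uses_dipoles <- function(variant) variant %in% c("FQFMU", "FQFMU_CT")

#' Build an MM topology of polarizable sites
#'
#' @param sites a data frame with columns `x`, `y`, `z` (Angstrom), `element`,
#'   `chi`, `eta` (atomic units), `molecule_id` (integer grouping) and
#'   optionally `alpha` (atomic units, required by dipole-carrying variants).
#' @param molecule_charges target total charge per molecule, either a single
#'   number recycled to all molecules or a vector named by molecule id.
#'   Defaults to 0 (neutral solvent molecules).
#' @param system_charge target total charge for the charge-transfer variant;
#'   defaults to the sum of the molecule charges.
#' @return an `mm_topology` tibble (one row per site, `site` index added) with
#'   constraint metadata stored in attributes.
#' @export
mm_topology <- function(sites, molecule_charges = 0, system_charge = NULL) {
  sites <- tibble::as_tibble(sites)
  needed <- c("x", "y", "z", "element", "chi", "eta", "molecule_id")
  missing <- setdiff(needed, names(sites))
  if (length(missing) > 0) {
    fq_abort(paste0("`sites` is missing column(s): ",
                    paste(missing, collapse = ", ")), "fqembed_bad_topology")
  }
  if (!"alpha" %in% names(sites)) sites$alpha <- NA_real_
  pos <- as.matrix(sites[, c("x", "y", "z")])
  if (any(!is.finite(pos))) {
    fq_abort("site positions must be finite.", "fqembed_bad_topology")
  }
  if (any(is.na(sites$molecule_id))) {
    fq_abort("every site must belong to exactly one molecule.",
             "fqembed_bad_topology")
  }
  if (any(!is.finite(sites$eta)) || any(sites$eta <= 0)) {
    fq_abort("chemical hardness `eta` must be positive on every site.",
             "fqembed_bad_parameters")
  }
  if (any(!is.na(sites$alpha) & sites$alpha <= 0)) {
    fq_abort("polarizability `alpha` must be positive where present.",
             "fqembed_bad_parameters")
  }
  if (nrow(sites) > 1) {
    dmin <- min(dist(pos))
    if (dmin <= 0.1) {
      fq_abort(sprintf(
        "degenerate geometry: minimum site separation %.4f Angstrom <= 0.1.",
        dmin), "fqembed_degenerate_geometry")
    }
  }
  mol_ids <- sort(unique(sites$molecule_id))
  if (length(molecule_charges) == 1) {
    molecule_charges <- setNames(rep(molecule_charges, length(mol_ids)),
                                 mol_ids)
  } else {
    if (is.null(names(molecule_charges))) names(molecule_charges) <- mol_ids
    molecule_charges <- molecule_charges[as.character(mol_ids)]
    if (any(is.na(molecule_charges))) {
      fq_abort("`molecule_charges` must cover every molecule id.",
               "fqembed_bad_topology")
    }
  }
  sites$site <- seq_len(nrow(sites))
  sites <- sites[, c("site", "element", "x", "y", "z",
                     "chi", "eta", "alpha", "molecule_id")]
  structure(sites,
            class = c("mm_topology", class(tibble::tibble()))) |>
    set_topology_attrs(molecule_charges,
                       system_charge %||% sum(molecule_charges))
}

set_topology_attrs <- function(top, molecule_charges, system_charge) {
  attr(top, "molecule_charges") <- molecule_charges
  attr(top, "system_charge") <- system_charge
  top
}

#' Charge-constraint targets of a topology
#'
#' `molecule_charges()` returns the target total charge of each MM molecule
#' (named by molecule id); `system_charge()` the target total charge used by
#' the charge-transfer variant.
#'
#' @param topology an [mm_topology()].
#' @return numeric vector (named, one per molecule) or a single number.
#' @export
molecule_charges <- function(topology) attr(topology, "molecule_charges")

#' @rdname molecule_charges
#' @export
system_charge <- function(topology) attr(topology, "system_charge")

n_molecules <- function(topology) length(unique(topology$molecule_id))

topology_positions_bohr <- function(topology) {
  angstrom_to_bohr(as.matrix(topology[, c("x", "y", "z")]))
}

check_variant_topology <- function(topology, variant) {
  variant <- ff_variant(variant)
  has_alpha <- !is.na(topology$alpha)
  if (variant == "FQ" && any(has_alpha)) {
    fq_abort("variant FQ forbids `alpha`; drop the polarizabilities.",
             "fqembed_bad_parameters")
  }
  if (variant_uses_dipoles(variant) && !all(has_alpha)) {
    fq_abort(sprintf("variant %s requires `alpha` on all sites.", variant),
             "fqembed_bad_parameters")
  }
  if (any(!is.finite(topology$chi))) {
    fq_abort("electronegativities `chi` contain non-finite values (placeholder parameter set?).",
             "fqembed_bad_parameters")
  }
  invisible(variant)
}

#' Build the water MM topology of a snapshot
#'
#' Extracts the water molecules of a snapshot tibble (rows with
#' `role == "water"`) and attaches per-element force-field parameters.
#'
#' @param snapshot a snapshot tibble (see [generate_snapshots()]).
#' @param params a parameter tibble as returned by [fq_parameters()].
#' @param variant force-field variant; for `"FQ"` polarizabilities are not
#'   attached.
#' @return an `mm_topology` of the water sites, molecules neutral.
#' @export
water_topology <- function(snapshot, params = fq_parameters("toy"),
                           variant = "FQ") {
  variant <- ff_variant(variant)
  wat <- dplyr::filter(snapshot, .data$role == "water")
  if (nrow(wat) == 0) {
    fq_abort("snapshot contains no water molecules.", "fqembed_bad_topology")
  }
  wat <- dplyr::left_join(wat, params[, c("element", "chi", "eta", "alpha")],
                          by = "element")
  if (!variant_uses_dipoles(variant)) wat$alpha <- NA_real_
  # renumber molecules 1..M in order of appearance
  wat$molecule_id <- match(wat$molecule_id, unique(wat$molecule_id))
  mm_topology(wat[, c("x", "y", "z", "element", "chi", "eta", "alpha",
                      "molecule_id")])
}
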