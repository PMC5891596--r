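#' Build the point-charge model of system 2
#'
#' For electrostatic embedding the QM calculation is polarized by a set of
#' point charges: exactly the system-2 (MM) atoms, at their current
#' coordinates, with their charges from the supplied charge set.  CL atoms
#' belong to the QM region and are never included.  No charge deletion or
#' redistribution near the junction is applied.
#'
#' @param topology full-system [topology()] (for the atom count).
#' @param structure n x 3 coordinate matrix.
#' @param region_map [assign_regions()] result.
#' @param charge_set numeric charge vector (e) per full-system atom; defaults
#'   to the topology charges.
#' @return data frame of class `point_charges` with columns `x`, `y`, `z`
#'   (Angstrom), `q` (e) and `atom` (full-system index).
#' @export
build_point_charge_model <- function(topology, structure, region_map,
                                     charge_set = NULL) {
  q <- if (is.null(charge_set)) topology$atoms$charge else as.numeric(charge_set)
  stopifnot(length(q) == n_atoms(topology))
  x <- as.matrix(structure)
  mm <- which(region_map$region == "MM")
  out <- data.frame(x = x[mm, 1], y = x[mm, 2], z = x[mm, 3],
                    q = q[mm], atom = mm)
  rownames(out) <- NULL
  class(out) <- c("point_charges", class(out))
  out
}

#' Zero the charges of one region
#'
#' Used by the electrostatic-embedding MM terms, where the QM-region charges
#' are set to zero to avoid double counting the electrostatics already
#' present in the embedded QM calculation.
#'
#' @param charge_set numeric charge vector (e).
#' @param region_map [assign_regions()] result.
#' @param which_region `"QM"` or `"MM"`.
#' @return charge vector with the selected region zeroed.
#' @export
zero_region_charges <- function(charge_set, region_map, which_region = "QM") {
  q <- as.numeric(charge_set)
  q[region_map$region == which_region] <- 0
  q
}

#' Merge QM-derived charges into a full-system charge set (mechanical embedding)
#'
#' Implements the charge-merging procedure for mechanical embedding: QM atoms
#' (except the link atoms) take their QM-derived charges, MM atoms keep their
#' original MM charges, and for each biochemical unit containing CL atoms a
#' constant offset is added to each CL atom's original MM charge so that the
#' unit's total charge equals its original integer total (plus a declared
#' integer charge external to the unit).  When a unit holds several CL atoms
#' the residual is split equally among them.  Charge transfer across the QM
#' region is allowed: individual QM residues need not end at integer charge,
#' but the full-system total is conserved.
#'
#' @param mm_charges original MM charge vector (e), full system.
#' @param qm_charges QM-derived charges, full-length vector with finite
#'   values at least for the non-CL QM atoms.
#' @param region_map [assign_regions()] result.
#' @param unit_partition integer/factor assigning every atom to a biochemical
#'   unit (e.g. the residue index); defaults to a single unit.
#' @param unit_targets optional numeric vector of target total charges per
#'   unit (in `sort(unique(unit_partition))` order); defaults to the rounded
#'   original MM total of each unit (which must be integer to 1e-4 e).
#' @param external_integer_charge integer charge external to the QM system
#'   added to the target of units containing CL atoms (default 0).
#' @param tol conservation tolerance (e).
#' @return list with `charges` (merged vector), `offsets` (per-CL offset,
#'   junction order), `provenance` (character per atom).
#' @export
merge_charges_me <- function(mm_charges, qm_charges, region_map,
                             unit_partition = NULL,
                             unit_targets = NULL,
                             external_integer_charge = 0, tol = 1e-4) {
  n <- length(region_map$region)
  mm_charges <- as.numeric(mm_charges)
  qm_charges <- as.numeric(qm_charges)
  stopifnot(length(mm_charges) == n, length(qm_charges) == n)
  if (is.null(unit_partition)) unit_partition <- rep(1L, n)
  units <- sort(unique(unit_partition))
  cl_atoms <- region_map$junctions$cl
  is_qm <- region_map$region == "QM"

  merged <- mm_charges
  prov <- rep("mm_original", n)
  take_qm <- is_qm & !(seq_len(n) %in% cl_atoms)
  if (any(!is.finite(qm_charges[take_qm])))
    stop("missing QM-derived charge for QM atom(s) ",
         paste(which(take_qm & !is.finite(qm_charges)), collapse = ", "))
  merged[take_qm] <- qm_charges[take_qm]
  prov[take_qm] <- "qm_derived"

  offsets <- rep(NA_real_, length(cl_atoms))
  for (ui in seq_along(units)) {
    members <- which(unit_partition == units[ui])
    target <- if (is.null(unit_targets)) {
      t0 <- sum(mm_charges[members])
      ## printed charge sets carry ~1e-4 rounding per atom; 5e-4 covers the
      ## accumulated rounding of a small unit when detecting the integer total
      if (abs(t0 - round(t0)) > 5e-4)
        stop(sprintf("unit %s has non-integer original MM total %.6f; supply unit_targets",
                     as.character(units[ui]), t0))
      round(t0)
    } else unit_targets[ui]
    unit_cl <- intersect(members, cl_atoms)
    if (length(unit_cl) > 0) target <- target + external_integer_charge
    residual <- target - sum(merged[members])
    if (length(unit_cl) == 0) {
      if (abs(residual) > tol)
        stop(sprintf("conservation error: unit %s has residual %.6f e but no CL atom to absorb it",
                     as.character(units[ui]), residual))
      next
    }
    off <- residual / length(unit_cl)
    merged[unit_cl] <- merged[unit_cl] + off
    prov[unit_cl] <- "merged"
    offsets[match(unit_cl, cl_atoms)] <- off
  }
  list(charges = merged, offsets = offsets, provenance = prov)
}

#' Copy QM-derived HL charges into a link spec
#'
#' @param qm_hl_charges numeric, one QM-derived HL charge (e) per junction.
#' @param link_specs [link_spec()] result.
#' @return the link spec with `hl_charge` filled in.
#' @export
assign_hl_charges <- function(qm_hl_charges, link_specs) {
  qm_hl_charges <- as.numeric(qm_hl_charges)
  if (length(qm_hl_charges) != nrow(link_specs))
    stop(sprintf("HL charge count (%d) does not match junction count (%d)",
                 length(qm_hl_charges), nrow(link_specs)))
  if (any(!is.finite(qm_hl_charges))) stop("missing HL charge value")
  link_specs$hl_charge <- qm_hl_charges
  link_specs
}
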