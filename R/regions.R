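#' Partition atoms into QM and MM regions
#'
#' The QM region (system 1) is the user's atom selection; everything else is
#' the MM region (system 2).  Junction (carbon-link) atoms are auto-detected:
#' a CL atom is a QM atom bonded to at least one MM atom.  Each CL must be
#' bonded to exactly one QM atom that is not itself a CL — its Q1 atom — and
#' every bond crossing the QM/MM boundary must pass through a CL.  Covalently
#' bonded CL pairs are supported but flagged with a warning (they require
#' cross-junction term removal in the truncated topology and are discouraged).
#'
#' @param topology a [topology()] object.
#' @param qm_atom_selection integer vector of QM atom indices (the selection
#'   includes the CL atoms).
#' @return a `region_map`: list with `region` (character vector, "QM"/"MM"
#'   per atom), `junctions` (data frame `q1`, `cl`), `cl_cl_bonds` (data
#'   frame of bonded CL pairs, possibly empty), and neighbor shells `q2`
#'   (QM neighbors of any Q1 other than CL), `m2` (list of MM neighbors per
#'   junction CL).
#' @export
assign_regions <- function(topology, qm_atom_selection) {
  n <- n_atoms(topology)
  sel <- unique(as.integer(qm_atom_selection))
  if (length(sel) == 0) stop("empty QM selection")
  if (any(sel < 1 | sel > n)) stop("QM selection index outside 1..", n)
  region <- rep("MM", n)
  region[sel] <- "QM"
  adj <- lapply(seq_len(n), function(i)
    c(topology$bonds$j[topology$bonds$i == i], topology$bonds$i[topology$bonds$j == i]))
  is_qm <- region == "QM"
  cl <- which(is_qm & vapply(seq_len(n), function(i) any(!is_qm[adj[[i]]]), logical(1)))
  ## every QM-MM bond must involve a CL on the QM side (true by construction
  ## of cl above); the remaining rule is the unique-Q1 condition.
  junctions <- data.frame(q1 = integer(), cl = integer())
  m2 <- list()
  for (c_at in cl) {
    qm_nb <- adj[[c_at]][is_qm[adj[[c_at]]]]
    q1 <- setdiff(qm_nb, cl)
    if (length(q1) == 0)
      stop(sprintf("region error: CL atom %d has no non-CL QM neighbor to act as Q1", c_at))
    if (length(q1) > 1)
      stop(sprintf("region error: CL atom %d is bonded to %d QM atoms (%s); Q1 must be unique",
                   c_at, length(q1), paste(q1, collapse = ",")))
    junctions <- rbind(junctions, data.frame(q1 = q1, cl = c_at))
    m2[[length(m2) + 1]] <- adj[[c_at]][!is_qm[adj[[c_at]]]]
  }
  clcl <- topology$bonds[topology$bonds$i %in% cl & topology$bonds$j %in% cl,
                         c("i", "j"), drop = FALSE]
  rownames(clcl) <- NULL
  if (nrow(clcl) > 0)
    warning("covalently bonded CL atoms detected (",
            paste(sprintf("%d-%d", clcl$i, clcl$j), collapse = ", "),
            "); cross-junction bonded terms will be removed from the truncated ",
            "topology. Bonded CL atoms are discouraged.")
  q2 <- unique(unlist(lapply(junctions$q1, function(q) {
    setdiff(adj[[q]][is_qm[adj[[q]]]], c(cl, junctions$q1))
  })))
  structure(list(region = region, junctions = junctions,
                 cl_cl_bonds = clcl, q2 = sort(q2), m2 = m2),
            class = "region_map")
}

#' @export
print.region_map <- function(x, ...) {
  cat(sprintf("Region map: %d QM / %d MM atoms, %d junction(s)\n",
              sum(x$region == "QM"), sum(x$region == "MM"), nrow(x$junctions)))
  if (nrow(x$junctions) > 0)
    cat("  junctions (Q1, CL):",
        paste(sprintf("(%d,%d)", x$junctions$q1, x$junctions$cl), collapse = " "), "\n")
  invisible(x)
}

#' Per-junction link-atom specification
#'
#' Collects, for every junction of a region map, the geometric and parametric
#' link data: the force-field equilibrium Q1-CL length `r0_cl` (looked up in
#' the topology's bond list), the QM-ideal Q1-HL length `r0_hl` (a user
#' input, obtained once from a QM optimization of the truncated residue), the
#' derived scale ratio `g = r0_hl / r0_cl`, the HL van der Waals atom-type
#' label, and an optional HL charge for mechanical embedding / ELAC.
#'
#' @param topology full-system [topology()].
#' @param region_map [assign_regions()] result.
#' @param r0_hl numeric, one ideal Q1-HL bond length (Angstrom) per junction
#'   (recycled if length 1).
#' @param hl_type HL atom-type label(s); must resolve in the LJ table of the
#'   topology the HL is placed into (default `"hl"`, a generic aliphatic-H
#'   type present in the built-in parameter set).
#' @param hl_charge optional HL charge(s) (e).
#' @return data frame of class `link_spec` with one row per junction:
#'   `q1`, `cl`, `r0_cl`, `r0_hl`, `g`, `kb_cl`, `hl_type`, `hl_charge`.
#' @export
link_spec <- function(topology, region_map, r0_hl, hl_type = "hl",
                      hl_charge = NA_real_) {
  jn <- region_map$junctions
  nj <- nrow(jn)
  if (nj == 0) {
    out <- data.frame(q1 = integer(), cl = integer(), r0_cl = numeric(),
                      r0_hl = numeric(), g = numeric(), kb_cl = numeric(),
                      hl_type = character(), hl_charge = numeric())
    class(out) <- c("link_spec", class(out))
    return(out)
  }
  r0_hl <- rep_len(as.numeric(r0_hl), nj)
  hl_type <- rep_len(as.character(hl_type), nj)
  hl_charge <- rep_len(as.numeric(hl_charge), nj)
  if (any(r0_hl <= 0)) stop("r0_hl must be positive")
  b <- topology$bonds
  r0_cl <- kb_cl <- numeric(nj)
  for (r in seq_len(nj)) {
    hit <- which((b$i == jn$q1[r] & b$j == jn$cl[r]) |
                 (b$j == jn$q1[r] & b$i == jn$cl[r]))
    if (length(hit) != 1)
      stop(sprintf("no unique Q1-CL bond term for junction (%d,%d)", jn$q1[r], jn$cl[r]))
    r0_cl[r] <- b$r0[hit]
    kb_cl[r] <- b$kb[hit]
  }
  g <- r0_hl / r0_cl
  if (any(g <= 0 | g >= 1))
    warning("link scale ratio g outside (0,1) for junction(s) ",
            paste(which(g <= 0 | g >= 1), collapse = ", "))
  out <- data.frame(q1 = jn$q1, cl = jn$cl, r0_cl = r0_cl, r0_hl = r0_hl,
                    g = g, kb_cl = kb_cl, hl_type = hl_type, hl_charge = hl_charge)
  class(out) <- c("link_spec", class(out))
  out
}

#' Place hydrogen link atoms along the Q1-CL bonds
#'
#' Each HL atom is placed on the Q1->CL ray at the scaled distance
#' `r_Q1-HL = r_Q1-CL * r0_HL / r0_CL`, i.e. `HL = Q1 + g (CL - Q1)` with the
#' geometry-independent constant `g = r0_HL / r0_CL`.  The HL therefore
#' introduces no new degrees of freedom: its coordinates are a fixed linear
#' map of the real atoms'.
#'
#' @param structure full-system n x 3 coordinate matrix.
#' @param region_map [assign_regions()] result.
#' @param link_specs [link_spec()] result.
#' @return list with `coords` (n1 x 3 coordinates of system 1, HL replacing
#'   CL in place), `map` (full-system atom index per row; CL indices at HL
#'   rows), `hl_rows` (row index of each junction's HL, junction order),
#'   `is_hl` (logical per row).
#' @export
place_link_atoms <- function(structure, region_map, link_specs) {
  x <- as.matrix(structure)
  qm_idx <- which(region_map$region == "QM")
  coords <- x[qm_idx, , drop = FALSE]
  is_hl <- logical(length(qm_idx))
  hl_rows <- integer(nrow(link_specs))
  for (r in seq_len(nrow(link_specs))) {
    q1 <- link_specs$q1[r]; cl <- link_specs$cl[r]
    v <- x[cl, ] - x[q1, ]
    if (sqrt(sum(v * v)) < 1e-10)
      stop(sprintf("geometry error: zero-length Q1-CL vector for junction (%d,%d)", q1, cl))
    row <- match(cl, qm_idx)
    coords[row, ] <- x[q1, ] + link_specs$g[r] * v
    is_hl[row] <- TRUE
    hl_rows[r] <- row
  }
  list(coords = coords, map = qm_idx, hl_rows = hl_rows, is_hl = is_hl)
}

#' Project HL gradient components onto the real atoms
#'
#' Because `HL = Q1 + g (CL - Q1)` with constant `g`, the chain rule maps a
#' gradient on the HL atom onto the real atoms as `dE/dCL += g dE/dHL` and
#' `dE/dQ1 += (1 - g) dE/dHL`.  Gradient rows of non-HL system-1 atoms map
#' through unchanged.
#'
#' @param gradient_with_hl n1 x 3 gradient on system-1 atoms (HL rows at the
#'   CL slots, as produced by [place_link_atoms()]).
#' @param region_map [assign_regions()] result.
#' @param link_specs [link_spec()] result.
#' @param placement result of [place_link_atoms()] (for the row map).
#' @param n_full number of atoms in the full system.
#' @return n_full x 3 gradient contribution on real atoms.
#' @export
project_link_gradient <- function(gradient_with_hl, region_map, link_specs,
                                  placement, n_full) {
  g_full <- matrix(0, n_full, 3)
  rows_plain <- which(!placement$is_hl)
  g_full[placement$map[rows_plain], ] <- gradient_with_hl[rows_plain, , drop = FALSE]
  for (r in seq_len(nrow(link_specs))) {
    ghl <- gradient_with_hl[placement$hl_rows[r], ]
    g <- link_specs$g[r]
    g_full[link_specs$cl[r], ] <- g_full[link_specs$cl[r], ] + g * ghl
    g_full[link_specs$q1[r], ] <- g_full[link_specs$q1[r], ] + (1 - g) * ghl
  }
  g_full
}

#' Scaled force constant for the Q1-HL link bond
#'
#' Returns the unique harmonic force constant that makes the Q1-HL bond
#' energy, evaluated at the scaled HL position, equal to the Q1-CL bond
#' energy at the CL position for every Q1-CL distance:
#' `k_HL = k_CL (r0_CL / r0_HL)^2`.  With `r_HL = g r_CL` and
#' `g = r0_HL/r0_CL`, `k_HL (g r_CL - r0_HL)^2 = k_CL (r_CL - r0_CL)^2`
#' identically; any other constant introduces a spurious link-bond force.
#'
#' @param k_cl Q1-CL force constant (kcal/mol/A^2).
#' @param r0_cl force-field equilibrium Q1-CL length (A).
#' @param r0_hl QM-ideal Q1-HL length (A).
#' @return k_HL (kcal/mol/A^2).
#' @export
scale_link_force_constant <- function(k_cl, r0_cl, r0_hl) {
  if (any(c(k_cl, r0_cl, r0_hl) <= 0)) stop("scale_link_force_constant: inputs must be positive")
  k_cl * (r0_cl / r0_hl)^2
}
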