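#' Generate the truncated link-atom topology for system 1
#'
#' Re-implements the automatic truncated-prmtop generation: the output
#' topology contains exactly the system-1 atoms, with every CL atom
#' converted in place to a hydrogen link atom (HL).  Bonded terms are all
#' terms of the full topology whose atoms lie entirely in system 1, with
#' CL-involving terms re-expressed on the HL:
#'
#' * the Q1-HL bond gets equilibrium length `r0_HL` and the force constant
#'   from [scale_link_force_constant()] (so its energy at the scaled HL
#'   position equals the Q1-CL bond energy at the CL position for every
#'   geometry);
#' * Q2-Q1-HL angles and Q3-Q2-Q1-HL dihedrals copy the corresponding ...-CL
#'   parameters unchanged (the HL lies on the Q1-CL ray, so these terms
#'   evaluate identically on HL and CL coordinates and cancel exactly
#'   between the two MM calculations of the subtractive scheme);
#' * for covalently bonded CL pairs, the CL-CL bond and every angle/dihedral
#'   whose bond path uses it are removed (the paper's DMDT complication);
#' * the HL atom takes the link spec's hydrogen van der Waals type and a mass
#'   of 1.008 amu;
#' * exclusions and 1-4 pairs are regenerated from the truncated
#'   connectivity.
#'
#' Charge handling (`charges`): `"zero"` zeroes every charge (the
#' electrostatic-embedding small-system term runs without electrostatics);
#' `"keep"` keeps original MM charges with the HL inheriting the CL charge
#' (the matched-charge mode that makes mechanical embedding collapse onto the
#' plain MM energy); `"qm"` uses a QM-derived charge set for the QM atoms and
#' the link spec's `hl_charge` for each HL (mechanical embedding / ELAC).
#'
#' @param full_topology full-system [topology()].
#' @param region_map [assign_regions()] result.
#' @param link_specs [link_spec()] result.
#' @param charges one of `"zero"`, `"keep"`, `"qm"`.
#' @param qm_charges named or full-length numeric vector of QM-derived
#'   charges indexed by full-system atom index (required for
#'   `charges = "qm"`; only QM-region entries are used, HL values come from
#'   `link_specs$hl_charge`).
#' @return list with `topology` (the truncated [topology()]), `map`
#'   (full-system index per truncated atom), `hl_rows`, `is_hl`.
#' @export
build_truncated_topology <- function(full_topology, region_map, link_specs,
                                     charges = c("zero", "keep", "qm"),
                                     qm_charges = NULL) {
  charges <- match.arg(charges)
  qm_idx <- which(region_map$region == "QM")
  map <- qm_idx                       # truncated row -> full index
  back <- match(seq_len(n_atoms(full_topology)), qm_idx)  # full -> truncated row
  cl_atoms <- link_specs$cl
  if (any(link_specs$q1 %in% cl_atoms))
    stop("unsupported topology: a junction Q1 atom is itself a CL atom")

  atoms <- full_topology$atoms[qm_idx, , drop = FALSE]
  rownames(atoms) <- NULL
  is_hl <- map %in% cl_atoms
  hl_rows <- match(cl_atoms, map)
  for (r in seq_along(hl_rows)) {
    row <- hl_rows[r]
    atoms$name[row] <- sprintf("HL%d", r)
    atoms$element[row] <- "H"
    atoms$type[row] <- link_specs$hl_type[r]
    atoms$mass[row] <- 1.008
  }
  atoms$charge <- switch(charges,
    zero = rep(0, nrow(atoms)),
    keep = atoms$charge,
    qm = {
      if (is.null(qm_charges)) stop("charges = 'qm' requires qm_charges")
      q <- as.numeric(qm_charges[map])
      q[hl_rows] <- link_specs$hl_charge
      if (any(!is.finite(q)))
        stop("missing QM-derived charge for truncated atom(s) ",
             paste(map[!is.finite(q)], collapse = ", "))
      q
    })

  in_s1 <- function(df, cols) {
    if (nrow(df) == 0) return(logical(0))
    Reduce(`&`, lapply(cols, function(cl) region_map$region[df[[cl]]] == "QM"))
  }
  ## drop terms whose bond path runs through a removed CL-CL bond
  uses_clcl <- function(df, cols) {
    if (nrow(df) == 0 || nrow(region_map$cl_cl_bonds) == 0)
      return(rep(FALSE, nrow(df)))
    bad <- rep(FALSE, nrow(df))
    for (r in seq_len(nrow(region_map$cl_cl_bonds))) {
      a <- region_map$cl_cl_bonds$i[r]; b <- region_map$cl_cl_bonds$j[r]
      for (s in seq_len(length(cols) - 1)) {
        p1 <- df[[cols[s]]]; p2 <- df[[cols[s + 1]]]
        bad <- bad | (p1 == a & p2 == b) | (p1 == b & p2 == a)
      }
    }
    bad
  }

  bonds <- full_topology$bonds
  keep <- in_s1(bonds, c("i", "j")) & !uses_clcl(bonds, c("i", "j"))
  bonds <- bonds[keep, , drop = FALSE]
  angles <- full_topology$angles
  keep <- in_s1(angles, c("i", "j", "k")) & !uses_clcl(angles, c("i", "j", "k"))
  angles <- angles[keep, , drop = FALSE]
  dihedrals <- full_topology$dihedrals
  keep <- in_s1(dihedrals, c("i", "j", "k", "l")) &
    !uses_clcl(dihedrals, c("i", "j", "k", "l"))
  dihedrals <- dihedrals[keep, , drop = FALSE]

  ## Q1-HL bond: scaled force constant, QM-ideal equilibrium length
  for (r in seq_len(nrow(link_specs))) {
    q1 <- link_specs$q1[r]; cl <- link_specs$cl[r]
    hit <- which((bonds$i == q1 & bonds$j == cl) | (bonds$j == q1 & bonds$i == cl))
    bonds$r0[hit] <- link_specs$r0_hl[r]
    bonds$kb[hit] <- scale_link_force_constant(link_specs$kb_cl[r],
                                               link_specs$r0_cl[r],
                                               link_specs$r0_hl[r])
  }

  reindex <- function(df, cols) {
    for (cl in cols) df[[cl]] <- back[df[[cl]]]
    df
  }
  bonds <- reindex(bonds, c("i", "j"))
  angles <- reindex(angles, c("i", "j", "k"))
  dihedrals <- reindex(dihedrals, c("i", "j", "k", "l"))

  lj <- full_topology$lj
  missing_hl <- setdiff(unique(link_specs$hl_type), lj$type)
  if (length(missing_hl))
    stop("missing LJ parameters for HL type(s) ", paste(missing_hl, collapse = ", "))

  top <- topology(atoms, lj, bonds, angles, dihedrals,
                  scee = full_topology$scee, scnb = full_topology$scnb,
                  title = paste(full_topology$title, "(truncated system 1)"))
  list(topology = top, map = map, hl_rows = hl_rows, is_hl = is_hl)
}
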