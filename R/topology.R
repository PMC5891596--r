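#' Molecular-mechanics topology
#'
#' A `topology` object is the single source of truth for force-field
#' parameters and connectivity of one system (full or truncated).  It holds,
#' in internal units (Angstrom, kcal/mol, electron charges, radians):
#'
#' * `atoms`: data frame with `name`, `element`, `type` (atom-type label),
#'   `mass` (amu), `charge` (e), `res_id`, `res_name`;
#' * `lj`: per atom-type Lennard-Jones parameters `type`, `rmin_half`
#'   (Rmin/2, Angstrom), `eps` (kcal/mol), combined with Lorentz-Berthelot
#'   rules (`Rmin_ij = Rmin/2_i + Rmin/2_j`, `eps_ij = sqrt(eps_i eps_j)`);
#' * `bonds`: `i`, `j`, `kb` (kcal/mol/A^2), `r0` (A); the harmonic form is
#'   `E = kb (r - r0)^2` without a 1/2 factor, the AMBER convention;
#' * `angles`: `i`, `j`, `k`, `kth` (kcal/mol/rad^2), `th0` (rad),
#'   `E = kth (theta - th0)^2`;
#' * `dihedrals`: `i`, `j`, `k`, `l`, `vn2` (barrier V_n/2, kcal/mol),
#'   `per` (periodicity), `phase` (rad); several rows may share one atom
#'   quadruple (multi-term Fourier series);
#' * `excl`: 1-2 and 1-3 pairs, fully excluded from nonbonded terms;
#' * `pairs14`: 1-4 pairs with electrostatic (`scee`) and van der Waals
#'   (`scnb`) scale divisors (interaction divided by the divisor).
#'
#' Atom indices are 1-based throughout; prmtop pointer conventions are
#' converted at the I/O boundary.
#'
#' @param atoms data frame as described above.
#' @param lj data frame of per-type Lennard-Jones parameters.
#' @param bonds,angles,dihedrals bonded-term data frames.
#' @param excl,pairs14 optional explicit nonbonded bookkeeping; when `NULL`
#'   both are derived from the bond graph (topological distance 1-2/1-3
#'   excluded, distance 3 scaled 1-4, counted once).
#' @param scee,scnb default 1-4 scale divisors used when deriving `pairs14`.
#' @param title free-text title.
#' @return an object of class `topology`.
#' @export
topology <- function(atoms, lj, bonds, angles, dihedrals,
                     excl = NULL, pairs14 = NULL,
                     scee = DEFAULT_SCEE, scnb = DEFAULT_SCNB,
                     title = "qmmlink topology") {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  bonds <- canonical_bonds(as.data.frame(bonds))
  angles <- canonical_angles(as.data.frame(angles))
  dihedrals <- canonical_dihedrals(as.data.frame(dihedrals))
  if (is.null(excl) || is.null(pairs14)) {
    nb <- derive_nonbonded(bonds, nrow(atoms), scee, scnb)
    if (is.null(excl)) excl <- nb$excl
    if (is.null(pairs14)) pairs14 <- nb$pairs14
  }
  top <- structure(list(
    atoms = atoms, lj = as.data.frame(lj, stringsAsFactors = FALSE),
    bonds = bonds, angles = angles, dihedrals = dihedrals,
    excl = canonical_pairs(as.data.frame(excl)),
    pairs14 = canonical_pairs(as.data.frame(pairs14)),
    scee = scee, scnb = scnb, title = title
  ), class = "topology")
  top
}

#' @export
print.topology <- function(x, ...) {
  cat(sprintf("MM topology: %d atoms, %d bonds, %d angles, %d dihedral terms\n",
              nrow(x$atoms), nrow(x$bonds), nrow(x$angles), nrow(x$dihedrals)))
  cat(sprintf("  exclusions: %d, 1-4 pairs: %d (scee %.3g, scnb %.3g)\n",
              nrow(x$excl), nrow(x$pairs14), x$scee, x$scnb))
  invisible(x)
}

n_atoms <- function(topology) nrow(topology$atoms)

canonical_bonds <- function(b) {
  if (nrow(b) == 0) return(data.frame(i = integer(), j = integer(),
                                      kb = numeric(), r0 = numeric()))
  swap <- b$i > b$j
  tmp <- b$i[swap]; b$i[swap] <- b$j[swap]; b$j[swap] <- tmp
  b <- b[order(b$i, b$j), , drop = FALSE]
  rownames(b) <- NULL
  b
}

canonical_angles <- function(a) {
  if (nrow(a) == 0) return(data.frame(i = integer(), j = integer(), k = integer(),
                                      kth = numeric(), th0 = numeric()))
  swap <- a$i > a$k
  tmp <- a$i[swap]; a$i[swap] <- a$k[swap]; a$k[swap] <- tmp
  a <- a[order(a$j, a$i, a$k), , drop = FALSE]
  rownames(a) <- NULL
  a
}

canonical_dihedrals <- function(d) {
  if (nrow(d) == 0) return(data.frame(i = integer(), j = integer(), k = integer(),
                                      l = integer(), vn2 = numeric(),
                                      per = numeric(), phase = numeric()))
  swap <- d$j > d$k | (d$j == d$k & d$i > d$l)
  for (cols in list(c("i", "l"), c("j", "k"))) {
    tmp <- d[[cols[1]]][swap]
    d[[cols[1]]][swap] <- d[[cols[2]]][swap]
    d[[cols[2]]][swap] <- tmp
  }
  d <- d[order(d$j, d$k, d$i, d$l, d$per), , drop = FALSE]
  rownames(d) <- NULL
  d
}

canonical_pairs <- function(p) {
  if (is.null(p) || nrow(p) == 0) {
    out <- data.frame(i = integer(), j = integer())
    if (!is.null(p) && all(c("scee", "scnb") %in% names(p))) {
      out$scee <- numeric(); out$scnb <- numeric()
    }
    return(out)
  }
  swap <- p$i > p$j
  tmp <- p$i[swap]; p$i[swap] <- p$j[swap]; p$j[swap] <- tmp
  p <- p[order(p$i, p$j), , drop = FALSE]
  rownames(p) <- NULL
  p
}

## Topological distances over the bond graph, up to distance 3.
bond_graph_distance <- function(bonds, n) {
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  if (nrow(bonds) > 0) {
    for (r in seq_len(nrow(bonds))) d[bonds$i[r], bonds$j[r]] <- d[bonds$j[r], bonds$i[r]] <- 1
  }
  for (step in 2:3) {
    idx <- which(d == step - 1, arr.ind = TRUE)
    for (r in seq_len(nrow(idx))) {
      a <- idx[r, 1]
      nb <- which(d[idx[r, 2], ] == 1)
      upd <- nb[d[a, nb] > step]
      d[a, upd] <- step
    }
  }
  d
}

derive_nonbonded <- function(bonds, n, scee = DEFAULT_SCEE, scnb = DEFAULT_SCNB) {
  d <- bond_graph_distance(bonds, n)
  excl <- which(upper.tri(d) & (d == 1 | d == 2), arr.ind = TRUE)
  p14 <- which(upper.tri(d) & d == 3, arr.ind = TRUE)
  list(
    excl = data.frame(i = excl[, 1], j = excl[, 2]),
    pairs14 = data.frame(i = p14[, 1], j = p14[, 2],
                         scee = rep(scee, nrow(p14)), scnb = rep(scnb, nrow(p14)))
  )
}

#' Validate a topology against its structural invariants
#'
#' Reports (never throws) violations of the `topology` invariants: term
#' indices inside the atom range, no duplicated bonds/angles (after canonical
#' ordering), 1-4 pairs listed exactly once and disjoint from the exclusion
#' list, nonnegative Lennard-Jones parameters, positive masses, finite
#' charges, and every atom type resolvable in the LJ table.
#'
#' @param topology a [topology()] object.
#' @return character vector of violation messages; empty if the topology is
#'   valid.
#' @export
validate_topology <- function(topology) {
  v <- character()
  n <- n_atoms(topology)
  chk_range <- function(df, cols, what) {
    for (cl in cols) {
      bad <- df[[cl]] < 1 | df[[cl]] > n | df[[cl]] != round(df[[cl]])
      if (any(bad)) v <<- c(v, sprintf("%s rows %s reference atom index outside 1..%d",
                                       what, paste(which(bad), collapse = ","), n))
    }
  }
  chk_range(topology$bonds, c("i", "j"), "bond")
  chk_range(topology$angles, c("i", "j", "k"), "angle")
  chk_range(topology$dihedrals, c("i", "j", "k", "l"), "dihedral")
  chk_range(topology$excl, c("i", "j"), "exclusion")
  chk_range(topology$pairs14, c("i", "j"), "1-4 pair")
  if (length(v)) return(v)  # index errors make the remaining checks unsafe

  key <- function(...) paste(..., sep = "-")
  bk <- key(topology$bonds$i, topology$bonds$j)
  if (anyDuplicated(bk))
    v <- c(v, sprintf("duplicated bond %s", paste(unique(bk[duplicated(bk)]), collapse = ", ")))
  ak <- key(topology$angles$i, topology$angles$j, topology$angles$k)
  if (anyDuplicated(ak))
    v <- c(v, sprintf("duplicated angle %s", paste(unique(ak[duplicated(ak)]), collapse = ", ")))
  dk <- key(topology$dihedrals$i, topology$dihedrals$j, topology$dihedrals$k,
            topology$dihedrals$l, topology$dihedrals$per)
  if (anyDuplicated(dk))
    v <- c(v, sprintf("duplicated dihedral term %s", paste(unique(dk[duplicated(dk)]), collapse = ", ")))
  ek <- key(topology$excl$i, topology$excl$j)
  if (anyDuplicated(ek))
    v <- c(v, "duplicated exclusion pair")
  pk <- key(topology$pairs14$i, topology$pairs14$j)
  if (anyDuplicated(pk))
    v <- c(v, "1-4 pair listed more than once")
  both <- intersect(pk, ek)
  if (length(both))
    v <- c(v, sprintf("pair %s is both excluded and a 1-4 pair", paste(both, collapse = ", ")))
  if (any(topology$excl$i == topology$excl$j))
    v <- c(v, "self exclusion")
  if (any(topology$atoms$mass <= 0))
    v <- c(v, "nonpositive atom mass")
  if (any(topology$lj$rmin_half < 0) || any(topology$lj$eps < 0))
    v <- c(v, "negative Lennard-Jones parameter")
  if (any(!is.finite(topology$atoms$charge)))
    v <- c(v, "non-finite charge")
  missing_type <- setdiff(unique(topology$atoms$type), topology$lj$type)
  if (length(missing_type))
    v <- c(v, sprintf("atom type(s) %s missing from LJ table", paste(missing_type, collapse = ", ")))
  v
}

## Per-atom LJ parameters, in atom order.
atom_lj <- function(topology) {
  idx <- match(topology$atoms$type, topology$lj$type)
  if (anyNA(idx)) stop("atom type(s) missing from LJ table: ",
                       paste(unique(topology$atoms$type[is.na(idx)]), collapse = ", "))
  list(rmin_half = topology$lj$rmin_half[idx], eps = topology$lj$eps[idx])
}
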