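#' Minimize a QM/MM scheme energy with the MM region frozen
#'
#' Deterministic quasi-Newton (L-BFGS-B) minimization of a scheme total
#' energy over the free atoms, with the frozen set (by default the whole MM
#' region) held bitwise fixed.  Optional harmonic distance restraints
#' `k (r - r_target)^2` support potential-energy scans along a chosen
#' coordinate.
#'
#' @param sys a [qmmm_system()].
#' @param scheme scheme name passed to [qmmm_energy()].
#' @param backend QM backend.
#' @param frozen integer vector of frozen atom indices (default: all MM
#'   atoms).
#' @param restraints data frame with columns `i`, `j`, `target` (Angstrom),
#'   `k` (kcal/mol/A^2), or `NULL`.
#' @param max_grad convergence threshold on the largest free-atom gradient
#'   component (kcal/mol/A).
#' @param rms_grad threshold on the free-atom RMS gradient.
#' @param max_iter iteration cap.
#' @param ... further arguments passed to [qmmm_energy()] (e.g.
#'   `matched_charges`, `blac`).
#' @return list with `structure` (optimized coordinates), `energy`,
#'   `trajectory` (energies of accepted steps), `converged`, `max_grad`,
#'   `rms_grad`, `iterations`.
#' @export
minimize <- function(sys, scheme = "sub", backend = surrogate_backend(),
                     frozen = NULL, restraints = NULL,
                     max_grad = 4.5e-4, rms_grad = 3.0e-4, max_iter = 500, ...) {
  stopifnot(max_grad > 0, rms_grad > 0)
  n <- n_atoms(sys$topology)
  if (is.null(frozen)) frozen <- which(sys$region_map$region == "MM")
  free <- setdiff(seq_len(n), frozen)
  if (length(free) == 0) stop("no free atoms to optimize")
  if (!is.null(restraints) && any(restraints$i == restraints$j))
    stop("restraint pairs must be distinct atoms")
  x0 <- as.matrix(sys$structure)
  traj <- numeric(0)

  eval_at <- function(p, gradient) {
    x <- x0
    x[free, ] <- matrix(p, ncol = 3)
    s2 <- sys; s2$structure <- x
    rep <- qmmm_energy(s2, scheme = scheme, backend = backend,
                       gradient = gradient, ...)
    e <- rep$total
    g <- rep$gradient
    if (!is.null(restraints)) {
      for (r in seq_len(nrow(restraints))) {
        d <- x[restraints$i[r], ] - x[restraints$j[r], ]
        rr <- sqrt(sum(d * d))
        e <- e + restraints$k[r] * (rr - restraints$target[r])^2
        if (gradient) {
          gi <- 2 * restraints$k[r] * (rr - restraints$target[r]) * d / rr
          g[restraints$i[r], ] <- g[restraints$i[r], ] + gi
          g[restraints$j[r], ] <- g[restraints$j[r], ] - gi
        }
      }
    }
    list(e = e, g = g)
  }
  fn <- function(p) {
    v <- eval_at(p, gradient = FALSE)$e
    traj <<- c(traj, v)
    v
  }
  gr <- function(p) as.vector(eval_at(p, gradient = TRUE)$g[free, , drop = FALSE])

  p0 <- as.vector(x0[free, , drop = FALSE])
  opt <- stats::optim(p0, fn, gr, method = "L-BFGS-B",
                      control = list(maxit = max_iter, factr = 10))
  x <- x0
  x[free, ] <- matrix(opt$par, ncol = 3)
  gfin <- eval_at(opt$par, gradient = TRUE)$g[free, , drop = FALSE]
  mg <- max(abs(gfin)); rg <- sqrt(mean(gfin^2))
  list(structure = x, energy = opt$value,
       trajectory = cummin(traj),
       converged = mg <= max_grad && rg <= rms_grad,
       max_grad = mg, rms_grad = rg, iterations = opt$counts[["function"]])
}

#' Root-mean-squared coordinate deviation
#'
#' With `superpose = TRUE` an optimal rigid-body (Kabsch) superposition of
#' `b` onto `a` is applied first — appropriate for isolated-molecule
#' comparisons.  Without superposition the raw coordinate RMSD is returned —
#' appropriate for frozen-environment comparisons, which share a frame.
#'
#' @param structure_a,structure_b n x 3 coordinate matrices.
#' @param atom_subset optional indices over which to compare.
#' @param superpose apply Kabsch superposition first?
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(structure_a, structure_b, atom_subset = NULL, superpose = FALSE) {
  a <- as.matrix(structure_a); b <- as.matrix(structure_b)
  if (!is.null(atom_subset)) {
    a <- a[atom_subset, , drop = FALSE]
    b <- b[atom_subset, , drop = FALSE]
  }
  stopifnot(nrow(a) == nrow(b))
  if (superpose) {
    if (nrow(a) < 3) stop("superposition requires at least 3 atoms")
    b <- kabsch_superpose(b, a)
  }
  sqrt(mean(rowSums((a - b)^2)))
}

## Kabsch: least-squares rigid superposition of `mobile` onto `target`.
kabsch_superpose <- function(mobile, target) {
  cm <- colMeans(mobile); ct <- colMeans(target)
  m0 <- sweep(mobile, 2, cm); t0 <- sweep(target, 2, ct)
  s <- svd(crossprod(m0, t0))
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sweep(m0 %*% t(R), 2, ct, "+")
}

#' Mean absolute deviation over internal coordinates
#'
#' Compares two conformations of the same topology over each bonded-term
#' class: mean absolute deviation of the bond lengths (Angstrom), of the
#' angles and of the dihedrals (degrees; dihedral differences wrapped to
#' (-180, 180]).
#'
#' @param structure_a,structure_b n x 3 coordinate matrices.
#' @param topology the shared [topology()].
#' @return named numeric: `mad_bond`, `mad_angle`, `mad_dihedral`.
#' @export
mad_internal_coordinates <- function(structure_a, structure_b, topology) {
  a <- as.matrix(structure_a); b <- as.matrix(structure_b)
  bl <- function(x) {
    d <- x[topology$bonds$i, , drop = FALSE] - x[topology$bonds$j, , drop = FALSE]
    sqrt(rowSums(d * d))
  }
  ang <- function(x) {
    u <- x[topology$angles$i, , drop = FALSE] - x[topology$angles$j, , drop = FALSE]
    v <- x[topology$angles$k, , drop = FALSE] - x[topology$angles$j, , drop = FALSE]
    ct <- rowSums(u * v) / (sqrt(rowSums(u * u)) * sqrt(rowSums(v * v)))
    acos(pmin(1, pmax(-1, ct))) * 180 / pi
  }
  dih <- function(x) {
    d <- topology$dihedrals
    b1 <- x[d$j, , drop = FALSE] - x[d$i, , drop = FALSE]
    b2 <- x[d$k, , drop = FALSE] - x[d$j, , drop = FALSE]
    b3 <- x[d$l, , drop = FALSE] - x[d$k, , drop = FALSE]
    n1 <- vcross(b1, b2); n2 <- vcross(b2, b3)
    atan2(rowSums(vcross(n1, n2) * b2) / rownorm(b2), rowSums(n1 * n2)) * 180 / pi
  }
  wrap <- function(x) {
    out <- (x + 180) %% 360 - 180
    out[out == -180] <- 180
    out
  }
  c(mad_bond = if (nrow(topology$bonds)) mean(abs(bl(a) - bl(b))) else 0,
    mad_angle = if (nrow(topology$angles)) mean(abs(ang(a) - ang(b))) else 0,
    mad_dihedral = if (nrow(topology$dihedrals))
      mean(abs(wrap(dih(a) - dih(b)))) else 0)
}
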