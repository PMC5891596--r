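#' QM backends
#'
#' A backend is a list with fields `label` and `evaluate(trunc, coords,
#' point_charges)` where `trunc` is the [build_truncated_topology()] result,
#' `coords` the system-1 coordinates (HL placed) and `point_charges` a
#' [build_point_charge_model()] data frame or `NULL`.  It returns a
#' `qm_result`: `energy` (kcal/mol), `grad_qm` (n1 x 3), `grad_ptch`
#' (m x 3 or NULL), `label`.  By contract the energy never includes the
#' self-energy of the point charges, and QM-point-charge Coulomb
#' interactions are neither excluded nor 1-4 scaled (a real QM code cannot
#' scale them), which reproduces the known embedding asymmetry across the
#' junction.
#'
#' @name qm-backends
NULL

qm_result <- function(energy, grad_qm, grad_ptch, label) {
  structure(list(energy = energy, grad_qm = grad_qm,
                 grad_ptch = grad_ptch, label = label),
            class = "qm_result")
}

## Unscaled Coulomb interaction between every system-1 atom and every point
## charge, with gradients on both sides.
embedding_coulomb <- function(coords, q_atoms, point_charges) {
  m <- nrow(point_charges)
  n1 <- nrow(coords)
  gq <- matrix(0, n1, 3)
  gp <- matrix(0, max(m, 0), 3)
  if (m == 0 || n1 == 0) return(list(energy = 0, grad_qm = gq, grad_ptch = gp))
  P <- unname(as.matrix(point_charges[, c("x", "y", "z")]))
  e <- 0
  for (a in seq_len(n1)) {
    d <- matrix(coords[a, ], m, 3, byrow = TRUE) - P
    r <- sqrt(rowSums(d * d))
    ee <- COULOMB_KCAL * q_atoms[a] * point_charges$q / r
    e <- e + sum(ee)
    gia <- d * (-ee / r^2)
    gq[a, ] <- gq[a, ] + colSums(gia)
    gp <- gp - gia
  }
  list(energy = e, grad_qm = gq, grad_ptch = gp)
}

#' MM-surrogate QM backend
#'
#' Evaluates the truncated system with the MM engine (all terms, using a
#' configurable surrogate charge set) and adds unscaled Coulomb interactions
#' between every system-1 atom (including HL) and every point charge.  This
#' is a stand-in "QM theory" whose physics is exactly the MM force field, so
#' that every coupling-scheme identity can be checked without an external
#' electronic-structure program.
#'
#' @param charge_set optional system-1 charge vector used as the surrogate
#'   "electron density"; defaults to the truncated topology's charges.
#' @return a backend object for [qm_evaluate()].
#' @export
surrogate_backend <- function(charge_set = NULL) {
  list(
    label = "mm-surrogate",
    evaluate = function(trunc, coords, point_charges = NULL) {
      q1 <- if (is.null(charge_set)) trunc$topology$atoms$charge
            else as.numeric(charge_set)
      rep <- mm_energy(trunc$topology, coords, term_filter("all"), charges = q1)
      e <- rep$total
      gq <- rep$gradient
      gp <- NULL
      if (!is.null(point_charges) && nrow(point_charges) > 0) {
        emb <- embedding_coulomb(coords, q1, point_charges)
        e <- e + emb$energy
        gq <- gq + emb$grad_qm
        gp <- emb$grad_ptch
      }
      qm_result(e, gq, gp, "mm-surrogate")
    }
  )
}

#' Smooth synthetic QM backend (for backend-agnostic assembly tests)
#'
#' Returns arbitrary-but-smooth analytic energies: a quadratic well over the
#' system-1 coordinates with seeded random centers and weights, plus a
#' bilinear coupling to the point charges.  Used to assert that the scheme
#' assemblies do no MM bookkeeping inside the QM term.
#'
#' @param seed integer seed for the random coefficients.
#' @return a backend object for [qm_evaluate()].
#' @export
fake_qm_backend <- function(seed = 1L) {
  force(seed)
  list(
    label = sprintf("fake-qm-%d", seed),
    evaluate = function(trunc, coords, point_charges = NULL) {
      n1 <- nrow(coords)
      rs <- local({
        set.seed(seed)
        list(a = runif(n1, 0.5, 2), c = matrix(runif(3 * n1, -1, 1), n1, 3),
             b = runif(1, 0.1, 0.5))
      })
      d <- coords - rs$c
      e <- sum(rs$a * rowSums(d * d))
      gq <- 2 * rs$a * d
      gp <- NULL
      if (!is.null(point_charges) && nrow(point_charges) > 0) {
        emb <- embedding_coulomb(coords, rep(rs$b, n1), point_charges)
        e <- e + emb$energy
        gq <- gq + emb$grad_qm
        gp <- emb$grad_ptch
      }
      qm_result(e, gq, gp, sprintf("fake-qm-%d", seed))
    }
  )
}

#' Evaluate the QM term of a QM/MM assembly
#'
#' @param trunc [build_truncated_topology()] result (system 1 with HL).
#' @param coords system-1 coordinates with HL placed
#'   ([place_link_atoms()]`$coords`).
#' @param point_charges [build_point_charge_model()] data frame or `NULL`
#'   (mechanical embedding).
#' @param backend a backend object ([surrogate_backend()],
#'   [fake_qm_backend()] or [file_exchange_backend()]).
#' @return a `qm_result`.
#' @export
qm_evaluate <- function(trunc, coords, point_charges = NULL,
                        backend = surrogate_backend()) {
  if (nrow(trunc$topology$atoms) != nrow(coords))
    stop("coordinate count does not match truncated topology")
  res <- backend$evaluate(trunc, coords, point_charges)
  if (!is.null(point_charges) && nrow(point_charges) > 0 &&
      (is.null(res$grad_ptch) || nrow(res$grad_ptch) != nrow(point_charges)))
    stop("backend did not return point-charge gradients of the right size")
  res
}

#' File-exchange adapter for external QM programs
#'
#' Writes the system-1 geometry and the point-charge model as plain text and
#' reads back an energy/gradient file, allowing any external QM program to be
#' coupled through a small shell wrapper.  Wire format: `coords.txt` has one
#' line per atom `element x y z` (Angstrom); `pointcharges.txt` one line per
#' charge `x y z q` (Angstrom, e); the result file must contain a line
#' `energy <kcal/mol>` followed by one `grad x y z` line per system-1 atom
#' and then one per point charge (kcal/mol/A).
#'
#' @param run_fn function(dir) invoked after the inputs are written; it must
#'   produce `result.txt` in `dir`.
#' @param dir exchange directory (created if needed).
#' @return a backend object for [qm_evaluate()].
#' @export
file_exchange_backend <- function(run_fn, dir = tempfile("qmx")) {
  list(
    label = "file-exchange",
    evaluate = function(trunc, coords, point_charges = NULL) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      writeLines(sprintf("%-2s %22.14f %22.14f %22.14f",
                         trunc$topology$atoms$element,
                         coords[, 1], coords[, 2], coords[, 3]),
                 file.path(dir, "coords.txt"))
      m <- if (is.null(point_charges)) 0 else nrow(point_charges)
      pc_lines <- if (m > 0)
        sprintf("%22.14f %22.14f %22.14f %14.8f", point_charges$x,
                point_charges$y, point_charges$z, point_charges$q)
      else character(0)
      writeLines(pc_lines, file.path(dir, "pointcharges.txt"))
      run_fn(dir)
      lines <- readLines(file.path(dir, "result.txt"))
      ev <- strsplit(trimws(lines), "\\s+")
      if (ev[[1]][1] != "energy") stop("malformed result.txt: first line must be 'energy <value>'")
      energy <- as.numeric(ev[[1]][2])
      gl <- ev[-1]
      need <- nrow(coords) + m
      if (length(gl) != need)
        stop(sprintf("result.txt has %d gradient lines, expected %d", length(gl), need))
      gm <- t(vapply(gl, function(v) as.numeric(v[2:4]), numeric(3)))
      qm_result(energy, gm[seq_len(nrow(coords)), , drop = FALSE],
                if (m > 0) gm[nrow(coords) + seq_len(m), , drop = FALSE] else NULL,
                "file-exchange")
    }
  )
}
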