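#' Term filters for cherry-picked MM evaluations
#'
#' A `term_filter` decides, from the QM/MM region labels of a term's atoms,
#' whether that term enters the MM sum.  It carries one predicate per term
#' class: `bonded` (bonds, angles, dihedrals), `elec` and `vdw` (nonbonded
#' pairs, including scaled 1-4 pairs).  Each predicate receives a character
#' matrix of region labels (`"QM"` or `"MM"`, one row per term, CL atoms
#' counting as QM) and returns a logical vector.
#'
#' Presets:
#' * `"all"` — every term (plain MM evaluation);
#' * `"bonded_at_least_one_mm"` — restricts bonded terms to those with at
#'   least one MM atom, passes nonbonded unchanged;
#' * `"elec_mm_mm_only"` — restricts electrostatics to pure MM-MM pairs;
#' * `"vdw_not_both_qm"` — drops van der Waals pairs wholly inside the QM
#'   region;
#' * `"elec_none"` — drops all electrostatics;
#' * `"additive_mm"` — conjunction of the three rules above: the
#'   cherry-picked MM term of the additive scheme (bonded with >= 1 MM atom,
#'   MM-MM electrostatics, van der Waals unless both atoms are QM);
#' * `"qm_only"` — the complement used by the strict-subtractive small-system
#'   term: bonded, electrostatic and van der Waals terms wholly inside the QM
#'   region.
#'
#' @param preset preset name, see above.
#' @param bonded,elec,vdw optional predicate overrides.
#' @return a `term_filter` object.
#' @export
term_filter <- function(preset = "all", bonded = NULL, elec = NULL, vdw = NULL) {
  pass <- function(lab) rep(TRUE, nrow(lab))
  none <- function(lab) rep(FALSE, nrow(lab))
  any_mm <- function(lab) rowSums(lab == "MM") >= 1
  all_mm <- function(lab) rowSums(lab == "MM") == ncol(lab)
  all_qm <- function(lab) rowSums(lab == "QM") == ncol(lab)
  f <- switch(preset,
    all = list(bonded = pass, elec = pass, vdw = pass),
    bonded_at_least_one_mm = list(bonded = any_mm, elec = pass, vdw = pass),
    elec_mm_mm_only = list(bonded = pass, elec = all_mm, vdw = pass),
    vdw_not_both_qm = list(bonded = pass, elec = pass,
                           vdw = function(lab) !all_qm(lab)),
    elec_none = list(bonded = pass, elec = none, vdw = pass),
    additive_mm = list(bonded = any_mm, elec = all_mm,
                       vdw = function(lab) !all_qm(lab)),
    qm_only = list(bonded = all_qm, elec = all_qm, vdw = all_qm),
    stop("unknown term_filter preset: ", preset)
  )
  if (!is.null(bonded)) f$bonded <- bonded
  if (!is.null(elec)) f$elec <- elec
  if (!is.null(vdw)) f$vdw <- vdw
  structure(c(f, list(name = preset)), class = "term_filter")
}

#' Combine two term filters by conjunction
#'
#' @param a,b `term_filter` objects.
#' @return a `term_filter` keeping a term only if both inputs keep it.
#' @export
filter_and <- function(a, b) {
  structure(list(
    bonded = function(lab) a$bonded(lab) & b$bonded(lab),
    elec = function(lab) a$elec(lab) & b$elec(lab),
    vdw = function(lab) a$vdw(lab) & b$vdw(lab),
    name = paste(a$name, "&", b$name)
  ), class = "term_filter")
}

#' Complement of a term filter (per term class)
#'
#' Together with the original filter this partitions every term class, so
#' that `E(all) = E(f) + E(filter_not(f))` for any filter `f`.
#'
#' @param f a `term_filter`.
#' @return the complementary `term_filter`.
#' @export
filter_not <- function(f) {
  structure(list(
    bonded = function(lab) !f$bonded(lab),
    elec = function(lab) !f$elec(lab),
    vdw = function(lab) !f$vdw(lab),
    name = paste0("!", f$name)
  ), class = "term_filter")
}

region_labels <- function(region_map, n) {
  if (is.null(region_map)) rep("MM", n) else region_map$region
}

label_matrix <- function(labels, idx_df, cols) {
  m <- vapply(cols, function(cl) labels[idx_df[[cl]]], character(nrow(idx_df)))
  if (nrow(idx_df) == 1) m <- matrix(m, nrow = 1)
  if (nrow(idx_df) == 0) m <- matrix(character(), 0, length(cols))
  m
}

#' Enumerate MM terms with their region annotation
#'
#' Lists every bond, angle, dihedral and nonbonded pair of a topology,
#' labelling each with its atoms' QM/MM regions (CL atoms count as QM).
#' Nonbonded pairs are all atom pairs minus the exclusion list; 1-4 pairs are
#' flagged and carry their scale divisors.
#'
#' @param topology a [topology()] object.
#' @param region_map optional [assign_regions()] result; when `NULL` all
#'   atoms are labelled MM.
#' @return list with data frames `bonds`, `angles`, `dihedrals`, `pairs`
#'   (columns `i`, `j`, `is14`, `scee`, `scnb`), each with a `regions`
#'   label column ("QM/QM" etc., sorted labels joined by "/").
#' @export
enumerate_terms <- function(topology, region_map = NULL) {
  n <- n_atoms(topology)
  lab <- region_labels(region_map, n)
  tag <- function(df, cols) {
    if (nrow(df) == 0) { df$regions <- character(0); return(df) }
    m <- label_matrix(lab, df, cols)
    df$regions <- apply(m, 1, function(r) paste(sort(r), collapse = "/"))
    df
  }
  pairs <- nonbonded_pairs(topology)
  list(
    bonds = tag(topology$bonds, c("i", "j")),
    angles = tag(topology$angles, c("i", "j", "k")),
    dihedrals = tag(topology$dihedrals, c("i", "j", "k", "l")),
    pairs = tag(pairs, c("i", "j"))
  )
}

## All nonbonded pairs: every i<j pair minus exclusions; 1-4 flagged.
nonbonded_pairs <- function(topology) {
  n <- n_atoms(topology)
  if (n < 2) {
    return(data.frame(i = integer(), j = integer(), is14 = logical(),
                      scee = numeric(), scnb = numeric()))
  }
  cmb <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  p <- data.frame(i = cmb[, 1], j = cmb[, 2])
  key <- function(i, j) i * (n + 1L) + j
  p <- p[!(key(p$i, p$j) %in% key(topology$excl$i, topology$excl$j)), , drop = FALSE]
  m14 <- match(key(p$i, p$j), key(topology$pairs14$i, topology$pairs14$j))
  p$is14 <- !is.na(m14)
  p$scee <- ifelse(p$is14, topology$pairs14$scee[m14], 1)
  p$scnb <- ifelse(p$is14, topology$pairs14$scnb[m14], 1)
  rownames(p) <- NULL
  p
}

## Accumulate per-term 3-vector contributions onto a gradient matrix,
## summing over repeated atom indices.
add_rows <- function(grad, idx, contrib) {
  if (length(idx) == 0) return(grad)
  s <- rowsum(contrib, group = idx)
  rows <- as.integer(rownames(s))
  grad[rows, ] <- grad[rows, ] + s
  grad
}

vcross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

rownorm <- function(a) sqrt(rowSums(a * a))

#' Molecular-mechanics energy and analytic gradient
#'
#' Evaluates the AMBER-form potential
#' `E = sum kb (r - r0)^2 + sum kth (theta - th0)^2 +
#'  sum (Vn/2)(1 + cos(n phi - gamma)) + sum_pairs (A/r^12 - B/r^6)/scnb +
#'  sum_pairs 332.0522 qi qj / (r scee)`
#' with no nonbonded cutoff.  1-2 and 1-3 pairs are fully excluded; 1-4 pairs
#' are divided by their scale divisors.  A [term_filter()] selects terms by
#' the QM/MM regions of their atoms, enabling both plain evaluations and the
#' additive scheme's cherry-picking.
#'
#' @param topology a [topology()] object.
#' @param structure numeric n x 3 coordinate matrix (Angstrom).
#' @param filter a [term_filter()] or preset name.
#' @param charges optional charge vector (e) overriding the topology charges.
#' @param region_map optional [assign_regions()] result (required for any
#'   region-sensitive filter).
#' @param gradient compute the analytic gradient (kcal/mol/A)?
#' @return an `energy_report`: list with `total` (kcal/mol), `components`
#'   (bond, angle, dihedral, vdw, vdw14, elec, elec14), `gradient`
#'   (n x 3 or NULL), `filter`, `charge_label`.
#' @export
mm_energy <- function(topology, structure, filter = term_filter("all"),
                      charges = NULL, region_map = NULL, gradient = TRUE) {
  if (is.character(filter)) filter <- term_filter(filter)
  x <- as.matrix(structure)
  n <- n_atoms(topology)
  stopifnot(nrow(x) == n, ncol(x) == 3)
  if (any(!is.finite(x))) stop("non-finite coordinates in structure")
  q <- if (is.null(charges)) topology$atoms$charge else as.numeric(charges)
  if (length(q) != n) stop("charge vector length does not match atom count")
  lab <- region_labels(region_map, n)
  grad <- matrix(0, n, 3)
  comp <- c(bond = 0, angle = 0, dihedral = 0, vdw = 0, vdw14 = 0,
            elec = 0, elec14 = 0)

  ## --- bonds
  b <- topology$bonds
  if (nrow(b) > 0) {
    keep <- filter$bonded(label_matrix(lab, b, c("i", "j")))
    b <- b[keep, , drop = FALSE]
  }
  if (nrow(b) > 0) {
    d <- x[b$i, , drop = FALSE] - x[b$j, , drop = FALSE]
    r <- rownorm(d)
    if (any(r < 1e-12)) stop("zero-length bond encountered")
    comp["bond"] <- sum(b$kb * (r - b$r0)^2)
    if (gradient) {
      dEdr <- 2 * b$kb * (r - b$r0)
      gi <- d * (dEdr / r)
      grad <- add_rows(grad, b$i, gi)
      grad <- add_rows(grad, b$j, -gi)
    }
  }

  ## --- angles
  a <- topology$angles
  if (nrow(a) > 0) {
    keep <- filter$bonded(label_matrix(lab, a, c("i", "j", "k")))
    a <- a[keep, , drop = FALSE]
  }
  if (nrow(a) > 0) {
    u <- x[a$i, , drop = FALSE] - x[a$j, , drop = FALSE]
    v <- x[a$k, , drop = FALSE] - x[a$j, , drop = FALSE]
    nu <- rownorm(u); nv <- rownorm(v)
    ct <- rowSums(u * v) / (nu * nv)
    ct <- pmin(1, pmax(-1, ct))
    th <- acos(ct)
    comp["angle"] <- sum(a$kth * (th - a$th0)^2)
    if (gradient) {
      ## guarded near-linear geometry: sin(theta) floored at 1e-12
      st <- pmax(sqrt(pmax(0, 1 - ct^2)), 1e-12)
      dEdth <- 2 * a$kth * (th - a$th0)
      dct_di <- (v / nv - ct * u / nu) / nu
      dct_dk <- (u / nu - ct * v / nv) / nv
      gi <- -(dEdth / st) * dct_di
      gk <- -(dEdth / st) * dct_dk
      grad <- add_rows(grad, a$i, gi)
      grad <- add_rows(grad, a$k, gk)
      grad <- add_rows(grad, a$j, -(gi + gk))
    }
  }

  ## --- dihedrals (IUPAC-signed torsion)
  dh <- topology$dihedrals
  if (nrow(dh) > 0) {
    keep <- filter$bonded(label_matrix(lab, dh, c("i", "j", "k", "l")))
    dh <- dh[keep, , drop = FALSE]
  }
  if (nrow(dh) > 0) {
    b1 <- x[dh$j, , drop = FALSE] - x[dh$i, , drop = FALSE]
    b2 <- x[dh$k, , drop = FALSE] - x[dh$j, , drop = FALSE]
    b3 <- x[dh$l, , drop = FALSE] - x[dh$k, , drop = FALSE]
    n1 <- vcross(b1, b2)
    n2 <- vcross(b2, b3)
    nb2 <- rownorm(b2)
    phi <- atan2(rowSums(vcross(n1, n2) * b2) / nb2, rowSums(n1 * n2))
    comp["dihedral"] <- sum(dh$vn2 * (1 + cos(dh$per * phi - dh$phase)))
    if (gradient) {
      dEdphi <- -dh$vn2 * dh$per * sin(dh$per * phi - dh$phase)
      sn1 <- pmax(rowSums(n1 * n1), 1e-24)
      sn2 <- pmax(rowSums(n2 * n2), 1e-24)
      Fi <- -n1 * (nb2 / sn1)           # dphi/dri
      Gl <- n2 * (nb2 / sn2)            # dphi/drl
      c12 <- rowSums(b1 * b2) / nb2^2
      c32 <- rowSums(b3 * b2) / nb2^2
      Fj <- -Fi - c12 * Fi + c32 * Gl   # dphi/drj
      Gk <- -Gl + c12 * Fi - c32 * Gl   # dphi/drk
      grad <- add_rows(grad, dh$i, dEdphi * Fi)
      grad <- add_rows(grad, dh$j, dEdphi * Fj)
      grad <- add_rows(grad, dh$k, dEdphi * Gk)
      grad <- add_rows(grad, dh$l, dEdphi * Gl)
    }
  }

  ## --- nonbonded pairs
  p <- nonbonded_pairs(topology)
  if (nrow(p) > 0) {
    labm <- label_matrix(lab, p, c("i", "j"))
    keep_e <- filter$elec(labm)
    keep_v <- filter$vdw(labm)
    keep <- keep_e | keep_v
    p <- p[keep, , drop = FALSE]
    keep_e <- keep_e[keep]; keep_v <- keep_v[keep]
  } else keep_e <- keep_v <- logical(0)
  if (nrow(p) > 0) {
    ljp <- atom_lj(topology)
    d <- x[p$i, , drop = FALSE] - x[p$j, , drop = FALSE]
    r2 <- rowSums(d * d)
    if (any(r2 < 1e-20)) stop("coincident atoms in nonbonded pair")
    r <- sqrt(r2)
    ## Lennard-Jones in Rmin/eps parametrization
    rmin <- ljp$rmin_half[p$i] + ljp$rmin_half[p$j]
    eps <- sqrt(ljp$eps[p$i] * ljp$eps[p$j])
    s6 <- (rmin^2 / r2)^3
    evdw_full <- eps * (s6 * s6 - 2 * s6)
    eelc_full <- COULOMB_KCAL * q[p$i] * q[p$j] / r
    wv <- ifelse(keep_v, 1 / p$scnb, 0)
    we <- ifelse(keep_e, 1 / p$scee, 0)
    comp["vdw"] <- sum(evdw_full[!p$is14] * wv[!p$is14])
    comp["vdw14"] <- sum(evdw_full[p$is14] * wv[p$is14])
    comp["elec"] <- sum(eelc_full[!p$is14] * we[!p$is14])
    comp["elec14"] <- sum(eelc_full[p$is14] * we[p$is14])
    if (gradient) {
      ## dE/dr per pair, both contributions
      dvdw_dr <- eps * (-12 * s6 * s6 / r + 12 * s6 / r)
      delc_dr <- -eelc_full / r
      dEdr <- dvdw_dr * wv + delc_dr * we
      gi <- d * (dEdr / r)
      grad <- add_rows(grad, p$i, gi)
      grad <- add_rows(grad, p$j, -gi)
    }
  }

  total <- sum(comp)
  structure(list(total = total, components = comp,
                 gradient = if (gradient) grad else NULL,
                 filter = filter$name,
                 charge_label = if (is.null(charges)) "topology" else "explicit"),
            class = "energy_report")
}

#' @export
print.energy_report <- function(x, ...) {
  cat(sprintf("MM energy (filter '%s'): %.6f kcal/mol\n", x$filter, x$total))
  print(round(x$components, 6))
  invisible(x)
}
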