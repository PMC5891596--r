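## ---------------------------------------------------------------------------
## Embedded toy force field ("toyff-1"): a small-molecule parameter set with
## magnitudes typical of general organic force fields.  Versioned and printed
## here so that fixtures never depend on an external force-field
## distribution.  The hydroxyl hydrogen (ho) deliberately has zero van der
## Waals depth, as in the common protein force fields; this makes the
## van der Waals link-atom correction vanish identically on the ethanol
## fixture, whose only CL-involving intra-QM pair is HO...C2.
## ---------------------------------------------------------------------------

TOYFF_VERSION <- "toyff-1"

toyff_lj <- function() data.frame(
  type = c("c3", "hc", "h1", "oh", "ho", "hl"),
  rmin_half = c(1.9080, 1.4870, 1.3870, 1.7210, 0.0000, 1.4870),
  eps = c(0.1094, 0.0157, 0.0157, 0.2104, 0.0000, 0.0157),
  stringsAsFactors = FALSE)

toyff_bond <- function(t1, t2) {
  tab <- list("ho-oh" = c(553.0, 0.960), "c3-oh" = c(320.0, 1.410),
              "c3-c3" = c(310.0, 1.526), "c3-h1" = c(340.0, 1.090),
              "c3-hc" = c(340.0, 1.090))
  p <- tab[[paste(sort(c(t1, t2)), collapse = "-")]]
  if (is.null(p)) stop("toyff: no bond parameters for ", t1, "-", t2)
  p
}

toyff_angle <- function(t1, t2, t3) {
  ends <- paste(sort(c(t1, t3)), collapse = "-")
  key <- paste(ends, t2, sep = "@")
  tab <- list("c3-ho@oh" = c(55.0, 108.5), "h1-ho@oh" = c(47.0, 108.2),
              "c3-oh@c3" = c(50.0, 109.5), "h1-oh@c3" = c(50.0, 109.5),
              "h1-h1@c3" = c(35.0, 109.5), "c3-h1@c3" = c(50.0, 109.5),
              "c3-hc@c3" = c(50.0, 109.5), "hc-hc@c3" = c(35.0, 109.5),
              "c3-c3@c3" = c(40.0, 109.5))
  p <- tab[[key]]
  if (is.null(p)) stop("toyff: no angle parameters for ", t1, "-", t2, "-", t3)
  c(p[1], p[2] * pi / 180)
}

toyff_dihedral <- function(t2, t3) {
  key <- paste(sort(c(t2, t3)), collapse = "-")
  tab <- list("c3-c3" = c(0.1556, 3, 0), "c3-oh" = c(0.1667, 3, 0))
  p <- tab[[key]]
  if (is.null(p)) stop("toyff: no dihedral parameters for central bond ", key)
  p
}

## ---------------------------------------------------------------------------
## geometry: internal-coordinate (z-matrix) chain builder
## ---------------------------------------------------------------------------

## rows of zmat: list(r_ref, r, a_ref, angle_deg, d_ref, dihedral_deg)
build_zmat_geometry <- function(zmat) {
  n <- length(zmat)
  x <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    z <- zmat[[i]]
    if (i == 1) next
    if (i == 2) { x[2, ] <- x[z[[1]], ] + c(z[[2]], 0, 0); next }
    th <- z[[4]] * pi / 180
    if (i == 3) {
      C <- x[z[[1]], ]; B <- x[z[[3]], ]
      u <- (B - C) / sqrt(sum((B - C)^2))
      perp <- c(-u[2], u[1], 0)
      if (sum(perp^2) < 1e-12) perp <- c(0, 1, 0)
      perp <- perp / sqrt(sum(perp^2))
      x[3, ] <- C + z[[2]] * (cos(th) * u + sin(th) * perp)
      next
    }
    phi <- z[[6]] * pi / 180
    C <- x[z[[1]], ]; B <- x[z[[3]], ]; A <- x[z[[5]], ]
    bc <- C - B; bc <- bc / sqrt(sum(bc^2))
    ab <- B - A
    nv <- c(ab[2] * bc[3] - ab[3] * bc[2], ab[3] * bc[1] - ab[1] * bc[3],
            ab[1] * bc[2] - ab[2] * bc[1])
    nv <- nv / sqrt(sum(nv^2))
    mv <- c(nv[2] * bc[3] - nv[3] * bc[2], nv[3] * bc[1] - nv[1] * bc[3],
            nv[1] * bc[2] - nv[2] * bc[1])
    d2 <- c(-z[[2]] * cos(th), z[[2]] * sin(th) * cos(phi),
            z[[2]] * sin(th) * sin(phi))
    x[i, ] <- C + d2[1] * bc + d2[2] * mv + d2[3] * nv
  }
  x
}

## derive angles and dihedrals from the bond list, parameters from toyff
toyff_topology <- function(atoms, bond_pairs, title) {
  n <- nrow(atoms)
  bonds <- do.call(rbind, lapply(bond_pairs, function(p) {
    bp <- toyff_bond(atoms$type[p[1]], atoms$type[p[2]])
    data.frame(i = p[1], j = p[2], kb = bp[1], r0 = bp[2])
  }))
  adj <- lapply(seq_len(n), function(i)
    c(bonds$j[bonds$i == i], bonds$i[bonds$j == i]))
  angles <- NULL
  for (j in seq_len(n)) {
    nb <- sort(adj[[j]])
    if (length(nb) < 2) next
    for (a in seq_along(nb)) for (b in seq_along(nb)) {
      if (a >= b) next
      ap <- toyff_angle(atoms$type[nb[a]], atoms$type[j], atoms$type[nb[b]])
      angles <- rbind(angles, data.frame(i = nb[a], j = j, k = nb[b],
                                         kth = ap[1], th0 = ap[2]))
    }
  }
  dihedrals <- NULL
  for (r in seq_len(nrow(bonds))) {
    j <- bonds$i[r]; k <- bonds$j[r]
    for (i in setdiff(adj[[j]], k)) for (l in setdiff(adj[[k]], j)) {
      if (i == l) next
      dp <- toyff_dihedral(atoms$type[j], atoms$type[k])
      dihedrals <- rbind(dihedrals,
                         data.frame(i = i, j = j, k = k, l = l,
                                    vn2 = dp[1], per = dp[2], phase = dp[3]))
    }
  }
  if (is.null(angles)) angles <- data.frame(i = integer(), j = integer(),
                                            k = integer(), kth = numeric(),
                                            th0 = numeric())
  if (is.null(dihedrals)) dihedrals <- data.frame(i = integer(), j = integer(),
                                                  k = integer(), l = integer(),
                                                  vn2 = numeric(), per = numeric(),
                                                  phase = numeric())
  topology(atoms, toyff_lj(), bonds, angles, dihedrals,
           title = paste0(title, " [", TOYFF_VERSION, "]"))
}

#' Gaussian coordinate perturbation with a fixed seed
#'
#' @param structure n x 3 coordinate matrix.
#' @param sd displacement standard deviation per Cartesian component (A).
#' @param seed integer seed.
#' @return perturbed coordinate matrix.
#' @export
perturb_structure <- function(structure, sd = 0.05, seed = 1L) {
  x <- as.matrix(structure)
  set.seed(seed)
  x + matrix(stats::rnorm(length(x), sd = sd), nrow(x), 3)
}

#' Built-in test systems
#'
#' Three fixtures, generated entirely from code and the embedded `toyff-1`
#' parameter set (deterministic: the same arguments always produce the same
#' system):
#'
#' * `"ethanol_methanol"` — 9-atom ethanol (atoms HO, O, C1, H11, H12, C2,
#'   H21, H22, H23) with the methanol part as QM region and one junction
#'   (Q1 = C1, CL = C2); MM charges are the ethanol Set1 column and the
#'   QM-derived set is the methanol ESP column (HL charge -0.0108 e).
#' * `"propane_two_junctions"` — 11-atom propane with the central CH2 as the
#'   interior of the QM region and both methyl carbons as CL atoms in the
#'   same biochemical unit, exercising the equal-split CL charge offset of
#'   the mechanical-embedding merge.
#' * `"butane_bonded_cl"` — 14-atom butane with the two central carbons as
#'   covalently bonded CL atoms (the dithiolene-analogue complication): the
#'   CL-CL bond and every bonded term across it must be removed from the
#'   truncated topology.
#'
#' @param name fixture name (see above).
#' @param jitter optional Gaussian coordinate jitter (A) applied with
#'   `seed`, for randomized-geometry property tests.
#' @param seed seed for the jitter.
#' @return a [qmmm_system()] with extra fields `name` and `qm_selection`.
#' @export
build_fixture <- function(name = c("ethanol_methanol", "propane_two_junctions",
                                   "butane_bonded_cl"),
                          jitter = 0, seed = 1L) {
  name <- match.arg(name)
  fx <- switch(name,
               ethanol_methanol = fixture_ethanol(),
               propane_two_junctions = fixture_propane(),
               butane_bonded_cl = fixture_butane())
  if (jitter > 0) fx$structure <- perturb_structure(fx$structure, jitter, seed)
  fx
}

fixture_ethanol <- function() {
  atoms <- data.frame(
    name = c("HO", "O", "C1", "H11", "H12", "C2", "H21", "H22", "H23"),
    element = c("H", "O", "C", "H", "H", "C", "H", "H", "H"),
    type = c("ho", "oh", "c3", "h1", "h1", "c3", "hc", "hc", "hc"),
    mass = c(1.008, 16.00, 12.01, 1.008, 1.008, 12.01, 1.008, 1.008, 1.008),
    charge = c(0.3570, -0.5847, 0.3841, -0.0534, -0.0534, -0.2324,
               0.0609, 0.0609, 0.0609),
    res_id = 1L, res_name = "EOH", stringsAsFactors = FALSE)
  bonds <- list(c(1, 2), c(2, 3), c(3, 4), c(3, 5), c(3, 6),
                c(6, 7), c(6, 8), c(6, 9))
  top <- toyff_topology(atoms, bonds, "ethanol")
  ## build order: O, C1, HO, C2, H11, H12, H21, H22, H23 -> reorder
  zm <- list(list(),                                   # O
             list(1L, 1.413, NULL, NULL, NULL, NULL),  # C1
             list(1L, 0.963, 2L, 108.6, NULL, NULL),   # HO
             list(2L, 1.530, 1L, 109.4, 3L, 180),      # C2
             list(2L, 1.092, 1L, 109.6, 4L, 121),      # H11
             list(2L, 1.091, 1L, 109.5, 4L, -121),     # H12
             list(4L, 1.093, 2L, 110.0, 1L, 180),      # H21
             list(4L, 1.090, 2L, 109.3, 1L, 60),       # H22
             list(4L, 1.091, 2L, 109.7, 1L, -60))      # H23
  xb <- build_zmat_geometry(zm)
  x <- xb[c(3, 1, 2, 5, 6, 4, 7, 8, 9), ]
  rmap <- assign_regions(top, 1:6)
  ls <- link_spec(top, rmap, r0_hl = 1.090, hl_type = "hl", hl_charge = -0.0108)
  qm_charges <- c(0.3977, -0.5903, 0.2120, -0.0043, -0.0043, NA, NA, NA, NA)
  fx <- qmmm_system(top, x, rmap, ls, qm_charges = qm_charges)
  fx$name <- "ethanol_methanol"
  fx$qm_selection <- 1:6
  fx
}

fixture_propane <- function() {
  atoms <- data.frame(
    name = c("C1", "H11", "H12", "H13", "C2", "H21", "H22",
             "C3", "H31", "H32", "H33"),
    element = c("C", "H", "H", "H", "C", "H", "H", "C", "H", "H", "H"),
    type = c("c3", "hc", "hc", "hc", "c3", "hc", "hc", "c3", "hc", "hc", "hc"),
    mass = c(12.01, 1.008, 1.008, 1.008, 12.01, 1.008, 1.008,
             12.01, 1.008, 1.008, 1.008),
    charge = c(-0.0900, 0.0300, 0.0300, 0.0300, -0.0600, 0.0300, 0.0300,
               -0.0900, 0.0300, 0.0300, 0.0300),
    res_id = 1L, res_name = "PRP", stringsAsFactors = FALSE)
  bonds <- list(c(1, 2), c(1, 3), c(1, 4), c(1, 5), c(5, 6), c(5, 7),
                c(5, 8), c(8, 9), c(8, 10), c(8, 11))
  top <- toyff_topology(atoms, bonds, "propane")
  zm <- list(list(),                                   # C1
             list(1L, 1.528, NULL, NULL, NULL, NULL),  # C2
             list(2L, 1.531, 1L, 112.0, NULL, NULL),   # C3
             list(1L, 1.091, 2L, 110.5, 3L, 180),      # H11
             list(1L, 1.090, 2L, 110.8, 3L, 60),       # H12
             list(1L, 1.092, 2L, 110.6, 3L, -60),      # H13
             list(2L, 1.093, 1L, 109.2, 3L, 121.5),    # H21
             list(2L, 1.092, 1L, 109.0, 3L, -121.5),   # H22
             list(3L, 1.090, 2L, 110.4, 1L, 180),      # H31
             list(3L, 1.091, 2L, 110.3, 1L, 60),       # H32
             list(3L, 1.092, 2L, 110.7, 1L, -60))      # H33
  xb <- build_zmat_geometry(zm)
  x <- xb[c(1, 4, 5, 6, 2, 7, 8, 3, 9, 10, 11), ]
  rmap <- assign_regions(top, c(1, 5, 6, 7, 8))
  ls <- link_spec(top, rmap, r0_hl = 1.090, hl_type = "hl",
                  hl_charge = c(0.0065, 0.0065))
  qm_charges <- rep(NA_real_, 11)
  qm_charges[c(5, 6, 7)] <- c(-0.0750, 0.0310, 0.0310)
  fx <- qmmm_system(top, x, rmap, ls, qm_charges = qm_charges)
  fx$name <- "propane_two_junctions"
  fx$qm_selection <- c(1, 5, 6, 7, 8)
  fx
}

fixture_butane <- function() {
  atoms <- data.frame(
    name = c("C1", "H11", "H12", "H13", "C2", "H21", "H22",
             "C3", "H31", "H32", "C4", "H41", "H42", "H43"),
    element = c("C", "H", "H", "H", "C", "H", "H", "C", "H", "H",
                "C", "H", "H", "H"),
    type = c("c3", "hc", "hc", "hc", "c3", "hc", "hc", "c3", "hc", "hc",
             "c3", "hc", "hc", "hc"),
    mass = c(12.01, 1.008, 1.008, 1.008, 12.01, 1.008, 1.008,
             12.01, 1.008, 1.008, 12.01, 1.008, 1.008, 1.008),
    charge = c(-0.0900, 0.0300, 0.0300, 0.0300, -0.0600, 0.0300, 0.0300,
               -0.0600, 0.0300, 0.0300, -0.0900, 0.0300, 0.0300, 0.0300),
    res_id = 1L, res_name = "BUT", stringsAsFactors = FALSE)
  bonds <- list(c(1, 2), c(1, 3), c(1, 4), c(1, 5), c(5, 6), c(5, 7),
                c(5, 8), c(8, 9), c(8, 10), c(8, 11), c(11, 12), c(11, 13),
                c(11, 14))
  top <- toyff_topology(atoms, bonds, "butane")
  zm <- list(list(),                                   # C1
             list(1L, 1.529, NULL, NULL, NULL, NULL),  # C2
             list(2L, 1.532, 1L, 112.4, NULL, NULL),   # C3
             list(3L, 1.530, 2L, 112.1, 1L, 178),      # C4
             list(1L, 1.090, 2L, 110.5, 3L, 180),      # H11
             list(1L, 1.091, 2L, 110.6, 3L, 60),       # H12
             list(1L, 1.092, 2L, 110.4, 3L, -60),      # H13
             list(2L, 1.093, 1L, 109.1, 3L, 121.3),    # H21
             list(2L, 1.092, 1L, 109.3, 3L, -121.5),   # H22
             list(3L, 1.091, 2L, 109.2, 4L, 121.4),    # H31
             list(3L, 1.090, 2L, 109.4, 4L, -121.2),   # H32
             list(4L, 1.091, 3L, 110.5, 2L, 180),      # H41
             list(4L, 1.090, 3L, 110.3, 2L, 60),       # H42
             list(4L, 1.092, 3L, 110.6, 2L, -60))      # H43
  xb <- build_zmat_geometry(zm)
  x <- xb[c(1, 5, 6, 7, 2, 8, 9, 3, 10, 11, 4, 12, 13, 14), ]
  rmap <- suppressWarnings(assign_regions(top, c(1, 2, 3, 4, 5, 8, 11, 12, 13, 14)))
  ls <- link_spec(top, rmap, r0_hl = 1.090, hl_type = "hl",
                  hl_charge = c(0.0050, 0.0050))
  qm_charges <- rep(NA_real_, 14)
  qm_charges[c(1, 2, 3, 4, 11, 12, 13, 14)] <-
    c(-0.0980, 0.0310, 0.0310, 0.0310, -0.0980, 0.0310, 0.0310, 0.0310)
  fx <- qmmm_system(top, x, rmap, ls, qm_charges = qm_charges)
  fx$name <- "butane_bonded_cl"
  fx$qm_selection <- c(1, 2, 3, 4, 5, 8, 11, 12, 13, 14)
  fx
}

#' Write a fixture to disk
#'
#' Emits the full-system topology in both dialects, coordinates (AMBER
#' restart and XYZ), the QM atom mask, the link specification and the MM /
#' QM-derived charge sets as two-column text.
#'
#' @param fx a fixture from [build_fixture()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fx, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_prmtop(fx$topology, file.path(dir, "full.prmtop"))
  write_native_topology(fx$topology, file.path(dir, "full.top"))
  write_inpcrd(fx$structure, file.path(dir, "full.inpcrd"), fx$name)
  write_xyz(fx$structure, fx$topology$atoms$element,
            file.path(dir, "full.xyz"), fx$name)
  writeLines(sprintf("%d", fx$qm_selection), file.path(dir, "qm_mask.txt"))
  ls <- fx$link_specs
  writeLines(c("# q1 cl r0_hl hl_type hl_charge",
               sprintf("%d %d %.6f %s %.6f", ls$q1, ls$cl, ls$r0_hl,
                       ls$hl_type, ls$hl_charge)),
             file.path(dir, "links.txt"))
  writeLines(sprintf("%d %.6f", seq_along(fx$mm_charges), fx$mm_charges),
             file.path(dir, "charges_mm.txt"))
  qc <- fx$qm_charges
  qc[is.na(qc)] <- 0
  writeLines(sprintf("%d %.6f", seq_along(qc), qc),
             file.path(dir, "charges_qm.txt"))
  invisible(dir)
}

#' Load a fixture written by [write_fixture()]
#'
#' @param dir fixture directory.
#' @return a [qmmm_system()].
#' @export
read_fixture <- function(dir) {
  ## the native dialect carries the full LJ table, including HL types that
  ## no full-system atom uses; the prmtop (written alongside) cannot
  top <- read_native_topology(file.path(dir, "full.top"))
  x <- read_inpcrd(file.path(dir, "full.inpcrd"))
  qm_sel <- as.integer(readLines(file.path(dir, "qm_mask.txt")))
  rmap <- suppressWarnings(assign_regions(top, qm_sel))
  lk <- utils::read.table(file.path(dir, "links.txt"), comment.char = "#",
                          col.names = c("q1", "cl", "r0_hl", "hl_type", "hl_charge"),
                          stringsAsFactors = FALSE)
  lk <- lk[match(rmap$junctions$cl, lk$cl), , drop = FALSE]
  ls <- link_spec(top, rmap, r0_hl = lk$r0_hl, hl_type = lk$hl_type,
                  hl_charge = lk$hl_charge)
  mmq <- utils::read.table(file.path(dir, "charges_mm.txt"))[, 2]
  qmq <- utils::read.table(file.path(dir, "charges_qm.txt"))[, 2]
  qmq[rmap$region == "MM"] <- NA
  qmq[rmap$junctions$cl] <- NA
  fx <- qmmm_system(top, x, rmap, ls, mm_charges = mmq, qm_charges = qmq)
  fx$qm_selection <- qm_sel
  fx
}
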