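test_that("region assignment finds junctions and neighbor shells", {
  fx <- build_fixture("ethanol_methanol")
  rm_ <- assign_regions(fx$topology, 1:6)
  expect_equal(rm_$region, c(rep("QM", 6), rep("MM", 3)))
  expect_equal(rm_$junctions, data.frame(q1 = 3L, cl = 6L),
               ignore_attr = TRUE)
  expect_equal(sort(rm_$m2[[1]]), 7:9)          # the terminal methyl hydrogens
  ## QM = everything: no junctions
  rm_all <- assign_regions(fx$topology, 1:9)
  expect_equal(nrow(rm_all$junctions), 0)
  ## bonded CL pair: two junctions and a flagged CL-CL bond
  bt <- build_fixture("butane_bonded_cl")
  expect_warning(assign_regions(bt$topology, bt$qm_selection),
                 "covalently bonded CL")
  expect_equal(bt$region_map$junctions$cl, c(5L, 8L))
  expect_equal(bt$region_map$junctions$q1, c(1L, 11L))
  expect_equal(nrow(bt$region_map$cl_cl_bonds), 1)
  ## errors: invalid selections
  expect_error(assign_regions(fx$topology, integer(0)), "empty")
  expect_error(assign_regions(fx$topology, 99), "outside")
  ## a CL whose only QM neighbour would itself be a CL has no valid Q1
  expect_error(suppressWarnings(assign_regions(bt$topology, c(5, 8))),
               "region error")
})

test_that("link atoms sit on the Q1-CL ray at the scaled distance", {
  ## synthetic two-carbon system at and away from the equilibrium length
  atoms <- data.frame(name = c("Q1", "CL", "M"), element = c("C", "C", "H"),
                      type = c("c3", "c3", "hc"), mass = c(12, 12, 1.008),
                      charge = 0, res_id = 1L, res_name = "LNK")
  lj <- data.frame(type = c("c3", "hc", "hl"),
                   rmin_half = c(1.908, 1.487, 1.487),
                   eps = c(0.1094, 0.0157, 0.0157))
  top <- topology(atoms, lj,
                  bonds = data.frame(i = c(1, 2), j = c(2, 3),
                                     kb = c(310, 340), r0 = c(1.526, 1.09)),
                  angles = data.frame(i = integer(), j = integer(),
                                      k = integer(), kth = numeric(),
                                      th0 = numeric()),
                  dihedrals = data.frame(i = integer(), j = integer(),
                                         k = integer(), l = integer(),
                                         vn2 = numeric(), per = numeric(),
                                         phase = numeric()))
  rm_ <- assign_regions(top, 1:2)
  ls <- link_spec(top, rm_, r0_hl = 1.09)
  ## bond at its equilibrium length: HL at the ideal QM distance
  x <- rbind(c(0, 0, 0), c(1.526, 0, 0), c(2.2, 1, 0))
  pl <- place_link_atoms(x, rm_, ls)
  expect_equal(pl$coords[pl$hl_rows[1], ], c(1.09, 0, 0))
  ## stretched bond: scaled position 2.0 * 1.09 / 1.526
  x2 <- rbind(c(0, 0, 0), c(2.0, 0, 0), c(2.2, 1, 0))
  pl2 <- place_link_atoms(x2, rm_, ls)
  expect_equal(pl2$coords[pl2$hl_rows[1], 1], 2.0 * 1.09 / 1.526,
               tolerance = 1e-12)
  ## colinearity holds for arbitrary geometry
  set.seed(4)
  for (rep in 1:20) {
    xr <- matrix(rnorm(9, sd = 2), 3, 3)
    plr <- place_link_atoms(xr, rm_, ls)
    hl <- plr$coords[plr$hl_rows[1], ]
    v1 <- hl - xr[1, ]; v2 <- xr[2, ] - xr[1, ]
    expect_lt(sqrt(sum((v1[c(2, 3, 1)] * v2[c(3, 1, 2)] -
                          v1[c(3, 1, 2)] * v2[c(2, 3, 1)])^2)), 1e-12)
    expect_gt(sum(v1 * v2), 0)
  }
  ## degenerate geometry is a hard error
  xz <- rbind(c(0, 0, 0), c(0, 0, 0), c(1, 1, 1))
  expect_error(place_link_atoms(xz, rm_, ls), "zero-length")
})

test_that("HL gradient components project onto CL and Q1 by the chain rule", {
  fx <- build_fixture("ethanol_methanol")
  pl <- place_link_atoms(fx$structure, fx$region_map, fx$link_specs)
  g <- fx$link_specs$g[1]
  ## zero HL gradient: pass-through
  gin <- matrix(seq_len(18), 6, 3)
  gin[pl$hl_rows[1], ] <- 0
  gout <- project_link_gradient(gin, fx$region_map, fx$link_specs, pl, 9)
  expect_equal(gout[1:5, ], gin[1:5, ])
  expect_equal(gout[6:9, ], matrix(0, 4, 3))
  ## unit x gradient on HL splits as g on CL and (1-g) on Q1
  gin2 <- matrix(0, 6, 3)
  gin2[pl$hl_rows[1], 1] <- 1
  gout2 <- project_link_gradient(gin2, fx$region_map, fx$link_specs, pl, 9)
  expect_equal(gout2[6, 1], g)
  expect_equal(gout2[3, 1], 1 - g)
  expect_equal(sum(gout2), 1)
})

test_that("the scaled link force constant reproduces the CL bond energy for every length", {
  expect_equal(scale_link_force_constant(250, 1.4, 1.4), 250)
  k_hl <- scale_link_force_constant(310, 1.526, 1.09)
  expect_equal(k_hl, 607.6, tolerance = 1e-12)
  g <- 1.09 / 1.526
  r <- seq(1.0, 2.2, length.out = 25)
  expect_lt(max(abs(k_hl * (g * r - 1.09)^2 - 310 * (r - 1.526)^2)), 1e-10)
  ## negative control: the inverted ratio breaks the identity off-equilibrium
  k_bad <- 310 * (1.09 / 1.526)^2
  expect_gt(max(abs(k_bad * (g * r - 1.09)^2 - 310 * (r - 1.526)^2)), 1e-2)
  expect_error(scale_link_force_constant(-1, 1, 1), "positive")
})

test_that("truncating ethanol yields exactly the methanol term inventory", {
  fx <- build_fixture("ethanol_methanol")
  tr <- build_truncated_topology(fx$topology, fx$region_map, fx$link_specs,
                                 "zero")
  top <- tr$topology
  nm <- top$atoms$name
  expect_equal(nm, c("HO", "O", "C1", "H11", "H12", "HL1"))
  bond_set <- sort(paste(nm[top$bonds$i], nm[top$bonds$j], sep = "-"))
  expect_equal(bond_set, sort(c("HO-O", "O-C1", "C1-H11", "C1-H12", "C1-HL1")))
  ang_set <- sort(paste(nm[top$angles$i], nm[top$angles$j], nm[top$angles$k],
                        sep = "-"))
  expect_equal(ang_set, sort(c("HO-O-C1", "O-C1-H11", "O-C1-H12", "O-C1-HL1",
                               "H11-C1-H12", "H11-C1-HL1", "H12-C1-HL1")))
  dih_set <- sort(paste(nm[top$dihedrals$i], nm[top$dihedrals$j],
                        nm[top$dihedrals$k], nm[top$dihedrals$l], sep = "-"))
  expect_equal(dih_set, sort(c("HO-O-C1-H11", "HO-O-C1-H12", "HO-O-C1-HL1")))
  ## the link bond carries the QM-ideal length and the rescaled constant
  lb <- top$bonds[top$bonds$j == 6 | top$bonds$i == 6, ]
  expect_equal(lb$r0, 1.090)
  expect_equal(lb$kb, 607.6, tolerance = 1e-10)
  ## copied angle parameters are the CL-side ones, unchanged
  oca <- top$angles[top$angles$i == 2 & top$angles$k == 6, ]
  full_oca <- fx$topology$angles[fx$topology$angles$i == 2 &
                                   fx$topology$angles$k == 6, ]
  expect_equal(oca$kth, full_oca$kth)
  expect_equal(oca$th0, full_oca$th0)
  ## zeroed charges for the electrostatic-embedding variant
  expect_equal(top$atoms$charge, rep(0, 6))
  expect_length(validate_topology(top), 0)
})

test_that("a whole-molecule QM region truncates to the full topology", {
  fx <- build_fixture("ethanol_methanol")
  rm_all <- assign_regions(fx$topology, 1:9)
  ls <- link_spec(fx$topology, rm_all, r0_hl = numeric(0))
  tr <- build_truncated_topology(fx$topology, rm_all, ls, "keep")
  expect_equal(tr$topology$bonds, fx$topology$bonds, ignore_attr = TRUE)
  expect_equal(tr$topology$angles, fx$topology$angles, ignore_attr = TRUE)
  expect_equal(tr$topology$dihedrals, fx$topology$dihedrals, ignore_attr = TRUE)
  expect_equal(tr$topology$atoms$charge, fx$topology$atoms$charge)
})

test_that("bonded CL pairs lose every cross-junction term in the truncated topology", {
  fx <- build_fixture("butane_bonded_cl")
  tr <- build_truncated_topology(fx$topology, fx$region_map, fx$link_specs,
                                 "zero")
  top <- tr$topology
  hl <- tr$hl_rows
  ## enumeration oracle: count the full-system all-QM terms whose bond path
  ## uses the CL-CL bond; none of them may survive
  reg <- fx$region_map$region
  clcl <- fx$region_map$cl_cl_bonds
  spans <- function(v) any(vapply(seq_len(length(v) - 1), function(s)
    any((v[s] == clcl$i & v[s + 1] == clcl$j) |
        (v[s] == clcl$j & v[s + 1] == clcl$i)), logical(1)))
  count_spanning <- 0
  for (r in seq_len(nrow(fx$topology$angles))) {
    v <- unlist(fx$topology$angles[r, c("i", "j", "k")])
    if (all(reg[v] == "QM") && spans(v)) count_spanning <- count_spanning + 1
  }
  expect_gt(count_spanning, 0)
  ## no bond between the two HL atoms, and no term containing both
  expect_false(any((top$bonds$i %in% hl) & (top$bonds$j %in% hl)))
  for (cl in list(top$angles[, c("i", "j", "k")],
                  top$dihedrals[, c("i", "j", "k", "l")]))
    if (nrow(cl)) expect_true(all(rowSums(matrix(unlist(cl) %in% hl,
                                                 nrow(cl))) < 2))
  expect_length(validate_topology(top), 0)
  ## expected surviving counts: two independent methyl-HL fragments
  expect_equal(nrow(top$bonds), 8)    # 2 x (3 C-H + C-HL)
  expect_equal(nrow(top$angles), 12)  # 2 x C(4,2)
  expect_equal(nrow(top$dihedrals), 0)
})

test_that("the truncated topology never references MM atoms", {
  for (nm in FIXTURES) {
    fx <- build_fixture(nm)
    tr <- build_truncated_topology(fx$topology, fx$region_map, fx$link_specs,
                                   "zero")
    n1 <- nrow(tr$topology$atoms)
    idx <- c(unlist(tr$topology$bonds[, c("i", "j")]),
             unlist(tr$topology$angles[, c("i", "j", "k")]),
             unlist(tr$topology$dihedrals[, c("i", "j", "k", "l")]),
             unlist(tr$topology$excl), unlist(tr$topology$pairs14[, c("i", "j")]))
    expect_true(all(idx >= 1 & idx <= n1))
    expect_equal(sum(fx$region_map$region == "QM"), n1)
  }
})

test_that("colinearity makes copied CL-parameter angle and torsion terms exact", {
  ## any Q2-Q1-HL angle equals Q2-Q1-CL, and torsions ending in HL equal
  ## those ending in CL, for random geometries
  fx <- build_fixture("ethanol_methanol")
  for (s in 1:10) {
    x <- perturb_structure(fx$structure, 0.15, s)
    pl <- place_link_atoms(x, fx$region_map, fx$link_specs)
    hl <- pl$coords[pl$hl_rows[1], ]
    expect_equal(angle_of(x[2, ], x[3, ], hl), angle_of(x[2, ], x[3, ], x[6, ]),
                 tolerance = 1e-12)
    expect_equal(torsion_of(x[1, ], x[2, ], x[3, ], hl),
                 torsion_of(x[1, ], x[2, ], x[3, ], x[6, ]), tolerance = 1e-10)
  }
})
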