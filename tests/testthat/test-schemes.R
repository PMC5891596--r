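test_that("the additive MM term is exactly the cherry-picked term inventory", {
  ## on ethanol, the included MM terms must be: the C2-H2 bonds, the
  ## C1-C2-H2 angles, the O/H1-C1-C2-H2 dihedrals, the MM-MM electrostatics
  ## and every vdW pair that is not QM-QM -- computed here by direct
  ## enumeration, independent of the term filters
  fx <- build_fixture("ethanol_methanol", jitter = 0.03, seed = 8)
  x <- fx$structure
  top <- fx$topology
  reg <- fx$region_map$region
  e_bond <- 0
  for (r in seq_len(nrow(top$bonds))) {
    v <- c(top$bonds$i[r], top$bonds$j[r])
    if (any(reg[v] == "MM"))
      e_bond <- e_bond + top$bonds$kb[r] *
        (sqrt(sum((x[v[1], ] - x[v[2], ])^2)) - top$bonds$r0[r])^2
  }
  e_ang <- 0
  for (r in seq_len(nrow(top$angles))) {
    v <- unlist(top$angles[r, c("i", "j", "k")])
    if (any(reg[v] == "MM"))
      e_ang <- e_ang + top$angles$kth[r] *
        (angle_of(x[v[1], ], x[v[2], ], x[v[3], ]) - top$angles$th0[r])^2
  }
  e_dih <- 0
  for (r in seq_len(nrow(top$dihedrals))) {
    v <- unlist(top$dihedrals[r, c("i", "j", "k", "l")])
    if (any(reg[v] == "MM"))
      e_dih <- e_dih + top$dihedrals$vn2[r] *
        (1 + cos(top$dihedrals$per[r] *
                   torsion_of(x[v[1], ], x[v[2], ], x[v[3], ], x[v[4], ]) -
                   top$dihedrals$phase[r]))
  }
  d <- graph_dist(cbind(top$bonds$i, top$bonds$j), 9)
  e_vdw <- e_elec <- 0
  for (i in 1:8) for (j in (i + 1):9) {
    if (d[i, j] <= 2) next
    r <- sqrt(sum((x[i, ] - x[j, ])^2))
    both_mm <- reg[i] == "MM" && reg[j] == "MM"
    both_qm <- reg[i] == "QM" && reg[j] == "QM"
    if (!both_qm) {
      p1 <- top$lj[top$lj$type == top$atoms$type[i], ]
      p2 <- top$lj[top$lj$type == top$atoms$type[j], ]
      e_vdw <- e_vdw + lj_pair_energy(p1$rmin_half, p1$eps, p2$rmin_half,
                                      p2$eps, r,
                                      if (d[i, j] == 3) top$scnb else 1)
    }
    if (both_mm)
      e_elec <- e_elec + 332.0522 * fx$mm_charges[i] * fx$mm_charges[j] / r /
        (if (d[i, j] == 3) top$scee else 1)
  }
  rep <- qmmm_energy(fx, "add", gradient = FALSE)
  expect_equal(unname(rep$terms["mm21"]), e_bond + e_ang + e_dih + e_vdw + e_elec,
               tolerance = 1e-10)
  ## by class as well
  cmp <- rep$mm_components$mm21
  expect_equal(unname(cmp["bond"]), e_bond, tolerance = 1e-10)
  expect_equal(unname(cmp["angle"]), e_ang, tolerance = 1e-10)
  expect_equal(unname(cmp["dihedral"]), e_dih, tolerance = 1e-10)
  expect_equal(unname(cmp["vdw"] + cmp["vdw14"]), e_vdw, tolerance = 1e-10)
  expect_equal(unname(cmp["elec"] + cmp["elec14"]), e_elec, tolerance = 1e-10)
})

test_that("degenerate regions collapse to pure MM or pure QM", {
  fx <- build_fixture("ethanol_methanol")
  ## QM region = whole molecule: no junctions, no point charges, bare QM
  rm_all <- assign_regions(fx$topology, 1:9)
  ls0 <- link_spec(fx$topology, rm_all, r0_hl = numeric(0))
  sys_all <- qmmm_system(fx$topology, fx$structure, rm_all, ls0,
                         mm_charges = fx$mm_charges)
  rep <- qmmm_energy(sys_all, "add", gradient = FALSE)
  expect_equal(unname(rep$terms["mm21"]), 0)
  tr <- build_truncated_topology(fx$topology, rm_all, ls0, "zero")
  bare_qm <- mm_energy(tr$topology, fx$structure, gradient = FALSE)$total
  expect_equal(rep$total, bare_qm, tolerance = 1e-12)
})

test_that("the strict-subtractive assembly reproduces the additive result exactly", {
  for (nm in FIXTURES) {
    fx <- build_fixture(nm, jitter = 0.06, seed = 23)
    add <- qmmm_energy(fx, "add")
    strict <- qmmm_energy(fx, "sub-strict")
    expect_lt(abs(add$total - strict$total), 1e-10)
    expect_lt(max(abs(add$gradient - strict$gradient)), 1e-10)
    expect_length(strict$terms, 3)
    expect_length(add$terms, 2)
  }
})

test_that("the subtractive-additive difference is the enumerated link-atom correction", {
  for (nm in FIXTURES) {
    fx <- build_fixture(nm, jitter = 0.06, seed = 29)
    diff <- qmmm_energy(fx, "sub", gradient = FALSE)$total -
      qmmm_energy(fx, "add", gradient = FALSE)$total
    expect_lt(abs(diff - brute_link_correction(fx)), 1e-10)
  }
  ## the one-junction fixture's only CL-involving intra-QM vdW partner (the
  ## hydroxyl hydrogen) has zero well depth, so the subtractive scheme and
  ## the additive scheme coincide exactly there
  eth <- build_fixture("ethanol_methanol", jitter = 0.1, seed = 5)
  expect_lt(abs(qmmm_energy(eth, "sub", gradient = FALSE)$total -
                qmmm_energy(eth, "add", gradient = FALSE)$total), 1e-10)
  ## the bonded-CL fixture has a genuinely nonzero correction
  but <- build_fixture("butane_bonded_cl")
  expect_gt(abs(qmmm_energy(but, "sub", gradient = FALSE)$total -
                qmmm_energy(but, "add", gradient = FALSE)$total), 1e-3)
})

test_that("mechanical embedding with matched charges collapses onto the plain MM energy", {
  for (nm in FIXTURES) {
    fx <- build_fixture(nm, jitter = 0.04, seed = 19)
    me <- qmmm_energy(fx, "me", matched_charges = TRUE, gradient = FALSE)
    ref <- mm_energy(fx$topology, fx$structure, gradient = FALSE)
    expect_equal(me$total, ref$total, tolerance = 1e-12)
    ## and the QM/small-system terms cancel exactly
    expect_equal(unname(me$terms["qm"] + me$terms["mm1"]), 0)
  }
})

test_that("mechanical embedding and ELAC assemble their distinct charge sets", {
  fx <- build_fixture("butane_bonded_cl", jitter = 0.04, seed = 3)
  me <- qmmm_energy(fx, "me", gradient = FALSE)
  elac <- qmmm_energy(fx, "elac", gradient = FALSE)
  expect_equal(me$embedding, "mechanical")
  expect_equal(elac$embedding, "electrostatic")
  ## the two differ exactly by the embedding interactions present in both
  ## the QM term and the subtracted small-system term of ELAC -- which
  ## cancel with the surrogate backend, leaving ME == ELAC totals
  expect_equal(me$total, elac$total, tolerance = 1e-10)
  ## with a backend whose density response is NOT the surrogate charges,
  ## the two schemes genuinely differ
  be <- fake_qm_backend(7)
  me2 <- qmmm_energy(fx, "me", be, gradient = FALSE)
  el2 <- qmmm_energy(fx, "elac", be, gradient = FALSE)
  expect_gt(abs(me2$total - el2$total), 1e-6)
})

test_that("dummy intra-QM parameters cannot leak into the subtractive total", {
  be <- fake_qm_backend(4)
  set.seed(77)
  for (nm in FIXTURES) {
    fx <- build_fixture(nm, jitter = 0.05, seed = 13)
    e0 <- qmmm_energy(fx, "sub", be, gradient = FALSE)$total
    for (p in eligible_dummy_params(fx)) {
      f2 <- fx
      f2$topology[[p$class]][[p$par]][p$row] <-
        f2$topology[[p$class]][[p$par]][p$row] * runif(1, 1.3, 2.5) + runif(1)
      expect_lt(abs(qmmm_energy(f2, "sub", be, gradient = FALSE)$total - e0),
                1e-10)
    }
  }
})

test_that("BLAC parameter substitution is surgical and *J restores the link identity", {
  fx <- build_fixture("ethanol_methanol", jitter = 0.05, seed = 9)
  ## a QM backend blind to MM parameters, so the substitution shows up only
  ## through the MM bookkeeping (as with a real QM program)
  be <- fake_qm_backend(3)
  ## empty alternate tables: BLAC degenerates to the standard subtractive
  b0 <- qmmm_energy(fx, "blac", be, blac = list(), gradient = FALSE)
  s0 <- qmmm_energy(fx, "sub", be, gradient = FALSE)
  expect_equal(b0$total, s0$total, tolerance = 1e-12)
  ## substituting one HL-side angle parameter changes the small-system term
  ## by exactly the closed-form single-term difference
  tr <- build_truncated_topology(fx$topology, fx$region_map, fx$link_specs,
                                 "zero")
  pl <- place_link_atoms(fx$structure, fx$region_map, fx$link_specs)
  row <- which(tr$topology$atoms$type[tr$topology$angles$i] == "oh" &
                 tr$topology$atoms$type[tr$topology$angles$k] == "hl")
  a <- tr$topology$angles[row, ]
  th <- angle_of(pl$coords[a$i, ], pl$coords[a$j, ], pl$coords[a$k, ])
  old_term <- a$kth * (th - a$th0)^2
  new_term <- 63 * (th - 1.95)^2
  b1 <- qmmm_energy(fx, "blac", be,
                    blac = list(hl = list(list(class = "angle",
                                               types = c("oh", "c3", "hl"),
                                               kth = 63, th0 = 1.95))),
                    gradient = FALSE)
  ## the substituted term sits in the subtracted E_MM1, so the total moves
  ## by -(new - old)
  expect_equal(b1$total - s0$total, -(new_term - old_term), tolerance = 1e-10)
  ## unknown parameter key is an explicit error naming the tuple
  expect_error(qmmm_energy(fx, "blac",
                           blac = list(hl = list(list(class = "angle",
                                                      types = c("xx", "yy", "zz"),
                                                      kth = 1))),
                           gradient = FALSE),
               "xx-yy-zz")
})

test_that("*J rescaling cancels the link-bond contribution for all geometries", {
  fx <- build_fixture("ethanol_methanol")
  ## alter the CL-side link-bond force constant (equilibrium kept), then let
  ## the *J rule reset the HL-side constant; the Q1-HL bond energy at the
  ## mapped HL position must equal the Q1-CL bond energy for every geometry
  alt_cl <- list(list(class = "bond", types = c("c3", "c3"), kb = 287))
  tr0 <- build_truncated_topology(fx$topology, fx$region_map, fx$link_specs,
                                  "zero")
  mod <- apply_blac_parameters(tr0, fx$topology, alt_params_cl = alt_cl,
                               link_specs = fx$link_specs,
                               rescale_link_k = TRUE)
  hlrow <- tr0$hl_rows[1]
  bf <- mod$full$bonds[mod$full$bonds$i == 3 & mod$full$bonds$j == 6, ]
  bt <- mod$trunc$topology$bonds
  bt <- bt[pmin(bt$i, bt$j) == 3 & pmax(bt$i, bt$j) == hlrow, ]
  expect_equal(bf$kb, 287)
  expect_equal(bt$kb, 287 * (1.526 / 1.09)^2, tolerance = 1e-12)
  g <- fx$link_specs$g[1]
  for (s in 1:10) {
    x <- perturb_structure(fx$structure, 0.15, s)
    r_cl <- sqrt(sum((x[3, ] - x[6, ])^2))
    r_hl <- g * r_cl
    expect_lt(abs(bt$kb * (r_hl - bt$r0)^2 - bf$kb * (r_cl - bf$r0)^2), 1e-10)
  }
  ## negative control: without rescaling, the HL side keeps the old constant
  ## and the two bond energies differ off-equilibrium
  mod2 <- apply_blac_parameters(tr0, fx$topology, alt_params_cl = alt_cl,
                                link_specs = fx$link_specs,
                                rescale_link_k = FALSE)
  bt2 <- mod2$trunc$topology$bonds
  bt2 <- bt2[pmin(bt2$i, bt2$j) == 3 & pmax(bt2$i, bt2$j) == hlrow, ]
  r_cl <- 1.7
  expect_gt(abs(bt2$kb * (g * r_cl - bt2$r0)^2 - 287 * (r_cl - 1.526)^2), 1e-3)
})

test_that("scheme reports decompose losslessly", {
  fx <- build_fixture("propane_two_junctions")
  add <- qmmm_energy(fx, "add", gradient = FALSE)
  sub <- qmmm_energy(fx, "sub", gradient = FALSE)
  da <- scheme_decomposition(add)
  ds <- scheme_decomposition(sub)
  expect_equal(sum(da$kcal_mol[da$class == "total"]), add$total,
               tolerance = 1e-12)
  expect_equal(sum(ds$kcal_mol[ds$class == "total"]), sub$total,
               tolerance = 1e-12)
  expect_equal(nrow(da[da$class == "total", ]), 2)
  expect_equal(nrow(ds[ds$class == "total", ]), 3)
  expect_equal(da$kj_mol, da$kcal_mol * 4.184)
  skip_if_not_installed("jsonlite")
  json <- jsonlite::toJSON(ds, digits = NA)
  back <- jsonlite::fromJSON(json)
  expect_equal(back$kcal_mol, ds$kcal_mol)
})
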