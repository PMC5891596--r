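## one-junction system with a single free QM atom for closed-form optima
single_bond_system <- function(kb = 310, r0 = 1.5) {
  atoms <- data.frame(name = c("A", "B", "M"), element = c("C", "C", "H"),
                      type = c("c3", "c3", "hc"), mass = c(12, 12, 1.008),
                      charge = 0, res_id = 1L, res_name = "OPT")
  lj <- data.frame(type = c("c3", "hc", "hl"), rmin_half = 0, eps = 0)
  top <- topology(atoms, lj,
                  bonds = data.frame(i = c(1, 2), j = c(2, 3),
                                     kb = c(kb, 340), r0 = c(r0, 1.09)),
                  angles = data.frame(i = integer(), j = integer(),
                                      k = integer(), kth = numeric(),
                                      th0 = numeric()),
                  dihedrals = data.frame(i = integer(), j = integer(),
                                         k = integer(), l = integer(),
                                         vn2 = numeric(), per = numeric(),
                                         phase = numeric()))
  rm_ <- assign_regions(top, 1:2)
  ls <- link_spec(top, rm_, r0_hl = 1.09)
  x <- rbind(c(0, 0, 0), c(1.8, 0, 0), c(2.9, 0.9, 0))
  qmmm_system(top, x, rm_, ls)
}

test_that("a single harmonic bond relaxes to its equilibrium length", {
  sys <- single_bond_system(kb = 310, r0 = 1.5)
  ## atom 1 free, everything else frozen
  out <- minimize(sys, scheme = "sub", frozen = 2:3, max_iter = 200)
  expect_true(out$converged)
  expect_equal(sqrt(sum((out$structure[1, ] - out$structure[2, ])^2)), 1.5,
               tolerance = 1e-5)
  ## frozen atoms bitwise untouched
  expect_identical(out$structure[2:3, ], sys$structure[2:3, ])
  ## energies non-increasing over accepted steps
  expect_true(all(diff(out$trajectory) <= 0))
})

test_that("a restrained bond converges to the weighted stationary point", {
  K <- 310; r_eq <- 1.5; k_res <- 150; r_tgt <- 1.9
  sys <- single_bond_system(kb = K, r0 = r_eq)
  out <- minimize(sys, scheme = "sub", frozen = 2:3,
                  restraints = data.frame(i = 1, j = 2, target = r_tgt,
                                          k = k_res))
  r_star <- (K * r_eq + k_res * r_tgt) / (K + k_res)
  expect_equal(sqrt(sum((out$structure[1, ] - out$structure[2, ])^2)), r_star,
               tolerance = 1e-5)
  ## re-running from the converged point changes nothing appreciable
  sys2 <- sys; sys2$structure <- out$structure
  out2 <- minimize(sys2, scheme = "sub", frozen = 2:3,
                   restraints = data.frame(i = 1, j = 2, target = r_tgt,
                                           k = k_res))
  expect_lt(abs(out2$energy - out$energy), 1e-8)
  expect_error(minimize(sys, restraints = data.frame(i = 1, j = 1,
                                                     target = 1, k = 1)),
               "distinct")
})

test_that("starting at the minimum leaves the structure unchanged", {
  sys <- single_bond_system()
  out <- minimize(sys, scheme = "sub", frozen = 2:3)
  sys2 <- sys; sys2$structure <- out$structure
  out2 <- minimize(sys2, scheme = "sub", frozen = 2:3)
  expect_lt(max(abs(out2$structure - out$structure)), 1e-5)
})

test_that("a frozen-MM minimization of ethanol lowers the scheme energy", {
  fx <- build_fixture("ethanol_methanol", jitter = 0.05, seed = 12)
  e0 <- qmmm_energy(fx, "sub", gradient = FALSE)$total
  out <- minimize(fx, scheme = "sub", max_iter = 300)
  expect_lt(out$energy, e0)
  expect_identical(out$structure[7:9, ], fx$structure[7:9, ])
  expect_true(out$converged)
})

test_that("rmsd handles translations, subsets and superposition", {
  a <- rbind(c(0, 0, 0), c(1, 0, 0))
  b <- rbind(c(0, 0, 0), c(1.2, 0, 0))
  expect_equal(rmsd(a, a), 0)
  expect_equal(rmsd(a, b), sqrt(0.04 / 2), tolerance = 1e-12)
  ## rigid translation: |t| raw, 0 after superposition
  x <- matrix(rnorm(15, sd = 2), 5, 3)
  t_vec <- c(1, -2, 2)
  xt <- sweep(x, 2, t_vec, "+")
  expect_equal(rmsd(x, xt), sqrt(sum(t_vec^2)), tolerance = 1e-10)
  expect_lt(rmsd(x, xt, superpose = TRUE), 1e-10)
  ## superposed rmsd invariant under any rigid transform of either input
  th <- 1.1
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  y <- perturb_structure(x, 0.1, 3)
  r0 <- rmsd(x, y, superpose = TRUE)
  expect_equal(rmsd(x, sweep(y %*% R, 2, c(3, 1, -2), "+"), superpose = TRUE),
               r0, tolerance = 1e-8)
  expect_equal(rmsd(sweep(x %*% R, 2, t_vec, "+"), y, superpose = TRUE), r0,
               tolerance = 1e-8)
  ## subset selection and the 3-atom superposition floor
  expect_equal(rmsd(x, y, atom_subset = 1:3, superpose = TRUE),
               rmsd(x[1:3, ], y[1:3, ], superpose = TRUE))
  expect_error(rmsd(a, b, superpose = TRUE), "at least 3")
})

test_that("rmsd agrees with an independent implementation", {
  skip_if_not_installed("bio3d")
  x <- matrix(rnorm(27), 9, 3)
  y <- perturb_structure(x, 0.2, 8)
  expect_equal(round(rmsd(x, y, superpose = TRUE), 3),
               bio3d::rmsd(as.vector(t(x)), as.vector(t(y)), fit = TRUE))
})

test_that("internal-coordinate MADs follow their definitions and wrap dihedrals", {
  fx <- build_fixture("ethanol_methanol")
  x <- fx$structure
  expect_equal(unname(mad_internal_coordinates(x, x, fx$topology)),
               c(0, 0, 0))
  ## stretch one bond by +0.08: MAD over the 8 bonds is 0.01
  b1 <- fx$topology$bonds[1, ]
  u <- (x[b1$i, ] - x[b1$j, ])
  u <- u / sqrt(sum(u^2))
  x2 <- x
  x2[b1$i, ] <- x2[b1$i, ] + 0.08 * u
  mads <- mad_internal_coordinates(x, x2, fx$topology)
  expect_equal(unname(mads["mad_bond"]), 0.08 / 8, tolerance = 1e-10)
  ## wrap-around: a 179 vs -179 degree torsion contributes 2, not 358
  atoms <- data.frame(name = c("A", "B", "C", "D"), element = "C", type = "c3",
                      mass = 12, charge = 0, res_id = 1L, res_name = "TOR")
  lj <- data.frame(type = "c3", rmin_half = 1.9, eps = 0.1)
  chain <- topology(atoms, lj,
                    bonds = data.frame(i = 1:3, j = 2:4, kb = 310, r0 = 1.5),
                    angles = data.frame(i = integer(), j = integer(),
                                        k = integer(), kth = numeric(),
                                        th0 = numeric()),
                    dihedrals = data.frame(i = 1, j = 2, k = 3, l = 4,
                                           vn2 = 0.1, per = 3, phase = 0))
  geom_at <- function(phi_deg) {
    phi <- phi_deg * pi / 180
    rbind(c(1, 0, -0.5), c(0, 0, 0), c(0, 0, 1.5),
          c(cos(phi), sin(phi), 2.0))
  }
  m <- mad_internal_coordinates(geom_at(179), geom_at(-179), chain)
  expect_equal(unname(m["mad_dihedral"]), 2, tolerance = 1e-8)
  expect_equal(unname(m["mad_bond"]), 0, tolerance = 1e-10)
})
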