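test_that("insertion energy reproduces LJ landmarks and the pair-sum oracle", {
  probe <- probe_spec(epsilon = 0.4, sigma = 3.0, bond_length = 1.2)
  s <- ils_settings()
  sig_c <- (3.0 + 3.0) / 2
  eps_c <- sqrt(0.4 * 0.4)
  # matrix atom at the LJ minimum distance of site 1, other site far away:
  # the pair contributes exactly -eps_combined
  rmin <- 2^(1 / 6) * sig_c
  atom <- c(rmin + 0.6, 0, 0)  # site 1 sits at (0.6, 0, 0)
  e <- insertion_energy(matrix(atom, 1, 3), 0.4, 3.0, probe,
                        position = c(0, 0, 0), orientation = c(1, 0, 0),
                        settings = s)
  far <- lj_pair_oracle(rmin + 1.2, eps_c, sig_c)  # site 2 contribution
  expect_equal(e, -eps_c + far, tolerance = 1e-10)
  # pair distance exactly sigma: zero crossing
  atom2 <- c(sig_c + 0.6, 0, 0)
  e2 <- insertion_energy(matrix(atom2, 1, 3), 0.4, 3.0, probe,
                         position = c(0, 0, 0), orientation = c(1, 0, 0),
                         settings = s)
  expect_equal(e2, lj_pair_oracle(sig_c + 1.2, eps_c, sig_c),
               tolerance = 1e-12)
  # diatomic between two matrix atoms: four-pair hand enumeration
  coords <- rbind(c(3.1, 0.4, -0.2), c(-2.8, -0.5, 0.7))
  eps_m <- c(0.3, 0.6); sig_m <- c(3.2, 3.6)
  ori <- c(1, 1, 1) / sqrt(3)
  e3 <- insertion_energy(coords, eps_m, sig_m, probe,
                         position = c(0.2, -0.1, 0.3), orientation = ori,
                         settings = s)
  e3_o <- insertion_energy_oracle(coords, eps_m, sig_m, probe,
                                  c(0.2, -0.1, 0.3), ori)
  expect_equal(e3, e3_o, tolerance = 1e-10)
  expect_error(insertion_energy(coords, eps_m, sig_m, probe, c(0, 0, 0),
                                c(1, 1, 0), settings = s), "unit vector")
})

test_that("geometric combining rule is honored", {
  probe <- probe_spec(epsilon = 0.4, sigma = 2.5)
  sg <- ils_settings(combining_rule = "geometric")
  e <- insertion_energy(matrix(c(5, 0, 0), 1, 3), 0.9, 3.6, probe,
                        c(0, 0, 0), c(0, 0, 1), settings = sg)
  e_o <- insertion_energy_oracle(matrix(c(5, 0, 0), 1, 3), 0.9, 3.6, probe,
                                 c(0, 0, 0), c(0, 0, 1),
                                 rule = "geometric")
  expect_equal(e, e_o, tolerance = 1e-10)
})

test_that("zero-epsilon probe yields an identically zero map", {
  sys <- single_atom_system()
  m <- compute_ils_map(sys$ensemble, probe_spec(epsilon = 0), sys$grid,
                       ils_settings(n_insertions_per_voxel = 25, seed = 3))
  expect_true(all(m$grid$values == 0))
  expect_false(any(m$capped))
})

test_that("voxels beyond the cutoff from every site are exactly zero", {
  ens <- conformation_ensemble(array(c(2, 2, 2), c(1, 3, 1)), 0.5, 3.4,
                               c(60, 60, 60))
  far_grid <- scalar_grid3d(c(40, 40, 40), 1, c(3, 3, 3))
  m <- compute_ils_map(ens, probe_spec(), far_grid,
                       ils_settings(n_insertions_per_voxel = 50, seed = 5))
  expect_true(all(m$grid$values == 0))
})

test_that("maps are deterministic in the seed and flag capped voxels", {
  sys <- single_atom_system()
  s <- ils_settings(n_insertions_per_voxel = 60, seed = 17)
  m1 <- compute_ils_map(sys$ensemble, probe_spec(), sys$grid, s)
  m2 <- compute_ils_map(sys$ensemble, probe_spec(), sys$grid, s)
  expect_identical(m1$grid$values, m2$grid$values)
  # the atom's own voxel is deep core: capped at the sentinel
  core <- position_to_voxel(sys$grid, matrix(sys$atom, 1, 3))
  expect_true(m1$capped[core])
  expect_equal(as.vector(m1$grid$values)[core], sys$grid$value_cap)
})

test_that("pooled-frame maps equal the weighted combination of sub-ensembles", {
  spec <- toy_system_spec(c(12, 12, 12),
                          data.frame(x = c(5, 7), y = 6, z = 6,
                                     epsilon = 0.5, sigma = 3.3,
                                     thermal_sigma = 0.4), seed = 31)
  ens <- make_fluctuating_ensemble(spec, 5)
  grid <- scalar_grid3d(c(4, 5, 5), 1, c(5, 3, 3))
  s <- ils_settings(n_insertions_per_voxel = 40, seed = 8)
  kT <- 0.0083144621 * s$temperature
  full <- compute_ils_map(ens, probe_spec(), grid, s)
  part1 <- compute_ils_map(ensemble_subset_for_test(ens, 1:2),
                           probe_spec(), grid, s, frame_ids = 1:2)
  part2 <- compute_ils_map(ensemble_subset_for_test(ens, 3:5),
                           probe_spec(), grid, s, frame_ids = 3:5)
  comb <- -kT * log((2 / 5) * exp(-part1$grid$values / kT) +
                      (3 / 5) * exp(-part2$grid$values / kT))
  uncapped <- !full$capped & !part1$capped & !part2$capped
  expect_equal(full$grid$values[uncapped], comb[uncapped],
               tolerance = 1e-10)
})

test_that("reference conversion shifts values and refuses double conversion", {
  sys <- single_atom_system()
  m <- compute_ils_map(sys$ensemble, probe_spec(), sys$grid,
                       ils_settings(n_insertions_per_voxel = 40, seed = 2))
  m0 <- convert_reference(m, 0)
  expect_equal(m0$grid$values, m$grid$values)
  mw <- convert_reference(m, -2)
  un <- !m$capped
  expect_equal(mw$grid$values[un], m$grid$values[un] + 2)
  expect_equal(mw$grid$values[m$capped],
               rep(sys$grid$value_cap, sum(m$capped)))
  expect_identical(mw$reference, "water")
  expect_error(convert_reference(mw, 1), "already")
})

test_that("bulk offset: empty box and ideal gas give exactly zero", {
  empty <- conformation_ensemble(array(numeric(0), c(0, 3, 2)),
                                 numeric(0), numeric(0), c(20, 20, 20))
  r <- estimate_bulk_offset(empty, probe_spec(),
                            ils_settings(n_insertions_per_voxel = 10,
                                         periodic = TRUE, seed = 4),
                            n_boot = 20)
  expect_identical(r$dG, 0)
  one <- conformation_ensemble(array(c(10, 10, 10), c(1, 3, 1)), 0.5, 3.4,
                               c(20, 20, 20))
  r2 <- estimate_bulk_offset(one, probe_spec(epsilon = 0),
                             ils_settings(n_insertions_per_voxel = 10,
                                          periodic = TRUE, seed = 4),
                             n_boot = 0)
  expect_identical(r2$dG, 0)
})

test_that("bulk offset of a dilute LJ fluid matches radial quadrature", {
  # one atom in a periodic box is the dilute limit; by translation
  # invariance the box-average insertion factor reduces to a radial
  # integral around the atom
  box <- c(30, 30, 30)
  spec <- toy_system_spec(box, data.frame(x = 15, y = 15, z = 15,
                                          epsilon = 0.5, sigma = 3.4,
                                          thermal_sigma = 0.3), seed = 6)
  ens <- make_fluctuating_ensemble(spec, 5)
  probe <- probe_spec()
  grid <- scalar_grid3d(box / 20, box / 10, c(10, 10, 10))
  est <- estimate_bulk_offset(ens, probe,
                              ils_settings(n_insertions_per_voxel = 800,
                                           periodic = TRUE, seed = 12),
                              grid = grid, n_boot = 200)
  # oracle: h(r) from the quadrature table; box average =
  # 1 + (4 pi / V) * int r^2 (h(r) - 1) dr   (h = 1 beyond ~6 A)
  beta <- 1 / (kB_o * 310)
  epsc <- sqrt(0.5 * probe$epsilon[1]); sigc <- (3.4 + probe$sigma[1]) / 2
  d <- probe$bond_length / 2
  gl <- pracma::gaussLegendre(256, -1, 1)
  r <- seq(0.05, 8, by = 5e-4)
  base <- matrix(r^2 + d^2, length(r), 256)
  cross <- outer(2 * d * r, gl$x)
  h <- 0.5 * as.vector(
    exp(-beta * (lj_pair_oracle(sqrt(base + cross), epsc, sigc) +
                   lj_pair_oracle(sqrt(pmax(base - cross, 0)), epsc,
                                  sigc))) %*% gl$w)
  avg <- 1 + 4 * pi / prod(box) * sum(r^2 * (h - 1)) * 5e-4
  dG_oracle <- -log(avg) / beta
  expect_lt(abs(est$dG - dG_oracle), 2 * est$se + 0.02)
})

test_that("a purely repulsive added atom never lowers nearby free energies", {
  base <- conformation_ensemble(array(c(8, 8, 8), c(1, 3, 1)), 0.4, 3.2,
                                c(16, 16, 16))
  added <- conformation_ensemble(array(c(8, 10, 8, 8, 8, 8), c(2, 3, 1)),
                                 c(0.4, 1e-12), c(3.2, 3.2), c(16, 16, 16))
  grid <- scalar_grid3d(c(6, 6, 6), 1, c(5, 5, 5))
  s <- ils_settings(n_insertions_per_voxel = 200, seed = 9)
  m1 <- compute_ils_map(base, probe_spec(), grid, s)
  m2 <- compute_ils_map(added, probe_spec(), grid, s)
  # tiny epsilon keeps the r^-12 wall but shrinks the well: the combined
  # depth sqrt(1e-12 * 0.43) ~ 7e-7 kJ/mol bounds any possible decrease
  near <- rowSums(sweep(voxel_centers(grid), 2, c(10, 8, 8))^2) <= 4
  expect_true(all(m2$grid$values[near] >= m1$grid$values[near] - 1e-5))
})
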