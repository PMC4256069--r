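test_that("a ligand pinned at a voxel center gives exactly 1/A^3 there", {
  g <- scalar_grid3d(c(0, 0, 0), 1, c(5, 5, 5))
  traj <- ligand_trajectory(matrix(rep(c(2, 3, 1), 50), ncol = 3,
                                   byrow = TRUE), c(5, 5, 5))
  d <- compute_density_map(traj, g)
  target <- position_to_voxel(g, matrix(c(2, 3, 1), 1, 3))
  expect_equal(as.vector(d$values)[target], 1.0)
  expect_equal(sum(d$values != 0), 1L)
})

test_that("normalization is exact: sum * voxel volume = mean in-grid count", {
  set.seed(5)
  g <- scalar_grid3d(c(1, 1, 1), c(0.8, 1, 1.2), c(6, 5, 4))
  pos <- array(runif(40 * 3 * 3, 0, 9), c(40, 3, 3))
  pos[3, 2, ] <- NA  # an absent ligand record
  traj <- ligand_trajectory(pos, c(9, 9, 9))
  d <- compute_density_map(traj, g)
  flat <- matrix(aperm(pos, c(2, 1, 3)), ncol = 3)
  inside <- sum(!is.na(position_to_voxel(g, flat[complete.cases(flat), ])))
  expect_equal(sum(d$values) * prod(g$spacing), inside / 40)
  expect_equal(attr(d, "n_absent"), 1L)
})

test_that("the map is the frame-weighted average of per-frame maps", {
  set.seed(8)
  g <- scalar_grid3d(c(0, 0, 0), 1, c(4, 4, 4))
  pos <- array(runif(10 * 2 * 3, 0, 4), c(10, 2, 3))
  traj <- ligand_trajectory(pos, c(4, 4, 4))
  whole <- compute_density_map(traj, g)
  per <- lapply(1:10, function(f)
    compute_density_map(ligand_trajectory(array(pos[f, , ],
                                                c(1, 2, 3)),
                                          c(4, 4, 4)), g)$values)
  expect_equal(whole$values, Reduce(`+`, per) / 10)
})

test_that("uniform ligand approaches the flat density 1/V", {
  set.seed(13)
  g <- scalar_grid3d(c(1, 1, 1), 2, c(4, 4, 4))  # 8 A^3 voxels in 8^3 box
  n <- 40000
  traj <- ligand_trajectory(matrix(runif(n * 3, 0, 8), ncol = 3), c(8, 8, 8))
  d <- compute_density_map(traj, g)
  expected <- 1 / 512
  counts <- d$values * n * prod(g$spacing)
  sigma3 <- 3 * sqrt(n * (8 / 512))
  expect_true(all(abs(counts - n * 8 / 512) < sigma3))
})

test_that("sampled density ratios follow the Boltzmann factor of the field", {
  # frozen single atom in a small box; compare the density ratio between
  # the attractive shell and distant voxels with exp(-beta ddG) from
  # quadrature
  atom <- c(7, 7, 7)
  ens <- conformation_ensemble(array(atom, c(1, 3, 1)), 0.5, 3.4,
                               c(14, 14, 14))
  grid <- scalar_grid3d(c(2, 2, 2), 1, c(11, 11, 11))
  traj <- sample_explicit_ligand(ens, probe_spec(), n_steps = 400000,
                                 seed = 33, trans_step = 1.2,
                                 record_stride = 2)
  qv <- single_atom_quadrature(atom, 0.5, 3.4, probe_spec(), grid)
  d <- compute_density_map(traj, grid)
  cen <- voxel_centers(grid)
  rr <- sqrt(rowSums(sweep(cen, 2, atom)^2))
  shell <- which(abs(rr - 4) < 0.3)   # attractive shell voxels
  far <- which(rr > 4.9)
  n_shell <- sum(d$values[shell]); n_far <- sum(d$values[far])
  ratio_obs <- (n_shell / length(shell)) / (n_far / length(far))
  beta <- 1 / (kB_o * 310)
  w_shell <- mean(exp(-beta * qv[shell]))
  w_far <- mean(exp(-beta * qv[far]))
  expect_equal(ratio_obs, w_shell / w_far, tolerance = 0.1)
})

test_that("iso-level report counts voxels and 26-connected components", {
  g <- scalar_grid3d(c(0, 0, 0), 1, c(6, 6, 6))
  expect_equal(isosurface_report(g, 1)$n_voxels, 0L)
  expect_equal(isosurface_report(g, 1)$n_components, 0L)
  # two disjoint blobs
  v <- array(0, c(6, 6, 6))
  v[1:2, 1:2, 1:2] <- 5
  v[5:6, 5:6, 5:6] <- 5
  g2 <- scalar_grid3d(c(0, 0, 0), 1, c(6, 6, 6), v)
  rep2 <- isosurface_report(g2, 1)
  expect_equal(rep2$n_voxels, 16L)
  expect_equal(rep2$n_components, 2L)
  expect_equal(sum(rep2$mask$values), 16)
  # random masks match an independent flood fill
  set.seed(21)
  for (i in 1:10) {
    vals <- runif(216)
    g3 <- scalar_grid3d(c(0, 0, 0), 1, c(6, 6, 6), vals)
    rep3 <- isosurface_report(g3, 0.7)
    expect_equal(rep3$n_components,
                 flood_cc_oracle(vals >= 0.7, c(6, 6, 6)))
  }
})

test_that("region occupancy counts are exact and translation-covariant", {
  set.seed(2)
  pos <- array(runif(30 * 4 * 3, 0, 10), c(30, 4, 3))
  traj <- ligand_trajectory(pos, c(10, 10, 10))
  all_in <- region_spec("slab", axis = 1, min = 0, max = 10)
  r <- region_occupancy(traj, all_in)
  expect_true(all(r$counts == 4))
  expect_equal(r$mean, 4)
  half <- region_spec("slab", axis = 2, min = 0, max = 5)
  rh <- region_occupancy(traj, half)
  se <- stats::sd(rh$counts) / sqrt(30)
  expect_lt(abs(rh$mean - 2), 3 * se + 0.5)
  # translation covariance
  shifted <- ligand_trajectory(pos + rep(2, length(pos)), c(12, 12, 12))
  slab0 <- region_spec("slab", axis = 3, min = 2, max = 4)
  slab1 <- region_spec("slab", axis = 3, min = 4, max = 6)
  expect_equal(region_occupancy(shifted, slab1)$counts,
               region_occupancy(traj, slab0)$counts)
  # sphere and mask kinds agree with direct checks
  sph <- region_spec("sphere", center = c(5, 5, 5), radius = 3)
  rs <- region_occupancy(traj, sph, window = c(5, 20))
  direct <- vapply(1:30, function(f)
    sum(rowSums(sweep(matrix(pos[f, , ], 4, 3), 2, c(5, 5, 5))^2) <= 9),
    numeric(1))
  expect_equal(rs$counts, as.integer(direct))
  expect_equal(rs$mean, mean(direct[5:20]))
  expect_error(region_spec("slab", axis = 1, min = 5, max = 2), "ordered")
})
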