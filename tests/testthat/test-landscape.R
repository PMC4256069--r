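test_that("a strictly monotone single well gives one basin", {
  cen <- c(3, 3, 3)
  g <- scalar_grid3d(c(0, 0, 0), 1, c(5, 5, 5))
  g$values[] <- apply(voxel_centers(g), 1, function(p) sum((p - cen)^2))
  tess <- tessellate(g, 26, cutoff = 100)
  expect_equal(nrow(tess$minima), 1L)
  expect_equal(tess$minima$voxel, position_to_voxel(g, matrix(cen, 1, 3)))
  expect_true(all(tess$labels == 1L))
})

test_that("flat grids drain to the smallest linearized index (tie rule)", {
  g <- scalar_grid3d(c(0, 0, 0), 1, c(4, 4, 4), rep(2, 64))
  for (conn in c(6, 18, 26)) {
    tess <- tessellate(g, conn, cutoff = 10)
    expect_equal(nrow(tess$minima), 1L)
    expect_equal(tess$minima$voxel, 1L)
    expect_true(all(tess$labels == 1L))
  }
})

test_that("cutoff excludes voxels; full exclusion is flagged", {
  v <- c(rep(1, 32), rep(50, 32))
  g <- scalar_grid3d(c(0, 0, 0), 1, c(4, 4, 4), v)
  tess <- tessellate(g, 26, cutoff = 20)
  expect_equal(sum(is.na(tess$labels)), 32L)
  expect_warning(tessellate(g, 26, cutoff = 0), "empty tessellation")
})

test_that("a 1D ridge yields the constructed saddle", {
  v <- array(10, c(7, 3, 3))
  v[, 2, 2] <- c(0, 1, 3, 1, 0.5, 0.4, 0.5)  # wells at x=1 and x=6, ridge 3
  v[4, 2, 2] <- 3
  g <- scalar_grid3d(c(0, 0, 0), 1, c(7, 3, 3), v)
  tess <- tessellate(g, 6, cutoff = 100)
  sad <- find_saddles(g, tess)
  two <- sad[sad$energy < 10, ]
  expect_equal(nrow(two), 1L)
  expect_equal(two$energy, 3)
  la <- tess$labels[position_to_voxel(g, matrix(c(0, 1, 1), 1, 3))]
  lb <- tess$labels[position_to_voxel(g, matrix(c(5, 1, 1), 1, 3))]
  expect_setequal(c(two$basin_a, two$basin_b), c(la, lb))
})

test_that("saddle paths descend monotonically to both minima", {
  set.seed(41)
  for (i in 1:5) {
    g <- random_grid(c(7, 7, 7))
    tess <- tessellate(g, 26, cutoff = 100)
    sad <- find_saddles(g, tess)
    v <- as.vector(g$values)
    for (r in seq_len(nrow(sad))) {
      p <- sad$path[[r]]
      ends <- tess$minima$voxel[c(sad$basin_a[r], sad$basin_b[r])]
      expect_setequal(c(p[1], p[length(p)]), ends)
      expect_true(all(v[p] <= sad$energy[r] + 1e-12))
      # rises monotonically from minimum A to the crossing, then falls
      # monotonically to minimum B
      i_top <- which.max(v[p])
      expect_true(all(diff(v[p][seq_len(i_top)]) >= -1e-12))
      expect_true(all(diff(v[p][i_top:length(p)]) <= 1e-12))
    }
  }
})

test_that("non-adjacent basin pairs get no saddle", {
  # three wells along x separated by high walls; outer wells never touch
  v <- array(100, c(9, 3, 3))
  v[c(2, 5, 8), 2, 2] <- c(0, -1, 0.5)
  v[c(3, 4), 2, 2] <- c(30, 30)
  v[c(6, 7), 2, 2] <- c(30, 30)
  g <- scalar_grid3d(c(0, 0, 0), 1, c(9, 3, 3), v, value_cap = 1000)
  tess <- tessellate(g, 6, cutoff = 50)  # background excluded
  sad <- find_saddles(g, tess)
  l1 <- tess$labels[position_to_voxel(g, matrix(c(1, 1, 1), 1, 3))]
  l3 <- tess$labels[position_to_voxel(g, matrix(c(7, 1, 1), 1, 3))]
  direct <- sad$basin_a == min(l1, l3) & sad$basin_b == max(l1, l3)
  expect_false(any(direct))
})

test_that("tessellation and saddles match the brute-force oracles", {
  set.seed(99)
  for (i in 1:12) {
    g <- random_grid(c(6, 6, 6))
    conn <- sample(c(6, 18, 26), 1)
    cutoff <- sample(c(3, 100), 1)
    tess <- tessellate(g, conn, cutoff)
    o <- descent_oracle(as.vector(g$values), g$dims, conn, cutoff)
    expect_identical(tess$labels, o$labels)
    expect_equal(tess$minima$voxel, o$minima, ignore_attr = TRUE)
    sad <- find_saddles(g, tess)
    so <- saddle_oracle(as.vector(g$values), g$dims, tess$labels, conn)
    expect_equal(sad$basin_a, so$basin_a, ignore_attr = TRUE)
    expect_equal(sad$basin_b, so$basin_b, ignore_attr = TRUE)
    expect_equal(sad$energy, so$energy, ignore_attr = TRUE)
    expect_equal(sad$voxel, so$voxel, ignore_attr = TRUE)
  }
})

test_that("network construction respects the cutoff and flags exterior", {
  set.seed(55)
  g <- random_grid(c(6, 6, 6), lo = 0, hi = 10)
  tess <- tessellate(g, 26, cutoff = 100)
  sad <- find_saddles(g, tess)
  net_none <- build_network(g, tess, sad, cutoff = -1)
  expect_equal(nrow(net_none$edges), 0L)
  expect_equal(nrow(net_none$nodes), nrow(tess$minima))
  # edge sets are monotone in the cutoff
  cuts <- sort(unique(sad$energy))
  last <- 0L
  for (ct in c(cuts, Inf)) {
    n_now <- nrow(build_network(g, tess, sad, cutoff = ct)$edges)
    expect_gte(n_now, last)
    last <- n_now
  }
  # a basin holding a face voxel is exterior
  net <- build_network(g, tess, sad, cutoff = Inf)
  face_basin <- tess$labels[1]  # corner voxel is on three faces
  expect_true(net$nodes$exterior[face_basin])
  # barriers are saddle minus source minimum, non-negative
  expect_true(all(net$edges$barrier_ab >= -1e-12))
  expect_true(all(net$edges$barrier_ba >= -1e-12))
  expect_equal(net$edges$barrier_ab,
               net$edges$energy - net$nodes$energy[net$edges$basin_a])
})

test_that("profiles alternate and their barriers are thermodynamically consistent", {
  # assemble a network by analysis of a 1D three-well landscape
  v <- array(20, c(11, 3, 3))
  v[, 2, 2] <- c(5, -20.47, 10, -7.12, 8, -15, 20, 20, 20, 20, 20)
  g <- scalar_grid3d(c(0, 0, 0), 1, c(11, 3, 3), v, value_cap = 100)
  net <- analyze_landscape(g, cutoff = 50, connectivity = 6,
                           cutoff_mode = "voxel")
  ord <- order(net$nodes$x)
  deep <- ord[net$nodes$energy[ord] < 0]
  prof <- extract_profile(net, deep)
  expect_equal(prof$sequence$type,
               c("minimum", "saddle", "minimum", "saddle", "minimum"))
  # forward barrier = saddle - preceding minimum
  expect_equal(prof$forward_barriers[1], 10 - (-20.47))
  expect_equal(prof$forward_barriers[2], 8 - (-7.12))
  rev_prof <- extract_profile(net, rev(deep))
  expect_equal(rev_prof$forward_barriers, rev(prof$reverse_barriers))
  # forward minus reverse barrier equals the free-energy difference
  dg <- prof$sequence$energy[3] - prof$sequence$energy[1]
  expect_equal(prof$forward_barriers[1] - prof$reverse_barriers[1], dg)
  expect_error(extract_profile(net, c(deep[1], deep[3])), "no edge")
})

test_that("block errors implement half-difference and the uncomputable flag", {
  set.seed(77)
  g1 <- random_grid(c(6, 6, 6), lo = -8, hi = 8)
  same <- block_errors(g1, g1, cutoff = 100)
  expect_true(all(same$minima$error == 0, na.rm = TRUE))
  expect_false(any(same$minima$uncomputable))
  expect_false(any(same$saddles$uncomputable))
  g2 <- g1
  g2$values <- g1$values + 2
  shifted <- block_errors(g1, g2, cutoff = 100)
  expect_true(all(shifted$minima$error == 1.0))
  expect_true(all(shifted$saddles$error == 1.0))
  # a feature present in one block only is flagged, not zero
  g3 <- g1
  extra <- c(2, 2, 2)
  vox <- position_to_voxel(g1, matrix(extra, 1, 3))
  g3$values[vox] <- min(g1$values) - 10  # new deep minimum in block 2 only
  mixed <- block_errors(g1, g3, matching_radius = 0.5, cutoff = 100)
  expect_true(any(mixed$minima$uncomputable))
  expect_true(all(is.na(mixed$minima$error[mixed$minima$uncomputable])))
  expect_error(block_errors(g1, random_grid(c(5, 5, 5)), cutoff = 10),
               "identical grid")
})

test_that("analysis is deterministic: identical inputs, identical outputs", {
  set.seed(3)
  g <- random_grid(c(7, 7, 7))
  a <- analyze_landscape(g, cutoff = 100)
  b <- analyze_landscape(g, cutoff = 100)
  expect_identical(a$nodes, b$nodes)
  expect_identical(a$edges$energy, b$edges$energy)
  expect_identical(attr(a, "tessellation")$labels,
                   attr(b, "tessellation")$labels)
})
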