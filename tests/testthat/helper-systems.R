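# Small reference systems built in code for the tests.

# a single frozen carbon-like LJ atom centered in a large box, with an
# 11x11x11 / 1 A grid around it (the quadrature benchmark system)
single_atom_system <- function() {
  atom <- c(20, 20, 20)
  list(atom = atom, eps_m = 0.5, sig_m = 3.4,
       ensemble = conformation_ensemble(array(atom, c(1, 3, 1)),
                                        0.5, 3.4, c(40, 40, 40)),
       grid = scalar_grid3d(c(15, 15, 15), 1, c(11, 11, 11)))
}

# two octahedral attractive cages of different depth in a frozen box: a
# two-cavity system whose cavity free-energy difference is tunable via
# the cage epsilons; the 4.2 A cage radius leaves room for the diatomic
# probe to rotate without a site hitting a wall
two_cavity_system <- function(eps_a = 3.0, eps_b = 1.0, cage_r = 4.2) {
  centers <- rbind(A = c(5.5, 6, 6), B = c(12.5, 6, 6))
  octa <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1)) * cage_r
  coords <- rbind(sweep(octa, 2, centers[1, ], "+"),
                  sweep(octa, 2, centers[2, ], "+"))
  eps <- c(rep(eps_a, 6), rep(eps_b, 6))
  list(centers = centers,
       ensemble = conformation_ensemble(array(coords, c(12, 3, 1)),
                                        eps, rep(3.0, 12), c(18, 12, 12)))
}

# voxelized spherical region masks around the two cavity centers, on a
# grid covering both cages
two_cavity_regions <- function(sys, radius = 1.5, spacing = 0.5) {
  grid <- scalar_grid3d(c(3.5, 4, 4), spacing, c(22, 9, 9))
  cen <- voxel_centers(grid)
  mk <- function(center) {
    inside <- rowSums(sweep(cen, 2, center)^2) <= radius^2
    scalar_grid3d(grid$origin, grid$spacing, grid$dims, as.numeric(inside))
  }
  list(grid = grid, mask_a = mk(sys$centers[1, ]),
       mask_b = mk(sys$centers[2, ]))
}

# Boltzmann weight of a region mask under an fe_map (proportional to the
# expected ligand count in the region)
region_boltzmann_weight <- function(map, mask, temperature = 310) {
  beta <- 1 / (kB_o * temperature)
  sel <- as.vector(mask$values) > 0
  sum(exp(-beta * as.vector(map$grid$values)[sel]))
}

# the quadrature reference for the single-atom benchmark is deterministic
# and reused by several tests; memoize it
single_atom_reference <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sys <- single_atom_system()
      cache <<- single_atom_quadrature(sys$atom, sys$eps_m, sys$sig_m,
                                       probe_spec(), sys$grid, tol = 0.005)
    }
    cache
  }
})

ensemble_subset_for_test <- function(ens, idx) {
  conformation_ensemble(ens$coords[, , idx, drop = FALSE], ens$epsilon,
                        ens$sigma, ens$box_lengths)
}

random_grid <- function(dims, lo = -5, hi = 5, cap = 100) {
  scalar_grid3d(c(0, 0, 0), 1, dims,
                stats::runif(prod(dims), lo, hi), value_cap = cap)
}
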