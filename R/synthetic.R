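#' Specification of a synthetic fluctuating LJ matrix
#'
#' Describes a toy assembly of Lennard-Jones sites with per-site thermal
#' fluctuation amplitudes — a tractable stand-in for a fluctuating
#' macromolecular matrix with internal cavities and transiently open
#' constrictions. Site displacements are modelled as independent
#' isotropic Gaussians about the mean positions.
#'
#' @param box_lengths numeric(3), orthorhombic box edges (A); the box
#'   spans \code{[0, L]} on each axis.
#' @param sites data frame with columns \code{x, y, z} (mean positions, A),
#'   \code{epsilon} (kJ/mol), \code{sigma} (A), \code{thermal_sigma} (A)
#'   and logical \code{gate} flagging constriction sites.
#' @param cavity_centers optional matrix of engineered cavity centers (A).
#' @param temperature K.
#' @param seed integer; the single source of randomness for ensemble
#'   generation from this spec.
#' @param metadata free-form list documenting the geometry.
#' @return object of class \code{toy_system_spec}.
#' @export
toy_system_spec <- function(box_lengths, sites, cavity_centers = NULL,
                            temperature = 310, seed = 1, metadata = list()) {
  box_lengths <- rep_len(as.numeric(box_lengths), 3)
  .assert(all(box_lengths > 0), "box_lengths must be > 0")
  need <- c("x", "y", "z", "epsilon", "sigma", "thermal_sigma")
  miss <- setdiff(need, names(sites))
  .assert(length(miss) == 0,
          paste("sites is missing column(s):", paste(miss, collapse = ", ")))
  if (is.null(sites$gate)) sites$gate <- FALSE
  .assert(all(sites$sigma > 0), "site sigma must be > 0")
  .assert(all(sites$epsilon >= 0), "site epsilon must be >= 0")
  .assert(all(sites$thermal_sigma >= 0), "thermal_sigma must be >= 0")
  pos <- as.matrix(sites[, c("x", "y", "z")])
  inside <- sweep(pos, 2, box_lengths, "<=") & pos >= 0
  .assert(all(inside), "all mean positions must lie inside the box")
  .assert(temperature > 0, "temperature must be > 0")
  structure(list(box_lengths = box_lengths, sites = sites,
                 cavity_centers = cavity_centers,
                 temperature = temperature, seed = as.integer(seed),
                 metadata = metadata),
            class = "toy_system_spec")
}

#' @export
print.toy_system_spec <- function(x, ...) {
  cat("toy_system_spec:", nrow(x$sites), "sites (", sum(x$sites$gate),
      "gate ), box", paste(signif(x$box_lengths, 4), collapse = " x "),
      "A, T =", x$temperature, "K\n")
  invisible(x)
}

#' Generate a fluctuating conformational ensemble
#'
#' Each site's position in each frame is its mean plus an isotropic
#' Gaussian displacement of standard deviation \code{thermal_sigma},
#' drawn from a generator seeded by the spec — the same spec and seed
#' always reproduce the ensemble bit for bit.
#'
#' @param spec a \code{\link{toy_system_spec}}.
#' @param n_frames number of frames (>= 1).
#' @return a \code{\link{conformation_ensemble}}.
#' @export
make_fluctuating_ensemble <- function(spec, n_frames) {
  .assert(inherits(spec, "toy_system_spec"), "spec must be a toy_system_spec")
  .assert(n_frames >= 1, "n_frames must be >= 1")
  ns <- nrow(spec$sites)
  mu <- as.matrix(spec$sites[, c("x", "y", "z")])
  ts <- spec$sites$thermal_sigma
  set.seed(spec$seed)
  coords <- array(NA_real_, c(ns, 3, n_frames))
  for (f in seq_len(n_frames))
    coords[, , f] <- mu + matrix(stats::rnorm(3 * ns), ns, 3) * ts
  conformation_ensemble(coords, spec$sites$epsilon, spec$sites$sigma,
                        spec$box_lengths)
}

#' Synthetic gated two-compartment channel system
#'
#' Builds a cylindrical channel along x: an open mouth at low x, a tube
#' lined by repulsive/weakly attractive wall rings, a constriction ring
#' of gate sites halfway, an attractive cavity near the closed end, and
#' an end cap. The gate ring radius grows linearly with
#' \code{open_fraction}: at 0 the gate sites sit on the channel axis and
#' fully occlude it; at 1 they are retracted into the wall and the
#' aperture clears twice the probe diameter. The steric occlusion of the
#' constriction therefore decreases monotonically with
#' \code{open_fraction}, as does the exterior-to-cavity saddle energy of
#' the resulting insertion map.
#'
#' @param open_fraction number in [0, 1].
#' @param seed integer seed stored in the spec.
#' @return a \code{\link{toy_system_spec}} with gate sites flagged and the
#'   geometry (axis, gate radius and aperture, cavity center) in
#'   \code{$metadata}.
#' @export
make_channel_system <- function(open_fraction, seed = 1) {
  .assert(is.numeric(open_fraction) && length(open_fraction) == 1 &&
            open_fraction >= 0 && open_fraction <= 1,
          "open_fraction must be a number in [0, 1]")
  box <- c(20, 14, 14)
  cyl <- function(x, radius, n, eps, sig, tsig, gate = FALSE, phase = 0) {
    th <- phase + 2 * pi * (seq_len(n) - 1) / n
    data.frame(x = rep(x, n), y = 7 + radius * cos(th),
               z = 7 + radius * sin(th), epsilon = eps, sigma = sig,
               thermal_sigma = tsig, gate = gate)
  }
  wall <- do.call(rbind, lapply(seq(3, 15, by = 1.5), function(xx)
    cyl(xx, radius = 6, n = 10, eps = 0.5, sig = 3.4, tsig = 0.25,
        phase = 0.1 * xx)))
  sigma_gate <- 3.4
  # two staggered 4-site sub-rings: closed (open_fraction 0) they tile
  # the whole lumen cross-section; open they retract into the wall
  r_inner <- 1.2 + 4.8 * open_fraction
  r_outer <- 3.4 + 2.4 * open_fraction
  gate <- rbind(cyl(8.25, radius = r_inner, n = 4, eps = 0.5,
                    sig = sigma_gate, tsig = 0.4, gate = TRUE),
                cyl(8.25, radius = r_outer, n = 4, eps = 0.5,
                    sig = sigma_gate, tsig = 0.4, gate = TRUE,
                    phase = pi / 4))
  r_gate <- min(r_inner, r_outer)
  cav_shell <- cyl(12.75, radius = 6, n = 10, eps = 2.0, sig = 3.4,
                   tsig = 0.25, phase = 0.3)
  cav_inner <- cyl(12.75, radius = 4.5, n = 8, eps = 1.5, sig = 3.0,
                   tsig = 0.25, phase = 0.6)
  capg <- expand.grid(y = 7 + c(-4.8, -2.4, 0, 2.4, 4.8),
                      z = 7 + c(-4.8, -2.4, 0, 2.4, 4.8))
  cap <- data.frame(x = 15.75, y = capg$y, z = capg$z, epsilon = 0.5,
                    sigma = 3.4, thermal_sigma = 0.25, gate = FALSE)
  sites <- rbind(wall, gate, cav_shell, cav_inner, cap)
  # aperture diameter of the constriction (free gap across the axis)
  gap <- 2 * max(0, r_gate - sigma_gate / 2)
  toy_system_spec(box, sites,
                  cavity_centers = matrix(c(12.75, 7, 7), 1, 3),
                  temperature = 310, seed = seed,
                  metadata = list(axis = "x", axis_yz = c(7, 7),
                                  mouth_x = 3, gate_x = 8.25,
                                  gate_radius = r_gate, gate_gap = gap,
                                  cavity_center = c(12.75, 7, 7),
                                  open_fraction = open_fraction))
}

#' Explicit-ligand trajectory container
#'
#' @param positions array \code{[n_frames, n_ligands, 3]} or an
#'   \code{n_frames x 3} matrix for a single ligand, of ligand
#'   center-of-geometry positions (A); \code{NA} rows mark absences.
#' @param box_lengths numeric(3) (A).
#' @param acceptance_rate,diagnostics optional sampler bookkeeping.
#' @return object of class \code{ligand_trajectory}.
#' @export
ligand_trajectory <- function(positions, box_lengths,
                              acceptance_rate = NA_real_,
                              diagnostics = list()) {
  if (length(dim(positions)) == 2)
    positions <- array(positions, c(nrow(positions), 1, 3))
  .assert(length(dim(positions)) == 3 && dim(positions)[3] == 3,
          "positions must be [n_frames, n_ligands, 3]")
  box_lengths <- rep_len(as.numeric(box_lengths), 3)
  structure(list(positions = positions, n_frames = dim(positions)[1],
                 n_ligands = dim(positions)[2], box_lengths = box_lengths,
                 acceptance_rate = acceptance_rate,
                 diagnostics = diagnostics),
            class = "ligand_trajectory")
}

#' @export
print.ligand_trajectory <- function(x, ...) {
  cat("ligand_trajectory:", x$n_frames, "frames,", x$n_ligands,
      "ligand(s), acceptance", signif(x$acceptance_rate, 3), "\n")
  invisible(x)
}

#' Metropolis sampling of an explicit diatomic ligand
#'
#' Random walk (rigid-body translation + rotation moves) of the diatomic
#' probe in the field of a randomly re-drawn ensemble frame, so that
#' recorded positions are asymptotically Boltzmann-distributed in the
#' frame-averaged sense. Deterministic given the seed.
#'
#' @param ensemble a \code{conformation_ensemble}.
#' @param probe a \code{\link{probe_spec}}.
#' @param n_steps Monte Carlo steps (>= 1).
#' @param temperature K.
#' @param seed integer seed.
#' @param trans_step max translation per move (A).
#' @param rot_step rotation angle scale per move (radians).
#' @param frame_stride steps between re-draws of the active frame.
#' @param record_stride steps between recorded positions.
#' @param lj_cutoff,periodic,combining_rule energy model controls, as in
#'   \code{\link{ils_settings}}.
#' @return a \code{\link{ligand_trajectory}} of probe centers. Fails with
#'   a diagnostic if a full window of moves (1000 steps) is rejected.
#' @export
sample_explicit_ligand <- function(ensemble, probe, n_steps, temperature = 310,
                                   seed = 1, trans_step = 0.4,
                                   rot_step = 0.4, frame_stride = 100,
                                   record_stride = 1, lj_cutoff = 14,
                                   periodic = FALSE,
                                   combining_rule = "lorentz_berthelot") {
  .assert(inherits(ensemble, "conformation_ensemble") &&
            ensemble$n_frames >= 1, "ensemble is empty")
  .assert(n_steps >= 1, "n_steps must be >= 1")
  cl <- combined_lj(probe, ensemble$epsilon, ensemble$sigma, combining_rule)
  beta <- 1 / (.kB * temperature)
  nf <- ensemble$n_frames
  ns <- ensemble$n_sites
  # frame-major stacking: row (f-1)*ns + s holds site s of frame f
  stacked <- do.call(rbind, lapply(seq_len(nf), function(f)
    matrix(ensemble$coords[, , f], ns, 3)))
  set.seed(seed)
  window <- 1000L
  res <- .metropolis_diatomic(stacked, ns, nf, cl$epsc, cl$sigc,
                              probe$bond_length / 2, lj_cutoff,
                              ensemble$box_lengths, periodic,
                              as.integer(n_steps), beta, trans_step,
                              rot_step, as.integer(frame_stride),
                              as.integer(record_stride), window)
  full <- n_steps %/% window
  if (full >= 1 && any(res$window_accepts[seq_len(full)] == 0))
    stop("explicit-ligand sampler: zero accepted moves over a full ",
         window, "-step window; step sizes or system are pathological",
         call. = FALSE)
  ligand_trajectory(matrix(res$positions, ncol = 3), ensemble$box_lengths,
                    acceptance_rate = res$acceptance_rate,
                    diagnostics = list(window_accepts = res$window_accepts,
                                       seed = seed, n_steps = n_steps))
}
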