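#' Diatomic apolar probe model
#'
#' Two LJ interaction sites at a fixed bond length, zero partial charges —
#' the standard representation of molecular oxygen as a small apolar
#' probe. Defaults are typical O2 parameters (per-site sigma 3.0 A,
#' epsilon 0.43 kJ/mol, bond 1.21 A); supply your own to match a given
#' force field.
#'
#' @param epsilon numeric(2) (or scalar), per-site well depth (kJ/mol).
#' @param sigma numeric(2) (or scalar), per-site LJ diameter (A).
#' @param bond_length site-site distance (A).
#' @return object of class \code{probe_spec}.
#' @export
probe_spec <- function(epsilon = 0.43, sigma = 3.0, bond_length = 1.21) {
  epsilon <- rep_len(as.numeric(epsilon), 2)
  sigma <- rep_len(as.numeric(sigma), 2)
  .assert(all(epsilon >= 0), "probe epsilon must be >= 0")
  .assert(all(sigma > 0), "probe sigma must be > 0")
  .assert(bond_length > 0, "bond_length must be > 0")
  structure(list(epsilon = epsilon, sigma = sigma,
                 bond_length = as.numeric(bond_length), charges = c(0, 0)),
            class = "probe_spec")
}

#' Insertion-map sampling settings
#'
#' @param n_insertions_per_voxel random probe placements per voxel per frame.
#' @param insertion_region \code{"cube"} (placements anywhere in the voxel
#'   cube, the default) or \code{"inscribed_sphere"} (within the sphere
#'   inscribed in the cube, for comparison with the older variant).
#' @param lj_cutoff LJ truncation distance (A); plain truncation.
#' @param temperature absolute temperature (K).
#' @param periodic use minimum-image distances. Off by default: after
#'   superposition onto a reference the lattice is broken; turn on for
#'   bulk-reference estimation.
#' @param seed integer seed; all randomness derives from it (one stream per
#'   voxel/frame, so results do not depend on evaluation order).
#' @param value_cap energy assigned to voxels whose average Boltzmann
#'   factor underflows (kJ/mol).
#' @param combining_rule \code{"lorentz_berthelot"} (arithmetic sigma,
#'   geometric epsilon) or \code{"geometric"} (both geometric).
#' @return object of class \code{ils_settings}.
#' @export
ils_settings <- function(n_insertions_per_voxel = 400,
                         insertion_region = c("cube", "inscribed_sphere"),
                         lj_cutoff = 14, temperature = 310,
                         periodic = FALSE, seed = 1, value_cap = 100,
                         combining_rule = c("lorentz_berthelot",
                                            "geometric")) {
  insertion_region <- match.arg(insertion_region)
  combining_rule <- match.arg(combining_rule)
  .assert(n_insertions_per_voxel >= 1, "n_insertions_per_voxel must be >= 1")
  .assert(lj_cutoff > 0, "lj_cutoff must be > 0")
  .assert(temperature > 0, "temperature must be > 0")
  structure(list(n_insertions_per_voxel = as.integer(n_insertions_per_voxel),
                 insertion_region = insertion_region,
                 lj_cutoff = lj_cutoff, temperature = temperature,
                 periodic = periodic, seed = as.integer(seed),
                 value_cap = value_cap, combining_rule = combining_rule),
            class = "ils_settings")
}

# combined (probe site x matrix site) LJ tables, m x 2 each
combined_lj <- function(probe, epsilon, sigma, rule = "lorentz_berthelot") {
  m <- length(epsilon)
  epsc <- sqrt(outer(epsilon, probe$epsilon))
  sigc <- if (rule == "lorentz_berthelot") {
    outer(sigma, probe$sigma, function(a, b) (a + b) / 2)
  } else {
    sqrt(outer(sigma, probe$sigma))
  }
  list(epsc = matrix(epsc, m, 2), sigc = matrix(sigc, m, 2))
}

#' Interaction energy of one probe placement
#'
#' LJ 12-6 energy of the rigid diatomic probe (sites at
#' \code{position +/- bond_length/2 * orientation}) against every matrix
#' site within the cutoff, using the configured combining rule. Overlaps
#' give large positive but finite energies.
#'
#' @param coords n_sites x 3 matrix of site positions (A).
#' @param epsilon,sigma per-site LJ parameters.
#' @param probe a \code{\link{probe_spec}}.
#' @param position numeric(3), probe center (A).
#' @param orientation numeric(3) unit vector along the bond.
#' @param box_lengths box edges (A), used when \code{periodic}.
#' @param settings an \code{\link{ils_settings}} (cutoff, periodicity, rule).
#' @return energy in kJ/mol.
#' @export
insertion_energy <- function(coords, epsilon, sigma, probe, position,
                             orientation, box_lengths = c(Inf, Inf, Inf),
                             settings = ils_settings()) {
  .assert(abs(sum(orientation^2) - 1) < 1e-8,
          "orientation must be a unit vector")
  cl <- combined_lj(probe, epsilon, sigma, settings$combining_rule)
  if (settings$periodic) .assert(all(is.finite(box_lengths)),
                                 "periodic energies need finite box_lengths")
  box <- ifelse(is.finite(box_lengths), box_lengths, 1e9)
  .lj_batch_energies(matrix(position, 1, 3), matrix(orientation, 1, 3),
                     probe$bond_length / 2, as.matrix(coords),
                     cl$epsc, cl$sigc, settings$lj_cutoff, box,
                     settings$periodic)[1]
}

# insertion positions for one voxel: n x 3 offsets from the voxel center
.insertion_offsets <- function(n, spacing, region) {
  if (region == "cube") {
    matrix((stats::runif(3 * n) - 0.5), ncol = 3) %*% diag(spacing)
  } else {
    r <- min(spacing) / 2
    out <- matrix(NA_real_, 0, 3)
    while (nrow(out) < n) {
      cand <- matrix((stats::runif(3 * n) - 0.5) * 2 * r, ncol = 3)
      cand <- cand[rowSums(cand^2) <= r^2, , drop = FALSE]
      out <- rbind(out, cand)
    }
    out[seq_len(n), , drop = FALSE]
  }
}

# per-voxel, per-frame log mean Boltzmann factors (nvox x length(frame_ids)).
# frame_ids seed the per-frame insertion streams, so a map over a frame
# subset reuses the draws of the full-ensemble run for those frames.
.ils_frame_logmeans <- function(ensemble, probe, grid, settings,
                                frame_ids = seq_len(ensemble$n_frames),
                                voxel_subset = NULL) {
  cl <- combined_lj(probe, ensemble$epsilon, ensemble$sigma,
                    settings$combining_rule)
  beta <- 1 / (.kB * settings$temperature)
  centers <- voxel_centers(grid)
  vox <- if (is.null(voxel_subset)) seq_len(n_voxels(grid)) else voxel_subset
  nf <- ensemble$n_frames
  .assert(length(frame_ids) == nf, "frame_ids must match the frame count")
  n <- settings$n_insertions_per_voxel
  box <- ensemble$box_lengths
  lm <- matrix(NA_real_, length(vox), nf)
  half <- probe$bond_length / 2
  for (iv in seq_along(vox)) {
    v <- vox[iv]
    for (f in seq_len(nf)) {
      set.seed(.stream_seed(settings$seed, v, frame_ids[f]))
      pos <- sweep(.insertion_offsets(n, grid$spacing,
                                      settings$insertion_region),
                   2, centers[v, ], "+")
      ori <- .runif_sphere(n)
      e <- .lj_batch_energies(pos, ori, half,
                              matrix(ensemble$coords[, , f],
                                     ensemble$n_sites, 3),
                              cl$epsc, cl$sigc, settings$lj_cutoff,
                              box, settings$periodic)
      lm[iv, f] <- logmeanexp(-beta * e)
    }
  }
  lm
}

# weighted log-mean over frames, exact zero for all-zero input
.log_weighted_mean <- function(x, w) {
  m <- max(x)
  if (m == -Inf) return(-Inf)
  m + log(sum(w * exp(x - m))) - log(sum(w))
}

#' Compute an implicit-ligand-sampling free-energy map
#'
#' Widom-style test-particle insertion of the diatomic probe over every
#' voxel of a grid: for each voxel the Gibbs free energy of moving the
#' probe from vacuum to that position is
#' \deqn{\Delta G(r) = -k_B T \ln \langle e^{-E_{int}/k_B T} \rangle}
#' with the average running over ensemble frames (weighted by their
#' frame weights) and, per frame, over random placements within the voxel
#' and uniformly random orientations. Averages are accumulated through a
#' shifted log-sum scheme; voxels whose average Boltzmann factor
#' underflows (or whose energy exceeds the cap) are set to
#' \code{value_cap} and flagged.
#'
#' @param ensemble a \code{conformation_ensemble}, already superposed onto
#'   a common reference if it derives from a trajectory.
#' @param probe a \code{\link{probe_spec}}.
#' @param grid a \code{\link{scalar_grid3d}} defining the map domain.
#' @param settings an \code{\link{ils_settings}}.
#' @param frame_ids integer labels used to seed per-frame insertion
#'   streams; defaults to \code{1:n_frames}. Supplying the original frame
#'   labels of a subset reproduces the draws of the full-ensemble run.
#' @return object of class \code{fe_map}: the value grid (kJ/mol),
#'   reference label, settings, capped-voxel mask and provenance.
#' @export
compute_ils_map <- function(ensemble, probe, grid, settings = ils_settings(),
                            frame_ids = seq_len(ensemble$n_frames)) {
  .assert(inherits(ensemble, "conformation_ensemble"),
          "ensemble must be a conformation_ensemble")
  .assert(ensemble$n_frames >= 1, "ensemble is empty")
  if (!settings$periodic) {
    cen <- voxel_centers(grid)
    .assert(all(cen >= -1e-9) &&
              all(sweep(cen, 2, ensemble$box_lengths, "<=")),
            "grid extends outside the box (periodic = FALSE)")
  }
  lm <- .ils_frame_logmeans(ensemble, probe, grid, settings, frame_ids)
  kT <- .kB * settings$temperature
  logtot <- apply(lm, 1, .log_weighted_mean, w = ensemble$frame_weights)
  dG <- -kT * logtot
  capped <- !is.finite(dG) | dG > grid$value_cap
  dG[capped] <- grid$value_cap
  g <- scalar_grid3d(grid$origin, grid$spacing, grid$dims, dG,
                     value_cap = grid$value_cap)
  structure(list(grid = g, reference = "vacuum", settings = settings,
                 probe = probe,
                 capped = array(capped, dim = grid$dims),
                 provenance = list(n_frames = ensemble$n_frames,
                                   n_sites = ensemble$n_sites,
                                   coord_checksum = sum(ensemble$coords))),
            class = "fe_map")
}

#' @export
print.fe_map <- function(x, ...) {
  cat("fe_map (", x$reference, " reference): ",
      paste(x$grid$dims, collapse = " x "), " voxels, ",
      sum(x$capped), " capped\n", sep = "")
  cat("  value range:",
      paste(signif(range(x$grid$values), 5), collapse = " .. "), "kJ/mol\n")
  invisible(x)
}

#' Convert a vacuum-reference map to the water reference
#'
#' Subtracts the probe's vacuum-to-water solvation free energy so map
#' values express the free energy of moving the probe from bulk water to
#' each position. Capped voxels keep the cap.
#'
#' @param map an \code{fe_map} with \code{reference == "vacuum"}.
#' @param dG_vac_to_wat solvation free energy offset (kJ/mol), e.g. from
#'   \code{\link{estimate_bulk_offset}} on a bulk reference ensemble.
#' @return the converted \code{fe_map} (\code{reference == "water"}).
#' @export
convert_reference <- function(map, dG_vac_to_wat) {
  .assert(inherits(map, "fe_map"), "map must be an fe_map")
  .assert(identical(map$reference, "vacuum"),
          "map is already in the water reference")
  v <- map$grid$values - dG_vac_to_wat
  v[map$capped] <- map$grid$value_cap
  map$grid$values <- v
  map$reference <- "water"
  map$offset <- dG_vac_to_wat
  map
}

#' Estimate the bulk-reference insertion free energy
#'
#' Averages the probe's Boltzmann insertion factor over positions,
#' orientations and frames of a homogeneous bulk reference ensemble —
#' the offset used by \code{\link{convert_reference}}. Reports a
#' bootstrap standard error over frames.
#'
#' @param reference_ensemble homogeneous \code{conformation_ensemble}
#'   (no engineered cavities); typically used with
#'   \code{settings$periodic = TRUE}.
#' @param probe a \code{\link{probe_spec}}.
#' @param settings an \code{\link{ils_settings}}.
#' @param grid optional sampling grid; default: an 6x6x6 grid spanning
#'   the central region of the box.
#' @param n_boot bootstrap replicates over frames.
#' @return list with \code{dG} (kJ/mol), \code{se}, \code{n_frames}.
#' @export
estimate_bulk_offset <- function(reference_ensemble, probe,
                                 settings = ils_settings(periodic = TRUE),
                                 grid = NULL, n_boot = 200) {
  ens <- reference_ensemble
  .assert(inherits(ens, "conformation_ensemble") && ens$n_frames >= 1,
          "reference ensemble is empty")
  if (is.null(grid)) {
    sp <- ens$box_lengths / 8
    grid <- scalar_grid3d(origin = ens$box_lengths / 4, spacing = sp,
                          dims = c(6, 6, 6))
  }
  lm <- .ils_frame_logmeans(ens, probe, grid, settings)
  kT <- .kB * settings$temperature
  # per-frame factor averaged over all voxels
  lf <- apply(lm, 2, logmeanexp)
  dG <- -kT * .log_weighted_mean(lf, ens$frame_weights)
  se <- NA_real_
  if (ens$n_frames > 1 && n_boot > 0) {
    set.seed(.stream_seed(settings$seed, 1L, 999983L))
    boots <- replicate(n_boot, {
      idx <- sample.int(ens$n_frames, replace = TRUE)
      -kT * .log_weighted_mean(lf[idx], ens$frame_weights[idx])
    })
    se <- stats::sd(boots)
  }
  list(dG = dG, se = se, n_frames = ens$n_frames)
}
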