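#' Probability-density grid from an explicit-ligand trajectory
#'
#' Histograms ligand centers onto the grid: each position is assigned to
#' its nearest voxel center, and the voxel value is the accumulated count
#' divided by (number of frames x voxel volume), i.e. a number density in
#' 1/A^3. Summing \code{values * voxel_volume} over the grid gives the
#' mean number of ligands inside the grid per frame, exactly.
#'
#' @param traj a \code{\link{ligand_trajectory}}.
#' @param grid a \code{\link{scalar_grid3d}} defining the histogram domain.
#' @param alignment optional list of per-frame rigid transforms (elements
#'   with \code{rotation} and \code{translation}, as produced by
#'   \code{\link{superpose_frames}}) applied to ligand positions before
#'   binning; length must equal \code{n_frames}.
#' @return a \code{scalar_grid3d} of densities with attributes
#'   \code{n_outside} (position records falling outside the grid) and
#'   \code{n_absent} (NA records).
#' @export
compute_density_map <- function(traj, grid, alignment = NULL) {
  .assert(inherits(traj, "ligand_trajectory"), "traj must be a ligand_trajectory")
  .assert(traj$n_frames >= 1, "trajectory has zero frames")
  if (!is.null(alignment))
    .assert(length(alignment) == traj$n_frames,
            "alignment series length must equal n_frames")
  # frame-major rows: row (f-1)*n_ligands + l holds ligand l of frame f
  pos <- matrix(NA_real_, traj$n_frames * traj$n_ligands, 3)
  for (f in seq_len(traj$n_frames))
    pos[seq.int((f - 1) * traj$n_ligands + 1, f * traj$n_ligands), ] <-
      matrix(traj$positions[f, , ], traj$n_ligands, 3)
  if (!is.null(alignment)) {
    for (f in seq_len(traj$n_frames)) {
      idx <- seq.int((f - 1) * traj$n_ligands + 1, f * traj$n_ligands)
      tr <- alignment[[f]]
      pos[idx, ] <- sweep(pos[idx, , drop = FALSE] %*% tr$rotation, 2,
                          tr$translation, "+")
    }
  }
  absent <- !stats::complete.cases(pos)
  vox <- position_to_voxel(grid, pos[!absent, , drop = FALSE])
  outside <- sum(is.na(vox))
  counts <- tabulate(vox[!is.na(vox)], nbins = n_voxels(grid))
  vol <- prod(grid$spacing)
  vals <- counts / (traj$n_frames * vol)
  out <- scalar_grid3d(grid$origin, grid$spacing, grid$dims, vals,
                       value_cap = grid$value_cap)
  attr(out, "n_outside") <- outside
  attr(out, "n_absent") <- sum(absent)
  out
}

# 26-connected component labelling of a logical mask (union-find)
.label_components <- function(mask, dims, connectivity = 26) {
  n <- prod(dims)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  offs <- .neighbor_offsets(connectivity)
  idx_arr <- array(seq_len(n), dim = dims)
  for (o in seq_len(nrow(offs))) {
    d <- offs[o, ]
    sel_a <- .shift_ranges(dims, d)
    if (is.null(sel_a)) next
    a <- idx_arr[sel_a$src_x, sel_a$src_y, sel_a$src_z]
    b <- idx_arr[sel_a$dst_x, sel_a$dst_y, sel_a$dst_z]
    keep <- mask[a] & mask[b]
    a <- a[keep]; b <- b[keep]
    for (t in seq_along(a)) {
      ra <- find(a[t]); rb <- find(b[t])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  lab <- rep(NA_integer_, n)
  on <- which(mask)
  roots <- vapply(on, find, integer(1))
  lab[on] <- match(roots, sort(unique(roots)))
  lab
}

#' Iso-level report for a density grid
#'
#' Counts voxels at or above a density level and their 26-connected
#' components — the numerical counterpart of drawing an iso-density
#' contour surface (the conventional display level for dioxygen maps is
#' 0.00015 1/A^3).
#'
#' @param grid a \code{scalar_grid3d} of densities (1/A^3).
#' @param level iso level (> 0).
#' @return list with \code{n_voxels}, \code{n_components}, and
#'   \code{mask} (a \code{scalar_grid3d} of 0/1 membership).
#' @export
isosurface_report <- function(grid, level = 0.00015) {
  .assert(level > 0, "level must be > 0")
  mask <- as.vector(grid$values >= level)
  lab <- .label_components(mask, grid$dims, 26)
  list(n_voxels = sum(mask),
       n_components = if (any(mask)) max(lab, na.rm = TRUE) else 0L,
       mask = scalar_grid3d(grid$origin, grid$spacing, grid$dims,
                            as.numeric(mask)))
}

#' Region specification for occupancy counting
#'
#' @param kind \code{"slab"} (bounds on one axis), \code{"sphere"}, or
#'   \code{"grid_mask"} (a \code{scalar_grid3d} of 0/1).
#' @param ... geometry: slab takes \code{axis} (1-3), \code{min}, \code{max};
#'   sphere takes \code{center} (3-vector), \code{radius}; grid_mask takes
#'   \code{mask} (the grid).
#' @return object of class \code{region_spec}.
#' @export
region_spec <- function(kind = c("slab", "sphere", "grid_mask"), ...) {
  kind <- match.arg(kind)
  p <- list(...)
  if (kind == "slab") {
    .assert(all(c("axis", "min", "max") %in% names(p)),
            "slab region needs axis, min, max")
    .assert(p$min <= p$max, "slab bounds must be ordered (min <= max)")
  } else if (kind == "sphere") {
    .assert(all(c("center", "radius") %in% names(p)) &&
              length(p$center) == 3 && p$radius > 0,
            "sphere region needs center (3-vector) and radius > 0")
  } else {
    .assert(inherits(p$mask, "scalar_grid3d"),
            "grid_mask region needs mask = scalar_grid3d")
  }
  structure(list(kind = kind, parameters = p), class = "region_spec")
}

.in_region <- function(region, pos) {
  p <- region$parameters
  switch(region$kind,
         slab = pos[, p$axis] >= p$min & pos[, p$axis] <= p$max,
         sphere = rowSums(sweep(pos, 2, p$center)^2) <= p$radius^2,
         grid_mask = {
           vox <- position_to_voxel(p$mask, pos)
           ok <- !is.na(vox)
           ok[ok] <- p$mask$values[vox[ok]] > 0
           ok
         })
}

#' Per-frame ligand counts in a region
#'
#' @param traj a \code{\link{ligand_trajectory}}.
#' @param region a \code{\link{region_spec}}.
#' @param window optional integer(2) frame range for the reported mean;
#'   default all frames.
#' @return list with \code{counts} (integer per frame), \code{mean}
#'   (over the window) and \code{window}.
#' @export
region_occupancy <- function(traj, region, window = NULL) {
  .assert(inherits(region, "region_spec"), "region must be a region_spec")
  counts <- integer(traj$n_frames)
  for (f in seq_len(traj$n_frames)) {
    pos <- matrix(traj$positions[f, , ], traj$n_ligands, 3)
    pos <- pos[stats::complete.cases(pos), , drop = FALSE]
    counts[f] <- if (nrow(pos)) sum(.in_region(region, pos)) else 0L
  }
  if (is.null(window)) window <- c(1L, traj$n_frames)
  list(counts = counts,
       mean = mean(counts[window[1]:window[2]]),
       window = window)
}
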