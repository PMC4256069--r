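#' Axis-aligned 3D scalar grid
#'
#' Container for volumetric data on a regular orthorhombic grid: free
#' energies (kJ/mol) or probability densities (1/A^3). Voxel centers are
#' located at \code{origin + (index - 1) * spacing}; the linearized voxel
#' index runs with x fastest (R array order).
#'
#' @param origin numeric(3), position of the first voxel center (A).
#' @param spacing numeric(3) (or scalar, recycled), voxel spacing per axis (A).
#' @param dims integer(3), number of voxels per axis.
#' @param values optional numeric array of dimension \code{dims}; defaults
#'   to zeros.
#' @param value_cap sentinel for "effectively infinite" energy (kJ/mol);
#'   voxels at the cap are treated as excluded by the landscape analysis.
#' @return An object of class \code{scalar_grid3d}.
#' @export
scalar_grid3d <- function(origin, spacing, dims, values = NULL,
                          value_cap = 100) {
  spacing <- rep_len(as.numeric(spacing), 3)
  origin <- as.numeric(origin)
  dims <- as.integer(dims)
  .assert(length(origin) == 3 && all(is.finite(origin)),
          "origin must be a finite 3-vector")
  .assert(length(dims) == 3 && all(dims >= 1L), "dims must be >= 1 per axis")
  .assert(all(spacing > 0), "spacing must be > 0")
  if (is.null(values)) values <- array(0, dim = dims)
  values <- array(as.numeric(values), dim = dims)
  .assert(all(is.finite(values)),
          "grid values must be finite (use value_cap for capped voxels)")
  structure(list(origin = origin, spacing = spacing, dims = dims,
                 values = values, value_cap = value_cap),
            class = "scalar_grid3d")
}

#' @export
print.scalar_grid3d <- function(x, ...) {
  cat("scalar_grid3d:", paste(x$dims, collapse = " x "), "voxels, spacing",
      paste(signif(x$spacing, 4), collapse = "/"), "A\n")
  cat("  origin:", paste(signif(x$origin, 6), collapse = ", "), "A\n")
  cat("  value range:", paste(signif(range(x$values), 6), collapse = " .. "),
      " (cap ", x$value_cap, ")\n", sep = "")
  invisible(x)
}

#' Number of voxels in a grid
#'
#' @param grid a \code{scalar_grid3d}.
#' @return integer voxel count.
#' @export
n_voxels <- function(grid) prod(grid$dims)

#' Voxel centers of a grid
#'
#' @param grid a \code{scalar_grid3d}.
#' @return matrix (n_voxels x 3) of voxel-center positions (A) in
#'   linearized order (x fastest).
#' @export
voxel_centers <- function(grid) {
  ax <- lapply(1:3, function(k)
    grid$origin[k] + (seq_len(grid$dims[k]) - 1) * grid$spacing[k])
  as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]],
                        KEEP.OUT.ATTRS = FALSE))
}

# linearized voxel index -> integer (i,j,k) triple
voxel_ijk <- function(grid, idx) {
  nx <- grid$dims[1]; ny <- grid$dims[2]
  idx0 <- idx - 1L
  cbind(i = idx0 %% nx + 1L,
        j = (idx0 %/% nx) %% ny + 1L,
        k = idx0 %/% (nx * ny) + 1L)
}

#' Positions of linearized voxel indices
#'
#' @param grid a \code{scalar_grid3d}.
#' @param idx linearized voxel indices.
#' @return matrix (length(idx) x 3) of voxel-center positions (A).
#' @export
voxel_position <- function(grid, idx) {
  ijk <- voxel_ijk(grid, idx)
  sweep(sweep(ijk - 1, 2, grid$spacing, "*"), 2, grid$origin, "+")
}

#' Nearest voxel index for positions
#'
#' @param grid a \code{scalar_grid3d}.
#' @param pos n x 3 matrix (or 3-vector) of positions (A).
#' @return integer linearized voxel indices (NA for positions outside
#'   the grid).
#' @export
position_to_voxel <- function(grid, pos) {
  pos <- matrix(pos, ncol = 3)
  ijk <- round(sweep(sweep(pos, 2, grid$origin, "-"), 2, grid$spacing, "/")) + 1
  ok <- ijk[, 1] >= 1 & ijk[, 1] <= grid$dims[1] &
    ijk[, 2] >= 1 & ijk[, 2] <= grid$dims[2] &
    ijk[, 3] >= 1 & ijk[, 3] <= grid$dims[3]
  out <- rep(NA_integer_, nrow(pos))
  out[ok] <- as.integer((ijk[ok, 3] - 1) * grid$dims[1] * grid$dims[2] +
                          (ijk[ok, 2] - 1) * grid$dims[1] + ijk[ok, 1])
  out
}

#' Write a grid in OpenDX format
#'
#' Plain-text OpenDX scalar field, readable by the usual molecular viewers.
#' The value cap is recorded in a header comment so the round trip is
#' lossless in metadata.
#'
#' @param grid a \code{scalar_grid3d}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_grid <- function(grid, path) {
  .assert(inherits(grid, "scalar_grid3d"), "grid must be a scalar_grid3d")
  d <- grid$dims
  n <- prod(d)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# gasmap OpenDX scalar grid"),
    sprintf("# value_cap %.17g", grid$value_cap),
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %.9g %.9g %.9g", grid$origin[1], grid$origin[2],
            grid$origin[3]),
    sprintf("delta %.9g 0 0", grid$spacing[1]),
    sprintf("delta 0 %.9g 0", grid$spacing[2]),
    sprintf("delta 0 0 %.9g", grid$spacing[3]),
    sprintf("object 2 class gridconnections counts %d %d %d", d[1], d[2],
            d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            n)), con)
  # DX convention: z varies fastest
  v <- as.vector(aperm(grid$values, c(3, 2, 1)))
  pad <- (-n) %% 3
  if (pad > 0) v <- c(v, rep(NA_real_, pad))
  m <- matrix(sprintf("%.9g", v), ncol = 3, byrow = TRUE)
  if (pad > 0) m[nrow(m), (3 - pad + 1):3] <- ""
  writeLines(trimws(apply(m, 1, paste, collapse = " ")), con)
  writeLines('attribute "dep" string "positions"', con)
  invisible(path)
}

#' Read an OpenDX grid
#'
#' @param path file written by \code{\link{write_grid}} or another tool
#'   emitting standard OpenDX scalar fields with axis-aligned deltas.
#' @return a \code{scalar_grid3d}.
#' @export
read_grid <- function(path) {
  .assert(file.exists(path), paste("no such file:", path))
  lines <- readLines(path)
  cap <- 100
  capline <- grep("^# value_cap ", lines, value = TRUE)
  if (length(capline)) cap <- as.numeric(sub("^# value_cap ", "", capline[1]))
  gp <- grep("class gridpositions", lines)
  .assert(length(gp) == 1, "malformed DX file: no gridpositions object")
  dims <- as.integer(strsplit(sub(".*counts +", "", lines[gp]), " +")[[1]])
  origin_line <- grep("^origin", lines, value = TRUE)[1]
  origin <- as.numeric(strsplit(trimws(sub("^origin", "", origin_line)),
                                " +")[[1]])
  deltas <- grep("^delta", lines, value = TRUE)
  .assert(length(deltas) == 3, "malformed DX file: expected 3 delta lines")
  dmat <- t(vapply(deltas, function(l)
    as.numeric(strsplit(trimws(sub("^delta", "", l)), " +")[[1]]),
    numeric(3)))
  .assert(all(abs(dmat[upper.tri(dmat) | lower.tri(dmat)]) < 1e-12),
          "only axis-aligned DX grids are supported")
  spacing <- diag(dmat)
  da <- grep("data follows", lines)
  .assert(length(da) >= 1, "malformed DX file: no data section")
  n <- prod(dims)
  body <- lines[(da[1] + 1):length(lines)]
  body <- body[!grepl("^(attribute|object|#)", body) & nzchar(trimws(body))]
  vals <- as.numeric(unlist(strsplit(trimws(body), "[ \t]+")))
  .assert(sum(!is.na(vals)) >= n, "malformed DX file: too few data values")
  vals <- vals[seq_len(n)]
  arr <- aperm(array(vals, dim = rev(dims)), c(3, 2, 1))
  scalar_grid3d(origin, spacing, dims, arr, value_cap = cap)
}
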