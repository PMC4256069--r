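#' @export
summary.fe_map <- function(object, ...) {
  v <- object$grid$values[!object$capped]
  cat("Insertion free-energy map (", object$reference, " reference)\n",
      sep = "")
  cat("  grid: ", paste(object$grid$dims, collapse = " x "), " voxels, ",
      "spacing ", paste(signif(object$grid$spacing, 4), collapse = "/"),
      " A\n", sep = "")
  cat("  frames averaged:", object$provenance$n_frames, "\n")
  cat("  capped voxels:", sum(object$capped), "of",
      length(object$capped), "\n")
  if (length(v)) {
    q <- stats::quantile(v, c(0, 0.05, 0.5, 0.95, 1))
    cat("  value quantiles (kJ/mol):\n")
    print(signif(q, 4))
  }
  invisible(object)
}

#' Plot a z-slice of a grid or free-energy map
#'
#' @param x a \code{scalar_grid3d} or \code{fe_map}.
#' @param k slice index along z (default: middle slice).
#' @param ... passed to \code{image}.
#' @export
plot.scalar_grid3d <- function(x, k = NULL, ...) {
  if (is.null(k)) k <- ceiling(x$dims[3] / 2)
  xs <- x$origin[1] + (seq_len(x$dims[1]) - 1) * x$spacing[1]
  ys <- x$origin[2] + (seq_len(x$dims[2]) - 1) * x$spacing[2]
  graphics::image(xs, ys, x$values[, , k], xlab = "x (A)", ylab = "y (A)",
                  main = sprintf("z-slice %d", k),
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(x)
}

#' @export
plot.fe_map <- function(x, k = NULL, ...) {
  v <- x$grid
  v$values[x$capped] <- NA
  plot.scalar_grid3d(v, k = k, ...)
}

#' Plot a pathway network projected on two axes
#'
#' Node size scales with depth (lower free energy = larger), edges are
#' drawn between connected minima with the saddle energy as label.
#'
#' @param x a \code{pathway_network}.
#' @param axes integer(2), projection axes (default x, y).
#' @param ... passed to \code{plot}.
#' @export
plot.pathway_network <- function(x, axes = c(1, 2), ...) {
  nm <- c("x", "y", "z")[axes]
  p <- as.matrix(x$nodes[, nm])
  graphics::plot(p, pch = 21,
                 bg = ifelse(x$nodes$exterior, "tomato", "steelblue"),
                 cex = 1 + 2 * (max(x$nodes$energy) - x$nodes$energy + 0.1) /
                   (diff(range(x$nodes$energy)) + 0.1),
                 xlab = paste0(nm[1], " (A)"), ylab = paste0(nm[2], " (A)"),
                 ...)
  for (i in seq_len(nrow(x$edges))) {
    a <- x$edges$basin_a[i]; b <- x$edges$basin_b[i]
    graphics::segments(p[a, 1], p[a, 2], p[b, 1], p[b, 2], col = "grey50")
  }
  invisible(x)
}

#' @export
plot.channel_profile <- function(x, ...) {
  e <- x$sequence$energy
  graphics::plot(seq_along(e), e, type = "b",
                 pch = ifelse(x$sequence$type == "minimum", 19, 1),
                 xlab = "position along route",
                 ylab = "free energy (kJ/mol)", ...)
  invisible(x)
}

#' @export
summary.pathway_network <- function(object, ...) {
  cat("Pathway network:", nrow(object$nodes), "minima,",
      nrow(object$edges), "edges (cutoff", object$cutoff, "kJ/mol)\n")
  if (nrow(object$nodes)) {
    cat("  deepest minimum:", signif(min(object$nodes$energy), 4),
        "kJ/mol; exterior minima:", sum(object$nodes$exterior), "\n")
  }
  if (nrow(object$edges)) {
    cat("  saddle energies (kJ/mol): ")
    cat(paste(signif(sort(object$edges$energy), 4), collapse = ", "), "\n")
  }
  invisible(object)
}
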