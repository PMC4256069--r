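# neighbor offsets for 6/18/26-connectivity (excluding the null offset)
.neighbor_offsets <- function(connectivity = 26) {
  .assert(connectivity %in% c(6, 18, 26), "connectivity must be 6, 18 or 26")
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  d2 <- rowSums(g^2)
  keep <- d2 > 0 & d2 <= switch(as.character(connectivity),
                                "6" = 1, "18" = 2, "26" = 3)
  g[keep, , drop = FALSE]
}

# index ranges for a vectorized shift by offset d: pairs (a, a + d)
.shift_ranges <- function(dims, d) {
  src <- dst <- vector("list", 3)
  for (k in 1:3) {
    lo <- max(1, 1 - d[k]); hi <- min(dims[k], dims[k] - d[k])
    if (lo > hi) return(NULL)
    src[[k]] <- lo:hi
    dst[[k]] <- (lo + d[k]):(hi + d[k])
  }
  list(src_x = src[[1]], src_y = src[[2]], src_z = src[[3]],
       dst_x = dst[[1]], dst_y = dst[[2]], dst_z = dst[[3]])
}

#' Steepest-descent (watershed) tessellation of an energy grid
#'
#' Classifies every voxel at or below the cutoff into the catchment basin
#' of a local minimum: each voxel repeatedly moves to its lowest-valued
#' neighbor until no neighbor improves on it. Ties (equal-valued lowest
#' neighbors, and plateaus) are broken toward the smallest linearized
#' voxel index, making the tessellation fully deterministic: on a flat
#' grid all voxels drain to the smallest index.
#'
#' @param grid a \code{scalar_grid3d} in energy units (kJ/mol).
#' @param connectivity 6, 18 or 26 (default; diagonal moves allowed).
#' @param cutoff voxels with value above this are excluded (kJ/mol).
#' @return object of class \code{basin_tessellation}: per-voxel labels
#'   (NA where excluded), a minima table (id, voxel, position, energy),
#'   and the descent pointer used for path tracing.
#' @export
tessellate <- function(grid, connectivity = 26, cutoff = 20) {
  .assert(inherits(grid, "scalar_grid3d"), "grid must be a scalar_grid3d")
  .assert(is.finite(cutoff), "cutoff must be finite")
  v <- as.vector(grid$values)
  n <- length(v)
  dims <- grid$dims
  excl <- v > cutoff
  if (all(excl)) {
    warning("all voxels excluded by the cutoff: empty tessellation")
    return(structure(list(labels = rep(NA_integer_, n),
                          minima = data.frame(id = integer(), voxel = integer(),
                                              x = numeric(), y = numeric(),
                                              z = numeric(), energy = numeric()),
                          descent = rep(NA_integer_, n), grid = grid,
                          connectivity = connectivity, cutoff = cutoff),
                     class = "basin_tessellation"))
  }
  idx_arr <- array(seq_len(n), dim = dims)
  bestval <- rep(Inf, n)
  bestidx <- rep(NA_integer_, n)
  offs <- .neighbor_offsets(connectivity)
  for (o in seq_len(nrow(offs))) {
    sr <- .shift_ranges(dims, offs[o, ])
    if (is.null(sr)) next
    a <- as.vector(idx_arr[sr$src_x, sr$src_y, sr$src_z])
    b <- as.vector(idx_arr[sr$dst_x, sr$dst_y, sr$dst_z])
    ok <- !excl[a] & !excl[b]
    a <- a[ok]; b <- b[ok]
    upd <- v[b] < bestval[a] | (v[b] == bestval[a] & b < bestidx[a])
    upd[is.na(upd)] <- FALSE
    bestval[a[upd]] <- v[b[upd]]
    bestidx[a[upd]] <- b[upd]
  }
  self <- seq_len(n)
  move <- !excl & !is.na(bestidx) &
    (bestval < v | (bestval == v & bestidx < self))
  nxt <- ifelse(move, bestidx, self)
  nxt[excl] <- NA_integer_
  # pointer jumping: each chain strictly decreases (value, index), so the
  # fixed point is reached in O(log n) doubling rounds
  repeat {
    nxt2 <- nxt
    act <- which(!is.na(nxt))
    nxt2[act] <- nxt[nxt[act]]
    if (identical(nxt2, nxt)) break
    nxt <- nxt2
  }
  min_vox <- which(!excl & self == ifelse(is.na(nxt), -1L, nxt))
  labels <- rep(NA_integer_, n)
  labels[!excl] <- match(nxt[!excl], min_vox)
  pos <- voxel_position(grid, min_vox)
  minima <- data.frame(id = seq_along(min_vox), voxel = min_vox,
                       x = pos[, 1], y = pos[, 2], z = pos[, 3],
                       energy = v[min_vox])
  # descent pointer (single step) for path tracing
  descent <- ifelse(move, bestidx, self)
  descent[excl] <- NA_integer_
  structure(list(labels = labels, minima = minima, descent = descent,
                 grid = grid, connectivity = connectivity, cutoff = cutoff),
            class = "basin_tessellation")
}

#' @export
print.basin_tessellation <- function(x, ...) {
  cat("basin_tessellation:", nrow(x$minima), "basins,",
      sum(!is.na(x$labels)), "of", length(x$labels),
      "voxels below cutoff", x$cutoff, "kJ/mol (connectivity",
      paste0(x$connectivity, ")\n"))
  invisible(x)
}

# single-step descent chain from a voxel to its basin minimum
.descent_chain <- function(tess, voxel) {
  path <- voxel
  repeat {
    nx <- tess$descent[voxel]
    if (is.na(nx) || nx == voxel) break
    path <- c(path, nx)
    voxel <- nx
  }
  path
}

#' Saddle points between adjacent basins
#'
#' The boundary between two basins is the set of neighboring voxel pairs
#' carrying different labels. The saddle energy is the minimum over the
#' boundary of the higher value of each pair, the saddle voxel is the
#' higher-valued voxel of the achieving pair (ties toward the smallest
#' linearized index), and steepest-descent paths are traced from the two
#' sides of the achieving pair down to the two minima. With this
#' convention the saddle energy equals the minimax (lowest achievable
#' maximum) energy over all voxel paths connecting the two minima within
#' the union of the two basins.
#'
#' @param grid the energy grid used for the tessellation.
#' @param tess a \code{\link{tessellate}} result on that grid.
#' @param connectivity neighbor rule; defaults to the tessellation's.
#' @return data frame with one row per adjacent basin pair: \code{basin_a},
#'   \code{basin_b}, \code{voxel}, \code{energy}, and a \code{path} list
#'   column of voxel-index polylines (minimum A ... saddle ... minimum B).
#' @export
find_saddles <- function(grid, tess, connectivity = tess$connectivity) {
  .assert(inherits(tess, "basin_tessellation"), "tess must be a tessellation")
  v <- as.vector(grid$values)
  dims <- grid$dims
  lab <- tess$labels
  idx_arr <- array(seq_along(v), dim = dims)
  offs <- .neighbor_offsets(connectivity)
  # each unordered pair once: keep lexicographically positive offsets
  pos_off <- offs[offs[, 1] > 0 | (offs[, 1] == 0 & offs[, 2] > 0) |
                    (offs[, 1] == 0 & offs[, 2] == 0 & offs[, 3] > 0), ,
                  drop = FALSE]
  A <- B <- integer(0)
  for (o in seq_len(nrow(pos_off))) {
    sr <- .shift_ranges(dims, pos_off[o, ])
    if (is.null(sr)) next
    a <- as.vector(idx_arr[sr$src_x, sr$src_y, sr$src_z])
    b <- as.vector(idx_arr[sr$dst_x, sr$dst_y, sr$dst_z])
    ok <- !is.na(lab[a]) & !is.na(lab[b]) & lab[a] != lab[b]
    A <- c(A, a[ok]); B <- c(B, b[ok])
  }
  empty <- data.frame(basin_a = integer(), basin_b = integer(),
                      voxel = integer(), energy = numeric())
  empty$path <- list()
  if (!length(A)) return(empty)
  la <- lab[A]; lb <- lab[B]
  pa <- pmin(la, lb); pb <- pmax(la, lb)
  hi <- ifelse(v[A] > v[B], A, ifelse(v[B] > v[A], B, pmin(A, B)))
  lo <- ifelse(hi == A, B, A)
  pm <- pmax(v[A], v[B])
  ord <- order(pa, pb, pm, hi, lo)
  key <- paste(pa, pb)[ord]
  first <- !duplicated(key)
  sel <- ord[first]
  res <- data.frame(basin_a = pa[sel], basin_b = pb[sel], voxel = hi[sel],
                    energy = pm[sel])
  res$path <- lapply(seq_along(sel), function(i) {
    s <- sel[i]
    side_a <- if (lab[A[s]] == res$basin_a[i]) A[s] else B[s]
    side_b <- if (side_a == A[s]) B[s] else A[s]
    c(rev(.descent_chain(tess, side_a)), .descent_chain(tess, side_b))
  })
  rownames(res) <- NULL
  res
}

#' Pathway network of minima and saddles
#'
#' Nodes are the free-energy minima; edges are the saddles whose energy
#' passes the construction cutoff, each carrying the forward and reverse
#' barriers (saddle minus source minimum). Minima whose basins contain a
#' voxel on a face of the grid are flagged as exterior.
#'
#' @param grid energy grid.
#' @param tess tessellation of \code{grid}.
#' @param saddles result of \code{\link{find_saddles}}.
#' @param cutoff maximum saddle energy admitted as an edge (kJ/mol). When
#'   the tessellation itself was restricted to voxels below a cutoff (the
#'   default "voxel" interpretation), every saddle already passes.
#' @return object of class \code{pathway_network} with \code{nodes} and
#'   \code{edges} data frames.
#' @export
build_network <- function(grid, tess, saddles, cutoff = 20) {
  lab <- tess$labels
  dims <- grid$dims
  idx_arr <- array(seq_along(lab), dim = dims)
  face <- unique(c(as.vector(idx_arr[c(1, dims[1]), , ]),
                   as.vector(idx_arr[, c(1, dims[2]), ]),
                   as.vector(idx_arr[, , c(1, dims[3])])))
  face_labels <- unique(lab[face])
  nodes <- tess$minima
  nodes$exterior <- nodes$id %in% face_labels
  keep <- saddles$energy <= cutoff
  ed <- saddles[keep, , drop = FALSE]
  if (nrow(ed)) {
    ed$barrier_ab <- ed$energy - nodes$energy[ed$basin_a]
    ed$barrier_ba <- ed$energy - nodes$energy[ed$basin_b]
  } else {
    ed$barrier_ab <- numeric(0)
    ed$barrier_ba <- numeric(0)
  }
  rownames(ed) <- NULL
  structure(list(nodes = nodes, edges = ed, cutoff = cutoff,
                 connectivity = tess$connectivity, grid = grid),
            class = "pathway_network")
}

#' @export
print.pathway_network <- function(x, ...) {
  cat("pathway_network:", nrow(x$nodes), "minima (",
      sum(x$nodes$exterior), "exterior ),", nrow(x$edges),
      "saddle edges at cutoff", x$cutoff, "kJ/mol\n")
  invisible(x)
}

#' Full landscape analysis of a free-energy map
#'
#' Convenience wrapper: tessellation, saddle search and network
#' construction in one call. Under \code{cutoff_mode = "voxel"} (default)
#' the cutoff bounds the voxel energies admitted to the tessellation;
#' under \code{"saddle"} all voxels up to the grid's value cap are
#' tessellated and the cutoff bounds the saddle energies admitted as
#' network edges.
#'
#' @param map an \code{fe_map} or \code{scalar_grid3d} of energies.
#' @param cutoff construction cutoff (kJ/mol).
#' @param connectivity 6, 18 or 26.
#' @param cutoff_mode "voxel" or "saddle".
#' @return a \code{pathway_network}; the tessellation is attached as
#'   attribute \code{"tessellation"}.
#' @export
analyze_landscape <- function(map, cutoff = 20, connectivity = 26,
                              cutoff_mode = c("voxel", "saddle")) {
  cutoff_mode <- match.arg(cutoff_mode)
  grid <- if (inherits(map, "fe_map")) map$grid else map
  tcut <- if (cutoff_mode == "voxel") cutoff else grid$value_cap
  tess <- tessellate(grid, connectivity, tcut)
  sad <- find_saddles(grid, tess)
  net <- build_network(grid, tess, sad,
                       cutoff = if (cutoff_mode == "voxel") tcut else cutoff)
  attr(net, "tessellation") <- tess
  net
}

# edge lookup helper: row index of the edge joining nodes i, j (or NA)
.edge_index <- function(network, i, j) {
  a <- pmin(i, j); b <- pmax(i, j)
  m <- match(paste(a, b), paste(network$edges$basin_a,
                                network$edges$basin_b))
  m
}

#' Bottleneck route between two minima
#'
#' Finds the route through the pathway network that minimizes the highest
#' saddle crossed (widest-path search by thresholding edges on saddle
#' energy).
#'
#' @param network a \code{pathway_network}.
#' @param from,to node ids.
#' @return list with \code{route} (node ids), \code{bottleneck} (kJ/mol),
#'   or NULL if the nodes are not connected.
#' @export
route_between <- function(network, from, to) {
  ed <- network$edges
  if (!nrow(ed)) return(NULL)
  levels <- sort(unique(ed$energy))
  nn <- nrow(network$nodes)
  connected_at <- function(t) {
    keep <- ed$energy <= t
    adj <- split(c(ed$basin_b[keep], ed$basin_a[keep]),
                 c(ed$basin_a[keep], ed$basin_b[keep]))
    seen <- rep(FALSE, nn); seen[from] <- TRUE
    queue <- from; prev <- rep(NA_integer_, nn)
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      for (nb in adj[[as.character(cur)]]) {
        if (!seen[nb]) {
          seen[nb] <- TRUE; prev[nb] <- cur; queue <- c(queue, nb)
        }
      }
    }
    if (seen[to]) prev else NULL
  }
  lo <- 1L; hi <- length(levels)
  if (is.null(connected_at(levels[hi]))) return(NULL)
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    if (is.null(connected_at(levels[mid]))) lo <- mid + 1L else hi <- mid
  }
  prev <- connected_at(levels[lo])
  route <- to
  while (route[1] != from) route <- c(prev[route[1]], route)
  list(route = route, bottleneck = levels[lo])
}

#' Free-energy profile along a route of minima
#'
#' Produces the alternating minimum/saddle energy sequence along an
#' ordered list of connected nodes, with the forward barrier at each step
#' defined as the saddle energy minus the preceding minimum's energy (the
#' barrier felt when moving along the route), and the reverse barrier as
#' saddle minus following minimum.
#'
#' @param network a \code{pathway_network}.
#' @param route ordered node ids; consecutive nodes must share an edge.
#' @return object of class \code{channel_profile}: a data frame of the
#'   alternating sequence (\code{type}, \code{id}, \code{energy}) plus
#'   \code{forward_barriers} and \code{reverse_barriers}.
#' @export
extract_profile <- function(network, route) {
  .assert(length(route) >= 2, "route must contain at least two nodes")
  eidx <- .edge_index(network, route[-length(route)], route[-1])
  if (anyNA(eidx))
    stop("route is broken: no edge between nodes ",
         route[which(is.na(eidx))[1]], " and ",
         route[which(is.na(eidx))[1] + 1], call. = FALSE)
  me <- network$nodes$energy[route]
  se <- network$edges$energy[eidx]
  seq_df <- data.frame(
    type = rep(c("minimum", "saddle"), length.out = 2 * length(route) - 1),
    id = as.integer(rbind(route, c(eidx, NA))[seq_len(2 * length(route) - 1)]),
    energy = as.numeric(rbind(me, c(se, NA))[seq_len(2 * length(route) - 1)]))
  structure(list(sequence = seq_df, route = route,
                 forward_barriers = se - me[-length(me)],
                 reverse_barriers = se - me[-1]),
            class = "channel_profile")
}

#' @export
print.channel_profile <- function(x, ...) {
  cat("channel_profile over", length(x$route), "minima\n")
  print(x$sequence, row.names = FALSE)
  cat("forward barriers (kJ/mol):",
      paste(signif(x$forward_barriers, 4), collapse = ", "), "\n")
  invisible(x)
}

# greedy nearest-position matching of two feature tables within a radius
.match_features <- function(pos1, pos2, radius) {
  if (!nrow(pos1) || !nrow(pos2))
    return(data.frame(i = integer(), j = integer(), dist = numeric()))
  d <- as.matrix(stats::dist(rbind(pos1, pos2)))
  d <- d[seq_len(nrow(pos1)), nrow(pos1) + seq_len(nrow(pos2)), drop = FALSE]
  cand <- which(d <= radius, arr.ind = TRUE)
  if (!nrow(cand)) return(data.frame(i = integer(), j = integer(),
                                     dist = numeric()))
  cand <- cand[order(d[cand]), , drop = FALSE]
  used1 <- rep(FALSE, nrow(pos1)); used2 <- rep(FALSE, nrow(pos2))
  keep <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, 1]; j <- cand[r, 2]
    if (!used1[i] && !used2[j]) {
      keep[r] <- TRUE; used1[i] <- TRUE; used2[j] <- TRUE
    }
  }
  data.frame(i = cand[keep, 1], j = cand[keep, 2],
             dist = d[cand[keep, , drop = FALSE]])
}

#' Block-based errors of minima and saddles
#'
#' Runs the landscape analysis independently on two maps computed from
#' disjoint halves (blocks) of the data, matches minima and saddles
#' between the blocks by nearest position within a radius, and reports
#' half the absolute energy difference as the error of each feature.
#' Features present in only one block have no computable error and are
#' flagged rather than assigned zero.
#'
#' @param map_block1,map_block2 \code{fe_map}s (or grids) on identical grids.
#' @param matching_radius maximum feature displacement for a match (A);
#'   default twice the grid spacing.
#' @param cutoff,connectivity,cutoff_mode as in
#'   \code{\link{analyze_landscape}}.
#' @return list with data frames \code{minima} and \code{saddles}:
#'   matched energies from each block, \code{error} (kJ/mol, NA when
#'   uncomputable) and logical \code{uncomputable}.
#' @export
block_errors <- function(map_block1, map_block2, matching_radius = NULL,
                         cutoff = 20, connectivity = 26,
                         cutoff_mode = "voxel") {
  g1 <- if (inherits(map_block1, "fe_map")) map_block1$grid else map_block1
  g2 <- if (inherits(map_block2, "fe_map")) map_block2$grid else map_block2
  .assert(identical(g1$dims, g2$dims) &&
            isTRUE(all.equal(g1$origin, g2$origin)) &&
            isTRUE(all.equal(g1$spacing, g2$spacing)),
          "the two block maps must share an identical grid")
  if (is.null(matching_radius)) matching_radius <- 2 * max(g1$spacing)
  n1 <- analyze_landscape(g1, cutoff, connectivity, cutoff_mode)
  n2 <- analyze_landscape(g2, cutoff, connectivity, cutoff_mode)
  feature_table <- function(t1, t2, pos1, pos2) {
    m <- .match_features(pos1, pos2, matching_radius)
    rows <- list()
    for (r in seq_len(nrow(m)))
      rows[[length(rows) + 1]] <- data.frame(
        block1 = m$i[r], block2 = m$j[r],
        energy1 = t1$energy[m$i[r]], energy2 = t2$energy[m$j[r]],
        error = abs(t1$energy[m$i[r]] - t2$energy[m$j[r]]) / 2,
        uncomputable = FALSE)
    for (i in setdiff(seq_len(nrow(t1)), m$i))
      rows[[length(rows) + 1]] <- data.frame(
        block1 = i, block2 = NA_integer_, energy1 = t1$energy[i],
        energy2 = NA_real_, error = NA_real_, uncomputable = TRUE)
    for (j in setdiff(seq_len(nrow(t2)), m$j))
      rows[[length(rows) + 1]] <- data.frame(
        block1 = NA_integer_, block2 = j, energy1 = NA_real_,
        energy2 = t2$energy[j], error = NA_real_, uncomputable = TRUE)
    if (!length(rows)) return(data.frame(
      block1 = integer(), block2 = integer(), energy1 = numeric(),
      energy2 = numeric(), error = numeric(), uncomputable = logical()))
    do.call(rbind, rows)
  }
  spos <- function(net) {
    if (!nrow(net$edges)) return(matrix(numeric(0), 0, 3))
    voxel_position(net$grid, net$edges$voxel)
  }
  list(minima = feature_table(n1$nodes, n2$nodes,
                              as.matrix(n1$nodes[, c("x", "y", "z")]),
                              as.matrix(n2$nodes[, c("x", "y", "z")])),
       saddles = feature_table(n1$edges, n2$edges, spos(n1), spos(n2)))
}
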