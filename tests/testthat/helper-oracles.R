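# Independent oracle implementations used to validate the package.
# These deliberately avoid the package's internal code paths: plain-R
# energy sums, loop-based descent, flood fills, and deterministic
# quadrature.

kB_o <- 0.0083144621

# plain-R truncated 12-6 LJ energy
lj_pair_oracle <- function(r, eps, sig, cutoff = 14) {
  r <- pmax(r, 1e-3)
  s6 <- (sig / r)^6
  ifelse(r >= cutoff | eps == 0, 0, 4 * eps * s6 * (s6 - 1))
}

# insertion energy by direct enumeration over the four (site, atom) pairs
insertion_energy_oracle <- function(coords, eps, sig, probe, position,
                                    orientation, cutoff = 14,
                                    rule = "lorentz_berthelot") {
  coords <- matrix(coords, ncol = 3)
  half <- probe$bond_length / 2
  e <- 0
  for (s in 1:2) {
    p <- position + (if (s == 1) 1 else -1) * half * orientation
    for (j in seq_len(nrow(coords))) {
      r <- sqrt(sum((p - coords[j, ])^2))
      epsc <- sqrt(eps[j] * probe$epsilon[s])
      sigc <- if (rule == "lorentz_berthelot")
        (sig[j] + probe$sigma[s]) / 2 else sqrt(sig[j] * probe$sigma[s])
      e <- e + lj_pair_oracle(r, epsc, sigc, cutoff)
    }
  }
  e
}

# ---- deterministic quadrature for a single frozen LJ atom ---------------
# Exploits spherical symmetry: the orientation average of the two-site
# Boltzmann factor at center distance rho is a 1D integral in cos(theta)
# (Gauss-Legendre); the cube average over insertion positions reduces to
# interpolation of that radial table over midpoint sub-grids, refined
# adaptively.
single_atom_quadrature <- function(atom, eps_m, sig_m, probe, grid,
                                   temperature = 310, cutoff = 14,
                                   tol = 0.01, kp_max = 128,
                                   skip_above = 35) {
  stopifnot(abs(diff(probe$epsilon)) < 1e-12,
            abs(diff(probe$sigma)) < 1e-12)
  beta <- 1 / (kB_o * temperature)
  kT <- 1 / beta
  epsc <- sqrt(eps_m * probe$epsilon[1])
  sigc <- (sig_m + probe$sigma[1]) / 2
  d <- probe$bond_length / 2
  gl <- pracma::gaussLegendre(256, -1, 1)
  r0k <- 0.05; drk <- 5e-4; rmaxk <- cutoff + 2
  rho_knots <- seq(r0k, rmaxk, by = drk)
  base <- matrix(rho_knots^2 + d^2, length(rho_knots), 256)
  cross <- outer(2 * d * rho_knots, gl$x)
  h_tab <- 0.5 * as.vector(
    exp(-beta * (lj_pair_oracle(sqrt(base + cross), epsc, sigc, cutoff) +
                   lj_pair_oracle(sqrt(pmax(base - cross, 0)), epsc, sigc,
                                  cutoff))) %*% gl$w)
  nk <- length(h_tab)
  h_fast <- function(r) {
    r[r > rmaxk - 0.01] <- rmaxk - 0.01
    r[r < r0k] <- r0k
    u <- (r - r0k) / drk
    i <- pmin(floor(u) + 1, nk - 1)
    fr <- u - (i - 1)
    h_tab[i] * (1 - fr) + h_tab[i + 1] * fr
  }
  sp <- grid$spacing
  vox_dG <- function(crel, kp) {
    off <- (seq_len(kp) - 0.5) / kp - 0.5
    r2 <- outer(outer((crel[1] + off * sp[1])^2,
                      (crel[2] + off * sp[2])^2, "+"),
                (crel[3] + off * sp[3])^2, "+")
    -kT * log(mean(h_fast(sqrt(r2))))
  }
  cen <- sweep(voxel_centers(grid), 2, atom)
  vapply(seq_len(nrow(cen)), function(i) {
    rmin <- sqrt(sum(pmax(abs(cen[i, ]) - max(sp) / 2, 0)^2))
    if (rmin > sigc + 1.5) return(vox_dG(cen[i, ], 16))
    kp <- 32
    prev <- vox_dG(cen[i, ], kp)
    repeat {
      kp <- kp * 2
      cur <- vox_dG(cen[i, ], kp)
      if (!is.finite(cur) && !is.finite(prev)) return(Inf)
      if (is.finite(cur) && cur > skip_above && is.finite(prev) &&
            prev > skip_above) return(cur)
      if (is.finite(cur) && is.finite(prev) && abs(cur - prev) < tol)
        return(cur)
      if (kp >= kp_max) return(cur)
      prev <- cur
    }
  }, numeric(1))
}

# ---- watershed / saddle / minimax oracles -------------------------------

# neighbor list: n x k matrix of neighbor indices (NA-padded)
neighbor_list_oracle <- function(dims, connectivity) {
  offs <- switch(as.character(connectivity),
                 "6" = rbind(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0),
                             c(0,0,1), c(0,0,-1)),
                 "18" = {
                   g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
                   g[rowSums(g^2) %in% c(1, 2), ]
                 },
                 "26" = {
                   g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
                   g[rowSums(g^2) > 0, ]
                 })
  n <- prod(dims)
  idx <- seq_len(n) - 1L
  i <- idx %% dims[1] + 1L
  j <- (idx %/% dims[1]) %% dims[2] + 1L
  k <- idx %/% (dims[1] * dims[2]) + 1L
  nb <- matrix(NA_integer_, n, nrow(offs))
  for (o in seq_len(nrow(offs))) {
    ii <- i + offs[o, 1]; jj <- j + offs[o, 2]; kk <- k + offs[o, 3]
    ok <- ii >= 1 & ii <= dims[1] & jj >= 1 & jj <= dims[2] &
      kk >= 1 & kk <= dims[3]
    nb[ok, o] <- (kk[ok] - 1L) * dims[1] * dims[2] +
      (jj[ok] - 1L) * dims[1] + ii[ok]
  }
  nb
}

# per-voxel loop descent following the stated rule: move to the neighbor
# minimizing (value, index); move only if it improves (value, index)
descent_oracle <- function(values, dims, connectivity, cutoff) {
  nb <- neighbor_list_oracle(dims, connectivity)
  n <- length(values)
  excl <- values > cutoff
  dest <- rep(NA_integer_, n)
  for (v in seq_len(n)) {
    if (excl[v]) next
    cur <- v
    repeat {
      nbs <- nb[cur, ]
      nbs <- nbs[!is.na(nbs)]
      nbs <- nbs[!excl[nbs]]
      if (!length(nbs)) break
      best <- nbs[order(values[nbs], nbs)][1]
      if (values[best] < values[cur] ||
            (values[best] == values[cur] && best < cur)) {
        cur <- best
      } else break
    }
    dest[v] <- cur
  }
  minima <- sort(unique(dest[!is.na(dest)]))
  list(labels = ifelse(is.na(dest), NA_integer_, match(dest, minima)),
       minima = minima)
}

# exhaustive boundary scan: for each adjacent basin pair keep the boundary
# voxel pair minimizing (max value, higher-voxel index, lower-voxel index)
saddle_oracle <- function(values, dims, labels, connectivity) {
  nb <- neighbor_list_oracle(dims, connectivity)
  rows <- list()
  for (v in seq_along(values)) {
    if (is.na(labels[v])) next
    for (w in nb[v, ]) {
      if (is.na(w) || w <= v || is.na(labels[w])) next
      if (labels[v] == labels[w]) next
      la <- min(labels[v], labels[w]); lb <- max(labels[v], labels[w])
      hi <- if (values[v] > values[w]) v else
        if (values[w] > values[v]) w else min(v, w)
      lo <- if (hi == v) w else v
      rows[[length(rows) + 1]] <-
        c(la, lb, max(values[v], values[w]), hi, lo)
    }
  }
  if (!length(rows)) return(data.frame(basin_a = integer(),
                                       basin_b = integer(),
                                       energy = numeric(),
                                       voxel = integer()))
  m <- do.call(rbind, rows)
  out <- list()
  for (key in unique(paste(m[, 1], m[, 2]))) {
    sub <- m[paste(m[, 1], m[, 2]) == key, , drop = FALSE]
    best <- sub[1, ]
    for (r in seq_len(nrow(sub))) {
      cand <- sub[r, ]
      if (cand[3] < best[3] ||
            (cand[3] == best[3] && cand[4] < best[4]) ||
            (cand[3] == best[3] && cand[4] == best[4] && cand[5] < best[5]))
        best <- cand
    }
    out[[key]] <- best
  }
  m <- do.call(rbind, out)
  res <- data.frame(basin_a = m[, 1], basin_b = m[, 2], energy = m[, 3],
                    voxel = as.integer(m[, 4]))
  res[order(res$basin_a, res$basin_b), ]
}

# lowest achievable maximum voxel energy over paths between two minima,
# restricted to the union of the two basins: binary search on the energy
# threshold + BFS flood fill
minimax_oracle <- function(values, dims, labels, connectivity, la, lb,
                           min_a, min_b) {
  nb <- neighbor_list_oracle(dims, connectivity)
  region <- !is.na(labels) & (labels == la | labels == lb)
  connected_at <- function(t) {
    open <- region & values <= t
    if (!open[min_a] || !open[min_b]) return(FALSE)
    seen <- logical(length(values))
    seen[min_a] <- TRUE
    queue <- min_a
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      for (w in nb[cur, ]) {
        if (!is.na(w) && open[w] && !seen[w]) {
          seen[w] <- TRUE
          if (w == min_b) return(TRUE)
          queue <- c(queue, w)
        }
      }
    }
    FALSE
  }
  lev <- sort(unique(values[region]))
  lo <- 1L; hi <- length(lev)
  if (!connected_at(lev[hi])) return(Inf)
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    if (connected_at(lev[mid])) hi <- mid else lo <- mid + 1L
  }
  lev[lo]
}

# 26-connected component count by recursive-free BFS flood fill
flood_cc_oracle <- function(mask, dims) {
  nb <- neighbor_list_oracle(dims, 26)
  seen <- logical(length(mask))
  ncomp <- 0L
  for (v in which(mask)) {
    if (seen[v]) next
    ncomp <- ncomp + 1L
    seen[v] <- TRUE
    queue <- v
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      for (w in nb[cur, ]) {
        if (!is.na(w) && mask[w] && !seen[w]) {
          seen[w] <- TRUE
          queue <- c(queue, w)
        }
      }
    }
  }
  ncomp
}
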