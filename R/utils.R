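# Boltzmann constant, kJ mol^-1 K^-1
.kB <- 0.0083144621

#' @useDynLib gasmap, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# numerically safe log(mean(exp(x))); returns -Inf for all -Inf input
logmeanexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) {
    if (m == -Inf) return(-Inf)
    stop("non-finite (NaN/+Inf) values in log-mean-exp")
  }
  m + log(mean(exp(x - m)))
}

# log(sum(w * exp(x))) with weights w >= 0
logsumexp_w <- function(x, w) {
  keep <- w > 0
  x <- x[keep]; w <- w[keep]
  m <- max(x)
  if (m == -Inf) return(-Inf)
  m + log(sum(w * exp(x - m)))
}

.assert <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

# deterministic small-integer stream seed from (seed, voxel, frame);
# stays below 2^31 so it is a valid set.seed() argument
.stream_seed <- function(seed, voxel, frame) {
  h <- ((seed %% 100003) * 97911 + (voxel - 1) * 7919 +
          (frame - 1) * 104729) %% 2147483629
  as.integer(h) + 1L
}

# uniform unit vectors, n x 3
.runif_sphere <- function(n) {
  v <- matrix(stats::rnorm(3 * n), ncol = 3)
  nrm <- sqrt(rowSums(v^2))
  nrm[nrm < 1e-12] <- 1
  v / nrm
}
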