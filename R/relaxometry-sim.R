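## CPMG decay simulation and the log-spaced T2 grid shared by both
## inverse-Laplace solvers.

#' Log-spaced T2 grid
#'
#' Default 200 points over [0.5, 3000] ms, wide enough to bracket the T2
#' range of leaf water pools from bound/cytoplasmic water (a few ms) to
#' vacuolar water in fully hydrated tissue (hundreds of ms). The lower
#' bound sits at the first-echo time of the reference acquisition
#' (2 tau = 0.4 ms): components decaying faster than the first recorded
#' echo are not identifiable and, if included in the grid, can absorb
#' arbitrarily large invisible amplitude that distorts the area
#' fractions of the real peaks.
#'
#' @param n number of grid points
#' @param t2min,t2max grid bounds in ms (t2min > 0)
#' @return strictly increasing numeric vector of T2 values in ms
#' @export
t2Grid <- function(n = 200, t2min = 0.5, t2max = 3000) {
  stopIfNot(n >= 2 && t2min > 0 && t2max > t2min,
            "grid needs n >= 2 and 0 < t2min < t2max")
  exp(seq(log(t2min), log(t2max), length.out = n))
}

#' Simulate a CPMG echo decay
#'
#' Multi-exponential signal model
#' \deqn{S(t_k) = \sum_i A_i \exp(-t_k / T_{2,i}) + \epsilon_k}
#' sampled at echo times t_k = 2 k tau (half-echo spacing tau, 0.2 ms in
#' the reference acquisition), with optional iid Gaussian noise.
#' Reproducible for a given \code{seed}; the caller's RNG state is left
#' untouched when a seed is supplied.
#'
#' @param components two-column matrix/data.frame (T2 ms, amplitude) or a
#'   list of such pairs; all T2 > 0, amplitudes >= 0
#' @param tau half-echo spacing in ms (> 0)
#' @param nEchoes number of echoes K (>= 2)
#' @param noiseSigma sd of additive Gaussian noise (0 = noiseless)
#' @param seed optional integer seed
#' @param meta metadata list stored on the decay (leaf_rank, dase, ...)
#' @return a \code{\link{CpmgDecay}}
#' @examples
#' d <- simulateCpmg(cbind(c(40, 400), c(0.4, 0.6)), tau = 0.2,
#'                   nEchoes = 2000, noiseSigma = 1e-3, seed = 1)
#' @export
simulateCpmg <- function(components, tau = 0.2, nEchoes = 2000,
                         noiseSigma = 0, seed = NULL, meta = list()) {
  if (is.list(components) && !is.data.frame(components))
    components <- do.call(rbind, lapply(components, unlist))
  components <- as.matrix(components)
  stopIfNot(ncol(components) == 2, "components must be (T2, amplitude) pairs")
  t2 <- components[, 1]; amp <- components[, 2]
  stopIfNot(all(t2 > 0), "all T2 must be positive")
  stopIfNot(all(amp >= 0), "amplitudes must be non-negative")
  stopIfNot(tau > 0, "tau must be positive")
  stopIfNot(nEchoes >= 2, "at least 2 echoes are required")
  times <- 2 * tau * seq_len(nEchoes)
  s <- as.vector(exp(-outer(times, 1 / t2)) %*% amp)
  if (noiseSigma > 0)
    s <- s + withLocalSeed(seed, stats::rnorm(nEchoes, sd = noiseSigma))
  CpmgDecay(times, s, noiseSigma = noiseSigma, meta = meta)
}

# Noise sd from the last 5% of echoes (first differences are used so a
# residual slow decay does not inflate the estimate).
estimateNoiseSigma <- function(decay) {
  y <- amplitudes(decay)
  k <- max(3L, ceiling(0.05 * length(y)))
  stats::sd(diff(utils::tail(y, k))) / sqrt(2)
}

# Assign echoes to log-spaced time bins. Early echoes fall into bins
# narrower than the echo spacing and are kept individually. Returns the
# bin index per echo (renumbered to drop empty bins), the per-bin echo
# count and the per-bin mean time.
binEchoes <- function(times, nBins = 150) {
  n <- length(times)
  if (n <= nBins)
    return(list(bin = seq_len(n), cnt = rep(1L, n), t = times))
  edges <- exp(seq(log(times[1] * (1 - 1e-9)), log(times[n]),
                   length.out = nBins + 1))
  bin <- findInterval(times, edges, rightmost.closed = TRUE)
  bin <- pmin(pmax(bin, 1L), nBins)
  bin <- match(bin, sort(unique(bin)))      # drop empty bins
  cnt <- tabulate(bin)
  list(bin = bin, cnt = cnt, t = as.vector(rowsum(times, bin) / cnt))
}
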