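## Seeded synthetic leaf T2 scenarios: per-day multi-exponential component
## specifications encoding the developmental pattern of the vacuolar
## signal (a single rising vt component that splits into a stable vs and
## an increasing vl), wrapped around the CPMG simulator.

#' Describe a synthetic leaf-development T2 scenario
#'
#' Before the split day each decay carries one vacuolar component whose
#' T2 rises across \code{vtRange}; from the split day on it carries two,
#' a stable \code{vs} (spongy mesophyll, smaller vacuoles) and a
#' \code{vl} rising across \code{vlRange} (palisade, larger vacuoles),
#' always with vl > vs. A short non-vacuolar component (cytoplasm/
#' apoplast water) is present throughout. Supplying \code{nVacuolar}
#' directly overrides the single-split pattern and allows arbitrary
#' merge/split sequences.
#'
#' @param seed integer seed for the decay noise
#' @param dase measurement days (strictly increasing)
#' @param splitDase first day with two vacuolar components (ignored when
#'   \code{nVacuolar} is given)
#' @param nVacuolar optional explicit vector of vacuolar component counts
#'   (1 or 2) per day
#' @param tau half-echo spacing in ms
#' @param nEchoes echoes per decay
#' @param snr signal-to-noise ratio S(0)/sigma; Inf = noiseless
#' @param shortT2,shortFrac T2 (ms) and amplitude fraction of the
#'   non-vacuolar component
#' @param vtRange single-component T2 endpoints (ms) across the series
#' @param vs stable spongy-vacuole T2 (ms)
#' @param vlRange palisade-vacuole T2 endpoints (ms) across the series
#' @return list of class \code{leafT2Scenario}
#' @export
leafT2Scenario <- function(seed = 1, dase = c(24, 32, 39, 46, 54, 62),
                           splitDase = 46, nVacuolar = NULL, tau = 0.2,
                           nEchoes = 5000, snr = 1000, shortT2 = 8,
                           shortFrac = 0.25, vtRange = c(150, 300),
                           vs = 150, vlRange = c(400, 550)) {
  stopIfNot(all(diff(dase) > 0), "dase must be strictly increasing")
  if (is.null(nVacuolar)) nVacuolar <- ifelse(dase < splitDase, 1L, 2L)
  stopIfNot(length(nVacuolar) == length(dase) && all(nVacuolar %in% 1:2),
            "nVacuolar must give 1 or 2 per day")
  stopIfNot(all(vlRange > vs), "vl must exceed vs at every day")
  structure(list(seed = as.integer(seed), dase = dase,
                 nVacuolar = as.integer(nVacuolar), tau = tau,
                 nEchoes = nEchoes, snr = snr, shortT2 = shortT2,
                 shortFrac = shortFrac, vtRange = vtRange, vs = vs,
                 vlRange = vlRange),
            class = "leafT2Scenario")
}

# Ground-truth component table (T2 ms, amplitude) for day index i.
.t2Components <- function(scenario, i) {
  nd <- length(scenario$dase)
  frac <- if (nd > 1) (i - 1) / (nd - 1) else 0
  vacAmp <- 1 - scenario$shortFrac
  short <- c(scenario$shortT2, scenario$shortFrac)
  if (scenario$nVacuolar[i] == 1) {
    vt <- scenario$vtRange[1] + frac * diff(scenario$vtRange)
    rbind(short, c(vt, vacAmp))
  } else {
    vl <- scenario$vlRange[1] + frac * diff(scenario$vlRange)
    rbind(short, c(scenario$vs, 0.45 * vacAmp), c(vl, 0.55 * vacAmp))
  }
}

#' Generate a DASE series of synthetic CPMG decays
#'
#' @param scenario a \code{\link{leafT2Scenario}}
#' @return list per day with \code{dase}, \code{decay}
#'   (\code{\link{CpmgDecay}} carrying \code{dase} in its metadata),
#'   \code{components} (ground-truth (T2, amplitude) matrix) and
#'   \code{nVacuolar} (ground-truth vacuolar count)
#' @examples
#' series <- makeLeafT2Series(leafT2Scenario(seed = 7, nEchoes = 2000))
#' @export
makeLeafT2Series <- function(scenario) {
  stopIfNot(inherits(scenario, "leafT2Scenario"),
            "scenario must come from leafT2Scenario()")
  lapply(seq_along(scenario$dase), function(i) {
    comp <- .t2Components(scenario, i)
    sigma <- if (is.finite(scenario$snr)) sum(comp[, 2]) / scenario$snr else 0
    decay <- simulateCpmg(comp, tau = scenario$tau,
                          nEchoes = scenario$nEchoes, noiseSigma = sigma,
                          seed = subSeed(scenario$seed, i),
                          meta = list(dase = scenario$dase[i]))
    list(dase = scenario$dase[i], decay = decay, components = comp,
         nVacuolar = scenario$nVacuolar[i])
  })
}
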