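## Leaf water status arithmetic, gravimetric watering targets and the
## ANOVA + Tukey HSD compact-letter utility used by every group figure.

#' Leaf relative water content and leaf water deficit
#'
#' \deqn{RWC = (fresh - dry) / (turgid - dry), \quad LWD = 1 - RWC}
#' Weights must satisfy dry <= fresh <= turgid with turgid > dry.
#' Vectorised over samples.
#'
#' @param fresh,turgid,dry leaf weights in grams
#' @return data.frame with columns rwc and lwd (each in [0, 1]; rows sum
#'   to 1 exactly)
#' @examples
#' rwcLwd(0.9, 1.0, 0.0)  # RWC 0.9, LWD 0.1: a well-watered leaf
#' @export
rwcLwd <- function(fresh, turgid, dry) {
  stopIfNot(all(turgid > dry), "turgid weight must exceed dry weight")
  stopIfNot(all(dry <= fresh & fresh <= turgid),
            "weights must satisfy dry <= fresh <= turgid")
  rwc <- (fresh - dry) / (turgid - dry)
  data.frame(rwc = rwc, lwd = 1 - rwc)
}

#' Watering target fraction for a condition
#'
#' Control, MWD and SWD correspond to 70, 40 and 20% of field capacity.
#'
#' @param condition "Control", "MWD" or "SWD"
#' @param fractions named override of the per-condition fractions
#' @return target fraction of field-capacity water mass, in (0, 1]
#' @export
waterRegime <- function(condition,
                        fractions = c(Control = 0.70, MWD = 0.40,
                                      SWD = 0.20)) {
  stopIfNot(all(fractions > 0 & fractions <= 1),
            "fractions must lie in (0, 1]")
  stopIfNot(condition %in% names(fractions),
            "unknown condition '%s'", condition)
  unname(fractions[condition])
}

#' Grams of water to add to reach a pot's target mass
#'
#' The weighing-based regime targets
#' \code{tare + drySoil + fraction * fcWater}; the amount to add is the
#' (non-negative) difference from the current total mass -- water is
#' never removed, so an over-target pot gets 0 g.
#'
#' @param currentMass current total pot mass (g)
#' @param tare pot tare mass (g)
#' @param drySoil dry soil mass (g)
#' @param fcWater water mass held at 100\% field capacity (g)
#' @param fraction target fraction of field capacity (e.g.
#'   \code{waterRegime("MWD")})
#' @return grams of water to add (>= 0)
#' @examples
#' wateringAmount(15000, 2000, 12000, 4857, 0.40)  # 942.8 g
#' @export
wateringAmount <- function(currentMass, tare, drySoil, fcWater, fraction) {
  stopIfNot(all(c(tare, drySoil, fcWater) > 0), "masses must be positive")
  stopIfNot(fraction > 0 && fraction <= 1, "fraction must lie in (0, 1]")
  pmax(0, tare + drySoil + fraction * fcWater - currentMass)
}

#' Osmotic potential corrected to full turgor
#'
#' Dilution (Van't Hoff) correction of an osmotic potential measured at a
#' given relative water content:
#' \eqn{\psi_\pi(full turgor) = \psi_\pi(RWC) \times RWC}. This assumes
#' osmolytes are conserved and solute concentration scales inversely with
#' symplastic water volume -- an assumption, stated as such, since
#' instruments report \eqn{\psi_\pi} at sampling RWC.
#'
#' @param psi osmotic potential at the measured RWC (MPa, negative)
#' @param rwc relative water content at measurement, in (0, 1]
#' @return osmotic potential at full turgor (MPa)
#' @export
psiFullTurgor <- function(psi, rwc) {
  stopIfNot(all(rwc > 0 & rwc <= 1), "rwc must lie in (0, 1]")
  psi * rwc
}

#' One-way ANOVA with Tukey HSD compact letter display
#'
#' Fits a one-way ANOVA, runs Tukey's HSD on all pairwise condition
#' contrasts and summarises the result as compact letters: groups sharing
#' a letter are not significantly different at \code{alpha}. Letters are
#' derived from the maximal cliques of the "not significantly different"
#' graph, ordered by decreasing group mean, so relabelling groups only
#' permutes the letters.
#'
#' Degenerate inputs with zero residual variance (identical constant
#' groups) are handled as "no difference" among equal-mean groups. If any
#' group has fewer than 2 values the letters are suppressed (NA) and only
#' the means are returned.
#'
#' @param values numeric response
#' @param groups group labels (coerced to factor)
#' @param alpha significance level (default 0.05)
#' @return data.frame with columns group, n, mean, se, letters, ordered
#'   by decreasing mean
#' @examples
#' set.seed(1)
#' anovaTukeyLetters(c(rnorm(7), rnorm(7), rnorm(7, 10)),
#'                   rep(c("a", "b", "c"), each = 7))
#' @export
anovaTukeyLetters <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  stopIfNot(nlevels(groups) >= 2, "at least two groups are required")
  stopIfNot(length(values) == length(groups),
            "values and groups lengths differ")
  lev <- levels(groups)
  n <- as.vector(table(groups))
  mu <- as.vector(tapply(values, groups, mean))
  se <- as.vector(tapply(values, groups, function(v)
    if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_))
  out <- data.frame(group = lev, n = n, mean = mu, se = se,
                    letters = NA_character_)
  if (any(n < 2)) {
    return(out[order(out$mean, decreasing = TRUE), , drop = FALSE])
  }
  ss <- sum((values - mu[as.integer(groups)])^2)
  nsd <- matrix(FALSE, length(lev), length(lev),
                dimnames = list(lev, lev))
  if (ss < 1e-12 * max(1, sum(values^2))) {
    # zero residual variance: difference = difference of exact means
    nsd[] <- outer(mu, mu, function(a, b) abs(a - b) < 1e-12)
  } else {
    fit <- stats::aov(values ~ groups)
    tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$groups
    nsd[] <- TRUE
    pair <- strsplit(rownames(tk), "-", fixed = TRUE)
    for (i in seq_len(nrow(tk))) {
      a <- pair[[i]][1]; b <- pair[[i]][2]
      if (tk[i, "p adj"] < alpha) nsd[a, b] <- nsd[b, a] <- FALSE
    }
  }
  diag(nsd) <- TRUE
  g <- igraph::graph_from_adjacency_matrix(nsd, mode = "undirected",
                                           diag = FALSE)
  cl <- igraph::max_cliques(g)
  cliqueBest <- vapply(cl, function(v) max(mu[as.integer(v)]), 0)
  cl <- cl[order(cliqueBest, decreasing = TRUE)]
  lets <- stats::setNames(rep("", length(lev)), lev)
  for (i in seq_along(cl))
    for (v in lev[as.integer(cl[[i]])])
      lets[v] <- paste0(lets[v], letters[i])
  lets <- vapply(lets, function(s)
    paste(sort(strsplit(s, "")[[1]]), collapse = ""), "")
  out$letters <- unname(lets[out$group])
  out[order(out$mean, decreasing = TRUE), , drop = FALSE]
}

#' Tidy container for water-potential time series
#'
#' Soil and leaf water potentials are instrument measurements; this
#' validates and stores them for plotting, nothing more.
#'
#' @param dase measurement days
#' @param potential water potential in MPa (<= 0)
#' @param compartment "soil" or "leaf"
#' @param condition watering condition per row
#' @return data.frame with the validated columns
#' @export
waterPotentialSeries <- function(dase, potential,
                                 compartment = c("soil", "leaf"),
                                 condition = "Control") {
  compartment <- match.arg(compartment)
  stopIfNot(all(potential <= 0), "water potentials must be <= 0 MPa")
  data.frame(dase = dase, potential_mpa = potential,
             compartment = compartment, condition = condition)
}

#' Plot water-potential series per condition
#'
#' @param series data.frame from \code{\link{waterPotentialSeries}} (rows
#'   may mix conditions)
#' @param ... passed to \code{\link[graphics]{matplot}}
#' @return invisibly, the wide matrix that was plotted
#' @export
plotWaterPotential <- function(series, ...) {
  days <- sort(unique(series$dase))
  conds <- unique(series$condition)
  m <- sapply(conds, function(cc) {
    s <- series[series$condition == cc, ]
    s$potential_mpa[match(days, s$dase)]
  })
  m <- matrix(m, length(days), length(conds),
              dimnames = list(days, conds))
  graphics::matplot(days, m, type = "b", pch = 16, lty = 1,
                    xlab = "DASE", ylab = "Water potential (MPa)", ...)
  graphics::legend("bottomleft", legend = conds, col = seq_along(conds),
                   pch = 16, bty = "n")
  invisible(m)
}
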