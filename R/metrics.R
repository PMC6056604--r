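#' Median rate ratio
#'
#' The Larsen-Merlo summary of cluster-level heterogeneity on the rate-ratio
#' scale: the median rate increase faced by a person moving from one
#' higher-level unit to another with a higher rate,
#' \deqn{\mathrm{MRR} = \exp\{\sqrt{2\sigma^2}\,\Phi^{-1}(0.75)\}.}
#' It equals 1 when there is no between-unit variation and is strictly
#' increasing in \eqn{\sigma^2}. \eqn{\Phi^{-1}(0.75)} is evaluated
#' numerically (\eqn{\approx 0.6745}), so the coefficient on
#' \eqn{\sqrt{\sigma^2}} is \eqn{\sqrt{2}\,\Phi^{-1}(0.75) \approx 0.954}.
#'
#' @param sigma2 non-negative variance(s); vectors are transformed per
#'   element, so a posterior \eqn{\sigma^2} chain yields an MRR chain.
#' @return rate ratio(s) \eqn{\ge 1}.
#' @export
mrr <- function(sigma2) {
  if (any(sigma2 < 0)) stop("sigma2 must be non-negative")
  exp(sqrt(2 * sigma2) * stats::qnorm(0.75))
}

#' MRR point estimate and credible interval from a variance chain
#'
#' The point estimate applies the transformation to the posterior mean of
#' \eqn{\sigma^2}; the interval is obtained per draw (the transformation is
#' monotone, so the interval is the transformed variance interval).
#'
#' @param sigma2Chain posterior draws of a variance component.
#' @param level credible level (default 0.95).
#' @return named numeric: \code{estimate}, \code{lower}, \code{upper}.
#' @export
mrrInterval <- function(sigma2Chain, level = 0.95) {
  q <- stats::quantile(mrr(sigma2Chain), c((1 - level) / 2, 1 - (1 - level) / 2))
  c(estimate = mrr(mean(sigma2Chain)),
    lower = unname(q[1]), upper = unname(q[2]))
}

#' Proportional change in variance
#'
#' Fractional reduction of a variance component after adding covariates:
#' \code{(vBefore - vAfter) / vBefore}. Negative values mean the variance
#' rose after adjustment.
#'
#' @param vBefore variance before adjustment (> 0).
#' @param vAfter variance after adjustment.
#' @return fraction (1 means the variance vanished).
#' @export
pcv <- function(vBefore, vAfter) {
  if (any(vBefore <= 0)) stop("vBefore must be positive")
  (vBefore - vAfter) / vBefore
}

#' Deviance information criterion
#'
#' \eqn{pD = \bar D - D(\bar\theta)} and \eqn{\mathrm{DIC} = \bar D + pD},
#' with the plug-in deviance evaluated at the posterior means of the
#' parameters (\eqn{\beta} and every \eqn{u}), not of the linear predictor.
#' A degenerate (constant) posterior therefore has \eqn{pD = 0} and DIC equal
#' to the plug-in deviance.
#'
#' @param fit an [MmFit-class].
#' @param data the [MmDataset-class] the model was fitted to.
#' @return named numeric: \code{DIC}, \code{pD}, \code{meanDeviance},
#'   \code{pluginDeviance}.
#' @export
dic <- function(fit, data) {
  stopifnot(methods::is(fit, "MmFit"), methods::is(data, "MmDataset"))
  dbar <- mean(fit@deviance)
  betaBar <- colMeans(fit@beta)
  uBar <- lapply(fit@u, colMeans)
  dhat <- poissonDeviance(data@y, .stateMu(data, betaBar, uBar))
  pd <- dbar - dhat
  c(DIC = dbar + pd, pD = pd, meanDeviance = dbar, pluginDeviance = dhat)
}

#' Posterior ranking of hospitals
#'
#' Ranks the units of a random classification by the posterior median of
#' their effect, with 95 percent credible intervals, and flags units whose
#' interval excludes 0 (higher- or lower-than-average rates). Rank 1 is the
#' lowest (most protective) effect.
#'
#' @param fit an [MmFit-class].
#' @param classification name or index of the classification to rank.
#' @param level credible level.
#' @return data.frame: \code{hospital_id}, \code{median}, \code{lower},
#'   \code{upper}, \code{rank}, \code{flag} ("low", "high" or "").
#' @export
rankHospitals <- function(fit, classification = 1L, level = 0.95) {
  u <- uSamples(fit, classification)
  a <- (1 - level) / 2
  med <- apply(u, 2L, stats::median)
  lo <- apply(u, 2L, stats::quantile, probs = a)
  hi <- apply(u, 2L, stats::quantile, probs = 1 - a)
  out <- data.frame(hospital_id = colnames(u), median = med,
                    lower = lo, upper = hi,
                    rank = rank(med, ties.method = "first"),
                    flag = ifelse(hi < 0, "low", ifelse(lo > 0, "high", "")),
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$rank), ]
}

#' Compare hospital rankings from two fits
#'
#' Pairs the posterior rankings of two models sharing (part of) a hospital
#' set — typically a multiple-membership weighted-network fit against a
#' discrete-HSA fit, which lacks hospitals with empty service areas — and
#' reports the Spearman rank correlation over the shared hospitals plus the
#' hospitals ranked only by the first fit.
#'
#' @param fitMm,fitRef two [MmFit-class] objects.
#' @param classification classification to compare (name or index, applied to
#'   both fits).
#' @return list: \code{table} (paired medians/intervals/ranks),
#'   \code{spearman}, \code{onlyInFirst} (hospital ids).
#' @export
compareRankings <- function(fitMm, fitRef, classification = 1L) {
  r1 <- rankHospitals(fitMm, classification)
  r2 <- rankHospitals(fitRef, classification)
  shared <- intersect(r1$hospital_id, r2$hospital_id)
  if (!length(shared)) stop("the two fits share no hospitals")
  tab <- merge(r1, r2, by = "hospital_id", suffixes = c(".mm", ".ref"))
  rho <- stats::cor(tab$median.mm, tab$median.ref, method = "spearman")
  list(table = tab[order(tab$rank.mm), ],
       spearman = unname(rho),
       onlyInFirst = sort(setdiff(r1$hospital_id, r2$hospital_id)))
}

#' Ratio of between-unit variances from two models
#'
#' Convenience comparison of the residual between-unit variance under two
#' clustering structures (e.g. weighted network vs discrete catchments),
#' reported as variance estimates and their ratio.
#'
#' @param vMm,vRef variance estimates (posterior means) from the two models.
#' @return named numeric: the two variances, their ratio, and the MRRs.
#' @export
varianceComparison <- function(vMm, vRef) {
  stopifnot(vMm >= 0, vRef > 0)
  c(varianceMm = vMm, varianceRef = vRef, ratio = vMm / vRef,
    mrrMm = mrr(vMm), mrrRef = mrr(vRef))
}

#' Metrics report for one or two fits
#'
#' Bundles the variance summaries (posterior mean and SE, MRR with credible
#' interval), the DIC, and the hospital ranking; with a baseline fit it adds
#' the PCV-style variance comparison and rank concordance.
#'
#' @param fit an [MmFit-class].
#' @param data the matching [MmDataset-class].
#' @param baselineFit,baselineData optional second fit for comparison.
#' @param classification classification to summarise.
#' @return list with elements \code{variance}, \code{mrr}, \code{dic},
#'   \code{ranking}, and optionally \code{comparison}.
#' @export
metricsReport <- function(fit, data, baselineFit = NULL, baselineData = NULL,
                          classification = 1L) {
  s2 <- sigma2Samples(fit)[, classification]
  out <- list(
    variance = c(mean = mean(s2), se = stats::sd(s2)),
    mrr = mrrInterval(s2),
    dic = dic(fit, data),
    ranking = rankHospitals(fit, classification))
  if (!is.null(baselineFit)) {
    s2b <- sigma2Samples(baselineFit)[, classification]
    out$comparison <- list(
      variances = varianceComparison(mean(s2), mean(s2b)),
      pcv = pcv(mean(s2), mean(s2b)),
      rankings = compareRankings(fit, baselineFit, classification))
    if (!is.null(baselineData))
      out$comparison$dicBaseline <- dic(baselineFit, baselineData)
  }
  out
}

#' Caterpillar plot of hospital effects
#'
#' Plots posterior medians and credible intervals of the hospital effects in
#' rank order, optionally overlaying a second fit's estimates for the shared
#' hospitals (the classical ranking-comparison figure).
#'
#' @param ranking data.frame from [rankHospitals()].
#' @param refRanking optional second ranking to overlay.
#' @param file optional PNG path; when NULL, plots to the active device.
#' @return the file path (or NULL), invisibly.
#' @export
caterpillarPlot <- function(ranking, refRanking = NULL, file = NULL) {
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 500)
    on.exit(grDevices::dev.off())
  }
  ord <- order(ranking$median)
  r <- ranking[ord, ]
  n <- nrow(r)
  ylim <- range(c(r$lower, r$upper,
                  if (!is.null(refRanking)) c(refRanking$lower, refRanking$upper)))
  graphics::plot(seq_len(n), r$median, pch = 16, ylim = ylim,
                 xlab = "hospital (ranked)", ylab = "posterior effect (log rate)",
                 main = "Hospital effects on admission rates")
  graphics::segments(seq_len(n), r$lower, seq_len(n), r$upper)
  graphics::abline(h = 0, lty = 2)
  if (!is.null(refRanking)) {
    m <- match(r$hospital_id, refRanking$hospital_id)
    graphics::points(seq_len(n) + 0.3, refRanking$median[m], pch = 1, col = 2)
    graphics::segments(seq_len(n) + 0.3, refRanking$lower[m],
                       seq_len(n) + 0.3, refRanking$upper[m], col = 2)
  }
  invisible(file)
}
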