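#' Group-mean-centre and rescale a hospital covariate
#'
#' Centres a hospital attribute on its mean across hospitals and rescales it
#' so that one unit corresponds to \code{scale} original units (for bed
#' occupancy in percent, \code{scale = 10} makes one unit a 10-percentage-
#' point change, the convention used when modelling occupancy effects).
#'
#' @param x named numeric vector of hospital attribute values.
#' @param scale original units per rescaled unit (default 10).
#' @return named numeric vector \code{(x - mean(x)) / scale}.
#' @export
centerHospitalCovariate <- function(x, scale = 10) {
  (x - mean(x)) / scale
}

#' Assemble a model-ready dataset
#'
#' Combines person-level outcome counts, follow-up offsets, person-level
#' fixed effects, optional weighted hospital-level covariates, and one or
#' more random classifications into an [MmDataset-class].
#'
#' Hospital covariates are attached as their weighted network average per
#' person (\code{W \%*\% x}); with \code{centerScale} set they are first
#' group-mean-centred and rescaled via [centerHospitalCovariate()].
#'
#' @param persons data.frame with \code{person_id}, the outcome and offset
#'   columns, and any fixed-effect columns.
#' @param classifications named list of sparse person x unit weight matrices
#'   (rows must sum to 1 and be named by person id), e.g. from
#'   [personWeightMatrix()] or [hsaMembershipMatrix()]. Persons missing from
#'   any classification are dropped with a message.
#' @param outcome name of the count outcome column.
#' @param offset name of the positive follow-up time column.
#' @param fixed character vector of person-level fixed-effect columns
#'   (an intercept is always included).
#' @param hospitalCovariates optional named list of named numeric vectors of
#'   hospital attributes; each is attached as a weighted average using the
#'   first classification's weights.
#' @param centerScale if non-NULL, hospital covariates are group-mean-centred
#'   and rescaled by this many original units per model unit.
#' @return an [MmDataset-class].
#' @export
buildMmDataset <- function(persons, classifications,
                           outcome = "y_preventable",
                           offset = "followup_years",
                           fixed = character(),
                           hospitalCovariates = NULL,
                           centerScale = 10) {
  .checkColumns(persons, c("person_id", outcome, offset, fixed), "persons")
  if (is.null(names(classifications)) || any(names(classifications) == ""))
    stop("classifications must be a named list")
  ids <- as.character(persons$person_id)
  keep <- rep(TRUE, length(ids))
  for (W in classifications) keep <- keep & ids %in% rownames(W)
  if (any(!keep))
    message(sum(!keep), " person(s) missing classification weights were dropped")
  persons <- persons[keep, , drop = FALSE]
  ids <- ids[keep]
  if (!nrow(persons)) stop("no persons remain after classification matching")
  cls <- lapply(classifications, function(W)
    methods::as(W[ids, , drop = FALSE], "CsparseMatrix"))

  t <- as.numeric(persons[[offset]])
  if (any(!is.finite(t)) || any(t <= 0))
    stop("offset column '", offset, "' must be positive follow-up time")
  y <- persons[[outcome]]
  if (any(y < 0) || any(y != round(y)))
    stop("outcome column '", outcome, "' must hold non-negative counts")

  X <- matrix(1, nrow(persons), 1, dimnames = list(NULL, "(Intercept)"))
  if (length(fixed))
    X <- cbind(X, as.matrix(persons[, fixed, drop = FALSE]))
  if (!is.null(hospitalCovariates)) {
    W1 <- cls[[1L]]
    for (nm in names(hospitalCovariates)) {
      x <- hospitalCovariates[[nm]]
      if (!is.null(centerScale)) x <- centerHospitalCovariate(x, centerScale)
      X <- cbind(X, weightedHospitalCovariate(W1, x))
      colnames(X)[ncol(X)] <- nm
    }
  }
  storage.mode(X) <- "double"
  methods::new("MmDataset", y = as.integer(round(y)), offset = t, X = X,
               classifications = cls, personIds = ids)
}

#' Prior settings for the multilevel Poisson sampler
#'
#' Diffuse defaults: iid Normal(0, 1e6) on every fixed effect and
#' Inverse-Gamma(0.001, 0.001) on every classification variance.
#'
#' @param betaVar prior variance of the fixed effects.
#' @param igShape,igRate shape and rate of the inverse-gamma variance prior.
#' @return list of prior settings.
#' @export
mmPriors <- function(betaVar = 1e6, igShape = 0.001, igRate = 0.001) {
  stopifnot(betaVar > 0, igShape > 0, igRate > 0)
  list(betaVar = betaVar, igShape = igShape, igRate = igRate)
}

#' MCMC settings
#'
#' Defaults follow the reference analysis: 5,000 burn-in iterations and
#' 20,000 stored samples (thinning 1). Adaptation of the random-walk step
#' sizes targets roughly 44 percent acceptance and happens only during
#' burn-in.
#'
#' @param burnin burn-in iterations (discarded, used for adaptation).
#' @param samples post burn-in iterations.
#' @param thin store every \code{thin}-th state.
#' @param seed integer RNG seed.
#' @param adaptBatch iterations per adaptation batch.
#' @param adaptTarget target acceptance rate.
#' @return list of MCMC settings.
#' @export
mcmcControl <- function(burnin = 5000, samples = 20000, thin = 1, seed = 1,
                        adaptBatch = 50, adaptTarget = 0.44) {
  stopifnot(burnin >= 0, samples > 0, thin >= 1, adaptBatch > 0)
  list(burnin = as.integer(burnin), samples = as.integer(samples),
       thin = as.integer(thin), seed = as.integer(seed),
       adaptBatch = as.integer(adaptBatch), adaptTarget = adaptTarget)
}

#' Fit a multilevel Poisson model by MCMC
#'
#' Samples the posterior of
#' \deqn{\log \mu_i = \log t_i + x_i'\beta + \sum_c \sum_j w^{(c)}_{ij} u^{(c)}_j,
#'       \quad u^{(c)}_j \sim N(0, \sigma^2_c)}
#' by adaptive Metropolis-within-Gibbs: random-walk Metropolis updates for
#' each fixed effect and each random effect (the Poisson likelihood is not
#' conjugate), and conjugate Gibbs draws for each variance component. The fit
#' is deterministic given \code{control$seed}.
#'
#' Classifications may be multiple-membership (fractional weight rows),
#' single-membership (unit rows) or any mix (cross-classified models). With
#' \code{fixU} / \code{fixSigma2}, individual blocks can be pinned to their
#' initial values, e.g. to examine conditional distributions.
#'
#' @param data an [MmDataset-class].
#' @param priors from [mmPriors()].
#' @param control from [mcmcControl()].
#' @param fixU,fixSigma2 logical vectors (one per classification): hold the
#'   random effects / the variance of that classification at its initial
#'   value.
#' @param uInit optional list of initial random-effect vectors. By default
#'   each u is initialised at crude per-unit log-rate deviations (smoothed,
#'   centred), which keeps the chain away from the degenerate
#'   \eqn{\sigma^2 \approx 0, u \approx 0} trap of the inverse-gamma Gibbs
#'   step.
#' @param sigma2Init initial variance(s), recycled over classifications; by
#'   default the variance of the initial u (at least 0.01).
#' @return an [MmFit-class]. A warning (not an error) is attached to the
#'   acceptance report when a block's post burn-in acceptance rate falls
#'   outside [0.1, 0.8].
#' @export
fitMmPoisson <- function(data, priors = mmPriors(), control = mcmcControl(),
                         fixU = NULL, fixSigma2 = NULL,
                         uInit = NULL, sigma2Init = NULL) {
  stopifnot(methods::is(data, "MmDataset"))
  methods::validObject(data)
  C <- length(data@classifications)
  if (is.null(fixU)) fixU <- rep(FALSE, C)
  if (is.null(fixSigma2)) fixSigma2 <- rep(FALSE, C)
  ybar <- sum(data@y) / sum(data@offset)
  betaInit <- c(log(max(ybar, 1e-8)), numeric(ncol(data@X) - 1L))
  mu0 <- data@offset * max(ybar, 1e-8)
  uDefault <- lapply(data@classifications, function(W) {
    r <- (as.numeric(data@y %*% W) + 0.5) / (as.numeric(mu0 %*% W) + 0.5)
    lr <- log(r)
    lr - mean(lr)
  })
  if (is.null(uInit)) uInit <- vector("list", C)
  for (c in seq_len(C))
    if (is.null(uInit[[c]])) uInit[[c]] <- uDefault[[c]]
  if (is.null(sigma2Init)) sigma2Init <- NA_real_
  sigma2Init <- rep_len(as.numeric(sigma2Init), C)
  na <- is.na(sigma2Init)
  sigma2Init[na] <- vapply(uInit[na], function(u) max(stats::var(u), 0.01),
                           numeric(1))

  set.seed(control$seed)
  res <- .mm_poisson_mcmc(
    y = data@y, log_t = log(data@offset), X = data@X,
    cls_i = lapply(data@classifications, function(W) W@i),
    cls_p = lapply(data@classifications, function(W) W@p),
    cls_x = lapply(data@classifications, function(W) W@x),
    cls_J = vapply(data@classifications, ncol, integer(1)),
    beta_prior_var = priors$betaVar,
    ig_shape = priors$igShape, ig_rate = priors$igRate,
    burnin = control$burnin, n_iter = control$samples, thin = control$thin,
    fix_u = fixU, fix_sigma2 = fixSigma2,
    u_init = uInit, sigma2_init = sigma2Init, beta_init = betaInit,
    adapt_batch = control$adaptBatch, adapt_target = control$adaptTarget)

  colnames(res$beta) <- colnames(data@X)
  colnames(res$sigma2) <- names(data@classifications)
  names(res$u) <- names(data@classifications)
  for (nm in names(res$u))
    colnames(res$u[[nm]]) <- colnames(data@classifications[[nm]])
  names(res$accept_beta) <- colnames(data@X)
  names(res$accept_u) <- names(data@classifications)

  methods::new("MmFit",
               beta = res$beta, u = res$u, sigma2 = res$sigma2,
               deviance = as.numeric(res$deviance),
               acceptance = list(beta = res$accept_beta, u = res$accept_u),
               control = c(control, priors = list(priors),
                           fixU = list(fixU), fixSigma2 = list(fixSigma2)))
}

#' Poisson deviance at a parameter state
#'
#' \eqn{-2 \sum_i [Y_i \log\mu_i - \mu_i - \log(Y_i!)]}, the saturated-free
#' deviance used for the DIC.
#'
#' @param y non-negative counts.
#' @param mu positive means.
#' @return scalar deviance.
#' @export
poissonDeviance <- function(y, mu) {
  stopifnot(length(y) == length(mu), all(mu > 0))
  -2 * sum(y * log(mu) - mu - lgamma(y + 1))
}

#' Linear predictor and deviance helpers for a fitted state
#' @noRd
.stateMu <- function(data, beta, uList) {
  eta <- log(data@offset) + as.numeric(data@X %*% beta)
  for (nm in names(data@classifications))
    eta <- eta + as.numeric(data@classifications[[nm]] %*% uList[[nm]])
  exp(eta)
}

#' MCMC diagnostics
#'
#' Effective sample sizes and Geweke z-scores per stored parameter, and the
#' acceptance rates per Metropolis block. Chains whose post burn-in
#' acceptance rate lies outside [0.1, 0.8], and (near-)constant chains, are
#' flagged.
#'
#' @param fit an [MmFit-class].
#' @return list with data.frame \code{parameters} (ess, geweke_z, flag),
#'   the acceptance rates, and character vector \code{warnings}.
#' @export
mmDiagnostics <- function(fit) {
  stopifnot(methods::is(fit, "MmFit"))
  chains <- cbind(fit@beta, fit@sigma2)
  colnames(chains) <- c(colnames(fit@beta),
                        paste0("sigma2[", colnames(fit@sigma2), "]"))
  ess <- apply(chains, 2L, chainEss)
  gz <- apply(chains, 2L, function(x) {
    if (stats::sd(x) < 1e-12) return(NA_real_)
    unname(coda::geweke.diag(coda::mcmc(x))$z)
  })
  flag <- ifelse(ess == 0, "degenerate",
                 ifelse(!is.na(gz) & abs(gz) > 3, "nonstationary?", ""))
  params <- data.frame(parameter = colnames(chains), ess = ess,
                       geweke_z = gz, flag = flag, row.names = NULL)
  warnings <- character()
  accAll <- c(fit@acceptance$beta,
              unlist(fit@acceptance$u, use.names = FALSE))
  bad <- accAll < 0.1 | accAll > 0.8
  fixed <- c(rep(FALSE, length(fit@acceptance$beta)),
             rep(fit@control$fixU,
                 vapply(fit@acceptance$u, length, integer(1))))
  if (any(bad & !fixed))
    warnings <- c(warnings, sprintf(
      "%d Metropolis block(s) with acceptance outside [0.1, 0.8]",
      sum(bad & !fixed)))
  list(parameters = params, acceptance = fit@acceptance, warnings = warnings)
}

#' Effective sample size of one chain
#'
#' \code{coda}'s spectral-density estimator; a chain with (numerically) zero
#' variance has ESS 0 by convention here, so degenerate chains are visible.
#'
#' @param x numeric chain.
#' @return effective sample size.
#' @export
chainEss <- function(x) {
  if (stats::sd(x) < 1e-12) return(0)
  unname(coda::effectiveSize(coda::mcmc(x)))
}

#' Export traceplots for a fit
#'
#' Writes a multi-panel traceplot (fixed effects, variances, deviance) to a
#' PNG file for the visual convergence check.
#'
#' @param fit an [MmFit-class].
#' @param file output PNG path.
#' @return the file path, invisibly.
#' @export
tracePlot <- function(fit, file) {
  chains <- cbind(fit@beta, fit@sigma2, deviance = fit@deviance)
  colnames(chains) <- c(colnames(fit@beta),
                        paste0("sigma2[", colnames(fit@sigma2), "]"),
                        "deviance")
  k <- ncol(chains)
  grDevices::png(file, width = 900, height = 220 * k)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(k, 1), mar = c(2.5, 4, 2, 1))
  for (j in seq_len(k))
    graphics::plot(chains[, j], type = "l", ylab = colnames(chains)[j],
                   xlab = "", main = colnames(chains)[j])
  invisible(file)
}
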