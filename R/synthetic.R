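#' Configure the synthetic area-hospital system
#'
#' Defaults describe a desk-scale system mirroring the statistical shape of a
#' large linked cohort: 60 residence areas and 15 hospitals (scaled from
#' 593 areas / 79 hospitals / ~267k persons), ~100 persons per area, mean
#' follow-up 3.7 years, about one all-cause admission per person over
#' follow-up and ~0.10 preventable hospitalizations per person, hospital
#' loyalty averaging about two-thirds of an area's admissions to its most
#' common hospital, and a between-hospital variance of 0.13 on the log-rate
#' scale.
#'
#' Patient flows follow a gravity model: the probability that a resident of
#' area a is admitted to hospital j is proportional to
#' \eqn{s_j \exp(-d_{aj}/\phi)} with hospital size \eqn{s_j}, Euclidean
#' distance \eqn{d_{aj}} on the unit square, and decay range \eqn{\phi}
#' (\code{flowConcentration}); smaller \eqn{\phi} concentrates each area on
#' its nearest large hospital. The default \eqn{\phi} is calibrated so the
#' mean top-1 share lands near 67 percent.
#'
#' @param nAreas number of residence areas.
#' @param nHospitals number of hospitals.
#' @param personsPerArea mean persons per area (negative-binomial).
#' @param personsDispersion negative-binomial size parameter (smaller = more
#'   skewed area populations).
#' @param hospitalSizeSd log-sd of hospital size weights.
#' @param flowConcentration gravity decay range \eqn{\phi > 0}.
#' @param admissionRate all-cause admissions per person-year.
#' @param preventableRate target marginal preventable hospitalizations per
#'   person-year (the baseline log-rate is calibrated to hit it).
#' @param sigma2U true between-hospital variance of the random effects.
#' @param beta named person-level fixed-effect coefficients for the generated
#'   covariates \code{age_band} (0/1/2), \code{sex} (0/1),
#'   \code{health_score} (standard normal).
#' @param followupRange range of the uniform follow-up draw, years
#'   (default mean 3.7).
#' @param nSla number of secondary-geography (SLA-analogue) units; areas are
#'   grouped into SLAs by a coarse spatial grid.
#' @param sigma2Sla true between-SLA variance (0 disables SLA effects).
#' @param occupancyMean,occupancySd hospital bed-occupancy distribution (%).
#' @return a [SimConfig-class].
#' @export
simConfig <- function(nAreas = 60, nHospitals = 15,
                      personsPerArea = 100, personsDispersion = 5,
                      hospitalSizeSd = 1, flowConcentration = 0.055,
                      admissionRate = 0.27, preventableRate = 0.027,
                      sigma2U = 0.13,
                      beta = c(age_band = 0.25, sex = -0.1, health_score = 0.35),
                      followupRange = c(1.4, 6.0),
                      nSla = 12, sigma2Sla = 0,
                      occupancyMean = 90, occupancySd = 8) {
  methods::new("SimConfig", params = list(
    nAreas = nAreas, nHospitals = nHospitals,
    personsPerArea = personsPerArea, personsDispersion = personsDispersion,
    hospitalSizeSd = hospitalSizeSd, flowConcentration = flowConcentration,
    admissionRate = admissionRate, preventableRate = preventableRate,
    sigma2U = sigma2U, beta = beta, followupRange = followupRange,
    nSla = nSla, sigma2Sla = sigma2Sla,
    occupancyMean = occupancyMean, occupancySd = occupancySd))
}

#' Generate a synthetic area-hospital system with known ground truth
#'
#' Places hospitals and areas on the unit square, derives gravity-model flow
#' probabilities, draws persons with covariates and follow-up, draws
#' all-cause admissions (multinomial over the area's flow distribution) and
#' preventable outcome counts
#' \eqn{Y_i \sim \mathrm{Poisson}\{t_i \exp(\beta_0 + x_i'\beta +
#' \sum_j p_{aj} u_j + v_{s})\}} with hospital effects
#' \eqn{u_j \sim N(0, \sigma^2_u)} and optional SLA effects
#' \eqn{v_s \sim N(0, \sigma^2_{SLA})}. Preventable counts are emitted as
#' additional flagged admission rows so the outcome can be re-counted from
#' the admission table. The baseline \eqn{\beta_0} is calibrated so the
#' marginal preventable rate matches \code{preventableRate}. Identical seed
#' and config give identical output.
#'
#' @param config a [SimConfig-class].
#' @param seed integer RNG seed.
#' @return list with data.frames \code{admissions} (person_id, area_id,
#'   hospital_id, preventable, episode_id), \code{persons} (person_id,
#'   area_id, sla_id, followup_years, age_band, sex, health_score,
#'   y_preventable), \code{hospitals} (hospital_id, occupancy_pct, size, x, y)
#'   and \code{truth} (u, beta, beta0, sigma2U, flow probabilities, SLA
#'   effects, seed).
#' @export
generateSystem <- function(config = simConfig(), seed = 1) {
  stopifnot(methods::is(config, "SimConfig"))
  methods::validObject(config)
  p <- config@params
  set.seed(as.integer(seed))

  hospIds <- sprintf("H%02d", seq_len(p$nHospitals))
  areaIds <- sprintf("A%03d", seq_len(p$nAreas))
  hx <- stats::runif(p$nHospitals); hy <- stats::runif(p$nHospitals)
  size <- exp(stats::rnorm(p$nHospitals, 0, p$hospitalSizeSd))
  occupancy <- stats::rnorm(p$nHospitals, p$occupancyMean, p$occupancySd)
  ax <- stats::runif(p$nAreas); ay <- stats::runif(p$nAreas)

  d <- sqrt(outer(ax, hx, "-")^2 + outer(ay, hy, "-")^2)
  # subtract the row minimum before exponentiating: invariant under the
  # normalisation, and keeps small decay ranges from underflowing every term
  flow <- sweep(exp(-(d - apply(d, 1L, min)) / p$flowConcentration), 2L, size, "*")
  flow <- flow / rowSums(flow)
  dimnames(flow) <- list(areaIds, hospIds)

  # secondary geography: coarse spatial grid over area coordinates
  g <- max(1L, ceiling(sqrt(p$nSla)))
  cell <- (pmin(floor(ax * g), g - 1)) * g + pmin(floor(ay * g), g - 1)
  slaOfArea <- sprintf("S%02d", as.integer(factor(cell)))
  slaIds <- sort(unique(slaOfArea))

  nPer <- pmax(1L, stats::rnbinom(p$nAreas, mu = p$personsPerArea,
                                  size = p$personsDispersion))
  n <- sum(nPer)
  areaIdx <- rep(seq_len(p$nAreas), nPer)
  persons <- data.frame(
    person_id = sprintf("P%06d", seq_len(n)),
    area_id = areaIds[areaIdx],
    sla_id = slaOfArea[areaIdx],
    followup_years = stats::runif(n, p$followupRange[1], p$followupRange[2]),
    age_band = sample(0:2, n, replace = TRUE, prob = c(0.45, 0.40, 0.15)),
    sex = stats::rbinom(n, 1, 0.5),
    health_score = stats::rnorm(n),
    stringsAsFactors = FALSE)

  u <- if (p$sigma2U > 0) stats::rnorm(p$nHospitals, 0, sqrt(p$sigma2U)) else
    numeric(p$nHospitals)
  names(u) <- hospIds
  v <- if (p$sigma2Sla > 0) stats::rnorm(length(slaIds), 0, sqrt(p$sigma2Sla)) else
    numeric(length(slaIds))
  names(v) <- slaIds

  X <- as.matrix(persons[, names(p$beta)])
  lp <- as.numeric(X %*% p$beta) + as.numeric(flow %*% u)[areaIdx] +
    v[persons$sla_id]
  t <- persons$followup_years
  beta0 <- log(p$preventableRate * sum(t) / sum(t * exp(lp)))
  y <- stats::rpois(n, t * exp(beta0 + lp))
  persons$y_preventable <- y

  drawHospitals <- function(personRows, counts) {
    tot <- sum(counts)
    if (tot == 0L) return(data.frame(person = integer(), hospital = character()))
    who <- rep(personRows, counts)
    hosp <- character(tot)
    byArea <- split(seq_len(tot), areaIdx[who])
    for (a in names(byArea)) {
      k <- byArea[[a]]
      hosp[k] <- sample(hospIds, length(k), replace = TRUE,
                        prob = flow[as.integer(a), ])
    }
    data.frame(person = who, hospital = hosp)
  }
  nAdm <- stats::rpois(n, p$admissionRate * t)
  allCause <- drawHospitals(seq_len(n), nAdm)
  prevRows <- drawHospitals(seq_len(n), y)
  admissions <- data.frame(
    person_id = persons$person_id[c(allCause$person, prevRows$person)],
    area_id = persons$area_id[c(allCause$person, prevRows$person)],
    hospital_id = c(allCause$hospital, prevRows$hospital),
    preventable = rep(c(0L, 1L), c(nrow(allCause), nrow(prevRows))),
    episode_id = NA_character_,
    stringsAsFactors = FALSE)

  hospitals <- data.frame(hospital_id = hospIds, occupancy_pct = occupancy,
                          size = size, x = hx, y = hy,
                          stringsAsFactors = FALSE)
  truth <- list(u = u, beta = p$beta, beta0 = beta0, sigma2U = p$sigma2U,
                sigma2Sla = p$sigma2Sla, v = v, flowProbs = flow,
                slaOfArea = stats::setNames(slaOfArea, areaIds),
                seed = as.integer(seed))
  list(admissions = admissions, persons = persons, hospitals = hospitals,
       truth = truth)
}

#' Loyalty profile of a system's patient flows
#'
#' For every area, the ordered shares of admissions to its most common,
#' second and third most common hospitals, with the usual summary statistics
#' (mean, interquartile range, min-max).
#'
#' @param admissions admissions data.frame (\code{area_id},
#'   \code{hospital_id}).
#' @return object of class \code{LoyaltyProfile}: list with \code{perArea}
#'   (data.frame of percent shares) and \code{summary} (statistics per rank).
#' @export
loyaltyProfile <- function(admissions) {
  flows <- computeAreaWeights(admissions)
  w <- as.matrix(flowWeights(flows))
  shares <- t(apply(w, 1L, function(r) {
    s <- sort(r, decreasing = TRUE)
    100 * c(s, 0, 0, 0)[1:3]
  }))
  perArea <- data.frame(area_id = rownames(w), share1 = shares[, 1],
                        share2 = shares[, 2], share3 = shares[, 3],
                        row.names = NULL, stringsAsFactors = FALSE)
  stat <- function(x) c(mean = mean(x), q25 = unname(stats::quantile(x, .25)),
                        q75 = unname(stats::quantile(x, .75)),
                        min = min(x), max = max(x))
  structure(list(perArea = perArea,
                 summary = rbind(share1 = stat(perArea$share1),
                                 share2 = stat(perArea$share2),
                                 share3 = stat(perArea$share3))),
            class = "LoyaltyProfile")
}

#' @export
print.LoyaltyProfile <- function(x, ...) {
  cat(sprintf("LoyaltyProfile over %d areas (%% of admissions):\n",
              nrow(x$perArea)))
  print(round(x$summary, 1))
  invisible(x)
}
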