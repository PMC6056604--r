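#' Run the full weighted-network analysis pipeline
#'
#' One call reproduces the whole workflow on any dataset: episode merging,
#' flow-weight and HSA construction with catchment descriptives, a
#' multiple-membership Poisson fit on the weighted network, a companion fit
#' clustering persons in their discrete HSA, and a comparison report
#' (variance ratio, PCV, MRRs, DIC, rank concordance). Deterministic given
#' \code{seed}. When \code{outDir} is given, every stage writes its artifacts
#' there together with a provenance record (\code{run.json}: config echo,
#' seed, package version).
#'
#' @param admissions,persons,hospitals input data.frames (e.g. from
#'   [readTables()] or [generateSystem()]).
#' @param outcome,offset,fixed,hospitalCovariates model structure; see
#'   [buildMmDataset()]. \code{hospitalCovariates} names columns of
#'   \code{hospitals}.
#' @param attributeEpisode episode attribution policy ("first" or "last").
#' @param priors,control sampler settings; see [mmPriors()], [mcmcControl()].
#' @param seed integer seed (overrides \code{control$seed}).
#' @param outDir optional output directory.
#' @param fitHsa also fit the discrete-HSA model and compare (default TRUE).
#' @param verbose log record counts per stage.
#' @return list: \code{flows}, \code{partition}, \code{summary},
#'   \code{dataset}, \code{fit}, and (with \code{fitHsa}) \code{datasetHsa},
#'   \code{fitHsa} and \code{report} (from [metricsReport()]).
#' @export
runPipeline <- function(admissions, persons, hospitals = NULL,
                        outcome = "y_preventable", offset = "followup_years",
                        fixed = intersect(c("age_band", "sex", "health_score"),
                                          names(persons)),
                        hospitalCovariates = character(),
                        attributeEpisode = c("first", "last"),
                        priors = mmPriors(), control = mcmcControl(),
                        seed = control$seed, outDir = NULL,
                        fitHsa = TRUE, verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  control$seed <- as.integer(seed)

  merged <- mergeEpisodes(admissions, match.arg(attributeEpisode))
  say("episodes: %d admission rows -> %d episodes", nrow(admissions), nrow(merged))
  flows <- computeAreaWeights(merged)
  partition <- assignHsa(flows)
  say("catchments: %d areas, %d hospitals, %d non-empty HSAs",
      nrow(flowWeights(flows)), ncol(flowWeights(flows)),
      length(partition@hospitals) - length(emptyHsas(partition)))

  if (!outcome %in% names(persons)) {
    prev <- merged[merged$preventable == 1, ]
    cnt <- table(factor(prev$person_id, levels = persons$person_id))
    persons[[outcome]] <- as.integer(cnt)
    say("outcome: counted %d preventable episodes from admissions", nrow(prev))
  }
  summary <- catchmentSummary(flows, partition, persons, merged)
  if (nrow(summary$exclusions))
    say("excluded %d person(s) in %d area(s) with no admissions",
        nrow(summary$exclusions), length(unique(summary$exclusions$area_id)))

  hcov <- NULL
  if (length(hospitalCovariates)) {
    if (is.null(hospitals)) stop("hospital table required for hospital covariates")
    hcov <- lapply(hospitalCovariates, function(nm)
      stats::setNames(hospitals[[nm]], hospitals$hospital_id))
    names(hcov) <- hospitalCovariates
  }

  W <- personWeightMatrix(flows, persons)$W
  dataset <- buildMmDataset(persons, list(hospital = W), outcome = outcome,
                            offset = offset, fixed = fixed,
                            hospitalCovariates = hcov)
  say("fitting multiple-membership model: %d persons, %d hospitals",
      length(dataset@y), ncol(W))
  fit <- fitMmPoisson(dataset, priors, control)

  out <- list(flows = flows, partition = partition, summary = summary,
              dataset = dataset, fit = fit)
  if (fitHsa) {
    Whsa <- hsaMembershipMatrix(partition, persons)
    datasetHsa <- buildMmDataset(persons, list(hospital = Whsa),
                                 outcome = outcome, offset = offset,
                                 fixed = fixed, hospitalCovariates = hcov)
    say("fitting HSA-clustered model: %d HSAs", ncol(Whsa))
    fitH <- fitMmPoisson(datasetHsa, priors, control)
    out$datasetHsa <- datasetHsa
    out$fitHsa <- fitH
    out$report <- metricsReport(fit, dataset, fitH, datasetHsa)
  } else {
    out$report <- metricsReport(fit, dataset)
  }

  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeCatchments(flows, partition, summary, file.path(outDir, "catchments"))
    writeFit(fit, dataset, file.path(outDir, "fit_mm"))
    if (fitHsa) writeFit(out$fitHsa, out$datasetHsa, file.path(outDir, "fit_hsa"))
    writeReport(out$report, file.path(outDir, "report"))
    jsonlite::write_json(
      list(seed = control$seed, control = control[c("burnin", "samples", "thin")],
           fixed = fixed, outcome = outcome, offset = offset,
           hospitalCovariates = hospitalCovariates,
           package = as.character(utils::packageVersion("hsanet"))),
      file.path(outDir, "run.json"), auto_unbox = TRUE)
  }
  out
}

#' Write a metrics report to a directory
#'
#' Emits \code{metrics.json} (variance, MRR, DIC, comparison) and
#' \code{ranking.csv}, plus caterpillar / comparison plots.
#'
#' @param report list from [metricsReport()].
#' @param dir output directory.
#' @return \code{dir}, invisibly.
#' @export
writeReport <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  js <- list(variance = as.list(report$variance),
             mrr = as.list(report$mrr), dic = as.list(report$dic))
  if (!is.null(report$comparison)) {
    js$comparison <- list(
      variances = as.list(report$comparison$variances),
      pcv = report$comparison$pcv,
      spearman = report$comparison$rankings$spearman,
      onlyInFirst = report$comparison$rankings$onlyInFirst)
    if (!is.null(report$comparison$dicBaseline))
      js$comparison$dicBaseline <- as.list(report$comparison$dicBaseline)
  }
  jsonlite::write_json(js, file.path(dir, "metrics.json"),
                       auto_unbox = TRUE, digits = 8)
  utils::write.csv(report$ranking, file.path(dir, "ranking.csv"),
                   row.names = FALSE)
  refRank <- if (!is.null(report$comparison)) {
    tab <- report$comparison$rankings$table
    data.frame(hospital_id = tab$hospital_id, median = tab$median.ref,
               lower = tab$lower.ref, upper = tab$upper.ref)
  } else NULL
  caterpillarPlot(report$ranking, refRank, file.path(dir, "caterpillar.png"))
  invisible(dir)
}
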