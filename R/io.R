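#' Read and validate the input tables
#'
#' Reads the admissions / persons / hospitals CSVs (gzip accepted
#' transparently via R connections), checks the declared schemas, applies
#' defaults for empty optional columns, and verifies referential integrity:
#' every admission's person must exist in the person table, and when hospital
#' covariates are needed, every admitted-to hospital must exist in the
#' hospital table.
#'
#' @param admissionsFile CSV with columns person_id, area_id, hospital_id,
#'   optionally preventable (0/1) and episode_id.
#' @param personsFile CSV with person_id, area_id, followup_years and any
#'   covariate columns.
#' @param hospitalsFile optional CSV with hospital_id and attribute columns.
#' @param checkHospitals require every admitted-to hospital in the hospital
#'   table (default: only when \code{hospitalsFile} is given).
#' @return list of validated data.frames \code{admissions}, \code{persons},
#'   \code{hospitals} (NULL when not supplied).
#' @export
readTables <- function(admissionsFile, personsFile, hospitalsFile = NULL,
                       checkHospitals = !is.null(hospitalsFile)) {
  admissions <- utils::read.csv(admissionsFile, stringsAsFactors = FALSE,
                                colClasses = "character")
  .checkColumns(admissions, c("person_id", "area_id", "hospital_id"),
                basename(admissionsFile))
  if (!"preventable" %in% names(admissions)) {
    admissions$preventable <- 0L
    message("admissions: no 'preventable' column; defaulting to 0")
  }
  admissions$preventable <- as.integer(admissions$preventable)
  if (anyNA(admissions$preventable) ||
      !all(admissions$preventable %in% c(0L, 1L)))
    stop("admissions column 'preventable' must be 0/1")
  if (!"episode_id" %in% names(admissions)) admissions$episode_id <- NA_character_

  persons <- utils::read.csv(personsFile, stringsAsFactors = FALSE)
  .checkColumns(persons, c("person_id", "area_id", "followup_years"),
                basename(personsFile))
  persons$person_id <- as.character(persons$person_id)
  persons$area_id <- as.character(persons$area_id)
  if (anyDuplicated(persons$person_id))
    stop("persons: duplicated person_id: ",
         persons$person_id[anyDuplicated(persons$person_id)])
  unknownPerson <- setdiff(admissions$person_id, persons$person_id)
  if (length(unknownPerson))
    stop("admissions reference unknown person(s): ",
         paste(utils::head(unknownPerson, 5), collapse = ", "))

  hospitals <- NULL
  if (!is.null(hospitalsFile)) {
    hospitals <- utils::read.csv(hospitalsFile, stringsAsFactors = FALSE)
    .checkColumns(hospitals, "hospital_id", basename(hospitalsFile))
    hospitals$hospital_id <- as.character(hospitals$hospital_id)
  }
  if (checkHospitals) {
    if (is.null(hospitals)) stop("hospital table required for hospital checks")
    unknownHosp <- setdiff(admissions$hospital_id, hospitals$hospital_id)
    if (length(unknownHosp))
      stop("admissions reference unknown hospital(s): ",
           paste(utils::head(unknownHosp, 5), collapse = ", "))
  }
  list(admissions = admissions, persons = persons, hospitals = hospitals)
}

#' Write catchment artifacts to a directory
#'
#' Emits \code{weights.csv} (area_id, hospital_id, weight — nonzero flows in
#' long format), \code{hsa.csv} (area_id, hospital_id), \code{summary.json}
#' (the catchment descriptives) and \code{exclusions.csv}.
#'
#' @param flows an [AreaFlows-class].
#' @param partition an [HsaPartition-class].
#' @param summary a \code{CatchmentSummary} from [catchmentSummary()].
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeCatchments <- function(flows, partition, summary, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- methods::as(flowWeights(flows), "TsparseMatrix")
  long <- data.frame(area_id = rownames(w)[w@i + 1L],
                     hospital_id = colnames(w)[w@j + 1L],
                     weight = w@x, stringsAsFactors = FALSE)
  long <- long[order(long$area_id, long$hospital_id), ]
  utils::write.csv(long, file.path(dir, "weights.csv"), row.names = FALSE)
  utils::write.csv(data.frame(area_id = names(hsaAssignment(partition)),
                              hospital_id = unname(hsaAssignment(partition))),
                   file.path(dir, "hsa.csv"), row.names = FALSE)
  utils::write.csv(summary$exclusions, file.path(dir, "exclusions.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(summary = cbind(statistic = rownames(summary$summary),
                         summary$summary),
         hospitals = summary$hospitals),
    file.path(dir, "summary.json"), dataframe = "rows", digits = 8)
  invisible(dir)
}

#' Write a fitted model to a directory
#'
#' Emits \code{chains.csv.gz} (long format: iteration, parameter, value),
#' \code{fit_summary.json} (posterior means/quantiles, DIC, settings echo)
#' and \code{diagnostics.json}.
#'
#' @param fit an [MmFit-class].
#' @param data the matching [MmDataset-class] (for the DIC).
#' @param dir output directory.
#' @return \code{dir}, invisibly.
#' @export
writeFit <- function(fit, data, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  uCols <- do.call(cbind, lapply(names(fit@u), function(nm) {
    m <- fit@u[[nm]]
    colnames(m) <- paste0("u[", nm, ":", colnames(m), "]")
    m
  }))
  chains <- cbind(fit@beta, fit@sigma2, uCols, deviance = fit@deviance)
  colnames(chains) <- c(colnames(fit@beta),
                        paste0("sigma2[", colnames(fit@sigma2), "]"),
                        colnames(uCols), "deviance")
  long <- data.frame(iteration = rep(seq_len(nrow(chains)), ncol(chains)),
                     parameter = rep(colnames(chains), each = nrow(chains)),
                     value = as.numeric(chains))
  con <- gzfile(file.path(dir, "chains.csv.gz"), "w")
  utils::write.csv(long, con, row.names = FALSE)
  close(con)
  s2 <- fit@sigma2
  summ <- list(
    settings = fit@control[c("burnin", "samples", "thin", "seed")],
    beta = apply(fit@beta, 2L, function(x)
      c(mean = mean(x), q2.5 = unname(stats::quantile(x, .025)),
        q97.5 = unname(stats::quantile(x, .975)))),
    sigma2 = apply(s2, 2L, function(x) c(mean = mean(x), se = stats::sd(x))),
    mrr = lapply(seq_len(ncol(s2)), function(k) mrrInterval(s2[, k])),
    dic = as.list(dic(fit, data)))
  names(summ$mrr) <- colnames(s2)
  jsonlite::write_json(summ, file.path(dir, "fit_summary.json"),
                       auto_unbox = TRUE, digits = 8)
  diag <- mmDiagnostics(fit)
  jsonlite::write_json(list(parameters = diag$parameters,
                            acceptance = diag$acceptance,
                            warnings = diag$warnings),
                       file.path(dir, "diagnostics.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = 8)
  invisible(dir)
}

#' Write a synthetic system to CSV files
#'
#' Emits \code{admissions.csv}, \code{persons.csv}, \code{hospitals.csv} in
#' the schemas the catchment builder consumes, plus \code{truth.json} with
#' the generating parameters.
#'
#' @param system list from [generateSystem()].
#' @param dir output directory.
#' @return \code{dir}, invisibly.
#' @export
writeSystem <- function(system, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(system$admissions, file.path(dir, "admissions.csv"),
                   row.names = FALSE)
  utils::write.csv(system$persons, file.path(dir, "persons.csv"),
                   row.names = FALSE)
  utils::write.csv(system$hospitals, file.path(dir, "hospitals.csv"),
                   row.names = FALSE)
  tr <- system$truth
  jsonlite::write_json(
    list(u = as.list(tr$u), beta = as.list(tr$beta), beta0 = tr$beta0,
         sigma2U = tr$sigma2U, sigma2Sla = tr$sigma2Sla, v = as.list(tr$v),
         slaOfArea = as.list(tr$slaOfArea), seed = tr$seed),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = 10)
  invisible(dir)
}

#' Read a model specification from YAML
#'
#' The model file declares the outcome and offset columns, person-level fixed
#' effects, hospital covariates, classifications (each either
#' \code{weights: multiple-membership} for flow weights or
#' \code{weights: hsa} for the discrete partition, or a person grouping
#' column), priors and MCMC settings. Missing blocks fall back to package
#' defaults.
#'
#' @param file YAML path.
#' @return list with elements \code{outcome}, \code{offset}, \code{fixed},
#'   \code{hospitalCovariates}, \code{classifications}, \code{priors},
#'   \code{control}.
#' @export
readModelSpec <- function(file) {
  m <- yaml::read_yaml(file)
  list(outcome = m$outcome %||% "y_preventable",
       offset = m$offset %||% "followup_years",
       fixed = as.character(m$fixed %||% character()),
       hospitalCovariates = as.character(m$hospital_covariates %||% character()),
       classifications = m$classifications %||%
         list(hospital = list(weights = "multiple-membership")),
       priors = do.call(mmPriors, as.list(m$priors %||% list())),
       control = do.call(mcmcControl, as.list(m$mcmc %||% list())))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
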