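#' Collapse hospital transfers into single episodes of care
#'
#' Admission rows sharing a person and episode identifier (for example a
#' transfer between hospitals, or a change of care type within one stay) are
#' collapsed to a single record so that each episode of care is counted once.
#' The merged episode is attributed to the first hospital of the episode by
#' default (the facility where the admission decision was made), or to the
#' last with \code{attributeTo = "last"}. Rows without an episode identifier
#' are treated as singleton episodes.
#'
#' @param admissions data.frame with columns \code{person_id},
#'   \code{area_id}, \code{hospital_id}, optionally \code{preventable} and
#'   \code{episode_id}. Rows are assumed to be in admission order within an
#'   episode.
#' @param attributeTo "first" or "last": which hospital of a merged episode
#'   receives the admission.
#' @return data.frame with one row per (person, episode); columns as input.
#' @export
mergeEpisodes <- function(admissions, attributeTo = c("first", "last")) {
  attributeTo <- match.arg(attributeTo)
  .checkColumns(admissions, c("person_id", "area_id", "hospital_id"), "admissions")
  if (!"episode_id" %in% names(admissions) || all(is.na(admissions$episode_id)))
    return(admissions)
  ep <- as.character(admissions$episode_id)
  # singleton key for rows without an episode id
  blank <- is.na(ep) | ep == ""
  ep[blank] <- paste0(".row", seq_len(nrow(admissions))[blank])
  key <- paste(admissions$person_id, ep, sep = "\r")
  pick <- if (attributeTo == "first") !duplicated(key) else !duplicated(key, fromLast = TRUE)
  out <- admissions[pick, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Compute area-level patient-flow weights
#'
#' For every residence area appearing in the admission records, computes the
#' proportional distribution of its admissions over hospitals: the weighted
#' hospital service area network. Areas with no admissions simply do not
#' appear (downstream, persons living in such areas are excluded with a
#' report, as the source cohort excluded 174 participants in 19 areas).
#'
#' @param admissions data.frame of (episode-merged) admissions with columns
#'   \code{area_id} and \code{hospital_id}. All rows are used: weights are
#'   built from all-cause admissions, independent of the preventable flag.
#' @return an [AreaFlows-class] object. Rows (areas) and columns (hospitals)
#'   are sorted lexicographically, so the result does not depend on the
#'   ordering of the input rows.
#' @export
computeAreaWeights <- function(admissions) {
  .checkColumns(admissions, c("area_id", "hospital_id"), "admissions")
  if (nrow(admissions) == 0L) stop("no admissions")
  a <- factor(as.character(admissions$area_id))
  h <- factor(as.character(admissions$hospital_id))
  counts <- Matrix::sparseMatrix(
    i = as.integer(a), j = as.integer(h), x = 1,
    dims = c(nlevels(a), nlevels(h)),
    dimnames = list(levels(a), levels(h)))
  weights <- Matrix::Diagonal(x = 1 / Matrix::rowSums(counts)) %*% counts
  dimnames(weights) <- dimnames(counts)
  methods::new("AreaFlows",
               weights = methods::as(weights, "CsparseMatrix"),
               counts = methods::as(counts, "CsparseMatrix"))
}

#' Assign each area to a discrete hospital service area
#'
#' Implements the plurality rule: every area is allocated to the hospital
#' receiving the largest share of its admissions. Exact ties are broken by
#' the lexicographically smallest hospital id, so the partition is
#' deterministic and invariant to input ordering. Hospitals that never win a
#' plurality keep an empty HSA.
#'
#' @param flows an [AreaFlows-class] object.
#' @return an [HsaPartition-class].
#' @export
assignHsa <- function(flows) {
  stopifnot(methods::is(flows, "AreaFlows"))
  w <- flows@weights[, order(colnames(flows@weights)), drop = FALSE]
  dense <- as.matrix(w)
  pick <- max.col(dense, ties.method = "first") # first = smallest id after sort
  assignment <- stats::setNames(colnames(dense)[pick], rownames(dense))
  assignment <- assignment[order(names(assignment))]
  methods::new("HsaPartition", assignment = assignment,
               hospitals = sort(colnames(dense)))
}

#' Market share index per hospital
#'
#' The proportion of a hospital's admissions that originate from areas inside
#' its own service area. A hospital with an empty HSA receives 0; a hospital
#' admitting only residents of its HSA receives 1.
#'
#' @param partition an [HsaPartition-class].
#' @param admissions admissions data.frame (\code{area_id},
#'   \code{hospital_id}); every area present must be covered by the partition.
#' @return named numeric vector over all hospitals in the partition.
#' @export
marketShareIndex <- function(partition, admissions) {
  stopifnot(methods::is(partition, "HsaPartition"))
  .checkColumns(admissions, c("area_id", "hospital_id"), "admissions")
  area <- as.character(admissions$area_id)
  hosp <- as.character(admissions$hospital_id)
  unknown <- setdiff(unique(area), names(partition@assignment))
  if (length(unknown))
    stop("areas not covered by the partition: ", paste(unknown, collapse = ", "))
  internal <- partition@assignment[area] == hosp
  tot <- table(factor(hosp, levels = partition@hospitals))
  int <- table(factor(hosp[internal], levels = partition@hospitals))
  msi <- ifelse(tot > 0, as.numeric(int) / as.numeric(tot), 0)
  names(msi) <- partition@hospitals
  msi[emptyHsas(partition)] <- 0
  msi
}

#' Person-level multiple-membership weight matrix
#'
#' Expands area flow weights to persons: each person's weight row is the flow
#' profile of their residence area. Persons whose area has no flow profile
#' (no admissions from that area) cannot be weighted and are returned in an
#' exclusions report rather than silently dropped.
#'
#' @param flows an [AreaFlows-class].
#' @param persons data.frame with columns \code{person_id} and \code{area_id}.
#' @return list with \code{W} (sparse person x hospital matrix, rows named by
#'   person id, every row summing to 1) and \code{exclusions} (data.frame of
#'   excluded persons with their area and a reason).
#' @export
personWeightMatrix <- function(flows, persons) {
  stopifnot(methods::is(flows, "AreaFlows"))
  .checkColumns(persons, c("person_id", "area_id"), "persons")
  area <- as.character(persons$area_id)
  known <- area %in% rownames(flows@weights)
  exclusions <- data.frame(
    person_id = as.character(persons$person_id[!known]),
    area_id = area[!known],
    reason = if (any(!known)) "area has no admissions" else character(),
    stringsAsFactors = FALSE)
  W <- flows@weights[area[known], , drop = FALSE]
  rownames(W) <- as.character(persons$person_id[known])
  list(W = W, exclusions = exclusions)
}

#' Weighted hospital-level covariate
#'
#' Computes, for each person, the weighted average of a hospital attribute
#' over the person's hospital network (for example mean bed occupancy across
#' all hospitals the person's area uses, weighted by flow share).
#'
#' @param W sparse person x hospital weight matrix (rows sum to 1).
#' @param covariate named numeric vector of hospital attribute values.
#' @return numeric vector, one weighted average per row of \code{W}.
#' @export
weightedHospitalCovariate <- function(W, covariate) {
  used <- colnames(W)[Matrix::colSums(W != 0) > 0]
  missing <- used[!(used %in% names(covariate)) | is.na(covariate[used])]
  if (length(missing))
    stop("covariate missing for hospital(s): ", paste(missing, collapse = ", "))
  x <- covariate[colnames(W)]
  x[is.na(x)] <- 0 # unweighted hospitals only
  as.numeric(W %*% x)
}

#' Descriptive summary of the weighting structure
#'
#' Computes the catchment descriptives used to characterise a weighted-HSAN
#' system: per-area participant/admission/hospital counts and top-1/2/3
#' hospital shares; per-hospital weighted catchment size, areas serviced,
#' areas contributing above 5/10/20/50 percent, and market share index; and
#' per-person network size and top shares. Each block is summarised by mean,
#' interquartile range and min-max.
#'
#' @param flows an [AreaFlows-class].
#' @param partition an [HsaPartition-class] for the same system.
#' @param persons persons data.frame (\code{person_id}, \code{area_id}).
#' @param admissions the admissions the flows were built from.
#' @return object of class \code{CatchmentSummary}: a list with data.frames
#'   \code{areas}, \code{hospitals}, \code{persons} and a \code{summary}
#'   table of (mean, q25, q75, min, max) per statistic.
#' @export
catchmentSummary <- function(flows, partition, persons, admissions) {
  w <- as.matrix(flows@weights)
  counts <- as.matrix(flows@counts)
  topShares <- function(m) {
    t(apply(m, 1L, function(r) {
      s <- sort(r, decreasing = TRUE)
      c(s, 0, 0, 0)[1:3]
    }))
  }
  pw <- personWeightMatrix(flows, persons)
  nPersons <- table(factor(as.character(persons$area_id), levels = rownames(w)))

  ts <- topShares(w)
  areas <- data.frame(
    area_id = rownames(w),
    participants = as.integer(nPersons),
    admissions = as.integer(rowSums(counts)),
    hospitals = as.integer(rowSums(counts > 0)),
    share1 = 100 * ts[, 1], share2 = 100 * ts[, 2], share3 = 100 * ts[, 3],
    row.names = NULL, stringsAsFactors = FALSE)

  thr <- c(0.05, 0.10, 0.20, 0.50)
  thrCounts <- do.call(cbind, lapply(thr, function(t) as.integer(colSums(w > t))))
  colnames(thrCounts) <- paste0("areasOver", c(5, 10, 20, 50))
  msi <- marketShareIndex(partition, admissions)
  hospitals <- data.frame(
    hospital_id = colnames(w),
    weightedCatchment = as.numeric(Matrix::colSums(pw$W)),
    areasServiced = as.integer(colSums(w > 0)),
    thrCounts,
    marketShare = 100 * msi[colnames(w)],
    row.names = NULL, stringsAsFactors = FALSE)

  wp <- as.matrix(pw$W)
  tsp <- topShares(wp)
  personsDf <- data.frame(
    person_id = rownames(wp),
    hospitals = as.integer(rowSums(wp > 0)),
    share1 = 100 * tsp[, 1], share2 = 100 * tsp[, 2], share3 = 100 * tsp[, 3],
    row.names = NULL, stringsAsFactors = FALSE)

  stat <- function(x) c(mean = mean(x), q25 = unname(stats::quantile(x, .25)),
                        q75 = unname(stats::quantile(x, .75)),
                        min = min(x), max = max(x))
  summary <- rbind(
    area_participants = stat(areas$participants),
    area_admissions = stat(areas$admissions),
    area_hospitals = stat(areas$hospitals),
    area_share1 = stat(areas$share1),
    area_share2 = stat(areas$share2),
    area_share3 = stat(areas$share3),
    hsa_catchment = stat(hospitals$weightedCatchment[hospitals$weightedCatchment > 0]),
    hosp_weighted_catchment = stat(hospitals$weightedCatchment),
    hosp_areas_serviced = stat(hospitals$areasServiced),
    hosp_market_share = stat(hospitals$marketShare),
    person_hospitals = stat(personsDf$hospitals),
    person_share1 = stat(personsDf$share1),
    person_share2 = stat(personsDf$share2),
    person_share3 = stat(personsDf$share3))

  structure(list(areas = areas, hospitals = hospitals, persons = personsDf,
                 exclusions = pw$exclusions, summary = as.data.frame(summary)),
            class = "CatchmentSummary")
}

#' @export
print.CatchmentSummary <- function(x, ...) {
  cat(sprintf("CatchmentSummary: %d areas, %d hospitals, %d persons (%d excluded)\n",
              nrow(x$areas), nrow(x$hospitals), nrow(x$persons), nrow(x$exclusions)))
  print(round(x$summary, 1))
  invisible(x)
}

#' Single-membership matrix from an HSA partition
#'
#' Builds the person x hospital indicator matrix that clusters every person
#' wholly in the plurality hospital of their area: the classical HSA
#' counterpart of the weighted network. Columns cover only hospitals with a
#' non-empty HSA.
#'
#' @param partition an [HsaPartition-class].
#' @param persons persons data.frame (\code{person_id}, \code{area_id}).
#' @return sparse person x hospital 0/1 matrix (rows sum to 1). Persons in
#'   areas not covered by the partition are dropped (consistent with
#'   [personWeightMatrix()] exclusions).
#' @export
hsaMembershipMatrix <- function(partition, persons) {
  stopifnot(methods::is(partition, "HsaPartition"))
  .checkColumns(persons, c("person_id", "area_id"), "persons")
  area <- as.character(persons$area_id)
  keep <- area %in% names(partition@assignment)
  hosp <- partition@assignment[area[keep]]
  hlev <- sort(unique(partition@assignment))
  Matrix::sparseMatrix(
    i = seq_len(sum(keep)), j = match(hosp, hlev), x = 1,
    dims = c(sum(keep), length(hlev)),
    dimnames = list(as.character(persons$person_id[keep]), hlev))
}

.checkColumns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(missing, collapse = ", ")))
  invisible(TRUE)
}
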