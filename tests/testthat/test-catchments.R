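test_that("episode merging attributes transfers to the first (or last) hospital", {
  adm <- data.frame(
    person_id = c("p1", "p1", "p2", "p2", "p3"),
    area_id = "A",
    hospital_id = c("H1", "H2", "H3", "H3", "H2"),
    episode_id = c("e1", "e1", "e2", "e2", "e3"),
    stringsAsFactors = FALSE)
  first <- mergeEpisodes(adm)
  expect_equal(nrow(first), 3L) # two episodes of 2 rows plus a singleton
  expect_equal(first$hospital_id[first$person_id == "p1"], "H1")
  last <- mergeEpisodes(adm, attributeTo = "last")
  expect_equal(last$hospital_id[last$person_id == "p1"], "H2")

  # distinct episode ids and absent episode column are identity cases
  adm2 <- adm; adm2$episode_id <- paste0("e", 1:5)
  expect_equal(nrow(mergeEpisodes(adm2)), 5L)
  expect_identical(mergeEpisodes(adm[, 1:3]), adm[, 1:3])

  # rows lacking an episode id stay singletons even next to merged ones
  adm3 <- adm; adm3$episode_id[3:4] <- NA
  expect_equal(nrow(mergeEpisodes(adm3)), 4L)

  expect_error(mergeEpisodes(adm[, c("person_id", "area_id")]), "hospital_id")
})

test_that("area weights are proportional admission counts and sum to one", {
  flows <- computeAreaWeights(toyAdmissions())
  w <- as.matrix(flowWeights(flows))
  expect_equal(w["A", ], c(H1 = 0.75, H2 = 0.25, H3 = 0))
  expect_equal(w["B", ], c(H1 = 1, H2 = 0, H3 = 0))
  expect_equal(w["C", ], c(H1 = 0.25, H2 = 0.5, H3 = 0.25))
  expect_true(all(abs(Matrix::rowSums(flowWeights(flows)) - 1) < 1e-9))
  expect_error(computeAreaWeights(toyAdmissions()[0, ]), "no admissions")
  # 3/2/1 example
  adm <- data.frame(person_id = "p", area_id = "Z",
                    hospital_id = rep(c("H1", "H2", "H3"), c(3, 2, 1)))
  wz <- as.matrix(flowWeights(computeAreaWeights(adm)))
  expect_equal(unname(wz[1, ]), c(3, 2, 1) / 6, tolerance = 1e-12)
})

test_that("plurality assignment uses argmax with lexicographic tie-break", {
  part <- assignHsa(computeAreaWeights(toyAdmissions()))
  expect_equal(hsaAssignment(part), c(A = "H1", B = "H1", C = "H2"))
  expect_equal(emptyHsas(part), "H3")

  # 5-area toy system: H3 never achieves plurality, tie in A5 goes to H1
  part5 <- assignHsa(computeAreaWeights(toyFiveAreaAdmissions()))
  expect_equal(hsaAssignment(part5),
               c(A1 = "H1", A2 = "H1", A3 = "H2", A4 = "H2", A5 = "H1"))
  expect_equal(emptyHsas(part5), "H3")
  expect_equal(sum(lengths(hsaMembers(part5)) > 0), 2L)
})

test_that("HSA assignment is invariant to admission row order", {
  adm <- toyFiveAreaAdmissions()
  base <- hsaAssignment(assignHsa(computeAreaWeights(adm)))
  for (s in 1:5) {
    set.seed(s)
    perm <- adm[sample(nrow(adm)), ]
    expect_identical(hsaAssignment(assignHsa(computeAreaWeights(perm))), base)
  }
})

test_that("market share index is the within-catchment admission fraction", {
  adm <- toyAdmissions()
  part <- assignHsa(computeAreaWeights(adm))
  msi <- marketShareIndex(part, adm)
  # H1 admissions: A 3, B 2, C 1; HSA(H1) = {A, B} -> 5/6
  expect_equal(msi[["H1"]], 5 / 6)
  # H2 admissions: A 1, C 2; HSA(H2) = {C} -> 2/3
  expect_equal(msi[["H2"]], 2 / 3)
  expect_equal(msi[["H3"]], 0) # empty HSA
  expect_true(all(msi >= 0 & msi <= 1))

  # all admissions internal -> 1
  adm1 <- data.frame(person_id = "p", area_id = "A", hospital_id = "H1")
  p1 <- assignHsa(computeAreaWeights(adm1))
  expect_equal(unname(marketShareIndex(p1, adm1)), 1)
})

test_that("person weight rows inherit the area profile and report exclusions", {
  flows <- computeAreaWeights(toyAdmissions())
  persons <- rbind(toyPersons(),
                   data.frame(person_id = "p7", area_id = "D",
                              followup_years = 3, y_preventable = 0L))
  pw <- personWeightMatrix(flows, persons)
  expect_equal(nrow(pw$W), 6L)
  expect_equal(unname(as.matrix(pw$W)["p1", ]), c(0.75, 0.25, 0))
  expect_equal(as.matrix(pw$W)["p1", ], as.matrix(pw$W)["p2", ]) # same area
  expect_true(all(abs(Matrix::rowSums(pw$W) - 1) < 1e-9))
  expect_equal(pw$exclusions$person_id, "p7")
  expect_match(pw$exclusions$reason, "no admissions")

  # column sums are weighted catchment sizes; hand-checked and total-preserving
  cs <- Matrix::colSums(pw$W)
  expect_equal(unname(cs), c(0.75 * 2 + 1 + 0.25 * 3, 0.25 * 2 + 0.5 * 3, 0.25 * 3))
  expect_equal(sum(cs), 6)
})

test_that("weighted hospital covariates are weight-row averages", {
  W <- Matrix::Matrix(rbind(c(0.6, 0.4), c(1, 0), c(0.25, 0.75)), sparse = TRUE)
  colnames(W) <- c("H1", "H2")
  occ <- c(H1 = 90, H2 = 100)
  expect_equal(weightedHospitalCovariate(W, occ), c(94, 90, 97.5))
  # uniform weights give the arithmetic mean
  W4 <- Matrix::Matrix(matrix(0.25, 1, 4,
                              dimnames = list(NULL, paste0("H", 1:4))), sparse = TRUE)
  x4 <- c(H1 = 1, H2 = 2, H3 = 3, H4 = 10)
  expect_equal(weightedHospitalCovariate(W4, x4), mean(x4))
  expect_error(weightedHospitalCovariate(W, c(H1 = 90)), "H2")
})

test_that("catchment summary reproduces hand-computed toy statistics", {
  adm <- toyAdmissions()
  flows <- computeAreaWeights(adm)
  part <- assignHsa(flows)
  cs <- catchmentSummary(flows, part, toyPersons(), adm)
  a <- cs$areas[cs$areas$area_id == "A", ]
  expect_equal(a$participants, 2L)
  expect_equal(a$admissions, 4L)
  expect_equal(a$hospitals, 2L)
  expect_equal(c(a$share1, a$share2, a$share3), c(75, 25, 0))
  expect_true(all(cs$areas$share1 + cs$areas$share2 + cs$areas$share3 <= 100 + 1e-9))
  # weighted catchments sum to the person count
  expect_equal(sum(cs$hospitals$weightedCatchment), nrow(toyPersons()),
               tolerance = 1e-6)
  # single area, single hospital: top share 100, all thresholds 1
  adm1 <- data.frame(person_id = "p", area_id = "A", hospital_id = "H1")
  per1 <- data.frame(person_id = "p", area_id = "A", followup_years = 1,
                     y_preventable = 0L)
  cs1 <- catchmentSummary(computeAreaWeights(adm1),
                          assignHsa(computeAreaWeights(adm1)), per1, adm1)
  expect_equal(cs1$areas$share1, 100)
  expect_equal(unname(unlist(
    cs1$hospitals[, c("areasOver5", "areasOver10", "areasOver20", "areasOver50")])),
    rep(1L, 4))
})

test_that("single-hospital areas make weighted catchments equal HSA populations", {
  adm <- toyAdmissions()
  adm$hospital_id <- c("H1", "H1", "H1", "H1", "H1", "H1", "H2", "H2", "H2", "H2")
  flows <- computeAreaWeights(adm)
  part <- assignHsa(flows)
  persons <- toyPersons()
  pw <- personWeightMatrix(flows, persons)
  hsaPop <- table(hsaAssignment(part)[persons$area_id])
  cs <- Matrix::colSums(pw$W)
  expect_equal(as.numeric(cs[names(hsaPop)]), as.numeric(hsaPop))
})
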