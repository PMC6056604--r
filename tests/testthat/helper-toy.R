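# Small hand-checkable flow systems used across tests.

# One row per admission.
toyAdmissions <- function() {
  data.frame(
    person_id = c("p1", "p1", "p1", "p2", "p3", "p3", "p4", "p5", "p5", "p6"),
    area_id   = c("A",  "A",  "A",  "A",  "B",  "B",  "C",  "C",  "C",  "C"),
    hospital_id = c("H1", "H1", "H1", "H2", "H1", "H1", "H1", "H2", "H2", "H3"),
    preventable = c(0L, 1L, 0L, 0L, 0L, 0L, 1L, 0L, 0L, 0L),
    stringsAsFactors = FALSE)
  # area A: H1 3, H2 1 -> (.75, .25); area B: H1 2 -> (1);
  # area C: H1 1, H2 2, H3 1 -> (.25, .5, .25)
}

toyPersons <- function() {
  data.frame(
    person_id = paste0("p", 1:6),
    area_id = c("A", "A", "B", "C", "C", "C"),
    followup_years = c(2, 4, 3, 1, 5, 2),
    y_preventable = c(1L, 0L, 0L, 1L, 0L, 0L),
    stringsAsFactors = FALSE)
}

# 5 areas x 3 hospitals where H3 never wins a plurality
toyFiveAreaAdmissions <- function() {
  counts <- rbind(
    A1 = c(H1 = 3, H2 = 1, H3 = 1),
    A2 = c(H1 = 2, H2 = 1, H3 = 1),
    A3 = c(H1 = 0, H2 = 3, H3 = 2),
    A4 = c(H1 = 1, H2 = 4, H3 = 0),
    A5 = c(H1 = 2, H2 = 2, H3 = 1)) # tie H1/H2 -> H1 by id order
  long <- do.call(rbind, lapply(rownames(counts), function(a)
    do.call(rbind, lapply(colnames(counts), function(h) {
      k <- counts[a, h]
      if (k == 0) return(NULL)
      data.frame(person_id = paste0(a, "x", h, seq_len(k)), area_id = a,
                 hospital_id = h, preventable = 0L, stringsAsFactors = FALSE)
    }))))
  rownames(long) <- NULL
  long
}

# deterministic small fitted dataset for sampler tests
smallMmData <- function(n = 400, J = 6, seed = 99, sigma = 0.4) {
  set.seed(seed)
  g <- sample(seq_len(J), n, replace = TRUE)
  u <- rnorm(J, 0, sigma)
  x <- rnorm(n)
  t <- runif(n, 1, 5)
  y <- rpois(n, t * exp(-1.5 + 0.3 * x + u[g]))
  W <- Matrix::sparseMatrix(i = seq_len(n), j = g, x = 1,
                            dims = c(n, J),
                            dimnames = list(sprintf("p%04d", seq_len(n)),
                                            sprintf("H%02d", seq_len(J))))
  persons <- data.frame(person_id = sprintf("p%04d", seq_len(n)),
                        y = y, t = t, x = x, stringsAsFactors = FALSE)
  list(persons = persons, W = W, g = g, u = u,
       dataset = buildMmDataset(persons, list(hospital = W), outcome = "y",
                                offset = "t", fixed = "x"))
}
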