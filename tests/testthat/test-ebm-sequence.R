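# fixed-density mixtures make every likelihood hand-computable
two_event_fixture <- function() {
  # subject value x = 1 for biomarker b1, x = 2 for b2; densities chosen
  # so that: a = p(x1|notE) = 0.6, A = p(x1|E) = 0.2,
  #          b = p(x2|notE) = 0.5, B = p(x2|E) = 0.9
  f1 <- constant_mixture(function(x) rep(0.6, length(x)),
                         function(x) rep(0.2, length(x)))
  f2 <- constant_mixture(function(x) rep(0.5, length(x)),
                         function(x) rep(0.9, length(x)))
  list(X = matrix(c(1, 2), 1, 2, dimnames = list("s1", c("b1", "b2"))),
       fits = list(b1 = f1, b2 = f2))
}

test_that("sequence likelihood equals hand arithmetic on a 2-event case", {
  fx <- two_event_fixture()
  # S = (b1, b2): stages contribute a*b (k=0), A*b (k=1), A*B (k=2)
  hand <- log((0.6 * 0.5 + 0.2 * 0.5 + 0.2 * 0.9) / 3)
  expect_equal(sequence_log_likelihood(fx$X, c("b1", "b2"), fx$fits), hand,
               tolerance = 1e-10)
  # S = (b2, b1): a*b, a*B, A*B
  hand2 <- log((0.6 * 0.5 + 0.6 * 0.9 + 0.2 * 0.9) / 3)
  expect_equal(sequence_log_likelihood(fx$X, c("b2", "b1"), fx$fits), hand2,
               tolerance = 1e-10)
})

test_that("likelihood is invariant to joint relabelling and marginalises missing", {
  fx <- two_event_fixture()
  # relabel: swap the columns of X and the fit list together with S
  Xsw <- fx$X[, c("b2", "b1"), drop = FALSE]
  expect_equal(sequence_log_likelihood(fx$X, c("b1", "b2"), fx$fits),
               sequence_log_likelihood(Xsw, c("b1", "b2"), fx$fits))

  # all-missing subject contributes factor 1
  X2 <- rbind(fx$X, matrix(NA_real_, 1, 2,
                           dimnames = list("s2", c("b1", "b2"))))
  expect_equal(sequence_log_likelihood(X2, c("b1", "b2"), fx$fits),
               sequence_log_likelihood(fx$X, c("b1", "b2"), fx$fits))
  expect_error(sequence_log_likelihood(fx$X, c("b1", "b1"), fx$fits),
               "permutation")
})

make_staged_data <- function(n_subj = 120, n_bm = 5, seed = 1,
                             truth = paste0("bm", seq_len(n_bm))) {
  # subjects drawn at known stages under the generating order `truth`:
  # abnormal values ~ N(-4, 1), normal ~ N(0, 1)
  set.seed(seed)
  stage <- sample(0:n_bm, n_subj, replace = TRUE)
  X <- matrix(rnorm(n_subj * n_bm), n_subj, n_bm,
              dimnames = list(sprintf("s%03d", 1:n_subj), truth))
  for (j in seq_len(n_subj)) {
    if (stage[j] > 0) {
      X[j, truth[seq_len(stage[j])]] <-
        rnorm(stage[j], -4, 1)
    }
  }
  fits <- setNames(lapply(seq_len(n_bm), function(i) {
    constant_mixture(function(x) dnorm(x, 0, 1),
                     function(x) dnorm(x, -4, 1))
  }), truth)
  list(X = X, fits = fits, truth = truth, stage = stage)
}

test_that("greedy search matches the exhaustive argmax on 5 events", {
  d <- make_staged_data(seed = 2)
  ml_greedy <- find_ml_sequence(d$X, d$fits, n_starts = 8, seed = 1)
  ml_exh <- find_ml_sequence(d$X, d$fits, method = "exhaustive")
  expect_equal(ml_greedy$log_likelihood, ml_exh$log_likelihood,
               tolerance = 1e-10)
  expect_equal(ml_exh$sequence, d$truth)

  # single-biomarker degenerate case
  one <- make_staged_data(n_subj = 30, n_bm = 1, seed = 3, truth = "only")
  expect_equal(find_ml_sequence(one$X, one$fits)$sequence, "only")
})

test_that("strongly staged data recover the generating order", {
  d <- make_staged_data(n_subj = 200, seed = 4)
  ml <- find_ml_sequence(d$X, d$fits, n_starts = 8, seed = 2)
  expect_equal(ml$sequence, d$truth)
})

test_that("MCMC is seeded, permutation-valid, and centres on the ML sequence", {
  d <- make_staged_data(seed = 5)
  ml <- find_ml_sequence(d$X, d$fits, n_starts = 5, seed = 1)
  ch1 <- mcmc_sample(d$X, d$fits, ml, n_iter = 600, seed = 7)
  ch2 <- mcmc_sample(d$X, d$fits, ml, n_iter = 600, seed = 7)
  expect_identical(ch1$samples, ch2$samples)
  expect_true(all(apply(ch1$samples, 1, function(r) setequal(r, 1:5))))

  # modal sampled sequence equals the ML sequence on well-separated data
  key <- apply(ch1$samples, 1, paste, collapse = "-")
  modal <- names(sort(table(key), decreasing = TRUE))[1]
  expect_equal(modal, paste(match(ml$sequence, ch1$biomarkers),
                            collapse = "-"))
  expect_error(mcmc_sample(d$X, d$fits, ml, n_iter = 0), "n_iter")
})

test_that("thinning keeps every factor-th sample", {
  d <- make_staged_data(n_subj = 40, n_bm = 3, seed = 6,
                        truth = c("a", "b", "c"))
  ml <- find_ml_sequence(d$X, d$fits, n_starts = 3, seed = 1)
  ch <- mcmc_sample(d$X, d$fits, ml, n_iter = 10000, seed = 1)
  th <- thin_chain(ch, 100)
  expect_equal(nrow(th$samples), 100)
  expect_equal(th$samples[2, ], ch$samples[101, ])
  expect_equal(th$thinning, 100L)
  # factor 1 leaves the chain unchanged; short chains keep one sample
  expect_equal(thin_chain(ch, 1)$samples, ch$samples)
  short <- ch; short$samples <- ch$samples[1:50, ]; short$log_lik <- ch$log_lik[1:50]
  expect_equal(nrow(thin_chain(short, 100)$samples), 1)
})

test_that("positional variance counts sequence frequencies", {
  seqs <- list(c("a", "b", "c"), c("a", "c", "b"), c("a", "b", "c"))
  pv <- positional_variance(seqs)
  expect_equal(unname(pv["a", ]), c(1, 0, 0))
  expect_equal(unname(pv["b", ]), c(0, 2 / 3, 1 / 3))
  expect_equal(unname(pv["c", ]), c(0, 1 / 3, 2 / 3))
  expect_equal(unname(rowSums(pv)), rep(1, 3), tolerance = 1e-9)
  expect_equal(unname(colSums(pv)), rep(1, 3), tolerance = 1e-9)

  # a degenerate chain yields a permutation matrix
  pv2 <- positional_variance(list(c("b", "a"), c("b", "a")))
  expect_equal(unclass(pv2)[c("a", "b"), ], diag(2)[2:1, ],
               ignore_attr = TRUE)
  expect_error(positional_variance(list(c("a", "b"), c("a", "c"))),
               "inconsistent")
})

test_that("position samples invert the sampled sequences", {
  d <- make_staged_data(n_subj = 40, n_bm = 3, seed = 7,
                        truth = c("a", "b", "c"))
  ml <- find_ml_sequence(d$X, d$fits, n_starts = 3, seed = 1)
  ch <- thin_chain(mcmc_sample(d$X, d$fits, ml, n_iter = 300, seed = 2), 10)
  ps <- position_samples(ch)
  # cross-check one sample by hand
  s1 <- ch$samples[1, ]
  for (i in seq_along(ch$biomarkers)) {
    expect_equal(ps$position[ps$sample == 1 &
                               ps$biomarker == ch$biomarkers[i]],
                 which(s1 == i))
  }
})

test_that("bootstrap sequences are reproducible and recover strong effects", {
  d <- make_staged_data(n_subj = 150, seed = 8)
  tbl <- tibble::as_tibble(d$X) |>
    dplyr::mutate(subject_id = rownames(d$X),
                  group = ifelse(d$stage == 0, "control", "patient"))
  b1 <- suppressWarnings(
    bootstrap_sequences(tbl, d$truth, n_boot = 10, seed = 3, n_starts = 3))
  b2 <- suppressWarnings(
    bootstrap_sequences(tbl, d$truth, n_boot = 10, seed = 3, n_starts = 3))
  expect_equal(lapply(b1, `[[`, "sequence"), lapply(b2, `[[`, "sequence"))
  first_events <- vapply(b1, function(s) s$sequence[1], "")
  expect_gte(mean(first_events == d$truth[1]), 0.9)
})

test_that("EBM staging matches hand-computed posteriors and boundary cases", {
  fx <- two_event_fixture()
  st <- stage_subjects_ebm(fx$X, c("b1", "b2"), fx$fits)
  hand <- c(0.6 * 0.5, 0.2 * 0.5, 0.2 * 0.9)
  expect_equal(st$posterior[[1]], hand / sum(hand), tolerance = 1e-10)
  expect_equal(st$stage, which.max(hand) - 1L)

  d <- make_staged_data(seed = 9)
  st2 <- stage_subjects_ebm(d$X, d$truth, d$fits)
  sums <- vapply(st2$posterior, sum, 0)
  expect_true(all(abs(sums - 1) < 1e-9))
  # clearly healthy and clearly end-stage subjects
  Xext <- matrix(c(0, 0, -4, -4, -4, 0, 0, 0, 0, 0), 2, 5, byrow = TRUE,
                 dimnames = list(c("healthy", "sick"), d$truth))
  Xext["sick", ] <- -4
  Xext["healthy", ] <- 0
  st3 <- stage_subjects_ebm(Xext, d$truth, d$fits)
  expect_equal(st3$stage[st3$subject_id == "healthy"], 0L)
  expect_equal(st3$stage[st3$subject_id == "sick"], 5L)

  # staging is invariant to joint relabelling of biomarkers and sequence
  perm <- c(3, 1, 2, 5, 4)
  st4 <- stage_subjects_ebm(d$X[, perm], d$truth, d$fits)
  expect_equal(st4$stage, st2$stage)
})
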