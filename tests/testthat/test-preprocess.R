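make_cov_table <- function(n = 200, beta_tiv = 0, site_offset = 0, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    subject_id = sprintf("S%03d", 1:n),
    group = "control",
    visit_index = 1L,
    age = rnorm(n, 70, 8),
    gender = sample(c("female", "male"), n, replace = TRUE),
    tiv = rnorm(n, 1450, 130),
    scanner = sample(c("1.5T", "3T"), n, replace = TRUE),
    site = sample(c("DRC", "UCSF", "HUVR"), n, replace = TRUE),
    vol = rnorm(n, 100, 5) + beta_tiv * (tiv - 1450) +
      site_offset * (site == "DRC") - site_offset * (site == "HUVR"))
}

covs <- c("age", "gender", "tiv", "scanner", "site")

test_that("adjustment leaves covariate-free data essentially unchanged", {
  tbl <- make_cov_table(n = 400, seed = 2)
  adj <- adjust_covariates(tbl, "vol", covs)
  # with true coefficients of zero, fitted contributions are sampling noise
  expect_lt(max(abs(adj$vol - tbl$vol)), 2)
  expect_lt(mean(abs(adj$vol - tbl$vol)), 0.5)
})

test_that("an injected TIV effect is removed", {
  tbl <- make_cov_table(n = 300, beta_tiv = 0.5, seed = 3)
  adj <- adjust_covariates(tbl, "vol", covs)
  expect_lt(abs(cor(adj$vol, tbl$tiv)), 0.05)
  # oracle: direct least-squares residuals (plus intercept) agree
  X <- model.matrix(~ age + gender + tiv + scanner + site, tbl)
  beta <- qr.coef(qr(X), tbl$vol)
  contrib <- X[, -1] %*% beta[-1]
  oracle <- tbl$vol - (contrib - mean(contrib))
  expect_equal(adj$vol, as.numeric(oracle), tolerance = 1e-8)
})

test_that("pure additive site offsets are equalised", {
  tbl <- make_cov_table(n = 600, site_offset = 7, seed = 4)
  adj <- adjust_covariates(tbl, "vol", covs)
  ms <- tapply(adj$vol, adj$site, mean)
  expect_lt(max(ms) - min(ms), 1.5)
})

test_that("adjustment is idempotent", {
  tbl <- make_cov_table(n = 200, beta_tiv = 0.3, seed = 5)
  a1 <- adjust_covariates(tbl, "vol", covs)
  a2 <- adjust_covariates(a1, "vol", covs)
  expect_lt(max(abs(a2$vol - a1$vol)), 1e-8)
})

test_that("rank-deficient designs fail naming the collinear columns", {
  tbl <- make_cov_table(n = 100, seed = 6)
  tbl$tiv2 <- tbl$tiv * 2
  expect_error(adjust_covariates(tbl, "vol", c(covs, "tiv2")),
               "collinear.*tiv2")
})

test_that("categories unseen in the reference sample are an error", {
  tbl <- make_cov_table(n = 100, seed = 7)
  tbl$group[1:50] <- "patient"
  tbl$site[tbl$group == "patient"][1] <- "NEW"
  tbl$site[tbl$group == "control"] <- sample(c("DRC", "UCSF"), 50, TRUE)
  expect_error(adjust_covariates(tbl, "vol", covs), "unseen")
})

test_that("aggregate_rois averages pairs first, then constituents", {
  m <- roi_mapping(tibble::tibble(region = c("r1", "r2", "r3"),
                                  roi = c("A", "A", "B")))
  out <- aggregate_rois(tibble::tibble(r1 = 2, r2 = 4, r3 = 10), m)
  expect_equal(out$A, 3)
  expect_equal(out$B, 10)

  # left/right averaged before ROI pooling
  m2 <- roi_mapping(tibble::tibble(region = c("r1", "r2"), roi = c("A", "A")),
                    pairs = tibble::tibble(left = c("l_r1", "l_r2"),
                                           right = c("p_r1", "p_r2"),
                                           region = c("r1", "r2")))
  out2 <- aggregate_rois(
    tibble::tibble(l_r1 = 1, p_r1 = 3, l_r2 = 10, p_r2 = 10), m2)
  expect_equal(out2$A, (2 + 10) / 2)

  # symmetric hemispheres equal the single-hemisphere mean
  out3 <- aggregate_rois(
    tibble::tibble(l_r1 = 5, p_r1 = 5, l_r2 = 9, p_r2 = 9), m2)
  expect_equal(out3$A, 7)

  expect_error(aggregate_rois(tibble::tibble(r1 = 1), m), "missing region")
})

test_that("the default mapping reduces 46 regions to 8 ROIs", {
  m <- default_roi_mapping()
  expect_equal(nrow(m$groups), 46)
  set.seed(8)
  tbl <- tibble::as_tibble(as.list(setNames(rnorm(46, 100, 10),
                                            m$groups$region)))
  out <- aggregate_rois(tbl, m)
  expect_setequal(names(out),
                  c("whole_brain", "hippocampal", "occipital", "frontal",
                    "entorhinal", "temporal", "parietal", "ventricle"))
  # permutation-invariance to input column order
  out_perm <- aggregate_rois(tbl[sample(names(tbl))], m)
  expect_equal(out[sort(names(out))], out_perm[sort(names(out_perm))])
})

test_that("z-scoring centres and scales relative to controls", {
  ref <- tibble::tibble(biomarker = "vol", mean = 100, sd = 10)
  tbl <- tibble::tibble(vol = c(100, 70, 120))
  z <- zscore_to_controls(tbl, ref)
  expect_equal(z$vol, c(0, -3, 2))

  set.seed(9)
  ctl <- tibble::tibble(subject_id = sprintf("C%03d", 1:100), group = "control",
                        visit_index = 1L, vol = rnorm(100, 50, 4))
  r <- control_reference(ctl, "vol")
  zz <- zscore_to_controls(ctl, r)
  expect_lt(abs(mean(zz$vol)), 3 / sqrt(100))
  expect_true(sd(zz$vol) > 0.8 && sd(zz$vol) < 1.2)
})

test_that("orientation flips increasing biomarkers and is an involution", {
  tbl <- tibble::tibble(ventricle = c(2, -1), hippocampal = c(1.5, 0))
  dirs <- c(ventricle = "increasing", hippocampal = "decreasing")
  o <- orient_abnormality(tbl, dirs)
  expect_equal(o$ventricle, c(-2, 1))
  expect_equal(o$hippocampal, tbl$hippocampal)
  oo <- orient_abnormality(o, dirs)
  expect_equal(oo$ventricle, tbl$ventricle)
  expect_error(orient_abnormality(tbl, c(nope = "decreasing")), "not in table")
})

test_that("floor rule assigns the floor once and censors afterwards", {
  expect_equal(apply_floor_rule(c(12, 0, 7, 9), 0), c(12, 0, 0, NA))
  expect_equal(apply_floor_rule(c(12, 11, 9), 0), c(12, 11, 9))
  expect_equal(apply_floor_rule(c(12, 5, 0), 0), c(12, 5, 0))
  # missing stays missing; later floors still trigger
  expect_equal(apply_floor_rule(c(10, NA, 0, 8, 6), 0), c(10, NA, 0, 0, NA))

  tbl <- tibble::tibble(
    subject_id = rep(c("a", "b"), each = 3),
    visit_index = rep(1:3, 2),
    score = c(5, 0, 4, 6, 5, 4))
  out <- apply_floor_rule_table(tbl, c(score = 0))
  expect_equal(out$score, c(5, 0, 0, 6, 5, 4))
})

test_that("z-scoring after adjustment keeps controls standardised", {
  tbl <- make_cov_table(n = 120, beta_tiv = 0.4, site_offset = 5, seed = 10)
  adj <- adjust_covariates(tbl, "vol", covs)
  r <- control_reference(adj, "vol")
  z <- zscore_to_controls(adj, r)
  expect_lt(abs(mean(z$vol)), 0.2)
  expect_true(sd(z$vol) > 0.8 && sd(z$vol) < 1.2)
})
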