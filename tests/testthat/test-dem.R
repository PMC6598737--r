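test_that("subject slopes equal the closed-form OLS estimates", {
  tbl <- tibble::tibble(
    subject_id = c("a", "a", "b", "b", "b"),
    years_since_baseline = c(0, 1, 0, 1, 2),
    vol = c(10, 8, 5, 5, 5))
  sl <- fit_subject_slopes(tbl, "vol")
  expect_equal(sl$slope[sl$subject_id == "a"], -2)
  expect_equal(sl$mean_value[sl$subject_id == "a"], 9)
  expect_equal(sl$slope[sl$subject_id == "b"], 0)

  # noisy collinear points vs the normal-equations oracle
  set.seed(1)
  t <- 0:4
  y <- 3 - 0.7 * t + rnorm(5, 0, 0.2)
  tbl2 <- tibble::tibble(subject_id = "s", years_since_baseline = t, vol = y)
  sl2 <- fit_subject_slopes(tbl2, "vol")
  beta <- solve(crossprod(cbind(1, t)), crossprod(cbind(1, t), y))
  expect_equal(sl2$slope, unname(beta[2, 1]), tolerance = 1e-10)
  expect_equal(sl2$mean_value, mean(y))

  # single-visit subjects are excluded, not fatal
  tbl3 <- dplyr::bind_rows(tbl, tibble::tibble(
    subject_id = "c", years_since_baseline = 0, vol = 1))
  sl3 <- fit_subject_slopes(tbl3, "vol")
  expect_setequal(sl3$subject_id, c("a", "b"))
  expect_equal(attr(sl3, "n_excluded"), 1L)
})

test_that("GP prediction agrees with direct kernel algebra at fixed hyperparameters", {
  set.seed(2)
  x <- runif(30, 0, 10)
  y <- sin(x) + rnorm(30, 0, 0.1)
  hyper <- list(ell = 1.5, sf2 = 1, sn2 = 0.01)
  xs <- seq(0, 10, length.out = 25)
  pred <- progmod:::gp_predict(x, y, hyper, xs)
  # oracle: naive matrix-inverse formulas
  k <- function(a, b) hyper$sf2 * exp(-0.5 * outer(a, b, `-`)^2 / hyper$ell^2)
  Kinv <- solve(k(x, x) + diag(hyper$sn2, 30))
  mu <- k(xs, x) %*% Kinv %*% y
  v <- hyper$sf2 - diag(k(xs, x) %*% Kinv %*% k(x, xs))
  expect_equal(pred$mean, as.numeric(mu), tolerance = 1e-8)
  expect_equal(pred$sd, sqrt(pmax(v, 0)), tolerance = 1e-6)
})

test_that("rate model recovers flat and curved rate functions", {
  set.seed(3)
  flat <- tibble::tibble(subject_id = as.character(1:40),
                         mean_value = runif(40, 0, 10),
                         slope = 0, n_visits = 3, follow_up_span = 2)
  m0 <- fit_rate_model(flat)
  expect_lt(max(abs(m0$rate)), 0.01)

  # known f(u) = -0.3 u (1 - u/10): posterior mean tracks the truth
  n <- 200
  u <- runif(n, 0.5, 9.5)
  f <- -0.3 * u * (1 - u / 10)
  sl <- tibble::tibble(subject_id = as.character(1:n), mean_value = u,
                       slope = f + rnorm(n, 0, 0.05),
                       n_visits = 3, follow_up_span = 2)
  m <- fit_rate_model(sl, seed = 4)
  interior <- m$grid > 1 & m$grid < 9
  truth <- -0.3 * m$grid * (1 - m$grid / 10)
  covered <- truth[interior] >= m$lo95[interior] &
    truth[interior] <= m$hi95[interior]
  expect_gte(mean(covered), 0.9)
  # band contains the posterior mean
  expect_true(all(m$lo95 <= m$rate & m$rate <= m$hi95))
})

test_that("integration reproduces closed-form trajectories", {
  # constant rate -0.5: value is linear in time
  g <- seq(0, 10, length.out = 200)
  tr <- integrate_trajectory(fake_rate_model(g, rep(-0.5, 200)))
  fitline <- lm(tr$value ~ tr$time)
  expect_equal(unname(coef(fitline)[2]), -0.5, tolerance = 1e-6)
  expect_equal(tr$start_value, 10)

  # logistic rate du/dt = -r u (K - u)/K has solution K / (1 + B exp(r t))
  K <- 10; r <- 0.3
  g2 <- seq(0.5, 9.5, length.out = 400)
  tr2 <- integrate_trajectory(fake_rate_model(g2, -r * g2 * (K - g2) / K))
  B <- (K - tr2$start_value) / tr2$start_value
  truth <- K / (1 + B * exp(r * tr2$time))
  expect_lt(max(abs(tr2$value - truth)), 0.01 * diff(range(g2)))
})

test_that("interior sign changes abort; edge zeros truncate", {
  g <- seq(0, 10, length.out = 300)
  # genuine interior crossing: down then up
  expect_error(integrate_trajectory(fake_rate_model(g, -sin(g * pi / 5))),
               "sign in the interior")
  # rate hitting zero at the lower limit: trajectory asymptotes, no error
  rate <- -pmax(g, 0) / 10
  tr <- integrate_trajectory(fake_rate_model(g, rate))
  expect_true(all(diff(tr$value) <= 1e-9))
  expect_gte(min(tr$value), 0)
})

test_that("differentiating the trajectory recovers the rate model", {
  K <- 10; r <- 0.3
  g <- seq(0.5, 9.5, length.out = 400)
  f <- -r * g * (K - g) / K
  tr <- integrate_trajectory(fake_rate_model(g, f))
  dt <- diff(tr$time)
  num_rate <- diff(tr$value) / dt
  mid_vals <- (tr$value[-1] + tr$value[-length(tr$value)]) / 2
  expected <- -r * mid_vals * (K - mid_vals) / K
  interior <- mid_vals > 1.5 & mid_vals < 8.5
  rel_err <- abs(num_rate[interior] - expected[interior]) /
    max(abs(expected))
  expect_lt(max(rel_err), 0.02)
})

test_that("t0 anchoring picks the accuracy-maximising threshold", {
  g <- seq(-8, 2, length.out = 300)
  tr <- integrate_trajectory(fake_rate_model(g, rep(-0.5, 300)))
  set.seed(5)
  ctl <- rnorm(60, 0, 0.1)
  pat <- rnorm(60, -5, 0.1)
  a <- anchor_t0(tr, ctl, pat)
  expect_true(a$t0_threshold > -4 && a$t0_threshold < -1)
  v0 <- approx(a$time, a$value, 0)$y
  expect_equal(v0, a$t0_threshold, tolerance = 1e-2)
  # z at t = 0 reflects the control reference
  expect_equal(approx(a$time, a$z, 0)$y,
               (a$t0_threshold - mean(ctl)) / sd(ctl), tolerance = 1e-2)

  # exhaustive-scan oracle over all midpoints
  pooled <- sort(unique(c(ctl, pat)))
  cand <- (pooled[-1] + pooled[-length(pooled)]) / 2
  acc <- sapply(cand, function(th) {
    a1 <- (sum(ctl > th) + sum(pat <= th)) / 120
    max(a1, 1 - a1)
  })
  best <- cand[acc == max(acc)]
  expect_equal(a$t0_threshold, best[ceiling(length(best) / 2)])

  # swapping the labels leaves the chosen threshold unchanged
  a_swap <- anchor_t0(tr, pat, ctl)
  expect_equal(a_swap$t0_threshold, a$t0_threshold)
})

test_that("anchoring shifts time without changing trajectory shape", {
  g <- seq(0.5, 9.5, length.out = 300)
  tr <- integrate_trajectory(fake_rate_model(g, -0.3 * g * (10 - g) / 10))
  set.seed(6)
  a <- anchor_t0(tr, rnorm(30, 8, 0.3), rnorm(30, 3, 0.5))
  v_before <- approx(tr$time, tr$value, c(2, 7))$y
  shift <- tr$time[1] - a$time[1]
  v_after <- approx(a$time, a$value, c(2, 7) - shift)$y
  expect_equal(diff(v_before), diff(v_after), tolerance = 1e-9)
})

test_that("DEM staging places on-curve subjects at their generating time", {
  g <- seq(0.5, 9.5, length.out = 300)
  tr <- integrate_trajectory(fake_rate_model(g, -0.3 * g * (10 - g) / 10))
  set.seed(7)
  a <- anchor_t0(tr, rnorm(50, 8.5, 0.2), rnorm(50, 3, 1))
  trajs <- list(vol = a)

  z_at <- function(t) approx(a$time, a$z, t, rule = 2)$y
  subj <- tibble::tibble(subject_id = c("u", "v"),
                         vol = z_at(c(3, -2)))
  st <- stage_subjects_dem(trajs, subj, grid_step = 0.05)
  expect_equal(st$stage_time[st$subject_id == "u"], 3, tolerance = 0.06)
  expect_equal(st$stage_time[st$subject_id == "v"], -2, tolerance = 0.06)

  # noisy subject equals a dense brute-force grid minimiser
  zn <- z_at(4) + 0.3
  grid <- seq(min(a$time), max(a$time), by = 0.05)
  sse <- (z_at(grid) - zn)^2
  st2 <- stage_subjects_dem(trajs, tibble::tibble(subject_id = "w", vol = zn),
                            grid_step = 0.05)
  expect_equal(st2$stage_time, grid[which.min(sse)], tolerance = 1e-9)

  # values beyond the trajectory range clamp to the boundary
  st3 <- stage_subjects_dem(trajs,
                            tibble::tibble(subject_id = "x",
                                           vol = min(a$z) - 5),
                            grid_step = 0.05)
  expect_equal(st3$stage_time, max(a$time), tolerance = 0.06)

  # staging is monotone in abnormality
  zz <- seq(0.5, -4, by = -0.5)
  stm <- stage_subjects_dem(
    trajs, tibble::tibble(subject_id = as.character(seq_along(zz)), vol = zz),
    grid_step = 0.05)
  expect_true(all(diff(stm$stage_time) >= 0))
})

test_that("bootstrap ensembles are seeded and cover the trajectory", {
  coh <- generate_cohort(logistic_cohort_config(noise_sd = 0.25,
                                                n_patients = 60,
                                                n_controls = 30, seed = 21))
  e1 <- bootstrap_trajectories(coh$data, "traj", n_boot = 3, seed = 9,
                               n_restarts = 2, grid_size = 60)
  e2 <- bootstrap_trajectories(coh$data, "traj", n_boot = 3, seed = 9,
                               n_restarts = 2, grid_size = 60)
  expect_equal(length(e1), 3)
  expect_equal(e1[[2]]$value, e2[[2]]$value)
  expect_equal(e1[[2]]$t0_threshold, e2[[2]]$t0_threshold)
  expect_true(all(vapply(e1, function(tr) isTRUE(tr$anchored), TRUE)))
})

test_that("trajectory-value comparisons match closed-form t statistics", {
  mk_traj <- function(offset) {
    structure(list(time = seq(-15, 15, by = 0.5),
                   value = NULL, z = -2 - 0.2 * seq(-15, 15, by = 0.5) + offset,
                   anchored = TRUE, direction = "decreasing",
                   t0_threshold = 0, value_low = 0, value_high = 1,
                   start_value = 1, control_mean = 0, control_sd = 1),
              class = "progmod_trajectory")
  }
  offA1 <- c(0, 0.1, -0.1, 0.05, -0.05)
  offA2 <- offA1 + c(1.0, 1.1, 0.9, 1.05, 0.95)
  ensembles <- list(
    gA = list(b1 = structure(lapply(offA1, mk_traj),
                             class = "progmod_trajectory_ensemble"),
              b2 = structure(lapply(offA2, mk_traj),
                             class = "progmod_trajectory_ensemble")),
    gB = list(b1 = structure(lapply(offA1, mk_traj),
                             class = "progmod_trajectory_ensemble"),
              b2 = structure(lapply(offA1 + 10, mk_traj),
                             class = "progmod_trajectory_ensemble")))
  res <- compare_trajectory_values(ensembles, times = 0)

  # within-group paired t equals the hand-computed statistic
  d <- offA1 - offA2
  t_hand <- mean(d) / (sd(d) / sqrt(5))
  row <- res[res$family == "within_group" & res$group == "gA", ]
  expect_equal(row$statistic, t_hand, tolerance = 1e-10)

  # identical ensembles across groups: p near 1
  same <- res[res$family == "between_group" & res$biomarker_i == "b1", ]
  expect_gt(same$p, 0.9)
  # strongly shifted ensembles: significant at the Bonferroni threshold
  diffr <- res[res$family == "between_group" & res$biomarker_i == "b2", ]
  expect_lt(diffr$p, diffr$threshold)
  # times outside the support are flagged not-evaluable
  res2 <- compare_trajectory_values(ensembles, times = 99)
  expect_true(all(!res2$evaluable))
})
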