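#' Per-subject biomarker rates of change
#'
#' Fits an ordinary least-squares line of biomarker value against years
#' since baseline for each subject independently; the slope measures the
#' subject's short-term rate of change and is paired with the mean of the
#' subject's observed values. Subjects with fewer than two usable visits
#' are excluded (and counted in the `"n_excluded"` attribute).
#'
#' @param table Cohort tibble with `subject_id`, `years_since_baseline`
#'   and the biomarker column.
#' @param biomarker Biomarker column name.
#' @return Tibble with `subject_id`, `mean_value`, `slope`, `n_visits`,
#'   `follow_up_span`.
#' @export
fit_subject_slopes <- function(table, biomarker) {
  if (!biomarker %in% names(table)) {
    abort(sprintf("biomarker '%s' not in table", biomarker))
  }
  d <- table |>
    select(subject_id = "subject_id", t = "years_since_baseline",
           y = all_of(biomarker)) |>
    filter(!is.na(.data$y))
  by_subj <- d |>
    group_by(.data$subject_id) |>
    summarise(
      n_visits = dplyr::n(),
      follow_up_span = max(.data$t) - min(.data$t),
      mean_value = mean(.data$y),
      slope = if (dplyr::n() >= 2 && max(.data$t) > min(.data$t)) {
        sum((.data$t - mean(.data$t)) * (.data$y - mean(.data$y))) /
          sum((.data$t - mean(.data$t))^2)
      } else NA_real_,
      .groups = "drop")
  out <- by_subj |> filter(!is.na(.data$slope))
  attr(out, "n_excluded") <- nrow(by_subj) - nrow(out)
  out
}

#' Gaussian-process rate-of-change model
#'
#' Regresses per-subject slopes on per-subject mean biomarker values with
#' a Gaussian process (squared-exponential kernel plus observation noise;
#' hyperparameters by marginal-likelihood maximisation over seeded
#' restarts), giving the average rate of change as a smooth function of
#' biomarker value with a pointwise 95% interval.
#'
#' @param slopes Output of [fit_subject_slopes()].
#' @param grid_size Number of evaluation points spanning the observed
#'   value range.
#' @param n_restarts Optimiser restarts.
#' @param seed Seed for the restart draws.
#' @return A `progmod_rate_model`: list with `grid`, `rate`, `lo95`,
#'   `hi95`, `hyper`, and the training points.
#' @export
fit_rate_model <- function(slopes, grid_size = 100, n_restarts = 5, seed = 1L) {
  if (nrow(slopes) < 5) abort("need at least 5 slope points to fit a rate model")
  x <- slopes$mean_value
  y <- slopes$slope
  if (diff(range(x)) <= 0) abort("degenerate value range: cannot fit rate model")
  hyper <- gp_fit_hyper(x, y, n_restarts = n_restarts, seed = seed)
  grid <- seq(min(x), max(x), length.out = grid_size)
  pred <- gp_predict(x, y, hyper, grid)
  structure(
    list(grid = grid, rate = pred$mean,
         lo95 = pred$mean - 1.96 * pred$sd,
         hi95 = pred$mean + 1.96 * pred$sd,
         hyper = hyper, x = x, y = y),
    class = "progmod_rate_model")
}

#' @export
print.progmod_rate_model <- function(x, ...) {
  cat("GP rate-of-change model on", length(x$x), "subjects;",
      sprintf("value range [%.3g, %.3g]; ell = %.3g, sf = %.3g, sn = %.3g\n",
              min(x$grid), max(x$grid), x$hyper$ell, sqrt(x$hyper$sf2),
              sqrt(x$hyper$sn2)))
  invisible(x)
}

#' Reconstruct a trajectory by integrating the rate model
#'
#' Solves `dt/du = 1 / rate(u)` from the starting integration limit along
#' the biomarker-value axis, then inverts to value as a function of time
#' on a uniform time grid. Integration limits are the values where the
#' posterior mean rate falls below a zero-tolerance or the limits of the
#' data; a sign change of the rate in the interior (beyond tolerance) is
#' an error, since the model requires a monotone trajectory.
#'
#' @param model A [fit_rate_model()] result.
#' @param zero_tol_frac Zero-tolerance as a fraction of the maximum
#'   absolute rate.
#' @param n_fine Fine value-grid size used for the quadrature.
#' @param time_step Uniform time-grid spacing (years).
#' @return A `progmod_trajectory` (unanchored): tibble-backed list with
#'   `time`, `value`, integration limits and the value where the
#'   trajectory starts.
#' @export
integrate_trajectory <- function(model, zero_tol_frac = 1e-3, n_fine = 2000,
                                 time_step = 0.1) {
  stopifnot(inherits(model, "progmod_rate_model"))
  u <- model$grid
  r <- model$rate
  tol <- zero_tol_frac * max(abs(r))
  strong <- abs(r) > tol
  if (!any(strong)) abort("rate is zero everywhere within tolerance")
  s <- sign(r[which.max(abs(r))])

  # run structure of the signed, above-tolerance rate: 0 = within
  # tolerance of zero, +/-1 = clearly signed
  sgn <- ifelse(strong, sign(r), 0)
  runs <- rle(sgn)
  ends <- cumsum(runs$lengths)
  starts_ <- ends - runs$lengths + 1L
  imax <- which.max(abs(r))
  k <- which(starts_ <= imax & ends >= imax)

  # a strongly opposite-signed region (at least half the peak rate) lying
  # strictly between two strongly dominant-signed regions means the rate
  # genuinely crosses zero in the interior; weaker near-zero wiggles at
  # the plateaus merely truncate the integration instead
  sign_tol <- 0.5 * max(abs(r))
  sgn2 <- ifelse(abs(r) > sign_tol, sign(r), 0)
  runs2 <- rle(sgn2)
  ends2 <- cumsum(runs2$lengths)
  starts2 <- ends2 - runs2$lengths + 1L
  dom <- which(runs2$values == s)
  opp <- which(runs2$values == -s)
  interior_opp <- opp[opp > min(dom) & opp < max(dom)]
  if (length(interior_opp)) {
    cross <- u[starts2[interior_opp[1]]]
    abort(sprintf(paste0("rate changes sign in the interior near value %.4g; ",
                         "trajectory is not monotone"), cross))
  }

  # integrate over the dominant-signed run containing the rate maximum;
  # integration stops where the rate falls within tolerance of zero
  u_lo <- u[starts_[k]]; u_hi <- u[ends[k]]

  # a strongly opposite-signed rate between the chosen run and the value
  # where the trajectory must start (upper limit for a decreasing
  # biomarker) also signals a genuine interior crossing; weak wiggles at
  # the healthy plateau only truncate the integration there
  before_start <- if (s < 0) u > u_hi else u < u_lo
  strong_opp <- before_start & sign(r) == -s & abs(r) > 0.5 * max(abs(r))
  if (any(strong_opp)) {
    cross <- u[which(strong_opp)[1]]
    abort(sprintf(paste0("rate changes sign in the interior near value %.4g; ",
                         "trajectory is not monotone"), cross))
  }

  # fine grid over the usable run; linear interpolation of the rate
  uf <- seq(u_lo, u_hi, length.out = n_fine)
  rf <- approx(u, r, uf)$y
  rf[abs(rf) < tol] <- s * tol # guard the quadrature at the run ends

  # time starts where the trajectory begins: upper value limit when the
  # biomarker decreases, lower limit when it increases
  if (s < 0) {
    uf <- rev(uf); rf <- rev(rf)
  }
  dt <- diff(uf) * 0.5 * (1 / rf[-1] + 1 / rf[-length(rf)])
  tt <- c(0, cumsum(dt))

  t_grid <- seq(0, max(tt), by = time_step)
  value <- approx(tt, uf, t_grid)$y
  structure(
    list(time = t_grid, value = value, z = NULL,
         value_low = u_lo, value_high = u_hi,
         start_value = if (s < 0) u_hi else u_lo,
         direction = if (s < 0) "decreasing" else "increasing",
         t0_threshold = NA_real_, anchored = FALSE,
         control_mean = NA_real_, control_sd = NA_real_),
    class = "progmod_trajectory")
}

#' Anchor a trajectory at the control/patient separation threshold
#'
#' Defines the reference time t0 = 0 as the biomarker value threshold
#' that best separates controls from patients (maximum classification
#' accuracy over candidate thresholds at the midpoints of the sorted
#' pooled values; ties resolved by the median maximiser), shifts the time
#' axis so `value(0)` equals that threshold, and attaches the z-score
#' scale with respect to the control sample.
#'
#' @param traj Unanchored [integrate_trajectory()] result.
#' @param control_values,patient_values Biomarker values (same scale as
#'   the trajectory) for controls and patients, typically baseline visits.
#' @return The anchored `progmod_trajectory`, with `time` relative to t0,
#'   `z` the control-referenced z-score, and `t0_threshold` recorded.
#' @export
anchor_t0 <- function(traj, control_values, patient_values) {
  stopifnot(inherits(traj, "progmod_trajectory"))
  control_values <- control_values[!is.na(control_values)]
  patient_values <- patient_values[!is.na(patient_values)]
  if (!length(control_values) || !length(patient_values)) {
    abort("both control and patient samples must be non-empty")
  }
  thr <- separation_threshold(control_values, patient_values)

  # locate t* with value(t*) = threshold (monotone trajectory)
  v <- traj$value; tt <- traj$time
  thr_clamped <- min(max(thr, min(v)), max(v))
  o <- order(v)
  t_star <- approx(v[o], tt[o], thr_clamped, ties = "ordered")$y
  out <- traj
  out$time <- tt - t_star
  out$t0_threshold <- thr
  out$control_mean <- mean(control_values)
  out$control_sd <- sd(control_values)
  if (is.na(out$control_sd) || out$control_sd <= 0) {
    warn("control sample has zero spread; z-scores use unit scale")
    out$control_sd <- 1
  }
  out$z <- (v - out$control_mean) / out$control_sd
  out$anchored <- TRUE
  out
}

# threshold maximising classification accuracy over midpoint candidates
separation_threshold <- function(control_values, patient_values) {
  pooled <- sort(unique(c(control_values, patient_values)))
  if (length(pooled) < 2) return(pooled[1])
  cand <- (pooled[-1] + pooled[-length(pooled)]) / 2
  n <- length(control_values) + length(patient_values)
  acc <- vapply(cand, function(th) {
    a1 <- (sum(control_values > th) + sum(patient_values <= th)) / n
    max(a1, 1 - a1)
  }, 0)
  best <- which(acc == max(acc))
  if (max(acc) <= 0.5 + 1 / n) {
    warn("controls and patients overlap completely; t0 threshold is arbitrary")
  }
  cand[best[ceiling(length(best) / 2)]]
}

#' @export
print.progmod_trajectory <- function(x, ...) {
  cat(sprintf("%s trajectory (%s): %d time points over [%.1f, %.1f] years%s\n",
              if (x$anchored) "Anchored" else "Unanchored", x$direction,
              length(x$time), min(x$time), max(x$time),
              if (x$anchored) sprintf("; t0 threshold %.3g", x$t0_threshold) else ""))
  invisible(x)
}

# z-score of a trajectory evaluated at arbitrary times (clamped at ends)
traj_z_at <- function(traj, times, clamp = TRUE) {
  stopifnot(isTRUE(traj$anchored))
  approx(traj$time, traj$z, times, rule = if (clamp) 2 else 1)$y
}

#' Stage subjects along the DEM timeline
#'
#' Places each subject at the time (years from t0) minimising the sum of
#' squared differences between the subject's observed z-scores and the
#' anchored trajectories' z(t), over the subject's non-missing biomarkers
#' with equal weights. Values beyond a trajectory's support are compared
#' against its clamped end values, so extreme subjects stage at the grid
#' boundary.
#'
#' @param trajectories Named list of anchored trajectories (one per
#'   biomarker).
#' @param subject_z Tibble with `subject_id` and one z-score column per
#'   biomarker (typically baseline visits, control-referenced and
#'   oriented like the trajectories).
#' @param grid_step Search-grid spacing in years.
#' @return Tibble with `subject_id`, `stage_time`, `residual`,
#'   `n_biomarkers_used`.
#' @export
stage_subjects_dem <- function(trajectories, subject_z, grid_step = 0.1) {
  stopifnot(length(trajectories) >= 1)
  bm <- intersect(names(trajectories), names(subject_z))
  if (!length(bm)) abort("no trajectory biomarker matches a subject_z column")
  t_min <- min(vapply(trajectories[bm], function(tr) min(tr$time), 0))
  t_max <- max(vapply(trajectories[bm], function(tr) max(tr$time), 0))
  grid <- seq(t_min, t_max, by = grid_step)
  Z <- vapply(bm, function(b) traj_z_at(trajectories[[b]], grid), numeric(length(grid)))

  res <- purrr::map(seq_len(nrow(subject_z)), function(i) {
    zobs <- as.numeric(as.data.frame(subject_z[i, bm]))
    usable <- !is.na(zobs)
    if (!any(usable)) {
      warn(sprintf("subject %s has no usable biomarker; skipped",
                   subject_z$subject_id[i]))
      return(NULL)
    }
    sse <- colSums((t(Z[, usable, drop = FALSE]) - zobs[usable])^2)
    j <- which.min(sse)
    tibble(subject_id = subject_z$subject_id[i], stage_time = grid[j],
           residual = sse[j], n_biomarkers_used = sum(usable))
  })
  list_rbind(res)
}

#' Fit the full DEM for one biomarker
#'
#' Convenience wrapper: subject slopes on all participants with two or
#' more visits, GP rate model, trajectory integration, and t0 anchoring
#' against baseline control versus patient values.
#'
#' @param table Cohort tibble (adjusted/z-scored as desired) with `group`.
#' @param biomarker Biomarker column.
#' @param grid_size,n_restarts,seed,zero_tol_frac,time_step Passed through.
#' @return Anchored `progmod_trajectory`.
#' @export
fit_dem <- function(table, biomarker, grid_size = 100, n_restarts = 5,
                    seed = 1L, zero_tol_frac = 1e-3, time_step = 0.1) {
  slopes <- fit_subject_slopes(table, biomarker)
  model <- fit_rate_model(slopes, grid_size = grid_size,
                          n_restarts = n_restarts, seed = seed)
  traj <- integrate_trajectory(model, zero_tol_frac = zero_tol_frac,
                               time_step = time_step)
  base <- table |>
    group_by(.data$subject_id) |>
    slice_min(.data$visit_index, n = 1, with_ties = FALSE) |>
    ungroup()
  anchor_t0(traj,
            control_values = base[[biomarker]][base$group == "control"],
            patient_values = base[[biomarker]][base$group != "control"])
}

#' Bootstrap ensemble of DEM trajectories
#'
#' Nonparametric subject-level resampling with replacement (stratified by
#' group so both controls and patients are always present), refitting the
#' whole DEM per replicate. Replicates whose integration fails are
#' dropped and counted; more than 50% failures is an error.
#'
#' @param table Cohort tibble with `group`.
#' @param biomarker Biomarker column.
#' @param n_boot Number of replicates.
#' @param seed Seed for the resampling and refits.
#' @param ... Passed to [fit_dem()].
#' @return A `progmod_trajectory_ensemble`: list of anchored trajectories
#'   with attribute `n_failed`.
#' @export
bootstrap_trajectories <- function(table, biomarker, n_boot = 100, seed = 1L, ...) {
  if (n_boot < 1) abort("n_boot must be >= 1")
  ids <- table |> distinct(.data$subject_id, .data$group)
  draws <- with_seed(child_seed(seed, "dem_boot"), {
    lapply(seq_len(n_boot), function(b) {
      unlist(lapply(split(ids$subject_id, ids$group), function(s) {
        sample(s, length(s), replace = TRUE)
      }), use.names = FALSE)
    })
  })
  fits <- purrr::imap(draws, function(drawn, b) {
    rows <- tibble(subject_id = drawn, boot_id = sprintf("b%05d", seq_along(drawn)))
    boot_tbl <- inner_join(rows, table, by = "subject_id",
                           relationship = "many-to-many") |>
      mutate(subject_id = .data$boot_id) |>
      select(-"boot_id")
    tryCatch(fit_dem(boot_tbl, biomarker, seed = child_seed(seed, paste0("fit", b)), ...),
             error = function(e) NULL)
  })
  failed <- sum(vapply(fits, is.null, TRUE))
  if (failed > n_boot / 2) {
    abort(sprintf("DEM bootstrap failed in %d of %d replicates", failed, n_boot))
  }
  structure(purrr::compact(fits), n_failed = failed,
            class = "progmod_trajectory_ensemble")
}

#' Compare estimated biomarker values at fixed times from t0
#'
#' Within-group comparisons use two-tailed paired t-tests across bootstrap
#' replicates of biomarker i versus biomarker j values at each requested
#' time; between-group comparisons use two-tailed two-sample t-tests per
#' biomarker per time. A single Bonferroni-corrected threshold covers all
#' tests performed.
#'
#' @param ensembles Named list (group -> named list of biomarker ->
#'   `progmod_trajectory_ensemble`).
#' @param times Years from t0 at which to compare (default -10, 0, +10).
#' @param alpha Family-wise error rate.
#' @return Tibble with one row per test: `family`, `group`, `biomarker_i`,
#'   `biomarker_j`, `time`, `estimate`, `statistic`, `p`, `m`,
#'   `threshold`, `significant`, `evaluable`.
#' @export
compare_trajectory_values <- function(ensembles, times = c(-10, 0, 10),
                                      alpha = 0.05) {
  z_at <- function(ens, t) vapply(ens, function(tr) {
    if (t < min(tr$time) || t > max(tr$time)) NA_real_ else traj_z_at(tr, t)
  }, 0)

  rows <- list()
  groups <- names(ensembles)
  for (g in groups) {
    bms <- names(ensembles[[g]])
    vals <- lapply(times, function(t) {
      vapply(bms, function(b) z_at(ensembles[[g]][[b]], t),
             numeric(length(ensembles[[g]][[1]])))
    })
    names(vals) <- as.character(times)
    for (ti in seq_along(times)) {
      V <- vals[[ti]]
      if (length(bms) >= 2) {
        for (i in seq_len(length(bms) - 1)) for (j in (i + 1):length(bms)) {
          ok <- complete.cases(V[, c(i, j)])
          evaluable <- sum(ok) >= 3 && sd(V[ok, i] - V[ok, j]) > 0
          tst <- if (evaluable) t.test(V[ok, i], V[ok, j], paired = TRUE) else NULL
          rows[[length(rows) + 1]] <- tibble(
            family = "within_group", group = g,
            biomarker_i = bms[i], biomarker_j = bms[j], time = times[ti],
            estimate = if (evaluable) unname(tst$estimate) else NA_real_,
            statistic = if (evaluable) unname(tst$statistic) else NA_real_,
            p = if (evaluable) tst$p.value else NA_real_,
            evaluable = evaluable)
        }
      }
    }
  }
  if (length(groups) >= 2) {
    for (gi in seq_len(length(groups) - 1)) for (gj in (gi + 1):length(groups)) {
      g1 <- groups[gi]; g2 <- groups[gj]
      shared <- intersect(names(ensembles[[g1]]), names(ensembles[[g2]]))
      for (b in shared) for (t in times) {
        v1 <- vapply(ensembles[[g1]][[b]], function(tr) {
          if (t < min(tr$time) || t > max(tr$time)) NA_real_ else traj_z_at(tr, t)
        }, 0)
        v2 <- vapply(ensembles[[g2]][[b]], function(tr) {
          if (t < min(tr$time) || t > max(tr$time)) NA_real_ else traj_z_at(tr, t)
        }, 0)
        v1 <- v1[!is.na(v1)]; v2 <- v2[!is.na(v2)]
        evaluable <- length(v1) >= 3 && length(v2) >= 3 &&
          (sd(v1) > 0 || sd(v2) > 0)
        tst <- if (evaluable) t.test(v1, v2) else NULL
        rows[[length(rows) + 1]] <- tibble(
          family = "between_group", group = paste(g1, "vs", g2),
          biomarker_i = b, biomarker_j = NA_character_, time = t,
          estimate = if (evaluable) mean(v1) - mean(v2) else NA_real_,
          statistic = if (evaluable) unname(tst$statistic) else NA_real_,
          p = if (evaluable) tst$p.value else NA_real_,
          evaluable = evaluable)
      }
    }
  }
  out <- list_rbind(rows)
  m <- sum(out$evaluable)
  out |>
    mutate(m = m, threshold = alpha / max(m, 1),
           significant = .data$evaluable & .data$p < alpha / max(m, 1))
}
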