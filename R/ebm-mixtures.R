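# Per-biomarker two-component mixtures separating the normal (pre-event)
# and abnormal (post-event) distributions. Gaussian flavour for volumes,
# kernel-density flavour for skewed / floored cognitive scores.

new_mixture_fit <- function(biomarker, flavour, dnorm_fun, dabn_fun, pi,
                            diagnostics) {
  structure(
    list(biomarker = biomarker, flavour = flavour,
         normal_density = dnorm_fun, abnormal_density = dabn_fun,
         pi = pi, diagnostics = diagnostics),
    class = "progmod_mixture")
}

#' @export
print.progmod_mixture <- function(x, ...) {
  cat(sprintf("%s mixture for '%s': pi(abnormal) = %.3f%s\n",
              x$flavour, x$biomarker %||% "?", x$pi,
              if (isTRUE(x$diagnostics$uninformative)) " [uninformative]" else ""))
  invisible(x)
}

#' Posterior probability that a value is abnormal
#'
#' `p(E | x) = pi f_a(x) / (pi f_a(x) + (1 - pi) f_n(x))`.
#'
#' @param fit A `progmod_mixture`.
#' @param x Values.
#' @return Probabilities in `[0, 1]`.
#' @export
prob_abnormal <- function(fit, x) {
  fa <- pmax(fit$abnormal_density(x), 1e-300)
  fn <- pmax(fit$normal_density(x), 1e-300)
  fit$pi * fa / (fit$pi * fa + (1 - fit$pi) * fn)
}

#' Constrained Gaussian mixture for a volume biomarker
#'
#' Two-component Gaussian mixture fitted by EM on the pooled control and
#' patient values. The normal component is initialised from the controls
#' and the abnormal component from the patients; during EM the normal
#' mean is constrained to stay on the control side of the abnormal mean
#' (the side implied by the initialisation), so components cannot swap
#' roles.
#'
#' @param values Numeric biomarker values (controls and patients pooled).
#' @param group_labels Character vector, `"control"` vs anything else.
#' @param max_iter,tol EM controls.
#' @param biomarker Optional label stored in the fit.
#' @return A `progmod_mixture` with Gaussian densities, mixing weight
#'   `pi` (probability abnormal), and diagnostics (`converged`,
#'   `uninformative`, parameter values).
#' @export
fit_gaussian_mixture <- function(values, group_labels, max_iter = 500,
                                 tol = 1e-8, biomarker = NULL) {
  ok <- !is.na(values)
  values <- values[ok]; group_labels <- group_labels[ok]
  is_ctl <- group_labels == "control"
  if (!any(is_ctl) || !any(!is_ctl)) {
    abort("need both control and patient values")
  }
  mu_ctl <- mean(values[is_ctl]); sd_ctl <- max(sd(values[is_ctl]), 1e-6)
  mu_n <- mu_ctl; sd_n <- sd_ctl
  mu_a <- mean(values[!is_ctl]); sd_a <- max(sd(values[!is_ctl]), 1e-6)
  side <- sign(mu_n - mu_a) # normal mean stays on this side of abnormal mean
  if (side == 0) side <- 1
  pi_a <- 0.5
  sd_floor <- max(sd(values) * 1e-3, 1e-9)

  ll_old <- -Inf; converged <- FALSE; n_clamped <- 0L
  for (it in seq_len(max_iter)) {
    fa <- dnorm(values, mu_a, sd_a); fn <- dnorm(values, mu_n, sd_n)
    denom <- pi_a * fa + (1 - pi_a) * fn
    denom[denom <= 0] <- 1e-300
    r <- pi_a * fa / denom # responsibility of abnormal component
    ll <- sum(log(denom))
    if (is.finite(ll) && abs(ll - ll_old) < tol * (1 + abs(ll))) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    pi_a <- mean(r)
    if (sum(r) > 0) {
      mu_a <- sum(r * values) / sum(r)
      sd_a <- max(sqrt(sum(r * (values - mu_a)^2) / sum(r)), sd_floor)
    }
    if (sum(1 - r) > 0) {
      mu_n <- sum((1 - r) * values) / sum(1 - r)
      sd_n <- max(sqrt(sum((1 - r) * (values - mu_n)^2) / sum(1 - r)), sd_floor)
    }
    # the normal component tracks the control distribution: its mean and SD
    # may drift only moderately from the control estimates
    mu_n <- min(max(mu_n, mu_ctl - 0.5 * sd_ctl), mu_ctl + 0.5 * sd_ctl)
    sd_n <- min(max(sd_n, 0.5 * sd_ctl), 1.5 * sd_ctl)
    # the abnormal mean stays on the abnormal side of the normal mean;
    # a persistently binding constraint means the components coincide
    if (side * (mu_n - mu_a) < 0) {
      mu_a <- mu_n
      n_clamped <- n_clamped + 1L
      if (n_clamped >= 3L) {
        converged <- TRUE
        break
      }
    }
    pi_a <- min(max(pi_a, 1e-6), 1 - 1e-6)
  }
  if (!converged) warn("Gaussian mixture EM did not converge; returning best iterate")
  # an abnormal component within ~1.5 control SDs of the control mean
  # carries little event information; flagged (but still usable)
  uninformative <- abs(mu_a - mu_ctl) < 1.5 * sd_ctl || pi_a < 0.01
  force(mu_n); force(sd_n); force(mu_a); force(sd_a)
  new_mixture_fit(
    biomarker, "gaussian",
    dnorm_fun = function(x) dnorm(x, mu_n, sd_n),
    dabn_fun = function(x) dnorm(x, mu_a, sd_a),
    pi = pi_a,
    diagnostics = list(mu_normal = mu_n, sd_normal = sd_n,
                       mu_abnormal = mu_a, sd_abnormal = sd_a,
                       converged = converged, uninformative = uninformative,
                       n_iter = it))
}

# weighted Gaussian KDE with Silverman bandwidth on the effective sample
weighted_kde <- function(x, w, bw = NULL) {
  w <- w / sum(w)
  if (is.null(bw)) {
    n_eff <- 1 / sum(w^2)
    mu <- sum(w * x)
    sdev <- sqrt(max(sum(w * (x - mu)^2), 1e-12))
    iqr_w <- unname(diff(Hmisc_wtd_quantile(x, w, c(0.25, 0.75))))
    sig <- min(sdev, if (iqr_w > 0) iqr_w / 1.349 else sdev)
    bw <- max(0.9 * sig * n_eff^(-1 / 5), 1e-6 * (max(x) - min(x) + 1))
  }
  force(x); force(w); force(bw)
  f <- function(q) {
    vapply(q, function(qi) sum(w * dnorm(qi, x, bw)), 0)
  }
  attr(f, "bw") <- bw
  f
}

# weighted quantile (type-7-free simple interpolation); avoids a Hmisc dep
Hmisc_wtd_quantile <- function(x, w, probs) {
  o <- order(x)
  x <- x[o]; w <- w[o] / sum(w)
  cw <- cumsum(w)
  vapply(probs, function(p) x[which(cw >= p)[1]], 0)
}

#' Kernel-density mixture for a cognitive biomarker
#'
#' Two-component mixture whose normal and abnormal densities are weighted
#' Gaussian-kernel density estimates, suited to bounded, floored or
#' skewed score distributions. Fitting alternates between (a) computing
#' each point's responsibility of being abnormal from the relative
#' component densities and (b) refitting each component KDE with those
#' responsibilities as weights, starting from the control/patient labels,
#' until hard assignments stabilise. Bandwidths follow Silverman's rule
#' on the responsibility-weighted sample.
#'
#' @inheritParams fit_gaussian_mixture
#' @param max_iter Maximum alternations.
#' @return A `progmod_mixture` with KDE densities.
#' @export
fit_kde_mixture <- function(values, group_labels, max_iter = 50,
                            biomarker = NULL) {
  ok <- !is.na(values)
  values <- values[ok]; group_labels <- group_labels[ok]
  is_ctl <- group_labels == "control"
  if (!any(is_ctl) || !any(!is_ctl)) abort("need both control and patient values")

  r <- as.numeric(!is_ctl) # responsibility of abnormal component
  r <- 0.9 * r + 0.05
  assign_old <- r >= 0.5
  pi_a <- mean(r)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    f_a <- weighted_kde(values, r)
    f_n <- weighted_kde(values, 1 - r)
    fa <- pmax(f_a(values), 1e-300)
    fn <- pmax(f_n(values), 1e-300)
    r_new <- pi_a * fa / (pi_a * fa + (1 - pi_a) * fn)
    # controls keep at least half their weight on the normal component
    r_new[is_ctl] <- pmin(r_new[is_ctl], 0.5)
    assign_new <- r_new >= 0.5
    pi_a <- min(max(mean(r_new), 1e-6), 1 - 1e-6)
    r <- r_new
    if (identical(assign_new, assign_old)) {
      converged <- TRUE
      break
    }
    assign_old <- assign_new
  }
  if (!converged) warn("KDE mixture assignments did not stabilise; returning last iterate")
  f_a <- weighted_kde(values, r)
  f_n <- weighted_kde(values, 1 - r)
  new_mixture_fit(
    biomarker, "kde", dnorm_fun = f_n, dabn_fun = f_a, pi = pi_a,
    diagnostics = list(bw_normal = attr(f_n, "bw"), bw_abnormal = attr(f_a, "bw"),
                       converged = converged, n_iter = it))
}

#' Fit mixtures for every biomarker in a table
#'
#' @param table Cohort tibble with `group` (controls vs patients).
#' @param biomarkers Biomarker columns.
#' @param flavour `"gaussian"` or `"kde"`, recycled per biomarker; volume
#'   biomarkers conventionally use `"gaussian"` and cognitive ones
#'   `"kde"`.
#' @param baseline_only Use only first visits (the EBM is cross-sectional).
#' @return Named list of `progmod_mixture` fits.
#' @export
fit_mixtures <- function(table, biomarkers, flavour = "gaussian",
                         baseline_only = TRUE) {
  if (baseline_only && "visit_index" %in% names(table)) {
    table <- table |>
      group_by(.data$subject_id) |>
      slice_min(.data$visit_index, n = 1, with_ties = FALSE) |>
      ungroup()
  }
  flavour <- rep_len(flavour, length(biomarkers))
  fits <- lapply(seq_along(biomarkers), function(i) {
    b <- biomarkers[i]
    if (flavour[i] == "kde") {
      fit_kde_mixture(table[[b]], table$group, biomarker = b)
    } else {
      fit_gaussian_mixture(table[[b]], table$group, biomarker = b)
    }
  })
  setNames(fits, biomarkers)
}
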