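#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a GP rate-of-change model
#'
#' @param x A `progmod_rate_model`.
#' @param ... Unused.
#' @return Tibble with `value`, `rate`, `lo95`, `hi95`.
#' @export
tidy.progmod_rate_model <- function(x, ...) {
  tibble(value = x$grid, rate = x$rate, lo95 = x$lo95, hi95 = x$hi95)
}

#' @rdname tidy.progmod_rate_model
#' @return For `glance()`: one-row tibble of hyperparameters and fit size.
#' @export
glance.progmod_rate_model <- function(x, ...) {
  tibble(n_subjects = length(x$x), length_scale = x$hyper$ell,
         signal_sd = sqrt(x$hyper$sf2), noise_sd = sqrt(x$hyper$sn2),
         neg_log_marginal_lik = x$hyper$nlml)
}

#' Tidy a reconstructed trajectory
#'
#' @param x A `progmod_trajectory`.
#' @param ... Unused.
#' @return Tibble with `time`, `value` and (if anchored) `z`.
#' @export
tidy.progmod_trajectory <- function(x, ...) {
  out <- tibble(time = x$time, value = x$value)
  if (x$anchored) out$z <- x$z
  out
}

#' @rdname tidy.progmod_trajectory
#' @export
glance.progmod_trajectory <- function(x, ...) {
  tibble(anchored = x$anchored, direction = x$direction,
         t0_threshold = x$t0_threshold,
         value_low = x$value_low, value_high = x$value_high,
         t_min = min(x$time), t_max = max(x$time))
}

#' Tidy a mixture fit
#'
#' Evaluates the normal and abnormal densities and `p(E|x)` on a grid.
#'
#' @param x A `progmod_mixture`.
#' @param range Evaluation range (defaults to the component means +/- 4
#'   SD for Gaussian fits, or is required for KDE fits).
#' @param n Grid size.
#' @param ... Unused.
#' @return Tibble with `value`, `density_normal`, `density_abnormal`,
#'   `prob_abnormal`.
#' @export
tidy.progmod_mixture <- function(x, range = NULL, n = 200, ...) {
  if (is.null(range)) {
    d <- x$diagnostics
    if (!is.null(d$mu_normal)) {
      range <- c(min(d$mu_normal - 4 * d$sd_normal, d$mu_abnormal - 4 * d$sd_abnormal),
                 max(d$mu_normal + 4 * d$sd_normal, d$mu_abnormal + 4 * d$sd_abnormal))
    } else {
      abort("`range` must be given for KDE mixtures")
    }
  }
  g <- seq(range[1], range[2], length.out = n)
  tibble(value = g, density_normal = x$normal_density(g),
         density_abnormal = x$abnormal_density(g),
         prob_abnormal = prob_abnormal(x, g))
}

#' @rdname tidy.progmod_mixture
#' @export
glance.progmod_mixture <- function(x, ...) {
  tibble(biomarker = x$biomarker %||% NA_character_, flavour = x$flavour,
         pi_abnormal = x$pi,
         converged = isTRUE(x$diagnostics$converged),
         uninformative = isTRUE(x$diagnostics$uninformative))
}

#' Tidy an MCMC chain over sequences
#'
#' @param x A `progmod_chain`.
#' @param ... Unused.
#' @return Long tibble of position samples (`sample`, `biomarker`,
#'   `position`).
#' @export
tidy.progmod_chain <- function(x, ...) position_samples(x)

#' @rdname tidy.progmod_chain
#' @export
glance.progmod_chain <- function(x, ...) {
  tibble(n_samples = nrow(x$samples), n_events = ncol(x$samples),
         acceptance_rate = x$acceptance_rate, thinning = x$thinning,
         seed = x$seed)
}

#' Tidy a positional variance matrix
#'
#' @param x A `progmod_posvar`.
#' @param ... Unused.
#' @return Long tibble with `biomarker`, `position`, `probability`.
#' @export
tidy.progmod_posvar <- function(x, ...) {
  m <- unclass(x)
  tibble(biomarker = rep(rownames(m), times = ncol(m)),
         position = rep(seq_len(ncol(m)), each = nrow(m)),
         probability = as.vector(m))
}
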