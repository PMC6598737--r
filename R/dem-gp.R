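# Gaussian-process regression of rate of change on biomarker value.
# Squared-exponential kernel plus observation noise; hyperparameters by
# maximising the log marginal likelihood over multiple seeded restarts.

se_kernel <- function(x1, x2, ell, sf2) {
  d <- outer(x1, x2, `-`)
  sf2 * exp(-0.5 * (d / ell)^2)
}

# negative log marginal likelihood; theta = log(ell, sf, sn)
gp_nlml <- function(theta, x, y) {
  ell <- exp(theta[1]); sf2 <- exp(2 * theta[2]); sn2 <- exp(2 * theta[3])
  n <- length(x)
  K <- se_kernel(x, x, ell, sf2) + diag(sn2, n)
  ch <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  alpha <- backsolve(ch, forwardsolve(t(ch), y))
  as.numeric(0.5 * sum(y * alpha) + sum(log(diag(ch))) + 0.5 * n * log(2 * pi))
}

gp_fit_hyper <- function(x, y, n_restarts = 5, seed = 1L) {
  xr <- diff(range(x))
  ys <- sd(y)
  if (xr <= 0) abort("degenerate value range: cannot fit rate model")
  if (ys == 0) ys <- max(abs(y), 1e-8)
  starts <- with_seed(seed, {
    base <- c(log(xr / 3), log(ys), log(ys / 3))
    rbind(base,
          matrix(rep(base, n_restarts - 1), ncol = 3, byrow = TRUE) +
            matrix(rnorm(3 * (n_restarts - 1), 0, 1), ncol = 3))
  })
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      optim(starts[i, ], gp_nlml, x = x, y = y, method = "L-BFGS-B",
            lower = c(log(xr / 50), log(ys / 100), log(ys / 1e4)),
            upper = c(log(xr * 10), log(ys * 100), log(ys * 10))),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) abort("GP hyperparameter optimisation failed on all restarts")
  list(ell = exp(best$par[1]), sf2 = exp(2 * best$par[2]),
       sn2 = exp(2 * best$par[3]), nlml = best$value)
}

gp_predict <- function(x, y, hyper, xstar) {
  n <- length(x)
  K <- se_kernel(x, x, hyper$ell, hyper$sf2) + diag(hyper$sn2, n)
  ch <- chol(K)
  alpha <- backsolve(ch, forwardsolve(t(ch), y))
  Ks <- se_kernel(xstar, x, hyper$ell, hyper$sf2)
  mu <- as.numeric(Ks %*% alpha)
  v <- forwardsolve(t(ch), t(Ks))
  var_f <- pmax(hyper$sf2 - colSums(v^2), 0)
  list(mean = mu, sd = sqrt(var_f))
}
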