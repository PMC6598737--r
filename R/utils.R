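#' @importFrom rlang abort warn inform %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom tidyr pivot_longer pivot_wider
#' @importFrom purrr map map_dbl map_lgl imap list_rbind
#' @importFrom stats approx coef dnorm lm median optim plogis predict qnorm
#'   quantile rbinom rnorm runif sd setNames t.test var wilcox.test complete.cases
#' @importFrom utils head tail write.csv read.csv
NULL

# numerically stable log(sum(exp(x)))
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# cumulative sums along rows of a matrix (over columns), vectorised over rows
row_cumsum <- function(m) {
  if (ncol(m) > 1) {
    for (j in 2:ncol(m)) m[, j] <- m[, j - 1L] + m[, j]
  }
  m
}

stopifnot_scalar_number <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min) {
    abort(sprintf("`%s` must be a single number >= %s", name, format(min)))
  }
  invisible(x)
}

# Derive an independent child seed from a base seed and a stream label.
# Keeps results reproducible when one seed must feed several stochastic
# stages without the stages sharing a stream.
child_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.double(seed) * 48271 + h * 1103 + 12345) %% 2147483647)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
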