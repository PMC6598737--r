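# Event-based model over orderings of biomarker abnormality events.
#
# Likelihood of a data matrix X (subjects x biomarkers, NA allowed) under
# an event sequence S with a uniform prior over stages k = 0..N:
#   P(X | S) = prod_j (1/(N+1)) sum_k prod_{i<=k} p(x_{S(i),j} | E)
#                                      prod_{i>k}  p(x_{S(i),j} | not E)
# Missing values contribute a factor 1 (marginalised out).

DENSITY_FLOOR <- 1e-12

# log densities under abnormal (E) and normal (notE) components;
# NA values become 0 so a missing measurement multiplies the likelihood by 1
ebm_log_densities <- function(X, fits) {
  X <- as_ebm_matrix(X, names(fits))
  logE <- matrix(0, nrow(X), ncol(X), dimnames = dimnames(X))
  logN <- logE
  for (b in colnames(X)) {
    x <- X[, b]
    obs <- !is.na(x)
    logE[obs, b] <- log(pmax(fits[[b]]$abnormal_density(x[obs]), DENSITY_FLOOR))
    logN[obs, b] <- log(pmax(fits[[b]]$normal_density(x[obs]), DENSITY_FLOOR))
  }
  list(logE = logE, logN = logN, biomarkers = colnames(X))
}

as_ebm_matrix <- function(X, biomarkers) {
  if (is.matrix(X)) {
    if (is.null(colnames(X))) colnames(X) <- biomarkers
    return(X[, biomarkers, drop = FALSE])
  }
  m <- as.matrix(as.data.frame(X)[biomarkers])
  rn <- if ("subject_id" %in% names(X)) X$subject_id else NULL
  rownames(m) <- rn
  m
}

# per-subject log-likelihood vector for a sequence given density matrices
seq_loglik_subjects <- function(ld, ord) {
  A <- ld$logE[, ord, drop = FALSE]
  B <- ld$logN[, ord, drop = FALSE]
  cumA <- row_cumsum(A)
  cumB <- row_cumsum(B)
  N <- ncol(A)
  totB <- cumB[, N]
  # stage sums: k = 0 .. N, columns of (J x N+1)
  M <- cbind(totB, cumA + (totB - cumB))
  mx <- apply(M, 1, max)
  mx + log(rowSums(exp(M - mx))) - log(N + 1)
}

seq_loglik_fast <- function(ld, ord) sum(seq_loglik_subjects(ld, ord))

#' Log-likelihood of an event sequence
#'
#' @param X Subjects-by-biomarkers data matrix or tibble (baseline
#'   values; `NA` allowed and marginalised out).
#' @param S Event sequence: character vector of biomarker names, earliest
#'   event first (or a `progmod_sequence`).
#' @param fits Named list of [fit_gaussian_mixture()] /
#'   [fit_kde_mixture()] results covering every biomarker in `S`.
#' @return Scalar log-likelihood.
#' @export
sequence_log_likelihood <- function(X, S, fits) {
  S <- as_sequence_labels(S)
  if (!setequal(S, names(fits)) || anyDuplicated(S)) {
    abort("S must be a permutation of the fitted biomarkers")
  }
  ld <- ebm_log_densities(X, fits)
  seq_loglik_fast(ld, match(S, ld$biomarkers))
}

as_sequence_labels <- function(S) {
  if (inherits(S, "progmod_sequence")) S$sequence else as.character(S)
}

new_sequence <- function(labels, loglik) {
  structure(list(sequence = labels, log_likelihood = loglik),
            class = "progmod_sequence")
}

#' @export
print.progmod_sequence <- function(x, ...) {
  cat("Event sequence (logL =", format(x$log_likelihood, digits = 6), "):\n  ",
      paste(x$sequence, collapse = " < "), "\n")
  invisible(x)
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (k in seq_len(n)) {
    rows <- r + seq_len(nrow(sub))
    out[rows, 1] <- k
    rest <- seq_len(n)[-k]
    out[rows, -1] <- matrix(rest[sub], nrow(sub))
    r <- r + nrow(sub)
  }
  out
}

greedy_ascent <- function(ld, ord) {
  N <- length(ord)
  ll <- seq_loglik_fast(ld, ord)
  repeat {
    best_ll <- ll; best_ord <- NULL
    for (i in seq_len(N - 1)) for (j in (i + 1):N) {
      cand <- ord
      cand[c(i, j)] <- cand[c(j, i)]
      cll <- seq_loglik_fast(ld, cand)
      if (cll > best_ll) {
        best_ll <- cll; best_ord <- cand
      }
    }
    if (is.null(best_ord)) break
    ord <- best_ord; ll <- best_ll
  }
  list(ord = ord, ll = ll)
}

#' Maximum-likelihood event sequence
#'
#' Greedy ascent over pairwise swaps from multiple random starting
#' permutations (default), or exhaustive enumeration of all `N!`
#' permutations for `N <= 7`.
#'
#' @inheritParams sequence_log_likelihood
#' @param n_starts Number of random restarts for the greedy search.
#' @param seed Seed for the restarts.
#' @param method `"greedy"` or `"exhaustive"`.
#' @return A `progmod_sequence`.
#' @export
find_ml_sequence <- function(X, fits, n_starts = 10, seed = 1L,
                             method = c("greedy", "exhaustive")) {
  method <- match.arg(method)
  ld <- ebm_log_densities(X, fits)
  N <- length(ld$biomarkers)
  if (N < 1) abort("need at least one biomarker")
  if (N == 1) {
    return(new_sequence(ld$biomarkers, seq_loglik_fast(ld, 1L)))
  }
  if (method == "exhaustive") {
    if (N > 7) abort("exhaustive search is limited to 7 biomarkers")
    perms <- all_permutations(N)
    lls <- vapply(seq_len(nrow(perms)), function(i) seq_loglik_fast(ld, perms[i, ]), 0)
    best <- which.max(lls)
    return(new_sequence(ld$biomarkers[perms[best, ]], lls[best]))
  }
  starts <- with_seed(seed, {
    lapply(seq_len(n_starts), function(i) sample.int(N))
  })
  best <- NULL
  for (st in starts) {
    res <- greedy_ascent(ld, st)
    if (is.null(best) || res$ll > best$ll) best <- res
  }
  new_sequence(ld$biomarkers[best$ord], best$ll)
}

#' MCMC posterior sampling over event sequences
#'
#' Metropolis-Hastings with random pairwise-swap proposals (symmetric, so
#' acceptance probability is `min(1, L'/L)`). Every sample is stored;
#' thin with [thin_chain()] before rank-based testing.
#'
#' @inheritParams sequence_log_likelihood
#' @param init Initial sequence (e.g. the ML sequence).
#' @param n_iter Number of iterations.
#' @param seed Seed.
#' @return A `progmod_chain`: integer sample matrix (`n_iter` rows, one
#'   column per sequence position), per-sample log-likelihoods,
#'   acceptance rate, biomarker labels, seed and thinning factor.
#' @export
mcmc_sample <- function(X, fits, init, n_iter = 100000, seed = 1L) {
  if (n_iter < 1) abort("n_iter must be >= 1")
  ld <- ebm_log_densities(X, fits)
  N <- length(ld$biomarkers)
  ord <- match(as_sequence_labels(init), ld$biomarkers)
  if (anyDuplicated(ord) || anyNA(ord) || length(ord) != N) {
    abort("init must be a permutation of the fitted biomarkers")
  }
  with_seed(seed, {
    samples <- matrix(0L, n_iter, N)
    lls <- numeric(n_iter)
    ll <- seq_loglik_fast(ld, ord)
    n_acc <- 0L
    ij <- matrix(sample.int(N, 2 * n_iter, replace = TRUE), ncol = 2)
    us <- runif(n_iter)
    for (it in seq_len(n_iter)) {
      i <- ij[it, 1]; j <- ij[it, 2]
      if (i != j) {
        cand <- ord
        cand[c(i, j)] <- cand[c(j, i)]
        cll <- seq_loglik_fast(ld, cand)
        if (cll >= ll || us[it] < exp(cll - ll)) {
          ord <- cand; ll <- cll; n_acc <- n_acc + 1L
        }
      }
      samples[it, ] <- ord
      lls[it] <- ll
    }
    structure(
      list(samples = samples, log_lik = lls,
           acceptance_rate = n_acc / n_iter,
           biomarkers = ld$biomarkers, seed = seed, thinning = 1L),
      class = "progmod_chain")
  })
}

#' @export
print.progmod_chain <- function(x, ...) {
  cat(sprintf("MCMC chain: %d samples of %d-event sequences (thinning %d, acceptance %.2f)\n",
              nrow(x$samples), ncol(x$samples), x$thinning, x$acceptance_rate))
  invisible(x)
}

#' Thin an MCMC chain
#'
#' Keeps samples at indices 1, 1 + factor, 1 + 2*factor, ... Adjacent
#' MCMC samples are correlated; rank-based tests on positions should use
#' a thinned chain (1 every 100 by default).
#'
#' @param chain A `progmod_chain`.
#' @param factor Thinning factor (>= 1).
#' @return The thinned `progmod_chain`.
#' @export
thin_chain <- function(chain, factor = 100) {
  if (factor < 1) abort("factor must be >= 1")
  keep <- seq(1L, nrow(chain$samples), by = as.integer(factor))
  chain$samples <- chain$samples[keep, , drop = FALSE]
  chain$log_lik <- chain$log_lik[keep]
  chain$thinning <- chain$thinning * as.integer(factor)
  chain
}

sequences_to_matrix <- function(sequences, biomarkers = NULL) {
  if (inherits(sequences, "progmod_chain")) {
    return(list(m = sequences$samples, biomarkers = sequences$biomarkers))
  }
  if (is.matrix(sequences)) {
    return(list(m = sequences, biomarkers = biomarkers %||% colnames(sequences)))
  }
  seqs <- lapply(sequences, as_sequence_labels)
  bms <- sort(seqs[[1]])
  ok <- vapply(seqs, function(s) setequal(s, bms) && !anyDuplicated(s), TRUE)
  if (!all(ok)) abort("sequences cover inconsistent biomarker sets")
  m <- do.call(rbind, lapply(seqs, function(s) match(s, bms)))
  list(m = m, biomarkers = bms)
}

#' Positional variance matrix of an ordering posterior
#'
#' `P[event, position]` = fraction of sampled sequences that place the
#' event at that position. Since every sample is a permutation, rows and
#' columns each sum to one.
#'
#' @param sequences A `progmod_chain` (use a thinned chain), a list of
#'   sequences, or an integer sample matrix.
#' @return A `progmod_posvar` matrix (events in rows, positions in
#'   columns).
#' @export
positional_variance <- function(sequences) {
  sm <- sequences_to_matrix(sequences)
  N <- ncol(sm$m)
  P <- matrix(0, N, N, dimnames = list(sm$biomarkers, paste0("pos", seq_len(N))))
  for (pos in seq_len(N)) {
    tab <- tabulate(sm$m[, pos], nbins = N)
    P[, pos] <- tab / nrow(sm$m)
  }
  structure(P, class = c("progmod_posvar", "matrix"))
}

#' Per-biomarker position samples from a chain or sequence set
#'
#' Long tibble of each biomarker's position (rank, 1 = earliest) in every
#' sampled/replicated sequence; input to the rank-based ordering tests.
#'
#' @inheritParams positional_variance
#' @param group Optional group label column to attach.
#' @return Tibble with `biomarker`, `sample`, `position` (and `group`).
#' @export
position_samples <- function(sequences, group = NULL) {
  sm <- sequences_to_matrix(sequences)
  N <- ncol(sm$m)
  pos <- t(apply(sm$m, 1, order)) # position of event e in each sample
  out <- tibble(
    sample = rep(seq_len(nrow(sm$m)), times = N),
    biomarker = rep(sm$biomarkers, each = nrow(sm$m)),
    position = as.vector(pos))
  if (!is.null(group)) out$group <- group
  out
}

#' Bootstrap replicate event sequences
#'
#' Subject-level resampling with replacement; per replicate the mixtures
#' are refitted and the ML sequence re-estimated. Replicates missing an
#' entire group are redrawn (at most 10 attempts each).
#'
#' @param table Baseline cohort tibble with `subject_id`, `group` and the
#'   biomarker columns.
#' @param biomarkers Biomarker columns.
#' @param flavour Mixture flavour per biomarker (recycled).
#' @param n_boot Number of replicates.
#' @param seed Seed.
#' @param n_starts Greedy restarts per replicate.
#' @return A list of `progmod_sequence` objects (class
#'   `progmod_sequence_set`).
#' @export
bootstrap_sequences <- function(table, biomarkers, flavour = "gaussian",
                                n_boot = 100, seed = 1L, n_starts = 5) {
  if (n_boot < 1) abort("n_boot must be >= 1")
  if ("visit_index" %in% names(table)) {
    table <- table |>
      group_by(.data$subject_id) |>
      slice_min(.data$visit_index, n = 1, with_ties = FALSE) |>
      ungroup()
  }
  groups_present <- unique(table$group)
  with_seed(child_seed(seed, "ebm_boot"), {
    reps <- vector("list", n_boot)
    for (b in seq_len(n_boot)) {
      for (attempt in seq_len(10)) {
        rows <- sample.int(nrow(table), nrow(table), replace = TRUE)
        if (setequal(unique(table$group[rows]), groups_present)) break
        if (attempt == 10) abort("could not draw a bootstrap replicate containing every group")
      }
      boot <- table[rows, ]
      fits <- fit_mixtures(boot, biomarkers, flavour, baseline_only = FALSE)
      reps[[b]] <- find_ml_sequence(boot, fits, n_starts = n_starts,
                                    seed = sample.int(2^30, 1))
    }
    structure(reps, class = "progmod_sequence_set")
  })
}

#' Stage subjects along an event sequence
#'
#' Posterior over stages `k = 0..N` for each subject:
#' `P(k | x) prop prod_{i<=k} p(x_i | E) prod_{i>k} p(x_i | not E)` under
#' a uniform stage prior; the reported stage is the posterior mode (ties
#' broken towards the smallest k). Subjects with no usable biomarker are
#' skipped with a warning.
#'
#' @inheritParams sequence_log_likelihood
#' @return Tibble with `subject_id`, `stage`, and a `posterior`
#'   list-column of length-(N+1) stage posteriors.
#' @export
stage_subjects_ebm <- function(X, S, fits) {
  S <- as_sequence_labels(S)
  ld <- ebm_log_densities(X, fits)
  ord <- match(S, ld$biomarkers)
  if (anyDuplicated(ord) || anyNA(ord)) {
    abort("S must be a permutation of the fitted biomarkers")
  }
  A <- ld$logE[, ord, drop = FALSE]
  B <- ld$logN[, ord, drop = FALSE]
  observed <- !is.na(as_ebm_matrix(X, ld$biomarkers))[, ord, drop = FALSE]
  cumA <- row_cumsum(A)
  cumB <- row_cumsum(B)
  N <- ncol(A)
  totB <- cumB[, N]
  M <- cbind(totB, cumA + (totB - cumB)) # J x (N+1) stage log-scores
  ids <- rownames(M) %||% as.character(seq_len(nrow(M)))
  res <- lapply(seq_len(nrow(M)), function(j) {
    if (!any(observed[j, ])) {
      warn(sprintf("subject %s has no usable biomarker; stage undefined", ids[j]))
      return(NULL)
    }
    lp <- unname(M[j, ]) - logsumexp(M[j, ])
    post <- exp(lp)
    tibble(subject_id = ids[j], stage = which.max(post) - 1L,
           posterior = list(post))
  })
  list_rbind(res)
}
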