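# Shared fixture builders. Everything is generated in code at test time.

# one-biomarker patient cohort on a known logistic trajectory
logistic_cohort_config <- function(noise_sd = 0, n_patients = 100,
                                   n_controls = 50, n_visits = 3,
                                   healthy_sd = 0, seed = 1L,
                                   latent_range = c(-12, 12)) {
  spec <- list(traj = biomarker_spec(
    "traj", "decreasing", onset_time = 0, transition_duration = 10,
    healthy_mean = 0, healthy_sd = healthy_sd, abnormal_shift = -5,
    noise_sd = noise_sd))
  vp <- c(rep(0, n_visits - 1), 1)
  cohort_config(biomarkers = list(g = spec), n_controls = n_controls,
                n_patients = c(g = n_patients), visits_per_subject = vp,
                dropout_prob_per_visit = 0, latent_time_range = latent_range,
                seed = seed)
}

# K staggered decreasing biomarkers for one patient group, strong separation
staggered_config <- function(n_biomarkers = 5, onset_gap = 2, shift = -5,
                             noise_sd = 0.5, healthy_sd = 0.5,
                             n_patients = 200, n_controls = 100,
                             n_visits = 1, seed = 1L) {
  names <- paste0("bm", seq_len(n_biomarkers))
  onsets <- setNames((seq_len(n_biomarkers) - 1) * onset_gap, names)
  specs <- lapply(names, function(nm) {
    biomarker_spec(nm, "decreasing", onset_time = onsets[[nm]],
                   transition_duration = 6, healthy_mean = 0,
                   healthy_sd = healthy_sd, abnormal_shift = shift,
                   noise_sd = noise_sd)
  })
  vp <- c(rep(0, n_visits - 1), 1)
  cohort_config(
    biomarkers = list(g = setNames(specs, names)),
    n_controls = n_controls, n_patients = c(g = n_patients),
    visits_per_subject = vp, dropout_prob_per_visit = 0,
    latent_time_range = c(-8, (n_biomarkers - 1) * onset_gap + 8),
    seed = seed)
}

baseline_visits <- function(table) {
  table |>
    dplyr::group_by(subject_id) |>
    dplyr::slice_min(visit_index, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
}

# mixture fit with fixed density functions, for hand-computable likelihoods
constant_mixture <- function(normal_fun, abnormal_fun, pi = 0.5) {
  structure(list(biomarker = NULL, flavour = "gaussian",
                 normal_density = normal_fun, abnormal_density = abnormal_fun,
                 pi = pi, diagnostics = list()),
            class = "progmod_mixture")
}

# rate model with a prescribed mean rate on a value grid
fake_rate_model <- function(grid, rate) {
  structure(list(grid = grid, rate = rate,
                 lo95 = rate - 1e-6, hi95 = rate + 1e-6,
                 hyper = list(ell = 1, sf2 = 1, sn2 = 1e-6, nlml = NA),
                 x = grid, y = rate),
            class = "progmod_rate_model")
}

kendall_tau_orders <- function(order_a, order_b) {
  stats::cor(match(order_a, order_a), match(order_b, order_a),
             method = "kendall")
}
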