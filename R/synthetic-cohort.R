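#' Describe a single biomarker's latent trajectory
#'
#' A biomarker transitions from a healthy plateau to an abnormal plateau
#' along a latent disease-time axis, following a logistic (sigmoid) curve.
#' `onset_time` is the midpoint of the transition and
#' `transition_duration` the window containing ~95% of the change
#' (the logistic scale is `transition_duration / 6`).
#'
#' @param name Biomarker label.
#' @param direction `"decreasing"` (volumes, most scores) or `"increasing"`
#'   (ventricles, timed tests): the direction in which abnormality moves.
#' @param onset_time Transition midpoint on the latent axis (years).
#' @param transition_duration Years over which ~95% of the transition occurs.
#' @param healthy_mean,healthy_sd Healthy plateau level and between-subject
#'   spread (biomarker units).
#' @param abnormal_shift Signed total change from healthy to abnormal
#'   plateau; its sign must match `direction`.
#' @param noise_sd Within-visit measurement noise SD.
#' @param floor_value Minimum attainable value (cognitive scores), or `NA`.
#' @return A `biomarker_spec` list.
#' @export
#' @examples
#' biomarker_spec("hippocampal", "decreasing", onset_time = 4,
#'                transition_duration = 8, abnormal_shift = -3, noise_sd = 0.4)
biomarker_spec <- function(name, direction = c("decreasing", "increasing"),
                           onset_time, transition_duration,
                           healthy_mean = 0, healthy_sd = 0,
                           abnormal_shift, noise_sd = 0,
                           floor_value = NA_real_) {
  direction <- match.arg(direction)
  stopifnot_scalar_number(transition_duration, "transition_duration")
  if (transition_duration <= 0) abort("`transition_duration` must be > 0")
  stopifnot_scalar_number(noise_sd, "noise_sd", min = 0)
  stopifnot_scalar_number(healthy_sd, "healthy_sd", min = 0)
  if (direction == "decreasing" && abnormal_shift >= 0) {
    abort(sprintf("biomarker '%s': decreasing direction requires abnormal_shift < 0", name))
  }
  if (direction == "increasing" && abnormal_shift <= 0) {
    abort(sprintf("biomarker '%s': increasing direction requires abnormal_shift > 0", name))
  }
  structure(
    list(name = name, direction = direction, onset_time = onset_time,
         transition_duration = transition_duration,
         healthy_mean = healthy_mean, healthy_sd = healthy_sd,
         abnormal_shift = abnormal_shift, noise_sd = noise_sd,
         floor_value = floor_value),
    class = "biomarker_spec"
  )
}

#' Noise-free biomarker value at a latent disease time
#'
#' Evaluates the generating sigmoid:
#' `healthy_mean + abnormal_shift * logistic((t - onset) / (duration/6))`.
#'
#' @param t Latent disease time(s), years.
#' @param spec A [biomarker_spec()].
#' @return Numeric vector of noise-free values.
#' @export
sigmoid_value <- function(t, spec) {
  stopifnot(inherits(spec, "biomarker_spec"))
  spec$healthy_mean +
    spec$abnormal_shift * plogis((t - spec$onset_time) / (spec$transition_duration / 6))
}

#' Configure a synthetic longitudinal cohort
#'
#' The cohort emulates a multi-centre longitudinal study: two patient
#' groups with group-specific event orderings (group-specific onset times
#' of the same biomarkers), controls held in the pre-onset regime, up to
#' six annual visits with independent per-visit dropout, additive linear
#' covariate effects (age, gender, TIV, scanner, site), between-subject
#' and within-visit Gaussian noise, and floor-censoring for biomarkers
#' with a floor value.
#'
#' @param biomarkers Named list (one element per patient group) of lists of
#'   [biomarker_spec()]s. All groups must share biomarker names and healthy
#'   parameters; onsets/durations may differ and define each group's
#'   ground-truth ordering.
#' @param n_controls,n_patients Number of controls; named vector of patient
#'   counts per group.
#' @param visits_per_subject Probability weights over 1..`length(.)` planned
#'   visits (default: all subjects planned for six visits).
#' @param visit_interval Years between visits.
#' @param dropout_prob_per_visit Independent probability of dropping out
#'   after each visit.
#' @param covariate_effects Named list of linear coefficients applied to
#'   every biomarker: `age` and `tiv` multiply centred covariates
#'   (age - 70, tiv - 1450); `gender` is the male-vs-female offset;
#'   `scanner` the 3T-vs-1.5T offset; `site` gives offsets
#'   `c(-1, 0, 1) * site` for the three sites.
#' @param latent_time_range Range (years) of patients' baseline latent
#'   disease times; controls sit fixed at the lower end.
#' @param seed Integer seed; the whole table is reproducible from it.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(biomarkers,
                          n_controls = 138,
                          n_patients = c(groupA = 117, groupB = 106),
                          visits_per_subject = c(0, 0, 0, 0, 0, 1),
                          visit_interval = 1,
                          dropout_prob_per_visit = 0.15,
                          covariate_effects = list(age = 0, gender = 0, tiv = 0,
                                                   scanner = 0, site = 0),
                          latent_time_range = c(-12, 15),
                          seed = 1L) {
  if (is.null(names(biomarkers)) || any(names(biomarkers) == "")) {
    abort("`biomarkers` must be a named list: one element per patient group")
  }
  nm <- lapply(biomarkers, function(g) vapply(g, `[[`, "", "name"))
  if (length(unique(lapply(nm, sort))) != 1L) {
    abort("all groups must share the same biomarker names")
  }
  if (n_controls < 0 || any(n_patients < 0)) abort("counts must be >= 0")
  if (dropout_prob_per_visit < 0 || dropout_prob_per_visit > 1) {
    abort("`dropout_prob_per_visit` must be in [0, 1]")
  }
  if (!setequal(names(biomarkers), names(n_patients))) {
    abort("`n_patients` names must match patient group names in `biomarkers`")
  }
  if (any(visits_per_subject < 0) || sum(visits_per_subject) <= 0) {
    abort("`visits_per_subject` must be nonnegative weights")
  }
  structure(
    list(biomarkers = biomarkers, n_controls = n_controls,
         n_patients = n_patients, visits_per_subject = visits_per_subject,
         visit_interval = visit_interval,
         dropout_prob_per_visit = dropout_prob_per_visit,
         covariate_effects = covariate_effects,
         latent_time_range = latent_time_range, seed = as.integer(seed)),
    class = "cohort_config"
  )
}

#' Default two-group study design
#'
#' Eight composite regional volumes (z-scale units) with an
#' occipital/parietal-first ordering in `groupA` and a
#' hippocampal/entorhinal-first ordering in `groupB`, mirroring the
#' posterior-first versus medial-temporal-first patterns of posterior
#' cortical atrophy and typical amnestic Alzheimer's disease.
#'
#' @param noise_sd Within-visit noise SD shared by all biomarkers.
#' @param healthy_sd Between-subject healthy spread shared by all biomarkers.
#' @param seed Seed stored in the config.
#' @param ... Passed on to [cohort_config()].
#' @return A `cohort_config`.
#' @export
default_cohort_config <- function(noise_sd = 0.6, healthy_sd = 0.8, seed = 1L, ...) {
  mk <- function(onsets) {
    imap(onsets, function(on, name) {
      dir <- if (name == "ventricle") "increasing" else "decreasing"
      biomarker_spec(
        name, direction = dir, onset_time = on, transition_duration = 10,
        healthy_mean = 0, healthy_sd = healthy_sd,
        abnormal_shift = if (dir == "increasing") 5 else -5,
        noise_sd = noise_sd
      )
    })
  }
  onsets_A <- c(occipital = 0, parietal = 1.5, temporal = 3, whole_brain = 4.5,
                ventricle = 6, frontal = 7.5, hippocampal = 9, entorhinal = 10.5)
  onsets_B <- c(hippocampal = 0, entorhinal = 1.5, temporal = 3, whole_brain = 4.5,
                ventricle = 6, frontal = 7.5, parietal = 9, occipital = 10.5)
  cohort_config(biomarkers = list(groupA = mk(onsets_A), groupB = mk(onsets_B)),
                seed = seed, ...)
}

covariate_contribution <- function(eff, age, gender, tiv, scanner, site) {
  (eff$age %||% 0) * (age - 70) +
    (eff$gender %||% 0) * (gender == "male") +
    (eff$tiv %||% 0) * (tiv - 1450) +
    (eff$scanner %||% 0) * (scanner == "3T") +
    (eff$site %||% 0) * (match(site, c("DRC", "UCSF", "HUVR")) - 2)
}

#' Generate a synthetic cohort with known ground truth
#'
#' Patients' baseline latent disease times are uniform over
#' `latent_time_range` (so the cross-section spans the disease course);
#' controls sit at the fixed pre-onset lower end. Observed value =
#' noise-free sigmoid + covariate contribution + subject-level healthy
#' offset + visit noise, clipped at the floor where one is declared.
#'
#' @param config A [cohort_config()].
#' @return A `progmod_cohort`: list with `$data` (tibble, one row per
#'   subject-visit), `$truth` (orderings, latent times, noise-free values)
#'   and `$config`.
#' @export
#' @examples
#' coh <- generate_cohort(default_cohort_config(seed = 42))
#' dplyr::count(coh$data, group)
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) abort("`config` must be a cohort_config")
  groups <- names(config$biomarkers)
  bm_names <- vapply(config$biomarkers[[1]], `[[`, "", "name")
  eff <- config$covariate_effects

  with_seed(config$seed, {
    subj <- list()
    idx <- 0L
    add_subjects <- function(n, group) {
      if (n == 0) return(NULL)
      tibble(
        subject_id = sprintf("S%04d", idx + seq_len(n)),
        group = group,
        age0 = rnorm(n, 70, 8),
        gender = sample(c("female", "male"), n, replace = TRUE),
        tiv = rnorm(n, 1450, 130),
        scanner = sample(c("1.5T", "3T"), n, replace = TRUE),
        site = sample(c("DRC", "UCSF", "HUVR"), n, replace = TRUE,
                      prob = c(0.5, 0.25, 0.25))
      )
    }
    for (g in groups) {
      s <- add_subjects(config$n_patients[[g]], g)
      idx <- idx + nrow(s %||% tibble())
      subj[[g]] <- s
    }
    s <- add_subjects(config$n_controls, "control")
    subj[["control"]] <- s
    subjects <- list_rbind(subj)

    ltr <- config$latent_time_range
    subjects$latent0 <- ifelse(subjects$group == "control", ltr[1],
                               runif(nrow(subjects), ltr[1], ltr[2]))

    # planned visits, then independent per-visit dropout (geometric waiting time)
    nv_max <- length(config$visits_per_subject)
    subjects$planned <- sample(seq_len(nv_max), nrow(subjects), replace = TRUE,
                               prob = config$visits_per_subject)
    p_drop <- config$dropout_prob_per_visit
    first_drop <- if (p_drop > 0) {
      stats::rgeom(nrow(subjects), p_drop) + 1L # visits attended before dropping
    } else rep(Inf, nrow(subjects))
    subjects$n_visits <- pmin(subjects$planned, first_drop)

    rep_idx <- rep(seq_len(nrow(subjects)), subjects$n_visits)
    k <- sequence(subjects$n_visits)
    visits <- tibble(
      subject_id = subjects$subject_id[rep_idx],
      group = subjects$group[rep_idx],
      visit_index = k,
      years_since_baseline = (k - 1) * config$visit_interval,
      age = subjects$age0[rep_idx] + (k - 1) * config$visit_interval,
      gender = subjects$gender[rep_idx],
      tiv = subjects$tiv[rep_idx],
      scanner = subjects$scanner[rep_idx],
      site = subjects$site[rep_idx],
      latent_time = ifelse(subjects$group[rep_idx] == "control",
                           subjects$latent0[rep_idx],
                           subjects$latent0[rep_idx] +
                             (k - 1) * config$visit_interval)
    )

    spec_group <- function(group) {
      if (group == "control") config$biomarkers[[1]] else config$biomarkers[[group]]
    }
    # subject-level healthy offsets, one per subject x biomarker
    offs <- matrix(rnorm(nrow(subjects) * length(bm_names)),
                   nrow(subjects), length(bm_names),
                   dimnames = list(subjects$subject_id, bm_names))

    clean <- visits[c("subject_id", "group", "visit_index", "latent_time")]
    for (b in seq_along(bm_names)) {
      nm <- bm_names[b]
      noisefree <- numeric(nrow(visits))
      observed <- numeric(nrow(visits))
      for (g in unique(visits$group)) {
        rows <- which(visits$group == g)
        sp <- spec_group(g)[[which(vapply(spec_group(g), `[[`, "", "name") == nm)]]
        nf <- sigmoid_value(visits$latent_time[rows], sp)
        cv <- covariate_contribution(eff, visits$age[rows], visits$gender[rows],
                                     visits$tiv[rows], visits$scanner[rows],
                                     visits$site[rows])
        ob <- nf + cv + sp$healthy_sd * offs[visits$subject_id[rows], b] +
          rnorm(length(rows), 0, sp$noise_sd)
        if (!is.na(sp$floor_value)) ob <- pmax(ob, sp$floor_value)
        noisefree[rows] <- nf
        observed[rows] <- ob
      }
      clean[[nm]] <- noisefree
      visits[[nm]] <- observed
    }

    orderings <- lapply(groups, function(g) ground_truth_ordering_impl(spec_group(g)))
    names(orderings) <- groups

    data <- visits |> select(-"latent_time")
    truth <- list(orderings = orderings,
                  latent = visits[c("subject_id", "group", "visit_index", "latent_time")],
                  noise_free = as_tibble(clean),
                  biomarkers = bm_names)
    structure(list(data = data, truth = truth, config = config),
              class = "progmod_cohort")
  })
}

ground_truth_ordering_impl <- function(specs) {
  onsets <- vapply(specs, `[[`, 0, "onset_time")
  labels <- vapply(specs, `[[`, "", "name")
  ord <- order(onsets, labels) # ties broken by label order
  tied <- anyDuplicated(onsets) > 0
  structure(labels[ord], tied = tied)
}

#' Ground-truth event ordering for a group
#'
#' Biomarkers sorted by generating onset time; ties broken by label order
#' and flagged via the `tied` attribute.
#'
#' @param truth The `$truth` element of a [generate_cohort()] result (or a
#'   whole `progmod_cohort`).
#' @param group Patient group label.
#' @return Character vector of biomarker names, earliest event first.
#' @export
ground_truth_ordering <- function(truth, group) {
  if (inherits(truth, "progmod_cohort")) truth <- truth$truth
  if (!group %in% names(truth$orderings)) {
    abort(sprintf("unknown group '%s'", group))
  }
  truth$orderings[[group]]
}

#' Write a cohort's table and ground truth to disk
#'
#' @param cohort A `progmod_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, "cohort.csv")
  js <- file.path(dir, "ground_truth.json")
  write.csv(cohort$data, csv, row.names = FALSE)
  truth <- cohort$truth
  jsonlite::write_json(
    list(orderings = lapply(truth$orderings, as.character),
         latent = truth$latent, noise_free = truth$noise_free),
    js, dataframe = "columns", digits = NA, auto_unbox = TRUE)
  invisible(c(cohort = csv, ground_truth = js))
}

#' @export
print.progmod_cohort <- function(x, ...) {
  cat("Synthetic cohort:", nrow(x$data), "visits,",
      length(unique(x$data$subject_id)), "subjects,",
      length(x$truth$biomarkers), "biomarkers\n")
  for (g in names(x$truth$orderings)) {
    cat("  ", g, "ordering:", paste(x$truth$orderings[[g]], collapse = " < "), "\n")
  }
  invisible(x)
}
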