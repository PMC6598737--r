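#' Configure an end-to-end progression-modelling run
#'
#' @param input Cohort tibble, or path to a long-format CSV (one row per
#'   subject-visit; columns `subject_id`, `group`, `visit_index`,
#'   `years_since_baseline`, covariates, biomarkers).
#' @param biomarkers Named character vector: abnormality direction
#'   (`"decreasing"`/`"increasing"`) per biomarker column.
#' @param families Named character vector per biomarker: `"volume"`
#'   (Gaussian mixture in the EBM) or `"cognitive"` (KDE mixture).
#' @param covariates Covariate columns to regress out (empty to skip).
#' @param groups Patient group labels to analyse (controls are always
#'   used as the reference).
#' @param dem List: `n_boot`, `times` (years from t0 for comparisons),
#'   `grid_size`, `time_step`.
#' @param ebm List: `n_iter` (MCMC), `thinning`, `n_starts`.
#' @param alpha Family-wise error rate for all test families.
#' @param out_dir Output directory (`NULL` for in-memory only).
#' @param seed Master seed; every stochastic stage draws a derived,
#'   stage-specific seed from it.
#' @return A `progmod_run_config`.
#' @export
run_config <- function(input, biomarkers, families = NULL,
                       covariates = character(), groups = NULL,
                       dem = list(), ebm = list(), alpha = 0.05,
                       out_dir = NULL, seed = 1L) {
  if (length(biomarkers) == 0) abort("`biomarkers` must name at least one column")
  if (is.null(names(biomarkers)) || any(names(biomarkers) == "")) {
    abort("`biomarkers` must be a named direction vector")
  }
  bad <- biomarkers[!biomarkers %in% c("decreasing", "increasing")]
  if (length(bad)) abort("directions must be 'decreasing' or 'increasing'")
  families <- families %||% setNames(rep("volume", length(biomarkers)),
                                     names(biomarkers))
  dem <- utils::modifyList(list(n_boot = 50, times = c(-10, 0, 10),
                                grid_size = 100, time_step = 0.1,
                                n_restarts = 5), dem)
  ebm <- utils::modifyList(list(n_iter = 10000, thinning = 100, n_starts = 10),
                           ebm)
  structure(
    list(input = input, biomarkers = biomarkers, families = families,
         covariates = covariates, groups = groups, dem = dem, ebm = ebm,
         alpha = alpha, out_dir = out_dir, seed = as.integer(seed)),
    class = "progmod_run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' @param path Config file; fields as in [run_config()].
#' @return A `progmod_run_config`.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path) else
    jsonlite::read_json(path, simplifyVector = TRUE)
  run_config(
    input = raw$input,
    biomarkers = unlist(raw$biomarkers),
    families = if (!is.null(raw$families)) unlist(raw$families),
    covariates = raw$covariates %||% character(),
    groups = raw$groups,
    dem = raw$dem %||% list(),
    ebm = raw$ebm %||% list(),
    alpha = raw$alpha %||% 0.05,
    out_dir = raw$out_dir,
    seed = raw$seed %||% 1L)
}

#' Run the full progression-modelling pipeline
#'
#' Preprocess (covariate adjustment, z-scoring to controls, orientation),
#' then per patient group: DEM trajectories with bootstrap ensembles, and
#' an EBM (Gaussian mixtures for volume biomarkers, KDE mixtures for
#' cognitive ones) with ML sequence, MCMC posterior, positional variance
#' and staging; finally rank-based within- and between-group ordering
#' tests and trajectory-value comparisons, all Bonferroni-controlled.
#' With an `out_dir`, every table is written as CSV plus a manifest with
#' content hashes.
#'
#' @param config A [run_config()].
#' @return A `progmod_run`: list with `data` (preprocessed), `dem`,
#'   `ebm`, `stats`, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "progmod_run_config"))
  tbl <- if (is.character(config$input)) {
    as_tibble(read.csv(config$input, stringsAsFactors = FALSE))
  } else as_tibble(config$input)
  bms <- names(config$biomarkers)
  miss <- setdiff(bms, names(tbl))
  if (length(miss)) abort(paste0("biomarker column(s) missing: ",
                                 paste(miss, collapse = ", ")))
  groups <- config$groups %||% setdiff(unique(tbl$group), "control")
  if (!"control" %in% tbl$group) abort("input must contain a 'control' group")
  seed <- config$seed

  # ---- preprocess ----
  if (length(config$covariates)) {
    tbl <- adjust_covariates(tbl, bms, config$covariates)
  }
  ref <- control_reference(tbl, bms)
  tbl_z <- zscore_to_controls(tbl, ref)
  tbl_z <- orient_abnormality(tbl_z, config$biomarkers)

  baseline <- tbl_z |>
    group_by(.data$subject_id) |>
    slice_min(.data$visit_index, n = 1, with_ties = FALSE) |>
    ungroup()

  # ---- DEM per group ----
  dem_res <- list()
  for (g in groups) {
    sub <- tbl_z |> filter(.data$group %in% c(g, "control"))
    trajectories <- setNames(lapply(bms, function(b) {
      tryCatch(
        fit_dem(sub, b, grid_size = config$dem$grid_size,
                time_step = config$dem$time_step,
                n_restarts = config$dem$n_restarts,
                seed = child_seed(seed, paste0("dem_", g, "_", b))),
        error = function(e) {
          warn(sprintf("DEM stage failed for biomarker '%s' in group '%s': %s",
                       b, g, conditionMessage(e)))
          NULL
        })
    }), bms)
    trajectories <- purrr::compact(trajectories)
    if (!length(trajectories)) {
      abort(sprintf("DEM stage failed for every biomarker in group '%s'", g))
    }
    ensembles <- if (config$dem$n_boot > 0) {
      bs <- setNames(lapply(names(trajectories), function(b) {
        tryCatch(
          bootstrap_trajectories(sub, b, n_boot = config$dem$n_boot,
                                 seed = child_seed(seed, paste0("demboot_", g, "_", b)),
                                 grid_size = config$dem$grid_size,
                                 time_step = config$dem$time_step,
                                 n_restarts = config$dem$n_restarts),
          error = function(e) {
            warn(sprintf("DEM bootstrap failed for biomarker '%s' in group '%s': %s",
                         b, g, conditionMessage(e)))
            NULL
          })
      }), names(trajectories))
      purrr::compact(bs)
    }
    base_g <- baseline |> filter(.data$group == g)
    staging <- stage_subjects_dem(trajectories, base_g[c("subject_id", bms)])
    dem_res[[g]] <- list(trajectories = trajectories, ensembles = ensembles,
                         staging = staging)
  }
  dem_tests <- if (config$dem$n_boot > 1) {
    compare_trajectory_values(
      lapply(dem_res, `[[`, "ensembles"),
      times = config$dem$times, alpha = config$alpha)
  }

  # ---- EBM per group ----
  flavour <- ifelse(config$families[bms] == "cognitive", "kde", "gaussian")
  ebm_res <- list()
  for (g in groups) {
    base_g <- baseline |> filter(.data$group %in% c(g, "control"))
    fits <- fit_mixtures(base_g, bms, flavour, baseline_only = FALSE)
    X <- base_g |> filter(.data$group == g)
    ml <- find_ml_sequence(X, fits, n_starts = config$ebm$n_starts,
                           seed = child_seed(seed, paste0("ml_", g)))
    chain <- mcmc_sample(X, fits, ml, n_iter = config$ebm$n_iter,
                         seed = child_seed(seed, paste0("mcmc_", g)))
    thinned <- thin_chain(chain, config$ebm$thinning)
    ebm_res[[g]] <- list(
      fits = fits, ml_sequence = ml, chain = thinned,
      positional_variance = positional_variance(thinned),
      positions = position_samples(thinned, group = g),
      staging = stage_subjects_ebm(X, ml, fits))
  }

  # ---- ordering statistics ----
  within_tables <- lapply(ebm_res, function(r) {
    within_group_order_table(r$positions, alpha = config$alpha)
  })
  between_table <- if (length(groups) >= 2) {
    between_group_order_table(ebm_res[[groups[1]]]$positions,
                              ebm_res[[groups[2]]]$positions,
                              alpha = config$alpha)
  }

  run <- structure(
    list(data = tbl_z, reference = ref, groups = groups,
         dem = dem_res, dem_tests = dem_tests, ebm = ebm_res,
         stats = list(within = within_tables, between = between_table),
         config = config, manifest = NULL),
    class = "progmod_run")
  if (!is.null(config$out_dir)) run <- write_run(run, config$out_dir)
  run
}

write_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  wr <- function(x, name) {
    p <- file.path(dir, name)
    write.csv(x, p, row.names = FALSE)
    paths[[name]] <<- p
  }
  wr(run$data, "preprocessed.csv")
  for (g in run$groups) {
    traj_tbl <- purrr::imap(run$dem[[g]]$trajectories, function(tr, b) {
      tibble(biomarker = b, time = tr$time, value = tr$value, z = tr$z)
    }) |> list_rbind()
    wr(traj_tbl, paste0("dem_trajectories_", g, ".csv"))
    wr(run$dem[[g]]$staging, paste0("dem_staging_", g, ".csv"))
    wr(tibble(position = seq_along(run$ebm[[g]]$ml_sequence$sequence),
              biomarker = run$ebm[[g]]$ml_sequence$sequence),
       paste0("ebm_sequence_", g, ".csv"))
    pv <- run$ebm[[g]]$positional_variance
    wr(cbind(tibble(biomarker = rownames(pv)), as.data.frame(unclass(pv))),
       paste0("ebm_positional_variance_", g, ".csv"))
    wr(run$ebm[[g]]$staging |> select("subject_id", "stage"),
       paste0("ebm_staging_", g, ".csv"))
    wr(run$stats$within[[g]], paste0("stats_within_", g, ".csv"))
  }
  if (!is.null(run$stats$between)) wr(run$stats$between, "stats_between.csv")
  if (!is.null(run$dem_tests)) wr(run$dem_tests, "dem_value_tests.csv")

  meta <- list(
    seed = run$config$seed,
    biomarkers = as.list(run$config$biomarkers),
    groups = run$groups,
    t0_thresholds = lapply(run$dem, function(d) {
      lapply(d$trajectories, function(tr) tr$t0_threshold)
    }),
    r_version = as.character(getRversion()))
  mp <- file.path(dir, "run_meta.json")
  jsonlite::write_json(meta, mp, auto_unbox = TRUE, digits = NA)
  paths[["run_meta.json"]] <- mp

  manifest <- tibble(file = names(paths),
                     md5 = unname(tools::md5sum(unlist(paths))))
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  run$manifest <- manifest
  run
}

#' @export
print.progmod_run <- function(x, ...) {
  cat("Progression-modelling run:", length(x$groups), "patient group(s),",
      length(x$config$biomarkers), "biomarkers\n")
  for (g in x$groups) {
    cat("  ", g, "ML sequence:",
        paste(x$ebm[[g]]$ml_sequence$sequence, collapse = " < "), "\n")
  }
  invisible(x)
}

#' Render standard report figures for a run
#'
#' Spaghetti plots per biomarker and group, DEM trajectory panels with
#' staging histograms, and positional variance heatmaps. Figures are
#' returned as ggplot objects and, if `dir` is given, also written as
#' PNG files.
#'
#' @param run A [run_pipeline()] result.
#' @param dir Optional output directory for PNGs.
#' @return Named list of ggplot objects.
#' @export
render_reports <- function(run, dir = NULL) {
  plots <- list()
  bms <- names(run$config$biomarkers)
  for (g in run$groups) {
    sub <- run$data |> filter(.data$group == g)
    plots[[paste0("spaghetti_", g)]] <- plot_spaghetti(sub, bms)
    plots[[paste0("trajectories_", g)]] <-
      plot_trajectories(run$dem[[g]]$trajectories,
                        staging = run$dem[[g]]$staging)
    plots[[paste0("posvar_", g)]] <-
      ggplot2::autoplot(run$ebm[[g]]$positional_variance) +
      ggplot2::ggtitle(paste("Positional variance:", g))
  }
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(plots)) {
      ggplot2::ggsave(file.path(dir, paste0(nm, ".png")), plots[[nm]],
                      width = 8, height = 6, dpi = 120)
    }
  }
  plots
}
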