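#' Adjust biomarker values for nuisance covariates
#'
#' Fits, per biomarker, a linear model of value on the named covariates
#' (categorical covariates one-hot encoded with the first level as
#' reference) and subtracts the fitted covariate contribution, retaining
#' the intercept. By default the model is fitted on controls only and then
#' applied to all rows, so that disease effects correlated with age are
#' not regressed out.
#'
#' @param table Long-format cohort tibble (one row per subject-visit) with
#'   a `group` column and the covariate and biomarker columns.
#' @param biomarkers Character vector of biomarker column names.
#' @param covariates Character vector of covariate column names present in
#'   `table` (e.g. `c("age", "gender", "tiv", "scanner", "site")`).
#' @param reference `"controls_only"` (default) fits on `group == "control"`;
#'   `"all"` fits on every complete row.
#' @return `table` with the biomarker columns replaced by adjusted values.
#' @export
adjust_covariates <- function(table, biomarkers, covariates,
                              reference = c("controls_only", "all")) {
  reference <- match.arg(reference)
  missing_cov <- setdiff(covariates, names(table))
  if (length(missing_cov)) {
    abort(paste0("covariate column(s) not in table: ",
                 paste(missing_cov, collapse = ", ")))
  }
  missing_bm <- setdiff(biomarkers, names(table))
  if (length(missing_bm)) {
    abort(paste0("biomarker column(s) not in table: ",
                 paste(missing_bm, collapse = ", ")))
  }

  fit_rows <- if (reference == "controls_only") table$group == "control" else
    rep(TRUE, nrow(table))
  cov_df <- as.data.frame(table[covariates])
  for (j in seq_along(cov_df)) {
    if (is.character(cov_df[[j]])) cov_df[[j]] <- factor(cov_df[[j]])
  }
  complete <- complete.cases(cov_df)
  fit_rows <- fit_rows & complete

  # drop covariates with a single level in the fitting sample
  use <- vapply(cov_df, function(x) {
    if (is.factor(x)) length(unique(x[fit_rows])) >= 2 else TRUE
  }, TRUE)
  cov_use <- covariates[use]
  if (!length(cov_use)) return(table)

  # relevel factors to those seen at fit time; unseen at apply time is an error
  for (cv in cov_use) {
    if (is.factor(cov_df[[cv]])) {
      seen <- unique(as.character(cov_df[[cv]][fit_rows]))
      unseen <- setdiff(unique(as.character(cov_df[[cv]][complete])), seen)
      if (length(unseen)) {
        abort(sprintf("covariate '%s' has level(s) unseen in the reference sample: %s",
                      cv, paste(unseen, collapse = ", ")))
      }
      cov_df[[cv]] <- factor(as.character(cov_df[[cv]]), levels = sort(seen))
    }
  }

  form <- stats::as.formula(paste("~", paste(cov_use, collapse = " + ")))
  mf <- stats::model.frame(form, cov_df, na.action = stats::na.pass)
  X_all <- stats::model.matrix(form, mf)
  # model.matrix keeps na.pass rows, so X_all aligns with `table` rows
  X <- X_all
  X_fit <- X[fit_rows, , drop = FALSE]

  qrX <- qr(X_fit)
  if (qrX$rank < ncol(X_fit)) {
    bad <- colnames(X_fit)[qrX$pivot[(qrX$rank + 1):ncol(X_fit)]]
    abort(paste0("rank-deficient covariate design; collinear column(s): ",
                 paste(bad, collapse = ", ")))
  }

  out <- table
  for (bm in biomarkers) {
    y <- table[[bm]]
    ok <- fit_rows & !is.na(y)
    beta <- qr.coef(qr(X[ok, , drop = FALSE]), y[ok])
    # covariate contribution relative to the reference sample's average
    # covariate profile, so the intercept (and overall level) is retained
    contrib <- X[, -1, drop = FALSE] %*% beta[-1]
    contrib <- contrib - mean(contrib[ok])
    out[[bm]] <- as.numeric(y - ifelse(is.na(contrib), 0, contrib))
  }
  out
}

#' Define a region-to-ROI mapping
#'
#' @param groups Tibble/data frame with columns `region` and `roi`: each
#'   retained (bilateral-averaged) region assigned to exactly one composite
#'   region of interest.
#' @param pairs Optional tibble with columns `left`, `right`, `region`
#'   naming the hemispheric column pair that averages into each region. If
#'   omitted, region columns are assumed already bilateral.
#' @param drop Character vector of region columns to discard.
#' @return A `roi_mapping` list.
#' @export
roi_mapping <- function(groups, pairs = NULL, drop = character()) {
  groups <- as_tibble(groups)
  stopifnot(all(c("region", "roi") %in% names(groups)))
  if (anyDuplicated(groups$region)) {
    abort("each region must map to exactly one ROI")
  }
  if (!is.null(pairs)) {
    pairs <- as_tibble(pairs)
    stopifnot(all(c("left", "right", "region") %in% names(pairs)))
  }
  structure(list(groups = groups, pairs = pairs, drop = drop),
            class = "roi_mapping")
}

#' Packaged default 46-region to 8-ROI mapping
#'
#' Maps 46 bilateral cortical/subcortical region volumes onto eight
#' composites: whole brain, hippocampal, occipital, frontal, entorhinal,
#' temporal (excluding hippocampus), parietal and ventricles. The region
#' list is reconstructed from the Neuromorphometrics atlas naming; ships
#' as `inst/extdata/roi_mapping_46to8.json` and can be replaced by any
#' user-supplied [roi_mapping()].
#'
#' @return A `roi_mapping`.
#' @export
default_roi_mapping <- function() {
  path <- system.file("extdata", "roi_mapping_46to8.json", package = "progmod")
  read_roi_mapping(path)
}

#' Read a ROI mapping from JSON or YAML
#'
#' @param path File with fields `groups` (region, roi), optional `pairs`
#'   and `drop`.
#' @return A `roi_mapping`.
#' @export
read_roi_mapping <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path) else
    jsonlite::read_json(path, simplifyVector = TRUE)
  roi_mapping(groups = as_tibble(raw$groups),
              pairs = if (!is.null(raw$pairs)) as_tibble(raw$pairs),
              drop = raw$drop %||% character())
}

#' Aggregate region columns into composite ROIs
#'
#' Left/right pairs are averaged first; each composite ROI is the
#' unweighted mean of its constituent (bilateral-averaged) regions.
#'
#' @param table Tibble with one column per region (plus any id columns,
#'   which pass through untouched).
#' @param mapping A [roi_mapping()].
#' @return `table` with region columns replaced by one column per ROI.
#' @export
#' @examples
#' m <- roi_mapping(tibble::tibble(region = c("r1", "r2", "r3"),
#'                                 roi = c("A", "A", "B")))
#' aggregate_rois(tibble::tibble(r1 = 2, r2 = 4, r3 = 10), m)
aggregate_rois <- function(table, mapping) {
  stopifnot(inherits(mapping, "roi_mapping"))
  tbl <- table
  if (!is.null(mapping$pairs) &&
      any(c(mapping$pairs$left, mapping$pairs$right) %in% names(tbl))) {
    need <- c(mapping$pairs$left, mapping$pairs$right)
    miss <- setdiff(need, names(tbl))
    if (length(miss)) {
      abort(paste0("missing region column(s): ", paste(miss, collapse = ", ")))
    }
    for (i in seq_len(nrow(mapping$pairs))) {
      p <- mapping$pairs[i, ]
      tbl[[p$region]] <- (tbl[[p$left]] + tbl[[p$right]]) / 2
    }
    tbl <- tbl[setdiff(names(tbl), need)]
  }
  tbl <- tbl[setdiff(names(tbl), mapping$drop)]
  miss <- setdiff(mapping$groups$region, names(tbl))
  if (length(miss)) {
    abort(paste0("missing region column(s): ", paste(miss, collapse = ", ")))
  }
  out <- tbl[setdiff(names(tbl), mapping$groups$region)]
  for (roi in unique(mapping$groups$roi)) {
    members <- mapping$groups$region[mapping$groups$roi == roi]
    out[[roi]] <- rowMeans(as.data.frame(tbl[members]))
  }
  out
}

#' Control reference statistics for z-scoring
#'
#' Mean and SD per biomarker among baseline control visits.
#'
#' @param table Cohort tibble with `group` and `visit_index` columns.
#' @param biomarkers Biomarker column names.
#' @param baseline_only Use only `visit_index == min(visit_index)` controls
#'   (default), avoiding weighting controls by visit count.
#' @return Tibble with columns `biomarker`, `mean`, `sd`.
#' @export
control_reference <- function(table, biomarkers, baseline_only = TRUE) {
  ctl <- table[table$group == "control", , drop = FALSE]
  if (baseline_only && "visit_index" %in% names(ctl)) {
    ctl <- ctl[ctl$visit_index == min(ctl$visit_index), , drop = FALSE]
  }
  ref <- tibble(
    biomarker = biomarkers,
    mean = vapply(biomarkers, function(b) mean(ctl[[b]], na.rm = TRUE), 0),
    sd = vapply(biomarkers, function(b) sd(ctl[[b]], na.rm = TRUE), 0)
  )
  if (any(!is.finite(ref$sd)) || any(ref$sd <= 0)) {
    abort("control SD must be positive for every biomarker")
  }
  ref
}

#' Z-score biomarkers relative to controls
#'
#' `z = (value - control_mean) / control_sd` per biomarker.
#'
#' @param table Cohort tibble.
#' @param reference A [control_reference()] tibble (`biomarker`, `mean`, `sd`).
#' @return `table` with biomarker columns replaced by z-scores.
#' @export
zscore_to_controls <- function(table, reference) {
  if (any(reference$sd <= 0)) abort("control SD must be positive")
  out <- table
  for (i in seq_len(nrow(reference))) {
    b <- reference$biomarker[i]
    out[[b]] <- (table[[b]] - reference$mean[i]) / reference$sd[i]
  }
  out
}

#' Orient biomarkers so abnormality is always decreasing
#'
#' Biomarkers declared `"increasing"` (ventricles, timed scores) are
#' negated so every biomarker moves downwards with disease; applying the
#' orientation twice restores the original values.
#'
#' @param table Cohort tibble.
#' @param directions Named character vector: `"decreasing"` or
#'   `"increasing"` per biomarker column.
#' @return `table` with oriented values; flipped biomarkers recorded in the
#'   `"flipped"` attribute.
#' @export
orient_abnormality <- function(table, directions) {
  bad <- names(directions)[!directions %in% c("decreasing", "increasing")]
  if (length(bad)) abort(paste0("invalid direction for: ", paste(bad, collapse = ", ")))
  miss <- setdiff(names(directions), names(table))
  if (length(miss)) abort(paste0("biomarker(s) not in table: ", paste(miss, collapse = ", ")))
  out <- table
  flipped <- names(directions)[directions == "increasing"]
  for (b in flipped) out[[b]] <- -out[[b]]
  attr(out, "flipped") <- flipped
  out
}

#' Apply the floor-score discontinuation rule to one test series
#'
#' When a subject first scores at floor, the test is discontinued: the
#' next visit is assigned the floor score (regardless of any recorded
#' value) and all later visits are set to missing. Existing missing values
#' are never resurrected.
#'
#' @param series Time-ordered numeric vector of one subject's scores on
#'   one test.
#' @param floor_value The test's floor score.
#' @return The modified series.
#' @export
#' @examples
#' apply_floor_rule(c(12, 0, 7, 9), floor_value = 0) # 12, 0, 0, NA
apply_floor_rule <- function(series, floor_value) {
  hit <- which(!is.na(series) & series <= floor_value)
  if (!length(hit)) return(series)
  first <- hit[1]
  if (first < length(series)) {
    series[first + 1L] <- floor_value
    if (first + 1L < length(series)) {
      series[(first + 2L):length(series)] <- NA_real_
    }
  }
  series
}

#' Apply the floor rule across a cohort table
#'
#' @param table Cohort tibble with `subject_id` and `visit_index`.
#' @param floors Named numeric vector: floor per biomarker column.
#' @return `table` with floored series processed per subject.
#' @export
apply_floor_rule_table <- function(table, floors) {
  out <- table |> arrange(.data$subject_id, .data$visit_index)
  for (b in names(floors)) {
    out <- out |>
      group_by(.data$subject_id) |>
      mutate(!!b := apply_floor_rule(.data[[b]], floors[[b]])) |>
      ungroup()
  }
  out
}
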