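# Synthetic cohorts with known ground truth, replacing access-controlled
# clinical data for every downstream stage.

#' Generate a feature-level cohort with a planted informative subset
#'
#' Two groups of subjects with `n_features` features: noise features are
#' `Normal(0, noise_sd)` in both groups; a random subset of
#' `n_informative` features has its group-1 mean shifted by
#' `effect * noise_sd` (a standardized mean difference of `effect`).  The
#' default group sizes, 72 and 68, mirror a two-arm clinical cohort of
#' healthy controls versus early-impairment patients.
#'
#' @param n_group0,n_group1 Subjects per group (defaults 72 and 68).
#' @param n_features Total features F.
#' @param n_informative Number of planted informative features (<= F).
#' @param effect Standardized mean difference of the informative features
#'   (>= 0).
#' @param noise_sd Feature standard deviation.
#' @param seed Integer seed; the cohort is bit-reproducible from
#'   `(arguments, seed)`.
#'
#' @return A feature table (tibble: `subject_id`, `group`, features
#'   `f001`, ...) with the ground truth attached as attribute
#'   `"ground_truth"` (see [ground_truth()]).
#' @export
generate_feature_cohort <- function(n_group0 = 72, n_group1 = 68,
                                    n_features = 200, n_informative = 10,
                                    effect = 1.5, noise_sd = 1, seed = 1L) {
  stopifnot(n_group0 >= 2, n_group1 >= 2, n_informative <= n_features,
            effect >= 0, noise_sd > 0)
  n <- n_group0 + n_group1
  with_seed(seed, {
    informative <- sort(sample.int(n_features, n_informative))
    X <- matrix(rnorm(n * n_features, sd = noise_sd), n, n_features)
    group <- c(rep(0L, n_group0), rep(1L, n_group1))
    X[group == 1L, informative] <- X[group == 1L, informative] +
      effect * noise_sd
    width <- max(3L, nchar(as.character(n_features)))
    colnames(X) <- sprintf(paste0("f%0", width, "d"), seq_len(n_features))
    out <- tibble::tibble(
      subject_id = sprintf("S%03d", seq_len(n)),
      group = group)
    out <- dplyr::bind_cols(out, tibble::as_tibble(X))
    attr(out, "ground_truth") <- list(
      informative = informative, effect = effect, noise_sd = noise_sd,
      seed = seed, level = "feature")
    attr(out, "group_names") <- c("group0", "group1")
    class(out) <- c("feature_table", class(out))
    out
  })
}

#' Generate an ROI time-series cohort with a planted connectivity contrast
#'
#' Per subject, a `T x n_roi` Gaussian series is drawn from a block
#' covariance structure: a designated block of `block_size` ROIs has
#' within-block correlation `rho0` in group 0 and `rho0 + delta_rho` in
#' group 1, all other pairs are uncorrelated.  The group-dependent
#' covariance induces connectivity and graph differences, so the full
#' extraction chain - not just the selector - can be exercised against a
#' known truth.  Defaults `t_points = 140`, `dt = 3` s match a typical
#' resting-state acquisition (TR = 3000 ms, 140 volumes).
#'
#' @param n_group0,n_group1 Subjects per group (defaults 72 and 68).
#' @param n_roi Number of ROIs.
#' @param t_points Timepoints per series (default 140).
#' @param dt Sampling interval in seconds (default 3).
#' @param block_size ROIs in the planted block (first `block_size` ROIs).
#' @param rho0 Within-block correlation in group 0, in `[0, 1)`.
#' @param delta_rho Added within-block correlation in group 1;
#'   `rho0 + delta_rho` must stay below 1.
#' @param seed Integer seed.
#'
#' @return A tibble with `subject_id`, `group` and a `series` list column
#'   of [roi_ts()] objects, plus attribute `"ground_truth"` (block ROI
#'   labels, correlations, seed).
#' @export
generate_timeseries_cohort <- function(n_group0 = 72, n_group1 = 68,
                                       n_roi = 16, t_points = 140, dt = 3,
                                       block_size = 4, rho0 = 0.2,
                                       delta_rho = 0.4, seed = 1L) {
  stopifnot(n_group0 >= 2, n_group1 >= 2, n_roi >= 2,
            block_size >= 2, block_size <= n_roi,
            rho0 >= 0, delta_rho >= 0, t_points >= 4)
  if (rho0 + delta_rho >= 1) abort("rho0 + delta_rho must be below 1.")

  block_cov <- function(rho) {
    sigma <- diag(n_roi)
    b <- seq_len(block_size)
    sigma[b, b] <- rho
    diag(sigma) <- 1
    # equicorrelation blocks with rho in [0, 1) are positive definite;
    # verified here so a bad request fails before sampling
    ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) abort("Requested covariance is not positive definite.")
    chol(sigma)
  }

  labels <- sprintf("ROI%03d", seq_len(n_roi))
  with_seed(seed, {
    chol0 <- block_cov(rho0)
    chol1 <- block_cov(rho0 + delta_rho)
    n <- n_group0 + n_group1
    group <- c(rep(0L, n_group0), rep(1L, n_group1))
    series <- lapply(seq_len(n), function(i) {
      ch <- if (group[i] == 0L) chol0 else chol1
      z <- matrix(rnorm(t_points * n_roi), t_points, n_roi) %*% ch
      roi_ts(z, dt = dt, roi_labels = labels,
             subject_id = sprintf("S%03d", i))
    })
    out <- tibble::tibble(subject_id = sprintf("S%03d", seq_len(n)),
                          group = group, series = series)
    attr(out, "ground_truth") <- list(
      block_rois = labels[seq_len(block_size)], rho0 = rho0,
      delta_rho = delta_rho, seed = seed, level = "timeseries")
    out
  })
}

#' Ground truth of a synthetic cohort
#' @param x A cohort from [generate_feature_cohort()] or
#'   [generate_timeseries_cohort()].
#' @return The generator's ground-truth list (informative indices or
#'   planted block, effect sizes, seed).
#' @export
ground_truth <- function(x) {
  gt <- attr(x, "ground_truth")
  if (is.null(gt)) abort("`x` carries no ground-truth attribute.")
  gt
}

#' Write a time-series cohort as per-subject TSV files plus a manifest
#'
#' Each subject's series goes to `<dir>/<subject_id>.tsv` (header = ROI
#' labels); `<dir>/manifest.tsv` maps `subject_id` to file and group, and
#' the ground truth is stored as `<dir>/ground_truth.json`.
#'
#' @param cohort A time-series cohort tibble.
#' @param dir Output directory (created if needed).
#' @rdname cohort_io
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dt <- cohort$series[[1]]$dt
  paths <- vapply(cohort$series, function(ts) {
    p <- file.path(dir, paste0(ts$subject_id, ".tsv"))
    readr::write_tsv(tibble::as_tibble(ts$data), p)
    basename(p)
  }, character(1))
  manifest <- tibble::tibble(subject_id = cohort$subject_id,
                             file = paths, group = cohort$group, dt = dt)
  readr::write_tsv(manifest, file.path(dir, "manifest.tsv"))
  gt <- attr(cohort, "ground_truth")
  if (!is.null(gt)) {
    jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' @rdname cohort_io
#' @export
read_cohort <- function(dir) {
  manifest <- readr::read_tsv(file.path(dir, "manifest.tsv"),
                              show_col_types = FALSE)
  series <- purrr::pmap(
    list(manifest$subject_id, manifest$file, manifest$dt),
    function(sid, f, dt) {
      m <- as.matrix(readr::read_tsv(file.path(dir, f),
                                     show_col_types = FALSE))
      roi_ts(m, dt = dt, subject_id = sid)
    })
  out <- tibble::tibble(subject_id = manifest$subject_id,
                        group = as.integer(manifest$group),
                        series = series)
  gt_path <- file.path(dir, "ground_truth.json")
  if (file.exists(gt_path)) {
    attr(out, "ground_truth") <- jsonlite::read_json(gt_path,
                                                     simplifyVector = TRUE)
  }
  out
}
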