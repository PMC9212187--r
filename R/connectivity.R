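#' ROI time-series container
#'
#' Wraps a `T x N` matrix of BOLD-like signals (rows = timepoints, columns
#' = regions of interest) together with ROI labels and the sampling
#' interval.
#'
#' @param data Numeric matrix, `T` timepoints by `N` ROIs, no missing
#'   values, `T >= 4`, `N >= 2`.
#' @param dt Sampling interval in seconds (the repetition time; 3.0 s for
#'   the acquisition this pipeline emulates).
#' @param roi_labels Character vector of `N` unique ROI labels; defaults to
#'   the matrix column names.
#' @param subject_id Optional subject identifier.
#'
#' @return An object of class `roi_ts`.
#' @export
#' @examples
#' ts <- roi_ts(matrix(rnorm(40), 10, 4), dt = 3)
roi_ts <- function(data, dt, roi_labels = colnames(data), subject_id = NA_character_) {
  data <- as.matrix(data)
  if (!is.numeric(data)) abort("`data` must be a numeric matrix.")
  if (anyNA(data)) abort("`data` must not contain missing values.")
  if (nrow(data) < 4L) abort("Need at least 4 timepoints.")
  if (ncol(data) < 2L) abort("Need at least 2 ROIs.")
  if (is.null(roi_labels)) roi_labels <- sprintf("ROI%03d", seq_len(ncol(data)))
  roi_labels <- as.character(roi_labels)
  if (length(roi_labels) != ncol(data) || anyDuplicated(roi_labels)) {
    abort("`roi_labels` must be unique and match the number of columns.")
  }
  check_scalar_number(dt, "dt", lower = 1e-12)
  colnames(data) <- roi_labels
  structure(
    list(data = data, roi_labels = roi_labels, dt = dt,
         subject_id = as.character(subject_id)),
    class = "roi_ts"
  )
}

#' @export
print.roi_ts <- function(x, ...) {
  cat(sprintf("<roi_ts> subject %s: %d timepoints x %d ROIs, dt = %g s\n",
              x$subject_id, nrow(x$data), ncol(x$data), x$dt))
  invisible(x)
}

#' Band-pass filter ROI time series
#'
#' Applies a zero-phase (forward-backward) 2nd-order Butterworth band-pass
#' filter to every ROI column independently and removes the column mean, so
#' that only fluctuations inside `(low, high)` Hz survive.  The default
#' band, 0.01-0.1 Hz, is the low-frequency range conventionally retained in
#' resting-state functional connectivity analysis.
#'
#' @param ts A [roi_ts()] object.
#' @param low,high Band edges in Hz; `0 <= low < high < 1/(2 dt)`.
#'
#' @return A filtered [roi_ts()] with the same shape and labels.
#' @export
bandpass_filter <- function(ts, low = 0.01, high = 0.1) {
  stopifnot(inherits(ts, "roi_ts"))
  nyquist <- 1 / (2 * ts$dt)
  if (!is.numeric(low) || !is.numeric(high) || low < 0 || high <= low) {
    abort("Need 0 <= low < high.")
  }
  if (high >= nyquist) {
    abort(sprintf("`high` (%g Hz) must be below the Nyquist frequency %g Hz.",
                  high, nyquist))
  }
  # filtfilt on a 2nd-order band-pass (4 states) needs a comfortable margin
  # of samples beyond the filter order for stable edge handling
  if (nrow(ts$data) < 16L) {
    abort("Too few timepoints for stable band-pass filtering (need >= 16).")
  }
  w <- c(low, high) / nyquist
  if (low == 0) {
    bf <- signal::butter(2, w[2], type = "low")
  } else {
    bf <- signal::butter(2, w, type = "pass")
  }
  centred <- sweep(ts$data, 2, colMeans(ts$data))
  filtered <- apply(centred, 2, function(col) signal::filtfilt(bf, col))
  filtered <- sweep(filtered, 2, colMeans(filtered)) # re-remove residual DC
  roi_ts(filtered, dt = ts$dt, roi_labels = ts$roi_labels,
         subject_id = ts$subject_id)
}

new_conn_matrix <- function(values, roi_labels, kind) {
  dimnames(values) <- list(roi_labels, roi_labels)
  structure(list(values = values, roi_labels = roi_labels, kind = kind),
            class = "conn_matrix")
}

#' ROI-to-ROI Pearson correlation matrix
#'
#' Computes the `N x N` matrix of Pearson correlations between ROI columns
#' (the ROI-to-ROI correlation, RRC, matrix).  The diagonal is set to zero
#' by convention; self-connectivity carries no information here.
#'
#' @param ts A [roi_ts()] object whose columns all have nonzero variance.
#'
#' @return A `conn_matrix` of kind `"pearson_r"`.
#' @export
roi_correlation <- function(ts) {
  stopifnot(inherits(ts, "roi_ts"))
  v <- apply(ts$data, 2, var)
  if (any(v == 0)) {
    abort(sprintf("Zero-variance ROI column(s): %s.",
                  paste(ts$roi_labels[v == 0], collapse = ", ")))
  }
  r <- stats::cor(ts$data)
  diag(r) <- 0
  new_conn_matrix(r, ts$roi_labels, "pearson_r")
}

#' Fisher z-transform of a correlation matrix
#'
#' Applies `z = atanh(r)` elementwise, the variance-stabilizing transform
#' for correlation coefficients (SE of z is approximately `1/sqrt(T - 3)`).
#' `|r|` is clipped to `1 - 1e-7` first so perfectly correlated columns
#' yield a large finite z rather than infinity; the diagonal stays zero.
#'
#' @param c A `conn_matrix` of kind `"pearson_r"` from [roi_correlation()].
#'
#' @return A `conn_matrix` of kind `"fisher_z"`.
#' @export
fisher_z <- function(c) {
  stopifnot(inherits(c, "conn_matrix"))
  if (c$kind != "pearson_r") abort("`fisher_z` expects a pearson_r matrix.")
  r <- pmin(pmax(c$values, -(1 - 1e-7)), 1 - 1e-7)
  z <- atanh(r)
  diag(z) <- 0
  new_conn_matrix(z, c$roi_labels, "fisher_z")
}

#' Threshold a Fisher-z connectivity matrix into a binary brain graph
#'
#' Two threshold rules are supported. `mode = "absolute"` keeps edges with
#' `z > value` (a one-sided rule on the signed z; set `use_abs = TRUE` to
#' rank by `|z|` instead). `mode = "proportional"` keeps exactly
#' `ceiling(value * N(N-1)/2)` strongest off-diagonal pairs, i.e. a fixed
#' edge density; ties are broken by `(i, j)` lexicographic order for bit
#' reproducibility.
#'
#' @param c A `conn_matrix` of kind `"fisher_z"`.
#' @param mode `"absolute"` (z-threshold) or `"proportional"` (density).
#' @param value z cutoff if absolute (> 0); edge-density fraction in
#'   `(0, 1]` if proportional. Default: proportional density 0.15.
#' @param use_abs Rank/threshold on `|z|` instead of signed z.
#'
#' @return A `brain_graph`: binary symmetric adjacency with zero diagonal,
#'   ROI labels, and the threshold spec used.
#' @export
threshold_adjacency <- function(c, mode = c("proportional", "absolute"),
                                value = 0.15, use_abs = FALSE) {
  stopifnot(inherits(c, "conn_matrix"))
  if (c$kind != "fisher_z") abort("`threshold_adjacency` expects a fisher_z matrix.")
  mode <- match.arg(mode)
  n <- length(c$roi_labels)
  z <- c$values
  if (use_abs) z <- abs(z)
  a <- matrix(0L, n, n)
  if (mode == "absolute") {
    check_scalar_number(value, "value", lower = .Machine$double.xmin)
    a[z > value] <- 1L
  } else {
    check_scalar_number(value, "value", lower = .Machine$double.xmin, upper = 1)
    n_pairs <- n * (n - 1) / 2
    n_edges <- ceiling(value * n_pairs)
    if (value * n_pairs < 1) {
      warn("Proportional threshold keeps less than one edge; graph has a single edge from ceiling().")
    }
    ut <- which(upper.tri(z), arr.ind = TRUE)
    # sort by z descending, ties by (row, col) lexicographic
    ord <- order(-z[ut], ut[, 1], ut[, 2])
    keep <- ut[ord[seq_len(min(n_edges, n_pairs))], , drop = FALSE]
    a[keep] <- 1L
  }
  diag(a) <- 0L
  a <- pmax(a, t(a))
  dimnames(a) <- list(c$roi_labels, c$roi_labels)
  structure(
    list(adjacency = a, roi_labels = c$roi_labels,
         spec = list(mode = mode, value = value, use_abs = use_abs)),
    class = "brain_graph"
  )
}

#' Construct a brain graph from a binary adjacency matrix
#'
#' Mostly useful for small hand-built graphs; pipelines normally obtain
#' graphs from [threshold_adjacency()].
#'
#' @param adjacency Binary symmetric matrix with zero diagonal.
#' @param roi_labels Node labels; default from dimnames or `n1..nN`.
#' @return A `brain_graph`.
#' @export
brain_graph <- function(adjacency, roi_labels = rownames(adjacency)) {
  a <- as.matrix(adjacency)
  if (is.null(roi_labels)) roi_labels <- paste0("n", seq_len(nrow(a)))
  if (!all(a %in% c(0, 1))) abort("Adjacency must be binary.")
  if (!isTRUE(all.equal(a, t(a)))) abort("Adjacency must be symmetric.")
  if (any(diag(a) != 0)) abort("Adjacency diagonal must be zero.")
  storage.mode(a) <- "integer"
  dimnames(a) <- list(roi_labels, roi_labels)
  structure(list(adjacency = a, roi_labels = as.character(roi_labels),
                 spec = list(mode = "manual", value = NA_real_,
                             use_abs = FALSE)),
            class = "brain_graph")
}

#' @export
print.brain_graph <- function(x, ...) {
  cat(sprintf("<brain_graph> %d nodes, %d edges (%s threshold %g)\n",
              length(x$roi_labels), sum(x$adjacency) / 2,
              x$spec$mode, x$spec$value))
  invisible(x)
}

#' Write / read a connectivity matrix as delimited text
#'
#' Square matrix with ROI labels as header row and first column.
#'
#' @param c A `conn_matrix`.
#' @param path File path.
#' @rdname conn_matrix_io
#' @export
write_conn_matrix <- function(c, path) {
  stopifnot(inherits(c, "conn_matrix"))
  df <- as.data.frame(c$values)
  df <- cbind(roi = c$roi_labels, df)
  readr::write_tsv(df, path)
  invisible(path)
}

#' @param kind Correlation kind stored in the file (`"fisher_z"` or
#'   `"pearson_r"`); the text format does not record it.
#' @rdname conn_matrix_io
#' @export
read_conn_matrix <- function(path, kind = "fisher_z") {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  labels <- df[[1]]
  m <- as.matrix(df[, -1])
  new_conn_matrix(m, labels, kind)
}
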