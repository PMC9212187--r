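#' Atlas configuration for feature assembly
#'
#' Describes how node-level graph measures are grouped into the feature
#' vector: a set of atlas ROI labels, a set of brain-network node labels
#' (each assigned to a named network), and optionally a global aggregate.
#' The reference layout is 132 atlas ROIs plus 32 network nodes grouped
#' into 8 networks plus one global aggregate, which with 7 measures per
#' node yields (132 + 32 + 1) x 7 = 1155 features.
#'
#' @param atlas_roi_labels Character vector of atlas ROI labels.
#' @param network_node_labels Character vector of network-node labels,
#'   disjoint from the atlas labels.
#' @param networks Named assignment of each network node to a network:
#'   a character vector parallel to `network_node_labels`. Defaults to one
#'   network containing all nodes.
#' @param include_global Append a global aggregate (per-measure mean over
#'   the network nodes)? Default `TRUE`.
#'
#' @return An `atlas_config` object.
#' @export
#' @examples
#' cfg <- atlas_config(sprintf("ROI%03d", 1:132), sprintf("NET%02d", 1:32),
#'                     networks = rep(sprintf("network%d", 1:8), each = 4))
atlas_config <- function(atlas_roi_labels, network_node_labels = character(),
                         networks = NULL, include_global = TRUE) {
  atlas_roi_labels <- as.character(atlas_roi_labels)
  network_node_labels <- as.character(network_node_labels)
  all_labels <- c(atlas_roi_labels, network_node_labels)
  if (anyDuplicated(all_labels)) {
    abort("Atlas and network labels must be disjoint and unique.")
  }
  if (is.null(networks)) {
    networks <- rep("network1", length(network_node_labels))
  }
  if (length(networks) != length(network_node_labels)) {
    abort("`networks` must assign every network node to exactly one network.")
  }
  structure(
    list(atlas_roi_labels = atlas_roi_labels,
         network_node_labels = network_node_labels,
         networks = as.character(networks),
         include_global = isTRUE(include_global)),
    class = "atlas_config"
  )
}

#' Number of features an atlas configuration produces
#' @param atlas An [atlas_config()].
#' @return Integer feature count.
#' @export
n_features <- function(atlas) {
  (length(atlas$atlas_roi_labels) + length(atlas$network_node_labels) +
     as.integer(atlas$include_global)) * 7L
}

#' Assemble a per-subject feature vector from graph measure sets
#'
#' Concatenates, in order: the seven measures of every atlas ROI node,
#' then of every network node, then (if configured) a global aggregate
#' defined as the per-measure arithmetic mean over the network nodes.
#' Feature names are `"<node>::<measure>"`, with `GLOBAL` as the aggregate
#' node label.
#'
#' @param roi_measures Tibble from [compute_measure_set()] covering the
#'   atlas ROI labels.
#' @param network_measures Tibble covering the network-node labels; may be
#'   the same measure set when all nodes live in one graph.
#' @param atlas An [atlas_config()].
#' @param global_over With `"network"` (default) the global aggregate
#'   averages the network nodes; `"all"` averages atlas and network nodes.
#'
#' @return A named numeric vector of length [n_features()].
#' @export
assemble_features <- function(roi_measures, network_measures, atlas,
                              global_over = c("network", "all")) {
  stopifnot(inherits(atlas, "atlas_config"))
  global_over <- match.arg(global_over)
  meas <- measure_names()

  pick <- function(set, labels, what) {
    miss <- setdiff(labels, set$node)
    if (length(miss) > 0) {
      abort(sprintf("Measure set is missing %s node(s): %s.",
                    what, paste(miss, collapse = ", ")))
    }
    m <- as.matrix(set[match(labels, set$node), meas])
    rownames(m) <- labels
    m
  }

  roi_m <- pick(roi_measures, atlas$atlas_roi_labels, "atlas")
  net_m <- pick(network_measures, atlas$network_node_labels, "network")

  blocks <- list()
  flatten <- function(m) {
    # node-major: all 7 measures of node 1, then node 2, ...
    v <- as.numeric(t(m))
    names(v) <- as.vector(t(outer(rownames(m), meas, paste, sep = "::")))
    v
  }
  if (nrow(roi_m) > 0) blocks <- c(blocks, list(flatten(roi_m)))
  if (nrow(net_m) > 0) blocks <- c(blocks, list(flatten(net_m)))
  if (atlas$include_global) {
    base <- if (global_over == "network" && nrow(net_m) > 0) net_m else
      rbind(roi_m, net_m)
    g <- colMeans(base)
    names(g) <- paste("GLOBAL", meas, sep = "::")
    blocks <- c(blocks, list(g))
  }
  out <- unlist(blocks)
  stopifnot(length(out) == n_features(atlas))
  out
}

#' Extract graph-measure features for a whole cohort
#'
#' Runs the full per-subject chain: (optional) band-pass filter, Pearson
#' ROI-to-ROI correlation, Fisher z-transform, adjacency thresholding, the
#' seven node-level graph measures, and feature assembly.  One graph is
#' built over the union of atlas ROIs and network nodes from a single
#' connectivity matrix; network-node measures are read from that graph.
#'
#' @param cohort A tibble with columns `subject_id`, `group`, and `series`
#'   (a list column of [roi_ts()] objects), e.g. from
#'   [generate_timeseries_cohort()].
#' @param atlas An [atlas_config()] whose labels together cover the ROI
#'   labels of every series.
#' @param band Numeric length-2 band in Hz, or `NULL` to skip filtering.
#' @param mode,value,use_abs Threshold rule, see [threshold_adjacency()].
#' @param group_names Two labels naming groups 0 and 1.
#'
#' @return A feature table: tibble with `subject_id`, `group`, and one
#'   column per assembled feature.
#' @export
extract_features <- function(cohort, atlas, band = c(0.01, 0.1),
                             mode = "proportional", value = 0.15,
                             use_abs = FALSE,
                             group_names = c("group0", "group1")) {
  stopifnot(is.data.frame(cohort),
            all(c("subject_id", "group", "series") %in% names(cohort)))
  rows <- purrr::pmap(
    list(cohort$subject_id, cohort$series),
    function(sid, ts) {
      if (!inherits(ts, "roi_ts")) abort("`series` must hold roi_ts objects.")
      if (!is.null(band)) ts <- bandpass_filter(ts, band[1], band[2])
      g <- threshold_adjacency(fisher_z(roi_correlation(ts)),
                               mode = mode, value = value, use_abs = use_abs)
      ms <- compute_measure_set(g)
      assemble_features(ms, ms, atlas)
    }
  )
  feat <- do.call(rbind, rows)
  out <- tibble::tibble(subject_id = cohort$subject_id,
                        group = as.integer(cohort$group))
  out <- dplyr::bind_cols(out, tibble::as_tibble(feat, .name_repair = "minimal"))
  attr(out, "group_names") <- group_names
  class(out) <- c("feature_table", class(out))
  out
}

#' Feature columns of a feature table
#'
#' A feature table is a tibble whose first columns are `subject_id` and
#' `group` (0/1); every remaining column is a feature.
#'
#' @param table A feature table.
#' @return Character vector of feature column names.
#' @export
feature_names <- function(table) {
  setdiff(names(table), c("subject_id", "group"))
}

#' @rdname feature_names
#' @return `feature_matrix`: the numeric subjects-by-features matrix.
#' @export
feature_matrix <- function(table) {
  as.matrix(table[, feature_names(table), drop = FALSE])
}

validate_feature_table <- function(table) {
  if (!is.data.frame(table) ||
      !all(c("subject_id", "group") %in% names(table))) {
    abort("A feature table needs `subject_id` and `group` columns.")
  }
  g <- table$group
  if (!all(g %in% c(0L, 1L))) abort("`group` must be coded 0/1.")
  if (length(unique(g)) < 2) abort("Both groups must be non-empty.")
  fm <- feature_matrix(table)
  if (anyNA(fm)) abort("Feature table must not contain missing values.")
  invisible(table)
}

#' Read / write a feature table as TSV
#'
#' Header = `subject_id`, `group`, then feature names; round-trips
#' losslessly (full double precision).
#'
#' @param table A feature table.
#' @param path File path.
#' @rdname feature_table_io
#' @export
write_feature_table <- function(table, path) {
  validate_feature_table(table)
  readr::write_tsv(table, path)
  invisible(path)
}

#' @rdname feature_table_io
#' @export
read_feature_table <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           subject_id = readr::col_character(),
                           group = readr::col_integer(),
                           .default = readr::col_double()
                         ))
  validate_feature_table(out)
  class(out) <- c("feature_table", class(out))
  out
}
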