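# The fixed 26-feature cluster descriptor. Display names follow the
# published enumeration order; snake names are the machine-usable column
# names. "total X" = sum of the per-cluster quantity over clusters,
# "average X" = mean over clusters; "n2n" abbreviates nucleus-to-nucleus
# (pairwise member distances); "MST" quantities summarise intra- or
# inter-cluster MST edge weights; areas are convex-hull areas of member
# centroids (px^2) unless the nucleus-pixel-area alternative is requested.

.feature_table <- tibble::tribble(
  ~display, ~snake,
  "total intra-cluster total MST distance", "total_intra_mst_total",
  "total intra-cluster nucleus to nucleus maximum distance", "total_intra_n2n_max",
  "inter-cluster centroid to centroid total distance", "inter_c2c_total",
  "inter-cluster total MST distance", "inter_mst_total",
  "number of clusters", "n_clusters",
  "total intra-cluster maximum MST distance", "total_intra_mst_max",
  "average intra-cluster nucleus to nucleus minimum distance", "avg_intra_n2n_min",
  "average intra-cluster nucleus to nucleus maximum distance", "avg_intra_n2n_max",
  "average intra-cluster maximum MST distance", "avg_intra_mst_max",
  "average cluster area", "avg_cluster_area",
  "total intra-cluster nucleus to nucleus total distance", "total_intra_n2n_total",
  "total intra-cluster minimum MST distance", "total_intra_mst_min",
  "total intra-cluster nucleus to nucleus minimum distance", "total_intra_n2n_min",
  "inter-cluster maximum MST distance", "inter_mst_max",
  "average intra-cluster total MST distance", "avg_intra_mst_total",
  "average intra-cluster minimum MST distance", "avg_intra_mst_min",
  "total cluster area", "total_cluster_area",
  "inter-cluster average MST distance", "inter_mst_avg",
  "average intra-cluster nucleus to nucleus average distance", "avg_intra_n2n_avg",
  "inter-cluster centroid to centroid average distance", "inter_c2c_avg",
  "minimum area of a cluster", "min_cluster_area",
  "average intra-cluster nucleus to nucleus total distance", "avg_intra_n2n_total",
  "inter-cluster centroid to centroid minimum distance", "inter_c2c_min",
  "inter-cluster centroid to centroid maximum distance", "inter_c2c_max",
  "maximum area of a cluster", "max_cluster_area",
  "inter-cluster minimum MST distance", "inter_mst_min"
)

#' Names of the 26 cluster features
#'
#' Returns the fixed, ordered names of the cluster descriptor. The order
#' is stable and is the column order of [extract_features()].
#'
#' @param format `"snake"` for machine-usable column names (default) or
#'   `"display"` for the long descriptive names; `"both"` returns the
#'   two-column mapping tibble.
#' @return Character vector of length 26, or a tibble for `"both"`.
#' @export
feature_names <- function(format = c("snake", "display", "both")) {
  format <- match.arg(format)
  switch(format,
         snake = .feature_table$snake,
         display = .feature_table$display,
         both = .feature_table)
}

#' Extract the 26-feature cluster descriptor
#'
#' Computes the full fixed-order feature vector of a clustered patch from
#' the per-cluster ([intra_cluster_summary()]) and between-cluster
#' ([inter_cluster_summary()]) distance summaries. Every "total" feature
#' is the sum, and every "average" feature the mean, of the corresponding
#' per-cluster quantity, so `total = n_clusters * average` holds exactly.
#' With a single cluster all nine inter-cluster features are 0 (not
#' missing), keeping vectors complete for downstream learning.
#'
#' @param cs A `cluster_set` from [cut_edges()] or [cluster_nuclei()].
#' @param areas Optional per-vertex nucleus pixel areas; required when
#'   `area_mode = "nucleus"`.
#' @param area_mode Cluster-area reading: `"hull"` (convex-hull area of
#'   member centroids, the default) or `"nucleus"` (sum of member nucleus
#'   pixel areas).
#' @return A one-row tibble with the 26 feature columns in
#'   [feature_names()] order.
#' @export
extract_features <- function(cs, areas = NULL,
                             area_mode = c("hull", "nucleus")) {
  stopifnot(inherits(cs, "cluster_set"))
  if (!length(cs$clusters)) stop("empty cluster set", call. = FALSE)
  area_mode <- match.arg(area_mode)
  if (area_mode == "nucleus" && is.null(areas)) {
    stop('`areas` is required when area_mode = "nucleus"', call. = FALSE)
  }
  intra <- intra_cluster_summary(cs, areas = areas)
  inter <- inter_cluster_summary(cs)
  carea <- if (area_mode == "hull") intra$hull_area else intra$nucleus_area
  out <- tibble::tibble(
    total_intra_mst_total = sum(intra$mst_total),
    total_intra_n2n_max = sum(intra$pair_max),
    inter_c2c_total = inter$c2c_total,
    inter_mst_total = inter$mst_total,
    n_clusters = inter$n_clusters,
    total_intra_mst_max = sum(intra$mst_max),
    avg_intra_n2n_min = mean(intra$pair_min),
    avg_intra_n2n_max = mean(intra$pair_max),
    avg_intra_mst_max = mean(intra$mst_max),
    avg_cluster_area = mean(carea),
    total_intra_n2n_total = sum(intra$pair_total),
    total_intra_mst_min = sum(intra$mst_min),
    total_intra_n2n_min = sum(intra$pair_min),
    inter_mst_max = inter$mst_max,
    avg_intra_mst_total = mean(intra$mst_total),
    avg_intra_mst_min = mean(intra$mst_min),
    total_cluster_area = sum(carea),
    inter_mst_avg = inter$mst_avg,
    avg_intra_n2n_avg = mean(intra$pair_avg),
    inter_c2c_avg = inter$c2c_avg,
    min_cluster_area = min(carea),
    avg_intra_n2n_total = mean(intra$pair_total),
    inter_c2c_min = inter$c2c_min,
    inter_c2c_max = inter$c2c_max,
    max_cluster_area = max(carea),
    inter_mst_min = inter$mst_min
  )
  stopifnot(identical(names(out), feature_names()))
  out
}
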