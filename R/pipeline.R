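# Pipeline orchestration: normalize -> deconvolve -> segment -> cluster ->
# features (-> select -> classify), with persisted intermediates and a
# manifest for auditability.

#' Pipeline configuration
#'
#' All stage parameters in one serialisable object. Defaults are the
#' package defaults of each stage; see [segment_config()],
#' [cut_edges()], [select_features()], [five_fold_evaluate()].
#'
#' @param segment A [segment_config()].
#' @param cut_mode,cut_value MST edge-cut rule (default threshold, 10 px).
#' @param area_mode Cluster-area reading for [extract_features()].
#' @param k_select,min_votes Feature-selection parameters.
#' @param n_splits,train_frac,scheme Classification protocol.
#' @param run_selection,run_classification Toggle the learning stages
#'   (they also require labels).
#' @param seed Master seed.
#' @return A list of class `pipeline_config`, version-stamped.
#' @export
pipeline_config <- function(segment = segment_config(),
                            cut_mode = "threshold", cut_value = 10,
                            area_mode = "hull", k_select = 16L,
                            min_votes = 4L, n_splits = 5L,
                            train_frac = 0.8, scheme = "split_test",
                            run_selection = TRUE,
                            run_classification = TRUE, seed = 1L) {
  structure(list(version = "1", segment = segment, cut_mode = cut_mode,
                 cut_value = cut_value, area_mode = area_mode,
                 k_select = as.integer(k_select),
                 min_votes = as.integer(min_votes),
                 n_splits = as.integer(n_splits), train_frac = train_frac,
                 scheme = scheme, run_selection = run_selection,
                 run_classification = run_classification,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration as JSON
#'
#' The round trip is lossless (the stain matrix is stored row-wise).
#'
#' @param config A [pipeline_config()].
#' @param path JSON file path.
#' @return `path` (write) or the restored `pipeline_config` (read).
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  x$segment <- unclass(x$segment)
  x$segment$stain_matrix <- as.vector(t(x$segment$stain_matrix))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  sm <- matrix(x$segment$stain_matrix, nrow = 2, byrow = TRUE,
               dimnames = list(c("hematoxylin", "eosin"), c("R", "G", "B")))
  seg <- do.call(segment_config,
                 c(x$segment[setdiff(names(x$segment), "stain_matrix")],
                   list(stain_matrix = sm)))
  args <- x[setdiff(names(x), c("segment", "version"))]
  do.call(pipeline_config, c(list(segment = seg), args))
}

stage <- function(name, id, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed for '%s': %s",
                 name, id, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full cluster-analysis pipeline
#'
#' Executes segmentation, MST clustering and feature extraction for every
#' patch, then (when labels are available) majority-voting feature
#' selection and supervised/unsupervised classification. Intermediates
#' (masks, centroid tables, cluster assignments, the vote matrix, metric
#' tables) are written to `out_dir` when given, and a manifest records
#' the config hash, seed and per-stage counts.
#'
#' @param images A named list of RGB arrays, or a character vector of PNG
#'   paths (names/base names become image ids), or a directory containing
#'   PNGs.
#' @param labels Optional grade labels, one per image (enables the
#'   selection and classification stages).
#' @param config A [pipeline_config()].
#' @param reference Optional stain-normalization reference
#'   (`stain_stats` or RGB array).
#' @param out_dir Optional output directory for intermediates.
#' @return List of class `pipeline_result`: `features` (tibble, one row
#'   per image), `selection` (vote matrix or NULL), `classification`
#'   (list of metric tibbles or NULL), `manifest`.
#' @export
run_pipeline <- function(images, labels = NULL,
                         config = pipeline_config(), reference = NULL,
                         out_dir = NULL) {
  if (is.character(images) && length(images) == 1L && dir.exists(images)) {
    images <- list.files(images, pattern = "\\.png$", full.names = TRUE)
  }
  if (is.character(images)) {
    if (!length(images)) {
      stop("pipeline stage 'input': no images found", call. = FALSE)
    }
    paths <- images
    images <- lapply(paths, read_patch)
    names(images) <- sub("\\.png$", "", basename(paths))
  }
  if (!length(images)) {
    stop("pipeline stage 'input': no images supplied", call. = FALSE)
  }
  if (is.null(names(images)) || any(names(images) == "")) {
    names(images) <- sprintf("image_%03d", seq_along(images))
  }
  if (!is.null(labels) && length(labels) != length(images)) {
    stop("pipeline stage 'input': one label per image required",
         call. = FALSE)
  }
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE,
                                    recursive = TRUE)
  counts <- list()
  feats <- vector("list", length(images))
  for (i in seq_along(images)) {
    id <- names(images)[i]
    nuc <- stage("segment", id,
                 segment_nuclei(images[[i]], config$segment,
                                reference = reference))
    cs <- stage("cluster", id,
                cluster_nuclei(nuc$centroids, mode = config$cut_mode,
                               value = config$cut_value))
    fv <- stage("features", id,
                extract_features(cs, areas = nuc$centroids$area,
                                 area_mode = config$area_mode))
    counts[[id]] <- list(n_nuclei = nrow(nuc$centroids),
                         n_clusters = length(cs$clusters))
    feats[[i]] <- dplyr::bind_cols(tibble::tibble(image_id = id), fv)
    if (!is.null(out_dir)) {
      write_mask(nuc$mask, file.path(out_dir, paste0(id, "_mask.pgm")))
      utils::write.csv(nuc$centroids,
                       file.path(out_dir, paste0(id, "_centroids.csv")),
                       row.names = FALSE)
      utils::write.csv(
        data.frame(label = seq_along(cs$membership),
                   cluster = cs$membership),
        file.path(out_dir, paste0(id, "_clusters.csv")), row.names = FALSE)
    }
  }
  features <- dplyr::bind_rows(feats)
  if (!is.null(labels)) features$grade <- labels
  selection <- NULL
  classification <- NULL
  if (!is.null(labels) && config$run_selection) {
    selection <- stage("select", "feature table",
                       select_features(features, labels = "grade",
                                       k_select = min(config$k_select,
                                                      26L),
                                       min_votes = config$min_votes,
                                       seed = config$seed))
  }
  if (!is.null(labels) && config$run_classification) {
    y <- as_label_factor(labels)
    feasible <- min(table(y)) >=
      ceiling(config$n_splits / (1 - config$train_frac))
    classification <- if (feasible) {
      keep <- if (!is.null(selection)) selected_features(selection) else
        feature_names()
      tab <- features[c("image_id", keep)]
      tab$grade <- y
      list(
        supervised = stage("classify", "supervised",
                           five_fold_evaluate(tab, "grade",
                                              model = "stacked",
                                              n_splits = config$n_splits,
                                              seed = config$seed,
                                              scheme = config$scheme,
                                              train_frac =
                                                config$train_frac)),
        unsupervised = stage("classify", "unsupervised",
                             five_fold_evaluate(tab, "grade",
                                                model = "kmedoids",
                                                n_splits = config$n_splits,
                                                seed = config$seed)))
    } else NULL
  }
  manifest <- list(
    version = config$version,
    config_hash = digest::digest(config),
    seed = config$seed,
    n_images = length(images),
    per_image = counts,
    feature_hash = digest::digest(features))
  if (!is.null(out_dir)) {
    utils::write.csv(features, file.path(out_dir, "features.csv"),
                     row.names = FALSE)
    if (!is.null(selection)) {
      utils::write.csv(as.data.frame(selection),
                       file.path(out_dir, "votes.csv"), row.names = FALSE)
    }
    if (!is.null(classification)) {
      utils::write.csv(classification$supervised,
                       file.path(out_dir, "metrics_supervised.csv"),
                       row.names = FALSE)
      utils::write.csv(classification$unsupervised,
                       file.path(out_dir, "metrics_unsupervised.csv"),
                       row.names = FALSE)
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  structure(list(features = features, selection = selection,
                 classification = classification, manifest = manifest),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d images -> %d x %d feature table\n",
              x$manifest$n_images, nrow(x$features),
              ncol(x$features)))
  if (!is.null(x$selection)) {
    cat(sprintf("  selection: %d features selected\n",
                length(selected_features(x$selection))))
  }
  if (!is.null(x$classification)) {
    avg <- x$classification$supervised
    cat(sprintf("  supervised average-split accuracy: %.1f%%\n",
                avg$accuracy[avg$split == "Average Split"]))
  }
  invisible(x)
}
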