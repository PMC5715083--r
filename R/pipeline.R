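# End-to-end pipeline: masks -> gland table -> image features -> grading
# report, plus configuration and label-file handling.

#' Pipeline configuration
#'
#' Nested configuration for the full pipeline. Every section accepts the same
#' arguments as its constructor; unknown keys are rejected.
#'
#' @param aberrance list of [aberrance_config()] overrides.
#' @param bins list with `step`, `start`, `n_bins` for the BAM histogram.
#' @param postprocess list of [postprocess_config()] overrides.
#' @param grading list of [grading_config()] overrides.
#' @param synthetic list of [synthetic_config()] overrides.
#' @return list of class `pipeline_config` with fully populated sections.
#' @export
pipeline_config <- function(aberrance = list(), bins = list(),
                            postprocess = list(), grading = list(),
                            synthetic = list()) {
  build <- function(fun, args, allowed) {
    bad <- setdiff(names(args), allowed)
    if (length(bad))
      gb_stop("glandbam_schema", "unknown config key(s): %s",
              paste(bad, collapse = ", "))
    do.call(fun, args)
  }
  bins_full <- utils::modifyList(list(step = 0.015, start = 0, n_bins = 7L), bins)
  bad <- setdiff(names(bins), c("step", "start", "n_bins"))
  if (length(bad))
    gb_stop("glandbam_schema", "unknown config key(s): %s", paste(bad, collapse = ", "))
  structure(list(
    aberrance = build(aberrance_config, aberrance, names(formals(aberrance_config))),
    bins = bins_full,
    postprocess = build(postprocess_config, postprocess, names(formals(postprocess_config))),
    grading = build(grading_config, grading, names(formals(grading_config))),
    synthetic = build(synthetic_config, synthetic, names(formals(synthetic_config)))
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML (or JSON)
#'
#' Sections and keys must match [pipeline_config()]; unknown keys are
#' rejected. A loaded configuration round-trips: writing it back with
#' [write_pipeline_config()] and reloading yields an identical object.
#'
#' @param path YAML (or JSON) file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  bad <- setdiff(names(raw), c("aberrance", "bins", "postprocess", "grading", "synthetic"))
  if (length(bad))
    gb_stop("glandbam_schema", "unknown config section(s): %s", paste(bad, collapse = ", "))
  do.call(pipeline_config, raw)
}

#' Write a pipeline configuration as YAML
#' @param config a `pipeline_config`.
#' @param path output path.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(lapply(config, function(s) lapply(unclass(s), identity)), path)
  invisible(path)
}

# polynomial rolling hash of the serialized configuration, for provenance
# lines in logs and reports
config_hash <- function(config) {
  s <- yaml::as.yaml(lapply(config, unclass))
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Read a grade label file
#'
#' CSV with header `image_id,label`; labels must be `normal`, `low_grade` or
#' `high_grade`. Duplicated image ids keep the last row, with a warning.
#'
#' @param path CSV path.
#' @return named character vector mapping image_id to grade.
#' @export
read_labels <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("image_id", "label") %in% names(df)))
    gb_stop("glandbam_schema", "label file needs columns image_id,label")
  bad <- which(!df$label %in% GRADES)
  if (length(bad))
    gb_stop("glandbam_schema", "unknown label '%s' in row %d",
            df$label[bad[1L]], bad[1L])
  if (anyDuplicated(df$image_id)) {
    warning("duplicate image_id(s) in label file; last occurrence wins")
    df <- df[!duplicated(df$image_id, fromLast = TRUE), , drop = FALSE]
  }
  setNames(df$label, df$image_id)
}

#' Run the full grading pipeline on a directory of masks
#'
#' For every PNG/TIFF label mask: extract glands, compute aberrance, build
#' pre- and post-postprocessing feature rows; then cross-validate the grader
#' on the postprocessed features of all images with known labels. Per-image
#' failures are logged and skipped, never fatal.
#'
#' Writes `glands.csv`, `features_pre.csv`, `features_post.csv`,
#' `report.json`, `roc_points.csv` and `pipeline.log` to `out_dir`.
#'
#' @param mask_dir directory of mask images.
#' @param labels_file optional CSV for [read_labels()]; unlabeled images are
#'   graded as `unknown` and excluded from cross-validation.
#' @param config a `pipeline_config`, a YAML path, or NULL for defaults.
#' @param out_dir output directory (created if needed).
#' @return list with `glands`, `features_pre`, `features_post`, `reports`
#'   (one `eval_report` per task), invisibly.
#' @export
run_pipeline <- function(mask_dir, labels_file = NULL, config = NULL,
                         out_dir = "glandbam_out") {
  config <- if (is.null(config)) pipeline_config()
  else if (is.character(config)) read_pipeline_config(config)
  else config
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  log_path <- file.path(out_dir, "pipeline.log")
  logf <- function(fmt, ...) cat(sprintf(paste0(fmt, "\n"), ...),
                                 file = log_path, append = TRUE)
  cat(sprintf("glandbam pipeline | config %s | seed %d\n",
              config_hash(config), config$grading$seed), file = log_path)
  paths <- list.files(mask_dir, pattern = "\\.(png|tif|tiff)$",
                      ignore.case = TRUE, full.names = TRUE)
  labels <- if (is.null(labels_file)) character(0) else read_labels(labels_file)
  glands <- list(); pre <- list(); post <- list()
  bins <- config$bins
  for (p in sort(paths)) {
    image_id <- tools::file_path_sans_ext(basename(p))
    res <- tryCatch({
      mask <- read_mask(p)
      records <- image_aberrance_table(mask, image_id, config$aberrance)
      label <- if (image_id %in% names(labels)) labels[[image_id]] else "unknown"
      f_pre <- compute_image_features(records, step = bins$step,
                                      start = bins$start, n_bins = bins$n_bins,
                                      include_baseline = config$aberrance$baseline,
                                      label = label)
      pp <- postprocess_features(records, f_pre, config$postprocess,
                                 step = bins$step, start = bins$start,
                                 n_bins = bins$n_bins)
      list(records = pp$records, f_pre = f_pre, f_post = pp$features)
    }, error = function(e) {
      logf("SKIP %s: %s", image_id, conditionMessage(e))
      NULL
    })
    if (is.null(res)) next
    df <- as.data.frame(res$records)
    glands[[image_id]] <- df
    pre[[image_id]] <- res$f_pre
    post[[image_id]] <- res$f_post
    logf("image %s: %d glands, %d excluded, mean_bam %.4f, RI %.3f, label %s",
         image_id, nrow(df), sum(df$excluded), res$f_post$mean_bam,
         res$f_post$regularity_index, res$f_post$label)
  }
  if (!length(post))
    gb_stop("glandbam_invalid_input", "no valid images found in %s", mask_dir)
  glands <- do.call(rbind, glands)
  features_pre <- do.call(rbind, pre)
  features_post <- do.call(rbind, post)
  rownames(glands) <- rownames(features_pre) <- rownames(features_post) <- NULL
  write.csv(glands, file.path(out_dir, "glands.csv"), row.names = FALSE)
  write.csv(features_pre, file.path(out_dir, "features_pre.csv"), row.names = FALSE)
  write.csv(features_post, file.path(out_dir, "features_post.csv"), row.names = FALSE)
  labeled <- features_post[features_post$label %in% GRADES, , drop = FALSE]
  reports <- list()
  roc_rows <- list()
  for (task in c("two_class", "three_class")) {
    cfg_t <- config$grading; cfg_t$task <- task
    rep_t <- tryCatch(cross_validate(labeled, cfg_t), error = function(e) {
      logf("grading (%s) skipped: %s", task, conditionMessage(e)); NULL
    })
    if (is.null(rep_t)) next
    reports[[task]] <- rep_t
    for (k in names(rep_t$roc))
      roc_rows[[paste(task, k)]] <- data.frame(task = task, class = k,
                                               rep_t$roc[[k]]$points)
  }
  jsonlite::write_json(lapply(reports, eval_report_json),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (length(roc_rows))
    write.csv(do.call(rbind, roc_rows), file.path(out_dir, "roc_points.csv"),
              row.names = FALSE)
  invisible(list(glands = glands, features_pre = features_pre,
                 features_post = features_post, reports = reports))
}

# JSON-friendly view of an eval_report
eval_report_json <- function(r) {
  list(task = r$task, feature_set = r$feature_set, n_images = r$n_images,
       folds = r$folds, repeats = r$repeats,
       accuracy_mean = unname(r$accuracy["mean"]),
       accuracy_sd = unname(r$accuracy["sd"]),
       per_class = r$per_class,
       confusion = as.data.frame.matrix(r$confusion),
       auc = lapply(r$roc, `[[`, "auc"),
       binary_views = r$binary_views)
}
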