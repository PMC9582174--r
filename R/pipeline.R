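#' Run the full annotation-agreement pipeline
#'
#' Orchestrates the analysis stages in order: (optional) occlusion saliency
#' per case, free-text normalization and topic extraction, per-case and
#' per-image-variant anchor clustering followed by cross-variant merging,
#' per-ROI topic percentage tables, main-label agreement, and Mann-Whitney
#' group comparisons. All artifacts are written to `out_dir` together with a
#' run manifest (configuration, seed, package version, MD5 content hash of
#' every output file). Re-running with identical inputs and seed reproduces
#' byte-identical CSV/JSON outputs.
#'
#' @param annotations annotation table (data frame) or path to a CSV in the
#'   [read_annotations()] dialect.
#' @param cases case metadata (data frame with `case_id`, `truth`,
#'   `ai_label`) or path to a CSV.
#' @param lexicon a `topic_lexicon`.
#' @param cluster_threshold anchor clustering threshold in pixels.
#' @param merge_variants merge clusters across the original/saliency image
#'   variants (identity registration)?
#' @param comparisons named list of group contrasts; see
#'   [default_comparisons()].
#' @param volumes optional named list (by `case_id`) of 3D arrays or NIfTI
#'   paths; if given together with `scorer`, an occlusion saliency map is
#'   computed and written per case.
#' @param scorer optional scorer for the saliency stage.
#' @param occlusion an [occlusion_config()] for the saliency stage.
#' @param out_dir output directory; `NULL` skips writing.
#' @param seed integer seed recorded in the manifest and applied before any
#'   stage that could consume randomness.
#' @return list of class `obsm_results`: `vectors`, `clusters` (named by
#'   case), `cluster_table`, `assignment_table`, `profiles`, `agreement`,
#'   `comparisons`, `saliency` (per-case peak slices, if computed),
#'   `manifest`.
#' @export
run_full_study <- function(annotations, cases, lexicon = default_lexicon(),
                           cluster_threshold = 50, merge_variants = TRUE,
                           comparisons = default_comparisons(),
                           volumes = NULL, scorer = NULL,
                           occlusion = occlusion_config(),
                           out_dir = NULL, seed = 1L) {
  if (is.character(annotations)) {
    if (!file.exists(annotations))
      stop("annotation file not found: ", annotations, call. = FALSE)
    annotations <- read_annotations(annotations)
  } else {
    annotations <- validate_annotations(annotations)
  }
  if (is.character(cases)) {
    if (!file.exists(cases))
      stop("case metadata file not found: ", cases, call. = FALSE)
    cases <- read_case_meta(cases)
  } else {
    stopifnot(is.data.frame(cases),
              all(c("case_id", "truth", "ai_label") %in% names(cases)))
    cases$group <- derive_group(cases$truth, cases$ai_label)
  }
  if (!all(annotations$case_id %in% cases$case_id))
    stop("annotations reference case(s) without metadata", call. = FALSE)
  set.seed(seed)

  # --- optional saliency stage -----------------------------------------
  saliency <- NULL
  if (!is.null(volumes) && !is.null(scorer)) {
    saliency <- lapply(names(volumes), function(cid) {
      v <- volumes[[cid]]
      if (is.character(v)) v <- read_volume(v)
      map <- compute_occlusion_map(v, scorer, occlusion)
      up <- upsample_map(map, "trilinear")
      peak <- select_peak_slice(up)
      if (!is.null(out_dir)) {
        dir.create(file.path(out_dir, "saliency"), showWarnings = FALSE,
                   recursive = TRUE)
        write_saliency(map, file.path(out_dir, "saliency",
                                      paste0(cid, "_saliency.nii.gz")))
      }
      list(case_id = cid, map = map, peak_slice = peak)
    })
    names(saliency) <- names(volumes)
  }

  # --- text stage -------------------------------------------------------
  vectors <- annotation_topic_vectors(annotations, lexicon)

  # --- clustering stage -------------------------------------------------
  cluster_case <- function(df) {
    df <- df[order(df$reader_id), , drop = FALSE]
    anchors <- data.frame(annotation_id = df$annotation_id,
                          case_id = df$case_id, reader_id = df$reader_id,
                          image_variant = df$image_variant,
                          x = df$x_ul, y = df$y_ul,
                          stringsAsFactors = FALSE)
    if (merge_variants) {
      parts <- lapply(c("original", "saliency"), function(v)
        cluster_annotations(anchors[anchors$image_variant == v, ,
                                    drop = FALSE],
                            threshold = cluster_threshold))
      merge_registered_clusters(parts[[1L]], parts[[2L]],
                                merge_threshold = cluster_threshold)
    } else {
      cluster_annotations(anchors, threshold = cluster_threshold)
    }
  }
  case_ids <- sort(unique(annotations$case_id))
  clusters <- lapply(case_ids, function(cid)
    cluster_case(annotations[annotations$case_id == cid, , drop = FALSE]))
  names(clusters) <- case_ids

  # case-scoped cluster ids made globally unique
  assignment_table <- do.call(rbind, lapply(case_ids, function(cid) {
    a <- clusters[[cid]]$assignments
    a$cluster_id <- sprintf("%s_%02d", cid, a$cluster_id)
    a
  }))
  rownames(assignment_table) <- NULL
  cluster_table <- do.call(rbind, lapply(case_ids, function(cid) {
    cl <- clusters[[cid]]$clusters
    data.frame(case_id = cid,
               cluster_id = sprintf("%s_%02d", cid, cl$cluster_id),
               n_members = cl$n_members,
               median_x = cl$median_x, median_y = cl$median_y,
               stringsAsFactors = FALSE)
  }))
  rownames(cluster_table) <- NULL

  # --- statistics stage -------------------------------------------------
  profiles <- topic_percent_table(assignment_table, vectors, lexicon)
  agreement <- main_label_agreement(assignment_table, vectors)
  comparison_table <- compare_groups(profiles, cases,
                                     comparisons = comparisons,
                                     lexicon = lexicon)

  results <- list(vectors = vectors, clusters = clusters,
                  assignment_table = assignment_table,
                  cluster_table = cluster_table, profiles = profiles,
                  agreement = agreement, comparisons = comparison_table,
                  saliency = saliency, seed = seed)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(
      annotation_topics = "annotation_topics.csv",
      cluster_members = "cluster_members.csv",
      clusters = "clusters.csv",
      topic_profiles = "topic_profiles.csv",
      agreement = "agreement.json",
      comparisons = "comparisons.csv")
    utils::write.csv(vectors, file.path(out_dir, paths["annotation_topics"]),
                     row.names = FALSE)
    utils::write.csv(assignment_table,
                     file.path(out_dir, paths["cluster_members"]),
                     row.names = FALSE)
    utils::write.csv(cluster_table, file.path(out_dir, paths["clusters"]),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(profiles),
                     file.path(out_dir, paths["topic_profiles"]),
                     row.names = FALSE)
    jsonlite::write_json(list(per_roi = agreement$per_roi,
                              n_rois = agreement$n_rois,
                              n_unanimous = agreement$n_unanimous,
                              overall_unanimous_rate =
                                agreement$overall_unanimous_rate,
                              overall_unanimous_pct =
                                agreement$overall_unanimous_pct,
                              mean_modal_fraction =
                                agreement$mean_modal_fraction),
                         file.path(out_dir, paths["agreement"]),
                         auto_unbox = TRUE, digits = NA)
    utils::write.csv(comparison_table,
                     file.path(out_dir, paths["comparisons"]),
                     row.names = FALSE)
    files <- file.path(out_dir, paths)
    manifest <- list(
      package_version = as.character(utils::packageVersion("obsm")),
      seed = seed,
      cluster_threshold = cluster_threshold,
      merge_variants = merge_variants,
      comparisons = names(comparisons),
      n_annotations = nrow(annotations),
      n_cases = nrow(cases),
      files = data.frame(file = unname(paths),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    results$manifest <- manifest
  }
  structure(results, class = "obsm_results")
}

#' @export
print.obsm_results <- function(x, ...) {
  cat(sprintf(paste0("pipeline results: %d annotations in %d clusters ",
                     "across %d cases; %d nodule ROIs profiled\n"),
              nrow(x$assignment_table), nrow(x$cluster_table),
              length(x$clusters), nrow(x$profiles)))
  print(x$agreement)
  invisible(x)
}
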