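#' Derive the AI-correctness case group
#'
#' Cases are grouped by truth label and the AI tool's output: `cB`/`cM` are
#' correctly classified benign/malignant cases, `mB` is a benign case the AI
#' called malignant (a false positive), `mM` a malignant case the AI called
#' benign (a false negative).
#'
#' @param truth,ai_label character vectors with values `"benign"` or
#'   `"malignant"`.
#' @return character vector in `{cB, mB, cM, mM}`.
#' @export
derive_group <- function(truth, ai_label) {
  stopifnot(all(truth %in% c("benign", "malignant")),
            all(ai_label %in% c("benign", "malignant")),
            length(truth) == length(ai_label))
  ifelse(truth == "benign",
         ifelse(ai_label == "benign", "cB", "mB"),
         ifelse(ai_label == "malignant", "cM", "mM"))
}

#' Read case metadata from CSV
#'
#' Expected columns: `case_id`, `truth`, `ai_label`; the `group` column is
#' (re)derived with [derive_group()].
#'
#' @param path CSV path.
#' @return data frame with `case_id`, `truth`, `ai_label`, `group`.
#' @export
read_case_meta <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("case_id", "truth", "ai_label"), names(df))
  if (length(missing) > 0L)
    stop("case metadata is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  df$group <- derive_group(df$truth, df$ai_label)
  df
}

#' Mann-Whitney U test for two independent samples
#'
#' Rank-sum test with midranks for ties. The p-value is two-sided: exact (by
#' complete enumeration of the null distribution) when the combined sample
#' size is at most 16 and there are no ties, otherwise the normal
#' approximation with tie and continuity correction. Identical samples (all
#' values equal across both groups) return `U = n_a * n_b / 2` and `p = 1`.
#'
#' @param a,b numeric samples (each of length at least 1).
#' @return list of class `group_comparison`: `U` (statistic for sample `a`),
#'   `p`, `method` (`"exact"` or `"normal_tie_corrected"`), `n_a`, `n_b`.
#' @export
mann_whitney_u <- function(a, b) {
  stopifnot(is.numeric(a), is.numeric(b), length(a) >= 1L, length(b) >= 1L,
            all(is.finite(a)), all(is.finite(b)))
  n_a <- length(a); n_b <- length(b)
  ranks <- rank(c(a, b))
  u <- sum(ranks[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  ties <- anyDuplicated(c(a, b)) > 0L
  if (length(unique(c(a, b))) == 1L) {
    res <- list(U = n_a * n_b / 2, p = 1, method = "normal_tie_corrected",
                n_a = n_a, n_b = n_b)
    return(structure(res, class = "group_comparison"))
  }
  exact <- (n_a + n_b) <= 16L && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided", exact = exact,
                       correct = TRUE))
  structure(list(U = u, p = unname(wt$p.value),
                 method = if (exact) "exact" else "normal_tie_corrected",
                 n_a = n_a, n_b = n_b),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %g (n = %d, %d), two-sided p = %.4g [%s]\n",
              x$U, x$n_a, x$n_b, x$p, x$method))
  invisible(x)
}

# join cluster assignments with per-annotation topic vectors
cluster_vectors <- function(clusters, vectors) {
  assignments <- if (inherits(clusters, "roi_clusters")) clusters$assignments
                 else clusters
  stopifnot(is.data.frame(assignments),
            all(c("annotation_id", "cluster_id") %in% names(assignments)),
            is.data.frame(vectors),
            all(c("annotation_id", "main_label") %in% names(vectors)))
  merged <- merge(assignments[, c("annotation_id", "cluster_id",
                                  intersect("case_id", names(assignments)))],
                  vectors, by = "annotation_id")
  if (nrow(merged) < nrow(assignments))
    stop("every clustered annotation must have a topic vector", call. = FALSE)
  merged
}

#' Per-ROI topic percentage table
#'
#' For every cluster annotated as "nodule" by at least one reader, the
#' percentage of its member annotations whose text mentions each of the 14
#' topics (the shape of the published per-area descriptor tables).
#' Percentages are kept at full precision; printing rounds to integers.
#'
#' @param clusters a `roi_clusters` object (or its `assignments` data frame;
#'   a `case_id` column is carried through if present).
#' @param vectors per-annotation topic vectors from
#'   [annotation_topic_vectors()].
#' @param lexicon a `topic_lexicon`.
#' @param nodule_only keep only clusters containing at least one
#'   nodule-labeled annotation (default), as in the published tables.
#' @return data frame of class `topic_profiles`: `cluster_id`, `case_id`
#'   (if available), `n_annotations`, then one percentage column per topic.
#' @export
topic_percent_table <- function(clusters, vectors, lexicon = default_lexicon(),
                                nodule_only = TRUE) {
  merged <- cluster_vectors(clusters, vectors)
  topics <- lexicon$topics
  stopifnot(all(topics %in% names(merged)))
  rows <- lapply(split(merged, merged$cluster_id), function(g) {
    if (nrow(g) == 0L) return(NULL)
    if (nodule_only && !any(g$main_label == "nodule")) return(NULL)
    pct <- vapply(topics, function(t) 100 * mean(g[[t]]), numeric(1))
    out <- data.frame(cluster_id = g$cluster_id[1L], n_annotations = nrow(g))
    if (!is.null(g$case_id)) out$case_id <- g$case_id[1L]
    cbind(out, as.data.frame(as.list(pct), check.names = FALSE))
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0L) {
    warning("no nodule-labeled cluster found", call. = FALSE)
    return(structure(data.frame(), class = c("topic_profiles", "data.frame")))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("topic_profiles", "data.frame"))
}

#' @export
print.topic_profiles <- function(x, ...) {
  y <- as.data.frame(x)
  num <- setdiff(names(y)[vapply(y, is.numeric, TRUE)],
                 c("cluster_id", "n_annotations"))
  y[num] <- lapply(y[num], round)
  print(y, ...)
  invisible(x)
}

#' Main-label agreement across readers, per ROI
#'
#' For every cluster, the modal high-level label (nodule, vessel, ...) over
#' its members' non-"unlabeled" labels, the fraction of members bearing it,
#' and whether the readers were unanimous. The overall unanimity rate is the
#' share of ROIs on which every labeled annotation used the same main label,
#' also reported as a percentage rounded to the nearest integer.
#'
#' @inheritParams topic_percent_table
#' @return list of class `agreement_summary`: `per_roi` data frame
#'   (`cluster_id`, `n`, `n_labeled`, `modal_label`, `modal_fraction`,
#'   `unanimous`), `n_rois`, `n_unanimous`, `overall_unanimous_rate`
#'   (fraction) and `overall_unanimous_pct` (rounded percentage).
#' @export
main_label_agreement <- function(clusters, vectors) {
  merged <- cluster_vectors(clusters, vectors)
  per <- lapply(split(merged, merged$cluster_id), function(g) {
    labels <- g$main_label[g$main_label != "unlabeled"]
    if (length(labels) == 0L) {
      message("cluster ", g$cluster_id[1L],
              " has no labeled annotation; excluded from the unanimity rate")
      return(NULL)
    }
    tab <- sort(table(labels), decreasing = TRUE)
    data.frame(cluster_id = g$cluster_id[1L], n = nrow(g),
               n_labeled = length(labels),
               modal_label = names(tab)[1L],
               modal_fraction = as.numeric(tab[1L]) / length(labels),
               unanimous = length(tab) == 1L)
  })
  per <- do.call(rbind, per[!vapply(per, is.null, TRUE)])
  rownames(per) <- NULL
  n_rois <- nrow(per)
  n_unanimous <- sum(per$unanimous)
  structure(list(per_roi = per, n_rois = n_rois, n_unanimous = n_unanimous,
                 overall_unanimous_rate = n_unanimous / n_rois,
                 overall_unanimous_pct = round(100 * n_unanimous / n_rois),
                 mean_modal_fraction = mean(per$modal_fraction)),
            class = "agreement_summary")
}

#' @export
print.agreement_summary <- function(x, ...) {
  cat(sprintf(paste0("main-label agreement: %d of %d ROIs unanimous (%d%%); ",
                     "mean modal fraction %.2f\n"),
              x$n_unanimous, x$n_rois, x$overall_unanimous_pct,
              x$mean_modal_fraction))
  invisible(x)
}

#' Standard case-group comparisons
#'
#' The five preconfigured contrasts: within-benign (cB vs mB), within-
#' malignant (cM vs mM), all benign vs all malignant, and the two
#' cross-contrasts linking the AI output (cB vs mM: both called benign;
#' mB vs cM: both called malignant).
#'
#' @return named list of `list(a = groups, b = groups)` pairs.
#' @export
default_comparisons <- function() {
  list(cB_vs_mB = list(a = "cB", b = "mB"),
       cM_vs_mM = list(a = "cM", b = "mM"),
       B_vs_M = list(a = c("cB", "mB"), b = c("cM", "mM")),
       cB_vs_mM = list(a = "cB", b = "mM"),
       mB_vs_cM = list(a = "mB", b = "cM"))
}

#' Compare per-ROI topic percentages between case groups
#'
#' For each topic and each configured comparison, collects the per-ROI topic
#' percentages of the two case groups, reports the group means (unweighted
#' over ROIs by default, or weighted by annotation counts), and tests the
#' difference with [mann_whitney_u()]. P-values are reported raw, without
#' multiplicity adjustment; set `adjust = "BH"` for Benjamini-Hochberg
#' adjusted values in an extra column.
#'
#' @param profiles a `topic_profiles` table with a `case_id` column.
#' @param meta case metadata with `case_id` and `group` (see
#'   [read_case_meta()]).
#' @param comparisons named list as produced by [default_comparisons()].
#' @param lexicon a `topic_lexicon`.
#' @param weight `"roi"` (unweighted mean over ROIs, default) or
#'   `"annotation"` (ROIs weighted by their annotation counts) for the
#'   reported group means.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return data frame: `comparison`, `topic`, `n_a`, `n_b`, `mean_a`,
#'   `mean_b`, `U`, `p`, `method` (and `p_adj` if requested). Comparisons
#'   where either group has no ROI are skipped with a warning.
#' @export
compare_groups <- function(profiles, meta, comparisons = default_comparisons(),
                           lexicon = default_lexicon(),
                           weight = c("roi", "annotation"),
                           adjust = c("none", "BH")) {
  weight <- match.arg(weight)
  adjust <- match.arg(adjust)
  stopifnot(is.data.frame(profiles), "case_id" %in% names(profiles),
            is.data.frame(meta),
            all(c("case_id", "group") %in% names(meta)))
  if (!all(profiles$case_id %in% meta$case_id))
    stop("every ROI must map to a case with metadata", call. = FALSE)
  grp <- meta$group[match(profiles$case_id, meta$case_id)]
  topics <- intersect(lexicon$topics, names(profiles))
  rows <- list()
  for (cmp_name in names(comparisons)) {
    cmp <- comparisons[[cmp_name]]
    ia <- grp %in% cmp$a
    ib <- grp %in% cmp$b
    if (!any(ia) || !any(ib)) {
      warning("comparison ", cmp_name, " skipped: a group has no ROI",
              call. = FALSE)
      next
    }
    wmean <- function(v, idx) {
      if (weight == "roi") mean(v[idx])
      else stats::weighted.mean(v[idx], profiles$n_annotations[idx])
    }
    for (t in topics) {
      v <- profiles[[t]]
      mw <- mann_whitney_u(v[ia], v[ib])
      rows[[length(rows) + 1L]] <- data.frame(
        comparison = cmp_name, topic = t, n_a = sum(ia), n_b = sum(ib),
        mean_a = wmean(v, ia), mean_b = wmean(v, ib),
        U = mw$U, p = mw$p, method = mw$method)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (adjust == "BH" && !is.null(out))
    out$p_adj <- stats::ave(out$p, out$comparison,
                            FUN = function(p) stats::p.adjust(p, "BH"))
  out
}
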