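#' Phantom volume specification
#'
#' Describes a synthetic grayscale volume standing in for an LDCT scan:
#' Gaussian background noise plus one or more smooth spherical nodules,
#' optionally with radial spikes (a crude spiculation).
#'
#' @param shape volume dimensions (default 128 cubed).
#' @param background_noise_sd standard deviation of the zero-mean Gaussian
#'   background (intensity units).
#' @param nodules list of nodules, each
#'   `list(center = c(x, y, z), radius, intensity, spiculated = FALSE)`
#'   with the center in 0-based voxel coordinates.
#' @param seed integer RNG seed; generation is fully deterministic under it.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(128L, 128L, 128L),
                         background_noise_sd = 0.05,
                         nodules = list(list(center = c(64, 64, 64),
                                             radius = 6, intensity = 1,
                                             spiculated = FALSE)),
                         seed = 1L) {
  shape <- as.integer(rep_len(shape, 3L))
  stopifnot(all(shape >= 1L), background_noise_sd >= 0, is.list(nodules))
  for (nd in nodules) {
    stopifnot(length(nd$center) == 3L, nd$radius >= 1, is.numeric(nd$intensity))
    if (any(nd$center - nd$radius < 0) || any(nd$center + nd$radius > shape - 1))
      stop("nodule extends out of the volume bounds", call. = FALSE)
  }
  structure(list(shape = shape, background_noise_sd = background_noise_sd,
                 nodules = nodules, seed = as.integer(seed)),
            class = "phantom_spec")
}

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(code)
}

#' Generate a phantom volume with a ground-truth nodule mask
#'
#' @param spec a [phantom_spec()].
#' @return list with `volume` (3D array), `mask` (logical 3D array marking
#'   nodule voxels) and `spec`.
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  shape <- spec$shape
  with_seed(spec$seed, {
    volume <- array(if (spec$background_noise_sd > 0)
      stats::rnorm(prod(shape), 0, spec$background_noise_sd) else 0,
      dim = shape)
    mask <- array(FALSE, dim = shape)
    for (nd in spec$nodules) {
      r <- nd$radius
      lo <- pmax(floor(nd$center - 2 * r), 0)
      hi <- pmin(ceiling(nd$center + 2 * r), shape - 1)
      ix <- (lo[1L]:hi[1L]); iy <- (lo[2L]:hi[2L]); iz <- (lo[3L]:hi[3L])
      dx <- ix - nd$center[1L]; dy <- iy - nd$center[2L]; dz <- iz - nd$center[3L]
      dist <- sqrt(outer(outer(dx^2, dy^2, "+"), dz^2, "+"))
      # smooth profile: flat core with a soft shoulder at the radius
      prof <- nd$intensity / (1 + exp(3 * (dist - r)))
      volume[ix + 1L, iy + 1L, iz + 1L] <-
        volume[ix + 1L, iy + 1L, iz + 1L] + prof
      inside <- dist <= r
      if (isTRUE(nd$spiculated)) {
        ndir <- 6L
        dirs <- matrix(stats::rnorm(3L * ndir), ncol = 3L)
        dirs <- dirs / sqrt(rowSums(dirs^2))
        for (k in seq_len(ndir)) {
          for (s in seq(r, 2 * r, by = 0.5)) {
            p <- round(nd$center + s * dirs[k, ])
            if (all(p >= lo) && all(p <= hi)) {
              volume[p[1L] + 1L, p[2L] + 1L, p[3L] + 1L] <-
                volume[p[1L] + 1L, p[2L] + 1L, p[3L] + 1L] +
                nd$intensity * 0.5
              inside[p[1L] - lo[1L] + 1L, p[2L] - lo[2L] + 1L,
                     p[3L] - lo[3L] + 1L] <- TRUE
            }
          }
        }
      }
      mask[ix + 1L, iy + 1L, iz + 1L] <- mask[ix + 1L, iy + 1L, iz + 1L] | inside
    }
    list(volume = volume, mask = mask, spec = spec)
  })
}

#' Closed-form toy malignancy scorer
#'
#' Builds a scorer satisfying the "volume to malignancy score in \[0, 1\]"
#' contract from a ground-truth nodule mask:
#' `score = logistic(steepness * (mean intensity inside the mask - calibration))`.
#' Because the score depends on the volume only through the mask mean, the
#' saliency of any occlusion patch is analytically computable, and patches
#' disjoint from the mask have exactly zero saliency.
#'
#' @param mask logical 3D array marking the nodule voxels.
#' @param steepness logistic slope (default 8: an intact unit-intensity
#'   nodule scores about 0.98 against a zero background).
#' @param calibration intensity offset at which the score crosses 0.5
#'   (default 0.5, half the conventional unit nodule intensity).
#' @return a scorer `function(volume) -> numeric(1)` of class `toy_scorer`,
#'   with the mask indices, steepness and calibration attached as attributes.
#' @export
toy_scorer <- function(mask, steepness = 8, calibration = 0.5) {
  stopifnot(is.array(mask), length(dim(mask)) == 3L, is.logical(mask))
  idx <- which(mask)
  if (length(idx) == 0L) {
    warning("empty nodule mask: returning a constant 0.5 scorer",
            call. = FALSE)
    f <- function(volume) 0.5
  } else {
    n <- length(idx)
    f <- function(volume) {
      stats::plogis(steepness * (sum(volume[idx]) / n - calibration))
    }
  }
  structure(f, class = c("toy_scorer", "function"),
            mask_idx = idx, steepness = steepness, calibration = calibration,
            mask_shape = dim(mask))
}

#' Reader-study specification
#'
#' Defines the simulated multi-reader annotation study: the case mix (10
#' benign cases of which 3 misclassified by the AI as malignant, 10 malignant
#' of which 2 misclassified as benign), 36 readers, and the reader behaviour
#' model. With the defaults, cases carry 1-3 regions of interest (ROIs) at
#' fixed anchor positions at least 220 px apart on a 512x512 display image —
#' 17 ROIs on the benign and 24 on the malignant cases, of which 14 and 20
#' are nodules. Each reader annotates each true ROI independently with
#' probability `p_annotate` (0.7 gives roughly 1000 annotations), placing the
#' rectangle anchor with isotropic Gaussian jitter around the ROI anchor and
#' writing a text assembled from the ROI's main-label keyword plus per-topic
#' Bernoulli mentions with group-dependent probabilities, with stop words and
#' distance-1 typos injected at the stated rates.
#'
#' @param n_benign,n_benign_misclassified,n_malignant,n_malignant_misclassified
#'   case mix (misclassified counts must not exceed the group counts).
#' @param n_readers number of readers.
#' @param p_annotate probability that a reader annotates a given true ROI.
#' @param anchor_jitter_sd standard deviation (px) of the anchor jitter.
#' @param typo_rate per-token probability of a random single-character edit.
#' @param stopword_rate per-gap probability of inserting a stop word.
#' @param label_confusion_rate probability that a reader describes an ROI
#'   with a different high-level label than the true one (e.g. calls a
#'   vessel a nodule). The default 0 makes readers perfectly consistent, so
#'   agreement statistics on synthetic data exercise the arithmetic;
#'   raise it to emulate the label disagreement seen in real reader panels.
#' @param image_size display image size in pixels.
#' @param rois_benign,rois_malignant per-case ROI counts (1-4 each; defaults
#'   sum to 17 and 24).
#' @param nonnodule_per_group number of non-nodule ROIs (vessel or
#'   diaphragm/rib) per truth group, assigned to the last secondary ROIs.
#' @param topic_probs 4 x 14 matrix of per-annotation topic mention
#'   probabilities, rows `cB, mB, cM, mM`, columns the lexicon topics; applies
#'   to nodule ROIs (non-nodule ROIs mention no topics). The default table is
#'   directional: lower-likelihood descriptors are commoner on benign-truth
#'   ROIs, higher-likelihood descriptors on malignant-truth ROIs, and
#'   misclassified benign ROIs lean towards malignant vocabulary.
#' @param lexicon a `topic_lexicon`.
#' @param seed integer RNG seed.
#' @return object of class `study_spec`.
#' @export
study_spec <- function(n_benign = 10L, n_benign_misclassified = 3L,
                       n_malignant = 10L, n_malignant_misclassified = 2L,
                       n_readers = 36L, p_annotate = 0.7,
                       anchor_jitter_sd = 5, typo_rate = 0.05,
                       stopword_rate = 0.3, label_confusion_rate = 0,
                       image_size = c(512L, 512L),
                       rois_benign = c(2L, 2L, 2L, 2L, 2L, 2L, 2L, 1L, 1L, 1L),
                       rois_malignant = c(3L, 3L, 3L, 3L, 2L, 2L, 2L, 2L, 2L, 2L),
                       nonnodule_per_group = c(benign = 3L, malignant = 4L),
                       topic_probs = default_topic_probs(),
                       lexicon = default_lexicon(), seed = 1L) {
  stopifnot(n_benign_misclassified <= n_benign,
            n_malignant_misclassified <= n_malignant,
            n_readers >= 1L,
            p_annotate >= 0, p_annotate <= 1,
            anchor_jitter_sd >= 0, typo_rate >= 0, typo_rate <= 1,
            stopword_rate >= 0, stopword_rate <= 1,
            label_confusion_rate >= 0, label_confusion_rate <= 1,
            length(rois_benign) == n_benign,
            length(rois_malignant) == n_malignant,
            all(c(rois_benign, rois_malignant) >= 1L),
            all(c(rois_benign, rois_malignant) <= 4L),
            is.matrix(topic_probs), nrow(topic_probs) == 4L,
            all(topic_probs >= 0), all(topic_probs <= 1),
            inherits(lexicon, "topic_lexicon"))
  if (!identical(colnames(topic_probs), lexicon$topics))
    stop("topic_probs columns must match the lexicon topics", call. = FALSE)
  structure(list(n_benign = as.integer(n_benign),
                 n_benign_misclassified = as.integer(n_benign_misclassified),
                 n_malignant = as.integer(n_malignant),
                 n_malignant_misclassified = as.integer(n_malignant_misclassified),
                 n_readers = as.integer(n_readers), p_annotate = p_annotate,
                 anchor_jitter_sd = anchor_jitter_sd, typo_rate = typo_rate,
                 stopword_rate = stopword_rate,
                 label_confusion_rate = label_confusion_rate,
                 image_size = as.integer(image_size),
                 rois_benign = as.integer(rois_benign),
                 rois_malignant = as.integer(rois_malignant),
                 nonnodule_per_group = nonnodule_per_group,
                 topic_probs = topic_probs, lexicon = lexicon,
                 seed = as.integer(seed)),
            class = "study_spec")
}

#' @rdname study_spec
#' @export
default_topic_probs <- function(lexicon = default_lexicon()) {
  m <- rbind(
    #      solid single small benign circ  calc  adeno malig irreg spic  cons  indet lobul nonsp
    cB = c(0.30, 0.10, 0.25, 0.08, 0.06, 0.08, 0.00, 0.01, 0.01, 0.01, 0.01, 0.02, 0.01, 0.02),
    mB = c(0.25, 0.05, 0.15, 0.04, 0.03, 0.05, 0.05, 0.05, 0.05, 0.08, 0.03, 0.10, 0.08, 0.06),
    cM = c(0.12, 0.01, 0.10, 0.02, 0.02, 0.02, 0.03, 0.15, 0.12, 0.12, 0.03, 0.02, 0.03, 0.03),
    mM = c(0.14, 0.01, 0.10, 0.02, 0.02, 0.02, 0.02, 0.12, 0.10, 0.10, 0.03, 0.02, 0.02, 0.03))
  colnames(m) <- lexicon$topics
  m
}

# fixed candidate anchor positions; pairwise distances >= 220 px
roi_positions <- function() {
  list(c(80, 80), c(300, 80), c(80, 300), c(300, 300))
}

random_typo <- function(word) {
  n <- nchar(word)
  op <- sample(c("sub", "ins", "del"), 1L)
  pos <- sample.int(n, 1L)
  ch <- sample(letters, 1L)
  switch(op,
         sub = paste0(substr(word, 1L, pos - 1L), ch,
                      substr(word, pos + 1L, n)),
         ins = paste0(substr(word, 1L, pos), ch, substr(word, pos + 1L, n)),
         del = if (n > 1L) paste0(substr(word, 1L, pos - 1L),
                                  substr(word, pos + 1L, n)) else word)
}

#' Generate a synthetic multi-reader annotation study
#'
#' Simulates the full reader study described by a [study_spec()] and returns
#' both the observable tables (annotations, case metadata) and the ground
#' truth needed for recovery tests (true ROI per annotation, true topic
#' mentions, true main labels). Deterministic under the spec seed.
#'
#' @param spec a [study_spec()].
#' @return list of class `synthetic_study`: `annotations` (annotation-table
#'   dialect plus `annotation_id`), `cases` (`case_id`, `truth`, `ai_label`,
#'   `group`), `roi_truth` (`case_id`, `roi_id`, `anchor_x`, `anchor_y`,
#'   `slice_index`, `main_label`, `group`), `annotation_truth`
#'   (`annotation_id`, `case_id`, `roi_id`, `main_label`, one 0/1 column per
#'   topic) and `spec`.
#' @export
generate_study <- function(spec = study_spec()) {
  stopifnot(inherits(spec, "study_spec"))
  lex <- spec$lexicon
  topics <- lex$topics
  stop_pool <- c("the", "a", "is", "of", "in", "with", "and", "there")

  cases <- data.frame(
    case_id = c(sprintf("b%02d", seq_len(spec$n_benign)),
                sprintf("m%02d", seq_len(spec$n_malignant))),
    truth = rep(c("benign", "malignant"),
                c(spec$n_benign, spec$n_malignant)),
    stringsAsFactors = FALSE)
  # the last k cases of each truth group are the AI misclassifications
  mis <- c(seq_len(spec$n_benign) > spec$n_benign - spec$n_benign_misclassified,
           seq_len(spec$n_malignant) >
             spec$n_malignant - spec$n_malignant_misclassified)
  cases$ai_label <- ifelse(xor(cases$truth == "malignant", mis),
                           "malignant", "benign")
  cases$group <- derive_group(cases$truth, cases$ai_label)

  roi_counts <- c(spec$rois_benign, spec$rois_malignant)
  positions <- roi_positions()

  with_seed(spec$seed, {
    # --- ground-truth ROI table ----------------------------------------
    roi_rows <- list()
    for (ci in seq_len(nrow(cases))) {
      k <- roi_counts[ci]
      for (j in seq_len(k)) {
        pos <- positions[[j]]
        roi_rows[[length(roi_rows) + 1L]] <- data.frame(
          case_id = cases$case_id[ci], roi_id = j,
          anchor_x = pos[1L], anchor_y = pos[2L],
          slice_index = sample(30:90, 1L),
          main_label = "nodule", group = cases$group[ci],
          stringsAsFactors = FALSE)
      }
    }
    roi_truth <- do.call(rbind, roi_rows)
    # non-nodule labels go to the last secondary ROIs of each truth group
    for (tr in c("benign", "malignant")) {
      nn <- spec$nonnodule_per_group[[if (tr == "benign") "benign"
                                      else "malignant"]]
      idx <- which(substr(roi_truth$case_id, 1L, 1L) ==
                     substr(tr, 1L, 1L) & roi_truth$roi_id > 1L)
      take <- utils::tail(idx, nn)
      labels <- rep_len(c("vessel", "vessel", "diaphragm_rib"), length(take))
      roi_truth$main_label[take] <- labels
    }

    # --- annotations ----------------------------------------------------
    n_max <- nrow(roi_truth) * spec$n_readers
    col_case <- col_reader <- col_variant <- col_text <- character(n_max)
    col_x <- col_y <- col_w <- col_h <- numeric(n_max)
    col_slice <- col_roi <- integer(n_max)
    col_label <- character(n_max)
    mention_mat <- matrix(0L, nrow = n_max, ncol = length(topics),
                          dimnames = list(NULL, topics))
    counter <- 0L
    for (ri in seq_len(nrow(roi_truth))) {
      roi <- roi_truth[ri, ]
      probs <- if (roi$main_label == "nodule")
        spec$topic_probs[roi$group, ] else rep(0, length(topics))
      for (rd in seq_len(spec$n_readers)) {
        if (stats::runif(1L) > spec$p_annotate) next
        counter <- counter + 1L
        mention <- stats::rbinom(length(topics), 1L, probs)
        # the label this reader expresses (possibly confused)
        expressed <- roi$main_label
        if (spec$label_confusion_rate > 0 &&
            stats::runif(1L) < spec$label_confusion_rate)
          expressed <- sample(setdiff(lex$main_label_order, roi$main_label), 1L)
        kw_pool <- lex$main_labels[[expressed]]
        kw_pool <- kw_pool[!grepl(" ", kw_pool, fixed = TRUE)]
        words <- sample(kw_pool, 1L)
        for (t in which(mention == 1L))
          words <- c(words, sample(lex$synonyms[[topics[t]]], 1L))
        if (length(words) > 1L)
          words <- words[sample.int(length(words))]
        # inject stop words between tokens
        keep <- stats::runif(length(words)) < spec$stopword_rate
        if (any(keep)) {
          ins <- sample(stop_pool, sum(keep), replace = TRUE)
          words[keep] <- paste(words[keep], ins)
        }
        out <- unlist(strsplit(words, " ", fixed = TRUE), use.names = FALSE)
        # typos: single-character edits on alphabetic tokens
        if (spec$typo_rate > 0) {
          hit <- which(nchar(out) >= 4L & grepl("^[a-z]+$", out) &
                         stats::runif(length(out)) < spec$typo_rate)
          for (k in hit) out[k] <- random_typo(out[k])
        }
        jit <- stats::rnorm(2L, 0, spec$anchor_jitter_sd)
        col_case[counter] <- roi$case_id
        col_reader[counter] <- sprintf("r%02d", rd)
        col_variant[counter] <- sample(c("original", "saliency"), 1L)
        col_x[counter] <- round(max(0, roi$anchor_x + jit[1L]), 1L)
        col_y[counter] <- round(max(0, roi$anchor_y + jit[2L]), 1L)
        col_w[counter] <- round(stats::runif(1L, 30, 80))
        col_h[counter] <- round(stats::runif(1L, 30, 80))
        col_slice[counter] <- roi$slice_index
        col_text[counter] <- paste(out, collapse = " ")
        col_roi[counter] <- roi$roi_id
        col_label[counter] <- expressed     # per-annotation expressed label
        mention_mat[counter, ] <- mention
      }
    }
    keep <- seq_len(counter)
    ids <- sprintf("a%04d", keep)
    annotations <- data.frame(
      annotation_id = ids, case_id = col_case[keep],
      reader_id = col_reader[keep], image_variant = col_variant[keep],
      x_ul = col_x[keep], y_ul = col_y[keep],
      width = col_w[keep], height = col_h[keep],
      slice_index = col_slice[keep], text = col_text[keep],
      stringsAsFactors = FALSE)
    annotation_truth <- data.frame(
      annotation_id = ids, case_id = col_case[keep],
      roi_id = col_roi[keep], main_label = col_label[keep],
      mention_mat[keep, , drop = FALSE],
      check.names = FALSE, stringsAsFactors = FALSE)
    structure(list(annotations = annotations, cases = cases,
                   roi_truth = roi_truth,
                   annotation_truth = annotation_truth, spec = spec),
              class = "synthetic_study")
  })
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf(paste0("synthetic reader study: %d annotations, %d cases ",
                     "(%s), %d true ROIs, %d readers, seed %d\n"),
              nrow(x$annotations), nrow(x$cases),
              paste(sprintf("%s=%d", names(table(x$cases$group)),
                            table(x$cases$group)), collapse = " "),
              nrow(x$roi_truth), x$spec$n_readers, x$spec$seed))
  invisible(x)
}

#' Write a synthetic study to disk
#'
#' Writes `annotations.csv` and `cases.csv` (the observable inputs of the
#' analysis pipeline) plus `ground_truth.json` (ROI and per-annotation truth,
#' for recovery checks).
#'
#' @param study a `synthetic_study`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(study$annotations, file.path(dir, "annotations.csv"),
                   row.names = FALSE)
  utils::write.csv(study$cases, file.path(dir, "cases.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(roi_truth = study$roi_truth,
                            annotation_truth = study$annotation_truth,
                            seed = study$spec$seed),
                       file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
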