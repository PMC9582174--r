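test_that("phantom generation is deterministic and honors its spec", {
  # no nodules, no noise: constant volume, empty mask
  spec0 <- phantom_spec(shape = 16, background_noise_sd = 0, nodules = list(),
                        seed = 2)
  ph0 <- generate_phantom(spec0)
  expect_identical(unique(as.vector(ph0$volume)), 0)
  expect_false(any(ph0$mask))

  spec <- phantom_spec(shape = 48, nodules = list(
    list(center = c(24, 24, 24), radius = 4, intensity = 1)), seed = 5)
  ph <- generate_phantom(spec)
  expect_identical(ph$volume, generate_phantom(spec)$volume)   # determinism

  # mask voxel count within 20% of the analytic sphere volume
  analytic <- 4 / 3 * pi * 4^3
  expect_lt(abs(sum(ph$mask) - analytic) / analytic, 0.2)
  # nodule voxels are brighter than background on average
  expect_gt(mean(ph$volume[ph$mask]), mean(ph$volume[!ph$mask]) + 0.5)

  expect_error(phantom_spec(shape = 16, nodules = list(
    list(center = c(15, 8, 8), radius = 4, intensity = 1))), "bounds")
})

test_that("toy scorer is monotone in nodule intensity and mask-local", {
  fx <- small_fixture()
  intact <- fx$scorer(fx$volume)
  zeroed <- fx$volume
  zeroed[fx$mask] <- 0
  expect_lt(fx$scorer(zeroed), intact)

  # occluding a patch disjoint from the mask yields exactly zero saliency
  occluded <- occlude(fx$volume, c(12, 12, 12), occlusion_config(patch = 4))
  expect_identical(intact - fx$scorer(occluded), 0)

  expect_warning(s0 <- toy_scorer(array(FALSE, dim = c(4, 4, 4))), "empty")
  expect_identical(s0(array(9, dim = c(4, 4, 4))), 0.5)
})

test_that("the default study reproduces the case mix and scale", {
  study <- generate_study(study_spec(seed = 3))
  expect_identical(study$annotations, generate_study(study_spec(seed = 3))$annotations)
  expect_false(identical(study$annotations,
                         generate_study(study_spec(seed = 4))$annotations))

  cases <- study$cases
  expect_identical(sum(cases$truth == "benign" & cases$ai_label == "malignant"), 3L)
  expect_identical(sum(cases$truth == "malignant" & cases$ai_label == "benign"), 2L)
  expect_identical(as.integer(table(cases$group)[c("cB", "mB", "cM", "mM")]),
                   c(7L, 3L, 8L, 2L))

  # 17 + 24 true ROIs, of which 14 + 20 nodules
  rt <- study$roi_truth
  benign <- substr(rt$case_id, 1, 1) == "b"
  expect_identical(sum(benign), 17L)
  expect_identical(sum(!benign), 24L)
  expect_identical(sum(benign & rt$main_label == "nodule"), 14L)
  expect_identical(sum(!benign & rt$main_label == "nodule"), 20L)

  # about a thousand annotations from 36 readers
  expect_gt(nrow(study$annotations), 900)
  expect_lt(nrow(study$annotations), 1150)
  expect_identical(length(unique(study$annotations$reader_id)), 36L)
  expect_true(all(table(study$annotations$case_id) > 0))

  # annotation tables pass ingest validation round-tripped through CSV
  dir <- file.path(tempdir(), "study_csv")
  write_study(study, dir)
  back <- read_annotations(file.path(dir, "annotations.csv"))
  expect_identical(nrow(back), nrow(study$annotations))
  meta <- read_case_meta(file.path(dir, "cases.csv"))
  expect_identical(meta$group, cases$group)
})

test_that("recovered topic percentages track the generating probability", {
  lex <- default_lexicon()
  probs <- default_topic_probs()
  probs[, ] <- 0
  probs[, "solid"] <- 0.4
  pct <- numeric(20)
  for (s in seq_len(20)) {
    study <- generate_study(study_spec(seed = 100 + s, topic_probs = probs,
                                       typo_rate = 0))
    truth <- study$annotation_truth
    nod <- truth[truth$main_label == "nodule", ]
    per_roi <- tapply(nod$solid, paste(nod$case_id, nod$roi_id),
                      function(x) 100 * mean(x))
    pct[s] <- mean(per_roi)
  }
  expect_lt(abs(mean(pct) - 40), 3)
})

test_that("label confusion lowers unanimity but stays recoverable", {
  study <- generate_study(study_spec(seed = 55, typo_rate = 0,
                                     label_confusion_rate = 0.3))
  # the expressed (confused) labels are still extracted exactly
  vec <- annotation_topic_vectors(study$annotations)
  expect_identical(vec$main_label, study$annotation_truth$main_label)
  # and they disagree with the ROI truth for roughly the confusion rate
  truth_label <- study$roi_truth$main_label[
    match(paste(study$annotation_truth$case_id, study$annotation_truth$roi_id),
          paste(study$roi_truth$case_id, study$roi_truth$roi_id))]
  conf <- mean(vec$main_label != truth_label)
  expect_gt(conf, 0.2); expect_lt(conf, 0.4)
  res <- run_full_study(study$annotations, study$cases, seed = 55)
  expect_lt(res$agreement$overall_unanimous_rate, 0.5)
})

test_that("recovery degrades monotonically along the noise ladder", {
  lex <- default_lexicon()
  recovery <- function(typo_rate, seed = 900, ...) {
    study <- generate_study(study_spec(seed = seed, typo_rate = typo_rate))
    vec <- annotation_topic_vectors(study$annotations, ...)
    truth <- study$annotation_truth
    same <- vapply(seq_len(nrow(vec)), function(i)
      all(vec[i, lex$topics] == truth[i, lex$topics]) &&
        vec$main_label[i] == truth$main_label[i], TRUE)
    mean(same)
  }
  # text ladder: recovery never improves as the typo rate rises
  r0 <- recovery(0); r1 <- recovery(0.1); r2 <- recovery(0.4)
  expect_identical(r0, 1)          # noiseless: exact recovery
  expect_gte(r0, r1)
  expect_gte(r1, r2)
  # the corrector is doing real work: switching it off at a heavy typo
  # rate must lose strictly more vectors than leaving it on
  r2_off <- recovery(0.4, max_edit_distance = 0)
  expect_lt(r2_off, 0.9)
  expect_gt(r2, r2_off)

  # spatial ladder: cluster-count error grows with anchor jitter
  count_error <- function(jitter, seed = 901) {
    study <- generate_study(study_spec(seed = seed,
                                       anchor_jitter_sd = jitter))
    truth_counts <- table(study$roi_truth$case_id)
    err <- 0L
    for (cid in names(truth_counts)) {
      d <- study$annotations[study$annotations$case_id == cid, ]
      res <- cluster_annotations(data.frame(annotation_id = d$annotation_id,
                                            reader_id = d$reader_id,
                                            x = d$x_ul, y = d$y_ul),
                                 threshold = 50)
      err <- err + abs(nrow(res$clusters) - truth_counts[[cid]])
    }
    err
  }
  e0 <- count_error(0); e1 <- count_error(5); e2 <- count_error(40)
  expect_identical(e0, 0L)
  expect_identical(e1, 0L)         # the study's own jitter is recoverable
  expect_gt(e2, 0L)                # extreme jitter fragments the ROIs
})
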