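test_that("case groups derive exactly from truth and AI label", {
  expect_identical(derive_group(c("benign", "benign", "malignant", "malignant"),
                                c("benign", "malignant", "malignant", "benign")),
                   c("cB", "mB", "cM", "mM"))
  expect_error(derive_group("benign", "unknown"))
})

test_that("Mann-Whitney matches hand-computed and enumerated references", {
  # U = 0, two-sided p = 2/6 by enumerating all C(4,2) labelings
  mw <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_identical(mw$U, 0)
  expect_equal(mw$p, 2 / 6, tolerance = 1e-12)
  expect_identical(mw$method, "exact")

  # identical multisets are exchangeable: p = 1
  mw <- mann_whitney_u(c(5, 1, 9), c(9, 5, 1))
  expect_equal(mw$p, 1)

  # all values identical across both samples
  mw <- mann_whitney_u(rep(2, 4), rep(2, 6))
  expect_identical(mw$U, 12)
  expect_identical(mw$p, 1)
})

test_that("exact-regime p-values equal exhaustive enumeration", {
  set.seed(41)
  for (n_a in 1:6) for (n_b in n_a:min(6, 12 - n_a)) {
    for (rep in 1:2) {
      pooled <- sample(seq_len(50), n_a + n_b)   # tie-free
      a <- pooled[seq_len(n_a)]; b <- pooled[-seq_len(n_a)]
      mw <- mann_whitney_u(a, b)
      expect_identical(mw$method, "exact")
      expect_equal(mw$p, mw_enum_oracle(a, b), tolerance = 1e-12)
    }
  }
})

test_that("U statistic duality and tie handling hold", {
  set.seed(43)
  for (rep in 1:20) {
    a <- sample(0:10, sample(2:12, 1), replace = TRUE)
    b <- sample(0:10, sample(2:12, 1), replace = TRUE)
    ua <- mann_whitney_u(a, b); ub <- mann_whitney_u(b, a)
    expect_equal(ua$U + ub$U, length(a) * length(b))
    expect_equal(ua$p, ub$p, tolerance = 1e-12)
    expect_gt(ua$p, 0); expect_lte(ua$p, 1)
    expect_gte(ua$U, 0); expect_lte(ua$U, length(a) * length(b))
  }
})

make_toy_clusters <- function() {
  # two clusters: one with 4 nodule annotations, one vessel-only
  assignments <- data.frame(
    annotation_id = sprintf("a%02d", 1:7),
    cluster_id = c(rep("c1", 4), rep("c2", 3)),
    case_id = "k1")
  lex <- default_lexicon()
  pres <- matrix(0L, 7, 14, dimnames = list(NULL, lex$topics))
  pres[1, "solid"] <- 1L
  vectors <- data.frame(annotation_id = sprintf("a%02d", 1:7), pres,
                        check.names = FALSE)
  vectors$main_label <- c(rep("nodule", 4), rep("vessel", 3))
  list(assignments = assignments, vectors = vectors, lexicon = lex)
}

test_that("topic percentages are per-ROI annotation fractions", {
  toy <- make_toy_clusters()
  prof <- topic_percent_table(toy$assignments, toy$vectors, toy$lexicon)
  expect_identical(nrow(prof), 1L)             # vessel-only ROI excluded
  expect_identical(prof$cluster_id, "c1")
  expect_equal(prof$solid, 25)
  expect_equal(sum(unlist(prof[toy$lexicon$topics])), 25)  # all-zero elsewhere
  prof_all <- topic_percent_table(toy$assignments, toy$vectors, toy$lexicon,
                                  nodule_only = FALSE)
  expect_identical(nrow(prof_all), 2L)
  expect_equal(unlist(prof_all[2, toy$lexicon$topics], use.names = FALSE),
               rep(0, 14))
})

test_that("main-label agreement counts unanimity over labeled members", {
  toy <- make_toy_clusters()
  agr <- main_label_agreement(toy$assignments, toy$vectors)
  expect_identical(agr$n_rois, 2L)
  expect_identical(agr$n_unanimous, 2L)

  # mixed-label ROI: modal fraction from a hand count (3 nodule / 5 labeled)
  toy$vectors$main_label <- c("nodule", "nodule", "nodule", "vessel",
                              "vessel", "unlabeled", "vessel")
  toy$assignments$cluster_id <- c(rep("c1", 5), "c1", "c2")
  agr <- main_label_agreement(toy$assignments, toy$vectors)
  row <- agr$per_roi[agr$per_roi$cluster_id == "c1", ]
  expect_identical(row$n_labeled, 5L)
  expect_equal(row$modal_fraction, 3 / 5)
  expect_false(row$unanimous)

  # published arithmetic: 5 unanimous areas of 41 is a 12% unanimity rate
  assignments <- data.frame(
    annotation_id = sprintf("a%03d", 1:82),
    cluster_id = rep(sprintf("c%02d", 1:41), each = 2))
  labels <- rep("nodule", 82)
  labels[seq(11, 82, by = 2)] <- "vessel"      # clusters 6..41 split labels
  vectors <- data.frame(annotation_id = sprintf("a%03d", 1:82),
                        main_label = labels)
  agr <- main_label_agreement(assignments, vectors)
  expect_identical(agr$n_rois, 41L)
  expect_identical(agr$n_unanimous, 5L)
  expect_identical(agr$overall_unanimous_pct, 12)
})

test_that("group comparisons assemble per-ROI samples and flag empty groups", {
  lex <- default_lexicon()
  set.seed(47)
  profiles <- data.frame(cluster_id = sprintf("c%02d", 1:12),
                         n_annotations = rep(10L, 12),
                         case_id = sprintf("k%02d", 1:12))
  for (t in lex$topics) profiles[[t]] <- 0
  profiles$spiculated <- c(round(runif(6, 40, 60)), round(runif(6, 0, 5)))
  meta <- data.frame(case_id = sprintf("k%02d", 1:12),
                     truth = rep(c("malignant", "benign"), each = 6),
                     ai_label = rep(c("malignant", "benign"), each = 6))
  meta$group <- derive_group(meta$truth, meta$ai_label)

  # mM and mB are empty: those comparisons are skipped with warnings
  w <- capture_warnings(cmp <- compare_groups(profiles, meta, lexicon = lex))
  expect_length(w, 4)
  expect_true(all(grepl("skipped", w)))
  expect_identical(sort(unique(cmp$comparison)), "B_vs_M")
  spic <- cmp[cmp$topic == "spiculated", ]
  expect_lt(spic$p, 0.05)
  expect_equal(spic$mean_b, mean(profiles$spiculated[1:6]))  # benign = group a

  # both groups all-zero for a topic gives p = 1
  solid <- cmp[cmp$topic == "solid", ]
  expect_identical(solid$p, 1)
  expect_identical(solid$U, 18)   # n_a * n_b / 2

  # Benjamini-Hochberg column on request
  suppressWarnings(
    cmp_adj <- compare_groups(profiles, meta, lexicon = lex, adjust = "BH"))
  expect_true("p_adj" %in% names(cmp_adj))
  expect_true(all(cmp_adj$p_adj >= cmp_adj$p - 1e-12))
})
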