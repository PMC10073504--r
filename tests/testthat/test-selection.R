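test_that("paired samples pair each subject's flanking segment means", {
  set.seed(1)
  fm <- synthetic_feature_matrix(85, c(relax = 0, neutral = 0, negative = 5,
                                       positive = 0),
                                 between_sd = 1, within_sd = 0.5)
  ps <- paired_samples(fm, "X", c("neutral", "negative"))
  expect_equal(nrow(ps), 85)
  expect_lt(abs(mean(ps$after - ps$before) - 5), 0.5)
  # relax flanks count as neutral: negative -> neutral uses the relax block
  ps2 <- paired_samples(fm, "X", c("negative", "neutral"))
  expect_lt(abs(mean(ps2$after - ps2$before) + 5), 0.5)
  # identical before/after
  fm0 <- fm
  fm0$X <- fm0$subject  # constant within subject
  ps0 <- paired_samples(fm0, "X", c("neutral", "negative"))
  expect_true(all(ps0$after - ps0$before == 0))
  # a subject missing the transition is dropped with a warning
  fm3 <- fm[!(fm$subject == 1 & fm$segment >= 4), ]
  expect_warning(ps3 <- paired_samples(fm3, "X", c("neutral", "positive")),
                 "dropped")
  expect_equal(nrow(ps3), 84)
})

test_that("transition selection keeps planted effects and rejects nulls", {
  set.seed(2)
  fm <- synthetic_feature_matrix(85, c(relax = 0, neutral = 0, negative = 1,
                                       positive = 1),
                                 between_sd = 1, within_sd = 1)
  res <- transition_select(fm, features = "X")
  expect_true("X" %in% res$final_subset)
  expect_s3_class(res, "selection_result")
  # degenerate: constant within subject in every segment -> p = 1
  fm0 <- fm; fm0$X <- fm0$subject * 1.0
  res0 <- transition_select(fm0, features = "X")
  expect_false("X" %in% res0$final_subset)
  expect_true(all(res0$table[, grep("^p_", names(res0$table))] == 1))
  expect_error(transition_select(fm[fm$subject <= 4, ], features = "X"),
               "6 subjects")
})

test_that("discrete selection finds monotone state effects and rejects nulls", {
  set.seed(3)
  fm <- synthetic_feature_matrix(85, c(relax = 0, neutral = 0, negative = 1,
                                       positive = 2),
                                 between_sd = 1, within_sd = 1)
  res <- discrete_select(fm, features = "X")
  expect_true("X" %in% res$final_subset)
  fm0 <- fm; fm0$X <- fm0$subject * 1.0
  res0 <- discrete_select(fm0, features = "X")
  expect_false("X" %in% res0$final_subset)
})

test_that("the redundancy filter is greedy, order-dependent and idempotent", {
  set.seed(4)
  n <- 400
  a <- stats::rnorm(n)
  fm <- as_feature_matrix(data.frame(
    subject = rep(1:10, each = 40), segment = 1, label = "neutral",
    window = rep(1:40, 10), A = a, B = 2 * a + 1, C = stats::rnorm(n),
    K = rep(1, n)))
  r1 <- redundancy_filter(c("A", "B", "C"), fm)
  expect_equal(r1$kept, c("A", "C"))
  expect_equal(r1$discarded$feature, "B")
  expect_equal(r1$discarded$partner, "A")
  expect_equal(r1$discarded$r, 1.0, tolerance = 1e-12)
  # order reversal discards the other partner
  r2 <- redundancy_filter(c("B", "A", "C"), fm)
  expect_equal(r2$kept, c("B", "C"))
  expect_equal(r2$discarded$feature, "A")
  # independent noise features all kept
  expect_equal(redundancy_filter(c("A", "C"), fm)$kept, c("A", "C"))
  # constant feature kept but flagged
  r3 <- redundancy_filter(c("A", "K"), fm)
  expect_true("K" %in% r3$kept)
  expect_true("K" %in% r3$flagged_constant)
  # idempotence: filtering the kept set changes nothing
  r4 <- redundancy_filter(r1$kept, fm)
  expect_equal(r4$kept, r1$kept)
  expect_equal(nrow(r4$discarded), 0)
})

test_that("significance sets are monotone in alpha for both methods", {
  set.seed(5)
  for (rep in 1:3) {
    fm <- synthetic_feature_matrix(30, c(relax = 0, neutral = 0,
                                         negative = 0.3, positive = 0.15),
                                   between_sd = 1, within_sd = 1)
    for (f in c("Y", "Z"))
      fm[[f]] <- stats::rnorm(nrow(fm)) + 0.2 * (fm$label == "negative")
    for (selector in list(transition_select, discrete_select)) {
      s01 <- selector(fm, alpha = 0.01, features = c("X", "Y", "Z"))
      s05 <- selector(fm, alpha = 0.05, features = c("X", "Y", "Z"))
      sig01 <- s01$table$feature[s01$table$significant]
      sig05 <- s05$table$feature[s05$table$significant]
      expect_true(all(sig01 %in% sig05))
    }
  }
})

test_that("transition pairing outperforms unpaired state comparison on fading effects", {
  set.seed(6)
  reps <- 40
  m3 <- m1 <- logical(reps)
  for (i in seq_len(reps)) {
    fm <- fading_fm(40)
    m3[i] <- "X" %in% transition_select(fm, features = "X")$final_subset
    m1[i] <- "X" %in% discrete_select(fm, features = "X")$final_subset
  }
  expect_gt(mean(m3), mean(m1) + 0.3)
})

test_that("per-group PCA keeps the stated dimensions and variance ordering", {
  set.seed(7)
  reg <- feature_registry()
  n <- 300
  fm <- data.frame(subject = rep(1:10, each = 30), segment = 1,
                   label = "neutral", window = rep(1:30, 10))
  for (f in reg$all) fm[[f]] <- stats::rnorm(n)
  fm <- as_feature_matrix(fm)
  red <- pca_reduce(fm)
  pc_cols <- grep("_PC", names(red), value = TRUE)
  expect_length(pc_cols, 17)
  expect_length(grep("^ECG_PC", pc_cols), 6)
  expect_length(grep("^BVP_PC", pc_cols), 5)
  expect_length(grep("^GSR_PC", pc_cols), 6)
  evr <- attr(red, "explained_variance_ratio")
  for (g in names(evr)) {
    expect_true(all(diff(evr[[g]]) <= 1e-12))
    expect_lte(sum(evr[[g]]), 1 + 1e-9)
  }
  # full dimensions reconstruct exactly
  full <- pca_reduce(fm, c(ECG = 15, BVP = 12, GSR = 12))
  X <- scale(as.matrix(fm[, reg$ecg]))
  sc <- as.matrix(full[, grep("^ECG_PC", names(full))])
  rec <- sc %*% t(attr(full, "loadings")$ECG)
  expect_lt(max(abs(rec - X)), 1e-8)
  # a one-factor group concentrates variance in its first component
  fm2 <- fm
  base <- stats::rnorm(n)
  for (f in reg$ecg) fm2[[f]] <- base + 0.01 * stats::rnorm(n)
  evr1 <- attr(pca_reduce(fm2), "explained_variance_ratio")$ECG[1]
  expect_gt(evr1, 0.99)
  expect_error(pca_reduce(fm, c(ECG = 20, BVP = 5, GSR = 6)), "components")
})

test_that("annotation bookkeeping reproduces the printed selection counts", {
  tbl <- read_annotation_table(system.file("extdata", "table1.csv",
                                           package = "transfeat"))
  m1 <- selection_from_annotations(tbl, "M1")
  expect_equal(m1$preliminary_count, 33)
  expect_equal(m1$discarded_count, 11)
  expect_equal(m1$final_count, 22)
  m3 <- selection_from_annotations(tbl, "M3")
  expect_equal(m3$preliminary_count, 17)
  expect_equal(m3$discarded_count, 4)
  expect_equal(m3$final_count, 13)
  expect_equal(unname(m3$per_signal_final), c(5, 4, 4))
  expect_true(all(c("SDNN_ECG", "MEANT_GSR", "MAXPA_BVP") %in%
                    m3$final_features))
  # empty marker table
  none <- tbl; none$marker <- "-"
  z <- selection_from_annotations(none, "M3")
  expect_equal(c(z$preliminary_count, z$discarded_count, z$final_count),
               c(0, 0, 0))
  bad <- tbl; bad$marker[1] <- "??"
  expect_error(selection_from_annotations(read_annotation_table(
    {f <- tempfile(fileext = ".csv"); utils::write.csv(bad, f, row.names = FALSE); f}
  ), "M1"), "marker")
})
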