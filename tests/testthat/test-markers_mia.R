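test_that("rf_rank finds a planted perfect separator and is deterministic", {
  firsts <- vapply(1:5, function(s) {
    pt <- planted_table(seed = s)
    rf_rank(pt$table, pt$labels, n_top = 10, seed = s)$otu_id[1]
  }, character(1))
  expect_true(all(firsts == "PLANTED"))
  pt <- planted_table(seed = 9)
  r1 <- rf_rank(pt$table, pt$labels, seed = 7)
  r2 <- rf_rank(pt$table, pt$labels, seed = 7)
  expect_identical(r1, r2)
  expect_true(all(diff(r1$importance) <= 0))          # descending importance
  expect_equal(r1$direction[r1$otu_id == "PLANTED"], "ASD-enriched")
  expect_error(rf_rank(pt$table, rep("ASD", 30)), "2 classes")
})

test_that("label shuffling flattens the planted importance", {
  pt <- planted_table(seed = 3)
  set.seed(30)
  null_ranks <- vapply(1:8, function(i) {
    rk <- rf_rank(pt$table, sample(pt$labels), seed = i)
    which(rk$otu_id == "PLANTED")
  }, integer(1))
  # planted OTU no longer pinned to the top under the null
  expect_gt(median(null_ranks), 3)
})

test_that("cv_error_curve recovers small panels and respects determinism", {
  pt <- planted_table(n_noise = 30, n_per_group = 15, seed = 4)
  rk <- rf_rank(pt$table, pt$labels, n_top = 10, seed = 4)
  cv <- cv_error_curve(pt$table, pt$labels, rk, folds = 5, trials = 2,
                       n_trees = 100, seed = 8)
  expect_true(all(cv$error >= 0 & cv$error <= 1))
  expect_equal(cv$selected_error, min(cv$error))
  expect_equal(cv$selected_k, cv$k[which.min(cv$error)])
  cv2 <- cv_error_curve(pt$table, pt$labels, rk, folds = 5, trials = 2,
                        n_trees = 100, seed = 8)
  expect_identical(cv$error, cv2$error)                 # bit-identical rerun
  # with the separator ranked first, tiny panels already classify well
  expect_lt(cv$error[1], 0.25)

  # pure-noise labels: error hovers near the minority-class rate
  set.seed(31)
  noise_tab <- random_table(20, 30, lambda = 25)
  lab <- rep(c("ASD", "control"), 15)
  rk0 <- rf_rank(noise_tab, lab, n_top = 5, seed = 1)
  cv0 <- cv_error_curve(noise_tab, lab, rk0, folds = 5, trials = 2,
                        n_trees = 100, seed = 2)
  expect_true(all(abs(cv0$error - 0.5) < 0.3))
})

test_that("mia_score implements the two-sided mean formula", {
  x <- c(a1 = 10, a2 = 20, c1 = 30, other = 99)
  panel <- list(asd_otus = c("a1", "a2"), control_otus = "c1")
  expect_equal(mia_score(x, panel), 30 / 2 - 30 / 1)    # -15
  # empty-side convention: control-only panel -> minus the mean
  expect_equal(mia_score(x, list(asd_otus = character(0),
                                 control_otus = c("a1", "c1"))), -20)
  expect_error(mia_score(x, list(asd_otus = "zz", control_otus = "c1")),
               "zz")
  expect_error(mia_score(x, list(asd_otus = character(0),
                                 control_otus = character(0))), "at least one")
  # random tables vs one-line recomputation, both scales
  set.seed(51)
  tab <- random_table(8, 6)
  panel2 <- list(asd_otus = c("OTU01", "OTU03"),
                 control_otus = c("OTU02", "OTU05", "OTU08"))
  sc <- mia_scores(tab, panel2, scale = "counts")
  for (s in colnames(tab$counts)) {
    v <- tab$counts[, s]
    expect_equal(sc[[s]], mean(v[panel2$asd_otus]) - mean(v[panel2$control_otus]))
  }
  rel <- relative_abundance(tab)
  scr <- mia_scores(tab, panel2, scale = "relative")
  expect_equal(unname(scr),
               unname(colMeans(rel[panel2$asd_otus, ]) -
                        colMeans(rel[panel2$control_otus, ])))
})

test_that("roc AUC equals the Mann-Whitney identity and endpoints", {
  # perfect separation
  rc <- roc(c(1, 2, 3, 10, 11, 12), rep(c("control", "ASD"), each = 3))
  expect_equal(rc$auc, 1)
  set.seed(52)
  rc0 <- roc(rnorm(2000), sample(rep(c("ASD", "control"), 1000)))
  expect_equal(rc0$auc, 0.5, tolerance = 0.05)
  # U-statistic oracle with half-credit ties, random instances
  for (i in 1:50) {
    n1 <- sample(3:12, 1); n2 <- sample(3:12, 1)
    scores <- c(sample(0:5, n1, TRUE), sample(0:5, n2, TRUE))
    labels <- rep(c("ASD", "control"), c(n1, n2))
    pos <- scores[seq_len(n1)]; neg <- scores[-seq_len(n1)]
    u <- sum(outer(pos, neg, ">")) + 0.5 * sum(outer(pos, neg, "=="))
    expect_equal(roc(scores, labels)$auc, u / (n1 * n2), tolerance = 1e-12)
  }
  # thresholds descending, TPR/FPR non-decreasing along them
  rc2 <- roc(c(3, 1, 2, 2), c("ASD", "control", "ASD", "control"))
  expect_true(all(diff(rc2$thresholds) <= 0))
  expect_true(all(diff(rc2$tpr) >= 0))
  expect_true(all(diff(rc2$fpr) >= 0))
})

test_that("youden_cutoff maximises J and matches a confusion-matrix oracle", {
  scores <- c(1, 2, 3, 10, 11, 12)
  labels <- rep(c("control", "ASD"), each = 3)
  yc <- youden_cutoff(roc(scores, labels))
  expect_equal(yc$sensitivity, 1)
  expect_equal(yc$specificity, 1)
  expect_gte(yc$cutoff, 3); expect_lt(yc$cutoff, 10)
  # single positive + single negative
  yc2 <- youden_cutoff(roc(c(5, 1), c("ASD", "control")))
  expect_equal(yc2$sensitivity, 1); expect_equal(yc2$specificity, 1)
  # achieved sens/spec re-verified by direct counting at the cutoff
  set.seed(53)
  for (i in 1:20) {
    scores <- round(rnorm(30), 1)
    labels <- sample(rep(c("ASD", "control"), 15))
    yc <- youden_cutoff(roc(scores, labels))
    pred <- classify_mia(scores, yc$cutoff)
    expect_equal(yc$sensitivity, mean(pred[labels == "ASD"] == "ASD"))
    expect_equal(yc$specificity,
                 mean(pred[labels == "control"] == "control"))
  }
})

test_that("classify_mia uses the strict-inequality boundary", {
  expect_equal(classify_mia(0, 0), "control")      # score == cutoff
  expect_equal(classify_mia(1e-9, 0), "ASD")
})

test_that("enumerate_panels: grid count identity and powerset dominance", {
  set.seed(54)
  tab <- random_table(25, 20)
  labels <- rep(c("ASD", "control"), each = 10)
  ranking <- data.frame(
    otu_id = rownames(tab$counts)[1:20],
    importance = 20:1,
    direction = rep(c("ASD-enriched", "control-enriched"), c(7, 13)))
  ps <- enumerate_panels(ranking, tab, labels)
  expect_equal(nrow(ps$panels), (7 + 1) * (13 + 1) - 1)  # 111 candidates
  expect_true(all(ps$panels$auc <= ps$best$auc))
  # powerset >= grid at M = N = 2 (grid panels are a subset)
  rk4 <- data.frame(otu_id = rownames(tab$counts)[1:4],
                    importance = 4:1,
                    direction = rep(c("ASD-enriched", "control-enriched"),
                                    each = 2))
  best_grid <- enumerate_panels(rk4, tab, labels, mode = "grid")$best$auc
  best_pow <- enumerate_panels(rk4, tab, labels, mode = "powerset")$best$auc
  expect_gte(best_pow, best_grid)
  # powerset refused above 16 markers
  expect_error(enumerate_panels(ranking, tab, labels, mode = "powerset"),
               "> 16")
  # AUC invariant under monotone transform of abundances entering MIA
  ps_rel <- enumerate_panels(ranking, tab, labels, scale = "relative")
  expect_true(all(ps_rel$panels$auc >= 0 & ps_rel$panels$auc <= 1))
})

test_that("panel selection on planted data is honest out of sample", {
  st <- generate_study(synth_config(
    n_otus = 80, n_diff_per_habitat = 10, log2_fold_change = 2,
    corr_block_size = 0, depth_mean = 6000, depth_sd = 300,
    group_sizes = c(HS = 100, HP = 0, AS = 100, AP = 0), seed = 55))
  md <- st$metadata
  set.seed(56)
  train <- unlist(lapply(split(md$sample_id, md$group), function(ids)
    sample(ids, length(ids) * 0.6)))
  test <- setdiff(md$sample_id, train)
  tr_tab <- subset_table(st$table, samples = train)
  te_tab <- subset_table(st$table, samples = test)
  tr_lab <- md$group[match(train, md$sample_id)]
  te_lab <- md$group[match(test, md$sample_id)]
  rk <- rf_rank(tr_tab, tr_lab, n_top = 20, seed = 57)
  ps <- enumerate_panels(rk, tr_tab, tr_lab)
  ev <- evaluate_panel(te_tab, te_lab, ps$best$panel, ps$best$cutoff)
  expect_gte(ev$auc, ps$best$auc - 0.15)   # limited optimism
  expect_lte(ev$auc, ps$best$auc + 0.02)   # no better than train (noise slack)
})
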