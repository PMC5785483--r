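as_binary_labels <- function(labels, positive = "ASD") {
  labels <- as.character(labels)
  classes <- unique(labels)
  if (length(classes) != 2L)
    stopf("need exactly 2 classes, found %d (%s)", length(classes),
          paste(utils::head(classes, 4), collapse = ", "))
  if (!positive %in% classes) stopf("positive class '%s' absent", positive)
  as.integer(labels == positive)
}

feature_matrix <- function(table) {
  t(relative_abundance(table))  # samples x OTUs
}

#' Random-forest marker ranking
#'
#' Trains a random forest (500 trees, sqrt(p) features per split, trees
#' grown to purity) on per-sample OTU relative abundances and ranks OTUs
#' by impurity-decrease variable importance. Enrichment direction is
#' taken from a differential-screen result when supplied, otherwise from
#' the sign of the group mean difference; markers with exactly zero mean
#' difference get an NA direction (and are skipped by panel enumeration).
#'
#' @param table an [otu_table] restricted to the samples of interest.
#' @param labels group label per table column ("ASD"/"control").
#' @param n_top number of top-importance OTUs to retain (default 60).
#' @param n_trees forest size.
#' @param diff optional `diff_result` used for direction assignment.
#' @param seed integer seed.
#' @return data.frame of class `marker_ranking`: otu_id, importance,
#'   direction, in descending importance order.
#' @export
rf_rank <- function(table, labels, n_top = 60, n_trees = 500,
                    diff = NULL, seed = NULL) {
  y <- as_binary_labels(labels)
  if (min(table(y)) < 2L) stopf("need >= 2 samples per class")
  X <- feature_matrix(table)
  mtry <- max(1L, floor(sqrt(ncol(X))))
  imp <- rf_importance_cpp(X, y, as.integer(n_trees), mtry, 1L,
                           derive_seed(seed %||% 1L, "rf_rank"))
  names(imp) <- colnames(X)
  ord <- order(imp, decreasing = TRUE)
  keep <- utils::head(ord, n_top)
  mean_diff <- rowMeans(t(X)[, y == 1L, drop = FALSE]) -
    rowMeans(t(X)[, y == 0L, drop = FALSE])
  direction <- ifelse(mean_diff > 0, "ASD-enriched",
                      ifelse(mean_diff < 0, "control-enriched", NA_character_))
  if (!is.null(diff)) {
    hit <- match(colnames(X), diff$taxon_id)
    direction[!is.na(hit)] <- diff$direction[hit[!is.na(hit)]]
  }
  structure(data.frame(otu_id = colnames(X)[keep],
                       importance = unname(imp[keep]),
                       direction = direction[keep],
                       stringsAsFactors = FALSE),
            class = c("marker_ranking", "data.frame"))
}

stratified_folds <- function(y, folds) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold
}

#' Cross-validated classification-error curve over marker counts
#'
#' For each k, a random forest on the top-k ranked markers is evaluated
#' by stratified `folds`-fold cross-validation, repeated `trials` times;
#' the reported error is the mean misclassification rate over all
#' folds and trials. `selected_k` is the k with minimum mean error
#' (smallest k on ties) — the study-design device for choosing how many
#' taxa the classifier needs.
#'
#' @param table an [otu_table].
#' @param labels group label per sample.
#' @param ranking a `marker_ranking` from [rf_rank()].
#' @param folds,trials cross-validation design (defaults 10 x 10).
#' @param k_grid marker counts to evaluate (default 1..nrow(ranking)).
#' @param n_trees forest size per fit.
#' @param seed integer seed; fixed seed reproduces the curve exactly.
#' @return list of class `cv_curve`: `k`, `error`, `selected_k`,
#'   `selected_error`.
#' @export
cv_error_curve <- function(table, labels, ranking, folds = 10, trials = 10,
                           k_grid = NULL, n_trees = 500, seed = NULL) {
  y <- as_binary_labels(labels)
  X <- feature_matrix(table)[, ranking$otu_id, drop = FALSE]
  k_grid <- k_grid %||% seq_len(nrow(ranking))
  if (any(k_grid < 1L | k_grid > nrow(ranking))) stopf("k_grid out of range")
  errs <- with_seed(seed, {
    sub_seed <- derive_seed(seed %||% 1L, "cv")
    sapply(k_grid, function(k) {
      Xk <- X[, seq_len(k), drop = FALSE]
      mtry <- max(1L, floor(sqrt(k)))
      wrong <- 0L; total <- 0L
      for (tr in seq_len(trials)) {
        fold <- stratified_folds(y, folds)
        for (f in seq_len(folds)) {
          test <- which(fold == f)
          if (!length(test) || length(unique(y[-test])) < 2L) next
          pred <- rf_predict_cpp(Xk[-test, , drop = FALSE], y[-test],
                                 Xk[test, , drop = FALSE],
                                 as.integer(n_trees), mtry, 1L,
                                 sub_seed + 1000L * tr + f + k)
          wrong <- wrong + sum(pred != y[test])
          total <- total + length(test)
        }
      }
      wrong / total
    })
  })
  best <- which.min(errs)  # which.min takes the first (smallest k) on ties
  structure(list(k = k_grid, error = errs, selected_k = k_grid[best],
                 selected_error = errs[best]),
            class = "cv_curve")
}

#' Microbial index of ASD (MIA) for one sample
#'
#' MIA = mean abundance of the panel's ASD-enriched OTUs minus mean
#' abundance of its control-enriched OTUs. An empty side contributes 0.
#' The abundance scale (raw counts vs relative abundance) is the
#' caller's choice; the package default is counts.
#'
#' @param sample_abundances named abundance vector for one sample.
#' @param panel list with character vectors `asd_otus` and
#'   `control_otus`, at least one non-empty.
#' @return numeric MIA score.
#' @export
mia_score <- function(sample_abundances, panel) {
  m <- length(panel$asd_otus); n <- length(panel$control_otus)
  if (m + n < 1L) stopf("panel must contain at least one OTU")
  missing <- setdiff(c(panel$asd_otus, panel$control_otus),
                     names(sample_abundances))
  if (length(missing))
    stopf("OTU(s) absent from sample: %s", paste(missing, collapse = ", "))
  up <- if (m) sum(sample_abundances[panel$asd_otus]) / m else 0
  down <- if (n) sum(sample_abundances[panel$control_otus]) / n else 0
  up - down
}

#' MIA scores for every sample of a table
#'
#' @param table an [otu_table].
#' @param panel see [mia_score()].
#' @param scale "counts" (default; raw read counts) or "relative".
#' @return named numeric vector, one score per sample.
#' @export
mia_scores <- function(table, panel, scale = c("counts", "relative")) {
  scale <- match.arg(scale)
  mat <- if (scale == "counts") table$counts else relative_abundance(table)
  vapply(colnames(mat), function(s) mia_score(mat[, s], panel), numeric(1))
}

#' ROC curve and AUC
#'
#' Thresholds at the unique scores (plus sentinels at +/-Inf); a sample
#' is called positive when its score strictly exceeds the threshold.
#' AUC by the trapezoidal rule, so tied scores contribute half credit —
#' identical to the Mann-Whitney U / (n1*n2) statistic.
#'
#' @param scores numeric score per sample.
#' @param labels class label per sample.
#' @param positive label counted as positive (default "ASD").
#' @return list of class `roc_curve`: `thresholds` (descending), `tpr`,
#'   `fpr`, `auc`.
#' @export
roc <- function(scores, labels, positive = "ASD") {
  y <- as_binary_labels(labels, positive)
  if (length(scores) != length(y)) stopf("scores and labels differ in length")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  pos <- scores[y == 1L]; neg <- scores[y == 0L]
  tpr <- vapply(thr, function(t) mean(pos > t), numeric(1))
  fpr <- vapply(thr, function(t) mean(neg > t), numeric(1))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(thresholds = thr, tpr = tpr, fpr = fpr, auc = auc),
            class = "roc_curve")
}

#' Youden-optimal cut-off of a ROC curve
#'
#' Maximises sensitivity + specificity - 1 over the finite thresholds;
#' ties go to the threshold with higher sensitivity, then to the smaller
#' absolute cut-off. The achieved sensitivity/specificity at the
#' returned cut-off are reported (classification rule: score > cutoff
#' is positive).
#'
#' @param roc a `roc_curve` from [roc()].
#' @return list: `cutoff`, `sensitivity`, `specificity`, `youden`.
#' @export
youden_cutoff <- function(roc) {
  finite <- is.finite(roc$thresholds)
  thr <- roc$thresholds[finite]
  sens <- roc$tpr[finite]
  spec <- 1 - roc$fpr[finite]
  j <- sens + spec - 1
  best <- which(j == max(j))
  if (length(best) > 1L) best <- best[order(-sens[best], abs(thr[best]))][1L]
  list(cutoff = thr[best], sensitivity = sens[best],
       specificity = spec[best], youden = j[best])
}

#' Classify samples by MIA score
#'
#' MIA strictly greater than the cut-off is called ASD; a score exactly
#' at the cut-off is called control.
#'
#' @param scores numeric MIA score(s).
#' @param cutoff decision threshold.
#' @return character vector of "ASD"/"control".
#' @export
classify_mia <- function(scores, cutoff) {
  ifelse(scores > cutoff, "ASD", "control")
}

make_panel <- function(asd_otus, control_otus) {
  list(asd_otus = as.character(asd_otus),
       control_otus = as.character(control_otus))
}

panel_eval <- function(table, labels, panel, scale) {
  sc <- mia_scores(table, panel, scale)
  rc <- roc(sc, labels)
  yc <- youden_cutoff(rc)
  list(scores = sc, roc = rc, auc = rc$auc, cutoff = yc$cutoff,
       sensitivity = yc$sensitivity, specificity = yc$specificity)
}

#' Enumerate MIA marker panels and pick the best by AUC
#'
#' Grid mode (default, mirroring the panel-naming convention AS{m}HS{n}):
#' panels are top-m ASD-enriched x top-n control-enriched markers in
#' importance order, over all (m, n) with m + n >= 1 — (M+1)(N+1)-1
#' candidates. Powerset mode evaluates every subset of the ranked
#' markers and is refused above 16 markers; it exists as a small-scale
#' oracle for the grid. Markers with NA direction are excluded. The best
#' panel maximises AUC; ties go to the smaller panel (m + n, then m).
#'
#' @param ranking a `marker_ranking`.
#' @param table an [otu_table] over the same samples the panels are
#'   evaluated on.
#' @param labels group label per sample.
#' @param mode "grid" or "powerset".
#' @param scale MIA abundance scale, "counts" (default) or "relative".
#' @return list of class `panel_search`: `panels` (data.frame m, n,
#'   label, auc, cutoff, sensitivity, specificity), `best` (panel with
#'   scores/ROC details), `mode`, `scale`.
#' @export
enumerate_panels <- function(ranking, table, labels,
                             mode = c("grid", "powerset"),
                             scale = c("counts", "relative")) {
  mode <- match.arg(mode)
  scale <- match.arg(scale)
  if (nrow(ranking) < 1L) stopf("ranking is empty")
  rk <- ranking[!is.na(ranking$direction), , drop = FALSE]
  asd_rk <- rk$otu_id[rk$direction == "ASD-enriched"]
  ctl_rk <- rk$otu_id[rk$direction == "control-enriched"]
  M <- length(asd_rk); N <- length(ctl_rk)
  if (M + N < 1L) stopf("no directed markers to enumerate")
  cand <- list()
  if (mode == "grid") {
    for (m in 0:M) for (n in 0:N) {
      if (m + n < 1L) next
      cand[[length(cand) + 1L]] <- list(
        m = m, n = n,
        panel = make_panel(utils::head(asd_rk, m), utils::head(ctl_rk, n)))
    }
  } else {
    if (M + N > 16L)
      stopf("powerset mode refused for %d markers (> 16); use mode = 'grid'",
            M + N)
    all_ids <- c(asd_rk, ctl_rk)
    for (mask in seq_len(2^(M + N) - 1L)) {
      sel <- all_ids[bitwAnd(mask, bitwShiftL(1L, seq_along(all_ids) - 1L)) != 0L]
      cand[[length(cand) + 1L]] <- list(
        m = sum(sel %in% asd_rk), n = sum(sel %in% ctl_rk),
        panel = make_panel(intersect(sel, asd_rk), intersect(sel, ctl_rk)))
    }
  }
  rows <- vector("list", length(cand))
  evals <- vector("list", length(cand))
  for (i in seq_along(cand)) {
    ev <- panel_eval(table, labels, cand[[i]]$panel, scale)
    evals[[i]] <- ev
    rows[[i]] <- data.frame(
      m = cand[[i]]$m, n = cand[[i]]$n,
      label = sprintf("AS%dHS%d", cand[[i]]$m, cand[[i]]$n),
      auc = ev$auc, cutoff = ev$cutoff,
      sensitivity = ev$sensitivity, specificity = ev$specificity,
      stringsAsFactors = FALSE)
  }
  panels <- do.call(rbind, rows)
  ord <- order(-panels$auc, panels$m + panels$n, panels$m)
  best_i <- ord[1L]
  best <- c(cand[[best_i]]["m"], cand[[best_i]]["n"],
            list(label = panels$label[best_i], panel = cand[[best_i]]$panel),
            evals[[best_i]])
  structure(list(panels = panels[ord, ], best = best, mode = mode,
                 scale = scale),
            class = "panel_search")
}

#' @export
print.panel_search <- function(x, ...) {
  cat(sprintf("panel_search (%s, %s scale): %d panels; best %s AUC=%.3f cutoff=%.4g sens=%.3f spec=%.3f\n",
              x$mode, x$scale, nrow(x$panels), x$best$label, x$best$auc,
              x$best$cutoff, x$best$sensitivity, x$best$specificity))
  invisible(x)
}

#' Evaluate a fixed panel and cut-off on held-out samples
#'
#' For honest assessment: choose the panel and cut-off on training
#' samples ([enumerate_panels()]), then measure AUC and the confusion
#' matrix at the frozen cut-off here on test samples only.
#'
#' @param table an [otu_table] of the evaluation samples.
#' @param labels group label per sample.
#' @param panel a panel (`asd_otus`, `control_otus`).
#' @param cutoff frozen decision threshold.
#' @param scale MIA abundance scale.
#' @return list: `auc`, `sensitivity`, `specificity`, `accuracy`.
#' @export
evaluate_panel <- function(table, labels, panel, cutoff,
                           scale = c("counts", "relative")) {
  scale <- match.arg(scale)
  sc <- mia_scores(table, panel, scale)
  rc <- roc(sc, labels)
  pred <- classify_mia(sc, cutoff)
  y <- as_binary_labels(labels)
  list(auc = rc$auc,
       sensitivity = mean(pred[y == 1L] == "ASD"),
       specificity = mean(pred[y == 0L] == "control"),
       accuracy = mean((pred == "ASD") == (y == 1L)))
}
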