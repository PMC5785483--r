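#' Relative abundance matrix
#'
#' Each column (sample) divided by its total; zeros preserved.
#'
#' @param table an [otu_table] (or a bare count matrix).
#' @return numeric matrix with columns summing to 1.
#' @export
relative_abundance <- function(table) {
  counts <- if (inherits(table, "otu_table")) table$counts else table
  totals <- colSums(counts)
  if (any(totals == 0)) stopf("empty sample column")
  sweep(counts, 2, totals, "/")
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact p by full enumeration of rank assignments when both groups have
#' at most 8 observations and there are no ties; otherwise the normal
#' approximation with tie and continuity corrections. Returns the
#' Mann-Whitney U statistic of `x`.
#'
#' @param x,y numeric vectors with >= 3 observations each.
#' @return list(W, p_value, exact).
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (length(x) < 3L || length(y) < 3L) stopf("need >= 3 observations per group")
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(c(x, y)))
  if (all(x %in% y) && all(y %in% x) && length(unique(c(x, y))) == 1L)
    return(list(W = u, p_value = 1, exact = FALSE))
  if (n1 <= 8L && n2 <= 8L && !ties) {
    # exact null distribution of U by enumerating all rank subsets
    combos <- utils::combn(n1 + n2, n1)
    u_all <- colSums(combos) - n1 * (n1 + 1) / 2
    p <- min(1, 2 * min(mean(u_all <= u), mean(u_all >= u)))
    return(list(W = u, p_value = p, exact = TRUE))
  }
  n <- n1 + n2
  mu <- n1 * n2 / 2
  tie_tab <- table(r)
  sigma2 <- (n1 * n2 / 12) * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
  if (sigma2 <= 0) return(list(W = u, p_value = 1, exact = FALSE))
  z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
  list(W = u, p_value = min(1, 2 * stats::pnorm(-abs(z))), exact = FALSE)
}

#' Benjamini-Hochberg FDR q-values
#'
#' Step-up adjustment: after sorting, q(i) = min over j >= i of
#' p(j) * m / j, capped at 1, restored to the input order. NAs propagate
#' (and are excluded from m).
#'
#' @param p_values numeric vector of p-values.
#' @param method "BH" (default) or "BY" (Benjamini-Yekutieli, adds the
#'   harmonic-sum factor for arbitrary dependence).
#' @return q-values in the input order.
#' @export
bh_fdr <- function(p_values, method = c("BH", "BY")) {
  method <- match.arg(method)
  q <- rep(NA_real_, length(p_values))
  ok <- which(!is.na(p_values))
  if (!length(ok)) return(q)
  p <- p_values[ok]
  m <- length(p)
  o <- order(p)
  fac <- if (method == "BY") sum(1 / seq_len(m)) else 1
  stepped <- rev(cummin(rev(p[o] * fac * m / seq_len(m))))
  q[ok[o]] <- pmin(1, stepped)
  q
}

#' Differential-abundance screen
#'
#' Per-habitat Wilcoxon rank-sum comparison of ASD versus control
#' relative abundances at a taxonomic rank, with BH-FDR within the
#' (habitat, rank) family. A taxon is significant iff p < `p_cut` and
#' q < `q_cut`; direction follows the sign of the group mean difference.
#'
#' @param table an [otu_table].
#' @param metadata sample metadata (see [read_metadata()]).
#' @param rank taxonomic rank ("otu" for no aggregation).
#' @param habitat "saliva" or "plaque".
#' @param p_cut,q_cut significance thresholds (both 0.05 by default).
#' @param fdr_method "BH" or "BY".
#' @return data.frame of class `diff_result`: taxon_id, rank, habitat,
#'   mean relative abundances, direction, p_value, q_value, significant.
#' @export
differential_screen <- function(table, metadata, rank = "otu",
                                habitat = c("saliva", "plaque"),
                                p_cut = 0.05, q_cut = 0.05,
                                fdr_method = "BH") {
  habitat <- match.arg(habitat)
  md <- metadata[metadata$habitat == habitat, ]
  miss <- setdiff(md$sample_id, colnames(table$counts))
  if (length(miss)) stopf("metadata sample(s) not in table: %s",
                          paste(miss, collapse = ", "))
  tab <- aggregate_taxa(subset_table(table, samples = md$sample_id), rank)
  rel <- relative_abundance(tab)
  asd <- md$sample_id[md$group == "ASD"]
  ctl <- md$sample_id[md$group == "control"]
  if (length(asd) < 3L || length(ctl) < 3L)
    stopf("need >= 3 samples per group in habitat %s", habitat)
  res <- lapply(rownames(rel), function(tx) {
    a <- rel[tx, asd]; b <- rel[tx, ctl]
    wt <- wilcoxon_rank_sum(a, b)
    data.frame(taxon_id = tx, rank = rank, habitat = habitat,
               mean_rel_abund_asd = mean(a), mean_rel_abund_control = mean(b),
               direction = if (mean(a) >= mean(b)) "ASD-enriched" else "control-enriched",
               p_value = wt$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q_value <- bh_fdr(out$p_value, method = fdr_method)
  out$significant <- out$p_value < p_cut & out$q_value < q_cut
  structure(out, class = c("diff_result", "data.frame"))
}

#' Spearman correlation of taxa with clinical variables
#'
#' Correlates the `top_k` most abundant taxa (by overall mean relative
#' abundance) with clinical indices using Spearman's rank correlation on
#' pairwise-complete observations (average ranks for ties; missing
#' clinical values are never imputed). A constant variable or fewer than
#' 3 complete pairs yields an absent (NA) coefficient with `n_pairs`
#' recorded. Row and column orders for heat-map display come from
#' unsupervised hierarchical clustering (average linkage on 1 - rho).
#'
#' @param table an [otu_table].
#' @param metadata sample metadata.
#' @param top_k number of most-abundant taxa to retain.
#' @param variables clinical columns to use (default: all available).
#' @param habitat optionally restrict to one habitat's samples.
#' @return list of class `clinical_correlation`: `correlations` (long
#'   data.frame: otu_id, variable, spearman_rho, p_value, n_pairs),
#'   `rho` (taxa x variables matrix), `row_order`, `col_order`.
#' @export
clinical_correlation <- function(table, metadata, top_k = 50,
                                 variables = NULL, habitat = NULL) {
  if (!is.null(habitat)) {
    habitat <- match.arg(habitat, HABITATS)
    metadata <- metadata[metadata$habitat == habitat, ]
  }
  metadata <- metadata[metadata$sample_id %in% colnames(table$counts), ]
  tab <- subset_table(table, samples = metadata$sample_id)
  rel <- relative_abundance(tab)
  variables <- variables %||%
    intersect(c("abc_score", "age", "bmi", "dmft", "dmfs", "pli", "gi",
                "bi", "bop", "pd"), names(metadata))
  keep <- head(order(rowMeans(rel), decreasing = TRUE), top_k)
  rel <- rel[keep, , drop = FALSE]
  out <- list()
  rho_m <- matrix(NA_real_, nrow(rel), length(variables),
                  dimnames = list(rownames(rel), variables))
  for (v in variables) {
    y <- metadata[[v]][match(colnames(rel), metadata$sample_id)]
    for (tx in rownames(rel)) {
      x <- rel[tx, ]
      ok <- !is.na(x) & !is.na(y)
      n_pairs <- sum(ok)
      rho <- p <- NA_real_
      if (n_pairs >= 3L && stats::sd(x[ok]) > 0 && stats::sd(y[ok]) > 0) {
        ct <- suppressWarnings(
          stats::cor.test(x[ok], y[ok], method = "spearman", exact = FALSE))
        rho <- unname(ct$estimate); p <- ct$p.value
        rho_m[tx, v] <- rho
      }
      out[[paste(tx, v)]] <- data.frame(
        otu_id = tx, variable = v, spearman_rho = rho, p_value = p,
        n_pairs = n_pairs, stringsAsFactors = FALSE)
    }
  }
  long <- do.call(rbind, out)
  rownames(long) <- NULL
  structure(list(correlations = long, rho = rho_m,
                 row_order = cluster_order(rho_m),
                 col_order = cluster_order(t(rho_m))),
            class = "clinical_correlation")
}

# Average-linkage hierarchical clustering on 1 - rho of row profiles;
# rows too sparse to correlate keep their original position at the end.
cluster_order <- function(m) {
  usable <- which(rowSums(!is.na(m)) >= 2 &
                    apply(m, 1, function(r) stats::sd(r, na.rm = TRUE) > 0))
  if (length(usable) < 3L) return(rownames(m))
  cm <- suppressWarnings(stats::cor(t(m[usable, , drop = FALSE]),
                                    use = "pairwise.complete.obs"))
  cm[is.na(cm)] <- 0
  hc <- stats::hclust(stats::as.dist(1 - cm), method = "average")
  c(rownames(m)[usable][hc$order], rownames(m)[-usable])
}
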