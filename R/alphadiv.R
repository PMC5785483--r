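#' Rarefy one sample without replacement
#'
#' Random subsampling of reads to a fixed depth (multivariate
#' hypergeometric draw). The rarefied vector sums exactly to `depth` and
#' never gains support: OTUs at zero stay at zero.
#'
#' @param sample_counts non-negative integer vector (may be named).
#' @param depth target depth; must not exceed `sum(sample_counts)`.
#' @param seed integer seed or NULL.
#' @return integer vector of the same length and names.
#' @export
rarefy <- function(sample_counts, depth, seed = NULL) {
  total <- sum(sample_counts)
  if (depth > total)
    stopf("rarefaction depth %d exceeds sample total %d", depth, total)
  if (depth == total) return(as.integer(sample_counts) |>
                              stats::setNames(names(sample_counts)))
  with_seed(seed, {
    reads <- rep.int(seq_along(sample_counts), sample_counts)
    keep <- sample(reads, depth)
    out <- tabulate(keep, nbins = length(sample_counts))
    stats::setNames(as.integer(out), names(sample_counts))
  })
}

check_nonzero <- function(counts) {
  if (all(counts == 0)) stopf("all-zero count vector")
  if (any(counts < 0)) stopf("negative counts")
  counts
}

#' Shannon diversity (natural log) and Shannon evenness
#'
#' `shannon()` returns H = -sum p_i ln p_i over nonzero proportions;
#' `shannoneven()` returns H / ln(S_obs), defined as 0 when only one OTU
#' is observed.
#'
#' @param counts non-negative count vector with at least one nonzero entry.
#' @param base logarithm base (default natural log, the mothur convention).
#' @return numeric scalar.
#' @export
shannon <- function(counts, base = exp(1)) {
  check_nonzero(counts)
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p, base = base))
}

#' @rdname shannon
#' @export
shannoneven <- function(counts, base = exp(1)) {
  check_nonzero(counts)
  s <- sum(counts > 0)
  if (s < 2L) return(0)
  shannon(counts, base) / log(s, base = base)
}

#' ACE richness estimator
#'
#' Abundance-based coverage estimator with rare/abundant threshold 10
#' (EstimateS convention): S_abund + S_rare/C_ace + (F1/C_ace) * gamma^2,
#' where C_ace = 1 - F1/N_rare and gamma^2 is the rare-species
#' coefficient-of-variation term floored at 0. When every rare read is a
#' singleton (C_ace = 0) the estimator is undefined and Chao1 is returned
#' instead.
#'
#' @param counts non-negative count vector with at least one nonzero entry.
#' @param rare_threshold counts <= this are "rare" (default 10).
#' @return numeric richness estimate, always >= observed richness.
#' @export
ace <- function(counts, rare_threshold = 10) {
  check_nonzero(counts)
  x <- counts[counts > 0]
  rare <- x[x <= rare_threshold]
  s_abund <- sum(x > rare_threshold)
  s_rare <- length(rare)
  if (s_rare == 0L) return(s_abund)
  n_rare <- sum(rare)
  f1 <- sum(rare == 1L)
  if (f1 == n_rare) return(chao1(counts))
  c_ace <- 1 - f1 / n_rare
  fi <- tabulate(rare, nbins = rare_threshold)
  g2 <- max(0, (s_rare / c_ace) * sum(seq_len(rare_threshold) *
                                        (seq_len(rare_threshold) - 1) * fi) /
              (n_rare * (n_rare - 1)) - 1)
  s_abund + s_rare / c_ace + (f1 / c_ace) * g2
}

chao1 <- function(counts) {
  x <- counts[counts > 0]
  f1 <- sum(x == 1L); f2 <- sum(x == 2L)
  length(x) + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Good's coverage
#'
#' 1 - F1/N: the estimated fraction of the community represented by the
#' sample, F1 = number of singleton OTUs, N = total reads.
#'
#' @param counts non-negative count vector with N >= 1.
#' @return fraction in \[0, 1\].
#' @export
goods_coverage <- function(counts) {
  n <- sum(counts)
  if (n < 1) stopf("need at least one read")
  1 - sum(counts == 1L) / n
}

#' Rarefaction curve for one sample
#'
#' Mean observed OTU count at each depth over `replicates` random
#' subsamples; monotone non-decreasing in depth, equal to observed
#' richness at full depth.
#'
#' @param sample_counts non-negative integer vector.
#' @param depths increasing depths, each <= the sample total.
#' @param replicates subsamples per depth.
#' @param seed integer seed or NULL.
#' @return data.frame (depth, mean_observed).
#' @export
rarefaction_curve <- function(sample_counts, depths, replicates = 10, seed = NULL) {
  check_nonzero(sample_counts)
  with_seed(seed, {
    mean_obs <- vapply(depths, function(d) {
      mean(vapply(seq_len(replicates), function(r)
        sum(rarefy(sample_counts, d) > 0), numeric(1)))
    }, numeric(1))
    data.frame(depth = depths, mean_observed = mean_obs)
  })
}

#' Alpha-diversity profile of every sample
#'
#' Rarefies each sample to a common depth, then computes observed OTUs,
#' ACE, Shannon, Shannon evenness and Good's coverage. Samples with fewer
#' reads than `depth` are dropped with a warning (they cannot be rarefied
#' without replacement).
#'
#' @param table an [otu_table].
#' @param depth rarefaction depth; default = smallest per-sample total.
#' @param seed integer seed or NULL.
#' @return data.frame of class `alpha_result`, one row per retained sample.
#' @export
alpha_diversity <- function(table, depth = NULL, seed = NULL) {
  counts <- table$counts
  totals <- colSums(counts)
  depth <- depth %||% min(totals)
  drop <- totals < depth
  if (any(drop))
    warnf("dropping %d sample(s) below rarefaction depth %d: %s",
          sum(drop), depth, paste(colnames(counts)[drop], collapse = ", "))
  keep <- colnames(counts)[!drop]
  if (!length(keep)) stopf("no sample reaches rarefaction depth %d", depth)
  with_seed(seed, {
    res <- lapply(keep, function(sid) {
      x <- rarefy(counts[, sid], depth)
      data.frame(sample_id = sid, observed_otus = sum(x > 0),
                 ace = ace(x), shannon = shannon(x),
                 shannoneven = shannoneven(x),
                 goods_coverage = goods_coverage(x),
                 rarefaction_depth = depth, stringsAsFactors = FALSE)
    })
    structure(do.call(rbind, res), class = c("alpha_result", "data.frame"))
  })
}

#' Welch two-sample t-test on per-sample index values
#'
#' @param values_a,values_b numeric vectors (>= 2 each).
#' @param pooled use the pooled-variance (classic Student) test instead
#'   of Welch.
#' @return list(t, df, p_value, mean_a, mean_b).
#' @export
compare_alpha <- function(values_a, values_b, pooled = FALSE) {
  if (length(values_a) < 2L || length(values_b) < 2L)
    stopf("need >= 2 values per group")
  ht <- stats::t.test(values_a, values_b, var.equal = pooled)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, mean_a = mean(values_a), mean_b = mean(values_b))
}

#' Group-wise alpha comparison table
#'
#' Welch t-tests of every index between ASD and control within each
#' habitat.
#'
#' @param alpha an `alpha_result` from [alpha_diversity()].
#' @param metadata sample metadata (see [read_metadata()]).
#' @return data.frame (habitat, index, t, p_value, mean_asd, mean_control).
#' @export
compare_alpha_groups <- function(alpha, metadata) {
  md <- metadata[match(alpha$sample_id, metadata$sample_id), ]
  idx <- c("observed_otus", "ace", "shannon", "shannoneven")
  out <- list()
  for (h in intersect(HABITATS, unique(md$habitat))) {
    sel <- md$habitat == h
    for (v in idx) {
      a <- alpha[[v]][sel & md$group == "ASD"]
      b <- alpha[[v]][sel & md$group == "control"]
      if (length(a) < 2L || length(b) < 2L) next
      ht <- compare_alpha(a, b)
      out[[paste(h, v)]] <- data.frame(
        habitat = h, index = v, t = ht$t, p_value = ht$p_value,
        mean_asd = ht$mean_a, mean_control = ht$mean_b,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
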