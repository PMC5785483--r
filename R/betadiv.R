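#' Collapse an OTU table to a taxonomic rank
#'
#' Counts are summed within identical lineage prefixes up to `rank`;
#' OTUs whose lineage is missing or does not reach `rank` are pooled
#' under "unclassified". Column sums are invariant.
#'
#' @param table an [otu_table].
#' @param rank one of "phylum", "class", "order", "family", "genus",
#'   "species", or "otu" (identity).
#' @return An [otu_table] whose rows are taxa at `rank`.
#' @export
aggregate_taxa <- function(table, rank = "genus") {
  rank <- match.arg(rank, c(RANKS, "otu"))
  if (rank == "otu") return(table)
  k <- match(rank, RANKS)
  lineage <- table$taxonomy[rownames(table$counts)]
  key <- vapply(lineage, function(lin) {
    if (is.na(lin) || !nzchar(lin)) return("unclassified")
    parts <- strsplit(lin, ";", fixed = TRUE)[[1L]]
    if (length(parts) < k || !nzchar(trimws(parts[k]))) return("unclassified")
    paste(trimws(parts[seq_len(k)]), collapse = ";")
  }, character(1), USE.NAMES = FALSE)
  agg <- rowsum(table$counts, group = key)
  storage.mode(agg) <- "integer"
  otu_table(agg, stats::setNames(rownames(agg), rownames(agg)))
}

# Per-branch mass profile: for a tips x k matrix of leaf values, returns
# the edge lengths and the summed value under each branch (postorder
# accumulation). Missing tips are an error per the UniFrac precondition.
branch_profile <- function(tree, leaf_values) {
  tree <- validate_tree(tree)
  tips <- tree$tip.label
  missing <- setdiff(rownames(leaf_values), tips)
  if (length(missing))
    stopf("OTU(s) not in tree: %s", paste(utils::head(missing, 3), collapse = ", "))
  n_tip <- length(tips)
  n_node <- n_tip + tree$Nnode
  k <- ncol(leaf_values)
  mass <- matrix(0, n_node, k)
  mass[seq_len(n_tip), ] <- leaf_values[match(tips, rownames(leaf_values)), ,
                                        drop = FALSE] |>
    (\(m) { m[is.na(m)] <- 0; m })()
  tr <- stats::reorder(tree, "postorder")
  for (i in seq_len(nrow(tr$edge)))
    mass[tr$edge[i, 1L], ] <- mass[tr$edge[i, 1L], ] + mass[tr$edge[i, 2L], ]
  lengths <- tr$edge.length %||% rep(1, nrow(tr$edge))
  list(lengths = lengths, branch_mass = mass[tr$edge[, 2L], , drop = FALSE])
}

as_leaf_matrix <- function(counts_a, counts_b) {
  ids <- union(names(counts_a), names(counts_b))
  m <- matrix(0, length(ids), 2, dimnames = list(ids, c("A", "B")))
  m[names(counts_a), 1L] <- counts_a
  m[names(counts_b), 2L] <- counts_b
  m
}

#' Unweighted UniFrac distance between two samples
#'
#' Presence-based phylogenetic distance: the branch length unique to one
#' sample divided by the total branch length covered by either, in
#' \[0, 1\].
#'
#' @param tree rooted `ape::phylo` whose leaves cover both samples'
#'   nonzero OTUs.
#' @param counts_a,counts_b named count vectors.
#' @return distance in \[0, 1\].
#' @export
unweighted_unifrac <- function(tree, counts_a, counts_b) {
  if (sum(counts_a) == 0 && sum(counts_b) == 0)
    stopf("both samples are empty")
  m <- as_leaf_matrix(counts_a, counts_b) > 0
  bp <- branch_profile(tree, m * 1)
  ia <- bp$branch_mass[, 1L] > 0
  ib <- bp$branch_mass[, 2L] > 0
  denom <- sum(bp$lengths * pmax(ia, ib))
  if (denom == 0) return(0)
  sum(bp$lengths * abs(ia - ib)) / denom
}

#' Weighted UniFrac distance between two samples
#'
#' Abundance-weighted phylogenetic distance: sum over branches of
#' branch length times the absolute difference in the fraction of each
#' sample's reads below the branch. The normalised form divides by
#' `sum(l_b * (p_A + p_B))`, bounding the distance to \[0, 1\]; the raw
#' form omits the division.
#'
#' @inheritParams unweighted_unifrac
#' @param normalized divide by the branch-sum normaliser (default TRUE).
#' @return non-negative distance (<= 1 when normalised).
#' @export
weighted_unifrac <- function(tree, counts_a, counts_b, normalized = TRUE) {
  if (sum(counts_a) == 0 || sum(counts_b) == 0)
    stopf("weighted UniFrac needs nonzero totals in both samples")
  m <- as_leaf_matrix(counts_a, counts_b)
  m <- sweep(m, 2, colSums(m), "/")
  bp <- branch_profile(tree, m)
  num <- sum(bp$lengths * abs(bp$branch_mass[, 1L] - bp$branch_mass[, 2L]))
  if (!normalized) return(num)
  denom <- sum(bp$lengths * (bp$branch_mass[, 1L] + bp$branch_mass[, 2L]))
  if (denom == 0) return(0)
  num / denom
}

#' Pairwise UniFrac distance matrix
#'
#' Computes all branch profiles in one postorder pass, so large tables
#' are handled efficiently.
#'
#' @param table an [otu_table] (typically genus-aggregated for this
#'   study design; pass the OTU-level table for OTU-resolution
#'   distances).
#' @param tree rooted `ape::phylo` covering the table's rows.
#' @param metric "uw-unifrac" or "w-unifrac" (normalised weighted).
#' @return symmetric distance matrix with sample-id dimnames.
#' @export
distance_matrix <- function(table, tree, metric = c("w-unifrac", "uw-unifrac")) {
  metric <- match.arg(metric)
  counts <- table$counts
  if (any(colSums(counts) == 0)) stopf("empty sample in table")
  if (metric == "w-unifrac") {
    leaf <- sweep(counts, 2, colSums(counts), "/")
  } else {
    leaf <- (counts > 0) * 1
  }
  bp <- branch_profile(tree, leaf)
  l <- bp$lengths
  bm <- bp$branch_mass
  n <- ncol(counts)
  dm <- matrix(0, n, n, dimnames = list(colnames(counts), colnames(counts)))
  if (metric == "uw-unifrac") {
    ind <- bm > 0
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      denom <- sum(l * (ind[, i] | ind[, j]))
      d <- if (denom == 0) 0 else sum(l * xor(ind[, i], ind[, j])) / denom
      dm[i, j] <- dm[j, i] <- d
    }
  } else {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      num <- sum(l * abs(bm[, i] - bm[, j]))
      denom <- sum(l * (bm[, i] + bm[, j]))
      d <- if (denom == 0) 0 else num / denom
      dm[i, j] <- dm[j, i] <- d
    }
  }
  dm
}

#' Principal coordinate analysis (classical MDS)
#'
#' Gower double-centering of -D^2/2 followed by eigendecomposition;
#' coordinates are eigenvectors scaled by the square root of their
#' eigenvalues. Axes with non-positive eigenvalues are dropped (with a
#' message when negative eigenvalues carry noticeable magnitude).
#'
#' @param dm symmetric distance matrix with dimnames.
#' @return list of class `pcoa_result`: `sample_ids`, `coordinates`
#'   (samples x axes), `eigenvalues`, `proportion_explained`.
#' @export
pcoa <- function(dm) {
  dm <- validate_distance_matrix(dm)
  n <- nrow(dm)
  a <- -0.5 * dm^2
  centred <- a - rowMeans(a) - rep(colMeans(a), each = n) + mean(a)
  eig <- eigen(centred, symmetric = TRUE)
  tol <- max(abs(eig$values)) * 1e-9
  pos <- eig$values > tol
  neg_mag <- sum(abs(pmin(eig$values, 0)))
  if (neg_mag > tol * n)
    message(sprintf("pcoa: dropping negative eigenvalues (total magnitude %.3g)",
                    neg_mag))
  values <- eig$values[pos]
  coords <- eig$vectors[, pos, drop = FALSE] %*% diag(sqrt(values), sum(pos))
  dimnames(coords) <- list(rownames(dm), paste0("PCo", seq_len(sum(pos))))
  structure(list(sample_ids = rownames(dm), coordinates = coords,
                 eigenvalues = values,
                 proportion_explained = values / sum(values)),
            class = "pcoa_result")
}

#' One-factor PERMANOVA
#'
#' Permutational multivariate analysis of variance on a distance matrix:
#' pseudo-F from total and within-group sums of squared distances, with a
#' permutation p-value of resolution 1/(n_permutations + 1).
#'
#' @param dm symmetric distance matrix with sample-id dimnames.
#' @param labels group label per sample (same order as `dm`).
#' @param n_permutations number of label permutations.
#' @param seed integer seed or NULL.
#' @return list of class `permanova_result`: `pseudo_F`, `p_value`,
#'   `n_permutations`, `group_sizes`.
#' @export
permanova <- function(dm, labels, n_permutations = 999, seed = NULL) {
  dm <- validate_distance_matrix(dm)
  labels <- as.character(labels)
  if (length(labels) != nrow(dm)) stopf("labels length must match dm")
  sizes <- table(labels)
  if (any(sizes < 2L)) stopf("every group needs >= 2 samples")
  if (length(sizes) < 2L) stopf("need >= 2 groups")
  d2 <- dm^2
  n <- nrow(dm)
  a <- length(sizes)
  f_stat <- function(lab) {
    ss_w <- 0
    for (g in unique(lab)) {
      idx <- which(lab == g)
      ss_w <- ss_w + sum(d2[idx, idx]) / (2 * length(idx))
    }
    ss_t <- sum(d2) / (2 * n)
    ((ss_t - ss_w) / (a - 1)) / (ss_w / (n - a))
  }
  f_obs <- f_stat(labels)
  p <- with_seed(seed, {
    hits <- 0L
    for (i in seq_len(n_permutations))
      if (f_stat(sample(labels)) >= f_obs) hits <- hits + 1L
    (1 + hits) / (1 + n_permutations)
  })
  structure(list(pseudo_F = f_obs, p_value = p,
                 n_permutations = n_permutations,
                 group_sizes = as.integer(sizes)),
            class = "permanova_result")
}
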