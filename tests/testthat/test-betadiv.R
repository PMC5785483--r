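test_that("aggregate_taxa collapses lineages and conserves counts", {
  tab <- tiny_table()
  expect_identical(aggregate_taxa(tab, "otu"), tab)
  gen <- aggregate_taxa(tab, "genus")
  expect_equal(nrow(gen$counts), 2L)  # Streptococcus + Prevotella
  expect_equal(colSums(gen$counts), colSums(tab$counts))
  strep <- grep("Streptococcus$", rownames(gen$counts), value = TRUE)
  expect_equal(unname(gen$counts[strep, ]), unname(colSums(tab$counts[1:2, ])))
  # species rank: OTU3 has no species field -> pooled under unclassified
  sp <- aggregate_taxa(tab, "species")
  expect_true("unclassified" %in% rownames(sp$counts))
  expect_equal(colSums(sp$counts), colSums(tab$counts))
})

test_that("UniFrac trivial identities hold", {
  tr <- ape::read.tree(text = "((A:1,B:2):1,(C:1,D:3):2);")
  cc <- function(...) setNames(c(...), c("A", "B", "C", "D"))
  # identical presence/composition -> 0
  expect_equal(unweighted_unifrac(tr, cc(1, 1, 0, 0), cc(2, 5, 0, 0)), 0)
  expect_equal(weighted_unifrac(tr, cc(1, 2, 3, 0), cc(2, 4, 6, 0)), 0)
  # disjoint root subtrees -> unweighted distance 1
  expect_equal(unweighted_unifrac(tr, cc(1, 1, 0, 0), cc(0, 0, 1, 1)), 1)
  # scaling one sample leaves weighted distance unchanged; symmetry
  a <- cc(3, 1, 0, 2); b <- cc(0, 2, 2, 1)
  expect_equal(weighted_unifrac(tr, a, b), weighted_unifrac(tr, a * 10, b))
  expect_equal(weighted_unifrac(tr, a, b), weighted_unifrac(tr, b, a))
  expect_error(unweighted_unifrac(tr, cc(0, 0, 0, 0), cc(0, 0, 0, 0)),
               "empty")
})

test_that("UniFrac equals the brute-force branch enumeration oracle", {
  set.seed(11)
  for (i in 1:60) {
    n <- sample(3:6, 1)
    tr <- generate_tree(sprintf("L%d", seq_len(n)))
    a <- random_counts_on_tree(tr)
    b <- random_counts_on_tree(tr)
    if (sum(a) == 0) a[1] <- 1
    if (sum(b) == 0) b[1] <- 1
    expect_equal(unweighted_unifrac(tr, a, b),
                 oracle_unifrac(tr, a, b, weighted = FALSE),
                 tolerance = 1e-12)
    expect_equal(weighted_unifrac(tr, a, b),
                 oracle_unifrac(tr, a, b, weighted = TRUE),
                 tolerance = 1e-12)
    expect_equal(weighted_unifrac(tr, a, b, normalized = FALSE),
                 oracle_unifrac(tr, a, b, weighted = TRUE, normalized = FALSE),
                 tolerance = 1e-12)
  }
})

test_that("distance_matrix agrees with single-pair calls and metric axioms", {
  set.seed(12)
  tab <- random_table(12, 7)
  tr <- generate_tree(rownames(tab$counts), seed = 5)
  for (metric in c("w-unifrac", "uw-unifrac")) {
    dm <- distance_matrix(tab, tr, metric)
    expect_equal(dm, t(dm))
    expect_equal(unname(diag(dm)), rep(0, 7))
    fun <- if (metric == "w-unifrac") weighted_unifrac else unweighted_unifrac
    for (pair in list(c(1, 2), c(3, 7), c(4, 5)))
      expect_equal(dm[pair[1], pair[2]],
                   fun(tr, tab$counts[, pair[1]], tab$counts[, pair[2]]),
                   tolerance = 1e-12)
    # permutation equivariance
    perm <- sample(colnames(tab$counts))
    dm_p <- distance_matrix(subset_table(tab, samples = perm), tr, metric)
    expect_equal(dm_p, dm[perm, perm])
  }
  # duplicate sample -> zero distance
  counts <- cbind(tab$counts, dup = tab$counts[, 1])
  dm <- distance_matrix(otu_table(counts), tr, "w-unifrac")
  expect_equal(dm["S01", "dup"], 0)
  # unweighted distances satisfy the triangle inequality
  dmu <- distance_matrix(tab, tr, "uw-unifrac")
  for (i in 1:7) for (j in 1:7) for (k in 1:7)
    expect_lte(dmu[i, j], dmu[i, k] + dmu[k, j] + 1e-12)
})

test_that("pcoa recovers Euclidean configurations", {
  set.seed(13)
  pts <- matrix(rnorm(20), 10, 2,
                dimnames = list(paste0("s", 1:10), NULL))
  dm <- as.matrix(dist(pts))
  pc <- pcoa(dm)
  expect_equal(pc$eigenvalues, sort(pc$eigenvalues, decreasing = TRUE))
  expect_lte(sum(pc$proportion_explained), 1 + 1e-12)
  rec <- as.matrix(dist(pc$coordinates))
  expect_equal(unname(rec), unname(dm), tolerance = 1e-9)
  # 2 samples: one axis, separation = distance
  dm2 <- matrix(c(0, 3, 3, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  pc2 <- pcoa(dm2)
  expect_equal(ncol(pc2$coordinates), 1L)
  expect_equal(abs(diff(unname(pc2$coordinates[, 1]))), 3)
  # all-equal distances among 3 samples: equilateral, two equal eigenvalues
  dm3 <- matrix(1, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(dm3) <- 0
  pc3 <- pcoa(dm3)
  expect_equal(pc3$eigenvalues[1], pc3$eigenvalues[2], tolerance = 1e-9)
  rec3 <- as.matrix(dist(pc3$coordinates))
  expect_equal(unname(rec3), unname(dm3), tolerance = 1e-9)
})

test_that("permanova statistic and p-value behave correctly", {
  set.seed(14)
  pts <- rbind(matrix(rnorm(40), 20), matrix(rnorm(40, 6), 20))
  rownames(pts) <- paste0("s", 1:40)
  dm <- as.matrix(dist(pts))
  lab <- rep(c("g1", "g2"), each = 20)
  pr <- permanova(dm, lab, n_permutations = 999, seed = 1)
  # complete separation saturates the permutation p-value
  expect_equal(pr$p_value, 1 / 1000)
  expect_gt(pr$pseudo_F, 1)
  # permutation invariance of F under relabelled-but-equal partition
  pr2 <- permanova(dm, rep(c("B", "A"), each = 20), n_permutations = 9, seed = 1)
  expect_equal(pr2$pseudo_F, pr$pseudo_F)
  expect_error(permanova(dm, c("a", rep("b", 39)), seed = 1), ">= 2")

  # oracle: vegan::adonis2 computes the same pseudo-F
  skip_if_not_installed("vegan")
  ad <- vegan::adonis2(as.dist(dm) ~ lab, permutations = 99)
  expect_equal(pr$pseudo_F, ad$F[1], tolerance = 1e-9)
})

test_that("exemplar_tree produces a tree over aggregated taxa", {
  st <- generate_study(synth_config(n_otus = 40, seed = 3, depth_mean = 2000,
                                    depth_sd = 100, n_diff_per_habitat = 6))
  gen <- aggregate_taxa(st$table, "genus")
  gt <- exemplar_tree(st$table, st$tree, "genus")
  expect_setequal(gt$tip.label, rownames(gen$counts))
  dm <- distance_matrix(gen, gt, "w-unifrac")
  expect_equal(dim(dm), c(111L, 111L))
})
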