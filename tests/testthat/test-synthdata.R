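test_that("default config reproduces the study design shape", {
  cfg <- synth_config(seed = 42)
  st <- generate_study(cfg)
  expect_equal(dim(st$table$counts), c(405L, 111L))
  tab <- table(st$metadata$group, st$metadata$habitat)
  expect_equal(tab["control", "saliva"], 27L)
  expect_equal(tab["control", "plaque"], 26L)
  expect_equal(tab["ASD", "saliva"], 32L)
  expect_equal(tab["ASD", "plaque"], 26L)
  # column sums equal the drawn depths, all above the truncation floor
  expect_true(all(colSums(st$table$counts) >= 1000))
  # ABC present only for ASD subjects
  expect_true(all(is.na(st$metadata$abc_score[st$metadata$group == "control"])))
  expect_true(all(!is.na(st$metadata$abc_score[st$metadata$group == "ASD"])))
  # identical seed => bit-identical output
  st2 <- generate_study(cfg)
  expect_identical(st$table$counts, st2$table$counts)
  expect_identical(st$metadata, st2$metadata)
  expect_identical(ape::write.tree(st$tree), ape::write.tree(st2$tree))
})

test_that("config invariants are enforced", {
  expect_error(synth_config(n_otus = 1), "n_otus")
  expect_error(synth_config(depth_mean = 0), "depth_mean")
  expect_error(synth_config(dirichlet_concentration = 0), "concentration")
  expect_error(synth_config(n_diff_per_habitat = 500, n_otus = 100), "n_diff")
  # fold change so extreme that spiked mass exhausts the composition
  cfg <- synth_config(n_otus = 10, n_diff_per_habitat = 6,
                      log2_fold_change = 30, prop_asd_enriched = 0.5,
                      corr_block_size = 0, seed = 1)
  expect_error(generate_study(cfg), "fold")
})

test_that("null effect (lfc = 0) leaves groups exchangeable but labelled", {
  cfg <- synth_config(n_otus = 50, n_diff_per_habitat = 8,
                      log2_fold_change = 0, corr_block_size = 0,
                      depth_mean = 5000, depth_sd = 500,
                      group_sizes = c(HS = 15, HP = 0, AS = 15, AP = 0),
                      seed = 5)
  st <- generate_study(cfg)
  expect_equal(nrow(st$truth), 8L)   # truth still labelled
  dr <- differential_screen(st$table, st$metadata, rank = "otu",
                            habitat = "saliva")
  planted <- dr[dr$taxon_id %in% st$truth$otu_id, ]
  # Wilcoxon rejection on planted-but-null OTUs stays near alpha
  expect_lte(sum(planted$p_value < 0.05), 3)
})

test_that("mass-preserving spike yields the programmed fold change", {
  # scaled-down Monte-Carlo version of the generative-definition check:
  # mean ratio of spiked-OTU group-mean relative abundances ~= 2^3 = 8
  # ratio-of-sums estimator: E[sum of spiked ASD means] is exactly
  # 2^lfc times E[sum of matched control means], and pooling avoids the
  # Jensen bias a per-dataset ratio of noisy means would carry
  n_rep <- 300
  up_asd <- up_ctl <- down_asd <- down_ctl <- 0
  for (r in seq_len(n_rep)) {
    cfg <- synth_config(n_otus = 20, n_diff_per_habitat = 4,
                        log2_fold_change = 3, prop_asd_enriched = 0.5,
                        corr_block_size = 0, depth_mean = 20000,
                        depth_sd = 1000, clinical_corr = 0,
                        group_sizes = c(HS = 50, HP = 0, AS = 50, AP = 0),
                        seed = 1000 + r)
    st <- generate_study(cfg)
    rel <- relative_abundance(st$table)
    asd <- st$metadata$sample_id[st$metadata$group == "ASD"]
    ctl <- st$metadata$sample_id[st$metadata$group == "control"]
    up <- st$truth$otu_id[st$truth$direction == "ASD-enriched"]
    down <- st$truth$otu_id[st$truth$direction == "control-enriched"]
    up_asd <- up_asd + sum(rowMeans(rel[up, asd, drop = FALSE]))
    up_ctl <- up_ctl + sum(rowMeans(rel[up, ctl, drop = FALSE]))
    down_asd <- down_asd + sum(rowMeans(rel[down, asd, drop = FALSE]))
    down_ctl <- down_ctl + sum(rowMeans(rel[down, ctl, drop = FALSE]))
  }
  expect_equal(up_asd / up_ctl, 8, tolerance = 0.05)
  expect_equal(down_ctl / down_asd, 8, tolerance = 0.05)
})

test_that("ABC score tracks ASD marker load at the configured correlation", {
  cfg <- synth_config(n_otus = 50, n_diff_per_habitat = 10,
                      log2_fold_change = 2, clinical_corr = 0.4,
                      corr_block_size = 0, depth_mean = 5000, depth_sd = 300,
                      group_sizes = c(HS = 5, HP = 0, AS = 1000, AP = 0),
                      seed = 9)
  st <- generate_study(cfg)
  md <- st$metadata[st$metadata$group == "ASD", ]
  rel <- relative_abundance(st$table)
  mk <- st$truth$otu_id[st$truth$direction == "ASD-enriched" &
                          st$truth$habitat == "saliva"]
  load <- colSums(rel[mk, md$sample_id, drop = FALSE])
  rho <- cor(load, md$abc_score, method = "spearman")
  expect_lt(abs(rho - 0.4), 0.1)
  # Table-1-style scale
  expect_equal(mean(md$abc_score), 78.66, tolerance = 0.1)
})

test_that("generate_tree produces valid rooted bifurcating trees", {
  expect_error(generate_tree("one"), ">= 2")
  expect_error(generate_tree(c("a", "a")), "duplicate")
  # 2 leaves: single cherry
  tr2 <- generate_tree(c("a", "b"), seed = 1)
  expect_equal(ape::Ntip(tr2), 2L)
  expect_equal(tr2$Nnode, 1L)
  expect_equal(nrow(tr2$edge), 2L)
  # n leaves: n-1 internal nodes, 2n-2 branches
  for (n in c(5, 17, 40)) {
    tr <- generate_tree(sprintf("x%02d", seq_len(n)), seed = n)
    expect_equal(ape::Ntip(tr), n)
    expect_equal(tr$Nnode, n - 1L)
    expect_equal(nrow(tr$edge), 2L * n - 2L)
    expect_true(ape::is.rooted(tr))
  }
  # same seed twice => identical Newick
  expect_identical(ape::write.tree(generate_tree(letters[1:8], seed = 3)),
                   ape::write.tree(generate_tree(letters[1:8], seed = 3)))
})

test_that("write_study emits all four artifacts readably", {
  dir <- withr::local_tempdir()
  st <- generate_study(synth_config(n_otus = 20, seed = 2,
                                    depth_mean = 1500, depth_sd = 100,
                                    n_diff_per_habitat = 4))
  write_study(st, dir)
  expect_identical(read_otu_table(file.path(dir, "otu_table.tsv"))$counts,
                   st$table$counts)
  expect_equal(nrow(read_metadata(file.path(dir, "metadata.tsv"))), 111L)
  expect_equal(sort(read_newick(file.path(dir, "tree.nwk"))$tip.label),
               sort(rownames(st$table$counts)))
  truth <- read.delim(file.path(dir, "truth.tsv"))
  expect_named(truth, c("otu_id", "habitat", "direction", "log2_fold_change",
                        "corr_block"))
})
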