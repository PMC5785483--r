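# Shared fixtures: everything is built in code at test time.

# tiny deterministic OTU table
tiny_table <- function() {
  counts <- matrix(c(5L, 3L, 2L,
                     0L, 7L, 1L), nrow = 3,
                   dimnames = list(c("OTU1", "OTU2", "OTU3"), c("S1", "S2")))
  otu_table(counts, c(
    OTU1 = "Firmicutes;Bacilli;Lactobacillales;Streptococcaceae;Streptococcus;Streptococcus mitis",
    OTU2 = "Firmicutes;Bacilli;Lactobacillales;Streptococcaceae;Streptococcus;Streptococcus mutans",
    OTU3 = "Bacteroidetes;Bacteroidia;Bacteroidales;Prevotellaceae;Prevotella"))
}

# random count table with named dims
random_table <- function(n_otus, n_samples, lambda = 20) {
  counts <- matrix(rpois(n_otus * n_samples, lambda), n_otus,
                   dimnames = list(sprintf("OTU%02d", seq_len(n_otus)),
                                   sprintf("S%02d", seq_len(n_samples))))
  counts[1, colSums(counts) == 0] <- 1L
  storage.mode(counts) <- "integer"
  otu_table(counts)
}

# a small two-group metadata frame over a table's samples
two_group_metadata <- function(sample_ids, habitat = "saliva") {
  n <- length(sample_ids)
  half <- n %/% 2
  data.frame(sample_id = sample_ids,
             subject_id = paste0("SUBJ", seq_len(n)),
             group = rep(c("ASD", "control"), c(half, n - half)),
             habitat = habitat, stringsAsFactors = FALSE)
}

# Brute-force UniFrac oracle: enumerates each branch's descendant leaves
# with ape::extract.clade (independent of the package's postorder pass)
# and applies the definitions directly.
oracle_unifrac <- function(tree, a, b, weighted = FALSE, normalized = TRUE) {
  n_tip <- length(tree$tip.label)
  leaves_under <- function(child) {
    if (child <= n_tip) tree$tip.label[child]
    else ape::extract.clade(tree, child)$tip.label
  }
  pa <- a / sum(a); pb <- b / sum(b)
  num <- den <- 0
  for (e in seq_len(nrow(tree$edge))) {
    l <- tree$edge.length[e]
    lv <- leaves_under(tree$edge[e, 2])
    if (weighted) {
      wa <- sum(pa[lv]); wb <- sum(pb[lv])
      num <- num + l * abs(wa - wb)
      den <- den + l * (wa + wb)
    } else {
      ia <- any(a[lv] > 0); ib <- any(b[lv] > 0)
      num <- num + l * abs(ia - ib)
      den <- den + l * max(ia, ib)
    }
  }
  if (weighted && !normalized) return(num)
  if (den == 0) 0 else num / den
}

random_counts_on_tree <- function(tree, max_count = 5) {
  setNames(sample(0:max_count, length(tree$tip.label), replace = TRUE),
           tree$tip.label)
}

# build a table with one perfectly separating OTU among noise
planted_table <- function(n_noise = 40, n_per_group = 15, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_group
  counts <- matrix(rpois(n_noise * n, 30), n_noise, n)
  sep <- c(rpois(n_per_group, 5), rpois(n_per_group, 60))  # control | ASD low/high
  counts <- rbind(counts, sep)
  rownames(counts) <- c(sprintf("N%02d", seq_len(n_noise)), "PLANTED")
  colnames(counts) <- sprintf("s%02d", seq_len(n))
  storage.mode(counts) <- "integer"
  list(table = otu_table(counts),
       labels = rep(c("control", "ASD"), each = n_per_group))
}

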