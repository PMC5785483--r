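#' Configuration for the synthetic study generator
#'
#' Defaults reproduce the shape of the two-habitat ASD case-control design
#' this package targets: 111 samples in four groups (healthy saliva HS=27,
#' healthy plaque HP=26, ASD saliva AS=32, ASD plaque AP=26), 405 OTUs,
#' and per-sample sequencing depth ~ Normal(33959, 4253) truncated at
#' 1000 reads.
#'
#' @param n_otus number of OTUs.
#' @param group_sizes named integer vector with entries HS, HP, AS, AP
#'   (healthy/ASD x saliva/plaque); zeros allowed.
#' @param depth_mean,depth_sd per-sample read depth distribution (reads).
#' @param n_diff_per_habitat number of differentially abundant (spiked)
#'   OTUs planted per habitat.
#' @param log2_fold_change effect size of spiked OTUs (base-2 log scale);
#'   ASD-enriched OTUs are multiplied, control-enriched divided, by
#'   `2^log2_fold_change` in the ASD base composition.
#' @param prop_asd_enriched fraction of spiked OTUs that are ASD-enriched
#'   (the remainder are control-enriched, i.e. depleted in ASD). Either a
#'   scalar or a named vector with entries `saliva` and `plaque`; the
#'   default makes plaque depletion-dominant, matching the all-control
#'   plaque marker panel of this study design.
#' @param base_abundance_sigma log-normal spread (SD of natural log) of
#'   baseline OTU mean abundances.
#' @param dirichlet_concentration Dirichlet-multinomial concentration;
#'   smaller = more between-sample overdispersion.
#' @param clinical_corr target correlation between the ABC severity score
#'   and a subject's summed ASD-enriched marker abundance.
#' @param corr_block_size number of control-enriched spiked OTUs per
#'   habitat coupled through a shared per-sample latent factor in control
#'   samples (emulates a commensal co-occurrence guild); 0 disables.
#' @param corr_block_sigma SD of the latent factor (natural-log scale).
#' @param seed integer seed; identical seed gives bit-identical output.
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(n_otus = 405L,
                         group_sizes = c(HS = 27L, HP = 26L, AS = 32L, AP = 26L),
                         depth_mean = 33959,
                         depth_sd = 4253,
                         n_diff_per_habitat = 40L,
                         log2_fold_change = 2,
                         prop_asd_enriched = c(saliva = 0.35, plaque = 0.15),
                         base_abundance_sigma = 1.5,
                         dirichlet_concentration = 400,
                         clinical_corr = 0.4,
                         corr_block_size = 6L,
                         corr_block_sigma = 1.5,
                         seed = NULL) {
  cfg <- list(n_otus = as.integer(n_otus), group_sizes = group_sizes,
              depth_mean = depth_mean, depth_sd = depth_sd,
              n_diff_per_habitat = as.integer(n_diff_per_habitat),
              log2_fold_change = log2_fold_change,
              prop_asd_enriched = prop_asd_enriched,
              base_abundance_sigma = base_abundance_sigma,
              dirichlet_concentration = dirichlet_concentration,
              clinical_corr = clinical_corr,
              corr_block_size = as.integer(corr_block_size),
              corr_block_sigma = corr_block_sigma,
              seed = if (is.null(seed)) NULL else as.integer(seed))
  validate_synth_config(cfg)
}

validate_synth_config <- function(cfg) {
  if (cfg$n_otus < 2L) stopf("n_otus must be >= 2")
  gs <- cfg$group_sizes
  if (!all(c("HS", "HP", "AS", "AP") %in% names(gs)))
    stopf("group_sizes needs entries HS, HP, AS, AP")
  if (any(gs < 0) || sum(gs) < 2L) stopf("group sizes must be >= 0 and sum >= 2")
  if (cfg$depth_mean <= 0 || cfg$depth_sd < 0) stopf("depth_mean must be > 0, depth_sd >= 0")
  if (cfg$n_diff_per_habitat < 0L || cfg$n_diff_per_habitat > cfg$n_otus)
    stopf("n_diff_per_habitat must be in [0, n_otus]")
  if (any(cfg$prop_asd_enriched < 0) || any(cfg$prop_asd_enriched > 1))
    stopf("prop_asd_enriched must be in [0, 1]")
  if (length(cfg$prop_asd_enriched) > 1L &&
      !all(HABITATS %in% names(cfg$prop_asd_enriched)))
    stopf("per-habitat prop_asd_enriched needs entries saliva and plaque")
  if (cfg$base_abundance_sigma < 0) stopf("base_abundance_sigma must be >= 0")
  if (cfg$dirichlet_concentration <= 0) stopf("dirichlet_concentration must be > 0")
  if (abs(cfg$clinical_corr) > 1) stopf("clinical_corr must be in [-1, 1]")
  if (cfg$corr_block_size < 0L) stopf("corr_block_size must be >= 0")
  structure(cfg, class = "synth_config")
}

# Plausible oral genera used to decorate synthetic lineages. Spiked
# ASD-enriched OTUs are drawn to pathogen-like genera, control-enriched to
# commensal-like genera, so genus-level screens see the planted pattern.
.ORAL_TAXA <- list(
  asd_like = list(c("Proteobacteria", "Gammaproteobacteria", "Pasteurellales",
                    "Pasteurellaceae", "Haemophilus"),
                  c("Firmicutes", "Bacilli", "Lactobacillales",
                    "Streptococcaceae", "Streptococcus"),
                  c("Actinobacteria", "Actinobacteria", "Micrococcales",
                    "Micrococcaceae", "Rothia")),
  control_like = list(c("Bacteroidetes", "Bacteroidia", "Bacteroidales",
                        "Prevotellaceae", "Prevotella"),
                      c("Bacteroidetes", "Bacteroidia", "Bacteroidales",
                        "Prevotellaceae", "Alloprevotella"),
                      c("Fusobacteria", "Fusobacteriia", "Fusobacteriales",
                        "Fusobacteriaceae", "Fusobacterium"),
                      c("Actinobacteria", "Actinobacteria", "Actinomycetales",
                        "Actinomycetaceae", "Actinomyces"),
                      c("Firmicutes", "Negativicutes", "Selenomonadales",
                        "Selenomonadaceae", "Selenomonas"),
                      c("Bacteroidetes", "Bacteroidia", "Bacteroidales",
                        "Porphyromonadaceae", "Porphyromonas")),
  background = list(c("Firmicutes", "Negativicutes", "Veillonellales",
                      "Veillonellaceae", "Veillonella"),
                    c("Proteobacteria", "Betaproteobacteria", "Neisseriales",
                      "Neisseriaceae", "Neisseria"),
                    c("Bacteroidetes", "Flavobacteriia", "Flavobacteriales",
                      "Flavobacteriaceae", "Capnocytophaga"),
                    c("Fusobacteria", "Fusobacteriia", "Fusobacteriales",
                      "Leptotrichiaceae", "Leptotrichia"),
                    c("Firmicutes", "Bacilli", "Lactobacillales",
                      "Carnobacteriaceae", "Granulicatella"),
                    c("Firmicutes", "Bacilli", "Bacillales",
                      "Gemellaceae", "Gemella"),
                    c("Actinobacteria", "Coriobacteriia", "Coriobacteriales",
                      "Coriobacteriaceae", "Atopobium"),
                    c("Proteobacteria", "Epsilonproteobacteria",
                      "Campylobacterales", "Campylobacteraceae", "Campylobacter")))

make_lineage <- function(base, otu_id) {
  paste(c(base, paste0(base[5L], " sp. ", otu_id)), collapse = ";")
}

# Draw one Dirichlet vector with parameter alpha (unnormalised is fine).
rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

# Spiked-OTU selection with a feasibility guard. Down-spiked candidates
# (depleted commensals) come from the third abundance quartile:
# significantly depleted commensals are by necessity moderately abundant,
# well-detected taxa (an OTU already at the detection limit cannot lose a
# measurable 2^lfc), while depleting dominants would raise evenness, the
# opposite of the depletion phenotype this generator emulates. Up-spiked candidates
# (pathogen blooms) extend into the abundant tail (any abundance above the rarest quartile,
# including dominants) because the blooming taxa of this study design
# (Streptococcus, Haemophilus) are dominant community members whose
# expansion concentrates dominance and lowers diversity/evenness.
# Up-spikes are admitted sequentially only while their post-spike mass
# stays below 0.5, so the mass-preserving rescale of the unspiked block
# always has a positive factor.
pick_spikes <- function(base, n_diff, prop_up, lfc) {
  n <- length(base)
  if (n_diff == 0L) return(list(up = integer(0), down = integer(0)))
  cand_up <- which(base >= stats::quantile(base, 0.25))
  cand_down <- which(base >= stats::quantile(base, 0.50) &
                       base <= stats::quantile(base, 0.75))
  if (length(cand_down) < n_diff) {
    cand_down <- which(base <= stats::quantile(base, 0.75))
    cand_up <- union(cand_up, cand_down)
  }
  if (length(cand_down) < n_diff)
    cand_up <- cand_down <- order(base)[seq_len(min(n, n_diff))]
  n_up <- round(prop_up * n_diff)
  n_down <- n_diff - n_up
  # one dominant-pathogen bloom per habitat: the largest taxon whose
  # expansion stays feasible, concentrating dominance in the ASD group
  # (the Streptococcus-like signature of this study design)
  up <- integer(0); mass <- 0
  if (n_up >= 1L) {
    bloom_cand <- which(base * 2^lfc < 0.4)
    if (length(bloom_cand)) {
      up <- bloom_cand[which.max(base[bloom_cand])]
      mass <- base[up] * 2^lfc
    }
  }
  ord <- setdiff(sample(cand_up), up)
  i <- 1L
  while (length(up) < n_up && i <= length(ord)) {
    m <- base[ord[i]] * 2^lfc
    if (mass + m < 0.5) { up <- c(up, ord[i]); mass <- mass + m }
    i <- i + 1L
  }
  if (length(up) < n_up) {
    # random greedy failed; deterministic fallback takes the smallest
    # shares, which is feasible whenever any choice is
    small <- cand_up[order(base[cand_up])]
    up <- utils::head(small, n_up)
    if (sum(base[up]) * 2^lfc >= 0.5)
      stopf("log2_fold_change=%g too large: spiked mass would exhaust the composition", lfc)
  }
  rest <- setdiff(sample(cand_down), up)
  if (length(rest) < n_down)
    stopf("not enough candidate OTUs for %d control-enriched spikes", n_down)
  down <- rest[seq_len(n_down)]
  list(up = sort(up), down = sort(down))
}

# ASD base composition: spiked masses set exactly to base*2^(+-lfc), the
# unspiked block rescaled to restore sum 1, so the group-mean
# relative-abundance ratio of a spiked OTU is exactly 2^lfc.
spike_composition <- function(base, up, down, lfc) {
  new <- base
  new[up] <- base[up] * 2^lfc
  new[down] <- base[down] / 2^lfc
  spiked <- c(up, down)
  if (!length(spiked)) return(new)
  s <- (1 - sum(new[spiked])) / (1 - sum(base[spiked]))
  if (!is.finite(s) || s <= 0)
    stopf("spiked fold-change drives unspiked base mass to <= 0 (rescale factor %.3g)", s)
  new[-spiked] <- base[-spiked] * s
  new
}

rtruncnorm_depth <- function(n, mean, sd, lower = 1000) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    d <- stats::rnorm(1, mean, sd)
    while (d < lower) d <- stats::rnorm(1, mean, sd)
    out[i] <- round(d)
  }
  out
}

#' Generate a complete synthetic study
#'
#' Draws habitat-specific base compositions (log-normal, normalised per
#' habitat so saliva and plaque communities differ more than disease
#' groups), plants `n_diff_per_habitat` differential OTUs per habitat with
#' a mass-preserving `2^log2_fold_change` spike, couples a block of
#' control-enriched OTUs through a per-sample latent factor in control
#' samples, samples counts Dirichlet-multinomially at truncated-normal
#' depths, and builds clinical metadata in which the ABC severity score
#' correlates positively with each ASD subject's spiked-marker load.
#'
#' @param config a [synth_config()].
#' @return list with `table` ([otu_table]), `metadata` (data.frame),
#'   `tree` (`ape::phylo`), and `truth` (data.frame: otu_id, habitat,
#'   direction, log2_fold_change).
#' @export
generate_study <- function(config = synth_config()) {
  config <- validate_synth_config(config)
  with_seed(config$seed, generate_study_impl(config))
}

generate_study_impl <- function(cfg) {
  n <- cfg$n_otus
  ids <- sprintf("OTU%03d", seq_len(n))

  # habitat-specific base compositions
  base <- list()
  for (h in HABITATS) {
    b <- exp(stats::rnorm(n, 0, cfg$base_abundance_sigma))
    base[[h]] <- b / sum(b)
  }

  # planted differential OTUs per habitat (only habitats with samples)
  gs0 <- cfg$group_sizes
  hab_n <- c(saliva = gs0[["HS"]] + gs0[["AS"]],
             plaque = gs0[["HP"]] + gs0[["AP"]])
  truth <- list(); asd_base <- list(); spikes <- list()
  for (h in HABITATS) {
    if (hab_n[[h]] == 0L) {
      spikes[[h]] <- list(up = integer(0), down = integer(0))
      asd_base[[h]] <- base[[h]]
      next
    }
    prop_h <- if (length(cfg$prop_asd_enriched) > 1L)
      cfg$prop_asd_enriched[[h]] else cfg$prop_asd_enriched
    sp <- pick_spikes(base[[h]], cfg$n_diff_per_habitat,
                      prop_h, cfg$log2_fold_change)
    spikes[[h]] <- sp
    asd_base[[h]] <- spike_composition(base[[h]], sp$up, sp$down,
                                       cfg$log2_fold_change)
    if (length(sp$up) + length(sp$down))
      truth[[h]] <- data.frame(
        otu_id = ids[c(sp$up, sp$down)],
        habitat = h,
        direction = rep(c("ASD-enriched", "control-enriched"),
                        c(length(sp$up), length(sp$down))),
        log2_fold_change = cfg$log2_fold_change,
        stringsAsFactors = FALSE)
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(otu_id = character(0), habitat = character(0),
               direction = character(0), log2_fold_change = numeric(0))
  rownames(truth) <- NULL

  # taxonomy: spiked OTUs get pathogen-/commensal-like genera, the rest
  # background oral genera
  lineage_pool <- function(k, pool)
    vapply(sample.int(length(pool), k, replace = TRUE),
           function(j) pool[[j]], character(5))
  tax <- character(n)
  bg <- matrix(lineage_pool(n, .ORAL_TAXA$background), nrow = 5)
  for (i in seq_len(n)) tax[i] <- make_lineage(bg[, i], ids[i])
  for (h in HABITATS) {
    up <- spikes[[h]]$up; down <- spikes[[h]]$down
    if (length(up)) {
      m <- matrix(lineage_pool(length(up), .ORAL_TAXA$asd_like), nrow = 5)
      for (k in seq_along(up)) tax[up[k]] <- make_lineage(m[, k], ids[up[k]])
    }
    if (length(down)) {
      m <- matrix(lineage_pool(length(down), .ORAL_TAXA$control_like), nrow = 5)
      for (k in seq_along(down)) tax[down[k]] <- make_lineage(m[, k], ids[down[k]])
    }
  }
  taxonomy <- stats::setNames(tax, ids)

  # sample bookkeeping
  gs <- cfg$group_sizes
  grp_of <- c(HS = "control", HP = "control", AS = "ASD", AP = "ASD")
  hab_of <- c(HS = "saliva", HP = "plaque", AS = "saliva", AP = "plaque")
  n_subj <- c(control = max(gs[["HS"]], gs[["HP"]]),
              ASD = max(gs[["AS"]], gs[["AP"]]))
  subj_prefix <- c(control = "H", ASD = "A")

  meta <- list(); cols <- list(); samp_ids <- character(0)
  # latent co-occurrence block: the corr_block_size most abundant
  # control-enriched spiked OTUs of each habitat (abundant enough for the
  # co-variation to survive counting noise), coupled in control samples
  # through a shared log-normal factor
  block <- lapply(HABITATS, function(h) {
    d <- spikes[[h]]$down
    d[order(base[[h]][d], decreasing = TRUE)][
      seq_len(min(cfg$corr_block_size, length(d)))]
  })
  names(block) <- HABITATS
  truth$corr_block <- logical(nrow(truth))
  for (h in HABITATS)
    truth$corr_block[truth$habitat == h &
                       truth$otu_id %in% ids[block[[h]]]] <- TRUE

  conc <- cfg$dirichlet_concentration
  for (code in c("HS", "HP", "AS", "AP")) {
    ng <- gs[[code]]
    if (ng == 0L) next
    g <- grp_of[[code]]; h <- hab_of[[code]]
    comp <- if (g == "ASD") asd_base[[h]] else base[[h]]
    depths <- rtruncnorm_depth(ng, cfg$depth_mean, cfg$depth_sd)
    for (i in seq_len(ng)) {
      p <- rdirichlet1(conc * comp)
      blk <- block[[h]]
      if (g == "control" && length(blk) && cfg$corr_block_sigma > 0) {
        # latent-factor abundances for the block: shared factor f plus
        # small idiosyncratic noise, both mean-one so expected abundance
        # (hence enrichment direction) is preserved
        sz <- cfg$corr_block_sigma
        f <- exp(stats::rnorm(1, 0, sz) - sz^2 / 2)
        e <- exp(stats::rnorm(length(blk), 0, 0.5) - 0.125)
        pb <- comp[blk] * f * e
        if (sum(pb) > 0.5) pb <- pb * 0.5 / sum(pb)
        p[blk] <- 0
        p <- p / sum(p) * (1 - sum(pb))
        p[blk] <- pb
      }
      cnt <- stats::rmultinom(1, depths[i], p)[, 1L]
      sid <- sprintf("%s%02d", code, i)
      samp_ids <- c(samp_ids, sid)
      cols[[sid]] <- cnt
      meta[[sid]] <- data.frame(
        sample_id = sid,
        subject_id = sprintf("%s%02d", subj_prefix[[g]], i),
        group = g, habitat = h, stringsAsFactors = FALSE)
    }
  }
  counts <- do.call(cbind, cols)
  rownames(counts) <- ids
  storage.mode(counts) <- "integer"
  metadata <- do.call(rbind, meta)
  rownames(metadata) <- NULL

  metadata <- add_clinical(metadata, counts, truth, cfg)
  tree <- generate_tree(ids, seed = NULL)  # inside the seeded stream

  list(table = otu_table(counts, taxonomy), metadata = metadata,
       tree = tree, truth = truth)
}

# Clinical covariates per subject (shared across that subject's samples),
# drawn around published case-control demographics for this design; the
# ABC severity score is a linear function of realised ASD-marker load plus
# Gaussian noise, rescaled to mean 78.66, SD 26.46, ASD subjects only.
add_clinical <- function(metadata, counts, truth, cfg) {
  subjects <- unique(metadata[, c("subject_id", "group")])
  ns <- nrow(subjects)
  par <- list( # mean/sd pairs: ASD, control
    age  = list(ASD = c(10.02, 1.43), control = c(10.19, 0.59)),
    bmi  = list(ASD = c(19.59, 3.60), control = c(19.92, 4.53)),
    dmft = list(ASD = c(2.03, 1.79),  control = c(1.04, 1.86)),
    dmfs = list(ASD = c(3.91, 3.83),  control = c(1.96, 3.86)),
    pli  = list(ASD = c(1.88, 0.43),  control = c(1.88, 0.34)),
    gi   = list(ASD = c(0.90, 0.44),  control = c(0.25, 0.47)),
    bi   = list(ASD = c(1.02, 0.72),  control = c(0.25, 0.47)),
    bop  = list(ASD = c(0.69, 0.56),  control = c(0.31, 0.45)),
    pd   = list(ASD = c(1.92, 0.37),  control = c(1.81, 0.47)))
  p_female <- c(ASD = 5 / 32, control = 6 / 27)
  draws <- list()
  for (v in names(par)) {
    x <- numeric(ns)
    for (i in seq_len(ns)) {
      ms <- par[[v]][[subjects$group[i]]]
      x[i] <- max(0, stats::rnorm(1, ms[1], ms[2]))
    }
    draws[[v]] <- round(x, 2)
  }
  sex <- ifelse(stats::runif(ns) < p_female[subjects$group], "F", "M")

  # marker load: summed relative abundance of ASD-enriched spiked OTUs in
  # the subject's saliva sample (plaque fallback)
  rel <- sweep(counts, 2, colSums(counts), "/")
  load <- rep(NA_real_, ns)
  for (i in seq_len(ns)) {
    rows <- metadata[metadata$subject_id == subjects$subject_id[i], ]
    rows <- rows[order(match(rows$habitat, HABITATS)), ]
    sid <- rows$sample_id[1L]
    hab <- rows$habitat[1L]
    mk <- truth$otu_id[truth$habitat == hab & truth$direction == "ASD-enriched"]
    load[i] <- if (length(mk)) sum(rel[mk, sid]) else 0
  }
  abc <- rep(NA_real_, ns)
  is_asd <- subjects$group == "ASD"
  if (any(is_asd)) {
    z <- load[is_asd]
    z <- if (stats::sd(z) > 0) (z - mean(z)) / stats::sd(z) else z * 0
    r <- cfg$clinical_corr
    raw <- r * z + sqrt(max(0, 1 - r^2)) * stats::rnorm(sum(is_asd))
    abc[is_asd] <- pmax(0, round(78.66 + 26.46 * raw, 1))
  }
  subj <- data.frame(subject_id = subjects$subject_id, age = draws$age,
                     sex = sex, bmi = draws$bmi, abc_score = abc,
                     dmft = round(draws$dmft), dmfs = round(draws$dmfs),
                     pli = draws$pli, gi = draws$gi, bi = draws$bi,
                     bop = draws$bop, pd = draws$pd,
                     stringsAsFactors = FALSE)
  out <- merge(metadata, subj, by = "subject_id", sort = FALSE)
  out <- out[order(match(out$sample_id, metadata$sample_id)),
             c("sample_id", "subject_id", "group", "habitat", "age", "sex",
               "bmi", "abc_score", "dmft", "dmfs", "pli", "gi", "bi",
               "bop", "pd")]
  rownames(out) <- NULL
  out
}

#' Generate a random rooted bifurcating tree over OTU ids
#'
#' Sequential random joins with i.i.d. exponential(1) branch lengths;
#' leaves are exactly the given ids. Seed-deterministic.
#'
#' @param otu_ids character vector of >= 2 unique leaf ids.
#' @param seed integer seed or NULL (use current RNG stream).
#' @return An `ape::phylo` rooted binary tree.
#' @export
generate_tree <- function(otu_ids, seed = NULL) {
  if (length(otu_ids) < 2L) stopf("need >= 2 OTU ids")
  if (anyDuplicated(otu_ids)) stopf("duplicate OTU ids")
  with_seed(seed, {
    nodes <- otu_ids
    while (length(nodes) > 1L) {
      pick <- sample.int(length(nodes), 2L)
      bl <- stats::rexp(2L)
      joined <- sprintf("(%s:%.10f,%s:%.10f)",
                        nodes[pick[1L]], bl[1L], nodes[pick[2L]], bl[2L])
      nodes <- c(nodes[-pick], joined)
    }
    tree <- ape::read.tree(text = paste0(nodes, ";"))
    validate_tree(tree)
  })
}

#' Write all synthetic-study artifacts to a directory
#'
#' @param study result of [generate_study()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_otu_table(study$table, file.path(dir, "otu_table.tsv"))
  write_metadata(study$metadata, file.path(dir, "metadata.tsv"))
  write_newick(study$tree, file.path(dir, "tree.nwk"))
  utils::write.table(study$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
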