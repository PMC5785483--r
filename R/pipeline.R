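#' Pipeline run configuration
#'
#' One flat configuration object for the full study replay
#' (simulate -> alpha -> beta -> diff -> network -> markers -> mia).
#' Inputs may be read from files (`table_path`, `metadata_path`,
#' `tree_path`) or generated by the synthetic module when the paths are
#' NULL. The cross-validation defaults here (3 trials, 200 trees) are
#' deliberately lighter than the per-function defaults so a full
#' 405 x 111 replay stays within a small CPU budget; raise them for
#' publication-grade curves.
#'
#' @param out_dir run directory (created; stage outputs and the manifest
#'   are written beneath it).
#' @param seed mandatory integer seed for every stochastic stage.
#' @param table_path,metadata_path,tree_path optional input files; all
#'   NULL means simulate with `synth`.
#' @param synth a [synth_config()] used when simulating.
#' @param rarefaction_depth reads; NULL = minimum per-sample total.
#' @param beta_rank rank for beta diversity ("genus" default; UniFrac at
#'   an aggregated rank uses an exemplar-pruned tree).
#' @param beta_metric "w-unifrac" or "uw-unifrac".
#' @param permutations PERMANOVA permutations.
#' @param diff_ranks ranks screened for differential abundance.
#' @param p_cut,q_cut significance thresholds.
#' @param rho_threshold co-occurrence |rho| threshold.
#' @param n_top,folds,trials,n_trees marker-selection parameters.
#' @param mia_scale "counts" or "relative"; `mia_mode` "grid" or
#'   "powerset".
#' @param mia_mode see above.
#' @return validated list of class `run_config`.
#' @export
run_config <- function(out_dir, seed,
                       table_path = NULL, metadata_path = NULL,
                       tree_path = NULL, synth = synth_config(),
                       rarefaction_depth = NULL,
                       beta_rank = "genus", beta_metric = "w-unifrac",
                       permutations = 999,
                       diff_ranks = c("phylum", "genus", "otu"),
                       p_cut = 0.05, q_cut = 0.05, rho_threshold = 0.5,
                       n_top = 60, folds = 10, trials = 3, n_trees = 200,
                       mia_scale = "counts", mia_mode = "grid") {
  if (missing(seed) || is.null(seed)) stopf("seed is mandatory")
  stopifnot(p_cut > 0, p_cut <= 1, q_cut > 0, q_cut <= 1,
            rho_threshold >= 0, rho_threshold <= 1,
            n_top >= 1, folds >= 2, trials >= 1, permutations >= 1)
  mia_scale <- match.arg(mia_scale, c("counts", "relative"))
  mia_mode <- match.arg(mia_mode, c("grid", "powerset"))
  beta_metric <- match.arg(beta_metric, c("w-unifrac", "uw-unifrac"))
  beta_rank <- match.arg(beta_rank, c(RANKS, "otu"))
  diff_ranks <- vapply(diff_ranks, match.arg, character(1),
                       choices = c(RANKS, "otu"))
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 table_path = table_path, metadata_path = metadata_path,
                 tree_path = tree_path, synth = synth,
                 rarefaction_depth = rarefaction_depth,
                 beta_rank = beta_rank, beta_metric = beta_metric,
                 permutations = permutations, diff_ranks = unname(diff_ranks),
                 p_cut = p_cut, q_cut = q_cut,
                 rho_threshold = rho_threshold, n_top = n_top,
                 folds = folds, trials = trials, n_trees = n_trees,
                 mia_scale = mia_scale, mia_mode = mia_mode),
            class = "run_config")
}

#' Exemplar tree at an aggregated rank
#'
#' UniFrac at a rank coarser than OTU needs a tree whose leaves are the
#' aggregated taxa. Each taxon is represented by its highest-count
#' member OTU; the OTU tree is pruned to the exemplars and relabelled.
#'
#' @param table OTU-level [otu_table].
#' @param tree OTU-level rooted tree.
#' @param rank aggregation rank ("otu" returns the tree unchanged).
#' @return `ape::phylo` with aggregated taxon labels.
#' @export
exemplar_tree <- function(table, tree, rank) {
  if (rank == "otu") return(tree)
  k <- match(rank, RANKS)
  lineage <- table$taxonomy[rownames(table$counts)]
  key <- vapply(lineage, function(lin) {
    if (is.na(lin) || !nzchar(lin)) return("unclassified")
    parts <- strsplit(lin, ";", fixed = TRUE)[[1L]]
    if (length(parts) < k || !nzchar(trimws(parts[k]))) return("unclassified")
    paste(trimws(parts[seq_len(k)]), collapse = ";")
  }, character(1), USE.NAMES = FALSE)
  totals <- rowSums(table$counts)
  exemplar <- vapply(split(seq_along(key), key), function(rows)
    rownames(table$counts)[rows[which.max(totals[rows])]], character(1))
  pruned <- ape::keep.tip(tree, unname(exemplar))
  pruned$tip.label <- names(exemplar)[match(pruned$tip.label, exemplar)]
  pruned
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  path
}

#' Run the full pipeline
#'
#' Executes all seven stages, writes every output under
#' `config$out_dir`, and records a machine-readable manifest
#' (stage, parameters, output files with MD5 hashes). Re-running with an
#' identical config reproduces identical hashes. Any stage failure
#' aborts with the stage name.
#'
#' @param config a [run_config()].
#' @return the manifest data.frame, invisibly; also written as
#'   `manifest.tsv`.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  note <- function(stage, params, files) {
    manifest[[stage]] <<- if (length(files)) data.frame(
      stage = stage, parameters = params,
      file = basename(files), md5 = unname(tools::md5sum(files)),
      stringsAsFactors = FALSE)
    else data.frame(stage = stage, parameters = params,
                    file = NA_character_, md5 = NA_character_,
                    stringsAsFactors = FALSE)
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stopf("stage '%s' failed: %s", stage, conditionMessage(e)))
  }
  out <- function(...) file.path(config$out_dir, ...)

  # -- stage 1: simulate (or load) ------------------------------------
  study <- run_stage("simulate", {
    if (is.null(config$table_path)) {
      cfg <- config$synth
      cfg$seed <- derive_seed(config$seed, "simulate")
      st <- generate_study(validate_synth_config(cfg))
      write_study(st, config$out_dir)
      st
    } else {
      st <- list(table = read_otu_table(config$table_path),
                 metadata = read_metadata(config$metadata_path),
                 tree = read_newick(config$tree_path), truth = NULL)
      file.copy(c(config$table_path, config$metadata_path, config$tree_path),
                config$out_dir, overwrite = TRUE)
      st
    }
  })
  tab <- study$table; md <- study$metadata; tree <- study$tree
  missing <- setdiff(colnames(tab$counts), md$sample_id)
  if (length(missing))
    stopf("stage 'simulate' failed: table sample(s) missing from metadata: %s",
          paste(missing, collapse = ", "))
  log_stage("simulate", otus = nrow(tab$counts), samples = ncol(tab$counts))
  input_files <- if (is.null(config$table_path))
    out(c("otu_table.tsv", "metadata.tsv", "tree.nwk", "truth.tsv"))
  else out(basename(c(config$table_path, config$metadata_path,
                      config$tree_path)))
  note("simulate", sprintf("seed=%d", config$seed), input_files)

  # -- stage 2: alpha -------------------------------------------------
  run_stage("alpha", {
    al <- alpha_diversity(tab, depth = config$rarefaction_depth,
                          seed = derive_seed(config$seed, "alpha"))
    write_tsv(al, out("alpha_diversity.tsv"))
    write_tsv(compare_alpha_groups(al, md), out("alpha_comparison.tsv"))
    log_stage("alpha", samples = nrow(al), depth = al$rarefaction_depth[1])
    note("alpha", sprintf("depth=%d", al$rarefaction_depth[1]),
         out(c("alpha_diversity.tsv", "alpha_comparison.tsv")))
  })

  # -- stage 3: beta --------------------------------------------------
  run_stage("beta", {
    btab <- aggregate_taxa(tab, config$beta_rank)
    btree <- exemplar_tree(tab, tree, config$beta_rank)
    dm <- distance_matrix(btab, btree, config$beta_metric)
    write_distance_matrix(dm, out("distance_matrix.tsv"))
    pc <- pcoa(dm)
    coords <- data.frame(sample_id = pc$sample_ids,
                         pc$coordinates[, seq_len(min(4, ncol(pc$coordinates))),
                                        drop = FALSE])
    write_tsv(coords, out("pcoa_coordinates.tsv"))
    contrasts <- list(
      habitat = list(ids = md$sample_id, labels = md$habitat),
      disease_saliva = list(ids = md$sample_id[md$habitat == "saliva"],
                            labels = md$group[md$habitat == "saliva"]),
      disease_plaque = list(ids = md$sample_id[md$habitat == "plaque"],
                            labels = md$group[md$habitat == "plaque"]))
    rows <- lapply(names(contrasts), function(nm) {
      ct <- contrasts[[nm]]
      if (length(unique(ct$labels)) < 2L) return(NULL)
      pr <- permanova(dm[ct$ids, ct$ids], ct$labels,
                      n_permutations = config$permutations,
                      seed = derive_seed(config$seed, paste0("perm_", nm)))
      data.frame(contrast = nm, pseudo_F = pr$pseudo_F, p_value = pr$p_value,
                 n_permutations = pr$n_permutations, stringsAsFactors = FALSE)
    })
    write_tsv(do.call(rbind, rows), out("permanova.tsv"))
    log_stage("beta", rank = config$beta_rank, metric = config$beta_metric)
    note("beta", sprintf("rank=%s metric=%s perms=%d", config$beta_rank,
                         config$beta_metric, config$permutations),
         out(c("distance_matrix.tsv", "pcoa_coordinates.tsv", "permanova.tsv")))
  })

  # -- stage 4: differential abundance --------------------------------
  diff_otu <- list()
  run_stage("diff", {
    all_rows <- list()
    for (h in intersect(HABITATS, unique(md$habitat))) {
      for (r in config$diff_ranks) {
        dr <- differential_screen(tab, md, rank = r, habitat = h,
                                  p_cut = config$p_cut, q_cut = config$q_cut)
        all_rows[[paste(h, r)]] <- dr
        if (r == "otu") diff_otu[[h]] <- dr
      }
    }
    write_tsv(do.call(rbind, all_rows), out("differential_abundance.tsv"))
    n_sig <- sum(do.call(rbind, all_rows)$significant)
    log_stage("diff", families = length(all_rows), significant = n_sig)
    note("diff", sprintf("ranks=%s p<%g q<%g",
                         paste(config$diff_ranks, collapse = "+"),
                         config$p_cut, config$q_cut),
         out("differential_abundance.tsv"))
  })

  # -- stage 5: co-occurrence networks --------------------------------
  run_stage("network", {
    files <- character(0); stats_rows <- list()
    for (h in names(diff_otu)) {
      sig <- diff_otu[[h]][diff_otu[[h]]$significant, ]
      if (nrow(sig) < 2L) {
        log_stage("network", habitat = h, skipped = "fewer than 2 significant OTUs")
        next
      }
      dirs <- stats::setNames(sig$direction, sig$taxon_id)
      for (g in GROUPS) {
        net <- build_network(tab, sig$taxon_id, metadata = md, group = g,
                             habitat = h, threshold = config$rho_threshold,
                             directions = dirs)
        stem <- sprintf("network_%s_%s", g, h)
        write_edge_list(net, out(paste0(stem, ".tsv")))
        write_graphml(net, out(paste0(stem, ".graphml")))
        ns <- network_stats(net)
        stats_rows[[stem]] <- data.frame(
          group = g, habitat = h, n_nodes = ns$n_nodes, n_edges = ns$n_edges,
          n_positive = ns$n_positive, n_negative = ns$n_negative,
          n_components = ns$n_components, stringsAsFactors = FALSE)
        files <- c(files, out(paste0(stem, c(".tsv", ".graphml"))))
      }
    }
    if (length(stats_rows)) {
      write_tsv(do.call(rbind, stats_rows), out("network_stats.tsv"))
      files <- c(files, out("network_stats.tsv"))
    }
    log_stage("network", networks = length(stats_rows))
    note("network", sprintf("threshold=%g", config$rho_threshold),
         if (length(files)) files else character(0))
  })

  # -- stages 6-7: markers and MIA ------------------------------------
  rankings <- list()
  run_stage("markers", {
    files <- character(0)
    for (h in intersect(HABITATS, unique(md$habitat))) {
      sel <- md[md$habitat == h, ]
      if (length(unique(sel$group)) < 2L) next
      htab <- subset_table(tab, samples = sel$sample_id)
      rk <- rf_rank(htab, sel$group, n_top = config$n_top,
                    n_trees = max(config$n_trees, 500),
                    diff = diff_otu[[h]],
                    seed = derive_seed(config$seed, paste0("rf_", h)))
      cv <- cv_error_curve(htab, sel$group, rk, folds = config$folds,
                           trials = config$trials, n_trees = config$n_trees,
                           seed = derive_seed(config$seed, paste0("cv_", h)))
      rankings[[h]] <- rk
      write_tsv(rk, out(sprintf("marker_ranking_%s.tsv", h)))
      write_tsv(data.frame(k = cv$k, error = cv$error),
                out(sprintf("cv_curve_%s.tsv", h)))
      log_stage("markers", habitat = h, selected_k = cv$selected_k,
                selected_error = round(cv$selected_error, 4))
      files <- c(files, out(sprintf(c("marker_ranking_%s.tsv",
                                      "cv_curve_%s.tsv"), h)))
    }
    note("markers", sprintf("n_top=%d folds=%d trials=%d trees=%d",
                            config$n_top, config$folds, config$trials,
                            config$n_trees), files)
  })

  run_stage("mia", {
    files <- character(0)
    for (h in names(rankings)) {
      sel <- md[md$habitat == h, ]
      htab <- subset_table(tab, samples = sel$sample_id)
      ps <- enumerate_panels(rankings[[h]], htab, sel$group,
                             mode = config$mia_mode, scale = config$mia_scale)
      write_tsv(ps$panels, out(sprintf("mia_panels_%s.tsv", h)))
      best <- data.frame(
        habitat = h, label = ps$best$label, m = ps$best$m, n = ps$best$n,
        auc = ps$best$auc, cutoff = ps$best$cutoff,
        sensitivity = ps$best$sensitivity, specificity = ps$best$specificity,
        asd_otus = paste(ps$best$panel$asd_otus, collapse = ","),
        control_otus = paste(ps$best$panel$control_otus, collapse = ","),
        stringsAsFactors = FALSE)
      write_tsv(best, out(sprintf("mia_best_%s.tsv", h)))
      preds <- data.frame(sample_id = names(ps$best$scores),
                          mia = unname(ps$best$scores),
                          predicted = classify_mia(ps$best$scores,
                                                   ps$best$cutoff),
                          stringsAsFactors = FALSE)
      write_tsv(preds, out(sprintf("mia_predictions_%s.tsv", h)))
      log_stage("mia", habitat = h, best = ps$best$label,
                auc = round(ps$best$auc, 4))
      files <- c(files, out(sprintf(c("mia_panels_%s.tsv", "mia_best_%s.tsv",
                                      "mia_predictions_%s.tsv"), h)))
    }
    note("mia", sprintf("mode=%s scale=%s", config$mia_mode,
                        config$mia_scale), files)
  })

  manifest <- do.call(rbind, manifest)
  rownames(manifest) <- NULL
  write_tsv(manifest, file.path(config$out_dir, "manifest.tsv"))
  invisible(manifest)
}
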