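#' Build a co-occurrence network from significant OTUs
#'
#' Pairwise Spearman correlation of relative abundances over the selected
#' samples; undirected edges kept iff |rho| strictly exceeds `threshold`.
#' Zero-variance OTUs are excluded from edge computation but retained as
#' isolated nodes (with a message). Node attributes carry mean relative
#' abundance, genus label and enrichment direction, matching what a
#' Cytoscape rendering needs.
#'
#' @param table an [otu_table] (OTU level).
#' @param significant_otus character vector of >= 2 OTU ids (typically
#'   the significant set from [differential_screen()]).
#' @param metadata optional sample metadata; with `group`/`habitat` set,
#'   the correlation uses only that group's samples in that habitat.
#' @param group,habitat optional sample filters.
#' @param threshold absolute-correlation threshold (default 0.5, strict).
#' @param directions optional named character vector otu_id -> direction.
#' @return list of class `cooc_network` with `nodes` and `edges`
#'   data.frames.
#' @export
build_network <- function(table, significant_otus, metadata = NULL,
                          group = NULL, habitat = NULL, threshold = 0.5,
                          directions = NULL) {
  if (length(significant_otus) < 2L) stopf("need >= 2 significant OTUs")
  samples <- colnames(table$counts)
  if (!is.null(metadata)) {
    md <- metadata
    if (!is.null(group)) md <- md[md$group == match.arg(group, GROUPS), ]
    if (!is.null(habitat)) md <- md[md$habitat == match.arg(habitat, HABITATS), ]
    samples <- intersect(samples, md$sample_id)
  }
  if (length(samples) < 4L) stopf("need >= 4 samples for co-occurrence")
  significant_otus <- unique(significant_otus)
  # relative abundance w.r.t. the whole community, then restrict rows
  rel <- relative_abundance(subset_table(table, samples = samples))
  unknown <- setdiff(significant_otus, rownames(rel))
  if (length(unknown))
    stopf("unknown OTU id(s): %s", paste(unknown, collapse = ", "))
  rel <- rel[significant_otus, , drop = FALSE]
  sds <- apply(rel, 1, stats::sd)
  flat <- names(sds)[sds == 0]
  if (length(flat))
    message(sprintf("build_network: %d zero-variance OTU(s) kept as isolated nodes: %s",
                    length(flat), paste(utils::head(flat, 5), collapse = ", ")))
  active <- setdiff(rownames(rel), flat)
  edges <- data.frame(source = character(0), target = character(0),
                      rho = numeric(0), sign = character(0),
                      stringsAsFactors = FALSE)
  if (length(active) >= 2L) {
    cm <- suppressWarnings(stats::cor(t(rel[active, , drop = FALSE]),
                                      method = "spearman"))
    idx <- which(upper.tri(cm) & abs(cm) > threshold, arr.ind = TRUE)
    if (nrow(idx)) {
      edges <- data.frame(
        source = rownames(cm)[idx[, 1L]],
        target = colnames(cm)[idx[, 2L]],
        rho = cm[idx],
        sign = ifelse(cm[idx] > 0, "positive", "negative"),
        stringsAsFactors = FALSE)
    }
  }
  genus <- vapply(rownames(rel), function(id) {
    lin <- table$taxonomy[id]
    if (is.na(lin) || !nzchar(lin)) return("unclassified")
    parts <- strsplit(lin, ";", fixed = TRUE)[[1L]]
    if (length(parts) >= 5L && nzchar(parts[5L])) trimws(parts[5L]) else "unclassified"
  }, character(1))
  nodes <- data.frame(
    otu_id = rownames(rel),
    mean_rel_abund = rowMeans(rel),
    genus = genus,
    direction = if (is.null(directions)) NA_character_ else
      unname(directions[rownames(rel)]),
    stringsAsFactors = FALSE)
  rownames(nodes) <- NULL
  structure(list(nodes = nodes, edges = edges, threshold = threshold),
            class = "cooc_network")
}

#' @export
print.cooc_network <- function(x, ...) {
  cat(sprintf("cooc_network: %d nodes, %d edges (|rho| > %g)\n",
              nrow(x$nodes), nrow(x$edges), x$threshold))
  invisible(x)
}

#' Summary statistics of a co-occurrence network
#'
#' @param net a `cooc_network`.
#' @return list: `n_nodes`, `n_edges`, `n_positive`, `n_negative`,
#'   `degree` (named vector), `n_components`, `component_sizes`.
#' @export
network_stats <- function(net) {
  ids <- net$nodes$otu_id
  deg <- stats::setNames(integer(length(ids)), ids)
  for (k in seq_len(nrow(net$edges))) {
    deg[net$edges$source[k]] <- deg[net$edges$source[k]] + 1L
    deg[net$edges$target[k]] <- deg[net$edges$target[k]] + 1L
  }
  g <- igraph::graph_from_data_frame(
    net$edges[, c("source", "target")], directed = FALSE,
    vertices = data.frame(name = ids))
  comp <- igraph::components(g)
  list(n_nodes = length(ids), n_edges = nrow(net$edges),
       n_positive = sum(net$edges$sign == "positive"),
       n_negative = sum(net$edges$sign == "negative"),
       degree = deg, n_components = comp$no,
       component_sizes = sort(as.integer(comp$csize), decreasing = TRUE))
}
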