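#' OTU count table with taxonomy
#'
#' The universal input of the pipeline: a non-negative integer count matrix
#' (OTUs in rows, samples in columns) plus an optional semicolon-separated
#' taxonomic lineage (phylum;class;order;family;genus;species, trailing
#' ranks may be absent) per OTU.
#'
#' @param counts integer matrix, OTUs x samples, with unique rownames
#'   (OTU ids) and colnames (sample ids).
#' @param taxonomy named character vector of lineages; names must be a
#'   subset of the OTU ids. May be NULL.
#' @return An object of class `otu_table`: a list with elements `counts`
#'   (integer matrix) and `taxonomy` (named character vector, possibly
#'   empty).
#' @export
otu_table <- function(counts, taxonomy = NULL) {
  if (!is.matrix(counts)) stopf("counts must be a matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stopf("counts must have OTU rownames and sample colnames")
  if (anyDuplicated(rownames(counts))) stopf("duplicate OTU ids")
  if (anyDuplicated(colnames(counts))) stopf("duplicate sample ids")
  if (any(is.na(counts))) stopf("NA counts are not allowed")
  if (any(counts < 0)) stopf("negative counts are not allowed")
  if (any(counts != round(counts))) stopf("counts must be integers")
  storage.mode(counts) <- "integer"
  if (any(colSums(counts) == 0))
    stopf("sample(s) with all-zero counts: %s",
          paste(colnames(counts)[colSums(counts) == 0], collapse = ", "))
  taxonomy <- taxonomy %||% character(0)
  if (length(taxonomy) && !all(names(taxonomy) %in% rownames(counts)))
    stopf("taxonomy keys must be a subset of OTU ids")
  structure(list(counts = counts, taxonomy = taxonomy), class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("otu_table: %d OTUs x %d samples, %d with taxonomy\n",
              nrow(x$counts), ncol(x$counts), length(x$taxonomy)))
  invisible(x)
}

#' @export
dim.otu_table <- function(x) dim(x$counts)

otu_ids <- function(x) rownames(x$counts)
sample_ids <- function(x) colnames(x$counts)

#' Subset an OTU table by samples and/or OTUs
#' @param table an [otu_table].
#' @param samples,otus character vectors of ids to keep (NULL keeps all).
#' @export
subset_table <- function(table, samples = NULL, otus = NULL) {
  counts <- table$counts
  if (!is.null(otus)) {
    missing <- setdiff(otus, rownames(counts))
    if (length(missing)) stopf("unknown OTU id(s): %s", paste(missing, collapse = ", "))
    counts <- counts[otus, , drop = FALSE]
  }
  if (!is.null(samples)) {
    missing <- setdiff(samples, colnames(counts))
    if (length(missing)) stopf("unknown sample id(s): %s", paste(missing, collapse = ", "))
    counts <- counts[, samples, drop = FALSE]
  }
  tax <- table$taxonomy[names(table$taxonomy) %in% rownames(counts)]
  otu_table(counts, tax)
}

#' Read a TSV OTU table
#'
#' Classic QIIME-style dialect: header row of sample ids, first column
#' `otu_id`, optional final column `taxonomy` holding the
#' semicolon-separated lineage. Malformed input (non-integer counts,
#' negative counts, duplicate ids, ragged rows) is rejected with the
#' offending line named, never coerced.
#'
#' @param path file path.
#' @return An [otu_table].
#' @export
read_otu_table <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L) stopf("%s: need a header and at least one OTU row", path)
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  if (length(header) < 2L) stopf("%s line 1: header needs otu_id plus >=1 sample", path)
  has_tax <- identical(tolower(header[length(header)]), "taxonomy")
  samples <- header[-c(1L, if (has_tax) length(header))]
  if (anyDuplicated(samples)) stopf("%s line 1: duplicate sample ids", path)
  n_field <- length(header)
  rows <- strsplit(lines[-1L], "\t", fixed = TRUE)
  ids <- character(length(rows))
  tax <- character(length(rows))
  counts <- matrix(0L, length(rows), length(samples),
                   dimnames = list(NULL, samples))
  for (i in seq_along(rows)) {
    f <- rows[[i]]
    if (length(f) != n_field)
      stopf("%s line %d: expected %d fields, found %d", path, i + 1L, n_field, length(f))
    ids[i] <- f[[1L]]
    vals <- f[seq_along(samples) + 1L]
    num <- suppressWarnings(as.numeric(vals))
    bad <- which(is.na(num) | num != round(num) | num < 0)
    if (length(bad))
      stopf("%s line %d, sample %s: invalid count '%s'",
            path, i + 1L, samples[bad[1L]], vals[bad[1L]])
    counts[i, ] <- as.integer(num)
    if (has_tax) tax[i] <- f[[n_field]]
  }
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1L]
    stopf("%s: duplicate OTU id '%s' (line %d)", path, dup,
          which(ids == dup)[2L] + 1L)
  }
  rownames(counts) <- ids
  taxonomy <- if (has_tax) stats::setNames(tax, ids)[nzchar(tax)] else NULL
  otu_table(counts, taxonomy)
}

#' Write an OTU table as TSV
#' @param table an [otu_table].
#' @param path output file.
#' @export
write_otu_table <- function(table, path) {
  counts <- table$counts
  tax <- table$taxonomy[rownames(counts)]
  tax[is.na(tax)] <- ""
  lines <- c(
    paste(c("otu_id", colnames(counts), "taxonomy"), collapse = "\t"),
    vapply(seq_len(nrow(counts)), function(i)
      paste(c(rownames(counts)[i], counts[i, ], tax[i]), collapse = "\t"),
      character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read sample metadata
#'
#' TSV with columns `sample_id`, `subject_id`, `group` (ASD/control),
#' `habitat` (saliva/plaque), `age`, `sex`, `bmi`, `abc_score` (ASD
#' subjects only; empty = absent), and the oral-health indices `dmft`,
#' `dmfs`, `pli`, `gi`, `bi`, `bop`, `pd`. Empty clinical fields are read
#' as NA and handled pairwise-complete downstream, never imputed.
#'
#' @param path file path.
#' @return data.frame, one row per sample.
#' @export
read_metadata <- function(path) {
  md <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE, na.strings = c("", "NA"))
  validate_metadata(md)
}

validate_metadata <- function(md) {
  need <- c("sample_id", "subject_id", "group", "habitat")
  missing <- setdiff(need, names(md))
  if (length(missing)) stopf("metadata missing column(s): %s", paste(missing, collapse = ", "))
  if (anyDuplicated(md$sample_id)) stopf("metadata: duplicate sample ids")
  bad <- setdiff(unique(md$group), GROUPS)
  if (length(bad)) stopf("metadata: unknown group '%s' (allowed: %s)",
                         bad[1L], paste(GROUPS, collapse = ", "))
  bad <- setdiff(unique(md$habitat), HABITATS)
  if (length(bad)) stopf("metadata: unknown habitat '%s' (allowed: %s)",
                         bad[1L], paste(HABITATS, collapse = ", "))
  clin <- intersect(c("age", "bmi", "abc_score", "dmft", "dmfs", "pli",
                      "gi", "bi", "bop", "pd"), names(md))
  for (v in clin) {
    md[[v]] <- as.numeric(md[[v]])
    if (any(md[[v]] < 0, na.rm = TRUE)) stopf("metadata: negative %s", v)
  }
  md
}

#' Write sample metadata as TSV
#' @param metadata data.frame as returned by [read_metadata()].
#' @param path output file.
#' @export
write_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read / write a rooted Newick tree
#'
#' Thin validated wrappers around ape's Newick parser. The tree must be
#' rooted, leaf labels unique, branch lengths (when present) non-negative;
#' unlabelled internal nodes and zero-length branches are allowed.
#'
#' @param path file path.
#' @return An `ape::phylo` tree.
#' @export
read_newick <- function(path) {
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stopf("%s: Newick parse error: %s",
                                             path, conditionMessage(e)))
  if (is.null(tree)) stopf("%s: Newick parse error", path)
  validate_tree(tree)
}

validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stopf("not a phylogenetic tree")
  if (!ape::is.rooted(tree)) stopf("tree must be rooted")
  if (anyDuplicated(tree$tip.label)) stopf("tree has duplicate leaf labels")
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0))
    stopf("tree has negative branch lengths")
  tree
}

#' @rdname read_newick
#' @param tree an `ape::phylo` object.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 12)
  invisible(path)
}

#' Read / write a labelled distance matrix (TSV, labels in row and column)
#' @param dm symmetric numeric matrix with matching dimnames.
#' @param path file path.
#' @export
write_distance_matrix <- function(dm, path) {
  validate_distance_matrix(dm)
  utils::write.table(cbind(sample_id = rownames(dm), as.data.frame(dm)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  if (!identical(rownames(m), colnames(m)))
    stopf("%s: row and column labels disagree", path)
  validate_distance_matrix(m)
}

validate_distance_matrix <- function(dm) {
  if (!is.matrix(dm) || nrow(dm) != ncol(dm)) stopf("distance matrix must be square")
  if (any(dm < 0)) stopf("distances must be non-negative")
  if (max(abs(dm - t(dm))) > 1e-12) stopf("distance matrix must be symmetric (tol 1e-12)")
  if (any(abs(diag(dm)) > 1e-12)) stopf("distance matrix diagonal must be zero")
  dm
}

#' Export a co-occurrence network
#'
#' `write_edge_list` writes a Cytoscape-ready TSV (source, target, rho,
#' sign); `write_graphml` writes GraphML with node attributes (mean
#' relative abundance, genus, enrichment direction).
#'
#' @param net a `cooc_network` from [build_network()].
#' @param path output file.
#' @export
write_edge_list <- function(net, path) {
  utils::write.table(net$edges[, c("source", "target", "rho", "sign")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
write_graphml <- function(net, path) {
  g <- as_igraph(net)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

as_igraph <- function(net) {
  g <- igraph::graph_from_data_frame(
    net$edges[, c("source", "target", "rho", "sign")],
    directed = FALSE, vertices = net$nodes)
  g
}
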