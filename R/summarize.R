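#' Molecular-function category breakdown
#'
#' Counts category hits for a set of proteins against an offline
#' annotation table.  A protein annotated with k categories contributes
#' one hit to each (so hits can exceed proteins); proteins absent from the
#' annotation count toward `total_proteins` only.  Percentages are hits
#' over total hits.  The result is invariant under permutation of the
#' input accessions.
#'
#' @param accessions Character vector of protein accessions (duplicates
#'   are collapsed); must be non-empty.
#' @param annotation Long-format annotation data frame from
#'   [read_annotation()].
#' @return Object of class `"category_breakdown"`: list with
#'   `total_proteins`, `recognized_proteins`, `total_hits`, `hits` (named
#'   integer vector) and `percent` (named numeric vector).
#' @export
summarize_categories <- function(accessions, annotation) {
  accessions <- unique(accessions)
  if (length(accessions) == 0L)
    stop("empty accession list", call. = FALSE)
  ann <- annotation[annotation$accession %in% accessions, , drop = FALSE]
  hits <- table(factor(ann$category, levels = annotation_vocabulary()))
  hits <- as.integer(hits)
  names(hits) <- annotation_vocabulary()
  hits <- hits[hits > 0]
  total_hits <- sum(hits)
  structure(list(
    total_proteins = length(accessions),
    recognized_proteins = length(unique(ann$accession)),
    total_hits = total_hits,
    hits = hits,
    percent = if (total_hits > 0) 100 * hits / total_hits else numeric()
  ), class = "category_breakdown")
}

#' @export
print.category_breakdown <- function(x, ...) {
  cat(sprintf("%d proteins, %d recognized, %d category hits\n",
              x$total_proteins, x$recognized_proteins, x$total_hits))
  for (nm in names(x$hits))
    cat(sprintf("  %-30s %3d hits (%.1f%%)\n", nm, x$hits[[nm]],
                x$percent[[nm]]))
  invisible(x)
}

#' Connected components of a protein-interaction subnetwork
#'
#' Induces the subgraph of a user-supplied interaction edge list on a
#' protein set, keeping edges with confidence `score >= score_cutoff`, and
#' decomposes it into connected components.  Every input protein appears
#' in exactly one component (isolated proteins are singletons).
#' Components are ordered by size descending, ties broken by the
#' lexicographically smallest member; members within a component are
#' sorted, so the output is deterministic.
#'
#' @param accessions Character vector of proteins to induce on.
#' @param edges Edge data frame from [read_edges()].
#' @param score_cutoff Minimum edge confidence retained (default 0.4).
#' @return Object of class `"network_summary"`: list with `n_nodes`,
#'   `n_edges`, `components` (list of character vectors) and `degree`
#'   (named integer vector).
#' @export
network_components <- function(accessions, edges, score_cutoff = 0.4) {
  accessions <- unique(accessions)
  keep <- edges$score >= score_cutoff &
    edges$accession_a %in% accessions &
    edges$accession_b %in% accessions
  e <- edges[keep, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    e[, c("accession_a", "accession_b")],
    directed = FALSE,
    vertices = data.frame(name = accessions, stringsAsFactors = FALSE))
  comp <- igraph::components(g)
  members <- split(names(comp$membership), comp$membership)
  members <- lapply(members, sort)
  ord <- order(-vapply(members, length, 1L),
               vapply(members, `[`, "", 1L))
  deg <- igraph::degree(g)
  structure(list(n_nodes = length(accessions),
                 n_edges = nrow(e),
                 components = unname(members[ord]),
                 degree = deg[accessions]),
            class = "network_summary")
}

#' @export
print.network_summary <- function(x, ...) {
  cat(sprintf("%d proteins, %d interactions, %d components\n",
              x$n_nodes, x$n_edges, length(x$components)))
  sizes <- vapply(x$components, length, 1L)
  cat("component sizes:", paste(sizes, collapse = ", "), "\n")
  invisible(x)
}
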