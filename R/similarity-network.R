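# Cross-submission similarity analyses: duplicate detection among top-ranked
# predictions, thresholded Tanimoto similarity networks and their
# connected-component subclusters.

#' Deduplicate top-ranked submissions by structure
#'
#' Counts distinct chemical structures among each team's rank-1 compound,
#' using the canonical identity key so the same molecule written as different
#' SMILES strings collapses to one entry.
#'
#' @param submissions a `submission_set` (see [read_submissions()]).
#' @param rank which rank to deduplicate (default 1).
#' @return list with `unique_compounds` (data frame: first-seen team, id,
#'   SMILES, key) and `n_unique`.
#' @export
dedup_top_ranked <- function(submissions, rank = 1) {
  stopifnot(inherits(submissions, "submission_set"))
  entries <- submissions$entries
  top <- entries[entries$rank == rank, , drop = FALSE]
  if (nrow(top) == 0)
    return(list(unique_compounds = top, n_unique = 0L))
  keys <- character(nrow(top))
  for (i in seq_len(nrow(top))) {
    keys[i] <- tryCatch(canonical_key(top$smiles[i]), error = function(e)
      stop(sprintf("team %s: unparseable SMILES \"%s\" (%s)",
                   top$team[i], top$smiles[i], conditionMessage(e)),
           call. = FALSE))
  }
  top$key <- keys
  uniq <- top[!duplicated(keys), , drop = FALSE]
  list(unique_compounds = uniq, n_unique = nrow(uniq))
}

#' Build a thresholded similarity network
#'
#' Nodes are compounds; an edge joins i and j when their Tanimoto similarity
#' is at or above `threshold` (the published network convention: "edges
#' below the cutoff are filtered out", so the boundary value keeps its edge).
#'
#' @param matrix square symmetric Tanimoto matrix (e.g. from
#'   [similarity_matrix()]).
#' @param threshold edge-inclusion cutoff in \[0, 1\].
#' @return a `similarity_network`: `graph` (igraph, weighted), `threshold`,
#'   `membership` (component label per node, labelled by smallest member
#'   index), `edges` data frame.
#' @export
build_network <- function(matrix, threshold = 0.4) {
  matrix <- as.matrix(matrix)
  if (nrow(matrix) != ncol(matrix))
    stop("similarity matrix must be square", call. = FALSE)
  if (max(abs(matrix - t(matrix))) > 1e-8)
    stop("similarity matrix must be symmetric", call. = FALSE)
  if (is.null(rownames(matrix)))
    rownames(matrix) <- colnames(matrix) <- paste0("cpd", seq_len(nrow(matrix)))
  adj <- matrix
  adj[adj < threshold] <- 0
  diag(adj) <- 0
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           weighted = TRUE)
  memb <- component_labels(g)
  ed <- igraph::as_data_frame(g, what = "edges")
  names(ed) <- c("from", "to", "tc")[seq_len(ncol(ed))]
  structure(list(graph = g, threshold = threshold, membership = memb,
                 edges = ed),
            class = "similarity_network")
}

# Connected components, deterministically labelled: component containing the
# smallest node index gets label 1, and so on.
component_labels <- function(g) {
  comp <- igraph::components(g)$membership
  relabel <- match(comp, unique(comp))
  stats::setNames(relabel, igraph::V(g)$name)
}

#' Connected components of a similarity network
#'
#' @param net a `similarity_network`.
#' @return named integer vector of component labels (a partition of the
#'   nodes; labels ordered by smallest member index).
#' @export
network_components <- function(net) {
  stopifnot(inherits(net, "similarity_network"))
  net$membership
}

#' @export
print.similarity_network <- function(x, ...) {
  cat(sprintf(
    "<similarity_network> %d nodes, %d edges (Tc >= %.2f), %d components\n",
    igraph::vcount(x$graph), igraph::ecount(x$graph), x$threshold,
    length(unique(x$membership))))
  invisible(x)
}

#' Cross-set similar pairs
#'
#' All pairs (a, b) with Tanimoto similarity strictly above `threshold`,
#' the convention of the cross-team analysis ("no similar molecule submitted
#' by another team, Tc > 0.5"). Self-pairs are excluded when the two sets
#' are the same object; pairs within one team are excluded when team
#' attributions are supplied (the question is similarity *across* teams).
#'
#' @param set_a,set_b character vectors of SMILES (named = compound ids) or
#'   lists of `mol_graph`. Omitting `set_b` switches to same-set mode, where
#'   self-pairs and mirrored duplicates are dropped; passing `set_b`
#'   explicitly (even a copy of `set_a`) treats the two sets as distinct
#'   collections, so a compound does pair with its copy.
#' @param threshold strict lower bound for reported pairs.
#' @param dialect fingerprint dialect (default the network standard,
#'   `"path1024"`).
#' @param team_a,team_b optional team attribution per compound; when given,
#'   within-team pairs are dropped unless `include_within_team = TRUE`.
#' @param include_within_team keep pairs from the same team.
#' @return data frame `a`, `b`, `tc`, sorted by decreasing similarity.
#' @export
cross_set_pairs <- function(set_a, set_b = NULL, threshold = 0.5,
                            dialect = "path1024",
                            team_a = NULL, team_b = NULL,
                            include_within_team = FALSE) {
  same <- is.null(set_b)
  if (same) set_b <- set_a
  tc <- similarity_matrix(set_a, set_b, dialect = dialect)
  if (is.null(rownames(tc))) rownames(tc) <- paste0("a", seq_len(nrow(tc)))
  if (is.null(colnames(tc))) colnames(tc) <- paste0("b", seq_len(ncol(tc)))
  idx <- which(tc > threshold, arr.ind = TRUE)
  if (same) idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
  out <- data.frame(a = rownames(tc)[idx[, 1]], b = colnames(tc)[idx[, 2]],
                    tc = tc[idx])
  if (!is.null(team_a) && !is.null(team_b) && !include_within_team &&
      nrow(out) > 0) {
    keep <- team_a[idx[, 1]] != team_b[idx[, 2]]
    out <- out[keep, , drop = FALSE]
  }
  out[order(-out$tc, out$a, out$b), , drop = FALSE]
}

#' Export a similarity network
#'
#' @param net a `similarity_network`.
#' @param graphml,edge_csv optional output paths (GraphML and edge-list CSV).
#' @return invisibly, the paths written.
#' @export
write_network <- function(net, graphml = NULL, edge_csv = NULL) {
  stopifnot(inherits(net, "similarity_network"))
  written <- character()
  if (!is.null(graphml)) {
    igraph::write_graph(net$graph, graphml, format = "graphml")
    written <- c(written, graphml)
  }
  if (!is.null(edge_csv)) {
    utils::write.csv(net$edges, edge_csv, row.names = FALSE)
    written <- c(written, edge_csv)
  }
  invisible(written)
}
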