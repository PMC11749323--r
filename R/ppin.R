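#' Assemble a protein-protein interaction network
#'
#' Restricts a physical-interaction edge table to edges with at least one
#' endpoint among the query genes (genes carrying exonic CHD-SNPs).
#' Non-query endpoints pulled in by such edges are kept and flagged
#' `added`; isolated query genes are retained as singletons. Self-loops are
#' dropped with a warning.
#'
#' @param query_genes character vector of gene symbols.
#' @param edge_table data.frame with columns `geneA`, `geneB`, optional
#'   `weight` (default 1) and optional `interaction_type` (rows other than
#'   "physical" are discarded when the column is present).
#' @return list of class `ppin_network`: `nodes` (name, origin) and `edges`
#'   (from, to, weight).
#' @export
build_network <- function(query_genes, edge_table) {
  query_genes <- unique(query_genes)
  if (!is.null(edge_table) && nrow(edge_table)) {
    if ("interaction_type" %in% names(edge_table)) {
      edge_table <- edge_table[edge_table$interaction_type == "physical", , drop = FALSE]
    }
    loops <- edge_table$geneA == edge_table$geneB
    if (any(loops)) {
      warning(sum(loops), " self-loop(s) dropped", call. = FALSE)
      edge_table <- edge_table[!loops, , drop = FALSE]
    }
    keep <- edge_table$geneA %in% query_genes | edge_table$geneB %in% query_genes
    edge_table <- edge_table[keep, , drop = FALSE]
  }
  if (is.null(edge_table) || nrow(edge_table) == 0L) {
    warning("no usable edges; network consists of isolated query genes", call. = FALSE)
    edges <- data.frame(from = character(0), to = character(0), weight = numeric(0))
  } else {
    w <- if ("weight" %in% names(edge_table)) edge_table$weight else 1
    edges <- data.frame(from = edge_table$geneA, to = edge_table$geneB,
                        weight = w, stringsAsFactors = FALSE)
    # canonical undirected orientation, drop duplicate pairs
    flip <- edges$from > edges$to
    tmp <- edges$from[flip]; edges$from[flip] <- edges$to[flip]; edges$to[flip] <- tmp
    edges <- edges[!duplicated(paste(edges$from, edges$to)), , drop = FALSE]
    rownames(edges) <- NULL
  }
  node_names <- unique(c(query_genes, edges$from, edges$to))
  nodes <- data.frame(name = node_names,
                      origin = ifelse(node_names %in% query_genes, "query", "added"),
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges), class = "ppin_network")
}

# Symmetric weighted adjacency matrix of a ppin_network.
network_adjacency <- function(network) {
  nm <- network$nodes$name
  A <- matrix(0, length(nm), length(nm), dimnames = list(nm, nm))
  if (nrow(network$edges)) {
    i <- match(network$edges$from, nm)
    j <- match(network$edges$to, nm)
    A[cbind(i, j)] <- network$edges$weight
    A[cbind(j, i)] <- network$edges$weight
  }
  A
}

#' Markov Cluster algorithm (MCL)
#'
#' Canonical MCL on the network's adjacency matrix: self-loops of weight 1
#' are added, columns are normalised to stochastic form, then expansion
#' (matrix power) and inflation (elementwise power followed by column
#' renormalisation) alternate, with entries below `prune` zeroed and the
#' columns renormalised, until the largest entry change falls below `tol`
#' or `max_iter` is hit. In the limit matrix rows with a nonzero diagonal
#' are attractors; each node joins every attractor it flows to, and
#' overlapping attractor systems are unioned so the final partition is
#' disjoint. Cluster ids are dense from 1, ordered by decreasing size.
#'
#' @param network a [build_network()] object.
#' @param inflation inflation exponent (granularity dial, default 2.0).
#' @param expansion matrix-power exponent (default 2).
#' @param prune entries below this are zeroed each iteration.
#' @param max_iter,tol convergence controls.
#' @return list of class `mcl_clustering`: `partition` (named integer
#'   vector), `n_clusters`, `converged`, `iterations`.
#' @export
mcl <- function(network, inflation = 2.0, expansion = 2L, prune = 1e-6,
                max_iter = 100L, tol = 1e-8) {
  A <- network_adjacency(network)
  if (nrow(A) == 0L) stop("empty network", call. = FALSE)
  diag(A) <- diag(A) + 1
  M <- sweep(A, 2, colSums(A), "/")
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    Mexp <- M
    for (k in seq_len(expansion - 1L)) Mexp <- Mexp %*% M
    Minf <- Mexp ^ inflation
    Minf <- sweep(Minf, 2, colSums(Minf), "/")
    Minf[Minf < prune] <- 0
    cs <- colSums(Minf)
    cs[cs == 0] <- 1
    Minf <- sweep(Minf, 2, cs, "/")
    delta <- max(abs(Minf - M))
    M <- Minf
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warning("MCL did not converge in ", max_iter, " iterations", call. = FALSE)
  }
  nm <- rownames(M)
  attractors <- which(diag(M) > 0)
  # node j belongs to every attractor i with M[i, j] > 0; union overlapping
  # attractor systems via connected components of the membership graph
  memb <- M[attractors, , drop = FALSE] > 0
  idx <- which(memb, arr.ind = TRUE)
  g <- igraph::graph_from_edgelist(
    cbind(paste0("attr_", attractors[idx[, 1]]), nm[idx[, 2]]), directed = FALSE)
  g <- igraph::add_vertices(g, length(setdiff(nm, igraph::V(g)$name)),
                            name = setdiff(nm, igraph::V(g)$name))
  comp <- igraph::components(g)$membership
  part <- comp[nm]
  sizes <- table(part)
  size_rank <- stats::setNames(rank(-as.numeric(sizes), ties.method = "first"),
                               names(sizes))
  partition <- stats::setNames(as.integer(size_rank[as.character(part)]), nm)
  structure(list(partition = partition,
                 n_clusters = length(unique(partition)),
                 converged = converged, iterations = iter),
            class = "mcl_clustering")
}

#' Per-cluster node and edge counts
#'
#' @param clustering an [mcl()] result.
#' @param network the clustered [build_network()] object.
#' @return list: `clusters` data.frame (`cluster`, `n_nodes`, `n_edges`)
#'   sorted by size descending, and `n_inter_cluster_edges`.
#' @export
cluster_summary <- function(clustering, network) {
  part <- clustering$partition
  if (!all(network$nodes$name %in% names(part))) {
    stop("clustering does not cover the network", call. = FALSE)
  }
  e_from <- part[network$edges$from]
  e_to <- part[network$edges$to]
  intra <- e_from == e_to
  n_nodes <- table(part)
  n_edges <- table(factor(e_from[intra], levels = names(n_nodes)))
  df <- data.frame(cluster = as.integer(names(n_nodes)),
                   n_nodes = as.integer(n_nodes),
                   n_edges = as.integer(n_edges))
  df <- df[order(-df$n_nodes, df$cluster), , drop = FALSE]
  rownames(df) <- NULL
  list(clusters = df, n_inter_cluster_edges = sum(!intra))
}
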