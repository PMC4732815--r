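#' Identity-by-state distance matrix
#'
#' Pairwise IBS similarity: the mean, over markers non-missing in both
#' samples, of the shared-allele fraction (0, 0.5 or 1 per marker). The
#' returned distance is `1 - similarity`.
#'
#' @param g a `canidiv_genotypes` with at least 2 samples.
#' @return symmetric numeric matrix of class `canidiv_dist` with zero
#'   diagonal, values in [0, 1], dimnames = sample ids and attribute
#'   `metric = "one_minus_ibs"`.
#' @export
ibs_distance <- function(g) {
  stopifnot(inherits(g, "canidiv_genotypes"))
  X <- g$calls
  n <- nrow(X)
  if (n < 2L) stop("need at least 2 samples")
  ids <- g$samples$iid
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    xi <- X[i, ]
    for (j in (i + 1L):n) {
      xj <- X[j, ]
      ok <- !is.na(xi) & !is.na(xj)
      if (!any(ok)) {
        stop(sprintf("no overlapping markers for pair %s / %s", ids[i], ids[j]))
      }
      d <- mean(abs(xi[ok] - xj[ok]) / 2)
      D[i, j] <- d
      D[j, i] <- d
    }
  }
  attr(D, "metric") <- "one_minus_ibs"
  class(D) <- c("canidiv_dist", "matrix")
  D
}

#' Population network from a distance matrix
#'
#' Builds a mutual k-nearest-neighbour graph: an edge is kept only when each
#' endpoint is among the other's `k` nearest neighbours, where the neighbour
#' set is tie-inclusive (every node at the k-th-nearest distance belongs to
#' it, so the construction is deterministic and rank-based). Edge weights
#' `1 - distance` are carried for visualisation only; cluster labels come from
#' connected components refined by deterministic unweighted modularity-based
#' community detection (fast-greedy), so clustering is invariant to adding a
#' constant to all distances. Clusters smaller than `min_cluster` are flagged
#' unclustered.
#'
#' @param d distance matrix from [ibs_distance()] (any symmetric matrix with
#'   zero diagonal works).
#' @param k neighbour count (default 10); must be < number of samples.
#' @param min_cluster minimum cluster size (default 2).
#' @return list of class `canidiv_network`: `graph` (igraph), `nodes` (data
#'   frame `id`, `cluster` (NA when unclustered), `unclustered`), `edges`
#'   (data frame `from`, `to`, `weight`), `k`, `min_cluster`.
#' @export
build_network <- function(d, k = 10L, min_cluster = 2L) {
  d <- unclass(d)
  n <- nrow(d)
  if (!isTRUE(all.equal(d, t(d)))) stop("distance matrix must be symmetric")
  if (k >= n) stop("k must be smaller than the number of samples")
  ids <- rownames(d)
  if (is.null(ids)) ids <- sprintf("S%d", seq_len(n))
  # tie-inclusive k nearest neighbours per node
  nn <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    cand <- setdiff(seq_len(n), i)
    kth <- sort(d[i, cand], partial = k)[k]
    nn[i, cand[d[i, cand] <= kth + 1e-12]] <- TRUE
  }
  mutual <- nn & t(nn)
  ut <- which(mutual & upper.tri(mutual), arr.ind = TRUE)
  edges <- data.frame(from = ids[ut[, 1L]], to = ids[ut[, 2L]],
                      weight = 1 - d[ut], stringsAsFactors = FALSE)
  gr <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                      vertices = data.frame(name = ids))
  comp <- igraph::components(gr)$membership
  # refine each non-trivial component by deterministic modularity communities
  membership <- integer(n)
  names(membership) <- ids
  next_label <- 0L
  for (cpt in sort(unique(comp))) {
    vs <- names(comp)[comp == cpt]
    sub <- igraph::induced_subgraph(gr, vs)
    if (length(vs) >= 3L && igraph::ecount(sub) > 0L) {
      cm <- igraph::cluster_fast_greedy(sub, weights = NA)
      mem <- igraph::membership(cm)
      # only split a component when the partition has positive modularity
      if (igraph::modularity(sub, mem) <= 1e-12) {
        mem <- stats::setNames(rep(1L, length(vs)), vs)
      }
    } else {
      mem <- stats::setNames(rep(1L, length(vs)), vs)
    }
    membership[vs] <- next_label + as.integer(mem)
    next_label <- next_label + max(as.integer(mem))
  }
  sizes <- table(membership)
  uncl <- sizes[as.character(membership)] < min_cluster
  cluster <- ifelse(uncl, NA_integer_, membership)
  # relabel clusters 1..K by decreasing size then first id
  lv <- unique(cluster[!is.na(cluster)])
  if (length(lv)) {
    ordlv <- lv[order(-as.integer(sizes[as.character(lv)]), lv)]
    cluster <- match(cluster, ordlv)
  }
  nodes <- data.frame(id = ids, cluster = cluster,
                      unclustered = as.logical(uncl), stringsAsFactors = FALSE)
  rownames(nodes) <- NULL
  structure(list(graph = gr, nodes = nodes, edges = edges,
                 k = k, min_cluster = min_cluster),
            class = "canidiv_network")
}

#' @export
print.canidiv_network <- function(x, ...) {
  nc <- length(unique(stats::na.omit(x$nodes$cluster)))
  cat(sprintf("Population network: %d nodes, %d edges (mutual %d-NN)\n",
              nrow(x$nodes), nrow(x$edges), x$k))
  cat(sprintf("%d cluster(s) of size >= %d; %d unclustered node(s)\n",
              nc, x$min_cluster, sum(x$nodes$unclustered)))
  invisible(x)
}

#' Write network files
#'
#' Emits a GraphML file, a plain edge list (`source`, `target`, `weight`) and
#' a node-attribute TSV with cluster labels.
#'
#' @param net a `canidiv_network`.
#' @param prefix output path prefix (writes `<prefix>.graphml`,
#'   `<prefix>_edges.tsv`, `<prefix>_nodes.tsv`).
#' @export
write_network <- function(net, prefix) {
  stopifnot(inherits(net, "canidiv_network"))
  igraph::write_graph(net$graph, paste0(prefix, ".graphml"), format = "graphml")
  utils::write.table(net$edges, paste0(prefix, "_edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(net$nodes, paste0(prefix, "_nodes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

#' Neighbour-joining tree from a distance matrix
#'
#' Saitou-Nei neighbour joining (exact on additive tree metrics). Negative
#' branch lengths are clamped to zero with the total deficit recorded in
#' attribute `clamped`.
#'
#' @param d symmetric distance matrix with at least 3 taxa.
#' @return an [ape::phylo] tree (unrooted).
#' @export
nj_tree <- function(d) {
  d <- unclass(d)
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8))) {
    stop("distance matrix must be symmetric")
  }
  if (nrow(d) < 3L) stop("neighbour joining needs at least 3 taxa")
  tr <- ape::nj(stats::as.dist(d))
  neg <- tr$edge.length < 0
  clamped <- sum(tr$edge.length[neg])
  if (any(neg)) tr$edge.length[neg] <- 0
  attr(tr, "clamped") <- clamped
  tr
}

#' Write a tree in Newick format
#'
#' @param tree an [ape::phylo] object.
#' @param path output file.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
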