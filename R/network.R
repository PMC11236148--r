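#' Build a signed co-occurrence network from abundance correlations
#'
#' Pairwise species correlations (Spearman by default) across the samples in
#' scope; an edge joins two species when |r| passes the threshold and the
#' (multiplicity-adjusted) p-value is small enough. Isolated species are
#' dropped, and a module partition (greedy modularity optimisation on |r|
#' weights) is attached so the returned object always satisfies the network
#' contract used by the topology panel and the Zi-Pi role computation.
#'
#' Correlation p-values use the t approximation
#' t = r sqrt((n-2)/(1-r^2)) for both Pearson and (rank-transformed)
#' Spearman coefficients.
#'
#' @param ab an \code{abundance_table}
#' @param method \code{"spearman"} (default) or \code{"pearson"}
#' @param min_abs_r edge threshold on |r| (default 0.6)
#' @param max_p threshold on the adjusted p-value (default 0.05)
#' @param correction \code{"BH"} (Benjamini-Hochberg, default) or
#'   \code{"none"}
#' @param min_prevalence species present in fewer samples are excluded
#'   before correlation (default 3)
#' @param scope optional metadata filter as in \code{\link{subset_samples}}
#' @param seed seed for the module detection
#' @return object of class \code{cooccur_network}: \code{graph} (igraph with
#'   edge attributes \code{r} and \code{sign}), \code{membership} (named
#'   module IDs, contiguous from 1), \code{modularity}, \code{params}
#' @export
build_network <- function(ab, method = c("spearman", "pearson"),
                          min_abs_r = 0.6, max_p = 0.05,
                          correction = c("BH", "none"),
                          min_prevalence = 3, scope = NULL, seed = 1) {
  method <- match.arg(method)
  correction <- match.arg(correction)
  sub <- subset_samples(ab, scope)
  m <- sub$counts
  n <- nrow(m)
  if (n < 5) stop("co-occurrence network needs at least 5 samples")

  keep <- colSums(m > 0) >= min_prevalence
  m <- m[, keep, drop = FALSE]
  constant <- apply(m, 2, function(x) stats::var(x) == 0)
  if (any(constant)) {
    warning("dropping constant species: ",
            paste(colnames(m)[constant], collapse = ", "))
    m <- m[, !constant, drop = FALSE]
  }
  if (ncol(m) < 2) stop("fewer than 2 species pass the prevalence filter")

  r <- stats::cor(m, method = method)
  r_clip <- pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)
  tval <- r_clip * sqrt((n - 2) / (1 - r_clip^2))
  p <- 2 * stats::pt(-abs(tval), df = n - 2)
  p[abs(r) >= 1 - 1e-12] <- 0

  ut <- upper.tri(r)
  p_adj <- p
  p_adj[ut] <- stats::p.adjust(p[ut], method = correction)
  sel <- ut & abs(r) >= min_abs_r & p_adj <= max_p
  idx <- which(sel, arr.ind = TRUE)

  edges <- data.frame(
    from = colnames(m)[idx[, 1]],
    to = colnames(m)[idx[, 2]],
    r = r[sel],
    stringsAsFactors = FALSE
  )
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = colnames(m))
  g <- igraph::delete_vertices(g, igraph::V(g)[igraph::degree(g) == 0])
  igraph::E(g)$sign <- ifelse(igraph::E(g)$r >= 0, 1L, -1L)
  igraph::E(g)$weight <- abs(igraph::E(g)$r)

  net <- structure(list(graph = g, membership = NULL, modularity = NA_real_,
                        params = list(method = method, min_abs_r = min_abs_r,
                                      max_p = max_p, correction = correction,
                                      min_prevalence = min_prevalence,
                                      n_samples = n)),
                   class = "cooccur_network")
  if (igraph::ecount(g) > 0) net <- detect_modules(net, seed = seed)
  net
}

#' @export
print.cooccur_network <- function(x, ...) {
  g <- x$graph
  cat(sprintf("co-occurrence network: %d nodes, %d edges (%s, |r| >= %g)\n",
              igraph::vcount(g), igraph::ecount(g), x$params$method,
              x$params$min_abs_r))
  if (!is.null(x$membership)) {
    cat(sprintf("  modules: %d (modularity %.3f)\n",
                length(unique(x$membership)), x$modularity))
  }
  invisible(x)
}

#' Detect modules by modularity maximisation
#'
#' Sign is ignored; |r| edge weights are used. The partition is stored on
#' the network (module IDs relabelled contiguous from 1) together with its
#' Newman modularity.
#'
#' @param net a \code{cooccur_network} with at least one edge
#' @param algorithm \code{"greedy"} (fast greedy agglomeration, default,
#'   deterministic) or \code{"louvain"}
#' @param seed RNG seed (relevant for louvain)
#' @return the network with \code{membership} and \code{modularity} set
#' @export
detect_modules <- function(net, algorithm = c("greedy", "louvain"), seed = 1) {
  algorithm <- match.arg(algorithm)
  g <- net$graph
  if (igraph::ecount(g) < 1) stop("module detection needs at least one edge")
  set.seed(seed)
  comm <- switch(algorithm,
                 greedy = igraph::cluster_fast_greedy(g,
                                                      weights = igraph::E(g)$weight),
                 louvain = igraph::cluster_louvain(g,
                                                   weights = igraph::E(g)$weight))
  memb <- igraph::membership(comm)
  memb <- match(memb, sort(unique(memb)))  # contiguous from 1
  names(memb) <- igraph::V(g)$name
  net$membership <- memb
  net$modularity <- igraph::modularity(g, memb, weights = igraph::E(g)$weight)
  net
}

#' Average degree of a graph with N nodes and E edges
#' @param n_nodes number of nodes
#' @param n_edges number of undirected edges
#' @return 2E/N
#' @export
average_degree <- function(n_nodes, n_edges) 2 * n_edges / n_nodes

#' Density of a simple undirected graph with N nodes and E edges
#' @inheritParams average_degree
#' @return 2E/(N(N-1))
#' @export
network_density <- function(n_nodes, n_edges) {
  2 * n_edges / (n_nodes * (n_nodes - 1))
}

#' Topology panel of a co-occurrence network
#'
#' The standard network-level summary: node and edge counts, average degree
#' 2E/N, Newman modularity of the stored partition (|r| weights, sign
#' ignored), density 2E/(N(N-1)), mean local clustering coefficient (nodes
#' of degree < 2 contribute 0), mean shortest-path length over connected
#' pairs only, and the percentage of positively / negatively signed edges.
#'
#' @param net a \code{cooccur_network} with at least 2 nodes
#' @return list of class \code{network_topology}
#' @export
topology <- function(net) {
  g <- net$graph
  N <- igraph::vcount(g)
  E <- igraph::ecount(g)
  if (N < 2) stop("topology needs at least 2 nodes")
  cl <- igraph::transitivity(g, type = "local", isolates = "zero")
  # degree-1 nodes also carry no triangles; force their contribution to 0
  cl[is.na(cl)] <- 0
  mpl <- if (E == 0) NA_real_ else
    igraph::mean_distance(g, directed = FALSE, unconnected = TRUE)
  if (E == 0) warning("edgeless network: mean path length undefined")
  signs <- if (E > 0) igraph::E(g)$sign else integer(0)
  structure(list(
    n_nodes = N,
    n_edges = E,
    average_degree = average_degree(N, E),
    modularity = net$modularity,
    density = network_density(N, E),
    clustering_coefficient = mean(cl),
    mean_path_length = mpl,
    positive_ratio = if (E > 0) 100 * mean(signs > 0) else NA_real_,
    negative_ratio = if (E > 0) 100 * mean(signs < 0) else NA_real_
  ), class = "network_topology")
}

#' @export
print.network_topology <- function(x, ...) {
  fmt <- c(n_nodes = "%d", n_edges = "%d", average_degree = "%.2f",
           modularity = "%.3f", density = "%.3f",
           clustering_coefficient = "%.3f", mean_path_length = "%.3f",
           positive_ratio = "%.2f", negative_ratio = "%.2f")
  cat("network topology\n")
  for (nm in names(fmt)) {
    v <- x[[nm]]
    cat(sprintf(paste0("  %-24s ", fmt[[nm]], "\n"), nm,
                if (is.na(v)) NA else v))
  }
  invisible(x)
}

#' Export a network as an edge list or GraphML
#'
#' @param net a \code{cooccur_network}
#' @param path output file
#' @param format \code{"edgelist"} (3-column TSV: u, v, signed r) or
#'   \code{"graphml"}
#' @return \code{path}, invisibly
#' @export
write_network <- function(net, path, format = c("edgelist", "graphml")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(net$graph, path, format = "graphml")
  } else {
    el <- igraph::as_data_frame(net$graph, what = "edges")
    utils::write.table(el[, c("from", "to", "r")], path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
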