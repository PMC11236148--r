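#' Zi-Pi node roles of a co-occurrence network
#'
#' For each node i of a partitioned network, computes the within-module
#' degree z-score
#' \deqn{Z_i = (K_i - \bar{K}_{si}) / \sigma_{K_{si}}}
#' where K_i is the number of links of i to other members of its own module
#' and the mean and SD are taken over the members of that module, and the
#' participation coefficient
#' \deqn{P_i = 1 - \sum_s (K_{is}/k_i)^2}
#' where K_is is the number of links of i into module s and k_i is the TOTAL
#' degree of i (the Guimera-Amaral convention). Roles follow the classical
#' thresholds, with strict comparisons so boundary values fall in the lower
#' category:
#' \itemize{
#'   \item Zi <= 2.5, Pi <= 0.62: peripheral
#'   \item Zi <= 2.5, Pi >  0.62: connector
#'   \item Zi >  2.5, Pi <= 0.62: module hub
#'   \item Zi >  2.5, Pi >  0.62: network hub
#' }
#' Connectors, module hubs and network hubs are the candidate keystone
#' species. Degenerate cases: a module whose within-module degrees have zero
#' SD gives Zi = 0 for its members by convention; a degree-0 node gets
#' Pi = 0 with a warning.
#'
#' @param net a \code{cooccur_network} with a module partition
#' @return data.frame with columns \code{node}, \code{module},
#'   \code{degree}, \code{Zi}, \code{Pi}, \code{role}
#' @export
zi_pi <- function(net) {
  if (is.null(net$membership)) stop("network has no module partition")
  g <- net$graph
  nodes <- igraph::V(g)$name
  memb <- net$membership[nodes]
  adj <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  adj <- (adj > 0) * 1  # unweighted, simple
  deg <- rowSums(adj)
  mods <- sort(unique(memb))

  # K_is: node x module matrix of link counts into each module
  k_is <- vapply(mods, function(s) {
    rowSums(adj[, memb == s, drop = FALSE])
  }, numeric(length(nodes)))
  if (is.null(dim(k_is))) k_is <- matrix(k_is, ncol = length(mods))

  k_within <- k_is[cbind(seq_along(nodes), match(memb, mods))]
  zi <- numeric(length(nodes))
  for (s in mods) {
    idx <- memb == s
    mu <- mean(k_within[idx])
    sdv <- stats::sd(k_within[idx])
    zi[idx] <- if (sum(idx) < 2 || is.na(sdv) || sdv == 0) 0 else
      (k_within[idx] - mu) / sdv
  }

  if (any(deg == 0)) warning("degree-0 node(s): participation set to 0")
  pi <- ifelse(deg == 0, 0, 1 - rowSums((k_is / pmax(deg, 1))^2))

  role <- ifelse(zi > 2.5,
                 ifelse(pi > 0.62, "network_hub", "module_hub"),
                 ifelse(pi > 0.62, "connector", "peripheral"))
  data.frame(node = nodes, module = as.integer(memb), degree = as.integer(deg),
             Zi = zi, Pi = pi, role = role,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Extract keystone candidates from a node-role table
#'
#' Keystones are all non-peripheral nodes (network hubs, module hubs,
#' connectors), ordered by role importance and then by Zi + Pi descending.
#'
#' @param roles data.frame as returned by \code{\link{zi_pi}}
#' @return subset of \code{roles}, possibly empty
#' @export
classify_keystones <- function(roles) {
  ks <- roles[roles$role != "peripheral", , drop = FALSE]
  if (nrow(ks) == 0) return(ks)
  role_rank <- match(ks$role, c("network_hub", "module_hub", "connector"))
  ks <- ks[order(role_rank, -(ks$Zi + ks$Pi)), , drop = FALSE]
  rownames(ks) <- NULL
  ks
}
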