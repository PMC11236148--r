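# Shared fixture builders; everything is generated in code.

toy_counts <- function() {
  m <- matrix(c(1, 2,
                0, 4,
                5, 0), nrow = 3, byrow = TRUE,
              dimnames = list(c("s1", "s2", "s3"), c("spA", "spB")))
  m
}

toy_metadata <- function(samples, ecosystems, seasons = NULL) {
  data.frame(sample = samples,
             ecosystem = ecosystems,
             season = seasons %||% rep("Spring", length(samples)),
             latitude = seq(28.3, 29.3, length.out = length(samples)),
             longitude = seq(88.9, 89.6, length.out = length(samples)),
             altitude = 4000,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Survey inventory expanded to species-level presence tables (memoised).
table2_tables <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- composition_to_tables(composition_fixture())
    cache
  }
})

# Wrap an igraph into a cooccur_network, defaulting edge r to +1 and the
# module partition to the given membership (or a greedy one).
make_net <- function(g, membership = NULL) {
  if (is.null(igraph::E(g)$r)) igraph::E(g)$r <- 1
  igraph::E(g)$sign <- ifelse(igraph::E(g)$r >= 0, 1L, -1L)
  igraph::E(g)$weight <- abs(igraph::E(g)$r)
  if (is.null(igraph::V(g)$name)) {
    igraph::V(g)$name <- paste0("n", seq_len(igraph::vcount(g)))
  }
  net <- structure(list(graph = g, membership = NULL, modularity = NA_real_,
                        params = list(method = "manual", min_abs_r = 0,
                                      max_p = 1, correction = "none",
                                      min_prevalence = 0, n_samples = NA)),
                   class = "cooccur_network")
  if (!is.null(membership)) {
    memb <- membership
    names(memb) <- igraph::V(g)$name
    net$membership <- memb
    net$modularity <- igraph::modularity(g, memb,
                                         weights = igraph::E(g)$weight)
  } else if (igraph::ecount(g) > 0) {
    net <- detect_modules(net)
  }
  net
}

# Independent Zi/Pi oracle: direct adjacency enumeration, written against
# the role definitions, not against the package internals.
zi_pi_oracle <- function(adj, memb) {
  n <- nrow(adj)
  deg <- rowSums(adj)
  zi <- numeric(n); pi <- numeric(n)
  for (i in seq_len(n)) {
    own <- memb == memb[i]
    kw_i <- sum(adj[i, own])
    kw_all <- vapply(which(own), function(j) sum(adj[j, own]), 0)
    sdv <- stats::sd(kw_all)
    zi[i] <- if (length(kw_all) < 2 || is.na(sdv) || sdv == 0) 0 else
      (kw_i - mean(kw_all)) / sdv
    if (deg[i] == 0) {
      pi[i] <- 0
    } else {
      acc <- 0
      for (s in unique(memb)) {
        k_is <- sum(adj[i, memb == s])
        acc <- acc + (k_is / deg[i])^2
      }
      pi[i] <- 1 - acc
    }
  }
  list(zi = zi, pi = pi)
}

# Small filtered-survey scenario used by several stochastic tests.
small_filtered_scn <- function(strength, seed, n_species = 80,
                               community_size_N = 500) {
  sim_scenario(n_species = n_species,
               habitats = c(Dry = 6, Wet = 6),
               seasons = "Summer",
               swc_ranges = list(Dry = c(5, 20), Wet = c(70, 90)),
               migration_m = 0.1, community_size_N = community_size_N,
               env_filter_strength = strength, seed = seed)
}
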