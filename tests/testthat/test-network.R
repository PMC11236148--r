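test_that("perfect monotone association yields a single signed edge", {
  base <- c(1, 3, 5, 7, 9, 11)
  m <- cbind(sp1 = base, sp2 = 2 * base,
             sp3 = c(4, 1, 8, 2, 6, 3))
  rownames(m) <- paste0("s", 1:6)
  net <- build_network(abundance_table(m), min_abs_r = 0.9)
  el <- igraph::as_data_frame(net$graph)
  expect_equal(nrow(el), 1)
  expect_setequal(unlist(el[, c("from", "to")]), c("sp1", "sp2"))
  expect_gt(el$r, 0)

  m2 <- cbind(sp1 = base, sp2 = rev(base) + 1,
              sp3 = c(4, 1, 8, 2, 6, 3))
  rownames(m2) <- paste0("s", 1:6)
  net2 <- build_network(abundance_table(m2), min_abs_r = 0.9)
  el2 <- igraph::as_data_frame(net2$graph)
  expect_equal(nrow(el2), 1)
  expect_lt(el2$r, 0)
  expect_equal(igraph::E(net2$graph)$sign, -1L)
})

test_that("network construction enforces sample and species preconditions", {
  m <- matrix(rpois(8, 4) + 1, 4, 2,
              dimnames = list(paste0("s", 1:4), c("a", "b")))
  expect_error(build_network(abundance_table(m)), "at least 5 samples")

  m2 <- cbind(sp1 = c(1, 2, 3, 4, 5, 6), sp2 = c(2, 4, 6, 8, 10, 12),
              flat = rep(3, 6))
  rownames(m2) <- paste0("s", 1:6)
  expect_warning(build_network(abundance_table(m2), min_abs_r = 0.8),
                 "constant species.*flat")
})

test_that("module detection recovers planted correlation blocks exactly", {
  set.seed(17)
  n <- 30
  z1 <- rnorm(n); z2 <- rnorm(n)
  mk <- function(z) round(50 + 10 * z + 2.2 * rnorm(n))
  m <- cbind(sapply(1:10, function(i) mk(z1)),
             sapply(1:10, function(i) mk(z2)))
  m[m < 0] <- 0
  colnames(m) <- c(paste0("a", 1:10), paste0("b", 1:10))
  rownames(m) <- paste0("s", 1:n)
  net <- build_network(abundance_table(m), min_abs_r = 0.6)
  expect_equal(igraph::vcount(net$graph), 20)
  memb <- net$membership
  expect_equal(length(unique(memb)), 2)
  expect_equal(length(unique(memb[paste0("a", 1:10)])), 1)
  expect_equal(length(unique(memb[paste0("b", 1:10)])), 1)
})

test_that("topology metrics are exact on a complete graph", {
  net <- make_net(igraph::make_full_graph(5), membership = rep(1, 5))
  tp <- topology(net)
  expect_equal(tp$density, 1)
  expect_equal(tp$clustering_coefficient, 1)
  expect_equal(tp$mean_path_length, 1)
  expect_equal(tp$average_degree, 4)
  expect_equal(tp$positive_ratio, 100)
  expect_equal(tp$negative_ratio, 0)
})

test_that("average degree equals 2E/N on every constructed network", {
  set.seed(23)
  for (i in 1:5) {
    g <- igraph::sample_gnp(12, 0.35)
    if (igraph::ecount(g) == 0) next
    net <- make_net(g)
    tp <- topology(net)
    expect_equal(tp$average_degree,
                 2 * igraph::ecount(g) / igraph::vcount(g))
    expect_equal(tp$positive_ratio + tp$negative_ratio, 100)
  }
})

test_that("modularity separates cliques and stays near zero on dense random graphs", {
  g2 <- igraph::disjoint_union(igraph::make_full_graph(5),
                               igraph::make_full_graph(5))
  net2 <- make_net(g2)
  expect_equal(length(unique(net2$membership)), 2)

  bridged <- igraph::add_edges(g2, c(1, 6))
  netb <- make_net(bridged)
  # two-module partition of two 5-cliques + 1 bridge: Q = 20/21 - 1/2
  expect_equal(netb$modularity, 20 / 21 - 0.5, tolerance = 1e-10)
  expect_gt(netb$modularity, 0.3)

  set.seed(5)
  er <- igraph::sample_gnp(40, 0.5)
  expect_lt(make_net(er)$modularity, 0.3)
})

test_that("module detection is deterministic under a fixed seed", {
  set.seed(77)
  g <- igraph::sample_gnp(25, 0.2)
  net <- make_net(g)
  a <- detect_modules(net, algorithm = "louvain", seed = 4)
  b <- detect_modules(net, algorithm = "louvain", seed = 4)
  expect_identical(a$membership, b$membership)
  expect_identical(a$modularity, b$modularity)
})

test_that("network export writes a readable edge list and GraphML", {
  g <- igraph::make_ring(4)
  igraph::E(g)$r <- c(0.9, -0.8, 0.7, 0.65)
  net <- make_net(g)
  f1 <- withr::local_tempfile(fileext = ".tsv")
  write_network(net, f1)
  el <- utils::read.table(f1, header = TRUE, sep = "\t")
  expect_equal(nrow(el), 4)
  expect_true(any(el$r < 0))
  f2 <- withr::local_tempfile(fileext = ".graphml")
  write_network(net, f2, format = "graphml")
  g2 <- igraph::read_graph(f2, format = "graphml")
  expect_equal(igraph::ecount(g2), 4)
})
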