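#' Bray-Curtis dissimilarity matrix
#'
#' d(x, y) = sum|x_i - y_i| / sum(x_i + y_i), in [0, 1]: 0 for identical
#' abundance vectors, 1 for samples sharing no species. Computed with
#' \code{vegan::vegdist}.
#'
#' @param ab an \code{abundance_table} or a samples x species numeric matrix
#' @param relativize divide each sample by its total first (the default keeps
#'   raw counts)
#' @return a \code{dist} object with attribute \code{metric = "bray"}
#' @export
bray_curtis <- function(ab, relativize = FALSE) {
  m <- if (inherits(ab, "abundance_table")) ab$counts else as.matrix(ab)
  tot <- rowSums(m)
  if (any(tot == 0)) {
    stop("zero-total sample(s): ",
         paste(rownames(m)[tot == 0], collapse = ", "))
  }
  if (relativize) m <- m / tot
  d <- vegan::vegdist(m, method = "bray")
  attr(d, "metric") <- "bray"
  d
}

#' Non-metric multidimensional scaling with random restarts
#'
#' Kruskal stress-1 NMDS (monotone regression, via \code{vegan::monoMDS}).
#' The first start is the metric-scaling configuration; subsequent restarts
#' use random initial coordinates, and the lowest-stress solution is kept.
#' Fully deterministic under a fixed seed.
#'
#' @param d a \code{dist} object (typically Bray-Curtis)
#' @param k number of ordination dimensions (>= 2)
#' @param restarts number of starts (first is metric-scaling based)
#' @param maxit maximum iterations per start
#' @param seed RNG seed
#' @return object of class \code{nmds_ordination}: \code{points} (n x k),
#'   \code{stress} (Kruskal stress-1, in [0, 1]), \code{k},
#'   \code{converged}, \code{seed}. If no start converged the best
#'   configuration is still returned with \code{converged = FALSE} and a
#'   warning.
#' @export
nmds <- function(d, k = 2, restarts = 50, maxit = 500, seed = 1) {
  n <- attr(d, "Size")
  if (k < 2) stop("k must be at least 2")
  if (n <= k + 1) stop("need more samples than k + 1")
  set.seed(seed)
  best <- NULL
  best_converged <- FALSE
  for (i in seq_len(restarts)) {
    fit <- if (i == 1) {
      try(vegan::monoMDS(d, k = k, model = "global", maxit = maxit),
          silent = TRUE)
    } else {
      init <- matrix(stats::rnorm(n * k), n, k)
      try(vegan::monoMDS(d, y = init, k = k, model = "global", maxit = maxit),
          silent = TRUE)
    }
    if (inherits(fit, "try-error")) next
    conv <- fit$icause != 1L  # 1 = stopped at the iteration cap
    if (is.null(best) || fit$stress < best$stress) {
      best <- fit
      best_converged <- conv
    } else {
      best_converged <- best_converged || FALSE
    }
  }
  if (is.null(best)) stop("all NMDS starts failed")
  if (!best_converged) warning("best NMDS configuration did not converge")
  pts <- best$points
  rownames(pts) <- attr(d, "Labels")
  structure(list(points = pts, stress = best$stress, k = k,
                 converged = best_converged, restarts = restarts,
                 seed = seed),
            class = "nmds_ordination")
}

#' @export
print.nmds_ordination <- function(x, ...) {
  cat(sprintf("NMDS ordination: %d samples in %d dimensions\n",
              nrow(x$points), x$k))
  cat(sprintf("  stress (Kruskal stress-1): %.4f%s\n", x$stress,
              if (x$converged) "" else "  [not converged]"))
  invisible(x)
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' One-way pseudo-F test of group differences on a dissimilarity matrix
#' (Anderson's partitioning of squared dissimilarities), with a label
#' permutation null: p = (1 + #{F_perm >= F_obs}) / (1 + n_perm).
#'
#' @param d a \code{dist} object
#' @param groups group labels, one per sample
#' @param n_perm number of permutations (>= 99)
#' @param seed RNG seed
#' @return list of class \code{permanova_test}: \code{F}, \code{p},
#'   \code{n_perm}, \code{df}
#' @export
permanova <- function(d, groups, n_perm = 999, seed = 1) {
  groups <- factor(groups)
  n <- attr(d, "Size")
  stopifnot(length(groups) == n)
  a <- nlevels(groups)
  if (a < 2L) stop("all samples are in one group")
  if (n_perm < 99) stop("n_perm must be at least 99")

  d2 <- as.matrix(d)^2
  sst <- sum(d2) / (2 * n)
  f_of <- function(g) {
    ssw <- 0
    for (lv in levels(g)) {
      idx <- which(g == lv)
      ssw <- ssw + sum(d2[idx, idx]) / (2 * length(idx))
    }
    ssa <- sst - ssw
    (ssa / (a - 1)) / (ssw / (n - a))
  }
  obs <- f_of(groups)
  if (!is.finite(obs)) {
    # zero within-group or zero total dissimilarity
    if (sst == 0) {
      return(structure(list(F = NaN, p = 1, n_perm = n_perm,
                            df = c(a - 1, n - a)),
                       class = "permanova_test"))
    }
  }
  set.seed(seed)
  perm <- replicate(n_perm, f_of(factor(sample(as.integer(groups)),
                                        levels = seq_len(a))))
  p <- (1 + sum(perm >= obs)) / (1 + n_perm)
  structure(list(F = obs, p = p, n_perm = n_perm, df = c(a - 1, n - a)),
            class = "permanova_test")
}

#' @export
print.permanova_test <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F(%d, %d) = %.3f, p = %.4g (%d permutations)\n",
              x$df[1], x$df[2], x$F, x$p, x$n_perm))
  invisible(x)
}
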