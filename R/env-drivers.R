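#' Mantel test between two distance matrices
#'
#' Correlates the off-diagonal elements of two distance matrices over the
#' same samples and assesses significance by jointly permuting the rows and
#' columns of the second matrix: p = (1 + #\{r_perm >= r_obs\}) / (1 +
#' n_perm), one-sided.
#'
#' @param d1,d2 \code{dist} objects with matching labels
#' @param n_perm number of permutations (>= 99)
#' @param seed RNG seed
#' @param method correlation type, \code{"pearson"} or \code{"spearman"}
#' @return list of class \code{mantel_test}: \code{r}, \code{p},
#'   \code{n_perm}, \code{method}
#' @export
mantel <- function(d1, d2, n_perm = 999, seed = 1,
                   method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (n_perm < 99) stop("n_perm must be at least 99")
  l1 <- attr(d1, "Labels"); l2 <- attr(d2, "Labels")
  if (!is.null(l1) && !is.null(l2)) {
    if (!setequal(l1, l2)) {
      stop("sample sets differ: ",
           paste(c(setdiff(l1, l2), setdiff(l2, l1)), collapse = ", "))
    }
    m2 <- as.matrix(d2)[l1, l1]
  } else {
    if (attr(d1, "Size") != attr(d2, "Size")) stop("matrix sizes differ")
    m2 <- as.matrix(d2)
  }
  m1 <- as.matrix(d1)
  n <- nrow(m1)
  lt <- lower.tri(m1)
  v1 <- m1[lt]
  r_obs <- stats::cor(v1, m2[lt], method = method)
  set.seed(seed)
  r_perm <- replicate(n_perm, {
    idx <- sample.int(n)
    stats::cor(v1, m2[idx, idx][lt], method = method)
  })
  p <- (1 + sum(r_perm >= r_obs)) / (1 + n_perm)
  structure(list(r = r_obs, p = p, n_perm = n_perm, method = method),
            class = "mantel_test")
}

#' @export
print.mantel_test <- function(x, ...) {
  cat(sprintf("Mantel test (%s): r = %.4f, p = %.4g (%d permutations)\n",
              x$method, x$r, x$p, x$n_perm))
  invisible(x)
}

#' Per-factor environmental distance matrix
#'
#' Absolute pairwise difference of one environmental factor across samples.
#' Samples with a missing value for the factor are dropped (pairwise
#' exclusion), with a warning.
#'
#' @param env an \code{env_table}
#' @param factor_name column of \code{env}, e.g. \code{"SWC"}
#' @return a \code{dist} object labelled by the retained samples
#' @export
env_distance <- function(env, factor_name) {
  if (!factor_name %in% names(env)) stop("unknown factor: ", factor_name)
  x <- env[[factor_name]]
  names(x) <- env$sample
  if (anyNA(x)) {
    warning("dropping ", sum(is.na(x)), " sample(s) with missing ",
            factor_name)
    x <- x[!is.na(x)]
  }
  stats::dist(x)
}

#' Mantel panel of community dissimilarity against environmental factors
#'
#' Runs one Mantel test per factor (absolute-difference distance), dropping
#' samples with missing values for that factor from both matrices.
#'
#' @param d_comm community \code{dist} (e.g. Bray-Curtis)
#' @param env an \code{env_table} covering the community samples
#' @param factors character vector of factor columns
#' @param n_perm,seed,method passed to \code{\link{mantel}}
#' @return data.frame with columns \code{factor}, \code{r}, \code{p},
#'   \code{n}
#' @export
mantel_env <- function(d_comm, env, factors, n_perm = 999, seed = 1,
                       method = "pearson") {
  labs <- attr(d_comm, "Labels")
  mcomm <- as.matrix(d_comm)
  out <- lapply(seq_along(factors), function(i) {
    f <- factors[i]
    d_env <- suppressWarnings(env_distance(env, f))
    keep <- intersect(labs, attr(d_env, "Labels"))
    if (length(keep) < 4) stop("too few complete samples for factor ", f)
    d1 <- stats::as.dist(mcomm[keep, keep])
    d2 <- stats::as.dist(as.matrix(d_env)[keep, keep])
    mt <- mantel(d1, d2, n_perm = n_perm, seed = derive_seed(seed, i),
                 method = method)
    data.frame(factor = f, r = mt$r, p = mt$p, n = length(keep),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Great-circle distance matrix between sampling sites
#'
#' Haversine distance (Earth radius 6371 km) from decimal-degree
#' coordinates.
#'
#' @param metadata data.frame with columns \code{sample}, \code{latitude},
#'   \code{longitude} (an \code{abundance_table} metadata slot works)
#' @return a \code{dist} object in kilometres
#' @export
geo_distance <- function(metadata) {
  need <- c("latitude", "longitude")
  miss <- setdiff(need, names(metadata))
  if (length(miss)) stop("missing coordinate column(s): ",
                         paste(miss, collapse = ", "))
  if (anyNA(metadata$latitude) || anyNA(metadata$longitude)) {
    stop("missing coordinates for sample(s): ",
         paste(metadata$sample[is.na(metadata$latitude) |
                                 is.na(metadata$longitude)], collapse = ", "))
  }
  pts <- cbind(metadata$longitude, metadata$latitude)
  km <- geosphere::distm(pts, fun = function(p1, p2) {
    geosphere::distHaversine(p1, p2, r = 6371000)
  }) / 1000
  rownames(km) <- colnames(km) <- metadata$sample
  stats::as.dist(km)
}

#' Distance-decay regression of community dissimilarity on a distance
#'
#' Ordinary least squares of the pairwise community dissimilarities on the
#' pairwise predictor distances (geographic km or per-factor differences).
#' Because pairwise dissimilarities are not independent, significance is
#' assessed by Mantel-style permutation of the community matrix:
#' p = (1 + #\{|r_perm| >= |r_obs|\}) / (1 + n_perm).
#'
#' @param d_comm community \code{dist}
#' @param d_pred predictor \code{dist} over the same samples
#' @param n_perm number of permutations
#' @param seed RNG seed
#' @return list of class \code{decay_fit}: \code{slope}, \code{intercept},
#'   \code{r}, \code{p}, \code{n_pairs}; a constant predictor yields NA
#'   slope/r with \code{degenerate = TRUE} and a warning.
#' @export
distance_decay <- function(d_comm, d_pred, n_perm = 999, seed = 1) {
  l1 <- attr(d_comm, "Labels"); l2 <- attr(d_pred, "Labels")
  if (!is.null(l1) && !is.null(l2) && !setequal(l1, l2)) {
    stop("sample sets differ: ",
         paste(c(setdiff(l1, l2), setdiff(l2, l1)), collapse = ", "))
  }
  mc <- as.matrix(d_comm)
  mp <- as.matrix(d_pred)
  if (!is.null(l1) && !is.null(l2)) mp <- mp[l1, l1]
  lt <- lower.tri(mc)
  x <- mp[lt]; y <- mc[lt]
  if (stats::var(x) == 0) {
    warning("constant predictor: decay slope undefined")
    return(structure(list(slope = NA_real_, intercept = NA_real_,
                          r = NA_real_, p = NA_real_,
                          n_pairs = sum(lt), degenerate = TRUE),
                     class = "decay_fit"))
  }
  fit <- stats::lm(y ~ x)
  r_obs <- stats::cor(x, y)
  n <- nrow(mc)
  set.seed(seed)
  r_perm <- replicate(n_perm, {
    idx <- sample.int(n)
    stats::cor(x, mc[idx, idx][lt])
  })
  p <- (1 + sum(abs(r_perm) >= abs(r_obs))) / (1 + n_perm)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r = r_obs, p = p, n_pairs = sum(lt), degenerate = FALSE),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  if (isTRUE(x$degenerate)) {
    cat("distance-decay fit: degenerate (constant predictor)\n")
  } else {
    cat(sprintf(
      "distance-decay fit: slope = %.4g, r = %.3f, p = %.4g (%d pairs)\n",
      x$slope, x$r, x$p, x$n_pairs))
  }
  invisible(x)
}
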