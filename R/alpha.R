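#' Shannon-Wiener diversity index (natural log)
#'
#' H = -sum (n_i/N) ln(n_i/N) over species with positive counts; zero counts
#' contribute nothing. Reported in nats.
#'
#' @param counts non-negative abundance vector with at least one positive
#'   entry
#' @return H in nats
#' @export
shannon <- function(counts) {
  if (any(counts < 0)) stop("negative counts")
  pos <- counts[counts > 0]
  if (!length(pos)) stop("all-zero abundance vector")
  p <- pos / sum(pos)
  -sum(p * log(p))
}

#' Margalef richness index
#'
#' D = (S - 1) / ln N, with the convention D = 0 when N = 1.
#'
#' @param S number of species observed (>= 1)
#' @param N total number of individuals (>= 1)
#' @return D (unitless)
#' @export
margalef <- function(S, N) {
  if (S < 1) stop("S must be at least 1")
  if (N < 1) stop("N must be at least 1")
  if (N == 1) return(0)
  (S - 1) / log(N)
}

#' Per-sample alpha diversity
#'
#' @param ab an \code{abundance_table}
#' @param group_by optional metadata variable; when given, group means of the
#'   per-sample indices are appended as an attribute \code{"group_means"}
#'   (the convention of the soil-protist literature), or the group's pooled
#'   community is recomputed when \code{pooled = TRUE}.
#' @param pooled see \code{group_by}
#' @return data.frame with per-sample \code{H} (nats), \code{D}, \code{S},
#'   \code{N}
#' @export
alpha_diversity <- function(ab, group_by = NULL, pooled = FALSE) {
  m <- ab$counts
  res <- data.frame(
    sample = rownames(m),
    H = apply(m, 1, shannon),
    S = as.integer(rowSums(m > 0)),
    N = rowSums(m),
    stringsAsFactors = FALSE
  )
  res$D <- mapply(margalef, res$S, res$N)
  res <- res[, c("sample", "H", "D", "S", "N")]
  rownames(res) <- NULL
  if (!is.null(group_by)) {
    if (is.null(ab$metadata) || !group_by %in% names(ab$metadata)) {
      stop("metadata variable not found: ", group_by)
    }
    g <- as.character(ab$metadata[[group_by]])
    if (pooled) {
      gm <- do.call(rbind, lapply(sort(unique(g)), function(lv) {
        tot <- colSums(m[g == lv, , drop = FALSE])
        data.frame(group = lv, H = shannon(tot),
                   D = margalef(sum(tot > 0), sum(tot)),
                   S = sum(tot > 0), N = sum(tot))
      }))
    } else {
      gm <- aggregate(res[, c("H", "D", "S", "N")], list(group = g), mean)
    }
    attr(res, "group_means") <- gm
  }
  res
}

#' C/P quotient (Colpodea / polyhymenophora bioindication ratio)
#'
#' Ratio of Colpodea (r-selected colonizers of harsh soils) to the
#' "polyhymenophoran" classes Spirotrichea + Heterotrichea + Armophorea
#' (k-selected). A quotient <= 1 indicates a relatively benign, stable soil
#' habitat; > 1 a relatively poor one. The default basis is species richness
#' ("proportion of species"); an abundance basis is provided because usage in
#' the bioindication literature varies.
#'
#' @param ab an \code{abundance_table}
#' @param tax a \code{taxonomy_table} resolving the class of every species
#' @param scope \code{NULL} (all samples) or a metadata filter as in
#'   \code{\link{subset_samples}}
#' @param basis \code{"richness"} (default) or \code{"abundance"}
#' @return data.frame of class \code{cp_result}: \code{colpodea},
#'   \code{polyhymenophora}, \code{quotient}, \code{verdict} ("good" iff
#'   quotient <= 1), \code{undefined} (TRUE when the denominator is zero; the
#'   quotient is then NA, not infinity).
#' @export
cp_quotient <- function(ab, tax, scope = NULL,
                        basis = c("richness", "abundance")) {
  basis <- match.arg(basis)
  sub <- subset_samples(ab, scope)
  tx <- match_taxonomy(sub, tax)
  tot <- colSums(sub$counts)
  present <- tot > 0
  weight <- if (basis == "richness") as.numeric(present) else tot
  c_val <- sum(weight[tx$class == "Colpodea"])
  p_val <- sum(weight[tx$class %in% c("Spirotrichea", "Heterotrichea",
                                      "Armophorea")])
  undefined <- p_val == 0
  q <- if (undefined) NA_real_ else c_val / p_val
  out <- data.frame(
    scope = if (is.null(scope)) "all" else
      paste(names(scope), vapply(scope, paste, "", collapse = "|"),
            sep = "=", collapse = "; "),
    basis = basis,
    colpodea = c_val,
    polyhymenophora = p_val,
    quotient = q,
    verdict = if (undefined) NA_character_ else if (q <= 1) "good" else "poor",
    undefined = undefined,
    stringsAsFactors = FALSE
  )
  class(out) <- c("cp_result", "data.frame")
  out
}

#' Compare a per-sample statistic among groups
#'
#' Omnibus and pairwise comparisons of a per-sample index (e.g. Shannon H)
#' among ecosystems or seasons. \code{method = "anova"} runs ordinary one-way
#' ANOVA with Tukey HSD pairwise tests; \code{method = "permutation"} (the
#' recommended default for the small group sizes typical of soil surveys)
#' permutes group labels and compares the observed F statistic against the
#' permutation distribution, with pairwise two-group permutation tests
#' (Benjamini-Hochberg adjusted).
#'
#' @param values numeric per-sample statistic
#' @param groups group labels, same length
#' @param method \code{"permutation"} or \code{"anova"}
#' @param n_perm number of label permutations (>= 999 recommended)
#' @param seed RNG seed for the permutations
#' @return list with \code{statistic} (F), \code{p}, \code{pairwise}
#'   (data.frame of group pairs and p-values) and \code{method}
#' @export
compare_groups <- function(values, groups,
                           method = c("permutation", "anova"),
                           n_perm = 999, seed = 1) {
  method <- match.arg(method)
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  if (any(table(groups) < 2L)) stop("every group needs at least 2 samples")
  stopifnot(length(values) == length(groups))

  f_stat <- function(y, g) {
    n <- length(y)
    a <- nlevels(g)
    gm <- tapply(y, g, mean)
    ng <- tabulate(g)
    ssb <- sum(ng * (gm - mean(y))^2)
    ssw <- sum((y - gm[as.integer(g)])^2)
    (ssb / (a - 1)) / (ssw / (n - a))
  }

  if (method == "anova") {
    fit <- stats::aov(values ~ groups)
    an <- summary(fit)[[1]]
    pw <- stats::TukeyHSD(fit)$groups
    pairwise <- data.frame(pair = rownames(pw), p = pw[, "p adj"],
                           stringsAsFactors = FALSE, row.names = NULL)
    return(list(statistic = an$`F value`[1], p = an$`Pr(>F)`[1],
                pairwise = pairwise, method = "anova"))
  }

  # permutation route
  if (stats::var(values) == 0) {
    lv <- levels(groups)
    prs <- utils::combn(lv, 2)
    pairwise <- data.frame(pair = paste(prs[1, ], prs[2, ], sep = "-"),
                           p = 1, p_adj = 1, stringsAsFactors = FALSE)
    return(list(statistic = 0, p = 1, pairwise = pairwise,
                method = "permutation"))
  }
  set.seed(seed)
  obs <- f_stat(values, groups)
  perm <- replicate(n_perm, f_stat(values, sample(groups)))
  p <- (1 + sum(perm >= obs)) / (1 + n_perm)

  lv <- levels(groups)
  prs <- utils::combn(lv, 2)
  pw_p <- apply(prs, 2, function(pr) {
    idx <- groups %in% pr
    y <- values[idx]; g <- droplevels(groups[idx])
    if (stats::var(y) == 0) return(1)
    o <- abs(diff(tapply(y, g, mean)))
    pp <- replicate(n_perm, abs(diff(tapply(y, sample(g), mean))))
    (1 + sum(pp >= o)) / (1 + n_perm)
  })
  pairwise <- data.frame(pair = paste(prs[1, ], prs[2, ], sep = "-"),
                         p = pw_p, p_adj = stats::p.adjust(pw_p, "BH"),
                         stringsAsFactors = FALSE)
  list(statistic = obs, p = p, pairwise = pairwise, method = "permutation")
}
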