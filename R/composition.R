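#' Summarize species composition at a taxonomic rank
#'
#' Counts the distinct morphospecies under each taxon at the requested rank
#' and expresses each as a percentage of the total species inventory, the
#' standard composition panel of soil ciliate surveys.
#'
#' @param ab an \code{abundance_table}
#' @param tax a \code{taxonomy_table} covering all species of \code{ab}
#' @param rank one of \code{"genus"}, \code{"family"}, \code{"order"},
#'   \code{"class"}
#' @return data.frame with columns \code{taxon}, \code{species_count} and
#'   \code{percent} (half-up rounded to 2 decimals; sums to 100 within
#'   rounding), sorted by decreasing species count.
#' @export
summarize_composition <- function(ab, tax,
                                  rank = c("order", "class", "family", "genus")) {
  rank <- match.arg(rank)
  tx <- match_taxonomy(ab, tax)
  counts <- table(tx[[rank]])
  total <- length(species(ab))
  out <- data.frame(taxon = names(counts),
                    species_count = as.integer(counts),
                    stringsAsFactors = FALSE)
  out$percent <- round_half_up(100 * out$species_count / total, 2)
  out <- out[order(-out$species_count, out$taxon), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Exhaustive shared/exclusive species counts across groups
#'
#' Partitions the observed species by the exact set of groups (ecosystems or
#' seasons) in which they occur — the counts behind an UpSet plot. A species
#' is present in a group when its summed count over the group's samples is
#' positive.
#'
#' @param ab an \code{abundance_table} with metadata
#' @param group_by metadata variable, e.g. \code{"ecosystem"} or
#'   \code{"season"}
#' @return data.frame with one row per non-empty subset of groups:
#'   \code{subset} (group names joined by \code{" & "}), \code{degree}
#'   (subset size) and \code{n_species} (species present in exactly those
#'   groups). Rows sum to the number of species observed anywhere.
#' @export
shared_species <- function(ab, group_by) {
  if (is.null(ab$metadata) || !group_by %in% names(ab$metadata)) {
    stop("metadata variable not found: ", group_by)
  }
  g <- as.character(ab$metadata[[group_by]])
  groups <- sort(unique(g))
  if (length(groups) < 2L) stop("shared_species needs at least 2 groups")

  # presence matrix: group x species
  pres <- vapply(groups, function(lv) {
    colSums(ab$counts[g == lv, , drop = FALSE]) > 0
  }, logical(ncol(ab$counts)))
  pres <- t(pres)  # groups x species

  # enumerate all non-empty subsets
  k <- length(groups)
  subs <- expand.grid(rep(list(c(FALSE, TRUE)), k))[-1, , drop = FALSE]
  names(subs) <- groups
  pattern_of <- function(mask) paste(groups[mask], collapse = " & ")
  observed <- colSums(pres) > 0
  sp_pattern <- apply(pres[, observed, drop = FALSE], 2,
                      function(col) pattern_of(col))
  out <- data.frame(
    subset = apply(subs, 1, function(row) pattern_of(as.logical(row))),
    degree = rowSums(subs),
    stringsAsFactors = FALSE
  )
  tab <- table(sp_pattern)
  out$n_species <- as.integer(tab[out$subset])
  out$n_species[is.na(out$n_species)] <- 0L
  out <- out[order(-out$degree, out$subset), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_observed") <- sum(observed)
  out
}

#' Packaged composition inventory of a plateau river-basin ciliate survey
#'
#' Family-level inventory (class, order, family, number of genera, number of
#' species) of the 199 soil ciliate morphospecies recorded across the four
#' ecosystems of a Tibetan-plateau river-basin survey; used as a built-in
#' worked example and fixture.
#'
#' @return data.frame with columns \code{class, order, family, genera,
#'   species}
#' @export
composition_fixture <- function() {
  path <- system.file("extdata", "survey_composition.tsv",
                      package = "protistecol")
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Expand a family-level inventory into species-level tables
#'
#' Creates one pseudo-species record per counted species (presence 1 in a
#' single inventory sample) together with a matching taxonomy, so that
#' richness-based summaries (composition percentages, C/P quotient) of the
#' inventory can be computed with the ordinary table machinery. Pseudo genus
#' IDs are allocated round-robin within each family.
#'
#' @param comp data.frame as returned by \code{\link{composition_fixture}}
#' @return list with elements \code{abundance} (an \code{abundance_table}
#'   with one sample) and \code{taxonomy} (a \code{taxonomy_table})
#' @export
composition_to_tables <- function(comp) {
  rows <- lapply(seq_len(nrow(comp)), function(i) {
    r <- comp[i, ]
    n_sp <- r$species
    genus_ids <- paste0(r$family, "_G", seq_len(r$genera))
    data.frame(
      species = sprintf("%s_sp%02d", r$family, seq_len(n_sp)),
      genus = rep_len(genus_ids, n_sp),
      family = r$family, order = r$order, class = r$class,
      stringsAsFactors = FALSE
    )
  })
  tax <- taxonomy_table(do.call(rbind, rows))
  m <- matrix(1, nrow = 1, ncol = nrow(tax),
              dimnames = list("inventory", tax$species))
  list(abundance = abundance_table(m), taxonomy = tax)
}

#' Published co-occurrence network sizes of the plateau ciliate survey
#'
#' Node and edge counts of the seven co-occurrence networks (four ecosystems,
#' three seasons); inputs for the derived-degree/density arithmetic of
#' \code{\link{average_degree}} and \code{\link{network_density}}.
#'
#' @return data.frame with columns \code{network, n_nodes, n_edges}
#' @export
network_sizes_fixture <- function() {
  path <- system.file("extdata", "survey_network_sizes.tsv",
                      package = "protistecol")
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
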