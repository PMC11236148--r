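#' Construct a validated abundance table
#'
#' The central data container of the package: a sample x species matrix of
#' non-negative morphospecies counts (individuals per culture, unitless
#' integers accepted), optionally carrying per-sample metadata (ecosystem,
#' season, latitude/longitude in decimal degrees, altitude in m).
#'
#' @param counts numeric matrix, samples as rows, species as columns; row and
#'   column names are the sample and species identifiers.
#' @param metadata optional data.frame with a \code{sample} column matching
#'   the rownames of \code{counts} and any of \code{ecosystem}, \code{season},
#'   \code{latitude}, \code{longitude}, \code{altitude}.
#' @return an object of class \code{abundance_table}: a list with elements
#'   \code{counts} and \code{metadata}.
#' @export
abundance_table <- function(counts, metadata = NULL) {
  counts <- as.matrix(counts)
  if (length(counts) == 0L || nrow(counts) == 0L || ncol(counts) == 0L) {
    stop("abundance table is empty")
  }
  if (is.null(rownames(counts))) {
    rownames(counts) <- paste0("sample", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- paste0("sp", seq_len(ncol(counts)))
  }
  storage.mode(counts) <- "double"
  counts[is.na(counts)] <- 0

  dup_s <- rownames(counts)[duplicated(rownames(counts))]
  if (length(dup_s)) {
    stop("duplicate sample IDs: ", paste(unique(dup_s), collapse = ", "))
  }
  dup_sp <- colnames(counts)[duplicated(colnames(counts))]
  if (length(dup_sp)) {
    stop("duplicate species IDs: ", paste(unique(dup_sp), collapse = ", "))
  }
  neg <- which(counts < 0, arr.ind = TRUE)
  if (nrow(neg)) {
    stop(sprintf("negative count at sample '%s', species '%s'",
                 rownames(counts)[neg[1, 1]], colnames(counts)[neg[1, 2]]))
  }

  if (!is.null(metadata)) {
    metadata <- as.data.frame(metadata)
    if (!"sample" %in% names(metadata)) {
      stop("metadata must have a 'sample' column")
    }
    missing <- setdiff(rownames(counts), metadata$sample)
    if (length(missing)) {
      stop("metadata missing for samples: ", paste(missing, collapse = ", "))
    }
    metadata <- metadata[match(rownames(counts), metadata$sample), , drop = FALSE]
    rownames(metadata) <- metadata$sample
  }

  structure(list(counts = counts, metadata = metadata),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d samples x %d species\n",
              nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  total individuals: %s; species with records: %d\n",
              format(sum(x$counts), big.mark = ","),
              sum(colSums(x$counts) > 0)))
  if (!is.null(x$metadata)) {
    vars <- setdiff(names(x$metadata), "sample")
    cat("  metadata:", paste(vars, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of samples / species of an abundance table
#' @param ab an \code{abundance_table}
#' @return character vector of IDs
#' @export
samples <- function(ab) rownames(ab$counts)

#' @rdname samples
#' @export
species <- function(ab) colnames(ab$counts)

#' Subset an abundance table by a metadata filter
#'
#' @param ab an \code{abundance_table}
#' @param scope \code{NULL} (all samples) or a named list such as
#'   \code{list(ecosystem = "Wetland")}; several names are combined with AND,
#'   vector values with OR.
#' @param drop_empty drop species with zero total in the subset
#' @return an \code{abundance_table}
#' @export
subset_samples <- function(ab, scope = NULL, drop_empty = FALSE) {
  keep <- rep(TRUE, nrow(ab$counts))
  if (!is.null(scope) && length(scope)) {
    if (is.null(ab$metadata)) stop("scope filter requires sample metadata")
    for (v in names(scope)) {
      if (!v %in% names(ab$metadata)) stop("unknown metadata variable: ", v)
      keep <- keep & ab$metadata[[v]] %in% scope[[v]]
    }
  }
  if (!any(keep)) stop("scope selects no samples")
  counts <- ab$counts[keep, , drop = FALSE]
  if (drop_empty) counts <- counts[, colSums(counts) > 0, drop = FALSE]
  abundance_table(counts, if (is.null(ab$metadata)) NULL else
    ab$metadata[keep, , drop = FALSE])
}

infer_sep <- function(path) {
  if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
}

#' Read an abundance table from a delimited text file
#'
#' @param path file path (CSV or TSV; delimiter inferred from the extension
#'   unless \code{sep} is given).
#' @param sep field delimiter; \code{NULL} to infer.
#' @param orientation \code{"samples_rows"} (canonical: first column sample
#'   IDs, header species IDs) or \code{"species_rows"} (transposed on read).
#' @param metadata optional path to a metadata table (CSV/TSV with a
#'   \code{sample} column) or a data.frame.
#' @return an \code{abundance_table}; blank cells are read as 0.
#' @export
read_abundance <- function(path, sep = NULL,
                           orientation = c("samples_rows", "species_rows"),
                           metadata = NULL) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- sep %||% infer_sep(path)
  df <- tryCatch(
    utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                      row.names = NULL, stringsAsFactors = FALSE),
    error = function(e) stop("abundance table is empty or unreadable: ",
                             path, call. = FALSE))
  if (nrow(df) == 0L || ncol(df) < 2L) stop("abundance table is empty")
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    suppressWarnings(storage.mode(m) <- "double")
    if (anyNA(m) && any(!is.na(df[, -1]) & is.na(m))) {
      stop("non-numeric count values in ", path)
    }
  }
  m[is.na(m)] <- 0
  rownames(m) <- ids
  if (orientation == "species_rows") m <- t(m)
  if (is.character(metadata)) {
    metadata <- utils::read.table(metadata, sep = infer_sep(metadata),
                                  header = TRUE, stringsAsFactors = FALSE,
                                  check.names = FALSE)
  }
  abundance_table(m, metadata)
}

#' Write an abundance table (and its metadata) to delimited text
#'
#' Inverse of \code{\link{read_abundance}}: reading a written table yields an
#' identical object.
#'
#' @param ab an \code{abundance_table}
#' @param path output file path
#' @param sep field delimiter
#' @param metadata_path optional path for the metadata table
#' @return \code{path}, invisibly
#' @export
write_abundance <- function(ab, path, sep = "\t", metadata_path = NULL) {
  df <- data.frame(sample = rownames(ab$counts), ab$counts,
                   check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  if (!is.null(metadata_path) && !is.null(ab$metadata)) {
    utils::write.table(ab$metadata, metadata_path, sep = sep, quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Construct a validated taxonomy table
#'
#' Maps each morphospecies to a four-rank lineage (genus, family, order,
#' class). Ranks must be internally consistent: a family belongs to exactly
#' one order and an order to exactly one class.
#'
#' @param df data.frame with columns \code{species, genus, family, order,
#'   class}, all non-empty strings.
#' @return a \code{taxonomy_table} (validated data.frame)
#' @export
taxonomy_table <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  need <- c("species", "genus", "family", "order", "class")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("taxonomy missing columns: ", paste(miss, collapse = ", "))
  df <- df[, need]
  for (col in need) {
    df[[col]] <- as.character(df[[col]])
    if (any(is.na(df[[col]]) | !nzchar(df[[col]]))) {
      stop("empty values in taxonomy column '", col, "'")
    }
  }
  if (anyDuplicated(df$species)) {
    stop("duplicate species in taxonomy: ",
         paste(unique(df$species[duplicated(df$species)]), collapse = ", "))
  }
  fam_ord <- unique(df[, c("family", "order")])
  if (anyDuplicated(fam_ord$family)) {
    stop("inconsistent taxonomy: family mapped to more than one order: ",
         paste(unique(fam_ord$family[duplicated(fam_ord$family)]), collapse = ", "))
  }
  ord_cls <- unique(df[, c("order", "class")])
  if (anyDuplicated(ord_cls$order)) {
    stop("inconsistent taxonomy: order mapped to more than one class: ",
         paste(unique(ord_cls$order[duplicated(ord_cls$order)]), collapse = ", "))
  }
  structure(df, class = c("taxonomy_table", "data.frame"))
}

#' Read a taxonomy table (TSV with columns species,genus,family,order,class)
#' @param path file path
#' @param sep field delimiter; \code{NULL} to infer from the extension
#' @return a \code{taxonomy_table}
#' @export
read_taxonomy <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  taxonomy_table(utils::read.table(path, sep = sep %||% infer_sep(path),
                                   header = TRUE, stringsAsFactors = FALSE,
                                   check.names = FALSE))
}

# Resolve taxonomy for the species of an abundance table; error on unmapped
# species, warn about taxonomy-only species (ignored).
match_taxonomy <- function(ab, tax) {
  sp <- species(ab)
  unmapped <- setdiff(sp, tax$species)
  if (length(unmapped)) {
    stop("species without taxonomy: ", paste(unmapped, collapse = ", "))
  }
  extra <- setdiff(tax$species, sp)
  if (length(extra)) {
    warning(length(extra), " taxonomy species absent from abundance table; ignored")
  }
  tax[match(sp, tax$species), , drop = FALSE]
}

#' Construct a validated environmental-factor table
#'
#' Per-sample soil physicochemistry: SWC (soil water content, % by mass),
#' pH (unitless), TN (total nitrogen, g/kg), SOM (soil organic matter, g/kg),
#' AP (available phosphorus, mg/kg), RAK (rapid available potassium, mg/kg),
#' ST (soil surface temperature, degrees C) and altitude (m). Missing values
#' are allowed and propagate as pairwise exclusion downstream.
#'
#' @param df data.frame with a \code{sample} column and any of the factor
#'   columns above.
#' @return an \code{env_table} (validated data.frame)
#' @export
env_table <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!"sample" %in% names(df)) stop("env table must have a 'sample' column")
  if (anyDuplicated(df$sample)) stop("duplicate sample IDs in env table")
  num <- setdiff(names(df), "sample")
  for (col in num) df[[col]] <- as.numeric(df[[col]])
  chk <- function(col, lo, hi) {
    if (col %in% names(df)) {
      bad <- which(!is.na(df[[col]]) & (df[[col]] < lo | df[[col]] > hi))
      if (length(bad)) {
        stop(sprintf("%s out of range [%g, %g] for sample(s): %s", col, lo, hi,
                     paste(df$sample[bad], collapse = ", ")))
      }
    }
  }
  chk("SWC", 0, 100); chk("pH", 0, 14)
  for (col in intersect(c("TN", "SOM", "AP", "RAK"), names(df))) chk(col, 0, Inf)
  rownames(df) <- df$sample
  structure(df, class = c("env_table", "data.frame"))
}

#' Read an environmental-factor table from CSV/TSV
#' @param path file path
#' @param sep field delimiter; \code{NULL} to infer from the extension
#' @return an \code{env_table}
#' @export
read_env <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  env_table(utils::read.table(path, sep = sep %||% infer_sep(path),
                              header = TRUE, stringsAsFactors = FALSE,
                              check.names = FALSE))
}

# Check that env covers the abundance samples (env may be a superset).
match_env <- function(ab, env) {
  missing <- setdiff(samples(ab), env$sample)
  if (length(missing)) {
    stop("env table missing samples: ", paste(missing, collapse = ", "))
  }
  env[match(samples(ab), env$sample), , drop = FALSE]
}
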