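#' Run the full community-ecology pipeline
#'
#' Orchestrates the analysis end to end from a configuration (a YAML file
#' path or an equivalent nested list): table IO, alpha diversity and C/P
#' quotient, beta diversity (Bray-Curtis, NMDS, PERMANOVA), per-group
#' co-occurrence networks with topology panels, Zi-Pi keystones, Mantel /
#' distance-decay environmental drivers, and neutral-model fits. Each stage
#' writes a TSV into the output directory and everything is aggregated into
#' a machine-readable \code{results.json} (no timestamps, so identical
#' configurations produce byte-identical results).
#'
#' Configuration fields: \code{abundance} (path; required), \code{metadata},
#' \code{taxonomy}, \code{env} (paths; optional), \code{group_by}
#' (metadata variable, default \code{"ecosystem"}), \code{out_dir}
#' (required), \code{seed} (required when \code{strict}, the default),
#' \code{n_perm} (default 999), \code{network} (list of
#' \code{build_network} arguments), \code{factors} (env factors for the
#' Mantel panel). Stages whose inputs are absent (e.g. no env table) are
#' skipped with a warning and recorded under \code{skipped}; any stage
#' failure aborts with the stage name after marking the results incomplete.
#'
#' @param config path to a YAML file or a named list
#' @param strict reject configurations without an explicit seed
#' @return the results list, invisibly; side effect: files in
#'   \code{out_dir}
#' @export
run_pipeline <- function(config, strict = TRUE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  for (field in c("abundance", "out_dir")) {
    if (is.null(config[[field]])) stop("config is missing '", field, "'")
  }
  if (strict && is.null(config$seed)) {
    stop("strict mode: config must set an explicit seed")
  }
  seed <- config$seed %||% 1
  n_perm <- config$n_perm %||% 999
  group_by <- config$group_by %||% "ecosystem"
  out_dir <- config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  results <- list(config = config[setdiff(names(config), "out_dir")],
                  skipped = character(0), stages = list())
  tsv <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    name
  }
  run_stage <- function(name, fun) {
    tryCatch(fun(), error = function(e) {
      results$incomplete <- TRUE
      jsonlite::write_json(results, file.path(out_dir, "results.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  # -- tables_io ------------------------------------------------------
  ab <- run_stage("tables_io", function() {
    read_abundance(config$abundance, metadata = config$metadata)
  })
  tax <- if (!is.null(config$taxonomy)) {
    run_stage("tables_io", function() read_taxonomy(config$taxonomy))
  }
  env <- if (!is.null(config$env)) {
    run_stage("tables_io", function() read_env(config$env))
  }
  has_groups <- !is.null(ab$metadata) && group_by %in% names(ab$metadata)

  # -- alpha ----------------------------------------------------------
  run_stage("alpha", function() {
    alpha <- alpha_diversity(ab, group_by = if (has_groups) group_by)
    tsv(alpha, "alpha.tsv")
    gm <- attr(alpha, "group_means")
    if (!is.null(gm)) tsv(gm, "alpha_group_means.tsv")
    results$stages$alpha <<- list(
      file = "alpha.tsv",
      mean_H = mean(alpha$H), mean_D = mean(alpha$D),
      group_means = gm)
    if (!is.null(tax)) {
      scopes <- if (has_groups) {
        lv <- unique(ab$metadata[[group_by]])
        stats::setNames(lapply(lv, function(x) {
          s <- list(x); names(s) <- group_by; s
        }), lv)
      } else list(all = NULL)
      cp <- do.call(rbind, lapply(scopes, function(s) cp_quotient(ab, tax, s)))
      cp <- rbind(cp, cp_quotient(ab, tax, NULL))
      tsv(cp, "cp.tsv")
      results$stages$cp <<- list(file = "cp.tsv",
                                 quotients = stats::setNames(cp$quotient,
                                                             cp$scope))
    } else {
      warning("no taxonomy table: C/P stage skipped")
      results$skipped <<- c(results$skipped, "cp")
    }
  })

  # -- beta -----------------------------------------------------------
  d <- run_stage("beta", function() {
    d <- bray_curtis(ab)
    dm <- as.matrix(d)
    tsv(data.frame(sample = rownames(dm), dm, check.names = FALSE),
        "bray_curtis.tsv")
    ord <- nmds(d, seed = derive_seed(seed, 11))
    tsv(data.frame(sample = rownames(ord$points), ord$points,
                   check.names = FALSE), "nmds.tsv")
    results$stages$beta <<- list(stress = ord$stress,
                                 converged = ord$converged)
    if (has_groups) {
      pt <- permanova(d, ab$metadata[[group_by]], n_perm = n_perm,
                      seed = derive_seed(seed, 12))
      results$stages$beta$permanova <<- list(F = pt$F, p = pt$p,
                                             n_perm = pt$n_perm)
    } else {
      results$skipped <<- c(results$skipped, "permanova")
    }
    d
  })

  # -- network + keystone --------------------------------------------
  run_stage("network", function() {
    if (!has_groups) {
      results$skipped <<- c(results$skipped, "network", "keystone")
      warning("no '", group_by, "' metadata: network stage skipped")
      return(invisible(NULL))
    }
    lv <- unique(ab$metadata[[group_by]])
    topo_rows <- list()
    role_rows <- list()
    for (x in lv) {
      scope <- stats::setNames(list(x), group_by)
      net <- tryCatch(
        do.call(build_network,
                c(list(ab = ab, scope = scope,
                       seed = derive_seed(seed, 21)),
                  config$network)),
        error = function(e) {
          warning("network for ", x, " skipped: ", conditionMessage(e))
          NULL
        })
      if (is.null(net) || igraph::ecount(net$graph) == 0) next
      tp <- topology(net)
      topo_rows[[x]] <- data.frame(group = x,
                                   as.data.frame(unclass(tp)))
      roles <- zi_pi(net)
      roles$group <- x
      role_rows[[x]] <- roles
      write_network(net, file.path(out_dir, paste0("network_", gsub("\\W+", "_", x),
                                                   ".tsv")))
    }
    if (length(topo_rows)) {
      topo <- do.call(rbind, topo_rows)
      tsv(topo, "topology.tsv")
      roles <- do.call(rbind, role_rows)
      tsv(roles, "node_roles.tsv")
      ks <- classify_keystones(roles)
      tsv(ks, "keystones.tsv")
      results$stages$network <<- list(file = "topology.tsv",
                                      groups = topo$group,
                                      n_nodes = topo$n_nodes,
                                      n_edges = topo$n_edges)
      results$stages$keystone <<- list(file = "keystones.tsv",
                                       n_keystones = nrow(ks))
    } else {
      results$skipped <<- c(results$skipped, "network", "keystone")
    }
    invisible(NULL)
  })

  # -- drivers --------------------------------------------------------
  if (!is.null(env)) {
    run_stage("drivers", function() {
      factors <- config$factors %||%
        intersect(c("SWC", "pH", "TN", "SOM", "AP", "RAK", "ST"), names(env))
      mt <- mantel_env(d, env, factors, n_perm = n_perm,
                       seed = derive_seed(seed, 31))
      tsv(mt, "mantel.tsv")
      results$stages$drivers <<- list(file = "mantel.tsv",
                                      mantel = mt)
      if (all(c("latitude", "longitude") %in% names(ab$metadata %||% list()))) {
        dg <- geo_distance(ab$metadata)
        dec <- distance_decay(d, dg, n_perm = n_perm,
                              seed = derive_seed(seed, 32))
        decay <- data.frame(predictor = "geographic_km", slope = dec$slope,
                            r = dec$r, p = dec$p)
        for (i in seq_along(factors)) {
          de <- suppressWarnings(env_distance(env, factors[i]))
          keep <- intersect(attr(d, "Labels"), attr(de, "Labels"))
          dd <- distance_decay(stats::as.dist(as.matrix(d)[keep, keep]),
                               stats::as.dist(as.matrix(de)[keep, keep]),
                               n_perm = n_perm,
                               seed = derive_seed(seed, 32 + i))
          decay <- rbind(decay,
                         data.frame(predictor = factors[i], slope = dd$slope,
                                    r = dd$r, p = dd$p))
        }
        tsv(decay, "decay.tsv")
        results$stages$drivers$decay <<- decay
      }
    })
  } else {
    warning("no env table: drivers stage skipped")
    results$skipped <- c(results$skipped, "drivers")
  }

  # -- ncm ------------------------------------------------------------
  run_stage("ncm", function() {
    fits <- list(all = fit_ncm(ab))
    if (has_groups) {
      for (x in unique(ab$metadata[[group_by]])) {
        scope <- stats::setNames(list(x), group_by)
        fits[[x]] <- tryCatch(fit_ncm(ab, scope), error = function(e) NULL)
      }
      fits <- Filter(Negate(is.null), fits)
    }
    cmp <- if (length(fits) >= 2) compare_scopes(fits) else
      data.frame(scope = names(fits), m = fits[[1]]$m, Nm = fits[[1]]$Nm,
                 R2 = fits[[1]]$R2, fraction_within = fits[[1]]$fraction_within)
    tsv(cmp, "ncm_fits.tsv")
    tsv(fits[["all"]]$data, "ncm_envelope.tsv")
    results$stages$ncm <<- list(file = "ncm_fits.tsv", fits = cmp)
  })

  jsonlite::write_json(results, file.path(out_dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(results)
}
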