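#' Define a simulation scenario
#'
#' Fixes the conditions of a synthetic soil-protist survey: a regional
#' metacommunity with a skewed species-abundance distribution, local
#' communities of fixed size sampled with dispersal limitation (the
#' stationary Sloan/Hubbell approximation: Dirichlet-multinomial draws with
#' Dirichlet weights N m p_i), an optional environmental filter coupling
#' species optima to a soil-water-content gradient, and site metadata laid
#' out like a plateau river-basin survey (19 sites in four habitats,
#' three seasons).
#'
#' @param n_species metacommunity species richness (default 200)
#' @param habitats named integer vector: sites per habitat (default 4
#'   grassland + 5 farmland + 5 wetland + 5 sea buckthorn forest = 19 sites)
#' @param seasons season labels (default Spring/Summer/Autumn; each site is
#'   redrawn independently per season)
#' @param sad metacommunity species-abundance distribution:
#'   \code{"logseries"} (default; Fisher's alpha solved to give
#'   \code{n_species} at the realized survey size) or \code{"lognormal"}
#' @param sad_sdlog sdlog of the log-normal variant
#' @param migration_m migration probability in (0, 1]
#' @param community_size_N individuals per local community (default 1000)
#' @param env_filter_strength >= 0; 0 = strictly neutral; larger values
#'   narrow species' effective niches along the SWC axis
#' @param swc_ranges named list of per-habitat SWC ranges (% by mass);
#'   defaults are non-overlapping with wetland highest
#' @param env_ranges named list of (min, max) for the remaining factors
#' @param seed master seed; all randomness derives from it
#' @return object of class \code{sim_scenario}
#' @export
sim_scenario <- function(n_species = 200,
                         habitats = c(Grassland = 4, Farmland = 5,
                                      Wetland = 5,
                                      `Sea buckthorn forest` = 5),
                         seasons = c("Spring", "Summer", "Autumn"),
                         sad = c("logseries", "lognormal"),
                         sad_sdlog = 2,
                         migration_m = 0.1,
                         community_size_N = 1000,
                         env_filter_strength = 0,
                         swc_ranges = list(Grassland = c(5, 20),
                                           Farmland = c(20, 35),
                                           `Sea buckthorn forest` = c(35, 50),
                                           Wetland = c(60, 90)),
                         env_ranges = list(pH = c(6.5, 8.5), TN = c(0.5, 3),
                                           SOM = c(10, 60), AP = c(5, 40),
                                           RAK = c(50, 200), ST = c(5, 20)),
                         seed = 1) {
  sad <- match.arg(sad)
  if (migration_m <= 0 || migration_m > 1) {
    stop("migration_m must be in (0, 1]")
  }
  if (community_size_N < 1) stop("community_size_N must be >= 1")
  if (n_species < 1) stop("n_species must be >= 1")
  if (env_filter_strength < 0) stop("env_filter_strength must be >= 0")
  if (is.null(names(habitats))) stop("habitats must be a named vector")
  structure(list(n_species = n_species, habitats = habitats,
                 seasons = seasons, sad = sad, sad_sdlog = sad_sdlog,
                 migration_m = migration_m,
                 community_size_N = community_size_N,
                 env_filter_strength = env_filter_strength,
                 swc_ranges = swc_ranges, env_ranges = env_ranges,
                 seed = seed),
            class = "sim_scenario")
}

# Metacommunity relative abundances. Log-series: Fisher's alpha is solved
# from S = alpha log(1 + NT/alpha) at the realized survey size NT, then S
# abundances are drawn iid from the logarithmic distribution with
# x = NT/(NT + alpha).
metacommunity_abundances <- function(scn) {
  S <- scn$n_species
  if (scn$sad == "lognormal") {
    ab <- stats::rlnorm(S, meanlog = 0, sdlog = scn$sad_sdlog)
  } else {
    NT <- scn$community_size_N * sum(scn$habitats) * length(scn$seasons)
    alpha <- stats::uniroot(function(a) a * log(1 + NT / a) - S,
                            interval = c(1e-3, 1e6))$root
    x <- NT / (NT + alpha)
    kmax <- max(1000, ceiling(10 / (1 - x)))
    k <- seq_len(kmax)
    ab <- sample(k, S, replace = TRUE, prob = x^k / k)
  }
  p <- ab / sum(ab)
  sort(p, decreasing = TRUE)
}

# Site frame shared by both generators: site IDs, habitat, coordinates.
site_frame <- function(scn) {
  habitat <- rep(names(scn$habitats), scn$habitats)
  n_sites <- length(habitat)
  data.frame(
    site = sprintf("S%02d", seq_len(n_sites)),
    ecosystem = habitat,
    latitude = stats::runif(n_sites, 28.3, 29.3),
    longitude = stats::runif(n_sites, 88.9, 89.6),
    altitude = stats::runif(n_sites, 3830, 4800),
    stringsAsFactors = FALSE
  )
}

# Per-sample environment. SWC from the habitat's range; other factors
# uniform within env_ranges; seasons are independent redraws.
draw_env <- function(scn, sites, sample_ids, habitat_of, season_of) {
  swc <- vapply(seq_along(sample_ids), function(i) {
    rg <- scn$swc_ranges[[habitat_of[i]]] %||% range(unlist(scn$swc_ranges))
    stats::runif(1, rg[1], rg[2])
  }, 0)
  env <- data.frame(sample = sample_ids, SWC = swc,
                    stringsAsFactors = FALSE)
  for (f in names(scn$env_ranges)) {
    rg <- scn$env_ranges[[f]]
    env[[f]] <- stats::runif(length(sample_ids), rg[1], rg[2])
  }
  env$altitude <- sites$altitude[match(sub("_.*$", "", sample_ids),
                                       sites$site)]
  env
}

# Dirichlet-multinomial local community: Dirichlet weights N m p, then a
# multinomial of community_size_N individuals.
draw_community <- function(p_local, Nm, size) {
  shape <- Nm * p_local
  w <- stats::rgamma(length(shape), shape = shape, rate = 1)
  if (sum(w) == 0) w[which.max(shape)] <- 1
  as.integer(stats::rmultinom(1, size = size, prob = w / sum(w)))
}

simulate_core <- function(scn, filtered) {
  # Phase A (seed substream 1): metacommunity, sites, environment, optima.
  set.seed(derive_seed(scn$seed, 1))
  p <- metacommunity_abundances(scn)
  species_ids <- sprintf("sp%03d", seq_along(p))
  sites <- site_frame(scn)
  grid <- expand.grid(site = sites$site, season = scn$seasons,
                      stringsAsFactors = FALSE)
  sample_ids <- paste(grid$site, grid$season, sep = "_")
  habitat_of <- sites$ecosystem[match(grid$site, sites$site)]
  env <- draw_env(scn, sites, sample_ids, habitat_of, grid$season)
  swc_all <- unlist(scn$swc_ranges)
  swc_span <- max(swc_all) - min(swc_all)
  optima <- stats::runif(length(p), min(swc_all), max(swc_all))

  # Phase B (seed substream 2): local community draws. Consumes the same
  # RNG stream for any filter strength, so strength 0 reproduces the
  # neutral draw exactly.
  set.seed(derive_seed(scn$seed, 2))
  Nm <- scn$community_size_N * scn$migration_m
  counts <- matrix(0L, nrow = length(sample_ids), ncol = length(p),
                   dimnames = list(sample_ids, species_ids))
  for (i in seq_along(sample_ids)) {
    if (filtered && scn$env_filter_strength > 0) {
      kern <- exp(-scn$env_filter_strength *
                    ((env$SWC[i] - optima) / swc_span)^2)
      p_local <- p * kern
      p_local <- p_local / sum(p_local)
    } else {
      p_local <- p
    }
    counts[i, ] <- draw_community(p_local, Nm, scn$community_size_N)
  }

  metadata <- data.frame(sample = sample_ids,
                         ecosystem = habitat_of,
                         season = grid$season,
                         latitude = sites$latitude[match(grid$site, sites$site)],
                         longitude = sites$longitude[match(grid$site, sites$site)],
                         altitude = sites$altitude[match(grid$site, sites$site)],
                         stringsAsFactors = FALSE)
  ab <- abundance_table(counts, metadata)
  truth <- list(m = scn$migration_m, N = scn$community_size_N,
                Nm = Nm, metacommunity = stats::setNames(p, species_ids),
                optima = stats::setNames(optima, species_ids),
                env_filter_strength = if (filtered) scn$env_filter_strength
                else 0)
  list(abundance = ab, env = env_table(env), truth = truth)
}

#' Simulate a strictly neutral community survey
#'
#' Every local community is a Dirichlet-multinomial draw with Dirichlet
#' weights N m p_i around the shared metacommunity, so a species with
#' metacommunity frequency p has occurrence statistics governed by the Sloan
#' beta model with parameter N m. Per-sample totals equal
#' \code{community_size_N} exactly; output is reproducible under the
#' scenario seed.
#'
#' @param scn a \code{sim_scenario}
#' @return an \code{abundance_table} with metadata; the generating truth
#'   (m, N, Nm, metacommunity abundances) is attached as
#'   \code{attr(, "truth")}
#' @export
simulate_neutral <- function(scn) {
  out <- simulate_core(scn, filtered = FALSE)
  ab <- out$abundance
  attr(ab, "truth") <- out$truth
  ab
}

#' Simulate an environmentally filtered community survey
#'
#' As \code{\link{simulate_neutral}}, but species carry Gaussian niche
#' optima on the soil-water-content axis and each site's expected
#' composition is the metacommunity weighted by the niche kernel
#' exp(-w ((SWC - optimum)/range)^2), renormalized before the
#' Dirichlet-multinomial draw. With \code{env_filter_strength = 0} the
#' output equals \code{simulate_neutral} under the same seed.
#'
#' @param scn a \code{sim_scenario} (typically with
#'   \code{env_filter_strength > 0})
#' @return list with \code{abundance} (an \code{abundance_table}),
#'   \code{env} (an \code{env_table}) and \code{truth} (generating
#'   parameters incl. species optima)
#' @export
simulate_filtered <- function(scn) {
  simulate_core(scn, filtered = TRUE)
}

#' Write a simulated dataset to a directory
#'
#' Emits abundance.csv, env.csv, metadata.csv and truth.json.
#'
#' @param scn a \code{sim_scenario}
#' @param dir output directory (created if needed)
#' @return \code{dir}, invisibly
#' @export
write_simulation <- function(scn, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  out <- simulate_filtered(scn)
  write_abundance(out$abundance, file.path(dir, "abundance.csv"), sep = ",",
                  metadata_path = file.path(dir, "metadata.csv"))
  utils::write.table(out$env, file.path(dir, "env.csv"), sep = ",",
                     quote = FALSE, row.names = FALSE)
  truth <- out$truth
  truth$metacommunity <- as.list(truth$metacommunity)
  truth$optima <- as.list(truth$optima)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
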