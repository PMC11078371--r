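#' Define a synthetic survey scenario
#'
#' Bundles every knob of the synthetic community generator: taxonomy sizes,
#' station count and bounding box, environmental field parameters, niche
#' widths, dispersal limitation and the seed.  Defaults mirror a
#' continental-shelf polychaete survey: 61 stations, 173 species in 40
#' families within one class, a west--east sedimentary/thermal gradient
#' across the bounding box, spatially autocorrelated environmental noise,
#' and occupancy shaped by both environmental filtering and
#' distance-limited dispersal from a species' home station.
#'
#' Environmental fields are generated as
#' `mean + slope * (lon - mid) + GRF(range_km, sd_spatial) + N(0, sd_noise)`
#' where GRF is a Gaussian random field with exponential covariance; the
#' raw sand score is pushed through a logistic to a [0, 1] sand fraction.
#'
#' @param n_stations number of stations (default 61).
#' @param n_species,n_genera,n_families taxonomy sizes (one class).
#' @param bbox named vector `lon_min, lon_max, lat_min, lat_max` in decimal
#'   degrees; default 97.1--89.7 W, 18.5--22.3 N.
#' @param env list of per-variable field parameters; each element is a list
#'   `mean, slope, range_km, sd_spatial, sd_noise` (slope per degree of
#'   longitude).  Variables `depth`, `temperature`, `salinity` are emitted
#'   as-is; `sand` is logistic-transformed to a fraction.
#' @param niche_tolerance niche width (sd, in z-score units of each
#'   environmental variable); `Inf` switches environmental filtering off.
#' @param dispersal_rate decay rate per km of the dispersal kernel;
#'   0 switches dispersal limitation off.
#' @param dispersal_amp logit-scale amplitude of the dispersal penalty.
#' @param baseline_logit occupancy on the logit scale for a species at its
#'   home station under a perfect niche match (default 2).  Niche and
#'   dispersal penalties only subtract from it, so under the default
#'   penalties the realized marginal occupancy is roughly 0.15--0.2,
#'   giving shelf-survey richness per station; with filtering switched off
#'   (`niche_tolerance = Inf`, `dispersal_rate = 0`) occupancy is iid
#'   Bernoulli(plogis(baseline_logit)).
#' @param seed integer seed.
#' @return Object of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(n_stations = 61, n_species = 173,
                               n_genera = 80, n_families = 40,
                               bbox = c(lon_min = -97.1, lon_max = -89.7,
                                        lat_min = 18.5, lat_max = 22.3),
                               env = NULL,
                               niche_tolerance = 1.5,
                               dispersal_rate = 0.004,
                               dispersal_amp = 3,
                               baseline_logit = 2,
                               seed = 1L) {
  if (is.null(env)) {
    env <- list(
      depth = list(mean = 60, slope = 0, range_km = 100,
                   sd_spatial = 25, sd_noise = 8),
      temperature = list(mean = 22.5, slope = 0.45, range_km = 150,
                         sd_spatial = 1.2, sd_noise = 0.3),
      salinity = list(mean = 36.3, slope = 0.06, range_km = 150,
                      sd_spatial = 0.35, sd_noise = 0.08),
      sand = list(mean = 0, slope = 0.85, range_km = 120,
                  sd_spatial = 1, sd_noise = 0.3))
  }
  bbox <- unlist(bbox)
  if (is.null(names(bbox)) || !all(c("lon_min", "lon_max", "lat_min",
                                     "lat_max") %in% names(bbox))) {
    names(bbox) <- c("lon_min", "lon_max", "lat_min", "lat_max")
  }
  stopifnot(n_stations >= 1, n_species >= 1, n_genera >= 1,
            n_families >= 1, n_genera >= n_families,
            n_species >= n_genera, niche_tolerance > 0,
            dispersal_rate >= 0, dispersal_amp >= 0)
  structure(list(n_stations = as.integer(n_stations),
                 n_species = as.integer(n_species),
                 n_genera = as.integer(n_genera),
                 n_families = as.integer(n_families),
                 bbox = bbox, env = env,
                 niche_tolerance = niche_tolerance,
                 dispersal_rate = dispersal_rate,
                 dispersal_amp = dispersal_amp,
                 baseline_logit = baseline_logit,
                 seed = as.integer(seed)),
            class = "synthetic_scenario")
}

#' @export
print.synthetic_scenario <- function(x, ...) {
  cat(sprintf("Synthetic scenario: %d stations, %d species / %d genera / %d families\n",
              x$n_stations, x$n_species, x$n_genera, x$n_families))
  cat(sprintf("niche tolerance %.2f sd, dispersal rate %.4f /km (amp %.1f), baseline logit %.2f, seed %d\n",
              x$niche_tolerance, x$dispersal_rate, x$dispersal_amp,
              x$baseline_logit, x$seed))
  invisible(x)
}

#' Generate a strict-tree synthetic taxonomy
#'
#' Genera are assigned to families and species to genera uniformly at
#' random subject to every family holding at least one genus and every
#' genus at least one species, so the requested counts are met exactly and
#' the strict-tree invariant holds by construction.
#'
#' @param scenario a [synthetic_scenario()].
#' @return A validated taxonomy data.frame (species, genus, family, class).
#' @export
gen_taxonomy <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(scenario$seed)
  nf <- scenario$n_families; ng <- scenario$n_genera
  ns <- scenario$n_species
  fam_of_gen <- c(seq_len(nf),
                  sample.int(nf, ng - nf, replace = TRUE))
  gen_of_sp <- c(seq_len(ng),
                 sample.int(ng, ns - ng, replace = TRUE))
  tab <- data.frame(
    species = sprintf("Species_%03d", seq_len(ns)),
    genus = sprintf("Genus_%03d", gen_of_sp),
    family = sprintf("Family_%03d", fam_of_gen[gen_of_sp]),
    class = "Classa",
    stringsAsFactors = FALSE)
  validate_taxonomy(tab)
}

# Gaussian random field with exponential covariance on great-circle
# distances; returns one draw per station.
grf_exponential <- function(geo_km, range_km, sd) {
  if (sd <= 0) return(rep(0, nrow(geo_km)))
  cov <- sd^2 * exp(-geo_km / range_km)
  ch <- chol(cov + diag(1e-8 * sd^2, nrow(geo_km)))
  drop(crossprod(ch, stats::rnorm(nrow(geo_km))))
}

#' Generate station coordinates and environment
#'
#' Stations are placed uniformly in the bounding box.  Each environmental
#' variable is a longitude gradient plus a spatially autocorrelated
#' Gaussian field (exponential covariance with the stated range) plus
#' white noise; the sand score is mapped through a logistic to a [0, 1]
#' fraction.  Stations are also labelled with a true sedimentary region
#' (terrigenous / transitional / carbonate analogue) by longitude thirds.
#'
#' @param scenario a [synthetic_scenario()].
#' @return data.frame: station, lon, lat, one column per environmental
#'   variable, and `region` (the generating truth label).
#' @export
gen_stations_env <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(scenario$seed + 1L)
  n <- scenario$n_stations
  bb <- scenario$bbox
  lon <- stats::runif(n, bb["lon_min"], bb["lon_max"])
  lat <- stats::runif(n, bb["lat_min"], bb["lat_max"])
  st <- data.frame(station = sprintf("st%03d", seq_len(n)),
                   lon = lon, lat = lat, stringsAsFactors = FALSE)
  geo <- unclass(geo_distance_matrix(st))
  mid <- mean(bb[c("lon_min", "lon_max")])
  for (v in names(scenario$env)) {
    p <- scenario$env[[v]]
    field <- p$mean + p$slope * (lon - mid) +
      grf_exponential(geo, p$range_km, p$sd_spatial) +
      stats::rnorm(n, 0, p$sd_noise)
    st[[v]] <- if (v == "sand") stats::plogis(field) else field
  }
  if ("depth" %in% names(st)) st$depth <- pmax(st$depth, 5)
  cuts <- bb["lon_min"] + diff(bb[c("lon_min", "lon_max")]) * c(1, 2) / 3
  st$region <- cut(lon, c(-Inf, cuts, Inf),
                   labels = c("terrigenous", "transitional", "carbonate"))
  st
}

#' Generate presence/absence communities with known structure
#'
#' Occupancy of species s at station k follows a Bernoulli draw with
#' probability
#' `plogis(baseline - sum_v (z_vk - opt_sv)^2 / (2 tol^2)
#'         + amp * (exp(-rate * d_k,home_s) - 1))`,
#' where z are z-scored environmental variables, optima are drawn per
#' species, and the dispersal penalty is zero at the species' random home
#' station and approaches `-amp` far from it.  With `tol = Inf` and
#' `rate = 0` this collapses to iid Bernoulli(plogis(baseline)).  Draws
#' producing empty stations are regenerated (up to 10 attempts) with a
#' warning.
#'
#' @param taxonomy taxonomy table from [gen_taxonomy()].
#' @param stations station table from [gen_stations_env()].
#' @param scenario the generating [synthetic_scenario()].
#' @return list: `community` (station x species 0/1 matrix), `truth`
#'   (list: occupancy probability matrix, species optima, home stations,
#'   region labels, scenario).
#' @export
gen_communities <- function(taxonomy, stations, scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(scenario$seed + 2L)
  sp <- taxonomy$species
  ns <- length(sp)
  n <- nrow(stations)
  env_vars <- intersect(names(scenario$env), names(stations))
  z <- scale(as.matrix(stations[env_vars]))
  z[is.nan(z)] <- 0                      # constant fields carry no signal
  tol <- scenario$niche_tolerance
  geo <- unclass(geo_distance_matrix(stations))
  opt <- matrix(stats::rnorm(ns * length(env_vars)), ns,
                dimnames = list(sp, env_vars))
  home <- sample.int(n, ns, replace = TRUE)
  logit <- matrix(scenario$baseline_logit, n, ns,
                  dimnames = list(stations$station, sp))
  if (is.finite(tol)) {
    for (v in seq_along(env_vars)) {
      logit <- logit - outer(z[, v], opt[, v], "-")^2 / (2 * tol^2)
    }
  }
  if (scenario$dispersal_rate > 0 && scenario$dispersal_amp > 0) {
    dist_home <- geo[, home, drop = FALSE]          # n x ns
    logit <- logit + scenario$dispersal_amp *
      (exp(-scenario$dispersal_rate * dist_home) - 1)
  }
  prob <- stats::plogis(logit)
  for (attempt in seq_len(10)) {
    comm <- matrix(stats::rbinom(length(prob), 1, prob), n,
                   dimnames = dimnames(prob))
    if (all(rowSums(comm) > 0) && all(colSums(comm) >= 0)) break
    if (attempt == 10) {
      warning("empty stations persisted after 10 redraws; keeping last draw",
              call. = FALSE)
    } else {
      warning("redrawing communities: empty station in draw ", attempt,
              call. = FALSE)
    }
  }
  truth <- list(occupancy_prob = prob, optima = opt,
                home_station = stations$station[home],
                region = stations$region, scenario = scenario)
  list(community = comm, truth = truth)
}

#' Simulate a full synthetic survey
#'
#' Convenience wrapper chaining [gen_taxonomy()], [gen_stations_env()] and
#' [gen_communities()].
#'
#' @param scenario a [synthetic_scenario()].
#' @return list: `taxonomy`, `stations`, `community`, `truth`.
#' @export
simulate_survey <- function(scenario = synthetic_scenario()) {
  tax <- gen_taxonomy(scenario)
  st <- gen_stations_env(scenario)
  cm <- gen_communities(tax, st, scenario)
  list(taxonomy = tax, stations = st, community = cm$community,
       truth = cm$truth)
}
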