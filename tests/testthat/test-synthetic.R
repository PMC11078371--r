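test_that("gen_taxonomy hits the requested sizes and is deterministic", {
  sc <- synthetic_scenario(n_species = 8, n_genera = 4, n_families = 2,
                           seed = 3)
  tax <- gen_taxonomy(sc)
  expect_equal(nrow(tax), 8)
  expect_equal(length(unique(tax$genus)), 4)
  expect_equal(length(unique(tax$family)), 2)
  expect_equal(length(unique(tax$class)), 1)
  expect_identical(tax, gen_taxonomy(sc))
  # default scenario mirrors the study scale
  sc_def <- synthetic_scenario()
  expect_equal(sc_def$n_stations, 61)
  expect_equal(sc_def$n_species, 173)
  expect_equal(sc_def$n_families, 40)
  # large instance stays a strict tree (validate_taxonomy re-checks)
  big <- gen_taxonomy(synthetic_scenario(n_species = 200, n_genera = 90,
                                         n_families = 40, seed = 1))
  expect_equal(nrow(big), 200)
  expect_silent(validate_taxonomy(big))
  expect_error(synthetic_scenario(n_species = 5, n_genera = 10,
                                  n_families = 2), "n_species")
})

test_that("environmental fields honour gradient, noise and bounds", {
  # zero slope and zero noise: constant field
  sc <- synthetic_scenario(n_stations = 12, n_species = 10, n_genera = 5,
                           n_families = 2, seed = 4,
                           env = list(depth = list(mean = 50, slope = 0,
                                                   range_km = 100,
                                                   sd_spatial = 0,
                                                   sd_noise = 0)))
  st <- gen_stations_env(sc)
  expect_equal(st$depth, rep(50, 12))
  bb <- sc$bbox
  expect_true(all(st$lon >= bb["lon_min"] & st$lon <= bb["lon_max"]))
  expect_true(all(st$lat >= bb["lat_min"] & st$lat <= bb["lat_max"]))
  # sand fraction is a logistic transform, bounded in [0, 1]
  st2 <- gen_stations_env(synthetic_scenario(n_stations = 40, seed = 5))
  expect_true(all(st2$sand >= 0 & st2$sand <= 1))
  expect_true(all(levels(st2$region) ==
                    c("terrigenous", "transitional", "carbonate")))
})

test_that("generated fields carry the stated autocorrelation range", {
  # empirical exponential-correlation range recovered within 25% on
  # average over seeds (single-field variogram estimates are noisy)
  range_true <- 120
  est <- vapply(1:20, function(seed) {
    sc <- synthetic_scenario(
      n_stations = 70, seed = seed,
      env = list(depth = list(mean = 0, slope = 0, range_km = range_true,
                              sd_spatial = 1, sd_noise = 0)))
    st <- gen_stations_env(sc)
    geo <- unclass(geo_distance_matrix(st))
    f <- st$depth
    ut <- upper.tri(geo)
    # moment estimator: fit gamma(d) = s2 * (1 - exp(-d/r)) by least squares
    sv <- 0.5 * outer(f, f, "-")^2
    obj <- function(p) {
      sum((sv[ut] - p[2] * (1 - exp(-geo[ut] / p[1])))^2)
    }
    optim(c(100, var(f)), obj, method = "L-BFGS-B",
          lower = c(5, 1e-4))$par[1]
  }, numeric(1))
  expect_lt(abs(mean(est) - range_true) / range_true, 0.25)
})

test_that("niche-neutral, dispersal-free occupancy is iid Bernoulli", {
  sc <- synthetic_scenario(n_stations = 40, n_species = 60, n_genera = 30,
                           n_families = 15, niche_tolerance = Inf,
                           dispersal_rate = 0, baseline_logit = -1,
                           seed = 6)
  sim <- simulate_survey(sc)
  p <- plogis(-1)
  expect_true(all(sim$truth$occupancy_prob == p))
  n_draw <- length(sim$community)
  phat <- mean(sim$community)
  se <- sqrt(p * (1 - p) / n_draw)
  expect_lt(abs(phat - p), 4 * se)
})

test_that("two-region niche structure is recovered by theta+ clustering", {
  # tight tolerances + a saturating (step-like) sand gradient: the logistic
  # pushes sand to ~0 west and ~1 east of the bounding-box midline, so the
  # generating region of every station is known exactly
  recovered <- vapply(1:10, function(seed) {
    sc <- synthetic_scenario(
      n_stations = 30, n_species = 120, n_genera = 60, n_families = 30,
      niche_tolerance = 0.3, dispersal_rate = 0, baseline_logit = 3.5,
      seed = seed,
      env = list(sand = list(mean = 0, slope = 30, range_km = 1e4,
                             sd_spatial = 0, sd_noise = 0.05)))
    sim <- suppressWarnings(simulate_survey(sc))
    mid <- mean(sc$bbox[c("lon_min", "lon_max")])
    two_region <- ifelse(sim$stations$lon > mid, 2, 1)
    om <- tax_path_lengths(sim$taxonomy)
    keep <- rowSums(sim$community) >= 5
    th <- theta_plus_matrix(sim$community[keep, ], om)
    cl <- cut_assemblages(ward_cluster(th), 2)
    adjusted_rand(cl$labels, two_region[keep])
  }, numeric(1))
  expect_gt(mean(recovered), 0.8)
})

test_that("dispersal limitation induces distance decay that scales with rate", {
  # rates chosen so the kernel range (1/rate = 500-2000 km) stays at or
  # above the typical station spacing; far steeper kernels degenerate to
  # spatially unresolvable site-level noise
  rates <- c(0.0005, 0.001, 0.002)
  slopes <- vapply(seq_along(rates), function(i) {
    b <- vapply(1:4, function(seed) {
      sc <- synthetic_scenario(
        n_stations = 25, n_species = 60, n_genera = 30, n_families = 15,
        niche_tolerance = Inf, dispersal_rate = rates[i],
        dispersal_amp = 4, baseline_logit = 2, seed = seed * 10 + i)
      sim <- suppressWarnings(simulate_survey(sc))
      om <- tax_path_lengths(sim$taxonomy)
      keep <- rowSums(sim$community) >= 2
      th <- theta_plus_matrix(sim$community[keep, ], om)
      geo <- geo_distance_matrix(sim$stations[keep, ])
      fit_decay(th, geo)$b
    }, numeric(1))
    mean(b)
  }, numeric(1))
  expect_true(all(slopes > 0))
  expect_gt(cor(rates, slopes, method = "spearman"), 0)
})
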