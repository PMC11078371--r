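#' Average taxonomic distinctness of a species set
#'
#' Delta+ is the mean taxonomic path length over all unordered pairs of
#' species present in a sample,
#' \deqn{\Delta^+ = \frac{\sum\sum_{i<j} \omega_{ij}}{S(S-1)/2},}
#' where S is the species richness.  Being presence/absence based it is
#' largely independent of sampling effort, which is what makes the
#' randomization funnel test possible.
#'
#' @param species character vector of species names present in the sample.
#' @param omega path-length matrix from [tax_path_lengths()].
#' @return Scalar Delta+ on the omega scale (0--`scale_max`).
#' @seealso [lambda_plus()], [build_funnel()]
#' @export
delta_plus <- function(species, omega) {
  sub <- omega_subset(omega, species)
  s <- nrow(sub)
  if (s < 2L) {
    stop("delta_plus undefined for fewer than 2 species", call. = FALSE)
  }
  sum(sub[upper.tri(sub)]) / (s * (s - 1) / 2)
}

#' Variation in taxonomic distinctness of a species set
#'
#' Lambda+ is the variance of the pairwise path lengths about Delta+,
#' \deqn{\Lambda^+ = \frac{\sum\sum_{i<j} (\omega_{ij}-\Delta^+)^2}{S(S-1)/2}.}
#' The deviations must be squared: the raw mean deviation is identically
#' zero by construction.  Lambda+ is zero for any two-species sample and for
#' any sample in which all pairs sit at the same taxonomic distance.
#'
#' @inheritParams delta_plus
#' @return Scalar Lambda+ in squared omega units.
#' @export
lambda_plus <- function(species, omega) {
  sub <- omega_subset(omega, species)
  s <- nrow(sub)
  if (s < 2L) {
    stop("lambda_plus undefined for fewer than 2 species", call. = FALSE)
  }
  w <- sub[upper.tri(sub)]
  mean((w - mean(w))^2)
}

#' Per-station taxonomic distinctness
#'
#' Computes richness, Delta+ and Lambda+ for every station of a
#' presence/absence community matrix.  Stations with fewer than two species
#' get NA for both statistics and are flagged, not dropped.
#'
#' @param comm station x species matrix with 0/1 entries and dimnames.
#' @param omega path-length matrix covering every species column.
#' @return data.frame with columns `station`, `S`, `delta_plus`,
#'   `lambda_plus`.
#' @export
taxonomic_distinctness <- function(comm, omega) {
  comm <- validate_community(comm, rownames(omega))
  out <- data.frame(station = rownames(comm),
                    S = as.integer(rowSums(comm > 0)),
                    delta_plus = NA_real_, lambda_plus = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(comm))) {
    sp <- colnames(comm)[comm[i, ] > 0]
    if (length(sp) >= 2L) {
      out$delta_plus[i] <- delta_plus(sp, omega)
      out$lambda_plus[i] <- lambda_plus(sp, omega)
    }
  }
  low <- out$station[out$S < 2L]
  if (length(low)) {
    message("stations with S < 2 reported as NA: ",
            paste(low, collapse = ", "))
  }
  out
}

# Basic checks shared by every consumer of a community matrix.
validate_community <- function(comm, taxonomy_species = NULL,
                               allow_empty = FALSE) {
  comm <- as.matrix(comm)
  if (is.null(rownames(comm)) || is.null(colnames(comm))) {
    stop("community matrix needs station row names and species column names",
         call. = FALSE)
  }
  if (!all(comm %in% c(0, 1))) {
    stop("community matrix must be binary 0/1", call. = FALSE)
  }
  if (!is.null(taxonomy_species)) {
    missing <- setdiff(colnames(comm), taxonomy_species)
    if (length(missing)) {
      stop("species missing from taxonomy: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  if (!allow_empty && any(rowSums(comm) == 0)) {
    warning("all-zero station(s): ",
            paste(rownames(comm)[rowSums(comm) == 0], collapse = ", "),
            call. = FALSE)
  }
  storage.mode(comm) <- "double"
  comm
}

#' Randomization confidence funnel for Delta+ or Lambda+
#'
#' Simulates the null distribution of a distinctness statistic for random
#' subsets of each size m drawn uniformly without replacement from a master
#' species list, and records the simulated mean and the central
#' `1 - alpha` percentile envelope.  Observed stations whose statistic
#' falls outside the envelope at their richness are more (above) or less
#' (below) taxonomically structured than expected from the master list.
#'
#' @param master_taxonomy taxonomy table for the master species list, or a
#'   precomputed [tax_path_lengths()] matrix.
#' @param statistic `"delta_plus"` or `"lambda_plus"`.
#' @param m_grid integer vector of subset sizes (each in `[2, S_total]`).
#' @param n_sim random subsets per m (default 1000; values below 100 warn).
#' @param alpha envelope tail mass (default 0.05 for a 95% funnel).
#' @param seed integer seed; the result is deterministic given it.
#' @param weights step weights, used when `master_taxonomy` is a table.
#' @return Object of class `funnel`: data.frame `grid` (m, mean, lower,
#'   upper), the full-list value `theoretical_mean`, plus `statistic`,
#'   `n_sim`, `alpha`, `seed`.
#' @export
build_funnel <- function(master_taxonomy,
                         statistic = c("delta_plus", "lambda_plus"),
                         m_grid = NULL, n_sim = 1000, alpha = 0.05,
                         seed = 1L, weights = tax_step_weights()) {
  statistic <- match.arg(statistic)
  omega <- if (inherits(master_taxonomy, "path_lengths")) master_taxonomy
           else tax_path_lengths(master_taxonomy, weights)
  s_total <- nrow(omega)
  if (is.null(m_grid)) m_grid <- 2:s_total
  m_grid <- sort(unique(as.integer(m_grid)))
  if (any(m_grid < 2L) || any(m_grid > s_total)) {
    stop("m_grid must lie within [2, ", s_total, "]", call. = FALSE)
  }
  if (n_sim < 100) warning("n_sim < 100 gives unstable funnel limits",
                           call. = FALSE)
  stat_fun <- if (statistic == "delta_plus") delta_plus else lambda_plus
  species <- rownames(omega)
  full_value <- stat_fun(species, omega)

  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  grid <- data.frame(m = m_grid, mean = NA_real_, lower = NA_real_,
                     upper = NA_real_)
  for (r in seq_along(m_grid)) {
    m <- m_grid[r]
    if (m == s_total) {
      grid$mean[r] <- grid$lower[r] <- grid$upper[r] <- full_value
      next
    }
    vals <- vapply(seq_len(n_sim), function(i) {
      stat_fun(sample(species, m), omega)
    }, numeric(1))
    grid$mean[r] <- mean(vals)
    q <- stats::quantile(vals, c(alpha / 2, 1 - alpha / 2), names = FALSE)
    grid$lower[r] <- q[1]
    grid$upper[r] <- q[2]
  }
  structure(list(grid = grid, theoretical_mean = full_value,
                 statistic = statistic, n_sim = n_sim, alpha = alpha,
                 seed = as.integer(seed), s_total = s_total),
            class = "funnel")
}

#' @export
print.funnel <- function(x, ...) {
  cat(sprintf("%s funnel: %d sizes m in [%d, %d], n_sim = %d, %g%% limits\n",
              x$statistic, nrow(x$grid), min(x$grid$m), max(x$grid$m),
              x$n_sim, 100 * (1 - x$alpha)))
  cat(sprintf("full-list value: %.4f\n", x$theoretical_mean))
  invisible(x)
}

# Linear interpolation of funnel limits between grid points.
funnel_limits_at <- function(funnel, m) {
  g <- funnel$grid
  if (any(m < min(g$m)) || any(m > max(g$m))) {
    stop("station richness outside funnel grid [", min(g$m), ", ", max(g$m),
         "]; rebuild the funnel with a wider m_grid", call. = FALSE)
  }
  data.frame(m = m,
             lower = stats::approx(g$m, g$lower, xout = m)$y,
             upper = stats::approx(g$m, g$upper, xout = m)$y,
             mean = stats::approx(g$m, g$mean, xout = m)$y)
}

#' Classify stations against a confidence funnel
#'
#' Labels each station `below`, `inside` or `above` the funnel envelope at
#' its own richness (limits interpolated linearly between grid sizes).
#' Stations with undefined statistics (S < 2) get NA.
#'
#' @param results data.frame from [taxonomic_distinctness()].
#' @param funnel a [build_funnel()] result; its `statistic` selects which
#'   column of `results` is compared.
#' @return `results` with extra columns `lower`, `upper` and `funnel_class`
#'   (factor with levels below/inside/above).
#' @export
classify_stations <- function(results, funnel) {
  stopifnot(inherits(funnel, "funnel"))
  value <- results[[funnel$statistic]]
  out <- results
  out$lower <- NA_real_
  out$upper <- NA_real_
  out$funnel_class <- factor(rep(NA_character_, nrow(out)),
                             levels = c("below", "inside", "above"))
  ok <- !is.na(value)
  if (any(ok)) {
    lim <- funnel_limits_at(funnel, results$S[ok])
    out$lower[ok] <- lim$lower
    out$upper[ok] <- lim$upper
    cls <- ifelse(value[ok] < lim$lower, "below",
                  ifelse(value[ok] > lim$upper, "above", "inside"))
    out$funnel_class[ok] <- cls
  }
  out
}

# Save/restore .Random.seed so seeded helpers do not clobber the caller's
# RNG stream.
get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}
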