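#' Taxonomic dissimilarity between two samples
#'
#' Theta+ is a presence/absence beta-diversity coefficient built on the
#' taxonomic path-length matrix: each species is matched to its nearest
#' relative in the other sample and the directed minima are averaged.  The
#' default "pooled" form is
#' \deqn{\theta^+(A,B) = \frac{\sum_{i \in A}\min_{j \in B}\omega_{ij} +
#'   \sum_{j \in B}\min_{i \in A}\omega_{ij}}{S_A + S_B};}
#' `method = "average"` instead averages the two directed means with equal
#' weight regardless of richness.  Shared species contribute zero, so
#' theta+ is 0 exactly when the two samples are identical as sets, and it
#' never exceeds the maximal path length.
#'
#' @param sample_a,sample_b character vectors of species names (non-empty).
#' @param omega path-length matrix from [tax_path_lengths()].
#' @param method `"pooled"` (richness-weighted, default) or `"average"`.
#' @return Scalar dissimilarity on the omega scale.
#' @export
theta_plus <- function(sample_a, sample_b, omega,
                       method = c("pooled", "average")) {
  method <- match.arg(method)
  a <- unique(as.character(sample_a))
  b <- unique(as.character(sample_b))
  if (length(a) == 0L || length(b) == 0L) {
    stop("theta_plus undefined for empty samples", call. = FALSE)
  }
  sub <- omega_subset(omega, union(a, b))
  cross <- sub[a, b, drop = FALSE]
  min_a <- apply(cross, 1, min)   # nearest relative in B for each i in A
  min_b <- apply(cross, 2, min)   # nearest relative in A for each j in B
  if (method == "pooled") {
    (sum(min_a) + sum(min_b)) / (length(a) + length(b))
  } else {
    (mean(min_a) + mean(min_b)) / 2
  }
}

#' Pairwise theta+ dissimilarity matrix
#'
#' @param comm station x species 0/1 matrix.
#' @param omega path-length matrix covering all species.
#' @param method passed to [theta_plus()].
#' @return Symmetric station x station matrix, class
#'   `c("dissim_matrix", "matrix")`, zero diagonal.
#' @export
theta_plus_matrix <- function(comm, omega, method = c("pooled", "average")) {
  method <- match.arg(method)
  comm <- validate_community(comm, rownames(omega))
  empty <- rownames(comm)[rowSums(comm) == 0]
  if (length(empty)) {
    stop("theta_plus undefined for empty stations: ",
         paste(empty, collapse = ", "), call. = FALSE)
  }
  n <- nrow(comm)
  d <- matrix(0, n, n, dimnames = list(rownames(comm), rownames(comm)))
  sets <- lapply(seq_len(n), function(i) colnames(comm)[comm[i, ] > 0])
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- theta_plus(sets[[i]], sets[[j]], omega,
                                       method = method)
    }
  }
  structure(d, class = c("dissim_matrix", "matrix"))
}

#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6371 km.  Vectorised over
#' coordinates in decimal degrees (west longitudes negative).
#'
#' @param lat1,lon1,lat2,lon2 coordinates in decimal degrees.
#' @return Distance(s) in km.
#' @examples
#' haversine_km(0, 0, 1, 0)   # one degree of latitude, ~111.19 km
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  if (any(abs(c(lat1, lat2)) > 90) || any(abs(c(lon1, lon2)) > 360)) {
    stop("coordinates out of range (lat in [-90,90], lon in [-360,360])",
         call. = FALSE)
  }
  r <- 6371.0
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad / 2
  dlon <- (lon2 - lon1) * to_rad / 2
  a <- sin(dlat)^2 + cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon)^2
  2 * r * asin(pmin(1, sqrt(a)))
}

#' Great-circle distance matrix between stations
#'
#' @param stations data.frame with columns `station`, `lat`, `lon` (decimal
#'   degrees), or a matrix/data.frame with lon/lat columns and station row
#'   names.
#' @return Symmetric station x station matrix of distances in km, class
#'   `c("geo_matrix", "matrix")`.
#' @export
geo_distance_matrix <- function(stations) {
  st <- as_station_table(stations)
  n <- nrow(st)
  d <- matrix(0, n, n, dimnames = list(st$station, st$station))
  for (i in seq_len(n - 1)) {
    j <- (i + 1):n
    d[i, j] <- d[j, i] <- haversine_km(st$lat[i], st$lon[i],
                                       st$lat[j], st$lon[j])
  }
  structure(d, class = c("geo_matrix", "matrix"))
}

as_station_table <- function(stations) {
  st <- as.data.frame(stations)
  names(st) <- tolower(names(st))
  if (!"station" %in% names(st)) {
    st$station <- rownames(stations)
  }
  need <- c("station", "lat", "lon")
  if (!all(need %in% names(st))) {
    stop("station table needs columns station, lat, lon", call. = FALSE)
  }
  st$station <- as.character(st$station)
  st
}

# Unordered station pairs of two matching square matrices as a data.frame.
pairs_long <- function(dissim, geo) {
  stopifnot(identical(rownames(dissim), rownames(geo)))
  ut <- upper.tri(dissim)
  idx <- which(ut, arr.ind = TRUE)
  data.frame(i = rownames(dissim)[idx[, 1]],
             j = colnames(dissim)[idx[, 2]],
             dissim = dissim[ut], km = geo[ut],
             stringsAsFactors = FALSE)
}

#' Exponential distance decay of taxonomic dissimilarity
#'
#' Fits the expected dissimilarity between station pairs as an exponential
#' function of great-circle distance, `E[y] = a * exp(b * d)`, via a
#' Gaussian GLM with log link (iteratively reweighted least squares) on all
#' unordered pairs.  The intercept `a` is on the response (dissimilarity)
#' scale; the slope `b` is per km on the log scale.  Co-located pairs
#' (d = 0) are retained and distances are not transformed.
#'
#' @param dissim dissimilarity matrix from [theta_plus_matrix()].
#' @param geo distance matrix from [geo_distance_matrix()] with the same
#'   stations in the same order.
#' @return Object of class `decay_fit` with elements `a`, `b`, `coef`
#'   (linear predictor scale), `fitted`, `pairs`, the underlying `glm`, and
#'   empty bootstrap slots (see [bootstrap_decay()]).
#' @export
fit_decay <- function(dissim, geo) {
  pr <- pairs_long(dissim, geo)
  if (nrow(pr) < 10) stop("need at least 10 station pairs", call. = FALSE)
  fit <- stats::glm(dissim ~ km, data = pr,
                    family = stats::gaussian(link = "log"),
                    start = c(log(max(mean(pr$dissim), 1e-8)), 0),
                    control = stats::glm.control(maxit = 200, epsilon = 1e-12))
  if (!fit$converged) {
    stop("decay GLM did not converge after 200 IRLS iterations; ",
         "deviance = ", signif(fit$deviance, 6), call. = FALSE)
  }
  cf <- stats::coef(fit)
  structure(list(a = unname(exp(cf[1])), b = unname(cf[2]), coef = cf,
                 fitted = stats::fitted(fit), pairs = pr, glm = fit,
                 stations = rownames(dissim), dissim = unclass(dissim),
                 geo = unclass(geo),
                 boot = NULL, n_boot = 0L, seed = NA_integer_),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("Exponential distance decay: y = %.4f * exp(%.6f * d_km), %d pairs\n",
              x$a, x$b, nrow(x$pairs)))
  if (!is.null(x$boot)) {
    ci_a <- stats::quantile(x$boot$a, c(.025, .975))
    ci_b <- stats::quantile(x$boot$b, c(.025, .975))
    cat(sprintf("bootstrap (%d reps): a in [%.3f, %.3f], b in [%.6f, %.6f]\n",
                x$n_boot, ci_a[1], ci_a[2], ci_b[1], ci_b[2]))
  }
  invisible(x)
}

#' Bootstrap the distance-decay coefficients
#'
#' Resamples stations (not pairs) with replacement, rebuilds the induced
#' pair set and refits the log-link Gaussian GLM, so the pairwise
#' dependence induced by shared stations is respected.  Degenerate
#' resamples with a single distinct station are redrawn (count reported).
#'
#' @param fit a [fit_decay()] result.
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @param level confidence level for the percentile intervals.
#' @return `fit` with `boot` (data.frame of `a`, `b`), `ci` and bookkeeping
#'   fields filled in.
#' @export
bootstrap_decay <- function(fit, n_boot = 1000, seed = 1L, level = 0.95) {
  stopifnot(inherits(fit, "decay_fit"))
  st <- fit$stations
  n <- length(st)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  ab <- matrix(NA_real_, n_boot, 2)
  redraws <- 0L
  for (r in seq_len(n_boot)) {
    repeat {
      take <- sample.int(n, n, replace = TRUE)
      if (length(unique(take)) >= 2L) break
      redraws <- redraws + 1L
    }
    d_b <- fit$dissim[take, take]
    g_b <- fit$geo[take, take]
    # duplicate stations create zero-distance self pairs; keep only pairs of
    # distinct original stations
    keep <- outer(take, take, "!=")[upper.tri(d_b)]
    y <- d_b[upper.tri(d_b)][keep]
    d <- g_b[upper.tri(g_b)][keep]
    cf <- tryCatch(stats::coef(stats::glm(y ~ d,
            family = stats::gaussian(link = "log"),
            start = c(log(max(mean(y), 1e-8)), 0),
            control = stats::glm.control(maxit = 200, epsilon = 1e-12))),
          error = function(e) c(NA_real_, NA_real_))
    ab[r, ] <- c(exp(cf[1]), cf[2])
  }
  ok <- stats::complete.cases(ab)
  if (!all(ok)) warning(sum(!ok), " bootstrap refits failed and were dropped",
                        call. = FALSE)
  boot <- data.frame(a = ab[ok, 1], b = ab[ok, 2])
  alpha <- (1 - level) / 2
  fit$boot <- boot
  fit$n_boot <- as.integer(n_boot)
  fit$seed <- as.integer(seed)
  fit$redraws <- redraws
  fit$ci <- rbind(a = stats::quantile(boot$a, c(alpha, 1 - alpha)),
                  b = stats::quantile(boot$b, c(alpha, 1 - alpha)))
  fit
}
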