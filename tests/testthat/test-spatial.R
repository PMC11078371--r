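# shared Euclidean playground: points in 5-d, distances are exactly
# embeddable, so vegan and closed-form oracles apply at machine precision
make_euclid <- function(n = 20, p = 5, seed = 9) {
  set.seed(seed)
  pts <- matrix(rnorm(n * p), n)
  rownames(pts) <- sprintf("st%02d", seq_len(n))
  list(pts = pts, d = as.matrix(stats::dist(pts)))
}

test_that("dbMEM basis has the transect eigenstructure", {
  st <- data.frame(station = sprintf("t%02d", 1:10),
                   lon = seq(-95, -90.5, by = 0.5), lat = 20)
  basis <- build_dbmem(st)
  v <- basis$vectors
  expect_equal(crossprod(v), diag(ncol(v)), ignore_attr = TRUE,
               tolerance = 1e-10)
  expect_equal(colSums(v), rep(0, ncol(v)), ignore_attr = TRUE,
               tolerance = 1e-10)
  sign_changes <- function(x) sum(diff(sign(x)) != 0)
  sc <- apply(v[, basis$retained, drop = FALSE], 2, sign_changes)
  expect_equal(unname(sc[1]), 1)                    # MEM1 monotone
  expect_true(all(diff(sc) >= 0))                   # sine-like ordering
  expect_gt(basis$moran[basis$retained[1]],
            basis$moran[basis$retained[length(basis$retained)]])
  # positive + negative eigenvalues partition the n-1 dimensions
  expect_equal(length(basis$values), nrow(st) - 1)
})

test_that("dbMEM retains only positive-autocorrelation eigenvectors", {
  sim <- small_survey(seed = 17, n_stations = 18)
  basis <- build_dbmem(sim$stations)
  e_null <- -1 / (basis$n - 1)
  expect_true(all(basis$moran[basis$retained] > e_null))
  expect_true(all(basis$values[match(basis$retained,
                                     colnames(basis$vectors))] > 0))
  expect_error(build_dbmem(sim$stations[1:3, ]), "at least 4")
  # duplicate coordinates warn but do not fail
  st2 <- sim$stations
  st2$lon[2] <- st2$lon[1]; st2$lat[2] <- st2$lat[1]
  expect_warning(build_dbmem(st2), "duplicate")
})

test_that("pcoa_embed reconstructs Euclidean configurations", {
  eu <- make_euclid(n = 15, p = 2, seed = 10)
  emb <- pcoa_embed(eu$d)
  expect_equal(as.matrix(stats::dist(emb$coords)), eu$d,
               ignore_attr = TRUE, tolerance = 1e-8)
  # eigenvalues agree with cmdscale
  cm <- stats::cmdscale(stats::as.dist(eu$d), k = 2, eig = TRUE)
  expect_equal(emb$pos_values, cm$eig[1:ncol(emb$coords)],
               tolerance = 1e-8)

  # 2-station matrix: one axis, exact distance
  d2 <- matrix(c(0, 3, 3, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  e2 <- pcoa_embed(d2)
  expect_equal(ncol(e2$coords), 1)
  expect_equal(abs(e2$coords[1] - e2$coords[2]), 3, tolerance = 1e-10)
})

test_that("pcoa reconstruction bound and Lingoes on theta+ matrices", {
  sim <- small_survey(seed = 19, n_stations = 12)
  om <- tax_path_lengths(sim$taxonomy)
  th <- theta_plus_matrix(sim$community, om)
  emb <- pcoa_embed(th)
  rec <- as.matrix(stats::dist(emb$coords))
  neg <- sum(abs(emb$values[emb$values < 0]))
  # dropped negative eigenvalues bound the worst-case squared distortion
  expect_lte(max(abs(rec^2 - unclass(th)^2)), 2 * neg + 1e-8)
  lin <- pcoa_embed(th, correction = "lingoes")
  expect_gte(min(lin$pos_values), 0)
  # corrected embedding has no dropped structure for off-diagonal pairs
  expect_equal(ncol(lin$coords) >= ncol(emb$coords), TRUE)
})

test_that("dbrda equals the ANOVA decomposition for a binary constraint", {
  eu <- make_euclid(n = 16, p = 4, seed = 12)
  grp <- rep(0:1, each = 8)
  res <- taxodive::dbrda(eu$d, cbind(grp = grp))
  # oracle: between-group share of total sum of squares of the points
  y <- scale(eu$pts, scale = FALSE)
  means <- apply(y, 2, function(col) tapply(col, grp, mean))
  ss_between <- sum(8 * means^2)
  expect_equal(length(res$eig), 1)
  expect_equal(res$percent[1], 100 * ss_between / sum(y^2),
               tolerance = 1e-8)
  two_grp <- tapply(res$site_scores[, 1], grp, mean)
  expect_true(prod(two_grp) < 0)   # groups on opposite sides of axis 1
})

test_that("dbrda matches vegan capscale on Euclidean input", {
  skip_if_not_installed("vegan")
  eu <- make_euclid(n = 20, p = 5, seed = 13)
  set.seed(1301)   # decorrelated from the seed that built the points
  X <- data.frame(a = eu$pts[, 1] + rnorm(20, 0, .5), b = rnorm(20))
  mine <- taxodive::dbrda(eu$d, X)
  ref <- vegan::capscale(stats::as.dist(eu$d) ~ a + b, data = X)
  expect_equal(mine$percent[1:2],
               unname(ref$CCA$eig / ref$tot.chi * 100), tolerance = 1e-10)
  expect_equal(mine$adj_r2, vegan::RsquareAdj(ref)$adj.r.squared,
               tolerance = 1e-10)
  # constraints orthogonal to the embedding: residualized noise
  q <- qr.Q(qr(cbind(1, eu$pts)))
  noise <- matrix(rnorm(20 * 2), 20)
  ortho <- noise - q %*% crossprod(q, noise)
  res0 <- taxodive::dbrda(eu$d, ortho)
  expect_lt(res0$r2, 1e-10)
  # constraints spanning the full embedding: saturation at 100%
  res1 <- taxodive::dbrda(eu$d, eu$pts)
  expect_equal(res1$r2, 1, tolerance = 1e-10)
  expect_error(taxodive::dbrda(eu$d, matrix(rnorm(20 * 25), 20)),
               "more constraint columns")
})

test_that("dbrda with identity constraints reproduces PCoA percentages", {
  sim <- small_survey(seed = 23, n_stations = 12)
  om <- tax_path_lengths(sim$taxonomy)
  th <- theta_plus_matrix(sim$community, om)
  emb <- pcoa_embed(th)
  res <- taxodive::dbrda(emb, emb$coords)
  expect_equal(sort(res$percent, decreasing = TRUE)[1:3],
               unname(100 * emb$pos_values[1:3] / emb$total_inertia),
               tolerance = 1e-8)
})

test_that("forward selection recovers a single generating variable", {
  hits <- 0
  second <- 0
  for (seed in 1:10) {
    set.seed(seed)
    n <- 30
    cand <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n),
                       x4 = rnorm(n))
    y <- cbind(cand$x2 + rnorm(n, 0, 0.4), rnorm(n, 0, 0.4))
    fs <- forward_select(y, cand, alpha = 0.05, n_perm = 199, seed = seed)
    if (length(fs$selected) >= 1 && fs$selected[1] == "x2") hits <- hits + 1
    if (length(fs$selected) > 1) second <- second + 1
  }
  expect_gte(hits, 9)      # generating variable found first in >= 90%
  expect_lte(second, 3)    # rarely admits a spurious second variable
})

test_that("forward selection respects the global test and the cap", {
  # pure-noise response: global test blocks selection most of the time
  reject <- 0
  for (seed in 1:20) {
    set.seed(seed + 50)
    y <- matrix(rnorm(25 * 2), 25)
    cand <- data.frame(a = rnorm(25), b = rnorm(25), c = rnorm(25))
    fs <- suppressMessages(
      forward_select(y, cand, alpha = 0.05, n_perm = 99, seed = seed))
    if (length(fs$selected) > 0) reject <- reject + 1
  }
  expect_lte(reject, 4)    # ~5% type-I, binomial slack on 20 runs

  # alpha = 1 and no cap: every non-collinear candidate enters
  set.seed(3)
  y <- matrix(rnorm(20 * 2), 20)
  cand <- data.frame(a = rnorm(20), b = rnorm(20), c = rnorm(20))
  fs_all <- forward_select(y, cand, alpha = 1, n_perm = 49, seed = 1,
                           use_adjr2_cap = FALSE)
  expect_setequal(fs_all$selected, c("a", "b", "c"))
  # collinear candidate is skipped with a warning
  cand$d <- cand$a * 2
  expect_warning(
    fs_coll <- forward_select(y, cand, alpha = 1, n_perm = 49, seed = 1,
                              use_adjr2_cap = FALSE),
    "collinear")
  expect_length(fs_coll$selected, 3)
})

test_that("variation partitioning matches vegan and sums to one", {
  skip_if_not_installed("vegan")
  eu <- make_euclid(n = 20, p = 5, seed = 14)
  set.seed(1401)
  X1 <- data.frame(a = eu$pts[, 1] + rnorm(20, 0, .5), b = rnorm(20))
  X2 <- matrix(rnorm(20 * 2), 20,
               dimnames = list(rownames(eu$pts), c("u", "v")))
  vp <- variation_partition(eu$d, X1 = X1, X2 = X2, n_perm = 99, seed = 4)
  vv <- vegan::varpart(stats::as.dist(eu$d), as.matrix(scale(X1)), X2)
  ref <- vv$part$indfract$Adj.R.squared
  expect_equal(c(vp$fractions$adj_R2, vp$residual), ref,
               tolerance = 1e-10)
  expect_equal(sum(vp$fractions$adj_R2) + vp$residual, 1,
               tolerance = 1e-10)
  # unique fractions are testable, shared are not
  expect_true(all(!is.na(
    vp$fractions$p_value[grepl("unique", vp$fractions$fraction)])))
  expect_true(all(is.na(
    vp$fractions$p_value[grepl("shared", vp$fractions$fraction)])))
})

test_that("partitioning isolates a pure X1 signal and absorbs duplicates", {
  set.seed(15)
  n <- 25
  X1 <- matrix(rnorm(n * 2), n, dimnames = list(NULL, c("e1", "e2")))
  pts <- cbind(X1 %*% c(1, -1), X1 %*% c(1, 1)) + matrix(rnorm(n * 2, 0, .3), n)
  rownames(pts) <- sprintf("s%02d", 1:n)
  d <- as.matrix(stats::dist(pts))
  X3 <- matrix(rnorm(n * 2), n, dimnames = list(NULL, c("m1", "m2")))
  vp <- variation_partition(d, X1 = X1, X3 = X3, n_perm = 99, seed = 5)
  u1 <- vp$fractions$adj_R2[vp$fractions$fraction == "unique X1"]
  u3 <- vp$fractions$adj_R2[vp$fractions$fraction == "unique X3"]
  expect_gt(u1, 0.7)
  expect_lt(abs(u3), 0.1)
  # X1 duplicated as X3: the shared cell absorbs everything
  vp2 <- variation_partition(d, X1 = X1, X3 = X1 + 0, n_perm = 0, seed = 5)
  sh <- vp2$fractions$adj_R2[vp2$fractions$fraction == "shared X1&X3"]
  expect_gt(sh, 0.7)
  expect_lt(abs(vp2$fractions$adj_R2[vp2$fractions$fraction == "unique X1"]),
            0.05)
})

test_that("partition fractions are invariant to station reordering", {
  eu <- make_euclid(n = 18, p = 4, seed = 16)
  set.seed(1601)
  X1 <- matrix(rnorm(18 * 2), 18)
  X2 <- matrix(rnorm(18 * 2), 18)
  vp <- variation_partition(eu$d, X1 = X1, X2 = X2, n_perm = 0)
  perm <- sample(18)
  vp_p <- variation_partition(eu$d[perm, perm], X1 = X1[perm, ],
                              X2 = X2[perm, ], n_perm = 0)
  expect_equal(vp$fractions$adj_R2, vp_p$fractions$adj_R2,
               tolerance = 1e-10)
})

test_that("partial dbrda identities", {
  eu <- make_euclid(n = 20, p = 5, seed = 17)
  set.seed(1701)
  X1 <- matrix(rnorm(20 * 2), 20, dimnames = list(NULL, c("a", "b")))
  X2 <- matrix(rnorm(20 * 2), 20, dimnames = list(NULL, c("u", "v")))
  # conditioning on nothing reduces to plain dbrda
  plain <- taxodive::dbrda(eu$d, X1)
  part0 <- partial_dbrda(eu$d, X1, NULL, n_perm = 49)
  expect_equal(part0$eig, plain$eig, tolerance = 1e-10)
  # focal inside the span of the conditioning: zero partial fraction
  expect_warning(
    part_sub <- partial_dbrda(eu$d, X1 %*% diag(2), X1, n_perm = 49),
    "collinear")
  expect_lt(abs(part_sub$adj_r2), 1e-10)
  # orthogonal generating signals: partial fraction = unique fraction
  vp <- variation_partition(eu$d, X1 = X1, X2 = X2, n_perm = 0)
  p1 <- partial_dbrda(eu$d, X1, X2, n_perm = 49)
  u1 <- vp$fractions$adj_R2[vp$fractions$fraction == "unique X1"]
  expect_equal(p1$adj_r2, u1, tolerance = 1e-10)
})
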