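test_that("ward clustering separates constructed blobs and matches hand LW", {
  bl <- block_dissim(c(5, 5), within = 5, between = 60, seed = 2)
  cl <- cut_assemblages(ward_cluster(bl$d), 2)
  expect_equal(adjusted_rand(cl$labels, bl$labels), 1)
  expect_true(all(diff(cl$hclust$height) >= -1e-9))

  # identical stations merge at height zero
  d0 <- matrix(10, 4, 4); d0[1, 2] <- d0[2, 1] <- 0; diag(d0) <- 0
  rownames(d0) <- colnames(d0) <- paste0("x", 1:4)
  cl0 <- ward_cluster(d0)
  expect_equal(min(cl0$hclust$height), 0)

  # n = 3: hand-applied Lance-Williams recursion for ward.D2
  d3 <- matrix(0, 3, 3)
  d3[1, 2] <- d3[2, 1] <- 2; d3[1, 3] <- d3[3, 1] <- 5
  d3[2, 3] <- d3[3, 2] <- 6
  rownames(d3) <- colnames(d3) <- letters[1:3]
  h <- ward_cluster(d3)$hclust
  # first merge (a,b) at 2; then d(ab,c)^2 = (2*25 + 2*36 - 4)/3
  expect_equal(h$height, c(2, sqrt((2 * 25 + 2 * 36 - 4) / 3)))
  dasym <- d3; dasym[1, 2] <- 3         # break symmetry
  expect_error(ward_cluster(dasym), "symmetric")
  expect_error(ward_cluster(matrix(-1, 3, 3)), "negative|diagonal")
})

test_that("silhouette width matches cluster::silhouette and picks k", {
  skip_if_not_installed("cluster")
  bl <- block_dissim(c(4, 5, 6), within = 5, between = 60, seed = 3)
  lab <- bl$labels
  mine <- silhouette_width(bl$d, lab)
  ref <- mean(cluster::silhouette(lab, stats::as.dist(bl$d))[, 3])
  expect_equal(mine, ref, tolerance = 1e-12)

  cl <- choose_k(ward_cluster(bl$d), 2:6)
  expect_equal(cl$k, 3)
  expect_equal(adjusted_rand(cl$labels, lab), 1)

  bl2 <- block_dissim(c(6, 6), within = 4, between = 50, seed = 4)
  expect_equal(choose_k(ward_cluster(bl2$d), 2:5)$k, 2)

  # degenerate: all-equal dissimilarities
  dflat <- matrix(10, 8, 8); diag(dflat) <- 0
  rownames(dflat) <- colnames(dflat) <- paste0("f", 1:8)
  expect_warning(clf <- choose_k(ward_cluster(dflat), 2:4),
                 "no silhouette support")
  expect_equal(clf$k, 2)
  expect_error(choose_k(ward_cluster(bl$d), integer(0)), "empty k_range")
})

test_that("ANOSIM definitional maximum, vegan agreement, midranks", {
  skip_if_not_installed("vegan")
  bl <- block_dissim(c(5, 5), within = 5, between = 60, seed = 5)
  res <- anosim_test(bl$d, bl$labels, n_perm = 99, seed = 1)
  expect_equal(res$statistic, 1)     # all between > all within
  expect_lte(res$p_value, 0.05)

  sim <- small_survey(seed = 6)
  om <- tax_path_lengths(sim$taxonomy)
  th <- theta_plus_matrix(sim$community, om)
  lab <- rep(1:3, each = 5)
  mine <- anosim_test(th, lab, n_perm = 49, seed = 1)
  ref <- vegan::anosim(stats::as.dist(th), factor(lab), permutations = 0)
  expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)

  # rank-based: invariant under monotone transforms
  mono <- anosim_test(th^2 + 3 * th, lab, n_perm = 49, seed = 1)
  expect_equal(mono$statistic, mine$statistic, tolerance = 1e-12)

  expect_error(anosim_test(th, c(1, rep(2, 14))), "at least 2")
  expect_error(anosim_test(th, rep(1, 15)), "2 groups")
})

test_that("sampled permutation p approaches the exact enumeration p", {
  bl <- block_dissim(c(3, 3), within = 10, between = 25, jitter = 8,
                     seed = 8)
  exact <- anosim_test(bl$d, bl$labels, exact = TRUE)
  # independent oracle: enumerate distinct assignments of 3 of 6 stations
  # to group 1 (each assignment appears 3!3! times among permutations)
  rk <- matrix(0, 6, 6)
  rk[upper.tri(rk)] <- rank(bl$d[upper.tri(bl$d)])
  rk <- rk + t(rk)
  r_stat <- function(g1) {
    w <- c(); b <- c()
    for (i in 1:5) for (j in (i + 1):6) {
      if ((i %in% g1) == (j %in% g1)) w <- c(w, rk[i, j])
      else b <- c(b, rk[i, j])
    }
    (mean(b) - mean(w)) / (15 / 2)
  }
  combs <- utils::combn(6, 3)
  r_all <- apply(combs, 2, r_stat)
  r_obs <- r_stat(1:3)
  expect_equal(exact$statistic, r_obs, tolerance = 1e-12)
  expect_equal(exact$p_value, mean(r_all >= r_obs - 1e-12),
               tolerance = 1e-12)
  # sampled p with many permutations is close to exact
  samp <- anosim_test(bl$d, bl$labels, n_perm = 1999, seed = 3)
  expect_lt(abs(samp$p_value - exact$p_value), 0.05)
})

test_that("pairwise ANOSIM equals one-way on the two-group submatrix", {
  sim <- small_survey(seed = 14)
  om <- tax_path_lengths(sim$taxonomy)
  th <- theta_plus_matrix(sim$community, om)
  lab <- rep(1:3, each = 5)
  pw <- pairwise_anosim(th, lab, n_perm = 99, seed = 10)
  keep <- lab %in% c(1, 2)
  direct <- anosim_test(th[keep, keep], lab[keep], n_perm = 99,
                        seed = 10 + 1)
  expect_equal(pw$R[pw$group1 == 1 & pw$group2 == 2], direct$statistic)
  expect_equal(pw$p_value[1], direct$p_value)
  pb <- pairwise_anosim(th, lab, n_perm = 99, seed = 10,
                        adjust = "bonferroni")
  expect_true(all(pb$p_value >= pw$p_value - 1e-12))
})

test_that("dendrogram export is valid Newick", {
  bl <- block_dissim(c(3, 3), seed = 9)
  cl <- ward_cluster(bl$d)
  txt <- write_dendrogram(cl)
  expect_match(txt, "^\\(.*\\);$")
  phy <- ape::read.tree(text = txt)
  expect_equal(sort(phy$tip.label), sort(rownames(bl$d)))
})
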