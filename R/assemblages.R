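#' Ward clustering of a dissimilarity matrix
#'
#' Agglomerative hierarchical clustering of stations under the Ward
#' criterion, applied to the raw taxonomic dissimilarities.  `ward.D2`
#' (squared dissimilarities inside the Lance--Williams update) is the
#' default; `ward.D` is offered because legacy software disagrees on which
#' variant "Ward's method" means.
#'
#' @param dissim symmetric dissimilarity matrix (zero diagonal).
#' @param method `"ward.D2"` (default) or `"ward.D"`.
#' @return Object of class `assemblage_clustering` wrapping the `hclust`
#'   tree plus the input dissimilarities; `k` and `labels` are filled by
#'   [choose_k()] / [cut_assemblages()].
#' @export
ward_cluster <- function(dissim, method = c("ward.D2", "ward.D")) {
  method <- match.arg(method)
  d <- check_dissim(dissim)
  if (nrow(d) < 3) stop("need at least 3 stations to cluster", call. = FALSE)
  hc <- stats::hclust(stats::as.dist(d), method = method)
  structure(list(hclust = hc, dissim = d, method = method,
                 k = NULL, labels = NULL, silhouette = NULL),
            class = "assemblage_clustering")
}

check_dissim <- function(dissim) {
  d <- unclass(as.matrix(dissim))
  if (anyNA(d)) stop("missing values in dissimilarity matrix", call. = FALSE)
  if (nrow(d) != ncol(d) || max(abs(d - t(d))) > 1e-8) {
    stop("dissimilarity matrix must be square and symmetric", call. = FALSE)
  }
  if (any(d < -1e-12)) stop("negative dissimilarities", call. = FALSE)
  if (any(abs(diag(d)) > 1e-12)) stop("non-zero diagonal", call. = FALSE)
  if (is.null(rownames(d))) {
    rownames(d) <- colnames(d) <- paste0("st", seq_len(nrow(d)))
  }
  d
}

#' Average silhouette width of a partition
#'
#' For station i with within-cluster mean dissimilarity a(i) and nearest
#' other-cluster mean dissimilarity b(i), the silhouette is
#' `(b - a) / max(a, b)`; singleton clusters contribute 0.  Returns the
#' mean over stations.
#'
#' @param dissim symmetric dissimilarity matrix.
#' @param labels integer/factor cluster membership per station.
#' @return Average silhouette width (scalar in [-1, 1]).
#' @export
silhouette_width <- function(dissim, labels) {
  d <- check_dissim(dissim)
  lab <- as.integer(factor(labels))
  n <- nrow(d)
  stopifnot(length(lab) == n)
  ks <- sort(unique(lab))
  if (length(ks) < 2) stop("need at least 2 clusters", call. = FALSE)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(lab == lab[i])
    if (length(own) == 1L) { s[i] <- 0; next }
    a <- mean(d[i, setdiff(own, i)])
    b <- min(vapply(setdiff(ks, lab[i]),
                    function(k) mean(d[i, lab == k]), numeric(1)))
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mean(s)
}

#' Choose the number of assemblages by average silhouette width
#'
#' Cuts the dendrogram at each candidate k, computes the average silhouette
#' width against the original dissimilarities, and keeps the k that
#' maximises it (ties broken toward the smallest k).  When all candidate
#' partitions have silhouette near zero the matrix carries no group
#' structure; the smallest k is returned with a warning.
#'
#' @param clustering result of [ward_cluster()].
#' @param k_range candidate cluster numbers, a subset of `[2, n - 1]`.
#' @return `clustering` updated with `k`, `labels` (named integer vector)
#'   and `silhouette` (data.frame k, avg_width).
#' @export
choose_k <- function(clustering, k_range = 2:8) {
  stopifnot(inherits(clustering, "assemblage_clustering"))
  n <- nrow(clustering$dissim)
  k_range <- sort(unique(as.integer(k_range)))
  k_range <- k_range[k_range >= 2 & k_range <= n - 1]
  if (length(k_range) == 0) stop("empty k_range", call. = FALSE)
  widths <- vapply(k_range, function(k) {
    silhouette_width(clustering$dissim,
                     stats::cutree(clustering$hclust, k = k))
  }, numeric(1))
  sil <- data.frame(k = k_range, avg_width = widths)
  if (max(widths) < 0.05) {
    warning("no silhouette support for any k; returning smallest candidate",
            call. = FALSE)
    best <- k_range[1]
  } else {
    best <- k_range[which.max(widths)]   # which.max takes the first (smallest k) tie
  }
  clustering$k <- best
  clustering$silhouette <- sil
  clustering$labels <- stats::cutree(clustering$hclust, k = best)
  clustering
}

#' Cut a clustering at a fixed number of assemblages
#'
#' @param clustering result of [ward_cluster()].
#' @param k number of clusters.
#' @return `clustering` with `k` and `labels` set.
#' @export
cut_assemblages <- function(clustering, k) {
  stopifnot(inherits(clustering, "assemblage_clustering"))
  clustering$k <- as.integer(k)
  clustering$labels <- stats::cutree(clustering$hclust, k = k)
  clustering
}

#' @export
print.assemblage_clustering <- function(x, ...) {
  cat("Ward clustering (", x$method, ") of ", nrow(x$dissim),
      " stations\n", sep = "")
  if (!is.null(x$k)) {
    cat("k =", x$k, "assemblages; sizes:",
        paste(table(x$labels), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based permutation test of separation between a priori groups in a
#' dissimilarity matrix.  With midranks r of all n(n-1)/2 dissimilarities,
#' \deqn{R = \frac{\bar r_{between} - \bar r_{within}}{M/2}, \quad M = n(n-1)/2,}
#' so R near 1 means all between-group dissimilarities exceed all
#' within-group ones.  The p value is `(1 + #{perm R >= observed}) /
#' (n_perm + 1)` under random relabelling, or the exact enumeration
#' fraction when `exact = TRUE` (feasible for small n).
#'
#' @param dissim symmetric dissimilarity matrix.
#' @param labels group membership per station (>= 2 groups, each of
#'   size >= 2).
#' @param n_perm permutations (default 999).
#' @param seed integer seed for the permutations.
#' @param exact if TRUE, enumerate all distinct label permutations instead
#'   of sampling (p then has no +1 correction).
#' @return Object of class `anosim_result`: `statistic` (R), `p_value`,
#'   `n_perm`, `perm_R`, `seed`, `groups`.
#' @export
anosim_test <- function(dissim, labels, n_perm = 999, seed = 1L,
                        exact = FALSE) {
  d <- check_dissim(dissim)
  lab <- factor(labels)
  n <- nrow(d)
  stopifnot(length(lab) == n)
  if (nlevels(lab) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(table(lab) < 2)) {
    stop("every group must have at least 2 stations", call. = FALSE)
  }
  ut <- upper.tri(d)
  rk <- rank(d[ut])                       # midranks for ties
  m <- length(rk)
  same <- outer(lab, lab, "==")[ut]
  r_of <- function(same_vec) {
    (mean(rk[!same_vec]) - mean(rk[same_vec])) / (m / 2)
  }
  r_obs <- r_of(same)
  if (exact) {
    perms <- all_permutations(n)
    perm_r <- apply(perms, 1, function(p) {
      r_of(outer(lab[p], lab[p], "==")[ut])
    })
    p_val <- mean(perm_r >= r_obs - 1e-12)
    n_perm <- nrow(perms)
  } else {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(as.integer(seed))
    perm_r <- vapply(seq_len(n_perm), function(i) {
      p <- sample.int(n)
      r_of(outer(lab[p], lab[p], "==")[ut])
    }, numeric(1))
    p_val <- (1 + sum(perm_r >= r_obs - 1e-12)) / (n_perm + 1)
  }
  structure(list(statistic = r_obs, p_value = p_val,
                 n_perm = as.integer(n_perm), perm_R = perm_r,
                 seed = if (exact) NA_integer_ else as.integer(seed),
                 exact = exact, groups = levels(lab),
                 group_sizes = as.integer(table(lab))),
            class = "anosim_result")
}

all_permutations <- function(n) {
  if (n > 8) stop("exact enumeration limited to n <= 8", call. = FALSE)
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(pos) {
    left <- sub[, seq_len(pos - 1), drop = FALSE]
    right <- if (pos <= n - 1) sub[, pos:(n - 1), drop = FALSE] else
      matrix(0L, nrow(sub), 0)
    cbind(left, rep(n, nrow(sub)), right)
  }))
}

#' @export
print.anosim_result <- function(x, ...) {
  cat(sprintf("ANOSIM R = %.4f, p = %.4g (%s, %d permutations)\n",
              x$statistic, x$p_value,
              if (x$exact) "exact" else "sampled", x$n_perm))
  invisible(x)
}

#' Pairwise ANOSIM between all cluster pairs
#'
#' One-way ANOSIM restricted to each pair of groups' submatrix, as used to
#' confirm separation between delineated assemblages.  P values are
#' unadjusted by default; `adjust = "bonferroni"` multiplies by the number
#' of pairs.
#'
#' @inheritParams anosim_test
#' @param adjust `"none"` (default) or `"bonferroni"`.
#' @return data.frame with one row per group pair: `group1`, `group2`,
#'   `R`, `p_value`.
#' @export
pairwise_anosim <- function(dissim, labels, n_perm = 999, seed = 1L,
                            adjust = c("none", "bonferroni")) {
  adjust <- match.arg(adjust)
  d <- check_dissim(dissim)
  lab <- factor(labels)
  lv <- levels(lab)
  cmb <- utils::combn(lv, 2)
  out <- data.frame(group1 = cmb[1, ], group2 = cmb[2, ],
                    R = NA_real_, p_value = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(ncol(cmb))) {
    keep <- lab %in% cmb[, i]
    res <- anosim_test(d[keep, keep], droplevels(lab[keep]),
                       n_perm = n_perm, seed = seed + i)
    out$R[i] <- res$statistic
    out$p_value[i] <- res$p_value
  }
  if (adjust == "bonferroni") {
    out$p_value <- pmin(1, out$p_value * nrow(out))
  }
  out
}

#' Export a dendrogram as Newick text
#'
#' Writes the merge tree with heights in nested-parenthesis (Newick)
#' format for external plotting.
#'
#' @param clustering result of [ward_cluster()].
#' @param path file to write; if NULL the Newick string is returned.
#' @return The Newick string, invisibly when written to file.
#' @export
write_dendrogram <- function(clustering, path = NULL) {
  stopifnot(inherits(clustering, "assemblage_clustering"))
  phy <- ape::as.phylo(clustering$hclust)
  txt <- ape::write.tree(phy)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}
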