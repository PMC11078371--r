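#' Distance-based Moran eigenvector maps
#'
#' Builds an orthogonal spatial basis from the stations' great-circle
#' distance matrix.  Distances are truncated at `t` (by default the longest
#' edge of the minimum spanning tree, which keeps the connection graph in
#' one piece); connected pairs get the weight `1 - (d/(4t))^2`, others 0.
#' Eigenvectors of the double-centred weight matrix are the MEMs, indexed
#' MEM1, MEM2, ... in decreasing eigenvalue order, so MEM1 carries the
#' broadest spatial scale.  Only eigenvectors with positive eigenvalue and
#' Moran's I above its null expectation `-1/(n-1)` model positive spatial
#' autocorrelation and are retained for use as spatial predictors.
#'
#' @param coords station table with `station`, `lat`, `lon` columns (decimal
#'   degrees), or a precomputed [geo_distance_matrix()].
#' @param truncation optional truncation distance t in km; defaults to the
#'   longest MST edge.
#' @return Object of class `dbmem_basis`: `vectors` (station x MEM,
#'   orthonormal), `values` (eigenvalues), `moran` (Moran's I per MEM),
#'   `retained` (names of positive-autocorrelation MEMs), `truncation`.
#' @export
build_dbmem <- function(coords, truncation = NULL) {
  d <- if (inherits(coords, "geo_matrix")) unclass(coords)
       else unclass(geo_distance_matrix(coords))
  n <- nrow(d)
  if (n < 4) stop("need at least 4 stations for dbMEM", call. = FALSE)
  if (any(d[upper.tri(d)] < 1e-9)) {
    warning("duplicate coordinates detected; co-located stations share MEM scores",
            call. = FALSE)
  }
  t <- if (is.null(truncation)) max(mst_edges(d)) else as.numeric(truncation)
  if (t <= 0) stop("truncation distance must be positive", call. = FALSE)
  w <- 1 - (d / (4 * t))^2
  w[d > t] <- 0
  diag(w) <- 0
  cw <- double_center(w)
  eig <- eigen(cw, symmetric = TRUE)
  tol <- max(abs(eig$values)) * 1e-9
  keep <- abs(eig$values) > tol
  vals <- eig$values[keep]
  vecs <- eig$vectors[, keep, drop = FALSE]
  colnames(vecs) <- paste0("MEM", seq_along(vals))
  rownames(vecs) <- rownames(d)
  s0 <- sum(w)
  moran <- vapply(seq_along(vals), function(k) {
    v <- vecs[, k]
    (n / s0) * drop(crossprod(v, w %*% v)) / drop(crossprod(v))
  }, numeric(1))
  names(moran) <- colnames(vecs)
  e_null <- -1 / (n - 1)
  retained <- colnames(vecs)[vals > tol & moran > e_null]
  structure(list(vectors = vecs, values = vals, moran = moran,
                 retained = retained, truncation = t, n = n,
                 weights = w),
            class = "dbmem_basis")
}

#' @export
print.dbmem_basis <- function(x, ...) {
  cat(sprintf("dbMEM basis: %d stations, truncation %.2f km, %d eigenvectors (%d retained, positive autocorrelation)\n",
              x$n, x$truncation, length(x$values), length(x$retained)))
  invisible(x)
}

# Prim's algorithm; returns the edge lengths of the minimum spanning tree.
mst_edges <- function(d) {
  n <- nrow(d)
  in_tree <- c(TRUE, rep(FALSE, n - 1))
  best <- d[1, ]
  edges <- numeric(0)
  for (step in seq_len(n - 1)) {
    cand <- which(!in_tree)
    nxt <- cand[which.min(best[cand])]
    edges <- c(edges, best[nxt])
    in_tree[nxt] <- TRUE
    best <- pmin(best, d[nxt, ])
  }
  edges
}

double_center <- function(m) {
  rm <- rowMeans(m); cm <- colMeans(m); gm <- mean(m)
  sweep(sweep(m, 1, rm), 2, cm) + gm
}

#' Split retained MEMs into broad- and fine-scale blocks
#'
#' The retained (positive-autocorrelation) eigenvectors are ordered from
#' broad to fine spatial scale; by default the first half of that spectrum
#' is the broad block and the rest fine.  Explicit membership can be given
#' to reproduce any published assignment.
#'
#' @param basis a [build_dbmem()] result.
#' @param mems optional character vector restricting to a subset (e.g. the
#'   forward-selected MEMs); defaults to all retained.
#' @param broad optional character vector naming the broad-scale MEMs
#'   explicitly; overrides the half-spectrum rule.
#' @return list with matrices `broad` and `fine` (either may have zero
#'   columns).
#' @export
split_mems <- function(basis, mems = NULL, broad = NULL) {
  stopifnot(inherits(basis, "dbmem_basis"))
  mems <- if (is.null(mems)) basis$retained else intersect(mems, colnames(basis$vectors))
  # keep spectral (scale) order
  mems <- colnames(basis$vectors)[colnames(basis$vectors) %in% mems]
  if (is.null(broad)) {
    idx_all <- match(mems, basis$retained)
    half <- ceiling(length(basis$retained) / 2)
    broad <- mems[idx_all <= half]
  }
  fine <- setdiff(mems, broad)
  list(broad = basis$vectors[, intersect(mems, broad), drop = FALSE],
       fine = basis$vectors[, fine, drop = FALSE])
}

#' Principal-coordinate embedding of a dissimilarity matrix
#'
#' Gower double-centring of `-0.5 * D^2` followed by eigen-decomposition.
#' Positive-eigenvalue axes are kept, scaled by the square root of their
#' eigenvalue, so Euclidean distances between rows reproduce the input
#' exactly when it is Euclidean-embeddable.  The Lingoes correction (add a
#' constant to off-diagonal squared dissimilarities) is available for
#' matrices with large negative eigenvalues.
#'
#' @param dissim symmetric dissimilarity matrix with zero diagonal.
#' @param correction `"none"` (drop negative axes, default) or
#'   `"lingoes"`.
#' @return Object of class `pcoa_embedding`: `coords` (station x axis),
#'   `values` (all eigenvalues of the uncorrected analysis), `total_inertia`
#'   (sum of positive eigenvalues used as the denominator downstream),
#'   `correction`.
#' @export
pcoa_embed <- function(dissim, correction = c("none", "lingoes")) {
  correction <- match.arg(correction)
  d <- check_dissim(dissim)
  g <- double_center(-0.5 * d^2)
  eig <- eigen(g, symmetric = TRUE)
  values <- eig$values
  if (correction == "lingoes" && min(values) < -1e-8) {
    c_add <- -min(values)
    d2 <- d^2 + 2 * c_add
    diag(d2) <- 0
    g <- double_center(-0.5 * d2)
    eig <- eigen(g, symmetric = TRUE)
  }
  tol <- max(abs(eig$values)) * 1e-8
  pos <- eig$values > tol
  coords <- sweep(eig$vectors[, pos, drop = FALSE], 2,
                  sqrt(eig$values[pos]), "*")
  rownames(coords) <- rownames(d)
  colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  structure(list(coords = coords, values = values,
                 pos_values = eig$values[pos],
                 total_inertia = sum(eig$values[pos]),
                 correction = correction),
            class = "pcoa_embedding")
}

# Coerce constraints (data.frame / matrix / vector) to a centred numeric
# matrix; factors expand to treatment contrasts.
block_matrix <- function(x, standardize = FALSE) {
  if (is.null(x)) return(NULL)
  if (is.matrix(x) && is.numeric(x)) {
    m <- x
  } else {
    df <- as.data.frame(x)
    m <- stats::model.matrix(~ . - 1, data = df)
  }
  if (ncol(m) == 0) return(NULL)
  m <- scale(m, center = TRUE, scale = FALSE)
  sds <- apply(m, 2, stats::sd)
  m <- m[, sds > 1e-12, drop = FALSE]
  if (ncol(m) == 0) return(NULL)
  if (standardize) m <- scale(m, center = FALSE, scale = TRUE)
  m
}

as_embedding <- function(x) {
  if (inherits(x, "pcoa_embedding")) return(x)
  if (inherits(x, "dissim_matrix") || is.matrix(x)) return(pcoa_embed(x))
  stop("expected a dissimilarity matrix or pcoa_embedding", call. = FALSE)
}

# Least-squares machinery on the embedding: explained sum of squares,
# fitted values and rank, via QR on the centred constraint matrix.
project_fit <- function(y, x) {
  qrx <- qr(x)
  q <- qr.Q(qrx)[, seq_len(qrx$rank), drop = FALSE]
  fitted <- q %*% crossprod(q, y)
  list(fitted = fitted, rank = qrx$rank, q = q)
}

adjusted_r2 <- function(r2, n, q) {
  if (n - q - 1 <= 0) return(NA_real_)
  1 - (1 - r2) * (n - 1) / (n - q - 1)
}

#' Distance-based redundancy analysis
#'
#' Constrained ordination of the principal-coordinate embedding of a
#' dissimilarity matrix on a set of explanatory variables: the embedding is
#' regressed on the constraints and the fitted values are decomposed into
#' orthogonal constrained axes.  Axis percentages are relative to the total
#' inertia (sum of positive PCoA eigenvalues), so they match the usual
#' "percent of total variation" reading of a dbRDA plot.
#'
#' @param dissim dissimilarity matrix (or a [pcoa_embed()] result to reuse
#'   an existing embedding).
#' @param constraints data.frame or numeric matrix of explanatory
#'   variables, rows matching stations.
#' @param n_perm if > 0, a permutation test of the constrained model
#'   (pseudo-F, free row permutation) is run.
#' @param seed seed for the permutation test.
#' @return Object of class `dbrda_result`: `eig` (constrained axis
#'   eigenvalues), `percent` (per-axis % of total inertia), `site_scores`,
#'   `lc_scores`, `biplot_scores`, `r2`, `adj_r2`, `rank`, and `p_value`
#'   when tested.
#' @export
dbrda <- function(dissim, constraints, n_perm = 0, seed = 1L) {
  emb <- as_embedding(dissim)
  y <- emb$coords
  n <- nrow(y)
  x <- block_matrix(constraints)
  if (is.null(x)) stop("no usable constraint columns", call. = FALSE)
  if (nrow(x) != n) stop("constraint rows must match stations", call. = FALSE)
  if (ncol(x) > n - 1) {
    stop("more constraint columns than stations - 1", call. = FALSE)
  }
  if (anyNA(x)) stop("missing values in constraints", call. = FALSE)
  pf <- project_fit(y, x)
  sv <- svd(pf$fitted)
  tol <- max(sv$d) * 1e-8
  keep <- sv$d > tol
  eig_c <- sv$d[keep]^2
  axes <- sv$v[, keep, drop = FALSE]
  total <- emb$total_inertia
  site <- y %*% axes                       # wa-style scores
  lc <- pf$fitted %*% axes                 # constrained (lc) scores
  colnames(site) <- colnames(lc) <- paste0("dbRDA", seq_len(ncol(site)))
  rownames(site) <- rownames(lc) <- rownames(y)
  bip <- suppressWarnings(stats::cor(x, lc))
  r2 <- sum(eig_c) / total
  adj <- adjusted_r2(r2, n, pf$rank)
  p_val <- NA_real_
  if (n_perm > 0) {
    p_val <- permute_pseudo_f(y, x, cond = NULL, n_perm = n_perm,
                              seed = seed)
  }
  structure(list(eig = eig_c, percent = 100 * eig_c / total,
                 site_scores = site, lc_scores = lc, biplot_scores = bip,
                 r2 = r2, adj_r2 = adj, rank = pf$rank,
                 total_inertia = total, n = n, p_value = p_val,
                 n_perm = n_perm),
            class = "dbrda_result")
}

#' @export
print.dbrda_result <- function(x, ...) {
  cat(sprintf("dbRDA: %d constrained axes, R2 = %.4f (adj %.4f)\n",
              length(x$eig), x$r2, x$adj_r2))
  k <- min(4, length(x$percent))
  cat("axis % of total inertia:",
      paste(sprintf("%.2f", x$percent[seq_len(k)]), collapse = ", "),
      if (length(x$percent) > k) "..." else "", "\n")
  if (!is.na(x$p_value)) {
    cat(sprintf("permutation test: p = %.4g (%d permutations)\n",
                x$p_value, x$n_perm))
  }
  invisible(x)
}

# Pseudo-F permutation test; with conditioning, residuals of the reduced
# model are permuted (permutation under the reduced model).
permute_pseudo_f <- function(y, x, cond = NULL, n_perm = 999, seed = 1L) {
  n <- nrow(y)
  q_cond <- 0L
  if (!is.null(cond)) {
    pc <- project_fit(y, cond)
    y <- y - pc$fitted
    x <- x - project_fit(x, cond)$fitted
    q_cond <- pc$rank
  }
  stat <- function(yy) {
    pf <- project_fit(yy, x)
    ss_fit <- sum(pf$fitted^2)
    ss_res <- sum((yy - pf$fitted)^2)
    df2 <- n - pf$rank - q_cond - 1
    (ss_fit / pf$rank) / (ss_res / max(df2, 1))
  }
  f_obs <- stat(y)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  f_perm <- vapply(seq_len(n_perm), function(i) {
    stat(y[sample.int(n), , drop = FALSE])
  }, numeric(1))
  (1 + sum(f_perm >= f_obs - 1e-12)) / (n_perm + 1)
}

#' Forward selection of constraints with the double stopping rule
#'
#' Selects explanatory variables for a constrained ordination one at a
#' time.  The global model with every candidate is tested first; if it is
#' not significant no variable is selected.  At each step the candidate
#' giving the largest increase in R-squared enters if (a) its partial
#' permutation p-value is at most `alpha`, and (b) the cumulative adjusted
#' R-squared does not exceed that of the global model.  Candidates nearly
#' collinear with the current selection are skipped with a warning.
#'
#' @param response dissimilarity matrix, [pcoa_embed()] result, or a
#'   numeric response matrix.
#' @param candidates data.frame or matrix of candidate variables
#'   (standardized internally).
#' @param alpha entry significance threshold (default 0.05).
#' @param n_perm permutations per test (default 999).
#' @param seed integer seed.
#' @param use_adjr2_cap disable with FALSE to let every significant
#'   candidate enter.
#' @return Object of class `forward_selection`: `selected` (names in entry
#'   order), `trace` (per-step R2, adjusted R2, p), `global_p`,
#'   `global_adj_r2`.
#' @export
forward_select <- function(response, candidates, alpha = 0.05,
                           n_perm = 999, seed = 1L, use_adjr2_cap = TRUE) {
  y <- if (is.matrix(response) && !inherits(response, "dissim_matrix")) {
    scale(response, scale = FALSE)
  } else as_embedding(response)$coords
  n <- nrow(y)
  x_all <- block_matrix(candidates, standardize = TRUE)
  if (is.null(x_all)) stop("no usable candidates", call. = FALSE)
  ss_tot <- sum(scale(y, scale = FALSE)^2)
  vars <- colnames(x_all)
  pf_all <- project_fit(y, x_all)
  global_r2 <- sum(pf_all$fitted^2) / ss_tot
  global_adj <- adjusted_r2(global_r2, n, pf_all$rank)
  global_p <- permute_pseudo_f(y, x_all, n_perm = n_perm, seed = seed)
  sel <- character(0)
  trace <- data.frame(variable = character(0), r2 = numeric(0),
                      adj_r2 = numeric(0), p_value = numeric(0),
                      stringsAsFactors = FALSE)
  if (global_p > alpha) {
    message("global model not significant (p = ", signif(global_p, 3),
            "); no variables selected")
    return(structure(list(selected = sel, trace = trace,
                          global_p = global_p, global_adj_r2 = global_adj,
                          alpha = alpha, n_perm = n_perm, seed = seed),
                     class = "forward_selection"))
  }
  remaining <- vars
  step <- 0L
  repeat {
    step <- step + 1L
    if (!length(remaining)) break
    x_sel <- if (length(sel)) x_all[, sel, drop = FALSE] else NULL
    # drop candidates collinear with the current selection
    if (!is.null(x_sel)) {
      coll <- vapply(remaining, function(v) {
        r <- x_all[, v] - project_fit(cbind(x_all[, v]), x_sel)$fitted
        1 - sum(r^2) / sum(x_all[, v]^2) > 0.999
      }, logical(1))
      if (any(coll)) {
        warning("skipping collinear candidate(s): ",
                paste(remaining[coll], collapse = ", "), call. = FALSE)
        remaining <- remaining[!coll]
        if (!length(remaining)) break
      }
    }
    r2s <- vapply(remaining, function(v) {
      sum(project_fit(y, cbind(x_sel, x_all[, v]))$fitted^2) / ss_tot
    }, numeric(1))
    best <- remaining[which.max(r2s)]
    r2_new <- max(r2s)
    q_new <- length(sel) + 1L
    adj_new <- adjusted_r2(r2_new, n, q_new)
    p_new <- permute_pseudo_f(y, cbind(x_all[, best]), cond = x_sel,
                              n_perm = n_perm, seed = seed + step)
    if (p_new > alpha) break
    # the adjusted-R2 cap cannot bind before any variable is in the model:
    # with pure-noise co-candidates the global adjusted R2 sits at the true
    # model's level, so a strict cap would reject a lone true predictor
    # about half the time; step 1 is already guarded by the global test
    if (use_adjr2_cap && length(sel) >= 1L &&
        adj_new > global_adj + 1e-12) break
    sel <- c(sel, best)
    remaining <- setdiff(remaining, best)
    trace <- rbind(trace, data.frame(variable = best, r2 = r2_new,
                                     adj_r2 = adj_new, p_value = p_new,
                                     stringsAsFactors = FALSE))
  }
  structure(list(selected = sel, trace = trace, global_p = global_p,
                 global_adj_r2 = global_adj, alpha = alpha,
                 n_perm = n_perm, seed = seed),
            class = "forward_selection")
}

#' @export
print.forward_selection <- function(x, ...) {
  cat(sprintf("Forward selection: global p = %.4g, global adj R2 = %.4f\n",
              x$global_p, x$global_adj_r2))
  if (length(x$selected)) {
    print(x$trace, row.names = FALSE)
  } else cat("no variables selected\n")
  invisible(x)
}

#' Variation partitioning over up to four explanatory blocks
#'
#' Decomposes the variation of a community dissimilarity matrix explained
#' by explanatory blocks -- typically environment (X1), linear spatial
#' coordinates (X2), broad-scale dbMEMs (X3) and fine-scale dbMEMs (X4) --
#' into all unique and shared fractions on the adjusted R-squared
#' (Ezekiel) scale, via dbRDA on every union of blocks and inclusion--
#' exclusion.  Marginal (each block alone) and unique (each block given all
#' others) fractions get Monte Carlo permutation tests; shared fractions
#' are not testable.  Fractions plus the residual sum to 1 exactly.
#'
#' @param dissim dissimilarity matrix or [pcoa_embed()] result.
#' @param X1,X2,X3,X4 explanatory blocks (data.frame/matrix or NULL);
#'   typically forward-selected upstream.
#' @param n_perm permutations for the testable fractions (default 999).
#' @param seed integer seed.
#' @return Object of class `variation_partition`: `fractions` (data.frame
#'   with fraction label, blocks involved, adj_R2, p_value where testable),
#'   `unions` (adjusted R2 of every tested union), `residual`.
#' @export
variation_partition <- function(dissim, X1 = NULL, X2 = NULL, X3 = NULL,
                                X4 = NULL, n_perm = 999, seed = 1L) {
  emb <- as_embedding(dissim)
  y <- emb$coords
  n <- nrow(y)
  blocks <- list(X1 = block_matrix(X1, standardize = TRUE),
                 X2 = block_matrix(X2, standardize = TRUE),
                 X3 = block_matrix(X3, standardize = TRUE),
                 X4 = block_matrix(X4, standardize = TRUE))
  blocks <- blocks[!vapply(blocks, is.null, logical(1))]
  b <- length(blocks)
  if (b < 2) stop("need at least 2 non-empty blocks", call. = FALSE)
  ss_tot <- sum(scale(y, scale = FALSE)^2)
  subsets <- lapply(seq_len(2^b - 1), function(m) {
    which(bitwAnd(m, 2^(seq_len(b) - 1)) > 0)
  })
  adj_of_union <- vapply(subsets, function(s) {
    x <- do.call(cbind, blocks[s])
    qrx <- qr(x)
    if (qrx$rank >= n - 1) {
      stop("rank-deficient or saturated union of blocks: ",
           paste(names(blocks)[s], collapse = "+"), call. = FALSE)
    }
    pf <- project_fit(y, x)
    adjusted_r2(sum(pf$fitted^2) / ss_tot, n, pf$rank)
  }, numeric(1))
  names(adj_of_union) <- vapply(subsets, function(s)
    paste(names(blocks)[s], collapse = "+"), character(1))

  # Moebius-style solve: adjR2(union S) = sum of cells T with T
  # intersecting S.  Cells are indexed by non-empty subsets.
  n_sub <- 2^b - 1
  a_mat <- matrix(0, n_sub, n_sub)
  for (i in seq_len(n_sub)) {
    for (j in seq_len(n_sub)) {
      if (bitwAnd(i, j) > 0) a_mat[i, j] <- 1
    }
  }
  cells <- solve(a_mat, adj_of_union)
  cell_label <- vapply(subsets, function(s) {
    if (length(s) == 1) paste0("unique ", names(blocks)[s])
    else paste("shared", paste(names(blocks)[s], collapse = "&"))
  }, character(1))
  fractions <- data.frame(fraction = cell_label,
                          blocks = names(adj_of_union),
                          adj_R2 = unname(cells),
                          p_value = NA_real_,
                          stringsAsFactors = FALSE)
  # permutation tests: marginal and unique fractions
  marg <- data.frame(fraction = paste("marginal", names(blocks)),
                     blocks = names(blocks),
                     adj_R2 = adj_of_union[match(names(blocks),
                                                 names(adj_of_union))],
                     p_value = NA_real_, stringsAsFactors = FALSE)
  for (k in seq_len(b)) {
    marg$p_value[k] <- permute_pseudo_f(y, blocks[[k]], n_perm = n_perm,
                                        seed = seed + k)
    others <- do.call(cbind, blocks[-k])
    idx <- which(lengths(subsets) == 1 &
                   vapply(subsets, function(s) s[1] == k, logical(1)))
    fractions$p_value[idx] <- permute_pseudo_f(y, blocks[[k]], cond = others,
                                               n_perm = n_perm,
                                               seed = seed + 100 + k)
  }
  residual <- 1 - adj_of_union[n_sub]   # all blocks together
  structure(list(fractions = fractions, marginal = marg,
                 unions = adj_of_union, residual = unname(residual),
                 n_perm = n_perm, seed = seed, blocks = names(blocks)),
            class = "variation_partition")
}

#' @export
print.variation_partition <- function(x, ...) {
  cat("Variation partitioning over blocks:",
      paste(x$blocks, collapse = ", "), "\n")
  print(x$fractions, row.names = FALSE, digits = 4)
  cat(sprintf("residual: %.4f (fractions + residual = %.10f)\n",
              x$residual, sum(x$fractions$adj_R2) + x$residual))
  invisible(x)
}

#' Partial distance-based redundancy analysis
#'
#' dbRDA of a focal block after removing the effect of conditioning
#' blocks: the embedding and the focal variables are residualised on the
#' conditioning variables and the ordination runs on the residuals.  The
#' reported `adj_r2` is the adjusted semipartial fraction
#' `adjR2(focal + conditioning) - adjR2(conditioning)`, which equals the
#' corresponding unique fraction of [variation_partition()] when the
#' conditioning set is "all other blocks".  Significance is assessed by
#' permutation of the reduced-model residuals.
#'
#' @param dissim dissimilarity matrix or [pcoa_embed()] result.
#' @param focal focal explanatory block.
#' @param conditioning conditioning block(s); NULL reduces to [dbrda()].
#' @param n_perm permutations (default 999).
#' @param seed integer seed.
#' @return A `dbrda_result` on the residualised problem, with `adj_r2`
#'   replaced by the adjusted semipartial fraction and `p_value` from the
#'   reduced-model permutation test.
#' @export
partial_dbrda <- function(dissim, focal, conditioning = NULL, n_perm = 999,
                          seed = 1L) {
  emb <- as_embedding(dissim)
  y <- emb$coords
  n <- nrow(y)
  xf <- block_matrix(focal, standardize = TRUE)
  xc <- block_matrix(conditioning, standardize = TRUE)
  if (is.null(xf)) stop("empty focal block", call. = FALSE)
  ss_tot <- sum(scale(y, scale = FALSE)^2)
  if (is.null(xc)) {
    res <- dbrda(emb, xf, n_perm = n_perm, seed = seed)
    return(res)
  }
  pc <- project_fit(y, xc)
  y_res <- y - pc$fitted
  xf_res <- xf - project_fit(xf, xc)$fitted
  if (max(abs(xf_res)) < 1e-8) {
    warning("focal block is collinear with the conditioning set",
            call. = FALSE)
  }
  pf_full <- project_fit(y, cbind(xf, xc))
  r2_full <- sum(pf_full$fitted^2) / ss_tot
  r2_cond <- sum(pc$fitted^2) / ss_tot
  adj_sp <- adjusted_r2(r2_full, n, pf_full$rank) -
    adjusted_r2(r2_cond, n, pc$rank)
  pf <- project_fit(y_res, xf_res)
  sv <- svd(pf$fitted)
  keep <- sv$d > max(sv$d, 1e-300) * 1e-8 & sv$d > 1e-10
  eig_c <- sv$d[keep]^2
  axes <- sv$v[, keep, drop = FALSE]
  site <- y_res %*% axes
  lc <- pf$fitted %*% axes
  if (ncol(site)) {
    colnames(site) <- colnames(lc) <- paste0("dbRDA", seq_len(ncol(site)))
    rownames(site) <- rownames(lc) <- rownames(y)
  }
  p_val <- permute_pseudo_f(y, xf, cond = xc, n_perm = n_perm, seed = seed)
  structure(list(eig = eig_c, percent = 100 * eig_c / emb$total_inertia,
                 site_scores = site, lc_scores = lc,
                 biplot_scores = if (ncol(lc)) suppressWarnings(
                   stats::cor(xf_res, lc)) else NULL,
                 r2 = sum(eig_c) / ss_tot, adj_r2 = adj_sp,
                 rank = pf$rank, total_inertia = emb$total_inertia,
                 n = n, p_value = p_val, n_perm = n_perm),
            class = "dbrda_result")
}
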