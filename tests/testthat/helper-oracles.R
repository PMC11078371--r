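# Independent brute-force oracles and small fixtures.  Everything here
# recomputes from first principles (explicit loops over the taxonomy
# lineage), deliberately sharing no code with the package internals.

# Path length between two species straight from their lineage rows:
# count ranks climbed to the lowest common one, then apply cumulative
# step weights and rescale so three steps = scale_max.
oracle_omega_pair <- function(tax, sp1, sp2, steps = c(1, 1, 1),
                              scale_max = 100) {
  r1 <- tax[tax$species == sp1, ]
  r2 <- tax[tax$species == sp2, ]
  lvl <- if (sp1 == sp2) 0L
    else if (r1$genus == r2$genus) 1L
    else if (r1$family == r2$family) 2L
    else 3L
  if (lvl == 0L) return(0)
  cum <- cumsum(steps)
  cum[lvl] / cum[3] * scale_max
}

oracle_omega_matrix <- function(tax, ...) {
  s <- tax$species
  out <- matrix(0, length(s), length(s), dimnames = list(s, s))
  for (i in seq_along(s)) {
    for (j in seq_along(s)) {
      out[i, j] <- oracle_omega_pair(tax, s[i], s[j], ...)
    }
  }
  out
}

# Double-loop Delta+ / Lambda+ over an explicit pair list.
oracle_delta_plus <- function(species, om) {
  s <- length(species)
  tot <- 0
  for (i in seq_len(s - 1)) {
    for (j in (i + 1):s) tot <- tot + om[species[i], species[j]]
  }
  tot / (s * (s - 1) / 2)
}

oracle_lambda_plus <- function(species, om) {
  s <- length(species)
  dp <- oracle_delta_plus(species, om)
  tot <- 0
  for (i in seq_len(s - 1)) {
    for (j in (i + 1):s) tot <- tot + (om[species[i], species[j]] - dp)^2
  }
  tot / (s * (s - 1) / 2)
}

# Directed nearest-relative enumeration for theta+.
oracle_theta_plus <- function(a, b, om) {
  mins_a <- vapply(a, function(i) min(om[i, b]), numeric(1))
  mins_b <- vapply(b, function(j) min(om[a, j]), numeric(1))
  (sum(mins_a) + sum(mins_b)) / (length(a) + length(b))
}

# 4-species toy: two congeneric, one confamilial, one in another family.
toy4_taxonomy <- function() {
  data.frame(species = c("s1", "s2", "s3", "s4"),
             genus = c("G1", "G1", "G2", "G3"),
             family = c("F1", "F1", "F1", "F2"),
             class = "Cl", stringsAsFactors = FALSE)
}

# 5-species toy for theta+: 3 vs 2 species, no shared species.
toy5_taxonomy <- function() {
  data.frame(species = paste0("t", 1:5),
             genus = c("Ga", "Ga", "Gb", "Gc", "Gd"),
             family = c("Fa", "Fa", "Fa", "Fb", "Fb"),
             class = "Cl", stringsAsFactors = FALSE)
}

# Small random taxonomy for property tests (independent of gen_taxonomy's
# layout choices, still strict-tree by construction).
rand_taxonomy <- function(n_species, seed) {
  set.seed(seed)
  nf <- max(2, round(n_species / 4))
  ng <- max(nf, round(n_species / 2))
  fam_of_gen <- c(seq_len(nf), sample.int(nf, ng - nf, replace = TRUE))
  gen_of_sp <- c(seq_len(ng),
                 sample.int(ng, n_species - ng, replace = TRUE))
  data.frame(species = sprintf("Sp%02d", seq_len(n_species)),
             genus = sprintf("G%02d", gen_of_sp),
             family = sprintf("F%02d", fam_of_gen[gen_of_sp]),
             class = "Cl", stringsAsFactors = FALSE)
}

# Adjusted Rand index between two partitions.
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(tab)
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  (sij - expected) / ((si + sj) / 2 - expected)
}

# Block dissimilarity matrix: small within-block, large between-block,
# plus deterministic jitter to break ties.
block_dissim <- function(sizes, within = 5, between = 60, jitter = 1,
                         seed = 1) {
  set.seed(seed)
  lab <- rep(seq_along(sizes), sizes)
  n <- length(lab)
  d <- matrix(0, n, n, dimnames = list(paste0("b", 1:n), paste0("b", 1:n)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      base <- if (lab[i] == lab[j]) within else between
      d[i, j] <- d[j, i] <- base + stats::runif(1, 0, jitter)
    }
  }
  list(d = d, labels = lab)
}

# Tiny default survey reused across tests (cheap, deterministic).
small_survey <- function(seed = 5, n_stations = 15, n_species = 30) {
  suppressWarnings(simulate_survey(synthetic_scenario(
    n_stations = n_stations, n_species = n_species,
    n_genera = max(4, n_species %/% 2),
    n_families = max(2, n_species %/% 4), seed = seed)))
}
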