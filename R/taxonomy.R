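#' Step weights for taxonomic path lengths
#'
#' Defines the per-level step lengths used when measuring the taxonomic path
#' between two species through the Linnaean hierarchy, and the value the
#' largest attainable path is rescaled to.
#'
#' The three steps are, in order: species to genus, genus to family, and
#' family to class (the tree root when all species share one class).  The
#' published distinctness literature rarely states edge weights; the default
#' is equal steps rescaled so the maximal path equals 100, which is the
#' convention under which average taxonomic distinctness lives on a 0--100
#' scale.
#'
#' @param steps numeric vector of length 3, positive step lengths for
#'   (species->genus, genus->family, family->class).
#' @param scale_max positive scalar; the largest attainable path length is
#'   rescaled to this value (default 100).
#' @return An object of class `step_weights`.
#' @examples
#' tax_step_weights()                  # equal steps, max path = 100
#' tax_step_weights(c(1, 2, 3), 100)   # deeper ranks weigh more
#' @export
tax_step_weights <- function(steps = c(1, 1, 1), scale_max = 100) {
  steps <- as.numeric(steps)
  if (length(steps) != 3L || any(!is.finite(steps)) || any(steps <= 0)) {
    stop("`steps` must be 3 positive numbers", call. = FALSE)
  }
  if (!is.numeric(scale_max) || length(scale_max) != 1L || scale_max <= 0) {
    stop("`scale_max` must be a positive scalar", call. = FALSE)
  }
  structure(list(steps = steps, scale_max = scale_max),
            class = "step_weights")
}

#' @export
print.step_weights <- function(x, ...) {
  cat("Taxonomic step weights:", paste(signif(x$steps, 4), collapse = ", "),
      "| max path scaled to", x$scale_max, "\n")
  invisible(x)
}

norm_name <- function(x) {
  x <- gsub("\\s+", " ", trimws(as.character(x)))
  # Title-case the first letter only; taxonomic names are case-insensitive
  # in practice but canonically capitalised.
  paste0(toupper(substring(x, 1, 1)), tolower(substring(x, 2)))
}

#' Validate a taxonomy table
#'
#' Checks that a species/genus/family/class table is a strict tree: species
#' names unique, each genus under exactly one family, each family under
#' exactly one class.  Names are whitespace-trimmed and case-normalised
#' before checking; no fuzzy matching is attempted.
#'
#' @param table data.frame with columns `species`, `genus`, `family`,
#'   `class` (extra columns are dropped with a warning).
#' @return The validated, name-normalised data.frame (one row per species).
#' @examples
#' tax <- data.frame(species = c("a one", "a two", "b one"),
#'                   genus = c("A", "A", "B"),
#'                   family = c("Fam1", "Fam1", "Fam2"),
#'                   class = "Poly")
#' validate_taxonomy(tax)
#' @export
validate_taxonomy <- function(table) {
  if (is.null(table) || !is.data.frame(table) || nrow(table) == 0L) {
    stop("empty taxonomy", call. = FALSE)
  }
  need <- c("species", "genus", "family", "class")
  names(table) <- tolower(names(table))
  miss <- setdiff(need, names(table))
  if (length(miss)) {
    stop("taxonomy table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  extra <- setdiff(names(table), need)
  if (length(extra)) {
    warning("ignoring extra taxonomy column(s): ",
            paste(extra, collapse = ", "), call. = FALSE)
  }
  tab <- table[need]
  for (col in need) tab[[col]] <- norm_name(tab[[col]])
  if (any(tab == "" | is.na(tab))) {
    bad <- which(rowSums(tab == "" | is.na(tab)) > 0)
    stop("taxonomy rows with missing names: ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  }
  dup <- unique(tab$species[duplicated(tab$species)])
  if (length(dup)) {
    stop("duplicate species in taxonomy: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  gf <- unique(tab[c("genus", "family")])
  badg <- unique(gf$genus[duplicated(gf$genus)])
  if (length(badg)) {
    stop("genus assigned to more than one family: ",
         paste(badg, collapse = ", "), call. = FALSE)
  }
  fc <- unique(tab[c("family", "class")])
  badf <- unique(fc$family[duplicated(fc$family)])
  if (length(badf)) {
    stop("family assigned to more than one class: ",
         paste(badf, collapse = ", "), call. = FALSE)
  }
  rownames(tab) <- NULL
  tab
}

#' Pairwise taxonomic path lengths
#'
#' Builds the symmetric matrix of taxonomic path lengths omega between all
#' species pairs.  The path between two species is counted in rank steps to
#' their lowest common rank: congeneric pairs take one step, confamilial
#' pairs (different genus) two, and pairs sharing only the class three.
#' Step lengths come from [tax_step_weights()] and the matrix is rescaled so
#' the maximum attainable path equals `scale_max` (100 by default, giving
#' attainable values 100/3, 200/3 and 100 under equal steps).
#'
#' @param table a taxonomy table (validated by [validate_taxonomy()]; it is
#'   re-validated here).
#' @param weights a [tax_step_weights()] object.
#' @return A symmetric numeric matrix with species names on both margins,
#'   class `c("path_lengths", "matrix")`, zero diagonal, and attributes
#'   `weights` and `taxonomy`.
#' @examples
#' tax <- data.frame(species = c("s1", "s2", "s3"),
#'                   genus = c("G1", "G1", "G2"),
#'                   family = c("F1", "F1", "F2"), class = "Poly")
#' tax_path_lengths(tax)
#' @export
tax_path_lengths <- function(table, weights = tax_step_weights()) {
  tab <- validate_taxonomy(table)
  if (!inherits(weights, "step_weights")) {
    stop("`weights` must come from tax_step_weights()", call. = FALSE)
  }
  # cumulative path length to the lowest common rank: genus, family, class
  cum <- cumsum(weights$steps)
  scale <- weights$scale_max / cum[3]
  s <- tab$species
  n <- length(s)
  g <- match(tab$genus, unique(tab$genus))
  f <- match(tab$family, unique(tab$family))
  level <- matrix(3, n, n)                 # default: share class only
  level[outer(f, f, "==")] <- 2            # same family
  level[outer(g, g, "==")] <- 1            # same genus
  omega <- matrix(cum[level], n, n) * scale
  diag(omega) <- 0
  dimnames(omega) <- list(s, s)
  structure(omega, class = c("path_lengths", "matrix"),
            weights = weights, taxonomy = tab)
}

# Subset an omega matrix to a species set, with a clear error for species
# that are absent from the taxonomy it was built from.
omega_subset <- function(omega, species) {
  species <- unique(as.character(species))
  missing <- setdiff(species, rownames(omega))
  if (length(missing)) {
    stop("species missing from taxonomy: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  omega[species, species, drop = FALSE]
}
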