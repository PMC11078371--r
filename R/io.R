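#' Read a taxonomy CSV
#'
#' Expects header columns `species,genus,family,class`; extra columns are
#' ignored with a warning.  The table is validated against the strict-tree
#' invariant.
#'
#' @param path CSV file.
#' @return Validated taxonomy data.frame.
#' @export
read_taxonomy <- function(path) {
  validate_taxonomy(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Read an occurrence table (long or wide)
#'
#' Long form has columns `station,species` (one row per occurrence); wide
#' form has a first `station` column followed by one 0/1 column per
#' species.  The format is auto-detected from the header.
#'
#' @param path CSV file.
#' @return station x species 0/1 matrix.
#' @export
read_occurrence <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  names(df)[1] <- tolower(names(df)[1])
  if (ncol(df) == 2 && all(tolower(names(df)) == c("station", "species"))) {
    st <- unique(df[[1]])
    sp <- sort(unique(df[[2]]))
    comm <- matrix(0, length(st), length(sp), dimnames = list(st, sp))
    comm[cbind(match(df[[1]], st), match(df[[2]], sp))] <- 1
  } else {
    if (names(df)[1] != "station") {
      stop("occurrence CSV must start with a 'station' column ",
           "(wide) or be exactly station,species (long)", call. = FALSE)
    }
    comm <- as.matrix(df[, -1, drop = FALSE])
    rownames(comm) <- as.character(df[[1]])
    if (!all(comm %in% 0:1)) {
      stop("wide occurrence matrix must be 0/1", call. = FALSE)
    }
  }
  storage.mode(comm) <- "double"
  comm
}

#' Write an occurrence matrix as a wide CSV
#' @param comm station x species matrix.
#' @param path output CSV.
#' @export
write_occurrence <- function(comm, path) {
  df <- data.frame(station = rownames(comm), comm, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
}

#' Read a station table CSV
#'
#' Needs `station,lat,lon` plus any environmental columns; coordinates are
#' decimal degrees (WGS84 assumed, west longitudes negative).
#'
#' @param path CSV file.
#' @return data.frame with validated coordinates.
#' @export
read_stations <- function(path) {
  st <- utils::read.csv(path, stringsAsFactors = FALSE)
  st <- as_station_table(st)
  bad <- which(!is.finite(st$lat) | !is.finite(st$lon) |
                 abs(st$lat) > 90 | abs(st$lon) > 360)
  if (length(bad)) {
    stop("malformed coordinates in station rows: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  dup <- unique(st$station[duplicated(st$station)])
  if (length(dup)) stop("duplicate stations: ", paste(dup, collapse = ", "),
                        call. = FALSE)
  st
}

#' Write a square matrix as CSV with station ids
#' @param m square matrix with dimnames.
#' @param path output CSV.
#' @export
write_square_matrix <- function(m, path) {
  df <- data.frame(station = rownames(m), unclass(m), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
}

#' Read a square matrix CSV written by [write_square_matrix()]
#' @param path CSV file.
#' @return matrix with station dimnames.
#' @export
read_square_matrix <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  m
}

#' Assemble a pipeline configuration
#'
#' Collects paths and stage settings with the defaults used throughout the
#' package; a single global seed feeds every stochastic stage through
#' documented fixed offsets (funnel +10/+11, bootstrap +20, ANOSIM +30,
#' forward selection +40/+41, partitioning +50).
#'
#' @param taxonomy,occurrence,stations input CSV paths (NULL to use a
#'   synthetic scenario instead).
#' @param scenario optional [synthetic_scenario()] used when paths are
#'   NULL.
#' @param funnel_n_sim,funnel_alpha funnel settings.
#' @param n_boot decay bootstrap replicates.
#' @param k_range,ward_method clustering settings.
#' @param truncation optional dbMEM truncation override (km).
#' @param broad_mems optional explicit broad-scale MEM names.
#' @param select_alpha,n_perm selection/testing settings.
#' @param theta_method pooled or average theta+.
#' @param seed global seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(taxonomy = NULL, occurrence = NULL,
                            stations = NULL, scenario = NULL,
                            funnel_n_sim = 1000, funnel_alpha = 0.05,
                            n_boot = 1000, k_range = 2:8,
                            ward_method = "ward.D2", truncation = NULL,
                            broad_mems = NULL, select_alpha = 0.05,
                            n_perm = 999,
                            theta_method = "pooled", seed = 1L) {
  structure(list(taxonomy = taxonomy, occurrence = occurrence,
                 stations = stations, scenario = scenario,
                 funnel_n_sim = funnel_n_sim, funnel_alpha = funnel_alpha,
                 n_boot = n_boot, k_range = k_range,
                 ward_method = ward_method, truncation = truncation,
                 broad_mems = broad_mems, select_alpha = select_alpha,
                 n_perm = n_perm, theta_method = theta_method,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration as JSON
#' @param config a [pipeline_config()].
#' @param path JSON file.
#' @export
write_config <- function(config, path) {
  cfg <- config
  if (!is.null(cfg$scenario)) {
    cfg$scenario <- unclass(cfg$scenario)
    # jsonlite drops names of atomic vectors; store the bbox as a list
    cfg$scenario$bbox <- as.list(cfg$scenario$bbox)
  }
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(cfg$scenario)) {
    sc <- cfg$scenario
    env <- sc$env
    cfg$scenario <- synthetic_scenario(
      n_stations = sc$n_stations, n_species = sc$n_species,
      n_genera = sc$n_genera, n_families = sc$n_families,
      bbox = unlist(sc$bbox), env = env,
      niche_tolerance = sc$niche_tolerance,
      dispersal_rate = sc$dispersal_rate,
      dispersal_amp = sc$dispersal_amp,
      baseline_logit = sc$baseline_logit, seed = sc$seed)
  }
  cfg$k_range <- as.integer(cfg$k_range)
  do.call(pipeline_config, cfg[setdiff(names(cfg), character(0))])
}

#' Read and cross-validate the three input tables
#'
#' Loads taxonomy, occurrence and station CSVs named in a config (or
#' simulates them from its scenario) and checks referential integrity:
#' every occurring species must be in the taxonomy and every occurring
#' station in the station table.
#'
#' @param config a [pipeline_config()].
#' @return list: `taxonomy`, `community`, `stations`.
#' @export
read_inputs <- function(config) {
  if (is.null(config$taxonomy) || is.null(config$occurrence) ||
      is.null(config$stations)) {
    sc <- if (is.null(config$scenario)) {
      synthetic_scenario(seed = config$seed)
    } else config$scenario
    sim <- simulate_survey(sc)
    return(sim[c("taxonomy", "stations", "community")])
  }
  tax <- read_taxonomy(config$taxonomy)
  comm <- read_occurrence(config$occurrence)
  st <- read_stations(config$stations)
  orphan_sp <- setdiff(colnames(comm), tax$species)
  if (length(orphan_sp)) {
    stop("occurrence species absent from taxonomy: ",
         paste(orphan_sp, collapse = ", "), call. = FALSE)
  }
  orphan_st <- setdiff(rownames(comm), st$station)
  if (length(orphan_st)) {
    stop("occurrence stations absent from station table: ",
         paste(orphan_st, collapse = ", "), call. = FALSE)
  }
  st <- st[match(rownames(comm), st$station), ]
  list(taxonomy = tax, community = comm, stations = st)
}

#' Run the full analysis pipeline
#'
#' Chains every stage on one set of inputs: path lengths, per-station
#' distinctness with Delta+/Lambda+ funnels, the theta+ dissimilarity
#' matrix, exponential distance decay with bootstrap, Ward clustering with
#' silhouette k and (pairwise) ANOSIM, dbMEM construction, forward
#' selection of environmental and spatial predictors, dbRDA, and
#' four-block variation partitioning.  Every intermediate is written as
#' CSV/JSON under `out_dir` together with a manifest of checksums.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if missing).
#' @return list with all stage results plus `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("run")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  stages <- character(0)
  log_stage <- function(name) {
    stages <<- c(stages, name)
    message(sprintf("[%s] stage %d: %s", format(Sys.time(), "%H:%M:%S"),
                    length(stages), name))
  }
  run <- function(name, expr) {
    log_stage(name)
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  inputs <- run("inputs", read_inputs(config))
  tax <- inputs$taxonomy; comm <- inputs$community; st <- inputs$stations
  utils::write.csv(tax, file.path(out_dir, "taxonomy.csv"), row.names = FALSE)
  write_occurrence(comm, file.path(out_dir, "occurrence.csv"))
  utils::write.csv(st, file.path(out_dir, "stations.csv"), row.names = FALSE)

  omega <- run("path_lengths", tax_path_lengths(tax))

  distinct <- run("distinctness", {
    res <- taxonomic_distinctness(comm, omega)
    m_obs <- sort(unique(res$S[res$S >= 2]))
    m_grid <- sort(unique(c(2, m_obs, nrow(tax))))
    fun_d <- build_funnel(omega, "delta_plus", m_grid = m_grid,
                          n_sim = config$funnel_n_sim,
                          alpha = config$funnel_alpha, seed = seed + 10L)
    fun_l <- build_funnel(omega, "lambda_plus", m_grid = m_grid,
                          n_sim = config$funnel_n_sim,
                          alpha = config$funnel_alpha, seed = seed + 11L)
    cls <- classify_stations(res, fun_d)
    cls$lambda_class <- classify_stations(res, fun_l)$funnel_class
    utils::write.csv(cls, file.path(out_dir, "distinctness.csv"),
                     row.names = FALSE)
    utils::write.csv(fun_d$grid, file.path(out_dir, "funnel_delta.csv"),
                     row.names = FALSE)
    utils::write.csv(fun_l$grid, file.path(out_dir, "funnel_lambda.csv"),
                     row.names = FALSE)
    list(result = cls, funnel_delta = fun_d, funnel_lambda = fun_l)
  })

  theta <- run("theta_plus", {
    th <- theta_plus_matrix(comm, omega, method = config$theta_method)
    write_square_matrix(th, file.path(out_dir, "theta_plus.csv"))
    th
  })
  geo <- run("geo_distances", {
    g <- geo_distance_matrix(st)
    write_square_matrix(g, file.path(out_dir, "geo_km.csv"))
    g
  })

  decay <- run("decay", {
    fit <- fit_decay(theta, geo)
    fit <- bootstrap_decay(fit, n_boot = config$n_boot, seed = seed + 20L)
    utils::write.csv(fit$pairs, file.path(out_dir, "decay_pairs.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(a = fit$a, b = fit$b,
                              ci = as.data.frame(fit$ci),
                              n_boot = fit$n_boot, seed = fit$seed),
                         file.path(out_dir, "decay_fit.json"),
                         auto_unbox = TRUE, digits = NA)
    fit
  })

  clust <- run("clustering", {
    cl <- ward_cluster(theta, method = config$ward_method)
    cl <- choose_k(cl, k_range = config$k_range)
    utils::write.csv(data.frame(station = names(cl$labels),
                                cluster = unname(cl$labels)),
                     file.path(out_dir, "assemblages.csv"),
                     row.names = FALSE)
    write_dendrogram(cl, file.path(out_dir, "dendrogram.nwk"))
    cl
  })

  anosim_res <- run("anosim", {
    sizes <- table(clust$labels)
    keep <- clust$labels %in% names(sizes)[sizes >= 2]
    if (!all(keep)) {
      message("ANOSIM: dropping singleton cluster station(s): ",
              paste(names(clust$labels)[!keep], collapse = ", "))
    }
    th_k <- theta[keep, keep]
    lab_k <- factor(clust$labels[keep])
    if (nlevels(lab_k) < 2) {
      message("ANOSIM skipped: fewer than 2 clusters of size >= 2")
      glob <- NULL
      pw <- data.frame(group1 = character(0), group2 = character(0),
                       R = numeric(0), p_value = numeric(0))
    } else {
      glob <- anosim_test(th_k, lab_k, n_perm = config$n_perm,
                          seed = seed + 30L)
      pw <- pairwise_anosim(th_k, lab_k, n_perm = config$n_perm,
                            seed = seed + 30L)
    }
    utils::write.csv(pw, file.path(out_dir, "anosim_pairwise.csv"),
                     row.names = FALSE)
    list(global = glob, pairwise = pw)
  })

  spatial <- run("dbmem", {
    basis <- build_dbmem(st, truncation = config$truncation)
    write_square_matrix(basis$vectors, file.path(out_dir, "dbmem.csv"))
    basis
  })

  env_vars <- setdiff(names(st), c("station", "lat", "lon", "region"))
  emb <- pcoa_embed(theta)
  selection <- run("forward_selection", {
    env_sel <- forward_select(emb, st[env_vars],
                              alpha = config$select_alpha,
                              n_perm = config$n_perm, seed = seed + 40L)
    mem_sel <- forward_select(emb,
                              spatial$vectors[, spatial$retained,
                                              drop = FALSE],
                              alpha = config$select_alpha,
                              n_perm = config$n_perm, seed = seed + 41L)
    list(env = env_sel, mem = mem_sel)
  })

  # fall back to full candidate sets when selection is empty so the
  # ordination stages remain exercisable; flagged in the manifest
  env_used <- if (length(selection$env$selected)) selection$env$selected
              else env_vars
  mem_used <- if (length(selection$mem$selected)) selection$mem$selected
              else spatial$retained

  ordination <- run("dbrda", {
    x <- cbind(as.matrix(st[env_used]),
               spatial$vectors[, mem_used, drop = FALSE])
    res <- dbrda(emb, x, n_perm = config$n_perm, seed = seed + 50L)
    utils::write.csv(data.frame(station = rownames(res$site_scores),
                                res$site_scores),
                     file.path(out_dir, "dbrda_scores.csv"),
                     row.names = FALSE)
    res
  })

  partition <- run("partition", {
    mems <- split_mems(spatial, mems = mem_used, broad = config$broad_mems)
    coords_xy <- scale(as.matrix(st[c("lon", "lat")]), scale = FALSE)
    part <- variation_partition(emb,
                                X1 = st[env_used],
                                X2 = coords_xy,
                                X3 = if (ncol(mems$broad)) mems$broad,
                                X4 = if (ncol(mems$fine)) mems$fine,
                                n_perm = config$n_perm, seed = seed + 51L)
    utils::write.csv(part$fractions, file.path(out_dir, "partition.csv"),
                     row.names = FALSE)
    part
  })

  files <- list.files(out_dir, full.names = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("taxodive")),
    seed = seed, stages = stages, n_stages = length(stages),
    env_selected = env_used, mem_selected = mem_used,
    selection_fallback = c(env = !length(selection$env$selected),
                           mem = !length(selection$mem$selected)),
    stochastic_settings = list(funnel_n_sim = config$funnel_n_sim,
                               n_boot = config$n_boot,
                               n_perm = config$n_perm),
    checksums = as.list(tools::md5sum(files)),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(inputs = inputs, omega = omega, distinctness = distinct,
                 theta = theta, geo = geo, decay = decay,
                 clustering = clust, anosim = anosim_res,
                 dbmem = spatial, selection = selection,
                 dbrda = ordination, partition = partition,
                 manifest = manifest, out_dir = out_dir))
}
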