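#' Run configuration for the end-to-end pipeline
#'
#' Collects the input paths, thresholds and flags of a full analysis run.
#' The defaults are the conventional genome-scale constants for this kind
#' of study: edge significance p < 1e-7, differential-expression FDR
#' q < 0.10, ANOVA P < 0.01, enrichment FDR < 0.01, fold change > 1.5.
#'
#' @param matrix_file,variable_file,sample_file Measurement matrix TSVs
#'   (see [read_matrix_tsv()]).
#' @param hub_file Hub list TSV (see [read_hubs_tsv()]).
#' @param geneset_file Optional GMT file for enrichment.
#' @param idmap_file Optional identifier map TSV.
#' @param external_de_file Optional external DE contrast TSV for the
#'   direction-consistency report.
#' @param consistency_hub Hub whose neighbourhood is scored against the
#'   external contrast (default: the first physiology hub).
#' @param panel Optional gene panel (character vector) for KNN
#'   classification of healthy vs COPD samples.
#' @param edge_p,de_q,anova_p,enrich_q,min_fold Analysis thresholds.
#' @param estimator MI estimator (see [mutual_information()]).
#' @param n_permutations Null MI draws for [calibrate_null()].
#' @param n_null Null draws for [coupling_score()].
#' @param paired Paired pre/post t-tests (default TRUE).
#' @param dpi Apply [apply_dpi()] to the merged network (default FALSE).
#' @param dpi_tolerance DPI tolerance.
#' @param group_standardize Standardize within groups (default FALSE).
#' @param log2_expression Expression rows are log2-scale (default TRUE).
#' @param knn_k Neighbour count for [knn_cv()].
#' @param seed Integer seed driving every stochastic stage.
#' @return Object of class `run_config` (a validated list).
#' @export
run_config <- function(matrix_file = NULL, variable_file = NULL,
                       sample_file = NULL, hub_file = NULL,
                       geneset_file = NULL, idmap_file = NULL,
                       external_de_file = NULL, consistency_hub = NULL,
                       panel = NULL,
                       edge_p = 1e-7, de_q = 0.10, anova_p = 0.01,
                       enrich_q = 0.01, min_fold = 1.5,
                       estimator = "gaussian_kernel",
                       n_permutations = 1e5, n_null = 1000,
                       paired = TRUE, dpi = FALSE, dpi_tolerance = 0,
                       group_standardize = FALSE, log2_expression = TRUE,
                       knn_k = 3, seed = 1L) {
  for (nm in c("edge_p", "de_q", "anova_p", "enrich_q")) {
    v <- get(nm)
    if (!is.numeric(v) || v <= 0 || v >= 1)
      stop(nm, " must be in (0, 1)")
  }
  if (min_fold <= 1) stop("min_fold must be > 1")
  if (seed != round(seed)) stop("seed must be an integer")
  structure(list(matrix_file = matrix_file, variable_file = variable_file,
                 sample_file = sample_file, hub_file = hub_file,
                 geneset_file = geneset_file, idmap_file = idmap_file,
                 external_de_file = external_de_file,
                 consistency_hub = consistency_hub, panel = panel,
                 edge_p = edge_p, de_q = de_q, anova_p = anova_p,
                 enrich_q = enrich_q, min_fold = min_fold,
                 estimator = estimator,
                 n_permutations = as.integer(n_permutations),
                 n_null = as.integer(n_null), paired = paired, dpi = dpi,
                 dpi_tolerance = dpi_tolerance,
                 group_standardize = group_standardize,
                 log2_expression = log2_expression, knn_k = knn_k,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path Path to a YAML file whose keys match the arguments of
#'   [run_config()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown))
    stop("unknown config keys in ", path, ": ",
         paste(unknown, collapse = ", "))
  do.call(run_config, y)
}

#' Execute the full analysis pipeline
#'
#' Reads the inputs, standardizes, calibrates the MI null, infers one
#' module per hub, merges them (optionally DPI-pruned), computes the
#' training response per group, the two-factor ANOVA, optional enrichment,
#' the remodelling-vs-bioenergetics coupling report, the optional
#' direction-consistency report and the optional KNN panel classification,
#' and writes every result plus a manifest into `out_dir`.  Re-running with
#' the identical config and seed reproduces identical outputs.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory results
#'   (`matrix`, `calibration`, `modules`, `network`, `de`, `anova`,
#'   `coupling`, `consistency`, `classification`, `enrichment`, `manifest`).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_file <- file.path(out_dir, "run.log")
  logf <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S "), sprintf(...))
    cat(msg, "\n", sep = "", file = log_file, append = TRUE)
    message(msg)
  }
  logf("run_pipeline start, seed = %d", config$seed)

  m <- read_matrix_tsv(config$matrix_file, config$variable_file,
                       config$sample_file, config$log2_expression)
  hubs <- read_hubs_tsv(config$hub_file)
  miss <- setdiff(hubs$hub_id, rownames(m$values))
  if (length(miss)) stop("hubs missing from the matrix: ",
                         paste(miss, collapse = ", "))

  sm <- standardize(m, by_group = config$group_standardize)
  write_matrix_tsv(sm, file.path(out_dir, "standardized_matrix.tsv"),
                   file.path(out_dir, "standardized_variables.tsv"),
                   file.path(out_dir, "standardized_samples.tsv"))

  logf("calibrating MI null (%d permutations, %s)",
       config$n_permutations, config$estimator)
  cal <- calibrate_null(sm, n_permutations = config$n_permutations,
                        seed = config$seed, estimator = config$estimator)
  write_calibration(cal, file.path(out_dir, "calibration.json"))

  logf("inferring %d hub modules at p < %g", nrow(hubs), config$edge_p)
  modules <- lapply(seq_len(nrow(hubs)), function(i)
    infer_module(sm, hubs$hub_id[i], cal, config$edge_p,
                 hub_category = hubs$category[i]))
  network <- merge_modules(modules)
  if (config$dpi) network <- apply_dpi(network, config$dpi_tolerance)
  write_graphml(network, file.path(out_dir, "network.graphml"))
  write_sif(network, file.path(out_dir, "network.sif"))

  de <- list()
  for (g in unique(m$sample_meta$group)) {
    de[[g]] <- tryCatch(
      train_response(m, g, paired = config$paired, fdr = config$de_q),
      error = function(e) { logf("train_response(%s): %s", g,
                                 conditionMessage(e)); NULL })
    if (!is.null(de[[g]]))
      write_de_tsv(de[[g]], file.path(out_dir, paste0("de_", g, ".tsv")))
  }
  anova <- two_factor_anova(m)
  utils::write.table(anova, file.path(out_dir, "anova.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  enrichment <- NULL
  first_de <- Filter(Negate(is.null), de)
  if (!is.null(config$geneset_file) && length(first_de)) {
    sets <- read_gmt(config$geneset_file)
    sig <- first_de[[1]]$id[first_de[[1]]$direction != "ns"]
    enrichment <- enrich(sig, sets,
                         universe = first_de[[1]]$id, fdr = config$enrich_q)
    utils::write.table(enrichment, file.path(out_dir, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  coupling <- tryCatch(
    coupling_score(network, n_null = config$n_null, seed = config$seed),
    error = function(e) { logf("coupling_score: %s", conditionMessage(e))
      NULL })
  if (!is.null(coupling))
    jsonlite::write_json(unclass(coupling),
                         file.path(out_dir, "coupling.json"),
                         auto_unbox = TRUE, digits = NA)

  consistency <- NULL
  if (!is.null(config$external_de_file)) {
    ext <- read_de_tsv(config$external_de_file)
    hub <- config$consistency_hub
    if (is.null(hub)) hub <- hubs$hub_id[hubs$category == "physiology"][1]
    consistency <- tryCatch(
      direction_consistency(network, hub, ext, fdr = config$de_q),
      error = function(e) { logf("direction_consistency: %s",
                                 conditionMessage(e)); NULL })
    if (!is.null(consistency))
      jsonlite::write_json(unclass(consistency),
                           file.path(out_dir, "consistency.json"),
                           auto_unbox = TRUE, digits = NA)
  }

  classification <- NULL
  if (!is.null(config$panel)) {
    lab <- ifelse(m$sample_meta$group == "healthy", "healthy", "COPD")
    names(lab) <- m$sample_meta$id
    classification <- knn_cv(sm, lab, config$panel, k = config$knn_k,
                             seed = config$seed)
    utils::write.table(classification$predictions,
                       file.path(out_dir, "classification.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  cfg_for_hash <- config
  manifest <- list(
    package_version = as.character(utils::packageVersion("muscleNet")),
    seed = config$seed,
    config = unclass(cfg_for_hash),
    config_hash = .config_hash(cfg_for_hash),
    outputs = list.files(out_dir))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  logf("run_pipeline done: %d nodes, %d edges",
       igraph::vcount(network), igraph::ecount(network))
  invisible(list(matrix = sm, calibration = cal, modules = modules,
                 network = network, de = de, anova = anova,
                 coupling = coupling, consistency = consistency,
                 classification = classification, enrichment = enrichment,
                 manifest = manifest))
}

.config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                              digits = NA, null = "null"), tmp)
  unname(tools::md5sum(tmp))
}
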