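#' Multi-modal measurement matrix
#'
#' The central data container: a variables-by-samples numeric matrix together
#' with per-variable and per-sample annotation.  Variables span three
#' modalities -- whole-body physiology, serum protein levels and muscle gene
#' expression -- measured on the same subjects before ("pre") and after
#' ("post") a training programme.
#'
#' @param values Numeric matrix, variables in rows, samples in columns.
#'   Row and column names are taken from `variable_meta$id` /
#'   `sample_meta$id` when absent.
#' @param variable_meta Data frame with columns `id` and `modality`
#'   (one of `"physiology"`, `"serum_protein"`, `"gene_expression"`),
#'   one row per variable, in row order of `values`.
#' @param sample_meta Data frame with columns `id`, `subject`, `group`,
#'   `timepoint` (`"pre"`/`"post"`), one row per sample, in column order of
#'   `values`.
#' @param log2_expression Logical flag: are gene-expression rows on the
#'   log2 scale (as for normalized microarray data)?  Governs how fold
#'   changes are computed downstream.
#'
#' @return An object of class `measurement_matrix`: a list with elements
#'   `values`, `variable_meta`, `sample_meta`, `log2_expression`.
#' @export
measurement_matrix <- function(values, variable_meta, sample_meta,
                               log2_expression = TRUE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  variable_meta <- as.data.frame(variable_meta, stringsAsFactors = FALSE)
  sample_meta <- as.data.frame(sample_meta, stringsAsFactors = FALSE)

  if (!all(c("id", "modality") %in% names(variable_meta)))
    stop("variable_meta needs columns 'id' and 'modality'")
  if (!all(c("id", "subject", "group", "timepoint") %in% names(sample_meta)))
    stop("sample_meta needs columns 'id', 'subject', 'group', 'timepoint'")
  if (nrow(values) != nrow(variable_meta))
    stop("values has ", nrow(values), " rows but variable_meta has ",
         nrow(variable_meta))
  if (ncol(values) != nrow(sample_meta))
    stop("values has ", ncol(values), " columns but sample_meta has ",
         nrow(sample_meta))
  if (anyDuplicated(variable_meta$id))
    stop("duplicated variable ids: ",
         paste(unique(variable_meta$id[duplicated(variable_meta$id)]),
               collapse = ", "))
  if (anyDuplicated(sample_meta$id))
    stop("duplicated sample ids: ",
         paste(unique(sample_meta$id[duplicated(sample_meta$id)]),
               collapse = ", "))
  bad_mod <- setdiff(unique(variable_meta$modality),
                     c("physiology", "serum_protein", "gene_expression"))
  if (length(bad_mod))
    stop("unknown modality: ", paste(bad_mod, collapse = ", "))
  if (any(is.na(sample_meta$group)) || any(is.na(sample_meta$timepoint)))
    stop("sample_meta has missing group or timepoint labels")
  if (any(is.infinite(values)))
    stop("values must be finite (use NA to flag missing entries)")

  rownames(values) <- variable_meta$id
  colnames(values) <- sample_meta$id
  structure(list(values = values,
                 variable_meta = variable_meta,
                 sample_meta = sample_meta,
                 log2_expression = isTRUE(log2_expression)),
            class = "measurement_matrix")
}

#' @export
print.measurement_matrix <- function(x, ...) {
  cat("measurement_matrix:", nrow(x$values), "variables x",
      ncol(x$values), "samples\n")
  cat("  modalities:",
      paste(sprintf("%s (%d)", names(table(x$variable_meta$modality)),
                    table(x$variable_meta$modality)), collapse = ", "), "\n")
  cat("  groups:",
      paste(sprintf("%s (%d)", names(table(x$sample_meta$group)),
                    table(x$sample_meta$group)), collapse = ", "), "\n")
  if (isTRUE(attr(x, "standardized"))) cat("  standardized\n")
  invisible(x)
}

#' Subset a measurement matrix by variables and/or samples
#'
#' @param m A `measurement_matrix`.
#' @param variables,samples Character vectors of ids (default: keep all).
#' @return A `measurement_matrix` restricted to the requested rows/columns.
#' @export
subset_matrix <- function(m, variables = NULL, samples = NULL) {
  stopifnot(inherits(m, "measurement_matrix"))
  vi <- if (is.null(variables)) seq_len(nrow(m$values)) else {
    miss <- setdiff(variables, m$variable_meta$id)
    if (length(miss)) stop("unknown variables: ", paste(miss, collapse = ", "))
    match(variables, m$variable_meta$id)
  }
  si <- if (is.null(samples)) seq_len(ncol(m$values)) else {
    miss <- setdiff(samples, m$sample_meta$id)
    if (length(miss)) stop("unknown samples: ", paste(miss, collapse = ", "))
    match(samples, m$sample_meta$id)
  }
  out <- measurement_matrix(m$values[vi, si, drop = FALSE],
                            m$variable_meta[vi, , drop = FALSE],
                            m$sample_meta[si, , drop = FALSE],
                            m$log2_expression)
  attr(out, "standardized") <- attr(m, "standardized")
  out
}

#' Read a measurement matrix from TSV files
#'
#' The matrix file is tab-separated with a header row of sample ids and the
#' variable id in the first column; the metadata files are tab-separated with
#' headers `id`/`modality` and `id`/`subject`/`group`/`timepoint`.
#' Non-numeric cells are reported with their row and column position.
#'
#' @param matrix_file,variable_file,sample_file Paths to the three TSVs.
#' @param log2_expression See [measurement_matrix()].
#' @return A `measurement_matrix`.
#' @export
read_matrix_tsv <- function(matrix_file, variable_file, sample_file,
                            log2_expression = TRUE) {
  raw <- utils::read.delim(matrix_file, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character")
  ids <- raw[[1]]
  num <- suppressWarnings(
    vapply(raw[-1], function(col) as.numeric(col), numeric(nrow(raw))))
  if (nrow(raw) == 1) num <- matrix(num, nrow = 1)
  was_na <- vapply(raw[-1], function(col) col %in% c("NA", ""),
                   logical(nrow(raw)))
  if (nrow(raw) == 1) was_na <- matrix(was_na, nrow = 1)
  bad <- which(is.na(num) & !was_na, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric cell in %s at row %d (variable '%s'), column '%s'",
                 matrix_file, bad[1, 1], ids[bad[1, 1]],
                 names(raw[-1])[bad[1, 2]]))
  }
  rownames(num) <- ids
  vmeta <- utils::read.delim(variable_file, sep = "\t",
                             stringsAsFactors = FALSE)
  smeta <- utils::read.delim(sample_file, sep = "\t",
                             stringsAsFactors = FALSE,
                             colClasses = "character")
  if (!identical(ids, vmeta$id))
    vmeta <- vmeta[match(ids, vmeta$id), , drop = FALSE]
  if (!identical(colnames(num), smeta$id))
    smeta <- smeta[match(colnames(num), smeta$id), , drop = FALSE]
  measurement_matrix(num, vmeta, smeta, log2_expression)
}

#' Write a measurement matrix to TSV files
#'
#' Inverse of [read_matrix_tsv()]; plain UTF-8, tab separators, "." decimal.
#'
#' @param m A `measurement_matrix`.
#' @param matrix_file,variable_file,sample_file Output paths.
#' @return Invisibly, the paths written.
#' @export
write_matrix_tsv <- function(m, matrix_file, variable_file, sample_file) {
  stopifnot(inherits(m, "measurement_matrix"))
  df <- data.frame(variable_id = rownames(m$values), m$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, matrix_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(m$variable_meta, variable_file, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(m$sample_meta, sample_file, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(matrix_file, variable_file, sample_file))
}

#' Read a hub list (hub_id, category) from TSV
#'
#' Categories follow the hub taxonomy: `physiology`, `serum_cytokine`,
#' `receptor_gene`, `glycolysis_gene`.
#'
#' @param path Path to a two-column tab-separated file with header.
#' @return Data frame with columns `hub_id`, `category`.
#' @export
read_hubs_tsv <- function(path) {
  h <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("hub_id", "category") %in% names(h)))
    stop("hub file needs columns 'hub_id' and 'category'")
  bad <- setdiff(unique(h$category), hub_categories())
  if (length(bad)) stop("unknown hub category: ", paste(bad, collapse = ", "))
  h
}

#' Hub category taxonomy
#'
#' The four hub classes used throughout: physiological measures, serum
#' cytokines, muscle-expressed cytokine/growth-factor receptor genes, and
#' glycolysis/gluconeogenesis enzyme genes.  The first and last anchor the
#' bioenergetics side of the network, the middle two the tissue-remodelling
#' side.
#'
#' @return Character vector of the four category names.
#' @export
hub_categories <- function() {
  c("physiology", "serum_cytokine", "receptor_gene", "glycolysis_gene")
}

#' Category sets for the two biological sub-networks
#'
#' @param side `"remodelling"` (serum cytokines + receptor genes) or
#'   `"bioenergetics"` (physiology + glycolysis genes).
#' @return Character vector of hub categories.
#' @export
subnetwork_categories <- function(side = c("remodelling", "bioenergetics")) {
  side <- match.arg(side)
  if (side == "remodelling") c("serum_cytokine", "receptor_gene")
  else c("physiology", "glycolysis_gene")
}
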