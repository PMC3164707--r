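#' Standardize each variable to mean 0, standard deviation 1
#'
#' Puts measurements in different units (physiology, serum protein, gene
#' expression) on a directly comparable scale by z-scoring every variable
#' across all samples (sample standard deviation, n - 1 denominator).
#' Constant variables and variables with more than `max_missing` missing
#' entries cannot be standardized and are dropped with a warning, never
#' silently zero-filled.  Idempotent: standardizing twice equals
#' standardizing once.
#'
#' @param m A [measurement_matrix()].
#' @param by_group If `TRUE`, standardize within each group separately
#'   (off by default; the joint scaling across all samples is the intended
#'   behaviour for network inference).
#' @param max_missing Maximum tolerated fraction of missing values per
#'   variable.
#' @return A `measurement_matrix` with attribute `standardized = TRUE` and
#'   attribute `dropped` listing excluded variable ids.
#' @export
standardize <- function(m, by_group = FALSE, max_missing = 0.2) {
  stopifnot(inherits(m, "measurement_matrix"))
  v <- m$values
  frac_na <- rowMeans(is.na(v))
  too_missing <- frac_na > max_missing
  sds <- apply(v, 1, stats::sd, na.rm = TRUE)
  constant <- !too_missing & (is.na(sds) | sds == 0)
  drop <- too_missing | constant
  if (any(drop)) {
    msg <- character(0)
    if (any(constant))
      msg <- c(msg, paste0("constant variables dropped: ",
                           paste(rownames(v)[constant], collapse = ", ")))
    if (any(too_missing))
      msg <- c(msg, paste0(">", round(100 * max_missing),
                           "% missing, dropped: ",
                           paste(rownames(v)[too_missing], collapse = ", ")))
    warning(paste(msg, collapse = "; "))
    v <- v[!drop, , drop = FALSE]
    m$variable_meta <- m$variable_meta[!drop, , drop = FALSE]
  }
  scale_rows <- function(x) {
    mu <- rowMeans(x, na.rm = TRUE)
    x <- x - mu
    s <- apply(x, 1, stats::sd, na.rm = TRUE)
    x / s
  }
  if (by_group) {
    for (g in unique(m$sample_meta$group)) {
      idx <- m$sample_meta$group == g
      v[, idx] <- scale_rows(v[, idx, drop = FALSE])
    }
  } else {
    v <- scale_rows(v)
  }
  m$values <- v
  attr(m, "standardized") <- TRUE
  attr(m, "dropped") <- rownames(m$values)[integer(0)]
  if (any(drop)) attr(m, "dropped") <- names(which(drop))
  m
}

#' Read a two-column identifier map from TSV
#'
#' Generic cross-species / cross-platform identifier table (e.g. a
#' homology map), columns `source_id` and `target_id`.
#'
#' @param path Path to the TSV.
#' @return Data frame with the two columns, duplicated pairs removed.
#' @export
read_idmap_tsv <- function(path) {
  im <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("source_id", "target_id") %in% names(im)))
    stop("id map needs columns 'source_id' and 'target_id'")
  im[!duplicated(im[c("source_id", "target_id")]), , drop = FALSE]
}

#' Map differential-expression results onto another identifier universe
#'
#' Joins a DE table through an identifier map (for instance mouse-to-human
#' homologues) and restricts to a target universe.  One-to-many mappings
#' expand to all targets carrying the source's statistics; many-to-one
#' mappings keep the entry with the smallest p-value.  The mapped fraction
#' (sources with at least one target in the universe / all sources in the
#' table) is attached as attribute `mapped_fraction`.
#'
#' @param de A `diff_expr` data frame (see [train_response()]).
#' @param idmap Data frame with columns `source_id`, `target_id`.
#' @param target_universe Character vector of admissible target ids.
#' @return A `diff_expr` data frame keyed by target id.
#' @export
map_ids <- function(de, idmap, target_universe) {
  if (is.null(idmap) || nrow(idmap) == 0) stop("id map is empty")
  idmap <- idmap[!duplicated(idmap[c("source_id", "target_id")]), , drop = FALSE]
  hit <- merge(de, idmap, by.x = "id", by.y = "source_id")
  hit <- hit[hit$target_id %in% target_universe, , drop = FALSE]
  n_src <- length(unique(de$id))
  mapped_frac <- if (n_src == 0) 0 else length(unique(hit$id)) / n_src
  if (nrow(hit) == 0) {
    warning("no identifiers mapped into the target universe")
    out <- de[integer(0), , drop = FALSE]
  } else {
    # many-to-one: keep the smallest-p source per target
    hit <- hit[order(hit$target_id, hit$p_value), , drop = FALSE]
    hit <- hit[!duplicated(hit$target_id), , drop = FALSE]
    out <- hit
    out$source_id <- out$id
    out$id <- out$target_id
    out$target_id <- NULL
    rownames(out) <- NULL
  }
  attr(out, "mapped_fraction") <- mapped_frac
  class(out) <- unique(c("diff_expr", class(out)))
  out
}
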