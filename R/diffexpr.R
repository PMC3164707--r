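#' Benjamini-Hochberg step-up q-values
#'
#' Step-up adjusted p-values controlling the false discovery rate:
#' q_(i) = min over j >= i of p_(j) * m / j, capped at 1, mapped back to the
#' input order.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return q-values in the input order.
#' @export
bh_fdr <- function(p_values) {
  if (anyNA(p_values)) stop("p-values must not be missing")
  if (any(p_values < 0 | p_values > 1)) stop("p-values must be in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

# paired / unpaired t statistics, vectorized over matrix rows.
# zero-variance rows get p = 1 and a flag rather than NaN.
.row_t_paired <- function(d) {
  ns <- ncol(d)
  mu <- rowMeans(d)
  sd_d <- apply(d, 1, stats::sd)
  flagged <- sd_d == 0
  tstat <- ifelse(flagged, 0, mu / (sd_d / sqrt(ns)))
  p <- ifelse(flagged, 1, 2 * stats::pt(-abs(tstat), df = ns - 1))
  list(statistic = tstat, p_value = p, flagged = flagged)
}

.row_t_welch <- function(a, b) {
  na <- ncol(a); nb <- ncol(b)
  va <- apply(a, 1, stats::var); vb <- apply(b, 1, stats::var)
  flagged <- (va + vb) == 0
  se2 <- va / na + vb / nb
  tstat <- ifelse(flagged, 0, (rowMeans(b) - rowMeans(a)) / sqrt(se2))
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- ifelse(flagged, 1, 2 * stats::pt(-abs(tstat), df = df))
  list(statistic = tstat, p_value = p, flagged = flagged)
}

#' Training response of one group: pre vs post differential expression
#'
#' Tests every gene-expression variable for a pre/post training difference
#' within one group; physiology and serum variables are excluded.  The
#' default is a paired t-test by subject (the cohorts sample the same
#' subjects at both timepoints); an unpaired Welch test is available by
#' flag.  Fold changes are group-mean ratios on the linear scale: for
#' log2-scale expression matrices the mean difference is anti-logged, and
#' ratios below 1 are sign-folded to negative reciprocals (0.5 prints as
#' -2).  Directions are called only below the FDR threshold.
#'
#' @param m A [measurement_matrix()].
#' @param group Group label to test (needs >= 3 subjects with both
#'   timepoints when paired, >= 3 samples per timepoint otherwise).
#' @param paired Paired by subject (default) or unpaired.
#' @param fdr FDR threshold used for the `direction` call (default 0.10).
#' @return A data frame of class `diff_expr` with columns `id`,
#'   `statistic`, `fold_change`, `p_value`, `q_value`, `direction`
#'   (`up`/`down`/`ns`), `flagged`.
#' @export
train_response <- function(m, group, paired = TRUE, fdr = 0.10) {
  stopifnot(inherits(m, "measurement_matrix"))
  sm <- m$sample_meta
  if (!group %in% sm$group) stop("unknown group: ", group)
  genes <- m$variable_meta$id[m$variable_meta$modality == "gene_expression"]
  if (!length(genes)) stop("no gene-expression variables in the matrix")
  gsm <- sm[sm$group == group, , drop = FALSE]
  pre_ids <- gsm$id[gsm$timepoint == "pre"]
  post_ids <- gsm$id[gsm$timepoint == "post"]
  pre <- m$values[genes, pre_ids, drop = FALSE]
  post <- m$values[genes, post_ids, drop = FALSE]

  if (paired) {
    subj_pre <- gsm$subject[match(pre_ids, gsm$id)]
    subj_post <- gsm$subject[match(post_ids, gsm$id)]
    both <- intersect(subj_pre, subj_post)
    if (length(both) < 3)
      stop("group '", group, "' has only ", length(both),
           " subjects with both timepoints (need >= 3 for a paired test)")
    d <- post[, match(both, subj_post), drop = FALSE] -
      pre[, match(both, subj_pre), drop = FALSE]
    tt <- .row_t_paired(d)
  } else {
    if (ncol(pre) < 3 || ncol(post) < 3)
      stop("group '", group, "' needs >= 3 samples per timepoint, has ",
           ncol(pre), " pre and ", ncol(post), " post")
    tt <- .row_t_welch(pre, post)
  }

  delta <- rowMeans(post) - rowMeans(pre)
  ratio <- if (m$log2_expression) 2^delta else {
    rp <- rowMeans(post) / rowMeans(pre)
    ifelse(is.finite(rp) & rp > 0, rp, NA_real_)
  }
  fold <- ifelse(!is.na(ratio) & ratio < 1, -1 / ratio, ratio)

  q <- bh_fdr(tt$p_value)
  direction <- ifelse(q < fdr & !tt$flagged,
                      ifelse(tt$statistic > 0, "up", "down"), "ns")
  out <- data.frame(id = genes, statistic = unname(tt$statistic),
                    fold_change = unname(fold),
                    p_value = unname(tt$p_value), q_value = unname(q),
                    direction = direction, flagged = unname(tt$flagged),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "group") <- group
  attr(out, "paired") <- paired
  attr(out, "fdr") <- fdr
  class(out) <- c("diff_expr", class(out))
  out
}

#' Two-factor fixed-effects ANOVA across all variables
#'
#' Fits the additive two-way model (disease group + training timepoint by
#' default, no interaction) to every variable and reports type-II main
#' effect p-values with per-factor Benjamini-Hochberg q-values across
#' variables.  Implemented as QR projections of the shared design, so the
#' fit is vectorized over thousands of variables.  Constant variables are
#' flagged and excluded.  A factor that happens to have a single level is
#' dropped from the design (its p-values are `NA`), which reduces the model
#' to a one-way ANOVA.
#'
#' @param m A [measurement_matrix()].
#' @param factors Length-2 character vector naming the `sample_meta` columns
#'   for the disease and training factors.
#' @param interaction Include the interaction term (off by default; when on,
#'   main effects are still type II, i.e. adjusted for each other but not
#'   for the interaction).
#' @return Data frame of class `anova_result` with columns `id`,
#'   `p_disease`, `p_training`, `q_disease`, `q_training`.
#' @export
two_factor_anova <- function(m, factors = c("group", "timepoint"),
                             interaction = FALSE) {
  stopifnot(inherits(m, "measurement_matrix"), length(factors) == 2)
  sm <- m$sample_meta
  if (!all(factors %in% names(sm)))
    stop("factors must name sample_meta columns")
  fA <- factor(sm[[factors[1]]])
  fB <- factor(sm[[factors[2]]])
  if (nlevels(fA) >= 2 && nlevels(fB) >= 2) {
    cells <- table(fA, fB)
    if (any(cells < 2)) {
      bad <- which(cells < 2, arr.ind = TRUE)
      stop("cells with fewer than 2 observations: ",
           paste(sprintf("(%s, %s)", rownames(cells)[bad[, 1]],
                         colnames(cells)[bad[, 2]]), collapse = ", "))
    }
  }

  Y <- t(m$values)                       # samples x variables
  keep <- apply(Y, 2, function(col) stats::sd(col) > 0)
  if (any(!keep))
    warning("constant variables excluded: ",
            paste(colnames(Y)[!keep], collapse = ", "))
  Yk <- Y[, keep, drop = FALSE]
  n <- nrow(Yk)

  rss <- function(X) {
    q <- qr(X)
    colSums(qr.resid(q, Yk)^2)
  }
  has_A <- nlevels(fA) >= 2
  has_B <- nlevels(fB) >= 2
  terms_full <- c(if (has_A) "fA", if (has_B) "fB",
                  if (interaction && has_A && has_B) "fA:fB")
  mk <- function(terms) {
    f <- stats::as.formula(paste("~", if (length(terms))
      paste(terms, collapse = "+") else "1"))
    stats::model.matrix(f, data = data.frame(fA = fA, fB = fB))
  }
  X_main <- mk(setdiff(terms_full, "fA:fB"))
  rss_main <- rss(X_main)
  df_res <- n - qr(mk(terms_full))$rank
  rss_full <- rss(mk(terms_full))

  pf_term <- function(drop_term) {
    X_red <- mk(setdiff(setdiff(terms_full, "fA:fB"), drop_term))
    rss_red <- rss(X_red)
    df_num <- qr(X_main)$rank - qr(X_red)$rank
    fstat <- ((rss_red - rss_main) / df_num) / (rss_full / df_res)
    stats::pf(fstat, df_num, df_res, lower.tail = FALSE)
  }
  pA <- if (has_A) pf_term("fA") else rep(NA_real_, ncol(Yk))
  pB <- if (has_B) pf_term("fB") else rep(NA_real_, ncol(Yk))

  out <- data.frame(id = colnames(Y), p_disease = NA_real_,
                    p_training = NA_real_, q_disease = NA_real_,
                    q_training = NA_real_, stringsAsFactors = FALSE)
  out$p_disease[keep] <- unname(pA)
  out$p_training[keep] <- unname(pB)
  if (has_A) out$q_disease[keep] <- bh_fdr(pA)
  if (has_B) out$q_training[keep] <- bh_fdr(pB)
  out$flagged <- !keep
  rownames(out) <- NULL
  class(out) <- c("anova_result", class(out))
  out
}

#' Filter a DE table to a target list with FDR and fold-change thresholds
#'
#' Mirrors curated-target analyses (e.g. restricting to experimentally
#' validated NF-kB targets and keeping genes at q below 10% with fold above
#' 1.5): retains entries of `target_list` with `q_value < fdr` and
#' `|fold_change| > min_fold`, and reports the direction split.
#'
#' @param de A `diff_expr` data frame.
#' @param target_list Character vector of gene ids.
#' @param fdr FDR cutoff.
#' @param min_fold Minimum absolute (sign-folded) fold change.
#' @return The filtered `diff_expr` rows, with attributes `n_up`, `n_down`.
#' @export
filter_targets <- function(de, target_list, fdr = 0.10, min_fold = 1.5) {
  keep <- de$id %in% target_list & de$q_value < fdr &
    !is.na(de$fold_change) & abs(de$fold_change) > min_fold
  out <- de[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_up") <- sum(out$statistic > 0)
  attr(out, "n_down") <- sum(out$statistic < 0)
  class(out) <- unique(c("diff_expr", class(out)))
  out
}

#' Gene-set enrichment by the exact hypergeometric (one-sided Fisher) test
#'
#' For each set, the probability of observing at least the attained overlap
#' between the query list and the set, drawing `|list|` genes from the
#' universe without replacement; Benjamini-Hochberg correction across sets.
#' Sets are intersected with the universe before testing; list members
#' outside the universe are dropped with a warning.
#'
#' @param list_ids Character vector: the query gene list.
#' @param sets Named list of character vectors (e.g. from [read_gmt()]).
#' @param universe Character vector: the background universe.
#' @param fdr Significance threshold on q.
#' @return Data frame of class `enrichment_result` with columns `set`,
#'   `overlap`, `set_size`, `list_size`, `universe_size`, `p_value`,
#'   `q_value`, `significant`.
#' @export
enrich <- function(list_ids, sets, universe, fdr = 0.01) {
  if (!length(universe)) stop("universe must not be empty")
  universe <- unique(universe)
  outside <- setdiff(list_ids, universe)
  if (length(outside)) {
    warning(length(outside), " list ids outside the universe were dropped")
    list_ids <- intersect(list_ids, universe)
  }
  list_ids <- unique(list_ids)
  N <- length(universe)
  nl <- length(list_ids)
  res <- lapply(names(sets), function(nm) {
    s <- intersect(unique(sets[[nm]]), universe)
    k <- length(intersect(s, list_ids))
    p <- if (nl == 0 || length(s) == 0) 1 else
      stats::phyper(k - 1, length(s), N - length(s), nl, lower.tail = FALSE)
    data.frame(set = nm, overlap = k, set_size = length(s),
               list_size = nl, universe_size = N, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q_value <- bh_fdr(out$p_value)
  out$significant <- out$q_value < fdr
  out <- out[order(out$p_value), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", class(out))
  out
}

#' Read gene sets from a GMT file
#'
#' Tab-separated: set name, description, then member ids.
#'
#' @param path Path to the GMT file.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t"), function(f) f[-(1:2)])
  names(sets) <- vapply(strsplit(lines, "\t"), `[[`, character(1), 1)
  sets
}

#' Write a DE table as TSV
#'
#' @param de A `diff_expr` data frame.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_de_tsv <- function(de, path) {
  utils::write.table(de, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a DE table from TSV
#'
#' @param path Path to a TSV written by [write_de_tsv()].
#' @return A `diff_expr` data frame.
#' @export
read_de_tsv <- function(path) {
  de <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  class(de) <- c("diff_expr", class(de))
  de
}
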