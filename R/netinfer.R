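#' Calibrate the null distribution of mutual information by permutation
#'
#' Draws random variable pairs from the matrix, independently permutes one
#' member and records the MI, yielding a null sample of the estimator under
#' independence at the matrix's sample size.  An exponential tail is fitted
#' to the upper 5% of the null (maximum-likelihood rate on the excesses over
#' the 95% quantile), so that thresholds for p-values far below
#' 1/n_permutations -- such as the genome-scale edge threshold p < 1e-7 --
#' are obtained by extrapolation.  Significant connections selected at a
#' given p keep the pairwise false-positive rate below that level.
#'
#' @param m A [measurement_matrix()] (standardization is irrelevant for the
#'   rank-based default estimator but harmless).
#' @param n_permutations Number of null MI draws (>= 100; default 1e5).
#' @param seed Integer seed; the calibration is reproducible given the seed.
#' @param estimator MI estimator, see [mutual_information()].
#' @return An object of class `mi_null_calibration`: `n_permutations`,
#'   sorted `null_mi`, `tail_loc` (95% quantile), `tail_rate` (exponential
#'   rate), `n_samples`, `estimator`, `seed`.
#' @export
calibrate_null <- function(m, n_permutations = 1e5, seed = 1L,
                           estimator = "gaussian_kernel") {
  stopifnot(inherits(m, "measurement_matrix"))
  if (n_permutations < 100) stop("n_permutations must be >= 100")
  v <- m$values
  if (nrow(v) < 2) stop("need at least two variables to form null pairs")
  set.seed(seed)
  n <- ncol(v)
  gauss <- estimator == "gaussian_kernel"
  scores <- if (gauss) t(apply(v, 1, .normal_scores)) else v
  null_mi <- numeric(n_permutations)
  for (b in seq_len(n_permutations)) {
    ij <- sample.int(nrow(v), 2)
    x <- scores[ij[1], ]
    y <- scores[ij[2], ][sample.int(n)]
    null_mi[b] <- if (gauss) .mi_gauss(x, y) else
      mutual_information(x, y, estimator)
  }
  null_mi <- sort(null_mi)
  loc <- stats::quantile(null_mi, 0.95, names = FALSE, type = 7)
  exceed <- null_mi[null_mi > loc]
  rate <- if (length(exceed) && mean(exceed - loc) > 0)
    1 / mean(exceed - loc) else Inf
  structure(list(n_permutations = as.integer(n_permutations),
                 null_mi = null_mi, tail_loc = loc, tail_rate = rate,
                 n_samples = n, estimator = estimator,
                 seed = as.integer(seed)),
            class = "mi_null_calibration")
}

#' @export
print.mi_null_calibration <- function(x, ...) {
  cat("mi_null_calibration:", x$n_permutations, "permutations at n =",
      x$n_samples, "samples (", x$estimator, ")\n")
  cat(sprintf("  95%% null MI = %.4g, tail rate = %.4g\n",
              x$tail_loc, x$tail_rate))
  cat(sprintf("  thresholds: p=0.05 -> %.4g, p=1e-3 -> %.4g, p=1e-7 -> %.4g\n",
              mi_threshold_at(x, 0.05), mi_threshold_at(x, 1e-3),
              mi_threshold_at(x, 1e-7)))
  invisible(x)
}

#' MI cutoff corresponding to a null tail probability
#'
#' Monotonically decreasing in `p`; for p >= 0.05 the empirical null
#' quantile, below that the fitted exponential tail.  At p = 1 the threshold
#' is the minimum observed null MI.
#'
#' @param calibration An `mi_null_calibration`.
#' @param p Tail probability (vectorized), in (0, 1].
#' @return MI threshold(s).
#' @export
mi_threshold_at <- function(calibration, p) {
  stopifnot(inherits(calibration, "mi_null_calibration"))
  if (any(p <= 0 | p > 1)) stop("p must be in (0, 1]")
  vapply(p, function(pp) {
    if (pp >= 0.05)
      stats::quantile(calibration$null_mi, 1 - pp, names = FALSE, type = 7)
    else
      calibration$tail_loc + log(0.05 / pp) / calibration$tail_rate
  }, numeric(1))
}

#' Null tail probability of an observed MI value
#'
#' Inverse of [mi_threshold_at()]: empirical tail fraction below the fitted
#' region, exponential tail above it.
#'
#' @param calibration An `mi_null_calibration`.
#' @param mi Observed MI value(s).
#' @return p-value(s) in (0, 1].
#' @export
mi_p_value <- function(calibration, mi) {
  stopifnot(inherits(calibration, "mi_null_calibration"))
  nm <- calibration$null_mi
  n <- length(nm)
  vapply(mi, function(v) {
    if (v <= calibration$tail_loc) {
      # (1 + #null >= v) / (1 + N): never exactly zero
      (1 + sum(nm >= v)) / (1 + n)
    } else {
      min(1, 0.05 * exp(-calibration$tail_rate * (v - calibration$tail_loc)))
    }
  }, numeric(1))
}

#' Store / load a calibration as JSON
#'
#' @param calibration An `mi_null_calibration`.
#' @param path JSON file path.
#' @return `write_calibration` invisibly returns the path;
#'   `read_calibration` returns the calibration object.
#' @export
write_calibration <- function(calibration, path) {
  jsonlite::write_json(unclass(calibration), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$null_mi <- as.numeric(x$null_mi)
  structure(x, class = "mi_null_calibration")
}

#' Infer the network module (neighbourhood) of one hub
#'
#' Computes the MI of the hub with every other variable and keeps the
#' targets exceeding the calibrated threshold at `p_threshold`.  Each edge
#' carries a sign from the Pearson correlation of the pair; if that is
#' exactly zero the Spearman correlation decides, and if both vanish the
#' sign defaults to +1 with a flag.
#'
#' @param m A [measurement_matrix()].
#' @param hub_id Variable id of the hub (must be present).
#' @param calibration An `mi_null_calibration` built on a matrix with the
#'   same number of samples.
#' @param p_threshold Edge significance threshold (default the genome-scale
#'   1e-7; scaled-down cohorts typically use 1e-3).
#' @param hub_category Optional hub category annotation carried into the
#'   module (see [hub_categories()]).
#' @return An object of class `network_module`: `hub_id`, `hub_category`,
#'   and `edges` (data frame `target_id`, `mi`, `p_value`, `sign`,
#'   `sign_flagged`).
#' @export
infer_module <- function(m, hub_id, calibration, p_threshold = 1e-7,
                         hub_category = NA_character_) {
  stopifnot(inherits(m, "measurement_matrix"),
            inherits(calibration, "mi_null_calibration"))
  if (!hub_id %in% rownames(m$values)) stop("unknown hub: ", hub_id)
  if (calibration$n_samples != ncol(m$values))
    stop("calibration was built for ", calibration$n_samples,
         " samples but the matrix has ", ncol(m$values))
  thr <- mi_threshold_at(calibration, p_threshold)
  v <- m$values
  others <- setdiff(rownames(v), hub_id)
  gauss <- calibration$estimator == "gaussian_kernel"
  hx <- if (gauss) .normal_scores(v[hub_id, ]) else v[hub_id, ]
  mis <- vapply(others, function(o) {
    if (gauss) .mi_gauss(hx, .normal_scores(v[o, ]))
    else mutual_information(v[hub_id, ], v[o, ], calibration$estimator)
  }, numeric(1))
  keep <- which(mis > thr)
  targets <- others[keep]
  sign_flagged <- logical(length(targets))
  signs <- integer(length(targets))
  for (i in seq_along(targets)) {
    r <- stats::cor(v[hub_id, ], v[targets[i], ],
                    use = "pairwise.complete.obs")
    if (is.na(r) || r == 0)
      r <- stats::cor(v[hub_id, ], v[targets[i], ], method = "spearman",
                      use = "pairwise.complete.obs")
    if (is.na(r) || r == 0) {
      signs[i] <- 1L
      sign_flagged[i] <- TRUE
    } else signs[i] <- as.integer(sign(r))
  }
  edges <- data.frame(target_id = targets, mi = unname(mis[keep]),
                      p_value = mi_p_value(calibration, unname(mis[keep])),
                      sign = signs, sign_flagged = sign_flagged,
                      stringsAsFactors = FALSE)
  edges <- edges[order(-edges$mi), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(hub_id = hub_id, hub_category = hub_category,
                 edges = edges, p_threshold = p_threshold,
                 mi_threshold = thr, candidates = others),
            class = "network_module")
}

#' @export
print.network_module <- function(x, ...) {
  cat("network_module: hub", x$hub_id,
      if (!is.na(x$hub_category)) paste0("(", x$hub_category, ")"),
      "with", nrow(x$edges), "edges at p <", format(x$p_threshold), "\n")
  invisible(x)
}

#' Merge hub modules into one interaction network
#'
#' Builds the union of the module edge sets as an undirected signed weighted
#' graph.  Duplicate edges (the same unordered pair contributed by several
#' modules) are collapsed to a single edge keeping the maximum-MI record;
#' the provenance attribute lists every contributing hub.  Every hub appears
#' as a node even with zero significant edges.  Node categories are the hub
#' categories, or `"target"` for plain targets.
#'
#' @param modules List of `network_module` objects built on the same matrix.
#' @return An [igraph::igraph] with vertex attributes `name`, `category` and
#'   edge attributes `mi`, `p_value`, `sign`, `provenance`.
#' @export
merge_modules <- function(modules) {
  if (length(modules) == 0)
    return(igraph::make_empty_graph(n = 0, directed = FALSE))
  stopifnot(all(vapply(modules, inherits, logical(1), "network_module")))
  hub_ids <- vapply(modules, `[[`, character(1), "hub_id")
  if (anyDuplicated(hub_ids))
    stop("duplicate hub_id across modules: ",
         paste(unique(hub_ids[duplicated(hub_ids)]), collapse = ", "))
  hub_cat <- vapply(modules, function(mo)
    if (is.na(mo$hub_category)) "hub" else mo$hub_category, character(1))
  names(hub_cat) <- hub_ids

  el <- do.call(rbind, lapply(modules, function(mo) {
    if (nrow(mo$edges) == 0) return(NULL)
    data.frame(hub = mo$hub_id, target = mo$edges$target_id,
               mi = mo$edges$mi, p_value = mo$edges$p_value,
               sign = mo$edges$sign, stringsAsFactors = FALSE)
  }))
  if (!is.null(el) && nrow(el)) {
    a <- pmin(el$hub, el$target)
    b <- pmax(el$hub, el$target)
    key <- paste(a, b, sep = "\r")
    prov <- vapply(split(el$hub, key), function(h)
      paste(sort(unique(h)), collapse = ","), character(1))
    el <- el[order(key, -el$mi), , drop = FALSE]
    key_sorted <- sort(key)
    el <- el[!duplicated(key_sorted), , drop = FALSE]
    el$provenance <- unname(prov[unique(key_sorted)])
  }
  nodes <- unique(c(hub_ids, if (!is.null(el)) c(el$hub, el$target)))
  cats <- ifelse(nodes %in% hub_ids, hub_cat[nodes], "target")
  g <- igraph::make_empty_graph(n = length(nodes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = nodes)
  g <- igraph::set_vertex_attr(g, "category", value = unname(cats))
  if (!is.null(el) && nrow(el)) {
    g <- igraph::add_edges(g, rbind(match(el$hub, nodes),
                                    match(el$target, nodes)))
    g <- igraph::set_edge_attr(g, "mi", value = el$mi)
    g <- igraph::set_edge_attr(g, "p_value", value = el$p_value)
    g <- igraph::set_edge_attr(g, "sign", value = el$sign)
    g <- igraph::set_edge_attr(g, "provenance", value = el$provenance)
  }
  # candidate target universe across modules: the pool the permutation
  # null of coupling_score redraws from
  cand <- unique(unlist(lapply(modules, `[[`, "candidates")))
  g <- igraph::set_graph_attr(g, "target_universe",
                              setdiff(cand, hub_ids))
  g
}

#' Prune indirect edges with the data-processing inequality
#'
#' In a Markov chain X -> Y -> Z the information between the end points
#' cannot exceed that of either direct link, so in every triangle the edge
#' with the smallest MI is the candidate indirect interaction.  For each
#' triangle the weakest edge is removed when its MI is below
#' `(1 - tolerance)` times the smaller of the other two; `tolerance = 0` is
#' the strict rule.  All triangles are scanned against the original edge
#' weights before any removal.  Ties on the minimum are broken
#' deterministically by removing the lexicographically last edge by
#' (min id, max id).
#'
#' Off by default in the pipeline: hub-anchored modules are star-shaped and
#' rarely form triangles, so keeping every significant edge is the natural
#' default for this design.
#'
#' @param network An interaction network from [merge_modules()] with edge
#'   attribute `mi`.
#' @param tolerance Fraction >= 0.
#' @return The pruned network (edge set is a subset of the input's).
#' @export
apply_dpi <- function(network, tolerance = 0) {
  if (tolerance < 0) stop("tolerance must be >= 0")
  if (igraph::ecount(network) == 0) return(network)
  if (is.null(igraph::edge_attr(network, "mi")))
    stop("network edges must carry an 'mi' attribute")
  tri <- matrix(as.integer(igraph::triangles(network)), nrow = 3)
  if (ncol(tri) == 0) return(network)
  mi <- igraph::edge_attr(network, "mi")
  nms <- igraph::V(network)$name
  edge_key <- function(i, j) paste(pmin(nms[i], nms[j]), pmax(nms[i], nms[j]),
                                   sep = "\r")
  drop <- logical(igraph::ecount(network))
  for (t in seq_len(ncol(tri))) {
    vt <- tri[, t]
    eid <- igraph::get_edge_ids(network, c(vt[1], vt[2], vt[2], vt[3],
                                           vt[1], vt[3]))
    w <- mi[eid]
    lo <- which(w == min(w))
    if (length(lo) > 1) {
      keys <- edge_key(c(vt[1], vt[2], vt[1])[lo], c(vt[2], vt[3], vt[3])[lo])
      lo <- lo[order(keys)][length(lo)]
    }
    if (w[lo] < (1 - tolerance) * min(w[-lo]))
      drop[eid[lo]] <- TRUE
  }
  igraph::delete_edges(network, which(drop))
}

#' Export a network as SIF (Cytoscape quick-load)
#'
#' One line per edge: `node TAB mi TAB node`.  Isolated nodes are listed on
#' their own line.
#'
#' @param network An igraph interaction network.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_sif <- function(network, path) {
  el <- igraph::as_edgelist(network)
  lines <- if (nrow(el)) paste(el[, 1], "mi", el[, 2], sep = "\t") else
    character(0)
  iso <- igraph::V(network)$name[igraph::degree(network) == 0]
  writeLines(c(lines, iso), path)
  invisible(path)
}

#' Export a network as GraphML with node and edge attributes
#'
#' Cytoscape-loadable; keeps `category` on nodes and `mi`, `p_value`,
#' `sign`, `provenance` on edges.
#'
#' @param network An igraph interaction network.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_graphml <- function(network, path) {
  igraph::write_graph(network, path, format = "graphml")
  invisible(path)
}
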