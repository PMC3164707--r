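# helpers over interaction networks -------------------------------------

.hub_vertices <- function(network, cats) {
  igraph::V(network)$name[igraph::V(network)$category %in% cats]
}

.non_hub_nodes <- function(network) {
  igraph::V(network)$name[igraph::V(network)$category == "target"]
}

# union of non-hub neighbours of a set of hubs
.target_set <- function(network, hubs) {
  if (!length(hubs)) return(character(0))
  nb <- unique(unlist(lapply(hubs, function(h)
    igraph::neighbors(network, h)$name)))
  setdiff(nb, .hub_vertices(network, setdiff(unique(
    igraph::V(network)$category), "target")))
}

#' Coupling between two hub-category sub-networks
#'
#' Quantifies how much the neighbourhoods of two hub classes -- typically
#' the tissue-remodelling hubs (serum cytokines, receptor genes) versus the
#' bioenergetics hubs (physiology, glycolysis genes) -- share targets.  The
#' primary statistic is the Jaccard overlap of the two target-set unions,
#' `|T_A intersect T_B| / |T_A union T_B|`; the fraction of targets linked
#' to hubs of both categories among targets linked to either is reported
#' alongside.  Significance comes from a degree-preserving permutation
#' null: each hub redraws its targets uniformly without replacement from
#' all non-hub nodes, and the empirical p-value is
#' `(1 + #null >= observed) / (1 + n_null)`.  A near-zero score with a
#' non-significant p is the "uncoupled" signature; healthy-muscle-like
#' networks score high.
#'
#' @param network An interaction network from [merge_modules()].
#' @param cats_a,cats_b Character vectors of hub categories
#'   (see [subnetwork_categories()]).
#' @param n_null Number of null permutations.
#' @param seed Integer seed.
#' @param target_pool Candidate targets the null redraws from.  Defaults to
#'   the network's recorded `target_universe` (every variable a module
#'   scanned), falling back to the non-hub nodes.
#' @return Object of class `coupling_report`: `jaccard`,
#'   `cross_edge_fraction`, `null_mean`, `null_sd`, `p_value`,
#'   `null_quantile` (fraction of null below the observed), `n_null`,
#'   target-set sizes.
#' @export
coupling_score <- function(network,
                           cats_a = subnetwork_categories("remodelling"),
                           cats_b = subnetwork_categories("bioenergetics"),
                           n_null = 1000, seed = 1L, target_pool = NULL) {
  hubs_a <- .hub_vertices(network, cats_a)
  hubs_b <- .hub_vertices(network, cats_b)
  if (!length(hubs_a)) stop("no hubs with category in: ",
                            paste(cats_a, collapse = ", "))
  if (!length(hubs_b)) stop("no hubs with category in: ",
                            paste(cats_b, collapse = ", "))
  deg <- igraph::degree(network)
  for (side in list(c("A", cats_a), c("B", cats_b))) {
    hh <- if (side[1] == "A") hubs_a else hubs_b
    if (sum(deg[hh]) == 0)
      stop("category set ", paste(side[-1], collapse = "/"),
           " has no edges")
  }
  jac <- function(ta, tb) {
    u <- union(ta, tb)
    if (!length(u)) 0 else length(intersect(ta, tb)) / length(u)
  }
  ta <- .target_set(network, hubs_a)
  tb <- .target_set(network, hubs_b)
  observed <- jac(ta, tb)
  either <- union(ta, tb)
  cross_frac <- if (!length(either)) 0 else
    length(intersect(ta, tb)) / length(either)

  # degree-preserving null: every hub redraws its targets from the
  # candidate pool
  pool <- target_pool
  if (is.null(pool))
    pool <- igraph::graph_attr(network, "target_universe")
  if (is.null(pool)) pool <- .non_hub_nodes(network)
  # degrees sorted so the null draw (and hence p) is invariant under hub
  # relabeling within a category
  hub_deg_a <- sort(vapply(hubs_a, function(h)
    length(.target_set(network, h)), integer(1)))
  hub_deg_b <- sort(vapply(hubs_b, function(h)
    length(.target_set(network, h)), integer(1)))
  set.seed(seed)
  null_scores <- vapply(seq_len(n_null), function(b) {
    na <- unique(unlist(lapply(hub_deg_a, function(d)
      sample(pool, min(d, length(pool))))))
    nb <- unique(unlist(lapply(hub_deg_b, function(d)
      sample(pool, min(d, length(pool))))))
    jac(na, nb)
  }, numeric(1))
  structure(list(jaccard = observed, cross_edge_fraction = cross_frac,
                 n_targets_a = length(ta), n_targets_b = length(tb),
                 shared_targets = length(intersect(ta, tb)),
                 null_mean = mean(null_scores), null_sd = stats::sd(null_scores),
                 p_value = (1 + sum(null_scores >= observed)) / (1 + n_null),
                 null_quantile = mean(null_scores < observed),
                 n_null = as.integer(n_null), seed = as.integer(seed)),
            class = "coupling_report")
}

#' @export
print.coupling_report <- function(x, ...) {
  cat(sprintf(
    "coupling_report: jaccard = %.3f (%d shared of %d/%d targets)\n",
    x$jaccard, x$shared_targets, x$n_targets_a, x$n_targets_b))
  cat(sprintf("  null mean %.3f sd %.3f, empirical p = %.4g (%d draws)\n",
              x$null_mean, x$null_sd, x$p_value, x$n_null))
  invisible(x)
}

#' Map differential-expression calls onto the network
#'
#' Annotates every network node present in the DE table with its regulation
#' direction (`up`/`down` where `q_value < fdr`, otherwise `ns`); nodes
#' absent from the table are annotated `ns`.  Per-hub counts of regulated
#' neighbours summarize where the transcriptional response concentrates.
#'
#' @param network An interaction network from [merge_modules()].
#' @param de A `diff_expr` data frame.
#' @param fdr FDR threshold for calling a node regulated.
#' @return List of class `mapped_network`: `network` (igraph with vertex
#'   attributes `de_direction`, `de_q`) and `hub_summary` (data frame
#'   `hub_id`, `n_up`, `n_down`).
#' @export
map_de <- function(network, de, fdr = 0.10) {
  nodes <- igraph::V(network)$name
  idx <- match(nodes, de$id)
  q <- de$q_value[idx]
  stat <- de$statistic[idx]
  dir <- ifelse(!is.na(q) & q < fdr, ifelse(stat > 0, "up", "down"), "ns")
  n_missing <- sum(is.na(idx))
  if (n_missing)
    message(n_missing, " network nodes absent from the DE table, marked ns")
  g <- igraph::set_vertex_attr(network, "de_direction", value = dir)
  g <- igraph::set_vertex_attr(g, "de_q",
                               value = ifelse(is.na(q), NA_real_, q))
  hubs <- nodes[igraph::V(network)$category != "target"]
  hub_summary <- do.call(rbind, lapply(hubs, function(h) {
    nb <- igraph::neighbors(g, h)$name
    data.frame(hub_id = h,
               n_up = sum(dir[match(nb, nodes)] == "up"),
               n_down = sum(dir[match(nb, nodes)] == "down"),
               n_neighbors = length(nb), stringsAsFactors = FALSE)
  }))
  structure(list(network = g, hub_summary = hub_summary),
            class = "mapped_network")
}

#' Direction-consistency of a hub neighbourhood against an external contrast
#'
#' For the direct (distance-1) neighbours of a hub, counts how many are
#' called regulated in an external DE contrast and how many of those move in
#' the direction the network predicts: a positive edge predicts `up`, a
#' negative edge predicts `down`.  This is the quantitative form of checking
#' whether genes linked to an oxygen-uptake hub respond to hypoxia the way
#' their correlation sign anticipates.
#'
#' @param network An interaction network from [merge_modules()].
#' @param hub_id Hub vertex name (must have at least one neighbour).
#' @param external_de A `diff_expr` data frame for the external contrast.
#' @param fdr FDR threshold for calling a neighbour regulated.
#' @return Object of class `consistency_report`: `hub_id`, `n_neighbors`,
#'   `n_regulated`, `n_concordant`, `fraction_regulated`,
#'   `fraction_concordant`.
#' @export
direction_consistency <- function(network, hub_id, external_de, fdr = 0.10) {
  nodes <- igraph::V(network)$name
  if (!hub_id %in% nodes) stop("unknown hub: ", hub_id)
  nb <- igraph::neighbors(network, hub_id)$name
  if (!length(nb)) stop("hub ", hub_id, " has no neighbours")
  eids <- igraph::get_edge_ids(network, as.vector(rbind(hub_id, nb)))
  signs <- igraph::edge_attr(network, "sign", eids)
  idx <- match(nb, external_de$id)
  q <- external_de$q_value[idx]
  stat <- external_de$statistic[idx]
  regulated <- !is.na(q) & q < fdr
  dir_up <- stat > 0
  concord <- regulated & ((signs == 1 & dir_up) | (signs == -1 & !dir_up))
  structure(list(hub_id = hub_id, n_neighbors = length(nb),
                 n_regulated = sum(regulated),
                 n_concordant = sum(concord, na.rm = TRUE),
                 fraction_regulated = mean(regulated),
                 fraction_concordant = if (sum(regulated) == 0) NA_real_ else
                   sum(concord, na.rm = TRUE) / sum(regulated)),
            class = "consistency_report")
}

#' @export
print.consistency_report <- function(x, ...) {
  cat(sprintf(
    "consistency_report: hub %s, %d neighbours, %d regulated (%.0f%%), %d concordant (%s)\n",
    x$hub_id, x$n_neighbors, x$n_regulated, 100 * x$fraction_regulated,
    x$n_concordant,
    if (is.na(x$fraction_concordant)) "NA" else
      sprintf("%.0f%%", 100 * x$fraction_concordant)))
  invisible(x)
}
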