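local_calibration <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      m <- make_null_matrix(40, 8, seed = 17)
      cache <<- calibrate_null(m, n_permutations = 2000, seed = 17)
    }
    cache
  }
})

test_that("calibration thresholds are monotone and anchored to the null", {
  cal <- local_calibration()
  ps <- c(1, 0.5, 0.05, 1e-2, 1e-3, 1e-5, 1e-7)
  thr <- mi_threshold_at(cal, ps)
  # decreasing p -> non-decreasing cutoff, strictly so in the fitted tail
  expect_true(all(diff(thr) >= 0))
  expect_true(all(diff(thr[3:7]) > 0))
  expect_lte(thr[1], min(cal$null_mi))     # threshold at p = 1
  # threshold at p = 1/N should sit near the max observed null MI
  t_anchor <- mi_threshold_at(cal, 1 / cal$n_permutations)
  expect_lt(abs(t_anchor - max(cal$null_mi)), 4 / cal$tail_rate)
  expect_error(mi_threshold_at(cal, 0), "p must be")
  expect_error(calibrate_null(make_null_matrix(40, 8, 1),
                              n_permutations = 10), ">= 100")
})

test_that("mi_p_value inverts mi_threshold_at across both regimes", {
  cal <- local_calibration()
  for (p in c(0.2, 0.05, 1e-3, 1e-6)) {
    thr <- mi_threshold_at(cal, p)
    expect_equal(mi_p_value(cal, thr), p, tolerance = 0.25 * p + 2e-3)
  }
  # monotone decreasing in mi
  mis <- seq(0, 0.4, by = 0.02)
  expect_true(all(diff(mi_p_value(cal, mis)) <= 0))
})

test_that("calibration is reproducible and serializes through JSON", {
  m <- make_null_matrix(20, 5, seed = 3)
  a <- calibrate_null(m, n_permutations = 500, seed = 11)
  b <- calibrate_null(m, n_permutations = 500, seed = 11)
  expect_identical(a$null_mi, b$null_mi)
  td <- withr::local_tempdir()
  write_calibration(a, file.path(td, "cal.json"))
  back <- read_calibration(file.path(td, "cal.json"))
  expect_equal(back$null_mi, a$null_mi, tolerance = 1e-12)
  expect_equal(mi_threshold_at(back, 1e-4), mi_threshold_at(a, 1e-4),
               tolerance = 1e-10)
})

test_that("a hub with no correlated partners yields an empty module", {
  m <- make_null_matrix(40, 8, seed = 17)
  cal <- local_calibration()
  mod <- infer_module(m, "G0001", cal, p_threshold = 1e-7)
  expect_equal(nrow(mod$edges), 0)
  expect_error(infer_module(m, "NOPE", cal), "unknown hub")
})

test_that("planted modules are recovered with signed edges", {
  net <- infer_cohort_network(seed = 31, neg_target_frac = 0)
  for (i in seq_along(net$modules)) {
    mod <- net$modules[[i]]
    planted <- net$cohort$truth$module_membership[[mod$hub_id]]
    expect_gte(mean(planted %in% mod$edges$target_id), 0.8)
    # positive-loading targets must all carry sign +1
    rec <- mod$edges[mod$edges$target_id %in% planted, ]
    expect_true(all(rec$sign == 1L))
  }
})

test_that("negative-loading targets get negative edge signs", {
  net <- infer_cohort_network(seed = 32, neg_target_frac = 1)
  mod <- net$modules[[1]]
  planted <- net$cohort$truth$module_membership[[mod$hub_id]]
  rec <- mod$edges[mod$edges$target_id %in% planted, ]
  expect_gt(nrow(rec), 10)
  expect_true(all(rec$sign == -1L))
})

test_that("merge_modules unions modules with max-MI collapse", {
  mk_mod <- function(hub, targets, mis, signs = 1) {
    structure(list(hub_id = hub, hub_category = "physiology",
                   edges = data.frame(target_id = targets, mi = mis,
                                      p_value = rep(1e-8, length(targets)),
                                      sign = rep_len(signs, length(targets)),
                                      sign_flagged = rep(FALSE, length(targets))),
                   p_threshold = 1e-3, mi_threshold = 0.1,
                   candidates = c("t1", "t2", "t3", "t4", "h2", "h1")),
              class = "network_module")
  }
  m1 <- mk_mod("h1", c("t1", "t2"), c(0.5, 0.3))
  m2 <- mk_mod("h2", c("t3", "t4"), c(0.4, 0.2))
  g <- merge_modules(list(m1, m2))
  expect_equal(igraph::vcount(g), 6)   # 2 hubs + 4 disjoint targets
  expect_equal(igraph::ecount(g), 4)

  # same unordered pair contributed twice: single edge, max MI kept,
  # provenance lists both hubs
  m1b <- mk_mod("h1", "h2", 0.4)
  m2b <- mk_mod("h2", "h1", 0.6)
  g2 <- merge_modules(list(m1b, m2b))
  expect_equal(igraph::ecount(g2), 1)
  expect_equal(igraph::E(g2)$mi, 0.6)
  expect_equal(igraph::E(g2)$provenance, "h1,h2")

  # shared target keeps one edge per hub
  g3 <- merge_modules(list(mk_mod("h1", "t1", 0.5), mk_mod("h2", "t1", 0.3)))
  expect_equal(igraph::degree(g3)[["t1"]], 2)

  # hubs with zero edges still appear
  m_empty <- mk_mod("h9", character(0), numeric(0))
  g4 <- merge_modules(list(m_empty))
  expect_true("h9" %in% igraph::V(g4)$name)
  expect_equal(igraph::ecount(g4), 0)

  expect_error(merge_modules(list(m1, m1)), "duplicate hub_id")
  g5 <- merge_modules(list())
  expect_equal(igraph::vcount(g5), 0)
})

test_that("DPI removes exactly the non-adjacent edges of Markov chains", {
  # 3-chain: X -> Y -> Z, binary symmetric channels with flip 0.1
  mi_xy <- oracle_bsc_mi(0.1)
  mi_yz <- oracle_bsc_mi(0.1)
  mi_xz <- oracle_bsc_mi(c(0.1, 0.1))
  g <- igraph::graph_from_literal(X - Y, Y - Z, X - Z)
  g <- igraph::set_edge_attr(g, "mi", value = c(mi_xy, mi_yz, mi_xz)[
    match(apply(igraph::as_edgelist(g), 1, function(e)
      paste(sort(e), collapse = "")),
      c("XY", "YZ", "XZ"))])
  pruned <- apply_dpi(g, tolerance = 0)
  kept <- apply(igraph::as_edgelist(pruned), 1, function(e)
    paste(sort(e), collapse = "-"))
  expect_setequal(kept, c("X-Y", "Y-Z"))

  # 4-chain with heterogeneous flips: only adjacent edges survive in the
  # complete graph weighted by exact MIs
  flips <- c(0.1, 0.15, 0.05)
  nodes <- c("A", "B", "C", "D")
  g4 <- igraph::make_full_graph(4)
  g4 <- igraph::set_vertex_attr(g4, "name", value = nodes)
  el <- igraph::as_edgelist(g4)
  mis <- apply(el, 1, function(e) {
    i <- match(e[1], nodes); j <- match(e[2], nodes)
    lo <- min(i, j); hi <- max(i, j)
    oracle_bsc_mi(flips[lo:(hi - 1)])
  })
  g4 <- igraph::set_edge_attr(g4, "mi", value = mis)
  pruned4 <- apply_dpi(g4, tolerance = 0)
  kept4 <- apply(igraph::as_edgelist(pruned4), 1, function(e)
    paste(sort(e), collapse = "-"))
  expect_setequal(kept4, c("A-B", "B-C", "C-D"))

  # tolerance high enough that no triangle violates: no-op
  expect_equal(igraph::ecount(apply_dpi(g, tolerance = 1)), 3)
  expect_error(apply_dpi(g, tolerance = -0.1), ">= 0")
})

test_that("network exports are Cytoscape-loadable and faithful", {
  net <- infer_cohort_network(seed = 33)
  td <- withr::local_tempdir()
  write_graphml(net$network, file.path(td, "n.graphml"))
  back <- igraph::read_graph(file.path(td, "n.graphml"), format = "graphml")
  expect_equal(igraph::ecount(back), igraph::ecount(net$network))
  expect_setequal(igraph::V(back)$name, igraph::V(net$network)$name)
  expect_equal(sort(igraph::E(back)$mi), sort(igraph::E(net$network)$mi),
               tolerance = 1e-9)

  write_sif(net$network, file.path(td, "n.sif"))
  sif <- readLines(file.path(td, "n.sif"))
  n_edges <- sum(grepl("\tmi\t", sif, fixed = TRUE))
  expect_equal(n_edges, igraph::ecount(net$network))
})
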