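test_that("bh_fdr matches the brute-force step-up oracle", {
  # hand-checked: each p_(i) * 5 / i equals 0.05
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04, 0.05)), rep(0.05, 5))
  expect_equal(bh_fdr(0.037), 0.037)   # m = 1

  set.seed(12)
  for (i in 1:200) {
    p <- runif(sample(1:50, 1))^sample(1:3, 1)
    expect_equal(bh_fdr(p), oracle_bh(p), tolerance = 1e-12)
  }
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(bh_fdr(c(0.1, NA)), "missing")
})

test_that("train_response guards zero variance and orders by effect", {
  co <- generate_cohort(cohort_spec(n_subjects_per_group = 6, n_genes = 50,
                                    module_size = 5,
                                    n_de = c(healthy = 0, COPD_N = 0,
                                             COPD_L = 0), seed = 8))
  m <- co$matrix
  # make post identical to pre for every healthy subject
  sm <- m$sample_meta
  pre <- sm$id[sm$group == "healthy" & sm$timepoint == "pre"]
  post <- sm$id[sm$group == "healthy" & sm$timepoint == "post"]
  m$values[, post] <- m$values[, pre]
  de <- train_response(m, "healthy")
  expect_true(all(de$p_value == 1))
  expect_true(all(de$flagged))
  expect_true(all(de$direction == "ns"))

  # a single huge injected effect dominates the ranking
  m2 <- co$matrix
  g <- "GENE0010"
  m2$values[g, post] <- m2$values[g, post] +
    10 * sd(m2$values[g, pre])
  de2 <- train_response(m2, "healthy")
  expect_equal(de2$id[which.min(de2$p_value)], g)
  expect_equal(de2$direction[de2$id == g], "up")

  expect_error(train_response(m, "nope"), "unknown group")
  expect_error(
    train_response(generate_cohort(cohort_spec(n_subjects_per_group = 2,
                                               n_genes = 20, module_size = 2,
                                               seed = 1))$matrix, "healthy"),
    "healthy")
})

test_that("paired train_response equals a one-sample t-test on differences", {
  co <- generate_cohort(cohort_spec(n_subjects_per_group = 6, n_genes = 30,
                                    module_size = 3, seed = 9))
  m <- co$matrix
  de <- train_response(m, "COPD_N")
  sm <- m$sample_meta
  gsm <- sm[sm$group == "COPD_N", ]
  for (g in c("GENE0003", "GENE0017")) {
    pre <- m$values[g, gsm$id[gsm$timepoint == "pre"]]
    post <- m$values[g, gsm$id[gsm$timepoint == "post"]]
    tt <- t.test(post - pre)
    expect_equal(de$p_value[de$id == g], tt$p.value, tolerance = 1e-12)
    expect_equal(de$statistic[de$id == g], unname(tt$statistic),
                 tolerance = 1e-12)
  }
})

test_that("fold changes are linear-scale ratios, sign-folded below 1", {
  co <- generate_cohort(cohort_spec(n_subjects_per_group = 6, n_genes = 20,
                                    module_size = 2,
                                    n_de = c(healthy = 0), seed = 10))
  m <- co$matrix
  sm <- m$sample_meta
  pre <- sm$id[sm$group == "healthy" & sm$timepoint == "pre"]
  post <- sm$id[sm$group == "healthy" & sm$timepoint == "post"]
  # exact +/-1 log2 shift over the paired pre values
  m$values["GENE0005", post] <- m$values["GENE0005", pre] + 1
  m$values["GENE0006", post] <- m$values["GENE0006", pre] - 1
  de <- train_response(m, "healthy")
  expect_equal(de$fold_change[de$id == "GENE0005"], 2, tolerance = 1e-9)
  expect_equal(de$fold_change[de$id == "GENE0006"], -2, tolerance = 1e-9)
})

test_that("two_factor_anova agrees with the reference implementation", {
  skip_if_not_installed("car")
  m <- make_null_matrix(12, 5, seed = 14)
  # add structure so p-values span the range
  m$values[1, m$sample_meta$group == "healthy"] <-
    m$values[1, m$sample_meta$group == "healthy"] + 2
  m$values[2, m$sample_meta$timepoint == "post"] <-
    m$values[2, m$sample_meta$timepoint == "post"] + 1.5
  res <- two_factor_anova(m)
  for (i in c(1, 2, 7)) {
    dat <- data.frame(y = m$values[i, ],
                      disease = factor(m$sample_meta$group),
                      training = factor(m$sample_meta$timepoint))
    ref <- car::Anova(lm(y ~ disease + training, dat), type = 2)
    expect_equal(res$p_disease[i], ref[["Pr(>F)"]][1], tolerance = 1e-10)
    expect_equal(res$p_training[i], ref[["Pr(>F)"]][2], tolerance = 1e-10)
  }
})

test_that("with a single-level training factor the disease p-value reduces
           to the pooled two-sample t-test", {
  m <- make_null_matrix(8, 6, seed = 15, groups = c("healthy", "COPD_N"))
  pre_only <- subset_matrix(
    m, samples = m$sample_meta$id[m$sample_meta$timepoint == "pre"])
  res <- two_factor_anova(pre_only)
  expect_true(all(is.na(res$p_training)))
  for (i in c(1, 5)) {
    tt <- t.test(pre_only$values[i, ] ~ pre_only$sample_meta$group,
                 var.equal = TRUE)
    expect_equal(res$p_disease[i], tt$p.value, tolerance = 1e-10)
  }
})

test_that("anova rejects empty cells and flags constant variables", {
  m <- make_null_matrix(5, 4, seed = 16)
  drop <- m$sample_meta$group == "COPD_L" & m$sample_meta$timepoint == "post"
  m_bad <- subset_matrix(m, samples = m$sample_meta$id[!drop])
  expect_error(two_factor_anova(m_bad), "COPD_L")

  m2 <- make_null_matrix(5, 4, seed = 16)
  m2$values[3, ] <- 7
  expect_warning(res <- two_factor_anova(m2), "constant")
  expect_true(res$flagged[3])
  expect_true(is.na(res$p_disease[3]))
})

test_that("filter_targets applies the FDR and fold thresholds jointly", {
  de <- data.frame(id = c("a", "b", "c", "d"),
                   statistic = c(3, 2.5, -4, 5),
                   fold_change = c(1.6, 1.4, -2.0, 3.0),
                   p_value = c(0.01, 0.01, 0.001, 0.5),
                   q_value = c(0.05, 0.05, 0.01, 0.6),
                   direction = c("up", "up", "down", "ns"))
  out <- filter_targets(de, c("a", "b", "c", "d"), fdr = 0.10,
                        min_fold = 1.5)
  expect_setequal(out$id, c("a", "c"))   # b fails fold, d fails q
  expect_equal(attr(out, "n_up"), 1)
  expect_equal(attr(out, "n_down"), 1)
  expect_equal(nrow(filter_targets(de, character(0))), 0)
})

test_that("a curated-target filter recovers exactly the injected genes", {
  # 94-gene curated list, 13 planted up-effects of fold 1.8: the filter
  # keeps exactly the injected genes, all up
  set.seed(18)
  spec <- cohort_spec(n_subjects_per_group = 12, n_genes = 300,
                      module_size = 10, n_de = c(healthy = 0),
                      noise_sd = 0.25, seed = 18)
  co <- generate_cohort(spec)
  m <- co$matrix
  genes <- m$variable_meta$id[m$variable_meta$modality == "gene_expression"]
  curated <- sample(setdiff(genes, unlist(co$truth$module_membership)), 94)
  injected <- sample(curated, 13)
  sm <- m$sample_meta
  post <- sm$id[sm$group == "healthy" & sm$timepoint == "post"]
  m$values[injected, post] <- m$values[injected, post] + log2(1.8)
  de <- train_response(m, "healthy")
  out <- filter_targets(de, curated, fdr = 0.10, min_fold = 1.5)
  expect_setequal(out$id, injected)
  expect_equal(attr(out, "n_down"), 0)
})

test_that("enrichment p-values equal the exact hypergeometric tail", {
  set.seed(19)
  universe <- sprintf("g%03d", 1:400)
  sets <- lapply(1:10, function(i) sample(universe, sample(10:60, 1)))
  names(sets) <- paste0("set", 1:10)
  lst <- sample(universe, 50)
  res <- enrich(lst, sets, universe, fdr = 0.01)
  for (i in seq_len(nrow(res))) {
    r <- res[i, ]
    expect_equal(r$p_value,
                 oracle_hyper_tail(r$overlap, r$set_size, r$universe_size,
                                   r$list_size),
                 tolerance = 1e-12)
  }
  expect_equal(bh_fdr(res$p_value[order(res$p_value)]), res$q_value)

  # list identical to one set: that set attains the smallest p
  sets2 <- c(sets, list(exact = lst[1:20]))
  res2 <- enrich(lst[1:20], sets2, universe)
  expect_equal(res2$set[1], "exact")

  # empty list: all p = 1
  res3 <- enrich(character(0), sets, universe)
  expect_true(all(res3$p_value == 1))
  expect_error(enrich(lst, sets, character(0)), "universe")
})

test_that("GMT and DE TSV round-trips are lossless", {
  td <- withr::local_tempdir()
  writeLines(c("setA\tdesc\tg1\tg2\tg3", "setB\tother desc\tg9"),
             file.path(td, "sets.gmt"))
  sets <- read_gmt(file.path(td, "sets.gmt"))
  expect_equal(sets, list(setA = c("g1", "g2", "g3"), setB = "g9"))

  de <- data.frame(id = c("a", "b"), statistic = c(1.5, -2),
                   fold_change = c(1.2, -1.8), p_value = c(0.1, 0.01),
                   q_value = c(0.2, 0.02), direction = c("ns", "down"),
                   flagged = FALSE)
  write_de_tsv(de, file.path(td, "de.tsv"))
  back <- read_de_tsv(file.path(td, "de.tsv"))
  expect_equal(back$p_value, de$p_value, tolerance = 1e-12)
  expect_equal(back$direction, de$direction)
})
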