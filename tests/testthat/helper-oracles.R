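# Independent oracles used across the suite.  Each one deliberately takes a
# different computational route from the package implementation it checks.

# MI of a joint probability table via the entropy identity
# I(X;Y) = H(X) + H(Y) - H(X,Y)
oracle_mi_table <- function(p) {
  p <- p / sum(p)
  ent <- function(q) { q <- q[q > 0]; -sum(q * log(q)) }
  ent(rowSums(p)) + ent(colSums(p)) - ent(as.vector(p))
}

# expand a count table into paired symbol vectors
table_to_vectors <- function(tab) {
  idx <- which(tab > 0, arr.ind = TRUE)
  x <- rep(idx[, 1], tab[tab > 0])
  y <- rep(idx[, 2], tab[tab > 0])
  list(x = x, y = y)
}

# brute-force Benjamini-Hochberg step-up: q_(i) = min_{j>=i} p_(j) m / j
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    cand <- vapply(i:m, function(j) p[o[j]] * m / j, numeric(1))
    q_sorted[i] <- min(1, min(cand))
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# hypergeometric upper-tail by direct summation
oracle_hyper_tail <- function(overlap, set_size, universe_size, list_size) {
  ks <- overlap:min(set_size, list_size)
  sum(vapply(ks, function(k)
    choose(set_size, k) * choose(universe_size - set_size, list_size - k),
    numeric(1))) / choose(universe_size, list_size)
}

# exact pairwise MI between positions i < j of a stationary binary symmetric
# Markov chain with per-step flip probabilities `flips` (uniform start):
# composed flip probability, then the 2x2 joint table
oracle_bsc_mi <- function(flips) {
  q <- 0.5 * (1 - prod(1 - 2 * flips))
  joint <- matrix(c(0.5 * (1 - q), 0.5 * q, 0.5 * q, 0.5 * (1 - q)), 2)
  oracle_mi_table(joint)
}

# brute-force KNN leave-one-out: double loop, no shared code with knn_cv
oracle_knn_loo <- function(x, y, k) {
  n <- ncol(x)
  pred <- character(n)
  for (i in seq_len(n)) {
    d <- rep(Inf, n)
    for (j in seq_len(n)) if (j != i) d[j] <- sum((x[, i] - x[, j])^2)
    nn <- order(d, seq_len(n))[seq_len(k)]
    tab <- table(y[nn])
    top <- names(tab)[tab == max(tab)]
    pred[i] <- if (length(top) == 1) top else {
      hit <- top[1]
      for (j in nn) if (y[j] %in% top) { hit <- y[j]; break }
      hit
    }
  }
  pred
}

# small standardized matrix of i.i.d. Gaussian variables with labels
make_null_matrix <- function(n_var, n_subj_per_group, seed,
                             groups = c("healthy", "COPD_N", "COPD_L")) {
  set.seed(seed)
  subjects <- paste0(rep(groups, each = n_subj_per_group), "_s",
                     seq_len(n_subj_per_group))
  sample_meta <- data.frame(
    id = paste0(rep(subjects, each = 2), "_", c("pre", "post")),
    subject = rep(subjects, each = 2),
    group = rep(rep(groups, each = n_subj_per_group), each = 2),
    timepoint = rep(c("pre", "post"), length(subjects)),
    stringsAsFactors = FALSE)
  values <- matrix(rnorm(n_var * nrow(sample_meta)), n_var)
  variable_meta <- data.frame(id = sprintf("G%04d", seq_len(n_var)),
                              modality = "gene_expression",
                              stringsAsFactors = FALSE)
  measurement_matrix(values, variable_meta, sample_meta)
}

# standard scaled-down cohort -> inferred network used by several tests
infer_cohort_network <- function(seed, coupling = 0.3, p_threshold = 1e-3,
                                 n_permutations = 2000, ...) {
  spec <- cohort_spec(seed = seed, coupling = coupling, ...)
  co <- generate_cohort(spec)
  sm <- standardize(co$matrix)
  cal <- calibrate_null(sm, n_permutations = n_permutations, seed = seed)
  mods <- lapply(seq_len(nrow(spec$hubs)), function(i)
    infer_module(sm, spec$hubs$hub_id[i], cal, p_threshold,
                 hub_category = spec$hubs$category[i]))
  list(spec = spec, cohort = co, matrix = sm, calibration = cal,
       modules = mods, network = merge_modules(mods))
}

# two-class expression matrix with a mean separation on every gene
make_labeled <- function(n_per_class, n_genes, sep = 0, seed = 1,
                         majority_first = FALSE) {
  set.seed(seed)
  n <- 2 * n_per_class
  cls <- rep(c("healthy", "COPD"), each = n_per_class)
  if (majority_first) cls <- c(rep("healthy", n_per_class + 2),
                               rep("COPD", n_per_class - 2))
  v <- matrix(rnorm(n_genes * n), n_genes)
  v <- v + matrix(rep(ifelse(cls == "COPD", sep, 0), each = n_genes),
                  n_genes)
  m <- measurement_matrix(
    v, data.frame(id = sprintf("g%02d", seq_len(n_genes)),
                  modality = "gene_expression"),
    data.frame(id = sprintf("s%02d", seq_len(n)),
               subject = sprintf("p%02d", seq_len(n)),
               group = ifelse(cls == "healthy", "healthy", "COPD_N"),
               timepoint = "pre"))
  list(m = m, labels = stats::setNames(cls, sprintf("s%02d", seq_len(n))))
}

# external DE table whose directions follow the planted edge signs
de_from_truth <- function(truth, flip = FALSE) {
  signs <- unlist(unname(truth$target_sign))
  dirs <- ifelse(signs > 0, 1, -1) * (if (flip) -1 else 1)
  data.frame(id = names(signs), statistic = dirs,
             fold_change = ifelse(dirs > 0, 2, -2),
             p_value = 1e-4, q_value = 1e-3,
             direction = ifelse(dirs > 0, "up", "down"),
             stringsAsFactors = FALSE)
}
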