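#' Specification of a synthetic multi-modal cohort
#'
#' Defines the generative model for a three-group training-study cohort
#' (healthy, COPD with normal fat-free-mass index, COPD with low FFMI), each
#' subject sampled pre and post training.  Hub variables carry latent
#' factors; each hub owns a disjoint module of target genes correlated with
#' it at `hub_target_corr`; tissue-remodelling hub factors (serum cytokines,
#' receptor genes) are coupled to bioenergetics hub factors (physiology,
#' glycolysis genes) at correlation `coupling`; designated genes respond to
#' training group-specifically.
#'
#' @param n_subjects_per_group Subjects per group (each contributes a pre and
#'   a post sample).
#' @param n_genes,n_phys,n_serum Counts of gene-expression, physiology and
#'   serum variables.
#' @param hubs Data frame with columns `hub_id`, `category`
#'   (see [hub_categories()]).  Physiology/serum hubs are realized as
#'   physiology/serum variables, gene hubs as gene-expression variables.
#' @param module_size Target genes planted per hub (modules are disjoint).
#' @param hub_target_corr Population correlation between a target and its
#'   hub, in \[0, 1).
#' @param coupling Population correlation between each remodelling hub
#'   factor and its paired bioenergetics hub factor, in \[0, 1).
#' @param subject_corr Within-subject correlation of the pre and post latent
#'   factors, in \[0, 1\]; pre/post samples of a subject share this much of
#'   the subject's factor.
#' @param train_effect_sd_units Training effect for responsive genes, in
#'   units of the pre-training standard deviation; a single number or a
#'   named vector by group.
#' @param noise_sd Residual standard deviation of target genes and noise
#'   genes.
#' @param n_de Named integer vector: number of training-responsive genes per
#'   group.  The default mirrors a cohort in which healthy muscle mounts a
#'   broad transcriptional response, preserved-mass COPD a reduced one, and
#'   wasted-mass COPD almost none.
#' @param de_up_frac Fraction of responsive genes that go up.
#' @param neg_target_frac Fraction of module targets with negative loading
#'   on their hub.
#' @param seed Integer seed; identical spec + seed reproduce the cohort
#'   bit-for-bit.
#'
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects_per_group = 8,
                        n_genes = 200, n_phys = 4, n_serum = 5,
                        hubs = default_hubs(),
                        module_size = 20,
                        hub_target_corr = 0.8,
                        coupling = 0.3,
                        subject_corr = 0.5,
                        train_effect_sd_units = 2,
                        noise_sd = 1,
                        n_de = c(healthy = 40, COPD_N = 12, COPD_L = 2),
                        de_up_frac = 0.7,
                        neg_target_frac = 0.3,
                        seed = 1L) {
  hubs <- as.data.frame(hubs, stringsAsFactors = FALSE)
  stopifnot(all(c("hub_id", "category") %in% names(hubs)))
  bad <- setdiff(unique(hubs$category), hub_categories())
  if (length(bad)) stop("invalid hub category: ", paste(bad, collapse = ", "))
  if (anyDuplicated(hubs$hub_id)) stop("duplicated hub ids")
  counts <- c(n_subjects_per_group = n_subjects_per_group, n_genes = n_genes,
              n_phys = n_phys, n_serum = n_serum, module_size = module_size)
  if (any(counts < 1)) stop("all counts must be >= 1: ",
                            paste(names(counts)[counts < 1], collapse = ", "))
  for (nm in c("hub_target_corr", "coupling")) {
    v <- get(nm)
    if (v < 0 || v >= 1) stop(nm, " must be in [0, 1)")
  }
  if (subject_corr < 0 || subject_corr > 1) stop("subject_corr must be in [0, 1]")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  n_gene_hubs <- sum(hubs$category %in% c("receptor_gene", "glycolysis_gene"))
  if (module_size * nrow(hubs) > n_genes)
    stop("sizing error: module_size * n_hubs (", module_size * nrow(hubs),
         ") exceeds n_genes (", n_genes, ")")
  if (sum(hubs$category == "physiology") > n_phys)
    stop("more physiology hubs than physiology variables")
  if (sum(hubs$category == "serum_cytokine") > n_serum)
    stop("more serum hubs than serum variables")
  if (n_gene_hubs > n_genes) stop("more gene hubs than genes")
  groups <- c("healthy", "COPD_N", "COPD_L")
  if (is.null(names(n_de))) names(n_de) <- groups[seq_along(n_de)]
  if (length(train_effect_sd_units) == 1 && is.null(names(train_effect_sd_units)))
    train_effect_sd_units <- stats::setNames(rep(train_effect_sd_units,
                                                 length(groups)), groups)
  structure(list(n_subjects_per_group = as.integer(n_subjects_per_group),
                 n_genes = as.integer(n_genes), n_phys = as.integer(n_phys),
                 n_serum = as.integer(n_serum), hubs = hubs,
                 module_size = as.integer(module_size),
                 hub_target_corr = hub_target_corr, coupling = coupling,
                 subject_corr = subject_corr,
                 train_effect_sd_units = train_effect_sd_units,
                 noise_sd = noise_sd, n_de = n_de, de_up_frac = de_up_frac,
                 neg_target_frac = neg_target_frac,
                 groups = groups, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Default hub panel
#'
#' One hub per category: peak oxygen uptake (physiology), interleukin-6
#' (serum cytokine), the interleukin-1 receptor (muscle-expressed receptor
#' gene) and muscle phosphofructokinase (glycolysis gene).
#'
#' @return Data frame with columns `hub_id`, `category`.
#' @export
default_hubs <- function() {
  data.frame(hub_id = c("VO2peak", "IL6", "IL1R1", "PFKM"),
             category = c("physiology", "serum_cytokine",
                          "receptor_gene", "glycolysis_gene"),
             stringsAsFactors = FALSE)
}

# Round-robin pairing of remodelling hubs with bioenergetics hubs; each pair
# of latent factors is drawn with correlation `coupling`.
.hub_pairing <- function(hubs) {
  rem <- which(hubs$category %in% subnetwork_categories("remodelling"))
  bio <- which(hubs$category %in% subnetwork_categories("bioenergetics"))
  if (!length(rem) || !length(bio)) return(NULL)
  k <- max(length(rem), length(bio))
  data.frame(rem = rem[((seq_len(k) - 1) %% length(rem)) + 1],
             bio = bio[((seq_len(k) - 1) %% length(bio)) + 1])[
               seq_len(min(length(rem), length(bio))), , drop = FALSE]
}

#' Generate a synthetic cohort with planted structure
#'
#' Draws per-subject and per-sample latent factors for every hub (pre/post
#' samples of a subject share the subject component, weight `subject_corr`),
#' couples remodelling factors to bioenergetics factors pairwise at
#' `coupling`, plants `module_size` disjoint target genes per hub at
#' population correlation `hub_target_corr` (a `neg_target_frac` share with
#' negative sign), fills the remaining genes with i.i.d. Gaussian noise,
#' puts physiology/serum variables on arbitrary scales (random positive
#' scale and offset) so that standardization is genuinely exercised, and
#' injects group-specific training effects into the designated responsive
#' genes.
#'
#' @param spec A [cohort_spec()].
#' @return A list with elements `matrix` (a [measurement_matrix()]) and
#'   `truth` (class `cohort_truth`: `module_membership`, `target_sign`,
#'   `coupling`, `de_genes`, `hub_pairs`).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  ns <- spec$n_subjects_per_group
  groups <- spec$groups
  subjects <- paste0(rep(groups, each = ns), "_s",
                     rep(seq_len(ns), length(groups)))
  sample_meta <- data.frame(
    id = paste0(rep(subjects, each = 2), "_", c("pre", "post")),
    subject = rep(subjects, each = 2),
    group = rep(rep(groups, each = ns), each = 2),
    timepoint = rep(c("pre", "post"), length(subjects)),
    stringsAsFactors = FALSE)
  n_samp <- nrow(sample_meta)
  n_subj <- length(subjects)
  subj_of <- match(sample_meta$subject, subjects)

  hubs <- spec$hubs
  nh <- nrow(hubs)
  pairs <- .hub_pairing(hubs)

  # latent hub factors: subject component + sample innovation, both with the
  # pairwise coupling structure, combined with weight subject_corr
  draw_factors <- function(n) {
    f <- matrix(stats::rnorm(nh * n), nh, n)
    if (!is.null(pairs) && spec$coupling > 0) {
      for (r in seq_len(nrow(pairs))) {
        a <- pairs$rem[r]; b <- pairs$bio[r]
        f[b, ] <- spec$coupling * f[a, ] +
          sqrt(1 - spec$coupling^2) * f[b, ]
      }
    }
    f
  }
  fs <- draw_factors(n_subj)    # subject level
  fe <- draw_factors(n_samp)    # sample level
  w <- spec$subject_corr
  factors <- sqrt(w) * fs[, subj_of, drop = FALSE] + sqrt(1 - w) * fe
  rownames(factors) <- hubs$hub_id

  # variable ids per modality; hubs occupy the leading slots of their modality
  phys_hub <- hubs$hub_id[hubs$category == "physiology"]
  serum_hub <- hubs$hub_id[hubs$category == "serum_cytokine"]
  gene_hub <- hubs$hub_id[hubs$category %in% c("receptor_gene", "glycolysis_gene")]
  phys_ids <- c(phys_hub, sprintf("PHYS%02d", seq_len(spec$n_phys - length(phys_hub))))
  if (spec$n_phys == length(phys_hub)) phys_ids <- phys_hub
  serum_ids <- c(serum_hub, sprintf("SERUM%02d", seq_len(spec$n_serum - length(serum_hub))))
  if (spec$n_serum == length(serum_hub)) serum_ids <- serum_hub
  gene_ids <- c(gene_hub, sprintf("GENE%04d", seq_len(spec$n_genes - length(gene_hub))))

  values <- matrix(NA_real_, spec$n_phys + spec$n_serum + spec$n_genes, n_samp)
  rownames(values) <- c(phys_ids, serum_ids, gene_ids)
  r <- spec$hub_target_corr
  res_sd <- spec$noise_sd * sqrt(1 - r^2)

  # hubs observe their own factor
  for (h in hubs$hub_id) values[h, ] <- factors[h, ]
  # non-hub physiology/serum variables: independent noise
  for (v in setdiff(c(phys_ids, serum_ids), hubs$hub_id))
    values[v, ] <- stats::rnorm(n_samp)

  # disjoint target modules drawn from the non-hub genes
  free_genes <- setdiff(gene_ids, gene_hub)
  target_pool <- sample(free_genes, spec$module_size * nh)
  module_membership <- split(target_pool,
                             rep(hubs$hub_id, each = spec$module_size))
  module_membership <- module_membership[hubs$hub_id]
  target_sign <- list()
  for (h in hubs$hub_id) {
    tg <- module_membership[[h]]
    sg <- ifelse(stats::runif(length(tg)) < spec$neg_target_frac, -1, 1)
    names(sg) <- tg
    target_sign[[h]] <- sg
    for (i in seq_along(tg))
      values[tg[i], ] <- sg[i] * r * factors[h, ] +
        res_sd * stats::rnorm(n_samp)
  }
  # remaining genes: i.i.d. noise
  for (v in setdiff(free_genes, target_pool))
    values[v, ] <- spec$noise_sd * stats::rnorm(n_samp)

  # gene-expression baseline (log2 microarray-like level)
  baseline <- stats::rnorm(length(gene_ids), mean = 7, sd = 1)
  values[gene_ids, ] <- values[gene_ids, ] + baseline
  # physiology/serum on arbitrary scales
  for (v in c(phys_ids, serum_ids)) {
    sc <- exp(stats::rnorm(1, 1, 0.5))
    off <- stats::rnorm(1, 50, 20)
    values[v, ] <- off + sc * values[v, ]
  }

  variable_meta <- data.frame(
    id = rownames(values),
    modality = c(rep("physiology", spec$n_phys),
                 rep("serum_protein", spec$n_serum),
                 rep("gene_expression", spec$n_genes)),
    stringsAsFactors = FALSE)
  m <- measurement_matrix(values, variable_meta, sample_meta)

  # designated training-responsive genes per group; hub genes stay clean
  # anchors and are never designated
  de_pool <- setdiff(gene_ids, gene_hub)
  de_genes <- list()
  for (g in groups) {
    ng <- if (g %in% names(spec$n_de)) spec$n_de[[g]] else 0L
    ng <- min(ng, length(de_pool))
    if (ng > 0) {
      picked <- sample(de_pool, ng)
      dirs <- ifelse(stats::runif(ng) < spec$de_up_frac, "up", "down")
      names(dirs) <- picked
      de_genes[[g]] <- dirs
    } else de_genes[[g]] <- stats::setNames(character(0), character(0))
  }
  truth <- structure(list(module_membership = module_membership,
                          target_sign = target_sign,
                          coupling = spec$coupling,
                          de_genes = de_genes,
                          hub_pairs = if (is.null(pairs)) NULL else
                            data.frame(rem = hubs$hub_id[pairs$rem],
                                       bio = hubs$hub_id[pairs$bio],
                                       stringsAsFactors = FALSE)),
                     class = "cohort_truth")

  for (g in groups) {
    eff <- spec$train_effect_sd_units[[g]]
    if (length(truth$de_genes[[g]]) && eff != 0)
      m <- inject_de(m, truth, g, eff)
  }
  list(matrix = m, truth = truth)
}

#' Inject a training effect into designated genes of one group
#'
#' Shifts the post-timepoint values of the group's responsive genes by
#' `effect_sd_units` times the gene's pre-timepoint standard deviation in
#' that group, signed by the recorded direction.  All other cells are left
#' untouched.
#'
#' @param m A [measurement_matrix()].
#' @param truth A `cohort_truth` (from [generate_cohort()]) whose
#'   `de_genes[[group]]` names the genes and directions.
#' @param group Group label present in the matrix.
#' @param effect_sd_units Effect size in pre-timepoint SD units.
#' @return The modified `measurement_matrix`.
#' @export
inject_de <- function(m, truth, group, effect_sd_units) {
  stopifnot(inherits(m, "measurement_matrix"))
  if (!group %in% m$sample_meta$group)
    stop("unknown group: ", group)
  dirs <- truth$de_genes[[group]]
  if (is.null(dirs)) stop("no DE genes recorded for group ", group)
  miss <- setdiff(names(dirs), rownames(m$values))
  if (length(miss)) stop("unknown gene ids: ", paste(miss, collapse = ", "))
  if (effect_sd_units == 0) return(m)
  pre <- m$sample_meta$group == group & m$sample_meta$timepoint == "pre"
  post <- m$sample_meta$group == group & m$sample_meta$timepoint == "post"
  for (gene in names(dirs)) {
    s <- stats::sd(m$values[gene, pre])
    shift <- effect_sd_units * s * if (dirs[[gene]] == "up") 1 else -1
    m$values[gene, post] <- m$values[gene, post] + shift
  }
  m
}

#' Write a generated cohort to disk
#'
#' Matrix and metadata as TSV (see [write_matrix_tsv()]), the hub list as
#' TSV, and the ground truth as JSON.
#'
#' @param cohort A list `(matrix, truth)` from [generate_cohort()].
#' @param spec The [cohort_spec()] used (for the hub list).
#' @param dir Output directory (created if absent).
#' @return Invisibly, the directory.
#' @export
write_cohort <- function(cohort, spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix_tsv(cohort$matrix,
                   file.path(dir, "matrix.tsv"),
                   file.path(dir, "variables.tsv"),
                   file.path(dir, "samples.tsv"))
  utils::write.table(spec$hubs, file.path(dir, "hubs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- cohort$truth
  jsonlite::write_json(
    list(module_membership = truth$module_membership,
         target_sign = lapply(truth$target_sign, as.list),
         coupling = truth$coupling,
         de_genes = lapply(truth$de_genes, as.list)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
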