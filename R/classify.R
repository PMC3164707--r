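#' Cross-validated k-nearest-neighbour classification from a gene panel
#'
#' Discriminates sample classes (for instance healthy versus diseased
#' muscle) from a small panel of genes -- e.g. a handful of histone
#' deacetylases -- with k-nearest neighbours under leave-one-out or
#' stratified k-fold cross-validation.  Distances are Euclidean on
#' row-standardized panel values; distance ties are broken by the smallest
#' sample index, so leave-one-out results are fully deterministic and
#' invariant to sample ordering.  With two classes and odd `k`, vote ties
#' cannot occur; with more classes a vote tie goes to the tied class with
#' the nearest neighbour.
#'
#' @param m A [measurement_matrix()].
#' @param labels Named character vector or factor: class per sample id
#'   (names must cover the matrix samples), or a `sample_meta` column name.
#' @param panel Character vector of panel gene ids (all must be present).
#' @param k Number of neighbours (odd; default 3).
#' @param cv `"leave_one_out"` (default) or `"stratified_kfold"`.
#' @param k_folds Folds for the stratified scheme.
#' @param seed Seed for the fold assignment (unused by leave-one-out).
#' @return List of class `knn_result`: `accuracy`, `predictions` (data
#'   frame `sample_id`, `truth`, `predicted`, `correct`), `k`, `cv`.
#' @export
knn_cv <- function(m, labels, panel, k = 3,
                   cv = c("leave_one_out", "stratified_kfold"),
                   k_folds = 5, seed = 1L) {
  stopifnot(inherits(m, "measurement_matrix"))
  cv <- match.arg(cv)
  if (length(panel) == 0) stop("panel must not be empty")
  if (k %% 2 != 1) stop("k must be odd (tie avoidance)")
  miss <- setdiff(panel, rownames(m$values))
  if (length(miss)) stop("panel genes missing from the matrix: ",
                         paste(miss, collapse = ", "))
  ids <- m$sample_meta$id
  if (length(labels) == 1 && labels %in% names(m$sample_meta))
    labels <- stats::setNames(as.character(m$sample_meta[[labels]]), ids)
  if (is.null(names(labels))) names(labels) <- ids
  y <- as.character(labels[ids])
  if (anyNA(y)) stop("labels missing for some samples")
  tab <- table(y)
  if (any(tab < k + 1))
    stop("every class needs >= k + 1 samples; violated by: ",
         paste(names(tab)[tab < k + 1], collapse = ", "))

  x <- m$values[panel, , drop = FALSE]
  sds <- apply(x, 1, stats::sd)
  if (any(sds == 0)) {
    warning("constant panel genes carry no information: ",
            paste(panel[sds == 0], collapse = ", "))
    sds[sds == 0] <- 1
  }
  x <- (x - rowMeans(x)) / sds
  d2 <- as.matrix(stats::dist(t(x)))^2
  n <- ncol(x)

  predict_one <- function(test_idx, train_idx) {
    dd <- d2[test_idx, train_idx]
    # order by distance then by original sample index (deterministic ties)
    nn <- train_idx[order(dd, train_idx)][seq_len(min(k, length(train_idx)))]
    votes <- table(y[nn])
    top <- names(votes)[votes == max(votes)]
    if (length(top) == 1) return(top)
    # vote tie (>2 classes): tied class owning the nearest neighbour
    for (j in nn) if (y[j] %in% top) return(y[j])
    top[1]
  }

  if (cv == "leave_one_out") {
    pred <- vapply(seq_len(n), function(i)
      predict_one(i, setdiff(seq_len(n), i)), character(1))
  } else {
    set.seed(seed)
    fold <- integer(n)
    for (cls in names(tab)) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep_len(seq_len(k_folds), length(idx))
    }
    pred <- character(n)
    for (f in seq_len(k_folds)) {
      test <- which(fold == f)
      train <- which(fold != f)
      for (i in test) pred[i] <- predict_one(i, train)
    }
  }
  predictions <- data.frame(sample_id = ids, truth = y, predicted = pred,
                            correct = pred == y, stringsAsFactors = FALSE)
  structure(list(accuracy = mean(pred == y), predictions = predictions,
                 k = k, cv = cv, panel = panel),
            class = "knn_result")
}

#' @export
print.knn_result <- function(x, ...) {
  cat(sprintf("knn_result: %.1f%% accuracy (%s, k = %d, %d-gene panel)\n",
              100 * x$accuracy, x$cv, x$k, length(x$panel)))
  invisible(x)
}
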