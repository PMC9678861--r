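#' Per-class precision, recall and F1
#'
#' One-vs-rest confusion counts per class: precision = TP / (TP + FP),
#' recall = TP / (TP + FN), F1 = 2 P R / (P + R). Any quantity with a zero
#' denominator is defined as 0, which keeps every score bounded in \[0, 1\].
#' Macro averages are unweighted means over the classes present in `truth`
#' (predicted-only classes accumulate false positives but are not scored).
#'
#' @param truth Vector of true class labels.
#' @param estimate Vector of predicted class labels, same length.
#' @return An object of class `class_metrics`: use [generics::tidy()] for the
#'   per-class table and [generics::glance()] for the macro averages.
#' @export
precision_recall_f1 <- function(truth, estimate) {
  if (length(truth) != length(estimate)) {
    abort("truth and estimate must have equal length")
  }
  if (length(truth) == 0) abort("at least one sample is required")
  truth <- as.character(truth)
  estimate <- as.character(estimate)
  classes <- sort(unique(truth))
  n <- length(truth)
  by_class <- purrr::map_dfr(classes, function(cl) {
    tp <- sum(truth == cl & estimate == cl)
    fp <- sum(truth != cl & estimate == cl)
    fn <- sum(truth == cl & estimate != cl)
    tn <- n - tp - fp - fn
    precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
    recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f1 <- if (precision + recall == 0) 0 else
      2 * precision * recall / (precision + recall)
    tibble::tibble(class = cl, tp = tp, fp = fp, fn = fn, tn = tn,
                   precision = precision, recall = recall, f1 = f1)
  })
  structure(
    list(by_class = by_class,
         macro_precision = mean(by_class$precision),
         macro_recall = mean(by_class$recall),
         macro_f1 = mean(by_class$f1),
         n = n),
    class = "class_metrics"
  )
}

#' @export
print.class_metrics <- function(x, ...) {
  cat("Classification metrics over", nrow(x$by_class), "classes,",
      x$n, "samples\n")
  print(x$by_class)
  cat(sprintf("macro precision %.4f  recall %.4f  F1 %.4f\n",
              x$macro_precision, x$macro_recall, x$macro_f1))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method generics::tidy
tidy.class_metrics <- function(x, ...) x$by_class

#' @exportS3Method generics::glance
glance.class_metrics <- function(x, ...) {
  tibble::tibble(macro_precision = x$macro_precision,
                 macro_recall = x$macro_recall,
                 macro_f1 = x$macro_f1, n_classes = nrow(x$by_class),
                 n = x$n)
}

# Squared Euclidean cross-distance matrix (queries x references).
.cross_dist2 <- function(query_x, train_x) {
  d2 <- outer(rowSums(query_x^2), rowSums(train_x^2), "+") -
    2 * query_x %*% t(train_x)
  d2[d2 < 0] <- 0
  d2
}

# k-NN voting on a precomputed squared-distance matrix with integer labels.
# Majority among the k nearest; majority ties go to the tied label with the
# nearest representative; distance ties to the lower training-row index
# (order() is stable).
.knn_core <- function(d2, labels_int, n_lab, k) {
  vapply(seq_len(nrow(d2)), function(i) {
    nb <- order(d2[i, ])[seq_len(k)]
    labs <- labels_int[nb]
    cnt <- tabulate(labs, n_lab)
    m <- max(cnt)
    tied <- which(cnt == m)
    if (length(tied) == 1L) tied else labs[labs %in% tied][1]
  }, integer(1))
}

# Unweighted mean of per-class F1 over the classes present in truth; plain
# vectors, used on the optimisation hot path. precision_recall_f1() computes
# the same macro F1 with full per-class output.
.macro_f1 <- function(truth, pred) {
  classes <- sort(unique(truth))
  f1 <- vapply(classes, function(cl) {
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    p <- if (tp + fp == 0) 0 else tp / (tp + fp)
    r <- if (tp + fn == 0) 0 else tp / (tp + fn)
    if (p + r == 0) 0 else 2 * p * r / (p + r)
  }, numeric(1))
  mean(f1)
}

#' k-nearest-neighbour label prediction under Euclidean distance
#'
#' For each query the `k` nearest training rows are retrieved and the
#' majority label among them is predicted. A majority tie goes to the tied
#' label whose representative is nearest (for the usual k = 3 three-way tie
#' this is the single nearest neighbour's label); equal distances are broken
#' by lower training-row index.
#'
#' @param train_x Numeric matrix of training rows (mask already applied).
#' @param train_labels Label vector, one per training row.
#' @param query_x Numeric matrix of query rows, same number of columns.
#' @param k Number of neighbours (default 3).
#' @return Character vector of predicted labels, one per query row.
#' @export
knn_predict <- function(train_x, train_labels, query_x, k = 3) {
  train_x <- as.matrix(train_x); query_x <- as.matrix(query_x)
  if (k < 1) abort("k must be >= 1")
  if (nrow(train_x) < k) abort("k exceeds the number of training rows")
  if (ncol(train_x) != ncol(query_x)) abort("column count mismatch")
  train_labels <- as.character(train_labels)
  lev <- sort(unique(train_labels))
  d2 <- .cross_dist2(query_x, train_x)
  lev[.knn_core(d2, match(train_labels, lev), length(lev), k)]
}

#' Image-search quality of a feature subset (macro F1)
#'
#' Every query-split slide is used as a search query against the reference
#' split: its `k` nearest neighbours under Euclidean distance on the
#' selected feature dimensions are retrieved and vote on its primary
#' diagnosis. Search quality is the macro F1 of these predictions over the
#' diagnoses, the first objective of the feature-selection problem.
#'
#' @param table A feature-table tibble with assigned splits.
#' @param mask Binary 0/1 vector over the feature columns, or `NULL` for all
#'   features.
#' @param query_split,reference_split Split names (defaults: validation
#'   queried against train, as during optimisation; use test vs train for
#'   final reporting).
#' @param k Number of neighbours (default 3).
#' @return Macro F1 in \[0, 1\].
#' @export
search_f1 <- function(table, mask = NULL, query_split = "validation",
                      reference_split = "train", k = 3) {
  feats <- feature_names(table)
  mask <- .check_mask(mask, length(feats))
  ref <- table[!is.na(table$split) & table$split == reference_split, ]
  qry <- table[!is.na(table$split) & table$split == query_split, ]
  if (nrow(ref) == 0 || nrow(qry) == 0) abort("empty query or reference split")
  sel <- feats[mask == 1]
  pred <- knn_predict(as.matrix(ref[sel]), ref$diagnosis,
                      as.matrix(qry[sel]), k = k)
  precision_recall_f1(qry$diagnosis, pred)$macro_f1
}

#' Ratio of selected features
#'
#' The second objective: the fraction of feature dimensions a binary mask
#' retains, `sum(mask) / D`.
#'
#' @param mask Binary 0/1 vector.
#' @return A number in \[0, 1\].
#' @export
feature_ratio <- function(mask) {
  mask <- .check_mask(mask, length(mask), allow_empty = TRUE)
  sum(mask) / length(mask)
}

# One-vs-all linear SVM decision values; returns eval-rows x classes matrix.
.ovr_svm_decision <- function(train_x, train_labels, eval_x, cost) {
  classes <- sort(unique(train_labels))
  y <- match(train_labels, classes)
  W <- svc_ovr_fit(train_x, y, length(classes), cost)
  d <- nrow(W) - 1L
  dec <- eval_x %*% W[seq_len(d), , drop = FALSE] +
    matrix(W[d + 1L, ], nrow(eval_x), length(classes), byrow = TRUE)
  colnames(dec) <- classes
  dec
}

#' Site-bias indicator: institution-classification accuracy
#'
#' The third objective. A one-vs-all linear-kernel SVM is trained on the
#' training split, restricted to the selected feature dimensions, with the
#' source institution as the target; the returned value is the fraction of
#' evaluation-split slides whose institution is predicted correctly. High
#' values mean the selected features still leak acquisition-site signatures;
#' chance level (1 / number of sites for balanced sites) means the subset
#' carries no institutional signal the probe can exploit.
#'
#' @inheritParams search_f1
#' @param train_split,eval_split Split names.
#' @param cost SVM regularisation constant C (default 1).
#' @param standardize Standardise features to unit variance on the training
#'   split before fitting (default `FALSE`: features are used as-is).
#' @return Overall accuracy in \[0, 1\].
#' @export
site_accuracy <- function(table, mask = NULL, train_split = "train",
                          eval_split = "validation", cost = 1,
                          standardize = FALSE) {
  feats <- feature_names(table)
  mask <- .check_mask(mask, length(feats))
  tr <- table[!is.na(table$split) & table$split == train_split, ]
  ev <- table[!is.na(table$split) & table$split == eval_split, ]
  if (nrow(tr) == 0 || nrow(ev) == 0) abort("empty train or eval split")
  if (length(unique(tr$site)) < 2) {
    abort("site accuracy undefined: fewer than 2 sites in the training split")
  }
  sel <- feats[mask == 1]
  train_x <- as.matrix(tr[sel]); eval_x <- as.matrix(ev[sel])
  if (standardize) {
    s <- apply(train_x, 2, stats::sd)
    s[s == 0] <- 1
    train_x <- sweep(train_x, 2, s, "/")
    eval_x <- sweep(eval_x, 2, s, "/")
  }
  dec <- .ovr_svm_decision(train_x, tr$site, eval_x, cost)
  pred <- colnames(dec)[max.col(dec, ties.method = "first")]
  mean(pred == ev$site)
}

.check_mask <- function(mask, D, allow_empty = FALSE) {
  if (is.null(mask)) return(rep(1L, D))
  mask <- as.integer(mask)
  if (length(mask) != D) {
    abort(paste0("mask length ", length(mask),
                 " does not match feature count ", D))
  }
  if (!all(mask %in% c(0L, 1L))) abort("mask must be binary 0/1")
  if (!allow_empty && sum(mask) == 0) {
    abort("empty mask: no feature selected (see repair_empty_mask)")
  }
  mask
}

#' Optimiser configuration
#'
#' Bundles every setting of the evolutionary feature-selection run. Defaults
#' are the method's standard operating point (population 50, fitness budget
#' 512,000, k = 3 neighbours, linear SVM); operator rates and NSGA-III
#' details the method leaves open use standard values
#' (one-point crossover probability 0.9, per-bit mutation rate 1/D,
#' Das-Dennis reference points with 12 divisions, unbiased 0.5 initialisation
#' density).
#'
#' @param population_size Even integer >= 4 (default 50).
#' @param fitness_budget Total number of fitness evaluations (default
#'   512000; desk-scale runs use far less).
#' @param crossover_probability Probability a parent pair is recombined.
#' @param mutation_rate Per-bit flip probability; `NULL` means 1/D.
#' @param reference_divisions Das-Dennis divisions p (default 12, giving 91
#'   reference points for 3 objectives).
#' @param k_neighbors k of the retrieval evaluation (default 3).
#' @param svm_cost Linear SVM regularisation constant C (default 1).
#' @param svm_standardize Standardise features before the SVM probe.
#' @param init_density Probability a bit starts at 1 (default 0.5; sparse
#'   values such as 0.05 bias the search toward small subsets).
#' @param seed Integer seed; all run randomness derives from it.
#' @param query_split,reference_split Splits used by the fitness function.
#' @param normalization `"range"` (ideal-point shift and range division, the
#'   default) or `"hyperplane"` (canonical NSGA-III extreme-point intercepts).
#' @return A `moo_config` list.
#' @export
moo_config <- function(population_size = 50, fitness_budget = 512000,
                       crossover_probability = 0.9, mutation_rate = NULL,
                       reference_divisions = 12, k_neighbors = 3,
                       svm_cost = 1, svm_standardize = FALSE,
                       init_density = 0.5, seed = 1L,
                       query_split = "validation", reference_split = "train",
                       normalization = c("range", "hyperplane")) {
  if (population_size < 4 || population_size %% 2 != 0) {
    abort("population_size must be an even integer >= 4")
  }
  if (fitness_budget < population_size) {
    abort("fitness_budget must be at least population_size")
  }
  if (!is.null(mutation_rate) &&
      (mutation_rate < 0 || mutation_rate > 1)) {
    abort("mutation_rate must be in [0, 1]")
  }
  if (init_density <= 0 || init_density > 1) {
    abort("init_density must be in (0, 1]")
  }
  structure(list(
    population_size = as.integer(population_size),
    fitness_budget = as.integer(fitness_budget),
    crossover_probability = crossover_probability,
    mutation_rate = mutation_rate,
    reference_divisions = as.integer(reference_divisions),
    k_neighbors = as.integer(k_neighbors),
    svm_cost = svm_cost,
    svm_standardize = isTRUE(svm_standardize),
    init_density = init_density,
    seed = as.integer(seed),
    query_split = query_split,
    reference_split = reference_split,
    normalization = match.arg(normalization)
  ), class = "moo_config")
}

#' Evaluate the three objectives of a candidate mask
#'
#' Computes the objective vector in minimisation orientation:
#' `f1_loss = 1 - search_f1` (query split against reference split),
#' `f2_ratio = feature_ratio(mask)`, and `f3_site_acc = site_accuracy`
#' (trained on the reference split, evaluated on the query split). One call
#' consumes one unit of the fitness budget.
#'
#' @param table A feature-table tibble with assigned splits.
#' @param mask Binary 0/1 vector (non-empty; see [repair_empty_mask()]).
#' @param config A [moo_config()].
#' @return Named numeric vector `c(f1_loss, f2_ratio, f3_site_acc)`, each in
#'   \[0, 1\]. Deterministic: repeated calls agree exactly.
#' @export
evaluate_individual <- function(table, mask, config = moo_config()) {
  .make_evaluator(table, config)(mask)
}

# Precomputes the split matrices and label encodings once, returning a
# closure that evaluates one mask. run_nsga3() calls this once per run so
# the thousands of fitness calls skip the tibble subsetting.
.make_evaluator <- function(table, config) {
  feats <- feature_names(table)
  D <- length(feats)
  ref <- table[!is.na(table$split) & table$split == config$reference_split, ]
  qry <- table[!is.na(table$split) & table$split == config$query_split, ]
  if (nrow(ref) == 0 || nrow(qry) == 0) abort("empty query or reference split")
  if (length(unique(ref$site)) < 2) {
    abort("site accuracy undefined: fewer than 2 sites in the training split")
  }
  ref_x <- as.matrix(ref[feats]); qry_x <- as.matrix(qry[feats])
  diag_lev <- sort(unique(ref$diagnosis))
  ref_diag <- match(ref$diagnosis, diag_lev)
  qry_diag <- qry$diagnosis
  if (config$svm_standardize) {
    s <- apply(ref_x, 2, stats::sd)
    s[s == 0] <- 1
    svm_ref <- sweep(ref_x, 2, s, "/")
    svm_qry <- sweep(qry_x, 2, s, "/")
  } else {
    svm_ref <- ref_x; svm_qry <- qry_x
  }
  ref_site <- ref$site; qry_site <- qry$site
  k <- config$k_neighbors
  function(mask) {
    mask <- .check_mask(mask, D)
    sel <- which(mask == 1L)
    d2 <- .cross_dist2(qry_x[, sel, drop = FALSE],
                       ref_x[, sel, drop = FALSE])
    pred <- diag_lev[.knn_core(d2, ref_diag, length(diag_lev), k)]
    dec <- .ovr_svm_decision(svm_ref[, sel, drop = FALSE], ref_site,
                             svm_qry[, sel, drop = FALSE], config$svm_cost)
    site_pred <- colnames(dec)[max.col(dec, ties.method = "first")]
    c(f1_loss = 1 - .macro_f1(qry_diag, pred),
      f2_ratio = length(sel) / D,
      f3_site_acc = mean(site_pred == qry_site))
  }
}
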