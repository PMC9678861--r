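# Fixtures and independent oracles used across the suite. Oracles are
# deliberately written as plain, slow, straight-line code so they share no
# logic with the package implementations they check.

# A small deterministic feature table: two diagnoses separated on f1/f2,
# two sites separated on f3/f4, a noise dimension f5.
toy_table <- function(n_per_cell = 6, sep = 6, seed = 42) {
  withr::with_seed(seed, {
    grid <- expand.grid(diagnosis = c("DXa", "DXb"),
                        site = c("siteA", "siteB"),
                        rep = seq_len(n_per_cell),
                        stringsAsFactors = FALSE)
    n <- nrow(grid)
    X <- matrix(rnorm(n * 5), n, 5)
    X[, 1:2] <- X[, 1:2] + sep * (grid$diagnosis == "DXb")
    X[, 3:4] <- X[, 3:4] + sep * (grid$site == "siteB")
    tbl <- feature_table(X, sample_id = sprintf("s%03d", seq_len(n)),
                         diagnosis = grid$diagnosis, site = grid$site)
    split_dataset(tbl, c(0.5, 0.25, 0.25), seed = seed)
  })
}

# Brute-force macro F1 from explicitly counted confusion cells.
oracle_macro_f1 <- function(truth, pred) {
  classes <- sort(unique(truth))
  f1s <- numeric(0)
  for (cl in classes) {
    tp <- 0; fp <- 0; fn <- 0
    for (i in seq_along(truth)) {
      if (truth[i] == cl && pred[i] == cl) tp <- tp + 1
      if (truth[i] != cl && pred[i] == cl) fp <- fp + 1
      if (truth[i] == cl && pred[i] != cl) fn <- fn + 1
    }
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1s <- c(f1s, if (p + r > 0) 2 * p * r / (p + r) else 0)
  }
  mean(f1s)
}

# Exhaustive per-query distance sort with the package's voting rules.
oracle_knn <- function(train_x, train_labels, query_x, k) {
  out <- character(nrow(query_x))
  for (i in seq_len(nrow(query_x))) {
    d <- numeric(nrow(train_x))
    for (j in seq_len(nrow(train_x))) {
      d[j] <- sum((query_x[i, ] - train_x[j, ])^2)
    }
    nb <- order(d)[seq_len(k)]
    labs <- train_labels[nb]
    tab <- table(labs)
    top <- names(tab)[tab == max(tab)]
    out[i] <- if (length(top) == 1) top else labs[labs %in% top][1]
  }
  out
}

# O(N^2 M) dominance peeling straight from the definition: a candidate is
# in the current front iff no remaining candidate is no-worse everywhere
# and better somewhere; extract and repeat.
oracle_peel_fronts <- function(objs) {
  M <- ncol(objs)
  remaining <- seq_len(nrow(objs))
  fronts <- list()
  while (length(remaining) > 0) {
    sub <- objs[remaining, , drop = FALSE]
    nd <- vapply(seq_along(remaining), function(ii) {
      oi <- matrix(sub[ii, ], nrow(sub), M, byrow = TRUE)
      dominators <- rowSums(sub <= oi) == M & rowSums(sub < oi) > 0
      !any(dominators)
    }, logical(1))
    fronts[[length(fronts) + 1]] <- remaining[nd]
    remaining <- remaining[!nd]
  }
  fronts
}

# One-vs-all linear SVM built on e1071/libsvm: the independent probe.
oracle_ovr_svm_predict <- function(train_x, train_labels, eval_x, cost = 1) {
  classes <- sort(unique(train_labels))
  dec <- sapply(classes, function(cl) {
    y <- factor(train_labels == cl, levels = c(FALSE, TRUE))
    fit <- e1071::svm(train_x, y, kernel = "linear", cost = cost,
                      scale = FALSE)
    d <- attr(predict(fit, eval_x, decision.values = TRUE),
              "decision.values")[, 1]
    # orient decision values so positive means "this class"
    if (fit$labels[1] == 1) -d else d
  })
  classes[max.col(dec, ties.method = "first")]
}

small_benchmark_spec <- function(seed = 1) {
  synthetic_spec(diagnoses = paste0("DX", 1:3), sites = paste0("site", 1:4),
                 d_class = 6, d_site = 6, d_confounded = 4, d_noise = 16,
                 n_per_diagnosis_per_split = c(30, 12, 12),
                 confounding = 0.5, seed = seed)
}
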