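#' Pick the maximum-F1 solution from a Pareto front
#'
#' Selects the archived feature subset with the best validation search F1
#' (minimal `f1_loss`). Ties are broken by smaller feature ratio, then
#' smaller site accuracy, then lowest lexicographic mask order, so the pick
#' is deterministic.
#'
#' @param front Archive tibble from [run_nsga3()] (or any tibble with
#'   `f1_loss`, `f2_ratio`, `f3_site_acc`, `mask_bits` columns).
#' @return The selected row, a one-row tibble.
#' @export
pick_max_f1_solution <- function(front) {
  if (nrow(front) == 0) abort("empty Pareto front")
  front |>
    dplyr::arrange(.data$f1_loss, .data$f2_ratio, .data$f3_site_acc,
                   .data$mask_bits) |>
    dplyr::slice(1)
}

#' Final test-set evaluation of a feature subset
#'
#' The reporting protocol: test-split slides are used as search queries
#' against the train split, and the site probe is trained on the train split
#' and evaluated on the test split. Validation rows play no part.
#'
#' @param table A feature-table tibble with train and test splits.
#' @param mask Binary 0/1 vector over the feature columns.
#' @param k Number of retrieval neighbours (default 3).
#' @param cost SVM regularisation constant (default 1).
#' @return A one-row tibble: `search_f1`, `site_accuracy`, `n_selected`.
#' @export
evaluate_on_test <- function(table, mask, k = 3, cost = 1) {
  splits <- unique(table$split)
  if (!all(c("train", "test") %in% splits)) {
    abort("table needs train and test splits")
  }
  tibble::tibble(
    search_f1 = search_f1(table, mask, query_split = "test",
                          reference_split = "train", k = k),
    site_accuracy = site_accuracy(table, mask, train_split = "train",
                                  eval_split = "test", cost = cost),
    n_selected = sum(.check_mask(mask, length(mask)))
  )
}

#' Leave-one-out retrieval on an external cohort
#'
#' Validates a selected feature subset on slides from an institution that
#' took part in neither training nor optimisation: every external slide is
#' used as a query against all the other external slides, classified by the
#' k-NN voting rule on the masked features, and per-diagnosis F1 plus the
#' unweighted average are reported.
#'
#' @param table External feature-table tibble (splits are ignored; every row
#'   participates).
#' @param mask Binary 0/1 vector over the feature columns.
#' @param k Number of neighbours (default 3).
#' @return A `class_metrics` object (see [precision_recall_f1()]).
#' @export
external_validation <- function(table, mask = NULL, k = 3) {
  table <- validate_feature_table(table)
  feats <- feature_names(table)
  mask <- .check_mask(mask, length(feats))
  if (nrow(table) < k + 1) abort("external table needs at least k + 1 samples")
  small <- table(table$diagnosis)
  small <- names(small)[small <= k]
  if (length(small) > 0) {
    warning("class(es) with <= k samples, scored anyway: ",
            paste(small, collapse = ", "))
  }
  x <- as.matrix(table[feats[mask == 1]])
  d2 <- .cross_dist2(x, x)
  diag(d2) <- Inf                         # a query never retrieves itself
  labels <- table$diagnosis
  pred <- vapply(seq_len(nrow(x)), function(i) {
    nb <- order(d2[i, ])[seq_len(k)]
    labs <- labels[nb]
    counts <- table(labs)
    top <- names(counts)[counts == max(counts)]
    if (length(top) == 1) top else labs[labs %in% top][1]
  }, character(1))
  precision_recall_f1(labels, pred)
}

#' Two-sided Wilcoxon signed-rank test for paired replicates
#'
#' Used to judge whether selected-feature metrics differ from all-feature
#' metrics across optimisation replicates. Zero differences are dropped;
#' tied absolute differences receive mid-ranks. With at most 25 non-zero
#' differences the p-value is exact — the distribution of the rank sum over
#' all 2^n sign assignments, enumerated by convolution so rank ties are
#' honoured — and beyond that a normal approximation with continuity and
#' tie correction is used. With a single non-zero difference the exact
#' branch yields p = 1.
#'
#' @param paired_a,paired_b Equal-length numeric vectors (>= 5 pairs).
#' @return A one-row tibble: `statistic` (V, the positive-rank sum),
#'   `p_value`, `n_effective` (non-zero pairs), `method`.
#' @export
wilcoxon_compare <- function(paired_a, paired_b) {
  if (length(paired_a) != length(paired_b)) abort("unequal lengths")
  if (length(paired_a) < 5) abort("at least 5 pairs are required")
  d <- paired_a - paired_b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) abort("degenerate input: all paired differences are zero")
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= 25) {
    # exact distribution of V over all 2^n sign assignments, computed by
    # convolution over doubled mid-ranks (integers even with rank ties)
    r2 <- as.integer(round(2 * r))
    counts <- c(1, numeric(sum(r2)))       # counts[s + 1] = #patterns, sum s
    for (ri in r2) {
      shifted <- c(numeric(ri), counts[seq_len(length(counts) - ri)])
      counts <- counts + shifted
    }
    sums <- seq_along(counts) - 1
    v2 <- round(2 * v)
    total <- 2^n
    p <- 2 * min(sum(counts[sums <= v2]), sum(counts[sums >= v2])) / total
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (v - mu - 0.5 * sign(v - mu)) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation"
  }
  tibble::tibble(statistic = v, p_value = min(1, p),
                 n_effective = n, method = method)
}

#' Run the full per-tumour-type replicate experiment
#'
#' For every tumour type in the table (skipping, with a warning, types with
#' fewer than two diagnoses, on which diagnosis search is undefined) and
#' every replicate, runs [run_nsga3()] on the tumour-type row subset with
#' replicate seed `config$seed + replicate`, picks the max-F1 archive
#' solution and evaluates it on the test split. Results are serialised to
#' `output_dir` as one JSON file per (tumour type, replicate); existing
#' files are loaded instead of recomputed, so an interrupted experiment
#' resumes where it stopped. Serialised files contain no timestamps and are
#' byte-identical across reruns with the same config.
#'
#' @param table A feature-table tibble with assigned splits.
#' @param config A [moo_config()]; `config$seed` is the replicate base seed.
#' @param n_replicates Number of independent runs per tumour type
#'   (full-scale protocol: 31, reflecting the stochasticity of
#'   evolutionary runs).
#' @param output_dir Directory for result files, or `NULL` to keep results
#'   in memory only.
#' @return A list of `run_result` objects; see [render_report()].
#' @export
run_experiment <- function(table, config = moo_config(), n_replicates = 31,
                           output_dir = NULL) {
  table <- validate_feature_table(table)
  if (n_replicates < 1) abort("n_replicates must be >= 1")
  if (!is.null(output_dir)) {
    if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
    cfg <- unclass(config)
    cfg$mutation_rate <- if (is.null(cfg$mutation_rate)) "1/D" else
      cfg$mutation_rate
    cfg$n_replicates <- n_replicates
    cfg_path <- file.path(output_dir, "config.json")
    if (!file.exists(cfg_path)) {
      jsonlite::write_json(cfg, cfg_path, auto_unbox = TRUE, digits = NA)
    }
  }
  results <- list()
  for (type in unique(table$tumor_type)) {
    sub <- subset_by_tumor_type(table, type)
    if (length(unique(sub$diagnosis)) < 2) {
      warning("tumor type '", type,
              "' has a single diagnosis; skipped (search undefined)")
      next
    }
    D <- length(feature_names(sub))
    all_mask <- rep(1L, D)
    baseline <- evaluate_on_test(sub, all_mask, k = config$k_neighbors,
                                 cost = config$svm_cost)
    for (rep_i in seq_len(n_replicates)) {
      path <- if (is.null(output_dir)) NULL else
        file.path(output_dir, sprintf("%s_rep%03d.json", type, rep_i))
      if (!is.null(path) && file.exists(path)) {
        res <- .read_run_result(path)
      } else {
        rep_config <- config
        rep_config$seed <- config$seed + rep_i
        t0 <- proc.time()[["elapsed"]]
        run <- run_nsga3(sub, rep_config)
        elapsed <- proc.time()[["elapsed"]] - t0
        chosen <- pick_max_f1_solution(run$archive)
        test <- evaluate_on_test(sub, chosen$mask[[1]],
                                 k = config$k_neighbors,
                                 cost = config$svm_cost)
        res <- structure(list(
          tumor_type = type, replicate = rep_i, seed = rep_config$seed,
          archive = run$archive[c("mask_bits", "n_selected", "f1_loss",
                                  "f2_ratio", "f3_site_acc")],
          chosen_mask_bits = chosen$mask_bits,
          chosen_validation_f1 = chosen$search_f1,
          test = test, baseline = baseline,
          elapsed_seconds = elapsed
        ), class = "run_result")
        if (!is.null(path)) .write_run_result(res, path)
      }
      results[[length(results) + 1L]] <- res
    }
  }
  results
}

# Serialised run results are deterministic: elapsed wall time is kept only
# in memory, never written.
.write_run_result <- function(res, path) {
  payload <- res[setdiff(names(res), "elapsed_seconds")]
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

.read_run_result <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  payload$archive <- tibble::as_tibble(payload$archive)
  payload$test <- tibble::as_tibble(payload$test)
  payload$baseline <- tibble::as_tibble(payload$baseline)
  payload$elapsed_seconds <- NA_real_
  structure(payload, class = "run_result")
}

#' Decode a bitstring mask
#'
#' @param bits A string of `0`/`1` characters.
#' @return Integer 0/1 vector.
#' @export
mask_from_bits <- function(bits) {
  as.integer(strsplit(bits, "")[[1]])
}

#' Summarise an experiment: selected vs all features
#'
#' Aggregates [run_experiment()] results into the reporting table: for each
#' tumour type, the all-features test metrics next to the per-replicate
#' mean (and median) metrics of the picked max-F1 subsets, with two-sided
#' Wilcoxon signed-rank p-values comparing the selected-feature metric
#' against the all-features metric across replicates (computable once there
#' are at least 5 replicates). `significant_*` flags mark p < 0.05.
#'
#' @param results List of `run_result` objects from [run_experiment()].
#' @param output_dir Optional directory; if given, writes `report.csv` and a
#'   human-readable `report.txt`.
#' @return A tibble with one row per tumour type.
#' @export
render_report <- function(results, output_dir = NULL) {
  if (length(results) == 0) abort("no results to report")
  rows <- purrr::map_dfr(results, function(r) {
    tibble::tibble(
      tumor_type = r$tumor_type, replicate = r$replicate,
      search_f1 = r$test$search_f1, site_accuracy = r$test$site_accuracy,
      n_selected = r$test$n_selected,
      search_f1_all = r$baseline$search_f1,
      site_accuracy_all = r$baseline$site_accuracy)
  })
  report <- rows |>
    dplyr::group_by(.data$tumor_type) |>
    dplyr::summarise(
      n_replicates = dplyr::n(),
      site_accuracy_all = .data$site_accuracy_all[1],
      site_accuracy_selected = mean(.data$site_accuracy),
      search_f1_all = .data$search_f1_all[1],
      search_f1_selected = mean(.data$search_f1),
      n_selected_mean = mean(.data$n_selected),
      p_site = .maybe_wilcoxon(.data$site_accuracy, .data$site_accuracy_all),
      p_search = .maybe_wilcoxon(.data$search_f1, .data$search_f1_all),
      .groups = "drop") |>
    dplyr::mutate(
      significant_site = !is.na(.data$p_site) & .data$p_site < 0.05,
      significant_search = !is.na(.data$p_search) & .data$p_search < 0.05)
  if (!is.null(output_dir)) {
    if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
    readr::write_csv(report, file.path(output_dir, "report.csv"),
                     progress = FALSE)
    txt <- c("Evolutionary feature selection: selected vs all features", "",
             utils::capture.output(print(as.data.frame(report))))
    writeLines(txt, file.path(output_dir, "report.txt"))
  }
  report
}

.maybe_wilcoxon <- function(selected, all_features) {
  if (length(selected) < 5) return(NA_real_)
  tryCatch(wilcoxon_compare(selected, all_features)$p_value,
           error = function(e) NA_real_)
}
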