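make_front <- function(...) {
  rows <- list(...)
  tibble::tibble(
    mask_bits = vapply(rows, function(r) r$bits, character(1)),
    mask = lapply(rows, function(r) as.integer(strsplit(r$bits, "")[[1]])),
    n_selected = vapply(rows, function(r) sum(as.integer(strsplit(r$bits, "")[[1]])), numeric(1)),
    f1_loss = vapply(rows, function(r) r$o[1], numeric(1)),
    f2_ratio = vapply(rows, function(r) r$o[2], numeric(1)),
    f3_site_acc = vapply(rows, function(r) r$o[3], numeric(1)),
    search_f1 = 1 - vapply(rows, function(r) r$o[1], numeric(1)))
}

test_that("max-F1 picking follows the full tie-break chain", {
  single <- make_front(list(bits = "101", o = c(0.3, 0.6, 0.2)))
  expect_equal(pick_max_f1_solution(single)$mask_bits, "101")

  two <- make_front(list(bits = "111", o = c(0.2, 1, 0.5)),
                    list(bits = "100", o = c(0.1, 1 / 3, 0.6)))
  expect_equal(pick_max_f1_solution(two)$mask_bits, "100")

  # ties resolved by f2, then f3, then lexicographic mask order
  tied <- make_front(list(bits = "110", o = c(0.1, 2 / 3, 0.4)),
                     list(bits = "011", o = c(0.1, 2 / 3, 0.3)),
                     list(bits = "010", o = c(0.1, 1 / 3, 0.9)),
                     list(bits = "001", o = c(0.1, 1 / 3, 0.9)))
  expect_equal(pick_max_f1_solution(tied)$mask_bits, "001")

  # brute-force ordering oracle on a shuffled front
  withr::with_seed(13, {
    objs <- cbind(sample(c(0.1, 0.2), 20, TRUE),
                  sample(c(0.25, 0.5), 20, TRUE),
                  runif(20))
    bits <- vapply(1:20, function(i) {
      paste(sample(0:1, 8, TRUE), collapse = "")
    }, character(1))
  })
  front <- do.call(make_front, purrr::map(1:20, function(i) {
    list(bits = bits[i], o = objs[i, ])
  }))
  got <- pick_max_f1_solution(front)
  ord <- order(objs[, 1], objs[, 2], objs[, 3], bits)
  expect_equal(got$mask_bits, bits[ord[1]])
  expect_error(pick_max_f1_solution(front[0, ]), "empty")
})

test_that("test evaluation composes the objective calls on the test split", {
  gen <- generate_biased_dataset(small_benchmark_spec())
  tbl <- gen$table
  D <- length(feature_names(tbl))
  out <- evaluate_on_test(tbl, rep(1L, D))
  expect_equal(out$n_selected, D)
  expect_equal(out$search_f1,
               search_f1(tbl, query_split = "test", reference_split = "train"))
  expect_equal(out$site_accuracy,
               site_accuracy(tbl, train_split = "train", eval_split = "test"))
  expect_identical(out, evaluate_on_test(tbl, rep(1L, D)))
  no_test <- tbl[tbl$split != "test", ]
  expect_error(evaluate_on_test(no_test, rep(1L, D)), "test split")
})

test_that("external validation is leave-one-out and order invariant", {
  spec <- synthetic_spec(diagnoses = paste0("K", 1:3), sites = c("ext1", "ext2"),
                         d_class = 6, d_site = 2, d_confounded = 0,
                         d_noise = 8, class_effect = 5, confounding = 0,
                         n_per_diagnosis_per_split = c(20, 10, 10), seed = 77)
  ext <- generate_biased_dataset(spec)$table
  m <- external_validation(ext)
  expect_gt(m$macro_f1, 0.95)

  shuffled <- ext[withr::with_seed(3, sample(nrow(ext))), ]
  m2 <- external_validation(shuffled)
  expect_equal(m2$macro_f1, m$macro_f1)
  expect_equal(dplyr::arrange(tidy(m2), class), dplyr::arrange(tidy(m), class))
})

test_that("external validation equals a brute-force per-query sort", {
  gen <- generate_biased_dataset(small_benchmark_spec(seed = 8))
  ext <- gen$table[1:40, ]
  mask <- rep(1L, length(feature_names(ext)))
  m <- external_validation(ext, mask, k = 3)
  x <- as.matrix(ext[feature_names(ext)])
  pred <- character(nrow(x))
  for (i in seq_len(nrow(x))) {
    pred[i] <- oracle_knn(x[-i, , drop = FALSE], ext$diagnosis[-i],
                          x[i, , drop = FALSE], k = 3)
  }
  expect_equal(m$macro_f1, oracle_macro_f1(ext$diagnosis, pred))
})

test_that("a pure-noise mask scores near chance on external search", {
  f1s <- vapply(1:5, function(s) {
    spec <- synthetic_spec(diagnoses = c("K1", "K2"), sites = c("e1", "e2"),
                           d_class = 4, d_site = 0, d_confounded = 0,
                           d_noise = 12, confounding = 0,
                           n_per_diagnosis_per_split = c(40, 20, 20),
                           seed = 600 + s)
    gen <- generate_biased_dataset(spec)
    noise_mask <- as.integer(gen$truth$role == "noise")
    external_validation(gen$table, noise_mask)$macro_f1
  }, numeric(1))
  expect_lt(abs(median(f1s) - 0.5), 0.15)
})

test_that("external validation warns on classes too small for k", {
  tbl <- toy_table()
  tiny <- tbl[c(which(tbl$diagnosis == "DXa"), which(tbl$diagnosis == "DXb")[1:2]), ]
  expect_warning(external_validation(tiny, k = 3), "<= k")
})

test_that("wilcoxon test is exact on the all-positive-shift case", {
  a <- 1:10 + 0.5
  b <- 1:10 - 0.5
  out <- wilcoxon_compare(a, b)
  expect_equal(out$p_value, 2 / 2^10)
  expect_equal(out$statistic, 55)
  expect_equal(out$method, "exact")
})

test_that("a single non-zero difference yields p = 1", {
  a <- c(1, 2, 3, 4, 5)
  b <- c(1, 2, 3, 4, 5.7)
  out <- wilcoxon_compare(a, b)
  expect_equal(out$n_effective, 1)
  expect_equal(out$p_value, 1)
  expect_error(wilcoxon_compare(a, a), "all paired differences are zero")
})

test_that("wilcoxon p-values match the reference implementation", {
  withr::with_seed(61, {
    for (trial in 1:100) {
      n <- sample(6:30, 1)
      a <- rnorm(n)
      b <- rnorm(n)
      ours <- wilcoxon_compare(a, b)
      ref <- suppressWarnings(
        stats::wilcox.test(a, b, paired = TRUE,
                           exact = ours$method == "exact",
                           correct = TRUE))
      expect_lt(abs(ours$p_value - ref$p.value), 1e-6)
      expect_equal(ours$statistic, unname(ref$statistic))
    }
  })
})

test_that("experiments run per tumour type with distinct replicate seeds", {
  gen <- generate_biased_dataset(small_benchmark_spec(seed = 12))
  tbl <- gen$table
  cfg <- moo_config(population_size = 6, fitness_budget = 18, seed = 40,
                    reference_divisions = 3)
  out_dir <- withr::local_tempdir()
  res <- run_experiment(tbl, cfg, n_replicates = 2, output_dir = out_dir)
  expect_length(res, 2)
  expect_equal(vapply(res, function(r) r$seed, numeric(1)), c(41, 42))
  expect_equal(vapply(res, function(r) r$replicate, numeric(1)), c(1, 2))
  files <- list.files(out_dir, pattern = "_rep[0-9]+\\.json$")
  expect_length(files, 2)
  expect_true(file.exists(file.path(out_dir, "config.json")))

  # resume: result files are loaded, not recomputed
  before <- file.mtime(file.path(out_dir, files))
  Sys.sleep(1.1)
  res2 <- run_experiment(tbl, cfg, n_replicates = 2, output_dir = out_dir)
  expect_identical(file.mtime(file.path(out_dir, files)), before)
  expect_equal(res2[[1]]$archive, res[[1]]$archive, tolerance = 1e-12)

  # archives are mutually non-dominated
  for (r in res) {
    objs <- as.matrix(r$archive[c("f1_loss", "f2_ratio", "f3_site_acc")])
    expect_length(oracle_peel_fronts(objs), 1)
  }
})

test_that("single-diagnosis tumour types are skipped with a warning", {
  gen <- generate_biased_dataset(small_benchmark_spec(seed = 12))
  tbl <- gen$table
  solo <- tbl[tbl$diagnosis == "DX1", ]
  solo$tumor_type <- "solo"
  both <- dplyr::bind_rows(tbl, dplyr::mutate(solo, sample_id = paste0("x", sample_id)))
  cfg <- moo_config(population_size = 6, fitness_budget = 6, seed = 40,
                    reference_divisions = 3)
  expect_warning(res <- run_experiment(both, cfg, n_replicates = 1),
                 "single diagnosis")
  expect_equal(unique(vapply(res, function(r) r$tumor_type, character(1))),
               "synthetic")
})

test_that("the report aggregates replicate metrics correctly", {
  gen <- generate_biased_dataset(small_benchmark_spec(seed = 12))
  cfg <- moo_config(population_size = 6, fitness_budget = 18, seed = 40,
                    reference_divisions = 3)
  res <- run_experiment(gen$table, cfg, n_replicates = 3)
  rep_tbl <- render_report(res)
  expect_equal(nrow(rep_tbl), 1)
  expect_equal(rep_tbl$n_replicates, 3)
  f1s <- vapply(res, function(r) r$test$search_f1, numeric(1))
  expect_equal(rep_tbl$search_f1_selected, mean(f1s))
  expect_equal(rep_tbl$site_accuracy_all, res[[1]]$baseline$site_accuracy)
  expect_true(is.na(rep_tbl$p_site))   # < 5 replicates: no test

  out_dir <- withr::local_tempdir()
  render_report(res, out_dir)
  expect_true(file.exists(file.path(out_dir, "report.csv")))
  expect_true(file.exists(file.path(out_dir, "report.txt")))
})
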