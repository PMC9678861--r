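#' @useDynLib slidesieve, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang .data abort
#' @importFrom stats setNames
NULL

# Reserved label columns of a feature table; every other column is a feature
# dimension, in file/column order.
.reserved_cols <- c("sample_id", "diagnosis", "site", "tumor_type", "split")

.split_levels <- c("train", "validation", "test")

#' Construct a feature table
#'
#' A feature table is a tibble with one row per whole-slide image (WSI): the
#' label columns `sample_id`, `diagnosis` (primary diagnosis / cancer
#' subtype), `site` (source institution), `tumor_type` (organ-level grouping)
#' and `split` (`train`, `validation` or `test`), followed by one numeric
#' column per deep-feature dimension. All user-facing functions in slidesieve
#' take such a tibble as their first argument.
#'
#' @param x Numeric matrix (samples x features) or data frame of features.
#'   Column names are kept; unnamed columns are named `f0001`, `f0002`, ...
#' @param sample_id Character vector of unique sample identifiers.
#' @param diagnosis,site Character vectors of per-sample labels.
#' @param tumor_type Character vector of per-sample tumour-type groups
#'   (defaults to a single group).
#' @param split Character vector in `c("train", "validation", "test")`, or
#'   `NA` to leave unassigned (see [split_dataset()]).
#' @return A validated feature-table tibble.
#' @seealso [validate_feature_table()], [read_feature_table()]
#' @export
feature_table <- function(x, sample_id, diagnosis, site,
                          tumor_type = "all", split = NA_character_) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(colnames(x))) {
    colnames(x) <- sprintf("f%04d", seq_len(ncol(x)))
  }
  tbl <- tibble::tibble(
    sample_id = as.character(sample_id),
    diagnosis = as.character(diagnosis),
    site = as.character(site),
    tumor_type = rep_len(as.character(tumor_type), nrow(x)),
    split = rep_len(as.character(split), nrow(x))
  )
  tbl <- dplyr::bind_cols(tbl, tibble::as_tibble(x))
  validate_feature_table(tbl)
}

#' Validate a feature table
#'
#' Checks the feature-table contract: the five reserved label columns are
#' present, sample ids are unique, every feature column is numeric and
#' finite, split values are `train`/`validation`/`test` (or `NA`), and no
#' label is missing.
#'
#' @param table A feature-table tibble.
#' @return The table, invisibly coerced to a tibble, if valid; otherwise an
#'   error describing the first violation found.
#' @export
validate_feature_table <- function(table) {
  table <- tibble::as_tibble(table)
  missing_cols <- setdiff(.reserved_cols, names(table))
  if (length(missing_cols) > 0) {
    abort(paste0("feature table is missing label column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  feats <- feature_names(table)
  if (length(feats) == 0) abort("feature table has no feature columns")
  if (anyDuplicated(table$sample_id)) {
    dup <- table$sample_id[duplicated(table$sample_id)][1]
    abort(paste0("duplicate sample_id: '", dup, "'"))
  }
  for (col in .reserved_cols[1:4]) {
    if (anyNA(table[[col]])) abort(paste0("missing values in '", col, "'"))
  }
  bad_split <- !is.na(table$split) & !table$split %in% .split_levels
  if (any(bad_split)) {
    abort(paste0("invalid split value '", table$split[bad_split][1],
                 "' (expected train/validation/test)"))
  }
  for (col in feats) {
    v <- table[[col]]
    if (!is.numeric(v)) {
      abort(paste0("feature column '", col, "' is not numeric"))
    }
    if (!all(is.finite(v))) {
      abort(paste0("non-finite value in feature column '", col,
                   "', row ", which(!is.finite(v))[1]))
    }
  }
  table
}

#' Feature column names of a feature table
#'
#' @param table A feature-table tibble.
#' @return Character vector of feature column names, in column order.
#' @export
feature_names <- function(table) {
  setdiff(names(table), .reserved_cols)
}

#' Extract the numeric feature matrix
#'
#' @param table A feature-table tibble.
#' @param split Optional split name; if given, only rows of that split.
#' @return A numeric matrix (samples x features) with sample ids as row
#'   names.
#' @export
feature_matrix <- function(table, split = NULL) {
  if (!is.null(split)) table <- table[!is.na(table$split) & table$split == split, ]
  m <- as.matrix(table[feature_names(table)])
  storage.mode(m) <- "double"
  rownames(m) <- table$sample_id
  m
}

#' Read a feature table from disk
#'
#' Two on-disk formats are supported. `delimited` is UTF-8 CSV with a
#' mandatory header; the columns `sample_id`, `diagnosis`, `site`,
#' `tumor_type` and `split` are reserved and every remaining column is a
#' feature dimension, in file order. `binary` is an Arrow/Feather (IPC) file
#' carrying the same columns plus a self-describing JSON metadata block
#' (format version, feature column names, free-text provenance).
#'
#' @param path File path.
#' @param format `"auto"` (by file extension: `.csv` vs `.feather`/`.arrow`),
#'   `"delimited"` or `"binary"`.
#' @return A validated feature-table tibble; feature column order is the file
#'   column order.
#' @export
read_feature_table <- function(path, format = c("auto", "delimited", "binary")) {
  format <- .resolve_format(match.arg(format), path)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (format == "delimited") {
    tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                           col_types = readr::cols(
                             sample_id = readr::col_character(),
                             diagnosis = readr::col_character(),
                             site = readr::col_character(),
                             tumor_type = readr::col_character(),
                             split = readr::col_character(),
                             .default = readr::col_double()
                           ))
  } else {
    tbl <- tibble::as_tibble(arrow::read_feather(path))
    tbl$sample_id <- as.character(tbl$sample_id)
  }
  validate_feature_table(tbl)
}

#' Write a feature table to disk
#'
#' Inverse of [read_feature_table()]: `read(write(t))` reproduces `t`
#' bit-exactly on the binary format and within numeric text precision
#' (17 significant digits, i.e. double round-trip) on the delimited format.
#'
#' @param table A valid feature-table tibble.
#' @param path Destination file path.
#' @param format See [read_feature_table()].
#' @param provenance Free-text provenance string stored in the binary
#'   format's metadata block (e.g. the feature extractor used).
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path,
                                format = c("auto", "delimited", "binary"),
                                provenance = "") {
  table <- validate_feature_table(table)
  format <- .resolve_format(match.arg(format), path)
  if (format == "delimited") {
    out <- table
    for (col in feature_names(out)) {
      out[[col]] <- sprintf("%.17g", out[[col]])
    }
    readr::write_csv(out, path, progress = FALSE)
  } else {
    at <- arrow::as_arrow_table(table)
    at$metadata$slidesieve <- jsonlite::toJSON(list(
      format_version = "1",
      feature_columns = feature_names(table),
      provenance = provenance
    ), auto_unbox = TRUE)
    arrow::write_feather(at, path)
  }
  invisible(path)
}

.resolve_format <- function(format, path) {
  if (format != "auto") return(format)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("csv", "tsv", "txt")) return("delimited")
  if (ext %in% c("feather", "arrow", "ipc")) return("binary")
  abort(paste0("cannot infer format from extension '.", ext,
               "'; pass format = \"delimited\" or \"binary\""))
}

#' Aggregate patch features into a whole-slide representation (MFV)
#'
#' A WSI is scanned as a set of tissue patches, each described by a deep
#' feature vector (e.g. 135 patches of 1024 KimiaNet features). The mean of
#' feature vectors (MFV) over all patches is used as the slide-level
#' representation.
#'
#' @param x A patches x features numeric matrix for one WSI, or a data frame
#'   of patch rows with a `wsi_id` column identifying the slide each patch
#'   belongs to.
#' @param ... Unused.
#' @return For a matrix: a named numeric vector of per-dimension means. For a
#'   data frame: a tibble with one row per `wsi_id` and the per-slide means.
#' @export
aggregate_mfv <- function(x, ...) UseMethod("aggregate_mfv")

#' @rdname aggregate_mfv
#' @export
aggregate_mfv.matrix <- function(x, ...) {
  if (nrow(x) < 1 || ncol(x) < 1) abort("patch set must be at least 1 x 1")
  if (!all(is.finite(x))) abort("non-finite value in patch features")
  colMeans(x)
}

#' @rdname aggregate_mfv
#' @export
aggregate_mfv.data.frame <- function(x, ...) {
  if (!"wsi_id" %in% names(x)) abort("patch data frame needs a 'wsi_id' column")
  x |>
    dplyr::group_by(.data$wsi_id) |>
    dplyr::summarise(dplyr::across(dplyr::where(is.numeric), mean),
                     .groups = "drop")
}

#' Drop rare metadata groups
#'
#' Slide-level metadata records are grouped by the combination of
#' `morphology`, `primary_diagnosis` and `tissue_or_organ`; groups with fewer
#' than `min_count` members are removed so every surviving group can populate
#' all data splits. Record order is preserved.
#'
#' @param records A data frame of metadata records.
#' @param min_count Minimum group size to survive (default 20).
#' @param group_cols Grouping key columns.
#' @return The surviving records, original order preserved.
#' @export
filter_rare_groups <- function(records, min_count = 20,
                               group_cols = c("morphology",
                                              "primary_diagnosis",
                                              "tissue_or_organ")) {
  if (min_count < 1) abort("min_count must be >= 1")
  records <- tibble::as_tibble(records)
  missing_cols <- setdiff(group_cols, names(records))
  if (length(missing_cols) > 0) {
    abort(paste0("missing grouping column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  for (col in group_cols) {
    v <- records[[col]]
    if (anyNA(v) || any(!nzchar(as.character(v)))) {
      abort(paste0("empty or missing value in grouping column '", col, "'"))
    }
  }
  key <- do.call(paste, c(lapply(group_cols, function(c) records[[c]]),
                          sep = "\r"))
  counts <- table(key)
  records[counts[key] >= min_count, ]
}

#' Restrict a feature table to one tumour type
#'
#' Feature selection is run as independent per-tumour-type optimisation
#' problems; this restricts the rows to one tumour type, leaving feature
#' columns and split assignments untouched.
#'
#' @param table A feature-table tibble.
#' @param tumor_type A tumour-type label present in `table`.
#' @return The row subset, a feature-table tibble.
#' @export
subset_by_tumor_type <- function(table, tumor_type) {
  table <- validate_feature_table(table)
  if (!tumor_type %in% table$tumor_type) {
    abort(paste0("unknown tumor_type '", tumor_type, "'"))
  }
  table[table$tumor_type == tumor_type, ]
}

#' Assign train/validation/test splits, stratified by diagnosis
#'
#' Used when a table arrives without a split assignment (synthetic data or
#' external cohorts). Per-diagnosis split proportions match the target
#' fractions within one sample; assignment is deterministic given `seed`.
#' Stratification is on diagnosis only — never on site, so the site
#' confounder keeps its natural, possibly skewed, distribution across
#' splits.
#'
#' @param table A feature-table tibble.
#' @param fractions Numeric length-3 `(train, validation, test)`, positive or
#'   zero, summing to 1.
#' @param seed Integer seed.
#' @return The table with its `split` column assigned.
#' @export
split_dataset <- function(table, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  table <- validate_feature_table(table)
  if (length(fractions) != 3 || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-9) {
    abort("fractions must be 3 non-negative numbers summing to 1")
  }
  n_splits <- sum(fractions > 0)
  split <- character(nrow(table))
  withr::with_seed(seed, {
    for (diag in unique(table$diagnosis)) {
      idx <- which(table$diagnosis == diag)
      n <- length(idx)
      if (n < n_splits) {
        abort(paste0("diagnosis '", diag, "' has ", n,
                     " sample(s), fewer than the ", n_splits,
                     " requested splits"))
      }
      counts <- .apportion(n, fractions)
      lab <- rep(.split_levels, counts)
      split[idx] <- sample(lab)
    }
  })
  table$split <- split
  table
}

# Largest-remainder apportionment of n samples to the three splits; every
# positive fraction gets at least one sample.
.apportion <- function(n, fractions) {
  target <- n * fractions
  counts <- floor(target)
  counts[fractions > 0 & counts == 0] <- 1
  while (sum(counts) > n) {
    # only possible when the at-least-one rule overshot
    i <- which.max(counts - target)
    counts[i] <- counts[i] - 1
  }
  while (sum(counts) < n) {
    rem <- target - counts
    rem[fractions == 0] <- -Inf
    i <- which.max(rem)
    counts[i] <- counts[i] + 1
  }
  as.integer(counts)
}
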