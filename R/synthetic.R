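#' Specification of a synthetic site-confounded feature benchmark
#'
#' Describes a feature table with four planted kinds of dimensions:
#' class-informative (diagnosis signal only), site-informative (acquisition
#' site signal only — the bias), confounded (both signals added) and pure
#' noise. The generator also controls how unevenly diagnoses are distributed
#' across sites (`confounding`), emulating cohorts where each hospital
#' contributes mostly one cancer subtype so that site shortcuts masquerade
#' as diagnostic signal.
#'
#' Defaults define the package's desk-scale benchmark: 128 dimensions
#' (16 class, 16 site, 8 confounded, 88 noise), 4 diagnoses, 6 sites,
#' centroid separations of 2 noise standard deviations, confounding 0.6 and
#' 60/20/20 samples per diagnosis per split.
#'
#' @param diagnoses Character vector of diagnosis labels (>= 2).
#' @param sites Character vector of site labels (>= 2).
#' @param d_class,d_site,d_confounded,d_noise Dimension counts per role.
#' @param class_effect,site_effect Mean centroid separation per informative
#'   dimension, in units of `noise_sd`: within a block of d dimensions,
#'   every pair of centroids is `effect * sqrt(d)` apart (and so never
#'   closer than `effect`).
#' @param confounding In \[0, 1\]: 0 = sites independent of diagnosis, 1 =
#'   each diagnosis concentrated on its own disjoint block of sites.
#' @param n_per_diagnosis_per_split Integer length-3
#'   `(train, validation, test)` sample counts per diagnosis.
#' @param noise_sd Feature noise standard deviation.
#' @param seed Integer seed; the whole table is deterministic given it.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(diagnoses = paste0("DX", 1:4),
                           sites = paste0("site", 1:6),
                           d_class = 16, d_site = 16, d_confounded = 8,
                           d_noise = 88,
                           class_effect = 2, site_effect = 2,
                           confounding = 0.6,
                           n_per_diagnosis_per_split = c(60, 20, 20),
                           noise_sd = 1, seed = 1L) {
  if (length(diagnoses) < 2 || length(sites) < 2) {
    abort("at least 2 diagnoses and 2 sites are required")
  }
  counts <- c(d_class, d_site, d_confounded, d_noise)
  if (any(counts < 0) || sum(counts) < 1) {
    abort("dimension counts must be non-negative and sum to >= 1")
  }
  if (confounding < 0 || confounding > 1) abort("confounding must be in [0, 1]")
  if (confounding == 1 && length(diagnoses) > length(sites)) {
    abort(paste0("confounding = 1 needs at least as many sites as diagnoses",
                 " (disjoint site blocks are impossible otherwise)"))
  }
  if (length(n_per_diagnosis_per_split) != 3 ||
      any(n_per_diagnosis_per_split < 0) ||
      sum(n_per_diagnosis_per_split) < 1) {
    abort("n_per_diagnosis_per_split must be 3 non-negative counts")
  }
  if (noise_sd <= 0) abort("noise_sd must be positive")
  structure(list(
    diagnoses = as.character(diagnoses), sites = as.character(sites),
    d_class = as.integer(d_class), d_site = as.integer(d_site),
    d_confounded = as.integer(d_confounded), d_noise = as.integer(d_noise),
    class_effect = class_effect, site_effect = site_effect,
    confounding = confounding,
    n_per_diagnosis_per_split = as.integer(n_per_diagnosis_per_split),
    noise_sd = noise_sd, seed = as.integer(seed)
  ), class = "synthetic_spec")
}

# k centroids in d dimensions: an orthonormal frame (QR of a Gaussian
# matrix) scaled so every pair of centroids sits sep_per_dim * sqrt(d)
# apart — a mean separation of sep_per_dim per dimension of the block, and
# never less than sep_per_dim in total.
.separated_centroids <- function(k, d, sep_per_dim, what) {
  if (k > d) {
    abort(paste0(what, " dimensions (", d, ") must be >= number of ",
                 what, " centroids (", k, ")"))
  }
  g <- matrix(stats::rnorm(d * k), d, k)
  q <- qr.Q(qr(g))[, seq_len(k), drop = FALSE]   # orthonormal columns
  t(q) * sep_per_dim * sqrt(d / 2) / sqrt(2)
}

#' Generate a site-confounded synthetic feature table with ground truth
#'
#' Sites are drawn per sample from a diagnosis-conditional distribution: a
#' `(1 - confounding)`-weighted uniform mixture with a block distribution
#' that concentrates each diagnosis on its own subset of sites. Each feature
#' is Gaussian around a centroid that depends on the diagnosis (class
#' dimensions), the site (site dimensions), both added (confounded
#' dimensions) or neither (noise dimensions); centroid frames are drawn once
#' per spec with pairwise separation equal to the configured effect sizes.
#' Splits are assigned exactly per diagnosis with the configured counts.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `table` (a feature-table tibble) and `truth` (a
#'   tibble with one row per dimension: `dimension`, `feature`, `role`).
#' @export
generate_biased_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n_diag <- length(spec$diagnoses); n_site <- length(spec$sites)
  D <- spec$d_class + spec$d_site + spec$d_confounded + spec$d_noise
  n_per_diag <- sum(spec$n_per_diagnosis_per_split)
  roles <- rep(c("class", "site", "confounded", "noise"),
               c(spec$d_class, spec$d_site, spec$d_confounded, spec$d_noise))

  # diagnosis-conditional site distributions
  block <- matrix(0, n_diag, n_site)
  for (i in seq_len(n_diag)) {
    mine <- which((seq_len(n_site) - 1) %% n_diag == (i - 1))
    block[i, mine] <- 1 / length(mine)
  }
  site_probs <- (1 - spec$confounding) / n_site + spec$confounding * block

  withr::with_seed(spec$seed, {
    mu_class <- if (spec$d_class > 0)
      .separated_centroids(n_diag, spec$d_class,
                           spec$class_effect * spec$noise_sd, "class")
    mu_site <- if (spec$d_site > 0)
      .separated_centroids(n_site, spec$d_site,
                           spec$site_effect * spec$noise_sd, "site")
    mu_conf_class <- if (spec$d_confounded > 0)
      .separated_centroids(n_diag, spec$d_confounded,
                           spec$class_effect * spec$noise_sd, "class")
    mu_conf_site <- if (spec$d_confounded > 0)
      .separated_centroids(n_site, spec$d_confounded,
                           spec$site_effect * spec$noise_sd, "site")

    diagnosis <- rep(spec$diagnoses, each = n_per_diag)
    n <- length(diagnosis)
    site <- character(n)
    split <- character(n)
    for (i in seq_len(n_diag)) {
      idx <- which(diagnosis == spec$diagnoses[i])
      site[idx] <- sample(spec$sites, n_per_diag, replace = TRUE,
                          prob = site_probs[i, ])
      split[idx] <- sample(rep(c("train", "validation", "test"),
                               spec$n_per_diagnosis_per_split))
    }

    mu <- matrix(0, n, D)
    di <- match(diagnosis, spec$diagnoses)
    si <- match(site, spec$sites)
    if (spec$d_class > 0) {
      mu[, roles == "class"] <- mu_class[di, , drop = FALSE]
    }
    if (spec$d_site > 0) {
      mu[, roles == "site"] <- mu_site[si, , drop = FALSE]
    }
    if (spec$d_confounded > 0) {
      mu[, roles == "confounded"] <-
        mu_conf_class[di, , drop = FALSE] + mu_conf_site[si, , drop = FALSE]
    }
    X <- mu + matrix(stats::rnorm(n * D, sd = spec$noise_sd), n, D)
  })

  colnames(X) <- sprintf("f%04d", seq_len(D))
  table <- feature_table(X,
                         sample_id = sprintf("wsi%05d", seq_len(nrow(X))),
                         diagnosis = diagnosis, site = site,
                         tumor_type = "synthetic", split = split)
  truth <- tibble::tibble(dimension = seq_len(D),
                          feature = colnames(X), role = roles)
  list(table = table, truth = truth)
}

#' Selected-feature composition against planted ground truth
#'
#' For a candidate mask and a generator ground truth, reports per dimension
#' role how much of the role was selected (`fraction_selected` =
#' selected-in-role / role size) and how much of the mask each role makes up
#' (`fraction_of_mask` = selected-in-role / total selected). Recovery of the
#' planted structure shows as high class fractions and near-zero site
#' fractions.
#'
#' @param mask Binary 0/1 vector of length D.
#' @param truth Ground-truth tibble from [generate_biased_dataset()].
#' @return A tibble with one row per role present in `truth`.
#' @export
ground_truth_report <- function(mask, truth) {
  if (length(mask) != nrow(truth)) {
    abort("mask length does not match the number of dimensions in truth")
  }
  mask <- .check_mask(mask, length(mask), allow_empty = TRUE)
  total <- sum(mask)
  truth |>
    dplyr::mutate(selected = mask == 1) |>
    dplyr::group_by(.data$role) |>
    dplyr::summarise(n_dims = dplyr::n(),
                     n_selected = sum(.data$selected), .groups = "drop") |>
    dplyr::mutate(
      fraction_selected = .data$n_selected / .data$n_dims,
      fraction_of_mask = if (total == 0) 0 else .data$n_selected / total)
}
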