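#' Pareto dominance (all-minimisation)
#'
#' `a` dominates `b` iff `a` is no worse in every objective and strictly
#' better in at least one.
#'
#' @param a,b Numeric objective vectors of equal length.
#' @return Logical scalar.
#' @export
dominates <- function(a, b) {
  if (length(a) != length(b)) abort("objective vectors differ in length")
  all(a <= b) && any(a < b)
}

# Pairwise domination matrix: dom[i, j] is TRUE iff row i dominates row j.
.domination_matrix <- function(objs) {
  n <- nrow(objs)
  dom <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    oi <- matrix(objs[i, ], n, ncol(objs), byrow = TRUE)
    dom[i, ] <- rowSums(oi <= objs) == ncol(objs) & rowSums(oi < objs) > 0
  }
  dom
}

#' Fast non-dominated sorting
#'
#' Partitions a set of objective vectors into successive non-dominated
#' fronts: front 1 holds all non-dominated vectors, front r the vectors that
#' become non-dominated once fronts below r are removed.
#'
#' @param objs Numeric matrix, one row per individual, one column per
#'   objective, minimisation orientation.
#' @return List with `fronts` (list of integer row-index vectors) and `rank`
#'   (integer vector, 1-based front index per row).
#' @export
fast_nondominated_sort <- function(objs) {
  objs <- as.matrix(objs)
  if (any(!is.finite(objs))) abort("unevaluated or non-finite objectives")
  n <- nrow(objs)
  dom <- .domination_matrix(objs)
  n_dominators <- colSums(dom)
  rank <- integer(n)
  fronts <- list()
  current <- which(n_dominators == 0)
  r <- 0L
  while (length(current) > 0) {
    r <- r + 1L
    rank[current] <- r
    fronts[[r]] <- current
    released <- integer(0)
    for (i in current) {
      dominated <- which(dom[i, ])
      n_dominators[dominated] <- n_dominators[dominated] - 1L
      released <- c(released, dominated[n_dominators[dominated] == 0L])
    }
    current <- sort(unique(released))
  }
  list(fronts = fronts, rank = rank)
}

#' Das-Dennis reference points on the unit simplex
#'
#' All points whose coordinates are `j / divisions` for non-negative
#' integers `j` summing to `divisions`: the canonical structured reference
#' set of NSGA-III, `choose(divisions + M - 1, M - 1)` points for `M`
#' objectives.
#'
#' @param n_obj Number of objectives M (default 3).
#' @param divisions Number of divisions p along each axis (default 12, 91
#'   points for M = 3).
#' @return Matrix with `choose(divisions + n_obj - 1, n_obj - 1)` rows, each
#'   non-negative and summing to 1.
#' @export
generate_reference_points <- function(n_obj = 3, divisions = 12) {
  if (divisions < 1) abort("divisions must be >= 1")
  recurse <- function(m, left) {
    if (m == 1) return(matrix(left, 1, 1))
    do.call(rbind, lapply(0:left, function(j) {
      cbind(j, recurse(m - 1, left - j))
    }))
  }
  pts <- recurse(n_obj, divisions) / divisions
  dimnames(pts) <- NULL
  pts
}

#' Normalise objective vectors to the unit range
#'
#' Shifts each component by the ideal point (component-wise minimum over the
#' set) and divides by the component range; zero ranges are replaced by 1.
#' With `method = "hyperplane"` the divisor is instead the axis intercept of
#' the hyperplane through the extreme points (canonical NSGA-III), falling
#' back to the range when the hyperplane is degenerate.
#'
#' @param objs Numeric matrix of objective vectors (rows).
#' @param method `"range"` (default) or `"hyperplane"`.
#' @return Matrix of the same shape with the ideal at the origin.
#' @export
normalize_objectives <- function(objs, method = c("range", "hyperplane")) {
  method <- match.arg(method)
  objs <- as.matrix(objs)
  ideal <- apply(objs, 2, min)
  shifted <- sweep(objs, 2, ideal)
  denom <- apply(shifted, 2, max)
  if (method == "hyperplane" && nrow(objs) >= ncol(objs)) {
    m <- ncol(objs)
    # extreme point per axis: minimiser of the achievement scalarizing
    # function along that axis
    eps <- 1e-6
    extremes <- t(vapply(seq_len(m), function(j) {
      w <- rep(eps, m); w[j] <- 1
      asf <- apply(sweep(shifted, 2, w, "/"), 1, max)
      shifted[which.min(asf), ]
    }, numeric(m)))
    intercepts <- tryCatch({
      b <- solve(extremes, rep(1, m))
      ic <- 1 / b
      if (any(!is.finite(ic)) || any(ic <= 0)) denom else ic
    }, error = function(e) denom)
    denom <- intercepts
  }
  denom[denom <= 0] <- 1
  sweep(shifted, 2, denom, "/")
}

# Perpendicular distance from each normalized point (rows of z) to the line
# through the origin and each reference point (rows of r).
.perp_dist <- function(z, r) {
  rn <- r / sqrt(rowSums(r^2))
  proj <- z %*% t(rn)                     # points x refs scalar projections
  z2 <- rowSums(z^2)
  d2 <- outer(z2, rep(1, nrow(r))) - proj^2
  d2[d2 < 0] <- 0
  sqrt(d2)
}

#' NSGA-III environmental selection: association and niching
#'
#' Admits whole fronts in rank order until the next front would overflow the
#' target size, then fills the remainder from the splitting front by
#' reference-point niching: every candidate is associated with its nearest
#' reference line (perpendicular distance in normalised objective space),
#' and members are drawn one at a time from the reference point with the
#' smallest current niche count (ties broken uniformly at random), taking
#' the closest associated candidate when the niche is empty and a random
#' associated candidate otherwise.
#'
#' Uses R's current RNG stream; seed it for reproducibility.
#'
#' @param objs Numeric matrix of objective vectors for all candidates.
#' @param fronts List of integer index vectors as from
#'   [fast_nondominated_sort()].
#' @param refpoints Reference-point matrix from
#'   [generate_reference_points()].
#' @param target_size Number of candidates to select.
#' @param normalization Passed to [normalize_objectives()].
#' @return Integer vector of `target_size` selected row indices.
#' @export
associate_and_niche <- function(objs, fronts, refpoints, target_size,
                                normalization = "range") {
  objs <- as.matrix(objs)
  if (sum(lengths(fronts)) < target_size) {
    abort("fewer candidates than target_size")
  }
  selected <- integer(0)
  l <- 0L
  while (l < length(fronts) &&
         length(selected) + length(fronts[[l + 1L]]) <= target_size) {
    l <- l + 1L
    selected <- c(selected, fronts[[l]])
  }
  n_missing <- target_size - length(selected)
  if (n_missing == 0L) return(selected)
  split_front <- fronts[[l + 1L]]

  considered <- c(selected, split_front)
  z <- normalize_objectives(objs[considered, , drop = FALSE],
                            method = normalization)
  pd <- .perp_dist(z, refpoints)
  assoc <- max.col(-pd, ties.method = "first")   # nearest ref per candidate
  dist <- pd[cbind(seq_along(assoc), assoc)]

  n_sel <- length(selected)
  niche_count <- tabulate(assoc[seq_len(n_sel)], nbins = nrow(refpoints))
  pending <- seq_len(length(split_front)) + n_sel   # rows of z / assoc
  active_ref <- rep(TRUE, nrow(refpoints))
  picked <- integer(0)
  while (length(picked) < n_missing) {
    counts <- ifelse(active_ref, niche_count, Inf)
    least <- which(counts == min(counts))
    j <- if (length(least) == 1) least else least[sample.int(length(least), 1)]
    members <- pending[assoc[pending] == j]
    if (length(members) == 0) {
      active_ref[j] <- FALSE
      next
    }
    pick <- if (niche_count[j] == 0) {
      members[which.min(dist[members])]
    } else if (length(members) == 1) members else {
      members[sample.int(length(members), 1)]
    }
    picked <- c(picked, pick)
    pending <- setdiff(pending, pick)
    niche_count[j] <- niche_count[j] + 1L
  }
  c(selected, considered[picked])
}

#' One-point crossover of two binary masks
#'
#' A cut point c is drawn uniformly from 1..D-1; the bits after the cut are
#' swapped between the parents, yielding two offspring.
#'
#' @param a,b Binary 0/1 vectors of equal length D >= 2.
#' @return List of two offspring masks.
#' @export
one_point_crossover <- function(a, b) {
  if (length(a) != length(b)) abort("parent masks differ in length")
  D <- length(a)
  if (D < 2) abort("masks must have length >= 2")
  cut <- sample.int(D - 1L, 1L)
  list(c(a[seq_len(cut)], b[(cut + 1L):D]),
       c(b[seq_len(cut)], a[(cut + 1L):D]))
}

#' Bit-wise mutation
#'
#' Each bit flips independently with probability `rate`.
#'
#' @param mask Binary 0/1 vector.
#' @param rate Per-bit flip probability in \[0, 1\].
#' @return The mutated mask.
#' @export
bitwise_mutation <- function(mask, rate) {
  if (rate < 0 || rate > 1) abort("rate must be in [0, 1]")
  flip <- stats::runif(length(mask)) < rate
  mask[flip] <- 1L - mask[flip]
  mask
}

#' Repair an all-zero mask
#'
#' An empty subset cannot be evaluated (no feature to search on); if every
#' bit is 0, exactly one uniformly random bit is set. Non-empty masks pass
#' through unchanged.
#'
#' @param mask Binary 0/1 vector.
#' @return A mask with at least one bit set.
#' @export
repair_empty_mask <- function(mask) {
  if (sum(mask) == 0) mask[sample.int(length(mask), 1L)] <- 1L
  mask
}

#' Random initial population of binary masks
#'
#' Each bit is set independently with probability `init_density`; all-zero
#' masks are repaired.
#'
#' @param config A [moo_config()].
#' @param D Number of feature dimensions.
#' @return Integer matrix, `population_size` x `D`.
#' @export
initialize_population <- function(config, D) {
  n <- config$population_size
  pop <- matrix(as.integer(stats::runif(n * D) < config$init_density), n, D)
  for (i in seq_len(n)) pop[i, ] <- repair_empty_mask(pop[i, ])
  pop
}

# Binary tournament on rank; ties broken uniformly at random.
.tournament <- function(rank) {
  ij <- sample.int(length(rank), 2L)
  if (rank[ij[1]] < rank[ij[2]]) ij[1]
  else if (rank[ij[2]] < rank[ij[1]]) ij[2]
  else ij[sample.int(2L, 1L)]
}

.mask_key <- function(mask) paste(mask, collapse = "")

# Keep only mutually non-dominated, mask-deduplicated rows.
.nondominated_subset <- function(masks, objs) {
  keys <- apply(masks, 1, .mask_key)
  keep <- !duplicated(keys)
  masks <- masks[keep, , drop = FALSE]
  objs <- objs[keep, , drop = FALSE]
  dom <- .domination_matrix(objs)
  nd <- colSums(dom) == 0
  list(masks = masks[nd, , drop = FALSE], objs = objs[nd, , drop = FALSE])
}

#' Run binary-encoded NSGA-III feature selection
#'
#' Evolves a population of binary feature masks against the three objectives
#' (search-quality loss, feature ratio, site-classification accuracy; see
#' [evaluate_individual()]). Each generation produces `population_size`
#' offspring by binary-tournament-on-rank mating selection, one-point
#' crossover, bit-wise mutation and empty-mask repair; parents and offspring
#' then compete in NSGA-III environmental selection
#' ([fast_nondominated_sort()] + [associate_and_niche()]). An external
#' archive accumulates every evaluated individual and retains the
#' non-dominated set. The loop stops when the next generation would exceed
#' the fitness budget. Duplicate masks are served from an evaluation cache;
#' cache hits still consume budget.
#'
#' The run is fully deterministic given `config$seed`.
#'
#' @param table A feature-table tibble with train and validation splits.
#' @param config A [moo_config()].
#' @param track_archive If `TRUE`, snapshot the archive's objective matrix
#'   after every generation into `$archive_history` (for auditing archive
#'   monotonicity; off by default to save memory).
#' @return An object of class `nsga3_run` with components `population`,
#'   `archive` and `history` (tibbles), `config`, and `feature_names`. Use
#'   [generics::tidy()] / [generics::glance()] / [ggplot2::autoplot()].
#' @export
run_nsga3 <- function(table, config = moo_config(), track_archive = FALSE) {
  table <- validate_feature_table(table)
  feats <- feature_names(table)
  D <- length(feats)
  mut_rate <- if (is.null(config$mutation_rate)) 1 / D else config$mutation_rate
  refpoints <- generate_reference_points(3, config$reference_divisions)
  n <- config$population_size

  evaluator <- .make_evaluator(table, config)
  cache <- new.env(parent = emptyenv())
  evals_used <- 0L
  eval_mask <- function(mask) {
    evals_used <<- evals_used + 1L
    key <- .mask_key(mask)
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    v <- evaluator(mask)
    cache[[key]] <- v
    v
  }
  eval_all <- function(masks) {
    t(apply(masks, 1, eval_mask))
  }

  history <- list()
  archive_history <- list()
  log_gen <- function(gen, objs, archive_size) {
    history[[length(history) + 1L]] <<- tibble::tibble(
      generation = gen, evaluations = evals_used,
      best_f1_loss = min(objs[, 1]), median_f1_loss = stats::median(objs[, 1]),
      best_f2_ratio = min(objs[, 2]), median_f2_ratio = stats::median(objs[, 2]),
      best_f3_site_acc = min(objs[, 3]),
      median_f3_site_acc = stats::median(objs[, 3]),
      archive_size = archive_size)
  }

  withr::with_seed(config$seed, {
    pop <- initialize_population(config, D)
    objs <- eval_all(pop)
    arch <- .nondominated_subset(pop, objs)
    rank <- fast_nondominated_sort(objs)$rank
    gen <- 0L
    log_gen(gen, objs, nrow(arch$masks))
    if (track_archive) archive_history[[1L]] <- arch$objs

    while (evals_used + n <= config$fitness_budget) {
      gen <- gen + 1L
      off <- matrix(0L, n, D)
      for (p in seq_len(n / 2)) {
        i <- .tournament(rank); j <- .tournament(rank)
        pair <- if (stats::runif(1) < config$crossover_probability) {
          one_point_crossover(pop[i, ], pop[j, ])
        } else list(pop[i, ], pop[j, ])
        off[2 * p - 1L, ] <- repair_empty_mask(bitwise_mutation(pair[[1]], mut_rate))
        off[2 * p, ] <- repair_empty_mask(bitwise_mutation(pair[[2]], mut_rate))
      }
      off_objs <- eval_all(off)
      arch <- .nondominated_subset(rbind(arch$masks, off),
                                   rbind(arch$objs, off_objs))
      union_masks <- rbind(pop, off)
      union_objs <- rbind(objs, off_objs)
      nds <- fast_nondominated_sort(union_objs)
      sel <- associate_and_niche(union_objs, nds$fronts, refpoints, n,
                                 normalization = config$normalization)
      pop <- union_masks[sel, , drop = FALSE]
      objs <- union_objs[sel, , drop = FALSE]
      rank <- fast_nondominated_sort(objs)$rank
      log_gen(gen, objs, nrow(arch$masks))
      if (track_archive) archive_history[[gen + 1L]] <- arch$objs
    }
  })

  structure(list(
    population = .individuals_tibble(pop, objs, rank = rank),
    archive = .individuals_tibble(arch$masks, arch$objs),
    history = dplyr::bind_rows(history),
    evaluations = evals_used,
    generations = length(history) - 1L,
    archive_history = if (track_archive) archive_history,
    config = config,
    feature_names = feats
  ), class = "nsga3_run")
}

.individuals_tibble <- function(masks, objs, rank = NULL) {
  tbl <- tibble::tibble(
    mask = lapply(seq_len(nrow(masks)), function(i) masks[i, ]),
    mask_bits = apply(masks, 1, .mask_key),
    n_selected = as.integer(rowSums(masks)),
    f1_loss = objs[, 1], f2_ratio = objs[, 2], f3_site_acc = objs[, 3],
    search_f1 = 1 - objs[, 1]
  )
  if (!is.null(rank)) tbl$rank <- rank
  tbl
}

#' @export
print.nsga3_run <- function(x, ...) {
  cat("NSGA-III feature-selection run\n")
  cat("  features:", length(x$feature_names),
      " population:", x$config$population_size,
      " evaluations:", x$evaluations,
      " generations:", x$generations, "\n")
  cat("  archive:", nrow(x$archive), "non-dominated feature subsets\n")
  best <- pick_max_f1_solution(x$archive)
  cat(sprintf("  max-F1 solution: search F1 %.3f, site accuracy %.3f, %d features\n",
              best$search_f1, best$f3_site_acc, best$n_selected))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.nsga3_run <- function(x, unit = c("archive", "population", "history"),
                           ...) {
  unit <- match.arg(unit)
  x[[unit]]
}

#' @exportS3Method generics::glance
glance.nsga3_run <- function(x, ...) {
  tibble::tibble(
    n_features = length(x$feature_names),
    evaluations = x$evaluations,
    generations = x$generations,
    archive_size = nrow(x$archive),
    best_search_f1 = max(x$archive$search_f1),
    min_site_accuracy = min(x$archive$f3_site_acc),
    min_n_selected = min(x$archive$n_selected)
  )
}

#' Plot an NSGA-III run
#'
#' `type = "front"` shows the archived Pareto front as pairwise objective
#' scatter plots; `type = "history"` shows per-generation best and median
#' objective trajectories.
#'
#' @param object An `nsga3_run`.
#' @param type `"front"` or `"history"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.nsga3_run <- function(object, type = c("front", "history"), ...) {
  type <- match.arg(type)
  if (type == "front") {
    object$archive |>
      ggplot2::ggplot(ggplot2::aes(x = .data$search_f1,
                                   y = .data$f3_site_acc,
                                   colour = .data$n_selected)) +
      ggplot2::geom_point() +
      ggplot2::labs(x = "search macro F1 (validation)",
                    y = "site-classification accuracy",
                    colour = "features",
                    title = "Archived Pareto front") +
      ggplot2::theme_minimal()
  } else {
    object$history |>
      tidyr::pivot_longer(dplyr::starts_with(c("best_", "median_")),
                          names_to = c("stat", "objective"),
                          names_pattern = "(best|median)_(.*)") |>
      ggplot2::ggplot(ggplot2::aes(x = .data$generation, y = .data$value,
                                   colour = .data$stat)) +
      ggplot2::geom_line() +
      ggplot2::facet_wrap(~objective, scales = "free_y") +
      ggplot2::labs(x = "generation", y = "objective value",
                    colour = NULL) +
      ggplot2::theme_minimal()
  }
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
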