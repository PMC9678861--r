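test_that("dominance follows the no-worse-and-somewhere-better rule", {
  expect_true(dominates(c(0.1, 0.2, 0.3), c(0.2, 0.2, 0.3)))
  expect_false(dominates(c(0.1, 0.2, 0.3), c(0.1, 0.2, 0.3)))  # irreflexive
  expect_false(dominates(c(0.1, 0.9), c(0.9, 0.1)))
  expect_false(dominates(c(0.9, 0.1), c(0.1, 0.9)))
  expect_error(dominates(c(0.1), c(0.1, 0.2)), "length")
})

test_that("dominance algebra holds on random triples", {
  withr::with_seed(17, {
    for (i in 1:2000) {
      a <- runif(3); b <- runif(3); c <- runif(3)
      expect_false(dominates(a, a))
      if (dominates(a, b)) expect_false(dominates(b, a))   # antisymmetry
      if (dominates(a, b) && dominates(b, c)) {
        expect_true(dominates(a, c))                       # transitivity
      }
    }
  })
})

test_that("non-dominated sorting handles degenerate populations", {
  same <- matrix(0.5, 4, 3)
  out <- fast_nondominated_sort(same)
  expect_equal(out$fronts, list(1:4))
  chain <- rbind(c(0.1, 0.1, 0.1), c(0.2, 0.2, 0.2), c(0.3, 0.3, 0.3))
  out2 <- fast_nondominated_sort(chain)
  expect_equal(out2$fronts, list(1L, 2L, 3L))
  expect_equal(out2$rank, 1:3)
})

test_that("non-dominated sorting equals brute-force peeling on random sets", {
  withr::with_seed(23, {
    for (n in c(20, 80, 200)) {
      objs <- matrix(runif(n * 3), n, 3)
      got <- fast_nondominated_sort(objs)$fronts
      want <- oracle_peel_fronts(objs)
      expect_equal(lapply(got, sort), lapply(want, sort))
    }
  })
})

test_that("Das-Dennis reference points have the lattice count and unit sums", {
  p1 <- generate_reference_points(3, 1)
  expect_equal(nrow(p1), 3)
  expect_equal(sort(p1[, 1]), c(0, 0, 1))
  expect_equal(nrow(generate_reference_points(3, 2)), 6)
  p12 <- generate_reference_points(3, 12)
  expect_equal(nrow(p12), choose(14, 2))   # 91
  expect_true(all(abs(rowSums(p12) - 1) < 1e-12))
  # enumeration check: every row is a distinct lattice point
  expect_equal(nrow(unique(p12 * 12)), 91)
  expect_true(all(abs(p12 * 12 - round(p12 * 12)) < 1e-9))
})

test_that("objective normalisation shifts to the ideal and divides ranges", {
  single <- normalize_objectives(matrix(c(3, 4, 5), 1))
  expect_equal(as.numeric(single), c(0, 0, 0))
  two <- normalize_objectives(rbind(c(0, 0, 0), c(1, 2, 4)))
  expect_equal(two[2, ], c(1, 1, 1))
  withr::with_seed(31, {
    z <- normalize_objectives(matrix(runif(60, 2, 9), 20, 3))
  })
  expect_true(all(z >= 0 & z <= 1))
})

test_that("niching selection admits whole fronts then fills by reference point", {
  # 8 candidates, 3 reference points, target 4. Rows 1:3 are the first
  # front (associated to r2, r2, r3 => niche counts r1 0, r2 2, r3 1); rows
  # 4:8 are the second front. One seat remains: the least-crowded reference
  # is r1 (count 0, unique), its associated split-front members are rows 4
  # (perp. distance 0.9823) and 8 (0.9487), and an empty niche takes the
  # closest, so row 8 completes the selection. Component ideals are 0 and
  # ranges 1, making the hand arithmetic exact; no tie-break randomness is
  # exercised.
  objs <- rbind(
    c(0.0, 0.95, 0.3),    # A front 1 -> r2
    c(0.3, 0.9, 0.0),     # B front 1 -> r2
    c(0.2, 0.0, 0.9),     # C front 1 -> r3
    c(1.0, 0.25, 0.95),   # E front 2 -> r1
    c(0.1, 1.0, 0.4),     # F front 2 -> r2
    c(0.25, 0.05, 1.0),   # G front 2 -> r3
    c(0.4, 0.95, 0.25),   # H front 2 -> r2
    c(0.95, 0.3, 0.9)     # I front 2 -> r1, closest to the r1 line
  )
  nds <- fast_nondominated_sort(objs)
  expect_equal(nds$fronts, list(1:3, 4:8))
  refs <- generate_reference_points(3, 1)
  sel <- withr::with_seed(1, associate_and_niche(objs, nds$fronts, refs, 4))
  expect_setequal(sel, c(1, 2, 3, 8))
})

test_that("niching selection respects rank precedence and exact fits", {
  withr::with_seed(37, {
    objs <- matrix(runif(120), 40, 3)
    nds <- fast_nondominated_sort(objs)
    refs <- generate_reference_points(3, 4)
    # exact fit: identity selection
    sel_all <- associate_and_niche(objs, nds$fronts, refs, 40)
    expect_setequal(sel_all, 1:40)
    # any target: a selected rank never skips an unselected lower rank
    for (target in c(5, 17, 31)) {
      sel <- associate_and_niche(objs, nds$fronts, refs, target)
      expect_equal(length(sel), target)
      ranks <- nds$rank[sel]
      unselected <- setdiff(1:40, sel)
      if (length(unselected) > 0) {
        expect_true(max(ranks) <= min(nds$rank[unselected]) ||
                      all(nds$rank[unselected] >= max(ranks)))
      }
    }
    # the first front alone exceeding the target: selection all rank 1
    big_front <- matrix(runif(90), 30, 3)
    nds2 <- fast_nondominated_sort(big_front)
    if (length(nds2$fronts[[1]]) >= 10) {
      sel2 <- associate_and_niche(big_front, nds2$fronts, refs, 10)
      expect_true(all(nds2$rank[sel2] == 1))
    }
  })
})

test_that("one-point crossover swaps suffixes and conserves bits by position", {
  withr::with_seed(41, {
    a <- rep(1L, 4); b <- rep(0L, 4)
    kids <- one_point_crossover(a, b)
    cut <- sum(kids[[1]])
    expect_equal(kids[[1]], c(rep(1L, cut), rep(0L, 4 - cut)))
    expect_equal(kids[[2]], c(rep(0L, cut), rep(1L, 4 - cut)))

    same <- one_point_crossover(c(1L, 0L, 1L), c(1L, 0L, 1L))
    expect_equal(same[[1]], c(1L, 0L, 1L))

    for (trial in 1:1000) {
      p1 <- as.integer(runif(12) < 0.5)
      p2 <- as.integer(runif(12) < 0.5)
      kids <- one_point_crossover(p1, p2)
      expect_equal(kids[[1]] + kids[[2]], p1 + p2)  # positional conservation
    }
  })
})

test_that("bit-wise mutation flips at the configured rate", {
  mask <- c(1L, 0L, 1L, 1L, 0L)
  expect_identical(withr::with_seed(1, bitwise_mutation(mask, 0)), mask)
  expect_identical(withr::with_seed(1, bitwise_mutation(mask, 1)),
                   1L - mask)
  D <- 1024
  withr::with_seed(43, {
    flips <- vapply(1:10000, function(i) {
      sum(bitwise_mutation(rep(0L, D), 1 / D))
    }, numeric(1))
  })
  se <- sqrt(1 * (1 - 1 / D) / 10000)
  expect_lt(abs(mean(flips) - 1), 3 * se)
})

test_that("empty masks are repaired to a uniform single bit", {
  expect_equal(repair_empty_mask(c(0L, 1L, 0L)), c(0L, 1L, 0L))
  withr::with_seed(47, {
    reps <- vapply(1:10000, function(i) which(repair_empty_mask(rep(0L, 5)) == 1L),
                   integer(1))
  })
  tab <- table(factor(reps, levels = 1:5))
  expect_gt(stats::chisq.test(tab)$p.value, 0.01)
})

test_that("population initialisation respects density and repairs empties", {
  cfg <- moo_config(population_size = 50, fitness_budget = 50,
                    init_density = 1)
  pop <- withr::with_seed(1, initialize_population(cfg, 16))
  expect_true(all(pop == 1L))

  cfg2 <- moo_config(population_size = 50, fitness_budget = 50)
  p1 <- withr::with_seed(5, initialize_population(cfg2, 1024))
  p2 <- withr::with_seed(5, initialize_population(cfg2, 1024))
  expect_identical(p1, p2)
  mean_pc <- mean(rowSums(p1))
  se <- sqrt(1024 * 0.25 / 50)
  expect_lt(abs(mean_pc - 512), 3 * se)
  expect_true(all(rowSums(p1) >= 1))
})

test_that("a budget of one population returns the evaluated initial population", {
  gen <- generate_biased_dataset(small_benchmark_spec())
  cfg <- moo_config(population_size = 8, fitness_budget = 8, seed = 11,
                    reference_divisions = 4)
  run <- run_nsga3(gen$table, cfg)
  expect_equal(run$generations, 0)
  expect_equal(run$evaluations, 8)
  expect_equal(nrow(run$population), 8)
  # archive is the non-dominated subset of the initial population
  objs <- as.matrix(run$population[c("f1_loss", "f2_ratio", "f3_site_acc")])
  nd <- oracle_peel_fronts(objs)[[1]]
  expect_setequal(run$archive$mask_bits,
                  unique(run$population$mask_bits[nd]))
})

test_that("runs are deterministic given the seed and respect the budget", {
  gen <- generate_biased_dataset(small_benchmark_spec())
  cfg <- moo_config(population_size = 10, fitness_budget = 64, seed = 19,
                    reference_divisions = 4)
  r1 <- run_nsga3(gen$table, cfg)
  r2 <- run_nsga3(gen$table, cfg)
  expect_identical(r1$archive, r2$archive)
  expect_identical(r1$population, r2$population)
  expect_identical(r1$history, r2$history)
  expect_lte(r1$evaluations, 64)
  expect_gt(r1$evaluations, 64 - 10)
})

test_that("the archive is non-dominated throughout and never regresses", {
  gen <- generate_biased_dataset(small_benchmark_spec())
  cfg <- moo_config(population_size = 10, fitness_budget = 150, seed = 29,
                    reference_divisions = 4)
  run <- run_nsga3(gen$table, cfg, track_archive = TRUE)
  hist <- run$archive_history
  expect_gt(length(hist), 2)
  for (snapshot in hist) {
    fronts <- oracle_peel_fronts(snapshot)
    expect_equal(length(fronts), 1)   # mutually non-dominated
  }
  # elitist monotonicity: a point in a later archive state is never
  # dominated by any point of any earlier archive state
  for (g in 2:length(hist)) {
    for (gp in 1:(g - 1)) {
      prev <- hist[[gp]]
      for (i in seq_len(nrow(hist[[g]]))) {
        pt <- hist[[g]][i, ]
        expect_false(any(apply(prev, 1, function(q) dominates(q, pt))))
      }
    }
  }
})
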