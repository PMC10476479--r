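test_that("exhaustive search reproduces frozen hand-derived optima", {
  # uniform 4 levels, m = 1: the middle cut balances both classes
  r <- exhaustive_search(gray_histogram(rep(0.25, 4)), m = 1)
  expect_equal(r$best_thresholds$cuts, 2L)
  expect_equal(r$best_value, 2)

  # two-spike histogram: all cuts strictly above the lower spike tie at 0;
  # the lexicographic rule returns the smallest
  r2 <- exhaustive_search(gray_histogram(c(0.5, 0, 0, 0.5)), m = 1)
  expect_equal(r2$best_thresholds$cuts, 1L)
  expect_equal(r2$best_value, 0)

  # uniform 5 levels, m = 2: optimum splits class sizes as evenly as
  # possible; (1,3), (2,3), (2,4) tie at log2(1)+log2(2)+log2(2) = 2 bits
  r3 <- exhaustive_search(gray_histogram(rep(0.2, 5)), m = 2)
  expect_equal(r3$best_thresholds$cuts, c(1L, 3L))
  expect_equal(r3$best_value, 2, tolerance = 1e-12)
})

test_that("exhaustive search matches the independent brute-force oracle", {
  set.seed(71)
  for (rep in 1:20) {
    Z <- sample(4:16, 1)
    m <- sample(1:2, 1)
    if (m + 1L > Z) next
    h <- random_hist(Z)
    got <- exhaustive_search(h, m = m)
    want <- brute_search(h$probs, m)
    expect_identical(got$best_thresholds$cuts, as.integer(want$cuts))
    expect_equal(got$best_value, want$value, tolerance = 1e-10)
  }
})

test_that("search refuses infeasible problems and huge enumerations", {
  const <- gray_histogram(c(0, 1, 0, 0))
  expect_error(exhaustive_search(const, m = 1),
               class = "maxentseg_feasibility_error")
  expect_error(exhaustive_search(gray_histogram(rep(1 / 256, 256)), m = 6),
               class = "maxentseg_resource_error")
  expect_error(population_search(const, search_config(1)),
               class = "maxentseg_feasibility_error")
})

test_that("population search is reproducible and elitist", {
  set.seed(81)
  h <- random_hist(64L)
  cfg <- search_config(2, seed = 42L)
  r1 <- population_search(h, cfg)
  r2 <- population_search(h, cfg)
  expect_identical(serialize(r1, NULL), serialize(r2, NULL))
  expect_true(all(diff(r1$history) >= 0))
  expect_equal(length(r1$history), r1$generations_run)
  # best value is the objective re-evaluated at the best vector
  expect_equal(r1$best_value, kapur_objective(h, r1$best_thresholds),
               tolerance = 1e-12)
})

test_that("an optimum present at initialization is kept from generation one", {
  # Z = 4, m = 1: 30 random individuals over {1, 2, 3} contain the optimal
  # cut at initialization (checked below), so history starts at the optimum.
  h <- gray_histogram(c(0.4, 0.1, 0.3, 0.2))
  oracle <- exhaustive_search(h, m = 1)
  r <- population_search(h, search_config(1, seed = 42L))
  expect_equal(r$history[1], oracle$best_value, tolerance = 1e-12)
})

test_that("a different seed changes the search trajectory, not the contract", {
  set.seed(82)
  h <- random_hist(64L)
  ra <- population_search(h, search_config(2, seed = 1L))
  rb <- population_search(h, search_config(2, seed = 2L))
  expect_true(all(diff(rb$history) >= 0))
  # both feasible
  expect_false(is.na(kapur_objective(h, ra$best_thresholds)))
  expect_false(is.na(kapur_objective(h, rb$best_thresholds)))
})

test_that("population search does not disturb the caller's RNG stream", {
  set.seed(7)
  draws_clean <- stats::runif(3)
  set.seed(7)
  invisible(population_search(gray_histogram(rep(1 / 16, 16)),
                              search_config(1, seed = 5L)))
  expect_identical(stats::runif(3), draws_clean)
})

test_that("population search finds the exhaustive optimum on modest problems", {
  set.seed(91)
  for (rep in 1:5) {
    h <- random_hist(64L)
    m <- sample(1:2, 1)
    oracle <- exhaustive_search(h, m = m)
    got <- population_search(h, search_config(m, seed = rep))
    expect_equal(got$best_value, oracle$best_value, tolerance = 1e-6)
  }
})

test_that("segment composes histogram, search and labeling", {
  spec <- phantom_spec(
    shape = c(48L, 48L),
    classes = list(
      tissue_class("background", list(type = "full"), 10),
      tissue_class("liver", list(type = "ellipse", center = c(24, 24),
                                 axes = c(16, 11), rotation = 0.2), 32),
      tissue_class("tumor", list(type = "disk", center = c(22, 20),
                                 radius = 5), 54)
    ),
    noise_sd = 0, n_levels = 64L, seed = 3L
  )
  ph <- generate_phantom(spec)
  seg <- segment(ph$image, 2, method = "exhaustive")
  # zero noise: classes occupy disjoint gray levels, recovery is perfect
  ev <- evaluate_segmentation(seg$labels, ph$truth)
  expect_equal(ev$per_class_dice, c(1, 1, 1))
  expect_equal(ev$overall_accuracy, 1)
  # cuts separate the three pure gray values
  expect_true(seg$thresholds$cuts[1] > 10 && seg$thresholds$cuts[1] <= 32)
  expect_true(seg$thresholds$cuts[2] > 32 && seg$thresholds$cuts[2] <= 54)

  # with mild noise the optimum is unique and both methods return the same
  # threshold vector
  spec_n <- phantom_spec(
    shape = spec$shape, classes = spec$classes, noise_sd = 2,
    n_levels = 64L, seed = 3L
  )
  phn <- generate_phantom(spec_n)
  segn_e <- segment(phn$image, 2, method = "exhaustive")
  segn_p <- segment(phn$image, 2, method = "population", seed = 9L)
  expect_identical(segn_p$thresholds$cuts, segn_e$thresholds$cuts)

  # population method matches the oracle objective on this 3-class scene
  # (zero noise makes every separating vector tie at J = 0, so cut vectors
  # are compared through the objective, not element-wise)
  segp <- segment(ph$image, 2, method = "population", seed = 9L)
  expect_equal(segp$result$best_value, seg$result$best_value, tolerance = 1e-12)
  evp <- evaluate_segmentation(segp$labels, ph$truth)
  expect_equal(evp$per_class_dice, c(1, 1, 1))

  # constant image: no feasible threshold
  const <- gray_image(matrix(7L, 8, 8))
  expect_error(segment(const, 1), class = "maxentseg_feasibility_error")
})
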