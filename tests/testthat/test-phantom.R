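test_that("zero-noise phantoms take exactly the class mean values", {
  spec <- phantom_spec(
    shape = c(32L, 32L),
    classes = list(
      tissue_class("background", list(type = "full"), 5),
      tissue_class("liver", list(type = "ellipse", center = c(16, 16),
                                 axes = c(10, 7)), 20),
      tissue_class("tumor", list(type = "disk", center = c(15, 14),
                                 radius = 3), 40)
    ),
    noise_sd = 0, n_levels = 64L
  )
  ph <- generate_phantom(spec, seed = 1)
  vals <- sort(unique(as.vector(ph$image$pixels)))
  expect_equal(vals, c(5L, 20L, 40L))
  # histogram spikes carry the region pixel fractions
  h <- compute_histogram(ph$image)
  fr <- tabulate(ph$truth$labels + 1L, nbins = 3) / 1024
  expect_equal(h$probs[c(6, 21, 41)], fr)
})

test_that("ground-truth labels match the painted geometry exactly", {
  spec <- phantom_preset("liver3")
  labs <- generate_phantom(spec, seed = 2)$truth
  # painting order: tumor over liver over background; disk area fully labeled 2
  g <- spec$classes[[3]]$geometry
  rows <- matrix(seq_len(256), 256, 256)
  cols <- matrix(seq_len(256), 256, 256, byrow = TRUE)
  in_disk <- (rows - g$center[1])^2 + (cols - g$center[2])^2 <= g$radius^2
  expect_true(all(labs$labels[in_disk] == 2L))
  expect_true(all(labs$labels[!in_disk] != 2L))
})

test_that("fixed seeds reproduce phantoms byte-for-byte", {
  spec <- phantom_preset("liver3")
  a <- generate_phantom(spec, seed = 5)
  b <- generate_phantom(spec, seed = 5)
  expect_identical(serialize(a$image, NULL), serialize(b$image, NULL))
  c <- generate_phantom(spec, seed = 6)
  expect_false(identical(a$image$pixels, c$image$pixels))
})

test_that("the analytic histogram model tracks the empirical histogram", {
  spec <- phantom_preset("liver3")
  model <- phantom_histogram_model(spec)
  expect_equal(sum(model$probs), 1, tolerance = 1e-12)

  # empirical histogram approaches the model as the image grows
  small_spec <- phantom_spec(
    shape = c(64L, 64L),
    classes = list(
      tissue_class("background", list(type = "full"), 40),
      tissue_class("liver", list(type = "ellipse", center = c(32, 32),
                                 axes = c(23, 16), rotation = 0.35), 120),
      tissue_class("tumor", list(type = "disk", center = c(30, 23),
                                 radius = 6), 200)
    ),
    noise_sd = 10
  )
  small_model <- phantom_histogram_model(small_spec)
  l1 <- function(spec, model, seed) {
    h <- compute_histogram(generate_phantom(spec, seed = seed)$image)
    sum(abs(h$probs - model$probs))
  }
  l1_small <- mean(vapply(1:10, function(s) l1(small_spec, small_model, s), 0))
  l1_big <- mean(vapply(1:10, function(s) l1(spec, model, s), 0))
  expect_lt(l1_big, l1_small)

  # zero noise collapses the mixture to spikes at the means
  spike_spec <- phantom_spec(
    shape = c(16L, 16L),
    classes = list(tissue_class("background", list(type = "full"), 12)),
    noise_sd = 0, n_levels = 32L
  )
  m <- phantom_histogram_model(spike_spec)
  expect_equal(m$probs[13], 1)
})

test_that("segmentation overlap improves as noise shrinks", {
  mk <- function(sd) {
    phantom_spec(
      shape = c(96L, 96L),
      classes = list(
        tissue_class("background", list(type = "full"), 40),
        tissue_class("liver", list(type = "ellipse", center = c(48, 48),
                                   axes = c(34, 24), rotation = 0.35), 120),
        tissue_class("tumor", list(type = "disk", center = c(44, 34),
                                   radius = 9), 200)
      ),
      noise_sd = sd
    )
  }
  min_dice <- vapply(c(20, 10, 2, 0), function(sd) {
    ph <- generate_phantom(mk(sd), seed = 17)
    seg <- segment(ph$image, 2, method = "exhaustive")
    min(evaluate_segmentation(seg$labels, ph$truth)$per_class_dice)
  }, 0)
  expect_true(all(diff(min_dice) > 0))
  expect_equal(min_dice[4], 1)
})

test_that("invalid specs are rejected with field-level messages", {
  bg <- tissue_class("background", list(type = "full"), 10)
  expect_error(
    phantom_spec(classes = list(bg, tissue_class("x", list(type = "full"), 5))),
    class = "maxentseg_domain_error"
  )  # means not increasing
  expect_error(
    phantom_spec(classes = list(tissue_class("x", list(type = "full"), 300))),
    class = "maxentseg_domain_error"
  )  # mean outside gray range
  expect_error(
    phantom_spec(classes = list(
      bg,
      tissue_class("big", list(type = "disk", center = c(10, 10), radius = 50), 80)
    ), shape = c(32L, 32L)),
    class = "maxentseg_domain_error"
  )  # geometry outside frame
})

test_that("too-close class means raise a recorded separability warning", {
  spec <- phantom_spec(
    classes = list(
      tissue_class("background", list(type = "full"), 100),
      tissue_class("liver", list(type = "ellipse", center = c(128, 128),
                                 axes = c(60, 40)), 120)
    ),
    noise_sd = 10
  )
  expect_warning(ph <- generate_phantom(spec, seed = 1), "separable")
  expect_length(ph$warnings, 1)
})
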