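test_that("the ideal template is arc-convergent with the configured geometry", {
  tpl <- make_ideal_template()
  gt <- attr(tpl, "ground_truth")
  o <- locate_point_O(build_planes(tpl))
  expect_equal(o$point, gt$O, tolerance = 1e-9)
  expect_lt(o$residual, 1e-9)
  expect_equal(landmark_dist(tpl, "S", "N"), gt$sn_length)
  expect_equal(gt$sn_length, 71, tolerance = 0.1)
  fit <- estimate_mandible(tpl)
  expect_lt(fit$estimate$gap_Go, 1e-6)
  expect_lt(fit$estimate$gap_Pog, 1e-6)

  # unreachable geometry is rejected
  expect_error(make_ideal_template(template_config(r_anterior = 5)),
               "inconsistent config")
  expect_error(template_config(angles = c(mandibular = -11, occlusal = -7.5,
                                          palatal = -3, basal = 95)),
               "anteriorly")
})

test_that("cohort generation is seed-deterministic and honours its spec", {
  spec <- cohort_spec(n = 40, seed = 77)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a, b)
  expect_length(a$subjects, 40)
  expect_identical(nrow(a$meta), 40L)
  expect_true(all(a$meta$class %in% c("I", "II", "III")))

  c2 <- generate_cohort(cohort_spec(n = 40, seed = 78))
  expect_false(identical(a$subjects, c2$subjects))
})

test_that("a noiseless class-I cohort reproduces the template exactly", {
  spec <- cohort_spec(n = 5, class_mix = c(I = 1, II = 0, III = 0),
                      digitization_sd = 0, scale_sd = 0, pog_lift = 0,
                      seed = 3)
  coh <- generate_cohort(spec)
  tpl <- make_ideal_template()
  for (s in coh$subjects)
    expect_equal(unname(do.call(rbind, s$points)),
                 unname(do.call(rbind, tpl$points)), tolerance = 1e-12)
})

test_that("skeletal class shifts displace the mandibular landmarks sagittally", {
  mk <- function(mix) generate_cohort(cohort_spec(
    n = 1, class_mix = mix, digitization_sd = 0, scale_sd = 0,
    pog_lift = 0, seed = 5))$subjects[[1]]
  i <- mk(c(I = 1, II = 0, III = 0))
  ii <- mk(c(I = 0, II = 1, III = 0))
  iii <- mk(c(I = 0, II = 0, III = 1))
  expect_equal(get_landmark(ii, "Go"), get_landmark(i, "Go") + c(-6, 0))
  expect_equal(get_landmark(iii, "Me"), get_landmark(i, "Me") + c(6, 0))
  expect_equal(get_landmark(ii, "S"), get_landmark(i, "S"))  # cranium fixed
})

test_that("expected class counts follow the multinomial law across seeds", {
  counts <- sapply(1:60, function(s)
    table(factor(generate_cohort(cohort_spec(n = 100, seed = s))$meta$class,
                 levels = c("I", "II", "III"))))
  m <- rowMeans(counts)
  # expectation (28, 26, 46); se of each mean ~ sqrt(p(1-p)*100/60) < 0.65
  expect_equal(unname(m), c(28, 26, 46), tolerance = 0.1)
})

test_that("repeat digitization adds calibrated Gaussian noise", {
  tpl <- make_ideal_template()
  expect_identical(digitize_repeat(tpl, 0)$points, tpl$points)

  set.seed(55)
  diffs <- unlist(lapply(1:300, function(i) {
    r <- digitize_repeat(tpl, 0.5)
    mapply(function(a, b) a - b, r$points, tpl$points)
  }))
  expect_lt(abs(stats::sd(diffs) - 0.5) / 0.5, 0.15)

  r1 <- digitize_repeat(tpl, 0.5, seed = 1)
  r2 <- digitize_repeat(tpl, 0.5, seed = 2)
  expect_identical(names(r1$points), names(r2$points))
  expect_false(identical(r1$points, r2$points))
  expect_identical(digitize_repeat(tpl, 0.5, seed = 9),
                   digitize_repeat(tpl, 0.5, seed = 9))
})

test_that("shape labels are drawn from the requested joint distribution", {
  degen <- matrix(0, 3, 3); degen[2, 1] <- 1
  lab <- sample_shape_labels(20, degen, seed = 1)
  expect_true(all(lab$palate == "concave"))
  expect_true(all(lab$mandible == "horizontal"))

  expect_identical(sample_shape_labels(50, seed = 42),
                   sample_shape_labels(50, seed = 42))

  # empirical mean cell counts over many seeds track the reference counts
  ref <- unclass(shape_reference_counts())
  tot <- matrix(0, 3, 3, dimnames = dimnames(ref))
  n_seeds <- 500
  for (s in seq_len(n_seeds)) {
    lab <- sample_shape_labels(100, seed = s)
    tot <- tot + table(factor(lab$mandible, levels = rownames(ref)),
                       factor(lab$palate, levels = colnames(ref)))
  }
  expect_true(all(abs(tot / n_seeds - ref) <= 1))
})

test_that("SN/Go-Me simulation recovers its generating line", {
  d <- simulate_sn_gome(n = 4000, seed = 10)
  f <- ols_fit(d$sn, d$gome)
  expect_equal(f$slope, 0.5426, tolerance = 0.05)
  expect_equal(f$intercept, 22.65, tolerance = 4)
  expect_identical(simulate_sn_gome(n = 10, seed = 3),
                   simulate_sn_gome(n = 10, seed = 3))
})

test_that("cohorts round-trip through the on-disk directory format", {
  dir <- withr::local_tempdir()
  coh <- generate_cohort(cohort_spec(n = 6, seed = 2))
  write_cohort(coh, dir)
  expect_true(file.exists(file.path(dir, "metadata.json")))
  back <- read_cohort(dir)
  expect_length(back$subjects, 6)
  expect_identical(back$meta$class, coh$meta$class)
  ids <- vapply(back$subjects, function(s) s$subject_id, character(1))
  expect_identical(sort(ids), sort(coh$meta$subject_id))
  for (i in seq_along(back$subjects)) {
    orig <- coh$subjects[[match(back$subjects[[i]]$subject_id,
                                coh$meta$subject_id)]]
    expect_identical(back$subjects[[i]]$points, orig$points)
  }
})
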