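test_that("the four planes pass through their defining landmarks", {
  tpl <- make_ideal_template()
  planes <- build_planes(tpl)
  expect_lt(perpendicular_distance(get_landmark(tpl, "Go"),
                                   planes$mandibular), 1e-12)
  expect_lt(perpendicular_distance(get_landmark(tpl, "Me"),
                                   planes$mandibular), 1e-12)
  expect_lt(perpendicular_distance(get_landmark(tpl, "ANS"),
                                   planes$palatal), 1e-12)
  expect_lt(perpendicular_distance(get_landmark(tpl, "Si"),
                                   planes$basal), 1e-12)
  # closed ideal occlusion: U1 = L1 and U6 = L6 lie on the occlusal plane
  expect_lt(perpendicular_distance(get_landmark(tpl, "U1"),
                                   planes$occlusal), 1e-12)
  expect_lt(perpendicular_distance(get_landmark(tpl, "U6"),
                                   planes$occlusal), 1e-12)

  # template plane directions equal the configured angles
  cfg <- template_config()
  gt <- norm_dir(cfg$angles)
  expect_equal(planes$mandibular$direction, gt[["mandibular"]],
               tolerance = 1e-9)
  expect_equal(planes$occlusal$direction, gt[["occlusal"]], tolerance = 1e-9)
  expect_equal(planes$palatal$direction, gt[["palatal"]], tolerance = 1e-9)
  expect_equal(planes$basal$direction, gt[["basal"]], tolerance = 1e-9)

  degen <- tpl
  degen$points$Me <- degen$points$Go
  expect_error(build_planes(degen), "mandibular")
})

test_that("point O strategies agree under concurrency and match the grid oracle otherwise", {
  tpl <- make_ideal_template()
  planes <- build_planes(tpl)
  o_ls <- locate_point_O(planes, "least_squares")
  o_pm <- locate_point_O(planes, "pairwise_mean")
  expect_equal(o_ls$point, attr(tpl, "ground_truth")$O, tolerance = 1e-9)
  expect_equal(o_pm$point, o_ls$point, tolerance = 1e-9)
  expect_lt(o_ls$residual, 1e-9)
  expect_lt(o_pm$residual, 1e-9)

  two <- structure(list(a = line2d(c(0, 1), atan(2) * 180 / pi),
                        b = line2d(c(0, 4), 135)), class = "sassouni_planes")
  expect_equal(locate_point_O(two)$point, c(1, 3), tolerance = 1e-9)

  # perturbed planes: least-squares O against the grid-search oracle
  set.seed(21)
  jit <- lapply(unclass(planes), function(l)
    line2d(l$anchor + stats::rnorm(2, 0, 1.5), l$direction + stats::rnorm(1, 0, 0.8)))
  fit <- least_squares_point(jit)
  oracle <- grid_ls_point(jit, fit$point - 3, fit$point + 3)
  expect_equal(fit$point, oracle, tolerance = 1e-2)
})

test_that("the least-squares concurrency residual is rigid-motion invariant", {
  set.seed(5)
  tpl <- make_ideal_template()
  noisy <- digitize_repeat(tpl, 1.0, seed = 9)
  res0 <- locate_point_O(build_planes(noisy))$residual
  for (rep in 1:5) {
    ang <- stats::runif(1, -180, 180); shift <- stats::rnorm(2, 0, 40)
    moved <- noisy
    moved$points <- lapply(moved$points, function(p)
      rotate_point(p, c(0, 0), ang) + shift)
    expect_equal(locate_point_O(build_planes(moved))$residual, res0,
                 tolerance = 1e-9)
  }
})

test_that("the construction's arcs pass through their defining landmarks", {
  tpl <- make_ideal_template()
  con <- build_construction(tpl)
  on_arc <- function(p, arc)
    abs(sqrt(sum((p - arc$center)^2)) - arc$radius)
  expect_equal(con$anterior_arc$radius,
               sqrt(sum((con$O - get_landmark(tpl, "ANS"))^2)))
  expect_lt(on_arc(get_landmark(tpl, "Sp"), con$posterior_arc), 1e-9)
  # in the well-proportioned face the anterior arc passes through
  # Pog, U1, ANS and N; the posterior arc through Go and Sp
  for (nm in c("Pog", "U1", "ANS", "N"))
    expect_lt(on_arc(get_landmark(tpl, nm), con$anterior_arc), 1e-6)
  for (nm in c("Go", "Sp"))
    expect_lt(on_arc(get_landmark(tpl, nm), con$posterior_arc), 1e-6)

  bad <- tpl
  bad$points$Sp <- attr(tpl, "ground_truth")$O
  expect_error(build_construction(bad), "zero posterior radius")
})

test_that("estimated Go and Pog sit on both the arc and the mandibular plane", {
  set.seed(31)
  for (rep in 1:25) {
    spec <- cohort_spec(n = 1, digitization_sd = 1.0, seed = rep)
    sub <- generate_cohort(spec)$subjects[[1]]
    con <- build_construction(sub)
    go <- estimate_gonion(con); pog <- estimate_pogonion(con)
    if (!is.null(go)) {
      expect_lt(abs(sqrt(sum((go - con$O)^2)) - con$posterior_arc$radius),
                1e-9 * con$posterior_arc$radius)
      expect_lt(perpendicular_distance(go, con$planes$mandibular), 1e-9)
    }
    if (!is.null(pog)) {
      expect_lt(abs(sqrt(sum((pog - con$O)^2)) - con$anterior_arc$radius),
                1e-9 * con$anterior_arc$radius)
      expect_lt(perpendicular_distance(pog, con$planes$mandibular), 1e-9)
    }
  }
})

test_that("estimation is exact on the ideal template and NULL on a radial miss", {
  tpl <- make_ideal_template()
  con <- build_construction(tpl)
  expect_equal(estimate_gonion(con), get_landmark(tpl, "Go"),
               tolerance = 1e-9)
  expect_equal(estimate_pogonion(con), get_landmark(tpl, "Pog"),
               tolerance = 1e-9)

  # shrink the posterior arc below the O-to-MdP distance: geometric miss
  miss <- con
  gap <- perpendicular_distance(con$O, con$planes$mandibular)
  miss$posterior_arc <- circle2d(con$O, gap * 0.9)
  expect_null(estimate_gonion(miss))
  expect_gt(arc_miss_shortfall(miss, "posterior"), 0)
})

test_that("a traced Pog above the mandibular plane is estimated inferiorly", {
  set.seed(13)
  for (lift in c(2, 4, 6)) {
    tpl <- make_ideal_template(template_config(pog_above_mdp = lift))
    fit <- estimate_mandible(tpl)
    est <- fit$estimate
    expect_false(is.null(est$est_Pog))
    expect_lt(est$est_Pog[2], est$traced_Pog[2])
    expect_lt(est$dPog[2], 0)
  }
})

test_that("estimate comparison computes signed differences and Euclidean gaps", {
  tr <- list(Go = c(-10, -80), Pog = c(62, -90))
  same <- compare_estimates(list(Go = tr$Go, Pog = tr$Pog), tr)
  expect_equal(same$gap_Go, 0)
  expect_equal(same$gap_Pog, 0)

  off <- compare_estimates(list(Go = tr$Go + c(3, 4), Pog = tr$Pog), tr)
  expect_equal(off$dGo, c(3, 4))
  expect_equal(off$gap_Go, 5)

  set.seed(2)
  for (rep in 1:20) {
    d <- stats::rnorm(2)
    cmp <- compare_estimates(list(Go = tr$Go + d, Pog = NULL), tr)
    expect_equal(cmp$gap_Go, sqrt(d[1]^2 + d[2]^2), tolerance = 1e-12)
    expect_true(is.na(cmp$gap_Pog))
    expect_true("pogonion_arc_miss" %in% cmp$flags)
  }
})

test_that("heuristic shape classification applies thresholds with closed non-extreme boundaries", {
  base <- make_ideal_template()  # divergence 18 deg, PV on the chord
  lab <- classify_shapes_heuristic(base)
  expect_identical(lab$palate, "horizontal")
  expect_identical(lab$mandible, "horizontal")
  expect_identical(lab$source, "heuristic")

  # divergence 40 deg (> 32): oblique / hyperdivergent
  steep <- make_ideal_template(template_config(
    angles = c(mandibular = -33, occlusal = -7.5, palatal = -3, basal = 7)))
  expect_identical(classify_shapes_heuristic(steep)$mandible, "oblique")

  # boundary values land in the non-extreme class: a divergence exactly
  # equal to either threshold is 'curved' (strict inequalities on both
  # sides), and a palate deviation of exactly 0 is 'horizontal' even at
  # threshold t = 0
  p <- build_planes(base)
  div <- abs(p$mandibular$direction - p$basal$direction) %% 180
  div <- min(div, 180 - div)
  expect_identical(
    classify_shapes_heuristic(base, theta_hi = div, theta_lo = 0)$mandible,
    "curved")
  expect_identical(
    classify_shapes_heuristic(base, theta_hi = 90, theta_lo = div)$mandible,
    "curved")
  conv10 <- make_ideal_template(template_config(pv_deviation = 0.10))
  ans <- get_landmark(conv10, "ANS"); pns <- get_landmark(conv10, "PNS")
  pv <- get_landmark(conv10, "PV")
  chord <- ans - pns
  len <- sqrt(sum(chord^2))
  cross <- chord[1] * (pv[2] - pns[2]) - chord[2] * (pv[1] - pns[1])
  dev <- -cross / len / len
  expect_identical(classify_shapes_heuristic(conv10, t = dev)$palate,
                   "horizontal")

  # palate deviation: inferior positive -> convex, superior -> concave
  conv <- make_ideal_template(template_config(pv_deviation = 0.10))
  expect_identical(classify_shapes_heuristic(conv)$palate, "convex")
  conc <- make_ideal_template(template_config(pv_deviation = -0.10))
  expect_identical(classify_shapes_heuristic(conc)$palate, "concave")

  # PV absent: warned and labelled horizontal
  nopv <- base
  nopv$points$PV <- NULL
  expect_warning(lab2 <- classify_shapes_heuristic(nopv), "PV absent")
  expect_identical(lab2$palate, "horizontal")
})
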