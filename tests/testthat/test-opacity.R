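test_that("power opacity functions satisfy their boundary and range contracts", {
  for (cc in c(0.5, 1, 3, 7)) {
    expect_equal(power_decreasing(0, cc), 1)
    expect_equal(power_decreasing(1, cc), 0)
    expect_equal(power_increasing(1, cc), 1)
    expect_equal(power_increasing(0, cc), 0)
  }
  expect_equal(power_decreasing(0.5, 3), 0.125)
  expect_equal(power_increasing(0.5, 1), 0.5)

  x <- seq(0, 1, length.out = 1e4)
  for (cc in c(0.5, 2, 3, 7)) {
    ad <- power_decreasing(x, cc)
    ai <- power_increasing(x, cc)
    expect_true(all(ad >= 0 & ad <= 1) && all(ai >= 0 & ai <= 1))
    expect_true(all(diff(ad) <= 0))          # monotone non-increasing
    expect_true(all(diff(ai) >= 0))          # monotone non-decreasing
    expect_equal(ad, power_increasing(1 - x, cc), tolerance = 1e-12)
  }
  # raising c lowers the decreasing opacity pointwise on (0, 1)
  interior <- x[x > 0 & x < 1]
  expect_true(all(power_decreasing(interior, 7) < power_decreasing(interior, 3)))

  expect_error(power_decreasing(1.1, 3), "\\[0, 1\\]")
  expect_error(power_decreasing(-0.1, 3), "\\[0, 1\\]")
  expect_error(power_decreasing(0.5, -1), "positive")
  # floating-point slack just outside [0,1] is clipped, not rejected
  expect_equal(power_decreasing(1 + 1e-12, 3), 0)
})

test_that("linear ramp in theta evaluates and clamps per its piecewise form", {
  expect_equal(linear_theta(0, a = 2 / pi, b = 0), 0)
  expect_equal(linear_theta(pi / 2, a = 2 / pi, b = 0), 1)
  expect_equal(linear_theta(pi / 4, a = 4 / pi, b = -0.5), 0.5)
  # below -b/a the ramp clamps to 0; above (1-b)/a it clamps to 1
  expect_equal(linear_theta(0.3, a = 1, b = -0.5), 0)
  expect_equal(linear_theta(1.5, a = 2, b = -0.5), 1)
  expect_error(linear_theta(0.1, a = 0, b = 0), "slope")
  expect_error(linear_theta(2, a = 1, b = 0), "pi/2")
})

test_that("assign_opacity covers the scale x function option matrix", {
  straight <- make_phantom("straight", n_streamlines = 4,
                           points_per_streamline = 30, seed = 1)
  t_par <- c(0, 0, 1)   # parallel to the bundle
  for (scale in c("local", "global_endpoints", "global_scatter")) {
    dec <- assign_opacity(straight, opacity_config(
      scale = scale, axis_mode = "fixed", t = t_par, fun = "power_decreasing", c = 1))
    expect_true(all(abs(unlist(dec$scalars$alpha)) < 1e-9), info = scale)
    inc <- assign_opacity(straight, opacity_config(
      scale = scale, axis_mode = "fixed", t = t_par, fun = "power_increasing", c = 3))
    expect_true(all(abs(unlist(inc$scalars$alpha) - 1) < 1e-9), info = scale)
  }
  # view-axis coupling: same result as passing the axis as fixed
  v <- unitize(c(1, 1, 1))
  a_view <- assign_opacity(straight, opacity_config(
    scale = "local", axis_mode = "view", fun = "power_decreasing"), view_axis = v)
  a_fix <- assign_opacity(straight, opacity_config(
    scale = "local", axis_mode = "fixed", t = v, fun = "power_decreasing"))
  expect_equal(a_view$scalars$alpha, a_fix$scalars$alpha)
  expect_error(assign_opacity(straight, opacity_config(
    scale = "local", axis_mode = "view", fun = "power_decreasing")), "view_axis")
})

test_that("global scales broadcast one alpha per streamline; local matches on straight lines", {
  tg <- make_phantom("arc", n_streamlines = 5, points_per_streamline = 60,
                     arc_angle_deg = 150, seed = 3)
  cfg <- opacity_config(scale = "global_scatter", axis_mode = "fixed",
                        t = unitize(c(1, 2, 0)), fun = "power_decreasing")
  out <- assign_opacity(tg, cfg)
  for (a in out$scalars$alpha) expect_length(unique(a), 1)

  straight <- make_phantom("straight", n_streamlines = 3,
                           points_per_streamline = 40, seed = 9)
  t_ax <- unitize(c(1, 0, 1))
  loc <- assign_opacity(straight, opacity_config("local", "fixed", t_ax,
                                                 "power_decreasing"))
  glo <- assign_opacity(straight, opacity_config("global_scatter", "fixed", t_ax,
                                                 "power_decreasing"))
  expect_equal(loc$scalars$alpha, glo$scalars$alpha, tolerance = 1e-9)
})

test_that("assign_opacity is invariant to reversing a streamline's point order", {
  tg <- make_phantom("helix", n_streamlines = 2, points_per_streamline = 50,
                     seed = 6)
  rev_tg <- tractogram(lapply(tg$streamlines, function(sl) sl[nrow(sl):1, ]))
  for (scale in c("local", "global_endpoints", "global_scatter")) {
    cfg <- opacity_config(scale, "fixed", unitize(c(1, 1, 0)), "power_increasing")
    a <- assign_opacity(tg, cfg)$scalars$alpha
    b <- assign_opacity(rev_tg, cfg)$scalars$alpha
    expect_equal(lapply(a, rev), b, tolerance = 1e-12, info = scale)
  }
})

test_that("the dispersion gate makes low-c_l streamlines fully opaque", {
  straight <- cbind(seq(-30, 30, length.out = 100), 0, 0)
  semi <- arc_points(0, pi, 100)
  tg <- tractogram(list(straight, semi))
  cfg <- opacity_config(scale = "global_scatter", axis_mode = "fixed",
                        t = c(1, 0, 0), fun = "power_decreasing", c = 3,
                        T_cl = 0.29)
  out <- assign_opacity(tg, cfg)
  # straight: c_l = 1, above the gate, so alpha follows the opacity function
  expect_true(all(abs(out$scalars$alpha[[1]]) < 1e-9))
  # semicircle: c_l ~ 0, below the gate, forced opaque
  expect_true(all(out$scalars$alpha[[2]] == 1))
  # gate applies across scales, including local
  out_loc <- assign_opacity(tg, opacity_config(
    scale = "local", axis_mode = "fixed", t = c(1, 0, 0),
    fun = "power_decreasing", T_cl = 0.29))
  expect_true(all(out_loc$scalars$alpha[[2]] == 1))
  expect_true(any(out_loc$scalars$alpha[[1]] < 1))
})

test_that("closed loops get alpha = 1 under the endpoints scale, with a report", {
  loop <- arc_points(0, 2 * pi, 100)
  tg <- tractogram(list(loop))
  cfg <- opacity_config("global_endpoints", "fixed", c(1, 0, 0),
                        "power_increasing")
  expect_message(out <- assign_opacity(tg, cfg), "undefined global axis")
  expect_true(all(out$scalars$alpha[[1]] == 1))
})

test_that("every alpha lies in [0, 1] across random configurations", {
  set.seed(13)
  shapes <- c("straight", "arc", "helix", "crossing")
  funs <- c("power_decreasing", "power_increasing", "linear_theta")
  for (rep in 1:12) {
    tg <- make_phantom(sample(shapes, 1), n_streamlines = 4,
                       points_per_streamline = 30, jitter_kappa = 20, seed = rep)
    cfg <- opacity_config(
      scale = sample(c("local", "global_endpoints", "global_scatter"), 1),
      axis_mode = "fixed", t = random_unit_axis(),
      fun = sample(funs, 1), c = stats::runif(1, 0.5, 10),
      a = stats::runif(1, 0.2, 3), b = stats::runif(1, -1, 1),
      T_cl = if (stats::runif(1) < 0.5) stats::runif(1) else NULL)
    a <- unlist(assign_opacity(tg, cfg)$scalars$alpha)
    expect_true(all(a >= 0 & a <= 1))
  }
})

test_that("dot histogram counts orientations and respects conservation", {
  straight <- make_phantom("straight", n_streamlines = 5,
                           points_per_streamline = 20, seed = 2)
  h <- dot_histogram(straight, "local", t = c(0, 0, 1), nbins = 10)
  expect_equal(sum(h$counts), sum(n_points(straight)))
  expect_equal(h$counts[10], sum(n_points(straight)))  # all mass in top bin

  hg <- dot_histogram(straight, "global_scatter", t = c(0, 0, 1), nbins = 5)
  expect_equal(sum(hg$counts), n_streamlines(straight))

  h1 <- dot_histogram(straight, "local", t = c(0, 0, 1), nbins = 1)
  expect_equal(h1$counts, sum(n_points(straight)))

  expect_error(dot_histogram(tractogram(list()), "local", c(0, 0, 1), 5),
               "empty")
})

test_that("|n.t| of uniform axes is uniform on [0,1] (Archimedes projection)", {
  set.seed(99)
  axes <- sample_watson(1e5, c(0, 0, 1), kappa = 0)
  tg <- axes_as_tractogram(axes)
  h <- dot_histogram(tg, "global_endpoints", t = c(0, 0, 1), nbins = 20)
  p <- stats::chisq.test(h$counts, p = rep(1 / 20, 20))$p.value
  expect_gt(p, 0.01)
})
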