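test_that("extent is the base-tip distance and rigid-motion invariant", {
  tr <- make_track(c(5, 5), angle = atan2(4, 3))
  expect_equal(series_of(tr)$extents, c(5, 5))
  tr0 <- make_track(c(0, 0))
  expect_equal(series_of(tr0)$extents, c(0, 0))

  set.seed(101)
  for (rep in 1:20) {
    n <- sample(3:8, 1)
    b <- matrix(rnorm(2 * n, sd = 5), ncol = 2)
    p <- b + matrix(rnorm(2 * n, sd = 3), ncol = 2)
    mk <- function(bm, pm) filopodium_track(1,
      base = data.frame(frame = 1:n, x = bm[, 1], y = bm[, 2]),
      tip = data.frame(frame = 1:n, x = pm[, 1], y = pm[, 2]),
      window_start_frame = 1, window_end_frame = n + 1)
    e0 <- series_of(mk(b, p))$extents
    expect_true(all(e0 >= 0))
    # translation by (10, -7), then rotation by a random angle
    shift <- c(10, -7)
    th <- runif(1, 0, 2 * pi)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    e1 <- series_of(mk(sweep(b, 2, shift, "+"),
                       sweep(p, 2, shift, "+")))$extents
    e2 <- series_of(mk(b %*% t(R), p %*% t(R)))$extents
    expect_equal(e1, e0, tolerance = 1e-12)
    expect_equal(e2, e0, tolerance = 1e-12)
  }
})

test_that("window-truncation flags follow the paired frames", {
  s <- series_of(make_track(c(2, 4, 2), first_frame = 2))
  expect_false(s$touches_window_start)
  expect_false(s$touches_window_end)
  s1 <- series_of(make_track(c(2, 4, 2), first_frame = 1))
  expect_true(s1$touches_window_start)
  s2 <- series_of(make_track(c(2, 4, 2), first_frame = 14))  # ends at 16
  expect_true(s2$touches_window_end)
})

test_that("fit_triangle matches the hand-constructed examples", {
  # symmetric triangle
  tri <- fit_triangle(extent_series(c(0, 2, 4), c(2, 4, 2), 2))
  expect_equal(tri[c("t_origin", "t_end", "Emax", "Ve", "Vr", "lifetime")],
               list(t_origin = -2, t_end = 6, Emax = 4, Ve = 1, Vr = 1,
                    lifetime = 8))
  # degenerate one-frame spike at t = 0
  sp <- fit_triangle(extent_series(0, 5, 2))
  expect_equal(sp$Ve, 2.5); expect_equal(sp$Vr, 2.5)
  expect_equal(sp$lifetime, 4)
  # plateau tied at Emax: first peak -> Ve, last peak -> Vr
  pl <- fit_triangle(extent_series(c(0, 2), c(3, 3), 2))
  expect_equal(pl$Ve, 1.5); expect_equal(pl$Vr, 1.5)
  expect_equal(pl$lifetime, 6)
  expect_error(fit_triangle(extent_series(c(0, 2), c(0, 0), 2)),
               "no extension")
})

test_that("fit_trapezoid matches the hand-constructed examples", {
  trap <- fit_trapezoid(extent_series(seq(0, 8, 2), c(3, 6, 6, 6, 3), 2))
  expect_equal(trap$t_origin, -2); expect_equal(trap$t_end, 10)
  expect_equal(trap$t_half, 4); expect_equal(trap$Es, 6)
  expect_equal(trap$t_s_start, 2); expect_equal(trap$t_s_end, 6)
  expect_equal(trap$Vs, 0)
  expect_equal(trap$Ve, 1.5); expect_equal(trap$Vr, 1.5)
  expect_equal(trap$lifetime, 12)

  # perfectly triangular series degenerates to the triangle construction
  s <- extent_series(c(0, 2, 4), c(2, 4, 2), 2)
  d <- fit_trapezoid(s)
  expect_equal(d$t_s_start, d$t_s_end)
  expect_equal(d$Vs, 0)
  expect_equal(model_curve(d, s$times), model_curve(fit_triangle(s), s$times))

  # symmetric series: Ve equals Vr exactly
  sym <- fit_trapezoid(extent_series(seq(0, 10, 2), c(1, 4, 4, 4, 4, 1), 2))
  expect_identical(sym$Ve, sym$Vr)
})

test_that("model_curve is continuous, zero outside, exact at vertices", {
  s <- extent_series(c(0, 2, 4), c(2, 4, 2), 2)
  tri <- fit_triangle(s)
  expect_equal(model_curve(tri, 0), 2)
  expect_equal(model_curve(tri, tri$t_origin), 0)
  expect_equal(model_curve(tri, tri$t_peak_first), tri$Emax)
  expect_equal(model_curve(tri, c(-100, 100)), c(0, 0))
  # continuity: small steps give small changes
  grid <- seq(tri$t_origin - 1, tri$t_end + 1, by = 0.001)
  expect_lt(max(abs(diff(model_curve(tri, grid)))), 0.01)
  trap <- fit_trapezoid(extent_series(seq(0, 8, 2), c(3, 6, 6, 6, 3), 2))
  gridt <- seq(trap$t_origin - 1, trap$t_end + 1, by = 0.001)
  expect_lt(max(abs(diff(model_curve(trap, gridt)))), 0.01)
  expect_equal(model_curve(trap, trap$t_origin), 0)
})

test_that("noiseless model sampling is recovered exactly by the fits", {
  set.seed(7)
  dt <- 2
  for (rep in 1:25) {
    k_e <- sample(1:6, 1); k_r <- sample(1:6, 1)
    Emax <- runif(1, 1, 9)
    t0 <- sample(0:5, 1) * dt
    # triangle: vertices on the frame grid
    tt <- seq(t0 + dt, t0 + (k_e + k_r - 1) * dt, by = dt)
    Ve <- Emax / (k_e * dt); Vr <- Emax / (k_r * dt)
    ee <- pmin(Ve * (tt - t0), Vr * (t0 + (k_e + k_r) * dt - tt))
    fit <- fit_triangle(extent_series(tt, ee, dt))
    expect_equal(fit$Ve, Ve, tolerance = 1e-9)
    expect_equal(fit$Vr, Vr, tolerance = 1e-9)
    expect_equal(fit$Emax, Emax, tolerance = 1e-9)
    expect_equal(fit$lifetime, (k_e + k_r) * dt, tolerance = 1e-9)
    # RMSE of the fitted curve on noiseless triangular data is 0
    expect_lt(classify_dynamics(extent_series(tt, ee, dt))$rmse_triangle,
              1e-10)

    # trapezoid with flat plateau attained at half-lifetime
    k_p <- sample(1:4, 1) + abs(k_e - k_r)   # half-lifetime on the plateau
    L <- (k_e + k_p + k_r) * dt
    tt2 <- seq(t0 + dt, t0 + L - dt, by = dt)
    up <- Ve2 <- Emax / (k_e * dt); dn <- Emax / (k_r * dt)
    ee2 <- pmin(Emax, up * (tt2 - t0), dn * (t0 + L - tt2))
    fit2 <- fit_trapezoid(extent_series(tt2, ee2, dt))
    expect_equal(fit2$Es, Emax, tolerance = 1e-9)
    expect_equal(fit2$Ve, up, tolerance = 1e-9)
    expect_equal(fit2$Vr, dn, tolerance = 1e-9)
    expect_equal(fit2$Vs, 0, tolerance = 1e-12)
  }
})

test_that("classification follows RMSE with ties to triangle", {
  s_tri <- extent_series(c(0, 2, 4), c(2, 4, 2), 2)
  cls <- classify_dynamics(s_tri)
  expect_equal(cls$model_label, "triangle")
  expect_equal(cls$rmse_triangle, cls$rmse_trapezoid)

  s_trap <- extent_series(seq(0, 8, 2), c(3, 6, 6, 6, 3), 2)
  cls2 <- classify_dynamics(s_trap)
  expect_equal(cls2$model_label, "trapezoid")
  expect_equal(cls2$rmse_trapezoid, 0)
  expect_gt(cls2$rmse_triangle, 0)
})

test_that("classification is invariant to rigid motion of the track", {
  set.seed(33)
  cfg <- generator_config(n_tracks = 10, noise_sigma_um = 0.1, seed = 5)
  co <- gen_cohort(cfg)
  for (tr in co$tracks[1:5]) {
    lab0 <- classify_dynamics(series_of(tr))$model_label
    tr2 <- tr
    th <- runif(1, 0, 2 * pi); R <- matrix(c(cos(th), sin(th),
                                             -sin(th), cos(th)), 2)
    for (role in c("base", "tip")) {
      xy <- as.matrix(tr2[[role]][, c("x", "y")]) %*% t(R)
      tr2[[role]]$x <- xy[, 1] + 12.5
      tr2[[role]]$y <- xy[, 2] - 3.25
    }
    expect_equal(classify_dynamics(series_of(tr2))$model_label, lab0)
  }
})

test_that("lifetime is (n frames + 1) * dt for gap-free tracks", {
  for (n in 2:6) {
    s <- extent_series(seq(0, by = 2, length.out = n),
                       c(seq_len(ceiling(n / 2)),
                         rev(seq_len(floor(n / 2)))), 2)
    expect_equal(fit_triangle(s)$lifetime, (n + 1) * 2)
  }
})

test_that("summarize_filopodium applies the phase-eligibility rules", {
  # fully inside the window: both phases observed
  s <- summarize_filopodium(make_track(c(2, 4, 2), first_frame = 5))
  expect_true(s$has_elongation); expect_true(s$has_retraction)
  expect_false(is.na(s$Ve_um_per_min)); expect_false(is.na(s$Vr_um_per_min))
  expect_equal(s$Emax_um, 4)

  # present at the movie's final frame: no retraction phase
  s2 <- summarize_filopodium(make_track(c(2, 4, 6), first_frame = 14))
  expect_false(s2$has_retraction)
  expect_true(is.na(s2$Vr_um_per_min))

  # present at the first frame: no elongation phase
  s3 <- summarize_filopodium(make_track(c(6, 4, 2), first_frame = 1))
  expect_false(s3$has_elongation)
  expect_true(is.na(s3$Ve_um_per_min))

  # born at its maximum: elongation not observable either
  s4 <- summarize_filopodium(make_track(c(4, 3, 2), first_frame = 5))
  expect_false(s4$has_elongation)
  expect_true(s4$has_retraction)
})
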