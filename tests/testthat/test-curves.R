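# Analytic power curves, Bezier machinery, sinus/symmetry construction.

test_that("leaflet curve satisfies its three defining conditions", {
  # hand-substituted coefficients for l_ro=15, l_ri=10, l_a=pi/3, l_p=2
  cv <- power_curve(10, 15, pi / 3, 2, 10)
  expect_equal(cv$coeff, -2.5 / (15 * sin(pi / 3))^2, tolerance = 1e-12)
  expect_equal(cv$coeff, -0.0148148, tolerance = 1e-5)
  expect_equal(power_curve_eval(cv, 5), 9.6296, tolerance = 1e-4)

  set.seed(11)
  for (k in 1:100) {
    p <- random_params()
    f <- make_leaflet_curve(p)
    expect_identical(power_curve_eval(f, 0), p$l_ri)
    ymax <- p$l_ro * sin(p$l_a)
    expect_equal(power_curve_eval(f, ymax), p$l_ro * cos(p$l_a),
                 tolerance = 1e-10)
    # zero slope at the symmetry line (power > 1)
    h <- 1e-7 * ymax
    expect_lt(abs(power_curve_eval(f, h) - p$l_ri) / h, 1e-4)
  }
})

test_that("bending curve mirrors the leaflet construction at z = b_h", {
  cv <- power_curve(6, 14, pi / 3, 3, 5)
  expect_equal(cv$coeff, 1 / (14 * sin(pi / 3))^3, tolerance = 1e-12)
  set.seed(12)
  for (k in 1:50) {
    p <- random_params()
    g <- make_bending_curve(p)
    expect_identical(power_curve_eval(g, 0), p$b_ri)
    expect_equal(power_curve_eval(g, p$b_ro * sin(p$b_a)),
                 p$b_ro * cos(p$b_a), tolerance = 1e-10)
    expect_identical(g$plane_z, p$b_h)
  }
})

test_that("power curve rejects degenerate parameters", {
  expect_error(power_curve(5, 10, 0, 2, 1), "positive")
  expect_error(power_curve(5, 10, pi / 4, 1, 1), "power")
  expect_error(leaflet_params(l_ro = 10, l_ri = 11, l_a = 1, l_p = 2,
                              l_h = 10, r_r = 12, b_ro = 9, b_ri = 5,
                              b_a = 1, b_p = 2, b_h = 5),
               "l_ri < l_ro")
})

test_that("Bezier evaluation interpolates endpoints and stays in the hull", {
  set.seed(13)
  for (deg in 2:3) {
    P <- matrix(rnorm((deg + 1) * 3, sd = 5), ncol = 3)
    bz <- bezier_curve(P)
    expect_equal(bezier_eval(bz, 0)[1, ], setNames(P[1, ], c("x", "y", "z")))
    expect_equal(bezier_eval(bz, 1)[1, ],
                 setNames(P[deg + 1, ], c("x", "y", "z")))
    pts <- bezier_eval(bz, runif(50))
    for (j in 1:3) {
      expect_gte(min(pts[, j]), min(P[, j]) - 1e-12)
      expect_lte(max(pts[, j]), max(P[, j]) + 1e-12)
    }
  }
})

test_that("De Casteljau split is an exact reparametrization", {
  set.seed(14)
  P <- matrix(rnorm(12, sd = 10), ncol = 3)
  bz <- bezier_curve(P)
  for (t_split in c(0.25, 0.5, 0.8)) {
    sp <- split_bezier(bz, t_split)
    expect_equal(bezier_eval(sp$lower, 1), bezier_eval(bz, t_split),
                 tolerance = 1e-13)
    expect_equal(bezier_eval(sp$upper, 0), bezier_eval(bz, t_split),
                 tolerance = 1e-13)
    s <- runif(200)
    err_lo <- max(abs(bezier_eval(sp$lower, s) -
                        bezier_eval(bz, s * t_split)))
    err_hi <- max(abs(bezier_eval(sp$upper, s) -
                        bezier_eval(bz, t_split + s * (1 - t_split))))
    expect_lt(err_lo, 1e-12)
    expect_lt(err_hi, 1e-12)
  }
  # straight segment: shared endpoint is the midpoint
  seg <- bezier_curve(rbind(c(0, 0, 0), c(1, 1, 1) / 3,
                            c(2, 2, 2) / 3, c(1, 1, 1)))
  sp <- split_bezier(seg, 0.5)
  expect_equal(as.vector(bezier_eval(sp$lower, 1)), c(0.5, 0.5, 0.5),
               tolerance = 1e-13)
  expect_error(split_bezier(bz, 0), "t_split")
  expect_error(split_bezier(bz, 1), "t_split")
})

test_that("sinus curve interpolates the bending-plane outer point", {
  p <- ref_params()
  sn <- make_sinus_curve(p)
  # l_h=10, b_h=5: s_sin = 1/2 and P1 = 2 B(1/2) - (P0 + P2)/2
  expect_equal(attr(sn, "s_sin"), 0.5)
  target <- c(p$b_ro * cos(p$b_a), p$b_ro * sin(p$b_a), p$b_h)
  P0 <- sn$control[1, ]; P2 <- sn$control[3, ]
  expect_equal(unname(sn$control[2, ]), 2 * target - 0.5 * P0 - 0.5 * P2,
               tolerance = 1e-12)

  set.seed(15)
  for (k in 1:100) {
    q <- random_params()
    s <- q$b_h / q$l_h
    sn <- make_sinus_curve(q)
    expect_equal(as.vector(bezier_eval(sn, s)),
                 c(q$b_ro * cos(q$b_a), q$b_ro * sin(q$b_a), q$b_h),
                 tolerance = 1e-10)
    expect_equal(as.vector(bezier_eval(sn, 0)),
                 c(q$r_r * cos(q$l_a), q$r_r * sin(q$l_a), 0),
                 tolerance = 1e-12)
    expect_equal(as.vector(bezier_eval(sn, 1)),
                 c(q$l_ro * cos(q$l_a), q$l_ro * sin(q$l_a), q$l_h),
                 tolerance = 1e-12)
  }
})

test_that("symmetry curve is planar and interpolates the bending point", {
  # default weights -0.2, r_r=12, b_ri=6, b_h=5 give Q1 = (7.8, 0, 1.5)
  p <- ref_params(b_ri = 6)
  cv <- make_symmetry_curve(p)
  expect_equal(unname(cv$control[2, ]), c(7.8, 0, 1.5), tolerance = 1e-12)

  set.seed(16)
  for (k in 1:100) {
    q <- random_params()
    cv <- make_symmetry_curve(q)
    expect_true(all(cv$control[, 2] == 0))
    pts <- bezier_eval(cv, runif(20))
    expect_true(all(abs(pts[, 2]) < 1e-14))
    s <- q$b_h / q$l_h
    expect_equal(as.vector(bezier_eval(cv, s)), c(q$b_ri, 0, q$b_h),
                 tolerance = 1e-10)
    expect_equal(as.vector(bezier_eval(cv, 0)), c(q$r_r, 0, 0))
    expect_equal(as.vector(bezier_eval(cv, 1)), c(q$l_ri, 0, q$l_h))
  }
})

test_that("cubic edge approximation hugs the analytic curve", {
  p <- ref_params()
  f <- make_leaflet_curve(p)
  bz <- approximate_edge_as_bezier(f, p$t0, p$t3)
  # endpoint interpolation
  expect_equal(as.vector(bezier_eval(bz, 0)), c(p$l_ri, 0, p$l_h),
               tolerance = 1e-12)
  expect_equal(as.vector(bezier_eval(bz, 1)),
               c(p$l_ro * cos(p$l_a), p$l_ro * sin(p$l_a), p$l_h),
               tolerance = 1e-10)
  # zero slope at the symmetry line: L1_x -> L0_x as fd_step -> 0 (the
  # finite-difference tangent is O(fd^{p-1})), y offset is t0 * y_max
  for (fd in c(1e-3, 1e-5, 1e-7)) {
    bzf <- approximate_edge_as_bezier(f, 0.3, 0.3, fd_step = fd)
    expect_lt(abs(bzf$control[2, 1] - bzf$control[1, 1]),
              0.3 * f$y_max * abs(f$coeff) * fd * 1.5)
    expect_equal(bzf$control[2, 2], 0.3 * f$y_max)
  }
  # dense-sampling distance to the analytic curve, fixture cohort
  for (nm in c("healthy", "mild", "moderate", "severe")) {
    q <- generate_fixture(nm)[[1]]
    fa <- make_leaflet_curve(q)
    bq <- approximate_edge_as_bezier(fa, q$t0, q$t3)
    samp <- bezier_eval(bq, seq(0, 1, length.out = 101))
    yy <- seq(0, fa$y_max, length.out = 400)
    an <- power_curve_eval(fa, yy, as_xyz = TRUE)
    dmax <- max(vapply(seq_len(nrow(samp)), function(i) {
      sqrt(min(colSums((t(an) - samp[i, ])^2)))
    }, 0))
    expect_lt(dmax, 0.05 * q$l_ro)
  }
  expect_error(approximate_edge_as_bezier(f, 0.3, 0.3, fd_step = 2 * f$y_max),
               "fd_step")
})
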