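# Coons patches, half-leaflet assembly, full-valve symmetry properties.

test_that("Coons patch reproduces its boundary curves and corners", {
  p <- ref_params()
  hl <- build_half_leaflet(p)
  uu <- seq(0, 1, length.out = 50)
  for (patch in list(hl$top, hl$bottom)) {
    expect_lt(max(abs(coons_eval(patch, uu, 0) -
                        curve_eval(patch$south, uu))), 1e-9)
    expect_lt(max(abs(coons_eval(patch, uu, 1) -
                        curve_eval(patch$north, uu))), 1e-9)
    expect_lt(max(abs(coons_eval(patch, 0, uu) -
                        curve_eval(patch$west, uu))), 1e-9)
    expect_lt(max(abs(coons_eval(patch, 1, uu) -
                        curve_eval(patch$east, uu))), 1e-9)
  }
  # corners
  expect_equal(as.vector(coons_eval(hl$top, 0, 0)),
               unname(hl$top$corners["SW", ]), tolerance = 1e-12)
  expect_equal(as.vector(coons_eval(hl$top, 1, 1)),
               unname(hl$top$corners["NE", ]), tolerance = 1e-12)
  # the top NE corner is the commissure point
  expect_equal(as.vector(coons_eval(hl$top, 1, 1)),
               c(p$l_ro * cos(p$l_a), p$l_ro * sin(p$l_a), p$l_h),
               tolerance = 1e-9)
})

test_that("Coons evaluation agrees with an independent term-by-term sum", {
  p <- ref_params()
  hl <- build_half_leaflet(p)
  patch <- hl$top
  u <- 0.5; v <- 0.5
  # direct bilinear-blend formula, written out term by term
  S <- curve_eval(patch$south, u); N <- curve_eval(patch$north, u)
  W <- curve_eval(patch$west, v); E <- curve_eval(patch$east, v)
  C <- patch$corners
  manual <- (1 - v) * S + v * N + (1 - u) * W + u * E -
    ((1 - u) * (1 - v) * C["SW", ] + u * v * C["NE", ] +
       u * (1 - v) * C["SE", ] + (1 - u) * v * C["NW", ])
  expect_equal(as.vector(coons_eval(patch, u, v)), as.vector(manual),
               tolerance = 1e-13)
})

test_that("corner mismatch is detected and named", {
  bad_north <- bezier_curve(rbind(c(0, 0, 1), c(1, 0, 1)))
  south <- bezier_curve(rbind(c(0, 0, 0), c(1, 0, 0)))
  west <- bezier_curve(rbind(c(0, 0, 0), c(0.5, 0, 1)))  # NW end off by 0.5
  east <- bezier_curve(rbind(c(1, 0, 0), c(1, 0, 1)))
  expect_error(make_coons_patch(south, bad_north, west, east), "NW")
})

test_that("half-leaflet patches join smoothly at the bending curve", {
  set.seed(21)
  for (k in 1:5) {
    p <- random_params()
    hl <- build_half_leaflet(p)
    uu <- seq(0, 1, length.out = 40)
    shared <- max(abs(coons_eval(hl$top, uu, 0) -
                        coons_eval(hl$bottom, uu, 1)))
    expect_lt(shared, 1e-10)
    # z ranges of the two patches partition [0, l_h] at b_h
    gr <- expand.grid(u = seq(0, 1, 0.05), v = seq(0, 1, 0.05))
    zt <- coons_eval(hl$top, gr$u, gr$v)[, 3]
    zb <- coons_eval(hl$bottom, gr$u, gr$v)[, 3]
    expect_gte(min(zt), p$b_h - 1e-9); expect_lte(max(zt), p$l_h + 1e-9)
    expect_gte(min(zb), 0 - 1e-9); expect_lte(max(zb), p$b_h + 1e-9)
    # the u=1 boundary of the top patch is the split sinus curve
    sin_top <- hl$curves$sinus_split$upper
    expect_lt(max(abs(coons_eval(hl$top, 1, uu) -
                        bezier_eval(sin_top, uu))), 1e-10)
  }
})

test_that("identical leaflets at 120 degrees give a 3-fold symmetric valve", {
  v <- symmetric_valve()
  uu <- runif(30); vv <- runif(30)
  R <- matrix(c(cos(2 * pi / 3), sin(2 * pi / 3), 0,
                -sin(2 * pi / 3), cos(2 * pi / 3), 0, 0, 0, 1), 3, 3)
  for (part in c(1, 2)) {  # top patch of leaflet 1 -> leaflet 2, etc.
    a <- valve_patch_eval(v, part, uu, vv) %*% t(R)
    b <- valve_patch_eval(v, part + 2, uu, vv)
    expect_lt(max(abs(a - b)), 1e-9)
  }
})

test_that("mirrored half is the reflection of the base half", {
  v <- symmetric_valve()
  uu <- runif(20); vv <- runif(20)
  base <- valve_patch_eval(v, 1, uu, vv, mirrored = FALSE)
  mir <- valve_patch_eval(v, 1, uu, vv, mirrored = TRUE)
  expect_equal(mir, base * matrix(rep(c(1, -1, 1), each = 20), ncol = 3),
               tolerance = 1e-14)
})

test_that("valve assembly warns on angle deficit and commissure gaps", {
  p <- ref_params()
  small <- modifyList(p, list(l_a = 50 * pi / 180, b_a = 50 * pi / 180))
  class(small) <- "leaflet_params"
  w <- capture_warnings(
    assemble_valve(list(small,
                        modifyList(small, list(theta = 2 * pi / 3)),
                        modifyList(small, list(theta = 4 * pi / 3)))))
  expect_true(any(grepl("half-angles|commissure", w)))
  # well-closed valve: no warning
  expect_silent(symmetric_valve())
})

test_that("mixed half-angles keep commissures together within tolerance", {
  p <- ref_params()
  angles <- c(50, 60, 70) * pi / 180
  thetas <- c(0, 0, 0)
  # place leaflets so adjacent commissures meet: theta_{i+1} = theta_i +
  # l_a_i + l_a_{i+1}
  thetas[2] <- thetas[1] + angles[1] + angles[2]
  thetas[3] <- thetas[2] + angles[2] + angles[3]
  leaflets <- lapply(1:3, function(i)
    modifyList(p, list(l_a = angles[i], b_a = angles[i], theta = thetas[i])))
  for (i in 1:3) class(leaflets[[i]]) <- "leaflet_params"
  v <- assemble_valve(leaflets)
  expect_lt(max(v$commissure_gaps), 1.0)
  # the three leaflets really are different surfaces
  a <- valve_patch_eval(v, 1, 0.7, 0.7)
  b <- valve_patch_eval(v, 3, 0.7, 0.7) %*% t(rbind(
    c(cos(thetas[2]), sin(thetas[2]), 0),
    c(-sin(thetas[2]), cos(thetas[2]), 0),
    c(0, 0, 1)))
  expect_gt(max(abs(a - b)), 0.1)
})

test_that("all sampled surface points stay inside the valve cylinder", {
  set.seed(22)
  for (k in 1:3) {
    p <- random_params()
    # random draws need not close the valve; closure warnings are expected
    v <- suppressWarnings(symmetric_valve(p))
    s <- valve_sample_surface(v, 15, 15)
    r <- sqrt(rowSums(s$vertices[, 1:2]^2))
    expect_true(all(is.finite(s$vertices)))
    expect_lte(max(r), p$l_ro * (1 + 1e-6))
    expect_gte(min(s$vertices[, 3]), -1e-9)
    expect_lte(max(s$vertices[, 3]), p$l_h * (1 + 1e-6))
  }
})
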