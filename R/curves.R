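#' Analytic power curve of a leaflet cross-section
#'
#' The free edge of a leaflet at height `z = l_h`, and likewise the bending
#' curve at `z = b_h`, are described in their horizontal plane as
#' `x = f(y) = r_inner + coeff * y^power`, where the coefficient is fixed by
#' requiring the curve to start on the inner circle with zero slope and to
#' meet the outer circle at the commissure angle. This constructor builds the
#' generic curve; [make_leaflet_curve()] and [make_bending_curve()] apply it
#' to the two parameter groups.
#'
#' @param r_inner Inner radius at the symmetry line (mm); `f(0) = r_inner`.
#' @param r_outer Outer-circle radius (mm).
#' @param half_angle Half-angle at which the curve meets the outer circle (rad).
#' @param power Curve power (`> 1` so the slope at `y = 0` vanishes).
#' @param plane_z Height of the plane the curve lives in (mm).
#' @return An object of class `power_curve` with fields `r_inner`, `coeff`,
#'   `power`, `plane_z`, `y_max` (= `r_outer * sin(half_angle)`).
#' @seealso [power_curve_eval()], [approximate_edge_as_bezier()]
#' @export
power_curve <- function(r_inner, r_outer, half_angle, power, plane_z) {
  y_max <- r_outer * sin(half_angle)
  if (y_max <= 0)
    stop("power_curve: r_outer * sin(half_angle) must be positive")
  if (power <= 1) stop("power_curve: power must be > 1")
  coeff <- (r_outer * cos(half_angle) - r_inner) / y_max^power
  structure(list(r_inner = r_inner, coeff = coeff, power = power,
                 plane_z = plane_z, y_max = y_max,
                 r_outer = r_outer, half_angle = half_angle),
            class = "power_curve")
}

#' Evaluate a power curve
#'
#' @param curve A `power_curve`.
#' @param y Lateral coordinate(s), mm, in `[0, y_max]`.
#' @param as_xyz If `TRUE` return an `n x 3` matrix `(f(y), y, plane_z)`,
#'   otherwise the scalar values `f(y)`.
#' @return Numeric vector `f(y)` or an `n x 3` coordinate matrix.
#' @export
power_curve_eval <- function(curve, y, as_xyz = FALSE) {
  x <- curve$r_inner + curve$coeff * y^curve$power
  if (!as_xyz) return(x)
  cbind(x = x, y = y, z = rep(curve$plane_z, length(y)))
}

#' Leaflet (free-edge) curve from leaflet parameters
#'
#' Builds the analytic curve of the leaflet free edge in the plane `z = l_h`:
#' `f(y) = l_ri + alpha * y^l_p` with
#' `alpha = (l_ro cos(l_a) - l_ri) / (l_ro sin(l_a))^l_p`, so that
#' `f(0) = l_ri`, `f'(0) = 0`, and the curve meets the outer circle at the
#' commissure point `(l_ro cos(l_a), l_ro sin(l_a))`.
#'
#' @param params A [leaflet_params()] object.
#' @return A `power_curve` in the plane `z = l_h`.
#' @export
make_leaflet_curve <- function(params) {
  validate_leaflet_params(params)
  power_curve(params$l_ri, params$l_ro, params$l_a, params$l_p, params$l_h)
}

#' Bending curve from leaflet parameters
#'
#' Same construction as [make_leaflet_curve()] with the bending-plane
#' parameters: `g(y) = b_ri + beta * y^b_p` in the plane `z = b_h`, with
#' `beta = (b_ro cos(b_a) - b_ri) / (b_ro sin(b_a))^b_p`.
#'
#' @param params A [leaflet_params()] object.
#' @return A `power_curve` in the plane `z = b_h`.
#' @export
make_bending_curve <- function(params) {
  validate_leaflet_params(params)
  power_curve(params$b_ri, params$b_ro, params$b_a, params$b_p, params$b_h)
}

# ---------------------------------------------------------------------------
# Bezier curves

#' Bezier curve in 3D
#'
#' @param control An `(degree+1) x 3` matrix of control points (mm).
#' @return An object of class `bezier_curve`.
#' @export
bezier_curve <- function(control) {
  control <- as.matrix(control)
  if (ncol(control) != 3L || nrow(control) < 2L)
    stop("bezier_curve: control must be an (n>=2) x 3 matrix")
  storage.mode(control) <- "double"
  structure(list(control = control, degree = nrow(control) - 1L),
            class = "bezier_curve")
}

#' Evaluate a Bezier curve (Bernstein form, vectorized in t)
#'
#' @param curve A `bezier_curve`.
#' @param t Parameter value(s) in `[0, 1]`.
#' @return A `length(t) x 3` coordinate matrix.
#' @export
bezier_eval <- function(curve, t) {
  P <- curve$control
  d <- curve$degree
  B <- vapply(0:d, function(k) {
    choose(d, k) * (1 - t)^(d - k) * t^k
  }, numeric(length(t)))
  if (length(t) == 1L) B <- matrix(B, nrow = 1L)
  out <- B %*% P
  colnames(out) <- c("x", "y", "z")
  out
}

#' Split a Bezier curve with De Casteljau's algorithm
#'
#' Subdivides the curve at `t_split` into two Bezier curves of the same
#' degree, `lower` covering the original `[0, t_split]` and `upper` covering
#' `[t_split, 1]`, exactly (the split curves are reparametrizations of the
#' original restricted to the two subintervals).
#'
#' @param curve A `bezier_curve`.
#' @param t_split Split parameter, strictly inside `(0, 1)`.
#' @return A list with `bezier_curve` elements `lower` and `upper`.
#' @export
split_bezier <- function(curve, t_split) {
  if (!(t_split > 0 && t_split < 1))
    stop("split_bezier: t_split must be in (0,1)")
  P <- curve$control
  n <- nrow(P)
  lower <- matrix(0, n, 3)
  upper <- matrix(0, n, 3)
  lower[1, ] <- P[1, ]
  upper[n, ] <- P[n, ]
  lev <- P
  for (k in 2:n) {
    lev <- (1 - t_split) * lev[-nrow(lev), , drop = FALSE] +
      t_split * lev[-1, , drop = FALSE]
    lower[k, ] <- lev[1, ]
    upper[n - k + 1, ] <- lev[nrow(lev), ]
  }
  list(lower = bezier_curve(lower), upper = bezier_curve(upper))
}

#' Reverse a Bezier curve's orientation
#' @param curve A `bezier_curve`.
#' @return The same curve traversed from `t = 1` to `t = 0`.
#' @export
reverse_bezier <- function(curve) {
  bezier_curve(curve$control[nrow(curve$control):1, , drop = FALSE])
}

# ---------------------------------------------------------------------------
# Sinus and symmetry curves

#' Sinus curve (quadratic Bezier) of a half leaflet
#'
#' Replaces the sinus/interleaflet anatomy with a quadratic Bezier running
#' from the annulus-plane attachment `P0 = (r_r cos(l_a), r_r sin(l_a), 0)`
#' up to the commissure `P2 = (l_ro cos(l_a), l_ro sin(l_a), l_h)`. The middle
#' control point `P1` is solved so the curve passes through the bending-plane
#' outer point `(b_ro cos(b_a), b_ro sin(b_a), b_h)` — the point where the
#' bending curve meets the outer circle — at parameter `s_sin = b_h / l_h`.
#'
#' @param params A [leaflet_params()] object.
#' @param P0 Optional override for the start point (3-vector, mm).
#' @return A degree-2 `bezier_curve` with attribute `s_sin`.
#' @export
make_sinus_curve <- function(params, P0 = NULL) {
  validate_leaflet_params(params)
  s <- params$b_h / params$l_h
  if (s <= 0 || s >= 1) stop("make_sinus_curve: s_sin must be inside (0,1)")
  if (is.null(P0))
    P0 <- c(params$r_r * cos(params$l_a), params$r_r * sin(params$l_a), 0)
  P2 <- c(params$l_ro * cos(params$l_a), params$l_ro * sin(params$l_a),
          params$l_h)
  target <- c(params$b_ro * cos(params$b_a), params$b_ro * sin(params$b_a),
              params$b_h)
  P1 <- (target - (1 - s)^2 * P0 - s^2 * P2) / (2 * (1 - s) * s)
  out <- bezier_curve(rbind(P0, P1, P2))
  attr(out, "s_sin") <- s
  out
}

#' Symmetry curve (cubic Bezier) of a half leaflet
#'
#' The belly profile of the leaflet in its symmetry plane `y = 0`: a cubic
#' Bezier from the annulus point `Q0 = (r_r, 0, 0)` to the free-edge point
#' `Q3 = (l_ri, 0, l_h)`. `Q1` sets the departure tangent via the weights
#' `xQ1_sym`, `zQ1_sym` (default -0.2 each); `Q2` is solved so the curve
#' passes through the bending point `(b_ri, 0, b_h)` at parameter
#' `s_sym = b_h / l_h`.
#'
#' @param params A [leaflet_params()] object.
#' @return A degree-3 `bezier_curve` with attribute `s_sym`; every control
#'   point (hence the whole curve) has `y = 0`.
#' @export
make_symmetry_curve <- function(params) {
  validate_leaflet_params(params)
  s <- params$b_h / params$l_h
  if (s <= 0 || s >= 1) stop("make_symmetry_curve: s_sym must be inside (0,1)")
  Q0 <- c(params$r_r, 0, 0)
  Q3 <- c(params$l_ri, 0, params$l_h)
  Q1 <- c((params$r_r + params$b_ri) / 2 +
            params$xQ1_sym * (params$r_r - params$b_ri),
          0,
          params$b_h / 2 + params$zQ1_sym * params$b_h)
  target <- c(params$b_ri, 0, params$b_h)
  Q2 <- (target - (1 - s)^3 * Q0 - 3 * s * (1 - s)^2 * Q1 - s^3 * Q3) /
    (3 * s^2 * (1 - s))
  out <- bezier_curve(rbind(Q0, Q1, Q2, Q3))
  attr(out, "s_sym") <- s
  out
}

#' Cubic Bezier approximation of an analytic power curve
#'
#' The Coons construction needs all four patch boundaries as parametric
#' curves, so the analytic leaflet/bending curves are approximated by cubic
#' Beziers. End control points are the analytic endpoints; the inner control
#' points are placed along finite-difference estimates of the curve tangent
#' at the two ends, offset by the calibration weights `t0` (at the symmetry
#' line) and `t3` (at the commissure) expressed as fractions of the lateral
#' extent `y_max`:
#' `L1 = (L0_x + t0 y_max (f(L0_y + fd) - L0_x)/fd, L0_y + t0 y_max)` and
#' `L2 = (L3_x + t3 y_max (f(L3_y - fd) - L3_x)/fd, L3_y - t3 y_max)`.
#' The fractional form keeps the weights dimensionless and scale-invariant;
#' `t0 = t3 = 1/3` is the cubic-Hermite placement, exact for power-2 edges.
#'
#' @param curve A `power_curve`.
#' @param t0,t3 Tangent weights in `(0, 1)`, fractions of `y_max`.
#' @param fd_step Finite-difference step (mm); default `1e-6 * y_max / sin(a)`
#'   scale-free via the curve's outer radius.
#' @return A degree-3 `bezier_curve` in the plane `z = plane_z`, running from
#'   the symmetry line (`t = 0`) to the commissure (`t = 1`).
#' @export
approximate_edge_as_bezier <- function(curve, t0 = 0.3, t3 = 0.3,
                                       fd_step = 1e-6 * curve$r_outer) {
  if (!(t0 > 0 && t0 < 1) || !(t3 > 0 && t3 < 1))
    stop("approximate_edge_as_bezier: t0, t3 must lie in (0,1)")
  if (fd_step <= 0) stop("approximate_edge_as_bezier: fd_step must be > 0")
  y0 <- 0
  y3 <- curve$y_max
  if (y3 - fd_step < 0)
    stop("approximate_edge_as_bezier: fd_step exceeds the curve extent")
  L0 <- c(power_curve_eval(curve, y0), y0)
  L3 <- c(power_curve_eval(curve, y3), y3)
  s0 <- t0 * y3
  s3 <- t3 * y3
  L1 <- c(L0[1] + s0 * (power_curve_eval(curve, y0 + fd_step) - L0[1]) / fd_step,
          L0[2] + s0)
  L2 <- c(L3[1] + s3 * (power_curve_eval(curve, y3 - fd_step) - L3[1]) / fd_step,
          L3[2] - s3)
  z <- curve$plane_z
  bezier_curve(rbind(c(L0, z), c(L1, z), c(L2, z), c(L3, z)))
}

#' Calibrate the edge-approximation tangent weights
#'
#' The weights `t0`, `t3` that place the inner control points of the cubic
#' edge Beziers depend mostly on the curve power and must be calibrated per
#' parameter set. This performs a grid search over weight pairs, scoring each
#' candidate by the maximum distance from a dense sampling of the Bezier to
#' the analytic curve, for both the leaflet and the bending curve, and
#' returns the pair minimizing the worse of the two.
#'
#' @param params A [leaflet_params()] object.
#' @param grid Candidate weight values (each in `(0, 1)`).
#' @return A list with `t0`, `t3` and the achieved `max_error` (mm).
#' @export
calibrate_edge_weights <- function(params, grid = seq(0.1, 0.9, by = 0.1)) {
  curves <- list(make_leaflet_curve(params), make_bending_curve(params))
  dense <- lapply(curves, function(cv)
    power_curve_eval(cv, seq(0, cv$y_max, length.out = 400), as_xyz = TRUE))
  score <- function(t0, t3) {
    max(vapply(seq_along(curves), function(i) {
      bz <- approximate_edge_as_bezier(curves[[i]], t0, t3)
      samp <- bezier_eval(bz, seq(0, 1, length.out = 101))
      an <- dense[[i]]
      D2 <- outer(rowSums(samp^2), rowSums(an^2), "+") -
        2 * samp %*% t(an)
      max(apply(D2, 1, min))
    }, 0))
  }
  best <- c(NA, NA, Inf)
  for (t0 in grid) for (t3 in grid) {
    s <- score(t0, t3)
    if (s < best[3]) best <- c(t0, t3, s)
  }
  list(t0 = best[1], t3 = best[2], max_error = sqrt(best[3]))
}

# ---------------------------------------------------------------------------
# Circular arc (annulus attachment boundary of the bottom patch)

#' Circular arc curve at constant height
#'
#' @param radius Arc radius (mm).
#' @param plane_z Height (mm).
#' @param angle0,angle1 Start/end angle (rad); parameter `t = 0` maps to
#'   `angle0`, `t = 1` to `angle1`.
#' @return An object of class `arc_curve`.
#' @export
arc_curve <- function(radius, plane_z, angle0, angle1) {
  structure(list(radius = radius, plane_z = plane_z,
                 angle0 = angle0, angle1 = angle1),
            class = "arc_curve")
}

#' Evaluate a patch boundary curve at parameter values
#'
#' Generic evaluator used by the Coons machinery: dispatches on
#' `bezier_curve` and `arc_curve`.
#'
#' @param curve A boundary curve object.
#' @param t Parameter value(s) in `[0, 1]`.
#' @return A `length(t) x 3` coordinate matrix.
#' @export
curve_eval <- function(curve, t) UseMethod("curve_eval")

#' @export
curve_eval.bezier_curve <- function(curve, t) bezier_eval(curve, t)

#' @export
curve_eval.arc_curve <- function(curve, t) {
  a <- curve$angle0 + t * (curve$angle1 - curve$angle0)
  cbind(x = curve$radius * cos(a), y = curve$radius * sin(a),
        z = rep(curve$plane_z, length(t)))
}
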