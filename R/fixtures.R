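#' Synthetic valve parameter cohorts
#'
#' The imaging protocol that produces per-patient leaflet parameters is out of
#' scope here, so the package ships a deterministic generator of plausible
#' parameter sets spanning healthy to severely stenotic valves. The ranges are
#' package choices grounded in normal adult aortic dimensions, *not* taken
#' from any published patient table: aortic radius `l_ro` 12-16 mm, annulus
#' `r_r` 10-14 mm, leaflet height `l_h` 8-12 mm, bending height about half the
#' leaflet height, and an orifice ratio `l_ri / l_ro` stepping from 0.55
#' (healthy) down to 0.15 (severe). Curve powers grow with severity (stiffer,
#' flatter bellies), within 2-6.
#'
#' @param name One of `"healthy"`, `"mild"`, `"moderate"`, `"severe"`.
#' @param seed Optional integer seed controlling the per-leaflet asymmetry
#'   jitter. The same seed always yields the same cohort; `NULL` (default)
#'   disables jitter entirely, giving three identical leaflets.
#' @param jitter Relative jitter amplitude applied per leaflet to radii and
#'   powers, and (sum-preservingly) to the half-angles. Defaults to 0.05 when
#'   a seed is given, 0 otherwise.
#' @return A list of three [leaflet_params()] objects with `theta` at 0, 120
#'   and 240 degrees, carrying attributes `name` and `seed`.
#' @examples
#' fx <- generate_fixture("severe", seed = 42)
#' orifice_area(fx) < orifice_area(generate_fixture("healthy", seed = 42))
#' @export
generate_fixture <- function(name = c("healthy", "mild", "moderate", "severe"),
                             seed = NULL,
                             jitter = if (is.null(seed)) 0 else 0.05) {
  name <- match.arg(name)
  grade <- c(healthy = 1, mild = 2, moderate = 3, severe = 4)[[name]]
  base <- list(
    l_ro = 14, r_r = 12, l_h = 10, b_h = 5, b_ro = 13,
    l_a = pi / 3, b_a = pi / 3,
    ri_ratio = c(0.55, 0.42, 0.28, 0.15)[grade],
    l_p = c(2, 3, 4, 5)[grade],
    b_p = c(2, 2.5, 3, 3.5)[grade])

  jit <- matrix(0, 3, 4)
  da <- c(0, 0, 0)
  if (jitter > 0) {
    if (is.null(seed)) stop("generate_fixture: jitter > 0 requires a seed")
    rng <- (function(s) {
      old <- if (exists(".Random.seed", .GlobalEnv))
        get(".Random.seed", .GlobalEnv) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
      set.seed(as.integer(s))
      list(jit = matrix(rnorm(12, 0, 1), 3, 4), da = rnorm(3, 0, 1))
    })(seed)
    jit <- pmax(pmin(rng$jit, 2), -2) * jitter
    # half-angle jitter redistributed so the three leaflets still close
    da <- (rng$da - mean(rng$da)) * jitter * base$l_a
  }

  lapply(1:3, function(i) {
    l_ri <- base$ri_ratio * base$l_ro * (1 + jit[i, 1])
    b_ri <- (l_ri + 0.35 * (base$r_r - l_ri)) * (1 + jit[i, 2])
    p <- leaflet_params(
      l_ro = base$l_ro, l_ri = l_ri,
      l_a = base$l_a + da[i], l_p = max(1.5, base$l_p * (1 + jit[i, 3])),
      l_h = base$l_h, r_r = base$r_r,
      b_ro = base$b_ro, b_ri = b_ri,
      b_a = base$b_a + da[i], b_p = max(1.5, base$b_p * (1 + jit[i, 4])),
      b_h = base$b_h, theta = (i - 1) * 2 * pi / 3)
    # tangent weights are power-dependent; calibrate them per leaflet
    cal <- calibrate_edge_weights(p)
    p$t0 <- cal$t0
    p$t3 <- cal$t3
    attr(p, "name") <- name
    p
  }) -> out
  attr(out, "name") <- name
  attr(out, "seed") <- seed
  out
}

#' Orifice area enclosed by the three free edges
#'
#' Samples each leaflet's free-edge curve (both mirrored halves) at the
#' leaflet plane, orders the points by azimuth around the valve axis, and
#' applies the shoelace formula. Used to rank fixtures by stenosis severity.
#'
#' @param leaflets A list of three [leaflet_params()] objects.
#' @param n Samples per half free edge.
#' @return Orifice area in mm^2.
#' @export
orifice_area <- function(leaflets, n = 100) {
  pts <- do.call(rbind, lapply(leaflets, function(p) {
    cv <- make_leaflet_curve(p)
    y <- seq(0, cv$y_max, length.out = n)
    loc <- power_curve_eval(cv, y, as_xyz = TRUE)
    both <- rbind(loc, cbind(loc[, 1], -loc[, 2], loc[, 3]))
    both[, 1:2] %*% t(rot_z(p$theta)[1:2, 1:2])
  }))
  ang <- atan2(pts[, 2], pts[, 1])
  o <- order(ang)
  x <- pts[o, 1]; y <- pts[o, 2]
  xs <- c(x, x[1]); ys <- c(y, y[1])
  abs(sum(xs[-1] * ys[-length(ys)] - xs[-length(xs)] * ys[-1])) / 2
}
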