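#' Per-leaflet valve parameters
#'
#' Bundles the scalar parameters that drive every curve of one aortic-valve
#' leaflet: the free-edge (leaflet) curve at height `l_h`, the bending curve at
#' height `b_h`, the annulus attachment, and the Bezier tangent weights used
#' when the analytic curves are approximated and when the symmetry curve is
#' built. All lengths are millimetres, all angles radians (see
#' [leaflet_params_from_degrees()] for the file-facing degree form).
#'
#' @param l_ro Outer (aortic) radius at the leaflet plane `z = l_h` (mm).
#' @param l_ri Inner-circle radius at the leaflet plane; the valve opening at
#'   the symmetry line (mm). Must satisfy `0 < l_ri < l_ro`.
#' @param l_a Leaflet half-angle (rad), in `(0, pi/2)`.
#' @param l_p Leaflet power (dimensionless, `> 1`), controls how sharply the
#'   free edge sweeps from the inner circle to the commissure.
#' @param l_h Leaflet height (mm): the `z` level of the free edge.
#' @param r_r Annulus radius (mm): the lowest attachment ring at `z = 0`.
#' @param b_ro,b_ri,b_a,b_p Bending-curve analogues of `l_ro, l_ri, l_a, l_p`,
#'   defined at `z = b_h`.
#' @param b_h Bending height (mm), strictly between 0 and `l_h`.
#' @param theta Rotation of this leaflet about the valve axis (rad).
#' @param t0,t3 Edge-Bezier tangent weights in `(0, 1)` used when the analytic
#'   leaflet/bending curves are approximated by cubic Beziers.
#' @param xQ1_sym,zQ1_sym Symmetry-curve tangent weights (default `-0.2` each).
#'
#' @return An object of class `leaflet_params` (a named list).
#' @examples
#' p <- leaflet_params(l_ro = 14, l_ri = 7, l_a = pi / 3, l_p = 2, l_h = 10,
#'                     r_r = 12, b_ro = 13, b_ri = 8, b_a = pi / 3, b_p = 2,
#'                     b_h = 5)
#' p$l_ri
#' @export
leaflet_params <- function(l_ro, l_ri, l_a, l_p, l_h, r_r,
                           b_ro, b_ri, b_a, b_p, b_h,
                           theta = 0, t0 = 0.3, t3 = 0.3,
                           xQ1_sym = -0.2, zQ1_sym = -0.2) {
  p <- list(l_ro = l_ro, l_ri = l_ri, l_a = l_a, l_p = l_p, l_h = l_h,
            r_r = r_r, b_ro = b_ro, b_ri = b_ri, b_a = b_a, b_p = b_p,
            b_h = b_h, theta = theta, t0 = t0, t3 = t3,
            xQ1_sym = xQ1_sym, zQ1_sym = zQ1_sym)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("leaflet_params: '", nm, "' must be a finite numeric scalar")
  }
  class(p) <- "leaflet_params"
  validate_leaflet_params(p)
  p
}

#' Validate leaflet parameters
#'
#' Checks the geometric invariants every leaflet parameter set must satisfy
#' (positivity, ordering of radii, angle and power ranges, tangent weights in
#' the open unit interval). Called by [leaflet_params()]; exported so parameter
#' sets read from files can be re-checked.
#'
#' @param p A `leaflet_params` object.
#' @return `p`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_leaflet_params <- function(p) {
  chk <- function(ok, msg) if (!ok) stop("leaflet_params: ", msg, call. = FALSE)
  chk(p$l_ri > 0 && p$l_ri < p$l_ro, "requires 0 < l_ri < l_ro")
  chk(p$b_ri > 0 && p$b_ri <= p$b_ro, "requires 0 < b_ri <= b_ro")
  chk(p$b_h > 0 && p$b_h < p$l_h, "requires 0 < b_h < l_h")
  chk(p$l_a > 0 && p$l_a < pi / 2, "requires 0 < l_a < pi/2")
  chk(p$b_a > 0 && p$b_a < pi / 2, "requires 0 < b_a < pi/2")
  chk(p$l_p > 1, "requires l_p > 1")
  chk(p$b_p > 1, "requires b_p > 1")
  chk(p$r_r > 0, "requires r_r > 0")
  chk(p$t0 > 0 && p$t0 < 1, "requires t0 in (0,1)")
  chk(p$t3 > 0 && p$t3 < 1, "requires t3 in (0,1)")
  invisible(p)
}

#' Build leaflet parameters from a degree-valued list
#'
#' Parameter files store angles in degrees; internally everything is radians.
#' This converts the angle fields (`l_a`, `b_a`, `theta`) and passes the rest
#' through to [leaflet_params()].
#'
#' @param x A named list with the fields of [leaflet_params()], angles in
#'   degrees.
#' @return A `leaflet_params` object (angles in radians).
#' @export
leaflet_params_from_degrees <- function(x) {
  x <- as.list(x)
  for (nm in c("l_a", "b_a", "theta"))
    if (!is.null(x[[nm]])) x[[nm]] <- x[[nm]] * pi / 180
  do.call(leaflet_params, x)
}

#' @export
print.leaflet_params <- function(x, ...) {
  cat("Leaflet parameters (mm / rad):\n")
  cat(sprintf("  leaflet plane z=%g: l_ro=%g l_ri=%g l_a=%.4f l_p=%g\n",
              x$l_h, x$l_ro, x$l_ri, x$l_a, x$l_p))
  cat(sprintf("  bending plane z=%g: b_ro=%g b_ri=%g b_a=%.4f b_p=%g\n",
              x$b_h, x$b_ro, x$b_ri, x$b_a, x$b_p))
  cat(sprintf("  annulus r_r=%g  theta=%.4f  t0=%g t3=%g\n",
              x$r_r, x$theta, x$t0, x$t3))
  invisible(x)
}
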