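#' Coons patch from four boundary curves
#'
#' Bilinearly blends four boundary curves into a surface
#' `h(u, v) = (1-v) S(u) + v N(u) + (1-u) W(v) + u E(v) - bilinear(corners)`,
#' the classic Coons construction: the ruled surfaces between opposite edges
#' are summed and the bilinear interpolant of the corners subtracted so each
#' boundary is reproduced exactly. The south edge (`v = 0`) is the bending
#' curve for the top half-leaflet patch and the annulus arc for the bottom
#' one; north (`v = 1`) the leaflet curve resp. bending curve; west/east
#' (`u = 0` / `u = 1`) the symmetry resp. sinus sub-curves.
#'
#' @param south,north Curves parameterized by `u` (symmetry line at `u = 0`,
#'   sinus side at `u = 1`).
#' @param west,east Curves parameterized by `v` (south end at `v = 0`).
#' @param corner_tol Maximum allowed corner mismatch (mm) between the two
#'   edges meeting at each corner; exceeded mismatches raise an error naming
#'   the offending corner.
#' @return An object of class `coons_patch` with the four edges and the
#'   corner matrix (rows `SW`, `SE`, `NW`, `NE`).
#' @export
make_coons_patch <- function(south, north, west, east, corner_tol = 1e-8) {
  corn <- rbind(
    (curve_eval(south, 0) + curve_eval(west, 0)) / 2,
    (curve_eval(south, 1) + curve_eval(east, 0)) / 2,
    (curve_eval(north, 0) + curve_eval(west, 1)) / 2,
    (curve_eval(north, 1) + curve_eval(east, 1)) / 2)
  rownames(corn) <- c("SW", "SE", "NW", "NE")
  mism <- c(
    SW = sqrt(sum((curve_eval(south, 0) - curve_eval(west, 0))^2)),
    SE = sqrt(sum((curve_eval(south, 1) - curve_eval(east, 0))^2)),
    NW = sqrt(sum((curve_eval(north, 0) - curve_eval(west, 1))^2)),
    NE = sqrt(sum((curve_eval(north, 1) - curve_eval(east, 1))^2)))
  if (any(mism > corner_tol)) {
    bad <- names(mism)[which.max(mism)]
    stop(sprintf(
      "make_coons_patch: corner %s mismatch %.3e mm exceeds tolerance %.1e",
      bad, max(mism), corner_tol))
  }
  structure(list(south = south, north = north, west = west, east = east,
                 corners = corn),
            class = "coons_patch")
}

#' Evaluate a Coons patch
#'
#' @param patch A `coons_patch`.
#' @param u,v Parameter vectors of equal length (or length 1, recycled),
#'   values in `[0, 1]`.
#' @return A `n x 3` coordinate matrix (mm).
#' @export
coons_eval <- function(patch, u, v) {
  n <- max(length(u), length(v))
  u <- rep_len(u, n)
  v <- rep_len(v, n)
  C <- patch$corners
  ruled <- (1 - v) * curve_eval(patch$south, u) +
    v * curve_eval(patch$north, u) +
    (1 - u) * curve_eval(patch$west, v) +
    u * curve_eval(patch$east, v)
  bil <- cbind((1 - u) * (1 - v), u * (1 - v), (1 - u) * v, u * v) %*% C
  out <- ruled - bil
  colnames(out) <- c("x", "y", "z")
  out
}

#' Build the two Coons patches of one half leaflet
#'
#' Approximates the leaflet and bending analytic curves by cubic Beziers,
#' splits the sinus and symmetry curves at the bending plane
#' (`s = b_h / l_h`) with De Casteljau's algorithm, and assembles the top
#' patch (between bending and leaflet curves) and bottom patch (between the
#' annulus boundary and the bending curve). The two patches share the bending
#' Bezier pointwise.
#'
#' @param params A [leaflet_params()] object.
#' @param P0_sinus Optional override of the sinus-curve start point; the
#'   default is the annulus point beneath the commissure,
#'   `(r_r cos(l_a), r_r sin(l_a), 0)`.
#' @param annulus_edge Either `"arc"` (default; circular arc of radius `r_r`
#'   at `z = 0` from angle 0 to `l_a`) or `"point"` (degenerate bottom edge
#'   collapsed onto `Q0`, which also forces `P0 = Q0`).
#' @return A list with `coons_patch` elements `top` and `bottom`, plus the
#'   constituent `curves`.
#' @export
build_half_leaflet <- function(params, P0_sinus = NULL,
                               annulus_edge = c("arc", "point")) {
  validate_leaflet_params(params)
  annulus_edge <- match.arg(annulus_edge)
  if (annulus_edge == "point" && is.null(P0_sinus))
    P0_sinus <- c(params$r_r, 0, 0)

  leaflet_an <- make_leaflet_curve(params)
  bending_an <- make_bending_curve(params)
  leaflet_bz <- approximate_edge_as_bezier(leaflet_an, params$t0, params$t3)
  bending_bz <- approximate_edge_as_bezier(bending_an, params$t0, params$t3)

  sinus <- make_sinus_curve(params, P0 = P0_sinus)
  sym <- make_symmetry_curve(params)
  s_sin <- attr(sinus, "s_sin")
  s_sym <- attr(sym, "s_sym")
  sinus_sp <- split_bezier(sinus, s_sin)
  sym_sp <- split_bezier(sym, s_sym)

  # Top patch: south = bending curve, north = leaflet curve; the west/east
  # edges are the upper sub-curves oriented with v = 0 on the bending plane.
  top <- make_coons_patch(south = bending_bz, north = leaflet_bz,
                          west = sym_sp$upper, east = sinus_sp$upper)

  south_bottom <- if (annulus_edge == "arc") {
    arc_curve(params$r_r, 0, 0, params$l_a)
  } else {
    bezier_curve(rbind(c(params$r_r, 0, 0), c(params$r_r, 0, 0)))
  }
  bottom <- make_coons_patch(south = south_bottom, north = bending_bz,
                             west = sym_sp$lower, east = sinus_sp$lower)

  list(top = top, bottom = bottom,
       curves = list(leaflet_analytic = leaflet_an,
                     bending_analytic = bending_an,
                     leaflet_bezier = leaflet_bz,
                     bending_bezier = bending_bz,
                     sinus = sinus, symmetry = sym,
                     sinus_split = sinus_sp, symmetry_split = sym_sp))
}

#' Assemble the full three-leaflet valve surface set
#'
#' Each leaflet contributes two Coons patches built in its local frame
#' (symmetry plane `y = 0`); the mirrored half is realized by reflecting the
#' query/sample point across that plane, and the leaflet is rotated by its
#' `theta` about the valve (`z`) axis. Inter-leaflet symmetry is *not*
#' enforced: the three parameter sets may differ freely. Two soft validations
#' are reported as warnings, never errors: the half-angle sum
#' `sum(2 * l_a)` deviating from `2*pi`, and adjacent commissure points
#' farther apart than `gap_tol`.
#'
#' @param leaflets A list of three [leaflet_params()] objects (each carrying
#'   its own `theta`).
#' @param angle_tol Tolerance (rad) on `|sum(2 l_a) - 2 pi|` before warning.
#' @param gap_tol Tolerance (mm) on adjacent commissure gaps before warning.
#' @param ... Passed to [build_half_leaflet()].
#' @return An object of class `valve_surface`: a list with `patches` (six
#'   entries, each `list(patch, theta, leaflet, part)`), the input
#'   parameters, and summary extents `max_l_ro`, `max_l_h`.
#' @export
assemble_valve <- function(leaflets, angle_tol = 5 * pi / 180, gap_tol = 1.0,
                           ...) {
  if (length(leaflets) != 3L)
    stop("assemble_valve: exactly three leaflet parameter sets are required")
  lapply(leaflets, validate_leaflet_params)

  patches <- list()
  for (i in 1:3) {
    hl <- build_half_leaflet(leaflets[[i]], ...)
    patches[[length(patches) + 1L]] <-
      list(patch = hl$top, theta = leaflets[[i]]$theta, leaflet = i,
           part = "top")
    patches[[length(patches) + 1L]] <-
      list(patch = hl$bottom, theta = leaflets[[i]]$theta, leaflet = i,
           part = "bottom")
  }

  angle_sum <- sum(vapply(leaflets, function(p) 2 * p$l_a, 0))
  if (abs(angle_sum - 2 * pi) > angle_tol)
    warning(sprintf(
      "assemble_valve: leaflet half-angles sum to %.1f deg (expected 360)",
      angle_sum * 180 / pi))

  # Commissures: leaflet i's sinus-side commissure sits at theta_i + l_a_i;
  # its mirrored twin at theta_i - l_a_i. Adjacent leaflets should meet.
  comm <- lapply(leaflets, function(p) {
    pt <- c(p$l_ro * cos(p$l_a), p$l_ro * sin(p$l_a), p$l_h)
    list(plus = rot_z(p$theta) %*% pt,
         minus = rot_z(p$theta) %*% c(pt[1], -pt[2], pt[3]))
  })
  gaps <- vapply(1:3, function(i) {
    j <- i %% 3 + 1
    sqrt(sum((comm[[i]]$plus - comm[[j]]$minus)^2))
  }, 0)
  if (any(gaps > gap_tol))
    warning(sprintf(
      "assemble_valve: commissure gap(s) up to %.2f mm exceed %.2f mm",
      max(gaps), gap_tol))

  structure(list(patches = patches, leaflets = leaflets,
                 commissure_gaps = gaps, angle_sum = angle_sum,
                 max_l_ro = max(vapply(leaflets, `[[`, 0, "l_ro")),
                 max_l_h = max(vapply(leaflets, `[[`, 0, "l_h"))),
            class = "valve_surface")
}

# rotation about the valve (z) axis
rot_z <- function(theta) {
  c <- cos(theta); s <- sin(theta)
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3)
}

#' Evaluate one valve patch in world coordinates
#'
#' @param valve A `valve_surface`.
#' @param i Patch index, 1..6.
#' @param u,v Parameter vectors in `[0, 1]`.
#' @param mirrored If `TRUE`, evaluate the mirrored half (reflection across
#'   the leaflet's local `y = 0` plane before rotation).
#' @return A `n x 3` coordinate matrix (mm) in the valve frame.
#' @export
valve_patch_eval <- function(valve, i, u, v, mirrored = FALSE) {
  entry <- valve$patches[[i]]
  pts <- coons_eval(entry$patch, u, v)
  if (mirrored) pts[, 2] <- -pts[, 2]
  pts %*% t(rot_z(entry$theta))
}

#' @export
print.valve_surface <- function(x, ...) {
  cat("Aortic valve surface set: 6 Coons patches (3 leaflets x top/bottom)\n")
  cat(sprintf("  max l_ro = %.2f mm, max l_h = %.2f mm\n",
              x$max_l_ro, x$max_l_h))
  cat(sprintf("  half-angle sum = %.1f deg; commissure gaps = %s mm\n",
              x$angle_sum * 180 / pi,
              paste(sprintf("%.3f", x$commissure_gaps), collapse = ", ")))
  invisible(x)
}
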