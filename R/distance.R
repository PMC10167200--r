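#' Resistive field configuration
#'
#' @param C Penalization constant added to the momentum equation on the valve
#'   (default `1e8`, a value large enough to drive the velocity on the
#'   leaflets to a negligible fraction of the inlet peak).
#' @param h_phys Physiological leaflet thickness (mm, `>= 0`); keeps the
#'   resistive layer from thinning below anatomy under mesh refinement.
#' @param epsilon_override Optional explicit half-thickness (mm), bypassing
#'   the `max(h_phys/2, 0.75 h_max)` rule.
#' @return An object of class `resistive_config`.
#' @export
resistive_config <- function(C = 1e8, h_phys = 0, epsilon_override = NULL) {
  if (C <= 0) stop("resistive_config: C must be > 0")
  if (h_phys < 0) stop("resistive_config: h_phys must be >= 0")
  structure(list(C = C, h_phys = h_phys,
                 epsilon_override = epsilon_override),
            class = "resistive_config")
}

#' Resistive layer half-thickness
#'
#' `epsilon = max(h_phys / 2, 0.75 * h_max)`: 75% of the maximum mesh size
#' keeps the thresholded layer free of holes, while the physiological floor
#' prevents it from collapsing below the anatomical leaflet thickness when
#' the mesh is refined. An explicit `override` wins over both.
#'
#' @param h_max Maximum mesh size (mm, `> 0`).
#' @param h_phys Physiological leaflet thickness (mm, `>= 0`).
#' @param override Optional explicit epsilon (mm).
#' @return Epsilon in mm.
#' @examples
#' compute_epsilon(0.75)       # 0.5625, the fine-preset coarse mesh
#' compute_epsilon(0.5, 2.0)   # floor active: 1.0
#' @export
compute_epsilon <- function(h_max, h_phys = 0, override = NULL) {
  if (!is.null(override)) return(override)
  if (h_max <= 0) stop("compute_epsilon: h_max must be > 0")
  if (h_phys < 0) stop("compute_epsilon: h_phys must be >= 0")
  max(h_phys / 2, 0.75 * h_max)
}

# All 12 sheets of the valve: 6 patches x {plain, mirrored}
valve_sheets <- function(valve) {
  sheets <- list()
  for (i in seq_along(valve$patches))
    for (mir in c(FALSE, TRUE))
      sheets[[length(sheets) + 1L]] <- list(patch_index = i, mirrored = mir)
  sheets
}

# Dense (u,v) samples of every sheet; returns per-sheet point matrices plus
# the largest adjacent-sample spacing (a bound on the grid-search error).
valve_surface_samples <- function(valve, n = 41) {
  u <- rep(seq(0, 1, length.out = n), times = n)
  v <- rep(seq(0, 1, length.out = n), each = n)
  sheets <- valve_sheets(valve)
  out <- vector("list", length(sheets))
  spacing <- 0
  for (k in seq_along(sheets)) {
    s <- sheets[[k]]
    pts <- valve_patch_eval(valve, s$patch_index, u, v,
                            mirrored = s$mirrored)
    idx <- matrix(seq_len(n * n), n, n)
    du <- pts[as.vector(idx[-1, ]), ] - pts[as.vector(idx[-n, ]), ]
    dv <- pts[as.vector(idx[, -1]), ] - pts[as.vector(idx[, -n]), ]
    spacing <- max(spacing, sqrt(max(rowSums(du^2), rowSums(dv^2))))
    out[[k]] <- pts
  }
  list(sheets = sheets, points = out, n = n, max_spacing = spacing,
       u = u, v = v)
}

# nearest dense-sample distance (and its sheet/uv) for a block of points
nearest_sample <- function(points, samples, chunk = 2000L) {
  npt <- nrow(points)
  best_d2 <- rep(Inf, npt)
  best_sheet <- integer(npt)
  best_idx <- integer(npt)
  for (k in seq_along(samples$points)) {
    S <- samples$points[[k]]
    s2 <- rowSums(S^2)
    for (i0 in seq(1L, npt, by = chunk)) {
      i1 <- min(npt, i0 + chunk - 1L)
      X <- points[i0:i1, , drop = FALSE]
      D2 <- outer(rowSums(X^2), s2, "+") - 2 * X %*% t(S)
      j <- max.col(-D2, ties.method = "first")
      d2 <- D2[cbind(seq_len(nrow(D2)), j)]
      upd <- d2 < best_d2[i0:i1]
      ii <- (i0:i1)[upd]
      best_d2[ii] <- d2[upd]
      best_sheet[ii] <- k
      best_idx[ii] <- j[upd]
    }
  }
  list(d = sqrt(pmax(best_d2, 0)), sheet = best_sheet,
       u = samples$u[best_idx], v = samples$v[best_idx])
}

# local box-constrained minimization of the point-to-patch distance
refine_distance <- function(point, valve, sheet, u0, v0) {
  s <- sheet
  obj <- function(par) {
    p <- valve_patch_eval(valve, s$patch_index, par[1], par[2],
                          mirrored = s$mirrored)
    sum((p - point)^2)
  }
  res <- tryCatch(
    optim(c(u0, v0), obj, method = "L-BFGS-B", lower = 0, upper = 1,
          control = list(factr = 10, pgtol = 1e-14, maxit = 200,
                         ndeps = c(1e-7, 1e-7))),
    error = function(e) NULL)
  if (is.null(res)) {
    # optimizer failure: refined grid fallback
    warning("distance minimization failed to converge; using refined grid")
    g <- seq(0, 1, length.out = 101)
    uu <- rep(g, 101); vv <- rep(g, each = 101)
    pts <- valve_patch_eval(valve, s$patch_index, uu, vv,
                            mirrored = s$mirrored)
    return(sqrt(min(rowSums((pts - matrix(point, nrow(pts), 3,
                                          byrow = TRUE))^2))))
  }
  sqrt(res$value)
}

#' Minimum distance from points to the valve surface
#'
#' For each query point, evaluates a coarse `coarse_n x coarse_n` parameter
#' grid on every patch (and every mirrored half, i.e. the reflected query is
#' covered by sampling the mirrored sheet), picks the best candidates, and
#' polishes them with box-constrained local minimization over the closed
#' parameter square. This realizes the nodewise distance minimization that
#' defines the resistive surface.
#'
#' @param points A 3-vector or an `n x 3` matrix (mm, valve frame).
#' @param valve A `valve_surface`.
#' @param coarse_n Coarse multistart grid resolution per patch (default 7).
#' @param top_k Number of best candidate sheets polished per point.
#' @return Numeric vector of distances (mm).
#' @export
min_distance_to_valve <- function(points, valve, coarse_n = 7, top_k = 4) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  samples <- valve_surface_samples(valve, n = coarse_n)
  sheets <- samples$sheets
  npt <- nrow(points)
  # coarse distances to every sheet
  d2s <- matrix(Inf, npt, length(sheets))
  arg <- matrix(0L, npt, length(sheets))
  for (k in seq_along(samples$points)) {
    S <- samples$points[[k]]
    D2 <- outer(rowSums(points^2), rowSums(S^2), "+") - 2 * points %*% t(S)
    j <- max.col(-D2, ties.method = "first")
    d2s[, k] <- D2[cbind(seq_len(npt), j)]
    arg[, k] <- j
  }
  out <- numeric(npt)
  for (i in seq_len(npt)) {
    ord <- order(d2s[i, ])[seq_len(min(top_k, ncol(d2s)))]
    # the best coarse sample is itself on the surface: a valid upper bound
    best <- sqrt(max(min(d2s[i, ]), 0))
    for (k in ord) {
      d <- refine_distance(points[i, ], valve, sheets[[k]],
                           samples$u[arg[i, k]], samples$v[arg[i, k]])
      best <- min(best, d)
    }
    out[i] <- best
  }
  out
}

#' Build the resistive function gamma on a volume mesh
#'
#' Computes the nodewise minimum distance `d` from the mesh to the valve
#' surface set and thresholds it: `gamma = C` where `d <= epsilon` (inclusive
#' at equality), 0 elsewhere. A dense-sample prefilter decides most nodes
#' without optimization: a node whose nearest dense sample is within
#' `epsilon` is certainly inside the layer, one farther than
#' `epsilon + max sample spacing` certainly outside; only the ambiguous shell
#' is polished with the local minimizer. The prefilter never changes a value,
#' it only skips provably decided nodes.
#'
#' @param mesh A `volume_mesh`.
#' @param valve A `valve_surface`.
#' @param config A [resistive_config()].
#' @param sample_n Dense prefilter grid resolution per patch.
#' @return An object of class `gamma_field`: `values` (one per node, each 0
#'   or `C`), `epsilon_used` (mm), `support_count`, and the refined node
#'   distances available as attribute `"shell_distances"`.
#' @export
build_gamma <- function(mesh, valve, config = resistive_config(),
                        sample_n = 41) {
  eps <- compute_epsilon(mesh$h_max, config$h_phys, config$epsilon_override)
  samples <- valve_surface_samples(valve, n = sample_n)
  near <- nearest_sample(mesh$nodes, samples)
  delta <- samples$max_spacing

  inside <- near$d <= eps
  ambiguous <- which(!inside & near$d <= eps + delta)
  shell_d <- numeric(0)
  if (length(ambiguous)) {
    shell_d <- vapply(ambiguous, function(i) {
      min(near$d[i],
          refine_distance(mesh$nodes[i, ], valve,
                          samples$sheets[[near$sheet[i]]],
                          near$u[i], near$v[i]))
    }, 0)
    inside[ambiguous] <- shell_d <= eps
  }

  values <- ifelse(inside, config$C, 0)
  support <- sum(inside)
  if (support == 0L)
    warning("build_gamma: empty support; valve does not touch the mesh")
  else
    check_support_connectivity(mesh, inside)

  structure(list(values = values, epsilon_used = eps,
                 support_count = support, C = config$C),
            class = "gamma_field",
            shell_distances = shell_d, shell_nodes = ambiguous)
}

# warn if the gamma support splits into many components (holes in leaflets)
check_support_connectivity <- function(mesh, inside, max_components = 6L) {
  ids <- which(inside)
  if (length(ids) < 2L) return(invisible())
  remap <- integer(nrow(mesh$nodes)); remap[ids] <- seq_along(ids)
  cells <- mesh$cells
  pairs <- rbind(cells[, c(1, 2)], cells[, c(1, 3)], cells[, c(1, 4)],
                 cells[, c(2, 3)], cells[, c(2, 4)], cells[, c(3, 4)])
  keep <- inside[pairs[, 1]] & inside[pairs[, 2]]
  pairs <- pairs[keep, , drop = FALSE]
  parent <- seq_along(ids)
  find <- function(a) { while (parent[a] != a) { parent[a] <<- parent[parent[a]]; a <- parent[a] }; a }
  for (r in seq_len(nrow(pairs))) {
    a <- find(remap[pairs[r, 1]]); b <- find(remap[pairs[r, 2]])
    if (a != b) parent[a] <- b
  }
  ncomp <- length(unique(vapply(seq_along(ids), find, 0L)))
  if (ncomp > max_components)
    warning(sprintf(
      "build_gamma: support splits into %d components; the resistive layer may have holes (consider increasing epsilon)",
      ncomp))
  invisible(ncomp)
}

#' Export a gamma field as VTK point data
#'
#' @param field A `gamma_field`.
#' @param mesh The `volume_mesh` it lives on.
#' @param path Output path (legacy ASCII VTK). Values are written in full
#'   precision, so reading the file back reproduces them bitwise.
#' @return `path`, invisibly.
#' @export
export_gamma <- function(field, mesh, path) {
  if (length(field$values) != nrow(mesh$nodes))
    stop("export_gamma: field/mesh size mismatch")
  write_vtk_mesh(mesh, path, point_data = list(gamma = field$values))
}

#' @export
print.gamma_field <- function(x, ...) {
  cat(sprintf(
    "Resistive field: C=%.3g, epsilon=%.4g mm, support %d of %d nodes\n",
    x$C, x$epsilon_used, x$support_count, length(x$values)))
  invisible(x)
}
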