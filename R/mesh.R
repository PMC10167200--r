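#' Cylindrical domain specification
#'
#' Describes the computational domain for the transvalvular flow problem: a
#' cylinder aligned with the valve axis, locally refined around the valve.
#' Default extents place the inlet two leaflet-heights upstream of the annulus
#' (entry region) and the outlet six leaflet-heights downstream (room for the
#' jet to develop).
#'
#' @param radius Cylinder radius (mm); conventionally the largest leaflet
#'   outer radius.
#' @param z_min,z_max Axial extents (mm); must satisfy `z_min < 0 < z_max`.
#' @param h_fine Target mesh size inside the refinement band (mm).
#' @param h_coarse Target mesh size elsewhere (mm); `>= h_fine`.
#' @param refine_zmin,refine_zmax Axial extent of the refinement band (mm).
#' @return An object of class `cylinder_spec`.
#' @export
cylinder_spec <- function(radius, z_min, z_max, h_fine = 0.5, h_coarse = 0.75,
                          refine_zmin = -2 * h_coarse,
                          refine_zmax = z_max / 6 + 2 * h_coarse) {
  if (!(z_min < 0 && z_max > 0)) stop("cylinder_spec: need z_min < 0 < z_max")
  if (!(h_fine > 0 && h_fine <= h_coarse))
    stop("cylinder_spec: need 0 < h_fine <= h_coarse")
  if (!(refine_zmin > z_min && refine_zmax < z_max &&
        refine_zmin < refine_zmax))
    stop("cylinder_spec: refinement band must lie strictly inside the domain")
  structure(list(radius = radius, z_min = z_min, z_max = z_max,
                 h_fine = h_fine, h_coarse = h_coarse,
                 refine_zmin = refine_zmin, refine_zmax = refine_zmax),
            class = "cylinder_spec")
}

#' Cylinder specification fitted to a valve
#'
#' Radius is the largest leaflet outer radius; the domain spans
#' `[-2 l_h, +6 l_h]` around the valve and the refinement band covers the
#' valve's axial extent with a two-cell margin.
#'
#' @param valve A `valve_surface`.
#' @param h_fine,h_coarse Mesh sizes (mm); the fine-preset values are
#'   0.5/0.75, the desk-scale preset 1.5/2.25.
#' @return A `cylinder_spec`.
#' @export
cylinder_spec_for_valve <- function(valve, h_fine = 0.5, h_coarse = 0.75) {
  lh <- valve$max_l_h
  cylinder_spec(radius = valve$max_l_ro,
                z_min = -2 * lh, z_max = 6 * lh,
                h_fine = h_fine, h_coarse = h_coarse,
                refine_zmin = -2 * h_coarse,
                refine_zmax = lh + 2 * h_coarse)
}

# --- 2D disk triangulation: concentric rings of 6j nodes, annuli stitched by
#     an angular two-pointer sweep -----------------------------------------
disk_triangulation <- function(radius, h) {
  m <- max(2L, as.integer(ceiling(radius / h - 1e-9)))
  dr <- radius / m
  pts <- matrix(0, 1, 2)
  ring_ids <- list(`0` = 1L)
  for (j in 1:m) {
    nj <- 6L * j
    a <- 2 * pi * (0:(nj - 1L)) / nj
    ring_ids[[as.character(j)]] <- nrow(pts) + seq_len(nj)
    pts <- rbind(pts, cbind(j * dr * cos(a), j * dr * sin(a)))
  }
  tris <- vector("list", m)
  for (j in 1:m) {
    I <- ring_ids[[j]]; O <- ring_ids[[j + 1L]]
    nI <- length(I); nO <- length(O)
    aI <- atan2(pts[I, 2], pts[I, 1]); aI[aI < -1e-12] <- aI[aI < -1e-12] + 2 * pi
    aO <- atan2(pts[O, 2], pts[O, 1]); aO[aO < -1e-12] <- aO[aO < -1e-12] + 2 * pi
    t_loc <- matrix(0L, nI + nO, 3)
    i <- 1L; o <- 1L; oo <- 0L; k <- 0L
    ii <- if (nI == 1L) 1L else 0L  # a lone centre node is never advanced
    next_in <- function(i) if (i < nI) aI[i + 1L] else aI[1L] + 2 * pi
    next_out <- function(o) if (o < nO) aO[o + 1L] else aO[1L] + 2 * pi
    while (ii < nI || oo < nO) {
      k <- k + 1L
      adv_out <- (oo < nO) && (ii >= nI || next_out(o) <= next_in(i) || nI == 1L)
      if (adv_out) {
        o2 <- o %% nO + 1L
        t_loc[k, ] <- c(I[i], O[o], O[o2])
        o <- o2; oo <- oo + 1L
      } else {
        i2 <- i %% nI + 1L
        t_loc[k, ] <- c(I[i], O[o], I[i2])
        i <- i2; ii <- ii + 1L
      }
    }
    tris[[j]] <- t_loc[seq_len(k), , drop = FALSE]
  }
  tris <- do.call(rbind, tris)
  list(points = pts, triangles = tris, n_rings = m,
       outer_ring = ring_ids[[m + 1L]])
}

# graded z levels: coarse - fine - coarse, each segment uniform
graded_z_levels <- function(spec) {
  seg <- function(a, b, h) {
    n <- max(1L, ceiling((b - a) / h - 1e-9))
    seq(a, b, length.out = n + 1L)
  }
  z1 <- seg(spec$z_min, spec$refine_zmin, spec$h_coarse)
  z2 <- seg(spec$refine_zmin, spec$refine_zmax, spec$h_fine)
  z3 <- seg(spec$refine_zmax, spec$z_max, spec$h_coarse)
  unique(c(z1, z2, z3))
}

#' Generate the tetrahedral cylinder mesh
#'
#' Builds a structured tetrahedral mesh of the cylinder: a triangulated disk
#' (concentric rings at the fine in-plane spacing) extruded through graded
#' axial layers (fine spacing inside the refinement band, coarse outside);
#' each prism is split into three tetrahedra with an index-based diagonal
#' rule so neighbouring prisms conform. Boundary facets are tagged `inlet`
#' (`z = z_min`), `outlet` (`z = z_max`) and `wall` (lateral surface).
#'
#' @param spec A [cylinder_spec()].
#' @return An object of class `volume_mesh`: `nodes` (`n x 3`, mm), `cells`
#'   (`m x 4`, positively oriented), `h_max` (nominal maximum mesh size =
#'   `h_coarse`, mm), `boundary` (list of facet index matrices `inlet`,
#'   `outlet`, `wall`), and extrusion metadata under `meta` (disk
#'   triangulation, layer levels, per-node disk areas) used for plane
#'   averaging and diagnostics.
#' @export
generate_cylinder_mesh <- function(spec) {
  disk <- disk_triangulation(spec$radius, spec$h_fine)
  zs <- graded_z_levels(spec)
  nd <- nrow(disk$points)
  nl <- length(zs)
  nodes <- cbind(x = rep(disk$points[, 1], nl),
                 y = rep(disk$points[, 2], nl),
                 z = rep(zs, each = nd))

  nt <- nrow(disk$triangles)
  # prisms: disk triangle x layer gap
  bot <- disk$triangles[rep(seq_len(nt), nl - 1L), ] +
    rep((0:(nl - 2L)) * nd, each = nt)
  P <- cbind(bot, bot + nd)  # columns: b1 b2 b3 t1 t2 t3

  # bring global-min vertex to position 1 (flip top/bottom, then rotate)
  amin <- max.col(-P, ties.method = "first")
  flip <- amin > 3L
  P[flip, ] <- P[flip, c(4:6, 1:3)]
  amin <- max.col(-P[, 1:3, drop = FALSE], ties.method = "first")
  for (k in 2:3) {
    rows <- amin == k
    pb <- ((k - 1) + 0:2) %% 3 + 1
    P[rows, ] <- P[rows, c(pb, pb + 3L)]
  }
  # choose diagonal of the far quad face by the smaller-index rule
  caseA <- pmin(P[, 2], P[, 6]) < pmin(P[, 3], P[, 5])
  tets <- rbind(
    cbind(P[caseA, 1], P[caseA, 2], P[caseA, 3], P[caseA, 6]),
    cbind(P[caseA, 1], P[caseA, 2], P[caseA, 6], P[caseA, 5]),
    cbind(P[caseA, 1], P[caseA, 5], P[caseA, 6], P[caseA, 4]),
    cbind(P[!caseA, 1], P[!caseA, 2], P[!caseA, 3], P[!caseA, 5]),
    cbind(P[!caseA, 1], P[!caseA, 3], P[!caseA, 6], P[!caseA, 5]),
    cbind(P[!caseA, 1], P[!caseA, 5], P[!caseA, 6], P[!caseA, 4]))

  # orient all tets positively
  v <- tet_volumes(nodes, tets)
  neg <- v < 0
  tets[neg, c(3, 4)] <- tets[neg, c(4, 3)]
  v <- abs(v)
  if (any(v <= 0)) stop("generate_cylinder_mesh: degenerate cell produced")

  boundary <- classify_boundary_faces(nodes, tets, spec)

  # per-node disk areas (for area-averaged plane quantities)
  d2 <- disk$points
  tri <- disk$triangles
  a2 <- abs((d2[tri[, 2], 1] - d2[tri[, 1], 1]) *
              (d2[tri[, 3], 2] - d2[tri[, 1], 2]) -
              (d2[tri[, 3], 1] - d2[tri[, 1], 1]) *
              (d2[tri[, 2], 2] - d2[tri[, 1], 2])) / 2
  w <- numeric(nd)
  for (cidx in 1:3) {
    acc <- tapply(a2 / 3, tri[, cidx], sum)
    w[as.integer(names(acc))] <- w[as.integer(names(acc))] + acc
  }

  structure(list(nodes = nodes, cells = tets, h_max = spec$h_coarse,
                 boundary = boundary, spec = spec,
                 meta = list(disk = disk, z_levels = zs, n_disk = nd,
                             n_layers = nl, node_area = w)),
            class = "volume_mesh")
}

# signed volumes of tets, vectorized
tet_volumes <- function(nodes, tets) {
  a <- nodes[tets[, 1], , drop = FALSE]
  b <- nodes[tets[, 2], , drop = FALSE] - a
  cc <- nodes[tets[, 3], , drop = FALSE] - a
  d <- nodes[tets[, 4], , drop = FALSE] - a
  (b[, 1] * (cc[, 2] * d[, 3] - cc[, 3] * d[, 2]) -
     b[, 2] * (cc[, 1] * d[, 3] - cc[, 3] * d[, 1]) +
     b[, 3] * (cc[, 1] * d[, 2] - cc[, 2] * d[, 1])) / 6
}

# boundary = faces appearing in exactly one tet; tag by position
classify_boundary_faces <- function(nodes, tets, spec) {
  faces <- rbind(tets[, c(2, 3, 4)], tets[, c(1, 4, 3)],
                 tets[, c(1, 2, 4)], tets[, c(1, 3, 2)])
  s1 <- pmin(faces[, 1], faces[, 2], faces[, 3])
  s3 <- pmax(faces[, 1], faces[, 2], faces[, 3])
  s2 <- faces[, 1] + faces[, 2] + faces[, 3] - s1 - s3
  nmax <- as.numeric(nrow(nodes) + 1)
  key <- (as.numeric(s1) * nmax + s2) * nmax + s3
  idx <- match(key, key)
  cnt <- tabulate(idx, nbins = length(key))
  bf <- faces[cnt[idx] == 1L, , drop = FALSE]
  zr <- nodes[, 3]
  tol <- 1e-9 * max(1, abs(spec$z_max - spec$z_min))
  z1 <- matrix(zr[bf], ncol = 3)
  on_in <- rowSums(abs(z1 - spec$z_min) < tol) == 3L
  on_out <- rowSums(abs(z1 - spec$z_max) < tol) == 3L
  list(inlet = bf[on_in, , drop = FALSE],
       outlet = bf[on_out, , drop = FALSE],
       wall = bf[!(on_in | on_out), , drop = FALSE])
}

# areas of triangular facets, vectorized
facet_areas <- function(nodes, faces) {
  a <- nodes[faces[, 1], , drop = FALSE]
  e1 <- nodes[faces[, 2], , drop = FALSE] - a
  e2 <- nodes[faces[, 3], , drop = FALSE] - a
  nx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  ny <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  nz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  sqrt(nx^2 + ny^2 + nz^2) / 2
}

# unique edges of the mesh restricted to cells whose centroid satisfies `sel`
mesh_edge_lengths <- function(mesh, sel = NULL) {
  cells <- mesh$cells
  if (!is.null(sel)) {
    zc <- (mesh$nodes[cells[, 1], 3] + mesh$nodes[cells[, 2], 3] +
             mesh$nodes[cells[, 3], 3] + mesh$nodes[cells[, 4], 3]) / 4
    cells <- cells[sel(zc), , drop = FALSE]
  }
  pairs <- rbind(cells[, c(1, 2)], cells[, c(1, 3)], cells[, c(1, 4)],
                 cells[, c(2, 3)], cells[, c(2, 4)], cells[, c(3, 4)])
  pairs <- cbind(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2]))
  pairs <- unique(pairs)
  sqrt(rowSums((mesh$nodes[pairs[, 1], ] - mesh$nodes[pairs[, 2], ])^2))
}

#' @export
print.volume_mesh <- function(x, ...) {
  cat(sprintf(
    "Tetrahedral cylinder mesh: %d nodes, %d cells (r=%.1f mm, z in [%.1f, %.1f] mm)\n",
    nrow(x$nodes), nrow(x$cells), x$spec$radius, x$spec$z_min, x$spec$z_max))
  cat(sprintf("  size field: h_fine=%.2f / h_coarse=%.2f mm (band [%.1f, %.1f])\n",
              x$spec$h_fine, x$spec$h_coarse, x$spec$refine_zmin,
              x$spec$refine_zmax))
  invisible(x)
}

#' Write a mesh (with optional nodal fields) as legacy ASCII VTK
#'
#' @param mesh A `volume_mesh`.
#' @param path Output path.
#' @param point_data Named list of nodal fields: numeric vectors (scalars) or
#'   `n x 3` matrices (vectors). Values are printed with full double
#'   precision (`%.17g`), so a read round trip is bitwise exact.
#' @return `path`, invisibly.
#' @export
write_vtk_mesh <- function(mesh, path, point_data = list()) {
  n <- nrow(mesh$nodes); m <- nrow(mesh$cells)
  fmt_rows <- function(M) apply(M, 1, function(r)
    paste(sprintf("%.17g", r), collapse = " "))
  lines <- c("# vtk DataFile Version 3.0", "riisvalve mesh", "ASCII",
             "DATASET UNSTRUCTURED_GRID",
             sprintf("POINTS %d double", n), fmt_rows(mesh$nodes),
             sprintf("CELLS %d %d", m, 5 * m),
             apply(mesh$cells - 1L, 1, function(r)
               paste(c(4L, r), collapse = " ")),
             sprintf("CELL_TYPES %d", m), rep("10", m))
  if (length(point_data)) {
    lines <- c(lines, sprintf("POINT_DATA %d", n))
    for (nm in names(point_data)) {
      val <- point_data[[nm]]
      if (is.matrix(val)) {
        lines <- c(lines, sprintf("VECTORS %s double", nm), fmt_rows(val))
      } else {
        lines <- c(lines, sprintf("SCALARS %s double 1", nm),
                   "LOOKUP_TABLE default", sprintf("%.17g", val))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a legacy ASCII VTK unstructured grid written by [write_vtk_mesh()]
#'
#' @param path VTK file path.
#' @return A list with `nodes`, `cells` and `point_data` (named list).
#' @export
read_vtk_mesh <- function(path) {
  ln <- readLines(path)
  ip <- grep("^POINTS", ln)[1]
  n <- as.integer(strsplit(ln[ip], " +")[[1]][2])
  nodes <- matrix(scan(text = ln[(ip + 1):(ip + n)], quiet = TRUE),
                  ncol = 3, byrow = TRUE)
  ic <- grep("^CELLS", ln)[1]
  m <- as.integer(strsplit(ln[ic], " +")[[1]][2])
  cells <- matrix(scan(text = ln[(ic + 1):(ic + m)], quiet = TRUE),
                  ncol = 5, byrow = TRUE)[, -1, drop = FALSE] + 1L
  pd <- list()
  ipd <- grep("^POINT_DATA", ln)
  if (length(ipd)) {
    k <- ipd[1] + 1L
    while (k <= length(ln)) {
      hdr <- strsplit(ln[k], " +")[[1]]
      if (hdr[1] == "SCALARS") {
        vals <- as.numeric(ln[(k + 2):(k + 1 + n)])
        pd[[hdr[2]]] <- vals
        k <- k + 2L + n
      } else if (hdr[1] == "VECTORS") {
        vals <- matrix(scan(text = ln[(k + 1):(k + n)], quiet = TRUE),
                       ncol = 3, byrow = TRUE)
        pd[[hdr[2]]] <- vals
        k <- k + 1L + n
      } else k <- k + 1L
    }
  }
  list(nodes = nodes, cells = cells, point_data = pd)
}
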