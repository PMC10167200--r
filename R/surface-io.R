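#' Sample the valve surface into a triangle soup
#'
#' Evaluates every patch (and its mirrored half) on an `nu x nv` parameter
#' grid and triangulates each quad into two triangles. Vertices shared
#' between patches of the same leaflet (along the bending curve and the
#' symmetry plane) are deduplicated so each leaflet is watertight along its
#' internal seams.
#'
#' @param valve A `valve_surface`.
#' @param nu,nv Grid resolution per patch (both `>= 2`).
#' @param dedup_tol Vertex-merge tolerance (mm).
#' @return A list with `vertices` (`n x 3`), `triangles` (`m x 3`, 1-based),
#'   and `sheet` (integer sheet id per triangle; 12 sheets = 6 patches x 2
#'   halves).
#' @export
valve_sample_surface <- function(valve, nu = 25, nv = 25, dedup_tol = 1e-6) {
  if (nu < 2 || nv < 2) stop("valve_sample_surface: nu, nv must be >= 2")
  ug <- rep(seq(0, 1, length.out = nu), times = nv)
  vg <- rep(seq(0, 1, length.out = nv), each = nu)
  # quad -> 2 triangles, indices into the nu x nv grid (column-major by v)
  qi <- as.vector(outer(1:(nu - 1), (0:(nv - 2)) * nu, "+"))
  tri1 <- cbind(qi, qi + 1, qi + nu + 1)
  tri2 <- cbind(qi, qi + nu + 1, qi + nu)
  tris0 <- rbind(tri1, tri2)

  verts <- list(); tris <- list(); sheet <- list()
  off <- 0L; sid <- 0L
  for (i in seq_along(valve$patches)) {
    for (mir in c(FALSE, TRUE)) {
      sid <- sid + 1L
      V <- valve_patch_eval(valve, i, ug, vg, mirrored = mir)
      Tm <- tris0
      if (mir) Tm <- Tm[, c(1, 3, 2)]  # keep outward orientation consistent
      verts[[sid]] <- V
      tris[[sid]] <- Tm + off
      sheet[[sid]] <- rep(sid, nrow(Tm))
      off <- off + nrow(V)
    }
  }
  V <- do.call(rbind, verts)
  Tm <- do.call(rbind, tris)
  sh <- unlist(sheet)

  # merge coincident vertices (quantized key)
  key <- paste(round(V[, 1] / dedup_tol), round(V[, 2] / dedup_tol),
               round(V[, 3] / dedup_tol))
  first <- !duplicated(key)
  newid <- match(key, key[first])
  V <- V[first, , drop = FALSE]
  Tm <- matrix(newid[Tm], ncol = 3)
  # drop degenerate triangles created by merging (e.g. a collapsed edge)
  keep <- Tm[, 1] != Tm[, 2] & Tm[, 2] != Tm[, 3] & Tm[, 1] != Tm[, 3]
  list(vertices = V, triangles = Tm[keep, , drop = FALSE], sheet = sh[keep],
       nu = nu, nv = nv)
}

#' Sample a valve surface and write it to STL or VTK
#'
#' @param valve A `valve_surface`.
#' @param nu,nv Sampling resolution per patch.
#' @param path Output file path.
#' @param format `"stl"` (binary) or `"vtk"` (legacy ASCII polydata).
#' @return Invisibly, the sampled surface (as from [valve_sample_surface()]).
#' @export
sample_and_export <- function(valve, nu, nv, path, format = c("stl", "vtk")) {
  format <- match.arg(format)
  surf <- valve_sample_surface(valve, nu, nv)
  if (format == "stl") {
    write_stl_binary(surf$vertices, surf$triangles, path)
  } else {
    write_vtk_polydata(surf$vertices, surf$triangles, path)
  }
  invisible(surf)
}

#' Write a binary STL file
#'
#' @param vertices `n x 3` coordinate matrix (mm).
#' @param triangles `m x 3` 1-based index matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stl_binary <- function(vertices, triangles, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  header <- charToRaw(sprintf("%-80s", "riisvalve surface export"))[1:80]
  writeBin(header, con)
  m <- nrow(triangles)
  writeBin(as.integer(m), con, size = 4, endian = "little")
  a <- vertices[triangles[, 1], , drop = FALSE]
  b <- vertices[triangles[, 2], , drop = FALSE]
  cc <- vertices[triangles[, 3], , drop = FALSE]
  e1 <- b - a; e2 <- cc - a
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(nrm^2)); len[len == 0] <- 1
  nrm <- nrm / len
  # 12 floats per facet then a 2-byte attribute count
  block <- cbind(nrm, a, b, cc)
  for (k in seq_len(m)) {
    writeBin(as.numeric(block[k, ]), con, size = 4, endian = "little")
    writeBin(as.integer(0), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read a binary STL file
#'
#' @param path STL file path.
#' @return A list with `vertices` (`3m x 3`, one row per facet corner, not
#'   deduplicated) and `triangles` (`m x 3`).
#' @export
read_stl_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  invisible(readBin(con, "raw", 80))
  m <- readBin(con, "integer", 1, size = 4, endian = "little")
  V <- matrix(0, 3 * m, 3)
  for (k in seq_len(m)) {
    vals <- readBin(con, "numeric", 12, size = 4, endian = "little")
    invisible(readBin(con, "integer", 1, size = 2, endian = "little"))
    V[3 * k - 2, ] <- vals[4:6]
    V[3 * k - 1, ] <- vals[7:9]
    V[3 * k, ] <- vals[10:12]
  }
  list(vertices = V,
       triangles = matrix(seq_len(3 * m), ncol = 3, byrow = TRUE))
}

#' Write a legacy ASCII VTK polydata surface
#'
#' @param vertices `n x 3` coordinate matrix.
#' @param triangles `m x 3` 1-based index matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vtk_polydata <- function(vertices, triangles, path) {
  n <- nrow(vertices); m <- nrow(triangles)
  lines <- c("# vtk DataFile Version 3.0",
             "riisvalve surface", "ASCII", "DATASET POLYDATA",
             sprintf("POINTS %d double", n),
             apply(vertices, 1, function(r) paste(sprintf("%.17g", r),
                                                  collapse = " ")),
             sprintf("POLYGONS %d %d", m, 4 * m),
             apply(triangles - 1L, 1, function(r)
               paste(c(3L, r), collapse = " ")))
  writeLines(lines, path)
  invisible(path)
}
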