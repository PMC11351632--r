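# Surface mesh export for tube models: triangulated, closed (capped) surface
# on an (s, theta) grid, written as ASCII OBJ or PLY in millimetre units.
# Right-handed axes; the tube axis is +x in the straight limit.

#' Triangulated surface mesh of a tube model
#'
#' Samples the luminal surface on a regular `(s, theta)` grid, sweeps it
#' along the (possibly curved) centerline, and closes both ends with
#' triangle fans so the result is a watertight closed surface.
#'
#' @param tube A `tube_model`.
#' @param resolution Azimuthal sample count (>= 8); the axial count is
#'   `4 * resolution`.
#' @return A list of class `tube_mesh` with `vertices` (n x 3 matrix, mm)
#'   and `faces` (m x 3 integer matrix, 1-based, outward-oriented).
#' @export
export_mesh <- function(tube, resolution = 32L) {
  if (resolution < 8L) stop("resolution must be at least 8")
  n_th <- as.integer(resolution)
  n_s <- 4L * n_th
  s <- seq(0, tube$total_length, length.out = n_s)
  theta <- seq(0, 2 * pi, length.out = n_th + 1L)[-(n_th + 1L)]
  cl <- centerline_points(tube, s)

  verts <- matrix(0, nrow = n_s * n_th + 2L, ncol = 3L)
  for (i in seq_len(n_s)) {
    r <- local_radius(tube, rep(s[i], n_th), theta)
    # in-plane normal (rotate tangent by 90 deg) and out-of-plane z
    nx <- -sin(cl[i, "psi"]); ny <- cos(cl[i, "psi"])
    idx <- (i - 1L) * n_th + seq_len(n_th)
    verts[idx, 1] <- cl[i, "x"] + r * cos(theta) * nx
    verts[idx, 2] <- cl[i, "y"] + r * cos(theta) * ny
    verts[idx, 3] <- r * sin(theta)
  }
  c0 <- n_s * n_th + 1L  # uterine end centre
  c1 <- n_s * n_th + 2L  # infundibular end centre
  verts[c0, ] <- c(cl[1, "x"], cl[1, "y"], 0)
  verts[c1, ] <- c(cl[n_s, "x"], cl[n_s, "y"], 0)

  faces <- matrix(0L, nrow = 2L * (n_s - 1L) * n_th + 2L * n_th, ncol = 3L)
  k <- 0L
  for (i in seq_len(n_s - 1L)) {
    j <- seq_len(n_th)
    jn <- c(seq_len(n_th)[-1L], 1L)
    a <- (i - 1L) * n_th + j
    b <- (i - 1L) * n_th + jn
    cc <- i * n_th + j
    d <- i * n_th + jn
    faces[k + j, ] <- cbind(a, b, cc)
    faces[k + n_th + j, ] <- cbind(b, d, cc)
    k <- k + 2L * n_th
  }
  j <- seq_len(n_th); jn <- c(seq_len(n_th)[-1L], 1L)
  faces[k + j, ] <- cbind(jn, j, rep(c0, n_th))
  k <- k + n_th
  base <- (n_s - 1L) * n_th
  faces[k + j, ] <- cbind(base + j, base + jn, rep(c1, n_th))

  structure(list(vertices = verts, faces = faces), class = "tube_mesh")
}

#' Check that a triangulated mesh is a closed (watertight) surface
#'
#' @param mesh A `tube_mesh`.
#' @return List with `watertight` (every edge shared by exactly two faces)
#'   and `euler` (V - E + F; 2 for a closed capped tube).
#' @export
mesh_is_watertight <- function(mesh) {
  f <- mesh$faces
  edges <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  tab <- table(key)
  v <- nrow(mesh$vertices); e <- length(tab); fa <- nrow(f)
  list(watertight = all(tab == 2L), euler = v - e + fa)
}

#' Signed volume enclosed by a closed triangulated mesh
#'
#' Divergence-theorem sum of signed tetrahedron volumes; positive for
#' outward-oriented faces.
#'
#' @param mesh A `tube_mesh`.
#' @return Volume in mm^3.
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  cross <- cbind(b[, 2] * cc[, 3] - b[, 3] * cc[, 2],
                 b[, 3] * cc[, 1] - b[, 1] * cc[, 3],
                 b[, 1] * cc[, 2] - b[, 2] * cc[, 1])
  abs(sum(rowSums(a * cross)) / 6)
}

#' Write a mesh to Wavefront OBJ or ASCII PLY
#'
#' @param mesh A `tube_mesh`.
#' @param path Output file; format chosen from the `.obj` / `.ply` extension.
#' @export
write_mesh <- function(mesh, path) {
  ext <- tolower(tools::file_ext(path))
  v <- mesh$vertices; f <- mesh$faces
  if (ext == "obj") {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(sprintf("v %.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
    writeLines(sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3]), con)
  } else if (ext == "ply") {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(c("ply", "format ascii 1.0",
                 paste("element vertex", nrow(v)),
                 "property float x", "property float y", "property float z",
                 paste("element face", nrow(f)),
                 "property list uchar int vertex_indices", "end_header"), con)
    writeLines(sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
    writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  } else stop("unsupported mesh format: ", ext)
  invisible(path)
}

#' Read a Wavefront OBJ mesh written by [write_mesh()]
#'
#' @param path OBJ file path.
#' @return A `tube_mesh`.
#' @export
read_obj <- function(path) {
  lines <- readLines(path)
  vl <- lines[startsWith(lines, "v ")]
  fl <- lines[startsWith(lines, "f ")]
  v <- do.call(rbind, lapply(strsplit(vl, "\\s+"), function(p)
    as.numeric(p[2:4])))
  f <- do.call(rbind, lapply(strsplit(fl, "\\s+"), function(p)
    as.integer(p[2:4])))
  structure(list(vertices = v, faces = f), class = "tube_mesh")
}
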