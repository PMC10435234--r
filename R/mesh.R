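#' Triangle meshes
#'
#' Minimal triangle-mesh support for surface landmark projection: ASCII OFF
#' and ASCII PLY reading/writing and exact closest-point projection onto the
#' mesh surface. Faces with more than three vertices are fan-triangulated on
#' read; zero-area faces are dropped from projection.
#'
#' @param vertices V x 3 numeric matrix.
#' @param faces F x 3 integer matrix of 1-based vertex indices.
#' @return An object of class `triangle_mesh`.
#' @export
triangle_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3L)
  if (ncol(vertices) != 3L) stop("vertices must be V x 3")
  if (nrow(faces) < 1L) stop("mesh has no faces")
  if (any(faces < 1L) || any(faces > nrow(vertices)))
    stop("face indices out of range")
  if (any(!is.finite(vertices))) stop("non-finite vertex coordinates")
  structure(list(vertices = vertices, faces = faces), class = "triangle_mesh")
}

#' Read a mesh from ASCII OFF or PLY
#' @param path file path; format chosen by extension (`.off`, `.ply`).
#' @return A [triangle_mesh()].
#' @export
read_mesh <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         off = .read_off(path),
         ply = .read_ply(path),
         stop("unsupported mesh format: .", ext))
}

#' Write a mesh to ASCII OFF or PLY
#' @param mesh a [triangle_mesh()].
#' @param path file path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  ext <- tolower(tools::file_ext(path))
  v <- mesh$vertices; f <- mesh$faces
  if (ext == "off") {
    con <- file(path, "w"); on.exit(close(con))
    writeLines("OFF", con)
    writeLines(sprintf("%d %d 0", nrow(v), nrow(f)), con)
    utils::write.table(format(v, digits = 17, trim = TRUE, scientific = FALSE),
                       con, row.names = FALSE, col.names = FALSE, quote = FALSE)
    utils::write.table(cbind(3L, f - 1L), con, row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
  } else if (ext == "ply") {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(c("ply", "format ascii 1.0",
                 sprintf("element vertex %d", nrow(v)),
                 "property double x", "property double y", "property double z",
                 sprintf("element face %d", nrow(f)),
                 "property list uchar int vertex_indices", "end_header"), con)
    utils::write.table(format(v, digits = 17, trim = TRUE, scientific = FALSE),
                       con, row.names = FALSE, col.names = FALSE, quote = FALSE)
    utils::write.table(cbind(3L, f - 1L), con, row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
  } else stop("unsupported mesh format: .", ext)
  invisible(path)
}

.read_off <- function(path) {
  toks <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  if (toks[1L] != "OFF") stop("not an OFF file: ", path)
  toks <- toks[-1L]
  nv <- as.integer(toks[1L]); nf <- as.integer(toks[2L])
  toks <- toks[-(1:3)]                     # skip edge count
  v <- matrix(as.numeric(toks[seq_len(3L * nv)]), ncol = 3L, byrow = TRUE)
  toks <- toks[-seq_len(3L * nv)]
  faces <- list(); i <- 1L
  for (k in seq_len(nf)) {
    m <- as.integer(toks[i])
    idx <- as.integer(toks[(i + 1L):(i + m)]) + 1L
    # fan-triangulate polygons
    for (j in seq_len(m - 2L)) faces[[length(faces) + 1L]] <- idx[c(1L, j + 1L, j + 2L)]
    i <- i + m + 1L
  }
  triangle_mesh(v, do.call(rbind, faces))
}

.read_ply <- function(path) {
  lines <- readLines(path)
  if (trimws(lines[1L]) != "ply") stop("not a PLY file: ", path)
  hdr_end <- which(trimws(lines) == "end_header")[1L]
  hdr <- lines[seq_len(hdr_end)]
  if (!any(grepl("format ascii", hdr))) stop("only ASCII PLY is supported")
  nv <- as.integer(sub(".*element vertex +", "", grep("element vertex", hdr, value = TRUE)[1L]))
  nf <- as.integer(sub(".*element face +", "", grep("element face", hdr, value = TRUE)[1L]))
  body <- lines[-(seq_len(hdr_end))]
  vtoks <- strsplit(trimws(body[seq_len(nv)]), "[ \t]+")
  v <- t(vapply(vtoks, function(s) as.numeric(s[1:3]), numeric(3)))
  ftoks <- strsplit(trimws(body[nv + seq_len(nf)]), "[ \t]+")
  faces <- list()
  for (s in ftoks) {
    m <- as.integer(s[1L]); idx <- as.integer(s[1L + seq_len(m)]) + 1L
    for (j in seq_len(m - 2L)) faces[[length(faces) + 1L]] <- idx[c(1L, j + 1L, j + 2L)]
  }
  triangle_mesh(v, do.call(rbind, faces))
}

# Exact closest point on triangle (a, b, c) to point p (Ericson's region
# decomposition); returns the closest point.
.closest_point_triangle <- function(p, a, b, c) {
  ab <- b - a; ac <- c - a; ap <- p - a
  d1 <- sum(ab * ap); d2 <- sum(ac * ap)
  if (d1 <= 0 && d2 <= 0) return(a)
  bp <- p - b
  d3 <- sum(ab * bp); d4 <- sum(ac * bp)
  if (d3 >= 0 && d4 <= d3) return(b)
  vc <- d1 * d4 - d3 * d2
  if (vc <= 0 && d1 >= 0 && d3 <= 0) return(a + (d1 / (d1 - d3)) * ab)
  cp <- p - c
  d5 <- sum(ab * cp); d6 <- sum(ac * cp)
  if (d6 >= 0 && d5 <= d6) return(c)
  vb <- d5 * d2 - d1 * d6
  if (vb <= 0 && d2 >= 0 && d6 <= 0) return(a + (d2 / (d2 - d6)) * ac)
  va <- d3 * d6 - d5 * d4
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0)
    return(b + ((d4 - d3) / ((d4 - d3) + (d5 - d6))) * (c - b))
  denom <- 1 / (va + vb + vc)
  a + ab * (vb * denom) + ac * (vc * denom)
}

#' Project points onto a mesh surface
#'
#' Exact per-triangle closest-point projection; each query point is replaced
#' by its nearest point on the mesh. Degenerate (zero-area) triangles are
#' excluded.
#'
#' @param points Q x 3 matrix of query points.
#' @param mesh a [triangle_mesh()].
#' @return Q x 3 matrix of surface points.
#' @export
project_to_mesh <- function(points, mesh) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  points <- matrix(as.numeric(points), ncol = 3L)
  v <- mesh$vertices; f <- mesh$faces
  e1 <- v[f[, 2L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  e2 <- v[f[, 3L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  area2 <- sqrt(rowSums(cr^2))
  keep <- which(area2 > 1e-14 * max(area2))
  if (!length(keep)) stop("mesh has no non-degenerate faces")
  cent <- (v[f[, 1L], , drop = FALSE] + v[f[, 2L], , drop = FALSE] +
           v[f[, 3L], , drop = FALSE]) / 3
  out <- points
  for (q in seq_len(nrow(points))) {
    p <- points[q, ]
    # order candidate triangles by centroid distance and prune by bound
    d2c <- rowSums(sweep(cent[keep, , drop = FALSE], 2L, p)^2)
    ord <- keep[order(d2c)]
    best <- Inf; bestpt <- p
    for (t in ord) {
      cp <- .closest_point_triangle(p, v[f[t, 1L], ], v[f[t, 2L], ], v[f[t, 3L], ])
      d2 <- sum((p - cp)^2)
      if (d2 < best) { best <- d2; bestpt <- cp }
    }
    out[q, ] <- bestpt
  }
  out
}
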