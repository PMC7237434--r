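#' Indexed triangle meshes
#'
#' A \code{tri_mesh} is a vertex matrix (n x 3, mm) plus a face index matrix
#' (m x 3, 1-based, consistent winding). Degenerate (zero-area) faces are
#' rejected at construction.
#'
#' @param vertices n x 3 numeric matrix.
#' @param faces m x 3 integer matrix of vertex indices.
#' @param drop_degenerate drop zero-area faces instead of erroring.
#' @return an object of class \code{tri_mesh}.
#' @export
tri_mesh <- function(vertices, faces, drop_degenerate = FALSE) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  stopifnot(ncol(vertices) == 3)
  if (nrow(vertices) == 0 || nrow(faces) == 0)
    stop("empty mesh: no vertices or faces")
  if (any(faces < 1) || any(faces > nrow(vertices)))
    stop("face indices out of range")
  a <- vertices[faces[, 2], , drop = FALSE] - vertices[faces[, 1], , drop = FALSE]
  b <- vertices[faces[, 3], , drop = FALSE] - vertices[faces[, 1], , drop = FALSE]
  cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  area2 <- sqrt(rowSums(cr^2))
  deg <- area2 < 1e-14
  if (any(deg)) {
    if (drop_degenerate) faces <- faces[!deg, , drop = FALSE]
    else stop(sum(deg), " degenerate (zero-area) face(s)")
  }
  structure(list(vertices = vertices, faces = faces), class = "tri_mesh")
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("tri_mesh: %d vertices, %d faces%s\n",
              nrow(x$vertices), nrow(x$faces),
              if (is_closed_mesh(x)) " (closed)" else ""))
  invisible(x)
}

#' Is a mesh closed (watertight)?
#'
#' Every edge must be shared by exactly two faces.
#' @param mesh a \code{tri_mesh}.
#' @return logical.
#' @export
is_closed_mesh <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- pmin(e[, 1], e[, 2]) * (nrow(mesh$vertices) + 1) + pmax(e[, 1], e[, 2])
  all(tabulate(match(key, unique(key))) == 2L)
}

#' Euler characteristic V - E + F of a mesh
#' @param mesh a \code{tri_mesh}.
#' @return integer.
#' @export
euler_characteristic <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- pmin(e[, 1], e[, 2]) * (nrow(mesh$vertices) + 1) + pmax(e[, 1], e[, 2])
  length(unique(as.vector(f))) - length(unique(key)) + nrow(f)
}

#' Signed volume of a closed triangle mesh
#'
#' Sums the signed volumes of the tetrahedra spanned by each triangular face
#' and a reference point. For a closed, consistently wound mesh the result is
#' independent of the reference point; the mesh centroid is used for
#' definiteness. The absolute value is returned (winding is fixed upstream so
#' outward normals give positive volume).
#'
#' @param mesh a closed \code{tri_mesh}.
#' @param origin optional reference point (3-vector); defaults to the vertex
#'   centroid.
#' @param signed return the raw signed sum instead of its absolute value.
#' @return volume in the cube of the vertex units (mm^3 for mm vertices).
#' @export
signed_mesh_volume <- function(mesh, origin = NULL, signed = FALSE) {
  stopifnot(inherits(mesh, "tri_mesh"))
  if (!is_closed_mesh(mesh))
    warning("mesh is not closed; volume depends on the reference point")
  v <- mesh$vertices
  if (is.null(origin)) origin <- colMeans(v)
  v <- sweep(v, 2, origin)
  f <- mesh$faces
  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  det3 <- p1[, 1] * (p2[, 2] * p3[, 3] - p2[, 3] * p3[, 2]) -
          p1[, 2] * (p2[, 1] * p3[, 3] - p2[, 3] * p3[, 1]) +
          p1[, 3] * (p2[, 1] * p3[, 2] - p2[, 2] * p3[, 1])
  vol <- sum(det3) / 6
  if (signed) vol else abs(vol)
}

#' Write / read Wavefront OBJ meshes
#'
#' Plain-text OBJ with \code{v} and \code{f} records and 1-based indices.
#'
#' @param mesh a \code{tri_mesh}.
#' @param path file path.
#' @return \code{write_obj} returns \code{path} invisibly; \code{read_obj}
#'   returns a \code{tri_mesh}.
#' @export
write_obj <- function(mesh, path) {
  stopifnot(inherits(mesh, "tri_mesh"))
  if (nrow(mesh$vertices) == 0 || nrow(mesh$faces) == 0)
    stop("refusing to write an empty mesh")
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("v %.9g %.9g %.9g",
                     mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d",
                     mesh$faces[, 1], mesh$faces[, 2], mesh$faces[, 3]), con)
  invisible(path)
}

#' @rdname write_obj
#' @export
read_obj <- function(path) {
  ln <- readLines(path)
  vl <- ln[startsWith(ln, "v ")]
  fl <- ln[startsWith(ln, "f ")]
  if (!length(vl)) stop("no vertices in OBJ: ", path)
  vmat <- do.call(rbind, lapply(strsplit(trimws(sub("^v", "", vl)), "\\s+"),
                                function(x) as.numeric(x[1:3])))
  # face records may carry v/vt/vn triplets; keep the vertex index
  fmat <- do.call(rbind, lapply(strsplit(trimws(sub("^f", "", fl)), "\\s+"),
                                function(x) as.integer(sub("/.*$", "", x[1:3]))))
  tri_mesh(vmat, fmat)
}
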