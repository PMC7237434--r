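#' Fill a coronal ring with a harmonic (minimal) surface
#'
#' The ring is projected onto the plane of its first two principal
#' directions; a triangular mesh is built for the enclosed planar domain; and
#' the x-, y-, z-coordinate functions of the surface are obtained by solving
#' three discrete Laplace (Poisson) equations with cotangent weights on that
#' mesh, with the ring coordinates as Dirichlet boundary values. Interior
#' vertex coordinates therefore equal the cotangent-weighted average of their
#' neighbours; a planar boundary fills to an exactly planar surface, while a
#' non-planar ring yields a curved (harmonic) span.
#'
#' The planar domain is meshed with concentric copies of the boundary loop
#' shrunk toward the 2D centroid plus a central vertex, loops stitched by
#' their arc-length parameter. This is valid for rings whose projection is
#' star-shaped about its centroid, which holds for the convex-oval coronal
#' cross-sections the method targets; a self-intersecting projected boundary
#' is rejected.
#'
#' @param ring a \code{coronal_ring}, or an n x 3 matrix of ordered boundary
#'   samples.
#' @param density interior vertex spacing as a multiple of the boundary
#'   sample spacing (1 = comparable spacing; smaller = finer interior).
#' @param clamp_cotangent clamp negative cotangent weights (obtuse triangles)
#'   at zero; default keeps them, matching the cotangent-Laplacian surface
#'   editing formulation.
#' @return object of class \code{coronal_surface}: list with \code{mesh}
#'   (a \code{tri_mesh} whose first \code{n} vertices are the boundary ring
#'   samples), \code{boundary_idx}, and \code{ring}.
#' @export
fill_harmonic_surface <- function(ring, density = 1, clamp_cotangent = FALSE) {
  B <- if (inherits(ring, "coronal_ring")) ring$points else as.matrix(ring)
  n <- nrow(B)
  stopifnot(n >= 8)
  ctr <- colMeans(B)
  Bc <- sweep(B, 2, ctr)
  sv <- svd(Bc)
  uv <- Bc %*% sv$v[, 1:2]                 # first two principal directions
  if (polygon_self_intersects(uv))
    stop("geometry error: projected ring boundary self-intersects")
  # orient the 2D loop counterclockwise for consistent face winding
  a2 <- sum(uv[, 1] * c(uv[-1, 2], uv[1, 2]) - uv[, 2] * c(uv[-1, 1], uv[1, 1])) / 2
  ccw <- a2 >= 0
  ord <- if (ccw) seq_len(n) else c(1, n:2)
  uvo <- uv[ord, , drop = FALSE]
  mesh2 <- disk_mesh(uvo, density)
  # solve three Dirichlet problems: boundary = ring coordinates
  L <- cotangent_laplacian(mesh2$vertices, mesh2$faces, clamp_cotangent)
  nb <- n
  ni <- nrow(mesh2$vertices) - nb
  V3 <- matrix(0, nrow(mesh2$vertices), 3)
  V3[seq_len(nb), ] <- B[ord, , drop = FALSE]
  if (ni > 0) {
    ib <- seq_len(nb)
    ii <- nb + seq_len(ni)
    Lii <- L[ii, ii, drop = FALSE]
    Lib <- L[ii, ib, drop = FALSE]
    rhs <- -as.matrix(Lib %*% V3[ib, , drop = FALSE])
    sol <- as.matrix(Matrix::solve(Lii, rhs))
    V3[ii, ] <- sol
  }
  # map faces back so boundary vertex k corresponds to original ring index
  inv <- integer(n); inv[ord] <- seq_len(n)
  vert_map <- c(inv, if (ni > 0) nb + seq_len(ni))
  Vout <- matrix(0, nrow(V3), 3)
  Vout[vert_map, ] <- V3
  UVout <- matrix(0, nrow(V3), 2)
  UVout[vert_map, ] <- mesh2$vertices
  faces <- matrix(vert_map[mesh2$faces], ncol = 3)
  mesh <- tri_mesh(Vout, faces, drop_degenerate = TRUE)
  structure(list(mesh = mesh, boundary_idx = seq_len(n), planar_uv = UVout,
                 planar_faces = faces,
                 ring = if (inherits(ring, "coronal_ring")) ring else coronal_ring(B)),
            class = "coronal_surface")
}

#' @export
print.coronal_surface <- function(x, ...) {
  cat(sprintf("coronal_surface: %d boundary + %d interior vertices, %d faces\n",
              length(x$boundary_idx),
              nrow(x$mesh$vertices) - length(x$boundary_idx),
              nrow(x$mesh$faces)))
  invisible(x)
}

# Structured disk mesh of the region enclosed by a CCW 2D loop: concentric
# shrunk copies of the loop (vertex count proportional to scale) stitched by
# arc-length parameter, plus a central vertex. Boundary vertices come first,
# in the input order. Returns list(vertices = m x 2, faces = k x 3).
disk_mesh <- function(uv, density = 1) {
  n <- nrow(uv)
  c2 <- colMeans(uv)
  r_mean <- mean(sqrt(rowSums(sweep(uv, 2, c2)^2)))
  spacing <- perimeter2(uv) / n * density
  L <- max(2L, round(r_mean / spacing))       # number of interior loops
  par_of <- function(P) {                     # arc-length parameter in [0,1)
    seg <- sqrt(rowSums(diff(rbind(P, P[1, ]))^2))
    cs <- cumsum(c(0, seg))
    cs[seq_len(nrow(P))] / cs[length(cs)]
  }
  verts <- uv
  pars <- list(par_of(uv))
  counts <- n
  for (j in seq_len(L - 1)) {
    f <- 1 - j / L
    nj <- max(8L, round(n * f))
    # resample the boundary loop at nj equal-arc params, then shrink
    t0 <- pars[[1]]
    tq <- seq(0, 1, length.out = nj + 1)[seq_len(nj)]
    P <- loop_interp(uv, t0, tq)
    Pj <- sweep(sweep(P, 2, c2) * f, 2, c2, `+`)
    verts <- rbind(verts, Pj)
    pars <- c(pars, list(tq))
    counts <- c(counts, nj)
  }
  verts <- rbind(verts, c2)                   # central vertex
  offs <- cumsum(c(0, counts))
  fl <- vector("list", length(counts))
  for (j in seq_len(length(counts) - 1)) {
    fl[[j]] <- stitch_loops(offs[j] + seq_len(counts[j]), pars[[j]],
                            offs[j + 1] + seq_len(counts[j + 1]), pars[[j + 1]])
  }
  cidx <- nrow(verts)
  last <- offs[length(counts)] + seq_len(counts[length(counts)])
  fl[[length(counts)]] <- cbind(last, c(last[-1], last[1]), cidx)
  list(vertices = verts, faces = do.call(rbind, fl))
}

perimeter2 <- function(uv) sum(sqrt(rowSums(diff(rbind(uv, uv[1, ]))^2)))

# periodic linear interpolation of a closed 2D loop at parameters tq
loop_interp <- function(P, t0, tq) {
  tt <- c(t0, 1)
  PP <- rbind(P, P[1, ])
  idx <- findInterval(tq, tt, rightmost.closed = TRUE)
  idx[idx >= length(tt)] <- length(tt) - 1
  w <- (tq - tt[idx]) / (tt[idx + 1] - tt[idx])
  PP[idx, , drop = FALSE] + (PP[idx + 1, , drop = FALSE] - PP[idx, , drop = FALSE]) * w
}

# Triangulate the annulus between an outer loop (indices ia, params ta) and
# inner loop (ib, tb), both CCW and parameterized in [0,1). Greedy advance on
# the smaller next parameter; returns faces wound consistently (outer CCW).
stitch_loops <- function(ia, ta, ib, tb) {
  na <- length(ia); nb <- length(ib)
  faces <- matrix(0L, na + nb, 3)
  i <- 1L; j <- 1L; k <- 0L
  ta_ext <- c(ta, ta[1] + 1)
  tb_ext <- c(tb, tb[1] + 1)
  while (i <= na || j <= nb) {
    k <- k + 1L
    adv_a <- if (i > na) FALSE else if (j > nb) TRUE else ta_ext[i + 1] <= tb_ext[j + 1]
    ai <- ia[(i - 1L) %% na + 1L]; ai1 <- ia[i %% na + 1L]
    bj <- ib[(j - 1L) %% nb + 1L]; bj1 <- ib[j %% nb + 1L]
    if (adv_a) { faces[k, ] <- c(ai, ai1, bj); i <- i + 1L }
    else       { faces[k, ] <- c(ai, bj1, bj); j <- j + 1L }
  }
  faces[seq_len(k), , drop = FALSE]
}

# O(n^2) segment-intersection scan for closed 2D polygons (n ~ 300 is fine)
polygon_self_intersects <- function(uv) {
  n <- nrow(uv)
  a <- uv
  b <- uv[c(2:n, 1), , drop = FALSE]
  seg_int <- function(p1, p2, p3, p4) {
    d1 <- cross2(p4 - p3, p1 - p3); d2 <- cross2(p4 - p3, p2 - p3)
    d3 <- cross2(p2 - p1, p3 - p1); d4 <- cross2(p2 - p1, p4 - p1)
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  for (i in seq_len(n - 2)) {
    jj <- (i + 2):n
    jj <- jj[!(i == 1 & jj == n)]             # skip segments sharing a vertex
    for (j in jj)
      if (seg_int(a[i, ], b[i, ], a[j, ], b[j, ])) return(TRUE)
  }
  FALSE
}

cross2 <- function(u, v) u[1] * v[2] - u[2] * v[1]

# Sparse cotangent Laplacian (positive semi-definite convention:
# L[i,i] = sum_j w_ij, L[i,j] = -w_ij, w_ij = (cot a + cot b) / 2).
cotangent_laplacian <- function(V, F, clamp = FALSE) {
  V <- as.matrix(V)
  if (ncol(V) == 2) V <- cbind(V, 0)
  i1 <- F[, 1]; i2 <- F[, 2]; i3 <- F[, 3]
  cot_at <- function(a, b, c) {               # cotangent of angle at vertex a
    u <- V[b, , drop = FALSE] - V[a, , drop = FALSE]
    v <- V[c, , drop = FALSE] - V[a, , drop = FALSE]
    dot <- rowSums(u * v)
    crs <- sqrt(pmax(rowSums(u^2) * rowSums(v^2) - dot^2, 1e-300))
    dot / crs
  }
  c1 <- cot_at(i1, i2, i3)                    # opposite edge (i2, i3)
  c2 <- cot_at(i2, i3, i1)
  c3 <- cot_at(i3, i1, i2)
  if (clamp) { c1 <- pmax(c1, 0); c2 <- pmax(c2, 0); c3 <- pmax(c3, 0) }
  ii <- c(i2, i3, i3, i1, i1, i2)
  jj <- c(i3, i2, i1, i3, i2, i1)
  ww <- c(c1, c1, c2, c2, c3, c3) / 2
  nv <- nrow(V)
  W <- Matrix::sparseMatrix(i = ii, j = jj, x = ww, dims = c(nv, nv))
  Matrix::Diagonal(nv, Matrix::rowSums(W)) - W
}

#' Harmonic-surface residual check
#'
#' Maximum absolute Laplacian residual at interior vertices, per coordinate:
#' how far each interior vertex is from the cotangent-weighted average of its
#' neighbours. Used by validity tests.
#'
#' @param surface a \code{coronal_surface}.
#' @return numeric length-3 (x, y, z residual maxima).
#' @export
harmonic_residual <- function(surface) {
  V <- surface$mesh$vertices
  L <- cotangent_laplacian(surface$planar_uv, surface$planar_faces)
  ii <- setdiff(seq_len(nrow(V)), surface$boundary_idx)
  if (!length(ii)) return(c(0, 0, 0))
  r <- as.matrix(L %*% V)[ii, , drop = FALSE]
  apply(abs(r), 2, max)
}
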