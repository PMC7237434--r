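#' 3D Delaunay tetrahedralization
#'
#' Incremental (Bowyer-Watson) Delaunay tetrahedralization of a 3D point
#' cloud. Degenerate inputs (grids, cospherical points) are handled by a
#' tiny deterministic jitter applied internally; the returned tetrahedra
#' index the original, unperturbed points.
#'
#' @param points n x 3 numeric matrix, n >= 4.
#' @param seed integer seed for the internal jitter / insertion order.
#' @return m x 4 integer matrix of tetrahedron vertex indices (1-based).
#' @export
delaunay3d <- function(points, seed = 1L) {
  P <- as.matrix(points)
  stopifnot(ncol(P) == 3)
  if (anyNA(P) || any(!is.finite(P))) stop("non-finite points")
  if (nrow(P) < 4) stop("need at least 4 points")
  .delaunay3d_cpp(P, as.integer(seed))
}

# volumes (mm^3) of tetrahedra given as an m x 4 index matrix
tetra_volumes <- function(points, tets) {
  a <- points[tets[, 1], , drop = FALSE]
  b <- points[tets[, 2], , drop = FALSE] - a
  c_ <- points[tets[, 3], , drop = FALSE] - a
  d <- points[tets[, 4], , drop = FALSE] - a
  det3 <- b[, 1] * (c_[, 2] * d[, 3] - c_[, 3] * d[, 2]) -
          b[, 2] * (c_[, 1] * d[, 3] - c_[, 3] * d[, 1]) +
          b[, 3] * (c_[, 1] * d[, 2] - c_[, 2] * d[, 1])
  abs(det3) / 6
}

# circumsphere radii of tetrahedra (Inf for degenerate ones); vectorized
# Cramer solve of 2 (p_k - p_1) . x = |p_k|^2 - |p_1|^2, k = 2..4
tetra_circumradii <- function(points, tets) {
  p1 <- points[tets[, 1], , drop = FALSE]
  a <- points[tets[, 2], , drop = FALSE] - p1
  b <- points[tets[, 3], , drop = FALSE] - p1
  c_ <- points[tets[, 4], , drop = FALSE] - p1
  ra <- rowSums(a^2) / 2; rb <- rowSums(b^2) / 2; rc <- rowSums(c_^2) / 2
  det3 <- function(u, v, w)
    u[, 1] * (v[, 2] * w[, 3] - v[, 3] * w[, 2]) -
    u[, 2] * (v[, 1] * w[, 3] - v[, 3] * w[, 1]) +
    u[, 3] * (v[, 1] * w[, 2] - v[, 2] * w[, 1])
  D <- det3(a, b, c_)
  # Cramer: replace one coordinate column with the rhs
  dx <- det3(cbind(ra, a[, 2], a[, 3]),
             cbind(rb, b[, 2], b[, 3]), cbind(rc, c_[, 2], c_[, 3]))
  dy <- det3(cbind(a[, 1], ra, a[, 3]), cbind(b[, 1], rb, b[, 3]),
             cbind(c_[, 1], rc, c_[, 3]))
  dz <- det3(cbind(a[, 1], a[, 2], ra), cbind(b[, 1], b[, 2], rb),
             cbind(c_[, 1], c_[, 2], rc))
  bad <- abs(D) < 1e-300
  Ds <- ifelse(bad, 1, D)
  ctr <- cbind(dx / Ds, dy / Ds, dz / Ds)   # relative to p1
  r <- sqrt(rowSums(ctr^2))
  r[bad] <- Inf
  r
}

#' Alpha-shape volume of a 3D point cloud
#'
#' Delaunay-tetrahedralizes the cloud, keeps tetrahedra whose circumscribing
#' sphere has radius at most \code{alpha} (the circumradius convention of
#' alphashape3d-style alpha shapes), and sums their volumes. As
#' \code{alpha} grows the result approaches the convex-hull volume;
#' moderate alpha carves concavities. Tetrahedra with volume below
#' \code{min_tet_volume} are excluded before the circumradius test to avoid
#' numerically unbounded circumradii on slivers.
#'
#' @param points n x 3 numeric matrix (mm), or an \code{oral_boundary_cloud}.
#' @param alpha alpha radius, mm (default 6).
#' @param min_tet_volume sliver exclusion threshold, mm^3.
#' @param seed jitter seed passed to \code{\link{delaunay3d}}.
#' @return volume in mm^3. Degenerate (coplanar) clouds return 0 with a
#'   warning.
#' @export
alpha_shape_volume <- function(points, alpha = 6, min_tet_volume = 1e-12,
                               seed = 1L) {
  if (inherits(points, "oral_boundary_cloud")) points <- points$points
  P <- as.matrix(points)
  stopifnot(alpha > 0)
  if (nrow(P) < 4) stop("need at least 4 affinely independent points")
  if (svd(sweep(P, 2, colMeans(P)))$d[3] < 1e-9 * max(1, svd(sweep(P, 2, colMeans(P)))$d[1])) {
    warning("degenerate (coplanar) cloud: zero volume")
    return(0)
  }
  tets <- delaunay3d(P, seed = seed)
  vol <- tetra_volumes(P, tets)
  keep <- vol >= min_tet_volume
  tets <- tets[keep, , drop = FALSE]
  vol <- vol[keep]
  if (is.finite(alpha)) {
    r <- tetra_circumradii(P, tets)
    vol <- vol[r <= alpha]
  }
  sum(vol)
}

#' Convex-hull volume of a point cloud
#'
#' Computed from the boundary faces of the Delaunay tetrahedralization by
#' the divergence theorem (an algorithmic path independent of summing
#' tetra volumes).
#'
#' @param points n x 3 numeric matrix.
#' @param seed jitter seed.
#' @return hull volume in mm^3.
#' @export
convex_hull_volume <- function(points, seed = 1L) {
  P <- as.matrix(points)
  tets <- delaunay3d(P, seed = seed)
  # boundary faces appear in exactly one tetrahedron
  fc <- rbind(tets[, c(1, 2, 3)], tets[, c(1, 2, 4)],
              tets[, c(1, 3, 4)], tets[, c(2, 3, 4)])
  lo <- pmin(fc[, 1], fc[, 2], fc[, 3])
  hi <- pmax(fc[, 1], fc[, 2], fc[, 3])
  mid <- fc[, 1] + fc[, 2] + fc[, 3] - lo - hi
  key <- paste(lo, mid, hi)
  hull <- fc[key %in% names(which(table(key) == 1L)), , drop = FALSE]
  ctr <- colMeans(P)
  v1 <- P[hull[, 1], , drop = FALSE]
  v2 <- P[hull[, 2], , drop = FALSE]
  v3 <- P[hull[, 3], , drop = FALSE]
  # orient each face outward from the centroid
  n1 <- v2 - v1; n2 <- v3 - v1
  nrm <- cbind(n1[, 2] * n2[, 3] - n1[, 3] * n2[, 2],
               n1[, 3] * n2[, 1] - n1[, 1] * n2[, 3],
               n1[, 1] * n2[, 2] - n1[, 2] * n2[, 1])
  out_sign <- sign(rowSums((v1 - matrix(ctr, nrow(v1), 3, byrow = TRUE)) * nrm))
  sw <- out_sign < 0
  tmp <- hull[sw, 2]; hull[sw, 2] <- hull[sw, 3]; hull[sw, 3] <- tmp
  v1 <- P[hull[, 1], , drop = FALSE]
  v2 <- P[hull[, 2], , drop = FALSE]
  v3 <- P[hull[, 3], , drop = FALSE]
  v1 <- sweep(v1, 2, ctr); v2 <- sweep(v2, 2, ctr); v3 <- sweep(v3, 2, ctr)
  det3 <- v1[, 1] * (v2[, 2] * v3[, 3] - v2[, 3] * v3[, 2]) -
          v1[, 2] * (v2[, 1] * v3[, 3] - v2[, 3] * v3[, 1]) +
          v1[, 3] * (v2[, 1] * v3[, 2] - v2[, 2] * v3[, 1])
  sum(det3) / 6
}

#' Assemble the oral-cavity boundary cloud for one frame
#'
#' The oral cavity is bounded superiorly by the hard-palate mucosa,
#' anteriorly/laterally by the lingual tooth and mandible surfaces,
#' posteroinferiorly by the anterior hyoid, and inferiorly by a straight
#' mylohyoid raphe running from the inferior hyoid pole to the mandibular
#' symphysis. Rigid component clouds are posed into the cranial frame and
#' unioned with the sampled raphe segment.
#'
#' @param cranial_cloud k x 3 matrix: hard palate + teeth landmarks, already
#'   in the cranial frame.
#' @param mandible_cloud,hyoid_cloud reference landmark clouds in bone-fixed
#'   coordinates.
#' @param mandible_pose,hyoid_pose lists with \code{R}, \code{t} posing the
#'   bone-fixed clouds into the cranial frame for this frame (see
#'   \code{\link{estimate_pose}}); NULL poses skip the frame with an error.
#' @param raphe_endpoints 2 x 3 matrix: inferior hyoid pole and mandibular
#'   symphysis, in the cranial frame.
#' @param raphe_n number of raphe line samples (default 50).
#' @return object of class \code{oral_boundary_cloud}: list with
#'   \code{points} (m x 3) and \code{n_points}.
#' @export
assemble_boundary_cloud <- function(cranial_cloud, mandible_cloud, hyoid_cloud,
                                    mandible_pose, hyoid_pose,
                                    raphe_endpoints, raphe_n = 50) {
  if (is.null(mandible_pose) || is.null(hyoid_pose) ||
      anyNA(mandible_pose$R) || anyNA(hyoid_pose$R))
    stop("missing pose for frame")
  pose_pts <- function(cloud, pose)
    sweep(as.matrix(cloud) %*% t(pose$R), 2, pose$t, `+`)
  re <- as.matrix(raphe_endpoints)
  stopifnot(nrow(re) == 2, ncol(re) == 3)
  w <- seq(0, 1, length.out = raphe_n)
  raphe <- outer(1 - w, re[1, ]) + outer(w, re[2, ])
  pts <- rbind(as.matrix(cranial_cloud),
               pose_pts(mandible_cloud, mandible_pose),
               pose_pts(hyoid_cloud, hyoid_pose),
               raphe)
  if (any(!is.finite(pts))) stop("non-finite boundary points")
  log_stage("assemble_boundary_cloud", n_points = nrow(pts))
  structure(list(points = pts, n_points = nrow(pts)),
            class = "oral_boundary_cloud")
}

#' @export
print.oral_boundary_cloud <- function(x, ...) {
  cat(sprintf("oral_boundary_cloud: %d points\n", x$n_points))
  invisible(x)
}
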