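#' Build the three tongue-region primitive meshes
#'
#' The tongue is modelled as three adjacent geometric primitives delimited by
#' the middle and posterior coronal surfaces:
#' \itemize{
#'   \item AOT cone: middle coronal surface as base, anterior (tip) marker as
#'     apex;
#'   \item POT deformed cylinder: middle and posterior coronal surfaces as
#'     the two bases, side wall connecting matched ring samples;
#'   \item TB cone: posterior coronal surface as base, vallecular marker as
#'     apex.
#' }
#' Each primitive is closed (watertight) with winding fixed so outward
#' normals give positive signed volume.
#'
#' @param middle_surf,posterior_surf \code{coronal_surface}s built on rings
#'   already in matched correspondence (same sample count, same handedness,
#'   matched start points; see \code{\link{resample_matched_rings}}).
#' @param anterior_marker 3-vector, apex of the AOT cone.
#' @param vallecula_marker 3-vector, apex of the TB cone, or NULL/NA to omit
#'   the TB mesh (fallback logged).
#' @return named list of \code{tri_mesh}: \code{aot}, \code{pot}, \code{tb}
#'   (NULL when the vallecular marker is missing).
#' @export
build_primitives <- function(middle_surf, posterior_surf,
                             anterior_marker, vallecula_marker = NULL) {
  stopifnot(inherits(middle_surf, "coronal_surface"),
            inherits(posterior_surf, "coronal_surface"))
  nm <- length(middle_surf$boundary_idx)
  np <- length(posterior_surf$boundary_idx)
  if (nm != np) stop("rings are not in matched correspondence (", nm, " vs ", np, ")")
  aot <- cone_mesh(middle_surf, as.numeric(anterior_marker))
  pot <- cylinder_mesh(middle_surf, posterior_surf)
  tb <- NULL
  if (!is.null(vallecula_marker) && !anyNA(vallecula_marker)) {
    tb <- cone_mesh(posterior_surf, as.numeric(vallecula_marker))
  } else {
    log_stage("build_primitives", tb = "omitted: vallecular marker missing")
  }
  list(aot = aot, pot = pot, tb = tb)
}

# direction in which the base mesh's faces traverse the boundary loop:
# +1 when some face contains the edge 1 -> 2 in cyclic face order, -1 when
# it contains 2 -> 1
boundary_traversal <- function(surf) {
  f <- surf$mesh$faces
  hit <- which(rowSums(f == 1L) > 0 & rowSums(f == 2L) > 0)
  for (i in hit) {
    v <- f[i, ]
    for (k in 1:3) if (v[k] == 1L && v[k %% 3 + 1] == 2L) return(1L)
    for (k in 1:3) if (v[k] == 2L && v[k %% 3 + 1] == 1L) return(-1L)
  }
  stop("boundary edge 1-2 not found in base mesh")
}

# closed cone: surface mesh as base plus a triangle fan from apex to the
# boundary ring, windings consistent by construction; global orientation
# fixed so the signed volume is positive
cone_mesh <- function(surf, apex) {
  V <- rbind(surf$mesh$vertices, apex)
  ap <- nrow(V)
  ring <- surf$boundary_idx
  n <- length(ring)
  nxt <- c(2:n, 1)
  # fan traverses each boundary edge opposite to the base faces
  fan <- if (boundary_traversal(surf) > 0)
    cbind(ring[nxt], ring, ap) else cbind(ring, ring[nxt], ap)
  m <- tri_mesh(V, rbind(surf$mesh$faces, fan), drop_degenerate = TRUE)
  orient_outward(m)
}

# closed deformed cylinder: two base surfaces plus a quad strip (split into
# triangles) between matched boundary samples
cylinder_mesh <- function(surf_a, surf_b) {
  na <- nrow(surf_a$mesh$vertices)
  V <- rbind(surf_a$mesh$vertices, surf_b$mesh$vertices)
  n <- length(surf_a$boundary_idx)
  ra <- surf_a$boundary_idx
  rb <- surf_b$boundary_idx + na
  nxt <- c(2:n, 1)
  fa <- surf_a$mesh$faces
  if (boundary_traversal(surf_a) < 0) fa <- fa[, c(1, 3, 2)]
  fb <- surf_b$mesh$faces
  if (boundary_traversal(surf_b) < 0) fb <- fb[, c(1, 3, 2)]
  fb <- fb[, c(1, 3, 2)] + na      # flip cap B so the two caps face apart
  # with cap A traversing k -> k+1, side quads traverse k+1 -> k on A
  side <- rbind(cbind(ra[nxt], ra, rb),
                cbind(ra[nxt], rb, rb[nxt]))
  m <- tri_mesh(V, rbind(fa, fb, side), drop_degenerate = TRUE)
  orient_outward(m)
}

# flip every face when the signed volume is negative
orient_outward <- function(mesh) {
  if (signed_mesh_volume(mesh, signed = TRUE) < 0)
    mesh <- tri_mesh(mesh$vertices, mesh$faces[, c(1, 3, 2)])
  mesh
}

#' Regional tongue volumes per frame
#'
#' Runs the full regional-volume algorithm for each requested frame: fit the
#' middle and posterior coronal spline rings through their 4 control points,
#' resample into matched correspondence, fill each ring with a harmonic
#' surface, assemble the AOT cone / POT deformed cylinder / TB cone, and sum
#' signed tetrahedron volumes. Frames whose geometry fails (missing markers,
#' self-intersecting ring) yield NA volumes and the pipeline continues.
#'
#' @param markers a \code{marker_set} in the cranial frame containing
#'   \code{middle_surface}, \code{lateral_right}, \code{lateral_left},
#'   \code{middle_deep}, \code{posterior_surface}, \code{posterior_right},
#'   \code{posterior_left}, \code{anterior}, and optionally \code{vallecula}.
#' @param hyoid_dorsal frames x 3 matrix: reconstructed dorsal hyoid point.
#' @param frames integer vector of frames to evaluate (default all).
#' @param n_ring equal-arc-length samples per ring (default 300).
#' @param density interior mesh density passed to
#'   \code{\link{fill_harmonic_surface}}.
#' @param keep_meshes return the primitive meshes of each frame.
#' @return data.frame with columns \code{frame}, \code{aot_ml},
#'   \code{pot_ml}, \code{tb_ml} (volumes in mL = mm^3/1000); when
#'   \code{keep_meshes} is TRUE, a \code{meshes} attribute holds the per-frame
#'   primitive lists.
#' @export
regional_volumes <- function(markers, hyoid_dorsal, frames = NULL,
                             n_ring = 300, density = 1, keep_meshes = FALSE) {
  if (is.null(frames)) frames <- seq_len(n_frames(markers))
  hy <- as.matrix(hyoid_dorsal)
  res <- data.frame(frame = frames, aot_ml = NA_real_, pot_ml = NA_real_,
                    tb_ml = NA_real_)
  meshes <- if (keep_meshes) vector("list", length(frames)) else NULL
  need <- c("middle_surface", "lateral_right", "lateral_left", "middle_deep",
            "posterior_surface", "posterior_right", "posterior_left", "anterior")
  miss <- setdiff(need, marker_names(markers))
  if (length(miss)) stop("missing required markers: ", paste(miss, collapse = ", "))
  has_vall <- "vallecula" %in% marker_names(markers)
  for (k in seq_along(frames)) {
    f <- frames[k]
    out <- tryCatch({
      at <- function(nm) markers$coords[f, nm, ]
      # start controls first: middle deep / dorsal hyoid
      cp_mid <- rbind(at("middle_deep"), at("lateral_left"),
                      at("middle_surface"), at("lateral_right"))
      cp_post <- rbind(hy[f, ], at("posterior_left"),
                       at("posterior_surface"), at("posterior_right"))
      ring_m <- fit_coronal_ring(cp_mid)
      ring_p <- fit_coronal_ring(cp_post)
      rs <- resample_matched_rings(ring_m, ring_p, n = n_ring)
      surf_m <- fill_harmonic_surface(coronal_ring(rs$middle), density = density)
      surf_p <- fill_harmonic_surface(coronal_ring(rs$posterior), density = density)
      vall <- if (has_vall) at("vallecula") else NULL
      prim <- build_primitives(surf_m, surf_p, at("anterior"), vall)
      list(prim = prim,
           vols = c(aot = signed_mesh_volume(prim$aot) / 1000,
                    pot = signed_mesh_volume(prim$pot) / 1000,
                    tb = if (is.null(prim$tb)) NA_real_ else
                      signed_mesh_volume(prim$tb) / 1000))
    }, error = function(e) {
      log_stage("regional_volumes", frame = f, error = conditionMessage(e))
      NULL
    })
    if (is.null(out)) next
    res$aot_ml[k] <- out$vols[["aot"]]
    res$pot_ml[k] <- out$vols[["pot"]]
    res$tb_ml[k] <- out$vols[["tb"]]
    if (keep_meshes) meshes[[k]] <- out$prim
  }
  if (keep_meshes) attr(res, "meshes") <- meshes
  res
}
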