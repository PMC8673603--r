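#' Surface area of a mesh or face subset
#'
#' @param mesh a [triangle_mesh()].
#' @param face_subset integer vector of 1-based face indices, or `"all"`.
#' @return total triangle area in mm^2; additive over disjoint subsets.
#' @export
surface_area <- function(mesh, face_subset = "all") {
  stopifnot(inherits(mesh, "triangle_mesh"))
  a <- triangle_areas(mesh$vertices, mesh$faces)
  if (identical(face_subset, "all")) return(sum(a))
  face_subset <- as.integer(face_subset)
  if (length(face_subset) == 0L) return(0)
  if (any(face_subset < 1L) || any(face_subset > nrow(mesh$faces)))
    stop("invalid face index in face_subset", call. = FALSE)
  sum(a[face_subset])
}

#' Cross-section of a mesh at a plane
#'
#' Cuts the mesh at `plane` and returns the planar area enclosed by the
#' intersection contour(s) and the surface area of the mesh portion above the
#' plane (straddling triangles clipped at the plane).
#'
#' `area2d` is computed by Stokes' theorem as the plane-projected signed area
#' of the clipped above-plane surface, which equals the area enclosed by the
#' intersection contours (outer contours minus holes) for consistently
#' oriented meshes, and remains exact when the cut passes exactly through mesh
#' boundary vertices. The contour itself is still assembled by chaining
#' intersection segments (endpoint tolerance 1e-6 mm); an unclosed chain is an
#' error naming the gap location.
#'
#' @param mesh a [triangle_mesh()] with outward/occlusal-up face orientation.
#' @param plane a [plane3d()].
#' @return list with `area2d`, `area3d_above` (mm^2) and `contours` (list of
#'   closed 3D polylines on the plane; may be empty for boundary-touching
#'   cuts).
#' @export
cross_section_at_plane <- function(mesh, plane) {
  stopifnot(inherits(mesh, "triangle_mesh"), inherits(plane, "plane3d"))
  v <- mesh$vertices; f <- mesh$faces
  s <- plane_distance(plane, v)
  eps <- 1e-9 * max(1, max(abs(s)))
  if (all(s < -eps)) {
    warning("plane lies entirely above the mesh; both areas are 0")
    return(list(area2d = 0, area3d_above = 0, contours = list()))
  }
  s1 <- s[f[, 1]]; s2 <- s[f[, 2]]; s3 <- s[f[, 3]]
  above <- s1 >= -eps & s2 >= -eps & s3 >= -eps
  below <- s1 <= eps & s2 <= eps & s3 <= eps & !above
  straddle <- !(above | below)

  areas <- triangle_areas(v, f)
  nrm <- face_normals(mesh)
  nz <- as.numeric(nrm %*% plane$normal)
  area3d <- sum(areas[above])
  area2d <- sum(areas[above] * nz[above])

  segs <- list()
  for (i in which(straddle)) {
    tri <- v[f[i, ], , drop = FALSE]
    sv <- c(s1[i], s2[i], s3[i])
    clip <- clip_triangle_above(tri, sv, eps)
    if (!is.null(clip$poly)) {
      va <- polygon_vector_area(clip$poly)
      area3d <- area3d + sqrt(sum(va^2))
      area2d <- area2d + sum(va * plane$normal)
    }
    if (!is.null(clip$segment)) segs[[length(segs) + 1L]] <- clip$segment
  }
  contours <- assemble_contours(segs, tol = 1e-6)
  list(area2d = max(0, area2d), area3d_above = area3d, contours = contours)
}

# Clip one triangle (rows = vertices, CCW) against halfspace s >= 0.
# Returns the clipped polygon (3D, orientation preserved) and the on-plane
# crossing segment, if the triangle genuinely straddles the plane.
clip_triangle_above <- function(tri, sv, eps) {
  poly <- list(); crossings <- list()
  for (k in 1:3) {
    j <- if (k == 3L) 1L else k + 1L
    pk <- tri[k, ]; pj <- tri[j, ]
    sk <- sv[k]; sj <- sv[j]
    if (sk >= -eps) poly[[length(poly) + 1L]] <- pk
    if ((sk > eps && sj < -eps) || (sk < -eps && sj > eps)) {
      t <- sk / (sk - sj)
      q <- pk + t * (pj - pk)
      poly[[length(poly) + 1L]] <- q
      crossings[[length(crossings) + 1L]] <- q
    }
  }
  out <- list(poly = NULL, segment = NULL)
  if (length(poly) >= 3L) out$poly <- do.call(rbind, poly)
  # include on-plane vertices as crossing points so segments meet at them
  onplane <- which(abs(sv) <= eps)
  for (k in onplane) crossings[[length(crossings) + 1L]] <- tri[k, ]
  if (length(crossings) >= 2L)
    out$segment <- rbind(crossings[[1L]], crossings[[2L]])
  out
}

# 0.5 * sum(p_i x p_{i+1}): vector area of a planar polygon given in order
polygon_vector_area <- function(poly) {
  n <- nrow(poly)
  j <- c(2:n, 1L)
  p <- poly; q <- poly[j, , drop = FALSE]
  0.5 * c(sum(p[, 2] * q[, 3] - p[, 3] * q[, 2]),
          sum(p[, 3] * q[, 1] - p[, 1] * q[, 3]),
          sum(p[, 1] * q[, 2] - p[, 2] * q[, 1]))
}

# Chain crossing segments into closed contours; error if a chain stays open.
assemble_contours <- function(segs, tol = 1e-6) {
  if (length(segs) == 0L) return(list())
  ends <- do.call(rbind, lapply(segs, function(s) s))
  key <- apply(round(ends / tol), 1L, paste, collapse = ",")
  ukey <- unique(key)
  idx <- match(key, ukey)                       # 2 rows per segment
  n_seg <- length(segs)
  a <- idx[seq(1L, 2L * n_seg, by = 2L)]
  b <- idx[seq(2L, 2L * n_seg, by = 2L)]
  keep <- a != b                                # drop degenerate point-segments
  a <- a[keep]; b <- b[keep]
  if (length(a) == 0L) return(list())
  deg <- tabulate(c(a, b), nbins = length(ukey))
  odd <- which(deg %% 2L == 1L)
  if (length(odd) > 0L) {
    p <- ends[match(odd[1L], idx), ]
    stop(sprintf("open cross-section contour: unmatched segment end near (%.4f, %.4f, %.4f)",
                 p[1], p[2], p[3]), call. = FALSE)
  }
  # walk edges into cycles
  adj <- vector("list", length(ukey))
  for (i in seq_along(a)) {
    adj[[a[i]]] <- c(adj[[a[i]]], i)
    adj[[b[i]]] <- c(adj[[b[i]]], i)
  }
  used <- logical(length(a))
  pts <- ends[match(seq_along(ukey), idx), , drop = FALSE]
  contours <- list()
  for (start_edge in seq_along(a)) {
    if (used[start_edge]) next
    cyc <- integer(0)
    node <- a[start_edge]; first <- node
    repeat {
      nxt <- NULL
      for (e in adj[[node]]) if (!used[e]) { nxt <- e; break }
      if (is.null(nxt)) break
      used[nxt] <- TRUE
      node <- if (a[nxt] == node) b[nxt] else a[nxt]
      cyc <- c(cyc, node)
      if (node == first) break
    }
    if (length(cyc) >= 3L)
      contours[[length(contours) + 1L]] <- pts[cyc, , drop = FALSE]
  }
  contours
}
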