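#' Triangle surface meshes
#'
#' Minimal triangle-mesh container used by surface-based registration. Faces
#' are 1-based vertex index triples. Zero-area faces are tolerated up to a
#' small fraction (they occur at the poles of procedurally generated
#' meshes) and are warned about; above the threshold the mesh is rejected.
#'
#' @param vertices Numeric N x 3 matrix, mm.
#' @param faces Integer M x 3 matrix of vertex indices (1-based).
#' @param frame Frame name the vertices live in.
#' @param max_degenerate_fraction Maximum tolerated fraction of zero-area
#'   faces (default 0.02).
#' @return Object of class `surface_model`.
#' @export
surface_model <- function(vertices, faces, frame,
                          max_degenerate_fraction = 0.02) {
  vertices <- rbind(vertices)
  storage.mode(vertices) <- "double"
  faces <- rbind(faces)
  storage.mode(faces) <- "integer"
  if (nrow(vertices) < 3L) {
    nav_abort("a surface needs at least 3 vertices", "mesh_error")
  }
  if (ncol(vertices) != 3L || ncol(faces) != 3L || nrow(faces) < 1L) {
    nav_abort("vertices must be N x 3 and faces M x 3", "mesh_error")
  }
  if (anyNA(vertices) || any(!is.finite(vertices))) {
    nav_abort("vertex coordinates must be finite", "mesh_error")
  }
  if (min(faces) < 1L || max(faces) > nrow(vertices)) {
    nav_abort("face indices out of vertex range", "mesh_error")
  }
  .check_frame(frame)
  areas <- .triangle_areas(vertices, faces)
  n_degen <- sum(areas < 1e-12)
  if (n_degen > max_degenerate_fraction * nrow(faces)) {
    nav_abort(sprintf("mesh has %d zero-area faces (> %.0f%% of %d)",
                      n_degen, 100 * max_degenerate_fraction, nrow(faces)),
              "mesh_error")
  }
  structure(list(vertices = unname(vertices), faces = unname(faces),
                 frame = frame, n_degenerate_faces = n_degen),
            class = "surface_model")
}

#' @export
print.surface_model <- function(x, ...) {
  cat(sprintf("<surface_model> %d vertices, %d faces, frame %s\n",
              nrow(x$vertices), nrow(x$faces), x$frame))
  invisible(x)
}

.triangle_areas <- function(v, f) {
  a <- v[f[, 1], , drop = FALSE]
  ab <- v[f[, 2], , drop = FALSE] - a
  ac <- v[f[, 3], , drop = FALSE] - a
  cr <- cbind(ab[, 2] * ac[, 3] - ab[, 3] * ac[, 2],
              ab[, 3] * ac[, 1] - ab[, 1] * ac[, 3],
              ab[, 1] * ac[, 2] - ab[, 2] * ac[, 1])
  0.5 * sqrt(rowSums(cr^2))
}

# Closest point on each triangle for paired rows (p, a, b, c all n x 3).
# Region-based algorithm: classify the projection of p against the
# triangle's Voronoi regions (vertices, edges, interior) and clamp.
.closest_point_on_triangles <- function(p, a, b, c) {
  ab <- b - a; ac <- c - a; ap <- p - a
  d1 <- rowSums(ab * ap); d2 <- rowSums(ac * ap)
  bp <- p - b
  d3 <- rowSums(ab * bp); d4 <- rowSums(ac * bp)
  cp <- p - c
  d5 <- rowSums(ab * cp); d6 <- rowSums(ac * cp)
  vc <- d1 * d4 - d3 * d2
  vb <- d5 * d2 - d1 * d6
  va <- d3 * d6 - d5 * d4

  n <- nrow(p)
  out <- matrix(0, n, 3)
  done <- rep(FALSE, n)
  take <- function(mask, pts) {
    m <- mask & !done
    if (any(m)) out[m, ] <<- pts[m, , drop = FALSE]
    done <<- done | m
  }
  eps <- .Machine$double.xmin
  take(d1 <= 0 & d2 <= 0, a)                                    # vertex a
  take(d3 >= 0 & d4 <= d3, b)                                   # vertex b
  take(vc <= 0 & d1 >= 0 & d3 <= 0,
       a + ab * (d1 / pmax(d1 - d3, eps)))                      # edge ab
  take(d6 >= 0 & d5 <= d6, c)                                   # vertex c
  take(vb <= 0 & d2 >= 0 & d6 <= 0,
       a + ac * (d2 / pmax(d2 - d6, eps)))                      # edge ac
  take(va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0,
       b + (c - b) * ((d4 - d3) / pmax((d4 - d3) + (d5 - d6), eps)))  # edge bc
  denom <- pmax(va + vb + vc, eps)
  take(rep(TRUE, n), a + ab * (vb / denom) + ac * (vc / denom)) # interior
  out
}

#' Closest points on a mesh
#'
#' For each query point, finds the globally closest point on the triangulated
#' surface (closest point on any triangle, not nearest vertex). Equidistant
#' candidates resolve to the lowest face index.
#'
#' @param points Numeric P x 3 matrix of query points (same frame as the mesh).
#' @param surface A [surface_model].
#' @return List with `points` (P x 3 closest points), `distance` (P), and
#'   `face` (P, 1-based face index).
#' @export
closest_point_on_mesh <- function(points, surface) {
  stopifnot(inherits(surface, "surface_model"))
  points <- rbind(points)
  P <- nrow(points); M <- nrow(surface$faces)
  v <- surface$vertices; f <- surface$faces
  # expand all (face, point) pairs; face index varies fastest so that
  # which.min's first-minimum rule realizes the lowest-face-index tie-break
  fi <- rep.int(seq_len(M), P)
  pi <- rep(seq_len(P), each = M)
  cp <- .closest_point_on_triangles(points[pi, , drop = FALSE],
                                    v[f[fi, 1], , drop = FALSE],
                                    v[f[fi, 2], , drop = FALSE],
                                    v[f[fi, 3], , drop = FALSE])
  d2 <- rowSums((cp - points[pi, , drop = FALSE])^2)
  d2m <- matrix(d2, nrow = M, ncol = P)
  best <- max.col(-t(d2m), ties.method = "first")   # per point, lowest face
  idx <- (seq_len(P) - 1L) * M + best
  list(points = cp[idx, , drop = FALSE],
       distance = sqrt(d2[idx]),
       face = best)
}

#' Procedural ellipsoid mesh
#'
#' Latitude/longitude triangulation of an ellipsoid, used by the study
#' simulator as a coarse stand-in for a skin surface (synthetic; no
#' anatomical fidelity claimed beyond smoothness and curvature).
#'
#' @param semiaxes Numeric length-3 semi-axis lengths, mm.
#' @param center Numeric length-3 center, mm.
#' @param frame Frame name.
#' @param n_theta,n_phi Latitudinal/longitudinal resolution.
#' @return A [surface_model].
#' @export
ellipsoid_mesh <- function(semiaxes = c(70, 90, 110), center = c(0, 0, 0),
                           frame = "PATIENT", n_theta = 14L, n_phi = 24L) {
  th <- seq(0, pi, length.out = n_theta + 1L)
  ph <- seq(0, 2 * pi, length.out = n_phi + 1L)[-(n_phi + 1L)]
  grid <- expand.grid(ph = ph, th = th[-c(1L, n_theta + 1L)])
  verts <- cbind(sin(grid$th) * cos(grid$ph),
                 sin(grid$th) * sin(grid$ph),
                 cos(grid$th))
  verts <- rbind(c(0, 0, 1), verts, c(0, 0, -1))
  verts <- sweep(verts %*% diag(semiaxes), 2L, -center)
  vid <- function(i, j) 1L + (i - 1L) * n_phi + ((j - 1L) %% n_phi) + 1L
  faces <- list()
  for (j in seq_len(n_phi)) {                       # pole caps
    faces[[length(faces) + 1L]] <- c(1L, vid(1L, j), vid(1L, j + 1L))
    faces[[length(faces) + 1L]] <- c(nrow(verts), vid(n_theta - 1L, j + 1L),
                                     vid(n_theta - 1L, j))
  }
  for (i in seq_len(n_theta - 2L)) {                # bands
    for (j in seq_len(n_phi)) {
      faces[[length(faces) + 1L]] <- c(vid(i, j), vid(i + 1L, j), vid(i, j + 1L))
      faces[[length(faces) + 1L]] <- c(vid(i, j + 1L), vid(i + 1L, j),
                                       vid(i + 1L, j + 1L))
    }
  }
  surface_model(verts, do.call(rbind, faces), frame)
}

#' Synthetic face surface
#'
#' An ellipsoid head with smooth Gaussian protrusions added along the
#' outward radial direction: nose, brow ridges, chin, one ear, plus a fixed
#' scatter of low-amplitude texture features. The protrusions break the
#' ellipsoid's near-symmetries so surface matching is well conditioned:
#' plain ellipsoids leave rotations about their axes almost unconstrained
#' and make ICP creep tangentially. Synthetic: no anatomical fidelity is
#' claimed beyond smoothness, scale and asymmetry.
#'
#' @param semiaxes,center,frame,n_theta,n_phi As in [ellipsoid_mesh()];
#'   the +y axis is the facial (anterior) direction and +z superior.
#' @return A [surface_model].
#' @export
synthetic_face_mesh <- function(semiaxes = c(75, 95, 105),
                                center = c(0, -70, 60), frame = "PATIENT",
                                n_theta = 12L, n_phi = 20L) {
  base <- ellipsoid_mesh(semiaxes, center, frame, n_theta, n_phi)
  v <- base$vertices
  rel <- sweep(v, 2L, center)
  radial <- rel / sqrt(rowSums(rel^2))
  # named features + fixed pseudo-random texture scatter (directions from
  # the head center, projected onto the ellipsoid surface)
  dirs <- rbind(
    c(  0,  1.0, -0.5),   # nose
    c(-0.5, 1.0,  0.1),   # brow L
    c( 0.5, 1.0,  0.1),   # brow R
    c(  0,  0.8, -1.2),   # chin
    c(-1.0, -0.3, -0.4)   # left ear region (asymmetry anchor: one side only)
  )
  amp <- c(14, 7, 7, 9, 6)
  width <- c(24, 20, 20, 26, 22)
  n_texture <- 12L
  tex <- .with_seed(830125L, matrix(stats::rnorm(3L * n_texture), ncol = 3L))
  dirs <- rbind(dirs, tex)
  amp <- c(amp, .with_seed(830126L, stats::runif(n_texture, 2.5, 5)))
  width <- c(width, rep(14, n_texture))
  disp <- numeric(nrow(v))
  for (b in seq_len(nrow(dirs))) {
    u <- dirs[b, ] / sqrt(sum(dirs[b, ]^2))
    s <- 1 / sqrt(sum((u / semiaxes)^2))   # ray-ellipsoid intersection
    d2 <- rowSums(sweep(v, 2L, center + s * u)^2)
    disp <- disp + amp[b] * exp(-d2 / (2 * width[b]^2))
  }
  surface_model(v + radial * disp, base$faces, frame)
}

#' Sample points on a mesh surface
#'
#' Area-weighted random sampling of points on the triangles of a mesh,
#' mimicking a probe swept over a surface.
#'
#' @param surface A [surface_model].
#' @param n Number of points.
#' @return A [landmark_set] (labels `s1..sn`) in the mesh frame.
#' @export
sample_mesh_points <- function(surface, n) {
  stopifnot(inherits(surface, "surface_model"), n >= 1)
  areas <- .triangle_areas(surface$vertices, surface$faces)
  fi <- sample.int(nrow(surface$faces), n, replace = TRUE, prob = areas)
  u <- stats::runif(n); v <- stats::runif(n)
  flip <- u + v > 1
  u[flip] <- 1 - u[flip]; v[flip] <- 1 - v[flip]
  a <- surface$vertices[surface$faces[fi, 1], , drop = FALSE]
  b <- surface$vertices[surface$faces[fi, 2], , drop = FALSE]
  c <- surface$vertices[surface$faces[fi, 3], , drop = FALSE]
  pts <- a + (b - a) * u + (c - a) * v
  landmark_set(paste0("s", seq_len(n)), pts, surface$frame)
}
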