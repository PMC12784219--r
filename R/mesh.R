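#' Triangulated tissue surface
#'
#' A `surface_mesh` is one triangulated tissue boundary: a numeric `V x 3`
#' vertex matrix in millimetres and an integer `T x 3` triangle matrix of
#' 1-based vertex indices, wound counter-clockwise seen from outside for
#' closed meshes. A mesh constructed by radial projection from a centre is
#' star-shaped with respect to that centre: every ray from the centre crosses
#' the surface exactly once. The centre is recorded in `star_center`.
#'
#' @param vertices numeric matrix `V x 3`, coordinates in mm.
#' @param triangles integer matrix `T x 3`, 1-based vertex indices.
#' @param tissue one of `"scalp"`, `"skull"`, `"csf"`, `"cortex"`, `"other"`.
#' @param star_center optional length-3 centre w.r.t. which the mesh is
#'   star-shaped, or `NULL` when unknown.
#' @return An object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, triangles, tissue = "other", star_center = NULL) {
  vertices <- as_point_matrix(vertices, "vertices")
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  if (ncol(triangles) != 3L) stop("`triangles` must have 3 columns")
  if (nrow(triangles) > 0L) {
    if (min(triangles) < 1L || max(triangles) > nrow(vertices))
      stop("triangle indices out of range [1, V]")
    rep_v <- triangles[, 1L] == triangles[, 2L] |
      triangles[, 1L] == triangles[, 3L] |
      triangles[, 2L] == triangles[, 3L]
    if (any(rep_v)) stop("triangles must not repeat a vertex")
  }
  tissue <- match.arg(tissue, c("scalp", "skull", "csf", "cortex", "other"))
  if (!is.null(star_center)) star_center <- as.numeric(star_center)[1:3]
  structure(
    list(vertices = unname(vertices), triangles = unname(triangles),
         tissue = tissue, star_center = star_center),
    class = "surface_mesh"
  )
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> tissue=%s  V=%d  T=%d%s\n",
              x$tissue, nrow(x$vertices), nrow(x$triangles),
              if (!is.null(x$star_center)) "  (star-shaped)" else ""))
  invisible(x)
}

as_point_matrix <- function(x, what = "points") {
  if (is.data.frame(x)) x <- as.matrix(x[, c("x", "y", "z")])
  if (is.null(dim(x))) x <- matrix(as.numeric(x), ncol = 3L, byrow = TRUE)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (ncol(x) != 3L) stop("`", what, "` must be n x 3")
  if (anyNA(x) || any(!is.finite(x))) stop("`", what, "` must be finite")
  unname(x)
}

unit_rows <- function(m, zero_error = TRUE) {
  n <- sqrt(rowSums(m^2))
  if (any(n == 0)) {
    if (zero_error) stop("zero-length vector cannot be normalized")
    n[n == 0] <- 1
  }
  m / n
}

#' Reference sphere triangulation
#'
#' Builds an evenly triangulated closed unit sphere with exactly `v_count`
#' vertices and `2 * v_count - 4` triangles, used as the shared reference
#' triangulation for star-shaped head surfaces. The construction places
#' `v_count - 2` vertices on latitude rings between two poles; the ring
#' layout (`n_lat x n_lon = v_count - 2`) is chosen so longitudinal and
#' latitudinal spacing are as even as possible. Triangles are wound
#' counter-clockwise seen from outside.
#'
#' @param v_count number of vertices; `v_count - 2` must have an integer
#'   factorization (any composite or prime works; a prime gives a single ring).
#' @return A `surface_mesh` of the unit sphere, star-shaped around the origin.
#' @export
sphere_triangulation <- function(v_count = 1922L) {
  v_count <- as.integer(v_count)
  if (v_count < 6L) stop("v_count must be >= 6")
  n <- v_count - 2L
  divs <- which(n %% seq_len(n) == 0L)
  # want n_lon ~ 2 * n_lat for even angular spacing
  n_lon <- divs[which.min(abs(divs - sqrt(2 * n)))]
  n_lat <- n %/% n_lon
  if (n_lon < 3L) { # degenerate ring; fall back to the other orientation
    n_lon <- n %/% n_lon
    n_lat <- n %/% n_lon
  }
  if (n_lon < 3L) stop("v_count - 2 admits no ring layout with >= 3 longitudes")

  theta <- pi * seq_len(n_lat) / (n_lat + 1)
  phi <- 2 * pi * (seq_len(n_lon) - 1L) / n_lon
  rings <- do.call(rbind, lapply(theta, function(th)
    cbind(sin(th) * cos(phi), sin(th) * sin(phi), rep(cos(th), n_lon))))
  verts <- rbind(c(0, 0, 1), rings, c(0, 0, -1))
  north <- 1L
  south <- v_count
  ring_idx <- function(i, j) 1L + (i - 1L) * n_lon + ((j - 1L) %% n_lon) + 1L

  tris <- vector("list", 2L * n_lat)
  j <- seq_len(n_lon)
  tris[[1L]] <- cbind(north, ring_idx(1L, j), ring_idx(1L, j + 1L))
  if (n_lat > 1L) {
    for (i in seq_len(n_lat - 1L)) {
      u1 <- ring_idx(i, j); u2 <- ring_idx(i, j + 1L)
      l1 <- ring_idx(i + 1L, j); l2 <- ring_idx(i + 1L, j + 1L)
      tris[[2L * i]] <- cbind(u1, l1, l2)
      tris[[2L * i + 1L]] <- cbind(u1, l2, u2)
    }
  }
  tris[[2L * n_lat]] <- cbind(south, ring_idx(n_lat, j + 1L), ring_idx(n_lat, j))
  tri <- do.call(rbind, tris)

  # enforce outward winding (normals point away from the origin)
  a <- verts[tri[, 1L], , drop = FALSE]
  b <- verts[tri[, 2L], , drop = FALSE]
  c_ <- verts[tri[, 3L], , drop = FALSE]
  nrm <- cross_rows(b - a, c_ - a)
  flip <- rowSums(nrm * (a + b + c_)) < 0
  if (any(flip)) tri[flip, 2:3] <- tri[flip, 3:2]

  surface_mesh(verts, tri, tissue = "other", star_center = c(0, 0, 0))
}

cross_rows <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Project a radial function onto a reference sphere triangulation
#'
#' Builds a star-shaped surface by evaluating a positive radial function on the
#' vertex directions of a reference unit-sphere triangulation: vertex i is
#' `center + radial_fn(u_i) * u_i`. The triangle array is copied from the
#' reference, so all surfaces built from one reference share a triangulation,
#' and the result is star-shaped from `center` by construction.
#'
#' @param radial_fn either a function taking an `n x 3` matrix of unit
#'   directions and returning `n` positive radii (mm), or a single positive
#'   number for a sphere.
#' @param center length-3 centre (mm).
#' @param reference a `surface_mesh` unit sphere (see [sphere_triangulation()]).
#' @param tissue tissue tag for the result.
#' @return A `surface_mesh`, star-shaped w.r.t. `center`.
#' @export
project_to_sphere_triangulation <- function(radial_fn, center = c(0, 0, 0),
                                            reference = sphere_triangulation(),
                                            tissue = "other") {
  u <- unit_rows(reference$vertices)
  r <- if (is.function(radial_fn)) radial_fn(u) else rep(as.numeric(radial_fn), nrow(u))
  r <- as.numeric(r)
  if (length(r) != nrow(u)) stop("radial_fn must return one radius per direction")
  if (any(!is.finite(r)) || any(r <= 0)) stop("radial function must be positive and finite")
  center <- as.numeric(center)[1:3]
  v <- r * u + matrix(center, nrow(u), 3L, byrow = TRUE)
  surface_mesh(v, reference$triangles, tissue = tissue, star_center = center)
}

#' Area-weighted vertex normals
#'
#' Outward vertex normals computed as the normalized area-weighted average of
#' incident triangle normals (triangle cross products carry the area weight).
#'
#' @param mesh a `surface_mesh` with outward triangle winding.
#' @return `V x 3` matrix of unit normals.
#' @export
vertex_normals <- function(mesh) {
  v <- mesh$vertices; f <- mesh$triangles
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  fn <- cross_rows(b - a, c_ - a) # length = 2 * area
  n <- matrix(0, nrow(v), 3L)
  for (k in 1:3) {
    idx <- f[, k]
    n[, 1] <- n[, 1] + tapply_add(fn[, 1], idx, nrow(v))
    n[, 2] <- n[, 2] + tapply_add(fn[, 2], idx, nrow(v))
    n[, 3] <- n[, 3] + tapply_add(fn[, 3], idx, nrow(v))
  }
  unit_rows(n)
}

tapply_add <- function(x, idx, n) {
  out <- numeric(n)
  s <- rowsum(x, idx)
  out[as.integer(rownames(s))] <- s
  out
}

# quasi-uniform directions on the sphere (Fibonacci spiral), deterministic
fibonacci_directions <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  ga <- pi * (3 - sqrt(5))
  cbind(r * cos(ga * i), r * sin(ga * i), z)
}
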