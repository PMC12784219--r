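#' Anatomical fiducials
#'
#' The three landmarks defining head coordinate frames: nasion (NAS) and the
#' left and right pre-auricular points (LPA, RPA), in mm. They must be
#' non-collinear, otherwise the frame is ill-posed.
#'
#' @param nas,lpa,rpa length-3 coordinates (mm).
#' @return An object of class `fiducials`.
#' @export
fiducials <- function(nas, lpa, rpa) {
  nas <- as.numeric(nas)[1:3]; lpa <- as.numeric(lpa)[1:3]; rpa <- as.numeric(rpa)[1:3]
  if (anyNA(c(nas, lpa, rpa))) stop("fiducials must be finite length-3 points")
  cr <- crossprod3(lpa - nas, rpa - nas)
  scale <- max(sqrt(sum((lpa - nas)^2)), sqrt(sum((rpa - nas)^2)), 1e-12)
  if (sqrt(sum(cr^2)) <= 1e-9 * scale^2)
    stop("fiducials are collinear; head frame is ill-posed")
  structure(list(nas = nas, lpa = lpa, rpa = rpa), class = "fiducials")
}

crossprod3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

fiducial_matrix <- function(fid) rbind(fid$nas, fid$lpa, fid$rpa)

#' Rigid transform
#'
#' A rotation + translation pair mapping points as `x -> R x + t`. The rotation
#' must be orthonormal with determinant +1.
#'
#' @param rotation 3x3 orthonormal matrix, `det = +1`.
#' @param translation length-3 vector (mm).
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)[1:3]
  if (!all(dim(rotation) == c(3L, 3L))) stop("rotation must be 3x3")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6)
    stop("rotation must be orthonormal")
  if (abs(det(rotation) - 1) > 1e-6) stop("rotation must have determinant +1")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' Apply, invert and compose rigid transforms
#'
#' `transform_points()` applies a rigid transform to an `n x 3` point matrix,
#' a `surface_mesh`, a `fiducials` triple, or a whole `head_model`.
#'
#' @param xf a `rigid_transform`.
#' @param x points / mesh / fiducials / head model to transform.
#' @return The transformed object, same type as `x`.
#' @export
transform_points <- function(xf, x) {
  UseMethod("transform_points", x)
}

#' @export
transform_points.default <- function(xf, x) {
  p <- as_point_matrix(x)
  p %*% t(xf$rotation) + matrix(xf$translation, nrow(p), 3L, byrow = TRUE)
}

#' @export
transform_points.surface_mesh <- function(xf, x) {
  out <- x
  out$vertices <- transform_points.default(xf, x$vertices)
  if (!is.null(x$star_center))
    out$star_center <- drop(transform_points.default(xf, rbind(x$star_center)))
  out
}

#' @export
transform_points.fiducials <- function(xf, x) {
  m <- transform_points.default(xf, fiducial_matrix(x))
  fiducials(m[1, ], m[2, ], m[3, ])
}

#' @rdname transform_points
#' @export
invert_transform <- function(xf) {
  rigid_transform(t(xf$rotation), -drop(t(xf$rotation) %*% xf$translation))
}

#' @rdname transform_points
#' @param a,b transforms; the composition applies `b` first, then `a`.
#' @export
compose_transforms <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  drop(a$rotation %*% b$translation) + a$translation)
}

#' CTF alignment from fiducials
#'
#' Constructs the rigid transform into the CTF head frame: origin at the
#' midpoint of LPA and RPA, x-axis toward NAS, ALS orientation (x = anterior,
#' y = left, z = superior), original size in mm. Axes: `x = unit(NAS - origin)`,
#' `z = unit(x × (LPA - RPA))`, `y = z × x`.
#'
#' @param fid a `fiducials` object; must be non-collinear.
#' @return A `rigid_transform` mapping the input frame into CTF.
#' @export
ctf_from_fiducials <- function(fid) {
  stopifnot(inherits(fid, "fiducials"))
  origin <- (fid$lpa + fid$rpa) / 2
  xax <- fid$nas - origin
  nx <- sqrt(sum(xax^2))
  if (nx <= 1e-12) stop("NAS coincides with the LPA/RPA midpoint")
  xax <- xax / nx
  zax <- crossprod3(xax, fid$lpa - fid$rpa)
  nz <- sqrt(sum(zax^2))
  if (nz <= 1e-12) stop("fiducials are collinear; CTF frame is ill-posed")
  zax <- zax / nz
  yax <- crossprod3(zax, xax)
  rot <- rbind(xax, yax, zax)
  dimnames(rot) <- NULL
  rigid_transform(rot, -drop(rot %*% origin))
}

#' Nested four-shell head model
#'
#' Ordered nested tissue boundaries (scalp, skull, CSF, cortex) that share one
#' triangle array and one vertex count, plus fiducials and a coordinate-system
#' tag. Nesting (surfaces in order cortex <= csf <= skull <= scalp along rays
#' from the cortex centroid) is checkable via [check_nesting()], not enforced.
#'
#' @param scalp,skull,csf,cortex `surface_mesh` shells, outermost first.
#' @param fiducials a `fiducials` object.
#' @param coord_system `"native"`, `"acpc"` or `"ctf"`.
#' @return An object of class `head_model` with elements `shells` (named list),
#'   `fiducials`, `coord_system`.
#' @export
head_model <- function(scalp, skull, csf, cortex, fiducials,
                       coord_system = c("native", "acpc", "ctf")) {
  shells <- list(scalp = scalp, skull = skull, csf = csf, cortex = cortex)
  for (nm in names(shells)) {
    if (!inherits(shells[[nm]], "surface_mesh")) stop("shells must be surface_mesh")
    shells[[nm]]$tissue <- nm
  }
  v <- vapply(shells, function(s) nrow(s$vertices), 0L)
  if (length(unique(v)) != 1L) stop("all shells must share one vertex count")
  tri <- shells$scalp$triangles
  for (nm in names(shells)[-1])
    if (!identical(shells[[nm]]$triangles, tri))
      stop("all shells must share one triangle array")
  stopifnot(inherits(fiducials, "fiducials"))
  coord_system <- match.arg(coord_system)
  structure(list(shells = shells, fiducials = fiducials,
                 coord_system = coord_system),
            class = "head_model")
}

#' @export
print.head_model <- function(x, ...) {
  cat(sprintf("<head_model> V=%d per shell, frame=%s\n",
              nrow(x$shells$scalp$vertices), x$coord_system))
  invisible(x)
}

tissue_order <- c("scalp", "skull", "csf", "cortex")

#' @export
transform_points.head_model <- function(xf, x) {
  x$shells <- lapply(x$shells, function(s) transform_points(xf, s))
  x$fiducials <- transform_points(xf, x$fiducials)
  x
}

#' Align a head model to its own fiducials (CTF frame)
#'
#' @param head a `head_model`.
#' @return The head transformed into CTF, tagged `coord_system = "ctf"`.
#' @export
align_ctf <- function(head) {
  xf <- ctf_from_fiducials(head$fiducials)
  out <- transform_points(xf, head)
  out$coord_system <- "ctf"
  out
}

#' Ray-mesh intersection
#'
#' Nearest intersection of a ray with a triangulated surface
#' (Moller-Trumbore per triangle, determinant epsilon 1e-12; ties between
#' coincident hits go to the lowest triangle index; degenerate triangles are
#' skipped). Only intersections with strictly positive ray parameter count.
#'
#' @param mesh a `surface_mesh`.
#' @param origin length-3 ray origin (mm).
#' @param direction length-3 ray direction (need not be unit length).
#' @return A list with `point` (length-3), `triangle` (index), `distance`
#'   (mm along the normalized direction), or `NULL` when the ray misses.
#' @export
ray_mesh_intersect <- function(mesh, origin, direction) {
  direction <- as.numeric(direction)[1:3]
  nd <- sqrt(sum(direction^2))
  if (nd == 0) stop("direction must be nonzero")
  if (nrow(mesh$triangles) == 0L) return(NULL)
  hit <- cpp_ray_mesh(rbind(as.numeric(origin)[1:3]), rbind(direction / nd),
                      mesh$vertices, mesh$triangles)
  if (is.na(hit$t[1])) return(NULL)
  list(point = drop(hit$point[1, ]), triangle = hit$triangle[1],
       distance = hit$t[1])
}

# vectorized form: origins 1x3 or Kx3, dirs Kx3 (rows normalized here).
# With a single shared origin and a non-trivial mesh the cone-pruned scan is
# used; it returns the same nearest hits as the full scan.
rays_mesh_intersect <- function(mesh, origins, dirs) {
  dirs <- unit_rows(as_point_matrix(dirs, "dirs"))
  origins <- as_point_matrix(origins, "origins")
  if (nrow(origins) == 1L && nrow(mesh$triangles) >= 200L)
    cpp_ray_mesh_star(origins[1L, ], dirs, mesh$vertices, mesh$triangles)
  else
    cpp_ray_mesh(origins, dirs, mesh$vertices, mesh$triangles)
}

#' Cut a point set above the ears
#'
#' Keeps the points whose signed distance above the fiducial plane (the plane
#' through NAS, LPA and RPA, normal oriented superiorly) is at least `offset`
#' millimetres; ties at exactly `offset` are kept. This reproduces the usual
#' scalp-proxy preprocessing of photogrammetry scans.
#'
#' @param points `n x 3` matrix (mm), same frame as `fid`.
#' @param fid a `fiducials` object.
#' @param offset height above the fiducial plane in mm (default 35).
#' @return The kept subset of rows of `points` (possibly 0 rows, with a
#'   warning).
#' @export
cut_above_ears <- function(points, fid, offset = 35) {
  points <- as_point_matrix(points)
  # superior orientation: positive component along CTF z
  zsup <- ctf_from_fiducials(fid)$rotation[3, ]
  n <- crossprod3(fid$lpa - fid$nas, fid$rpa - fid$nas)
  n <- n / sqrt(sum(n^2))
  if (sum(n * zsup) < 0) n <- -n
  d <- drop((points - matrix(fid$nas, nrow(points), 3L, byrow = TRUE)) %*% n)
  keep <- d >= offset
  if (!any(keep)) warning("cut_above_ears removed every point")
  points[keep, , drop = FALSE]
}

#' Shift points inward along their normals
#'
#' Translates each point by `-distance` times its outward unit normal, e.g. to
#' compensate electrode-holder thickness in digitized montages. Non-unit
#' normals are normalized; a zero normal is an error.
#'
#' @param points `n x 3` matrix (mm).
#' @param normals `n x 3` outward normals.
#' @param distance shift in mm (default 12).
#' @return Shifted `n x 3` matrix.
#' @export
move_inward <- function(points, normals, distance = 12) {
  points <- as_point_matrix(points)
  normals <- as_point_matrix(normals, "normals")
  if (nrow(normals) != nrow(points)) stop("one normal per point required")
  points - distance * unit_rows(normals)
}

#' Farthest-point decimation of a point cloud
#'
#' Deterministic farthest-point sampling: the first point is the one farthest
#' from the cloud centroid, each subsequent point maximizes the distance to the
#' already selected set. Spreads `target_n` points over the input.
#'
#' @param points `n x 3` matrix.
#' @param target_n number of points to keep (`1 <= target_n <= n`).
#' @return `target_n x 3` subset of `points`.
#' @export
decimate_pointcloud <- function(points, target_n) {
  points <- as_point_matrix(points)
  n <- nrow(points)
  target_n <- as.integer(target_n)
  if (target_n <= 0L) stop("target_n must be positive")
  if (target_n > n) stop("target_n exceeds number of points")
  if (target_n == n) return(points)
  ctr <- colMeans(points)
  sel <- integer(target_n)
  sel[1L] <- which.max(rowSums((points - matrix(ctr, n, 3L, byrow = TRUE))^2))
  mind <- rowSums((points - matrix(points[sel[1L], ], n, 3L, byrow = TRUE))^2)
  if (target_n > 1L) for (k in 2L:target_n) {
    sel[k] <- which.max(mind)
    d <- rowSums((points - matrix(points[sel[k], ], n, 3L, byrow = TRUE))^2)
    mind <- pmin(mind, d)
  }
  points[sel, , drop = FALSE]
}

#' Check shell nesting by raycasting
#'
#' Casts `n_rays` quasi-uniform rays from the cortex centroid and checks that
#' the four shells are hit in strictly increasing order cortex < CSF < skull <
#' scalp along every ray, as required for boundary-element head modelling.
#'
#' @param head a `head_model`.
#' @param n_rays number of test rays (default 200).
#' @return A list: `ok` (logical), `min_gap_per_pair` (named mm vector for the
#'   adjacent pairs csf-cortex, skull-csf, scalp-skull), `n_missed` rays that
#'   missed at least one shell.
#' @export
check_nesting <- function(head, n_rays = 200L) {
  ctr <- colMeans(head$shells$cortex$vertices)
  dirs <- fibonacci_directions(as.integer(n_rays))
  dist <- sapply(tissue_order, function(nm) {
    rays_mesh_intersect(head$shells[[nm]], rbind(ctr), dirs)$t
  })
  missed <- rowSums(is.na(dist)) > 0
  gaps <- cbind(csf_cortex = dist[, "csf"] - dist[, "cortex"],
                skull_csf = dist[, "skull"] - dist[, "csf"],
                scalp_skull = dist[, "scalp"] - dist[, "skull"])
  ok <- !any(missed) && all(gaps > 0)
  min_gap <- apply(gaps[!missed, , drop = FALSE], 2, function(g)
    if (length(g)) min(g) else NA_real_)
  list(ok = ok, min_gap_per_pair = min_gap, n_missed = sum(missed))
}
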