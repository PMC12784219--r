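#' Fit a 3D thin-plate spline
#'
#' Thin-plate spline interpolation/smoothing in 3D with kernel `U(r) = r`:
#' solves the standard bordered system for warp coefficients and an affine
#' part under the side conditions that the coefficient columns are orthogonal
#' to `{1, x, y, z}` at the control points. With `regularization = 0` the
#' transform interpolates `dst` at `src` exactly.
#'
#' @param src `L x 3` source control points (mm), `L >= 4`, non-coplanar when
#'   `regularization = 0`.
#' @param dst `L x 3` target points.
#' @param regularization non-negative smoothing added to the kernel diagonal.
#' @return An object of class `tps_transform`: `control_src`, `coefficients`
#'   (`L x 3`), `affine` (`3 x 4`, acting as `A [x; 1]`), `bending_energy`.
#' @export
fit_tps <- function(src, dst, regularization = 0) {
  src <- as_point_matrix(src, "src")
  dst <- as_point_matrix(dst, "dst")
  L <- nrow(src)
  if (nrow(dst) != L) stop("src and dst must have the same number of points")
  if (L < 4L) stop("need at least 4 control points")
  if (regularization < 0) stop("regularization must be >= 0")
  K <- tps_kernel(src, src) + diag(regularization, L)
  P <- cbind(1, src)
  M <- rbind(cbind(K, P), cbind(t(P), matrix(0, 4L, 4L)))
  rhs <- rbind(dst, matrix(0, 4L, 3L))
  sol <- tryCatch(solve(M, rhs), error = function(e)
    stop("degenerate control configuration (coplanar or duplicated source ",
         "points); increase `regularization`", call. = FALSE))
  W <- sol[seq_len(L), , drop = FALSE]
  A <- t(sol[L + 1:4, , drop = FALSE]) # 3 x 4, columns (const, x, y, z)
  be <- sum(W * (K %*% W))
  structure(list(control_src = src, coefficients = W,
                 affine = A, bending_energy = be,
                 regularization = regularization),
            class = "tps_transform")
}

tps_kernel <- function(a, b) {
  # |a_i - b_j| kernel matrix
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

#' Apply a thin-plate-spline transform
#'
#' @param tps a `tps_transform`.
#' @param points `n x 3` matrix (mm).
#' @return Warped `n x 3` matrix.
#' @export
transform_tps <- function(tps, points) {
  p <- as_point_matrix(points)
  U <- tps_kernel(p, tps$control_src)
  cbind(1, p) %*% t(tps$affine) + U %*% tps$coefficients
}

#' Template-warp baseline (TPS)
#'
#' The template-warping individualization baseline: for each proxy point the
#' corresponding template-scalp point is found by raytracing from the template
#' cortex centroid (the same construction as the shape-difference metric), a 3D
#' thin-plate spline is fitted on those correspondences, and the warp is
#' applied to all four shells and the fiducials. Fast and simple, but inner
#' shells inherit the template's details, and spiky proxies can distort the
#' result (nesting is re-checked and violations reported).
#'
#' @param template a `head_model` in CTF (typically the population mean head).
#' @param proxy a `scalp_proxy`; CTF-aligned via its fiducials unless
#'   `align = FALSE`.
#' @param regularization TPS smoothing; the default `NULL` uses
#'   `1e-6 * median control spacing` to stabilize near-coplanar layouts.
#' @param align CTF-align the proxy first (default TRUE).
#' @return A list of class `tps_warp_result`: `head` (warped `head_model`),
#'   `tps`, `nesting` (report from [check_nesting()]), `n_missed`
#'   correspondences dropped because the ray missed the template scalp.
#' @export
warp_headmodel <- function(template, proxy, regularization = NULL, align = TRUE) {
  stopifnot(inherits(template, "head_model"), inherits(proxy, "scalp_proxy"))
  if (align) proxy <- align_proxy_ctf(proxy)
  ctr <- colMeans(template$shells$cortex$vertices)
  p <- proxy$points
  dirs <- p - matrix(ctr, nrow(p), 3L, byrow = TRUE)
  hit <- rays_mesh_intersect(template$shells$scalp, rbind(ctr), dirs)
  ok <- !is.na(hit$t)
  if (sum(ok) < 4L) stop("degenerate correspondences: fewer than 4 proxy rays ",
                         "intersect the template scalp")
  src <- hit$point[ok, , drop = FALSE]
  dst <- p[ok, , drop = FALSE]
  if (is.null(regularization)) {
    nn <- apply(tps_kernel(src, src) + diag(Inf, nrow(src)), 1, min)
    regularization <- 1e-6 * median(nn)
  }
  tps <- fit_tps(src, dst, regularization)
  out <- template
  for (nm in tissue_order) {
    out$shells[[nm]]$vertices <- transform_tps(tps, template$shells[[nm]]$vertices)
    out$shells[[nm]]$star_center <- NULL
  }
  fm <- transform_tps(tps, fiducial_matrix(template$fiducials))
  out$fiducials <- fiducials(fm[1, ], fm[2, ], fm[3, ])
  nest <- check_nesting(out)
  if (!nest$ok)
    warning("TPS-warped head violates shell nesting; baseline warps can distort")
  structure(list(head = out, tps = tps, nesting = nest,
                 n_missed = sum(!ok)),
            class = "tps_warp_result")
}
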