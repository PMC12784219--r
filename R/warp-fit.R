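#' Scalp proxy
#'
#' A sparse or dense point sample of the outer head surface standing in for
#' the true scalp: a photogrammetry point cloud, digitized electrode positions,
#' or vertices of a scanned mesh, together with the subject's fiducials.
#'
#' @param points `K x 3` matrix (mm), `K >= 4`.
#' @param fiducials a `fiducials` object in the same frame as `points`.
#' @param provenance `"photogrammetry"`, `"electrodes"` or `"mesh"`.
#' @param labels optional character vector of per-point labels.
#' @return An object of class `scalp_proxy`.
#' @export
scalp_proxy <- function(points, fiducials,
                        provenance = c("photogrammetry", "electrodes", "mesh"),
                        labels = NULL) {
  points <- as_point_matrix(points)
  if (nrow(points) < 4L) stop("a scalp proxy needs at least 4 points")
  stopifnot(inherits(fiducials, "fiducials"))
  provenance <- match.arg(provenance)
  if (!is.null(labels) && length(labels) != nrow(points))
    stop("one label per point required")
  structure(list(points = points, fiducials = fiducials,
                 provenance = provenance, labels = labels),
            class = "scalp_proxy")
}

#' @export
print.scalp_proxy <- function(x, ...) {
  cat(sprintf("<scalp_proxy> %d points (%s)\n", nrow(x$points), x$provenance))
  invisible(x)
}

#' Align a scalp proxy to the CTF frame via its fiducials
#'
#' @param proxy a `scalp_proxy`.
#' @return The proxy with points and fiducials in CTF coordinates.
#' @export
align_proxy_ctf <- function(proxy) {
  xf <- ctf_from_fiducials(proxy$fiducials)
  proxy$points <- transform_points(xf, proxy$points)
  proxy$fiducials <- transform_points(xf, proxy$fiducials)
  proxy
}

#' Preprocess a scalp proxy
#'
#' CTF-aligns the proxy, cuts it above the ears, and optionally decimates it by
#' farthest-point sampling -- the standard preparation of photogrammetry scans
#' before fitting.
#'
#' @param proxy a `scalp_proxy`.
#' @param cut_offset mm above the fiducial plane (default 35); `NULL` skips.
#' @param target_n decimation target (default `NULL` = keep all).
#' @return The preprocessed `scalp_proxy`.
#' @export
preprocess_proxy <- function(proxy, cut_offset = 35, target_n = NULL) {
  proxy <- align_proxy_ctf(proxy)
  if (!is.null(cut_offset)) {
    proxy$points <- cut_above_ears(proxy$points, proxy$fiducials, cut_offset)
    proxy$labels <- NULL
  }
  if (!is.null(target_n) && target_n < nrow(proxy$points))
    proxy$points <- decimate_pointcloud(proxy$points, target_n)
  proxy
}

#' Fit configuration
#'
#' Tunable parameters of the shape-model fit.
#'
#' @param n_pcs number of principal components to optimize (default 16, a good
#'   accuracy/overfitting compromise).
#' @param metric `"shape_difference"` (raytraced along rays from the cortex
#'   centroid; meshing-independent, the default) or `"vertex_distance"`
#'   (nearest mesh vertex).
#' @param penalty_threshold inter-shell proximity threshold T in mm (default 1).
#' @param penalty_weight multiplier lambda on the penalty term (default 1, i.e.
#'   plain addition; 0 disables).
#' @param squared use squared distances in the data term (default FALSE:
#'   unsquared Euclidean norms).
#' @param max_iter BFGS iteration cap (default 60).
#' @param tol relative objective tolerance (default 1e-6).
#' @param method `"bfgs"` (quasi-Newton with central-difference gradients) or
#'   `"frozen"` (alternating frozen-correspondence linear least squares; fast).
#' @param seed integer seed recorded with the fit.
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(n_pcs = 16L,
                       metric = c("shape_difference", "vertex_distance"),
                       penalty_threshold = 1, penalty_weight = 1,
                       squared = FALSE, max_iter = 60L, tol = 1e-6,
                       method = c("bfgs", "frozen"), seed = 1L) {
  metric <- match.arg(metric)
  method <- match.arg(method)
  if (penalty_threshold <= 0) stop("penalty_threshold must be > 0")
  n_pcs <- as.integer(n_pcs)
  if (n_pcs < 1L) stop("n_pcs must be >= 1")
  structure(list(n_pcs = n_pcs, metric = metric,
                 penalty_threshold = penalty_threshold,
                 penalty_weight = penalty_weight, squared = squared,
                 max_iter = as.integer(max_iter), tol = tol,
                 method = method, seed = as.integer(seed)),
            class = "fit_config")
}

#' Vertex-distance metric
#'
#' Distance from each proxy point to its nearest vertex on the scalp mesh.
#' Meshing-dependent: it includes the tangential offset to the nearest vertex.
#'
#' @param proxy a `scalp_proxy` or `K x 3` matrix.
#' @param scalp a `surface_mesh`.
#' @return Numeric vector of per-point distances (mm).
#' @export
vertex_distance_metric <- function(proxy, scalp) {
  p <- if (inherits(proxy, "scalp_proxy")) proxy$points else as_point_matrix(proxy)
  cpp_nearest_vertex(p, scalp$vertices)$distance
}

#' Shape-difference metric
#'
#' For each proxy point, casts the ray from the head centre (the mean cortex
#' vertex when fitting a head model) through the point, intersects it with the
#' scalp mesh, and takes the Euclidean distance from the proxy point to that
#' intersection. Approximately normal to the surface and independent of where
#' the mesh vertices happen to sit. Rays that miss (non-star-shaped
#' intermediate meshes) fall back to the vertex distance for that point; the
#' count of fallbacks is attached as attribute `n_fallback`.
#'
#' @param proxy a `scalp_proxy` or `K x 3` matrix.
#' @param scalp a `surface_mesh`.
#' @param center length-3 ray origin (mm).
#' @return Numeric vector of per-point distances (mm), attribute `n_fallback`.
#' @export
shape_difference_metric <- function(proxy, scalp, center) {
  p <- if (inherits(proxy, "scalp_proxy")) proxy$points else as_point_matrix(proxy)
  center <- as.numeric(center)[1:3]
  dirs <- p - matrix(center, nrow(p), 3L, byrow = TRUE)
  hit <- rays_mesh_intersect(scalp, rbind(center), dirs)
  d <- sqrt(rowSums((p - hit$point)^2))
  miss <- is.na(hit$t)
  if (any(miss))
    d[miss] <- cpp_nearest_vertex(p[miss, , drop = FALSE], scalp$vertices)$distance
  attr(d, "n_fallback") <- sum(miss)
  d
}

#' Inter-shell proximity penalty
#'
#' Sum over all unordered pairs of distinct shells, over all vertex pairs
#' closer than the threshold `T`, of `T - distance` (mm). Zero exactly when
#' every inter-shell vertex pair is at least `T` apart; keeps the reconstructed
#' shells usable for boundary-element modelling.
#'
#' @param head a `head_model`.
#' @param T proximity threshold in mm (default 1).
#' @return Non-negative scalar (mm).
#' @export
penalty_g <- function(head, T = 1) {
  P <- do.call(rbind, lapply(tissue_order, function(nm) head$shells[[nm]]$vertices))
  v <- nrow(head$shells$scalp$vertices)
  shell <- rep.int(seq_len(4L), rep.int(v, 4L))
  cpp_penalty_g(P, shell, T)
}

#' Shape-fit objective
#'
#' Reconstructs the head from PC weights, recomputes proxy correspondences
#' under the configured metric (they are recomputed at every evaluation), and
#' returns the summed per-point distances plus `penalty_weight` times the
#' inter-shell penalty.
#'
#' @param weights numeric PC weight vector (raw units).
#' @param model a `shape_model`.
#' @param proxy a `scalp_proxy` in CTF.
#' @param cfg a `fit_config`.
#' @return Scalar objective value; attributes `data_term`, `penalty`,
#'   `residuals`.
#' @export
pcawarp_objective <- function(weights, model, proxy, cfg = fit_config()) {
  head <- reconstruct_head_fast(model, weights)
  r <- metric_residuals(head, proxy, cfg)
  data_term <- if (cfg$squared) sum(r^2) else sum(r)
  pen <- if (cfg$penalty_weight != 0)
    penalty_g(head, cfg$penalty_threshold) else 0
  out <- data_term + cfg$penalty_weight * pen
  attr(out, "data_term") <- data_term
  attr(out, "penalty") <- pen
  attr(out, "residuals") <- r
  out
}

metric_residuals <- function(head, proxy, cfg) {
  scalp <- head$shells$scalp
  if (cfg$metric == "vertex_distance") {
    vertex_distance_metric(proxy, scalp)
  } else {
    shape_difference_metric(proxy, scalp, colMeans(head$shells$cortex$vertices))
  }
}

#' Fit shape-model weights to a scalp proxy
#'
#' The core individualization step: starting from the mean head (zero
#' weights), minimizes the summed proxy-to-scalp metric plus the inter-shell
#' penalty over the first `n_pcs` PC weights. Weights are internally scaled by
#' the per-component singular values so the optimizer sees comparably scaled
#' axes; results are reported in raw units. The remaining surfaces (skull, CSF,
#' cortex) and the fiducials follow from the shape model.
#'
#' `method = "bfgs"` (default) runs quasi-Newton minimization with central
#' finite-difference gradients and one restart from the best iterate if the
#' first run stalls above it. `method = "frozen"` alternates freezing the
#' correspondences with an exact linear least-squares solve (fast mode;
#' penalty not included in the solve, re-scored at the end).
#'
#' @param model a `shape_model`.
#' @param proxy a `scalp_proxy`; aligned to CTF via its fiducials unless
#'   `align = FALSE`.
#' @param cfg a `fit_config`.
#' @param align CTF-align the proxy first (default TRUE).
#' @return An object of class `pcawarp_fit`: `weights`, `head` (reconstructed
#'   `head_model`), `objective` (the data term: summed metric residuals at the
#'   returned weights, mm), `penalty` (mm), `total_objective`
#'   (`objective + penalty_weight * penalty`, the minimized quantity),
#'   `residuals`, `n_obj_evals`, `converged`, `trace` (total objective per
#'   accepted improvement), `config`.
#' @export
fit_pcawarp <- function(model, proxy, cfg = fit_config(), align = TRUE) {
  stopifnot(inherits(model, "shape_model"), inherits(proxy, "scalp_proxy"))
  if (align) proxy <- align_proxy_ctf(proxy)
  n_pcs <- min(cfg$n_pcs, nrow(model$components))
  sigma <- model$singular_values[seq_len(n_pcs)]
  sigma[sigma < 1e-8 * max(sigma, 1e-300)] <- max(sigma[1], 1e-8)

  evals <- 0L
  best <- list(value = Inf, w = rep(0, n_pcs))
  trace <- numeric(0)
  fn <- function(s) {
    w <- s * sigma
    val <- as.numeric(pcawarp_objective(w, model, proxy, cfg))
    evals <<- evals + 1L
    if (val < best$value) {
      best <<- list(value = val, w = w)
      trace[length(trace) + 1L] <<- val
    }
    val
  }

  if (cfg$method == "frozen") {
    w <- frozen_fit(model, proxy, cfg, n_pcs)
    fn(w / sigma) # score (records best)
    converged <- TRUE
  } else {
    h <- 1e-3
    gr <- function(s) {
      vapply(seq_along(s), function(j) {
        sp <- s; sm <- s
        sp[j] <- s[j] + h; sm[j] <- s[j] - h
        (fn(sp) - fn(sm)) / (2 * h)
      }, 0)
    }
    opt <- optim(rep(0, n_pcs), fn, gr, method = "BFGS",
                 control = list(maxit = cfg$max_iter, reltol = cfg$tol))
    converged <- opt$convergence == 0L
    if (!converged && opt$value > best$value + cfg$tol * abs(best$value)) {
      # restart once from the best iterate seen
      opt2 <- optim(best$w / sigma, fn, gr, method = "BFGS",
                    control = list(maxit = cfg$max_iter, reltol = cfg$tol))
      converged <- opt2$convergence == 0L
    }
  }

  obj <- pcawarp_objective(best$w, model, proxy, cfg)
  structure(list(
    weights = best$w, head = reconstruct_head(model, best$w),
    objective = attr(obj, "data_term"), penalty = attr(obj, "penalty"),
    total_objective = attr(obj, "data_term") +
      cfg$penalty_weight * attr(obj, "penalty"),
    residuals = attr(obj, "residuals"),
    n_obj_evals = evals, converged = converged, trace = trace,
    config = cfg
  ), class = "pcawarp_fit")
}

#' @export
print.pcawarp_fit <- function(x, ...) {
  cat(sprintf("<pcawarp_fit> %d PCs, data term %.4g + penalty %.4g, %d evals%s\n",
              length(x$weights), x$objective, x$penalty,
              x$n_obj_evals, if (x$converged) "" else " [not converged]"))
  invisible(x)
}

# alternating frozen-correspondence linear least squares (squared data term).
# Scalp vertex positions are affine in the weights, so with correspondences
# frozen the solve is a dense linear LS on the stacked 3K equations.
frozen_fit <- function(model, proxy, cfg, n_pcs, n_outer = 8L) {
  v <- model$v_count
  p <- proxy$points
  K <- nrow(p)
  comps <- model$components[seq_len(n_pcs), , drop = FALSE]
  w <- rep(0, n_pcs)
  for (it in seq_len(n_outer)) {
    head <- reconstruct_head(model, w)
    tgt <- frozen_targets(head, p, cfg)
    # rows of the scalp block for the selected支持 points
    rows <- as.vector(t(outer(3L * (tgt$vidx - 1L), 1:3, "+"))) # x,y,z per vertex
    A <- t(comps[, rows, drop = FALSE]) * model$scale[rows]
    b <- as.numeric(t(tgt$target)) - model$mean[rows]
    w_new <- qr.solve(A, b)
    if (max(abs(w_new - w)) < 1e-9) { w <- w_new; break }
    w <- w_new
  }
  w
}

# correspondences for the frozen solve: nearest scalp vertex per proxy point
# (vertex_distance) or the vertex nearest the ray intersection (shape_difference)
frozen_targets <- function(head, p, cfg) {
  scalp <- head$shells$scalp
  if (cfg$metric == "vertex_distance") {
    vidx <- cpp_nearest_vertex(p, scalp$vertices)$index
  } else {
    ctr <- colMeans(head$shells$cortex$vertices)
    dirs <- p - matrix(ctr, nrow(p), 3L, byrow = TRUE)
    hit <- rays_mesh_intersect(scalp, rbind(ctr), dirs)
    vidx <- integer(nrow(p))
    ok <- !is.na(hit$t)
    if (any(ok)) {
      # use the hit triangle's nearest vertex as the moving vertex
      tri <- scalp$triangles[hit$triangle[ok], , drop = FALSE]
      vpos <- hit$point[ok, , drop = FALSE]
      pick <- max.col(-sapply(1:3, function(k)
        rowSums((scalp$vertices[tri[, k], , drop = FALSE] - vpos)^2)))
      vidx[ok] <- tri[cbind(seq_len(sum(ok)), pick)]
    }
    if (any(!ok))
      vidx[!ok] <- cpp_nearest_vertex(p[!ok, , drop = FALSE], scalp$vertices)$index
  }
  list(vidx = vidx, target = p)
}
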