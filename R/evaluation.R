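#' Per-tissue shape-error report
#'
#' Compares a fitted head model against a ground-truth head model with both
#' error metrics. `vertex_distance` is the Euclidean distance between
#' corresponding vertices (requires identical vertex count); `shape_difference`
#' is, for each truth vertex, the distance along the ray from the truth cortex
#' centroid through that vertex to its intersection with the fitted surface
#' (meshing-independent).
#'
#' @param fitted,truth `head_model`s.
#' @param metrics metrics to compute (default both).
#' @return A tibble with columns `tissue`, `metric`, `median`, `mean`, `sd`
#'   (mm), class `pcawarp_error_report`. When one metric is requested the
#'   columns stay the same with a single metric level.
#' @export
shape_error_report <- function(fitted, truth,
                               metrics = c("vertex_distance", "shape_difference")) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  maps <- per_vertex_errors(fitted, truth, metrics)
  out <- purrr::map_dfr(metrics, function(m)
    purrr::map_dfr(tissue_order, function(nm) {
      e <- maps[[m]][[nm]]
      tibble::tibble(tissue = nm, metric = m, median = median(e),
                     mean = mean(e), sd = sd(e))
    }))
  class(out) <- c("pcawarp_error_report", class(out))
  out
}

per_vertex_errors <- function(fitted, truth, metrics) {
  res <- list()
  if ("vertex_distance" %in% metrics) {
    res$vertex_distance <- lapply(setNames(tissue_order, tissue_order), function(nm) {
      a <- fitted$shells[[nm]]$vertices; b <- truth$shells[[nm]]$vertices
      if (nrow(a) != nrow(b))
        stop("vertex_distance requires identical vertex counts")
      sqrt(rowSums((a - b)^2))
    })
  }
  if ("shape_difference" %in% metrics) {
    ctr <- colMeans(truth$shells$cortex$vertices)
    res$shape_difference <- lapply(setNames(tissue_order, tissue_order), function(nm) {
      shape_difference_metric(truth$shells[[nm]]$vertices,
                              fitted$shells[[nm]], ctr)
    })
  }
  res
}

#' Per-vertex shape-difference error map
#'
#' Shape difference per truth vertex and tissue, with a display cap applied
#' (raw values retained) for error-map rendering.
#'
#' @param fitted,truth `head_model`s.
#' @param cap display cap in mm (default 11).
#' @return A tibble with columns `tissue`, `vertex`, `raw`, `display`
#'   (`pmin(raw, cap)`).
#' @export
per_vertex_error_map <- function(fitted, truth, cap = 11) {
  maps <- per_vertex_errors(fitted, truth, "shape_difference")$shape_difference
  purrr::map_dfr(tissue_order, function(nm)
    tibble::tibble(tissue = nm, vertex = seq_along(maps[[nm]]),
                   raw = as.numeric(maps[[nm]]),
                   display = pmin(as.numeric(maps[[nm]]), cap)))
}

#' Relative residual variance
#'
#' `RV = sum((x - xhat)^2) / sum(x^2)`: the fraction of signal variance left
#' unexplained by a fitted pattern. Zero for a perfect fit, one for a zero
#' prediction, invariant to joint rescaling of `x` and `xhat`.
#'
#' @param x measured potentials vector.
#' @param xhat fitted potentials vector, same length.
#' @return Non-negative scalar.
#' @export
residual_variance <- function(x, xhat) {
  if (length(x) != length(xhat)) stop("x and xhat must have the same length")
  ss <- sum(x^2)
  if (ss == 0) stop("x must not be all zero")
  sum((x - xhat)^2) / ss
}

#' Standard tissue conductivities
#'
#' The conductivity constants (S/m) conventionally used for four-shell BEM
#' head models: scalp 0.465, skull 0.01, CSF 1.65, cortex 0.201 (mean of gray
#' and white matter).
#'
#' @return Named numeric vector.
#' @export
tissue_conductivities <- function() {
  c(scalp = 0.465, skull = 0.01, csf = 1.65, cortex = 0.201)
}

#' Analytic single-sphere EEG forward model
#'
#' Closed-form surface potential of a current dipole inside a homogeneous
#' conducting sphere with insulating exterior, average-referenced over the
#' electrodes. For electrode position `e` on the sphere (radius R, centre c,
#' conductivity sigma), dipole position `r0` and moment `m`:
#' `V = (1 / 4 pi sigma) * [ 2 (e - r0) . m / d^3 +
#'  ( (e - r0)/d + e'/R ) . m / (R (d + R - r0'.e'/R)) ]`
#' with `d = |e - r0|` and primes relative to the sphere centre. This serves as
#' a desk-scale stand-in for numerical BEM/FEM solvers when exercising the
#' dipole-fitting machinery; any function with the same signature can replace
#' it.
#'
#' @param dipole list with `position` (length-3, mm, strictly inside the
#'   sphere) and `moment` (length-3).
#' @param electrodes `E x 3` matrix of positions on the sphere (mm).
#' @param sphere list with `center` (default origin), `radius` (mm),
#'   `conductivity` (S/m, default 0.33).
#' @return Length-`E` average-referenced potential vector.
#' @export
sphere_forward <- function(dipole, electrodes,
                           sphere = list(center = c(0, 0, 0), radius = 85,
                                         conductivity = 0.33)) {
  e <- as_point_matrix(electrodes, "electrodes")
  ctr <- as.numeric(sphere$center %||% c(0, 0, 0))[1:3]
  R <- sphere$radius
  sig <- sphere$conductivity %||% 0.33
  r0 <- as.numeric(dipole$position)[1:3] - ctr
  m <- as.numeric(dipole$moment)[1:3]
  if (sum(r0^2) >= R^2) stop("dipole must lie strictly inside the sphere")
  ep <- e - matrix(ctr, nrow(e), 3L, byrow = TRUE)
  dv <- ep - matrix(r0, nrow(e), 3L, byrow = TRUE)
  d <- sqrt(rowSums(dv^2))
  cdenom <- d + R - drop(ep %*% r0) / R
  pot <- (2 * drop(dv %*% m) / d^3 +
            (drop(dv %*% m) / d + drop(ep %*% m) / R) / (R * cdenom)) /
    (4 * pi * sig)
  pot - mean(pot)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# gain matrix (E x 3, average-referenced) of a unit-moment dipole basis
sphere_gain <- function(position, electrodes, sphere) {
  sapply(1:3, function(k) {
    m <- numeric(3); m[k] <- 1
    sphere_forward(list(position = position, moment = m), electrodes, sphere)
  })
}

#' Build a regular source grid inside the cortex mesh
#'
#' Axis-aligned lattice with the given spacing clipped to points inside the
#' cortex surface (ray-parity test along +z: odd crossing count = inside).
#'
#' @param cortex a closed `surface_mesh`.
#' @param spacing lattice spacing in mm (default 10).
#' @param margin shrink the bounding box by this many mm (default 0).
#' @return `G x 3` matrix of grid positions.
#' @export
source_grid <- function(cortex, spacing = 10, margin = 0) {
  v <- cortex$vertices
  lo <- apply(v, 2, min) + margin
  hi <- apply(v, 2, max) - margin
  ax <- lapply(1:3, function(k) seq(lo[k], hi[k], by = spacing))
  g <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]]))
  cnt <- cpp_ray_mesh_count(g, matrix(rep(c(0, 0, 1), each = nrow(g)), ncol = 3L),
                            cortex$vertices, cortex$triangles)
  g[cnt %% 2L == 1L, , drop = FALSE]
}

#' Linear (grid-scan) dipole fit
#'
#' For every grid position, solves the optimal dipole moment by linear least
#' squares against the forward model's gain matrix and scores the residual
#' variance; returns the grid point with minimal RV (ties to the lowest grid
#' index). Rank-deficient gain matrices are skipped and counted.
#'
#' @param pattern measured potential vector (average-referenced).
#' @param forward function `(position) -> E x 3` gain matrix.
#' @param grid `G x 3` candidate source positions.
#' @return A list of class `dipole_fit`: `position`, `moment`, `rv`, `stage =
#'   "linear"`, `n_evals`, `n_skipped`, `grid_index`.
#' @export
dipole_fit_linear <- function(pattern, forward, grid) {
  grid <- as_point_matrix(grid, "grid")
  if (nrow(grid) == 0L) stop("empty source grid")
  best <- list(rv = Inf, idx = NA_integer_, moment = rep(NA_real_, 3))
  n_skipped <- 0L
  for (i in seq_len(nrow(grid))) {
    G <- forward(grid[i, ])
    qrG <- qr(G)
    if (qrG$rank < 3L) { n_skipped <- n_skipped + 1L; next }
    mom <- qr.coef(qrG, pattern)
    rv <- residual_variance(pattern, drop(G %*% mom))
    if (rv < best$rv) best <- list(rv = rv, idx = i, moment = mom)
  }
  if (!is.finite(best$rv)) stop("all grid points had rank-deficient gain")
  structure(list(position = grid[best$idx, ], moment = as.numeric(best$moment),
                 rv = best$rv, stage = "linear", n_evals = nrow(grid),
                 n_skipped = n_skipped, grid_index = best$idx),
            class = "dipole_fit")
}

#' Nonlinear dipole refinement
#'
#' Local minimization of the residual variance over the dipole position (the
#' moment is re-solved linearly at each position), started from a linear-scan
#' result. Positions are constrained by `inside`, a predicate for the source
#' compartment; excursions are pushed back by an RV penalty. The returned RV is
#' never larger than the initial one. An aborted optimization is flagged and
#' reported with `rv = 1` by convention.
#'
#' @param pattern measured potential vector.
#' @param forward function `(position) -> E x 3` gain matrix.
#' @param init a `dipole_fit` (typically from [dipole_fit_linear()]).
#' @param inside optional predicate `(position) -> logical`; default accepts
#'   everything.
#' @return A `dipole_fit` with `stage = "nonlinear"` and `aborted` flag.
#' @export
dipole_fit_nonlinear <- function(pattern, forward, init, inside = NULL) {
  rv_at <- function(pos) {
    if (!is.null(inside) && !isTRUE(inside(pos))) return(2)
    G <- tryCatch(forward(pos), error = function(e) NULL)
    if (is.null(G)) return(2)
    qrG <- qr(G)
    if (qrG$rank < 3L) return(2)
    residual_variance(pattern, drop(G %*% qr.coef(qrG, pattern)))
  }
  n_evals <- 0L
  opt <- tryCatch(
    optim(init$position, function(p) { n_evals <<- n_evals + 1L; rv_at(p) },
          method = "Nelder-Mead",
          control = list(maxit = 500, reltol = 1e-10)),
    error = function(e) NULL)
  if (is.null(opt)) {
    return(structure(list(position = init$position, moment = init$moment,
                          rv = 1.0, stage = "nonlinear", n_evals = n_evals,
                          aborted = TRUE),
                     class = "dipole_fit"))
  }
  if (opt$value <= init$rv) {
    pos <- opt$par
    G <- forward(pos)
    mom <- qr.coef(qr(G), pattern)
    rv <- residual_variance(pattern, drop(G %*% mom))
  } else {
    pos <- init$position; mom <- init$moment; rv <- init$rv
  }
  structure(list(position = as.numeric(pos), moment = as.numeric(mom), rv = rv,
                 stage = "nonlinear", n_evals = n_evals, aborted = FALSE),
            class = "dipole_fit")
}

#' Pairwise one-sided model comparison
#'
#' One-sided paired Wilcoxon signed-rank tests of "model a has smaller errors
#' than model b" for every ordered pair of models, Benjamini-Hochberg adjusted
#' over all tested pairs. All-tied pairs are reported with `p = 1` and flagged.
#'
#' @param paired_errors numeric matrix, heads (rows) x models (columns, named).
#' @return A tibble with columns `model_a`, `model_b`, `p_value`, `p_adjusted`,
#'   `all_tied`.
#' @export
compare_models <- function(paired_errors) {
  m <- as.matrix(paired_errors)
  if (nrow(m) < 6L) stop("need at least 6 paired observations")
  if (is.null(colnames(m))) colnames(m) <- paste0("model", seq_len(ncol(m)))
  pairs <- expand.grid(a = colnames(m), b = colnames(m),
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$a != pairs$b, ]
  res <- purrr::pmap_dfr(pairs, function(a, b) {
    d <- m[, a] - m[, b]
    tied <- all(d == 0)
    p <- if (tied) 1 else
      suppressWarnings(wilcox.test(m[, a], m[, b], paired = TRUE,
                                   alternative = "less")$p.value)
    tibble::tibble(model_a = a, model_b = b, p_value = p, all_tied = tied)
  })
  res$p_adjusted <- p.adjust(res$p_value, method = "BH")
  res
}

#' PC-count / proxy-size sweep
#'
#' Full-factorial evaluation over component counts and proxy sizes: for each
#' evaluated fold a shape model is trained on the remaining heads, a proxy of
#' the requested size is sampled from the held-out head, fitted, and the
#' per-tissue shape differences against the held-out truth recorded. Medians
#' over folds are reported per cell; runtime is logged, not asserted.
#'
#' @param population a `synthetic_population` (or list of `head_model`s).
#' @param pcs_grid component counts (default `c(1, 5, 10, 16)`).
#' @param proxy_sizes proxy point counts (default `c(21, 64, 343)`).
#' @param folds fold indices to evaluate (default all heads).
#' @param proxy_mode `"electrodes"` (deterministic layouts) or
#'   `"photogrammetry"`.
#' @param noise_sd proxy noise in mm (default 0: perfect proxy).
#' @param cfg_base `fit_config` whose non-swept fields are reused.
#' @param seed base seed for proxy sampling.
#' @return A tibble with columns `n_pcs`, `n_proxy`, `tissue`,
#'   `median_shape_difference`, `runtime_sec`, class `pcawarp_sweep`; per-fold
#'   values in attribute `per_fold`.
#' @export
sweep_table <- function(population, pcs_grid = c(1L, 5L, 10L, 16L),
                        proxy_sizes = c(21L, 64L, 343L),
                        folds = NULL,
                        proxy_mode = c("electrodes", "photogrammetry"),
                        noise_sd = 0, cfg_base = fit_config(), seed = 1L) {
  proxy_mode <- match.arg(proxy_mode)
  heads <- if (inherits(population, "synthetic_population")) population$heads
           else population
  if (is.null(folds)) folds <- seq_along(heads)
  rows <- purrr::map_dfr(folds, function(i) {
    model <- fit_shape_model(heads[-i])
    truth <- heads[[i]]
    purrr::map_dfr(proxy_sizes, function(np) {
      proxy <- sample_scalp_proxy(truth, mode = proxy_mode, n_points = np,
                                  noise_sd = noise_sd, seed = seed + i)
      purrr::map_dfr(pcs_grid, function(k) {
        cfg <- cfg_base
        cfg$n_pcs <- as.integer(k)
        t0 <- proc.time()[["elapsed"]]
        fit <- fit_pcawarp(model, proxy, cfg, align = FALSE)
        dt <- proc.time()[["elapsed"]] - t0
        rep_ <- shape_error_report(fit$head, truth, metrics = "shape_difference")
        tibble::tibble(fold = i, n_pcs = k, n_proxy = np,
                       tissue = rep_$tissue, shape_difference = rep_$median,
                       runtime_sec = dt)
      })
    })
  })
  out <- rows |>
    dplyr::group_by(.data$n_pcs, .data$n_proxy, .data$tissue) |>
    dplyr::summarise(median_shape_difference = median(.data$shape_difference),
                     runtime_sec = mean(.data$runtime_sec), .groups = "drop")
  class(out) <- c("pcawarp_sweep", class(out))
  attr(out, "per_fold") <- rows
  out
}
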