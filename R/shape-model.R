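#' Flatten a head model into a shape vector
#'
#' Concatenates the four shells' vertex coordinates (per vertex x, y, z) in the
#' fixed tissue order scalp, skull, CSF, cortex, followed by the NAS, LPA and
#' RPA fiducials. For `V` vertices per shell the mesh block has `12 * V`
#' entries and the full vector `12 * V + 9` (with the default `V = 1922`:
#' 23064 and 23073).
#'
#' @param head a `head_model` in CTF coordinates.
#' @return Numeric vector of length `12 * V + 9` with attribute `v_count`.
#' @export
flatten_head <- function(head) {
  stopifnot(inherits(head, "head_model"))
  v <- vapply(head$shells, function(s) nrow(s$vertices), 0L)
  if (length(unique(v)) != 1L) stop("shells disagree on vertex count")
  sv <- c(unlist(lapply(tissue_order, function(nm) as.numeric(t(head$shells[[nm]]$vertices))),
                 use.names = FALSE),
          head$fiducials$nas, head$fiducials$lpa, head$fiducials$rpa)
  attr(sv, "v_count") <- v[[1]]
  sv
}

#' Rebuild a head model from a shape vector
#'
#' Inverse of [flatten_head()]: splits the vector back into four shells on the
#' reference topology (triangle array and star centres taken from `reference`)
#' and the three fiducials.
#'
#' @param sv numeric shape vector of length `12 * V + 9`.
#' @param reference a `head_model` providing the shared triangulation.
#' @return A `head_model`.
#' @export
unflatten_head <- function(sv, reference) {
  v <- nrow(reference$shells$scalp$vertices)
  if (length(sv) != 12L * v + 9L)
    stop("shape vector length does not match reference topology")
  shells <- list()
  for (i in seq_along(tissue_order)) {
    nm <- tissue_order[i]
    block <- sv[((i - 1L) * 3L * v + 1L):(i * 3L * v)]
    ref <- reference$shells[[nm]]
    shells[[nm]] <- surface_mesh(matrix(block, ncol = 3L, byrow = TRUE),
                                 ref$triangles, tissue = nm,
                                 star_center = ref$star_center)
  }
  fid_block <- sv[(12L * v + 1L):(12L * v + 9L)]
  head_model(shells$scalp, shells$skull, shells$csf, shells$cortex,
             fiducials(fid_block[1:3], fid_block[4:6], fid_block[7:9]),
             coord_system = reference$coord_system)
}

#' Fit a PCA shape model over a head population
#'
#' Flattens every head into a shape vector, optionally normalizes, and extracts
#' principal components as the top right-singular vectors of the centred data
#' matrix (SVD, no covariance formation). With centring-only normalization (the
#' default; all coordinates share mm units) reconstruction of any training head
#' from all components is exact to numerical precision.
#'
#' @param population list of `head_model`s with identical topology, in CTF.
#' @param n_comp number of components to keep (at most `n - 1`; default all).
#' @param normalization `"center"` (default) or `"zscore"` (per-coordinate
#'   variance scaling, available but off by default).
#' @return An object of class `shape_model`: `mean` (raw per-coordinate mean),
#'   `scale`, `components` (`n_comp x D`, orthonormal rows), `singular_values`,
#'   `v_count`, `tissue_order`, `n_train`, `normalization`, `reference`.
#' @export
fit_shape_model <- function(population, n_comp = NULL,
                            normalization = c("center", "zscore")) {
  normalization <- match.arg(normalization)
  if (length(population) < 2L) stop("need at least 2 heads")
  X <- do.call(rbind, lapply(population, flatten_head))
  n <- nrow(X); D <- ncol(X)
  mu <- colMeans(X)
  sc <- if (normalization == "zscore") {
    s <- apply(X, 2, sd); s[s < 1e-12] <- 1; s
  } else structure(rep(1, D), unit = TRUE)
  Xc <- sweep(sweep(X, 2, mu), 2, sc, "/")
  max_comp <- n - 1L
  if (is.null(n_comp)) n_comp <- max_comp
  n_comp <- min(as.integer(n_comp), max_comp)
  sv <- svd(Xc, nu = 0, nv = max_comp)
  structure(list(
    mean = mu, scale = sc,
    components = t(sv$v[, seq_len(n_comp), drop = FALSE]),
    singular_values = sv$d[seq_len(n_comp)],
    v_count = attr(flatten_head(population[[1]]), "v_count"),
    tissue_order = tissue_order, n_train = n,
    normalization = normalization,
    reference = population[[1]]
  ), class = "shape_model")
}

#' @export
print.shape_model <- function(x, ...) {
  cat(sprintf("<shape_model> V=%d, D=%d, %d components from %d heads (%s)\n",
              x$v_count, length(x$mean), nrow(x$components), x$n_train,
              x$normalization))
  invisible(x)
}

#' Reconstruct a head from PC weights
#'
#' Evaluates `mean + sum_j w_j PC_j` in the normalized space, denormalizes, and
#' unflattens into a four-shell head model. A zero weight vector returns the
#' mean head.
#'
#' @param model a `shape_model`.
#' @param weights numeric vector of PC weights, length at most `n_comp`.
#' @return A `head_model`.
#' @export
reconstruct_head <- function(model, weights = numeric(0)) {
  unflatten_head(reconstruct_vector(model, weights), model$reference)
}

# validation-free reconstruction reusing the reference topology; used inside
# the optimizer loop where the objective is evaluated thousands of times
reconstruct_head_fast <- function(model, weights) {
  x <- reconstruct_vector(model, weights)
  v <- model$v_count
  head <- model$reference
  for (i in seq_len(4L)) {
    nm <- tissue_order[i]
    head$shells[[nm]]$vertices <-
      matrix(x[((i - 1L) * 3L * v + 1L):(i * 3L * v)], ncol = 3L, byrow = TRUE)
  }
  fb <- x[(12L * v + 1L):(12L * v + 9L)]
  head$fiducials <- structure(list(nas = fb[1:3], lpa = fb[4:6], rpa = fb[7:9]),
                              class = "fiducials")
  head
}

reconstruct_vector <- function(model, weights) {
  n_pcs <- length(weights)
  n_comp <- nrow(model$components)
  if (n_pcs > n_comp) stop("more weights than components")
  x <- model$mean
  if (n_pcs > 0L) {
    # zero-pad instead of subsetting `components`: avoids copying the matrix
    w <- if (n_pcs < n_comp) c(weights, numeric(n_comp - n_pcs)) else weights
    delta <- drop(crossprod(model$components, w))
    x <- x + if (isTRUE(attr(model$scale, "unit"))) delta else model$scale * delta
  }
  x
}

#' Project a head onto the leading principal components
#'
#' Closed-form least-squares weights of the normalized, centred shape vector on
#' the first `n_pcs` components (inner products, valid by orthonormality).
#'
#' @param model a `shape_model`.
#' @param head a `head_model` with matching topology.
#' @param n_pcs number of components (default all).
#' @return Numeric weight vector of length `n_pcs`.
#' @export
project_weights <- function(model, head, n_pcs = nrow(model$components)) {
  n_pcs <- as.integer(n_pcs)
  if (n_pcs > nrow(model$components)) stop("n_pcs exceeds available components")
  if (n_pcs == 0L) return(numeric(0))
  x <- (flatten_head(head) - model$mean) / model$scale
  drop(model$components[seq_len(n_pcs), , drop = FALSE] %*% x)
}

#' Leave-one-head-out reconstruction error curve
#'
#' For each held-out head, fits a shape model on the remaining heads, projects
#' the held-out head on the first `n_pcs` components, reconstructs, and scores
#' each tissue shell with the chosen metric; `n_pcs = 0` is the mean-head
#' baseline. Returns the mean error over folds per tissue and component count.
#'
#' @param population list of `head_model`s (>= 3).
#' @param pcs_grid integer vector of component counts (0 allowed).
#' @param metric `"vertex_distance"` or `"shape_difference"`.
#' @param folds optional integer vector of fold indices to evaluate (defaults
#'   to all heads); the model is always trained on all remaining heads.
#' @return A tibble with columns `n_pcs`, `tissue`, `mean_error` (mm over the
#'   evaluated folds), class `pcawarp_loo`.
#' @export
loo_curve <- function(population, pcs_grid = c(0L, 1L, 2L, 4L, 8L, 16L),
                      metric = c("vertex_distance", "shape_difference"),
                      folds = seq_along(population)) {
  metric <- match.arg(metric)
  if (length(population) < 3L) stop("need at least 3 heads")
  pcs_grid <- sort(unique(as.integer(pcs_grid)))
  rows <- purrr::map_dfr(folds, function(i) {
    model <- fit_shape_model(population[-i])
    truth <- population[[i]]
    purrr::map_dfr(pcs_grid, function(k) {
      rec <- reconstruct_head(model, project_weights(model, truth, k))
      rep_ <- shape_error_report(rec, truth, metrics = metric)
      tibble::tibble(fold = i, n_pcs = k, tissue = rep_$tissue,
                     error = rep_$mean)
    })
  })
  out <- rows |>
    dplyr::group_by(.data$n_pcs, .data$tissue) |>
    dplyr::summarise(mean_error = mean(.data$error), .groups = "drop") |>
    dplyr::mutate(metric = metric)
  class(out) <- c("pcawarp_loo", class(out))
  attr(out, "per_fold") <- rows
  out
}
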