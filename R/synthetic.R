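#' Synthetic head-population specification
#'
#' Parameters of the synthetic population generator, a statistical stand-in
#' for a large segmented-MRI head database: nested anisotropic star-shaped
#' shells on a shared reference triangulation, with low-rank cross-tissue
#' shape variation so inner surfaces are predictable from the scalp, plus
#' independent per-vertex radial noise.
#'
#' @param n_heads number of heads.
#' @param k_latent number of latent shape factors (default 8).
#' @param base_radii four strictly decreasing shell radii in mm
#'   (scalp, skull, csf, cortex; default 100, 95, 90, 85).
#' @param anisotropy fixed per-axis scale factors applied to all shells
#'   (default `c(1.05, 0.95, 1.00)`: slightly elongated anterior-posterior).
#' @param mode_amplitudes relative radial amplitude per latent factor
#'   (default 0.015, i.e. about 1.5% radial modulation per unit latent score,
#'   giving a few millimetres of realistic scalp variation).
#' @param tissue_loadings `4 x k` matrix coupling tissues (rows, scalp to
#'   cortex) to factors; default columns `(1.0, 0.9, 0.85, 0.8)`: inner shells
#'   co-vary strongly with the scalp.
#' @param vertex_noise_sd independent radial noise per vertex in mm (default 0).
#' @param v_count vertices per shell (default 1922).
#' @param seed integer seed.
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(n_heads = 60L, k_latent = 8L,
                            base_radii = c(100, 95, 90, 85),
                            anisotropy = c(1.05, 0.95, 1.00),
                            mode_amplitudes = 0.015,
                            tissue_loadings = NULL,
                            vertex_noise_sd = 0, v_count = 1922L, seed = 1L) {
  if (length(base_radii) != 4L || any(diff(base_radii) >= 0))
    stop("base_radii must be 4 strictly decreasing values (scalp > ... > cortex)")
  k_latent <- as.integer(k_latent)
  mode_amplitudes <- rep_len(mode_amplitudes, k_latent)
  if (is.null(tissue_loadings))
    tissue_loadings <- matrix(c(1.0, 0.9, 0.85, 0.8), 4L, k_latent)
  tissue_loadings <- as.matrix(tissue_loadings)
  if (!all(dim(tissue_loadings) == c(4L, k_latent)))
    stop("tissue_loadings must be 4 x k_latent")
  structure(list(n_heads = as.integer(n_heads), k_latent = k_latent,
                 base_radii = base_radii,
                 anisotropy = rep_len(as.numeric(anisotropy), 3L),
                 mode_amplitudes = mode_amplitudes,
                 tissue_loadings = tissue_loadings,
                 vertex_noise_sd = vertex_noise_sd,
                 v_count = as.integer(v_count), seed = as.integer(seed)),
            class = "population_spec")
}

# real spherical-harmonic-like directional basis, degrees 1..3 (15 functions),
# evaluated on unit directions; deterministic ordering: degree-major, the
# standard real polynomial forms within a degree.
sh_raw <- function(u) {
  x <- u[, 1]; y <- u[, 2]; z <- u[, 3]
  cbind(
    x, y, z,                                            # degree 1
    x * y, y * z, z * x, x^2 - y^2, 3 * z^2 - 1,        # degree 2
    (5 * z^2 - 3) * z, (5 * z^2 - 1) * x, (5 * z^2 - 1) * y,  # degree 3
    (x^2 - y^2) * z, x * y * z,
    (x^2 - 3 * y^2) * x, (3 * x^2 - y^2) * y
  )
}

# Latent mode functions: the raw basis corrected by three smooth bumps so that
# every mode vanishes at the fiducial directions (+x, +y, -y). Heads generated
# from these modes keep NAS on the +x axis and LPA/RPA symmetric on the y axis,
# so the population is exactly CTF-consistent and flattened coordinates stay
# linear in the latent scores (exact rank k with zero noise). Columns are
# scaled to unit RMS over the supplied directions.
sh_modes <- function(u, k) {
  basis <- sh_raw(u)
  if (k > ncol(basis))
    stop("at most ", ncol(basis), " latent factors are supported")
  fdir <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, -1, 0))
  bump <- function(m) ((1 + m %*% t(fdir)) / 2)^4 # n x 3, bump j peaks at fdir j
  G <- bump(fdir)                                  # 3 x 3, G[i, j] = h_j(f_i)
  coefs <- solve(G, sh_raw(fdir))                  # 3 x 15
  corrected <- basis - bump(u) %*% coefs
  corrected <- corrected[, seq_len(k), drop = FALSE]
  sweep(corrected, 2, sqrt(colMeans(corrected^2)), "/")
}

ellipsoid_radial <- function(radius, anis) {
  a <- radius * anis
  function(u) 1 / sqrt((u[, 1] / a[1])^2 + (u[, 2] / a[2])^2 + (u[, 3] / a[3])^2)
}

# fiducials evaluated analytically on the scalp radial field: NAS on the +x
# axis, LPA/RPA on the ±y axes. Keeps noise-free populations exactly CTF.
analytic_fiducials <- function(radial_fn) {
  axes <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, -1, 0))
  r <- radial_fn(axes)
  fiducials(nas = r[1] * axes[1, ], lpa = r[2] * axes[2, ],
            rpa = r[3] * axes[3, ])
}

# fiducials raytraced on the meshed scalp (used when vertex noise makes the
# analytic field unavailable off-vertex)
template_fiducials <- function(scalp) {
  hit <- function(d) ray_mesh_intersect(scalp, c(0, 0, 0), d)$point
  fiducials(nas = hit(c(1, 0, 0)), lpa = hit(c(0, 1, 0)), rpa = hit(c(0, -1, 0)))
}

#' Template head of a synthetic population
#'
#' Four nested anisotropic star-shaped shells on the shared reference
#' triangulation, with NAS at the anterior scalp intersection of the +x axis
#' and LPA/RPA at the lateral scalp intersections of the ±y axes, so the head
#' is exactly CTF-consistent.
#'
#' @param spec a `population_spec`.
#' @param reference optional reference sphere (defaults to
#'   `sphere_triangulation(spec$v_count)`).
#' @return A `head_model` in CTF.
#' @export
make_template <- function(spec, reference = NULL) {
  if (is.null(reference)) reference <- sphere_triangulation(spec$v_count)
  shells <- lapply(seq_len(4L), function(t)
    project_to_sphere_triangulation(
      ellipsoid_radial(spec$base_radii[t], spec$anisotropy),
      center = c(0, 0, 0), reference = reference, tissue = tissue_order[t]))
  head <- head_model(shells[[1]], shells[[2]], shells[[3]], shells[[4]],
                     analytic_fiducials(ellipsoid_radial(spec$base_radii[1],
                                                         spec$anisotropy)),
                     coord_system = "ctf")
  nest <- check_nesting(head)
  if (!nest$ok) stop("base radii / anisotropy violate shell nesting")
  head
}

#' Generate a synthetic head population
#'
#' Head `i`'s radial field for tissue `t` is
#' `base_t(u) * (1 + sum_f loadings[t, f] * z_if * amp_f * mode_f(u))` with
#' latent scores `z ~ N(0, 1)` shared across tissues and smooth directional
#' modes (real spherical-harmonic-like patterns up to degree 3 that vanish at
#' the fiducial directions, keeping the population exactly CTF-consistent and
#' the flattened coordinates linear in the scores), plus independent Gaussian
#' radial vertex noise. Fiducials are the scalp intersections of the +x and
#' ±y axes; noisy heads are re-aligned to CTF via their fiducials. Heads
#' violating shell nesting are rejected and resampled; the count is reported.
#'
#' @param spec a `population_spec`.
#' @return An object of class `synthetic_population`: `heads` (list of
#'   `head_model`), `latents` (`n x k` matrix), `spec`, `template`,
#'   `n_rejected`.
#' @export
generate_population <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  reference <- sphere_triangulation(spec$v_count)
  template <- make_template(spec, reference)
  u <- unit_rows(reference$vertices)
  modes <- sh_modes(u, spec$k_latent) # V x k
  amp <- spec$mode_amplitudes
  base <- lapply(seq_len(4L), function(t)
    ellipsoid_radial(spec$base_radii[t], spec$anisotropy)(u))

  set.seed(spec$seed)
  heads <- vector("list", spec$n_heads)
  latents <- matrix(NA_real_, spec$n_heads, spec$k_latent)
  n_rejected <- 0L
  for (i in seq_len(spec$n_heads)) {
    repeat {
      z <- rnorm(spec$k_latent)
      shells <- vector("list", 4L)
      ok_radii <- TRUE
      for (t in seq_len(4L)) {
        r <- base[[t]] * (1 + drop(modes %*% (amp * spec$tissue_loadings[t, ] * z)))
        if (spec$vertex_noise_sd > 0)
          r <- r + rnorm(length(r), sd = spec$vertex_noise_sd)
        if (any(r <= 0)) { ok_radii <- FALSE; break }
        shells[[t]] <- surface_mesh(r * u, reference$triangles,
                                    tissue = tissue_order[t],
                                    star_center = c(0, 0, 0))
      }
      if (!ok_radii) { n_rejected <- n_rejected + 1L; next }
      # noise-free heads are exactly CTF by construction: the modes vanish at
      # the fiducial directions, so the analytic fiducials are the template's.
      # Vertex noise perturbs the scalp, so fiducials are then re-measured by
      # raytracing and the head re-aligned.
      if (spec$vertex_noise_sd > 0) {
        head <- head_model(shells[[1]], shells[[2]], shells[[3]], shells[[4]],
                           template_fiducials(shells[[1]]),
                           coord_system = "ctf")
        head <- align_ctf(head)
      } else {
        head <- head_model(shells[[1]], shells[[2]], shells[[3]], shells[[4]],
                           template$fiducials, coord_system = "ctf")
      }
      if (check_nesting(head, n_rays = 100L)$ok) {
        heads[[i]] <- head
        latents[i, ] <- z
        break
      }
      n_rejected <- n_rejected + 1L
    }
  }
  structure(list(heads = heads, latents = latents, spec = spec,
                 template = template, n_rejected = n_rejected),
            class = "synthetic_population")
}

#' @export
print.synthetic_population <- function(x, ...) {
  cat(sprintf("<synthetic_population> %d heads, k=%d, V=%d (%d rejected)\n",
              length(x$heads), x$spec$k_latent, x$spec$v_count, x$n_rejected))
  invisible(x)
}

#' Sample a scalp proxy from a head
#'
#' Emulates the two scalp-proxy acquisition modes. `"photogrammetry"`: points
#' sampled uniformly over the scalp surface above the ear plane (area-weighted
#' random triangles, random barycentric coordinates) with isotropic Gaussian
#' noise. `"electrodes"`: a deterministic quasi-regular ring-and-arc layout of
#' exactly `n_points` positions on the upper scalp, approximating the
#' 10-20/10-10/10-5 electrode densities (21/64/343 points), projected onto the
#' scalp by raytracing from the cortex centroid. All points lie at least 35 mm
#' above the fiducial plane by construction; fiducials are copied from the
#' head.
#'
#' @param head a CTF-aligned `head_model`.
#' @param mode `"photogrammetry"` or `"electrodes"`.
#' @param n_points number of proxy points.
#' @param noise_sd isotropic positional noise in mm (default 0).
#' @param seed integer seed (photogrammetry sampling and noise).
#' @param min_height mm above the fiducial plane (default 35).
#' @return A `scalp_proxy`.
#' @export
sample_scalp_proxy <- function(head, mode = c("photogrammetry", "electrodes"),
                               n_points = 150L, noise_sd = 0, seed = 1L,
                               min_height = 35) {
  mode <- match.arg(mode)
  scalp <- head$shells$scalp
  set.seed(seed)
  if (mode == "photogrammetry") {
    v <- scalp$vertices; f <- scalp$triangles
    zmin <- apply(matrix(v[f, 3], nrow(f), 3L), 1, min)
    keep <- which(zmin >= min_height)
    if (!length(keep)) stop("no scalp triangles above the cutting plane")
    a <- v[f[keep, 1], , drop = FALSE]
    b <- v[f[keep, 2], , drop = FALSE]
    c_ <- v[f[keep, 3], , drop = FALSE]
    area <- 0.5 * sqrt(rowSums(cross_rows(b - a, c_ - a)^2))
    tri <- sample.int(length(keep), n_points, replace = TRUE, prob = area)
    r1 <- sqrt(runif(n_points)); r2 <- runif(n_points)
    w1 <- 1 - r1; w2 <- r1 * (1 - r2); w3 <- r1 * r2
    pts <- w1 * a[tri, , drop = FALSE] + w2 * b[tri, , drop = FALSE] +
      w3 * c_[tri, , drop = FALSE]
  } else {
    dirs <- electrode_directions(n_points, head, min_height)
    ctr <- colMeans(head$shells$cortex$vertices)
    hit <- rays_mesh_intersect(scalp, rbind(ctr), dirs)
    if (anyNA(hit$t)) stop("electrode ray missed the scalp")
    pts <- hit$point
  }
  if (noise_sd > 0) pts <- pts + matrix(rnorm(3L * nrow(pts), sd = noise_sd),
                                        ncol = 3L)
  scalp_proxy(pts, head$fiducials, provenance = mode)
}

# deterministic ring-and-arc layout: polar angles from +z down to the angle
# where the scalp reaches min_height; per-ring counts proportional to the ring
# circumference with largest-remainder rounding to hit n exactly.
electrode_directions <- function(n, head, min_height) {
  ctr <- colMeans(head$shells$cortex$vertices)
  # conservative maximum polar angle: direction at which a sphere through the
  # lowest admissible scalp point stays above min_height
  rad <- min(sqrt(rowSums((head$shells$scalp$vertices -
                             matrix(ctr, nrow(head$shells$scalp$vertices), 3L,
                                    byrow = TRUE))^2)))
  zc <- min_height - ctr[3]
  theta_max <- acos(min(1, max(-1, (zc + 5) / rad))) # 5 mm safety margin
  n <- as.integer(n)
  if (n == 1L) return(rbind(c(0, 0, 1)))
  n_rings <- max(2L, round(sqrt(n / 2)) + 1L)
  theta <- theta_max * seq_len(n_rings) / n_rings
  weights <- sin(theta)
  m <- n - 1L # one point at the pole
  counts <- floor(m * weights / sum(weights))
  rem <- m - sum(counts)
  if (rem > 0) {
    frac <- m * weights / sum(weights) - counts
    counts[order(frac, decreasing = TRUE)[seq_len(rem)]] <-
      counts[order(frac, decreasing = TRUE)[seq_len(rem)]] + 1L
  }
  dirs <- rbind(c(0, 0, 1))
  for (i in seq_len(n_rings)) {
    if (counts[i] == 0L) next
    phi <- 2 * pi * (seq_len(counts[i]) - 1L) / counts[i] +
      (i %% 2L) * pi / max(counts[i], 1L) # stagger alternate rings
    dirs <- rbind(dirs, cbind(sin(theta[i]) * cos(phi),
                              sin(theta[i]) * sin(phi),
                              rep(cos(theta[i]), counts[i])))
  }
  dirs
}
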