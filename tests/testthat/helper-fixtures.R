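# Fixtures are generated in code and cached per session so several test files
# can share one synthetic population without regenerating it.
fixture_env <- new.env(parent = emptyenv())

test_population <- function(n = 12, k = 3, v = 162L, noise = 0, seed = 7,
                            amplitudes = 0.015) {
  key <- paste("pop", n, k, v, noise, seed, amplitudes, sep = "_")
  if (is.null(fixture_env[[key]]))
    fixture_env[[key]] <- generate_population(population_spec(
      n_heads = n, k_latent = k, v_count = v, vertex_noise_sd = noise,
      mode_amplitudes = amplitudes, seed = seed))
  fixture_env[[key]]
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

row_cross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

random_star_mesh <- function(v = 162L, seed = 1, base = 100, wobble = 10) {
  set.seed(seed)
  ref <- sphere_triangulation(v)
  co <- rnorm(6)
  radial <- function(u) {
    base + wobble * (co[1] * u[, 1] + co[2] * u[, 2] + co[3] * u[, 3] +
                       co[4] * u[, 1] * u[, 2] + co[5] * (u[, 3]^2 - 1 / 3) +
                       co[6] * u[, 1] * u[, 3])
  }
  project_to_sphere_triangulation(radial, c(0, 0, 0), ref)
}

random_rotation <- function(seed) {
  set.seed(seed)
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# brute-force nearest intersection: plain R loop over every triangle
bf_ray_mesh <- function(mesh, origin, dir) {
  dir <- dir / sqrt(sum(dir^2))
  v <- mesh$vertices
  f <- mesh$triangles
  best <- NULL
  for (i in seq_len(nrow(f))) {
    a <- v[f[i, 1], ]; b <- v[f[i, 2], ]; cc <- v[f[i, 3], ]
    e1 <- b - a; e2 <- cc - a
    p <- cross3(dir, e2)
    det <- sum(e1 * p)
    if (abs(det) <= 1e-12) next
    tv <- origin - a
    u <- sum(tv * p) / det
    if (u < -1e-9 || u > 1 + 1e-9) next
    q <- cross3(tv, e1)
    w <- sum(dir * q) / det
    if (w < -1e-9 || u + w > 1 + 1e-9) next
    t <- sum(e2 * q) / det
    if (t <= 1e-12) next
    if (is.null(best) || t < best$t) best <- list(t = t, tri = i)
  }
  best
}

# brute-force inter-shell penalty: double loop over all unordered shell pairs
bf_penalty <- function(head, T) {
  shells <- lapply(c("scalp", "skull", "csf", "cortex"),
                   function(nm) head$shells[[nm]]$vertices)
  g <- 0
  for (i in 1:3) for (j in (i + 1):4) {
    a <- shells[[i]]; b <- shells[[j]]
    for (p in seq_len(nrow(a))) {
      d <- sqrt(colSums((t(b) - a[p, ])^2))
      g <- g + sum(pmax(0, T - d[d < T]))
    }
  }
  g
}

# homogeneous-sphere surface potential of a monopole via the Legendre series
# (insulated boundary), used to build a two-monopole dipole oracle
series_monopole <- function(r0, elec, R, sigma, n_terms = 300) {
  b <- sqrt(sum(r0^2))
  out <- numeric(nrow(elec))
  for (k in seq_len(nrow(elec))) {
    e <- elec[k, ]
    cosg <- if (b == 0) 1 else sum(e * r0) / (R * b)
    # recurrence for Legendre polynomials
    pm1 <- 1; p0 <- cosg; s <- 0
    for (n in 1:n_terms) {
      pn <- if (n == 1) p0 else ((2 * n - 1) * cosg * p0 - (n - 1) * pm1) / n
      if (n > 1) { pm1 <- p0; p0 <- pn }
      s <- s + (2 * n + 1) / n * (b / R)^n * pn
    }
    out[k] <- s / (4 * pi * sigma * R)
  }
  out
}

series_dipole <- function(position, moment, elec, R, sigma, h = 1e-4) {
  mn <- sqrt(sum(moment^2))
  if (mn == 0) return(numeric(nrow(elec)))
  u <- moment / mn
  # finite two-monopole dipole with Richardson extrapolation in the spacing
  approx_h <- function(hh) {
    (series_monopole(position + hh / 2 * u, elec, R, sigma) -
       series_monopole(position - hh / 2 * u, elec, R, sigma)) * (mn / hh)
  }
  v <- (4 * approx_h(h / 2) - approx_h(h)) / 3
  v - mean(v)
}
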