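make_proxy_from <- function(head, n = 150, seed = 5) {
  sample_scalp_proxy(head, "photogrammetry", n, noise_sd = 0, seed = seed)
}

test_that("vertex-distance metric equals the brute-force nearest-vertex scan", {
  mesh <- random_star_mesh(162L, seed = 7)
  # coincident points score zero
  expect_equal(vertex_distance_metric(mesh$vertices[1:10, ], mesh),
               rep(0, 10))
  sph <- project_to_sphere_triangulation(100, reference = sphere_triangulation(642L))
  d <- vertex_distance_metric(rbind(c(0, 0, 110)), sph)
  expect_gte(d, 10)
  expect_lt(d, 10.6) # 10 + chord deviation of the mesh

  set.seed(8)
  pts <- matrix(rnorm(90, sd = 120), ncol = 3)
  got <- vertex_distance_metric(pts, mesh)
  want <- apply(pts, 1, function(p) min(sqrt(colSums((t(mesh$vertices) - p)^2))))
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("shape-difference metric measures along centroid rays", {
  sph <- project_to_sphere_triangulation(100, reference = sphere_triangulation(642L))
  d <- shape_difference_metric(rbind(c(0, 0, 110)), sph, c(0, 0, 0))
  expect_equal(as.numeric(d), 10, tolerance = 0.5)

  # a point on the surface mid-triangle: shape difference ~ 0,
  # vertex distance clearly positive
  tri <- sph$triangles[1, ]
  mid <- colMeans(sph$vertices[tri, ])
  sd_ <- shape_difference_metric(rbind(mid), sph, c(0, 0, 0))
  vd <- vertex_distance_metric(rbind(mid), sph)
  expect_lt(as.numeric(sd_), 1e-9)
  expect_gt(vd, 10 * as.numeric(sd_) + 0.5)

  # meshing invariance: the same ellipsoid triangulated at two resolutions
  abc <- c(100, 90, 95)
  radial <- function(u) 1 / sqrt(rowSums(sweep(u, 2, abc, "/")^2))
  fine <- project_to_sphere_triangulation(radial, reference = sphere_triangulation(642L))
  coarse <- project_to_sphere_triangulation(radial, reference = sphere_triangulation(362L))
  set.seed(9)
  pts <- fine$vertices[sample(642, 40), ]
  sd_c <- shape_difference_metric(pts, coarse, c(0, 0, 0))
  vd_c <- vertex_distance_metric(pts, coarse)
  edge <- max(sqrt(rowSums((coarse$vertices[coarse$triangles[, 1], ] -
                              coarse$vertices[coarse$triangles[, 2], ])^2)))
  expect_lt(max(sd_c), edge / 2)
  expect_gt(max(vd_c), max(sd_c)) # vertex distance is meshing-dependent
})

test_that("inter-shell penalty matches the brute-force double loop", {
  ref <- sphere_triangulation(162L)
  sph <- function(r, t) project_to_sphere_triangulation(r, reference = ref, tissue = t)
  fid <- fiducials(c(100, 0, 0), c(0, 100, 0), c(0, -100, 0))
  far <- head_model(sph(100, "scalp"), sph(95, "skull"), sph(90, "csf"),
                    sph(85, "cortex"), fid, "ctf")
  expect_equal(penalty_g(far, T = 1), 0)

  # exactly one cross-shell pair at distance 0.4 with T = 1 contributes 0.6
  close1 <- far
  v <- close1$shells$csf$vertices
  target <- close1$shells$skull$vertices[1, ]
  v[1, ] <- target - 0.4 * target / sqrt(sum(target^2))
  close1$shells$csf$vertices <- v
  expect_equal(penalty_g(close1, T = 1), 0.6, tolerance = 1e-9)

  # random deformed heads vs O(V^2) oracle (V <= 200)
  pop <- test_population(n = 3, k = 3, v = 162L, seed = 43, amplitudes = 0.03)
  for (h in pop$heads) {
    for (T in c(2, 5)) expect_equal(penalty_g(h, T), bf_penalty(h, T),
                                    tolerance = 1e-9)
  }
})

test_that("objective combines data term and penalty as configured", {
  pop <- test_population(n = 10, k = 3, v = 162L, seed = 47)
  model <- fit_shape_model(pop$heads)
  mean_head <- reconstruct_head(model, numeric(0))
  proxy <- make_proxy_from(mean_head, n = 120, seed = 3)
  cfg <- fit_config(n_pcs = 3, metric = "shape_difference")
  obj0 <- pcawarp_objective(rep(0, 3), model, proxy, cfg)
  expect_lt(attr(obj0, "data_term"), 1e-6) # proxy sampled from the mean head
  cfg0 <- cfg; cfg0$penalty_weight <- 0
  objn <- pcawarp_objective(rep(0, 3), model, proxy, cfg0)
  expect_equal(as.numeric(objn), attr(objn, "data_term"))

  # central finite differences agree with an independent R-only objective
  cfg_vd <- fit_config(n_pcs = 3, metric = "vertex_distance", penalty_weight = 0)
  r_objective <- function(w) {
    x <- model$mean + drop(crossprod(model$components[1:3, , drop = FALSE], w))
    v <- matrix(x[1:(3 * 162)], ncol = 3, byrow = TRUE) # scalp block
    sum(apply(proxy$points, 1, function(p) min(sqrt(colSums((t(v) - p)^2)))))
  }
  set.seed(51)
  w <- rnorm(3) * model$singular_values[1:3] * 0.3
  h <- 1e-4 * model$singular_values[1:3]
  for (j in 1:3) {
    e <- numeric(3); e[j] <- h[j]
    g_pkg <- (as.numeric(pcawarp_objective(w + e, model, proxy, cfg_vd)) -
                as.numeric(pcawarp_objective(w - e, model, proxy, cfg_vd))) / (2 * h[j])
    g_r <- (r_objective(w + e) - r_objective(w - e)) / (2 * h[j])
    expect_equal(g_pkg, g_r, tolerance = 1e-6)
  }
})

test_that("fitting a proxy of the mean head returns (near) zero weights", {
  pop <- test_population(n = 10, k = 3, v = 162L, seed = 47)
  model <- fit_shape_model(pop$heads)
  mean_head <- reconstruct_head(model, numeric(0))
  proxy <- make_proxy_from(mean_head, n = 120, seed = 3)
  fit <- fit_pcawarp(model, proxy, fit_config(n_pcs = 3), align = FALSE)
  expect_lt(fit$objective, 1e-4)
  expect_lt(max(abs(fit$weights)) / model$singular_values[1], 1e-3)
  expect_lte(fit$total_objective,
             as.numeric(pcawarp_objective(rep(0, 3), model, proxy,
                                          fit$config)) + 1e-12)
})

test_that("hidden shells of an unseen head are recovered from its scalp", {
  pop <- test_population(n = 13, k = 3, v = 162L, noise = 0, seed = 53)
  model <- fit_shape_model(pop$heads[-1])
  truth <- pop$heads[[1]]
  proxy <- make_proxy_from(truth, n = 150, seed = 5)
  fit <- fit_pcawarp(model, proxy, fit_config(n_pcs = 3), align = FALSE)
  rep_fit <- shape_error_report(fit$head, truth, "shape_difference")
  rep_base <- shape_error_report(reconstruct_head(model, numeric(0)), truth,
                                 "shape_difference")
  cortex_fit <- rep_fit$median[rep_fit$tissue == "cortex"]
  cortex_base <- rep_base$median[rep_base$tissue == "cortex"]
  expect_lt(cortex_fit, 0.5 * cortex_base)
  expect_true(fit$converged)
  # deterministic: same inputs, same result
  fit2 <- fit_pcawarp(model, proxy, fit_config(n_pcs = 3), align = FALSE)
  expect_identical(fit$weights, fit2$weights)
})

test_that("frozen-correspondence mode matches a direct linear solve", {
  pop <- test_population(n = 10, k = 3, v = 162L, seed = 47)
  model <- fit_shape_model(pop$heads)
  truth <- pop$heads[[2]]
  proxy <- make_proxy_from(truth, n = 100, seed = 6)
  cfg <- fit_config(n_pcs = 3, metric = "vertex_distance", method = "frozen")
  fit <- fit_pcawarp(model, proxy, cfg, align = FALSE)

  # one more frozen step from the solution must reproduce it: the weights are
  # the least-squares solution for their own correspondences
  vidx <- pcawarp:::cpp_nearest_vertex(proxy$points,
                                       fit$head$shells$scalp$vertices)$index
  rows <- as.vector(t(outer(3L * (vidx - 1L), 1:3, "+")))
  A <- t(model$components[1:3, rows, drop = FALSE]) * model$scale[rows]
  b <- as.numeric(t(proxy$points)) - model$mean[rows]
  w_direct <- qr.solve(A, b)
  expect_equal(fit$weights, w_direct, tolerance = 1e-6)
})

test_that("weight trace is non-increasing and the fit is seed-independent", {
  pop <- test_population(n = 10, k = 3, v = 162L, seed = 47)
  model <- fit_shape_model(pop$heads)
  proxy <- make_proxy_from(pop$heads[[4]], n = 80, seed = 2)
  fit <- fit_pcawarp(model, proxy, fit_config(n_pcs = 3), align = FALSE)
  expect_true(all(diff(fit$trace) <= 0)) # recorded at accepted improvements
  gl <- glance(fit)
  expect_equal(gl$n_pcs, 3L)
  expect_equal(nrow(tidy(fit)), 3L)
})
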