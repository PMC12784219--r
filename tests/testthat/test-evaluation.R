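test_that("shape-error report matches hand-rolled per-vertex aggregation", {
  pop <- test_population(n = 4, k = 3, v = 162L, seed = 83, amplitudes = 0.02)
  a <- pop$heads[[1]]; b <- pop$heads[[2]]
  rep0 <- shape_error_report(a, a)
  expect_true(all(rep0$median < 1e-9 & rep0$mean < 1e-9))

  shifted <- a
  for (nm in c("scalp", "skull", "csf", "cortex"))
    shifted$shells[[nm]]$vertices <- a$shells[[nm]]$vertices +
      matrix(c(0, 0, 5), 162L, 3L, byrow = TRUE)
  repv <- shape_error_report(shifted, a, metrics = "vertex_distance")
  expect_equal(repv$median, rep(5, 4))

  rep_ab <- shape_error_report(a, b)
  vd <- rep_ab[rep_ab$metric == "vertex_distance" & rep_ab$tissue == "skull", ]
  hand <- sqrt(rowSums((a$shells$skull$vertices - b$shells$skull$vertices)^2))
  expect_equal(vd$median, median(hand), tolerance = 1e-12)
  expect_equal(vd$mean, mean(hand), tolerance = 1e-12)
  expect_equal(vd$sd, sd(hand), tolerance = 1e-12)

  sd_row <- rep_ab[rep_ab$metric == "shape_difference" & rep_ab$tissue == "scalp", ]
  ctr <- colMeans(b$shells$cortex$vertices)
  hand_sd <- vapply(seq_len(162L), function(i) {
    p <- b$shells$scalp$vertices[i, ]
    hit <- bf_ray_mesh(a$shells$scalp, ctr, p - ctr)
    d <- (p - ctr); d <- d / sqrt(sum(d^2))
    sqrt(sum((p - (ctr + hit$t * d))^2))
  }, 0)
  expect_equal(sd_row$mean, mean(hand_sd), tolerance = 1e-9)
})

test_that("per-vertex error maps cap for display and agree with the report", {
  pop <- test_population(n = 4, k = 3, v = 162L, seed = 83, amplitudes = 0.02)
  a <- pop$heads[[1]]
  expect_true(all(per_vertex_error_map(a, a)$raw < 1e-9))

  big <- a
  big$shells$scalp$vertices <- a$shells$scalp$vertices * 1.25 # ~25 mm off
  m <- per_vertex_error_map(big, a, cap = 11)
  scalp <- m[m$tissue == "scalp", ]
  expect_true(any(scalp$raw > 11))
  expect_true(all(scalp$display <= 11))
  expect_equal(scalp$display, pmin(scalp$raw, 11))

  rep_ <- shape_error_report(big, a, metrics = "shape_difference")
  expect_equal(mean(scalp$raw), rep_$mean[rep_$tissue == "scalp"],
               tolerance = 1e-12)
})

test_that("residual variance identities hold exactly", {
  set.seed(87)
  x <- rnorm(64)
  xh <- x + rnorm(64, sd = 0.3)
  expect_equal(residual_variance(x, x), 0)
  expect_equal(residual_variance(x, 0 * x), 1)
  expect_equal(residual_variance(c(1, 1), c(0, 1)), 0.5)
  expect_equal(residual_variance(3.7 * x, 3.7 * xh), residual_variance(x, xh),
               tolerance = 1e-12)
  expect_error(residual_variance(rep(0, 3), rep(1, 3)), "zero")
})

sphere_cfg <- list(center = c(0, 0, 0), radius = 85, conductivity = 0.33)

upper_electrodes <- function(n = 64, R = 85) {
  d <- pcawarp:::fibonacci_directions(2 * n)
  R * d[d[, 3] > 0, , drop = FALSE][seq_len(n), ]
}

test_that("analytic sphere forward model: linearity, equivariance, series oracle", {
  elec <- upper_electrodes()
  dip <- list(position = c(10, -15, 30), moment = c(1, 2, -1))
  v1 <- sphere_forward(dip, elec, sphere_cfg)
  v2 <- sphere_forward(list(position = dip$position, moment = 2 * dip$moment),
                       elec, sphere_cfg)
  expect_equal(v2, 2 * v1, tolerance = 1e-12)
  expect_equal(mean(v1), 0, tolerance = 1e-15) # average reference

  rot <- random_rotation(91)
  v3 <- sphere_forward(list(position = drop(rot %*% dip$position),
                            moment = drop(rot %*% dip$moment)),
                       elec %*% t(rot), sphere_cfg)
  expect_equal(v3, v1, tolerance = 1e-10)

  expect_error(sphere_forward(list(position = c(90, 0, 0), moment = c(1, 0, 0)),
                              elec, sphere_cfg), "inside")

  # truncated Legendre-series oracle over random configurations
  set.seed(93)
  for (i in 1:100) {
    pos <- rnorm(3); pos <- pos / sqrt(sum(pos^2)) * runif(1, 5, 60)
    mom <- rnorm(3)
    got <- sphere_forward(list(position = pos, moment = mom), elec, sphere_cfg)
    want <- series_dipole(pos, mom, elec, R = 85, sigma = 0.33)
    expect_equal(got, want, tolerance = 1e-8)
  }
})

test_that("linear grid scan recovers on-grid dipoles exactly", {
  elec <- upper_electrodes()
  fwd <- function(pos) pcawarp:::sphere_gain(pos, elec, sphere_cfg)
  grid <- as.matrix(expand.grid(x = seq(-40, 40, 20), y = seq(-40, 40, 20),
                                z = seq(-40, 40, 20)))
  grid <- grid[rowSums(grid^2) < 70^2, ]
  truth_i <- 17L
  pattern <- drop(fwd(grid[truth_i, ]) %*% c(2, -1, 3))
  fit <- dipole_fit_linear(pattern, fwd, grid)
  expect_equal(fit$grid_index, truth_i)
  expect_lt(fit$rv, 1e-10)
  expect_equal(fit$moment, c(2, -1, 3), tolerance = 1e-6)

  # independent exhaustive re-computation of the per-point RV minimum
  rvs <- apply(grid, 1, function(p) {
    G <- fwd(p)
    residual_variance(pattern, drop(G %*% qr.solve(G, pattern)))
  })
  expect_equal(fit$rv, min(rvs), tolerance = 1e-12)
  expect_equal(fit$grid_index, which.min(rvs))
})

test_that("nonlinear refinement improves off-grid fits and never worsens RV", {
  elec <- upper_electrodes()
  fwd <- function(pos) pcawarp:::sphere_gain(pos, elec, sphere_cfg)
  grid <- as.matrix(expand.grid(x = seq(-40, 40, 20), y = seq(-40, 40, 20),
                                z = seq(-40, 40, 20)))
  grid <- grid[rowSums(grid^2) < 70^2, ]

  truth_pos <- c(13, -7, 24) # off-grid
  pattern <- drop(fwd(truth_pos) %*% c(1, 1, 0.5))
  lin <- dipole_fit_linear(pattern, fwd, grid)
  nl <- dipole_fit_nonlinear(pattern, fwd, lin,
                             inside = function(p) sum(p^2) < 80^2)
  expect_lte(nl$rv, lin$rv + 1e-12)
  expect_lt(nl$rv, 1e-8)
  expect_lt(sqrt(sum((nl$position - truth_pos)^2)), 20 / 5)

  # starting at the truth stays there
  init <- structure(list(position = truth_pos, moment = c(1, 1, 0.5),
                         rv = residual_variance(pattern,
                                                drop(fwd(truth_pos) %*% c(1, 1, 0.5))),
                         stage = "linear", grid_index = NA),
                    class = "dipole_fit")
  stay <- dipole_fit_nonlinear(pattern, fwd, init)
  expect_lt(stay$rv, 1e-10)

  # monotonicity on random noisy cases
  set.seed(95)
  for (i in 1:20) {
    pos <- rnorm(3, sd = 20)
    if (sum(pos^2) > 60^2) pos <- pos * 60 / sqrt(sum(pos^2))
    pat <- drop(fwd(pos) %*% rnorm(3)) + rnorm(nrow(elec), sd = 0.1)
    pat <- pat - mean(pat)
    l <- dipole_fit_linear(pat, fwd, grid)
    n <- dipole_fit_nonlinear(pat, fwd, l)
    expect_lte(n$rv, l$rv + 1e-12)
  }
})

test_that("pairwise model comparison uses one-sided Wilcoxon with BH", {
  set.seed(97)
  a <- rexp(22, 1 / 10)
  errs <- cbind(A = a, B = a + 5, C = a + rnorm(22, sd = 0.1))
  res <- compare_models(errs)
  expect_equal(nrow(res), 6L)
  ab <- res[res$model_a == "A" & res$model_b == "B", ]
  expect_lt(ab$p_adjusted, 0.01)
  ba <- res[res$model_a == "B" & res$model_b == "A", ]
  expect_gt(ba$p_adjusted, 0.5)
  # BH is monotone in the raw p-values
  ord <- order(res$p_value)
  expect_true(all(diff(res$p_adjusted[ord]) >= -1e-15))
  # self-comparison: all tied
  res2 <- compare_models(cbind(A = a, B = a))
  expect_true(all(res2$all_tied))
  expect_true(all(res2$p_adjusted >= 0.5))
  expect_error(compare_models(errs[1:4, ]), "6")
})

test_that("source grids are inside the cortex and sweep tables are complete", {
  pop <- test_population(n = 6, k = 2, v = 162L, seed = 101)
  cortex <- pop$heads[[1]]$shells$cortex
  g <- source_grid(cortex, spacing = 20)
  expect_gt(nrow(g), 10)
  ctr <- colMeans(cortex$vertices)
  rad <- sqrt(rowSums((cortex$vertices - matrix(ctr, 162L, 3L, byrow = TRUE))^2))
  expect_true(all(sqrt(rowSums((g - matrix(ctr, nrow(g), 3L, byrow = TRUE))^2)) <
                    max(rad)))

  tab <- sweep_table(pop, pcs_grid = c(1L, 2L), proxy_sizes = c(12L, 24L),
                     folds = 1:2, cfg_base = fit_config(n_pcs = 2, max_iter = 20))
  expect_setequal(unique(tab$n_pcs), c(1L, 2L))
  expect_setequal(unique(tab$n_proxy), c(12L, 24L))
  expect_equal(nrow(tab), 2L * 2L * 4L)
  expect_true(all(c("median_shape_difference", "runtime_sec") %in% names(tab)))
})
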