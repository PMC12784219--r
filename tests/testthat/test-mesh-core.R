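test_that("sphere triangulation is closed, outward-wound and star-shaped", {
  for (v in c(162L, 642L, 1922L)) {
    s <- sphere_triangulation(v)
    expect_equal(nrow(s$vertices), v)
    expect_equal(nrow(s$triangles), 2L * v - 4L)
    expect_equal(max(abs(sqrt(rowSums(s$vertices^2)) - 1)), 0, tolerance = 1e-12)
    e <- rbind(s$triangles[, 1:2], s$triangles[, 2:3], s$triangles[, c(3, 1)])
    key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    expect_true(all(table(key) == 2)) # closed 2-manifold
    a <- s$vertices[s$triangles[, 1], ]
    b <- s$vertices[s$triangles[, 2], ]
    cc <- s$vertices[s$triangles[, 3], ]
    expect_true(all(rowSums(row_cross(b - a, cc - a) * (a + b + cc)) > 0))
  }
  # every ray from the star centre crosses exactly once (>= 1000 directions)
  s <- random_star_mesh(162L, seed = 5)
  set.seed(2)
  d <- matrix(rnorm(3600), ncol = 3)
  cnt <- pcawarp:::cpp_ray_mesh_count(rbind(c(0, 0, 0)),
                                      d / sqrt(rowSums(d^2)),
                                      s$vertices, s$triangles)
  expect_true(all(cnt == 1L))
})

test_that("ray-mesh intersection matches sphere geometry and misses correctly", {
  s <- sphere_triangulation(1922L)
  hit <- ray_mesh_intersect(s, c(0, 0, 0), c(1, 0, 0))
  expect_equal(hit$point, c(1, 0, 0), tolerance = 5e-3)
  expect_equal(hit$distance, 1, tolerance = 5e-3)
  expect_null(ray_mesh_intersect(s, c(10, 0, 0), c(1, 0, 0)))
  expect_error(ray_mesh_intersect(s, c(0, 0, 0), c(0, 0, 0)), "nonzero")
})

test_that("ray-mesh intersection equals the brute-force all-triangle scan", {
  mesh <- random_star_mesh(162L, seed = 3)
  set.seed(4)
  for (i in 1:50) {
    origin <- rnorm(3, sd = 20)
    dir <- rnorm(3)
    got <- ray_mesh_intersect(mesh, origin, dir)
    want <- bf_ray_mesh(mesh, origin, dir)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(got$distance, want$t, tolerance = 1e-12)
      expect_equal(got$triangle, want$tri)
      # intersection point lies in the plane of, and inside, its triangle
      tri <- mesh$triangles[got$triangle, ]
      a <- mesh$vertices[tri[1], ]; b <- mesh$vertices[tri[2], ]
      cc <- mesh$vertices[tri[3], ]
      n <- cross3(b - a, cc - a)
      expect_lt(abs(sum((got$point - a) * n)) / sqrt(sum(n^2)), 1e-8)
    }
  }
})

test_that("CTF alignment satisfies its frame definition", {
  fid <- fiducials(nas = c(100, 0, 0), lpa = c(0, 70, 0), rpa = c(0, -70, 0))
  xf <- ctf_from_fiducials(fid)
  expect_equal(xf$rotation, diag(3), tolerance = 1e-9)
  expect_equal(xf$translation, c(0, 0, 0), tolerance = 1e-9)

  set.seed(9)
  for (i in 1:10) {
    f2 <- fiducials(rnorm(3, sd = 50), rnorm(3, sd = 50), rnorm(3, sd = 50))
    xf2 <- ctf_from_fiducials(f2)
    new <- transform_points(xf2, f2)
    expect_equal((new$lpa + new$rpa) / 2, c(0, 0, 0), tolerance = 1e-9)
    expect_equal(new$nas[2:3], c(0, 0), tolerance = 1e-9)
    expect_gt(new$nas[1], 0)
    expect_equal(c(new$lpa[3], new$rpa[3]), c(0, 0), tolerance = 1e-9)
    expect_gt(new$lpa[2], 0) # ALS: left is +y
    # distances preserved
    expect_equal(sqrt(sum((new$nas - new$lpa)^2)),
                 sqrt(sum((f2$nas - f2$lpa)^2)), tolerance = 1e-9)
  }
  expect_error(fiducials(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)), "collinear")
})

test_that("CTF re-alignment recovers a rigidly moved head and is idempotent", {
  pop <- test_population(n = 3, k = 2, v = 162L, seed = 11)
  head <- pop$heads[[1]]
  rot <- random_rotation(21)
  xf <- rigid_transform(rot, c(13, -8, 25))
  moved <- transform_points(xf, head)
  back <- align_ctf(moved)
  for (nm in c("scalp", "skull", "csf", "cortex"))
    expect_lt(max(abs(back$shells[[nm]]$vertices - head$shells[[nm]]$vertices)),
              1e-6)
  again <- align_ctf(head) # already CTF -> identity
  expect_lt(max(abs(again$shells$scalp$vertices - head$shells$scalp$vertices)),
            1e-9)
})

test_that("cut_above_ears keeps exactly the points above the offset plane", {
  fid <- fiducials(c(100, 0, 0), c(0, 70, 0), c(0, -70, 0)) # plane z = 0
  pts <- rbind(c(0, 0, 40), c(0, 0, 30), c(50, 20, 36), c(0, 0, 35))
  kept <- cut_above_ears(pts, fid, offset = 35)
  expect_equal(kept, pts[c(1, 3, 4), ]) # ties at the offset are kept
  expect_equal(cut_above_ears(pts, fid, offset = -1e9), pts)

  # random cloud in a rotated frame equals the brute-force plane filter
  rot <- random_rotation(31)
  shift <- c(5, -12, 40)
  f2 <- fiducials(drop(rot %*% c(100, 0, 0)) + shift,
                  drop(rot %*% c(0, 70, 0)) + shift,
                  drop(rot %*% c(0, -70, 0)) + shift)
  set.seed(32)
  cloud0 <- matrix(rnorm(300, sd = 60), ncol = 3)
  cloud <- cloud0 %*% t(rot) + matrix(shift, 100, 3, byrow = TRUE)
  got <- cut_above_ears(cloud, f2, offset = 35)
  expect_equal(got, cloud[cloud0[, 3] >= 35, , drop = FALSE], tolerance = 1e-9)
})

test_that("move_inward shifts along normalized outward normals", {
  u <- pcawarp:::fibonacci_directions(200)
  pts <- 100 * u
  shifted <- move_inward(pts, u, 12)
  expect_equal(sqrt(rowSums(shifted^2)), rep(88, 200), tolerance = 1e-9)
  expect_equal(move_inward(pts, 3 * u, 0), pts, ignore_attr = TRUE)

  # ellipsoid with analytic normals matches the closed-form offset
  abc <- c(100, 85, 90)
  p <- sweep(u, 2, abc, "*")
  n <- sweep(p, 2, abc^2, "/")
  n <- n / sqrt(rowSums(n^2))
  expect_equal(move_inward(p, sweep(p, 2, abc^2, "/"), 7), p - 7 * n,
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_error(move_inward(pts[1:2, ], rbind(c(0, 0, 0), c(1, 0, 0)), 5),
               "zero")
})

test_that("radial projection onto the reference triangulation", {
  ref <- sphere_triangulation(162L)
  m <- project_to_sphere_triangulation(100, reference = ref)
  expect_equal(m$vertices, 100 * ref$vertices, tolerance = 1e-12)
  expect_identical(m$triangles, ref$triangles)

  abc <- c(100, 85, 90)
  radial <- function(u) 1 / sqrt((u[, 1] / abc[1])^2 + (u[, 2] / abc[2])^2 +
                                   (u[, 3] / abc[3])^2)
  ell <- project_to_sphere_triangulation(radial, reference = ref)
  expect_equal(rowSums(sweep(ell$vertices, 2, abc, "/")^2), rep(1, 162L),
               tolerance = 1e-9)

  # applying the projection to the radial field of its own output is idempotent
  r_own <- sqrt(rowSums(ell$vertices^2))
  again <- project_to_sphere_triangulation(function(u) r_own, reference = ref)
  expect_equal(again$vertices, ell$vertices, tolerance = 1e-12)
  expect_error(project_to_sphere_triangulation(function(u) rep(-1, nrow(u)),
                                               reference = ref), "positive")
})

test_that("nesting check flags ordered and swapped shells", {
  ref <- sphere_triangulation(162L)
  sph <- function(r, t) project_to_sphere_triangulation(r, reference = ref,
                                                        tissue = t)
  fid <- fiducials(c(100, 0, 0), c(0, 100, 0), c(0, -100, 0))
  good <- head_model(sph(100, "scalp"), sph(95, "skull"), sph(90, "csf"),
                     sph(85, "cortex"), fid, "ctf")
  rep_ <- check_nesting(good)
  expect_true(rep_$ok)
  expect_equal(unname(rep_$min_gap_per_pair), rep(5, 3), tolerance = 0.2)

  swapped <- head_model(sph(100, "scalp"), sph(90, "skull"), sph(95, "csf"),
                        sph(85, "cortex"), fid, "ctf")
  expect_false(check_nesting(swapped)$ok)

  # refinement: 10x denser raycasting agrees on the ok flag
  pop <- test_population(n = 4, k = 3, v = 162L, seed = 13)
  for (h in pop$heads)
    expect_equal(check_nesting(h, 100L)$ok, check_nesting(h, 1000L)$ok)
})

test_that("farthest-point decimation spreads points", {
  set.seed(41)
  pts <- matrix(rnorm(3000), ncol = 3)
  pts <- 100 * pts / sqrt(rowSums(pts^2))
  keep_all <- decimate_pointcloud(pts, nrow(pts))
  expect_equal(keep_all, pts)

  two <- rbind(matrix(rnorm(1500, sd = 2), ncol = 3),
               matrix(rnorm(1500, sd = 2) + 100, ncol = 3))
  sel2 <- decimate_pointcloud(two, 2L)
  expect_equal(sort(sel2[, 1] > 50), c(FALSE, TRUE)) # one point per cluster

  min_pair <- function(m) min(dist(m))
  fps <- min_pair(decimate_pointcloud(pts, 150L))
  set.seed(42)
  rnd <- vapply(1:20, function(i) min_pair(pts[sample(nrow(pts), 150L), ]), 0)
  expect_gte(fps, median(rnd))
  expect_error(decimate_pointcloud(pts, 0L), "positive")
})

test_that("vertex normals of a sphere are radial", {
  s <- sphere_triangulation(642L)
  n <- vertex_normals(s)
  expect_gt(min(rowSums(n * s$vertices)), 0.99)
})
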