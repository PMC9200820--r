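test_that("superposition recovers rigid motions exactly", {
  set.seed(42)
  x <- matrix(rnorm(12), ncol = 3)  # 4 non-coplanar points
  s0 <- kabsch_superpose(x, x)
  expect_equal(s0$rmsd, 0, tolerance = 1e-12)
  expect_equal(s0$rotation, diag(3), tolerance = 1e-8)

  # 90 degree rotation about z then translation (5, 0, 0)
  R <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  y <- sweep(x %*% t(R), 2, c(5, 0, 0), "+")
  s <- kabsch_superpose(x, y)
  expect_equal(s$rmsd, 0, tolerance = 1e-12)
  expect_equal(apply_superposition(s, x), y, tolerance = 1e-10)
  # proper rotation, orthonormal
  expect_equal(crossprod(s$rotation), diag(3), tolerance = 1e-8)
  expect_equal(det(s$rotation), 1, tolerance = 1e-10)
})

test_that("superposition RMSD matches the numerical rigid-fit oracle", {
  # unit square with one corner displaced 1 A out of plane
  target <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  mobile <- target
  mobile[3, 3] <- 1
  set.seed(7)
  expect_equal(kabsch_superpose(mobile, target)$rmsd,
               rigid_fit_oracle_rmsd(mobile, target), tolerance = 1e-6)
})

test_that("superposition rmsd is invariant under joint rigid motions", {
  set.seed(5)
  for (i in 1:10) {
    a <- matrix(rnorm(30), ncol = 3)
    b <- matrix(rnorm(30), ncol = 3)
    r0 <- kabsch_superpose(a, b)$rmsd
    R <- rodrigues(runif(3, -pi, pi))
    t0 <- rnorm(3, sd = 20)
    a2 <- sweep(a %*% t(R), 2, t0, "+")
    b2 <- sweep(b %*% t(R), 2, t0, "+")
    expect_equal(kabsch_superpose(a2, b2)$rmsd, r0, tolerance = 1e-9)
  }
})

test_that("superposition rejects degenerate input", {
  x <- matrix(rnorm(12), ncol = 3)
  expect_error(kabsch_superpose(x, x[1:3, ]), "mismatched")
  expect_error(kabsch_superpose(x[1:2, ], x[1:2, ]), "at least 3")
  expect_error(kabsch_superpose(x, x, weights = rep(0, 4)), "zero weights")
})

test_that("pairwise RMSD matrix is symmetric, zero-diagonal and pairwise-exact", {
  set.seed(8)
  coords <- replicate(4, matrix(rnorm(30, sd = 3), ncol = 3), simplify = FALSE)
  ens <- toy_ensemble(coords)
  m <- pairwise_rmsd_matrix(ens)
  expect_equal(m, t(m), tolerance = 1e-9)
  expect_equal(unname(diag(m)), rep(0, 4))
  expect_true(all(m >= 0))
  for (i in 1:3) for (j in (i + 1):4) {
    expect_equal(m[i, j], kabsch_superpose(coords[[i]], coords[[j]])$rmsd,
                 tolerance = 1e-9)
  }
  # identical models give an all-zero matrix
  same <- toy_ensemble(list(coords[[1]], coords[[1]], coords[[1]]))
  expect_equal(max(pairwise_rmsd_matrix(same)), 0, tolerance = 1e-9)
})

test_that("alignment collapses rigid-motion copies onto one conformation", {
  set.seed(9)
  base <- matrix(rnorm(60, sd = 5), ncol = 3)
  copies <- c(list(base), replicate(5, random_rigid_motion(base),
                                    simplify = FALSE))
  al <- align_to_mean(toy_ensemble(copies))
  expect_true(al$converged)
  expect_lt(max(pairwise_rmsd_matrix(al$ensemble)), 1e-6)
})

test_that("the aligned mean of two models is the coordinate midpoint", {
  set.seed(10)
  a <- matrix(rnorm(30), ncol = 3)
  b <- a + matrix(rnorm(30, sd = 0.1), ncol = 3)
  al <- align_to_mean(toy_ensemble(list(a, b)), tol = 1e-10, max_iter = 50)
  mid <- (model_coords(al$ensemble, 1) + model_coords(al$ensemble, 2)) / 2
  expect_equal(al$mean, mid, tolerance = 1e-8)
})

test_that("aligning an already-aligned ensemble changes nothing", {
  set.seed(11)
  base <- matrix(rnorm(90, sd = 5), ncol = 3)
  coords <- lapply(1:6, function(i) base + matrix(rnorm(90, sd = 0.2), ncol = 3))
  once <- align_to_mean(toy_ensemble(coords), tol = 1e-10, max_iter = 100)
  twice <- align_to_mean(once$ensemble, tol = 1e-10, max_iter = 100)
  expect_lt(max(abs(twice$ensemble$xyz - once$ensemble$xyz)), 1e-5)
})

test_that("RMSF reproduces the analytic two-point case and is rigid-invariant", {
  spec <- synthetic_spec(n_models = 1L, seed = 1L)
  base <- model_coords(make_endpoints(spec)$open, 1L)
  d <- 3  # Angstrom displacement
  a <- base; a[10, 1] <- a[10, 1] + d
  b <- base; b[10, 1] <- b[10, 1] - d
  ens <- toy_ensemble(list(a, b))
  prof <- rmsf_profile(ens, "calpha")
  expect_equal(prof$rmsf_nm[10], d / 10, tolerance = 1e-12)
  expect_equal(prof$rmsf_nm[-10], rep(0, nrow(prof) - 1), tolerance = 1e-12)
  # a common rigid motion of the whole aligned ensemble changes nothing
  set.seed(12)
  R <- rodrigues(runif(3, -pi, pi)); tv <- rnorm(3, sd = 30)
  moved <- toy_ensemble(lapply(list(a, b), function(m) {
    sweep(m %*% t(R), 2, tv, "+")
  }))
  expect_equal(rmsf_profile(moved, "calpha")$rmsf_nm, prof$rmsf_nm,
               tolerance = 1e-9)
  expect_error(rmsf_profile(subset_models(ens, 1L)), "single-model")
})

test_that("region shift RMSD is zero across a pure rigid motion", {
  spec <- synthetic_spec(n_models = 1L, seed = 2L)
  ep <- make_endpoints(spec)
  set.seed(13)
  moved <- toy_ensemble(list(random_rigid_motion(model_coords(ep$open, 1L))),
                        ids = "moved")
  moved$atoms <- ep$open$atoms
  r <- region_shift_rmsd(ep$open, moved, region_spec("arm", "A", 1, 10),
                         fit_selection = "calpha")
  expect_equal(r, 0, tolerance = 1e-9)
  # and large across a genuine hinge opening
  r2 <- region_shift_rmsd(ep$open, ep$closed, region_spec("arm", "A", 1, 10),
                          fit_selection = "calpha")
  expect_gt(r2, 1)
})
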