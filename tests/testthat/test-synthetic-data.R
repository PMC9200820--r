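test_that("endpoint geometry realizes the requested aperture angles", {
  for (theta in c(60, 90, 120)) {
    spec <- synthetic_spec(theta_open = 130, theta_closed = theta - 10,
                           n_models = 1L)
    ep <- make_endpoints(spec)
    expect_equal(n_atoms(ep$open), spec$n_res)
    expect_equal(n_atoms(ep$closed), spec$n_res)
    ang <- aperture_angle(ep$open, ep$regions[1, ], ep$regions[2, ],
                          ep$regions[3, ])
    expect_equal(ang, 130, tolerance = 1)
    ang_c <- aperture_angle(ep$closed, ep$regions[1, ], ep$regions[2, ],
                            ep$regions[3, ])
    expect_equal(ang_c, theta - 10, tolerance = 1)
  }
  expect_error(synthetic_spec(n_res = 20L, arm_len = 20L), "2 \\* arm_len")
  expect_error(synthetic_spec(theta_open = 60, theta_closed = 90),
               "theta_closed < theta_open")
})

test_that("endpoint separation grows with the aperture difference", {
  rmsds <- vapply(c(20, 40, 60), function(dtheta) {
    spec <- synthetic_spec(theta_open = 80 + dtheta, theta_closed = 80,
                           n_models = 1L)
    ep <- make_endpoints(spec)
    kabsch_superpose(model_coords(ep$open, 1L),
                     model_coords(ep$closed, 1L))$rmsd
  }, numeric(1L))
  expect_true(all(diff(rmsds) > 0))
})

test_that("two-state sampling is deterministic, counted and degenerate-exact", {
  # pure open state, no noise: every model equals the open endpoint
  spec0 <- synthetic_spec(mixture_weights = c(open = 1, closed = 0),
                          state_sd = 0, coord_noise_sd = 0, n_models = 5L,
                          seed = 101L)
  d0 <- sample_two_state_ensemble(spec0)
  for (i in 1:5) {
    expect_equal(model_coords(d0$ensemble, i),
                 model_coords(d0$endpoints$open, 1L), tolerance = 1e-12)
  }

  spec <- synthetic_spec(n_models = 37L, seed = 102L)
  d1 <- sample_two_state_ensemble(spec)
  expect_equal(n_models(d1$ensemble), 37L)
  d2 <- sample_two_state_ensemble(spec)
  expect_identical(d1$ensemble$xyz, d2$ensemble$xyz)
  spec_b <- synthetic_spec(n_models = 37L, seed = 103L)
  expect_false(identical(sample_two_state_ensemble(spec_b)$ensemble$xyz,
                         d1$ensemble$xyz))
})

test_that("double-well energies hit the wells and barrier analytically", {
  em <- energy_model_spec(well_depth = 700, barrier_height = 25,
                          asymmetry = 0, energy_noise_sd = 0)
  truth <- data.frame(model_id = c("a", "b", "c"), lambda = c(0, 1, 0.5))
  e <- lookup_energies(assign_energies(truth, em), c("a", "b", "c"))
  expect_equal(unname(e[c("a", "b")]), c(-700, -700))
  expect_equal(unname(e["c"]), -700 + 25)

  # seeded noisy table equals an independent re-evaluation of the formula
  em2 <- energy_model_spec(well_depth = 700, barrier_height = 25,
                           asymmetry = 3, energy_noise_sd = 5)
  set.seed(104)
  lam <- runif(50)
  truth2 <- data.frame(model_id = sprintf("m%02d", 1:50), lambda = lam)
  got <- lookup_energies(assign_energies(truth2, em2, seed = 105L),
                         truth2$model_id)
  set.seed(105)
  noise <- rnorm(50, 0, 5)
  manual <- -700 + 16 * 25 * lam^2 * (1 - lam)^2 + 3 * lam + noise
  expect_equal(unname(got), manual, tolerance = 1e-12)
})

test_that("the pseudo-trajectory relaxes, repeats and hits its stationary variance", {
  spec <- synthetic_spec(n_models = 1L, coord_noise_sd = 0)
  # sigma = 0: deterministic monotone relaxation to mu
  md0 <- pseudo_md_spec(n_frames = 200L, kappa = 0.5, mu = 0.9, sigma = 0,
                        seed = 111L)
  tr0 <- sample_pseudo_md(spec, md0)
  expect_true(all(diff(tr0$lambda) >= 0))
  expect_equal(tr0$lambda[200L], 0.9, tolerance = 1e-3)

  md <- pseudo_md_spec(n_frames = 300L, seed = 112L)
  expect_identical(sample_pseudo_md(spec, md)$lambda,
                   sample_pseudo_md(spec, md)$lambda)

  # small-noise stationary variance of the discrete mean-reverting walk
  md2 <- pseudo_md_spec(n_frames = 1e5L, dt = 0.05, kappa = 0.5, mu = 0.5,
                        sigma = 0.05, seed = 113L)
  tr2 <- sample_pseudo_md(synthetic_spec(n_models = 1L, n_res = 6L,
                                         arm_len = 2L, coord_noise_sd = 0),
                          md2)
  expect_true(all(tr2$lambda > -0.2 & tr2$lambda < 1.2))
  v_expected <- md2$sigma^2 * md2$dt /
    (2 * md2$kappa * md2$dt - md2$kappa^2 * md2$dt^2)
  burn <- tr2$lambda[-(1:1000)]
  expect_equal(stats::var(burn), v_expected, tolerance = 0.10)
})

test_that("the energy filter preferentially removes barrier-region models", {
  # morph coordinates spanning the well-to-well domain: the high-energy
  # (removed) models must concentrate near the barrier at lambda = 0.5
  set.seed(121)
  lam <- runif(400)
  truth <- data.frame(model_id = sprintf("m%03d", 1:400), lambda = lam)
  em <- energy_model_spec(barrier_height = 25, energy_noise_sd = 5)
  et <- assign_energies(truth, em, seed = 122L)
  f <- mean_energy_filter(et, truth$model_id)
  named_lam <- stats::setNames(lam, truth$model_id)
  expect_gt(mean(abs(named_lam[f$kept_ids] - 0.5)),
            mean(abs(named_lam[f$removed_ids] - 0.5)))
})

test_that("ground truth serializes with energies joined", {
  spec <- synthetic_spec(n_models = 8L, seed = 131L)
  d <- sample_two_state_ensemble(spec)
  et <- assign_energies(d$truth, energy_model_spec(), seed = 132L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_ground_truth(d$truth, et, path)
  back <- read.csv(path)
  expect_equal(names(back), c("model_id", "lambda", "state",
                              "energy_kcal_mol"))
  expect_equal(back$energy_kcal_mol, unname(lookup_energies(et, back$model_id)),
               tolerance = 1e-9)
})

test_that("the full synthetic pipeline recovers states and populations", {
  # filter -> elbow -> cut -> classify at the study scale, several seeds
  open_fracs <- numeric(0)
  for (seed in 141:150) {
    spec <- synthetic_spec(n_models = 1000L, seed = seed)
    d <- sample_two_state_ensemble(spec)
    et <- assign_energies(d$truth, energy_model_spec(), seed = seed + 500L)
    f <- mean_energy_filter(et, d$ensemble$model_ids)
    kept <- subset_models(d$ensemble, f$kept_ids)
    m <- pairwise_rmsd_matrix(extract_atoms(kept, "backbone"))
    k <- as.integer(elbow_select_k(m, 10L))
    expect_equal(k, 2L)
    lab <- cut_hierarchy(m, k)
    truth_kept <- d$truth$state[match(f$kept_ids, d$truth$model_id)]
    expect_equal(mclust::adjustedRandIndex(lab, truth_kept), 1.0)
    refs <- ensemble(rbind(d$endpoints$open$xyz, d$endpoints$closed$xyz),
                     d$endpoints$open$atoms, c("open", "closed"))
    cls <- classify_by_reference(kept, refs)
    truth_frac <- mean(truth_kept == "open")
    got <- unname(cls$fractions["open-like"])
    expect_equal(got, truth_frac, tolerance = 0.03)
    open_fracs <- c(open_fracs, got)
  }
  # across seeds the recovered open fraction matches the nominal mixture
  expect_equal(mean(open_fracs), 0.30, tolerance = 0.03)
})
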