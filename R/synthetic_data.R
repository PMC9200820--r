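# run code under a given seed without disturbing the caller's RNG state;
# all generators in this file are pure functions of (spec, seed)
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specification of a synthetic two-state hinge-bending ensemble
#'
#' The generator emulates the input of a post-prediction ensemble analysis:
#' a set of decoy models drawn from a noisy two-state mixture over a
#' one-dimensional open-closed morph coordinate, the kind of conformational
#' heterogeneity a residue-contact-driven structure predictor produces for
#' a hinged protein. The geometry is a CA-only chain of two straight arms
#' joined at a hinge segment; "open" and "closed" differ in the angle the
#' arms subtend at the hinge. The morph coordinate lambda runs from 0
#' (open) to 1 (closed); each model draws its state from the mixture
#' weights, its lambda from a normal around the state's nominal value, and
#' adds isotropic coordinate noise.
#'
#' Defaults follow the study conditions the package is validated under:
#' 1000 models per decoy set, a 30/70 open/closed mixture, tight state
#' dispersion (`state_sd = 0.02`) and 0.2 A per-axis coordinate noise, so
#' that the two states are separated far above the noise floor.
#'
#' @param n_res total residues, `>= 2 * arm_len + 2`.
#' @param arm_len residues per arm.
#' @param theta_open,theta_closed arm aperture in degrees for the two
#'   endpoint conformations, `0 < theta_closed < theta_open <= 180`.
#' @param mixture_weights length-2 non-negative weights `(open, closed)`
#'   summing to 1.
#' @param state_sd standard deviation of lambda around its state's nominal
#'   value (0 or 1).
#' @param coord_noise_sd isotropic per-axis coordinate noise, Angstrom.
#' @param n_models number of models to draw.
#' @param seed integer seed; generation is deterministic given the spec.
#' @return validated list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_res = 46L, arm_len = 20L,
                           theta_open = 130, theta_closed = 60,
                           mixture_weights = c(open = 0.3, closed = 0.7),
                           state_sd = 0.02, coord_noise_sd = 0.2,
                           n_models = 1000L, seed = 1L) {
  n_res <- as.integer(n_res); arm_len <- as.integer(arm_len)
  if (n_res < 6L) stop("n_res must be >= 6")
  if (n_res < 2L * arm_len + 2L) stop("need n_res >= 2 * arm_len + 2")
  if (!(theta_closed > 0 && theta_closed < theta_open && theta_open <= 180)) {
    stop("need 0 < theta_closed < theta_open <= 180")
  }
  if (length(mixture_weights) != 2L || any(mixture_weights < 0) ||
      abs(sum(mixture_weights) - 1) > 1e-12) {
    stop("mixture_weights must be two non-negative values summing to 1")
  }
  if (state_sd < 0 || coord_noise_sd < 0) stop("noise sds must be >= 0")
  structure(list(n_res = n_res, arm_len = arm_len, theta_open = theta_open,
                 theta_closed = theta_closed,
                 mixture_weights = stats::setNames(as.numeric(mixture_weights),
                                                   c("open", "closed")),
                 state_sd = state_sd, coord_noise_sd = coord_noise_sd,
                 n_models = as.integer(n_models), seed = as.integer(seed)),
            class = "synthetic_spec")
}

# ideal CA chain for a given aperture angle (degrees): arm A in, hinge
# along z centred at the origin, arm B out; CA spacing 3.8 A
hinge_chain_coords <- function(n_res, arm_len, theta_deg) {
  spacing <- 3.8
  half <- theta_deg * pi / 360  # theta/2 in radians
  ua <- c(cos(half), sin(half), 0)
  ub <- c(cos(half), -sin(half), 0)
  hinge_len <- n_res - 2L * arm_len
  arm_a <- t(vapply(seq_len(arm_len), function(i) {
    (arm_len - i + 1L) * spacing * ua
  }, numeric(3L)))
  hinge <- cbind(0, 0, (seq_len(hinge_len) - (hinge_len + 1) / 2) * spacing)
  arm_b <- t(vapply(seq_len(arm_len), function(j) j * spacing * ub,
                    numeric(3L)))
  rbind(arm_a, hinge, arm_b)
}

#' Open and closed endpoint structures of the synthetic hinge
#'
#' Builds the two CA-only endpoint conformations and the region
#' definitions (arm A, hinge, arm B) that the descriptor operations
#' consume. By construction the hinge centroid sits exactly between the
#' arm centroids, so the aperture angle of each endpoint equals its
#' `theta`.
#'
#' @param spec a [synthetic_spec].
#' @return list with `open` and `closed` (single-model [ensemble]s, model
#'   ids `"open"`/`"closed"`) and `regions` (a 3-row [region_spec]:
#'   `arm_a`, `hinge`, `arm_b`).
#' @export
make_endpoints <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  atoms <- data.frame(elety = "CA", resid = "ALA", chain = "A",
                      resno = seq_len(spec$n_res), stringsAsFactors = FALSE)
  mk <- function(theta, id) {
    ensemble(matrix(coords2vec(
      hinge_chain_coords(spec$n_res, spec$arm_len, theta)), nrow = 1L),
      atoms, id)
  }
  l <- spec$arm_len; h <- spec$n_res - 2L * spec$arm_len
  regions <- rbind(region_spec("arm_a", "A", 1L, l),
                   region_spec("hinge", "A", l + 1L, l + h),
                   region_spec("arm_b", "A", l + h + 1L, spec$n_res))
  class(regions) <- c("region_spec", "data.frame")
  list(open = mk(spec$theta_open, "open"),
       closed = mk(spec$theta_closed, "closed"),
       regions = regions)
}

#' Sample a synthetic two-state decoy ensemble with ground truth
#'
#' Each model draws a state (open/closed) from the mixture weights, a
#' morph coordinate lambda from a normal centred on the state's nominal
#' value (0 = open, 1 = closed), and takes coordinates
#' `(1 - lambda) * open + lambda * closed` plus isotropic Gaussian noise.
#'
#' @param spec a [synthetic_spec].
#' @return list with `ensemble` (model ids `m0001...`), `truth`
#'   (data.frame `model_id`, `lambda`, `state`) and `endpoints` (the
#'   [make_endpoints] output used).
#' @export
sample_two_state_ensemble <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  ep <- make_endpoints(spec)
  xo <- ep$open$xyz[1L, ]; xc <- ep$closed$xyz[1L, ]
  n <- spec$n_models
  with_seed(spec$seed, {
    states <- sample(c("open", "closed"), n, replace = TRUE,
                     prob = spec$mixture_weights)
    lambda <- stats::rnorm(n, mean = ifelse(states == "open", 0, 1),
                           sd = spec$state_sd)
    xyz <- outer(1 - lambda, xo) + outer(lambda, xc)
    if (spec$coord_noise_sd > 0) {
      xyz <- xyz + matrix(stats::rnorm(length(xyz), 0, spec$coord_noise_sd),
                          nrow = n)
    }
    ids <- sprintf("m%04d", seq_len(n))
    list(ensemble = ensemble(xyz, ep$open$atoms, ids),
         truth = data.frame(model_id = ids, lambda = lambda, state = states,
                            stringsAsFactors = FALSE),
         endpoints = ep)
  })
}

#' Specification of the synthetic double-well energy model
#'
#' Stands in for an external rescoring step: a symmetric quartic double
#' well in the morph coordinate with minima at lambda = 0 and 1, an
#' optional linear tilt, and Gaussian scoring noise:
#' `E(lambda) = -well_depth + 16 * barrier_height * lambda^2 * (1 - lambda)^2
#'  + asymmetry * lambda + N(0, energy_noise_sd^2)` (kcal/mol).
#' At the barrier top (lambda = 0.5) the quartic term equals
#' `barrier_height` exactly.
#'
#' Defaults put the wells near -700 kcal/mol with a 25 kcal/mol barrier
#' and 5 kcal/mol scoring noise — the scale of coarse-grained decoy scores
#' for a ~200-residue protein, with the barrier well above the noise.
#'
#' @param well_depth depth of the wells, kcal/mol (energy at the minima is
#'   `-well_depth` when `asymmetry = 0`).
#' @param barrier_height barrier above the wells, kcal/mol, `>= 0`.
#' @param asymmetry linear tilt coefficient, kcal/mol.
#' @param energy_noise_sd scoring noise sd, kcal/mol, `>= 0`.
#' @return validated list of class `energy_model_spec`.
#' @export
energy_model_spec <- function(well_depth = 700, barrier_height = 25,
                              asymmetry = 0, energy_noise_sd = 5) {
  if (barrier_height < 0) stop("barrier_height must be >= 0")
  if (energy_noise_sd < 0) stop("energy_noise_sd must be >= 0")
  structure(list(well_depth = well_depth, barrier_height = barrier_height,
                 asymmetry = asymmetry, energy_noise_sd = energy_noise_sd),
            class = "energy_model_spec")
}

#' Assign double-well energies to sampled models
#'
#' @param truth the ground-truth data.frame from
#'   [sample_two_state_ensemble] (columns `model_id`, `lambda`).
#' @param emodel an [energy_model_spec].
#' @param seed integer seed for the scoring noise.
#' @return an [energy_table].
#' @export
assign_energies <- function(truth, emodel = energy_model_spec(), seed = 1L) {
  stopifnot(inherits(emodel, "energy_model_spec"))
  lam <- truth$lambda
  e <- -emodel$well_depth +
    16 * emodel$barrier_height * lam^2 * (1 - lam)^2 +
    emodel$asymmetry * lam
  if (emodel$energy_noise_sd > 0) {
    e <- e + with_seed(seed, stats::rnorm(length(lam), 0,
                                          emodel$energy_noise_sd))
  }
  energy_table(truth$model_id, e)
}

#' Specification of a pseudo-trajectory on the morph coordinate
#'
#' Emulates a reference MD run as a discrete mean-reverting
#' (Ornstein-Uhlenbeck-type) random walk on lambda:
#' `lambda[t+1] = lambda[t] + kappa * (mu - lambda[t]) * dt
#'  + sigma * sqrt(dt) * xi[t]`,
#' reflected into \[-0.2, 1.2\] so frames may slightly over-open or
#' over-close beyond the crystallographic endpoints. Defaults place the
#' reversion target between the states (`mu = 0.5`) with a diffusion
#' strong enough to visit both wells over 500 frames.
#'
#' @param n_frames number of frames, `>= 2`.
#' @param dt unitless integration step.
#' @param kappa mean-reversion rate, `>= 0`.
#' @param mu reversion target on the morph coordinate.
#' @param sigma diffusion scale.
#' @param seed integer seed.
#' @return validated list of class `pseudo_md_spec`.
#' @export
pseudo_md_spec <- function(n_frames = 500L, dt = 0.05, kappa = 1,
                           mu = 0.5, sigma = 0.6, seed = 1L) {
  n_frames <- as.integer(n_frames)
  if (n_frames < 2L) stop("n_frames must be >= 2")
  if (kappa < 0) stop("kappa must be >= 0")
  if (dt <= 0) stop("dt must be > 0")
  structure(list(n_frames = n_frames, dt = dt, kappa = kappa, mu = mu,
                 sigma = sigma, seed = as.integer(seed)),
            class = "pseudo_md_spec")
}

# reflect x into [lo, hi]
reflect_into <- function(x, lo, hi) {
  while (x < lo || x > hi) {
    if (x < lo) x <- 2 * lo - x
    if (x > hi) x <- 2 * hi - x
  }
  x
}

#' Sample a pseudo-trajectory ensemble
#'
#' Generates the mean-reverting lambda trace and renders each frame as the
#' corresponding morph conformation plus the spec's coordinate noise.
#'
#' @param spec a [synthetic_spec] (provides the endpoint geometry and
#'   coordinate noise).
#' @param md a [pseudo_md_spec].
#' @return list with `ensemble` (frame ids `f0001...`), `lambda` (the
#'   trace) and `endpoints`.
#' @export
sample_pseudo_md <- function(spec, md = pseudo_md_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"), inherits(md, "pseudo_md_spec"))
  ep <- make_endpoints(spec)
  xo <- ep$open$xyz[1L, ]; xc <- ep$closed$xyz[1L, ]
  n <- md$n_frames
  with_seed(md$seed, {
    xi <- stats::rnorm(n - 1L)
    lambda <- numeric(n)
    lambda[1L] <- md$mu
    for (t in seq_len(n - 1L)) {
      step <- lambda[t] + md$kappa * (md$mu - lambda[t]) * md$dt +
        md$sigma * sqrt(md$dt) * xi[t]
      lambda[t + 1L] <- reflect_into(step, -0.2, 1.2)
    }
    xyz <- outer(1 - lambda, xo) + outer(lambda, xc)
    if (spec$coord_noise_sd > 0) {
      xyz <- xyz + matrix(stats::rnorm(length(xyz), 0, spec$coord_noise_sd),
                          nrow = n)
    }
    ids <- sprintf("f%04d", seq_len(n))
    list(ensemble = ensemble(xyz, ep$open$atoms, ids),
         lambda = lambda, endpoints = ep)
  })
}

#' Write the synthetic ground truth as CSV
#'
#' Columns `model_id,lambda,state,energy_kcal_mol`.
#'
#' @param truth ground truth from [sample_two_state_ensemble].
#' @param energies an [energy_table] covering the truth's models.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, energies, path) {
  df <- truth
  df$energy_kcal_mol <- unname(lookup_energies(energies, truth$model_id))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
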