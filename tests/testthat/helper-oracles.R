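# Independent oracles and fixture builders used across the suite.

# Rodrigues rotation from a rotation vector (axis * angle)
rodrigues <- function(w) {
  th <- sqrt(sum(w^2))
  if (th < 1e-12) return(diag(3))
  k <- w / th
  K <- matrix(c(0, -k[3], k[2],
                k[3], 0, -k[1],
                -k[2], k[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# brute-force rigid-fit RMSD: numerical minimization over rotation vector
# and translation, multiple starts; independent of the SVD route
rigid_fit_oracle_rmsd <- function(mobile, target, n_starts = 6L) {
  obj <- function(p) {
    R <- rodrigues(p[1:3])
    moved <- sweep(mobile %*% t(R), 2, p[4:6], "+")
    sqrt(mean(rowSums((moved - target)^2)))
  }
  shift0 <- colMeans(target) - colMeans(mobile)
  starts <- list(c(0, 0, 0, shift0))
  for (i in seq_len(n_starts)) {
    starts[[i + 1L]] <- c(stats::runif(3, -pi, pi), shift0)
  }
  best <- Inf
  for (s in starts) {
    fit <- stats::optim(s, obj, method = "BFGS",
                        control = list(reltol = 1e-15, maxit = 5000))
    fit2 <- stats::optim(fit$par, obj, method = "Nelder-Mead",
                         control = list(reltol = 1e-15, maxit = 5000))
    best <- min(best, fit$value, fit2$value)
  }
  best
}

# random proper rigid motion applied to an n x 3 coordinate matrix
random_rigid_motion <- function(coords) {
  R <- rodrigues(stats::runif(3, -pi, pi))
  sweep(coords %*% t(R), 2, stats::rnorm(3, sd = 10), "+")
}

# an ensemble of k mutually near-equidistant conformational blobs:
# base CA chain displaced along orthonormalized random 3N directions
make_blob_ensemble <- function(n_per_blob, n_blobs, sep = 15, noise = 0.1,
                               seed = 1L) {
  spec <- synthetic_spec(n_models = 1L, seed = seed)
  base <- make_endpoints(spec)$open
  m <- n_atoms(base)
  set.seed(seed)
  dirs <- qr.Q(qr(matrix(rnorm(3 * m * n_blobs), ncol = n_blobs)))
  scale <- sep * sqrt(m) / sqrt(2)
  n <- n_per_blob * n_blobs
  xyz <- matrix(0, n, 3 * m)
  truth <- integer(n)
  for (b in seq_len(n_blobs)) {
    rows <- (b - 1L) * n_per_blob + seq_len(n_per_blob)
    centre <- base$xyz[1L, ] + scale * dirs[, b]
    xyz[rows, ] <- matrix(centre, n_per_blob, 3 * m, byrow = TRUE) +
      rnorm(n_per_blob * 3 * m, sd = noise)
    truth[rows] <- b
  }
  list(ensemble = ensemble(xyz, base$atoms, sprintf("b%03d", seq_len(n))),
       truth = truth)
}

# tiny CA-only ensemble from a list of n x 3 coordinate matrices
toy_ensemble <- function(coord_list, ids = NULL) {
  m <- nrow(coord_list[[1L]])
  atoms <- data.frame(elety = "CA", resid = "GLY", chain = "A",
                      resno = seq_len(m), stringsAsFactors = FALSE)
  xyz <- do.call(rbind, lapply(coord_list, function(x) as.vector(t(x))))
  if (is.null(ids)) ids <- paste0("t", seq_along(coord_list))
  ensemble(xyz, atoms, ids)
}

# write a multi-model PDB text fixture with optional HETATM ligand lines
write_toy_pdb <- function(path, n_models = 1L, n_res = 3L, with_het = FALSE,
                          shift_fun = function(i) (i - 1) * 0.5) {
  lines <- character()
  for (i in seq_len(n_models)) {
    if (n_models > 1L) lines <- c(lines, sprintf("MODEL     %4d", i))
    eleno <- 0L
    for (r in seq_len(n_res)) {
      for (a in c("N", "CA", "C", "O")) {
        eleno <- eleno + 1L
        x <- r * 3.8 + shift_fun(i)
        pad <- if (nchar(a) < 4L) paste0(" ", formatC(a, width = -3)) else a
        lines <- c(lines, sprintf(
          "ATOM  %5d %4s ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00",
          eleno, pad, r, x, r * 1.0, 0.0))
      }
    }
    if (with_het) {
      lines <- c(lines,
        "HETATM  900 FE   HEM A 201      50.000  50.000  50.000  1.00  0.00",
        "HETATM  901  O   HOH A 301      60.000  60.000  60.000  1.00  0.00")
    }
    if (n_models > 1L) lines <- c(lines, "ENDMDL")
  }
  writeLines(c(lines, "END"), path)
  path
}
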