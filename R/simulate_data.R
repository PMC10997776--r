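#' Synthetic benchmark datasets
#'
#' Generators for the simulated manifolds used throughout the package's
#' experiments. All are seed-deterministic and retain the latent ground
#' truth (noise-free coordinates, angles, true class labels) as attributes
#' so that experiments can compare against it.
#'
#' @name simulated_data
NULL

#' Noisy sinusoid in three dimensions
#'
#' Points of the form `(x + ex, cos(x) + ey, cos(x - 0.5) + ez)` with
#' `x ~ U(0, 2*pi)`, `ex ~ U(-1, 1)` and `ey, ez ~ U(-0.3, 0.3)`: a
#' one-dimensional curve thickened by bounded uniform noise.
#'
#' @param n number of points.
#' @param seed optional RNG seed.
#' @return an `n` x 3 data frame (columns `x`, `y`, `z`) with attribute
#'   `"latent"`: a data frame of the noise-free `t`, `y0`, `z0`.
#' @export
sim_sinusoid <- function(n = 1000, seed = NULL) {
  with_seed(seed, {
    t <- runif(n, 0, 2 * pi)
    y0 <- cos(t)
    z0 <- cos(t - 0.5)
    out <- data.frame(x = t + runif(n, -1, 1),
                      y = y0 + runif(n, -0.3, 0.3),
                      z = z0 + runif(n, -0.3, 0.3))
    attr(out, "latent") <- data.frame(t = t, y0 = y0, z0 = z0)
    out
  })
}

#' Torus surface sample
#'
#' Standard torus parameterisation with angles `u, v ~ U(0, 2*pi)`:
#' `((R + r cos v) cos u, (R + r cos v) sin u, r sin v)`. Sampling is
#' uniform in parameter space, not surface-area corrected.
#'
#' @param n number of points.
#' @param R,r major and minor radii (`R > r > 0`).
#' @param seed optional RNG seed.
#' @return an `n` x 3 data frame with attribute `"latent"` (`u`, `v`).
#' @export
sim_torus <- function(n = 1000, R = 2, r = 1, seed = NULL) {
  if (!(R > r && r > 0)) stop("need R > r > 0")
  with_seed(seed, {
    u <- runif(n, 0, 2 * pi)
    v <- runif(n, 0, 2 * pi)
    out <- data.frame(x = (R + r * cos(v)) * cos(u),
                      y = (R + r * cos(v)) * sin(u),
                      z = r * sin(v))
    attr(out, "latent") <- data.frame(u = u, v = v)
    out
  })
}

#' Uniform sample on the unit circle
#'
#' @param n number of points (`>= 2`).
#' @param seed optional RNG seed.
#' @return an `n` x 2 data frame with attribute `"angles"`; ground-truth
#'   manifold distances are arc lengths, see [circle_arc_distances()].
#' @export
sim_circle <- function(n = 100, seed = NULL) {
  if (n < 2) stop("need n >= 2")
  with_seed(seed, {
    th <- runif(n, 0, 2 * pi)
    out <- data.frame(x = cos(th), y = sin(th))
    attr(out, "angles") <- th
    out
  })
}

#' Arc-length distance matrix for circle angles
#'
#' @param angles numeric vector of angles in radians.
#' @return symmetric matrix of `min(|a - b|, 2*pi - |a - b|)`.
#' @export
circle_arc_distances <- function(angles) {
  d <- abs(outer(angles, angles, "-"))
  pmin(d, 2 * pi - d)
}

#' Annulus (ring) sample
#'
#' Uniform angles with radii `U(r_in, r_out)` — a two-dimensional shape with
#' a central cavity, used to demonstrate that the union of local hulls
#' preserves holes that a single global convex hull would swallow.
#'
#' @param n number of points.
#' @param r_in,r_out inner and outer radii.
#' @param seed optional RNG seed.
#' @return an `n` x 2 data frame.
#' @export
sim_annulus <- function(n = 200, r_in = 1, r_out = 1.5, seed = NULL) {
  if (!(r_out > r_in && r_in > 0)) stop("need r_out > r_in > 0")
  with_seed(seed, {
    th <- runif(n, 0, 2 * pi)
    rad <- runif(n, r_in, r_out)
    data.frame(x = rad * cos(th), y = rad * sin(th))
  })
}

#' Synthetic labeled two-class cohort
#'
#' Two Gaussian point clouds with unit within-class spread whose means are
#' `separation` apart along the first coordinate, with labels optionally
#' flipped at rate `label_noise`. At `separation = 0` the classes are
#' indistinguishable; large separations are trivially separable. Stands in
#' for a binary-outcome clinical cohort in classifier benchmarks.
#'
#' @param n total number of points (split evenly).
#' @param separation distance between class means (`>= 0`).
#' @param d ambient dimension.
#' @param label_noise probability each label is flipped.
#' @param seed optional RNG seed.
#' @return data frame with `d` feature columns `f1..fd` and a binary
#'   `label` column; attribute `"true_label"` holds the pre-noise labels.
#' @export
sim_cohort <- function(n = 500, separation = 2, d = 5, label_noise = 0,
                       seed = NULL) {
  if (separation < 0) stop("'separation' must be >= 0")
  with_seed(seed, {
    n1 <- n %/% 2L
    n0 <- n - n1
    X <- matrix(rnorm(n * d), n, d)
    true <- c(rep(0L, n0), rep(1L, n1))
    X[true == 1L, 1] <- X[true == 1L, 1] + separation
    lab <- true
    if (label_noise > 0) {
      flip <- runif(n) < label_noise
      lab[flip] <- 1L - lab[flip]
    }
    out <- as.data.frame(X)
    names(out) <- paste0("f", seq_len(d))
    out$label <- lab
    attr(out, "true_label") <- true
    out
  })
}
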