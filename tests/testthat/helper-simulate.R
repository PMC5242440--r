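# Test-side simulation helpers, written independently of the package
# internals so planted-structure checks do not reuse the code they audit.

# orthonormal (quadrature inner product) Fourier-type basis on the 288 grid
test_orthonormal_basis <- function(k = 3) {
  t <- time_grid()
  w <- grid_weight()
  raw <- cbind(sin(2 * pi * t / 24), cos(2 * pi * t / 24),
               sin(4 * pi * t / 24), cos(4 * pi * t / 24))[, seq_len(k),
                                                           drop = FALSE]
  for (j in seq_len(k)) {
    v <- raw[, j]
    if (j > 1) {
      for (i in seq_len(j - 1)) v <- v - sum(v * raw[, i]) * w * raw[, i]
    }
    raw[, j] <- v / sqrt(sum(v^2) * w)
  }
  raw
}

# rank-K curves Y_i = mu + sum_k xi_ik phi_k + iid noise; caller seeds the RNG
sim_rank_curves <- function(n, lambda, noise_sd = 0, mu = NULL) {
  phi <- test_orthonormal_basis(length(lambda))
  if (is.null(mu)) mu <- 3 + 0.8 * sin(2 * pi * time_grid() / 24)
  xi <- vapply(lambda, function(l) rnorm(n, 0, sqrt(l)), numeric(n))
  xi <- matrix(xi, nrow = n)
  curves <- sweep(xi %*% t(phi), 2L, mu, `+`)
  if (noise_sd > 0) curves <- curves + matrix(rnorm(n * 288, 0, noise_sd), n)
  list(curves = curves, mu = mu, phi = phi, xi = xi)
}

# principal angle (degrees) between two unit-norm grid functions
principal_angle_deg <- function(f, g) {
  ip <- abs(sum(f * g) * grid_weight())
  acos(min(ip, 1)) * 180 / pi
}

# naive double-loop evaluation of the two-sample AD rank statistic, kept
# deliberately close to the textbook formula as an independent oracle
ad_oracle <- function(x, y) {
  n1 <- length(x)
  n2 <- length(y)
  N <- n1 + n2
  pooled <- sort(c(x, y))
  total <- 0
  for (i in 1:2) {
    ni <- if (i == 1) n1 else n2
    sample_i <- if (i == 1) x else y
    inner <- 0
    for (j in 1:(N - 1)) {
      Mij <- sum(sample_i <= pooled[j])
      inner <- inner + (N * Mij - j * ni)^2 / (j * (N - j))
    }
    total <- total + inner / ni
  }
  total / N
}

# a tiny synthetic cohort for io/pipeline tests
small_cohort <- function(n_normal = 3, n_djd = 4, seed = 11, noise_sd = 0.5,
                         ...) {
  generate_cohort(generator_config(
    seed = seed, n_per_group = c(Normal = n_normal, DJD = n_djd),
    noise_sd = noise_sd, ...))
}
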