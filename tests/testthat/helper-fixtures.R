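# Shared fixtures: small polygons and quick configs built in code.

square_poly <- function(cx, cy, half) {
  cbind(c(cx - half, cx + half, cx + half, cx - half),
        c(cy - half, cy - half, cy + half, cy + half))
}

circle_poly <- function(cx, cy, r, n = 64L) {
  ang <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(cx + r * cos(ang), cy + r * sin(ang))
}

# random star-shaped (simple) polygon around a center
random_star_poly <- function(cx, cy, r, n = 12L, jitter = 0.4) {
  ang <- sort(stats::runif(n, 0, 2 * pi))
  rad <- r * (1 + stats::runif(n, -jitter, jitter))
  cbind(cx + rad * cos(ang), cy + rad * sin(ang))
}

# fast noise-free movie config for deterministic geometry checks
quiet_config <- function(n_cells = 1, alpha_fraction = 1, ...) {
  movie_config(n_cells = n_cells, alpha_fraction = alpha_fraction,
               noise_gaussian_sigma = 0, noise_poisson = FALSE,
               bleach_rate_per_frame = 0, ...)
}
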