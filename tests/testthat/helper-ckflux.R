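# shared fixtures: noiseless designs and seeded random parameter draws

noiseless_design <- function(n_points = 12, t_max = 900, c0 = 2, f = 0.05,
                             t_prime = NULL) {
  simulation_design(time_grid = seq(0, t_max, length.out = n_points),
                    c0 = c0, f = f, noise_sd = 0, t_prime = t_prime)
}

noisy_design <- function(seed, n_points = 12, t_max = 900, c0 = 2, f = 0.05,
                         noise_frac = 0.02, t_prime = NULL) {
  simulation_design(time_grid = seq(0, t_max, length.out = n_points),
                    c0 = c0, f = f, noise_sd = noise_frac * c0, seed = seed,
                    t_prime = t_prime)
}

# random kinetic parameter draws in the physically plausible ranges used
# for the oracle-equivalence property
draw_kinetics <- function(n, seed) {
  set.seed(seed)
  data.frame(I = stats::runif(n, 1e-4, 1e-1),
             E = stats::runif(n, 1e-4, 1e-1),
             K = stats::runif(n, 0, 0.3),
             f = stats::runif(n, 1e-3, 0.2))
}

# paint a mask in the default passing green on near-white for idempotence
# checks
mask_to_image <- function(mask, green = c(0.20, 0.60, 0.20),
                          background = c(0.96, 0.96, 0.93)) {
  h <- nrow(mask); w <- ncol(mask)
  img <- array(rep(background, each = h * w), dim = c(h, w, 3))
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[mask] <- green[ch]
    img[, , ch] <- plane
  }
  img
}

# rank-formula Kruskal-Wallis H, independent of stats::kruskal.test
kw_H <- function(groups) {
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), lengths(groups))
  r <- rank(x)
  N <- length(x)
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, g, function(ri) length(ri) * (mean(ri) - (N + 1) / 2)^2))
  ties <- table(x)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}
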