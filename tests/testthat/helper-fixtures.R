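# In-code fixtures shared across the suite.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

# A small localization table: n emitters re-localized over n_frames
# consecutive frames with Gaussian noise sigma (the structure NeNA assumes).
static_field <- function(n_emitters = 150, n_frames = 60, sigma = 10,
                         fov = 20000, seed = 42) {
  with_seed(seed, {
    ex <- stats::runif(n_emitters, 0, fov)
    ey <- stats::runif(n_emitters, 0, fov)
    df <- data.frame(
      frame = rep(seq_len(n_frames) - 1L, each = n_emitters),
      x = rep(ex, n_frames) + stats::rnorm(n_emitters * n_frames, 0, sigma),
      y = rep(ey, n_frames) + stats::rnorm(n_emitters * n_frames, 0, sigma))
    localization_table(df, fov = c(fov, fov))
  })
}

# Single walker moving deterministically v nm/frame along x.
ballistic_track <- function(len = 20, v = 20) {
  data.frame(track_id = 1L, frame = seq_len(len) - 1L,
             x = v * (seq_len(len) - 1L), y = 0)
}

# Config helpers for the generator at specific study conditions.
cfg_monomers <- function(seed, p = 0.34)
  sim_config(seed = seed, composition = c(monomer = 1, dimer = 0),
             p = p, d = 1, L = 1)

cfg_mixture <- function(seed, f_dimer, p = 0.27, d_abs = 0.64)
  sim_config(seed = seed,
             composition = c(monomer = 1 - f_dimer, dimer = f_dimer),
             p = p, d = d_abs, L = 1)

cfg_states <- function(seed, fractions, D_free = 0.1, D_conf = 0.03,
                       r_c = 100, mean_len = 20, sigma_loc = 10)
  sim_config(seed = seed, sigma_loc = sigma_loc,
             diffusion = list(fractions = fractions, D_free = D_free,
                              D_conf = D_conf, r_c = r_c,
                              track_mean_length = mean_len))

# Independent enumeration oracle for the appearance pmf: convolve m
# geometric(p) trains over all compositions of n into m positive parts.
oracle_pmf_appearances <- function(n, m, p) {
  geo <- function(k) p * (1 - p)^(k - 1)
  if (m == 1) return(geo(n))
  tot <- 0
  recurse <- function(remaining, parts_left, acc) {
    if (parts_left == 1) {
      if (remaining >= 1) tot <<- tot + acc * geo(remaining)
      return(invisible())
    }
    for (k in seq_len(remaining - parts_left + 1))
      recurse(remaining - k, parts_left - 1, acc * geo(k))
  }
  recurse(n, m, 1)
  tot
}

# Monte-Carlo oracle for the observed dimer pmf: two Bernoulli(d) labels
# conditioned on >= 1 detected, each detected label drawing geometric(p)
# appearances.
mc_dimer_counts <- function(n_draws, p, d, seed = 1) {
  with_seed(seed, {
    det <- matrix(stats::runif(2 * n_draws) < d, ncol = 2)
    keep <- rowSums(det) >= 1
    det <- det[keep, , drop = FALSE]
    k <- rowSums(det)
    counts <- stats::rgeom(sum(k), p) + 1L
    as.integer(rowsum(counts, rep(seq_len(nrow(det)), k)))
  })
}

# Total variation distance between an empirical sample and a pmf over
# n = 1..n_max (tail mass lumped at n_max).
tv_distance <- function(sample, pmf_vals) {
  n_max <- length(pmf_vals)
  emp <- tabulate(pmin(sample, n_max), nbins = n_max) / length(sample)
  th <- pmf_vals
  th[n_max] <- th[n_max] + max(0, 1 - sum(th))
  sum(abs(emp - th)) / 2
}
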