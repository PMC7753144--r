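test_that("config validation catches out-of-range fields", {
  expect_error(sim_config(composition = c(monomer = 0.6, dimer = 0.6)),
               class = "qp_parameter_error")
  expect_error(sim_config(p = 0), class = "qp_parameter_error")
  expect_error(sim_config(lambda_um2 = -1), class = "qp_parameter_error")
  expect_error(sim_config(diffusion = list(
    fractions = c(immobile = 0.5, confined = 0.5, free = 0.5),
    D_free = 0.1, D_conf = 0.03, r_c = 100, track_mean_length = 20)),
    class = "qp_parameter_error")
})

test_that("config YAML round trip preserves every field", {
  cfg <- sim_config(seed = 3, p = 0.34, lambda_um2 = 0.4)
  tmp <- withr::local_tempfile(fileext = ".yaml")
  write_sim_config(cfg, tmp)
  back <- read_sim_config(tmp)
  expect_equal(unclass(back), unclass(cfg))
  writeLines("p: [0.2\n  broken", tmp)
  expect_error(read_sim_config(tmp), class = "qp_usage_error")
})

test_that("blink-count generator honors degenerate photophysics", {
  all_mono <- sim_config(seed = 1, composition = c(monomer = 1, dimer = 0),
                         p = 1, d = 1, L = 1)
  sim <- sim_blink_counts(500, all_mono)
  expect_true(all(sim$truth$n_appearances == 1))
  expect_equal(attr(sim$truth, "n_rejected"), 0)

  dimers <- sim_config(seed = 2, composition = c(monomer = 0, dimer = 1),
                       d = 1, L = 1)
  sim2 <- sim_blink_counts(500, dimers)
  expect_true(all(sim2$truth$n_appearances >= 2))
  expect_true(all(sim2$truth$detected <= sim2$truth$labeled))
  expect_true(all(sim2$truth$labeled <= sim2$truth$size))
})

test_that("empirical blink pmf converges to the analytic mixture", {
  f_true <- 0.71; p <- 0.27; d_abs <- 0.64
  sim <- sim_blink_counts(1e5, cfg_mixture(seed = 13, f_dimer = f_true),
                          n_max = 100)
  f_obs <- true_to_observed_fraction(f_true, d_abs)
  pmf <- f_obs * pmf_dimer(1:100, p, d_to_q(d_abs)) +
    (1 - f_obs) * pmf_appearances(1:100, 1, p)
  emp <- sim$hist$counts / sim$hist$total_clusters
  th <- pmf; th[100] <- th[100] + max(0, 1 - sum(th))
  expect_lt(sum(abs(emp - th)) / 2, 0.01)
})

test_that("simulated fields have Poisson cluster counts and exact ground truth", {
  ns <- vapply(1:20, function(s)
    nrow(sim_localization_field(sim_config(seed = 300 + s,
                                           n_frames = 3000))$truth),
    numeric(1))
  # lambda * area = 63; mean over 20 fields within 3 SE
  expect_lt(abs(mean(ns) - 63), 3 * sqrt(63 / 20))

  cfg0 <- sim_config(seed = 5, sigma_loc = 0, lambda_um2 = 0.2,
                     n_frames = 3000)
  sim0 <- sim_localization_field(cfg0)
  # zero localization noise: all localizations of a cluster coincide
  spread <- tapply(seq_len(nrow(sim0$table)), attr(sim0$truth, "loc_cluster"),
                   function(ix) max(stats::dist(sim0$table[ix, c("x", "y")]), 0))
  expect_true(all(unlist(spread) == 0))
})

test_that("track generator matches Brownian closed forms", {
  cfg <- cfg_states(14, c(immobile = 0, confined = 0, free = 1), D_free = 0.1)
  sim <- sim_tracks(cfg, n_tracks = 600)
  steps <- do.call(rbind, lapply(split(sim$tracks, sim$tracks$track_id),
                                 function(tr) cbind(diff(tr$x), diff(tr$y))))
  v_exp <- 2 * 0.1 * cfg$frame_time * 1e6 + 2 * cfg$sigma_loc^2   # nm^2/axis
  expect_equal(mean(c(steps[, 1]^2, steps[, 2]^2)), v_exp, tolerance = 0.05)

  # D_free = 0: tracks reduce to localization noise around fixed points
  cfg0 <- cfg_states(15, c(immobile = 0, confined = 0, free = 1), D_free = 0)
  sim0 <- sim_tracks(cfg0, n_tracks = 50)
  sp <- tapply(seq_len(nrow(sim0$tracks)), sim0$tracks$track_id, function(ix)
    stats::sd(sim0$tracks$x[ix]))
  expect_lt(max(unlist(sp)), 5 * cfg0$sigma_loc)

  # confined long-lag MSD bounded by the uniform-in-disk limit
  cfgc <- cfg_states(16, c(immobile = 0, confined = 1, free = 0),
                     D_conf = 0.1, r_c = 100, mean_len = 30)
  simc <- sim_tracks(cfgc, n_tracks = 300)
  long_msd <- vapply(split(simc$tracks, simc$tracks$track_id), function(tr) {
    if (nrow(tr) < 8) return(NA_real_)
    m <- compute_msd(tr, cfgc$frame_time)$msd
    m[length(m)]
  }, numeric(1))
  bound <- 2 * (100 / 1000)^2 + 4 * (cfgc$sigma_loc / 1000)^2
  expect_lt(mean(long_msd, na.rm = TRUE), bound)
})

test_that("ligand channel places localizations at bound sites only", {
  cfg1 <- sim_config(seed = 17, ligand = list(bound_fraction = 1,
                                              channel_sigma = 0,
                                              locs_per_site = 1))
  sim <- sim_localization_field(cfg1, n_clusters = 50)
  lig <- sim_ligand_channel(sim$truth, cfg1)
  expect_equal(nrow(lig$table), 50)
  expect_equal(sort(lig$table$x), sort(sim$truth$x), tolerance = 1e-9)
  expect_true(all(lig$truth$bound))
  expect_true(all(lig$table$channel == 1L))

  cfg0 <- sim_config(seed = 18, ligand = list(bound_fraction = 0,
                                              channel_sigma = 0,
                                              locs_per_site = 1))
  lig0 <- sim_ligand_channel(sim$truth, cfg0)
  expect_equal(nrow(lig0$table), 0)
  expect_error(sim_ligand_channel(NULL, cfg0), class = "qp_data_error")
})

test_that("identical seeds give byte-identical outputs, streams are split", {
  cfg <- sim_config(seed = 19)
  a <- sim_localization_field(cfg); b <- sim_localization_field(cfg)
  expect_identical(a, b)
  ta <- sim_tracks(cfg, 50); tb <- sim_tracks(cfg, 50)
  expect_identical(ta, tb)
  ha <- sim_blink_counts(1000, cfg); hb <- sim_blink_counts(1000, cfg)
  expect_identical(ha, hb)

  # changing only the photophysics leaves population and positions fixed
  cfg2 <- sim_config(seed = 19, p = 0.5)
  c2 <- sim_localization_field(cfg2, n_clusters = nrow(a$truth))
  expect_identical(c2$truth[c("size", "labeled", "detected")],
                   a$truth[c("size", "labeled", "detected")])
})
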