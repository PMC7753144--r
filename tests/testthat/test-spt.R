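test_that("linking follows single walkers and separates distant emitters", {
  walk <- data.frame(frame = 0:19, x = 20 * (0:19), y = 0)
  tab <- localization_table(walk, fov = c(1000, 10))
  tr <- link_localizations(tab, max_disp = 100)
  expect_equal(length(unique(tr$track_id)), 1)
  expect_equal(nrow(tr), 20)

  two <- rbind(walk, transform(walk, x = x + 5000))
  tr2 <- link_localizations(localization_table(two, fov = c(6000, 10)),
                            max_disp = 100)
  expect_equal(length(unique(tr2$track_id)), 2)
  expect_true(all(table(tr2$track_id) == 20))
  expect_error(link_localizations(tab, max_disp = -1),
               class = "qp_parameter_error")
})

test_that("linking recovers simulated well-separated tracks", {
  sim <- sim_tracks(sim_config(seed = 4, fov_nm = c(20000, 20000)),
                    n_tracks = 100)
  lk <- link_localizations(sim$table, max_disp = 500, max_gap = 1)
  lens <- as.integer(table(lk$track_id))
  # compare multiset of lengths against the ground truth
  matched <- sum(sort(lens) == sort(sim$truth$length))
  expect_gte(matched / nrow(sim$truth), 0.95)
})

test_that("MSD: zero for static, exact for ballistic, reversible", {
  stat <- data.frame(frame = 0:9, x = rep(5, 10), y = rep(7, 10))
  m0 <- compute_msd(stat, 0.02)
  expect_true(all(m0$msd == 0))
  expect_equal(length(m0$msd), 5)
  expect_true(all(diff(m0$n_pairs) <= 0))

  v <- 20  # nm/frame
  mb <- compute_msd(ballistic_track(20, v), 0.02)
  expect_equal(mb$msd, ((v / 1000) * seq_len(10))^2, tolerance = 1e-12)

  rev <- ballistic_track(20, v)
  rev$x <- rev(rev$x)
  expect_equal(compute_msd(rev, 0.02)$msd, mb$msd, tolerance = 1e-12)
  expect_error(compute_msd(stat[1:5, ], 0.02), class = "qp_data_error")
})

test_that("ensemble MSD of simulated Brownian tracks is 4 D tau", {
  cfg <- cfg_states(5, c(immobile = 0, confined = 0, free = 1),
                    D_free = 0.1, sigma_loc = 0)
  sim <- sim_tracks(cfg, n_tracks = 1000)
  rows <- split(seq_len(nrow(sim$tracks)), sim$tracks$track_id)
  msd1 <- vapply(rows, function(ix) {
    tr <- sim$tracks[ix, ]
    if (nrow(tr) < 8) return(NA_real_)
    compute_msd(tr, cfg$frame_time)$msd[1]
  }, numeric(1))
  expect_equal(mean(msd1, na.rm = TRUE), 4 * 0.1 * cfg$frame_time,
               tolerance = 0.05)
  # slope over the first 4 lags
  msd4 <- vapply(rows, function(ix) {
    tr <- sim$tracks[ix, ]
    if (nrow(tr) < 8) return(rep(NA_real_, 4))
    compute_msd(tr, cfg$frame_time)$msd[1:4]
  }, numeric(4))
  ens <- rowMeans(msd4, na.rm = TRUE)
  slope <- coef(lm(ens ~ I(cfg$frame_time * 1:4)))[2]
  expect_equal(unname(slope) / 4, 0.1, tolerance = 0.05)
})

test_that("classification: static tracks are immobile, Brownian tracks free", {
  stat <- data.frame(frame = 0:19, x = rep(0, 20), y = rep(0, 20))
  noisy <- with_seed(3, transform(stat, x = x + rnorm(20, 0, 10),
                                  y = y + rnorm(20, 0, 10)))
  cl <- classify_track(compute_msd(noisy, 0.02), sigma_loc = 10)
  expect_equal(cl$state, "immobile")
  expect_lt(cl$plateau, 3 * 4e-4)

  for (D in c(0.05, 0.1)) {
    sim <- sim_tracks(cfg_states(6, c(immobile = 0, confined = 0, free = 1),
                                 D_free = D), n_tracks = 400)
    mr <- mobility_report(sim$tracks, 10, bootstrap_B = 100, seed = 1)
    expect_gte(mr$fractions[["free"]], 0.90)
    expect_equal(mr$D_mean[["free"]], D, tolerance = 0.10)
  }
})

test_that("confined tracks are detected well above chance with plateau at r_c^2 scale", {
  sim <- sim_tracks(cfg_states(7, c(immobile = 0, confined = 1, free = 0),
                               D_conf = 0.1, r_c = 100), n_tracks = 400)
  rows <- split(seq_len(nrow(sim$tracks)), sim$tracks$track_id)
  cls <- lapply(rows, function(ix) {
    tr <- sim$tracks[ix, ]
    if (nrow(tr) < 8) return(NULL)
    classify_track(compute_msd(tr, 0.02), 10)
  })
  cls <- Filter(Negate(is.null), cls)
  states <- vapply(cls, `[[`, character(1), "state")
  expect_gte(mean(states == "confined"), 0.5)
  # fitted plateau of confined calls sits at the r_c^2 = 0.01 um^2 scale
  P <- vapply(cls[states == "confined"], `[[`, numeric(1), "conf_P")
  expect_equal(median(P), 0.01, tolerance = 0.5)
})

test_that("mobility report pools fractions with bootstrap SEMs deterministically", {
  sim <- sim_tracks(cfg_states(8, c(immobile = 1, confined = 0, free = 0)),
                    n_tracks = 100)
  mr <- mobility_report(sim$tracks, 10, bootstrap_B = 100, seed = 5)
  expect_equal(unname(mr$fractions), c(1, 0, 0))
  expect_equal(sum(mr$fractions), 1, tolerance = 1e-9)

  sim3 <- sim_tracks(cfg_states(9, c(immobile = 0.72, confined = 0.14,
                                     free = 0.14)), n_tracks = 300)
  a <- mobility_report(sim3$tracks, 10, bootstrap_B = 100, seed = 5)
  b <- mobility_report(sim3$tracks, 10, bootstrap_B = 100, seed = 5)
  expect_identical(a[c("fractions", "fractions_sem", "D_mean", "D_sem")],
                   b[c("fractions", "fractions_sem", "D_mean", "D_sem")])
  expect_equal(sum(a$fractions), 1, tolerance = 1e-9)
  expect_true(all(a$fractions_sem >= 0))

  tiny <- sim_tracks(cfg_states(10, c(immobile = 1, confined = 0, free = 0)),
                     n_tracks = 10)
  expect_error(mobility_report(tiny$tracks, 10, bootstrap_B = 100),
               class = "qp_data_error")
})

test_that("channel comparison reports differences and rejects dt mismatch", {
  sim <- sim_tracks(cfg_states(11, c(immobile = 0.3, confined = 0.2,
                                     free = 0.5)), n_tracks = 300)
  r <- mobility_report(sim$tracks, 10, bootstrap_B = 100, seed = 1)
  cmp0 <- compare_channels(r, r)
  expect_true(all(cmp0$frac_diff == 0))
  expect_true(all(cmp0$D_diff == 0 | is.na(cmp0$D_diff)))

  # ligand channel enriched for immobile tracks -> negative immobile diff
  siml <- sim_tracks(cfg_states(12, c(immobile = 0.7, confined = 0.1,
                                      free = 0.2)), n_tracks = 300)
  rl <- mobility_report(siml$tracks, 10, bootstrap_B = 100, seed = 1)
  cmp <- compare_channels(r, rl)
  expect_lt(cmp$frac_diff[cmp$state == "immobile"], 0)

  r2 <- r; r2$frame_time <- 0.05
  expect_error(compare_channels(r, r2), class = "qp_comparison_error")
})
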