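test_that("divisions conserve plasmids and runs are reproducible", {
  pars <- default_params()
  strat <- uniform_strategy(0.3, 50)
  sim <- simulate_lineages(pars, strat, t_max = 8, init_z = rep(10L, 20),
                           max_cells = 2000, seed = 101)
  expect_gt(nrow(sim$records), 100)
  expect_true(all(sim$records$daughter1_z + sim$records$daughter2_z ==
                    sim$records$mother_z))
  expect_true(all(sim$records$daughter1_z >= 0))
  expect_true(all(sim$census$z >= 0 & sim$census$z <= 50))
  sim2 <- simulate_lineages(pars, strat, t_max = 8, init_z = rep(10L, 20),
                            max_cells = 2000, seed = 101)
  expect_identical(sim$records, sim2$records)
  expect_identical(sim$census, sim2$census)
})

test_that("without replication every mother divides at her birth load", {
  pars <- model_parameters(b = 0)
  sim <- simulate_lineages(pars, uniform_strategy(0.5, 50), t_max = 25,
                           init_z = 16L, max_cells = 500, seed = 3)
  # b = 0: copy numbers can only halve down the pedigree, so each recorded
  # mother load must be reachable by successive splits from 16
  expect_true(all(sim$records$mother_z <= 16))
  # daughters inherit exactly the mother's plasmids (conservation re-check)
  expect_true(all(sim$records$daughter1_z + sim$records$daughter2_z ==
                    sim$records$mother_z))
})

test_that("daughter1 share recovers the segregation probability", {
  pars <- default_params()
  strat <- segregation_strategy(c(rep(0.5, 25), rep(0.2, 25)))
  sim <- simulate_lineages(pars, strat, t_max = 14, init_z = rep(30L, 40),
                           max_cells = 6000, seed = 11,
                           drop_plasmid_free = TRUE)
  for (z in c(20, 30)) {
    rec <- sim$records[sim$records$mother_z == z, ]
    expect_gt(nrow(rec), 30)
    n_trials <- nrow(rec) * z
    p_true <- as.numeric(strat)[z]
    se <- sqrt(p_true * (1 - p_true) / n_trials)
    p_emp <- sum(rec$daughter1_z) / n_trials
    expect_lt(abs(p_emp - p_true), 4 * se)
  }
})

test_that("plasmid-bearing growth rate converges to the spectral bound", {
  pars <- default_params()
  strat <- uniform_strategy(0.4, 50)
  l1 <- spectral_bound(build_generator(pars, strat))$lambda1
  sim <- simulate_lineages(pars, strat, t_max = 40,
                           init_z = rep(10L, 200), max_cells = 8000,
                           seed = 21, drop_plasmid_free = TRUE)
  est <- lineage_growth_rate(sim, t_min = 10)
  expect_lt(abs(est - l1), 0.05)
})

test_that("stationary census approaches the dominant eigenvector", {
  pars <- default_params()
  ess <- cached_default_ess()
  sd <- stationary_distribution(pars, ess$p_star)
  sim <- simulate_lineages(pars, ess$p_star, t_max = 60,
                           init_z = rep(10L, 100), max_cells = 10000,
                           seed = 31, drop_plasmid_free = TRUE)
  expect_gte(nrow(sim$census), 10000)
  emp <- tabulate(factor(sim$census$z, levels = 1:50)) / nrow(sim$census)
  tv <- 0.5 * sum(abs(emp - sd$density))
  expect_lt(tv, 0.1)
})

test_that("fluorescence proxy scales with copy number", {
  pars <- default_params()
  sim <- simulate_lineages(pars, uniform_strategy(0.4, 50), t_max = 8,
                           init_z = rep(10L, 20), max_cells = 2000,
                           seed = 41)
  noiseless <- fluorescence_proxy(sim, gain = 10, noise_sd = 0)
  expect_equal(noiseless$f1, 10 * noiseless$daughter1_z)
  expect_equal(noiseless$mother_f, 10 * noiseless$mother_z)
  # attenuation of the correlation under additive noise follows the
  # variance ratio rho = sd_signal / sqrt(sd_signal^2 + sd_noise^2)
  noisy <- fluorescence_proxy(sim, gain = 10, noise_sd = 5, seed = 42)
  keep <- noisy$f1 > 0               # truncation at 0 distorts the tail
  rho_obs <- cor(noisy$f1[keep], noisy$daughter1_z[keep])
  s2 <- var(10 * noisy$daughter1_z[keep])
  rho_exp <- sqrt(s2 / (s2 + 25))
  expect_lt(abs(rho_obs - rho_exp), 0.02)
})

test_that("share histograms are exactly symmetric about one half", {
  pars <- default_params()
  strat <- segregation_strategy(c(rep(0.5, 30), rep(0.2, 20)))
  sim <- simulate_lineages(pars, strat, t_max = 14, init_z = rep(25L, 50),
                           max_cells = 5000, seed = 51,
                           drop_plasmid_free = TRUE)
  fl <- fluorescence_proxy(sim, gain = 10, noise_sd = 3, seed = 52)
  for (mode in c("max-relative", "quantile")) {
    hh <- share_histograms(fl, n_strata = 10, n_bins = 20,
                           strata_mode = mode)
    for (st in unique(hh$stratum)) {
      counts <- hh$count[hh$stratum == st]
      expect_identical(counts, rev(counts))   # bin-exact mirror symmetry
    }
  }
  # equal segregation, no noise: shares of low/medium-load mothers
  # concentrate at 1/2 (binomial scatter narrows with the load)
  sim_eq <- simulate_lineages(pars, uniform_strategy(0.5, 50), t_max = 10,
                              init_z = rep(10L, 50), max_cells = 5000,
                              seed = 53)
  fl_eq <- fluorescence_proxy(sim_eq, gain = 10, noise_sd = 0)
  med <- fl_eq[fl_eq$mother_z >= 11 & fl_eq$mother_z <= 25, ]
  share_med <- med$f1 / (med$f1 + med$f2)
  expect_gt(mean(share_med >= 0.25 & share_med <= 0.75), 0.9)
  # strongly asymmetric segregation at high load: shares are bimodal
  # off-centre (the central band loses most of its mass)
  hi <- fl[fl$mother_z >= 40, ]
  share_hi <- pmin(hi$f1, hi$f2) / (hi$f1 + hi$f2)
  expect_gt(nrow(hi), 50)
  expect_lt(mean(share_hi >= 0.4), 0.5)
  expect_gt(mean(share_hi <= 0.35), 0.4)
})

test_that("rank plot orders mothers and bifurcates at high load", {
  pars <- default_params()
  ess <- cached_default_ess()
  sim <- simulate_lineages(pars, ess$p_star, t_max = 30,
                           init_z = rep(10L, 50), max_cells = 5000,
                           seed = 61, drop_plasmid_free = TRUE)
  fl <- fluorescence_proxy(sim, gain = 10, noise_sd = 0)
  rp <- rank_plot_table(fl)
  expect_equal(rp$rank, seq_len(nrow(rp)))
  expect_true(!is.unsorted(rp$mother_f))
  expect_true(all(rp$daughter_low_f <= rp$daughter_high_f))
  # low-rank mothers split near-evenly; high-rank mothers do not
  lo <- rp[rp$mother_f <= 10 * 15 & rp$mother_f >= 10 * 4, ]
  hi <- rp[rp$mother_f >= 10 * 45, ]
  expect_gt(nrow(lo), 20)
  expect_gt(nrow(hi), 20)
  gap <- function(d) mean((d$daughter_high_f - d$daughter_low_f) /
                            d$mother_f)
  expect_gt(gap(hi), gap(lo) + 0.2)
  # the lower branch stays roughly flat: its mean load stops tracking
  # half the mother's
  expect_lt(mean(hi$daughter_low_f / hi$mother_f), 0.3)
})

test_that("strategy re-estimation recovers the input within its CIs", {
  pars <- default_params()
  strat <- segregation_strategy(c(rep(0.5, 29), rep(0.25, 21)))
  sim <- simulate_lineages(pars, strat, t_max = 16, init_z = rep(25L, 100),
                           max_cells = 8000, seed = 71,
                           drop_plasmid_free = TRUE)
  expect_gt(nrow(sim$records), 1e4)
  est <- estimate_strategy(sim, z_hat = 50)
  well_sampled <- est$n >= 50
  expect_gt(sum(well_sampled), 10)
  inside <- est$lower - 1e-9 <= as.numeric(strat) &
    as.numeric(strat) <= est$upper + 1e-9
  # joint coverage: a 95% CI per z may miss occasionally
  expect_gt(mean(inside[well_sampled]), 0.85)
  expect_lt(max(abs(est$p_hat[well_sampled] -
                      as.numeric(strat)[well_sampled])), 0.05)
  # never-observed mothers are flagged with n = 0 and NA estimates
  unseen <- est$n == 0
  expect_true(all(is.na(est$p_hat[unseen])))
})

test_that("division records round-trip through TSV with a sidecar", {
  pars <- default_params()
  sim <- simulate_lineages(pars, uniform_strategy(0.4, 50), t_max = 6,
                           init_z = rep(10L, 10), max_cells = 1000,
                           seed = 81)
  path <- file.path(withr::local_tempdir(), "records.tsv")
  write_division_records(sim, path)
  back <- read_division_records(path)
  expect_equal(back$records$mother_z, sim$records$mother_z)
  expect_equal(back$records$time, sim$records$time, tolerance = 1e-12)
  expect_equal(back$meta$params$z_hat, 50)
  expect_equal(back$meta$schema, "plasmidseg-division-records/1")
})
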