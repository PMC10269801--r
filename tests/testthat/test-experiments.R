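test_that("growth sweep lays out one internally consistent row per group-volume", {
  cfg <- default_config()
  v_grid <- 10^seq(0, 8, length.out = 17)
  sw <- sweep_growth(c("diatom", "other", "diatom_no_si"), v_grid, cfg)
  expect_equal(nrow(sw), 3 * length(v_grid))
  expect_named(sw, c("group", "volume_um3", "qc_molC", "fpho_molC_per_day",
                     "mu_per_day", "silica_fraction"))

  # within-row consistency: mu == f_pho / (q_c * total cost factor)
  for (g in unique(sw$group)) {
    p <- taxon_parameters(g, cfg)
    rows <- sw[sw$group == g, ]
    expect_equal(rows$mu_per_day,
                 rows$fpho_molC_per_day / (rows$qc_molC *
                                             total_cost_factor(p)),
                 tolerance = 1e-12)
    expect_true(all(diff(rows$volume_um3) > 0))
    expect_true(all(rows$mu_per_day >= 0))
  }

  # all groups share the same light, so F_Pho is identical across groups
  wide <- split(sw$fpho_molC_per_day, sw$group)
  expect_identical(wide$diatom, wide$other)
  expect_identical(wide$diatom, wide$diatom_no_si)

  # where the diatom quota is below the other quota, its growth is higher
  d <- sw[sw$group == "diatom", ]
  o <- sw[sw$group == "other", ]
  lighter <- d$qc_molC < o$qc_molC
  expect_true(all(d$mu_per_day[lighter] > o$mu_per_day[lighter]))

  # single-volume grid: one row per group
  one <- sweep_growth(c("diatom", "other"), v_grid = 100, config = cfg)
  expect_equal(nrow(one), 2)

  expect_error(sweep_growth("chlorophyte", v_grid = c(1, 10), config = cfg),
               "unknown taxon group")
  expect_error(sweep_growth("diatom", v_grid = c(10, 1), config = cfg),
               "increasing")
})

test_that("the no-silica counterfactual rescales growth by the cost ratio", {
  v_grid <- 10^seq(0, 8, length.out = 20)
  sw <- sweep_growth(c("diatom", "diatom_no_si"), v_grid)
  ratio <- sw$mu_per_day[sw$group == "diatom_no_si"] /
    sw$mu_per_day[sw$group == "diatom"]
  expect_equal(ratio, rep(1.718221 / 1.966633, length(v_grid)),
               tolerance = 1e-12)
})

test_that("fate sweep produces linear per-volume flux columns", {
  mu_grid <- seq(0, 2, by = 0.25)
  fd <- sweep_fate(mu_grid, v = 100, "diatom")
  fo <- sweep_fate(mu_grid, v = 100, "other")

  expect_true(all(fo$silica_per_volume == 0))
  expect_equal(fd$total_per_volume[1], 0)

  # linearity: flux / mu constant for mu > 0
  pos <- fd$mu_per_day > 0
  for (col in c("biosynthesis_per_volume", "respiration_per_volume",
                "silica_per_volume", "total_per_volume")) {
    slopes <- fd[[col]][pos] / fd$mu_per_day[pos]
    expect_equal(slopes, rep(slopes[1], sum(pos)), tolerance = 1e-12)
  }

  # silica share of total is the parameter ratio at every positive mu
  share <- fd$silica_per_volume[pos] / fd$total_per_volume[pos]
  expect_equal(share, rep(silica_fraction_of_cost(default_diatom()),
                          sum(pos)), tolerance = 1e-12)
})

test_that("observation scoring recovers constructed offsets and scatter", {
  sw <- sweep_growth("diatom", 10^seq(0, 8, length.out = 40))

  # observations sampled exactly from the model curve: zero residuals
  exact <- tibble::tibble(volume_um3 = sw$volume_um3[c(5, 15, 30)],
                          mu_per_day = sw$mu_per_day[c(5, 15, 30)],
                          group = "diatom")
  fit <- compare_observations(sw, exact)
  expect_equal(fit$rmse, 0, tolerance = 1e-12)
  expect_equal(fit$bias, 0, tolerance = 1e-12)

  # a constant x 10^0.3 offset appears as 0.3 log10 bias
  off <- exact
  off$mu_per_day <- off$mu_per_day * 10^0.3
  fit <- compare_observations(sw, off)
  expect_equal(fit$bias, 0.3, tolerance = 1e-12)
  expect_equal(fit$rmse, 0.3, tolerance = 1e-12)

  # shipped synthetic fixture: lognormal scatter sigma = 0.2, seed 1
  obs <- simulate_observations(sw, n_per_group = 100, sigma_log10 = 0.2,
                               seed = 1)
  fit <- compare_observations(sw, obs)
  expect_gt(fit$rmse, 0.15)
  expect_lt(fit$rmse, 0.25)

  # no overlap is an explicit error
  far <- tibble::tibble(volume_um3 = 1e12, mu_per_day = 1, group = "diatom")
  expect_error(compare_observations(sw, far), "volume range")
  alien <- tibble::tibble(volume_um3 = 10, mu_per_day = 1, group = "cyano")
  expect_error(compare_observations(sw, alien), "shared")
})

test_that("default curves reproduce the expected growth-volume shapes", {
  sw <- sweep_growth()
  for (g in c("diatom", "other", "diatom_no_si")) {
    rows <- sw[sw$group == g & sw$volume_um3 >= 1e3, ]
    expect_true(all(diff(rows$mu_per_day) < 0),
                info = paste("decreasing above 1e3 um^3:", g))
  }
  d <- sw[sw$group == "diatom", ]
  o <- sw[sw$group == "other", ]
  n <- sw[sw$group == "diatom_no_si", ]
  expect_true(all(d$mu_per_day > o$mu_per_day))
  expect_true(all(n$mu_per_day < d$mu_per_day))
  # peak calibration: maximum near 2 d^-1 around 100 um^3
  expect_equal(max(d$mu_per_day), 2, tolerance = 0.01)
  expect_gt(d$volume_um3[which.max(d$mu_per_day)], 30)
  expect_lt(d$volume_um3[which.max(d$mu_per_day)], 300)
})

test_that("doubling the Si:C ratio barely moves diatom growth", {
  cfg <- default_config()
  cfg2 <- cfg
  cfg2$taxa$diatom$r_sic <- 2 * cfg$taxa$diatom$r_sic
  v_grid <- 10^seq(0, 8, length.out = 15)
  mu1 <- sweep_growth("diatom", v_grid, cfg)$mu_per_day
  mu2 <- sweep_growth("diatom", v_grid, cfg2)$mu_per_day
  expect_true(all(abs(mu2 - mu1) / mu1 < 0.03))
  expect_true(all(mu2 < mu1))  # direction: more silica, slightly slower
})

test_that("calibration hits a requested growth-volume peak", {
  cfg <- default_config()
  cfg$quadrature <- list(n_rho = 64, n_s = 64)
  cal <- calibrate_light(cfg, target_mu = 1.5, target_v = 50)
  p <- taxon_parameters("diatom", cal)
  env <- light_environment(cal$light$i0, cal$light$k_att)
  pp <- photosynthesis_parameters(cal$photosynthesis$p_max_v,
                                  cal$photosynthesis$i_sat)
  mu_of <- function(lv) {
    v <- 10^lv
    growth_rate(cellular_photosynthesis(v, env, pp, 64, 64), v, p)
  }
  opt <- optimize(mu_of, c(-1, 6), maximum = TRUE)
  expect_equal(10^opt$maximum, 50, tolerance = 0.02)
  expect_equal(opt$objective, 1.5, tolerance = 1e-3)
})
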