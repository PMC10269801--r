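light_from_config <- function(config) {
  light_environment(config$light$i0, config$light$k_att)
}

photo_from_config <- function(config) {
  photosynthesis_parameters(config$photosynthesis$p_max_v,
                            config$photosynthesis$i_sat)
}

#' Log-spaced volume grid from a configuration
#'
#' @param config a configuration list.
#' @return volumes in \eqn{\mu m^3}, log-spaced over
#'   `[sweep$v_min, sweep$v_max]`.
#' @export
volume_grid <- function(config = default_config()) {
  s <- config$sweep
  if (s$n_points == 1) return(s$v_min)
  10^seq(log10(s$v_min), log10(s$v_max), length.out = s$n_points)
}

#' Growth rate versus cell volume sweep per taxon group
#'
#' Runs the steady-state model over a volume grid for each taxon group.
#' All groups share the same light environment and
#' photosynthesis-irradiance parameters (and hence the same `F_Pho` at a
#' given volume); groups differ only in their quota constants and cost
#' factors.
#'
#' @param groups character vector of taxon groups; each must have a block
#'   under `taxa` in the configuration.
#' @param v_grid positive, strictly increasing volumes, \eqn{\mu m^3};
#'   defaults to [volume_grid()].
#' @param config a configuration list.
#' @return a tibble with one row per (group, volume): `group`,
#'   `volume_um3`, `qc_molC`, `fpho_molC_per_day`, `mu_per_day`,
#'   `silica_fraction` (share of the total carbon cost spent on silica
#'   deposition; 0 for non-silicifying groups).
#' @export
#' @examples
#' sw <- sweep_growth(c("diatom", "other"),
#'                    v_grid = 10^seq(0, 8, length.out = 9))
#' sw[sw$volume_um3 == 100, ]
sweep_growth <- function(groups = c("diatom", "other", "diatom_no_si"),
                         v_grid = volume_grid(config),
                         config = default_config()) {
  if (any(!is.finite(v_grid)) || any(v_grid <= 0)) {
    stop("volume grid must be positive and finite", call. = FALSE)
  }
  if (is.unsorted(v_grid, strictly = TRUE)) {
    stop("volume grid must be strictly increasing", call. = FALSE)
  }
  env <- light_from_config(config)
  pp <- photo_from_config(config)
  f_pho <- cellular_photosynthesis(v_grid, env, pp,
                                   n_rho = config$quadrature$n_rho,
                                   n_s = config$quadrature$n_s)
  dplyr::bind_rows(lapply(groups, function(g) {
    p <- taxon_parameters(g, config)
    e_si <- silica_cost_factor(p)
    tibble::tibble(
      group = g,
      volume_um3 = v_grid,
      qc_molC = carbon_quota(v_grid, p),
      fpho_molC_per_day = f_pho,
      mu_per_day = growth_rate(f_pho, v_grid, p),
      silica_fraction = e_si / total_cost_factor(p)
    )
  }))
}

#' Fate-of-carbon sweep over growth rates
#'
#' Per-volume carbon fluxes (mol C \eqn{\mu m^{-3}} d\eqn{^{-1}}) into
#' biosynthesis, growth respiration, silica deposition and excretion, for
#' each growth rate in `mu_grid`, at a fixed cell volume. Each column is
#' exactly linear in the growth rate; the silica column is identically
#' zero for non-silicifying groups.
#'
#' @param mu_grid non-negative growth rates, d\eqn{^{-1}}.
#' @param v cell volume, \eqn{\mu m^3}.
#' @param group taxon group name.
#' @inheritParams sweep_growth
#' @return a tibble with columns `group`, `volume_um3`, `mu_per_day`, the
#'   four per-volume flux columns, and `total_per_volume`.
#' @export
sweep_fate <- function(mu_grid, v, group, config = default_config()) {
  if (any(!is.finite(mu_grid)) || any(mu_grid < 0)) {
    stop("growth rates must be non-negative and finite", call. = FALSE)
  }
  p <- taxon_parameters(group, config)
  rows <- lapply(mu_grid, function(mu) {
    b <- carbon_fate(mu, v, p)
    tibble::tibble(
      group = group, volume_um3 = v, mu_per_day = mu,
      biosynthesis_per_volume = b$flux_biosynthesis / v,
      respiration_per_volume = b$flux_respiration / v,
      silica_per_volume = b$flux_silica_cost / v,
      excretion_per_volume = b$flux_excretion / v,
      total_per_volume = b$f_pho / v
    )
  })
  dplyr::bind_rows(rows)
}

#' Score a model sweep against observed growth-volume data
#'
#' Interpolates the model curve linearly in (log10 volume, log10 growth
#' rate) for each group and reports the log10-space residual summary of
#' the observations against it.
#'
#' @param model a sweep tibble from [sweep_growth()].
#' @param obs a data frame with columns `volume_um3`, `mu_per_day`, and
#'   `group`.
#' @return a tibble with one row per group present in both tables:
#'   `group`, `n` (observations inside the model's volume range), `bias`
#'   (mean log10 observed minus model) and `rmse` (root mean square log10
#'   residual).
#' @export
compare_observations <- function(model, obs) {
  needed <- c("volume_um3", "mu_per_day", "group")
  if (!all(needed %in% names(obs))) {
    stop("observations need columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  shared <- intersect(unique(obs$group), unique(model$group))
  if (length(shared) == 0) {
    stop("no taxon group shared between model sweep and observations",
         call. = FALSE)
  }
  out <- lapply(shared, function(g) {
    m <- model[model$group == g, ]
    o <- obs[obs$group == g, ]
    pred <- approx(log10(m$volume_um3), log10(m$mu_per_day),
                   xout = log10(o$volume_um3), rule = 1)$y
    keep <- is.finite(pred)
    if (!any(keep)) {
      stop("no observations for group '", g,
           "' fall inside the model volume range", call. = FALSE)
    }
    res <- log10(o$mu_per_day[keep]) - pred[keep]
    tibble::tibble(group = g, n = sum(keep), bias = mean(res),
                   rmse = sqrt(mean(res^2)))
  })
  dplyr::bind_rows(out)
}

#' Synthetic observed growth-volume scatter around the model curve
#'
#' Emulates a compilation of laboratory nutrient-replete growth rates:
#' volumes drawn log-uniformly over the model range and growth rates
#' scattered lognormally (sd `sigma_log10` in log10 units) around the
#' model curve for the group. Useful as a fixture for
#' [compare_observations()] and as a stand-in for observation tables the
#' user would otherwise supply.
#'
#' @param model a sweep tibble from [sweep_growth()].
#' @param n_per_group observations per group.
#' @param sigma_log10 lognormal scatter, log10 units.
#' @param seed integer seed.
#' @return a tibble with columns `volume_um3`, `mu_per_day`, `group`.
#' @export
simulate_observations <- function(model,
                                  n_per_group = 100,
                                  sigma_log10 = 0.2,
                                  seed = 1) {
  set.seed(derive_seed(seed, "observations"))
  out <- lapply(unique(model$group), function(g) {
    m <- model[model$group == g, ]
    lv <- runif(n_per_group, log10(min(m$volume_um3)),
                log10(max(m$volume_um3)))
    lmu <- approx(log10(m$volume_um3), log10(m$mu_per_day), xout = lv)$y
    tibble::tibble(
      volume_um3 = 10^lv,
      mu_per_day = 10^(lmu + rnorm(n_per_group, 0, sigma_log10)),
      group = g
    )
  })
  dplyr::bind_rows(out)
}

#' Calibrate the light parameters to a target growth-volume peak
#'
#' Solves for the intracellular attenuation coefficient `k_att` and the
#' maximum volumetric fixation rate `p_max_v` such that the diatom
#' growth-volume curve attains its maximum `target_mu` at volume
#' `target_v`, holding `i0` and `i_sat` at their configured values. The
#' peak position depends only on `k_att` (growth rate is proportional to
#' `p_max_v`), so the solve splits into a one-dimensional root find on
#' `log10 k_att` followed by a linear rescale of `p_max_v`. This is how
#' the package's default light parameters were produced.
#'
#' @param config a configuration list supplying `i0`, `i_sat`, and the
#'   diatom quota constants.
#' @param target_mu peak growth rate, d\eqn{^{-1}}.
#' @param target_v volume at the peak, \eqn{\mu m^3}.
#' @param k_range search interval for `k_att`, \eqn{\mu m^{-1}}.
#' @return the configuration with `light$k_att` and
#'   `photosynthesis$p_max_v` replaced by the calibrated values.
#' @export
calibrate_light <- function(config = default_config(), target_mu = 2,
                            target_v = 100, k_range = c(1e-3, 10)) {
  p <- taxon_parameters("diatom", config)
  pp_unit <- photosynthesis_parameters(1, config$photosynthesis$i_sat)
  i0 <- config$light$i0
  # volume at which mu(v) peaks, for a given attenuation coefficient
  peak_volume <- function(k) {
    env <- light_environment(i0, k)
    obj <- function(lv) {
      v <- 10^lv
      growth_rate(cellular_photosynthesis(v, env, pp_unit, 64, 64), v, p)
    }
    10^optimize(obj, c(-2, 10), maximum = TRUE, tol = 1e-6)$maximum
  }
  root <- uniroot(function(lk) log10(peak_volume(10^lk)) - log10(target_v),
                  log10(k_range), tol = 1e-10)
  k_att <- 10^root$root
  env <- light_environment(i0, k_att)
  mu_unit <- growth_rate(
    cellular_photosynthesis(target_v, env, pp_unit,
                            config$quadrature$n_rho, config$quadrature$n_s),
    target_v, p)
  config$light$k_att <- k_att
  config$photosynthesis$p_max_v <- target_mu / mu_unit
  config
}
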