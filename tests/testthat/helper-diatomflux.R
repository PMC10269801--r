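# shared fixtures: default parameter objects and independent brute-force
# oracles for the optics integrals

default_diatom <- function() taxon_parameters("diatom")
default_other <- function() taxon_parameters("other")
default_no_si <- function() taxon_parameters("diatom_no_si")

default_env <- function(cfg = default_config()) {
  light_environment(cfg$light$i0, cfg$light$k_att)
}

default_pp <- function(cfg = default_config()) {
  photosynthesis_parameters(cfg$photosynthesis$p_max_v,
                            cfg$photosynthesis$i_sat)
}

# brute-force midpoint-rule double integral over (beam offset, depth along
# chord); independent of the package's Gauss-Legendre path
brute_force_fpho <- function(v, env, pp, n = 2000) {
  r <- (3 * v / (4 * pi))^(1 / 3)
  rho <- (seq_len(n) - 0.5) / n * r
  u <- (seq_len(n) - 0.5) / n
  chord <- 2 * sqrt(pmax(r^2 - rho^2, 0))
  s <- outer(chord, u)
  rate <- pp$p_max_v * (1 - exp(-env$i0 * exp(-env$k_att * s) / pp$i_sat))
  2 * pi * sum(rho * chord * rowSums(rate)) * (r / n) * (1 / n)
}

# brute-force chord sum for the absorbed fraction of a collimated beam
brute_force_absorbed <- function(k_att, r, n = 1e6) {
  rho <- (seq_len(n) - 0.5) / n * r
  chord <- 2 * sqrt(pmax(r^2 - rho^2, 0))
  (2 / r^2) * sum(rho * (1 - exp(-k_att * chord))) * (r / n)
}

# random-but-valid cell parameters for property-style tests
random_parameters <- function() {
  group <- sample(c("diatom", "other", "diatom_no_si"), 1)
  cell_parameters(
    group = group,
    a_c = runif(1, 0.01, 1),
    b_c = runif(1, 0.3, 1.5),
    e_mu = runif(1, 0, 2),
    e_si_per_si = if (group == "other") 0 else runif(1, 0, 1),
    r_sic = if (group == "other") 0 else runif(1, 0, 0.5),
    e_ex = runif(1, 0, 0.3)
  )
}
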