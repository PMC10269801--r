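# grams of C per mole; quota compilations report pg C, cost factors are molar
C_MOLAR_MASS <- 12.011
PG_C_TO_MOL <- 1e-12 / C_MOLAR_MASS

#' Per-taxon cell parameters
#'
#' Bundles the constants that distinguish a taxon group in the carbon
#' budget: the allometric quota law \eqn{Q_C = a_C V^{b_C}}, the growth
#' respiration factor, and the silica deposition cost.
#'
#' @param group taxon class: `"diatom"`, `"other"` (non-diatom
#'   phytoplankton), or `"diatom_no_si"` — a counterfactual diatom whose
#'   frustule costs as much carbon per mole of Si as ordinary biomass
#'   production costs per mole of C.
#' @param a_c quota at V = 1 \eqn{\mu m^3}, in pg C per cell (converted to
#'   mol C internally).
#' @param b_c dimensionless allometric exponent, in (0, 2).
#' @param e_mu growth respiration factor, mol C respired per mol biomass C.
#' @param e_si_per_si direct deposition cost, mol C per mol Si.
#' @param r_sic cellular Si:C molar ratio; must be 0 for `group = "other"`.
#' @param e_ex optional excreted fraction, mol C per mol biomass C.
#' @return an object of class `cell_parameters`.
#' @export
#' @examples
#' p <- cell_parameters("diatom", a_c = 0.1166, b_c = 0.881, e_mu = 0.691,
#'                      e_si_per_si = 0.167, r_sic = 0.163)
#' total_cost_factor(p)
cell_parameters <- function(group = c("diatom", "other", "diatom_no_si"),
                            a_c, b_c, e_mu, e_si_per_si = 0, r_sic = 0,
                            e_ex = 0) {
  group <- match.arg(group)
  num1 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
      stop("'", nm, "' must be a finite numeric scalar", call. = FALSE)
    }
    x
  }
  a_c <- num1(a_c, "a_c"); b_c <- num1(b_c, "b_c")
  e_mu <- num1(e_mu, "e_mu"); e_si_per_si <- num1(e_si_per_si, "e_si_per_si")
  r_sic <- num1(r_sic, "r_sic"); e_ex <- num1(e_ex, "e_ex")
  if (a_c <= 0) stop("a_c must be > 0", call. = FALSE)
  if (b_c <= 0 || b_c >= 2) stop("b_c must lie in (0, 2)", call. = FALSE)
  if (e_mu < 0 || e_si_per_si < 0 || r_sic < 0 || e_ex < 0) {
    stop("cost factors e_mu, e_si_per_si, r_sic, e_ex must be >= 0",
         call. = FALSE)
  }
  if (group == "other" && r_sic != 0) {
    stop("non-diatom cells deposit no silica: r_sic must be 0 for group ",
         "'other'", call. = FALSE)
  }
  structure(
    list(group = group, a_c = a_c, b_c = b_c, e_mu = e_mu,
         e_si_per_si = e_si_per_si, r_sic = r_sic, e_ex = e_ex),
    class = "cell_parameters"
  )
}

#' @export
print.cell_parameters <- function(x, ...) {
  cat("<cell_parameters> group:", x$group, "\n")
  cat(sprintf("  quota: Q_C = %.4g pg C * V^%.3f\n", x$a_c, x$b_c))
  cat(sprintf("  e_mu = %.4g, e_si_per_si = %.4g, r_sic = %.4g, e_ex = %.4g\n",
              x$e_mu, x$e_si_per_si, x$r_sic, x$e_ex))
  cat(sprintf("  E_Si = %.6g, total cost factor = %.6g\n",
              silica_cost_factor(x), total_cost_factor(x)))
  invisible(x)
}

#' Cell parameters for a taxon group from a configuration
#'
#' @param group taxon group name, matching a block under `taxa` in the
#'   configuration.
#' @param config a configuration list; defaults to [default_config()].
#' @return a [cell_parameters()] object.
#' @export
taxon_parameters <- function(group, config = default_config()) {
  block <- config$taxa[[group]]
  if (is.null(block)) {
    stop("unknown taxon group '", group, "'; configured groups: ",
         paste(names(config$taxa), collapse = ", "), call. = FALSE)
  }
  cell_parameters(
    group = group, a_c = block$a_c, b_c = block$b_c, e_mu = block$e_mu,
    e_si_per_si = block$e_si_per_si, r_sic = block$r_sic,
    e_ex = if (is.null(block$e_ex)) 0 else block$e_ex
  )
}

#' Cellular carbon quota from cell volume
#'
#' The allometric quota law \eqn{Q_C = a_C V^{b_C}}, with the pg-C
#' prefactor converted to moles of carbon per cell.
#'
#' @param v cell volume(s), \eqn{\mu m^3}; must be positive.
#' @param p a [cell_parameters()] object.
#' @return quota in mol C cell\eqn{^{-1}}, same length as `v`.
#' @export
#' @examples
#' p <- taxon_parameters("diatom")
#' carbon_quota(c(1, 100, 1e4), p)
carbon_quota <- function(v, p) {
  stopifnot(inherits(p, "cell_parameters"))
  if (any(!is.finite(v)) || any(v <= 0)) {
    stop("cell volume must be positive and finite", call. = FALSE)
  }
  p$a_c * PG_C_TO_MOL * v^p$b_c
}

#' Silica deposition cost factor E_Si
#'
#' Carbon spent on frustule deposition per mole of biomass carbon
#' produced: the deposition cost per mole of Si times the cellular Si:C
#' ratio. Zero when the cell deposits no silica. For the
#' `diatom_no_si` counterfactual the per-Si cost is replaced by the full
#' biomass production cost `1 + e_mu`, i.e. frustule carbon is priced like
#' ordinary biomass.
#'
#' @inheritParams carbon_quota
#' @return dimensionless E_Si.
#' @export
silica_cost_factor <- function(p) {
  stopifnot(inherits(p, "cell_parameters"))
  if (p$group == "diatom_no_si") {
    (1 + p$e_mu) * p$r_sic
  } else {
    p$e_si_per_si * p$r_sic
  }
}

#' Total carbon cost factor
#'
#' Moles of carbon fixed per mole of biomass carbon retained:
#' `1 + e_mu + E_Si + e_ex` — biosynthesis itself, growth respiration,
#' silica deposition, and optional excretion. This is the denominator of
#' the steady-state growth rate.
#'
#' @inheritParams carbon_quota
#' @return dimensionless factor, at least 1.
#' @export
total_cost_factor <- function(p) {
  stopifnot(inherits(p, "cell_parameters"))
  1 + p$e_mu + silica_cost_factor(p) + p$e_ex
}

#' Share of the total carbon cost spent on silica deposition
#'
#' `E_Si / (1 + e_mu + E_Si + e_ex)`. A pure parameter ratio: independent
#' of cell volume, growth rate, and light.
#'
#' @inheritParams carbon_quota
#' @return dimensionless fraction in `[0, 1)`.
#' @export
#' @examples
#' silica_fraction_of_cost(taxon_parameters("diatom"))  # ~0.016
silica_fraction_of_cost <- function(p) {
  stopifnot(inherits(p, "cell_parameters"))
  if (p$group == "other") {
    stop("silica cost share is undefined for non-silicifying cells ",
         "(group 'other')", call. = FALSE)
  }
  silica_cost_factor(p) / total_cost_factor(p)
}

#' Steady-state growth rate
#'
#' At steady state the carbon fixed per day equals the carbon spent per
#' day, so \eqn{\mu = F_{Pho} / [Q_C (1 + e_\mu + E_{Si} + e_{ex})]}.
#'
#' @param f_pho cellular photosynthesis rate, mol C cell\eqn{^{-1}}
#'   d\eqn{^{-1}}; non-negative. Vectorized together with `v`.
#' @inheritParams carbon_quota
#' @return growth rate(s), d\eqn{^{-1}}.
#' @export
#' @examples
#' p <- taxon_parameters("diatom")
#' growth_rate(2e-13, v = 100, p)
growth_rate <- function(f_pho, v, p) {
  stopifnot(inherits(p, "cell_parameters"))
  if (any(!is.finite(f_pho)) || any(f_pho < 0)) {
    stop("photosynthesis rate must be non-negative and finite",
         call. = FALSE)
  }
  f_pho / (carbon_quota(v, p) * total_cost_factor(p))
}

#' Fate-of-carbon decomposition at a given growth rate
#'
#' Splits the photosynthetic carbon supply that sustains growth rate `mu`
#' into its four sinks: biosynthesis (\eqn{\mu Q_C}), growth respiration
#' (\eqn{\mu Q_C e_\mu}), silica deposition cost (\eqn{\mu Q_C E_{Si}})
#' and excretion (\eqn{\mu Q_C e_{ex}}). Their sum is the photosynthesis
#' rate `f_pho` required at steady state; every flux is exactly linear in
#' `mu`.
#'
#' @param mu growth rate, d\eqn{^{-1}}; non-negative scalar.
#' @inheritParams carbon_quota
#' @param v cell volume, \eqn{\mu m^3}; positive scalar.
#' @return an object of class `carbon_budget`: a list with `mu`, `q_c`,
#'   `f_pho`, `flux_biosynthesis`, `flux_respiration`, `flux_silica_cost`,
#'   `flux_excretion` (all fluxes mol C cell\eqn{^{-1}} d\eqn{^{-1}}).
#' @export
#' @examples
#' carbon_fate(mu = 1, v = 100, taxon_parameters("diatom"))
carbon_fate <- function(mu, v, p) {
  stopifnot(inherits(p, "cell_parameters"), length(mu) == 1, length(v) == 1)
  if (!is.finite(mu) || mu < 0) {
    stop("growth rate must be non-negative and finite", call. = FALSE)
  }
  q_c <- carbon_quota(v, p)
  biosynthesis <- mu * q_c
  respiration <- biosynthesis * p$e_mu
  silica <- biosynthesis * silica_cost_factor(p)
  excretion <- biosynthesis * p$e_ex
  structure(
    list(
      mu = mu, q_c = q_c,
      f_pho = biosynthesis + respiration + silica + excretion,
      flux_biosynthesis = biosynthesis,
      flux_respiration = respiration,
      flux_silica_cost = silica,
      flux_excretion = excretion
    ),
    class = "carbon_budget"
  )
}

#' @export
print.carbon_budget <- function(x, ...) {
  cat("<carbon_budget> mu =", format(x$mu), "d^-1, Q_C =",
      format(x$q_c, digits = 4), "mol C\n")
  fl <- c(biosynthesis = x$flux_biosynthesis,
          respiration = x$flux_respiration,
          silica_cost = x$flux_silica_cost,
          excretion = x$flux_excretion)
  shares <- if (x$f_pho > 0) fl / x$f_pho else fl * 0
  for (nm in names(fl)) {
    cat(sprintf("  %-13s %.4g mol C cell^-1 d^-1 (%.2f%%)\n",
                nm, fl[[nm]], 100 * shares[[nm]]))
  }
  cat("  required F_Pho:", format(x$f_pho, digits = 4),
      "mol C cell^-1 d^-1\n")
  invisible(x)
}
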