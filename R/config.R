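#' Default model configuration
#'
#' Returns the full configuration tree used throughout the package: one
#' parameter block per taxon group, the light environment, the
#' photosynthesis-irradiance parameters, quadrature resolution, sweep
#' settings, and the settings of the two synthetic-data generators.
#'
#' Allometric quota constants default to the empirical carbon-volume
#' regressions for diatoms (`a_c = 0.1166` pg C, `b_c = 0.881`) and for
#' non-diatom protists (`a_c = 0.2163` pg C, `b_c = 0.939`), so that the
#' diatom quota lies below the non-diatom quota across the whole sweep
#' range. `i0`, `i_sat` are typical surface-ocean values; `k_att` and
#' `p_max_v` come from a one-off run of [calibrate_light()] that places the
#' peak of the diatom growth-volume curve at 2 d\eqn{^{-1}} near
#' 100 \eqn{\mu m^3}.
#'
#' @return A named nested list. Units: `a_c` pg C per cell at
#'   V = 1 \eqn{\mu m^3}; `i0`, `i_sat` \eqn{\mu}mol photons m\eqn{^{-2}}
#'   s\eqn{^{-1}}; `k_att` \eqn{\mu m^{-1}}; `p_max_v` mol C
#'   \eqn{\mu m^{-3}} d\eqn{^{-1}}; cost factors dimensionless (mol C per
#'   mol C, or mol C per mol Si for `e_si_per_si`).
#' @export
#' @examples
#' cfg <- default_config()
#' names(cfg)
#' cfg$taxa$diatom$r_sic
default_config <- function() {
  diatom <- list(
    a_c = 10^-0.933,      # pg C cell^-1 at V = 1 um^3
    b_c = 0.881,
    e_mu = 0.691,         # growth respiration, mol C (mol biomass C)^-1
    e_si_per_si = 0.167,  # deposition cost, mol C (mol Si)^-1
    r_sic = 0.163,        # cellular Si:C, mol Si (mol C)^-1
    e_ex = 0              # excreted fraction, mol C (mol biomass C)^-1
  )
  list(
    taxa = list(
      diatom = diatom,
      other = list(
        a_c = 10^-0.665,
        b_c = 0.939,
        e_mu = 0.691,
        e_si_per_si = 0,
        r_sic = 0,
        e_ex = 0
      ),
      diatom_no_si = diatom
    ),
    light = list(
      i0 = 200,                    # umol photons m^-2 s^-1
      k_att = 0.3797598021513      # um^-1, from calibrate_light()
    ),
    photosynthesis = list(
      p_max_v = 2.568157601449e-14, # mol C um^-3 d^-1, from calibrate_light()
      i_sat = 60                    # umol photons m^-2 s^-1
    ),
    quadrature = list(n_rho = 128, n_s = 128),
    sweep = list(v_min = 1, v_max = 1e8, n_points = 60),
    observations = list(n_per_group = 100, sigma_log10 = 0.2),
    transcripts = list(
      n_samples = 66,
      total_meanlog = log(1e5),
      total_sdlog = 0.6,
      base_proportions = list(
        ribosomal_protein = 0.04,
        actin = 0.012,
        tubulin = 0.012,
        other = 0.936
      ),
      ribosomal_uplift = 1.5,
      cytoskeleton_factor = 0.5
    )
  )
}

#' Load and validate a configuration file
#'
#' Reads a YAML (or JSON, a YAML subset) configuration, fills every missing
#' field from [default_config()], rejects unknown keys by name, and checks
#' the parameter invariants. An empty file yields the full default
#' configuration.
#'
#' @param path path to a YAML configuration file.
#' @return the validated, fully populated configuration list.
#' @seealso [default_config()], [dump_config()]
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    stop("config file not found: ", path, call. = FALSE)
  }
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  defaults <- default_config()
  check_unknown_keys(user, defaults)
  cfg <- modify_list_recursive(defaults, user)
  validate_config(cfg)
  cfg
}

#' Write a configuration to a YAML file
#'
#' @param config a configuration list, e.g. from [load_config()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
dump_config <- function(config, path) {
  yaml::write_yaml(config, path, precision = 12)
  invisible(path)
}

# recursive merge: values in `user` override `defaults`, element-wise for
# nested lists
modify_list_recursive <- function(defaults, user) {
  for (key in names(user)) {
    if (is.list(user[[key]]) && is.list(defaults[[key]])) {
      defaults[[key]] <- modify_list_recursive(defaults[[key]], user[[key]])
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

check_unknown_keys <- function(user, defaults, prefix = character()) {
  if (!is.list(user)) return(invisible(NULL))
  # taxa blocks may introduce new group names; fields inside are still checked
  open_level <- length(prefix) == 1 && identical(prefix, "taxa")
  for (key in names(user)) {
    path <- c(prefix, key)
    template <- if (open_level) defaults[["diatom"]] else defaults[[key]]
    if (is.null(template) && !open_level) {
      stop("unknown configuration key: ", paste(path, collapse = "."),
           call. = FALSE)
    }
    if (is.list(user[[key]])) {
      check_unknown_keys(user[[key]], template, path)
    }
  }
  invisible(NULL)
}

validate_config <- function(config) {
  stopifnot(is.list(config$taxa), length(config$taxa) >= 1)
  for (group in names(config$taxa)) {
    block <- config$taxa[[group]]
    p <- cell_parameters(
      group = group, a_c = block$a_c, b_c = block$b_c, e_mu = block$e_mu,
      e_si_per_si = block$e_si_per_si, r_sic = block$r_sic,
      e_ex = if (is.null(block$e_ex)) 0 else block$e_ex
    )
    invisible(p)
  }
  with(config$light, {
    if (i0 < 0) stop("light.i0 must be >= 0", call. = FALSE)
    if (k_att < 0) stop("light.k_att must be >= 0", call. = FALSE)
  })
  with(config$photosynthesis, {
    if (p_max_v <= 0) stop("photosynthesis.p_max_v must be > 0", call. = FALSE)
    if (i_sat <= 0) stop("photosynthesis.i_sat must be > 0", call. = FALSE)
  })
  with(config$sweep, {
    if (v_min <= 0 || v_max <= v_min) {
      stop("sweep volume range must satisfy 0 < v_min < v_max", call. = FALSE)
    }
    if (n_points < 1) stop("sweep.n_points must be >= 1", call. = FALSE)
  })
  invisible(config)
}

#' Hash a configuration
#'
#' Stable content hash of a configuration list, recorded in the metadata
#' header of every output table so a result can be traced to the exact
#' parameter set that produced it.
#'
#' @inheritParams dump_config
#' @return a character scalar.
#' @export
config_hash <- function(config) {
  rlang::hash(config)
}

#' Derive a module-specific sub-seed
#'
#' All stochastic pieces of a run are seeded from one integer; each module
#' derives its own stream deterministically from that master seed and a
#' label, so adding a generator to a pipeline never perturbs the draws of
#' another.
#'
#' @param seed master integer seed.
#' @param label character label of the consuming module.
#' @return an integer in `[0, 2^31)`.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(length(seed) == 1, is.finite(seed))
  chars <- utf8ToInt(label)
  offset <- sum(chars * seq_along(chars))
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + offset) %% 2147483647)
}

#' Write a result table with a reproducibility header
#'
#' Prepends commented metadata (package version, configuration hash, seed)
#' to a CSV/TSV so any output file is traceable to the run that made it.
#'
#' @param x a data frame.
#' @param path output path; a `.tsv` extension selects tab separation.
#' @param config optional configuration list to hash into the header.
#' @param seed optional seed to record.
#' @return `path`, invisibly.
#' @seealso [read_output_table()]
#' @export
write_output_table <- function(x, path, config = NULL, seed = NULL) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  header <- c(
    paste0("# package: diatomflux ", as.character(packageVersion("diatomflux"))),
    if (!is.null(config)) paste0("# config_hash: ", config_hash(config)),
    if (!is.null(seed)) paste0("# seed: ", format(seed))
  )
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(x, con, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a table written by [write_output_table()]
#'
#' @param path path to a CSV/TSV with `#`-prefixed metadata lines.
#' @return a tibble.
#' @export
read_output_table <- function(path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  tibble::as_tibble(
    utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                      stringsAsFactors = FALSE)
  )
}
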