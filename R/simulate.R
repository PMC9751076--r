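#' Simulation configuration for the synthetic grassland generator
#'
#' Parameters of the community-dynamics generator. Biomass of species i in
#' plot j (sown richness N) and year t (t = 0, 1, ...) is
#' \deqn{(m_{0i}/N) \, w_{ij} \, e^{-r(N) t} \, e^{u_t + v_{it} +
#'   \epsilon_{ijt}}}
#' where `m0_i` is the species' lognormal monoculture baseline (g/m2),
#' `r(N) = max(d0 - d1 log2 N, 0)` is the richness-dependent proportional
#' decline per year, `u_t` is a year effect common to all species and plots,
#' `v_it` is a species-specific year deviation shared across plots (a species
#' has one "good year" everywhere, which is what makes monoculture-based
#' relative yields meaningful), and `eps` is residual log-scale noise. In
#' mixtures `w_ij = exp(sel_link z_i)` (z_i the standardized log m0_i),
#' normalized to mean 1 within the plot's composition so that dominance is
#' redistributed among species without inflating the relative yield total:
#' `sel_link` is thereby a pure selection-effect control (it couples a
#' species' monoculture baseline to its mixture dominance while leaving the
#' expected complementarity effect at zero). With probability `dropout_prob`
#' a plot-species-year value is set to 0, exercising the monoculture-failure
#' exclusion path of the partitioning.
#'
#' @param n_years Number of annual harvest years.
#' @param start_year First calendar year ("year 1").
#' @param m0_log_mean,m0_log_sd Lognormal parameters of the monoculture
#'   baseline m0 (log g/m2 scale).
#' @param d0 Baseline proportional productivity decline per year.
#' @param d1 Decline reduction per log2(richness) unit (d1 > 0 makes
#'   diverse mixtures decline more slowly, generating a growing
#'   complementarity effect).
#' @param sigma_year SD of the common year effect u_t.
#' @param sigma_species_year SD of the species-specific year deviation v_it.
#' @param sigma_resid SD of residual log-scale noise.
#' @param sel_link Selection-effect control coupling baseline m0 to mixture
#'   dominance.
#' @param dropout_prob Yearly probability that a species yields 0 in a plot.
#' @param seed Optional default seed used by [simulate_experiment()].
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_years = 17L, start_year = 2003L,
                              m0_log_mean = log(400), m0_log_sd = 0.4,
                              d0 = 0.06, d1 = 0.015,
                              sigma_year = 0.2, sigma_species_year = 0.25,
                              sigma_resid = 0.15, sel_link = 0.2,
                              dropout_prob = 0.02, seed = NULL) {
  cfg <- list(n_years = as.integer(n_years), start_year = as.integer(start_year),
              m0_log_mean = m0_log_mean, m0_log_sd = m0_log_sd,
              d0 = d0, d1 = d1, sigma_year = sigma_year,
              sigma_species_year = sigma_species_year,
              sigma_resid = sigma_resid, sel_link = sel_link,
              dropout_prob = dropout_prob, seed = seed)
  if (cfg$n_years < 1L) stop("n_years must be >= 1")
  for (nm in c("m0_log_sd", "sigma_year", "sigma_species_year", "sigma_resid"))
    if (cfg[[nm]] < 0) stop(nm, " must be >= 0")
  if (cfg$dropout_prob < 0 || cfg$dropout_prob >= 1)
    stop("dropout_prob must be in [0, 1)")
  structure(cfg, class = "simulation_config")
}

#' Update fields of a simulation configuration
#'
#' @param cfg A `simulation_config`.
#' @param ... Named fields to replace; the result is re-validated.
#' @return A `simulation_config`.
#' @export
update_config <- function(cfg, ...) {
  stopifnot(inherits(cfg, "simulation_config"))
  new <- list(...)
  bad <- setdiff(names(new), names(unclass(cfg)))
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  args <- unclass(cfg)
  args[names(new)] <- new
  do.call(simulation_config, args)
}

#' Named scenario presets for the generator
#'
#' * `null`: no richness-dependent effects (d1 = 0, sel_link = 0) with a
#'   field-wide decline and interannual noise; biodiversity effects are zero
#'   within noise.
#' * `complementarity_growth`: richness-dependent decline (d1 > 0) so the
#'   relative yield total of mixtures grows over years.
#' * `asynchrony`: species-specific year deviations dominate, generating
#'   asynchronous population fluctuations.
#' * `selection`: dominance coupled to monoculture baseline (sel_link > 0)
#'   with no decline gradient; selection effects are positive on average
#'   while complementarity stays near zero.
#' * `jena_like`: all components active over 17 years (13 five-year rolling
#'   windows downstream).
#'
#' The magnitudes of the variance components are illustrative choices, not
#' field-calibrated values; see the methods vignette.
#'
#' @param name Optional preset name; if omitted the full named list is
#'   returned. An unknown name is an error listing the available presets.
#' @return A `simulation_config` or a named list of them.
#' @export
scenario_presets <- function(name = NULL) {
  presets <- list(
    null = simulation_config(d0 = 0.03, d1 = 0, sigma_year = 0.15,
                             sigma_species_year = 0.15, sigma_resid = 0.1,
                             sel_link = 0, dropout_prob = 0),
    complementarity_growth = simulation_config(d0 = 0.06, d1 = 0.015,
                                               sigma_year = 0.1,
                                               sigma_species_year = 0.1,
                                               sigma_resid = 0.1,
                                               sel_link = 0, dropout_prob = 0),
    asynchrony = simulation_config(d0 = 0, d1 = 0, sigma_year = 0.05,
                                   sigma_species_year = 0.4,
                                   sigma_resid = 0.1, sel_link = 0,
                                   dropout_prob = 0),
    selection = simulation_config(d0 = 0, d1 = 0, sigma_year = 0.1,
                                  sigma_species_year = 0.1, sigma_resid = 0.1,
                                  sel_link = 0.4, dropout_prob = 0),
    jena_like = simulation_config())
  if (is.null(name)) return(presets)
  if (!name %in% names(presets))
    stop("unknown preset '", name, "'; available: ",
         paste(names(presets), collapse = ", "))
  presets[[name]]
}

#' Simulate a species-level biomass time series for a design
#'
#' Generates the long-format biomass table the analysis pipeline consumes,
#' together with the realized ground truth (per-species baselines, year
#' effects, species-year deviations) for parameter-recovery tests.
#' Monoculture-reference plots use N = 1 and no dominance term. Strictly
#' reproducible given the seed.
#'
#' @param design A design from [build_design()].
#' @param cfg A [simulation_config()].
#' @param seed Integer seed (falls back to `cfg$seed`, then 1).
#' @return A list with elements `biomass` (data.frame `plot_id`, `year`,
#'   `species_id`, `biomass`), `truth` (list of `m0`, `year_effects`,
#'   `species_year`), and `config`.
#' @export
simulate_experiment <- function(design, cfg = simulation_config(),
                                seed = NULL) {
  stopifnot(inherits(cfg, "simulation_config"), is.data.frame(design))
  if (is.null(seed)) seed <- if (is.null(cfg$seed)) 1L else cfg$seed
  set.seed(seed)
  species <- sort(unique(unlist(design$composition)))
  S <- length(species)
  TY <- cfg$n_years
  m0 <- stats::rlnorm(S, cfg$m0_log_mean, cfg$m0_log_sd)
  names(m0) <- species
  z <- if (S > 1) as.numeric(scale(log(m0))) else 0
  names(z) <- species
  u <- stats::rnorm(TY, 0, cfg$sigma_year)
  v <- matrix(stats::rnorm(S * TY, 0, cfg$sigma_species_year), S, TY)
  rownames(v) <- species

  nsp <- lengths(design$composition)
  drow <- rep(seq_len(nrow(design)), nsp)     # design row per (plot, species)
  sp <- unlist(design$composition)
  # dominance weight per (plot, species), mean 1 within each composition
  w <- rep(1, length(sp))
  if (cfg$sel_link != 0) {
    for (i in which(nsp > 1 & !design$is_monoculture_reference)) {
      idx <- which(drow == i)
      e <- exp(cfg$sel_link * z[sp[idx]])
      w[idx] <- e / mean(e)
    }
  }
  np <- length(sp)
  row_d <- rep(drow, each = TY)
  row_sp <- rep(sp, each = TY)
  row_w <- rep(w, each = TY)
  t <- rep(0:(TY - 1L), times = np)
  N <- design$sown_richness[row_d]
  rate <- pmax(cfg$d0 - cfg$d1 * log2(N), 0)
  eps <- stats::rnorm(np * TY, 0, cfg$sigma_resid)
  biomass <- (m0[row_sp] / N) * row_w * exp(-rate * t) *
    exp(u[t + 1L] + v[cbind(match(row_sp, species), t + 1L)] + eps)
  if (cfg$dropout_prob > 0)
    biomass[stats::runif(np * TY) < cfg$dropout_prob] <- 0
  out <- data.frame(plot_id = design$plot_id[row_d],
                    year = cfg$start_year + t,
                    species_id = row_sp,
                    biomass = as.numeric(biomass),
                    stringsAsFactors = FALSE)
  out <- out[order(out$plot_id, out$year, out$species_id), ]
  rownames(out) <- NULL
  truth <- list(
    m0 = data.frame(species_id = species, m0 = as.numeric(m0),
                    z = as.numeric(z), stringsAsFactors = FALSE),
    year_effects = data.frame(year = cfg$start_year + 0:(TY - 1L),
                              u = u),
    species_year = data.frame(
      species_id = rep(species, times = TY),
      year = rep(cfg$start_year + 0:(TY - 1L), each = S),
      v = as.numeric(v)))
  list(biomass = out, truth = truth, config = cfg, seed = seed)
}
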