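# Shared fixtures: reduced pools/designs for fast Monte-Carlo loops, and
# hand-built toy designs/tables for oracle checks.

# First n species of each functional group (default 16-species pool).
small_pool <- function(n_per_fg = c(3L, 4L, 5L, 4L)) {
  p <- species_pool()
  idx <- unlist(lapply(seq_along(n_per_fg), function(k) {
    fg <- c("legume", "grass", "tall_herb", "small_herb")[k]
    which(p$functional_group == fg)[seq_len(n_per_fg[k])]
  }))
  p[idx, , drop = FALSE]
}

small_design <- function(seed = 1L, n_comp = 6L, levels = c(1L, 2L, 4L, 8L),
                         pool = small_pool()) {
  build_design(pool, levels, rep(n_comp, length(levels)), n_blocks = 4L,
               seed = seed)
}

# Simulate a preset with field overrides on a design.
quick_sim <- function(design, preset = "null", seed = 1L, ...) {
  cfg <- scenario_presets(preset)
  dots <- list(...)
  if (length(dots)) cfg <- do.call(update_config, c(list(cfg), dots))
  simulate_experiment(design, cfg, seed = seed)
}

# Hand-built design: monoculture-reference plots for every pool species plus
# explicitly given mixture compositions (a list of species-id vectors).
toy_design <- function(mixtures, pool_species,
                       extra_mono = character(0)) {
  n_mix <- length(mixtures)
  mono_sp <- c(pool_species, extra_mono)  # duplicates allowed: >1 mono plot
  rows_mix <- data.frame(
    plot_id = sprintf("mix%d", seq_len(n_mix)),
    block = 1L,
    sown_richness = lengths(mixtures),
    fg_richness = 1L,
    is_monoculture_reference = FALSE,
    stringsAsFactors = FALSE)
  rows_mono <- data.frame(
    plot_id = sprintf("M_%s_%d", mono_sp, seq_along(mono_sp)),
    block = 1L,
    sown_richness = 1L,
    fg_richness = 1L,
    is_monoculture_reference = TRUE,
    stringsAsFactors = FALSE)
  d <- rbind(rows_mix, rows_mono)
  d$composition <- I(c(mixtures, as.list(mono_sp)))
  d
}

# Long table from per-plot species series: series is a named list
# plot_id -> named list species -> numeric vector over `years`.
toy_table <- function(series, years) {
  rows <- list()
  for (pid in names(series)) {
    for (sp in names(series[[pid]])) {
      rows[[length(rows) + 1L]] <- data.frame(
        plot_id = pid, year = years, species_id = sp,
        biomass = series[[pid]][[sp]], stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# Independent brute-force evaluation of the additive-partition formulas,
# written as literally as possible (the oracle for partition tests).
oracle_partition <- function(O, M) {
  N <- length(O)
  RY <- O / M
  RYT <- sum(RY)
  CE <- (RYT - 1) * sum(M / N)
  SE <- (N - 1) * stats::cov(M, RY - 1 / N)
  NE <- sum(O) - sum(M / N)
  list(RYT = RYT, NE = NE, CE = CE, SE = SE)
}
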