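#' Per species-year monoculture yield index
#'
#' Builds the lookup M_i(year): the mean annual yield of each species over
#' its monoculture-reference plots. A plot-year with no recorded rows counts
#' as 0 (the species did not establish); entries with M_i = 0 are flagged
#' unusable and excluded from the partition for that year.
#'
#' @param table Long-format biomass table (see [read_biomass()]).
#' @param design Design identifying monoculture-reference plots.
#' @return A data.frame `species_id`, `year`, `M`, `n_plots`, `usable`.
#' @export
monoculture_index <- function(table, design) {
  mono <- design[design$is_monoculture_reference, , drop = FALSE]
  if (nrow(mono) == 0L) stop("design contains no monoculture-reference plots")
  mono_sp <- vapply(mono$composition, function(x) x[[1L]], "")
  need <- sort(unique(unlist(
    design$composition[!design$is_monoculture_reference])))
  missing <- setdiff(need, mono_sp)
  if (length(missing))
    stop("no monoculture-reference plot for species: ",
         paste(missing, collapse = ", "))
  years <- sort(unique(table$year))
  tb <- table[table$plot_id %in% mono$plot_id, , drop = FALSE]
  grid <- expand.grid(plot_id = mono$plot_id, year = years,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  if (nrow(tb)) {
    tot <- stats::aggregate(biomass ~ plot_id + year, data = tb, FUN = sum)
    grid <- merge(grid, tot, by = c("plot_id", "year"), all.x = TRUE)
  } else {
    grid$biomass <- NA_real_
  }
  grid$biomass[is.na(grid$biomass)] <- 0
  grid$species_id <- mono_sp[match(grid$plot_id, mono$plot_id)]
  m <- stats::aggregate(biomass ~ species_id + year, data = grid, FUN = mean)
  names(m)[names(m) == "biomass"] <- "M"
  np <- stats::aggregate(biomass ~ species_id + year, data = grid,
                         FUN = length)
  names(np)[names(np) == "biomass"] <- "n_plots"
  out <- merge(m, np, by = c("species_id", "year"))
  out$usable <- out$M > 0
  out <- out[order(out$species_id, out$year), ]
  rownames(out) <- NULL
  out
}

# Additive partition for one plot-year over the usable species set.
# With cov() in the sum-of-cross-products/(N-1) convention,
# NE = CE + SE holds as an algebraic identity.
partition_core <- function(O, M) {
  RY <- O / M
  RYT <- sum(RY)
  Mbar <- mean(M)
  CE <- (RYT - 1) * Mbar
  SE <- sum((M - Mbar) * (RY - mean(RY)))
  list(RYT = RYT, NE = sum(O) - Mbar, CE = CE, SE = SE, RY = RY)
}

#' Per-species relative yields
#'
#' RY_i = O_i / M_i for every species of every mixture plot-year with a
#' usable monoculture yield. Zero observed mixture biomass is kept
#' (RY_i = 0); only M_i = 0 makes a species unusable.
#'
#' @inheritParams monoculture_index
#' @param mono Output of [monoculture_index()].
#' @return A data.frame `plot_id`, `year`, `species_id`, `O`, `M`, `RY`,
#'   `usable`.
#' @export
species_relative_yields <- function(table, mono, design) {
  des <- design[!design$is_monoculture_reference & design$sown_richness >= 2L,
                , drop = FALSE]
  years <- sort(unique(table$year))
  nsp <- lengths(des$composition)
  drow <- rep(seq_len(nrow(des)), nsp)
  sp <- unlist(des$composition)
  long <- data.frame(
    plot_id = rep(des$plot_id[drow], each = length(years)),
    year = rep(years, times = length(sp)),
    species_id = rep(sp, each = length(years)),
    stringsAsFactors = FALSE)
  okey <- paste(table$plot_id, table$year, table$species_id)
  long$O <- table$biomass[match(paste(long$plot_id, long$year,
                                      long$species_id), okey)]
  long$O[is.na(long$O)] <- 0
  mkey <- paste(mono$species_id, mono$year)
  mi <- match(paste(long$species_id, long$year), mkey)
  long$M <- mono$M[mi]
  long$usable <- mono$usable[mi]
  long$usable[is.na(long$usable)] <- FALSE
  long$RY <- ifelse(long$usable, long$O / long$M, NA_real_)
  long
}

#' Annual additive partition of biodiversity effects
#'
#' For every non-reference plot and year: the plot's annual yield (ANPP), its
#' community relative yield (ANPP divided by the mean yield of all
#' monoculture plots that year), and for mixtures the relative yield total
#' (RYT), net (NE), complementarity (CE) and selection (SE) effects:
#' RY_i = O_i/M_i, CE = (RYT - 1) mean(M_i),
#' SE = (N - 1) cov(M_i, RY_i - 1/N), NE = sum(O_i) - mean(M_i), computed
#' over the N_used species with usable monoculture yields so that
#' NE = CE + SE holds identically. Plot-years with fewer than two usable
#' species carry NA effects and a reason code.
#'
#' @inheritParams species_relative_yields
#' @return A data.frame of class `AnnualEffects` columns: `plot_id`, `year`,
#'   `N_sown`, `N_used`, `ANPP`, `RY_community`, `RYT`, `NE`, `CE`, `SE`,
#'   `excluded_species`, `reason`.
#' @export
partition_annual <- function(table, mono, design) {
  des <- design[!design$is_monoculture_reference, , drop = FALSE]
  years <- sort(unique(table$year))
  okey <- paste(table$plot_id, table$year, table$species_id)
  oval <- stats::setNames(table$biomass, okey)
  mkey <- paste(mono$species_id, mono$year)
  mval <- stats::setNames(mono$M, mkey)
  muse <- stats::setNames(mono$usable, mkey)
  # mean yield of all monoculture plots per year (plot-weighted)
  mm <- vapply(split(mono, mono$year),
               function(d) sum(d$M * d$n_plots) / sum(d$n_plots), 0)

  n <- nrow(des) * length(years)
  plot_id <- character(n); year <- integer(n)
  N_sown <- integer(n); N_used <- rep(NA_integer_, n)
  ANPP <- numeric(n); RYc <- numeric(n)
  RYT <- rep(NA_real_, n); NE <- rep(NA_real_, n)
  CE <- rep(NA_real_, n); SE <- rep(NA_real_, n)
  excl <- character(n); reason <- character(n)
  k <- 0L
  for (i in seq_len(nrow(des))) {
    comp <- des$composition[[i]]
    pid <- des$plot_id[i]
    for (yr in years) {
      k <- k + 1L
      plot_id[k] <- pid
      year[k] <- yr
      N_sown[k] <- des$sown_richness[i]
      O <- oval[paste(pid, yr, comp)]
      O[is.na(O)] <- 0
      ANPP[k] <- sum(O)
      RYc[k] <- ANPP[k] / mm[[as.character(yr)]]
      if (des$sown_richness[i] < 2L) {
        reason[k] <- "sown richness < 2: partition undefined"
        next
      }
      key <- paste(comp, yr)
      us <- muse[key]
      us[is.na(us)] <- FALSE
      N_used[k] <- sum(us)
      if (any(!us)) excl[k] <- paste(comp[!us], collapse = ";")
      if (N_used[k] < 2L) {
        reason[k] <- "fewer than 2 species with usable monoculture yield"
        next
      }
      p <- partition_core(unname(O[us]), unname(mval[key][us]))
      RYT[k] <- p$RYT; NE[k] <- p$NE; CE[k] <- p$CE; SE[k] <- p$SE
    }
  }
  out <- data.frame(plot_id = plot_id, year = year, N_sown = N_sown,
                    N_used = N_used, ANPP = ANPP, RY_community = RYc,
                    RYT = RYT, NE = NE, CE = CE, SE = SE,
                    excluded_species = excl, reason = reason,
                    stringsAsFactors = FALSE)
  class(out) <- c("AnnualEffects", "data.frame")
  out
}

#' Quartile-fence outlier flags for CE and SE
#'
#' Flags complementarity/selection values outside
#' \[Q1 - m IQR, Q3 + m IQR\] (quartiles by linear interpolation, R type 7).
#' Flagged rows keep their values; downstream regressions exclude them. With
#' a degenerate IQR of 0 nothing is flagged, and `multiplier = Inf` flags
#' nothing.
#'
#' @param effects Output of [partition_annual()] or [partition_window()].
#' @param multiplier Positive fence multiplier (default 6).
#' @param by_year Compute fences within each year instead of pooled.
#' @return `effects` with logical columns `outlier_CE`, `outlier_SE`,
#'   `outlier_flag` added.
#' @export
flag_outliers <- function(effects, multiplier = 6, by_year = FALSE) {
  if (!is.numeric(multiplier) || length(multiplier) != 1L ||
      is.na(multiplier) || multiplier <= 0)
    stop("multiplier must be a single positive number")
  flag1 <- function(x) {
    f <- rep(FALSE, length(x))
    ok <- is.finite(x)
    if (sum(ok) >= 4L) {
      q <- stats::quantile(x[ok], c(0.25, 0.75), type = 7, names = FALSE)
      iqr <- q[2] - q[1]
      delta <- if (iqr > 0) multiplier * iqr else 0
      f[ok] <- x[ok] < q[1] - delta | x[ok] > q[2] + delta
    }
    f
  }
  grp <- if (by_year) effects$year else rep(1L, nrow(effects))
  apply_grp <- function(x) {
    f <- rep(FALSE, length(x))
    for (ix in split(seq_along(x), grp)) f[ix] <- flag1(x[ix])
    f
  }
  effects$outlier_CE <- apply_grp(effects$CE)
  effects$outlier_SE <- apply_grp(effects$SE)
  effects$outlier_flag <- effects$outlier_CE | effects$outlier_SE
  effects
}

#' Windowed additive partition
#'
#' Sums species biomass and monoculture yields over the window years first,
#' then applies the identical partition formulas; a species is excluded if
#' its summed monoculture yield over the window is 0. Under a temporal
#' portfolio effect (different species dominating in different years while
#' tracking their monoculture patterns), the windowed CE exceeds the mean of
#' the annual CEs: yearly selection effects scale up to an interannual
#' complementarity effect.
#'
#' @inheritParams species_relative_yields
#' @param start First year of the window.
#' @param width Window width in years; all window years must be present.
#' @return As [partition_annual()], with `year` set to the window start and
#'   columns `window_start`, `width` appended.
#' @export
partition_window <- function(table, mono, design, start, width) {
  yrs <- start:(start + width - 1L)
  have <- unique(table$year)
  if (!all(yrs %in% have))
    stop("window years missing from table: ",
         paste(setdiff(yrs, have), collapse = ", "))
  sub <- table[table$year %in% yrs, , drop = FALSE]
  summed <- stats::aggregate(biomass ~ plot_id + species_id, data = sub,
                             FUN = sum)
  summed$year <- as.integer(start)
  msub <- mono[mono$year %in% yrs, , drop = FALSE]
  msum <- stats::aggregate(M ~ species_id, data = msub, FUN = sum)
  nmean <- stats::aggregate(n_plots ~ species_id, data = msub, FUN = mean)
  msum <- merge(msum, nmean, by = "species_id")
  msum$year <- as.integer(start)
  msum$usable <- msum$M > 0
  out <- partition_annual(
    summed[, c("plot_id", "year", "species_id", "biomass")], msum, design)
  out$window_start <- as.integer(start)
  out$width <- as.integer(width)
  out
}
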