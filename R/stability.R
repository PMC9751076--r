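#' Enumerate rolling and non-overlapping windows
#'
#' All consecutive fixed-width windows over a span of years
#' (count = n_years - width + 1), plus the maximal set of `floor(n/width)`
#' non-overlapping windows spread evenly between the first and last year
#' (for 17 years and width 5 these are 2003-2007, 2009-2013, 2015-2019).
#'
#' @param years Integer vector of consecutive years (e.g. `2003:2019`).
#' @param width Window width in years, at least 2.
#' @return A list with data.frames `rolling` and `nonoverlapping`, each with
#'   columns `start` and `width`.
#' @export
enumerate_windows <- function(years, width) {
  years <- sort(unique(as.integer(years)))
  n <- length(years)
  if (n >= 2L && !all(diff(years) == 1L))
    stop("years must form a consecutive sequence")
  if (width < 2L) stop("window width must be >= 2 (variance undefined)")
  if (width > n) stop("window width exceeds the number of years")
  roll <- data.frame(start = years[seq_len(n - width + 1L)],
                     width = as.integer(width))
  k <- n %/% width
  starts <- if (k == 1L) years[1L] else
    years[1L] + as.integer(round((0:(k - 1L)) * (n - width) / (k - 1L)))
  list(rolling = roll,
       nonoverlapping = data.frame(start = as.integer(starts),
                                   width = as.integer(width)))
}

#' Temporal stability and synchrony metrics for one window
#'
#' Per plot, over the window's annual community yield series: temporal mean
#' `mu_net`, sample standard deviation `sd_net` (n-1), `cv_net = sd/mu`, and
#' `stability = mu/sd` (the inverse coefficient of variation). Synchrony is
#' `theta = sd_net / sum_i(sigma_i)` over the sown species' annual series
#' (zeros filled in for years a sown species was not recorded), asynchrony is
#' `1 - theta`, population variability is `cv_pop = sum_i(sigma_i)/mu_net`
#' with `pop_stability` its inverse. The identity `cv_net = theta * cv_pop`
#' holds by construction. Plots missing any window year are flagged with a
#' reason and NA metrics, as are plots with zero mean or with all-constant
#' species series (synchrony undefined).
#'
#' @param table Long-format biomass table.
#' @param design Experimental design (all plots, including monoculture
#'   references, receive a record).
#' @param start First year of the window.
#' @param width Window width in years.
#' @return A data.frame with one row per plot: `plot_id`, `sown_richness`,
#'   `is_monoculture_reference`, `window_start`, `width`, `mu_net`, `sd_net`,
#'   `cv_net`, `stability`, `sum_sigma`, `theta`, `asynchrony`, `cv_pop`,
#'   `pop_stability`, `anpp_sum`, `reason`.
#' @export
window_metrics <- function(table, design, start, width) {
  if (width < 2L) stop("window width must be >= 2 (variance undefined)")
  yrs <- start:(start + width - 1L)
  sub <- table[table$year %in% yrs, , drop = FALSE]
  bylot <- split(sub, sub$plot_id)
  n <- nrow(design)
  out <- data.frame(
    plot_id = design$plot_id,
    sown_richness = design$sown_richness,
    is_monoculture_reference = design$is_monoculture_reference,
    window_start = as.integer(start), width = as.integer(width),
    mu_net = NA_real_, sd_net = NA_real_, cv_net = NA_real_,
    stability = NA_real_, sum_sigma = NA_real_, theta = NA_real_,
    asynchrony = NA_real_, cv_pop = NA_real_, pop_stability = NA_real_,
    anpp_sum = NA_real_, reason = "", stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    d <- bylot[[design$plot_id[i]]]
    if (is.null(d) || !all(yrs %in% d$year)) {
      out$reason[i] <- "plot missing window year(s)"
      next
    }
    comp <- design$composition[[i]]
    mat <- matrix(0, length(comp), width,
                  dimnames = list(comp, as.character(yrs)))
    hit <- d$species_id %in% comp
    mat[cbind(match(d$species_id[hit], comp),
              match(d$year[hit], yrs))] <- d$biomass[hit]
    comm <- colSums(mat)
    mu <- mean(comm)
    sdn <- stats::sd(comm)
    sig <- apply(mat, 1L, stats::sd)
    ssum <- sum(sig)
    out$mu_net[i] <- mu
    out$sd_net[i] <- sdn
    out$anpp_sum[i] <- sum(comm)
    out$sum_sigma[i] <- ssum
    if (ssum > 0) {
      out$theta[i] <- sdn / ssum
      out$asynchrony[i] <- 1 - sdn / ssum
    } else {
      out$reason[i] <- "all species series constant: synchrony undefined"
    }
    if (mu > 0) {
      out$cv_net[i] <- sdn / mu
      out$cv_pop[i] <- ssum / mu
      out$stability[i] <- if (sdn > 0) mu / sdn else Inf
      out$pop_stability[i] <- if (ssum > 0) mu / ssum else NA_real_
    } else {
      out$reason[i] <- paste0(out$reason[i],
                              if (nzchar(out$reason[i])) "; ",
                              "zero mean yield: CV undefined")
    }
  }
  out
}

#' Stability metrics over all rolling windows
#'
#' @inheritParams window_metrics
#' @param width Window width in years.
#' @return Row-bound [window_metrics()] records for every rolling window.
#' @export
rolling_window_metrics <- function(table, design, width) {
  w <- enumerate_windows(sort(unique(table$year)), width)$rolling
  do.call(rbind, lapply(w$start, function(s)
    window_metrics(table, design, s, width)))
}

#' Stability metrics pooled over the full span of years
#'
#' @inheritParams window_metrics
#' @return A single [window_metrics()] record set with width equal to the
#'   number of years present.
#' @export
pooled_metrics <- function(table, design) {
  yrs <- sort(unique(table$year))
  window_metrics(table, design, yrs[1L], length(yrs))
}
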