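# Single OLS line with slope inference; returns NULL when x has fewer than
# three distinct values (per-time fits are skipped rather than forced).
ols_line <- function(y, x) {
  ok <- is.finite(y) & is.finite(x)
  y <- y[ok]; x <- x[ok]
  if (length(y) < 3L || length(unique(x)) < 3L) return(NULL)
  fit <- stats::lm(y ~ x)
  s <- suppressWarnings(summary(fit))  # exact fits are legitimate here
  cf <- s$coefficients
  list(b = cf[2L, 1L], intercept = cf[1L, 1L], se = cf[2L, 2L],
       p = cf[2L, 4L], r2 = s$r.squared, n = length(y))
}

#' Per-year richness-response power-law fits
#'
#' For every year, ordinary least-squares fits against log(sown richness):
#' `sqrt_ANPP` (square-root transformed yield, all gradient plots), `log_RY`
#' (log community relative yield), `NE`, `CE`, `SE` on the original scale
#' (mixtures, outlier-flagged records excluded when flag columns are
#' present), and `log_RYT`. Years with fewer than three distinct richness
#' values for a response are skipped and listed in the `skipped` attribute.
#'
#' @param effects Output of [partition_annual()], optionally passed through
#'   [flag_outliers()].
#' @param responses Subset of
#'   `c("sqrt_ANPP", "log_RY", "NE", "CE", "SE", "log_RYT")`.
#' @return A data.frame `response`, `year`, `b`, `intercept`, `se`, `p`,
#'   `r2`, `n`; slopes of log-log fits are the power exponents b.
#' @export
yearly_richness_fits <- function(effects,
                                 responses = c("sqrt_ANPP", "log_RY", "NE",
                                               "CE", "SE", "log_RYT")) {
  responses <- match.arg(responses, several.ok = TRUE)
  has_flags <- all(c("outlier_CE", "outlier_SE") %in% names(effects))
  all_ok <- function(d) rep(TRUE, nrow(d))
  pick <- function(d, resp) {
    switch(resp,
      sqrt_ANPP = list(y = sqrt(d$ANPP), keep = all_ok(d)),
      log_RY = list(y = log(d$RY_community), keep = d$RY_community > 0),
      NE = list(y = d$NE,
                keep = if (has_flags) !(d$outlier_CE | d$outlier_SE)
                       else all_ok(d)),
      CE = list(y = d$CE,
                keep = if (has_flags) !d$outlier_CE else all_ok(d)),
      SE = list(y = d$SE,
                keep = if (has_flags) !d$outlier_SE else all_ok(d)),
      log_RYT = list(y = log(d$RYT), keep = !is.na(d$RYT) & d$RYT > 0))
  }
  rows <- list()
  skipped <- list()
  for (yr in sort(unique(effects$year))) {
    d <- effects[effects$year == yr, , drop = FALSE]
    for (resp in responses) {
      v <- pick(d, resp)
      keep <- v$keep & !is.na(v$keep)
      f <- ols_line(v$y[keep], log(d$N_sown[keep]))
      if (is.null(f)) {
        skipped[[length(skipped) + 1L]] <- data.frame(
          response = resp, year = yr,
          reason = "fewer than 3 distinct richness values",
          stringsAsFactors = FALSE)
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        response = resp, year = yr, b = f$b, intercept = f$intercept,
        se = f$se, p = f$p, r2 = f$r2, n = f$n, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    stop("no year could be fitted (need >= 3 distinct richness values)")
  attr(out, "skipped") <- do.call(rbind, skipped)
  out
}

#' Richness-effect slopes relative to the yearly field-mean yield
#'
#' Biodiversity effects are measured on the absolute yield scale, which
#' drifts over years; dividing each year's richness-NE/CE/SE slope by that
#' year's grand-mean plot yield expresses the slopes on a comparable
#' relative scale.
#'
#' @param fits Output of [yearly_richness_fits()] containing NE/CE/SE rows.
#' @param table The biomass table the effects were computed from (used for
#'   the per-year grand mean over all plots).
#' @return The NE/CE/SE rows of `fits` with columns `grand_mean_ANPP` and
#'   `b_rel = b / grand_mean_ANPP` added. A zero grand mean gives NA with a
#'   warning.
#' @export
relative_effect_slopes <- function(fits, table) {
  out <- fits[fits$response %in% c("NE", "CE", "SE"), , drop = FALSE]
  if (nrow(out) == 0L) stop("fits contain no NE/CE/SE slopes")
  anpp <- stats::aggregate(biomass ~ plot_id + year, data = table, FUN = sum)
  gm <- stats::aggregate(biomass ~ year, data = anpp, FUN = mean)
  out$grand_mean_ANPP <- gm$biomass[match(out$year, gm$year)]
  zero <- !is.na(out$grand_mean_ANPP) & out$grand_mean_ANPP == 0
  if (any(zero)) {
    warning("zero grand-mean ANPP in year(s): ",
            paste(unique(out$year[zero]), collapse = ", "))
    out$grand_mean_ANPP[zero] <- NA_real_
  }
  out$b_rel <- out$b / out$grand_mean_ANPP
  rownames(out) <- NULL
  out
}

#' Trend of per-time slopes over time
#'
#' Regresses a slope series (per-year or per-window coefficients) on time to
#' test for a directional trend. With `time_transform = "log"` the time axis
#' is the log of the 1-based time index, matching trend fits of the form
#' slope ~ log(window).
#'
#' @param fits A data.frame with a value column (default `b`), a grouping
#'   column (`response` or `chain`, optional), and a time column (`year`,
#'   `window_start`, `window`, or `time`).
#' @param time_transform `"linear"` or `"log"`.
#' @param value_col Name of the value column.
#' @return A data.frame `response`, `trend`, `se`, `p`, `r2`, `n` (one row
#'   per group). Fewer than 3 time points is an error.
#' @export
slope_trend <- function(fits, time_transform = c("linear", "log"),
                        value_col = "b") {
  tt <- match.arg(time_transform)
  tcol <- intersect(c("year", "window_start", "window", "time"), names(fits))
  if (length(tcol) == 0L) stop("no time column found in fits")
  tcol <- tcol[1L]
  if (!value_col %in% names(fits)) stop("no '", value_col, "' column in fits")
  gcol <- intersect(c("response", "chain"), names(fits))
  g <- if (length(gcol)) fits[[gcol[1L]]] else rep("all", nrow(fits))
  sp <- split(fits, g)
  res <- lapply(names(sp), function(nm) {
    d <- sp[[nm]]
    if (nrow(d) < 3L) stop("need at least 3 time points per group")
    x <- d[[tcol]]
    if (tt == "log") x <- log(x - min(x) + 1)
    f <- ols_line(d[[value_col]], x)
    if (is.null(f)) stop("need at least 3 distinct time points per group")
    data.frame(response = nm, trend = f$b, se = f$se, p = f$p, r2 = f$r2,
               n = f$n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Productivity relative to the first year
#'
#' Divides each plot's annual yield by its first-year yield and fits, per
#' sown-richness level (monoculture-reference plots excluded), a linear
#' trend of the log ratio on years since the start: the per-level
#' proportional rate of productivity change. Plots without a positive
#' first-year yield are excluded with a message.
#'
#' @param table Long-format biomass table.
#' @param design Experimental design.
#' @return A list with `series` (per plot-year `ratio` and `log_ratio`) and
#'   `trends` (per richness level: `slope`, `se`, `p`, `n`).
#' @export
relative_to_year1 <- function(table, design) {
  anpp <- stats::aggregate(biomass ~ plot_id + year, data = table, FUN = sum)
  yr1 <- min(anpp$year)
  base <- anpp[anpp$year == yr1, ]
  b <- stats::setNames(base$biomass, base$plot_id)
  anpp$base <- b[anpp$plot_id]
  drop <- is.na(anpp$base) | anpp$base <= 0
  if (any(drop))
    message(length(unique(anpp$plot_id[drop])),
            " plot(s) without positive first-year yield excluded")
  ser <- anpp[!drop, , drop = FALSE]
  ser$ratio <- ser$biomass / ser$base
  ser$log_ratio <- ifelse(ser$ratio > 0, log(ser$ratio), NA_real_)
  di <- match(ser$plot_id, design$plot_id)
  ser$sown_richness <- design$sown_richness[di]
  ser$is_monoculture_reference <- design$is_monoculture_reference[di]
  mix <- ser[!ser$is_monoculture_reference & !is.na(ser$sown_richness), ,
             drop = FALSE]
  trends <- lapply(split(mix, mix$sown_richness), function(d) {
    x <- d$year - yr1
    ok <- is.finite(d$log_ratio)
    if (sum(ok) < 3L) return(NULL)
    fit <- summary(stats::lm(d$log_ratio[ok] ~ x[ok]))$coefficients
    data.frame(sown_richness = d$sown_richness[1L], slope = fit[2L, 1L],
               se = fit[2L, 2L], p = fit[2L, 4L], n = sum(ok))
  })
  trends <- do.call(rbind, Filter(Negate(is.null), trends))
  rownames(trends) <- NULL
  rownames(ser) <- NULL
  list(series = ser, trends = trends)
}

#' Decompose richness-stability slopes per window
#'
#' Per window, on the common set of plots where all quantities are positive
#' and finite (which excludes monocultures, whose asynchrony is 0), OLS
#' power-law slopes on log(sown richness) of: the temporal mean (`b_mean`),
#' temporal SD (`b_SD`), community stability (`b_cvnet_inv`), asynchrony
#' `log(1 - theta)` (`b_async`), inverse synchrony `log(1/theta)`
#' (`b_invtheta`), and population stability (`b_cvpop_inv`). Because least
#' squares is linear in the response on a shared regressor set, the exact
#' identities `b_cvnet_inv = b_mean - b_SD` and
#' `b_cvnet_inv = b_invtheta + b_cvpop_inv` hold; the asynchrony-based sum
#' `b_async + b_cvpop_inv` does not, and its gap is reported alongside.
#'
#' @param metrics Output of [window_metrics()] /
#'   [rolling_window_metrics()].
#' @return A data.frame with one row per window: the six slopes and
#'   `identity_gap_mean_sd`, `identity_gap_theta`, `identity_gap_async`, `n`.
#' @export
decompose_window_slopes <- function(metrics) {
  res <- lapply(split(metrics, metrics$window_start), function(d) {
    ok <- is.finite(d$mu_net) & d$mu_net > 0 &
      is.finite(d$sd_net) & d$sd_net > 0 &
      is.finite(d$theta) & d$theta > 0 & d$theta < 1
    d <- d[ok, , drop = FALSE]
    x <- log(d$sown_richness)
    if (nrow(d) < 3L || length(unique(x)) < 3L) return(NULL)
    b <- function(y) unname(stats::coef(stats::lm(y ~ x))[2L])
    b_mean <- b(log(d$mu_net))
    b_SD <- b(log(d$sd_net))
    b_cvnet_inv <- b(log(d$mu_net / d$sd_net))
    b_async <- b(log(1 - d$theta))
    b_invtheta <- b(log(1 / d$theta))
    b_cvpop_inv <- b(log(d$mu_net * d$theta / d$sd_net))
    data.frame(window_start = d$window_start[1L], width = d$width[1L],
               n = nrow(d), b_mean = b_mean, b_SD = b_SD,
               b_cvnet_inv = b_cvnet_inv, b_async = b_async,
               b_invtheta = b_invtheta, b_cvpop_inv = b_cvpop_inv,
               identity_gap_mean_sd = b_cvnet_inv - (b_mean - b_SD),
               identity_gap_theta = b_cvnet_inv - (b_invtheta + b_cvpop_inv),
               identity_gap_async = b_cvnet_inv - (b_async + b_cvpop_inv))
  })
  out <- do.call(rbind, Filter(Negate(is.null), res))
  if (is.null(out)) stop("no window had >= 3 usable distinct richness values")
  out <- out[order(out$window_start), ]
  rownames(out) <- NULL
  out
}
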