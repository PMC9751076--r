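# Kahn topological sort; NULL if the edge set contains a cycle.
topo_sort <- function(nodes, edges) {
  indeg <- stats::setNames(integer(length(nodes)), nodes)
  for (v in edges$to) indeg[v] <- indeg[v] + 1L
  queue <- nodes[indeg == 0L]
  order <- character(0)
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    order <- c(order, v)
    ch <- edges$to[edges$from == v]
    for (w in ch) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- c(queue, w)
    }
  }
  if (length(order) != length(nodes)) NULL else order
}

#' Recursive path-model specification
#'
#' The default structure links sown richness (SR, log scale) to the windowed
#' complementarity (CE) and selection (SE) effects and community yield
#' (ANPP); SR, CE, SE and ANPP drive population stability (CVpop_inv); SR,
#' CE and SE drive asynchrony (Async); and asynchrony and population
#' stability jointly determine community stability (CommStab) — no direct
#' SR to CommStab edge. CE-SE and Async-CVpop_inv residuals are free to
#' covary. Any acyclic edge set over named nodes may be supplied instead.
#'
#' @param edges data.frame with columns `from`, `to`; must be acyclic.
#' @param free_cov data.frame with columns `a`, `b`: residual covariances
#'   reported empirically.
#' @return An object of class `path_model_spec` with elements `nodes`,
#'   `edges`, `free_cov`, `order` (a topological order).
#' @export
path_model_spec <- function(edges = NULL, free_cov = NULL) {
  if (is.null(edges)) {
    edges <- data.frame(
      from = c("SR", "SR", "SR", "CE", "SE", "SR", "CE", "SE", "ANPP",
               "SR", "CE", "SE", "CVpop_inv", "Async"),
      to = c("CE", "SE", "ANPP", "ANPP", "ANPP", "CVpop_inv", "CVpop_inv",
             "CVpop_inv", "CVpop_inv", "Async", "Async", "Async",
             "CommStab", "CommStab"),
      stringsAsFactors = FALSE)
  }
  if (is.null(free_cov)) {
    free_cov <- data.frame(a = c("CE", "Async"), b = c("SE", "CVpop_inv"),
                           stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(edges), all(c("from", "to") %in% names(edges)))
  if (anyDuplicated(paste(edges$from, edges$to)))
    stop("duplicated edge in path model")
  nodes <- unique(c(edges$from, edges$to))
  order <- topo_sort(nodes, edges)
  if (is.null(order)) stop("path model contains a cycle")
  bad <- c(setdiff(free_cov$a, nodes), setdiff(free_cov$b, nodes))
  if (length(bad))
    stop("free covariance references undeclared node(s): ",
         paste(bad, collapse = ", "))
  structure(list(nodes = nodes, edges = edges, free_cov = free_cov,
                 order = order),
            class = "path_model_spec")
}

#' Min-max scale to (eps, 1]
#'
#' `(x - min)/(max - min)` clamped below at `eps` so a subsequent log is
#' defined at the minimum; monotone order is preserved.
#'
#' @param x Numeric vector with positive range.
#' @param eps Lower clamp, default 1e-3.
#' @return Scaled vector in `(eps, 1]` (the minimum maps to `eps`).
#' @export
minmax_scale <- function(x, eps = 1e-3) {
  r <- range(x, finite = TRUE)
  if (!is.finite(r[1L]) || r[2L] == r[1L])
    stop("min-max scaling needs a positive finite range")
  pmax((x - r[1L]) / (r[2L] - r[1L]), eps)
}

#' Transform and standardize path-analysis node data
#'
#' Applies the canonical transforms — log for SR (sown richness), ANPP,
#' CVpop_inv and CommStab; min-max scaling to (eps, 1] followed by log for
#' CE; SE and Async untransformed — drops rows with undefined values, and
#' standardizes every node to mean 0, SD 1.
#'
#' @param data data.frame with columns `SR`, `CE`, `SE`, `ANPP`,
#'   `CVpop_inv`, `Async`, `CommStab` on their raw scales (and optionally
#'   `obs_id` or `plot_id`, kept as row identifiers for group comparisons).
#' @param eps Lower clamp of the CE min-max scaling.
#' @param min_rows Minimum usable rows (default 10); fewer is an error.
#' @return Standardized data.frame with attributes `n_dropped` and
#'   `row_ids`.
#' @export
prepare_path_data <- function(data, eps = 1e-3, min_rows = 10L) {
  req <- c("SR", "CE", "SE", "ANPP", "CVpop_inv", "Async", "CommStab")
  miss <- setdiff(req, names(data))
  if (length(miss))
    stop("missing node column(s): ", paste(miss, collapse = ", "))
  pre <- data[stats::complete.cases(data[req]), , drop = FALSE]
  if (nrow(pre) == 0L) stop("fewer than ", min_rows, " usable rows")
  if (length(unique(pre$CE[is.finite(pre$CE)])) < 2L)
    stop("zero variance node: CE")
  x <- data.frame(
    SR = log(pre$SR),
    CE = log(minmax_scale(pre$CE, eps)),
    SE = pre$SE,
    ANPP = log(pre$ANPP),
    CVpop_inv = log(pre$CVpop_inv),
    Async = pre$Async,
    CommStab = log(pre$CommStab))
  ok <- rowSums(!is.finite(as.matrix(x))) == 0L
  x <- x[ok, , drop = FALSE]
  if (nrow(x) < min_rows) stop("fewer than ", min_rows, " usable rows")
  for (nm in names(x))
    if (stats::sd(x[[nm]]) == 0) stop("zero variance node: ", nm)
  out <- as.data.frame(scale(x))
  attr(out, "n_dropped") <- nrow(data) - nrow(x)
  idcol <- intersect(c("obs_id", "plot_id"), names(data))
  if (length(idcol)) attr(out, "row_ids") <- pre[[idcol[1L]]][ok]
  out
}

#' Windowed node table for path analysis
#'
#' Merges the stability metrics and the windowed additive partition for one
#' window into the raw node table the path model uses (mixture plots only),
#' after removing windowed CE/SE quartile-fence outliers.
#'
#' @inheritParams partition_window
#' @param outlier_multiplier Fence multiplier for [flag_outliers()] applied
#'   to the windowed CE/SE.
#' @return data.frame with columns `plot_id`, `SR`, `CE`, `SE`, `ANPP`,
#'   `CVpop_inv`, `Async`, `CommStab` (raw scales), ready for
#'   [prepare_path_data()].
#' @export
assemble_path_data <- function(table, mono, design, start, width,
                               outlier_multiplier = 6) {
  wm <- window_metrics(table, design, start, width)
  pw <- partition_window(table, mono, design, start, width)
  pw <- flag_outliers(pw, multiplier = outlier_multiplier)
  d <- merge(wm[, c("plot_id", "sown_richness", "anpp_sum", "pop_stability",
                    "asynchrony", "stability")],
             pw[, c("plot_id", "CE", "SE", "outlier_flag")],
             by = "plot_id")
  d <- d[d$sown_richness >= 2L & !d$outlier_flag, , drop = FALSE]
  data.frame(plot_id = d$plot_id,
             obs_id = paste0(d$plot_id, "@", start),
             SR = d$sown_richness, CE = d$CE,
             SE = d$SE, ANPP = d$anpp_sum, CVpop_inv = d$pop_stability,
             Async = d$asynchrony, CommStab = d$stability,
             stringsAsFactors = FALSE)
}

# Equation-wise estimates of the recursive system on a standardized table.
fit_equations <- function(X, spec) {
  endo <- unique(spec$edges$to)
  co <- numeric(nrow(spec$edges))
  r2 <- stats::setNames(numeric(length(endo)), endo)
  resid <- list()
  for (nd in endo) {
    pa <- spec$edges$from[spec$edges$to == nd]
    mm <- cbind(1, as.matrix(X[pa]))
    if (length(pa) > 1L && kappa(crossprod(mm)) > 1e8)
      stop("collinear parents for node ", nd, ": ",
           paste(pa, collapse = ", "))
    f <- stats::lm.fit(mm, X[[nd]])
    co[spec$edges$to == nd] <- f$coefficients[-1L]
    r2[nd] <- 1 - sum(f$residuals^2) /
      sum((X[[nd]] - mean(X[[nd]]))^2)
    resid[[nd]] <- f$residuals
  }
  list(co = co, r2 = r2, resid = resid)
}

#' Fit a recursive path model by equation-wise least squares
#'
#' Each endogenous node is regressed on its declared parents on standardized
#' data, giving standardized path coefficients (for this acyclic structure
#' with disturbance-level covariances the point estimates coincide with
#' maximum-likelihood SEM estimates). Inference is by nonparametric
#' bootstrap over rows: each replicate resamples rows with replacement,
#' re-standardizes, and refits; percentile confidence intervals and
#' two-sided sign-crossing p-values are reported. Residual correlations for
#' the declared free pairs are reported empirically.
#'
#' @param data Standardized node table from [prepare_path_data()] (any
#'   numeric table is standardized internally).
#' @param spec A [path_model_spec()].
#' @param n_boot Number of bootstrap replicates (>= 1000 recommended).
#' @param seed Integer seed; the bootstrap is exactly reproducible.
#' @return An object of class `path_fit`: `edges` (with `estimate`, `se`,
#'   `ci_lo`, `ci_hi`, `p`), `boot` (replicate x edge matrix), `r2`,
#'   `resid_cor`, `n`, `spec`, `row_ids`, `n_boot`, `seed`.
#' @export
fit_paths <- function(data, spec = path_model_spec(), n_boot = 1000L,
                      seed = 1L) {
  stopifnot(inherits(spec, "path_model_spec"))
  row_ids <- attr(data, "row_ids")
  data <- as.data.frame(data)
  miss <- setdiff(spec$nodes, names(data))
  if (length(miss))
    stop("data lacks node column(s): ", paste(miss, collapse = ", "))
  X <- as.data.frame(scale(data[spec$nodes]))
  n <- nrow(X)
  pt <- fit_equations(X, spec)
  set.seed(seed)
  B <- matrix(NA_real_, n_boot, nrow(spec$edges))
  for (bi in seq_len(n_boot)) {
    r <- NULL
    for (try in 1:100) {
      idx <- sample.int(n, n, replace = TRUE)
      D <- X[idx, , drop = FALSE]
      if (any(vapply(D, stats::sd, 0) == 0)) next
      r <- tryCatch(fit_equations(as.data.frame(scale(D)), spec)$co,
                    error = function(e) NULL)
      if (!is.null(r)) break
    }
    if (is.null(r)) stop("bootstrap failed to find a usable resample")
    B[bi, ] <- r
  }
  ci <- t(apply(B, 2L, stats::quantile, probs = c(0.025, 0.975)))
  p <- apply(B, 2L, function(v)
    max(min(1, 2 * min(mean(v <= 0), mean(v >= 0))), 2 / n_boot))
  edges <- cbind(spec$edges,
                 data.frame(estimate = pt$co, se = apply(B, 2L, stats::sd),
                            ci_lo = ci[, 1L], ci_hi = ci[, 2L], p = p))
  rc <- NULL
  if (nrow(spec$free_cov)) {
    rc <- spec$free_cov
    rc$cor <- NA_real_
    for (i in seq_len(nrow(rc))) {
      ra <- if (rc$a[i] %in% names(pt$resid)) pt$resid[[rc$a[i]]]
            else X[[rc$a[i]]]
      rb <- if (rc$b[i] %in% names(pt$resid)) pt$resid[[rc$b[i]]]
            else X[[rc$b[i]]]
      rc$cor[i] <- stats::cor(ra, rb)
    }
  }
  structure(list(edges = edges, boot = B, r2 = pt$r2, resid_cor = rc,
                 n = n, spec = spec, row_ids = row_ids,
                 n_boot = as.integer(n_boot), seed = seed),
            class = "path_fit")
}

#' @export
print.path_fit <- function(x, ...) {
  cat("Recursive path fit (equation-wise least squares), n =", x$n,
      ", bootstrap replicates =", x$n_boot, "\n")
  print(x$edges, digits = 3)
  invisible(x)
}

# All simple directed paths from `from` to `to` in the spec's DAG.
all_paths <- function(spec, from, to) {
  out <- list()
  walk <- function(node, path) {
    if (node == to) {
      out[[length(out) + 1L]] <<- path
      return(invisible())
    }
    for (nx in spec$edges$to[spec$edges$from == node])
      walk(nx, c(path, nx))
  }
  walk(from, from)
  out
}

chain_label <- function(ch) paste(ch, collapse = " -> ")

# Bootstrap product of a chain's edge coefficients.
chain_stats <- function(fit, ch) {
  ekey <- paste(fit$spec$edges$from, fit$spec$edges$to)
  ek <- paste(ch[-length(ch)], ch[-1L])
  ix <- match(ek, ekey)
  if (any(is.na(ix)))
    stop("chain uses undeclared edge: ", ek[which(is.na(ix))[1L]])
  est <- prod(fit$edges$estimate[ix])
  bv <- apply(fit$boot[, ix, drop = FALSE], 1L, prod)
  list(est = est, bv = bv)
}

#' Indirect effects along declared chains
#'
#' The indirect effect of a chain is the product of its standardized edge
#' coefficients; confidence intervals are propagated by recomputing the
#' product in every bootstrap replicate.
#'
#' @param fit A [fit_paths()] result.
#' @param chains Optional list of node-name vectors. By default all simple
#'   directed paths from `from` to `to` with at least one mediator.
#' @param from,to Endpoints for the default chain enumeration.
#' @return A data.frame `chain`, `estimate`, `ci_lo`, `ci_hi`, `p`.
#' @export
indirect_effects <- function(fit, chains = NULL, from = "SR",
                             to = "CommStab") {
  stopifnot(inherits(fit, "path_fit"))
  if (is.null(chains)) {
    chains <- Filter(function(ch) length(ch) >= 3L,
                     all_paths(fit$spec, from, to))
    if (length(chains) == 0L)
      stop("no mediated path from ", from, " to ", to)
  }
  rows <- lapply(chains, function(ch) {
    s <- chain_stats(fit, ch)
    data.frame(chain = chain_label(ch), estimate = s$est,
               ci_lo = unname(stats::quantile(s$bv, 0.025)),
               ci_hi = unname(stats::quantile(s$bv, 0.975)),
               p = max(min(1, 2 * min(mean(s$bv <= 0), mean(s$bv >= 0))),
                       2 / fit$n_boot),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Direct, indirect, and total effects on a target node
#'
#' The direct effect is the `from -> target` coefficient (0 if the edge is
#' absent), the indirect effect sums the products over every mediated path,
#' and total = direct + indirect, each with bootstrap intervals computed
#' replicate-wise.
#'
#' @param fit A [fit_paths()] result.
#' @param target Target node name.
#' @param from Source node (default SR).
#' @return A data.frame with rows `direct`, `indirect`, `total`.
#' @export
total_effects <- function(fit, target, from = "SR") {
  stopifnot(inherits(fit, "path_fit"))
  ekey <- paste(fit$spec$edges$from, fit$spec$edges$to)
  di <- match(paste(from, target), ekey)
  d_est <- if (is.na(di)) 0 else fit$edges$estimate[di]
  d_bv <- if (is.na(di)) rep(0, fit$n_boot) else fit$boot[, di]
  chains <- Filter(function(ch) length(ch) >= 3L,
                   all_paths(fit$spec, from, target))
  i_est <- 0
  i_bv <- rep(0, fit$n_boot)
  for (ch in chains) {
    s <- chain_stats(fit, ch)
    i_est <- i_est + s$est
    i_bv <- i_bv + s$bv
  }
  mk <- function(effect, est, bv) data.frame(
    effect = effect, estimate = est,
    ci_lo = unname(stats::quantile(bv, 0.025)),
    ci_hi = unname(stats::quantile(bv, 0.975)),
    p = max(min(1, 2 * min(mean(bv <= 0), mean(bv >= 0))), 2 / fit$n_boot),
    stringsAsFactors = FALSE)
  out <- rbind(mk("direct", d_est, d_bv),
               mk("indirect", i_est, i_bv),
               mk("total", d_est + i_est, d_bv + i_bv))
  out$target <- target
  out
}

# Letter display: groups share a letter iff not significantly different.
# Maximal cliques of the similarity graph by subset enumeration (small k).
assign_letters <- function(sim) {
  k <- nrow(sim)
  if (k > 15L) stop("letter display supports at most 15 groups")
  cliques <- list()
  for (s in seq_len(2^k - 1L)) {
    mem <- which(bitwAnd(s, 2^(seq_len(k) - 1L)) > 0L)
    ok <- all(sim[mem, mem])
    if (ok) cliques[[length(cliques) + 1L]] <- mem
  }
  sizes <- lengths(cliques)
  maximal <- Filter(function(cl) {
    !any(vapply(cliques, function(o)
      length(o) > length(cl) && all(cl %in% o), FALSE))
  }, cliques)
  maximal <- maximal[order(vapply(maximal, min, 0L))]
  lab <- rep("", k)
  for (i in seq_along(maximal))
    lab[maximal[[i]]] <- paste0(lab[maximal[[i]]], letters[i])
  lab
}

#' Compare path coefficients between independently fitted groups
#'
#' Pairwise differences in standardized edge coefficients between groups
#' fitted on disjoint observation sets (e.g. non-overlapping windows), with
#' bootstrap intervals from the difference of independent bootstrap draws
#' and unadjusted letter groupings at the chosen level (groups sharing a
#' letter do not differ significantly).
#'
#' @param fits Named list of [fit_paths()] results with identical edge sets
#'   and bootstrap sizes. If row identifiers are present, overlapping sets
#'   are an error (the independence assumption would be violated).
#' @param alpha Significance level for the letter display.
#' @return A list with `differences` (edge, pair, diff, ci, p) and
#'   `letters` (edge x group letter table).
#' @export
compare_groups <- function(fits, alpha = 0.05) {
  stopifnot(is.list(fits), length(fits) >= 2L)
  if (is.null(names(fits)) || any(!nzchar(names(fits))))
    names(fits) <- paste0("group", seq_along(fits))
  for (f in fits) stopifnot(inherits(f, "path_fit"))
  ekey <- paste(fits[[1L]]$spec$edges$from, fits[[1L]]$spec$edges$to)
  for (f in fits[-1L]) {
    if (!identical(paste(f$spec$edges$from, f$spec$edges$to), ekey))
      stop("groups were fitted with different edge sets")
    if (f$n_boot != fits[[1L]]$n_boot)
      stop("groups were fitted with different bootstrap sizes")
  }
  ids <- lapply(fits, function(f) f$row_ids)
  if (all(!vapply(ids, is.null, FALSE))) {
    cmb <- utils::combn(length(fits), 2L)
    for (j in seq_len(ncol(cmb))) {
      if (length(intersect(ids[[cmb[1L, j]]], ids[[cmb[2L, j]]])))
        stop("groups share observations; independent groups required")
    }
  }
  pairs <- utils::combn(names(fits), 2L)
  diffs <- list()
  pmat <- array(NA_real_, c(length(ekey), length(fits), length(fits)))
  for (j in seq_len(ncol(pairs))) {
    g1 <- pairs[1L, j]; g2 <- pairs[2L, j]
    i1 <- match(g1, names(fits)); i2 <- match(g2, names(fits))
    for (e in seq_along(ekey)) {
      dv <- fits[[g1]]$boot[, e] - fits[[g2]]$boot[, e]
      dd <- fits[[g1]]$edges$estimate[e] - fits[[g2]]$edges$estimate[e]
      p <- max(min(1, 2 * min(mean(dv <= 0), mean(dv >= 0))),
               2 / fits[[g1]]$n_boot)
      diffs[[length(diffs) + 1L]] <- data.frame(
        edge = ekey[e], group1 = g1, group2 = g2, diff = dd,
        ci_lo = unname(stats::quantile(dv, 0.025)),
        ci_hi = unname(stats::quantile(dv, 0.975)), p = p,
        stringsAsFactors = FALSE)
      pmat[e, i1, i2] <- pmat[e, i2, i1] <- p
    }
  }
  lets <- lapply(seq_along(ekey), function(e) {
    sim <- pmat[e, , ] >= alpha
    diag(sim) <- TRUE
    stats::setNames(assign_letters(sim), names(fits))
  })
  letters_df <- do.call(rbind, lapply(seq_along(ekey), function(e)
    data.frame(edge = ekey[e], group = names(fits),
               letters = unname(lets[[e]]), stringsAsFactors = FALSE)))
  list(differences = do.call(rbind, diffs), letters = letters_df)
}

#' Temporal trends of indirect effects across windows
#'
#' Regresses each chain's indirect effect on the window index (or its log)
#' to detect strengthening or weakening mediation over time.
#'
#' @param chain_table Row-bound [indirect_effects()] results with a window
#'   column (`window`, `window_start`, or `time`) added.
#' @param time_transform `"linear"` or `"log"`.
#' @return A data.frame with one trend fit per chain (see [slope_trend()]).
#' @export
indirect_trends <- function(chain_table, time_transform = c("linear", "log")) {
  slope_trend(chain_table, time_transform = time_transform,
              value_col = "estimate")
}
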