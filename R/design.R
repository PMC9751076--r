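#' Default 60-species grassland pool
#'
#' The species pool used by the default experimental design: 60 species in
#' four functional groups (12 legumes, 16 grasses, 20 tall herbs, 12 small
#' herbs).
#'
#' @return A data.frame with columns `species_id` and `functional_group`.
#' @export
#' @examples
#' table(species_pool()$functional_group)
species_pool <- function() {
  fg <- rep(c("legume", "grass", "tall_herb", "small_herb"),
            times = c(12L, 16L, 20L, 12L))
  data.frame(species_id = sprintf("sp%02d", seq_along(fg)),
             functional_group = fg,
             stringsAsFactors = FALSE)
}

#' Build a randomized sown-diversity design
#'
#' Draws distinct random species compositions for each sown-richness level,
#' spreads the plots evenly across blocks, and appends one
#' monoculture-reference plot per pool species (the source of the per-species
#' monoculture yields `M_i`). Compositions are re-drawn internally until all
#' are distinct, so duplicates are never emitted.
#'
#' @param pool Species pool (data.frame with `species_id`, `functional_group`).
#' @param richness_levels Integer vector of sown richness levels.
#' @param n_compositions Number of distinct compositions per level (same
#'   length as `richness_levels`).
#' @param n_blocks Number of blocks plots are spread across.
#' @param seed Integer seed; the design is deterministic given the seed.
#' @return A data.frame with one row per plot: `plot_id`, `block`,
#'   `sown_richness`, `fg_richness`, `is_monoculture_reference`, and a list
#'   column `composition` of species ids.
#' @export
build_design <- function(pool = species_pool(),
                         richness_levels = c(1L, 2L, 4L, 8L, 16L),
                         n_compositions = c(16L, 16L, 16L, 16L, 14L),
                         n_blocks = 4L,
                         seed = 1L) {
  stopifnot(is.data.frame(pool),
            all(c("species_id", "functional_group") %in% names(pool)),
            length(richness_levels) == length(n_compositions),
            n_blocks >= 1L)
  if (anyDuplicated(pool$species_id))
    stop("duplicated species_id in pool")
  if (any(richness_levels > nrow(pool)))
    stop("richness level exceeds pool size")
  if (any(richness_levels == 1L & n_compositions > nrow(pool)))
    stop("more single-species compositions requested than pool species")
  set.seed(seed)
  rows <- list()
  for (k in seq_along(richness_levels)) {
    r <- richness_levels[k]
    m <- n_compositions[k]
    keys <- character(0)
    comps <- vector("list", m)
    drawn <- 0L
    tries <- 0L
    while (drawn < m) {
      tries <- tries + 1L
      if (tries > 1000L * m)
        stop("unable to draw ", m, " distinct compositions at richness ", r)
      s <- sort(sample(pool$species_id, r))
      key <- paste(s, collapse = "|")
      if (!key %in% keys) {
        keys <- c(keys, key)
        drawn <- drawn + 1L
        comps[[drawn]] <- s
      }
    }
    for (j in seq_len(m)) {
      rows[[length(rows) + 1L]] <- list(
        plot_id = sprintf("N%02d_%02d", r, j),
        block = ((j - 1L) %% n_blocks) + 1L,
        sown_richness = as.integer(r),
        composition = comps[[j]],
        is_monoculture_reference = FALSE)
    }
  }
  for (i in seq_len(nrow(pool))) {
    rows[[length(rows) + 1L]] <- list(
      plot_id = paste0("M_", pool$species_id[i]),
      block = ((i - 1L) %% n_blocks) + 1L,
      sown_richness = 1L,
      composition = pool$species_id[i],
      is_monoculture_reference = TRUE)
  }
  fg <- stats::setNames(pool$functional_group, pool$species_id)
  design <- data.frame(
    plot_id = vapply(rows, function(x) x$plot_id, ""),
    block = vapply(rows, function(x) x$block, 0L),
    sown_richness = vapply(rows, function(x) x$sown_richness, 0L),
    fg_richness = vapply(rows, function(x)
      length(unique(fg[x$composition])), 0L),
    is_monoculture_reference =
      vapply(rows, function(x) x$is_monoculture_reference, FALSE),
    stringsAsFactors = FALSE)
  design$composition <- I(lapply(rows, function(x) x$composition))
  design
}

#' Default experimental design
#'
#' The canonical sown-diversity gradient: richness levels 1, 2, 4, 8, 16 with
#' 16 distinct compositions per level except 14 at richness 16 (single
#' functional-group mixtures of legumes or small herbs cannot be assembled at
#' that level from the default pool), spread across 4 blocks, plus one
#' monoculture-reference plot for each of the 60 pool species.
#'
#' @param seed Integer seed.
#' @return See [build_design()].
#' @export
build_default_design <- function(seed = 1L) {
  build_design(seed = seed)
}
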