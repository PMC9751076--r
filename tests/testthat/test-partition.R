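test_that("monoculture index averages plots and flags failures", {
  d <- toy_design(list(c("spA", "spB")), c("spA", "spB"),
                  extra_mono = "spA")  # two monoculture plots for spA
  tb <- toy_table(list(
    M_spA_1 = list(spA = c(100, 0)),
    M_spA_3 = list(spA = c(60, 0)),
    M_spB_2 = list(spB = c(50, 40)),
    mix1 = list(spA = c(30, 20), spB = c(20, 25))), years = 2003:2004)
  mono <- monoculture_index(tb, d)
  expect_equal(mono$M[mono$species_id == "spA" & mono$year == 2003], 80)
  expect_equal(mono$n_plots[mono$species_id == "spA"][1], 2)
  expect_false(mono$usable[mono$species_id == "spA" & mono$year == 2004])
  expect_equal(mono$M[mono$species_id == "spB" & mono$year == 2003], 50)
  # single-plot species: M equals that plot's value
  expect_true(mono$usable[mono$species_id == "spB" & mono$year == 2004])
  # missing monoculture is a hard error naming the species
  d2 <- toy_design(list(c("spA", "spC")), c("spA"))
  expect_error(monoculture_index(tb, d2), "spC")
})

test_that("two-species partitions match brute-force formula evaluation", {
  cases <- list(
    list(M = c(100, 50), O = c(60, 20),
         RYT = 1.0, NE = 5, CE = 0, SE = 5),
    list(M = c(100, 100), O = c(80, 80),
         RYT = 1.6, NE = 60, CE = 60, SE = 0),
    list(M = c(100, 50), O = c(50, 25),   # exact null: O_i = M_i / N
         RYT = 1.0, NE = 0, CE = 0, SE = 0))
  for (cs in cases) {
    d <- toy_design(list(c("spA", "spB")), c("spA", "spB"))
    tb <- toy_table(list(
      M_spA_1 = list(spA = rep(cs$M[1], 2)),
      M_spB_2 = list(spB = rep(cs$M[2], 2)),
      mix1 = list(spA = rep(cs$O[1], 2), spB = rep(cs$O[2], 2))),
      years = 2003:2004)
    eff <- partition_annual(tb, monoculture_index(tb, d), d)
    row <- eff[eff$plot_id == "mix1" & eff$year == 2003, ]
    expect_equal(row$RYT, cs$RYT)
    expect_equal(row$NE, cs$NE)
    expect_equal(row$CE, cs$CE)
    expect_equal(row$SE, cs$SE)
    orc <- oracle_partition(cs$O, cs$M)
    expect_equal(row$NE, orc$NE)
    expect_equal(row$CE, orc$CE)
    expect_equal(row$SE, orc$SE)
    # NE also equals sum(O) - sum(M)/N directly
    expect_equal(row$NE, sum(cs$O) - sum(cs$M) / 2)
  }
})

test_that("species without usable monoculture are excluded with reasons", {
  d <- toy_design(list(c("spA", "spB", "spC")), c("spA", "spB", "spC"))
  tb <- toy_table(list(
    M_spA_1 = list(spA = c(100, 100)),
    M_spB_2 = list(spB = c(50, 0)),     # fails in year 2
    M_spC_3 = list(spC = c(0, 0)),      # never establishes
    mix1 = list(spA = c(40, 40), spB = c(20, 20), spC = c(10, 10))),
    years = 2003:2004)
  eff <- partition_annual(tb, monoculture_index(tb, d), d)
  y1 <- eff[eff$year == 2003, ]
  expect_equal(y1$N_used, 2L)
  expect_equal(y1$excluded_species, "spC")
  expect_equal(y1$ANPP, 70)  # excluded species still counts toward yield
  orc <- oracle_partition(c(40, 20), c(100, 50))
  expect_equal(y1$NE, orc$NE)
  expect_equal(y1$CE, orc$CE)
  y2 <- eff[eff$year == 2004, ]
  expect_equal(y2$N_used, 1L)
  expect_true(is.na(y2$CE))
  expect_match(y2$reason, "fewer than 2")
})

test_that("quartile-fence outlier flags match the stated rule", {
  eff <- data.frame(year = rep(2003, 5), CE = c(1, 2, 3, 4, 100),
                    SE = c(0, 0, 0, 0, 0))
  fl <- flag_outliers(eff, multiplier = 6)
  # brute-force fences with linear-interpolation quartiles
  q <- quantile(eff$CE, c(.25, .75), type = 7)
  expect_equal(unname(q), c(2, 4))
  expect_equal(fl$outlier_CE, eff$CE > q[2] + 6 * (q[2] - q[1]) |
                 eff$CE < q[1] - 6 * (q[2] - q[1]))
  expect_equal(which(fl$outlier_CE), 5L)
  expect_false(any(fl$outlier_SE))  # IQR 0: equality band flags nothing
  expect_false(any(flag_outliers(eff, multiplier = Inf)$outlier_CE))
  expect_error(flag_outliers(eff, multiplier = 0), "positive")
  expect_error(flag_outliers(eff, multiplier = -2), "positive")
  # per-year fences differ from pooled when years differ in scale
  eff2 <- data.frame(year = rep(c(2003, 2004), each = 5),
                     CE = c(1, 2, 3, 4, 100, 1000, 2000, 3000, 4000, 3100),
                     SE = 0)
  expect_equal(which(flag_outliers(eff2, by_year = TRUE)$outlier_CE), 5L)
})

test_that("windowed partition scales linearly for constant biomass", {
  d <- toy_design(list(c("spA", "spB")), c("spA", "spB"))
  tb <- toy_table(list(
    M_spA_1 = list(spA = rep(100, 5)),
    M_spB_2 = list(spB = rep(50, 5)),
    mix1 = list(spA = rep(60, 5), spB = rep(20, 5))), years = 2003:2007)
  mono <- monoculture_index(tb, d)
  ann <- partition_annual(tb, mono, d)
  win <- partition_window(tb, mono, d, 2003, 5)
  a <- ann[ann$plot_id == "mix1" & ann$year == 2003, ]
  w <- win[win$plot_id == "mix1", ]
  expect_equal(w$NE, 5 * a$NE)
  expect_equal(w$CE, 5 * a$CE)
  expect_equal(w$SE, 5 * a$SE)
  expect_equal(w$RYT, a$RYT)  # relative quantities are scale-free
})

test_that("alternating dominance scales annual SE up to interannual CE", {
  MA <- c(100, 10, 100, 10); MB <- c(10, 100, 10, 100)
  OA <- c(90, 5, 90, 5); OB <- c(5, 90, 5, 90)
  d <- toy_design(list(c("spA", "spB")), c("spA", "spB"))
  tb <- toy_table(list(M_spA_1 = list(spA = MA), M_spB_2 = list(spB = MB),
                       mix1 = list(spA = OA, spB = OB)), years = 2003:2006)
  mono <- monoculture_index(tb, d)
  ann <- partition_annual(tb, mono, d)
  win <- partition_window(tb, mono, d, 2003, 4)
  # oracle: evaluate the formulas directly on annual and summed biomass
  ann_or <- vapply(1:4, function(t)
    oracle_partition(c(OA[t], OB[t]), c(MA[t], MB[t]))$CE, 0)
  win_or <- oracle_partition(c(sum(OA), sum(OB)), c(sum(MA), sum(MB)))
  expect_equal(ann$CE[ann$plot_id == "mix1"], ann_or)
  expect_equal(win$CE[win$plot_id == "mix1"], win_or$CE)
  expect_gt(win_or$CE, mean(ann_or))
  # the annual effects here are pure selection; the windowed CE dominates
  expect_equal(win$SE[win$plot_id == "mix1"], 0)
  expect_gt(mean(ann$SE[ann$plot_id == "mix1"]), 0)
})

test_that("partition is order-invariant and scales with biomass units", {
  d <- small_design(seed = 8, n_comp = 3L, levels = c(2L, 4L))
  sim <- quick_sim(d, "jena_like", seed = 11, n_years = 3)
  tb <- sim$biomass
  mono <- monoculture_index(tb, d)
  eff <- partition_annual(tb, mono, d)
  # shuffle row order
  tb2 <- tb[sample(nrow(tb)), ]
  eff2 <- partition_annual(tb2, monoculture_index(tb2, d), d)
  expect_equal(eff2$CE, eff$CE)
  expect_equal(eff2$SE, eff$SE)
  # rescaling biomass by c scales NE/CE/SE by c, leaves RY/RYT unchanged
  tb3 <- tb; tb3$biomass <- tb3$biomass * 3.7
  eff3 <- partition_annual(tb3, monoculture_index(tb3, d), d)
  expect_equal(eff3$NE, 3.7 * eff$NE, tolerance = 1e-12)
  expect_equal(eff3$CE, 3.7 * eff$CE, tolerance = 1e-12)
  expect_equal(eff3$SE, 3.7 * eff$SE, tolerance = 1e-12)
  expect_equal(eff3$RYT, eff$RYT, tolerance = 1e-12)
  expect_equal(eff3$RY_community, eff$RY_community, tolerance = 1e-12)
})

test_that("NE = CE + SE holds identically, including windowed records", {
  d <- small_design(seed = 9)
  sim <- quick_sim(d, "jena_like", seed = 13, n_years = 6)
  mono <- monoculture_index(sim$biomass, d)
  eff <- partition_annual(sim$biomass, mono, d)
  ok <- !is.na(eff$NE)
  expect_gt(sum(ok), 50)
  expect_lt(max(abs(eff$NE[ok] - eff$CE[ok] - eff$SE[ok])), 1e-9)
  win <- partition_window(sim$biomass, mono, d, 2003, 5)
  okw <- !is.na(win$NE)
  expect_lt(max(abs(win$NE[okw] - win$CE[okw] - win$SE[okw])), 1e-9)
  expect_true(all(win$RYT[okw] >= 0))
  expect_true(all(eff$N_used[ok] <= eff$N_sown[ok]))
})

test_that("windowed CE tracks the mean annual CE over the same window", {
  d <- small_design(seed = 10)
  sim <- quick_sim(d, "jena_like", seed = 17, n_years = 7)
  mono <- monoculture_index(sim$biomass, d)
  eff <- partition_annual(sim$biomass, mono, d)
  win <- partition_window(sim$biomass, mono, d, 2003, 5)
  ann <- aggregate(CE ~ plot_id, eff[eff$year %in% 2003:2007, ], mean)
  m <- merge(win[, c("plot_id", "CE")], ann, by = "plot_id")
  rho <- cor(m$CE.x, m$CE.y, method = "spearman", use = "complete.obs")
  expect_gt(rho, 0)
})
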