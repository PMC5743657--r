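test_that("sequential SS match a hand-computed one-way ANOVA", {
  ds <- oneway_dataset(c(1, 2, 3, 4, 5, 6), rep(c("g1", "g2"), each = 3))
  tab <- fit_anova(ds, "sla", list(group = "individual"))
  expect_equal(tab$SS[1], 13.5)
  expect_equal(tab$SS[2], 4)
  expect_equal(tab$df, c(1L, 4L))
  expect_equal(tab$MS, c(13.5, 1))
  expect_equal(tab$pseudo_F[1], 13.5)
  expect_equal(tab$variance_pct, c(13.5, 4) / 17.5 * 100)
})

test_that("a constant response yields zero SS and undefined pseudo-F", {
  ds <- oneway_dataset(rep(5, 8), rep(c("g1", "g2"), each = 4))
  tab <- fit_anova(ds, "sla", list(group = "individual"))
  expect_equal(tab$SS, c(0, 0), tolerance = 1e-12)
  expect_true(is.na(tab$pseudo_F[1]))
  tab <- permutation_pvalues(tab, n_perm = 19, seed = 1)
  expect_equal(tab$p_perm[1], 1)
})

test_that("permutation p-values match full enumeration on a 2x2 layout", {
  y <- c(1.3, 2.9, 7.1, 8.4)
  grp <- c("g1", "g1", "g2", "g2")
  ds <- oneway_dataset(y, grp)
  tab <- fit_anova(ds, "sla", list(group = "individual"))

  # brute-force oracle over all 4! = 24 relabelings
  perms <- as.matrix(expand.grid(a = 1:4, b = 1:4, c = 1:4, d = 1:4))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 4L), ]
  f_all <- apply(perms, 1, function(p) oneway_oracle(y[p], grp)$f)
  f_obs <- oneway_oracle(y, grp)$f
  p_enum <- mean(f_all >= f_obs)

  identity_row <- which(apply(perms, 1, function(p) all(p == 1:4)))
  tab <- permutation_pvalues(tab, permutations = perms[-identity_row, ])
  expect_equal(tab$p_perm[1], p_enum)
})

test_that("sequential SS over all terms plus residual add up to the total", {
  ds <- study_dataset(seed = 21)
  for (tr in c("sla", "pi")) {
    tab <- fit_anova(ds, tr)
    expect_equal(sum(tab$SS), attr(tab, "ss_total"),
                 tolerance = 1e-8)
    expect_equal(sum(tab$variance_pct), 100, tolerance = 1e-6)
    expect_equal(tab$MS, tab$SS / tab$df)
    expect_equal(tab$df[nrow(tab)], 408L - 136L)
  }
})

test_that("sequential and partial SS agree on balanced designs and match aov", {
  # balanced: equal individuals per quadrat
  cfg <- small_config(seed = 31, variance_fractions = list(
    sla = c(quadrat = 0.1, individual = 0.2, h_class = 0.2, position = 0.1,
            `h_class:position` = 0.05, `quadrat:position` = 0.05,
            residual = 0.3)))
  ds <- generate_dataset(cfg)
  seq_tab <- fit_anova(ds, "sla")
  par_tab <- fit_anova(ds, "sla", ss_type = "partial")
  expect_equal(seq_tab$SS, par_tab$SS, tolerance = 1e-8)
  expect_equal(seq_tab$df, par_tab$df)

  d <- as.data.frame(ds)
  d$ind <- interaction(d$quadrat, d$individual, drop = TRUE)
  classical <- anova(stats::lm(
    sla ~ quadrat * h_class * position + quadrat:ind +
      quadrat:ind:h_class + quadrat:ind:position + quadrat:ind:h_class:position,
    data = d))
  expect_equal(sum(seq_tab$SS), sum(classical$`Sum Sq`), tolerance = 1e-8)
  expect_equal(seq_tab$SS[seq_tab$term == "h_class"],
               classical["h_class", "Sum Sq"], tolerance = 1e-8)
  expect_equal(seq_tab$pseudo_F[seq_tab$term == "h_class"],
               classical["h_class", "Mean Sq"] / classical["Residuals", "Mean Sq"],
               tolerance = 1e-8)
})

test_that("sequential SS and pseudo-F agree with an independent PERMANOVA oracle", {
  skip_if_not_installed("vegan")
  ds <- generate_dataset(small_config(seed = 41, variance_fractions = list(
    sla = c(quadrat = 0.15, individual = 0.2, h_class = 0.25, position = 0,
            `h_class:position` = 0, `quadrat:position` = 0, residual = 0.4))))
  d <- as.data.frame(ds)
  d$ind <- interaction(d$quadrat, d$individual, drop = TRUE)
  tab <- fit_anova(ds, "sla", default_model_terms(include_interactions = FALSE))
  ref <- vegan::adonis2(dist(d$sla) ~ quadrat + h_class + position + quadrat:ind,
                        data = d, by = "terms", permutations = 2)
  expect_equal(tab$SS, ref$SumOfSqs[seq_len(nrow(tab))], tolerance = 1e-8)
  expect_equal(tab$pseudo_F[1:4], ref$F[1:4], tolerance = 1e-8)
})

test_that("aliased terms are reported by name", {
  d <- as.data.frame(study_dataset(seed = 51))
  d$h_class <- "a"   # constant factor
  ds <- trait_dataset(d, c("sla", "pi"))
  expect_error(fit_anova(ds, "sla", list(quadrat = "quadrat", h_class = "h_class")),
               "h_class.*aliased|aliased.*h_class")
})

test_that("a strong height-class effect is detected at the permutation floor", {
  # height-class contrast three residual SDs wide, on residual-only noise
  fr <- list(sla = c(residual = 1))
  floor_hits <- vapply(1:10, function(seed) {
    base <- generate_dataset(synth_config(grand_mean = c(sla = 8),
                                          total_sd = c(sla = 1),
                                          variance_fractions = fr, seed = seed))
    d <- as.data.frame(base)
    d$sla <- d$sla + 3 * ifelse(d$h_class == "b", 1, 0)
    ds <- trait_dataset(d, "sla")
    tab <- fit_anova(ds, "sla")
    tab <- permutation_pvalues(tab, n_perm = 99, seed = seed + 1000)
    tab$p_perm[tab$term == "h_class"] <= 1 / 100
  }, logical(1))
  expect_gte(mean(floor_hits), 0.95)
})

test_that("permutation p-values are deterministic given the seed", {
  ds <- generate_dataset(small_config(seed = 61, variance_fractions = list(
    sla = c(quadrat = 0.2, individual = 0.2, h_class = 0, position = 0,
            `h_class:position` = 0, `quadrat:position` = 0, residual = 0.6))))
  tab <- fit_anova(ds, "sla")
  p1 <- permutation_pvalues(tab, n_perm = 99, seed = 7)$p_perm
  p2 <- permutation_pvalues(tab, n_perm = 99, seed = 7)$p_perm
  expect_identical(p1, p2)
})

test_that("variance percentages and canopy/individual grouping follow the SS-ratio rule", {
  ds <- oneway_dataset(c(1, 2, 3, 4, 5, 6, 7, 9), rep(c("g1", "g2"), each = 4))
  tab <- fit_anova(ds, "sla", list(A = "individual"))
  pct <- variance_percentages(tab)
  expect_equal(sum(pct), 100)
  expect_equal(unname(pct["A"]), unname(100 * tab$SS[1] / sum(tab$SS)))

  full <- fit_anova(study_dataset(seed = 71), "sla")
  grouped <- grouped_variance_percentages(full)
  pcts <- variance_percentages(full)
  canopy_terms <- c("h_class", "position", "quadrat:h_class", "quadrat:position",
                    "h_class:position", "individual(quadrat):h_class",
                    "individual(quadrat):position", "quadrat:h_class:position",
                    "individual(quadrat):h_class:position")
  expect_equal(unname(grouped["canopy"]), sum(pcts[canopy_terms]))
  expect_equal(unname(grouped["individual"]),
               sum(pcts[c("quadrat", "individual(quadrat)")]))
  expect_equal(sum(grouped), 100, tolerance = 1e-8)
})
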