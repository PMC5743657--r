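test_that("whole-data statistics match a hand computation with the t quantile", {
  ds <- tiny_dataset(c(1, 2, 3))
  st <- whole_data_stats(ds, "sla")
  expect_equal(st$mean, 2)
  expect_equal(st$sd, 1)
  expect_equal(st$se, 1 / sqrt(3))
  half <- qt(0.975, df = 2) * 1 / sqrt(3)
  expect_equal(st$ci_low, 2 - half)
  expect_equal(st$ci_high, 2 + half)
  expect_equal(half, 4.302653 * 0.5773503, tolerance = 1e-6)
  expect_false(st$degenerate)
})

test_that("constant traits give a degenerate interval and a flag", {
  ds <- tiny_dataset(rep(5, 4))
  st <- whole_data_stats(ds, "sla")
  expect_true(st$degenerate)
  expect_equal(st$ci_low, st$ci_high)
  expect_equal(st$ci_low, 5)
  expect_error(whole_data_stats(tiny_dataset(3)), "at least 2")
})

test_that("standardized deviation behaves as |x - mean| / sd", {
  expect_equal(standardized_deviation(8.02, 8.02, 1.5), 0)
  expect_equal(standardized_deviation(8.32, 8.02, 1.5), 0.2)
  # affine invariance: scale and shift everything consistently
  a <- 3.7; b <- 12
  expect_equal(standardized_deviation(a * 8.32 + b, a * 8.02 + b, a * 1.5),
               standardized_deviation(8.32, 8.02, 1.5))
  expect_error(standardized_deviation(1, 1, 0), "whole_sd")
})

# A hand-built summaries table: one strategy over several sizes per trait.
fake_summary <- function(strategy, i, l, trait, mean, se) {
  data.frame(strategy = strategy, n_individuals = i, leaves_per_individual = l,
             total_leaves = i * l, trait = trait, mean = mean, se = se,
             cv = se / mean, reps = 499L, seed = 1L, stringsAsFactors = FALSE)
}

fake_stats <- function(traits = c("sla", "pi"),
                       mean = c(sla = 8.02, pi = 3.29),
                       sd = c(sla = 1.5, pi = 1.1),
                       half = c(sla = 0.15, pi = 0.105)) {
  out <- data.frame(trait = traits, n = 408L, mean = mean[traits],
                    sd = sd[traits], se = sd[traits] / sqrt(408),
                    ci_low = mean[traits] - half[traits],
                    ci_high = mean[traits] + half[traits],
                    degenerate = FALSE, stringsAsFactors = FALSE)
  attr(out, "level") <- 0.95
  class(out) <- c("whole_data_stats", "data.frame")
  out
}

test_that("screening uses closed CI bounds and an all-traits conjunction", {
  st <- fake_stats()
  se_min <- c(sla = 0.29, pi = 0.22)
  # mean exactly on the upper CI bound passes; SE exactly at SE_min passes
  summ <- rbind(
    fake_summary("edge", 5, 5, "sla", 8.02 + 0.15, 0.29),
    fake_summary("edge", 5, 5, "pi", 3.29, 0.22),
    fake_summary("off_one_trait", 5, 5, "sla", 8.02, 0.10),
    fake_summary("off_one_trait", 5, 5, "pi", 3.29 + 0.2, 0.10),
    fake_summary("imprecise", 5, 5, "sla", 8.02, 0.35),
    fake_summary("imprecise", 5, 5, "pi", 3.29, 0.10)
  )
  res <- screen_strategies(summ, st, se_min)
  adm <- unique(res[res$admissible, "strategy"])
  expect_equal(adm, "edge")
  off <- res[res$strategy == "off_one_trait", ]
  expect_true(off$pass_mean[off$trait == "sla"])
  expect_false(off$pass_mean[off$trait == "pi"])
  expect_false(all(off$admissible))
  expect_error(screen_strategies(summ, st, c(sla = 0.29)), "pi")
})

test_that("strategies whose restricted support shifts the mean are screened out", {
  base <- generate_dataset(synth_config(
    n_quadrats = 3, individuals_per_quadrat = c(4, 4, 4),
    leaves_per_stratum = 3, grand_mean = c(sla = 8), total_sd = c(sla = 0.5),
    variance_fractions = list(sla = c(residual = 1)), seed = 201))
  d <- as.data.frame(base)
  delta <- 1  # far beyond the CI half-width of ~0.05
  d$sla <- d$sla + ifelse(d$position == "E", delta, 0)
  ds <- trait_dataset(d, "sla")
  st <- whole_data_stats(ds)
  specs <- list(RANDOM = builtin_strategies()$RANDOM,
                ext = strategy_spec("ext", "random", "random", c("aE", "bE")))
  sizes <- list(sampling_size(6, 4), sampling_size(8, 6))
  g <- run_grid(ds, specs, sizes = sizes, reps = 199, seed = 31)
  res <- screen_strategies(g$summaries, st, c(sla = Inf))  # accuracy only
  expect_true(res$admissible[res$strategy == "RANDOM"][1])
  expect_false(res$admissible[res$strategy == "ext"][1])
})

test_that("a single admissible size is both minimum and optimal", {
  st <- fake_stats("sla", c(sla = 8), c(sla = 1), c(sla = 0.1))
  summ <- rbind(
    fake_summary("RANDOM", 5, 5, "sla", 8.02, 0.25),
    fake_summary("RANDOM", 2, 2, "sla", 8.5, 0.8)   # inadmissible
  )
  sel <- select_sizes(summ, st, c(sla = 0.3))
  expect_false(sel$no_admissible)
  expect_equal(nrow(sel$admissible), 1L)
  expect_equal(sel$minimum_size$total_leaves, 25L)
  expect_equal(sel$optimal_size$total_leaves, 25L)
})

test_that("the largest single-step drop of sum-of-S picks the optimal size", {
  st <- fake_stats("sla", c(sla = 8), c(sla = 1), c(sla = 1))
  # S values: 0.30, 0.28, 0.05, 0.04 -> biggest drop at the third size
  summ <- rbind(
    fake_summary("RANDOM", 5, 2, "sla", 8.30, 0.1),
    fake_summary("RANDOM", 5, 3, "sla", 8.28, 0.1),
    fake_summary("RANDOM", 10, 2, "sla", 8.05, 0.1),
    fake_summary("RANDOM", 10, 3, "sla", 8.04, 0.1)
  )
  sel <- select_sizes(summ, st, c(sla = 0.3))
  expect_equal(sel$minimum_size$total_leaves, 10L)
  expect_equal(sel$optimal_size$n_individuals, 10L)
  expect_equal(sel$optimal_size$leaves_per_individual, 2L)
  # audit table allows recomputing each S
  expect_equal(sel$table$S_sla,
               abs(c(8.30, 8.28, 8.05, 8.04) - 8) / 1)
})

test_that("minimum-size ties on total leaves break toward fewer individuals", {
  st <- fake_stats("sla", c(sla = 8), c(sla = 1), c(sla = 1))
  summ <- rbind(
    fake_summary("RANDOM", 2, 6, "sla", 8.1, 0.1),
    fake_summary("RANDOM", 3, 4, "sla", 8.1, 0.1),
    fake_summary("RANDOM", 4, 6, "sla", 8.0, 0.1)
  )
  sel <- select_sizes(summ, st, c(sla = 0.3))
  expect_equal(sel$minimum_size$n_individuals, 2L)
})

test_that("no admissible design is reported explicitly", {
  st <- fake_stats("sla", c(sla = 8), c(sla = 1), c(sla = 0.01))
  summ <- fake_summary("RANDOM", 5, 5, "sla", 9, 0.5)
  sel <- select_sizes(summ, st, c(sla = 0.1))
  expect_true(sel$no_admissible)
  expect_null(sel$minimum_size)
  expect_output(print(sel), "No admissible")
})

test_that("widening the confidence interval never removes admissible strategies", {
  se_min <- c(sla = 0.3)
  summ <- rbind(
    fake_summary("A", 5, 5, "sla", 8.10, 0.2),
    fake_summary("B", 5, 5, "sla", 8.30, 0.2),
    fake_summary("C", 5, 5, "sla", 9.00, 0.2)
  )
  narrow <- fake_stats("sla", c(sla = 8), c(sla = 1), c(sla = 0.15))
  wide <- fake_stats("sla", c(sla = 8), c(sla = 1), c(sla = 0.5))
  adm_narrow <- with(screen_strategies(summ, narrow, se_min),
                     unique(strategy[admissible]))
  adm_wide <- with(screen_strategies(summ, wide, se_min),
                   unique(strategy[admissible]))
  expect_true(all(adm_narrow %in% adm_wide))
  expect_setequal(adm_narrow, "A")
  expect_setequal(adm_wide, c("A", "B"))
})
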