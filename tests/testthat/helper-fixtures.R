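# Fixtures built in code: small hand-laid datasets and scaled-down
# synthetic configurations used across the test files.

# A minimal valid dataset from a vector of trait values; one individual,
# leaves cycled over the four canopy strata.
tiny_dataset <- function(values, trait = "sla") {
  n <- length(values)
  strata <- expand.grid(position = c("E", "I"), h_class = c("a", "b"),
                        stringsAsFactors = FALSE)
  i <- ((seq_len(n) - 1L) %% 4L) + 1L
  d <- data.frame(leaf_id = sprintf("L%02d", seq_len(n)),
                  quadrat = "Q1", individual = "i01",
                  h_class = strata$h_class[i], position = strata$position[i],
                  exposure = "N", stringsAsFactors = FALSE)
  d[[trait]] <- values
  trait_dataset(d, trait)
}

# One-way layout: `values` split into groups via `group` labels mapped to
# the h_class/individual column so a single-term ANOVA can target it.
oneway_dataset <- function(values, group, trait = "sla") {
  stopifnot(length(values) == length(group))
  d <- data.frame(leaf_id = sprintf("L%02d", seq_along(values)),
                  quadrat = "Q1", individual = as.character(group),
                  h_class = "a", position = "E", exposure = "N",
                  stringsAsFactors = FALSE)
  d[[trait]] <- values
  trait_dataset(d, trait)
}

# Study-shaped synthetic dataset (3 quadrats with 5/17/12 individuals,
# 12 leaf pairs each -> 408 rows).
study_dataset <- function(seed = 1, ...) {
  generate_dataset(synth_config(seed = seed, ...))
}

# Small design for permutation-heavy tests: 3 quadrats x 3 individuals,
# 2 leaves per stratum (one per h_class x position cell x 2) -> 72 rows.
small_config <- function(seed, variance_fractions = NULL, total_sd = c(sla = 1)) {
  synth_config(n_quadrats = 3, individuals_per_quadrat = c(3, 3, 3),
               leaves_per_stratum = 2, grand_mean = c(sla = 8),
               total_sd = total_sd,
               variance_fractions = variance_fractions, seed = seed)
}

# Balanced two-factor dataset: q quadrats x i individuals x full stratum
# grid, all effects supplied by the caller's function of the design row.
null_fractions <- function() {
  list(sla = c(quadrat = 0, individual = 0, h_class = 0, position = 0,
               `h_class:position` = 0, `quadrat:position` = 0, residual = 1))
}

# Classical one-way ANOVA computed from first principles (test oracle).
oneway_oracle <- function(values, group) {
  g <- split(values, group)
  grand <- mean(values)
  ss_between <- sum(vapply(g, function(v) length(v) * (mean(v) - grand)^2, 0))
  ss_within <- sum(vapply(g, function(v) sum((v - mean(v))^2), 0))
  df_b <- length(g) - 1L
  df_w <- length(values) - length(g)
  list(ss_between = ss_between, ss_within = ss_within,
       df_between = df_b, df_within = df_w,
       f = (ss_between / df_b) / (ss_within / df_w))
}
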