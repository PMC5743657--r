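# Two-step selection of sampling strategies and sizes: screen by accuracy
# (strategy mean inside the whole-data confidence interval) and precision
# (mean SE at or below the flex-point SE_min), then rank admissible sizes
# by the standardized deviation S to pick the minimum and optimal sizes.

#' Whole-dataset summary statistics per trait
#'
#' Mean, SD, SE and the t-based confidence interval of the mean,
#' `mean +/- t(N-1, (1+level)/2) * SD/sqrt(N)`, per trait. Constant traits
#' yield a degenerate (zero-width) interval and are flagged.
#'
#' @param dataset a [trait_dataset].
#' @param traits traits to summarize (default: all).
#' @param level confidence level (default 0.95).
#' @return data frame of class `"whole_data_stats"`: `trait`, `n`, `mean`,
#'   `sd`, `se`, `ci_low`, `ci_high`, `degenerate`.
#' @export
whole_data_stats <- function(dataset, traits = trait_names(dataset),
                             level = 0.95) {
  stopifnot(inherits(dataset, "trait_dataset"), level > 0, level < 1)
  d <- as.data.frame(dataset)
  n <- nrow(d)
  if (n < 2L) stop("need at least 2 observations", call. = FALSE)
  rows <- lapply(traits, function(tr) {
    v <- d[[tr]]
    m <- mean(v); s <- stats::sd(v)
    se <- s / sqrt(n)
    half <- stats::qt((1 + level) / 2, df = n - 1) * se
    data.frame(trait = tr, n = n, mean = m, sd = s, se = se,
               ci_low = m - half, ci_high = m + half,
               degenerate = s == 0, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "level") <- level
  class(out) <- c("whole_data_stats", "data.frame")
  out
}

#' Standardized deviation from the whole-data mean
#'
#' The accuracy score of a sampling design:
#' `S = |x_m - whole_mean| / whole_sd`, where `x_m` is the design's mean
#' trait estimate. Invariant under common affine rescaling of the means
#' with the SD scaled accordingly.
#'
#' @param x_m design mean estimate(s).
#' @param whole_mean whole-data mean.
#' @param whole_sd whole-data standard deviation (must be positive).
#' @return non-negative numeric, vectorized over `x_m`.
#' @export
standardized_deviation <- function(x_m, whole_mean, whole_sd) {
  if (any(whole_sd <= 0)) stop("whole_sd must be > 0", call. = FALSE)
  abs(x_m - whole_mean) / whole_sd
}

.stats_row <- function(stats_df, tr) {
  i <- match(tr, stats_df$trait)
  if (is.na(i)) stop("no whole-data stats for trait '", tr, "'", call. = FALSE)
  stats_df[i, ]
}

#' Screen strategies by accuracy and precision
#'
#' Strategy-level screening over each strategy's simulated size grid: a
#' strategy is admissible when, for every trait, its aggregated mean lies
#' inside the whole-data confidence interval (closed interval - a mean
#' exactly on a bound passes) and its aggregated SE is at or below
#' `se_min`. Aggregation over the strategy's sizes uses the median of the
#' per-size means and SEs by default (matching a box-plot reading of the
#' per-strategy distributions); set `aggregate = "mean"` to average
#' instead.
#'
#' @param summaries long summary data frame from [run_grid()]
#'   (`$summaries`), or [simulate_strategy()] output row-bound over sizes.
#' @param stats a [whole_data_stats()] table.
#' @param se_min named numeric: flex-point SE threshold per trait, as from
#'   [fit_breakpoint()] `value_at_psi`.
#' @param aggregate `"median"` or `"mean"`.
#' @return data frame of class `"screening_result"`, one row per
#'   (strategy, trait): aggregated `mean` and `se`, `pass_mean`,
#'   `pass_se`, and the per-strategy `admissible` conjunction.
#' @export
screen_strategies <- function(summaries, stats, se_min,
                              aggregate = c("median", "mean")) {
  aggregate <- match.arg(aggregate)
  agg_fun <- if (aggregate == "median") {
    function(x) stats::median(x, na.rm = TRUE)
  } else {
    function(x) mean(x, na.rm = TRUE)
  }
  traits <- unique(summaries$trait)
  miss <- setdiff(traits, names(se_min))
  if (length(miss) > 0L) {
    stop("se_min missing for trait(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  rows <- list()
  for (st in unique(summaries$strategy)) {
    sub <- summaries[summaries$strategy == st, ]
    for (tr in traits) {
      if (!tr %in% sub$trait) {
        stop("strategy '", st, "' has no summaries for trait '", tr, "'",
             call. = FALSE)
      }
      s_tr <- sub[sub$trait == tr, ]
      wm <- .stats_row(stats, tr)
      m <- agg_fun(s_tr$mean)
      se <- agg_fun(s_tr$se)
      rows[[length(rows) + 1L]] <- data.frame(
        strategy = st, trait = tr, mean = m, se = se,
        pass_mean = m >= wm$ci_low & m <= wm$ci_high,
        pass_se = is.finite(se) & se <= se_min[[tr]],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  adm <- tapply(out$pass_mean & out$pass_se, out$strategy, all)
  out$admissible <- as.logical(adm[out$strategy])
  attr(out, "aggregate") <- aggregate
  attr(out, "se_min") <- se_min
  class(out) <- c("screening_result", "data.frame")
  out
}

#' Select minimum and optimal sampling sizes
#'
#' Operates on per-size summaries (typically one admissible strategy's
#' grid). A size is admissible when, for every trait, its mean lies inside
#' the whole-data confidence interval (closed) and its mean SE is at or
#' below `se_min`. Among admissible sizes:
#' \itemize{
#'   \item the \emph{minimum} size is the one with the fewest total
#'     leaves (ties broken by fewer individuals);
#'   \item the \emph{optimal} size is found by ordering admissible sizes
#'     by total leaves and picking the size with the largest single-step
#'     decrease of the summed standardized deviation
#'     (`sum_S = sum over traits of S`) relative to the previous
#'     admissible size (ties broken by fewer total leaves) - the best
#'     accuracy gain per unit of extra effort.
#' }
#' The full S table is returned for audit, so every pass/fail and the two
#' picks can be recomputed from the stored summaries.
#'
#' @param summaries long per-size summary data frame (columns as produced
#'   by [simulate_strategy()]).
#' @param stats a [whole_data_stats()] table.
#' @param se_min named numeric threshold per trait.
#' @return list of class `"selection_result"`: `table` (per strategy/size:
#'   per-trait S spread over columns `S_<trait>`, `sum_S`, `admissible`),
#'   `admissible` (subset, ordered by total leaves), `minimum_size`,
#'   `optimal_size` (each `NULL` when nothing is admissible),
#'   `no_admissible` flag, and an `audit` list with the thresholds used.
#' @export
select_sizes <- function(summaries, stats, se_min) {
  traits <- unique(summaries$trait)
  miss <- setdiff(traits, names(se_min))
  if (length(miss) > 0L) {
    stop("se_min missing for trait(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  key <- unique(summaries[, c("strategy", "n_individuals",
                              "leaves_per_individual", "total_leaves")])
  rownames(key) <- NULL
  s_cols <- paste0("S_", traits)
  key[s_cols] <- NA_real_
  key$admissible <- TRUE
  for (i in seq_len(nrow(key))) {
    for (tr in traits) {
      row <- summaries[summaries$strategy == key$strategy[i] &
                       summaries$n_individuals == key$n_individuals[i] &
                       summaries$leaves_per_individual == key$leaves_per_individual[i] &
                       summaries$trait == tr, ]
      if (nrow(row) != 1L) {
        stop("expected exactly one summary row per (strategy, size, trait)",
             call. = FALSE)
      }
      wm <- .stats_row(stats, tr)
      key[i, paste0("S_", tr)] <-
        standardized_deviation(row$mean, wm$mean, wm$sd)
      in_ci <- row$mean >= wm$ci_low & row$mean <= wm$ci_high
      precise <- is.finite(row$se) & row$se <= se_min[[tr]]
      key$admissible[i] <- key$admissible[i] && in_ci && precise
    }
  }
  key$sum_S <- rowSums(key[, s_cols, drop = FALSE])

  adm <- key[key$admissible, , drop = FALSE]
  adm <- adm[order(adm$total_leaves, adm$n_individuals), , drop = FALSE]
  result <- list(table = key, admissible = adm,
                 minimum_size = NULL, optimal_size = NULL,
                 no_admissible = nrow(adm) == 0L,
                 audit = list(se_min = se_min,
                              ci_level = attr(stats, "level"),
                              traits = traits,
                              rule = "largest single-step drop of sum_S along total-leaves order"))
  if (nrow(adm) == 0L) {
    class(result) <- "selection_result"
    return(result)
  }
  result$minimum_size <- adm[1L, ]
  if (nrow(adm) == 1L) {
    result$optimal_size <- adm[1L, ]
  } else {
    drop_s <- c(NA_real_, adm$sum_S[-nrow(adm)] - adm$sum_S[-1L])
    best <- which(drop_s == max(drop_s, na.rm = TRUE))
    best <- best[which.min(adm$total_leaves[best])]
    result$optimal_size <- adm[best, ]
  }
  class(result) <- "selection_result"
  result
}

#' @export
print.selection_result <- function(x, ...) {
  if (x$no_admissible) {
    cat("No admissible sampling design under the accuracy/precision criteria.\n")
    return(invisible(x))
  }
  fmt <- function(r) sprintf("%s_%d_%d (%d leaves, sum S = %.4f)",
                             r$strategy, r$n_individuals,
                             r$leaves_per_individual, r$total_leaves, r$sum_S)
  cat("Admissible sizes:", nrow(x$admissible), "\n")
  cat("Minimum sampling size:", fmt(x$minimum_size), "\n")
  cat("Optimal sampling size:", fmt(x$optimal_size), "\n")
  invisible(x)
}
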