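# Field-sampling strategies: multistage (individuals, then leaves within
# individuals) draws without replacement, optionally stratified over the
# four canopy strata or restricted to a subset of them, simulated over a
# grid of (individuals x leaves per individual) sampling sizes.

.ALL_STRATA <- c("aE", "aI", "bE", "bI")

#' Define a sampling strategy
#'
#' A strategy fixes how individuals are chosen (uniformly anywhere, or a
#' fixed, as-equal-as-feasible number per quadrat) and how leaves are
#' chosen within each selected individual (uniformly among eligible
#' leaves, or stratified as evenly as possible over the eligible canopy
#' strata). `allowed_strata` restricts eligibility, e.g. `c("aE", "bE")`
#' samples only external leaves.
#'
#' @param name strategy label.
#' @param individual_selection `"random"` or `"fixed_per_quadrat"`.
#' @param leaf_selection `"random"` or `"stratified"`.
#' @param allowed_strata subset of `c("aE","aI","bE","bI")` (height class
#'   then position).
#' @param preset_size optional `c(n_individuals, leaves_per_individual)`
#'   recording a recommended size for the strategy.
#' @return list of class `"strategy_spec"`.
#' @export
strategy_spec <- function(name,
                          individual_selection = c("random", "fixed_per_quadrat"),
                          leaf_selection = c("random", "stratified"),
                          allowed_strata = .ALL_STRATA,
                          preset_size = NULL) {
  individual_selection <- match.arg(individual_selection)
  leaf_selection <- match.arg(leaf_selection)
  allowed_strata <- as.character(allowed_strata)
  if (length(allowed_strata) < 1L || !all(allowed_strata %in% .ALL_STRATA)) {
    stop("allowed_strata must be a non-empty subset of ",
         paste(.ALL_STRATA, collapse = ", "), call. = FALSE)
  }
  # fixed order aE, aI, bE, bI for deterministic remainder allocation
  allowed_strata <- .ALL_STRATA[.ALL_STRATA %in% allowed_strata]
  if (!is.null(preset_size)) {
    stopifnot(length(preset_size) == 2L, all(preset_size >= 1))
    preset_size <- sampling_size(preset_size[1], preset_size[2])
  }
  structure(list(name = name, individual_selection = individual_selection,
                 leaf_selection = leaf_selection,
                 allowed_strata = allowed_strata, preset_size = preset_size),
            class = "strategy_spec")
}

#' A sampling size: individuals by leaves per individual
#'
#' @param n_individuals number of individuals to sample.
#' @param leaves_per_individual leaves drawn from each individual.
#' @return list of class `"sampling_size"` with `total_leaves` =
#'   `n_individuals * leaves_per_individual`.
#' @export
sampling_size <- function(n_individuals, leaves_per_individual) {
  n_individuals <- as.integer(n_individuals)
  leaves_per_individual <- as.integer(leaves_per_individual)
  stopifnot(n_individuals >= 1L, leaves_per_individual >= 1L)
  structure(list(n_individuals = n_individuals,
                 leaves_per_individual = leaves_per_individual,
                 total_leaves = n_individuals * leaves_per_individual),
            class = "sampling_size")
}

#' Built-in strategy registry
#'
#' The named strategies compared in the analysis:
#' \describe{
#'   \item{RANDOM}{individuals and leaves fully at random, ignoring all
#'     spatial levels.}
#'   \item{Q_fixed}{an equal number of individuals per quadrat, leaves at
#'     random.}
#'   \item{stRANDOM}{random individuals, leaves stratified over the four
#'     canopy strata.}
#'   \item{stQ_fixed}{equal individuals per quadrat and leaves stratified
#'     over the four strata (the most spatially constrained design).}
#'   \item{cor, cor_min, per, per_min}{external-stratum-only ("sun leaf")
#'     protocol variants restricted to `c("aE","bE")`, carrying the
#'     literature-recommended preset sizes: 4 leaves from 10 individuals
#'     (preferred: `per`, `cor`) or 5 leaves from 5 individuals (minimum:
#'     `per_min`, `cor_min`).}
#'   \item{cor_b, cor_min_b, per_b, per_min_b}{as above but restricted to
#'     the upper external stratum `"bE"` only.}
#' }
#' The registry is a plain named list; extend it with [strategy_spec()].
#'
#' @return named list of `strategy_spec` objects.
#' @export
builtin_strategies <- function() {
  ext <- c("aE", "bE")
  up <- "bE"
  list(
    RANDOM    = strategy_spec("RANDOM", "random", "random"),
    Q_fixed   = strategy_spec("Q_fixed", "fixed_per_quadrat", "random"),
    stRANDOM  = strategy_spec("stRANDOM", "random", "stratified"),
    stQ_fixed = strategy_spec("stQ_fixed", "fixed_per_quadrat", "stratified"),
    cor       = strategy_spec("cor", "random", "random", ext, c(10, 4)),
    cor_min   = strategy_spec("cor_min", "random", "random", ext, c(5, 5)),
    per       = strategy_spec("per", "random", "random", ext, c(10, 4)),
    per_min   = strategy_spec("per_min", "random", "random", ext, c(5, 5)),
    cor_b     = strategy_spec("cor_b", "random", "random", up, c(10, 4)),
    cor_min_b = strategy_spec("cor_min_b", "random", "random", up, c(5, 5)),
    per_b     = strategy_spec("per_b", "random", "random", up, c(10, 4)),
    per_min_b = strategy_spec("per_min_b", "random", "random", up, c(5, 5))
  )
}

# Internal index of a dataset: per-individual row lists, overall and per
# stratum, plus quadrat membership.
.dataset_index <- function(dataset, allowed_strata) {
  d <- as.data.frame(dataset)
  stratum <- paste0(d$h_class, d$position)
  eligible <- stratum %in% allowed_strata
  uid <- paste(d$quadrat, d$individual, sep = "/")
  uids <- sort(unique(uid))
  rows_by_ind <- lapply(uids, function(u) which(uid == u & eligible))
  rows_by_ind_str <- lapply(uids, function(u) {
    lapply(stats::setNames(allowed_strata, allowed_strata),
           function(s) which(uid == u & stratum == s))
  })
  quadrat_of <- vapply(uids, function(u) d$quadrat[uid == u][1L], character(1))
  list(uids = uids, rows_by_ind = rows_by_ind,
       rows_by_ind_str = rows_by_ind_str, quadrat_of = quadrat_of,
       quadrats = sort(unique(d$quadrat)))
}

# Per-quadrat individual counts k_q: as equal as feasible, remainder to
# quadrats in label order.
.quadrat_allocation <- function(n_individuals, quadrats) {
  Q <- length(quadrats)
  base <- n_individuals %/% Q
  rem <- n_individuals %% Q
  k <- rep(base, Q) + c(rep(1L, rem), rep(0L, Q - rem))
  stats::setNames(as.integer(k), quadrats)
}

# Per-stratum leaf counts: as even as possible over allowed strata, excess
# to strata in fixed order aE, aI, bE, bI.
.stratum_allocation <- function(leaves_per_individual, allowed_strata) {
  S <- length(allowed_strata)
  base <- leaves_per_individual %/% S
  rem <- leaves_per_individual %% S
  k <- rep(base, S) + c(rep(1L, rem), rep(0L, S - rem))
  stats::setNames(as.integer(k), allowed_strata)
}

#' Check whether a strategy/size cell is feasible on a dataset
#'
#' A cell is feasible when enough individuals exist (per quadrat, for
#' fixed-per-quadrat selection) and every individual can supply the
#' requested leaves under the strategy's stratum constraints, so that any
#' stage-1 draw can be completed.
#'
#' @param dataset a [trait_dataset].
#' @param spec a [strategy_spec()].
#' @param size a [sampling_size()].
#' @return `TRUE`, or `FALSE` with attribute `reason`.
#' @export
strategy_feasible <- function(dataset, spec, size) {
  idx <- .dataset_index(dataset, spec$allowed_strata)
  fail <- function(reason) structure(FALSE, reason = reason)
  if (size$n_individuals > length(idx$uids)) {
    return(fail(sprintf("requested %d individuals, only %d available",
                        size$n_individuals, length(idx$uids))))
  }
  if (spec$individual_selection == "fixed_per_quadrat") {
    k <- .quadrat_allocation(size$n_individuals, idx$quadrats)
    avail <- table(factor(idx$quadrat_of, levels = idx$quadrats))
    short <- names(k)[k > as.integer(avail)]
    if (length(short) > 0L) {
      return(fail(sprintf("quadrat %s has fewer than %d individuals",
                          short[1L], k[short[1L]])))
    }
  }
  if (spec$leaf_selection == "stratified") {
    alloc <- .stratum_allocation(size$leaves_per_individual, spec$allowed_strata)
    for (s in names(alloc)) {
      cap <- vapply(idx$rows_by_ind_str, function(r) length(r[[s]]), integer(1))
      if (any(cap < alloc[[s]])) {
        return(fail(sprintf(
          "stratum %s holds %d leaves in some individual, %d requested",
          s, min(cap), alloc[[s]])))
      }
    }
  } else {
    cap <- vapply(idx$rows_by_ind, length, integer(1))
    if (any(cap < size$leaves_per_individual)) {
      return(fail(sprintf(
        "only %d eligible leaves (strata %s) in some individual, %d requested",
        min(cap), paste(spec$allowed_strata, collapse = "/"),
        size$leaves_per_individual)))
    }
  }
  TRUE
}

# One multistage draw from a prebuilt index; returns row indices.
.draw_rows <- function(idx, spec, size) {
  if (spec$individual_selection == "fixed_per_quadrat") {
    k <- .quadrat_allocation(size$n_individuals, idx$quadrats)
    chosen <- integer(0)
    for (q in idx$quadrats) {
      in_q <- which(idx$quadrat_of == q)
      chosen <- c(chosen, in_q[sample.int(length(in_q), k[[q]])])
    }
  } else {
    chosen <- sample.int(length(idx$uids), size$n_individuals)
  }

  rows <- integer(0)
  if (spec$leaf_selection == "stratified") {
    alloc <- .stratum_allocation(size$leaves_per_individual, spec$allowed_strata)
    for (ci in chosen) {
      for (s in names(alloc)) {
        if (alloc[[s]] == 0L) next
        r <- idx$rows_by_ind_str[[ci]][[s]]
        rows <- c(rows, r[sample.int(length(r), alloc[[s]])])
      }
    }
  } else {
    for (ci in chosen) {
      r <- idx$rows_by_ind[[ci]]
      rows <- c(rows, r[sample.int(length(r), size$leaves_per_individual)])
    }
  }
  rows
}

#' Draw one multistage sample
#'
#' Stage 1 selects `size$n_individuals` individuals without replacement
#' (uniformly, or a fixed number per quadrat); stage 2 selects
#' `size$leaves_per_individual` leaves within each selected individual
#' without replacement, uniformly among eligible leaves or stratified over
#' the allowed strata. Uses the current RNG state.
#'
#' @inheritParams strategy_feasible
#' @return the sampled rows of `dataset` (a data frame).
#' @export
draw_sample <- function(dataset, spec, size) {
  ok <- strategy_feasible(dataset, spec, size)
  if (!isTRUE(ok)) {
    stop("infeasible sampling size for strategy '", spec$name, "': ",
         attr(ok, "reason"), call. = FALSE)
  }
  idx <- .dataset_index(dataset, spec$allowed_strata)
  as.data.frame(dataset)[.draw_rows(idx, spec, size), , drop = FALSE]
}

#' Simulate a strategy at one sampling size
#'
#' Draws `reps` independent multistage samples and records, per trait and
#' replicate, the sample mean, the standard error (sample SD over the
#' square root of the total number of leaves) and the coefficient of
#' variation; the summary holds their means over replicates. At the
#' exhaustive size (all individuals, all leaves) every replicate equals
#' the full dataset, so the across-replicate variance is zero. A total of
#' one leaf has no SD; its `se`/`cv` are `NA`.
#'
#' @inheritParams strategy_feasible
#' @param reps number of replicates (default 4999).
#' @param seed integer seed; the summary is deterministic given it.
#' @return data frame of class `"strategy_summary"`, one row per trait:
#'   `strategy`, `n_individuals`, `leaves_per_individual`, `total_leaves`,
#'   `trait`, `mean`, `se`, `cv`, `reps`, `seed`.
#' @export
simulate_strategy <- function(dataset, spec, size, reps = 4999, seed = NULL) {
  ok <- strategy_feasible(dataset, spec, size)
  if (!isTRUE(ok)) {
    stop("infeasible sampling size for strategy '", spec$name, "': ",
         attr(ok, "reason"), call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  trs <- trait_names(dataset)
  ntot <- size$total_leaves
  idx <- .dataset_index(dataset, spec$allowed_strata)
  vals <- lapply(stats::setNames(trs, trs),
                 function(tr) as.data.frame(dataset)[[tr]])
  acc_mean <- acc_se <- acc_cv <- matrix(0, reps, length(trs),
                                         dimnames = list(NULL, trs))
  for (r in seq_len(reps)) {
    rows <- .draw_rows(idx, spec, size)
    for (tr in trs) {
      v <- vals[[tr]][rows]
      m <- mean(v)
      sdev <- if (ntot > 1L) stats::sd(v) else NA_real_
      acc_mean[r, tr] <- m
      acc_se[r, tr] <- sdev / sqrt(ntot)
      acc_cv[r, tr] <- sdev / m
    }
  }
  out <- data.frame(
    strategy = spec$name,
    n_individuals = size$n_individuals,
    leaves_per_individual = size$leaves_per_individual,
    total_leaves = ntot,
    trait = trs,
    mean = colMeans(acc_mean),
    se = colMeans(acc_se),
    cv = colMeans(acc_cv),
    reps = as.integer(reps),
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("strategy_summary", "data.frame")
  out
}

#' Simulate strategies over a sampling-size grid
#'
#' Runs [simulate_strategy()] for every feasible (strategy, size) cell.
#' Each cell gets its own sub-seed derived from `seed` and the cell index,
#' so any single cell can be reproduced in isolation with
#' `simulate_strategy(..., seed = <cell seed>)` (the seed is recorded in
#' the output). Infeasible cells are recorded as skipped, with the
#' binding constraint - infeasibility is data, not failure.
#'
#' @param dataset a [trait_dataset].
#' @param specs named list of [strategy_spec()] objects.
#' @param sizes list of [sampling_size()] objects; default is the full
#'   grid 1..(number of individuals) x 1..(max leaves per individual).
#' @param reps replicates per cell.
#' @param seed master integer seed.
#' @param quiet suppress per-skip log lines.
#' @return list of class `"strategy_grid"`: `summaries` (long data frame)
#'   and `skipped` (strategy, n_individuals, leaves_per_individual,
#'   reason).
#' @export
run_grid <- function(dataset, specs, sizes = NULL, reps = 4999, seed = 1L,
                     quiet = TRUE) {
  stopifnot(inherits(dataset, "trait_dataset"))
  if (inherits(specs, "strategy_spec")) specs <- list(specs)
  if (is.null(sizes)) {
    des <- summarize_design(dataset)
    max_leaves <- max(des$leaves_per_individual)
    sizes <- list()
    for (i in seq_len(des$n_individuals)) {
      for (l in seq_len(max_leaves)) {
        sizes[[length(sizes) + 1L]] <- sampling_size(i, l)
      }
    }
  }
  summaries <- list()
  skipped <- list()
  cell <- 0L
  for (spec in specs) {
    for (size in sizes) {
      cell <- cell + 1L
      cell_seed <- as.integer((as.numeric(seed) + 1000003 * cell) %% 2147483647)
      ok <- strategy_feasible(dataset, spec, size)
      if (!isTRUE(ok)) {
        skipped[[length(skipped) + 1L]] <- data.frame(
          strategy = spec$name, n_individuals = size$n_individuals,
          leaves_per_individual = size$leaves_per_individual,
          reason = attr(ok, "reason"), stringsAsFactors = FALSE)
        if (!quiet) {
          log_event("simulate-strategies", "WARN",
                    sprintf("skipping %s_%d_%d: %s", spec$name,
                            size$n_individuals, size$leaves_per_individual,
                            attr(ok, "reason")))
        }
        next
      }
      summaries[[length(summaries) + 1L]] <-
        simulate_strategy(dataset, spec, size, reps = reps, seed = cell_seed)
    }
  }
  out <- list(
    summaries = if (length(summaries) > 0L) do.call(rbind, summaries)
                else data.frame(),
    skipped = if (length(skipped) > 0L) do.call(rbind, skipped)
              else data.frame(strategy = character(0),
                              n_individuals = integer(0),
                              leaves_per_individual = integer(0),
                              reason = character(0))
  )
  class(out) <- "strategy_grid"
  out
}
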