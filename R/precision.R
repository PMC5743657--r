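# Resampling precision curves (mean SE and CV against sample size) and
# their flex point, estimated by a one-breakpoint segmented regression.

#' Resampled precision curve of a trait
#'
#' For each sample size `n` on the grid, draws `reps` simple random
#' samples of `n` leaves without replacement and records the replicate
#' standard error (sample SD / sqrt(n)) and coefficient of variation
#' (sample SD / sample mean); the curve stores their means over
#' replicates. `n = 1` has no SD and is dropped with a warning when
#' requested.
#'
#' @param dataset a [trait_dataset].
#' @param trait trait column to resample.
#' @param n_grid sample sizes (default `2:N`); must lie in `[2, N]`.
#' @param reps replicates per size (default 4999).
#' @param seed integer seed; the curve is deterministic given it.
#' @return data frame of class `"precision_curve"` with columns `n`,
#'   `mean_se`, `mean_cv`; attributes `trait`, `reps`, `seed`, `n_total`,
#'   `sd_whole`.
#' @export
resample_se_curve <- function(dataset, trait, n_grid = NULL, reps = 4999,
                              seed = NULL) {
  stopifnot(inherits(dataset, "trait_dataset"))
  if (!trait %in% trait_names(dataset)) {
    stop("trait '", trait, "' not in dataset", call. = FALSE)
  }
  if (reps < 2) stop("reps must be >= 2", call. = FALSE)
  y <- as.data.frame(dataset)[[trait]]
  N <- length(y)
  if (is.null(n_grid)) n_grid <- seq.int(2L, N)
  n_grid <- sort(unique(as.integer(n_grid)))
  if (any(n_grid > N)) stop("sample sizes exceed the dataset size ", N, call. = FALSE)
  if (any(n_grid < 1L)) stop("sample sizes must be >= 1", call. = FALSE)
  if (any(n_grid == 1L)) {
    warning("n = 1 has no standard error and is excluded from the curve")
    n_grid <- n_grid[n_grid > 1L]
  }
  if (length(n_grid) < 1L) stop("empty sample-size grid", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  mean_se <- mean_cv <- numeric(length(n_grid))
  for (g in seq_along(n_grid)) {
    n <- n_grid[g]
    idx <- vapply(seq_len(reps), function(i) sample.int(N, n), integer(n))
    x <- matrix(y[idx], n, reps)
    m <- colMeans(x)
    sdev <- sqrt(pmax(colSums(x * x) - n * m * m, 0) / (n - 1))
    mean_se[g] <- mean(sdev / sqrt(n))
    mean_cv[g] <- mean(sdev / m)
  }
  out <- data.frame(n = n_grid, mean_se = mean_se, mean_cv = mean_cv)
  attr(out, "trait") <- trait
  attr(out, "reps") <- as.integer(reps)
  attr(out, "seed") <- seed
  attr(out, "n_total") <- N
  attr(out, "sd_whole") <- stats::sd(y)
  class(out) <- c("precision_curve", "data.frame")
  out
}

# Broken-line fit with the breakpoint fixed at psi; returns rss and coefs.
.segmented_at <- function(x, y, psi) {
  X <- cbind(1, x, pmax(x - psi, 0))
  fit <- stats::lm.fit(X, y)
  list(rss = sum(fit$residuals^2), coef = fit$coefficients)
}

#' Segmented (broken-line) fit of a precision curve
#'
#' Fits `y = b0 + b1*n + b2*(n - psi)+` to the curve. The breakpoint is
#' initialized by an exhaustive search over interior grid points and then
#' refined by iterative linearization: the working model adds the gap
#' covariate `-I(n > psi)`, and each step updates
#' `psi <- psi + gamma/b2` until `|delta psi| < 1e-8` (at most 100
#' iterations). Two flex values are returned: `value_at_psi`, the
#' broken-line fit evaluated at the breakpoint, and `curve_value_at_psi`,
#' the observed curve linearly interpolated at the breakpoint. The latter
#' defines the minimum acceptable precision `SE_min` (on a steeply convex
#' SE curve the broken-line vertex dips below the curve itself; the
#' precision threshold is the SE the curve actually attains at the flex
#' point). A curve with no detectable slope change (the two-segment fit
#' does not improve on a single line) is flagged `converged = FALSE` with
#' diagnostic `"rss_flat"`.
#'
#' @param curve a `"precision_curve"`, or any data frame with the
#'   predictor in its first column and the response named by `response`.
#' @param response which column to fit: `"se"` (default) or `"cv"`.
#' @return list of class `"breakpoint_fit"`: `psi`, `value_at_psi`,
#'   `curve_value_at_psi`, `intercept`, `slope_left`, `slope_right`,
#'   `rss`, `converged`, `iterations`, `diagnostic`, `trait`, `response`.
#' @export
fit_breakpoint <- function(curve, response = c("se", "cv")) {
  response <- match.arg(response)
  x <- curve$n
  y <- if (response == "se") curve$mean_se else curve$mean_cv
  k <- length(x)
  if (k < 6L) stop("need at least 6 grid points to fit a breakpoint", call. = FALSE)
  if (is.unsorted(x, strictly = TRUE)) stop("grid must be strictly increasing", call. = FALSE)

  # single-line reference and exhaustive interior grid search
  line_fit <- stats::lm.fit(cbind(1, x), y)
  rss_line <- sum(line_fit$residuals^2)
  cand <- x[seq.int(2L, k - 1L)]
  grid_rss <- vapply(cand, function(p) .segmented_at(x, y, p)$rss, numeric(1))
  best <- which.min(grid_rss)
  psi <- cand[best]
  rss_grid_best <- grid_rss[best]

  scale_y <- sum((y - mean(y))^2)
  if (!(rss_grid_best < rss_line - 1e-12 * max(scale_y, 1e-300))) {
    co <- line_fit$coefficients
    fit <- list(psi = psi, value_at_psi = unname(co[1] + co[2] * psi),
                curve_value_at_psi = stats::approx(x, y, xout = psi)$y,
                intercept = unname(co[1]), slope_left = unname(co[2]),
                slope_right = unname(co[2]), rss = rss_line,
                converged = FALSE, iterations = 0L, diagnostic = "rss_flat",
                trait = attr(curve, "trait"), response = response)
    class(fit) <- "breakpoint_fit"
    return(fit)
  }

  # Iterative linearization on the gap coefficient
  lo <- min(x); hi <- max(x)
  converged <- FALSE
  iter <- 0L
  psi_cur <- psi
  for (iter in seq_len(100L)) {
    U <- pmax(x - psi_cur, 0)
    V <- -as.numeric(x > psi_cur)
    fit_w <- stats::lm.fit(cbind(1, x, U, V), y)
    co <- fit_w$coefficients
    b2 <- co[3]; gam <- co[4]
    if (!is.finite(b2) || !is.finite(gam) || abs(b2) < 1e-300) break
    step <- gam / b2
    psi_new <- psi_cur + step
    if (!is.finite(psi_new) || psi_new <= lo || psi_new >= hi) break
    if (abs(psi_new - psi_cur) < 1e-8) {
      psi_cur <- psi_new
      converged <- TRUE
      break
    }
    psi_cur <- psi_new
  }

  if (converged) {
    seg <- .segmented_at(x, y, psi_cur)
    if (seg$rss <= rss_grid_best + 1e-12 * max(scale_y, 1e-300)) {
      psi <- psi_cur
      final <- seg
    } else {
      final <- .segmented_at(x, y, psi)   # grid point beat the iteration
      converged <- FALSE
    }
  } else {
    final <- .segmented_at(x, y, psi)
  }
  co <- final$coef
  fit <- list(psi = unname(psi), value_at_psi = unname(co[1] + co[2] * psi),
              curve_value_at_psi = stats::approx(x, y, xout = psi)$y,
              intercept = unname(co[1]), slope_left = unname(co[2]),
              slope_right = unname(co[2] + co[3]), rss = final$rss,
              converged = converged, iterations = iter,
              diagnostic = if (converged) "ok" else "grid_fallback",
              trait = attr(curve, "trait"), response = response)
  class(fit) <- "breakpoint_fit"
  fit
}

#' @export
print.breakpoint_fit <- function(x, ...) {
  cat("Segmented fit (", x$response, if (!is.null(x$trait)) paste0(", ", x$trait),
      "): psi = ", format(x$psi, digits = 6),
      ", fitted value at psi = ", format(x$value_at_psi, digits = 6),
      ", curve value at psi = ", format(x$curve_value_at_psi, digits = 6),
      if (!x$converged) paste0("  [", x$diagnostic, "]"), "\n", sep = "")
  invisible(x)
}
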