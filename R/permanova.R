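# Univariate PERMANOVA over the nested canopy/plot design.  With a
# Euclidean distance and a single response, permutational sums of squares
# equal classical ANOVA sums of squares computed by orthogonal projection
# onto each term's model space; significance comes from Freedman-Lane
# permutation of reduced-model residuals.

#' Model terms of the nested canopy design
#'
#' Returns the ordered term list used throughout: quadrat, height class,
#' crown position (E/I), individual nested in quadrat, and all printed
#' interactions, ending with the four-way individual(quadrat) x h_class x
#' position term. Each term is described by the design columns whose full
#' crossing spans its cell space; nesting of individual in quadrat is
#' expressed by including `quadrat` among the individual term's columns.
#'
#' @param include_interactions if `FALSE`, only the four main terms.
#' @return named list of character vectors (term -> design columns).
#' @export
default_model_terms <- function(include_interactions = TRUE) {
  main <- list(
    quadrat  = "quadrat",
    h_class  = "h_class",
    position = "position",
    `individual(quadrat)` = c("quadrat", "individual")
  )
  if (!include_interactions) return(main)
  c(main, list(
    `quadrat:h_class`  = c("quadrat", "h_class"),
    `quadrat:position` = c("quadrat", "position"),
    `h_class:position` = c("h_class", "position"),
    `individual(quadrat):h_class`  = c("quadrat", "individual", "h_class"),
    `individual(quadrat):position` = c("quadrat", "individual", "position"),
    `quadrat:h_class:position` = c("quadrat", "h_class", "position"),
    `individual(quadrat):h_class:position` =
      c("quadrat", "individual", "h_class", "position")
  ))
}

# Indicator (cell-means) matrix spanning the crossing of `cols` in `data`.
.term_indicator <- function(data, cols) {
  f <- interaction(data[cols], drop = TRUE, lex.order = TRUE)
  if (nlevels(f) < 2L) return(matrix(1, nrow(data), 1))
  m <- stats::model.matrix(~ 0 + f)
  dimnames(m) <- NULL
  m
}

# Incremental term bases: the cell-indicator block of each term,
# residualized against the intercept and every term it contains (its
# marginal terms), so that e.g. the individual(quadrat) x h_class block no
# longer spans the h_class main effect.  Reduced models for partial SS and
# Freedman-Lane permutation drop exactly one term's incremental space.
.term_bases <- function(data, terms) {
  blocks <- lapply(terms, function(cols) .term_indicator(data, cols))
  n <- nrow(data)
  ones <- matrix(1, n, 1)
  bases <- vector("list", length(terms))
  for (j in seq_along(terms)) {
    contained <- vapply(seq_along(terms), function(i) {
      i != j && all(terms[[i]] %in% terms[[j]]) &&
        length(terms[[i]]) < length(terms[[j]])
    }, logical(1))
    M <- do.call(cbind, c(list(ones), blocks[contained]))
    Z <- qr.resid(qr(M), blocks[[j]])
    # columns fully absorbed by the marginal terms are aliased: drop them,
    # so rank bookkeeping sees the term's true incremental dimension
    orig_norm <- sqrt(colSums(blocks[[j]]^2))
    keep <- sqrt(colSums(Z^2)) > 1e-8 * pmax(orig_norm, 1)
    bases[[j]] <- Z[, keep, drop = FALSE]
  }
  names(bases) <- names(terms)
  bases
}

# RSS and rank of the least-squares fit of y on X (X always has columns).
.proj_rss <- function(X, y) {
  q <- qr(X)
  r <- q$rank
  if (r >= length(y)) return(list(rss = 0, rank = r))
  qty <- qr.qty(q, y)
  list(rss = sum(qty[seq.int(r + 1L, length(y))]^2), rank = r)
}

#' Permutational ANOVA table (sums of squares, pseudo-F)
#'
#' Partitions the corrected total sum of squares of one trait over the
#' given terms by orthogonal projection. `"sequential"` (the default)
#' attributes to each term its extra SS in the stated order; `"partial"`
#' attributes the extra SS of each term given all other terms. On balanced
#' designs the two coincide. Pseudo-F is the term mean square over the
#' residual mean square (all factors treated as fixed); per-term variance
#' percentages are SS ratios against the corrected total.
#'
#' @param dataset a [trait_dataset].
#' @param trait trait column to analyse.
#' @param terms ordered named list of term definitions, as from
#'   [default_model_terms()].
#' @param ss_type `"sequential"` or `"partial"`.
#' @return data frame of class `"itv_anova"` with one row per term plus a
#'   `Residual` row: columns `term`, `df`, `SS`, `MS`, `pseudo_F`,
#'   `variance_pct`. Attributes carry the trait, total SS, term
#'   definitions, and the source data needed for permutation tests.
#' @export
fit_anova <- function(dataset, trait, terms = default_model_terms(),
                      ss_type = c("sequential", "partial")) {
  ss_type <- match.arg(ss_type)
  stopifnot(inherits(dataset, "trait_dataset"))
  if (!trait %in% trait_names(dataset)) {
    stop("trait '", trait, "' not in dataset", call. = FALSE)
  }
  d <- as.data.frame(dataset)
  y <- d[[trait]]
  n <- length(y)
  for (tm in names(terms)) {
    miss <- setdiff(terms[[tm]], names(d))
    if (length(miss) > 0L) {
      stop("term '", tm, "' uses missing column(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
  }

  blocks <- .term_bases(d, terms)
  ones <- matrix(1, n, 1)
  ss_total <- sum((y - mean(y))^2)

  full <- .proj_rss(do.call(cbind, c(list(ones), blocks)), y)
  df_resid <- n - full$rank
  if (df_resid <= 0) stop("design leaves no residual degrees of freedom", call. = FALSE)

  k <- length(blocks)
  df <- ss <- numeric(k)
  if (ss_type == "sequential") {
    prev <- .proj_rss(ones, y)
    X <- ones
    for (j in seq_len(k)) {
      X <- cbind(X, blocks[[j]])
      cur <- .proj_rss(X, y)
      df[j] <- cur$rank - prev$rank
      ss[j] <- prev$rss - cur$rss
      if (df[j] < 1L) {
        stop("term '", names(terms)[j],
             "' is aliased (adds no degrees of freedom) given preceding terms",
             call. = FALSE)
      }
      prev <- cur
    }
  } else {
    for (j in seq_len(k)) {
      red <- .proj_rss(do.call(cbind, c(list(ones), blocks[-j])), y)
      df[j] <- full$rank - red$rank
      ss[j] <- red$rss - full$rss
      if (df[j] < 1L) {
        stop("term '", names(terms)[j],
             "' is aliased (adds no degrees of freedom) given the other terms",
             call. = FALSE)
      }
    }
  }
  ss <- pmax(ss, 0)
  ss_resid <- full$rss
  ms <- ss / df
  ms_resid <- ss_resid / df_resid
  constant_y <- ss_total < max(1e-24, 1e-18 * n * (mean(y)^2 + 1))
  pseudo_f <- if (constant_y || ms_resid <= 0) rep(NA_real_, k) else ms / ms_resid

  tab <- data.frame(
    term = c(names(terms), "Residual"),
    df = c(df, df_resid),
    SS = c(ss, ss_resid),
    MS = c(ms, ms_resid),
    pseudo_F = c(pseudo_f, NA_real_),
    variance_pct = if (constant_y) c(rep(0, k), 0)
                   else c(ss, ss_resid) / ss_total * 100,
    stringsAsFactors = FALSE
  )
  rownames(tab) <- NULL
  attr(tab, "trait") <- trait
  attr(tab, "ss_type") <- ss_type
  attr(tab, "ss_total") <- ss_total
  attr(tab, "nobs") <- n
  attr(tab, "terms") <- terms
  attr(tab, "data") <- d[, unique(c(unlist(terms), trait)), drop = FALSE]
  class(tab) <- c("itv_anova", "data.frame")
  tab
}

#' @export
print.itv_anova <- function(x, digits = 4, ...) {
  cat("Permutational ANOVA (Euclidean distance), trait:",
      attr(x, "trait"), "-", attr(x, "ss_type"), "SS\n")
  y <- as.data.frame(x)
  y$SS <- signif(y$SS, digits); y$MS <- signif(y$MS, digits)
  y$pseudo_F <- signif(y$pseudo_F, digits)
  y$variance_pct <- round(y$variance_pct, 2)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Freedman-Lane permutation p-values
#'
#' For each term, fits the reduced model holding every other term, permutes
#' the reduced-model residuals, adds them back onto the reduced-model
#' fitted values, and recomputes the pseudo-F of the tested term (its
#' extra SS given the reduced model, over the full-model residual mean
#' square). The p-value is `(1 + #permuted F >= observed F) / (1 + n_perm)`.
#' The observed statistic is recomputed in the same extra-SS form, which
#' coincides with the table's pseudo-F on balanced designs and for
#' single-term models.
#'
#' @param table an `"itv_anova"` from [fit_anova()].
#' @param n_perm number of random permutations (default 999).
#' @param seed integer seed; the permutation draw is deterministic given it.
#' @param permutations optional integer matrix (one permutation of
#'   `1:n` per row) used verbatim instead of random draws, e.g. a full
#'   enumeration; the identity row should be omitted, the `+1` term of the
#'   p-value formula accounts for it.
#' @return the table with a `p_perm` column filled in for every term.
#' @export
permutation_pvalues <- function(table, n_perm = 999, seed = NULL,
                                permutations = NULL) {
  stopifnot(inherits(table, "itv_anova"))
  d <- attr(table, "data")
  terms <- attr(table, "terms")
  trait <- attr(table, "trait")
  y <- d[[trait]]
  n <- length(y)

  if (is.null(permutations)) {
    if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
    if (!is.null(seed)) set.seed(seed)
    permutations <- t(vapply(seq_len(n_perm), function(i) sample.int(n),
                             integer(n)))
  } else {
    permutations <- as.matrix(permutations)
    if (ncol(permutations) != n) {
      stop("`permutations` must have one column per observation", call. = FALSE)
    }
    n_perm <- nrow(permutations)
  }

  if (sum((y - mean(y))^2) < max(1e-24, 1e-18 * n * (mean(y)^2 + 1))) {
    table$p_perm <- c(rep(1, length(terms)), NA_real_)
    attr(table, "n_perm") <- if (is.null(permutations)) n_perm else nrow(permutations)
    attr(table, "perm_seed") <- seed
    return(table)
  }

  blocks <- .term_bases(d, terms)
  ones <- matrix(1, n, 1)
  qr_full <- qr(do.call(cbind, c(list(ones), blocks)))
  r_full <- qr_full$rank
  df_resid <- n - r_full

  k <- length(blocks)
  p <- numeric(k)
  for (j in seq_len(k)) {
    qr_red <- qr(do.call(cbind, c(list(ones), blocks[-j])))
    r_red <- qr_red$rank
    df_j <- r_full - r_red

    rss_of <- function(qrobj, r, Y) {
      qty <- qr.qty(qrobj, Y)
      if (is.matrix(Y)) colSums(qty[seq.int(r + 1L, n), , drop = FALSE]^2)
      else sum(qty[seq.int(r + 1L, n)]^2)
    }
    rss_red_obs <- rss_of(qr_red, r_red, y)
    rss_full_obs <- rss_of(qr_full, r_full, y)
    f_obs <- ((rss_red_obs - rss_full_obs) / df_j) / (rss_full_obs / df_resid)

    fitted_red <- y - qr.resid(qr_red, y)
    res_red <- y - fitted_red
    Yp <- fitted_red + matrix(res_red[t(permutations)], n, n_perm)
    rss_red_p <- rss_of(qr_red, r_red, Yp)
    rss_full_p <- rss_of(qr_full, r_full, Yp)
    f_perm <- ((rss_red_p - rss_full_p) / df_j) / (rss_full_p / df_resid)

    if (!is.finite(f_obs)) {
      p[j] <- 1
    } else {
      tol <- 1e-12 * (abs(f_obs) + 1)
      p[j] <- (1 + sum(f_perm >= f_obs - tol, na.rm = TRUE)) / (1 + n_perm)
    }
  }
  table$p_perm <- c(p, NA_real_)
  attr(table, "n_perm") <- n_perm
  attr(table, "perm_seed") <- seed
  table
}

#' Per-term variance percentages
#'
#' SS of each term (and the residual) divided by the corrected total SS,
#' times 100. For sequential tables these sum to 100.
#'
#' @param table an `"itv_anova"`.
#' @return named numeric vector of percentages.
#' @export
variance_percentages <- function(table) {
  stopifnot(inherits(table, "itv_anova"))
  stats::setNames(table$variance_pct, table$term)
}

#' Canopy- versus individual-related variance groups
#'
#' Groups the per-term percentages into `canopy` (every term involving
#' height class or crown position, including their interactions with
#' quadrat or individual), `individual` (terms involving only quadrat
#' and/or individual), and `residual`.
#'
#' @param table an `"itv_anova"`.
#' @return named numeric vector `c(canopy=, individual=, residual=)`.
#' @export
grouped_variance_percentages <- function(table) {
  stopifnot(inherits(table, "itv_anova"))
  terms <- attr(table, "terms")
  pct <- stats::setNames(table$variance_pct, table$term)
  canopy_terms <- names(terms)[vapply(terms, function(cols)
    any(c("h_class", "position") %in% cols), logical(1))]
  ind_terms <- setdiff(names(terms), canopy_terms)
  c(canopy = sum(pct[canopy_terms]),
    individual = sum(pct[ind_terms]),
    residual = unname(pct["Residual"]))
}
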