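# Leaf-level trait tables: construction, validation, I/O, design summaries.

.FACTOR_COLS <- c("quadrat", "individual", "h_class", "position", "exposure")
.KEY_COLS    <- c("quadrat", "individual", "leaf_id")
.H_LEVELS    <- c("a", "b")
.POS_LEVELS  <- c("E", "I")
.EXP_LEVELS  <- c("N", "S", "E", "W")

#' Construct and validate a leaf-trait dataset
#'
#' A trait dataset is a data frame with one row per leaf pair and columns
#' `leaf_id`, `quadrat`, `individual` (labels unique within quadrat),
#' `h_class` (canopy height class, `"a"` = base to 2.5 m, `"b"` = 2.5 m to
#' top), `position` (`"E"` external / `"I"` internal crown stratum),
#' `exposure` (`"N"/"S"/"E"/"W"`), plus one numeric column per trait.
#' Trait values must be finite and strictly positive; osmotic potential is
#' stored as the positive magnitude of a negative potential (units -MPa).
#'
#' @param data data frame holding the columns above.
#' @param trait_names character vector naming the trait columns (e.g.
#'   `c("sla", "pi")`).
#' @return The validated data frame with class `"trait_dataset"` and the
#'   trait names attached as attribute `trait_names`.
#' @export
trait_dataset <- function(data, trait_names) {
  if (!is.data.frame(data)) stop("`data` must be a data.frame", call. = FALSE)
  if (nrow(data) < 1L) stop("dataset must contain at least one observation", call. = FALSE)
  if (length(trait_names) < 1L) stop("`trait_names` must name at least one trait column", call. = FALSE)
  need <- c("leaf_id", .FACTOR_COLS, trait_names)
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols) > 0L) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  for (col in c("leaf_id", .FACTOR_COLS)) data[[col]] <- as.character(data[[col]])

  .check_levels(data, "h_class", .H_LEVELS)
  .check_levels(data, "position", .POS_LEVELS)
  .check_levels(data, "exposure", .EXP_LEVELS)

  for (tr in trait_names) {
    v <- data[[tr]]
    if (!is.numeric(v)) stop("trait column '", tr, "' is not numeric", call. = FALSE)
    bad <- which(!is.finite(v))
    if (length(bad) > 0L) {
      stop("trait '", tr, "' has non-finite value(s) at row(s) ",
           paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
    }
    bad <- which(v <= 0)
    if (length(bad) > 0L) {
      stop("trait '", tr, "' must be strictly positive; violated at row(s) ",
           paste(utils::head(bad, 5L), collapse = ", "),
           " (osmotic potential is stored as a positive magnitude)", call. = FALSE)
    }
  }

  key <- do.call(paste, c(data[.KEY_COLS], sep = "\r"))
  if (anyDuplicated(key)) {
    stop("(quadrat, individual, leaf_id) must be unique; duplicated at row(s) ",
         paste(utils::head(which(duplicated(key)), 5L), collapse = ", "), call. = FALSE)
  }

  rownames(data) <- NULL
  attr(data, "trait_names") <- as.character(trait_names)
  class(data) <- c("trait_dataset", "data.frame")
  data
}

.check_levels <- function(data, col, levels) {
  bad <- which(!(data[[col]] %in% levels))
  if (length(bad) > 0L) {
    stop("column '", col, "' has illegal level '", data[[col]][bad[1L]],
         "' at row ", bad[1L], " (allowed: ", paste(levels, collapse = ", "), ")",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Trait names of a dataset
#' @param dataset a `trait_dataset`.
#' @return character vector of trait column names.
#' @export
trait_names <- function(dataset) attr(dataset, "trait_names")

#' Read a leaf-trait table from delimited text
#'
#' Expects a header row. Columns can be renamed through `col_map` when the
#' file does not use the canonical names (`quadrat`, `individual`,
#' `h_class`, `position`, `exposure`, `leaf_id`, and one column per trait).
#' If `leaf_id` is absent a running index within each individual is
#' created.
#'
#' @param path file to read.
#' @param trait_names trait columns to parse (default `c("sla", "pi")`).
#' @param sep field separator (default comma).
#' @param col_map named character vector mapping canonical name ->
#'   file column name, e.g. `c(quadrat = "plot")`.
#' @param pi_negative if `TRUE`, the `pi` column holds signed (negative)
#'   osmotic potentials and is negated on input to the positive-magnitude
#'   convention.
#' @return a validated [trait_dataset].
#' @export
read_trait_table <- function(path, trait_names = c("sla", "pi"), sep = ",",
                             col_map = NULL, pi_negative = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      src <- col_map[[canon]]
      if (!src %in% names(raw)) {
        stop("col_map points '", canon, "' at column '", src,
             "' which is not in the file", call. = FALSE)
      }
      names(raw)[names(raw) == src] <- canon
    }
  }
  need <- c(.FACTOR_COLS, trait_names)
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0L) {
    stop("file is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"leaf_id" %in% names(raw)) {
    raw$leaf_id <- stats::ave(seq_len(nrow(raw)),
                              paste(raw$quadrat, raw$individual, sep = "\r"),
                              FUN = seq_along)
    raw$leaf_id <- sprintf("L%02d", raw$leaf_id)
  }
  for (tr in trait_names) {
    parsed <- suppressWarnings(as.numeric(raw[[tr]]))
    bad <- which(is.na(parsed) & !is.na(raw[[tr]]) & nzchar(raw[[tr]]))
    if (length(bad) > 0L) {
      stop("trait column '", tr, "' is unparseable at row ", bad[1L],
           " (value '", raw[[tr]][bad[1L]], "')", call. = FALSE)
    }
    raw[[tr]] <- parsed
  }
  if (pi_negative && "pi" %in% trait_names) raw$pi <- -raw$pi
  trait_dataset(raw, trait_names)
}

#' Write a leaf-trait table as delimited text
#'
#' Numeric trait values are written with 15 significant digits so that a
#' read/write round trip preserves them to well below 1e-9.
#'
#' @param dataset a `trait_dataset`.
#' @param path output file.
#' @param sep field separator.
#' @return the path, invisibly.
#' @export
write_trait_table <- function(dataset, path, sep = ",") {
  stopifnot(inherits(dataset, "trait_dataset"))
  trs <- trait_names(dataset)
  if (length(trs) < 1L) stop("dataset has no trait columns to write", call. = FALSE)
  out <- as.data.frame(dataset)[, c("leaf_id", .FACTOR_COLS, trs)]
  for (tr in trs) out[[tr]] <- formatC(out[[tr]], digits = 15, format = "g")
  ok <- tryCatch({
    utils::write.table(out, path, sep = sep, quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("could not write '", path, "': ", conditionMessage(ok), call. = FALSE)
  invisible(path)
}

#' Summarize a sampling design
#'
#' Counts quadrats, individuals (total and per quadrat), leaves (total and
#' per individual) and leaves per canopy stratum (height class x
#' external/internal position), overall and per individual.
#'
#' @param dataset a `trait_dataset`.
#' @return a list of class `"design_summary"`.
#' @export
summarize_design <- function(dataset) {
  stopifnot(inherits(dataset, "trait_dataset"))
  d <- as.data.frame(dataset)
  ind_uid <- paste(d$quadrat, d$individual, sep = "/")
  per_quadrat <- tapply(ind_uid, d$quadrat, function(x) length(unique(x)))
  per_quadrat <- stats::setNames(as.integer(per_quadrat), names(per_quadrat))
  leaves_per_ind <- table(ind_uid)
  stratum <- table(h_class = d$h_class, position = d$position)
  per_ind_stratum <- table(individual = ind_uid,
                           stratum = paste0(d$h_class, d$position))
  out <- list(
    n_quadrats = length(unique(d$quadrat)),
    n_individuals = length(unique(ind_uid)),
    individuals_per_quadrat = per_quadrat[order(names(per_quadrat))],
    n_leaves = nrow(d),
    leaves_per_individual = leaves_per_ind,
    stratum_counts = stratum,
    per_individual_stratum = per_ind_stratum
  )
  stopifnot(sum(out$individuals_per_quadrat) == out$n_individuals,
            sum(out$leaves_per_individual) == out$n_leaves,
            sum(out$stratum_counts) == out$n_leaves)
  class(out) <- "design_summary"
  out
}

#' @export
print.design_summary <- function(x, ...) {
  cat("Sampling design:", x$n_leaves, "leaves from", x$n_individuals,
      "individuals in", x$n_quadrats, "quadrat(s)\n")
  cat("Individuals per quadrat:\n")
  print(x$individuals_per_quadrat)
  cat("Leaves per (h_class x position) stratum:\n")
  print(x$stratum_counts)
  invisible(x)
}

#' Specific leaf area
#'
#' SLA is fresh leaf area divided by leaf dry weight, in mm^2/mg.
#'
#' @param leaf_area fresh leaf area in mm^2 (positive).
#' @param dry_weight leaf dry weight in mg (positive).
#' @return SLA in mm^2/mg (vectorized).
#' @export
compute_sla <- function(leaf_area, dry_weight) {
  if (any(!is.finite(leaf_area)) || any(!is.finite(dry_weight))) {
    stop("leaf_area and dry_weight must be finite", call. = FALSE)
  }
  if (any(leaf_area <= 0)) stop("leaf_area must be > 0", call. = FALSE)
  if (any(dry_weight <= 0)) stop("dry_weight must be > 0", call. = FALSE)
  leaf_area / dry_weight
}
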