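#' Path-count tables
#'
#' The universal input of the package: for every binary intervention path of
#' a protocol, the number of women `N(path)` who followed it.  Counts are
#' stored for all `2^n` paths in canonical order (paths not supplied count
#' zero).
#'
#' @param counts Either a named numeric vector (names are binary path ids
#'   such as `"101"`, or comma-free flag strings matching
#'   `rownames(enumerate_paths(protocol))`), or a data frame with one 0/1
#'   column per protocol label plus a `count` column.
#' @param protocol An [intervention_protocol()].
#' @param stratum Optional stratum label (e.g. a Robson class) carried in
#'   the table metadata.
#' @return An object of class `path_count_table`: a list with elements
#'   `protocol`, `paths` (the canonical `2^n x n` flag matrix), `counts`
#'   (integer vector aligned with `paths`), `N` (total women) and
#'   `stratum`.
#' @examples
#' path_count_table(c("000" = 387, "100" = 160, "001" = 25))
#' @export
path_count_table <- function(counts, protocol = intervention_protocol(),
                             stratum = NULL) {
  protocol <- as_protocol(protocol)
  paths <- enumerate_paths(protocol)
  full <- integer(nrow(paths))
  names(full) <- rownames(paths)

  if (is.data.frame(counts)) {
    missing_cols <- setdiff(c(protocol$labels, "count"), names(counts))
    if (length(missing_cols))
      stop("count data frame lacks column(s): ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    flags <- as.matrix(counts[protocol$labels])
    check_binary_matrix(flags, rows = seq_len(nrow(flags)))
    ids <- path_id(flags)
    if (anyDuplicated(ids))
      stop("duplicate path rows in count table", call. = FALSE)
    vals <- counts$count
    names(vals) <- ids
    counts <- vals
  } else if (is.null(names(counts)) && length(counts) == nrow(paths)) {
    # unnamed full-length vector: assumed in canonical order
    names(counts) <- rownames(paths)
  }

  if (is.null(names(counts)))
    stop("counts must be named by binary path id (e.g. \"101\")",
         call. = FALSE)
  unknown <- setdiff(names(counts), names(full))
  if (length(unknown))
    stop("unknown path id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts)))
    stop("path counts must be nonnegative integers", call. = FALSE)
  full[names(counts)] <- as.integer(round(counts))

  structure(list(protocol = protocol, paths = paths, counts = full,
                 N = sum(full), stratum = stratum),
            class = "path_count_table")
}

check_binary_matrix <- function(flags, rows, cols = colnames(flags)) {
  bad <- which(!(flags %in% c(0, 1)) | is.na(flags))
  if (length(bad)) {
    i <- ((bad[1] - 1L) %% nrow(flags)) + 1L
    j <- ((bad[1] - 1L) %/% nrow(flags)) + 1L
    stop(sprintf("non-binary flag value %s at row %s, column '%s'",
                 flags[bad[1]], rows[i], cols[j]), call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.path_count_table <- function(x, ...) {
  cat("Path-count table (protocol ",
      paste(x$protocol$labels, collapse = ","), "): N = ", x$N,
      if (!is.null(x$stratum)) paste0(", stratum ", x$stratum), "\n",
      sep = "")
  print(as.data.frame(x))
  invisible(x)
}

#' @export
as.data.frame.path_count_table <- function(x, ...) {
  d <- as.data.frame(x$paths)
  d$treatments <- as.integer(rowSums(x$paths))
  d$count <- x$counts
  rownames(d) <- NULL
  d
}

stop_if_degenerate <- function(table) {
  if (table$N == 0L)
    stop("degenerate path-count table: N = 0 women", call. = FALSE)
  invisible(table)
}

#' Aggregate per-woman records into path-count tables
#'
#' Tallies a data frame of per-woman binary intervention flags into a
#' [path_count_table()], optionally one table per stratum (e.g. per Robson
#' class).  When the raw data carry separate `amniotomy` and `oxytocin`
#' flags instead of a single augmentation flag, the two are merged by
#' logical OR first (augmentation means either or both given after labour
#' onset).
#'
#' @param records Data frame with one row per woman and one 0/1 column per
#'   protocol label; optional columns `woman_id` and the stratum column.
#' @param protocol An [intervention_protocol()].
#' @param stratify_by Optional column name; when given, returns a named
#'   list of tables, one per observed stratum.  Strata must come from the
#'   Robson vocabulary when `stratify_by = "robson_class"`.
#' @param augmentation_from Character vector of raw column names merged by
#'   OR into the first protocol label when that label is absent from
#'   `records` (default `c("amniotomy", "oxytocin")`).
#' @return A `path_count_table`, or a named list of them when stratified.
#' @examples
#' recs <- data.frame(A = c(0, 1, 1), V = c(0, 0, 0), C = c(0, 0, 0))
#' path_table_from_records(recs)
#' @export
path_table_from_records <- function(records, protocol = intervention_protocol(),
                                    stratify_by = NULL,
                                    augmentation_from = c("amniotomy", "oxytocin")) {
  protocol <- as_protocol(protocol)
  records <- merge_augmentation(records, protocol$labels[1], augmentation_from)
  missing_cols <- setdiff(protocol$labels, names(records))
  if (length(missing_cols))
    stop("records lack protocol column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)

  if (!is.null(stratify_by)) {
    if (!stratify_by %in% names(records))
      stop("no stratum column '", stratify_by, "' in records", call. = FALSE)
    strata <- records[[stratify_by]]
    if (anyNA(strata))
      stop("missing stratum labels in column '", stratify_by, "'",
           call. = FALSE)
    if (identical(stratify_by, "robson_class")) {
      unknown <- setdiff(unique(strata), robson_classes())
      if (length(unknown))
        stop("unknown Robson class label(s): ",
             paste(unknown, collapse = ", "), call. = FALSE)
    }
    pieces <- split(records, strata, drop = TRUE)
    return(lapply(stats::setNames(names(pieces), names(pieces)), function(s) {
      out <- path_table_from_records(pieces[[s]], protocol)
      out$stratum <- s
      out
    }))
  }

  flags <- as.matrix(records[protocol$labels])
  rows <- if ("woman_id" %in% names(records)) records$woman_id
          else seq_len(nrow(records))
  if (nrow(flags)) check_binary_matrix(flags, rows)
  storage.mode(flags) <- "integer"

  ids <- if (nrow(flags)) path_id(flags) else character(0)
  tab <- table(factor(ids, levels = rownames(enumerate_paths(protocol))))
  out <- path_count_table(stats::setNames(as.integer(tab), names(tab)),
                          protocol)
  if (out$N == 0L)
    warning("empty record set: degenerate table with N = 0", call. = FALSE)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

merge_augmentation <- function(records, into, from) {
  if (into %in% names(records)) return(records)
  if (!all(from %in% names(records))) return(records)
  vals <- as.matrix(records[from])
  if (nrow(vals)) check_binary_matrix(vals, seq_len(nrow(vals)))
  records[[into]] <- if (nrow(vals)) as.integer(apply(vals, 1, max)) else integer(0)
  records
}

#' Expand a path-count table back to per-woman records
#'
#' Inverse of [path_table_from_records()]: one row per woman, in canonical
#' path order.  Round-tripping a table through `expand_records()` and back
#' reproduces it exactly.
#'
#' @param table A [path_count_table()].
#' @return Data frame with one 0/1 column per protocol label.
#' @export
expand_records <- function(table) {
  stopifnot(inherits(table, "path_count_table"))
  idx <- rep(seq_len(nrow(table$paths)), times = table$counts)
  d <- as.data.frame(table$paths[idx, , drop = FALSE])
  rownames(d) <- NULL
  d
}
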