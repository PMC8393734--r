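# Data container and file I/O for grouped two-isoform splicing counts.
#
# A dataset holds, for M cells and N splicing events, three M x N count
# matrices (reads unique to isoform 1, reads unique to isoform 2, and
# ambiguous reads) together with a per-event 2 x 3 effective-length matrix.
# On disk the three matrices are stored as Matrix Market files with events
# as rows and cells as columns; in memory we keep the transposed (cells x
# events) orientation used by the model.

# Coerce any matrix-like input to a numeric general CsparseMatrix.
.as_dgc <- function(m) {
  if (!methods::is(m, "Matrix")) m <- Matrix::Matrix(as.matrix(m), sparse = TRUE)
  m <- methods::as(methods::as(m, "CsparseMatrix"), "generalMatrix")
  if (!methods::is(m, "dMatrix")) m <- m * 1
  m
}

#' Construct a grouped splicing count dataset
#'
#' Bundles the three read-group count matrices with per-event effective
#' lengths and identifiers, and validates all structural invariants.
#'
#' @param iso1,iso2,ambiguous Cells x events count matrices (base or
#'   `Matrix` sparse matrices) of reads unique to isoform 1, unique to
#'   isoform 2, and ambiguous between the two. Counts must be non-negative
#'   integers.
#' @param lengths Per-event effective lengths: either an `N x 2 x 3` array
#'   (`lengths[g, h, k]` = number of read start positions on isoform `h` of
#'   event `g` yielding a read of group `k`) or an `N x 6` matrix with
#'   columns `l11, l12, l13, l21, l22, l23`. Required constraints:
#'   `l12 = l21 = 0` and `l13 = l23` for every event, and any event with
#'   group-1 (group-2) counts must have `l11 > 0` (`l22 > 0`).
#' @param cell_ids,event_ids Character identifiers; lengths must match the
#'   count matrix dimensions.
#' @param event_meta Optional per-event annotation `data.frame` (e.g. gene
#'   symbol); must have one row per event.
#'
#' @return An object of class `SplicingCountData`: a list with elements
#'   `counts` (list of three `dgCMatrix`), `lengths` (N x 2 x 3 array),
#'   `cell_ids`, `event_ids`, `event_meta`.
#' @export
#' @examples
#' s1 <- matrix(c(3, 0, 0, 0), 2, 2)
#' s2 <- matrix(0, 2, 2)
#' s3 <- matrix(1, 2, 2)
#' L <- effective_lengths_se(100, 50, 100, read_len = 10)
#' lengths <- matrix(rep(as.vector(t(L)), each = 2), 2, 6)
#' splicing_count_data(s1, s2, s3, lengths,
#'                     cell_ids = c("c1", "c2"), event_ids = c("e1", "e2"))
splicing_count_data <- function(iso1, iso2, ambiguous, lengths,
                                cell_ids, event_ids, event_meta = NULL) {
  counts <- list(iso1 = iso1, iso2 = iso2, ambiguous = ambiguous)
  counts <- lapply(counts, .as_dgc)
  if (is.matrix(lengths)) {
    if (ncol(lengths) != 6L)
      stop("'lengths' matrix must have 6 columns: l11, l12, l13, l21, l22, l23")
    lengths <- array(c(lengths[, 1], lengths[, 4], lengths[, 2],
                       lengths[, 5], lengths[, 3], lengths[, 6]),
                     dim = c(nrow(lengths), 2L, 3L))
  }
  x <- structure(list(counts = counts, lengths = lengths,
                      cell_ids = as.character(cell_ids),
                      event_ids = as.character(event_ids),
                      event_meta = event_meta),
                 class = "SplicingCountData")
  validate_scd(x)
}

#' Validate a SplicingCountData object
#'
#' Checks every structural invariant (consistent dimensions, non-negative
#' integral counts, the `l12 = l21 = 0` / `l13 = l23` length constraints,
#' and positive unique-read lengths wherever unique reads are observed).
#' Violations raise an error naming the offending coordinate; nothing is
#' silently fixed.
#'
#' @param x A `SplicingCountData` candidate.
#' @return `x`, invisibly unchanged, if valid.
#' @export
validate_scd <- function(x) {
  stopifnot(inherits(x, "SplicingCountData"))
  M <- length(x$cell_ids)
  N <- length(x$event_ids)
  group_names <- c("iso1", "iso2", "ambiguous")
  for (k in seq_len(3)) {
    m <- x$counts[[k]]
    if (nrow(m) != M || ncol(m) != N)
      stop(sprintf("count matrix '%s' is %d x %d but identifiers imply %d x %d",
                   group_names[k], nrow(m), ncol(m), M, N))
    tr <- Matrix::summary(m)
    bad <- which(tr$x < 0 | tr$x != round(tr$x))
    if (length(bad)) {
      b <- bad[1L]
      stop(sprintf(
        "invalid count %g in group '%s' at (cell = %s, event = %s): counts must be non-negative integers",
        tr$x[b], group_names[k], x$cell_ids[tr$i[b]], x$event_ids[tr$j[b]]))
    }
  }
  L <- x$lengths
  if (length(dim(L)) != 3L || dim(L)[1] != N || dim(L)[2] != 2L || dim(L)[3] != 3L)
    stop(sprintf("'lengths' must be an %d x 2 x 3 array", N))
  if (any(L < 0)) stop("effective lengths must be non-negative")
  if (any(L[, 1, 2] != 0) || any(L[, 2, 1] != 0)) {
    g <- which(L[, 1, 2] != 0 | L[, 2, 1] != 0)[1L]
    stop(sprintf("event %s violates l12 = l21 = 0", x$event_ids[g]))
  }
  if (any(L[, 1, 3] != L[, 2, 3])) {
    g <- which(L[, 1, 3] != L[, 2, 3])[1L]
    stop(sprintf("event %s violates l13 = l23", x$event_ids[g]))
  }
  has1 <- Matrix::colSums(x$counts$iso1) > 0
  has2 <- Matrix::colSums(x$counts$iso2) > 0
  if (any(has1 & L[, 1, 1] <= 0)) {
    g <- which(has1 & L[, 1, 1] <= 0)[1L]
    stop(sprintf("event %s has isoform-1-unique reads but l11 = 0", x$event_ids[g]))
  }
  if (any(has2 & L[, 2, 2] <= 0)) {
    g <- which(has2 & L[, 2, 2] <= 0)[1L]
    stop(sprintf("event %s has isoform-2-unique reads but l22 = 0", x$event_ids[g]))
  }
  if (!is.null(x$event_meta) && nrow(x$event_meta) != N)
    stop("'event_meta' must have one row per event")
  if (anyDuplicated(x$cell_ids)) stop("duplicated cell identifiers")
  if (anyDuplicated(x$event_ids)) stop("duplicated event identifiers")
  invisible(x)
}

#' @export
print.SplicingCountData <- function(x, ...) {
  tot <- sum(Matrix::colSums(x$counts$iso1)) + sum(Matrix::colSums(x$counts$iso2)) +
    sum(Matrix::colSums(x$counts$ambiguous))
  cat(sprintf("SplicingCountData: %d cells x %d events, %.0f reads total\n",
              length(x$cell_ids), length(x$event_ids), tot))
  invisible(x)
}

#' @export
dim.SplicingCountData <- function(x) {
  c(length(x$cell_ids), length(x$event_ids))
}

#' Subset a splicing count dataset
#'
#' @param x A `SplicingCountData`.
#' @param i Cell index (integer, logical or character).
#' @param j Event index (integer, logical or character).
#' @param ... Ignored.
#' @return The subset `SplicingCountData`, order preserved as given.
#' @export
`[.SplicingCountData` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_along(x$cell_ids)
  if (missing(j)) j <- seq_along(x$event_ids)
  if (is.character(i)) i <- match(i, x$cell_ids)
  if (is.character(j)) j <- match(j, x$event_ids)
  counts <- lapply(x$counts, function(m) m[i, j, drop = FALSE])
  meta <- if (is.null(x$event_meta)) NULL else x$event_meta[j, , drop = FALSE]
  structure(list(counts = counts,
                 lengths = x$lengths[j, , , drop = FALSE],
                 cell_ids = x$cell_ids[i], event_ids = x$event_ids[j],
                 event_meta = meta),
            class = "SplicingCountData")
}

#' Default event-filtering thresholds
#'
#' Events are kept when, pooling reads over all cells, they have at least
#' `min_total_reads` reads in the three groups combined, at least
#' `min_unique_reads` isoform-unique reads (groups 1 + 2), at least
#' `min_cells_with_unique` cells carrying at least one unique read, and a
#' pooled minor-isoform unique-read fraction of at least
#' `min_minor_fraction`.
#'
#' @param min_total_reads Minimum pooled total reads (default 50).
#' @param min_unique_reads Minimum pooled unique reads (default 10).
#' @param min_cells_with_unique Minimum number of cells with >= 1 unique
#'   read (default 30).
#' @param min_minor_fraction Minimum pooled minor-isoform fraction of
#'   unique reads (default 0.001); must be <= 0.5.
#' @return A `filter_thresholds` list.
#' @export
filter_thresholds <- function(min_total_reads = 50L, min_unique_reads = 10L,
                              min_cells_with_unique = 30L,
                              min_minor_fraction = 0.001) {
  stopifnot(min_total_reads >= 0, min_unique_reads >= 0,
            min_cells_with_unique >= 0,
            min_minor_fraction >= 0, min_minor_fraction <= 0.5)
  structure(list(min_total_reads = as.integer(min_total_reads),
                 min_unique_reads = as.integer(min_unique_reads),
                 min_cells_with_unique = as.integer(min_cells_with_unique),
                 min_minor_fraction = min_minor_fraction),
            class = "filter_thresholds")
}

#' Filter uninformative splicing events
#'
#' Applies the four pooled-count rules of [filter_thresholds()] and reports,
#' for each dropped event, the first rule it failed (rules are checked in
#' the order total reads, unique reads, cells with unique reads, minor
#' fraction). An event with zero unique reads fails the minor-fraction rule
#' by convention (its fraction is defined as 0), though such events always
#' fail the unique-read rule first under positive thresholds. Cells are
#' never filtered and the order of surviving events is unchanged, so the
#' operation is idempotent.
#'
#' @param data A `SplicingCountData`.
#' @param thresholds A [filter_thresholds()] list.
#' @return A list with `data` (the filtered `SplicingCountData`) and
#'   `report`, a `data.frame` with one row per input event and columns
#'   `event_id`, `kept`, `rule` (`NA` for kept events; otherwise one of
#'   `"total_reads"`, `"unique_reads"`, `"cells_with_unique"`,
#'   `"minor_fraction"`).
#' @export
filter_events <- function(data, thresholds = filter_thresholds()) {
  validate_scd(data)
  stopifnot(inherits(thresholds, "filter_thresholds"))
  c1 <- Matrix::colSums(data$counts$iso1)
  c2 <- Matrix::colSums(data$counts$iso2)
  c3 <- Matrix::colSums(data$counts$ambiguous)
  uniq <- c1 + c2
  total <- uniq + c3
  n_cells_uniq <- Matrix::colSums((data$counts$iso1 + data$counts$iso2) > 0)
  minor <- ifelse(uniq > 0, pmin(c1, c2) / uniq, 0)

  rule <- rep(NA_character_, length(total))
  rule[is.na(rule) & total < thresholds$min_total_reads] <- "total_reads"
  rule[is.na(rule) & uniq < thresholds$min_unique_reads] <- "unique_reads"
  rule[is.na(rule) & n_cells_uniq < thresholds$min_cells_with_unique] <- "cells_with_unique"
  rule[is.na(rule) & minor < thresholds$min_minor_fraction] <- "minor_fraction"
  kept <- is.na(rule)
  report <- data.frame(event_id = data$event_ids, kept = kept, rule = rule,
                       stringsAsFactors = FALSE)
  list(data = data[, which(kept)], report = report)
}

.read_id_tsv <- function(path) {
  x <- utils::read.delim(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  x
}

#' Read a grouped splicing count dataset from a directory
#'
#' Expects `isoform1.mtx`, `isoform2.mtx`, `ambiguous.mtx` (Matrix Market,
#' events as rows, cells as columns), `cells.tsv` (column `cell_id`),
#' `events.tsv` (column `event_id` plus optional annotation columns) and
#' `lengths.tsv` (columns `event_id, l11, l12, l13, l21, l22, l23`).
#'
#' @param dir Directory containing the files above.
#' @return A validated `SplicingCountData`.
#' @export
load_splice_counts <- function(dir) {
  paths <- file.path(dir, c("isoform1.mtx", "isoform2.mtx", "ambiguous.mtx",
                            "cells.tsv", "events.tsv", "lengths.tsv"))
  names(paths) <- basename(paths)
  missing <- !file.exists(paths)
  if (any(missing))
    stop("missing input file(s): ", paste(paths[missing], collapse = ", "))
  mats <- lapply(paths[1:3], Matrix::readMM)
  dims <- vapply(mats, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    off <- which(dims[1, ] != dims[1, 1] | dims[2, ] != dims[2, 1])[1L]
    stop(sprintf("dimension mismatch in '%s': %d x %d, expected %d x %d",
                 names(paths)[off], dims[1, off], dims[2, off],
                 dims[1, 1], dims[2, 1]))
  }
  cells <- .read_id_tsv(paths["cells.tsv"])
  events <- .read_id_tsv(paths["events.tsv"])
  if (nrow(cells) != dims[2, 1])
    stop(sprintf("dimension mismatch in 'cells.tsv': %d cells listed, matrices have %d columns",
                 nrow(cells), dims[2, 1]))
  if (nrow(events) != dims[1, 1])
    stop(sprintf("dimension mismatch in 'events.tsv': %d events listed, matrices have %d rows",
                 nrow(events), dims[1, 1]))
  len <- utils::read.delim(paths["lengths.tsv"], sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("event_id", "l11", "l12", "l13", "l21", "l22", "l23")
  if (!all(need %in% names(len)))
    stop("'lengths.tsv' must have columns ", paste(need, collapse = ", "))
  if (nrow(len) != nrow(events))
    stop(sprintf("dimension mismatch in 'lengths.tsv': %d rows, expected %d",
                 nrow(len), nrow(events)))
  idx <- match(events$event_id, len$event_id)
  if (anyNA(idx)) stop("'lengths.tsv' is missing events: ",
                       paste(utils::head(events$event_id[is.na(idx)], 3), collapse = ", "))
  len <- len[idx, ]
  splicing_count_data(Matrix::t(mats[[1]]), Matrix::t(mats[[2]]),
                      Matrix::t(mats[[3]]),
                      as.matrix(len[, c("l11", "l12", "l13", "l21", "l22", "l23")]),
                      cell_ids = cells$cell_id, event_ids = events$event_id,
                      event_meta = events)
}

#' Write a grouped splicing count dataset to a directory
#'
#' Inverse of [load_splice_counts()]; files are written in the same
#' events x cells Matrix Market orientation.
#'
#' @param data A `SplicingCountData`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_splice_counts <- function(data, dir) {
  validate_scd(data)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Matrix::writeMM(Matrix::t(data$counts$iso1), file.path(dir, "isoform1.mtx"))
  Matrix::writeMM(Matrix::t(data$counts$iso2), file.path(dir, "isoform2.mtx"))
  Matrix::writeMM(Matrix::t(data$counts$ambiguous), file.path(dir, "ambiguous.mtx"))
  utils::write.table(data.frame(cell_id = data$cell_ids),
                     file.path(dir, "cells.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  meta <- if (is.null(data$event_meta))
    data.frame(event_id = data$event_ids) else data$event_meta
  utils::write.table(meta, file.path(dir, "events.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  L <- data$lengths
  utils::write.table(data.frame(event_id = data$event_ids,
                                l11 = L[, 1, 1], l12 = L[, 1, 2], l13 = L[, 1, 3],
                                l21 = L[, 2, 1], l22 = L[, 2, 2], l23 = L[, 2, 3]),
                     file.path(dir, "lengths.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
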