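# RNA-velocity support: spliced/unspliced counts treated as a two-isoform
# event (PSI = spliced fraction), one-vs-rest differential momentum gene
# detection, and the cross-boundary directedness (CBDir) score for
# externally computed velocity fields.

#' Recast spliced/unspliced counts as a two-isoform splicing dataset
#'
#' Group 1 = spliced, group 2 = unspliced, group 3 empty; all genes get
#' the unit effective-length matrix `[[1,0,0],[0,1,0]]`, so PSI is the
#' spliced fraction.
#'
#' @param spliced,unspliced Cells x genes count matrices with matching
#'   dimensions (and dimnames, when present).
#' @return A validated `SplicingCountData`.
#' @export
velocity_to_splicing <- function(spliced, unspliced) {
  if (!all(dim(spliced) == dim(unspliced)))
    stop(sprintf("shape mismatch: spliced is %d x %d, unspliced is %d x %d",
                 nrow(spliced), ncol(spliced), nrow(unspliced), ncol(unspliced)))
  M <- nrow(spliced); N <- ncol(spliced)
  cell_ids <- if (!is.null(rownames(spliced))) rownames(spliced)
              else sprintf("cell%d", seq_len(M))
  gene_ids <- if (!is.null(colnames(spliced))) colnames(spliced)
              else sprintf("gene%d", seq_len(N))
  Lv <- velocity_lengths()
  lengths <- matrix(rep(c(Lv[1, ], Lv[2, ]), each = N), N, 6)
  zero <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                               dims = c(M, N))
  splicing_count_data(spliced, unspliced, zero, lengths,
                      cell_ids = cell_ids, event_ids = gene_ids)
}

#' Per-cell gene detection rate
#'
#' Fraction of genes with at least one read (spliced + unspliced) in each
#' cell; intended as an additional cell covariate in differential momentum
#' tests to absorb coverage differences.
#'
#' @param spliced,unspliced Cells x genes count matrices.
#' @return Numeric vector of length `nrow(spliced)`, entries in `[0, 1]`.
#' @export
detection_rate <- function(spliced, unspliced) {
  if (!all(dim(spliced) == dim(unspliced)))
    stop("shape mismatch between 'spliced' and 'unspliced'")
  tot <- spliced + unspliced
  as.numeric(Matrix::rowSums(tot > 0)) / ncol(spliced)
}

#' Detect differential momentum genes (one cell group vs rest)
#'
#' For each tested group, fits the cell-covariate model with intercept,
#' gene detection rate and the one-vs-rest group indicator, against the
#' nested model without the indicator, and reports per-gene ELBO gains.
#' Genes exceeding the threshold (default 5) in any group are candidate
#' differential momentum genes.
#'
#' @param spliced,unspliced Cells x genes count matrices.
#' @param groups Per-cell group labels (factor or character).
#' @param test_groups Levels to test one-vs-rest (default: all levels).
#' @param config A [fit_config()] (mode forced to `"mode2_diff"`).
#' @param threshold ELBO-gain hit threshold (default 5).
#' @param use_detection_rate Include the detection-rate covariate
#'   (default TRUE).
#' @return A `diff_table` with `feature` naming the tested group.
#' @export
detect_dmg <- function(spliced, unspliced, groups, test_groups = NULL,
                       config = fit_config(mode = "mode2_diff"),
                       threshold = 5, use_detection_rate = TRUE) {
  groups <- as.factor(groups)
  if (length(groups) != nrow(spliced))
    stop("'groups' must have one label per cell")
  if (is.null(test_groups)) test_groups <- levels(groups)
  data <- velocity_to_splicing(spliced, unspliced)
  out <- vector("list", length(test_groups))
  for (i in seq_along(test_groups)) {
    g <- test_groups[i]
    Y <- cbind(intercept = 1,
               indicator = as.numeric(groups == g))
    if (use_detection_rate)
      Y <- cbind(Y[, "intercept", drop = FALSE],
                 det_rate = detection_rate(spliced, unspliced),
                 indicator = Y[, "indicator"])
    tab <- elbo_gain_test(data, Y, "indicator", config = config,
                          threshold = threshold)
    tab$feature <- as.character(g)
    out[[i]] <- tab
  }
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  call_hits(tab, threshold)
}

#' k-nearest-neighbour sets in an embedding
#'
#' Simple Euclidean fallback for when the upstream velocity pipeline's
#' neighbour graph is not available. Self is excluded.
#'
#' @param positions Cells x d coordinate matrix.
#' @param k Number of neighbours (default 30, capped at M - 1).
#' @return List of integer neighbour index vectors, one per cell.
#' @export
knn_neighbors <- function(positions, k = 30L) {
  M <- nrow(positions)
  k <- min(k, M - 1L)
  d2 <- as.matrix(stats::dist(positions))^2
  lapply(seq_len(M), function(c) {
    ord <- order(d2[c, ])
    setdiff(ord, c)[seq_len(k)]
  })
}

#' Cross-boundary directedness of a velocity field
#'
#' For each cell of group A with at least one group-B neighbour, the mean
#' cosine between its velocity vector and the displacement vectors towards
#' its B neighbours; the summary is the mean over scored cells. Scores lie
#' in `[-1, 1]`. Terms with a zero-norm velocity or zero displacement are
#' skipped (counted in `n_skipped`); A cells without B neighbours are
#' unscored and excluded from the mean.
#'
#' @param positions Cells x d embedding coordinates.
#' @param velocities Cells x d velocity vectors (same space).
#' @param groups Per-cell labels.
#' @param from,to Labels of the source (A) and successor (B) group of the
#'   known transition.
#' @param neighbors Optional precomputed neighbour sets (list of integer
#'   vectors, or a cells x k index matrix); defaults to
#'   [knn_neighbors()] on `positions`.
#' @param k Neighbours for the fallback k-NN (default 30).
#' @return A `cbdir_result` list: `scores` (named, per scored A cell),
#'   `mean`, `n_scored`, `n_skipped`.
#' @export
cbdir <- function(positions, velocities, groups, from, to,
                  neighbors = NULL, k = 30L) {
  positions <- as.matrix(positions); velocities <- as.matrix(velocities)
  if (!all(dim(positions) == dim(velocities)))
    stop("'positions' and 'velocities' must have the same dimensions")
  M <- nrow(positions)
  if (length(groups) != M) stop("'groups' must have one label per cell")
  if (is.null(neighbors)) neighbors <- knn_neighbors(positions, k)
  if (is.matrix(neighbors))
    neighbors <- lapply(seq_len(nrow(neighbors)), function(i) neighbors[i, ])
  if (any(vapply(seq_len(M), function(c) c %in% neighbors[[c]], logical(1))))
    stop("neighbour sets must exclude the cell itself")
  a_cells <- which(groups == from)
  scores <- numeric(0)
  n_skipped <- 0L
  for (c in a_cells) {
    nb <- neighbors[[c]]
    nb <- nb[groups[nb] == to]
    if (!length(nb)) next
    v <- velocities[c, ]
    nv <- sqrt(sum(v^2))
    cos_terms <- numeric(0)
    for (cp in nb) {
      dx <- positions[cp, ] - positions[c, ]
      nd <- sqrt(sum(dx^2))
      if (nv == 0 || nd == 0) {
        n_skipped <- n_skipped + 1L
        next
      }
      cos_terms <- c(cos_terms, sum(v * dx) / (nv * nd))
    }
    if (!length(cos_terms)) next
    scores <- c(scores, stats::setNames(mean(cos_terms), as.character(c)))
  }
  if (n_skipped > 0)
    warning(sprintf("%d (cell, neighbour) terms skipped (zero-norm velocity or displacement)",
                    n_skipped))
  structure(list(scores = scores,
                 mean = if (length(scores)) mean(scores) else NA_real_,
                 n_scored = length(scores), n_skipped = n_skipped),
            class = "cbdir_result")
}

#' @export
print.cbdir_result <- function(x, ...) {
  cat(sprintf("CBDir: mean %.4f over %d scored cells (%d terms skipped)\n",
              x$mean, x$n_scored, x$n_skipped))
  invisible(x)
}
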