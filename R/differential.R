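# Differential splicing / differential momentum detection by variational
# model comparison. For each tested cell covariate t, the full model M1
# (all covariates) is compared per event with the nested model M0 in
# which the coefficient of t is fixed to zero (the column is left out,
# all other columns retained). Both fits share the initialisation, the
# training-noise seed and the evaluation draws, so the per-event
# ELBO gain = ELBO1 - ELBO0 approximates a log Bayes factor with little
# Monte-Carlo noise in the difference.

#' Test cell covariates by per-event ELBO gain
#'
#' @param data A filtered `SplicingCountData`.
#' @param cell_features M x K numeric matrix with named columns; should
#'   contain an intercept (constant) column alongside the tested
#'   covariates. A warning is given when none is present.
#' @param test_features Character vector of column names to test, one at a
#'   time. A constant test column is an error (no contrast).
#' @param config A [fit_config()]; the mode is forced to `"mode2_diff"`.
#' @param threshold ELBO-gain hit threshold passed to [call_hits()]
#'   (default 3).
#' @return A `data.frame` of class `diff_table` with one row per
#'   (event, tested feature): `event_id`, `feature`, `effect` (the M1
#'   coefficient on logit-PSI), `elbo0`, `elbo1`, `elbo_gain`,
#'   `elbo_gain_se` (common-random-number MC standard error) and `is_hit`.
#'   Negative gains are reported as-is (no evidence for the feature).
#' @export
elbo_gain_test <- function(data, cell_features, test_features,
                           config = fit_config(mode = "mode2_diff"),
                           threshold = 3) {
  Y <- as.matrix(cell_features)
  if (is.null(colnames(Y))) stop("'cell_features' must have column names")
  missing <- setdiff(test_features, colnames(Y))
  if (length(missing))
    stop("test feature(s) not in 'cell_features': ",
         paste(missing, collapse = ", "))
  const <- apply(Y, 2, function(v) max(v) == min(v))
  if (any(const[test_features]))
    stop("no contrast: test feature(s) constant across cells: ",
         paste(test_features[const[test_features]], collapse = ", "))
  if (!any(const))
    warning("'cell_features' has no intercept (constant) column")
  config$mode <- "mode2_diff"

  fit1 <- fit_splicing(data, cell_features = Y, config = config)
  out <- vector("list", length(test_features))
  for (i in seq_along(test_features)) {
    t_feat <- test_features[i]
    Y0 <- Y[, setdiff(colnames(Y), t_feat), drop = FALSE]
    fit0 <- if (ncol(Y0) > 0) {
      fit_splicing(data, cell_features = Y0, config = config)
    } else {
      cfg0 <- config; cfg0$mode <- "mode0"
      fit_splicing(data, config = cfg0)
    }
    gain <- fit1$elbo_event - fit0$elbo_event
    # common random numbers: SE of the per-sample likelihood difference
    dll <- fit1$ll_eval - fit0$ll_eval
    gain_se <- sqrt(rowSums((dll - rowMeans(dll))^2) /
                      (ncol(dll) - 1L) / ncol(dll))
    out[[i]] <- data.frame(event_id = data$event_ids, feature = t_feat,
                           effect = fit1$B[, t_feat],
                           elbo0 = fit0$elbo_event, elbo1 = fit1$elbo_event,
                           elbo_gain = gain, elbo_gain_se = gain_se,
                           stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  attr(tab, "fit1") <- fit1
  call_hits(tab, threshold)
}

#' Flag hits at an ELBO-gain threshold
#'
#' @param table A `diff_table` (or any `data.frame` with an `elbo_gain`
#'   column).
#' @param threshold Events with `elbo_gain > threshold` are hits
#'   (default 3).
#' @return The table with `is_hit` set, class `diff_table`.
#' @export
call_hits <- function(table, threshold = 3) {
  stopifnot("elbo_gain" %in% names(table))
  table$is_hit <- table$elbo_gain > threshold
  attr(table, "threshold") <- threshold
  class(table) <- unique(c("diff_table", class(table)))
  table
}

#' Empirical null gains by label permutation
#'
#' Re-runs [elbo_gain_test()] with the tested covariate permuted across
#' cells; useful for calibrating an ELBO-gain threshold empirically. No
#' multiplicity correction is otherwise applied by the package.
#'
#' @param data A filtered `SplicingCountData`.
#' @param cell_features M x K matrix with named columns.
#' @param test_feature Single column name to permute and test.
#' @param n_perm Number of permutations (default 5; each costs two fits).
#' @param config A [fit_config()].
#' @param seed Seed for the permutations (default 1).
#' @return Numeric matrix of null gains, events x permutations.
#' @export
permutation_null <- function(data, cell_features, test_feature, n_perm = 5L,
                             config = fit_config(mode = "mode2_diff"),
                             seed = 1L) {
  Y <- as.matrix(cell_features)
  restore <- .restore_rng(); on.exit(restore())
  set.seed(seed)
  perms <- replicate(n_perm, sample(nrow(Y)))
  gains <- matrix(NA_real_, length(data$event_ids), n_perm)
  for (p in seq_len(n_perm)) {
    Yp <- Y
    Yp[, test_feature] <- Y[perms[, p], test_feature]
    tab <- elbo_gain_test(data, Yp, test_feature, config = config)
    gains[, p] <- tab$elbo_gain
  }
  rownames(gains) <- data$event_ids
  gains
}
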