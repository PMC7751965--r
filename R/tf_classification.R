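# Location-dependent activator/repressor classification. Two separate
# schemes, never merged: (1) by the coefficient sign of binary features in a
# fitted selection model (all selected features are already significant);
# (2) per TF, a standalone OLS on its eight window columns with a p-value
# ceiling (default 1e-5) giving activator / repressor / insignificant calls.

#' Classify the binary features of a fitted model by coefficient sign
#'
#' A positive coefficient marks the TF as an activator (or coactivator) in
#' that window, a negative one as a repressor (or corepressor). Abundance
#' and extra columns are passed through unclassified.
#'
#' @param model a fitted `prom_model` from [forward_select()] whose column
#'   metadata identifies binary features.
#' @return data.frame with one row per binary feature: `feature`, `tf`,
#'   `window`, `category`, `coefficient`, `p_value`.
#' @export
classify_model_features <- function(model) {
  stopifnot(inherits(model, "prom_model"))
  cols <- model$columns
  if (is.null(cols))
    stop_promreg("model carries no column metadata; fit via forward_select ",
                 "on a feature_matrix")
  keep <- which(cols$kind == "binary")
  if (!length(keep))
    return(data.frame(feature = character(), tf = character(),
                      window = character(), category = character(),
                      coefficient = numeric(), p_value = numeric(),
                      stringsAsFactors = FALSE))
  feats <- cols$name[keep]
  coefs <- unname(model$coefficients[feats])
  data.frame(feature = feats,
             tf = cols$tf[keep],
             window = window_label(cols$x1[keep], cols$x2[keep]),
             category = ifelse(coefs > 0, "activator",
                               ifelse(coefs < 0, "repressor",
                                      "insignificant")),
             coefficient = coefs,
             p_value = unname(model$p_values[feats]),
             stringsAsFactors = FALSE)
}

#' Classify one TF over its eight windows by a standalone regression
#'
#' Fits a single OLS of the activity on the TF's eight binary window
#' columns and calls each window: repressor if its coefficient is negative
#' with p-value below `alpha`, activator if positive with p-value below
#' `alpha`, otherwise insignificant. All-zero (or constant) columns are
#' reported insignificant with an `undefined_coefficient` flag.
#'
#' @param tf TF name (annotation only).
#' @param X8 numeric matrix of the TF's 8 binary window columns; column
#'   names must be window labels (see [default_windows()]`$label`).
#' @param y LTE response vector.
#' @param alpha p-value ceiling (default 1e-5).
#' @return data.frame with 8 rows: `tf`, `window`, `category`,
#'   `coefficient`, `p_value`, `undefined_coefficient`, `r_op_of_model`.
#' @export
classify_tf_by_windows <- function(tf, X8, y, alpha = 1e-5) {
  X8 <- as.matrix(X8)
  stopifnot(ncol(X8) == 8, !is.null(colnames(X8)))
  sds <- apply(X8, 2, stats::sd)
  usable <- sds > 0
  if (!any(usable))
    stop_promreg("classify_tf_by_windows: all window columns constant")
  m <- ols_fit(X8[, usable, drop = FALSE], y)
  out <- data.frame(tf = tf, window = colnames(X8),
                    category = "insignificant",
                    coefficient = NA_real_, p_value = NA_real_,
                    undefined_coefficient = !usable,
                    r_op_of_model = m$r_op,
                    stringsAsFactors = FALSE)
  w <- colnames(X8)[usable]
  out$coefficient[usable] <- unname(m$coefficients[w])
  out$p_value[usable] <- unname(m$p_values[w])
  sig <- usable & !is.na(out$p_value) & out$p_value < alpha
  out$category[sig & out$coefficient > 0] <- "activator"
  out$category[sig & out$coefficient < 0] <- "repressor"
  out
}

#' Observed-to-expected ratio of simultaneous binding
#'
#' The fraction of TSSs bound in both columns divided by the product of the
#' marginal binding fractions (independence null). Values below 1 indicate
#' avoidance of simultaneous binding, above 1 co-occurrence. Symmetric in
#' its arguments.
#'
#' @param feature_a,feature_b binary 0/1 columns of equal length.
#' @return the ratio (non-negative real).
#' @export
cobinding_ratio <- function(feature_a, feature_b) {
  stopifnot(length(feature_a) == length(feature_b),
            all(feature_a %in% c(0, 1)), all(feature_b %in% c(0, 1)))
  pa <- mean(feature_a)
  pb <- mean(feature_b)
  if (pa == 0 || pb == 0)
    stop_promreg("cobinding_ratio: zero marginal binding frequency")
  mean(feature_a * feature_b) / (pa * pb)
}

#' Features most correlated with a target feature
#'
#' Pearson correlation of the target against every other non-constant
#' column of the matrix, ranked by signed r descending (or |r| with
#' `use_abs = TRUE`); ties break by column index.
#'
#' @param target column name in `fm`, or a numeric vector.
#' @param fm a `feature_matrix` or numeric matrix.
#' @param k number of features to return (default 5; fewer if fewer exist).
#' @param use_abs rank by absolute correlation instead of signed.
#' @return data.frame (feature, r) with up to `k` rows.
#' @export
top_correlated_features <- function(target, fm, k = 5, use_abs = FALSE) {
  X <- as_design(fm)$X
  if (is.character(target)) {
    if (!target %in% colnames(X))
      stop_promreg("target column '", target, "' not in matrix")
    tv <- X[, target]
    X <- X[, colnames(X) != target, drop = FALSE]
  } else {
    tv <- as.numeric(target)
  }
  if (stats::sd(tv) == 0)
    stop_promreg("top_correlated_features: zero-variance target")
  sds <- apply(X, 2, stats::sd)
  keep <- which(sds > 0)
  if (!length(keep))
    return(data.frame(feature = character(), r = numeric()))
  rs <- drop(stats::cor(tv, X[, keep, drop = FALSE]))
  key <- if (use_abs) -abs(rs) else -rs
  ord <- order(key, keep)  # ties: lowest column index
  topk <- utils::head(ord, k)
  data.frame(feature = colnames(X)[keep][topk], r = unname(rs[topk]),
             stringsAsFactors = FALSE)
}
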