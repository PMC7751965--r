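# OLS engine and greedy forward feature selection.
#
# At every step the single candidate whose inclusion gives the highest
# Pearson correlation R_o-p between predicted and observed activity joins
# the model. With an intercept, maximizing R_o-p over one added column is
# equivalent to maximizing the squared partial correlation of the candidate
# with the current residual, so the search is run incrementally on a
# Gram-Schmidt orthogonal basis: O(n * p) per step instead of p full OLS
# fits. The final model is refitted by plain OLS on the selected columns
# (tests verify equivalence against an exhaustive lm()-based greedy oracle).

#' Selection configuration
#'
#' @param max_steps maximum number of forward-selection steps (default 20).
#' @param p_stop p-value ceiling for attendant-feature selection: selection
#'   stops when the least significant coefficient's p-value exceeds this
#'   (default 1e-20).
#' @param seed optional seed for randomized operations (cross-validation
#'   splits).
#' @param tie_tol two candidates within this of the best achievable
#'   R_o-p^2 gain are tied; the lowest column index wins (default 1e-12).
#' @return a `selection_config`.
#' @export
selection_config <- function(max_steps = 20L, p_stop = 1e-20, seed = NULL,
                             tie_tol = 1e-12) {
  stopifnot(max_steps >= 1)
  structure(list(max_steps = as.integer(max_steps), p_stop = p_stop,
                 seed = seed, tie_tol = tie_tol),
            class = "selection_config")
}

as_design <- function(features) {
  if (inherits(features, "feature_matrix"))
    list(X = features$values, columns = features$columns)
  else {
    X <- as.matrix(features)
    if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
    list(X = X, columns = NULL)
  }
}

#' Ordinary least squares fit with t-test p-values
#'
#' Fits `y ~ intercept + X` by QR, returning coefficients, standard errors,
#' two-sided t-test p-values (floored at 1e-300 with a flag) and
#' `r_op = cor(fitted, y)`.
#'
#' @param X numeric matrix of feature columns (may be a `feature_matrix`).
#' @param y response (LTE vector).
#' @return a `prom_model`: intercept, features, coefficients, se, t,
#'   p_values, p_floored, r_op, fitted, df_residual, n.
#' @export
ols_fit <- function(X, y) {
  d <- as_design(X)
  X <- d$X
  n <- length(y)
  stopifnot(nrow(X) == n)
  p <- ncol(X)
  if (n <= p + 1)
    stop_promreg("ols_fit: need n > p + 1 (n = ", n, ", p = ", p, ")")
  Xi <- cbind(`(Intercept)` = 1, X)
  fit <- stats::lm.fit(Xi, y)
  r <- fit$rank
  if (r < ncol(Xi)) {
    aliased <- colnames(Xi)[fit$qr$pivot[(r + 1):ncol(Xi)]]
    stop_promreg("ols_fit: singular design; collinear column(s): ",
                 paste(aliased, collapse = ", "))
  }
  rss <- sum(fit$residuals^2)
  df_res <- n - ncol(Xi)
  sigma2 <- rss / df_res
  R <- qr.R(fit$qr)
  cov_unscaled <- chol2inv(R)
  piv <- fit$qr$pivot
  se <- numeric(ncol(Xi))
  se[piv] <- sqrt(diag(cov_unscaled) * sigma2)
  coefs <- fit$coefficients
  tval <- coefs / se
  pval <- 2 * stats::pt(-abs(tval), df_res)
  floored <- pval < 1e-300
  pval[floored] <- 1e-300
  fitted <- drop(Xi %*% coefs)
  r_op <- if (stats::sd(fitted) == 0) 0 else stats::cor(fitted, y)
  feat <- colnames(X)
  structure(list(intercept = unname(coefs[1]),
                 features = feat,
                 coefficients = stats::setNames(coefs[-1], feat),
                 se = stats::setNames(se[-1], feat),
                 p_values = stats::setNames(pval[-1], feat),
                 p_floored = stats::setNames(floored[-1], feat),
                 intercept_p = unname(pval[1]),
                 r_op = r_op, fitted = fitted, df_residual = df_res,
                 n = n, columns = d$columns, trace = NULL),
            class = "prom_model")
}

#' @export
print.prom_model <- function(x, ...) {
  cat(sprintf("<prom_model> %d feature(s), n = %d, R_o-p = %.4f\n",
              length(x$features), x$n, x$r_op))
  invisible(x)
}

#' Predict from a fitted model
#' @param object a `prom_model`.
#' @param newdata matrix or `feature_matrix` containing the model's columns.
#' @param ... unused.
#' @export
predict.prom_model <- function(object, newdata, ...) {
  X <- as_design(newdata)$X
  missing <- setdiff(object$features, colnames(X))
  if (length(missing))
    stop_promreg("predict: missing column(s): ",
                 paste(missing, collapse = ", "))
  drop(object$intercept +
         X[, object$features, drop = FALSE] %*% object$coefficients)
}

#' Greedy forward feature selection maximizing R_o-p
#'
#' At each step, the candidate column whose inclusion into the OLS model
#' gives the highest correlation between predicted and observed activity is
#' selected; selection runs for `config$max_steps` steps (fewer if the fit
#' becomes perfect or candidates are exhausted). Constant columns are
#' skipped with a warning; exact ties (to `tie_tol`) resolve to the lowest
#' column index. The returned model is refitted by [ols_fit()] on the
#' selected columns and carries the step trace.
#'
#' @param features a `feature_matrix` or numeric matrix of candidates.
#' @param y response (LTE vector).
#' @param config a [selection_config()].
#' @param extra optional named matrix/vector of additional candidate columns
#'   (e.g. a mean or predicted-mean profile), appended after the feature
#'   columns.
#' @return a `prom_model` with `$trace`: data.frame(step, feature, r_op,
#'   increment).
#' @export
forward_select <- function(features, y, config = selection_config(),
                           extra = NULL) {
  d <- as_design(features)
  X <- d$X
  columns <- d$columns
  if (!is.null(extra)) {
    extra <- as.matrix(extra)
    if (is.null(colnames(extra)))
      colnames(extra) <- paste0("extra", seq_len(ncol(extra)))
    X <- cbind(X, extra)
    if (!is.null(columns)) {
      columns <- rbind(columns,
                       data.frame(name = colnames(extra), kind = "extra",
                                  tf = NA_character_, x1 = NA_integer_,
                                  x2 = NA_integer_, stringsAsFactors = FALSE))
    }
  }
  sel <- greedy_core(X, y, max_steps = config$max_steps,
                     tie_tol = config$tie_tol)
  if (!length(sel$selected))
    stop_promreg("forward_select: no usable (non-constant) candidate columns")
  model <- ols_fit(X[, sel$selected, drop = FALSE], y)
  model$trace <- sel$trace
  if (!is.null(columns))
    model$columns <- columns[match(sel$selected, columns$name), , drop = FALSE]
  model$config <- config
  model
}

# Incremental greedy search on an orthogonalized design. Returns the
# selected column names (in order) and the R_o-p step trace.
greedy_core <- function(X, y, max_steps, tie_tol = 1e-12,
                        start = character(0)) {
  n <- length(y)
  stopifnot(nrow(X) == n)
  ry <- y - mean(y)
  tss_tot <- sum(ry^2)
  if (tss_tot == 0)
    stop_promreg("response has zero variance")
  RX <- sweep(X, 2, colMeans(X))
  cnorm0 <- colSums(RX^2)
  const <- cnorm0 <= 1e-12 * n
  if (any(const))
    warning(sum(const), " constant candidate column(s) skipped",
            call. = FALSE)
  active <- !const
  cnorm <- cnorm0
  take <- function(j) {
    # orthogonalize everything against the accepted column
    q <- RX[, j] / sqrt(cnorm[j])
    qtR <- drop(crossprod(RX, q))
    RX <<- RX - tcrossprod(q, qtR)
    cnorm <<- pmax(cnorm - qtR^2, 0)
    ry <<- ry - q * sum(q * ry)
    active[j] <<- FALSE
  }
  for (s in start) {
    j <- match(s, colnames(X))
    if (is.na(j)) stop_promreg("unknown start column: ", s)
    take(j)
  }
  selected <- character(0)
  trace <- data.frame(step = integer(), feature = character(),
                      r_op = numeric(), increment = numeric(),
                      stringsAsFactors = FALSE)
  prev_rop <- sqrt(max(0, 1 - sum(ry^2) / tss_tot))
  for (step in seq_len(max_steps)) {
    # drop candidates that became collinear with the selected set
    active[active & cnorm <= 1e-10 * pmax(cnorm0, 1e-300)] <- FALSE
    if (!any(active)) break
    ry2 <- sum(ry^2)
    if (ry2 <= 1e-12 * tss_tot) break  # perfect fit
    idx <- which(active)
    sc <- drop(crossprod(RX[, idx, drop = FALSE], ry))^2 /
      (cnorm[idx] * ry2)
    best <- max(sc)
    j <- idx[which(sc >= best - tie_tol)[1]]  # lowest index among ties
    take(j)
    rop <- sqrt(max(0, 1 - sum(ry^2) / tss_tot))
    selected <- c(selected, colnames(X)[j])
    trace <- rbind(trace, data.frame(step = step, feature = colnames(X)[j],
                                     r_op = rop,
                                     increment = rop - prev_rop,
                                     stringsAsFactors = FALSE))
    prev_rop <- rop
  }
  list(selected = selected, trace = trace)
}

#' Cross-validate a forward-selected model on a 50/50 TSS split
#'
#' TSS rows are split at random into equal-size training and test halves;
#' forward selection and the final refit use only the training half, and
#' R_o-p is evaluated on both halves with that training model. The full-data
#' model's R_o-p is reported alongside.
#'
#' @inheritParams forward_select
#' @param seed split seed (defaults to `config$seed`, else 1).
#' @return list with `r_op_full`, `r_op_train`, `r_op_test`, `n_train`,
#'   `n_test`, and the training `model`.
#' @export
cross_validate_model <- function(features, y, config = selection_config(),
                                 seed = NULL) {
  d <- as_design(features)
  X <- d$X
  n <- length(y)
  if (n < 200) stop_promreg("cross_validate_model: need n >= 200")
  seed <- seed %||% config$seed %||% 1L
  train <- with_seed(seed, sort(sample(n, floor(n / 2))))
  test <- setdiff(seq_len(n), train)
  full <- forward_select(features, y, config)
  m_train <- forward_select(X[train, , drop = FALSE], y[train], config)
  pred_test <- predict(m_train, X[test, , drop = FALSE])
  r_test <- if (stats::sd(pred_test) == 0) 0 else stats::cor(pred_test, y[test])
  list(r_op_full = full$r_op, r_op_train = m_train$r_op, r_op_test = r_test,
       n_train = length(train), n_test = length(test), model = m_train)
}

#' Build the predicted mean profile over several cell lines
#'
#' Runs forward selection independently per cell line and averages the
#' fitted activity profiles per TSS. The result captures the transcription
#' activity common to the lines and can be supplied as an extra candidate to
#' [forward_select()] ("advanced" models).
#'
#' @param per_cell_line list of `list(features =, y =)` pairs sharing one
#'   TSS universe and ordering.
#' @param config a [selection_config()].
#' @return numeric vector (per-TSS mean of fitted profiles), with attribute
#'   `models` (the per-line fits).
#' @export
build_predicted_mean_profile <- function(per_cell_line,
                                         config = selection_config()) {
  stopifnot(length(per_cell_line) >= 1)
  ids <- lapply(per_cell_line, function(l)
    if (inherits(l$features, "feature_matrix")) l$features$tss_id else NULL)
  ids <- ids[!vapply(ids, is.null, TRUE)]
  if (length(ids) > 1 &&
      !all(vapply(ids[-1], identical, TRUE, ids[[1]])))
    stop_promreg("cell lines do not share the TSS universe/ordering")
  lens <- vapply(per_cell_line, function(l) length(l$y), 0L)
  if (length(unique(lens)) != 1)
    stop_promreg("cell lines do not share the TSS universe/ordering")
  models <- lapply(per_cell_line, function(l)
    forward_select(l$features, l$y, config))
  fitted <- vapply(models, `[[`, numeric(lens[1]), "fitted")
  structure(rowMeans(fitted), models = models)
}

#' Continue selection into attendant features
#'
#' Extends an already selected model by further greedy steps; after each
#' inclusion the model is refitted and selection stops (rejecting the last
#' feature) as soon as the least significant coefficient's p-value exceeds
#' `config$p_stop` (default 1e-20). Attendant features are less important
#' than the initial set but still highly significant.
#'
#' @inheritParams forward_select
#' @param already_selected a fitted `prom_model` or character vector of
#'   already selected column names.
#' @return data.frame (feature, coefficient, p_value) of the accepted
#'   extension, in selection order; zero rows if nothing survives.
#' @export
select_attendant_features <- function(features, y, already_selected,
                                      config = selection_config()) {
  d <- as_design(features)
  X <- d$X
  base <- if (inherits(already_selected, "prom_model"))
    already_selected$features else as.character(already_selected)
  missing <- setdiff(base, colnames(X))
  if (length(missing))
    stop_promreg("already_selected column(s) not in features: ",
                 paste(missing, collapse = ", "))
  sel <- suppressWarnings(
    greedy_core(X, y, max_steps = config$max_steps,
                tie_tol = config$tie_tol, start = base))
  accepted <- character(0)
  out <- data.frame(feature = character(), coefficient = numeric(),
                    p_value = numeric(), stringsAsFactors = FALSE)
  for (f in sel$selected) {
    trial <- c(base, accepted, f)
    m <- ols_fit(X[, trial, drop = FALSE], y)
    if (max(m$p_values) > config$p_stop) break
    accepted <- c(accepted, f)
    out <- data.frame(feature = accepted,
                      coefficient = unname(m$coefficients[accepted]),
                      p_value = unname(m$p_values[accepted]),
                      stringsAsFactors = FALSE)
  }
  out
}
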