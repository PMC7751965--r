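# Expression transforms and profile-level analyses. Activities are modelled
# on the LTE scale: LTE = 0 if EL < 2, else log10(EL), where EL is the raw
# CAGE-derived expression level. Closely spaced TSSs (< max_gap bp apart,
# single linkage within a chromosome) can be sum-transformed: each member of
# a cluster gets the LTE of the cluster's summed EL.

#' Log-transformed expression (LTE)
#'
#' `LTE(EL) = 0` if `EL < 2`, else `log10(EL)`. Vectorized.
#'
#' @param el raw expression level(s), `>= 0`.
#' @return LTE value(s), `>= 0`.
#' @export
lte_transform <- function(el) {
  if (any(is.na(el)) || any(el < 0))
    stop_promreg("lte_transform: expression levels must be >= 0")
  ifelse(el < 2, 0, log10(el))
}

#' Construct an activity profile
#'
#' @param label object name (e.g. a cell line).
#' @param object_type one of `"cell_line"`, `"primary_cell"`, `"tissue"`.
#' @param values LTE values aligned to a shared TSS ordering.
#' @return an `activity_profile`.
#' @export
activity_profile <- function(label, object_type = c("cell_line",
                                                    "primary_cell", "tissue"),
                             values) {
  object_type <- match.arg(object_type)
  stopifnot(is.numeric(values), all(values >= 0))
  structure(list(label = label, object_type = object_type,
                 values = as.numeric(values)),
            class = "activity_profile")
}

#' Per-TSS mean of aligned activity profiles
#'
#' @param profiles list of [activity_profile]s (or numeric vectors) on the
#'   same TSS ordering.
#' @return numeric vector of per-TSS means.
#' @export
mean_profile <- function(profiles) {
  vals <- lapply(profiles, function(p)
    if (inherits(p, "activity_profile")) p$values else as.numeric(p))
  len <- unique(lengths(vals))
  if (length(len) != 1)
    stop_promreg("mean_profile: profiles have differing lengths")
  Reduce(`+`, vals) / length(vals)
}

#' Sum-transformation configuration
#' @param max_gap bp threshold: TSSs strictly closer than this are grouped
#'   (default 100).
#' @export
sum_transform_config <- function(max_gap = 100) {
  stopifnot(is.numeric(max_gap), max_gap > 0)
  structure(list(max_gap = max_gap), class = "sum_transform_config")
}

#' Sum-transform the expression of closely spaced TSSs
#'
#' TSSs on the same chromosome are grouped by single linkage on
#' `|delta position| < max_gap` (strand-agnostic). Every member of a group
#' receives the LTE of the group's summed raw EL; isolated TSSs keep the LTE
#' of their own EL.
#'
#' @param tss_table a `tss_table`.
#' @param cell_line name of the EL column to transform.
#' @param config a [sum_transform_config()].
#' @return numeric LTE vector aligned to `tss_table` rows, with attribute
#'   `component` (integer group ids) and `component_sum` (per-row summed EL).
#' @export
sum_transform <- function(tss_table, cell_line,
                          config = sum_transform_config()) {
  el <- tss_table[[cell_line]]
  if (is.null(el)) stop_promreg("no EL column '", cell_line, "'")
  n <- nrow(tss_table)
  comp <- integer(n)
  next_id <- 0L
  for (idx in split(seq_len(n), tss_table$chrom)) {
    ord <- idx[order(tss_table$position[idx])]
    pos <- tss_table$position[ord]
    # single linkage on a line: components are maximal runs of gaps < max_gap
    new_comp <- c(TRUE, diff(pos) >= config$max_gap)
    comp[ord] <- next_id + cumsum(new_comp)
    next_id <- next_id + sum(new_comp)
  }
  sums <- stats::ave(el, comp, FUN = sum)
  structure(lte_transform(sums), component = comp, component_sum = sums)
}

#' Summarize pairwise profile correlations per object type
#'
#' Computes all pairwise Pearson correlations between profiles within each
#' object type, plus one control group: a seeded uniform sample (without
#' replacement, across all types) of `random_sample_size` profiles. Pairs
#' involving a zero-variance profile are excluded and counted.
#'
#' @param profiles list of [activity_profile]s.
#' @param random_sample_size size of the mixed random control sample
#'   (`NULL` to skip).
#' @param seed RNG seed for the control sample.
#' @return data.frame with one row per group: `group`, `size`, `n_pairs`,
#'   `mean_r`, `min_r`, `max_r`, `n_undefined`.
#' @export
profile_correlation_summary <- function(profiles, random_sample_size = NULL,
                                        seed = 1L) {
  stopifnot(all(vapply(profiles, inherits, TRUE, "activity_profile")))
  types <- vapply(profiles, `[[`, "", "object_type")
  summarize <- function(group, ps) {
    mat <- vapply(ps, `[[`, numeric(length(ps[[1]]$values)), "values")
    sds <- apply(mat, 2, stats::sd)
    ok <- sds > 0
    n_undef <- 0L
    rs <- numeric(0)
    if (sum(ok) >= 2) {
      cm <- stats::cor(mat[, ok, drop = FALSE])
      rs <- cm[lower.tri(cm)]
    }
    total_pairs <- choose(length(ps), 2)
    n_undef <- total_pairs - length(rs)
    data.frame(group = group, size = length(ps), n_pairs = length(rs),
               mean_r = if (length(rs)) mean(rs) else NA_real_,
               min_r = if (length(rs)) min(rs) else NA_real_,
               max_r = if (length(rs)) max(rs) else NA_real_,
               n_undefined = n_undef, stringsAsFactors = FALSE)
  }
  out <- list()
  for (ty in unique(types)) {
    ps <- profiles[types == ty]
    if (length(ps) >= 2) out[[ty]] <- summarize(ty, ps)
  }
  if (!is.null(random_sample_size)) {
    if (random_sample_size > length(profiles))
      stop_promreg("random_sample_size exceeds number of profiles")
    pick <- with_seed(seed, sample(length(profiles), random_sample_size))
    out[["randomly selected sample"]] <-
      summarize("randomly selected sample", profiles[pick])
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Regress one activity profile on another
#'
#' Ordinary least squares of `y` on `x`; R_o-p is the Pearson correlation
#' between fitted and observed `y`.
#'
#' @param y,x [activity_profile]s or numeric vectors on the same TSS
#'   ordering.
#' @return list with `intercept`, `slope`, `r_op`.
#' @export
cross_profile_regression <- function(y, x) {
  yv <- if (inherits(y, "activity_profile")) y$values else as.numeric(y)
  xv <- if (inherits(x, "activity_profile")) x$values else as.numeric(x)
  if (length(yv) != length(xv))
    stop_promreg("profiles have differing lengths")
  if (stats::sd(xv) == 0)
    stop_promreg("cross_profile_regression: zero-variance predictor")
  slope <- stats::cov(xv, yv) / stats::var(xv)
  intercept <- mean(yv) - slope * mean(xv)
  fitted <- intercept + slope * xv
  r_op <- if (stats::sd(fitted) == 0 || stats::sd(yv) == 0) 0
  else stats::cor(fitted, yv)
  list(intercept = intercept, slope = slope, r_op = r_op)
}
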