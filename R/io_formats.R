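# I/O for the formats the pipeline touches: BED interval tracks for TF
# binding regions (TFBRs), the TSS activity table, and TSV model reports.
# Coordinates are BED-style 0-based half-open internally; TSS positions are
# stored 1-based as in annotation tables and converted on use.

#' Construct a TFBR set
#'
#' A TFBR set holds the binding regions of one transcription factor for one
#' (cell line, experiment, peak caller) combination. Intervals are 0-based
#' half-open and kept sorted by (chrom, start, end). For `caller = "final"`
#' (the per-TF union across experiments) intervals must additionally be
#' non-overlapping within each chromosome.
#'
#' @param intervals data.frame with columns `chrom` (character), `start`,
#'   `end` (integers, 0-based half-open, `end > start >= 0`).
#' @param tf transcription factor name.
#' @param cell_line,experiment_id,caller labels; `caller` is the peak-caller
#'   name, `"refined"` (post consensus filtering) or `"final"` (per-TF union).
#' @return an object of class `tfbr_set`.
#' @export
tfbr_set <- function(intervals, tf, cell_line = NA_character_,
                     experiment_id = NA_character_, caller = "final") {
  stopifnot(is.data.frame(intervals),
            all(c("chrom", "start", "end") %in% names(intervals)))
  intervals <- data.frame(chrom = as.character(intervals$chrom),
                          start = as.numeric(intervals$start),
                          end = as.numeric(intervals$end),
                          stringsAsFactors = FALSE)
  if (nrow(intervals)) {
    bad <- which(!(intervals$start >= 0 & intervals$end > intervals$start))
    if (length(bad))
      stop_promreg("invalid interval(s) at row(s) ", paste(bad, collapse = ", "),
                   ": need 0 <= start < end")
    intervals <- intervals[lex_order(intervals$chrom, intervals$start,
                                     intervals$end), , drop = FALSE]
    rownames(intervals) <- NULL
  }
  x <- structure(list(tf = tf, cell_line = cell_line,
                      experiment_id = experiment_id, caller = caller,
                      intervals = intervals),
                 class = "tfbr_set")
  if (identical(caller, "final") && nrow(intervals) > 1) {
    by_chrom <- split(intervals, intervals$chrom)
    for (df in by_chrom) {
      if (nrow(df) > 1 && any(df$start[-1] < df$end[-nrow(df)]))
        stop_promreg("final TFBR set for ", tf,
                     " contains overlapping intervals on ", df$chrom[1])
    }
  }
  x
}

#' @export
print.tfbr_set <- function(x, ...) {
  cat(sprintf("<tfbr_set> tf=%s caller=%s cell_line=%s experiment=%s: %d interval(s)\n",
              x$tf, x$caller, x$cell_line, x$experiment_id, nrow(x$intervals)))
  invisible(x)
}

n_intervals <- function(x) nrow(x$intervals)

#' Read TF binding regions from a BED file
#'
#' Parses a 3+ column tab-separated BED file (chrom, start, end; 0-based
#' half-open). Extra columns are ignored; `track`, `browser` and `#` comment
#' lines and blank lines are skipped. Intervals are returned sorted, so the
#' result is independent of line order in the file.
#'
#' @param path file path.
#' @inheritParams tfbr_set
#' @return a [tfbr_set].
#' @export
read_tfbr_bed <- function(path, tf, cell_line = NA_character_,
                          experiment_id = NA_character_, caller = "final") {
  lines <- readLines(path, warn = FALSE)
  keep <- !(grepl("^\\s*$", lines) | grepl("^(track|browser)\\b", lines) |
              grepl("^#", lines))
  idx <- which(keep)
  if (!length(idx))
    return(tfbr_set(data.frame(chrom = character(), start = numeric(),
                               end = numeric()),
                    tf, cell_line, experiment_id, caller))
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3))
    stop_promreg("BED parse error at line ", idx[which(nf < 3)[1]],
                 ": fewer than 3 columns")
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end) | start != floor(start) |
                 end != floor(end))
  if (length(bad))
    stop_promreg("BED parse error at line ", idx[bad[1]],
                 ": non-integer coordinate")
  bad <- which(end <= start | start < 0)
  if (length(bad))
    stop_promreg("BED parse error at line ", idx[bad[1]],
                 ": end <= start or negative start")
  tfbr_set(data.frame(chrom = chrom, start = start, end = end),
           tf, cell_line, experiment_id, caller)
}

#' Write a TFBR set as BED
#' @param x a [tfbr_set].
#' @param path output path.
#' @export
write_tfbr_bed <- function(x, path) {
  stopifnot(inherits(x, "tfbr_set"))
  df <- x$intervals
  lines <- sprintf("%s\t%d\t%d", df$chrom, as.integer(df$start),
                   as.integer(df$end))
  writeLines(lines, path)
  invisible(path)
}

#' Read a TSS activity table
#'
#' The table is tab-separated with a header whose first four columns are
#' `tss_id`, `chrom`, `position` (1-based bp of the TSS), `strand` (`+`/`-`),
#' followed by one column per cell line holding the raw expression level EL
#' (non-negative; CAGE-derived). Cell-line column order is preserved and
#' defines the profile ordering downstream.
#'
#' @param path file path.
#' @return a data.frame of class `tss_table` with attribute `cell_lines`.
#' @export
read_tss_activity_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  req <- c("tss_id", "chrom", "position", "strand")
  if (length(names(df)) < 4 || !identical(names(df)[1:4], req))
    stop_promreg("TSS table must start with columns: ",
                 paste(req, collapse = ", "))
  as_tss_table(df)
}

#' Validate a data.frame as a TSS table
#' @param df data.frame with columns tss_id, chrom, position, strand and one
#'   EL column per cell line.
#' @return the validated `tss_table`.
#' @export
as_tss_table <- function(df) {
  df$tss_id <- as.character(df$tss_id)
  df$chrom <- as.character(df$chrom)
  if (anyDuplicated(df$tss_id))
    stop_promreg("duplicate tss_id: ",
                 df$tss_id[duplicated(df$tss_id)][1])
  if (any(is.na(df$position)) || any(df$position < 1))
    stop_promreg("TSS position must be >= 1 (1-based)")
  if (!all(df$strand %in% c("+", "-")))
    stop_promreg("strand must be '+' or '-' (required for window orientation)")
  cl <- setdiff(names(df), c("tss_id", "chrom", "position", "strand"))
  for (col in cl) {
    v <- df[[col]]
    if (!is.numeric(v) || any(is.na(v)) || any(v < 0))
      stop_promreg("expression level column '", col,
                   "' must be numeric and >= 0")
  }
  attr(df, "cell_lines") <- cl
  class(df) <- c("tss_table", "data.frame")
  df
}

#' @export
#' @rdname read_tss_activity_table
#' @param x a `tss_table`.
#' @param path output path.
write_tss_activity_table <- function(x, path) {
  stopifnot(inherits(x, "tss_table"))
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

cell_lines <- function(x) attr(x, "cell_lines")

# p-values at or below the 1e-300 floor are rendered as in published model
# tables; everything else in full precision.
format_p <- function(p, floored = p <= 1e-300) {
  out <- vapply(seq_along(p), function(i) {
    if (is.na(p[i])) "NA"
    else if (isTRUE(floored[i]) || p[i] < 1e-300) "<1.0e-300"
    else sprintf("%.4g", p[i])
  }, "")
  out
}

#' Write a fitted model as a TSV report
#'
#' One row per selected feature in selection order, with the correlation
#' coefficient R_o-p reached at the step that introduced the feature, its
#' increment over the previous step, and the coefficient and two-sided
#' t-test p-value from the final refitted model. p-values below 1e-300 are
#' rendered `<1.0e-300`.
#'
#' @param model a fitted `prom_model` with a step trace (see
#'   [forward_select()]).
#' @param path output path.
#' @export
write_model_report <- function(model, path) {
  if (!inherits(model, "prom_model") || is.null(model$coefficients))
    stop_promreg("write_model_report needs a fitted prom_model")
  header <- "Feature\tR_o-p\tincrement\tcoefficient\tp_value"
  trace <- model$trace
  if (is.null(trace)) {
    # plain OLS fit: no step trace, report features in column order
    trace <- data.frame(feature = model$features,
                        r_op = rep(NA_real_, length(model$features)),
                        increment = rep(NA_real_, length(model$features)))
  }
  if (!nrow(trace)) {
    writeLines(header, path)
    return(invisible(path))
  }
  coefs <- model$coefficients[trace$feature]
  pvals <- model$p_values[trace$feature]
  floored <- model$p_floored[trace$feature]
  lines <- sprintf("%s\t%s\t%s\t%s\t%s",
                   trace$feature,
                   ifelse(is.na(trace$r_op), "NA", sprintf("%.6f", trace$r_op)),
                   ifelse(is.na(trace$increment), "NA",
                          sprintf("%.6f", trace$increment)),
                   fmt_num(coefs),
                   format_p(pvals, floored))
  writeLines(c(header, lines), path)
  invisible(path)
}
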