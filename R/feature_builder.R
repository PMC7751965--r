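# Promoter-window feature construction. For each TSS, eight fixed windows of
# TSS-relative offsets define promoter regions; per window the pipeline
# derives one real-valued Abundance feature (fraction m0/m of TFs with at
# least one final TFBR overlapping the window — a cis-regulatory-module
# indicator) and, per TF, one binary presence/absence feature. The full
# matrix has 8*(m+1) columns for m TFs.

#' The eight default promoter windows
#'
#' Closed TSS-relative offset intervals, in bp. Offset 0 is the TSS base
#' itself and belongs to `[-100, 0]`; together the windows tile
#' -5000..+1000 without gaps.
#'
#' @return data.frame with columns `x1`, `x2`, `label`.
#' @export
default_windows <- function() {
  x1 <- c(-5000L, -1000L, -500L, -200L, -100L, 1L, 101L, 501L)
  x2 <- c(-1001L, -501L, -201L, -101L, 0L, 100L, 500L, 1000L)
  data.frame(x1 = x1, x2 = x2, label = window_label(x1, x2),
             stringsAsFactors = FALSE)
}

window_label <- function(x1, x2) sprintf("[%d, %d]", x1, x2)

#' Map a promoter window to genomic coordinates
#'
#' Realizes a TSS-relative closed offset window `[x1, x2]` on the genome.
#' On the plus strand it covers 1-based positions `position + x1` to
#' `position + x2`; on the minus strand `position - x2` to `position - x1`,
#' so that negative offsets are always upstream. Windows are clamped at the
#' chromosome start (possibly becoming empty).
#'
#' @param position 1-based TSS position(s).
#' @param strand `"+"` or `"-"`, recycled.
#' @param x1,x2 window offsets (closed bounds).
#' @return data.frame with 0-based half-open `start`, `end` (empty windows
#'   have `end <= start`).
#' @export
window_to_genomic <- function(position, strand, x1, x2) {
  stopifnot(all(strand %in% c("+", "-")))
  plus <- strand == "+"
  lo <- ifelse(plus, position + x1, position - x2)
  hi <- ifelse(plus, position + x2, position - x1)
  lo <- pmax(lo, 1)
  data.frame(start = lo - 1, end = pmax(hi, 0))
}

# Overlap of a single query [qs, qe) with any interval of a tfbr_set.
overlaps_any <- function(chrom, qs, qe, tfbrs) {
  if (qe <= qs) return(FALSE)
  iv <- tfbrs$intervals
  any(iv$chrom == chrom & iv$start < qe & iv$end > qs)
}

#' Binary TF-presence feature for one TSS and window
#'
#' 1 iff any TFBR of the set shares at least one bp with the genomic
#' realization of the window around the TSS.
#'
#' @param tss one-row `tss_table` (or list with `chrom`, `position`,
#'   `strand`).
#' @param w one-row window (fields `x1`, `x2`).
#' @param tfbrs a final [tfbr_set].
#' @return 0 or 1.
#' @export
compute_binary_feature <- function(tss, w, tfbrs) {
  g <- window_to_genomic(tss$position, tss$strand, w$x1, w$x2)
  as.integer(overlaps_any(tss$chrom, g$start, g$end, tfbrs))
}

#' Abundance feature for one TSS and window
#'
#' The ratio m0/m where m0 is the number of TFs with at least one TFBR
#' overlapping the window, out of m TFs available for the cell line.
#'
#' @inheritParams compute_binary_feature
#' @param all_tfbrs list of final [tfbr_set]s, one per distinct TF.
#' @param m number of TFs (defaults to `length(all_tfbrs)`).
#' @return real in \[0, 1\].
#' @export
compute_abundance <- function(tss, w, all_tfbrs, m = length(all_tfbrs)) {
  if (m == 0) stop_promreg("compute_abundance: m = 0 TFs")
  m0 <- sum(vapply(all_tfbrs, function(s) compute_binary_feature(tss, w, s),
                   0L))
  m0 / m
}

tfbr_granges <- function(x) {
  iv <- x$intervals
  GenomicRanges::GRanges(iv$chrom,
                         IRanges::IRanges(start = iv$start + 1, end = iv$end))
}

#' Build the primary feature matrix
#'
#' Constructs, for every TSS, the eight Abundance columns (window order)
#' followed by, for each TF in lexicographic name order, its eight binary
#' presence columns — 8*(m+1) columns for m TFs and the default windows.
#'
#' @param tss_table a `tss_table` (see [read_tss_activity_table()]).
#' @param all_tfbrs named or unnamed list of final [tfbr_set]s, one per
#'   distinct TF.
#' @param windows window table as from [default_windows()].
#' @return a `feature_matrix`: list with `values` (numeric matrix, rows =
#'   TSSs), `columns` (descriptor data.frame: name, kind, tf, x1, x2),
#'   `tss_id`, and `m`.
#' @export
build_primary_features <- function(tss_table, all_tfbrs,
                                   windows = default_windows()) {
  stopifnot(inherits(tss_table, "tss_table") || is.data.frame(tss_table))
  tf_names <- vapply(all_tfbrs, `[[`, "", "tf")
  if (anyDuplicated(tf_names))
    stop_promreg("duplicate TF names: ",
                 paste(unique(tf_names[duplicated(tf_names)]), collapse = ", "))
  m <- length(all_tfbrs)
  if (m == 0) stop_promreg("no TFBR sets supplied")
  ord <- lex_order(tf_names)
  all_tfbrs <- all_tfbrs[ord]
  tf_names <- tf_names[ord]

  n <- nrow(tss_table)
  k <- nrow(windows)
  # genomic realization of every (tss, window) query, in window-major blocks
  qs <- qe <- numeric(n * k)
  for (j in seq_len(k)) {
    g <- window_to_genomic(tss_table$position, tss_table$strand,
                           windows$x1[j], windows$x2[j])
    idx <- (j - 1L) * n + seq_len(n)
    qs[idx] <- g$start; qe[idx] <- g$end
  }
  nonempty <- qe > qs
  q_gr <- GenomicRanges::GRanges(rep(tss_table$chrom, k)[nonempty],
                                 IRanges::IRanges(start = qs[nonempty] + 1,
                                                  end = qe[nonempty]))
  binary <- matrix(0, nrow = n * k, ncol = m)
  for (t in seq_len(m)) {
    subj <- tfbr_granges(all_tfbrs[[t]])
    hits <- GenomicRanges::findOverlaps(q_gr, subj, minoverlap = 1L)
    hit_rows <- which(nonempty)[unique(S4Vectors::queryHits(hits))]
    binary[hit_rows, t] <- 1
  }
  # abundance per window = row mean of the binary indicators across TFs
  abundance <- matrix(0, nrow = n, ncol = k)
  for (j in seq_len(k)) {
    idx <- (j - 1L) * n + seq_len(n)
    abundance[, j] <- rowSums(binary[idx, , drop = FALSE]) / m
  }
  values <- matrix(0, nrow = n, ncol = k * (m + 1))
  values[, seq_len(k)] <- abundance
  for (t in seq_len(m)) {
    cols <- k + (t - 1L) * k + seq_len(k)
    for (j in seq_len(k))
      values[, cols[j]] <- binary[(j - 1L) * n + seq_len(n), t]
  }
  columns <- data.frame(
    name = c(paste0("Abundance ", windows$label),
             unlist(lapply(tf_names, function(tf)
               paste0(tf, " ", windows$label)))),
    kind = c(rep("abundance", k), rep("binary", k * m)),
    tf = c(rep(NA_character_, k), rep(tf_names, each = k)),
    x1 = rep(windows$x1, m + 1),
    x2 = rep(windows$x2, m + 1),
    stringsAsFactors = FALSE)
  colnames(values) <- columns$name
  rownames(values) <- tss_table$tss_id
  structure(list(values = values, columns = columns,
                 tss_id = tss_table$tss_id, m = m),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d TSSs x %d features (m = %d TFs; %d abundance + %d binary)\n",
              nrow(x$values), ncol(x$values), x$m,
              sum(x$columns$kind == "abundance"),
              sum(x$columns$kind == "binary")))
  invisible(x)
}

#' Restrict a feature matrix to an allow-list of TFs
#'
#' Keeps the binary columns of the listed TFs (used for comparisons on a
#' fixed TF subset); abundance columns are kept or dropped via
#' `keep_abundance`.
#'
#' @param fm a `feature_matrix`.
#' @param tfs character vector of TF names to keep.
#' @param keep_abundance keep the 8 abundance columns (default FALSE: a pure
#'   TF-subset comparison).
#' @return a filtered `feature_matrix` (with `m` unchanged; abundance values
#'   still refer to the full TF universe).
#' @export
filter_features_tfs <- function(fm, tfs, keep_abundance = FALSE) {
  stopifnot(inherits(fm, "feature_matrix"))
  keep <- fm$columns$kind == "binary" & fm$columns$tf %in% tfs
  if (keep_abundance) keep <- keep | fm$columns$kind == "abundance"
  structure(list(values = fm$values[, keep, drop = FALSE],
                 columns = fm$columns[keep, , drop = FALSE],
                 tss_id = fm$tss_id, m = fm$m),
            class = "feature_matrix")
}

#' Write / read a feature matrix as TSV plus a column-metadata sidecar
#' @param fm a `feature_matrix`.
#' @param path matrix TSV path (rows = tss_id).
#' @param meta_path sidecar TSV path for column descriptors.
#' @export
write_feature_matrix <- function(fm, path, meta_path = paste0(path, ".cols")) {
  df <- data.frame(tss_id = fm$tss_id, fm$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- fm$columns
  meta$m <- fm$m
  utils::write.table(meta, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path, meta_path = paste0(path, ".cols")) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  meta <- utils::read.delim(meta_path, check.names = FALSE,
                            stringsAsFactors = FALSE)
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df$tss_id
  structure(list(values = values,
                 columns = meta[, c("name", "kind", "tf", "x1", "x2")],
                 tss_id = df$tss_id, m = meta$m[1]),
            class = "feature_matrix")
}
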