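# Three-step meta-processing of per-experiment ChIP-seq peak sets:
# (1) overlap the peak sets of several callers into consensus clusters,
# (2) drop single-caller "orphan" clusters when the experiment's FPCM
#     quality metric exceeds its threshold (default 3.0),
# (3) union the refined per-experiment sets into one final per-TF track.
# Overlap always means >= 1 shared bp: touching half-open intervals
# ([0,10) and [10,20)) do NOT overlap.

#' Meta-processing configuration
#'
#' @param fpcm_threshold positive real; orphan clusters are removed only when
#'   the experiment's FPCM exceeds this value (default 3.0).
#' @param fpcm_values optional named numeric vector / list mapping
#'   experiment_id to its FPCM value.
#' @param fpcm_fn optional callable taking the cluster list and returning an
#'   FPCM value; used when no explicit value is available. The FPCM formula
#'   itself is not part of this package — the value is injected.
#' @return a `meta_config` list.
#' @export
meta_config <- function(fpcm_threshold = 3.0, fpcm_values = NULL,
                        fpcm_fn = NULL) {
  stopifnot(is.numeric(fpcm_threshold), fpcm_threshold > 0)
  structure(list(fpcm_threshold = fpcm_threshold,
                 fpcm_values = fpcm_values, fpcm_fn = fpcm_fn),
            class = "meta_config")
}

#' Cluster the peaks of several callers into consensus overlap clusters
#'
#' Pools all intervals from the supplied caller-specific TFBR sets (which
#' must share one TF and one experiment) and computes, per chromosome, the
#' connected components of the interval-overlap graph (>= 1 shared bp).
#' Each component becomes one cluster with its merged span, member list and
#' support = number of distinct callers contributing.
#'
#' @param sets list of [tfbr_set]s, one per caller, same tf and experiment.
#' @return a list of clusters (class `overlap_clusters`); each cluster is a
#'   list with `chrom`, `start`, `end` (merged span), `members` (data.frame
#'   caller/chrom/start/end) and `support`.
#' @export
cluster_caller_peaks <- function(sets) {
  stopifnot(length(sets) >= 1, all(vapply(sets, inherits, TRUE, "tfbr_set")))
  tfs <- unique(vapply(sets, `[[`, "", "tf"))
  if (length(tfs) != 1)
    stop_promreg("cluster_caller_peaks: mixed TF labels: ",
                 paste(tfs, collapse = ", "))
  exps <- unique(vapply(sets, function(s) as.character(s$experiment_id), ""))
  if (length(exps) != 1)
    stop_promreg("cluster_caller_peaks: mixed experiment ids")
  pooled <- do.call(rbind, lapply(sets, function(s) {
    if (!nrow(s$intervals)) return(NULL)
    cbind(s$intervals, caller = s$caller, stringsAsFactors = FALSE)
  }))
  clusters <- list()
  if (!is.null(pooled) && nrow(pooled)) {
    pooled <- pooled[lex_order(pooled$chrom, pooled$start, pooled$end), ,
                     drop = FALSE]
    for (df in split(pooled, factor(pooled$chrom, unique(pooled$chrom)))) {
      # sweep line: sorted by start, a new component starts whenever the next
      # start is at or beyond the running max end (half-open semantics)
      run_end <- cummax(df$end)
      new_comp <- c(TRUE, df$start[-1] >= run_end[-nrow(df)])
      comp <- cumsum(new_comp)
      for (members in split(df, comp)) {
        clusters[[length(clusters) + 1L]] <- list(
          chrom = members$chrom[1],
          start = min(members$start),
          end = max(members$end),
          members = members[, c("caller", "chrom", "start", "end")],
          support = length(unique(members$caller)))
      }
    }
  }
  structure(clusters, class = "overlap_clusters", tf = tfs,
            experiment_id = exps)
}

resolve_fpcm <- function(clusters, fpcm, config) {
  if (!is.null(fpcm)) return(fpcm)
  exp_id <- attr(clusters, "experiment_id")
  if (!is.null(config$fpcm_values) && !is.null(exp_id) &&
      !is.na(exp_id) && exp_id %in% names(config$fpcm_values))
    return(as.numeric(config$fpcm_values[[exp_id]]))
  if (!is.null(config$fpcm_fn)) return(config$fpcm_fn(clusters))
  stop_promreg("no FPCM value obtainable for experiment '", exp_id,
               "': supply `fpcm`, add it to meta_config(fpcm_values=), ",
               "or register meta_config(fpcm_fn=)")
}

#' Apply the FPCM orphan gate to consensus clusters
#'
#' When the experiment's FPCM exceeds the configured threshold, clusters
#' supported by a single caller (orphans: regions that overlap no region from
#' any other caller) are removed. Surviving clusters are emitted as their
#' merged spans in a refined TFBR set.
#'
#' @param clusters output of [cluster_caller_peaks()].
#' @param fpcm the experiment's FPCM value; if `NULL`, looked up in `config`.
#' @param config a [meta_config()].
#' @return a [tfbr_set] with `caller = "refined"`.
#' @export
refine_with_fpcm_gate <- function(clusters, fpcm = NULL,
                                  config = meta_config()) {
  stopifnot(inherits(clusters, "overlap_clusters"))
  fpcm <- resolve_fpcm(clusters, fpcm, config)
  keep <- if (fpcm > config$fpcm_threshold)
    vapply(clusters, function(cl) cl$support > 1L, TRUE)
  else rep(TRUE, length(clusters))
  kept <- clusters[keep]
  iv <- if (length(kept))
    data.frame(chrom = vapply(kept, `[[`, "", "chrom"),
               start = vapply(kept, `[[`, 0, "start"),
               end = vapply(kept, `[[`, 0, "end"))
  else data.frame(chrom = character(), start = numeric(), end = numeric())
  tfbr_set(iv, tf = attr(clusters, "tf"),
           experiment_id = attr(clusters, "experiment_id"),
           caller = "refined")
}

# Merge intervals sharing >= 1 bp into maximal non-overlapping intervals.
merge_intervals <- function(df) {
  if (nrow(df) < 2) return(df)
  df <- df[lex_order(df$chrom, df$start, df$end), , drop = FALSE]
  out <- lapply(split(df, factor(df$chrom, unique(df$chrom))), function(d) {
    run_end <- cummax(d$end)
    new_comp <- c(TRUE, d$start[-1] >= run_end[-nrow(d)])
    comp <- cumsum(new_comp)
    data.frame(chrom = d$chrom[!duplicated(comp)],
               start = tapply(d$start, comp, min),
               end = tapply(d$end, comp, max))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Union refined per-experiment TFBR sets into the final per-TF track
#'
#' Concatenates the refined sets of all experiments for one TF and merges
#' intervals sharing at least one bp into maximal non-overlapping intervals.
#'
#' @param refined list of refined [tfbr_set]s for a single TF.
#' @return a [tfbr_set] with `caller = "final"`.
#' @export
union_refined <- function(refined) {
  if (inherits(refined, "tfbr_set")) refined <- list(refined)
  stopifnot(length(refined) >= 1,
            all(vapply(refined, inherits, TRUE, "tfbr_set")))
  tfs <- unique(vapply(refined, `[[`, "", "tf"))
  if (length(tfs) != 1)
    stop_promreg("union_refined: mixed TFs: ", paste(tfs, collapse = ", "))
  cls <- unique(vapply(refined, function(s) as.character(s$cell_line), ""))
  pooled <- do.call(rbind, lapply(refined, `[[`, "intervals"))
  tfbr_set(merge_intervals(pooled), tf = tfs,
           cell_line = if (length(cls) == 1) cls else NA_character_,
           caller = "final")
}
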