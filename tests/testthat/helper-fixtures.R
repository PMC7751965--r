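# Shared fixture builders: everything is generated in code at test time.

iv_df <- function(chrom, start, end) {
  data.frame(chrom = chrom, start = start, end = end,
             stringsAsFactors = FALSE)
}

toy_tfbr <- function(starts, ends, tf = "TFA", chrom = "chr1",
                     caller = "final", experiment_id = NA_character_) {
  tfbr_set(iv_df(rep(chrom, length(starts)), starts, ends),
           tf = tf, experiment_id = experiment_id, caller = caller)
}

toy_tss <- function(position, strand = "+", chrom = "chr1", el = NULL) {
  n <- length(position)
  df <- data.frame(tss_id = sprintf("t%03d", seq_len(n)),
                   chrom = rep(chrom, n)[seq_len(n)],
                   position = position,
                   strand = rep(strand, length.out = n),
                   stringsAsFactors = FALSE)
  if (!is.null(el)) df$CELL <- el
  as_tss_table(df)
}

# Independent oracle: connected components of the pairwise interval-overlap
# graph (>= 1 shared bp, half-open), by breadth-first search.
overlap_components_oracle <- function(df) {
  n <- nrow(df)
  adj <- outer(seq_len(n), seq_len(n), function(i, j)
    df$chrom[i] == df$chrom[j] & df$start[i] < df$end[j] &
      df$end[i] > df$start[j])
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  comp
}

# Independent oracle: greedy forward selection by exhaustive refitting with
# lm() at every step, maximizing cor(fitted, y); ties -> lowest index.
greedy_oracle <- function(X, y, steps) {
  selected <- integer(0)
  rops <- numeric(0)
  for (s in seq_len(steps)) {
    remaining <- setdiff(seq_len(ncol(X)), selected)
    remaining <- remaining[apply(X[, remaining, drop = FALSE], 2, sd) > 0]
    if (!length(remaining)) break
    score <- vapply(remaining, function(j) {
      fit <- lm(y ~ X[, c(selected, j), drop = FALSE])
      if (anyNA(coef(fit))) return(-Inf)
      cor(fitted(fit), y)
    }, 0)
    best <- max(score)
    pick <- remaining[which(score >= best - 1e-12)[1]]
    selected <- c(selected, pick)
    rops <- c(rops, best)
  }
  list(selected = selected, r_op = rops)
}
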