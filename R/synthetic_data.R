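# Synthetic data with known ground truth, emulating the statistical
# structure the analysis assumes: a TSS landscape where a stated fraction
# of TSSs (default 55.6%) has a neighbor closer than 100 bp; per-TF binding
# tracks realized as intervals inside promoter windows with configurable
# propensities; activities generated on the LTE scale by a sparse linear
# model on the realized features plus Gaussian noise, back-transformed to
# raw EL; and jittered multi-caller peak replicates with injected orphan
# peaks for the meta-processing stage.

#' Simulation configuration
#'
#' Defaults describe the stated world the pipeline is tested in: 5000 TSSs
#' of which 55.6% have a neighbor < 100 bp, 25 TF binding tracks with
#' window-binding propensity 0.2, 10 sparse true effects with |beta| in
#' [0.1, 0.5] on binary features, LTE noise sd 0.3, intercept 1.
#'
#' @param seed base RNG seed; stage generators derive their streams from it.
#' @param n_tss number of TSSs.
#' @param m_tfs number of TF tracks.
#' @param close_pair_fraction target fraction of TSSs with a neighbor
#'   < 100 bp (default 0.556).
#' @param chrom chromosome name of the toy genome.
#' @param chrom_length chromosome length in bp; `NULL` sizes it to fit.
#' @param binding_propensity scalar, or `m_tfs` x 8 matrix, of per-(TF,
#'   window) probabilities that a TFBR is placed in a TSS's window.
#' @param true_effects data.frame (tf, window (index 1..8), beta); `NULL`
#'   uses the default 10 mixed-sign effects.
#' @param noise_sd Gaussian noise sd on the LTE scale.
#' @param intercept baseline LTE.
#' @param background_rate expected background TFBRs per Mb per TF
#'   (default 0).
#' @param min_tfbr_width minimum width of placed TFBRs (bp).
#' @param jitter_sd caller boundary jitter sd (bp) for replicate fixtures.
#' @param dropout per-caller probability of missing a true peak.
#' @param orphan_rate per-caller false-peak rate (fraction of true peak
#'   count), placed to overlap nothing.
#' @param line_divergence for multi-cell-line simulation: probability that
#'   a line redraws a binding indicator instead of sharing the base draw
#'   (default 0.2, giving cross-line activity correlations comparable to
#'   those observed between real cell lines).
#' @param cell_line label for the generated EL column.
#' @return a `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_tss = 5000L, m_tfs = 25L,
                       close_pair_fraction = 0.556, chrom = "chr1",
                       chrom_length = NULL, binding_propensity = 0.2,
                       true_effects = NULL, noise_sd = 0.3, intercept = 1.0,
                       background_rate = 0, min_tfbr_width = 20L,
                       jitter_sd = 10, dropout = 0.05, orphan_rate = 0.2,
                       line_divergence = 0.2, cell_line = "SIM") {
  stopifnot(n_tss >= 1, m_tfs >= 1, close_pair_fraction >= 0,
            close_pair_fraction <= 1, noise_sd >= 0,
            all(binding_propensity >= 0), all(binding_propensity <= 1))
  if (is.null(true_effects)) true_effects <- default_true_effects(m_tfs)
  structure(list(seed = as.integer(seed), n_tss = as.integer(n_tss),
                 m_tfs = as.integer(m_tfs),
                 close_pair_fraction = close_pair_fraction, chrom = chrom,
                 chrom_length = chrom_length,
                 binding_propensity = binding_propensity,
                 true_effects = true_effects, noise_sd = noise_sd,
                 intercept = intercept, background_rate = background_rate,
                 min_tfbr_width = as.integer(min_tfbr_width),
                 jitter_sd = jitter_sd, dropout = dropout,
                 orphan_rate = orphan_rate,
                 line_divergence = line_divergence, cell_line = cell_line),
            class = "sim_config")
}

sim_tf_names <- function(m) sprintf("TF%03d", seq_len(m))

#' Default sparse true effects: 10 mixed-sign coefficients
#' @param m_tfs number of TFs available (must be >= 10 for the default set).
#' @return data.frame (tf, window, beta).
#' @export
default_true_effects <- function(m_tfs) {
  k <- min(10L, m_tfs)
  tfs <- sim_tf_names(m_tfs)[seq_len(k)]
  beta <- c(0.5, -0.4, 0.45, 0.3, -0.25, 0.35, 0.2, -0.15, 0.25, 0.1)[seq_len(k)]
  window <- c(6L, 5L, 7L, 6L, 5L, 8L, 4L, 7L, 3L, 2L)[seq_len(k)]
  data.frame(tf = tfs, window = window, beta = beta,
             stringsAsFactors = FALSE)
}

#' Generate a TSS landscape
#'
#' Places TSSs on a toy chromosome so that a `close_pair_fraction` of them
#' sits in clusters with neighbor gaps drawn uniformly below 100 bp while
#' the rest are isolated (>= 100 bp — in fact several kb — from any other
#' TSS). Strands are uniform. Deterministic given the config seed.
#'
#' @param config a [sim_config()].
#' @param seed stage seed (default `config$seed`).
#' @return a `tss_table` (no EL columns yet) with attribute `chrom_length`.
#' @export
generate_tss_landscape <- function(config, seed = config$seed) {
  n <- config$n_tss
  n_close <- round(config$close_pair_fraction * n)
  if (n_close == 1L) n_close <- 0L  # a single TSS cannot have a close pair
  n_pairs <- n_close %/% 2L
  triple <- n_close %% 2L == 1L
  sizes <- c(rep(1L, n - n_close),
             if (triple && n_pairs >= 1) c(rep(2L, n_pairs - 1L), 3L)
             else rep(2L, n_pairs))
  with_seed(seed, {
    sizes <- sample(sizes)  # interleave isolated TSSs and clusters
    # unit spacing > 10 kb + max cluster span, so the [-5000, +1000] windows
    # of distinct units can never overlap: binding propensities are then
    # realized exactly in the features of isolated TSSs
    gaps <- sample(11000:13000, length(sizes), replace = TRUE)
    anchors <- 10000 + cumsum(gaps)
    need <- anchors[length(anchors)] + 12000
    chrom_length <- config$chrom_length %||% need
    if (chrom_length < need)
      stop_promreg("chromosome too short for ", n, " TSSs: need >= ", need)
    pos <- integer(0)
    for (i in seq_along(sizes)) {
      within <- if (sizes[i] > 1)
        cumsum(c(0L, sample(1:99, sizes[i] - 1L, replace = TRUE)))
      else 0L
      pos <- c(pos, anchors[i] + within)
    }
    strand <- sample(c("+", "-"), n, replace = TRUE)
    df <- data.frame(tss_id = sprintf("tss_%06d", seq_len(n)),
                     chrom = config$chrom, position = pos, strand = strand,
                     stringsAsFactors = FALSE)
    tt <- as_tss_table(df)
    attr(tt, "chrom_length") <- chrom_length
    tt
  })
}

#' Draw the per-(TSS, TF, window) binding indicator matrix
#'
#' @param tss_table TSS landscape.
#' @param config a [sim_config()].
#' @param seed stage seed.
#' @param base optional base indicator matrix of the same shape; entries are
#'   copied except that each is redrawn with probability
#'   `config$line_divergence` (models cell lines sharing most binding).
#' @return n x (m*8) 0/1 matrix with columns named `tf|window_index`.
#' @export
draw_binding_matrix <- function(tss_table, config,
                                seed = config$seed + 1000L, base = NULL) {
  n <- nrow(tss_table)
  m <- config$m_tfs
  prop <- config$binding_propensity
  if (length(prop) == 1) prop <- matrix(prop, m, 8)
  stopifnot(nrow(prop) == m, ncol(prop) == 8)
  tfs <- sim_tf_names(m)
  with_seed(seed, {
    pmat <- matrix(rep(t(prop), each = n), nrow = n)  # n x (m*8), tf-major
    b <- matrix(as.numeric(stats::runif(n * m * 8) < pmat), nrow = n)
    if (!is.null(base)) {
      keep <- matrix(stats::runif(n * m * 8) >= config$line_divergence,
                     nrow = n)
      b <- ifelse(keep, base, b)
    }
    colnames(b) <- paste0(rep(tfs, each = 8), "|", rep(1:8, m))
    b
  })
}

#' Generate final per-TF TFBR sets realizing a binding indicator matrix
#'
#' For every (TSS, TF, window) indicator equal to 1, a TFBR is placed as a
#' random sub-interval strictly inside the genomic realization of that
#' window, guaranteeing overlap. Per TF, intervals are merged into the
#' final (union) track. Optional background intervals are added at
#' `background_rate` per Mb.
#'
#' @param tss_table TSS landscape from [generate_tss_landscape()].
#' @param config a [sim_config()].
#' @param seed stage seed.
#' @param binding optional pre-drawn indicator matrix from
#'   [draw_binding_matrix()].
#' @return named list of final [tfbr_set]s with attribute `binding`.
#' @export
generate_tfbr_sets <- function(tss_table, config,
                               seed = config$seed + 1000L, binding = NULL) {
  if (is.null(binding))
    binding <- draw_binding_matrix(tss_table, config, seed)
  n <- nrow(tss_table)
  m <- config$m_tfs
  tfs <- sim_tf_names(m)
  win <- default_windows()
  chrom_length <- attr(tss_table, "chrom_length") %||% Inf
  # genomic windows per (tss, window)
  gw <- lapply(seq_len(8), function(j)
    window_to_genomic(tss_table$position, tss_table$strand,
                      win$x1[j], win$x2[j]))
  out <- with_seed(seed + 1L, {
    sets <- vector("list", m)
    names(sets) <- tfs
    for (t in seq_len(m)) {
      starts <- ends <- numeric(0)
      for (j in seq_len(8)) {
        hit <- which(binding[, (t - 1L) * 8L + j] == 1)
        if (!length(hit)) next
        ws <- gw[[j]]$start[hit]
        we <- gw[[j]]$end[hit]
        width <- we - ws
        ok <- width > 0
        ws <- ws[ok]; we <- we[ok]; width <- width[ok]
        minw <- pmin(config$min_tfbr_width, width)
        len <- minw + floor(stats::runif(length(ws)) * (width - minw + 1))
        off <- floor(stats::runif(length(ws)) * (width - len + 1))
        starts <- c(starts, ws + off)
        ends <- c(ends, ws + off + len)
      }
      if (config$background_rate > 0 && is.finite(chrom_length)) {
        n_bg <- stats::rpois(1, config$background_rate * chrom_length / 1e6)
        if (n_bg > 0) {
          bs <- floor(stats::runif(n_bg) * (chrom_length - 200))
          starts <- c(starts, bs)
          ends <- c(ends, bs + 200)
        }
      }
      iv <- merge_intervals(data.frame(chrom = rep(config$chrom,
                                                   length(starts)),
                                       start = starts, end = ends))
      sets[[t]] <- tfbr_set(iv, tf = tfs[t], cell_line = config$cell_line,
                            caller = "final")
    }
    sets
  })
  attr(out, "binding") <- binding
  out
}

#' Generate activities from the realized features
#'
#' On the LTE scale: `LTE* = intercept + sum(beta * feature) + N(0,
#' noise_sd)`, floored at 0. Raw EL is the back-transform `10^LTE*` when
#' `LTE* > 0`, otherwise a uniform draw in [0, 2) so that non-expressed
#' TSSs have LTE exactly 0.
#'
#' @param tss_table TSS landscape.
#' @param fm `feature_matrix` built from the generated TFBRs.
#' @param config a [sim_config()].
#' @param seed stage seed.
#' @return the `tss_table` with the EL column `config$cell_line` added and
#'   attribute `ground_truth`: list(beta (named by feature column),
#'   intercept, noise_sd, signal, lte_star, theoretical_r).
#' @export
generate_activities <- function(tss_table, fm, config,
                                seed = config$seed + 2000L) {
  stopifnot(inherits(fm, "feature_matrix"))
  eff <- config$true_effects
  win <- default_windows()
  feat_names <- paste0(eff$tf, " ", win$label[eff$window])
  missing <- setdiff(feat_names, colnames(fm$values))
  if (length(missing))
    stop_promreg("true-effect feature(s) not in matrix: ",
                 paste(missing, collapse = ", "))
  beta <- stats::setNames(eff$beta, feat_names)
  signal <- drop(fm$values[, feat_names, drop = FALSE] %*% beta)
  with_seed(seed, {
    noise <- stats::rnorm(nrow(tss_table), 0, config$noise_sd)
    lte_star <- pmax(config$intercept + signal + noise, 0)
    el <- ifelse(lte_star > 0, 10^lte_star,
                 stats::runif(nrow(tss_table), 0, 2))
    tss_table[[config$cell_line]] <- el
    attr(tss_table, "cell_lines") <- c(cell_lines(tss_table) %||% character(0),
                                       config$cell_line)
    v <- stats::var(signal)
    attr(tss_table, "ground_truth") <- list(
      beta = beta, intercept = config$intercept,
      noise_sd = config$noise_sd, signal = signal, lte_star = lte_star,
      theoretical_r = sqrt(v / (v + config$noise_sd^2)))
    tss_table
  })
}

#' Generate jittered multi-caller replicates of a true peak set
#'
#' Each caller reproduces each true peak with probability `1 - dropout`,
#' with boundaries jittered by rounded Gaussians (clamped so the jittered
#' peak still overlaps the true one), plus caller-specific false peaks at
#' `orphan_rate` placed to overlap nothing (neither true peaks, however
#' jittered, nor any other placed false peak).
#'
#' @param true_peaks a [tfbr_set] of true peaks.
#' @param config a [sim_config()].
#' @param callers caller labels (default the four used in consensus
#'   meta-processing workflows).
#' @param seed stage seed.
#' @return named list of caller [tfbr_set]s (caller = label,
#'   experiment_id = that of `true_peaks`).
#' @export
generate_caller_replicates <- function(true_peaks, config,
                                       callers = c("GEM", "MACS2", "PICS",
                                                   "SISSRs"),
                                       seed = config$seed + 3000L) {
  stopifnot(inherits(true_peaks, "tfbr_set"))
  iv <- true_peaks$intervals
  n_true <- nrow(iv)
  pad <- ceiling(4 * config$jitter_sd) + 5
  chrom_length <- max(iv$end) + 50000
  occupied <- data.frame(chrom = iv$chrom, start = pmax(iv$start - pad, 0),
                         end = iv$end + pad)
  with_seed(seed, {
    out <- list()
    for (cl in callers) {
      kept <- which(stats::runif(n_true) >= config$dropout)
      ds <- round(stats::rnorm(length(kept), 0, config$jitter_sd))
      de <- round(stats::rnorm(length(kept), 0, config$jitter_sd))
      s <- iv$start[kept] + ds
      e <- iv$end[kept] + de
      # clamp: keep validity and >= 1 bp overlap with the true peak
      s <- pmax(pmin(s, iv$end[kept] - 1), 0)
      e <- pmax(e, s + 1, iv$start[kept] + 1)
      n_false <- round(config$orphan_rate * n_true)
      fs <- numeric(0)
      for (i in seq_len(n_false)) {
        for (try in 1:1000) {
          cand <- floor(stats::runif(1) * (chrom_length - 150))
          clash <- any(occupied$start < cand + 150 & occupied$end > cand)
          if (!clash) break
        }
        if (clash) stop_promreg("could not place a non-overlapping false peak")
        fs <- c(fs, cand)
        occupied <- rbind(occupied,
                          data.frame(chrom = iv$chrom[1],
                                     start = cand - pad, end = cand + 150 + pad))
      }
      df <- data.frame(chrom = c(iv$chrom[kept], rep(iv$chrom[1], n_false)),
                       start = c(s, fs), end = c(e, fs + 150))
      out[[cl]] <- tfbr_set(df, tf = true_peaks$tf,
                            cell_line = true_peaks$cell_line,
                            experiment_id = true_peaks$experiment_id,
                            caller = cl)
    }
    out
  })
}

#' Simulate a complete single-cell-line dataset
#'
#' Orchestrates landscape, binding, feature construction and activity
#' generation with seeds derived from `config$seed`.
#'
#' @param config a [sim_config()].
#' @return list with `tss` (tss_table incl. EL column and ground truth),
#'   `tfbrs` (final per-TF sets), `features` (feature_matrix), and `truth`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  tss <- generate_tss_landscape(config)
  tfbrs <- generate_tfbr_sets(tss, config)
  fm <- build_primary_features(tss, tfbrs)
  tss <- generate_activities(tss, fm, config)
  list(tss = tss, tfbrs = tfbrs, features = fm,
       truth = attr(tss, "ground_truth"))
}

#' Simulate several cell lines sharing true effects and most binding
#'
#' All lines share the TSS universe and the true-effect coefficients; each
#' line's binding indicators are the base line's redrawn independently with
#' probability `config$line_divergence`, and each line gets independent
#' activity noise. This emulates the high cross-line correlation of real
#' transcription activity profiles.
#'
#' @param config a [sim_config()].
#' @param n_lines number of cell lines (>= 2).
#' @return list with `tss` (landscape), `lines`: per line
#'   list(cell_line, features, y, truth).
#' @export
simulate_multi_line <- function(config = sim_config(), n_lines = 3L) {
  stopifnot(n_lines >= 2)
  tss <- generate_tss_landscape(config)
  base <- draw_binding_matrix(tss, config, seed = config$seed + 1000L)
  lines <- vector("list", n_lines)
  for (i in seq_len(n_lines)) {
    cfg_i <- config
    cfg_i$cell_line <- paste0("LINE", i)
    b <- if (i == 1) base
    else draw_binding_matrix(tss, config, seed = config$seed + 1000L + i,
                             base = base)
    tfbrs <- generate_tfbr_sets(tss, cfg_i, seed = config$seed + 4000L + i,
                                binding = b)
    fm <- build_primary_features(tss, tfbrs)
    tt <- generate_activities(tss, fm, cfg_i, seed = config$seed + 5000L + i)
    lines[[i]] <- list(cell_line = cfg_i$cell_line, features = fm,
                       y = lte_transform(tt[[cfg_i$cell_line]]),
                       truth = attr(tt, "ground_truth"))
  }
  names(lines) <- vapply(lines, `[[`, "", "cell_line")
  list(tss = tss, lines = lines)
}
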