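test_that("caller peaks cluster into overlap components with support counts", {
  A <- toy_tfbr(100, 200, caller = "A", experiment_id = "e1")
  B <- toy_tfbr(150, 250, caller = "B", experiment_id = "e1")
  C <- toy_tfbr(400, 500, caller = "C", experiment_id = "e1")
  cl <- cluster_caller_peaks(list(A, B, C))
  expect_length(cl, 2)
  expect_equal(cl[[1]][c("start", "end", "support")],
               list(start = 100, end = 250, support = 2L))
  expect_equal(cl[[2]][c("start", "end", "support")],
               list(start = 400, end = 500, support = 1L))

  solo <- toy_tfbr(c(10, 300), c(50, 350), caller = "A",
                   experiment_id = "e1")
  cl2 <- cluster_caller_peaks(list(solo))
  expect_length(cl2, 2)
  expect_true(all(vapply(cl2, `[[`, 0L, "support") == 1L))

  chain <- cluster_caller_peaks(list(
    toy_tfbr(0, 10, caller = "A", experiment_id = "e1"),
    toy_tfbr(9, 20, caller = "B", experiment_id = "e1"),
    toy_tfbr(19, 30, caller = "C", experiment_id = "e1")))
  expect_length(chain, 1)
  expect_equal(chain[[1]]$support, 3L)

  expect_error(cluster_caller_peaks(list(A, toy_tfbr(1, 2, tf = "OTHER",
                                                     experiment_id = "e1"))),
               "mixed TF")
})

test_that("clustering matches a brute-force connected-component oracle", {
  set.seed(7)
  for (rep in 1:5) {
    dfs <- lapply(c("A", "B", "C", "D"), function(cal) {
      st <- sample(0:900, 12)
      toy_tfbr(st, st + sample(10:120, 12, replace = TRUE), caller = cal,
               experiment_id = "e1")
    })
    cl <- cluster_caller_peaks(dfs)
    pooled <- do.call(rbind, lapply(dfs, `[[`, "intervals"))
    comp <- overlap_components_oracle(pooled)
    expect_length(cl, length(unique(comp)))
    # merged spans and member counts agree with the oracle partition
    oracle_spans <- sort(vapply(split(seq_len(nrow(pooled)), comp),
                                function(i) max(pooled$end[i]) -
                                  min(pooled$start[i]), 0))
    got_spans <- sort(vapply(cl, function(x) x$end - x$start, 0))
    expect_equal(got_spans, unname(oracle_spans))
    # touching half-open intervals never merge
    expect_true(all(vapply(cl, function(x) nrow(x$members) >= 1, TRUE)))
  }
})

test_that("support is invariant to caller set order", {
  set.seed(11)
  sets <- lapply(c("A", "B", "C"), function(cal) {
    st <- sample(0:500, 8)
    toy_tfbr(st, st + 30, caller = cal, experiment_id = "e1")
  })
  s1 <- sort(vapply(cluster_caller_peaks(sets), `[[`, 0L, "support"))
  s2 <- sort(vapply(cluster_caller_peaks(rev(sets)), `[[`, 0L, "support"))
  expect_identical(s1, s2)
})

test_that("FPCM gate removes orphans only above the threshold", {
  sets <- list(toy_tfbr(c(100, 400), c(200, 500), caller = "A",
                        experiment_id = "e1"),
               toy_tfbr(150, 250, caller = "B", experiment_id = "e1"))
  cl <- cluster_caller_peaks(sets)  # support 2 at 100-250, support 1 at 400-500
  below <- refine_with_fpcm_gate(cl, fpcm = 2.5)
  expect_equal(nrow(below$intervals), 2)
  above <- refine_with_fpcm_gate(cl, fpcm = 3.5)
  expect_equal(nrow(above$intervals), 1)
  expect_equal(above$intervals$start, 100)
  expect_equal(above$caller, "refined")

  # nothing to remove when all clusters have support >= 2
  sets2 <- list(toy_tfbr(100, 200, caller = "A", experiment_id = "e1"),
                toy_tfbr(150, 250, caller = "B", experiment_id = "e1"))
  cl2 <- cluster_caller_peaks(sets2)
  expect_equal(refine_with_fpcm_gate(cl2, fpcm = 100)$intervals,
               refine_with_fpcm_gate(cl2, fpcm = 0.1)$intervals)

  # gate never increases the interval count
  expect_lte(nrow(above$intervals), length(cl))
  expect_error(refine_with_fpcm_gate(cl), "FPCM")
  # config-supplied FPCM values are honored
  cfg <- meta_config(fpcm_values = list(e1 = 3.5))
  expect_equal(nrow(refine_with_fpcm_gate(cl, config = cfg)$intervals), 1)
})

test_that("union_refined merges on >= 1 shared bp and matches a bp-mask oracle", {
  u <- union_refined(list(toy_tfbr(100, 200, caller = "refined"),
                          toy_tfbr(150, 300, caller = "refined")))
  expect_equal(u$intervals, iv_df("chr1", 100, 300))
  expect_equal(u$caller, "final")

  disjoint <- union_refined(list(toy_tfbr(500, 600, caller = "refined"),
                                 toy_tfbr(10, 20, caller = "refined")))
  expect_equal(disjoint$intervals$start, c(10, 500))

  # touching half-open intervals stay separate
  touch <- union_refined(list(toy_tfbr(0, 10, caller = "refined"),
                              toy_tfbr(10, 20, caller = "refined")))
  expect_equal(nrow(touch$intervals), 2)

  set.seed(3)
  exps <- lapply(1:3, function(i) {
    st <- sample(0:950, 15)
    toy_tfbr(st, pmin(st + sample(5:80, 15, replace = TRUE), 1000),
             caller = "refined")
  })
  u3 <- union_refined(exps)
  mask <- rep(FALSE, 1000)
  for (s in exps) for (i in seq_len(nrow(s$intervals)))
    mask[(s$intervals$start[i] + 1):s$intervals$end[i]] <- TRUE
  runs <- rle(mask)
  stops <- cumsum(runs$lengths)
  starts <- stops - runs$lengths + 1
  oracle <- iv_df("chr1", starts[runs$values] - 1, stops[runs$values])
  expect_equal(u3$intervals, oracle)

  # idempotence: union of the output with itself equals itself
  expect_equal(union_refined(list(u3, u3))$intervals, u3$intervals)
  expect_error(union_refined(list(u3, toy_tfbr(1, 2, tf = "Z"))), "mixed")
})
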