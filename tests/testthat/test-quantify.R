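test_that("compute_rpm scales by library size and conserves 1e6 per column", {
  m <- count_matrix(matrix(c(5L, 999995L, 20L, 999980L), ncol = 2,
                           dimnames = list(c("a", "fill"), c("s1", "s2"))))
  rpm <- compute_rpm(m)
  expect_equal(rpm["a", "s1"], 5)
  expect_equal(colSums(rpm), c(s1 = 1e6, s2 = 1e6))
  zero <- matrix(c(1L, 0L), 1, 2, dimnames = list("a", c("s1", "s2")))
  expect_error(compute_rpm(count_matrix(zero)), "s2")
})

test_that("expression filter implements floor(geometric mean RPM) > 1", {
  counts <- rbind(kept = c(1, 4, 16),        # gm 4 -> kept
                  edge = c(1, 1, 4),         # gm ~1.59, floor 1 -> dropped
                  zero = c(0, 100, 100),     # zeros annihilate -> dropped
                  two = c(2, 2, 2))          # gm 2 -> kept (boundary is >1)
  colnames(counts) <- paste0("s", 1:3)
  m <- rpm_exact_matrix(counts)
  expect_setequal(setdiff(expression_filter(m), "filler"), c("kept", "two"))
  # monotonicity: adding counts to a kept row never drops it
  counts2 <- counts
  counts2["kept", ] <- counts["kept", ] + c(10, 0, 5)
  expect_true("kept" %in% expression_filter(rpm_exact_matrix(counts2)))
})

test_that("geom_mean handles zeros and rejects bad input", {
  expect_equal(geom_mean(c(1, 4, 16)), 4)
  expect_equal(geom_mean(c(0, 100)), 0)
  expect_error(geom_mean(c(-1, 2)), "negative")
  expect_error(geom_mean(numeric()), "empty")
})

test_that("TMM factors match the brute-force published estimator and edgeR", {
  skip_if_not_installed("edgeR")
  set.seed(31)
  for (rep in 1:3) {
    counts <- matrix(rnbinom(50 * 6, mu = 200, size = 2), 50, 6,
                     dimnames = list(paste0("g", 1:50), paste0("s", 1:6)))
    counts[1, 1] <- counts[1, 1] * 10
    f <- tmm_factors(count_matrix(counts))
    expect_equal(unname(f), oracle_tmm(counts), tolerance = 1e-12)
    expect_equal(unname(f),
                 unname(edgeR::calcNormFactors(counts, method = "TMM")),
                 tolerance = 1e-12)
  }
})

test_that("TMM invariances: identical and scaled columns give unit factors", {
  base <- matrix(rep(c(10L, 50L, 200L, 5L, 80L), 4), ncol = 4,
                 dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
  expect_equal(unname(tmm_factors(count_matrix(base))), rep(1, 4))
  scaled <- base
  scaled[, 2] <- base[, 2] * 2L       # library-size scaling absorbs doubling
  expect_equal(unname(tmm_factors(count_matrix(scaled))), rep(1, 4))
  # invariance to scaling any column: exact for the unweighted estimator
  # (precision weights are count-scale dependent by construction, so the
  # weighted default is only asymptotically scale invariant)
  set.seed(8)
  m <- matrix(rnbinom(200, mu = 100, size = 1), 50, 4,
              dimnames = list(paste0("g", 1:50), paste0("s", 1:4)))
  m[1:5, 3] <- m[1:5, 3] * 8L
  f1 <- tmm_factors(count_matrix(m), do_weighting = FALSE)
  m2 <- m; m2[, 2] <- m2[, 2] * 5L
  expect_equal(unname(tmm_factors(count_matrix(m2), do_weighting = FALSE)),
               unname(f1), tolerance = 1e-12)
  fw1 <- tmm_factors(count_matrix(m))
  fw2 <- tmm_factors(count_matrix(m2))
  expect_equal(unname(fw2), unname(fw1), tolerance = 0.05)
})

test_that("TMM flags degenerate columns and requires positive counts", {
  m <- matrix(c(10L, 20L, 30L, 0L, 7L, 0L), ncol = 2,
              dimnames = list(paste0("g", 1:3), c("s1", "s2")))
  expect_warning(f <- tmm_factors(count_matrix(m)), "degenerate")
  m0 <- matrix(c(1L, 2L, 0L, 0L), ncol = 2,
               dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(tmm_factors(count_matrix(m0)), "no positive")
})

test_that("group_expressed_sets: identical groups share a core; planted exclusives surface", {
  set.seed(4)
  block <- matrix(rnbinom(40 * 3, mu = 500, size = 5), 40, 3)
  counts <- cbind(block, block, block, block)
  rownames(counts) <- paste0("iso", 1:40)
  colnames(counts) <- paste0("s", 1:12)
  design <- rep(c("W_N", "W_T", "BAA_N", "BAA_T"), each = 3)
  res <- group_expressed_sets(count_matrix(counts), design)
  expect_equal(lengths(res$exclusive), c(BAA_N = 0L, BAA_T = 0L,
                                         W_N = 0L, W_T = 0L))
  expect_setequal(res$core, res$per_group$W_N)

  # silence iso1 outside BAA_T: it must be exclusive to BAA_T
  counts2 <- counts
  counts2["iso1", design != "BAA_T"] <- 0L
  res2 <- group_expressed_sets(count_matrix(counts2), design)
  expect_true("iso1" %in% res2$exclusive$BAA_T)
  expect_false("iso1" %in% res2$core)
  expect_true(length(res2$core) + sum(lengths(res2$exclusive)) <=
                length(res2$union))
  expect_error(
    group_expressed_sets(count_matrix(counts),
                         factor(rep("W_N", 12), levels = c("W_N", "W_T"))),
    "empty group")
})

test_that("count matrices round-trip through TSV and aggregate calls", {
  cfg <- sim_config(seed = 19, read_depth = 600)
  ref <- make_reference(cfg)
  tabs <- list(sampleA = call_isomirs(simulate_reads(ref, cfg)$reads$read, ref),
               sampleB = call_isomirs(
                 simulate_reads(ref, sim_config(seed = 20, read_depth = 600))$reads$read,
                 ref))
  m <- isomir_count_matrix(tabs)
  expect_equal(unname(m$lib_sizes),
               unname(vapply(tabs, function(tt) sum(tt$count), 0)))
  f <- withr::local_tempfile()
  write_count_matrix(m, f)
  expect_equal(read_count_matrix(f)$counts, m$counts)
})
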