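test_that("centering flattens qualifying segments and spares the rest", {
  # 10 guides / 4 genes around -2.1, then 6 guides forced to 2 genes
  set.seed(4)
  lfc <- c(rnorm(10, -2.1, 0.3), rep(-1.5, 6))
  prof <- toy_profile(lfc, guides_per_gene = 3)
  # genes: rows 1..10 span genes 1-4 (3,3,3,1), rows 11..16 genes 4-6
  segs <- manual_segments(prof, list(c(1, 10), c(11, 16)))
  segs$n_genes <- c(4L, 2L)   # count within each segment
  res <- correct_profile(prof, segs, correction_params(min_genes = 3))
  expect_true(res$segments$corrected[1])
  expect_false(res$segments$corrected[2])
  expect_equal(mean(res$corrected_profile$logfc[1:10]), 0, tolerance = 1e-12)
  expect_identical(res$corrected_profile$logfc[11:16], prof$logfc[11:16])
  expect_equal(res$offsets[1:10], rep(mean(prof$logfc[1:10]), 10))
  expect_equal(res$offsets[11:16], rep(0, 6))
})

test_that("median centering subtracts the median and reports the mean", {
  vals <- c(-5, 0, 0, 0, 0, 1, 1, 1, 1)
  prof <- toy_profile(vals, guides_per_gene = 1)  # 9 distinct genes
  segs <- manual_segments(prof, list(c(1, 9)))
  res <- correct_profile(prof, segs,
                         correction_params(center = "median"))
  expect_equal(median(res$corrected_profile$logfc), 0, tolerance = 1e-12)
  expect_equal(res$corrected_profile$logfc, vals - median(vals))
  # diagnostic mean stays the arithmetic mean of the uncorrected values
  expect_equal(res$segments$seg_mean, mean(vals))
})

test_that("correction is idempotent given the same segments", {
  set.seed(9)
  prof <- toy_profile(rnorm(30, -1), guides_per_gene = 2)
  segs <- manual_segments(prof, list(c(1, 12), c(13, 30)))
  first <- correct_profile(prof, segs)
  segs2 <- first$segments[, setdiff(names(first$segments),
                                    c("corrected", "offset"))]
  segs2$seg_mean <- vapply(seq_len(nrow(segs2)), function(s)
    mean(first$corrected_profile$logfc[segs2$global_start[s]:segs2$global_end[s]]),
    numeric(1))
  second <- correct_profile(first$corrected_profile, segs2)
  expect_equal(second$corrected_profile$logfc, first$corrected_profile$logfc,
               tolerance = 1e-12)
})

test_that("segments failing the partition precondition are rejected", {
  prof <- toy_profile(rnorm(10))
  expect_error(correct_profile(prof, manual_segments(prof, list(c(1, 6)))),
               "partition")
  expect_error(correct_profile(prof, manual_segments(prof,
                                                     list(c(1, 6), c(6, 10)))),
               "partition")
})

test_that("the adaptive min-genes trial table has the expected shape", {
  set.seed(31)
  n <- 240  # 120 genes on one chromosome, bias region spanning 15 genes
  lfc <- rnorm(n, 0, 0.2)
  bias_rows <- 61:90
  lfc[bias_rows] <- lfc[bias_rows] - 2
  prof <- toy_profile(lfc, guides_per_gene = 2)
  bias_genes <- unique(prof$gene[bias_rows])
  ess <- sample(setdiff(unique(prof$gene), bias_genes), 20)
  lfc2 <- prof$logfc
  lfc2[prof$gene %in% ess] <- lfc2[prof$gene %in% ess] - 3
  prof$logfc <- lfc2
  sets <- list(essential_test = ess, amplified = bias_genes,
               amplified_non_expressed = bias_genes,
               filter_set = ess[1:5])
  res <- choose_min_genes(prof, candidate_ns = c(2, 3, 5),
                          control_sets = sets,
                          cbs = cbs_params(seed = 77, nperm = 2000))
  expect_equal(nrow(res$trials), 3 * 2)
  expect_true(res$chosen_n %in% c(2, 3, 5))
  # the planted region spans 15 genes, so thresholds below that behave alike
  by_n <- tapply(res$trials$reduction_amplified,
                 res$trials$min_genes, mean)
  expect_lt(max(by_n) - min(by_n), 15)

  # degenerate flat screen: nothing to correct
  flat <- toy_profile(rep(0.2, 40), guides_per_gene = 2)
  sets2 <- list(essential_test = unique(flat$gene)[1:3],
                amplified = unique(flat$gene)[4:6],
                amplified_non_expressed = unique(flat$gene)[4:6])
  res2 <- choose_min_genes(flat, candidate_ns = c(2, 3),
                           control_sets = sets2,
                           cbs = cbs_params(seed = 5, nperm = 500))
  expect_true(res2$no_op)
  expect_true(all(abs(res2$trials$reduction_amplified) < 1e-9))
})
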