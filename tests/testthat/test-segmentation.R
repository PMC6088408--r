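test_that("the arc statistic behaves like a two-sample t", {
  x <- rep(2.5, 12)
  for (pair in list(c(0, 4), c(3, 9), c(5, 12)))
    expect_equal(cbs_statistic(x, pair[1], pair[2]), 0)

  # clean two-level vector: the maximising arc is exactly the raised block
  y <- c(0, 0, 0, 5, 5, 5)
  br <- brute_max_arc(y)
  expect_equal(br$cuts, 3L)
  expect_equal(abs(cbs_statistic(y, 3, 6)), br$t)

  set.seed(5)
  z <- rnorm(15)
  for (pair in list(c(0, 5), c(2, 9)))
    expect_equal(cbs_statistic(-z, pair[1], pair[2]),
                 -cbs_statistic(z, pair[1], pair[2]))

  expect_error(cbs_statistic(z, 0, 15), "complement")
})

test_that("the split search equals exhaustive enumeration on short vectors", {
  set.seed(11)
  for (trial in 1:60) {
    m <- sample(5:20, 1)
    x <- rnorm(m) + ifelse(runif(m) < 0.2, -3, 0)
    br <- brute_max_arc(x)
    ks <- cbs_max_split(x)
    expect_equal(as.integer(sort(setdiff(c(ks$i, ks$j), c(0L, m)))), br$cuts)
    expect_equal(abs(ks$t), br$t, tolerance = 1e-9)
  }
})

test_that("permutation p-values match exhaustive enumeration on tiny vectors", {
  set.seed(21)
  for (trial in 1:4) {
    n <- sample(6:8, 1)
    x <- rnorm(n) + c(rep(-1.5, 2), rep(0, n - 2))
    best <- cbs_max_split(x)
    p_exact <- .cbs_exact_pvalue_cpp(x, 2L, best$B)
    pv <- cbs_split_pvalue(x, cbs_params(nperm = 10000, early_stop = FALSE))
    mc_err <- 3 * sqrt(p_exact * (1 - p_exact) / 10000) + 2e-4
    expect_lt(abs(pv$p - p_exact), mc_err + 1 / 10000)
  }
})

test_that("segmentation recovers planted change-points and leaves flat data alone", {
  expect_equal(nrow(segment_chromosome(rep(1.3, 50), cbs_params(seed = 1))), 1L)
  expect_equal(segment_chromosome(2.2, cbs_params())$n_guides, 1L)

  set.seed(42)
  x <- c(rnorm(40, 0, 0.05), rnorm(40, -3, 0.05), rnorm(40, 0, 0.05))
  segs <- segment_chromosome(x, cbs_params(seed = 9))
  expect_equal(segs$start_index, c(1L, 41L, 81L))
  expect_equal(segs$end_index, c(40L, 80L, 120L))
  expect_equal(segs$seg_mean[2], -3, tolerance = 0.05)
})

test_that("genome segmentation composes chromosomes and is deterministic", {
  prof <- rbind(toy_profile(rep(0.5, 30), chrom = "1"),
                toy_profile(rep(-1, 30), chrom = "2"))
  prof$guide_id <- sprintf("g%03d", seq_len(nrow(prof)))
  segs <- segment_genome(prof, cbs_params(seed = 2))
  expect_equal(nrow(segs), 2L)
  expect_equal(segs$seg_mean, c(0.5, -1))
  expect_equal(segs$n_genes, c(15, 15))

  set.seed(8)
  planted <- c(rnorm(40, 0, 0.05), rnorm(40, -2, 0.05), rnorm(40, 0, 0.05))
  prof2 <- rbind(toy_profile(planted, chrom = "1"),
                 toy_profile(rnorm(40, 1, 0.05), chrom = "2"))
  prof2$guide_id <- sprintf("g%03d", seq_len(nrow(prof2)))
  s1 <- segment_genome(prof2, cbs_params(seed = 5))
  expect_equal(nrow(s1), 4L)
  expect_false(any(s1$global_start[s1$chrom == "2"] <= 120))

  s2 <- segment_genome(prof2, cbs_params(seed = 5))
  expect_identical(s1, s2)
})

test_that("segments always partition each chromosome", {
  set.seed(13)
  for (trial in 1:10) {
    m <- sample(10:80, 1)
    x <- rnorm(m) + rep(c(0, -sample(0:3, 1)), each = ceiling(m / 2))[1:m]
    segs <- segment_chromosome(x, cbs_params(seed = trial))
    expect_equal(segs$start_index[1], 1L)
    expect_equal(segs$end_index[nrow(segs)], m)
    if (nrow(segs) > 1)
      expect_equal(segs$start_index[-1], segs$end_index[-nrow(segs)] + 1L)
    expect_true(all(segs$n_guides >= 1))
  }
})

test_that("stronger planted shifts are recovered at least as often as weaker ones", {
  recovery <- function(shift, seeds) {
    hits <- 0
    for (s in seeds) {
      set.seed(s)
      x <- c(rnorm(25, 0, 0.25), rnorm(25, -shift, 0.25), rnorm(25, 0, 0.25))
      segs <- segment_chromosome(x, cbs_params(seed = s + 1000))
      ok <- any(abs(segs$start_index - 26) <= 2 & abs(segs$end_index - 50) <= 2)
      hits <- hits + ok
    }
    hits / length(seeds)
  }
  seeds <- 1:15
  rates <- vapply(c(0.25, 1.5, 6), recovery, numeric(1), seeds = seeds)
  expect_true(all(diff(rates) >= 0))
  expect_equal(rates[3], 1)
})
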