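scored <- function(labels, scores = seq_along(labels)) {
  # labels: character vector of "E", "N", "x" (library item outside controls)
  nm <- sprintf("it%02d", seq_along(labels))
  list(scores = setNames(scores, nm),
       E = nm[labels == "E"], N = nm[labels == "N"])
}

test_that("the FDR threshold follows the control-only precision scan", {
  s <- scored(c("E", "E", "E", "N", "E", "N", "N"))
  dc <- fdr_threshold(s$scores, s$E, s$N, fdr = 0.05)
  expect_equal(dc$k_star, 3L)
  expect_equal(dc$f_star, 3)
  expect_equal(dc$called, c("it01", "it02"))  # strict inequality

  # all leading controls essential: k* runs to the last pure-E rank and the
  # non-control item is ignored by the scan but eligible for calling
  s2 <- scored(c("E", "E", "x", "E"))
  dc2 <- fdr_threshold(c(s2$scores, itN = 99), s2$E, "itN")
  expect_equal(dc2$k_star, 3L)
  expect_equal(dc2$f_star, 4)
  expect_setequal(dc2$called, c("it01", "it02", "it03"))

  # fdr = 0 stops at the last pure-E prefix
  s3 <- scored(c("E", "N", "E", "E"))
  dc3 <- fdr_threshold(s3$scores, s3$E, s3$N, fdr = 0)
  expect_equal(dc3$k_star, 1L)

  # no qualifying rank: empty call with the -Inf sentinel
  s4 <- scored(c("N", "E"))
  dc4 <- fdr_threshold(s4$scores, s4$E, s4$N, fdr = 0)
  expect_equal(dc4$k_star, 0L)
  expect_equal(dc4$f_star, -Inf)
  expect_length(dc4$called, 0)
})

test_that("the threshold equals the brute-force prefix scan on random orderings", {
  set.seed(14)
  for (trial in 1:200) {
    L <- sample(4:12, 1)
    labels <- sample(c("E", "N"), L, replace = TRUE)
    if (length(unique(labels)) < 2) next
    s <- scored(labels, scores = sort(rnorm(L)))
    dc <- fdr_threshold(s$scores, s$E, s$N, fdr = 0.05)
    br <- brute_fdr_scan(unname(s$scores), labels == "E", 0.05)
    expect_equal(dc$k_star, br$k_star)
    expect_equal(dc$f_star, br$f_star)
  }
})

test_that("gene-level calls average guides before thresholding", {
  prof <- data.frame(gene = c("A", "A", "B", "C"),
                     logfc = c(-2, -4, -6, 0), stringsAsFactors = FALSE)
  dc <- call_genes(prof, essential = c("A", "B"), non_essential = "C")
  expect_equal(unname(dc$gene_scores[c("A", "B", "C")]), c(-3, -6, 0))
  expect_equal(dc$k_star, 2L)
  # separable controls: every essential below the threshold gene is called;
  # the gene defining F* itself is excluded by the strict inequality
  expect_setequal(dc$called, "B")
  expect_equal(dc$f_star, -3)

  # at scale the 5% budget lets k* run past the last essential, so the
  # threshold clears the whole set: full recall
  sep <- setNames(c(seq(-9, -5, length.out = 60),
                    seq(-1, 0, length.out = 40)),
                  sprintf("G%03d", 1:100))
  ess100 <- sprintf("G%03d", 1:60)
  expect_equal(recall_at_fdr(sep, ess100, sprintf("G%03d", 61:100), ess100),
               1.0)
})

test_that("recall curves integrate to the expected areas", {
  set.seed(15)
  n <- 2000
  sc <- setNames(rnorm(n), sprintf("g%d", 1:n))
  pos <- sample(names(sc), 400)
  expect_equal(recall_curve(sc, pos)$aurc, 0.5, tolerance = 0.05)

  # positives occupying the top ranks push the area towards 1
  sc2 <- setNames(c(seq(-5, -4, length.out = 50), seq(0, 1, length.out = 950)),
                  sprintf("g%d", 1:1000))
  expect_gt(recall_curve(sc2, sprintf("g%d", 1:50))$aurc, 0.95)

  expect_equal(recall_reduction(sc, sc, pos), 0)
})

test_that("recall at the FDR cutoff is monotone in the FDR level", {
  set.seed(16)
  s <- scored(sample(c("E", "N", "x"), 200, replace = TRUE),
              scores = sort(rnorm(200)) + rnorm(200, 0, 0.3))
  prev <- -1
  for (fdr in c(0, 0.01, 0.05, 0.1, 0.25)) {
    r <- recall_at_fdr(s$scores, s$E, s$N, s$E, fdr = fdr)
    expect_gte(r, prev)
    prev <- r
  }
})

test_that("profile preservation is perfect for identical rankings", {
  set.seed(17)
  pre <- setNames(rnorm(300), sprintf("g%d", 1:300))
  expect_equal(profile_preservation(pre, pre, c(10, 50))$auprc, c(1, 1))
  # reversing the ranking collapses the area towards the prevalence baseline
  rev_auprc <- profile_preservation(pre, -pre, 30)$auprc
  expect_lt(rev_auprc, 0.3)
  # shrinking perturbations recover the signal monotonically
  auprcs <- vapply(c(2, 0.5, 0.05), function(sd) {
    set.seed(18)
    profile_preservation(pre, pre + rnorm(300, 0, sd), 30)$auprc
  }, numeric(1))
  expect_true(all(diff(auprcs) > 0))
  expect_error(profile_preservation(pre, pre, 301), "exceeds")
})

test_that("the bias starting point is the first significantly shifted CN", {
  set.seed(19)
  groups <- list("2" = rnorm(30, -0.1, 0.1), "3" = rnorm(10, -0.1, 0.1),
                 "4" = rnorm(10, -0.1, 0.1), "6" = rnorm(8, -2, 0.1),
                 "8" = rnorm(6, -2.2, 0.1))
  expect_equal(as.numeric(bias_starting_point(groups)), 6)

  # singleton groups are skipped and the scan continues
  groups2 <- list("2" = rnorm(30, 0, 0.1), "3" = rnorm(1),
                  "4" = rnorm(10, -3, 0.1))
  expect_warning(sp <- bias_starting_point(groups2), "skipped")
  expect_equal(as.numeric(sp), 4)

  # identically distributed groups rarely trigger: check the Welch p-values
  # against the closed-form Welch statistic on a fixed pair
  a <- c(-0.12, -0.40, 0.21, 0.05, -0.33)
  b <- c(-1.95, -2.21, -2.02)
  tt <- t.test(b, a, var.equal = FALSE)
  se <- sqrt(var(a) / 5 + var(b) / 3)
  t_manual <- (mean(b) - mean(a)) / se
  df_manual <- se^4 / ((var(a) / 5)^2 / 4 + (var(b) / 3)^2 / 2)
  expect_equal(unname(tt$statistic), t_manual, tolerance = 1e-10)
  expect_equal(unname(tt$parameter), df_manual, tolerance = 1e-10)
  p3 <- attr(bias_starting_point(list("2" = a, "3" = b)), "p_values")[["3"]]
  expect_equal(p3, tt$p.value, tolerance = 1e-12)
})

test_that("the bias critical point sits at the knee of the CN response", {
  # flat response through CN 7, then an accelerating depletion: the knee
  # is the last flat copy number
  cn <- rep(2:10, each = 3)
  level <- c(rep(-0.1, 6), -1.2, -2.6, -3.6)[match(cn, 2:10)]
  res <- bias_critical_point(cn, level)
  expect_equal(res$critical_point, 7)
  expect_false(res$weak)

  # exhaustive candidate oracle: recompute every slope difference directly
  avg <- tapply(level, cn, mean)
  cnv <- as.numeric(names(avg))
  diffs <- sapply(3:9, function(n) {
    lo <- cnv <= n; hi <- cnv > n
    if (sum(lo) < 2 || sum(hi) < 2) return(NA_real_)
    abs(ls_slope_oracle(cnv[lo], avg[lo]) - ls_slope_oracle(cnv[hi], avg[hi]))
  })
  expect_equal(unname(res$slope_diffs), diffs, tolerance = 1e-10)
  expect_equal(res$critical_point, (3:9)[which.max(diffs)])

  # globally linear data: a candidate is still reported but flagged weak
  lin <- bias_critical_point(cn, -0.2 * cn)
  expect_true(lin$weak)
  expect_lt(lin$slope_difference, 1e-9)

  # minimal CN range: single candidate, right side has one CN value only
  res4 <- bias_critical_point(rep(2:4, each = 2),
                              c(0, 0, -0.1, -0.1, -2, -2))
  expect_equal(res4$critical_point, 3)
  expect_true(res4$weak)
})

test_that("fitness-gene impact classifies attenuated and distorted genes", {
  genes <- sprintf("G%02d", 1:10)
  pre <- data.frame(gene = genes,
                    significant = c(rep(TRUE, 6), rep(FALSE, 4)),
                    direction = c(rep("loss", 5), "gain", rep("loss", 4)),
                    stringsAsFactors = FALSE)
  expect_equal(fitness_gene_impact(pre, pre)$pct_attenuated_vs_screened, 0)
  expect_equal(fitness_gene_impact(pre, pre)$pct_distorted_vs_screened, 0)

  post <- pre
  post$significant <- c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE,
                        rep(FALSE, 4))
  post$direction[5] <- "gain"   # significant both ways, flipped
  lfc <- setNames(c(-3, -0.2, -2.5, -2.8, -2.6, 1, 0, 0, 0, 0), genes)
  ann <- list(fpkm = setNames(c(0.01, rep(10, 9)), genes),
              amplified = character(0), non_essential = character(0))
  imp <- fitness_gene_impact(pre, post, annotations = ann,
                             pre_gene_logfc = lfc)
  expect_setequal(imp$attenuated, c("G01", "G02"))
  expect_equal(imp$distorted, "G05")
  expect_equal(imp$pct_attenuated_vs_significant, 100 * 2 / 6)
  part <- imp$attenuated_loss_partition
  expect_equal(part$non_expressed, "G01")
  # G02 has a mild pre-correction phenotype (above the loss-gene upper
  # quartile) and is not otherwise explained
  expect_equal(part$mild_phenotype, "G02")
  expect_length(part$unexplained, 0)

  # missing annotations propagate as not-computable
  imp2 <- fitness_gene_impact(pre, post)
  expect_true(is.na(imp2$attenuated_loss_partition$non_expressed[1]))
})
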