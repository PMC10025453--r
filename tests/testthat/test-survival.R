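test_that("stratification picks the extreme scores and respects skips", {
  v <- setNames(c(3, 2, 1, -1, -2, -3), paste0("s", 1:6))
  lab <- stratify_by_mps(v, 2)
  expect_setequal(names(lab)[lab == "plus"], c("s1", "s2"))
  expect_setequal(names(lab)[lab == "minus"], c("s5", "s6"))
  expect_null(stratify_by_mps(setNames(rep(0, 6), paste0("s", 1:6)), 2))
  lab3 <- stratify_by_mps(v, 3)  # k equals the count of each polarity
  expect_setequal(names(lab3)[lab3 == "plus"], c("s1", "s2", "s3"))
  expect_error(stratify_by_mps(v, 0), "positive")
})

test_that("mirrored arms give a null log-rank and extreme separation a tiny p", {
  ids <- paste0("s", 1:20)
  out <- data.frame(sample_id = ids,
                    time = rep(c(1, 2, 3, 4, 5), 4),
                    event = rep(1, 20))
  lab <- setNames(rep(c("plus", "minus"), 10), ids)
  # identical survival experience in both arms
  cmp <- compare_survival(lab, out)
  expect_gt(cmp$logrank_p, 0.95)

  out2 <- data.frame(sample_id = ids,
                     time = c(rep(1, 10), rep(10, 10)),
                     event = c(rep(1, 10), rep(0, 10)))
  lab2 <- setNames(c(rep("plus", 10), rep("minus", 10)), ids)
  # complete separation: Cox likelihood is monotone, warning expected
  cmp2 <- suppressWarnings(compare_survival(lab2, out2))
  expect_lt(cmp2$logrank_p, 1e-4)
  expect_lt(cmp2$log2_hr, 0)   # plus arm dies early => survives shorter
})

test_that("swapping arm labels flips effect signs but not p-values", {
  set.seed(51)
  out <- toy_outcomes(40)
  lab <- setNames(rep(c("plus", "minus"), 20), out$sample_id)
  swp <- setNames(ifelse(lab == "plus", "minus", "plus"), out$sample_id)
  a <- compare_survival(lab, out)
  b <- compare_survival(swp, out)
  expect_equal(a$logrank_p, b$logrank_p)
  expect_equal(a$cox_p, b$cox_p, tolerance = 1e-6)
  expect_equal(a$log2_hr, -b$log2_hr, tolerance = 1e-6)
  expect_equal(a$wald_z, -b$wald_z, tolerance = 1e-6)
})

test_that("no-event cohorts are flagged undefined", {
  out <- data.frame(sample_id = paste0("s", 1:10),
                    time = 1:10, event = rep(0, 10))
  lab <- setNames(rep(c("plus", "minus"), 5), out$sample_id)
  cmp <- compare_survival(lab, out)
  expect_false(cmp$defined)
  expect_true(is.na(cmp$logrank_p))
})

test_that("empirical FDR bounds, monotonicity and null calibration hold", {
  set.seed(52)
  out <- toy_outcomes(60, event_p = 0.9)
  expect_equal(empirical_fdr(1, out, k = 10, n_null = 200, seed = 3), 1)
  expect_equal(empirical_fdr(0, out, k = 10, n_null = 200, seed = 3), 0)
  expect_equal(empirical_fdr(0, out, k = 10, n_null = 200, seed = 3,
                             pseudo_count = TRUE), 1 / 201)
  ps <- seq(0, 1, by = 0.1)
  fdrs <- vapply(ps, function(p)
    empirical_fdr(p, out, k = 10, n_null = 200, seed = 3), 0)
  expect_true(all(diff(fdrs) >= 0))
  # with exponential no-structure survival, a median null p has fdr ~ 0.5
  null_p <- pcmkit:::logrank_null_pvals(out, 10, 400, seed = 9)
  med <- median(null_p)
  expect_equal(empirical_fdr(med, null_p = null_p), 0.5, tolerance = 0.1)
})

test_that("label-switch null is available and calibrated at the median", {
  set.seed(53)
  out <- toy_outcomes(40, event_p = 1)
  lab <- setNames(rep(c("plus", "minus"), 20), out$sample_id)
  fdr <- empirical_fdr(0.5, out, k = 20, n_null = 200, seed = 4,
                       method = "label_switch", labels = lab)
  expect_true(fdr >= 0 && fdr <= 1)
})

test_that("single-locus stratification enforces the 15-patient rule", {
  set.seed(54)
  out <- toy_outcomes(300)
  mut <- setNames(rep(0, 300), out$sample_id)
  mut[1:10] <- 1   # only 10 mutants
  r <- single_locus_prognosis(mut, "mutation", out)
  expect_true(r$skipped)
  mut[1:60] <- 1
  r2 <- single_locus_prognosis(mut, "mutation", out)
  expect_false(r2$skipped)
  expect_error(single_locus_prognosis(setNames(rnorm(300), out$sample_id),
                                      "mutation", out), "binary")
  zpos <- setNames(abs(rnorm(300)) + 0.1, out$sample_id)
  expect_true(single_locus_prognosis(zpos, "expression", out)$skipped)
})

test_that("a planted hazard ratio of 2 is detected with adequate power", {
  hits <- vapply(1:40, function(s) {
    set.seed(400 + s)
    n <- 400
    ids <- sprintf("s%03d", 1:n)
    grp <- rep(c(1, 0), each = n / 2)
    time <- rexp(n, 0.05 * 2^grp)
    cens <- rexp(n, 0.02)
    out <- data.frame(sample_id = ids, time = pmin(time, cens),
                      event = as.integer(time <= cens))
    f <- setNames(ifelse(grp == 1, 1, 0), ids)
    r <- single_locus_prognosis(f, "mutation", out)
    isTRUE(r$prognostic)
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("Stouffer combination and the module-vs-locus ratio follow the formulas", {
  expect_equal(stouffer_combine(c(2, 2, 2)), 6 / sqrt(3))
  expect_equal(stouffer_combine(3.2), 3.2)
  expect_equal(stouffer_combine(c(1, -1)), 0)
  expect_error(stouffer_combine(numeric(0)), "no z")
  expect_equal(module_vs_locus_ratio(4, c(2, -1)), 1)
  expect_equal(module_vs_locus_ratio(2, 2), 0)
  expect_warning(r <- module_vs_locus_ratio(2, 0), "infinite")
  expect_identical(r, Inf)
  # monotone in module strength
  expect_gt(module_vs_locus_ratio(c(3, 3), 2),
            module_vs_locus_ratio(c(2, 3), 2))
})

test_that("multivariate Cox keeps an independent module effect and flags collinearity", {
  set.seed(55)
  n <- 500
  ids <- sprintf("s%03d", 1:n)
  arm <- rep(c("plus", "minus"), n / 2)
  stage <- sample(c("I", "II", "III"), n, replace = TRUE)
  lp <- 0.9 * (arm == "plus") + 0.5 * (stage == "III")
  time <- rexp(n, 0.05 * exp(lp))
  out <- data.frame(sample_id = ids, time = pmin(time, rexp(n, 0.02)),
                    event = as.integer(time <= rexp(n, 0.02)))
  out$event <- 1L  # keep the fixture simple: full follow-up
  out$time <- time
  lab <- setNames(arm, ids)
  cov <- data.frame(sample_id = ids, stage = stage)
  res <- multivariate_cox(lab, out, cov)
  expect_true(attr(res, "arm_significant"))
  expect_lt(res$p[res$term == "stageIII"], 0.05)
  # covariate identical to the arm label: collinear
  cov2 <- data.frame(sample_id = ids, copy = arm)
  res2 <- multivariate_cox(lab, out, cov2)
  expect_true(any(res2$singular))
})
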