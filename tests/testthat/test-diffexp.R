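test_that("t-test recovers no-effect and forced-effect cases", {
  block <- matrix(c(1, 5, 2, 4, 2, 6, 3, 1, 2, 7, 1, 3), 3, 4)
  m <- make_matrix(cbind(block, block), 3, 8)  # case columns = control columns
  ph <- two_group_pheno(colnames(m))
  de <- diffexp_ttest(m, ph)
  expect_equal(de$logratio, rep(0, 3))
  expect_equal(de$pval, rep(1, 3))
  expect_true(all(de$adj.pval >= de$pval))

  set.seed(1)
  m2 <- make_matrix(c(rep(1, 3), rep(3, 3)) + rnorm(6, sd = 1e-6), 1, 6)
  de2 <- diffexp_ttest(m2, two_group_pheno(colnames(m2), 3))
  expect_equal(de2$logratio, 2, tolerance = 1e-4)
  expect_lt(de2$pval, 1e-6)
  expect_equal(de2$meanExp, 2, tolerance = 1e-4)
})

test_that("t-test p agrees with a label-permutation oracle", {
  set.seed(7)
  n <- 30
  m <- make_matrix(rnorm(n, 8), 1, n)
  ph <- two_group_pheno(colnames(m), n / 2)
  de <- diffexp_ttest(m, ph, equal_var = TRUE)
  x <- as.vector(unclass(m))
  grp <- as.integer(names(ph) %in% names(ph)[ph == "case"])
  tstat_of <- function(g) {
    a <- x[g == 1]; b <- x[g == 0]
    sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) / (n - 2)
    (mean(a) - mean(b)) / sqrt(sp2 * (2 / (n / 2)))
  }
  t_obs <- tstat_of(grp)
  B <- 10000
  t_null <- replicate(B, tstat_of(sample(grp)))
  p_perm <- mean(abs(t_null) >= abs(t_obs))
  # band: 3 * Monte-Carlo SE plus the O(1/n) gap between the conditional
  # permutation test and the unconditional t reference
  band <- 3 * sqrt(p_perm * (1 - p_perm) / B) + 0.015
  expect_lt(abs(de$pval - p_perm), band)
})

test_that("t-test handles zero-variance degenerate features", {
  vals <- rbind(z001 = c(rep(1, 4), rep(2, 4)), z002 = rep(3, 8))
  colnames(vals) <- sprintf("s%03d", 1:8)
  m <- expression_matrix(vals, "log2")
  # feature z001: ctrl all 1, case all 2; z002: all 3
  ph <- two_group_pheno(colnames(m))
  expect_warning(de <- diffexp_ttest(m, ph), "zero variance")
  expect_equal(de$pval[de$feature == "z002"], 1)
  expect_lt(de$pval[de$feature == "z001"], 1e-300)
})

test_that("wilcoxon p matches exhaustive enumeration at n=3 vs 3", {
  set.seed(11)
  for (rep in 1:5) {
    vals <- sample(seq(1, 60, by = 1.7), 6)  # distinct values, no ties
    m <- make_matrix(vals, 1, 6)
    ph <- two_group_pheno(colnames(m), 3)
    de <- diffexp_wilcoxon(m, ph)
    p_enum <- wilcox_enum_p(vals[4:6], vals[1:3])
    expect_equal(de$pval, p_enum, tolerance = 1e-12)
  }

  # strict separation attains the minimal achievable p for these sizes
  m2 <- make_matrix(c(1, 2, 3, 10, 11, 12), 1, 6)
  de2 <- diffexp_wilcoxon(m2, two_group_pheno(colnames(m2), 3))
  expect_equal(de2$pval, 2 / choose(6, 3), tolerance = 1e-12)

  # fully tied feature gets p = 1
  m3 <- make_matrix(rep(5, 6), 1, 6)
  expect_equal(diffexp_wilcoxon(m3, two_group_pheno(colnames(m3), 3))$pval, 1)
})

test_that("moderated t tracks ordinary t under equal variances and gains power", {
  set.seed(5)
  m <- make_matrix(rnorm(200 * 8, 8), 200, 8)
  ph <- two_group_pheno(colnames(m))
  p_mod <- diffexp_modt(m, ph)$pval
  p_ord <- diffexp_ttest(m, ph, equal_var = TRUE)$pval
  expect_gt(cor(p_mod, p_ord, method = "spearman"), 0.9)

  # 500 features, 50 shifted, tiny groups: at matched empirical type-I
  # error the moderated test should not lose power
  set.seed(9)
  n_feat <- 500; shifted <- 1:50
  sds <- sqrt(1 / rgamma(n_feat, shape = 4, rate = 4))
  vals <- matrix(rnorm(n_feat * 6, 0, sds), n_feat, 6)
  vals[shifted, 4:6] <- vals[shifted, 4:6] + 2.5 * sds[shifted]
  m2 <- make_matrix(as.numeric(vals), n_feat, 6)
  ph2 <- two_group_pheno(colnames(m2), 3)
  p_mod2 <- diffexp_modt(m2, ph2)$pval
  p_ord2 <- diffexp_ttest(m2, ph2, equal_var = TRUE)$pval
  thr <- function(p) quantile(p[-shifted], 0.05, names = FALSE)
  power_mod <- mean(p_mod2[shifted] <= thr(p_mod2))
  power_ord <- mean(p_ord2[shifted] <= thr(p_ord2))
  expect_gte(power_mod, power_ord)

  expect_error(diffexp_modt(m[1:5, ], ph, trend = TRUE), "10 features")
})

test_that("rank product flags the consistently extreme feature first", {
  set.seed(13)
  m <- make_matrix(rnorm(50 * 8, 8), 50, 8)
  m[1, ] <- c(rep(12, 4), rep(2, 4))  # hugely down in case
  ph <- two_group_pheno(colnames(m))
  de <- diffexp_rankprod(m, ph, n_perm = 100)
  rp <- attr(de, "rank_product")
  expect_equal(unname(which.min(rp)), 1L)
  expect_equal(unname(rp[1]), 1)  # rank 1 in every comparison
  expect_lt(de$pval[1], 0.1)
  expect_error(diffexp_rankprod(m, ph, n_perm = 50), "at least 100")
})

test_that("rank product null p values are approximately uniform", {
  set.seed(17)
  m <- make_matrix(rnorm(1000 * 10), 1000, 10)
  ph <- two_group_pheno(colnames(m))
  de <- diffexp_rankprod(m, ph, n_perm = 200)
  ks <- suppressWarnings(stats::ks.test(de$pval, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("rank product p values are stable when doubling n_perm", {
  set.seed(19)
  m <- make_matrix(rnorm(50 * 8, 8), 50, 8)
  ph <- two_group_pheno(colnames(m))
  p1 <- diffexp_rankprod(m, ph, n_perm = 200)$pval
  p2 <- diffexp_rankprod(m, ph, n_perm = 400)$pval
  # p = 2 * min(p_down, p_up): binomial SE of the halved tail, doubled,
  # plus the 1/(B+1) estimator grain
  band <- 3 * 2 * sqrt((p1 / 2) * (1 - p1 / 2) / 200) + 1 / 201
  expect_true(all(abs(p1 - p2) <= band))
})

test_that("adjustment matches the step-up definition and dominance holds", {
  expect_equal(adjust_pvalues(0.03, "BH"), 0.03)
  expect_equal(adjust_pvalues(0.03, "bonferroni"), 0.03)
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03, 0.04), "BH"), rep(0.04, 4))
  set.seed(23)
  for (i in 1:20) {
    p <- runif(sample(1:40, 1))
    expect_equal(adjust_pvalues(p, "BH"), bh_brute(p), tolerance = 1e-14)
    expect_equal(adjust_pvalues(p, "bonferroni"), bonferroni_brute(p),
                 tolerance = 1e-14)
    expect_true(all(adjust_pvalues(p, "bonferroni") >=
                      adjust_pvalues(p, "BH") - 1e-14))
  }
  expect_error(adjust_pvalues(c(0.5, 1.2), "BH"), "\\[0, 1\\]")
})

test_that("DE tables round-trip through import and validate columns", {
  set.seed(29)
  m <- make_matrix(rnorm(40, 8), 5, 8)
  ph <- two_group_pheno(colnames(m))
  de <- diffexp_ttest(m, ph)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_diffexp(de, path)
  back <- import_diffexp(path)
  expect_equal(back$logratio, de$logratio, tolerance = 1e-12)
  expect_equal(back$pval, de$pval, tolerance = 1e-12)

  # extra columns preserved
  de$note <- "x"
  write_diffexp(de, path)
  expect_true("note" %in% names(import_diffexp(path)))

  # missing column named in the error
  bad <- de[, setdiff(names(de), "adj.pval")]
  utils::write.table(bad, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(import_diffexp(path), "adj.pval")
})

test_that("all methods are invariant to sample order and symmetric in labels", {
  set.seed(31)
  m <- make_matrix(rnorm(30 * 10, 8), 30, 10)
  ph <- two_group_pheno(colnames(m))
  shuf <- sample(ncol(m))
  m_shuf <- expression_matrix(unclass(m)[, shuf], "log2")
  ph_swap <- phenotype_table(names(ph), as.character(ph),
                             control = "case", case = "control")
  funs <- list(
    ttest = function(mm, pp) diffexp_ttest(mm, pp),
    wilcoxon = function(mm, pp) diffexp_wilcoxon(mm, pp),
    modt = function(mm, pp) diffexp_modt(mm, pp),
    rankprod = function(mm, pp) diffexp_rankprod(mm, pp, n_perm = 100))
  for (nm in names(funs)) {
    fun <- funs[[nm]]
    a <- fun(m, ph)
    b <- fun(m_shuf, ph)
    expect_identical(a$pval, b$pval)
    expect_identical(a$logratio, b$logratio)
    s <- fun(m, ph_swap)
    expect_identical(s$logratio, -a$logratio)
    if (nm == "modt") {
      # the design-swapped QR fit differs at machine precision
      expect_equal(s$pval, a$pval, tolerance = 1e-12)
    } else {
      expect_identical(s$pval, a$pval)
    }
  }
})
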