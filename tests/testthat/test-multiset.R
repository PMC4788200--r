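pairs_df <- function(mirna, mrna) {
  data.frame(miRNA = mirna, mRNA = mrna,
             meanExp.miRNA = 8, stringsAsFactors = FALSE)
}

test_that("Venn cells partition the union of interactions", {
  A <- pairs_df(c("m1", "m1", "m2"), c("g1", "g2", "g3"))
  B <- pairs_df(c("m1", "m2", "m2"), c("g1", "g3", "g4"))
  C <- pairs_df(c("m1", "m3"), c("g1", "g5"))
  sh <- shared_interactions(list(A = A, B = B, C = C))
  cells <- setNames(sh$cells$count, sh$cells$subset)
  # hand enumeration: m1-g1 in all three; m2-g3 in A,B; m1-g2 only A;
  # m2-g4 only B; m3-g5 only C
  expect_equal(cells[["A&B&C"]], 1L)
  expect_equal(cells[["A&B"]], 1L)
  expect_equal(cells[["A"]], 1L)
  expect_equal(cells[["B"]], 1L)
  expect_equal(cells[["C"]], 1L)
  expect_equal(cells[["A&C"]], 0L)
  expect_equal(sum(cells), sh$union_size)
  expect_equal(sh$union_size, 5L)

  # identical tables all land in the full-intersection cell
  sh2 <- shared_interactions(list(X = A, Y = A))
  c2 <- setNames(sh2$cells$count, sh2$cells$subset)
  expect_equal(c2[["X&Y"]], 3L)
  expect_equal(c2[["X"]] + c2[["Y"]], 0L)

  expect_error(shared_interactions(list(A = A)), "at least 2")
})

test_that("per-dataset totals decompose over the Venn cells", {
  set.seed(3)
  mk <- function() {
    n <- sample(5:12, 1)
    pairs_df(sprintf("m%d", sample(1:4, n, TRUE)),
             sprintf("g%d", sample(1:6, n, TRUE)))
  }
  tabs <- list(d1 = mk(), d2 = mk(), d3 = mk())
  sh <- shared_interactions(tabs)
  for (d in names(tabs)) {
    in_cell <- grepl(paste0("(^|&)", d, "(&|$)"), sh$cells$subset)
    expect_equal(sum(sh$cells$count[in_cell]),
                 nrow(unique(tabs[[d]][, c("miRNA", "mRNA")])))
  }
})

test_that("specific interactions are focal-only and measurable elsewhere", {
  A <- pairs_df(c("m1", "m1", "m2"), c("g1", "g2", "g9"))
  B <- pairs_df("m1", "g1")
  uni <- list(
    A = list(mirna = c("m1", "m2"), mrna = c("g1", "g2", "g9")),
    B = list(mirna = c("m1", "m2"), mrna = c("g1", "g2"))  # g9 not expressed in B
  )
  # m1-g1 is shared -> excluded; m1-g2 specific and measurable -> kept;
  # m2-g9 focal-only but unmeasurable in B -> excluded with a message
  expect_message(sp <- specific_interactions(list(A = A, B = B), "A", uni),
                 "not measurable")
  expect_identical(sp$mRNA, "g2")

  # without universes the measurability restriction is skipped
  sp2 <- specific_interactions(list(A = A, B = B), "A")
  expect_setequal(sp2$mRNA, c("g2", "g9"))

  # brute-force set difference cross-check
  keyA <- paste(A$miRNA, A$mRNA); keyB <- paste(B$miRNA, B$mRNA)
  expect_setequal(paste(sp2$miRNA, sp2$mRNA), setdiff(keyA, keyB))

  # shared everywhere -> nothing specific
  expect_equal(nrow(specific_interactions(list(A = A, B = A), "A")), 0L)
  expect_error(specific_interactions(list(A = A, B = B), "Z"), "not among")
})

test_that("specificity summary bounds specific targets by totals", {
  A <- pairs_df(c("m1", "m1", "m2", "m3"), c("g1", "g2", "g3", "g4"))
  B <- pairs_df(c("m1", "m2"), c("g1", "g3"))
  sc <- specificity_scatter(list(A = A, B = B), "A")
  expect_true(all(sc$n_specific <= sc$n_total))
  expect_equal(sc$n_specific[sc$miRNA == "m1"], 1L)
  expect_equal(sc$n_specific[sc$miRNA == "m2"], 0L)
  expect_equal(sc$n_specific[sc$miRNA == "m3"], 1L)
  # identical tables: all specific counts zero
  sc2 <- specificity_scatter(list(A = A, B = A), "A")
  expect_true(all(sc2$n_specific == 0L))
})

test_that("the pair matrix keeps pairs measured everywhere, flagged somewhere", {
  mk_corr <- function(cors) {
    data.frame(miRNA = rep(c("m1", "m2"), each = 2),
               mRNA = rep(c("g1", "g2"), 2),
               cor = cors, stringsAsFactors = FALSE)
  }
  corr <- list(d1 = mk_corr(c(-0.8, -0.1, 0.2, -0.5)),
               d2 = mk_corr(c(-0.7, 0.0, 0.1, -0.4)),
               d3 = mk_corr(c(-0.6, 0.1, 0.3, 0.2))[1:3, ])  # m2-g2 unmeasured
  comb <- list(d1 = pairs_df(c("m1", "m2"), c("g1", "g2")),
               d2 = pairs_df("m1", "g1"),
               d3 = pairs_df("m1", "g1"))
  pm <- build_pair_matrix(corr, comb)
  # m1-g1 significant somewhere and measured everywhere -> kept;
  # m2-g2 significant in d1 but unmeasured in d3 -> dropped;
  # m1-g2 / m2-g1 never significant -> dropped
  expect_equal(nrow(pm$cor), 1L)
  expect_identical(pm$pairs$miRNA, "m1")
  expect_equal(unname(pm$cor[1, ]), c(-0.8, -0.7, -0.6))
  expect_true(pm$flags[1, "d1"])
})

test_that("k-means on pair profiles recovers planted structure deterministically", {
  # k = 1: the single center is the column means
  set.seed(7)
  x <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, c("a", "b", "c")))
  km1 <- cluster_pairs(x, k = 1)
  expect_equal(unname(km1$centers[1, ]), unname(colMeans(x)), tolerance = 1e-12)

  # 6 points in 2 well-separated blobs: recovered partition matches the
  # best 2-partition found by exhaustive search over assignments
  blob <- rbind(matrix(rnorm(9, 0, 0.05), 3), matrix(rnorm(9, 5, 0.05), 3))
  km2 <- cluster_pairs(blob, k = 2)
  expect_equal(length(unique(km2$cluster[1:3])), 1L)
  expect_equal(length(unique(km2$cluster[4:6])), 1L)
  expect_false(km2$cluster[1] == km2$cluster[4])
  sse <- function(assign) {
    sum(vapply(unique(assign), function(g) {
      ctr <- colMeans(blob[assign == g, , drop = FALSE])
      sum(sweep(blob[assign == g, , drop = FALSE], 2, ctr)^2)
    }, numeric(1)))
  }
  best <- min(vapply(1:31, function(code) {
    a <- as.integer(intToBits(code))[1:6]
    if (length(unique(a)) < 2) Inf else sse(a)
  }, numeric(1)))
  expect_equal(km2$tot.withinss, best, tolerance = 1e-9)

  # SSE non-increasing in k under the fixed protocol
  set.seed(11)
  y <- matrix(rnorm(200), 50, 4)
  sses <- vapply(1:4, function(k) cluster_pairs(y, k = k)$tot.withinss,
                 numeric(1))
  expect_true(all(diff(sses) <= 1e-9))

  # bit-reproducible under the same seed
  expect_identical(cluster_pairs(y, k = 3, seed = 5)$cluster,
                   cluster_pairs(y, k = 3, seed = 5)$cluster)
  expect_error(cluster_pairs(y, k = 51), "exceeds")
})

test_that("dataset clustering merges identical columns first; PCA is standardized", {
  centers <- matrix(c(-0.5, -0.1, 0.2, 0.3,
                      -0.5, -0.1, 0.2, 0.3,
                      0.4, 0.5, -0.3, -0.2), nrow = 4,
                    dimnames = list(NULL, c("d1", "d2", "d3")))
  cd <- cluster_datasets(centers)
  expect_equal(cd$hclust$height[1], 0)
  first_pair <- cd$hclust$labels[abs(cd$hclust$merge[1, ])]
  expect_setequal(first_pair, c("d1", "d2"))
  # planted similarity: a 4-dataset tree pairs the two similar pairs
  set.seed(13)
  base1 <- rnorm(4); base2 <- rnorm(4) + 3
  cent4 <- cbind(a1 = base1, a2 = base1 + rnorm(4, 0, 0.01),
                 b1 = base2, b2 = base2 + rnorm(4, 0, 0.01))
  cd4 <- cluster_datasets(cent4)
  m <- cd4$hclust$merge
  leaves <- function(row) cd4$hclust$labels[abs(m[row, m[row, ] < 0])]
  expect_setequal(leaves(1), c("a1", "a2"))
  expect_setequal(leaves(2), c("b1", "b2"))
  # correlation-matrix PCA: component variances sum to #variables
  expect_equal(sum(cd4$pca$sdev^2), ncol(t(cent4)), tolerance = 1e-9)
  expect_error(cluster_datasets(centers[, 1:2]), "3 datasets")
})
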