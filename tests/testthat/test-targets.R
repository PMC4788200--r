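toy_sig <- function(n = 10) {
  data.frame(
    miRNA = sprintf("mir%02d", rep(1:2, each = n / 2)),
    mRNA = sprintf("g%02d", seq_len(n)),
    cor = seq(-0.9, -0.5, length.out = n),
    pval = seq(1e-6, 1e-3, length.out = n),
    adj.pval = seq(1e-5, 1e-2, length.out = n),
    stringsAsFactors = FALSE
  )
}

toy_de <- function(features, lr) {
  data.frame(feature = features, logratio = lr,
             meanExp = seq_along(features) + 5,
             pval = 0.01, adj.pval = 0.02, stringsAsFactors = FALSE)
}

test_that("target databases load, deduplicate and round-trip", {
  path <- withr::local_tempfile()
  writeLines(c("mirA\tg1", "mirA\tg2", "mirB\tg1", "mirA\tg1", "mirB\tg3"), path)
  expect_message(db <- load_target_db(path, name = "toy"), "1 duplicate")
  expect_equal(nrow(db$pairs), 4L)

  out <- withr::local_tempfile()
  write_target_db(db, out)
  db2 <- load_target_db(out, name = "toy")
  expect_setequal(paste(db$pairs$miRNA, db$pairs$mRNA),
                  paste(db2$pairs$miRNA, db2$pairs$mRNA))

  empty <- withr::local_tempfile()
  file.create(empty)
  expect_error(load_target_db(empty), "empty")

  onecol <- withr::local_tempfile()
  writeLines(c("mirA", "mirB"), onecol)
  expect_error(load_target_db(onecol), "2 columns")
})

test_that("intersection implements the min-support decision rule", {
  sig <- toy_sig(10)
  de_mir <- toy_de(unique(sig$miRNA), c(1, -1))
  de_mrna <- toy_de(unique(sig$mRNA), rep(c(-0.5, 0.5), 5))
  key <- function(d) paste(d$miRNA, d$mRNA)
  dbA <- target_db(sig$miRNA[1:4], sig$mRNA[1:4], "A")
  dbB <- target_db(sig$miRNA[c(3, 4, 7)], sig$mRNA[c(3, 4, 7)], "B")

  c1 <- intersect_with_targets(sig, de_mir, de_mrna, list(dbA, dbB), 1)
  expect_equal(nrow(c1), 5L)  # union: {1,2,3,4} + {7}
  c2 <- intersect_with_targets(sig, de_mir, de_mrna, list(dbA, dbB), 2)
  expect_equal(nrow(c2), 2L)  # overlap: {3,4}
  expect_equal(c2$dat.sum, c(2L, 2L))
  expect_equal(c1$dat.sum, rowSums(c1[, c("dat.A", "dat.B")]))

  # brute-force set algebra cross-check
  brute <- intersect(key(sig), union(key(dbA$pairs), key(dbB$pairs)))
  expect_setequal(key(c1), brute)

  # schema and score
  expect_identical(names(c1), c("miRNA", "mRNA", "cor", "pval", "adj.pval",
                                "logratio.miRNA", "logratio.mRNA",
                                "meanExp.miRNA", "meanExp.mRNA",
                                "dat.A", "dat.B", "dat.sum", "score"))
  expect_equal(c1$score, -2 * c1$logratio.miRNA * c1$logratio.mRNA)

  # empty database list yields an empty table
  c0 <- intersect_with_targets(sig, de_mir, de_mrna, list(), 1)
  expect_equal(nrow(c0), 0L)

  # monotonicity in the support threshold
  expect_gte(nrow(c1), nrow(c2))
  expect_gte(nrow(c2), nrow(intersect_with_targets(sig, de_mir, de_mrna,
                                                   list(dbA, dbB), 3)))

  # missing DE annotation is an error listing the ids
  expect_error(intersect_with_targets(sig, toy_de("mir01", 1), de_mrna,
                                      list(dbA, dbB), 1), "mir02")
})

test_that("score satisfies its sign and symmetry contracts", {
  expect_equal(compute_score(0, 3), 0)
  expect_equal(compute_score(2, 0), 0)
  expect_equal(compute_score(1, -1), 2)
  set.seed(1)
  a <- rnorm(20); b <- rnorm(20)
  expect_equal(compute_score(a, b), compute_score(b, a))
  expect_equal(compute_score(-a, -b), compute_score(a, b))
  expect_equal(compute_score(a, -b), -compute_score(a, b))
  # opposed fold-changes give a positive score
  expect_true(all(compute_score(abs(a), -abs(b)) >= 0))
})

test_that("per-miRNA false-positive ratios follow the defining arithmetic", {
  # mirX: 4 predicted expressed targets, 3 confirmed -> 25% false positives
  dbs <- list(target_db(c(rep("mirX", 4), rep("mirY", 2), "mirZ"),
                        c("g1", "g2", "g3", "g4", "g1", "g2", "g_unexpr"),
                        "db1"))
  combined <- data.frame(miRNA = c("mirX", "mirX", "mirX"),
                         mRNA = c("g1", "g2", "g3"), stringsAsFactors = FALSE)
  fp <- mirna_fp_ratio(dbs, combined, c("mirX", "mirY", "mirZ"),
                       sprintf("g%d", 1:4))
  expect_equal(fp$fp_percent[fp$miRNA == "mirX"], 25)
  expect_equal(fp$fp_percent[fp$miRNA == "mirY"], 100)
  # mirZ's only prediction is unexpressed -> omitted
  expect_false("mirZ" %in% fp$miRNA)
  # conservation: confirmed counts sum to the distinct pair count
  expect_equal(sum(fp$n_confirmed), nrow(unique(combined)))
})

test_that("count summaries partition the mRNAs and accumulate coverage", {
  combined <- data.frame(
    miRNA = c("m1", "m1", "m1", "m2", "m2", "m3"),
    mRNA  = c("g1", "g2", "g3", "g2", "g4", "g2"),
    stringsAsFactors = FALSE)
  cs <- count_summaries(combined, expressed_mrnas = 5)
  expect_identical(cs$targets_per_mirna$miRNA, c("m1", "m2", "m3"))
  expect_identical(cs$targets_per_mirna$n_targets, c(3L, 2L, 1L))
  # hand-enumerated pie: g1,g3,g4 by 1; g2 by 3; one expressed untargeted
  expect_identical(as.integer(cs$mirnas_per_mrna),
                   c(1L, 3L, 0L, 1L, 0L, 0L, 0L))
  expect_equal(sum(cs$mirnas_per_mrna), 5)
  # coverage: m1 covers 3, +m2 covers 4, +m3 adds nothing
  expect_equal(cs$cumulative_coverage$covered, c(3L, 4L, 4L))
  expect_true(all(diff(cs$cumulative_coverage$fraction) >= 0))

  expect_error(count_summaries(combined, expressed_mrnas = 3), "smaller")

  # empty table: everything in category 0, empty curve
  cs0 <- count_summaries(combined[0, ], expressed_mrnas = 5)
  expect_equal(as.integer(cs0$mirnas_per_mrna), c(5L, rep(0L, 6)))
  expect_equal(nrow(cs0$cumulative_coverage), 0L)
})

test_that("top_interactions is deterministic under ties and row order", {
  sig <- toy_sig(10)
  sig$adj.pval <- rep(0.01, 10)  # full tie on the primary key
  de_mir <- toy_de(unique(sig$miRNA), c(1, -1))
  de_mrna <- toy_de(unique(sig$mRNA), rep(-0.5, 10))
  db <- target_db(sig$miRNA, sig$mRNA, "A")
  comb <- intersect_with_targets(sig, de_mir, de_mrna, list(db), 1)
  t1 <- top_interactions(comb, 4)
  t2 <- top_interactions(comb[rev(seq_len(nrow(comb))), ], 4)
  expect_identical(t1, t2)
  expect_identical(t1$mRNA, sort(t1$mRNA))
  expect_equal(nrow(top_interactions(comb, 100)), nrow(comb))
  expect_error(top_interactions(comb, 0), "at least 1")
})
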