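fake_clinical <- function(n, seed = 1) {
  set.seed(seed)
  clinical_table(
    sample_id = paste0("s", seq_len(n)),
    er = sample(c("pos", "neg"), n, replace = TRUE),
    her2 = sample(c("pos", "neg"), n, replace = TRUE),
    grade = sample(1:3, n, replace = TRUE),
    tp53 = sample(c("wildtype", "mutant"), n, replace = TRUE),
    subtype = sample(c("luminal", "basal", "other"), n, replace = TRUE),
    rfs_time = runif(n, 0.5, 10), rfs_event = rbinom(n, 1, 0.5)
  )
}

test_that("association scan applies Wilcoxon to two-level and KW to grade", {
  cl <- fake_clinical(60, seed = 51)
  set.seed(52)
  e <- matrix(rnorm(120), 2, 60,
              dimnames = list(c("L1", "L2"), cl$sample_id))
  # plant a TP53 effect on L1
  e["L1", cl$tp53 == "mutant"] <- e["L1", cl$tp53 == "mutant"] + 2
  res <- association_scan(e, cl, "tp53")
  expect_equal(res$test, rep("wilcoxon", 2))
  expect_true(res$significant[res$locus_id == "L1"])
  expect_false(res$significant[res$locus_id == "L2"])
  expect_true(all(res$q >= res$p - 1e-12))
  resg <- association_scan(e, cl, "grade")
  expect_equal(unique(resg$test), "kruskal_wallis")
  # equal constant groups: no evidence, p = 1
  e0 <- matrix(5, 1, 60, dimnames = list("L1", cl$sample_id))
  res0 <- association_scan(e0, cl, "grade")
  expect_equal(res0$p, 1)
})

test_that("Kruskal-Wallis H matches the definition and an exhaustive relabeling p", {
  cl <- clinical_table(paste0("s", 1:9), grade = rep(1:3, each = 3))
  v <- c(1.2, 0.8, 1.9, 2.5, 3.1, 2.2, 0.5, 4.0, 3.3)
  e <- matrix(v, 1, 9, dimnames = list("L1", cl$sample_id))
  res <- association_scan(e, cl, "grade")
  H_oracle <- kruskal_oracle_H(v, rep(1:3, each = 3))
  got <- kruskal.test(v, factor(rep(1:3, each = 3)))
  expect_equal(unname(got$statistic), H_oracle, tolerance = 1e-12)
  # exhaustive relabeling reference distribution of H
  combos <- utils::combn(9, 3)
  Hs <- apply(combos, 2, function(i1) {
    rest <- setdiff(1:9, i1)
    c2 <- utils::combn(rest, 3)
    apply(c2, 2, function(i2) {
      g <- integer(9)
      g[i1] <- 1
      g[i2] <- 2
      g[g == 0] <- 3
      kruskal_oracle_H(v, g)
    })
  })
  p_perm <- mean(Hs >= H_oracle - 1e-9)
  expect_lt(abs(res$p - p_perm), 0.08)  # chi-square approximation at n = 9
})

test_that("consistent associations require significance and concordant direction in both cohorts", {
  a <- data.frame(locus_id = c("L1", "L2", "L3"), variable = "er",
                  test = "wilcoxon", p = c(0.001, 0.001, 0.001),
                  q = c(0.01, 0.20, 0.01), significant = c(TRUE, FALSE, TRUE),
                  direction = c(1.5, 1.5, 1.5))
  b <- data.frame(locus_id = c("L1", "L2", "L3"), variable = "er",
                  test = "wilcoxon", p = c(0.002, 0.002, 0.002),
                  q = c(0.03, 0.01, 0.04), significant = TRUE,
                  direction = c(2.0, 2.0, -0.8))
  out <- consistent_associations(a, b)
  expect_equal(out$locus_id, "L1")  # L2 fails q in A, L3 flips direction
  # without the concordance requirement L3 is admitted
  out2 <- consistent_associations(a, b, require_concordant_direction = FALSE)
  expect_setequal(out2$locus_id, c("L1", "L3"))
})

test_that("median split sends ties low and the log-rank matches the O-E oracle", {
  cl <- fake_clinical(86, seed = 53)
  e <- setNames(rnorm(86), cl$sample_id)  # all unique -> 43/43 split
  sp <- survival_median_split(e, cl)
  expect_equal(sp$n_low, 43L)
  expect_equal(sp$n_high, 43L)
  oracle <- logrank_oracle(cl$rfs_time, cl$rfs_event, as.character(sp$group))
  expect_equal(sp$chisq, oracle$chisq, tolerance = 1e-9)
  expect_equal(sp$p, oracle$p, tolerance = 1e-9)
  # identical survival in both groups: statistic 0, p 1
  cl2 <- clinical_table(paste0("s", 1:8), rfs_time = rep(c(1, 2, 3, 4), 2),
                        rfs_event = rep(c(1, 1, 0, 1), 2))
  e2 <- setNames(c(1, 2, 3, 4, 11, 12, 13, 14), cl2$sample_id)
  sp2 <- survival_median_split(e2, cl2)
  expect_equal(sp2$chisq, 0, tolerance = 1e-12)
  expect_equal(sp2$p, 1, tolerance = 1e-9)
  # hand-built 6-sample toy with an event imbalance
  cl3 <- clinical_table(paste0("s", 1:6), rfs_time = c(1, 2, 3, 4, 5, 6),
                        rfs_event = c(1, 1, 1, 0, 0, 0))
  e3 <- setNames(c(1, 2, 3, 10, 11, 12), cl3$sample_id)
  sp3 <- survival_median_split(e3, cl3)
  or3 <- logrank_oracle(cl3$rfs_time, cl3$rfs_event, as.character(sp3$group))
  expect_equal(sp3$chisq, or3$chisq, tolerance = 1e-9)
  # no events at all -> untestable
  cl4 <- clinical_table(paste0("s", 1:6), rfs_time = 1:6, rfs_event = 0)
  expect_false(survival_median_split(e3, cl4)$testable)
})

test_that("miRNA-mRNA screen selects |rho| > 0.3 consistently across cohorts", {
  set.seed(54)
  n <- 40
  z <- rnorm(n)
  mi <- matrix(z, 1, n, dimnames = list("miR-x", paste0("s", 1:n)))
  mr <- rbind(
    g_pos = z + rnorm(n, 0, 0.5),    # strongly positive
    g_neg = -z + rnorm(n, 0, 0.5),   # strongly negative
    g_null = rnorm(n)
  )
  colnames(mr) <- paste0("s", 1:n)
  ca <- mirna_mrna_correlation(mi, mr)
  expect_true(ca$selected[ca$gene == "g_pos"])
  expect_true(ca$selected[ca$gene == "g_neg"])
  expect_gt(ca$rho[ca$gene == "g_pos"], 0.3)
  expect_lt(ca$rho[ca$gene == "g_neg"], -0.3)
  # second cohort with a sign flip on g_neg
  z2 <- rnorm(n)
  mi2 <- matrix(z2, 1, n, dimnames = list("miR-x", paste0("s", 1:n)))
  mr2 <- rbind(g_pos = z2 + rnorm(n, 0, 0.5), g_neg = z2 + rnorm(n, 0, 0.5),
               g_null = rnorm(n))
  colnames(mr2) <- paste0("s", 1:n)
  cb <- mirna_mrna_correlation(mi2, mr2)
  cons <- consistent_correlations(ca, cb)
  expect_true("g_pos" %in% cons$gene)
  expect_false("g_neg" %in% cons$gene)   # selected in both but sign flips
  expect_false("g_null" %in% cons$gene)  # not selected in either
  # consistency is symmetric in cohort order
  cons_rev <- consistent_correlations(cb, ca)
  expect_setequal(cons$gene, cons_rev$gene)
})

test_that("screen hits use |0.2| for viability and |z| > 1.96 for lysate endpoints", {
  set.seed(55)
  lys <- rnorm(40)
  lys[1] <- mean(lys[-1]) + 4 * sd(lys[-1])  # clear outlier
  d <- data.frame(
    cell_line = "KPL4",
    mirna = paste0("m", 1:44),
    endpoint = c(rep("viability", 4), rep("ki67", 40)),
    normalized_value = c(-0.25, 0.15, 0.21, -0.2, lys)
  )
  out <- screen_hit_call(d)
  expect_equal(out$hit[1:4], c(TRUE, FALSE, TRUE, FALSE))  # strict at 0.2
  expect_true(is.na(out$z[1]))
  ki <- out[out$endpoint == "ki67", ]
  expect_equal(ki$z, (lys - mean(lys)) / sd(lys))
  expect_equal(ki$hit, abs(ki$z) > 1.96)
  expect_true(any(ki$hit))
  d0 <- data.frame(cell_line = "a", mirna = "m", endpoint = "pakt",
                   normalized_value = rep(1, 5))
  expect_error(screen_hit_call(d0), "zero standard deviation")
})
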