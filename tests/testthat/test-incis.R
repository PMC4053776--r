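make_ab <- function(cn_states, meth_states, samples = NULL) {
  if (is.null(samples)) samples <- paste0("s", seq_along(cn_states))
  aberration_matrix(
    matrix(cn_states, 1, length(cn_states), dimnames = list("L1", samples)),
    matrix(meth_states, 1, length(meth_states), dimnames = list("L1", samples))
  )
}

test_that("combined-category groups pool either-axis aberrations against clean samples", {
  ab <- make_ab(c("gain", "neutral", "gain", "neutral"),
                c("normal", "hypo", "hypo", "normal"),
                c("gain_only", "hypo_only", "both", "neither"))
  g <- build_groups("L1", ab, "activating", "combined")
  expect_setequal(g$altered, c("gain_only", "hypo_only", "both"))
  expect_equal(g$reference, "neither")
  expect_true(g$cn_contributes && g$meth_contributes)
  # no gains anywhere: copy-number altered group is empty
  ab2 <- make_ab(rep("neutral", 4), rep("normal", 4))
  expect_length(build_groups("L1", ab2, "activating", "copy_number")$altered, 0)
  # silencing scenario is the loss/hyper mirror image
  ab3 <- make_ab(c("loss", "gain", "neutral"), c("hyper", "normal", "normal"))
  gs <- build_groups("L1", ab3, "silencing", "copy_number")
  expect_equal(gs$altered, "s1")
  expect_setequal(gs$reference, c("s2", "s3"))  # gains sit in the reference
})

test_that("groups match a per-sample set-comprehension oracle on random states", {
  set.seed(41)
  for (rep in 1:20) {
    cn <- sample(c("gain", "loss", "neutral", "missing"), 30, replace = TRUE)
    me <- sample(c("hypo", "hyper", "normal", "missing"), 30, replace = TRUE)
    ab <- make_ab(cn, me)
    sm <- paste0("s", 1:30)
    for (sc in c("activating", "silencing")) {
      want_cn <- if (sc == "activating") "gain" else "loss"
      want_me <- if (sc == "activating") "hypo" else "hyper"
      g <- build_groups("L1", ab, sc, "combined")
      expect_setequal(g$altered, sm[cn == want_cn | me == want_me])
      expect_setequal(g$reference,
                      sm[cn != "missing" & me != "missing" &
                           cn != want_cn & me != want_me])
      g1 <- build_groups("L1", ab, sc, "methylation")
      expect_setequal(g1$altered, sm[me == want_me])
      expect_setequal(g1$reference, sm[me != "missing" & me != want_me])
    }
  }
})

test_that("rank-sum test agrees with exhaustive enumeration for small groups", {
  ts <- rank_sum_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(ts$p, 0.1)  # most extreme of C(6,3)=20 assignments, doubled
  expect_equal(ts$W, 6)    # smallest possible rank sum of the first group
  # identical multisets: symmetric, p capped at 1
  expect_equal(rank_sum_test(c(1, 2, 3), c(1, 2, 3))$p, 1)
  set.seed(42)
  for (rep in 1:40) {
    n <- sample(3:8, 1)
    m <- sample(3:8, 1)
    x <- rnorm(n)
    y <- rnorm(m)
    got <- rank_sum_test(x, y)
    oracle <- exact_ranksum(x, y)
    expect_equal(got$W, oracle$W)
    expect_equal(got$p, oracle$p, tolerance = 1e-12)
    # two-sided p is symmetric in the group order
    expect_equal(rank_sum_test(y, x)$p, got$p, tolerance = 1e-12)
  }
  # groups below the minimum size are flagged, not errors
  expect_false(rank_sum_test(c(1, 2), c(3, 4, 5))$testable)
})

test_that("BH adjustment equals the naive step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.73), 0.73)  # single p unchanged
  set.seed(43)
  for (rep in 1:10) {
    p <- runif(sample(5:40, 1))
    q <- bh_adjust(p)
    expect_equal(q, naive_bh(p), tolerance = 1e-12)
    expect_true(all(q <= 1))
    # monotone in p-rank
    expect_true(all(diff(q[order(p)]) >= -1e-12))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Spearman rho with heavy ties equals the mid-rank Pearson oracle", {
  set.seed(44)
  for (rep in 1:15) {
    x <- sample(1:4, 25, replace = TRUE)  # tie-heavy
    y <- x + sample(0:2, 25, replace = TRUE)
    expect_equal(spearman_rho(x, y), spearman_oracle(x, y), tolerance = 1e-12)
  }
  expect_true(is.na(spearman_rho(c(1, 2), c(3, 4))))  # < 3 complete pairs
})

test_that("direction filter keeps positive CN and negative methylation correlations", {
  e <- c(1, 2, 3, 4, 5, 6)
  cn_up <- c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6)
  beta_up <- cn_up
  # rho_cn > 0 under the copy-number category passes
  expect_true(direction_check(e, cn_up, NULL, "copy_number")$passes)
  # positive methylation-expression correlation fails the methylation test
  dc <- direction_check(e, NULL, beta_up, "methylation")
  expect_gt(dc$rho_meth, 0)
  expect_false(dc$passes)
  expect_true(direction_check(e, NULL, rev(beta_up), "methylation")$passes)
  # combined: every contributing axis must pass
  both <- direction_check(e, cn_up, beta_up, "combined",
                          cn_contributes = TRUE, meth_contributes = TRUE)
  expect_false(both$passes)
  cn_only <- direction_check(e, cn_up, beta_up, "combined",
                             cn_contributes = TRUE, meth_contributes = FALSE)
  expect_true(cn_only$passes)
})

test_that("family complementarity is the element-wise OR of member activating states", {
  samples <- paste0("s", 1:6)
  cn <- rbind(LA = c("gain", "neutral", "neutral", "gain", "neutral", "neutral"),
              LB = c("neutral", "neutral", "gain", "neutral", "neutral", "neutral"))
  me <- rbind(LA = rep("normal", 6),
              LB = c("normal", "hypo", "normal", "normal", "normal", "normal"))
  colnames(cn) <- colnames(me) <- samples
  ab <- aberration_matrix(cn, me)
  ann <- group_families(mirna_annotation(
    c("LA", "LB"), c("mA", "mB"), "chr1", c(100, 900), c(121, 921), "+",
    rep("UCAGUGCACUACAGAACUUUGU", 2)  # identical seed -> one family
  ))
  incis <- data.frame(locus_id = c("LA", "LB"), effect = "activating",
                      driver_class = "copy_number")
  prof <- family_complementarity(ann, ab, incis)
  expect_length(prof, 1)
  member_oracle <- (cn == "gain") | (me == "hypo")
  expect_equal(prof[[1]]$member_state, member_oracle)
  expect_equal(prof[[1]]$overall, apply(member_oracle, 2, any))
  expect_equal(prof[[1]]$fraction_altered, 4 / 6)
  # a patient with {gain, normal} members is overall altered; all-clean is not
  expect_true(prof[[1]]$overall[["s1"]])
  expect_false(prof[[1]]$overall[["s5"]])
  # families with fewer than two in-cis members are skipped
  prof2 <- family_complementarity(ann, ab, incis[1, , drop = FALSE])
  expect_length(prof2, 0)
})

test_that("detection on a small synthetic cohort recovers planted loci", {
  b <- generate_cohort(small_config(seed = 2))
  prep <- prepare_cohort(b)
  det <- detect_incis(prep)
  ev <- evaluate_against_truth(det, b$truth)
  expect_gte(ev$sensitivity, 0.8)
  expect_lte(ev$fdp, 0.2)
  # q >= p everywhere and all significant calls pass the direction filter
  expect_true(all(det$results$q >= det$results$p - 1e-12))
  expect_true(all(det$results$passes_direction[det$results$significant]))
  # a cohort with no aberrations at all yields no testable in-cis loci
  ab0 <- prep$aberrations
  ab0$cn_state[] <- "neutral"
  ab0$meth_state[] <- "normal"
  prep0 <- prep
  prep0$aberrations <- ab0
  expect_warning(det0 <- detect_incis(prep0), "no testable")
  expect_null(det0$incis)
})

test_that("paired CpG assays report the more conservative of the two p-values", {
  set.seed(45)
  # discovery: one hypomethylation-driven locus
  n <- 60
  tumors <- paste0("t", 1:n)
  altered <- tumors[1:20]
  e <- setNames(rnorm(n, 8, 0.5), tumors)
  e[altered] <- e[altered] + 1.5
  beta <- setNames(rep(0.5, n) + rnorm(n, 0, 0.02), tumors)
  beta[altered] <- beta[altered] - 0.2
  lb <- matrix(beta, 1, n, dimnames = list("LX", tumors))
  nb <- matrix(0.5 + rnorm(12, 0, 0.02), 1, 12,
               dimnames = list("LX", paste0("nn", 1:12)))
  refs <- fit_normal_reference(nb)
  st <- call_methylation_state(lb, refs)
  disc_bundle <- list(
    expression = matrix(e, 1, n, dimnames = list("LX", tumors)),
    locus_cn = NULL, locus_beta = lb,
    aberrations = aberration_matrix(meth_state = st)
  )
  disc <- detect_incis(disc_bundle)
  expect_equal(disc$incis$locus_id, "LX")
  # replication with two probes over the same promoter, one noisier
  e2 <- setNames(rnorm(n, 8, 0.5), tumors)
  e2[altered] <- e2[altered] + 1.2
  b1 <- beta
  b2 <- beta + rnorm(n, 0, 0.08)  # second assay degraded
  pb <- rbind(cg_a = b1, cg_b = pmin(1, pmax(0, b2)))
  colnames(pb) <- tumors
  pbn <- rbind(cg_a = 0.5 + rnorm(12, 0, 0.02), cg_b = 0.5 + rnorm(12, 0, 0.08))
  colnames(pbn) <- paste0("nn", 1:12)
  repl_bundle <- list(
    expression = matrix(e2, 1, n, dimnames = list("LX", tumors)),
    locus_cn = NULL, locus_beta = NULL,
    aberrations = aberration_matrix(
      meth_state = matrix("missing", 1, n, dimnames = list("LX", tumors))),
    probe_beta = pb, probe_beta_normals = pbn
  )
  rp <- replicate_incis(disc, repl_bundle,
                        cpg_pairs = list(LX = c("cg_a", "cg_b")))
  # oracle: run the single-assay test for each probe via the public API
  p_each <- vapply(c("cg_a", "cg_b"), function(pr) {
    r1 <- fit_normal_reference(pbn[pr, , drop = FALSE])
    s1 <- call_methylation_state(pb[pr, , drop = FALSE], r1)
    rownames(s1) <- "LX"
    g <- build_groups("LX", aberration_matrix(meth_state = s1),
                      "activating", "methylation")
    rank_sum_test(e2[g$altered], e2[g$reference])$p
  }, numeric(1))
  expect_equal(rp$tests$p, max(p_each))
})
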