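# Independent oracles used across test files. These deliberately use naive
# algorithms (exhaustive enumeration, full sorts) so they share no code path
# with the implementation they check.

# minimum of SSE + gamma * breakpoints over all 2^(n-1) breakpoint subsets
brute_force_pcf <- function(x, gamma) {
  n <- length(x)
  best <- Inf
  best_k <- NA_integer_
  for (mask in 0:(2^(n - 1) - 1)) {
    cuts <- which(bitwAnd(mask, 2^(0:(n - 2))) > 0)  # breakpoint after index
    bounds <- c(0, cuts, n)
    sse <- 0
    for (s in seq_len(length(bounds) - 1)) {
      seg <- x[(bounds[s] + 1):bounds[s + 1]]
      sse <- sse + sum((seg - mean(seg))^2)
    }
    obj <- sse + gamma * length(cuts)
    if (obj < best) {
      best <- obj
      best_k <- length(cuts) + 1L
    }
  }
  list(objective = best, n_segments = best_k)
}

# exact two-sided rank-sum p by enumerating all C(n+m, n) group assignments
exact_ranksum <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x)
  r <- rank(pooled)  # mid-ranks
  W_obs <- sum(r[seq_len(n)])
  combos <- utils::combn(length(pooled), n)
  Ws <- colSums(matrix(r[combos], nrow = n))
  mu <- n * (length(pooled) + 1) / 2
  p <- mean(abs(Ws - mu) >= abs(W_obs - mu) - 1e-9)
  list(W = W_obs, p = min(1, p))
}

# quadratic-time BH from the definition
naive_bh <- function(p) {
  m <- length(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(1, min(vapply(seq_len(m), function(j) {
      if (p[j] >= p[i]) {
        rj <- sum(p <= p[j])
        min(1, p[j] * m / rj)
      } else Inf
    }, numeric(1))))
  }
  q
}

# Spearman rho as Pearson on mid-ranks, written out
spearman_oracle <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  mx <- mean(rx)
  my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# two-group log-rank chi-square from the O-E / hypergeometric-variance table
logrank_oracle <- function(time, event, group) {
  stopifnot(length(unique(group)) == 2)
  g1 <- sort(unique(group))[1]
  O <- 0; E <- 0; V <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n_t <- sum(at_risk)
    n1 <- sum(at_risk & group == g1)
    d_t <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == g1)
    O <- O + d1
    E <- E + d_t * n1 / n_t
    if (n_t > 1) {
      V <- V + d_t * (n1 / n_t) * (1 - n1 / n_t) * (n_t - d_t) / (n_t - 1)
    }
  }
  chisq <- (O - E)^2 / V
  list(chisq = chisq, p = pchisq(chisq, 1, lower.tail = FALSE))
}

# Kruskal-Wallis H with tie correction, from the definition
kruskal_oracle_H <- function(values, group) {
  n <- length(values)
  r <- rank(values)
  H <- 12 / (n * (n + 1)) *
    sum(tapply(r, group, function(ri) length(ri) * mean(ri)^2)) -
    3 * (n + 1)
  ties <- table(values)
  H / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# small-cohort simulation settings shared by unit tests; scaled down from the
# default study conditions for speed, never used by the acceptance tests
small_config <- function(seed = 1, ...) {
  simulation_config(
    n_tumors = 40, n_normals = 10, n_chromosomes = 3, probes_per_chrom = 200,
    n_loci = 60, n_families_multilocus = 2, n_multicopy_mature = 2,
    n_gain_driven = 4, n_hypo_driven = 4, n_loss_driven = 2,
    n_hyper_driven = 2, n_combined = 2, cn_window_probes = 41,
    n_mrna_genes = 40, seed = seed, ...
  )
}

# hand-built three-tier annotation + probes used by locus-model tests
tier_fixture <- function() {
  ann <- mirna_annotation(
    locus_id = c("L1", "L2", "L3"),
    mature_id = c("miR-a", "miR-b", "miR-c"),
    chrom = "chr1", start = c(1000L, 50000L, 90000L),
    end = c(1021L, 50021L, 90021L), strand = "+",
    mature_sequence = c("UCAGUGCACUACAGAACUUUGU",
                        "UGUAAACAUCCUACACUCAGCU",
                        "UAUUGCACUUGUCCCGGCCUGU"),
    host_gene = c(NA, "HOST1", NA),
    intronic = c(FALSE, TRUE, FALSE)
  )
  probes <- probe_annotation(
    probe_id = c("p1", "p2", "p3", "hp1", "hp2", "body1", "far"),
    chrom = "chr1",
    pos = c(900L, 950L, 1100L, 48000L, 48100L, 50500L, 91000L),
    feature_class = c("TSS1500", "TSS1500", "FirstExon", "TSS1500", "5UTR",
                      "Body", "TSS1500"),
    gene = c(NA, NA, NA, "HOST1", "HOST1", "HOST1", NA),
    designated_locus_ids = c("L1", "L1", "L1", "", "", "", "")
  )
  list(ann = ann, probes = probes)
}
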