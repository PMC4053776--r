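.scenario_states <- function(scenario) {
  switch(scenario,
    activating = list(cn = "gain", meth = "hypo"),
    silencing = list(cn = "loss", meth = "hyper"),
    stop("unknown scenario: ", scenario)
  )
}

#' Partition samples into altered and reference groups for one locus
#'
#' Under the activating scenario the aberrations of interest are copy-number
#' gain and hypomethylation; under the silencing scenario, loss and
#' hypermethylation. The `copy_number` and `methylation` categories test one
#' axis; `combined` pools samples with at least one aberration of the
#' scenario type on either axis against samples with none. Reference samples
#' must have non-missing state on the tested axis (both axes for
#' `combined`).
#'
#' @param locus_id Locus to test.
#' @param aberrations An [aberration_matrix()].
#' @param scenario `"activating"` or `"silencing"`.
#' @param category `"copy_number"`, `"methylation"` or `"combined"`.
#' @return List with character vectors `altered` and `reference` (sample
#'   ids), and logicals `cn_contributes`, `meth_contributes` recording which
#'   axes put samples into the altered group.
#' @export
build_groups <- function(locus_id, aberrations,
                         scenario = c("activating", "silencing"),
                         category = c("copy_number", "methylation", "combined")) {
  scenario <- match.arg(scenario)
  category <- match.arg(category)
  if (!locus_id %in% rownames(aberrations$cn_state)) {
    stop("locus not in aberration matrix: ", locus_id)
  }
  st <- .scenario_states(scenario)
  cn <- aberrations$cn_state[locus_id, ]
  me <- aberrations$meth_state[locus_id, ]
  samples <- colnames(aberrations$cn_state)
  cn_ok <- cn != "missing"
  me_ok <- me != "missing"
  cn_alt <- cn_ok & cn == st$cn
  me_alt <- me_ok & me == st$meth
  if (category == "copy_number") {
    altered <- samples[cn_alt]
    reference <- samples[cn_ok & !cn_alt]
    contrib <- c(cn = TRUE, meth = FALSE)
  } else if (category == "methylation") {
    altered <- samples[me_alt]
    reference <- samples[me_ok & !me_alt]
    contrib <- c(cn = FALSE, meth = TRUE)
  } else {
    altered <- samples[cn_alt | me_alt]
    reference <- samples[cn_ok & me_ok & !cn_alt & !me_alt]
    contrib <- c(cn = any(cn_alt), meth = any(me_alt))
  }
  list(altered = altered, reference = reference,
       cn_contributes = unname(contrib["cn"]),
       meth_contributes = unname(contrib["meth"]))
}

#' Wilcoxon rank-sum test with mid-ranks
#'
#' `W` is the rank sum of the first group (mid-ranks for ties). The two-sided
#' p-value is from exact enumeration when the pooled size is at most 20 and
#' there are no ties, otherwise from the normal approximation with tie and
#' continuity correction.
#'
#' @param x,y Numeric value vectors of the two groups.
#' @param min_group_size Groups below this size are flagged untestable
#'   (default 3).
#' @return List with `W`, `p`, and `testable`; untestable inputs give
#'   `W = NA`, `p = NA`, `testable = FALSE` rather than an error.
#' @export
rank_sum_test <- function(x, y, min_group_size = 3) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  n <- length(x)
  m <- length(y)
  if (n < min_group_size || m < min_group_size) {
    return(list(W = NA_real_, p = NA_real_, testable = FALSE))
  }
  ht <- suppressWarnings(
    wilcox.test(x, y, exact = (n + m) <= 20, correct = TRUE)
  )
  # wilcox.test reports the Mann-Whitney U; convert to the rank sum of x
  list(W = unname(ht$statistic) + n * (n + 1) / 2,
       p = min(ht$p.value, 1), testable = TRUE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment `q_(i) = min_{j >= i} min(1, p_(j) * m / j)` mapped
#' back to input order; missing values stay missing and do not count toward
#' `m`.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values in input order.
#' @export
bh_adjust <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(pvalues, method = "BH")
}

#' Spearman correlation over complete pairs
#'
#' Mid-rank Spearman rho; returns `NA` with fewer than `min_pairs` complete
#' pairs or when either ranking is constant.
#'
#' @param x,y Numeric vectors.
#' @param min_pairs Minimum complete pairs (default 3).
#' @return Single numeric rho (or `NA`).
#' @export
spearman_rho <- function(x, y, min_pairs = 3) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < min_pairs) return(NA_real_)
  if (length(unique(x[ok])) < 2 || length(unique(y[ok])) < 2) return(NA_real_)
  cor(x[ok], y[ok], method = "spearman")
}

#' Direction filter for candidate in-cis loci
#'
#' A copy-number association is kept only with positive copy
#' number-expression correlation; a methylation association only with
#' negative methylation-expression correlation. For the combined category the
#' requirement applies to every axis that contributed samples to the altered
#' group.
#'
#' @param expression Numeric expression vector over samples.
#' @param locus_cn Segment-assigned copy-number vector over the same samples
#'   (may be `NULL` when the axis was not measured).
#' @param locus_beta Locus methylation beta vector (may be `NULL`).
#' @param category Test category.
#' @param cn_contributes,meth_contributes For `combined`, which axes placed
#'   samples in the altered group (see [build_groups()]).
#' @return List with `rho_cn`, `rho_meth`, `passes` (logical, `NA` when the
#'   needed correlation is not computable).
#' @export
direction_check <- function(expression, locus_cn = NULL, locus_beta = NULL,
                            category = c("copy_number", "methylation", "combined"),
                            cn_contributes = TRUE, meth_contributes = TRUE) {
  category <- match.arg(category)
  rho_cn <- if (is.null(locus_cn)) NA_real_ else spearman_rho(locus_cn, expression)
  rho_meth <- if (is.null(locus_beta)) NA_real_ else spearman_rho(locus_beta, expression)
  cn_pass <- if (is.na(rho_cn)) NA else rho_cn > 0
  meth_pass <- if (is.na(rho_meth)) NA else rho_meth < 0
  passes <- switch(category,
    copy_number = cn_pass,
    methylation = meth_pass,
    combined = {
      need <- c(if (cn_contributes) cn_pass, if (meth_contributes) meth_pass)
      if (length(need) == 0) NA else all(need)
    }
  )
  list(rho_cn = rho_cn, rho_meth = rho_meth, passes = passes)
}

.test_specs <- function() {
  expand.grid(scenario = c("activating", "silencing"),
              category = c("copy_number", "methylation", "combined"),
              stringsAsFactors = FALSE)
}

#' Detect in-cis miRNAs in one cohort
#'
#' Runs, for every locus, six tests (activating and silencing scenarios x
#' copy-number, methylation and combined categories): Wilcoxon rank-sum on
#' expression between altered and reference samples, Benjamini-Hochberg
#' adjustment within each scenario-category family across testable loci, and
#' the correlation direction filter. A locus is in-cis if any test reaches
#' `q < fdr_alpha` and passes the direction filter.
#'
#' @param bundle List with `expression` (loci x samples, normalized,
#'   locus-expanded), `aberrations` (an [aberration_matrix()]), `locus_cn`
#'   and `locus_beta` matrices (either may be `NULL` if unmeasured).
#' @param min_group_size Minimum altered/reference group size (default 3);
#'   smaller groups make a locus untestable for that spec and it is excluded
#'   from the BH denominator.
#' @param fdr_alpha Significance threshold on q (default 0.05).
#' @return List with `results` (one row per locus x testable spec, columns
#'   `locus_id`, `scenario`, `category`, `n_altered`, `n_ref`, `W`, `p`, `q`,
#'   `rho_cn`, `rho_meth`, `passes_direction`, `significant`) and `incis`
#'   (one row per in-cis locus: `locus_id`, `effect`, `driver_class`).
#' @export
detect_incis <- function(bundle, min_group_size = 3, fdr_alpha = 0.05) {
  expr <- bundle$expression
  ab <- bundle$aberrations
  samples <- intersect(colnames(expr), colnames(ab$cn_state))
  loci <- intersect(rownames(expr), rownames(ab$cn_state))
  if (length(loci) == 0 || length(samples) == 0) {
    warning("no testable loci or samples shared between expression and aberrations")
    return(list(results = NULL, incis = NULL))
  }
  specs <- .test_specs()
  rows <- vector("list", length(loci) * nrow(specs))
  k <- 0L
  for (lid in loci) {
    e <- expr[lid, samples]
    cn_v <- if (!is.null(bundle$locus_cn) && lid %in% rownames(bundle$locus_cn)) {
      bundle$locus_cn[lid, samples]
    } else NULL
    be_v <- if (!is.null(bundle$locus_beta) && lid %in% rownames(bundle$locus_beta)) {
      bundle$locus_beta[lid, samples]
    } else NULL
    for (s in seq_len(nrow(specs))) {
      sc <- specs$scenario[s]
      ca <- specs$category[s]
      if (ca %in% c("methylation", "combined") && is.null(be_v) &&
          is.null(bundle$locus_beta)) next
      g <- build_groups(lid, ab, sc, ca)
      g$altered <- intersect(g$altered, samples)
      g$reference <- intersect(g$reference, samples)
      ts <- rank_sum_test(e[g$altered], e[g$reference], min_group_size)
      if (!ts$testable) next
      dc <- direction_check(e, cn_v, be_v, ca,
                            g$cn_contributes, g$meth_contributes)
      k <- k + 1L
      rows[[k]] <- data.frame(
        locus_id = lid, scenario = sc, category = ca,
        n_altered = length(g$altered), n_ref = length(g$reference),
        W = ts$W, p = ts$p, q = NA_real_,
        rho_cn = dc$rho_cn, rho_meth = dc$rho_meth,
        passes_direction = dc$passes,
        stringsAsFactors = FALSE
      )
    }
  }
  if (k == 0L) {
    warning("no testable locus/spec combinations")
    return(list(results = NULL, incis = NULL))
  }
  res <- do.call(rbind, rows[seq_len(k)])
  for (s in seq_len(nrow(specs))) {
    sel <- res$scenario == specs$scenario[s] & res$category == specs$category[s]
    if (any(sel)) res$q[sel] <- bh_adjust(res$p[sel])
  }
  res$significant <- res$q < fdr_alpha & !is.na(res$passes_direction) &
    res$passes_direction
  list(results = res, incis = .summarize_incis(res))
}

# per-locus effect and driver class from the per-spec results
.summarize_incis <- function(res) {
  sig <- res[res$significant, , drop = FALSE]
  if (nrow(sig) == 0) {
    return(data.frame(locus_id = character(0), effect = character(0),
                      driver_class = character(0), stringsAsFactors = FALSE))
  }
  out <- lapply(split(sig, sig$locus_id), function(d) {
    act <- any(d$scenario == "activating")
    sil <- any(d$scenario == "silencing")
    effect <- if (act && sil) "both" else if (act) "activating" else "silencing"
    cn_sig <- any(d$category == "copy_number")
    meth_sig <- any(d$category == "methylation")
    driver <- if (cn_sig && !meth_sig) "copy_number"
      else if (meth_sig && !cn_sig) "methylation"
      else "combination"  # both single-axis tests, or only the combined test
    data.frame(locus_id = d$locus_id[1], effect = effect,
               driver_class = driver, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$locus_id), , drop = FALSE]
}

#' Label the inferred aberration mechanism of an in-cis locus
#'
#' Maps the per-spec results of one locus to a single mechanism label
#' comparable to a simulation truth table: `gain`, `loss`, `hypo`, `hyper`
#' when one axis drives the signal (scenario gives the direction), `combined`
#' when the driver class is a combination.
#'
#' @param results The `results` table from [detect_incis()].
#' @param incis The `incis` table from [detect_incis()].
#' @return Named character vector, one label per in-cis locus.
#' @export
mechanism_label <- function(results, incis) {
  if (is.null(incis) || nrow(incis) == 0) return(character(0))
  lab <- vapply(seq_len(nrow(incis)), function(i) {
    lid <- incis$locus_id[i]
    if (incis$driver_class[i] == "combination") return("combined")
    d <- results[results$locus_id == lid & results$significant, , drop = FALSE]
    d <- d[d$category != "combined", , drop = FALSE]
    d <- d[which.min(d$p), , drop = FALSE]  # strongest single-axis signal
    if (d$category == "copy_number") {
      if (d$scenario == "activating") "gain" else "loss"
    } else {
      if (d$scenario == "activating") "hypo" else "hyper"
    }
  }, character(1), USE.NAMES = FALSE)
  setNames(lab, incis$locus_id)
}

#' Replicate discovered in-cis miRNAs in an independent cohort
#'
#' Each discovery candidate's significant scenario/category tests are re-run
#' on the replication cohort where the corresponding axis was measured. A
#' candidate replicates if a matching test reaches uncorrected
#' `p < replication_alpha` with the same aberration type and passes the
#' direction filter. When two CpG assays cover the same promoter, the test is
#' run separately per assay and the larger (most conservative) p-value is
#' reported. Candidates absent from the replication expression matrix are
#' dropped from the denominator; candidates with no measurable axis are
#' marked unassessable.
#'
#' @param discovery Output of [detect_incis()] on the discovery cohort.
#' @param repl_bundle Bundle for the replication cohort (as [detect_incis()];
#'   for paired-assay testing also `probe_beta` and `probe_beta_normals`
#'   probe-level matrices).
#' @param min_group_size,replication_alpha Test configuration (defaults 3 and
#'   0.05).
#' @param cpg_pairs Optional named list: locus id -> the two probe ids whose
#'   assays cover that promoter.
#' @param k Threshold multiplier for per-assay methylation calling
#'   (default 2).
#' @return List with `tests` (per candidate x re-run spec: `p`,
#'   `passes_direction`, `replicated`) and `candidates` (per candidate:
#'   `assessable`, `replicated`, `replicated_type`).
#' @export
replicate_incis <- function(discovery, repl_bundle, min_group_size = 3,
                            replication_alpha = 0.05, cpg_pairs = NULL, k = 2) {
  cand <- discovery$incis
  if (is.null(cand) || nrow(cand) == 0) {
    return(list(tests = NULL, candidates = NULL))
  }
  expr <- repl_bundle$expression
  ab <- repl_bundle$aberrations
  samples <- colnames(expr)
  test_rows <- list()
  cand_rows <- list()
  for (i in seq_len(nrow(cand))) {
    lid <- cand$locus_id[i]
    if (!lid %in% rownames(expr)) next  # not expressed in replication
    e <- expr[lid, samples]
    disc <- discovery$results
    disc <- disc[disc$locus_id == lid & disc$significant, , drop = FALSE]
    cn_v <- if (!is.null(repl_bundle$locus_cn) &&
                lid %in% rownames(repl_bundle$locus_cn)) {
      repl_bundle$locus_cn[lid, samples]
    } else NULL
    be_v <- if (!is.null(repl_bundle$locus_beta) &&
                lid %in% rownames(repl_bundle$locus_beta)) {
      repl_bundle$locus_beta[lid, samples]
    } else NULL
    any_assessable <- FALSE
    rep_types <- character(0)
    for (j in seq_len(nrow(disc))) {
      sc <- disc$scenario[j]
      ca <- disc$category[j]
      measurable <- switch(ca,
        copy_number = !is.null(cn_v),
        methylation = !is.null(be_v) || !is.null(cpg_pairs[[lid]]),
        combined = !is.null(cn_v) && (!is.null(be_v) || !is.null(cpg_pairs[[lid]]))
      )
      if (!measurable) next
      any_assessable <- TRUE
      if (ca == "methylation" && !is.null(cpg_pairs[[lid]])) {
        out <- .paired_cpg_test(lid, cpg_pairs[[lid]], repl_bundle, sc,
                                e, samples, min_group_size, k)
        p <- out$p
        passes <- out$passes
      } else {
        g <- build_groups(lid, ab, sc, ca)
        ts <- rank_sum_test(e[intersect(g$altered, samples)],
                            e[intersect(g$reference, samples)],
                            min_group_size)
        dc <- direction_check(e, cn_v, be_v, ca,
                              g$cn_contributes, g$meth_contributes)
        p <- ts$p
        passes <- dc$passes
      }
      replicated <- !is.na(p) && p < replication_alpha &&
        !is.na(passes) && passes
      if (replicated) rep_types <- c(rep_types, paste(sc, ca, sep = "/"))
      test_rows[[length(test_rows) + 1L]] <- data.frame(
        locus_id = lid, scenario = sc, category = ca, p = p,
        passes_direction = passes, replicated = replicated,
        stringsAsFactors = FALSE
      )
    }
    cand_rows[[length(cand_rows) + 1L]] <- data.frame(
      locus_id = lid, assessable = any_assessable,
      replicated = length(rep_types) > 0,
      replicated_type = paste(rep_types, collapse = ";"),
      stringsAsFactors = FALSE
    )
  }
  list(tests = if (length(test_rows)) do.call(rbind, test_rows) else NULL,
       candidates = if (length(cand_rows)) do.call(rbind, cand_rows) else NULL)
}

# run the methylation-category test once per CpG assay and keep the larger p
.paired_cpg_test <- function(lid, probe_ids, repl_bundle, scenario, e,
                             samples, min_group_size, k) {
  ps <- numeric(0)
  passes <- logical(0)
  for (pr in probe_ids) {
    if (!pr %in% rownames(repl_bundle$probe_beta) ||
        !pr %in% rownames(repl_bundle$probe_beta_normals)) next
    nb <- repl_bundle$probe_beta_normals[pr, , drop = FALSE]
    tb <- repl_bundle$probe_beta[pr, samples, drop = FALSE]
    rownames(nb) <- rownames(tb) <- lid
    refs <- fit_normal_reference(nb, k = k)
    st <- call_methylation_state(tb, refs)
    ab1 <- aberration_matrix(meth_state = st)
    g <- build_groups(lid, ab1, scenario, "methylation")
    ts <- rank_sum_test(e[intersect(g$altered, samples)],
                        e[intersect(g$reference, samples)], min_group_size)
    dc <- direction_check(e, NULL, tb[lid, ], "methylation")
    ps <- c(ps, ts$p)
    passes <- c(passes, isTRUE(dc$passes))
  }
  if (length(ps) == 0 || all(is.na(ps))) {
    return(list(p = NA_real_, passes = NA))
  }
  worst <- which.max(ps)  # most conservative assay
  list(p = ps[worst], passes = all(passes))
}

#' Seed-family complementarity profiles
#'
#' For each seed family with at least two in-cis member loci, computes the
#' per-sample activating aberration state of every member (copy-number gain
#' or hypomethylation) and the family's overall state (logical OR over
#' members), plus the fraction of samples with at least one activating
#' aberration in the family.
#'
#' @param annotations A [group_families()]-annotated [mirna_annotation()].
#' @param aberrations An [aberration_matrix()].
#' @param incis The `incis` table from [detect_incis()].
#' @return List of profiles, each with `family_id`, `locus_ids`,
#'   `member_state` (loci x samples logical), `overall` (per-sample logical)
#'   and `fraction_altered`.
#' @export
family_complementarity <- function(annotations, aberrations, incis) {
  if (is.null(incis) || nrow(incis) == 0) return(list())
  fam <- split(annotations$locus_id, annotations$family_id)
  fam <- lapply(fam, intersect, incis$locus_id)
  fam <- fam[lengths(fam) >= 2]
  lapply(seq_along(fam), function(i) {
    ids <- intersect(fam[[i]], rownames(aberrations$cn_state))
    member <- aberrations$cn_state[ids, , drop = FALSE] == "gain" |
      aberrations$meth_state[ids, , drop = FALSE] == "hypo"
    overall <- apply(member, 2, any)
    list(family_id = names(fam)[i], locus_ids = ids, member_state = member,
         overall = overall, fraction_altered = mean(overall))
  })
}
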