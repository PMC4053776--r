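#' Construct a clinical covariate table
#'
#' @param sample_id Sample identifiers.
#' @param er,her2 `"pos"`, `"neg"` or `NA`.
#' @param grade Histological grade 1/2/3 or `NA`.
#' @param tp53 `"wildtype"`, `"mutant"` or `NA`.
#' @param subtype `"luminal"`, `"basal"`, `"other"` or `NA`.
#' @param rfs_time Relapse-free survival time (>= 0).
#' @param rfs_event 1 = relapse/death, 0 = censored, `NA` = unknown.
#' @return `data.frame` with class `clinical_table`.
#' @export
clinical_table <- function(sample_id, er = NA, her2 = NA, grade = NA,
                           tp53 = NA, subtype = NA, rfs_time = NA,
                           rfs_event = NA) {
  d <- data.frame(
    sample_id = as.character(sample_id),
    er = as.character(er), her2 = as.character(her2),
    grade = as.integer(grade), tp53 = as.character(tp53),
    subtype = as.character(subtype),
    rfs_time = as.numeric(rfs_time), rfs_event = as.integer(rfs_event),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(d$sample_id)) stop("duplicated sample_id in clinical table")
  if (any(d$rfs_time < 0, na.rm = TRUE)) stop("rfs_time must be non-negative")
  class(d) <- c("clinical_table", "data.frame")
  d
}

#' Scan replicated in-cis miRNAs for clinical/molecular associations
#'
#' Two-level variables (ER, HER2, TP53, subtype) use the Wilcoxon rank-sum
#' test; histological grade uses Kruskal-Wallis with tie correction. P-values
#' are BH-adjusted across loci per variable.
#'
#' @param expression Loci x samples normalized expression matrix (typically
#'   restricted to replicated in-cis loci).
#' @param clinical A [clinical_table()].
#' @param variable One of `"er"`, `"her2"`, `"grade"`, `"tp53"`, `"subtype"`.
#'   For `"subtype"` only luminal and basal samples are compared.
#' @param min_group_size Minimum per-level sample count (default 3).
#' @param fdr_alpha Significance threshold on q (default 0.05).
#' @return `data.frame` with `locus_id`, `variable`, `test`, `p`, `q`,
#'   `significant`, `direction` (for two-level variables the median
#'   expression difference, level2 minus level1; for grade the Spearman rho
#'   of expression vs grade), or `NULL` when the variable is degenerate.
#' @export
association_scan <- function(expression, clinical, variable,
                             min_group_size = 3, fdr_alpha = 0.05) {
  stopifnot(is.matrix(expression))
  cl <- clinical[match(colnames(expression), clinical$sample_id), ]
  v <- switch(variable,
    er = cl$er, her2 = cl$her2, tp53 = cl$tp53,
    subtype = ifelse(cl$subtype %in% c("luminal", "basal"), cl$subtype, NA),
    grade = cl$grade,
    stop("unknown clinical variable: ", variable)
  )
  lv <- sort(unique(v[!is.na(v)]))
  counts <- table(v)
  if (length(lv) < 2 || sum(counts >= min_group_size) < 2) {
    warning("variable '", variable, "' has fewer than two usable levels; skipped")
    return(NULL)
  }
  rows <- lapply(rownames(expression), function(lid) {
    e <- expression[lid, ]
    if (variable == "grade") {
      ok <- !is.na(v) & !is.na(e)
      grp <- factor(v[ok])
      if (nlevels(grp) < 2 || any(table(grp) < min_group_size)) return(NULL)
      ht <- kruskal.test(e[ok], grp)
      # all observations tied: H degenerates to 0/0; no evidence, p = 1
      p_kw <- if (is.finite(ht$p.value)) ht$p.value else 1
      data.frame(locus_id = lid, variable = variable, test = "kruskal_wallis",
                 p = p_kw, direction = spearman_rho(e[ok], v[ok]),
                 stringsAsFactors = FALSE)
    } else {
      x <- e[!is.na(v) & v == lv[1]]
      y <- e[!is.na(v) & v == lv[2]]
      ts <- rank_sum_test(x, y, min_group_size)
      if (!ts$testable) return(NULL)
      data.frame(locus_id = lid, variable = variable, test = "wilcoxon",
                 p = ts$p,
                 direction = median(y, na.rm = TRUE) - median(x, na.rm = TRUE),
                 stringsAsFactors = FALSE)
    }
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) return(NULL)
  res <- do.call(rbind, rows)
  res$q <- bh_adjust(res$p)
  res$significant <- res$q < fdr_alpha
  res[, c("locus_id", "variable", "test", "p", "q", "significant", "direction")]
}

#' Clinical associations consistent across two cohorts
#'
#' Keeps loci significant (`q < alpha`) for the same variable in both
#' cohorts with concordant direction.
#'
#' @param results_a,results_b [association_scan()] outputs for one variable
#'   in each cohort.
#' @param alpha Threshold on q (default 0.05).
#' @param require_concordant_direction Default `TRUE`.
#' @return Merged `data.frame` of the consistent loci (suffixes `_a`, `_b`).
#' @export
consistent_associations <- function(results_a, results_b, alpha = 0.05,
                                    require_concordant_direction = TRUE) {
  if (is.null(results_a) || is.null(results_b)) {
    return(NULL)
  }
  stopifnot(identical(unique(results_a$variable), unique(results_b$variable)))
  m <- merge(results_a, results_b, by = c("locus_id", "variable"),
             suffixes = c("_a", "_b"))
  keep <- m$q_a < alpha & m$q_b < alpha
  if (require_concordant_direction) {
    keep <- keep & sign(m$direction_a) == sign(m$direction_b)
  }
  m[keep & !is.na(keep), , drop = FALSE]
}

#' Log-rank test after a median split of one locus's expression
#'
#' Samples at or below the median go to the low group, samples strictly
#' above to the high group (with all-unique expression values and even n this
#' yields two equal halves). The two-group log-rank statistic uses the
#' standard hypergeometric variance with tied event times handled by the
#' usual formula; p is from chi-square on 1 df.
#'
#' @param expression Named numeric vector of one locus's expression.
#' @param clinical A [clinical_table()] with `rfs_time` / `rfs_event`.
#' @return List with `group` (named `"low"`/`"high"` factor), `n_low`,
#'   `n_high`, `chisq`, `p`, `testable`. Cohorts without events are flagged
#'   untestable.
#' @export
survival_median_split <- function(expression, clinical) {
  cl <- clinical[match(names(expression), clinical$sample_id), ]
  ok <- !is.na(expression) & !is.na(cl$rfs_time) & !is.na(cl$rfs_event)
  e <- expression[ok]
  time <- cl$rfs_time[ok]
  event <- cl$rfs_event[ok]
  med <- median(e)
  group <- factor(ifelse(e > med, "high", "low"), levels = c("low", "high"))
  if (sum(event) < 2 || nlevels(droplevels(group)) < 2) {
    return(list(group = group, n_low = sum(group == "low"),
                n_high = sum(group == "high"),
                chisq = NA_real_, p = NA_real_, testable = FALSE))
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  list(group = group, n_low = sum(group == "low"),
       n_high = sum(group == "high"),
       chisq = unname(sd$chisq),
       p = pchisq(sd$chisq, df = 1, lower.tail = FALSE),
       testable = TRUE)
}

#' miRNA-mRNA Spearman correlation screen
#'
#' Computes Spearman rho for every (miRNA, gene) pair over shared samples;
#' a pair is selected when `|rho|` strictly exceeds the threshold.
#'
#' @param mirna,mrna Feature x sample expression matrices (columns matched by
#'   name).
#' @param rho_threshold Default 0.3.
#' @param min_pairs Pairs with fewer complete observations are skipped
#'   (default 3).
#' @return `data.frame` with `mirna`, `gene`, `rho`, `selected`.
#' @export
mirna_mrna_correlation <- function(mirna, mrna, rho_threshold = 0.3,
                                   min_pairs = 3) {
  shared <- intersect(colnames(mirna), colnames(mrna))
  if (length(shared) < min_pairs) stop("fewer than min_pairs shared samples")
  a <- t(mirna[, shared, drop = FALSE])
  b <- t(mrna[, shared, drop = FALSE])
  rho <- suppressWarnings(
    cor(a, b, method = "spearman", use = "pairwise.complete.obs")
  )
  n_pair <- crossprod(!is.na(a), !is.na(b))
  rho[n_pair < min_pairs] <- NA
  out <- data.frame(
    mirna = rep(rownames(rho), times = ncol(rho)),
    gene = rep(colnames(rho), each = nrow(rho)),
    rho = as.vector(rho),
    stringsAsFactors = FALSE
  )
  out <- out[!is.na(out$rho), , drop = FALSE]
  out$selected <- abs(out$rho) > rho_threshold
  rownames(out) <- NULL
  out
}

#' Correlated pairs consistent across two cohorts
#'
#' Pairs selected in both cohorts with the same correlation sign.
#'
#' @param cor_a,cor_b [mirna_mrna_correlation()] outputs.
#' @return Merged `data.frame` of consistent pairs (suffixes `_a`, `_b`).
#' @export
consistent_correlations <- function(cor_a, cor_b) {
  m <- merge(cor_a, cor_b, by = c("mirna", "gene"), suffixes = c("_a", "_b"))
  keep <- m$selected_a & m$selected_b & sign(m$rho_a) == sign(m$rho_b)
  m[keep, , drop = FALSE]
}

#' Call hits in the functional miRNA overexpression screen
#'
#' Viability endpoints come in normalized log2 form and a measurement is a
#' hit when its absolute value strictly exceeds 0.2 (the 2-SD band of the
#' screen). Lysate-array endpoints (Ki67, cPARP, p-AKT) are converted to
#' z-scores against the whole screen for that endpoint and are hits when
#' `|z| > 1.96`.
#'
#' @param measurements `data.frame` with columns `cell_line`, `mirna`,
#'   `endpoint` (one of `viability`, `ki67`, `cparp`, `pakt`) and
#'   `normalized_value`.
#' @param viability_cutoff Default 0.2.
#' @param z_cutoff Default 1.96.
#' @return Input with `z` (NA for viability) and `hit` columns added.
#' @export
screen_hit_call <- function(measurements, viability_cutoff = 0.2,
                            z_cutoff = 1.96) {
  stopifnot(all(c("cell_line", "mirna", "endpoint", "normalized_value") %in%
                  names(measurements)))
  ok_ep <- c("viability", "ki67", "cparp", "pakt")
  if (!all(measurements$endpoint %in% ok_ep)) {
    stop("endpoint must be one of: ", paste(ok_ep, collapse = ", "))
  }
  measurements$z <- NA_real_
  measurements$hit <- NA
  for (ep in unique(measurements$endpoint)) {
    sel <- measurements$endpoint == ep
    v <- measurements$normalized_value[sel]
    if (ep == "viability") {
      measurements$hit[sel] <- abs(v) > viability_cutoff
    } else {
      s <- sd(v)
      if (is.na(s) || s == 0) stop("zero standard deviation in screen endpoint ", ep)
      z <- (v - mean(v)) / s
      measurements$z[sel] <- z
      measurements$hit[sel] <- abs(z) > z_cutoff
    }
  }
  measurements
}
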