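#' Normalize log2 miRNA expression by the per-sample 90th percentile
#'
#' Rows (miRNAs) detected in fewer than `detection_fraction` of the samples
#' are removed first; then, per sample, the 90th percentile of the remaining
#' rows is subtracted from that sample's column, so each column's 90th
#' percentile is 0 afterwards.
#'
#' @param raw Numeric matrix of log2 signal intensities (miRNAs x samples).
#' @param detected Logical matrix congruent to `raw` flagging detected
#'   measurements; if `NULL`, non-missing values stand in for detected.
#' @param percentile Percentile to subtract, default 0.90. Quantiles use
#'   linear interpolation between order statistics (type 7).
#' @param detection_fraction Minimum fraction of samples a miRNA must be
#'   detected in, default 0.10 (rows strictly below are excluded).
#' @return The filtered, normalized matrix.
#' @export
normalize_mirna_expression <- function(raw, detected = NULL,
                                       percentile = 0.90,
                                       detection_fraction = 0.10) {
  stopifnot(is.matrix(raw), percentile > 0, percentile < 1,
            detection_fraction > 0, detection_fraction < 1)
  if (is.null(detected)) detected <- !is.na(raw)
  stopifnot(identical(dim(detected), dim(raw)))
  frac <- rowMeans(detected)
  keep <- frac >= detection_fraction
  if (!any(keep)) stop("all miRNAs removed by the detection filter")
  x <- raw[keep, , drop = FALSE]
  q90 <- apply(x, 2, function(col) {
    if (all(is.na(col))) stop("cannot take percentile of an all-missing sample")
    quantile(col, probs = percentile, na.rm = TRUE, type = 7, names = FALSE)
  })
  sweep(x, 2, q90, "-")
}

#' Summarize probe-level methylation to one beta value per miRNA locus
#'
#' When several probes represent a locus the per-sample median beta over the
#' assigned probes is used; single-probe loci pass through unchanged. Samples
#' for which all assigned probes are missing get a missing locus value.
#'
#' @param beta Numeric matrix of beta values in `[0,1]` (probes x samples).
#' @param assignments Probe assignments from [assign_methylation_probes()].
#' @return Locus x sample beta matrix.
#' @export
summarize_locus_methylation <- function(beta, assignments) {
  stopifnot(is.matrix(beta))
  rng <- range(beta, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1) stop("beta values must lie in [0, 1]")
  out <- matrix(NA_real_, nrow(assignments), ncol(beta),
                dimnames = list(assignments$locus_id, colnames(beta)))
  for (i in seq_len(nrow(assignments))) {
    ids <- assignments$probe_ids[[i]]
    missing_ids <- setdiff(ids, rownames(beta))
    if (length(missing_ids) > 0) {
      stop("assigned probes absent from beta matrix: ",
           paste(missing_ids, collapse = ", "))
    }
    sub <- beta[ids, , drop = FALSE]
    out[i, ] <- apply(sub, 2, function(v) {
      v <- v[!is.na(v)]
      if (length(v) == 0) NA_real_ else median(v)
    })
  }
  out
}

#' Center copy-number log-ratios per sample
#'
#' Subtracts each sample's median (or mean) so the per-column centering
#' statistic of the output is 0.
#'
#' @param cn Numeric matrix of log2 copy-number ratios (features x samples).
#' @param statistic `"median"` (default, robust) or `"mean"`.
#' @return Centered matrix.
#' @export
center_log_ratios <- function(cn, statistic = c("median", "mean")) {
  statistic <- match.arg(statistic)
  stopifnot(is.matrix(cn))
  ctr <- apply(cn, 2, function(col) {
    if (all(is.na(col))) stop("cannot center an all-missing sample")
    if (statistic == "median") median(col, na.rm = TRUE) else mean(col, na.rm = TRUE)
  })
  sweep(cn, 2, ctr, "-")
}

#' Average replicate arrays of the same sample
#'
#' Utility for designs where each sample was hybridized more than once:
#' columns sharing a sample id are averaged (mean of non-missing replicates).
#'
#' @param x Numeric matrix, one column per array.
#' @param sample_of Character vector mapping each column to its sample id.
#' @return Matrix with one column per unique sample id.
#' @export
average_replicates <- function(x, sample_of) {
  stopifnot(is.matrix(x), length(sample_of) == ncol(x))
  ids <- unique(sample_of)
  out <- vapply(ids, function(s) {
    rowMeans(x[, sample_of == s, drop = FALSE], na.rm = TRUE)
  }, numeric(nrow(x)))
  out[is.nan(out)] <- NA_real_
  dimnames(out) <- list(rownames(x), ids)
  out
}
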