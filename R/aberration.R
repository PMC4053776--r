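#' Fit a normal-tissue methylation reference per locus
#'
#' For each locus the median `m` and sample standard deviation `sd` (n-1
#' denominator) of beta in the normal samples define the calling thresholds
#' `hi = m + k*sd` and `lo = m - k*sd`. A threshold falling outside the
#' admissible beta range `[0, 1]` cannot discriminate, so the corresponding
#' call is disabled: `hypo_assessable` is `FALSE` when `lo < 0` and
#' `hyper_assessable` is `FALSE` when `hi > 1`.
#'
#' @param normal_beta Locus x sample beta matrix of normal-tissue samples,
#'   values in `[0, 1]` (percent methylation in `[0, 100]` is accepted with
#'   `scale = "percent"` and rescaled).
#' @param k Threshold multiplier, default 2.
#' @param scale `"beta"` (default) or `"percent"`.
#' @return `data.frame` with columns `locus_id`, `m`, `sd`, `hi`, `lo`, `k`,
#'   `hypo_assessable`, `hyper_assessable`, `n_normals`, `usable`. Loci with
#'   fewer than 2 usable normals are flagged `usable = FALSE` and excluded
#'   from methylation calling.
#' @export
fit_normal_reference <- function(normal_beta, k = 2,
                                 scale = c("beta", "percent")) {
  scale <- match.arg(scale)
  stopifnot(is.matrix(normal_beta), k > 0)
  if (scale == "percent") normal_beta <- normal_beta / 100
  rng <- range(normal_beta, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1) stop("beta values must lie in [0, 1]")
  n_ok <- rowSums(!is.na(normal_beta))
  m <- apply(normal_beta, 1, median, na.rm = TRUE)
  s <- apply(normal_beta, 1, sd, na.rm = TRUE)
  usable <- n_ok >= 2
  if (any(!usable)) {
    message(sprintf(
      "%d locus/loci with < 2 usable normals excluded from methylation calling",
      sum(!usable)))
  }
  hi <- m + k * s
  lo <- m - k * s
  data.frame(
    locus_id = rownames(normal_beta),
    m = m, sd = s, hi = hi, lo = lo, k = k,
    hypo_assessable = usable & !(lo < 0),
    hyper_assessable = usable & !(hi > 1),
    n_normals = n_ok,
    usable = usable,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Call per-sample methylation states against a normal reference
#'
#' A tumor sample is `hyper` at a locus if its beta strictly exceeds
#' `m + k*sd` of the normals, `hypo` if strictly below `m - k*sd`, otherwise
#' `normal`. Calls on an axis whose threshold is degenerate (outside `[0,1]`)
#' are not assessed and return `normal`. Missing beta gives `missing`.
#'
#' @param tumor_beta Locus x sample beta matrix.
#' @param refs Reference table from [fit_normal_reference()].
#' @param scale `"beta"` (default) or `"percent"` (values rescaled by 1/100).
#' @return Character matrix of states in
#'   `{"hypo", "normal", "hyper", "missing"}`, loci x samples.
#' @export
call_methylation_state <- function(tumor_beta, refs,
                                   scale = c("beta", "percent")) {
  scale <- match.arg(scale)
  stopifnot(is.matrix(tumor_beta))
  if (scale == "percent") tumor_beta <- tumor_beta / 100
  idx <- match(rownames(tumor_beta), refs$locus_id)
  if (anyNA(idx)) {
    warning("loci without a normal reference are reported as missing: ",
            paste(utils::head(rownames(tumor_beta)[is.na(idx)], 5), collapse = ", "))
  }
  st <- matrix("missing", nrow(tumor_beta), ncol(tumor_beta),
               dimnames = dimnames(tumor_beta))
  for (i in seq_len(nrow(tumor_beta))) {
    j <- idx[i]
    if (is.na(j) || !refs$usable[j]) next
    b <- tumor_beta[i, ]
    s <- ifelse(is.na(b), "missing", "normal")
    if (refs$hyper_assessable[j]) s[!is.na(b) & b > refs$hi[j]] <- "hyper"
    if (refs$hypo_assessable[j]) s[!is.na(b) & b < refs$lo[j]] <- "hypo"
    st[i, ] <- s
  }
  st
}

#' Call per-sample copy-number states from segmented log ratios
#'
#' Gain if the segmented value strictly exceeds `gain_cutoff`, loss if
#' strictly below `loss_cutoff`, otherwise neutral; values exactly at a
#' cutoff are neutral; missing values propagate.
#'
#' @param locus_cn Locus x sample matrix of segment-assigned log2 ratios.
#' @param gain_cutoff Default 0.1.
#' @param loss_cutoff Default -0.1.
#' @return Character matrix of states in
#'   `{"loss", "neutral", "gain", "missing"}`.
#' @export
call_copy_number_state <- function(locus_cn, gain_cutoff = 0.1,
                                   loss_cutoff = -0.1) {
  stopifnot(is.matrix(locus_cn), gain_cutoff > 0, loss_cutoff < 0)
  st <- matrix("neutral", nrow(locus_cn), ncol(locus_cn),
               dimnames = dimnames(locus_cn))
  st[!is.na(locus_cn) & locus_cn > gain_cutoff] <- "gain"
  st[!is.na(locus_cn) & locus_cn < loss_cutoff] <- "loss"
  st[is.na(locus_cn)] <- "missing"
  st
}

#' Bundle copy-number and methylation state layers
#'
#' @param cn_state Matrix from [call_copy_number_state()] (or `NULL`).
#' @param meth_state Matrix from [call_methylation_state()] (or `NULL`).
#' @return List with class `aberration_matrix` and elements `cn_state`,
#'   `meth_state`; layers share locus rows (union) and sample columns, with
#'   `"missing"` filled in where a layer does not cover a locus.
#' @export
aberration_matrix <- function(cn_state = NULL, meth_state = NULL) {
  if (is.null(cn_state) && is.null(meth_state)) {
    stop("at least one state layer is required")
  }
  loci <- union(rownames(cn_state), rownames(meth_state))
  samples <- union(colnames(cn_state), colnames(meth_state))
  pad <- function(m) {
    out <- matrix("missing", length(loci), length(samples),
                  dimnames = list(loci, samples))
    if (!is.null(m)) out[rownames(m), colnames(m)] <- m
    out
  }
  structure(list(cn_state = pad(cn_state), meth_state = pad(meth_state)),
            class = "aberration_matrix")
}

#' Export an aberration matrix as two-character codes
#'
#' Each cell is coded `<cn><meth>` with cn in `{G gain, L loss, . neutral,
#' ? missing}` and meth in `{H hyper, O hypo, . normal, ? missing}`; a legend
#' file is written next to the table.
#'
#' @param ab An [aberration_matrix()].
#' @param path Output file; the legend goes to `<path>.legend`.
#' @export
write_aberrations <- function(ab, path) {
  cn_code <- c(gain = "G", loss = "L", neutral = ".", missing = "?")
  me_code <- c(hyper = "H", hypo = "O", normal = ".", missing = "?")
  codes <- matrix(paste0(cn_code[ab$cn_state], me_code[ab$meth_state]),
                  nrow(ab$cn_state), dimnames = dimnames(ab$cn_state))
  write.table(data.frame(locus_id = rownames(codes), codes,
                         check.names = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(c("position 1 (copy number): G=gain L=loss .=neutral ?=missing",
               "position 2 (methylation): H=hyper O=hypo .=normal ?=missing"),
             paste0(path, ".legend"))
  invisible(path)
}
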