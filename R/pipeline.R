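#' Read a feature x sample matrix from the TSV interchange format
#'
#' First column holds feature ids, the header row sample ids; missing values
#' are encoded `NA`.
#'
#' @param path Input file.
#' @param kind Optional value check: `"beta"` enforces values in `[0, 1]`.
#' @return Numeric matrix with row and column names.
#' @export
read_matrix <- function(path, kind = c("any", "beta")) {
  kind <- match.arg(kind)
  d <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(d) < 2) stop("malformed matrix file (need id column + samples): ", path)
  ids <- as.character(d[[1]])
  if (anyDuplicated(ids)) {
    stop("duplicate feature id in ", path, ": ",
         ids[duplicated(ids)][1])
  }
  samples <- colnames(d)[-1]
  if (anyDuplicated(samples)) {
    stop("duplicate sample id in ", path, ": ",
         samples[duplicated(samples)][1])
  }
  m <- as.matrix(d[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric values in matrix file: ", path)
  dimnames(m) <- list(ids, samples)
  if (kind == "beta") {
    rng <- range(m, na.rm = TRUE)
    if (rng[1] < 0 || rng[2] > 1) {
      stop("beta values outside [0, 1] in ", path)
    }
  }
  m
}

#' @rdname read_matrix
#' @param x Matrix to write (rownames = feature ids).
#' @param digits Significant digits written (default 10).
#' @export
write_matrix <- function(x, path, digits = 10) {
  stopifnot(is.matrix(x), !is.null(rownames(x)), !is.null(colnames(x)))
  d <- data.frame(feature_id = rownames(x),
                  signif(x, digits), check.names = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Prepare one cohort for in-cis testing
#'
#' Runs the per-cohort stages: expression normalization and locus expansion,
#' methylation probe assignment and locus summarization, normal-reference
#' fitting and methylation calling, copy-number centering, segmentation,
#' locus assignment and copy-number calling.
#'
#' @param bundle A [generate_cohort()] bundle or [read_fixture()] list.
#' @param gamma Segmentation penalty (default 40; use a slightly larger value
#'   for lower-resolution replication arrays).
#' @param k Methylation threshold multiplier (default 2).
#' @param percentile,detection_fraction Expression normalization parameters.
#' @param gain_cutoff,loss_cutoff Copy-number call cutoffs.
#' @return List ready for [detect_incis()]: `expression`, `locus_cn`,
#'   `locus_beta`, `aberrations`, plus `segments`, `refs`, `assignments`,
#'   `annotation`, `clinical`, `log` (stage counts).
#' @export
prepare_cohort <- function(bundle, gamma = 40, k = 2, percentile = 0.90,
                           detection_fraction = 0.10,
                           gain_cutoff = 0.1, loss_cutoff = -0.1) {
  log <- list()
  expr_m <- normalize_mirna_expression(bundle$expression_raw, bundle$detected,
                                       percentile, detection_fraction)
  log$n_mature_detected <- nrow(expr_m)
  expression <- expand_to_loci(expr_m, bundle$annotation)
  log$n_loci_expression <- nrow(expression)

  assignments <- assign_methylation_probes(bundle$annotation, bundle$meth_probes)
  log$tier_counts <- table(assignments$tier)
  locus_beta <- summarize_locus_methylation(bundle$beta_tumors, assignments)
  normal_beta <- summarize_locus_methylation(bundle$beta_normals, assignments)
  refs <- fit_normal_reference(normal_beta, k = k)
  meth_state <- call_methylation_state(locus_beta, refs)

  cn_centered <- center_log_ratios(bundle$cn_probes)
  segments <- segment_cohort(cn_centered, bundle$probe_positions, gamma = gamma)
  log$n_segments <- nrow(segments)
  locus_cn <- assign_locus_copy_number(segments, bundle$annotation)
  cn_state <- call_copy_number_state(locus_cn, gain_cutoff, loss_cutoff)

  ab <- aberration_matrix(cn_state, meth_state)
  log$n_cn_aberrant <- sum(cn_state %in% c("gain", "loss"))
  log$n_meth_aberrant <- sum(meth_state %in% c("hypo", "hyper"))

  list(expression = expression, locus_cn = locus_cn, locus_beta = locus_beta,
       aberrations = ab, segments = segments, refs = refs,
       assignments = assignments, annotation = bundle$annotation,
       clinical = bundle$clinical, log = log)
}

#' Run the full in-cis discovery pipeline
#'
#' Sequences preprocessing, segmentation, aberration calling, in-cis
#' detection, optional replication in a second cohort, family
#' complementarity, and (optionally) clinical association scans. Reports are
#' written as TSV files when `outdir` is given.
#'
#' @param discovery Bundle for the discovery cohort.
#' @param replication Optional bundle for the replication cohort.
#' @param gamma,gamma_replication Segmentation penalties (defaults 40 and
#'   50; the replication default accounts for lower array resolution).
#' @param k Methylation threshold multiplier (default 2).
#' @param min_group_size,fdr_alpha,replication_alpha Test configuration.
#' @param clinical_variables Variables to scan (default ER, HER2, grade,
#'   TP53, subtype) for the replicated -- or, without a replication cohort,
#'   all in-cis -- loci.
#' @param outdir Optional report directory.
#' @return List with `prepared` (and `prepared_replication`), `detection`,
#'   `replication`, `families`, `associations`, and `log`.
#' @export
run_pipeline <- function(discovery, replication = NULL,
                         gamma = 40, gamma_replication = 50, k = 2,
                         min_group_size = 3, fdr_alpha = 0.05,
                         replication_alpha = 0.05,
                         clinical_variables = c("er", "her2", "grade",
                                                "tp53", "subtype"),
                         outdir = NULL) {
  prep <- prepare_cohort(discovery, gamma = gamma, k = k)
  detection <- detect_incis(prep, min_group_size = min_group_size,
                            fdr_alpha = fdr_alpha)
  log <- prep$log
  log$n_incis <- if (is.null(detection$incis)) 0L else nrow(detection$incis)

  prep_rep <- NULL
  repl <- NULL
  if (!is.null(replication)) {
    prep_rep <- prepare_cohort(replication, gamma = gamma_replication, k = k)
    repl <- replicate_incis(detection, prep_rep,
                            min_group_size = min_group_size,
                            replication_alpha = replication_alpha)
    log$n_replicated <- if (is.null(repl$candidates)) 0L else
      sum(repl$candidates$replicated)
  }

  fams <- family_complementarity(discovery$annotation, prep$aberrations,
                                 detection$incis)
  log$n_complementary_families <- length(fams)

  assoc <- NULL
  scan_loci <- if (!is.null(repl) && !is.null(repl$candidates)) {
    repl$candidates$locus_id[repl$candidates$replicated]
  } else if (!is.null(detection$incis)) {
    detection$incis$locus_id
  } else character(0)
  scan_loci <- intersect(scan_loci, rownames(prep$expression))
  if (length(scan_loci) > 0 && !is.null(prep$clinical)) {
    assoc <- lapply(clinical_variables, function(v) {
      suppressWarnings(
        association_scan(prep$expression[scan_loci, , drop = FALSE],
                         prep$clinical, v, min_group_size = min_group_size,
                         fdr_alpha = fdr_alpha)
      )
    })
    assoc <- do.call(rbind, assoc[!vapply(assoc, is.null, logical(1))])
  }

  out <- list(prepared = prep, prepared_replication = prep_rep,
              detection = detection, replication = repl,
              families = fams, associations = assoc, log = log)
  if (!is.null(outdir)) .write_reports(out, outdir)
  out
}

.write_reports <- function(out, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outdir, f)
  if (!is.null(out$detection$results)) {
    write.table(out$detection$results, p("incis_tests.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(out$detection$incis)) {
    write.table(out$detection$incis, p("incis_loci.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(out$replication$candidates)) {
    write.table(out$replication$candidates, p("replication.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(out$associations)) {
    write.table(out$associations, p("clinical_associations.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_seg(out$prepared$segments, p("segments.seg"))
  counts <- vapply(out$log, function(x) paste(format(x), collapse = " "),
                   character(1))
  writeLines(paste0(names(out$log), "\t", counts), p("run_log.tsv"))
  invisible(outdir)
}

#' Summary table of in-cis results in the reporting layout
#'
#' One row per in-cis locus with location, correlations and aberration type,
#' mirroring the package's main report.
#'
#' @param detection Output of [detect_incis()].
#' @param annotations A [mirna_annotation()] table.
#' @return `data.frame` with locus, mature and accession ids, location,
#'   `rho_cn`, `rho_meth`, `effect`, `driver_class`.
#' @export
incis_summary <- function(detection, annotations) {
  inc <- detection$incis
  if (is.null(inc) || nrow(inc) == 0) return(NULL)
  res <- detection$results
  best <- do.call(rbind, lapply(inc$locus_id, function(lid) {
    d <- res[res$locus_id == lid & res$significant, , drop = FALSE]
    d[which.min(d$p), c("rho_cn", "rho_meth"), drop = FALSE]
  }))
  idx <- match(inc$locus_id, annotations$locus_id)
  data.frame(
    locus_id = inc$locus_id,
    mature_id = annotations$mature_id[idx],
    mimat_id = annotations$mimat_id[idx],
    location = paste0(annotations$chrom[idx], ":", annotations$start[idx]),
    rho_cn = best$rho_cn, rho_meth = best$rho_meth,
    effect = inc$effect, driver_class = inc$driver_class,
    stringsAsFactors = FALSE
  )
}
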