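#' Exact piecewise-constant segmentation of one copy-number track
#'
#' Finds the segmentation of an ordered signal minimizing
#' \deqn{\sum_{seg} \sum_{i \in seg} (x_i - \bar x_{seg})^2 + \gamma \cdot \#breakpoints}
#' by exact O(n^2) dynamic programming. Segment means are the arithmetic means
#' of member values. Ties in the objective are broken toward fewer
#' breakpoints, then earlier breakpoints, so output is deterministic.
#'
#' @param signal Finite numeric vector (one sample, one chromosome, probes in
#'   genomic order).
#' @param gamma Non-negative penalty per breakpoint (default 40; on raw
#'   log-ratio tracks see [segment_cohort()] for noise scaling).
#' @return `data.frame` with columns `first_probe_index`, `last_probe_index`
#'   (0-based, inclusive), `n_probes`, `mean`; attribute `objective` holds the
#'   minimized objective value.
#' @export
pcf_segment <- function(signal, gamma = 40) {
  if (length(signal) < 1) stop("empty signal")
  if (!all(is.finite(signal))) stop("non-finite values in signal")
  if (!is.numeric(gamma) || length(gamma) != 1 || gamma < 0) {
    stop("gamma must be a single non-negative number")
  }
  res <- pcf_dp(as.numeric(signal), gamma)
  out <- data.frame(
    first_probe_index = res$first,
    last_probe_index = res$last,
    n_probes = res$last - res$first + 1L,
    mean = res$mean
  )
  attr(out, "objective") <- res$objective
  out
}

# noise SD estimate from lag-1 differences (robust to true breakpoints,
# which are rare among consecutive probe pairs)
.track_noise_sd <- function(x) {
  if (length(x) < 3) return(stats::sd(x))
  stats::mad(diff(x)) / sqrt(2)
}

#' Segment all samples' copy-number tracks per chromosome
#'
#' Applies [pcf_segment()] per sample and chromosome. Because the spec
#' objective is on the raw scale while the conventional penalty
#' \eqn{\gamma = 40} is calibrated for noise-normalized data, the penalty is
#' by default scaled by a per-track noise variance estimate (squared
#' MAD of lag-1 differences / \eqn{\sqrt 2}), which makes \eqn{\gamma}
#' comparable across tracks of different noise levels. Missing probes are
#' dropped from a track before segmentation.
#'
#' @param cn Centered log2 ratio matrix, probes x samples, rownames = probe ids.
#' @param probe_positions `data.frame` with columns `probe_id`, `chrom`, `pos`.
#' @param gamma Breakpoint penalty (default 40).
#' @param scale_penalty Scale `gamma` by the per-track noise variance
#'   estimate (default `TRUE`).
#' @return `data.frame` of segments: `sample`, `chrom`, `start_bp`, `end_bp`,
#'   `num_mark`, `seg_mean`, `first_probe_index`, `last_probe_index` (indices
#'   within the chromosome's retained probe order).
#' @export
segment_cohort <- function(cn, probe_positions, gamma = 40,
                           scale_penalty = TRUE) {
  stopifnot(is.matrix(cn), !is.null(rownames(cn)))
  pp <- probe_positions[match(rownames(cn), probe_positions$probe_id), ]
  if (anyNA(pp$probe_id)) stop("probes in matrix missing from probe_positions")
  res <- vector("list", 0)
  for (ch in unique(pp$chrom)) {
    in_ch <- which(pp$chrom == ch)
    ord <- in_ch[order(pp$pos[in_ch])]
    pos <- pp$pos[ord]
    for (s in colnames(cn)) {
      x <- cn[ord, s]
      ok <- !is.na(x)
      if (!any(ok)) {
        warning(sprintf("sample %s has no usable probes on %s", s, ch))
        next
      }
      xs <- x[ok]
      bp <- pos[ok]
      g <- gamma
      if (scale_penalty) {
        sigma2 <- .track_noise_sd(xs)^2
        g <- gamma * max(sigma2, 1e-12)
      }
      seg <- pcf_segment(xs, g)
      res[[length(res) + 1L]] <- data.frame(
        sample = s, chrom = ch,
        start_bp = bp[seg$first_probe_index + 1L],
        end_bp = bp[seg$last_probe_index + 1L],
        num_mark = seg$n_probes, seg_mean = seg$mean,
        first_probe_index = seg$first_probe_index,
        last_probe_index = seg$last_probe_index,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, res)
}

#' Assign each miRNA locus the mean of its covering copy-number segment
#'
#' A locus receives the mean of the segment whose genomic span (first to last
#' probe position, inclusive at both boundaries) covers the locus start
#' coordinate; loci outside all probe spans on their chromosome receive the
#' nearest segment's mean.
#'
#' @param segments Segment table from [segment_cohort()].
#' @param annotations A [mirna_annotation()] table.
#' @return Locus x sample matrix of segmented log2 ratios; loci on
#'   chromosomes without probes get missing values (with a warning).
#' @export
assign_locus_copy_number <- function(segments, annotations) {
  samples <- unique(segments$sample)
  out <- matrix(NA_real_, nrow(annotations), length(samples),
                dimnames = list(annotations$locus_id, samples))
  warned <- character(0)
  for (s in samples) {
    seg_s <- segments[segments$sample == s, , drop = FALSE]
    for (ch in unique(annotations$chrom)) {
      li <- which(annotations$chrom == ch)
      seg <- seg_s[seg_s$chrom == ch, , drop = FALSE]
      if (nrow(seg) == 0) {
        warned <- union(warned, ch)
        next
      }
      seg <- seg[order(seg$start_bp), , drop = FALSE]
      for (i in li) {
        p <- annotations$start[i]
        hit <- which(seg$start_bp <= p & p <= seg$end_bp)
        if (length(hit) >= 1) {
          out[i, s] <- seg$seg_mean[hit[1]]
        } else {
          d <- pmin(abs(seg$start_bp - p), abs(seg$end_bp - p))
          out[i, s] <- seg$seg_mean[which.min(d)]
        }
      }
    }
  }
  if (length(warned) > 0) {
    warning("no copy-number segments on chromosome(s): ",
            paste(warned, collapse = ", "))
  }
  out
}

#' Write segments in SEG format
#'
#' @param segments Segment table from [segment_cohort()].
#' @param path Output file.
#' @export
write_seg <- function(segments, path) {
  d <- data.frame(
    sample = segments$sample, chrom = segments$chrom,
    loc.start = segments$start_bp, loc.end = segments$end_bp,
    num.mark = segments$num_mark, seg.mean = segments$seg_mean
  )
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
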