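#' Extract the seed sequence of a mature miRNA
#'
#' The seed is the 7-mer at positions 2-8 (1-based) of the mature sequence;
#' miRNAs sharing a seed form a family and are expected to share target
#' repertoires.
#'
#' @param mature_sequence Character vector of mature RNA sequences over
#'   `{A, C, G, U}` (lower case accepted), each of length >= 8.
#' @return Character vector of uppercase 7-mers.
#' @examples
#' extract_seed("UCAGUGCACUACAGAACUUUGU")  # "CAGUGCA"
#' @export
extract_seed <- function(mature_sequence) {
  if (!is.character(mature_sequence) || length(mature_sequence) == 0) {
    stop("invalid annotation: 'mature_sequence' must be a character vector")
  }
  s <- toupper(mature_sequence)
  if (any(is.na(s)) || any(nchar(s) < 8)) {
    stop("invalid annotation: mature sequence shorter than 8 nt")
  }
  if (any(grepl("[^ACGU]", s))) {
    stop("invalid annotation: mature sequence contains characters outside A/C/G/U")
  }
  substr(s, 2L, 8L)
}

#' Build a miRNA locus annotation table
#'
#' One row per genomic copy of a mature miRNA. The seed (positions 2-8 of the
#' mature sequence) is derived on construction. One mature miRNA may own
#' several locus rows (multi-copy miRNAs).
#'
#' @param locus_id Unique locus identifiers.
#' @param mature_id Mature miRNA names (may repeat across loci).
#' @param chrom,start,end,strand Genomic interval, 1-based inclusive
#'   coordinates, strand `"+"` or `"-"`.
#' @param mature_sequence Mature RNA sequences (length >= 8, A/C/G/U).
#' @param mimat_id Optional accession strings.
#' @param host_gene Optional host gene ids (`NA` for intergenic loci).
#' @param intronic Logical, whether the locus lies in an intron of the host.
#' @return A `data.frame` with class `mirna_annotation`, including derived
#'   `seed` and (after [group_families()]) `family_id` columns.
#' @export
mirna_annotation <- function(locus_id, mature_id, chrom, start, end, strand,
                             mature_sequence, mimat_id = NA_character_,
                             host_gene = NA_character_, intronic = FALSE) {
  ann <- data.frame(
    locus_id = as.character(locus_id),
    mature_id = as.character(mature_id),
    mimat_id = as.character(mimat_id),
    chrom = as.character(chrom),
    start = as.integer(start),
    end = as.integer(end),
    strand = as.character(strand),
    mature_sequence = toupper(as.character(mature_sequence)),
    host_gene = as.character(host_gene),
    intronic = as.logical(intronic),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(ann$locus_id)) {
    stop("invalid annotation: duplicated locus_id")
  }
  if (any(ann$start < 1L) || any(ann$end < ann$start)) {
    stop("invalid annotation: require start >= 1 and end >= start")
  }
  if (!all(ann$strand %in% c("+", "-"))) {
    stop("invalid annotation: strand must be '+' or '-'")
  }
  ann$seed <- extract_seed(ann$mature_sequence)
  class(ann) <- c("mirna_annotation", "data.frame")
  ann
}

#' Group miRNA loci into seed families
#'
#' Loci belong to the same family if and only if their seeds (mature sequence
#' positions 2-8) are identical. The family id is the seed followed by the
#' lexicographically smallest member mature id, so ids are deterministic under
#' any input ordering. Singleton families are kept.
#'
#' @param annotations A [mirna_annotation()] table.
#' @return The annotation with a `family_id` column added. The mapping
#'   family -> member loci is available via `split(ann$locus_id, ann$family_id)`.
#' @export
group_families <- function(annotations) {
  stopifnot(is.data.frame(annotations), !is.null(annotations$seed))
  rep_id <- vapply(
    split(annotations$mature_id, annotations$seed),
    function(ids) min(sort(unique(ids))),
    character(1)
  )
  annotations$family_id <- paste0(annotations$seed, "|", rep_id[annotations$seed])
  annotations
}

#' Expand a mature-miRNA matrix to one row per genomic locus
#'
#' Expression arrays measure mature miRNAs; when a mature miRNA is encoded at
#' several genomic loci the transcript's origin is unidentifiable, so every
#' locus receives a copy of the mature miRNA's expression row. All in-cis
#' testing is done on the expanded (locus x sample) matrix.
#'
#' @param mature_matrix Numeric matrix, rows = mature ids, columns = samples.
#' @param annotations A [mirna_annotation()] table.
#' @return Numeric matrix with one row per annotated locus of the retained
#'   mature miRNAs, rownames = locus ids, column order preserved.
#' @export
expand_to_loci <- function(mature_matrix, annotations) {
  stopifnot(is.matrix(mature_matrix), !is.null(rownames(mature_matrix)))
  known <- rownames(mature_matrix) %in% annotations$mature_id
  if (!all(known)) {
    warning(sprintf(
      "dropping %d mature miRNA(s) without locus annotation: %s",
      sum(!known), paste(utils::head(rownames(mature_matrix)[!known], 5), collapse = ", ")
    ))
  }
  kept <- mature_matrix[known, , drop = FALSE]
  ann <- annotations[annotations$mature_id %in% rownames(kept), , drop = FALSE]
  out <- kept[ann$mature_id, , drop = FALSE]
  rownames(out) <- ann$locus_id
  out
}

#' Collapse a locus-level matrix back to mature miRNAs
#'
#' Inverse of [expand_to_loci()] for matrices whose locus rows are exact
#' copies: keeps the first locus row of each mature miRNA.
#'
#' @param locus_matrix Locus x sample matrix produced by [expand_to_loci()].
#' @param annotations A [mirna_annotation()] table.
#' @return Mature x sample matrix.
#' @export
collapse_to_mature <- function(locus_matrix, annotations) {
  idx <- match(rownames(locus_matrix), annotations$locus_id)
  mature <- annotations$mature_id[idx]
  first <- !duplicated(mature)
  out <- locus_matrix[first, , drop = FALSE]
  rownames(out) <- mature[first]
  out
}

#' Build a methylation probe annotation table
#'
#' @param probe_id Probe identifiers (unique).
#' @param chrom Chromosome of the interrogated CpG.
#' @param pos 1-based CpG position.
#' @param feature_class One of `TSS1500`, `5UTR`, `FirstExon`, `Body`,
#'   `3UTR`, `Intergenic`. Only the first three are promoter probes
#'   (within 1,500 bp upstream of the TSS, in the 5' UTR, or in the first
#'   exon); gene-body and 3' UTR probes are never used for promoter
#'   methylation.
#' @param gene Gene whose promoter/body the probe annotates (`NA` if none).
#' @param designated_locus_ids Semicolon-joined locus ids the array vendor
#'   designated this probe to (empty string or `NA` if none).
#' @return A `data.frame` with class `probe_annotation`.
#' @export
probe_annotation <- function(probe_id, chrom, pos, feature_class,
                             gene = NA_character_,
                             designated_locus_ids = "") {
  cls <- c("TSS1500", "5UTR", "FirstExon", "Body", "3UTR", "Intergenic")
  pr <- data.frame(
    probe_id = as.character(probe_id),
    chrom = as.character(chrom),
    pos = as.integer(pos),
    feature_class = as.character(feature_class),
    gene = as.character(gene),
    designated_locus_ids = ifelse(is.na(designated_locus_ids), "",
                                  as.character(designated_locus_ids)),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(pr$probe_id)) stop("duplicated probe_id")
  if (!all(pr$feature_class %in% cls)) {
    stop("feature_class must be one of: ", paste(cls, collapse = ", "))
  }
  pr$is_promoter <- pr$feature_class %in% c("TSS1500", "5UTR", "FirstExon")
  class(pr) <- c("probe_annotation", "data.frame")
  pr
}

# split semicolon-joined designated locus ids into a list column
.designated_list <- function(probes) {
  strsplit(ifelse(probes$designated_locus_ids == "", NA_character_,
                  probes$designated_locus_ids), ";", fixed = TRUE)
}

#' Assign methylation probes to miRNA loci by the three-tier rule
#'
#' Tier 1 (`designated`): all promoter probes the vendor annotation
#' designates to the locus. Tier 2 (`host_promoter`), only when tier 1 is
#' empty and the locus is intronic in a coding host gene: the host gene's
#' proximal-promoter probes (TSS1500 / 5' UTR / first exon). Tier 3
#' (`nearest`): the single probe closest to the locus start on the same
#' chromosome, ties broken toward the lower coordinate. Every locus receives
#' exactly one assignment.
#'
#' @param annotations A [mirna_annotation()] table.
#' @param probes A [probe_annotation()] table.
#' @return `data.frame` with columns `locus_id`, `tier`, and a list column
#'   `probe_ids`.
#' @export
assign_methylation_probes <- function(annotations, probes) {
  desig <- .designated_list(probes)
  # invert: locus -> designated promoter probe ids
  has_desig <- !vapply(desig, function(x) all(is.na(x)), logical(1))
  inv <- list()
  if (any(has_desig)) {
    flat <- data.frame(
      probe_id = rep(probes$probe_id[has_desig],
                     lengths(desig[has_desig])),
      promoter = rep(probes$is_promoter[has_desig],
                     lengths(desig[has_desig])),
      locus_id = unlist(desig[has_desig]),
      stringsAsFactors = FALSE
    )
    flat <- flat[flat$promoter, , drop = FALSE]
    inv <- split(flat$probe_id, flat$locus_id)
  }
  prom <- probes[probes$is_promoter & !is.na(probes$gene), , drop = FALSE]
  gene_prom <- split(prom$probe_id, prom$gene)

  out <- vector("list", nrow(annotations))
  for (i in seq_len(nrow(annotations))) {
    lid <- annotations$locus_id[i]
    ids <- inv[[lid]]
    if (!is.null(ids) && length(ids) > 0) {
      out[[i]] <- list(locus_id = lid, tier = "designated", probe_ids = ids)
      next
    }
    hg <- annotations$host_gene[i]
    if (isTRUE(annotations$intronic[i]) && !is.na(hg) &&
        !is.null(gene_prom[[hg]]) && length(gene_prom[[hg]]) > 0) {
      out[[i]] <- list(locus_id = lid, tier = "host_promoter",
                       probe_ids = gene_prom[[hg]])
      next
    }
    same <- which(probes$chrom == annotations$chrom[i])
    if (length(same) == 0) {
      stop(sprintf("unassignable locus '%s': no methylation probes on %s",
                   lid, annotations$chrom[i]))
    }
    d <- abs(probes$pos[same] - annotations$start[i])
    cand <- same[d == min(d)]
    nearest <- cand[which.min(probes$pos[cand])]
    out[[i]] <- list(locus_id = lid, tier = "nearest",
                     probe_ids = probes$probe_id[nearest])
  }
  data.frame(
    locus_id = vapply(out, `[[`, character(1), "locus_id"),
    tier = vapply(out, `[[`, character(1), "tier"),
    probe_ids = I(lapply(out, `[[`, "probe_ids")),
    stringsAsFactors = FALSE
  )
}

#' Read / write the tab-separated annotation interchange formats
#'
#' @param path File path.
#' @return `read_annotation()` returns a [mirna_annotation()];
#'   `read_probe_annotation()` a [probe_annotation()].
#' @name annotation_io
NULL

#' @rdname annotation_io
#' @export
read_annotation <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  mirna_annotation(d$locus_id, d$mature_id, d$chrom, d$start, d$end,
                   d$strand, d$sequence, mimat_id = d$mimat_id,
                   host_gene = d$host_gene, intronic = d$intronic)
}

#' @rdname annotation_io
#' @param annotations,probes Tables to write.
#' @export
write_annotation <- function(annotations, path) {
  d <- annotations[, c("locus_id", "mature_id", "mimat_id", "chrom", "start",
                       "end", "strand", "mature_sequence", "host_gene",
                       "intronic")]
  names(d)[names(d) == "mature_sequence"] <- "sequence"
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname annotation_io
#' @export
read_probe_annotation <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
  d$designated_locus_ids[is.na(d$designated_locus_ids)] <- ""
  probe_annotation(d$probe_id, d$chrom, d$pos, d$feature_class,
                   gene = d$gene, designated_locus_ids = d$designated_locus_ids)
}

#' @rdname annotation_io
#' @export
write_probe_annotation <- function(probes, path) {
  d <- probes[, c("probe_id", "chrom", "pos", "feature_class", "gene",
                  "designated_locus_ids")]
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname annotation_io
#' @export
write_bed6 <- function(annotations, path) {
  # BED is 0-based half-open; internal coordinates are 1-based inclusive
  d <- data.frame(annotations$chrom, annotations$start - 1L, annotations$end,
                  annotations$locus_id, 0L, annotations$strand)
  write.table(d, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
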