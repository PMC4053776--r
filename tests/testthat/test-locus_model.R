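# Table-style mature sequences with their known seeds (positions 2-8)
tbl_seqs <- c(
  "miR-148a-3p" = "UCAGUGCACUACAGAACUUUGU",
  "miR-148b-3p" = "UCAGUGCAUCACAGAACUUUGU",
  "miR-106b-5p" = "UAAAGUGCUGACAGUGCAGAU",
  "miR-17-5p"   = "CAAAGUGCUUACAGUGCAGGUAG",
  "miR-20a-5p"  = "UAAAGUGCUUAUAGUGCAGGUAG",
  "miR-130b-3p" = "CAGUGCAAUGAUGAAAGGGCAU",
  "miR-454-3p"  = "UAGUGCAAUAUUGCUUAUAGGGU",
  "miR-30b-5p"  = "UGUAAACAUCCUACACUCAGCU",
  "miR-30c-5p"  = "UGUAAACAUCCUACACUCUCAGC",
  "miR-30d-5p"  = "UGUAAACAUCCCCGACUGGAAG",
  "miR-30e-5p"  = "UGUAAACAUCCUUGACUGGAAG",
  "miR-92a-3p"  = "UAUUGCACUUGUCCCGGCCUGU",
  "miR-92b-3p"  = "UAUUGCACUCGUCCCGGCCUCC"
)

test_that("seed extraction takes positions 2-8 of the mature sequence", {
  expect_equal(extract_seed("UCAGUGCACUACAGAACUUUGU"), "CAGUGCA")
  expect_equal(extract_seed("UGUAAACAUCCUACACUCAGCU"), "GUAAACA")
  expect_equal(extract_seed("UAUUGCAC"), "AUUGCAC")  # minimal 8-mer
  expect_equal(extract_seed("ucagugcacu"), "CAGUGCA")  # case-insensitive
  expect_error(extract_seed("UCAGUGC"), "shorter than 8")
  expect_error(extract_seed("UCAGTGCACU"), "A/C/G/U")  # DNA alphabet rejected
})

test_that("identical seeds define families; 13 multi-copy loci give 5 families", {
  ann <- mirna_annotation(
    locus_id = paste0("L", seq_along(tbl_seqs)),
    mature_id = names(tbl_seqs), chrom = "chr1",
    start = 1000 * seq_along(tbl_seqs), end = 1000 * seq_along(tbl_seqs) + 21,
    strand = "+", mature_sequence = unname(tbl_seqs)
  )
  ann <- group_families(ann)
  expect_equal(length(unique(ann$family_id)), 5L)
  # miR-92a/92b share a seed hence a family
  fam92 <- ann$family_id[ann$mature_id %in% c("miR-92a-3p", "miR-92b-3p")]
  expect_equal(length(unique(fam92)), 1L)
  # grouping is invariant under input permutation (equivalence relation)
  set.seed(7)
  for (rep in 1:5) {
    perm <- sample(nrow(ann))
    ann2 <- group_families(ann[perm, ])
    expect_equal(
      lapply(split(ann2$locus_id, ann2$family_id), sort),
      lapply(split(ann$locus_id, ann$family_id), sort)
    )
  }
  # two loci of the same mature miRNA fall in the same family
  ann3 <- group_families(mirna_annotation(
    locus_id = c("A", "B"), mature_id = c("m1", "m1"), chrom = "chr1",
    start = c(100, 900), end = c(121, 921), strand = "+",
    mature_sequence = rep("UCAGUGCACUACAGAACUUUGU", 2)
  ))
  expect_equal(ann3$family_id[1], ann3$family_id[2])
})

test_that("locus expansion copies mature rows and collapse inverts it", {
  ann <- mirna_annotation(
    locus_id = c("L1", "L2a", "L2b"), mature_id = c("m1", "m2", "m2"),
    chrom = "chr1", start = c(100, 500, 900), end = c(121, 521, 921),
    strand = "+", mature_sequence = rep("UCAGUGCACUACAGAACUUUGU", 3)
  )
  m <- matrix(rnorm(6), 2, 3, dimnames = list(c("m1", "m2"), c("s1", "s2", "s3")))
  ex <- expand_to_loci(m, ann)
  expect_equal(rownames(ex), c("L1", "L2a", "L2b"))
  expect_equal(unname(ex["L2a", ]), unname(ex["L2b", ]))
  expect_equal(unname(ex["L2a", ]), unname(m["m2", ]))
  expect_equal(colnames(ex), colnames(m))
  # duplicated rows double that miRNA's contribution to column sums
  expect_equal(colSums(ex), colSums(m) + m["m2", ])
  # collapsing recovers the mature matrix exactly
  expect_equal(collapse_to_mature(ex, ann), m)
  # unannotated mature miRNAs are dropped with a warning
  m2 <- rbind(m, unknown = rnorm(3))
  expect_warning(ex2 <- expand_to_loci(m2, ann), "unknown")
  expect_equal(nrow(ex2), 3L)
})

test_that("probe assignment follows the designated/host/nearest hierarchy", {
  fx <- tier_fixture()
  asn <- assign_methylation_probes(fx$ann, fx$probes)
  asn <- asn[match(c("L1", "L2", "L3"), asn$locus_id), ]
  # L1: three designated promoter probes
  expect_equal(asn$tier[1], "designated")
  expect_setequal(asn$probe_ids[[1]], c("p1", "p2", "p3"))
  # L2: intronic, no designated probes -> host promoter probes only
  # (the gene-body probe of HOST1 is excluded)
  expect_equal(asn$tier[2], "host_promoter")
  expect_setequal(asn$probe_ids[[2]], c("hp1", "hp2"))
  # L3: intergenic, no designated probes -> single nearest probe
  expect_equal(asn$tier[3], "nearest")
  expect_equal(asn$probe_ids[[3]], "far")
  # tiers partition the loci: exactly one assignment each
  expect_equal(sort(asn$locus_id), sort(fx$ann$locus_id))
})

test_that("nearest-probe fallback matches a linear-scan oracle with low-coordinate ties", {
  set.seed(11)
  for (rep in 1:10) {
    pos <- sort(sample(1:100000, 30))
    probes <- probe_annotation(paste0("p", 1:30), "chr5", pos, "Body")
    start <- sample(1:100000, 1)
    ann <- mirna_annotation("LX", "mX", "chr5", start, start + 21, "+",
                            "UCAGUGCACUACAGAACUUUGU")
    asn <- assign_methylation_probes(ann, probes)
    d <- abs(pos - start)
    oracle <- paste0("p", which(d == min(d)))  # may be two on a tie
    expect_true(asn$probe_ids[[1]] %in% oracle)
    if (length(oracle) == 2) {
      # equidistant: lower coordinate wins
      expect_equal(asn$probe_ids[[1]], oracle[1])
    }
  }
  # locus on a probe-free chromosome is unassignable
  probes <- probe_annotation("p1", "chr1", 500L, "TSS1500")
  ann <- mirna_annotation("LY", "mY", "chr9", 100L, 121L, "+",
                          "UCAGUGCACUACAGAACUUUGU")
  expect_error(assign_methylation_probes(ann, probes), "unassignable.*LY")
})

test_that("annotation tables round-trip through the TSV format", {
  fx <- tier_fixture()
  f1 <- tempfile(fileext = ".tsv")
  f2 <- tempfile(fileext = ".tsv")
  write_annotation(fx$ann, f1)
  back <- read_annotation(f1)
  expect_equal(back$locus_id, fx$ann$locus_id)
  expect_equal(back$seed, fx$ann$seed)
  expect_equal(back$host_gene, fx$ann$host_gene)
  write_probe_annotation(fx$probes, f2)
  pback <- read_probe_annotation(f2)
  expect_equal(pback$probe_id, fx$probes$probe_id)
  expect_equal(pback$is_promoter, fx$probes$is_promoter)
  # BED6 export shifts start by one (0-based half-open)
  f3 <- tempfile(fileext = ".bed")
  write_bed6(fx$ann, f3)
  bed <- read.delim(f3, header = FALSE)
  expect_equal(bed$V2, fx$ann$start - 1L)
  expect_equal(bed$V3, fx$ann$end)
})
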