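#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate a desk-scale breast tumor cohort: 100 tumors with a
#' 17-sample normal methylation reference, five chromosomes of 2,000
#' copy-number probes at 10 kb spacing, and 500 miRNA loci of which 80 carry
#' a planted in-cis mechanism (20 gain, 20 hypomethylation, 15 loss, 15
#' hypermethylation, 10 combined gain+hypomethylation). Planted loci shift
#' expression by `effect_size_expr` log2 units in 30% of tumors; copy-number
#' events are 81-probe segments of amplitude `cn_segment_shift`; methylation
#' events shift beta by `beta_shift` against a clipped-Gaussian background.
#'
#' @param n_tumors,n_normals Cohort sizes.
#' @param n_chromosomes,probes_per_chrom,probe_spacing_bp Copy-number grid.
#' @param n_loci Number of miRNA loci.
#' @param n_families_multilocus Seed families with two planted members on
#'   complementary (disjoint) altered sample sets.
#' @param n_multicopy_mature Mature miRNAs encoded at two loci each.
#' @param n_gain_driven,n_hypo_driven,n_loss_driven,n_hyper_driven,n_combined
#'   Planted mechanism counts.
#' @param effect_size_expr Expression shift (log2) in altered samples.
#' @param altered_fraction Fraction of tumors altered per planted locus.
#' @param cn_segment_shift,cn_noise_sd,cn_window_probes Copy-number event
#'   amplitude, per-probe noise SD, and event width in probes.
#' @param beta_noise_sd,beta_shift Methylation noise SD and aberration shift.
#' @param expr_noise_sd Expression noise SD (log2).
#' @param n_mrna_genes,n_correlated_genes,n_candidate_mirnas,mrna_coupling
#'   mRNA layer: total genes, planted correlated genes per candidate miRNA,
#'   number of candidate miRNAs, and coupling coefficient.
#' @param clinical_effect Expression shift added in TP53-mutant samples (for
#'   one designated locus) and basal-like samples (for another).
#' @param survival_loghr Log hazard ratio per standardized expression unit of
#'   the prognostic locus (negative expression effect on hazard).
#' @param censor_max Upper bound of the uniform censoring time.
#' @param seed Random seed; the bundle is deterministic given the seed.
#' @return List with class `sim_config`.
#' @export
simulation_config <- function(n_tumors = 100, n_normals = 17,
                              n_chromosomes = 5, probes_per_chrom = 2000,
                              probe_spacing_bp = 10000,
                              n_loci = 500, n_families_multilocus = 5,
                              n_multicopy_mature = 5,
                              n_gain_driven = 20, n_hypo_driven = 20,
                              n_loss_driven = 15, n_hyper_driven = 15,
                              n_combined = 10,
                              effect_size_expr = 1.5, altered_fraction = 0.3,
                              cn_segment_shift = 0.3, cn_noise_sd = 0.15,
                              cn_window_probes = 81,
                              beta_noise_sd = 0.02, beta_shift = 0.2,
                              expr_noise_sd = 0.5,
                              n_mrna_genes = 300, n_correlated_genes = 5,
                              n_candidate_mirnas = 4, mrna_coupling = 0.8,
                              clinical_effect = 1.2, survival_loghr = 0.8,
                              censor_max = 12, seed = 1) {
  cfg <- as.list(environment())
  n_planted <- n_gain_driven + n_hypo_driven + n_loss_driven +
    n_hyper_driven + n_combined
  if (n_planted + 2 * n_multicopy_mature + 20 > n_loci) {
    stop("planted + multi-copy + tier-demo loci exceed n_loci")
  }
  if (n_families_multilocus > min(n_gain_driven, n_hypo_driven)) {
    stop("n_families_multilocus cannot exceed the gain- and hypo-driven counts")
  }
  if (altered_fraction <= 0 || altered_fraction >= 1) {
    stop("altered_fraction must be in (0, 1)")
  }
  cfg$n_planted <- n_planted
  class(cfg) <- c("sim_config", "list")
  cfg
}

.random_sequences <- function(n, seed_pool) {
  # unique seeds, random flanks; 22-mers
  seeds <- seed_pool[seq_len(n)]
  vapply(seeds, function(s) {
    nt <- c("A", "C", "G", "U")
    paste0(paste(sample(nt, 1), collapse = ""), s,
           paste(sample(nt, 14, replace = TRUE), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

#' Generate a synthetic tumor cohort with planted in-cis structure
#'
#' Produces all pipeline inputs: locus annotation (with seed families and
#' multi-copy mature miRNAs), probe-level copy-number log-ratios
#' (piecewise-constant events plus Gaussian noise), probe-level methylation
#' beta for tumors and normals (clipped Gaussian around per-locus baselines,
#' shifted in altered tumors), mature-level log2 expression coupled in cis to
#' the planted aberrations, an mRNA matrix with planted correlated genes, a
#' clinical table with planted subgroup effects and survival, and the ground
#' truth table. Probe assignment tiers are exercised: most loci have
#' designated promoter probes, ten are intronic and fall back to host-gene
#' promoter probes, ten more to the nearest probe.
#'
#' Passing `template` (a previous bundle) reuses its annotation, probe
#' layout, baselines and mechanism truth while redrawing patients, noise,
#' clinical data and altered sample sets — twin cohorts for replication
#' testing share mechanisms but nothing sample-level.
#'
#' @param cfg A [simulation_config()].
#' @param template Optional bundle from a previous [generate_cohort()] call.
#' @return List with class `mircis_bundle`: `annotation`, `probe_positions`,
#'   `cn_probes`, `meth_probes`, `beta_tumors`, `beta_normals`,
#'   `expression_raw`, `detected`, `mrna`, `clinical`, `truth`, `config`.
#' @export
generate_cohort <- function(cfg = simulation_config(), template = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n_t <- cfg$n_tumors
  tumors <- sprintf("T%03d", seq_len(n_t))
  normals <- sprintf("N%03d", seq_len(cfg$n_normals))

  if (is.null(template)) {
    skel <- .build_skeleton(cfg)
  } else {
    skel <- template$skeleton
  }
  ann <- skel$annotation
  n_loci <- nrow(ann)

  # --- altered sample sets (always redrawn) ---
  n_alt <- round(cfg$altered_fraction * n_t)
  altered <- vector("list", n_loci)
  names(altered) <- ann$locus_id
  planted <- which(skel$mechanism != "none")
  for (i in planted) altered[[i]] <- sort(sample(tumors, n_alt))
  # complementary families: member 2 altered set disjoint from member 1
  for (f in seq_len(nrow(skel$family_pairs))) {
    i1 <- skel$family_pairs$member1[f]
    i2 <- skel$family_pairs$member2[f]
    pool <- setdiff(tumors, altered[[i1]])
    altered[[i2]] <- sort(sample(pool, min(n_alt, length(pool))))
  }

  # --- copy number: baseline noise + planted windows ---
  pp <- skel$probe_positions
  cn <- matrix(rnorm(nrow(pp) * n_t, 0, cfg$cn_noise_sd), nrow(pp), n_t,
               dimnames = list(pp$probe_id, tumors))
  for (i in planted) {
    mech <- skel$mechanism[i]
    if (!mech %in% c("gain", "loss", "combined")) next
    rows <- skel$cn_window_rows[[ann$locus_id[i]]]
    who <- altered[[i]]
    if (mech == "combined") who <- who[seq_len(ceiling(length(who) / 2))]
    shift <- if (mech == "loss") -cfg$cn_segment_shift else cfg$cn_segment_shift
    cn[rows, who] <- cn[rows, who] + shift
  }

  # --- methylation: clipped Gaussian around per-locus baselines ---
  probes <- skel$meth_probes
  mu_probe <- skel$mu_locus[skel$probe_owner]
  clip01 <- function(x) {
    x[x < 0] <- 0
    x[x > 1] <- 1
    x
  }
  bt <- matrix(rnorm(nrow(probes) * n_t, 0, cfg$beta_noise_sd),
               nrow(probes), n_t,
               dimnames = list(probes$probe_id, tumors)) + mu_probe
  bn <- matrix(rnorm(nrow(probes) * cfg$n_normals, 0, cfg$beta_noise_sd),
               nrow(probes), cfg$n_normals,
               dimnames = list(probes$probe_id, normals)) + mu_probe
  for (i in planted) {
    mech <- skel$mechanism[i]
    if (!mech %in% c("hypo", "hyper", "combined")) next
    rows <- which(skel$probe_owner == i)
    who <- altered[[i]]
    if (mech == "combined") who <- who[-seq_len(ceiling(length(who) / 2))]
    shift <- if (mech == "hyper") cfg$beta_shift else -cfg$beta_shift
    bt[rows, who] <- bt[rows, who] + shift
  }
  bt <- clip01(bt)
  bn <- clip01(bn)

  # --- expression: per-mature baseline + in-cis effect + noise ---
  matures <- unique(ann$mature_id)
  expr <- matrix(rnorm(length(matures) * n_t, 0, cfg$expr_noise_sd),
                 length(matures), n_t,
                 dimnames = list(matures, tumors)) + skel$a_mature[matures]
  for (i in planted) {
    m <- ann$mature_id[i]
    dirn <- if (skel$mechanism[i] %in% c("loss", "hyper")) -1 else 1
    expr[m, altered[[i]]] <- expr[m, altered[[i]]] +
      dirn * cfg$effect_size_expr
  }

  # --- clinical covariates with planted effects ---
  subtype <- sample(c("luminal", "basal", "other"), n_t, replace = TRUE,
                    prob = c(0.55, 0.30, 0.15))
  er_p <- c(luminal = 0.9, basal = 0.15, other = 0.5)[subtype]
  er <- ifelse(runif(n_t) < er_p, "pos", "neg")
  her2 <- ifelse(runif(n_t) < 0.2, "pos", "neg")
  grade <- sample(1:3, n_t, replace = TRUE, prob = c(0.2, 0.4, 0.4))
  tp53 <- ifelse(runif(n_t) < 0.35, "mutant", "wildtype")
  m_tp53 <- ann$mature_id[skel$clin_tp53_locus]
  m_sub <- ann$mature_id[skel$clin_subtype_locus]
  expr[m_tp53, tp53 == "mutant"] <- expr[m_tp53, tp53 == "mutant"] +
    cfg$clinical_effect
  expr[m_sub, subtype == "basal"] <- expr[m_sub, subtype == "basal"] +
    cfg$clinical_effect

  # --- survival: exponential, log-hazard linear in prognostic expression ---
  m_surv <- ann$mature_id[skel$surv_locus]
  z <- as.numeric(scale(expr[m_surv, ]))
  haz <- 0.15 * exp(-cfg$survival_loghr * z)
  t_event <- rexp(n_t, rate = haz)
  t_cens <- runif(n_t, 0, cfg$censor_max)
  rfs_time <- pmin(t_event, t_cens)
  rfs_event <- as.integer(t_event <= t_cens)
  clinical <- clinical_table(tumors, er = er, her2 = her2, grade = grade,
                             tp53 = tp53, subtype = subtype,
                             rfs_time = rfs_time, rfs_event = rfs_event)

  # --- mRNA with planted correlated genes for the candidate miRNAs ---
  genes <- sprintf("GENE%04d", seq_len(cfg$n_mrna_genes))
  mrna <- matrix(rnorm(cfg$n_mrna_genes * n_t, 8, 1), cfg$n_mrna_genes, n_t,
                 dimnames = list(genes, tumors))
  cand_idx <- planted[seq_len(min(cfg$n_candidate_mirnas, length(planted)))]
  corr_truth <- list()
  g_next <- 1L
  for (ci in seq_along(cand_idx)) {
    m <- ann$mature_id[cand_idx[ci]]
    zc <- as.numeric(scale(expr[m, ]))
    for (gg in seq_len(cfg$n_correlated_genes)) {
      b <- cfg$mrna_coupling * if (gg %% 2 == 0) -1 else 1
      mrna[genes[g_next], ] <- 8 + b * zc + rnorm(n_t, 0, 0.7)
      corr_truth[[length(corr_truth) + 1L]] <- data.frame(
        mirna = m, gene = genes[g_next], sign = sign(b),
        stringsAsFactors = FALSE)
      g_next <- g_next + 1L
    }
  }

  truth <- list(
    loci = data.frame(locus_id = ann$locus_id, mechanism = skel$mechanism,
                      stringsAsFactors = FALSE),
    altered = altered,
    clin_tp53_locus = ann$locus_id[skel$clin_tp53_locus],
    clin_subtype_locus = ann$locus_id[skel$clin_subtype_locus],
    surv_locus = ann$locus_id[skel$surv_locus],
    correlated_pairs = if (length(corr_truth)) do.call(rbind, corr_truth) else NULL
  )

  structure(list(
    annotation = ann, probe_positions = pp, cn_probes = cn,
    meth_probes = probes, beta_tumors = bt, beta_normals = bn,
    expression_raw = expr, detected = !is.na(expr), mrna = mrna,
    clinical = clinical, truth = truth, config = cfg, skeleton = skel
  ), class = "mircis_bundle")
}

# static cohort skeleton: annotation, probe layout, baselines, mechanisms
.build_skeleton <- function(cfg) {
  n_loci <- cfg$n_loci
  chroms <- paste0("chr", seq_len(cfg$n_chromosomes))
  locus_id <- sprintf("locus_%04d", seq_len(n_loci))

  # planted mechanism blocks at the front of the locus table
  mechanism <- rep("none", n_loci)
  i <- 1L
  blocks <- c(gain = cfg$n_gain_driven, hypo = cfg$n_hypo_driven,
              loss = cfg$n_loss_driven, hyper = cfg$n_hyper_driven,
              combined = cfg$n_combined)
  idx <- list()
  for (b in names(blocks)) {
    idx[[b]] <- seq.int(i, length.out = blocks[[b]])
    mechanism[idx[[b]]] <- b
    i <- i + blocks[[b]]
  }
  n_planted <- cfg$n_planted

  # seed families: pair gain- with hypo-driven loci (identical seeds)
  family_pairs <- data.frame(
    member1 = idx$gain[seq_len(cfg$n_families_multilocus)],
    member2 = idx$hypo[seq_len(cfg$n_families_multilocus)]
  )
  # multi-copy mature miRNAs among the unplanted loci
  mc <- seq.int(n_planted + 1L, length.out = 2L * cfg$n_multicopy_mature)

  mature_id <- sprintf("mir_%04d", seq_len(n_loci))
  for (j in seq_len(cfg$n_multicopy_mature)) {
    mature_id[mc[2 * j]] <- mature_id[mc[2 * j - 1]]
  }

  nt <- c("A", "C", "G", "U")
  seed_pool <- unique(replicate(n_loci + 50,
                                paste(sample(nt, 7, replace = TRUE), collapse = "")))
  seqs <- .random_sequences(n_loci, seed_pool)
  for (f in seq_len(nrow(family_pairs))) {
    s1 <- seqs[family_pairs$member1[f]]
    flank <- paste(sample(nt, 14, replace = TRUE), collapse = "")
    seqs[family_pairs$member2[f]] <- paste0(sample(nt, 1), substr(s1, 2, 8), flank)
  }
  for (j in seq_len(cfg$n_multicopy_mature)) {
    seqs[mc[2 * j]] <- seqs[mc[2 * j - 1]]
  }

  # copy-number probe grid and planted windows
  pos_grid <- seq_len(cfg$probes_per_chrom) * cfg$probe_spacing_bp
  pp <- data.frame(
    probe_id = sprintf("cnp_%s_%04d", rep(chroms, each = cfg$probes_per_chrom),
                       rep(seq_len(cfg$probes_per_chrom), cfg$n_chromosomes)),
    chrom = rep(chroms, each = cfg$probes_per_chrom),
    pos = rep(pos_grid, cfg$n_chromosomes),
    stringsAsFactors = FALSE
  )
  cn_planted <- c(idx$gain, idx$loss, idx$combined)
  n_win_per_chrom <- ceiling(length(cn_planted) / cfg$n_chromosomes)
  half <- (cfg$cn_window_probes - 1) %/% 2
  locus_chrom <- character(n_loci)
  locus_start <- integer(n_loci)
  cn_window_rows <- list()
  for (w in seq_along(cn_planted)) {
    li <- cn_planted[w]
    ch_i <- ((w - 1L) %% cfg$n_chromosomes) + 1L
    slot <- ((w - 1L) %/% cfg$n_chromosomes) + 1L
    center <- round(cfg$probes_per_chrom * slot / (n_win_per_chrom + 1))
    center <- min(max(center, half + 1L), cfg$probes_per_chrom - half)
    locus_chrom[li] <- chroms[ch_i]
    locus_start[li] <- pos_grid[center]
    cn_window_rows[[locus_id[li]]] <-
      (ch_i - 1L) * cfg$probes_per_chrom + seq.int(center - half, center + half)
  }
  # remaining loci: 5 kb grid positions, distinct from planted CN centers
  rest <- which(locus_start == 0L)
  grid5 <- seq(5e4, (cfg$probes_per_chrom - 5) * cfg$probe_spacing_bp, by = 5000)
  for (ch_i in seq_len(cfg$n_chromosomes)) {
    members <- rest[((seq_along(rest) - 1L) %% cfg$n_chromosomes) + 1L == ch_i]
    used <- locus_start[locus_chrom == chroms[ch_i] & locus_start > 0]
    avail <- setdiff(grid5, used)
    pos <- sort(sample(avail, length(members)))
    locus_chrom[members] <- chroms[ch_i]
    locus_start[members] <- pos
  }

  # methylation probe assignment tiers: last 20 loci exercise host/nearest
  tier_host <- seq.int(n_loci - 19L, n_loci - 10L)
  tier_near <- seq.int(n_loci - 9L, n_loci)
  host_gene <- rep(NA_character_, n_loci)
  intronic <- rep(FALSE, n_loci)
  host_gene[tier_host] <- sprintf("HG%02d", seq_along(tier_host))
  intronic[tier_host] <- TRUE

  p_rows <- list()
  probe_owner <- integer(0)
  for (i2 in seq_len(n_loci)) {
    lid <- locus_id[i2]
    if (i2 %in% tier_near) {
      p_rows[[lid]] <- data.frame(
        probe_id = paste0("near_", lid), chrom = locus_chrom[i2],
        pos = locus_start[i2] + 500L, feature_class = "Intergenic",
        gene = NA_character_, designated_locus_ids = "",
        stringsAsFactors = FALSE)
      probe_owner <- c(probe_owner, i2)
    } else if (i2 %in% tier_host) {
      p_rows[[lid]] <- data.frame(
        probe_id = paste0("hostp_", lid, "_", 1:2), chrom = locus_chrom[i2],
        pos = locus_start[i2] - c(3000L, 2900L), feature_class = "TSS1500",
        gene = host_gene[i2], designated_locus_ids = "",
        stringsAsFactors = FALSE)
      probe_owner <- c(probe_owner, i2, i2)
    } else {
      p_rows[[lid]] <- data.frame(
        probe_id = paste0("desig_", lid, "_", 1:2), chrom = locus_chrom[i2],
        pos = locus_start[i2] + c(100L, 200L), feature_class = "TSS1500",
        gene = NA_character_, designated_locus_ids = lid,
        stringsAsFactors = FALSE)
      probe_owner <- c(probe_owner, i2, i2)
    }
  }
  pr <- do.call(rbind, p_rows)
  probes <- probe_annotation(pr$probe_id, pr$chrom, pr$pos, pr$feature_class,
                             gene = pr$gene,
                             designated_locus_ids = pr$designated_locus_ids)

  ann <- mirna_annotation(
    locus_id = locus_id, mature_id = mature_id, chrom = locus_chrom,
    start = locus_start, end = locus_start + 21L,
    strand = sample(c("+", "-"), n_loci, replace = TRUE),
    mature_sequence = seqs,
    mimat_id = sprintf("MIMAT%07d", seq_len(n_loci)),
    host_gene = host_gene, intronic = intronic
  )
  ann <- group_families(ann)

  # designated clinical / survival loci (planted, methylation-driven)
  list(
    annotation = ann, probe_positions = pp, meth_probes = probes,
    probe_owner = probe_owner, cn_window_rows = cn_window_rows,
    mechanism = mechanism, family_pairs = family_pairs,
    mu_locus = runif(n_loci, 0.15, 0.75),
    a_mature = setNames(runif(length(unique(mature_id)), 6, 12),
                        unique(mature_id)),
    clin_tp53_locus = idx$hypo[cfg$n_families_multilocus + 1L],
    clin_subtype_locus = idx$hypo[cfg$n_families_multilocus + 2L],
    surv_locus = idx$hyper[1L]
  )
}

#' Compare a detected in-cis set with the simulation truth
#'
#' @param detection Output of [detect_incis()].
#' @param truth The `truth` element of a [generate_cohort()] bundle.
#' @return List with `sensitivity` (planted loci recovered), `fdp` (detected
#'   loci with no planted mechanism), `mechanism_accuracy` (recovered planted
#'   loci whose [mechanism_label()] matches the truth), and the underlying
#'   counts.
#' @export
evaluate_against_truth <- function(detection, truth) {
  planted <- truth$loci$locus_id[truth$loci$mechanism != "none"]
  found <- if (is.null(detection$incis)) character(0) else detection$incis$locus_id
  tp <- intersect(found, planted)
  fp <- setdiff(found, planted)
  labels <- mechanism_label(detection$results, detection$incis)
  mech_ok <- if (length(tp) == 0) NA_real_ else {
    mean(labels[tp] == truth$loci$mechanism[match(tp, truth$loci$locus_id)])
  }
  list(
    sensitivity = if (length(planted)) length(tp) / length(planted) else NA_real_,
    fdp = if (length(found)) length(fp) / length(found) else 0,
    mechanism_accuracy = mech_ok,
    n_planted = length(planted), n_detected = length(found),
    n_true_positive = length(tp), n_false_positive = length(fp)
  )
}

#' Write a cohort bundle to disk as plain-text fixtures
#'
#' Emits every external-interface format (TSV matrices, annotation, probe
#' tables, clinical table, truth table) so the bundle round-trips losslessly
#' through [read_fixture()].
#'
#' @param bundle A [generate_cohort()] bundle.
#' @param dir Writable output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_fixture <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_annotation(bundle$annotation, p("annotation.tsv"))
  write_probe_annotation(bundle$meth_probes, p("meth_probes.tsv"))
  write.table(bundle$probe_positions, p("cn_probe_positions.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_matrix(bundle$cn_probes, p("cn_probes.tsv"))
  write_matrix(bundle$beta_tumors, p("beta_tumors.tsv"))
  write_matrix(bundle$beta_normals, p("beta_normals.tsv"))
  write_matrix(bundle$expression_raw, p("expression.tsv"))
  write_matrix(1 * bundle$detected, p("detected.tsv"))
  write_matrix(bundle$mrna, p("mrna.tsv"))
  write.table(bundle$clinical, p("clinical.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  tr <- bundle$truth$loci
  tr$altered <- vapply(bundle$truth$altered[tr$locus_id],
                       function(x) paste(x, collapse = ";"), character(1))
  write.table(tr, p("truth.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a fixture directory written by [write_fixture()]
#'
#' @param dir Fixture directory.
#' @return List with the file-backed bundle components (`annotation`,
#'   `probe_positions`, `cn_probes`, `meth_probes`, `beta_tumors`,
#'   `beta_normals`, `expression_raw`, `detected`, `mrna`, `clinical`,
#'   `truth`).
#' @export
read_fixture <- function(dir) {
  p <- function(f) file.path(dir, f)
  needed <- c("annotation.tsv", "meth_probes.tsv", "cn_probe_positions.tsv",
              "cn_probes.tsv", "beta_tumors.tsv", "beta_normals.tsv",
              "expression.tsv", "detected.tsv", "mrna.tsv", "clinical.tsv",
              "truth.tsv")
  missing <- needed[!file.exists(p(needed))]
  if (length(missing) > 0) {
    stop("missing fixture file(s): ", paste(p(missing), collapse = ", "))
  }
  cl <- read.delim(p("clinical.tsv"), stringsAsFactors = FALSE)
  tr <- read.delim(p("truth.tsv"), stringsAsFactors = FALSE)
  altered <- strsplit(ifelse(is.na(tr$altered), "", tr$altered), ";",
                      fixed = TRUE)
  names(altered) <- tr$locus_id
  list(
    annotation = group_families(read_annotation(p("annotation.tsv"))),
    probe_positions = read.delim(p("cn_probe_positions.tsv"),
                                 stringsAsFactors = FALSE),
    cn_probes = read_matrix(p("cn_probes.tsv")),
    meth_probes = read_probe_annotation(p("meth_probes.tsv")),
    beta_tumors = read_matrix(p("beta_tumors.tsv"), kind = "beta"),
    beta_normals = read_matrix(p("beta_normals.tsv"), kind = "beta"),
    expression_raw = read_matrix(p("expression.tsv")),
    detected = read_matrix(p("detected.tsv")) > 0,
    mrna = read_matrix(p("mrna.tsv")),
    clinical = clinical_table(cl$sample_id, cl$er, cl$her2, cl$grade,
                              cl$tp53, cl$subtype, cl$rfs_time, cl$rfs_event),
    truth = list(loci = tr[, c("locus_id", "mechanism")], altered = altered)
  )
}
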