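.CH_GENES <- c("DNMT3A", "TET2", "ASXL1", "JAK2", "TP53", "SF3B1",
               "SRSF2", "PPM1D")
.OTHER_GENES <- c("GAPDH", "ACTB", "ALB", "TTN", "MUC16")

#' Synthetic cohort parameters
#'
#' The stated world of the generator. Two depth regimes are emulated:
#' whole-exome (`"wes"`, mean 150x) and error-corrected ultra-deep
#' targeted (`"ultradeep"`, mean 5000x), with per-site depth drawn
#' negative-binomially (variance `mu + dispersion * mu^2`). Four variant
#' classes are planted: true CH (VAF uniform on `ch_vaf_range`,
#' CH-gene nonsynonymous annotations, balanced strands), germline
#' heterozygotes (VAF ~ 0.5 at shared population loci with matching gnomAD
#' frequencies), recurrent low-VAF strand-skewed artifacts (per-locus
#' occurrence probabilities `artifact_occurrence`, recycled; by default a
#' mixture of clearly-artifactual 0.30 and partition-sensitive 0.08), and,
#' in paired mode, tumor cfDNA contamination (high tumor VAF, trace blood
#' VAF). By default the artifact VAF band lies strictly below the CH VAF
#' floor (separability is the point of the fixture); set
#' `separable = FALSE` to lift that constraint for hard-mode inputs.
#'
#' @param n_samples cohort size (>= 2).
#' @param depth_mode `"wes"` (~150x) or `"ultradeep"` (~5000x).
#' @param n_loci panel size available for artifact/germline placement.
#' @param ch_rate expected true-CH variants per sample (Poisson).
#' @param ch_vaf_range true CH VAF bounds (default 0.02 to 0.2).
#' @param artifact_loci number of recurrent artifact sites.
#' @param artifact_occurrence per-sample occurrence probabilities, recycled
#'   over artifact loci.
#' @param artifact_vaf_range true artifact VAF band (default 0.008-0.015).
#' @param artifact_strand_skew probability of an artifact alt read mapping
#'   to the forward strand (0.5 = balanced; default 0.65 inflates SOR while
#'   remaining below the default `sor_max`).
#' @param germline_rate expected heterozygous germline variants per sample.
#' @param contamination_rate expected tumor-contamination variants per
#'   sample (paired mode).
#' @param paired also simulate paired tumor samples.
#' @param tumor_depth_mean mean depth of the paired (tumor) sequencing.
#' @param depth_dispersion negative-binomial overdispersion (default 0.3).
#' @param seed integer seed; identical seeds give identical cohorts.
#' @param separable enforce artifact VAF ceiling < CH VAF floor.
#' @return object of class `sim_params`.
#' @export
sim_params <- function(n_samples, depth_mode = c("wes", "ultradeep"),
                       n_loci = 400L, ch_rate = 2,
                       ch_vaf_range = c(0.02, 0.2),
                       artifact_loci = 12L,
                       artifact_occurrence = c(0.30, 0.08),
                       artifact_vaf_range = c(0.008, 0.015),
                       artifact_strand_skew = 0.65,
                       germline_rate = 10, contamination_rate = 1,
                       paired = FALSE, tumor_depth_mean = 150,
                       depth_dispersion = 0.3, seed = 1L,
                       separable = TRUE) {
  depth_mode <- match.arg(depth_mode)
  p <- list(n_samples = as.integer(n_samples), depth_mode = depth_mode,
            depth_mean = if (depth_mode == "wes") 150 else 5000,
            n_loci = as.integer(n_loci), ch_rate = ch_rate,
            ch_vaf_range = ch_vaf_range, artifact_loci = as.integer(artifact_loci),
            artifact_occurrence = artifact_occurrence,
            artifact_vaf_range = artifact_vaf_range,
            artifact_strand_skew = artifact_strand_skew,
            germline_rate = germline_rate,
            contamination_rate = contamination_rate,
            paired = isTRUE(paired), tumor_depth_mean = tumor_depth_mean,
            depth_dispersion = depth_dispersion, seed = as.integer(seed),
            separable = isTRUE(separable))
  if (p$n_samples < 2L) stop("n_samples must be >= 2")
  if (p$n_loci < p$artifact_loci) stop("n_loci must be >= artifact_loci")
  if (any(p$artifact_occurrence <= 0 | p$artifact_occurrence >= 1))
    stop("artifact_occurrence probabilities must lie in (0, 1)")
  if (p$separable && max(p$artifact_vaf_range) >= min(p$ch_vaf_range))
    stop("artifact VAF ceiling must lie below the CH VAF floor ",
         "(set separable = FALSE to override)")
  structure(p, class = "sim_params")
}

.rdepth <- function(n, mu, dispersion) {
  pmax(stats::rnbinom(n, mu = mu, size = 1 / dispersion), 2L)
}

.rand_alleles <- function(n) {
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1), "")
  list(ref = ref, alt = unname(alt))
}

#' Simulate a seeded synthetic cohort
#'
#' Plants the four variant classes described in [sim_params()] and draws
#' read-level evidence: `alt_ad ~ Binomial(dp, vaf_true)` with the depth
#' negative-binomial per site, strand split `Binomial(alt_ad, 0.5)` for CH
#' and germline but skewed for artifacts, TLOD a monotone function of
#' `alt_ad` with unit Gaussian noise (`2 * alt_ad + N(0,1)`; enough to
#' exercise the threshold, with no claim of caller fidelity). A variant
#' record is emitted only when at least 2 alternate reads were drawn (a
#' caller would not report less); the truth table keeps every planted
#' event, with `emitted_blood` marking those that produced a blood record.
#'
#' @param params a [sim_params()] object.
#' @return object of class `sim_cohort`: `$table` (a [cohort_table()],
#'   including `tissue == "paired"` records in paired mode), `$truth` (one
#'   row per planted (sample, variant): class in ch/germline/artifact/
#'   contamination, simulated VAF and depth), and `$params`.
#' @export
simulate_cohort <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  .with_seed(params$seed, .simulate_impl(params))
}

.simulate_impl <- function(p) {
  n <- p$n_samples
  sids <- sprintf("S%04d", seq_len(n))

  ev <- list()
  # recurrent artifact loci ------------------------------------------------
  A <- p$artifact_loci
  if (A > 0L) {
    al <- .rand_alleles(A)
    occ <- rep_len(p$artifact_occurrence, A)
    avaf <- stats::runif(A, p$artifact_vaf_range[1], p$artifact_vaf_range[2])
    for (a in seq_len(A)) {
      carriers <- which(stats::runif(n) < occ[a])
      if (length(carriers) == 0L) next
      ev[[length(ev) + 1L]] <- data.frame(
        sample_id = sids[carriers], chrom = "chr1", pos = 10000L + a * 100L,
        ref = al$ref[a], alt = al$alt[a], class = "artifact",
        true_vaf = avaf[a], tumor_vaf = NA_real_,
        gene = NA_character_, exonic_function = NA_character_,
        gnomad_af = NA_real_, dbsnp_id = NA_character_,
        cosmic_id = NA_character_, stringsAsFactors = FALSE)
    }
  }
  # shared germline heterozygous loci --------------------------------------
  G <- max(1L, round(p$germline_rate / 0.275))
  popf <- stats::runif(G, 0.05, 0.5)
  popf <- pmin(popf * p$germline_rate / sum(popf), 0.95)
  gl <- .rand_alleles(G)
  geff <- sample(c("synonymous SNV", "nonsynonymous SNV"), G, replace = TRUE)
  ggene <- sample(.OTHER_GENES, G, replace = TRUE)
  for (g in seq_len(G)) {
    carriers <- which(stats::runif(n) < popf[g])
    if (length(carriers) == 0L) next
    ev[[length(ev) + 1L]] <- data.frame(
      sample_id = sids[carriers], chrom = "chr1", pos = 200000L + g * 100L,
      ref = gl$ref[g], alt = gl$alt[g], class = "germline",
      true_vaf = 0.5, tumor_vaf = 0.5,
      gene = ggene[g], exonic_function = geff[g],
      gnomad_af = round(popf[g], 4), dbsnp_id = sprintf("rs%07d", g),
      cosmic_id = NA_character_, stringsAsFactors = FALSE)
  }
  # true CH ----------------------------------------------------------------
  kch <- stats::rpois(n, p$ch_rate)
  if (sum(kch) > 0L) {
    si <- rep(seq_len(n), kch)
    m <- length(si)
    gidx <- sample(seq_along(.CH_GENES), m, replace = TRUE)
    pos <- 1000000L + gidx * 1000000L + sample.int(500000L, m, replace = TRUE)
    cal <- .rand_alleles(m)
    ev[[length(ev) + 1L]] <- data.frame(
      sample_id = sids[si], chrom = "chr1", pos = pos,
      ref = cal$ref, alt = cal$alt, class = "ch",
      true_vaf = stats::runif(m, p$ch_vaf_range[1], p$ch_vaf_range[2]),
      tumor_vaf = NA_real_,
      gene = .CH_GENES[gidx],
      exonic_function = sample(c("nonsynonymous SNV", "stopgain",
                                 "frameshift insertion", "frameshift deletion"),
                               m, replace = TRUE, prob = c(0.7, 0.1, 0.1, 0.1)),
      gnomad_af = NA_real_,
      dbsnp_id = NA_character_,
      cosmic_id = ifelse(stats::runif(m) < 0.5,
                         sprintf("COSM%06d", sample.int(999999L, m, replace = TRUE)),
                         NA_character_),
      stringsAsFactors = FALSE)
  }
  # tumor cfDNA contamination (paired mode) --------------------------------
  if (p$paired && p$contamination_rate > 0) {
    kc <- stats::rpois(n, p$contamination_rate)
    if (sum(kc) > 0L) {
      si <- rep(seq_len(n), kc)
      m <- length(si)
      cal <- .rand_alleles(m)
      ev[[length(ev) + 1L]] <- data.frame(
        sample_id = sids[si], chrom = "chr1",
        pos = 50000000L + sample.int(1000000L, m, replace = TRUE),
        ref = cal$ref, alt = cal$alt, class = "contamination",
        true_vaf = stats::runif(m, 0.001, 0.01),
        tumor_vaf = stats::runif(m, 0.2, 0.6),
        gene = sample(.OTHER_GENES, m, replace = TRUE),
        exonic_function = "nonsynonymous SNV",
        gnomad_af = NA_real_, dbsnp_id = NA_character_,
        cosmic_id = NA_character_, stringsAsFactors = FALSE)
    }
  }

  events <- do.call(rbind, ev)
  # collisions (same sample, same variant) are vanishingly rare but would
  # violate the one-record-per-key invariant; drop duplicates
  events <- events[!duplicated(paste(events$sample_id, events$chrom,
                                     events$pos, events$ref, events$alt)), ]
  m <- nrow(events)

  # blood read evidence -----------------------------------------------------
  dp <- .rdepth(m, p$depth_mean, p$depth_dispersion)
  alt_ad <- stats::rbinom(m, dp, events$true_vaf)
  skew <- ifelse(events$class == "artifact", p$artifact_strand_skew, 0.5)
  saf <- stats::rbinom(m, alt_ad, skew)
  sar <- alt_ad - saf
  ref_ad <- dp - alt_ad
  ref_fw <- stats::rbinom(m, ref_ad, 0.5)
  ref_rv <- ref_ad - ref_fw
  tlod <- round(2 * alt_ad + stats::rnorm(m), 2)
  emitted <- alt_ad >= 2L

  blood <- data.frame(
    sample_id = events$sample_id, tissue = "blood",
    chrom = events$chrom, pos = events$pos, ref = events$ref, alt = events$alt,
    vaf = alt_ad / dp, dp = dp, alt_ad = alt_ad,
    saf = saf, sar = sar, ref_fw = ref_fw, ref_rv = ref_rv,
    sor = compute_sor(ref_fw, ref_rv, saf, sar),
    tlod = tlod,
    gene = events$gene, exonic_function = events$exonic_function,
    gnomad_af = events$gnomad_af, dbsnp_id = events$dbsnp_id,
    cosmic_id = events$cosmic_id, in_repeat_region = NA,
    stringsAsFactors = FALSE)[emitted, , drop = FALSE]

  paired_rec <- NULL
  if (p$paired) {
    tsel <- which(events$class %in% c("germline", "contamination"))
    if (length(tsel) > 0L) {
      tm <- length(tsel)
      tdp <- .rdepth(tm, p$tumor_depth_mean, p$depth_dispersion)
      tvaf <- events$tumor_vaf[tsel]
      talt <- stats::rbinom(tm, tdp, tvaf)
      tsaf <- stats::rbinom(tm, talt, 0.5)
      trf <- stats::rbinom(tm, tdp - talt, 0.5)
      tem <- talt >= 2L
      paired_rec <- data.frame(
        sample_id = events$sample_id[tsel], tissue = "paired",
        chrom = events$chrom[tsel], pos = events$pos[tsel],
        ref = events$ref[tsel], alt = events$alt[tsel],
        vaf = talt / tdp, dp = tdp, alt_ad = talt,
        saf = tsaf, sar = talt - tsaf, ref_fw = trf, ref_rv = tdp - talt - trf,
        sor = compute_sor(trf, tdp - talt - trf, tsaf, talt - tsaf),
        tlod = round(2 * talt + stats::rnorm(tm), 2),
        gene = events$gene[tsel], exonic_function = events$exonic_function[tsel],
        gnomad_af = events$gnomad_af[tsel], dbsnp_id = events$dbsnp_id[tsel],
        cosmic_id = events$cosmic_id[tsel], in_repeat_region = NA,
        stringsAsFactors = FALSE)[tem, , drop = FALSE]
    }
  }

  truth <- data.frame(
    sample_id = events$sample_id, chrom = events$chrom, pos = events$pos,
    ref = events$ref, alt = events$alt, class = events$class,
    true_vaf = events$true_vaf, dp = dp, emitted_blood = emitted,
    stringsAsFactors = FALSE)

  pm <- NULL
  if (p$paired) {
    pm <- stats::setNames(sids, sids)
  }
  tab <- merge_cohort(list(rbind(blood, paired_rec)),
                      paired_map = pm, sample_ids = sids)
  structure(list(table = tab, truth = truth, params = p),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("sim_cohort: %d samples (%s, ~%gx), seed %d%s\n",
              x$params$n_samples, x$params$depth_mode, x$params$depth_mean,
              x$params$seed, if (x$params$paired) ", paired" else ""))
  print(table(x$truth$class))
  invisible(x)
}

# ---- VCF emission -------------------------------------------------------

.VCF_HEADER <- c(
  "##fileformat=VCFv4.2",
  "##contig=<ID=chr1>",
  "##INFO=<ID=TLOD,Number=A,Type=Float,Description=\"Tumor log odds that the variant exists\">",
  "##INFO=<ID=SOR,Number=1,Type=Float,Description=\"Symmetric strand odds ratio\">",
  "##INFO=<ID=Gene.refGene,Number=1,Type=String,Description=\"Gene symbol\">",
  "##INFO=<ID=ExonicFunc.refGene,Number=1,Type=String,Description=\"Exonic function\">",
  "##INFO=<ID=gnomAD_exome_AF,Number=1,Type=Float,Description=\"gnomAD exome allele frequency\">",
  "##INFO=<ID=avsnp150,Number=1,Type=String,Description=\"dbSNP id\">",
  "##INFO=<ID=cosmic70,Number=1,Type=String,Description=\"COSMIC id\">",
  "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
  "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
  "##FORMAT=<ID=AF,Number=A,Type=Float,Description=\"Allele fraction\">",
  "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
  "##FORMAT=<ID=SB,Number=4,Type=Integer,Description=\"Per-strand counts: ref fwd, ref rev, alt fwd, alt rev\">"
)

.vcf_info_field <- function(key, val, encode = FALSE) {
  ifelse(is.na(val), NA_character_,
         paste0(key, "=", if (encode) gsub(" ", "_", val) else val))
}

.write_vcf <- function(rec, path, sample_id) {
  rec <- rec[order(rec$chrom, rec$pos, rec$alt), , drop = FALSE]
  info_parts <- cbind(
    .vcf_info_field("TLOD", ifelse(is.na(rec$tlod), NA, sprintf("%.2f", rec$tlod))),
    .vcf_info_field("SOR", ifelse(is.na(rec$sor), NA, sprintf("%.3f", rec$sor))),
    .vcf_info_field("Gene.refGene", rec$gene),
    .vcf_info_field("ExonicFunc.refGene", rec$exonic_function, encode = TRUE),
    .vcf_info_field("gnomAD_exome_AF",
                    ifelse(is.na(rec$gnomad_af), NA, sprintf("%.4g", rec$gnomad_af))),
    .vcf_info_field("avsnp150", rec$dbsnp_id),
    .vcf_info_field("cosmic70", rec$cosmic_id))
  info <- apply(info_parts, 1, function(z) {
    z <- z[!is.na(z)]
    if (length(z) == 0L) "." else paste(z, collapse = ";")
  })
  fmt <- sprintf("0/1:%d,%d:%s:%d:%d,%d,%d,%d",
                 rec$dp - rec$alt_ad, rec$alt_ad,
                 sprintf("%.6g", rec$alt_ad / rec$dp), rec$dp,
                 rec$ref_fw, rec$ref_rv, rec$saf, rec$sar)
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s\tGT:AD:AF:DP:SB\t%s",
                  rec$chrom, rec$pos, rec$ref, rec$alt, info, fmt)
  writeLines(c(.VCF_HEADER,
               paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                      sample_id),
               body), path)
  invisible(path)
}

#' Write a simulated cohort as per-sample VCFs plus a sample sheet
#'
#' Emits valid VCF 4.2 per sample (and per paired sample in paired mode)
#' with FORMAT AD/AF/DP/SB, INFO TLOD/SOR and ANNOVAR-style annotation
#' keys matching the default [annotation_schema()], a `sample_sheet.tsv`,
#' and — when `x` is a `sim_cohort` — the `truth.tsv` table. The files
#' parse cleanly back through [parse_vcf()] / [vcf2input()].
#'
#' @param x a `sim_cohort` (from [simulate_cohort()]) or a
#'   [cohort_table()].
#' @param out_dir output directory (created if needed).
#' @return path of the sample sheet, invisibly.
#' @export
write_cohort_vcfs <- function(x, out_dir) {
  tab <- if (inherits(x, "sim_cohort")) x$table else x
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sids <- attr(tab, "sample_ids")
  pm <- attr(tab, "paired_map")
  sheet <- data.frame(sample_id = sids,
                      blood_vcf = file.path(out_dir, paste0(sids, ".blood.vcf")),
                      paired_vcf = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_along(sids)) {
    s <- sids[i]
    .write_vcf(tab[tab$sample_id == s & tab$tissue == "blood", , drop = FALSE],
               sheet$blood_vcf[i], s)
    if (s %in% names(pm)) {
      pv <- file.path(out_dir, paste0(s, ".paired.vcf"))
      .write_vcf(tab[tab$sample_id == s & tab$tissue == "paired", , drop = FALSE],
                 pv, s)
      sheet$paired_vcf[i] <- pv
    }
  }
  sheet_path <- file.path(out_dir, "sample_sheet.tsv")
  utils::write.table(sheet, sheet_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  if (inherits(x, "sim_cohort"))
    utils::write.table(x$truth, file.path(out_dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(sheet_path)
}
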