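# fixture builders: everything is generated in code at test time

# a small random cohort exercising every filter dimension, including
# missing metrics/annotations and (optionally) paired records
random_micro_cohort <- function(seed, paired = FALSE) {
  set.seed(seed)
  n_samples <- sample(2:5, 1)
  sids <- sprintf("M%02d", seq_len(n_samples))
  n_var <- sample(4:20, 1)
  pool <- data.frame(
    chrom = "chr1",
    pos = sample(100:120, n_var, replace = TRUE),
    ref = sample(c("A", "C", "G", "T"), n_var, replace = TRUE),
    stringsAsFactors = FALSE)
  pool$alt <- vapply(pool$ref, function(r)
    sample(setdiff(c("A", "C", "G", "T"), r), 1), "")
  rows <- list()
  maybe_na <- function(x, p = 0.25) ifelse(runif(length(x)) < p, NA, x)
  for (s in sids) {
    idx <- sample(n_var, sample(1:n_var, 1))
    k <- length(idx)
    dp <- sample(10:200, k, replace = TRUE)
    alt_ad <- pmin(dp, rpois(k, 8))
    saf <- rbinom(k, alt_ad, 0.5)
    rows[[s]] <- data.frame(
      sample_id = s, tissue = "blood",
      chrom = pool$chrom[idx], pos = pool$pos[idx],
      ref = pool$ref[idx], alt = pool$alt[idx],
      vaf = alt_ad / dp, dp = dp, alt_ad = alt_ad,
      saf = as.integer(maybe_na(saf)), sar = as.integer(maybe_na(alt_ad - saf)),
      ref_fw = NA_integer_, ref_rv = NA_integer_,
      sor = maybe_na(runif(k, 0, 6)),
      tlod = maybe_na(runif(k, 0, 40)),
      gene = "GENE1",
      exonic_function = maybe_na(sample(c("synonymous SNV", "nonsynonymous SNV",
                                          "stopgain", "unknown"),
                                        k, replace = TRUE), 0.3),
      gnomad_af = maybe_na(runif(k, 0, 0.01), 0.6),
      dbsnp_id = maybe_na(rep("rs1", k), 0.6),
      cosmic_id = maybe_na(rep("COSM1", k), 0.6),
      in_repeat_region = maybe_na(runif(k) < 0.2, 0.5),
      stringsAsFactors = FALSE)
  }
  pm <- NULL
  if (paired) {
    withp <- sample(sids, max(1, n_samples - 1))
    pm <- setNames(withp, withp)
    for (s in withp) {
      b <- rows[[s]]
      # paired record for a random subset of the blood variants
      take <- runif(nrow(b)) < 0.6
      if (!any(take)) next
      p <- b[take, , drop = FALSE]
      p$tissue <- "paired"
      p$dp <- sample(30:150, nrow(p), replace = TRUE)
      p$alt_ad <- rbinom(nrow(p), p$dp, runif(nrow(p), 0, 0.4))
      p$vaf <- p$alt_ad / p$dp
      rows[[paste0(s, "_p")]] <- p
    }
  }
  df <- do.call(rbind, rows)
  df <- df[!duplicated(paste(df$sample_id, df$tissue, df$chrom, df$pos,
                             df$ref, df$alt)), ]
  cohort_table(df, sample_ids = sids, paired_map = pm)
}

random_micro_config <- function(seed) {
  set.seed(seed + 1000)
  filter_config(
    vaf_min = runif(1, 0, 0.05), vaf_max = runif(1, 0.3, 0.6),
    dp_min = sample(10:40, 1), alt_ad_min = sample(2:8, 1),
    saf_min = sample(0:4, 1), sar_min = sample(0:4, 1),
    sor_max = runif(1, 1, 5), tlod_min = runif(1, 0, 15),
    prevalence_max = runif(1, 0.1, 0.8), gnomad_max = 0.001)
}

# a hand-written VCF exercising parser corner cases
write_fixture_vcf <- function(path, lines) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1>",
    "##INFO=<ID=TLOD,Number=A,Type=Float,Description=\"tlod\">",
    "##INFO=<ID=SOR,Number=1,Type=Float,Description=\"sor\">",
    "##INFO=<ID=Gene.refGene,Number=1,Type=String,Description=\"gene\">",
    "##INFO=<ID=ExonicFunc.refGene,Number=1,Type=String,Description=\"func\">",
    "##INFO=<ID=gnomAD_exome_AF,Number=1,Type=Float,Description=\"af\">",
    "##INFO=<ID=avsnp150,Number=1,Type=String,Description=\"rs\">",
    "##INFO=<ID=cosmic70,Number=1,Type=String,Description=\"cosmic\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"gt\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"ad\">",
    "##FORMAT=<ID=AF,Number=A,Type=Float,Description=\"af\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"dp\">",
    "##FORMAT=<ID=SB,Number=4,Type=Integer,Description=\"sb\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1")
  writeLines(c(header, lines), path)
  path
}
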