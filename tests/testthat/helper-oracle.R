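# Independent brute-force re-implementations used as oracles. Everything
# here is deliberately written as explicit per-record loops with literal
# comparisons, sharing no code with the package internals.

# hypergeometric upper-tail by direct enumeration of the 2x2 tables
brute_hyper_tail <- function(blood_alt, blood_dp, tumor_alt, tumor_dp) {
  K <- blood_alt + tumor_alt          # total alt reads
  Nn <- blood_dp + tumor_dp           # total reads
  total <- 0
  for (x in blood_alt:min(blood_dp, K)) {
    if (K - x > tumor_dp) next
    total <- total + choose(K, x) * choose(Nn - K, blood_dp - x) / choose(Nn, blood_dp)
  }
  total
}

# full four-tier filter, one record at a time
brute_filter <- function(table, config) {
  blood <- table[table$tissue == "blood", , drop = FALSE]
  sample_ids <- attr(table, "sample_ids")
  N <- length(sample_ids)
  paired <- table[table$tissue == "paired", , drop = FALSE]
  pm <- attr(table, "paired_map")
  paired_samples <- union(names(pm), unique(paired$sample_id))

  out <- data.frame(key = character(nrow(blood)), keep = NA,
                    reasons = character(nrow(blood)), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(blood))) {
    b <- blood[i, ]
    reasons <- character()
    # population tier: count carrier samples by loops
    allele_n <- 0L
    locus_n <- 0L
    for (s in unique(blood$sample_id)) {
      sb <- blood[blood$sample_id == s, , drop = FALSE]
      if (any(sb$chrom == b$chrom & sb$pos == b$pos &
              sb$ref == b$ref & sb$alt == b$alt)) allele_n <- allele_n + 1L
      if (any(sb$chrom == b$chrom & sb$pos == b$pos)) locus_n <- locus_n + 1L
    }
    if (allele_n / N > config$prevalence_max) reasons <- c(reasons, "POP_ALLELE")
    if (locus_n / N > config$prevalence_max) reasons <- c(reasons, "POP_LOCUS")
    # technical tier
    if (!is.na(b$vaf) && b$vaf < config$vaf_min) reasons <- c(reasons, "VAF_LOW")
    if (!is.na(b$vaf) && b$vaf > config$vaf_max) reasons <- c(reasons, "VAF_HIGH")
    if (!is.na(b$dp) && b$dp <= config$dp_min) reasons <- c(reasons, "DP")
    if (!is.na(b$alt_ad) && b$alt_ad < config$alt_ad_min) reasons <- c(reasons, "ALT_AD")
    if (!is.na(b$saf) && b$saf < config$saf_min) reasons <- c(reasons, "SAF")
    if (!is.na(b$sar) && b$sar < config$sar_min) reasons <- c(reasons, "SAR")
    if (!is.na(b$sor) && b$sor > config$sor_max) reasons <- c(reasons, "SOR")
    if (!is.na(b$tlod) && b$tlod < config$tlod_min) reasons <- c(reasons, "TLOD")
    # functional tier
    ef <- b$exonic_function
    if (!is.na(ef) && ef == "synonymous SNV") reasons <- c(reasons, "SYNONYMOUS")
    if (!is.na(ef) && ef != "synonymous SNV" && !(ef %in% config$keep_effects))
      reasons <- c(reasons, "EFFECT")
    if (!is.na(b$in_repeat_region) && b$in_repeat_region)
      reasons <- c(reasons, "REPEAT")
    germ <- FALSE
    if (!is.na(b$gnomad_af) && b$gnomad_af > config$gnomad_max) germ <- TRUE
    if (!is.na(b$dbsnp_id) && is.na(b$gnomad_af) && is.na(b$cosmic_id)) germ <- TRUE
    if (germ) reasons <- c(reasons, "GERMLINE_DB")
    # individual (paired) tier
    if (config$mode == "paired" && b$sample_id %in% paired_samples &&
        nrow(paired) > 0L) {
      hit <- paired[paired$sample_id == b$sample_id & paired$chrom == b$chrom &
                    paired$pos == b$pos & paired$ref == b$ref &
                    paired$alt == b$alt, , drop = FALSE]
      if (nrow(hit) == 1L) {
        ta <- hit$alt_ad; td <- hit$dp
      } else {
        ta <- 0L
        td <- round(median(paired$dp[paired$sample_id == b$sample_id]))
      }
      if (!is.na(ta) && !is.na(td) && td > 0L) {
        p <- fisher.test(matrix(c(b$alt_ad, b$dp - b$alt_ad, ta, td - ta),
                                nrow = 2, byrow = TRUE),
                         alternative = "greater")$p.value
        if (p >= config$paired_alpha) {
          if (ta / td > b$vaf) reasons <- c(reasons, "PAIR_TUMOR")
          else reasons <- c(reasons, "PAIR_GERMLINE")
        }
      }
    }
    out$key[i] <- paste(b$sample_id,
                        paste(b$chrom, b$pos, b$ref, b$alt, sep = ":"), sep = "|")
    out$keep[i] <- length(reasons) == 0L
    out$reasons[i] <- paste(sort(reasons), collapse = ";")
  }
  out
}

brute_consistency <- function(full, pooled) {
  full <- unique(full); pooled <- unique(pooled)
  common <- intersect(full, pooled)
  list(common_fraction = if (length(full) == 0) 1 else length(common) / length(full),
       unique_full_fraction = if (length(full) == 0) 0 else
         length(setdiff(full, pooled)) / length(full),
       unique_pooled_fraction = if (length(pooled) == 0) 0 else
         length(setdiff(pooled, full)) / length(pooled))
}
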