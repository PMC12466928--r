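#' Reason codes, in canonical report order
#'
#' Population tier first (it is applied first), then technical, functional,
#' and individual (paired) reasons. A record is a CH call iff no reason
#' fires; all criteria are evaluated (not short-circuited) so removals are
#' fully auditable.
#' @export
CH_REASONS <- c("POP_ALLELE", "POP_LOCUS",
                "VAF_LOW", "VAF_HIGH", "DP", "ALT_AD", "SAF", "SAR",
                "SOR", "TLOD",
                "SYNONYMOUS", "EFFECT", "REPEAT", "GERMLINE_DB",
                "PAIR_GERMLINE", "PAIR_TUMOR")

.cohort_size <- function(table) {
  sid <- attr(table, "sample_ids")
  if (!is.null(sid) && length(sid) > 0L) return(length(sid))
  length(unique(table$sample_id[table$tissue == "blood"]))
}

# carrier counts over blood records: allele level (exact variant key) and
# locus level (any alternate allele at the position, counting samples)
.prevalence_counts <- function(blood) {
  vk <- .variant_key(blood)
  lk <- .locus_key(blood)
  a_cnt <- stats::ave(seq_along(vk), vk, FUN = length)
  u <- !duplicated(paste(blood$sample_id, lk, sep = "\r"))
  tab <- table(lk[u])
  l_cnt <- as.integer(tab[lk])
  list(allele = a_cnt, locus = l_cnt, vk = vk, lk = lk)
}

#' Population prevalence filter
#'
#' Computes, over the blood records of the cohort passed in (so a subset
#' run uses subset prevalence), each variant's allele-level prevalence
#' (carriers of the exact allele / cohort size) and locus-level prevalence
#' (carriers of any alternate at the position / cohort size). A variant is
#' removed for all carriers iff either prevalence strictly exceeds
#' `prevalence_max`; boundary equality passes.
#'
#' @param table a [cohort_table()].
#' @param config a [filter_config()].
#' @return data frame with one row per distinct variant key: chrom, pos,
#'   ref, alt, allele_prevalence, locus_prevalence, removed, reasons.
#' @export
population_prevalence_filter <- function(table, config = filter_config()) {
  blood <- .blood_rows(table)
  N <- .cohort_size(table)
  if (N < 1L || nrow(blood) == 0L) stop("empty cohort")
  pc <- .prevalence_counts(blood)
  first <- !duplicated(pc$vk)
  ap <- pc$allele[first] / N
  lp <- pc$locus[first] / N
  fail_a <- ap > config$prevalence_max
  fail_l <- lp > config$prevalence_max
  reasons <- mapply(function(a, l)
    paste(c("POP_ALLELE"[a], "POP_LOCUS"[l]), collapse = ";"),
    fail_a, fail_l)
  data.frame(chrom = blood$chrom[first], pos = blood$pos[first],
             ref = blood$ref[first], alt = blood$alt[first],
             allele_prevalence = ap, locus_prevalence = lp,
             removed = fail_a | fail_l, reasons = reasons,
             stringsAsFactors = FALSE)
}

# ---- vectorized tier evaluators (blood rows in, logical fail columns out)

.fail_pop <- function(allele_cnt, locus_cnt, N, cutoff) {
  cbind(POP_ALLELE = allele_cnt / N > cutoff,
        POP_LOCUS = locus_cnt / N > cutoff)
}

.fail_technical <- function(blood, cfg) {
  f <- function(x, cond) !is.na(x) & cond
  cbind(
    VAF_LOW = f(blood$vaf, blood$vaf < cfg$vaf_min),
    VAF_HIGH = f(blood$vaf, blood$vaf > cfg$vaf_max),
    DP = f(blood$dp, blood$dp <= cfg$dp_min),
    ALT_AD = f(blood$alt_ad, blood$alt_ad < cfg$alt_ad_min),
    SAF = f(blood$saf, blood$saf < cfg$saf_min),
    SAR = f(blood$sar, blood$sar < cfg$sar_min),
    SOR = f(blood$sor, blood$sor > cfg$sor_max),
    TLOD = f(blood$tlod, blood$tlod < cfg$tlod_min)
  )
}

.fail_functional <- function(blood, cfg) {
  ef <- blood$exonic_function
  syn <- !is.na(ef) & ef == "synonymous SNV"
  eff <- !is.na(ef) & !syn & !(ef %in% cfg$keep_effects)
  if (!is.null(cfg$gene_allowlist))
    eff <- eff | (!is.na(blood$gene) & !(blood$gene %in% cfg$gene_allowlist))
  gdb <- (!is.na(blood$gnomad_af) & blood$gnomad_af > cfg$gnomad_max) |
    (!is.na(blood$dbsnp_id) & is.na(blood$gnomad_af) & is.na(blood$cosmic_id))
  cbind(SYNONYMOUS = syn,
        EFFECT = eff,
        REPEAT = !is.na(blood$in_repeat_region) & blood$in_repeat_region,
        GERMLINE_DB = gdb)
}

#' One-sided exact enrichment p-value for blood vs paired sample
#'
#' Exact (hypergeometric / one-sided Fisher) tail probability that the
#' blood alternate-read fraction exceeds the paired sample's, from the 2x2
#' table `[blood alt, blood ref; tumor alt, tumor ref]`. Vectorized.
#'
#' @param blood_alt,blood_dp alternate reads and depth in blood.
#' @param tumor_alt,tumor_dp alternate reads and depth in the paired sample.
#' @return p-values in `[0, 1]`.
#' @export
paired_enrichment_p <- function(blood_alt, blood_dp, tumor_alt, tumor_dp) {
  stats::phyper(blood_alt - 1L, blood_alt + tumor_alt,
                (blood_dp - blood_alt) + (tumor_dp - tumor_alt),
                blood_dp, lower.tail = FALSE)
}

# join blood rows against paired-tissue records; absent paired sites get
# tumor alt = 0 with tumor dp imputed as that paired sample's median depth
.paired_stats <- function(table, blood) {
  pm <- attr(table, "paired_map")
  paired <- table[table$tissue == "paired", , drop = FALSE]
  paired_samples <- union(names(pm), unique(paired$sample_id))
  n <- nrow(blood)
  has_pair <- blood$sample_id %in% paired_samples
  ta <- rep(NA_integer_, n); td <- rep(NA_integer_, n)
  n_imputed <- 0L
  if (nrow(paired) > 0L && any(has_pair)) {
    idx <- match(paste(blood$sample_id, .variant_key(blood)),
                 paste(paired$sample_id, .variant_key(paired)))
    ta <- paired$alt_ad[idx]
    td <- paired$dp[idx]
    med <- tapply(paired$dp, paired$sample_id, stats::median)
    miss <- has_pair & is.na(idx)
    n_imputed <- sum(miss)
    ta[miss] <- 0L
    td[miss] <- as.integer(round(med[blood$sample_id[miss]]))
  } else {
    has_pair[] <- FALSE
  }
  ok <- has_pair & !is.na(ta) & !is.na(td) & td > 0L
  p <- rep(NA_real_, n); tv <- rep(NA_real_, n)
  p[ok] <- paired_enrichment_p(blood$alt_ad[ok], blood$dp[ok], ta[ok], td[ok])
  tv[ok] <- ta[ok] / td[ok]
  list(has_pair = ok, p = p, tumor_vaf = tv, n_imputed = n_imputed,
       n_unpaired_samples = length(setdiff(unique(blood$sample_id),
                                           paired_samples)))
}

.fail_paired <- function(blood, ps, cfg) {
  enr <- ps$has_pair & !is.na(ps$p) & ps$p < cfg$paired_alpha
  not_enr <- ps$has_pair & !enr
  cbind(PAIR_GERMLINE = not_enr & ps$tumor_vaf <= blood$vaf,
        PAIR_TUMOR = not_enr & ps$tumor_vaf > blood$vaf)
}

# full 16-column failure matrix for the blood rows of a table
.fail_matrix <- function(table, config, blood = .blood_rows(table),
                         quiet = FALSE) {
  N <- .cohort_size(table)
  pc <- .prevalence_counts(blood)
  m <- cbind(
    .fail_pop(pc$allele, pc$locus, N, config$prevalence_max),
    .fail_technical(blood, config),
    .fail_functional(blood, config)
  )
  if (config$mode == "paired") {
    ps <- .paired_stats(table, blood)
    if (!quiet) {
      if (ps$n_imputed > 0L)
        message(ps$n_imputed, " blood variant(s) absent from the paired VCF: ",
                "tumor depth imputed as the paired sample's median depth")
      if (ps$n_unpaired_samples > 0L)
        message(ps$n_unpaired_samples,
                " sample(s) lack paired data; single-sample logic applied")
    }
    m <- cbind(m, .fail_paired(blood, ps, config))
  } else {
    m <- cbind(m, PAIR_GERMLINE = rep(FALSE, nrow(blood)),
               PAIR_TUMOR = rep(FALSE, nrow(blood)))
  }
  m[, CH_REASONS, drop = FALSE]
}

#' Technical-tier decision for one variant record
#'
#' Applies the VAF window, depth, alternate allele depth, per-strand
#' support, strand odds ratio and TLOD criteria to a single blood record.
#' Every criterion is evaluated; missing metrics pass.
#'
#' @param record one-row data frame or named list with the record fields.
#' @param config a [filter_config()].
#' @return list with `keep` (logical) and `reasons` (character vector in
#'   canonical order; empty iff `keep`).
#' @export
technical_filter <- function(record, config = filter_config()) {
  fields <- c("vaf", "dp", "alt_ad", "saf", "sar", "sor", "tlod")
  rl <- as.list(record)
  for (f in fields) if (is.null(rl[[f]])) rl[[f]] <- NA
  df <- as.data.frame(rl[fields], stringsAsFactors = FALSE)
  m <- .fail_technical(df, config)
  reasons <- colnames(m)[as.vector(m[1, ])]
  list(keep = length(reasons) == 0L, reasons = reasons)
}

#' Functional-tier decision for one variant record
#'
#' Removes synonymous variants, effects outside `keep_effects`, repeat
#' region variants, and likely germline database variants: gnomAD allele
#' frequency above `gnomad_max`, or a bare dbSNP membership with no gnomAD
#' frequency and no cancer-database (COSMIC) evidence — COSMIC evidence
#' rescues dbSNP-listed variants. Missing annotations pass.
#'
#' @inheritParams technical_filter
#' @return list with `keep` and `reasons` as in [technical_filter()].
#' @export
functional_filter <- function(record, config = filter_config()) {
  fields <- c("exonic_function", "gene", "gnomad_af", "dbsnp_id", "cosmic_id",
              "in_repeat_region")
  rl <- as.list(record)
  for (f in fields) if (is.null(rl[[f]])) rl[[f]] <- NA
  df <- as.data.frame(rl[fields], stringsAsFactors = FALSE)
  m <- .fail_functional(df, config)
  reasons <- colnames(m)[as.vector(m[1, ])]
  list(keep = length(reasons) == 0L, reasons = reasons)
}

#' Classify a blood variant against its paired-sample counterpart
#'
#' Builds the 2x2 read-count table and applies the one-sided exact test for
#' enrichment of the alternate fraction in blood. Significant enrichment
#' (`p < paired_alpha`) classifies the variant as CH; otherwise the variant
#' is removed and the direction of the VAF difference labels it
#' `pair_tumor` (paired VAF higher: likely tumor cfDNA contamination) or
#' `pair_germline` (similar or lower paired VAF). A variant absent from the
#' paired VCF is tested against tumor alt = 0 with depth `tumor_dp`
#' (typically the paired sample's median depth).
#'
#' @param blood one-row blood record (needs `alt_ad`, `dp`, `vaf`).
#' @param paired matching paired-sample record, or `NULL` if absent.
#' @param config a [filter_config()].
#' @param tumor_dp imputed paired depth used when `paired` is `NULL`.
#' @return list with `class` (one of `"ch_enriched"`, `"pair_germline"`,
#'   `"pair_tumor"`) and `p` (the exact one-sided p-value).
#' @export
paired_classify <- function(blood, paired = NULL,
                            config = filter_config(mode = "paired"),
                            tumor_dp = NULL) {
  b <- as.list(blood)
  if (is.na(b$dp) || b$dp <= 0) stop("zero blood depth")
  if (is.null(paired)) {
    if (is.null(tumor_dp)) stop("tumor_dp required when paired record absent")
    ta <- 0L; td <- as.integer(tumor_dp)
  } else {
    p <- as.list(paired)
    ta <- p$alt_ad; td <- p$dp
  }
  pv <- paired_enrichment_p(b$alt_ad, b$dp, ta, td)
  tumor_vaf <- ta / td
  cls <- if (pv < config$paired_alpha) "ch_enriched"
         else if (tumor_vaf > b$vaf) "pair_tumor" else "pair_germline"
  list(class = cls, p = pv)
}

#' Run the four-tier CH filter over a cohort
#'
#' Tier order: population prevalence first, then technical, functional, and
#' individual (paired) metrics. A decision is recorded for every blood
#' record, with every firing reason (later tiers are still evaluated after
#' an earlier removal, for audit). The output is deterministic in
#' `(table, config)` and invariant to row and sample order.
#'
#' @param table a [cohort_table()] (paired mode reads `tissue == "paired"`
#'   rows; samples without a pair fall back to single-sample logic).
#' @param config a [filter_config()].
#' @return an object of class `ch_callset`: list with `calls` (kept
#'   records), `decisions` (one row per blood record with semicolon-joined
#'   reason codes), `summary` (counts removed per reason), `config`,
#'   `sample_ids`, and `call_keys` (`sample|chrom:pos:ref:alt`).
#' @export
run_chipfilter <- function(table, config = filter_config()) {
  if (!inherits(table, "cohort_table")) table <- cohort_table(table)
  blood <- .blood_rows(table)
  if (nrow(blood) == 0L) stop("empty cohort table")
  if (anyDuplicated(paste(blood$sample_id, .variant_key(blood))))
    stop("duplicate (sample, variant) blood records; merge the cohort first")
  if (config$mode == "paired" &&
      !any(table$tissue == "paired") && length(attr(table, "paired_map")) == 0L)
    stop("paired mode requested but the table holds no paired data")
  m <- .fail_matrix(table, config, blood)
  keep <- rowSums(m) == 0L
  reasons <- vapply(seq_len(nrow(m)), function(i)
    paste(CH_REASONS[m[i, ]], collapse = ";"), "")
  decisions <- data.frame(
    sample_id = blood$sample_id, chrom = blood$chrom, pos = blood$pos,
    ref = blood$ref, alt = blood$alt, vaf = blood$vaf, dp = blood$dp,
    keep = keep, reasons = reasons, stringsAsFactors = FALSE)
  calls <- as.data.frame(blood)[keep, c("sample_id", "chrom", "pos", "ref",
                                        "alt", "vaf", "dp", "gene",
                                        "exonic_function"), drop = FALSE]
  class(calls) <- "data.frame"
  rownames(calls) <- NULL
  structure(list(
    calls = calls,
    decisions = decisions,
    summary = list(
      n_records = nrow(blood),
      n_calls = sum(keep),
      n_samples = .cohort_size(table),
      removed_by_reason = colSums(m)
    ),
    config = config,
    sample_ids = attr(table, "sample_ids"),
    call_keys = .call_key(blood)[keep]
  ), class = "ch_callset")
}

#' @export
print.ch_callset <- function(x, ...) {
  s <- x$summary
  cat(sprintf("ch_callset: %d CH calls from %d records across %d samples (mode: %s)\n",
              s$n_calls, s$n_records, s$n_samples, x$config$mode))
  rb <- s$removed_by_reason[s$removed_by_reason > 0]
  if (length(rb) > 0L) {
    cat("  records failing per reason:\n")
    for (k in names(rb)) cat(sprintf("    %-13s %d\n", k, rb[[k]]))
  }
  invisible(x)
}

#' @export
summary.ch_callset <- function(object, ...) {
  s <- object$summary
  out <- c(list(calls_per_sample = table(object$calls$sample_id)), s)
  class(out) <- "summary.ch_callset"
  out
}

#' @export
print.summary.ch_callset <- function(x, ...) {
  cat(sprintf("%d CH calls / %d records / %d samples\n",
              x$n_calls, x$n_records, x$n_samples))
  cat("removals per reason (audited, overlapping):\n")
  print(x$removed_by_reason)
  invisible(x)
}

#' Write a call set to disk
#'
#' Writes `calls.tsv` (sample, chrom, pos, ref, alt, vaf, dp, gene, effect),
#' `decisions.tsv` (semicolon-joined reason codes) and `summary.txt`
#' (counts removed per tier) under `dir`.
#'
#' @param x a `ch_callset`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_callset <- function(x, dir) {
  stopifnot(inherits(x, "ch_callset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("calls.tsv", "decisions.tsv", "summary.txt"))
  utils::write.table(x$calls, paths[1], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(x$decisions, paths[2], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  s <- x$summary
  writeLines(c(
    sprintf("records\t%d", s$n_records),
    sprintf("calls\t%d", s$n_calls),
    sprintf("samples\t%d", s$n_samples),
    sprintf("%s\t%d", names(s$removed_by_reason), s$removed_by_reason)
  ), paths[3])
  invisible(paths)
}
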