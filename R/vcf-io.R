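#' Default ANNOVAR-style annotation schema
#'
#' Maps the semantic annotation fields the filters read onto VCF INFO keys.
#' The defaults follow ANNOVAR's refGene / gnomAD / avsnp / cosmic naming;
#' override any element to match a different annotator.
#'
#' @param gene,exonic_function,gnomad_af,dbsnp_id,cosmic_id INFO key names.
#' @return named list of INFO keys.
#' @export
annotation_schema <- function(gene = "Gene.refGene",
                              exonic_function = "ExonicFunc.refGene",
                              gnomad_af = "gnomAD_exome_AF",
                              dbsnp_id = "avsnp150",
                              cosmic_id = "cosmic70") {
  list(gene = gene, exonic_function = exonic_function,
       gnomad_af = gnomad_af, dbsnp_id = dbsnp_id, cosmic_id = cosmic_id)
}

#' Symmetric strand odds ratio (SOR)
#'
#' GATK-style strand-bias statistic. With a pseudocount of 1 added to every
#' count, let `r = (ref_fw * alt_rv) / (ref_rv * alt_fw)`. Then
#' `SOR = log(r + 1/r) + log(refRatio) - log(altRatio)` where each ratio is
#' the min/max of the (pseudocounted) per-allele strand counts. Balanced
#' strands give `log(2)`; an alternate allele seen predominantly on one
#' strand gives large values. Vectorized; `NA` counts yield `NA`.
#'
#' @param ref_fw,ref_rv reference-supporting reads, forward/reverse strand.
#' @param alt_fw,alt_rv alternate-supporting reads, forward/reverse strand.
#' @return non-negative numeric vector.
#' @examples
#' compute_sor(10, 10, 5, 5)   # log(2)
#' compute_sor(5, 5, 10, 0)    # strand-biased alt: ~4.8
#' @export
compute_sor <- function(ref_fw, ref_rv, alt_fw, alt_rv) {
  n <- max(length(ref_fw), length(ref_rv), length(alt_fw), length(alt_rv))
  rf <- rep_len(as.numeric(ref_fw), n); rv <- rep_len(as.numeric(ref_rv), n)
  af <- rep_len(as.numeric(alt_fw), n); ar <- rep_len(as.numeric(alt_rv), n)
  if (any(c(rf, rv, af, ar) < 0, na.rm = TRUE))
    stop("strand counts must be non-negative")
  rf <- rf + 1; rv <- rv + 1; af <- af + 1; ar <- ar + 1
  r <- (rf * ar) / (rv * af)
  sym <- r + 1 / r
  ref_ratio <- pmin(rf, rv) / pmax(rf, rv)
  alt_ratio <- pmin(af, ar) / pmax(af, ar)
  log(sym) + log(ref_ratio) - log(alt_ratio)
}

# pull one sample's values out of a readVcf geno entry that may be a
# plain matrix, a matrix of vectors, or a 3-d array
.geno_row_values <- function(g, i, si) {
  if (is.null(g)) return(NULL)
  if (length(dim(g)) == 3L) return(g[i, si, ])
  v <- g[i, si]
  if (is.list(v)) v[[1]] else v
}

.info_chr <- function(inf, key, i) {
  if (is.null(key) || !key %in% names(inf)) return(NA_character_)
  v <- inf[[key]][[i]]
  if (length(v) == 0L || all(is.na(v))) return(NA_character_)
  v <- as.character(v)[1]
  if (v %in% c(".", "")) NA_character_ else v
}

# ANNOVAR VCF output encodes spaces as underscores and a few reserved
# characters as \xNN escapes
.decode_annovar <- function(x) {
  x <- gsub("\\\\x3b", ";", x)
  x <- gsub("\\\\x3d", "=", x)
  gsub("_", " ", x)
}

#' Parse a single-sample somatic VCF into variant records
#'
#' Reads a VCF 4.x file (plain or bgzipped) through
#' [VariantAnnotation::readVcf()] and flattens it into the long record
#' format used by [cohort_table()]. Multi-allelic lines are split into one
#' record per alternate allele with per-allele AD. VAF is taken from FORMAT
#' `AF` when present, else computed as `alt_ad / dp`. Per-strand alternate
#' counts come from the FORMAT `SB` table (ref_fw, ref_rv, alt_fw, alt_rv)
#' when present; SOR is taken from INFO when present, else computed with
#' [compute_sor()] from the strand table. Records without a positive read
#' depth are skipped with one summary warning. Annotation fields named by
#' `schema` that are absent from the file are set missing, never fatal.
#'
#' @param path VCF file path.
#' @param sample_id identifier to stamp on the records.
#' @param tissue `"blood"` or `"paired"`.
#' @param schema [annotation_schema()] mapping.
#' @return data frame of variant records (canonical cohort columns).
#' @export
parse_vcf <- function(path, sample_id, tissue = c("blood", "paired"),
                      schema = annotation_schema()) {
  tissue <- match.arg(tissue)
  if (!file.exists(path)) stop("VCF file not found: ", path)
  vcf <- suppressWarnings(VariantAnnotation::readVcf(path))
  n <- nrow(vcf)
  if (n == 0L) {
    warning("no parseable variant lines in ", path)
    return(cohort_table(NULL))
  }
  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  refs <- as.character(VariantAnnotation::ref(vcf))
  alt_raw <- VariantAnnotation::alt(vcf)
  alt_list <- lapply(seq_len(n), function(i) as.character(alt_raw[[i]]))

  sn <- colnames(vcf)
  si <- 1L
  if (length(sn) > 1L) {
    hit <- match(sample_id, sn)
    if (!is.na(hit)) si <- hit
    else warning("multi-sample VCF ", path, ": using first sample column '",
                 sn[1], "'")
  }
  g <- VariantAnnotation::geno(vcf)
  inf <- VariantAnnotation::info(vcf)
  has <- function(k) k %in% names(g)

  out <- vector("list", n)
  n_skipped <- 0L
  for (i in seq_len(n)) {
    alts <- alt_list[[i]]
    nalt <- length(alts)
    if (nalt == 0L) next
    ad <- if (has("AD")) suppressWarnings(as.integer(.geno_row_values(g$AD, i, si))) else NULL
    dp <- if (has("DP")) suppressWarnings(as.integer(.geno_row_values(g$DP, i, si)[1])) else NA_integer_
    if (is.na(dp) && !is.null(ad)) dp <- sum(ad, na.rm = TRUE)
    if (is.na(dp) || dp <= 0L) { n_skipped <- n_skipped + nalt; next }
    af <- if (has("AF")) suppressWarnings(as.numeric(.geno_row_values(g$AF, i, si))) else NULL
    sb <- if (has("SB")) suppressWarnings(as.integer(.geno_row_values(g$SB, i, si))) else NULL
    if (!is.null(sb) && (length(sb) != 4L || anyNA(sb))) sb <- NULL
    sor_i <- if ("SOR" %in% names(inf)) suppressWarnings(as.numeric(inf$SOR[[i]][1])) else NA_real_
    if (is.na(sor_i) && !is.null(sb)) sor_i <- compute_sor(sb[1], sb[2], sb[3], sb[4])
    tlod_i <- if ("TLOD" %in% names(inf)) suppressWarnings(as.numeric(inf$TLOD[[i]])) else NA_real_

    alt_ad <- rep(NA_integer_, nalt)
    if (!is.null(ad) && length(ad) >= nalt + 1L) alt_ad <- ad[1L + seq_len(nalt)]
    vaf <- rep(NA_real_, nalt)
    if (!is.null(af)) vaf[seq_len(min(nalt, length(af)))] <- af[seq_len(min(nalt, length(af)))]
    vaf[is.na(vaf)] <- alt_ad[is.na(vaf)] / dp
    tl <- rep(NA_real_, nalt)
    if (!all(is.na(tlod_i))) tl[seq_len(min(nalt, length(tlod_i)))] <-
      tlod_i[seq_len(min(nalt, length(tlod_i)))]

    out[[i]] <- data.frame(
      sample_id = sample_id, tissue = tissue, chrom = chrom[i], pos = pos[i],
      ref = refs[i], alt = alts,
      vaf = vaf, dp = dp, alt_ad = alt_ad,
      saf = if (is.null(sb)) NA_integer_ else sb[3],
      sar = if (is.null(sb)) NA_integer_ else sb[4],
      ref_fw = if (is.null(sb)) NA_integer_ else sb[1],
      ref_rv = if (is.null(sb)) NA_integer_ else sb[2],
      sor = sor_i, tlod = tl,
      gene = .info_chr(inf, schema$gene, i),
      exonic_function = {
        v <- .info_chr(inf, schema$exonic_function, i)
        if (is.na(v)) v else .decode_annovar(v)
      },
      gnomad_af = suppressWarnings(as.numeric(.info_chr(inf, schema$gnomad_af, i))),
      dbsnp_id = .info_chr(inf, schema$dbsnp_id, i),
      cosmic_id = .info_chr(inf, schema$cosmic_id, i),
      in_repeat_region = NA,
      stringsAsFactors = FALSE
    )
  }
  if (n_skipped > 0L)
    warning(n_skipped, " allele record(s) in ", basename(path),
            " skipped: no positive read depth")
  rec <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(rec)) return(cohort_table(NULL))
  rownames(rec) <- NULL
  rec
}

#' Read a sample sheet
#'
#' Tab-separated with header columns `sample_id`, `blood_vcf` and optional
#' `paired_vcf`. Empty or `NA` paired entries mean no paired sample.
#'
#' @param path sample sheet path.
#' @return data frame with columns sample_id, blood_vcf, paired_vcf.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop("sample sheet not found: ", path)
  sh <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, comment.char = "#",
                          na.strings = c("NA", ""))
  need <- c("sample_id", "blood_vcf")
  miss <- setdiff(need, names(sh))
  if (length(miss) > 0L)
    stop("sample sheet lacks column(s): ", paste(miss, collapse = ", "))
  if (!"paired_vcf" %in% names(sh)) sh$paired_vcf <- NA_character_
  bad <- which(is.na(sh$sample_id) | is.na(sh$blood_vcf))
  if (length(bad) > 0L)
    stop("malformed sample sheet row(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(sh$sample_id))
    stop("duplicate sample_id in sample sheet")
  sh[, c("sample_id", "blood_vcf", "paired_vcf")]
}

#' Build a cohort table from a sample sheet of VCFs
#'
#' The `vcf2input` step: parses each sample's blood VCF (and paired VCF when
#' given), streaming one sample at a time, and merges the records into one
#' [cohort_table()]. Paired records are stored under the blood sample id
#' with `tissue == "paired"`.
#'
#' @param sample_sheet path to a sample sheet, or a data frame as returned
#'   by [read_sample_sheet()].
#' @param schema [annotation_schema()] mapping.
#' @param out optional path; when given the table is also written with
#'   [write_cohort_table()].
#' @return a [cohort_table()].
#' @export
vcf2input <- function(sample_sheet, schema = annotation_schema(), out = NULL) {
  sh <- if (is.data.frame(sample_sheet)) sample_sheet else read_sample_sheet(sample_sheet)
  recs <- vector("list", nrow(sh))
  pm <- character()
  for (i in seq_len(nrow(sh))) {
    r <- parse_vcf(sh$blood_vcf[i], sh$sample_id[i], "blood", schema)
    if (!is.na(sh$paired_vcf[i])) {
      p <- parse_vcf(sh$paired_vcf[i], sh$sample_id[i], "paired", schema)
      r <- rbind(as.data.frame(r), as.data.frame(p))
      pm[sh$sample_id[i]] <- sh$sample_id[i]
    }
    recs[[i]] <- r
  }
  tab <- merge_cohort(recs, paired_map = if (length(pm)) pm else NULL,
                      sample_ids = sh$sample_id)
  if (!is.null(out)) write_cohort_table(tab, out)
  tab
}

#' Flag records falling in repeat regions
#'
#' Overlaps record positions with a repeat mask (BED, 0-based half-open, or
#' any file [rtracklayer::import()] understands, or a `GRanges`) and sets
#' the `in_repeat_region` annotation.
#'
#' @param table a [cohort_table()].
#' @param mask BED file path or `GRanges`.
#' @return the table with `in_repeat_region` filled in (TRUE/FALSE).
#' @export
flag_repeat_regions <- function(table, mask) {
  if (is.character(mask)) mask <- rtracklayer::import(mask)
  gr <- GenomicRanges::GRanges(table$chrom,
                               IRanges::IRanges(table$pos, width = nchar(table$ref)))
  hit <- GenomicRanges::countOverlaps(gr, mask, ignore.strand = TRUE) > 0L
  table$in_repeat_region <- hit
  table
}
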