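#' @keywords internal
".COHORT_COLS" <- c(
  "sample_id", "tissue", "chrom", "pos", "ref", "alt",
  "vaf", "dp", "alt_ad", "saf", "sar", "ref_fw", "ref_rv",
  "sor", "tlod",
  "gene", "exonic_function", "gnomad_af", "dbsnp_id", "cosmic_id",
  "in_repeat_region"
)

# column type templates used when building/reading tables
.cohort_prototype <- function() {
  data.frame(
    sample_id = character(), tissue = character(), chrom = character(),
    pos = integer(), ref = character(), alt = character(),
    vaf = numeric(), dp = integer(), alt_ad = integer(),
    saf = integer(), sar = integer(), ref_fw = integer(), ref_rv = integer(),
    sor = numeric(), tlod = numeric(),
    gene = character(), exonic_function = character(),
    gnomad_af = numeric(), dbsnp_id = character(), cosmic_id = character(),
    in_repeat_region = logical(),
    stringsAsFactors = FALSE
  )
}

#' Construct a cohort table
#'
#' The cohort table is the long-format merge of per-sample variant records:
#' one row per (sample, tissue, chrom, pos, ref, alt). It carries two
#' attributes: `sample_ids`, the ordered set of blood sample identifiers
#' defining the cohort (and the denominator of every prevalence), and
#' `paired_map`, a named character vector mapping blood sample ids to the
#' identifier under which their paired (non-blood) records are stored.
#'
#' @param records data frame with (a superset of) the canonical columns;
#'   missing optional columns are added as `NA`.
#' @param sample_ids ordered character vector of blood sample ids. Defaults
#'   to the blood samples present in `records`.
#' @param paired_map named character vector (names = blood ids); may be
#'   `NULL` when no paired data exist.
#' @return a `data.frame` of class `cohort_table`.
#' @export
cohort_table <- function(records, sample_ids = NULL, paired_map = NULL) {
  proto <- .cohort_prototype()
  if (is.null(records) || nrow(records) == 0L) {
    records <- proto
  } else {
    records <- as.data.frame(records, stringsAsFactors = FALSE)
    miss <- setdiff(.COHORT_COLS, names(records))
    for (m in miss) records[[m]] <- proto[[m]][NA_integer_][seq_len(nrow(records))]
    records <- records[, .COHORT_COLS]
    records$pos <- as.integer(records$pos)
    records$dp <- as.integer(records$dp)
    for (cc in c("alt_ad", "saf", "sar", "ref_fw", "ref_rv"))
      records[[cc]] <- as.integer(records[[cc]])
    for (cc in c("vaf", "sor", "tlod", "gnomad_af"))
      records[[cc]] <- as.numeric(records[[cc]])
    records$in_repeat_region <- as.logical(records$in_repeat_region)
  }
  if (is.null(sample_ids)) {
    sample_ids <- unique(records$sample_id[records$tissue == "blood"])
  }
  stopifnot(!anyDuplicated(sample_ids))
  if (!is.null(paired_map)) {
    if (is.null(names(paired_map))) names(paired_map) <- paired_map
    bad <- setdiff(names(paired_map), sample_ids)
    if (length(bad) > 0L)
      stop("paired_map refers to unknown blood samples: ",
           paste(bad, collapse = ", "))
  }
  rownames(records) <- NULL
  structure(records,
            sample_ids = as.character(sample_ids),
            paired_map = paired_map,
            class = c("cohort_table", "data.frame"))
}

#' @export
print.cohort_table <- function(x, ...) {
  sid <- attr(x, "sample_ids")
  pm <- attr(x, "paired_map")
  cat(sprintf("cohort_table: %d records, %d blood samples, %d paired\n",
              nrow(x), length(sid), length(pm)))
  cat(sprintf("  tissues: %s\n",
              paste(sprintf("%s=%d", names(table(x$tissue)), table(x$tissue)),
                    collapse = ", ")))
  if (nrow(x) > 0L) {
    utils::str(utils::head(as.data.frame(x), 3), give.attr = FALSE)
  }
  invisible(x)
}

# keys ------------------------------------------------------------------

.variant_key <- function(df) paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")
.locus_key <- function(df) paste(df$chrom, df$pos, sep = ":")
.call_key <- function(df) paste(df$sample_id, .variant_key(df), sep = "|")
.blood_rows <- function(table) table[table$tissue == "blood", , drop = FALSE]

#' Merge per-sample record collections into one cohort table
#'
#' Duplicate (sample, tissue, variant) entries collapse to the record with
#' the highest read depth; ties keep the first encountered (logged). The
#' same (sample, tissue) supplied in more than one input element is a
#' configuration error, as it usually indicates a sample-sheet mistake.
#'
#' @param per_sample_records list of record data frames (e.g. from
#'   [parse_vcf()]).
#' @param paired_map named character vector mapping blood sample ids to the
#'   sample id carrying their `tissue == "paired"` records.
#' @param sample_ids optional explicit cohort definition (ordered blood
#'   sample ids); samples without records are then still counted in
#'   prevalence denominators.
#' @return a [cohort_table()].
#' @export
merge_cohort <- function(per_sample_records, paired_map = NULL,
                         sample_ids = NULL) {
  if (is.data.frame(per_sample_records))
    per_sample_records <- list(per_sample_records)
  combos <- lapply(per_sample_records, function(d)
    unique(paste(d$sample_id, d$tissue)))
  dup <- unlist(combos)[duplicated(unlist(combos))]
  if (length(dup) > 0L)
    stop("duplicate sample_id across inputs: ", paste(unique(dup), collapse = ", "))
  rec <- do.call(rbind, lapply(per_sample_records, function(d)
    cohort_table(d)[, , drop = FALSE]))
  rec <- as.data.frame(rec, stringsAsFactors = FALSE)
  if (nrow(rec) > 0L) {
    key <- paste(rec$sample_id, rec$tissue, .variant_key(rec), sep = "\r")
    ord <- order(factor(key, levels = unique(key)), -rec$dp)
    rec <- rec[ord, , drop = FALSE]
    dups <- duplicated(paste(rec$sample_id, rec$tissue, .variant_key(rec), sep = "\r"))
    if (any(dups)) {
      message(sum(dups), " duplicate (sample, tissue, variant) record(s) collapsed",
              " to the highest-depth entry")
      rec <- rec[!dups, , drop = FALSE]
    }
  }
  cohort_table(rec, sample_ids = sample_ids, paired_map = paired_map)
}

# TSV snapshot ----------------------------------------------------------

.fmt_col <- function(x) {
  if (is.double(x)) {
    out <- sprintf("%.17g", x)
    out[is.na(x)] <- "NA"
    out
  } else if (is.logical(x)) {
    ifelse(is.na(x), "NA", ifelse(x, "TRUE", "FALSE"))
  } else {
    out <- as.character(x)
    out[is.na(x)] <- "NA"
    out
  }
}

#' Write / read a cohort table TSV snapshot
#'
#' The snapshot lets large cohorts skip re-parsing VCFs. Metadata
#' (`sample_ids`, `paired_map`) ride in `#`-prefixed header lines; the
#' column header line also starts with `#`. Round-tripping is exact:
#' doubles are serialized with 17 significant digits.
#'
#' @param table a [cohort_table()].
#' @param path output / input file path.
#' @return `write_cohort_table` returns `path` invisibly;
#'   `read_cohort_table` returns a [cohort_table()].
#' @export
write_cohort_table <- function(table, path) {
  stopifnot(inherits(table, "cohort_table"))
  sid <- attr(table, "sample_ids")
  pm <- attr(table, "paired_map")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#chcohort cohort_table v1", con)
  writeLines(paste0("#sample_ids=", paste(sid, collapse = ",")), con)
  if (length(pm) > 0L)
    writeLines(paste0("#paired_map=",
                      paste(names(pm), pm, sep = ":", collapse = ",")), con)
  writeLines(paste0("#", paste(.COHORT_COLS, collapse = "\t")), con)
  if (nrow(table) > 0L) {
    cols <- lapply(as.data.frame(table)[, .COHORT_COLS], .fmt_col)
    writeLines(do.call(paste, c(cols, sep = "\t")), con)
  }
  invisible(path)
}

#' @rdname write_cohort_table
#' @export
read_cohort_table <- function(path) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  get_meta <- function(key) {
    hit <- meta[startsWith(meta, paste0("#", key, "="))]
    if (length(hit) == 0L) return(NULL)
    sub(paste0("^#", key, "="), "", hit[1])
  }
  sid <- get_meta("sample_ids")
  sid <- if (is.null(sid) || sid == "") character() else strsplit(sid, ",")[[1]]
  pm_raw <- get_meta("paired_map")
  pm <- NULL
  if (!is.null(pm_raw) && nzchar(pm_raw)) {
    parts <- strsplit(strsplit(pm_raw, ",")[[1]], ":")
    pm <- vapply(parts, `[`, "", 2)
    names(pm) <- vapply(parts, `[`, "", 1)
  }
  if (length(body) == 0L)
    return(cohort_table(NULL, sample_ids = sid, paired_map = pm))
  df <- utils::read.table(text = body, sep = "\t", header = FALSE,
                          col.names = .COHORT_COLS, na.strings = "NA",
                          colClasses = c(
                            sample_id = "character", tissue = "character",
                            chrom = "character", pos = "integer",
                            ref = "character", alt = "character",
                            vaf = "numeric", dp = "integer", alt_ad = "integer",
                            saf = "integer", sar = "integer",
                            ref_fw = "integer", ref_rv = "integer",
                            sor = "numeric", tlod = "numeric",
                            gene = "character", exonic_function = "character",
                            gnomad_af = "numeric", dbsnp_id = "character",
                            cosmic_id = "character",
                            in_repeat_region = "logical"),
                          quote = "", comment.char = "")
  cohort_table(df, sample_ids = sid, paired_map = pm)
}
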