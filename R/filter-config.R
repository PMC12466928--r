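.DEFAULT_KEEP_EFFECTS <- c(
  "nonsynonymous SNV", "stopgain", "stoploss",
  "frameshift insertion", "frameshift deletion",
  "nonframeshift insertion", "nonframeshift deletion",
  "splicing"
)

#' Filter configuration
#'
#' Every tunable threshold of the four filter tiers, with its comparator
#' semantics. Comparators (boundary behaviour is deliberate and mixed):
#' \itemize{
#'  \item VAF passes iff `vaf_min <= vaf <= vaf_max` (equality passes);
#'  \item depth passes iff `dp > dp_min` (strict, the conventional "DP > 20");
#'  \item `alt_ad >= alt_ad_min`, `saf >= saf_min`, `sar >= sar_min`,
#'        `sor <= sor_max`, `tlod >= tlod_min`;
#'  \item a variant is removed cohort-wide iff its allele- or locus-level
#'        cohort prevalence is strictly greater than `prevalence_max`;
#'  \item `gnomad_af > gnomad_max` marks a likely germline database variant.
#' }
#' A missing metric passes its criterion (inputs from arbitrary callers may
#' lack SB/SOR/TLOD); such passes are counted in the run summary.
#'
#' @param vaf_min,vaf_max VAF window (defaults 0.02 and 0.35).
#' @param dp_min strict depth cutoff (default 20).
#' @param alt_ad_min minimum alternate allele depth (default 5).
#' @param saf_min,sar_min minimum alt reads per strand (default 3 each).
#' @param sor_max maximum strand odds ratio (default 3.0).
#' @param tlod_min minimum tumor log-odds (default 6.3).
#' @param prevalence_max cohort prevalence ceiling (default 0.10).
#' @param gnomad_max gnomAD allele-frequency ceiling (default 0.001).
#' @param keep_effects exonic functions considered CH-relevant.
#' @param paired_alpha one-sided significance level of the paired
#'   blood-vs-tumor enrichment test (default 0.05).
#' @param mode `"single"` or `"paired"`.
#' @param gene_allowlist optional character vector; when set, records in
#'   other genes are removed (reason EFFECT). Off (`NULL`) by default.
#' @return object of class `filter_config`.
#' @export
filter_config <- function(vaf_min = 0.02, vaf_max = 0.35,
                          dp_min = 20L, alt_ad_min = 5L,
                          saf_min = 3L, sar_min = 3L,
                          sor_max = 3.0, tlod_min = 6.3,
                          prevalence_max = 0.10, gnomad_max = 0.001,
                          keep_effects = .DEFAULT_KEEP_EFFECTS,
                          paired_alpha = 0.05,
                          mode = c("single", "paired"),
                          gene_allowlist = NULL) {
  mode <- match.arg(mode)
  cfg <- list(vaf_min = as.numeric(vaf_min), vaf_max = as.numeric(vaf_max),
              dp_min = as.numeric(dp_min), alt_ad_min = as.numeric(alt_ad_min),
              saf_min = as.numeric(saf_min), sar_min = as.numeric(sar_min),
              sor_max = as.numeric(sor_max), tlod_min = as.numeric(tlod_min),
              prevalence_max = as.numeric(prevalence_max),
              gnomad_max = as.numeric(gnomad_max),
              keep_effects = as.character(keep_effects),
              paired_alpha = as.numeric(paired_alpha),
              mode = mode, gene_allowlist = gene_allowlist)
  .validate_config(cfg)
  structure(cfg, class = "filter_config")
}

.validate_config <- function(cfg) {
  with(cfg, {
    if (!(vaf_min >= 0 && vaf_min < vaf_max && vaf_max <= 1))
      stop("need 0 <= vaf_min < vaf_max <= 1")
    if (any(c(dp_min, alt_ad_min, saf_min, sar_min) < 0))
      stop("count thresholds must be >= 0")
    if (sor_max < 0) stop("sor_max must be >= 0")
    if (!(prevalence_max >= 0 && prevalence_max <= 1))
      stop("prevalence_max must be in [0, 1]")
    if (!(gnomad_max >= 0 && gnomad_max <= 1))
      stop("gnomad_max must be in [0, 1]")
    if (!(paired_alpha > 0 && paired_alpha < 1))
      stop("paired_alpha must be in (0, 1)")
  })
  invisible(cfg)
}

#' @export
print.filter_config <- function(x, ...) {
  cat("chcohort filter_config (mode:", x$mode, ")\n")
  num <- c("vaf_min", "vaf_max", "dp_min", "alt_ad_min", "saf_min", "sar_min",
           "sor_max", "tlod_min", "prevalence_max", "gnomad_max", "paired_alpha")
  for (k in num) cat(sprintf("  %-15s %s\n", k, format(x[[k]])))
  cat("  keep_effects   ", paste(x$keep_effects, collapse = "; "), "\n")
  if (!is.null(x$gene_allowlist))
    cat("  gene_allowlist ", paste(x$gene_allowlist, collapse = ","), "\n")
  invisible(x)
}

#' Read a flat key-value configuration file
#'
#' One `key = value` pair per line; `#` starts a comment. Every
#' [filter_config()] field is addressable by name; `keep_effects` and
#' `gene_allowlist` take comma-separated lists. An unknown key is an error
#' (never silently ignored).
#'
#' @param path config file path.
#' @param base configuration supplying values for keys the file omits.
#' @return a [filter_config()].
#' @export
read_filter_config <- function(path, base = filter_config()) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  known <- names(base)
  vals <- as.list(base)
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) stop("malformed config line: '", ln, "'")
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (!key %in% known)
      stop("unknown configuration key: '", key, "'")
    vals[[key]] <- switch(key,
      keep_effects = ,
      gene_allowlist = trimws(strsplit(val, ",")[[1]]),
      mode = val,
      as.numeric(val))
  }
  do.call(filter_config, vals)
}

# set the parameter addressed by a scan metric; SAFSAR moves both strand
# minima jointly
.set_param <- function(config, metric, value) {
  switch(metric,
    VAF = { config$vaf_min <- value },
    PREVALENCE = { config$prevalence_max <- value },
    DP = { config$dp_min <- value },
    SOR = { config$sor_max <- value },
    SAFSAR = { config$saf_min <- value; config$sar_min <- value },
    stop("unknown metric: ", metric))
  .validate_config(config)
  config
}
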