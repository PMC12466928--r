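#' Permutation scan plan
#'
#' Describes one parameter scan: the metric, its candidate grid, the subset
#' proportions, and the number of permutations per proportion. Default
#' grids: VAF 0 to 0.1 by 0.005; PREVALENCE 0 to 0.15 by 0.01; DP 0 to 50
#' by 5; SOR 0.5 to 6 by 0.5; SAFSAR 0 to 10 by 1. Default proportions are
#' 1/2, 1/3, ..., 1/10 of the cohort.
#'
#' @param metric one of `"VAF"`, `"PREVALENCE"`, `"DP"`, `"SOR"`,
#'   `"SAFSAR"` (the latter sets the forward- and reverse-strand minima
#'   jointly).
#' @param grid strictly increasing candidate values; `NULL` for the
#'   metric's default.
#' @param proportions subset proportions in `(0, 1]`.
#' @param n_perm permutations per proportion (>= 1).
#' @param seed integer seed; the whole scan is reproducible from it.
#' @return object of class `permutation_plan`.
#' @export
permutation_plan <- function(metric = c("VAF", "PREVALENCE", "DP", "SOR", "SAFSAR"),
                             grid = NULL, proportions = 1 / (2:10),
                             n_perm = 100L, seed = 1L) {
  metric <- match.arg(metric)
  if (is.null(grid)) {
    grid <- switch(metric,
      VAF = seq(0, 0.1, by = 0.005),
      PREVALENCE = seq(0, 0.15, by = 0.01),
      DP = seq(0, 50, by = 5),
      SOR = seq(0.5, 6, by = 0.5),
      SAFSAR = 0:10)
  }
  grid <- as.numeric(grid)
  if (length(grid) < 1L || any(diff(grid) <= 0))
    stop("grid must be strictly increasing")
  proportions <- as.numeric(proportions)
  if (any(proportions <= 0 | proportions > 1))
    stop("proportions must lie in (0, 1]")
  if (n_perm < 1L) stop("n_perm must be >= 1")
  structure(list(metric = metric, grid = grid, proportions = proportions,
                 n_perm = as.integer(n_perm), seed = as.integer(seed)),
            class = "permutation_plan")
}

.validate_grid <- function(metric, grid, base_config) {
  ok <- switch(metric,
    VAF = all(grid >= 0 & grid < base_config$vaf_max),
    PREVALENCE = all(grid >= 0 & grid <= 1),
    DP = all(grid >= 0),
    SOR = all(grid >= 0),
    SAFSAR = all(grid >= 0))
  if (!ok)
    stop("grid value outside the legal range of parameter ", metric)
  invisible(TRUE)
}

# run code under a temporary seed, restoring the caller's RNG state
.with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  force(code)
}

# one deterministic stream per (proportion index, permutation index),
# independent of the scanned grid value so the same partitions are reused
# across the grid (common random numbers)
.derive_seed <- function(seed, p_i, r) {
  as.integer((as.double(seed) * 97 + p_i * 100003 + r * 1009) %% 2147483647L)
}

#' Randomly partition the cohort into disjoint subsets
#'
#' Partitions all `N` samples into `k = round(1 / proportion)` subsets of
#' size `floor(N/k)` or `ceiling(N/k)` (the remainder spread one per
#' subset), uniformly at random using the current RNG stream.
#'
#' @param sample_ids cohort sample identifiers.
#' @param proportion target subset proportion; `1` yields the full cohort
#'   as a single subset.
#' @return list of `k` disjoint character vectors whose union is the
#'   cohort.
#' @export
make_partition <- function(sample_ids, proportion) {
  k <- max(1L, as.integer(round(1 / proportion)))
  N <- length(sample_ids)
  if (N < k) stop("cohort of ", N, " samples cannot form ", k, " subsets")
  shuffled <- sample(sample_ids, N)
  sizes <- rep(N %/% k, k)
  rem <- N - sum(sizes)
  if (rem > 0L) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  split(shuffled, rep(seq_len(k), times = sizes))
}

#' Consistency between full-cohort and pooled subset calls
#'
#' Set statistics over (sample, variant) call keys: the fraction of
#' full-cohort calls also present in the pooled subset calls
#' (`common_fraction`), and the two unique fractions. Empty denominators
#' follow the convention (1, 0, 0).
#'
#' @param full_calls,pooled_calls character vectors of call keys.
#' @return list with `common_fraction`, `unique_full_fraction`,
#'   `unique_pooled_fraction`.
#' @export
consistency <- function(full_calls, pooled_calls) {
  full <- unique(full_calls)
  pooled <- unique(pooled_calls)
  n_full <- length(full)
  n_pooled <- length(pooled)
  n_common <- sum(full %in% pooled)
  list(
    common_fraction = if (n_full == 0L) 1 else n_common / n_full,
    unique_full_fraction = if (n_full == 0L) 0 else
      (n_full - n_common) / n_full,
    unique_pooled_fraction = if (n_pooled == 0L) 0 else
      (n_pooled - n_common) / n_pooled
  )
}

#' Precision and recall of a call set against a curated truth set
#'
#' @param calls character vector of call keys (`sample|chrom:pos:ref:alt`).
#' @param truth character vector of curated truth keys, or a data frame
#'   with columns sample_id, chrom, pos, ref, alt.
#' @return named numeric vector `c(precision, recall)`; empty calls give
#'   precision 1, empty truth gives recall 1.
#' @export
precision_recall <- function(calls, truth) {
  if (is.data.frame(truth)) truth <- truth_keys(truth)
  calls <- unique(calls)
  truth <- unique(truth)
  tp <- sum(calls %in% truth)
  c(precision = if (length(calls) == 0L) 1 else tp / length(calls),
    recall = if (length(truth) == 0L) 1 else tp / length(truth))
}

#' Read a curated CH truth table
#'
#' Tab-separated with header columns sample_id, chrom, pos, ref, alt.
#'
#' @param path file path.
#' @return data frame.
#' @export
read_truth <- function(path) {
  tr <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, comment.char = "#")
  need <- c("sample_id", "chrom", "pos", "ref", "alt")
  miss <- setdiff(need, names(tr))
  if (length(miss) > 0L)
    stop("truth table lacks column(s): ", paste(miss, collapse = ", "))
  tr
}

#' @rdname read_truth
#' @param truth data frame with sample_id, chrom, pos, ref, alt.
#' @export
truth_keys <- function(truth) {
  paste(truth$sample_id,
        paste(truth$chrom, truth$pos, truth$ref, truth$alt, sep = ":"),
        sep = "|")
}

#' Saturation (inflection) point of a consistency curve
#'
#' The plateau method (default) returns the smallest grid value whose mean
#' consistency reaches `(1 - epsilon)` times the curve maximum; the
#' curvature method returns the interior grid value maximizing the negative
#' second central difference. Ties break to the smallest grid value. The
#' result carries attribute `saturated = FALSE` when only the final grid
#' point qualifies (no saturation before the end of the grid).
#'
#' @param grid strictly increasing grid values (>= 3 points).
#' @param means mean consistency at each grid value.
#' @param method `"plateau"` or `"curvature"`.
#' @param epsilon plateau tolerance (default 0.02).
#' @return the selected grid value, with attribute `saturated`.
#' @export
detect_inflection <- function(grid, means, method = c("plateau", "curvature"),
                              epsilon = 0.02) {
  method <- match.arg(method)
  if (length(grid) < 3L || length(means) != length(grid))
    stop("need >= 3 (grid, mean) pairs")
  if (method == "plateau") {
    thr <- (1 - epsilon) * max(means)
    idx <- which(means >= thr)[1]
    structure(grid[idx], saturated = idx < length(grid))
  } else {
    inner <- 2:(length(grid) - 1L)
    # second central difference; the knee is its most negative point
    d2 <- means[inner - 1L] - 2 * means[inner] + means[inner + 1L]
    idx <- inner[which.max(-d2)]
    structure(grid[idx], saturated = TRUE)
  }
}

#' Permutation scan of one filter parameter
#'
#' For each candidate value of the scanned parameter, calls CH on the full
#' cohort, then — for each subset proportion and permutation — partitions
#' the cohort into disjoint subsets, runs the filter independently within
#' each subset (cohort prevalence recomputed inside the subset), pools the
#' union of subset calls, and records the consistency of full-cohort calls
#' with the pool. The same partitions are reused across grid values
#' (common random numbers), so curves differ only through the parameter.
#' When a truth set is supplied, precision and recall of the full-cohort
#' calls are reported per grid value. Deterministic given inputs and
#' `plan$seed`.
#'
#' @param table a [cohort_table()].
#' @param base_config a [filter_config()] fixing all non-scanned
#'   parameters.
#' @param plan a [permutation_plan()].
#' @param truth optional curated truth (data frame or key vector), see
#'   [precision_recall()].
#' @param pool `"partition"` (default: pooled calls are the union over all
#'   subsets of the partition) or `"single_subset"` (only the first subset
#'   is used and the comparison is restricted to its samples).
#' @return object of class `consistency_curve`: long results table
#'   (`$table`), per-proportion inflection values (`$inflection`), and the
#'   full-cohort call counts per grid value (`$full_calls`).
#' @export
permutation_scan <- function(table, base_config = filter_config(), plan,
                             truth = NULL, pool = c("partition", "single_subset")) {
  pool <- match.arg(pool)
  stopifnot(inherits(plan, "permutation_plan"))
  if (!inherits(table, "cohort_table")) table <- cohort_table(table)
  blood <- .blood_rows(table)
  if (nrow(blood) == 0L) stop("empty cohort table")
  sids <- attr(table, "sample_ids")
  N <- length(sids)
  metric <- plan$metric
  grid <- plan$grid
  J <- length(grid)
  .validate_grid(metric, grid, base_config)
  for (p in plan$proportions)
    if (N < max(1L, as.integer(round(1 / p))))
      stop("cohort too small for proportion ", format(p))

  pc <- .prevalence_counts(blood)
  keys <- .call_key(blood)
  ps <- if (base_config$mode == "paired") .paired_stats(table, blood) else NULL
  nonpop_for <- function(cfg) {
    m <- cbind(.fail_technical(blood, cfg), .fail_functional(blood, cfg))
    if (!is.null(ps)) m <- cbind(m, .fail_paired(blood, ps, cfg))
    rowSums(m) > 0L
  }
  nonpop <- matrix(FALSE, nrow(blood), J)
  if (metric == "PREVALENCE") {
    base_mask <- nonpop_for(base_config)
    for (j in seq_len(J)) nonpop[, j] <- base_mask
  } else {
    for (j in seq_len(J))
      nonpop[, j] <- nonpop_for(.set_param(base_config, metric, grid[j]))
  }
  cutoffs <- if (metric == "PREVALENCE") grid else
    rep(base_config$prevalence_max, J)
  full_popfail <- vapply(cutoffs, function(cu)
    pc$allele / N > cu | pc$locus / N > cu, logical(nrow(blood)))
  full_keep <- !nonpop & !full_popfail

  pr <- NULL
  if (!is.null(truth)) {
    tk <- if (is.data.frame(truth)) truth_keys(truth) else truth
    pr <- t(vapply(seq_len(J), function(j)
      precision_recall(keys[full_keep[, j]], tk), c(precision = 0, recall = 0)))
  }

  P <- length(plan$proportions)
  ul <- !duplicated(paste(blood$sample_id, pc$lk, sep = "\r"))
  common <- array(NA_real_, c(P, J, plan$n_perm))
  for (p_i in seq_len(P)) {
    p <- plan$proportions[p_i]
    for (r in seq_len(plan$n_perm)) {
      part <- .with_seed(.derive_seed(plan$seed, p_i, r),
                         make_partition(sids, p))
      assign_id <- rep(seq_along(part), times = lengths(part))
      names(assign_id) <- unlist(part)
      sizes <- lengths(part)
      sid_row <- assign_id[blood$sample_id]
      ssz <- sizes[sid_row]
      grp_a <- paste(pc$vk, sid_row, sep = "\r")
      ca <- stats::ave(seq_along(grp_a), grp_a, FUN = length)
      grp_l <- paste(pc$lk, sid_row, sep = "\r")
      ltab <- table(grp_l[ul])
      cl <- as.integer(ltab[grp_l])
      use <- if (pool == "single_subset") sid_row == 1L else
        rep(TRUE, nrow(blood))
      for (j in seq_len(J)) {
        subfail <- ca / ssz > cutoffs[j] | cl / ssz > cutoffs[j]
        pooled_keep <- !nonpop[, j] & !subfail
        nf <- sum(full_keep[use, j])
        common[p_i, j, r] <- if (nf == 0L) 1 else
          sum(full_keep[use, j] & pooled_keep[use]) / nf
      }
    }
  }

  means <- apply(common, c(1, 2), mean)
  sds <- apply(common, c(1, 2), stats::sd)
  infl <- data.frame(
    proportion = plan$proportions,
    inflection = NA_real_, saturated = NA)
  if (J >= 3L) {
    for (p_i in seq_len(P)) {
      v <- detect_inflection(grid, means[p_i, ])
      infl$inflection[p_i] <- as.numeric(v)
      infl$saturated[p_i] <- attr(v, "saturated")
    }
  }
  long <- data.frame(
    metric = metric,
    grid_value = rep(grid, each = P),
    proportion = rep(plan$proportions, times = J),
    mean_consistency = as.vector(means),
    sd_consistency = as.vector(sds),
    n_perm = plan$n_perm,
    precision = if (is.null(pr)) NA_real_ else rep(pr[, "precision"], each = P),
    recall = if (is.null(pr)) NA_real_ else rep(pr[, "recall"], each = P),
    stringsAsFactors = FALSE)
  long$inflection_flag <- !is.na(infl$inflection[match(long$proportion,
                                                       infl$proportion)]) &
    long$grid_value == infl$inflection[match(long$proportion, infl$proportion)]
  structure(list(
    metric = metric, grid = grid, proportions = plan$proportions,
    n_perm = plan$n_perm, seed = plan$seed, pool = pool,
    table = long, inflection = infl,
    full_calls = data.frame(grid_value = grid, n_calls = colSums(full_keep),
                            precision = if (is.null(pr)) NA_real_ else pr[, "precision"],
                            recall = if (is.null(pr)) NA_real_ else pr[, "recall"])
  ), class = "consistency_curve")
}

#' @export
print.consistency_curve <- function(x, ...) {
  cat(sprintf("consistency_curve: %s scan, %d grid values x %d proportions, %d permutations (seed %d)\n",
              x$metric, length(x$grid), length(x$proportions), x$n_perm, x$seed))
  cat("inflection (plateau) per proportion:\n")
  print(x$inflection, row.names = FALSE)
  invisible(x)
}

#' Plot a consistency curve
#'
#' Mean permutation consistency against the scanned parameter, one line
#' per subset proportion, with the per-proportion plateau inflection marked.
#'
#' @param x a `consistency_curve`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.consistency_curve <- function(x, ...) {
  m <- matrix(x$table$mean_consistency, nrow = length(x$proportions))
  graphics::matplot(x$grid, t(m), type = "b", pch = 16, lty = 1,
                    xlab = x$metric, ylab = "mean consistency",
                    main = sprintf("%s permutation scan (n_perm = %d)",
                                   x$metric, x$n_perm), ...)
  ok <- !is.na(x$inflection$inflection)
  if (any(ok))
    graphics::abline(v = unique(x$inflection$inflection[ok]), lty = 3)
  graphics::legend("bottomright",
                   legend = sprintf("1/%d", round(1 / x$proportions)),
                   col = seq_along(x$proportions), pch = 16, lty = 1,
                   title = "subset", bty = "n")
  invisible(x)
}

#' Write a scan result table
#'
#' Long-format TSV: metric, grid value, proportion, mean and sd of
#' consistency, n_perm, precision, recall, inflection flag.
#'
#' @param curve a `consistency_curve`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scan <- function(curve, path) {
  stopifnot(inherits(curve, "consistency_curve"))
  utils::write.table(curve$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
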