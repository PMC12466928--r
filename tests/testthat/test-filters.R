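make_blood <- function(sample_id, pos, ref = "A", alt = "T", vaf = 0.05,
                       dp = 100L, alt_ad = 5L, saf = 3L, sar = 3L,
                       sor = 1, tlod = 20, ...) {
  data.frame(sample_id = sample_id, tissue = "blood", chrom = "chr1",
             pos = as.integer(pos), ref = ref, alt = alt, vaf = vaf,
             dp = as.integer(dp), alt_ad = as.integer(alt_ad),
             saf = as.integer(saf), sar = as.integer(sar),
             sor = sor, tlod = tlod, ..., stringsAsFactors = FALSE)
}

test_that("filter_config validates its invariants", {
  expect_error(filter_config(vaf_min = 0.5, vaf_max = 0.3), "vaf_min")
  expect_error(filter_config(alt_ad_min = -1), ">= 0")
  expect_error(filter_config(paired_alpha = 1.2), "paired_alpha")
  expect_silent(filter_config(vaf_min = 0, prevalence_max = 1))
})

test_that("population prevalence removes by allele and locus with a strict boundary", {
  # 10-sample cohort; variant in 3 samples: prevalence 0.30 > 0.10 -> removed
  sids <- sprintf("S%02d", 1:10)
  recs <- rbind(make_blood("S01", 100), make_blood("S02", 100),
                make_blood("S03", 100),
                # single-carrier variant: prevalence 0.10, boundary passes
                make_blood("S04", 200),
                # two distinct alts at one locus, one carrier each:
                # allele 0.10 each but locus 0.20 -> both removed (POP_LOCUS)
                make_blood("S05", 300, alt = "G"),
                make_blood("S06", 300, alt = "C"))
  tab <- cohort_table(recs, sample_ids = sids)
  pv <- population_prevalence_filter(tab, filter_config())
  v100 <- pv[pv$pos == 100, ]
  expect_equal(v100$allele_prevalence, 0.3)
  expect_true(v100$removed)
  v200 <- pv[pv$pos == 200, ]
  expect_equal(v200$allele_prevalence, 0.1)
  expect_false(v200$removed)                     # equality passes
  v300 <- pv[pv$pos == 300, ]
  expect_equal(v300$allele_prevalence, c(0.1, 0.1))
  expect_equal(v300$locus_prevalence, c(0.2, 0.2))
  expect_true(all(v300$removed))
  expect_true(all(v300$reasons == "POP_LOCUS"))
  expect_error(population_prevalence_filter(cohort_table(NULL)), "empty")
})

test_that("technical tier applies every comparator and lets missing metrics pass", {
  cfg <- filter_config()
  d <- technical_filter(list(vaf = 0.05, dp = 100, alt_ad = 5, saf = 3,
                             sar = 2, sor = 1.0, tlod = 20), cfg)
  expect_false(d$keep)
  expect_equal(d$reasons, "SAR")                 # only sar 2 < 3 fails
  d2 <- technical_filter(list(vaf = 0.01, dp = 100, alt_ad = 5, saf = 3,
                              sar = 3, sor = 1.0, tlod = 20), cfg)
  expect_equal(d2$reasons, "VAF_LOW")            # below the 0.02 floor
  # all metrics missing except vaf and dp: everything else passes
  d3 <- technical_filter(list(vaf = 0.05, dp = 50, alt_ad = NA, saf = NA,
                              sar = NA, sor = NA, tlod = NA), cfg)
  expect_true(d3$keep)
  # boundary semantics: vaf == vaf_min passes, dp == dp_min fails (strict)
  d4 <- technical_filter(list(vaf = 0.02, dp = 20, alt_ad = 5, saf = 3,
                              sar = 3, sor = 3, tlod = 6.3), cfg)
  expect_equal(d4$reasons, "DP")
})

test_that("functional tier: synonymity, effect set, repeat mask, germline databases", {
  cfg <- filter_config()
  expect_equal(functional_filter(list(exonic_function = "synonymous SNV"), cfg)$reasons,
               "SYNONYMOUS")
  expect_equal(functional_filter(list(gnomad_af = 0.05), cfg)$reasons,
               "GERMLINE_DB")
  # dbSNP-listed but with COSMIC evidence and no gnomAD frequency: kept
  expect_true(functional_filter(list(dbsnp_id = "rs1", cosmic_id = "COSM1"),
                                cfg)$keep)
  # dbSNP-only membership with no gnomAD and no COSMIC: removed
  expect_false(functional_filter(list(dbsnp_id = "rs1"), cfg)$keep)
  expect_equal(functional_filter(list(in_repeat_region = TRUE), cfg)$reasons,
               "REPEAT")
  expect_equal(functional_filter(list(exonic_function = "unknown"), cfg)$reasons,
               "EFFECT")
  # missing annotations pass
  expect_true(functional_filter(list(), cfg)$keep)
})

test_that("paired classification matches the exact one-sided test", {
  cfg <- filter_config(mode = "paired")
  b <- list(alt_ad = 10L, dp = 100L, vaf = 0.10)
  t0 <- list(alt_ad = 0L, dp = 100L, vaf = 0)
  r <- paired_classify(b, t0, cfg)
  expect_equal(r$p, 7.710261e-4, tolerance = 1e-6)   # frozen from enumeration
  expect_equal(r$p, brute_hyper_tail(10, 100, 0, 100), tolerance = 1e-12)
  expect_equal(r$class, "ch_enriched")
  # similar VAFs, not significant, tumor marginally higher -> pair_tumor
  r2 <- paired_classify(list(alt_ad = 48L, dp = 100L, vaf = 0.48),
                        list(alt_ad = 52L, dp = 100L, vaf = 0.52), cfg)
  expect_equal(r2$p, 0.7602008, tolerance = 1e-6)
  expect_equal(r2$class, "pair_tumor")
  # cfDNA contamination pattern: much higher tumor VAF
  r3 <- paired_classify(list(alt_ad = 2L, dp = 200L, vaf = 0.01),
                        list(alt_ad = 80L, dp = 200L, vaf = 0.4), cfg)
  expect_equal(r3$class, "pair_tumor")
  # absent from the paired VCF: tested against 0 / imputed depth
  r4 <- paired_classify(list(alt_ad = 10L, dp = 100L, vaf = 0.1), NULL, cfg,
                        tumor_dp = 100)
  expect_equal(r4$class, "ch_enriched")
  expect_error(paired_classify(list(alt_ad = 0L, dp = 0L, vaf = NA), t0, cfg),
               "zero blood depth")
})

test_that("run_chipfilter composes tiers, records audits, is order-invariant", {
  sids <- sprintf("S%02d", 1:10)
  recs <- do.call(rbind, lapply(sids[1:3], function(s) make_blood(s, 100)))
  recs <- rbind(recs, make_blood("S04", 500))
  tab <- cohort_table(recs, sample_ids = sids)
  cs <- run_chipfilter(tab)
  # prevalent variant removed for all carriers with population reasons only,
  # later tiers still evaluated (and passing) for audit
  dec <- cs$decisions[cs$decisions$pos == 100, ]
  expect_true(all(!dec$keep))
  expect_true(all(dec$reasons == "POP_ALLELE;POP_LOCUS"))
  expect_true(cs$decisions$keep[cs$decisions$pos == 500])
  # determinism and row/sample-order invariance
  cs2 <- run_chipfilter(tab)
  expect_identical(cs$call_keys, cs2$call_keys)
  shuf <- cohort_table(recs[sample(nrow(recs)), ], sample_ids = rev(sids))
  expect_setequal(run_chipfilter(shuf)$call_keys, cs$call_keys)
  expect_error(run_chipfilter(cohort_table(NULL)), "empty")
  expect_error(run_chipfilter(tab, filter_config(mode = "paired")),
               "no paired data")
})

test_that("keep is true iff no reason fires, for random cohorts", {
  for (seed in 1:5) {
    tab <- random_micro_cohort(seed, paired = seed %% 2 == 0)
    cfg <- filter_config(mode = if (seed %% 2 == 0) "paired" else "single")
    cs <- run_chipfilter(tab, cfg)
    expect_identical(cs$decisions$keep, cs$decisions$reasons == "")
    expect_setequal(cs$call_keys,
                    with(cs$decisions[cs$decisions$keep, ],
                         paste(sample_id, paste(chrom, pos, ref, alt, sep = ":"),
                               sep = "|")))
  }
})
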