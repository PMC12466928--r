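test_that("compute_sor matches hand-evaluated values and its symmetries", {
  # balanced strands: r = 1, sym = 2, both ratios 1 -> log(2)
  expect_equal(compute_sor(10, 10, 5, 5), log(2), tolerance = 1e-12)
  # strand-biased alternate allele -> large SOR (hand-evaluated)
  expect_equal(compute_sor(5, 5, 10, 0), 4.804021, tolerance = 1e-6)
  # (a, a, b, b) is exactly log(2) for any a, b
  set.seed(1)
  for (i in 1:20) {
    a <- sample(0:500, 1); b <- sample(0:500, 1)
    expect_equal(compute_sor(a, a, b, b), log(2), tolerance = 1e-12)
  }
  # invariance under simultaneous strand-label swap on both alleles
  for (i in 1:50) {
    x <- sample(0:100, 4, replace = TRUE)
    expect_equal(compute_sor(x[1], x[2], x[3], x[4]),
                 compute_sor(x[2], x[1], x[4], x[3]), tolerance = 1e-12)
  }
  expect_error(compute_sor(-1, 2, 3, 4), "non-negative")
})

test_that("parse_vcf derives VAF from AD, honors FORMAT AF, splits multi-allelics", {
  p <- write_fixture_vcf(tempfile(fileext = ".vcf"), c(
    # no AF field: vaf must equal alt_ad / dp = 10 / 100
    "chr1\t100\t.\tA\tT\t.\tPASS\tTLOD=20\tGT:AD:DP\t0/1:90,10:100",
    # FORMAT AF present and different from AD/DP: AF wins
    "chr1\t200\t.\tC\tG\t.\tPASS\tTLOD=20\tGT:AD:AF:DP\t0/1:90,10:0.123:100",
    # two alternate alleles: one record each with per-allele AD
    "chr1\t300\t.\tG\tA,C\t.\tPASS\tTLOD=9,4\tGT:AD:DP\t0/1:80,15,5:100",
    # strand table but no INFO SOR: computed via compute_sor
    "chr1\t400\t.\tT\tA\t.\tPASS\tTLOD=20\tGT:AD:DP:SB\t0/1:20,10:30:10,10,5,5"))
  rec <- parse_vcf(p, "S1", "blood")
  expect_equal(nrow(rec), 5L)
  r1 <- rec[rec$pos == 100, ]
  expect_equal(r1$alt_ad, 10L)
  expect_equal(r1$dp, 100L)
  expect_equal(r1$vaf, 0.10)
  expect_equal(rec$vaf[rec$pos == 200], 0.123)
  r3 <- rec[rec$pos == 300, ]
  expect_equal(sort(r3$alt_ad), c(5L, 15L))
  expect_equal(sort(r3$alt), c("A", "C"))
  expect_equal(sort(r3$tlod), c(4, 9))          # Number=A per-allele TLOD
  expect_equal(unique(paste(r3$chrom, r3$pos)), "chr1 300")  # shared locus key
  r4 <- rec[rec$pos == 400, ]
  expect_equal(r4$saf, 5L)
  expect_equal(r4$sar, 5L)
  expect_equal(r4$sor, compute_sor(10, 10, 5, 5), tolerance = 1e-9)
  # absent annotation columns are missing, not fatal
  expect_true(all(is.na(rec$gnomad_af)))
  expect_true(all(is.na(rec$exonic_function)))
})

test_that("parse_vcf decodes ANNOVAR-style annotations and skips zero-depth rows", {
  p <- write_fixture_vcf(tempfile(fileext = ".vcf"), c(
    paste0("chr1\t100\t.\tA\tT\t.\tPASS\t",
           "TLOD=20;Gene.refGene=DNMT3A;ExonicFunc.refGene=nonsynonymous_SNV;",
           "gnomAD_exome_AF=0.002;avsnp150=rs123;cosmic70=COSM9",
           "\tGT:AD:DP\t0/1:90,10:100"),
    "chr1\t200\t.\tC\tG\t.\tPASS\tTLOD=1\tGT:AD:DP\t0/1:0,0:0"))
  expect_warning(rec <- parse_vcf(p, "S1", "blood"), "no positive read depth")
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$exonic_function, "nonsynonymous SNV")
  expect_equal(rec$gene, "DNMT3A")
  expect_equal(rec$gnomad_af, 0.002)
  expect_equal(rec$dbsnp_id, "rs123")
  expect_equal(rec$cosmic_id, "COSM9")
  expect_error(parse_vcf(tempfile(), "S1"), "not found")
})

test_that("merge_cohort unions, deduplicates by highest depth, rejects duplicate samples", {
  a <- data.frame(sample_id = "A", tissue = "blood", chrom = "chr1",
                  pos = 1L, ref = "A", alt = "T", vaf = 0.1, dp = 50L,
                  alt_ad = 5L, stringsAsFactors = FALSE)
  b <- a; b$sample_id <- "B"; b$pos <- 2L
  tab <- merge_cohort(list(a, b))
  expect_equal(nrow(tab), 2L)                      # disjoint union
  dup <- rbind(a, transform(a, dp = 80L))          # same key twice: keep dp 80
  expect_message(tab2 <- merge_cohort(list(dup)), "collapsed")
  expect_equal(nrow(tab2), 1L)
  expect_equal(tab2$dp, 80L)
  expect_error(merge_cohort(list(a, a)), "duplicate sample_id")
  # blood + paired for one individual stay distinguishable
  p <- a; p$tissue <- "paired"
  tabp <- merge_cohort(list(rbind(a, p)), paired_map = c(A = "A"))
  expect_equal(sort(tabp$tissue), c("blood", "paired"))
})

test_that("cohort table TSV snapshot round-trips field-wise identically", {
  sim <- simulate_cohort(sim_params(n_samples = 8, seed = 11, paired = TRUE))
  path <- tempfile(fileext = ".tsv")
  write_cohort_table(sim$table, path)
  back <- read_cohort_table(path)
  expect_identical(as.data.frame(back), as.data.frame(sim$table))
  expect_identical(attr(back, "sample_ids"), attr(sim$table, "sample_ids"))
  expect_identical(attr(back, "paired_map"), attr(sim$table, "paired_map"))
})

test_that("parse_vcf recovers exactly the simulated (alt_ad, dp) pairs", {
  sim <- simulate_cohort(sim_params(n_samples = 5, seed = 3))
  dir <- tempfile()
  sheet <- write_cohort_vcfs(sim, dir)
  tab <- vcf2input(sheet)
  key <- function(d) paste(d$sample_id, d$tissue, d$chrom, d$pos, d$ref, d$alt)
  expect_setequal(key(tab), key(sim$table))
  m <- match(key(sim$table), key(tab))
  expect_identical(tab$alt_ad[m], sim$table$alt_ad)
  expect_identical(tab$dp[m], sim$table$dp)
  expect_equal(tab$vaf[m], sim$table$vaf, tolerance = 1e-4)
})
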