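test_that("quality masking uses a strict below-99 rule", {
  calls <- matrix(c(0L, 1L, 2L, 1L), 2, 2)
  qual <- matrix(c(98, 99, 100, 98.5), 2, 2)
  gm <- make_gm(calls, qual)
  m <- mask_low_quality_calls(gm)
  expect_true(is.na(m$calls[1, 1]))   # 98 -> missing
  expect_equal(m$calls[2, 1], 1L)     # 99 retained (strict <)
  expect_equal(m$calls[1, 2], 2L)
  expect_true(is.na(m$calls[2, 2]))
  # nothing below threshold -> identity
  gm_hi <- make_gm(calls, matrix(99, 2, 2))
  expect_identical(mask_low_quality_calls(gm_hi)$calls, gm_hi$calls)
})

test_that("sample and variant missingness filters use strict thresholds", {
  # 10 variants: sample A missing 4/10 (>30% out), B missing 3/10 (kept)
  calls <- matrix(1L, 3, 10)
  calls[1, 1:4] <- NA
  calls[2, 1:3] <- NA
  calls[3, ] <- c(0L, rep(1L, 9))
  gm <- make_gm(calls)
  sf <- filter_samples_by_missingness(gm)
  expect_equal(sf$excluded$sample_id, "s01")
  expect_equal(rownames(sf$genotypes$calls), c("s02", "s03"))

  # among the 2 kept samples: v1..v3 now 1/2 = 50% missing (>20% out)
  vf <- filter_variants_by_missingness(sf$genotypes)
  expect_equal(vf$excluded$variant_id, c("v01", "v02", "v03"))

  # exactly at the boundary: 20% missing retained, 30% sample retained
  calls2 <- matrix(1L, 10, 10)
  calls2[1:2, 1] <- NA            # v1: 20% missing
  calls2[, 2] <- c(0L, rep(1L, 9))
  gm2 <- make_gm(calls2)
  expect_equal(nrow(filter_variants_by_missingness(gm2)$excluded), 0)

  # empty matrix passes through without error
  gm0 <- make_gm(matrix(integer(0), 0, 0,
                        dimnames = list(character(), character())))
  expect_equal(nrow(filter_samples_by_missingness(gm0)$excluded), 0)
})

test_that("monomorphic variants are dropped, missing calls ignored", {
  calls <- cbind(v1 = c(0L, 0L, 0L), v2 = c(0L, NA, 0L),
                 v3 = c(0L, 1L, 0L), v4 = c(NA, NA, NA))
  rownames(calls) <- paste0("s", 1:3)
  gm <- make_gm(calls)
  d <- drop_monomorphic(gm)
  expect_equal(colnames(d$genotypes$calls), "v3")
  expect_equal(d$excluded$reason[d$excluded$variant_id == "v4"],
               "all_missing")
  expect_equal(d$excluded$reason[d$excluded$variant_id == "v2"],
               "monomorphic")
})

test_that("HWE exact test matches the enumeration oracle on spot cases", {
  expect_equal(hwe_exact_test(1, 0, 0), 1)
  expect_equal(hwe_exact_test(25, 50, 25), hwe_oracle(25, 50, 25))
  expect_gt(hwe_exact_test(25, 50, 25), 0.9)
  p_extreme <- hwe_exact_test(50, 0, 50)
  expect_equal(p_extreme, hwe_oracle(50, 0, 50))
  expect_lt(p_extreme, 0.03)
  expect_error(hwe_exact_test(0, 0, 0), "no genotypes")
  # folding symmetry: swapping homozygote roles changes nothing
  expect_equal(hwe_exact_test(40, 12, 3), hwe_exact_test(3, 12, 40))
})

test_that("unrelated selection keeps one lexicographically-smallest member per family", {
  ph <- data.frame(sample_id = c("c1", "c2", "dad", "mom", "x"),
                   father_id = c("dad", "dad", NA, NA, NA),
                   mother_id = c("mom", "mom", NA, NA, NA))
  expect_equal(select_unrelated(ph), c("c1", "x"))
  # all unrelated -> identity
  ph2 <- data.frame(sample_id = c("b", "a"))
  expect_equal(select_unrelated(ph2), c("a", "b"))
  # trio whose parents are absent from the table: child is a singleton
  ph3 <- data.frame(sample_id = "kid", father_id = "gone",
                    mother_id = "also_gone")
  expect_equal(suppressWarnings(select_unrelated(ph3)), "kid")
})

test_that("Mendelian trio check matches the exhaustive 3x3x3 truth table", {
  expect_equal(mendelian_trio_check(2, 0, 0), "inconsistent")
  expect_equal(mendelian_trio_check(1, 0, 2), "consistent")
  expect_equal(mendelian_trio_check(NA, 0, 0), "untestable")
  expect_equal(mendelian_trio_check(0, 1, NA), "untestable")
  # independent enumeration over transmitted-allele pairs
  allele_sets <- list(`0` = 0, `1` = c(0, 1), `2` = 1)
  for (ch in 0:2) for (fa in 0:2) for (mo in 0:2) {
    ok <- FALSE
    for (a in allele_sets[[fa + 1]]) for (b in allele_sets[[mo + 1]])
      if (a + b == ch) ok <- TRUE
    expect_equal(mendelian_trio_check(ch, fa, mo),
                 if (ok) "consistent" else "inconsistent",
                 label = paste(ch, fa, mo))
  }
})

test_that("MAF computation folds to the minor allele", {
  expect_equal(compute_maf(c(0, 0, 0))$maf, 0)
  expect_equal(compute_maf(c(0, 1, 2))$maf, 0.5)
  m <- compute_maf(c(2, 2, 1, NA))
  expect_equal(m$maf, 1 / 6)
  expect_equal(m$minor, "other")   # the coded allele was the major one
  expect_error(compute_maf(c(NA, NA)), "all calls missing")
})

test_that("additive and dominant codings behave and propagate missingness", {
  x <- c(0L, 1L, 2L, NA)
  expect_equal(code_additive(x), c(0, 1, 2, NA))
  expect_equal(code_dominant(x), c(0, 1, 1, NA))
})

test_that("rare-variant collapsing is the per-site presence proportion", {
  tiles <- build_tiles(data.frame(chrom = "chr1", start = 400, end = 600),
                       c(chr1 = 1000))
  # tile 1: [0, 500) holds v1..v3 (pos 100..300); tile 2 has none
  calls <- rbind(s1 = c(1L, 0L, 0L),   # het at 1 of 3 sites
                 s2 = c(0L, 0L, 0L),   # carries nothing
                 s3 = c(NA, 2L, 0L),   # missing one site, minor at 1 of 2
                 s4 = c(NA, NA, NA))   # all missing
  colnames(calls) <- c("v1", "v2", "v3")
  gm <- make_gm(calls, pos = c(100L, 200L, 300L))
  cc <- collapse_rare_variants(gm, tiles)
  expect_equal(ncol(cc), 1)   # the rare-free tile yields no column
  expect_equal(unname(cc[, 1]), c(1 / 3, 0, 0.5, NA))
  # allele-fraction alternative
  cf <- collapse_rare_variants(gm, tiles, method = "allele_fraction")
  expect_equal(unname(cf[, 1]), c(1 / 6, 0, 0.5, NA))
  # two sites, het at one
  gm2 <- make_gm(rbind(s1 = c(1L, 0L)), pos = c(100L, 200L))
  expect_equal(unname(collapse_rare_variants(gm2, tiles)[, 1]), 0.5)
  # single rare variant in a tile: collapsed equals dominant coding
  gm1 <- make_gm(cbind(v1 = c(0L, 1L, 2L, NA)), pos = 100L)
  expect_equal(unname(collapse_rare_variants(gm1, tiles)[, 1]),
               unname(code_dominant(c(0L, 1L, 2L, NA))))
})

test_that("collapsed codes always lie in [0, 1]", {
  set.seed(14)
  tiles <- build_tiles(data.frame(chrom = "chr1", start = 400, end = 600),
                       c(chr1 = 1000))
  for (i in 1:20) {
    calls <- matrix(sample(c(0L, 0L, 0L, 1L, 2L, NA), 40, replace = TRUE),
                    8, 5)
    dimnames(calls) <- list(paste0("s", 1:8), paste0("v", 1:5))
    gm <- make_gm(calls, pos = c(50L, 150L, 450L, 700L, 900L))
    cc <- collapse_rare_variants(gm, tiles)
    expect_true(all(cc >= 0 & cc <= 1, na.rm = TRUE))
  }
})

test_that("the full QC pipeline applies filters in order and reports dimensions", {
  set.seed(33)
  cfg <- sim_config(frac_low_quality = 0.05, missing_rate = 0.02)
  sim <- simulate_study(cfg)
  disc_ids <- sim$pheno$sample_id[sim$pheno$cohort == "DISC"]
  gm <- subset_genotypes(sim$genotypes, samples = disc_ids)
  qc <- run_variant_qc(gm, sim$pheno[sim$pheno$cohort == "DISC", ])
  d <- qc$report$retained_dimensions
  expect_identical(unname(d["n_samples"]), nrow(qc$genotypes$calls))
  expect_identical(unname(d["n_variants"]), ncol(qc$genotypes$calls))
  expect_gt(qc$report$masked_calls, 0)
  # every exclusion carries a reason code
  expect_true(all(nzchar(qc$report$excluded_variants$reason)))
  # no surviving variant is monomorphic and none breaches the missingness cap
  expect_true(all(apply(qc$genotypes$calls, 2, function(x)
    length(unique(x[!is.na(x)])) > 1)))
  expect_true(all(colMeans(is.na(qc$genotypes$calls)) <= 0.20))
  # HWE flags are annotations: flagged variants stay in the matrix
  expect_true(all(qc$report$hwe$variant_id %in%
                    colnames(qc$genotypes$calls)))
  # rarity classification matches the MAF < 0.05 rule
  expect_identical(qc$report$maf$rarity_class,
                   ifelse(qc$report$maf$maf < 0.05, "rare", "common"))
})
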