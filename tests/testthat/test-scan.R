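write_scan_fixture <- function(dir, n = 10, drop_pheno_sample = FALSE) {
  cfg <- sim_config(n = n, maf1 = 0.5, maf2 = 0.5, delta = c(0.5),
                    seed = 111)
  sim <- simulate_cohort(cfg)
  gp <- file.path(dir, "geno.tsv") ; pp <- file.path(dir, "pheno.tsv")
  vp <- file.path(dir, "geno.vcf")
  cohort <- sim$cohort
  names(cohort)[names(cohort) == "Y"] <- "trait1"
  if (drop_pheno_sample) cohort <- cohort[-1, ]
  write.table(cohort, pp, sep = "\t", quote = FALSE, row.names = FALSE)
  write_cohort(sim, gp, file.path(dir, "unused.tsv"), vcf_path = vp)
  mf <- file.path(dir, "manifest.tsv")
  write.table(data.frame(tf = "PGR", bqtl = "V1", bqtl_effect_allele = "B",
                         fqtl = "V2", fqtl_effect_allele = "F",
                         mechanism = "eQTL", trait = "trait1",
                         trait_type = "continuous", scope = "all"),
              mf, sep = "\t", quote = FALSE, row.names = FALSE)
  list(sim = sim, geno_tsv = gp, vcf = vp, pheno = pp, manifest = mf)
}

test_that("VCF round-trip reproduces the simulated dosages", {
  skip_if_not_installed("vcfR")
  dir <- withr::local_tempdir()
  fx <- write_scan_fixture(dir)
  suppressMessages(
    inp <- load_inputs(fx$vcf, fx$pheno, fx$manifest))
  expect_equal(inp$genotypes$V1, fx$sim$genotypes$V1)
  expect_equal(inp$genotypes$V2, fx$sim$genotypes$V2)
  expect_equal(inp$variants$counted_allele, c("B", "F"))
  # manifest effect allele is the ALT/counted allele: no flip
  d <- aiescan:::entry_data(inp, inp$manifest[1, ])
  expect_equal(d$V1, fx$sim$genotypes$V1)
})

test_that("dosages flip when the effect allele is the file's other allele", {
  d <- c(0L, 1L, 2L, 1L)
  expect_equal(orient_dosage(d, "B", "b", "B"), d)
  expect_equal(orient_dosage(d, "B", "b", "b"), 2L - d)
  # involution: flipping twice restores the input
  expect_equal(orient_dosage(orient_dosage(d, "B", "b", "b"),
                             "b", "B", "B"), d)
  expect_error(orient_dosage(d, "B", "b", "X"), "neither")
})

test_that("sample alignment drops non-shared rows and reports the count", {
  skip_if_not_installed("vcfR")
  dir <- withr::local_tempdir()
  fx <- write_scan_fixture(dir, drop_pheno_sample = TRUE)
  expect_message(inp <- load_inputs(fx$vcf, fx$pheno, fx$manifest),
                 "aligned 9 shared samples")
  expect_equal(inp$n_shared, 9)
  expect_equal(inp$genotypes$sample_id, inp$cohort$sample_id)
})

test_that("missing variants, traits and empty intersections are named", {
  dir <- withr::local_tempdir()
  fx <- write_scan_fixture(dir)
  bad_mf <- file.path(dir, "bad_manifest.tsv")
  mf <- read.delim(fx$manifest)
  mf$bqtl <- "V99"
  write.table(mf, bad_mf, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(suppressMessages(
    load_inputs(fx$geno_tsv, fx$pheno, bad_mf)), "V99")
  pheno2 <- read.delim(fx$pheno)
  pheno2$sample_id <- paste0("X", pheno2$sample_id)
  p2 <- file.path(dir, "pheno2.tsv")
  write.table(pheno2, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_inputs(fx$geno_tsv, p2, fx$manifest), "no shared")
})

test_that("run_scan covers every manifest entry exactly once and is
           deterministic", {
  cfg <- sim_config(n = 1500, maf1 = 0.5, maf2 = 0.5, alpha1 = 0.1,
                    gamma = 0, delta = c(0.5), seed = 112)
  sim <- simulate_cohort(cfg)
  # second pair of variants: reuse V1/V2 under different manifest ids
  genotypes <- sim$genotypes
  genotypes$V3 <- rev(genotypes$V1) ; genotypes$V4 <- rev(genotypes$V2)
  cohort <- sim$cohort ; names(cohort)[2] <- "trait1"
  manifest <- expand.grid(bqtl = c("V1", "V3"), fqtl = c("V2", "V4"),
                          stringsAsFactors = FALSE)
  manifest <- data.frame(tf = "AR", manifest, bqtl_effect_allele = "B",
                         fqtl_effect_allele = "F", mechanism = "eQTL",
                         trait = "trait1", trait_type = "continuous",
                         scope = "all")
  inputs <- list(genotypes = genotypes, variants = NULL, cohort = cohort,
                 manifest = manifest)
  config <- scan_config(nuisance = nuisance_spec("glm"), seed = 5)
  scan1 <- run_scan(inputs, config)
  expect_equal(nrow(scan1$results), 4)
  expect_true(all(scan1$results$status == "ok"))
  expect_true(all(scan1$results$k %in% 0:4))
  expect_true(all(scan1$results$q_H >= scan1$results$p_H))
  scan2 <- run_scan(inputs, config)
  expect_identical(scan1$results, scan2$results)
  # per-entry failures are isolated, not fatal
  manifest_bad <- manifest
  manifest_bad$trait[2] <- "no_such_trait"
  scan3 <- run_scan(list(genotypes = genotypes, variants = NULL,
                         cohort = cohort, manifest = manifest_bad),
                    config)
  expect_equal(scan3$results$status[2], "error")
  expect_match(scan3$results$error[2], "no_such_trait")
  expect_equal(sum(scan3$results$status == "ok"), 3)
})

test_that("a strong interaction among nulls is flagged after BH", {
  n <- 8000
  cfg0 <- sim_config(n = n, maf1 = 0.4, maf2 = 0.4, alpha1 = 0.1,
                     gamma = 0, delta = c(0.5), confound_strength = 0.3,
                     seed = 113)
  sim <- simulate_cohort(cfg0)
  genotypes <- sim$genotypes
  cohort <- sim$cohort
  set.seed(114)
  genotypes$V3 <- rbinom(n, 2, 0.4)
  genotypes$V4 <- rbinom(n, 2, 0.4)
  names(cohort)[2] <- "null_trait"
  cohort$hit_trait <- cohort$null_trait +
    0.5 * genotypes$V3 * genotypes$V4
  manifest <- data.frame(tf = "PGR",
                         bqtl = c("V1", "V3"), fqtl = c("V2", "V4"),
                         bqtl_effect_allele = "B",
                         fqtl_effect_allele = "F", mechanism = "hQTL",
                         trait = c("null_trait", "hit_trait"),
                         trait_type = "continuous", scope = "all")
  scan <- run_scan(list(genotypes = genotypes, variants = NULL,
                        cohort = cohort, manifest = manifest),
                   scan_config(nuisance = nuisance_spec("glm"), seed = 6))
  hit <- scan$results[scan$results$trait == "hit_trait", ]
  expect_true(hit$significant)
  expect_lt(hit$q_H, 0.05)
  expect_true(!is.null(scan$components) && nrow(scan$components) > 0)
  dir <- withr::local_tempdir()
  paths <- write_scan_results(scan, dir)
  expect_true(all(file.exists(file.path(dir, c("results.tsv",
                                               "components.tsv")))))
})

test_that("identical sex strata give an exactly zero 3-point estimate", {
  base <- toy_data(n = 600, seed = 115)
  base$Y <- base$V1 * base$V2 * 0.3 + base$W1 + rnorm(600, 0, 0.3)
  twin <- rbind(transform(base, S = 0), transform(base, S = 1))
  res <- sex_stratified_scan(twin, "continuous",
                             scan_config(nuisance = nuisance_spec("glm"),
                                         seed = 9))
  expect_false(res$sex_diff$skipped)
  expect_equal(unname(res$sex_diff$theta),
               rep(0, res$sex_diff$k), tolerance = 1e-10)
  expect_false(res$males$skipped)
  expect_equal(res$males$theta, res$females$theta, tolerance = 1e-8)
})
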