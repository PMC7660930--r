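test_that("genotype_panel validates shapes, alleles and dosage range", {
  expect_error(genotype_panel(matrix(0, 2, 2),
                              data.frame(snp_id = "s1", chrom = "1", pos = 1,
                                         ref = "A", alt = "G")),
               "column count")
  expect_error(genotype_panel(matrix(3, 2, 1),
                              data.frame(snp_id = "s1", chrom = "1", pos = 1,
                                         ref = "A", alt = "G")),
               "\\[0, 2\\]")
  expect_error(genotype_panel(matrix(1, 2, 1),
                              data.frame(snp_id = "s1", chrom = "1", pos = 1,
                                         ref = "A", alt = "A")),
               "distinct")
  expect_error(genotype_panel(matrix(1, 2, 1),
                              data.frame(snp_id = "s1", chrom = "1", pos = 0,
                                         ref = "A", alt = "G")),
               "1-based")
})

test_that("qc_filter removes rare, ambiguous and monomorphic SNPs and imputes", {
  withr::local_seed(42)
  n <- 400
  dos <- cbind(rbinom(n, 2, 0.005),   # rare
               rbinom(n, 2, 0.3),     # fine but A/T ambiguous
               rbinom(n, 2, 0.3),     # fine
               rep(1, n),             # monomorphic
               rbinom(n, 2, 0.4))     # fine, gets missing values
  dos[1:5, 5] <- NA
  panel <- genotype_panel(
    dos,
    data.frame(snp_id = paste0("s", 1:5), chrom = "1", pos = 1:5 * 100L,
               ref = c("A", "A", "A", "C", "ACG"),
               alt = c("G", "T", "C", "A", "A")))
  out <- qc_filter(panel, maf_min = 0.01)
  expect_identical(out$snps$snp_id, c("s3", "s5"))
  expect_false(anyNA(out$dosages))
  # mean imputation: missing entries replaced by the observed mean
  expect_equal(out$dosages[1, "s5"], mean(dos[-(1:5), 5]))
  # idempotent
  again <- qc_filter(out, maf_min = 0.01)
  expect_equal(again$dosages, out$dosages)
  expect_equal(again$snps, out$snps)
})

test_that("qc_filter is the identity on a clean panel and errors on empty result", {
  panel <- make_panel(n = 100, p = 4, seed = 2)
  panel <- qc_filter(panel)  # ensure clean
  out <- qc_filter(panel)
  expect_identical(out$dosages, panel$dosages)
  rare <- genotype_panel(matrix(c(0, 0, 0, 1), 4, 1),
                         data.frame(snp_id = "s1", chrom = "1", pos = 10,
                                    ref = "A", alt = "G"))
  expect_error(qc_filter(rare, maf_min = 0.3), "empty panel")
})

test_that("indels with complementary-looking alleles are not ambiguous", {
  expect_false(is_ambiguous_pair("AT", "T"))
  expect_true(all(is_ambiguous_pair(c("A", "T", "C", "G"),
                                    c("T", "A", "G", "C"))))
})

test_that("cis_snps keeps the 1 Mb window inclusive on both ends", {
  gene <- gene_info("g1", "1", tss = 2e6, tes = 201e4)
  pos <- as.integer(c(1e6, 1e6 - 1, 1500000, 2005000, 3010000, 3010001, 32e5))
  panel <- make_panel(n = 10, p = 7, seed = 3, pos = pos)
  out <- cis_snps(panel, gene)
  # tss - 1e6 = 1e6 retained; 1e6 - 1 excluded; tes + 1e6 = 301e4 retained
  expect_identical(out$snps$pos, pos[c(1, 3, 4, 5)])
  # window 0 keeps only [tss, tes]
  inside <- cis_snps(panel, gene, window_bp = 0)
  expect_identical(inside$snps$pos, pos[4])
  # absent chromosome warns and returns empty
  gene2 <- gene_info("g2", "7", 1e6, 1e6)
  expect_warning(empty <- cis_snps(panel, gene2), "absent")
  expect_equal(n_snps(empty), 0)
})

test_that("mask_annotations zeroes insignificant entries and never increases values", {
  vals <- matrix(c(3.2, 3.2, 0.5, 2), 2, 2)
  pv <- matrix(c(0.5, 1e-4, 0.009, 0.011), 2, 2)
  out <- mask_annotations(vals, pv, alpha = 1e-2)
  expect_equal(unname(out$values[1, 1]), 0)
  expect_true(out$masked[1, 1])
  expect_equal(unname(out$values[2, 1]), 3.2)
  expect_false(out$masked[2, 1])
  expect_equal(unname(out$values[2, 2]), 0)  # p = 0.011 >= alpha
  expect_true(all(out$values <= vals))
  # fully masked
  allmask <- mask_annotations(vals, matrix(1, 2, 2))
  expect_true(all(allmask$values == 0))
  expect_true(all(allmask$masked))
  # negative raw values rejected; shape mismatch rejected
  expect_error(mask_annotations(-vals, pv), "non-negative")
  expect_error(mask_annotations(vals, pv[1, , drop = FALSE]), "shapes")
})

test_that("expression and GWAS TSVs round-trip and reject bad headers", {
  dir <- withr::local_tempdir()
  expr <- tibble::tibble(gene_id = c("g1", "g2"), s1 = c(0.5, -1), s2 = c(2, 3))
  path <- file.path(dir, "expr.tsv")
  write_expression_tsv(expr, path)
  expect_equal(read_expression_tsv(path), expr)
  ev <- expression_for_gene(expr, "g2", c("s2", "s1"))
  expect_equal(ev$values, c(3, -1))
  expect_error(expression_for_gene(expr, "g9"), "not found")
  expect_error(expression_for_gene(expr, "g1", c("s1", "s9")), "absent")

  gw <- gwas_summary(tibble::tibble(snp_id = c("s1", "s2"), a1 = c("G", "C"),
                                    a2 = c("A", "T"), z = c(1.5, -0.2)),
                     n_gwas = 5000)
  gpath <- file.path(dir, "gwas.tsv")
  write_gwas_tsv(gw, gpath)
  back <- read_gwas_tsv(gpath)
  expect_equal(back$records, gw$records)
  expect_equal(back$n_gwas, 5000L)
  # missing mandatory header is a hard failure
  readr::write_tsv(tibble::tibble(SNP = "s1", A1 = "G", A2 = "A", Z = 1),
                   gpath)
  expect_error(read_gwas_tsv(gpath), "mandatory header")
})

test_that("BED annotation coordinates convert 0-based half-open to 1-based", {
  dir <- withr::local_tempdir()
  bed <- tibble::tibble(chrom = "1", start = 99L, end = 100L,
                        track = "H3K4me1", value = 2.5, pvalue = 1e-5)
  path <- file.path(dir, "ann.tsv")
  readr::write_tsv(bed, path)
  tracks <- read_annotation_bed(path)
  expect_equal(tracks$start, 100L)
  expect_equal(tracks$end, 100L)
  # the interval [99,100) covers exactly the SNP at 1-based pos 100
  panel <- make_panel(n = 10, p = 2, seed = 4, pos = c(100L, 101L))
  A <- annotate_panel(panel, tracks)
  expect_equal(unname(A$values[, 1]), c(2.5, 0))
  # write converts back to BED convention
  out <- file.path(dir, "out.tsv")
  write_annotation_bed(tracks, out)
  expect_equal(readr::read_tsv(out, show_col_types = FALSE)$start, 99L)
})

test_that("overlapping intervals take the maximum value per track", {
  panel <- make_panel(n = 10, p = 1, seed = 5, pos = 500L)
  tracks <- tibble::tibble(chrom = "1", start = c(400L, 450L),
                           end = c(600L, 550L), track = "t1",
                           value = c(1.2, 4), pvalue = c(1e-4, 1e-4))
  A <- annotate_panel(panel, tracks)
  expect_equal(unname(A$values[1, 1]), 4)
})

test_that("model stores round-trip through their tabular schema", {
  snps <- tibble::tibble(snp_id = paste0("s", 1:3), chrom = "1",
                         pos = c(10L, 20L, 30L), ref = "A", alt = "G",
                         maf = NA_real_, train_mean = c(0.4, 1.1, 0.9))
  m <- tgen:::new_tgen_model("g1", "liver", snps, beta_hat = c(0.2, 0, -0.5),
                             pps = c(0.9, 0.01, 0.7),
                             omega_hat = c(-2.2, 0.31),
                             method_tag = "tgen", cv_r2 = 0.12,
                             cv_pvalue = 3e-4)
  dir <- withr::local_tempdir()
  prefix <- file.path(dir, "liver")
  write_model_store(list(m), prefix)
  back <- read_model_store(prefix)[["g1"]]
  expect_equal(back$beta_hat, m$beta_hat)
  expect_equal(back$pps, m$pps)
  expect_equal(back$omega_hat, m$omega_hat)
  expect_equal(back$snps$train_mean, snps$train_mean)
  expect_equal(back$cv_r2, 0.12)
  expect_equal(back$method_tag, "tgen")
})

test_that("VCF round-trips dosages and keeps 1-based positions", {
  panel <- make_panel(n = 8, p = 3, seed = 6, pos = c(100L, 250L, 999L))
  dir <- withr::local_tempdir()
  path <- file.path(dir, "panel.vcf")
  write_vcf_panel(panel, path)
  back <- read_vcf_panel(path)
  expect_equal(back$snps$pos, c(100L, 250L, 999L))
  expect_equal(unname(back$dosages), unname(panel$dosages))
  expect_equal(back$sample_ids, panel$sample_ids)
})

test_that("PLINK1 bed/bim/fam round-trips hard-call dosages", {
  panel <- make_panel(n = 11, p = 4, seed = 7)  # 11 samples: partial last byte
  panel$dosages[3, 2] <- NA
  dir <- withr::local_tempdir()
  prefix <- file.path(dir, "toy")
  write_plink_panel(panel, prefix)
  back <- read_plink_panel(prefix)
  expect_equal(unname(back$dosages), unname(panel$dosages))
  expect_equal(back$snps$snp_id, panel$snps$snp_id)
  expect_equal(back$snps$ref, panel$snps$ref)
  expect_equal(back$snps$alt, panel$snps$alt)
  expect_equal(back$sample_ids, panel$sample_ids)
  # corrupt magic is rejected
  writeBin(as.raw(c(0, 0, 0)), paste0(prefix, ".bed"))
  expect_error(read_plink_panel(prefix), "magic")
})
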