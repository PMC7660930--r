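#' Read / write genotype panels in PLINK1 bed/bim/fam format
#'
#' Implements the PLINK1 binary format directly (magic bytes `6c 1b`,
#' SNP-major mode `01`, two bits per genotype). Dosages count A1 alleles,
#' and the panel's alternative (effect) allele is stored as A1, the
#' reference as A2, so round-trips preserve the dosage coding. Genotype
#' codes: `00` = homozygous A1 (dosage 2), `10` = heterozygous (1), `11` =
#' homozygous A2 (0), `01` = missing.
#'
#' @param prefix Path prefix; reads/writes `<prefix>.bed`, `<prefix>.bim`,
#'   `<prefix>.fam`.
#' @return (read) a [genotype_panel()]; (write) the prefix, invisibly.
#' @export
read_plink_panel <- function(prefix) {
  bed <- paste0(prefix, ".bed")
  bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  for (f in base::c(bed, bim, fam)) {
    if (!file.exists(f)) stop("PLINK file not found: ", f)
  }
  bim_tbl <- readr::read_tsv(bim, col_names = base::c("chrom", "snp_id", "cm",
                                                      "pos", "a1", "a2"),
                             show_col_types = FALSE, progress = FALSE)
  fam_tbl <- utils::read.table(fam, header = FALSE,
                               col.names = base::c("fid", "iid", "pat", "mat",
                                                   "sex", "pheno"),
                               colClasses = "character")
  n <- nrow(fam_tbl)
  p <- nrow(bim_tbl)
  bytes_per_snp <- ceiling(n / 4)
  raw <- readBin(bed, "raw", n = 3 + p * bytes_per_snp)
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b)) {
    stop("not a PLINK1 bed file (bad magic bytes): ", bed)
  }
  if (raw[3] != as.raw(0x01)) stop("only SNP-major bed files are supported")
  if (length(raw) != 3 + p * bytes_per_snp) {
    stop("bed file size inconsistent with bim/fam dimensions")
  }
  body <- raw[-(1:3)]
  # decode all genotypes at once: 4 two-bit codes per byte
  ints <- as.integer(body)
  codes <- rbind(ints %% 4L, (ints %/% 4L) %% 4L,
                 (ints %/% 16L) %% 4L, (ints %/% 64L) %% 4L)
  lookup <- base::c(`0` = 2, `1` = NA_real_, `2` = 1, `3` = 0)
  dos <- matrix(NA_real_, n, p)
  for (j in seq_len(p)) {
    col_codes <- codes[, ((j - 1) * bytes_per_snp + 1):(j * bytes_per_snp)]
    dos[, j] <- lookup[as.character(col_codes[seq_len(n)])]
  }
  snps <- tibble::tibble(snp_id = bim_tbl$snp_id,
                         chrom = as.character(bim_tbl$chrom),
                         pos = as.integer(bim_tbl$pos),
                         ref = bim_tbl$a2, alt = bim_tbl$a1)
  genotype_panel(dos, snps, fam_tbl$iid)
}

#' @rdname read_plink_panel
#' @param panel A [genotype_panel()]; dosages are rounded to 0/1/2 on write.
#' @export
write_plink_panel <- function(panel, prefix) {
  stopifnot(inherits(panel, "tgen_panel"))
  n <- n_samples(panel)
  p <- n_snps(panel)
  readr::write_tsv(tibble::tibble(chrom = panel$snps$chrom,
                                  snp_id = panel$snps$snp_id, cm = 0L,
                                  pos = panel$snps$pos,
                                  a1 = panel$snps$alt, a2 = panel$snps$ref),
                   paste0(prefix, ".bim"), col_names = FALSE)
  writeLines(paste(panel$sample_ids, panel$sample_ids, 0, 0, 0, -9),
             paste0(prefix, ".fam"))
  bytes_per_snp <- ceiling(n / 4)
  code_for <- base::c(3L, 2L, 0L)  # dosage 0,1,2 -> code
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(base::c(0x6c, 0x1b, 0x01)), con)
  for (j in seq_len(p)) {
    d <- round(panel$dosages[, j])
    codes <- ifelse(is.na(d), 1L, code_for[pmin(pmax(d, 0), 2) + 1L])
    codes <- base::c(codes, rep(0L, 4 * bytes_per_snp - n))
    m <- matrix(codes, nrow = 4)
    bytes <- m[1, ] + m[2, ] * 4L + m[3, ] * 16L + m[4, ] * 64L
    writeBin(as.raw(bytes), con)
  }
  invisible(prefix)
}
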