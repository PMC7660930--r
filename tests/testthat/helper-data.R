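# shared fixture builders: everything generated in code at test time

make_panel <- function(n = 20, p = 5, seed = 1, chrom = "1",
                       pos = NULL, ref = NULL, alt = NULL, maf = NULL) {
  withr::with_seed(seed, {
    if (is.null(maf)) maf <- runif(p, 0.1, 0.5)
    dos <- sapply(maf, function(f) rbinom(n, 2, f))
    dos <- matrix(dos, n, p)
    genotype_panel(
      dos,
      data.frame(snp_id = sprintf("s%03d", seq_len(p)), chrom = chrom,
                 pos = pos %||% (seq_len(p) * 1000L),
                 ref = ref %||% rep("A", p), alt = alt %||% rep("G", p)),
      sprintf("ind%03d", seq_len(n)))
  })
}

# rank-based (Mann-Whitney) AUC of score for recovering binary labels
auc_score <- function(score, labels) {
  labels <- as.logical(labels)
  r <- rank(score)
  n1 <- sum(labels); n0 <- sum(!labels)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
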