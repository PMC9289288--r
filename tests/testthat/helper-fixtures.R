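# Hand-built three-gene annotation used across unit tests:
#  GA: 2 transcripts on chr1 (+): T1 exons [100,200) [400,500) [700,800),
#      T2 skips the middle exon -> flattening and rule-2 geometry differ
#  GB: single-exon gene on chr1 (+): [2000,2400)  (intronless)
#  GC: minus-strand 2-exon gene on chr2: [100,300) [600,900)
tiny_annotation <- function(cytobands = NULL) {
  exons <- tibble::tribble(
    ~transcript_id, ~gene_id, ~chrom, ~strand, ~start, ~end,
    "GA_T1", "GA", "chr1", "+", 100L, 200L,
    "GA_T1", "GA", "chr1", "+", 400L, 500L,
    "GA_T1", "GA", "chr1", "+", 700L, 800L,
    "GA_T2", "GA", "chr1", "+", 100L, 200L,
    "GA_T2", "GA", "chr1", "+", 700L, 800L,
    "GB_T1", "GB", "chr1", "+", 2000L, 2400L,
    "GC_T1", "GC", "chr2", "-", 100L, 300L,
    "GC_T1", "GC", "chr2", "-", 600L, 900L)
  biotypes <- tibble::tibble(
    transcript_id = c("GA_T1", "GA_T2", "GB_T1", "GC_T1"),
    biotype = c("protein_coding", "retained_intron", "protein_coding", "nmd"))
  genome_annotation(exons, biotypes = biotypes,
                    chrom_lengths = c(chr1 = 5000, chr2 = 2000),
                    cytobands = cytobands)
}

# a contrast-result-like tibble for call/transition tests
fake_result <- function(gene_id, lfc, fdr, observable = !is.na(fdr)) {
  tibble::tibble(gene_id = gene_id, base_mean = 100, lfc = lfc,
                 se = 0.1, stat = lfc / 0.1, p = fdr, fdr = fdr,
                 observable = observable)
}

# two-sided Fisher p by exhaustive hypergeometric enumeration (the
# independent oracle for every Fisher call in the package)
hyper_fisher_oracle <- function(a, b, c, d) {
  r1 <- a + b
  c1 <- a + c
  n <- a + b + c + d
  if (r1 == 0 || c1 == 0 || r1 == n || c1 == n) return(1)
  ks <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- stats::dhyper(ks, r1, n - r1, c1)
  p_obs <- stats::dhyper(a, r1, n - r1, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# BH step-up from the definition: fdr_i = min_{k: p_(k) >= p_(i)} m p_(k) / k
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o]
  adj <- rev(cummin(rev(m * ranked / seq_len(m))))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# Spearman as rank-then-Pearson
spearman_oracle <- function(x, y) stats::cor(rank(x), rank(y))
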