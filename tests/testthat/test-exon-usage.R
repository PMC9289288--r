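test_that("exon flattening splits at boundaries and records parentage", {
  exons <- tibble::tibble(
    transcript_id = c("T1", "T2"), gene_id = "G", chrom = "chr1",
    strand = "+", start = c(0L, 0L), end = c(10L, 20L))
  ann <- genome_annotation(exons)
  bins <- flatten_exons(ann)
  expect_equal(bins$start, c(0L, 10L))
  expect_equal(bins$end, c(10L, 20L))
  expect_setequal(bins$transcripts[[1]], c("T1", "T2"))
  expect_equal(bins$transcripts[[2]], "T2")   # only the longer transcript

  # single-transcript gene: bins are the exons
  ann2 <- tiny_annotation()
  b2 <- flatten_exons(ann2)
  gc_bins <- b2[b2$gene_id == "GC", ]
  expect_equal(nrow(gc_bins), 2)
  expect_equal(gc_bins$start, c(100L, 600L))
  # bins within a gene are disjoint and cover the exon union
  ga <- b2[b2$gene_id == "GA", ]
  expect_true(all(ga$start[-1] >= ga$end[-nrow(ga)]))
  expect_equal(sum(ga$end - ga$start), 300L)
})

test_that("bin counting assigns pairs to every overlapped bin of their gene", {
  ann <- synthetic_annotation(n_genes = 30, seed = 61)
  bins <- flatten_exons(ann)
  sam <- tempfile(fileext = ".sam")
  truth <- generate_sam_fixture(ann, n_pairs = 300, path = sam, seed = 62)
  bc <- count_exon_bins(sam, ann, bins)
  expect_equal(dim(bc), c(nrow(bins), 1L))
  # exonic pairs land in >= 1 bin; fully intronic pairs in none
  cls <- classify_reads(sam, ann)
  n_exonic <- sum(cls$class %in% c("spliced", "ambiguous"))
  expect_gte(sum(bc), n_exonic)   # junction pairs hit two bins
  expect_gt(sum(bc), 0)
})

test_that("the usage test recovers shifts, is antisymmetric and expression-free", {
  set.seed(63)
  n_genes <- 150
  n_bins <- 3
  bins <- tibble::tibble(
    bin_id = sprintf("g%03d:E%03d", rep(1:n_genes, each = n_bins),
                     rep(1:n_bins, n_genes)),
    gene_id = sprintf("g%03d", rep(1:n_genes, each = n_bins)))
  grp <- rep(c("Ctrl", "hypg3"), each = 4)
  usage <- matrix(1 / n_bins, n_genes * n_bins, 8)
  hot <- which(rep(1:n_bins, n_genes) == 1 &
                 rep(1:n_genes, each = n_bins) <= 15)
  usage[hot, grp == "Ctrl"] <- 0.5
  usage[hot, grp == "hypg3"] <- 0.8
  for (g in 1:15) {
    rest <- ((g - 1) * n_bins + 2):(g * n_bins)
    usage[rest, grp == "Ctrl"] <- 0.25
    usage[rest, grp == "hypg3"] <- 0.1
  }
  cnt <- matrix(rpois(n_genes * n_bins * 8, 800 * usage), n_genes * n_bins, 8,
                dimnames = list(bins$bin_id, paste0("s", 1:8)))
  deu <- deu_test(cnt, bins, grp, "hypg3", "Ctrl")
  b <- deu$bins
  expect_true(all(b$fdr[hot] < 0.05))
  expect_true(all(b$usage_lfc[hot] > 0))
  # per-gene aggregation flags the shifted genes
  expect_true(all(sprintf("g%03d", 1:15) %in%
                    deu$genes$gene_id[deu$genes$significant]))
  # null bins of unshifted genes stay quiet at roughly the nominal rate
  null_bins <- which(rep(1:n_genes, each = n_bins) > 15)
  expect_lt(mean(b$p[null_bins] < 0.05, na.rm = TRUE), 0.1)

  # antisymmetry
  deu_sw <- deu_test(cnt, bins, grp, "Ctrl", "hypg3")
  expect_equal(deu$bins$usage_lfc, -deu_sw$bins$usage_lfc)
  expect_equal(deu$bins$p, deu_sw$bins$p)

  # doubling all counts of one condition leaves usage untouched
  cnt2 <- cnt
  cnt2[, grp == "hypg3"] <- cnt2[, grp == "hypg3"] * 2L
  deu2 <- deu_test(cnt2, bins, grp, "hypg3", "Ctrl")
  unshifted <- b$observable & seq_len(nrow(b)) %in% null_bins
  expect_lt(max(abs(deu2$bins$usage_lfc[unshifted])), 0.6)
  expect_equal(cor(deu$bins$usage_lfc[b$observable],
                   deu2$bins$usage_lfc[b$observable]), 1, tolerance = 0.05)

  # single-bin genes are skipped
  solo <- tibble::tibble(bin_id = "solo:E001", gene_id = "solo")
  cnt_solo <- matrix(100L, 1, 8, dimnames = list("solo:E001", paste0("s", 1:8)))
  d_solo <- deu_test(cnt_solo, solo, grp, "hypg3", "Ctrl")
  expect_true(is.na(d_solo$bins$p))
  expect_false(d_solo$bins$observable)
})

test_that("usage calls feed the transition machinery over shared bins", {
  set.seed(64)
  bins <- tibble::tibble(bin_id = sprintf("g%02d:E%03d", rep(1:40, each = 2),
                                          rep(1:2, 40)),
                         gene_id = sprintf("g%02d", rep(1:40, each = 2)))
  grp <- rep(c("A", "B"), each = 4)
  cnt <- matrix(rpois(80 * 8, 200), 80, 8, dimnames = list(bins$bin_id, NULL))
  colnames(cnt) <- paste0("s", 1:8)
  dA <- deu_test(cnt, bins, grp, "B", "A")
  tt <- du_temporal_coherence(dA, dA)
  # identical results: no off-diagonal mass
  expect_true(all(tt$from == tt$to))
  expect_equal(sum(tt$n), sum(dA$bins$observable))
})

test_that("DU-transcript mapping dedupes per direction and keeps both signs", {
  bins <- tibble::tibble(
    bin_id = c("G:E001", "G:E002", "G:E003"),
    gene_id = "G",
    transcripts = list(c("T1", "T2", "T3"), c("T1"), c("T1")))
  deu <- structure(list(
    bins = tibble::tibble(bin_id = bins$bin_id, gene_id = "G",
                          usage_lfc = c(1, 2, -1),
                          fdr = c(0.01, 0.01, 0.001), observable = TRUE),
    genes = tibble::tibble(), contrast = "x", alpha = 0.05),
    class = "deu_result")
  got <- map_du_to_transcripts(deu, bins)
  inc <- got$transcript_id[got$direction == "increased"]
  dec <- got$transcript_id[got$direction == "decreased"]
  expect_setequal(inc, c("T1", "T2", "T3"))  # 3 parents of one bin, T1 once
  expect_equal(dec, "T1")                    # both-signs transcript in each set
  # non-significant bins contribute nothing
  deu$bins$fdr <- 0.5
  expect_equal(nrow(map_du_to_transcripts(deu, bins)), 0)
})
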