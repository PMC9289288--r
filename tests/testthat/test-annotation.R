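test_that("GTF coordinates convert to 0-based half-open and structure is parsed", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    paste("chr1", "test", "exon", 11, 20, ".", "+", ".",
          'gene_id "G"; transcript_id "G_T1"; transcript_biotype "protein_coding";',
          sep = "\t"),
    paste("chr1", "test", "exon", 31, 40, ".", "+", ".",
          'gene_id "G"; transcript_id "G_T1"; transcript_biotype "protein_coding";',
          sep = "\t"),
    paste("chr1", "test", "exon", 11, 40, ".", "+", ".",
          'gene_id "G"; transcript_id "G_T2"; transcript_biotype "processed_transcript";',
          sep = "\t")), gtf)
  ann <- read_gtf(gtf)
  expect_equal(nrow(ann$genes), 1)
  expect_equal(nrow(ann$transcripts), 2)
  e1 <- ann$exons[ann$exons$transcript_id == "G_T1", ]
  expect_equal(e1$start, c(10L, 30L))
  expect_equal(e1$end, c(20L, 40L))
  # Ensembl biotype strings map into the internal vocabulary
  expect_setequal(ann$transcripts$biotype, c("protein_coding", "orf_lacking"))
  # intron = gap between the two exons
  introns <- intron_intervals(ann, "G_T1")
  expect_equal(introns$start, 20L)
  expect_equal(introns$end, 30L)
})

test_that("intron extraction drops zero-length gaps and single-exon transcripts", {
  exons <- tibble::tibble(
    transcript_id = c("T1", "T1", "T2", "T3", "T3"),
    gene_id = c("G1", "G1", "G2", "G3", "G3"),
    chrom = "chr1", strand = "+",
    start = c(0L, 10L, 50L, 100L, 105L),
    end = c(5L, 15L, 60L, 105L, 110L))
  ann <- genome_annotation(exons)
  expect_equal(intron_intervals(ann, "T1")[c("start", "end")],
               tibble::tibble(start = 5L, end = 10L))
  expect_equal(nrow(intron_intervals(ann, "T2")), 0)   # single exon
  expect_equal(nrow(intron_intervals(ann, "T3")), 0)   # abutting exons
})

test_that("malformed GTF lines and missing transcript_id are rejected", {
  bad <- tempfile(fileext = ".gtf")
  writeLines(c(
    paste("chr1", "t", "exon", 1, 10, ".", "+", ".", 'gene_id "G"; transcript_id "T";',
          sep = "\t"),
    "chr1\tbroken line with too few fields"), bad)
  expect_error(read_gtf(bad), "line 2")

  no_tx <- tempfile(fileext = ".gtf")
  writeLines(paste("chr1", "t", "exon", 1, 10, ".", "+", ".", 'gene_id "G";',
                   sep = "\t"), no_tx)
  expect_error(read_gtf(no_tx), "transcript_id")
})

test_that("cytoband assignment uses the strand-aware 5' end", {
  bands <- tibble::tibble(chrom = "chr1",
                          start = c(0L, 1000L), end = c(1000L, 5000L),
                          name = c("p1", "q1"))
  exons <- tibble::tibble(
    transcript_id = c("Tp", "Tm", "Tx"),
    gene_id = c("Gplus", "Gminus", "Gother"),
    chrom = c("chr1", "chr1", "chr9"), strand = c("+", "-", "+"),
    start = c(100L, 600L, 10L), end = c(500L, 1400L, 100L))
  expect_warning(
    ann <- genome_annotation(exons, chrom_lengths = c(chr1 = 5000, chr9 = 200),
                             cytobands = bands),
    "unassigned")
  g <- ann$genes
  expect_equal(g$cytoband[g$gene_id == "Gplus"], "p1")     # 5' end = start 100
  expect_equal(g$cytoband[g$gene_id == "Gminus"], "q1")    # 5' end = 1400 - 1
  expect_true(is.na(g$cytoband[g$gene_id == "Gother"]))    # chrom not in table
})

test_that("GTF round trip reproduces the model and geometry partitions the span", {
  ann <- synthetic_annotation(n_genes = 30, seed = 11)
  gtf <- tempfile(fileext = ".gtf")
  write_gtf(ann, gtf)
  ann2 <- read_gtf(gtf, chrom_lengths = ann$chrom_lengths)
  expect_identical(ann$transcripts, ann2$transcripts)
  expect_identical(ann$exons, ann2$exons)
  expect_identical(ann$genes[setdiff(names(ann$genes), "cytoband")],
                   ann2$genes[setdiff(names(ann2$genes), "cytoband")])

  # union(exons) + union(introns) == transcript span, exactly, per transcript
  introns <- intron_intervals(ann)
  for (tx in sample(ann$transcripts$transcript_id, 10)) {
    ex <- ann$exons[ann$exons$transcript_id == tx, ]
    intr <- introns[introns$transcript_id == tx, ]
    covered <- sum(ex$end - ex$start) + sum(intr$end - intr$start)
    expect_equal(covered, max(ex$end) - min(ex$start))
  }
})

test_that("cytoband tables reject overlapping bands and load from TSV", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("chr1\t0\t1000\tp1", "chr1\t1000\t2000\tq1"), tsv)
  cb <- read_cytobands(tsv)
  expect_equal(cb$name, c("p1", "q1"))
  bad <- tibble::tibble(chrom = "chr1", start = c(0L, 500L),
                        end = c(1000L, 1500L), name = c("p1", "q1"))
  expect_error(genome_annotation(
    tibble::tibble(transcript_id = "T", gene_id = "G", chrom = "chr1",
                   strand = "+", start = 0L, end = 10L),
    cytobands = bad), "overlapping cytobands")
})
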