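test_that("gene assignment requires containment by exactly one gene", {
  ann <- tiny_annotation()
  # blocks inside GA's span
  expect_equal(assign_gene(ann, "chr1", tibble::tibble(start = 120L, end = 150L)),
               "GA")
  # blocks spanning GA and GB -> unassigned
  expect_true(is.na(assign_gene(ann, "chr1",
                                tibble::tibble(start = c(150L, 2100L),
                                               end = c(180L, 2200L)))))
  # unannotated chromosome -> unassigned
  expect_true(is.na(assign_gene(ann, "chr7",
                                tibble::tibble(start = 10L, end = 40L))))
})

test_that("classification rules fire in their stated order", {
  ann <- tiny_annotation()
  # gap exactly matching GA_T1's first intron [200,400), blocks exonic
  junction <- list(list(blocks = tibble::tibble(start = c(180L, 400L),
                                                end = c(200L, 430L)),
                        gaps = tibble::tibble(start = 200L, end = 400L)))
  expect_equal(classify_read(ann, "GA", junction), "spliced")

  # read inside [500,700): intronic in GA_T1 (intron 2) AND GA_T2 (part of
  # its single long intron) -> unspliced
  intronic <- list(list(blocks = tibble::tibble(start = 550L, end = 600L)))
  expect_equal(classify_read(ann, "GA", intronic), "unspliced")

  # read inside [200,400): intronic only in GA_T2 (GA_T1 has an exon there?
  # no - [200,400) is GA_T1's intron 1 and inside GA_T2's single intron)
  # -> intronic in all -> unspliced
  intr2 <- list(list(blocks = tibble::tibble(start = 250L, end = 300L)))
  expect_equal(classify_read(ann, "GA", intr2), "unspliced")

  # exonic read in middle exon [400,500): exonic in GA_T1, intronic in
  # GA_T2 -> not intronic in ALL, no junction -> ambiguous
  mid <- list(list(blocks = tibble::tibble(start = 420L, end = 470L)))
  expect_equal(classify_read(ann, "GA", mid), "ambiguous")

  # single-exon (intronless) gene: any read is spliced by definition
  single <- list(list(blocks = tibble::tibble(start = 2100L, end = 2150L)))
  expect_equal(classify_read(ann, "GB", single), "spliced")

  # partial-boundary gap (not matching both intron edges) -> ambiguous
  partial <- list(list(blocks = tibble::tibble(start = c(180L, 410L),
                                               end = c(200L, 440L)),
                       gaps = tibble::tibble(start = 200L, end = 410L)))
  expect_equal(classify_read(ann, "GA", partial), "ambiguous")

  # pair rule: one junction mate + one mate touching constitutive intron
  # -> unspliced wins
  mixed <- c(junction, intronic)
  expect_equal(classify_read(ann, "GA", mixed), "unspliced")
})

test_that("fixture classification recovers every constructed truth label", {
  ann <- synthetic_annotation(n_genes = 60, seed = 21)
  sam <- tempfile(fileext = ".sam")
  truth <- generate_sam_fixture(ann, n_pairs = 800, path = sam, seed = 22)
  cls <- classify_reads(sam, ann)
  j <- dplyr::inner_join(truth, cls, by = "qname")
  expect_equal(nrow(j), 800)
  expect_equal(j$gene_id.y, j$gene_id.x)
  expect_equal(j$class, j$truth)
})

test_that("layer counting conserves assigned pairs and ignores record order", {
  ann <- synthetic_annotation(n_genes = 40, seed = 31)
  sam <- tempfile(fileext = ".sam")
  truth <- generate_sam_fixture(ann, n_pairs = 300, path = sam, seed = 32)
  lc <- count_layers(sam, ann)
  smry <- attr(lc, "summary")
  expect_equal(sum(total_counts(lc)), smry$assigned)
  expect_equal(smry$assigned + smry$unassigned, 300)

  # shuffle body lines: counts identical
  lines <- readLines(sam)
  hdr <- startsWith(lines, "@")
  shuffled <- tempfile(fileext = ".sam")
  set.seed(1)
  writeLines(c(lines[hdr], sample(lines[!hdr])), shuffled)
  lc2 <- count_layers(shuffled, ann)
  expect_identical(unname(lc$spliced), unname(lc2$spliced))
  expect_identical(unname(lc$unspliced), unname(lc2$unspliced))
  expect_identical(unname(lc$ambiguous), unname(lc2$ambiguous))
})

test_that("empty alignments yield all-zero matrices and bad input errors", {
  ann <- tiny_annotation()
  empty <- tempfile(fileext = ".sam")
  writeLines(gravirebound:::.sam_header(ann), empty)
  lc <- count_layers(empty, ann)
  expect_equal(sum(total_counts(lc)), 0)
  expect_equal(dim(lc), c(3L, 1L))

  headerless <- tempfile(fileext = ".sam")
  writeLines("r1\t99\tchr1\t10\t60\t30M\t=\t10\t0\tAAA\tIII", headerless)
  expect_error(count_layers(headerless, ann), "header")
  expect_error(count_layers(tempfile(), ann), "no such")
})

test_that("secondary and duplicate alignments are excluded from counting", {
  ann <- tiny_annotation()
  sam <- tempfile(fileext = ".sam")
  rec <- function(qn, flag, pos, cigar = "30M") {
    paste(qn, flag, "chr1", pos, 60, cigar, "=", pos, 0,
          strrep("A", 30), strrep("I", 30), sep = "\t")
  }
  writeLines(c(gravirebound:::.sam_header(ann),
               rec("r1", 99, 2101), rec("r1", 147, 2151),
               rec("r1", 355, 2101),          # secondary copy of mate 1
               rec("r2", 1123, 2101), rec("r2", 1171, 2151)),  # duplicate pair
             sam)
  lc <- count_layers(sam, ann)
  # r1 counted once (GB single-exon -> spliced); r2 dropped as duplicate
  expect_equal(sum(total_counts(lc)), 1)
  expect_equal(unname(lc$spliced["GB", 1]), 1L)
})
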