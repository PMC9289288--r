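test_that("expectation model conserves totals exactly", {
  # two equal regions, 100 DEGs total -> 50 each
  tal <- tibble::tibble(region = c("chr1", "chr2"),
                        n_detected = c(500L, 500L),
                        n_deg = c(70L, 30L), n_up = c(40L, 10L),
                        n_down = c(30L, 20L))
  ex <- expected_counts(tal)
  expect_equal(ex$expected_deg, c(50, 50))
  # expected up = n_deg x global up fraction (50/100)
  expect_equal(ex$expected_up, c(35, 15))
  # region with no DEGs gets expected_up 0
  tal0 <- tibble::tibble(region = "chrX", n_detected = 10L, n_deg = 0L,
                         n_up = 0L, n_down = 0L)
  expect_equal(expected_counts(dplyr::bind_rows(tal, tal0))$expected_up[3], 0)

  # conservation on random tallies
  set.seed(30)
  for (i in 1:5) {
    r <- tibble::tibble(region = paste0("r", 1:8),
                        n_detected = rpois(8, 200) + 1L)
    r$n_deg <- rbinom(8, r$n_detected, 0.1)
    r$n_up <- rbinom(8, r$n_deg, 0.6)
    r$n_down <- r$n_deg - r$n_up
    e <- expected_counts(r)
    expect_equal(sum(e$expected_deg), sum(e$n_deg))
    expect_equal(sum(e$expected_up), sum(e$n_up) + sum(e$n_down) * 0,
                 tolerance = 1e-9)
    expect_equal(sum(e$expected_up),
                 sum(e$n_deg) * sum(e$n_up) / (sum(e$n_up) + sum(e$n_down)))
  }
})

test_that("regional Fisher tests match exhaustive hypergeometric enumeration", {
  # proportional table -> odds ratio 1, p = 1
  tal <- tibble::tibble(region = c("A", "B"),
                        n_detected = c(100L, 900L),
                        n_deg = c(10L, 90L), n_up = c(5L, 45L),
                        n_down = c(5L, 45L))
  ft <- fisher_region_tests(tal)
  expect_equal(ft$fisher_p_total, c(1, 1))

  # against the enumeration oracle for small margins
  set.seed(31)
  for (i in 1:20) {
    n_det <- sample(5:15, 2)
    n_deg <- c(rbinom(1, n_det[1], 0.5), rbinom(1, n_det[2], 0.3))
    n_up <- rbinom(2, n_deg, 0.5)
    tal <- tibble::tibble(region = c("A", "B"), n_detected = n_det,
                          n_deg = n_deg, n_up = n_up, n_down = n_deg - n_up)
    ft <- fisher_region_tests(tal)
    a <- n_deg[1]; b <- n_det[1] - n_deg[1]
    c_ <- n_deg[2]; d <- n_det[2] - n_deg[2]
    expect_equal(ft$fisher_p_total[1], hyper_fisher_oracle(a, b, c_, d))
    expect_equal(ft$fisher_p_updown[1],
                 hyper_fisher_oracle(n_up[1], n_deg[1] - n_up[1],
                                     n_up[2], n_deg[2] - n_up[2]))
  }
})

test_that("expected-actual correlation behaves at the extremes and matches ranks", {
  tal <- tibble::tibble(region = paste0("r", 1:6),
                        n_detected = c(100L, 200L, 300L, 400L, 500L, 600L))
  tal$n_deg <- c(10L, 20L, 30L, 40L, 50L, 60L)   # proportional to detected
  tal$n_up <- c(5L, 10L, 15L, 20L, 25L, 30L)
  tal$n_down <- tal$n_deg - tal$n_up
  # actual identical in rank to expected -> rho 1
  expect_equal(expected_actual_correlation(tal)$rho_total, 1)

  # reversed ranking -> rho -1
  rev_tal <- tal
  rev_tal$n_deg <- rev(tal$n_deg)
  rev_tal$n_up <- rev(tal$n_up)
  rev_tal$n_down <- rev_tal$n_deg - rev_tal$n_up
  expect_equal(expected_actual_correlation(rev_tal)$rho_total, -1)

  set.seed(32)
  r <- tibble::tibble(region = paste0("r", 1:10),
                      n_detected = rpois(10, 300) + 1L)
  r$n_deg <- rbinom(10, r$n_detected, 0.2)
  r$n_up <- rbinom(10, r$n_deg, 0.5)
  r$n_down <- r$n_deg - r$n_up
  e <- expected_counts(r)
  got <- expected_actual_correlation(e)
  expect_equal(got$rho_total, spearman_oracle(e$expected_deg, e$n_deg))
  expect_error(expected_actual_correlation(e[1:2, ]), "3 regions")
})

test_that("DU-exon distribution applies the global increased:decreased ratio", {
  du <- tibble::tibble(
    region = c(rep("chr1", 8), rep("chr2", 8)),
    direction = c(rep("increased", 6), rep("decreased", 2),
                  rep("increased", 6), rep("decreased", 2)))
  res <- du_exon_distribution(du)
  # global ratio 12:4 = 3:1 -> a region with 8 DU exons expects 6 increased
  expect_equal(res$expected_increased, c(6, 6))
  expect_equal(sum(res$expected_increased), sum(res$n_increased))
  # balanced regions are not significant
  expect_true(all(res$fdr > 0.05))

  # via gene mapping through the annotation
  ann <- tiny_annotation()
  du2 <- tibble::tibble(gene_id = c("GA", "GA", "GC"),
                        direction = c("increased", "decreased", "increased"))
  res2 <- du_exon_distribution(du2, ann)
  expect_setequal(res2$region, c("chr1", "chr2"))
  expect_equal(res2$n_du[res2$region == "chr1"], 2L)
})

test_that("region tallies aggregate calls over annotation placement", {
  bands <- tibble::tibble(chrom = rep(c("chr1", "chr2"), each = 1),
                          start = 0L, end = c(5000L, 2000L),
                          name = c("p1", "q1"))
  ann <- tiny_annotation(cytobands = bands)
  calls <- tibble::tibble(gene_id = c("GA", "GB", "GC"),
                          call = c("up", "ns", "down"))
  tal <- region_tally(calls, ann, level = "chromosome")
  expect_equal(tal$n_detected[tal$region == "chr1"], 2L)
  expect_equal(tal$n_up[tal$region == "chr1"], 1L)
  expect_equal(tal$n_down[tal$region == "chr2"], 1L)
  cb <- region_tally(calls, ann, level = "cytoband")
  expect_setequal(cb$region, c("chr1:p1", "chr2:q1"))
})
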