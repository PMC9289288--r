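test_that("regulation calls map statistics deterministically", {
  res <- fake_result(paste0("g", 1:5),
                     lfc = c(0.5, -3, 0.2, 0, 1),
                     fdr = c(0.01, 0.2, NA, 0.01, 0.04))
  calls <- call_regulation(res)
  expect_equal(calls$call, c("up", "ns", "unobserved", "ns", "up"))
  # lfc exactly 0 with significant fdr is ns (tie-break), g4 above
})

test_that("transition tables partition the shared observable universe", {
  a <- tibble::tibble(gene_id = paste0("g", 1:6),
                      call = c("up", "up", "down", "ns", "ns", "unobserved"))
  b <- tibble::tibble(gene_id = paste0("g", 1:6),
                      call = c("down", "down", "down", "up", "ns", "up"))
  tt <- transition_table(a, b)
  expect_equal(sum(tt$n), 5)   # g6 unobserved in a
  expect_equal(tt$n[tt$from == "up" & tt$to == "down"], 2)
  expect_setequal(tt$ids[tt$from == "up" & tt$to == "down"][[1]], c("g1", "g2"))
  # every shared gene appears exactly once
  expect_equal(sort(unlist(tt$ids)), paste0("g", 1:5))

  # all genes moving to one cell
  allup <- tibble::tibble(gene_id = paste0("g", 1:4), call = "up")
  alldown <- tibble::tibble(gene_id = paste0("g", 1:4), call = "down")
  one <- transition_table(allup, alldown)
  expect_equal(nrow(one), 1)
  expect_equal(one$n, 4)

  # disjoint observability errors
  left <- tibble::tibble(gene_id = c("g1", "g2"), call = c("up", "unobserved"))
  right <- tibble::tibble(gene_id = c("g1", "g2"), call = c("unobserved", "up"))
  expect_error(transition_table(left, right), "no gene")
})

test_that("grey-ball refinement follows the three-contrast rules", {
  mk <- function(c3, cB, cC) {
    refine_grey_categories(
      tibble::tibble(gene_id = "g", call = c3),
      tibble::tibble(gene_id = "g", call = cB),
      tibble::tibble(gene_id = "g", call = cC))$category
  }
  expect_equal(mk("down", "ns", "down"), "inner_grey")
  expect_equal(mk("down", "up", "down"), "outer_grey")
  expect_equal(mk("down", "up", "ns"), "recovered")
  expect_equal(mk("down", "ns", "ns"), "recovered")
  expect_equal(mk("down", "up", "up"), "overshoot")
  expect_equal(mk("down", "down", "down"), "continued")
  # mirrored definitions for genes up at 3 min
  expect_equal(mk("up", "ns", "up"), "inner_grey")
  expect_equal(mk("up", "down", "up"), "outer_grey")
  expect_equal(mk("up", "down", "down"), "overshoot")  # inverted past control
  expect_equal(mk("up", "down", "ns"), "recovered")
  # ns at 3 min contributes no row
  expect_equal(nrow(refine_grey_categories(
    tibble::tibble(gene_id = "g", call = "ns"),
    tibble::tibble(gene_id = "g", call = "ns"),
    tibble::tibble(gene_id = "g", call = "ns"))), 0)
})

test_that("rebound correlation equals rank-then-Pearson and detects inversion", {
  set.seed(20)
  lfc <- rnorm(50)
  a <- fake_result(paste0("g", 1:50), lfc, fdr = runif(50))
  b_anti <- fake_result(paste0("g", 1:50), -lfc, fdr = runif(50))
  expect_equal(rebound_correlation(a, b_anti)$rho, -1)

  b_perm <- fake_result(paste0("g", 1:50), sample(lfc), fdr = runif(50))
  expect_lt(abs(rebound_correlation(a, b_perm)$rho), 0.35)

  b_rand <- fake_result(paste0("g", 1:50), rnorm(50), fdr = runif(50))
  expect_equal(rebound_correlation(a, b_rand)$rho,
               spearman_oracle(lfc, b_rand$lfc))

  # constant vector flagged as degenerate
  b_const <- fake_result(paste0("g", 1:50), rep(1, 50), fdr = runif(50))
  rc <- rebound_correlation(a, b_const)
  expect_true(rc$degenerate)
  expect_true(is.na(rc$rho))

  expect_error(rebound_correlation(a[1:2, ], b_rand[1:2, ]), "3 shared")
})

test_that("cross-dataset coherence scores directional persistence", {
  base <- tibble::tibble(gene_id = paste0("g", 1:10),
                         call = rep(c("up", "down", "ns"), length.out = 10))
  same <- list(t1 = base, t2 = base, t3 = base)
  cs <- cross_dataset_coherence(same)
  expect_equal(cs$coherence$frac_same_direction, c(1, 1))

  flipped <- base
  flipped$call <- dplyr::recode(base$call, up = "down", down = "up")
  cf <- cross_dataset_coherence(list(t1 = base, t2 = flipped))
  expect_equal(cf$coherence$frac_same_direction, 0)

  # recurrently regulated subset: non-ns in >= threshold datasets
  expect_setequal(cs$recurrent_genes$gene_id,
                  base$gene_id[base$call != "ns"])
  expect_error(cross_dataset_coherence(list(base)), "at least 2")
})

test_that("a simulated rebound time course is recovered end to end", {
  ann <- synthetic_annotation(n_genes = 600, seed = 51)
  truth <- simulate_ground_truth(ann, seed = 52)
  lc <- simulate_layered_counts(simulation_design(), truth, seed = 53)
  de <- de_layers(lc, layers = "total",
                  contrasts = c("hypg3-Ctrl", "hypg15-hypg3"))
  deA <- de[de$contrast == "hypg3-Ctrl", ]
  deB <- de[de$contrast == "hypg15-hypg3", ]
  cA <- call_regulation(deA)
  cB <- call_regulation(deB)
  tt <- transition_table(cA, cB)
  # partition property on real output
  shared <- sum(tt$n)
  expect_equal(shared, sum(cA$call != "unobserved" &
                             cB$call[match(cA$gene_id, cB$gene_id)] != "unobserved"))
  # majority of 3-min up genes leave "up" at the second contrast
  up3 <- cA$gene_id[cA$call == "up"]
  expect_gt(length(up3), 10)
  exited <- cB$call[match(up3, cB$gene_id)] != "up"
  expect_gt(mean(exited), 0.7)
  # fold changes anticorrelate
  expect_lt(rebound_correlation(deA, deB)$rho, -0.3)
})
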