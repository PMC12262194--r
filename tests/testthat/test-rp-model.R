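test_that("peak-gene linking matches brute-force pairwise distances", {
  idx <- suppressWarnings(link_peaks_to_genes(toy_peaks(), toy_tss(), window = 1e5))

  # brute force over all (gene, peak) pairs on the shared chromosome
  brute <- list()
  tss <- toy_tss(); pk <- toy_peaks()
  for (i in seq_len(nrow(tss))) for (j in seq_len(nrow(pk))) {
    if (tss$chrom[i] != pk$chrom[j]) next
    pos <- tss$pos[i]
    d_gen <- if (pos >= pk$start[j] && pos < pk$end[j]) 0
      else if (pk$end[j] <= pos) -(pos - (pk$end[j] - 1L))
      else pk$start[j] - pos
    d <- if (tss$strand[i] == "+") d_gen else -d_gen
    if (abs(d) <= 1e5) {
      brute[[length(brute) + 1L]] <- data.frame(
        gene = tss$gene[i], peak = pk$peak[j], distance = d)
    }
  }
  brute <- do.call(rbind, brute)
  m <- merge(as.data.frame(idx[, c("gene", "peak", "distance")]), brute,
             by = c("gene", "peak"))
  expect_identical(nrow(m), nrow(brute))
  expect_identical(nrow(idx), nrow(brute))
  expect_equal(m$distance.x, m$distance.y)

  # p1 spans gA's TSS: d = 0, weight 1 at any decay
  expect_identical(idx$distance[idx$gene == "gA" & idx$peak == "p1"], 0)
  # p4 is ~110 kb from gB (pos 150000, peak at 260000): outside the window
  expect_false(any(idx$gene == "gB" & idx$peak == "p4"))
  # warns about chr2 TSS? (none here) but warns when TSS chrom has no peaks
  expect_warning(
    link_peaks_to_genes(toy_peaks()[1:4, ],
                        dplyr::mutate(toy_tss(), chrom = c("chr1", "chrX"))),
    "chrX")
})

test_that("regulatory-potential scores are the weighted accessibility sum", {
  sm <- small_multiome()
  g <- sm$truth$genes$gene[sm$truth$genes$class == "regulated"][1]
  model <- fit_rp_model(g, sm$idx, sm$ds$acc, sm$ds$expr, sm$ds$cells$libsize)

  # hand computation: weights {1, .5, .1} x counts {2, 4, 10} -> 5.0
  hand <- model
  hand$peaks <- hand$peaks[1:3, ]
  hand$peaks$weight <- c(1, 0.5, 0.1)
  acc3 <- matrix(c(2, 4, 10), 3, 1, dimnames = list(hand$peaks$peak, "c1"))
  expect_equal(unname(rp_scores(hand, acc3)), 5.0)

  # linearity and the zero case
  A <- as.matrix(sm$ds$acc)
  expect_equal(rp_scores(model, 2 * A), 2 * rp_scores(model, A))
  expect_true(all(rp_scores(model, A * 0) == 0))
  expect_true(all(rp_scores(model, A) >= 0))
  expect_error(rp_scores(model, A[-match(model$peaks$peak[1], rownames(A)), ]),
               class = "bifurcgrn_validation_error")
})

test_that("rp model weights decay from 1 at the TSS and the fit beats the null", {
  sm <- small_multiome()
  g <- sm$truth$genes$gene[sm$truth$genes$class == "regulated"][1]
  m <- fit_rp_model(g, sm$idx, sm$ds$acc, sm$ds$expr, sm$ds$cells$libsize)
  expect_gte(m$loglik, m$loglik_null)
  expect_true(all(m$peaks$weight > 0 & m$peaks$weight <= 1))
  # within a side, weight is non-increasing in |distance|
  for (s in c("upstream", "downstream")) {
    pk <- m$peaks[m$peaks$side == s, ]
    if (nrow(pk) > 1) {
      o <- order(abs(pk$distance))
      expect_true(all(diff(pk$weight[o]) <= 1e-12))
    }
  }
})

test_that("a planted positive link yields beta > 0 and a likelihood gain", {
  set.seed(41)
  n <- 400
  acc <- matrix(rpois(n, 3), 1, n, dimnames = list("pk1", sprintf("c%d", 1:n)))
  y <- round(5 * acc[1, ]) + rpois(n, 1)
  idx <- tibble::tibble(gene = "g1", peak = "pk1", chrom = "chr1",
                        start = 1000L, end = 1400L, distance = 500,
                        side = "downstream")
  m <- fit_rp_model("g1", idx, acc, y, libsize = rep(1, n))
  expect_gt(m$beta, 0)
  expect_gt(m$loglik, m$loglik_null)

  # expression independent of accessibility: small likelihood ratio
  y0 <- rpois(n, 4)
  m0 <- fit_rp_model("g1", idx, acc, y0, libsize = rep(1, n))
  expect_lt(m0$loglik - m0$loglik_null, 5)

  # all-zero accessibility: degenerate intercept-only model
  mz <- fit_rp_model("g1", idx, acc * 0, y, libsize = rep(1, n))
  expect_true(mz$degenerate)
  expect_identical(mz$beta, 0)
  expect_equal(mz$loglik, mz$loglik_null)
})

test_that("planted decay length is recovered within one grid step", {
  truth <- generate_true_grn(n_tf = 6, n_gene = 12, n_cre_per_gene = 6,
                             seed = 501, decay_range = c(1e4, 1e4))
  ds <- suppressWarnings(simulate_multiome(truth, n_cells = 2000, seed = 601))
  tss <- ds$genes[, c("gene", "chrom", "tss", "strand")]
  names(tss)[3] <- "pos"
  idx <- suppressWarnings(link_peaks_to_genes(ds$peaks, tss, window = 1e5))
  g <- truth$genes$gene[truth$genes$class == "regulated"][1]
  m <- fit_rp_model(g, idx, ds$acc, ds$expr, ds$cells$libsize)

  grid <- decay_grid()
  near <- which.min(abs(log(grid) - log(1e4)))
  allowed <- grid[max(1, near - 1):min(length(grid), near + 1)]
  expect_true(m$decay_up %in% allowed)
  expect_true(m$decay_down %in% allowed)
})
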