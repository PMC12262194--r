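fake_model <- function(gene, peaks, weights, chrom = "chr1") {
  idx <- tibble::tibble(
    peak = peaks, chrom = chrom,
    start = seq(1000L, by = 1000L, length.out = length(peaks)),
    end = seq(1400L, by = 1000L, length.out = length(peaks)),
    distance = seq(500, by = 1000, length.out = length(peaks)),
    side = "downstream", weight = weights)
  structure(list(gene = gene, decay_up = 1e4, decay_down = 1e4, peaks = idx,
                 alpha = 0, beta = 1, loglik = 0, loglik_null = -1,
                 degenerate = FALSE, grid = decay_grid()),
            class = "rp_model")
}

toy_degs <- function(genes) {
  out <- tibble::tibble(gene = genes, log2fc_rep1 = 1, log2fc_rep2 = 1,
                        mean_log2fc = 1, direction = "up")
  class(out) <- c("deg_tbl", class(out))
  out
}

test_that("target scores sum the weights of seqlet-bearing cCREs", {
  m <- fake_model("g1", c("p1", "p2", "p3"), c(0.8, 0.3, 0.6))
  # seqlets inside p1 and p2; one outside every cCRE; one of the wrong family
  seqlets <- tibble::tibble(
    chrom = "chr1",
    start = c(1100L, 2100L, 99000L, 3100L),
    end = c(1110L, 2110L, 99010L, 3110L),
    strand = "+",
    family = c("ISRE", "ISRE", "ISRE", "EICE"))
  out <- rp_score_targets(toy_degs("g1"), list(g1 = m), seqlets,
                          family_map = list(TFX = "ISRE"))
  expect_equal(out$rp_score, 0.8 + 0.3)
  expect_identical(out$n_seqlet_cres, 2L)
  expect_true(out$direct_target)

  # no cognate seqlet in any linked cCRE: score 0, not a direct target
  none <- rp_score_targets(toy_degs("g1"), list(g1 = m), seqlets,
                           family_map = list(TFY = "AP1"))
  expect_identical(none$rp_score, 0)
  expect_false(none$direct_target)
})

test_that("splitting a cCRE weight preserves the gene score", {
  m1 <- fake_model("g1", c("p1"), 1.1)
  m2 <- fake_model("g1", c("p1", "p2"), c(0.8, 0.3))
  sq <- tibble::tibble(chrom = "chr1", start = c(1100L, 2100L),
                       end = c(1110L, 2110L), strand = "+", family = "ISRE")
  s1 <- rp_score_targets(toy_degs("g1"), list(g1 = m1), sq,
                         family_map = list(T = "ISRE"))$rp_score
  s2 <- rp_score_targets(toy_degs("g1"), list(g1 = m2), sq,
                         family_map = list(T = "ISRE"))$rp_score
  expect_equal(s1, s2)
})

test_that("DEGs without an RP model are flagged and never direct targets", {
  m <- fake_model("g1", "p1", 0.5)
  sq <- tibble::tibble(chrom = "chr1", start = 1100L, end = 1110L,
                       strand = "+", family = "ISRE")
  out <- rp_score_targets(toy_degs(c("g1", "g_missing")), list(g1 = m), sq,
                          family_map = list(T = "ISRE"))
  miss <- out[out$gene == "g_missing", ]
  expect_true(miss$flagged)
  expect_false(miss$direct_target)
  expect_true(is.na(miss$rp_score))
})

test_that("overlap statistics match the exhaustive hypergeometric oracle", {
  universe <- sprintf("g%d", 1:100)
  A <- universe[1:10]
  B <- universe[5:16]
  res <- target_overlap(A, B, universe)
  expect_identical(res$n_overlap, 6L)

  # brute-force two-sided Fisher: sum of hypergeometric point probabilities
  # no larger than the observed table's
  probs <- vapply(0:10, function(k)
    dhyper(k, 10, 90, 12), numeric(1))
  p_brute <- sum(probs[probs <= probs[6 + 1] * (1 + 1e-7)])
  expect_equal(res$p, p_brute, tolerance = 1e-9)
  # sample odds ratio (no zero cells): (6 * 84) / (4 * 6)
  expect_equal(res$odds_ratio, (6 * 84) / (4 * 6))

  # disjoint sets: continuity-corrected OR, no enrichment signal
  d <- target_overlap(universe[1:5], universe[6:10], universe)
  expect_identical(d$n_overlap, 0L)
  expect_equal(d$odds_ratio, (0.5 * 90.5) / (5.5 * 5.5))
  expect_gte(d$p, 0.5)

  # degenerate: both sets equal the universe
  full <- target_overlap(universe, universe, universe)
  expect_equal(full$p, 1)
  expect_error(target_overlap(A, B, character(0)),
               class = "bifurcgrn_validation_error")
  expect_error(target_overlap(c(A, "zz"), B, universe),
               class = "bifurcgrn_validation_error")
})

test_that("batch overlaps apply BH across all tested pairs", {
  universe <- sprintf("g%d", 1:60)
  sets <- list(a = universe[1:20], b = universe[10:30], c = universe[40:60])
  out <- pairwise_target_overlap(sets, universe)
  expect_identical(nrow(out), 3L)
  expect_equal(out$fdr, p.adjust(out$p, "BH"))
})

test_that("planted direct targets are recovered from the full seqlet chain", {
  sm <- small_multiome()
  genes <- sm$truth$genes$gene[sm$truth$genes$class == "regulated"][1:6]
  models <- lapply(setNames(genes, genes), fit_rp_model, index = sm$idx,
                   acc = sm$ds$acc, expr = sm$ds$expr,
                   libsize = sm$ds$cells$libsize)
  seqs <- simulate_peak_sequences(sm$ds, seed = 91)
  tf <- sm$truth$tfs$tf[sm$truth$tfs$role == "pro_PB"][1]
  fam <- sm$truth$tfs$motif_family[sm$truth$tfs$tf == tf]
  targets <- intersect(sm$truth$edges$gene[sm$truth$edges$tf == tf], genes)
  out <- rp_score_targets(toy_degs(targets), models, seqs$seqlets,
                          family_map = setNames(list(fam), tf))
  # every planted target carries >= 1 cognate seqlet in a linked cCRE
  expect_gte(mean(out$direct_target), 0.8)
})
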