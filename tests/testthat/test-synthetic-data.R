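test_that("truth generation is deterministic and structurally sound", {
  t1 <- generate_true_grn(n_tf = 6, n_gene = 30, seed = 42)
  t2 <- generate_true_grn(n_tf = 6, n_gene = 30, seed = 42)
  expect_identical(serialize(t1, NULL), serialize(t2, NULL))

  expect_error(generate_true_grn(n_tf = 3, n_gene = 10), class = "bifurcgrn_config_error")

  # every planted edge's TF must bind >= 1 cCRE of its target (brute force)
  t3 <- generate_true_grn(n_tf = 6, n_gene = 200, seed = 7)
  for (i in seq_len(nrow(t3$edges))) {
    tf <- t3$edges$tf[i]; g <- t3$edges$gene[i]
    bound <- t3$cres$bound_tfs[t3$cres$gene == g]
    expect_true(any(vapply(bound, function(b) tf %in% b, logical(1))),
                info = sprintf("edge %s -> %s", tf, g))
  }
  # decay lengths positive; roles include both fate classes
  expect_true(all(t3$genes$decay_up > 0) && all(t3$genes$decay_down > 0))
  expect_setequal(unique(t3$tfs$role), c("pro_PB", "pro_GC", "housekeeping"))
})

test_that("housekeeping genes with n_cre_hk = 0 have no cCREs and no edges", {
  truth <- generate_true_grn(n_tf = 6, n_gene = 20, n_cre_hk = 0, seed = 3)
  hk <- truth$genes$gene[truth$genes$class == "housekeeping"]
  expect_true(length(hk) > 0)
  expect_false(any(truth$cres$gene %in% hk))
  expect_false(any(truth$edges$gene %in% hk))
})

test_that("multiome simulation is seeded and respects the generative model", {
  truth <- generate_true_grn(n_tf = 6, n_gene = 12, seed = 5)
  d1 <- suppressWarnings(simulate_multiome(truth, n_cells = 150, seed = 9))
  d2 <- suppressWarnings(simulate_multiome(truth, n_cells = 150, seed = 9))
  expect_identical(as.matrix(d1$expr), as.matrix(d2$expr))
  expect_identical(as.matrix(d1$acc), as.matrix(d2$acc))

  expect_true(all(d1$expr@x >= 0) && all(d1$acc@x >= 0))
  expect_identical(dim(d1$expr), c(nrow(d1$genes), nrow(d1$cells)))
  expect_identical(dim(d1$acc), c(nrow(d1$peaks), nrow(d1$cells)))
  expect_error(simulate_multiome(truth, 100, branch_point = 1.2),
               class = "bifurcgrn_config_error")

  bad <- truth
  bad$genes$decay_up[1] <- -5
  expect_error(suppressWarnings(simulate_multiome(bad, 50, seed = 1)),
               class = "bifurcgrn_validation_error")
})

test_that("zero expression effect decouples expression from accessibility", {
  truth <- generate_true_grn(n_tf = 6, n_gene = 12, seed = 5,
                             decay_range = c(1e4, 1e4))
  ds <- suppressWarnings(
    simulate_multiome(truth, n_cells = 600, seed = 2, base_expr_effect = 0))
  g <- truth$genes$gene[truth$genes$class == "regulated"][1]
  cre <- ds$peaks$peak[ds$peaks$gene == g]
  w <- exp(-abs(truth$cres$distance[match(cre, truth$cres$cre)]) / 1e4)
  rp <- as.numeric(crossprod(as.matrix(ds$acc[cre, , drop = FALSE]), w))
  r <- cor(rp, as.numeric(ds$expr[g, ]))
  expect_lt(abs(r), 0.1)
})

test_that("clonotype simulation honors concordance and enumerable nulls", {
  # rho = 1: no clone of size >= 2 is bifurcated
  ct <- simulate_clonotypes(300, concordance = 1, seed = 2)
  cls <- classify_clonotypes(ct)
  expect_identical(unname(cls$counts$n[cls$counts$category == "bifurcated"]), 0L)

  # rho = 0, pi = 0.5, size exactly 2: the 4 equally likely fate pairs give
  # an expected bifurcated fraction of 1/2
  set.seed(31)
  frac <- mean(replicate(200, {
    ct <- simulate_clonotypes(60, mean_size_pb = 1e-9, mean_size_gc = 1e-9,
                              concordance = 0, pi_pb = 0.5,
                              seed = sample.int(1e6, 1))
    # force size-2 clones by pairing consecutive singletons
    ct$clonotype <- rep(sprintf("c%d", seq_len(30)), each = 2)
    cls <- classify_clonotypes(ct)
    cls$counts$n[cls$counts$category == "bifurcated"] / 30
  }))
  expect_equal(frac, 0.5, tolerance = 0.05)

  expect_identical(nrow(simulate_clonotypes(0, seed = 1)), 0L)
  expect_error(simulate_clonotypes(10, concordance = 2),
               class = "bifurcgrn_config_error")
})

test_that("fixtures round-trip through disk exactly", {
  sm <- small_multiome()
  dir <- withr::local_tempdir()
  seqs <- simulate_peak_sequences(sm$ds, seed = 4)
  manifest <- emit_fixtures(sm$ds, out_dir = dir, sequences = seqs)
  expect_true(all(file.exists(file.path(dir, manifest$file))))
  expect_true(all(nchar(manifest$md5) == 32))

  back <- read_fixtures(dir)
  expect_equal(as.matrix(back$expr), as.matrix(sm$ds$expr))
  expect_equal(as.matrix(back$acc), as.matrix(sm$ds$acc))
  expect_equal(back$cells$cell, sm$ds$cells$cell)

  # BED intervals: 0-based half-open and coordinate-sorted
  bed <- back$peaks
  expect_true(all(bed$end > bed$start))
  key <- order(bed$chrom, bed$start, bed$end)
  expect_identical(key, seq_len(nrow(bed)))
  m <- dplyr::inner_join(bed, sm$ds$peaks, by = "peak")
  expect_identical(m$start.x, m$start.y)
  expect_identical(m$end.x, m$end.y)
})

test_that("sequence planting records seqlets at their true positions", {
  sm <- small_multiome()
  seqs <- simulate_peak_sequences(sm$ds, seed = 4)
  sq <- seqs$seqlets
  expect_true(nrow(sq) > 0)
  consensus <- c(ISRE = "GAAA..GAAA", EICE = "GGAA..GAAA", AP1 = "TGA[CG]TCA")
  for (i in seq_len(min(nrow(sq), 25))) {
    pk <- sq$peak[i]
    off <- sq$start[i] - sm$ds$peaks$start[match(pk, sm$ds$peaks$peak)]
    sub <- substr(as.character(seqs$sequences[[pk]]),
                  off + 1, off + (sq$end[i] - sq$start[i]))
    if (sq$strand[i] == "-") {
      sub <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(sub)))
    }
    expect_true(grepl(paste0("^", consensus[[sq$family[i]]], "$"), sub),
                info = sprintf("row %d (%s)", i, sq$family[i]))
  }
})

test_that("simulated DEG replicates share true effects plus independent noise", {
  truth <- generate_true_grn(n_tf = 6, n_gene = 40, seed = 13)
  tf <- truth$tfs$tf[1]
  dr <- simulate_deg_replicates(truth, tf, seed = 21)
  targets <- truth$edges$gene[truth$edges$tf == tf]
  expect_true(all(dr$true_lfc[setdiff(names(dr$true_lfc), targets)] == 0))
  # replicate noise is independent: residuals uncorrelated-ish
  r1 <- dr$rep1$log2fc - dr$true_lfc
  r2 <- dr$rep2$log2fc - dr$true_lfc
  expect_lt(abs(cor(r1, r2)), 0.4)
  # knocking out an activator lowers its targets
  act <- truth$edges$gene[truth$edges$tf == tf & truth$edges$sign == 1]
  expect_true(all(dr$true_lfc[act] < 0))
})
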