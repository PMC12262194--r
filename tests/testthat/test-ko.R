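ko_edges <- function(df, state = "S") {
  out <- tibble::tibble(state = state, tf = df$tf, gene = df$gene,
                        weight = df$weight, se = 0.1, p = 1e-6, round = 2L)
  class(out) <- c("edge_tbl", class(out))
  out
}

test_that("knockout with zero weights only removes the TF's own expression", {
  E <- matrix(c(2, 1, 3, 0.5, 1, 2), 3, 2,
              dimnames = list(c("T", "A", "B"), c("c1", "c2")))
  e <- ko_edges(data.frame(tf = "T", gene = "A", weight = 0))
  d <- simulate_ko(e, E, rep("S", 2), "T")
  expect_equal(d["T", ], -E["T", ])
  expect_true(all(d[c("A", "B"), ] == 0))
})

test_that("cells without TF expression are a global no-op", {
  E <- matrix(c(0, 1, 2, 0, 3, 1), 3, 2,
              dimnames = list(c("T", "A", "B"), c("c1", "c2")))
  e <- ko_edges(data.frame(tf = "T", gene = "A", weight = 0.5))
  d <- simulate_ko(e, E, rep("S", 2), "T")
  expect_true(all(d == 0))
})

test_that("a two-edge chain propagates the product of weights", {
  # T -> A (w1) -> B (w2), no clamping: Delta_B = w1 * w2 * (-x_T)
  w1 <- 0.3; w2 <- 0.4
  E <- matrix(c(2, 5, 5), 3, 1, dimnames = list(c("T", "A", "B"), "c1"))
  e <- ko_edges(data.frame(tf = c("T", "A"), gene = c("A", "B"),
                           weight = c(w1, w2)))
  d <- simulate_ko(e, E, "S", "T", n_steps = 2)
  expect_equal(d["T", 1], -2)
  expect_equal(d["A", 1], w1 * (-2))
  expect_equal(d["B", 1], w2 * w1 * (-2))

  # n_steps = 1 equals a single matrix-vector product on delta0
  d1 <- simulate_ko(e, E, "S", "T", n_steps = 1)
  W <- matrix(0, 3, 3, dimnames = list(rownames(E), rownames(E)))
  W["A", "T"] <- w1; W["B", "A"] <- w2
  delta0 <- c(-2, 0, 0)
  expect_equal(unname(d1[, 1]), unname(delta0 + W %*% delta0)[, 1])
})

test_that("clamping floors simulated expression at zero and holds the TF down", {
  # strong positive edge would push A below zero without the clamp
  E <- matrix(c(4, 1, 0), 3, 1, dimnames = list(c("T", "A", "B"), "c1"))
  e <- ko_edges(data.frame(tf = c("T", "A"), gene = c("A", "B"),
                           weight = c(2, 1)))
  d <- simulate_ko(e, E, "S", "T", n_steps = 3)
  expect_true(all(E + d >= -1e-12))
  expect_equal((E + d)["T", 1], 0)
  # A is clamped to 0 (shift -1, not -8), so B sees -1 through w = 1
  expect_equal(d["A", 1], -1)
  expect_equal(d["B", 1], 0) # B already at 0, clamp holds it there
})

test_that("states without a fitted network keep a zero shift", {
  E <- matrix(2, 2, 2, dimnames = list(c("T", "A"), c("c1", "c2")))
  e <- ko_edges(data.frame(tf = "T", gene = "A", weight = 0.5), state = "S1")
  d <- simulate_ko(e, E, c("S1", "S2"), "T")
  expect_equal(d["A", "c1"], 0.5 * (-2))
  expect_equal(unname(d[, "c2"]), c(0, 0))
  expect_error(simulate_ko(e, E, c("S1", "S2"), "Z"),
               class = "bifurcgrn_validation_error")
})

test_that("perturbation scores are the per-cell dot products, bilinear in scale", {
  emb <- tibble::tibble(cell = sprintf("c%d", 1:4),
                        x = c(0, 1, 0, 1), y = c(0, 0, 1, 1))
  mk <- function(vx, vy) {
    structure(list(cells = tibble::tibble(cell = emb$cell, x = emb$x,
                                          y = emb$y, vx = vx, vy = vy),
                   grid = NULL, kind = "differentiation"),
              class = "vector_field")
  }
  g <- mk(c(1, 0.5, -0.2, 0), c(0, 1, 0.3, -1))
  # pfield = dfield: every score is |g|^2
  r <- perturbation_scores(g, g, gc_cells = c("c1", "c2"), pb_cells = c("c3", "c4"))
  expect_equal(r$cells$ps, g$cells$vx^2 + g$cells$vy^2)
  expect_equal(r$delta_ps, r$net_gc - r$net_pb)
  # antisymmetry
  gm <- mk(-g$cells$vx, -g$cells$vy)
  r2 <- perturbation_scores(gm, g, c("c1", "c2"), c("c3", "c4"))
  expect_equal(r2$cells$ps, -r$cells$ps)
  # bilinearity under scaling of the differentiation field
  g3 <- mk(3 * g$cells$vx, 3 * g$cells$vy)
  r3 <- perturbation_scores(g, g3, c("c1", "c2"), c("c3", "c4"))
  expect_equal(r3$delta_ps, 3 * r$delta_ps)
  expect_error(perturbation_scores(g, g, c("c1", "c2"), c("c2", "c3")),
               class = "bifurcgrn_validation_error")
})

test_that("knockouts of planted fate TFs shift flows toward the opposite fate", {
  truth <- generate_true_grn(n_tf = 8, n_gene = 40, seed = 301)
  ds <- suppressWarnings(simulate_multiome(truth, n_cells = 800, seed = 302))
  fit <- fit_all_states(ds, truth_base_grn(truth), p_cut = 0.05)
  fin <- final_edges(fit$edges)
  dfield <- differentiation_flow(ds$cells[, c("cell", "x", "y")],
                                 ds$cells$pseudotime)
  pb_tf <- pick_role_tf(truth, fin, "pro_PB")
  gc_tf <- pick_role_tf(truth, fin, "pro_GC")
  skip_if(is.na(pb_tf) || is.na(gc_tf), "role TF missing from fitted networks")
  r_pb <- score_tf_ko(fit$edges, fit$E, ds$cells, pb_tf, dfield,
                      k_neighbors = 150)
  r_gc <- score_tf_ko(fit$edges, fit$E, ds$cells, gc_tf, dfield,
                      k_neighbors = 150)
  expect_gt(r_pb$delta_ps, 0)
  expect_lt(r_gc$delta_ps, 0)
})
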