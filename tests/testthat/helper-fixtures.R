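# shared builders; heavier objects are memoised for the session
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, build) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, build(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

small_multiome <- function() {
  cached("small_multiome", function() {
    truth <- generate_true_grn(n_tf = 6, n_gene = 16, n_cre_per_gene = 4,
                               seed = 11)
    ds <- suppressWarnings(simulate_multiome(truth, n_cells = 400, seed = 12))
    tss <- ds$genes[, c("gene", "chrom", "tss", "strand")]
    names(tss)[3] <- "pos"
    idx <- suppressWarnings(link_peaks_to_genes(ds$peaks, tss, window = 1e5))
    list(truth = truth, ds = ds, idx = idx)
  })
}

toy_peaks <- function() {
  tibble::tibble(
    peak = paste0("p", 1:5),
    chrom = c("chr1", "chr1", "chr1", "chr1", "chr2"),
    start = c(900L, 5000L, 120000L, 260000L, 1000L),
    end =   c(1100L, 5400L, 120500L, 260400L, 1500L)
  )
}

toy_tss <- function() {
  tibble::tibble(
    gene = c("gA", "gB"),
    chrom = c("chr1", "chr1"),
    pos = c(1000L, 150000L),
    strand = c("+", "-")
  )
}

# base network straight from planted edges (uniform scores)
truth_base_grn <- function(truth) {
  bg <- tibble::tibble(tf = truth$edges$tf, gene = truth$edges$gene,
                       score = 1, source = "isd")
  class(bg) <- c("base_grn", class(bg))
  bg
}

fit_all_states <- function(ds, bg, ...) {
  E <- normalize_expression(ds$expr)
  ets <- suppressMessages(lapply(c("ActB", "GC", "PB"), function(st)
    fit_state_grn(bg, E, ds$cells$state, st, ...)))
  list(E = E, edges = ets)
}

# pick, for a TF role, the planted TF with the most final edges
pick_role_tf <- function(truth, fin, role) {
  cand <- intersect(truth$tfs$tf[truth$tfs$role == role], unique(fin$tf))
  if (length(cand) == 0) return(NA_character_)
  cand[which.max(vapply(cand, function(t) sum(fin$tf == t), integer(1)))]
}
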