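#' Bayesian ridge regression by evidence approximation
#'
#' Linear model y = Xw + e with an isotropic Gaussian prior w ~ N(0, 1/a)
#' and noise precision b, both set by MacKay fixed-point updates that
#' maximize the marginal likelihood. The intercept is handled by centering
#' and is not penalized. At a fixed prior precision tending to 0 the
#' posterior mean equals ordinary least squares.
#'
#' @param X Predictor matrix (n x p).
#' @param y Response vector.
#' @param lambda Fixed prior precision, or NULL (default) to estimate it.
#' @param max_iter,tol Fixed-point iteration controls.
#' @return List: `coef` (posterior mean, named by column), `se` (posterior
#'   sd of each coefficient), `intercept`, `alpha`, `beta`, `n_iter`.
#' @export
bayes_ridge <- function(X, y, lambda = NULL, max_iter = 300, tol = 1e-8) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n, n > 1, p >= 1)
  xm <- colMeans(X); ym <- mean(y)
  Xc <- sweep(X, 2, xm)
  yc <- y - ym
  XtX <- crossprod(Xc)
  Xty <- crossprod(Xc, yc)[, 1]

  vy <- stats::var(yc)
  beta <- if (vy > 0) 1 / vy else 1
  alpha <- lambda %||% 1
  m <- rep(0, p)
  for (it in seq_len(max_iter)) {
    S <- solve(alpha * diag(p) + beta * XtX)
    m_new <- beta * (S %*% Xty)[, 1]
    gamma <- p - alpha * sum(diag(S))
    rss <- sum((yc - Xc %*% m_new)^2)
    beta_new <- max(min((n - 1 - gamma) / max(rss, 1e-12), 1e10), 1e-10)
    alpha_new <- if (is.null(lambda)) {
      max(min(gamma / max(sum(m_new^2), 1e-12), 1e10), 1e-10)
    } else alpha
    done <- max(abs(m_new - m)) < tol
    m <- m_new; alpha <- alpha_new; beta <- beta_new
    if (done && it > 1) break
  }
  S <- solve(alpha * diag(p) + beta * XtX)
  list(coef = setNames(m, colnames(X)),
       se = setNames(sqrt(pmax(diag(S), 0)), colnames(X)),
       intercept = ym - sum(xm * m),
       alpha = alpha, beta = beta, n_iter = it)
}

#' Fit a state-specific weighted regulatory network
#'
#' For each target gene, regresses its expression on its candidate TFs
#' (those linked in the base network) over the cells of one state using
#' Bayesian ridge regression. A first round fits all base-network
#' candidates; edges with two-sided normal-tail p < `p_cut` are ranked
#' (ascending p, then descending |weight|, then lexically) and capped at
#' `edge_cap`; a second round refits each gene on its retained TFs only.
#' Round-2 rows carry the final weights.
#'
#' @param base A `base_grn`.
#' @param expr Normalized gene x cell expression (see
#'   [normalize_expression()]); rows must include TFs.
#' @param states Per-cell state labels aligned with `colnames(expr)`.
#' @param state State to fit.
#' @param edge_cap Maximum retained round-1 edges (default 10000).
#' @param p_cut Retention threshold on the edge p-value (default 0.001).
#' @param lambda Fixed ridge prior precision, or NULL to estimate per gene.
#' @param min_cells Minimum cells required in the state.
#' @return An `edge_tbl` tibble: state, tf, gene, weight, se, p, round
#'   (1 or 2), retained (round-1 rows only).
#' @export
fit_state_grn <- function(base, expr, states, state, edge_cap = 10000,
                          p_cut = 0.001, lambda = NULL, min_cells = 20) {
  if (!state %in% states) stop_validate(sprintf("state '%s' absent from labels", state))
  cells <- which(states == state)
  if (length(cells) < min_cells) {
    stop_validate(sprintf("state '%s' has %d cells; >= %d required",
                          state, length(cells), min_cells))
  }
  E <- as.matrix(expr[, cells, drop = FALSE])
  feat_sd <- apply(E, 1, sd)
  dropped <- rownames(E)[feat_sd == 0]
  if (length(dropped) > 0) {
    rlang::inform(sprintf("state '%s': dropping %d zero-variance gene(s)",
                          state, length(dropped)))
  }

  cand <- dplyr::filter(tibble::as_tibble(base),
                        .data$gene %in% rownames(E), .data$tf %in% rownames(E),
                        .data$tf != .data$gene,
                        !.data$gene %in% dropped, !.data$tf %in% dropped)
  fit_round <- function(cand_tbl, round_id) {
    out <- lapply(unique(cand_tbl$gene), function(g) {
      tfs <- unique(cand_tbl$tf[cand_tbl$gene == g])
      fit <- bayes_ridge(t(E[tfs, , drop = FALSE]), E[g, ], lambda = lambda)
      z <- abs(fit$coef) / pmax(fit$se, .Machine$double.xmin)
      tibble::tibble(
        state = state, tf = tfs, gene = g,
        weight = unname(fit$coef), se = unname(fit$se),
        p = pmax(2 * pnorm(-z), .Machine$double.xmin),
        round = round_id
      )
    })
    dplyr::bind_rows(out)
  }

  r1 <- fit_round(cand, 1L)
  keep <- dplyr::slice_head(
    dplyr::arrange(dplyr::filter(r1, .data$p < p_cut),
                   .data$p, dplyr::desc(abs(.data$weight)), .data$tf, .data$gene),
    n = edge_cap)
  r1$retained <- paste(r1$tf, r1$gene) %in% paste(keep$tf, keep$gene)
  r2 <- if (nrow(keep) > 0) {
    fit_round(keep[, c("tf", "gene")], 2L)
  } else r1[0, setdiff(names(r1), "retained")]
  r2$retained <- NA
  edges <- dplyr::bind_rows(r1, r2)
  attr(edges, "state") <- state
  attr(edges, "edge_cap") <- edge_cap
  attr(edges, "p_cut") <- p_cut
  class(edges) <- c("edge_tbl", class(edges))
  edges
}

#' Final (round-2) edges of one or more fitted states
#' @param edges An `edge_tbl` or list of them.
#' @return Tibble of round-2 rows.
#' @export
final_edges <- function(edges) {
  if (inherits(edges, "edge_tbl")) edges <- list(edges)
  dplyr::bind_rows(lapply(edges, function(e) {
    tibble::as_tibble(e[e$round == 2L, setdiff(names(e), "retained")])
  }))
}
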