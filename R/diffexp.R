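#' Two-sample t test on Ct values
#'
#' Pooled-variance Student t by default (Welch optional), two-sided p from
#' the t distribution. With zero pooled variance the statistic degenerates:
#' the test then reports p = 1 when the group means are equal and p = 0
#' (with `degenerate = TRUE`) when they differ, so the sign of the mean
#' difference still carries.
#'
#' @param g1,g2 numeric vectors of values for each group (>= 2 each).
#' @param variance `"pooled"` or `"welch"`.
#' @return list with `t`, `p`, `df`, `diff` (mean(g1) - mean(g2)) and
#'   `degenerate`.
#' @export
two_sample_t <- function(g1, g2, variance = c("pooled", "welch")) {
  variance <- match.arg(variance)
  g1 <- g1[!is.na(g1)]; g2 <- g2[!is.na(g2)]
  if (length(g1) < 2L || length(g2) < 2L) {
    stop_mirct("each group needs >= 2 non-missing values", "degenerate")
  }
  st <- group_t_stats(matrix(c(g1, g2), nrow = 1L),
                      seq_along(g1), length(g1), length(g2), variance)
  list(t = st$t[1L], p = st$p[1L], df = st$df[1L], diff = st$diff[1L],
       degenerate = st$degenerate[1L])
}

# Vectorized per-row two-group t statistics. X: rows = assays; idx1:
# column indices of group 1. Degenerate zero-variance rows get p from the
# sign of the mean difference.
group_t_stats <- function(X, idx1, n1, n2, variance = "pooled") {
  # both groups are summed directly (not by subtraction from totals) so a
  # label assignment and its complement give bit-identical p-values
  X1 <- X[, idx1, drop = FALSE]
  X2 <- X[, -idx1, drop = FALSE]
  s1 <- rowSums(X1); ss1 <- rowSums(X1 ^ 2)
  s2 <- rowSums(X2); ss2 <- rowSums(X2 ^ 2)
  m1 <- s1 / n1; m2 <- s2 / n2
  css1 <- pmax(ss1 - s1 ^ 2 / n1, 0)
  css2 <- pmax(ss2 - s2 ^ 2 / n2, 0)
  d <- m1 - m2
  if (variance == "pooled") {
    df <- rep(n1 + n2 - 2, nrow(X))
    se2 <- (css1 + css2) / df * (1 / n1 + 1 / n2)
  } else {
    v1 <- css1 / (n1 - 1) / n1
    v2 <- css2 / (n2 - 1) / n2
    se2 <- v1 + v2
    df <- se2 ^ 2 / (v1 ^ 2 / (n1 - 1) + v2 ^ 2 / (n2 - 1))
    df[se2 == 0] <- n1 + n2 - 2
  }
  degenerate <- se2 == 0
  t <- d / sqrt(se2)
  t[degenerate & d == 0] <- 0
  p <- 2 * stats::pt(-abs(t), df)
  p[degenerate] <- ifelse(d[degenerate] == 0, 1, 0)
  list(t = t, p = p, df = df, diff = d, m1 = m1, m2 = m2,
       degenerate = degenerate)
}

# All (or B random) group-1 index sets for n1-of-n label permutations.
# When n_perm >= choose(n, n1) the distinct assignments are enumerated
# exhaustively instead of sampled.
permutation_sets <- function(n, n1, n_perm) {
  total <- choose(n, n1)
  if (n_perm >= total) {
    list(idx = utils::combn(n, n1), exhaustive = TRUE)
  } else {
    idx <- replicate(n_perm, sort(sample.int(n, n1)))
    list(idx = idx, exhaustive = FALSE)
  }
}

#' Westfall-Young min-P differential expression fit
#'
#' Per-assay two-group comparison of preprocessed Ct values with
#' permutation-based family-wise error control. For each assay a pooled
#' two-sample t test gives the nominal (raw) p-value; `n_perm` permutations
#' of the group labels give a matrix of null p-values from which three
#' quantities are estimated:
#'
#' * step-down min-P adjusted p-values: with assays ordered by raw p, the
#'   adjusted p of the i-th assay is `(1 + #\{b : q_b,i <= p_(i)\}) / (1 + B)`
#'   where `q_b,i` is the successive minimum of permutation b's p-values
#'   over ranks i..m, with monotonicity enforced down the ranking;
#' * an overall p: the single-step global min-P test, i.e. the probability
#'   that a permutation's smallest p-value is at most the observed smallest;
#' * empirical q-values from the permutation null (see
#'   [empirical_qvalues()]).
#'
#' If `n_perm` is at least the number of distinct label assignments
#' `choose(n, n1)`, the permutation distribution is enumerated exhaustively.
#' Lower Ct means higher expression, so an assay with a negative mean Ct
#' difference (group 1 minus group 2) is reported as direction `"up"` in
#' group 1.
#'
#' @param x a preprocessed, complete [ct_matrix()] (assays with missing
#'   values are dropped with a warning).
#' @param design a [group_design()]; group 1 = `PGRN+`, group 2 = `PGRN-`.
#' @param n_perm number of label permutations (default 1000).
#' @param alpha nominal significance level used by [rank_candidates()]
#'   (default 0.05).
#' @param variance `"pooled"` (default) or `"welch"`.
#' @param seed optional integer seed for the permutation draw.
#' @return a `mir_diffexp` object: per-assay table (`assay_id`, group
#'   means, `diff`, `t`, `df`, `p_raw`, `p_perm`, `p_wy`, `q_emp`,
#'   `direction`), `overall_p`, `n_perm` used, and fit metadata.
#' @export
mir_diffexp <- function(x, design, n_perm = 1000L, alpha = 0.05,
                        variance = c("pooled", "welch"), seed = NULL) {
  variance <- match.arg(variance)
  if (n_perm < 1L) stop_mirct("n_perm must be >= 1", "config")
  if (alpha <= 0 || alpha >= 1) stop_mirct("alpha must be in (0,1)", "config")
  design <- align_design(design, x)
  v <- unclass(x)
  has_na <- rowSums(is.na(v)) > 0L
  if (any(has_na)) {
    warning(sprintf("%d assay(s) with missing values dropped from testing",
                    sum(has_na)))
    v <- v[!has_na, , drop = FALSE]
  }
  if (nrow(v) == 0L) stop_mirct("no complete assays to test", "data")
  idx1 <- which(design$group == "PGRN+")
  n1 <- length(idx1); n2 <- ncol(v) - n1
  if (n1 < 2L || n2 < 2L) {
    stop_mirct("each group needs >= 2 samples", "degenerate")
  }

  obs <- group_t_stats(v, idx1, n1, n2, variance)
  m <- nrow(v)

  if (!is.null(seed)) set.seed(seed)
  ps <- permutation_sets(ncol(v), n1, n_perm)
  if (ps$exhaustive && n_perm > ncol(ps$idx)) {
    message(sprintf(
      "n_perm (%d) >= distinct label assignments (%d): enumerating exhaustively",
      n_perm, ncol(ps$idx)))
  }
  B <- ncol(ps$idx)
  perm_p <- matrix(NA_real_, m, B)
  for (b in seq_len(B)) {
    perm_p[, b] <- group_t_stats(v, ps$idx[, b], n1, n2, variance)$p
  }

  # raw permutation p per assay (bias-protected estimator, never 0)
  p_perm <- (1 + rowSums(perm_p <= obs$p)) / (1 + B)

  # step-down min-P: order by raw p, ties broken by assay id
  ord <- order(obs$p, rownames(v))
  q_min <- apply(perm_p[ord, , drop = FALSE], 2L,
                 function(col) rev(cummin(rev(col))))
  if (m == 1L) q_min <- matrix(q_min, nrow = 1L)
  p_ord <- obs$p[ord]
  adj <- (1 + rowSums(q_min <= p_ord)) / (1 + B)
  adj <- cummax(adj)
  p_wy <- numeric(m)
  p_wy[ord] <- adj
  overall_p <- adj[1L]

  q_emp <- empirical_qvalues(obs$p, perm_p)

  tab <- data.frame(
    assay_id = rownames(v),
    mean_g1 = obs$m1, mean_g2 = obs$m2, diff = obs$diff,
    t = obs$t, df = obs$df,
    p_raw = obs$p, p_perm = p_perm, p_wy = p_wy, q_emp = q_emp,
    direction = ifelse(obs$diff < 0, "up",
                       ifelse(obs$diff > 0, "down", "none")),
    degenerate = obs$degenerate,
    stringsAsFactors = FALSE, row.names = NULL)

  structure(list(table = tab, overall_p = overall_p, n_perm = B,
                 exhaustive = ps$exhaustive, alpha = alpha,
                 variance = variance, n_group1 = n1, n_group2 = n2,
                 n_dropped = sum(has_na), seed = seed,
                 call = match.call()),
            class = "mir_diffexp")
}

#' Empirical q-values from a permutation null
#'
#' For each observed p-value `p_i`, the q-value estimate is the expected
#' number of null p-values at or below `p_i` (averaged over permutations)
#' divided by the observed number at or below `p_i`, capped at 1 and then
#' monotonized by cumulative minimum from the largest p downward. The null
#' proportion is fixed at 1 (conservative).
#'
#' @param p_obs observed raw p-values (one per assay).
#' @param perm_p matrix of null p-values, assays x permutations, from the
#'   same permutation run.
#' @return numeric vector of q-values aligned with `p_obs`.
#' @export
empirical_qvalues <- function(p_obs, perm_p) {
  if (is.null(dim(perm_p)) || ncol(perm_p) == 0L) {
    stop_mirct("empty permutation p-value matrix", "data")
  }
  B <- ncol(perm_p)
  null_sorted <- sort(as.vector(perm_p))
  obs_sorted <- sort(p_obs)
  exp_null <- findInterval(p_obs, null_sorted) / B
  n_obs <- findInterval(p_obs, obs_sorted)
  q <- pmin(exp_null / n_obs, 1)
  # monotonize: q must be non-decreasing in p
  ord <- order(p_obs, decreasing = TRUE)
  q[ord] <- cummin(q[ord])
  q
}

#' Candidate list from a differential-expression fit
#'
#' Assays with raw p below `alpha`, ordered by raw p, annotated with the
#' expression direction in group 1 (`"up"` = lower Ct in PGRN+ carriers).
#'
#' @param fit a [mir_diffexp()] object.
#' @param alpha threshold (defaults to the fit's alpha).
#' @return data frame of candidate assays (possibly empty).
#' @export
rank_candidates <- function(fit, alpha = fit$alpha) {
  stopifnot(inherits(fit, "mir_diffexp"))
  tab <- fit$table[!fit$table$degenerate, , drop = FALSE]
  cand <- tab[tab$p_raw < alpha, , drop = FALSE]
  cand <- cand[order(cand$p_raw, cand$assay_id), , drop = FALSE]
  rownames(cand) <- NULL
  cand
}

#' @export
print.mir_diffexp <- function(x, ...) {
  cat(sprintf("Westfall-Young min-P differential expression fit\n"))
  cat(sprintf("  %d assays, %d vs %d samples; %d permutations%s\n",
              nrow(x$table), x$n_group1, x$n_group2, x$n_perm,
              if (x$exhaustive) " (exhaustive)" else ""))
  cat(sprintf("  overall P = %.4g; smallest q = %.4g\n",
              x$overall_p, min(x$table$q_emp)))
  n_cand <- sum(x$table$p_raw < x$alpha & !x$table$degenerate)
  cat(sprintf("  %d assay(s) with raw p < %.3g\n", n_cand, x$alpha))
  invisible(x)
}

#' @export
summary.mir_diffexp <- function(object, ...) {
  cand <- rank_candidates(object)
  structure(list(fit = object, candidates = cand),
            class = "summary.mir_diffexp")
}

#' @export
print.summary.mir_diffexp <- function(x, ...) {
  print(x$fit)
  if (nrow(x$candidates)) {
    cat("\nCandidates (raw p < alpha):\n")
    show <- x$candidates[, c("assay_id", "diff", "t", "p_raw", "p_wy",
                             "q_emp", "direction")]
    print(format(show, digits = 3), row.names = FALSE)
  } else {
    cat("\nNo candidates at the nominal threshold.\n")
  }
  invisible(x)
}

#' Mean Ct differences from a fit
#' @param object a `mir_diffexp` object.
#' @param ... unused.
#' @return named numeric vector of group-1 minus group-2 mean Ct.
#' @export
coef.mir_diffexp <- function(object, ...) {
  stats::setNames(object$table$diff, object$table$assay_id)
}

#' Volcano plot of a differential-expression fit
#'
#' Mean Ct difference (sign flipped so that right = higher expression in
#' group 1) against -log10 raw p, with the nominal threshold drawn.
#'
#' @param x a `mir_diffexp` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.mir_diffexp <- function(x, ...) {
  tab <- x$table
  graphics::plot(-tab$diff, -log10(tab$p_raw),
                 xlab = "-(mean Ct difference)  [right = up in group 1]",
                 ylab = "-log10 raw p", pch = 20,
                 col = ifelse(tab$p_raw < x$alpha, "firebrick", "grey40"),
                 ...)
  graphics::abline(h = -log10(x$alpha), lty = 2)
  invisible(x)
}
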