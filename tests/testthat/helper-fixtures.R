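# Small builders shared across test files.

# Ct matrix with auto ids; vals filled column-major like matrix()
make_ct <- function(vals, nrow, stage = "raw") {
  m <- matrix(vals, nrow = nrow)
  dimnames(m) <- list(sprintf("a%02d", seq_len(nrow(m))),
                      sprintf("s%02d", seq_len(ncol(m))))
  ct_matrix(m, stage)
}

make_design <- function(n1, n2) {
  group_design(sprintf("s%02d", seq_len(n1 + n2)),
               c(rep("PGRN+", n1), rep("PGRN-", n2)))
}

# Exhaustive Westfall-Young step-down oracle: enumerates every n1-of-n
# label assignment, computes pooled-t p-values with stats::t.test, and
# applies the successive-minima definition directly.
wy_oracle <- function(v, n1) {
  n <- ncol(v)
  sets <- utils::combn(n, n1)
  B <- ncol(sets)
  pfun <- function(idx1) {
    apply(v, 1, function(r)
      stats::t.test(r[idx1], r[-idx1], var.equal = TRUE)$p.value)
  }
  p_obs <- unname(pfun(seq_len(n1)))
  perm_p <- apply(sets, 2, pfun)
  if (is.null(dim(perm_p))) perm_p <- matrix(perm_p, nrow = 1)
  ord <- order(p_obs, rownames(v))
  m <- nrow(v)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    qb <- apply(perm_p[ord[i:m], , drop = FALSE], 2, min)
    adj[i] <- (1 + sum(qb <= p_obs[ord[i]])) / (1 + B)
  }
  adj <- cummax(adj)
  out <- numeric(m)
  out[ord] <- adj
  list(p_obs = p_obs, p_wy = out,
       overall_p = adj[1])
}

# O(n^2) exhaustive KNN imputation oracle, mirroring the documented rule.
knn_oracle <- function(v, k) {
  out <- v
  m <- nrow(v)
  for (a in seq_len(m)) for (s in seq_len(ncol(v))) {
    if (!is.na(v[a, s])) next
    d <- rep(Inf, m)
    for (b in seq_len(m)) {
      if (b == a || is.na(v[b, s])) next
      shared <- which(!is.na(v[a, ]) & !is.na(v[b, ]))
      if (length(shared) == 0) next
      d[b] <- sum((v[a, shared] - v[b, shared])^2) / length(shared)
    }
    nb <- order(d)[seq_len(min(k, sum(is.finite(d))))]
    nb <- nb[is.finite(d[nb])]
    out[a, s] <- mean(v[nb, s])
  }
  out
}
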