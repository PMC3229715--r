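#' Detection filter for minimally expressed assays
#'
#' Excludes every assay for which `max_missing_frac` (default 20%) or more
#' of the samples have a missing Ct or a Ct above `max_ct` (default 35);
#' the boundary counts as excluded. In retained assays, surviving cells
#' with Ct above `max_ct` are set to missing so the imputation step can
#' fill them.
#'
#' @param x a raw [ct_matrix()].
#' @param max_ct detection Ct threshold (default 35).
#' @param max_missing_frac exclusion fraction (default 0.20).
#' @return list with `ct` (filtered matrix), `excluded` (assay ids) and
#'   `n_censored` (retained cells set to missing because Ct > `max_ct`).
#' @export
detection_filter <- function(x, max_ct = 35, max_missing_frac = 0.20) {
  check_stage(x, "raw", "detection_filter")
  if (nrow(x) == 0L || ncol(x) == 0L) {
    stop_mirct("empty Ct matrix", "data")
  }
  if (max_missing_frac <= 0 || max_missing_frac > 1) {
    stop_mirct("max_missing_frac must be in (0, 1]", "config")
  }
  bad <- is.na(x) | x > max_ct
  frac_bad <- rowMeans(bad)
  drop <- frac_bad >= max_missing_frac
  kept <- unclass(x)[!drop, , drop = FALSE]
  censor <- !is.na(kept) & kept > max_ct
  kept[censor] <- NA_real_
  list(ct = ct_matrix(kept, "filtered"),
       excluded = rownames(x)[drop],
       n_censored = sum(censor))
}

#' Lowess normalization against a median reference profile
#'
#' Removes sample-level intensity trends. The reference profile is the
#' per-assay median Ct across samples; for each sample, a lowess curve of
#' the deviation (sample Ct minus reference) against the reference Ct is
#' fitted over the non-missing assays and subtracted. A constant sample
#' offset is removed exactly; Ct-dependent trends are removed smoothly.
#' Missing cells stay missing.
#'
#' @param x a filtered [ct_matrix()].
#' @param span lowess smoother span, fraction of points (default 2/3).
#' @return normalized `ct_matrix`.
#' @export
lowess_normalize <- function(x, span = 2 / 3) {
  check_stage(x, c("raw", "filtered"), "lowess_normalize")
  if (span <= 0 || span > 1) stop_mirct("span must be in (0, 1]", "config")
  v <- unclass(x)
  ref <- apply(v, 1L, stats::median, na.rm = TRUE)
  if (any(is.na(ref))) {
    stop_mirct(sprintf("assay '%s' has no observed values",
                       rownames(x)[which(is.na(ref))[1L]]), "data")
  }
  out <- v
  for (j in seq_len(ncol(v))) {
    obs <- which(!is.na(v[, j]))
    if (length(obs) < 10L) {
      stop_mirct(sprintf(
        "sample '%s' has only %d observed values; >= 10 needed for lowess",
        colnames(x)[j], length(obs)), "data")
    }
    dev <- v[obs, j] - ref[obs]
    fit <- stats::lowess(ref[obs], dev, f = span)
    fitted <- stats::approx(fit$x, fit$y, xout = ref[obs], rule = 2,
                            ties = mean)$y
    out[obs, j] <- v[obs, j] - fitted
  }
  set_stage(ct_matrix(out, "filtered"), "normalized")
}

#' K-nearest-neighbour imputation of missing Ct values
#'
#' Each missing cell (assay a, sample s) is replaced by the unweighted
#' mean, over the `k` assays most similar to a, of their Ct in s.
#' Similarity is root-mean-square Euclidean distance computed over the
#' samples where both assays are observed (so assays sharing few samples
#' are not unfairly favoured); only assays observed in s are eligible
#' neighbours. If fewer than `k` are eligible all of them are used, with a
#' warning; a cell with no eligible neighbour is an error.
#'
#' @param x a normalized [ct_matrix()].
#' @param k neighbour count (default 10).
#' @return complete `ct_matrix` (no missing values).
#' @export
knn_impute <- function(x, k = 10L) {
  check_stage(x, c("raw", "filtered", "normalized"), "knn_impute")
  if (k < 1L) stop_mirct("k must be >= 1", "config")
  v <- unclass(x)
  miss <- is.na(v)
  if (!any(miss)) return(set_stage(x, "imputed"))
  if (any(rowSums(!miss) == 0L)) {
    stop_mirct(sprintf("assay '%s' has no observed values",
                       rownames(x)[which(rowSums(!miss) == 0L)[1L]]), "data")
  }
  d2 <- knn_distance2(v)
  out <- v
  short <- 0L
  rows_with_miss <- which(rowSums(miss) > 0L)
  for (a in rows_with_miss) {
    for (s in which(miss[a, ])) {
      cand <- which(!miss[, s])
      dd <- d2[a, cand]
      cand <- cand[is.finite(dd)]
      if (length(cand) == 0L) {
        stop_mirct(sprintf(
          "no eligible neighbour for assay '%s' in sample '%s'",
          rownames(x)[a], colnames(x)[s]), "data")
      }
      if (length(cand) < k) short <- short + 1L
      dd <- d2[a, cand]
      nb <- cand[order(dd, cand)][seq_len(min(k, length(cand)))]
      out[a, s] <- mean(v[nb, s])
    }
  }
  if (short > 0L) {
    warning(sprintf(
      "%d cell(s) had fewer than k eligible neighbours; used all available",
      short))
  }
  set_stage(ct_matrix(out, "normalized"), "imputed")
}

# squared per-sample-scaled Euclidean distance between all assay pairs,
# NA-aware: d2[i,j] = sum_{s observed in both} (x_i - x_j)^2 / n_shared.
# Inf where no samples are shared; diagonal Inf (an assay is not its own
# neighbour).
knn_distance2 <- function(v) {
  w <- !is.na(v)
  m0 <- v
  m0[!w] <- 0
  wn <- w * 1
  cross <- tcrossprod(m0)
  sq <- tcrossprod(m0 ^ 2, wn)
  nshared <- tcrossprod(wn)
  d2 <- (sq + t(sq) - 2 * cross) / nshared
  d2[nshared == 0] <- Inf
  diag(d2) <- Inf
  d2
}

#' Winsorize extreme values per assay
#'
#' Shrinks particularly extreme values toward the centre of each assay's
#' distribution so they cannot dominate the group comparison: values
#' outside `median +/- c * 1.4826 * MAD` are clamped to the nearest bound.
#' Assays with zero MAD are left unchanged (no meaningful scale to clamp
#' against). Idempotent.
#'
#' @param x an imputed [ct_matrix()].
#' @param c robust-z bound (default 3).
#' @return winsorized `ct_matrix`.
#' @export
shrink_extremes <- function(x, c = 3) {
  check_stage(x, c("raw", "filtered", "normalized", "imputed", "shrunk"),
              "shrink_extremes")
  if (c <= 0) stop_mirct("shrink bound c must be > 0", "config")
  v <- unclass(x)
  for (a in seq_len(nrow(v))) {
    row <- v[a, ]
    m <- stats::median(row, na.rm = TRUE)
    s <- stats::mad(row, na.rm = TRUE)  # includes the 1.4826 consistency factor
    if (is.na(s) || s == 0) next
    lo <- m - c * s
    hi <- m + c * s
    v[a, ] <- pmin(pmax(row, lo), hi)
  }
  set_stage(ct_matrix(v, ct_stage(x)), "shrunk")
}

#' Full preprocessing pipeline
#'
#' Applies, in order: detection filter, lowess normalization, KNN
#' imputation, winsorization. Returns the analysis-ready matrix and a
#' stage report.
#'
#' @param x a raw [ct_matrix()].
#' @param max_ct,max_missing_frac see [detection_filter()].
#' @param span see [lowess_normalize()].
#' @param k see [knn_impute()].
#' @param shrink_c see [shrink_extremes()].
#' @return list with `ct` (stage `"shrunk"`, complete) and `report`
#'   (per-stage counts).
#' @export
preprocess_ct <- function(x, max_ct = 35, max_missing_frac = 0.20,
                          span = 2 / 3, k = 10L, shrink_c = 3) {
  flt <- detection_filter(x, max_ct = max_ct,
                          max_missing_frac = max_missing_frac)
  n_missing_after_filter <- sum(is.na(flt$ct))
  norm <- lowess_normalize(flt$ct, span = span)
  imp <- knn_impute(norm, k = k)
  shr <- shrink_extremes(imp, c = shrink_c)
  n_shrunk <- sum(unclass(shr) != unclass(imp))
  list(ct = shr,
       report = list(
         n_assays_raw = nrow(x),
         n_samples = ncol(x),
         n_excluded = length(flt$excluded),
         excluded_assay_ids = flt$excluded,
         n_assays_retained = nrow(flt$ct),
         n_censored_cells = flt$n_censored,
         n_imputed_cells = n_missing_after_filter,
         n_shrunk_cells = n_shrunk,
         stages = c("raw", "filtered", "normalized", "imputed", "shrunk")))
}
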