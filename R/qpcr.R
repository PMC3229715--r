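#' Reconcile duplicate qPCR wells
#'
#' Each assay-sample pair is run in duplicate. If the two wells agree to
#' within `threshold` cycles (strictly more than `threshold` apart triggers
#' the rule), their mean is the reconciled Ct. Otherwise the well more
#' extreme relative to the assay's distribution across all samples — the
#' one farther, in absolute difference, from the median of all of that
#' assay's wells — is deleted and the other kept. A lone well is kept
#' as-is; if both wells of a pair are equidistant from the centre their
#' mean is used, keeping the rule symmetric in well order.
#'
#' @param wells a [qpcr_wells()] table.
#' @param threshold duplicate disagreement threshold (default 2 Ct).
#' @return data frame `assay_id`, `sample_id`, `ct` (NA when both wells
#'   missing), with the table's `control_assay_id` attribute carried over.
#' @export
reconcile_duplicates <- function(wells, threshold = 2) {
  if (threshold <= 0) stop_mirct("threshold must be > 0", "config")
  df <- as.data.frame(wells)
  centre <- tapply(df$ct, df$assay_id, stats::median, na.rm = TRUE)
  key <- interaction(df$assay_id, df$sample_id, drop = TRUE)
  rec <- lapply(split(df, key), function(pair) {
    ct <- pair$ct[!is.na(pair$ct)]
    out <- pair[1L, c("assay_id", "sample_id")]
    if (length(ct) == 0L) {
      out$ct <- NA_real_
    } else if (length(ct) == 1L) {
      out$ct <- ct
    } else if (abs(ct[1L] - ct[2L]) > threshold) {
      d <- abs(ct - centre[[pair$assay_id[1L]]])
      out$ct <- if (d[1L] == d[2L]) mean(ct) else ct[which.min(d)]
    } else {
      out$ct <- mean(ct)
    }
    out
  })
  out <- do.call(rbind, rec)
  out <- out[order(out$assay_id, out$sample_id), ]
  rownames(out) <- NULL
  attr(out, "control_assay_id") <- attr(wells, "control_assay_id")
  out
}

#' Minus delta-Ct values against the endogenous control
#'
#' The delta-Ct of a target assay in a sample is its reconciled Ct minus
#' the control's (RNU48) reconciled Ct in the same sample; its negation,
#' the minus delta-Ct, is taken as the log2 of scaled expression (one
#' cycle = one doubling at perfect efficiency). Samples whose control Ct
#' is missing are excluded for all assays, with a warning.
#'
#' @param reconciled output of [reconcile_duplicates()].
#' @param control_assay_id control assay (defaults to the table's
#'   attribute, else `"RNU48"`).
#' @return data frame `assay_id`, `sample_id`, `ct`, `delta_ct`,
#'   `minus_dct` for target assays only.
#' @export
delta_ct <- function(reconciled,
                     control_assay_id = attr(reconciled, "control_assay_id")
                       %||% "RNU48") {
  df <- as.data.frame(reconciled)
  ctrl <- df[df$assay_id == control_assay_id, ]
  if (nrow(ctrl) == 0L) {
    stop_mirct(sprintf("control assay '%s' not in reconciled table",
                       control_assay_id), "data")
  }
  ctrl_ct <- stats::setNames(ctrl$ct, ctrl$sample_id)
  bad <- names(ctrl_ct)[is.na(ctrl_ct)]
  if (length(bad)) {
    warning(sprintf("control Ct missing for sample(s) %s; excluded",
                    paste(bad, collapse = ", ")))
  }
  tgt <- df[df$assay_id != control_assay_id, ]
  tgt <- tgt[!tgt$sample_id %in% bad, ]
  tgt$delta_ct <- tgt$ct - ctrl_ct[tgt$sample_id]
  tgt$minus_dct <- -tgt$delta_ct
  rownames(tgt) <- NULL
  tgt
}

#' Group fold changes from minus delta-Ct values
#'
#' For each assay, compares the minus delta-Ct of group 1 (PGRN+) against
#' group 2 (PGRN-) with a pooled two-sample t test. The difference in
#' group means `d` and its confidence interval are exponentiated base 2
#' (perfect amplification efficiency), so the fold change is `2^d` and
#' `log2(FC)` is exactly the minus delta-Ct mean difference. Assays are
#' additionally flagged undetectable when the median reconciled Ct exceeds
#' `min_ct_detect` or more than half the samples are missing.
#'
#' @param mdct output of [delta_ct()].
#' @param design a [group_design()].
#' @param ci_level confidence level (default 0.95).
#' @param min_ct_detect detectability Ct bound (default 35).
#' @return a `qpcr_validation` object: per-assay `n_g1`, `n_g2`, `d`
#'   (log2 fold change), `fc`, `ci_lo`, `ci_hi`, `t`, `p`, `detectable`.
#' @export
qpcr_validate <- function(mdct, design, ci_level = 0.95,
                          min_ct_detect = 35) {
  if (ci_level <= 0 || ci_level >= 1) {
    stop_mirct("ci_level must be in (0,1)", "config")
  }
  grp <- stats::setNames(as.character(design$group), design$sample_id)
  unknown <- setdiff(unique(mdct$sample_id), names(grp))
  if (length(unknown)) {
    stop_mirct(sprintf("sample(s) missing from the sample sheet: %s",
                       paste(unknown, collapse = ", ")), "data")
  }
  res <- lapply(split(mdct, mdct$assay_id), function(a) {
    g <- grp[a$sample_id]
    x1 <- a$minus_dct[g == "PGRN+" & !is.na(a$minus_dct)]
    x2 <- a$minus_dct[g == "PGRN-" & !is.na(a$minus_dct)]
    n_all <- length(a$ct)
    detect <- stats::median(a$ct, na.rm = TRUE) <= min_ct_detect &&
      mean(is.na(a$ct)) <= 0.5
    if (length(x1) < 2L || length(x2) < 2L) {
      return(data.frame(assay_id = a$assay_id[1L], n_g1 = length(x1),
                        n_g2 = length(x2), d = NA_real_, fc = NA_real_,
                        ci_lo = NA_real_, ci_hi = NA_real_, t = NA_real_,
                        p = NA_real_, degenerate = TRUE,
                        detectable = detect, stringsAsFactors = FALSE))
    }
    tt <- two_sample_t(x1, x2, "pooled")
    se <- if (is.finite(tt$t) && tt$t != 0) tt$diff / tt$t else {
      sp2 <- (sum((x1 - mean(x1))^2) + sum((x2 - mean(x2))^2)) / tt$df
      sqrt(sp2 * (1 / length(x1) + 1 / length(x2)))
    }
    crit <- stats::qt(1 - (1 - ci_level) / 2, tt$df)
    data.frame(assay_id = a$assay_id[1L],
               n_g1 = length(x1), n_g2 = length(x2),
               d = tt$diff, fc = 2 ^ tt$diff,
               ci_lo = 2 ^ (tt$diff - crit * se),
               ci_hi = 2 ^ (tt$diff + crit * se),
               t = tt$t, p = tt$p, degenerate = tt$degenerate,
               detectable = detect, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, res)
  rownames(tab) <- NULL
  structure(list(table = tab, ci_level = ci_level,
                 min_ct_detect = min_ct_detect, call = match.call()),
            class = "qpcr_validation")
}

#' Run the full qPCR validation arm on a well table
#'
#' Convenience wrapper: [reconcile_duplicates()] then [delta_ct()] then
#' [qpcr_validate()].
#'
#' @param wells a [qpcr_wells()] table.
#' @param design a [group_design()].
#' @param dup_threshold duplicate disagreement threshold (default 2 Ct).
#' @param ci_level confidence level (default 0.95).
#' @param min_ct_detect detectability bound (default 35).
#' @return a `qpcr_validation` object.
#' @export
qpcr_pipeline <- function(wells, design, dup_threshold = 2,
                          ci_level = 0.95, min_ct_detect = 35) {
  rec <- reconcile_duplicates(wells, threshold = dup_threshold)
  mdct <- delta_ct(rec)
  qpcr_validate(mdct, design, ci_level = ci_level,
                min_ct_detect = min_ct_detect)
}

#' Detectability flags for reconciled assays
#'
#' An assay is undetectable when its median reconciled Ct exceeds
#' `min_ct_detect` (low expression means high Ct) or more than half its
#' samples are missing.
#'
#' @param reconciled output of [reconcile_duplicates()].
#' @param min_ct_detect Ct bound (default 35).
#' @return named logical vector (TRUE = detectable).
#' @export
detectability_check <- function(reconciled, min_ct_detect = 35) {
  df <- as.data.frame(reconciled)
  vapply(split(df, df$assay_id), function(a) {
    stats::median(a$ct, na.rm = TRUE) <= min_ct_detect &&
      mean(is.na(a$ct)) <= 0.5
  }, logical(1))
}

#' @export
print.qpcr_validation <- function(x, ...) {
  cat(sprintf("qPCR validation: %d assay(s), %d%% CI\n",
              nrow(x$table), round(100 * x$ci_level)))
  show <- x$table[, c("assay_id", "n_g1", "n_g2", "fc", "ci_lo", "ci_hi",
                      "p", "detectable")]
  print(format(show, digits = 3), row.names = FALSE)
  invisible(x)
}

#' @export
summary.qpcr_validation <- function(object, ...) {
  tab <- object$table
  cat(sprintf("%d assay(s): %d detectable, %d significant at p < 0.05\n",
              nrow(tab), sum(tab$detectable),
              sum(tab$p < 0.05 & tab$detectable, na.rm = TRUE)))
  invisible(object)
}

#' Fold-change plot of a qPCR validation
#'
#' Point estimates with confidence bars on a log2 axis, unity line drawn.
#'
#' @param x a `qpcr_validation` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.qpcr_validation <- function(x, ...) {
  tab <- x$table[!is.na(x$table$fc), ]
  n <- nrow(tab)
  graphics::plot(seq_len(n), tab$fc, log = "y", xaxt = "n", pch = 19,
                 ylim = range(c(tab$ci_lo, tab$ci_hi), na.rm = TRUE),
                 xlab = "", ylab = "fold change (PGRN+ / PGRN-)", ...)
  graphics::axis(1, at = seq_len(n), labels = tab$assay_id, las = 2,
                 cex.axis = 0.8)
  graphics::segments(seq_len(n), tab$ci_lo, seq_len(n), tab$ci_hi)
  graphics::abline(h = 1, lty = 2)
  invisible(x)
}
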