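#' Ct matrix container
#'
#' A `ct_matrix` is a numeric matrix of qPCR cycle-threshold (Ct) values
#' with assays in rows and samples in columns, plus a `stage` attribute
#' recording where it sits in the preprocessing pipeline. Lower Ct means
#' higher expression (one Ct unit is about a 2-fold difference in abundance
#' at perfect amplification efficiency). Missing wells are `NA`.
#'
#' @param values numeric matrix (assays x samples) with unique, non-empty
#'   rownames (assay ids) and colnames (sample ids); `NA` marks missing.
#' @param stage pipeline stage tag, one of `"raw"`, `"filtered"`,
#'   `"normalized"`, `"imputed"`, `"shrunk"`.
#' @return a `ct_matrix` object.
#' @export
ct_matrix <- function(values, stage = "raw") {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_mirct("`values` must be a numeric matrix", "data")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop_mirct("ct_matrix requires assay rownames and sample colnames", "data")
  }
  if (anyDuplicated(rownames(values))) {
    dup <- rownames(values)[duplicated(rownames(values))][1L]
    stop_mirct(sprintf("duplicate assay id: '%s'", dup), "data")
  }
  if (anyDuplicated(colnames(values))) {
    dup <- colnames(values)[duplicated(colnames(values))][1L]
    stop_mirct(sprintf("duplicate sample id: '%s'", dup), "data")
  }
  if (any(!is.finite(values) & !is.na(values))) {
    stop_mirct("non-finite Ct values present (Inf/NaN)", "data")
  }
  stage <- match.arg(stage, ct_stages())
  structure(values, stage = stage, class = c("ct_matrix", class(values)))
}

ct_stages <- function() c("raw", "filtered", "normalized", "imputed", "shrunk")

#' @export
print.ct_matrix <- function(x, ...) {
  cat(sprintf("ct_matrix: %d assays x %d samples [stage: %s]\n",
              nrow(x), ncol(x), ct_stage(x)))
  nm <- sum(is.na(x))
  cat(sprintf("  missing cells: %d (%.1f%%)\n", nm, 100 * nm / length(x)))
  rng <- range(x, na.rm = TRUE)
  cat(sprintf("  Ct range: %.2f - %.2f\n", rng[1], rng[2]))
  invisible(x)
}

#' Pipeline stage of a Ct matrix
#' @param x a `ct_matrix`.
#' @return the stage tag string.
#' @export
ct_stage <- function(x) attr(x, "stage") %||% "raw"

set_stage <- function(x, stage) {
  attr(x, "stage") <- match.arg(stage, ct_stages())
  x
}

# Enforce that `x` has reached (at least) one of the stages in `allowed`;
# stage transitions only ever move forward through ct_stages().
check_stage <- function(x, allowed, op) {
  st <- ct_stage(x)
  if (!st %in% allowed) {
    stop_mirct(sprintf(
      "%s expects a matrix at stage %s, got '%s'",
      op, paste(sQuote(allowed), collapse = " or "), st), "data")
  }
  invisible(st)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# classed conditions so callers (and the CLI) can map errors to exit codes:
# config errors -> 2, data errors -> 3, statistical degeneracy -> 4
stop_mirct <- function(msg, class = c("config", "data", "degenerate"),
                       call = sys.call(-1)) {
  class <- match.arg(class)
  stop(errorCondition(msg,
                      class = c(paste0("mirct_", class, "_error"),
                                "mirct_error", "error", "condition"),
                      call = call))
}

#' Sample design for a two-group comparison
#'
#' Validates a sample sheet: one row per sample with the PGRN mutation
#' group, tissue, and FTLD-TDP pathology subtype. The comparison is always
#' `PGRN+` (carriers, group 1) versus `PGRN-` (non-carriers, group 2).
#'
#' @param sample_id character vector of unique sample ids.
#' @param group `"PGRN+"` or `"PGRN-"` per sample.
#' @param tissue `"cortex"` or `"cerebellum"` per sample (recycled).
#' @param subtype `"type1"`, `"type2"`, `"type3"` or `"n/a"` (recycled).
#' @return a `group_design` data frame.
#' @export
group_design <- function(sample_id, group, tissue = "cortex",
                         subtype = "n/a") {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id)) {
    stop_mirct(sprintf("duplicate sample id: '%s'",
                       sample_id[duplicated(sample_id)][1L]), "data")
  }
  group <- as.character(group)
  bad <- setdiff(unique(group), c("PGRN+", "PGRN-"))
  if (length(bad)) {
    stop_mirct(sprintf("unknown group '%s'; allowed: PGRN+, PGRN-", bad[1L]),
               "data")
  }
  tissue <- rep_len(as.character(tissue), length(sample_id))
  bad <- setdiff(unique(tissue), c("cortex", "cerebellum"))
  if (length(bad)) {
    stop_mirct(sprintf("unknown tissue '%s'; allowed: cortex, cerebellum",
                       bad[1L]), "data")
  }
  subtype <- rep_len(as.character(subtype), length(sample_id))
  bad <- setdiff(unique(subtype), c("type1", "type2", "type3", "n/a"))
  if (length(bad)) {
    stop_mirct(sprintf(
      "unknown subtype '%s'; allowed: type1, type2, type3, n/a", bad[1L]),
      "data")
  }
  structure(
    data.frame(sample_id = sample_id,
               group = factor(group, levels = c("PGRN+", "PGRN-")),
               tissue = tissue, subtype = subtype,
               stringsAsFactors = FALSE),
    class = c("group_design", "data.frame"))
}

# Align a design to the columns of a Ct matrix (every sample must be
# labelled) and return it in matrix column order.
align_design <- function(design, x) {
  missing <- setdiff(colnames(x), design$sample_id)
  if (length(missing)) {
    stop_mirct(sprintf("sample(s) missing from the sample sheet: %s",
                       paste(missing, collapse = ", ")), "data")
  }
  design[match(colnames(x), design$sample_id), , drop = FALSE]
}
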