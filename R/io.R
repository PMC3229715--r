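#' Read a tab-delimited Ct table
#'
#' Expects a header row of sample ids and a first column of assay ids;
#' missing wells are encoded as an empty field or `"NA"`. Malformed input
#' is rejected, not coerced, and every error names the offending row or
#' column. Ct values above 40 (beyond the usual instrument cycle range)
#' are accepted with a warning.
#'
#' @param path path to a TSV file.
#' @param stage stage tag to attach (default `"raw"`).
#' @return a [ct_matrix()].
#' @export
read_ct_table <- function(path, stage = "raw") {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) {
    stop_mirct(sprintf("'%s': need a header and at least one assay row", path),
               "data")
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  ncol_expected <- length(header)
  samples <- header[-1L]
  body <- fields[-1L]
  n <- lengths(body)
  # trailing empty fields are dropped by strsplit; pad (they encode NA)
  short <- n < ncol_expected
  body[short] <- lapply(body[short], function(f)
    c(f, rep("", ncol_expected - length(f))))
  if (any(lengths(body) != ncol_expected)) {
    bad <- which(lengths(body) != ncol_expected)[1L]
    stop_mirct(sprintf("'%s': ragged row %d (assay '%s'): %d fields, expected %d",
                       path, bad + 1L, body[[bad]][1L],
                       lengths(body)[bad], ncol_expected), "data")
  }
  assays <- vapply(body, `[[`, character(1), 1L)
  if (anyDuplicated(assays)) {
    stop_mirct(sprintf("'%s': duplicated assay row '%s'",
                       path, assays[duplicated(assays)][1L]), "data")
  }
  if (anyDuplicated(samples)) {
    stop_mirct(sprintf("'%s': duplicated sample column '%s'",
                       path, samples[duplicated(samples)][1L]), "data")
  }
  raw <- t(vapply(body, function(f) f[-1L], character(length(samples))))
  if (length(samples) == 1L) raw <- matrix(raw, ncol = 1L)
  raw[raw == "" | raw == "NA"] <- NA_character_
  vals <- suppressWarnings(array(as.numeric(raw), dim(raw)))
  bad <- which(is.na(vals) & !is.na(raw), arr.ind = TRUE)
  if (nrow(bad)) {
    stop_mirct(sprintf("'%s': non-numeric Ct at assay '%s', sample '%s': '%s'",
                       path, assays[bad[1L, 1L]], samples[bad[1L, 2L]],
                       raw[bad[1L, , drop = FALSE]]), "data")
  }
  dimnames(vals) <- list(assays, samples)
  n_high <- sum(vals > 40, na.rm = TRUE)
  if (n_high > 0L) {
    warning(sprintf("%d Ct value(s) above 40 in '%s'", n_high, path))
  }
  ct_matrix(vals, stage = stage)
}

#' Write a Ct table
#'
#' Writes the tab-delimited format [read_ct_table()] reads; missing wells
#' are written as `"NA"`. Round-trips at full printed precision.
#'
#' @param x a `ct_matrix`.
#' @param path output path.
#' @export
write_ct_table <- function(x, path) {
  chr <- trimws(formatC(unclass(x), digits = 17, format = "g"))
  chr[is.na(x)] <- "NA"
  dim(chr) <- dim(x)
  lines <- c(paste(c("assay_id", colnames(x)), collapse = "\t"),
             paste(rownames(x), apply(chr, 1L, paste, collapse = "\t"),
                   sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a sample sheet
#'
#' TSV with columns `sample_id`, `group`, `tissue`, `subtype`; group must
#' be `PGRN+` or `PGRN-`.
#'
#' @param path path to a TSV file.
#' @return a [group_design()].
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("sample_id", "group", "tissue", "subtype")
  if (nrow(df) == 0L) {
    stop_mirct(sprintf("'%s': empty sample sheet", path), "data")
  }
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop_mirct(sprintf("'%s': missing column(s): %s",
                       path, paste(miss, collapse = ", ")), "data")
  }
  group_design(df$sample_id, df$group, df$tissue, df$subtype)
}

#' Read per-miRNA predicted-target lists
#'
#' Two-column TSV (`mirna_id`, `gene_symbol`), TargetScan-style. Gene
#' symbols are upper-cased and de-duplicated per miRNA.
#'
#' @param path path to a TSV file (header optional, detected by name).
#' @return named list: miRNA id -> character vector of target gene symbols.
#' @export
read_target_lists <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, header = FALSE,
                          col.names = c("mirna_id", "gene_symbol"),
                          colClasses = "character")
  if (nrow(df) && tolower(df$mirna_id[1L]) %in% c("mirna_id", "mirna")) {
    df <- df[-1L, , drop = FALSE]
  }
  if (any(!nzchar(df$gene_symbol))) {
    stop_mirct(sprintf("'%s': empty gene symbol at row %d",
                       path, which(!nzchar(df$gene_symbol))[1L]), "data")
  }
  df$gene_symbol <- toupper(df$gene_symbol)
  lapply(split(df$gene_symbol, df$mirna_id), unique)
}

#' Read an mRNA differential-expression table
#'
#' Four-column TSV: `probeset_id`, `gene_symbol`, `direction` (`up`/`down`),
#' `p_value`. Probeset ids must be unique and p-values in [0, 1].
#'
#' @param path path to a TSV file.
#' @return data frame with normalized (upper-case) gene symbols.
#' @export
read_mrna_de_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("probeset_id", "gene_symbol", "direction", "p_value")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop_mirct(sprintf("'%s': missing column(s): %s",
                       path, paste(miss, collapse = ", ")), "data")
  }
  validate_mrna_de_table(df, path)
}

validate_mrna_de_table <- function(df, what = "DE table") {
  if (anyDuplicated(df$probeset_id)) {
    stop_mirct(sprintf("%s: duplicated probeset id '%s'", what,
                       df$probeset_id[duplicated(df$probeset_id)][1L]), "data")
  }
  bad <- which(!is.finite(df$p_value) | df$p_value < 0 | df$p_value > 1)
  if (length(bad)) {
    stop_mirct(sprintf("%s: p-value outside [0,1] at probeset '%s': %s",
                       what, df$probeset_id[bad[1L]], df$p_value[bad[1L]]),
               "data")
  }
  bad <- setdiff(unique(df$direction), c("up", "down"))
  if (length(bad)) {
    stop_mirct(sprintf("%s: unknown direction '%s'; allowed: up, down",
                       what, bad[1L]), "data")
  }
  df$gene_symbol <- toupper(df$gene_symbol)
  df
}

#' Read a duplicate-well qPCR table
#'
#' TSV with columns `assay_id`, `sample_id`, `well_replicate` (1 or 2) and
#' `ct` (`NA` for undetermined wells). At most two wells per assay-sample
#' pair; the endogenous-control assay must be present for every sample.
#'
#' @param path path to a TSV file.
#' @param control_assay_id endogenous control assay (default `"RNU48"`).
#' @return a `qpcr_wells` data frame with a `control_assay_id` attribute.
#' @export
read_qpcr_wells <- function(path, control_assay_id = "RNU48") {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("assay_id", "sample_id", "well_replicate", "ct")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop_mirct(sprintf("'%s': missing column(s): %s",
                       path, paste(miss, collapse = ", ")), "data")
  }
  qpcr_wells(df, control_assay_id)
}

#' Construct/validate a qPCR well table
#' @param df data frame with `assay_id`, `sample_id`, `well_replicate`, `ct`.
#' @param control_assay_id endogenous control assay id.
#' @return a `qpcr_wells` data frame.
#' @export
qpcr_wells <- function(df, control_assay_id = "RNU48") {
  key <- paste(df$assay_id, df$sample_id, sep = "\r")
  over <- names(which(table(key) > 2L))
  if (length(over)) {
    stop_mirct(sprintf(">2 wells for assay/sample '%s'",
                       gsub("\r", " / ", over[1L])), "data")
  }
  if (!control_assay_id %in% df$assay_id) {
    stop_mirct(sprintf("control assay '%s' absent from well table",
                       control_assay_id), "data")
  }
  samples <- unique(df$sample_id)
  ctrl <- df[df$assay_id == control_assay_id, ]
  no_ctrl <- setdiff(samples, ctrl$sample_id)
  if (length(no_ctrl)) {
    stop_mirct(sprintf("control assay '%s' missing for sample(s): %s",
                       control_assay_id, paste(no_ctrl, collapse = ", ")),
               "data")
  }
  structure(df, control_assay_id = control_assay_id,
            class = c("qpcr_wells", "data.frame"))
}

#' Write a qPCR well table
#' @param wells a `qpcr_wells` data frame.
#' @param path output path.
#' @export
write_qpcr_wells <- function(wells, path) {
  utils::write.table(as.data.frame(wells), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
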