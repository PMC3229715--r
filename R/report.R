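#' Adjusted, median-centered report matrix
#'
#' Prepares a normalized Ct matrix for heat-map and boxplot display:
#' values become `40 - Ct` (40 being the instrument's cycle ceiling), so
#' that a higher adjusted value means higher expression, and each assay is
#' then centered on its median. The per-assay median of the output is 0 by
#' construction, and the adjustment is strictly decreasing in Ct.
#'
#' @param x a normalized or imputed [ct_matrix()].
#' @param constant the adjustment constant (default 40).
#' @return numeric matrix of centered adjusted values (same dimnames).
#' @export
adjusted_ct_matrix <- function(x, constant = 40) {
  v <- constant - unclass(x)
  med <- apply(v, 1L, stats::median, na.rm = TRUE)
  out <- sweep(v, 1L, med)
  class(out) <- "matrix"
  attr(out, "stage") <- NULL
  out
}

#' Per-group five-number summaries of a report matrix
#'
#' For each assay and each group (optionally stratified further by
#' pathology subtype) returns min, first quartile, median, third quartile
#' and max of the adjusted values — the numbers a grouped boxplot draws.
#' Empty groups are omitted with a warning.
#'
#' @param report matrix from [adjusted_ct_matrix()].
#' @param design a [group_design()].
#' @param by `"group"` (default) or `"group_subtype"` to split PGRN- by
#'   FTLD-TDP pathology subtype.
#' @return data frame: `assay_id`, `stratum`, `n`, `min`, `q1`, `median`,
#'   `q3`, `max`.
#' @export
group_boxplot_summary <- function(report, design, by = c("group",
                                                         "group_subtype")) {
  by <- match.arg(by)
  design <- design[match(colnames(report), design$sample_id), , drop = FALSE]
  if (anyNA(design$sample_id)) {
    stop_mirct("sample(s) in the matrix are missing from the sample sheet",
               "data")
  }
  strata <- if (by == "group") as.character(design$group) else
    paste(design$group, design$subtype)
  levs <- unique(strata)
  out <- list()
  for (st in levs) {
    cols <- which(strata == st)
    if (length(cols) == 0L) {
      warning(sprintf("stratum '%s' is empty; omitted", st))
      next
    }
    for (a in seq_len(nrow(report))) {
      vals <- report[a, cols]
      vals <- vals[!is.na(vals)]
      if (length(vals) == 0L) next
      q <- stats::quantile(vals, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
      out[[length(out) + 1L]] <- data.frame(
        assay_id = rownames(report)[a], stratum = st, n = length(vals),
        min = q[1L], q1 = q[2L], median = q[3L], q3 = q[4L], max = q[5L],
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

config_get <- function(config, key, default = NULL, required = FALSE) {
  val <- config[[key]]
  if (is.null(val)) {
    if (required) stop_mirct(sprintf("missing config key: '%s'", key),
                             "config")
    return(default)
  }
  val
}

#' Run the full pipeline from a config
#'
#' Orchestrates simulate-or-load, preprocessing, differential expression,
#' and the optional qPCR-validation and target-integration arms, writing
#' all result tables plus a machine-readable run manifest (seed,
#' parameters, per-stage counts) to an output directory. All randomness
#' flows from the single top-level `seed`, so a rerun with the same config
#' reproduces the outputs byte for byte.
#'
#' Config keys (YAML file or list): `seed`, `outdir`; either `simulate:`
#' (arguments of [simulate_array_dataset()]) or `inputs: {ct, design}`
#' (paths); optional `preprocess:`, `diffexp:`, `qpcr: {wells, control,
#' dup_threshold, ci_level}`, `integrate: {de_a, de_b, targets, mirnas}`.
#'
#' @param config path to a YAML file or an equivalent named list.
#' @return (invisibly) list with the fitted objects and the manifest.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop_mirct("config must be a list or YAML path",
                                   "config")
  outdir <- config_get(config, "outdir", required = TRUE)
  seed <- config_get(config, "seed", required = TRUE)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    sim_args$seed <- seed
    sim <- do.call(simulate_array_dataset, sim_args)
    ct <- sim$ct; design <- sim$design
  } else {
    inputs <- config_get(config, "inputs", required = TRUE)
    ct <- read_ct_table(config_get(inputs, "ct", required = TRUE))
    design <- read_sample_sheet(config_get(inputs, "design", required = TRUE))
  }

  pp <- config_get(config, "preprocess", list())
  pre <- preprocess_ct(ct,
                       max_ct = config_get(pp, "max_ct", 35),
                       max_missing_frac = config_get(pp, "max_missing_frac",
                                                     0.20),
                       span = config_get(pp, "span", 2 / 3),
                       k = config_get(pp, "k", 10L),
                       shrink_c = config_get(pp, "shrink_c", 3))
  write_ct_table(pre$ct, file.path(outdir, "processed.tsv"))

  de <- config_get(config, "diffexp", list())
  fit <- mir_diffexp(pre$ct, design,
                     n_perm = config_get(de, "n_perm", 1000L),
                     alpha = config_get(de, "alpha", 0.05),
                     variance = config_get(de, "variance", "pooled"),
                     seed = seed)
  utils::write.table(fit$table, file.path(outdir, "diffexp.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cand <- rank_candidates(fit)
  utils::write.table(cand, file.path(outdir, "candidates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  rep_mat <- adjusted_ct_matrix(pre$ct)
  utils::write.table(
    data.frame(assay_id = rownames(rep_mat), rep_mat, check.names = FALSE),
    file.path(outdir, "report_matrix.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  box <- group_boxplot_summary(rep_mat, design)
  utils::write.table(box, file.path(outdir, "boxplot_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  val <- NULL
  if (!is.null(config$qpcr)) {
    qp <- config$qpcr
    wells <- read_qpcr_wells(config_get(qp, "wells", required = TRUE),
                             config_get(qp, "control", "RNU48"))
    val <- qpcr_pipeline(wells, design,
                         dup_threshold = config_get(qp, "dup_threshold", 2),
                         ci_level = config_get(qp, "ci_level", 0.95))
    utils::write.table(val$table, file.path(outdir, "validation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  integ <- NULL
  if (!is.null(config$integrate)) {
    ig <- config$integrate
    integ <- integrate_targets(
      read_mrna_de_table(config_get(ig, "de_a", required = TRUE)),
      read_mrna_de_table(config_get(ig, "de_b", required = TRUE)),
      read_target_lists(config_get(ig, "targets", required = TRUE)),
      config_get(ig, "mirnas", required = TRUE),
      alpha = config_get(ig, "alpha", 0.05))
    write_integration(integ, file.path(outdir, "genes.tsv"))
  }

  manifest <- list(
    seed = seed,
    parameters = list(
      preprocess = pre$report[c("n_assays_raw", "n_samples")],
      n_perm = fit$n_perm, alpha = fit$alpha, variance = fit$variance),
    stage_counts = pre$report[c("n_excluded", "n_assays_retained",
                                "n_censored_cells", "n_imputed_cells",
                                "n_shrunk_cells")],
    results = list(
      n_tested = nrow(fit$table), n_candidates = nrow(cand),
      overall_p = fit$overall_p, smallest_q = min(fit$table$q_emp),
      n_validated = if (is.null(val)) NA else
        sum(val$table$p < 0.05 & val$table$detectable, na.rm = TRUE),
      n_integrated_genes = if (is.null(integ)) NA else integ$total))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(ct = pre$ct, preprocess_report = pre$report, fit = fit,
                 candidates = cand, validation = val, integration = integ,
                 manifest = manifest))
}
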