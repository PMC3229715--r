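#' Genes significantly down-regulated in both tissues
#'
#' From two mRNA differential-expression tables (e.g. frontal cortex and
#' cerebellum), selects the genes with at least one probeset that is
#' down-regulated at `p < alpha` in each table (strict inequality; the
#' any-probeset rule performs the probeset-to-gene collapse).
#'
#' @param table_a,table_b DE tables as from [read_mrna_de_table()].
#' @param alpha significance threshold (default 0.05).
#' @return sorted character vector of gene symbols (upper-case).
#' @export
select_down_in_both <- function(table_a, table_b, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop_mirct("alpha must be in (0,1)", "config")
  table_a <- validate_mrna_de_table(as.data.frame(table_a), "table_a")
  table_b <- validate_mrna_de_table(as.data.frame(table_b), "table_b")
  if (nrow(table_a) == 0L || nrow(table_b) == 0L) {
    warning("empty DE table; no genes selected")
    return(character(0))
  }
  qualify <- function(tb) {
    unique(tb$gene_symbol[tb$direction == "down" & tb$p_value < alpha])
  }
  sort(intersect(qualify(table_a), qualify(table_b)))
}

#' Anti-correlated miRNA-mRNA target integration
#'
#' Intersects a set of down-regulated genes with the predicted targets of
#' up-regulated candidate miRNAs: a gene is kept iff it is down-regulated
#' (in both tissues, per [select_down_in_both()]) and is a predicted target
#' of at least one candidate. This is the anti-correlation pattern expected
#' under miRNA-mediated repression — where the miRNA is up, its targets
#' should be down.
#'
#' @param down_genes character vector of down-in-both gene symbols.
#' @param targets named list: miRNA id -> character vector of predicted
#'   target gene symbols (as from [read_target_lists()]).
#' @param candidate_mirnas the candidate miRNA ids; every one must be
#'   present in `targets`.
#' @return a `mir_integration` object: `genes` data frame (`gene`,
#'   `n_mirnas`, `mirnas` semicolon-joined), `tally` (multiplicity ->
#'   gene count), `total` genes.
#' @export
anti_correlate <- function(down_genes, targets, candidate_mirnas) {
  absent <- setdiff(candidate_mirnas, names(targets))
  if (length(absent)) {
    stop_mirct(sprintf("candidate miRNA(s) absent from the target map: %s",
                       paste(absent, collapse = ", ")), "data")
  }
  down_genes <- toupper(down_genes)
  hits <- lapply(candidate_mirnas, function(m) {
    intersect(down_genes, toupper(targets[[m]]))
  })
  names(hits) <- candidate_mirnas
  genes <- sort(unique(unlist(hits)))
  per_gene <- lapply(genes, function(g) {
    sort(candidate_mirnas[vapply(hits, function(h) g %in% h, logical(1))])
  })
  n <- vapply(per_gene, length, integer(1))
  tab <- data.frame(
    gene = genes,
    n_mirnas = n,
    mirnas = vapply(per_gene, paste, character(1), collapse = ";"),
    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$n_mirnas, tab$gene), , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(genes = tab,
                 mirna_map = stats::setNames(per_gene, genes),
                 candidate_mirnas = candidate_mirnas,
                 tally = tally_by_mirna_count_tab(tab),
                 total = nrow(tab)),
            class = "mir_integration")
}

#' Multiplicity tally of an integration result
#'
#' Histogram of genes by how many candidate miRNAs target them.
#'
#' @param result a [anti_correlate()] result.
#' @return named integer vector: multiplicity (as name) -> gene count.
#' @export
tally_by_mirna_count <- function(result) {
  stopifnot(inherits(result, "mir_integration"))
  result$tally
}

tally_by_mirna_count_tab <- function(tab) {
  if (nrow(tab) == 0L) return(stats::setNames(integer(0), character(0)))
  tt <- table(tab$n_mirnas)
  stats::setNames(as.integer(tt), names(tt))
}

#' Full integration stage
#'
#' [select_down_in_both()] followed by [anti_correlate()].
#'
#' @param table_a,table_b mRNA DE tables for the two tissues.
#' @param targets per-miRNA predicted target lists.
#' @param candidate_mirnas candidate miRNA ids.
#' @param alpha significance threshold (default 0.05).
#' @return a `mir_integration` object.
#' @export
integrate_targets <- function(table_a, table_b, targets, candidate_mirnas,
                              alpha = 0.05) {
  down <- select_down_in_both(table_a, table_b, alpha = alpha)
  anti_correlate(down, targets, candidate_mirnas)
}

#' @export
print.mir_integration <- function(x, ...) {
  cat(sprintf(
    "miRNA-mRNA anti-correlation: %d gene(s) across %d candidate miRNA(s)\n",
    x$total, length(x$candidate_mirnas)))
  if (length(x$tally)) {
    for (k in rev(names(x$tally))) {
      cat(sprintf("  targeted by %s miRNA(s): %d gene(s)\n",
                  k, x$tally[[k]]))
    }
  }
  invisible(x)
}

#' @export
summary.mir_integration <- function(object, ...) {
  print(object)
  if (object$total) {
    cat("\n")
    print(format(object$genes), row.names = FALSE)
  }
  invisible(object)
}

#' Write an integration result as TSV
#' @param result a `mir_integration` object.
#' @param path output path.
#' @export
write_integration <- function(result, path) {
  utils::write.table(result$genes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
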