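#' Simulate a miRNA Ct array dataset with planted truth
#'
#' Generates a raw assays-x-samples Ct matrix emulating a TaqMan low-density
#' array study of two patient groups (default: 8 PGRN mutation carriers vs
#' 32 non-carriers over 664 assays). The generative model is
#' `Ct = baseline(assay) + effect(assay) * I(group 1) + shift(sample) + noise`,
#' with expression-dependent missingness: a well drops out with probability
#' `plogis(missing_slope * (Ct - missing_midpoint))`, so dim wells (high Ct)
#' are the ones lost, coupling missingness to the detection filter the way
#' real plates do. Differential assays get a signed Ct shift in group 1
#' (negative shift = higher expression, since lower Ct means more
#' transcript); signs are split as evenly as possible between up and down.
#'
#' @param n_assays number of miRNA assays (default 664).
#' @param n_group1,n_group2 samples per group (defaults 8 and 32).
#' @param n_true_de number of truly differential assays (default 20).
#' @param effect_range_ct magnitude range of the planted Ct shift
#'   (default `c(0.5, 2)` cycles).
#' @param baseline_ct_mean,baseline_ct_sd distribution of per-assay
#'   baseline Ct (defaults 28 and 3).
#' @param sample_shift_sd sd of the per-sample additive intensity shift
#'   (default 0.5 Ct) that normalization should remove.
#' @param noise_sd well-level noise sd (default 0.6 Ct).
#' @param missing_midpoint,missing_slope logistic dropout parameters
#'   (defaults 34 Ct and 0.35 per Ct).
#' @param censor_ct detection limit carried as metadata (default 35);
#'   values beyond it are reported as measured and handled by the filter.
#' @param seed optional integer seed.
#' @return list with `ct` (raw [ct_matrix()]), `design` ([group_design()])
#'   and `truth` (list: `de_assay_ids`, `effect_ct` — signed shifts, named
#'   by assay).
#' @export
simulate_array_dataset <- function(n_assays = 664L, n_group1 = 8L,
                                   n_group2 = 32L, n_true_de = 20L,
                                   effect_range_ct = c(0.5, 2),
                                   baseline_ct_mean = 28,
                                   baseline_ct_sd = 3,
                                   sample_shift_sd = 0.5,
                                   noise_sd = 0.6,
                                   missing_midpoint = 34,
                                   missing_slope = 0.35,
                                   censor_ct = 35,
                                   seed = NULL) {
  if (n_assays < 1L || n_group1 < 1L || n_group2 < 1L) {
    stop_mirct("n_assays, n_group1 and n_group2 must be positive", "config")
  }
  if (n_true_de < 0L || n_true_de > n_assays) {
    stop_mirct("n_true_de must lie in [0, n_assays]", "config")
  }
  if (baseline_ct_sd < 0 || sample_shift_sd < 0 || noise_sd < 0) {
    stop_mirct("standard deviations must be non-negative", "config")
  }
  if (length(effect_range_ct) != 2L || any(effect_range_ct <= 0) ||
      effect_range_ct[2L] < effect_range_ct[1L]) {
    stop_mirct("effect_range_ct must be a positive increasing interval",
               "config")
  }
  if (!is.null(seed)) set.seed(seed)

  n <- n_group1 + n_group2
  assay_ids <- sprintf("miR-sim-%04d", seq_len(n_assays))
  sample_ids <- sprintf("S%03d", seq_len(n))
  grp1 <- c(rep(TRUE, n_group1), rep(FALSE, n_group2))

  baseline <- stats::rnorm(n_assays, baseline_ct_mean, baseline_ct_sd)
  effect <- numeric(n_assays)
  de_idx <- integer(0)
  if (n_true_de > 0L) {
    # plant signal on assays expressed clear of the dropout zone (expected
    # per-well dropout under ~20%), mirroring a study whose candidates are
    # by construction among the detectable assays
    eligible <- which(baseline <= missing_midpoint - 4)
    if (length(eligible) < n_true_de) eligible <- seq_len(n_assays)
    de_idx <- sort(eligible[sample.int(length(eligible), n_true_de)])
    mag <- stats::runif(n_true_de, effect_range_ct[1L], effect_range_ct[2L])
    sign <- rep(c(-1, 1), length.out = n_true_de)
    if (n_true_de > 1L) sign <- sample(sign)
    effect[de_idx] <- sign * mag
  }
  shift <- stats::rnorm(n, 0, sample_shift_sd)

  latent <- outer(baseline, rep(1, n)) +
    outer(effect, as.numeric(grp1)) +
    outer(rep(1, n_assays), shift) +
    matrix(stats::rnorm(n_assays * n, 0, noise_sd), n_assays, n)
  p_miss <- stats::plogis(missing_slope * (latent - missing_midpoint))
  obs <- latent
  obs[stats::runif(length(latent)) < p_miss] <- NA_real_
  dimnames(obs) <- list(assay_ids, sample_ids)

  design <- group_design(
    sample_ids,
    ifelse(grp1, "PGRN+", "PGRN-"),
    tissue = "cortex",
    subtype = ifelse(grp1, "type1",
                     paste0("type", rep_len(1:3, n))))

  list(ct = ct_matrix(obs, "raw"),
       design = design,
       truth = list(
         de_assay_ids = assay_ids[de_idx],
         effect_ct = stats::setNames(effect[de_idx], assay_ids[de_idx]),
         latent = structure(latent, dimnames = list(assay_ids, sample_ids)),
         censor_ct = censor_ct))
}

#' Simulate a duplicate-well qPCR validation plate
#'
#' Produces two technical-replicate wells per sample for each requested
#' assay plus the endogenous control (RNU48, never differential). Each
#' sample carries an additive shift shared by all its wells — removed by
#' the delta-Ct step — and with probability `outlier_rate` one well of a
#' pair is displaced upward by more than 2 cycles, to exercise the
#' duplicate-reconciliation rule.
#'
#' @param assay_ids target assays to plate.
#' @param design a [group_design()]; wells are generated for its samples.
#' @param effect_ct named numeric: signed Ct shift applied to group-1
#'   samples per assay (negative = higher expression in group 1); assays
#'   not named get zero. The control assay is always flat.
#' @param baseline_ct named or scalar baseline Ct per assay (default 27);
#'   the control defaults to 24.
#' @param dup_noise_sd technical noise sd per well (default 0.25 Ct).
#' @param outlier_rate probability a pair contains a displaced well
#'   (default 0).
#' @param sample_shift_sd sd of the per-sample shift (default 0.5 Ct).
#' @param control_assay_id endogenous control id (default `"RNU48"`).
#' @param seed optional integer seed.
#' @return list with `wells` (a `qpcr_wells` data frame) and `truth`.
#' @export
simulate_qpcr_plate <- function(assay_ids, design, effect_ct = NULL,
                                baseline_ct = 27, dup_noise_sd = 0.25,
                                outlier_rate = 0, sample_shift_sd = 0.5,
                                control_assay_id = "RNU48", seed = NULL) {
  if (length(assay_ids) == 0L) {
    stop_mirct("assay_ids must be non-empty", "config")
  }
  if (outlier_rate < 0 || outlier_rate > 1) {
    stop_mirct("outlier_rate must be a probability", "config")
  }
  if (!is.null(effect_ct)) {
    unknown <- setdiff(names(effect_ct), assay_ids)
    if (length(unknown)) {
      stop_mirct(sprintf("effect for unknown assay id: %s",
                         paste(unknown, collapse = ", ")), "config")
    }
  }
  if (!is.null(seed)) set.seed(seed)

  all_assays <- unique(c(assay_ids, control_assay_id))
  eff <- stats::setNames(numeric(length(all_assays)), all_assays)
  if (!is.null(effect_ct)) eff[names(effect_ct)] <- effect_ct
  eff[control_assay_id] <- 0

  base <- stats::setNames(rep_len(baseline_ct, length(all_assays)), all_assays)
  if (!is.null(names(baseline_ct))) {
    base[names(baseline_ct)] <- baseline_ct
  }
  if (is.null(names(baseline_ct)) || !control_assay_id %in% names(baseline_ct)) {
    base[control_assay_id] <- 24
  }

  samples <- design$sample_id
  grp1 <- design$group == "PGRN+"
  shift <- stats::rnorm(length(samples), 0, sample_shift_sd)

  grid <- expand.grid(assay_id = all_assays, sample_id = samples,
                      stringsAsFactors = FALSE)
  latent <- base[grid$assay_id] +
    eff[grid$assay_id] * grp1[match(grid$sample_id, samples)] +
    shift[match(grid$sample_id, samples)]
  w1 <- latent + stats::rnorm(nrow(grid), 0, dup_noise_sd)
  w2 <- latent + stats::rnorm(nrow(grid), 0, dup_noise_sd)
  is_out <- stats::runif(nrow(grid)) < outlier_rate
  # one-sided displacement of a single well, always > 2 cycles
  disp <- stats::runif(nrow(grid), 2.5, 6)
  which_well <- stats::runif(nrow(grid)) < 0.5
  w1[is_out & which_well] <- w1[is_out & which_well] + disp[is_out & which_well]
  w2[is_out & !which_well] <- w2[is_out & !which_well] + disp[is_out & !which_well]

  wells <- data.frame(
    assay_id = rep(grid$assay_id, 2L),
    sample_id = rep(grid$sample_id, 2L),
    well_replicate = rep(1:2, each = nrow(grid)),
    ct = c(w1, w2),
    stringsAsFactors = FALSE)
  ord <- order(wells$assay_id, wells$sample_id, wells$well_replicate)
  wells <- wells[ord, ]
  rownames(wells) <- NULL

  list(wells = qpcr_wells(wells, control_assay_id),
       truth = list(effect_ct = eff, baseline_ct = base,
                    outlier = stats::setNames(is_out,
                        paste(grid$assay_id, grid$sample_id))))
}

#' Simulate target lists and mRNA DE tables for the integration stage
#'
#' Builds the three inputs of the anti-correlation analysis with planted
#' truth: a per-miRNA predicted-target map, and two mRNA
#' differential-expression tables (cortex-like and cerebellum-like).
#' Planted genes are significantly down-regulated in both tissues and
#' assigned to their planted multiplicity of candidate miRNAs; decoy genes
#' are constructed to fail exactly one filter each — down in a single
#' tissue only, up-regulated, non-significant, or down in both but
#' predicted by no candidate miRNA.
#'
#' @param planted data frame with columns `gene` and `mirna`: the planted
#'   gene-to-miRNA assignments (one row per pair). May be empty.
#' @param candidate_mirnas the candidate miRNA set; defaults to the miRNAs
#'   appearing in `planted`.
#' @param n_decoys number of decoy genes (default 40), cycled over the
#'   four decoy classes.
#' @param alpha significance threshold the fixtures are built around
#'   (default 0.05).
#' @param seed optional integer seed.
#' @return list with `targets` (miRNA -> gene vector), `de_cortex`,
#'   `de_cerebellum` (DE tables) and `truth`.
#' @export
simulate_integration_fixtures <- function(planted,
                                          candidate_mirnas = NULL,
                                          n_decoys = 40L,
                                          alpha = 0.05,
                                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  planted <- as.data.frame(planted)
  if (nrow(planted) > 0L &&
      !all(c("gene", "mirna") %in% names(planted))) {
    stop_mirct("planted needs columns `gene` and `mirna`", "config")
  }
  if (is.null(candidate_mirnas)) {
    candidate_mirnas <- unique(planted$mirna)
  }
  if (nrow(planted) > 0L) {
    planted$gene <- toupper(planted$gene)
    per_gene <- table(planted$gene)
    if (any(per_gene > length(candidate_mirnas))) {
      stop_mirct("planted multiplicity exceeds the number of candidate miRNAs",
                 "config")
    }
  }
  planted_genes <- unique(planted$gene)

  decoy_genes <- sprintf("DECOY%04d", seq_len(n_decoys))
  # class 1: down in cortex only; 2: up in both; 3: down both, p >= alpha;
  # 4: down in both tissues but not a predicted target
  decoy_class <- rep_len(1:4, n_decoys)

  targets <- stats::setNames(
    lapply(candidate_mirnas, function(m) {
      sort(unique(planted$gene[planted$mirna == m]))
    }), candidate_mirnas)
  targeted_decoys <- decoy_genes[decoy_class != 4L]
  if (length(targeted_decoys) && length(candidate_mirnas)) {
    hit <- sample(seq_along(candidate_mirnas), length(targeted_decoys),
                  replace = TRUE)
    for (i in seq_along(targeted_decoys)) {
      m <- candidate_mirnas[hit[i]]
      targets[[m]] <- sort(unique(c(targets[[m]], targeted_decoys[i])))
    }
  }

  sig_p <- function(k) stats::runif(k, 1e-4, alpha * 0.9)
  ns_p <- function(k) stats::runif(k, alpha * 1.2, 0.9)

  make_table <- function(tissue) {
    gene <- c(planted_genes, decoy_genes)
    dir <- character(length(gene))
    p <- numeric(length(gene))
    pl <- seq_along(planted_genes)
    dir[pl] <- "down"; p[pl] <- sig_p(length(pl))
    off <- length(planted_genes)
    for (i in seq_len(n_decoys)) {
      j <- off + i
      dir[j] <- switch(decoy_class[i],
                       "down",                       # class 1
                       "up",                         # class 2
                       "down",                       # class 3
                       "down")                       # class 4
      p[j] <- switch(decoy_class[i],
                     if (tissue == "cortex") sig_p(1) else ns_p(1),
                     sig_p(1),
                     ns_p(1),
                     sig_p(1))
    }
    data.frame(probeset_id = sprintf("PS_%s_%04d", tissue, seq_along(gene)),
               gene_symbol = gene, direction = dir, p_value = p,
               stringsAsFactors = FALSE)
  }
  de_cortex <- make_table("cortex")
  de_cerebellum <- make_table("cbl")

  # a second, non-qualifying probeset for the first two planted genes,
  # to exercise the any-probeset gene collapse
  if (length(planted_genes) >= 1L) {
    extra <- planted_genes[seq_len(min(2L, length(planted_genes)))]
    add <- data.frame(
      probeset_id = sprintf("PS_cortex_x%02d", seq_along(extra)),
      gene_symbol = extra, direction = "down", p_value = ns_p(length(extra)),
      stringsAsFactors = FALSE)
    de_cortex <- rbind(de_cortex, add)
  }

  list(targets = targets,
       de_cortex = validate_mrna_de_table(de_cortex, "cortex fixture"),
       de_cerebellum = validate_mrna_de_table(de_cerebellum, "cerebellum fixture"),
       truth = list(planted = planted, decoy_genes = decoy_genes,
                    decoy_class = stats::setNames(decoy_class, decoy_genes)))
}

#' Candidate miRNA-to-gene target assignments
#'
#' The published gene-to-miRNA target assignments for the five candidate
#' miRNAs up-regulated in both frontal cortex and cerebellum of PGRN
#' mutation carriers (miR-922, miR-516a-3p, miR-571, miR-548b-5p,
#' miR-548c-5p): 18 genes, of which BAI3, GK and SLC23A2 are each predicted
#' targets of three of the five miRNAs. Used as the worked example for the
#' integration stage and as planted truth for its fixtures.
#'
#' @return data frame with columns `gene` and `mirna`, one row per
#'   predicted gene-miRNA pair.
#' @export
ftld_candidate_targets <- function() {
  pairs <- list(
    BAI3    = c("miR-922", "miR-548b-5p", "miR-548c-5p"),
    GK      = c("miR-571", "miR-548b-5p", "miR-548c-5p"),
    SLC23A2 = c("miR-922", "miR-548b-5p", "miR-548c-5p"),
    GTDC1   = c("miR-516a-3p", "miR-571"),
    CNR1    = c("miR-548b-5p", "miR-548c-5p"),
    FAM134B = c("miR-548b-5p", "miR-548c-5p"),
    HS2ST1  = c("miR-548b-5p", "miR-548c-5p"),
    MYT1L   = c("miR-548b-5p", "miR-548c-5p"),
    NCAM1   = c("miR-548b-5p", "miR-548c-5p"),
    TMEM135 = c("miR-548b-5p", "miR-548c-5p"),
    ATP8A1  = "miR-922",
    KCNAB1  = "miR-922",
    PTPRD   = "miR-922",
    RASA1   = "miR-922",
    REEP1   = "miR-922",
    SNCA    = "miR-922",
    A2BP1   = "miR-516a-3p",
    ASTN1   = "miR-516a-3p")
  data.frame(gene = rep(names(pairs), lengths(pairs)),
             mirna = unlist(pairs, use.names = FALSE),
             stringsAsFactors = FALSE)
}

#' The five cerebellum-validated candidate miRNAs
#' @return character vector of miRNA ids.
#' @export
ftld_candidate_mirnas <- function() {
  c("miR-922", "miR-516a-3p", "miR-571", "miR-548b-5p", "miR-548c-5p")
}
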