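cancer_gene_pool <- c(
  "TP53", "BRCA1", "BRCA2", "ATM", "FBXW7", "ERCC2", "PIK3CA", "KRAS",
  "NRAS", "PTEN", "RB1", "ARID1A", "CDK12", "CCNE1", "MYC", "NF1",
  "CHEK2", "BRIP1", "PALB2", "RAD51C", "RAD51D", "BARD1", "MSH2",
  "MSH6", "MLH1", "EGFR", "ERBB2", "AKT1", "CTNNB1", "SMARCA4"
)

hk_gene_pool <- c("ACTB", "GAPDH", "TUBB", "B2M", "GUSB", "HPRT1", "PGK1",
                  "RPL19", "SDHA", "TBP")

default_somatic_counts <- function(n_tr, n_ntr) {
  c(rep_len(c(8L, 7L, 2L, 1L, 2L), n_tr), rep_len(c(2L, 1L, 0L, 2L, 1L), n_ntr))
}

#' Specification of a synthetic study cohort
#'
#' Bundles every parameter of the synthetic-data generators, with defaults
#' emulating the study conditions: 10 patients split 5 tumour-reactive (TR)
#' / 5 non-reactive (NTR); per-patient somatic SNV counts
#' `{8,7,2,1,2 | 2,1,0,2,1}`, which over the 0.524 Mb panel give a cohort
#' TMB median of 3.8 and range 0–15.3 SNVs/Mb; TR patients split into a
#' high-TMB/low-GEP and a low-TMB/high-GEP sub-scenario so that the TMB-or-
#' GEP stratification rule is genuinely exercised; negative-binomial probe
#' counts with a +0.5 log10 shift of signature genes in GEP-high samples;
#' Poisson ELISPOT replicates (target mean 150 vs medium 10 for reactive
#' products, 10 vs 10 otherwise, 3 replicates); binomial gating cascades;
#' and multinomial IF fields (20 per compartment) with an enriched
#' epithelial CD137+PD-1+CD8+ phenotype in TR patients.
#'
#' Every stochastic draw is governed by `seed` through fixed per-stage
#' offsets (overridable via `stage_seeds`), so each assay's files are
#' reproducible in isolation: changing only the elispot stage seed leaves
#' the variant and expression outputs untouched.
#'
#' @param seed master integer seed.
#' @param n_patients number of patients.
#' @param n_tr number of tumour-reactive patients (the first `n_tr`).
#' @param variants,expression,elispot,gating,if_fields named lists of
#'   stage parameters; any entry supplied overrides the default.
#' @param stage_seeds optional named list overriding the per-stage seeds
#'   (`variants`, `expression`, `elispot`, `gating`, `if_fields`).
#' @return An object of class `synthetic_cohort_spec`.
#' @export
synthetic_cohort_spec <- function(seed = 1L, n_patients = 10L, n_tr = 5L,
                                  variants = list(), expression = list(),
                                  elispot = list(), gating = list(),
                                  if_fields = list(), stage_seeds = list()) {
  stopifnot(n_patients >= 1L, n_tr >= 0L, n_tr <= n_patients)
  n_ntr <- n_patients - n_tr
  patients <- sprintf("P%02d", seq_len(n_patients))
  tr_label <- stats::setNames(
    c(rep("TR", n_tr), rep("NTR", n_ntr)), patients)

  merge_defaults <- function(defaults, user) {
    defaults[names(user)] <- user
    defaults
  }
  variants <- merge_defaults(list(
    somatic_counts = default_somatic_counts(n_tr, n_ntr),
    n_germline = 30L,
    n_artifacts = 10L,
    somatic_vaf_range = c(0.05, 0.35),
    germline_maf_range = c(0.001, 0.40),
    germline_indel_fraction = 0.2,
    panel_mb = 0.524
  ), variants)
  if (length(variants$somatic_counts) != n_patients) {
    stop("variants$somatic_counts must have one entry per patient", call. = FALSE)
  }
  expression <- merge_defaults(list(
    n_endogenous = 120L,
    n_controls = 4L,
    delta_log10 = 0.5,
    shift_mode = "split",       # "split": only low-TMB TR patients GEP-high;
                                # "all_tr": every TR patient shifted
    high_tmb_threshold = 5L,    # somatic count above which a TR patient is
                                # in the high-TMB/low-GEP sub-scenario
    endogenous_dispersion = 0.05,
    hk_dispersion = 0.005,
    baseline_meanlog = log(300),
    baseline_sdlog = 1,
    hk_mu = 1000,
    size_factor_sdlog = 0.15,
    pos_ladder = c(8192, 2048, 512, 128, 32, 8),
    neg_mean = 12
  ), expression)
  elispot <- merge_defaults(list(
    replicates = 3L,
    lambda_medium = 10,
    lambda_target_reactive = 150,
    lambda_target_nonreactive = 10,
    lambda_blocked = 20,
    lambda_unrelated = 10,
    lambda_cd3 = 400,
    reactive_fraction = "PD1_hi"
  ), elispot)
  gating <- merge_defaults(list(
    n_living = 20000L,
    p_cd45 = 0.30,
    p_cd3 = 0.60,
    p_cd4 = 0.40,
    p_cd8 = c(TR = 0.35, NTR = 0.20),
    p_pd1hi_cd8 = c(TR = 0.40, NTR = 0.15),
    p_cd137_pd1hi = c(TR = 0.25, NTR = 0.05)
  ), gating)
  if_fields <- merge_defaults(list(
    n_fields = 20L,
    total_mean = c(stroma = 500, epithelium = 800),
    p_cd8 = c(TR = 0.050, NTR = 0.020),
    p_cd4 = c(TR = 0.060, NTR = 0.030),
    p_pd1_cd8 = c(TR = 0.020, NTR = 0.006),
    p_pd1_cd4 = c(TR = 0.015, NTR = 0.006),
    p_cd137_pd1_cd8 = c(TR = 0.010, NTR = 0.001),
    p_cd137_pd1_cd4 = c(TR = 0.004, NTR = 0.001),
    p_foxp3 = c(TR = 0.010, NTR = 0.010),
    stroma_multiplier = 1.5     # TIL phenotypes are denser in stroma
  ), if_fields)

  seeds <- list(variants = seed, expression = seed + 10000L,
                elispot = seed + 20000L, gating = seed + 30000L,
                if_fields = seed + 40000L)
  seeds[names(stage_seeds)] <- stage_seeds

  structure(
    list(seed = seed, n_patients = n_patients, n_tr = n_tr,
         patients = patients, tr_label = tr_label,
         variants = variants, expression = expression, elispot = elispot,
         gating = gating, if_fields = if_fields, stage_seeds = seeds),
    class = "synthetic_cohort_spec"
  )
}

#' @export
print.synthetic_cohort_spec <- function(x, ...) {
  cat(sprintf("Synthetic cohort spec: %d patients (%d TR / %d NTR), seed %d\n",
              x$n_patients, x$n_tr, x$n_patients - x$n_tr, x$seed))
  cat("  somatic SNVs per patient:",
      paste(x$variants$somatic_counts, collapse = " "), "\n")
  invisible(x)
}

#' Ground-truth GEP-high patients of a synthetic cohort
#'
#' The patients whose signature genes carry the generator's log10 shift:
#' under `shift_mode = "split"` the TR patients outside the high-TMB
#' sub-scenario, under `"all_tr"` every TR patient.
#'
#' @param spec a [synthetic_cohort_spec()].
#' @return Character vector of patient ids.
#' @export
gep_shifted_patients <- function(spec) {
  tr <- names(spec$tr_label)[spec$tr_label == "TR"]
  if (identical(spec$expression$shift_mode, "all_tr")) return(tr)
  counts <- stats::setNames(spec$variants$somatic_counts, spec$patients)
  tr[counts[tr] <= spec$expression$high_tmb_threshold]
}

clean_metrics <- function(n) {
  data.frame(
    depth = round(stats::runif(n, 150, 900)),
    call_quality = round(stats::runif(n, 50, 100), 1),
    nc_fraction = round(stats::runif(n, 0, 0.025), 4),
    strand_bias = round(stats::runif(n, -150, -85), 1),
    stringsAsFactors = FALSE
  )
}

random_sites <- function(n) {
  bases <- c("A", "C", "G", "T")
  if (n == 0L) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      gene = character(0), consequence = character(0),
                      stringsAsFactors = FALSE))
  }
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
  data.frame(
    chrom = paste0("chr", sample(1:22, n, replace = TRUE)),
    pos = sample.int(2e8, n),
    ref = ref, alt = alt,
    gene = sample(cancer_gene_pool, n, replace = TRUE),
    consequence = sample(c("non_synonymous", "synonymous", "other"), n,
                         replace = TRUE, prob = c(0.6, 0.3, 0.1)),
    stringsAsFactors = FALSE
  )
}

#' Simulate the variant table of one patient
#'
#' Generates `somatic_counts[patient]` somatic SNVs that pass every site
#' filter by construction (VAF in the somatic range, absent population MAF,
#' clean quality metrics), `n_germline` germline polymorphisms (VAF in the
#' heterozygous band \[0.40, 0.60\] or homozygous band (0.80, 1\], positive
#' population MAF, a fraction of them indels) and `n_artifacts` records
#' each violating exactly one named site filter. Deterministic given the
#' spec's seed.
#'
#' @param spec a [synthetic_cohort_spec()].
#' @param patient patient id (e.g. `"P01"`) or index.
#' @return List with `records` (validated variant data frame carrying a
#'   `variant_id` column) and `truth` (data frame `variant_id`, `status`
#'   in somatic/germline/artifact, `artifact_reason`).
#' @export
simulate_variants <- function(spec, patient) {
  stopifnot(inherits(spec, "synthetic_cohort_spec"))
  if (is.numeric(patient)) patient <- spec$patients[patient]
  idx <- match(patient, spec$patients)
  if (is.na(idx)) stop("unknown patient: ", patient, call. = FALSE)
  vp <- spec$variants
  with_local_seed(spec$stage_seeds$variants + idx, {
    n_som <- vp$somatic_counts[idx]
    n_ger <- vp$n_germline
    n_art <- vp$n_artifacts
    art_reasons <- rep_len(c("LOW_DEPTH", "LOW_QUALITY", "HIGH_NC",
                             "STRAND_BIAS", "LOW_VAF"), n_art)

    som <- cbind(random_sites(n_som), clean_metrics(n_som))
    som$variant_class <- rep("SNV", n_som)
    som$vaf <- round(stats::runif(n_som, vp$somatic_vaf_range[1],
                                  vp$somatic_vaf_range[2]), 3)
    som$pop_maf_enf <- rep(NA_real_, n_som)
    som$status <- rep("somatic", n_som)
    som$artifact_reason <- rep("", n_som)

    ger <- cbind(random_sites(n_ger), clean_metrics(n_ger))
    het <- stats::runif(n_ger) < 0.5
    ger$vaf <- round(ifelse(het, stats::runif(n_ger, 0.40, 0.60),
                            stats::runif(n_ger, 0.801, 1.0)), 3)
    ger$pop_maf_enf <- round(stats::runif(n_ger, vp$germline_maf_range[1],
                                          vp$germline_maf_range[2]), 4)
    is_indel <- stats::runif(n_ger) < vp$germline_indel_fraction
    ger$variant_class <- ifelse(is_indel, "INDEL", "SNV")
    ger$alt[is_indel] <- paste0(ger$ref[is_indel], "A")
    ger$status <- rep("germline", n_ger)
    ger$artifact_reason <- rep("", n_ger)

    art <- cbind(random_sites(n_art), clean_metrics(n_art))
    art$variant_class <- rep("SNV", n_art)
    art$vaf <- round(stats::runif(n_art, vp$somatic_vaf_range[1],
                                  vp$somatic_vaf_range[2]), 3)
    art$pop_maf_enf <- rep(NA_real_, n_art)
    art$depth[art_reasons == "LOW_DEPTH"] <- 50
    art$call_quality[art_reasons == "LOW_QUALITY"] <- 20
    art$nc_fraction[art_reasons == "HIGH_NC"] <- 0.08
    art$strand_bias[art_reasons == "STRAND_BIAS"] <- -40
    art$vaf[art_reasons == "LOW_VAF"] <- 0.01
    art$status <- rep("artifact", n_art)
    art$artifact_reason <- art_reasons

    all <- rbind(som, ger, art)
    all$patient_id <- rep(patient, nrow(all))
    all <- all[sample.int(nrow(all)), , drop = FALSE]
    all$variant_id <- sprintf("%s_v%03d", patient, seq_len(nrow(all)))
    rownames(all) <- NULL
    records <- validate_variants(
      all[, c(variant_columns, "variant_id"), drop = FALSE])
    list(
      records = records,
      truth = all[, c("variant_id", "status", "artifact_reason")]
    )
  })
}

#' Simulate the cohort's expression count matrix
#'
#' Draws negative-binomial counts for endogenous and housekeeping genes with
#' a shared per-sample size factor (so housekeeping normalisation can undo
#' it), a fixed geometric positive-control ladder scaled by the same factor,
#' and low-mean Poisson negative controls. Signature genes in GEP-high
#' samples are up-shifted by `delta_log10` on the mean. Four non-malignant
#' control samples are appended.
#'
#' @param spec a [synthetic_cohort_spec()].
#' @return List with `matrix` (a [count_matrix()]) and `truth` (per-sample
#'   group, GEP shift and size factor).
#' @export
simulate_expression <- function(spec) {
  stopifnot(inherits(spec, "synthetic_cohort_spec"))
  ep <- spec$expression
  sigs <- read_signatures()
  sig_genes <- sort(unique(unlist(sigs)))
  n_extra <- max(0L, ep$n_endogenous - length(sig_genes))
  end_genes <- c(sig_genes, sprintf("GENE%03d", seq_len(n_extra)))
  hk_genes <- hk_gene_pool
  pos_genes <- paste0("POS_", LETTERS[seq_along(ep$pos_ladder)])
  neg_genes <- paste0("NEG_", LETTERS[1:8])
  genes <- c(end_genes, hk_genes, pos_genes, neg_genes)
  gene_class <- c(rep("endogenous", length(end_genes)),
                  rep("housekeeping", length(hk_genes)),
                  rep("positive", length(pos_genes)),
                  rep("negative", length(neg_genes)))
  controls <- sprintf("C%02d", spec$n_patients + seq_len(ep$n_controls))
  samples <- c(spec$patients, controls)
  groups <- c(unname(spec$tr_label), rep("control", ep$n_controls))
  shifted <- gep_shifted_patients(spec)

  with_local_seed(spec$stage_seeds$expression, {
    mu_end <- stats::rlnorm(length(end_genes), ep$baseline_meanlog,
                            ep$baseline_sdlog)
    names(mu_end) <- end_genes
    sf <- stats::rlnorm(length(samples), 0, ep$size_factor_sdlog)
    names(sf) <- samples
    counts <- matrix(0, nrow = length(genes), ncol = length(samples),
                     dimnames = list(genes, samples))
    for (s in samples) {
      mu <- mu_end * sf[s]
      if (s %in% shifted) {
        mu[sig_genes] <- mu[sig_genes] * 10^ep$delta_log10
      }
      counts[end_genes, s] <- stats::rnbinom(length(mu), mu = mu,
                                             size = 1 / ep$endogenous_dispersion)
      counts[hk_genes, s] <- stats::rnbinom(length(hk_genes),
                                            mu = ep$hk_mu * sf[s],
                                            size = 1 / ep$hk_dispersion)
      counts[pos_genes, s] <- pmax(stats::rpois(length(pos_genes),
                                                ep$pos_ladder * sf[s]), 1)
      counts[neg_genes, s] <- stats::rpois(length(neg_genes), ep$neg_mean)
    }
    list(
      matrix = count_matrix(counts, gene_class, groups),
      truth = data.frame(
        sample_id = samples,
        group = groups,
        gep_shifted = samples %in% shifted,
        size_factor = unname(sf),
        stringsAsFactors = FALSE
      )
    )
  })
}

#' Simulate ELISPOT plates for every TIL product
#'
#' Each patient contributes two products (PD-1neg- and PD-1hi-derived).
#' Reactive products (the configured fraction of TR patients) draw
#' autologous-target replicates at `lambda_target_reactive`, HLA-blocked
#' replicates at `lambda_blocked` and unrelated-target replicates at
#' `lambda_unrelated`; non-reactive products draw every target at the
#' medium rate. All counts are Poisson.
#'
#' @param spec a [synthetic_cohort_spec()].
#' @return List with `plates` (long data frame `patient_id`, `fraction`,
#'   `condition`, `replicate`, `spots`) and `truth` (per product:
#'   `reactive`).
#' @export
simulate_elispot <- function(spec) {
  stopifnot(inherits(spec, "synthetic_cohort_spec"))
  el <- spec$elispot
  conditions <- c("medium", "autologous_tumour",
                  "autologous_tumour_plus_HLAblock", "unrelated_tumour",
                  "antiCD3_positive_control")
  with_local_seed(spec$stage_seeds$elispot, {
    rows <- list(); truth <- list()
    for (p in spec$patients) {
      for (fr in c("PD1_neg", "PD1_hi")) {
        reactive <- spec$tr_label[[p]] == "TR" && fr == el$reactive_fraction
        lambda <- c(
          medium = el$lambda_medium,
          autologous_tumour = if (reactive) el$lambda_target_reactive
                              else el$lambda_target_nonreactive,
          autologous_tumour_plus_HLAblock = if (reactive) el$lambda_blocked
                                            else el$lambda_target_nonreactive,
          unrelated_tumour = el$lambda_unrelated,
          antiCD3_positive_control = el$lambda_cd3
        )
        for (cond in conditions) {
          rows[[length(rows) + 1L]] <- data.frame(
            patient_id = p, fraction = fr, condition = cond,
            replicate = seq_len(el$replicates),
            spots = stats::rpois(el$replicates, lambda[[cond]]),
            stringsAsFactors = FALSE
          )
        }
        truth[[length(truth) + 1L]] <- data.frame(
          patient_id = p, fraction = fr, reactive = reactive,
          stringsAsFactors = FALSE
        )
      }
    }
    list(plates = do.call(rbind, rows), truth = do.call(rbind, truth))
  })
}

#' Simulate the CD137 confirmation assay
#'
#' Percent CD137+ of gated CD8 blasts per culture condition; reactive
#' products upregulate CD137 with autologous tumour.
#'
#' @param spec a [synthetic_cohort_spec()].
#' @return Data frame `patient_id`, `fraction`, `condition`, `percent`.
#' @export
simulate_cd137 <- function(spec) {
  stopifnot(inherits(spec, "synthetic_cohort_spec"))
  el <- spec$elispot
  with_local_seed(spec$stage_seeds$elispot + 1L, {
    rows <- list()
    for (p in spec$patients) {
      for (fr in c("PD1_neg", "PD1_hi")) {
        reactive <- spec$tr_label[[p]] == "TR" && fr == el$reactive_fraction
        pct <- c(
          alone = stats::runif(1, 0.1, 0.6),
          autologous_tumour = if (reactive) stats::runif(1, 4, 12)
                              else stats::runif(1, 0.1, 0.8),
          unrelated_tumour = stats::runif(1, 0.1, 0.8)
        )
        rows[[length(rows) + 1L]] <- data.frame(
          patient_id = p, fraction = fr, condition = names(pct),
          percent = round(unname(pct), 2), stringsAsFactors = FALSE
        )
      }
    }
    do.call(rbind, rows)
  })
}

synthetic_gating_tree <- function() {
  data.frame(
    node = c("living", "CD45", "CD3", "CD4", "CD8",
             "PD1hi_CD8", "CD137_PD1hi_CD8"),
    parent = c(NA, "living", "CD45", "CD3", "CD3", "CD8", "PD1hi_CD8"),
    stringsAsFactors = FALSE
  )
}

#' Simulate gating counts for one patient
#'
#' Binomial cascade down the gating tree (living -> CD45 -> CD3 -> CD4/CD8
#' -> PD-1hi -> CD137), so the child <= parent invariant holds by
#' construction; TR patients draw richer CD8/PD-1hi/CD137 compartments.
#'
#' @param spec a [synthetic_cohort_spec()].
#' @param patient patient id or index.
#' @return Data frame `patient_id`, `node`, `count`.
#' @export
simulate_gating <- function(spec, patient) {
  stopifnot(inherits(spec, "synthetic_cohort_spec"))
  if (is.numeric(patient)) patient <- spec$patients[patient]
  idx <- match(patient, spec$patients)
  if (is.na(idx)) stop("unknown patient: ", patient, call. = FALSE)
  g <- spec$gating
  grp <- spec$tr_label[[patient]]
  with_local_seed(spec$stage_seeds$gating + idx, {
    living <- g$n_living
    cd45 <- stats::rbinom(1, living, g$p_cd45)
    cd3 <- stats::rbinom(1, cd45, g$p_cd3)
    cd8 <- stats::rbinom(1, cd3, g$p_cd8[[grp]])
    cd4 <- stats::rbinom(1, cd3 - cd8, g$p_cd4)
    pd1hi <- stats::rbinom(1, cd8, g$p_pd1hi_cd8[[grp]])
    cd137 <- stats::rbinom(1, pd1hi, g$p_cd137_pd1hi[[grp]])
    data.frame(
      patient_id = patient,
      node = c("living", "CD45", "CD3", "CD4", "CD8",
               "PD1hi_CD8", "CD137_PD1hi_CD8"),
      count = c(living, cd45, cd3, cd4, cd8, pd1hi, cd137),
      stringsAsFactors = FALSE
    )
  })
}

if_phenotypes <- c("CD8", "CD4", "PD1_CD8", "PD1_CD4",
                   "CD137_PD1_CD8", "CD137_PD1_CD4", "FOXP3")

#' Simulate multiplex-IF field counts for one patient
#'
#' Per field and compartment, the total cell count is Poisson and phenotype
#' counts are multinomial with group-specific probabilities; the epithelial
#' CD137+PD-1+CD8+ probability is higher in TR patients.
#'
#' @param spec a [synthetic_cohort_spec()].
#' @param patient patient id or index.
#' @return Data frame `patient_id`, `field_id`, `compartment`, `phenotype`,
#'   `cell_count`, `total_cells_in_field`.
#' @export
simulate_if_fields <- function(spec, patient) {
  stopifnot(inherits(spec, "synthetic_cohort_spec"))
  if (is.numeric(patient)) patient <- spec$patients[patient]
  idx <- match(patient, spec$patients)
  if (is.na(idx)) stop("unknown patient: ", patient, call. = FALSE)
  f <- spec$if_fields
  grp <- spec$tr_label[[patient]]
  probs_for <- function(compartment) {
    p <- c(f$p_cd8[[grp]], f$p_cd4[[grp]], f$p_pd1_cd8[[grp]],
           f$p_pd1_cd4[[grp]], f$p_cd137_pd1_cd8[[grp]],
           f$p_cd137_pd1_cd4[[grp]], f$p_foxp3[[grp]])
    if (compartment == "stroma") p <- p * f$stroma_multiplier
    c(p, 1 - sum(p))
  }
  with_local_seed(spec$stage_seeds$if_fields + idx, {
    rows <- list()
    for (comp in c("stroma", "epithelium")) {
      pr <- probs_for(comp)
      for (fid in seq_len(f$n_fields)) {
        total <- stats::rpois(1, f$total_mean[[comp]]) + 1L
        cnt <- as.vector(stats::rmultinom(1, total, pr))
        rows[[length(rows) + 1L]] <- data.frame(
          patient_id = patient, field_id = fid, compartment = comp,
          phenotype = c(if_phenotypes, "other"),
          cell_count = cnt, total_cells_in_field = total,
          stringsAsFactors = FALSE
        )
      }
    }
    do.call(rbind, rows)
  })
}

#' Generate a complete synthetic cohort on disk
#'
#' Writes every input file the analysis stages consume — variant table,
#' expression count matrix with gene classes, sample groups, ELISPOT
#' plates, CD137 assay, gating counts and tree, IF field table — plus a
#' ground-truth manifest (JSON). A single call reproduces the full bundle
#' byte-identically from `(spec, seed)`.
#'
#' @param spec a [synthetic_cohort_spec()].
#' @param dir output directory.
#' @param force overwrite an existing non-empty directory.
#' @return Invisibly, a named list of file paths plus the ground truth.
#' @export
simulate_cohort <- function(spec, dir, force = FALSE) {
  stopifnot(inherits(spec, "synthetic_cohort_spec"))
  if (dir.exists(dir) && length(list.files(dir)) && !force) {
    stop("output directory ", dir, " is not empty; use force = TRUE",
         call. = FALSE)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(f) file.path(dir, f)

  var_sims <- lapply(spec$patients, function(p) simulate_variants(spec, p))
  variants <- do.call(rbind, lapply(var_sims, `[[`, "records"))
  var_truth <- do.call(rbind, lapply(var_sims, `[[`, "truth"))
  utils::write.table(variants, path("variants.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(var_truth, path("variant_truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  expr <- simulate_expression(spec)
  cm <- expr$matrix
  counts_df <- data.frame(gene = rownames(cm$counts),
                          gene_class = unname(cm$gene_class),
                          cm$counts, check.names = FALSE,
                          stringsAsFactors = FALSE)
  utils::write.csv(counts_df, path("counts.csv"), row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(data.frame(sample_id = names(cm$groups),
                              group = unname(cm$groups)),
                   path("groups.csv"), row.names = FALSE, quote = FALSE)

  eli <- simulate_elispot(spec)
  utils::write.csv(eli$plates, path("elispot.csv"), row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(simulate_cd137(spec), path("cd137.csv"),
                   row.names = FALSE, quote = FALSE)

  gat <- do.call(rbind, lapply(spec$patients,
                               function(p) simulate_gating(spec, p)))
  utils::write.csv(gat, path("gating_counts.csv"), row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(synthetic_gating_tree(), path("gating_tree.csv"),
                   row.names = FALSE, quote = FALSE)

  iff <- do.call(rbind, lapply(spec$patients,
                               function(p) simulate_if_fields(spec, p)))
  utils::write.csv(iff, path("if_fields.csv"), row.names = FALSE,
                   quote = FALSE)

  truth <- list(
    seed = spec$seed,
    n_patients = spec$n_patients,
    patients = spec$patients,
    tr_label = as.list(spec$tr_label),
    n_somatic = as.list(stats::setNames(spec$variants$somatic_counts,
                                        spec$patients)),
    gep_shifted = gep_shifted_patients(spec),
    reactive_products = eli$truth[eli$truth$reactive, c("patient_id", "fraction")]
  )
  jsonlite::write_json(truth, path("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(
    files = list(
      variants = path("variants.tsv"),
      variant_truth = path("variant_truth.tsv"),
      counts = path("counts.csv"),
      groups = path("groups.csv"),
      elispot = path("elispot.csv"),
      cd137 = path("cd137.csv"),
      gating_counts = path("gating_counts.csv"),
      gating_tree = path("gating_tree.csv"),
      if_fields = path("if_fields.csv"),
      manifest = path("manifest.json")
    ),
    truth = truth
  ))
}

#' Read an expression count matrix from CSV
#'
#' Counterpart of the `counts.csv`/`groups.csv` files written by
#' [simulate_cohort()]: a CSV with columns `gene`, `gene_class` and one
#' column per sample, plus an optional sample-group CSV (`sample_id`,
#' `group`).
#'
#' @param counts_path path to the count CSV.
#' @param groups_path optional path to the group CSV.
#' @return A [count_matrix()].
#' @export
read_count_matrix <- function(counts_path, groups_path = NULL) {
  df <- utils::read.csv(counts_path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  if (!all(c("gene", "gene_class") %in% names(df))) {
    stop("count CSV must have 'gene' and 'gene_class' columns", call. = FALSE)
  }
  m <- as.matrix(df[, setdiff(names(df), c("gene", "gene_class")), drop = FALSE])
  rownames(m) <- df$gene
  groups <- NULL
  if (!is.null(groups_path)) {
    g <- utils::read.csv(groups_path, stringsAsFactors = FALSE)
    groups <- g$group[match(colnames(m), g$sample_id)]
    groups[is.na(groups)] <- "unknown"
  }
  count_matrix(m, df$gene_class, groups)
}
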