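#' Filter thresholds for the somatic SNV cascade
#'
#' Bundles the site-quality and germline-filter thresholds used by
#' [apply_site_filters()], [apply_germline_filter()] and [call_somatic()].
#' Defaults reproduce the TruSight Tumor 170 tumour-only workflow: positions
#' with depth < 100, call quality < 40, no-call fraction >= 0.03 (SNVs only),
#' strand-bias score > -80 or VAF < 0.05 are discarded; variants with VAF in
#' [0.40, 0.60] or above 0.80 that carry a nonzero population minor-allele
#' frequency (European non-Finnish) are treated as germline polymorphisms.
#'
#' Boundary conventions: depth 99 fails and 100 passes; NC exactly 0.03
#' fails (inclusive); VAF exactly 0.05 passes (strict `<`); strand bias
#' exactly -80 passes (strict `>`); the germline VAF window is closed,
#' `[0.40, 0.60]`, and the upper arm is strict, `> 0.80`.
#'
#' @param min_depth minimum read depth; sites below fail with `LOW_DEPTH`.
#' @param min_quality minimum variant call quality (`LOW_QUALITY` below).
#' @param max_nc_snv no-call fraction at which an SNV fails (`HIGH_NC`,
#'   inclusive bound). Applies to SNVs only; indels/MNVs skip this predicate.
#' @param strand_bias_cut strand-bias cut: scores strictly greater than this
#'   (i.e. more biased, in the caller's convention where more negative is
#'   cleaner) fail with `STRAND_BIAS`.
#' @param min_vaf minimum variant allele frequency (strict `<` fails,
#'   `LOW_VAF`).
#' @param germline_vaf_low,germline_vaf_high closed VAF window flagged as
#'   potentially germline (heterozygous band).
#' @param germline_vaf_upper VAF above which (strictly) a variant is in the
#'   homozygous germline band.
#' @param panel_mb sequenced panel footprint in megabases used by
#'   [compute_tmb()] (0.524 Mb for TST170).
#' @param maf_always_excludes if `TRUE`, any variant with a positive
#'   population MAF is excluded as germline regardless of its VAF; the default
#'   `FALSE` restricts the MAF rule to the germline VAF bands.
#' @param count_only_nonsynonymous if `TRUE`, [call_somatic()] additionally
#'   requires `consequence == "non_synonymous"`.
#' @param missing_metric_fails if `TRUE` (default) a record missing a metric
#'   needed by a predicate fails closed with reason `MISSING_METRIC`; if
#'   `FALSE` the predicate is treated as passing (fail-open).
#' @return An object of class `filter_thresholds`.
#' @examples
#' th <- filter_thresholds()
#' th$panel_mb
#' @export
filter_thresholds <- function(min_depth = 100,
                              min_quality = 40,
                              max_nc_snv = 0.03,
                              strand_bias_cut = -80,
                              min_vaf = 0.05,
                              germline_vaf_low = 0.40,
                              germline_vaf_high = 0.60,
                              germline_vaf_upper = 0.80,
                              panel_mb = 0.524,
                              maf_always_excludes = FALSE,
                              count_only_nonsynonymous = FALSE,
                              missing_metric_fails = TRUE) {
  stopifnot(
    min_depth >= 0, min_quality >= 0,
    max_nc_snv >= 0, max_nc_snv <= 1,
    min_vaf >= 0,
    min_vaf < germline_vaf_low,
    germline_vaf_low < germline_vaf_high,
    germline_vaf_high <= germline_vaf_upper,
    germline_vaf_upper <= 1,
    panel_mb > 0
  )
  structure(
    list(
      min_depth = min_depth, min_quality = min_quality,
      max_nc_snv = max_nc_snv, strand_bias_cut = strand_bias_cut,
      min_vaf = min_vaf,
      germline_vaf_low = germline_vaf_low,
      germline_vaf_high = germline_vaf_high,
      germline_vaf_upper = germline_vaf_upper,
      panel_mb = panel_mb,
      maf_always_excludes = isTRUE(maf_always_excludes),
      count_only_nonsynonymous = isTRUE(count_only_nonsynonymous),
      missing_metric_fails = isTRUE(missing_metric_fails)
    ),
    class = "filter_thresholds"
  )
}

#' @export
print.filter_thresholds <- function(x, ...) {
  cat("Somatic filter thresholds\n")
  cat(sprintf("  site: depth >= %g, quality >= %g, NC < %g (SNV), strand bias <= %g, VAF >= %g\n",
              x$min_depth, x$min_quality, x$max_nc_snv, x$strand_bias_cut, x$min_vaf))
  cat(sprintf("  germline: VAF in [%.2f, %.2f] or > %.2f with population MAF > 0%s\n",
              x$germline_vaf_low, x$germline_vaf_high, x$germline_vaf_upper,
              if (x$maf_always_excludes) " (MAF > 0 always excludes)" else ""))
  cat(sprintf("  panel: %g Mb%s\n", x$panel_mb,
              if (x$count_only_nonsynonymous) ", non-synonymous SNVs only" else ""))
  invisible(x)
}

variant_columns <- c(
  "patient_id", "chrom", "pos", "ref", "alt", "variant_class", "depth",
  "call_quality", "nc_fraction", "strand_bias", "vaf", "pop_maf_enf",
  "gene", "consequence"
)

#' Validate a variant table
#'
#' Checks a data frame of called variants against the record invariants:
#' VAF and no-call fraction in \[0, 1\], nonnegative integer depth, position
#' >= 1, and single-base REF/ALT for rows labelled `SNV`. A missing
#' population MAF must be `NA` (absent from the database), never 0.
#'
#' @param records data frame with one row per called variant; required
#'   columns: `patient_id`, `chrom`, `pos`, `ref`, `alt`, `variant_class`
#'   (one of `"SNV"`, `"INDEL"`, `"MNV"`), `depth`, `call_quality`,
#'   `nc_fraction`, `strand_bias`, `vaf`, `pop_maf_enf` (NA when the variant
#'   is absent from the population database), `gene`, `consequence`.
#' @return The validated data frame (invisibly usable in a pipeline).
#' @export
validate_variants <- function(records) {
  stopifnot(is.data.frame(records))
  missing_cols <- setdiff(variant_columns, names(records))
  if (length(missing_cols)) {
    stop("variant table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad <- function(cond, what) {
    i <- which(cond)
    if (length(i)) {
      stop(sprintf("invalid %s in variant row(s) %s", what,
                   paste(utils::head(i, 5), collapse = ", ")), call. = FALSE)
    }
  }
  bad(!is.na(records$vaf) & (records$vaf < 0 | records$vaf > 1), "vaf (must be in [0,1])")
  bad(!is.na(records$nc_fraction) & (records$nc_fraction < 0 | records$nc_fraction > 1),
      "nc_fraction (must be in [0,1])")
  bad(!is.na(records$depth) & (records$depth < 0 | records$depth != floor(records$depth)),
      "depth (must be a nonnegative integer)")
  bad(!is.na(records$pos) & records$pos < 1, "pos (must be >= 1)")
  bad(!is.na(records$pop_maf_enf) & (records$pop_maf_enf < 0 | records$pop_maf_enf > 1),
      "pop_maf_enf (must be in [0,1] or NA)")
  bad(!records$variant_class %in% c("SNV", "INDEL", "MNV"), "variant_class")
  is_snv <- records$variant_class == "SNV"
  bad(is_snv & (nchar(records$ref) != 1L | nchar(records$alt) != 1L),
      "SNV alleles (REF and ALT must be single bases)")
  records
}

#' Read a per-patient variant table
#'
#' Ingests called variants from a tab-delimited table or a VCF. Tabular input
#' must carry the columns listed in [validate_variants()] (renameable through
#' `col_map`). VCF input is parsed with \pkg{vcfR}; per-site metrics are read
#' from INFO keys named in `col_map` and multi-allelic lines are expanded to
#' one record per ALT allele. A missing population-MAF annotation becomes
#' `NA` ("absent from the database"), never 0.
#'
#' @param path path to the file.
#' @param dialect `"tsv"` or `"vcf"`.
#' @param col_map named character vector mapping the canonical field names to
#'   the file's column names (TSV) or INFO keys (VCF). VCF defaults:
#'   `depth = "DP"`, `nc_fraction = "NC"`, `strand_bias = "SB"`,
#'   `vaf = "AF"`, `pop_maf_enf = "MAF_ENF"`, `gene = "GENE"`,
#'   `consequence = "CONSEQ"`; call quality is the QUAL column.
#' @param patient_id patient identifier to assign when the file does not
#'   carry one (required for VCF).
#' @return A validated variant data frame.
#' @export
read_variant_table <- function(path, dialect = c("tsv", "vcf"),
                               col_map = NULL, patient_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (dialect == "tsv") {
    read_variant_tsv(path, col_map, patient_id)
  } else {
    read_variant_vcf(path, col_map, patient_id)
  }
}

read_variant_tsv <- function(path, col_map, patient_id) {
  # read everything as character first: single-base alleles like "T" must
  # not be parsed as logicals
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("NA", ""), colClasses = "character")
  if (!is.null(col_map)) {
    for (canonical in names(col_map)) {
      src <- col_map[[canonical]]
      if (!src %in% names(df)) {
        stop("column mapping refers to absent column '", src,
             "' (for field '", canonical, "')", call. = FALSE)
      }
      names(df)[names(df) == src] <- canonical
    }
  }
  if (!"patient_id" %in% names(df)) {
    if (is.null(patient_id)) {
      stop("no 'patient_id' column and no patient_id supplied", call. = FALSE)
    }
    df$patient_id <- patient_id
  }
  missing_cols <- setdiff(variant_columns, names(df))
  if (length(missing_cols)) {
    stop("variant table is missing required column(s): ",
         paste(missing_cols, collapse = ", "),
         "; map them with col_map", call. = FALSE)
  }
  for (col in c("pos", "depth", "call_quality", "nc_fraction", "strand_bias",
                "vaf", "pop_maf_enf")) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      bad <- which(!is.na(v) & is.na(num))
      if (length(bad)) {
        stop(sprintf("malformed %s at line %d of %s", col, bad[1] + 1L, path),
             call. = FALSE)
      }
      df[[col]] <- num
    }
  }
  out <- df[, union(variant_columns, names(df)), drop = FALSE]
  tryCatch(validate_variants(out), error = function(e) {
    stop(conditionMessage(e), " (file ", path, ")", call. = FALSE)
  })
}

default_vcf_info_map <- c(
  depth = "DP", nc_fraction = "NC", strand_bias = "SB", vaf = "AF",
  pop_maf_enf = "MAF_ENF", gene = "GENE", consequence = "CONSEQ"
)

read_variant_vcf <- function(path, col_map, patient_id) {
  if (is.null(patient_id)) {
    stop("patient_id is required when reading a VCF", call. = FALSE)
  }
  map <- default_vcf_info_map
  if (!is.null(col_map)) map[names(col_map)] <- unlist(col_map)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) {
    return(validate_variants(empty_variant_table()))
  }
  info_get <- function(line, key) {
    fields <- strsplit(line, ";", fixed = TRUE)[[1]]
    hit <- grep(paste0("^", key, "="), fields, value = TRUE)
    if (!length(hit)) return(NA_character_)
    sub(paste0("^", key, "="), "", hit[1])
  }
  rows <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    info <- fix$INFO[i]
    per_allele <- function(key) {
      raw <- info_get(info, key)
      if (is.na(raw)) return(rep(NA_character_, length(alts)))
      vals <- strsplit(raw, ",", fixed = TRUE)[[1]]
      if (length(vals) == length(alts)) vals else rep(vals[1], length(alts))
    }
    vafs <- suppressWarnings(as.numeric(per_allele(map[["vaf"]])))
    mafs <- suppressWarnings(as.numeric(per_allele(map[["pop_maf_enf"]])))
    genes <- per_allele(map[["gene"]])
    cons <- per_allele(map[["consequence"]])
    num1 <- function(key) suppressWarnings(as.numeric(info_get(info, key)))
    ref <- fix$REF[i]
    rows[[i]] <- data.frame(
      patient_id = patient_id,
      chrom = fix$CHROM[i],
      pos = as.numeric(fix$POS[i]),
      ref = ref,
      alt = alts,
      variant_class = ifelse(nchar(ref) == 1L & nchar(alts) == 1L, "SNV",
                             ifelse(nchar(ref) == nchar(alts), "MNV", "INDEL")),
      depth = num1(map[["depth"]]),
      call_quality = suppressWarnings(as.numeric(fix$QUAL[i])),
      nc_fraction = num1(map[["nc_fraction"]]),
      strand_bias = num1(map[["strand_bias"]]),
      vaf = vafs,
      pop_maf_enf = mafs,
      gene = ifelse(is.na(genes), "", genes),
      consequence = ifelse(is.na(cons), "unknown", cons),
      stringsAsFactors = FALSE
    )
  }
  validate_variants(do.call(rbind, rows))
}

empty_variant_table <- function() {
  data.frame(
    patient_id = character(), chrom = character(), pos = numeric(),
    ref = character(), alt = character(), variant_class = character(),
    depth = numeric(), call_quality = numeric(), nc_fraction = numeric(),
    strand_bias = numeric(), vaf = numeric(), pop_maf_enf = numeric(),
    gene = character(), consequence = character(), stringsAsFactors = FALSE
  )
}

join_reasons <- function(reason_list) {
  vapply(reason_list, function(r) paste(r, collapse = ";"), character(1))
}

# Evaluate each site predicate independently; a record can fail several.
site_reason_list <- function(records, thresholds) {
  th <- thresholds
  n <- nrow(records)
  is_snv <- records$variant_class == "SNV"
  pred <- list(
    LOW_DEPTH   = records$depth < th$min_depth,
    LOW_QUALITY = records$call_quality < th$min_quality,
    HIGH_NC     = is_snv & records$nc_fraction >= th$max_nc_snv,
    STRAND_BIAS = records$strand_bias > th$strand_bias_cut,
    LOW_VAF     = records$vaf < th$min_vaf
  )
  missing <- rep(FALSE, n)
  for (name in names(pred)) {
    p <- pred[[name]]
    missing <- missing | is.na(p)
    pred[[name]] <- !is.na(p) & p
  }
  reasons <- vector("list", n)
  for (i in seq_len(n)) {
    r <- names(pred)[vapply(pred, `[[`, logical(1), i)]
    if (missing[i] && th$missing_metric_fails) r <- c(r, "MISSING_METRIC")
    reasons[[i]] <- r
  }
  if (any(missing) && th$missing_metric_fails) {
    warning(sum(missing), " record(s) with missing QC metrics failed closed (MISSING_METRIC)",
            call. = FALSE)
  }
  reasons
}

germline_reason_list <- function(records, thresholds) {
  th <- thresholds
  vaf <- records$vaf
  maf <- records$pop_maf_enf
  in_window <- !is.na(vaf) &
    ((vaf >= th$germline_vaf_low & vaf <= th$germline_vaf_high) |
       vaf > th$germline_vaf_upper)
  maf_positive <- !is.na(maf) & maf > 0
  hit <- if (th$maf_always_excludes) maf_positive else (in_window & maf_positive)
  lapply(hit, function(h) if (h) "GERMLINE_VAF_MAF" else character(0))
}

verdict_frame <- function(records, reasons) {
  data.frame(
    patient_id = records$patient_id,
    chrom = records$chrom,
    pos = records$pos,
    ref = records$ref,
    alt = records$alt,
    passed = lengths(reasons) == 0L,
    reasons = join_reasons(reasons),
    stringsAsFactors = FALSE
  )
}

#' Apply the site-quality filters
#'
#' Evaluates the five site-level predicates independently on every record:
#' depth below `min_depth` (`LOW_DEPTH`), call quality below `min_quality`
#' (`LOW_QUALITY`), no-call fraction at or above `max_nc_snv` for SNVs only
#' (`HIGH_NC`), strand-bias score above `strand_bias_cut` (`STRAND_BIAS`)
#' and VAF below `min_vaf` (`LOW_VAF`). A record may carry several reasons.
#'
#' @param records validated variant data frame (see [validate_variants()]).
#' @param thresholds a [filter_thresholds()] object.
#' @return A data frame of verdicts with columns `passed` (logical) and
#'   `reasons` (semicolon-joined failure reasons, empty when passed), one row
#'   per input record in input order.
#' @export
apply_site_filters <- function(records, thresholds = filter_thresholds()) {
  records <- validate_variants(records)
  verdict_frame(records, site_reason_list(records, thresholds))
}

#' Apply the germline-polymorphism filter
#'
#' Flags reason `GERMLINE_VAF_MAF` when a variant sits in a germline VAF band
#' (closed window `[germline_vaf_low, germline_vaf_high]`, typically the
#' heterozygous band 0.40–0.60, or strictly above `germline_vaf_upper`,
#' the homozygous band > 0.80) *and* has a positive population minor-allele
#' frequency. Variants absent from the population database (`pop_maf_enf`
#' `NA`) are always retained. With `maf_always_excludes = TRUE` in the
#' thresholds, any positive MAF excludes regardless of VAF.
#'
#' @inheritParams apply_site_filters
#' @return A verdict data frame as in [apply_site_filters()].
#' @export
apply_germline_filter <- function(records, thresholds = filter_thresholds()) {
  records <- validate_variants(records)
  verdict_frame(records, germline_reason_list(records, thresholds))
}

#' Call somatic SNVs for one patient
#'
#' Runs the full cascade — site filters, germline filter and the SNV-only
#' rule — and returns the retained somatic SNVs together with a complete
#' audit trail: every input record either appears in the call set or carries
#' at least one failure reason (`NOT_SNV` for clean non-SNVs, and
#' `NOT_NONSYNONYMOUS` when `count_only_nonsynonymous` is set). All
#' predicates are evaluated independently, so the cascade retains exactly
#' the records a joint evaluation of all predicates would.
#'
#' @param records validated variant data frame for a single patient.
#' @param thresholds a [filter_thresholds()] object.
#' @return An object of class `somatic_callset`: list with `patient_id`,
#'   `records` (the retained somatic SNV rows), `n_somatic_snv`, and `audit`
#'   (per-record verdicts).
#' @seealso [call_somatic_cohort()] to split a multi-patient table.
#' @export
call_somatic <- function(records, thresholds = filter_thresholds()) {
  records <- validate_variants(records)
  if (length(unique(records$patient_id)) > 1L) {
    stop("records span several patients; use call_somatic_cohort()", call. = FALSE)
  }
  site <- site_reason_list(records, thresholds)
  germ <- germline_reason_list(records, thresholds)
  extra <- lapply(seq_len(nrow(records)), function(i) {
    r <- character(0)
    if (records$variant_class[i] != "SNV") r <- c(r, "NOT_SNV")
    if (thresholds$count_only_nonsynonymous &&
        !identical(records$consequence[i], "non_synonymous")) {
      r <- c(r, "NOT_NONSYNONYMOUS")
    }
    r
  })
  reasons <- Map(c, site, germ, extra)
  keep <- lengths(reasons) == 0L
  structure(
    list(
      patient_id = if (nrow(records)) records$patient_id[1] else NA_character_,
      records = records[keep, , drop = FALSE],
      n_somatic_snv = sum(keep),
      audit = verdict_frame(records, reasons)
    ),
    class = "somatic_callset"
  )
}

#' Call somatic SNVs for every patient in a table
#'
#' @inheritParams call_somatic
#' @return A named list of `somatic_callset` objects, one per patient.
#' @export
call_somatic_cohort <- function(records, thresholds = filter_thresholds()) {
  records <- validate_variants(records)
  split_records <- split(records, records$patient_id)
  lapply(split_records, call_somatic, thresholds = thresholds)
}

#' @export
print.somatic_callset <- function(x, ...) {
  cat(sprintf("Somatic call set for %s: %d somatic SNV(s) of %d input record(s)\n",
              x$patient_id, x$n_somatic_snv, nrow(x$audit)))
  invisible(x)
}

#' Panel-normalised tumour mutational burden
#'
#' TMB is the number of retained somatic SNVs divided by the sequenced panel
#' footprint in megabases (0.524 Mb for TST170). The value is returned at
#' full precision; the conventional display rounds to one decimal.
#'
#' @param callset a `somatic_callset` from [call_somatic()].
#' @param panel_mb panel footprint in megabases, > 0.
#' @return An object of class `tmb_result`: data frame with `patient_id`,
#'   `n_somatic_snv`, `panel_mb` and `tmb`.
#' @examples
#' \dontrun{compute_tmb(call_somatic(records))}
#' @export
compute_tmb <- function(callset, panel_mb = 0.524) {
  stopifnot(inherits(callset, "somatic_callset"))
  if (!is.numeric(panel_mb) || panel_mb <= 0) {
    stop("panel_mb must be a positive number of megabases", call. = FALSE)
  }
  structure(
    data.frame(
      patient_id = callset$patient_id,
      n_somatic_snv = callset$n_somatic_snv,
      panel_mb = panel_mb,
      tmb = callset$n_somatic_snv / panel_mb,
      stringsAsFactors = FALSE
    ),
    class = c("tmb_result", "data.frame")
  )
}

#' @export
print.tmb_result <- function(x, ...) {
  cat(sprintf("TMB: %.1f somatic SNVs/Mb (%d SNVs over %g Mb) for %s\n",
              x$tmb, x$n_somatic_snv, x$panel_mb, x$patient_id))
  invisible(x)
}

#' Cohort TMB table
#'
#' @param callsets list of `somatic_callset` objects.
#' @param panel_mb panel footprint in megabases.
#' @return A data frame with one `tmb_result` row per patient.
#' @export
compute_tmb_cohort <- function(callsets, panel_mb = 0.524) {
  out <- do.call(rbind, lapply(callsets, function(cs) {
    as.data.frame(compute_tmb(cs, panel_mb))
  }))
  rownames(out) <- NULL
  out
}

#' Patient-by-gene mutation matrix (oncoprint summary)
#'
#' Summarises somatic call sets into the matrix behind an oncoprint: a
#' logical patient x gene matrix (mutated at least once), the percentage of
#' patients carrying a mutation in each gene, and the total number of
#' somatic SNVs per gene across the cohort (a patient with two SNVs in one
#' gene contributes one `TRUE` cell but two to the total).
#'
#' @param callsets list of `somatic_callset` objects (one per patient).
#' @return An object of class `gene_mutation_matrix`: list with `matrix`
#'   (logical, patients x genes), `gene_pct` (named numeric, percent of
#'   patients mutated) and `gene_totals` (named integer).
#' @export
gene_mutation_matrix <- function(callsets) {
  patients <- vapply(callsets, `[[`, character(1), "patient_id")
  recs <- do.call(rbind, lapply(callsets, `[[`, "records"))
  if (is.null(recs) || nrow(recs) == 0L) {
    m <- matrix(FALSE, nrow = length(patients), ncol = 0,
                dimnames = list(patients, character(0)))
    return(structure(list(matrix = m, gene_pct = numeric(0),
                          gene_totals = integer(0)),
                     class = "gene_mutation_matrix"))
  }
  recs <- recs[nzchar(recs$gene), , drop = FALSE]
  genes <- sort(unique(recs$gene))
  m <- matrix(FALSE, nrow = length(patients), ncol = length(genes),
              dimnames = list(patients, genes))
  for (i in seq_len(nrow(recs))) {
    m[recs$patient_id[i], recs$gene[i]] <- TRUE
  }
  structure(
    list(
      matrix = m,
      gene_pct = 100 * colSums(m) / length(patients),
      gene_totals = vapply(genes, function(g) sum(recs$gene == g), integer(1))
    ),
    class = "gene_mutation_matrix"
  )
}

#' @export
print.gene_mutation_matrix <- function(x, ...) {
  cat(sprintf("Mutation matrix: %d patient(s) x %d gene(s)\n",
              nrow(x$matrix), ncol(x$matrix)))
  if (ncol(x$matrix)) {
    top <- sort(x$gene_pct, decreasing = TRUE)
    top <- utils::head(top, 5)
    cat("  most frequently mutated:",
        paste(sprintf("%s (%.0f%%)", names(top), top), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Variant report restricted to a gene list
#'
#' Counts variants whose gene symbol falls in a supplied list (for example
#' the DNA damage-repair genes covered by the panel): total variants,
#' number of distinct genes affected, and per-patient counts with their
#' mean and dispersion across patients.
#'
#' @param x either a validated variant data frame (all variants, so indels
#'   count too) or a list of `somatic_callset` objects (somatic SNVs only).
#' @param gene_list nonempty character vector of gene symbols.
#' @param dispersion `"sd"` (sample standard deviation across patients,
#'   default) or `"sem"` (standard error of the mean).
#' @return List with `n_variants`, `n_genes`, `per_patient` (named integer
#'   vector over all patients in `x`, zeros included), `mean` and
#'   `dispersion` (value of the chosen measure).
#' @export
gene_subset_report <- function(x, gene_list, dispersion = c("sd", "sem")) {
  dispersion <- match.arg(dispersion)
  if (length(gene_list) == 0L) {
    stop("gene_list must be a nonempty set of gene symbols", call. = FALSE)
  }
  if (is.data.frame(x)) {
    recs <- validate_variants(x)
    patients <- unique(recs$patient_id)
  } else {
    patients <- vapply(x, `[[`, character(1), "patient_id")
    recs <- do.call(rbind, lapply(x, `[[`, "records"))
    if (is.null(recs)) recs <- empty_variant_table()
  }
  hit <- recs[recs$gene %in% gene_list, , drop = FALSE]
  per_patient <- vapply(patients, function(p) sum(hit$patient_id == p), integer(1))
  names(per_patient) <- patients
  disp_value <- if (length(per_patient) > 1L) {
    s <- stats::sd(per_patient)
    if (dispersion == "sem") s / sqrt(length(per_patient)) else s
  } else {
    NA_real_
  }
  list(
    n_variants = nrow(hit),
    n_genes = length(unique(hit$gene)),
    per_patient = per_patient,
    mean = if (length(per_patient)) mean(per_patient) else NA_real_,
    dispersion = disp_value,
    dispersion_type = dispersion
  )
}
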