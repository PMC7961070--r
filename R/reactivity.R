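#' ELISPOT specific-spot statistic
#'
#' The target-specific spot count of a TIL product is the mean spot count in
#' the presence of target cells minus twice the mean spot count of the
#' product cultured alone (medium). Replicates are aggregated by arithmetic
#' mean by default (median selectable); the result may be negative and is
#' reported as-is, never clipped.
#'
#' @param target_counts,medium_counts nonempty numeric vectors of replicate
#'   spot counts (spots per 5e4 effector cells).
#' @param aggregate `"mean"` (default) or `"median"`.
#' @return The specific-spot statistic (a real number).
#' @examples
#' specific_spots(c(80), c(10))       # 60
#' specific_spots(c(35, 45), c(5, 5)) # 30
#' @export
specific_spots <- function(target_counts, medium_counts,
                           aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  if (!length(target_counts) || !length(medium_counts)) {
    stop("target and medium replicate sets must be nonempty", call. = FALSE)
  }
  agg <- if (aggregate == "mean") mean else stats::median
  agg(target_counts) - 2 * agg(medium_counts)
}

#' Positivity call on a specific-spot value
#'
#' A reactivity is positive when the specific-spot statistic strictly
#' exceeds the threshold (30 spots by convention; exactly 30 is negative).
#'
#' @param specific specific-spot statistic.
#' @param threshold positivity threshold (default 30).
#' @return Logical.
#' @export
call_positive <- function(specific, threshold = 30) {
  specific > threshold
}

#' HLA-I restriction of a tumour response
#'
#' A positive response is HLA-I-restricted when HLA-I blockade reduces the
#' specific-spot statistic by at least `reduction_fraction` (blocked value
#' at or below `(1 - reduction_fraction)` of the unblocked value, which must
#' be positive). Returns `NA` (not assessed) when the blocked condition was
#' not measured.
#'
#' @param specific_unblocked,specific_blocked specific-spot statistics with
#'   and without HLA-I blocking antibody; pass `NULL`/`NA` for the blocked
#'   value when the condition is absent.
#' @param reduction_fraction minimum fractional reduction (default 0.5).
#' @return `TRUE`, `FALSE`, or `NA` when not assessed.
#' @export
hla_restriction <- function(specific_unblocked, specific_blocked = NULL,
                            reduction_fraction = 0.5) {
  if (is.null(specific_blocked) || is.na(specific_blocked)) return(NA)
  specific_unblocked > 0 &&
    specific_blocked <= (1 - reduction_fraction) * specific_unblocked
}

#' Tumour specificity of a response
#'
#' A response is tumour-specific when the autologous-tumour reactivity is
#' positive while the unrelated-tumour reactivity is not. `NA` (not
#' assessed) when the unrelated-target condition was not measured.
#'
#' @param specific_autologous,specific_unrelated specific-spot statistics
#'   against autologous and unrelated tumour targets.
#' @param threshold positivity threshold (default 30).
#' @return `TRUE`, `FALSE`, or `NA` when not assessed.
#' @export
tumour_specificity <- function(specific_autologous, specific_unrelated = NULL,
                               threshold = 30) {
  if (is.null(specific_unrelated) || is.na(specific_unrelated)) return(NA)
  call_positive(specific_autologous, threshold) &&
    !call_positive(specific_unrelated, threshold)
}

#' CD137 upregulation call
#'
#' Confirms activation by flow cytometry: positive when the percentage of
#' CD137+ cells (of gated CD8 blasts) after co-culture with autologous
#' tumour is at least `fold_threshold` times the percentage of the product
#' cultured alone and reaches the absolute floor `min_percent`. The CD137
#' readout is advisory: it confirms, but never overrides, the ELISPOT label.
#'
#' @param percent_alone,percent_tumour CD137+ percentages in \[0, 100\] for
#'   the product alone and with autologous tumour.
#' @param fold_threshold minimum fold increase (default 2).
#' @param min_percent minimum absolute percentage (default 1).
#' @return Logical.
#' @export
cd137_call <- function(percent_alone, percent_tumour,
                       fold_threshold = 2.0, min_percent = 1.0) {
  stopifnot(percent_alone >= 0, percent_alone <= 100,
            percent_tumour >= 0, percent_tumour <= 100)
  percent_tumour >= fold_threshold * percent_alone &&
    percent_tumour >= min_percent
}

#' Reactivity call for one TIL product
#'
#' Computes the specific-spot statistic for every target condition on an
#' ELISPOT plate and derives the positivity, HLA-I-restriction and
#' tumour-specificity calls.
#'
#' @param plate data frame with columns `condition` (one of `medium`,
#'   `autologous_tumour`, `autologous_tumour_plus_HLAblock`,
#'   `unrelated_tumour`, `antiCD3_positive_control`) and `spots` (replicate
#'   counts, one row per replicate); the `medium` condition is required.
#' @param threshold positivity threshold.
#' @param reduction_fraction HLA-blockade reduction fraction.
#' @param aggregate replicate aggregation, `"mean"` or `"median"`.
#' @return List of class `reactivity_call`: `specific` (named vector per
#'   target condition), `positive`, `hla_restricted`, `tumour_specific`
#'   (the latter two `NA` when not assessed).
#' @export
reactivity_call <- function(plate, threshold = 30, reduction_fraction = 0.5,
                            aggregate = "mean") {
  stopifnot(is.data.frame(plate), all(c("condition", "spots") %in% names(plate)))
  if (any(plate$spots < 0)) stop("spot counts must be >= 0", call. = FALSE)
  reps <- split(plate$spots, plate$condition)
  if (!"medium" %in% names(reps)) {
    stop("plate must include a 'medium' condition", call. = FALSE)
  }
  targets <- intersect(
    c("autologous_tumour", "autologous_tumour_plus_HLAblock", "unrelated_tumour"),
    names(reps)
  )
  if (!"autologous_tumour" %in% targets) {
    stop("plate has no autologous_tumour condition", call. = FALSE)
  }
  specific <- vapply(targets, function(cond) {
    specific_spots(reps[[cond]], reps$medium, aggregate)
  }, numeric(1))
  auto <- specific[["autologous_tumour"]]
  blocked <- if ("autologous_tumour_plus_HLAblock" %in% targets) {
    specific[["autologous_tumour_plus_HLAblock"]]
  } else {
    NULL
  }
  unrelated <- if ("unrelated_tumour" %in% targets) {
    specific[["unrelated_tumour"]]
  } else {
    NULL
  }
  structure(
    list(
      specific = specific,
      positive = call_positive(auto, threshold),
      hla_restricted = hla_restriction(auto, blocked, reduction_fraction),
      tumour_specific = tumour_specificity(auto, unrelated, threshold)
    ),
    class = "reactivity_call"
  )
}

#' @export
print.reactivity_call <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "not assessed" else if (v) "yes" else "no"
  cat(sprintf("ELISPOT reactivity: %.1f specific spots vs autologous tumour -> %s\n",
              x$specific[["autologous_tumour"]],
              if (x$positive) "POSITIVE" else "negative"))
  cat(sprintf("  HLA-I-restricted: %s; tumour-specific: %s\n",
              fmt(x$hla_restricted), fmt(x$tumour_specific)))
  invisible(x)
}

#' Classify a patient as tumour-reactive (TR) or not (NTR)
#'
#' A patient is TR when at least one TIL fraction (PD-1neg or PD-1hi
#' derived) mounts a positive response against autologous tumour. A
#' positive but non-HLA-restricted response still counts towards TR and is
#' flagged, mirroring the reporting convention for such responses.
#'
#' @param patient_id identifier.
#' @param calls named list of `reactivity_call` objects, one per fraction
#'   (e.g. `PD1_neg`, `PD1_hi`); at least one must include an
#'   autologous-tumour condition.
#' @return List of class `patient_reactivity`: `patient_id`, `label`
#'   (`"TR"`/`"NTR"`), `responding_fractions`, `flags` (e.g.
#'   `"non-HLA-restricted response (PD1_neg)"`), `calls`.
#' @export
classify_patient <- function(patient_id, calls) {
  if (!length(calls)) {
    stop("no reactivity calls supplied for patient ", patient_id, call. = FALSE)
  }
  stopifnot(all(vapply(calls, inherits, logical(1), "reactivity_call")))
  positive <- vapply(calls, `[[`, logical(1), "positive")
  responding <- names(calls)[positive]
  flags <- character(0)
  for (fr in responding) {
    hla <- calls[[fr]]$hla_restricted
    if (!is.na(hla) && !hla) {
      flags <- c(flags, sprintf("non-HLA-restricted response (%s)", fr))
    }
  }
  structure(
    list(
      patient_id = patient_id,
      label = if (any(positive)) "TR" else "NTR",
      responding_fractions = responding,
      flags = flags,
      calls = calls
    ),
    class = "patient_reactivity"
  )
}

#' @export
print.patient_reactivity <- function(x, ...) {
  cat(sprintf("%s: %s", x$patient_id, x$label))
  if (length(x$responding_fractions)) {
    cat(" (responding:", paste(x$responding_fractions, collapse = ", "), ")")
  }
  cat("\n")
  for (f in x$flags) cat("  flag:", f, "\n")
  invisible(x)
}

#' Classify every patient in a long-format ELISPOT table
#'
#' @param elispot data frame with columns `patient_id`, `fraction`,
#'   `condition`, `spots` (one row per replicate).
#' @param threshold positivity threshold.
#' @param reduction_fraction HLA-blockade reduction fraction.
#' @return Named list of `patient_reactivity` objects.
#' @export
classify_cohort <- function(elispot, threshold = 30, reduction_fraction = 0.5) {
  stopifnot(is.data.frame(elispot),
            all(c("patient_id", "fraction", "condition", "spots") %in% names(elispot)))
  by_patient <- split(elispot, elispot$patient_id)
  lapply(by_patient, function(df) {
    fractions <- split(df, df$fraction)
    assessed <- Filter(function(fr) "autologous_tumour" %in% fr$condition,
                       fractions)
    if (!length(assessed)) {
      stop("patient ", df$patient_id[1],
           " has no fraction tested against autologous tumour", call. = FALSE)
    }
    calls <- lapply(assessed, reactivity_call,
                    threshold = threshold,
                    reduction_fraction = reduction_fraction)
    classify_patient(df$patient_id[1], calls)
  })
}
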