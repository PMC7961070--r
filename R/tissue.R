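#' Validate gating counts against a gating tree
#'
#' Checks the cytometry invariant that every child population is no larger
#' than its parent, for every patient.
#'
#' @param counts data frame with columns `patient_id`, `node`, `count`
#'   (cell counts per gating node).
#' @param tree data frame with columns `node`, `parent` (`NA` or `""` for
#'   the root, typically the living-cell gate).
#' @return The validated `counts` data frame, invisibly usable downstream.
#' @export
validate_gating <- function(counts, tree) {
  stopifnot(is.data.frame(counts),
            all(c("patient_id", "node", "count") %in% names(counts)),
            is.data.frame(tree), all(c("node", "parent") %in% names(tree)))
  if (any(counts$count < 0)) stop("gating counts must be >= 0", call. = FALSE)
  for (pid in unique(counts$patient_id)) {
    sub <- counts[counts$patient_id == pid, ]
    lut <- stats::setNames(sub$count, sub$node)
    for (i in seq_len(nrow(tree))) {
      child <- tree$node[i]; parent <- tree$parent[i]
      if (is.na(parent) || !nzchar(parent)) next
      if (child %in% names(lut) && parent %in% names(lut) &&
          lut[[child]] > lut[[parent]]) {
        stop(sprintf("gating violation for %s: %s (%g) exceeds parent %s (%g)",
                     pid, child, lut[[child]], parent, lut[[parent]]),
             call. = FALSE)
      }
    }
  }
  counts
}

#' Subset frequency relative to a reference population
#'
#' Percentage of a gated subset relative either to its immediate parent in
#' the gating tree or to the living-cell root, the two conventions used when
#' reporting TIL subset frequencies. A zero reference count yields `NA`
#' (frequency undefined, reported as missing rather than 0) with a warning.
#'
#' @param counts gating-count data frame for one patient (`node`, `count`).
#' @param node gating node to quantify.
#' @param reference `"parent"` (immediate parent per `tree`) or the name of
#'   a reference node (e.g. the living gate).
#' @param tree gating-tree data frame (`node`, `parent`); required when
#'   `reference = "parent"`.
#' @return Percentage in \[0, 100\], or `NA` when the reference is empty.
#' @export
subset_frequency <- function(counts, node, reference = "parent", tree = NULL) {
  stopifnot(all(c("node", "count") %in% names(counts)))
  lut <- stats::setNames(counts$count, counts$node)
  if (!node %in% names(lut)) stop("unknown node: ", node, call. = FALSE)
  ref_node <- if (identical(reference, "parent")) {
    if (is.null(tree)) stop("tree required for reference = 'parent'", call. = FALSE)
    p <- tree$parent[match(node, tree$node)]
    if (is.na(p) || !nzchar(p)) node else p
  } else {
    reference
  }
  if (!ref_node %in% names(lut)) stop("unknown reference node: ", ref_node, call. = FALSE)
  ref <- lut[[ref_node]]
  if (ref == 0) {
    warning("reference population '", ref_node, "' is empty; frequency undefined",
            call. = FALSE)
    return(NA_real_)
  }
  100 * lut[[node]] / ref
}

#' Field-averaged multiplex-IF phenotype percentages
#'
#' For each field the phenotype percentage is 100 x cell count / total cells
#' in that field; the per-patient summary is the *unweighted arithmetic
#' mean of the field percentages* (not the pooled-count ratio — the two
#' differ when field totals vary), with its SD and the number of fields,
#' per tissue compartment. Fields where the phenotype is absent contribute
#' 0%.
#'
#' @param table data frame with columns `patient_id`, `field_id`,
#'   `compartment` (`stroma`/`epithelium`), `phenotype`, `cell_count`,
#'   `total_cells_in_field`.
#' @return Data frame `(patient_id, compartment, phenotype, mean_percent,
#'   sd_percent, n_fields)`.
#' @export
if_percentages <- function(table) {
  needed <- c("patient_id", "field_id", "compartment", "phenotype",
              "cell_count", "total_cells_in_field")
  stopifnot(is.data.frame(table), all(needed %in% names(table)))
  if (any(table$cell_count < 0) || any(table$total_cells_in_field <= 0)) {
    stop("cell_count must be >= 0 and total_cells_in_field > 0", call. = FALSE)
  }
  agg <- stats::aggregate(cell_count ~ patient_id + compartment + field_id,
                          data = table, FUN = sum)
  tot <- table[!duplicated(table[c("patient_id", "compartment", "field_id")]),
               c("patient_id", "compartment", "field_id", "total_cells_in_field")]
  chk <- merge(agg, tot)
  over <- chk$cell_count > chk$total_cells_in_field
  if (any(over)) {
    stop("phenotype counts exceed total cells in field(s): ",
         paste(utils::head(chk$field_id[over], 3), collapse = ", "),
         call. = FALSE)
  }
  table$percent <- 100 * table$cell_count / table$total_cells_in_field
  out <- stats::aggregate(
    percent ~ patient_id + compartment + phenotype, data = table,
    FUN = function(v) c(mean = mean(v), sd = stats::sd(v), n = length(v))
  )
  data.frame(
    patient_id = out$patient_id,
    compartment = out$compartment,
    phenotype = out$phenotype,
    mean_percent = out$percent[, "mean"],
    sd_percent = out$percent[, "sd"],
    n_fields = out$percent[, "n"],
    stringsAsFactors = FALSE
  )
}

#' Compare a tissue measurement between TR and NTR patients
#'
#' Thin wrapper over the exact and Monte-Carlo Mann-Whitney tests with the
#' tail and confidence-level conventions used for cytometry (two-tailed,
#' 95%) and IF (one-tailed, 90%, Monte Carlo) comparisons.
#'
#' @param values_tr,values_ntr numeric vectors of per-patient values.
#' @param tail `"two"`, `"greater"` or `"less"` (direction of TR vs NTR).
#' @param method `"exact"` or `"monte_carlo"`.
#' @param confidence_level reporting metadata (does not alter p).
#' @param n_perm,seed Monte-Carlo settings.
#' @return A `group_comparison` object.
#' @export
compare_groups <- function(values_tr, values_ntr, tail = "two",
                           method = c("exact", "monte_carlo"),
                           confidence_level = 0.95,
                           n_perm = 1e5L, seed = 1L) {
  method <- match.arg(method)
  if (method == "exact") {
    exact_mann_whitney(values_tr, values_ntr, tail = tail,
                       confidence_level = confidence_level)
  } else {
    monte_carlo_p(values_tr, values_ntr, tail = tail, n_perm = n_perm,
                  seed = seed, confidence_level = confidence_level)
  }
}
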