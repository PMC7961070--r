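#' Construct a gene x sample count matrix
#'
#' Container for raw probe counts with per-gene class labels (endogenous,
#' housekeeping, positive, negative control) and per-sample group labels
#' (TR, NTR, control, unknown), the substrate of the normalisation chain.
#'
#' @param counts numeric matrix, genes in rows (unique rownames = symbols),
#'   samples in columns (unique colnames), all values >= 0.
#' @param gene_class character vector (length = rows) with values in
#'   `endogenous`, `housekeeping`, `positive`, `negative`.
#' @param groups optional character vector (length = columns) with values in
#'   `TR`, `NTR`, `control`, `unknown`; defaults to `unknown`.
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts, gene_class, groups = NULL) {
  stopifnot(is.matrix(counts), is.numeric(counts))
  if (any(counts < 0, na.rm = TRUE)) stop("counts must be nonnegative", call. = FALSE)
  if (is.null(rownames(counts)) || anyDuplicated(rownames(counts))) {
    stop("counts must have unique gene symbols as rownames", call. = FALSE)
  }
  if (is.null(colnames(counts)) || anyDuplicated(colnames(counts))) {
    stop("counts must have unique sample ids as colnames", call. = FALSE)
  }
  if (length(gene_class) != nrow(counts)) {
    stop("gene_class must have one entry per gene", call. = FALSE)
  }
  if (!all(gene_class %in% c("endogenous", "housekeeping", "positive", "negative"))) {
    stop("gene_class values must be endogenous/housekeeping/positive/negative",
         call. = FALSE)
  }
  if (is.null(groups)) groups <- rep("unknown", ncol(counts))
  if (length(groups) != ncol(counts)) {
    stop("groups must have one entry per sample", call. = FALSE)
  }
  if (!all(groups %in% c("TR", "NTR", "control", "unknown"))) {
    stop("groups must be TR/NTR/control/unknown", call. = FALSE)
  }
  structure(
    list(counts = counts,
         gene_class = stats::setNames(gene_class, rownames(counts)),
         groups = stats::setNames(groups, colnames(counts)),
         provenance = character(0)),
    class = "count_matrix"
  )
}

#' @export
print.count_matrix <- function(x, ...) {
  cls <- table(x$gene_class)
  cat(sprintf("count_matrix: %d genes x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s %d", names(cls), cls), collapse = ", ")))
  if (length(x$provenance)) {
    cat("  normalisation applied:", paste(x$provenance, collapse = " -> "), "\n")
  }
  invisible(x)
}

geomean <- function(v) exp(mean(log(v)))

#' Positive-control normalisation
#'
#' Scales every sample by `target / g_s`, where `g_s` is that sample's
#' geometric mean of the positive-control probes, removing plate/lane
#' intensity differences. By default `target` is the cohort's arithmetic
#' mean of the per-sample geometric means, which keeps values on the
#' original count scale; a fixed numeric `target` anchors the scale to a
#' constant instead, making each sample's factor depend only on its own
#' controls (the choice [normalize_counts()] makes, so that downstream
#' scores are strictly invariant to per-sample rescaling of the raw
#' counts).
#'
#' @param x a `count_matrix`.
#' @param target `NULL` (cohort mean of positive-control geometric means)
#'   or a fixed positive number.
#' @return The `count_matrix` with scaled counts; the scale factors are
#'   attached as attribute `scale_factors` and the step is recorded in
#'   `provenance`.
#' @export
positive_control_normalize <- function(x, target = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  pos <- x$counts[x$gene_class == "positive", , drop = FALSE]
  if (nrow(pos) == 0L) stop("no positive-control genes in matrix", call. = FALSE)
  zero <- colnames(pos)[apply(pos, 2, function(v) any(v <= 0))]
  if (length(zero)) {
    stop("nonpositive positive-control counts in sample(s): ",
         paste(zero, collapse = ", "), call. = FALSE)
  }
  gm <- apply(pos, 2, geomean)
  if (is.null(target)) target <- mean(gm)
  sf <- target / gm
  x$counts <- sweep(x$counts, 2, sf, `*`)
  x$provenance <- c(x$provenance, "positive_control")
  attr(x, "scale_factors") <- sf
  x
}

#' Background flooring from negative controls
#'
#' Sets a per-sample background floor at `mean(negatives) + 2 * sd(negatives)`
#' (sample SD; 0 with a single negative probe), raised to at least 1 so that
#' the subsequent log10 transform is nonnegative, and floors every
#' endogenous and housekeeping value below it.
#'
#' @param x a `count_matrix`.
#' @return The `count_matrix` with floored counts; per-sample floors in
#'   attribute `floors`.
#' @export
background_floor <- function(x) {
  stopifnot(inherits(x, "count_matrix"))
  neg <- x$counts[x$gene_class == "negative", , drop = FALSE]
  if (nrow(neg) == 0L) stop("no negative-control genes in matrix", call. = FALSE)
  sds <- apply(neg, 2, function(v) if (length(v) > 1L) stats::sd(v) else 0)
  floors <- pmax(colMeans(neg) + 2 * sds, 1)
  target <- x$gene_class %in% c("endogenous", "housekeeping")
  for (j in seq_len(ncol(x$counts))) {
    v <- x$counts[target, j]
    x$counts[target, j] <- pmax(v, floors[j])
  }
  x$provenance <- c(x$provenance, "background_floor")
  attr(x, "floors") <- floors
  x
}

#' Select the most stable housekeeping genes
#'
#' Ranks housekeeping genes by ascending coefficient of variation of their
#' log10 positive-control-normalised counts across samples (applying
#' positive-control normalisation internally if it has not been run) and
#' returns the top `k`, ties broken alphabetically.
#'
#' @param x a `count_matrix`.
#' @param k number of housekeeping genes to keep.
#' @return Character vector of `k` gene symbols, most stable first.
#' @export
select_stable_hk <- function(x, k) {
  stopifnot(inherits(x, "count_matrix"))
  hk <- names(x$gene_class)[x$gene_class == "housekeeping"]
  if (length(hk) < k) {
    stop("requested ", k, " housekeeping genes but only ", length(hk),
         " present", call. = FALSE)
  }
  if (!"positive_control" %in% x$provenance) x <- positive_control_normalize(x)
  m <- log10(pmax(x$counts[hk, , drop = FALSE], 1))
  cv <- apply(m, 1, function(v) {
    mu <- mean(v)
    if (mu == 0) Inf else stats::sd(v) / mu
  })
  ord <- order(cv, names(cv))
  names(cv)[ord][seq_len(k)]
}

#' Housekeeping-gene normalisation
#'
#' Scales every sample by `target / h_s`, where `h_s` is that sample's
#' geometric mean of the selected housekeeping genes, removing RNA
#' content/loading differences. As in [positive_control_normalize()],
#' `target` defaults to the cohort mean of the per-sample geometric means
#' and may be fixed to a constant for a cohort-independent scale.
#'
#' @param x a `count_matrix`.
#' @param hk_genes character vector of housekeeping gene symbols present in
#'   the matrix with positive values (run [background_floor()] first).
#' @param target `NULL` (cohort mean) or a fixed positive number.
#' @return The `count_matrix` with scaled counts and updated provenance.
#' @export
hk_normalize <- function(x, hk_genes, target = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  missing <- setdiff(hk_genes, rownames(x$counts))
  if (length(missing)) {
    stop("housekeeping gene(s) absent from matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  hk <- x$counts[hk_genes, , drop = FALSE]
  if (any(hk <= 0)) {
    stop("nonpositive housekeeping values; run background_floor() first",
         call. = FALSE)
  }
  gm <- apply(hk, 2, geomean)
  if (is.null(target)) target <- mean(gm)
  sf <- target / gm
  x$counts <- sweep(x$counts, 2, sf, `*`)
  x$provenance <- c(x$provenance, "housekeeping")
  attr(x, "hk_genes") <- hk_genes
  attr(x, "scale_factors") <- sf
  x
}

#' Full normalisation chain
#'
#' Positive-control scaling, background flooring from negative controls,
#' then housekeeping scaling with the `hk_k` most stable housekeeping
#' genes — the standard nCounter-style scheme, fully specified here so
#' results are reproducible without vendor software. Both scaling steps
#' use fixed targets (`pos_target`, `hk_target`), so every sample's scale
#' factor is a function of that sample's own control probes alone; signature
#' scores computed downstream are then strictly invariant to arbitrary
#' per-sample rescaling of the raw counts, and comparable across cohorts.
#' The defaults put typical probe counts back on a raw-count-like scale.
#'
#' @param x a `count_matrix` of raw counts.
#' @param hk_k number of stable housekeeping genes to use (capped at the
#'   number available).
#' @param pos_target fixed positive-control geometric-mean target.
#' @param hk_target fixed housekeeping geometric-mean target.
#' @return A normalised `count_matrix` (linear scale; take `log10` of
#'   `$counts` for the log view).
#' @export
normalize_counts <- function(x, hk_k = 10L, pos_target = 512,
                             hk_target = 1000) {
  stopifnot(inherits(x, "count_matrix"))
  n_hk <- sum(x$gene_class == "housekeeping")
  if (n_hk < 2L) stop("at least 2 housekeeping genes required", call. = FALSE)
  x <- positive_control_normalize(x, target = pos_target)
  x <- background_floor(x)
  hk <- select_stable_hk(x, min(hk_k, n_hk))
  hk_normalize(x, hk, target = hk_target)
}

#' Read signature gene lists from YAML
#'
#' @param path YAML file of the form `name: [SYMBOL, SYMBOL, ...]`. The
#'   package ships the published IFN-gamma (6-gene), Expanded immune
#'   (18-gene) and T-cell-inflamed (18-gene) lists in
#'   `system.file("extdata", "signatures.yaml", package = "tilmark")`.
#' @return Named list of character vectors of gene symbols.
#' @export
read_signatures <- function(path = system.file("extdata", "signatures.yaml",
                                               package = "tilmark")) {
  sig <- yaml::read_yaml(path)
  if (!length(sig) || any(!lengths(sig))) {
    stop("signature YAML must map names to nonempty gene lists", call. = FALSE)
  }
  lapply(sig, as.character)
}

#' Immune signature score (mean log10 expression)
#'
#' The GEP score of a sample is the arithmetic mean of log10 normalised
#' expression over the signature genes present in the matrix. Signature
#' genes missing from the matrix are reported; when fewer than
#' `coverage_fraction` of them are present the score is refused.
#'
#' @param x a normalised `count_matrix` (see [normalize_counts()]).
#' @param signature character vector of gene symbols, or a single name
#'   looked up in the shipped signature YAML (`"IFN-g"`, `"ExpandedImmune"`,
#'   `"TcellInflamed"`).
#' @param name label for the signature in the output.
#' @param coverage_fraction minimum fraction of signature genes that must be
#'   present (default 0.8).
#' @return Data frame `(sample_id, signature, score)` with the missing genes
#'   (if any) in attribute `missing_genes`.
#' @export
score_signature <- function(x, signature, name = NULL, coverage_fraction = 0.8) {
  stopifnot(inherits(x, "count_matrix"))
  if (length(signature) == 1L && !signature %in% rownames(x$counts)) {
    sigs <- read_signatures()
    if (!signature %in% names(sigs)) {
      stop("unknown signature '", signature, "'", call. = FALSE)
    }
    if (is.null(name)) name <- signature
    signature <- sigs[[signature]]
  }
  if (is.null(name)) name <- "custom"
  present <- intersect(signature, rownames(x$counts))
  missing <- setdiff(signature, rownames(x$counts))
  if (length(present) < coverage_fraction * length(signature)) {
    stop("only ", length(present), "/", length(signature),
         " signature genes present (below coverage ", coverage_fraction,
         "); missing: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  vals <- log10(x$counts[present, , drop = FALSE])
  out <- data.frame(
    sample_id = colnames(x$counts),
    signature = name,
    score = colMeans(vals),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  attr(out, "missing_genes") <- missing
  out
}

#' Differential expression between two sample groups
#'
#' For every endogenous gene, tests log10 normalised expression between the
#' two groups (Welch two-sample t-test by default; exact Mann-Whitney
#' selectable for consistency with the rest of the analysis) and computes
#' the linear-scale fold change as the ratio of group geometric means.
#' Genes are flagged `up` when FC > `fc_up` with p < `alpha`, `down` when
#' FC < `fc_down` with p < `alpha`, otherwise `ns`. Raw p-values drive the
#' flags (no multiplicity correction, matching the p < 0.05 convention of
#' the source analysis); Benjamini-Hochberg q-values are reported alongside.
#'
#' @param x a normalised `count_matrix` with group labels.
#' @param group_a,group_b group labels to compare (FC is a/b).
#' @param test `"welch"` or `"mannwhitney"`.
#' @param fc_up,fc_down fold-change gates for the flags.
#' @param alpha significance gate for the flags.
#' @return Data frame `(gene, fold_change, p_value, q_value, flag)`.
#' @export
differential_expression <- function(x, group_a = "TR", group_b = "NTR",
                                    test = c("welch", "mannwhitney"),
                                    fc_up = 2, fc_down = 0.5, alpha = 0.05) {
  stopifnot(inherits(x, "count_matrix"))
  test <- match.arg(test)
  a_cols <- names(x$groups)[x$groups == group_a]
  b_cols <- names(x$groups)[x$groups == group_b]
  if (length(a_cols) < 2L || length(b_cols) < 2L) {
    stop("need at least 2 samples per group", call. = FALSE)
  }
  genes <- names(x$gene_class)[x$gene_class == "endogenous"]
  lv <- log10(x$counts[genes, , drop = FALSE])
  res <- lapply(genes, function(g) {
    va <- lv[g, a_cols]; vb <- lv[g, b_cols]
    fc <- 10^(mean(va) - mean(vb))
    p <- if (stats::sd(c(va, vb)) == 0) {
      warning("gene ", g, " has constant values in both groups; p = 1",
              call. = FALSE)
      1
    } else if (test == "welch") {
      tryCatch(stats::t.test(va, vb)$p.value,
               error = function(e) {
                 warning("degenerate values for gene ", g, "; p = 1", call. = FALSE)
                 1
               })
    } else {
      exact_mann_whitney(va, vb, tail = "two")$p_value
    }
    c(fc = fc, p = p)
  })
  fc <- vapply(res, `[[`, numeric(1), "fc")
  p <- vapply(res, `[[`, numeric(1), "p")
  flag <- rep("ns", length(genes))
  flag[fc > fc_up & p < alpha] <- "up"
  flag[fc < fc_down & p < alpha] <- "down"
  data.frame(
    gene = genes,
    fold_change = fc,
    p_value = p,
    q_value = stats::p.adjust(p, method = "BH"),
    flag = flag,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Standardise and cluster genes/samples for a heatmap
#'
#' Centres each gene's log10 expression by its cross-sample mean and (by
#' default) divides by its cross-sample SD (per-gene z-score; plain
#' centring selectable), then orders rows and columns by unsupervised
#' hierarchical clustering (Euclidean distance, average linkage). Leaf
#' order is deterministic: `hclust` resolves ties by input order.
#'
#' @param x a normalised `count_matrix`.
#' @param genes character vector of genes to display (e.g. the significant
#'   DEG set), nonempty.
#' @param standardise `"zscore"` (default) or `"center"`.
#' @return List with `matrix` (standardised, genes x samples), `row_order`,
#'   `col_order` (integer permutations), `row_hclust`, `col_hclust`
#'   (`col_hclust` is `NULL`, with a warning, when only one sample).
#' @export
heatmap_prepare <- function(x, genes, standardise = c("zscore", "center")) {
  stopifnot(inherits(x, "count_matrix"))
  standardise <- match.arg(standardise)
  if (length(genes) == 0L) stop("genes must be nonempty", call. = FALSE)
  missing <- setdiff(genes, rownames(x$counts))
  if (length(missing)) {
    stop("gene(s) absent from matrix: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  m <- log10(x$counts[genes, , drop = FALSE])
  mu <- rowMeans(m)
  m <- m - mu
  if (standardise == "zscore") {
    s <- apply(m, 1, stats::sd)
    s[is.na(s) | s == 0] <- 1  # constant rows (or n = 1) stay all-zero
    m <- m / s
  }
  row_hc <- if (nrow(m) > 1L) {
    stats::hclust(stats::dist(m, method = "euclidean"), method = "average")
  } else {
    NULL
  }
  col_hc <- if (ncol(m) > 1L) {
    stats::hclust(stats::dist(t(m), method = "euclidean"), method = "average")
  } else {
    warning("single sample; column clustering skipped", call. = FALSE)
    NULL
  }
  list(
    matrix = m,
    row_order = if (is.null(row_hc)) 1L else row_hc$order,
    col_order = if (is.null(col_hc)) seq_len(ncol(m)) else col_hc$order,
    row_hclust = row_hc,
    col_hclust = col_hc
  )
}
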