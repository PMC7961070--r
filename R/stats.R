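#' @keywords internal
new_group_comparison <- function(statistic, p_value, tail, method,
                                 n_permutations = NA_integer_,
                                 mc_ci_95 = c(NA_real_, NA_real_),
                                 confidence_level = 0.95) {
  structure(
    list(statistic = statistic, p_value = p_value, tail = tail,
         method = method, n_permutations = n_permutations,
         mc_ci_95 = mc_ci_95, confidence_level = confidence_level),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s test (%s-tailed): statistic = %g, p = %.6g\n",
              x$method, x$tail, x$statistic, x$p_value))
  if (identical(x$method, "monte_carlo")) {
    cat(sprintf("  %d permutations, 95%% CI on p: [%.6g, %.6g]\n",
                x$n_permutations, x$mc_ci_95[1], x$mc_ci_95[2]))
  }
  invisible(x)
}

# Mann-Whitney U for group x from pooled mid-ranks.
u_from_ranks <- function(rank_sum_x, nx) rank_sum_x - nx * (nx + 1) / 2

mw_tail_p <- function(u_all, u_obs, nx, ny, tail, eps = 1e-9) {
  mu <- nx * ny / 2
  switch(tail,
    two     = mean(abs(u_all - mu) >= abs(u_obs - mu) - eps),
    greater = mean(u_all >= u_obs - eps),
    less    = mean(u_all <= u_obs + eps)
  )
}

#' Exact Mann-Whitney test by full enumeration
#'
#' Computes the Mann-Whitney U statistic from mid-ranks of the pooled sample
#' and an exact p-value by enumerating all `choose(nx+ny, nx)` assignments of
#' the pooled values to the two groups, which handles ties exactly. The
#' two-tailed p-value is the probability, over all arrangements, that
#' `|U - nx*ny/2|` is at least the observed deviation. Designed for the
#' small cohorts of TIL studies (n <= 12 per group); larger inputs switch to
#' [monte_carlo_p()] with a warning.
#'
#' @param x,y numeric vectors, both nonempty.
#' @param tail `"two"` (default), `"greater"` (x stochastically larger) or
#'   `"less"`.
#' @param confidence_level reporting metadata carried into the result (does
#'   not alter the p-value).
#' @return A `group_comparison` object with `statistic` = U for `x`.
#' @examples
#' exact_mann_whitney(c(1, 2, 3), c(4, 5, 6))$p_value  # 0.1
#' @export
exact_mann_whitney <- function(x, y, tail = c("two", "greater", "less"),
                               confidence_level = 0.95) {
  tail <- match.arg(tail)
  if (length(x) == 0L || length(y) == 0L) {
    stop("both groups must be nonempty", call. = FALSE)
  }
  nx <- length(x); ny <- length(y); n <- nx + ny
  if (max(nx, ny) > 12L) {
    warning("group larger than 12; switching to Monte Carlo estimation",
            call. = FALSE)
    return(monte_carlo_p(x, y, tail = tail, n_perm = 1e5L, seed = 1L,
                         confidence_level = confidence_level))
  }
  pooled <- c(x, y)
  r <- rank(pooled)  # mid-ranks under ties
  u_obs <- u_from_ranks(sum(r[seq_len(nx)]), nx)
  n_arr <- choose(n, nx)
  if (n_arr <= 2e5) {
    idx <- utils::combn(n, nx)
    rank_sums <- colSums(matrix(r[idx], nrow = nx))
  } else {
    rank_sums <- utils::combn(n, nx, FUN = function(i) sum(r[i]))
  }
  u_all <- u_from_ranks(rank_sums, nx)
  p <- mw_tail_p(u_all, u_obs, nx, ny, tail)
  new_group_comparison(u_obs, p, tail, "exact_enumeration",
                       confidence_level = confidence_level)
}

with_local_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

#' Monte Carlo Mann-Whitney p-value
#'
#' Estimates the permutation p-value of the Mann-Whitney U statistic by
#' random re-assignment of the pooled values, using the add-one estimator
#' `(1 + k) / (1 + n_perm)` (valid as a permutation p-value and never zero),
#' with a normal-approximation 95% CI on the estimate. Fully reproducible
#' given `seed`; the global RNG state is restored on exit.
#'
#' @inheritParams exact_mann_whitney
#' @param n_perm number of random permutations, at least 1000.
#' @param seed integer seed for the permutation draws.
#' @return A `group_comparison` object with `method = "monte_carlo"`.
#' @export
monte_carlo_p <- function(x, y, tail = c("two", "greater", "less"),
                          n_perm = 1e5L, seed = 1L, confidence_level = 0.95) {
  tail <- match.arg(tail)
  if (n_perm < 1000L) stop("n_perm must be at least 1000", call. = FALSE)
  nx <- length(x); ny <- length(y); n <- nx + ny
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- u_from_ranks(sum(r[seq_len(nx)]), nx)
  mu <- nx * ny / 2
  eps <- 1e-9
  extreme <- with_local_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      u <- u_from_ranks(sum(r[sample.int(n, nx)]), nx)
      switch(tail,
        two     = abs(u - mu) >= abs(u_obs - mu) - eps,
        greater = u >= u_obs - eps,
        less    = u <= u_obs + eps
      )
    }, logical(1))
  })
  p_hat <- (1 + sum(extreme)) / (1 + n_perm)
  se <- sqrt(p_hat * (1 - p_hat) / n_perm)
  ci <- c(max(0, p_hat - 1.96 * se), min(1, p_hat + 1.96 * se))
  out <- new_group_comparison(u_obs, p_hat, tail, "monte_carlo",
                              n_permutations = as.integer(n_perm),
                              mc_ci_95 = ci,
                              confidence_level = confidence_level)
  out
}

#' Exact Wilcoxon matched-pairs signed-rank test
#'
#' Computes W as the sum of mid-ranks of the positive differences and an
#' exact p-value by enumerating all `2^n` sign assignments of the absolute
#' differences. Zero differences are dropped with a warning (Wilcoxon's
#' convention); with `zeros = "pratt"` they are ranked first and then
#' removed from the statistic (Pratt's method). Suited to paired designs of
#' the size used here (e.g. PD-1hi vs PD-1neg products at n = 5).
#'
#' @param paired_a,paired_b numeric vectors of equal length >= 1.
#' @param tail `"two"`, `"greater"` (a > b) or `"less"`.
#' @param zeros `"drop"` (default) or `"pratt"`.
#' @param confidence_level reporting metadata.
#' @return A `group_comparison` object with `statistic` = W.
#' @examples
#' wilcoxon_signed_rank_exact(2:6, 1:5)$p_value  # 2/32
#' @export
wilcoxon_signed_rank_exact <- function(paired_a, paired_b,
                                       tail = c("two", "greater", "less"),
                                       zeros = c("drop", "pratt"),
                                       confidence_level = 0.95) {
  tail <- match.arg(tail)
  zeros <- match.arg(zeros)
  if (length(paired_a) != length(paired_b) || length(paired_a) < 1L) {
    stop("paired_a and paired_b must have equal length >= 1", call. = FALSE)
  }
  d <- paired_a - paired_b
  zero <- d == 0
  if (all(zero)) {
    warning("all differences are zero; p = 1", call. = FALSE)
    return(new_group_comparison(0, 1, tail, "exact_enumeration",
                                confidence_level = confidence_level))
  }
  if (any(zero)) {
    if (zeros == "drop") {
      warning(sum(zero), " zero difference(s) dropped", call. = FALSE)
      d <- d[!zero]
      ranks <- rank(abs(d))
    } else {
      ranks_all <- rank(abs(d))   # zeros get the smallest ranks
      ranks <- ranks_all[!zero]
      d <- d[!zero]
    }
  } else {
    ranks <- rank(abs(d))
  }
  n <- length(d)
  if (n > 16L) {
    stop("exact sign-flip enumeration supports up to 16 nonzero pairs",
         call. = FALSE)
  }
  w_obs <- sum(ranks[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.numeric(signs %*% ranks)
  mu <- sum(ranks) / 2
  eps <- 1e-9
  p <- switch(tail,
    two     = mean(abs(w_all - mu) >= abs(w_obs - mu) - eps),
    greater = mean(w_all >= w_obs - eps),
    less    = mean(w_all <= w_obs + eps)
  )
  new_group_comparison(w_obs, p, tail, "exact_enumeration",
                       confidence_level = confidence_level)
}

#' Joint TMB/GEP stratification of patients
#'
#' Splits patients into biomarker quadrants at the supplied TMB and GEP
#' cuts and predicts tumour reactivity by the OR rule: a patient is
#' predicted TR when TMB exceeds `tmb_cut` *or* the GEP score exceeds
#' `gep_cut` (equivalently, predicted NTR only in the low/low quadrant).
#' When one biomarker is missing the prediction uses the observed one; a
#' patient missing both is excluded with a warning. Concordance is computed
#' against `tr_label` over labelled patients.
#'
#' @param profiles data frame with columns `patient_id`, `tmb`, a GEP score
#'   column (`gep_<signature>` or `gep`) and optionally `tr_label`
#'   (`"TR"`/`"NTR"`/`"unknown"`).
#' @param tmb_cut,gep_cut numeric thresholds (the study plots draw none;
#'   cuts are an explicit analysis choice).
#' @param signature which signature score column to use (default
#'   `"TcellInflamed"`, i.e. column `gep_TcellInflamed`, falling back to
#'   `gep`).
#' @return An object of class `stratification_result`: list with `table`
#'   (per patient: quadrant, predicted label, true label), `confusion`
#'   (2x2 counts), `concordance` (fraction of labelled patients whose
#'   prediction matches), `tmb_cut`, `gep_cut`.
#' @export
stratify <- function(profiles, tmb_cut, gep_cut, signature = "TcellInflamed") {
  stopifnot(is.data.frame(profiles), "patient_id" %in% names(profiles))
  gep_col <- paste0("gep_", signature)
  if (!gep_col %in% names(profiles)) gep_col <- "gep"
  if (!gep_col %in% names(profiles)) {
    stop("no GEP score column found (expected gep_", signature, " or gep)",
         call. = FALSE)
  }
  if (!"tmb" %in% names(profiles)) stop("profiles must have a tmb column", call. = FALSE)
  tmb <- profiles$tmb
  gep <- profiles[[gep_col]]
  usable <- !(is.na(tmb) & is.na(gep))
  if (any(!usable)) {
    warning("excluding ", sum(!usable),
            " patient(s) missing both biomarkers", call. = FALSE)
  }
  p <- profiles[usable, , drop = FALSE]
  tmb <- tmb[usable]; gep <- gep[usable]
  tmb_high <- !is.na(tmb) & tmb > tmb_cut
  gep_high <- !is.na(gep) & gep > gep_cut
  quadrant <- ifelse(is.na(tmb) | is.na(gep), NA_character_,
    paste0(ifelse(tmb_high, "highTMB", "lowTMB"), "_",
           ifelse(gep_high, "highGEP", "lowGEP")))
  predicted <- ifelse(tmb_high | gep_high, "TR", "NTR")
  tr_label <- if ("tr_label" %in% names(p)) p$tr_label else rep("unknown", nrow(p))
  labelled <- tr_label %in% c("TR", "NTR")
  confusion <- table(
    predicted = factor(predicted[labelled], levels = c("TR", "NTR")),
    truth = factor(tr_label[labelled], levels = c("TR", "NTR"))
  )
  concordance <- if (any(labelled)) {
    mean(predicted[labelled] == tr_label[labelled])
  } else {
    NA_real_
  }
  structure(
    list(
      table = data.frame(
        patient_id = p$patient_id, tmb = tmb, gep = gep,
        quadrant = quadrant, predicted = predicted, tr_label = tr_label,
        stringsAsFactors = FALSE
      ),
      confusion = confusion,
      concordance = concordance,
      tmb_cut = tmb_cut, gep_cut = gep_cut, signature = signature
    ),
    class = "stratification_result"
  )
}

#' @export
print.stratification_result <- function(x, ...) {
  cat(sprintf("TMB/GEP stratification (tmb > %g or %s GEP > %g => predicted TR)\n",
              x$tmb_cut, x$signature, x$gep_cut))
  print(x$confusion)
  cat(sprintf("Concordance with reactivity labels: %.3f\n", x$concordance))
  invisible(x)
}

#' Exploratory cut search for TMB/GEP stratification
#'
#' Scans candidate cuts at midpoints between consecutive observed biomarker
#' values and returns the pair maximising concordance with the reactivity
#' labels. Intended as a desk-scale exploration aid only: with cohorts of
#' ten patients the maximising cuts are over-fitted and are reported, never
#' applied automatically.
#'
#' @inheritParams stratify
#' @return List with `tmb_cut`, `gep_cut`, `concordance`.
#' @export
suggest_cuts <- function(profiles, signature = "TcellInflamed") {
  gep_col <- paste0("gep_", signature)
  if (!gep_col %in% names(profiles)) gep_col <- "gep"
  midpoints <- function(v) {
    v <- sort(unique(v[!is.na(v)]))
    if (length(v) < 2L) return(v)
    (utils::head(v, -1) + utils::tail(v, -1)) / 2
  }
  best <- list(tmb_cut = NA_real_, gep_cut = NA_real_, concordance = -Inf)
  for (tc in midpoints(profiles$tmb)) {
    for (gc in midpoints(profiles[[gep_col]])) {
      s <- stratify(profiles, tc, gc, signature)
      if (!is.na(s$concordance) && s$concordance > best$concordance) {
        best <- list(tmb_cut = tc, gep_cut = gc, concordance = s$concordance)
      }
    }
  }
  best
}
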