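test_that("positive-control scaling matches hand computation on a 2-sample toy", {
  cm <- toy_count_matrix(c("S1", "S2"))
  cm$counts["POS_A", ] <- c(10, 20)
  cm$counts["POS_B", ] <- c(10, 20)  # geomeans 10 and 20, cohort mean 15
  out <- positive_control_normalize(cm)
  sf <- attr(out, "scale_factors")
  expect_equal(unname(sf), c(1.5, 0.75))
  expect_equal(unname(sf["S2"] / sf["S1"]), 0.5)

  # identical samples -> factors all 1; single sample -> 1
  cm2 <- toy_count_matrix(c("A", "B"))
  cm2$counts[, "B"] <- cm2$counts[, "A"]
  expect_equal(unname(attr(positive_control_normalize(cm2), "scale_factors")),
               c(1, 1))
  cm3 <- toy_count_matrix("only")
  expect_equal(unname(attr(positive_control_normalize(cm3), "scale_factors")), 1)
})

test_that("background floor is mean(neg) + 2 sd(neg), at least 1", {
  cm <- toy_count_matrix("S1")
  cm$counts[c("NEG_A", "NEG_B", "NEG_C"), 1] <- c(5, 10, 15)  # floor 10 + 2*5
  cm$counts["END1", 1] <- 8
  cm$counts["SIG1", 1] <- 500
  out <- background_floor(cm)
  expect_equal(unname(attr(out, "floors")), 20)
  expect_equal(out$counts["END1", 1], 20)   # raised to the floor
  expect_equal(out$counts["SIG1", 1], 500)  # untouched above the floor

  cm$counts[c("NEG_A", "NEG_B", "NEG_C"), 1] <- 0
  expect_equal(unname(attr(background_floor(cm), "floors")), 1)

  cm$counts[c("NEG_A", "NEG_B", "NEG_C"), 1] <- 10  # sd 0
  expect_equal(unname(attr(background_floor(cm), "floors")), 10)
})

test_that("housekeeping stability ranking uses CV of log10 values", {
  cm <- toy_count_matrix(c("S1", "S2", "S3"))
  cm$counts["POS_A", ] <- 100; cm$counts["POS_B", ] <- 100  # pos norm = identity
  cm$counts["HK1", ] <- c(200, 200, 200)   # CV 0
  cm$counts["HK2", ] <- c(100, 400, 900)   # variable
  expect_equal(select_stable_hk(cm, 1), "HK1")
  expect_setequal(select_stable_hk(cm, 2), c("HK1", "HK2"))
  expect_error(select_stable_hk(cm, 3), "housekeeping")
})

test_that("housekeeping scaling matches the 2-sample toy and is scale-invariant", {
  cm <- toy_count_matrix(c("S1", "S2"))
  cm$counts["HK1", ] <- c(10, 40)
  cm$counts["HK2", ] <- c(10, 40)  # geomeans 10, 40; cohort mean 25
  out <- hk_normalize(cm, c("HK1", "HK2"))
  expect_equal(unname(attr(out, "scale_factors")), c(2.5, 0.625))

  # with a fixed target, multiplying one sample's whole column is undone
  # exactly (cohort-mean targets undo it up to a cohort-level factor)
  base <- toy_count_matrix(c("S1", "S2"), seed = 3)
  scaled <- base
  scaled$counts[, "S2"] <- scaled$counts[, "S2"] * 7
  n1 <- hk_normalize(base, c("HK1", "HK2"), target = 100)
  n2 <- hk_normalize(scaled, c("HK1", "HK2"), target = 100)
  expect_equal(n1$counts[, "S2"], n2$counts[, "S2"], tolerance = 1e-12)

  cm$counts["HK1", 1] <- 0
  expect_error(hk_normalize(cm, c("HK1", "HK2")), "background_floor")
})

test_that("signature score is the mean log10 over present genes", {
  cm <- toy_count_matrix("S1")
  cm$counts["SIG1", 1] <- 10
  cm$counts["SIG2", 1] <- 1000
  sc <- score_signature(cm, c("SIG1", "SIG2"), name = "toy")
  expect_equal(sc$score, 2.0)  # (1 + 3) / 2

  one <- score_signature(cm, "SIG1", name = "single")
  expect_equal(one$score, 1.0)

  # missing genes are reported; below coverage it errors naming them
  part <- score_signature(cm, c("SIG1", "SIG2", "ABSENT"),
                          name = "partial", coverage_fraction = 0.5)
  expect_equal(attr(part, "missing_genes"), "ABSENT")
  expect_error(
    score_signature(cm, c("SIG1", "ABSENT1", "ABSENT2"), name = "gone"),
    "ABSENT1"
  )
})

test_that("scores are invariant to per-sample scaling of raw counts", {
  spec <- synthetic_cohort_spec(seed = 11, n_patients = 6, n_tr = 3)
  ex <- simulate_expression(spec)
  base <- score_signature(normalize_counts(ex$matrix), "TcellInflamed")
  set.seed(99)
  factors <- runif(ncol(ex$matrix$counts), 0.25, 4)
  scaled <- ex$matrix
  scaled$counts <- sweep(scaled$counts, 2, factors, `*`)
  rescored <- score_signature(normalize_counts(scaled), "TcellInflamed")
  expect_lt(max(abs(base$score - rescored$score)), 1e-10)
})

test_that("raising a signature gene never lowers that sample's score", {
  spec <- synthetic_cohort_spec(seed = 12, n_patients = 4, n_tr = 2)
  ex <- simulate_expression(spec)
  sig <- read_signatures()$TcellInflamed
  for (mult in c(1.5, 3, 10)) {
    bumped <- ex$matrix
    bumped$counts[sig[1], "P01"] <- bumped$counts[sig[1], "P01"] * mult
    s0 <- score_signature(normalize_counts(ex$matrix), "TcellInflamed")
    s1 <- score_signature(normalize_counts(bumped), "TcellInflamed")
    expect_gte(s1$score[s1$sample_id == "P01"],
               s0$score[s0$sample_id == "P01"])
  }
})

deg_matrix <- function() {
  # 6 samples, 3 TR / 3 NTR; GENE_UP is exactly 4x in TR with tiny spread,
  # GENE_MID is 1.8x with tiny spread, GENE_FLAT identical everywhere.
  genes <- c("GENE_UP", "GENE_MID", "GENE_FLAT", "HK1", "HK2",
             "POS_A", "NEG_A", "NEG_B")
  cls <- c("endogenous", "endogenous", "endogenous", "housekeeping",
           "housekeeping", "positive", "negative", "negative")
  tr <- c("T1", "T2", "T3"); ntr <- c("N1", "N2", "N3")
  m <- matrix(100, nrow = length(genes), ncol = 6,
              dimnames = list(genes, c(tr, ntr)))
  m["GENE_UP", tr] <- c(400, 404, 396); m["GENE_UP", ntr] <- c(100, 101, 99)
  m["GENE_MID", tr] <- c(180, 181, 179); m["GENE_MID", ntr] <- c(100, 101, 99)
  count_matrix(m, cls, c("TR", "TR", "TR", "NTR", "NTR", "NTR"))
}

test_that("DEG flags respect both the fold-change and p-value gates", {
  suppressWarnings(deg <- differential_expression(deg_matrix()))
  deg <- deg[match(c("GENE_UP", "GENE_MID", "GENE_FLAT"), deg$gene), ]
  expect_equal(deg$flag, c("up", "ns", "ns"))
  expect_equal(deg$fold_change[1], 10^(mean(log10(c(400, 404, 396))) -
                                         mean(log10(c(100, 101, 99)))))
  expect_lt(deg$p_value[2], 0.05)        # significant but FC-gated to ns
  expect_equal(deg$p_value[3], 1)        # degenerate gene warned to p = 1
  expect_true(all(deg$q_value >= deg$p_value - 1e-12))
  # flag soundness over the whole table
  up <- deg$flag == "up"
  expect_true(all(deg$fold_change[up] > 2 & deg$p_value[up] < 0.05))

  # identical groups: FC 1, ns
  cm <- deg_matrix()
  cm$counts["GENE_UP", ] <- rep(c(100, 120, 110), 2)
  suppressWarnings(deg2 <- differential_expression(cm))
  expect_equal(deg2$fold_change[deg2$gene == "GENE_UP"], 1)
  expect_equal(deg2$flag[deg2$gene == "GENE_UP"], "ns")
})

test_that("the Mann-Whitney DEG variant agrees with the exact test", {
  suppressWarnings(deg <- differential_expression(deg_matrix(),
                                                  test = "mannwhitney"))
  g <- deg_matrix()
  va <- log10(g$counts["GENE_UP", c("T1", "T2", "T3")])
  vb <- log10(g$counts["GENE_UP", c("N1", "N2", "N3")])
  expect_equal(deg$p_value[deg$gene == "GENE_UP"],
               exact_mann_whitney(va, vb)$p_value)
})

test_that("heatmap standardisation and clustering are deterministic", {
  cm <- toy_count_matrix(c("S1", "S2", "S3"), seed = 5)
  hp <- heatmap_prepare(cm, c("SIG1", "SIG2", "END1"))
  expect_equal(unname(rowMeans(hp$matrix)), rep(0, 3))
  expect_equal(unname(apply(hp$matrix, 1, sd)), rep(1, 3))

  centred <- heatmap_prepare(cm, c("SIG1", "SIG2", "END1"),
                             standardise = "center")
  expect_equal(unname(rowMeans(centred$matrix)), rep(0, 3))

  # identical samples sit on adjacent leaves (zero distance)
  cm$counts[, "S2"] <- cm$counts[, "S1"]
  hp2 <- heatmap_prepare(cm, c("SIG1", "SIG2", "END1"))
  pos <- match(c(1, 2), hp2$col_order)
  expect_equal(abs(diff(pos)), 1)

  expect_error(heatmap_prepare(cm, character(0)), "nonempty")
  expect_warning(heatmap_prepare(toy_count_matrix("S1"), c("SIG1", "SIG2")),
                 "single sample")
})

test_that("3x3 heatmap clustering agrees with manual average linkage", {
  m <- matrix(c(1, 1.1, 5,
                2, 2.1, 6,
                10, 10.2, 30), nrow = 3, byrow = TRUE,
              dimnames = list(c("SIG1", "SIG2", "END1"), c("S1", "S2", "S3")))
  cm <- count_matrix(rbind(m,
                           HK1 = 100, HK2 = 100, POS_A = 100, NEG_A = 5),
                     c(rep("endogenous", 3), "housekeeping", "housekeeping",
                       "positive", "negative"))
  hp <- heatmap_prepare(cm, rownames(m))
  # oracle: standardised rows, closest column pair merges first
  z <- t(scale(t(log10(m))))
  d <- as.matrix(dist(t(z)))
  diag(d) <- Inf
  closest <- which(d == min(d), arr.ind = TRUE)[1, ]
  pos <- match(sort(closest), hp$col_order)
  expect_equal(abs(diff(pos)), 1)
  # merge heights equal the manual average-linkage heights
  dd <- dist(t(z))
  h1 <- min(dd)
  rest <- setdiff(1:3, closest)
  h2 <- mean(d[closest, rest])
  expect_equal(hp$col_hclust$height, c(h1, h2))
})

test_that("count matrices round-trip through CSV", {
  spec <- synthetic_cohort_spec(seed = 4, n_patients = 3, n_tr = 1)
  ex <- simulate_expression(spec)
  dir <- tempfile(); dir.create(dir)
  counts_df <- data.frame(gene = rownames(ex$matrix$counts),
                          gene_class = unname(ex$matrix$gene_class),
                          ex$matrix$counts, check.names = FALSE)
  write.csv(counts_df, file.path(dir, "c.csv"), row.names = FALSE, quote = FALSE)
  write.csv(data.frame(sample_id = names(ex$matrix$groups),
                       group = unname(ex$matrix$groups)),
            file.path(dir, "g.csv"), row.names = FALSE, quote = FALSE)
  back <- read_count_matrix(file.path(dir, "c.csv"), file.path(dir, "g.csv"))
  expect_equal(back$counts, ex$matrix$counts)
  expect_equal(back$gene_class, ex$matrix$gene_class)
  expect_equal(back$groups, ex$matrix$groups)
})
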