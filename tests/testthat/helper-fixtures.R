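# Builders for small in-code fixtures shared across the test files.

variant_row <- function(patient_id = "P01", chrom = "chr1", pos = 1000,
                        ref = "A", alt = "T", variant_class = "SNV",
                        depth = 500, call_quality = 80, nc_fraction = 0.01,
                        strand_bias = -100, vaf = 0.20,
                        pop_maf_enf = NA_real_, gene = "TP53",
                        consequence = "non_synonymous") {
  data.frame(patient_id = patient_id, chrom = chrom, pos = pos, ref = ref,
             alt = alt, variant_class = variant_class, depth = depth,
             call_quality = call_quality, nc_fraction = nc_fraction,
             strand_bias = strand_bias, vaf = vaf, pop_maf_enf = pop_maf_enf,
             gene = gene, consequence = consequence,
             stringsAsFactors = FALSE)
}

variant_table_of <- function(...) do.call(rbind, list(...))

# One-line joint evaluation of every somatic predicate, written independently
# of the cascade: the reference the audit trail must agree with.
joint_somatic_oracle <- function(records, th = filter_thresholds()) {
  with(records,
    depth >= th$min_depth &
    call_quality >= th$min_quality &
    !(variant_class == "SNV" & nc_fraction >= th$max_nc_snv) &
    strand_bias <= th$strand_bias_cut &
    vaf >= th$min_vaf &
    !(((vaf >= th$germline_vaf_low & vaf <= th$germline_vaf_high) |
         vaf > th$germline_vaf_upper) &
        !is.na(pop_maf_enf) & pop_maf_enf > 0) &
    variant_class == "SNV")
}

# Random records straddling every filter boundary (no missing metrics).
random_variant_records <- function(n, seed) {
  set.seed(seed)
  df <- variant_row()[rep(1, n), ]
  df$pos <- seq_len(n)
  df$depth <- sample(c(95:105, 50, 500), n, replace = TRUE)
  df$call_quality <- round(runif(n, 30, 60), 1)
  df$nc_fraction <- round(sample(c(0.01, 0.029, 0.03, 0.031, 0.08), n,
                                 replace = TRUE), 4)
  df$strand_bias <- sample(c(-100, -81, -80, -79, -40), n, replace = TRUE)
  df$vaf <- sample(c(0.01, 0.049, 0.05, 0.2, 0.4, 0.5, 0.6, 0.61, 0.8,
                     0.81, 0.95), n, replace = TRUE)
  df$pop_maf_enf <- ifelse(runif(n) < 0.5, NA_real_,
                           round(runif(n, 0, 0.3), 4))
  df$variant_class <- sample(c("SNV", "INDEL", "MNV"), n, replace = TRUE,
                             prob = c(0.7, 0.2, 0.1))
  df$alt[df$variant_class != "SNV"] <- "TA"
  rownames(df) <- NULL
  df
}

# Tiny count matrix: 3 endogenous (2 signature-like), 2 HK, 2 positive,
# 3 negative control genes over `samples`.
toy_count_matrix <- function(samples = c("S1", "S2"), seed = 1,
                             groups = NULL) {
  set.seed(seed)
  genes <- c("SIG1", "SIG2", "END1", "HK1", "HK2", "POS_A", "POS_B",
             "NEG_A", "NEG_B", "NEG_C")
  gene_class <- c("endogenous", "endogenous", "endogenous",
                  "housekeeping", "housekeeping", "positive", "positive",
                  "negative", "negative", "negative")
  m <- matrix(round(runif(length(genes) * length(samples), 100, 1000)),
              nrow = length(genes),
              dimnames = list(genes, samples))
  m["NEG_A", ] <- 5; m["NEG_B", ] <- 10; m["NEG_C", ] <- 15
  count_matrix(m, gene_class, groups)
}

# Independent Mann-Whitney oracle: enumerate group assignments and compute
# U by pairwise comparison counts (not via rank sums).
mw_oracle <- function(x, y, tail = "two") {
  pooled <- c(x, y)
  nx <- length(x); ny <- length(y); n <- nx + ny
  u_of <- function(xs, ys) {
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  u_obs <- u_of(x, y)
  mu <- nx * ny / 2
  combos <- utils::combn(n, nx)
  u_all <- apply(combos, 2, function(i) u_of(pooled[i], pooled[-i]))
  eps <- 1e-9
  switch(tail,
    two = mean(abs(u_all - mu) >= abs(u_obs - mu) - eps),
    greater = mean(u_all >= u_obs - eps),
    less = mean(u_all <= u_obs + eps))
}
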