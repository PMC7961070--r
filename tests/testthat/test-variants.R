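test_that("site filter boundaries follow the printed conventions", {
  th <- filter_thresholds()
  cases <- variant_table_of(
    variant_row(pos = 1, depth = 99),                       # LOW_DEPTH
    variant_row(pos = 2, depth = 100),                      # clean
    variant_row(pos = 3, nc_fraction = 0.03),               # HIGH_NC inclusive
    variant_row(pos = 4, nc_fraction = 0.029),              # clean
    variant_row(pos = 5, vaf = 0.05),                       # VAF 0.05 passes
    variant_row(pos = 6, vaf = 0.049),                      # LOW_VAF
    variant_row(pos = 7, strand_bias = -80),                # -80 passes
    variant_row(pos = 8, strand_bias = -79.5),              # STRAND_BIAS
    variant_row(pos = 9, call_quality = 39.9)               # LOW_QUALITY
  )
  v <- apply_site_filters(cases, th)
  expect_equal(v$passed, c(FALSE, TRUE, FALSE, TRUE, TRUE, FALSE, TRUE,
                           FALSE, FALSE))
  expect_equal(v$reasons[1], "LOW_DEPTH")
  expect_equal(v$reasons[3], "HIGH_NC")
  expect_equal(v$reasons[6], "LOW_VAF")
  expect_equal(v$reasons[8], "STRAND_BIAS")
  expect_equal(v$reasons[9], "LOW_QUALITY")
})

test_that("NC predicate applies to SNVs only and reasons accumulate", {
  indel <- variant_row(variant_class = "INDEL", ref = "A", alt = "AT",
                       nc_fraction = 0.5, depth = 200, call_quality = 60,
                       strand_bias = -90, vaf = 0.2)
  v <- apply_site_filters(indel)
  expect_true(v$passed)

  multi <- variant_row(depth = 10, call_quality = 5, vaf = 0.01)
  v2 <- apply_site_filters(multi)
  expect_false(v2$passed)
  expect_setequal(strsplit(v2$reasons, ";")[[1]],
                  c("LOW_DEPTH", "LOW_QUALITY", "LOW_VAF"))
})

test_that("missing metrics fail closed with a warning, fail open on request", {
  rec <- variant_row(strand_bias = NA_real_)
  expect_warning(v <- apply_site_filters(rec), "MISSING_METRIC")
  expect_false(v$passed)
  expect_match(v$reasons, "MISSING_METRIC")
  v2 <- apply_site_filters(rec, filter_thresholds(missing_metric_fails = FALSE))
  expect_true(v2$passed)
})

test_that("germline rule excludes window VAFs with positive MAF only", {
  th <- filter_thresholds()
  cases <- variant_table_of(
    variant_row(pos = 1, vaf = 0.50, pop_maf_enf = 0.01),  # excluded
    variant_row(pos = 2, vaf = 0.50, pop_maf_enf = NA),    # retained (absent)
    variant_row(pos = 3, vaf = 0.20, pop_maf_enf = 0.01),  # retained (outside window)
    variant_row(pos = 4, vaf = 0.85, pop_maf_enf = 0.02),  # excluded (> 0.8)
    variant_row(pos = 5, vaf = 0.80, pop_maf_enf = 0.02),  # retained (0.8 not > 0.8)
    variant_row(pos = 6, vaf = 0.40, pop_maf_enf = 0.02),  # excluded (closed window)
    variant_row(pos = 7, vaf = 0.60, pop_maf_enf = 0.02)   # excluded (closed window)
  )
  v <- apply_germline_filter(cases, th)
  expect_equal(v$passed, c(FALSE, TRUE, TRUE, FALSE, TRUE, FALSE, FALSE))
  expect_true(all(v$reasons[!v$passed] == "GERMLINE_VAF_MAF"))

  v2 <- apply_germline_filter(cases, filter_thresholds(maf_always_excludes = TRUE))
  expect_false(v2$passed[3])  # any positive MAF excludes under the toggle
  expect_true(v2$passed[2])   # absent MAF still retained
})

test_that("call_somatic keeps only passing SNVs and audits everything", {
  recs <- variant_table_of(
    variant_row(pos = 1),                                           # somatic SNV
    variant_row(pos = 2, variant_class = "INDEL", alt = "AT"),      # clean INDEL
    variant_row(pos = 3, vaf = 0.5, pop_maf_enf = 0.01),            # germline
    variant_row(pos = 4, depth = 10),                               # artifact
    variant_row(pos = 5, vaf = 0.5, pop_maf_enf = NA)               # somatic SNV
  )
  cs <- call_somatic(recs)
  expect_s3_class(cs, "somatic_callset")
  expect_equal(cs$n_somatic_snv, 2L)
  expect_equal(cs$n_somatic_snv, nrow(cs$records))
  expect_true(all(cs$records$variant_class == "SNV"))
  # audit completeness: retained xor >= 1 reason
  expect_equal(sum(cs$audit$passed), cs$n_somatic_snv)
  expect_true(all(nzchar(cs$audit$reasons[!cs$audit$passed])))
  expect_match(cs$audit$reasons[2], "NOT_SNV")

  expect_equal(call_somatic(recs[0, ])$n_somatic_snv, 0L)

  # 5 clean SNVs, 2 germline-flagged -> 3
  recs2 <- do.call(rbind, lapply(1:5, function(i) variant_row(pos = i)))
  recs2$vaf[4:5] <- 0.5
  recs2$pop_maf_enf[4:5] <- 0.01
  expect_equal(call_somatic(recs2)$n_somatic_snv, 3L)
})

test_that("non-synonymous-only counting is available as a toggle", {
  recs <- variant_table_of(
    variant_row(pos = 1, consequence = "non_synonymous"),
    variant_row(pos = 2, consequence = "synonymous")
  )
  expect_equal(call_somatic(recs)$n_somatic_snv, 2L)
  th <- filter_thresholds(count_only_nonsynonymous = TRUE)
  cs <- call_somatic(recs, th)
  expect_equal(cs$n_somatic_snv, 1L)
  expect_match(cs$audit$reasons[2], "NOT_NONSYNONYMOUS")
})

test_that("cascade equals joint predicate evaluation (commutativity)", {
  recs <- random_variant_records(400, seed = 42)
  recs$patient_id <- "P01"
  cs <- call_somatic(recs)
  expect_equal(cs$audit$passed, joint_somatic_oracle(recs))
})

test_that("TMB is SNV count over panel footprint and monotone", {
  mk <- function(k) {
    if (k == 0) return(call_somatic(variant_row()[0, ]))
    call_somatic(do.call(rbind, lapply(seq_len(k),
                                       function(i) variant_row(pos = i))))
  }
  expect_equal(compute_tmb(mk(0))$tmb, 0)
  expect_equal(round(compute_tmb(mk(2))$tmb, 1), 3.8)
  expect_equal(round(compute_tmb(mk(8))$tmb, 1), 15.3)
  # adding one passing SNV raises TMB by exactly 1/panel_mb
  expect_equal(compute_tmb(mk(5))$tmb - compute_tmb(mk(4))$tmb, 1 / 0.524)
  expect_error(compute_tmb(mk(1), panel_mb = 0), "positive")
})

test_that("gene mutation matrix separates boolean cells from totals", {
  recs1 <- variant_table_of(
    variant_row(patient_id = "P01", pos = 1, gene = "TP53"),
    variant_row(patient_id = "P01", pos = 2, gene = "TP53")
  )
  recs2 <- variant_row(patient_id = "P02", pos = 3, gene = "BRCA1")
  callsets <- list(call_somatic(recs1), call_somatic(recs2))
  gm <- gene_mutation_matrix(callsets)
  expect_true(gm$matrix["P01", "TP53"])
  expect_false(gm$matrix["P02", "TP53"])
  expect_equal(unname(gm$gene_totals["TP53"]), 2L)
  expect_equal(unname(gm$gene_pct["TP53"]), 50)
  expect_equal(unname(gm$gene_pct["BRCA1"]), 50)

  # single patient, one gene -> 100%
  gm1 <- gene_mutation_matrix(callsets[1])
  expect_equal(unname(gm1$gene_pct["TP53"]), 100)
})

test_that("gene subset report counts variants in the listed genes", {
  recs <- variant_table_of(
    variant_row(patient_id = "P01", pos = 1, gene = "ATM"),
    variant_row(patient_id = "P01", pos = 2, gene = "ATM"),
    variant_row(patient_id = "P01", pos = 3, gene = "ERCC2"),
    variant_row(patient_id = "P02", pos = 4, gene = "FBXW7"),
    variant_row(patient_id = "P02", pos = 5, gene = "TP53")
  )
  rep <- gene_subset_report(recs, c("ATM", "ERCC2", "FBXW7"))
  expect_equal(rep$n_variants, 4L)
  expect_equal(rep$n_genes, 3L)
  expect_equal(unname(rep$per_patient), c(3L, 1L))
  expect_equal(rep$mean, 2.0)
  expect_equal(rep$dispersion, sd(c(3, 1)))
  sem <- gene_subset_report(recs, c("ATM", "ERCC2", "FBXW7"),
                            dispersion = "sem")
  expect_equal(sem$dispersion, sd(c(3, 1)) / sqrt(2))

  disjoint <- gene_subset_report(recs, "NOTAGENE")
  expect_equal(disjoint$n_variants, 0L)
  expect_equal(disjoint$n_genes, 0L)
  expect_true(all(disjoint$per_patient == 0))
  expect_error(gene_subset_report(recs, character(0)), "nonempty")
})

test_that("tabular reading keeps absent MAF distinct from zero and flags bad rows", {
  tsv <- tempfile(fileext = ".tsv")
  df <- variant_table_of(
    variant_row(pos = 1, pop_maf_enf = NA),
    variant_row(pos = 2, pop_maf_enf = 0.01)
  )
  write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  rd <- read_variant_table(tsv, "tsv")
  expect_true(is.na(rd$pop_maf_enf[1]))
  expect_equal(rd$pop_maf_enf[2], 0.01)

  bad <- df; bad$vaf[2] <- 1.2
  write.table(bad, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_variant_table(tsv, "tsv"), "vaf")

  # unmappable column named in the error
  expect_error(read_variant_table(tsv, "tsv", col_map = c(vaf = "nope")),
               "nope")
})

test_that("VCF reading expands multi-allelic sites into per-ALT records", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    "##INFO=<ID=NC,Number=1,Type=Float,Description=\"No-call fraction\">",
    "##INFO=<ID=SB,Number=1,Type=Float,Description=\"Strand bias\">",
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Allele frequency\">",
    "##INFO=<ID=MAF_ENF,Number=A,Type=Float,Description=\"Population MAF\">",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "chr1\t100\t.\tA\tT,G\t60\t.\tDP=500;NC=0.01;SB=-100;AF=0.2,0.3;GENE=TP53",
    "chr2\t200\t.\tC\tG\t80\t.\tDP=300;NC=0.02;SB=-95;AF=0.5;MAF_ENF=0.1;GENE=BRCA1"
  ), vcf)
  rd <- read_variant_table(vcf, "vcf", patient_id = "P01")
  expect_equal(nrow(rd), 3L)
  expect_equal(rd$alt[1:2], c("T", "G"))
  expect_equal(rd$vaf[1:2], c(0.2, 0.3))
  expect_true(all(is.na(rd$pop_maf_enf[1:2])))  # absent, not zero
  expect_equal(rd$pop_maf_enf[3], 0.1)
  expect_equal(rd$call_quality, c(60, 60, 80))
})
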