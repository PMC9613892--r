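# Genotype QC, HWE, LD pruning, ancestry window and polygenic scoring.

test_that("HWE chi-square p-values match hand-computed oracles", {
  expect_equal(hwe_pvalue(c(25, 50, 25)), 1)
  # (30,40,30): expected (25,50,25), chi2 = 25/25 + 100/50 + 25/25 = 4
  expect_equal(hwe_pvalue(c(30, 40, 30)),
               pchisq(4, df = 1, lower.tail = FALSE), tolerance = 1e-12)
  # all-het: chi2 = n
  expect_lt(hwe_pvalue(c(0, 100, 0)), 1e-15)
  expect_equal(hwe_pvalue(c(0, 100, 0)),
               pchisq(100, df = 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_error(hwe_pvalue(c(0, 0, 0)), "all-zero")
  # monomorphic fits its expectation exactly
  expect_equal(hwe_pvalue(c(100, 0, 0)), 1)
})

test_that("variant QC applies strict call-rate, HWE and MAF thresholds", {
  set.seed(1)
  n <- 100
  ok <- rbinom(n, 2, 0.3)            # healthy variant
  low_cr <- rbinom(n, 2, 0.3); low_cr[1:11] <- NA   # call rate 0.89
  mono <- rep(0, n)                  # MAF 0
  hwe_bad <- rep(1, n)               # all-het
  perfect <- c(rep(0, 25), rep(1, 50), rep(2, 25))  # exact HWE
  g <- tiny_geno(cbind(ok, low_cr, mono, hwe_bad, perfect))
  keep <- variant_qc(g)
  expect_equal(as.vector(keep), c(TRUE, FALSE, FALSE, FALSE, TRUE))
  # idempotence: re-running QC on the filtered matrix removes nothing
  g2 <- genotype_data(g$dosage[, keep, drop = FALSE],
                      g$variants[keep, , drop = FALSE])
  expect_true(all(variant_qc(g2)))
  expect_error(variant_qc(tiny_geno(matrix(numeric(0), 10, 0))), "empty")
})

test_that("LD pruning removes duplicates, keeps independents, matches the brute-force oracle", {
  set.seed(2)
  n <- 300
  dup <- rbinom(n, 2, 0.4)
  g_dup <- tiny_geno(cbind(a = dup, b = dup, c = rbinom(n, 2, 0.4)))
  kept <- ld_prune(g_dup)
  expect_equal(length(kept), 2)     # exactly one of the duplicated pair
  set.seed(3)
  g_ind <- tiny_geno(sapply(1:20, function(i) rbinom(2000, 2, runif(1, 0.2, 0.5))))
  expect_equal(length(ld_prune(g_ind)), 20)
  # 60-variant fixture with correlation blocks vs the quadratic oracle
  set.seed(4)
  blocks <- do.call(cbind, lapply(1:12, function(b) {
    core <- rbinom(400, 2, runif(1, 0.15, 0.5))
    sapply(1:5, function(k) ifelse(runif(400) < 0.15,
                                   rbinom(400, 2, 0.3), core))
  }))
  g60 <- tiny_geno(blocks)
  expect_identical(ld_prune(g60), brute_force_prune(g60))
  # re-pruning the output removes nothing; output is a subset
  kept60 <- ld_prune(g60)
  expect_true(all(kept60 %in% g60$variants$id))
  gk <- genotype_data(g60$dosage[, kept60], g60$variants[match(kept60, g60$variants$id), ])
  expect_identical(ld_prune(gk), kept60)
  # unsorted variants rejected
  bad <- g60
  bad$variants$pos <- rev(bad$variants$pos)
  expect_error(ld_prune(bad), "sorted")
})

test_that("ancestry window keeps subjects within 7 reference SDs, boundary inclusive", {
  ref_mean <- rep(0, 6); ref_sd <- rep(1, 6)
  pc <- rbind(at_mean = rep(0, 6),
              boundary = c(7, 0, 0, 0, 0, 0),
              outside = c(8, 0, 0, 0, 0, 0),
              inside = rep(2, 6))
  keep <- ancestry_filter(pc, ref_mean, ref_sd)
  expect_equal(unname(keep), c(TRUE, TRUE, FALSE, TRUE))
  pc2 <- rbind(pc, missing = c(NA, 0, 0, 0, 0, 0))
  expect_warning(keep2 <- ancestry_filter(pc2, ref_mean, ref_sd), "missing")
  expect_false(keep2[["missing"]])
  expect_error(ancestry_filter(pc[, 1:3], ref_mean, ref_sd, k = 6), "exceeds")
})

test_that("polygenic scores implement weighted allele counting exactly", {
  g <- tiny_geno(rbind(c(0, 1, 2), c(0, 0, 0), c(2, 2, 2)))
  w <- weight_table(c("v001", "v002", "v003"), c("G", "G", "G"),
                    c(0.1, -0.2, 0.3))
  s <- compute_prs(g, w)
  expect_equal(unname(s$score[1]), 0.4)           # 0*0.1 + 1*(-0.2) + 2*0.3
  expect_equal(unname(s$score[2]), 0)             # all dosages zero
  expect_equal(unname(s$score[3]), 2 * (0.1 - 0.2 + 0.3))
  expect_equal(length(s$variants_used) + length(s$variants_skipped), nrow(w))
  # single variant, beta 0.5, dosage 2 -> 1.0
  g1 <- tiny_geno(matrix(2, 1, 1))
  expect_equal(unname(compute_prs(g1, weight_table("v001", "G", 0.5))$score), 1)
})

test_that("scoring orients to the effect allele and imputes missing dosages", {
  g <- tiny_geno(rbind(c(2, NA), c(0, 2), c(1, 0)))
  # effect allele = ref ("A"): dosage flips to 2 - g
  w_ref <- weight_table("v001", "A", 1)
  expect_equal(unname(compute_prs(g, w_ref)$score), c(0, 2, 1))
  # missing dosage -> 2 * effect allele frequency among observed (2,0 -> eaf 0.5)
  w2 <- weight_table("v002", "G", 1)
  expect_equal(unname(compute_prs(g, w2)$score), c(1, 2, 0))
  # mismatched allele and absent variant are skipped with reasons
  w3 <- weight_table(c("v001", "v002", "nope"), c("C", "G", "G"), c(1, 1, 1))
  s3 <- compute_prs(g, w3)
  expect_setequal(s3$skip_reasons$reason, c("allele_mismatch", "not_genotyped"))
  expect_error(compute_prs(g, weight_table("nope", "G", 1)), "zero")
})

test_that("palindromic variants are skipped with a warning", {
  d <- matrix(c(0, 1, 2, 2, 1, 0), 3, 2)
  rownames(d) <- sprintf("S%03d", 1:3)
  variants <- data.frame(id = c("amb", "ok"), chrom = 1L, pos = c(100L, 200L),
                         ref = c("A", "A"), alt = c("T", "G"),
                         stringsAsFactors = FALSE)
  g <- genotype_data(d, variants)
  w <- weight_table(c("amb", "ok"), c("T", "G"), c(1, 1))
  expect_warning(s <- compute_prs(g, w), "palindromic")
  expect_equal(s$variants_used, "ok")
})

test_that("scores are linear in the weights and match the double-loop oracle", {
  set.seed(5)
  for (i in 1:50) {
    n <- sample(5:30, 1); p <- sample(3:12, 1)
    d <- matrix(rbinom(n * p, 2, runif(1, 0.1, 0.5)), n, p)
    d[runif(n * p) < 0.05] <- NA
    d[, 1] <- ifelse(is.na(d[, 1]), 1, d[, 1])  # keep at least one clean column
    g <- tiny_geno(d, ref = sample(c("A", "T"), 1), alt = "G")
    w <- weight_table(g$variants$id, sample(c("G", g$variants$ref[1]), p, replace = TRUE),
                      rnorm(p))
    s <- compute_prs(g, w)
    expect_equal(unname(s$score), prs_oracle(g, w), tolerance = 1e-10)
    w2 <- weight_table(w$variant_id, w$effect_allele, 3.5 * w$beta)
    expect_equal(unname(compute_prs(g, w2)$score), unname(3.5 * s$score),
                 tolerance = 1e-10)
  }
})

test_that("monogenic flags collapse carriers per gene and overall", {
  carriers <- data.frame(subject_id = c("a", "b", "c"),
                         GBA = c(TRUE, FALSE, FALSE),
                         LRRK2 = c(FALSE, TRUE, FALSE),
                         SNCA = c(TRUE, FALSE, FALSE))
  f <- monogenic_flags(carriers)
  expect_equal(f$monogenic_any, c(1L, 1L, 0L))
  expect_equal(f$GBA, c(1L, 0L, 0L))
  expect_equal(f$SNCA, c(1L, 0L, 0L))
  # only-LRRK2 carrier
  expect_equal(unlist(f[2, c("GBA", "LRRK2", "SNCA", "monogenic_any")]),
               c(GBA = 0L, LRRK2 = 1L, SNCA = 0L, monogenic_any = 1L))
  expect_error(monogenic_flags(data.frame(subject_id = "a", PRKN = TRUE)),
               "unknown gene")
})

test_that("dosage TSV and VCF readers reproduce the same genotypes", {
  skip_if_not_installed("vcfR")
  dir <- withr::local_tempdir()
  gt <- rbind(c("0/0", "0/1"), c("1/1", "0/0"), c("0/1", "1|1"))
  vcf <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", "S001", "S002"), collapse = "\t"),
           paste(c("1", "100", "v001", "A", "G", ".", ".", ".", "GT",
                   gt[1, ]), collapse = "\t"),
           paste(c("1", "200", "v002", "C", "T", ".", ".", ".", "GT",
                   gt[2, ]), collapse = "\t"),
           paste(c("1", "300", "v003", "G", "A", ".", ".", ".", "GT",
                   gt[3, ]), collapse = "\t"))
  vcf_path <- file.path(dir, "g.vcf")
  writeLines(vcf, vcf_path)
  g_vcf <- read_vcf_dosage(vcf_path)
  expect_equal(unname(g_vcf$dosage),
               unname(rbind(S001 = c(0, 2, 1), S002 = c(1, 0, 2))))
  # same genotypes via the dosage-TSV path
  dos <- data.frame(subject_id = c("S001", "S002"),
                    v001 = c(0, 1), v002 = c(2, 0), v003 = c(1, 2))
  write.table(dos, file.path(dir, "d.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(g_vcf$variants, file.path(dir, "v.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  g_tsv <- read_dosage_tsv(file.path(dir, "d.tsv"), file.path(dir, "v.tsv"))
  expect_equal(g_tsv$dosage, g_vcf$dosage, ignore_attr = TRUE)
})
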