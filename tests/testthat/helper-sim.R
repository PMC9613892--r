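# Shared fixtures, built in code. Small cohorts are cached per
# (profile, n, seed) so several test files can reuse them without
# regenerating.

.sim_cache <- new.env(parent = emptyenv())

cached_sim <- function(profile = "ppmi_like", n = 200, seed = 101, ...) {
  key <- paste(profile, n, seed, sep = "_")
  if (is.null(.sim_cache[[key]])) {
    .sim_cache[[key]] <- generate_cohort(
      cohort_profile(profile, n_subjects = n, seed = seed, ...))
  }
  .sim_cache[[key]]
}

# small genotype fixture with exact dosages
tiny_geno <- function(dosage, chrom = 1L, ref = "A", alt = "G") {
  p <- ncol(dosage)
  variants <- data.frame(id = sprintf("v%03d", seq_len(p)),
                         chrom = rep(chrom, length.out = p),
                         pos = seq_len(p) * 100L,
                         ref = rep(ref, length.out = p),
                         alt = rep(alt, length.out = p),
                         stringsAsFactors = FALSE)
  rownames(dosage) <- sprintf("S%03d", seq_len(nrow(dosage)))
  genotype_data(dosage, variants)
}

# independent quadratic-time LD pruner implementing the stated rule from
# scratch: windows over the original variant order, pairs in index order,
# remove the lower-MAF member, rescan until clean
brute_force_prune <- function(geno, window = 50, step = 5, r2_max = 0.2) {
  g <- geno$dosage
  p <- ncol(g)
  maf <- sapply(seq_len(p), function(j) {
    f <- mean(g[, j], na.rm = TRUE) / 2
    min(f, 1 - f)
  })
  r2 <- function(i, j) {
    ok <- !is.na(g[, i]) & !is.na(g[, j])
    if (sum(ok) < 3 || sd(g[ok, i]) == 0 || sd(g[ok, j]) == 0) return(0)
    cor(g[ok, i], g[ok, j])^2
  }
  keep <- rep(TRUE, p)
  for (s in seq(1, max(1, p - 1), by = step)) {
    e <- min(s + window - 1, p)
    repeat {
      idx <- which(keep[s:e]) + s - 1
      hit <- FALSE
      if (length(idx) >= 2) {
        for (a in 1:(length(idx) - 1)) {
          for (b in (a + 1):length(idx)) {
            i <- idx[a]; j <- idx[b]
            if (geno$variants$chrom[i] != geno$variants$chrom[j]) next
            if (r2(i, j) > r2_max) {
              keep[if (maf[i] < maf[j]) i else j] <- FALSE
              hit <- TRUE; break
            }
          }
          if (hit) break
        }
      }
      if (!hit) break
    }
    if (e == p) break
  }
  geno$variants$id[keep]
}

# naive double-loop polygenic score oracle (effect-allele orientation and
# allele-frequency imputation of missing dosages, one subject at a time)
prs_oracle <- function(geno, weights) {
  n <- nrow(geno$dosage)
  out <- numeric(n)
  for (i in seq_len(nrow(weights))) {
    j <- match(weights$variant_id[i], geno$variants$id)
    if (is.na(j)) next
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    if (!is.na(comp[geno$variants$ref[j]]) &&
        comp[geno$variants$ref[j]] == geno$variants$alt[j]) next
    ea <- weights$effect_allele[i]
    g <- geno$dosage[, j]
    if (ea == geno$variants$alt[j]) {
    } else if (ea == geno$variants$ref[j]) {
      g <- 2 - g
    } else next
    eaf <- mean(g, na.rm = TRUE) / 2
    for (s in seq_len(n)) {
      gs <- if (is.na(g[s])) 2 * eaf else g[s]
      out[s] <- out[s] + weights$beta[i] * gs
    }
  }
  out
}

# Mann-Whitney U normalization: oracle identity for the trapezoidal ROC AUC
mw_auc <- function(y, prob) {
  r <- rank(prob)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
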