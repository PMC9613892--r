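# Genotype QC, ancestry window filtering, LD pruning, polygenic scoring and
# monogenic flags.

#' Construct a genotype container
#'
#' Holds an additive dosage matrix (subjects x variants, values in \[0, 2\]
#' counting the alternate allele, NA = missing) together with variant
#' metadata.
#'
#' @param dosage numeric matrix, subjects in rows (rownames = subject ids),
#'   variants in columns (colnames = variant ids).
#' @param variants data.frame with columns `id`, `chrom`, `pos`, `ref`,
#'   `alt`, one row per dosage column, in column order.
#' @return object of class `genotype_data`.
#' @export
genotype_data <- function(dosage, variants) {
  stopifnot(is.matrix(dosage), is.data.frame(variants))
  if (ncol(dosage) != nrow(variants)) {
    config_error("dosage columns (%d) and variant rows (%d) differ",
                 ncol(dosage), nrow(variants))
  }
  need <- c("id", "chrom", "pos", "ref", "alt")
  if (!all(need %in% names(variants))) {
    config_error("variant metadata needs columns: %s",
                 paste(need, collapse = ", "))
  }
  if (length(dosage) > 0 && !all(is.na(dosage))) {
    rng <- range(dosage, na.rm = TRUE)
    if (rng[1] < 0 || rng[2] > 2) config_error("dosages must lie in [0, 2]")
  }
  if (anyDuplicated(variants$id)) config_error("variant ids must be unique")
  colnames(dosage) <- variants$id
  structure(list(dosage = dosage, variants = variants),
            class = "genotype_data")
}

#' @export
print.genotype_data <- function(x, ...) {
  cat(sprintf("genotype_data: %d subjects x %d variants (%.2f%% missing)\n",
              nrow(x$dosage), ncol(x$dosage),
              100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' Per-variant genotype counts
#'
#' Hard-calls dosages (rounded to 0/1/2) and tabulates hom-ref / het /
#' hom-alt / missing per variant.
#'
#' @param geno a [genotype_data()].
#' @return data.frame with columns `id`, `hom_ref`, `het`, `hom_alt`,
#'   `missing`.
#' @export
genotype_counts <- function(geno) {
  g <- round(geno$dosage)
  data.frame(
    id = geno$variants$id,
    hom_ref = colSums(g == 0, na.rm = TRUE),
    het = colSums(g == 1, na.rm = TRUE),
    hom_alt = colSums(g == 2, na.rm = TRUE),
    missing = colSums(is.na(g)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Quality-control thresholds for variant filtering
#'
#' Defaults follow standard pre-PCA genotype QC: call rate > 95%,
#' Hardy-Weinberg equilibrium p > 1e-15, minor allele frequency > 1%,
#' LD pruning with a 50-variant window, step 5, r^2 0.2, and a European
#' ancestry window of 7 reference-panel standard deviations on the first 6
#' genetic principal components.
#'
#' @param call_rate_min,hwe_p_min,maf_min scalar thresholds (strict
#'   inequalities are applied).
#' @param prune_window,prune_step,prune_r2 LD-pruning parameters.
#' @param pc_k,pc_sd_window ancestry-window parameters.
#' @return list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(call_rate_min = 0.95, hwe_p_min = 1e-15,
                          maf_min = 0.01, prune_window = 50, prune_step = 5,
                          prune_r2 = 0.2, pc_k = 6, pc_sd_window = 7) {
  check_rates(call_rate_min, "call_rate_min")
  check_rates(maf_min, "maf_min")
  stopifnot(hwe_p_min >= 0, hwe_p_min <= 1, prune_window >= 2,
            prune_step >= 1, prune_r2 > 0, prune_r2 <= 1,
            pc_k >= 1, pc_sd_window > 0)
  structure(list(call_rate_min = call_rate_min, hwe_p_min = hwe_p_min,
                 maf_min = maf_min, prune_window = prune_window,
                 prune_step = prune_step, prune_r2 = prune_r2,
                 pc_k = pc_k, pc_sd_window = pc_sd_window),
            class = "qc_thresholds")
}

#' Hardy-Weinberg equilibrium chi-square p-value
#'
#' One-degree-of-freedom chi-square goodness-of-fit test of the observed
#' genotype counts against the expected Hardy-Weinberg proportions
#' (p^2, 2pq, q^2) at the sample allele frequency. A monomorphic variant
#' fits its expectation exactly and returns p = 1.
#'
#' @param counts numeric vector of length 3: (hom-ref, het, hom-alt).
#' @return scalar p-value.
#' @examples
#' hwe_pvalue(c(25, 50, 25))  # exact HWE proportions: p = 1
#' @export
hwe_pvalue <- function(counts) {
  stopifnot(length(counts) == 3L, all(counts >= 0))
  n <- sum(counts)
  if (n < 1) config_error("all-zero genotype counts")
  p_alt <- (counts[2] + 2 * counts[3]) / (2 * n)
  exp_counts <- n * c((1 - p_alt)^2, 2 * p_alt * (1 - p_alt), p_alt^2)
  nz <- exp_counts > 0
  chisq <- sum((counts[nz] - exp_counts[nz])^2 / exp_counts[nz])
  stats::pchisq(chisq, df = 1, lower.tail = FALSE)
}

#' Variant quality-control mask
#'
#' A variant is retained iff call rate > `call_rate_min` AND HWE p-value >
#' `hwe_p_min` AND minor allele frequency > `maf_min` (all strict).
#'
#' @param geno a [genotype_data()].
#' @param thr a [qc_thresholds()].
#' @return logical keep-mask of length `ncol(dosage)` with a `qc_table`
#'   attribute (per-variant call rate, MAF, HWE p).
#' @export
variant_qc <- function(geno, thr = qc_thresholds()) {
  stopifnot(inherits(geno, "genotype_data"))
  if (ncol(geno$dosage) == 0L) config_error("empty genotype matrix")
  cnt <- genotype_counts(geno)
  n <- nrow(geno$dosage)
  call_rate <- 1 - cnt$missing / n
  n_called <- pmax(cnt$hom_ref + cnt$het + cnt$hom_alt, 1L)
  p_alt <- (cnt$het + 2 * cnt$hom_alt) / (2 * n_called)
  maf <- pmin(p_alt, 1 - p_alt)
  hwe <- vapply(seq_len(nrow(cnt)), function(i) {
    hwe_pvalue(c(cnt$hom_ref[i], cnt$het[i], cnt$hom_alt[i]))
  }, numeric(1))
  keep <- call_rate > thr$call_rate_min & hwe > thr$hwe_p_min &
    maf > thr$maf_min
  attr(keep, "qc_table") <- data.frame(
    id = cnt$id, call_rate = call_rate, maf = maf, hwe_p = hwe,
    keep = keep, stringsAsFactors = FALSE)
  keep
}

# pairwise squared Pearson correlation of two dosage vectors over their
# jointly observed entries
dosage_r2 <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 3L) return(0)
  sa <- stats::sd(a[ok]); sb <- stats::sd(b[ok])
  if (sa == 0 || sb == 0) return(0)
  stats::cor(a[ok], b[ok])^2
}

#' Greedy LD pruning over sliding variant windows
#'
#' Slides a window of `window` consecutive variants along the
#' position-sorted variant list, advancing by `step`. Within each window,
#' pairs of still-retained variants are scanned in index order; whenever a
#' pair's squared dosage correlation exceeds `r2_max`, the member with the
#' lower minor allele frequency is removed (ties remove the later variant).
#' The procedure is deterministic and rescans each window until no retained
#' pair exceeds the threshold.
#'
#' @param geno a [genotype_data()]; variants must be sorted by (chrom, pos).
#' @param window window size in variants.
#' @param step window step in variants.
#' @param r2_max maximum allowed squared correlation.
#' @return character vector of retained variant ids.
#' @export
ld_prune <- function(geno, window = 50, step = 5, r2_max = 0.2) {
  stopifnot(inherits(geno, "genotype_data"))
  v <- geno$variants
  ord <- order(v$chrom, v$pos)
  if (!identical(ord, seq_len(nrow(v)))) {
    config_error("variants must be sorted by (chrom, pos) before pruning")
  }
  g <- geno$dosage
  p <- ncol(g)
  maf <- apply(g, 2, function(col) {
    f <- mean(col, na.rm = TRUE) / 2
    min(f, 1 - f)
  })
  keep <- rep(TRUE, p)
  starts <- seq(1L, max(1L, p - 1L), by = step)
  for (s in starts) {
    e <- min(s + window - 1L, p)
    if (e <= s) next
    # same-chromosome pairs only
    repeat {
      idx <- which(keep[s:e]) + s - 1L
      removed <- FALSE
      if (length(idx) >= 2L) {
        for (ii in seq_len(length(idx) - 1L)) {
          for (jj in seq((ii + 1L), length(idx))) {
            i <- idx[ii]; j <- idx[jj]
            if (v$chrom[i] != v$chrom[j]) next
            if (dosage_r2(g[, i], g[, j]) > r2_max) {
              drop <- if (maf[i] < maf[j]) i else if (maf[j] < maf[i]) j else j
              keep[drop] <- FALSE
              removed <- TRUE
              break
            }
          }
          if (removed) break
        }
      }
      if (!removed) break
    }
    if (e == p) break
  }
  v$id[keep]
}

#' Ancestry window filter on genetic principal components
#'
#' Keeps a subject iff every one of the first `k` principal-component
#' coordinates lies within `n_sd` reference-panel standard deviations of the
#' reference-panel mean (boundary inclusive). Subjects with any missing
#' coordinate are excluded with a warning.
#'
#' @param pc_coords numeric matrix/data.frame, subjects x components
#'   (rownames = subject ids).
#' @param ref_mean,ref_sd numeric vectors of reference-panel means and SDs,
#'   length >= `k`.
#' @param k number of components checked.
#' @param n_sd window half-width in reference SDs.
#' @return logical keep-mask, named by subject.
#' @export
ancestry_filter <- function(pc_coords, ref_mean, ref_sd, k = 6, n_sd = 7) {
  pc <- as.matrix(pc_coords)
  if (k > ncol(pc)) config_error("k = %d exceeds provided components (%d)",
                                 k, ncol(pc))
  stopifnot(length(ref_mean) >= k, length(ref_sd) >= k, all(ref_sd[1:k] > 0))
  dev <- abs(sweep(pc[, 1:k, drop = FALSE], 2, ref_mean[1:k]))
  within <- sweep(dev, 2, n_sd * ref_sd[1:k], "<=")
  keep <- rowSums(within) == k & !apply(is.na(pc[, 1:k, drop = FALSE]), 1, any)
  nmiss <- sum(apply(is.na(pc[, 1:k, drop = FALSE]), 1, any))
  if (nmiss > 0) {
    warning(sprintf("%d subject(s) with missing PC coordinates excluded", nmiss))
    keep[is.na(keep)] <- FALSE
  }
  stats::setNames(as.logical(keep), rownames(pc))
}

#' Read a polygenic-score weight table
#'
#' @param path TSV with header columns `variant_id`, `effect_allele`,
#'   `beta`.
#' @param name score name (e.g. "pd", "ea").
#' @return object of class `weight_table`.
#' @export
read_weight_table <- function(path, name = "prs") {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  weight_table(tab$variant_id, tab$effect_allele, tab$beta, name = name)
}

#' Construct a polygenic-score weight table
#'
#' @param variant_id,effect_allele,beta parallel vectors.
#' @param name score name.
#' @return object of class `weight_table`.
#' @export
weight_table <- function(variant_id, effect_allele, beta, name = "prs") {
  stopifnot(length(variant_id) == length(effect_allele),
            length(variant_id) == length(beta))
  if (anyDuplicated(variant_id)) config_error("weight-table variant ids must be unique")
  if (!all(is.finite(beta))) config_error("betas must be finite")
  structure(data.frame(variant_id = as.character(variant_id),
                       effect_allele = toupper(as.character(effect_allele)),
                       beta = as.numeric(beta), stringsAsFactors = FALSE),
            name = name, class = c("weight_table", "data.frame"))
}

is_palindromic <- function(ref, alt) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  !is.na(comp[ref]) & comp[ref] == alt
}

#' Polygenic score by weighted allele counting
#'
#' For each weight-table entry matched to a genotyped variant by id, the
#' dosage is oriented to the effect allele (g if the effect allele is the
#' alternate allele, 2 - g if it is the reference allele) and accumulated as
#' \eqn{S_j = \sum_i \beta_i g_{ij}}. Missing dosages are imputed as twice
#' the (oriented) effect-allele frequency among observed subjects.
#' Palindromic A/T and C/G variants cannot be strand-resolved and are
#' skipped with a warning; so are variants absent from the genotypes or
#' whose effect allele matches neither allele.
#'
#' @param geno a [genotype_data()].
#' @param weights a [weight_table()].
#' @return list of class `prs_result`: `score` (named per-subject vector),
#'   `variants_used`, `variants_skipped`, `skip_reasons` (data.frame).
#' @export
compute_prs <- function(geno, weights) {
  stopifnot(inherits(geno, "genotype_data"), inherits(weights, "weight_table"))
  v <- geno$variants
  n <- nrow(geno$dosage)
  score <- stats::setNames(numeric(n), rownames(geno$dosage))
  used <- character(0)
  skipped <- data.frame(variant_id = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  for (i in seq_len(nrow(weights))) {
    vid <- weights$variant_id[i]
    j <- match(vid, v$id)
    if (is.na(j)) {
      skipped <- rbind(skipped, data.frame(variant_id = vid,
                                           reason = "not_genotyped")); next
    }
    if (is_palindromic(v$ref[j], v$alt[j])) {
      skipped <- rbind(skipped, data.frame(variant_id = vid,
                                           reason = "ambiguous_palindromic")); next
    }
    ea <- weights$effect_allele[i]
    g <- geno$dosage[, j]
    if (ea == v$alt[j]) {
      # already counts the effect allele
    } else if (ea == v$ref[j]) {
      g <- 2 - g
    } else {
      skipped <- rbind(skipped, data.frame(variant_id = vid,
                                           reason = "allele_mismatch")); next
    }
    if (anyNA(g)) {
      eaf <- mean(g, na.rm = TRUE) / 2
      g[is.na(g)] <- 2 * eaf
    }
    score <- score + weights$beta[i] * g
    used <- c(used, vid)
  }
  if (length(used) == 0L) config_error("zero weight-table variants matched the genotypes")
  if (any(skipped$reason == "ambiguous_palindromic")) {
    warning(sprintf("%d palindromic variant(s) skipped (ambiguous strand)",
                    sum(skipped$reason == "ambiguous_palindromic")))
  }
  structure(list(score = score, variants_used = used,
                 variants_skipped = skipped$variant_id,
                 skip_reasons = skipped, name = attr(weights, "name")),
            class = "prs_result")
}

#' @export
print.prs_result <- function(x, ...) {
  cat(sprintf("polygenic score '%s': %d subjects, %d variants used, %d skipped\n",
              x$name, length(x$score), length(x$variants_used),
              length(x$variants_skipped)))
  invisible(x)
}

#' Monogenic risk flags for GBA, LRRK2 and SNCA
#'
#' Collapses per-subject carrier calls into one binary flag per gene plus a
#' combined any-gene flag.
#'
#' @param carriers data.frame with a `subject_id` column and one logical
#'   (or 0/1) column per gene; gene columns must be among GBA, LRRK2, SNCA.
#' @return data.frame: `subject_id`, `GBA`, `LRRK2`, `SNCA`, `monogenic_any`
#'   (all 0/1; genes absent from the input are 0).
#' @export
monogenic_flags <- function(carriers) {
  stopifnot(is.data.frame(carriers), "subject_id" %in% names(carriers))
  genes <- setdiff(names(carriers), "subject_id")
  known <- c("GBA", "LRRK2", "SNCA")
  bad <- setdiff(genes, known)
  if (length(bad) > 0) config_error("unknown gene(s): %s",
                                    paste(bad, collapse = ", "))
  out <- data.frame(subject_id = carriers$subject_id,
                    stringsAsFactors = FALSE)
  for (gn in known) {
    out[[gn]] <- if (gn %in% genes) as.integer(as.logical(carriers[[gn]])) else 0L
  }
  out$monogenic_any <- as.integer(out$GBA | out$LRRK2 | out$SNCA)
  out
}

#' Read an additive dosage matrix from a simple VCF
#'
#' Parses diploid GT fields of an uncompressed VCF into alternate-allele
#' dosages (requires the `vcfR` package).
#'
#' @param path VCF file path.
#' @return a [genotype_data()].
#' @export
read_vcf_dosage <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    config_error("reading VCF requires the 'vcfR' package")
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  count_alt <- function(x) {
    ifelse(is.na(x), NA_real_,
           vapply(strsplit(gsub("\\|", "/", x), "/"), function(a) {
             sum(a == "1")
           }, numeric(1)))
  }
  dos <- t(apply(gt, 1, count_alt))
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  variants <- data.frame(id = fix$ID, chrom = fix$CHROM,
                         pos = as.integer(fix$POS), ref = fix$REF,
                         alt = fix$ALT, stringsAsFactors = FALSE)
  genotype_data(t(dos), variants)
}

#' Read an additive dosage matrix from TSV
#'
#' Expects a header row of variant ids preceded by a `subject_id` column,
#' plus a companion variant-metadata TSV (`id`, `chrom`, `pos`, `ref`,
#' `alt`).
#'
#' @param dosage_path,variants_path file paths.
#' @return a [genotype_data()].
#' @export
read_dosage_tsv <- function(dosage_path, variants_path) {
  d <- utils::read.delim(dosage_path, stringsAsFactors = FALSE,
                         check.names = FALSE)
  variants <- utils::read.delim(variants_path, stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  genotype_data(m, variants)
}
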