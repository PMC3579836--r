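# Per-locus diagnostics for STR genotype tables: allele frequencies,
# observed/unbiased expected heterozygosity, PIC, Monte-Carlo exact HWE,
# null-allele screening, and the mother-offspring mismatch error rate.

# Extract the two allele columns of one locus; rows with any NA dropped.
locus_genotypes <- function(gt, locus) {
  cols <- paste0(locus, c(".1", ".2"))
  if (!all(cols %in% colnames(gt))) stop("locus not in table: ", locus)
  g <- gt[, cols, drop = FALSE]
  g[stats::complete.cases(g), , drop = FALSE]
}

loci_of <- function(gt) unique(sub("\\.[12]$", "", colnames(gt)))

#' Allele frequencies at one locus
#'
#' @param g two-column matrix of non-missing diploid genotypes at a locus
#'   (one row per typed individual).
#' @return Named numeric vector: allele count / (2 x n typed).
#' @export
allele_frequencies <- function(g) {
  g <- g[stats::complete.cases(g), , drop = FALSE]
  if (!nrow(g)) stop("all genotypes missing at this locus")
  tab <- table(c(g[, 1], g[, 2]))
  freqs <- as.numeric(tab) / (2 * nrow(g))
  stats::setNames(freqs, names(tab))
}

#' Summary statistics for one locus
#'
#' Observed heterozygosity is the fraction of typed individuals carrying two
#' different alleles. Expected heterozygosity uses the small-sample unbiased
#' estimator He = (2n/(2n-1)) (1 - sum p_i^2); set `unbiased = FALSE` for raw
#' gene diversity. PIC = 1 - sum p_i^2 - sum_{i<j} 2 p_i^2 p_j^2. The HWE
#' p-value comes from a seedable Monte-Carlo exact test ([hwe_exact_mc()]);
#' monomorphic loci get He = PIC = 0 and an undefined (NA) HWE p.
#'
#' @param g two-column genotype matrix at one locus (NA rows dropped).
#' @param locus locus name carried into the output.
#' @param n_perm Monte-Carlo permutations for the HWE test.
#' @param seed seed for the HWE test.
#' @param unbiased apply Nei's small-sample correction to He.
#' @return List of class `locus_summary`: locus, n_typed, k, allele_freqs,
#'   Ho, He, PIC, hwe_p, null_allele_z, null_allele_flag.
#' @export
locus_summary <- function(g, locus = "locus", n_perm = 10000L, seed = 1L,
                          unbiased = TRUE) {
  g <- g[stats::complete.cases(g), , drop = FALSE]
  n <- nrow(g)
  if (n < 2L) stop("need at least 2 typed individuals at ", locus)
  p <- allele_frequencies(g)
  k <- length(p)
  Ho <- mean(g[, 1] != g[, 2])
  gd <- 1 - sum(p^2)
  He <- if (unbiased) (2 * n / (2 * n - 1)) * gd else gd
  pic <- 1 - sum(p^2) - (sum(outer(p^2, p^2))  - sum(p^4)) # 2*sum_{i<j} p_i^2 p_j^2
  if (k == 1L) {
    He <- 0; pic <- 0
    hwe <- NA_real_
  } else {
    hwe <- hwe_exact_mc(g, n_perm = n_perm, seed = seed)
  }
  # null-allele screen: heterozygote deficit z-score (Ho below He by more
  # than binomial sampling noise suggests an amplification failure)
  z <- if (He > 0 && He < 1) (Ho - He) / sqrt(He * (1 - He) / n) else NA_real_
  out <- list(locus = locus, n_typed = n, k = k, allele_freqs = p,
              Ho = Ho, He = min(He, 1), PIC = pic, hwe_p = hwe,
              null_allele_z = z,
              null_allele_flag = !is.na(z) && z < -1.96)
  class(out) <- "locus_summary"
  out
}

#' Monte-Carlo exact test of Hardy-Weinberg equilibrium
#'
#' Guo-Thompson style permutation test: the observed alleles are repeatedly
#' shuffled and re-paired into diploid genotypes, and the p-value is the
#' fraction of shuffles whose conditional probability under HWE is no larger
#' than the observed table's (add-one correction). Suited to STR loci with
#' many alleles and sparse genotype classes, where the asymptotic chi-square
#' is unreliable.
#'
#' @param g two-column genotype matrix at one locus.
#' @param n_perm number of permutations (>= 1000 recommended).
#' @param seed integer seed.
#' @return p-value in (0, 1\].
#' @export
hwe_exact_mc <- function(g, n_perm = 10000L, seed = 1L) {
  g <- g[stats::complete.cases(g), , drop = FALSE]
  set.seed(seed)
  alleles <- c(g[, 1], g[, 2])
  n <- nrow(g)
  # log conditional probability of the genotype table given allele counts:
  # log P = log n! + h log 2 - sum log n_gg! + sum log a_k! - log (2n)!
  # terms constant under permutation are dropped
  log_stat <- function(a1, a2) {
    het <- sum(a1 != a2)
    key <- paste(pmin(a1, a2), pmax(a1, a2))
    het * log(2) - sum(lgamma(table(key) + 1))
  }
  obs <- log_stat(g[, 1], g[, 2])
  hits <- 0L
  for (b in seq_len(n_perm)) {
    perm <- sample(alleles)
    s <- log_stat(perm[seq_len(n)], perm[n + seq_len(n)])
    if (s <= obs + 1e-12) hits <- hits + 1L
  }
  (hits + 1) / (n_perm + 1)
}

#' Per-locus summary table for a genotype database
#'
#' One row per locus plus across-locus means and SDs, mirroring the
#' diagnostics conventionally reported for STR parentage databases
#' (alleles/locus, Ho, He, PIC, HWE).
#'
#' @param gt genotype matrix (two columns per locus).
#' @param n_perm,seed passed to [locus_summary()].
#' @return List: `per_locus` data.frame and `across_loci`
#'   (mean and sd of k, Ho, He, PIC).
#' @export
genotype_diagnostics <- function(gt, n_perm = 2000L, seed = 1L) {
  loci <- loci_of(gt)
  rows <- lapply(seq_along(loci), function(i) {
    ls <- locus_summary(locus_genotypes(gt, loci[i]), locus = loci[i],
                        n_perm = n_perm, seed = seed + i)
    data.frame(locus = ls$locus, n_typed = ls$n_typed, k = ls$k,
               Ho = ls$Ho, He = ls$He, PIC = ls$PIC, hwe_p = ls$hwe_p,
               null_allele_flag = ls$null_allele_flag,
               stringsAsFactors = FALSE)
  })
  per_locus <- do.call(rbind, rows)
  across <- sapply(per_locus[, c("k", "Ho", "He", "PIC")],
                   function(x) c(mean = mean(x), sd = stats::sd(x)))
  list(per_locus = per_locus, across_loci = across)
}

#' Mother-offspring mismatch error rate
#'
#' Fraction of genotyped dam-offspring pairs that share no allele at one or
#' more loci typed in both — the aggregate typing-error diagnostic reported
#' for parentage databases.
#'
#' @param pedigree pedigree data.frame.
#' @param gt observed genotype matrix.
#' @return List: `rate`, `n_pairs`, `n_mismatched`.
#' @export
mother_offspring_error_rate <- function(pedigree, gt) {
  loci <- loci_of(gt)
  ids <- rownames(gt)
  pairs <- pedigree[!is.na(pedigree$dam) &
                      pedigree$id %in% ids & pedigree$dam %in% ids,
                    c("id", "dam")]
  if (!nrow(pairs)) stop("no genotyped dam-offspring pairs")
  mism <- vapply(seq_len(nrow(pairs)), function(i) {
    o <- gt[pairs$id[i], ]
    m <- gt[pairs$dam[i], ]
    for (l in loci) {
      oc <- o[paste0(l, c(".1", ".2"))]
      mc <- m[paste0(l, c(".1", ".2"))]
      if (!anyNA(oc) && !anyNA(mc) && !any(oc %in% mc)) return(TRUE)
    }
    FALSE
  }, logical(1))
  list(rate = mean(mism), n_pairs = nrow(pairs), n_mismatched = sum(mism))
}

#' @export
print.locus_summary <- function(x, ...) {
  cat(sprintf("Locus %s: n=%d, k=%d, Ho=%.3f, He=%.3f, PIC=%.3f, HWE p=%s%s\n",
              x$locus, x$n_typed, x$k, x$Ho, x$He, x$PIC,
              ifelse(is.na(x$hwe_p), "NA", sprintf("%.4f", x$hwe_p)),
              if (isTRUE(x$null_allele_flag)) " [null-allele flag]" else ""))
  invisible(x)
}
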