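#' Pedigree kinship coefficient
#'
#' Standard recursive kinship f: for distinct individuals, f(x, y) is the
#' average of f over the later-born individual's parents and the other member;
#' f(x, x) = (1 + f(dam, sire)) / 2. Individuals with unknown parents are
#' treated as unique, mutually unrelated founders, so f is a lower bound when
#' the pedigree is incomplete.
#'
#' @param a,b individual ids.
#' @param ped pedigree data.frame (see [as_pedigree()]).
#' @return Kinship coefficient f in \[0, 1\].
#' @seealso [relatedness()] for r = 2f, [gene_drop_relatedness()] for a
#'   Monte-Carlo cross-check.
#' @export
kinship_coefficient <- function(a, b, ped) {
  px <- ped_index(ped)
  ia <- px$idx[[as.character(a)]]
  ib <- px$idx[[as.character(b)]]
  if (is.null(ia) || is.null(ib)) stop("id not in pedigree")
  # depth = position in topological order; recursing on the later individual
  # guarantees termination and correctness for arbitrary (acyclic) pedigrees
  memo <- new.env(parent = emptyenv())
  f <- function(i, j) {
    if (is.na(i) || is.na(j)) return(0)
    key <- if (i <= j) paste0(i, ":", j) else paste0(j, ":", i)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    val <- if (i == j) {
      (1 + f(px$dam[i], px$sire[i])) / 2
    } else {
      later <- max(i, j); other <- min(i, j)
      (f(px$dam[later], other) + f(px$sire[later], other)) / 2
    }
    memo[[key]] <- val
    val
  }
  f(ia, ib)
}

#' Pedigree relatedness coefficient
#'
#' r = 2f, the expected proportion of alleles shared identical by descent,
#' without inbreeding normalisation. Parent-offspring and full-sib dyads in a
#' non-inbred pedigree have r = 0.5; half first cousins have r = 0.0625.
#'
#' @inheritParams kinship_coefficient
#' @return Relatedness r.
#' @export
relatedness <- function(a, b, ped) 2 * kinship_coefficient(a, b, ped)

#' Half-up rounding for reported relatedness
#'
#' Reported r values follow the conventional half-up rule (0.0625 prints as
#' 0.063), not the round-half-even rule of base [round()].
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return Rounded values.
#' @export
round_half_up <- function(x, digits = 3) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

#' Full kinship matrix (tabular method)
#'
#' Computes f for all pairs in one pass over the topologically ordered
#' pedigree. Used where many pairs are screened (triad design).
#'
#' @param ped pedigree data.frame.
#' @return Symmetric matrix of kinship coefficients with id dimnames.
#' @export
kinship_matrix <- function(ped) {
  px <- ped_index(ped)
  n <- px$n
  K <- matrix(0, n, n, dimnames = list(px$ped$id, px$ped$id))
  dam <- px$dam; sire <- px$sire
  for (i in seq_len(n)) {
    fd <- if (!is.na(dam[i]) && !is.na(sire[i])) K[dam[i], sire[i]] else 0
    K[i, i] <- (1 + fd) / 2
    if (i > 1L) {
      j <- seq_len(i - 1L)
      kd <- if (!is.na(dam[i])) K[dam[i], j] else 0
      ks <- if (!is.na(sire[i])) K[sire[i], j] else 0
      K[i, j] <- K[j, i] <- (kd + ks) / 2
    }
  }
  K
}

#' Gene-dropping estimate of relatedness
#'
#' Monte-Carlo validation oracle: each founder receives two unique allele
#' labels, alleles are transmitted down the pedigree with independent fair
#' picks, and r is estimated as twice the mean probability that a random
#' allele from each individual is identical by descent.
#'
#' @inheritParams kinship_coefficient
#' @param n_drops number of independent drops.
#' @param seed integer seed.
#' @return List with `r_hat` and its Monte-Carlo standard error `se`.
#' @export
gene_drop_relatedness <- function(a, b, ped, n_drops = 1e4, seed = 1L) {
  px <- ped_index(ped)
  ia <- px$idx[[as.character(a)]]; ib <- px$idx[[as.character(b)]]
  if (is.null(ia) || is.null(ib)) stop("id not in pedigree")
  set.seed(seed)
  n <- px$n
  A1 <- matrix(0L, n_drops, n); A2 <- matrix(0L, n_drops, n)
  lab <- 0L
  for (i in seq_len(n)) {
    d <- px$dam[i]; s <- px$sire[i]
    if (is.na(d)) {
      lab <- lab + 1L; A1[, i] <- lab
    } else {
      pick <- stats::runif(n_drops) < 0.5
      A1[, i] <- ifelse(pick, A1[, d], A2[, d])
    }
    if (is.na(s)) {
      lab <- lab + 1L; A2[, i] <- lab
    } else {
      pick <- stats::runif(n_drops) < 0.5
      A2[, i] <- ifelse(pick, A1[, s], A2[, s])
    }
  }
  # f = mean IBD indicator over the 4 allele comparisons; r = 2f
  ibd <- (A1[, ia] == A1[, ib]) + (A1[, ia] == A2[, ib]) +
    (A2[, ia] == A1[, ib]) + (A2[, ia] == A2[, ib])
  per_drop <- 2 * ibd / 4
  list(r_hat = mean(per_drop),
       se = stats::sd(per_drop) / sqrt(n_drops))
}

#' Two-generation unrelatedness predicate
#'
#' TRUE iff the self+parent+grandparent ancestor sets of the two individuals
#' are disjoint (no shared parents or grandparents, and neither is an
#' ancestor of the other within two generations). When an individual's sire
#' (or a grandsire) is unknown, unknown ancestry is never silently treated as
#' disjoint: if `unresolved` supplies candidate-sire sets, any overlap between
#' a member's non-excluded candidates and the other member's ancestor set
#' triggers the expected-relatedness path, and the pair counts as unrelated
#' only if the expected r falls below `r_threshold`.
#'
#' @inheritParams kinship_coefficient
#' @param unresolved optional named list: id -> character vector of
#'   non-excluded candidate sires for individuals whose sire is unknown.
#' @param r_threshold relatedness bound below which an unresolved pair still
#'   counts as unrelated (default 0.063, three-decimal rounding boundary).
#' @param avoidance_r inbreeding-avoidance threshold passed through to
#'   [expected_relatedness()].
#' @return Logical.
#' @export
unrelated_two_generations <- function(a, b, ped, unresolved = NULL,
                                      r_threshold = 0.063,
                                      avoidance_r = 0.25) {
  a <- as.character(a); b <- as.character(b)
  if (a == b) stop("a and b must be distinct individuals")
  anc_a <- ancestors_two_generations(a, ped)
  anc_b <- ancestors_two_generations(b, ped)
  if (length(intersect(anc_a, anc_b))) return(FALSE)
  if (!is.null(unresolved)) {
    unk <- intersect(names(unresolved), c(a, b))
    for (u in unk) {
      other_anc <- if (u == a) anc_b else anc_a
      cands <- unresolved[[u]]
      if (length(intersect(cands, other_anc))) {
        er <- expected_relatedness(a, b, ped, unresolved,
                                   avoidance_r = avoidance_r)
        return(er$expected_r < r_threshold)
      }
    }
  }
  TRUE
}

#' Expected relatedness under unresolved paternity
#'
#' For individuals whose sire is unknown but whose non-excluded candidate
#' sires are listed, the pairwise relatedness is averaged over candidate
#' assignments: each candidate is grafted into the pedigree as the sire and r
#' is recomputed. Weights are uniform over candidates after zeroing those
#' whose relatedness with the individual's dam reaches `avoidance_r`
#' (inbreeding-avoidance adjustment); if all candidates are zeroed the
#' weights fall back to uniform with a warning. When both members are
#' unresolved the average runs over the product of the two candidate sets
#' (independent choices).
#'
#' @inheritParams kinship_coefficient
#' @param unresolved named list: id -> character vector of candidate sire ids;
#'   must cover every individual of the pair whose sire is `NA` that should be
#'   averaged over.
#' @param avoidance_r hard rejection threshold on r(candidate, dam).
#' @return List with fields `pair`, `candidate_sires` (named weight vectors),
#'   and `expected_r`.
#' @export
expected_relatedness <- function(a, b, ped, unresolved, avoidance_r = 0.25) {
  a <- as.character(a); b <- as.character(b)
  unk <- intersect(names(unresolved), c(a, b))
  if (!length(unk)) {
    return(list(pair = c(a, b), candidate_sires = list(),
                expected_r = relatedness(a, b, ped)))
  }
  weights <- lapply(unk, function(u) {
    cands <- as.character(unresolved[[u]])
    if (!length(cands)) stop("empty candidate set for ", u)
    dam_u <- ped$dam[match(u, ped$id)]
    w <- rep(1, length(cands))
    if (!is.na(dam_u)) {
      rc <- vapply(cands, function(cnd) relatedness(cnd, dam_u, ped), 0)
      w[rc >= avoidance_r] <- 0
    }
    if (all(w == 0)) {
      warning("all candidate sires of ", u,
              " fail the inbreeding-avoidance screen; using uniform weights")
      w <- rep(1, length(cands))
    }
    stats::setNames(w / sum(w), cands)
  })
  names(weights) <- unk
  combos <- expand.grid(lapply(weights, names), stringsAsFactors = FALSE)
  er <- 0
  for (k in seq_len(nrow(combos))) {
    ped_k <- ped
    wk <- 1
    for (u in unk) {
      cand <- combos[[u]][k]
      ped_k$sire[ped_k$id == u] <- cand
      wk <- wk * weights[[u]][[cand]]
    }
    if (wk > 0) er <- er + wk * relatedness(a, b, as_pedigree(ped_k))
  }
  list(pair = c(a, b), candidate_sires = weights, expected_r = er)
}
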