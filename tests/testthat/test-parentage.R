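# enumeration oracle: a candidate is compatible iff some choice of
# transmitted alleles (maternal from the mother where she is informative,
# paternal from the candidate) reproduces the offspring genotype
oracle_compatible <- function(off, cand, mother = NULL) {
  if (!is.null(mother) && any(off %in% mother)) {
    for (am in mother) for (ap in cand) {
      if (setequal(sort(c(am, ap)), sort(off)) ||
          all(sort(c(am, ap)) == sort(off))) return(TRUE)
    }
    return(FALSE)
  }
  any(cand %in% off)  # duo logic (also the maternal-mismatch fallback)
}

test_that("candidate sires respect age and the 200-day presence rule", {
  ped <- data.frame(
    id = c("kid", "mA", "mB", "mC", "mD"),
    sex = c("F", "M", "M", "M", "M"),
    birth_date = as.Date(c("2010-06-01", "1995-01-01", "1995-01-01",
                           "2006-01-01", "1995-01-01")),
    dam = NA_character_, sire = NA_character_, stringsAsFactors = FALSE)
  census <- data.frame(
    id = ped$id,
    start = as.Date(c("2010-06-01", "1995-01-01",
                      "2010-02-21",  # arrives only 100 days before birth
                      "2006-01-01", "1995-01-01")),
    end = as.Date(c("2012-01-01", "2012-01-01", "2012-01-01", "2012-01-01",
                    "2009-01-01")),  # mD gone before conception
    stringsAsFactors = FALSE)
  got <- candidate_sires("kid", ped, census, min_age_years = 6)
  expect_setequal(got, "mA")  # mB present too late, mC too young, mD absent
  expect_error(candidate_sires("ghost", ped, census), "not in pedigree")
  ped$birth_date[1] <- NA
  expect_error(candidate_sires("kid", ped, census), "birth date")
  # empty male population
  ped2 <- ped[1, ]; ped2$birth_date <- as.Date("2010-06-01")
  expect_length(candidate_sires("kid", ped2, census[1, ]), 0)
})

test_that("candidate filter equals a brute-force scan on a random census", {
  set.seed(14)
  n <- 200L
  ped <- data.frame(
    id = c("kid", sprintf("m%03d", 1:n)),
    sex = c("F", rep("M", n)),
    birth_date = c(as.Date("2012-07-15"),
                   as.Date("1990-01-01") + sample.int(7000, n)),
    dam = NA_character_, sire = NA_character_, stringsAsFactors = FALSE)
  census <- data.frame(
    id = ped$id,
    start = ped$birth_date + sample.int(300, n + 1, TRUE),
    stringsAsFactors = FALSE)
  census$end <- census$start + sample.int(6000, n + 1, TRUE)
  census$start[1] <- ped$birth_date[1]; census$end[1] <- as.Date("2015-01-01")
  got <- candidate_sires("kid", ped, census, min_age_years = 6,
                         lead_days = 200)
  ref <- as.Date("2012-07-15") - 200
  want <- character(0)
  for (i in 2:(n + 1)) {
    age <- as.numeric(ref - ped$birth_date[i]) / 365.25
    if (age >= 6 && census$start[i] <= ref && census$end[i] >= ref) {
      want <- c(want, ped$id[i])
    }
  }
  expect_setequal(got, want)
})

test_that("locus compatibility matches full enumeration over 3 alleles", {
  # hand cases
  expect_false(locus_compatible(c(1, 2), c(1, 3), mother = c(1, 1)))
  expect_false(locus_compatible(c(1, 2), c(3, 4)))
  expect_true(locus_compatible(c(1, 2), c(2, 3), mother = c(1, 1)))
  gts <- list(c(1, 1), c(2, 2), c(3, 3), c(1, 2), c(1, 3), c(2, 3))
  for (off in gts) for (cand in gts) {
    expect_identical(as.logical(locus_compatible(off, cand)),
                     oracle_compatible(off, cand))
    for (mom in gts) {
      got <- locus_compatible(off, cand, mom)
      expect_identical(as.logical(got), oracle_compatible(off, cand, mom),
                       info = paste("off", paste(off, collapse = "/"),
                                    "cand", paste(cand, collapse = "/"),
                                    "mom", paste(mom, collapse = "/")))
      expect_identical(attr(got, "maternal_mismatch"), !any(off %in% mom))
    }
  }
})

test_that("exclusion profiles count mismatches like a per-locus loop and
           gate testability at 12/15 common loci", {
  cl <- colony()
  ped <- cl$pedigree
  cfg0 <- sim_config(seed = 7, typing_error_rate = 0, mean_typed_loci = 21)
  g0 <- simulate_genotypes(ped, cfg0)
  kids <- utils::tail(ped$id[!is.na(ped$sire)], 10)
  for (oid in kids) {
    sire <- ped$sire[match(oid, ped$id)]
    mom <- ped$dam[match(oid, ped$id)]
    others <- setdiff(sample(rownames(g0$observed), 5), c(oid, sire, mom))
    prof <- exclusion_profiles(oid, c(sire, others), g0$observed, mom)
    expect_equal(prof$n_mismatches[prof$candidate == sire], 0L)
    # per-locus loop oracle
    for (ci in seq_len(nrow(prof))) {
      cid <- prof$candidate[ci]
      mis <- 0L; common <- 0L
      for (l in cl$geno$loci) {
        og <- g0$observed[oid, paste0(l, c(".1", ".2"))]
        cg <- g0$observed[cid, paste0(l, c(".1", ".2"))]
        mg <- g0$observed[mom, paste0(l, c(".1", ".2"))]
        if (anyNA(og) || anyNA(cg)) next
        common <- common + 1L
        mm <- if (anyNA(mg)) NULL else mg
        if (!oracle_compatible(og, cg, mm)) mis <- mis + 1L
      }
      expect_equal(prof$n_common_loci[ci], common)
      expect_equal(prof$n_mismatches[ci], mis)
    }
  }
  # trio with 11 common loci is untestable, 12 testable
  mk <- function(n_loci_typed) {
    L <- 21L
    gt <- matrix(rep(c(1L, 2L), each = 1), 3, 2 * L,
                 dimnames = list(c("off", "mom", "cand"),
                                 paste0(rep(sprintf("L%02d", 1:L), each = 2),
                                        c(".1", ".2"))))
    gt[, seq(1, 2 * L, 2)] <- 1L; gt[, seq(2, 2 * L, 2)] <- 2L
    gt["cand", (2 * n_loci_typed + 1):(2 * L)] <- NA_integer_
    gt
  }
  p11 <- exclusion_profiles("off", "cand", mk(11), "mom")
  expect_false(p11$testable)
  p12 <- exclusion_profiles("off", "cand", mk(12), "mom")
  expect_true(p12$testable)
  expect_equal(p12$mode, "trio")
  # duo needs 15
  p14 <- exclusion_profiles("off", "cand", mk(14), mother = NULL)
  expect_false(p14$testable)
  p15 <- exclusion_profiles("off", "cand", mk(15), mother = NULL)
  expect_true(p15$testable)
})

# enumeration oracle for the error-free likelihood ratio at one locus
oracle_lr_locus <- function(go, gc, gm, p) {
  trans <- function(a, g) mean(g == a)
  pop <- function(a) p[[as.character(a)]]
  off_prob <- function(mat_fun, pat_fun) {
    if (go[1] == go[2]) mat_fun(go[1]) * pat_fun(go[1])
    else mat_fun(go[1]) * pat_fun(go[2]) + mat_fun(go[2]) * pat_fun(go[1])
  }
  if (!is.null(gm) && any(go %in% gm)) {
    num <- off_prob(function(a) trans(a, gm), function(a) trans(a, gc))
    den <- off_prob(function(a) trans(a, gm), pop)
  } else {
    num <- off_prob(pop, function(a) trans(a, gc))
    den <- off_prob(pop, pop)
  }
  num / den
}

test_that("LOD scores equal hand and enumeration oracles at e = 0", {
  f1 <- list(L01 = c("1" = 0.5, "2" = 0.5))
  gt <- matrix(1L, 3, 2, dimnames = list(c("off", "mom", "cand"),
                                         c("L01.1", "L01.2")))
  expect_equal(as.numeric(lod_score("off", "cand", "mom", gt, f1, 0)),
               log(2))
  # incompatible candidate collapses to the sentinel
  gt2 <- gt; gt2["cand", ] <- c(2L, 2L)
  gt2["mom", ] <- c(1L, 1L); gt2["off", ] <- c(1L, 1L)
  expect_lt(as.numeric(lod_score("off", "cand", "mom", gt2, f1, 0)), -1e7)
  # random trios and duos against the enumeration oracle
  set.seed(17)
  p3 <- list(L01 = c("1" = 0.5, "2" = 0.3, "3" = 0.2))
  for (rep_i in 1:60) {
    draw <- function() sample(1:3, 2, TRUE, prob = c(0.5, 0.3, 0.2))
    gm <- draw(); gc <- draw()
    go <- c(sample(gm, 1), sample(gc, 1))  # true child of the pair
    if (rep_i %% 2 == 0) {                 # also exercise non-offspring
      go <- draw()
    }
    g3 <- rbind(off = go, mom = gm, cand = gc)
    colnames(g3) <- c("L01.1", "L01.2")
    use_mom <- rep_i %% 3 != 0
    lr <- oracle_lr_locus(go, gc, if (use_mom) gm else NULL, p3$L01)
    got <- as.numeric(lod_score("off", "cand",
                                if (use_mom) "mom" else NULL,
                                g3, p3, 0))
    if (lr == 0) expect_lt(got, -1e7) else expect_equal(got, log(lr))
  }
})

test_that("unseen alleles are floored rather than zeroing the likelihood", {
  f1 <- list(L01 = c("1" = 0.9, "2" = 0.1))
  gt <- matrix(c(3L, 1L, 3L, 3L), 2, 2, byrow = TRUE,
               dimnames = list(c("off", "cand"), c("L01.1", "L01.2")))
  got <- lod_score("off", "cand", NULL, gt, f1, 0)
  expect_true(is.finite(as.numeric(got)))
  expect_true(length(attr(got, "floored_alleles")) > 0)
})

test_that("the decision rule reproduces the exclusion/likelihood case split", {
  L <- 21L
  loci <- sprintf("L%02d", 1:L)
  cn <- paste0(rep(loci, each = 2), c(".1", ".2"))
  base <- matrix(1L, 5, 2 * L, dimnames = list(
    c("off", "mom", "true_sire", "rival1", "rival2"), cn))
  base["off", seq(2, 2 * L, 2)] <- 2L
  base["true_sire", ] <- 2L
  # rival1: 3 mismatching loci; rival2: 5
  mism <- function(row, k) {
    row[1:(2 * k)] <- 3L
    row
  }
  base["rival1", ] <- mism(base["true_sire", ], 3)
  base["rival2", ] <- mism(base["true_sire", ], 5)
  freqs <- stats::setNames(rep(list(c("1" = 0.4, "2" = 0.4, "3" = 0.2)), L),
                           loci)
  a <- assign_paternity("off", c("true_sire", "rival1", "rival2"), base,
                        "mom", freqs, error_rate = 0)
  expect_equal(a$sire, "true_sire")
  expect_equal(a$basis, "exclusion_strict")
  # one rival at exactly one mismatch: requires likelihood confirmation
  base2 <- base
  base2["rival1", ] <- mism(base["true_sire", ], 1)
  a2 <- assign_paternity("off", c("true_sire", "rival1", "rival2"), base2,
                         "mom", freqs, error_rate = 0.01,
                         critical_delta = 1)
  expect_equal(a2$basis, "likelihood_confirmed")
  expect_equal(a2$sire, "true_sire")
  expect_equal(a2$confidence_level, "95%")
  expect_true(a2$delta >= 1)
  # unreachable critical delta leaves the case unresolved
  a3 <- assign_paternity("off", c("true_sire", "rival1", "rival2"), base2,
                         "mom", freqs, error_rate = 0.01,
                         critical_delta = 1e6)
  expect_equal(a3$basis, "unresolved")
  # no zero-mismatch candidate
  a4 <- assign_paternity("off", c("rival1", "rival2"),
                         base, "mom", freqs, error_rate = 0)
  expect_equal(a4$basis, "unresolved")
  expect_true(is.na(a4$sire))
  # order independence of the candidate list
  a5 <- assign_paternity("off", c("rival2", "rival1", "true_sire"), base,
                         "mom", freqs, error_rate = 0)
  expect_equal(a5$sire, a$sire)
  expect_equal(a5$basis, a$basis)
})

test_that("critical delta is monotone in confidence level and locus count", {
  p <- c("1" = 0.3, "2" = 0.25, "3" = 0.2, "4" = 0.15, "5" = 0.1)
  mkf <- function(L) stats::setNames(rep(list(p), L), sprintf("L%02d", 1:L))
  cd95 <- confidence_critical_delta(mkf(16), n_candidates = 8,
                                    n_offspring_reps = 150, level = 0.95,
                                    seed = 5)
  cd80 <- confidence_critical_delta(mkf(16), n_candidates = 8,
                                    n_offspring_reps = 150, level = 0.80,
                                    seed = 5)
  expect_lte(cd80$critical_delta, cd95$critical_delta)
  # fully informative loci: nearly every assignment is correct
  expect_gte(cd95$success_rate, 0.95)
  # more loci never hurt (averaged over seeds)
  d_short <- d_long <- numeric(10)
  for (s in 1:10) {
    d_short[s] <- confidence_critical_delta(
      mkf(8), n_candidates = 8, n_offspring_reps = 120, level = 0.95,
      error_rate = 0.02, prop_loci_typed = 0.9,
      seed = 50 + s)$critical_delta
    d_long[s] <- confidence_critical_delta(
      mkf(16), n_candidates = 8, n_offspring_reps = 120, level = 0.95,
      error_rate = 0.02, prop_loci_typed = 0.9,
      seed = 50 + s)$critical_delta
  }
  expect_lte(mean(d_long), mean(d_short))
  expect_warning(
    confidence_critical_delta(mkf(8), n_candidates = 1,
                              n_offspring_reps = 10, level = 0.95, seed = 1),
    "degenerate")
})

test_that("grandsire cascade recovers simulated truth and skips ungenotyped
           branches", {
  cl <- colony()
  ped <- cl$pedigree
  cfg0 <- sim_config(seed = 7, typing_error_rate = 0, mean_typed_loci = 21)
  g0 <- simulate_genotypes(ped, cfg0)
  # focal individuals with a known dam whose sire is known (3 generations)
  focal <- ped$id[!is.na(ped$dam) &
                    !is.na(ped$sire[match(ped$dam, ped$id)])]
  focal <- utils::tail(focal, 8)
  parent_sires <- stats::setNames(ped$sire[match(focal, ped$id)], focal)
  gs <- assign_grandsires(focal, as.list(parent_sires), ped, cl$census,
                          g0$observed, cl$freqs, error_rate = 0)
  mat <- gs[gs$branch == "maternal" & !is.na(gs$grandsire), ]
  truth <- ped$sire[match(mat$parent, ped$id)]
  expect_true(all(mat$grandsire == truth))
  expect_gt(nrow(mat), 0)
  # assigned grandsires never exceed assigned parents
  expect_lte(sum(!is.na(gs$grandsire)), 2 * length(focal))
  # ungenotyped dam: branch skipped with a reason
  g_miss <- g0$observed
  dam1 <- ped$dam[match(focal[1], ped$id)]
  g_miss[dam1, ] <- NA_integer_
  gs2 <- assign_grandsires(focal[1], as.list(parent_sires[1]), ped,
                           cl$census, g_miss, cl$freqs, error_rate = 0)
  expect_equal(gs2$skipped_reason[gs2$branch == "maternal"],
               "parent ungenotyped")
})

test_that("with no typing error the true sire is never excluded", {
  for (seed in c(61, 62)) {
    sc <- small_colony(seed, typing_error_rate = 0)
    cfg0 <- sim_config(n_founders = 16L, n_years = 5L, births_per_year = 5L,
                       male_skew = 1, typing_error_rate = 0,
                       mean_typed_loci = 21, seed = seed)
    g0 <- simulate_genotypes(sc$pedigree, cfg0)
    kids <- sc$pedigree$id[!is.na(sc$pedigree$sire)]
    for (oid in utils::tail(kids, 25)) {
      sire <- sc$pedigree$sire[match(oid, sc$pedigree$id)]
      mom <- sc$pedigree$dam[match(oid, sc$pedigree$id)]
      prof <- exclusion_profiles(oid, sire, g0$observed, mom)
      expect_equal(prof$n_mismatches, 0L)
    }
  }
})
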