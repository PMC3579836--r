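# Shared fixtures, built in code and cached for the whole test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

# Five-individual-plus-founders pedigree in which X's and Y's fathers are
# paternal half brothers (one shared grandparent G); r(X, Y) = 1/16.
ped_half_first_cousins <- function() {
  as_pedigree(data.frame(
    id = c("G", "M1", "M2", "F1", "F2", "D1", "D2", "X", "Y"),
    sex = c("M", "F", "F", "M", "M", "F", "F", "M", "F"),
    birth_date = as.Date("2000-01-01") +
      c(0, 0, 0, 3650, 3650, 3650, 3650, 7300, 7300),
    dam = c(NA, NA, NA, "M1", "M2", NA, NA, "D1", "D2"),
    sire = c(NA, NA, NA, "G", "G", NA, NA, "F1", "F2"),
    stringsAsFactors = FALSE))
}

# two unrelated parents, two full-sib offspring
ped_nuclear <- function() {
  as_pedigree(data.frame(
    id = c("mom", "dad", "kid1", "kid2"),
    sex = c("F", "M", "F", "M"),
    birth_date = as.Date("2000-01-01") + c(0, 0, 3000, 3400),
    dam = c(NA, NA, "mom", "mom"),
    sire = c(NA, NA, "dad", "dad"),
    stringsAsFactors = FALSE))
}

# small random colony for property tests (fast to build)
small_colony <- function(seed, ...) {
  cfg <- sim_config(n_founders = 32L, n_years = 5L, births_per_year = 4L,
                    male_skew = 1, seed = seed, ...)
  c(list(config = cfg), simulate_pedigree(cfg))
}

# the full-size reference colony shared across test files
colony <- function() {
  cached("colony", function() {
    cfg <- sim_config(seed = 7)
    sim <- simulate_pedigree(cfg)
    geno <- simulate_genotypes(sim$pedigree, cfg)
    freqs <- lapply(geno$loci, function(l) {
      allele_frequencies(geno$observed[, paste0(l, c(".1", ".2"))])
    })
    names(freqs) <- geno$loci
    inv <- simulate_inventory(sim$pedigree, sim$census,
                              photo_date = "2017-06-01", seed = 2)
    list(config = cfg, pedigree = sim$pedigree, census = sim$census,
         geno = geno, freqs = freqs, inventory = inv)
  })
}

# the reference stimulus design built on the colony
design <- function() {
  cached("design", function() {
    cl <- colony()
    kd <- build_kd_triads(cl$pedigree, cl$inventory, seed = 3)
    used <- unique(c(kd$target_id, kd$match_id, kd$decoy_id))
    id <- build_id_triads(cl$pedigree, cl$inventory, exclude = used, seed = 3)
    list(kd = kd, id = id)
  })
}

# a rated experiment: 59 participants, one unique schedule each
rated_experiment <- function() {
  cached("rated", function() {
    dn <- design()
    cfg <- response_sim_config(seed = 9)
    schedules <- lapply(seq_len(cfg$n_participants), function(i) {
      randomize_session(dn$kd, dn$id, sprintf("P%03d", i), seed = 100L + i)
    })
    list(config = cfg, schedules = schedules,
         responses = simulate_responses(schedules, dn$kd, dn$id, cfg))
  })
}

# build a genotype matrix at a single locus from a vector of "a/b" strings
one_locus_gt <- function(pairs, locus = "L01") {
  m <- do.call(rbind, lapply(strsplit(pairs, "/"), as.integer))
  colnames(m) <- paste0(locus, c(".1", ".2"))
  rownames(m) <- sprintf("i%02d", seq_len(nrow(m)))
  m
}
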