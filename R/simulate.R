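#' Configuration for the colony simulator
#'
#' Defaults emulate a free-ranging rhesus colony of roughly 850 individuals
#' and its STR genotype database: a multi-generation pedigree with polygynous
#' reproductive skew and inbreeding avoidance, ~21 STR loci with ~7 alleles
#' each, and per-individual missingness averaging ~14.6 typed loci.
#'
#' @param n_founders founder individuals (half of each sex).
#' @param n_years breeding years simulated after the founders.
#' @param births_per_year infants born each year.
#' @param male_skew Dirichlet concentration for per-male paternity weights
#'   within a year; values below 1 concentrate paternity on few males.
#' @param reproductive_age_male minimum male age (years) at conception. The
#'   source population's threshold is not published; 6 years is a realistic
#'   age at first siring for free-ranging rhesus males.
#' @param reproductive_age_female minimum female age (years) at an infant's
#'   birth; rhesus females are sexually mature at 4.
#' @param inbreeding_avoidance_r proposed matings with pedigree relatedness
#'   at or above this value are rejected and the sire redrawn.
#' @param n_loci number of STR loci.
#' @param alleles_per_locus alleles segregating at each locus.
#' @param allele_freq_concentration Dirichlet concentration for founder
#'   allele frequencies (1 = uniform over the simplex).
#' @param typing_error_rate probability that a recorded allele is replaced by
#'   a uniformly random different allele.
#' @param mean_typed_loci expected number of typed loci per individual.
#' @param seed integer seed; each stage reseeds deterministically from it
#'   (the pedigree stage at `seed`, the genotype stage at `seed + 1`), so
#'   identical configs give identical outputs regardless of call order.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_founders = 160L, n_years = 17L, births_per_year = 40L,
                       male_skew = 0.5, reproductive_age_male = 6,
                       reproductive_age_female = 4,
                       inbreeding_avoidance_r = 0.25,
                       n_loci = 21L, alleles_per_locus = 7L,
                       allele_freq_concentration = 1,
                       typing_error_rate = 0.01, mean_typed_loci = 14.6,
                       seed = 1L) {
  cfg <- list(n_founders = as.integer(n_founders),
              n_years = as.integer(n_years),
              births_per_year = as.integer(births_per_year),
              male_skew = male_skew,
              reproductive_age_male = reproductive_age_male,
              reproductive_age_female = reproductive_age_female,
              inbreeding_avoidance_r = inbreeding_avoidance_r,
              n_loci = as.integer(n_loci),
              alleles_per_locus = as.integer(alleles_per_locus),
              allele_freq_concentration = allele_freq_concentration,
              typing_error_rate = typing_error_rate,
              mean_typed_loci = mean_typed_loci,
              seed = as.integer(seed))
  stopifnot(cfg$n_founders > 0, cfg$n_years >= 0, cfg$births_per_year > 0,
            cfg$male_skew > 0, cfg$reproductive_age_male > 0,
            cfg$reproductive_age_female > 0,
            cfg$inbreeding_avoidance_r >= 0, cfg$inbreeding_avoidance_r <= 1.01,
            cfg$n_loci > 0, cfg$alleles_per_locus > 1,
            cfg$allele_freq_concentration > 0,
            cfg$typing_error_rate >= 0, cfg$typing_error_rate <= 1,
            cfg$mean_typed_loci > 0, cfg$mean_typed_loci <= cfg$n_loci)
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a multi-generation colony pedigree and census
#'
#' Founders are seeded with staggered birth years; each subsequent year
#' produces `births_per_year` infants. Dams are drawn uniformly from females
#' of reproductive age alive at the birth (at most one infant per dam per
#' year); sires are drawn from males of reproductive age present at
#' conception (200 days before birth) with per-year Dirichlet-weighted
#' paternity, producing reproductive skew. Proposed matings with pedigree
#' relatedness >= `inbreeding_avoidance_r` are rejected and the sire redrawn
#' from the remaining eligible males.
#'
#' @param config a [sim_config()].
#' @return List with `pedigree` (id, sex, birth_date, dam, sire; topologically
#'   ordered) and `census` (id, start, end presence intervals).
#' @export
simulate_pedigree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  nf <- config$n_founders
  n_total <- nf + config$n_years * config$births_per_year
  year0 <- 2000L  # arbitrary calendar anchor

  id <- character(n_total)
  sex <- character(n_total)
  bdate <- rep(as.Date(NA), n_total)
  dam_i <- rep(NA_integer_, n_total)
  sire_i <- rep(NA_integer_, n_total)
  death <- rep(as.Date(NA), n_total)
  draw_lifespan <- function(n) pmin(28, 4 + stats::rgamma(n, shape = 7, scale = 2.5))

  founder_years <- year0 - sample(
    seq.int(ceiling(config$reproductive_age_male) + 1L, 22L),
    nf, replace = TRUE)
  id[1:nf] <- sprintf("F%03d", seq_len(nf))
  sex[1:nf] <- rep(c("F", "M"), length.out = nf)
  bdate[1:nf] <- as.Date(sprintf("%d-01-01", founder_years)) +
    sample.int(365L, nf, replace = TRUE) - 1L
  death[1:nf] <- bdate[1:nf] + round(draw_lifespan(nf) * 365.25)

  # recursive kinship on the parent-index arrays (indices are topological:
  # parents always precede children)
  kin2 <- function(i, j) {
    memo <- new.env(parent = emptyenv())
    f <- function(a, b) {
      if (is.na(a) || is.na(b)) return(0)
      key <- if (a <= b) paste0(a, ":", b) else paste0(b, ":", a)
      hit <- memo[[key]]
      if (!is.null(hit)) return(hit)
      val <- if (a == b) {
        (1 + f(dam_i[a], sire_i[a])) / 2
      } else {
        lt <- max(a, b); ot <- min(a, b)
        (f(dam_i[lt], ot) + f(sire_i[lt], ot)) / 2
      }
      memo[[key]] <- val
      val
    }
    2 * f(i, j)  # relatedness
  }

  row <- nf
  for (y in seq_len(config$n_years)) {
    year <- year0 + y
    dams_used <- integer(0)
    # Dirichlet paternity weights, one draw per male per year: the same
    # males are favoured across a season's conceptions, producing
    # reproductive skew beyond multinomial sampling noise
    w_year <- stats::rgamma(n_total, shape = config$male_skew)
    w_year[w_year <= 0] <- .Machine$double.xmin
    for (b in seq_len(config$births_per_year)) {
      doy <- sample.int(365L, 1L)
      birth <- as.Date(sprintf("%d-01-01", year)) + doy - 1L
      conception <- birth - 200L
      cur <- seq_len(row)
      age_birth <- as.numeric(birth - bdate[cur]) / 365.25
      age_conc <- as.numeric(conception - bdate[cur]) / 365.25
      f_rows <- cur[sex[cur] == "F" &
                      age_birth >= config$reproductive_age_female &
                      death[cur] >= birth & !(cur %in% dams_used)]
      if (!length(f_rows)) {
        stop("infeasible config: no eligible dams in year ", year)
      }
      m_rows <- cur[sex[cur] == "M" &
                      age_conc >= config$reproductive_age_male &
                      death[cur] >= conception]
      if (!length(m_rows)) {
        stop("infeasible config: no eligible sires in year ", year)
      }
      dam_row <- if (length(f_rows) == 1L) f_rows else sample(f_rows, 1L)
      dams_used <- c(dams_used, dam_row)
      w <- w_year[m_rows]
      sire_row <- NA_integer_
      repeat {
        if (all(w == 0)) {
          stop("infeasible config: no sire below the inbreeding-avoidance ",
               "threshold in year ", year)
        }
        pick <- if (length(m_rows) == 1L) 1L else
          sample.int(length(m_rows), 1L, prob = w)
        cand <- m_rows[pick]
        if (kin2(dam_row, cand) < config$inbreeding_avoidance_r) {
          sire_row <- cand
          break
        }
        w[pick] <- 0
      }
      row <- row + 1L
      id[row] <- sprintf("K%04d", row - nf)
      sex[row] <- sample(c("F", "M"), 1L)
      bdate[row] <- birth
      dam_i[row] <- dam_row
      sire_i[row] <- sire_row
      death[row] <- birth + round(draw_lifespan(1L) * 365.25)
    }
  }
  ped <- data.frame(id = id, sex = sex, birth_date = bdate,
                    dam = ifelse(is.na(dam_i), NA_character_, id[dam_i]),
                    sire = ifelse(is.na(sire_i), NA_character_, id[sire_i]),
                    stringsAsFactors = FALSE)
  attr(ped, "indexed") <- TRUE
  study_end <- as.Date(sprintf("%d-12-31", year0 + config$n_years))
  census <- data.frame(id = ped$id, start = ped$birth_date,
                       end = pmin(death, study_end),
                       stringsAsFactors = FALSE)
  list(pedigree = ped, census = census)
}

#' Simulate true and observed STR genotype tables
#'
#' Founder alleles are drawn from per-locus Dirichlet frequencies;
#' non-founders inherit one allele per parent uniformly at random. The
#' observed table applies (i) per-allele typing error — each recorded allele
#' independently replaced by a uniformly random *different* allele with
#' probability `typing_error_rate` — and (ii) missingness: each individual is
#' typed at a random subset of loci with expected size `mean_typed_loci`.
#'
#' @param pedigree pedigree from [simulate_pedigree()].
#' @param config the same [sim_config()].
#' @return List with integer matrices `true` and `observed`
#'   (rows = individuals, two columns per locus, `NA` = untyped),
#'   `allele_freqs` (generating frequencies, list per locus), and `loci`.
#' @export
simulate_genotypes <- function(pedigree, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)  # deterministic substream, independent of when
                              # the pedigree stage consumed its draws
  px <- ped_index(pedigree)
  n <- px$n; L <- config$n_loci; k <- config$alleles_per_locus
  loci <- sprintf("L%02d", seq_len(L))
  freqs <- lapply(seq_len(L), function(l) {
    g <- stats::rgamma(k, shape = config$allele_freq_concentration)
    stats::setNames(g / sum(g), seq_len(k))
  })
  names(freqs) <- loci
  true <- matrix(NA_integer_, n, 2L * L,
                 dimnames = list(px$ped$id,
                                 paste0(rep(loci, each = 2), c(".1", ".2"))))
  for (i in seq_len(n)) {
    d <- px$dam[i]; s <- px$sire[i]
    a1 <- if (is.na(d)) {
      vapply(freqs, function(p) sample.int(k, 1L, prob = p), 0L)
    } else {
      pick <- sample.int(2L, L, replace = TRUE)
      true[d, 2L * seq_len(L) - 2L + pick]
    }
    a2 <- if (is.na(s)) {
      vapply(freqs, function(p) sample.int(k, 1L, prob = p), 0L)
    } else {
      pick <- sample.int(2L, L, replace = TRUE)
      true[s, 2L * seq_len(L) - 2L + pick]
    }
    true[i, seq(1L, 2L * L, by = 2L)] <- a1
    true[i, seq(2L, 2L * L, by = 2L)] <- a2
  }
  observed <- true
  if (config$typing_error_rate > 0 && k > 1L) {
    err <- matrix(stats::runif(length(observed)) < config$typing_error_rate,
                  nrow = n)
    shift <- matrix(sample.int(k - 1L, length(observed), replace = TRUE),
                    nrow = n)
    repl <- (observed + shift - 1L) %% k + 1L  # uniform over the other alleles
    observed[err] <- repl[err]
  }
  # Missingness structure: databases are typed on a core panel present in
  # nearly every individual plus supplementary loci typed sporadically, and
  # a minority of animals are sparsely sampled overall. Per-locus typing
  # rates are scaled so the expected typed-locus count matches
  # mean_typed_loci.
  n_core <- min(L, 12L)
  q <- ifelse(stats::runif(n) < 0.15, 0.5, 1)   # per-individual quality
  target <- config$mean_typed_loci / 0.925      # E[q] = 0.925
  p_loc <- rep(0.98, L)
  if (L > n_core) {
    rest <- (target - 0.98 * n_core) / (L - n_core)
    p_loc[(n_core + 1L):L] <- min(max(rest, 0.02), 0.98)
  }
  for (i in seq_len(n)) {
    typed <- stats::runif(L) < p_loc * q[i]
    observed[i, rep(!typed, each = 2L)] <- NA_integer_
  }
  list(true = true, observed = observed, allele_freqs = freqs, loci = loci)
}

#' Simulate a photo inventory for the colony
#'
#' Stand-in for the image archive: individuals alive at `photo_date` receive
#' a frontal image and, independently, three-quarter views facing left and
#' right, each tagged with a lighting class.
#'
#' @param pedigree,census from [simulate_pedigree()].
#' @param photo_date date the photographs were taken.
#' @param p_frontal,p_three_quarter per-orientation availability.
#' @param seed integer seed.
#' @return data.frame: image_id, individual_id, orientation
#'   (frontal / three_quarter_left / three_quarter_right), lighting_class,
#'   photo_date.
#' @export
simulate_inventory <- function(pedigree, census, photo_date,
                               p_frontal = 0.95, p_three_quarter = 0.75,
                               seed = 1L) {
  set.seed(seed)
  photo_date <- as.Date(photo_date)
  present <- census$id[census$start <= photo_date & census$end >= photo_date]
  rows <- list()
  for (id in present) {
    light <- sample(c("open_shade", "sun"), 1L, prob = c(0.8, 0.2))
    if (stats::runif(1) < p_frontal) {
      rows[[length(rows) + 1L]] <- data.frame(
        image_id = paste0("img_", id, "_f"), individual_id = id,
        orientation = "frontal", lighting_class = light,
        photo_date = photo_date, stringsAsFactors = FALSE)
    }
    for (side in c("left", "right")) {
      if (stats::runif(1) < p_three_quarter) {
        rows[[length(rows) + 1L]] <- data.frame(
          image_id = paste0("img_", id, "_", substr(side, 1, 1)),
          individual_id = id,
          orientation = paste0("three_quarter_", side),
          lighting_class = light, photo_date = photo_date,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Genotype table I/O
#'
#' Tab-separated: `id` then two columns per locus; missing alleles are blank.
#' `write_genepop()` additionally emits the conventional GenePop layout with
#' two-digit allele codes.
#'
#' @param gt integer genotype matrix (rows = ids, two columns per locus).
#' @param path output path.
#' @name genotype_io
NULL

#' @rdname genotype_io
#' @export
write_genotypes <- function(gt, path) {
  df <- data.frame(id = rownames(gt), gt, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
}

#' @rdname genotype_io
#' @export
read_genotypes <- function(path) {
  df <- utils::read.delim(path, na.strings = "", check.names = FALSE)
  gt <- as.matrix(df[, -1, drop = FALSE])
  mode(gt) <- "integer"
  rownames(gt) <- df$id
  gt
}

#' @rdname genotype_io
#' @param title header line for the GenePop file.
#' @export
write_genepop <- function(gt, path, title = "simulated STR genotypes") {
  loci <- unique(sub("\\.[12]$", "", colnames(gt)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(title, con)
  writeLines(loci, con)
  writeLines("Pop", con)
  for (i in seq_len(nrow(gt))) {
    g <- vapply(loci, function(l) {
      a <- gt[i, paste0(l, c(".1", ".2"))]
      if (anyNA(a)) "0000" else sprintf("%02d%02d", a[1], a[2])
    }, "")
    writeLines(paste0(rownames(gt)[i], " ,  ", paste(g, collapse = " ")), con)
  }
  invisible(path)
}
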