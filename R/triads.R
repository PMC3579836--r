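# Constraint-satisfying stimulus triads (kin discrimination and individual
# discrimination) and restricted-randomized per-participant sessions.

age_at_years <- function(ids, pedigree, when) {
  floor(as.numeric(as.Date(when) - pedigree$birth_date[match(ids, pedigree$id)]) /
          365.25)
}

#' Build kin-discrimination triads
#'
#' Each KD triad shows a parent (target), its offspring (match, r >= 0.5 by
#' pedigree) and an unrelated decoy of the same sex as the offspring within
#' two whole years of age, two-generation-unrelated to both target and match
#' and with an image of the same lighting class as the match. Four
#' conditions (mother-daughter, mother-son, father-daughter, father-son) get
#' `n_per_condition` triads each. All individuals are sexually mature
#' (>= `min_age` at photo date) and each appears once in the whole design,
#' except `shared_targets` sires that are re-used exactly once, as targets,
#' across the two father conditions (so with the defaults 32 triads hold
#' 96 image slots but only 91 distinct animals). Decoy ties are broken by
#' smallest age gap then lexicographic id.
#'
#' @param pedigree pedigree data.frame.
#' @param inventory image inventory (image_id, individual_id, orientation,
#'   lighting_class, photo_date).
#' @param n_per_condition triads per condition (8 in the reference design).
#' @param shared_targets number of sires used as targets in both a
#'   father-daughter and a father-son triad (5 in the reference design).
#' @param max_age_gap decoy-match age difference bound in whole years.
#' @param min_age minimum age in whole years at photo date.
#' @param seed integer seed (candidate orderings are shuffled per attempt).
#' @param max_attempts restarts before declaring the inventory infeasible.
#' @return data.frame of 4 x `n_per_condition` triads: triad_id, kind,
#'   condition, target/match/decoy ids and image ids, lighting_class.
#' @export
build_kd_triads <- function(pedigree, inventory, n_per_condition = 8L,
                            shared_targets = 5L, max_age_gap = 2,
                            min_age = 4, seed = 1L, max_attempts = 25L) {
  stopifnot(shared_targets <= n_per_condition)
  photo_date <- as.Date(inventory$photo_date[1])
  frontal <- inventory[inventory$orientation == "frontal", ]
  frontal <- frontal[!duplicated(frontal$individual_id), ]
  pool <- pedigree[pedigree$id %in% frontal$individual_id, ]
  pool$age <- age_at_years(pool$id, pedigree, photo_date)
  pool <- pool[!is.na(pool$age) & pool$age >= min_age, ]
  img_of <- stats::setNames(frontal$image_id, frontal$individual_id)
  light_of <- stats::setNames(frontal$lighting_class, frontal$individual_id)

  conditions <- c("mother-daughter", "mother-son",
                  "father-daughter", "father-son")
  par_sex <- c("F", "F", "M", "M")
  off_sex <- c("F", "M", "F", "M")
  names(par_sex) <- names(off_sex) <- conditions

  # eligible parent-offspring dyads per condition
  dyads <- lapply(conditions, function(cond) {
    off <- pool[pool$sex == off_sex[cond], ]
    keep <- !is.na(if (par_sex[cond] == "F") off$dam else off$sire)
    off <- off[keep, ]
    parent <- if (par_sex[cond] == "F") off$dam else off$sire
    ok <- parent %in% pool$id
    data.frame(parent = parent[ok], offspring = off$id[ok],
               stringsAsFactors = FALSE)
  })
  names(dyads) <- conditions

  anc <- lapply(pool$id, ancestors_two_generations, ped = pedigree)
  names(anc) <- pool$id
  two_gen_unrelated_fast <- function(a, b) {
    !length(intersect(anc[[a]], anc[[b]]))
  }

  pick_decoy <- function(target, match, used) {
    m_age <- pool$age[match(match, pool$id)]
    m_sex <- pool$sex[match(match, pool$id)]
    cand <- pool[pool$sex == m_sex & !(pool$id %in% used) &
                   abs(pool$age - m_age) <= max_age_gap &
                   light_of[pool$id] == light_of[[match]], ]
    cand <- cand[vapply(cand$id, function(d) {
      two_gen_unrelated_fast(d, target) && two_gen_unrelated_fast(d, match)
    }, logical(1)), ]
    if (!nrow(cand)) return(NA_character_)
    cand <- cand[order(abs(cand$age - m_age), cand$id), ]
    cand$id[1]
  }

  for (attempt in seq_len(max_attempts)) {
    set.seed(seed + attempt - 1L)
    used <- character(0)       # individuals consumed (once each)
    triads <- list()
    failed_condition <- NULL

    # sires re-used as targets across the two father conditions
    fd <- dyads[["father-daughter"]]; fs <- dyads[["father-son"]]
    shared_pool <- intersect(fd$parent, fs$parent)
    shared_pool <- shared_pool[sample.int(length(shared_pool))]
    plan <- list()
    shared_used <- character(0)
    for (f in shared_pool) {
      if (length(shared_used) >= shared_targets) break
      ds <- fd$offspring[fd$parent == f]
      ss <- fs$offspring[fs$parent == f]
      ds <- setdiff(ds, c(used, f)); ss <- setdiff(ss, c(used, f))
      if (!length(ds) || !length(ss)) next
      d <- ds[sample.int(length(ds), 1L)]
      s <- ss[sample.int(length(ss), 1L)]
      if (d == s) next
      shared_used <- c(shared_used, f)
      used <- c(used, f, d, s)
      plan[[length(plan) + 1L]] <- list(cond = "father-daughter",
                                        parent = f, off = d)
      plan[[length(plan) + 1L]] <- list(cond = "father-son",
                                        parent = f, off = s)
    }
    if (length(shared_used) < shared_targets) {
      failed_condition <- "father-daughter/father-son (shared targets)"
    } else {
      counts <- c("mother-daughter" = 0L, "mother-son" = 0L,
                  "father-daughter" = as.integer(shared_targets),
                  "father-son" = as.integer(shared_targets))
      for (cond in conditions) {
        dy <- dyads[[cond]]
        dy <- dy[sample.int(nrow(dy)), , drop = FALSE]
        for (i in seq_len(nrow(dy))) {
          if (counts[cond] >= n_per_condition) break
          p <- dy$parent[i]; o <- dy$offspring[i]
          if (p %in% used || o %in% used || p == o) next
          used <- c(used, p, o)
          counts[cond] <- counts[cond] + 1L
          plan[[length(plan) + 1L]] <- list(cond = cond, parent = p, off = o)
        }
        if (counts[cond] < n_per_condition) {
          failed_condition <- cond
          break
        }
      }
    }
    if (is.null(failed_condition)) {
      ok <- TRUE
      for (t in plan) {
        decoy <- pick_decoy(t$parent, t$off, used)
        if (is.na(decoy)) { ok <- FALSE; failed_condition <- t$cond; break }
        used <- c(used, decoy)
        triads[[length(triads) + 1L]] <- data.frame(
          kind = "KD", condition = t$cond,
          target_id = t$parent, match_id = t$off, decoy_id = decoy,
          target_img = img_of[[t$parent]], match_img = img_of[[t$off]],
          decoy_img = img_of[[decoy]], lighting_class = light_of[[t$off]],
          facing = NA_character_, stringsAsFactors = FALSE)
      }
      if (ok) {
        out <- do.call(rbind, triads)
        out <- out[order(match(out$condition, conditions)), ]
        out$triad_id <- sprintf("KD%02d", seq_len(nrow(out)))
        rownames(out) <- NULL
        return(out[, c("triad_id", setdiff(names(out), "triad_id"))])
      }
    }
  }
  stop("infeasible image inventory for KD design; could not fill condition: ",
       failed_condition)
}

#' Build individual-discrimination triads
#'
#' Each ID triad shows a frontal target, the same individual in
#' three-quarter view (match) and a different, unrelated individual of the
#' same sex within two years of age, in a three-quarter view facing the same
#' way and matched for lighting class. The set holds `n_per_sex` male and
#' `n_per_sex` female triads; within each sex half the three-quarter pairs
#' face left and half face right. All individuals are distinct (and disjoint
#' from `exclude`, typically the KD stimulus animals).
#'
#' @param pedigree pedigree data.frame.
#' @param inventory image inventory.
#' @param n_per_sex triads per sex (6 in the reference design; must be even).
#' @param max_age_gap,min_age as in [build_kd_triads()].
#' @param exclude individual ids that must not appear.
#' @param seed integer seed.
#' @param max_attempts restarts before failure.
#' @return data.frame of 2 x `n_per_sex` triads with a `facing` column.
#' @export
build_id_triads <- function(pedigree, inventory, n_per_sex = 6L,
                            max_age_gap = 2, min_age = 4,
                            exclude = character(0), seed = 1L,
                            max_attempts = 25L) {
  stopifnot(n_per_sex %% 2L == 0L)
  photo_date <- as.Date(inventory$photo_date[1])
  frontal <- inventory[inventory$orientation == "frontal", ]
  frontal <- frontal[!duplicated(frontal$individual_id), ]
  tq <- inventory[inventory$orientation %in%
                    c("three_quarter_left", "three_quarter_right"), ]
  pool <- pedigree[pedigree$id %in% frontal$individual_id &
                     !(pedigree$id %in% exclude), ]
  pool$age <- age_at_years(pool$id, pedigree, photo_date)
  pool <- pool[!is.na(pool$age) & pool$age >= min_age, ]
  img_of <- stats::setNames(frontal$image_id, frontal$individual_id)
  light_of <- stats::setNames(frontal$lighting_class, frontal$individual_id)
  tq_img <- function(id, facing) {
    hit <- tq$image_id[tq$individual_id == id &
                         tq$orientation == paste0("three_quarter_", facing)]
    if (length(hit)) hit[1] else NA_character_
  }
  anc <- lapply(pool$id, ancestors_two_generations, ped = pedigree)
  names(anc) <- pool$id

  for (attempt in seq_len(max_attempts)) {
    set.seed(seed + 1000L + attempt - 1L)
    used <- character(0)
    triads <- list()
    failed <- NULL
    for (sx in c("M", "F")) {
      facings <- rep(c("left", "right"), each = n_per_sex / 2L)
      cands <- pool[pool$sex == sx, ]
      cands <- cands[sample.int(nrow(cands)), ]
      for (fc in facings) {
        placed <- FALSE
        for (i in seq_len(nrow(cands))) {
          tgt <- cands$id[i]
          if (tgt %in% used || is.na(tq_img(tgt, fc))) next
          t_age <- cands$age[i]
          dec_pool <- pool[pool$sex == sx & !(pool$id %in% c(used, tgt)) &
                             abs(pool$age - t_age) <= max_age_gap &
                             light_of[pool$id] == light_of[[tgt]], ]
          dec_pool <- dec_pool[vapply(dec_pool$id, function(d) {
            !length(intersect(anc[[d]], anc[[tgt]])) &&
              !is.na(tq_img(d, fc))
          }, logical(1)), ]
          if (!nrow(dec_pool)) next
          dec_pool <- dec_pool[order(abs(dec_pool$age - t_age), dec_pool$id), ]
          dec <- dec_pool$id[1]
          used <- c(used, tgt, dec)
          triads[[length(triads) + 1L]] <- data.frame(
            kind = "ID",
            condition = paste0(ifelse(sx == "M", "male", "female"), "-", fc),
            target_id = tgt, match_id = tgt, decoy_id = dec,
            target_img = img_of[[tgt]], match_img = tq_img(tgt, fc),
            decoy_img = tq_img(dec, fc), lighting_class = light_of[[tgt]],
            facing = fc, stringsAsFactors = FALSE)
          placed <- TRUE
          break
        }
        if (!placed) {
          failed <- paste0(ifelse(sx == "M", "male", "female"), "-", fc)
          break
        }
      }
      if (!is.null(failed)) break
    }
    if (is.null(failed)) {
      out <- do.call(rbind, triads)
      out$triad_id <- sprintf("ID%02d", seq_len(nrow(out)))
      rownames(out) <- NULL
      return(out[, c("triad_id", setdiff(names(out), "triad_id"))])
    }
  }
  stop("infeasible image inventory for ID design; could not fill condition: ",
       failed)
}

#' Restricted-randomized session schedule
#'
#' Interleaves the 44 trials evenly: the session is split into four quarters
#' of 11 trials, each holding two triads of every KD condition and three ID
#' trials (ID conditions rotated across quarters so each appears three times
#' overall), with order shuffled within quarter. The side of the correct
#' match is counterbalanced exactly 22 left / 22 right. A break marker
#' follows trial 22 (the session's midpoint).
#'
#' @param kd_triads,id_triads outputs of the builders (32 and 12 rows).
#' @param participant participant id carried into the schedule.
#' @param seed per-participant seed (distinct seeds give distinct orders).
#' @return data.frame: participant, position, quarter, triad_id, kind,
#'   condition, side_correct, break_after.
#' @export
randomize_session <- function(kd_triads, id_triads, participant = "P01",
                              seed = 1L) {
  stopifnot(nrow(kd_triads) == 32L, nrow(id_triads) == 12L)
  set.seed(seed)
  kd_conditions <- unique(kd_triads$condition)
  stopifnot(length(kd_conditions) == 4L)
  id_conditions <- unique(id_triads$condition)
  stopifnot(length(id_conditions) == 4L)
  # per-condition queues in random order
  kd_q <- lapply(kd_conditions, function(cc) {
    x <- kd_triads$triad_id[kd_triads$condition == cc]
    x[sample.int(length(x))]
  })
  names(kd_q) <- kd_conditions
  id_q <- lapply(id_conditions, function(cc) {
    x <- id_triads$triad_id[id_triads$condition == cc]
    x[sample.int(length(x))]
  })
  names(id_q) <- id_conditions
  rot <- sample.int(4L, 1L)
  rows <- list()
  for (q in 1:4) {
    ids <- character(0)
    for (cc in kd_conditions) {
      ids <- c(ids, kd_q[[cc]][1:2])
      kd_q[[cc]] <- kd_q[[cc]][-(1:2)]
    }
    # quarter q draws ID conditions (q+rot, q+rot+1, q+rot+2) mod 4: each of
    # the four ID conditions appears in exactly three quarters = 3 trials
    take <- id_conditions[((q + rot + 0:2) %% 4L) + 1L]
    for (cc in take) {
      ids <- c(ids, id_q[[cc]][1])
      id_q[[cc]] <- id_q[[cc]][-1]
    }
    ids <- ids[sample.int(length(ids))]
    rows[[q]] <- data.frame(participant = participant,
                            position = NA_integer_, quarter = q,
                            triad_id = ids, stringsAsFactors = FALSE)
  }
  sched <- do.call(rbind, rows)
  sched$position <- seq_len(nrow(sched))
  all_triads <- rbind(kd_triads, id_triads)
  m <- match(sched$triad_id, all_triads$triad_id)
  sched$kind <- all_triads$kind[m]
  sched$condition <- all_triads$condition[m]
  side <- c(rep("left", 22L), rep("right", 22L))[sample.int(44L)]
  sched$side_correct <- side
  sched$break_after <- sched$position == 22L
  rownames(sched) <- NULL
  sched
}

#' Re-validate a stimulus design and its schedules
#'
#' Independent re-check of every triad and schedule invariant: KD triads are
#' parent-offspring (r >= 0.5) with sex-, age- and lighting-matched decoys
#' unrelated for two generations; ID triads re-use the target individual in
#' a matched three-quarter view with the required sex/facing balance; no
#' individual appears twice within a triad, no image serves as both match
#' and decoy anywhere, target re-use respects the shared-sire allowance;
#' schedules hold 32 KD + 12 ID trials with the quarter quotas and exact
#' side balance.
#'
#' @param kd_triads,id_triads design tables.
#' @param schedules one schedule data.frame or a list of them.
#' @param pedigree,inventory the tables the design was built from.
#' @param n_per_condition,shared_targets,max_age_gap,min_age design params.
#' @return Character vector of violations (length 0 when the design is valid).
#' @export
validate_design <- function(kd_triads, id_triads, schedules = NULL,
                            pedigree, inventory, n_per_condition = 8L,
                            shared_targets = 5L, max_age_gap = 2,
                            min_age = 4) {
  bad <- character(0)
  note <- function(...) bad <<- c(bad, paste0(...))
  photo_date <- as.Date(inventory$photo_date[1])
  K <- kinship_matrix(pedigree)

  if (nrow(kd_triads) != 4L * n_per_condition) {
    note("KD triad count is ", nrow(kd_triads))
  }
  tab <- table(kd_triads$condition)
  if (any(tab != n_per_condition)) note("unbalanced KD conditions")
  sex_of <- stats::setNames(pedigree$sex, pedigree$id)
  for (i in seq_len(nrow(kd_triads))) {
    tr <- kd_triads[i, ]
    trio <- c(tr$target_id, tr$match_id, tr$decoy_id)
    if (anyDuplicated(trio)) {
      note(tr$triad_id, ": repeated individual")
      next
    }
    if (2 * K[tr$target_id, tr$match_id] < 0.5 - 1e-12) {
      note(tr$triad_id, ": target-match r < 0.5")
    }
    if (sex_of[[tr$decoy_id]] != sex_of[[tr$match_id]]) {
      note(tr$triad_id, ": decoy sex differs from match")
    }
    ages <- age_at_years(trio, pedigree, photo_date)
    if (any(ages < min_age)) note(tr$triad_id, ": immature individual")
    if (abs(ages[2] - ages[3]) > max_age_gap) {
      note(tr$triad_id, ": decoy age gap > ", max_age_gap)
    }
    if (!unrelated_two_generations(tr$decoy_id, tr$target_id, pedigree) ||
        !unrelated_two_generations(tr$decoy_id, tr$match_id, pedigree)) {
      note(tr$triad_id, ": decoy related within two generations")
    }
    inv_m <- inventory[inventory$image_id == tr$match_img, ]
    inv_d <- inventory[inventory$image_id == tr$decoy_img, ]
    if (inv_m$lighting_class != inv_d$lighting_class) {
      note(tr$triad_id, ": lighting mismatch")
    }
  }
  # target re-use: at most twice, only across different conditions
  reuse <- table(kd_triads$target_id)
  if (any(reuse > 2L)) note("a KD target is used more than twice")
  if (sum(reuse == 2L) != shared_targets) {
    note("shared-target count is ", sum(reuse == 2L))
  }
  for (t in names(reuse)[reuse == 2L]) {
    conds <- kd_triads$condition[kd_triads$target_id == t]
    if (anyDuplicated(conds)) note("target ", t, " re-used within a condition")
  }
  non_targets <- c(kd_triads$match_id, kd_triads$decoy_id)
  if (anyDuplicated(non_targets) ||
      length(intersect(non_targets, kd_triads$target_id))) {
    note("a KD match/decoy individual appears more than once")
  }
  if (length(intersect(c(kd_triads$match_img, id_triads$match_img),
                       c(kd_triads$decoy_img, id_triads$decoy_img)))) {
    note("an image appears as both match and decoy")
  }

  if (nrow(id_triads) != 12L) note("ID triad count is ", nrow(id_triads))
  id_sex <- substr(id_triads$condition, 1, 1)
  if (sum(id_sex == "m") != 6L || sum(id_sex == "f") != 6L) {
    note("ID sex balance violated")
  }
  if (any(table(id_triads$condition) != 3L)) {
    note("ID facing balance violated")
  }
  for (i in seq_len(nrow(id_triads))) {
    tr <- id_triads[i, ]
    if (tr$target_id != tr$match_id) note(tr$triad_id, ": match is not the target individual")
    if (tr$decoy_id == tr$target_id) {
      note(tr$triad_id, ": decoy is the target")
      next
    }
    if (sex_of[[tr$decoy_id]] != sex_of[[tr$target_id]]) {
      note(tr$triad_id, ": decoy sex differs")
    }
    ages <- age_at_years(c(tr$target_id, tr$decoy_id), pedigree, photo_date)
    if (abs(ages[1] - ages[2]) > max_age_gap) note(tr$triad_id, ": age gap")
    if (!unrelated_two_generations(tr$decoy_id, tr$target_id, pedigree)) {
      note(tr$triad_id, ": decoy related")
    }
    want <- paste0("three_quarter_", tr$facing)
    for (im in c(tr$match_img, tr$decoy_img)) {
      o <- inventory$orientation[inventory$image_id == im]
      if (!identical(o, want)) note(tr$triad_id, ": wrong orientation ", im)
    }
  }
  if (anyDuplicated(c(id_triads$target_id, id_triads$decoy_id))) {
    note("an ID individual appears more than once")
  }

  if (!is.null(schedules)) {
    if (is.data.frame(schedules)) schedules <- list(schedules)
    for (s in schedules) {
      if (nrow(s) != 44L) note("schedule length != 44")
      if (sum(s$kind == "KD") != 32L || sum(s$kind == "ID") != 12L) {
        note("schedule KD/ID split violated")
      }
      if (any(table(s$condition[s$kind == "KD"]) != 8L)) {
        note("schedule KD condition counts violated")
      }
      if (sum(s$side_correct == "left") != 22L) {
        note("schedule side balance violated")
      }
      for (q in 1:4) {
        qs <- s[s$quarter == q, ]
        if (any(table(factor(qs$condition[qs$kind == "KD"],
                             levels = unique(s$condition[s$kind == "KD"]))) != 2L)) {
          note("quarter ", q, " KD quota violated")
        }
        if (sum(qs$kind == "ID") != 3L) note("quarter ", q, " ID quota violated")
      }
    }
  }
  bad
}
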