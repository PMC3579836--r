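# 20-replicate parameter-recovery experiment at 200 participants, shared by
# the mixed-model coverage checks and the end-to-end sign-recovery check.
# Each replicate simulates a fresh rater sample on the reference design,
# fits the full fixed specification (Wald 95% intervals) and runs the full
# reduction procedure.

recovery_experiment <- function() {
  cached("recovery", function() {
    dn <- design()
    true_beta <- c(
      "(Intercept)" = 0.17, "linepaternal" = 0.47, "triad_typesame" = 0.34,
      "experienceyes" = 0.33, "trial_position_z" = 0.25,
      "linepaternal:experienceyes" = -0.30,
      "trial_position_z:experienceyes" = -0.19)
    full_terms <- c("line", "triad_type", "experience", "trial_position_z",
                    "line:experience", "trial_position_z:experience")
    n_rep <- 20L
    covered <- signs_full <- matrix(NA, n_rep, length(true_beta),
                                    dimnames = list(NULL, names(true_beta)))
    signs_reduced <- matrix(NA, n_rep, length(true_beta),
                            dimnames = list(NULL, names(true_beta)))
    for (r in seq_len(n_rep)) {
      cfg <- response_sim_config(n_participants = 200L, seed = 9000L + r)
      sch <- lapply(seq_len(200L), function(i) {
        randomize_session(dn$kd, dn$id, sprintf("P%03d", i),
                          seed = 20000L + 300L * r + i)
      })
      resp <- simulate_responses(sch, dn$kd, dn$id, cfg)
      d <- prepare_model_frame(resp, "KD")
      full <- fit_lmm(d, full_terms)
      fe <- full$fixed_effects
      for (nm in names(true_beta)) {
        row <- fe[match_coef(fe$term, nm), ]
        covered[r, nm] <- row$lower <= true_beta[nm] &&
          true_beta[nm] <= row$upper
        signs_full[r, nm] <- sign(row$estimate) == sign(true_beta[nm])
      }
      red <- reduce_model(resp, "KD")
      for (nm in names(true_beta)) {
        est <- reduced_estimate(red, nm)
        signs_reduced[r, nm] <- !is.na(est) &&
          sign(est) == sign(true_beta[nm])
      }
    }
    list(covered = covered, signs_full = signs_full,
         signs_reduced = signs_reduced, true_beta = true_beta)
  })
}

# coefficient lookup tolerant of interaction component order
match_coef <- function(terms, nm) {
  split_nm <- sort(strsplit(nm, ":", fixed = TRUE)[[1]])
  which(vapply(terms, function(t) {
    identical(sort(strsplit(t, ":", fixed = TRUE)[[1]]), split_nm)
  }, logical(1)))[1]
}

# estimate of a generating coefficient after reduction: from the final model
# when the term survived, else from the last model that contained it (trace)
reduced_estimate <- function(red, nm) {
  fe <- red$final$fixed_effects
  hit <- match_coef(fe$term, nm)
  if (!is.na(hit)) return(fe$estimate[hit])
  coef_to_term <- c(
    "linepaternal" = "line", "triad_typesame" = "triad_type",
    "experienceyes" = "experience",
    "trial_position_z" = "trial_position_z",
    "linepaternal:experienceyes" = "line:experience",
    "trial_position_z:experienceyes" = "trial_position_z:experience")
  tl <- coef_to_term[[nm]]
  if (is.null(tl)) return(NA_real_)
  row <- which(vapply(red$trace$term, function(t) {
    setequal(strsplit(t, ":", fixed = TRUE)[[1]],
             strsplit(tl, ":", fixed = TRUE)[[1]])
  }, logical(1)))
  if (length(row)) red$trace$estimate[row[1]] else NA_real_
}
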