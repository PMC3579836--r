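# 8-point forced-choice scores and the statistical analysis chain:
# per-participant screens, descriptive tests, crossed-random-effects Gaussian
# mixed models (ML), likelihood-ratio model reduction, and per-group
# intercept estimation with parametric-bootstrap intervals.

SCORE_GRID <- seq(-3.5, 3.5, by = 1)

#' Encode / decode a forced-choice response
#'
#' The 8-point scale runs from -3.5 to +3.5 in steps of 1; the sign is
#' positive iff the chosen side is the correct match, and the magnitude step
#' (1..4, "slightly" to "much more similar") maps to 0.5..3.5.
#'
#' @param chosen_side,correct_side "left" or "right".
#' @param magnitude_step integer 1..4.
#' @return `encode_score()`: a score on the grid. `decode_score()`: list with
#'   `correct` (logical) and `magnitude_step`.
#' @export
encode_score <- function(chosen_side, magnitude_step, correct_side) {
  if (!all(magnitude_step %in% 1:4)) stop("magnitude_step must be in 1..4")
  sgn <- ifelse(chosen_side == correct_side, 1, -1)
  sgn * (magnitude_step - 0.5)
}

#' @rdname encode_score
#' @param score value on the 8-point grid.
#' @export
decode_score <- function(score) {
  if (!all(score %in% SCORE_GRID)) stop("score not on the 8-point grid")
  list(correct = score > 0, magnitude_step = abs(score) + 0.5)
}

# round a latent value to the grid: nearest point, clamped at the ends;
# exact midpoints (including 0) resolve toward the positive side
discretize_score <- function(x) pmin(3.5, pmax(-3.5, floor(x) + 0.5))

#' Configuration for the rater-response simulator
#'
#' Fixed-effect defaults mirror the structure of a kin-discrimination
#' analysis with experience-dependent line and learning effects; random
#' intercept scales are chosen so that per-participant mean scores have a
#' spread of ~0.3 on the 8-point scale.
#'
#' @param n_participants raters.
#' @param p_expert probability a rater has prior experience with nonhuman
#'   primates.
#' @param beta named list of fixed effects on the latent score scale:
#'   intercept, line (paternal), triad_type (same-sex), experience (yes),
#'   trial_position (per SD of position), line_x_experience,
#'   trial_position_x_experience, plus id_intercept for
#'   individual-discrimination trials.
#' @param sigma_participant,sigma_triad,sigma_target,sigma_left,sigma_right
#'   crossed random-intercept SDs.
#' @param sigma_resid residual SD.
#' @param seed integer seed.
#' @return List of class `response_sim_config`.
#' @export
response_sim_config <- function(n_participants = 59L, p_expert = 35 / 59,
                                beta = list(), sigma_participant = 0.3,
                                sigma_triad = 0.4, sigma_target = 0.2,
                                sigma_left = 0.2, sigma_right = 0.2,
                                sigma_resid = 1.5, seed = 1L) {
  b <- list(intercept = 0.17, line = 0.47, triad_type = 0.34,
            experience = 0.33, trial_position = 0.25,
            line_x_experience = -0.30, trial_position_x_experience = -0.19,
            id_intercept = 2.14)
  b[names(beta)] <- beta
  cfg <- list(n_participants = as.integer(n_participants),
              p_expert = p_expert, beta = b,
              sigma_participant = sigma_participant,
              sigma_triad = sigma_triad, sigma_target = sigma_target,
              sigma_left = sigma_left, sigma_right = sigma_right,
              sigma_resid = sigma_resid, seed = as.integer(seed))
  sig <- unlist(cfg[grep("^sigma_", names(cfg))])
  stopifnot(all(sig >= 0), cfg$n_participants > 0,
            p_expert >= 0, p_expert <= 1)
  class(cfg) <- "response_sim_config"
  cfg
}

kd_line <- function(condition) {
  ifelse(startsWith(condition, "father"), "paternal", "maternal")
}
kd_triad_type <- function(condition) {
  ifelse(condition %in% c("mother-daughter", "father-son"), "same", "mixed")
}

#' Simulate forced-choice similarity scores over session schedules
#'
#' The latent score is a linear predictor (fixed effects of kin line, triad
#' type, experience, z-transformed trial position and their configured
#' interactions; individual-discrimination trials get their own intercept)
#' plus five crossed random intercepts (participant, triad, target image,
#' left image, right image) and Gaussian residual noise, then discretized to
#' the nearest point of the 8-point grid, clamped at +/-3.5, with exact
#' midpoints (including a latent value of 0) resolved toward the positive
#' side.
#'
#' @param schedules list of per-participant schedules from
#'   [randomize_session()].
#' @param kd_triads,id_triads the triad tables the schedules reference.
#' @param config a [response_sim_config()].
#' @return data.frame with one row per trial: participant, trial_position,
#'   trial_position_z, triad_id, kind, condition, line, triad_type,
#'   triad_sex, side_correct, experience, participant_gender, image ids,
#'   latent and score.
#' @export
simulate_responses <- function(schedules, kd_triads, id_triads, config) {
  stopifnot(inherits(config, "response_sim_config"))
  if (is.data.frame(schedules)) schedules <- list(schedules)
  stopifnot(length(schedules) == config$n_participants)
  set.seed(config$seed)
  b <- config$beta
  triads <- rbind(kd_triads, id_triads)
  imgs <- unique(c(triads$target_img, triads$match_img, triads$decoy_img))
  u_triad <- stats::setNames(stats::rnorm(nrow(triads), 0, config$sigma_triad),
                             triads$triad_id)
  u_target <- stats::setNames(stats::rnorm(length(imgs), 0, config$sigma_target), imgs)
  u_left <- stats::setNames(stats::rnorm(length(imgs), 0, config$sigma_left), imgs)
  u_right <- stats::setNames(stats::rnorm(length(imgs), 0, config$sigma_right), imgs)
  n_p <- config$n_participants
  u_part <- stats::rnorm(n_p, 0, config$sigma_participant)
  expert <- stats::runif(n_p) < config$p_expert
  gender <- sample(c("female", "male"), n_p, replace = TRUE)

  out <- vector("list", n_p)
  for (i in seq_len(n_p)) {
    s <- schedules[[i]]
    m <- match(s$triad_id, triads$triad_id)
    tr <- triads[m, ]
    left_img <- ifelse(s$side_correct == "left", tr$match_img, tr$decoy_img)
    right_img <- ifelse(s$side_correct == "right", tr$match_img, tr$decoy_img)
    pos_z <- as.numeric(scale(s$position))
    is_kd <- s$kind == "KD"
    line <- ifelse(is_kd, kd_line(s$condition), NA)
    ttype <- ifelse(is_kd, kd_triad_type(s$condition), NA)
    tsex <- ifelse(is_kd, NA, ifelse(startsWith(s$condition, "male"),
                                     "male", "female"))
    ex <- as.numeric(expert[i])
    fixed <- ifelse(is_kd,
                    b$intercept +
                      b$line * (line == "paternal") +
                      b$triad_type * (ttype == "same") +
                      b$experience * ex +
                      b$trial_position * pos_z +
                      b$line_x_experience * (line == "paternal") * ex +
                      b$trial_position_x_experience * pos_z * ex,
                    b$id_intercept)
    latent <- fixed + u_part[i] + u_triad[s$triad_id] +
      u_target[tr$target_img] + u_left[left_img] + u_right[right_img] +
      stats::rnorm(nrow(s), 0, config$sigma_resid)
    out[[i]] <- data.frame(
      participant = sprintf("P%03d", i),
      trial_position = s$position, trial_position_z = pos_z,
      triad_id = s$triad_id, kind = s$kind, condition = s$condition,
      line = line, triad_type = ttype, triad_sex = tsex,
      side_correct = s$side_correct,
      experience = ifelse(expert[i], "yes", "no"),
      participant_gender = gender[i],
      target_img = tr$target_img, left_img = left_img,
      right_img = right_img,
      latent = latent, score = discretize_score(latent),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-participant individual-discrimination screen
#'
#' Two-tailed one-sample t-test of each participant's 12 ID scores against
#' zero (chance). Zero-variance participants are flagged with an undefined
#' p-value rather than tested.
#'
#' @param responses response table (only `kind == "ID"` rows are used).
#' @param alpha significance level.
#' @return List: `per_participant` (participant, n, mean, t, df, p,
#'   significant, zero_variance), `n_significant`, `fraction_significant`.
#' @export
participant_id_screen <- function(responses, alpha = 0.05) {
  idr <- responses[responses$kind == "ID", ]
  parts <- split(idr$score, idr$participant)
  rows <- lapply(names(parts), function(p) {
    x <- parts[[p]]
    if (stats::sd(x) == 0) {
      return(data.frame(participant = p, n = length(x), mean = mean(x),
                        t = NA_real_, df = length(x) - 1L, p = NA_real_,
                        significant = NA, zero_variance = TRUE,
                        stringsAsFactors = FALSE))
    }
    tt <- stats::t.test(x, mu = 0)
    data.frame(participant = p, n = length(x), mean = mean(x),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, significant = tt$p.value < alpha,
               zero_variance = FALSE, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  list(per_participant = tab,
       n_significant = sum(tab$significant, na.rm = TRUE),
       fraction_significant = mean(tab$significant, na.rm = TRUE))
}

#' Model frame with treatment coding for one task
#'
#' Subsets a response table to one task and applies the reference levels
#' used throughout the analysis (maternal, mixed-sex, no-experience, female
#' and left all coded 0), re-z-scoring trial position within the subset.
#'
#' @param responses response table.
#' @param kind "KD" or "ID".
#' @return data.frame ready for [fit_lmm()].
#' @export
prepare_model_frame <- function(responses, kind = c("KD", "ID")) {
  kind <- match.arg(kind)
  d <- responses[responses$kind == kind, , drop = FALSE]
  if (kind == "KD") {
    d$line <- factor(d$line, levels = c("maternal", "paternal"))
    d$triad_type <- factor(d$triad_type, levels = c("mixed", "same"))
  } else {
    d$triad_sex <- factor(d$triad_sex, levels = c("female", "male"))
  }
  d$experience <- factor(d$experience, levels = c("no", "yes"))
  d$participant_gender <- factor(d$participant_gender,
                                 levels = c("female", "male"))
  d$side_correct <- factor(d$side_correct, levels = c("left", "right"))
  d$trial_position_z <- as.numeric(scale(d$trial_position))
  d
}

#' Fit a Gaussian mixed model with crossed random intercepts
#'
#' Maximum-likelihood fit (via `lme4::lmer`, `REML = FALSE`) of
#' `score ~ fixed terms + crossed random intercepts`, optionally with a
#' per-participant random slope on z-transformed trial position, with or
#' without an intercept-slope correlation. 95% intervals for the fixed
#' effects are Wald by default; `ci = "boot"` replaces them with seeded
#' parametric-bootstrap percentile intervals and two-sided bootstrap
#' p-values.
#'
#' @param data model frame from [prepare_model_frame()] (or any data.frame
#'   with `score` and the referenced columns).
#' @param fixed character vector of fixed-effect term labels
#'   (e.g. `c("line", "experience", "line:experience")`); empty for an
#'   intercept-only model.
#' @param random character vector of random-intercept grouping factors.
#' @param random_slope add a per-participant random slope on
#'   `trial_position_z`.
#' @param slope_correlated allow the intercept-slope correlation.
#' @param ci "wald" or "boot".
#' @param nboot parametric-bootstrap draws (>= 1000 recommended).
#' @param seed seed for the bootstrap.
#' @return List of class `model_fit`: `fit`, `fixed_effects` (term,
#'   estimate, se, lower, upper, p), `variance_components`,
#'   `log_likelihood`, `df`, `n_obs`, `converged`, `formula`.
#' @export
fit_lmm <- function(data, fixed = character(0),
                    random = c("participant", "triad_id", "target_img",
                               "left_img", "right_img"),
                    random_slope = FALSE, slope_correlated = FALSE,
                    ci = c("wald", "boot"), nboot = 1000L, seed = 1L) {
  ci <- match.arg(ci)
  rterms <- paste0("(1 | ", random, ")")
  if (random_slope) {
    op <- if (slope_correlated) " | " else " || "
    rterms[random == "participant"] <-
      paste0("(1 + trial_position_z", op, "participant)")
  }
  rhs <- paste(c("1", fixed, rterms), collapse = " + ")
  form <- stats::as.formula(paste("score ~", rhs))
  fit <- lme4::lmer(form, data = data, REML = FALSE,
                    control = lme4::lmerControl(
                      check.conv.singular = "ignore",
                      calc.derivs = FALSE))
  est <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  z <- est / se
  fe <- data.frame(term = names(est), estimate = unname(est),
                   se = unname(se),
                   lower = unname(est - stats::qnorm(0.975) * se),
                   upper = unname(est + stats::qnorm(0.975) * se),
                   p = unname(2 * stats::pnorm(-abs(z))),
                   stringsAsFactors = FALSE)
  if (ci == "boot") {
    bs <- boot_fixef(fit, nboot = nboot, seed = seed)
    fe$lower <- apply(bs, 2, stats::quantile, 0.025, na.rm = TRUE)
    fe$upper <- apply(bs, 2, stats::quantile, 0.975, na.rm = TRUE)
    fe$p <- vapply(seq_along(est), function(j) {
      center <- stats::median(bs[, j], na.rm = TRUE)
      shifted <- bs[, j] - center  # null distribution centred at 0
      mean(abs(shifted) >= abs(est[j]), na.rm = TRUE)
    }, 0)
  }
  vc <- as.data.frame(lme4::VarCorr(fit))
  vnm <- vc$grp
  extra <- !is.na(vc$var1) & vc$var1 != "(Intercept)"
  vnm[extra] <- paste0(vc$grp[extra], ":", vc$var1[extra])
  cov_row <- !is.na(vc$var2)
  vnm[cov_row] <- paste0(vc$grp[cov_row], ":", vc$var1[cov_row], ":",
                         vc$var2[cov_row])
  vcomp <- stats::setNames(vc$vcov, vnm)
  msgs <- fit@optinfo$conv$lme4$messages
  out <- list(fit = fit, fixed_effects = fe, variance_components = vcomp,
              log_likelihood = as.numeric(stats::logLik(fit)),
              df = attr(stats::logLik(fit), "df"),
              n_obs = stats::nobs(fit),
              converged = is.null(msgs) ||
                !any(grepl("failed to converge", unlist(msgs))),
              formula = form)
  class(out) <- "model_fit"
  out
}

# seeded parametric bootstrap of the fixed effects: simulate from the fitted
# model, refit, collect fixef draws
boot_fixef <- function(fit, nboot = 1000L, seed = 1L) {
  sims <- stats::simulate(fit, nsim = nboot, seed = seed)
  k <- length(lme4::fixef(fit))
  out <- matrix(NA_real_, nboot, k,
                dimnames = list(NULL, names(lme4::fixef(fit))))
  for (i in seq_len(nboot)) {
    bfit <- tryCatch(suppressWarnings(suppressMessages(
      lme4::refit(fit, sims[[i]]))), error = function(e) NULL)
    if (!is.null(bfit)) out[i, ] <- lme4::fixef(bfit)
  }
  out
}

#' Likelihood-ratio test between nested ML fits
#'
#' chi-square = 2 (logLik full - logLik reduced), clamped at zero when the
#' reduced fit is numerically better; degrees of freedom = difference in
#' parameter count.
#'
#' @param full,reduced `model_fit` objects on the same data.
#' @return List of class `lrt_result`: chi_sq, df, p.
#' @export
lrt <- function(full, reduced) {
  stopifnot(inherits(full, "model_fit"), inherits(reduced, "model_fit"))
  if (full$n_obs != reduced$n_obs) {
    stop("models were fitted to different data")
  }
  df <- full$df - reduced$df
  chi <- max(0, 2 * (full$log_likelihood - reduced$log_likelihood))
  if (df < 1L) {
    # identical specifications are the only admissible zero-df comparison
    if (df == 0L && chi < 1e-8) {
      out <- list(chi_sq = 0, df = 0L, p = 1)
      class(out) <- "lrt_result"
      return(out)
    }
    stop("models are not nested (no parameter difference)")
  }
  out <- list(chi_sq = chi, df = df,
              p = stats::pchisq(chi, df, lower.tail = FALSE))
  class(out) <- "lrt_result"
  out
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("LRT: chi-sq = %.3f, df = %d, p = %.4g\n", x$chi_sq, x$df, x$p))
  invisible(x)
}

#' @export
print.model_fit <- function(x, ...) {
  cat("Gaussian mixed model (ML):",
      deparse(x$formula), "\n")
  print(x$fixed_effects, digits = 3)
  cat("logLik:", format(x$log_likelihood), " n:", x$n_obs,
      if (!x$converged) " (NOT converged)", "\n")
  invisible(x)
}
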