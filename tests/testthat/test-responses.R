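test_that("score encoding spans the scale and round-trips", {
  expect_equal(encode_score("left", 4, "left"), 3.5)
  expect_equal(encode_score("right", 4, "left"), -3.5)
  expect_equal(encode_score("left", 1, "left"), 0.5)
  expect_error(encode_score("left", 5, "left"), "1..4")
  for (s in seq(-3.5, 3.5, 1)) {
    d <- decode_score(s)
    chosen <- if (d$correct) "left" else "right"
    expect_equal(encode_score(chosen, d$magnitude_step, "left"), s)
  }
  expect_error(decode_score(0), "grid")
})

test_that("the ID screen handles degenerate and null participants", {
  mk <- function(p, scores) data.frame(participant = p, kind = "ID",
                                       score = scores,
                                       stringsAsFactors = FALSE)
  resp <- rbind(mk("const", rep(3.5, 12)),
                mk("null", rep(c(-0.5, 0.5), 6)),
                mk("good", rep(c(2.5, 3.5), 6)))
  scr <- participant_id_screen(resp)
  tab <- scr$per_participant
  expect_true(tab$zero_variance[tab$participant == "const"])
  expect_true(is.na(tab$p[tab$participant == "const"]))
  expect_false(tab$significant[tab$participant == "null"])
  expect_equal(tab$t[tab$participant == "null"], 0)
  expect_true(tab$significant[tab$participant == "good"])
  expect_equal(tab$df, rep(11, 3))
})

test_that("the mixed model collapses to OLS when random variances vanish", {
  set.seed(23)
  n <- 400
  d <- data.frame(
    participant = rep(sprintf("P%02d", 1:20), each = n / 20),
    x = rnorm(n), stringsAsFactors = FALSE)
  e <- rnorm(n, 0, 1)
  # centre the noise within every grouping level: the between-group variance
  # estimate sits exactly on the zero boundary and the fit degenerates to OLS
  e <- e - stats::ave(e, d$participant)
  d$score <- 0.4 + 0.8 * d$x + e
  f <- fit_lmm(d, fixed = "x", random = "participant")
  ols <- stats::lm(score ~ x, data = d)
  expect_equal(f$fixed_effects$estimate, unname(stats::coef(ols)),
               tolerance = 1e-6)
  expect_lt(f$variance_components[["participant"]], 1e-8)
})

test_that("variance components match the balanced one-way ML closed form", {
  set.seed(24)
  a <- 30; n <- 8
  grp <- factor(rep(seq_len(a), each = n))
  y <- rep(rnorm(a, 0, 0.8), each = n) + rnorm(a * n, 1.5, 1.2)
  d <- data.frame(score = y, participant = grp)
  f <- fit_lmm(d, random = "participant")
  SSW <- sum(tapply(y, grp, function(v) sum((v - mean(v))^2)))
  SSB <- n * sum((tapply(y, grp, mean) - mean(y))^2)
  MSW <- SSW / (a * (n - 1)); MSB <- SSB / (a - 1)
  expect_equal(unname(f$variance_components["participant"]),
               (((a - 1) / a) * MSB - MSW) / n, tolerance = 1e-5)
  expect_equal(unname(f$variance_components["Residual"]), MSW,
               tolerance = 1e-5)
  expect_equal(f$fixed_effects$estimate[1], mean(y), tolerance = 1e-8)
})

test_that("log-likelihood never decreases when a parameter is added", {
  re <- rated_experiment()
  d <- prepare_model_frame(re$responses, "KD")
  ladder <- list(character(0), "line", c("line", "experience"),
                 c("line", "experience", "line:experience"),
                 c("line", "experience", "line:experience",
                   "trial_position_z"))
  lls <- vapply(ladder, function(tm) fit_lmm(d, tm)$log_likelihood, 0)
  expect_true(all(diff(lls) >= -1e-6))
})

test_that("likelihood-ratio tests follow their definition and have power", {
  re <- rated_experiment()
  d <- prepare_model_frame(re$responses, "KD")
  f0 <- fit_lmm(d, character(0))
  f1 <- fit_lmm(d, c("experience", "trial_position_z",
                     "trial_position_z:experience"))
  same <- lrt(f1, f1)
  expect_equal(same$chi_sq, 0)
  expect_equal(same$p, 1)
  out <- lrt(f1, f0)
  expect_equal(out$chi_sq,
               max(0, 2 * (f1$log_likelihood - f0$log_likelihood)))
  expect_equal(out$df, 3L)
  expect_error(lrt(f0, f1), "not nested")
  # power: data carry a strong learning effect by construction
  expect_lt(out$p, 0.05)
})

test_that("bootstrap intervals bracket the Wald estimate sensibly", {
  re <- rated_experiment()
  d <- prepare_model_frame(re$responses, "ID")
  f <- fit_lmm(d, character(0), ci = "boot", nboot = 200, seed = 4)
  ic <- f$fixed_effects[1, ]
  expect_lt(ic$lower, ic$estimate)
  expect_gt(ic$upper, ic$estimate)
  expect_lt(ic$p, 0.05)  # ID performance is far above chance
})

test_that("model reduction strips a null dataset down to the intercept", {
  dn <- design()
  cfg <- response_sim_config(
    n_participants = 40L,
    beta = list(intercept = 0.8, line = 0, triad_type = 0, experience = 0,
                trial_position = 0, line_x_experience = 0,
                trial_position_x_experience = 0, id_intercept = 2),
    sigma_participant = 0.2, sigma_triad = 0.2, sigma_target = 0.1,
    sigma_left = 0.1, sigma_right = 0.1, sigma_resid = 1.4, seed = 55)
  sch <- lapply(seq_len(40), function(i) {
    randomize_session(dn$kd, dn$id, sprintf("P%03d", i), seed = 600 + i)
  })
  resp <- simulate_responses(sch, dn$kd, dn$id, cfg)
  red <- reduce_model(resp, "KD")
  # every null interaction and the null learning effect end up dropped
  inter <- grepl(":", red$trace$term)
  expect_true(all(red$trace$action[inter] == "dropped"))
  expect_false("trial_position_z" %in% red$retained_terms)
  # the interest main effects survive by construction of the procedure
  expect_true(all(c("line", "triad_type", "experience") %in%
                    red$retained_terms))
  expect_false(red$random_structure$random_slope)
  expect_named(red$groups, "all")
  ic <- red$groups$all$intercept
  expect_gt(ic$estimate, 0.4)
  expect_lt(ic$p, 0.05)
  # the trace is deterministic given data and seed
  red2 <- reduce_model(resp, "KD")
  expect_identical(red$trace, red2$trace)
})

test_that("reduction recovers an experience-dependent learning effect and
           reports per-group intercepts", {
  re <- rated_experiment()
  red <- reduce_model(re$responses, "KD")
  expect_true(any(grepl("trial_position_z:experience|experience:trial_position_z",
                        red$trace$term[grepl("retained", red$trace$action)])))
  expect_setequal(names(red$groups), c("expert", "inexperienced"))
  # inexperienced raters improve across the session; experts start higher
  # and stay flat (the generating interaction cancels their slope)
  gi <- red$groups$inexperienced
  expect_true("trial_position_z" %in% gi$terms)
  slope <- gi$fit$fixed_effects
  expect_gt(slope$estimate[slope$term == "trial_position_z"], 0)
  expect_false("trial_position_z" %in% red$groups$expert$terms)
  for (g in red$groups) expect_gt(g$intercept$estimate, 0)
})

test_that("the ID reduction mirrors the main analysis format", {
  re <- rated_experiment()
  red <- reduce_model(re$responses, "ID")
  expect_named(red$groups, "all")
  ic <- red$groups$all$intercept
  expect_gt(ic$estimate, 1.5)
  expect_lt(ic$p, 0.001)
})

test_that("descriptive battery matches textbook formulas on fixtures", {
  mk <- function(p, kind, scores, exp) {
    data.frame(participant = p, kind = kind, score = scores,
               experience = exp, stringsAsFactors = FALSE)
  }
  # KD means differ from ID means by +d, -d alternating: paired t is 0
  parts <- sprintf("P%02d", 1:10)
  resp <- do.call(rbind, c(
    lapply(seq_along(parts), function(i) {
      base <- i / 10
      exp_i <- c("yes", "no")[1 + i %% 2]
      rbind(mk(parts[i], "ID", rep(base, 4), exp_i),
            mk(parts[i], "KD", rep(base + c(0.3, -0.3)[1 + i %% 2], 4),
               exp_i))
    })))
  ss <- summary_stats(resp)
  expect_equal(ss$kd_vs_id$t, 0)
  # unpaired t against the hand-computed pooled-variance formula
  x <- ss$per_participant$score_kd[ss$per_participant$experience == "yes"]
  y <- ss$per_participant$score_kd[ss$per_participant$experience == "no"]
  sp2 <- ((length(x) - 1) * stats::var(x) + (length(y) - 1) * stats::var(y)) /
    (length(x) + length(y) - 2)
  t_hand <- (mean(x) - mean(y)) /
    sqrt(sp2 * (1 / length(x) + 1 / length(y)))
  expect_equal(ss$expert_vs_inexperienced$t, t_hand)
  expect_error(summary_stats(resp[resp$participant == "P01", ]),
               "3 participants")
})

test_that("the unpaired screen rejects at the nominal rate under permuted
           labels", {
  re <- rated_experiment()
  ss <- summary_stats(re$responses)
  kd_means <- ss$per_participant$score_kd
  set.seed(71)
  n_yes <- sum(ss$per_participant$experience == "yes")
  rej <- vapply(1:400, function(i) {
    lab <- sample(rep(c("yes", "no"),
                      c(n_yes, length(kd_means) - n_yes)))
    stats::t.test(kd_means[lab == "yes"], kd_means[lab == "no"],
                  var.equal = TRUE)$p.value < 0.05
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 0.035)
})
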