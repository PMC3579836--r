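# Staged likelihood-ratio model reduction mirroring the analysis chain:
# random-structure tests, overall full-vs-null test, backward deletion of
# interactions then control main effects (trend terms retained), and final
# per-group intercept estimation.

term_vars <- function(label) strsplit(label, ":", fixed = TRUE)[[1]]
term_contains <- function(big, small) {
  all(term_vars(small) %in% term_vars(big)) &&
    length(term_vars(big)) > length(term_vars(small))
}

# estimate (first coefficient) of `term` in a fitted model_fit
term_estimate <- function(mf, term) {
  X <- stats::model.matrix(mf$fit)
  labs <- attr(stats::terms(mf$fit), "term.labels")
  j <- which(vapply(labs, function(l) setequal(term_vars(l), term_vars(term)),
                    logical(1)))
  if (!length(j)) return(NA_real_)
  cols <- which(attr(X, "assign") == j)
  if (!length(cols)) return(NA_real_)
  mf$fixed_effects$estimate[cols[1]]
}

kd_term_spec <- function() {
  data.frame(
    label = c("line", "triad_type", "experience", "trial_position_z",
              "participant_gender", "side_correct",
              "line:triad_type", "line:experience", "triad_type:experience",
              "trial_position_z:experience",
              "line:triad_type:experience"),
    order = c(1, 1, 1, 1, 1, 1, 2, 2, 2, 2, 3),
    role = c("interest", "interest", "interest", "control",
             "control", "control",
             "interest", "interest", "interest", "control", "interest"),
    stringsAsFactors = FALSE)
}

id_term_spec <- function() {
  data.frame(
    label = c("triad_sex", "experience", "trial_position_z",
              "participant_gender", "side_correct",
              "triad_sex:experience", "trial_position_z:experience"),
    order = c(1, 1, 1, 1, 1, 2, 2),
    role = c("interest", "interest", "control", "control", "control",
             "interest", "control"),
    stringsAsFactors = FALSE)
}

#' Staged likelihood-ratio model reduction
#'
#' Implements the full analysis chain for one task:
#' \enumerate{
#' \item Random structure: the full fixed specification is fitted with a
#'   per-participant random slope on trial position plus intercept-slope
#'   correlation; the correlation term, then the slope, are tested by LRT
#'   and removed when nonsignificant.
#' \item Overall test: the full model against a null holding only the
#'   control terms (no predictors of interest, no experience).
#' \item Backward deletion, highest-order terms first: each droppable term
#'   is tested by a single-term LRT; terms with p below `trend_alpha` are
#'   retained (flagged "trend" when between `alpha` and `trend_alpha`),
#'   others dropped. First-order terms of primary interest are never
#'   dropped from the final model; control main effects are dropped when
#'   nonsignificant. Marginality is respected (a term contained in a
#'   retained higher-order term is not tested). Estimates in the trace come
#'   from the last model containing the term.
#' \item Intercept estimation: all nonsignificant fixed effects are
#'   excluded; when a factor (experience) is significant — as a main effect
#'   or inside a retained interaction — the intercept model is fitted
#'   separately per level, retaining within each group whichever remaining
#'   terms stay significant there. Intercepts carry parametric-bootstrap
#'   intervals and p-values when `nboot > 0`, Wald otherwise.
#' }
#'
#' @param responses response table (see [simulate_responses()]).
#' @param kind "KD" or "ID".
#' @param alpha significance level.
#' @param trend_alpha retention threshold for nonsignificant trends.
#' @param nboot parametric-bootstrap draws for the intercept intervals
#'   (0 = Wald).
#' @param seed bootstrap seed.
#' @return List of class `model_reduction`: `random_structure`, `overall`,
#'   `trace` (data.frame), `final` (model_fit), `groups` (named list with
#'   per-group fits and intercept rows).
#' @export
reduce_model <- function(responses, kind = c("KD", "ID"), alpha = 0.05,
                         trend_alpha = 0.10, nboot = 0L, seed = 1L) {
  kind <- match.arg(kind)
  d <- prepare_model_frame(responses, kind)
  spec <- if (kind == "KD") kd_term_spec() else id_term_spec()
  full_terms <- spec$label

  # -- random structure ------------------------------------------------
  fit_corr <- fit_lmm(d, full_terms, random_slope = TRUE,
                      slope_correlated = TRUE)
  fit_slope <- fit_lmm(d, full_terms, random_slope = TRUE,
                       slope_correlated = FALSE)
  fit_int <- fit_lmm(d, full_terms)
  lrt_corr <- lrt(fit_corr, fit_slope)
  use_corr <- lrt_corr$p < alpha
  lrt_slope <- lrt(fit_slope, fit_int)
  use_slope <- use_corr || lrt_slope$p < alpha
  rs <- list(correlation = lrt_corr, slope = lrt_slope,
             random_slope = use_slope, slope_correlated = use_corr)
  refit <- function(terms) fit_lmm(d, terms, random_slope = use_slope,
                                   slope_correlated = use_corr)
  # -- overall full vs null test ---------------------------------------
  full_fit <- if (use_corr) fit_corr else if (use_slope) fit_slope else fit_int
  null_terms <- spec$label[spec$role == "control" &
                             !grepl("experience", spec$label)]
  overall <- lrt(full_fit, refit(null_terms))

  # -- staged backward deletion ----------------------------------------
  current <- full_terms
  cur_fit <- full_fit
  trace <- list()
  status <- stats::setNames(rep("retained", length(full_terms)), full_terms)
  for (ord in sort(unique(spec$order), decreasing = TRUE)) {
    for (tl in spec$label[spec$order == ord]) {
      if (!(tl %in% current)) next
      blocked <- any(vapply(current, function(o) term_contains(o, tl),
                            logical(1)))
      if (blocked) next
      if (ord == 1 && spec$role[spec$label == tl] == "interest") next
      candidate <- setdiff(current, tl)
      red_fit <- refit(candidate)
      test <- lrt(cur_fit, red_fit)
      action <- if (test$p < alpha) "retained (significant)" else
        if (test$p < trend_alpha) "retained (trend)" else "dropped"
      trace[[length(trace) + 1L]] <- data.frame(
        term = tl, chi_sq = test$chi_sq, df = test$df, p = test$p,
        estimate = term_estimate(cur_fit, tl), action = action,
        stringsAsFactors = FALSE)
      if (action == "dropped") {
        current <- candidate
        cur_fit <- red_fit
        status[tl] <- "dropped"
      } else {
        status[tl] <- action
      }
    }
  }
  trace <- if (length(trace)) do.call(rbind, trace) else
    data.frame(term = character(0))
  final_fit <- cur_fit

  # -- intercept estimation ---------------------------------------------
  # significance of each retained term in the final model, by LRT where
  # testable; interest mains inherit their single-term deletion p
  sig_terms <- trace$term[grepl("significant", trace$action)]
  keep_sig <- function(terms, data, boot_seed) {
    # iteratively drop nonsignificant terms (marginality respected)
    cur <- terms
    f <- fit_lmm(data, cur, random_slope = FALSE)
    changed <- TRUE
    while (changed && length(cur)) {
      changed <- FALSE
      for (tl in rev(cur)) {
        if (any(vapply(cur, function(o) term_contains(o, tl), logical(1)))) next
        g <- fit_lmm(data, setdiff(cur, tl), random_slope = FALSE)
        if (lrt(f, g)$p >= alpha) {
          cur <- setdiff(cur, tl)
          f <- g
          changed <- TRUE
        }
      }
    }
    f <- fit_lmm(data, cur, random_slope = FALSE,
                 ci = if (nboot > 0) "boot" else "wald", nboot = nboot,
                 seed = boot_seed)
    list(terms = cur, fit = f,
         intercept = f$fixed_effects[f$fixed_effects$term == "(Intercept)", ])
  }
  exp_significant <- any(grepl("experience", sig_terms))
  groups <- if (kind == "KD" && exp_significant) {
    # separate fits per experience level; candidate terms are the retained
    # ones with experience stripped out
    cand <- unique(unlist(lapply(current, function(tl) {
      v <- setdiff(term_vars(tl), "experience")
      if (length(v)) paste(v, collapse = ":") else NULL
    })))
    lv <- levels(d$experience)
    out <- lapply(seq_along(lv), function(k) {
      keep_sig(cand, d[d$experience == lv[k], , drop = FALSE], seed + k)
    })
    stats::setNames(out, c("inexperienced", "expert")[match(lv, c("no", "yes"))])
  } else {
    list(all = keep_sig(intersect(current, sig_terms), d, seed))
  }

  out <- list(kind = kind, random_structure = rs, overall = overall,
              trace = trace, final = final_fit, groups = groups,
              retained_terms = current)
  class(out) <- "model_reduction"
  out
}

#' @export
print.model_reduction <- function(x, ...) {
  cat(sprintf("%s task: overall LRT chi-sq = %.2f, df = %d, p = %.4g\n",
              x$kind, x$overall$chi_sq, x$overall$df, x$overall$p))
  cat("Reduction trace:\n")
  print(x$trace, digits = 3)
  for (g in names(x$groups)) {
    ic <- x$groups[[g]]$intercept
    cat(sprintf("Intercept [%s]: %.3f (95%% CI %.3f..%.3f, p = %.4g)\n",
                g, ic$estimate, ic$lower, ic$upper, ic$p))
  }
  invisible(x)
}

#' Descriptive statistics battery
#'
#' Per-participant mean KD and ID scores; paired t-test of KD against ID
#' performance; unpaired t-test of expert against inexperienced KD means;
#' Pearson correlation between ID and KD means; optional Spearman rank
#' correlations of experience duration (months categories) against both.
#'
#' @param responses response table.
#' @return List: `per_participant` (means and experience), `kd_vs_id`
#'   (paired t), `expert_vs_inexperienced` (unpaired t on KD means),
#'   `id_kd_correlation` (Pearson), optionally `duration_correlations`
#'   (Spearman) when a `experience_months` column is present.
#' @export
summary_stats <- function(responses) {
  agg <- function(kind) {
    r <- responses[responses$kind == kind, ]
    stats::aggregate(score ~ participant + experience, data = r, FUN = mean)
  }
  kd <- agg("KD"); id <- agg("ID")
  if (nrow(kd) < 3L) stop("need at least 3 participants")
  m <- merge(kd, id, by = c("participant", "experience"),
             suffixes = c("_kd", "_id"))
  paired <- stats::t.test(m$score_kd, m$score_id, paired = TRUE)
  expert <- m$score_kd[m$experience == "yes"]
  naive <- m$score_kd[m$experience == "no"]
  unpaired <- stats::t.test(expert, naive, var.equal = TRUE)
  pear <- stats::cor.test(m$score_id, m$score_kd, method = "pearson")
  out <- list(
    per_participant = m,
    kd_vs_id = list(t = unname(paired$statistic),
                    df = unname(paired$parameter), p = paired$p.value,
                    mean_kd = mean(m$score_kd), sd_kd = stats::sd(m$score_kd),
                    mean_id = mean(m$score_id), sd_id = stats::sd(m$score_id)),
    expert_vs_inexperienced = list(
      t = unname(unpaired$statistic), df = unname(unpaired$parameter),
      p = unpaired$p.value,
      mean_expert = mean(expert), sd_expert = stats::sd(expert),
      mean_inexperienced = mean(naive), sd_inexperienced = stats::sd(naive)),
    id_kd_correlation = list(r = unname(pear$estimate), n = nrow(m),
                             p = pear$p.value))
  if ("experience_months" %in% names(responses)) {
    em <- responses[!duplicated(responses$participant),
                    c("participant", "experience_months")]
    mm <- merge(m, em, by = "participant")
    sp <- function(y) {
      ct <- suppressWarnings(
        stats::cor.test(mm$experience_months, y, method = "spearman"))
      list(rho = unname(ct$estimate), p = ct$p.value)
    }
    out$duration_correlations <- list(id = sp(mm$score_id),
                                      kd = sp(mm$score_kd))
  }
  out
}
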