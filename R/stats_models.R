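# Linear mixed-effects layer: general LMM fitting with participant random
# intercepts, growth-curve analysis of looking time on orthogonal polynomial
# time, polynomial degree comparison, Tukey-adjusted post-hoc contrasts, and
# the pupil-gaze association models.

#' Center and scale continuous columns
#'
#' @param data a `data.frame`.
#' @param vars columns to scale; silently skips absent or non-numeric ones.
#' @return the data with scaled columns (mean 0, SD 1; constant columns are
#'   centered only).
#' @export
scale_continuous <- function(data, vars) {
  for (v in intersect(vars, names(data))) {
    if (!is.numeric(data[[v]])) next
    x <- data[[v]]
    s <- stats::sd(x, na.rm = TRUE)
    if (!is.finite(s) || s == 0) s <- 1
    data[[v]] <- (x - mean(x, na.rm = TRUE)) / s
  }
  data
}

# sum-to-zero contrasts on all factor/character columns so the marginal
# (type III) tests are well defined
.sum_contrasts <- function(data) {
  for (v in names(data)) {
    if (is.character(data[[v]])) data[[v]] <- factor(data[[v]])
    if (is.factor(data[[v]]) && nlevels(data[[v]]) > 1)
      stats::contrasts(data[[v]]) <- stats::contr.sum(nlevels(data[[v]]))
  }
  data
}

# Wald type-III chi-square tests from the fitted fixed effects (asymptotic;
# used where the Satterthwaite machinery would be needlessly expensive)
.wald_type3 <- function(model) {
  b <- lme4::fixef(model)
  V <- as.matrix(stats::vcov(model))
  asg <- attr(stats::model.matrix(model), "assign")
  labs <- attr(stats::terms(model), "term.labels")
  labs <- labs[!grepl("\\|", labs)]
  out <- data.frame(term = labs, statistic = NA_real_, df = NA_integer_,
                    p.value = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(labs)) {
    idx <- which(asg == i)
    if (length(idx) == 0) next
    bi <- b[idx]
    chi <- tryCatch(
      as.numeric(t(bi) %*% solve(V[idx, idx, drop = FALSE], bi)),
      error = function(e) NA_real_)
    out$statistic[i] <- chi
    out$df[i] <- length(idx)
    out$p.value[i] <- stats::pchisq(chi, length(idx), lower.tail = FALSE)
  }
  out
}

#' Fit a linear mixed model with a participant random intercept
#'
#' REML fit (by default) with sum-to-zero factor contrasts, continuous
#' predictors centered and scaled, marginal (type III) F-tests per fixed
#' term, and 95% Wald confidence intervals for the coefficients. Singular
#' fits produce a warning and a diagnostic flag, not an error.
#'
#' @param formula model formula including the random part, e.g.
#'   `y ~ group * aoi + age + sex + onscreen_time + (1 | participant_id)`.
#' @param data model data.
#' @param scale_vars continuous columns to center/scale before fitting
#'   (the outcome may be included).
#' @param ddf denominator-df method for the F-tests: `"Satterthwaite"`
#'   (default) or `"asymptotic"` (Wald chi-square; statistic reported in
#'   the same table with `df` = numerator df).
#' @param REML estimation criterion (default TRUE).
#' @return a `model_result`: list with `model`, `coefficients` (`term`,
#'   `estimate`, `ci_lo`, `ci_hi`), `tests` (type III table), `singular`,
#'   `logLik`, `AIC`, `BIC`.
#' @export
fit_lmm <- function(formula, data, scale_vars = character(0),
                    ddf = c("Satterthwaite", "asymptotic"), REML = TRUE) {
  ddf <- match.arg(ddf)
  data <- .sum_contrasts(scale_continuous(as.data.frame(data), scale_vars))
  outcome <- all.vars(formula)[1]
  if (stats::var(data[[outcome]], na.rm = TRUE) < .Machine$double.eps)
    stop("degenerate fit: outcome '", outcome, "' is constant")
  ctrl <- lme4::lmerControl(calc.derivs = FALSE,
                            check.conv.singular = lme4::.makeCC(
                              action = "ignore", tol = 1e-4))
  # lmerTest's refit machinery is only needed for Satterthwaite df
  model <- if (ddf == "Satterthwaite")
    lmerTest::lmer(formula, data = data, REML = REML, control = ctrl)
  else
    lme4::lmer(formula, data = data, REML = REML, control = ctrl)
  singular <- lme4::isSingular(model)
  if (singular)
    warning("singular fit: random-effect variance estimated at zero")
  b <- lme4::fixef(model)
  se <- sqrt(diag(as.matrix(stats::vcov(model))))
  coefs <- data.frame(term = names(b), estimate = as.numeric(b),
                      ci_lo = b - 1.96 * se, ci_hi = b + 1.96 * se,
                      stringsAsFactors = FALSE)
  rownames(coefs) <- NULL
  tests <- if (ddf == "Satterthwaite") {
    a <- stats::anova(model, type = 3, ddf = "Satterthwaite")
    data.frame(term = rownames(a), statistic = a[["F value"]],
               df = a$NumDF, ddf = a$DenDF, p.value = a[["Pr(>F)"]],
               stringsAsFactors = FALSE)
  } else {
    .wald_type3(model)
  }
  structure(list(model = model, coefficients = coefs, tests = tests,
                 singular = singular, logLik = as.numeric(stats::logLik(model)),
                 AIC = stats::AIC(model), BIC = stats::BIC(model),
                 formula = formula),
            class = "model_result")
}

#' @export
print.model_result <- function(x, ...) {
  cat("Linear mixed model:", deparse(x$formula), "\n")
  if (x$singular) cat("(singular fit)\n")
  cat("\nType III tests:\n")
  print(x$tests, digits = 3)
  invisible(x)
}

# attach orthogonal polynomial time columns ot1..otd; returns data + basis
.add_poly_time <- function(data, degree, basis = NULL) {
  if (is.null(basis)) basis <- stats::poly(data$time, degree)
  pb <- stats::predict(basis, data$time)
  for (d in seq_len(degree)) data[[paste0("ot", d)]] <- pb[, d]
  list(data = data, basis = basis)
}

# RHS pieces shared by the growth-curve and degree-comparison fits
.growth_rhs <- function(degree, has_aoi, has_emotion, covars,
                        random = "intercept", has_group = TRUE) {
  fac <- c(if (has_group) "group", if (has_aoi) "aoi",
           if (has_emotion) "emotion")
  fac_term <- paste(fac, collapse = " * ")
  ot <- paste0("(", paste(paste0("ot", seq_len(max(degree, 1))),
                          collapse = " + "), ")")
  main <- if (degree > 0 && length(fac) > 0) paste(ot, "*", fac_term)
  else if (degree > 0) ot
  else if (length(fac) > 0) fac_term
  else "1"
  re <- if (random == "slope" && degree > 0) {
    # diagonal by-participant slopes over time and, with two AOIs, over the
    # numeric AOI contrast and its products with time: lets the
    # eyes-vs-mouth trajectory difference have its own between-participant
    # variance (eyes and mouth counts are negatively correlated within a
    # participant, so independent per-AOI effects would understate it)
    sl <- paste0("ot", seq_len(degree))
    if (has_aoi) sl <- c("aoi_c", sl, paste0("ot", seq_len(degree), ":aoi_c"))
    paste0("(1 + ", paste(sl, collapse = " + "), " || participant_id)")
  } else {
    "(1 | participant_id)"
  }
  paste(c(main, covars, re), collapse = " + ")
}

#' Growth-curve analysis of looking-time progression
#'
#' Bin-level looking time (sample counts per 50 ms window) modelled on
#' orthogonal polynomial time (degrees 1..`degree`) fully crossed with
#' group x AOI x emotion, with the standard covariates and a participant
#' random intercept. The four-way interaction tests per polynomial degree
#' are reported in `tests`.
#'
#' @param bins bin-level table with columns `count`, `time`, `group`,
#'   `aoi`, `emotion`, `participant_id` and the covariates `age`, `sex`,
#'   `onscreen_time` (covariates absent from the data are dropped with a
#'   message; a single-level `aoi` or `emotion` is dropped with a warning).
#' @param degree polynomial degree (default 4).
#' @param ddf denominator-df method, see [fit_lmm()].
#' @param random random-effect structure: `"slope"` (default) adds
#'   uncorrelated by-participant(-by-AOI) random time slopes, which keeps
#'   the between-group trajectory tests calibrated in the presence of the
#'   strong serial dependence of 50 ms bins within a fixation;
#'   `"intercept"` is the participant-intercept-only structure.
#' @return a `model_result` with the orthogonal-poly basis stored as
#'   attribute `time_basis` (needed to evaluate contrasts at raw times).
#' @export
growth_curve_model <- function(bins, degree = 4,
                               ddf = c("Satterthwaite", "asymptotic"),
                               random = c("slope", "intercept")) {
  ddf <- match.arg(ddf)
  random <- match.arg(random)
  stopifnot(degree >= 1, degree <= 4)
  bins <- as.data.frame(bins)
  if (length(unique(bins$time)) < degree + 1)
    stop("insufficient distinct time bins for a degree-", degree, " fit")
  has_aoi <- "aoi" %in% names(bins) && length(unique(bins$aoi)) > 1
  has_emotion <- "emotion" %in% names(bins) && length(unique(bins$emotion)) > 1
  has_group <- "group" %in% names(bins) && length(unique(bins$group)) > 1
  if ("aoi" %in% names(bins) && !has_aoi)
    warning("single AOI level: AOI terms dropped")
  covars <- intersect(c("age", "sex", "onscreen_time"), names(bins))
  ap <- .add_poly_time(bins, degree)
  if (random == "slope" && has_aoi)
    ap$data$aoi_c <- ifelse(ap$data$aoi == sort(unique(ap$data$aoi))[1],
                            1, -1)
  f <- stats::as.formula(paste("count ~",
                               .growth_rhs(degree, has_aoi, has_emotion,
                                           covars, random, has_group)))
  mr <- fit_lmm(f, ap$data,
                scale_vars = c("count", "age", "onscreen_time"), ddf = ddf)
  attr(mr, "time_basis") <- ap$basis
  attr(mr, "degree") <- degree
  mr
}

#' Compare polynomial degrees for the growth-curve time course
#'
#' Maximum-likelihood fits for time polynomials of degree 0..`max_degree`
#' (same fixed/random structure otherwise), likelihood-ratio tests between
#' consecutive degrees, and information criteria. The recommended degree is
#' the largest `d` whose increment over `d - 1` is significant with all
#' lower increments significant too (increment-in-fit with parsimony).
#'
#' @param bins bin-level table, see [growth_curve_model()].
#' @param max_degree highest degree fitted (default 4).
#' @param alpha LRT significance level (default 0.05).
#' @return `data.frame` with one row per degree: `degree`, `logLik`, `AIC`,
#'   `BIC`, `lrt_chisq`, `lrt_df`, `lrt_p` (vs the previous degree), and
#'   attribute `recommended`.
#' @export
compare_polynomial_degrees <- function(bins, max_degree = 4, alpha = 0.05) {
  bins <- as.data.frame(bins)
  has_aoi <- "aoi" %in% names(bins) && length(unique(bins$aoi)) > 1
  has_emotion <- "emotion" %in% names(bins) && length(unique(bins$emotion)) > 1
  has_group <- "group" %in% names(bins) && length(unique(bins$group)) > 1
  covars <- intersect(c("age", "sex", "onscreen_time"), names(bins))
  ap <- .add_poly_time(bins, max(max_degree, 1))
  data <- .sum_contrasts(scale_continuous(ap$data,
                                          c("count", "age", "onscreen_time")))
  fits <- lapply(0:max_degree, function(d) {
    f <- stats::as.formula(paste("count ~",
                                 .growth_rhs(d, has_aoi, has_emotion, covars,
                                             has_group = has_group)))
    lme4::lmer(f, data = data, REML = FALSE,
               control = lme4::lmerControl(calc.derivs = FALSE,
                                           check.conv.singular = lme4::.makeCC(
                                             action = "ignore", tol = 1e-4)))
  })
  ll <- vapply(fits, function(m) as.numeric(stats::logLik(m)), numeric(1))
  npar <- vapply(fits, function(m) attr(stats::logLik(m), "df"), numeric(1))
  lrt_chisq <- c(NA, 2 * diff(ll))
  lrt_df <- c(NA, diff(npar))
  lrt_p <- ifelse(is.na(lrt_chisq), NA,
                  stats::pchisq(lrt_chisq, lrt_df, lower.tail = FALSE))
  out <- data.frame(degree = 0:max_degree, logLik = ll,
                    AIC = vapply(fits, stats::AIC, numeric(1)),
                    BIC = vapply(fits, stats::BIC, numeric(1)),
                    lrt_chisq = lrt_chisq, lrt_df = lrt_df, lrt_p = lrt_p)
  sig <- which(!is.na(out$lrt_p) & out$lrt_p < alpha)
  attr(out, "recommended") <- if (length(sig) == 0) 0L
  else out$degree[max(sig)]    # highest degree with a significant increment
  out
}

#' Tukey-adjusted post-hoc contrasts
#'
#' Estimated marginal means on a factor grid with Tukey-family adjustment.
#' For growth-curve models a vector of raw times can be supplied; the
#' orthogonal polynomial basis stored in the model is evaluated at those
#' times and the requested contrasts are computed at each time point
#' separately.
#'
#' @param mr a `model_result`.
#' @param specs emmeans specification, e.g. `~ emotion` or `~ group | aoi`.
#' @param at_times optional numeric vector of raw times (ms) for
#'   growth-curve models.
#' @param adjust p adjustment (default `"tukey"`).
#' @param lmer_df df method passed to emmeans (default `"asymptotic"`,
#'   which is exact enough at the denominator df of bin-level fits).
#' @return `data.frame` of contrasts: grid columns, `contrast`, `estimate`,
#'   `ci_lo`, `ci_hi`, `p.value`.
#' @export
posthoc_contrasts <- function(mr, specs, at_times = NULL, adjust = "tukey",
                              lmer_df = "asymptotic") {
  model <- mr$model
  grids <- list(NULL)
  if (!is.null(at_times)) {
    basis <- attr(mr, "time_basis")
    if (is.null(basis)) stop("model carries no time basis; at_times invalid")
    pb <- stats::predict(basis, at_times)
    degree <- attr(mr, "degree")
    grids <- lapply(seq_along(at_times), function(i) {
      at <- as.list(pb[i, seq_len(degree)])
      names(at) <- paste0("ot", seq_len(degree))
      at
    })
  }
  rows <- list()
  for (i in seq_along(grids)) {
    em <- if (is.null(grids[[i]]))
      emmeans::emmeans(model, specs, lmer.df = lmer_df)
    else
      emmeans::emmeans(model, specs, at = grids[[i]], lmer.df = lmer_df)
    ct <- summary(emmeans::contrast(em, "pairwise", adjust = adjust),
                  infer = c(TRUE, TRUE))
    ct <- as.data.frame(ct)
    class(ct) <- "data.frame"
    names(ct)[grep("lower\\.CL|LCL", names(ct))] <- "ci_lo"
    names(ct)[grep("upper\\.CL|UCL", names(ct))] <- "ci_hi"
    if (!is.null(at_times)) ct$time <- at_times[i]
    rows[[i]] <- ct
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pupil-gaze association models
#'
#' Per component window: an LMM of the fixation count and one of the mean
#' fixation duration on `PD x AOI x emotion`; per window x AOI: an LMM of
#' the mean looking time within the window's own time span on
#' `PD x emotion`. All models carry the standard covariates and a
#' participant random intercept; one model per AOI per window avoids
#' overfitting. Windows whose PD measure is entirely missing are skipped
#' with a message.
#'
#' @param pd trial-level PD measures from [pd_measures()] (columns
#'   `pd_trc1..k`).
#' @param outcomes fixation outcome table from [fixation_outcomes()].
#' @param bins trial x AOI x bin looking-time table (columns as in
#'   [sim_looking_bins()] or the pipeline's bin export).
#' @param windows `windows` table from [define_windows()].
#' @param participants covariate table (`participant_id`, `age`, `sex`,
#'   `onscreen_time`).
#' @param ddf denominator-df method, see [fit_lmm()].
#' @return named list of `model_result`s: `count_trc<k>`,
#'   `duration_trc<k>`, `looking_trc<k>_<aoi>`.
#' @export
association_models <- function(pd, outcomes, bins, windows, participants,
                               ddf = "Satterthwaite") {
  covars <- c("age", "sex", "onscreen_time")
  key <- c("participant_id", "trial_index")
  fix <- merge(outcomes, pd, by = intersect(names(outcomes), names(pd)))
  fix <- merge(fix, participants, by = "participant_id")
  if (nrow(fix) == 0) stop("empty join between PD measures and gaze outcomes")
  out <- list()
  for (k in seq_len(nrow(windows))) {
    pdv <- paste0("pd_trc", k)
    if (all(is.na(fix[[pdv]]))) {
      message("window ", k, ": PD measure entirely missing; models skipped")
      next
    }
    emo_term <- if (length(unique(fix$emotion)) > 1)
      paste0(pdv, " * aoi * emotion") else paste0(pdv, " * aoi")
    f_cnt <- stats::as.formula(paste(
      "n_fixations ~", emo_term, "+",
      paste(covars, collapse = " + "), "+ (1 | participant_id)"))
    out[[paste0("count_trc", k)]] <- fit_lmm(
      f_cnt, fix, scale_vars = c("n_fixations", pdv, "age", "onscreen_time"),
      ddf = ddf)
    dur <- fix[!is.na(fix$mean_duration), , drop = FALSE]
    f_dur <- stats::as.formula(paste(
      "mean_duration ~", emo_term, "+",
      paste(covars, collapse = " + "), "+ (1 | participant_id)"))
    out[[paste0("duration_trc", k)]] <- fit_lmm(
      f_dur, dur, scale_vars = c("mean_duration", pdv, "age", "onscreen_time"),
      ddf = ddf)
    # mean looking time within this window's time span, per trial x AOI
    sel <- bins$time >= windows$start_ms[k] & bins$time < windows$end_ms[k]
    lt <- stats::aggregate(count ~ participant_id + trial_index + aoi + emotion,
                           data = bins[sel, , drop = FALSE], FUN = mean)
    names(lt)[names(lt) == "count"] <- "looking"
    lt <- merge(lt, pd, by = intersect(names(lt), names(pd)))
    lt <- merge(lt, participants, by = "participant_id")
    emo_lt <- if (length(unique(lt$emotion)) > 1)
      paste0(pdv, " * emotion") else pdv
    for (aoi in c("eyes", "mouth")) {
      sub <- lt[lt$aoi == aoi, , drop = FALSE]
      if (nrow(sub) == 0) next
      f_lt <- stats::as.formula(paste(
        "looking ~", emo_lt, "+", paste(covars, collapse = " + "),
        "+ (1 | participant_id)"))
      out[[paste0("looking_trc", k, "_", aoi)]] <- fit_lmm(
        f_lt, sub, scale_vars = c("looking", pdv, "age", "onscreen_time"),
        ddf = ddf)
    }
  }
  out
}
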