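# Statistical stage: phase-wise linear mixed-effects models (Satterthwaite
# degrees of freedom via lmerTest), group-comparison variants, the retention
# first-two-trial differential, US habituation, cumulative-link mixed models
# for ordinal ratings (adaptive Gauss-Hermite quadrature), contingency
# awareness, and covariate sensitivity variants.

fit_result <- function(model_type, coefficients, varcomp = NULL,
                       converged = TRUE, note = NULL, n_obs = NA_integer_,
                       n_subjects = NA_integer_, fit = NULL, ...) {
  structure(list(model_type = model_type, coefficients = coefficients,
                 varcomp = varcomp, converged = converged, note = note,
                 n_obs = n_obs, n_subjects = n_subjects, fit = fit,
                 extra = list(...)),
            class = "fear_fit")
}

#' @export
print.fear_fit <- function(x, digits = 4, ...) {
  cat(sprintf("<fear_fit> %s  (n_obs=%s, n_subjects=%s, converged=%s)\n",
              x$model_type, x$n_obs, x$n_subjects, x$converged))
  if (!is.null(x$note)) cat("note:", x$note, "\n")
  print(format(x$coefficients, digits = digits), row.names = FALSE)
  if (!is.null(x$varcomp)) {
    cat(sprintf("subject-intercept SD = %.4g, residual SD = %.4g\n",
                x$varcomp$subject_sd, x$varcomp$residual_sd))
  }
  cat("No multiple-testing correction applied.\n")
  invisible(x)
}

#' Coefficient table of a fitted model
#'
#' @param fit a `fear_fit`.
#' @return data.frame with columns `term`, `estimate`, `se`, `statistic`,
#'   `df`, `p`.
#' @export
coef_table <- function(fit) {
  stopifnot(inherits(fit, "fear_fit"))
  fit$coefficients
}

# trial table -> analysis frame with treatment-coded factors
prepare_trials <- function(trials, phase = NULL,
                           reference_group = "adolescent",
                           trial_types = c("CS+", "CS-")) {
  d <- trials
  if (!is.null(phase)) d <- d[d$phase == phase, , drop = FALSE]
  d <- d[d$trial_type %in% trial_types, , drop = FALSE]
  d <- d[!is.na(d$scr_sqrt), , drop = FALSE]
  if ("CS+" %in% trial_types && "CS-" %in% trial_types) {
    d$cs <- factor(d$trial_type, levels = c("CS-", "CS+"))
  }
  if ("group" %in% names(d)) {
    groups <- c("child", "adolescent", "adult")
    d$group <- factor(d$group,
                      levels = c(reference_group,
                                 setdiff(groups, reference_group)))
  }
  d$trial <- as.numeric(d$trial_index)
  d$subject <- factor(d$subject)
  d
}

lmer_fit_result <- function(fm, data, model_type) {
  fit <- tryCatch(
    lmerTest::lmer(fm, data = data, REML = TRUE),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(fit_result(model_type, coefficients = NULL, converged = FALSE,
                      note = conditionMessage(fit), n_obs = nrow(data)))
  }
  sm <- summary(fit)
  co <- as.data.frame(sm$coefficients)
  tab <- data.frame(term = rownames(co), estimate = co[["Estimate"]],
                    se = co[["Std. Error"]], statistic = co[["t value"]],
                    df = co[["df"]], p = co[["Pr(>|t|)"]],
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  vc <- as.data.frame(lme4::VarCorr(fit))
  subj_sd <- vc$sdcor[vc$grp == "subject"][1]
  resid_sd <- vc$sdcor[vc$grp == "Residual"][1]
  msgs <- unlist(fit@optinfo$conv$lme4$messages)
  singular <- lme4::isSingular(fit, tol = 1e-4)
  note <- NULL
  if (singular) note <- "subject-intercept variance at boundary (~0)"
  # a boundary (singular) fit is converged; only real optimizer failures flag
  real_msgs <- msgs[!grepl("boundary \\(singular\\)", msgs)]
  conv <- length(real_msgs) == 0L
  if (length(msgs)) note <- paste(c(note, msgs), collapse = "; ")
  fit_result(model_type, coefficients = tab,
             varcomp = list(subject_sd = subj_sd, residual_sd = resid_sd),
             converged = conv, note = note,
             n_obs = stats::nobs(fit),
             n_subjects = nlevels(droplevels(data$subject)), fit = fit)
}

#' Phase-wise linear mixed-effects model
#'
#' Random-intercept Gaussian model of square-root-transformed SCR with CS
#' type, trial (numeric, 1-based within phase) and their interaction as fixed
#' effects, fitted by REML; p-values use Satterthwaite-approximated degrees
#' of freedom. CS- is the reference condition. Rows with missing outcomes are
#' dropped.
#'
#' @param trials trial table from [score_cohort()] (columns `subject`,
#'   `phase`, `trial_type`, `trial_index`, `scr_sqrt`, ...).
#' @param phase phase to analyse.
#' @param outcome outcome column (default `"scr_sqrt"`).
#' @param covariates optional character vector of additional fixed-effect
#'   columns.
#' @param center_trial center the trial index (default `FALSE`: raw 1..n).
#' @return a `fear_fit`.
#' @export
fit_phase_lmm <- function(trials, phase, outcome = "scr_sqrt",
                          covariates = NULL, center_trial = FALSE) {
  d <- prepare_trials(trials, phase)
  check_lmm_data(d)
  if (center_trial) d$trial <- d$trial - mean(d$trial)
  d$.y <- d[[outcome]]
  rhs <- paste(c("cs * trial", covariates, "(1 | subject)"), collapse = " + ")
  lmer_fit_result(stats::as.formula(paste(".y ~", rhs)), d,
                  paste0("lmm_", phase))
}

check_lmm_data <- function(d) {
  if (nlevels(droplevels(d$subject)) < 2L) {
    stop("need at least 2 subjects with non-missing outcomes", call. = FALSE)
  }
  per <- table(d$subject, d$trial_type)
  if (max(per) < 2L) {
    stop("need at least 2 trials per CS type", call. = FALSE)
  }
  invisible(TRUE)
}

#' Group-comparison linear mixed-effects model
#'
#' Adds age group and all its interactions (group x CS, group x trial,
#' group x CS x trial) to the phase-wise model. The reference group is
#' switchable: adolescents for the adolescent-dip contrasts, children for
#' the progressive-development contrasts.
#'
#' @inheritParams fit_phase_lmm
#' @param reference_group `"adolescent"` or `"child"` (any of the three
#'   labels is accepted).
#' @return a `fear_fit`.
#' @export
fit_group_lmm <- function(trials, phase, reference_group = "adolescent",
                          outcome = "scr_sqrt", covariates = NULL) {
  if (!"group" %in% names(trials)) {
    stop("`trials` has no `group` column", call. = FALSE)
  }
  d <- prepare_trials(trials, phase, reference_group = reference_group)
  if (nlevels(droplevels(d$group)) < 2L) {
    stop("need at least 2 groups", call. = FALSE)
  }
  check_lmm_data(d)
  d$.y <- d[[outcome]]
  rhs <- paste(c("cs * trial * group", covariates, "(1 | subject)"),
               collapse = " + ")
  lmer_fit_result(stats::as.formula(paste(".y ~", rhs)), d,
                  paste0("lmm_group_", phase))
}

#' Retention early-trial differential scores
#'
#' Per subject: mean sqrt-SCR of the first two retention CS+ trials minus the
#' first two CS- trials. By default a subject's score is missing if any of
#' the four contributing trials is missing; `require_complete = FALSE` uses
#' available-case means instead.
#'
#' @param trials trial table including the retention phase.
#' @param require_complete all four early trials required (default `TRUE`).
#' @return data.frame with `subject`, `group`, `early_diff`.
#' @export
retention_scores <- function(trials, require_complete = TRUE) {
  d <- trials[trials$phase == "retention" &
                trials$trial_type %in% c("CS+", "CS-") &
                trials$trial_index <= 2, , drop = FALSE]
  if (nrow(d) == 0L) stop("no retention trials found", call. = FALSE)
  split_by <- split(d, d$subject)
  rows <- lapply(split_by, function(s) {
    plus <- s$scr_sqrt[s$trial_type == "CS+"]
    minus <- s$scr_sqrt[s$trial_type == "CS-"]
    score <- if (require_complete &&
                 (length(plus) < 2L || length(minus) < 2L ||
                  anyNA(plus) || anyNA(minus))) {
      NA_real_
    } else {
      mean(plus, na.rm = TRUE) - mean(minus, na.rm = TRUE)
    }
    data.frame(subject = s$subject[1],
               group = if ("group" %in% names(s)) s$group[1] else NA,
               early_diff = score, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  excluded <- out$subject[!is.finite(out$early_diff)]
  if (length(excluded)) {
    message(length(excluded),
            " subject(s) excluded from retention scores (missing trials): ",
            paste(utils::head(excluded, 5), collapse = ", "))
  }
  out
}

#' Group regression of the retention differential
#'
#' Ordinary least squares of the early-trial CS+ minus CS- differential on
#' age group (two treatment-coded terms), with the overall group F test.
#'
#' @param scores data.frame from [retention_scores()].
#' @param reference_group reference level for the group factor.
#' @return a `fear_fit`; the overall F test is in `$extra$f_test`.
#' @export
retention_group_test <- function(scores, reference_group = "adolescent") {
  d <- scores[is.finite(scores$early_diff), , drop = FALSE]
  groups <- c("child", "adolescent", "adult")
  d$group <- factor(d$group, levels = c(reference_group,
                                        setdiff(groups, reference_group)))
  fit <- stats::lm(early_diff ~ group, data = d)
  sm <- summary(fit)
  co <- as.data.frame(sm$coefficients)
  tab <- data.frame(term = rownames(co), estimate = co[[1]], se = co[[2]],
                    statistic = co[[3]], df = fit$df.residual, p = co[[4]],
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  fstat <- sm$fstatistic
  f_test <- if (is.null(fstat)) NULL else {
    list(F = unname(fstat[1]), df1 = unname(fstat[2]),
         df2 = unname(fstat[3]),
         p = unname(stats::pf(fstat[1], fstat[2], fstat[3],
                              lower.tail = FALSE)))
  }
  fit_result("retention_group_regression", tab,
             n_obs = nrow(d), n_subjects = nrow(d), fit = fit,
             f_test = f_test)
}

#' US habituation model
#'
#' Linear mixed-effects model of sqrt-SCR to the unconditioned stimulus
#' during acquisition, with trial, group and their interaction as fixed
#' effects and a subject random intercept.
#'
#' @param trials trial table scored with `score_us = TRUE`.
#' @param reference_group reference group level.
#' @return a `fear_fit`.
#' @export
fit_us_habituation <- function(trials, reference_group = "adolescent") {
  d <- prepare_trials(trials, phase = "acquisition",
                      reference_group = reference_group,
                      trial_types = "US")
  if (nrow(d) == 0L) stop("no US-locked trials present", call. = FALSE)
  if (max(table(d$subject)) < 2L) {
    stop("need at least 2 US trials per subject", call. = FALSE)
  }
  d$.y <- d$scr_sqrt
  has_groups <- "group" %in% names(d) && nlevels(droplevels(d$group)) >= 2L
  rhs <- if (has_groups) "trial * group" else "trial"
  lmer_fit_result(stats::as.formula(paste(".y ~", rhs, "+ (1 | subject)")),
                  d, "lmm_us_habituation")
}

#' Contingency-awareness classification
#'
#' A participant is contingency aware iff they report that the CS+ face
#' screamed and the CS- face did not. Missing answers give a missing
#' classification.
#'
#' @param cs_plus_screamed,cs_minus_screamed logical vectors of reported
#'   answers.
#' @return logical vector.
#' @export
contingency_aware <- function(cs_plus_screamed, cs_minus_screamed) {
  ifelse(is.na(cs_plus_screamed) | is.na(cs_minus_screamed), NA,
         cs_plus_screamed & !cs_minus_screamed)
}

# ---------------------------------------------------------------------------
# Cumulative-link (proportional-odds) mixed model, fitted by maximising the
# marginal likelihood with a Gaussian subject random intercept integrated out
# by adaptive Gauss-Hermite quadrature.

# Golub-Welsch nodes/weights for Gauss-Hermite quadrature (weight e^{-x^2}).
gauss_hermite <- function(n) {
  if (n == 1L) return(list(nodes = 0, weights = sqrt(pi)))
  i <- seq_len(n - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- sqrt(i / 2)
  J[cbind(i + 1, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord], weights = sqrt(pi) * e$vectors[1, ord]^2)
}

# zeta (unconstrained) -> strictly increasing thresholds
zeta_to_theta <- function(zeta) {
  cumsum(c(zeta[1], exp(zeta[-1])))
}

clmm_loglik_parts <- function(theta, eta, y, K) {
  th <- c(-Inf, theta, Inf)
  a_hi <- th[y + 1L] - eta
  a_lo <- th[y] - eta
  list(a_hi = a_hi, a_lo = a_lo)
}

# per-observation log P(Y = y | u) and derivatives wrt u, vectorised
clmm_obs_terms <- function(a_hi, a_lo, sigma, deriv = FALSE) {
  F_hi <- stats::plogis(a_hi)
  F_lo <- stats::plogis(a_lo)
  p <- pmax(F_hi - F_lo, 1e-300)
  out <- list(logp = log(p))
  if (deriv) {
    f_hi <- F_hi * (1 - F_hi)
    f_lo <- F_lo * (1 - F_lo)
    fp_hi <- f_hi * (1 - 2 * F_hi)
    fp_lo <- f_lo * (1 - 2 * F_lo)
    r <- (f_hi - f_lo) / p
    out$d1 <- -sigma * r
    out$d2 <- sigma^2 * ((fp_hi - fp_lo) / p - r^2)
  }
  out
}

# negative marginal log-likelihood; subj is an integer index per observation
clmm_nll <- function(par, X, y, subj, K, n_sub, gh, sigma_fixed = NULL) {
  n_zeta <- K - 1L
  zeta <- par[seq_len(n_zeta)]
  beta <- par[n_zeta + seq_len(ncol(X))]
  sigma <- if (is.null(sigma_fixed)) exp(par[length(par)]) else sigma_fixed
  theta <- zeta_to_theta(zeta)
  if (any(!is.finite(theta))) return(1e10)
  eta <- if (ncol(X)) drop(X %*% beta) else numeric(length(y))
  parts <- clmm_loglik_parts(theta, eta, y, K)

  if (sigma == 0) {
    obs <- clmm_obs_terms(parts$a_hi, parts$a_lo, 0)
    return(-sum(obs$logp))
  }

  g_of_u <- function(u, deriv = FALSE) {
    uu <- u[subj]
    obs <- clmm_obs_terms(parts$a_hi - sigma * uu, parts$a_lo - sigma * uu,
                          sigma, deriv = deriv)
    g <- rowsum(obs$logp, subj)[, 1] - u^2 / 2
    if (!deriv) return(list(g = g))
    list(g = g,
         d1 = rowsum(obs$d1, subj)[, 1] - u,
         d2 = rowsum(obs$d2, subj)[, 1] - 1)
  }

  # adaptive quadrature: centre nodes at the per-subject mode of the
  # integrand (damped Newton)
  u <- numeric(n_sub)
  for (it in 1:25) {
    d <- g_of_u(u, deriv = TRUE)
    h <- pmin(d$d2, -1e-6)
    step <- d$d1 / h
    step <- pmax(pmin(step, 3), -3)
    u_new <- u - step
    if (max(abs(u_new - u)) < 1e-8) { u <- u_new; break }
    u <- u_new
  }
  d <- g_of_u(u, deriv = TRUE)
  s_i <- 1 / sqrt(pmax(-d$d2, 1e-8))

  log_terms <- matrix(NA_real_, n_sub, length(gh$nodes))
  for (k in seq_along(gh$nodes)) {
    uk <- u + sqrt(2) * s_i * gh$nodes[k]
    log_terms[, k] <- g_of_u(uk)$g + gh$nodes[k]^2 + log(gh$weights[k])
  }
  m <- apply(log_terms, 1, max)
  ll_i <- m + log(rowSums(exp(log_terms - m))) + log(sqrt(2) * s_i) -
    0.5 * log(2 * pi)
  nll <- -sum(ll_i)
  if (!is.finite(nll)) 1e10 else nll
}

#' Cumulative-link mixed model for ordinal ratings
#'
#' Proportional-odds (cumulative-logit) model with a Gaussian subject random
#' intercept, fitted by maximum marginal likelihood with the random effect
#' integrated out by adaptive Gauss-Hermite quadrature (nodes centred and
#' scaled at each subject's conditional mode; 1 node is the Laplace
#' approximation). Fixed effects are treatment-coded from `formula`;
#' coefficient tests are Wald z. Fitting is deterministic: starting values
#' come from a proportional-odds fit without random effects.
#'
#' @param formula fixed-effects formula with the ordinal outcome on the left,
#'   e.g. `rating ~ cs * phase`.
#' @param data data.frame; outcome must be integers (or an ordered factor)
#'   with at least 2 observed categories.
#' @param subject name of the grouping column for the random intercept.
#' @param nodes number of quadrature nodes (default 15).
#' @param sigma_fixed fix the random-intercept SD (e.g. 0 for a plain
#'   proportional-odds fit) instead of estimating it.
#' @return a `fear_fit`; `$varcomp$subject_sd` holds the estimated
#'   random-intercept SD, `$extra$thresholds` the cut points,
#'   `$extra$logLik` the maximised marginal log-likelihood.
#' @export
fit_clmm <- function(formula, data, subject = "subject", nodes = 15,
                     sigma_fixed = NULL) {
  vars <- c(all.vars(formula), subject)
  data <- data[stats::complete.cases(data[, vars, drop = FALSE]), ,
               drop = FALSE]
  mf <- stats::model.frame(formula, data)
  y_raw <- stats::model.response(mf)
  y <- if (is.ordered(y_raw) || is.factor(y_raw)) as.integer(y_raw) else {
    as.integer(y_raw)
  }
  lev <- sort(unique(y))
  if (length(lev) < 2L) {
    stop("outcome has a single observed category; cannot fit", call. = FALSE)
  }
  y <- match(y, lev)  # 1..K over observed categories
  K <- length(lev)
  X <- stats::model.matrix(formula, mf)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  subj_f <- factor(data[[subject]])
  subj <- as.integer(subj_f)
  n_sub <- nlevels(subj_f)
  gh <- gauss_hermite(nodes)

  # starting values from the no-random-effect proportional-odds fit
  start_fit <- tryCatch(
    MASS::polr(factor(y, levels = seq_len(K)) ~ X, Hess = FALSE),
    error = function(e) NULL)
  if (!is.null(start_fit)) {
    th0 <- unname(start_fit$zeta)
    beta0 <- unname(stats::coef(start_fit))
  } else {
    cum <- cumsum(tabulate(y, K) / length(y))[seq_len(K - 1)]
    th0 <- stats::qlogis(pmin(pmax(cum, 1e-3), 1 - 1e-3))
    beta0 <- rep(0, ncol(X))
  }
  zeta0 <- c(th0[1], log(pmax(diff(th0), 1e-3)))
  par0 <- c(zeta0, beta0)
  if (is.null(sigma_fixed)) par0 <- c(par0, log(1))

  opt <- stats::optim(par0, clmm_nll, X = X, y = y, subj = subj, K = K,
                      n_sub = n_sub, gh = gh, sigma_fixed = sigma_fixed,
                      method = "BFGS", hessian = TRUE,
                      control = list(maxit = 500, reltol = 1e-10))
  converged <- opt$convergence == 0
  n_zeta <- K - 1L
  zeta <- opt$par[seq_len(n_zeta)]
  beta <- opt$par[n_zeta + seq_len(ncol(X))]
  sigma <- if (is.null(sigma_fixed)) exp(opt$par[length(opt$par)]) else {
    sigma_fixed
  }
  theta <- zeta_to_theta(zeta)

  vcov_all <- tryCatch(solve(opt$hessian), error = function(e) NULL)
  se_beta <- if (!is.null(vcov_all)) {
    sqrt(pmax(diag(vcov_all)[n_zeta + seq_len(ncol(X))], 0))
  } else {
    rep(NA_real_, ncol(X))
  }
  z <- beta / se_beta
  tab <- data.frame(term = colnames(X), estimate = beta, se = se_beta,
                    statistic = z, df = NA_real_,
                    p = 2 * stats::pnorm(-abs(z)), stringsAsFactors = FALSE)
  fit_result("clmm", tab,
             varcomp = list(subject_sd = sigma, residual_sd = NA_real_),
             converged = converged,
             note = if (!converged) "optimizer did not converge" else NULL,
             n_obs = length(y), n_subjects = n_sub,
             thresholds = stats::setNames(theta,
                                          paste(lev[-K], lev[-1], sep = "|")),
             logLik = -opt$value, levels = lev)
}

#' Ratings model in the study's parameterisation
#'
#' Fits the cumulative-link mixed model of 1-5 fear ratings with CS, rating
#' phase, and (optionally) age group plus all interactions, with CS- and
#' acquisition as reference conditions and a subject random intercept.
#'
#' @param ratings data.frame with columns `subject`, `cs`, `phase`,
#'   `rating`, and `group` when `by_group = TRUE`.
#' @param by_group include age group and its interactions.
#' @param reference_group reference group level.
#' @param nodes quadrature nodes.
#' @return a `fear_fit`.
#' @export
fit_ratings_clmm <- function(ratings, by_group = FALSE,
                             reference_group = "adolescent", nodes = 15) {
  d <- ratings
  stopifnot(all(d$rating %in% 1:5))
  d$cs <- factor(d$cs, levels = c("CS-", "CS+"))
  d$phase <- factor(d$phase, levels = c("acquisition", "pre", "extinction"))
  fm <- rating ~ cs * phase
  if (by_group) {
    groups <- c("child", "adolescent", "adult")
    d$group <- factor(d$group, levels = c(reference_group,
                                          setdiff(groups, reference_group)))
    fm <- rating ~ cs * phase * group
  }
  fit_clmm(fm, d, subject = "subject", nodes = nodes)
}

#' Sensitivity-analysis suite
#'
#' Refits the base SCR models with (i) SES, (ii) US sound level as
#' covariates, (iii) the retention model additionally adjusted for days
#' between sessions, and (iv) on the contingency-aware subset only, then
#' tabulates sign and significance stability of every fixed effect against
#' the base fits. Covariates that are constant are dropped with a warning.
#'
#' @param trials trial table with covariate columns `ses`,
#'   `us_sound_level`, `days_between_sessions`, `aware`.
#' @param phases phases to analyse (default acquisition, extinction,
#'   retention).
#' @return list with `fits` (named list of `fear_fit`s) and `comparison`
#'   (data.frame: phase, variant, term, estimate, p, sign_stable,
#'   significance_stable vs the base model at alpha = 0.05).
#' @export
sensitivity_suite <- function(trials,
                              phases = c("acquisition", "extinction",
                                         "retention")) {
  need <- c("ses", "us_sound_level", "days_between_sessions", "aware")
  miss <- setdiff(need, names(trials))
  if (length(miss)) {
    stop("missing covariate columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  usable <- function(v) {
    ok <- length(unique(stats::na.omit(trials[[v]]))) > 1L
    if (!ok) warning("covariate `", v, "` is constant; dropped",
                     call. = FALSE)
    ok
  }
  fits <- list()
  rows <- list()
  for (ph in phases) {
    base <- fit_phase_lmm(trials, ph)
    fits[[paste0(ph, "_base")]] <- base
    variants <- list()
    if (usable("ses")) {
      variants$ses <- fit_phase_lmm(trials, ph, covariates = "ses")
    }
    if (usable("us_sound_level")) {
      variants$us_sound_level <-
        fit_phase_lmm(trials, ph, covariates = "us_sound_level")
    }
    if (ph == "retention" && usable("days_between_sessions")) {
      variants$days_between_sessions <-
        fit_phase_lmm(trials, ph, covariates = "days_between_sessions")
    }
    aware_trials <- trials[trials$aware %in% TRUE, , drop = FALSE]
    if (nrow(aware_trials)) {
      variants$aware_only <- fit_phase_lmm(aware_trials, ph)
    }
    for (vn in names(variants)) {
      v <- variants[[vn]]
      fits[[paste0(ph, "_", vn)]] <- v
      shared <- intersect(base$coefficients$term, v$coefficients$term)
      b <- base$coefficients[match(shared, base$coefficients$term), ]
      a <- v$coefficients[match(shared, v$coefficients$term), ]
      rows[[paste(ph, vn)]] <- data.frame(
        phase = ph, variant = vn, term = shared,
        estimate = a$estimate, p = a$p,
        sign_stable = sign(a$estimate) == sign(b$estimate),
        significance_stable = (a$p < 0.05) == (b$p < 0.05),
        stringsAsFactors = FALSE)
    }
  }
  list(fits = fits,
       comparison = do.call(rbind, c(rows, make.row.names = FALSE)))
}

# ---------------------------------------------------------------------------
# Direct trial-table generator for calibration studies: draws sqrt-SCR
# outcomes straight from the random-intercept LMM, bypassing the signal
# chain, so type-I-error and recovery simulations stay cheap.

#' Simulate a trial table directly from the mixed model
#'
#' Generates `scr_sqrt` outcomes from
#' `beta0 + beta_cs [CS+] + beta_trial trial + beta_cs_trial [CS+] trial +
#' group effects + subject intercept + noise` for a balanced design of
#' `n_trials` CS+ and `n_trials` CS- trials per subject. Used for type-I
#' calibration and parameter-recovery simulation studies of the fitting
#' machinery.
#'
#' @param n_subjects subjects per group (scalar, or named vector over
#'   groups).
#' @param n_trials trials per CS type.
#' @param beta named numeric: `intercept`, `cs`, `trial`, `cs_trial`; any
#'   subset may be given, others default to 0 (intercept 0.5).
#' @param group_effects optional named list of per-group additive offsets on
#'   the outcome (e.g. `list(child = 0.1)`); groups default to a single
#'   `"adolescent"` group when `n_subjects` is a scalar.
#' @param sigma_b subject random-intercept SD.
#' @param sigma_e residual SD.
#' @param phase phase label for the generated rows.
#' @param seed optional seed.
#' @return trial table data.frame compatible with [fit_phase_lmm()].
#' @export
simulate_lmm_trials <- function(n_subjects = 40, n_trials = 10,
                                beta = c(intercept = 0.5),
                                group_effects = NULL,
                                sigma_b = 0.2, sigma_e = 0.25,
                                phase = "acquisition", seed = NULL) {
  b <- c(intercept = 0.5, cs = 0, trial = 0, cs_trial = 0)
  b[names(beta)] <- beta
  if (length(n_subjects) == 1L && is.null(names(n_subjects))) {
    n_subjects <- c(adolescent = n_subjects)
  }
  build <- function() {
    rows <- list()
    sid <- 0L
    for (grp in names(n_subjects)) {
      g_off <- if (is.null(group_effects)) 0 else {
        group_effects[[grp]] %||% 0
      }
      for (i in seq_len(n_subjects[[grp]])) {
        sid <- sid + 1L
        bi <- stats::rnorm(1, 0, sigma_b)
        grid <- expand.grid(trial_index = seq_len(n_trials),
                            trial_type = c("CS-", "CS+"),
                            stringsAsFactors = FALSE)
        is_plus <- grid$trial_type == "CS+"
        mu <- b[["intercept"]] + b[["cs"]] * is_plus +
          b[["trial"]] * grid$trial_index +
          b[["cs_trial"]] * is_plus * grid$trial_index + g_off + bi
        rows[[sid]] <- data.frame(
          subject = sprintf("sim%04d", sid), group = grp, phase = phase,
          trial_type = grid$trial_type, trial_index = grid$trial_index,
          scr_sqrt = mu + stats::rnorm(nrow(grid), 0, sigma_e),
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, c(rows, make.row.names = FALSE))
  }
  if (is.null(seed)) build() else with_seed(seed, build())
}
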