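#' Standardise a numeric vector to z-scores
#'
#' Mean 0, SD 1, computed over non-missing values; missing values are
#' propagated unchanged. The SD convention is sample (n-1) by default.
#'
#' @param values numeric vector
#' @param sample_sd use the n-1 denominator (`TRUE`, default) or population
#'   n
#' @return z-scores
#' @export
standardise <- function(values, sample_sd = TRUE) {
  ok <- !is.na(values)
  if (sum(ok) < 2) abort_input("need at least 2 non-missing values")
  m <- mean(values[ok])
  s <- sd(values[ok])
  if (!sample_sd) s <- s * sqrt((sum(ok) - 1) / sum(ok))
  if (s == 0) abort_input("zero spread; cannot standardise")
  (values - m) / s
}

#' Specify one candidate mixed-effects model
#'
#' Candidate sets are explicit lists — there is no automatic selection.
#' Every model gets random intercepts for participant and for parent/carer
#' (some children are siblings); covariates expected standardised
#' (`trial_z`, `age_z`, questionnaire z-scores) must be standardised by the
#' caller before fitting.
#'
#' @param label short model name for the ledger
#' @param outcome response column name
#' @param fixed character vector of fixed-effect terms (interactions via
#'   `"a:b"` or `"a*b"`); use `"1"` for an intercept-only model
#' @param random grouping columns for random intercepts
#' @return an object of class `model_spec`
#' @export
model_spec <- function(label, outcome, fixed = "1",
                       random = c("participant_id", "parent_id")) {
  structure(list(label = label, outcome = outcome, fixed = fixed,
                 random = random),
            class = "model_spec")
}

spec_formula <- function(spec) {
  rhs <- paste(c(spec$fixed,
                 paste0("(1|", spec$random, ")")), collapse = " + ")
  stats::as.formula(paste(spec$outcome, "~", rhs))
}

spec_vars <- function(spec) {
  unique(c(spec$outcome, spec$random,
           all.vars(stats::as.formula(paste("~", paste(spec$fixed,
                                                       collapse = "+"))))))
}

#' Fit a candidate set of mixed-effects models into a comparison ledger
#'
#' Every candidate is fitted by maximum likelihood (not REML — the
#' candidates differ in fixed effects, so ML is required for AIC/BIC
#' comparability) on the identical listwise-complete rows over the union of
#' all candidates' variables. The ledger reports AIC, BIC and differences
#' to the best model per criterion; convergence failures and singular fits
#' are flagged, never dropped. Wald statistics (Z = beta / SE, normal
#' p-values) accompany each model's coefficients.
#'
#' @param data trial-level or participant-level data.frame
#' @param candidates list of [model_spec()] objects
#' @return an object of class `model_ledger`: `$table` (one row per model,
#'   sorted by AIC) and `$fits` (per model: coefficients, messages)
#' @export
fit_ledger <- function(data, candidates) {
  if (length(candidates) == 0) abort_input("candidate list is empty")
  vars <- unique(unlist(lapply(candidates, spec_vars)))
  vars <- setdiff(vars, "1")
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols))
    abort_input("data lacks columns: ", paste(missing_cols, collapse = ", "))
  dat <- data[complete.cases(data[, vars, drop = FALSE]), , drop = FALSE]
  fits <- lapply(candidates, function(spec) {
    msgs <- character(0)
    fit <- withCallingHandlers(
      tryCatch(lme4::lmer(spec_formula(spec), data = dat, REML = FALSE),
               error = function(e) e),
      warning = function(w) {
        msgs <<- c(msgs, conditionMessage(w))
        invokeRestart("muffleWarning")
      },
      message = function(m) {           # lme4 reports singular fits here
        msgs <<- c(msgs, trimws(conditionMessage(m)))
        invokeRestart("muffleMessage")
      })
    if (inherits(fit, "error"))
      return(list(spec = spec, ok = FALSE, messages = conditionMessage(fit)))
    cc <- summary(fit)$coefficients
    coefs <- data.frame(term = rownames(cc), beta = cc[, "Estimate"],
                        se = cc[, "Std. Error"],
                        z = cc[, "Estimate"] / cc[, "Std. Error"])
    coefs$p <- 2 * pnorm(-abs(coefs$z))
    rownames(coefs) <- NULL
    list(spec = spec, ok = TRUE, fit = fit, coefficients = coefs,
         aic = AIC(fit), bic = BIC(fit),
         singular = lme4::isSingular(fit), messages = msgs,
         n = nrow(dat))
  })
  names(fits) <- vapply(candidates, `[[`, "", "label")
  tab <- do.call(rbind, lapply(fits, function(f) {
    data.frame(label = f$spec$label,
               aic = if (f$ok) f$aic else NA_real_,
               bic = if (f$ok) f$bic else NA_real_,
               converged = f$ok && length(f$messages) == 0,
               singular = if (f$ok) f$singular else NA,
               n = if (f$ok) f$n else NA_integer_)
  }))
  tab$delta_aic <- tab$aic - min(tab$aic, na.rm = TRUE)
  tab$delta_bic <- tab$bic - min(tab$bic, na.rm = TRUE)
  tab <- tab[order(tab$aic), ]
  rownames(tab) <- NULL
  structure(list(table = tab, fits = fits), class = "model_ledger")
}

#' @export
print.model_ledger <- function(x, ...) {
  cat("<model_ledger>\n")
  print.data.frame(x$table, digits = 5)
  invisible(x)
}

#' Extract one model's coefficient table from a ledger
#'
#' @param ledger a [fit_ledger()] result
#' @param label model label
#' @return data.frame `term`, `beta`, `se`, `z`, `p`
#' @export
ledger_coefficients <- function(ledger, label) {
  f <- ledger$fits[[label]]
  if (is.null(f)) abort_input("no model labelled '", label, "'")
  if (!f$ok) abort_input("model '", label, "' failed to fit: ", f$messages)
  f$coefficients
}

#' Pairwise-complete bivariate correlation matrix
#'
#' Pearson correlations with two-sided p-values on pairwise-complete rows,
#' uncorrected (mirroring an alpha = 0.05 uncorrected report); the number
#' of complete pairs is reported per cell. Cells with fewer than 3 complete
#' pairs are flagged missing.
#'
#' @param cohort data.frame of per-participant measures
#' @param measures column names to correlate
#' @return an object of class `correlation_matrix` with matrices `r`, `p`,
#'   `n`
#' @export
correlate <- function(cohort, measures) {
  missing_cols <- setdiff(measures, names(cohort))
  if (length(missing_cols))
    abort_input("cohort lacks columns: ", paste(missing_cols, collapse = ", "))
  k <- length(measures)
  R <- P <- N <- matrix(NA_real_, k, k, dimnames = list(measures, measures))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (j < i) next
    xi <- cohort[[measures[i]]]; xj <- cohort[[measures[j]]]
    ok <- !is.na(xi) & !is.na(xj)
    N[i, j] <- N[j, i] <- sum(ok)
    if (i == j) { R[i, j] <- 1; P[i, j] <- 0; next }
    if (sum(ok) < 3) next
    ct <- cor.test(xi[ok], xj[ok], method = "pearson")
    R[i, j] <- R[j, i] <- unname(ct$estimate)
    P[i, j] <- P[j, i] <- ct$p.value
  }
  structure(list(r = R, p = P, n = N), class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, digits = 3, ...) {
  cat("<correlation_matrix> (upper: R, lower: p, diagonal: n complete)\n")
  k <- ncol(x$r)
  out <- matrix("", k, k, dimnames = dimnames(x$r))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    out[i, j] <- if (i == j) sprintf("n=%d", as.integer(x$n[i, j]))
    else if (i < j) formatC(x$r[i, j], digits = digits, format = "fg")
    else formatC(x$p[i, j], digits = digits, format = "g")
  }
  print(out, quote = FALSE)
  invisible(x)
}

#' Simulate a trial-level dwell table for the statistics layer
#'
#' A direct generator for the response table the dwell mixed models see:
#' standardised dwell per trial and condition, with participant and
#' parent/carer random intercepts (siblings share a parent), an optional
#' condition effect, and Gaussian residuals. Used for power and type-I
#' calibration checks without paying for full gaze-stream simulation.
#'
#' @param n_participants number of children
#' @param n_trials trials per participant
#' @param condition_effect shift of the disgust condition in SD units
#'   (negative = avoidance); 0 gives a null world
#' @param sibling_fraction fraction of children sharing a parent
#' @param sd_participant,sd_parent,sd_resid variance components
#' @param seed RNG seed
#' @return data.frame `participant_id`, `parent_id`, `condition`,
#'   `trial_z`, `dwell_z`
#' @export
simulate_dwell_table <- function(n_participants = 30, n_trials = 42,
                                 condition_effect = 0,
                                 sibling_fraction = 0.2,
                                 sd_participant = 0.5, sd_parent = 0.3,
                                 sd_resid = 1, seed = 1) {
  with_seed(seed, {
    parent <- seq_len(n_participants)
    n_sib <- round(sibling_fraction * n_participants)
    if (n_sib > 0 && n_participants >= 2) {
      sibs <- sample.int(n_participants, n_sib)
      for (i in sibs)
        parent[i] <- parent[sample(setdiff(seq_len(n_participants), i), 1)]
    }
    parent_id <- sprintf("f%03d", match(parent, unique(parent)))
    u_part <- rnorm(n_participants, 0, sd_participant)
    u_par <- rnorm(length(unique(parent_id)), 0, sd_parent)
    names(u_par) <- unique(parent_id)
    rows <- expand.grid(trial = seq_len(n_trials),
                        condition = c("neutral", "disgust"),
                        participant = seq_len(n_participants))
    eff <- ifelse(rows$condition == "disgust", condition_effect, 0)
    dwell <- u_part[rows$participant] + u_par[parent_id[rows$participant]] +
      eff + rnorm(nrow(rows), 0, sd_resid)
    data.frame(participant_id = sprintf("p%03d", rows$participant),
               parent_id = parent_id[rows$participant],
               condition = factor(rows$condition,
                                  levels = c("neutral", "disgust")),
               trial_z = standardise(rows$trial),
               dwell_z = dwell)
  })
}
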