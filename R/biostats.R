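# Bioassay survival statistics.
#
# Survival tables are plain data.frames with at least `time` (days, positive
# integers) and `event` (1 = death observed, 0 = censored); group membership
# is carried in a `group` column where needed.

check_survival <- function(x, label = "records") {
  stopifnot(is.data.frame(x))
  if (!all(c("time", "event") %in% names(x))) {
    stop(label, " must have columns 'time' and 'event'")
  }
  if (any(x$time < 1)) stop(label, ": time must be >= 1")
  if (!all(x$event %in% c(0, 1))) stop(label, ": event must be 0/1")
  x
}

#' Log-rank hazard ratio of a treated group versus control
#'
#' The Mantel-Haenszel style observed/expected estimator: at each distinct
#' event time the groups are pooled, the expected number of deaths per group
#' is computed from the at-risk sets, and the hazard ratio is
#' `(O_t / E_t) / (O_c / E_c)`. The chi-square statistic is
#' `sum((O - E)^2 / E)` with 1 df. This is the observed-versus-expected
#' log-rank method as implemented in standard bioassay software, not the
#' Cox-model hazard ratio.
#'
#' @param treated,control survival data.frames (`time`, `event`)
#' @param one_tailed halve the p value in the direction of excess treated
#'   mortality (used for planned one-sided comparisons)
#' @return list with `hazard_ratio`, `chi_square`, `p`, and the per-group
#'   observed/expected totals
#' @export
logrank_hazard_ratio <- function(treated, control, one_tailed = FALSE) {
  treated <- check_survival(treated, "treated")
  control <- check_survival(control, "control")
  if (sum(treated$event) + sum(control$event) == 0) {
    stop("no events in either group")
  }
  times <- sort(unique(c(treated$time[treated$event == 1],
                         control$time[control$event == 1])))
  O <- c(t = 0, c = 0); E <- c(t = 0, c = 0)
  for (tm in times) {
    n_t <- sum(treated$time >= tm); n_c <- sum(control$time >= tm)
    d_t <- sum(treated$time == tm & treated$event == 1)
    d_c <- sum(control$time == tm & control$event == 1)
    d <- d_t + d_c; n <- n_t + n_c
    O <- O + c(d_t, d_c)
    E <- E + d * c(n_t, n_c) / n
  }
  if (E[["t"]] == 0) stop("zero expected deaths in group 'treated'")
  if (E[["c"]] == 0) stop("zero expected deaths in group 'control'")
  hr <- if (O[["t"]] == 0) 0
        else if (O[["c"]] == 0) Inf
        else (O[["t"]] / E[["t"]]) / (O[["c"]] / E[["c"]])
  chi <- sum((O - E)^2 / E)
  p <- pchisq(chi, df = 1, lower.tail = FALSE)
  if (one_tailed) p <- if (hr >= 1) p / 2 else 1 - p / 2
  list(hazard_ratio = unname(hr), chi_square = unname(chi), p = unname(p),
       observed = O, expected = E)
}

#' Cox proportional-hazards fit with Harrell's concordance
#'
#' Fits the partial likelihood with Efron tie handling (daily mortality
#' checks make ties ubiquitous). Constant covariates are dropped with a
#' warning and reported with coefficient 0. Harrell's C is returned with a
#' normal-approximation 95% confidence interval.
#'
#' @param data data.frame with `time`, `event` and covariate columns
#' @param covariates character vector naming covariate columns
#' @return list with `coefficients` (data.frame: `term`, `beta`, `se`, `z`,
#'   `p`, `dropped`), `concordance`, `concordance_ci`
#' @export
cox_ph_fit <- function(data, covariates) {
  data <- check_survival(data)
  stopifnot(length(covariates) >= 1L, all(covariates %in% names(data)))
  constant <- covariates[vapply(covariates, function(v)
    length(unique(data[[v]])) < 2L, TRUE)]
  if (length(constant) > 0L) {
    warning("constant covariates dropped: ", paste(constant, collapse = ", "))
  }
  active <- setdiff(covariates, constant)
  if (length(active) == 0L) stop("no non-constant covariates")
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 paste(active, collapse = " + ")))
  fit <- survival::coxph(fml, data = data, ties = "efron")
  if (!is.null(fit$info) && any(grepl("did not converge", fit$info))) {
    stop("Cox fit did not converge: ", fit$info)
  }
  s <- summary(fit)
  coefs <- data.frame(term = rownames(s$coefficients),
                      beta = s$coefficients[, "coef"],
                      se = s$coefficients[, "se(coef)"],
                      z = s$coefficients[, "z"],
                      p = s$coefficients[, "Pr(>|z|)"],
                      dropped = FALSE, stringsAsFactors = FALSE,
                      row.names = NULL)
  for (v in constant) {
    coefs <- rbind(coefs, data.frame(term = v, beta = 0, se = NA, z = NA,
                                     p = NA, dropped = TRUE))
  }
  conc <- unname(fit$concordance[["concordance"]])
  conc_se <- unname(fit$concordance[["std"]])
  list(coefficients = coefs, concordance = conc,
       concordance_ci = conc + c(-1, 1) * qnorm(0.975) * conc_se)
}

#' Multiple regression of hazard ratios on design scores
#'
#' Ordinary least squares of per-dsRNA hazard ratios on design predictors
#' (mean siRNA score, mean accessibility score, target region, target
#' gene). Categorical predictors use treatment coding; reference levels are
#' selectable. Reports the coefficient table, the multiple correlation
#' coefficient R, and the Shapiro-Wilk residual-normality p value.
#'
#' @param data data.frame of per-dsRNA observations
#' @param formula model formula, e.g.
#'   `hazard_ratio ~ sirna_score + accessibility + region + gene`
#' @param reference named list mapping factor column names to their
#'   reference level
#' @return list with `coefficients` (data.frame: `term`, `estimate`, `se`,
#'   `t`, `p`), `multiple_R`, `shapiro_p`, `df_residual`
#' @export
hazard_regression <- function(data, formula, reference = NULL) {
  vars <- all.vars(formula)
  if (nrow(data) < length(vars) + 1L) stop("too few observations")
  for (v in names(reference)) {
    data[[v]] <- stats::relevel(factor(data[[v]]), ref = reference[[v]])
  }
  fit <- lm(formula, data = data)
  aliased <- is.na(stats::coef(fit))
  if (any(aliased)) {
    stop("rank-deficient design; aliased terms: ",
         paste(names(stats::coef(fit))[aliased], collapse = ", "))
  }
  s <- summary(fit)
  coefs <- data.frame(term = rownames(s$coefficients),
                      estimate = s$coefficients[, "Estimate"],
                      se = s$coefficients[, "Std. Error"],
                      t = s$coefficients[, "t value"],
                      p = s$coefficients[, "Pr(>|t|)"],
                      stringsAsFactors = FALSE, row.names = NULL)
  list(coefficients = coefs, multiple_R = sqrt(s$r.squared),
       shapiro_p = shapiro.test(stats::residuals(fit))$p.value,
       df_residual = fit$df.residual)
}

#' Paired t test
#'
#' Classical paired t on the within-pair differences, df = n - 1.
#'
#' @param a,b paired numeric vectors of equal length (n >= 2)
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`
#'   (direction of `mean(a - b)`)
#' @return list with `t`, `df`, `p`, `mean_difference`
#' @export
paired_t <- function(a, b, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(length(a) == length(b), length(a) >= 2L)
  d <- a - b
  n <- length(d)
  if (sd(d) == 0) {
    # identical pairs are a well-defined null result; a nonzero constant
    # difference leaves t undefined
    if (all(d == 0)) {
      return(list(t = 0, df = n - 1L, p = 1, mean_difference = 0))
    }
    stop("zero difference variance")
  }
  tstat <- mean(d) / (sd(d) / sqrt(n))
  p <- switch(alternative,
              two.sided = 2 * pt(abs(tstat), n - 1, lower.tail = FALSE),
              greater = pt(tstat, n - 1, lower.tail = FALSE),
              less = pt(tstat, n - 1))
  list(t = tstat, df = n - 1L, p = p, mean_difference = mean(d))
}

#' Read a delimited survival table
#'
#' Expected columns: `subject`, `group`, `day`, `event` (any order,
#' tab/comma/whitespace delimited with a header line).
#'
#' @param path file path
#' @param sep field separator; default tab
#' @return data.frame with columns `subject`, `group`, `time`, `event`
#' @export
read_survival_table <- function(path, sep = "\t") {
  x <- read.delim(path, sep = sep, stringsAsFactors = FALSE)
  need <- c("subject", "group", "day", "event")
  if (!all(need %in% names(x))) {
    stop("survival table needs columns: ", paste(need, collapse = ", "))
  }
  data.frame(subject = x$subject, group = x$group,
             time = as.integer(x$day), event = as.integer(x$event),
             stringsAsFactors = FALSE)
}
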