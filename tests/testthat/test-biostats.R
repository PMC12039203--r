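surv_df <- function(time, event) data.frame(time = time, event = event)

test_that("log-rank hazard ratio reproduces a hand-computed O/E table", {
  # treated: 2 deaths on day 1; control: 2 deaths on day 2
  # day 1: at risk 2/2, d = 2 -> E_t = 1, E_c = 1, O_t = 2
  # day 2: at risk 0/2, d = 2 -> E_c += 2, O_c = 2
  # HR = (2/1) / (2/3) = 3; chi2 = (2-1)^2/1 + (2-3)^2/3 = 4/3
  res <- logrank_hazard_ratio(surv_df(c(1, 1), c(1, 1)),
                              surv_df(c(2, 2), c(1, 1)))
  expect_equal(res$hazard_ratio, 3)
  expect_equal(res$chi_square, 4 / 3)
  expect_equal(unname(res$observed), c(2, 2))
  expect_equal(unname(res$expected), c(1, 3))
})

test_that("log-rank is null on identical groups and reciprocal on swap", {
  g <- gen_survival(40, c(t = 2), seed = 71)
  a <- g[g$group == "control", ]; b <- g[g$group == "t", ]
  same <- logrank_hazard_ratio(a, a)
  expect_equal(same$hazard_ratio, 1)
  expect_lt(same$chi_square, 1e-12)
  ab <- logrank_hazard_ratio(a, b); ba <- logrank_hazard_ratio(b, a)
  expect_equal(ab$hazard_ratio * ba$hazard_ratio, 1, tolerance = 1e-12)
})

test_that("observed/expected totals agree with survival::survdiff", {
  g <- gen_survival(60, c(t = 2.2), control_hazard = 0.08, seed = 72)
  treated <- g[g$group == "t", ]; control <- g[g$group == "control", ]
  res <- logrank_hazard_ratio(treated, control)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = g)
  # survdiff orders groups by factor level: control first
  expect_equal(unname(res$observed), unname(sd$obs[c(2, 1)]))
  expect_equal(unname(res$expected), unname(sd$exp[c(2, 1)]),
               tolerance = 1e-9)
  # one-tailed halves the p value in the excess-mortality direction
  res1 <- logrank_hazard_ratio(treated, control, one_tailed = TRUE)
  expect_equal(res1$p, res$p / 2)
})

test_that("log-rank errors on degenerate groups", {
  expect_error(logrank_hazard_ratio(surv_df(c(5, 5), c(0, 0)),
                                    surv_df(c(5, 5), c(0, 0))), "no events")
  # control fully censored before any treated death -> zero expected
  expect_error(logrank_hazard_ratio(surv_df(c(3, 3), c(1, 1)),
                                    surv_df(c(1, 1), c(0, 0))),
               "control")
})

gen_cox_data <- function(n, beta, seed, h0 = 0.05, max_day = 20) {
  with_seed_local <- function(seed, expr) {
    set.seed(seed); expr
  }
  with_seed_local(seed, {
    x <- rnorm(n)
    h <- 1 - (1 - h0)^exp(beta * x)
    day <- 1L + rgeom(n, h)
    event <- as.integer(day <= max_day)
    day[event == 0] <- max_day
    data.frame(time = day, event = event, x = x)
  })
}

test_that("cox_ph_fit recovers a known log-hazard coefficient", {
  d <- gen_cox_data(500, beta = 0.8, seed = 73)
  fit <- cox_ph_fit(d, "x")
  co <- fit$coefficients
  expect_lt(abs(co$beta - 0.8), 1.96 * co$se)
  expect_gt(fit$concordance, 0.6)
  # matches coxph directly (delegation contract)
  ref <- survival::coxph(survival::Surv(time, event) ~ x, data = d,
                         ties = "efron")
  expect_equal(co$beta, unname(coef(ref)), tolerance = 1e-9)
})

test_that("cox_ph_fit coefficient bias is small across seeds", {
  betas <- vapply(1:20, function(s) {
    d <- gen_cox_data(500, beta = 0.8, seed = 73 + s)
    cox_ph_fit(d, "x")$coefficients$beta
  }, 0)
  expect_lt(abs(mean(betas) - 0.8) / 0.8, 0.1)
})

test_that("an uninformative covariate gives concordance near 0.5", {
  d <- gen_cox_data(400, beta = 0, seed = 74)
  fit <- cox_ph_fit(d, "x")
  expect_lt(abs(fit$concordance - 0.5), 0.05)
  expect_true(fit$concordance_ci[1] < 0.5 & fit$concordance_ci[2] > 0.5)
})

test_that("constant covariates are dropped with a warning", {
  d <- gen_cox_data(100, beta = 0.5, seed = 75)
  d$flat <- 1
  expect_warning(fit <- cox_ph_fit(d, c("x", "flat")), "constant")
  row <- fit$coefficients[fit$coefficients$term == "flat", ]
  expect_equal(row$beta, 0)
  expect_true(row$dropped)
})

test_that("hazard_regression reproduces OLS and its diagnostics", {
  set.seed(76)
  n <- 40
  d <- data.frame(sirna_score = runif(n, 0, 100),
                  accessibility = runif(n),
                  region = sample(c("ORF", "UTR"), n, TRUE),
                  gene = sample(c("g1", "g2", "g3"), n, TRUE))
  d$hazard_ratio <- 2 + 0.05 * d$sirna_score + (d$region == "ORF") +
    rnorm(n, sd = 0.3)
  fml <- hazard_ratio ~ sirna_score + accessibility + region + gene
  res <- hazard_regression(d, fml, reference = list(gene = "g2"))
  ref <- lm(fml, data = transform(d, gene = relevel(factor(gene), "g2")))
  expect_equal(setNames(res$coefficients$estimate, res$coefficients$term),
               coef(ref), tolerance = 1e-12)
  expect_equal(res$multiple_R, sqrt(summary(ref)$r.squared))
  expect_equal(res$shapiro_p, shapiro.test(residuals(ref))$p.value)
  # normal equations oracle
  X <- model.matrix(fml, data = transform(d, gene = relevel(factor(gene),
                                                            "g2")))
  beta <- solve(t(X) %*% X, t(X) %*% d$hazard_ratio)
  expect_equal(res$coefficients$estimate, as.vector(beta), tolerance = 1e-9)
})

test_that("hazard_regression handles exact fits, nulls and rank deficiency", {
  set.seed(77)
  n <- 30
  d <- data.frame(x = runif(n), z = runif(n))
  d$y <- 1 + 2 * d$x - d$z
  expect_equal(suppressWarnings(hazard_regression(d, y ~ x + z)$multiple_R),
               1)

  d$y2 <- sample(d$y)  # permuted: no association
  big <- data.frame(x = runif(500))
  big$y <- rnorm(500)
  res <- hazard_regression(big, y ~ x)
  expect_lt(abs(res$coefficients$estimate[2]), 0.3)

  d$x2 <- d$x  # aliased
  expect_error(hazard_regression(d, y ~ x + x2), "aliased")
  expect_error(hazard_regression(d[1:2, ], y ~ x + z), "too few")
})

test_that("paired_t matches the hand formula and t.test", {
  a <- c(5, 7, 9, 11); b <- a - c(1, 2, 3, 4)
  res <- paired_t(a, b)
  d <- c(1, 2, 3, 4)
  expect_equal(res$t, mean(d) / (sd(d) / 2))
  expect_equal(res$df, 3)
  ref <- t.test(a, b, paired = TRUE)
  expect_equal(res$t, unname(ref$statistic))
  expect_equal(res$p, ref$p.value)

  same <- paired_t(a, a)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_error(paired_t(a, a - 2), "variance")
})

test_that("survival tables roundtrip through delimited text", {
  g <- gen_survival(10, c(hi = 2, lo = 1.2), seed = 78)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_survival_table(g, f)
  back <- read_survival_table(f)
  expect_equal(back$time, g$time)
  expect_equal(back$group, g$group)
  expect_equal(back$event, g$event)
})
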