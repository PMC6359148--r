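sim_binary_cohort <- function(n, beta, censor = 0.2, seed = 1) {
  set.seed(seed)
  x <- rbinom(n, 1, 0.5)
  t_event <- rexp(n, rate = 0.1 * exp(beta * x))
  cens <- runif(n) < censor
  data.frame(patient = sprintf("p%04d", 1:n),
             time = ifelse(cens, runif(n) * t_event, t_event),
             event = as.integer(!cens), x = x)
}

test_that("Kaplan-Meier matches the product-limit computation by hand", {
  km <- km_curve(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))
  # all censored: survival never drops
  km0 <- km_curve(c(1, 2, 3), c(0, 0, 0))
  expect_true(all(km0$surv == 1))
  # without censoring the curve is the empirical survival function
  set.seed(2)
  t <- rexp(40)
  km2 <- km_curve(t, rep(1, 40))
  emp <- vapply(km2$time, function(u) mean(t > u), 0)
  expect_equal(km2$surv, emp, tolerance = 1e-12)
})

test_that("log-rank is zero for identical groups and matches hand tabulation", {
  t <- c(1, 2, 3, 4)
  e <- c(1, 1, 0, 1)
  lr <- log_rank(c(t, t), c(e, e), rep(c("A", "B"), each = 4))
  expect_equal(lr$chi2, 0, tolerance = 1e-12)
  expect_equal(lr$p, 1, tolerance = 1e-12)

  # hand tabulation over the 4 distinct event times of A={1,2}, B={3,4}
  time <- c(1, 2, 3, 4)
  event <- c(1, 1, 1, 1)
  group <- c("A", "A", "B", "B")
  o_a <- 0; e_a <- 0; v <- 0
  for (tt in sort(unique(time[event == 1]))) {
    at_risk <- time >= tt
    n_tot <- sum(at_risk)
    n_a <- sum(at_risk & group == "A")
    d <- sum(time == tt & event == 1)
    d_a <- sum(time == tt & event == 1 & group == "A")
    o_a <- o_a + d_a
    e_a <- e_a + d * n_a / n_tot
    if (n_tot > 1) {
      v <- v + d * (n_a / n_tot) * (1 - n_a / n_tot) * (n_tot - d) / (n_tot - 1)
    }
  }
  expected_chi2 <- (o_a - e_a)^2 / v
  lr2 <- log_rank(time, event, group)
  expect_equal(lr2$chi2, expected_chi2, tolerance = 1e-9)
  # relabeling the groups changes nothing
  lr3 <- log_rank(time, event, rev(group))
  expect_equal(lr3$chi2, lr2$chi2, tolerance = 1e-12)
  expect_error(log_rank(time, c(0, 0, 0, 0), group), "no events")
})

test_that("Cox fitting recovers a planted binary effect and flags bad input", {
  d <- sim_binary_cohort(1000, log(2), seed = 8)
  fit <- cox_fit(d, "x")
  expect_true(fit$converged)
  expect_lt(abs(fit$beta[["x"]] - log(2)), 3 * fit$se[["x"]])
  # null covariate stays near zero
  d0 <- sim_binary_cohort(500, 0, seed = 6)
  fit0 <- cox_fit(d0, "x")
  expect_lt(abs(fit0$beta[["x"]]), 3 * fit0$se[["x"]])
  # degenerate designs are rejected
  d$const <- 1
  expect_error(cox_fit(d, "const"), "constant covariate")
  d$x2 <- 2 * d$x
  expect_error(cox_fit(d, c("x", "x2")), "collinear")
  d$event <- 0
  expect_error(cox_fit(d, "x"), "no events")
})

test_that("the Cox score test at beta = 0 equals the log-rank statistic", {
  d <- sim_binary_cohort(300, log(1.8), seed = 9)
  fit <- survival::coxph(survival::Surv(time, event) ~ x, data = d,
                         ties = "efron")
  score <- summary(fit)$sctest[["test"]]
  lr <- log_rank(d$time, d$event, d$x)
  expect_equal(score, lr$chi2, tolerance = 1e-6)
})

test_that("hazard ratio of the risk split is invariant to time rescaling", {
  d <- sim_binary_cohort(400, log(2), seed = 12)
  fit <- cox_fit(d, "x")
  p1 <- partition_and_test(fit, d)
  d2 <- d
  d2$time <- d2$time * 365.25
  p2 <- partition_and_test(cox_fit(d2, "x"), d2)
  expect_equal(p1$hazard_ratio, p2$hazard_ratio, tolerance = 1e-8)
  expect_equal(p1$log_rank_p, p2$log_rank_p, tolerance = 1e-8)
})

test_that("the prognostic index is the model's linear predictor", {
  d <- data.frame(patient = c("a", "b"), time = c(1, 2), event = c(1, 0),
                  g1 = c(2, 0), g2 = c(1, 4))
  expect_equal(prognostic_index(c(g1 = 0.5, g2 = -1), d), c(0, -4))
  expect_equal(prognostic_index(c(g1 = 0, g2 = 0), d), c(0, 0))
  expect_equal(prognostic_index(c(g1 = 1), d), d$g1)
  expect_error(prognostic_index(c(absent = 1), d), "absent")
})

test_that("median-PI partition separates a planted signature", {
  cfg <- sim_config(n_patients = 400, seed = 17)
  ex <- generate_expression(cfg)
  sv <- generate_survival(cfg, ex$truth)
  fit <- cox_fit(sv$survival)
  part <- partition_and_test(fit, sv$survival)
  expect_equal(sort(as.integer(table(part$partition$group))), c(200L, 200L))
  expect_lt(part$log_rank_p, 0.05)
  expect_gt(part$hazard_ratio, 1)
  # covariate t-tests: planted genes differ between risk groups
  expect_gt(mean(part$covariate_tests$significant), 0.5)
  # degenerate partition: identical PI cannot be split
  mdl <- structure(list(covariates = "g1", beta = c(g1 = 0)),
                   class = "cox_model")
  d <- data.frame(patient = letters[1:6], time = 1:6,
                  event = rep(1, 6), g1 = rep(2, 6))
  expect_error(partition_and_test(mdl, d), "cannot be split")
})

test_that("survival tables round-trip and are validated on read", {
  d <- sim_binary_cohort(20, log(2), seed = 3)
  path <- tempfile(fileext = ".tsv")
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_survival(path)
  expect_equal(back$time, d$time, tolerance = 1e-9)
  d$time[1] <- -1
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_survival(path), "non-positive")
})
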