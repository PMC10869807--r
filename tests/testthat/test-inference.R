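test_that("link choice follows the success-fraction policy", {
  d <- data.frame(presence = rep(c(0, 1), 50))
  expect_equal(suppressMessages(as.character(choose_link(d))), "logit")
  d_rare <- data.frame(presence = c(rep(0, 99), 1))
  expect_equal(suppressMessages(as.character(choose_link(d_rare, 0.1))),
               "cloglog")
  expect_equal(suppressMessages(as.character(choose_link(d_rare, 0))),
               "logit")
  expect_equal(attr(suppressMessages(choose_link(d)), "success_fraction"),
               0.5)
})

test_that("Nakagawa R2 reproduces closed-form component arithmetic", {
  # sigma2_f = 1, one random intercept of variance 1, logit
  r2 <- r2_nakagawa(sigma2_f = 1, sigma2_u = 1, link = "logit")
  expect_equal(unname(r2["marginal"]), 1 / (2 + pi^2 / 3), tolerance = 1e-12)
  expect_equal(unname(r2["conditional"]), 2 / (2 + pi^2 / 3),
               tolerance = 1e-12)
  expect_equal(unname(r2["marginal"]), 0.18904, tolerance = 1e-4)
  # no random variance: marginal equals conditional
  r2b <- r2_nakagawa(sigma2_f = 1, sigma2_u = 0, link = "logit")
  expect_equal(unname(r2b["marginal"]), unname(r2b["conditional"]))
  # intercept-only: marginal is zero
  r2c <- r2_nakagawa(sigma2_f = 0, sigma2_u = c(1, 0.5), link = "logit")
  expect_equal(unname(r2c["marginal"]), 0)
  # cloglog uses pi^2/6
  r2d <- r2_nakagawa(sigma2_f = 1, sigma2_u = 0, link = "cloglog")
  expect_equal(unname(r2d["marginal"]), 1 / (1 + pi^2 / 6), tolerance = 1e-12)
})

test_that("with negligible random variance the GLMM matches a plain GLM", {
  d <- sim_glmm_direct(40, 20, 4, beta0 = -0.5, beta1 = -0.6,
                       sds = c(0, 0, 0), seed = 31)
  fit <- suppressWarnings(fit_occurrence_glmm(d, "mpd_z"))
  glm_fit <- glm(presence ~ mpd_z, data = d, family = binomial())
  b_mixed <- fit$coefficients$estimate
  b_glm <- unname(coef(glm_fit))
  # within 2 joint standard errors of the plain logistic oracle
  expect_true(all(abs(b_mixed - b_glm) <
                    2 * summary(glm_fit)$coefficients[, 2]))
  expect_lt(sum(fit$ranef_var), 0.05)
  # with the variances forced to zero, the profiled mixed-model deviance is
  # minimized at the GLM solution and equals the GLM deviance
  dd <- lme4::glmer(presence ~ mpd_z + (1 | species) +
                      (1 | country / basin_id),
                    data = d, family = binomial(), devFunOnly = TRUE)
  theta0 <- rep(0, length(fit$ranef_var))
  expect_equal(dd(c(theta0, b_glm)), deviance(glm_fit), tolerance = 1e-8)
  opt <- optim(b_glm, function(b) dd(c(theta0, b)), method = "BFGS")
  expect_equal(opt$par, b_glm, tolerance = 1e-3)
})

test_that("degenerate designs and responses are rejected", {
  d <- sim_glmm_direct(20, 10, 2, -1, 0, seed = 1)
  d$const <- 1
  expect_error(fit_occurrence_glmm(d, "const"), "constant")
  d$presence <- 0L
  expect_error(fit_occurrence_glmm(d, "mpd_z"), "all-0")
})

test_that("adding a fixed predictor never decreases the log-likelihood", {
  d <- sim_glmm_direct(40, 16, 4, -1, -0.4, seed = 77)
  d$noise_z <- rnorm(nrow(d))
  f1 <- fit_occurrence_glmm(d, "mpd_z")
  f2 <- fit_occurrence_glmm(d, c("mpd_z", "noise_z"))
  expect_gte(f2$logLik, f1$logLik - 1e-6)
})

test_that("logit and cloglog fits agree in the sign of the relatedness effect", {
  sim <- simulate_database(sim_config(seed = 23))
  a <- classify_nonnatives(sim$db, "country")
  cl <- clean_database(sim$db, a, sim$tree)
  D <- cophenetic_distances(sim$tree)
  rec <- standardize_records(
    build_records(cl$db, classify_nonnatives(cl$db, "country"), D, "exotic"))
  b <- function(link) {
    f <- fit_occurrence_glmm(rec, "mpd_z", link = link)
    f$coefficients$estimate[f$coefficients$term == "mpd_z"]
  }
  expect_equal(sign(b("logit")), sign(b("cloglog")))
})

test_that("VIF matches its closed form and flags exact collinearity", {
  set.seed(3)
  n <- 400
  x1 <- rnorm(n); x1 <- (x1 - mean(x1)) / sd(x1)
  # residualize to make e exactly orthogonal to x1, then rescale to sd 1
  e <- residuals(lm(rnorm(n) ~ x1)); e <- e / sd(e)
  d <- data.frame(x1 = x1, x2 = e)
  v <- vif(d, c("x1", "x2"))
  expect_equal(unname(v), c(1, 1), tolerance = 1e-10)

  # exact sample correlation 0.8 -> VIF = 1/(1 - 0.64)
  d2 <- data.frame(x1 = x1, x2 = 0.8 * x1 + sqrt(1 - 0.64) * e)
  v2 <- vif(d2, c("x1", "x2"))
  expect_equal(unname(v2), rep(1 / (1 - 0.64), 2), tolerance = 1e-10)
  expect_equal(unname(v2)[1], 2.7778, tolerance = 1e-4)

  d3 <- data.frame(x1 = x1, x2 = 2 * x1, x3 = e)
  expect_true(is.infinite(
    suppressWarnings(vif(d3, c("x1", "x2", "x3")))["x1"]))
})

test_that("VIF agrees with the car implementation on random predictors", {
  skip_if_not_installed("car")
  set.seed(8)
  d <- as.data.frame(matrix(rnorm(300), ncol = 3))
  names(d) <- c("a", "b", "c")
  d$y <- rnorm(100)
  ours <- vif(d, c("a", "b", "c"))
  theirs <- car::vif(lm(y ~ a + b + c, data = d))
  expect_equal(unname(ours), unname(theirs[c("a", "b", "c")]),
               tolerance = 1e-10)
})

test_that("SEM reports the exact product rule and validates its inputs", {
  d <- sim_sem_direct(40, 16, 4, a_rich = -0.4, a_div = 0.2, b_rel = -0.6,
                      seed = 41)
  s <- suppressMessages(fit_sem(d, "mpd"))
  for (v in c("richness", "diversity")) {
    row <- s$indirect[s$indirect$from == v, ]
    expect_identical(row$estimate, row$path_a * row$path_b)
  }
  # paths into presence are the direct effects
  expect_setequal(s$direct$from, c("richness", "diversity"))
  # missing diversity column is a naming error
  d2 <- d; d2$native_mpd <- NULL
  expect_error(suppressMessages(fit_sem(d2, "mpd")), "native_mpd")
})

test_that("rows with undefined diversity are dropped with a message", {
  d <- sim_sem_direct(30, 12, 3, -0.4, 0, -0.6, seed = 51)
  d$native_mpd[d$basin_id == "b001"] <- NA
  expect_message(fit_sem(d, "mpd"), "dropped")
  s <- suppressMessages(fit_sem(d, "mpd"))
  expect_equal(s$n_dropped, sum(d$basin_id == "b001"))
  expect_equal(s$n, nrow(d) - s$n_dropped)
})

test_that("a null richness->relatedness path yields indirect effects near zero", {
  cover0 <- 0L
  n_rep <- 30
  for (i in seq_len(n_rep)) {
    d <- sim_sem_direct(40, 16, 4, a_rich = 0, a_div = -0.3, b_rel = -0.5,
                        seed = 600 + i)
    s <- suppressMessages(suppressWarnings(fit_sem(d, "mpd")))
    row <- s$indirect[s$indirect$from == "richness", ]
    if (row$lower <= 0 && 0 <= row$upper) cover0 <- cover0 + 1L
  }
  expect_gte(cover0, 26)  # ~ nominal 95% coverage of the true zero
})
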