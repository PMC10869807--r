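#' Choose the binomial link from the success fraction
#'
#' With many more establishment failures than successes the complementary
#' log-log link is preferred over the logit, as its asymmetry suits rare
#' events. The policy is a simple threshold on the observed success fraction.
#'
#' @param records data.frame with a `presence` column of 0/1.
#' @param threshold success fraction below which cloglog is chosen
#'   (default 0.10).
#' @return `"cloglog"` or `"logit"`; the observed fraction is attached as the
#'   `"success_fraction"` attribute and reported via `message()`.
#' @export
choose_link <- function(records, threshold = 0.10) {
  if (!"presence" %in% names(records)) stop("no 'presence' column")
  frac <- mean(records$presence)
  link <- if (frac < threshold) "cloglog" else "logit"
  message(sprintf("success fraction %.4f (threshold %.2f) -> %s link",
                  frac, threshold, link))
  structure(link, success_fraction = frac)
}

# distribution-specific variance of the latent residual (Nakagawa)
link_distribution_variance <- function(link) {
  switch(link,
         logit = pi^2 / 3,
         cloglog = pi^2 / 6,
         stop("unsupported link: ", link))
}

glmm_formula <- function(predictors, random) {
  re <- switch(random,
               nested = "(1 | species) + (1 | country/basin_id)",
               basin = "(1 | species) + (1 | basin_id)",
               stop("random must be 'nested' or 'basin'"))
  stats::as.formula(paste("presence ~",
                          paste(c(predictors, re), collapse = " + ")))
}

#' Fit the occurrence binomial mixed model
#'
#' Bernoulli GLMM for establishment success against relatedness (and optional
#' diversity/area covariates), with random intercepts for species and for
#' river basin nested in country (or basin alone for single-country fits),
#' estimated by Laplace-approximate maximum likelihood via `lme4::glmer`.
#'
#' @param records modeling table from [build_records()], with `_z` columns
#'   from [standardize_records()].
#' @param predictors character vector of fixed-effect column names
#'   (e.g. `"mpd_z"`; paper-style fits use a single relatedness predictor).
#' @param link `"logit"`, `"cloglog"`, or `"auto"` (delegate to
#'   [choose_link()]).
#' @param random `"nested"` for (1|species) + (1|country/basin), `"basin"`
#'   for (1|species) + (1|basin).
#' @param link_threshold passed to [choose_link()] when `link = "auto"`.
#' @return an object of class `occ_glmm`: list with `coefficients` (estimate,
#'   se, z, p per term), `ranef_var` (named variances), `r2` (marginal,
#'   conditional), `n`, `link`, `logLik`, `converged`, and the underlying
#'   `merMod` in `$fit`.
#' @export
fit_occurrence_glmm <- function(records, predictors = "mpd_z",
                                link = c("logit", "cloglog", "auto"),
                                random = c("nested", "basin"),
                                link_threshold = 0.10) {
  link <- match.arg(link)
  random <- match.arg(random)
  if (!all(predictors %in% names(records)))
    stop("missing predictor column(s): ",
         paste(setdiff(predictors, names(records)), collapse = ", "))
  y <- records$presence
  if (all(y == 0) || all(y == 1))
    stop("response is all-", y[1], "; both outcomes required")
  for (p in predictors)
    if (stats::sd(records[[p]], na.rm = TRUE) == 0)
      stop("predictor '", p, "' is constant (design not full rank)")
  if (link == "auto")
    link <- as.character(choose_link(records, link_threshold))

  use <- stats::complete.cases(records[, c("presence", predictors,
                                           "species", "basin_id", "country")])
  dat <- records[use, , drop = FALSE]
  form <- glmm_formula(predictors, random)
  fit <- suppressMessages(lme4::glmer(form, data = dat,
                                      family = stats::binomial(link = link)))
  res <- summarize_glmm(fit, link)
  res$n_dropped_na <- sum(!use)
  res
}

# shared extraction for glmer fits (internal)
summarize_glmm <- function(fit, link) {
  cf <- summary(fit)$coefficients
  coefs <- data.frame(term = rownames(cf), estimate = cf[, 1], se = cf[, 2],
                      z = cf[, 3], p = cf[, 4], row.names = NULL,
                      stringsAsFactors = FALSE)
  vc <- lme4::VarCorr(fit)
  rv <- vapply(vc, function(m) as.numeric(m[1, 1]), numeric(1))
  # a variance component on the zero boundary (singular fit) is a legitimate
  # optimum, not an optimizer failure; it is reported separately
  msgs <- fit@optinfo$conv$lme4$messages
  msgs <- msgs[!grepl("singular", msgs)]
  conv <- length(msgs) == 0 && fit@optinfo$conv$opt == 0
  out <- structure(list(fit = fit, coefficients = coefs, ranef_var = rv,
                        n = stats::nobs(fit), link = link,
                        logLik = as.numeric(stats::logLik(fit)),
                        converged = conv,
                        singular = lme4::isSingular(fit)),
                   class = "occ_glmm")
  out$r2 <- r2_nakagawa(out)
  out
}

#' @export
print.occ_glmm <- function(x, ...) {
  cat(sprintf("Binomial mixed model (%s link), n = %d%s\n", x$link, x$n,
              if (x$converged) "" else "  [convergence flagged]"))
  print(x$coefficients, digits = 4)
  cat("Random-intercept variances:\n")
  print(round(x$ranef_var, 4))
  cat(sprintf("R2 marginal = %.4f, conditional = %.4f\n",
              x$r2["marginal"], x$r2["conditional"]))
  invisible(x)
}

#' Marginal and conditional R-squared for a binomial mixed model
#'
#' Variance-decomposition R² after Nakagawa & Schielzeth: the marginal R² is
#' the fixed-effect variance over the total latent variance (fixed + summed
#' random-intercept variances + distribution variance, pi²/3 for logit and
#' pi²/6 for cloglog); the conditional R² adds the random-effect variance to
#' the numerator. The fixed-effect variance is the sample variance of the
#' fixed-effect linear predictor over the data.
#'
#' @param fit an `occ_glmm` from [fit_occurrence_glmm()], or `NULL` when
#'   supplying components directly.
#' @param sigma2_f,sigma2_u,link optional direct components: fixed-effect
#'   predictor variance, vector of random-intercept variances, link name.
#'   Used for closed-form checks.
#' @return named numeric vector `c(marginal =, conditional =)`.
#' @export
r2_nakagawa <- function(fit = NULL, sigma2_f = NULL, sigma2_u = NULL,
                        link = NULL) {
  if (!is.null(fit)) {
    if (!inherits(fit, "occ_glmm")) stop("not an 'occ_glmm' fit")
    X <- lme4::getME(fit$fit, "X")
    beta <- lme4::fixef(fit$fit)
    sigma2_f <- stats::var(as.numeric(X %*% beta))
    sigma2_u <- fit$ranef_var
    link <- fit$link
  }
  if (is.null(sigma2_f) || is.null(sigma2_u) || is.null(link))
    stop("supply a fit or all of sigma2_f, sigma2_u, link")
  s2d <- link_distribution_variance(link)
  tot <- sigma2_f + sum(sigma2_u) + s2d
  c(marginal = sigma2_f / tot,
    conditional = (sigma2_f + sum(sigma2_u)) / tot)
}

#' Variance inflation factors
#'
#' VIF_k = 1 / (1 - R²_k), where R²_k is from the ordinary least-squares
#' regression of predictor k on all other predictors. Exact collinearity is
#' reported as an infinite VIF, not an error.
#'
#' @param records data.frame containing the predictors.
#' @param predictors character vector of at least two column names.
#' @return named numeric vector of VIFs.
#' @export
vif <- function(records, predictors) {
  if (length(predictors) < 2) stop("need at least 2 predictors")
  X <- records[, predictors, drop = FALSE]
  X <- X[stats::complete.cases(X), , drop = FALSE]
  for (p in predictors)
    if (stats::sd(X[[p]]) == 0) stop("predictor '", p, "' is constant")
  out <- vapply(predictors, function(p) {
    f <- stats::as.formula(paste(p, "~",
                                 paste(setdiff(predictors, p), collapse = "+")))
    r2 <- summary(stats::lm(f, data = X))$r.squared
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  names(out) <- predictors
  out
}

#' Piecewise structural equation model for mediation through relatedness
#'
#' Decomposes the influence of native diversity on establishment into direct
#' paths and indirect paths mediated by nonnative-native relatedness, using
#' two component mixed models sharing the random-intercept structure of
#' [fit_occurrence_glmm()]:
#' \enumerate{
#'   \item Gaussian: `relatedness_z ~ richness_z + diversity_z + REs`
#'   \item Bernoulli: `presence ~ relatedness_z + richness_z + diversity_z + REs`
#' }
#' All continuous variables are z-scored over the rows entering the fit
#' (rows with undefined native diversity — basins with a single native — are
#' dropped first, with the count reported). Paths into the Bernoulli response
#' are on the latent (link) scale. Indirect effects are the product of the
#' path into relatedness and the relatedness -> presence path; the product
#' rule holds exactly by construction. Intervals are Wald 95%, with the
#' exact variance of a product of independent normals for the products.
#'
#' @param records modeling table from [build_records()].
#' @param diversity `"mpd"` (native MPD pairing) or `"mntd"`.
#' @param relatedness `"mpd"` or `"mntd"`; defaults to matching `diversity`.
#' @param link link for the Bernoulli component (`"logit"`, `"cloglog"`,
#'   `"auto"`).
#' @param random `"nested"` or `"basin"`, as in [fit_occurrence_glmm()].
#' @return object of class `sem_fit`: list with `paths` (term, from, to,
#'   estimate, se, lower, upper), `direct`, `indirect` (with product-normal intervals),
#'   `r2` per component, `n`, `n_dropped`, and the two component fits.
#' @export
fit_sem <- function(records, diversity = c("mpd", "mntd"),
                    relatedness = NULL,
                    link = c("logit", "cloglog", "auto"),
                    random = c("nested", "basin")) {
  diversity <- match.arg(diversity)
  link <- match.arg(link)
  random <- match.arg(random)
  if (is.null(relatedness)) relatedness <- diversity
  rel_col <- relatedness
  div_col <- paste0("native_", diversity)
  need <- c("presence", rel_col, "native_richness", div_col,
            "species", "basin_id", "country")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("missing column(s) for SEM: ", paste(miss, collapse = ", "))

  use <- stats::complete.cases(records[, need])
  n_dropped <- sum(!use)
  if (n_dropped > 0)
    message(n_dropped, " row(s) with undefined native diversity dropped")
  dat <- records[use, , drop = FALSE]
  if (nrow(dat) == 0) stop("no rows remain after dropping undefined diversity")

  zscore <- function(x) (x - mean(x)) / stats::sd(x)
  dat$.rel_z <- zscore(dat[[rel_col]])
  dat$.rich_z <- zscore(dat$native_richness)
  dat$.div_z <- zscore(dat[[div_col]])
  if (link == "auto") link <- as.character(choose_link(dat))

  re <- switch(random,
               nested = "(1 | species) + (1 | country/basin_id)",
               basin = "(1 | species) + (1 | basin_id)")
  f_rel <- stats::as.formula(paste(".rel_z ~ .rich_z + .div_z +", re))
  f_occ <- stats::as.formula(paste("presence ~ .rel_z + .rich_z + .div_z +", re))
  m_rel <- suppressMessages(suppressWarnings(
    lme4::lmer(f_rel, data = dat, REML = FALSE)))
  m_occ <- suppressMessages(lme4::glmer(
    f_occ, data = dat, family = stats::binomial(link = link)))

  path_tab <- function(fit, to, terms, labels) {
    cf <- summary(fit)$coefficients
    data.frame(from = labels, to = to,
               estimate = cf[terms, 1], se = cf[terms, 2],
               lower = cf[terms, 1] - 1.96 * cf[terms, 2],
               upper = cf[terms, 1] + 1.96 * cf[terms, 2],
               row.names = NULL, stringsAsFactors = FALSE)
  }
  p_rel <- path_tab(m_rel, "relatedness", c(".rich_z", ".div_z"),
                    c("richness", "diversity"))
  p_occ <- path_tab(m_occ, "presence", c(".rel_z", ".rich_z", ".div_z"),
                    c("relatedness", "richness", "diversity"))
  paths <- rbind(p_rel, p_occ)

  b_rel <- p_occ$estimate[p_occ$from == "relatedness"]
  se_b <- p_occ$se[p_occ$from == "relatedness"]
  indirect <- do.call(rbind, lapply(c("richness", "diversity"), function(v) {
    a <- p_rel$estimate[p_rel$from == v]
    se_a <- p_rel$se[p_rel$from == v]
    est <- a * b_rel
    # exact variance of a product of independent normals (Goodman);
    # the first-order (Sobel) variance omits the se_a^2 * se_b^2 term
    se <- sqrt(a^2 * se_b^2 + b_rel^2 * se_a^2 + se_a^2 * se_b^2)
    data.frame(from = v, estimate = est, se = se,
               lower = est - 1.96 * se, upper = est + 1.96 * se,
               path_a = a, path_b = b_rel, stringsAsFactors = FALSE)
  }))
  direct <- p_occ[p_occ$from %in% c("richness", "diversity"), , drop = FALSE]

  vc_rel <- lme4::VarCorr(m_rel)
  ru_rel <- vapply(vc_rel, function(m) as.numeric(m[1, 1]), numeric(1))
  s2f_rel <- stats::var(as.numeric(lme4::getME(m_rel, "X") %*%
                                     lme4::fixef(m_rel)))
  s2e_rel <- attr(vc_rel, "sc")^2
  r2_rel <- c(marginal = s2f_rel / (s2f_rel + sum(ru_rel) + s2e_rel),
              conditional = (s2f_rel + sum(ru_rel)) /
                (s2f_rel + sum(ru_rel) + s2e_rel))
  occ_sum <- summarize_glmm(m_occ, link)

  structure(list(paths = paths, direct = direct, indirect = indirect,
                 r2 = list(relatedness = r2_rel, presence = occ_sum$r2),
                 n = nrow(dat), n_dropped = n_dropped, link = link,
                 diversity = diversity, relatedness = relatedness,
                 fit_relatedness = m_rel, fit_presence = m_occ),
            class = "sem_fit")
}

#' @export
print.sem_fit <- function(x, ...) {
  cat(sprintf("Piecewise SEM (%s relatedness, native %s; %s link), n = %d\n",
              x$relatedness, x$diversity, x$link, x$n))
  cat("Paths:\n"); print(x$paths, digits = 3)
  cat("Indirect effects (through relatedness):\n")
  print(x$indirect[, c("from", "estimate", "lower", "upper")], digits = 3)
  invisible(x)
}
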