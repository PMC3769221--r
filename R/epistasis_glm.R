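# SNP-SNP interaction (epistasis) testing: logistic regression of case
# status on two allele-dosage terms and their product, with a
# likelihood-ratio test on the product term.

#' Fit a logistic regression by iteratively reweighted least squares
#'
#' Thin wrapper around the IRLS fitter in [stats::glm.fit()] that adds the
#' diagnostics the interaction test needs: a gradient-based convergence
#' check and detection of (quasi-)separation, flagged rather than raised.
#'
#' @param design Numeric covariate matrix (no intercept column; one is
#'   added).
#' @param outcome Binary 0/1 vector.
#' @param max_iter,tol IRLS control.
#' @return List of class `glm_fit`: `coefficients`, `standard_errors`,
#'   `log_likelihood`, `converged`, `separation`, `fitted`.
#' @export
fit_logistic <- function(design, outcome, max_iter = 100L, tol = 1e-10) {
  outcome <- as.numeric(outcome)
  if (!all(outcome %in% c(0, 1))) stop("outcome must be binary 0/1", call. = FALSE)
  if (length(unique(outcome)) < 2L) stop("constant outcome", call. = FALSE)
  X <- cbind(`(Intercept)` = 1, as.matrix(design))
  if (nrow(X) <= ncol(X)) stop("need more observations than covariates",
                               call. = FALSE)
  warned_sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(X, outcome, family = stats::binomial(),
                   control = stats::glm.control(maxit = max_iter,
                                                epsilon = tol)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        warned_sep <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  beta <- fit$coefficients
  mu <- fit$fitted.values
  grad <- drop(crossprod(X, outcome - mu))
  separation <- warned_sep || any(abs(beta) > 15)
  converged <- fit$converged && !separation && max(abs(grad)) < 1e-6
  W <- mu * (1 - mu)
  info <- crossprod(X * sqrt(W))
  se <- tryCatch(sqrt(diag(solve(info))), error = function(e)
    rep(NA_real_, length(beta)))
  names(se) <- names(beta)
  ll <- sum(outcome * log(pmax(mu, 1e-300)) +
              (1 - outcome) * log(pmax(1 - mu, 1e-300)))
  structure(list(coefficients = beta, standard_errors = se,
                 log_likelihood = ll, converged = converged,
                 separation = separation, fitted = mu),
            class = "glm_fit")
}

#' @export
print.glm_fit <- function(x, ...) {
  cat("logistic fit: logLik =", format(x$log_likelihood, digits = 6),
      if (x$separation) "(separation detected)" else
        if (!x$converged) "(NOT converged)" else "", "\n")
  print(round(rbind(beta = x$coefficients, se = x$standard_errors), 4))
  invisible(x)
}

#' Likelihood-ratio interaction test between two SNPs
#'
#' Fits case status on the two SNPs' genotype codings with and without a
#' product (interaction) term and compares them by a likelihood-ratio test
#' (1 df under additive coding). Additive coding is the minor-allele dosage
#' 0/1/2; dominant coding is carrier status 0/1. Samples missing either SNP
#' or a label are dropped.
#'
#' @param table A [genotype_table()].
#' @param snp_a,snp_b SNP ids.
#' @param labels A [cohort_labels()].
#' @param coding `"additive"` or `"dominant"`.
#' @return Test object with `statistic` (LRT), `df`, `p_value`, plus
#'   `beta_interaction`, `se_interaction` and the two `glm_fit`s.
#' @export
interaction_test <- function(table, snp_a, snp_b, labels,
                             coding = c("additive", "dominant")) {
  coding <- match.arg(coding)
  ia <- snp_index(table, snp_a); ib <- snp_index(table, snp_b)
  m <- match(labels$sample, table$samples)
  if (anyNA(m)) stop("labels refer to samples absent from the table",
                     call. = FALSE)
  da <- table$dosage[m, ia]; db <- table$dosage[m, ib]
  y <- as.integer(labels$status == "case")
  keep <- !is.na(da) & !is.na(db)
  da <- da[keep]; db <- db[keep]; y <- y[keep]
  if (coding == "dominant") { da <- as.integer(da > 0); db <- as.integer(db > 0) }
  X0 <- cbind(dose_a = da, dose_b = db)
  X1 <- cbind(X0, `dose_a:dose_b` = da * db)
  fit0 <- fit_logistic(X0, y)
  fit1 <- fit_logistic(X1, y)
  # collinear product column: glm.fit returns NA coefficient; LRT is 0
  df <- sum(!is.na(fit1$coefficients)) - sum(!is.na(fit0$coefficients))
  stat <- max(0, 2 * (fit1$log_likelihood - fit0$log_likelihood))
  p <- if (df < 1L) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  test_result(stat, max(df, 0L), p, "lrt",
              beta_interaction = unname(fit1$coefficients["dose_a:dose_b"]),
              se_interaction = unname(fit1$standard_errors["dose_a:dose_b"]),
              fit_full = fit1, fit_reduced = fit0, coding = coding,
              n_used = length(y))
}
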