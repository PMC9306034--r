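#' Multivariable logistic regression by IRLS
#'
#' Fits a binary logistic model by Newton-Raphson / iteratively reweighted
#' least squares: starting from zero coefficients, each step solves the
#' weighted least-squares system with weights `mu (1 - mu)` and working
#' response `eta + (y - mu) / w`, until the relative change in
#' log-likelihood falls below `tol`. Wald 95% intervals are
#' `exp(beta +/- 1.96 se)` with standard errors from the inverse observed
#' information at convergence. Both McFadden's pseudo-R-squared
#' (`1 - l/l0`) and Nagelkerke's rescaled Cox-Snell measure are reported,
#' with `l0` the intercept-only log-likelihood.
#'
#' The fit refuses to report estimates under perfect or quasi-perfect
#' separation (diverging linear predictor) and under a rank-deficient
#' design, naming the collinear columns.
#'
#' @param formula Model formula, e.g.
#'   `readmit_opd ~ sex + age_group + los_group + cssa + specialty_group +
#'   quality_high`; categorical terms should be factors with the intended
#'   reference level first (see [analysis_factors()]).
#' @param data Analysis tibble.
#' @param max_iter Maximum IRLS iterations (default 100).
#' @param tol Relative log-likelihood convergence tolerance (default 1e-10).
#' @return A `logistic_fit`: `coefficients`, `vcov`, `se`, `or_table`
#'   (tibble of terms with OR and Wald 95% CI), `loglik`, `loglik_null`,
#'   `r2_mcfadden`, `r2_nagelkerke`, `converged`, `n_iterations`, `n`,
#'   plus the design metadata used by [model_tables()].
#' @export
fit_logistic_irls <- function(formula, data, max_iter = 100, tol = 1e-10) {
  mf <- stats::model.frame(formula, data = data, drop.unused.levels = TRUE)
  y <- stats::model.response(mf)
  if (is.logical(y)) y <- as.integer(y)
  if (is.factor(y)) y <- as.integer(y) - 1L
  if (!all(y %in% c(0, 1))) {
    stop("outcome must be binary (0/1 or logical)", call. = FALSE)
  }
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  fit <- irls_engine(X, y, max_iter = max_iter, tol = tol)
  fit$terms <- attr(mf, "terms")
  fit$xlevels <- stats::.getXlevels(attr(mf, "terms"), mf)
  fit$assign <- attr(X, "assign")
  fit
}

# Core IRLS on an explicit design matrix (first column the intercept).
irls_engine <- function(X, y, max_iter = 100, tol = 1e-10) {
  n <- nrow(X)
  p <- ncol(X)
  qrX <- qr(X)
  if (qrX$rank < p) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):p]]
    stop("rank-deficient design: collinear column(s) ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }

  beta <- rep(0, p)
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    eta <- drop(X %*% beta)
    if (max(abs(eta)) > 30) {
      stop("perfect separation detected: the linear predictor diverged ",
           "(|eta| > 30); estimates are not reportable", call. = FALSE)
    }
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    z <- eta + (y - mu) / w
    wsq <- sqrt(w)
    fit_wls <- qr(X * wsq)
    beta <- qr.coef(fit_wls, z * wsq)
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    ll <- sum(y * log(mu) + (1 - y) * log1p(-mu))
    if (is.finite(ll_old) &&
        abs(ll - ll_old) < tol * (abs(ll_old) + tol)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    if (iter >= max_iter) break
  }
  if (max(abs(eta)) > 30) {
    stop("perfect separation detected: the linear predictor diverged ",
         "(|eta| > 30); estimates are not reportable", call. = FALSE)
  }

  w <- mu * (1 - mu)
  info <- crossprod(X * sqrt(w))
  vcov <- solve(info)
  dimnames(vcov) <- list(colnames(X), colnames(X))
  se <- sqrt(diag(vcov))
  names(beta) <- colnames(X)

  pbar <- mean(y)
  ll0 <- if (pbar %in% c(0, 1)) 0 else
    n * (pbar * log(pbar) + (1 - pbar) * log1p(-pbar))
  r2_mcf <- if (ll0 == 0) 0 else 1 - ll / ll0
  cox_snell <- 1 - exp((2 / n) * (ll0 - ll))
  r2_nag <- if (ll0 == 0) 0 else cox_snell / (1 - exp((2 / n) * ll0))

  z975 <- stats::qnorm(0.975)
  or_table <- tibble::tibble(
    term = colnames(X),
    estimate = unname(beta),
    se = unname(se),
    or = exp(unname(beta)),
    ci_low = exp(unname(beta) - z975 * unname(se)),
    ci_high = exp(unname(beta) + z975 * unname(se)))

  structure(list(coefficients = beta, vcov = vcov, se = se,
                 or_table = or_table, loglik = ll, loglik_null = ll0,
                 r2_mcfadden = r2_mcf, r2_nagelkerke = r2_nag,
                 converged = converged, n_iterations = iter, n = n,
                 fitted = mu),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, digits = 3, ...) {
  cat("<logistic_fit> n = ", x$n, ", logLik = ", format(x$loglik, digits = 6),
      ", iterations = ", x$n_iterations,
      if (!x$converged) " (NOT converged)", "\n", sep = "")
  tab <- x$or_table
  cat(sprintf("  %-28s %8s %18s\n", "term", "OR", "95% CI"))
  for (i in seq_len(nrow(tab))) {
    cat(sprintf("  %-28s %8.3f %9.3f-%-8.3f\n", tab$term[i], tab$or[i],
                tab$ci_low[i], tab$ci_high[i]))
  }
  cat(sprintf("  McFadden R2 = %.3f, Nagelkerke R2 = %.3f\n",
              x$r2_mcfadden, x$r2_nagelkerke))
  invisible(x)
}

#' Set analysis factor codings with the model reference levels
#'
#' Converts the derived covariates of the linked analysis table to factors
#' with the reference levels used throughout the adjusted models: male sex,
#' age 45-54, stay 1-3 days, no CSSA, "others" discharge specialty, and the
#' low level of each experience exposure ("Fair/Poor/Very poor" quality;
#' score below 8).
#'
#' @param linked Analysis tibble from [derive_covariates()].
#' @return The tibble with factor-coded `sex`, `age_group`, `los_group`,
#'   `cssa`, `specialty_group`, `quality_high`, `experience_high`.
#' @export
analysis_factors <- function(linked) {
  linked$sex <- factor(linked$sex, levels = c("male", "female"))
  linked$age_group <- factor(linked$age_group,
                             levels = c("45-54", "55-64", "65-74", "75+"))
  linked$los_group <- factor(linked$los_group,
                             levels = c("1-3 days", "4-7 days", "8+ days"))
  linked$cssa <- factor(ifelse(linked$cssa_flag, "yes", "no"),
                        levels = c("no", "yes"))
  linked$specialty_group <- factor(linked$specialty_group,
                                   levels = c("others", "medicine",
                                              "oncology", "surgery"))
  if ("quality_high" %in% names(linked)) {
    linked$quality_high <- factor(ifelse(linked$quality_high, "high", "low"),
                                  levels = c("low", "high"))
  }
  if ("experience_high" %in% names(linked)) {
    linked$experience_high <- factor(ifelse(linked$experience_high,
                                            ">=8", "<8"),
                                     levels = c("<8", ">=8"))
  }
  linked
}

#' Fit one adjusted readmission model
#'
#' Convenience wrapper fitting the multivariable logistic model of one
#' readmission outcome (`any`, `ae` or `opd`) on one experience exposure
#' (`quality` or `experience`), adjusted for sex, age group, length-of-stay
#' group, CSSA and discharge-specialty group.
#'
#' @param linked Analysis tibble ([derive_covariates()] output).
#' @param outcome One of `"any"`, `"ae"`, `"opd"`.
#' @param experience One of `"quality"`, `"experience"`.
#' @param ... Passed to [fit_logistic_irls()].
#' @return A `logistic_fit`.
#' @export
readmission_model <- function(linked, outcome = c("any", "ae", "opd"),
                              experience = c("quality", "experience"), ...) {
  outcome <- match.arg(outcome)
  experience <- match.arg(experience)
  dat <- analysis_factors(linked)
  lhs <- paste0("readmit_", outcome)
  rhs <- paste("sex", "age_group", "los_group", "cssa", "specialty_group",
               if (experience == "quality") "quality_high" else
                 "experience_high", sep = " + ")
  fit_logistic_irls(stats::as.formula(paste(lhs, "~", rhs)), dat, ...)
}

#' Render adjusted-OR model tables
#'
#' Lays three fitted models (any / A&E / outpatient readmission) side by
#' side in the conventional adjusted-OR table: one row per covariate level,
#' reference levels shown as `"Ref"`, each estimate formatted as
#' `"OR (low-high)"` with an asterisk when the 95% interval excludes 1.
#'
#' @param fits Named list of `logistic_fit` objects sharing one design
#'   (names become column headers).
#' @return Tibble with `variable`, `level` and one formatted column per fit.
#' @export
model_tables <- function(fits) {
  stopifnot(length(fits) >= 1, all(vapply(fits, inherits, TRUE, "logistic_fit")))
  f1 <- fits[[1]]
  if (is.null(f1$terms)) {
    stop("model_tables needs formula-based fits (design metadata missing)",
         call. = FALSE)
  }
  labels <- attr(f1$terms, "term.labels")
  rows <- list(tibble::tibble(variable = "(Intercept)", level = "",
                              term = "(Intercept)", ref = FALSE))
  for (v in labels) {
    levs <- f1$xlevels[[v]]
    if (is.null(levs)) {          # numeric covariate
      rows[[length(rows) + 1L]] <- tibble::tibble(
        variable = v, level = "", term = v, ref = FALSE)
    } else {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        variable = v, level = levs,
        term = c(NA_character_, paste0(v, levs[-1])),
        ref = c(TRUE, rep(FALSE, length(levs) - 1L)))
    }
  }
  layout <- dplyr::bind_rows(rows)

  fmt <- function(fit) {
    tab <- fit$or_table
    vapply(seq_len(nrow(layout)), function(i) {
      if (layout$ref[i]) return("Ref")
      j <- match(layout$term[i], tab$term)
      if (is.na(j)) return(NA_character_)
      star <- if (tab$ci_low[j] > 1 || tab$ci_high[j] < 1) "*" else ""
      sprintf("%.2f (%.2f-%.2f)%s", tab$or[j], tab$ci_low[j],
              tab$ci_high[j], star)
    }, character(1))
  }
  out <- layout[, c("variable", "level")]
  for (nm in names(fits)) out[[nm]] <- fmt(fits[[nm]])
  out
}
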