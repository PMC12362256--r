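#' Null-model fit for the kernel-machine (MiRKAT-style) engine
#'
#' Fits the outcome on covariates only — the null hypothesis of no
#' microbial effect — and returns the residuals (X minus the null fitted
#' values) and the
#' dispersion used to scale the score statistic. Continuous outcomes use a
#' least-squares fit with `phi` the residual variance; binary outcomes use
#' a logistic fit with `phi = 1` (score-test convention); survival outcomes
#' use a null proportional-hazards fit with martingale residuals and
#' `phi = 1`. These quantities depend only on the outcome side, so CAT
#' computes them once and reuses them across all permuted datasets.
#'
#' @param outcome An [outcome_spec] of kind continuous, binary or survival.
#' @param covariates Optional covariate data frame; defaults to the ones
#'   stored in the `outcome_spec`.
#' @return A list with `residuals`, `phi`, `kind`.
#' @export
mirkat_null_fit <- function(outcome, covariates = NULL) {
  if (!inherits(outcome, "outcome_spec")) {
    abort("outcome must be an outcome_spec")
  }
  covariates <- covariates %||% outcome$covariates
  kind <- outcome$kind
  if (kind == "categorical") {
    abort("the kernel engine supports continuous, binary or survival outcomes")
  }
  n <- length(outcome$values)
  df <- if (is.null(covariates)) {
    data.frame(row.names = seq_len(n))
  } else {
    as.data.frame(covariates)
  }
  if (kind == "continuous") {
    df$.y <- outcome$values
    fit <- lm(.y ~ ., data = df)
    r <- residuals(fit)
    phi <- sum(r^2) / fit$df.residual
  } else if (kind == "binary") {
    df$.y <- outcome$values
    fit <- tryCatch(
      glm(.y ~ ., data = df, family = binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1",
                  conditionMessage(w))) {
          abort(paste("perfect separation in the logistic null fit;",
                      "remove the offending covariate"))
        }
        suppressWarnings(glm(.y ~ ., data = df, family = binomial()))
      }
    )
    r <- outcome$values - stats::fitted(fit)
    phi <- 1
  } else { # survival
    surv <- survival::Surv(outcome$values, outcome$event)
    fit <- if (ncol(df) == 0) {
      survival::coxph(surv ~ 1)
    } else {
      survival::coxph(surv ~ ., data = df)
    }
    r <- residuals(fit, type = "martingale")
    phi <- 1
  }
  list(residuals = unname(r), phi = phi, kind = kind)
}

#' Kernel-machine score statistic and its scale-free R-squared analogue
#'
#' The score statistic of the variance-component test is the quadratic
#' form `Q = r' G r / (2 phi)` of the null-model residuals in the Gower
#' kernel. Its scale-free analogue `r2_kernel = r' G r / (tr(G) r'r)` is
#' the fraction of outcome-residual similarity explained by microbiome
#' similarity; it is invariant to rescaling either the residuals or the
#' distances, which makes it comparable across permuted datasets and
#' across metrics.
#'
#' @param r Residual vector from [mirkat_null_fit()].
#' @param phi Dispersion from the null fit.
#' @param g Gower-centered kernel matrix.
#' @return A list of class `kernel_score` with `q` and `r2_kernel`.
#' @export
mirkat_q <- function(r, phi, g) {
  r <- as.numeric(r)
  if (length(r) != nrow(g)) abort("residual length must match the kernel")
  tg <- sum(diag(g))
  rr <- sum(r^2)
  if (tg <= 0) abort("tr(G) must be positive")
  if (rr == 0) abort("residuals are identically zero")
  num <- drop(crossprod(r, g %*% r))
  structure(
    list(q = num / (2 * phi), r2_kernel = num / (tg * rr)),
    class = "kernel_score"
  )
}

#' @export
print.kernel_score <- function(x, ...) {
  cat(sprintf("<kernel_score> Q = %.4g, kernel R2 = %.4f\n",
              x$q, x$r2_kernel))
  invisible(x)
}

#' @rdname tidiers
#' @export
glance.kernel_score <- function(x, ...) {
  tibble::tibble(q = x$q, r2_kernel = x$r2_kernel)
}

#' Combine R-squared values across distance metrics
#'
#' When several metrics are in play, the per-dataset statistic is the
#' maximum R-squared over metrics; CAT applies this rule to the original
#' dataset and to each permuted dataset before differencing.
#'
#' @param r2_values Nonempty numeric vector of per-metric R-squared values
#'   computed on the same samples and outcome.
#' @return The maximum.
#' @export
max_over_metrics <- function(r2_values) {
  r2_values <- as.numeric(r2_values)
  if (length(r2_values) == 0) abort("no R-squared values supplied")
  max(r2_values)
}
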