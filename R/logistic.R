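# Univariate logistic calibration: probability of death as a function of a
# severity score, p = 1 / (1 + exp(-(b0 + b1 * x))), fitted by maximum
# likelihood via iteratively reweighted least squares.

#' Fit a univariate logistic mortality model
#'
#' Maximum-likelihood fit of `P(death | score) = 1 / (1 + exp(-(beta0 +
#' beta1 * score)))` by iteratively reweighted least squares (Newton
#' scoring). Initialisation is `beta = (logit(base rate), 0)`; convergence
#' is declared when the score (gradient) max-norm falls below `tol`.
#' Complete separation is detected up front and reported as an error naming
#' the direction, since the MLE does not exist there.
#'
#' @param scores numeric predictor (a severity score).
#' @param outcomes binary outcome: logical, 0/1 numeric, or a character
#'   vector of `"survived"`/`"died"` (died = 1).
#' @param tol convergence tolerance on the gradient max-norm.
#' @param max_iter maximum IRLS iterations.
#' @return object of class `logistic_fit`: `beta0`, `beta1`, `se_beta0`,
#'   `se_beta1`, `converged`, `iterations`, `log_likelihood`.
#' @examples
#' set.seed(1)
#' x <- rnorm(500, 5, 3)
#' y <- runif(500) < 1 / (1 + exp(-(-3 + 0.5 * x)))
#' fit_univariate_logistic(x, y)
#' @export
fit_univariate_logistic <- function(scores, outcomes, tol = 1e-8,
                                    max_iter = 50L) {
  y <- coerce_binary_outcome(outcomes)
  x <- as.numeric(scores)
  keep <- !(is.na(x) | is.na(y))
  x <- x[keep]; y <- y[keep]
  if (length(x) < 2L) validation_error("need at least two observations")
  if (all(y == 0) || all(y == 1)) {
    validation_error("outcomes contain a single class; logistic fit undefined")
  }
  if (min(x[y == 1]) > max(x[y == 0])) {
    eds_error(paste("complete separation: every positive score exceeds every",
                    "negative score (upward direction); MLE does not exist"),
              "edscores_separation_error")
  }
  if (max(x[y == 1]) < min(x[y == 0])) {
    eds_error(paste("complete separation: every positive score is below every",
                    "negative score (downward direction); MLE does not exist"),
              "edscores_separation_error")
  }

  X <- cbind(1, x)
  pbar <- mean(y)
  beta <- c(log(pbar / (1 - pbar)), 0)
  converged <- FALSE
  iter <- 0L
  H <- NULL
  while (iter < max_iter) {
    iter <- iter + 1L
    eta <- drop(X %*% beta)
    p <- 1 / (1 + exp(-eta))
    grad <- drop(crossprod(X, y - p))
    if (max(abs(grad)) < tol) {
      converged <- TRUE
      break
    }
    w <- p * (1 - p)
    H <- crossprod(X, X * w)
    if (!is.finite(rcond(H)) || rcond(H) < 1e-12) {
      eds_error("singular weight matrix in IRLS update",
                "edscores_singular_error")
    }
    beta <- beta + solve(H, grad)
  }
  eta <- drop(X %*% beta)
  p <- 1 / (1 + exp(-eta))
  w <- p * (1 - p)
  H <- crossprod(X, X * w)
  se <- sqrt(diag(solve(H)))
  ll <- sum(y * log(p) + (1 - y) * log1p(-p))
  structure(list(beta0 = beta[[1]], beta1 = beta[[2]],
                 se_beta0 = se[[1]], se_beta1 = se[[2]],
                 converged = converged, iterations = iter,
                 log_likelihood = ll),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf(
    "logistic fit: beta0 = %.4f (se %.4f), beta1 = %.4f (se %.4f)\n",
    x$beta0, x$se_beta0, x$beta1, x$se_beta1))
  cat(sprintf("  %s in %d iterations, log-likelihood %.4f\n",
              if (x$converged) "converged" else "NOT converged",
              x$iterations, x$log_likelihood))
  invisible(x)
}

#' Probability of death from a fitted logistic model
#'
#' Evaluates `p = 1 / (1 + exp(-(beta0 + beta1 * score)))`. Vectorised over
#' `score`.
#'
#' @param fit a [fit_univariate_logistic()] result (or any list with
#'   `beta0`, `beta1`).
#' @param score numeric score value(s).
#' @return predicted probabilities in (0, 1).
#' @examples
#' predict_probability(list(beta0 = -2, beta1 = 0.25), 8)  # 0.5
#' @export
predict_probability <- function(fit, score) {
  if (!is.finite(fit$beta0) || !is.finite(fit$beta1)) {
    validation_error("fit parameters must be finite")
  }
  1 / (1 + exp(-(fit$beta0 + fit$beta1 * score)))
}

coerce_binary_outcome <- function(outcomes) {
  if (is.logical(outcomes)) return(as.integer(outcomes))
  if (is.character(outcomes) || is.factor(outcomes)) {
    v <- as.character(outcomes)
    bad <- setdiff(unique(v[!is.na(v)]), OUTCOME_LEVELS)
    if (length(bad)) {
      validation_error(sprintf("unknown outcome labels: %s",
                               paste(bad, collapse = ", ")))
    }
    return(ifelse(is.na(v), NA_integer_, as.integer(v == "died")))
  }
  v <- as.numeric(outcomes)
  if (any(!is.na(v) & !(v %in% c(0, 1)))) {
    validation_error("numeric outcomes must be 0/1")
  }
  as.integer(v)
}
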