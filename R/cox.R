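# Partial-likelihood machinery for Cox proportional-hazards regression.
#
# cox_loglik returns the log partial likelihood, score vector and
# observed information at beta, with Breslow or Efron handling of tied
# death times.
cox_loglik <- function(time, status, X, beta, ties = "breslow") {
  k <- ncol(X)
  eta <- drop(X %*% beta)
  risk <- exp(eta)
  ev_times <- sort(unique(time[status == 1L]))
  ll <- 0
  U <- numeric(k)
  I <- matrix(0, k, k)
  for (t in ev_times) {
    Didx <- which(time == t & status == 1L)
    Ridx <- which(time >= t)
    d <- length(Didx)
    s0 <- sum(risk[Ridx])
    s1 <- drop(crossprod(X[Ridx, , drop = FALSE], risk[Ridx]))
    s2 <- crossprod(X[Ridx, , drop = FALSE],
                    X[Ridx, , drop = FALSE] * risk[Ridx])
    xd <- colSums(X[Didx, , drop = FALSE])
    if (ties == "breslow" || d == 1L) {
      ll <- ll + sum(eta[Didx]) - d * log(s0)
      U <- U + xd - d * s1 / s0
      I <- I + d * (s2 / s0 - tcrossprod(s1 / s0))
    } else {
      s0d <- sum(risk[Didx])
      s1d <- drop(crossprod(X[Didx, , drop = FALSE], risk[Didx]))
      s2d <- crossprod(X[Didx, , drop = FALSE],
                       X[Didx, , drop = FALSE] * risk[Didx])
      ll <- ll + sum(eta[Didx])
      for (l in seq_len(d) - 1L) {
        f <- l / d
        s0l <- s0 - f * s0d
        s1l <- s1 - f * s1d
        s2l <- s2 - f * s2d
        ll <- ll - log(s0l)
        U <- U + xd / d - s1l / s0l
        I <- I + s2l / s0l - tcrossprod(s1l / s0l)
      }
    }
  }
  list(loglik = ll, score = U, info = I)
}

# Per-subject score residuals for the sandwich variance,
# L_i = integral of (x_i - xbar(s)) dM_i(s) over the event times. With
# Efron ties each death time is split into d sub-steps whose risk set
# down-weights the tied deaths by l/d; Breslow uses the single full
# risk set (the two coincide without ties).
cox_score_residuals <- function(time, status, X, beta,
                                ties = "breslow") {
  k <- ncol(X)
  n <- nrow(X)
  risk <- exp(drop(X %*% beta))
  ev_times <- sort(unique(time[status == 1L]))
  L <- matrix(0, n, k)
  for (t in ev_times) {
    Didx <- which(time == t & status == 1L)
    Ridx <- which(time >= t)
    d <- length(Didx)
    s0 <- sum(risk[Ridx])
    s1 <- drop(crossprod(X[Ridx, , drop = FALSE], risk[Ridx]))
    if (ties == "breslow" || d == 1L) {
      xbar <- s1 / s0
      L[Didx, ] <- L[Didx, ] + sweep(X[Didx, , drop = FALSE], 2L, xbar)
      L[Ridx, ] <- L[Ridx, ] -
        sweep(X[Ridx, , drop = FALSE], 2L, xbar) * (risk[Ridx] * d / s0)
    } else {
      s0d <- sum(risk[Didx])
      s1d <- drop(crossprod(X[Didx, , drop = FALSE], risk[Didx]))
      xbar_sum <- numeric(k)
      for (l in seq_len(d) - 1L) {
        f <- l / d
        s0l <- s0 - f * s0d
        xbarl <- (s1 - f * s1d) / s0l
        xbar_sum <- xbar_sum + xbarl
        # hazard-increment part: tied deaths carry weight (1 - l/d)
        w <- rep(1, length(Ridx))
        w[Ridx %in% Didx] <- 1 - f
        L[Ridx, ] <- L[Ridx, ] -
          sweep(X[Ridx, , drop = FALSE], 2L, xbarl) *
            (risk[Ridx] * w / s0l)
      }
      L[Didx, ] <- L[Didx, ] +
        sweep(X[Didx, , drop = FALSE], 2L, xbar_sum / d)
    }
  }
  L
}

#' Fit a Cox proportional-hazards model
#'
#' Maximizes the Cox partial likelihood for the model
#' \eqn{h_i(t) = h_0(t) \exp(\beta_1 X_{i1} + \dots + \beta_k X_{ik})}
#' by Newton-Raphson from a zero start, with step-halving whenever a
#' step would decrease the likelihood. Model-based standard errors come
#' from the inverse observed information; with `robust = TRUE` the
#' sandwich (score-residual) variance estimator is reported alongside.
#' Tied death times are handled by the Breslow approximation by default,
#' or Efron's. The baseline hazard is not estimated; inference is on the
#' log hazard ratios only.
#'
#' @param data a [cox_dataset].
#' @param robust also compute sandwich standard errors.
#' @param ties `"breslow"` (default) or `"efron"`.
#' @param max_iter maximum Newton iterations.
#' @param tol convergence tolerance on the score (gradient) norm.
#' @return An object of class `cox_fit`: `beta`, `se_model`,
#'   `se_robust` (or `NULL`), `hazard_ratios`, `wald_z`, `wald_p`,
#'   `log_partial_likelihood`, `score_test` (the global score statistic
#'   at beta = 0), `converged`, `iter`, `n`, `n_events`.
#' @examples
#' d <- cox_dataset(time = c(2, 4, 5, 7, 9, 12),
#'                  status = c(1, 1, 0, 1, 1, 1),
#'                  covariates = cbind(dose = c(1, 1, 1, 0, 0, 0)))
#' fit_cox(d)
#' @export
fit_cox <- function(data, robust = FALSE, ties = c("breslow", "efron"),
                    max_iter = 50, tol = 1e-9) {
  stopifnot(inherits(data, "cox_dataset"))
  ties <- match.arg(ties)
  time <- data$time; status <- data$status; X <- data$covariates
  if (sum(status) < 1L) stop("no events: every subject is censored")
  if (any(apply(X, 2L, function(col) max(col) == min(col))))
    stop("collinear covariates: a risk factor is constant")
  k <- ncol(X)
  beta <- numeric(k)

  pl0 <- cox_loglik(time, status, X, beta, ties)
  info0_inv <- tryCatch(solve(pl0$info), error = function(e)
    stop("collinear covariates: singular information matrix"))
  score_test <- drop(crossprod(pl0$score, info0_inv %*% pl0$score))

  cur <- pl0
  converged <- FALSE
  iter <- 0L
  loglik_path <- cur$loglik
  while (iter < max_iter) {
    iter <- iter + 1L
    step <- tryCatch(solve(cur$info, cur$score), error = function(e)
      stop("collinear covariates: singular information matrix"))
    new_beta <- beta + step
    new <- cox_loglik(time, status, X, new_beta, ties)
    halvings <- 0L
    while (new$loglik < cur$loglik && halvings < 30L) {
      halvings <- halvings + 1L
      new_beta <- beta + step / 2^halvings
      new <- cox_loglik(time, status, X, new_beta, ties)
    }
    beta <- new_beta
    cur <- new
    loglik_path <- c(loglik_path, cur$loglik)
    if (max(abs(beta)) > 20)
      stop("complete separation of risk: a coefficient diverges ",
           "(the partial likelihood has no interior maximum)")
    if (sqrt(sum(cur$score^2)) < tol) { converged <- TRUE; break }
  }

  vcov_model <- tryCatch(solve(cur$info), error = function(e)
    stop("collinear covariates: singular information matrix"))
  se_model <- sqrt(diag(vcov_model))
  se_robust <- NULL
  if (robust) {
    L <- cox_score_residuals(time, status, X, beta, ties)
    D <- L %*% vcov_model                      # dfbeta residuals
    se_robust <- sqrt(diag(crossprod(D)))
  }
  se_wald <- if (robust) se_robust else se_model
  z <- beta / se_wald
  structure(list(beta = setNames(beta, colnames(X)),
                 se_model = setNames(se_model, colnames(X)),
                 se_robust = if (robust) setNames(se_robust, colnames(X)),
                 hazard_ratios = setNames(exp(beta), colnames(X)),
                 wald_z = z,
                 wald_p = 2 * pnorm(-abs(z)),
                 log_partial_likelihood = cur$loglik,
                 loglik_path = loglik_path,
                 score_test = score_test,
                 converged = converged, iter = iter, ties = ties,
                 robust = robust,
                 n = length(time), n_events = sum(status)),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, digits = 4, ...) {
  cat("Cox proportional-hazards fit (", x$ties, " ties), n = ", x$n,
      ", events = ", x$n_events, "\n", sep = "")
  tab <- data.frame(coef = round(x$beta, digits),
                    HR = round(x$hazard_ratios, digits),
                    se = round(x$se_model, digits))
  if (!is.null(x$se_robust)) tab$robust_se <- round(x$se_robust, digits)
  tab$z <- round(x$wald_z, 3)
  tab$p <- vapply(x$wald_p, format_pvalue, character(1))
  print(tab)
  if (!x$converged)
    cat("warning: Newton-Raphson did not converge in ", x$iter,
        " iterations\n", sep = "")
  invisible(x)
}

#' Coefficient table for a Cox fit
#'
#' @param fit a `cox_fit`.
#' @param file optional TSV path.
#' @return A data frame with one row per risk factor.
#' @export
cox_table <- function(fit, file = NULL) {
  out <- data.frame(
    factor = names(fit$beta), coef = unname(fit$beta),
    hazard_ratio = unname(fit$hazard_ratios),
    se_model = unname(fit$se_model),
    se_robust = if (!is.null(fit$se_robust)) unname(fit$se_robust)
                else NA_real_,
    wald_z = unname(fit$wald_z), p_value = unname(fit$wald_p))
  if (!is.null(file)) {
    utils::write.table(out, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(out))
  }
  out
}
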