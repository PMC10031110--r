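# Maximum-likelihood and full-information maximum-likelihood estimation.
#
# ML minimizes the normal-theory discrepancy
#   F(theta) = log|Sigma| + tr(S Sigma^-1) - log|S| - p
# by quasi-Newton iteration with analytic gradients; chi-square = n * F at
# the minimum (n = number of analyzed cases; the n vs n-1 convention is
# documented in the vignette and only enters MFI/ECVI through n).  FIML
# maximizes the casewise multivariate-normal log-likelihood of each row's
# observed subvector, with saturated (free) means.

ml_objective <- function(model, theta, S, logdetS) {
  Sigma <- implied_covariance(model, theta)
  ch <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(ch)) {
    ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
    return(1e6 + 1e4 * abs(min(ev)))
  }
  2 * sum(log(diag(ch))) + sum(S * chol2inv(ch)) - logdetS - nrow(S)
}

ml_gradient <- function(model, theta, S, logdetS) {
  Sigma <- implied_covariance(model, theta)
  ch <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(ch)) {  # numeric fallback in the penalized region
    h <- 1e-6
    return(vapply(seq_along(theta), function(k) {
      tp <- theta; tp[k] <- tp[k] + h
      tm <- theta; tm[k] <- tm[k] - h
      (ml_objective(model, tp, S, logdetS) -
         ml_objective(model, tm, S, logdetS)) / (2 * h)
    }, numeric(1)))
  }
  inv <- chol2inv(ch)
  G <- inv - inv %*% S %*% inv
  dS <- dSigma_dtheta(model, theta)
  vapply(dS, function(d) sum(G * d), numeric(1))
}

# central-difference Hessian of a gradient function
num_hessian <- function(grad_fn, theta, h = 1e-5) {
  q <- length(theta)
  H <- matrix(0, q, q)
  for (k in seq_len(q)) {
    hk <- h * (1 + abs(theta[k]))
    tp <- theta; tp[k] <- tp[k] + hk
    tm <- theta; tm[k] <- tm[k] - hk
    H[, k] <- (grad_fn(tp) - grad_fn(tm)) / (2 * hk)
  }
  (H + t(H)) / 2
}

# sample covariance with ML denominator n
ml_sample_cov <- function(data) {
  X <- as.matrix(data)
  n <- nrow(X)
  Xc <- sweep(X, 2, colMeans(X))
  crossprod(Xc) / n
}

baseline_stats <- function(S, n) {
  R <- stats::cov2cor(S)
  Fb <- -determinant(R, logarithm = TRUE)$modulus[1]
  p <- nrow(S)
  list(chisq = n * Fb, df = p * (p - 1) / 2)
}

#' Fit a structural equation model by maximum likelihood
#'
#' Minimizes the normal-theory discrepancy between the sample covariance
#' and the model-implied covariance. Supply either casewise `data` (complete
#' rows are analyzed, with the ML covariance denominator `n`) or a sample
#' covariance `sample_cov` with its `n`.
#'
#' @param model a `pubsem_model` from [parse_model()].
#' @param data data frame containing `model$obs` columns.
#' @param sample_cov covariance matrix (used if `data` is `NULL`).
#' @param n number of cases (required with `sample_cov`).
#' @param se `"naive"` (inverse observed information, default) or `"none"`.
#' @param check_id verify local identification at the start values.
#' @param start optional start vector.
#' @return object of class `pubsem_fit`: estimates, standard errors,
#'   log-likelihood, chi-square and degrees of freedom, fit indices
#'   (CFI/MFI/ECVI/SRMR), convergence diagnostics, and a flag for improper
#'   (Heywood) solutions.
#' @export
ml_fit <- function(model, data = NULL, sample_cov = NULL, n = NULL,
                   se = c("naive", "none"), check_id = TRUE, start = NULL) {
  se <- match.arg(se)
  if (!is.null(data)) {
    miss <- setdiff(model$obs, names(data))
    if (length(miss)) stop("data lacks columns: ", paste(miss, collapse = ", "))
    X <- data[, model$obs, drop = FALSE]
    cc <- complete.cases(X)
    if (!all(cc)) X <- X[cc, , drop = FALSE]
    n <- nrow(X)
    S <- ml_sample_cov(X)
  } else {
    if (is.null(sample_cov) || is.null(n))
      stop("supply either data, or sample_cov together with n")
    S <- as.matrix(sample_cov)[model$obs, model$obs, drop = FALSE]
  }
  p <- length(model$obs)
  if (n <= p) stop("n must exceed the number of observed variables")
  ch <- tryCatch(chol(S), error = function(e)
    stop("sample covariance is not positive definite"))
  logdetS <- 2 * sum(log(diag(ch)))

  theta0 <- if (is.null(start)) start_values(model, S) else start
  if (check_id) {
    id <- check_identification(model)
    if (!isTRUE(id))
      stop("model is not locally identified (Jacobian rank ", attr(id, "rank"),
           " < ", model$nfree, " free parameters)")
  }

  obj <- function(th) ml_objective(model, th, S, logdetS)
  gr <- function(th) ml_gradient(model, th, S, logdetS)
  opt <- nlminb(theta0, obj, gradient = gr,
                control = list(iter.max = 1000, eval.max = 2000,
                               rel.tol = 1e-12))
  if (max(abs(gr(opt$par))) > 1e-6) {  # polish with BFGS restarts
    for (i in 1:3) {
      pol <- optim(opt$par, obj, gr, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-14))
      if (pol$value <= opt$objective) opt[c("par", "objective")] <-
          list(pol$par, pol$value)
      if (max(abs(gr(opt$par))) < 1e-6) break
    }
  }
  if (max(abs(gr(opt$par))) > 1e-4) {   # last resort: fresh start
    opt2 <- nlminb(0.5 * theta0 + 0.1, obj, gradient = gr,
                   control = list(iter.max = 1000, eval.max = 2000,
                                  rel.tol = 1e-12))
    if (opt2$objective < opt$objective) opt <- opt2
  }
  theta <- setNames(opt$par, model$labels)
  gnorm <- max(abs(gr(theta)))
  converged <- gnorm < 1e-4

  Fmin <- max(opt$objective, 0)
  Sigma <- implied_covariance(model, theta)
  chisq <- n * Fmin
  df <- model_df(model)
  base <- baseline_stats(S, n)
  fi <- fit_indices(chisq, df, n, model$nfree, base$chisq, base$df, S, Sigma)
  loglik <- -n / 2 * (p * log(2 * pi) + as.numeric(
    determinant(Sigma, logarithm = TRUE)$modulus) +
      sum(S * solve(Sigma)))

  H <- num_hessian(gr, theta)
  vcov <- tryCatch((2 / n) * solve(H), error = function(e) NULL)
  se_naive <- if (se == "naive" && !is.null(vcov)) {
    d <- diag(vcov)
    sqrt(pmax(d, 0))
  } else NULL

  fit <- structure(list(
    model = model, estimator = "ML", theta = theta, se = se_naive,
    vcov = vcov, information = (n / 2) * H,
    n = n, p = p, q = model$nfree, df = df,
    F_min = Fmin, chisq = chisq, loglik = loglik,
    Sigma = Sigma, S = S, means = NULL,
    baseline = base, fit_indices = fi,
    converged = converged, iterations = opt$iterations,
    gradient_norm = gnorm), class = "pubsem_fit")
  fit$heywood <- has_heywood(fit)
  if (!converged)
    warning("ML fit did not converge (gradient norm ", signif(gnorm, 3), ")")
  if (fit$heywood)
    warning("improper (Heywood) solution: negative residual variance or |standardized loading| > 1")
  fit
}

has_heywood <- function(fit) {
  tab <- fit$model$params
  est <- ifelse(tab$free, fit$theta[tab$theta], tab$value)
  resvar <- tab$mat == "S" & tab$row == tab$col & tab$row %in% fit$model$obs
  if (any(est[resvar] < 0)) return(TRUE)
  std <- standardize(fit)
  ld <- std$mat == "A"
  any(abs(std$std[ld]) > 1 + 1e-8)
}

#' @export
print.pubsem_fit <- function(x, ...) {
  cat(sprintf("%s fit: %d cases, %d observed variables, %d free parameters\n",
              x$estimator, x$n, x$p, x$q))
  if (!is.na(x$chisq))
    cat(sprintf("  chi-square %.3f on %d df\n", x$chisq, x$df))
  if (!is.null(x$fit_indices) && !any(is.na(unlist(x$fit_indices))))
    cat(sprintf("  CFI %.3f  MFI %.3f  ECVI %.3f  SRMR %.4f\n",
                x$fit_indices$CFI, x$fit_indices$MFI,
                x$fit_indices$ECVI, x$fit_indices$SRMR))
  cat("  converged:", x$converged,
      " gradient norm:", signif(x$gradient_norm, 3), "\n")
  invisible(x)
}

#' Parameter table of a fit
#'
#' @param fit a `pubsem_fit`.
#' @return data frame with one row per model parameter: matrix, variables,
#'   label, estimate, standard error (free parameters only) and the
#'   standardized estimate.
#' @export
parameter_table <- function(fit) {
  tab <- fit$model$params
  est <- ifelse(tab$free, fit$theta[tab$theta], tab$value)
  se <- rep(NA_real_, nrow(tab))
  if (!is.null(fit$se)) se[tab$free] <- fit$se[tab$theta[tab$free]]
  std <- standardize(fit)
  data.frame(mat = tab$mat, lhs = tab$row, rhs = tab$col, label = tab$label,
             free = tab$free, est = est, se = se, std = std$std,
             stringsAsFactors = FALSE)
}

# ---------------------------------------------------------------------------
# FIML

missing_patterns <- function(X) {
  obs <- !is.na(X)
  key <- apply(obs, 1, paste, collapse = "")
  split(seq_len(nrow(X)), key)
}

#' Casewise (full-information) multivariate-normal log-likelihood
#'
#' Sums, over the rows of `data`, the log-density of each row's observed
#' subvector under the row-specific marginalization of the model-implied
#' covariance and the supplied mean vector. With complete data this equals
#' the complete-data normal log-likelihood.
#'
#' @param model a `pubsem_model`.
#' @param theta free-parameter vector for the covariance structure.
#' @param data data frame with `model$obs` columns; missing cells allowed,
#'   but every row must have at least one observed cell.
#' @param means named mean vector over the observed variables; defaults to
#'   available-case column means.
#' @return scalar log-likelihood.
#' @export
fiml_loglik <- function(model, theta, data, means = NULL) {
  X <- as.matrix(data[, model$obs, drop = FALSE])
  if (any(rowSums(!is.na(X)) == 0))
    stop("every row must have at least one observed cell")
  if (is.null(means)) means <- colMeans(X, na.rm = TRUE)
  if (!is.null(names(means))) means <- means[model$obs]
  Sigma <- implied_covariance(model, theta)
  fiml_loglik_mat(X, means, Sigma)
}

fiml_loglik_mat <- function(X, mu, Sigma) {
  ll <- 0
  for (rows in missing_patterns(X)) {
    idx <- which(!is.na(X[rows[1], ]))
    Sg <- Sigma[idx, idx, drop = FALSE]
    ch <- tryCatch(chol(Sg), error = function(e)
      stop("row-specific covariance submatrix is singular"))
    inv <- chol2inv(ch)
    cent <- sweep(X[rows, idx, drop = FALSE], 2, mu[idx])
    quad <- rowSums((cent %*% inv) * cent)
    ll <- ll - 0.5 * (length(rows) *
                        (length(idx) * log(2 * pi) + 2 * sum(log(diag(ch)))) +
                        sum(quad))
  }
  ll
}

# negative loglik and analytic gradient for (theta, nu)
fiml_obj_gr <- function(model, par, X, patterns, want_grad = TRUE) {
  q <- model$nfree
  p <- ncol(X)
  theta <- par[seq_len(q)]
  mu <- par[q + seq_len(p)]
  Sigma <- implied_covariance(model, theta)
  ll <- 0
  Macc <- matrix(0, p, p)
  gmu <- numeric(p)
  for (rows in patterns) {
    idx <- which(!is.na(X[rows[1], ]))
    Sg <- Sigma[idx, idx, drop = FALSE]
    ch <- tryCatch(chol(Sg), error = function(e) NULL)
    if (is.null(ch)) return(list(obj = 1e10, grad = rep(0, length(par))))
    inv <- chol2inv(ch)
    cent <- sweep(X[rows, idx, drop = FALSE], 2, mu[idx])
    CI <- cent %*% inv
    ll <- ll - 0.5 * (length(rows) *
                        (length(idx) * log(2 * pi) + 2 * sum(log(diag(ch)))) +
                        sum(CI * cent))
    if (want_grad) {
      W <- crossprod(cent)
      Macc[idx, idx] <- Macc[idx, idx] + length(rows) * inv - inv %*% W %*% inv
      gmu[idx] <- gmu[idx] + colSums(CI)
    }
  }
  grad <- NULL
  if (want_grad) {
    dS <- dSigma_dtheta(model, theta)
    gtheta <- vapply(dS, function(d) 0.5 * sum(Macc * d), numeric(1))
    grad <- c(gtheta, -gmu)   # gradient of the NEGATIVE loglik
  }
  list(obj = -ll, grad = grad)
}

# EM for the saturated multivariate-normal (mu, Sigma) with missing data;
# used for the FIML chi-square's saturated log-likelihood
em_mvnorm <- function(X, max_iter = 500, tol = 1e-10) {
  p <- ncol(X)
  mu <- colMeans(X, na.rm = TRUE)
  Sigma <- cov(X, use = "pairwise.complete.obs")
  Sigma[is.na(Sigma)] <- 0
  diag(Sigma)[is.na(diag(Sigma)) | diag(Sigma) <= 0] <- 1
  ev <- eigen((Sigma + t(Sigma)) / 2, symmetric = TRUE)
  Sigma <- ev$vectors %*% diag(pmax(ev$values, 1e-6), p) %*% t(ev$vectors)
  n <- nrow(X)
  pats <- missing_patterns(X)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    Ex <- matrix(0, n, p)
    Exx <- matrix(0, p, p)
    for (rows in pats) {
      o <- which(!is.na(X[rows[1], ])); m <- setdiff(seq_len(p), o)
      Xo <- X[rows, o, drop = FALSE]
      Ex[rows, o] <- Xo
      if (length(m)) {
        inv <- solve(Sigma[o, o, drop = FALSE])
        beta <- Sigma[m, o, drop = FALSE] %*% inv
        cond <- sweep(Xo, 2, mu[o])
        Ex[rows, m] <- matrix(mu[m], length(rows), length(m), byrow = TRUE) +
          cond %*% t(beta)
        C <- Sigma[m, m, drop = FALSE] -
          Sigma[m, o, drop = FALSE] %*% inv %*% Sigma[o, m, drop = FALSE]
        Exx[m, m] <- Exx[m, m] + length(rows) * C
      }
    }
    Exx <- Exx + crossprod(Ex)
    mu <- colMeans(Ex)
    Sigma <- Exx / n - tcrossprod(mu)
    Sigma <- (Sigma + t(Sigma)) / 2
    ll <- fiml_loglik_mat(X, mu, Sigma)
    if (abs(ll - ll_old) < tol * (abs(ll) + 1)) break
    ll_old <- ll
  }
  list(mu = mu, Sigma = Sigma, loglik = ll)
}

# independence baseline with missing data: univariate ML per column
fiml_baseline_loglik <- function(X) {
  sum(vapply(seq_len(ncol(X)), function(j) {
    x <- X[, j]; x <- x[!is.na(x)]
    v <- mean((x - mean(x))^2)
    -length(x) / 2 * (log(2 * pi) + log(v) + 1)
  }, numeric(1)))
}

#' Fit a structural equation model by full-information maximum likelihood
#'
#' Maximizes the casewise log-likelihood over the covariance-structure
#' parameters and saturated (free) means, handling missing cells without
#' imputation. The chi-square compares the model to the saturated
#' multivariate normal (estimated by EM when data are incomplete); the
#' baseline for CFI is the independence model with free variances and means.
#'
#' @inheritParams ml_fit
#' @param data data frame with `model$obs` columns; `NA`s allowed.
#' @return a `pubsem_fit`; `fit$means` holds the estimated means.
#' @export
fiml_fit <- function(model, data, se = c("naive", "none"), check_id = TRUE,
                     start = NULL) {
  se <- match.arg(se)
  X <- as.matrix(data[, model$obs, drop = FALSE])
  storage.mode(X) <- "double"
  empty <- rowSums(!is.na(X)) == 0
  if (any(empty)) {
    warning(sum(empty), " row(s) with no observed cell dropped")
    X <- X[!empty, , drop = FALSE]
  }
  n <- nrow(X); p <- ncol(X)
  patterns <- missing_patterns(X)

  S0 <- cov(X, use = "pairwise.complete.obs")
  S0[is.na(S0)] <- 0
  theta0 <- if (is.null(start)) start_values(model, S0) else start
  if (check_id && !isTRUE(check_identification(model)))
    stop("model is not locally identified")
  par0 <- c(theta0, colMeans(X, na.rm = TRUE))

  obj <- function(par) fiml_obj_gr(model, par, X, patterns, FALSE)$obj
  gr <- function(par) fiml_obj_gr(model, par, X, patterns, TRUE)$grad
  opt <- nlminb(par0, obj, gradient = gr,
                control = list(iter.max = 1000, eval.max = 2000))
  par <- opt$par
  gnorm <- max(abs(gr(par)))
  converged <- opt$convergence == 0 && gnorm < 1e-3 * (1 + abs(opt$objective))

  theta <- setNames(par[seq_len(model$nfree)], model$labels)
  mu <- setNames(par[model$nfree + seq_len(p)], model$obs)
  loglik <- -opt$objective
  Sigma <- implied_covariance(model, theta)

  complete <- all(!is.na(X))
  if (complete) {
    S_for_srmr <- ml_sample_cov(X)
    sat_ll <- -n / 2 * (p * log(2 * pi) +
                as.numeric(determinant(S_for_srmr, logarithm = TRUE)$modulus) + p)
  } else {
    em <- em_mvnorm(X)
    S_for_srmr <- em$Sigma
    sat_ll <- em$loglik
  }
  chisq <- max(2 * (sat_ll - loglik), 0)
  df <- model_df(model)   # saturated means cancel in the df count
  base_ll <- fiml_baseline_loglik(X)
  base <- list(chisq = max(2 * (sat_ll - base_ll), 0), df = p * (p - 1) / 2)
  fi <- fit_indices(chisq, df, n, model$nfree, base$chisq, base$df,
                    S_for_srmr, Sigma)

  H <- num_hessian(gr, par)
  vcov_all <- tryCatch(solve(H), error = function(e) NULL)
  se_naive <- if (se == "naive" && !is.null(vcov_all))
    sqrt(pmax(diag(vcov_all)[seq_len(model$nfree)], 0)) else NULL

  fit <- structure(list(
    model = model, estimator = "FIML", theta = theta, se = se_naive,
    vcov = if (!is.null(vcov_all))
      vcov_all[seq_len(model$nfree), seq_len(model$nfree), drop = FALSE]
    else NULL,
    information = H, n = n, p = p, q = model$nfree, df = df,
    F_min = chisq / n, chisq = chisq, loglik = loglik,
    Sigma = Sigma, S = S_for_srmr, means = mu,
    baseline = base, fit_indices = fi,
    converged = converged, iterations = opt$iterations,
    gradient_norm = gnorm), class = "pubsem_fit")
  fit$heywood <- has_heywood(fit)
  if (!converged)
    warning("FIML fit did not converge (gradient norm ", signif(gnorm, 3), ")")
  fit
}
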