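# Fit indices, standardized solutions, model comparison, robust standard
# errors and the mean-scaled chi-square.

#' Model fit indices
#'
#' Computes the four indices used for model comparison:
#' \describe{
#'   \item{CFI}{`1 - max(chisq - df, 0) / max(chisq_b - df_b, chisq - df, 0)`,
#'     against the independence baseline.}
#'   \item{MFI}{McDonald's noncentrality index `exp(-(chisq - df) / (2n))`.}
#'   \item{ECVI}{expected cross-validation index `(chisq + 2q) / n`.}
#'   \item{SRMR}{root mean square of the correlation-metric residuals of the
#'     sample versus implied covariance over the unique elements, diagonal
#'     included.}
#' }
#'
#' @param chisq,df model discrepancy statistic and degrees of freedom.
#' @param n analyzed sample size.
#' @param q number of free parameters.
#' @param chisq_baseline,df_baseline independence-model statistic/df.
#' @param S,Sigma_hat sample and implied covariance (for SRMR; optional).
#' @return list with components `CFI`, `MFI`, `ECVI`, `SRMR`.
#' @export
#' @examples
#' fi <- fit_indices(50, 10, 100, 20, 500, 45)
#' round(c(fi$CFI, fi$MFI, fi$ECVI), 4)  # 0.9121 0.8187 0.9000
fit_indices <- function(chisq, df, n, q, chisq_baseline, df_baseline,
                        S = NULL, Sigma_hat = NULL) {
  num <- max(chisq - df, 0)
  den <- max(chisq_baseline - df_baseline, chisq - df, 0)
  cfi <- if (den <= 0) 1 else 1 - num / den
  mfi <- exp(-(chisq - df) / (2 * n))
  ecvi <- (chisq + 2 * q) / n
  srmr <- NA_real_
  if (!is.null(S) && !is.null(Sigma_hat)) {
    d <- sqrt(diag(S))
    resid <- (S - Sigma_hat) / tcrossprod(d)
    srmr <- sqrt(mean(resid[lower.tri(resid, diag = TRUE)]^2))
  }
  list(CFI = cfi, MFI = mfi, ECVI = ecvi, SRMR = srmr)
}

#' Standardized solution
#'
#' Rescales every path and (co)variance so that all observed and latent
#' variables have unit variance: a path from j to i is multiplied by
#' `sqrt(V_jj / V_ii)` and a covariance divided by `sqrt(V_ii V_jj)`, where
#' `V` is the model-implied covariance over all variables. Loadings and
#' latent correlations are then on the familiar standardized scale.
#'
#' @param fit a `pubsem_fit`.
#' @return data frame: `mat`, `lhs`, `rhs`, `label`, `est`, `std`.
#' @export
standardize <- function(fit) {
  model <- fit$model
  tab <- model$params
  est <- ifelse(tab$free, fit$theta[tab$theta], tab$value)
  V <- implied_cov_all(model, fit$theta)$V
  sdv <- sqrt(pmax(diag(V), .Machine$double.eps))
  names(sdv) <- model$all
  if (any(diag(V) <= 0))
    warning("zero or negative implied variance; standardization is undefined there")
  std <- numeric(nrow(tab))
  for (k in seq_len(nrow(tab))) {
    i <- tab$row[k]; j <- tab$col[k]
    std[k] <- if (tab$mat[k] == "A") est[k] * sdv[j] / sdv[i]
    else est[k] / (sdv[i] * sdv[j])
  }
  data.frame(mat = tab$mat, lhs = tab$row, rhs = tab$col, label = tab$label,
             est = est, std = std, stringsAsFactors = FALSE)
}

# standardized covariance/correlation between two variables (either order)
std_covariance <- function(fit, a, b) {
  V <- implied_cov_all(fit$model, fit$theta)$V
  V[a, b] / sqrt(V[a, a] * V[b, b])
}

#' Compare fitted models
#'
#' Tabulates chi-square, df and the four fit indices for a set of fits on
#' the same data, flags the model favoured by each index, and, for each
#' consecutive pair (ordered as supplied), reports the chi-square difference
#' with its degrees of freedom and reference-distribution tail probability.
#'
#' @param ... `pubsem_fit` objects, or a single list of them.
#' @param names optional model names.
#' @return data frame of class `pubsem_comparison` with attribute
#'   `favoured` (named character vector, one entry per index).
#' @export
compare_models <- function(..., names = NULL) {
  fits <- list(...)
  if (length(fits) == 1 && is.list(fits[[1]]) && !inherits(fits[[1]], "pubsem_fit"))
    fits <- fits[[1]]
  if (is.null(names))
    names <- if (!is.null(base::names(fits))) base::names(fits)
  else paste0("model", seq_along(fits))
  ns <- vapply(fits, `[[`, numeric(1), "n")
  if (length(unique(ns)) > 1)
    stop("fits were obtained on different sample sizes: ",
         paste(ns, collapse = ", "))
  tab <- data.frame(
    model = names,
    chisq = vapply(fits, `[[`, numeric(1), "chisq"),
    df = vapply(fits, `[[`, numeric(1), "df"),
    CFI = vapply(fits, function(f) f$fit_indices$CFI, numeric(1)),
    MFI = vapply(fits, function(f) f$fit_indices$MFI, numeric(1)),
    ECVI = vapply(fits, function(f) f$fit_indices$ECVI, numeric(1)),
    SRMR = vapply(fits, function(f) f$fit_indices$SRMR, numeric(1)),
    stringsAsFactors = FALSE)
  tab$delta_chisq <- c(NA, abs(diff(tab$chisq)))
  tab$delta_df <- c(NA, abs(diff(tab$df)))
  tab$delta_p <- ifelse(is.na(tab$delta_df) | tab$delta_df == 0, NA,
                        pchisq(tab$delta_chisq, tab$delta_df,
                               lower.tail = FALSE))
  fav <- c(chisq = tab$model[which.min(tab$chisq)],
           CFI = tab$model[which.max(tab$CFI)],
           MFI = tab$model[which.max(tab$MFI)],
           ECVI = tab$model[which.min(tab$ECVI)],
           SRMR = tab$model[which.min(tab$SRMR)])
  structure(tab, favoured = fav, class = c("pubsem_comparison", "data.frame"))
}

#' @export
print.pubsem_comparison <- function(x, ...) {
  print.data.frame(x, digits = 4, row.names = FALSE)
  fav <- attr(x, "favoured")
  cat("favoured:", paste(names(fav), fav, sep = "->", collapse = "  "), "\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Robust (Huber-White) standard errors and the mean-scaled chi-square

# casewise score matrix (n x q) by central differences of the casewise
# log-likelihood; vectorized over cases within each parameter perturbation
casewise_scores <- function(fit, X, h = 1e-5) {
  model <- fit$model
  if (fit$estimator == "FIML") {
    par0 <- c(fit$theta, fit$means)
  } else {
    par0 <- fit$theta
    mu <- colMeans(X)
  }
  caseloglik <- function(par) {
    theta <- par[seq_len(model$nfree)]
    m <- if (fit$estimator == "FIML") par[model$nfree + seq_len(ncol(X))] else mu
    Sigma <- implied_covariance(model, theta)
    ll <- numeric(nrow(X))
    for (rows in missing_patterns(X)) {
      idx <- which(!is.na(X[rows[1], ]))
      Sg <- Sigma[idx, idx, drop = FALSE]
      ch <- chol(Sg)
      inv <- chol2inv(ch)
      cent <- sweep(X[rows, idx, drop = FALSE], 2, m[idx])
      ll[rows] <- -0.5 * (length(idx) * log(2 * pi) + 2 * sum(log(diag(ch))) +
                            rowSums((cent %*% inv) * cent))
    }
    ll
  }
  q <- length(par0)
  sc <- matrix(0, nrow(X), q)
  for (k in seq_len(q)) {
    hk <- h * (1 + abs(par0[k]))
    pp <- par0; pp[k] <- pp[k] + hk
    pm <- par0; pm[k] <- pm[k] - hk
    sc[, k] <- (caseloglik(pp) - caseloglik(pm)) / (2 * hk)
  }
  sc
}

#' Huber-White sandwich standard errors
#'
#' Computes robust standard errors `A^-1 B A^-1`, with `A` the observed
#' information of the fitted log-likelihood and `B` the outer-product sum of
#' per-case score contributions, evaluated at the estimates. Returned
#' alongside the naive (inverse-information) standard errors.
#'
#' @param fit a converged `pubsem_fit`.
#' @param data the casewise data the model was fitted to.
#' @return data frame with `label`, `est`, `se_naive`, `se_robust`.
#' @export
sandwich_se <- function(fit, data) {
  if (!fit$converged) stop("sandwich standard errors require a converged fit")
  X <- as.matrix(data[, fit$model$obs, drop = FALSE])
  storage.mode(X) <- "double"
  if (fit$estimator != "FIML") X <- X[complete.cases(X), , drop = FALSE]
  if (nrow(X) < 2)
    stop("casewise scores are degenerate with fewer than 2 cases")
  sc <- casewise_scores(fit, X)
  B <- crossprod(sc)
  A <- fit$information
  q <- fit$q
  qa <- nrow(A)   # FIML information includes the means
  Ainv <- tryCatch(solve(A), error = function(e)
    stop("observed information is singular"))
  V <- Ainv %*% B[seq_len(qa), seq_len(qa), drop = FALSE] %*% Ainv
  rob <- sqrt(pmax(diag(V), 0))
  labels <- fit$model$labels
  est <- unname(fit$theta)
  se_naive <- if (is.null(fit$se)) rep(NA_real_, q) else unname(fit$se)
  if (fit$estimator == "FIML") {  # means are estimated too
    labels <- c(labels, paste0(names(fit$means), "~1"))
    est <- c(est, unname(fit$means))
    se_naive <- c(se_naive, rep(NA_real_, length(fit$means)))
  }
  data.frame(label = labels, est = est, se_naive = se_naive,
             se_robust = rob[seq_along(labels)], stringsAsFactors = FALSE)
}

duplication_matrix <- function(p) {
  ps <- p * (p + 1) / 2
  D <- matrix(0, p * p, ps)
  k <- 0
  for (j in seq_len(p)) for (i in j:p) {
    k <- k + 1
    D[(j - 1) * p + i, k] <- 1
    D[(i - 1) * p + j, k] <- 1
  }
  D
}

#' Mean-scaled (robust) chi-square
#'
#' Scales the normal-theory chi-square by a factor derived from the
#' residual-weight trace against an empirical fourth-moment matrix
#' (the mean-correction of the Satorra-Bentler family). Under multivariate
#' normal data the scaling factor converges to 1 and the scaled and
#' unscaled statistics agree; under excess kurtosis the scaled statistic is
#' the better-calibrated test. The unscaled chi-square is always reported
#' alongside.
#'
#' @param fit a converged `pubsem_fit` with `df > 0`.
#' @param data casewise data (complete rows are used).
#' @return list with `chisq`, `scaled_chisq`, `scaling_factor`, `df`.
#' @export
scaled_chisq <- function(fit, data) {
  if (fit$df <= 0) stop("scaled chi-square requires df > 0")
  X <- as.matrix(data[, fit$model$obs, drop = FALSE])
  X <- X[complete.cases(X), , drop = FALSE]
  n <- nrow(X); p <- ncol(X)
  Xc <- sweep(X, 2, colMeans(X))
  S <- crossprod(Xc) / n
  lowmask <- lower.tri(S, diag = TRUE)
  # empirical fourth-moment (asymptotic) covariance of vech(S)
  Z <- t(apply(Xc, 1, function(x) tcrossprod(x)[lowmask]))
  Gamma <- crossprod(sweep(Z, 2, S[lowmask])) / n
  # normal-theory weight and model Jacobian on the vech scale
  Sigma <- fit$Sigma
  inv <- solve(Sigma)
  D <- duplication_matrix(p)
  W <- 0.5 * t(D) %*% (inv %x% inv) %*% D
  dS <- dSigma_dtheta(fit$model, fit$theta)
  Delta <- vapply(dS, function(m) m[lowmask], numeric(sum(lowmask)))
  WD <- W %*% Delta
  U <- W - WD %*% solve(t(Delta) %*% WD) %*% t(WD)
  cfac <- sum(diag(U %*% Gamma)) / fit$df
  list(chisq = fit$chisq, scaled_chisq = fit$chisq / cfac,
       scaling_factor = cfac, df = fit$df)
}
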