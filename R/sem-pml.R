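# Pairwise maximum likelihood for ordinal (and continuous) indicators.
#
# Ordinal variables are modelled as discretized standard-normal latent
# responses: free thresholds per item, unit total variance (the residual
# variance is 1 minus the model-implied communality, not a free parameter).
# The objective sums, over variable pairs and cases with both members
# observed, the log bivariate-normal rectangle probability implied by the
# thresholds and the model-implied polychoric correlation
# (pairwise-present likelihood; uniform pair weights).

# Gauss-Legendre nodes/weights on [-1, 1] by Golub-Welsch (eigen-decomposition
# of the Jacobi matrix); cached per order
gl_cache <- new.env(parent = emptyenv())
gauss_legendre <- function(m) {
  key <- as.character(m)
  if (!is.null(gl_cache[[key]])) return(gl_cache[[key]])
  k <- seq_len(m - 1)
  b <- k / sqrt(4 * k^2 - 1)
  J <- matrix(0, m, m)
  J[cbind(k, k + 1)] <- b
  J[cbind(k + 1, k)] <- b
  e <- eigen(J, symmetric = TRUE)
  res <- list(x = rev(e$values), w = rev(2 * e$vectors[1, ]^2))
  gl_cache[[key]] <- res
  res
}

#' Standard bivariate normal CDF
#'
#' `P(X <= h, Y <= k)` for standard bivariate normal variables with
#' correlation `rho`, vectorized over all three arguments. Computed by
#' Gauss-Legendre quadrature (64 nodes) of the tetrachoric series
#' representation `Phi2(h,k,rho) = Phi(h)Phi(k) + integral_0^rho
#' phi2(h,k;r) dr`, accurate to well below 1e-8 absolute for
#' `|rho| <= 0.999`.
#'
#' @param h,k upper limits (may be `Inf`/`-Inf`).
#' @param rho correlation(s), clamped to `[-0.9999, 0.9999]`.
#' @return vector of probabilities.
#' @export
pbvnorm <- function(h, k, rho) {
  nmax <- max(length(h), length(k), length(rho))
  h <- rep_len(h, nmax); k <- rep_len(k, nmax)
  rho <- pmin(pmax(rep_len(rho, nmax), -0.9999), 0.9999)
  out <- pnorm(h) * pnorm(k)
  fin <- is.finite(h) & is.finite(k) & rho != 0
  if (any(fin)) {
    gl <- gauss_legendre(64)
    hf <- h[fin]; kf <- k[fin]; rf <- rho[fin]
    # nodes r on [0, rho] per element: r = rho/2 * (x + 1)
    R <- outer(rf / 2, gl$x + 1)                     # n x m
    om <- 1 - R^2
    E <- exp(-(hf^2 - 2 * R * hf * kf + kf^2) / (2 * om)) / sqrt(om)
    out[fin] <- out[fin] + (E %*% gl$w) * rf / 2 / (2 * pi)
  }
  # infinite limits: P collapses to the univariate or to 0
  out[h == Inf] <- pnorm(k[h == Inf])
  out[k == Inf] <- pnorm(h[k == Inf])
  out[h == -Inf | k == -Inf] <- 0
  pmin(pmax(out, 0), 1)
}

# rectangle probabilities for all cells of a Ki x Kj table, given threshold
# vectors (without the infinite endpoints) and a scalar correlation
rectangle_probs <- function(tau_i, tau_j, rho) {
  bi <- c(-Inf, tau_i, Inf)
  bj <- c(-Inf, tau_j, Inf)
  Ki <- length(bi) - 1; Kj <- length(bj) - 1
  up_i <- bi[-1]; lo_i <- bi[-length(bi)]
  up_j <- bj[-1]; lo_j <- bj[-length(bj)]
  H <- matrix(rep(up_i, Kj), Ki, Kj)
  Hl <- matrix(rep(lo_i, Kj), Ki, Kj)
  K <- matrix(rep(up_j, each = Ki), Ki, Kj)
  Kl <- matrix(rep(lo_j, each = Ki), Ki, Kj)
  p <- pbvnorm(c(H), c(K), rho) - pbvnorm(c(Hl), c(K), rho) -
    pbvnorm(c(H), c(Kl), rho) + pbvnorm(c(Hl), c(Kl), rho)
  matrix(pmax(p, 1e-12), Ki, Kj)
}

# clone of the model with ordinal residual variances fixed to 0 (they are
# recomputed as 1 - communality at every evaluation)
constrain_ordinal_resid <- function(model, ordvars) {
  tab <- model$params
  hit <- tab$mat == "S" & tab$row == tab$col & tab$row %in% ordvars & tab$free
  tab$free[hit] <- FALSE
  tab$value[hit] <- 0
  free_labels <- unique(tab$label[tab$free])
  tab$theta <- ifelse(tab$free, match(tab$label, free_labels), 0L)
  m <- model
  m$params <- tab
  m$labels <- free_labels
  m$nfree <- length(free_labels)
  m
}

#' Fit a measurement model to ordinal/mixed data by pairwise likelihood
#'
#' @param model a `pubsem_model`.
#' @param data data frame with `model$obs` columns; ordinal columns coded as
#'   consecutive integers (an observed gap between categories is an error
#'   instructing a category merge), continuous columns are centered
#'   internally (covariance-only pairwise normal likelihood). Mixed
#'   ordinal-continuous pairs are not supported.
#' @param ordered character vector of ordinal variable names; by default,
#'   integer-valued columns with at most 10 distinct values.
#' @return a `pubsem_fit` with estimator `"PML"`; ordinal residual variances
#'   in the parameter table are the derived `1 - communality` values, and
#'   `fit$thresholds` holds the estimated thresholds. The chi-square and
#'   fit indices are not defined for this objective and are `NA`.
#' @export
pml_fit_ordinal <- function(model, data, ordered = NULL) {
  X <- data[, model$obs, drop = FALSE]
  if (is.null(ordered)) {
    ordered <- names(X)[vapply(names(X), function(v) {
      x <- X[[v]][!is.na(X[[v]])]
      length(x) > 0 && all(x == round(x)) && length(unique(x)) <= 10
    }, logical(1))]
  }
  contvars <- setdiff(model$obs, ordered)
  n <- nrow(X)

  # ordinal recode to 1..K; interior empty categories are unidentifiable
  lev <- list()
  for (v in ordered) {
    x <- X[[v]]
    u <- sort(unique(x[!is.na(x)]))
    if (length(u) < 2) stop("ordinal variable ", v, " has a single category")
    if (any(diff(u) > 1))
      stop("ordinal variable ", v, " has an empty category between ",
           u[which(diff(u) > 1)[1]], " and ", u[which(diff(u) > 1)[1] + 1],
           "; merge adjacent categories before fitting")
    X[[v]] <- match(x, u)
    lev[[v]] <- u
  }
  for (v in contvars) X[[v]] <- X[[v]] - mean(X[[v]], na.rm = TRUE)

  # pair inventory
  pairs <- utils::combn(model$obs, 2, simplify = FALSE)
  kind <- vapply(pairs, function(pr) {
    no <- sum(pr %in% ordered)
    if (no == 2) "oo" else if (no == 0) "cc" else "oc"
  }, character(1))
  if (any(kind == "oc"))
    stop("mixed ordinal-continuous pairs are not supported by the pairwise ",
         "estimator; use FIML with the items treated as numeric")

  tabs <- list(); Ws <- list(); npair <- list()
  for (i in seq_along(pairs)) {
    pr <- pairs[[i]]
    ok <- !is.na(X[[pr[1]]]) & !is.na(X[[pr[2]]])
    if (kind[i] == "oo") {
      tabs[[i]] <- table(factor(X[[pr[1]]][ok], levels = seq_along(lev[[pr[1]]])),
                         factor(X[[pr[2]]][ok], levels = seq_along(lev[[pr[2]]])))
    } else {
      M <- cbind(X[[pr[1]]][ok], X[[pr[2]]][ok])
      Ws[[i]] <- crossprod(M) / sum(ok)
      npair[[i]] <- sum(ok)
    }
  }

  inner <- constrain_ordinal_resid(model, ordered)
  qm <- inner$nfree

  # threshold layout and empirical starts
  tau_start <- list()
  for (v in ordered) {
    pr <- table(factor(X[[v]], levels = seq_along(lev[[v]])))
    cum <- cumsum(pr) / sum(pr)
    tau_start[[v]] <- qnorm(pmin(pmax(cum[-length(cum)], 1e-4), 1 - 1e-4))
  }
  tau_idx <- list(); off <- qm
  for (v in ordered) {
    tau_idx[[v]] <- off + seq_along(tau_start[[v]])
    off <- off + length(tau_start[[v]])
  }

  implied_star <- function(theta) {
    V <- implied_cov_all(inner, theta)$V[model$obs, model$obs, drop = FALSE]
    resid <- 1 - diag(V)[ordered]
    if (any(resid <= 1e-4)) return(NULL)   # communality at/over 1
    diag(V)[match(ordered, model$obs)] <- 1
    V
  }

  objective <- function(par) {
    theta <- par[seq_len(qm)]
    V <- implied_star(theta)
    if (is.null(V)) return(1e10)
    for (v in ordered) {
      tv <- par[tau_idx[[v]]]
      if (length(tv) > 1 && any(diff(tv) <= 1e-6)) return(1e10)
    }
    nll <- 0
    for (i in seq_along(pairs)) {
      pr <- pairs[[i]]
      if (kind[i] == "oo") {
        rho <- V[pr[1], pr[2]] / sqrt(V[pr[1], pr[1]] * V[pr[2], pr[2]])
        if (abs(rho) > 0.999) return(1e10)
        P <- rectangle_probs(par[tau_idx[[pr[1]]]], par[tau_idx[[pr[2]]]], rho)
        nll <- nll - sum(tabs[[i]] * log(P))
      } else {
        Ssub <- V[pr, pr]
        ch <- tryCatch(chol(Ssub), error = function(e) NULL)
        if (is.null(ch)) return(1e10)
        nll <- nll + 0.5 * npair[[i]] *
          (2 * log(2 * pi) + 2 * sum(log(diag(ch))) +
             sum(Ws[[i]] * chol2inv(ch)))
      }
    }
    nll
  }

  S0 <- diag(length(model$obs))
  dimnames(S0) <- list(model$obs, model$obs)
  if (length(contvars)) {
    Sc <- cov(X[, contvars, drop = FALSE], use = "pairwise.complete.obs")
    S0[contvars, contvars] <- Sc
  }
  theta0 <- start_values(inner, S0) * 0.7   # keep start communalities < 1
  par0 <- c(theta0, unlist(tau_start))
  opt <- nlminb(par0, objective,
                control = list(iter.max = 2000, eval.max = 4000))
  par <- opt$par
  theta_in <- setNames(par[seq_len(qm)], inner$labels)
  V <- implied_star(theta_in)
  if (is.null(V)) stop("pairwise fit ended at an inadmissible solution")

  # lift back onto the original parameterization: ordinal residual variances
  # become the derived 1 - communality values
  theta_full <- setNames(numeric(model$nfree), model$labels)
  theta_full[inner$labels] <- theta_in
  Vcommon <- implied_cov_all(inner, theta_in)$V[model$obs, model$obs]
  for (v in ordered) {
    lab <- paste0(v, "~~", v)
    if (lab %in% model$labels) theta_full[lab] <- 1 - Vcommon[v, v]
  }

  thresholds <- lapply(ordered, function(v) {
    tv <- par[tau_idx[[v]]]
    names(tv) <- paste0("t", seq_along(tv))
    tv
  })
  names(thresholds) <- ordered

  H <- tryCatch(num_hessian(function(pp) {
    h <- 1e-5
    vapply(seq_along(pp), function(k) {
      p1 <- pp; p1[k] <- p1[k] + h
      p2 <- pp; p2[k] <- p2[k] - h
      (objective(p1) - objective(p2)) / (2 * h)
    }, numeric(1))
  }, par), error = function(e) NULL)
  se <- if (!is.null(H)) {
    vc <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(vc)) {
      s <- rep(NA_real_, model$nfree)
      s[match(inner$labels, model$labels)] <-
        sqrt(pmax(diag(vc)[seq_len(qm)], 0))
      s
    } else NULL
  } else NULL

  gnorm <- NA_real_
  fit <- structure(list(
    model = model, estimator = "PML", theta = theta_full, se = se,
    vcov = NULL, information = NULL,
    n = n, p = length(model$obs), q = qm + length(unlist(tau_start)),
    df = NA_real_, F_min = opt$objective / n, chisq = NA_real_,
    loglik = -opt$objective, Sigma = V, S = NULL,
    means = NULL, thresholds = thresholds, ordered = ordered,
    baseline = NULL,
    fit_indices = list(CFI = NA_real_, MFI = NA_real_,
                       ECVI = NA_real_, SRMR = NA_real_),
    converged = opt$convergence == 0, iterations = opt$iterations,
    gradient_norm = gnorm), class = "pubsem_fit")
  fit$heywood <- FALSE
  fit
}
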