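# Model specification: a small structural-equation description language and
# its RAM (reticular action model) translation.
#
# Syntax, one statement per line (or `;`-separated):
#   F =~ x1 + x2 + 0.5*x3     loadings (premultiplier fixes the value)
#   y ~ x                     regression
#   a ~~ b                    (residual) covariance; a ~~ a variance
#   lab*x                     a character premultiplier labels the parameter;
#                             shared labels impose equality
#
# Defaults: every observed variable gets a free residual variance; every
# latent variable's (residual) variance is fixed to 1 (unit-variance
# identification, so loadings are reported on the scale of the standardized
# factors); covariances default to 0 unless declared.

#' Parse a model specification
#'
#' @param syntax character scalar or vector of statements (see Details in
#'   the package vignette for the grammar).
#' @return an object of class `pubsem_model`.
#' @export
#' @examples
#' m <- parse_model("
#'   adr =~ pds2 + pds3 + ld2
#'   gon =~ pds1 + pds4 + pds6 + ld1
#'   adr ~~ gon
#' ")
#' m
parse_model <- function(syntax) {
  lines <- unlist(strsplit(paste(syntax, collapse = "\n"), "[\n;]"))
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty model syntax")

  entries <- list()
  add <- function(mat, row, col, free, value, label)
    entries[[length(entries) + 1L]] <<- list(mat = mat, row = row, col = col,
                                             free = free, value = value,
                                             label = label)
  split_term <- function(term) {
    term <- trimws(term)
    if (grepl("\\*", term)) {
      parts <- trimws(strsplit(term, "\\*")[[1]])
      if (length(parts) != 2) stop("malformed term: ", term)
      mod <- suppressWarnings(as.numeric(parts[1]))
      if (is.na(mod) && parts[1] != "NA")
        list(var = parts[2], fixed = NA_real_, label = parts[1])
      else
        list(var = parts[2], fixed = mod, label = NA_character_)
    } else list(var = term, fixed = NA_real_, label = NA_character_)
  }

  latents <- character(0)
  for (ln in lines) {
    if (grepl("=~", ln, fixed = TRUE)) {
      op <- "=~"
    } else if (grepl("~~", ln, fixed = TRUE)) {
      op <- "~~"
    } else if (grepl("~", ln, fixed = TRUE)) {
      op <- "~"
    } else stop("statement without operator: ", ln)
    parts <- strsplit(ln, op, fixed = TRUE)[[1]]
    if (length(parts) != 2) stop("malformed statement: ", ln)
    lhs <- trimws(parts[1])
    terms <- lapply(strsplit(parts[2], "+", fixed = TRUE)[[1]], split_term)
    for (tm in terms) {
      lab <- tm$label
      if (op == "=~") {
        latents <- union(latents, lhs)
        if (is.na(lab) && is.na(tm$fixed)) lab <- paste0(lhs, "=~", tm$var)
        add("A", tm$var, lhs, is.na(tm$fixed), tm$fixed, lab)
      } else if (op == "~~") {
        if (is.na(lab) && is.na(tm$fixed)) lab <- paste0(lhs, "~~", tm$var)
        add("S", lhs, tm$var, is.na(tm$fixed), tm$fixed, lab)
      } else {
        if (is.na(lab) && is.na(tm$fixed)) lab <- paste0(lhs, "~", tm$var)
        add("A", lhs, tm$var, is.na(tm$fixed), tm$fixed, lab)
      }
    }
  }

  vars <- unique(unlist(lapply(entries, function(e) c(e$row, e$col))))
  obs <- setdiff(vars, latents)

  # default residual variances
  declared_var <- vapply(entries, function(e)
    if (e$mat == "S" && e$row == e$col) e$row else NA_character_, character(1))
  for (v in obs) if (!v %in% declared_var)
    add("S", v, v, TRUE, NA_real_, paste0(v, "~~", v))
  for (l in latents) if (!l %in% declared_var)
    add("S", l, l, FALSE, 1, NA_character_)

  tab <- do.call(rbind, lapply(entries, function(e)
    data.frame(mat = e$mat, row = e$row, col = e$col, free = e$free,
               value = e$value, label = e$label, stringsAsFactors = FALSE)))
  free_labels <- unique(tab$label[tab$free])
  tab$theta <- ifelse(tab$free, match(tab$label, free_labels), 0L)

  structure(list(syntax = paste(lines, collapse = "\n"),
                 obs = obs, latents = latents,
                 all = c(obs, latents), params = tab,
                 labels = free_labels, nfree = length(free_labels)),
            class = "pubsem_model")
}

#' @export
print.pubsem_model <- function(x, ...) {
  cat("Structural equation model specification\n")
  cat("  observed:", length(x$obs), " latent:", length(x$latents),
      " free parameters:", x$nfree, "\n")
  cat("  ", paste(x$latents, collapse = ", "), "\n")
  invisible(x)
}

#' Read/write a model specification file
#'
#' Models serialize to the plain-text statement syntax of [parse_model()],
#' one statement per line.
#'
#' @param path file path.
#' @param model a `pubsem_model`.
#' @return `read_model` returns a `pubsem_model`; `write_model` the path,
#'   invisibly.
#' @export
read_model <- function(path) parse_model(readLines(path, warn = FALSE))

#' @rdname read_model
#' @export
write_model <- function(model, path) {
  writeLines(model$syntax, path)
  invisible(path)
}

# Fill RAM matrices A (directed paths, rows receive) and S (symmetric) over
# all variables from a free-parameter vector theta.
ram_matrices <- function(model, theta) {
  v <- model$all
  nv <- length(v)
  A <- matrix(0, nv, nv, dimnames = list(v, v))
  S <- matrix(0, nv, nv, dimnames = list(v, v))
  tab <- model$params
  val <- ifelse(tab$free, theta[tab$theta], tab$value)
  for (k in seq_len(nrow(tab))) {
    if (tab$mat[k] == "A") {
      A[tab$row[k], tab$col[k]] <- val[k]
    } else {
      S[tab$row[k], tab$col[k]] <- val[k]
      S[tab$col[k], tab$row[k]] <- val[k]
    }
  }
  list(A = A, S = S)
}

# implied covariance over all variables (latents included)
implied_cov_all <- function(model, theta) {
  m <- ram_matrices(model, theta)
  IA <- diag(nrow(m$A)) - m$A
  B <- tryCatch(solve(IA), error = function(e)
    stop("singular (I - A): the directed-path matrix admits no reduced form"))
  V <- B %*% m$S %*% t(B)
  list(V = (V + t(V)) / 2, B = B, S = m$S)
}

#' Model-implied covariance matrix
#'
#' Assembles the covariance matrix implied by the model's paths at a given
#' free-parameter vector, via the reduced-form covariance
#' `(I-A)^-1 S (I-A)^-T` restricted to the observed variables.
#'
#' @param model a `pubsem_model`.
#' @param theta numeric vector of free parameters (order of
#'   `model$labels`).
#' @return covariance matrix over `model$obs`.
#' @export
implied_covariance <- function(model, theta) {
  stopifnot(length(theta) == model$nfree)
  implied_cov_all(model, theta)$V[model$obs, model$obs, drop = FALSE]
}

# derivative of the observed-block implied covariance wrt each free
# parameter; returns a list of p x p matrices (sparse work via outer
# products: dV = B dA V + (B dA V)' + B dS B')
dSigma_dtheta <- function(model, theta) {
  ic <- implied_cov_all(model, theta)
  B <- ic$B; V <- ic$V
  obs <- model$obs
  tab <- model$params
  out <- vector("list", model$nfree)
  for (k in seq_len(model$nfree)) {
    rows <- which(tab$free & tab$theta == k)
    dV <- matrix(0, nrow(V), ncol(V))
    for (r in rows) {
      i <- match(tab$row[r], model$all)
      j <- match(tab$col[r], model$all)
      if (tab$mat[r] == "A") {
        M <- B[, i] %*% t(V[j, ])   # B dA V for a single entry (i,j)
        dV <- dV + M + t(M)
      } else {
        M <- B[, i] %*% t(B[, j])
        dV <- dV + M
        if (i != j) dV <- dV + t(M)
      }
    }
    dimnames(dV) <- dimnames(V)
    out[[k]] <- dV[obs, obs, drop = FALSE]
  }
  out
}

# heuristic start values: loadings 0.7, regressions 0, latent covariances
# 0.3, observed residual variances half the sample variance, residual
# covariances 0
start_values <- function(model, sample_cov = NULL) {
  tab <- model$params
  theta <- numeric(model$nfree)
  for (k in seq_len(model$nfree)) {
    r <- which(tab$free & tab$theta == k)[1]
    row <- tab$row[r]; col <- tab$col[r]
    if (tab$mat[r] == "A") {
      theta[k] <- if (col %in% model$latents && row %in% model$obs) 0.7
      else if (col %in% model$latents) 0.7 else 0
    } else if (row == col) {
      theta[k] <- if (row %in% model$obs) {
        if (!is.null(sample_cov) && row %in% rownames(sample_cov))
          0.5 * sample_cov[row, row] else 0.5
      } else 1
    } else {
      theta[k] <- if (row %in% model$latents && col %in% model$latents) 0.3 else 0
    }
  }
  names(theta) <- model$labels
  theta
}

#' Check local identification
#'
#' Ranks the Jacobian of the unique elements of the implied covariance with
#' respect to the free parameters near the start values. The evaluation
#' point is deterministically jittered away from the (symmetric) start
#' heuristic so that coincidental rank drops at exactly-equal parameter
#' values do not masquerade as structural non-identification. A rank below
#' the number of free parameters means the model is not locally identified.
#'
#' @param model a `pubsem_model`.
#' @param theta parameter vector (defaults to jittered heuristic start
#'   values).
#' @return logical; `TRUE` when identified. Attribute `"rank"` carries the
#'   Jacobian rank.
#' @export
check_identification <- function(model, theta = NULL) {
  if (is.null(theta)) {
    theta <- start_values(model)
    theta <- theta + 0.03 * sin(seq_along(theta)) + 0.01
  }
  dS <- dSigma_dtheta(model, theta)
  p <- length(model$obs)
  lower <- lower.tri(matrix(0, p, p), diag = TRUE)
  J <- vapply(dS, function(m) m[lower], numeric(sum(lower)))
  r <- qr(J)$rank
  structure(r >= model$nfree, rank = r)
}

# degrees of freedom of the covariance structure
model_df <- function(model, meanstructure = FALSE) {
  p <- length(model$obs)
  p * (p + 1) / 2 + (if (meanstructure) p else 0) - model$nfree
}
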