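# Marker-wise linear mixed-model association engine, implemented from first
# principles. The model per marker is
#   y = X beta + mu + eps,  mu ~ N(0, sigma2_mu * K),  eps ~ N(0, sigma2_eps I)
# so Cov(y) = sigma2_mu * K + sigma2_eps * I. Variance components are
# estimated by spectral REML: K = U D U' is eigendecomposed once, y and X are
# rotated, and the restricted likelihood is profiled over the variance ratio
# lambda = sigma2_mu / sigma2_eps by 1-D search on log(lambda). Fixed effects
# are then estimated by GLS under the plugged-in covariance and tested with a
# Wald statistic against the standard normal.

kin_eigen <- function(K) {
  e <- eigen(unclass(K), symmetric = TRUE)
  e$values <- pmax(e$values, 0)
  e
}

# Restricted log-likelihood profile at variance ratio lambda, on rotated
# data. Returns the exact REML log-likelihood (all constants included) at
# the profiled sigma2_eps, i.e.
#   l_R(lambda) = -1/2 [ (n-p) log(2 pi sigma2_hat) + (n-p)
#                        + sum log(lambda d_i + 1)
#                        + log|X' W X| - log|X'X| ]
# with W = diag(1 / (lambda d_i + 1)) and sigma2_hat = RSS_W / (n - p).
reml_profile_point <- function(lam, ytil, Xtil, d, ldetXX) {
  n <- length(ytil)
  p <- ncol(Xtil)
  v <- lam * d + 1
  w <- 1 / v
  A <- crossprod(Xtil, Xtil * w)
  cA <- chol(A)
  b <- crossprod(Xtil, w * ytil)
  beta <- backsolve(cA, forwardsolve(t(cA), b))
  r <- ytil - Xtil %*% beta
  rss <- sum(w * r * r)
  s2e <- rss / (n - p)
  ll <- -0.5 * ((n - p) * log(2 * pi * s2e) + (n - p) + sum(log(v)) +
                  2 * sum(log(diag(cA))) - ldetXX)
  list(ll = ll, s2e = s2e, beta = beta, chol_A = cA)
}

#' Exact restricted log-likelihood of the kinship mixed model
#'
#' Evaluates the REML log-likelihood of `y ~ N(X beta, sigma2_mu K +
#' sigma2_eps I)` at given variance components, using the spectral rotation
#' (one eigendecomposition of `K`, then diagonal weighting). All constants
#' are included, so the value is directly comparable with a dense
#' multivariate-normal restricted likelihood.
#'
#' @param y Response vector.
#' @param X Design matrix (full column rank, fewer columns than rows).
#' @param K Kinship matrix (matrix or `kinship_matrix`).
#' @param sigma2_mu,sigma2_eps Variance components; `sigma2_eps > 0`.
#' @param eig Optional precomputed `eigen(K, symmetric = TRUE)`.
#' @return The restricted log-likelihood (scalar).
#' @export
restricted_loglik <- function(y, X, K, sigma2_mu, sigma2_eps, eig = NULL) {
  X <- as.matrix(X)
  n <- length(y)
  p <- ncol(X)
  stopifnot(n > p, sigma2_eps > 0, sigma2_mu >= 0)
  if (is.null(eig)) eig <- kin_eigen(K)
  ytil <- drop(crossprod(eig$vectors, y))
  Xtil <- crossprod(eig$vectors, X)
  lam <- sigma2_mu / sigma2_eps
  v <- lam * eig$values + 1
  w <- 1 / v
  A <- crossprod(Xtil, Xtil * w)
  cA <- chol(A)
  b <- crossprod(Xtil, w * ytil)
  beta <- backsolve(cA, forwardsolve(t(cA), b))
  r <- ytil - Xtil %*% beta
  rss <- sum(w * r * r)
  ldetXX <- 2 * sum(log(abs(diag(qr.R(qr(X))))))
  # l_R at fixed sigma2_eps (not profiled over sigma2_eps)
  -0.5 * ((n - p) * log(2 * pi * sigma2_eps) + sum(log(v)) +
            2 * sum(log(diag(cA))) - ldetXX + rss / sigma2_eps)
}

vc_result <- function(sigma2_mu, sigma2_eps, method, converged = TRUE,
                      boundary = FALSE, lambda = NA_real_,
                      loglik = NA_real_) {
  structure(list(sigma2_mu = sigma2_mu, sigma2_eps = sigma2_eps,
                 method = method, converged = converged, boundary = boundary,
                 lambda = lambda, loglik = loglik),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf(
    "<variance_components> sigma2_mu = %.4g, sigma2_eps = %.4g (%s%s)\n",
    x$sigma2_mu, x$sigma2_eps, x$method,
    if (x$boundary) ", boundary" else ""))
  invisible(x)
}

# Core REML search on rotated data; returns a variance_components object.
reml_core <- function(ytil, Xtil, d, ldetXX, grid_size = 100,
                      log_range = c(-10, 10), tol = 1e-8) {
  n <- length(ytil)
  p <- ncol(Xtil)
  grid <- seq(log_range[1], log_range[2], length.out = grid_size)
  ll <- vapply(grid, function(g) {
    reml_profile_point(exp(g), ytil, Xtil, d, ldetXX)$ll
  }, numeric(1))
  # smallest lambda wins ties: a flat profile (e.g. K = I) collapses to the
  # boundary solution sigma2_mu = 0 rather than drifting on numeric noise
  i <- which(ll >= max(ll) - 1e-8 * (1 + abs(max(ll))))[1]
  if (i == 1L) {
    # lower boundary: clamp the family component to exactly zero
    pt <- reml_profile_point(0, ytil, Xtil, d, ldetXX)
    return(vc_result(0, pt$s2e, "reml", boundary = TRUE, lambda = 0,
                     loglik = pt$ll))
  }
  if (i == grid_size) {
    lam <- exp(log_range[2])
    pt <- reml_profile_point(lam, ytil, Xtil, d, ldetXX)
    return(vc_result(lam * pt$s2e, pt$s2e, "reml", boundary = TRUE,
                     lambda = lam, loglik = pt$ll))
  }
  opt <- stats::optimize(function(g) {
    reml_profile_point(exp(g), ytil, Xtil, d, ldetXX)$ll
  }, interval = c(grid[i - 1L], grid[i + 1L]), maximum = TRUE, tol = tol)
  lam <- exp(opt$maximum)
  pt <- reml_profile_point(lam, ytil, Xtil, d, ldetXX)
  vc_result(lam * pt$s2e, pt$s2e, "reml", lambda = lam, loglik = pt$ll)
}

check_design <- function(y, X) {
  X <- as.matrix(X)
  n <- length(y)
  p <- ncol(X)
  if (n <= p) {
    stop_famlmm("need more observations than design columns",
                "famlmm_rank_error")
  }
  if (qr(X)$rank < p) {
    stop_famlmm("design matrix X is rank deficient", "famlmm_rank_error")
  }
  X
}

#' REML variance components under a kinship covariance
#'
#' Estimates `sigma2_mu` (family/polygenic) and `sigma2_eps` (residual) in
#' `Cov(y) = sigma2_mu K + sigma2_eps I` by restricted maximum likelihood.
#' `K` is eigendecomposed once; the restricted likelihood is profiled over
#' the ratio `lambda = sigma2_mu / sigma2_eps` with a coarse grid of 100
#' points on `log lambda` in `[-10, 10]` followed by bounded golden-section
#' refinement (tolerance `1e-8`). When the optimum sits at an endpoint the
#' ratio is clamped there and `boundary = TRUE` is reported; at the lower
#' endpoint the family component is set to exactly zero. With `K = I` the
#' ratio is unidentifiable and the documented tie-break is the boundary
#' solution `sigma2_mu = 0`, `sigma2_eps =` residual mean square.
#'
#' @param y Response vector.
#' @param X Design matrix.
#' @param K Kinship matrix.
#' @param eig Optional precomputed eigendecomposition of `K`.
#' @return A `variance_components` object with fields `sigma2_mu`,
#'   `sigma2_eps`, `method`, `converged`, `boundary`.
#' @export
reml_variance_components <- function(y, X, K, eig = NULL) {
  X <- check_design(y, X)
  if (stats::var(y) == 0) {
    return(vc_result(0, 0, "reml", boundary = TRUE, lambda = 0))
  }
  if (is.null(eig)) eig <- kin_eigen(K)
  ytil <- drop(crossprod(eig$vectors, y))
  Xtil <- crossprod(eig$vectors, X)
  ldetXX <- 2 * sum(log(abs(diag(qr.R(qr(X))))))
  reml_core(ytil, Xtil, eig$values, ldetXX)
}

#' Method-of-moments variance components (Haseman--Elston regression)
#'
#' Analysis-of-variance-style moment estimator: the off-diagonal products of
#' ordinary-least-squares residuals `e_i e_j` are regressed (through the
#' origin) on the kinship entries `K_ij`, giving `sigma2_mu`; the residual
#' variance is the diagonal residual mean square minus the fitted family
#' share. Negative estimates are clamped to zero with `boundary = TRUE`.
#'
#' @inheritParams reml_variance_components
#' @return A `variance_components` object with `method = "anova_mom"`.
#' @export
anova_variance_components <- function(y, X, K) {
  X <- check_design(y, X)
  K <- unclass(K)
  n <- length(y)
  p <- ncol(X)
  off <- K[upper.tri(K)]
  if (length(off) == 0 || diff(range(off)) < 1e-12) {
    stop_famlmm(
      "kinship matrix has constant off-diagonal; moment estimator degenerate",
      "famlmm_degenerate_error")
  }
  if (stats::var(y) == 0) {
    return(vc_result(0, 0, "anova_mom", boundary = TRUE))
  }
  e <- stats::lm.fit(X, y)$residuals
  s1 <- (drop(crossprod(e, K %*% e)) - sum(e^2 * diag(K))) / 2
  s2 <- (sum(K^2) - sum(diag(K)^2)) / 2
  s2mu <- s1 / s2
  rms <- sum(e^2) / (n - p)
  s2eps <- rms - s2mu * mean(diag(K))
  raw <- s2mu
  boundary <- FALSE
  if (s2mu < 0) {
    s2mu <- 0
    s2eps <- rms
    boundary <- TRUE
  }
  if (s2eps < 0) {
    s2eps <- 0
    boundary <- TRUE
  }
  out <- vc_result(s2mu, s2eps, "anova_mom", boundary = boundary,
                   lambda = if (s2eps > 0) s2mu / s2eps else NA_real_)
  out$sigma2_mu_raw <- raw  # pre-clamp moment estimate, for diagnostics
  out
}

#' Generalized least squares under a known covariance
#'
#' Computes the exact GLS solution `beta = (X'V^-1 X)^-1 X'V^-1 y` and its
#' covariance `(X'V^-1 X)^-1` via a Cholesky whitening of `V` (no explicit
#' inverse of `V` is formed).
#'
#' @param y Response vector.
#' @param X Design matrix, full column rank.
#' @param V Symmetric positive-definite covariance matrix.
#' @return List with `coefficients` (named vector) and `vcov` (the `p x p`
#'   coefficient covariance).
#' @export
gls_fit <- function(y, X, V) {
  X <- as.matrix(X)
  V <- unclass(V)
  cV <- tryCatch(chol(V), error = function(e) {
    stop_famlmm(sprintf(
      "covariance matrix is not positive definite (condition number %.3e)",
      kappa(V)), "famlmm_linalg_error")
  })
  wy <- backsolve(cV, y, transpose = TRUE)
  wX <- backsolve(cV, X, transpose = TRUE)
  A <- crossprod(wX)
  cA <- tryCatch(chol(A), error = function(e) {
    stop_famlmm(sprintf(
      "design is singular under the whitened metric (condition number %.3e)",
      kappa(A)), "famlmm_linalg_error")
  })
  vcov <- chol2inv(cA)
  beta <- drop(vcov %*% crossprod(wX, wy))
  names(beta) <- colnames(X)
  dimnames(vcov) <- list(colnames(X), colnames(X))
  list(coefficients = beta, vcov = vcov)
}

wald_p <- function(z, df = Inf) {
  p <- if (is.finite(df)) 2 * stats::pt(-abs(z), df) else 2 * stats::pnorm(-abs(z))
  pmax(p, .Machine$double.xmin)  # keep p in (0, 1]
}

assoc_row <- function(marker_id, option, n_used, estimate, std_error, p,
                      vc = NULL) {
  data.frame(marker_id = marker_id, option = option, n_used = n_used,
             estimate = estimate, std_error = std_error,
             statistic = estimate / std_error, p_value = p,
             sigma2_mu = if (is.null(vc)) NA_real_ else vc$sigma2_mu,
             sigma2_eps = if (is.null(vc)) NA_real_ else vc$sigma2_eps,
             boundary = if (is.null(vc)) NA else vc$boundary,
             stringsAsFactors = FALSE)
}

ols_test <- function(y, X, tested_col, reference_df = Inf) {
  fit <- stats::lm.fit(as.matrix(X), y)
  n <- length(y)
  p <- fit$rank
  if (p < ncol(X)) {
    stop_famlmm("design matrix X is rank deficient", "famlmm_rank_error")
  }
  rss <- sum(fit$residuals^2)
  s2 <- rss / (n - p)
  R <- qr.R(fit$qr)[seq_len(p), seq_len(p), drop = FALSE]
  XtXinv <- chol2inv(R)
  cols <- colnames(as.matrix(X))
  j <- if (is.character(tested_col)) match(tested_col, cols) else tested_col
  est <- fit$coefficients[j]
  se <- sqrt(s2 * XtXinv[j, j])
  df <- if (is.finite(reference_df)) n - p else Inf
  list(estimate = unname(est), std_error = se,
       p = wald_p(est / se, df = df))
}

#' Fit one marker under a covariance specification
#'
#' Applies one of the three modeling options to a single marker. The
#' `"kinship"` option estimates variance components (REML by default), forms
#' `V = sigma2_mu K + sigma2_eps I` and tests the coefficient by GLS with a
#' Wald statistic; `"independence"` is ordinary least squares on all
#' individuals; `"representative"` is ordinary least squares on the
#' one-per-family subset in `spec$active_ids`. All p-values use the standard
#' normal reference by default; `rep_reference = "t"` switches the
#' representative option to a Student-t reference with `n - p` degrees of
#' freedom.
#'
#' @param y Response vector aligned with the ids of `spec$matrix` (for the
#'   representative option, aligned with the full kinship matrix; rows are
#'   subset internally).
#' @param X Design matrix, same row order as `y`.
#' @param spec A [covariance_spec()].
#' @param vc_method `"reml"` or `"anova_mom"` (kinship option only).
#' @param tested Column (name or index) of `X` whose coefficient is tested;
#'   defaults to the `"tested"` attribute of `X`, else column 1.
#' @param rep_reference `"normal"` (default) or `"t"`.
#' @param marker_id Label for the output row.
#' @param full_ids Ids to which `y` rows correspond; defaults to the spec's
#'   matrix ids (kinship/independence) or is required when subsetting for
#'   the representative option from a longer vector.
#' @param eig Optional precomputed eigendecomposition of the kinship matrix
#'   (kinship option).
#' @return A one-row data.frame (`AssociationResult`): `marker_id`,
#'   `option`, `n_used`, `estimate`, `std_error`, `statistic`, `p_value`,
#'   `sigma2_mu`, `sigma2_eps`, `boundary`.
#' @export
fit_marker <- function(y, X, spec, vc_method = c("reml", "anova_mom"),
                       tested = NULL, rep_reference = c("normal", "t"),
                       marker_id = "marker", full_ids = NULL, eig = NULL) {
  vc_method <- match.arg(vc_method)
  rep_reference <- match.arg(rep_reference)
  stopifnot(inherits(spec, "covariance_spec"))
  X <- as.matrix(X)
  if (is.null(tested)) tested <- attr(X, "tested") %||% 1L
  if (spec$option == "representative") {
    ids <- full_ids %||% names(y)
    if (is.null(ids) && length(y) == length(spec$active_ids)) {
      ids <- spec$active_ids
    }
    if (is.null(ids)) {
      stop_famlmm(
        "representative option needs ids for y (names, full_ids) to subset",
        "famlmm_usage_error")
    }
    keep <- match(spec$active_ids, ids)
    if (anyNA(keep)) {
      stop_famlmm("active_ids not all present among the rows of y",
                  "famlmm_usage_error")
    }
    res <- ols_test(y[keep], X[keep, , drop = FALSE], tested,
                    reference_df = if (rep_reference == "t") 1 else Inf)
    return(assoc_row(marker_id, "representative", length(keep),
                     res$estimate, res$std_error, res$p))
  }
  if (length(y) != length(spec$active_ids)) {
    stop_famlmm("y must be aligned with spec$active_ids",
                "famlmm_usage_error")
  }
  if (spec$option == "independence") {
    res <- ols_test(y, X, tested)
    return(assoc_row(marker_id, "independence", length(y), res$estimate,
                     res$std_error, res$p))
  }
  # kinship option
  K <- spec$matrix
  if (is.null(eig)) eig <- kin_eigen(K)
  vc <- if (vc_method == "reml") {
    reml_variance_components(y, X, K, eig = eig)
  } else {
    anova_variance_components(y, X, K)
  }
  # GLS under V = s2mu K + s2eps I through the same spectral rotation
  wvals <- vc$sigma2_mu * eig$values + vc$sigma2_eps
  if (all(wvals <= 0)) {
    stop_famlmm("estimated covariance is singular (constant response?)",
                "famlmm_linalg_error")
  }
  w <- 1 / wvals
  ytil <- drop(crossprod(eig$vectors, y))
  Xtil <- crossprod(eig$vectors, X)
  A <- crossprod(Xtil, Xtil * w)
  cA <- chol(A)
  vcov <- chol2inv(cA)
  beta <- drop(vcov %*% crossprod(Xtil, w * ytil))
  cols <- colnames(X)
  j <- if (is.character(tested)) match(tested, cols) else tested
  est <- beta[j]
  se <- sqrt(vcov[j, j])
  assoc_row(marker_id, "kinship", length(y), est, se, wald_p(est / se),
            vc = vc)
}

#' Fit every marker of a simulated dataset under one modeling option
#'
#' Loops [fit_marker()] over all markers, sharing one eigendecomposition of
#' the kinship matrix (kinship option) and one representative draw
#' (representative option, drawn from `representative_seed`). Variance
#' components are re-estimated independently for every marker.
#'
#' @param dataset A [simulate_dataset()] result.
#' @param option `"representative"`, `"kinship"` or `"independence"`.
#' @param vc_method `"reml"` (default) or `"anova_mom"`.
#' @param representative_seed Seed for the representative draw; defaults to
#'   a seed derived from the dataset's config seed.
#' @param rep_reference Reference distribution for the representative
#'   option's Wald test, `"normal"` (default) or `"t"`.
#' @return A data.frame with one `AssociationResult` row per marker, in
#'   marker order.
#' @export
fit_all <- function(dataset, option = c("representative", "kinship",
                                        "independence"),
                    vc_method = c("reml", "anova_mom"),
                    representative_seed = NULL,
                    rep_reference = c("normal", "t")) {
  option <- match.arg(option)
  vc_method <- match.arg(vc_method)
  rep_reference <- match.arg(rep_reference)
  stopifnot(inherits(dataset, "sim_dataset"))
  Y <- dataset$responses
  X <- as.matrix(dataset$X)
  tested <- dataset$tested
  m <- ncol(Y)
  marker_ids <- colnames(Y)
  n <- nrow(Y)

  if (option == "independence") {
    rows <- lapply(seq_len(m), function(j) {
      res <- ols_test(Y[, j], X, tested)
      assoc_row(marker_ids[j], "independence", n, res$estimate,
                res$std_error, res$p)
    })
    return(do.call(rbind, rows))
  }

  if (option == "representative") {
    fam_map <- stats::setNames(dataset$family, dataset$ids)
    seed <- representative_seed %||% derive_seed(dataset$config$seed, 999)
    reps <- select_representatives(fam_map, seed)
    keep <- match(reps, dataset$ids)
    keep <- sort(keep)  # matrix order
    Xs <- X[keep, , drop = FALSE]
    df_flag <- rep_reference == "t"
    rows <- lapply(seq_len(m), function(j) {
      res <- ols_test(Y[keep, j], Xs, tested,
                      reference_df = if (df_flag) 1 else Inf)
      assoc_row(marker_ids[j], "representative", length(keep), res$estimate,
                res$std_error, res$p)
    })
    out <- do.call(rbind, rows)
    attr(out, "representatives") <- dataset$ids[keep]
    attr(out, "representative_seed") <- seed
    return(out)
  }

  # kinship option: share the eigendecomposition and rotations
  eig <- kin_eigen(dataset$kinship)
  Ytil <- crossprod(eig$vectors, Y)
  Xtil <- crossprod(eig$vectors, X)
  ldetXX <- 2 * sum(log(abs(diag(qr.R(qr(X))))))
  cols <- colnames(X)
  jcol <- if (is.character(tested)) match(tested, cols) else tested
  rows <- lapply(seq_len(m), function(j) {
    yt <- Ytil[, j]
    vc <- if (vc_method == "reml") {
      if (stats::var(Y[, j]) == 0) {
        vc_result(0, 0, "reml", boundary = TRUE, lambda = 0)
      } else {
        reml_core(yt, Xtil, eig$values, ldetXX)
      }
    } else {
      anova_variance_components(Y[, j], X, dataset$kinship)
    }
    wvals <- vc$sigma2_mu * eig$values + vc$sigma2_eps
    w <- 1 / wvals
    A <- crossprod(Xtil, Xtil * w)
    cA <- chol(A)
    vcov <- chol2inv(cA)
    beta <- drop(vcov %*% crossprod(Xtil, w * yt))
    est <- beta[jcol]
    se <- sqrt(vcov[jcol, jcol])
    assoc_row(marker_ids[j], "kinship", n, est, se, wald_p(est / se),
              vc = vc)
  })
  do.call(rbind, rows)
}
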