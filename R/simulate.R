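# Family-structured phenotype simulator. Each marker j gets an independent
# response vector drawn from the generating mixed model
#   y_j = delta_j * 1 + Z mu_j + eps_j,  mu_j ~ N(0, sigma2_mu * K),
#   eps_j ~ N(0, sigma2_eps * I),
# with delta_j = effect_delta for m_causal randomly chosen causal markers and
# 0 otherwise, so Cov(y_j) = sigma2_mu * K + sigma2_eps * I. In covariate
# mode the mean additionally contains X beta with a continuous exposure as
# the tested column.

#' Simulation configuration
#'
#' Collects every parameter of the family-structured simulation, including
#' the seed, so that a dataset can be regenerated bit-identically.
#'
#' @param n_families Number of sibship families (default 200).
#' @param family_size Siblings per family: a single integer or a vector of
#'   sizes recycled across families. The default `c(2, 3, 5, 7, 8)` gives a
#'   mixed sibship profile with mean size 5 (n = 1000 at 200 families);
#'   founders are latent, so each kinship block is exchangeable with
#'   off-diagonal `within_value`.
#' @param m_markers Number of simulated markers (default 1000).
#' @param m_causal Number of markers under the alternative (default 10).
#' @param effect_delta Mean shift (or exposure effect, in covariate mode) of
#'   a causal marker (default 0.2).
#' @param sigma2_mu Variance of the family/polygenic random effect
#'   (default 1).
#' @param sigma2_eps Residual variance (default 1).
#' @param within_value Within-family expected relationship (default 0.5,
#'   full siblings).
#' @param mode `"mean_shift"` (the alternative is a nonzero response mean;
#'   default) or `"covariate"` (the alternative is a nonzero coefficient on
#'   a simulated continuous exposure, with age/sex/site/PC-style nuisance
#'   covariates).
#' @param seed Integer seed driving every random draw.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_families = 200, family_size = c(2, 3, 5, 7, 8),
                       m_markers = 1000, m_causal = 10, effect_delta = 0.2,
                       sigma2_mu = 1, sigma2_eps = 1, within_value = 0.5,
                       mode = c("mean_shift", "covariate"), seed = 1) {
  mode <- match.arg(mode)
  cfg <- list(n_families = as.integer(n_families),
              family_size = as.integer(family_size),
              m_markers = as.integer(m_markers),
              m_causal = as.integer(m_causal),
              effect_delta = as.numeric(effect_delta),
              sigma2_mu = as.numeric(sigma2_mu),
              sigma2_eps = as.numeric(sigma2_eps),
              within_value = as.numeric(within_value),
              mode = mode, seed = as.integer(seed))
  if (cfg$m_causal > cfg$m_markers) {
    stop_famlmm("m_causal must not exceed m_markers", "famlmm_domain_error")
  }
  if (cfg$sigma2_mu < 0 || cfg$sigma2_eps <= 0) {
    stop_famlmm("need sigma2_mu >= 0 and sigma2_eps > 0",
                "famlmm_domain_error")
  }
  if (cfg$n_families < 1 || any(cfg$family_size < 1) || cfg$m_markers < 1) {
    stop_famlmm("sizes must be positive", "famlmm_domain_error")
  }
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  for (k in names(x)) {
    cat(sprintf("  %-12s %s\n", k, paste(format(x[[k]]), collapse = ",")))
  }
  invisible(x)
}

# Matrix square root of a PSD kinship matrix: Cholesky when positive
# definite, symmetric eigenvalue square root otherwise.
kinship_sqrt <- function(K) {
  L <- tryCatch(t(chol(unclass(K))), error = function(e) NULL)
  if (!is.null(L)) return(L)
  e <- eigen(unclass(K), symmetric = TRUE)
  vals <- pmax(e$values, 0)
  e$vectors %*% (sqrt(vals) * t(e$vectors))
}

#' Simulate a family-structured marker dataset
#'
#' Draws `m_markers` independent response vectors under the generating mixed
#' model (see the package vignette), with a known block kinship structure and
#' known causal markers. The same configuration always regenerates the same
#' dataset bit for bit.
#'
#' @param config A [sim_config()].
#' @param kinship Optional `kinship_matrix` to use instead of the default
#'   exchangeable sibship structure implied by the config; must be positive
#'   semidefinite and carry a `family` attribute (or supply `family`).
#' @param family Optional family vector for a supplied `kinship`.
#' @return An object of class `sim_dataset`: list with `responses` (an
#'   `n x m_markers` matrix, columns `M0001`, ...), `X` (design matrix),
#'   `tested` (name of the tested column), `truth` (logical vector of causal
#'   flags), `causal` (causal marker ids), `kinship`, `ids`, `family`, and
#'   `config`.
#' @export
simulate_dataset <- function(config, kinship = NULL, family = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(kinship)) {
    kinship <- exchangeable_family_matrix(config$n_families,
                                          config$family_size,
                                          config$within_value)
  } else {
    stopifnot(inherits(kinship, "kinship_matrix"))
    ev_min <- min(eigen(unclass(kinship), symmetric = TRUE,
                        only.values = TRUE)$values)
    if (ev_min < -1e-8 * max(1, max(abs(kinship)))) {
      stop_famlmm("supplied kinship matrix is not positive semidefinite",
                  "famlmm_domain_error")
    }
    if (is.null(family)) family <- attr(kinship, "family")
    if (is.null(family)) {
      stop_famlmm("a supplied kinship needs a family attribute or `family`",
                  "famlmm_domain_error")
    }
    attr(kinship, "family") <- family
  }
  ids <- rownames(kinship)
  fam <- attr(kinship, "family")
  n <- length(ids)
  m <- config$m_markers
  marker_ids <- sprintf("M%04d", seq_len(m))

  with_seed(config$seed, {
    causal_idx <- sort(sample.int(m, config$m_causal))
    if (config$mode == "covariate") {
      X <- goldn_design(n)
      tested <- "exposure"
      # fixed nuisance effects: modest, documented in the vignette
      beta_nuis <- c(`(Intercept)` = 0, exposure = 0, age = 0.01, sex = 0.25,
                     site = 0.25, PC1 = 0.5, PC2 = 0.5, PC3 = 0.5, PC4 = 0.5)
      base_mean <- drop(X %*% beta_nuis)
    } else {
      X <- matrix(1, n, 1, dimnames = list(ids, "(Intercept)"))
      tested <- "(Intercept)"
      base_mean <- numeric(n)
    }
    L <- kinship_sqrt(kinship)
    B <- sqrt(config$sigma2_mu) * (L %*% matrix(stats::rnorm(n * m), n, m))
    E <- sqrt(config$sigma2_eps) * matrix(stats::rnorm(n * m), n, m)
    Y <- B + E + base_mean
    delta <- numeric(m)
    delta[causal_idx] <- config$effect_delta
    if (config$mode == "covariate") {
      Y <- Y + outer(X[, "exposure"], delta)
    } else {
      Y <- Y + matrix(delta, n, m, byrow = TRUE)
    }
    dimnames(Y) <- list(ids, marker_ids)
    truth <- logical(m)
    truth[causal_idx] <- TRUE
    structure(list(responses = Y, X = X, tested = tested, truth = truth,
                   causal = marker_ids[causal_idx], kinship = kinship,
                   ids = ids, family = fam, config = config),
              class = "sim_dataset")
  })
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("<sim_dataset> ", length(x$ids), " individuals (",
      length(unique(x$family)), " families) x ", ncol(x$responses),
      " markers, ", sum(x$truth), " causal, mode = ", x$config$mode,
      ", seed = ", x$config$seed, "\n", sep = "")
  invisible(x)
}

# Internal: design matrix emulating the covariate structure of a
# family-cohort methylation analysis (intercept, tested continuous exposure,
# age, sex, site, 4 orthonormal mean-zero PC-like columns). Uses the current
# RNG stream.
goldn_design <- function(n) {
  if (n < 9) {
    stop_famlmm("need n >= 9 rows for the 9-column covariate design",
                "famlmm_domain_error")
  }
  exposure <- stats::rnorm(n)
  age <- sample(20:80, n, replace = TRUE)
  sex <- stats::rbinom(n, 1, 0.5)
  site <- stats::rbinom(n, 1, 0.5)
  # a constant binary column would break full rank; flip one entry
  if (length(unique(sex)) == 1) sex[1] <- 1 - sex[1]
  if (length(unique(site)) == 1) site[1] <- 1 - site[1]
  R <- matrix(stats::rnorm(n * 4), n, 4)
  Q <- qr.Q(qr(cbind(1, R)))[, 2:5, drop = FALSE]  # orthonormal, mean zero
  X <- cbind(`(Intercept)` = 1, exposure = exposure, age = age, sex = sex,
             site = site, PC1 = Q[, 1], PC2 = Q[, 2], PC3 = Q[, 3],
             PC4 = Q[, 4])
  attr(X, "tested") <- "exposure"
  X
}

#' Emulated family-cohort covariate design
#'
#' Builds an `n x 9` full-rank design emulating the fixed-effect structure of
#' a family methylation cohort: intercept, a standard-normal continuous
#' exposure (the tested covariate), integer age uniform on 20--80, binary
#' sex, binary study site, and 4 mutually orthogonal mean-zero
#' principal-component-like columns.
#'
#' @param n Number of rows (individuals); must be at least 9.
#' @param seed Integer seed.
#' @return An `n x 9` numeric matrix with a `"tested"` attribute naming the
#'   exposure column.
#' @export
emulate_goldn_covariates <- function(n, seed) {
  with_seed(seed, goldn_design(n))
}
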