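# Independent oracles and fixture generators used across the test files.
# These deliberately avoid the package's computational paths: the kinship
# oracle is Monte-Carlo gene dropping, and the likelihood oracle works on
# dense covariance matrices with explicit solves.

# --- random pedigree generator -----------------------------------------
# Builds a random non-inbred pedigree of at most `max_size` members:
# founder couples, children whose parents are drawn from founders of
# different couples (full- and half-sib structures), and optionally a third
# generation through new married-in founder spouses.
random_pedigree <- function(seed, max_size = 10) {
  set.seed(seed)
  n_founder_pairs <- sample(1:2, 1)
  id <- character(0)
  father <- character(0)
  mother <- character(0)
  sex <- character(0)
  add <- function(i, f, m, s) {
    id <<- c(id, i); father <<- c(father, f); mother <<- c(mother, m)
    sex <<- c(sex, s)
  }
  for (p in seq_len(n_founder_pairs)) {
    add(paste0("fa", p), NA, NA, "male")
    add(paste0("mo", p), NA, NA, "female")
  }
  founder_males <- id[sex == "male"]
  founder_females <- id[sex == "female"]
  n_children <- sample(2:(max_size - length(id) - 2), 1)
  children <- character(0)
  for (c_ in seq_len(n_children)) {
    f <- sample(founder_males, 1)
    m <- sample(founder_females, 1)
    ch <- paste0("ch", c_)
    add(ch, f, m, sample(c("male", "female"), 1))
    children <- c(children, ch)
  }
  # third generation: one child gets a married-in (unrelated) spouse
  room <- max_size - length(id)
  if (room >= 2 && stats::runif(1) < 0.6) {
    parent1 <- sample(children, 1)
    spouse_sex <- if (sex[id == parent1] == "male") "female" else "male"
    add("sp1", NA, NA, spouse_sex)
    n_gc <- sample(seq_len(room - 1), 1)
    for (g in seq_len(n_gc)) {
      f <- if (spouse_sex == "female") parent1 else "sp1"
      m <- if (spouse_sex == "female") "sp1" else parent1
      add(paste0("gc", g), f, m, sample(c("male", "female"), 1))
    }
  }
  pedigree(individual_id = id, family_id = "fam1", father_id = father,
           mother_id = mother, sex = sex)
}

# --- gene-dropping kinship oracle --------------------------------------
# Drops two uniquely labelled founder alleles per locus through the
# pedigree and estimates K = 2 * Phi as the average allele-sharing
# probability over n_loci replicate loci. Returns the estimate and its
# per-entry Monte-Carlo standard error.
genedrop_kinship <- function(ped, n_loci = 1e5, seed = 1) {
  set.seed(seed)
  ids <- ped$individual_id
  n <- length(ids)
  fa <- match(ped$father_id, ids)
  mo <- match(ped$mother_id, ids)
  ord <- famlmm:::topological_order(ped)
  a1 <- matrix(0L, n, n_loci)
  a2 <- matrix(0L, n, n_loci)
  next_label <- 1L
  fresh <- function(k) {
    out <- matrix(seq.int(next_label, length.out = k * n_loci),
                  nrow = k)
    next_label <<- next_label + k * n_loci
    out
  }
  for (j in ord) {
    if (is.na(fa[j])) {
      a1[j, ] <- fresh(1)
    } else {
      pick <- stats::runif(n_loci) < 0.5
      a1[j, ] <- ifelse(pick, a1[fa[j], ], a2[fa[j], ])
    }
    if (is.na(mo[j])) {
      a2[j, ] <- fresh(1)
    } else {
      pick <- stats::runif(n_loci) < 0.5
      a2[j, ] <- ifelse(pick, a1[mo[j], ], a2[mo[j], ])
    }
  }
  K_hat <- matrix(0, n, n, dimnames = list(ids, ids))
  K_se <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (i == j) {
        share <- 0.5 * (1 + (a1[i, ] == a2[i, ]))
      } else {
        share <- ((a1[i, ] == a1[j, ]) + (a1[i, ] == a2[j, ]) +
                    (a2[i, ] == a1[j, ]) + (a2[i, ] == a2[j, ])) / 4
      }
      K_hat[i, j] <- K_hat[j, i] <- 2 * mean(share)
      K_se[i, j] <- K_se[j, i] <- 2 * stats::sd(share) / sqrt(n_loci)
    }
  }
  list(estimate = K_hat, se = K_se)
}

# --- dense restricted log-likelihood oracle ----------------------------
# Direct multivariate-normal REML log-likelihood with explicit dense
# solves; independent of the package's spectral rotation.
dense_restricted_loglik <- function(y, X, K, sigma2_mu, sigma2_eps) {
  X <- as.matrix(X)
  n <- length(y)
  p <- ncol(X)
  V <- sigma2_mu * unclass(K) + sigma2_eps * diag(n)
  Vinv <- solve(V)
  XtVinvX <- t(X) %*% Vinv %*% X
  beta <- solve(XtVinvX, t(X) %*% Vinv %*% y)
  r <- y - X %*% beta
  quad <- drop(t(r) %*% Vinv %*% r)
  -0.5 * ((n - p) * log(2 * pi) +
            determinant(V, logarithm = TRUE)$modulus +
            determinant(XtVinvX, logarithm = TRUE)$modulus -
            determinant(t(X) %*% X, logarithm = TRUE)$modulus +
            quad)
}

# Dense REML oracle: coarse 2-D grid on the log variance components
# followed by Nelder-Mead refinement, all on the dense likelihood with
# explicit solves. Independent of the package's spectral profile search.
dense_reml_oracle <- function(y, X, K) {
  f <- function(par) {
    -dense_restricted_loglik(y, X, K, exp(par[1]), exp(par[2]))
  }
  grid <- as.matrix(expand.grid(lmu = seq(-4, 3, length.out = 8),
                                leps = seq(-4, 3, length.out = 8)))
  vals <- apply(grid, 1, f)
  start <- grid[which.min(vals), ]
  opt <- stats::optim(start, f, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 2000))
  list(sigma2_mu = unname(exp(opt$par[1])),
       sigma2_eps = unname(exp(opt$par[2])),
       loglik = -opt$value)
}

# Small default config for fast tests.
small_config <- function(...) {
  args <- list(...)
  defaults <- list(n_families = 30, family_size = 5, m_markers = 50,
                   m_causal = 5, effect_delta = 0.5, seed = 42)
  do.call(sim_config, utils::modifyList(defaults, args))
}

# Strip class/dimnames/family attributes for raw numeric comparison.
bare <- function(K) {
  x <- unclass(as.matrix(K))
  attr(x, "family") <- NULL
  unname(x)
}
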