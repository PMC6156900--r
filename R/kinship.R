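# Kinship / expected-relationship matrices. Convention: K = 2 * Phi where
# Phi is the kinship-coefficient matrix, so K has unit diagonal for non-inbred
# individuals (the GRM convention). The overall scale of K is absorbed by the
# family variance component, so the convention is free but must be consistent.

#' Construct a kinship (expected relationship) matrix object
#'
#' @param values Square numeric matrix, `K = 2 * Phi`.
#' @param ids Character vector of individual ids (row/column names).
#' @param family Optional character vector of family ids aligned with `ids`;
#'   used to draw family representatives downstream.
#' @param validate If `TRUE`, check symmetry, entry range, unit-or-larger
#'   diagonal, and positive semidefiniteness (smallest eigenvalue >= -1e-10).
#' @return An object of class `kinship_matrix`: the numeric matrix with
#'   dimnames `ids` and a `family` attribute.
#' @export
kinship_matrix <- function(values, ids = rownames(values), family = NULL,
                           validate = TRUE) {
  values <- as.matrix(values)
  if (is.null(ids)) ids <- paste0("id", seq_len(nrow(values)))
  ids <- as.character(ids)
  stopifnot(nrow(values) == ncol(values), length(ids) == nrow(values))
  dimnames(values) <- list(ids, ids)
  if (!is.null(family)) {
    stopifnot(length(family) == length(ids))
    family <- as.character(family)
  }
  K <- structure(values, class = c("kinship_matrix", "matrix", "array"),
                 family = family)
  if (validate) validate_kinship(K)
  K
}

#' Validate kinship-matrix invariants
#'
#' Symmetric, entries in `[0, 2]`, diagonal at least 1 (exactly 1 for
#' non-inbred individuals), positive semidefinite with smallest eigenvalue
#' no less than `-1e-10`.
#'
#' @param K A `kinship_matrix`.
#' @return `K`, invisibly.
#' @export
validate_kinship <- function(K) {
  if (!isSymmetric(unclass(K), tol = 1e-10)) {
    stop_famlmm("kinship matrix is not symmetric", "famlmm_domain_error")
  }
  if (any(K < -1e-12) || any(K > 2 + 1e-12)) {
    stop_famlmm("kinship entries must lie in [0, 2]", "famlmm_domain_error")
  }
  if (any(abs(diag(K)) < 1 - 1e-8)) {
    stop_famlmm("kinship diagonal must be at least 1 (K = 2*Phi convention)",
                "famlmm_domain_error")
  }
  ev_min <- min(eigen(unclass(K), symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < -1e-10 * max(1, max(abs(K)))) {
    stop_famlmm(sprintf(
      "kinship matrix is not positive semidefinite (min eigenvalue %.3e)",
      ev_min), "famlmm_domain_error")
  }
  invisible(K)
}

#' @export
print.kinship_matrix <- function(x, ...) {
  cat("<kinship_matrix> ", nrow(x), " x ", ncol(x), sep = "")
  fam <- attr(x, "family")
  if (!is.null(fam)) cat(", ", length(unique(fam)), " families", sep = "")
  cat("\n")
  if (nrow(x) <= 8) print(unclass(x)) else print(unclass(x)[1:6, 1:6])
  invisible(x)
}

#' Expected relationship matrix from a pedigree
#'
#' Computes kinship coefficients by the standard recursion over a
#' topologically ordered pedigree: founders are non-inbred and mutually
#' unrelated, `Phi_jj = (1 + Phi_fm) / 2` where `f`, `m` are the parents of
#' `j` (a missing parent contributes 0), and for `i` preceding `j`,
#' `Phi_ij = (Phi_if + Phi_im) / 2`. Returns `K = 2 * Phi`, block-diagonal
#' across families.
#'
#' @param ped A `pedigree` (or coercible data.frame).
#' @return A `kinship_matrix` in the pedigree's family-major order.
#' @examples
#' sibs <- pedigree(
#'   individual_id = c("f", "m", "s1", "s2"), family_id = "fam1",
#'   father_id = c(NA, NA, "f", "f"), mother_id = c(NA, NA, "m", "m"),
#'   sex = c("male", "female", "unknown", "unknown")
#' )
#' kinship_from_pedigree(sibs)["s1", "s2"]  # 0.5
#' @export
kinship_from_pedigree <- function(ped) {
  ped <- as_pedigree(ped)
  ids <- ped$individual_id
  n <- length(ids)
  fa <- match(ped$father_id, ids)
  mo <- match(ped$mother_id, ids)
  ord <- topological_order(ped)
  Phi <- matrix(0, n, n)
  done <- integer(0)
  for (j in ord) {
    f <- fa[j]
    m <- mo[j]
    Phi[j, j] <- 0.5 * (1 + if (!is.na(f) && !is.na(m)) Phi[f, m] else 0)
    if (length(done) > 0) {
      pf <- if (!is.na(f)) Phi[done, f] else 0
      pm <- if (!is.na(m)) Phi[done, m] else 0
      v <- 0.5 * (pf + pm)
      Phi[done, j] <- v
      Phi[j, done] <- v
    }
    done <- c(done, j)
  }
  kinship_matrix(2 * Phi, ids = ids, family = ped$family_id, validate = FALSE)
}

#' Block-diagonal exchangeable family relationship matrix
#'
#' Builds the kinship structure used for simulated sibship families:
#' `n_families` identical blocks of size `family_size`, each with unit
#' diagonal and constant off-diagonal `within_value` (0.5 for full siblings),
#' zero between families. Positive semidefinite for `within_value` in
#' `[0, 1)`.
#'
#' @param n_families Number of families.
#' @param family_size Individuals per family: a single integer, or a vector
#'   of sizes recycled across families (variable sibship sizes).
#' @param within_value Off-diagonal relationship within a family, in `[0, 1)`.
#' @param family_ids Optional family labels (default `F001`, `F002`, ...).
#' @return A `kinship_matrix` with ids `<family>_<member>`.
#' @examples
#' exchangeable_family_matrix(2, 2, 0.5)
#' exchangeable_family_matrix(4, c(2, 3), 0.5)  # sizes 2, 3, 2, 3
#' @export
exchangeable_family_matrix <- function(n_families, family_size,
                                       within_value = 0.5,
                                       family_ids = NULL) {
  if (n_families < 1 || any(family_size < 1)) {
    stop_famlmm("n_families and family_size must be positive",
                "famlmm_domain_error")
  }
  if (within_value < 0 || within_value >= 1) {
    stop_famlmm("within_value must lie in [0, 1)", "famlmm_domain_error")
  }
  if (is.null(family_ids)) {
    family_ids <- sprintf("F%03d", seq_len(n_families))
  }
  stopifnot(length(family_ids) == n_families)
  sizes <- rep_len(as.integer(family_size), n_families)
  n <- sum(sizes)
  K <- matrix(0, n, n)
  pos <- 0L
  for (b in seq_len(n_families)) {
    idx <- pos + seq_len(sizes[b])
    K[idx, idx] <- within_value
    pos <- pos + sizes[b]
  }
  diag(K) <- 1
  family <- rep(family_ids, times = sizes)
  ids <- paste0(family, "_", unlist(lapply(sizes, seq_len)))
  # PSD by construction: block eigenvalues are 1 - w and 1 + (s - 1) w
  kinship_matrix(K, ids = ids, family = family, validate = FALSE)
}

#' Draw one representative individual per family
#'
#' Uniform draw within each family, reproducible by seed. This is the
#' subsetting step of the "representative" modeling option: the chosen
#' individuals are subsequently treated as independent.
#'
#' @param x A `pedigree`, or a named character vector mapping
#'   `individual_id` to `family_id` (names = individual ids).
#' @param seed Integer seed; the same seed always returns the same set.
#' @return Character vector of individual ids, one per family, named by
#'   family id.
#' @export
select_representatives <- function(x, seed) {
  if (inherits(x, "pedigree") || is.data.frame(x)) {
    fams <- families(as_pedigree(x))
  } else {
    stopifnot(is.character(x), !is.null(names(x)))
    fams <- split(names(x), factor(x, levels = unique(x)))
  }
  if (any(lengths(fams) == 0)) {
    stop_famlmm("every family must be nonempty", "famlmm_validation_error")
  }
  with_seed(seed, {
    vapply(fams, function(ids) ids[sample.int(length(ids), 1)],
           character(1))
  })
}

#' Build the covariance specification for one modeling option
#'
#' The three strategies for family structure differ only in the random-effect
#' covariance they assume: `"kinship"` keeps the full relationship matrix
#' `K`; `"independence"` discards it and substitutes the identity on all
#' individuals; `"representative"` keeps one randomly drawn member per family
#' and uses the identity on that subset.
#'
#' @param option One of `"representative"`, `"kinship"`, `"independence"`.
#' @param kinship A `kinship_matrix` over the full sample.
#' @param representatives For `option = "representative"`, the ids returned
#'   by [select_representatives()].
#' @return An object of class `covariance_spec` with elements `option`,
#'   `matrix` (a `kinship_matrix` over `active_ids`) and `active_ids`.
#' @export
covariance_spec <- function(option = c("representative", "kinship",
                                       "independence"),
                            kinship, representatives = NULL) {
  option <- match.arg(option)
  stopifnot(inherits(kinship, "kinship_matrix"))
  ids <- rownames(kinship)
  fam <- attr(kinship, "family")
  if (option == "kinship") {
    mat <- kinship
    active <- ids
  } else if (option == "independence") {
    mat <- kinship_matrix(diag(length(ids)), ids = ids, family = fam,
                          validate = FALSE)
    active <- ids
  } else {
    if (is.null(representatives)) {
      stop_famlmm("the representative option requires `representatives`",
                  "famlmm_usage_error")
    }
    representatives <- as.character(representatives)
    if (!all(representatives %in% ids)) {
      stop_famlmm("representatives must be ids of the kinship matrix",
                  "famlmm_usage_error")
    }
    active <- ids[ids %in% representatives]  # keep matrix order
    mat <- kinship_matrix(diag(length(active)), ids = active,
                          family = if (!is.null(fam)) fam[ids %in% active],
                          validate = FALSE)
  }
  structure(list(option = option, matrix = mat, active_ids = active),
            class = "covariance_spec")
}

#' @export
print.covariance_spec <- function(x, ...) {
  cat("<covariance_spec> option =", x$option, "|", length(x$active_ids),
      "active individuals\n")
  invisible(x)
}

#' Write a kinship matrix as tab-separated text
#'
#' Square TSV with a header row of individual ids; values are printed with 12
#' significant digits.
#'
#' @param K A `kinship_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_kinship <- function(K, path) {
  stopifnot(inherits(K, "kinship_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(rownames(K), collapse = "\t"), con)
  apply_fmt <- function(row) paste(formatC(row, digits = 12, format = "g"),
                                   collapse = "\t")
  writeLines(vapply(seq_len(nrow(K)), function(i) apply_fmt(K[i, ]),
                    character(1)), con)
  invisible(path)
}

#' Read a kinship matrix written by [write_kinship()]
#'
#' @param path Path to the TSV file.
#' @param family Optional family vector aligned with the ids.
#' @param validate Check invariants (default `TRUE`).
#' @return A `kinship_matrix`.
#' @export
read_kinship <- function(path, family = NULL, validate = TRUE) {
  lines <- readLines(path)
  ids <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  vals <- do.call(rbind, lapply(lines[-1], function(l) {
    as.numeric(strsplit(l, "\t", fixed = TRUE)[[1]])
  }))
  if (is.null(family) && all(grepl("_", ids))) {
    family <- sub("_[^_]*$", "", ids)
  }
  kinship_matrix(vals, ids = ids, family = family, validate = validate)
}
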