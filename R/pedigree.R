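# Pedigree container: a validated data.frame of individuals with family and
# parent links, ordered family-major then by insertion order. All kinship
# matrices and simulated vectors share this ordering.

#' Construct a pedigree
#'
#' Builds a validated pedigree from per-individual vectors. Individuals are
#' reordered family-major (families in order of first appearance, insertion
#' order within family); every matrix or vector produced downstream follows
#' this ordering.
#'
#' @param individual_id Character vector of unique individual identifiers.
#' @param family_id Character vector of family identifiers.
#' @param father_id,mother_id Character vectors of parent identifiers;
#'   `NA` (or `"0"`, the PLINK missing code) marks an unknown parent. A
#'   present parent must resolve to an individual in the same family.
#' @param sex Character vector with values `"male"`, `"female"` or
#'   `"unknown"`.
#' @return An object of class `pedigree` (a data.frame with columns
#'   `individual_id`, `family_id`, `father_id`, `mother_id`, `sex`).
#' @examples
#' ped <- pedigree(
#'   individual_id = c("dad", "mom", "kid1", "kid2"),
#'   family_id = "fam1",
#'   father_id = c(NA, NA, "dad", "dad"),
#'   mother_id = c(NA, NA, "mom", "mom"),
#'   sex = c("male", "female", "unknown", "unknown")
#' )
#' @export
pedigree <- function(individual_id, family_id, father_id = NA_character_,
                     mother_id = NA_character_, sex = "unknown") {
  n <- length(individual_id)
  df <- data.frame(
    individual_id = as.character(individual_id),
    family_id = rep_len(as.character(family_id), n),
    father_id = rep_len(as.character(father_id), n),
    mother_id = rep_len(as.character(mother_id), n),
    sex = rep_len(as.character(sex), n),
    stringsAsFactors = FALSE
  )
  as_pedigree(df)
}

#' Coerce a data.frame to a pedigree
#'
#' @param x A data.frame with columns `individual_id`, `family_id`,
#'   `father_id`, `mother_id` and optionally `sex`.
#' @return A validated `pedigree`.
#' @export
as_pedigree <- function(x) {
  if (inherits(x, "pedigree")) return(x)
  stopifnot(is.data.frame(x))
  required <- c("individual_id", "family_id", "father_id", "mother_id")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    stop_famlmm(paste0("pedigree data.frame lacks column(s): ",
                       paste(missing_cols, collapse = ", ")),
                "famlmm_validation_error")
  }
  if (is.null(x$sex)) x$sex <- "unknown"
  for (col in c(required, "sex")) x[[col]] <- as.character(x[[col]])
  x$father_id[x$father_id %in% c("0", "")] <- NA_character_
  x$mother_id[x$mother_id %in% c("0", "")] <- NA_character_
  # family-major ordering: families by first appearance, then insertion order
  fam_order <- match(x$family_id, unique(x$family_id))
  x <- x[order(fam_order), c(required, "sex"), drop = FALSE]
  rownames(x) <- NULL
  ped <- structure(x, class = c("pedigree", "data.frame"))
  validate_pedigree(ped)
  ped
}

#' Validate pedigree invariants
#'
#' Checks that identifiers are unique, parent links resolve within the same
#' family, sex codes are recognized, and no individual is its own ancestor.
#' Errors are structured conditions of class `famlmm_validation_error` naming
#' the offending individual.
#'
#' @param ped A `pedigree`.
#' @return `ped`, invisibly.
#' @export
validate_pedigree <- function(ped) {
  ids <- ped$individual_id
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    stop_famlmm(paste0("duplicated individual_id: ", dup[1]),
                "famlmm_validation_error")
  }
  bad_sex <- !ped$sex %in% c("male", "female", "unknown")
  if (any(bad_sex)) {
    stop_famlmm(paste0("individual ", ids[which(bad_sex)[1]],
                       " has unrecognized sex code '",
                       ped$sex[which(bad_sex)[1]], "'"),
                "famlmm_validation_error")
  }
  for (col in c("father_id", "mother_id")) {
    parent <- ped[[col]]
    present <- !is.na(parent)
    unresolved <- present & !(parent %in% ids)
    if (any(unresolved)) {
      i <- which(unresolved)[1]
      stop_famlmm(paste0("individual ", ids[i], " has ", col, " '",
                         parent[i], "' that is not in the pedigree"),
                  "famlmm_validation_error")
    }
    cross <- present & (ped$family_id[match(parent, ids)] != ped$family_id)
    cross[is.na(cross)] <- FALSE
    if (any(cross)) {
      i <- which(cross)[1]
      stop_famlmm(paste0("individual ", ids[i], " has ", col, " '",
                         parent[i], "' from a different family"),
                  "famlmm_validation_error")
    }
  }
  topological_order(ped)  # errors on cycles
  invisible(ped)
}

# Topological order (parents before children); errors on cycles naming an
# individual on the cycle.
topological_order <- function(ped) {
  ids <- ped$individual_id
  n <- length(ids)
  fa <- match(ped$father_id, ids)
  mo <- match(ped$mother_id, ids)
  placed <- logical(n)
  parent_ok <- function(p) is.na(p) | placed[ifelse(is.na(p), 1L, p)]
  order_out <- integer(0)
  repeat {
    ready <- !placed & parent_ok(fa) & parent_ok(mo)
    if (!any(ready)) break
    order_out <- c(order_out, which(ready))
    placed[ready] <- TRUE
  }
  if (!all(placed)) {
    stop_famlmm(paste0("individual ", ids[which(!placed)[1]],
                       " is part of an ancestry cycle"),
                "famlmm_validation_error")
  }
  order_out
}

#' Split individual ids by family
#'
#' @param ped A `pedigree`.
#' @return A named list of character vectors, one per family, in order of
#'   first appearance.
#' @export
families <- function(ped) {
  ped <- as_pedigree(ped)
  split(ped$individual_id, factor(ped$family_id, levels = unique(ped$family_id)))
}

#' @export
print.pedigree <- function(x, ...) {
  cat("<pedigree> ", nrow(x), " individuals in ",
      length(unique(x$family_id)), " families\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("... (", nrow(x) - 10, " more rows)\n", sep = "")
  invisible(x)
}

#' Read a PLINK-style .fam pedigree file
#'
#' Whitespace-delimited columns `FID IID PAT MAT SEX PHENO`; `0` denotes a
#' missing parent, sex codes are 1 = male, 2 = female, 0 = unknown. The
#' phenotype column is ignored.
#'
#' @param path Path to the .fam file.
#' @return A `pedigree`.
#' @export
read_fam <- function(path) {
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 5) {
    stop_famlmm("a .fam file needs at least 5 columns (FID IID PAT MAT SEX)",
                "famlmm_validation_error")
  }
  names(df)[1:5] <- c("family_id", "individual_id", "father_id", "mother_id",
                      "sex_code")
  df$sex <- c("0" = "unknown", "1" = "male", "2" = "female")[df$sex_code]
  df$sex[is.na(df$sex)] <- "unknown"
  as_pedigree(df[, c("individual_id", "family_id", "father_id", "mother_id",
                     "sex")])
}

#' Write a pedigree as a PLINK-style .fam file
#'
#' @param ped A `pedigree`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fam <- function(ped, path) {
  ped <- as_pedigree(ped)
  sex_code <- c(male = "1", female = "2", unknown = "0")[ped$sex]
  out <- data.frame(ped$family_id, ped$individual_id,
                    ifelse(is.na(ped$father_id), "0", ped$father_id),
                    ifelse(is.na(ped$mother_id), "0", ped$mother_id),
                    sex_code, "-9")
  utils::write.table(out, path, sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
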