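# Plain-text readers and writers: dataset TSVs with a key:value config
# sidecar, association tables, Manhattan exports, study reports, and run
# manifests.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE, ...)
}

#' Write a simulation config as flat key:value text
#'
#' @param config A [sim_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  lines <- vapply(names(config), function(k) {
    v <- config[[k]]
    paste0(k, ": ", if (is.numeric(v)) {
      paste(format(v, digits = 17), collapse = ",")
    } else v)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a simulation config written by [write_sim_config()]
#'
#' Unknown keys raise an error naming the key; missing keys fall back to the
#' defaults of [sim_config()].
#'
#' @param path Path to the key:value file.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  lines <- grep("^\\s*(#|$)", readLines(path), invert = TRUE, value = TRUE)
  parts <- regmatches(lines, regexec("^\\s*([^:]+?)\\s*:\\s*(.*)$", lines))
  kv <- stats::setNames(vapply(parts, `[`, character(1), 3),
                        vapply(parts, `[`, character(1), 2))
  known <- names(formals(sim_config))
  bad <- setdiff(names(kv), known)
  if (length(bad) > 0) {
    stop_famlmm(paste0("unknown config key(s): ", paste(bad, collapse = ", ")),
                "famlmm_usage_error")
  }
  args <- lapply(names(kv), function(k) {
    if (k == "mode") {
      kv[[k]]
    } else {
      as.numeric(strsplit(kv[[k]], ",", fixed = TRUE)[[1]])
    }
  })
  names(args) <- names(kv)
  do.call(sim_config, args)
}

#' Write a simulated dataset as plain-text TSV files
#'
#' Creates `phenotypes.tsv` (rows = individuals, columns = marker
#' responses), `covariates.tsv`, `truth.tsv` (marker id and causal flag) and
#' a `config.txt` key:value sidecar capturing every generating parameter and
#' seed. The default exchangeable kinship structure is regenerated from the
#' sidecar on read; a custom kinship matrix is written to `kinship.tsv`.
#'
#' @param dataset A [simulate_dataset()] result.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "sim_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  phen <- data.frame(individual_id = dataset$ids, family_id = dataset$family,
                     dataset$responses, check.names = FALSE)
  write_tsv(phen, file.path(dir, "phenotypes.tsv"))
  cov <- data.frame(individual_id = dataset$ids, as.data.frame(dataset$X),
                    check.names = FALSE)
  write_tsv(cov, file.path(dir, "covariates.tsv"))
  write_tsv(data.frame(marker_id = colnames(dataset$responses),
                       causal = as.integer(dataset$truth)),
            file.path(dir, "truth.tsv"))
  write_sim_config(dataset$config, file.path(dir, "config.txt"))
  default_K <- exchangeable_family_matrix(dataset$config$n_families,
                                          dataset$config$family_size,
                                          dataset$config$within_value)
  if (!identical(dim(default_K), dim(dataset$kinship)) ||
      max(abs(unclass(default_K) - unclass(dataset$kinship))) > 1e-12) {
    write_kinship(dataset$kinship, file.path(dir, "kinship.tsv"))
  }
  invisible(dir)
}

#' Read a dataset directory written by [write_dataset()]
#'
#' @param dir Dataset directory.
#' @return A `sim_dataset`.
#' @export
read_dataset <- function(dir) {
  config <- read_sim_config(file.path(dir, "config.txt"))
  phen <- read_tsv(file.path(dir, "phenotypes.tsv"))
  ids <- phen$individual_id
  family <- phen$family_id
  Y <- as.matrix(phen[, -(1:2), drop = FALSE])
  rownames(Y) <- ids
  cov <- read_tsv(file.path(dir, "covariates.tsv"))
  X <- as.matrix(cov[, -1, drop = FALSE])
  rownames(X) <- ids
  truth_df <- read_tsv(file.path(dir, "truth.tsv"))
  truth <- as.logical(truth_df$causal[match(colnames(Y),
                                            truth_df$marker_id)])
  kin_path <- file.path(dir, "kinship.tsv")
  K <- if (file.exists(kin_path)) {
    read_kinship(kin_path, family = family)
  } else {
    exchangeable_family_matrix(config$n_families, config$family_size,
                               config$within_value)
  }
  tested <- if (config$mode == "covariate") "exposure" else "(Intercept)"
  attr(X, "tested") <- tested
  structure(list(responses = Y, X = X, tested = tested, truth = truth,
                 causal = colnames(Y)[truth], kinship = K, ids = ids,
                 family = family, config = config),
            class = "sim_dataset")
}

#' Write an association table as TSV
#'
#' Columns: `marker_id`, `option`, `n_used`, `estimate`, `std_error`,
#' `statistic`, `p_value`, `sigma2_mu`, `sigma2_eps`, `boundary`.
#'
#' @param results Data.frame from [fit_all()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_association <- function(results, path) {
  write_tsv(results, path)
}

#' Read an association TSV written by [write_association()]
#' @param path Path to the TSV.
#' @return A data.frame.
#' @export
read_association <- function(path) {
  read_tsv(path)
}

#' Write a Manhattan-style export (marker index vs -log10 p)
#'
#' @param results Association data.frame (single option).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manhattan <- function(results, path) {
  write_tsv(data.frame(index = seq_len(nrow(results)),
                       marker_id = results$marker_id,
                       neg_log10_p = -log10(results$p_value)),
            path)
}

#' Write a replicate-study report
#'
#' Produces `venn_runs.tsv` and `recovery_runs.tsv` (per-run values),
#' `venn_summary.tsv`, `recovery_summary.tsv` and `pairwise_overlap.tsv`
#' (mean and SD columns), and `summary.txt`, a plain-text digest laying out
#' the Venn regions as "mean +/- SD".
#'
#' @param study A [run_study()] result.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_study_report <- function(study, dir) {
  stopifnot(inherits(study, "family_study"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_tsv(study$venn, file.path(dir, "venn_runs.tsv"))
  write_tsv(study$recovery, file.path(dir, "recovery_runs.tsv"))
  write_tsv(study$venn_summary, file.path(dir, "venn_summary.tsv"))
  write_tsv(study$recovery_summary, file.path(dir, "recovery_summary.tsv"))
  write_tsv(study$pairwise, file.path(dir, "pairwise_overlap.tsv"))
  con <- file(file.path(dir, "summary.txt"), "w")
  on.exit(close(con))
  sink(con)
  print(study)
  sink()
  invisible(dir)
}

#' Write a run manifest
#'
#' Flat key:value text capturing the configuration echo, package version,
#' every derived seed, input/output paths and a timestamp — enough to
#' reproduce the run. Written before any output table by the analysis
#' drivers.
#'
#' @param path Output path.
#' @param config A `sim_config` (echoed with a `config.` prefix).
#' @param seeds Named list or vector of derived seeds.
#' @param files Named list or vector of input/output paths.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, config = NULL, seeds = NULL, files = NULL) {
  lines <- c(
    paste0("package_version: ",
           as.character(utils::packageVersion("famlmm"))),
    paste0("timestamp: ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  )
  if (!is.null(config)) {
    lines <- c(lines, vapply(names(config), function(k) {
      paste0("config.", k, ": ",
             paste(format(config[[k]], digits = 17), collapse = ","))
    }, character(1)))
  }
  if (!is.null(seeds)) {
    lines <- c(lines, vapply(names(seeds), function(k) {
      paste0("seed.", k, ": ", format(seeds[[k]]))
    }, character(1)))
  }
  if (!is.null(files)) {
    lines <- c(lines, vapply(names(files), function(k) {
      paste0("file.", k, ": ", files[[k]])
    }, character(1)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a manifest written by [write_manifest()]
#' @param path Manifest path.
#' @return Named character vector of key/value pairs.
#' @export
read_manifest <- function(path) {
  lines <- readLines(path)
  parts <- regmatches(lines, regexec("^([^:]+):\\s*(.*)$", lines))
  stats::setNames(vapply(parts, `[`, character(1), 3),
                  vapply(parts, `[`, character(1), 2))
}
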