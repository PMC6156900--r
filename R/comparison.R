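# Comparison harness: top-k marker sets per modeling option, three-way Venn
# region counts, truth recovery / false discovery rates, the nestedness
# diagnostic, the hybrid (independence intersect representative) strategy,
# and the replicate study driver that aggregates mean +/- SD across runs.

#' Top-k markers of an association table
#'
#' Orders one option's association results by ascending p-value, breaking
#' ties by ascending marker index (row order), and keeps the first
#' `min(k, m)` markers.
#'
#' @param results An association data.frame from [fit_all()] containing a
#'   single option.
#' @param k Number of markers to keep (`k >= 1`).
#' @param run_id Optional run label carried into the result.
#' @return An object of class `topk_set`: list with `option`, `run_id`,
#'   `k`, and `marker_ids` (ordered).
#' @export
top_k <- function(results, k, run_id = NA_integer_) {
  if (k < 1) stop_famlmm("k must be at least 1", "famlmm_usage_error")
  opts <- unique(results$option)
  if (length(opts) != 1) {
    stop_famlmm("top_k expects a single option per table",
                "famlmm_usage_error")
  }
  ord <- order(results$p_value, seq_len(nrow(results)))
  take <- ord[seq_len(min(k, nrow(results)))]
  structure(list(option = opts, run_id = run_id, k = as.integer(k),
                 marker_ids = results$marker_id[take]),
            class = "topk_set")
}

#' @export
print.topk_set <- function(x, ...) {
  cat("<topk_set> option =", x$option, "| k =", x$k, "|",
      length(x$marker_ids), "markers\n")
  invisible(x)
}

topk_ids <- function(x) {
  if (inherits(x, "topk_set")) x$marker_ids else as.character(x)
}

#' Markers passing a p-value threshold
#'
#' Alternative, non-default selection mode: instead of a fixed-size top-k
#' set, keep every marker with `p < alpha`, optionally Bonferroni-corrected
#' for the number of markers in the table. The result is ordered like
#' [top_k()] (ascending p, ties by index) and can be fed to the same
#' Venn/recovery machinery.
#'
#' @param results Association data.frame (single option).
#' @param alpha Significance level (default 0.05).
#' @param bonferroni If `TRUE`, use `alpha / m` as the per-marker cutoff.
#' @param run_id Optional run label.
#' @return A `topk_set` whose `k` is the number of selected markers (0 is
#'   possible).
#' @export
significant_markers <- function(results, alpha = 0.05, bonferroni = FALSE,
                                run_id = NA_integer_) {
  opts <- unique(results$option)
  if (length(opts) != 1) {
    stop_famlmm("significant_markers expects a single option per table",
                "famlmm_usage_error")
  }
  if (alpha <= 0 || alpha > 1) {
    stop_famlmm("alpha must lie in (0, 1]", "famlmm_usage_error")
  }
  cutoff <- if (bonferroni) alpha / nrow(results) else alpha
  keep <- which(results$p_value < cutoff)
  ord <- keep[order(results$p_value[keep], keep)]
  structure(list(option = opts, run_id = run_id, k = length(ord),
                 marker_ids = results$marker_id[ord]),
            class = "topk_set")
}

#' Three-way Venn region counts
#'
#' Counts the seven mutually exclusive regions of the Venn diagram of three
#' marker sets, labelled A (representative), B (kinship), C (independence).
#'
#' @param A,B,C `topk_set` objects or character vectors of marker ids.
#' @param run_id Optional run label.
#' @return An object of class `venn_summary`: named integer vector over
#'   regions `A`, `B`, `C`, `AB`, `AC`, `BC`, `ABC` (each exclusive), with a
#'   `run_id` attribute. Region counts containing a given set sum to that
#'   set's size.
#' @export
venn_counts <- function(A, B, C, run_id = NA_integer_) {
  a <- unique(topk_ids(A))
  b <- unique(topk_ids(B))
  c_ <- unique(topk_ids(C))
  u <- unique(c(a, b, c_))
  ina <- u %in% a
  inb <- u %in% b
  inc <- u %in% c_
  counts <- c(
    A = sum(ina & !inb & !inc),
    B = sum(!ina & inb & !inc),
    C = sum(!ina & !inb & inc),
    AB = sum(ina & inb & !inc),
    AC = sum(ina & !inb & inc),
    BC = sum(!ina & inb & inc),
    ABC = sum(ina & inb & inc)
  )
  structure(counts, run_id = run_id, class = c("venn_summary", "integer"))
}

#' Truth recovery of a top-k set
#'
#' @param topk A `topk_set` (or character vector of marker ids).
#' @param truth Character vector of true causal marker ids (nonempty).
#' @param option Optional label override.
#' @return A one-row data.frame: `option`, `size`, `true_positives`,
#'   `fdr = (size - true_positives) / size` (`NA` for an empty set).
#' @export
recovery <- function(topk, truth, option = NULL) {
  truth <- as.character(truth)
  if (length(truth) == 0) {
    stop_famlmm("truth set must be nonempty", "famlmm_usage_error")
  }
  ids <- topk_ids(topk)
  if (is.null(option)) {
    option <- if (inherits(topk, "topk_set")) topk$option else "set"
  }
  size <- length(ids)
  tp <- length(intersect(ids, truth))
  data.frame(option = option, size = size, true_positives = tp,
             fdr = if (size > 0) (size - tp) / size else NA_real_,
             stringsAsFactors = FALSE)
}

#' Hybrid strategy: intersection of independence and representative hits
#'
#' When kinship information is unavailable, markers identified by both the
#' independence scan and the representative scan form the hybrid set; on
#' average it trades set size for a lower false discovery rate than the
#' independence scan alone.
#'
#' @param indep_topk,rep_topk `topk_set` objects (or id vectors) over the
#'   same marker universe.
#' @return Character vector of marker ids (in the independence ordering).
#' @export
hybrid_set <- function(indep_topk, rep_topk) {
  intersect(topk_ids(indep_topk), topk_ids(rep_topk))
}

#' Nestedness diagnostic for the three options' top-k sets
#'
#' Under the idealized expectation the significant sets should nest:
#' representative within kinship within independence. Real and simulated
#' data usually violate this; the report only measures the departures and
#' never asserts nestedness.
#'
#' @param rep,kin,indep `topk_set` objects with equal `k`.
#' @return List with escape counts `n_rep_not_kin`, `n_kin_not_indep` and
#'   logical flags `rep_in_kin`, `kin_in_indep`.
#' @export
nestedness_report <- function(rep, kin, indep) {
  ks <- c(rep$k, kin$k, indep$k)
  if (length(unique(ks)) != 1) {
    stop_famlmm("nestedness_report requires equal k across options",
                "famlmm_usage_error")
  }
  r <- topk_ids(rep)
  k <- topk_ids(kin)
  i <- topk_ids(indep)
  list(n_rep_not_kin = length(setdiff(r, k)),
       n_kin_not_indep = length(setdiff(k, i)),
       rep_in_kin = all(r %in% k),
       kin_in_indep = all(k %in% i))
}

#' Replicate simulation study comparing the three modeling options
#'
#' For each of `n_replicates` independently simulated datasets: fit the
#' kinship and independence options once, fit the representative option for
#' each of `n_representative_draws` fresh one-per-family draws, form top-k
#' sets, and record Venn region counts (A = representative, B = kinship,
#' C = independence), truth recovery per option, and the hybrid
#' (independence intersect representative) set. One run = one (replicate,
#' draw) pair; the kinship and independence results are constant across
#' draws within a replicate and are repeated in the per-run table so that
#' pooled aggregation weights runs equally. Aggregates are the sample mean
#' and sample standard deviation (denominator `n - 1`) across runs. All
#' seeds are derived from `config$seed` via [derive_seed()] and logged.
#'
#' @param config A [sim_config()]; `config$seed` drives the whole study.
#' @param n_replicates Number of independent simulated datasets (default 3).
#' @param n_representative_draws Representative draws per dataset
#'   (default 5).
#' @param k Top-k set size (default 20).
#' @param vc_method Variance-component method for the kinship option.
#' @return An object of class `family_study`: list with per-run data.frames
#'   `venn` and `recovery`, aggregate data.frames `venn_summary` and
#'   `recovery_summary` (mean, sd), `pairwise` mean top-k overlaps between
#'   options, the `seeds` log, and the call parameters.
#' @export
run_study <- function(config, n_replicates = 3, n_representative_draws = 5,
                      k = 20, vc_method = c("reml", "anova_mom")) {
  vc_method <- match.arg(vc_method)
  stopifnot(inherits(config, "sim_config"),
            n_replicates >= 1, n_representative_draws >= 1)
  venn_rows <- list()
  rec_rows <- list()
  seed_rows <- list()
  for (r in seq_len(n_replicates)) {
    rep_cfg <- config
    rep_cfg$seed <- derive_seed(config$seed, 1, r)
    ds <- simulate_dataset(rep_cfg)
    truth_ids <- colnames(ds$responses)[ds$truth]
    kin_res <- fit_all(ds, "kinship", vc_method = vc_method)
    ind_res <- fit_all(ds, "independence")
    kin_top <- top_k(kin_res, k, run_id = r)
    ind_top <- top_k(ind_res, k, run_id = r)
    seed_rows[[length(seed_rows) + 1]] <-
      data.frame(replicate = r, draw = NA_integer_, role = "dataset",
                 seed = rep_cfg$seed)
    for (d in seq_len(n_representative_draws)) {
      draw_seed <- derive_seed(config$seed, 2, r, d)
      rep_res <- fit_all(ds, "representative", representative_seed = draw_seed)
      rep_top <- top_k(rep_res, k, run_id = r)
      seed_rows[[length(seed_rows) + 1]] <-
        data.frame(replicate = r, draw = d, role = "representative_draw",
                   seed = draw_seed)
      vc <- venn_counts(rep_top, kin_top, ind_top)
      venn_rows[[length(venn_rows) + 1]] <-
        cbind(data.frame(replicate = r, draw = d),
              as.data.frame(as.list(unclass(vc))))
      hyb <- hybrid_set(ind_top, rep_top)
      rec <- rbind(
        cbind(data.frame(replicate = r, draw = d),
              recovery(rep_top, truth_ids)),
        cbind(data.frame(replicate = r, draw = d),
              recovery(kin_top, truth_ids)),
        cbind(data.frame(replicate = r, draw = d),
              recovery(ind_top, truth_ids)),
        cbind(data.frame(replicate = r, draw = d),
              recovery(hyb, truth_ids, option = "hybrid"))
      )
      rec_rows[[length(rec_rows) + 1]] <- rec
    }
  }
  venn <- do.call(rbind, venn_rows)
  recov <- do.call(rbind, rec_rows)
  regions <- c("A", "B", "C", "AB", "AC", "BC", "ABC")
  venn_summary <- data.frame(
    region = regions,
    mean = vapply(regions, function(g) mean(venn[[g]]), numeric(1)),
    sd = vapply(regions, function(g) stats::sd(venn[[g]]), numeric(1)),
    row.names = NULL
  )
  opts <- c("representative", "kinship", "independence", "hybrid")
  recovery_summary <- do.call(rbind, lapply(opts, function(o) {
    sub <- recov[recov$option == o, ]
    data.frame(option = o,
               mean_size = mean(sub$size), sd_size = stats::sd(sub$size),
               mean_true_positives = mean(sub$true_positives),
               sd_true_positives = stats::sd(sub$true_positives),
               mean_fdr = mean(sub$fdr, na.rm = TRUE),
               sd_fdr = stats::sd(sub$fdr, na.rm = TRUE))
  }))
  # pairwise top-k overlaps, from the exclusive regions
  pairwise <- data.frame(
    pair = c("kinship_independence", "kinship_representative",
             "representative_independence"),
    mean_overlap = c(mean(venn$BC + venn$ABC), mean(venn$AB + venn$ABC),
                     mean(venn$AC + venn$ABC)),
    sd_overlap = c(stats::sd(venn$BC + venn$ABC),
                   stats::sd(venn$AB + venn$ABC),
                   stats::sd(venn$AC + venn$ABC))
  )
  structure(list(venn = venn, recovery = recov, venn_summary = venn_summary,
                 recovery_summary = recovery_summary, pairwise = pairwise,
                 seeds = do.call(rbind, seed_rows), config = config,
                 n_replicates = n_replicates,
                 n_representative_draws = n_representative_draws, k = k,
                 vc_method = vc_method),
            class = "family_study")
}

#' @export
print.family_study <- function(x, ...) {
  cat("<family_study> ", x$n_replicates, " replicates x ",
      x$n_representative_draws, " representative draws, top-", x$k,
      " sets (", x$vc_method, ")\n\n", sep = "")
  cat("Venn regions (A = representative, B = kinship, C = independence),",
      "mean +/- SD across runs:\n")
  vs <- x$venn_summary
  for (i in seq_len(nrow(vs))) {
    cat(sprintf("  %-4s %5.2f +/- %.2f\n", vs$region[i], vs$mean[i],
                vs$sd[i]))
  }
  cat("\nTruth recovery (of", sum(x$config$m_causal), "causal markers):\n")
  rs <- x$recovery_summary
  for (i in seq_len(nrow(rs))) {
    cat(sprintf("  %-15s size %5.2f | true positives %5.2f +/- %.2f | FDR %.3f\n",
                rs$option[i], rs$mean_size[i], rs$mean_true_positives[i],
                rs$sd_true_positives[i], rs$mean_fdr[i]))
  }
  invisible(x)
}
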