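fake_results <- function(p, option = "kinship") {
  data.frame(marker_id = sprintf("M%04d", seq_along(p)), option = option,
             n_used = 100L, estimate = 0, std_error = 1, statistic = 0,
             p_value = p, sigma2_mu = NA_real_, sigma2_eps = NA_real_,
             boundary = NA, stringsAsFactors = FALSE)
}

test_that("top_k orders by p-value with index tie-break", {
  # ties broken by ascending marker index
  tk <- top_k(fake_results(c(0.2, 0.1, 0.1)), 2)
  expect_equal(tk$marker_ids, c("M0002", "M0003"))

  # k larger than m returns everything, in order
  tk_all <- top_k(fake_results(c(0.5, 0.2, 0.9)), 10)
  expect_equal(tk_all$marker_ids, c("M0002", "M0001", "M0003"))

  # random table agrees with an exhaustive sort oracle
  set.seed(61)
  p <- runif(100)
  tk20 <- top_k(fake_results(p), 20)
  oracle <- sprintf("M%04d", order(p)[1:20])
  expect_equal(tk20$marker_ids, oracle)

  mixed <- rbind(fake_results(c(0.1), "kinship"),
                 fake_results(c(0.2), "independence"))
  expect_error(top_k(mixed, 1), class = "famlmm_usage_error")
  expect_error(top_k(fake_results(0.5), 0), class = "famlmm_usage_error")
})

test_that("venn_counts enumerates the seven exclusive regions", {
  s <- as.character(1:20)
  all_same <- venn_counts(s, s, s)
  expect_equal(unname(unclass(all_same)), c(0, 0, 0, 0, 0, 0, 20),
               ignore_attr = TRUE)

  disj <- venn_counts(as.character(1:20), as.character(21:40),
                      as.character(41:60))
  expect_equal(unname(unclass(disj)[c("A", "B", "C")]), c(20, 20, 20))
  expect_equal(sum(unclass(disj)[c("AB", "AC", "BC", "ABC")]), 0)

  v <- venn_counts(c("1", "2", "3"), c("2", "3", "4"), c("3", "4", "5"))
  expect_equal(unclass(v)[["ABC"]], 1)
  expect_equal(unclass(v)[["AB"]], 1)
  expect_equal(unclass(v)[["BC"]], 1)
  expect_equal(unclass(v)[["AC"]], 0)
  expect_equal(unclass(v)[["A"]], 1)
  expect_equal(unclass(v)[["B"]], 0)
  expect_equal(unclass(v)[["C"]], 1)
})

test_that("venn regions containing a set sum to that set's size", {
  set.seed(62)
  for (i in 1:20) {
    universe <- as.character(1:50)
    A <- sample(universe, 15)
    B <- sample(universe, 15)
    C <- sample(universe, 15)
    v <- unclass(venn_counts(A, B, C))
    expect_equal(sum(v[c("A", "AB", "AC", "ABC")]), 15)
    expect_equal(sum(v[c("B", "AB", "BC", "ABC")]), 15)
    expect_equal(sum(v[c("C", "AC", "BC", "ABC")]), 15)
    expect_equal(sum(v), length(unique(c(A, B, C))))
  }
})

test_that("recovery computes overlap and false discovery rate", {
  truth <- sprintf("M%04d", 1:10)
  expect_equal(recovery(truth[1:5], truth)$fdr, 0)          # subset of truth
  expect_equal(recovery(sprintf("X%d", 1:8), truth)$fdr, 1) # disjoint
  r <- recovery(c(truth, sprintf("X%d", 1:10)), truth)      # k=20, 10 true
  expect_equal(r$true_positives, 10)
  expect_equal(r$fdr, 0.5)
  expect_error(recovery(truth, character(0)), class = "famlmm_usage_error")
})

test_that("hybrid set is the intersection and always a subset of both parents", {
  a <- as.character(1:20)
  expect_equal(hybrid_set(a, a), a)
  expect_length(hybrid_set(as.character(1:10), as.character(11:20)), 0)
  set.seed(63)
  for (i in 1:10) {
    x <- sample(as.character(1:40), 20)
    y <- sample(as.character(1:40), 20)
    h <- hybrid_set(x, y)
    expect_true(all(h %in% x))
    expect_true(all(h %in% y))
  }
})

test_that("nestedness report measures departures without asserting nesting", {
  mk <- function(ids, option) {
    structure(list(option = option, run_id = NA, k = length(ids),
                   marker_ids = as.character(ids)), class = "topk_set")
  }
  nested <- nestedness_report(mk(1:5, "representative"),
                              mk(1:5, "kinship"),
                              mk(1:5, "independence"))
  expect_true(nested$rep_in_kin)
  expect_true(nested$kin_in_indep)
  expect_equal(nested$n_rep_not_kin, 0)

  disj <- nestedness_report(mk(1:5, "representative"),
                            mk(6:10, "kinship"),
                            mk(11:15, "independence"))
  expect_equal(disj$n_rep_not_kin, 5)
  expect_equal(disj$n_kin_not_indep, 5)
  expect_false(disj$rep_in_kin)

  expect_error(nestedness_report(mk(1:5, "a"), mk(1:4, "b"), mk(1:5, "c")),
               class = "famlmm_usage_error")
})

test_that("run_study is reproducible and satisfies its structural invariants", {
  cfg <- small_config(seed = 71)
  st1 <- run_study(cfg, n_replicates = 2, n_representative_draws = 2, k = 10)
  st2 <- run_study(cfg, n_replicates = 2, n_representative_draws = 2, k = 10)
  expect_identical(st1$venn, st2$venn)
  expect_identical(st1$recovery, st2$recovery)

  # per-run Venn conservation: regions containing each set sum to k
  v <- st1$venn
  expect_true(all(v$A + v$AB + v$AC + v$ABC == 10))
  expect_true(all(v$B + v$AB + v$BC + v$ABC == 10))
  expect_true(all(v$C + v$AC + v$BC + v$ABC == 10))

  # hybrid is never larger than either parent top-k
  hyb <- st1$recovery[st1$recovery$option == "hybrid", ]
  expect_true(all(hyb$size <= 10))

  # recovery rows: 4 options x replicates x draws
  expect_equal(nrow(st1$recovery), 4 * 2 * 2)
  expect_true(all(st1$recovery$fdr >= 0 & st1$recovery$fdr <= 1,
                  na.rm = TRUE))
  expect_true(all(st1$recovery$true_positives <= pmin(st1$recovery$size,
                                                      cfg$m_causal)))

  # kinship and independence rows are constant across draws in a replicate
  kin <- st1$recovery[st1$recovery$option == "kinship", ]
  expect_equal(length(unique(kin$true_positives[kin$replicate == 1])), 1)

  # aggregate uses the sample SD
  expect_equal(st1$venn_summary$sd,
               vapply(c("A", "B", "C", "AB", "AC", "BC", "ABC"),
                      function(g) stats::sd(v[[g]]), numeric(1)),
               ignore_attr = TRUE)
})

test_that("enlarging k never decreases the true-positive count", {
  cfg <- small_config(seed = 72, m_markers = 80, m_causal = 8)
  ds <- simulate_dataset(cfg)
  res <- fit_all(ds, "kinship")
  tps <- vapply(c(5, 10, 20, 40), function(k) {
    recovery(top_k(res, k), ds$causal)$true_positives
  }, numeric(1))
  expect_true(all(diff(tps) >= 0))
})

test_that("threshold selection mirrors the ranking rules and Bonferroni scales the cutoff", {
  p <- c(0.001, 0.2, 0.0004, 0.04, 0.6)
  res <- fake_results(p)
  sel <- significant_markers(res, alpha = 0.05)
  expect_equal(sel$marker_ids, c("M0003", "M0001", "M0004"))
  expect_equal(sel$k, 3)

  bonf <- significant_markers(res, alpha = 0.05, bonferroni = TRUE)
  expect_equal(bonf$marker_ids, c("M0003", "M0001"))  # cutoff 0.01

  none <- significant_markers(fake_results(c(0.5, 0.9)), alpha = 0.01)
  expect_equal(none$k, 0)
  expect_error(significant_markers(res, alpha = 0),
               class = "famlmm_usage_error")
})
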