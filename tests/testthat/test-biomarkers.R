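surv_tbl <- function(times, events = 1, ids = paste0("s", seq_along(times))) {
  tibble::tibble(
    sample_id = ids,
    time = times,
    event = rep_len(events, length(times))
  )
}

test_that("median split follows the strict rule with ties going long", {
  sp <- split_by_median(surv_tbl(c(1, 2, 3, 4)))
  expect_equal(sp$median_time, 2.5)
  expect_setequal(sp$long_group, c("s3", "s4"))
  expect_setequal(sp$short_group, c("s1", "s2"))

  tied <- split_by_median(surv_tbl(c(1, 2, 2, 3)))
  expect_equal(tied$median_time, 2)
  expect_setequal(tied$long_group, c("s2", "s3", "s4"))
  expect_setequal(tied$short_group, "s1")

  expect_error(split_by_median(surv_tbl(c(1, 2, 3))), "at least 4")
  expect_error(split_by_median(surv_tbl(rep(2, 5))), "degenerate")
})

test_that("candidate biomarkers require one-sided survival-group enrichment", {
  sets <- list(l1 = "X", l2 = "X", l3 = c("X", "Y"), l4 = c("X", "Y"),
               s1 = c("X", "Y"), s2 = "Y", s3 = "Y", s4 = "Z")
  split <- structure(list(long_group = paste0("l", 1:4),
                          short_group = paste0("s", 1:4), median_time = 10),
                     class = "smfe_survival_split")
  cand <- candidate_biomarkers(sets, non_de = c("X", "Y", "Z"), split, A = 0.6)
  # X: 4 long / 1 short = 0.8 > 0.6 -> kept; Y: 2/3 of 5 is not > 0.6 -> dropped
  # Z: 0 long / 1 short = 1 -> kept
  expect_setequal(cand$gene, c("X", "Z"))
  expect_equal(cand$n_long[cand$gene == "X"], 4L)
  expect_equal(cand$m_short[cand$gene == "X"], 1L)
  expect_equal(cand$enrichment[cand$gene == "X"], 0.8)

  # DE genes are excluded regardless of counts
  expect_equal(nrow(candidate_biomarkers(sets, non_de = "Y", split, A = 0.6)), 0L)
  # balanced genes are never candidates at A = 0.5 boundary semantics
  bal <- list(l1 = "W", l2 = "W", l3 = "W", s1 = "W", s2 = "W", s3 = "W")
  expect_equal(nrow(candidate_biomarkers(bal, "W", split, A = 0.6)), 0L)
})

test_that("candidate counts are exact and the rule is monotone in A", {
  withr::with_seed(70, {
    for (rep in 1:5) {
      samples <- paste0("p", 1:20)
      sets <- stats::setNames(lapply(samples, function(s) {
        sample(LETTERS[1:10], sample(1:4, 1))
      }), samples)
      split <- structure(list(long_group = samples[1:10],
                              short_group = samples[11:20], median_time = 1),
                         class = "smfe_survival_split")
      loose <- candidate_biomarkers(sets, LETTERS[1:10], split, A = 0.55)
      tight <- candidate_biomarkers(sets, LETTERS[1:10], split, A = 0.75)
      expect_true(all(tight$gene %in% loose$gene))
      for (i in seq_len(nrow(loose))) {
        g <- loose$gene[i]
        identified <- names(sets)[vapply(sets, function(s) g %in% s, logical(1))]
        expect_equal(loose$n_long[i] + loose$m_short[i],
                     length(intersect(identified,
                                      c(split$long_group, split$short_group))))
      }
    }
  })
})

test_that("biomarker classes require significance and a survival direction", {
  # clear separation: identified samples die early -> pessimistic
  rec <- surv_tbl(c(1, 2, 3, 4, 30, 40, 50, 60))
  res <- classify_biomarker("G", paste0("s", 1:4), rec)
  expect_true(res$direction_stat < 0)
  expect_equal(res$class, "pessimistic")

  # direction by restricted mean: identified surviving longer can never be
  # pessimistic
  rec2 <- surv_tbl(c(10, 11, 12, 1, 2, 3))
  res2 <- classify_biomarker("G", paste0("s", 1:3), rec2)
  expect_gt(res2$direction_stat, 0)
  expect_true(res2$class %in% c("optimistic", "none"))

  # identical survival in the two groups: no call
  rec3 <- surv_tbl(rep(c(5, 10, 15), 2))
  res3 <- classify_biomarker("G", paste0("s", 1:3), rec3)
  expect_equal(res3$class, "none")

  # no events at all: log-rank undefined
  rec4 <- surv_tbl(c(1, 2, 3, 4), events = 0)
  expect_warning(res4 <- classify_biomarker("G", c("s1", "s2"), rec4),
                 "no events")
  expect_equal(res4$class, "none")
})

test_that("swapping group labels flips the class and preserves the P value", {
  rec <- surv_tbl(c(1, 2, 3, 4, 5, 30, 40, 50, 60, 70))
  ident <- paste0("s", 1:5)
  other <- paste0("s", 6:10)
  a <- classify_biomarker("G", ident, rec)
  b <- classify_biomarker("G", other, rec)
  expect_equal(a$logrank_p, b$logrank_p, tolerance = 1e-12)
  expect_equal(a$direction_stat, -b$direction_stat, tolerance = 1e-12)
  expect_equal(sort(c(a$class, b$class)), c("optimistic", "pessimistic"))
})

test_that("the non-DE screen keeps null genes and drops shifted ones", {
  withr::with_seed(80, {
    n <- 20
    tumor <- rbind(
      null_gene = rnorm(n, 5),
      shifted = rnorm(n, 15),   # 10 SDs away
      flat = rep(2, n)
    )
    ref <- rbind(null_gene = rnorm(n, 5), shifted = rnorm(n, 5),
                 flat = rep(2, n))
    colnames(tumor) <- paste0("t", 1:n)
    colnames(ref) <- paste0("r", 1:n)
    expect_warning(keep <- non_de_genes(tumor, ref), "constant")
    expect_true("null_gene" %in% keep)
    expect_true("flat" %in% keep)
    expect_false("shifted" %in% keep)
  })
})

test_that("common signaling genes honor the membership fraction", {
  sets <- list(a = c("X", "Y"), b = c("X", "Y"), c = c("X", "Z"),
               d = "X", e = c("X", "Y"))
  expect_equal(common_signaling_genes(sets, names(sets), 1), "X")
  expect_setequal(common_signaling_genes(sets, names(sets), 0.6), c("X", "Y"))
  expect_error(common_signaling_genes(sets, "zz"), "no signaling set")
})

test_that("the end-to-end biomarker screen classifies a planted marker", {
  withr::with_seed(90, {
    genes <- paste0("g", 1:5)
    n <- 40
    samples <- paste0("p", sprintf("%02d", 1:n))
    positive <- samples[1:20]
    rec <- make_survival(samples, positive, hazard_ratio = 4,
                         baseline_scale = 100, censor_rate = 0.1, seed = 91)
    # hand-built scores object: marker gene g2 marks the positive samples
    sets <- stats::setNames(lapply(samples, function(s) {
      if (s %in% positive) "g2" else "g1"
    }), samples)
    scores <- structure(list(
      samples = tibble::tibble(sample_id = samples, global_score = 1,
                               n_scoreable = 2L, q = 1L),
      local = tibble::tibble(sample_id = samples, gene = "g2", smfe = 1),
      signaling = sets,
      params = list()
    ), class = "smfe_scores")
    tumor <- matrix(runif(5 * n, 0, 10), nrow = 5,
                    dimnames = list(genes, samples))
    ref <- matrix(runif(5 * 10, 0, 10), nrow = 5,
                  dimnames = list(genes, paste0("r", 1:10)))
    res <- find_biomarkers(scores, rec, tumor, ref)
    expect_true("g2" %in% res$gene)
    expect_equal(res$class[res$gene == "g2"], "pessimistic")
  })
})
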