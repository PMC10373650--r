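test_that("the reference-fitted min-max normalizer clips and zeroes constants", {
  ref <- matrix(c(2, 4, 6,
                  5, 5, 5), nrow = 2, byrow = TRUE,
                dimnames = list(c("g1", "g2"), paste0("r", 1:3)))
  norm <- fit_normalizer(ref)
  z <- normalize_expression(norm, ref)
  expect_equal(unname(z["g1", ]), c(0, 0.5, 1))
  expect_equal(unname(z["g2", ]), c(0, 0, 0))

  case <- matrix(c(10, 5), ncol = 1, dimnames = list(c("g1", "g2"), "c"))
  zc <- normalize_expression(norm, case)
  expect_equal(unname(zc[, 1]), c(1, 0))

  expect_error(fit_normalizer(ref[, 1, drop = FALSE]), "at least 2")
})

test_that("transition probabilities follow |PCC| / (1 + sum |PCC|)", {
  # two perfectly correlated neighbors: |PCC| = (1, 1) so p = (1/3, 1/3)
  cohort <- matrix(c(0, 1 / 3, 2 / 3, 1,
                     0, 1 / 3, 2 / 3, 1,
                     0, 1 / 3, 2 / 3, 1), nrow = 3, byrow = TRUE,
                   dimnames = list(c("A", "B", "C"), paste0("s", 1:4)))
  star <- star_network("A", c("B", "C"))
  tv <- transition_probs(cohort, local_network(star, "A"))
  expect_equal(unname(tv$p), c(1 / 3, 1 / 3))
  expect_equal(tv$S, 2)

  # zero-variance neighbors contribute |PCC| = 0
  cohort0 <- cohort
  cohort0["B", ] <- 0.5
  cohort0["C", ] <- 0.2
  tv0 <- transition_probs(cohort0, local_network(star, "A"))
  expect_equal(unname(tv0$p), c(0, 0))

  # probabilities always sum to S / (1 + S) < 1
  withr::with_seed(5, {
    for (rep in 1:20) {
      m <- matrix(runif(3 * 6), nrow = 3,
                  dimnames = list(c("A", "B", "C"), paste0("s", 1:6)))
      tv <- transition_probs(m, local_network(star, "A"))
      expect_equal(sum(tv$p), tv$S / (1 + tv$S))
      expect_true(all(tv$p >= 0 & tv$p < 1))
    }
  })
})

test_that("local MFE matches its closed form and conventions", {
  expect_equal(local_mfe(0, c(0.3, 0.4)), 0)
  expect_equal(local_mfe(0.7, c(0, 0)), 0)
  # xbar = 1/2, p = (1/3, 1/3): two terms of (1/6) ln 6
  expect_equal(local_mfe(0.5, c(1 / 3, 1 / 3)), log(6) / 3, tolerance = 1e-12)
})

test_that("entropy is maximal at uniform transition probabilities", {
  withr::with_seed(20, {
    for (rep in 1:200) {
      M <- sample(2:8, 1)
      raw <- runif(M)
      total <- runif(1, 0.05, 0.95)
      p <- raw / sum(raw) * total
      xbar <- runif(1)
      expect_lte(local_mfe(xbar, p), local_mfe(xbar, rep(total / M, M)) + 1e-12)
    }
  })
})

test_that("a single dominant neighbor gives no more entropy than the uniform case", {
  # one |PCC| -> 1 and the rest -> 0 concentrates the flow on one edge
  xbar <- 0.8
  concentrated <- c(0.5, 0, 0, 0)       # S = 1: p = (1/2, 0, 0, 0)
  uniform <- rep(0.5 / 4, 4)            # same total mass spread out
  expect_lte(local_mfe(xbar, concentrated), local_mfe(xbar, uniform))
  expect_equal(local_mfe(xbar, concentrated), -0.4 * log(0.4))
})

test_that("the differential score matches an independent literal evaluation", {
  t <- toy5()
  # frozen oracle values for the 5-gene toy (step-by-step evaluation)
  expect_equal(local_smfe(t$ref, t$case, local_network(t$net, "g1")),
               0.00407704711329332, tolerance = 1e-12)
  expect_equal(local_smfe(t$ref, t$case, local_network(t$net, "g2")),
               0.0823977194161357, tolerance = 1e-12)

  s <- score_sample(t$case, t$ref, t$net)
  expect_equal(glance(s)$global_score, 0.0823977194161357, tolerance = 1e-12)
  expect_equal(s$signaling$case, "g2")
})

test_that("degenerate centers and unscoreable genes are handled", {
  t <- toy5()
  ref <- t$ref
  ref["g1", ] <- 3  # constant center
  expect_equal(local_smfe(ref, t$case, local_network(t$net, "g1")), 0)

  expect_error(local_smfe(t$ref, t$case, local_network(t$net, "g4")),
               "not scoreable")
})

test_that("local scores are nonnegative for arbitrary valid inputs", {
  withr::with_seed(30, {
    for (rep in 1:10) {
      genes <- paste0("g", 1:6)
      ref <- matrix(runif(6 * 5, 0, 10), nrow = 6,
                    dimnames = list(genes, paste0("r", 1:5)))
      case <- stats::setNames(runif(6, 0, 12), genes)
      net <- suppressWarnings(build_network(
        data.frame(from = sample(genes, 12, replace = TRUE),
                   to = sample(genes, 12, replace = TRUE), score = 1),
        threshold = 0, directed = TRUE))
      ok <- tryCatch({
        s <- score_sample(case, ref, net)
        expect_true(all(s$local$smfe >= 0))
        expect_gte(glance(s)$global_score, 0)
        TRUE
      }, error = function(e) grepl("no scoreable genes", conditionMessage(e)))
      expect_true(ok)
    }
  })
})

test_that("Q follows the ceiling rule over scoreable genes", {
  withr::with_seed(40, {
    for (spec in list(c(100, 5), c(41, 3), c(20, 1))) {
      n <- spec[1]
      net <- ring_network(n)
      ref <- matrix(runif(n * 6, 0, 10), nrow = n,
                    dimnames = list(net$nodes, paste0("r", 1:6)))
      case <- stats::setNames(runif(n, 0, 10), net$nodes)
      s <- score_sample(case, ref, net)
      expect_equal(s$params$n_scoreable, n)
      expect_equal(s$params$q, spec[2])
      if (spec[2] == 1L) {
        expect_equal(glance(s)$global_score, max(s$local$smfe))
      }
    }
  })
})

test_that("scores are invariant to sample and edge-row permutations", {
  t <- toy5()
  base <- score_sample(t$case, t$ref, t$net)
  shuffled_ref <- t$ref[, c(3, 1, 4, 2)]
  row_order <- withr::with_seed(50, sample(nrow(t$edges)))
  shuffled_net <- build_network(t$edges[row_order, ],
                                threshold = 0, directed = TRUE)
  again <- score_sample(t$case, shuffled_ref, shuffled_net)
  expect_equal(again$local$smfe, base$local$smfe, tolerance = 1e-12)
  expect_equal(glance(again)$global_score, glance(base)$global_score,
               tolerance = 1e-12)
})

test_that("the literal score form matches its printed combination", {
  t <- toy5()
  got <- local_smfe(t$ref, t$case, local_network(t$net, "g1"),
                    eq6_form = "literal")
  want <- oracle_local_smfe(t$ref, t$case, "g1", c("g2", "g3", "g4"),
                            form = "literal")
  expect_equal(got, want, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(
    got, local_smfe(t$ref, t$case, local_network(t$net, "g1"))
  )))
})

test_that("network genes missing from the expression data are dropped with a warning", {
  t <- toy5()
  net <- build_network(rbind(t$edges, data.frame(from = "g1", to = "g9")),
                       threshold = 0, directed = TRUE)
  expect_warning(s <- score_sample(t$case, t$ref, net), "absent")
  expect_setequal(unique(s$local$gene), c("g1", "g2"))
})
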