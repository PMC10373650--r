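#' Fit the per-gene min-max normalizer on the reference cohort
#'
#' Expression enters the entropy formulas normalized to \[0, 1\]. The
#' normalizer is fitted on the reference samples only; any sample transformed
#' afterwards (including case samples) is clipped into \[0, 1\], so one
#' extreme case sample can never rescale the reference. A gene that is
#' constant in the reference maps to 0 everywhere.
#'
#' @param reference Reference expression (tibble with a gene column, or a
#'   genes x samples matrix) with at least 2 samples.
#' @return An `smfe_normalizer` with per-gene `fit_min` and `fit_max`.
#' @export
fit_normalizer <- function(reference) {
  ref <- as_expr_matrix(reference, "reference")
  if (ncol(ref) < 2L) abort("the reference cohort needs at least 2 samples")
  structure(
    list(
      genes = rownames(ref),
      fit_min = apply(ref, 1L, min),
      fit_max = apply(ref, 1L, max)
    ),
    class = "smfe_normalizer"
  )
}

#' Apply a fitted normalizer to an expression matrix
#'
#' @param normalizer An [fit_normalizer()] result.
#' @param expr Expression tibble or matrix covering the normalizer's genes.
#' @return A genes x samples matrix of values in \[0, 1\].
#' @export
normalize_expression <- function(normalizer, expr) {
  stopifnot(inherits(normalizer, "smfe_normalizer"))
  mat <- as_expr_matrix(expr)
  missing <- setdiff(normalizer$genes, rownames(mat))
  if (length(missing) > 0L) {
    abort(sprintf("expression is missing %d normalizer gene(s) (e.g. %s)",
                  length(missing), toString(head(missing, 3L))))
  }
  mat <- mat[normalizer$genes, , drop = FALSE]
  rng <- normalizer$fit_max - normalizer$fit_min
  z <- (mat - normalizer$fit_min) / ifelse(rng > 0, rng, 1)
  z[rng == 0, ] <- 0
  z[z < 0] <- 0
  z[z > 1] <- 1
  z
}

#' Transition probabilities of a local network
#'
#' For center gene \eqn{g^k} with neighbors \eqn{g^k_1..g^k_M}, the
#' probability of flowing to neighbor i is
#' \deqn{p_i = |PCC(g^k_i, g^k)| / (1 + \sum_j |PCC(g^k_j, g^k)|),}
#' where the constant 1 is the self term (the correlation of the center with
#' itself). Correlations are computed across the cohort's samples on
#' normalized expression; any pair involving a zero-variance vector
#' contributes 0.
#'
#' @param cohort Normalized genes x samples matrix (values in \[0, 1\]) with
#'   at least 2 samples.
#' @param local An [local_network()] result with at least 1 neighbor.
#' @return A list with `center`, `p` (named neighbor probabilities) and `S`
#'   (the summed neighbor absolute correlations), class `smfe_transition`.
#' @export
transition_probs <- function(cohort, local) {
  stopifnot(inherits(local, "smfe_local_network"), is.matrix(cohort))
  if (length(local$neighbors) == 0L) abort("local network has no neighbors")
  if (ncol(cohort) < 2L) abort("cohort needs at least 2 samples for correlations")
  center <- cohort[local$center, ]
  absr <- vapply(local$neighbors, function(nb) {
    abs(safe_pcc(cohort[nb, ], center))
  }, numeric(1L))
  S <- sum(absr)
  structure(list(center = local$center, p = absr / (1 + S), S = S),
            class = "smfe_transition")
}

# Pearson correlation with the zero-variance convention r = 0
safe_pcc <- function(x, y) {
  if (pop_var(x) <= .smfe_var_tol || pop_var(y) <= .smfe_var_tol) return(0)
  r <- cor(x, y)
  if (is.na(r)) 0 else max(-1, min(1, r))
}

.smfe_var_tol <- 1e-24

# population (divide-by-n) variance; the n vs n+1 cohorts differ by one
# sample, so the sample-SD n/(n-1) correction would inject a spurious term
pop_var <- function(x) {
  mean(x^2) - mean(x)^2
}

pop_sd <- function(x) {
  sqrt(max(pop_var(x), 0))
}

#' Local Markov flow entropy of one center gene
#'
#' \deqn{MFE_k = -\sum_i u_i \log u_i, \quad u_i = \bar x_k \, p_i,}
#' with the natural logarithm and the convention \eqn{0 \log 0 = 0}.
#' \eqn{\bar x_k} is the cohort mean of the center gene's normalized
#' expression.
#'
#' @param xbar Mean normalized expression of the center gene, in \[0, 1\].
#' @param tv Transition probabilities: an [transition_probs()] result or a
#'   bare numeric vector of probabilities.
#' @return Nonnegative entropy (nats).
#' @export
local_mfe <- function(xbar, tv) {
  p <- if (inherits(tv, "smfe_transition")) tv$p else as.numeric(tv)
  u <- xbar * p
  -sum(ifelse(u > 0, u * log(u), 0))
}

#' Differential local sMFE of one case sample at one gene
#'
#' Computes the local Markov flow entropy and the population SD of the
#' center gene under the n reference samples and again under the n + 1 mixed
#' cohort (reference plus the single case sample), all on expression
#' normalized with the reference-fitted min-max transform, and returns
#' \deqn{sMFE_k = \frac{1}{\log M}\,|SD^n \cdot MFE^n_k - SD^{n+1} \cdot MFE^{n+1}_k|.}
#'
#' The printed form of the score in which the n + 1 entropy enters
#' additively rather than as an SD-weighted product is available via
#' `eq6_form = "literal"`.
#'
#' @param reference Reference expression tibble or matrix (>= 2 samples).
#' @param case_sample Named numeric vector of the case sample's expression,
#'   or a 1-sample expression tibble/matrix.
#' @param local An [local_network()] result with M >= 2 neighbors.
#' @param eq6_form `"product"` (default) or `"literal"`.
#' @return Nonnegative differential score.
#' @export
local_smfe <- function(reference, case_sample, local,
                       eq6_form = c("product", "literal")) {
  eq6_form <- match.arg(eq6_form)
  stopifnot(inherits(local, "smfe_local_network"))
  M <- length(local$neighbors)
  if (M < 2L) abort(sprintf("gene '%s' is not scoreable: it has %d neighbor(s), need >= 2",
                            local$center, M))
  ref <- as_expr_matrix(reference, "reference")
  case <- as_case_vector(case_sample, rownames(ref))
  norm <- fit_normalizer(ref)
  zref <- normalize_expression(norm, ref)
  zcase <- normalize_case(norm, case)
  zmix <- cbind(zref, case = zcase)

  used <- c(local$center, local$neighbors)
  mfe_n <- local_mfe(mean(zref[local$center, ]),
                     transition_probs(zref[used, , drop = FALSE], local))
  mfe_n1 <- local_mfe(mean(zmix[local$center, ]),
                      transition_probs(zmix[used, , drop = FALSE], local))
  sd_n <- pop_sd(zref[local$center, ])
  sd_n1 <- pop_sd(zmix[local$center, ])
  combine_eq6(sd_n, mfe_n, sd_n1, mfe_n1, M, eq6_form)
}

combine_eq6 <- function(sd_n, mfe_n, sd_n1, mfe_n1, M, eq6_form) {
  diff <- switch(eq6_form,
    product = sd_n * mfe_n - sd_n1 * mfe_n1,
    literal = sd_n * mfe_n - sd_n1 + mfe_n1
  )
  abs(diff) / log(M)
}

as_case_vector <- function(case_sample, genes) {
  if (is.data.frame(case_sample) || (is.matrix(case_sample) && !is.null(dim(case_sample)))) {
    mat <- as_expr_matrix(case_sample, "case sample")
    if (ncol(mat) != 1L) abort("case_sample must contain exactly one sample")
    case <- mat[, 1L]
  } else {
    case <- case_sample
  }
  if (is.null(names(case))) abort("case sample values must be named by gene")
  missing <- setdiff(genes, names(case))
  if (length(missing) > 0L) {
    abort(sprintf("case sample is missing gene(s): %s", toString(head(missing, 3L))))
  }
  case[genes]
}

normalize_case <- function(normalizer, case) {
  rng <- normalizer$fit_max - normalizer$fit_min
  z <- (case[normalizer$genes] - normalizer$fit_min) / ifelse(rng > 0, rng, 1)
  z[rng == 0] <- 0
  pmin(pmax(z, 0), 1)
}

#' Score case samples against a reference cohort on a directed network
#'
#' The workhorse of the method. For every scoreable gene (>= 2 neighbors)
#' and every case sample it computes the differential local sMFE, then
#' summarizes each sample by the mean of its Q largest local scores, where
#' `Q = ceiling(fraction * L)` over the L scoreable genes; those Q genes are
#' the sample's signaling genes. Ties at the cutoff break by descending
#' score then ascending gene identifier.
#'
#' Network genes absent from either expression table are dropped from the
#' network with a warning before scoring.
#'
#' @param case Case expression tibble or matrix (>= 1 sample).
#' @param reference Reference expression tibble or matrix (>= 2 samples).
#' @param net An `smfe_network` from [build_network()].
#' @param fraction Signaling-gene fraction of scoreable genes (default 0.05,
#'   the top 5 percent).
#' @param eq6_form `"product"` (default) or `"literal"`; see [local_smfe()].
#' @param neighbor_mode Which neighbors form each local network (`"out"`,
#'   `"in"`, `"both"`).
#' @return An `smfe_scores` object; see [tidy.smfe_scores()] and
#'   [glance.smfe_scores()].
#' @export
score_samples <- function(case, reference, net, fraction = 0.05,
                          eq6_form = c("product", "literal"),
                          neighbor_mode = c("out", "in", "both")) {
  eq6_form <- match.arg(eq6_form)
  neighbor_mode <- match.arg(neighbor_mode)
  stopifnot(inherits(net, "smfe_network"))
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1) {
    abort("fraction must be in (0, 1]")
  }
  ref <- as_expr_matrix(reference, "reference")
  cas <- as_expr_matrix(case, "case")
  if (ncol(ref) < 2L) abort("the reference cohort needs at least 2 samples")
  shared <- intersect(rownames(ref), rownames(cas))
  net <- map_network(net, shared)
  el <- neighbor_edges(net, neighbor_mode)
  el <- arrange(el, .data$from, .data$to)
  centers <- sort(unique(el$from[duplicated(el$from)]))  # out-degree >= 2
  if (length(centers) == 0L) abort("no scoreable genes: every mapped gene has < 2 neighbors")
  el <- el[el$from %in% centers, , drop = FALSE]

  genes <- sort(unique(c(el$from, el$to)))
  norm <- fit_normalizer(ref[genes, , drop = FALSE])
  z <- normalize_expression(norm, ref[genes, , drop = FALSE])
  zc <- normalize_expression(norm, cas[genes, , drop = FALSE])

  src <- match(el$from, genes)
  tgt <- match(el$to, genes)
  n <- ncol(z)
  s1 <- rowSums(z)
  s2 <- rowSums(z * z)
  cp <- rowSums(z[src, , drop = FALSE] * z[tgt, , drop = FALSE])
  cidx <- match(centers, genes)
  M <- as.vector(table(factor(el$from, levels = centers)))

  edge_stats <- function(s1v, s2v, cpv, nn) {
    mu <- s1v / nn
    va <- pmax(s2v / nn - mu * mu, 0)
    cov <- cpv / nn - mu[src] * mu[tgt]
    ok <- va[src] > .smfe_var_tol & va[tgt] > .smfe_var_tol
    absr <- numeric(length(cov))
    absr[ok] <- pmin(abs(cov[ok]) / sqrt(va[src][ok] * va[tgt][ok]), 1)
    list(absr = absr, mu = mu, sd = sqrt(va))
  }
  center_factor <- factor(el$from, levels = centers)
  center_mfe <- function(st) {
    S <- as.vector(rowsum(st$absr, center_factor, reorder = FALSE))
    p <- st$absr / (1 + S[as.integer(center_factor)])
    u <- st$mu[cidx][as.integer(center_factor)] * p
    term <- ifelse(u > 0, -u * log(u), 0)
    as.vector(rowsum(term, center_factor, reorder = FALSE))
  }

  ref_stats <- edge_stats(s1, s2, cp, n)
  mfe_n <- center_mfe(ref_stats)
  sd_n <- ref_stats$sd[cidx]

  local_tbl <- purrr::map(colnames(zc), function(s) {
    zi <- zc[, s]
    mixed <- edge_stats(s1 + zi, s2 + zi * zi, cp + zi[src] * zi[tgt], n + 1)
    mfe_n1 <- center_mfe(mixed)
    sd_n1 <- mixed$sd[cidx]
    tibble(sample_id = s, gene = centers,
           smfe = combine_eq6(sd_n, mfe_n, sd_n1, mfe_n1, M, eq6_form))
  })
  local_tbl <- bind_rows(local_tbl)

  L <- length(centers)
  Q <- as.integer(ceiling(fraction * L))
  per_sample <- local_tbl |>
    group_by(.data$sample_id) |>
    arrange(desc(.data$smfe), .data$gene, .by_group = TRUE) |>
    summarise(global_score = mean(.data$smfe[seq_len(Q)]),
              signaling = list(.data$gene[seq_len(Q)]), .groups = "drop")
  per_sample <- per_sample[match(colnames(zc), per_sample$sample_id), ]

  structure(
    list(
      samples = tibble(sample_id = per_sample$sample_id,
                       global_score = per_sample$global_score,
                       n_scoreable = L, q = Q),
      local = local_tbl,
      signaling = setNames(per_sample$signaling, per_sample$sample_id),
      params = list(fraction = fraction, eq6_form = eq6_form,
                    neighbor_mode = neighbor_mode,
                    n_reference = n, n_scoreable = L, q = Q)
    ),
    class = "smfe_scores"
  )
}

#' Score a single case sample
#'
#' Convenience wrapper around [score_samples()] for one named expression
#' vector.
#'
#' @inheritParams score_samples
#' @param case_sample Named numeric vector (names are gene ids), or a
#'   1-sample expression tibble/matrix.
#' @param sample_id Identifier for the sample in the result.
#' @return An `smfe_scores` object with one sample.
#' @export
score_sample <- function(case_sample, reference, net, fraction = 0.05,
                         eq6_form = c("product", "literal"),
                         neighbor_mode = c("out", "in", "both"),
                         sample_id = "case") {
  if (is.numeric(case_sample) && !is.matrix(case_sample)) {
    case_sample <- matrix(case_sample, ncol = 1L,
                          dimnames = list(names(case_sample), sample_id))
  }
  score_samples(case_sample, reference, net, fraction = fraction,
                eq6_form = eq6_form, neighbor_mode = neighbor_mode)
}

#' @export
print.smfe_scores <- function(x, ...) {
  cat(sprintf("<smfe_scores> %d sample(s), %d scoreable gene(s), Q = %d\n",
              nrow(x$samples), x$params$n_scoreable, x$params$q))
  print(x$samples, ...)
  invisible(x)
}

#' Tidy per-gene local sMFE scores
#'
#' @param x An `smfe_scores` object.
#' @param ... Unused.
#' @return A tibble with one row per (sample, gene): `sample_id`, `gene`,
#'   `smfe`, and `signaling` (whether the gene is in that sample's top set).
#' @export
tidy.smfe_scores <- function(x, ...) {
  out <- x$local
  sig <- tibble(
    sample_id = rep(names(x$signaling), lengths(x$signaling)),
    gene = unlist(x$signaling, use.names = FALSE), signaling = TRUE
  )
  out <- left_join(out, sig, by = c("sample_id", "gene"))
  out$signaling[is.na(out$signaling)] <- FALSE
  out
}

#' Per-sample summary of an sMFE scoring run
#'
#' @param x An `smfe_scores` object.
#' @param ... Unused.
#' @return A tibble with `sample_id`, `global_score`, `n_scoreable`, `q`.
#' @export
glance.smfe_scores <- function(x, ...) {
  x$samples
}
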