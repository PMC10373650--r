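#' Split samples into long- and short-survival groups at the median time
#'
#' The split uses raw survival time regardless of censoring; samples tied
#' exactly at the median go to the long-survival group (the strict
#' greater/less rule leaves them unassigned otherwise).
#'
#' @param records Survival tibble (`sample_id`, `time`, `event`) with at
#'   least 4 records.
#' @param ties One of `"long"` (default) or `"short"`: which group receives
#'   samples whose time equals the median.
#' @return A list with `long_group`, `short_group` (character vectors) and
#'   `median_time`, of class `smfe_survival_split`.
#' @export
split_by_median <- function(records, ties = c("long", "short")) {
  ties <- match.arg(ties)
  records <- validate_survival(records)
  if (nrow(records) < 4L) abort("need at least 4 survival records to split")
  med <- stats::median(records$time)
  if (all(records$time == records$time[1L])) {
    abort("degenerate survival distribution: all times equal")
  }
  is_long <- if (ties == "long") records$time >= med else records$time > med
  structure(
    list(long_group = records$sample_id[is_long],
         short_group = records$sample_id[!is_long],
         median_time = med),
    class = "smfe_survival_split"
  )
}

#' Candidate prognostic biomarkers from signaling genes
#'
#' A non-differentially-expressed gene that appears in at least one sample's
#' signaling set is a candidate biomarker when its identified samples are
#' skewed toward one survival group: with n identified samples from the
#' long-survival group and m from the short-survival group, the gene is kept
#' iff `n/(n+m) > A` or `m/(n+m) > A`. The enrichment parameter A defaults
#' to 0.6.
#'
#' @param signaling_sets Named list mapping sample id to its signaling gene
#'   set (e.g. the `signaling` element of [score_samples()]).
#' @param non_de Character vector of non-differentially-expressed genes
#'   (see [non_de_genes()]). Genes outside it are excluded regardless of
#'   counts.
#' @param split An [split_by_median()] result.
#' @param A Enrichment threshold in \[0.5, 1).
#' @return A tibble `gene`, `n_long`, `m_short`, `enrichment`, one row per
#'   candidate.
#' @export
candidate_biomarkers <- function(signaling_sets, non_de, split, A = 0.6) {
  stopifnot(inherits(split, "smfe_survival_split"))
  if (!is.numeric(A) || A < 0.5 || A >= 1) abort("A must lie in [0.5, 1)")
  long_sets <- signaling_sets[intersect(names(signaling_sets), split$long_group)]
  short_sets <- signaling_sets[intersect(names(signaling_sets), split$short_group)]
  genes <- intersect(unique(unlist(signaling_sets, use.names = FALSE)), non_de)
  if (length(genes) == 0L) {
    return(tibble(gene = character(), n_long = integer(), m_short = integer(),
                  enrichment = double()))
  }
  n <- vapply(genes, function(g) sum(vapply(long_sets, function(s) g %in% s, logical(1L))),
              integer(1L))
  m <- vapply(genes, function(g) sum(vapply(short_sets, function(s) g %in% s, logical(1L))),
              integer(1L))
  out <- tibble(gene = genes, n_long = unname(n), m_short = unname(m))
  out <- out[out$n_long + out$m_short > 0L, , drop = FALSE]
  out$enrichment <- pmax(out$n_long, out$m_short) / (out$n_long + out$m_short)
  out <- out[out$n_long / (out$n_long + out$m_short) > A |
               out$m_short / (out$n_long + out$m_short) > A, , drop = FALSE]
  arrange(out, .data$gene)
}

#' Classify a candidate biomarker as optimistic or pessimistic
#'
#' Samples are divided by whether their signaling set contains the gene
#' (identified vs unidentified) and the two survival curves are compared by
#' a log-rank test. With P < `alpha`, the gene is an optimistic (O-sMFE)
#' biomarker when identified samples survive longer, a pessimistic (P-sMFE)
#' biomarker when they survive shorter; otherwise the class is `"none"`.
#' Direction is measured by the difference in restricted-mean survival over
#' the common follow-up window (identified minus unidentified).
#'
#' @param gene Gene identifier (carried into the result).
#' @param identified Character vector of identified sample ids.
#' @param records Survival tibble covering both groups.
#' @param alpha Significance level (default 0.05).
#' @return A one-row tibble: `gene`, `n_identified`, `n_unidentified`,
#'   `logrank_p`, `direction_stat`, `class`.
#' @export
classify_biomarker <- function(gene, identified, records, alpha = 0.05) {
  records <- validate_survival(records)
  grp <- records$sample_id %in% identified
  if (sum(grp) < 2L || sum(!grp) < 2L) {
    abort("identified and unidentified groups each need >= 2 survival records")
  }
  res <- tibble(gene = gene, n_identified = sum(grp), n_unidentified = sum(!grp),
                logrank_p = NA_real_, direction_stat = NA_real_, class = "none")
  if (sum(records$event) == 0L) {
    warn(sprintf("gene '%s': no events in either group; log-rank undefined", gene))
    return(res)
  }
  sdiff <- survival::survdiff(survival::Surv(time, event) ~ grp, data = records)
  res$logrank_p <- stats::pchisq(sdiff$chisq, df = 1L, lower.tail = FALSE)
  tmax <- min(max(records$time[grp]), max(records$time[!grp]))
  res$direction_stat <- rmst_km(records$time[grp], records$event[grp], tmax) -
    rmst_km(records$time[!grp], records$event[!grp], tmax)
  if (!is.na(res$logrank_p) && res$logrank_p < alpha) {
    res$class <- if (res$direction_stat > 0) "optimistic"
                 else if (res$direction_stat < 0) "pessimistic"
                 else "none"
  }
  res
}

# restricted mean survival time: area under the Kaplan-Meier curve on [0, tmax]
rmst_km <- function(time, event, tmax) {
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  tt <- c(0, fit$time[fit$time <= tmax], tmax)
  ss <- c(1, fit$surv[fit$time <= tmax])
  sum(ss * diff(tt))
}

#' Non-differentially-expressed genes between tumor and reference cohorts
#'
#' Per-gene two-sided Welch t-test with Benjamini-Hochberg adjustment;
#' genes whose adjusted P is at or above `fdr` are returned as non-DE.
#' Genes constant in both cohorts have an undefined statistic and are kept
#' as non-DE with a warning.
#'
#' @param tumor,reference Expression tibbles or matrices sharing gene ids,
#'   each with >= 2 samples.
#' @param fdr BH-adjusted significance threshold (default 0.05).
#' @return Character vector of non-DE gene identifiers.
#' @export
non_de_genes <- function(tumor, reference, fdr = 0.05) {
  tm <- as_expr_matrix(tumor, "tumor")
  rf <- as_expr_matrix(reference, "reference")
  if (ncol(tm) < 2L || ncol(rf) < 2L) abort("each cohort needs >= 2 samples")
  genes <- intersect(rownames(tm), rownames(rf))
  tm <- tm[genes, , drop = FALSE]
  rf <- rf[genes, , drop = FALSE]
  n1 <- ncol(tm); n2 <- ncol(rf)
  m1 <- rowMeans(tm); m2 <- rowMeans(rf)
  v1 <- rowSums((tm - m1)^2) / (n1 - 1)
  v2 <- rowSums((rf - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  degenerate <- !is.finite(p)  # zero variance in both cohorts
  if (any(degenerate)) {
    warn(sprintf("%d constant gene(s) have an undefined t statistic; kept as non-DE",
                 sum(degenerate)))
  }
  padj <- rep(NA_real_, length(p))
  padj[!degenerate] <- p.adjust(p[!degenerate], method = "BH")
  sort(genes[degenerate | padj >= fdr])
}

#' Common signaling genes of a sample group
#'
#' Genes present in at least `min_fraction` of the group's signaling sets;
#' with the default `min_fraction = 1` this is the strict intersection used
#' to read off dynamic network biomarkers at the critical stage.
#'
#' @inheritParams candidate_biomarkers
#' @param stage_samples Character vector of sample ids forming the group
#'   (e.g. the samples of the called critical stage).
#' @param min_fraction Required fraction of sets containing the gene.
#' @return Sorted character vector of genes.
#' @export
common_signaling_genes <- function(signaling_sets, stage_samples, min_fraction = 1) {
  stage_samples <- intersect(stage_samples, names(signaling_sets))
  if (length(stage_samples) == 0L) abort("stage_samples matches no signaling set")
  sets <- signaling_sets[stage_samples]
  counts <- table(unlist(sets, use.names = FALSE))
  sort(names(counts)[counts / length(sets) >= min_fraction])
}

#' Screen signaling genes for O-sMFE and P-sMFE prognostic biomarkers
#'
#' End-to-end biomarker discovery: split samples at the median survival
#' time, select candidate genes (non-DE signaling genes enriched in one
#' survival group beyond `A`), and classify each candidate by log-rank test
#' into optimistic (identified samples survive longer) or pessimistic
#' (shorter) biomarkers.
#'
#' @param scores An `smfe_scores` object for the tumor samples.
#' @param records Survival tibble (`sample_id`, `time`, `event`).
#' @param tumor,reference Expression tables used for the non-DE screen.
#' @param A Enrichment threshold (default 0.6).
#' @param alpha Log-rank significance level (default 0.05).
#' @param fdr BH threshold of the non-DE screen (default 0.05).
#' @param ties Median tie rule, see [split_by_median()].
#' @return A tibble with one row per candidate: `gene`, `n_long`, `m_short`,
#'   `enrichment`, `logrank_p`, `direction_stat`, `class`.
#' @export
find_biomarkers <- function(scores, records, tumor, reference, A = 0.6,
                            alpha = 0.05, fdr = 0.05, ties = "long") {
  stopifnot(inherits(scores, "smfe_scores"))
  records <- validate_survival(records)
  records <- records[records$sample_id %in% names(scores$signaling), , drop = FALSE]
  if (nrow(records) < 4L) abort("fewer than 4 scored samples have survival data")
  split <- split_by_median(records, ties = ties)
  nde <- non_de_genes(tumor, reference, fdr = fdr)
  cand <- candidate_biomarkers(scores$signaling, nde, split, A = A)
  if (nrow(cand) == 0L) {
    return(mutate(cand, logrank_p = double(), direction_stat = double(),
                  class = character()))
  }
  cls <- purrr::map(cand$gene, function(g) {
    identified <- names(scores$signaling)[vapply(scores$signaling,
                                                 function(s) g %in% s, logical(1L))]
    grp_n <- sum(records$sample_id %in% identified)
    if (grp_n < 2L || nrow(records) - grp_n < 2L) {
      return(tibble(gene = g, logrank_p = NA_real_,
                    direction_stat = NA_real_, class = "none"))
    }
    classify_biomarker(g, identified, records, alpha = alpha)[
      , c("gene", "logrank_p", "direction_stat", "class")]
  })
  left_join(cand, bind_rows(cls), by = "gene")
}
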