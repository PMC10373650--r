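#' Aggregate per-sample global sMFE scores by disease stage
#'
#' Builds the ordered stage series of mean global scores that the
#' tipping-point call is made on. Scored samples without an annotation, and
#' annotated samples without a score, are dropped with a warning; an empty
#' intersection is an error. A sample annotated more than once is an error.
#'
#' @param scores An `smfe_scores` object, or a data frame with columns
#'   `sample_id` and `global_score`.
#' @param annotation Stage annotation: `sample_id`, `stage_label`,
#'   `stage_order` (see [read_stage_annotation()]).
#' @return An `smfe_stage_series`: a tibble with one row per stage
#'   (`stage_label`, `stage_order`, `n`, `mean`, `sd`) in stage order,
#'   carrying the per-stage score lists as an attribute.
#' @export
stage_series <- function(scores, annotation) {
  if (inherits(scores, "smfe_scores")) scores <- glance(scores)
  scores <- as_tibble(scores)
  stopifnot(all(c("sample_id", "global_score") %in% names(scores)))
  ann <- validate_stage_annotation(annotation)

  unscored <- setdiff(ann$sample_id, scores$sample_id)
  unannotated <- setdiff(scores$sample_id, ann$sample_id)
  if (length(unannotated) > 0L) {
    warn(sprintf("%d scored sample(s) have no stage annotation and were dropped",
                 length(unannotated)))
  }
  if (length(unscored) > 0L) {
    warn(sprintf("%d annotated sample(s) have no score and were dropped",
                 length(unscored)))
  }
  joined <- dplyr::inner_join(scores, ann, by = "sample_id")
  if (nrow(joined) == 0L) abort("no sample is both scored and stage-annotated")

  joined <- arrange(joined, .data$stage_order, .data$sample_id)
  tab <- joined |>
    group_by(.data$stage_label, .data$stage_order) |>
    summarise(n = dplyr::n(), mean = mean(.data$global_score),
              sd = sd(.data$global_score), .groups = "drop") |>
    arrange(.data$stage_order)
  if (any(tab$n < 2L)) {
    warn(sprintf("stage(s) with a single sample cannot be tested: %s",
                 toString(tab$stage_label[tab$n < 2L])))
  }
  structure(tab,
            scores = split(joined$global_score, joined$stage_label),
            class = c("smfe_stage_series", class(tab)))
}

#' Call the tipping point of a stage series
#'
#' The candidate critical state is the stage with the largest mean global
#' sMFE among stages with at least `min_group` samples. Its scores are
#' compared with all other samples' scores pooled by a two-sided Welch
#' two-sample t-test; the candidate is reported as the critical state only
#' when P < `alpha`. The direction (an increase) is enforced by the argmax
#' itself, not by the test's sidedness.
#'
#' Because the tested stage is selected as the argmax, the family-wise null
#' rate of this call exceeds `alpha` and grows with the number of stages;
#' see the package vignette.
#'
#' @param series An [stage_series()] result.
#' @param alpha Significance level for the critical-state call (default
#'   0.05).
#' @param min_group Minimum samples a stage needs to be a candidate
#'   (default 2).
#' @return A one-row tibble: `candidate_stage`, `p_value`, `significant`,
#'   `mean_candidate`, `mean_others`, `n_candidate`, `n_others`.
#' @export
detect_tipping <- function(series, alpha = 0.05, min_group = 2L) {
  stopifnot(inherits(series, "smfe_stage_series"))
  score_list <- attr(series, "scores")
  eligible <- series$stage_label[series$n >= min_group]
  if (length(eligible) == 0L) abort("no stage has enough samples to test")
  means <- series$mean[match(eligible, series$stage_label)]
  candidate <- eligible[order(-means, eligible)][1L]
  x <- score_list[[candidate]]
  y <- unlist(score_list[setdiff(names(score_list), candidate)], use.names = FALSE)
  if (length(y) < min_group) abort("all usable samples fall in a single stage")
  p <- welch_p(x, y)
  tibble(
    candidate_stage = candidate,
    p_value = p,
    significant = p < alpha,
    mean_candidate = mean(x),
    mean_others = mean(y),
    n_candidate = length(x),
    n_others = length(y)
  )
}

# two-sided Welch t-test p-value, defined for degenerate (zero-variance)
# groups: equal constants give p = 1, distinct constants p = 0
welch_p <- function(x, y) {
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
  }
  tryCatch(t.test(x, y)$p.value, error = function(e) {
    if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0
  })
}

#' @export
print.smfe_stage_series <- function(x, ...) {
  cat("<smfe_stage_series>\n")
  NextMethod()
}

#' Plot the stage-wise mean sMFE curve
#'
#' @param object An [stage_series()] result.
#' @param ... Unused.
#' @return A ggplot: per-stage mean global sMFE with +/- 1 SE bars, in
#'   stage order.
#' @export
autoplot.smfe_stage_series <- function(object, ...) {
  df <- as_tibble(object)
  df$se <- df$sd / sqrt(df$n)
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$stage_label, .data$stage_order),
    y = .data$mean, group = 1
  )) +
    ggplot2::geom_line(color = "#c0392b") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$se,
                                        ymax = .data$mean + .data$se),
                           width = 0.15) +
    ggplot2::geom_point(size = 2, color = "#c0392b") +
    ggplot2::labs(x = "stage", y = "mean global sMFE") +
    ggplot2::theme_minimal()
}
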