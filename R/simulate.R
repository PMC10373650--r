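#' Generate a random directed gene network
#'
#' Two models: `"erdos_renyi"` draws each ordered pair independently with
#' probability `param`; `"scale_free"` draws a fixed number of edges
#' (`param` is the target mean out-degree) under power-law in/out fitness
#' (exponent 2.5), giving the heavy-tailed out-degree profile typical of
#' regulatory networks. Self-loops, multi-edges and isolated nodes are
#' removed; node names are `g001`, `g002`, ...
#'
#' @param n_genes Number of genes (>= 10).
#' @param model `"erdos_renyi"` or `"scale_free"`.
#' @param param Edge probability (ER) or mean out-degree (scale-free).
#' @param seed Integer seed; the result is deterministic given
#'   `(n_genes, model, param, seed)`.
#' @return An `smfe_network`.
#' @export
make_network <- function(n_genes, model = c("erdos_renyi", "scale_free"),
                         param = 0.05, seed = 1L) {
  model <- match.arg(model)
  if (!is.numeric(n_genes) || n_genes < 10) abort("n_genes must be >= 10")
  g <- withr::with_seed(as.integer(seed), {
    switch(model,
      erdos_renyi = igraph::sample_gnp(n_genes, param, directed = TRUE),
      scale_free = igraph::sample_fitness_pl(
        no.of.nodes = n_genes, no.of.edges = round(param * n_genes),
        exponent.out = 2.5, exponent.in = 2.5
      )
    )
  })
  g <- igraph::simplify(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  if (nrow(el) == 0L) abort("generated graph has no edges; increase param")
  nm <- sprintf("g%03d", seq_len(n_genes))
  new_smfe_network(arrange(
    tibble(from = nm[el[, 1L]], to = nm[el[, 2L]]),
    .data$from, .data$to
  ))
}

#' Describe a DNB-structured simulation scenario
#'
#' Encodes the dynamic-network-biomarker picture of a critical transition
#' as a generative model: a planted gene module whose within-module
#' correlation (`rho_in`) and standard deviation (`sd`) jump up, and whose
#' correlation with the rest of the network (`rho_out`) drops, at one
#' designated critical stage. All other stages, and the reference cohort,
#' use the base parameters. Defaults follow the desk-scale study design:
#' 200 genes with a 20-gene module, four stages of 30 samples plus 30
#' reference samples, SD tripling and rho_in 0.2 -> 0.8, rho_out
#' 0.2 -> 0.05 at stage III.
#'
#' @param n_genes Number of genes.
#' @param n_dnb Size of the planted module (used when `dnb_genes` is NULL).
#' @param dnb_genes Explicit module gene ids, or NULL to take the first
#'   `n_dnb` network nodes (the generator's covariance and graph models are
#'   exchangeable over genes, so any deterministic pick is equivalent).
#' @param stages Ordered stage labels.
#' @param critical_stage The stage carrying the critical-state parameters.
#' @param n_ref,n_per_stage Reference / per-stage sample counts.
#' @param sd_base,sd_crit Module gene SDs away from / at the critical stage
#'   (`sd_crit > sd_base`).
#' @param rho_in_base,rho_in_crit Within-module correlations
#'   (`rho_in_crit > rho_in_base`).
#' @param rho_out_base,rho_out_crit Module-to-outside correlations
#'   (`rho_out_crit <= rho_out_base`); `rho_out_base` is also the background
#'   correlation among non-module genes.
#' @param mean_expr Common expression mean (values are clipped at 0, so the
#'   mean should sit several SDs above 0).
#' @param mean_shift Added to module gene means at every tumor stage
#'   (default 0 keeps mean expression flat across stages, isolating the
#'   variance/correlation signal; set > 0 to create DE genes).
#' @param seed Integer seed.
#' @return A list of class `smfe_scenario`.
#' @export
dnb_scenario <- function(n_genes = 200L, n_dnb = 20L, dnb_genes = NULL,
                         stages = c("I", "II", "III", "IV"),
                         critical_stage = "III",
                         n_ref = 30L, n_per_stage = 30L,
                         sd_base = 1, sd_crit = 3,
                         rho_in_base = 0.2, rho_in_crit = 0.8,
                         rho_out_base = 0.2, rho_out_crit = 0.05,
                         mean_expr = 10, mean_shift = 0, seed = 1L) {
  sc <- list(n_genes = as.integer(n_genes), n_dnb = as.integer(n_dnb),
             dnb_genes = dnb_genes, stages = stages,
             critical_stage = critical_stage,
             n_ref = as.integer(n_ref), n_per_stage = as.integer(n_per_stage),
             sd_base = sd_base, sd_crit = sd_crit,
             rho_in_base = rho_in_base, rho_in_crit = rho_in_crit,
             rho_out_base = rho_out_base, rho_out_crit = rho_out_crit,
             mean_expr = mean_expr, mean_shift = mean_shift,
             seed = as.integer(seed))
  if (!critical_stage %in% stages) abort("critical_stage must be one of stages")
  if (sc$sd_crit <= sc$sd_base) abort("sd_crit must exceed sd_base")
  if (sc$rho_in_crit <= sc$rho_in_base) abort("rho_in_crit must exceed rho_in_base")
  if (sc$rho_out_crit > sc$rho_out_base) abort("rho_out_crit must not exceed rho_out_base")
  structure(sc, class = "smfe_scenario")
}

# block covariance for one condition; dnb index vector within 1..G
dnb_sigma <- function(G, dnb, sd_dnb, sd_bg, rho_in, rho_out, rho_bg) {
  sds <- rep(sd_bg, G)
  sds[dnb] <- sd_dnb
  R <- matrix(rho_bg, G, G)
  R[dnb, dnb] <- rho_in
  R[dnb, -dnb] <- rho_out
  R[-dnb, dnb] <- rho_out
  diag(R) <- 1
  Sigma <- R * tcrossprod(sds)
  ev <- min(eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < -1e-8 * max(diag(Sigma))) {
    abort(sprintf("covariance not positive semi-definite (min eigenvalue %.3g); check rho parameters", ev))
  }
  Sigma
}

#' Simulate a reference cohort and staged case cohorts with a planted DNB
#'
#' Per stage, samples are drawn from a multivariate Gaussian whose block
#' covariance realizes the scenario's parameters (critical-state values at
#' the critical stage, base values elsewhere and for the reference cohort),
#' then clipped at 0 so the expression matrix is nonnegative -- a mild
#' distortion of the target moments when the mean sits close to 0.
#'
#' The module is a group of interacting molecules: because the generator
#' gives every within-module gene pair the same correlation, the directed
#' network is by default augmented with every ordered within-module edge
#' (`wire_module = TRUE`), so the network topology matches the dependence
#' structure the covariance encodes. The returned `network` element carries
#' the augmented network and should be the one samples are scored against.
#'
#' @param scenario An [dnb_scenario()].
#' @param net An `smfe_network` whose nodes the genes are drawn for; the
#'   planted module must be (or is chosen as) a subset of its nodes.
#' @param wire_module Add all ordered within-module edges to the network
#'   (default `TRUE`).
#' @return A list: `reference` (expression tibble), `stages` (named list of
#'   expression tibbles), `annotation` (stage table for all case samples),
#'   `network` (the possibly augmented `smfe_network`), `dnb_genes`,
#'   `scenario`.
#' @export
make_dnb_dataset <- function(scenario, net, wire_module = TRUE) {
  stopifnot(inherits(scenario, "smfe_scenario"), inherits(net, "smfe_network"))
  genes <- sort(net$nodes)
  G <- length(genes)
  dnb_genes <- scenario$dnb_genes
  if (is.null(dnb_genes)) {
    # exchangeable covariance + exchangeable graph models: any deterministic
    # pick works; take the first n_dnb node names
    dnb_genes <- genes[seq_len(scenario$n_dnb)]
  }
  if (!all(dnb_genes %in% genes)) abort("dnb_genes must be a subset of the network nodes")
  dnb <- match(dnb_genes, genes)
  if (wire_module) {
    extra <- expand.grid(from = dnb_genes, to = dnb_genes,
                         stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
    extra <- extra[extra$from != extra$to, , drop = FALSE]
    net <- new_smfe_network(arrange(
      unique(bind_rows(net$edges, as_tibble(extra))), .data$from, .data$to
    ))
  }

  sig_base <- dnb_sigma(G, dnb, scenario$sd_base, scenario$sd_base,
                        scenario$rho_in_base, scenario$rho_out_base,
                        scenario$rho_out_base)
  sig_crit <- dnb_sigma(G, dnb, scenario$sd_crit, scenario$sd_base,
                        scenario$rho_in_crit, scenario$rho_out_crit,
                        scenario$rho_out_base)

  draw <- function(nsamp, Sigma, mu, prefix) {
    x <- MASS::mvrnorm(nsamp, mu = mu, Sigma = Sigma)
    x[x < 0] <- 0
    mat <- t(x)
    dimnames(mat) <- list(genes, sprintf("%s_%02d", prefix, seq_len(nsamp)))
    mat
  }

  mu_base <- rep(scenario$mean_expr, G)
  mu_stage <- mu_base
  mu_stage[dnb] <- mu_stage[dnb] + scenario$mean_shift

  out <- withr::with_seed(scenario$seed, {
    reference <- draw(scenario$n_ref, sig_base, mu_base, "ref")
    stage_mats <- lapply(scenario$stages, function(st) {
      Sigma <- if (st == scenario$critical_stage) sig_crit else sig_base
      draw(scenario$n_per_stage, Sigma, mu_stage, paste0("s", st))
    })
    names(stage_mats) <- scenario$stages
    list(reference = reference, stage_mats = stage_mats)
  })

  annotation <- bind_rows(lapply(seq_along(scenario$stages), function(i) {
    tibble(sample_id = colnames(out$stage_mats[[i]]),
           stage_label = scenario$stages[i], stage_order = i)
  }))
  list(
    reference = expr_to_tibble(out$reference),
    stages = lapply(out$stage_mats, expr_to_tibble),
    annotation = annotation,
    network = net,
    dnb_genes = dnb_genes,
    scenario = scenario
  )
}

#' Simulate survival linked to a marker-positive sample group
#'
#' Exponential survival times with the hazard multiplied by `hazard_ratio`
#' for marker-positive samples. Each sample is independently censored with
#' probability `censor_rate`; a censored sample's recorded time is uniform
#' on (0, its event time).
#'
#' @param samples Character vector of sample ids.
#' @param marker_positive Subset of `samples` carrying the marker.
#' @param hazard_ratio Hazard multiplier for marker-positive samples (> 0).
#' @param baseline_scale Mean survival time of marker-negative samples, in
#'   the study's time unit.
#' @param censor_rate Probability a sample is censored, in \[0, 1).
#' @param seed Integer seed.
#' @return A survival tibble (`sample_id`, `time`, `event`).
#' @export
make_survival <- function(samples, marker_positive = character(),
                          hazard_ratio = 1, baseline_scale = 365,
                          censor_rate = 0.2, seed = 1L) {
  if (!is.numeric(hazard_ratio) || hazard_ratio <= 0) abort("hazard_ratio must be > 0")
  if (!is.numeric(censor_rate) || censor_rate < 0 || censor_rate >= 1) {
    abort("censor_rate must lie in [0, 1)")
  }
  nn <- length(samples)
  withr::with_seed(as.integer(seed), {
    rate <- ifelse(samples %in% marker_positive, hazard_ratio, 1) / baseline_scale
    tt <- rexp(nn, rate = rate)
    cens <- rbinom(nn, 1L, censor_rate) == 1L
    time <- ifelse(cens, runif(nn, 0, tt), tt)
    tibble(sample_id = samples, time = time, event = as.integer(!cens))
  })
}
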