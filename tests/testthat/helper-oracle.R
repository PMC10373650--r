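# Independent literal evaluation of the local differential score, written
# as a plain step-by-step transcription: explicit loops, stats::cor for
# every correlation, no shared code with the package's scoring engine.

oracle_normalize <- function(ref_mat, vec) {
  out <- numeric(nrow(ref_mat))
  names(out) <- rownames(ref_mat)
  for (g in rownames(ref_mat)) {
    lo <- min(ref_mat[g, ])
    hi <- max(ref_mat[g, ])
    if (hi == lo) {
      out[g] <- 0
    } else {
      z <- (vec[g] - lo) / (hi - lo)
      out[g] <- min(max(z, 0), 1)
    }
  }
  out
}

oracle_pcc <- function(a, b) {
  if (length(unique(a)) == 1L || length(unique(b)) == 1L) return(0)
  r <- suppressWarnings(stats::cor(a, b))
  if (is.na(r)) 0 else r
}

oracle_pop_sd <- function(x) {
  mu <- mean(x)
  sqrt(sum((x - mu)^2) / length(x))
}

oracle_mfe <- function(xbar, pvec) {
  total <- 0
  for (p in pvec) {
    u <- xbar * p
    if (u > 0) total <- total - u * log(u)
  }
  total
}

# cohort: raw genes x samples matrix already restricted to the genes in play
oracle_cohort_mfe <- function(ref_mat, cohort, center, neighbors) {
  znorm <- sapply(colnames(cohort), function(s) oracle_normalize(ref_mat, cohort[, s]))
  absr <- sapply(neighbors, function(nb) abs(oracle_pcc(znorm[nb, ], znorm[center, ])))
  denom <- 1 + sum(absr)  # self term |PCC| = 1
  pvec <- absr / denom
  list(
    mfe = oracle_mfe(mean(znorm[center, ]), pvec),
    sd = oracle_pop_sd(znorm[center, ])
  )
}

# full local score of one gene for one case sample
oracle_local_smfe <- function(ref_mat, case_vec, center, neighbors,
                              form = "product") {
  stopifnot(length(neighbors) >= 2L)
  ref_part <- oracle_cohort_mfe(ref_mat, ref_mat, center, neighbors)
  mixed <- cbind(ref_mat, `__case__` = case_vec[rownames(ref_mat)])
  mix_part <- oracle_cohort_mfe(ref_mat, mixed, center, neighbors)
  raw <- if (form == "product") {
    ref_part$sd * ref_part$mfe - mix_part$sd * mix_part$mfe
  } else {
    ref_part$sd * ref_part$mfe - mix_part$sd + mix_part$mfe
  }
  abs(raw) / log(length(neighbors))
}

# every gene with >= 2 out-neighbors, plus the top-fraction summary
oracle_score_sample <- function(ref_mat, case_vec, edges, fraction = 0.05) {
  centers <- sort(unique(edges$from))
  local <- c()
  for (g in centers) {
    nbs <- sort(unique(edges$to[edges$from == g]))
    nbs <- setdiff(nbs, g)
    if (length(nbs) >= 2L) {
      local[g] <- oracle_local_smfe(ref_mat, case_vec, g, nbs)
    }
  }
  if (length(local) == 0L) {
    return(list(local = local, global = NA_real_, signaling = character()))
  }
  L <- length(local)
  Q <- ceiling(fraction * L)
  ord <- order(-local, names(local))
  list(local = local, global = mean(local[ord][seq_len(Q)]),
       signaling = names(local)[ord][seq_len(Q)])
}

# all directed labelled graphs (no self-loops) on the given nodes
enumerate_digraphs <- function(nodes) {
  pairs <- expand.grid(from = nodes, to = nodes, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, ]
  np <- nrow(pairs)
  lapply(seq_len(2^np) - 1L, function(mask) {
    pairs[bitwAnd(bitwShiftR(mask, seq_len(np) - 1L), 1L) == 1L, , drop = FALSE]
  })
}

random_expression <- function(genes, samples, seed) {
  withr::with_seed(seed, {
    mat <- matrix(runif(length(genes) * length(samples), 0, 10),
                  nrow = length(genes),
                  dimnames = list(genes, samples))
    mat
  })
}
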