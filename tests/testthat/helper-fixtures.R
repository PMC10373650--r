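# small in-code fixtures shared across test files

# directed ring where every node points at the next two: out-degree 2 all round
ring_network <- function(n) {
  ids <- sprintf("r%03d", seq_len(n))
  nxt <- function(i, k) ids[(i + k - 1L) %% n + 1L]
  build_network(
    data.frame(from = rep(ids, 2L),
               to = c(nxt(seq_len(n), 1L), nxt(seq_len(n), 2L))),
    threshold = 0, directed = TRUE
  )
}

star_network <- function(center = "A", leaves = c("B", "C", "D")) {
  build_network(data.frame(from = center, to = leaves),
                threshold = 0, directed = TRUE)
}

# deterministic 5-gene toy used by the core tests
toy5 <- function() {
  genes <- paste0("g", 1:5)
  ref <- matrix(
    c(2.0, 4.0, 6.0, 3.0,
      1.0, 0.5, 2.5, 2.0,
      5.0, 4.0, 1.0, 2.0,
      0.2, 0.9, 0.4, 0.8,
      3.0, 3.5, 2.0, 4.0),
    nrow = 5, byrow = TRUE,
    dimnames = list(genes, paste0("ref", 1:4))
  )
  case <- c(g1 = 5.0, g2 = 0.8, g3 = 3.0, g4 = 0.6, g5 = 1.0)
  edges <- data.frame(
    from = c("g1", "g1", "g1", "g2", "g2", "g3", "g4", "g5"),
    to   = c("g2", "g3", "g4", "g3", "g5", "g1", "g5", "g1")
  )
  list(genes = genes, ref = ref, case = case, edges = edges,
       net = build_network(edges, threshold = 0, directed = TRUE))
}

tsv_file <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# write a full simulated study to disk for pipeline-level tests
sim_run_files <- function(dir, seed = 17) {
  net <- make_network(200, "erdos_renyi", 0.05, seed = seed)
  sc <- dnb_scenario(seed = seed)
  dat <- make_dnb_dataset(sc, net)
  case <- do.call(cbind, lapply(dat$stages, function(s) {
    m <- as.matrix(s[, -1])
    rownames(m) <- s$gene
    m
  }))
  write_expression(case, file.path(dir, "case.tsv"))
  write_expression(dat$reference, file.path(dir, "reference.tsv"))
  readr::write_tsv(cbind(dat$network$edges, score = 1),
                   file.path(dir, "edges.tsv"))
  readr::write_tsv(dat$annotation, file.path(dir, "stages.tsv"))
  rec <- make_survival(colnames(case), character(), censor_rate = 0.2,
                       seed = seed)
  write_survival(rec, file.path(dir, "survival.tsv"))
  list(dat = dat, case = case)
}

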