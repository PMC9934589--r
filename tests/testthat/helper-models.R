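# Hand-built fixture models used across test files.

# EX_in -> A -> B -> EX_out, bottleneck [0, 10] on the import.
chain_model <- function(import_ub = 10) {
  metabolic_model(
    "chain",
    data.frame(id = c("A", "B"), name = c("A", "B"), compartment = "c"),
    data.frame(id = c("EX_in", "R1", "EX_out"),
               lower_bound = 0, upper_bound = c(import_ub, 100, 100),
               subsystem = c("exchange", "core", "exchange")),
    list(EX_in = c(A = 1), R1 = c(A = -1, B = 1), EX_out = c(B = -1)),
    list(EX_in = gpr_empty(), R1 = parse_gpr("g1"), EX_out = gpr_empty()),
    "EX_out")
}

# Two parallel equivalent routes A -> B.
parallel_model <- function() {
  metabolic_model(
    "parallel",
    data.frame(id = c("A", "B"), name = c("A", "B"), compartment = "c"),
    data.frame(id = c("EX_in", "P1", "P2", "EX_out"),
               lower_bound = 0, upper_bound = c(10, 100, 100, 100),
               subsystem = c("exchange", "core", "core", "exchange")),
    list(EX_in = c(A = 1), P1 = c(A = -1, B = 1), P2 = c(A = -1, B = 1),
         EX_out = c(B = -1)),
    NULL, "EX_out")
}

# Random small feasible model: a few linear chains plus a shared sink, with
# random bounds; always admits v = 0 and a positive optimum.
random_toy_model <- function(seed, n_chains = 3, len = 2) {
  withr::with_seed(seed, {
    mets <- list(); rxns <- list(); stoich <- list()
    for (i in seq_len(n_chains)) {
      ids <- sprintf("m%d_%d", i, seq_len(len))
      mets[[i]] <- ids
      stoich[[sprintf("in%d", i)]] <-
        stats::setNames(1, ids[1])
      for (j in seq_len(len - 1))
        stoich[[sprintf("c%d_%d", i, j)]] <-
          stats::setNames(c(-1, 1), ids[j:(j + 1)])
      stoich[[sprintf("use%d", i)]] <-
        stats::setNames(c(-1, 1), c(ids[len], "sink_met"))
    }
    stoich[["objective"]] <- c(sink_met = -1)
    ids <- names(stoich)
    ub <- round(stats::runif(length(ids), 2, 12), 2)
    metabolic_model(
      sprintf("rand%d", seed),
      data.frame(id = c(unlist(mets), "sink_met"),
                 name = "m", compartment = "c"),
      data.frame(id = ids, lower_bound = 0, upper_bound = ub,
                 subsystem = "core"),
      stoich, NULL, "objective")
  })
}
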