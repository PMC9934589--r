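toy_weighted_model <- function() {
  metabolic_model(
    "tw",
    data.frame(id = c("A", "B", "C"), name = "m", compartment = "c"),
    data.frame(id = c("EX_in", "r1", "r2", "r3", "EX_out"),
               lower_bound = 0, upper_bound = 100,
               subsystem = c("exchange", "s1", "s1", "s2", "exchange")),
    list(EX_in = c(A = 1), r1 = c(A = -1, B = 1), r2 = c(A = -1, B = 1),
         r3 = c(B = -1, C = 1), EX_out = c(C = -1)),
    list(EX_in = gpr_empty(), r1 = parse_gpr("g1 or g2"),
         r2 = parse_gpr("g3 and g4"), r3 = parse_gpr("g5"),
         EX_out = gpr_empty()),
    "EX_out")
}

test_that("reaction weights propagate through GPRs with max-over-OR, min-over-AND", {
  m <- toy_weighted_model()
  w <- c(g1 = 1.5, g2 = -0.5, g3 = 2, g4 = 0.25, g5 = -1)
  rw <- assign_reaction_weights(m, w)
  expect_equal(unname(rw["r1"]), 1.5)
  expect_equal(unname(rw["r2"]), 0.25)
  expect_equal(unname(rw["r3"]), -1)
  # empty GPRs are excluded, not zero-weighted
  expect_false("EX_in" %in% names(rw))
  # reactions whose genes are all absent are excluded too
  rw2 <- assign_reaction_weights(m, c(g5 = 1))
  expect_setequal(names(rw2), "r3")
})

test_that("reaction weights agree with the GPR oracle on random rules", {
  set.seed(21)
  genes <- paste0("g", 1:4)
  trees <- all_gpr_trees(genes, depth = 2)
  rules <- trees[sample.int(length(trees), 20)]
  m <- toy_weighted_model()
  for (tr in rules) {
    m$gpr[["r1"]] <- tr
    vals <- stats::setNames(round(stats::rnorm(4), 2), genes)
    rw <- assign_reaction_weights(m, vals)
    expect_equal(unname(rw["r1"]), gpr_oracle(tr, vals),
                 label = gpr_to_string(tr))
  }
})

test_that("task scores are plain means of available reaction weights", {
  rw <- c(a = 1, b = 2, c = 3)
  expect_equal(task_score(rw, c("a", "b", "c")), 2)
  expect_equal(task_score(stats::setNames(numeric(3), letters[1:3]),
                          c("a", "b")), 0)
  expect_warning(s <- task_score(rw, "zzz"), "skipped")
  expect_true(is.na(s))
})

test_that("permutation null matches the exhaustive distribution for a tiny pool", {
  # pool {0, 0, 6}, task size 2: exhaustive null means are {0, 3, 3}
  nulls <- permutation_null(2, c(0, 0, 6), n_perm = 3000, seed = 7)
  expect_setequal(unique(nulls), c(0, 3))
  p0 <- mean(nulls == 0)
  se <- sqrt((1 / 3) * (2 / 3) / 3000)
  expect_lt(abs(p0 - 1 / 3), 3 * se)
})

test_that("degenerate permutation pools behave as forced", {
  expect_equal(permutation_null(2, c(0, 0, 0, 0), n_perm = 50, seed = 1),
               rep(0, 50))
  expect_equal(permutation_null(3, c(1, 2, 3), n_perm = 20, seed = 1),
               rep(2, 20))
  expect_error(permutation_null(4, c(1, 2), n_perm = 10),
               class = "tidegem_config_error")
})

test_that("tide_test applies the add-one estimator and calls direction by tail", {
  nulls <- rep(1, 1000)
  r <- tide_test(1, nulls)
  expect_equal(r$p_upper, 1)
  expect_equal(r$p_lower, 1)
  expect_false(r$significant)
  expect_identical(r$direction, "none")

  r2 <- tide_test(5, stats::rnorm(1000))
  expect_equal(r2$p_upper, 1 / 1001)
  expect_true(r2$significant)
  expect_identical(r2$direction, "male_biased")
  expect_gt(r2$p_two_sided, 0)

  r3 <- tide_test(-5, stats::rnorm(1000))
  expect_identical(r3$direction, "female_biased")

  sym <- c(-(500:1) / 100, (1:500) / 100)
  r4 <- tide_test(0, sym)
  expect_gt(r4$p_two_sided, 0.99)
})

test_that("all-zero weights yield no significant task", {
  m <- build_toy_gem(toy_gem_config(n_subsystems = 4, seed = 31))
  w <- stats::setNames(rep(0, length(model_genes(m))), model_genes(m))
  res <- suppressMessages(tides_run(m, w, n_perm = 200, seed = 1))
  expect_equal(sum(res$significant), 0)
  expect_true(all(res$p_two_sided > 0))
})

test_that("a planted male effect is recovered as a significant male-biased task", {
  m <- build_toy_gem(toy_gem_config(n_subsystems = 5, seed = 32))
  sim <- simulate_expression(m, expression_sim_config(
    planted_effects = c(subsystem_03 = 1.0), noise_sd = 0.1, seed = 33))
  de <- restrict_to_model(differential_expression(sim$matrix, sim$labels), m)
  res <- suppressMessages(tides_run(m, de, n_perm = 1000, seed = 34))
  row <- res[res$task == "subsystem_03", ]
  expect_true(row$significant)
  expect_identical(row$direction, "male_biased")
  expect_equal(sum(res$significant), 1)
})

test_that("tides output is invariant to task and reaction ordering", {
  m <- build_toy_gem(toy_gem_config(n_subsystems = 4, seed = 35))
  sim <- simulate_expression(m, expression_sim_config(
    planted_effects = c(subsystem_01 = 0.8), noise_sd = 0.2, seed = 36))
  de <- restrict_to_model(differential_expression(sim$matrix, sim$labels), m)
  res1 <- suppressMessages(tides_run(m, de, n_perm = 300, seed = 37))

  tasks <- model_tasks(m)
  shuffled <- withr::with_seed(3, tasks[sample(names(tasks))])
  shuffled <- lapply(shuffled, function(x) withr::with_seed(4, sample(x)))
  res2 <- suppressMessages(tides_run(m, de, n_perm = 300, seed = 37,
                                     tasks = shuffled))
  o1 <- res1[order(res1$task), ]; o2 <- res2[order(res2$task), ]
  rownames(o1) <- rownames(o2) <- NULL
  expect_equal(o1, o2, ignore_attr = TRUE)
})

test_that("permutation p never reaches zero and falls as the planted effect grows", {
  m <- build_toy_gem(toy_gem_config(n_subsystems = 4, seed = 38))
  pvals <- vapply(c(0.25, 0.75, 2), function(eff) {
    sim <- simulate_expression(m, expression_sim_config(
      planted_effects = c(subsystem_02 = eff), noise_sd = 0.25, seed = 39))
    de <- restrict_to_model(differential_expression(sim$matrix, sim$labels), m)
    res <- suppressMessages(tides_run(m, de, n_perm = 500, seed = 40))
    res$p_two_sided[res$task == "subsystem_02"]
  }, numeric(1))
  expect_true(all(pvals > 0))
  expect_true(all(diff(pvals) <= 0))
})

test_that("the task-score matrix reports per-contrast scores with masking", {
  m <- build_toy_gem(toy_gem_config(n_subsystems = 4, seed = 41))
  sim <- simulate_expression(m, expression_sim_config(
    planted_effects = c(subsystem_01 = 1.2), noise_sd = 0.1, seed = 42))
  de <- restrict_to_model(differential_expression(sim$matrix, sim$labels), m)
  zero <- stats::setNames(rep(0, length(model_genes(m))), model_genes(m))
  tsm <- suppressMessages(task_score_matrix(
    m, list(drug1 = de, drug1_again = de, vehicle = zero),
    n_perm = 300, seed = 43))
  expect_identical(unname(tsm$score["drug1", ]),
                   unname(tsm$score["drug1_again", ]))
  expect_identical(unname(tsm$masked["drug1", ]),
                   unname(tsm$masked["drug1_again", ]))
  expect_true(all(tsm$masked["vehicle", ] == 0))
  expect_true(tsm$significant["drug1", "subsystem_01"])
  expect_equal(tsm$masked["drug1", "subsystem_01"],
               tsm$score["drug1", "subsystem_01"])
})
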