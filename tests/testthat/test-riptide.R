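test_that("abundance maps to rank-linear weights with tie sharing and median fill", {
  m <- chain_model()  # only R1 has a GPR (g1)
  w <- abundance_to_weights(m, c(g1 = 10))
  expect_equal(unname(w["R1"]), 0.5)          # single ranked reaction
  expect_equal(unname(w["EX_in"]), 0.5)       # no-GPR median fill

  m2 <- toy2 <- metabolic_model(
    "two",
    data.frame(id = "A", name = "A", compartment = "c"),
    data.frame(id = c("r_hi", "r_lo"), lower_bound = 0, upper_bound = 10,
               subsystem = ""),
    list(r_hi = c(A = 1), r_lo = c(A = -1)),
    list(r_hi = parse_gpr("gh"), r_lo = parse_gpr("gl")), "r_lo")
  w2 <- abundance_to_weights(m2, c(gh = 10, gl = 5))
  expect_equal(unname(w2[c("r_hi", "r_lo")]), c(0, 1))

  w3 <- abundance_to_weights(m2, c(gh = 7, gl = 7))
  expect_equal(unname(w3[c("r_hi", "r_lo")]), c(0.5, 0.5))

  expect_error(abundance_to_weights(m2, c(zz = 1)),
               class = "tidegem_config_error")
})

test_that("weight order is the exact reverse of abundance order", {
  m <- build_toy_gem(toy_gem_config(n_subsystems = 3, seed = 51))
  withr::with_seed(52, {
    ab <- stats::setNames(stats::runif(length(model_genes(m)), 1, 100),
                          model_genes(m))
  })
  w <- abundance_to_weights(m, ab)
  a <- vapply(m$reactions$id, function(rid)
    evaluate_gpr(m$gpr[[rid]], ab, "skip"), numeric(1))
  ranked <- !is.na(a)
  expect_equal(order(w[ranked], -a[ranked]), order(-a[ranked], w[ranked]))
  expect_true(all(w >= 0 & w <= 1))
})

test_that("pruning removes dead ends and the disfavored parallel route", {
  m <- parallel_model()
  pr <- prune_model(m, c(P1 = 0.1, P2 = 0.9), min_fraction = 0.4)
  expect_false("P2" %in% pr$model$reactions$id)
  expect_true("P1" %in% pr$model$reactions$id)
  expect_gte(pr$kept_fraction, 0.4)

  m2 <- build_toy_gem(toy_gem_config(n_subsystems = 3, seed = 53))
  w <- stats::setNames(rep(0.5, nrow(m2$reactions)), m2$reactions$id)
  pr2 <- prune_model(m2, w)
  expect_length(grep("_dead$", pr2$model$reactions$id), 0)
  expect_true(pr2$model$objective_id %in% pr2$model$reactions$id)
})

test_that("pruned models respect the objective-fraction window on random inputs", {
  for (seed in 1:10) {
    cfg <- toy_gem_config(n_subsystems = 2 + seed %% 3, seed = seed)
    m <- build_toy_gem(cfg)
    w <- withr::with_seed(seed, stats::setNames(
      stats::runif(nrow(m$reactions)), m$reactions$id))
    zstar <- solve_fba(m)$objective_value
    pr <- prune_model(m, w, min_fraction = 0.4)
    zp <- solve_fba(pr$model)$objective_value
    expect_gte(zp, 0.4 * zstar - 1e-6)
    expect_lte(zp, zstar + 1e-6)
  }
})

test_that("sampling a one-dimensional polytope is uniform on the interval", {
  m <- metabolic_model(
    "one",
    data.frame(id = "a", name = "a", compartment = "c"),
    data.frame(id = c("EX_a", "use"), lower_bound = c(0, 2),
               upper_bound = c(10, 4), subsystem = ""),
    list(EX_a = c(a = 1), use = c(a = -1)), NULL, "use")
  fs <- sample_context(m, weights = c(EX_a = 0.5, use = 0.5),
                       min_fraction = 0, n_flux_samples = 110, seed = 3)
  expect_equal(dim(fs), c(110, 2))
  expect_true(all(fs[, "use"] >= 2 - 1e-9 & fs[, "use"] <= 4 + 1e-9))
  se <- (4 - 2) / sqrt(12) / sqrt(110)
  expect_lt(abs(mean(fs[, "use"]) - 3), 3 * se)
  # the two reactions are coupled one-to-one
  expect_lt(max(abs(fs[, "EX_a"] - fs[, "use"])), 1e-9)
})

test_that("flux sampling is seeded, feasible, and non-vacuous", {
  m <- build_toy_gem(toy_gem_config(n_subsystems = 3, seed = 54))
  ab <- withr::with_seed(55, stats::setNames(
    2^stats::rnorm(length(model_genes(m)), 6, 1), model_genes(m)))
  w <- abundance_to_weights(m, ab)
  pr <- prune_model(m, w)
  fs1 <- sample_context(pr, w, seed = 56)
  fs2 <- sample_context(pr, w, seed = 56)
  expect_identical(fs1, fs2)
  expect_equal(nrow(fs1), 110)

  S <- stoich_matrix(pr$model)
  expect_lt(max(abs(S %*% t(fs1))), 1e-6)
  lb <- pr$model$reactions$lower_bound; ub <- pr$model$reactions$upper_bound
  expect_true(all(t(fs1) >= lb - 1e-6) && all(t(fs1) <= ub + 1e-6))
  # every kept reaction is active in at least one sample
  expect_true(all(apply(abs(fs1), 2, max) > 1e-6))
  # the objective holds its fraction in every sample
  zp <- solve_fba(pr$model)$objective_value
  expect_true(all(fs1[, "biomass"] >= 0.4 * zp - 1e-6))

  one <- sample_context(pr, w, n_flux_samples = 1, seed = 57)
  expect_equal(nrow(one), 1)
})

test_that("ensembles group retained models by sex and exclude failing samples", {
  m <- build_toy_gem(toy_gem_config(n_subsystems = 3, seed = 58))
  sim <- simulate_expression(m, expression_sim_config(n_per_sex = 3, seed = 59))
  expr <- sim$matrix
  # identical expression for two samples of the same sex
  expr[, "female_02"] <- expr[, "female_01"]
  # one sample whose expression provides no usable abundances
  expr[, "male_03"] <- NA_real_
  ens <- build_ensemble(m, expr, sim$labels, n_flux_samples = 20, seed = 60)
  expect_s3_class(ens, "context_ensemble")
  expect_identical(ens$excluded$sample, "male_03")
  expect_setequal(names(ens$models),
                  setdiff(names(sim$labels), "male_03"))
  expect_identical(ens$models$female_01$model$reactions$id,
                   ens$models$female_02$model$reactions$id)
  # sexes are disjoint by sample id
  expect_length(intersect(names(ens$models)[ens$sex == "male"],
                          names(ens$models)[ens$sex == "female"]), 0)
})

test_that("merging ensembles concatenates models and rejects duplicates", {
  m <- build_toy_gem(toy_gem_config(n_subsystems = 2, seed = 61))
  sim <- simulate_expression(m, expression_sim_config(n_per_sex = 3, seed = 62))
  males <- sim$labels[sim$labels == "male"]
  females <- sim$labels[sim$labels == "female"]
  e1 <- build_ensemble(m, sim$matrix, males, n_flux_samples = 5, seed = 63)
  e2 <- build_ensemble(m, sim$matrix, females, n_flux_samples = 5, seed = 64)
  ens <- merge_ensembles(e1, e2)
  expect_length(ens$models, 6)
  expect_error(merge_ensembles(e1, e1), class = "tidegem_validation_error")
})
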