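test_that("sex imputation splits samples at the configured quantiles", {
  mat <- matrix(1:100, 1, 100,
                dimnames = list("SRY", sprintf("s%03d", 1:100)))
  lab <- impute_sex(mat, "SRY", 0.16)
  expect_equal(sum(lab == "male"), 16)
  expect_equal(sum(lab == "female"), 16)
  expect_equal(sum(lab == "unassigned"), 68)
  # the top samples are the males
  expect_true(all(lab[sprintf("s%03d", 85:100)] == "male"))
})

test_that("sex imputation is invariant under strictly monotone marker transforms", {
  withr::with_seed(5, {
    v <- stats::rnorm(60)
    mat1 <- matrix(v, 1, 60, dimnames = list("mk", paste0("s", 1:60)))
    mat2 <- matrix(exp(2 * v) + 1, 1, 60,
                   dimnames = list("mk", paste0("s", 1:60)))
    expect_identical(impute_sex(mat1, "mk"), impute_sex(mat2, "mk"))
  })
})

test_that("degenerate imputation inputs fail soft or loud as documented", {
  mat <- matrix(c(1, 2), 1, 2, dimnames = list("mk", c("a", "b")))
  expect_warning(lab <- impute_sex(mat, "mk"), "unassigned")
  expect_true(all(lab == "unassigned"))
  cst <- matrix(1, 1, 50, dimnames = list("mk", paste0("s", 1:50)))
  expect_error(impute_sex(cst, "mk"), class = "tidegem_degenerate_error")
  expect_error(impute_sex(mat, "nope"), class = "tidegem_config_error")
})

test_that("imputed labels recover the generating sex for a well-separated marker", {
  m <- build_toy_gem(toy_gem_config(n_subsystems = 2, seed = 3))
  sim <- simulate_expression(m, expression_sim_config(
    n_per_sex = 25, noise_sd = 0.5, marker_gene_gap = 6, seed = 10))
  lab <- impute_sex(sim$matrix, "SRY_marker")
  assigned <- names(lab)[lab != "unassigned"]
  expect_gt(length(assigned), 10)
  expect_identical(lab[assigned], sim$labels[assigned])
})

test_that("the vectorized Welch test matches stats::t.test gene by gene", {
  withr::with_seed(11, {
    mat <- matrix(stats::rnorm(20 * 14), 20, 14,
                  dimnames = list(paste0("g", 1:20), paste0("s", 1:14)))
    i1 <- 1:8; i2 <- 9:14
    w <- tidegem:::welch_rows(mat, i1, i2)
    for (g in c(1, 7, 20)) {
      tt <- stats::t.test(mat[g, i1], mat[g, i2])
      expect_equal(unname(w$p[g]), tt$p.value, tolerance = 1e-12)
      expect_equal(unname(w$t[g]), unname(tt$statistic), tolerance = 1e-12)
    }
  })
})

test_that("differential expression zeroes non-significant genes and handles degenerate rows", {
  # a constant gene and a strongly shifted gene
  n <- 6
  mat <- rbind(flat = rep(5, 2 * n),
               up = c(rep(5, n), rep(8, n)) + rep(c(0.01, -0.01), n))
  colnames(mat) <- c(paste0("f", 1:n), paste0("m", 1:n))
  labels <- stats::setNames(rep(c("female", "male"), each = n), colnames(mat))
  de <- differential_expression(mat, labels)
  expect_equal(de$p[de$gene == "flat"], 1)
  expect_equal(de$weight[de$gene == "flat"], 0)
  expect_lt(de$fdr[de$gene == "up"], 0.1)
  expect_equal(de$weight[de$gene == "up"], 3, tolerance = 0.05)
  expect_error(differential_expression(mat, labels[c(1, 2, 7, 8)]),
               class = "tidegem_config_error")
})

test_that("FDR column equals the Benjamini-Hochberg step-up rule computed by hand", {
  withr::with_seed(12, {
    mat <- matrix(stats::rnorm(30 * 12), 30, 12,
                  dimnames = list(paste0("g", 1:30), paste0("s", 1:12)))
    labels <- stats::setNames(rep(c("female", "male"), each = 6),
                              colnames(mat))
    de <- differential_expression(mat, labels)
    p <- de$p
    n <- length(p)
    o <- order(p)
    hand <- numeric(n)
    hand[o] <- rev(cummin(rev(p[o] * n / seq_len(n))))
    expect_equal(de$fdr, pmin(hand, 1), tolerance = 1e-12)
  })
})

test_that("a planted effect is recovered with controlled weight and FDR", {
  m <- build_toy_gem(toy_gem_config(n_subsystems = 6, seed = 13))
  hits <- 0; reps <- 30
  for (r in seq_len(reps)) {
    sim <- simulate_expression(m, expression_sim_config(
      planted_effects = c(subsystem_02 = 1.0), n_per_sex = 20,
      noise_sd = 0.25, seed = 1000 + r))
    de <- differential_expression(sim$matrix, sim$labels)
    gs <- sim$affected_genes$subsystem_02
    rowsok <- de$gene %in% gs & de$fdr < 0.1 &
      de$weight > 0.8 & de$weight < 1.2
    if (sum(rowsok) == length(gs)) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.9)
})

test_that("under the global null the discovery fraction stays controlled", {
  m <- build_toy_gem(toy_gem_config(n_subsystems = 4, seed = 14))
  fracs <- vapply(1:50, function(r) {
    sim <- simulate_expression(m, expression_sim_config(
      n_per_sex = 10, noise_sd = 0.5, seed = 2000 + r))
    de <- differential_expression(sim$matrix, sim$labels)
    mean(de$fdr < 0.1)
  }, numeric(1))
  mc_se <- stats::sd(fracs) / sqrt(length(fracs))
  expect_lte(mean(fracs), 0.1 + 3 * mc_se)
})

test_that("restriction to model genes keeps the intersection and errors on disjoint sets", {
  m <- chain_model()  # genes: g1
  de <- structure(data.frame(gene = c("g1", "gX"), log2fc = c(1, 2),
                             p = c(0.01, 0.01), fdr = c(0.05, 0.05),
                             weight = c(1, 2)),
                  fdr_threshold = 0.1, class = c("de_weights", "data.frame"))
  r <- restrict_to_model(de, m)
  expect_identical(r$gene, "g1")
  de2 <- de; de2$gene <- c("gX", "gY")
  expect_error(restrict_to_model(de2, m), class = "tidegem_config_error")
})
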