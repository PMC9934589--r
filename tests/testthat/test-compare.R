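# Minimal hand-built ensembles: presence and flux content fully known.
fake_model <- function(ids) list(reactions = data.frame(id = ids))
fake_member <- function(sample, sex, ids, flux = NULL, n = 10) {
  fs <- if (is.null(flux)) {
    matrix(1, n, length(ids), dimnames = list(NULL, ids))
  } else flux
  list(sample = sample, sex = sex, model = fake_model(ids),
       kept_fraction = 1, flux_samples = fs)
}
fake_ensemble <- function(members) {
  structure(list(models = stats::setNames(members,
                                          vapply(members, `[[`, "", "sample")),
                 sex = vapply(members, `[[`, "", "sex"),
                 excluded = data.frame(), provenance = list()),
            class = "context_ensemble")
}

test_that("presence proportions match hand counts on a known ensemble", {
  ens <- fake_ensemble(c(
    lapply(1:4, function(i) fake_member(paste0("m", i), "male",
      if (i <= 2) c("r_core", "r_m") else "r_core")),
    lapply(1:4, function(i) fake_member(paste0("f", i), "female",
      if (i == 1) c("r_core", "r_f") else "r_core"))))
  pt <- presence_table(ens)
  expect_equal(pt$male_prop[pt$reaction == "r_core"], 1)
  expect_equal(pt$female_prop[pt$reaction == "r_core"], 1)
  expect_equal(pt$male_prop[pt$reaction == "r_m"], 0.5)
  expect_equal(pt$female_prop[pt$reaction == "r_m"], 0)
  expect_equal(pt$female_prop[pt$reaction == "r_f"], 0.25)
  # reactions in no model are absent from the table
  expect_false("r_ghost" %in% pt$reaction)

  ens1 <- fake_ensemble(list(fake_member("m1", "male", "r_core")))
  expect_error(presence_table(ens1), class = "tidegem_config_error")
})

test_that("presence is invariant to model ordering within each sex", {
  mk <- function(ord) fake_ensemble(c(
    lapply(ord, function(i) fake_member(paste0("m", i), "male",
      c("r_core", paste0("r_", i)))),
    list(fake_member("f1", "female", "r_core"))))
  p1 <- presence_table(mk(1:3))
  p2 <- presence_table(mk(3:1))
  expect_equal(p1, p2, ignore_attr = TRUE)
})

test_that("unique-reaction calls follow the threshold and strict-zero rule", {
  pt <- data.frame(reaction = c("a", "b", "c", "d"),
                   male_prop = c(0.5, 0.05, 0.5, 0.0),
                   female_prop = c(0.0, 0.0, 0.01, 0.4))
  un <- unique_reactions(pt, threshold = 0.10)
  expect_identical(un$male_unique, "a")    # 0.5 vs 0 -> unique
  expect_false("b" %in% un$male_unique)    # below the 10% floor
  expect_identical(un$shared, "c")         # present in both -> shared
  expect_identical(un$female_unique, "d")
  expect_length(intersect(un$male_unique, un$female_unique), 0)
  expect_error(unique_reactions(pt, threshold = 0.1, other_max = 0.2),
               class = "tidegem_config_error")
})

test_that("subsystem tallies count unique reactions per label, sorted", {
  m <- build_toy_gem(toy_gem_config(n_subsystems = 3, seed = 71))
  ss1 <- m$reactions$id[m$reactions$subsystem == "subsystem_01"][1:3]
  ss2 <- m$reactions$id[m$reactions$subsystem == "subsystem_02"][1]
  un <- structure(list(male_unique = character(0),
                       female_unique = c(ss1, ss2), shared = character(0),
                       threshold = 0.1, other_max = 0),
                  class = "unique_sets")
  tl <- subsystem_tally(un, m)
  expect_equal(nrow(tl$male), 0)
  expect_identical(tl$female$subsystem[1], "subsystem_01")
  expect_equal(tl$female$n, c(3, 1))
})

test_that("the MWU statistic matches brute-force pair counting", {
  withr::with_seed(72, {
    for (r in 1:25) {
      nx <- sample(2:12, 1); ny <- sample(2:12, 1)
      x <- round(stats::rnorm(nx), if (r %% 2) 3 else 0)  # some with ties
      y <- round(stats::rnorm(ny), if (r %% 2) 3 else 0)
      mw <- tidegem:::mwu_test(x, y)
      expect_equal(mw$statistic, mwu_stat_oracle(x, y))
    }
  })
})

test_that("exact MWU p agrees with exhaustive relabeling on tiny samples", {
  withr::with_seed(73, {
    for (r in 1:8) {
      x <- stats::rnorm(4); y <- stats::rnorm(5)
      mw <- tidegem:::mwu_test(x, y)
      expect_true(mw$exact)
      expect_equal(mw$p.value, mwu_exact_oracle(x, y), tolerance = 1e-10)
    }
  })
})

test_that("disjoint flux supports give an extreme exchange-flux p", {
  ens <- fake_ensemble(list(
    fake_member("m1", "male", "EX_x",
                matrix(stats::runif(40, 5, 6), 40, 1,
                       dimnames = list(NULL, "EX_x"))),
    fake_member("f1", "female", "EX_x",
                matrix(stats::runif(40, 1, 2), 40, 1,
                       dimnames = list(NULL, "EX_x")))))
  t <- exchange_flux_test(ens, "EX_x")
  expect_lt(t$p, 1e-6)
  expect_identical(t$direction, "male")
  expect_gt(t$median_male, t$median_female)
})

test_that("models lacking the reaction contribute zeros, absence everywhere errors", {
  ens <- fake_ensemble(list(
    fake_member("m1", "male", "EX_x",
                matrix(2, 10, 1, dimnames = list(NULL, "EX_x"))),
    fake_member("f1", "female", "other",
                matrix(1, 10, 1, dimnames = list(NULL, "other")))))
  t <- exchange_flux_test(ens, "EX_x")
  expect_equal(t$n_female, 10)
  expect_equal(t$median_female, 0)
  expect_error(exchange_flux_test(ens, "EX_nowhere"),
               class = "tidegem_config_error")
})

test_that("quarterly rate test computes per-quarter proportions and a MWU p", {
  rep1 <- simulate_reports(report_sim_config(
    n_quarters = 30, reports_per_quarter_per_sex = 2000,
    liver_event_rate = c(female = 0.02, male = 0.01), seed = 74))
  rt <- quarterly_rate_test(rep1)
  expect_lt(rt$p, 0.001)
  expect_gt(rt$median_female, rt$median_male)
  expect_equal(rt$n_quarters, 30)
  expect_equal(rt$rates$proportion,
               rt$rates$events / rt$rates$total)

  # single-sex input errors
  expect_error(quarterly_rate_test(rep1[rep1$sex == "female", ]),
               class = "tidegem_config_error")
  # a quarter with zero totals for one sex is dropped with a warning
  rep2 <- rep1[!(rep1$sex == "male" & rep1$quarter == 3), ]
  expect_warning(rt2 <- quarterly_rate_test(rep2), "dropping")
  expect_equal(rt2$n_quarters, 29)
})

test_that("event labels can be matched against a liver-term list", {
  reports <- data.frame(
    quarter = rep(1:4, each = 4),
    sex = rep(c("female", "male"), 8),
    event = rep(c("hepatotoxicity", "rash", "none", "drug-induced liver injury"),
                4))
  rt <- quarterly_rate_test(reports,
    liver_terms = c("hepatotoxicity", "drug-induced liver injury"))
  expect_equal(unique(rt$rates$proportion), 0.5)
  expect_error(quarterly_rate_test(reports[, c("quarter", "sex")]),
               class = "tidegem_config_error")
})

test_that("drug report ratios exclude low-count drugs and rank by skew", {
  reports <- data.frame(
    drug = c(rep("big", 100), rep("small", 99)),
    sex = c(rep("female", 60), rep("male", 40), rep("female", 99)))
  dr <- drug_report_ratio(reports, min_reports = 100)
  expect_identical(dr$drug, "big")
  expect_equal(dr$female_fraction, 0.6)

  # simulated sex-skewed intensities are ranked correctly
  rep2 <- simulate_reports(report_sim_config(
    n_quarters = 10, reports_per_quarter_per_sex = 3000, seed = 75))
  dr2 <- drug_report_ratio(rep2, min_reports = 1000)
  # generator intensities: drug_a most female-skewed ... drug_d most male-skewed
  expect_identical(dr2$drug, c("drug_a", "drug_b", "drug_c", "drug_d"))
})
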