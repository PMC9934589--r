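# Synthetic inputs: toy genome-scale models, sex-labeled expression matrices
# with planted subsystem effects, and adverse-event report tables. These
# generators define the study conditions every downstream stage is tested
# under; all are pure functions of their seed.

#' Configuration for the toy GEM generator
#'
#' @param n_subsystems Number of metabolic subsystems (>= 2); default 12,
#'   giving a task set large enough for calibration studies.
#' @param reactions_per_subsystem Chain length per subsystem (>= 3).
#' @param frac_and_rules Fraction of internal reactions given an AND
#'   (enzyme-complex) GPR over 2-3 genes.
#' @param frac_or_rules Fraction given an OR (isozyme) GPR over 2-3 genes;
#'   `frac_and_rules + frac_or_rules` must be <= 1. Remaining reactions get a
#'   single-gene GPR.
#' @param include_bile_pair Add a conjugated/deconjugated bile-acid analog
#'   pair: a direct cholate-analog importer and a glycocholate-analog
#'   importer feeding a deconjugation reaction (two redundant entry routes
#'   into the same internal metabolite).
#' @param seed Integer seed.
#' @return A `toy_gem_config` list.
#' @export
toy_gem_config <- function(n_subsystems = 12, reactions_per_subsystem = 4,
                           frac_and_rules = 0.2, frac_or_rules = 0.2,
                           include_bile_pair = TRUE, seed = 1) {
  assert_scalar_num(n_subsystems, "n_subsystems", 2)
  assert_scalar_num(reactions_per_subsystem, "reactions_per_subsystem", 3)
  assert_scalar_num(frac_and_rules, "frac_and_rules", 0, 1)
  assert_scalar_num(frac_or_rules, "frac_or_rules", 0, 1)
  if (frac_and_rules + frac_or_rules > 1)
    abort_("frac_and_rules + frac_or_rules must be <= 1",
           class = "tidegem_config_error")
  structure(list(n_subsystems = as.integer(n_subsystems),
                 reactions_per_subsystem = as.integer(reactions_per_subsystem),
                 frac_and_rules = frac_and_rules, frac_or_rules = frac_or_rules,
                 include_bile_pair = isTRUE(include_bile_pair),
                 seed = seed), class = "toy_gem_config")
}

#' Build a toy genome-scale metabolic model
#'
#' Each subsystem is a linear pathway from its own importer to a shared
#' currency metabolite consumed by a biomass-like objective sink, so the
#' pathways are redundant routes to the objective and transcript-guided
#' pruning can retain different subsets per sample. Every subsystem also
#' carries one parallel (alternative) first step and one dead-end branch, so
#' parsimony pruning is never vacuous. With `include_bile_pair`, an internal
#' cholate-analog metabolite has two entry routes: direct import
#' (`EX_cholate_in`, the deconjugated form) and import of a
#' glycocholate-analog (`EX_glycocholate_in`) followed by a deconjugation
#' reaction.
#'
#' @param config A [toy_gem_config()].
#' @return A validated `metabolic_model` with a strictly positive FBA
#'   optimum.
#' @export
build_toy_gem <- function(config = toy_gem_config()) {
  stopifnot(inherits(config, "toy_gem_config"))
  ns <- config$n_subsystems; k <- config$reactions_per_subsystem

  mets <- data.frame(id = "energy_c", name = "currency metabolite",
                     compartment = "c", stringsAsFactors = FALSE)
  rxns <- list(); stoich <- list(); gpr_str <- character(0)

  add_rxn <- function(id, s, lb, ub, subsystem) {
    rxns[[length(rxns) + 1L]] <<- data.frame(
      id = id, lower_bound = lb, upper_bound = ub, subsystem = subsystem,
      stringsAsFactors = FALSE)
    stoich[[id]] <<- s
  }
  add_met <- function(id, name) {
    mets <<- rbind(mets, data.frame(id = id, name = name, compartment = "c",
                                    stringsAsFactors = FALSE))
  }

  for (i in seq_len(ns)) {
    lab <- sprintf("subsystem_%02d", i)
    mid <- function(j) sprintf("met%02d_%d", i, j)
    for (j in 0:(k - 1)) add_met(mid(j), sprintf("metabolite %d of %s", j, lab))
    add_met(sprintf("dead%02d", i), sprintf("dead end of %s", lab))
    add_rxn(sprintf("EX_ss%02d_in", i),
            stats::setNames(1, mid(0)), 0, 10, "Exchange/demand reactions")
    for (j in seq_len(k - 1))
      add_rxn(sprintf("rxn%02d_%d", i, j),
              stats::setNames(c(-1, 1), c(mid(j - 1), mid(j))), 0, 100, lab)
    add_rxn(sprintf("rxn%02d_%d", i, k),
            stats::setNames(c(-1, 1), c(mid(k - 1), "energy_c")), 0, 100, lab)
    # parallel alternative first step (redundant route; one is prunable)
    add_rxn(sprintf("rxn%02d_1b", i),
            stats::setNames(c(-1, 1), c(mid(0), mid(1))), 0, 100, lab)
    # dead-end branch: forced to zero flux at steady state
    add_rxn(sprintf("rxn%02d_dead", i),
            stats::setNames(c(-1, 1), c(mid(1), sprintf("dead%02d", i))),
            0, 100, lab)
  }

  if (config$include_bile_pair) {
    add_met("cholate_c", "cholate analog (deconjugated bile acid)")
    add_met("glycocholate_c", "glycocholate analog (conjugated bile salt)")
    add_rxn("EX_cholate_in", c(cholate_c = 1), 0, 10,
            "Exchange/demand reactions")
    add_rxn("EX_glycocholate_in", c(glycocholate_c = 1), 0, 10,
            "Exchange/demand reactions")
    add_rxn("deconj_glycocholate",
            c(glycocholate_c = -1, cholate_c = 1), 0, 100, "bile_recycling")
    add_rxn("cholate_use", c(cholate_c = -1, energy_c = 1), 0, 100,
            "bile_recycling")
  }

  # with the bile pair, the objective also consumes the cholate analog, so
  # every context model must use one of the two entry routes (mirroring an
  # obligatory enterohepatic input)
  if (config$include_bile_pair) {
    add_rxn("biomass", c(energy_c = -1, cholate_c = -0.1), 0, 1000, "Biomass")
  } else {
    add_rxn("biomass", c(energy_c = -1), 0, 1000, "Biomass")
  }
  rxns <- do.call(rbind, rxns)

  # GPRs: one gene per internal reaction except configured fractions of
  # AND/OR rules over 2-3 genes; exchanges and the objective carry none
  gpr <- with_seed_(config$seed, {
    out <- stats::setNames(vector("list", nrow(rxns)), rxns$id)
    for (rid in rxns$id) {
      if (startsWith(rid, "EX_") || rid == "biomass") {
        out[[rid]] <- gpr_empty(); next
      }
      u <- stats::runif(1)
      if (u < config$frac_and_rules) {
        ng <- sample(2:3, 1)
        out[[rid]] <- gpr_node("and", lapply(paste0("g_", rid, "_", seq_len(ng)),
                                             gpr_gene))
      } else if (u < config$frac_and_rules + config$frac_or_rules) {
        ng <- sample(2:3, 1)
        out[[rid]] <- gpr_node("or", lapply(paste0("g_", rid, "_", seq_len(ng)),
                                            gpr_gene))
      } else {
        out[[rid]] <- gpr_gene(paste0("g_", rid))
      }
    }
    out
  })

  model <- metabolic_model(sprintf("toy_gem_s%d", config$seed), mets, rxns,
                           stoich, gpr, "biomass")
  z <- solve_fba(model)$objective_value
  if (z <= 0)
    abort_("generated model has non-positive objective optimum",
           class = "tidegem_generation_error")
  model
}

#' Configuration for the expression simulator
#'
#' @param planted_effects Named numeric vector of log2 fold changes (male
#'   minus female) per subsystem label; empty means global null.
#' @param n_per_sex Samples per sex (>= 3); default 20.
#' @param noise_sd Per-sample Gaussian noise SD on the log2 scale; default
#'   0.25 (microarray-like replicate noise).
#' @param baseline_log2_mean Mean of the per-gene baseline distribution
#'   (log2 intensity scale); default 6.
#' @param frac_affected Fraction of a planted subsystem's genes that carry
#'   the effect; default 0.8 so recovery works from partial signal.
#' @param marker_gene_gap log2 separation between the male and female modes
#'   of the appended male-marker gene; default 6 (clean bimodality).
#' @param marker_gene Name of the appended marker gene.
#' @param seed Integer seed.
#' @return An `expression_sim_config` list.
#' @export
expression_sim_config <- function(planted_effects = numeric(0), n_per_sex = 20,
                                  noise_sd = 0.25, baseline_log2_mean = 6,
                                  frac_affected = 0.8, marker_gene_gap = 6,
                                  marker_gene = "SRY_marker", seed = 1) {
  assert_scalar_num(n_per_sex, "n_per_sex", 3)
  assert_scalar_num(noise_sd, "noise_sd", 1e-12)
  assert_scalar_num(frac_affected, "frac_affected", 0, 1)
  assert_scalar_num(marker_gene_gap, "marker_gene_gap", 0)
  if (length(planted_effects) && is.null(names(planted_effects)))
    abort_("planted_effects must be named by subsystem label",
           class = "tidegem_config_error")
  structure(list(planted_effects = planted_effects,
                 n_per_sex = as.integer(n_per_sex), noise_sd = noise_sd,
                 baseline_log2_mean = baseline_log2_mean,
                 frac_affected = frac_affected,
                 marker_gene_gap = marker_gene_gap, marker_gene = marker_gene,
                 seed = seed), class = "expression_sim_config")
}

# Genes attached (via GPR leaves) to each subsystem of a model.
subsystem_genes <- function(model) {
  subs <- unique(model$reactions$subsystem[nzchar(model$reactions$subsystem)])
  stats::setNames(lapply(subs, function(ss) {
    rids <- model$reactions$id[model$reactions$subsystem == ss]
    sort(unique(unlist(lapply(model$gpr[rids], gpr_genes))))
  }), subs)
}

#' Simulate a sex-labeled log2 expression matrix for a model
#'
#' Per gene, a baseline is drawn once from Normal(`baseline_log2_mean`, 1);
#' male samples of genes in a planted subsystem are shifted by the planted
#' log2 effect (applied to `frac_affected` of the subsystem's genes); every
#' cell receives Normal(0, `noise_sd`) noise. A male-marker gene is appended
#' whose male mode exceeds its female mode by `marker_gene_gap`.
#'
#' @param model A `metabolic_model`; genes are the model's GPR leaves.
#' @param config An [expression_sim_config()].
#' @return List with `matrix` (gene x sample, log2 scale), `labels` (named
#'   character vector, sample -> `"male"`/`"female"`), and `affected_genes`
#'   (list per planted subsystem).
#' @export
simulate_expression <- function(model, config = expression_sim_config()) {
  stopifnot(inherits(model, "metabolic_model"),
            inherits(config, "expression_sim_config"))
  sg <- subsystem_genes(model)
  missing_ss <- setdiff(names(config$planted_effects), names(sg))
  if (length(missing_ss))
    abort_("planted subsystem '%s' not in model", missing_ss[1],
           class = "tidegem_config_error")

  genes <- model_genes(model)
  n <- config$n_per_sex
  samples <- c(sprintf("female_%02d", seq_len(n)),
               sprintf("male_%02d", seq_len(n)))
  sex <- stats::setNames(rep(c("female", "male"), each = n), samples)

  with_seed_(config$seed, {
    baseline <- stats::rnorm(length(genes), config$baseline_log2_mean, 1)
    mat <- matrix(baseline, length(genes), 2 * n,
                  dimnames = list(genes, samples))
    affected <- list()
    for (ss in names(config$planted_effects)) {
      gs <- sg[[ss]]
      n_aff <- ceiling(config$frac_affected * length(gs))
      gs_aff <- sample(gs)[seq_len(n_aff)]
      affected[[ss]] <- sort(gs_aff)
      mat[gs_aff, sex == "male"] <-
        mat[gs_aff, sex == "male"] + config$planted_effects[[ss]]
    }
    mat <- mat + matrix(stats::rnorm(length(mat), 0, config$noise_sd),
                        nrow(mat), ncol(mat))
    marker <- config$baseline_log2_mean +
      ifelse(sex == "male", config$marker_gene_gap, 0) +
      stats::rnorm(2 * n, 0, config$noise_sd)
    mat <- rbind(mat, matrix(marker, 1, 2 * n,
                             dimnames = list(config$marker_gene, samples)))
    list(matrix = mat, labels = sex, affected_genes = affected)
  })
}

#' Configuration for the adverse-event report simulator
#'
#' Defaults emulate a pharmacovigilance extract: 68 quarters, 10000 reports
#' per quarter per sex, and a liver-related event rate of 2% in females vs
#' 1% in males.
#'
#' @param n_quarters Number of quarters.
#' @param reports_per_quarter_per_sex Reports per quarter per sex.
#' @param liver_event_rate Named probabilities `c(female = , male = )`.
#' @param drugs `data.frame` with columns `name`, `female_intensity`,
#'   `male_intensity`: relative report intensity per drug per sex.
#' @param seed Integer seed.
#' @return A `report_sim_config` list.
#' @export
report_sim_config <- function(n_quarters = 68,
                              reports_per_quarter_per_sex = 10000,
                              liver_event_rate = c(female = 0.02, male = 0.01),
                              drugs = NULL, seed = 1) {
  assert_scalar_num(n_quarters, "n_quarters", 2)
  assert_scalar_num(reports_per_quarter_per_sex,
                    "reports_per_quarter_per_sex", 1)
  if (!all(c("female", "male") %in% names(liver_event_rate)) ||
      any(liver_event_rate < 0) || any(liver_event_rate > 1))
    abort_("liver_event_rate must be named probabilities for female and male",
           class = "tidegem_config_error")
  drugs <- drugs %||% data.frame(
    name = c("drug_a", "drug_b", "drug_c", "drug_d"),
    female_intensity = c(0.40, 0.30, 0.20, 0.10),
    male_intensity = c(0.10, 0.20, 0.30, 0.40),
    stringsAsFactors = FALSE)
  structure(list(n_quarters = as.integer(n_quarters),
                 reports_per_quarter_per_sex =
                   as.integer(reports_per_quarter_per_sex),
                 liver_event_rate = liver_event_rate, drugs = drugs,
                 seed = seed), class = "report_sim_config")
}

#' Simulate an adverse-event report table
#'
#' Per quarter and sex, exactly `reports_per_quarter_per_sex` reports are
#' generated; each report's drug is drawn with probability proportional to
#' the drug's sex-specific intensity, and its liver-event flag is Bernoulli
#' at the sex's rate.
#'
#' @param config A [report_sim_config()].
#' @return `data.frame` with columns `quarter` (integer), `sex`, `drug`,
#'   `liver_event` (logical).
#' @export
simulate_reports <- function(config = report_sim_config()) {
  stopifnot(inherits(config, "report_sim_config"))
  nq <- config$n_quarters; rq <- config$reports_per_quarter_per_sex
  with_seed_(config$seed, {
    out <- lapply(c("female", "male"), function(sx) {
      n <- nq * rq
      data.frame(
        quarter = rep(seq_len(nq), each = rq),
        sex = sx,
        drug = sample(config$drugs$name, n, replace = TRUE,
                      prob = config$drugs[[paste0(sx, "_intensity")]]),
        liver_event = stats::rbinom(n, 1, config$liver_event_rate[[sx]]) == 1L,
        stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
}
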