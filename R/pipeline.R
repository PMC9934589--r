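# Orchestration: flat key=value configuration, deterministic stage seeding,
# and an end-to-end run over synthetic inputs:
# simulate -> differential expression -> TIDEs -> contextualize -> compare.

pipeline_defaults <- function() list(
  # toy model
  n_subsystems = 12L, reactions_per_subsystem = 4L,
  frac_and_rules = 0.2, frac_or_rules = 0.2, include_bile_pair = TRUE,
  # expression simulation
  planted_effects = "", n_per_sex = 20L, noise_sd = 0.25,
  baseline_log2_mean = 6, frac_affected = 0.8, marker_gene_gap = 6,
  # sex imputation + differential expression
  impute_sex = TRUE, marker_quantile = 0.16, fdr_threshold = 0.1,
  # TIDEs
  n_perm = 1000L, alpha_per_tail = 0.025,
  # context extraction
  min_fraction = "0.4", n_flux_samples = 110L, thin = 100L, zero_tol = 1e-6,
  # comparisons
  presence_threshold = 0.10,
  # reports
  n_quarters = 68L, reports_per_quarter_per_sex = 10000L,
  liver_event_rate_female = 0.02, liver_event_rate_male = 0.01,
  min_reports = 100000L,
  # global
  seed = 1L, steady_state_tol = 1e-6
)

#' Assemble a pipeline configuration
#'
#' Unknown keys are errors. `min_fraction` may be a comma-separated list to
#' sweep the objective fraction (one ensemble per value);
#' `planted_effects` is a comma-separated `label=log2fc` list.
#'
#' @param ... Overrides of the documented defaults (see
#'   [run_all()]).
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- pipeline_defaults()
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    abort_("unknown configuration key '%s'", unknown[1],
           class = "tidegem_config_error")
  for (k in names(over)) {
    tmpl <- cfg[[k]]
    v <- over[[k]]
    cfg[[k]] <- if (is.logical(tmpl)) {
      if (is.character(v)) toupper(v) %in% c("TRUE", "T", "1", "YES") else
        isTRUE(v)
    } else if (is.integer(tmpl)) as.integer(v)
      else if (is.numeric(tmpl)) as.numeric(v)
      else as.character(v)
  }
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration file
#'
#' Flat `key = value` text; `#` starts a comment; unknown keys are errors.
#'
#' @param path Config file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) < 2
  if (any(bad))
    abort_("malformed config line: '%s'", lines[bad][1],
           class = "tidegem_config_error")
  keys <- trimws(vapply(kv, `[`, character(1), 1L))
  vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = "="),
                        character(1)))
  do.call(pipeline_config, stats::setNames(as.list(vals), keys))
}

parse_planted_effects <- function(spec) {
  if (!nzchar(trimws(spec))) return(numeric(0))
  parts <- strsplit(trimws(strsplit(spec, ",", fixed = TRUE)[[1]]), "=",
                    fixed = TRUE)
  stats::setNames(vapply(parts, function(p) as.numeric(p[2]), numeric(1)),
                  vapply(parts, `[`, character(1), 1L))
}

#' Run the full synthetic pipeline
#'
#' Stages run in dependency order; each stage draws its seed
#' deterministically from the master seed and the stage name, so a rerun
#' with an identical configuration reproduces every output. Outputs are
#' tab-delimited files (plus the model in the JSON dialect) under `out_dir`,
#' and a `log.txt` recording the configuration and stage seeds.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory stage results and the
#'   output paths.
#' @export
run_all <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(out_dir, "log.txt")
  log_lines <- c(sprintf("tidegem pipeline run %s", format(Sys.time())),
                 "configuration:",
                 vapply(names(config), function(k)
                   sprintf("  %s = %s", k, paste(config[[k]], collapse = ",")),
                   character(1)))
  stage_seed <- function(name) derive_seed(config$seed, name)
  note <- function(fmt, ...) log_lines <<- c(log_lines, sprintf(fmt, ...))
  fail <- function(stage, e)
    abort_("stage '%s' failed: %s", stage, conditionMessage(e),
           class = "tidegem_pipeline_error")

  # --- simulate -------------------------------------------------------------
  res <- list()
  tryCatch({
    model <- build_toy_gem(toy_gem_config(
      n_subsystems = config$n_subsystems,
      reactions_per_subsystem = config$reactions_per_subsystem,
      frac_and_rules = config$frac_and_rules,
      frac_or_rules = config$frac_or_rules,
      include_bile_pair = config$include_bile_pair,
      seed = stage_seed("gem")))
    write_model(model, file.path(out_dir, "model.json"))
    sim <- simulate_expression(model, expression_sim_config(
      planted_effects = parse_planted_effects(config$planted_effects),
      n_per_sex = config$n_per_sex, noise_sd = config$noise_sd,
      baseline_log2_mean = config$baseline_log2_mean,
      frac_affected = config$frac_affected,
      marker_gene_gap = config$marker_gene_gap,
      seed = stage_seed("expression")))
    expr_df <- data.frame(gene = rownames(sim$matrix), sim$matrix,
                          check.names = FALSE)
    write_tsv_(expr_df, file.path(out_dir, "expression.tsv"))
    write_tsv_(data.frame(sample = names(sim$labels), sex = unname(sim$labels)),
               file.path(out_dir, "labels.tsv"))
    res$model <- model; res$sim <- sim
    note("simulate: %d genes x %d samples (seed %d)", nrow(sim$matrix),
         ncol(sim$matrix), stage_seed("expression"))
  }, error = function(e) fail("simulate", e))

  # --- differential expression ---------------------------------------------
  tryCatch({
    labels <- if (config$impute_sex) {
      lab <- impute_sex(res$sim$matrix, "SRY_marker", config$marker_quantile)
      lab[lab != "unassigned"]
    } else res$sim$labels
    de <- differential_expression(res$sim$matrix, labels,
                                  config$fdr_threshold)
    dew <- restrict_to_model(de, res$model)
    write_tsv_(data.frame(gene = dew$gene, weight = dew$weight,
                          fdr = dew$fdr), file.path(out_dir, "weights.tsv"))
    res$labels <- labels; res$weights <- dew
    note("diffexpr: %d labeled samples, %d model genes, %d significant",
         length(labels), nrow(dew), sum(dew$weight != 0))
  }, error = function(e) fail("diffexpr", e))

  # --- tides ----------------------------------------------------------------
  tryCatch({
    tides <- tides_run(res$model, res$weights, n_perm = config$n_perm,
                       seed = stage_seed("tides"),
                       alpha_per_tail = config$alpha_per_tail)
    write_tides(tides, file.path(out_dir, "tides.tsv"))
    res$tides <- tides
    note("tides: %d tasks scored, %d significant (n_perm %d, alpha/tail %g)",
         nrow(tides), sum(tides$significant), config$n_perm,
         config$alpha_per_tail)
  }, error = function(e) fail("tides", e))

  # --- contextualize + compare (per min_fraction value) ---------------------
  fracs <- as.numeric(strsplit(as.character(config$min_fraction), ",")[[1]])
  res$ensembles <- list()
  for (mf in fracs) {
    tag <- sprintf("mf%s", sub("^0\\.", "", format(mf)))
    tryCatch({
      ens <- build_ensemble(res$model, res$sim$matrix, res$labels,
                            min_fraction = mf,
                            n_flux_samples = config$n_flux_samples,
                            seed = stage_seed(paste0("ensemble_", mf)),
                            thin = config$thin)
      write_ensemble_manifest(ens, file.path(out_dir,
                                             paste0("manifest_", tag, ".tsv")))
      pt <- presence_table(ens)
      write_tsv_(pt, file.path(out_dir, paste0("presence_", tag, ".tsv")))
      un <- unique_reactions(pt, config$presence_threshold)
      tl <- subsystem_tally(un, res$model)
      write_tsv_(data.frame(
        set = rep(c("male_unique", "female_unique", "shared"),
                  c(length(un$male_unique), length(un$female_unique),
                    length(un$shared))),
        reaction = c(un$male_unique, un$female_unique, un$shared)),
        file.path(out_dir, paste0("unique_", tag, ".tsv")))
      write_tsv_(rbind(
        data.frame(sex = rep("male", nrow(tl$male)), tl$male),
        data.frame(sex = rep("female", nrow(tl$female)), tl$female)),
        file.path(out_dir, paste0("tally_", tag, ".tsv")))
      ex <- list()
      for (rid in c("EX_cholate_in", "EX_glycocholate_in")) {
        if (rid %in% res$model$reactions$id) {
          t <- tryCatch(exchange_flux_test(ens, rid), error = function(e) NULL)
          if (!is.null(t)) ex[[rid]] <- t
        }
      }
      if (length(ex)) {
        write_tsv_(do.call(rbind, lapply(ex, function(t) data.frame(
          reaction = t$reaction, median_male = t$median_male,
          median_female = t$median_female, p = t$p, direction = t$direction))),
          file.path(out_dir, paste0("exchange_", tag, ".tsv")))
      }
      res$ensembles[[as.character(mf)]] <-
        list(ensemble = ens, presence = pt, unique = un, tally = tl,
             exchange = ex)
      note("contextualize[%g]: %d retained (%d female / %d male), %d excluded",
           mf, length(ens$models), sum(ens$sex == "female"),
           sum(ens$sex == "male"), nrow(ens$excluded))
    }, error = function(e) fail(sprintf("contextualize[%g]", mf), e))
  }

  # --- reports --------------------------------------------------------------
  tryCatch({
    reports <- simulate_reports(report_sim_config(
      n_quarters = config$n_quarters,
      reports_per_quarter_per_sex = config$reports_per_quarter_per_sex,
      liver_event_rate = c(female = config$liver_event_rate_female,
                           male = config$liver_event_rate_male),
      seed = stage_seed("reports")))
    rt <- quarterly_rate_test(reports)
    dr <- drug_report_ratio(reports, config$min_reports)
    write_tsv_(rt$rates, file.path(out_dir, "rate_series.tsv"))
    write_tsv_(data.frame(p = rt$p, median_female = rt$median_female,
                          median_male = rt$median_male),
               file.path(out_dir, "rate_test.tsv"))
    write_tsv_(dr, file.path(out_dir, "drug_ratios.tsv"))
    res$rate_test <- rt; res$drug_ratios <- dr
    note("reports: %d quarters, MWU p = %.3g", rt$n_quarters, rt$p)
  }, error = function(e) fail("reports", e))

  writeLines(log_lines, logf)
  res$out_dir <- out_dir
  invisible(res)
}
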