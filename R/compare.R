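# Between-group statistics: reaction presence and uniqueness across the
# sexes, subsystem tallies of unique reactions, exchange-flux distribution
# tests, and adverse-event report rate/ratio analyses.

# Mann-Whitney U wrapper: exact p when both sides have <= exact_max values
# and no ties, normal approximation with tie-corrected variance otherwise.
mwu_test <- function(x, y, exact_max = 20) {
  use_exact <- length(x) <= exact_max && length(y) <= exact_max &&
    !any(duplicated(c(x, y)))
  ht <- stats::wilcox.test(x, y, exact = use_exact, correct = FALSE)
  list(statistic = unname(ht$statistic), p.value = ht$p.value,
       exact = use_exact)
}

#' Reaction presence proportions per sex
#'
#' For every reaction kept in at least one retained context model, the
#' proportion of each sex's models that contain it (denominator = retained
#' models of that sex).
#'
#' @param ensemble A `context_ensemble` with at least one retained model per
#'   sex.
#' @return `data.frame` with columns `reaction`, `male_prop`, `female_prop`,
#'   and attributes `n_male`, `n_female`.
#' @export
presence_table <- function(ensemble) {
  stopifnot(inherits(ensemble, "context_ensemble"))
  sexes <- ensemble$sex
  n_m <- sum(sexes == "male"); n_f <- sum(sexes == "female")
  if (n_m == 0 || n_f == 0)
    abort_("need at least one retained model per sex (male %d, female %d)",
           n_m, n_f, class = "tidegem_config_error")
  sets <- lapply(ensemble$models, function(m) m$model$reactions$id)
  all_rxn <- sort(unique(unlist(sets)))
  count <- function(sx) {
    tab <- table(unlist(sets[sexes == sx]))
    out <- stats::setNames(rep(0, length(all_rxn)), all_rxn)
    out[names(tab)] <- as.numeric(tab)
    out
  }
  out <- data.frame(reaction = all_rxn,
                    male_prop = unname(count("male") / n_m),
                    female_prop = unname(count("female") / n_f),
                    stringsAsFactors = FALSE)
  structure(out, n_male = n_m, n_female = n_f)
}

#' Sex-unique and shared reactions at a prevalence threshold
#'
#' A reaction is male-unique when it appears in at least `threshold` of the
#' male models and in none of the female models (strict-zero reading;
#' `other_max` relaxes the zero to a small proportion). Shared reactions
#' appear with positive proportion in both sexes.
#'
#' @param table A presence table from [presence_table()].
#' @param threshold Own-sex prevalence floor; default 0.10.
#' @param other_max Maximum allowed proportion in the other sex; default 0
#'   (strictly absent). Must be below `threshold`.
#' @return A `unique_sets` list: `male_unique`, `female_unique`, `shared`
#'   (character vectors), plus the parameters.
#' @export
unique_reactions <- function(table, threshold = 0.10, other_max = 0) {
  assert_scalar_num(threshold, "threshold", 0, 1)
  assert_scalar_num(other_max, "other_max", 0, 1)
  if (other_max >= threshold)
    abort_("other_max must be below threshold", class = "tidegem_config_error")
  structure(list(
    male_unique = table$reaction[table$male_prop >= threshold &
                                 table$female_prop <= other_max],
    female_unique = table$reaction[table$female_prop >= threshold &
                                   table$male_prop <= other_max],
    shared = table$reaction[table$male_prop > 0 & table$female_prop > 0],
    threshold = threshold, other_max = other_max), class = "unique_sets")
}

#' Tally unique reactions by subsystem
#'
#' @param unique A `unique_sets` from [unique_reactions()].
#' @param model The source `metabolic_model` providing subsystem labels.
#' @return List with `male` and `female` data.frames (`subsystem`, `n`),
#'   sorted by descending count.
#' @export
subsystem_tally <- function(unique, model) {
  stopifnot(inherits(unique, "unique_sets"), inherits(model, "metabolic_model"))
  sub_of <- stats::setNames(model$reactions$subsystem, model$reactions$id)
  tally <- function(ids) {
    if (length(ids) == 0L)
      return(data.frame(subsystem = character(0), n = integer(0)))
    tab <- sort(table(sub_of[ids]), decreasing = TRUE)
    data.frame(subsystem = names(tab), n = as.integer(tab),
               stringsAsFactors = FALSE)
  }
  list(male = tally(unique$male_unique), female = tally(unique$female_unique))
}

#' Compare an exchange reaction's flux distribution between sexes
#'
#' Pools all flux samples per sex for the reaction across the ensemble's
#' retained models and compares them with a two-sided Mann-Whitney U test.
#' Models from which the reaction was pruned contribute zero flux
#' (`absent_as_zero = TRUE`, the default), since absence is informative for
#' import-capacity comparisons.
#'
#' @param ensemble A `context_ensemble`.
#' @param reaction_id Reaction id (typically an exchange reaction).
#' @param absent_as_zero Whether pruned-away models contribute zeros.
#' @return List with `reaction`, `median_male`, `median_female`, `p`,
#'   `n_male`, `n_female`, `direction` (sex with the higher median).
#' @export
exchange_flux_test <- function(ensemble, reaction_id, absent_as_zero = TRUE) {
  stopifnot(inherits(ensemble, "context_ensemble"))
  pull <- function(sx) {
    vals <- lapply(ensemble$models[ensemble$sex == sx], function(m) {
      fs <- m$flux_samples
      if (reaction_id %in% colnames(fs)) fs[, reaction_id]
      else if (absent_as_zero) rep(0, nrow(fs)) else NULL
    })
    unlist(vals, use.names = FALSE)
  }
  present <- any(vapply(ensemble$models, function(m)
    reaction_id %in% colnames(m$flux_samples), logical(1)))
  if (!present)
    abort_("reaction '%s' is absent from every model in the ensemble",
           reaction_id, class = "tidegem_config_error")
  vm <- pull("male"); vf <- pull("female")
  mw <- mwu_test(vm, vf)
  list(reaction = reaction_id,
       median_male = stats::median(vm), median_female = stats::median(vf),
       p = mw$p.value, n_male = length(vm), n_female = length(vf),
       direction = if (stats::median(vm) >= stats::median(vf)) "male" else
         "female")
}

#' Quarterly liver-event rate comparison between sexes
#'
#' Computes, per quarter and sex, the proportion of reports flagged as
#' liver-related, and compares the female and male quarterly proportion
#' vectors with a two-sided Mann-Whitney U test. Quarters with zero total
#' reports for either sex are dropped with a warning.
#'
#' @param reports Report table with columns `quarter`, `sex`, and either a
#'   logical `liver_event` column or an `event` column matched against
#'   `liver_terms`.
#' @param liver_terms Character vector of event labels counting as
#'   liver-related (required when `reports` has no `liver_event` column).
#' @return List with `rates` (data.frame quarter/sex/events/total/proportion),
#'   `p`, `median_female`, `median_male`, `n_quarters`.
#' @export
quarterly_rate_test <- function(reports, liver_terms = NULL) {
  if (!all(c("quarter", "sex") %in% names(reports)))
    abort_("reports need 'quarter' and 'sex' columns",
           class = "tidegem_config_error")
  flag <- if ("liver_event" %in% names(reports)) {
    as.logical(reports$liver_event)
  } else if ("event" %in% names(reports) && !is.null(liver_terms)) {
    reports$event %in% liver_terms
  } else {
    abort_("reports need a 'liver_event' column or an 'event' column plus liver_terms",
           class = "tidegem_config_error")
  }
  sexes <- sort(unique(reports$sex))
  if (!all(c("female", "male") %in% sexes))
    abort_("reports must contain both sexes", class = "tidegem_config_error")
  if (length(unique(reports$quarter)) < 2)
    abort_("need at least 2 quarters", class = "tidegem_config_error")

  total <- table(reports$quarter, reports$sex)
  events <- table(reports$quarter[flag], factor(reports$sex[flag],
                                                levels = colnames(total)))
  qs <- rownames(total)
  ev <- matrix(0, length(qs), ncol(total), dimnames = dimnames(total))
  ev[rownames(events), colnames(events)] <- events
  keep <- total[, "female"] > 0 & total[, "male"] > 0
  if (!all(keep)) {
    warning(sprintf("dropping %d quarter(s) with zero reports for a sex",
                    sum(!keep)))
  }
  qs <- qs[keep]
  prop_f <- ev[qs, "female"] / total[qs, "female"]
  prop_m <- ev[qs, "male"] / total[qs, "male"]
  if (length(qs) < 2)
    abort_("fewer than 2 usable quarters", class = "tidegem_config_error")
  rates <- rbind(
    data.frame(quarter = qs, sex = "female", events = as.integer(ev[qs, "female"]),
               total = as.integer(total[qs, "female"]), proportion = unname(prop_f)),
    data.frame(quarter = qs, sex = "male", events = as.integer(ev[qs, "male"]),
               total = as.integer(total[qs, "male"]), proportion = unname(prop_m)))
  mw <- mwu_test(prop_f, prop_m)
  list(rates = rates, p = mw$p.value,
       median_female = stats::median(prop_f),
       median_male = stats::median(prop_m), n_quarters = length(qs))
}

#' Per-drug female report fraction
#'
#' Drugs with fewer than `min_reports` total reports are excluded so the
#' sex ratio is not driven by small counts.
#'
#' @param reports Report table with columns `drug` and `sex`.
#' @param min_reports Minimum total reports per drug; default 100000.
#' @return `data.frame` with `drug`, `n_total`, `n_female`,
#'   `female_fraction`, sorted by descending fraction.
#' @export
drug_report_ratio <- function(reports, min_reports = 100000) {
  if (!all(c("drug", "sex") %in% names(reports)))
    abort_("reports need 'drug' and 'sex' columns",
           class = "tidegem_config_error")
  tot <- table(reports$drug)
  fem <- table(reports$drug[reports$sex == "female"])
  drugs <- names(tot)[tot >= min_reports]
  nf <- stats::setNames(rep(0, length(drugs)), drugs)
  nf[intersect(drugs, names(fem))] <- as.numeric(fem[intersect(drugs, names(fem))])
  out <- data.frame(drug = drugs, n_total = as.integer(tot[drugs]),
                    n_female = as.integer(nf),
                    female_fraction = as.numeric(nf / tot[drugs]),
                    stringsAsFactors = FALSE)
  out[order(-out$female_fraction), , drop = FALSE]
}
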