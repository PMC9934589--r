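# Metabolic task scoring from differential expression (TIDEs).
#
# Reactions inherit weights from their genes through the GPR (max over OR,
# min over AND). A task's score is the mean weight of its reactions; its
# significance comes from comparison with permuted task scores built from
# weights of reactions outside the task. Each tail is tested at
# alpha_per_tail (default 0.025, i.e. two-sided 0.05) with the add-one
# permutation p estimator, so p is never zero.

#' Tasks of a model
#'
#' The default task set is the partition of reactions by subsystem label
#' (reactions with an empty label are not in any task). A task file can
#' override: one task per line, `label<TAB>comma-separated reaction ids`.
#'
#' @param model A `metabolic_model`.
#' @param task_file Optional path to a task definition file.
#' @return Named list, task label -> character vector of reaction ids.
#' @export
model_tasks <- function(model, task_file = NULL) {
  stopifnot(inherits(model, "metabolic_model"))
  if (is.null(task_file)) {
    subs <- model$reactions$subsystem
    labs <- unique(subs[nzchar(subs)])
    return(stats::setNames(
      lapply(labs, function(l) model$reactions$id[subs == l]), labs))
  }
  lines <- readLines(task_file)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  labs <- vapply(parts, `[`, character(1), 1L)
  tasks <- stats::setNames(lapply(parts, function(p)
    trimws(strsplit(p[2L], ",", fixed = TRUE)[[1L]])), labs)
  bad <- setdiff(unlist(tasks), model$reactions$id)
  if (length(bad))
    abort_("task file references unknown reaction '%s'", bad[1],
           class = "tidegem_validation_error")
  tasks
}

#' GPR-propagated reaction weights
#'
#' Each reaction with a non-empty GPR receives
#' `evaluate_gpr(rule, weights, missing = "skip")`: the highest fold
#' difference across isozymes (OR) and the lowest across complex members
#' (AND). Reactions with an empty GPR, or whose genes are all absent from
#' the weight vector, are excluded from the map rather than scored zero, so
#' task scores average only evidence-bearing reactions.
#'
#' @param model A `metabolic_model`.
#' @param weights A `de_weights` object or named numeric vector of per-gene
#'   weights.
#' @return Named numeric vector, reaction id -> weight, covering only
#'   weightable reactions.
#' @export
assign_reaction_weights <- function(model, weights) {
  stopifnot(inherits(model, "metabolic_model"))
  w <- de_weight_vector(weights)
  out <- vapply(model$reactions$id, function(rid)
    evaluate_gpr(model$gpr[[rid]], w, missing = "skip"), numeric(1))
  out[!is.na(out)]
}

#' Score of one task
#'
#' Arithmetic mean of the task's reactions that carry a weight.
#'
#' @param reaction_weights Named numeric vector from
#'   [assign_reaction_weights()].
#' @param task Character vector of reaction ids.
#' @return Mean weight, or `NA_real_` (with a warning) when no task reaction
#'   carries a weight.
#' @export
task_score <- function(reaction_weights, task) {
  present <- intersect(task, names(reaction_weights))
  if (length(present) == 0L) {
    warning("no reaction in the task carries a weight; task skipped")
    return(NA_real_)
  }
  mean(reaction_weights[present])
}

#' Permutation null for a task score
#'
#' Each null score is the mean of `task_size` weights drawn uniformly
#' without replacement from the pool of weights outside the task.
#'
#' @param task_size Number of scored reactions in the task.
#' @param pool Numeric vector of out-of-task reaction weights; must have at
#'   least `task_size` elements.
#' @param n_perm Number of permutations; default 1000.
#' @param seed Optional seed.
#' @return Numeric vector of `n_perm` null scores.
#' @export
permutation_null <- function(task_size, pool, n_perm = 1000, seed = NULL) {
  if (length(pool) < task_size)
    abort_("pool (%d) smaller than task size (%d)", length(pool), task_size,
           class = "tidegem_config_error")
  np <- length(pool)
  with_seed_(seed,
    vapply(seq_len(n_perm), function(i)
      mean(pool[sample.int(np, task_size)]), numeric(1)))
}

#' Two-sided permutation test of a task score
#'
#' Uses the add-one empirical estimator per tail:
#' `p_upper = (1 + #\{null >= score\}) / (1 + n_perm)` and the analogous
#' lower tail; the reported two-sided p is twice the smaller tail, capped at
#' 1. The task is significant when the smaller tail is below
#' `alpha_per_tail`, and its direction is male-biased when the score lies
#' above the null median, female-biased below.
#'
#' @param score Observed task score.
#' @param null_scores Non-empty numeric vector of permuted scores.
#' @param alpha_per_tail Per-tail significance level; default 0.025.
#' @return List with `p_two_sided`, `p_upper`, `p_lower`, `significant`,
#'   `direction` (`"male_biased"`, `"female_biased"`, `"none"`).
#' @export
tide_test <- function(score, null_scores, alpha_per_tail = 0.025) {
  stopifnot(length(null_scores) > 0)
  n <- length(null_scores)
  p_up <- (1 + sum(null_scores >= score)) / (1 + n)
  p_lo <- (1 + sum(null_scores <= score)) / (1 + n)
  sig <- min(p_up, p_lo) < alpha_per_tail
  dir <- if (!sig) "none" else if (score > stats::median(null_scores))
    "male_biased" else "female_biased"
  list(p_two_sided = min(1, 2 * min(p_up, p_lo)), p_upper = p_up,
       p_lower = p_lo, significant = sig, direction = dir)
}

#' Run TIDEs over all tasks of a model
#'
#' @param model A `metabolic_model`.
#' @param weights A `de_weights` object or named per-gene weight vector
#'   (already restricted to model genes).
#' @param n_perm Permutations per task; default 1000.
#' @param seed Master seed; each task consumes an independent stream derived
#'   from the seed and the task label, so results do not depend on task or
#'   reaction ordering.
#' @param alpha_per_tail Per-tail significance level; default 0.025.
#' @param tasks Optional task list from [model_tasks()]; defaults to the
#'   model's subsystem partition.
#' @return A `tides_result` data.frame with one row per scorable task:
#'   `task`, `n_reactions_scored`, `score`, `p_two_sided`, `direction`,
#'   `significant`. Tasks with no weighted reaction are skipped (recorded in
#'   attribute `skipped_tasks`).
#' @export
tides_run <- function(model, weights, n_perm = 1000, seed = NULL,
                      alpha_per_tail = 0.025, tasks = NULL) {
  stopifnot(inherits(model, "metabolic_model"))
  rw <- assign_reaction_weights(model, weights)
  tasks <- tasks %||% model_tasks(model)
  rows <- list(); skipped <- character(0)
  for (lab in names(tasks)) {
    present <- sort(intersect(tasks[[lab]], names(rw)))
    if (length(present) == 0L) { skipped <- c(skipped, lab); next }
    score <- mean(rw[present])
    pool_ids <- sort(setdiff(names(rw), tasks[[lab]]))
    if (length(pool_ids) < length(present)) { skipped <- c(skipped, lab); next }
    nulls <- permutation_null(length(present), unname(rw[pool_ids]), n_perm,
                              seed = derive_seed(seed, lab))
    tt <- tide_test(score, nulls, alpha_per_tail)
    rows[[lab]] <- data.frame(task = lab, n_reactions_scored = length(present),
                              score = score, p_two_sided = tt$p_two_sided,
                              direction = tt$direction,
                              significant = tt$significant,
                              stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(task = character(0), n_reactions_scored = integer(0),
               score = numeric(0), p_two_sided = numeric(0),
               direction = character(0), significant = logical(0))
  rownames(out) <- NULL
  if (length(skipped))
    message(sprintf("skipped %d task(s) with no weighted reaction: %s",
                    length(skipped), paste(skipped, collapse = ", ")))
  structure(out, n_perm = n_perm, alpha_per_tail = alpha_per_tail,
            skipped_tasks = skipped, class = c("tides_result", "data.frame"))
}

#' Task-score matrix over multiple contrasts
#'
#' Runs TIDEs once per contrast (e.g., one drug-vs-control weight vector per
#' row) under a shared master seed, so identical weight vectors give
#' identical rows.
#'
#' @param model A `metabolic_model`.
#' @param contrasts Named list of `de_weights` objects or per-gene weight
#'   vectors.
#' @param n_perm,seed,alpha_per_tail As in [tides_run()].
#' @return A `task_score_matrix`: list of three contrast x task matrices
#'   `score` (raw), `masked` (score where significant, 0 otherwise), and
#'   `significant` (logical).
#' @export
task_score_matrix <- function(model, contrasts, n_perm = 1000, seed = NULL,
                              alpha_per_tail = 0.025) {
  stopifnot(length(contrasts) >= 1, !is.null(names(contrasts)))
  runs <- lapply(contrasts, function(w)
    tides_run(model, w, n_perm = n_perm, seed = seed,
              alpha_per_tail = alpha_per_tail))
  labs <- sort(unique(unlist(lapply(runs, function(r) r$task))))
  mk <- function(fill) matrix(fill, length(contrasts), length(labs),
                              dimnames = list(names(contrasts), labs))
  score <- mk(NA_real_); masked <- mk(0); sig <- mk(FALSE)
  for (cn in names(contrasts)) {
    r <- runs[[cn]]
    score[cn, r$task] <- r$score
    masked[cn, r$task] <- ifelse(r$significant, r$score, 0)
    sig[cn, r$task] <- r$significant
  }
  structure(list(score = score, masked = masked, significant = sig),
            class = "task_score_matrix")
}

#' Write a TIDEs result table to a tab-delimited file
#' @param result A `tides_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tides <- function(result, path) {
  write_tsv_(as.data.frame(result), path)
}
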