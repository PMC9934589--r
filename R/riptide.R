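# Transcript-guided context-specific model extraction and flux sampling.
#
# Pipeline per sample: map gene abundances to rank-linear reaction weights
# in [0, 1] (0 = highest abundance), minimize the weighted flux sum while
# holding a fraction of the FBA optimum, prune zero-flux reactions, fix the
# retained reactions to the directions they carried in the parsimonious
# solution, maximize the inversely weighted flux sum, and sample the
# resulting fraction-constrained flux polytope by hit-and-run.

#' Map gene abundances to reaction weights in [0, 1]
#'
#' Per-reaction abundance is `evaluate_gpr` over linear-scale abundances
#' (max across isozymes, min across complex subunits, absent genes skipped).
#' Reactions are then ranked and mapped affinely so the highest-abundance
#' reaction gets weight 0 and the lowest gets 1; ties share the mean of
#' their ranks' weights. Reactions with no abundance (empty GPR or all genes
#' missing) receive the median weight of the ranked reactions.
#'
#' @param model A `metabolic_model`.
#' @param abundance Named numeric vector of linear-scale gene expression.
#' @return Named numeric vector over all model reactions, values in [0, 1].
#' @export
abundance_to_weights <- function(model, abundance) {
  stopifnot(inherits(model, "metabolic_model"))
  a <- vapply(model$reactions$id, function(rid)
    evaluate_gpr(model$gpr[[rid]], abundance, missing = "skip"), numeric(1))
  ranked <- !is.na(a)
  if (!any(ranked))
    abort_("no reaction obtains an abundance from the given expression",
           class = "tidegem_config_error")
  n <- sum(ranked)
  w <- stats::setNames(rep(NA_real_, length(a)), names(a))
  w[ranked] <- if (n == 1) 0.5 else
    (rank(-a[ranked], ties.method = "average") - 1) / (n - 1)
  w[!ranked] <- stats::median(w[ranked])
  w
}

#' Prune a model to its transcript-supported parsimonious core
#'
#' Minimizes the weighted flux sum subject to the objective holding at least
#' `min_fraction` of the FBA optimum `Z*`, removes reactions with
#' `|v| <= zero_tol` (never the objective reaction) and orphaned
#' metabolites, and refits the pruned model to report the achieved fraction.
#'
#' @param model A `metabolic_model` with a positive FBA optimum.
#' @param weights Named reaction weights in [0, 1] from
#'   [abundance_to_weights()].
#' @param min_fraction Required objective fraction; default 0.40.
#' @param zero_tol Flux magnitude below which a reaction counts as inactive;
#'   default 1e-6 (above LP noise at the 1e-9 solver tolerance).
#' @return A `pruned_context`: list with `model` (pruned), `kept_fraction`
#'   (pruned optimum / Z*), `parsimony_flux` (over kept reactions), `zstar`,
#'   and `passes_filter` (kept_fraction >= min_fraction).
#' @export
prune_model <- function(model, weights, min_fraction = 0.40, zero_tol = 1e-6) {
  assert_scalar_num(min_fraction, "min_fraction", 0, 1)
  zstar <- solve_fba(model, "max")$objective_value
  if (zstar <= 0)
    abort_("model optimum is not positive; nothing to contextualize",
           class = "tidegem_infeasible_error")
  v <- minimize_weighted_l1(model, weights, objective_fraction = min_fraction,
                            zstar = zstar)
  keep <- union(names(v)[abs(v) > zero_tol], model$objective_id)
  pruned <- remove_reactions(model, setdiff(model$reactions$id, keep))
  zp <- solve_fba(pruned, "max")$objective_value
  kf <- zp / zstar
  structure(list(model = pruned, kept_fraction = kf,
                 parsimony_flux = v[pruned$reactions$id], zstar = zstar,
                 min_fraction = min_fraction, zero_tol = zero_tol,
                 passes_filter = kf >= min_fraction - 1e-9),
            class = "pruned_context")
}

# Hit-and-run sampler over {S v = 0, lb <= v <= ub, v[obj] >= obj_min}.
# Directions are drawn in the null space of S; each step moves uniformly
# within the feasible segment. Records every `thin`-th point.
hit_and_run <- function(x0, nullsp, lb, ub, obj_idx, obj_min, n_samples,
                        thin = 100, seed = NULL) {
  n <- length(x0)
  if (ncol(nullsp) == 0L) {
    out <- matrix(rep(x0, n_samples), n_samples, n, byrow = TRUE)
    colnames(out) <- names(x0)
    return(out)
  }
  with_seed_(seed, {
    total <- n_samples * thin
    D <- nullsp %*% matrix(stats::rnorm(ncol(nullsp) * total),
                           ncol(nullsp), total)
    D <- sweep(D, 2, pmax(sqrt(colSums(D^2)), 1e-12), "/")
    U <- stats::runif(total)
    x <- pmin(pmax(x0, lb), ub)
    out <- matrix(NA_real_, n_samples, n)
    tol <- 1e-10
    for (i in seq_len(total)) {
      d <- D[, i]
      act <- abs(d) > tol
      if (any(act)) {
        rl <- (lb[act] - x[act]) / d[act]
        ru <- (ub[act] - x[act]) / d[act]
        tmin <- max(pmin(rl, ru))
        tmax <- min(pmax(rl, ru))
        if (abs(d[obj_idx]) > tol) {
          tc <- (obj_min - x[obj_idx]) / d[obj_idx]
          if (d[obj_idx] > 0) tmin <- max(tmin, tc) else tmax <- min(tmax, tc)
        }
        if (tmax > tmin) x <- x + (tmin + U[i] * (tmax - tmin)) * d
      }
      if (i %% thin == 0L) out[i %/% thin, ] <- x
    }
    colnames(out) <- names(x0)
    out
  })
}

#' Flux-sample a pruned context model
#'
#' Reaction directions are first fixed to the signs of the parsimonious
#' solution (recomputed on the pruned model). Weights are inverted
#' (`w' = 1 - w`, so 1 marks the highest-abundance reaction) and the
#' `w'`-weighted flux sum is maximized on the direction-restricted model to
#' anchor the transcript-favored flux state. The polytope
#' `{S v = 0, directed bounds, v_obj >= min_fraction * Z_pruned}` is then
#' sampled `n_flux_samples` times by a seeded hit-and-run walk (thinning
#' `thin`), started from the centroid of the parsimonious, FBA-optimal and
#' weight-maximal vertices.
#'
#' @param pruned A `pruned_context` from [prune_model()], or a
#'   `metabolic_model`.
#' @param weights Named reaction weights in [0, 1] (entries for reactions
#'   absent from the pruned model are ignored; pruned reactions missing from
#'   `weights` default to 0.5).
#' @param min_fraction Objective fraction held during sampling; default 0.40.
#' @param n_flux_samples Number of recorded flux vectors; default 110.
#' @param seed Optional seed.
#' @param thin Walk steps between recorded samples; default 100.
#' @param zero_tol Direction-fixing tolerance on the parsimonious flux.
#' @return Matrix `n_flux_samples` x kept reactions of feasible flux
#'   vectors.
#' @export
sample_context <- function(pruned, weights, min_fraction = 0.40,
                           n_flux_samples = 110, seed = NULL, thin = 100,
                           zero_tol = 1e-6) {
  model <- if (inherits(pruned, "pruned_context")) pruned$model else pruned
  stopifnot(inherits(model, "metabolic_model"))
  assert_scalar_num(n_flux_samples, "n_flux_samples", 1)
  rid <- model$reactions$id
  w <- stats::setNames(rep(0.5, length(rid)), rid)
  w[intersect(names(weights), rid)] <- weights[intersect(names(weights), rid)]

  vp <- minimize_weighted_l1(model, w, objective_fraction = min_fraction)
  lb <- model$reactions$lower_bound; ub <- model$reactions$upper_bound
  lb <- ifelse(vp > zero_tol, pmax(lb, 0), lb)
  ub <- ifelse(vp < -zero_tol, pmin(ub, 0), ub)

  S <- stoich_matrix(model)
  iobj <- match(model$objective_id, rid)
  zp <- solve_fba(model, "max")$objective_value
  obj_min <- min_fraction * zp

  e_obj <- as.numeric(seq_along(rid) == iobj)
  fba_dir <- lp_solve(e_obj, A_eq = S, b_eq = rep(0, nrow(S)),
                      lb = lb, ub = ub, sense = "max")
  winv <- 1 - w
  wmax <- lp_solve(winv, A_eq = S, b_eq = rep(0, nrow(S)),
                   A_ge = matrix(e_obj, 1), b_ge = obj_min,
                   lb = lb, ub = ub, sense = "max")
  if (fba_dir$status != "optimal" || wmax$status != "optimal")
    abort_("could not anchor the sampling polytope (solver status %s/%s)",
           fba_dir$status, wmax$status, class = "tidegem_solver_error")
  x0 <- (as.numeric(vp) + fba_dir$x + wmax$x) / 3
  names(x0) <- rid

  sv <- svd(S, nu = 0, nv = ncol(S))
  r <- sum(sv$d > max(dim(S)) * max(sv$d, 1e-12) * 1e-12)
  nullsp <- if (r < ncol(S)) sv$v[, seq(r + 1, ncol(S)), drop = FALSE] else
    matrix(0, ncol(S), 0)

  hit_and_run(x0, nullsp, lb, ub, iobj, obj_min, n_flux_samples, thin, seed)
}

#' Build a per-sample ensemble of context-specific models
#'
#' For every labeled sample: convert its log2 expression to linear
#' abundances, derive reaction weights, prune, filter on the achieved
#' objective fraction, and flux-sample. Samples that error or fail the
#' fraction filter are excluded (with the reason recorded) without aborting
#' the ensemble.
#'
#' @param model A `metabolic_model`.
#' @param expression Gene x sample matrix on the log2 scale.
#' @param labels Named character vector, sample -> `"male"`/`"female"`
#'   (other labels are skipped).
#' @param min_fraction Objective fraction for pruning and the retention
#'   filter; default 0.40.
#' @param n_flux_samples Flux samples per retained model; default 110.
#' @param seed Master seed; per-sample streams are derived from it.
#' @param thin Hit-and-run thinning; default 100.
#' @return A `context_ensemble`: list with `models` (per retained sample:
#'   `sample`, `sex`, `model`, `kept_fraction`, `flux_samples`), `sex`,
#'   `excluded` (data.frame sample/sex/reason), `provenance`.
#' @export
build_ensemble <- function(model, expression, labels, min_fraction = 0.40,
                           n_flux_samples = 110, seed = NULL, thin = 100) {
  stopifnot(inherits(model, "metabolic_model"))
  labels <- labels[names(labels) %in% colnames(expression)]
  labels <- labels[labels %in% c("male", "female")]
  if (length(labels) == 0L)
    abort_("no male/female labeled samples", class = "tidegem_config_error")
  models <- list()
  excluded <- list()
  for (s in names(labels)) {
    res <- tryCatch({
      abund <- 2^expression[, s]
      names(abund) <- rownames(expression)
      wts <- abundance_to_weights(model, abund)
      pr <- prune_model(model, wts, min_fraction)
      if (!pr$passes_filter)
        abort_("kept fraction %.3f below min_fraction %.2f", pr$kept_fraction,
               min_fraction, class = "tidegem_fraction_filter_error")
      fs <- sample_context(pr, wts, min_fraction, n_flux_samples,
                           seed = derive_seed(seed, s), thin = thin)
      list(sample = s, sex = unname(labels[[s]]), model = pr$model,
           kept_fraction = pr$kept_fraction, flux_samples = fs)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      excluded[[s]] <- data.frame(sample = s, sex = unname(labels[[s]]),
                                  reason = conditionMessage(res),
                                  stringsAsFactors = FALSE)
    } else {
      models[[s]] <- res
    }
  }
  structure(list(
    models = models,
    sex = vapply(models, `[[`, character(1), "sex"),
    excluded = if (length(excluded)) do.call(rbind, excluded) else
      data.frame(sample = character(0), sex = character(0),
                 reason = character(0)),
    provenance = list(seed = seed, min_fraction = min_fraction,
                      n_flux_samples = n_flux_samples, thin = thin)
  ), class = "context_ensemble")
}

#' Merge context ensembles
#'
#' Combines the retained models and exclusion records of several ensembles,
#' e.g. per-sex ensembles built from sex-specific source models. Sample ids
#' must be disjoint.
#'
#' @param ... `context_ensemble` objects.
#' @return A `context_ensemble`.
#' @export
merge_ensembles <- function(...) {
  parts <- list(...)
  stopifnot(all(vapply(parts, inherits, logical(1), "context_ensemble")))
  models <- do.call(c, lapply(parts, `[[`, "models"))
  if (anyDuplicated(names(models)))
    abort_("duplicate sample id across ensembles",
           class = "tidegem_validation_error")
  structure(list(
    models = models,
    sex = vapply(models, `[[`, character(1), "sex"),
    excluded = do.call(rbind, lapply(parts, `[[`, "excluded")),
    provenance = parts[[1]]$provenance
  ), class = "context_ensemble")
}

#' @export
print.context_ensemble <- function(x, ...) {
  cat(sprintf("<context_ensemble: %d models (%d female / %d male), %d excluded>\n",
              length(x$models), sum(x$sex == "female"), sum(x$sex == "male"),
              nrow(x$excluded)))
  invisible(x)
}

#' Write the ensemble manifest to a tab-delimited file
#' @param ensemble A `context_ensemble`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ensemble_manifest <- function(ensemble, path) {
  rows <- lapply(ensemble$models, function(m) data.frame(
    sample = m$sample, sex = m$sex, kept_fraction = m$kept_fraction,
    n_reactions = nrow(m$model$reactions), excluded = FALSE,
    stringsAsFactors = FALSE))
  ex <- ensemble$excluded
  if (nrow(ex)) {
    rows <- c(rows, list(data.frame(sample = ex$sample, sex = ex$sex,
                                    kept_fraction = NA_real_,
                                    n_reactions = NA_integer_, excluded = TRUE,
                                    stringsAsFactors = FALSE)))
  }
  write_tsv_(do.call(rbind, rows), path)
}
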