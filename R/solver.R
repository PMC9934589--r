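# Linear-programming backend and the constraint-based analyses built on it.
#
# All flux computations go through one internal solver contract
# (lp_solve): build the LP, set the sense, solve, query the primal. The
# backend is a dense two-phase primal simplex with Dantzig pricing and a
# Bland anti-cycling fallback. Toy genome-scale models stay well below a few
# hundred variables, where a dense tableau is fast and numerically
# transparent; the contract keeps the backend swappable.

# Two-phase simplex on  min c'x  s.t.  A x (dir) b, x >= 0.
# dir is a character vector in {"<=", ">=", "="}. Returns status in
# {"optimal", "infeasible", "unbounded", "maxit"}.
simplex_standard <- function(cc, A, b, dir, maxit = 50000L, tol = 1e-9) {
  m <- nrow(A); n0 <- ncol(A)
  stopifnot(length(b) == m, length(dir) == m, length(cc) == n0)

  flip <- b < 0
  if (any(flip)) {
    A[flip, ] <- -A[flip, , drop = FALSE]
    b[flip] <- -b[flip]
    dir[flip] <- c("<=" = ">=", ">=" = "<=", "=" = "=")[dir[flip]]
  }

  n_sl <- sum(dir == "<=")
  n_su <- sum(dir == ">=")
  n_ar <- sum(dir != "<=")
  ntot <- n0 + n_sl + n_su + n_ar

  Tb <- matrix(0, m, ntot + 1L)
  Tb[, seq_len(n0)] <- A
  Tb[, ntot + 1L] <- b
  basis <- integer(m)
  is_art <- rep(FALSE, ntot)
  j_sl <- n0; j_su <- n0 + n_sl; j_ar <- n0 + n_sl + n_su
  for (i in seq_len(m)) {
    if (dir[i] == "<=") {
      j_sl <- j_sl + 1L; Tb[i, j_sl] <- 1; basis[i] <- j_sl
    } else if (dir[i] == ">=") {
      j_su <- j_su + 1L; Tb[i, j_su] <- -1
      j_ar <- j_ar + 1L; Tb[i, j_ar] <- 1; basis[i] <- j_ar; is_art[j_ar] <- TRUE
    } else {
      j_ar <- j_ar + 1L; Tb[i, j_ar] <- 1; basis[i] <- j_ar; is_art[j_ar] <- TRUE
    }
  }

  c2 <- c(cc, rep(0, ntot - n0))
  # reduced-cost rows (length ntot + 1; last entry = -objective value)
  r2 <- c(c2, 0)
  art_rows <- which(is_art[basis])
  r1 <- c(rep(0, ntot), 0)
  if (length(art_rows)) {
    r1 <- -colSums(Tb[art_rows, , drop = FALSE])
    r1[is_art] <- 0
  }
  basic2 <- which(c2[basis] != 0)
  for (i in basic2) r2 <- r2 - c2[basis[i]] * Tb[i, ]

  pivot <- function(p, q) {
    prow <- Tb[p, ] / Tb[p, q]
    col <- Tb[, q]; col[p] <- 0
    Tb <<- Tb - outer(col, prow)
    Tb[p, ] <<- prow
    r1 <<- r1 - r1[q] * prow
    r2 <<- r2 - r2[q] * prow
    basis[p] <<- q
  }

  run_phase <- function(rrow_get, allowed, maxit, bland_after) {
    it <- 0L
    repeat {
      it <- it + 1L
      if (it > maxit) return("maxit")
      r <- rrow_get()
      cand <- allowed & r[seq_len(ntot)] < -tol
      if (!any(cand)) return("optimal")
      q <- if (it > bland_after) which(cand)[1L] else {
        w <- which(cand); w[which.min(r[w])]
      }
      colq <- Tb[, q]
      rows <- which(colq > tol)
      if (!length(rows)) return("unbounded")
      ratio <- Tb[rows, ntot + 1L] / colq[rows]
      rmin <- min(ratio)
      ties <- rows[ratio <= rmin + 1e-12]
      p <- if (length(ties) > 1L) ties[which.min(basis[ties])] else ties
      pivot(p, q)
    }
  }

  bland_after <- 5L * (m + ntot)
  if (length(art_rows)) {
    st <- run_phase(function() r1, !is_art, maxit, bland_after)
    if (st == "maxit") return(list(status = "maxit"))
    phase1_obj <- sum(Tb[is_art[basis], ntot + 1L])
    if (phase1_obj > 1e-7) return(list(status = "infeasible"))
    # drive remaining artificial basics (at zero) out where possible
    for (i in which(is_art[basis])) {
      j <- which(!is_art[seq_len(ntot)] & abs(Tb[i, seq_len(ntot)]) > tol)[1L]
      if (!is.na(j)) pivot(i, j)
    }
  }
  st <- run_phase(function() r2, !is_art, maxit, bland_after)
  if (st != "optimal") return(list(status = st))

  x <- rep(0, ntot)
  x[basis] <- Tb[, ntot + 1L]
  list(status = "optimal", x = x[seq_len(n0)],
       value = sum(cc * x[seq_len(n0)]))
}

#' Solve a bounded linear program
#'
#' Internal solver contract used by all flux computations: optimize
#' `obj' x` over `{A_eq x = b_eq, A_ge x >= b_ge, lb <= x <= ub}`. All
#' bounds must be finite.
#'
#' @param obj Objective coefficient vector.
#' @param A_eq,b_eq Equality constraints (may be `NULL`).
#' @param A_ge,b_ge Greater-or-equal constraints (may be `NULL`).
#' @param lb,ub Finite variable bounds.
#' @param sense `"max"` or `"min"`.
#' @param tol Pivot tolerance.
#' @return List with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`,
#'   `"maxit"`), and for optimal solves `x` and `value`.
#' @keywords internal
#' @export
lp_solve <- function(obj, A_eq = NULL, b_eq = NULL, A_ge = NULL, b_ge = NULL,
                     lb, ub, sense = c("max", "min"), tol = 1e-9) {
  sense <- match.arg(sense)
  n <- length(obj)
  stopifnot(length(lb) == n, length(ub) == n)
  if (any(!is.finite(lb)) || any(!is.finite(ub)))
    abort_("lp_solve requires finite variable bounds",
           class = "tidegem_solver_error")
  if (any(lb > ub))
    return(list(status = "infeasible"))

  # shift y = x - lb >= 0; upper bounds become rows y_i <= ub_i - lb_i
  rows <- list(); rhs <- numeric(0); dir <- character(0)
  if (!is.null(A_eq) && nrow(A_eq) > 0) {
    rows[[length(rows) + 1L]] <- A_eq
    rhs <- c(rhs, b_eq - as.vector(A_eq %*% lb))
    dir <- c(dir, rep("=", nrow(A_eq)))
  }
  if (!is.null(A_ge) && nrow(A_ge) > 0) {
    rows[[length(rows) + 1L]] <- A_ge
    rhs <- c(rhs, b_ge - as.vector(A_ge %*% lb))
    dir <- c(dir, rep(">=", nrow(A_ge)))
  }
  span <- ub - lb
  ubrows <- which(span < Inf)  # all, given finiteness check
  Ub <- matrix(0, length(ubrows), n)
  Ub[cbind(seq_along(ubrows), ubrows)] <- 1
  rows[[length(rows) + 1L]] <- Ub
  rhs <- c(rhs, span[ubrows])
  dir <- c(dir, rep("<=", length(ubrows)))
  A <- do.call(rbind, rows)

  cc <- if (sense == "max") -obj else obj
  sol <- simplex_standard(cc, A, rhs, dir, tol = tol)
  if (sol$status != "optimal") return(sol)
  x <- sol$x + lb
  list(status = "optimal", x = x, value = sum(obj * x))
}

#' Flux balance analysis
#'
#' Maximizes (or minimizes) the flux through the model's objective reaction
#' subject to steady state (`S v = 0`) and flux bounds.
#'
#' @param model A `metabolic_model`.
#' @param sense `"max"` (default) or `"min"`.
#' @param steady_state_tol Post-hoc steady-state assertion tolerance.
#' @return An `fba_solution`: list with `objective_value`, `flux` (named
#'   vector over reactions), `status`, `sense`.
#' @export
solve_fba <- function(model, sense = c("max", "min"), steady_state_tol = 1e-6) {
  sense <- match.arg(sense)
  validate_model(model)
  S <- stoich_matrix(model)
  n <- ncol(S)
  obj <- as.numeric(colnames(S) == model$objective_id)
  sol <- lp_solve(obj, A_eq = S, b_eq = rep(0, nrow(S)),
                  lb = model$reactions$lower_bound,
                  ub = model$reactions$upper_bound, sense = sense)
  if (sol$status == "infeasible")
    abort_("model '%s' is infeasible", model$id,
           class = "tidegem_infeasible_error")
  if (sol$status == "unbounded")
    abort_("objective of model '%s' is unbounded", model$id,
           class = "tidegem_unbounded_error")
  if (sol$status != "optimal")
    abort_("solver failed with status '%s'", sol$status,
           class = "tidegem_solver_error")
  flux <- stats::setNames(sol$x, colnames(S))
  chk <- check_steady_state(model, flux, steady_state_tol)
  if (chk$max_residual > steady_state_tol)
    abort_("steady-state residual %.2e exceeds tolerance", chk$max_residual,
           class = "tidegem_solver_error")
  structure(list(objective_value = sol$value, flux = flux, status = "optimal",
                 sense = sense), class = "fba_solution")
}

#' Weighted flux-sum (L1) minimization
#'
#' Minimizes `sum_r w_r |v_r|` subject to steady state, flux bounds, and an
#' objective-holding constraint `v_obj >= objective_fraction * Z*`, where
#' `Z*` is the unconstrained FBA maximum. Absolute values are realized by
#' splitting each reaction into nonnegative forward and reverse components
#' that share the reaction's weight.
#'
#' @param model A `metabolic_model`.
#' @param weights Named nonnegative numeric vector of per-reaction weights;
#'   reactions not named default to weight 1.
#' @param objective_fraction Number in `[0, 1]`; fraction of the FBA optimum
#'   the solution must retain.
#' @param zstar Optional precomputed FBA maximum (skips the internal solve).
#' @return Named flux vector over all reactions, with attributes
#'   `objective_flux`, `weighted_flux_sum` and `zstar`.
#' @export
minimize_weighted_l1 <- function(model, weights = NULL, objective_fraction = 0,
                                 zstar = NULL) {
  validate_model(model)
  assert_scalar_num(objective_fraction, "objective_fraction", 0, 1)
  rid <- model$reactions$id
  w <- stats::setNames(rep(1, length(rid)), rid)
  if (!is.null(weights)) {
    if (any(weights < 0)) abort_("weights must be nonnegative",
                                 class = "tidegem_config_error")
    w[names(weights)[names(weights) %in% rid]] <-
      weights[names(weights) %in% rid]
  }
  if (is.null(zstar)) zstar <- solve_fba(model, "max")$objective_value

  S <- stoich_matrix(model)
  n <- ncol(S)
  lbv <- model$reactions$lower_bound; ubv <- model$reactions$upper_bound
  # v = f - r with f, r >= 0; box bounds chosen so f - r spans [lb, ub]
  lf <- pmax(lbv, 0); uf <- pmax(ubv, 0)
  lr <- pmax(-ubv, 0); ur <- pmax(-lbv, 0)
  A_eq <- cbind(S, -S)
  iobj <- which(rid == model$objective_id)
  A_ge <- matrix(0, 1, 2 * n)
  A_ge[1, iobj] <- 1; A_ge[1, n + iobj] <- -1
  b_ge <- objective_fraction * zstar
  sol <- lp_solve(c(w, w), A_eq = A_eq, b_eq = rep(0, nrow(S)),
                  A_ge = A_ge, b_ge = b_ge,
                  lb = c(lf, lr), ub = c(uf, ur), sense = "min")
  if (sol$status == "infeasible")
    abort_(paste0("flux-sum minimization infeasible under the ",
                  "objective-fraction constraint (fraction %.3f of Z* = %.6g)"),
           objective_fraction, zstar, class = "tidegem_infeasible_error")
  if (sol$status != "optimal")
    abort_("solver failed with status '%s'", sol$status,
           class = "tidegem_solver_error")
  v <- stats::setNames(sol$x[seq_len(n)] - sol$x[n + seq_len(n)], rid)
  structure(v, objective_flux = unname(v[model$objective_id]),
            weighted_flux_sum = sum(w * abs(v)), zstar = zstar)
}
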