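# Independent brute-force oracles used to validate the implementation paths.

# GPR oracle: bottom-up evaluation with Reduce over pmin/pmax, written
# independently of evaluate_gpr's recursion.
gpr_oracle <- function(rule, values, missing = "skip") {
  ev <- function(nd) {
    if (nd$kind == "empty") return(NA_real_)
    if (nd$kind == "gene") {
      if (nd$gene %in% names(values)) return(values[[nd$gene]])
      if (missing == "zero") return(0)
      if (missing == "error") stop("missing gene")
      return(NA_real_)
    }
    xs <- unlist(lapply(nd$children, ev))
    xs <- xs[!is.na(xs)]
    if (!length(xs)) return(NA_real_)
    Reduce(if (nd$kind == "and") min else max, xs)
  }
  ev(rule)
}

# Enumerate all AND/OR tree shapes over an ordered set of leaves (set
# partitions into >= 2 blocks, alternating operators handled by labeling
# every internal node both ways). Depth-limited.
all_gpr_trees <- function(leaves, depth = 3) {
  if (length(leaves) == 1L) return(list(gpr_gene(leaves)))
  if (depth == 0L) return(list())
  out <- list()
  # all ways to split the ordered leaves into >= 2 consecutive blocks
  n <- length(leaves)
  splits <- function(n) {
    # compositions of n into >= 2 parts
    res <- list()
    rec <- function(rem, acc) {
      if (rem == 0 && length(acc) >= 2) {
        res[[length(res) + 1L]] <<- acc
        return()
      }
      for (k in seq_len(rem)) rec(rem - k, c(acc, k))
    }
    rec(n, integer(0))
    res
  }
  for (comp in splits(n)) {
    ends <- cumsum(comp); starts <- c(1, head(ends, -1) + 1)
    blocks <- Map(function(s, e) leaves[s:e], starts, ends)
    kid_sets <- lapply(blocks, all_gpr_trees, depth = depth - 1)
    if (any(lengths(kid_sets) == 0)) next
    idx <- expand.grid(lapply(kid_sets, seq_along))
    for (r in seq_len(nrow(idx))) {
      kids <- Map(function(ks, i) ks[[i]], kid_sets, as.integer(idx[r, ]))
      for (op in c("and", "or")) {
        nd <- gpr_node(op, kids)
        # gpr_node flattens; only keep trees where the root is the op we set
        if (nd$kind %in% c("and", "or", "gene"))
          out[[length(out) + 1L]] <- nd
      }
    }
  }
  out
}

# LP oracle: enumerate basic solutions of {A v = b, lb <= v <= ub} by
# choosing rank(A) basic columns and fixing the others at a bound; the
# optimum of a bounded feasible LP is attained at one of these vertices.
lp_vertex_oracle <- function(obj, A, b, lb, ub, tol = 1e-8) {
  n <- ncol(A)
  qrA <- qr(A)
  r <- qrA$rank
  best <- -Inf
  for (B in utils::combn(n, r, simplify = FALSE)) {
    AB <- A[, B, drop = FALSE]
    if (qr(AB)$rank < r) next
    N <- setdiff(seq_len(n), B)
    grid <- expand.grid(rep(list(c(FALSE, TRUE)), length(N)))
    for (g in seq_len(nrow(grid))) {
      vN <- ifelse(unlist(grid[g, ]), ub[N], lb[N])
      rhs <- b - if (length(N)) A[, N, drop = FALSE] %*% vN else 0
      vB <- tryCatch(qr.solve(AB, rhs, tol = 1e-10),
                     error = function(e) NULL)
      if (is.null(vB)) next
      v <- numeric(n); v[B] <- vB; v[N] <- vN
      if (max(abs(A %*% v - b)) > tol) next
      if (any(v < lb - tol) || any(v > ub + tol)) next
      best <- max(best, sum(obj * v))
    }
  }
  best
}

# FBA oracle for a metabolic model via vertex enumeration.
fba_oracle <- function(model) {
  S <- stoich_matrix(model)
  obj <- as.numeric(colnames(S) == model$objective_id)
  lp_vertex_oracle(obj, S, rep(0, nrow(S)),
                   model$reactions$lower_bound, model$reactions$upper_bound)
}

# Weighted-L1 oracle with a different variable encoding: x = (v, t) with
# t_i >= |v_i| enforced by two inequality rows per reaction.
l1_oracle <- function(model, weights, objective_fraction) {
  S <- stoich_matrix(model)
  n <- ncol(S)
  rid <- colnames(S)
  w <- stats::setNames(rep(1, n), rid)
  w[names(weights)[names(weights) %in% rid]] <-
    weights[names(weights) %in% rid]
  zstar <- solve_fba(model, "max")$objective_value
  lbv <- model$reactions$lower_bound; ubv <- model$reactions$upper_bound
  tmax <- pmax(abs(lbv), abs(ubv))
  iobj <- match(model$objective_id, rid)
  A_eq <- cbind(S, matrix(0, nrow(S), n))
  A_ge <- rbind(
    cbind(-diag(n), diag(n)),   # t - v >= 0
    cbind(diag(n), diag(n)),    # t + v >= 0
    c(as.numeric(seq_len(n) == iobj), rep(0, n)))
  b_ge <- c(rep(0, 2 * n), objective_fraction * zstar)
  sol <- lp_solve(c(rep(0, n), unname(w)), A_eq = A_eq, b_eq = rep(0, nrow(S)),
                  A_ge = A_ge, b_ge = b_ge,
                  lb = c(lbv, rep(0, n)), ub = c(ubv, tmax), sense = "min")
  stopifnot(sol$status == "optimal")
  list(value = sol$value, v = stats::setNames(sol$x[seq_len(n)], rid))
}

# Mann-Whitney U statistic by direct pair counting.
mwu_stat_oracle <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}

# Exact two-sided MWU p by exhaustive relabeling (tiny samples only).
mwu_exact_oracle <- function(x, y) {
  pooled <- c(x, y); m <- length(x)
  combos <- utils::combn(length(pooled), m, simplify = FALSE)
  us <- vapply(combos, function(ix)
    mwu_stat_oracle(pooled[ix], pooled[-ix]), numeric(1))
  u <- mwu_stat_oracle(x, y)
  min(1, 2 * min(mean(us >= u), mean(us <= u)))
}
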