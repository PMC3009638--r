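# Linear-programming layer: a dense bounded-variable two-phase revised
# simplex. Flux bounds may be symbolically unbounded (+/-Inf); the solver
# substitutes a finite magnitude (default 1e6, option "synflux.inf_bound").
# Written for the moderately sized, highly degenerate equality systems of
# stoichiometric models: variables live between individual bounds (no
# big-M shifting), redundant mass-balance rows are dropped up front, and a
# Bland-rule fallback guards against cycling on degenerate vertices.

#' Finite magnitude substituted for symbolically unbounded flux bounds
#' @return A positive number (default `1e6`; set option
#'   `synflux.inf_bound` to override).
#' @export
flux_inf <- function() getOption("synflux.inf_bound", 1e6)

.finite_bounds <- function(lb, ub, big = flux_inf()) {
  lb[is.infinite(lb)] <- -big
  ub[is.infinite(ub)] <- big
  list(lb = lb, ub = ub)
}

# Minimize obj'x subject to A x = b, lb <= x <= ub (all finite except that
# artificial columns added internally are [0, Inf)). Returns
# list(status, x, objective). Tolerances: feasibility 1e-9 on the phase-1
# residual, reduced-cost 1e-9.
bounded_simplex <- function(A, b, lb, ub, obj,
                            feas_tol = 1e-9, cost_tol = 1e-9,
                            pivot_tol = 1e-10, warm = NULL) {
  m <- nrow(A); n <- ncol(A)
  if (any(lb > ub + feas_tol))
    return(list(status = "infeasible", x = NULL, objective = NA_real_))

  # initial nonbasic point: each structural variable at its bound nearer 0
  x <- ifelse(abs(lb) <= abs(ub), lb, ub)
  at_upper <- abs(lb) > abs(ub)
  r <- as.numeric(b - A %*% x)

  # artificial columns with signs matching the residual
  sgn <- ifelse(r >= 0, 1, -1)
  Aall <- cbind(A, diag(sgn, nrow = m))
  lball <- c(lb, rep(0, m))
  uball <- c(ub, rep(Inf, m))
  xall <- c(x, abs(r))
  at_upper <- c(at_upper, rep(FALSE, m))
  basis <- n + seq_len(m)
  nvar <- n + m

  # at_upper is tracked per variable (meaningful for nonbasic variables)
  run_phase <- function(cost, basis, xall, at_upper, uball, max_iter) {
    bland_after <- 5L * nvar
    iter <- 0L
    repeat {
      iter <- iter + 1L
      if (iter > max_iter)
        return(list(status = "iteration_limit", basis = basis, x = xall,
                    at_upper = at_upper))
      B <- Aall[, basis, drop = FALSE]
      nonbasic <- setdiff(seq_len(nvar), basis)
      # recompute basic values from the nonbasic bounds each iteration to
      # keep round-off from accumulating
      rhs <- b - Aall[, nonbasic, drop = FALSE] %*% xall[nonbasic]
      xB <- tryCatch(as.numeric(solve(B, rhs)), error = function(e) NULL)
      if (is.null(xB) || anyNA(xB))
        return(list(status = "singular", basis = basis, x = xall,
                    at_upper = at_upper))
      xall[basis] <- xB

      piv <- tryCatch(as.numeric(solve(t(B), cost[basis])),
                      error = function(e) NULL)
      if (is.null(piv) || anyNA(piv))
        return(list(status = "singular", basis = basis, x = xall,
                    at_upper = at_upper))
      d <- cost[nonbasic] -
        as.numeric(crossprod(Aall[, nonbasic, drop = FALSE], piv))

      au_nb <- at_upper[nonbasic]
      movable <- uball[nonbasic] - lball[nonbasic] > feas_tol
      eligible <- movable & ((!au_nb & d < -cost_tol) | (au_nb & d > cost_tol))
      if (!any(eligible))
        return(list(status = "optimal", basis = basis, x = xall,
                    at_upper = at_upper))
      idx <- which(eligible)
      enter_pos <- if (iter > bland_after) idx[which.min(nonbasic[idx])]
                   else idx[which.max(abs(d[idx]))]
      j <- nonbasic[enter_pos]
      sigma <- if (at_upper[j]) -1 else 1

      w <- as.numeric(solve(B, Aall[, j]))
      # ratio test: entering moves by t >= 0; basics change by delta * t
      t_own <- uball[j] - lball[j]
      delta <- -sigma * w
      t_basic <- rep(Inf, m)
      dec <- delta < -pivot_tol
      inc <- delta > pivot_tol
      t_basic[dec] <- (xall[basis][dec] - lball[basis][dec]) / (-delta[dec])
      t_basic[inc] <- (uball[basis][inc] - xall[basis][inc]) / delta[inc]
      t_basic[t_basic < 0] <- 0
      if (!is.finite(min(t_own, t_basic)))
        return(list(status = "unbounded", basis = basis, x = xall,
                    at_upper = at_upper))

      if (t_own <= min(t_basic)) {
        # bound flip: entering variable crosses to its opposite bound
        xall[j] <- if (sigma > 0) uball[j] else lball[j]
        xall[basis] <- xall[basis] + delta * t_own
        at_upper[j] <- sigma > 0
        next
      }
      t_min <- min(t_basic)
      cand <- which(t_basic <= t_min + 1e-12)
      leave_row <- if (iter > bland_after) cand[which.min(basis[cand])]
                   else cand[which.max(abs(delta[cand]))]
      t_star <- t_basic[leave_row]
      xall[basis] <- xall[basis] + delta * t_star
      xall[j] <- xall[j] + sigma * t_star
      leaving <- basis[leave_row]
      hit_lower <- delta[leave_row] < 0
      xall[leaving] <- if (hit_lower) lball[leaving] else uball[leaving]
      at_upper[leaving] <- !hit_lower
      basis[leave_row] <- j
    }
  }

  max_iter <- 200L * nvar
  if (!is.null(warm) && length(warm$x) == nvar) {
    # warm start: a feasible basis from a previous solve over the same
    # constraint system (objective may differ); artificials stay pinned
    uball[n + seq_len(m)] <- 0
    ph2 <- run_phase(c(obj, rep(0, m)), warm$basis, warm$x, warm$at_upper,
                     uball, max_iter)
    if (ph2$status == "optimal") {
      x <- ph2$x[seq_len(n)]
      return(list(status = "optimal", x = x, objective = sum(obj * x),
                  state = list(basis = ph2$basis, x = ph2$x,
                               at_upper = ph2$at_upper)))
    }
    # fall through to a cold solve on any warm-start trouble
  }
  ph1 <- run_phase(c(rep(0, n), rep(1, m)), basis, xall, at_upper, uball,
                   max_iter)
  if (ph1$status %in% c("iteration_limit", "singular"))
    return(list(status = ph1$status, x = NULL, objective = NA_real_))
  art_val <- sum(ph1$x[n + seq_len(m)])
  if (art_val > 1e-7)
    return(list(status = "infeasible", x = NULL, objective = NA_real_))
  # pin artificials at zero for phase 2 (basic artificials at zero may
  # remain in the basis to span redundant rows)
  uball[n + seq_len(m)] <- 0
  xall <- ph1$x
  xall[n + seq_len(m)] <- 0
  ph2 <- run_phase(c(obj, rep(0, m)), ph1$basis, xall, ph1$at_upper, uball,
                   max_iter)
  if (ph2$status %in% c("iteration_limit", "singular"))
    return(list(status = ph2$status, x = NULL, objective = NA_real_))
  if (ph2$status == "unbounded")
    return(list(status = "unbounded", x = NULL, objective = NA_real_))
  x <- ph2$x[seq_len(n)]
  list(status = "optimal", x = x, objective = sum(obj * x),
       state = list(basis = ph2$basis, x = ph2$x, at_upper = ph2$at_upper))
}

# Solve: optimize obj'v  s.t.  S v = 0, lb <= v <= ub, and optional coupling
# rows lo_k <= c_k' v <= up_k (handled via slack variables).
# Returns list(status, v, objective).
#
# Variables whose interval straddles zero (reversible fluxes) are split into
# positive and negative parts. This puts the all-zero flux vector at a
# vertex-adjacent starting point, so phase 1 only has to repair the few
# bounds that exclude zero (maintenance, fixed-growth bands) instead of
# hauling every reversible flux back from a big-M bound — which is both
# much faster and keeps degenerate optima from parking spurious
# futile-cycle fluxes at the solver's finite infinity.
solve_lp <- function(S, lb, ub, obj, sense = c("max", "min"),
                     couplings = NULL, big = flux_inf(), warm = NULL) {
  sense <- match.arg(sense)
  n <- length(obj)
  fb <- .finite_bounds(lb, ub, big)
  lb <- fb$lb; ub <- fb$ub
  if (any(lb > ub))
    return(list(status = "infeasible", v = NULL, objective = NA_real_))

  S <- as.matrix(S)
  cn <- colnames(S)
  # drop linearly dependent mass-balance rows (conserved moieties such as
  # the ATP/ADP pair duplicate rows up to sign); the homogeneous system's
  # solution set is unchanged
  if (nrow(S) > 1L) {
    qrS <- qr(t(S))
    if (qrS$rank < nrow(S))
      S <- S[sort(qrS$pivot[seq_len(qrS$rank)]), , drop = FALSE]
  }

  split <- which(lb < 0 & ub > 0)
  A <- cbind(S, -S[, split, drop = FALSE])
  alb <- c(replace(lb, split, 0), rep(0, length(split)))
  aub <- c(ub, -lb[split])
  aobj <- c(obj, -obj[split])
  b <- rep(0, nrow(S))

  if (!is.null(couplings) && length(couplings)) {
    # lo <= c'v <= up  becomes  c'v + s = up with 0 <= s <= up - lo
    for (cp in couplings) {
      up <- if (is.finite(cp$upper)) cp$upper else big * max(1, abs(cp$coef))
      lo <- if (is.finite(cp$lower)) cp$lower else -big * max(1, abs(cp$coef))
      row <- c(cp$coef, -cp$coef[split])
      A <- rbind(A, c(row, rep(0, ncol(A) - length(row))))
      A <- cbind(A, c(rep(0, nrow(A) - 1L), 1))
      b <- c(b, up)
      alb <- c(alb, 0)
      aub <- c(aub, up - lo)
      aobj <- c(aobj, 0)
    }
  }
  res <- bounded_simplex(A, b, alb, aub,
                         obj = if (sense == "max") -aobj else aobj,
                         warm = warm)
  if (res$status != "optimal")
    return(list(status = res$status, v = NULL, objective = NA_real_))
  v <- res$x[seq_len(n)]
  if (length(split))
    v[split] <- v[split] - res$x[n + seq_along(split)]
  names(v) <- cn
  list(status = "optimal", v = v, objective = sum(obj * v),
       state = res$state)
}
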