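# Minimization of metabolic adjustment: quadratic program predicting mutant
# fluxes as the feasible point of the perturbed network nearest (Euclidean
# distance) to a wild-type reference flux vector.

#' MOMA mutant flux prediction
#'
#' Finds the flux vector x in the mutant's feasible space minimizing the
#' Euclidean distance D(w, x) = sqrt(sum_i (w_i - x_i)^2) to the wild-type
#' reference w. Growth is read off the solution, not optimized: the method
#' deliberately relaxes the assumption that mutants grow optimally. The
#' squared distance is minimized (same argmin); the QP is strictly convex,
#' so the solution is unique.
#'
#' @param model A `metabolic_model`.
#' @param mutant_constraints Optional [constraint_set()] for the mutant.
#' @param disabled Reaction ids forced to zero flux in the mutant.
#' @param wild_type Reference flux vector: a `flux_distribution` (typically
#'   the unperturbed FBA solution under the same condition) or a named
#'   numeric vector covering all reactions.
#' @return A list of class `moma_solution` with `fluxes`, `distance`,
#'   `growth` (flux of the model's objective reaction), `reference` and
#'   `status` (`"optimal"` or `"infeasible"`).
#' @export
moma <- function(model, mutant_constraints = NULL, disabled = character(),
                 wild_type) {
  w <- if (inherits(wild_type, "flux_distribution")) wild_type$fluxes
       else wild_type
  rids <- reaction_ids(model)
  if (is.null(names(w)) || !all(rids %in% names(w)))
    stop("wild-type reference must cover all model reactions")
  w <- w[rids]

  S <- as.matrix(build_stoichiometric_matrix(model))
  eb <- effective_bounds(model, mutant_constraints, disabled)
  fb <- .finite_bounds(eb$lb, eb$ub)
  lb <- fb$lb; ub <- fb$ub
  n <- length(rids)

  # fixed variables (knockouts, maintenance flux, two-sided bounds) are
  # substituted out of the program — keeping them as equality rows makes
  # quadprog's active-set method fail spuriously on degenerate systems
  fixed <- which(ub - lb < 1e-12)
  free <- setdiff(seq_len(n), fixed)
  x_fix <- lb[fixed]
  rhs <- if (length(fixed)) -as.numeric(S[, fixed, drop = FALSE] %*% x_fix)
         else rep(0, nrow(S))
  Sf <- S[, free, drop = FALSE]
  # independent mass-balance rows only (solve.QP rejects rank deficiency);
  # verify the dropped rows are consistent with the kept ones afterwards
  qrS <- qr(t(Sf))
  keep <- qrS$pivot[seq_len(qrS$rank)]
  dropped <- setdiff(seq_len(nrow(Sf)), keep)
  Aeq <- Sf[keep, , drop = FALSE]
  beq <- rhs[keep]

  # pseudo-infinite bounds (the solver stand-in for +/-Inf) are omitted
  # from the active-set QP — they destabilize quadprog — and verified on
  # the solution instead
  big <- 0.999 * flux_inf()
  nf <- length(free)
  lo_rows <- which(lb[free] > -big)
  hi_rows <- which(ub[free] < big)
  Aineq <- rbind(diag(nf)[lo_rows, , drop = FALSE],
                 -diag(nf)[hi_rows, , drop = FALSE])
  bineq <- c(lb[free][lo_rows], -ub[free][hi_rows])

  cps <- expand_couplings(model, mutant_constraints)
  if (!is.null(cps)) {
    for (cp in cps) {
      base <- sum(cp$coef[fixed] * x_fix)
      cf <- cp$coef[free]
      if (is.finite(cp$lower)) {
        Aineq <- rbind(Aineq, cf); bineq <- c(bineq, cp$lower - base)
      }
      if (is.finite(cp$upper)) {
        Aineq <- rbind(Aineq, -cf); bineq <- c(bineq, -(cp$upper - base))
      }
    }
  }

  infeasible_result <- function() {
    structure(list(fluxes = NULL, distance = NA_real_,
                   growth = NA_real_, reference = w,
                   status = "infeasible"),
              class = "moma_solution")
  }

  # null-space reduction: x_free = x0 + Z t with Aeq x0 = beq and
  # Aeq Z = 0 turns the program into a small inequality-only QP, which
  # quadprog's active-set method solves reliably (it fails spuriously on
  # large degenerate equality blocks)
  x0 <- tryCatch(
    crossprod(Aeq, solve(tcrossprod(Aeq), beq)),
    error = function(e) NULL)
  if (is.null(x0) || max(abs(Aeq %*% x0 - beq)) > 1e-6)
    return(infeasible_result())
  x0 <- as.numeric(x0)
  qq <- qr(t(Aeq))
  r <- qq$rank
  xf <- if (r < nf) {
    Z <- qr.Q(qq, complete = TRUE)[, (r + 1):nf, drop = FALSE]
    G <- Aineq %*% Z
    h <- as.numeric(bineq - Aineq %*% x0)
    d <- as.numeric(crossprod(Z, w[free] - x0))
    # zero-growth and similarly degenerate mutants have flat feasible
    # regions on which the active-set method fails; a hair of relaxation
    # (well below all reporting tolerances) restores an interior
    sol <- NULL
    for (eps in c(0, 1e-9, 1e-8)) {
      sol <- tryCatch(
        quadprog::solve.QP(Dmat = diag(nf - r), dvec = d, Amat = t(G),
                           bvec = h - eps),
        error = function(e) NULL)
      if (!is.null(sol)) break
    }
    if (is.null(sol)) return(infeasible_result())
    x0 + as.numeric(Z %*% sol$solution)
  } else {
    if (length(bineq) && min(Aineq %*% x0 - bineq) < -1e-8)
      return(infeasible_result())
    x0
  }
  x <- numeric(n)
  x[fixed] <- x_fix
  x[free] <- xf
  names(x) <- rids
  # dropped dependent rows must still balance (they always do when the
  # fixed-variable substitution is consistent); otherwise truly infeasible
  if (length(dropped) && max(abs(Sf[dropped, , drop = FALSE] %*% x[free] -
                                   rhs[dropped])) > 1e-6)
    return(infeasible_result())
  if (any(x < lb - 1e-6) || any(x > ub + 1e-6))
    stop("MOMA solution escaped the finite solver box; increase the ",
         "'synflux.inf_bound' option")
  structure(list(fluxes = x,
                 distance = sqrt(sum((w - x)^2)),
                 growth = unname(x[model$objective]),
                 reference = w,
                 status = "optimal"),
            class = "moma_solution")
}

#' @export
print.moma_solution <- function(x, ...) {
  cat("MOMA solution (", x$status, ")\n", sep = "")
  if (is_feasible(x))
    cat(sprintf("  distance to wild type = %.6g, growth = %.6g\n",
                x$distance, x$growth))
  invisible(x)
}
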