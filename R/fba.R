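## FBA-level operations: plain flux balance analysis, the theoretical maxima
## of the three search axes, the minimum-total-flux "first LP" under box
## constraints, and the two-stage "second LP" that validates a knockout set.

FLUX_EPSILON_DEFAULT <- 1e-5
POST_TOL <- 1e-6
GROWTH_FIX_REL_TOL <- 1e-6

new_flux_distribution <- function(status, x = NULL, objective = NA_real_) {
  structure(
    list(status = status, x = x, objective = objective,
         total_abs_flux = if (is.null(x)) NA_real_ else sum(abs(x))),
    class = "flux_distribution"
  )
}

#' @export
print.flux_distribution <- function(x, ...) {
  cat("flux_distribution:", x$status)
  if (x$status == "optimal") {
    cat("  objective =", format(x$objective),
        " sum|x| =", format(x$total_abs_flux))
  }
  cat("\n")
  invisible(x)
}

#' Flux balance analysis
#'
#' Maximizes or minimizes the flux of one reaction over the steady-state
#' polytope `\{x : S x = 0, lb <= x <= ub\}`, optionally with per-reaction
#' bound overrides (e.g. knockouts as `[0, 0]`).
#'
#' @param model a [metabolic_model()].
#' @param objective reaction id whose flux is optimized.
#' @param sense `"max"` or `"min"`.
#' @param extra_bounds optional named list; each entry is `c(lb, ub)` for a
#'   reaction id and overrides that reaction's bounds.
#' @return a `flux_distribution` with `status`, and when optimal the flux
#'   vector `x` (named by reaction), `objective`, and `total_abs_flux`.
#' @examples
#' solve_fba(build_toy_network(), "R6", "max")$objective  # 3
#' @export
solve_fba <- function(model, objective, sense = c("max", "min"),
                      extra_bounds = NULL) {
  stopifnot(inherits(model, "metabolic_model"))
  sense <- match.arg(sense)
  oi <- match(objective, model$reaction_ids)
  if (is.na(oi)) stop("unknown objective reaction: ", objective, call. = FALSE)
  bnds <- override_bounds(model, extra_bounds)
  cc <- numeric(length(model$reaction_ids)); cc[oi] <- 1
  res <- lp_solve(cc, Aeq = model$S, beq = rep(0, nrow(model$S)),
                  lb = bnds$lb, ub = bnds$ub, maximize = sense == "max")
  if (res$status == "iteration_limit") {
    stop("LP solver failed: iteration limit reached", call. = FALSE)
  }
  if (res$status != "optimal") return(new_flux_distribution(res$status))
  x <- res$x
  names(x) <- model$reaction_ids
  new_flux_distribution("optimal", x, res$objective)
}

override_bounds <- function(model, extra_bounds) {
  lb <- model$lb; ub <- model$ub
  if (!is.null(extra_bounds)) {
    bad <- setdiff(names(extra_bounds), model$reaction_ids)
    if (length(bad)) {
      stop("unknown reaction id(s) in bounds: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    for (rid in names(extra_bounds)) {
      lb[[rid]] <- extra_bounds[[rid]][1]
      ub[[rid]] <- extra_bounds[[rid]][2]
    }
  }
  list(lb = lb, ub = ub)
}

## Split-variable representation: every reaction becomes one or two
## non-negative components so that sum(|x|) is LP-expressible as the
## component sum.  For fully irreversible models the representation is
## exact; with reversible reactions a forced LOWER bound on the component
## sum can be met by futile forward+backward activity, the standard
## relaxation of the (non-convex) true constraint.
split_model <- function(model, extra_bounds = NULL) {
  bnds <- override_bounds(model, extra_bounds)
  lb <- bnds$lb; ub <- bnds$ub
  n <- length(lb)
  cols <- list(); clb <- c(); cub <- c(); owner <- c(); sign <- c()
  for (j in seq_len(n)) {
    if (lb[j] >= 0) {
      cols[[length(cols) + 1]] <- model$S[, j]
      clb <- c(clb, lb[j]); cub <- c(cub, ub[j])
      owner <- c(owner, j); sign <- c(sign, 1)
    } else if (ub[j] <= 0) {
      cols[[length(cols) + 1]] <- -model$S[, j]
      clb <- c(clb, -ub[j]); cub <- c(cub, -lb[j])
      owner <- c(owner, j); sign <- c(sign, -1)
    } else {
      cols[[length(cols) + 1]] <- model$S[, j]
      clb <- c(clb, 0); cub <- c(cub, ub[j])
      owner <- c(owner, j); sign <- c(sign, 1)
      cols[[length(cols) + 1]] <- -model$S[, j]
      clb <- c(clb, 0); cub <- c(cub, -lb[j])
      owner <- c(owner, j); sign <- c(sign, -1)
    }
  }
  A <- do.call(cbind, cols)
  list(A = A, lb = clb, ub = cub, owner = owner, sign = sign,
       n_rxn = n)
}

## net flux row-vector (length = #components) for one reaction index
component_row <- function(sp, j) {
  r <- numeric(length(sp$owner))
  sel <- sp$owner == j
  r[sel] <- sp$sign[sel]
  r
}

recover_flux <- function(sp, y, reaction_ids) {
  x <- as.vector(tapply(y * sp$sign,
                        factor(sp$owner, levels = seq_len(sp$n_rxn)), sum))
  names(x) <- reaction_ids
  x
}

#' Box constraint on the (GR, PR, SF) solution space
#'
#' A closed box over the three search axes: growth rate, production rate
#' and total absolute flux.  `sf` may have an infinite upper bound (used by
#' the 2-D grid search, which does not constrain SF).
#'
#' @param gr,pr,sf numeric length-2 intervals `c(lo, hi)` with
#'   `0 <= lo <= hi`.
#' @return an object of class `box_constraint`.
#' @export
box_constraint <- function(gr, pr, sf) {
  chk <- function(v, nm, allow_inf = FALSE) {
    if (length(v) != 2 || v[1] < 0 || v[1] > v[2] ||
        (!allow_inf && !all(is.finite(v)))) {
      stop("invalid ", nm, " interval", call. = FALSE)
    }
  }
  chk(gr, "gr"); chk(pr, "pr"); chk(sf, "sf", allow_inf = TRUE)
  structure(list(gr = as.numeric(gr), pr = as.numeric(pr),
                 sf = as.numeric(sf)), class = "box_constraint")
}

#' Minimize total absolute flux inside a box
#'
#' The "first LP" of the subdivision search: minimize `sum(|x|)` subject to
#' steady state, flux bounds, the growth and production intervals of `box`,
#' and the SF interval enforced on the split-component sum.  When the LP is
#' feasible the returned vertex is deterministic (fixed solver, fixed
#' variable order), which makes the downstream candidate extraction
#' reproducible.
#'
#' @param model a [metabolic_model()].
#' @param box a [box_constraint()].
#' @param extra_bounds optional overrides as in [solve_fba()].
#' @return a `flux_distribution`; `status = "infeasible"` when no flux
#'   vector satisfies the box.
#' @examples
#' toy <- build_toy_network()
#' fd <- min_total_flux(toy, box_constraint(c(0, 3), c(0, 3), c(0, 26)))
#' round(fd$x, 6)  # (3, 0, 3, 0, 0, 3, 0)
#' @export
min_total_flux <- function(model, box, extra_bounds = NULL) {
  stopifnot(inherits(model, "metabolic_model"),
            inherits(box, "box_constraint"))
  gi <- role_index(model, "growth")
  ti <- role_index(model, "target")
  sp <- split_model(model, extra_bounds)
  nc <- length(sp$lb)
  grow <- component_row(sp, gi)
  trow <- component_row(sp, ti)
  srow <- rep(1, nc)
  Ale <- rbind(grow, trow); ble <- c(box$gr[2], box$pr[2])
  Age <- rbind(grow, trow); bge <- c(box$gr[1], box$pr[1])
  if (is.finite(box$sf[2])) { Ale <- rbind(Ale, srow); ble <- c(ble, box$sf[2]) }
  if (box$sf[1] > 0) { Age <- rbind(Age, srow); bge <- c(bge, box$sf[1]) }
  res <- lp_solve(rep(1, nc), Aeq = sp$A, beq = rep(0, nrow(sp$A)),
                  Ale = Ale, ble = ble, Age = Age, bge = bge,
                  lb = sp$lb, ub = sp$ub, maximize = FALSE)
  if (res$status == "iteration_limit") {
    stop("LP solver failed: iteration limit reached", call. = FALSE)
  }
  if (res$status != "optimal") return(new_flux_distribution(res$status))
  x <- recover_flux(sp, res$x, model$reaction_ids)
  fd <- new_flux_distribution("optimal", x, res$objective)
  fd
}

#' Theoretical maxima of the three search axes
#'
#' Computes the axis scales that the subdivision search divides:
#'
#' * `tmgr`: maximum growth rate over the model's steady-state polytope;
#' * `tmpr`: maximum production rate over the same polytope (no growth
#'   requirement);
#' * `tmsf`: a deterministic total-absolute-flux scale — first maximize
#'   production subject to `growth >= min_growth`, then fix production at
#'   that optimum and maximize the split-component sum over the optimal
#'   face.
#'
#' Maximizing the component sum (rather than reporting `sum(|x|)` at
#' whichever vertex the production LP happens to return) makes `tmsf`
#' independent of solver tie-breaking and a conservative cap for the SF
#' axis.  If the growth requirement is unattainable, `tmsf` is 0.
#'
#' @param model a [metabolic_model()] with growth and target roles.
#' @param min_growth minimum growth rate used in the `tmsf` stage.
#' @return an object of class `theoretical_maxima` with fields `tmgr`,
#'   `tmpr`, `tmsf`.
#' @examples
#' unlist(compute_theoretical_maxima(build_toy_network(), 1))  # 3 3 13
#' @export
compute_theoretical_maxima <- function(model, min_growth = 0) {
  stopifnot(inherits(model, "metabolic_model"))
  gi <- role_index(model, "growth")
  ti <- role_index(model, "target")
  g_fba <- solve_fba(model, model$reaction_ids[gi], "max")
  if (g_fba$status != "optimal") {
    stop("base model is ", g_fba$status,
         ": no steady-state flux satisfies the bounds", call. = FALSE)
  }
  tmgr <- g_fba$objective
  t_fba <- solve_fba(model, model$reaction_ids[ti], "max")
  tmpr <- t_fba$objective

  sp <- split_model(model)
  nc <- length(sp$lb)
  grow <- component_row(sp, gi)
  trow <- component_row(sp, ti)
  ## stage a: max production s.t. growth >= min_growth
  cc <- trow
  ra <- lp_solve(cc, Aeq = sp$A, beq = rep(0, nrow(sp$A)),
                 Age = rbind(grow), bge = min_growth,
                 lb = sp$lb, ub = sp$ub, maximize = TRUE)
  if (ra$status != "optimal") {
    tmsf <- 0
  } else {
    pr_star <- ra$objective
    ## stage b: max component sum over the optimal face
    rb <- lp_solve(rep(1, nc), Aeq = sp$A, beq = rep(0, nrow(sp$A)),
                   Age = rbind(grow, trow), bge = c(min_growth, pr_star),
                   Ale = rbind(trow), ble = pr_star,
                   lb = sp$lb, ub = sp$ub, maximize = TRUE)
    tmsf <- if (rb$status == "optimal") rb$objective else 0
  }
  structure(list(tmgr = max(tmgr, 0), tmpr = max(tmpr, 0),
                 tmsf = max(tmsf, 0)),
            class = "theoretical_maxima")
}

#' @export
print.theoretical_maxima <- function(x, ...) {
  cat(sprintf("theoretical maxima: TMGR = %g, TMPR = %g, TMSF = %g\n",
              x$tmgr, x$tmpr, x$tmsf))
  invisible(x)
}

#' Extract a deletion-candidate set from a flux distribution
#'
#' Collects the reactions whose absolute flux falls strictly below
#' `epsilon` (default `1e-5`), excluding the `protected` set.  This is the
#' candidate knockout set of the subdivision search: reactions the
#' minimum-flux solution does not use inside a sub-space are proposed for
#' deletion.
#'
#' @param flux an optimal `flux_distribution`.
#' @param protected character vector of reaction ids never proposed.
#' @param epsilon strict absolute-flux threshold.
#' @return character vector of reaction ids.
#' @export
extract_candidate <- function(flux, protected = character(),
                              epsilon = FLUX_EPSILON_DEFAULT) {
  stopifnot(inherits(flux, "flux_distribution"))
  if (flux$status != "optimal") {
    stop("extract_candidate requires an optimal flux distribution",
         call. = FALSE)
  }
  setdiff(names(flux$x)[abs(flux$x) < epsilon], protected)
}

#' Default protected reactions
#'
#' Reactions the search never proposes for deletion: the target and growth
#' reactions plus, when present, the glucose-uptake, oxygen-uptake,
#' ATP-maintenance and auxiliary-export reactions.  Deleting any of these
#' would contradict the experiment the search models (no growth objective,
#' no product read-out, or no medium).  Overridable wherever a `protected`
#' argument is accepted.
#'
#' @param model a [metabolic_model()].
#' @return character vector of reaction ids.
#' @export
default_protected <- function(model) {
  unique(unlist(model$roles, use.names = FALSE))
}

#' Validate a knockout set by two-stage LP
#'
#' The "second LP" of the search, run without any box constraints: stage 1
#' maximizes growth with all reactions in `K` fixed to zero; stage 2 fixes
#' growth at that maximum (within a relative tolerance of `1e-6`) and
#' minimizes production.  The returned pair `(gr_max, pr_min)` is the
#' worst-case production the cell guarantees at maximal growth — the
#' quantity growth coupling is judged on.  If stage 1 is infeasible (e.g. a
#' pinned uptake can no longer be consumed) the degenerate pair `(0, 0)` is
#' returned with `degenerate = TRUE`.
#'
#' @param model a [metabolic_model()] with growth and target roles.
#' @param K character vector of reaction ids to delete; must not contain
#'   the target reaction.
#' @return list with `gr_max`, `pr_min`, `degenerate`.
#' @examples
#' toy <- build_toy_network()
#' validate_deletion(toy, "R3")  # gr_max 1, pr_min 2
#' @export
validate_deletion <- function(model, K = character()) {
  stopifnot(inherits(model, "metabolic_model"))
  K <- as.character(K)
  bad <- setdiff(K, model$reaction_ids)
  if (length(bad)) {
    stop("unknown reaction id(s) in K: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  ti <- role_index(model, "target")
  if (model$reaction_ids[ti] %in% K) {
    stop("the target reaction cannot be deleted", call. = FALSE)
  }
  gi <- role_index(model, "growth")
  ko <- stats::setNames(rep(list(c(0, 0)), length(K)), K)
  s1 <- solve_fba(model, model$reaction_ids[gi], "max", extra_bounds = ko)
  if (s1$status != "optimal") {
    return(list(gr_max = 0, pr_min = 0, degenerate = TRUE))
  }
  gr_max <- s1$objective
  ## stage 2: min production with growth held at its maximum
  grow_fix <- gr_max * (1 - GROWTH_FIX_REL_TOL)
  bnds2 <- ko
  bnds2[[model$reaction_ids[gi]]] <-
    c(max(model$lb[[gi]], grow_fix), model$ub[[gi]])
  s2 <- solve_fba(model, model$reaction_ids[ti], "min", extra_bounds = bnds2)
  if (s2$status != "optimal") {
    return(list(gr_max = 0, pr_min = 0, degenerate = TRUE))
  }
  list(gr_max = gr_max, pr_min = max(s2$objective, 0), degenerate = FALSE)
}
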