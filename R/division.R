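## Solution-space subdivision: cube geometry, the feasibility mask that
## level n+1 inherits from level n, and the three searches (2-D grid,
## static 3-D cubes, dynamic doubling with pruning and early stop).

#' Search parameters for the subdivision methods
#'
#' @param min_growth minimum growth rate an accepted strategy must retain.
#' @param min_target minimum guaranteed production rate at maximal growth.
#' @param flux_epsilon strict absolute-flux threshold below which a
#'   reaction is proposed for deletion (default `1e-5`).
#' @param n_max maximum level exponent; the finest level divides each axis
#'   into `2^n_max` pieces (default 5, i.e. up to 32 divisions).
#' @param protected reaction ids never proposed for deletion; `NULL` means
#'   [default_protected()] of the model at run time.
#' @param include_root examine the single level-0 cube (the whole space)
#'   explicitly so its candidate is also validated?  When `FALSE` the root
#'   is treated as examined-and-feasible and refinement starts at 8 cubes.
#' @return an object of class `search_params`.
#' @export
search_params <- function(min_growth = 1e-3, min_target = 1e-3,
                          flux_epsilon = FLUX_EPSILON_DEFAULT,
                          n_max = 5, protected = NULL,
                          include_root = TRUE) {
  stopifnot(min_growth >= 0, min_target >= 0, flux_epsilon >= 0, n_max >= 0)
  structure(list(min_growth = min_growth, min_target = min_target,
                 flux_epsilon = flux_epsilon, n_max = as.integer(n_max),
                 protected = protected, include_root = isTRUE(include_root)),
            class = "search_params")
}

#' Box constraint of one cube
#'
#' At level exponent `n` each axis is divided into `P = 2^n` equal closed
#' intervals.  Cube `(i, j, k)` (1-based) spans
#' `[(i-1) TMGR / P, i TMGR / P]` on the growth axis, the analogue with
#' TMPR on the production axis, and `[(k-1) 2 TMSF / P, k 2 TMSF / P]` on
#' the total-absolute-flux axis (the SF axis spans twice its nominal scale,
#' so the union of cubes covers `[0, 2 TMSF]`).  Shared faces belong to
#' both adjacent cubes.
#'
#' @param maxima a `theoretical_maxima` object.
#' @param n level exponent (>= 0).
#' @param i,j,k 1-based axis indices in `[1, 2^n]`.
#' @return a [box_constraint()].
#' @examples
#' tm <- compute_theoretical_maxima(build_toy_network(), 1)
#' cube_bounds(tm, 1, 1, 1, 1)  # gr [0,1.5], pr [0,1.5], sf [0,13]
#' @export
cube_bounds <- function(maxima, n, i, j, k) {
  stopifnot(inherits(maxima, "theoretical_maxima"), n >= 0)
  P <- 2^n
  if (any(c(i, j, k) < 1) || any(c(i, j, k) > P)) {
    stop("cube index out of range for P = ", P, call. = FALSE)
  }
  box_constraint(
    gr = c(i - 1, i) * maxima$tmgr / P,
    pr = c(j - 1, j) * maxima$tmpr / P,
    sf = c(k - 1, k) * 2 * maxima$tmsf / P
  )
}

#' Create a feasibility grid
#'
#' Per-level book-keeping of the dynamic search: `d` flags the cubes that
#' must be examined (the explore mask) and `c` records, after examination,
#' whether the cube's first LP was feasible (1) or infeasible/skipped (0).
#'
#' @param P divisions per axis.
#' @param explore initial value of the explore mask (default all 1).
#' @return an object of class `feasibility_grid`.
#' @export
feasibility_grid <- function(P, explore = 1L) {
  structure(list(P = as.integer(P),
                 d = array(as.integer(explore), dim = c(P, P, P)),
                 c = array(0L, dim = c(P, P, P))),
            class = "feasibility_grid")
}

#' Inherit the explore mask at the next refinement level
#'
#' Each of the 8 children of cube `(i, j, k)` at level `P` — indices
#' `(2i-a, 2j-b, 2k-c)` with `a, b, c` in `{0, 1}` — inherits the parent's
#' feasibility flag as its explore mask at level `2P`.  Children of
#' infeasible parents are therefore never solved, which is sound: a
#' sub-space of an infeasible space is infeasible.
#'
#' @param parent a fully examined [feasibility_grid()].
#' @return a [feasibility_grid()] at level `2 * parent$P`.
#' @export
refine_mask <- function(parent) {
  stopifnot(inherits(parent, "feasibility_grid"))
  P2 <- 2L * parent$P
  child <- feasibility_grid(P2, explore = 0L)
  idx <- ceiling(seq_len(P2) / 2)
  child$d <- parent$c[idx, idx, idx, drop = FALSE]
  dim(child$d) <- c(P2, P2, P2)
  child
}

#' Examine one cube
#'
#' Runs the first LP ([min_total_flux()]) on the cube's box.  If
#' infeasible, returns feasibility flag 0 and no strategy.  Otherwise
#' extracts the candidate knockout set from the minimum-flux vertex,
#' validates it with the two-stage LP ([validate_deletion()]), and returns
#' flag 1 together with the strategy and its acceptance verdict
#' (`gr_max >= min_growth` and `pr_min >= min_target`).  A cube whose
#' candidate fails validation still counts as feasible and is refined at
#' the next level.
#'
#' @param model a [metabolic_model()].
#' @param box the cube's [box_constraint()].
#' @param params a [search_params()].
#' @param found_at provenance vector `c(P, i, j, k)` echoed in the result.
#' @return list with `c_flag` (0/1), `strategy` (a `deletion_strategy` or
#'   `NULL`) and `lp_count`.
#' @export
examine_cube <- function(model, box, params, found_at = c(NA, NA, NA, NA)) {
  protected <- params$protected
  if (is.null(protected)) protected <- default_protected(model)
  fd <- min_total_flux(model, box)
  if (fd$status != "optimal") {
    return(list(c_flag = 0L, strategy = NULL, lp_count = 1L))
  }
  K <- extract_candidate(fd, protected, params$flux_epsilon)
  val <- validate_deletion(model, K)
  accepted <- !val$degenerate &&
    val$gr_max >= params$min_growth && val$pr_min >= params$min_target
  strategy <- structure(
    list(K = K, GR = val$gr_max, PR = val$pr_min, accepted = accepted,
         found_at = found_at, first_lp_flux = fd$x,
         lp_count = if (val$degenerate) 2L else 3L),
    class = "deletion_strategy"
  )
  list(c_flag = 1L, strategy = strategy, lp_count = strategy$lp_count)
}

#' @export
print.deletion_strategy <- function(x, ...) {
  cat("deletion strategy:",
      if (length(x$K)) paste(x$K, collapse = ", ") else "(empty)", "\n")
  cat(sprintf("  GR = %g, PR = %g, %s\n", x$GR, x$PR,
              if (x$accepted) "ACCEPTED" else "rejected"))
  if (!any(is.na(x$found_at))) {
    cat(sprintf("  found at P = %d, cube (%d, %d, %d)\n",
                x$found_at[1], x$found_at[2], x$found_at[3], x$found_at[4]))
  }
  invisible(x)
}

trace_row <- function(P, i, j, k, status) {
  data.frame(P = P, i = i, j = j, k = k, status = status,
             stringsAsFactors = FALSE)
}

#' Dynamic cube search (doubling divisions with pruning)
#'
#' The dynamic search computes the axis maxima once, then iterates level
#' exponents `n = 0, 1, ..., n_max` (divisions `P = 2^n` per axis).  At
#' each level only cubes whose parent was feasible are examined, in
#' ascending `(i, j, k)` lexicographic order; the first accepted strategy
#' stops the search.  Skipped cubes are sound to skip: their parent's first
#' LP was infeasible, and a sub-space of an infeasible space is infeasible.
#'
#' @param model a [metabolic_model()] with growth and target roles.
#' @param params a [search_params()].
#' @param medium optional [medium_condition()] applied before searching.
#' @return an object of class `dyncube_result`: `strategy` (accepted
#'   `deletion_strategy`, or `NULL` if none found through `n_max`),
#'   `maxima`, `lp_count`, per-level accounting in `levels`, and the full
#'   cube `trace` (a data frame of cube indices and statuses).
#' @examples
#' res <- run_dyncubeprod(build_toy_network(),
#'                        search_params(min_growth = 1, min_target = 1))
#' res$strategy$K  # "R3"
#' @export
run_dyncubeprod <- function(model, params = search_params(), medium = NULL) {
  stopifnot(inherits(model, "metabolic_model"),
            inherits(params, "search_params"))
  if (!is.null(medium)) model <- apply_medium(model, medium)
  maxima <- compute_theoretical_maxima(model, params$min_growth)
  lp_count <- 4L  # the maxima LPs
  trace <- list()
  levels <- list()
  grid <- NULL
  accepted <- NULL

  for (n in 0:params$n_max) {
    P <- 2L^n
    if (is.null(grid)) {
      grid <- feasibility_grid(1L)
      if (!params$include_root) grid$c[1, 1, 1] <- 1L
    } else {
      grid <- refine_mask(grid)
    }
    if (n == 0 && !params$include_root) {
      levels[[as.character(P)]] <- c(examined = 0L, infeasible = 0L,
                                     rejected = 0L, skipped = 0L, lp = 0L)
      next
    }
    counts <- c(examined = 0L, infeasible = 0L, rejected = 0L,
                skipped = 0L, lp = 0L)
    for (i in seq_len(P)) for (j in seq_len(P)) for (k in seq_len(P)) {
      if (grid$d[i, j, k] == 0L) {
        counts["skipped"] <- counts["skipped"] + 1L
        trace[[length(trace) + 1]] <- trace_row(P, i, j, k, "skipped")
        next
      }
      box <- cube_bounds(maxima, n, i, j, k)
      ex <- examine_cube(model, box, params, found_at = c(P, i, j, k))
      lp_count <- lp_count + ex$lp_count
      counts["lp"] <- counts["lp"] + ex$lp_count
      counts["examined"] <- counts["examined"] + 1L
      grid$c[i, j, k] <- ex$c_flag
      if (ex$c_flag == 0L) {
        counts["infeasible"] <- counts["infeasible"] + 1L
        trace[[length(trace) + 1]] <- trace_row(P, i, j, k, "infeasible")
      } else if (ex$strategy$accepted) {
        trace[[length(trace) + 1]] <- trace_row(P, i, j, k, "accepted")
        accepted <- ex$strategy
        accepted$lp_count <- lp_count
        levels[[as.character(P)]] <- counts
        return(new_dyncube_result(accepted, maxima, lp_count, levels,
                                  trace, model))
      } else {
        counts["rejected"] <- counts["rejected"] + 1L
        trace[[length(trace) + 1]] <- trace_row(P, i, j, k, "rejected")
      }
    }
    levels[[as.character(P)]] <- counts
  }
  new_dyncube_result(NULL, maxima, lp_count, levels, trace, model)
}

new_dyncube_result <- function(strategy, maxima, lp_count, levels, trace,
                               model) {
  structure(list(strategy = strategy, maxima = maxima, lp_count = lp_count,
                 levels = levels,
                 trace = do.call(rbind, trace),
                 model = model),
            class = "dyncube_result")
}

#' @export
print.dyncube_result <- function(x, ...) {
  if (is.null(x$strategy)) {
    cat("no accepted deletion strategy (", x$lp_count, "LPs )\n")
  } else {
    print(x$strategy)
    cat("  total LPs solved:", x$lp_count, "\n")
  }
  invisible(x)
}

#' Static cube search at a fixed number of divisions
#'
#' Examines all `P^3` cubes at a single level (no inherited mask) and
#' returns every accepted strategy, the full feasibility grid, and the LP
#' tally.  With `stop_at_first = TRUE` the scan stops at the first accepted
#' strategy (useful when only the success/failure verdict is needed; the
#' verdict then matches the dynamic search capped at the same `P`).
#'
#' @param model a [metabolic_model()].
#' @param params a [search_params()].
#' @param P divisions per axis.
#' @param medium optional [medium_condition()].
#' @param stop_at_first stop scanning once a strategy is accepted?
#' @return list with `accepted` (list of strategies), `grid`
#'   (a [feasibility_grid()]), `lp_count`, `maxima`, `trace`.
#' @export
run_cubeprod <- function(model, params = search_params(), P = 1,
                         medium = NULL, stop_at_first = FALSE) {
  stopifnot(inherits(model, "metabolic_model"),
            inherits(params, "search_params"))
  if (!is.null(medium)) model <- apply_medium(model, medium)
  maxima <- compute_theoretical_maxima(model, params$min_growth)
  n <- as.integer(round(log2(P)))
  if (2^n != P) stop("P must be a power of two", call. = FALSE)
  grid <- feasibility_grid(P)
  lp_count <- 4L
  accepted <- list()
  trace <- list()
  for (i in seq_len(P)) for (j in seq_len(P)) for (k in seq_len(P)) {
    box <- cube_bounds(maxima, n, i, j, k)
    ex <- examine_cube(model, box, params, found_at = c(P, i, j, k))
    lp_count <- lp_count + ex$lp_count
    grid$c[i, j, k] <- ex$c_flag
    status <- if (ex$c_flag == 0L) "infeasible"
              else if (ex$strategy$accepted) "accepted" else "rejected"
    trace[[length(trace) + 1]] <- trace_row(P, i, j, k, status)
    if (status == "accepted") {
      accepted[[length(accepted) + 1]] <- ex$strategy
      if (stop_at_first) {
        return(list(accepted = accepted, grid = grid, lp_count = lp_count,
                    maxima = maxima, trace = do.call(rbind, trace)))
      }
    }
  }
  list(accepted = accepted, grid = grid, lp_count = lp_count,
       maxima = maxima, trace = do.call(rbind, trace))
}

#' Two-dimensional grid search (no SF axis)
#'
#' The grid variant divides only the growth and production axes into `P`
#' intervals each and leaves the total absolute flux unconstrained in the
#' first LP.  Examines all `P^2` grid cells and returns every accepted
#' strategy.  On networks where the minimum-flux solution of every cell
#' routes flux through the growth pathway, the grid search fails at every
#' `P`; constraining SF (the cube searches) is what makes the alternative
#' routes visible.
#'
#' @inheritParams run_cubeprod
#' @return list with `accepted`, `lp_count`, `maxima`, `trace`.
#' @export
run_gridprod <- function(model, params = search_params(), P = 1,
                         medium = NULL, stop_at_first = FALSE) {
  stopifnot(inherits(model, "metabolic_model"),
            inherits(params, "search_params"))
  if (!is.null(medium)) model <- apply_medium(model, medium)
  maxima <- compute_theoretical_maxima(model, params$min_growth)
  lp_count <- 4L
  accepted <- list()
  trace <- list()
  for (i in seq_len(P)) for (j in seq_len(P)) {
    box <- box_constraint(
      gr = c(i - 1, i) * maxima$tmgr / P,
      pr = c(j - 1, j) * maxima$tmpr / P,
      sf = c(0, Inf)
    )
    ex <- examine_cube(model, box, params, found_at = c(P, i, j, NA))
    lp_count <- lp_count + ex$lp_count
    status <- if (ex$c_flag == 0L) "infeasible"
              else if (ex$strategy$accepted) "accepted" else "rejected"
    trace[[length(trace) + 1]] <- trace_row(P, i, j, NA, status)
    if (status == "accepted") {
      accepted[[length(accepted) + 1]] <- ex$strategy
      if (stop_at_first) {
        return(list(accepted = accepted, lp_count = lp_count,
                    maxima = maxima, trace = do.call(rbind, trace)))
      }
    }
  }
  list(accepted = accepted, lp_count = lp_count, maxima = maxima,
       trace = do.call(rbind, trace))
}
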