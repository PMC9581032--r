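## Dense two-phase simplex with Bland's anti-cycling rule.
##
## The subdivision search solves thousands of small, frequently degenerate
## LPs (interval constraints collapse to points, optimal faces are flat), so
## the solver must be deterministic and must terminate on degenerate
## instances.  Bland's smallest-index rule guarantees both.  The tableau is
## dense; problem sizes here are tens of variables, not thousands.

LP_TOL_PIVOT <- 1e-9
LP_TOL_FEAS <- 1e-7

#' Solve a bounded linear program
#'
#' Minimizes (or maximizes) `obj %*% x` subject to `Aeq x = beq`,
#' `Ale x <= ble`, `Age x >= bge` and `lb <= x <= ub`, with a deterministic
#' dense two-phase simplex.  Intended for the small metabolic-network LPs
#' this package generates; every call with identical inputs returns the
#' identical vertex, which the candidate-extraction step relies on.
#'
#' @param obj numeric objective coefficients, length `n`.
#' @param Aeq,beq equality constraints (matrix with `n` columns, vector), or
#'   `NULL`.
#' @param Ale,ble less-or-equal constraints, or `NULL`.
#' @param Age,bge greater-or-equal constraints, or `NULL`.
#' @param lb,ub finite lower bounds and (possibly infinite) upper bounds,
#'   length `n`.
#' @param maximize maximize instead of minimize?
#' @return list with `status` (one of `"optimal"`, `"infeasible"`,
#'   `"unbounded"`), and on optimality `x` and `objective`.
#' @keywords internal
lp_solve <- function(obj, Aeq = NULL, beq = NULL, Ale = NULL, ble = NULL,
                     Age = NULL, bge = NULL, lb, ub, maximize = FALSE) {
  n <- length(obj)
  stopifnot(length(lb) == n, length(ub) == n, all(is.finite(lb)),
            all(lb <= ub + LP_TOL_FEAS))
  if (any(lb > ub)) {  # only within tolerance; clamp
    ub <- pmax(ub, lb)
  }
  sense <- if (maximize) -1 else 1
  cost <- sense * obj

  ## shift to z = x - lb >= 0
  shift_rhs <- function(A, b) if (is.null(A)) numeric(0) else b - as.vector(A %*% lb)
  as_mat <- function(A) {
    if (is.null(A)) matrix(0, 0, n) else matrix(A, ncol = n)
  }
  Aeq <- as_mat(Aeq); Ale <- as_mat(Ale); Age <- as_mat(Age)
  beq <- shift_rhs(Aeq, beq); ble <- shift_rhs(Ale, ble); bge <- shift_rhs(Age, bge)

  ## upper-bound rows for finite ub
  u <- ub - lb
  fin <- which(is.finite(u))
  Aub <- matrix(0, length(fin), n)
  if (length(fin)) Aub[cbind(seq_along(fin), fin)] <- 1
  bub <- u[fin]

  ## rows: [eq | le (incl ub rows) | ge], slack +1 on le, -1 on ge
  Ale2 <- rbind(Ale, Aub); ble2 <- c(ble, bub)
  m_eq <- nrow(Aeq); m_le <- nrow(Ale2); m_ge <- nrow(Age)
  m <- m_eq + m_le + m_ge
  A <- rbind(Aeq, Ale2, Age)
  b <- c(beq, ble2, bge)
  nslack <- m_le + m_ge
  Sl <- matrix(0, m, nslack)
  if (m_le) Sl[cbind(m_eq + seq_len(m_le), seq_len(m_le))] <- 1
  if (m_ge) Sl[cbind(m_eq + m_le + seq_len(m_ge), m_le + seq_len(m_ge))] <- -1
  Tm <- cbind(A, Sl)

  ## flip rows with negative rhs so b >= 0
  neg <- which(b < 0)
  if (length(neg)) { Tm[neg, ] <- -Tm[neg, , drop = FALSE]; b[neg] <- -b[neg] }

  ## initial basis: a slack column equal to +e_i serves; otherwise artificial
  ncol0 <- n + nslack
  basis <- integer(m)
  need_art <- rep(TRUE, m)
  for (i in seq_len(m_le)) {
    r <- m_eq + i
    if (!(r %in% neg)) { basis[r] <- n + i; need_art[r] <- FALSE }
  }
  art_rows <- which(need_art)
  nart <- length(art_rows)
  if (nart) {
    Ar <- matrix(0, m, nart)
    Ar[cbind(art_rows, seq_len(nart))] <- 1
    Tm <- cbind(Tm, Ar)
    basis[art_rows] <- ncol0 + seq_len(nart)
  }

  run_simplex <- function(Tm, b, basis, cvec, maxit) {
    nc <- ncol(Tm)
    for (it in seq_len(maxit)) {
      cb <- cvec[basis]
      red <- cvec - as.vector(crossprod(matrix(cb, ncol = 1), Tm))
      red[basis] <- 0
      cand <- which(red < -LP_TOL_PIVOT)
      if (!length(cand)) {
        return(list(status = "optimal", Tm = Tm, b = b, basis = basis))
      }
      e <- cand[1L]  # Bland: smallest index enters
      col <- Tm[, e]
      pos <- which(col > LP_TOL_PIVOT)
      if (!length(pos)) return(list(status = "unbounded"))
      ratio <- b[pos] / col[pos]
      rmin <- min(ratio)
      tie <- pos[ratio <= rmin + LP_TOL_PIVOT]
      r <- tie[which.min(basis[tie])]  # Bland: smallest basic index leaves
      piv <- Tm[r, e]
      Tm[r, ] <- Tm[r, ] / piv
      b[r] <- b[r] / piv
      other <- setdiff(seq_len(nrow(Tm)), r)
      f <- Tm[other, e]
      Tm[other, ] <- Tm[other, , drop = FALSE] - tcrossprod(f, Tm[r, ])
      b[other] <- b[other] - f * b[r]
      b[b < 0 & b > -LP_TOL_PIVOT] <- 0
      basis[r] <- e
    }
    list(status = "iteration_limit")
  }

  maxit <- 2000L + 200L * (m + ncol(Tm))

  if (nart) {
    c1 <- c(rep(0, ncol0), rep(1, nart))
    ph1 <- run_simplex(Tm, b, basis, c1, maxit)
    if (ph1$status != "optimal") {
      return(list(status = if (ph1$status == "unbounded") "infeasible" else ph1$status))
    }
    Tm <- ph1$Tm; b <- ph1$b; basis <- ph1$basis
    if (sum(b[basis > ncol0]) > LP_TOL_FEAS) {
      return(list(status = "infeasible"))
    }
    ## drive remaining zero-level artificials out of the basis
    for (r in which(basis > ncol0)) {
      piv_cols <- which(abs(Tm[r, seq_len(ncol0)]) > LP_TOL_PIVOT)
      if (length(piv_cols)) {
        e <- piv_cols[1L]
        piv <- Tm[r, e]
        Tm[r, ] <- Tm[r, ] / piv; b[r] <- b[r] / piv
        other <- setdiff(seq_len(nrow(Tm)), r)
        f <- Tm[other, e]
        Tm[other, ] <- Tm[other, , drop = FALSE] - tcrossprod(f, Tm[r, ])
        b[other] <- b[other] - f * b[r]
        basis[r] <- e
      }
    }
    keep <- which(basis <= ncol0)
    Tm <- Tm[keep, seq_len(ncol0), drop = FALSE]  # drop redundant rows + art cols
    b <- b[keep]; basis <- basis[keep]
  }

  c2 <- c(cost, rep(0, nslack))
  ph2 <- run_simplex(Tm, b, basis, c2, maxit)
  if (ph2$status != "optimal") return(list(status = ph2$status))
  z <- numeric(ncol0)
  z[ph2$basis] <- ph2$b
  x <- z[seq_len(n)] + lb
  list(status = "optimal", x = x, objective = sum(obj * x))
}
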