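## Independent brute-force oracle: enumerate all vertices of the bounded
## polyhedron {x : A x = b, lb <= x <= ub} by basis enumeration, and
## optimize linear functions over them.  Exponential, only for tiny
## fixtures; deliberately shares no code with the package's simplex.

enumerate_vertices <- function(A, b, lb, ub, tol = 1e-7) {
  A <- as.matrix(A)
  n <- ncol(A)
  r <- qr(A)$rank
  nfree <- n - r
  verts <- list()
  basis_sets <- utils::combn(n, r, simplify = FALSE)
  for (B in basis_sets) {
    AB <- A[, B, drop = FALSE]
    if (qr(AB)$rank < r) next
    N <- setdiff(seq_len(n), B)
    for (mask in 0:(2^nfree - 1)) {
      at_ub <- bitwAnd(mask, 2^(seq_len(nfree) - 1)) > 0
      xN <- ifelse(at_ub, ub[N], lb[N])
      if (any(!is.finite(xN))) next
      rhs <- b - if (nfree) A[, N, drop = FALSE] %*% xN else 0
      xB <- tryCatch(qr.solve(AB, rhs), error = function(e) NULL)
      if (is.null(xB)) next
      x <- numeric(n)
      x[B] <- xB; x[N] <- xN
      if (max(abs(A %*% x - b)) > tol) next
      if (any(x < lb - tol) || any(x > ub + tol)) next
      verts[[length(verts) + 1]] <- pmin(pmax(x, lb), ub)
    }
  }
  if (!length(verts)) return(matrix(numeric(), 0, n))
  V <- do.call(rbind, verts)
  V[!duplicated(round(V, 6)), , drop = FALSE]
}

## max/min of c'x over the vertex set (valid for LPs over bounded polytopes)
oracle_optimum <- function(V, cc, maximize = TRUE) {
  if (!nrow(V)) return(NULL)
  vals <- as.vector(V %*% cc)
  if (maximize) max(vals) else min(vals)
}

## vertices of a model's steady-state polytope, with optional extra
## equality rows (rows over reaction fluxes) appended
model_vertices <- function(model, extra_A = NULL, extra_b = NULL,
                           lb = model$lb, ub = model$ub) {
  A <- model$S
  b <- rep(0, nrow(A))
  if (!is.null(extra_A)) {
    A <- rbind(A, extra_A)
    b <- c(b, extra_b)
  }
  enumerate_vertices(A, b, lb, ub)
}

unit_row <- function(model, rid) {
  r <- numeric(length(model$reaction_ids))
  r[match(rid, model$reaction_ids)] <- 1
  r
}

test_path_extdata <- function(f) {
  system.file("extdata", f, package = "dyncubeprod")
}

## small standard fixtures used across test files
toy_params <- function(...) {
  search_params(min_growth = 1, min_target = 1, ...)
}

random_fixture <- function(seed) {
  m <- 3 + seed %% 3
  generate_random_network(m, m + 4 + seed %% 3, seed)
}
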