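#' The seven-reaction demonstration network
#'
#' A minimal irreversible network with four internal metabolites (C1-C4) on
#' which every step of the subdivision search can be followed by hand:
#'
#' * `R1`: nutrient uptake, `-> C1`, flux pinned to 3 (bounds `[3, 3]`);
#' * `R2`: `C1 -> C2`;
#' * `R3`: `C1 -> C3`, the direct route to the growth precursor;
#' * `R4`: `C2 -> C4`;
#' * `R5`: `C4 -> C3`, the capacity-limited alternative route (bounds
#'   `[0, 1]`);
#' * `R6`: growth, `C3 ->`;
#' * `R7`: target-metabolite production, `C4 ->`.
#'
#' With no deletions, maximizing growth gives GR = 3 and no production.
#' Deleting `R3` re-routes all input through `R2`/`R4` so that growth (at
#' most 1, through `R5`) forces a production flux of 2: growth coupling.
#' Deleting both `R3` and `R5` yields PR = 3 but kills growth.  The
#' theoretical maxima of the three search axes are TMGR = 3, TMPR = 3 and
#' TMSF = 13 (with a minimum growth of 1).
#'
#' @return a [metabolic_model()] with roles `growth = "R6"`,
#'   `target = "R7"`.
#' @export
build_toy_network <- function() {
  mets <- c("C1", "C2", "C3", "C4")
  rxns <- paste0("R", 1:7)
  S <- matrix(0, 4, 7, dimnames = list(mets, rxns))
  S["C1", "R1"] <- 1
  S["C1", "R2"] <- -1; S["C2", "R2"] <- 1
  S["C1", "R3"] <- -1; S["C3", "R3"] <- 1
  S["C2", "R4"] <- -1; S["C4", "R4"] <- 1
  S["C4", "R5"] <- -1; S["C3", "R5"] <- 1
  S["C3", "R6"] <- -1
  S["C4", "R7"] <- -1
  lb <- c(3, 0, 0, 0, 0, 0, 0)
  ub <- c(3, 1000, 1000, 1000, 1, 1000, 1000)
  metabolic_model(mets, rxns, S, lb, ub,
                  roles = list(growth = "R6", target = "R7"))
}

#' Generate a random irreversible test network
#'
#' Draws a mass-balanced, fully irreversible network for property testing:
#' one pinned-input uptake reaction feeding the first metabolite, a chain of
#' unit conversions guaranteeing every internal metabolite at least one
#' producer and one consumer, a growth export on the last chain metabolite,
#' a target export on a random interior metabolite, and random extra
#' branch reactions.  A random subset of internal reactions gets a tight
#' capacity cap, which is what creates re-routing (and hence growth
#' coupling) opportunities.  By construction the chain guarantees a feasible
#' flux with positive growth; the generator nevertheless verifies this and
#' errors (reporting the seed) if an inconsistent draw survives.
#'
#' @param n_metabolites number of internal metabolites (>= 2).
#' @param n_reactions total reactions; must be at least
#'   `n_metabolites + 2` (uptake + chain + growth and target exports).
#' @param seed integer; the same seed always yields the identical model.
#'   The caller's RNG state is left untouched.
#' @param uptake_rate pinned input flux (default 10).
#' @return a [metabolic_model()] with roles `growth` and `target`.
#' @export
generate_random_network <- function(n_metabolites, n_reactions, seed,
                                    uptake_rate = 10) {
  if (n_reactions < n_metabolites + 2) {
    stop("n_reactions must be >= n_metabolites + 2", call. = FALSE)
  }
  if (n_metabolites < 2) stop("need at least 2 metabolites", call. = FALSE)
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(seed)

  m <- n_metabolites; n <- n_reactions
  mets <- sprintf("M%02d", seq_len(m))
  rxns <- sprintf("V%02d", seq_len(n))

  for (attempt in 1:50) {
    S <- matrix(0, m, n, dimnames = list(mets, rxns))
    lb <- rep(0, n); ub <- rep(1000, n)

    S[1, 1] <- 1                                 # uptake: -> M1, pinned
    lb[1] <- ub[1] <- uptake_rate
    for (i in seq_len(m - 1)) {                  # chain M_i -> M_{i+1}
      S[i, i + 1] <- -1; S[i + 1, i + 1] <- 1
    }
    S[m, m + 1] <- -1                            # growth export
    tmet <- if (m > 2) sample(2:(m - 1), 1) else 1
    S[tmet, m + 2] <- -1                         # target export
    if (n > m + 2) {
      for (j in (m + 3):n) {
        ab <- sample.int(m, 2)                   # random internal A -> B
        S[ab[1], j] <- -1; S[ab[2], j] <- 1
      }
    }
    ## tight caps on some internal (chain/branch) reactions create the
    ## re-routing bottlenecks growth coupling needs
    internal <- setdiff(seq_len(n), c(1, m + 1, m + 2))
    ncap <- max(1L, length(internal) %/% 3L)
    caps <- sample(internal, ncap)
    ub[caps] <- round(runif(ncap, 0.1, 1.2) * uptake_rate, 3)

    roles <- list(growth = rxns[m + 1], target = rxns[m + 2])
    model <- metabolic_model(mets, rxns, S, lb, ub, roles)

    fba <- solve_fba(model, roles$growth, "max")
    if (fba$status == "optimal" && fba$objective > 1e-9) {
      return(model)
    }
  }
  stop("no feasible random network within 50 attempts for seed ", seed,
       call. = FALSE)
}
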