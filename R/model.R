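#' Construct a constraint-based metabolic model
#'
#' A `metabolic_model` holds the stoichiometric matrix `S` (one row per
#' internal metabolite, one column per reaction), per-reaction flux bounds
#' `lb`/`ub` in mmol/gDW/h, and a `roles` list naming the special reactions
#' the knockout search needs: `growth` (biomass), `target` (product export),
#' and optionally `glucose_uptake`, `oxygen_uptake` and `atp_maintenance`.
#'
#' The steady-state assumption of flux balance analysis applies to every row
#' of `S`: any admissible flux vector `x` satisfies `S x = 0` and
#' `lb <= x <= ub`.  Exchange (boundary) reactions appear as columns with a
#' single nonzero entry; uptake is the negative flux direction of an
#' exchange reaction.
#'
#' @param metabolite_ids character vector of unique internal metabolite ids.
#' @param reaction_ids character vector of unique reaction ids.
#' @param S numeric matrix, `length(metabolite_ids)` x `length(reaction_ids)`.
#' @param lb,ub numeric flux bounds per reaction, `lb <= ub`.
#' @param roles named list mapping role names to reaction ids.
#' @return an object of class `metabolic_model`.
#' @examples
#' toy <- build_toy_network()
#' toy
#' @export
metabolic_model <- function(metabolite_ids, reaction_ids, S, lb, ub,
                            roles = list()) {
  metabolite_ids <- as.character(metabolite_ids)
  reaction_ids <- as.character(reaction_ids)
  S <- as.matrix(S)
  if (anyDuplicated(reaction_ids)) {
    stop("reaction ids must be unique", call. = FALSE)
  }
  if (anyDuplicated(metabolite_ids)) {
    stop("metabolite ids must be unique", call. = FALSE)
  }
  if (!all(dim(S) == c(length(metabolite_ids), length(reaction_ids)))) {
    stop("S must be length(metabolite_ids) x length(reaction_ids)",
         call. = FALSE)
  }
  lb <- as.numeric(lb); ub <- as.numeric(ub)
  if (length(lb) != ncol(S) || length(ub) != ncol(S)) {
    stop("lb and ub must have one entry per reaction", call. = FALSE)
  }
  if (any(lb > ub)) {
    bad <- reaction_ids[lb > ub][1]
    stop("lower bound exceeds upper bound for reaction ", bad, call. = FALSE)
  }
  iso <- which(rowSums(S != 0) == 0)
  if (length(iso)) {
    stop("isolated metabolite(s) with no reaction: ",
         paste(metabolite_ids[iso], collapse = ", "), call. = FALSE)
  }
  roles <- roles[!vapply(roles, is.null, logical(1))]
  for (r in names(roles)) {
    if (!roles[[r]] %in% reaction_ids) {
      stop("role '", r, "' maps to unknown reaction ", roles[[r]],
           call. = FALSE)
    }
  }
  dimnames(S) <- list(metabolite_ids, reaction_ids)
  names(lb) <- names(ub) <- reaction_ids
  structure(
    list(metabolite_ids = metabolite_ids, reaction_ids = reaction_ids,
         S = S, lb = lb, ub = ub, roles = roles),
    class = "metabolic_model"
  )
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("metabolic_model:", length(x$metabolite_ids), "metabolites,",
      length(x$reaction_ids), "reactions\n")
  if (length(x$roles)) {
    cat("roles:", paste(names(x$roles), unlist(x$roles), sep = "=",
                        collapse = ", "), "\n")
  }
  nrev <- sum(x$lb < 0)
  cat("reversible reactions:", nrev, "\n")
  invisible(x)
}

#' Medium condition for a growth experiment
#'
#' Bundles the three medium parameters of a glucose-limited simulation:
#' `gur` (maximum glucose uptake rate), `our` (maximum oxygen uptake rate;
#' 0 means anaerobic) and `ngam` (minimum non-growth-associated ATP
#' maintenance flux), all in mmol/gDW/h and all non-negative.
#'
#' @param gur,our,ngam non-negative finite rates.
#' @return an object of class `medium_condition`.
#' @export
medium_condition <- function(gur = 10, our = 1000, ngam = 3.15) {
  vals <- c(gur = gur, our = our, ngam = ngam)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("gur, our and ngam must be non-negative and finite", call. = FALSE)
  }
  structure(list(gur = gur, our = our, ngam = ngam),
            class = "medium_condition")
}

#' Apply medium bounds to a model
#'
#' Sets the glucose-uptake lower bound to `-gur`, the oxygen-uptake lower
#' bound to `-our` and the ATP-maintenance lower bound to `ngam` on the
#' reactions named by the model's roles.  Any missing role is skipped with a
#' warning; all other bounds are untouched.  Applying the same medium twice
#' is a no-op.
#'
#' @param model a [metabolic_model()].
#' @param medium a [medium_condition()].
#' @return the constrained model.
#' @export
apply_medium <- function(model, medium) {
  stopifnot(inherits(model, "metabolic_model"),
            inherits(medium, "medium_condition"))
  set_lb <- function(m, role, value) {
    rid <- m$roles[[role]]
    if (is.null(rid)) {
      warning("model has no '", role, "' role; medium bound skipped",
              call. = FALSE)
      return(m)
    }
    m$lb[[rid]] <- value
    m
  }
  model <- set_lb(model, "glucose_uptake", -medium$gur)
  model <- set_lb(model, "oxygen_uptake", -medium$our)
  model <- set_lb(model, "atp_maintenance", medium$ngam)
  if (any(model$lb > model$ub)) {
    bad <- model$reaction_ids[model$lb > model$ub][1]
    stop("medium bound exceeds upper bound for reaction ", bad, call. = FALSE)
  }
  model
}

#' Ensure a target metabolite has an export reaction
#'
#' Growth coupling is judged on the outgoing flux of the target metabolite.
#' If the metabolite already feeds an export/exchange reaction (a column
#' whose only nonzero entry is a negative coefficient on that metabolite),
#' that reaction simply becomes the `target` role.  Otherwise an auxiliary
#' irreversible export reaction with stoichiometry -1 and bounds
#' `[0, 1000]` is appended and made the target.  Existing coefficients and
#' bounds are never altered, and repeated calls add nothing.
#'
#' @param model a [metabolic_model()].
#' @param metabolite id of the metabolite to export.
#' @return the model with a `target` role set.
#' @export
add_target_exchange <- function(model, metabolite) {
  stopifnot(inherits(model, "metabolic_model"))
  mi <- match(metabolite, model$metabolite_ids)
  if (is.na(mi)) {
    stop("unknown metabolite id: ", metabolite, call. = FALSE)
  }
  ## existing pure-export column consuming only this metabolite?
  nz_per_col <- colSums(model$S != 0)
  cand <- which(nz_per_col == 1 & model$S[mi, ] < 0)
  if (length(cand)) {
    model$roles$target <- model$reaction_ids[cand[1L]]
    return(model)
  }
  new_id <- paste0("EX_", metabolite, "_export")
  if (new_id %in% model$reaction_ids) {
    new_id <- make.unique(c(model$reaction_ids, new_id))[length(model$reaction_ids) + 1]
  }
  col <- matrix(0, nrow(model$S), 1)
  col[mi, 1] <- -1
  roles <- model$roles
  roles$target <- new_id
  roles$auxiliary_exchange <- new_id
  metabolic_model(
    model$metabolite_ids,
    c(model$reaction_ids, new_id),
    cbind(model$S, col),
    c(model$lb, 0),
    c(model$ub, 1000),
    roles
  )
}

## role index helpers ------------------------------------------------------

role_index <- function(model, role, required = TRUE) {
  rid <- model$roles[[role]]
  if (is.null(rid)) {
    if (required) stop("model has no '", role, "' role", call. = FALSE)
    return(NA_integer_)
  }
  match(rid, model$reaction_ids)
}
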