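#' Read a constraint-based model from disk
#'
#' Supports three dialects: BiGG JSON (`"bigg_json"`, the format of models
#' distributed by the BiGG database such as iJO1366), SBML Level 3 with the
#' FBC package (`"sbml"`), and this package's own round-trip-exact JSON dump
#' (`"native_json"`, written by [write_model()]).  `format = "auto"` picks
#' by file extension (`.xml`/`.sbml` -> SBML, `.json` -> sniffed JSON).
#'
#' Role autodetection follows BiGG naming conventions: the reaction carrying
#' a nonzero objective coefficient (or an id containing "biomass", case
#' insensitive) becomes `growth`; `EX_glc__D_e`, `EX_o2_e` and `ATPM` become
#' `glucose_uptake`, `oxygen_uptake` and `atp_maintenance` when present.
#' Explicit roles stored in a native dump always win.
#'
#' @param path file path.
#' @param format one of `"auto"`, `"bigg_json"`, `"sbml"`, `"native_json"`.
#' @return a [metabolic_model()].
#' @export
read_model <- function(path, format = c("auto", "bigg_json", "sbml",
                                        "native_json")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("model file not found: ", path, call. = FALSE)
  }
  if (format == "auto") {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) {
      "sbml"
    } else {
      js <- tryCatch(jsonlite::read_json(path), error = function(e) {
        stop("cannot parse ", path, " as JSON: ", conditionMessage(e),
             call. = FALSE)
      })
      if (identical(js$format, "dyncubeprod-model")) "native_json" else "bigg_json"
    }
  }
  switch(format,
         bigg_json = read_bigg_json(path),
         sbml = read_sbml_fbc(path),
         native_json = read_native_json(path))
}

read_bigg_json <- function(path) {
  js <- tryCatch(jsonlite::read_json(path), error = function(e) {
    stop("cannot parse BiGG JSON ", path, ": ", conditionMessage(e),
         call. = FALSE)
  })
  if (is.null(js$reactions) || is.null(js$metabolites)) {
    stop("BiGG JSON ", path, " lacks a 'reactions' or 'metabolites' array",
         call. = FALSE)
  }
  met_ids <- vapply(js$metabolites, function(m) as.character(m$id), "")
  rxn_ids <- vapply(js$reactions, function(r) as.character(r$id), "")
  S <- matrix(0, length(met_ids), length(rxn_ids))
  lb <- numeric(length(rxn_ids)); ub <- numeric(length(rxn_ids))
  obj <- numeric(length(rxn_ids))
  for (j in seq_along(js$reactions)) {
    r <- js$reactions[[j]]
    if (is.null(r$lower_bound) || is.null(r$upper_bound)) {
      stop("reaction ", rxn_ids[j], " lacks bounds", call. = FALSE)
    }
    lb[j] <- as.numeric(r$lower_bound); ub[j] <- as.numeric(r$upper_bound)
    obj[j] <- if (is.null(r$objective_coefficient)) 0 else
      as.numeric(r$objective_coefficient)
    for (mid in names(r$metabolites)) {
      mi <- match(mid, met_ids)
      if (is.na(mi)) {
        stop("reaction ", rxn_ids[j], " references unknown metabolite ", mid,
             call. = FALSE)
      }
      S[mi, j] <- as.numeric(r$metabolites[[mid]])
    }
  }
  roles <- list()
  gi <- which(obj != 0)
  if (!length(gi)) gi <- grep("biomass", rxn_ids, ignore.case = TRUE)
  if (length(gi)) roles$growth <- rxn_ids[gi[1L]]
  if ("EX_glc__D_e" %in% rxn_ids) roles$glucose_uptake <- "EX_glc__D_e"
  if ("EX_o2_e" %in% rxn_ids) roles$oxygen_uptake <- "EX_o2_e"
  if ("ATPM" %in% rxn_ids) roles$atp_maintenance <- "ATPM"
  metabolic_model(met_ids, rxn_ids, S, lb, ub, roles)
}

read_sbml_fbc <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop("cannot parse SBML ", path, ": ", conditionMessage(e), call. = FALSE)
  })
  xml2::xml_ns_strip(doc)
  sp <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  if (!length(sp)) stop("SBML ", path, " has no species", call. = FALSE)
  boundary <- xml2::xml_attr(sp, "boundaryCondition") %in% "true"
  met_ids <- xml2::xml_attr(sp, "id")[!boundary]
  params <- xml2::xml_find_all(doc, ".//listOfParameters/parameter")
  pval <- as.numeric(xml2::xml_attr(params, "value"))
  names(pval) <- xml2::xml_attr(params, "id")
  rx <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  if (!length(rx)) stop("SBML ", path, " has no reactions", call. = FALSE)
  rxn_ids <- xml2::xml_attr(rx, "id")
  S <- matrix(0, length(met_ids), length(rx))
  lb <- numeric(length(rx)); ub <- numeric(length(rx))
  lookup_bound <- function(node, attr, fallback) {
    ref <- xml2::xml_attr(node, attr)
    if (!is.na(ref) && ref %in% names(pval)) return(pval[[ref]])
    fallback
  }
  for (j in seq_along(rx)) {
    rev_ok <- !identical(xml2::xml_attr(rx[[j]], "reversible"), "false")
    lb[j] <- lookup_bound(rx[[j]], "lowerFluxBound", if (rev_ok) -1000 else 0)
    ub[j] <- lookup_bound(rx[[j]], "upperFluxBound", 1000)
    for (side in c(-1, 1)) {
      tag <- if (side < 0) "listOfReactants" else "listOfProducts"
      refs <- xml2::xml_find_all(rx[[j]], paste0("./", tag, "/speciesReference"))
      for (ref in refs) {
        mid <- xml2::xml_attr(ref, "species")
        st <- xml2::xml_attr(ref, "stoichiometry")
        st <- if (is.na(st)) 1 else as.numeric(st)
        mi <- match(mid, met_ids)
        if (!is.na(mi)) S[mi, j] <- S[mi, j] + side * st
      }
    }
  }
  roles <- list()
  fluxobj <- xml2::xml_find_first(doc, ".//*[local-name()='fluxObjective']")
  if (!inherits(fluxobj, "xml_missing") &&
      xml2::xml_attr(fluxobj, "reaction") %in% rxn_ids) {
    roles$growth <- xml2::xml_attr(fluxobj, "reaction")
  } else {
    gi <- grep("biomass", rxn_ids, ignore.case = TRUE)
    if (length(gi)) roles$growth <- rxn_ids[gi[1L]]
  }
  if ("EX_glc__D_e" %in% rxn_ids) roles$glucose_uptake <- "EX_glc__D_e"
  if ("EX_o2_e" %in% rxn_ids) roles$oxygen_uptake <- "EX_o2_e"
  if ("ATPM" %in% rxn_ids) roles$atp_maintenance <- "ATPM"
  metabolic_model(met_ids, rxn_ids, S, lb, ub, roles)
}

read_native_json <- function(path) {
  js <- tryCatch(jsonlite::read_json(path), error = function(e) {
    stop("cannot parse model JSON ", path, ": ", conditionMessage(e),
         call. = FALSE)
  })
  if (!identical(js$format, "dyncubeprod-model")) {
    stop(path, " is not a dyncubeprod native model dump", call. = FALSE)
  }
  met_ids <- unlist(js$metabolites)
  rxn_ids <- vapply(js$reactions, function(r) as.character(r$id), "")
  S <- matrix(0, length(met_ids), length(rxn_ids))
  lb <- numeric(length(rxn_ids)); ub <- numeric(length(rxn_ids))
  for (j in seq_along(js$reactions)) {
    r <- js$reactions[[j]]
    lb[j] <- as.numeric(r$lower_bound); ub[j] <- as.numeric(r$upper_bound)
    for (mid in names(r$metabolites)) {
      S[match(mid, met_ids), j] <- as.numeric(r$metabolites[[mid]])
    }
  }
  metabolic_model(met_ids, rxn_ids, S, lb, ub, lapply(js$roles, as.character))
}

#' Write a model as a native JSON dump
#'
#' The dump round-trips exactly: [read_model()] with
#' `format = "native_json"` restores `S`, `lb`, `ub` and the roles
#' bit-for-bit (doubles are serialized at full precision).
#'
#' @param model a [metabolic_model()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "metabolic_model"))
  rxns <- lapply(seq_along(model$reaction_ids), function(j) {
    nz <- which(model$S[, j] != 0)
    mets <- as.list(model$S[nz, j])
    names(mets) <- model$metabolite_ids[nz]
    list(id = model$reaction_ids[j],
         metabolites = mets,
         lower_bound = model$lb[[j]],
         upper_bound = model$ub[[j]])
  })
  obj <- list(format = "dyncubeprod-model", version = 1L,
              metabolites = model$metabolite_ids,
              reactions = rxns,
              roles = model$roles)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
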