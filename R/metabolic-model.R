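#' Stoichiometric metabolic models
#'
#' A `metabolic_model` holds a metabolite x reaction stoichiometric
#' matrix, per-reaction reversibility and pathway annotations, and the
#' identifier of the proliferation (growth) objective reaction.
#'
#' @param stoichiometry numeric metabolite x reaction matrix with row and
#'   column names.
#' @param reactions tibble with columns `id`, `reversible` (logical),
#'   `pathway` (character), one row per column of `stoichiometry`, same
#'   order.
#' @param objective reaction id of the proliferation objective.
#' @return an object of class `metabolic_model`.
#' @export
metabolic_model <- function(stoichiometry, reactions, objective) {
  reactions <- as_tibble(reactions)
  stopifnot(is.matrix(stoichiometry), is.numeric(stoichiometry))
  if (is.null(rownames(stoichiometry)) || is.null(colnames(stoichiometry))) {
    abort("stoichiometry needs metabolite rownames and reaction colnames.")
  }
  if (!identical(colnames(stoichiometry), reactions$id)) {
    abort("`reactions$id` must match the stoichiometry columns in order.")
  }
  if (!objective %in% reactions$id) {
    abort(sprintf("objective reaction '%s' is not in the model.", objective))
  }
  structure(list(stoichiometry = stoichiometry, reactions = reactions,
                 objective = objective),
            class = "metabolic_model")
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf(paste0("<metabolic_model> %d metabolites x %d reactions ",
                     "(%d reversible), objective '%s', %d pathway(s)\n"),
              nrow(x$stoichiometry), ncol(x$stoichiometry),
              sum(x$reactions$reversible), x$objective,
              length(unique(x$reactions$pathway))))
  invisible(x)
}

#' Remove reactions from a model
#'
#' Drops the given reaction columns (and any metabolites left orphaned).
#' The objective reaction cannot be removed.
#'
#' @param model a `metabolic_model`.
#' @param reaction_ids character vector of reactions to drop.
#' @return the reduced `metabolic_model`.
#' @export
remove_reactions <- function(model, reaction_ids) {
  if (length(reaction_ids) == 0L) return(model)
  if (model$objective %in% reaction_ids) {
    abort("the proliferation objective reaction cannot be removed.")
  }
  keep <- !model$reactions$id %in% reaction_ids
  S <- model$stoichiometry[, keep, drop = FALSE]
  used <- rowSums(S != 0) > 0
  metabolic_model(S[used, , drop = FALSE],
                  model$reactions[keep, , drop = FALSE],
                  model$objective)
}

#' Split reversible reactions into irreversible halves
#'
#' Every reversible reaction becomes a forward column (unchanged
#' stoichiometry) and a backward column (negated stoichiometry, id suffix
#' `_rev`); irreversible reactions pass through. All fluxes of the result
#' are constrained non-negative by the solver.
#'
#' @param model a `metabolic_model`.
#' @return an object of class `irreversible_model` with fields
#'   `stoichiometry`, `reaction_ids`, `proliferation_reaction`,
#'   `pathway_map` (named character) and `reverse_of` (named character
#'   linking each backward half to its forward half).
#' @export
to_irreversible <- function(model) {
  if (!inherits(model, "metabolic_model")) {
    abort("`model` must be a metabolic_model.")
  }
  S <- model$stoichiometry
  rx <- model$reactions
  cols <- list()
  pathway <- character(0)
  reverse_of <- character(0)
  for (i in seq_len(nrow(rx))) {
    id <- rx$id[i]
    cols[[id]] <- S[, i]
    pathway[id] <- rx$pathway[i]
    if (isTRUE(rx$reversible[i])) {
      rid <- paste0(id, "_rev")
      cols[[rid]] <- -S[, i]
      pathway[rid] <- rx$pathway[i]
      reverse_of[rid] <- id
    }
  }
  Sirr <- do.call(cbind, cols)
  colnames(Sirr) <- names(cols)
  structure(list(
    stoichiometry = Sirr,
    reaction_ids = colnames(Sirr),
    proliferation_reaction = model$objective,
    pathway_map = pathway,
    reverse_of = reverse_of
  ), class = "irreversible_model")
}

#' @export
print.irreversible_model <- function(x, ...) {
  cat(sprintf(paste0("<irreversible_model> %d metabolites x %d ",
                     "non-negative reactions, proliferation '%s'\n"),
              nrow(x$stoichiometry), ncol(x$stoichiometry),
              x$proliferation_reaction))
  invisible(x)
}

#' Read / write the JSON model dialect
#'
#' The dialect is
#' `{"metabolites": [...], "reactions": [{"id", "stoich": {met: coef},
#' "reversible", "pathway"}], "objective": "..."}`.
#' Round-trips preserve metabolite and reaction order.
#'
#' @param path file path.
#' @return `read_model_json()` returns a `metabolic_model`.
#' @export
read_model_json <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (file.size(path) == 0L) abort(sprintf("empty model file: %s", path))
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$reactions) || is.null(doc$objective)) {
    abort(sprintf("%s: model needs 'reactions' and 'objective'.", path))
  }
  mets <- unlist(doc$metabolites)
  rids <- vapply(doc$reactions, function(r) r$id, "")
  S <- matrix(0, nrow = length(mets), ncol = length(rids),
              dimnames = list(mets, rids))
  for (r in doc$reactions) {
    st <- unlist(r$stoich)
    unknown <- setdiff(names(st), mets)
    if (length(unknown) > 0L) {
      abort(sprintf("%s: reaction '%s' references unknown metabolite(s): %s",
                    path, r$id, paste(unknown, collapse = ", ")))
    }
    S[names(st), r$id] <- st
  }
  metabolic_model(
    S,
    tibble(id = rids,
           reversible = vapply(doc$reactions,
                               function(r) isTRUE(r$reversible), NA),
           pathway = vapply(doc$reactions,
                            function(r) r$pathway %||% "unassigned", "")),
    doc$objective
  )
}

#' @rdname read_model_json
#' @param model a `metabolic_model` to write.
#' @export
write_model_json <- function(model, path) {
  S <- model$stoichiometry
  rx <- model$reactions
  reactions <- lapply(seq_len(nrow(rx)), function(i) {
    st <- S[, i]
    st <- st[st != 0]
    list(id = rx$id[i], stoich = as.list(st),
         reversible = rx$reversible[i], pathway = rx$pathway[i])
  })
  jsonlite::write_json(
    list(metabolites = rownames(S), reactions = reactions,
         objective = model$objective),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an SBML Level-3 model
#'
#' Minimal reader for SBML L3 core plus the `fbc` package: species,
#' reactions with `speciesReference` stoichiometries, the `reversible`
#' attribute, and the active flux objective (which identifies the
#' proliferation reaction). Pathway annotations are taken from a
#' `<notes>` line of the form `pathway: NAME` inside each reaction, or
#' default to `"unassigned"`.
#'
#' @param path path to an SBML file.
#' @return a `metabolic_model`.
#' @export
read_model_sbml <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  doc <- xml2::read_xml(path)
  ns <- c(s = "http://www.sbml.org/sbml/level3/version1/core",
          fbc = "http://www.sbml.org/sbml/level3/version1/fbc/version2")
  species <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  mets <- xml2::xml_attr(species, "id")
  rxn_nodes <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  if (length(rxn_nodes) == 0L) abort(sprintf("%s: no reactions found.", path))
  rids <- xml2::xml_attr(rxn_nodes, "id")
  S <- matrix(0, nrow = length(mets), ncol = length(rids),
              dimnames = list(mets, rids))
  pathway <- character(length(rids))
  reversible <- logical(length(rids))
  for (i in seq_along(rxn_nodes)) {
    node <- rxn_nodes[[i]]
    reversible[i] <- identical(xml2::xml_attr(node, "reversible"), "true")
    for (ref in xml2::xml_find_all(
           node, "./s:listOfReactants/s:speciesReference", ns)) {
      sp <- xml2::xml_attr(ref, "species")
      st <- as.numeric(xml2::xml_attr(ref, "stoichiometry") %||% "1")
      S[sp, i] <- S[sp, i] - st
    }
    for (ref in xml2::xml_find_all(
           node, "./s:listOfProducts/s:speciesReference", ns)) {
      sp <- xml2::xml_attr(ref, "species")
      st <- as.numeric(xml2::xml_attr(ref, "stoichiometry") %||% "1")
      S[sp, i] <- S[sp, i] + st
    }
    notes <- xml2::xml_text(xml2::xml_find_first(node, "./s:notes", ns))
    m <- regmatches(notes, regexpr("pathway:\\s*\\S+", notes))
    pathway[i] <- if (length(m) == 1L && !is.na(m)) {
      sub("pathway:\\s*", "", m)
    } else {
      "unassigned"
    }
  }
  obj <- xml2::xml_find_first(
    doc, ".//fbc:listOfObjectives/fbc:objective/fbc:listOfFluxObjectives/fbc:fluxObjective",
    ns)
  if (inherits(obj, "xml_missing")) {
    abort(sprintf("%s: no fbc flux objective found.", path))
  }
  metabolic_model(S, tibble(id = rids, reversible = reversible,
                            pathway = pathway),
                  xml2::xml_attr(obj, "reaction"))
}
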