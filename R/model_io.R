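## Model serialization: COBRA-style JSON and SBML Level 3 core.

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
IVM_NS  <- "https://invivomca.r-lib/ns/model"

.model_to_list <- function(model) {
  list(
    id = model$id, name = model$name,
    metabolites = lapply(seq_len(nrow(model$metabolites)), function(i) {
      m <- model$metabolites[i, ]
      out <- list(id = m$id, name = m$name, internal = m$internal,
                  carbon = m$carbon)
      if (!is.na(m$formula)) out$formula <- m$formula
      if (!is.na(m$dG_f)) out$dG_f <- m$dG_f
      out
    }),
    reactions = lapply(unname(model$reactions), function(r) {
      out <- list(id = r$id, name = r$name,
                  stoichiometry = as.list(r$stoichiometry),
                  reversible = r$reversible, lb = r$lb, ub = r$ub,
                  pseudo = r$pseudo)
      if (!is.na(r$dG0)) out$dG0 <- r$dG0
      out
    })
  )
}

.model_from_list <- function(x) {
  mets <- do.call(rbind, lapply(x$metabolites, function(m)
    metabolite_spec(m$id, m$name %||% m$id,
                    internal = isTRUE(m$internal),
                    carbon = m$carbon %||% 0L,
                    formula = m$formula %||% NA_character_,
                    dG_f = m$dG_f %||% NA_real_)))
  rxns <- lapply(x$reactions, function(r)
    reaction_spec(r$id, unlist(r$stoichiometry), name = r$name %||% r$id,
                  reversible = isTRUE(r$reversible),
                  lb = r$lb %||% if (isTRUE(r$reversible)) -1000 else 0,
                  ub = r$ub %||% 1000,
                  dG0 = r$dG0 %||% NA_real_,
                  pseudo = isTRUE(r$pseudo)))
  metabolic_model(mets, rxns, id = x$id %||% "model", name = x$name %||% x$id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a model to JSON or SBML
#'
#' @param model A `metabolic_model`.
#' @param path Output file path.
#' @param format `"json"` or `"sbml"` (inferred from the file extension when
#'   missing).
#' @return Invisibly `path`.
#' @export
write_model <- function(model, path, format = c("auto", "json", "sbml")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml" else "json"
  if (format == "json") {
    jsonlite::write_json(.model_to_list(model), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  } else {
    .write_sbml(model, path)
  }
  invisible(path)
}

#' Read a model from JSON or SBML
#'
#' Round-trips losslessly with [write_model()] for all fields.
#'
#' @param path Input file path.
#' @param format `"json"` or `"sbml"` (inferred by default).
#' @return A `metabolic_model`.
#' @export
read_model <- function(path, format = c("auto", "json", "sbml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml" else "json"
  if (format == "json") {
    x <- tryCatch(jsonlite::read_json(path),
                  error = function(e) stop("cannot parse JSON model '", path,
                                           "': ", conditionMessage(e)))
    .model_from_list(x)
  } else {
    .read_sbml(path)
  }
}

## valid SBML SId: letters, digits, underscore, not starting with a digit
.sid <- function(id) {
  s <- gsub("[^A-Za-z0-9_]", "_", id)
  ifelse(grepl("^[0-9]", s), paste0("M_", s), s)
}

.write_sbml <- function(model, path) {
  doc <- xml2::xml_new_root("sbml", xmlns = SBML_NS,
                            "xmlns:ivm" = IVM_NS,
                            level = "3", version = "1")
  mdl <- xml2::xml_add_child(doc, "model", id = .sid(model$id),
                             name = model$name)
  xml2::xml_set_attr(mdl, "ivm:id", model$id)
  comps <- xml2::xml_add_child(mdl, "listOfCompartments")
  xml2::xml_add_child(comps, "compartment", id = "c", constant = "true")
  xml2::xml_add_child(comps, "compartment", id = "e", constant = "true")
  sp <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (i in seq_len(nrow(model$metabolites))) {
    m <- model$metabolites[i, ]
    node <- xml2::xml_add_child(
      sp, "species", id = .sid(m$id), name = m$name,
      compartment = if (m$internal) "c" else "e",
      hasOnlySubstanceUnits = "false",
      boundaryCondition = if (m$internal) "false" else "true",
      constant = "false")
    xml2::xml_set_attr(node, "ivm:id", m$id)
    xml2::xml_set_attr(node, "ivm:carbon", as.character(m$carbon))
    if (!is.na(m$formula)) xml2::xml_set_attr(node, "ivm:formula", m$formula)
    if (!is.na(m$dG_f)) xml2::xml_set_attr(node, "ivm:dGf", format(m$dG_f, digits = 17))
  }
  rx <- xml2::xml_add_child(mdl, "listOfReactions")
  for (r in model$reactions) {
    node <- xml2::xml_add_child(rx, "reaction", id = .sid(r$id), name = r$name,
                                reversible = tolower(as.character(r$reversible)),
                                fast = "false")
    xml2::xml_set_attr(node, "ivm:id", r$id)
    xml2::xml_set_attr(node, "ivm:lb", format(r$lb, digits = 17))
    xml2::xml_set_attr(node, "ivm:ub", format(r$ub, digits = 17))
    xml2::xml_set_attr(node, "ivm:pseudo", tolower(as.character(r$pseudo)))
    if (!is.na(r$dG0)) xml2::xml_set_attr(node, "ivm:dG0", format(r$dG0, digits = 17))
    s <- r$stoichiometry
    subs <- s[s < 0]; prods <- s[s > 0]
    if (length(subs)) {
      lo <- xml2::xml_add_child(node, "listOfReactants")
      for (j in seq_along(subs)) {
        ref <- xml2::xml_add_child(lo, "speciesReference",
                                   species = .sid(names(subs)[j]),
                                   stoichiometry = format(-subs[j], digits = 17),
                                   constant = "true")
        xml2::xml_set_attr(ref, "ivm:species", names(subs)[j])
      }
    }
    if (length(prods)) {
      lo <- xml2::xml_add_child(node, "listOfProducts")
      for (j in seq_along(prods)) {
        ref <- xml2::xml_add_child(lo, "speciesReference",
                                   species = .sid(names(prods)[j]),
                                   stoichiometry = format(prods[j], digits = 17),
                                   constant = "true")
        xml2::xml_set_attr(ref, "ivm:species", names(prods)[j])
      }
    }
  }
  xml2::write_xml(doc, path)
}

.read_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("cannot parse SBML '", path, "': ",
                                           conditionMessage(e)))
  ns <- c(s = SBML_NS, ivm = IVM_NS)
  mdl <- xml2::xml_find_first(doc, ".//s:model", ns)
  if (inherits(mdl, "xml_missing")) stop("no <model> element in ", path)
  att <- function(node, a, default = NA_character_) {
    v <- xml2::xml_attr(node, a, ns = ns)
    if (is.na(v)) default else v
  }
  sp_nodes <- xml2::xml_find_all(mdl, ".//s:listOfSpecies/s:species", ns)
  mets <- do.call(rbind, lapply(sp_nodes, function(n) {
    metabolite_spec(
      id = att(n, "ivm:id", xml2::xml_attr(n, "id")),
      name = att(n, "name", ""),
      internal = !identical(xml2::xml_attr(n, "boundaryCondition"), "true"),
      carbon = as.integer(att(n, "ivm:carbon", "0")),
      formula = att(n, "ivm:formula"),
      dG_f = as.numeric(att(n, "ivm:dGf")))
  }))
  rx_nodes <- xml2::xml_find_all(mdl, ".//s:listOfReactions/s:reaction", ns)
  rxns <- lapply(rx_nodes, function(n) {
    refs <- function(tag, sign) {
      nodes <- xml2::xml_find_all(n, paste0("./s:", tag, "/s:speciesReference"), ns)
      if (!length(nodes)) return(numeric(0))
      stats::setNames(
        sign * as.numeric(xml2::xml_attr(nodes, "stoichiometry")),
        vapply(nodes, function(x) att(x, "ivm:species", xml2::xml_attr(x, "species")),
               character(1)))
    }
    s <- c(refs("listOfReactants", -1), refs("listOfProducts", +1))
    reaction_spec(
      id = att(n, "ivm:id", xml2::xml_attr(n, "id")),
      stoichiometry = s,
      name = att(n, "name", ""),
      reversible = identical(xml2::xml_attr(n, "reversible"), "true"),
      lb = as.numeric(att(n, "ivm:lb", "0")),
      ub = as.numeric(att(n, "ivm:ub", "1000")),
      dG0 = as.numeric(att(n, "ivm:dG0")),
      pseudo = identical(att(n, "ivm:pseudo"), "true"))
  })
  metabolic_model(mets, rxns,
                  id = att(mdl, "ivm:id", xml2::xml_attr(mdl, "id")),
                  name = att(mdl, "name", ""))
}
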