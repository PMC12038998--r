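## -------------------------------------------------------------------------
## Reduced stoichiometric model of E. coli central carbon metabolism and
## L-cysteine biosynthesis: construction, validation, serialization.
## -------------------------------------------------------------------------

#' Species clamped (treated as external) by default
#'
#' Currency metabolites and cofactor pairs are clamped in reduced-model MCA:
#' their concentrations are treated as fixed boundary parameters rather than
#' balanced state variables. This avoids spurious conserved moieties
#' (e.g. ATP + ADP + AMP) dominating the network Jacobian. The designation is
#' a plain character vector so it can be overridden per analysis.
#'
#' @return Character vector of metabolite ids.
#' @export
default_clamped_species <- function() {
  c("atp", "adp", "amp", "nad", "nadh", "nadp", "nadph",
    "q8", "q8h2", "pi", "ppi", "co2", "h2s", "so3", "tsul", "glu")
}

#' Create a metabolite specification
#'
#' @param id Short identifier (BiGG-style).
#' @param name Human-readable name.
#' @param internal Logical; is the species mass-balanced at steady state?
#' @param carbon Number of carbon atoms tracked for carbon balancing
#'   (acyl-carrier and nicotinamide/quinone backbone carbons are not tracked;
#'   adenine nucleotides count 10 so that ATP-consuming reactions balance).
#' @param formula Optional elemental formula.
#' @param dG_f Optional standard Gibbs energy of formation, kJ/mol.
#' @return A one-row data.frame.
#' @export
metabolite_spec <- function(id, name = id, internal = TRUE, carbon = 0L,
                            formula = NA_character_, dG_f = NA_real_) {
  stopifnot(is.character(id), length(id) == 1L, nchar(id) > 0L, carbon >= 0)
  data.frame(id = id, name = name, internal = as.logical(internal),
             carbon = as.integer(carbon), formula = formula, dG_f = dG_f,
             stringsAsFactors = FALSE)
}

#' Create a reaction specification
#'
#' @param id Short identifier.
#' @param stoichiometry Named numeric vector, metabolite id -> signed
#'   coefficient (reactants negative, products positive). All coefficients
#'   must be nonzero.
#' @param name Enzyme name.
#' @param reversible Logical. Irreversible reactions get `lb = 0`.
#' @param lb,ub Flux bounds, mmol/g/h.
#' @param dG0 Optional standard transformed Gibbs reaction energy, kJ/mol.
#' @param pseudo Logical; lumped/transport pseudo-reactions exempt from the
#'   elemental carbon-balance invariant.
#' @return A list of class `reaction_spec`.
#' @export
reaction_spec <- function(id, stoichiometry, name = id, reversible = FALSE,
                          lb = if (reversible) -1000 else 0, ub = 1000,
                          dG0 = NA_real_, pseudo = FALSE) {
  stopifnot(is.character(id), length(id) == 1L, nchar(id) > 0L)
  stoichiometry <- unlist(stoichiometry)
  if (is.null(names(stoichiometry)) || any(names(stoichiometry) == ""))
    stop("stoichiometry must be a named vector of coefficients")
  if (any(stoichiometry == 0))
    stop("stoichiometric coefficients must be nonzero in reaction ", id)
  if (lb > ub) stop("reaction ", id, ": lower bound exceeds upper bound")
  structure(list(id = id, name = name,
                 stoichiometry = stoichiometry,
                 reversible = isTRUE(reversible),
                 lb = as.numeric(lb), ub = as.numeric(ub),
                 dG0 = as.numeric(dG0), pseudo = isTRUE(pseudo)),
            class = "reaction_spec")
}

#' Assemble a metabolic model
#'
#' @param metabolites data.frame of metabolite specs (rbind of
#'   [metabolite_spec()] rows).
#' @param reactions List of [reaction_spec()] objects.
#' @param id,name Model identifier and name.
#' @return Object of class `metabolic_model`.
#' @export
metabolic_model <- function(metabolites, reactions, id = "model", name = id) {
  if (anyDuplicated(metabolites$id))
    stop("duplicate metabolite ids: ",
         paste(unique(metabolites$id[duplicated(metabolites$id)]), collapse = ", "))
  rids <- vapply(reactions, `[[`, character(1), "id")
  if (anyDuplicated(rids))
    stop("duplicate reaction ids: ",
         paste(unique(rids[duplicated(rids)]), collapse = ", "))
  names(reactions) <- rids
  for (r in reactions) {
    missing <- setdiff(names(r$stoichiometry), metabolites$id)
    if (length(missing))
      stop("reaction ", r$id, " references unknown metabolites: ",
           paste(missing, collapse = ", "))
  }
  structure(list(id = id, name = name, metabolites = metabolites,
                 reactions = reactions),
            class = "metabolic_model")
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> ", x$id, ": ",
      length(x$reactions), " reactions, ",
      nrow(x$metabolites), " species (",
      sum(x$metabolites$internal), " internal)\n", sep = "")
  invisible(x)
}

#' Reaction ids of a model
#' @param model A `metabolic_model`.
#' @return Character vector.
#' @export
reaction_ids <- function(model) names(model$reactions)

#' Metabolite ids of a model
#' @param model A `metabolic_model`.
#' @param internal_only Restrict to mass-balanced species.
#' @return Character vector.
#' @export
metabolite_ids <- function(model, internal_only = FALSE) {
  if (internal_only) model$metabolites$id[model$metabolites$internal]
  else model$metabolites$id
}

## metabolite table of the reduced model: id, name, carbon
.reduced_metabolites <- function() {
  m <- rbind(
    metabolite_spec("glc_e",  "D-glucose (ext)",            FALSE, 6),
    metabolite_spec("g6p",    "glucose 6-phosphate",        TRUE,  6),
    metabolite_spec("f6p",    "fructose 6-phosphate",       TRUE,  6),
    metabolite_spec("fdp",    "fructose 1,6-bisphosphate",  TRUE,  6),
    metabolite_spec("dhap",   "dihydroxyacetone phosphate", TRUE,  3),
    metabolite_spec("gap",    "glyceraldehyde 3-phosphate", TRUE,  3),
    metabolite_spec("13dpg",  "1,3-bisphosphoglycerate",    TRUE,  3),
    metabolite_spec("3pg",    "3-phosphoglycerate",         TRUE,  3),
    metabolite_spec("2pg",    "2-phosphoglycerate",         TRUE,  3),
    metabolite_spec("pep",    "phosphoenolpyruvate",        TRUE,  3),
    metabolite_spec("pyr",    "pyruvate",                   TRUE,  3),
    metabolite_spec("accoa",  "acetyl-CoA",                 TRUE,  2),
    metabolite_spec("oaa",    "oxaloacetate",               TRUE,  4),
    metabolite_spec("cit",    "citrate",                    TRUE,  6),
    metabolite_spec("icit",   "isocitrate",                 TRUE,  6),
    metabolite_spec("akg",    "2-oxoglutarate",             TRUE,  5),
    metabolite_spec("succoa", "succinyl-CoA",               TRUE,  4),
    metabolite_spec("succ",   "succinate",                  TRUE,  4),
    metabolite_spec("fum",    "fumarate",                   TRUE,  4),
    metabolite_spec("mal",    "L-malate",                   TRUE,  4),
    metabolite_spec("6pgc",   "6-phosphogluconate",         TRUE,  6),
    metabolite_spec("ru5p",   "ribulose 5-phosphate",       TRUE,  5),
    metabolite_spec("xu5p",   "xylulose 5-phosphate",       TRUE,  5),
    metabolite_spec("r5p",    "ribose 5-phosphate",         TRUE,  5),
    metabolite_spec("s7p",    "sedoheptulose 7-phosphate",  TRUE,  7),
    metabolite_spec("e4p",    "erythrose 4-phosphate",      TRUE,  4),
    metabolite_spec("3php",   "3-phosphohydroxypyruvate",   TRUE,  3),
    metabolite_spec("pser",   "phosphoserine",              TRUE,  3),
    metabolite_spec("ser",    "L-serine",                   TRUE,  3),
    metabolite_spec("oas",    "O-acetylserine",             TRUE,  5),
    metabolite_spec("cys",    "L-cysteine",                 TRUE,  3),
    metabolite_spec("slcys",  "S-sulfo-L-cysteine",         TRUE,  3),
    metabolite_spec("ac",     "acetate",                    TRUE,  2),
    metabolite_spec("coa",    "coenzyme A",                 TRUE,  0),
    metabolite_spec("oas_e",  "O-acetylserine (ext)",       FALSE, 5),
    metabolite_spec("cys_e",  "L-cysteine (ext)",           FALSE, 3),
    metabolite_spec("h2o",    "water",                      FALSE, 0),
    metabolite_spec("atp",    "ATP",                        FALSE, 10),
    metabolite_spec("adp",    "ADP",                        FALSE, 10),
    metabolite_spec("amp",    "AMP",                        FALSE, 10),
    metabolite_spec("nad",    "NAD+",                       FALSE, 0),
    metabolite_spec("nadh",   "NADH",                       FALSE, 0),
    metabolite_spec("nadp",   "NADP+",                      FALSE, 0),
    metabolite_spec("nadph",  "NADPH",                      FALSE, 0),
    metabolite_spec("q8",     "ubiquinone-8",               FALSE, 0),
    metabolite_spec("q8h2",   "ubiquinol-8",                FALSE, 0),
    metabolite_spec("pi",     "orthophosphate",             FALSE, 0),
    metabolite_spec("ppi",    "pyrophosphate",              FALSE, 0),
    metabolite_spec("co2",    "carbon dioxide",             FALSE, 1),
    metabolite_spec("h2s",    "hydrogen sulfide",           FALSE, 0),
    metabolite_spec("so3",    "sulfite",                    FALSE, 0),
    metabolite_spec("tsul",   "thiosulfate",                FALSE, 0),
    metabolite_spec("glu",    "L-glutamate",                FALSE, 5)
  )
  m
}

.reduced_reactions <- function(split_exporter = FALSE) {
  r <- list(
    reaction_spec("PTS",    c(glc_e = -1, pep = -1, g6p = 1, pyr = 1),
                  "glucose phosphotransferase system"),
    reaction_spec("PGI",    c(g6p = -1, f6p = 1),
                  "glucose 6-phosphate isomerase"),
    reaction_spec("PFK",    c(f6p = -1, atp = -1, fdp = 1, adp = 1),
                  "phosphofructokinase"),
    reaction_spec("FBA",    c(fdp = -1, dhap = 1, gap = 1),
                  "fructose-bisphosphate aldolase"),
    reaction_spec("TPI",    c(dhap = -1, gap = 1),
                  "triose-phosphate isomerase"),
    reaction_spec("GAPD",   c(gap = -1, nad = -1, pi = -1, `13dpg` = 1, nadh = 1),
                  "glyceraldehyde 3-phosphate dehydrogenase"),
    reaction_spec("PGK",    c(`13dpg` = -1, adp = -1, `3pg` = 1, atp = 1),
                  "phosphoglycerate kinase"),
    reaction_spec("PGM",    c(`3pg` = -1, `2pg` = 1),
                  "phosphoglycerate mutase"),
    reaction_spec("ENO",    c(`2pg` = -1, pep = 1, h2o = 1),
                  "enolase"),
    reaction_spec("PDH",    c(nad = -1, pyr = -1, coa = -1, accoa = 1, nadh = 1, co2 = 1),
                  "pyruvate dehydrogenase"),
    reaction_spec("PPC",    c(pep = -1, co2 = -1, h2o = -1, oaa = 1, pi = 1),
                  "phosphoenolpyruvate carboxylase"),
    reaction_spec("ACS",    c(ac = -1, atp = -1, coa = -1, accoa = 1, amp = 1, ppi = 1),
                  "acetyl-CoA synthetase"),
    reaction_spec("CS",     c(accoa = -1, oaa = -1, h2o = -1, cit = 1, coa = 1),
                  "citrate synthase"),
    reaction_spec("ACONT",  c(cit = -1, icit = 1),
                  "aconitase"),
    reaction_spec("ICDH",   c(icit = -1, nadp = -1, akg = 1, nadph = 1, co2 = 1),
                  "isocitrate dehydrogenase"),
    reaction_spec("AKGDH",  c(akg = -1, coa = -1, nad = -1, succoa = 1, nadh = 1, co2 = 1),
                  "2-oxoglutarate dehydrogenase"),
    reaction_spec("SUCOAS", c(succoa = -1, adp = -1, pi = -1, succ = 1, atp = 1, coa = 1),
                  "succinyl-CoA synthetase"),
    reaction_spec("SUCDH",  c(succ = -1, q8 = -1, fum = 1, q8h2 = 1),
                  "succinate dehydrogenase"),
    reaction_spec("FUM",    c(fum = -1, h2o = -1, mal = 1),
                  "fumarase"),
    reaction_spec("MDH",    c(mal = -1, nad = -1, oaa = 1, nadh = 1),
                  "malate dehydrogenase"),
    reaction_spec("G6PDH",  c(g6p = -1, nad = -1, `6pgc` = 1, nadh = 1),
                  "glucose 6-phosphate dehydrogenase"),
    reaction_spec("GND",    c(`6pgc` = -1, nadp = -1, ru5p = 1, nadph = 1, co2 = 1),
                  "6-phosphogluconate dehydrogenase"),
    reaction_spec("RPE",    c(ru5p = -1, xu5p = 1),
                  "ribulose-phosphate epimerase"),
    reaction_spec("RPI",    c(ru5p = -1, r5p = 1),
                  "ribose-5-phosphate isomerase"),
    reaction_spec("TKT1",   c(xu5p = -1, r5p = -1, gap = 1, s7p = 1),
                  "transketolase 1"),
    reaction_spec("TKT2",   c(xu5p = -1, e4p = -1, f6p = 1, gap = 1),
                  "transketolase 2"),
    reaction_spec("TALA",   c(gap = -1, s7p = -1, f6p = 1, e4p = 1),
                  "transaldolase"),
    reaction_spec("PGCD",   c(nad = -1, `3pg` = -1, nadh = 1, `3php` = 1),
                  "phosphoglycerate dehydrogenase"),
    reaction_spec("PSERT",  c(`3php` = -1, glu = -1, pser = 1, akg = 1),
                  "phosphoserine transaminase"),
    reaction_spec("PSPL",   c(pser = -1, h2o = -1, pi = 1, ser = 1),
                  "phosphoserine phosphatase"),
    reaction_spec("SERAT",  c(accoa = -1, ser = -1, oas = 1, coa = 1),
                  "serine acetyltransferase"),
    reaction_spec("CYSS",   c(oas = -1, h2s = -1, cys = 1, ac = 1),
                  "L-cysteine synthase"),
    reaction_spec("SLCYSS", c(oas = -1, tsul = -1, slcys = 1, ac = 1),
                  "S-sulfo-L-cysteine synthase"),
    reaction_spec("SCYSSL", c(slcys = -1, nadph = -1, cys = 1, so3 = 1, nadp = 1),
                  "S-sulfo-L-cysteine lyase"),
    reaction_spec("NADH5",  c(nadh = -1, q8 = -1, nad = 1, q8h2 = 1),
                  "NADH dehydrogenase (lumped)", pseudo = TRUE),
    reaction_spec("ATPS",   c(adp = -1, pi = -1, atp = 1),
                  "ATP synthase (lumped)", pseudo = TRUE)
  )
  if (split_exporter) {
    r <- c(r, list(
      reaction_spec("YdeD_cys", c(cys = -1, cys_e = 1),
                    "L-cysteine export (YdeD)", pseudo = TRUE),
      reaction_spec("YdeD_oas", c(oas = -1, oas_e = 1),
                    "O-acetylserine export (YdeD)", pseudo = TRUE)))
  } else {
    r <- c(r, list(
      reaction_spec("YdeD", c(oas = -1, cys = -1, oas_e = 1, cys_e = 1),
                    "L-cysteine / O-acetylserine export (YdeD)", pseudo = TRUE)))
  }
  r
}

#' Build the reduced metabolic model for in vivo MCA
#'
#' Returns the 37-reaction reduced model of E. coli glycolysis, pentose
#' phosphate pathway, citrate cycle and L-cysteine biosynthesis used
#' throughout this package, with duplicate acetyl-CoA synthetase entries
#' collapsed to a single `ACS` reaction. The exporter YdeD co-exports
#' O-acetylserine and L-cysteine as a single 1:1-coupled reaction by default;
#' `split_exporter = TRUE` splits it into two independent export reactions
#' (useful for exporter-selectivity experiments).
#'
#' @param clamped Character vector of species ids treated as clamped
#'   (external) in addition to the extracellular species and water; defaults
#'   to [default_clamped_species()].
#' @param split_exporter Split the coupled YdeD export into two reactions.
#' @return A `metabolic_model`.
#' @export
build_reduced_model <- function(clamped = default_clamped_species(),
                                split_exporter = FALSE) {
  mets <- .reduced_metabolites()
  base_external <- c("glc_e", "oas_e", "cys_e", "h2o")
  mets$internal <- !(mets$id %in% c(base_external, clamped))
  metabolic_model(mets, .reduced_reactions(split_exporter),
                  id = "ecoli_cys_reduced",
                  name = "Reduced E. coli central carbon / L-cysteine model")
}

#' Stoichiometric matrix of a model
#'
#' @param model A `metabolic_model`.
#' @param internal_only Keep only rows of mass-balanced (internal) species.
#' @return Numeric matrix, metabolites x reactions; entry (j, i) is the
#'   signed coefficient of metabolite j in reaction i.
#' @export
stoichiometric_matrix <- function(model, internal_only = TRUE) {
  mets <- if (internal_only) metabolite_ids(model, TRUE) else metabolite_ids(model)
  rxns <- reaction_ids(model)
  N <- matrix(0, nrow = length(mets), ncol = length(rxns),
              dimnames = list(mets, rxns))
  for (r in model$reactions) {
    s <- r$stoichiometry
    keep <- names(s) %in% mets
    if (any(keep)) N[names(s)[keep], r$id] <- s[keep]
  }
  N
}

#' Add reactions (and optionally metabolites) to a model
#'
#' Returns a new model; the input is unchanged. Used to attach exchange,
#' uptake and biomass-drain reactions to the reduced core.
#'
#' @param model A `metabolic_model`.
#' @param reactions List of [reaction_spec()] objects (possibly empty).
#' @param metabolites Optional data.frame of new metabolite specs.
#' @return A `metabolic_model`.
#' @export
augment_model <- function(model, reactions, metabolites = NULL) {
  if (length(reactions) == 0L && is.null(metabolites)) return(model)
  new_ids <- vapply(reactions, `[[`, character(1), "id")
  clash <- intersect(new_ids, reaction_ids(model))
  if (length(clash))
    stop("reaction id(s) already present in model: ",
         paste(clash, collapse = ", "))
  mets <- model$metabolites
  if (!is.null(metabolites)) mets <- rbind(mets, metabolites)
  metabolic_model(mets, c(model$reactions, reactions),
                  id = model$id, name = model$name)
}

#' Carbon atom map of a model
#'
#' @param model A `metabolic_model`.
#' @param species Optional subset of metabolite ids; all by default.
#' @return Named integer vector metabolite id -> carbon atoms.
#' @export
carbon_map <- function(model, species = NULL) {
  cm <- stats::setNames(model$metabolites$carbon, model$metabolites$id)
  if (is.null(species)) return(cm)
  missing <- setdiff(species, names(cm))
  if (length(missing))
    stop("no carbon annotation for: ", paste(missing, collapse = ", "))
  cm[species]
}

#' Net tracked carbon per reaction
#'
#' @param model A `metabolic_model`.
#' @return Named numeric vector of net carbon (products minus reactants) per
#'   reaction; zero means elementally carbon-balanced under the tracked map.
#' @export
reaction_carbon_balance <- function(model) {
  cm <- carbon_map(model)
  vapply(model$reactions, function(r)
    sum(r$stoichiometry * cm[names(r$stoichiometry)]), numeric(1))
}

#' Ids of pseudo (lumped/transport) reactions
#' @param model A `metabolic_model`.
#' @return Character vector.
#' @export
pseudo_reactions <- function(model) {
  ids <- reaction_ids(model)
  ids[vapply(model$reactions, `[[`, logical(1), "pseudo")]
}

#' Validate model invariants
#'
#' Checks id uniqueness, stoichiometry references, bound ordering, and that
#' every non-pseudo reaction is carbon-balanced under the tracked carbon map.
#'
#' @param model A `metabolic_model`.
#' @return Invisibly `TRUE`; errors otherwise.
#' @export
validate_model <- function(model) {
  # constructor enforces ids/references/bounds; re-check balance here
  bal <- reaction_carbon_balance(model)
  off <- names(bal)[abs(bal) > 1e-9 & !(names(bal) %in% pseudo_reactions(model))]
  if (length(off))
    stop("non-pseudo reactions not carbon-balanced: ", paste(off, collapse = ", "))
  invisible(TRUE)
}
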