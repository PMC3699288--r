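#' Read a constraint-based model from SBML
#'
#' Accepts SBML Level 3 with the flux-balance-constraints (fbc) attributes as
#' the canonical dialect, and SBML Level 2 files that encode reaction bounds
#' as `LOWER_BOUND` / `UPPER_BOUND` kinetic-law parameters. Gene
#' associations and reaction categories are recovered from COBRA-style
#' notes (`GENE_ASSOCIATION:` / `CATEGORY:`); when no category note is
#' present the category is inferred with [infer_categories()].
#'
#' Bounds absent from the file default to (-1000, 1000) for reversible and
#' (0, 1000) for irreversible reactions.
#'
#' @param path path to an SBML file.
#' @return A validated `metabolic_model`.
#' @export
read_sbml <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  doc <- xml2::read_xml(path) # parse errors name the offending line
  xml2::xml_ns_strip(doc)
  mod <- xml2::xml_find_first(doc, ".//model")
  if (is.na(xml2::xml_name(mod))) stop("not an SBML file (no <model>): ", path)
  level <- xml2::xml_attr(doc, "level")

  comp_nodes <- xml2::xml_find_all(mod, ".//listOfCompartments/compartment")
  comp <- tibble::tibble(
    id = xml2::xml_attr(comp_nodes, "id"),
    name = dplyr::coalesce(xml2::xml_attr(comp_nodes, "name"),
                           xml2::xml_attr(comp_nodes, "id")))

  sp <- xml2::xml_find_all(mod, ".//listOfSpecies/species")
  met <- tibble::tibble(
    id = xml2::xml_attr(sp, "id"),
    name = dplyr::coalesce(xml2::xml_attr(sp, "name"), xml2::xml_attr(sp, "id")),
    compartment = xml2::xml_attr(sp, "compartment"),
    formula = xml2::xml_attr(sp, "chemicalFormula"),
    charge = suppressWarnings(as.integer(
      dplyr::coalesce(xml2::xml_attr(sp, "charge"), NA_character_))))
  boundary <- xml2::xml_attr(sp, "boundaryCondition") %in% "true"
  met <- met[!boundary, ]

  # fbc bound parameters (L3) live in listOfParameters
  par_nodes <- xml2::xml_find_all(mod, ".//listOfParameters/parameter")
  par <- setNames(as.numeric(xml2::xml_attr(par_nodes, "value")),
                  xml2::xml_attr(par_nodes, "id"))

  rxn_nodes <- xml2::xml_find_all(mod, ".//listOfReactions/reaction")
  n <- length(rxn_nodes)
  rxn <- tibble::tibble(
    id = xml2::xml_attr(rxn_nodes, "id"),
    name = dplyr::coalesce(xml2::xml_attr(rxn_nodes, "name"),
                           xml2::xml_attr(rxn_nodes, "id")),
    lower_bound = NA_real_, upper_bound = NA_real_,
    gene_association = "", category = NA_character_)
  sto <- vector("list", n)
  for (k in seq_len(n)) {
    node <- rxn_nodes[[k]]
    reversible <- !identical(xml2::xml_attr(node, "reversible"), "false")
    lb <- xml2::xml_attr(node, "lowerFluxBound")
    ub <- xml2::xml_attr(node, "upperFluxBound")
    lo <- if (!is.na(lb) && lb %in% names(par)) par[[lb]] else NA_real_
    up <- if (!is.na(ub) && ub %in% names(par)) par[[ub]] else NA_real_
    if (is.na(lo) || is.na(up)) {
      # Level 2 dialect: kinetic-law parameters
      kl <- xml2::xml_find_all(node, ".//kineticLaw//parameter")
      if (length(kl)) {
        kp <- setNames(as.numeric(xml2::xml_attr(kl, "value")),
                       xml2::xml_attr(kl, "id"))
        if (is.na(lo) && "LOWER_BOUND" %in% names(kp)) lo <- kp[["LOWER_BOUND"]]
        if (is.na(up) && "UPPER_BOUND" %in% names(kp)) up <- kp[["UPPER_BOUND"]]
      }
    }
    if (is.na(lo)) lo <- if (reversible) -1000 else 0
    if (is.na(up)) up <- 1000
    rxn$lower_bound[k] <- lo
    rxn$upper_bound[k] <- up
    notes <- xml2::xml_text(xml2::xml_find_all(node, ".//notes//p"))
    ga <- grep("^\\s*GENE_ASSOCIATION:", notes, value = TRUE)
    if (length(ga))
      rxn$gene_association[k] <- trimws(sub("^\\s*GENE_ASSOCIATION:", "", ga[1]))
    ct <- grep("^\\s*CATEGORY:", notes, value = TRUE)
    if (length(ct))
      rxn$category[k] <- trimws(sub("^\\s*CATEGORY:", "", ct[1]))
    refs <- function(xp, sign) {
      sr <- xml2::xml_find_all(node, xp)
      if (!length(sr)) return(NULL)
      coef <- as.numeric(dplyr::coalesce(xml2::xml_attr(sr, "stoichiometry"), "1"))
      tibble::tibble(reaction = rxn$id[k],
                     metabolite = xml2::xml_attr(sr, "species"),
                     coefficient = sign * coef)
    }
    sto[[k]] <- dplyr::bind_rows(refs(".//listOfReactants/speciesReference", -1),
                                 refs(".//listOfProducts/speciesReference", +1))
  }
  sto <- dplyr::bind_rows(sto)
  if (!nrow(sto))
    sto <- tibble::tibble(reaction = character(), metabolite = character(),
                          coefficient = numeric())
  # references to boundary-condition species are exchange placeholders
  boundary_ids <- xml2::xml_attr(sp, "id")[boundary]
  if (nrow(sto)) sto <- sto[!sto$metabolite %in% boundary_ids, ]

  obj <- xml2::xml_find_first(mod, ".//listOfObjectives//fluxObjective")
  objective_id <- if (!is.na(xml2::xml_name(obj))) {
    xml2::xml_attr(obj, "reaction")
  } else {
    # fall back to a reaction tagged biomass, else the last reaction
    bio <- rxn$id[!is.na(rxn$category) & rxn$category == "biomass"]
    if (length(bio)) bio[1] else if (n) rxn$id[n] else NA_character_
  }

  model <- metabolic_model(comp, met, rxn, sto, objective_id = objective_id,
                           id = xml2::xml_attr(mod, "id") %||% "model")
  if (anyNA(model$reactions$category)) {
    inferred <- infer_categories(model)$reactions$category
    keep <- !is.na(model$reactions$category)
    model$reactions$category[!keep] <- inferred[!keep]
  }
  validate_model(model)
  model
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

#' Write a model to SBML (Level 3 + flux bounds)
#'
#' Emits SBML Level 3 Version 1 with fbc-style `chemicalFormula` / `charge`
#' species attributes, bound parameters referenced by `lowerFluxBound` /
#' `upperFluxBound`, an fbc objective, and COBRA-style notes carrying the
#' gene association and reaction category so that [read_sbml()] round-trips
#' the model exactly (ids, stoichiometry, bounds, categories).
#'
#' @param model a `metabolic_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sbml <- function(model, path) {
  validate_model(model)
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  num <- function(x) sprintf("%.17g", x)
  ln <- character(0)
  push <- function(...) ln[[length(ln) + 1L]] <<- paste0(...)
  push('<?xml version="1.0" encoding="UTF-8"?>')
  push('<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">')
  push('  <model id="', esc(model$id), '">')
  push('    <listOfCompartments>')
  for (i in seq_len(nrow(model$compartments)))
    push('      <compartment id="', esc(model$compartments$id[i]),
         '" name="', esc(model$compartments$name[i]), '" constant="true"/>')
  push('    </listOfCompartments>')
  if (nrow(model$metabolites)) {
    push('    <listOfSpecies>')
    for (i in seq_len(nrow(model$metabolites))) {
      m <- model$metabolites[i, ]
      extra <- ""
      if (!is.na(m$formula)) extra <- paste0(extra, ' chemicalFormula="', esc(m$formula), '"')
      if (!is.na(m$charge)) extra <- paste0(extra, ' charge="', m$charge, '"')
      push('      <species id="', esc(m$id), '" name="', esc(m$name),
           '" compartment="', esc(m$compartment),
           '" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"',
           extra, '/>')
    }
    push('    </listOfSpecies>')
  }
  rx_ids <- model$reactions$id
  push('    <listOfParameters>')
  for (i in seq_along(rx_ids)) {
    push('      <parameter id="lb_', i, '" value="',
         num(model$reactions$lower_bound[i]), '" constant="true"/>')
    push('      <parameter id="ub_', i, '" value="',
         num(model$reactions$upper_bound[i]), '" constant="true"/>')
  }
  push('    </listOfParameters>')
  if (nrow(model$reactions)) {
    push('    <listOfReactions>')
    for (i in seq_len(nrow(model$reactions))) {
      r <- model$reactions[i, ]
      rev <- if (r$lower_bound < 0) "true" else "false"
      push('      <reaction id="', esc(r$id), '" name="', esc(r$name),
           '" reversible="', rev, '" fast="false" lowerFluxBound="lb_', i,
           '" upperFluxBound="ub_', i, '">')
      push('        <notes><body xmlns="http://www.w3.org/1999/xhtml">')
      if (r$gene_association != "")
        push('          <p>GENE_ASSOCIATION: ', esc(r$gene_association), '</p>')
      push('          <p>CATEGORY: ', r$category, '</p>')
      push('        </body></notes>')
      rows <- model$stoichiometry[model$stoichiometry$reaction == r$id, ]
      sub <- rows[rows$coefficient < 0, ]
      prod <- rows[rows$coefficient > 0, ]
      if (nrow(sub)) {
        push('        <listOfReactants>')
        for (k in seq_len(nrow(sub)))
          push('          <speciesReference species="', esc(sub$metabolite[k]),
               '" stoichiometry="', num(-sub$coefficient[k]), '" constant="true"/>')
        push('        </listOfReactants>')
      }
      if (nrow(prod)) {
        push('        <listOfProducts>')
        for (k in seq_len(nrow(prod)))
          push('          <speciesReference species="', esc(prod$metabolite[k]),
               '" stoichiometry="', num(prod$coefficient[k]), '" constant="true"/>')
        push('        </listOfProducts>')
      }
      push('      </reaction>')
    }
    push('    </listOfReactions>')
  }
  if (!is.na(model$objective_id)) {
    push('    <listOfObjectives activeObjective="obj">')
    push('      <objective id="obj" type="maximize">')
    push('        <listOfFluxObjectives>')
    push('          <fluxObjective reaction="', esc(model$objective_id),
         '" coefficient="1"/>')
    push('        </listOfFluxObjectives>')
    push('      </objective>')
    push('    </listOfObjectives>')
  }
  push('  </model>')
  push('</sbml>')
  ok <- tryCatch({ writeLines(ln, path); TRUE },
                 error = function(e) stop("cannot write ", path, ": ",
                                          conditionMessage(e)))
  invisible(path)
}
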