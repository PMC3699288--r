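#' Construct a constraint-based metabolic model
#'
#' The container used throughout the package: a validated list of tibbles
#' describing compartments, metabolites, reactions and reaction
#' stoichiometry, plus the id of the default objective reaction (typically
#' the biomass pseudo-reaction).
#'
#' Reaction `category` is an explicit tag with levels `metabolic`,
#' `transport`, `spontaneous`, `exchange`, `biomass` and `pseudo`; balance
#' checking and network summaries rely on it. Flux bounds are in
#' mmol gDW^-1 h^-1 and default to (-1000, 1000) for reversible and
#' (0, 1000) for irreversible reactions.
#'
#' @param compartments tibble with columns `id`, `name`.
#' @param metabolites tibble with columns `id`, `name`, `compartment`,
#'   `formula` (Hill notation string, `NA` = unknown, `""` = element-free
#'   pseudo-species) and `charge` (integer, `NA` = unknown).
#' @param reactions tibble with columns `id`, `name`, `lower_bound`,
#'   `upper_bound`, `gene_association` (boolean expression string over gene
#'   ids, `""` = none) and `category`.
#' @param stoichiometry tibble with columns `reaction`, `metabolite`,
#'   `coefficient` (negative = consumed).
#' @param objective_id reaction id of the default objective.
#' @param id model identifier.
#'
#' @return An object of class `metabolic_model`.
#' @seealso [read_sbml()], [stoichiometric_matrix()], [check_balance()],
#'   [model_summary()]
#' @export
metabolic_model <- function(compartments, metabolites, reactions,
                            stoichiometry, objective_id, id = "model") {
  fill_col <- function(df, col, default) {
    if (!col %in% names(df)) df[[col]] <- default
    df
  }
  metabolites <- fill_col(metabolites, "name", metabolites$id)
  metabolites <- fill_col(metabolites, "formula", NA_character_)
  metabolites <- fill_col(metabolites, "charge", NA_integer_)
  reactions <- fill_col(reactions, "name", reactions$id)
  reactions <- fill_col(reactions, "gene_association", "")
  reactions <- fill_col(reactions, "category", "metabolic")
  reactions <- fill_col(reactions, "lower_bound", NA_real_)
  reactions <- fill_col(reactions, "upper_bound", NA_real_)
  rev_default <- is.na(reactions$lower_bound)
  reactions$lower_bound[rev_default] <- -1000
  reactions$upper_bound[is.na(reactions$upper_bound)] <- 1000

  model <- structure(
    list(id = id,
         compartments = tibble::as_tibble(compartments),
         metabolites = tibble::as_tibble(metabolites),
         reactions = tibble::as_tibble(reactions),
         stoichiometry = tibble::as_tibble(stoichiometry),
         objective_id = objective_id),
    class = "metabolic_model")
  validate_model(model)
}

reaction_categories <- c("metabolic", "transport", "spontaneous",
                         "exchange", "biomass", "pseudo")

#' Validate referential integrity of a metabolic model
#'
#' Checks id uniqueness, compartment references, bound ordering, category
#' levels and that every metabolite referenced by a reaction is declared.
#' Called by all constructors; exported for use after manual edits.
#'
#' @param model a `metabolic_model`.
#' @return The model, invisibly unchanged, or an error describing the first
#'   integrity violation (naming the offending reaction or metabolite).
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  met <- model$metabolites; rxn <- model$reactions; sto <- model$stoichiometry
  if (anyDuplicated(met$id))
    stop("duplicated metabolite id: ", met$id[duplicated(met$id)][1])
  if (anyDuplicated(rxn$id))
    stop("duplicated reaction id: ", rxn$id[duplicated(rxn$id)][1])
  bad <- setdiff(met$compartment, model$compartments$id)
  if (length(bad))
    stop("metabolite compartment not declared: ", bad[1])
  if (any(rxn$lower_bound > rxn$upper_bound))
    stop("lower bound exceeds upper bound for reaction: ",
         rxn$id[rxn$lower_bound > rxn$upper_bound][1])
  bad <- setdiff(rxn$category, reaction_categories)
  if (length(bad)) stop("unknown reaction category: ", bad[1])
  bad <- setdiff(sto$reaction, rxn$id)
  if (length(bad)) stop("stoichiometry references unknown reaction: ", bad[1])
  dangling <- setdiff(sto$metabolite, met$id)
  if (length(dangling)) {
    rx <- sto$reaction[sto$metabolite %in% dangling][1]
    stop("reaction ", rx, " references undeclared metabolite: ", dangling[1])
  }
  if (!is.na(model$objective_id) && !model$objective_id %in% rxn$id)
    stop("objective reaction not found: ", model$objective_id)
  invisible(model)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> ", x$id, "\n", sep = "")
  cat("  ", nrow(x$metabolites), " metabolites, ",
      nrow(x$reactions), " reactions, ",
      nrow(x$compartments), " compartments\n", sep = "")
  cat("  objective: ", x$objective_id, "\n", sep = "")
  invisible(x)
}

#' Stoichiometric matrix of a model
#'
#' @param model a `metabolic_model`.
#' @return A sparse `Matrix` (metabolites x reactions) in declared order;
#'   entry (i, j) is the coefficient of metabolite i in reaction j.
#' @export
stoichiometric_matrix <- function(model) {
  i <- match(model$stoichiometry$metabolite, model$metabolites$id)
  j <- match(model$stoichiometry$reaction, model$reactions$id)
  Matrix::sparseMatrix(
    i = i, j = j, x = model$stoichiometry$coefficient,
    dims = c(nrow(model$metabolites), nrow(model$reactions)),
    dimnames = list(model$metabolites$id, model$reactions$id))
}

#' Elemental and charge balance check
#'
#' Verifies conservation of the requested elements (and, optionally, total
#' charge) for every reaction that is expected to be balanced; `exchange`,
#' `biomass` and `pseudo` reactions are skipped by construction. Hydrogen
#' imbalances are reported with a separate `flag`, since proton bookkeeping
#' depends on the protonation-state convention (intracellular pH varies
#' diurnally in cyanobacteria), as are pure water imbalances.
#'
#' @param model a `metabolic_model`.
#' @param elements element symbols to check (default C, N, O, P, S).
#' @param check_charge also check total charge conservation.
#' @return A tibble of findings with columns `reaction`, `quantity` (element
#'   symbol, `"charge"`, or `"unknown composition"`), `imbalance`
#'   (sum of coefficient x count; `NA` for unknown composition) and `flag`
#'   (`"standard"` or `"proton_convention"`). Zero rows means every checked
#'   reaction balances.
#' @export
#' @examples
#' m <- example_toy_model()
#' check_balance(m)
check_balance <- function(model, elements = c("C", "N", "O", "P", "S"),
                          check_charge = TRUE) {
  keep <- model$reactions$category %in% c("metabolic", "transport", "spontaneous")
  rxn_ids <- model$reactions$id[keep]
  sto <- model$stoichiometry[model$stoichiometry$reaction %in% rxn_ids, ]
  met <- model$metabolites
  comp <- parse_formula(met$formula)
  names(comp) <- met$id
  charge <- setNames(met$charge, met$id)

  findings <- list()
  add <- function(reaction, quantity, imbalance, flag = "standard") {
    findings[[length(findings) + 1L]] <<-
      tibble::tibble(reaction = reaction, quantity = quantity,
                     imbalance = imbalance, flag = flag)
  }
  for (rx in unique(sto$reaction)) {
    rows <- sto[sto$reaction == rx, ]
    known <- !vapply(comp[rows$metabolite], is.null, logical(1))
    if (!all(known)) {
      add(rx, "unknown composition", NA_real_)
      next
    }
    for (el in elements) {
      cnt <- vapply(comp[rows$metabolite],
                    function(p) if (el %in% names(p)) p[[el]] else 0,
                    numeric(1))
      imb <- sum(rows$coefficient * cnt)
      if (abs(imb) > 1e-9)
        add(rx, el, imb, if (el == "H") "proton_convention" else "standard")
    }
    if (check_charge) {
      ch <- charge[rows$metabolite]
      if (anyNA(ch)) {
        add(rx, "unknown composition", NA_real_)
      } else {
        imb <- sum(rows$coefficient * ch)
        if (abs(imb) > 1e-9) add(rx, "charge", imb)
      }
    }
  }
  if (!length(findings))
    return(tibble::tibble(reaction = character(), quantity = character(),
                          imbalance = numeric(), flag = character()))
  dplyr::bind_rows(findings)
}

#' Summary counts of a metabolic network
#'
#' Computes the headline network statistics: gene count, number of distinct
#' enzymes or enzyme complexes (distinct non-empty gene-association
#' expressions over metabolic and transport reactions), and reaction /
#' metabolite / compartment counts by category.
#'
#' @param model a `metabolic_model`.
#' @return A one-row tibble with columns `n_genes`, `n_enzymes`,
#'   `n_metabolic_reactions`, `n_metabolites`, `n_spontaneous`,
#'   `n_transport`, `n_compartments`.
#' @export
model_summary <- function(model) {
  rxn <- model$reactions
  gpr <- rxn$gene_association
  genes <- unique(unlist(lapply(gpr, extract_genes)))
  enz_scope <- rxn$category %in% c("metabolic", "transport")
  enz <- unique(gpr[enz_scope & gpr != ""])
  tibble::tibble(
    n_genes = length(genes),
    n_enzymes = length(enz),
    n_metabolic_reactions = sum(rxn$category == "metabolic"),
    n_metabolites = nrow(model$metabolites),
    n_spontaneous = sum(rxn$category == "spontaneous"),
    n_transport = sum(rxn$category == "transport"),
    n_compartments = nrow(model$compartments))
}

#' @export
summary.metabolic_model <- function(object, ...) model_summary(object)

# gene ids in a boolean gene-association expression ("g1 and (g2 or g3)")
extract_genes <- function(gpr) {
  if (is.na(gpr) || gpr == "") return(character(0))
  toks <- strsplit(gsub("[()]", " ", gpr), "\\s+")[[1]]
  setdiff(toks[toks != ""], c("and", "or", "AND", "OR"))
}

#' Infer reaction categories for models lacking explicit tags
#'
#' Third-party SBML rarely tags reaction classes. Heuristic used when
#' reading such files: single-metabolite stoichiometry is `exchange`;
#' stoichiometry spanning two or more compartments is `transport`; an empty
#' gene association with a non-enzymatic note is `spontaneous`; everything
#' else is `metabolic`. The classifier is tunable via `transport_spans`
#' (count boundary-diffusion steps as transport or not).
#'
#' @param model a `metabolic_model`.
#' @param spontaneous_ids reaction ids known to be non-enzymatic.
#' @param transport_spans minimum number of distinct compartments for a
#'   reaction to count as transport (default 2).
#' @return The model with `category` replaced by inferred values.
#' @export
infer_categories <- function(model, spontaneous_ids = character(),
                             transport_spans = 2) {
  met_comp <- setNames(model$metabolites$compartment, model$metabolites$id)
  cat_of <- function(rx) {
    rows <- model$stoichiometry[model$stoichiometry$reaction == rx, ]
    if (nrow(rows) <= 1) return("exchange")
    if (length(unique(met_comp[rows$metabolite])) >= transport_spans)
      return("transport")
    if (rx %in% spontaneous_ids) return("spontaneous")
    "metabolic"
  }
  model$reactions$category <-
    unname(vapply(model$reactions$id, cat_of, character(1)))
  model
}

#' A 12-reaction toy model for examples
#'
#' Small linear chain with a branch, used in documentation examples and as a
#' round-trip fixture. Carbon-balanced by construction.
#' @return A `metabolic_model`.
#' @export
example_toy_model <- function() {
  comp <- tibble::tibble(id = c("c", "e"), name = c("cytosol", "extracellular"))
  met <- tibble::tibble(
    id = c("A_e", "A", "B", "C", "D", "E_e"),
    compartment = c("e", "c", "c", "c", "c", "e"),
    formula = c("C2", "C2", "C2", "C2", "C2", "C2"),
    charge = 0L)
  rxn <- tibble::tibble(
    id = c("EX_A", "T_A", "R1", "R2", "R3", "R4", "R5", "R6",
           "T_E", "EX_E", "R7", "BIO"),
    lower_bound = c(-10, 0, 0, 0, -1000, 0, 0, 0, 0, 0, 0, 0),
    upper_bound = 1000,
    gene_association = c("", "gT1", "g1", "g2", "g3", "g4", "g5",
                         "g6 and g7", "gT2", "", "", ""),
    category = c("exchange", "transport", rep("metabolic", 6),
                 "transport", "exchange", "spontaneous", "biomass"))
  sto <- tibble::tribble(
    ~reaction, ~metabolite, ~coefficient,
    "EX_A", "A_e", -1,
    "T_A", "A_e", -1, "T_A", "A", 1,
    "R1", "A", -1, "R1", "B", 1,
    "R2", "B", -1, "R2", "C", 1,
    "R3", "C", -1, "R3", "D", 1,
    "R4", "A", -1, "R4", "D", 1,
    "R5", "D", -1, "R5", "B", 1,
    "R6", "B", -1, "R6", "C", 1,
    "T_E", "C", -1, "T_E", "E_e", 1,
    "EX_E", "E_e", -1,
    "R7", "D", -1, "R7", "C", 1,
    "BIO", "C", -1)
  metabolic_model(comp, met, rxn, sto, objective_id = "BIO", id = "toy12")
}
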