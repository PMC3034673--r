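#' Construct a metabolic model
#'
#' The central container of the package: a set of metabolites, a set of
#' reactions with stoichiometry and flux bounds, the gene catalogue, and the
#' id of the biomass objective reaction. All downstream analyses (matrix
#' construction, audits, FBA/FVA, screens, sweeps) operate on this object.
#'
#' @param metabolites data.frame with columns `id`, `name`, `compartment`
#'   (`"c"` intracellular or `"e"` extracellular), `formula` (Hill-notation
#'   elemental composition, `NA` if unknown) and `charge` (signed integer,
#'   `NA` if unknown).
#' @param reactions data.frame with columns `id`, `name`, `reversible`
#'   (logical), `lower_bound`, `upper_bound` (mmol/gDW/h), `subsystem`,
#'   `kind` (one of `"enzymatic"`, `"transport"`, `"exchange"`, `"biomass"`),
#'   `gene_association` (boolean expression over locus tags, `""` if none),
#'   and list columns `stoichiometry` (named numeric, metabolite id ->
#'   signed coefficient) and `ec_numbers` (character vector).
#' @param genes character vector of locus tags. Defaults to the tags
#'   appearing in the reactions' gene associations.
#' @param objective_id id of the biomass reaction used as default FBA
#'   objective, or `NA` for models without one.
#' @param validate run [validate_model()] on the result (default `TRUE`).
#' @return an object of class `metabolic_model`.
#' @seealso [make_mini_halophile()] for a ready-made example model.
#' @export
metabolic_model <- function(metabolites, reactions, genes = NULL,
                            objective_id = NA_character_, validate = TRUE) {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  met_defaults <- list(name = NA_character_, formula = NA_character_,
                       charge = NA_real_)
  for (col in names(met_defaults)) {
    if (is.null(metabolites[[col]])) {
      metabolites[[col]] <- rep(met_defaults[[col]], nrow(metabolites))
    }
  }
  rxn_defaults <- list(name = NA_character_, subsystem = NA_character_,
                       kind = "enzymatic", gene_association = "")
  for (col in names(rxn_defaults)) {
    if (is.null(reactions[[col]])) {
      reactions[[col]] <- rep(rxn_defaults[[col]], nrow(reactions))
    }
  }
  if (is.null(reactions$ec_numbers)) {
    reactions$ec_numbers <- replicate(nrow(reactions), character(0),
                                      simplify = FALSE)
  }
  # default bounds by reversibility (standard constraint-based convention)
  if (is.null(reactions$lower_bound)) {
    reactions$lower_bound <- ifelse(reactions$reversible, -1000, 0)
  }
  if (is.null(reactions$upper_bound)) {
    reactions$upper_bound <- rep(1000, nrow(reactions))
  }
  reactions$gene_association[is.na(reactions$gene_association)] <- ""
  if (is.null(genes)) {
    genes <- sort(unique(unlist(lapply(reactions$gene_association, gpr_genes))))
  }
  model <- structure(
    list(metabolites = metabolites, reactions = reactions,
         genes = as.character(genes), objective_id = objective_id),
    class = "metabolic_model")
  if (validate) validate_model(model)
  model
}

#' Validate a metabolic model
#'
#' Checks the structural invariants: unique ids, legal compartment codes,
#' consistent bounds (`lower <= upper`, irreversible implies `lower >= 0`),
#' non-empty stoichiometries without zero coefficients, resolvable
#' metabolite and gene references, exchange reactions touching only
#' extracellular species, and an objective id (when set) resolving to a
#' biomass-kind reaction. All violations are collected and reported
#' together.
#'
#' @param model a `metabolic_model`.
#' @return the model, invisibly; stops with a combined message otherwise.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  mets <- model$metabolites
  rxns <- model$reactions
  errs <- character(0)
  add <- function(...) errs[[length(errs) + 1L]] <<- paste0(...)

  if (anyDuplicated(mets$id)) {
    add("duplicate metabolite ids: ",
        paste(unique(mets$id[duplicated(mets$id)]), collapse = ", "))
  }
  if (anyDuplicated(rxns$id)) {
    add("duplicate reaction ids: ",
        paste(unique(rxns$id[duplicated(rxns$id)]), collapse = ", "))
  }
  bad_comp <- !mets$compartment %in% c("c", "e")
  if (any(bad_comp)) {
    add("illegal compartment (must be 'c' or 'e') for: ",
        paste(mets$id[bad_comp], collapse = ", "))
  }
  bad_kind <- !rxns$kind %in% c("enzymatic", "transport", "exchange", "biomass")
  if (any(bad_kind)) {
    add("illegal reaction kind for: ", paste(rxns$id[bad_kind], collapse = ", "))
  }
  if (any(rxns$lower_bound > rxns$upper_bound)) {
    add("lower_bound > upper_bound for: ",
        paste(rxns$id[rxns$lower_bound > rxns$upper_bound], collapse = ", "))
  }
  irrev_neg <- !rxns$reversible & rxns$lower_bound < 0
  if (any(irrev_neg)) {
    add("irreversible reaction with negative lower bound: ",
        paste(rxns$id[irrev_neg], collapse = ", "))
  }
  comp_of <- stats::setNames(mets$compartment, mets$id)
  for (i in seq_len(nrow(rxns))) {
    st <- rxns$stoichiometry[[i]]
    if (length(st) == 0L) {
      add("structural-error in reaction ", rxns$id[i], ": empty stoichiometry")
      next
    }
    if (any(abs(st) < 1e-12)) {
      add("structural-error in reaction ", rxns$id[i], ": zero coefficient for ",
          paste(names(st)[abs(st) < 1e-12], collapse = ", "))
    }
    unknown <- setdiff(names(st), mets$id)
    if (length(unknown)) {
      add("structural-error in reaction ", rxns$id[i],
          ": unresolved metabolite reference: ", paste(unknown, collapse = ", "))
      next
    }
    if (rxns$kind[i] == "exchange" &&
        any(comp_of[names(st)] != "e")) {
      add("exchange reaction ", rxns$id[i], " touches intracellular species: ",
          paste(names(st)[comp_of[names(st)] != "e"], collapse = ", "))
    }
  }
  gpr_all <- unique(unlist(lapply(rxns$gene_association, gpr_genes)))
  undeclared <- setdiff(gpr_all, model$genes)
  if (length(undeclared)) {
    add("genes used in associations but not declared: ",
        paste(undeclared, collapse = ", "))
  }
  if (!is.na(model$objective_id)) {
    j <- match(model$objective_id, rxns$id)
    if (is.na(j)) {
      add("objective_id '", model$objective_id, "' does not resolve to a reaction")
    } else if (rxns$kind[j] != "biomass") {
      add("objective reaction '", model$objective_id, "' is not of kind biomass")
    }
  }
  if (length(errs)) {
    stop("invalid metabolic model:\n  - ", paste(errs, collapse = "\n  - "),
         call. = FALSE)
  }
  invisible(model)
}

#' @export
print.metabolic_model <- function(x, ...) {
  kinds <- table(factor(x$reactions$kind,
                        levels = c("enzymatic", "transport", "exchange", "biomass")))
  cat("<metabolic_model> ", nrow(x$metabolites), " metabolites, ",
      nrow(x$reactions), " reactions, ", length(x$genes), " genes\n", sep = "")
  cat("  reactions by kind:",
      paste(names(kinds), kinds, sep = "=", collapse = ", "), "\n")
  cat("  objective:", x$objective_id, "\n")
  invisible(x)
}

# Extract the gene locus tags mentioned in a boolean gene-association
# expression. Accepts 'and'/'or' (any case), parentheses, and bare
# comma/semicolon-separated lists (treated downstream as OR over isoenzymes).
gpr_genes <- function(expr) {
  if (is.null(expr) || is.na(expr) || !nzchar(trimws(expr))) return(character(0))
  toks <- strsplit(expr, "[()]|,|;|\\s+")[[1]]
  toks <- toks[nzchar(toks)]
  toks <- toks[!tolower(toks) %in% c("and", "or")]
  unique(toks)
}

#' Build the stoichiometric matrix of a model
#'
#' Returns the sparse m-by-n matrix S whose entry `S[i, j]` is the signed
#' stoichiometric coefficient of metabolite i in reaction j (negative =
#' consumed, positive = produced, 0 = does not participate). Row names are
#' metabolite ids and column names reaction ids, which serve as the
#' row/column index maps.
#'
#' @param model a valid `metabolic_model`.
#' @return a `Matrix::sparseMatrix` (class `dgCMatrix`) with dimnames
#'   `list(metabolite ids, reaction ids)`.
#' @export
build_stoichiometric_matrix <- function(model) {
  mets <- model$metabolites$id
  rxns <- model$reactions$id
  st <- model$reactions$stoichiometry
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (j in seq_along(st)) {
    rows <- match(names(st[[j]]), mets)
    if (anyNA(rows)) {
      stop("structural-error in reaction ", rxns[j],
           ": unresolved metabolite reference: ",
           paste(names(st[[j]])[is.na(rows)], collapse = ", "), call. = FALSE)
    }
    ii <- c(ii, rows)
    jj <- c(jj, rep.int(j, length(rows)))
    xx <- c(xx, unname(st[[j]]))
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(length(mets), length(rxns)),
                       dimnames = list(mets, rxns))
}

#' Fraction of enzymatic reactions with a gene association
#'
#' The gene-enzyme-reaction coverage of a reconstruction: the share of
#' enzymatic reactions carrying a non-empty gene association.
#'
#' @param model a `metabolic_model` with at least one enzymatic reaction.
#' @return a fraction in `[0, 1]`.
#' @export
gene_reaction_coverage <- function(model) {
  enz <- model$reactions$kind == "enzymatic"
  if (!any(enz)) {
    stop("undefined-ratio: model has no enzymatic reactions", call. = FALSE)
  }
  has_gene <- nzchar(trimws(model$reactions$gene_association[enz]))
  sum(has_gene) / sum(enz)
}

#' Knock out reactions
#'
#' Returns a copy of the model with the flux bounds of the named reactions
#' set to `lower = upper = 0` (the classic in-silico deletion). The input
#' model is not modified. Knocking out an empty set returns the model
#' unchanged; the operation is idempotent and commutes across disjoint
#' reaction sets.
#'
#' @param model a `metabolic_model`.
#' @param reaction_ids character vector of reaction ids to disable.
#' @return the modified model.
#' @export
knock_out <- function(model, reaction_ids) {
  if (length(reaction_ids) == 0L) return(model)
  j <- match(reaction_ids, model$reactions$id)
  if (anyNA(j)) {
    stop("unknown reaction id(s): ",
         paste(reaction_ids[is.na(j)], collapse = ", "), call. = FALSE)
  }
  model$reactions$lower_bound[j] <- 0
  model$reactions$upper_bound[j] <- 0
  model
}

# Look up reactions carrying a given EC number. Returns reaction ids.
#' Find reactions by EC number
#'
#' @param model a `metabolic_model`.
#' @param ec a single EC number string, e.g. `"2.7.2.4"`.
#' @return character vector of reaction ids annotated with that EC.
#' @export
reactions_by_ec <- function(model, ec) {
  hit <- vapply(model$reactions$ec_numbers, function(e) ec %in% e, logical(1))
  model$reactions$id[hit]
}

# Internal convenience: assemble a model from a reaction table whose
# `equation` column is in the parse_reaction_equation() dialect. Metabolites
# not described in `metabolites` are created bare (compartment taken from the
# [tag] suffix of their id).
build_model_from_equations <- function(rxn, metabolites = NULL,
                                       objective_id = NA_character_,
                                       validate = TRUE) {
  parsed <- lapply(rxn$equation, parse_reaction_equation)
  rxn$stoichiometry <- lapply(parsed, `[[`, "stoichiometry")
  if (is.null(rxn$reversible)) {
    rxn$reversible <- vapply(parsed, `[[`, logical(1), "reversible")
  }
  rxn$equation <- NULL
  met_ids <- sort(unique(unlist(lapply(rxn$stoichiometry, names))))
  comp <- sub("^.*\\[([A-Za-z0-9]+)\\]$", "\\1", met_ids)
  mets <- data.frame(id = met_ids, name = met_ids, compartment = comp,
                     formula = NA_character_, charge = NA_real_,
                     stringsAsFactors = FALSE)
  if (!is.null(metabolites)) {
    k <- match(mets$id, metabolites$id)
    for (col in intersect(c("name", "formula", "charge"), names(metabolites))) {
      mets[[col]][!is.na(k)] <- metabolites[[col]][k[!is.na(k)]]
    }
  }
  metabolic_model(mets, rxn, objective_id = objective_id, validate = validate)
}
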