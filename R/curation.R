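#' Parse an elemental formula in Hill notation
#'
#' Accepts formulas such as `"C6H12O6"`, `"H2O"`, `"NaCl"` or
#' `"C10H12N5O13P3"`: a sequence of element symbols (capital letter plus
#' optional lowercase letter) each followed by an optional integer count.
#'
#' @param formula a single formula string.
#' @return named numeric vector of element counts.
#' @export
parse_formula <- function(formula) {
  if (is.na(formula) || !nzchar(formula)) {
    stop("formula-syntax error: empty formula", call. = FALSE)
  }
  toks <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  if (sum(nchar(toks)) != nchar(formula)) {
    stop("formula-syntax error: cannot parse \"", formula, "\"", call. = FALSE)
  }
  el <- sub("[0-9]*$", "", toks)
  ct <- as.numeric(sub("^[A-Z][a-z]?", "", toks))
  ct[is.na(ct)] <- 1
  counts <- tapply(ct, el, sum)
  stats::setNames(as.numeric(counts), names(counts))
}

# Elemental + charge deficit of one stoichiometry map given a metabolite
# registry (data.frame with id, formula, charge). deficit = products -
# substrates per element / charge; balanced <=> all zeros. Returns NULL if
# any participant lacks a formula ("unknown" reaction).
reaction_deficit <- function(stoichiometry, metabolites) {
  k <- match(names(stoichiometry), metabolites$id)
  if (anyNA(k)) {
    stop("unresolved metabolite reference: ",
         paste(names(stoichiometry)[is.na(k)], collapse = ", "), call. = FALSE)
  }
  formulas <- metabolites$formula[k]
  if (any(is.na(formulas) | !nzchar(formulas))) return(NULL)
  parsed <- lapply(seq_along(formulas), function(i) {
    tryCatch(parse_formula(formulas[i]),
             error = function(e) stop("formula-syntax error for metabolite ",
                                      metabolites$id[k[i]], ": ",
                                      conditionMessage(e), call. = FALSE))
  })
  elements <- sort(unique(unlist(lapply(parsed, names))))
  deficit <- stats::setNames(numeric(length(elements)), elements)
  for (i in seq_along(parsed)) {
    deficit[names(parsed[[i]])] <- deficit[names(parsed[[i]])] +
      stoichiometry[i] * parsed[[i]]
  }
  charges <- metabolites$charge[k]
  charge_deficit <- if (any(is.na(charges))) NA_real_ else
    sum(stoichiometry * charges)
  list(elements = deficit[abs(deficit) > 1e-9],
       charge = charge_deficit)
}

#' Check mass and charge balance of reactions
#'
#' For each reaction, sums elemental composition and charge over products
#' minus substrates. A reaction is `balanced` when every element and the
#' charge net to zero, `unbalanced` otherwise; reactions with any
#' formula-less participant are classified `unknown` (no verdict), and
#' boundary reactions (kind `exchange`) are classified `boundary` since
#' they intentionally create or drain mass.
#'
#' @param model a valid `metabolic_model`.
#' @param reaction_ids reactions to check; default all.
#' @return data.frame with columns `reaction_id`, `status`
#'   (`balanced`/`unbalanced`/`unknown`/`boundary`), `charge_deficit`
#'   (NA when any charge is unknown) and list column `element_deficit`
#'   (named numeric of nonzero per-element deficits, products minus
#'   substrates).
#' @examples
#' m <- make_mini_halophile()
#' table(check_mass_charge_balance(m)$status)
#' @export
check_mass_charge_balance <- function(model, reaction_ids = NULL) {
  rxns <- model$reactions
  if (!is.null(reaction_ids)) {
    j <- match(reaction_ids, rxns$id)
    if (anyNA(j)) stop("unknown reaction id(s): ",
                       paste(reaction_ids[is.na(j)], collapse = ", "),
                       call. = FALSE)
    rxns <- rxns[j, , drop = FALSE]
  }
  n <- nrow(rxns)
  status <- character(n)
  charge <- rep(NA_real_, n)
  deficits <- vector("list", n)
  for (i in seq_len(n)) {
    if (rxns$kind[i] == "exchange") {
      status[i] <- "boundary"
      deficits[[i]] <- numeric(0)
      next
    }
    d <- reaction_deficit(rxns$stoichiometry[[i]], model$metabolites)
    if (is.null(d)) {
      status[i] <- "unknown"
      deficits[[i]] <- numeric(0)
      next
    }
    charge[i] <- d$charge
    deficits[[i]] <- d$elements
    balanced <- length(d$elements) == 0L &&
      (is.na(d$charge) || abs(d$charge) < 1e-9)
    status[i] <- if (balanced) "balanced" else "unbalanced"
  }
  out <- data.frame(reaction_id = rxns$id, status = status,
                    charge_deficit = charge, stringsAsFactors = FALSE)
  out$element_deficit <- deficits
  out
}

#' Find dead-end metabolites
#'
#' A metabolite is a dead end when, counting a reversible reaction as both
#' a producer and a consumer of each of its participants, it has no
#' producing reaction or no consuming reaction. Exchange and biomass
#' reactions count as legitimate producers/consumers. Dead ends flag
#' reconstruction gaps: missing links that disconnect the species from the
#' rest of the network.
#'
#' @param model a valid `metabolic_model`.
#' @return data.frame with columns `metabolite_id` and `mode`
#'   (`"no-producer"` or `"no-consumer"`); a species in no reaction at all
#'   appears with both modes. Zero rows when the network has no gaps.
#' @export
find_dead_ends <- function(model) {
  mets <- model$metabolites$id
  produced <- stats::setNames(logical(length(mets)), mets)
  consumed <- produced
  for (i in seq_len(nrow(model$reactions))) {
    st <- model$reactions$stoichiometry[[i]]
    rev <- model$reactions$reversible[i]
    prod <- names(st)[st > 0]
    cons <- names(st)[st < 0]
    produced[prod] <- TRUE
    consumed[cons] <- TRUE
    if (rev) {
      produced[cons] <- TRUE
      consumed[prod] <- TRUE
    }
  }
  out <- rbind(
    data.frame(metabolite_id = mets[!produced],
               mode = rep("no-producer", sum(!produced)),
               stringsAsFactors = FALSE),
    data.frame(metabolite_id = mets[!consumed],
               mode = rep("no-consumer", sum(!consumed)),
               stringsAsFactors = FALSE))
  out[order(out$metabolite_id, out$mode), , drop = FALSE]
}

#' Metabolite and reaction adjacency matrices
#'
#' Two metabolites are adjacent when they co-occur in at least one
#' reaction; two reactions are adjacent when they share at least one
#' metabolite. Both matrices are symmetric binary matrices with zero
#' diagonal, the standard topological summaries built from the
#' stoichiometric matrix during reconstruction gap analysis.
#'
#' @param model a valid `metabolic_model`.
#' @return list with sparse matrices `metabolite` (m x m) and `reaction`
#'   (n x n).
#' @export
adjacency_matrices <- function(model) {
  S <- build_stoichiometric_matrix(model)
  B <- (abs(S) > 0) * 1
  met <- (B %*% Matrix::t(B)) > 0
  rxn <- (Matrix::t(B) %*% B) > 0
  met <- met * 1; rxn <- rxn * 1
  Matrix::diag(met) <- 0
  Matrix::diag(rxn) <- 0
  list(metabolite = Matrix::drop0(met), reaction = Matrix::drop0(rxn))
}

#' Network statistics
#'
#' Computes the descriptive characteristics of a reconstruction: gene and
#' metabolite counts (by compartment), reaction counts (by kind, and with
#' gene assignments by kind), the distribution of enzymatic reactions over
#' subsystems, the reactions-per-gene ratio per top-level EC class, and
#' the monofunctional fraction — the share of distinct EC numbers that
#' catalyze exactly one reaction.
#'
#' @param model a valid `metabolic_model`.
#' @return an object of class `network_stats` (a list).
#' @export
network_statistics <- function(model) {
  rxns <- model$reactions
  kinds <- factor(rxns$kind,
                  levels = c("enzymatic", "transport", "exchange", "biomass"))
  has_gene <- nzchar(trimws(rxns$gene_association))
  comp <- table(factor(model$metabolites$compartment, levels = c("c", "e")))

  sub_tab <- table(rxns$subsystem[!is.na(rxns$subsystem)])
  subsystem_distribution <- if (length(sub_tab)) {
    p <- as.numeric(sub_tab) / sum(sub_tab)
    stats::setNames(p, names(sub_tab))
  } else stats::setNames(numeric(0), character(0))

  ecs <- unlist(rxns$ec_numbers)
  ec_per_rxn <- rxns$ec_numbers
  # reactions-per-gene ratio per EC top-level class
  classes <- as.character(1:6)
  ec_class_ratio <- stats::setNames(rep(NA_real_, 6), classes)
  for (cl in classes) {
    in_class <- vapply(seq_len(nrow(rxns)), function(i) {
      any(startsWith(ec_per_rxn[[i]], paste0(cl, "."))) }, logical(1))
    genes_cl <- unique(unlist(lapply(rxns$gene_association[in_class], gpr_genes)))
    if (length(genes_cl)) ec_class_ratio[cl] <- sum(in_class) / length(genes_cl)
  }

  mono <- NA_real_
  if (length(ecs)) {
    per_ec <- table(unlist(lapply(seq_len(nrow(rxns)), function(i)
      unique(ec_per_rxn[[i]]))))
    mono <- sum(per_ec == 1L) / length(per_ec)
  }

  structure(list(
    n_genes = length(model$genes),
    n_metabolites = nrow(model$metabolites),
    metabolites_by_compartment = stats::setNames(as.integer(comp), names(comp)),
    n_reactions = nrow(rxns),
    reactions_by_kind = stats::setNames(as.integer(table(kinds)), levels(kinds)),
    reactions_with_genes_by_kind =
      stats::setNames(as.integer(table(kinds[has_gene])), levels(kinds)),
    subsystem_distribution = subsystem_distribution,
    ec_class_ratio = ec_class_ratio,
    monofunctional_fraction = mono), class = "network_stats")
}

#' @export
print.network_stats <- function(x, ...) {
  cat("<network_stats>\n")
  cat("  genes:", x$n_genes, " metabolites:", x$n_metabolites,
      "(", paste(names(x$metabolites_by_compartment),
                 x$metabolites_by_compartment, sep = "=", collapse = ", "),
      ")\n")
  cat("  reactions:", x$n_reactions, "(",
      paste(names(x$reactions_by_kind), x$reactions_by_kind, sep = "=",
            collapse = ", "), ")\n")
  cat("  monofunctional fraction:",
      format(round(x$monofunctional_fraction, 4)), "\n")
  invisible(x)
}

# Canonical direction-invariant signature of one reaction: sorted
# (species-key, coefficient) pairs, species keyed by formula when known,
# else by compartment-stripped id. A mapping override (old id -> key) may
# replace the default keying.
reaction_signature <- function(stoichiometry, metabolites, mapping = NULL) {
  k <- match(names(stoichiometry), metabolites$id)
  key <- sub("\\[[A-Za-z0-9]+\\]$", "", names(stoichiometry))
  f <- metabolites$formula[k]
  key <- ifelse(!is.na(f) & nzchar(f), f, tolower(key))
  if (!is.null(mapping)) {
    ov <- mapping[names(stoichiometry)]
    key <- ifelse(is.na(ov), key, ov)
  }
  # net duplicated keys (same species in two compartments)
  agg <- tapply(unname(stoichiometry), key, sum)
  agg <- agg[abs(agg) > 1e-9]
  if (length(agg) == 0L) return("")
  fmt <- function(v) paste(sprintf("%s:%.6g", names(v), unname(v))[order(names(v))],
                           collapse = "|")
  min(fmt(agg), fmt(-agg))
}

#' Compare the reaction contents of two models
#'
#' Matches reactions across two independently built models by canonical
#' signature: the multiset of (species, coefficient) pairs after
#' compartment normalization, keyed by elemental formula where available
#' (ids are not comparable across publications), and normalized for
#' direction. Exchange reactions are excluded (they encode the growth
#' medium, not metabolic capability), as are reactions whose signature
#' cancels to nothing under formula keying (pure same-species transport):
#' their signature carries no chemical information to match on. The
#' operation is symmetric in its arguments.
#'
#' @param model_a,model_b valid `metabolic_model` objects.
#' @param mapping_a,mapping_b optional named character vectors overriding
#'   the species key of given metabolite ids (a curated cross-model map).
#' @return list with `shared` (data.frame `id_a`, `id_b`, `signature`),
#'   `unique_a` and `unique_b` (character vectors of reaction ids).
#' @export
compare_models <- function(model_a, model_b, mapping_a = NULL,
                           mapping_b = NULL) {
  sig_of <- function(model, mapping) {
    keep <- model$reactions$kind != "exchange"
    ids <- model$reactions$id[keep]
    sig <- vapply(model$reactions$stoichiometry[keep], reaction_signature,
                  character(1), metabolites = model$metabolites,
                  mapping = mapping)
    data.frame(id = ids, sig = sig,
               stringsAsFactors = FALSE)[nzchar(sig), , drop = FALSE]
  }
  a <- sig_of(model_a, mapping_a)
  b <- sig_of(model_b, mapping_b)
  common <- intersect(a$sig, b$sig)
  shared <- do.call(rbind, lapply(common, function(s) {
    data.frame(id_a = a$id[a$sig == s][1], id_b = b$id[b$sig == s][1],
               signature = s, stringsAsFactors = FALSE)
  }))
  if (is.null(shared)) {
    shared <- data.frame(id_a = character(0), id_b = character(0),
                         signature = character(0), stringsAsFactors = FALSE)
  }
  list(shared = shared,
       unique_a = a$id[!a$sig %in% common],
       unique_b = b$id[!b$sig %in% common])
}

#' Audit a reconstruction
#'
#' Runs the quality-control battery over a model: dead-end metabolites,
#' mass/charge balance of every non-boundary reaction, and network
#' statistics.
#'
#' @param model a valid `metabolic_model`.
#' @return an object of class `audit_report`: list with `dead_ends`
#'   (see [find_dead_ends()]), `unbalanced` (balance rows with status
#'   `unbalanced`), `unknown_formula` (reaction ids that could not be
#'   checked), and `stats` (a `network_stats`).
#' @examples
#' audit_model(make_mini_halophile())
#' @export
audit_model <- function(model) {
  balance <- check_mass_charge_balance(model)
  structure(list(
    dead_ends = find_dead_ends(model),
    unbalanced = balance[balance$status == "unbalanced", , drop = FALSE],
    unknown_formula = balance$reaction_id[balance$status == "unknown"],
    stats = network_statistics(model)), class = "audit_report")
}

#' @export
print.audit_report <- function(x, ...) {
  cat("<audit_report>\n")
  cat("  dead-end metabolites:", nrow(x$dead_ends), "\n")
  if (nrow(x$dead_ends)) {
    print(utils::head(x$dead_ends, 10), row.names = FALSE)
  }
  cat("  unbalanced reactions:", nrow(x$unbalanced), "\n")
  if (nrow(x$unbalanced)) {
    for (i in seq_len(min(10, nrow(x$unbalanced)))) {
      d <- x$unbalanced$element_deficit[[i]]
      cat("    ", x$unbalanced$reaction_id[i], ": ",
          paste(names(d), d, sep = ":", collapse = " "),
          if (!is.na(x$unbalanced$charge_deficit[i]))
            paste0(" charge:", x$unbalanced$charge_deficit[i]) else "",
          "\n", sep = "")
    }
  }
  cat("  reactions with unknown formulas:", length(x$unknown_formula), "\n")
  invisible(x)
}

#' Write an audit report to disk
#'
#' Serializes an [audit_model()] report as JSON plus a human-readable TSV
#' of dead ends and imbalances.
#'
#' @param report an `audit_report`.
#' @param json_path path for the JSON document, or `NULL` to skip.
#' @param tsv_path path for the TSV summary, or `NULL` to skip.
#' @return invisibly, the paths written.
#' @export
write_audit_report <- function(report, json_path = NULL, tsv_path = NULL) {
  if (!is.null(json_path)) {
    doc <- list(
      dead_end_metabolites = report$dead_ends,
      unbalanced_reactions = lapply(seq_len(nrow(report$unbalanced)), function(i)
        list(reaction_id = report$unbalanced$reaction_id[i],
             element_deficit = as.list(report$unbalanced$element_deficit[[i]]),
             charge_deficit = report$unbalanced$charge_deficit[i])),
      unknown_formula = report$unknown_formula,
      stats = unclass(report$stats))
    jsonlite::write_json(doc, json_path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  }
  if (!is.null(tsv_path)) {
    n_d <- nrow(report$dead_ends)
    n_u <- nrow(report$unbalanced)
    rows <- rbind(
      data.frame(type = rep("dead_end", n_d),
                 id = report$dead_ends$metabolite_id,
                 detail = report$dead_ends$mode, stringsAsFactors = FALSE),
      data.frame(type = rep("unbalanced", n_u),
                 id = report$unbalanced$reaction_id,
                 detail = vapply(report$unbalanced$element_deficit, function(d)
                   paste(names(d), d, sep = ":", collapse = " "), character(1)),
                 stringsAsFactors = FALSE))
    utils::write.table(rows, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(c(json = json_path, tsv = tsv_path))
}
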