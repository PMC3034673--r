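# Column synonyms for the table dialect. Matching is case-insensitive and
# ignores spaces/underscores; supplementary spreadsheets name columns
# inconsistently, so each logical column accepts several spellings.
.rxn_columns <- list(
  id = c("id", "rxnid", "reactionid", "abbreviation", "rxn"),
  name = c("name", "reactionname", "description"),
  equation = c("equation", "reaction", "formula", "rxnformula"),
  reversible = c("reversible", "rev"),
  lower_bound = c("lowerbound", "lb", "alpha", "lower"),
  upper_bound = c("upperbound", "ub", "beta", "upper"),
  ec_numbers = c("ecnumbers", "ec", "ecnumber", "enzyme"),
  gene_association = c("genes", "geneassociation", "gpr", "generule"),
  subsystem = c("subsystem", "pathway", "category"),
  kind = c("kind", "type", "reactiontype"))

.met_columns <- list(
  id = c("id", "metid", "metaboliteid", "abbreviation"),
  name = c("name", "metabolitename", "description"),
  compartment = c("compartment", "comp"),
  formula = c("formula", "elementalformula", "composition"),
  charge = c("charge"))

match_columns <- function(have, wanted) {
  norm <- function(x) gsub("[ _.-]", "", tolower(x))
  out <- stats::setNames(rep(NA_character_, length(wanted)), names(wanted))
  for (logical_name in names(wanted)) {
    hit <- which(norm(have) %in% norm(wanted[[logical_name]]))
    if (length(hit)) out[logical_name] <- have[hit[1]]
  }
  out
}

read_table_file <- function(x) {
  if (is.data.frame(x)) return(x)
  utils::read.delim(x, stringsAsFactors = FALSE, check.names = FALSE,
                    colClasses = "character", na.strings = c("NA", ""),
                    fileEncoding = "UTF-8")
}

#' Read a model from reaction and metabolite tables
#'
#' Loads the TSV dialect: a reaction table (columns `id`, `name`,
#' `equation`, optional `reversible`, `lower_bound`, `upper_bound`,
#' `ec_numbers` (";"-separated), `genes`, `subsystem`, `kind`) and a
#' metabolite table (`id`, `name`, `compartment`, `formula`, `charge`).
#' Column-name matching is case-insensitive with documented synonyms;
#' unknown extra columns are carried through as annotations. All load
#' errors (missing mandatory columns, malformed equations, duplicate ids,
#' dangling metabolite references) are collected and reported together,
#' not fail-fast.
#'
#' @param reaction_table path to a TSV file or a data.frame.
#' @param metabolite_table path to a TSV file or a data.frame.
#' @param objective_id id of the biomass objective; by default the first
#'   reaction of kind `biomass`, if any.
#' @return a valid `metabolic_model`; row order of the input is preserved.
#' @export
read_model_tables <- function(reaction_table, metabolite_table,
                              objective_id = NULL) {
  rt <- read_table_file(reaction_table)
  mt <- read_table_file(metabolite_table)
  errs <- character(0)
  add <- function(...) errs[[length(errs) + 1L]] <<- paste0(...)

  rmap <- match_columns(names(rt), .rxn_columns)
  mmap <- match_columns(names(mt), .met_columns)
  for (must in c("id", "equation")) {
    if (is.na(rmap[must])) add("reaction table: missing mandatory column '",
                               must, "'")
  }
  for (must in c("id", "compartment")) {
    if (is.na(mmap[must])) add("metabolite table: missing mandatory column '",
                               must, "'")
  }
  if (length(errs)) stop("model load error:\n  - ",
                         paste(errs, collapse = "\n  - "), call. = FALSE)

  pick <- function(tab, map, col) if (is.na(map[col])) NULL else tab[[map[col]]]

  mets <- data.frame(id = pick(mt, mmap, "id"), stringsAsFactors = FALSE)
  mets$name <- pick(mt, mmap, "name")
  if (is.null(mets$name)) mets$name <- mets$id
  mets$compartment <- pick(mt, mmap, "compartment")
  mets$formula <- pick(mt, mmap, "formula")
  if (is.null(mets$formula)) mets$formula <- NA_character_
  ch <- pick(mt, mmap, "charge")
  mets$charge <- if (is.null(ch)) NA_real_ else suppressWarnings(as.numeric(ch))
  extra_m <- setdiff(names(mt), stats::na.omit(mmap))
  for (col in extra_m) mets[[paste0("annot_", col)]] <- mt[[col]]

  rxn <- data.frame(id = pick(rt, rmap, "id"), stringsAsFactors = FALSE)
  rxn$name <- pick(rt, rmap, "name")
  if (is.null(rxn$name)) rxn$name <- rxn$id
  eqs <- pick(rt, rmap, "equation")
  parsed <- vector("list", nrow(rxn))
  rev_from_eq <- logical(nrow(rxn))
  for (i in seq_len(nrow(rxn))) {
    p <- tryCatch(parse_reaction_equation(eqs[i]), error = function(e) e)
    if (inherits(p, "error")) {
      add("reaction row ", i, " (", rxn$id[i], "): ", conditionMessage(p))
    } else {
      parsed[[i]] <- p$stoichiometry
      rev_from_eq[i] <- p$reversible
    }
  }
  rv <- pick(rt, rmap, "reversible")
  rxn$reversible <- if (is.null(rv)) rev_from_eq else {
    v <- trimws(tolower(rv))
    ifelse(is.na(rv) | v == "", rev_from_eq, v %in% c("1", "true", "yes"))
  }
  lbv <- pick(rt, rmap, "lower_bound")
  ubv <- pick(rt, rmap, "upper_bound")
  rxn$lower_bound <- if (is.null(lbv)) ifelse(rxn$reversible, -1000, 0) else {
    x <- suppressWarnings(as.numeric(lbv))
    ifelse(is.na(x), ifelse(rxn$reversible, -1000, 0), x)
  }
  rxn$upper_bound <- if (is.null(ubv)) 1000 else {
    x <- suppressWarnings(as.numeric(ubv))
    ifelse(is.na(x), 1000, x)
  }
  ecv <- pick(rt, rmap, "ec_numbers")
  rxn$ec_numbers <- if (is.null(ecv)) {
    replicate(nrow(rxn), character(0), simplify = FALSE)
  } else {
    lapply(ecv, function(s) {
      if (is.na(s) || !nzchar(trimws(s))) character(0)
      else trimws(strsplit(s, ";")[[1]])
    })
  }
  ga <- pick(rt, rmap, "gene_association")
  rxn$gene_association <- if (is.null(ga)) "" else ifelse(is.na(ga), "", ga)
  ss <- pick(rt, rmap, "subsystem")
  rxn$subsystem <- if (is.null(ss)) NA_character_ else ss
  kd <- pick(rt, rmap, "kind")
  rxn$kind <- if (is.null(kd)) "enzymatic" else {
    ifelse(is.na(kd) | !nzchar(trimws(kd)), "enzymatic", trimws(tolower(kd)))
  }
  extra_r <- setdiff(names(rt), stats::na.omit(rmap))
  for (col in extra_r) rxn[[paste0("annot_", col)]] <- rt[[col]]

  if (anyDuplicated(rxn$id)) {
    dup <- unique(rxn$id[duplicated(rxn$id)])
    add("duplicate reaction id(s) in rows ",
        paste(which(rxn$id %in% dup), collapse = ", "), ": ",
        paste(dup, collapse = ", "))
  }
  if (anyDuplicated(mets$id)) {
    dup <- unique(mets$id[duplicated(mets$id)])
    add("duplicate metabolite id(s) in rows ",
        paste(which(mets$id %in% dup), collapse = ", "), ": ",
        paste(dup, collapse = ", "))
  }
  for (i in seq_len(nrow(rxn))) {
    if (is.null(parsed[[i]])) next
    dangling <- setdiff(names(parsed[[i]]), mets$id)
    if (length(dangling)) {
      add("reaction row ", i, " (", rxn$id[i],
          "): references undeclared metabolite(s): ",
          paste(dangling, collapse = ", "))
    }
  }
  if (length(errs)) stop("model load error:\n  - ",
                         paste(errs, collapse = "\n  - "), call. = FALSE)

  rxn$stoichiometry <- parsed
  if (is.null(objective_id)) {
    bm <- rxn$id[rxn$kind == "biomass"]
    objective_id <- if (length(bm)) bm[1] else NA_character_
  }
  metabolic_model(mets, rxn, objective_id = objective_id)
}

#' Write a model to reaction and metabolite TSV tables
#'
#' Inverse of [read_model_tables()]; writing then reading is the identity
#' after one normalization pass.
#'
#' @param model a valid `metabolic_model`.
#' @param reactions_path,metabolites_path output TSV paths.
#' @return invisibly, the two paths.
#' @export
write_model_tables <- function(model, reactions_path, metabolites_path) {
  rxns <- model$reactions
  out_r <- data.frame(
    id = rxns$id, name = rxns$name,
    equation = vapply(seq_len(nrow(rxns)), function(i)
      format_reaction_equation(rxns$stoichiometry[[i]], rxns$reversible[i]),
      character(1)),
    reversible = as.integer(rxns$reversible),
    lower_bound = rxns$lower_bound, upper_bound = rxns$upper_bound,
    ec_numbers = vapply(rxns$ec_numbers, paste, character(1), collapse = ";"),
    genes = rxns$gene_association, subsystem = rxns$subsystem,
    kind = rxns$kind, stringsAsFactors = FALSE)
  out_m <- model$metabolites[, c("id", "name", "compartment", "formula",
                                 "charge")]
  utils::write.table(out_r, reactions_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "", fileEncoding = "UTF-8")
  utils::write.table(out_m, metabolites_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(c(reactions_path, metabolites_path))
}

.model_schema_version <- "halofba-model-1"

#' Serialize a model to JSON / read it back
#'
#' A single JSON document mirroring the model: `schema_version`,
#' `metabolites`, `reactions` (stoichiometry as an id -> coefficient
#' object), `genes` and `objective_id`. Numbers are written at full
#' precision, so write-then-read is the identity on all fields including
#' bounds, EC numbers, gene associations and rational coefficients.
#'
#' @param model a valid `metabolic_model`.
#' @param path output file; when `NULL`, the JSON text is returned.
#' @return `write_model_json`: the path (or JSON string), invisibly when
#'   written to file. `read_model_json`: a `metabolic_model`.
#' @export
write_model_json <- function(model, path = NULL) {
  rxns <- model$reactions
  doc <- list(
    schema_version = .model_schema_version,
    objective_id = model$objective_id,
    genes = model$genes,
    metabolites = lapply(seq_len(nrow(model$metabolites)), function(i) {
      m <- model$metabolites[i, ]
      list(id = m$id, name = m$name, compartment = m$compartment,
           formula = m$formula, charge = m$charge)
    }),
    reactions = lapply(seq_len(nrow(rxns)), function(i) {
      list(id = rxns$id[i], name = rxns$name[i],
           stoichiometry = as.list(rxns$stoichiometry[[i]]),
           reversible = rxns$reversible[i],
           lower_bound = rxns$lower_bound[i],
           upper_bound = rxns$upper_bound[i],
           ec_numbers = as.list(rxns$ec_numbers[[i]]),
           gene_association = rxns$gene_association[i],
           subsystem = rxns$subsystem[i], kind = rxns$kind[i])
    }))
  txt <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, null = "null",
                          na = "null", pretty = TRUE)
  if (is.null(path)) return(as.character(txt))
  writeLines(txt, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_model_json
#' @param document a file path or a JSON string produced by
#'   [write_model_json()].
#' @export
read_model_json <- function(document) {
  doc <- jsonlite::fromJSON(document, simplifyVector = FALSE)
  if (is.null(doc$schema_version) ||
      !identical(doc$schema_version, .model_schema_version)) {
    stop("unsupported-version: expected schema_version '",
         .model_schema_version, "', got '",
         if (is.null(doc$schema_version)) "<missing>" else doc$schema_version,
         "'", call. = FALSE)
  }
  nul2na <- function(x, as = NA_character_) if (is.null(x)) as else x
  mets <- do.call(rbind, lapply(doc$metabolites, function(m) {
    data.frame(id = m$id, name = nul2na(m$name), compartment = m$compartment,
               formula = nul2na(m$formula),
               charge = nul2na(m$charge, NA_real_), stringsAsFactors = FALSE)
  }))
  rxn <- do.call(rbind, lapply(doc$reactions, function(r) {
    data.frame(id = r$id, name = nul2na(r$name),
               reversible = isTRUE(r$reversible),
               lower_bound = r$lower_bound, upper_bound = r$upper_bound,
               gene_association = nul2na(r$gene_association, ""),
               subsystem = nul2na(r$subsystem), kind = r$kind,
               stringsAsFactors = FALSE)
  }))
  rxn$stoichiometry <- lapply(doc$reactions, function(r) {
    st <- unlist(r$stoichiometry)
    stats::setNames(as.numeric(st), names(st))
  })
  rxn$ec_numbers <- lapply(doc$reactions, function(r)
    as.character(unlist(r$ec_numbers)))
  rxn$gene_association[is.na(rxn$gene_association)] <- ""
  metabolic_model(mets, rxn, genes = as.character(unlist(doc$genes)),
                  objective_id = nul2na(doc$objective_id))
}

#' Convert a supplementary workbook to model TSV tables
#'
#' Reads an Excel workbook holding a reaction sheet and a metabolite sheet
#' (sheet names matched case-insensitively against "reactions" and
#' "metabolites", else the first two sheets are used), writes the two TSV
#' tables of the dialect read by [read_model_tables()], and logs the
#' column mapping it inferred so it can be confirmed manually. Requires
#' the readxl package.
#'
#' @param workbook path to an .xlsx file.
#' @param out_dir output directory for `reactions.tsv` and
#'   `metabolites.tsv`.
#' @return invisibly, the paths of the two TSV files.
#' @export
convert_model_xlsx <- function(workbook, out_dir = ".") {
  if (!requireNamespace("readxl", quietly = TRUE)) {
    stop("convert_model_xlsx requires the 'readxl' package", call. = FALSE)
  }
  sheets <- readxl::excel_sheets(workbook)
  find_sheet <- function(pat, fallback) {
    hit <- grep(pat, sheets, ignore.case = TRUE, value = TRUE)
    if (length(hit)) hit[1] else sheets[fallback]
  }
  rs <- find_sheet("reaction", 1L)
  ms <- find_sheet("metabolite", 2L)
  rt <- as.data.frame(readxl::read_excel(workbook, sheet = rs))
  mt <- as.data.frame(readxl::read_excel(workbook, sheet = ms))
  rmap <- match_columns(names(rt), .rxn_columns)
  mmap <- match_columns(names(mt), .met_columns)
  message("workbook column mapping (reactions, sheet '", rs, "'):")
  for (k in names(rmap)) message("  ", k, " <- ",
                                 ifelse(is.na(rmap[k]), "<absent>", rmap[k]))
  message("workbook column mapping (metabolites, sheet '", ms, "'):")
  for (k in names(mmap)) message("  ", k, " <- ",
                                 ifelse(is.na(mmap[k]), "<absent>", mmap[k]))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rp <- file.path(out_dir, "reactions.tsv")
  mp <- file.path(out_dir, "metabolites.tsv")
  utils::write.table(rt, rp, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "", fileEncoding = "UTF-8")
  utils::write.table(mt, mp, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "", fileEncoding = "UTF-8")
  invisible(c(rp, mp))
}
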