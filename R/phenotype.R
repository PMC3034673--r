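# Substrate-utilization phenotype screening: growth verdicts on sole carbon
# (and, for nitrogenous substrates, sole nitrogen) sources, enzyme-activity
# feasibility tests, and growth-vs-uptake response curves.

# thresholds: "positive growth" and "carries flux" are not defined by any
# printed convention, so the package fixes them here.
.growth_threshold <- 1e-6   # h^-1
.flux_threshold <- 1e-9     # mmol/gDW/h

#' Screen substrates for in-silico utilization
#'
#' For each substrate, builds a minimal medium with that substrate as the
#' sole carbon source at `uptake_rate` (in `"max"` mode, so a substrate
#' the network cannot use is simply left untouched rather than forced),
#' runs FBA on the biomass objective, and issues a `+`/`-` growth verdict.
#' Substrates whose formula contains nitrogen are additionally made the
#' sole nitrogen source (the ammonia exchange is closed). A substrate with
#' no exchange/transport route is reported `-` with the reason, not an
#' error.
#'
#' @param model a valid `metabolic_model`.
#' @param substrates character vector of substrate names/ids; defaults to
#'   every extracellular carbon species with an exchange reaction.
#' @param uptake_rate uptake rate in mmol/gDW/h (default 3).
#' @param aerobic logical, default `TRUE`.
#' @param reference optional data.frame with columns `substrate` and
#'   `in_vivo`, merged into the output for concordance checks.
#' @return data.frame with one row per substrate: `substrate`, `in_silico`
#'   (`+`/`-`), `growth_rate`, `transport_reactions` and
#'   `utilization_reactions` (";"-collapsed ids of reactions carrying
#'   |flux| above threshold and touching the substrate species), `note`;
#'   plus `in_vivo` and `concordant` when a reference is given.
#' @examples
#' m <- make_mini_halophile()
#' substrate_screen(m, c("glc", "ala", "lac"), uptake_rate = 3)
#' @export
substrate_screen <- function(model, substrates = NULL, uptake_rate = 3,
                             aerobic = TRUE, reference = NULL) {
  if (is.null(substrates)) {
    ex <- which(model$reactions$kind == "exchange")
    sp <- vapply(model$reactions$stoichiometry[ex],
                 function(st) names(st)[1], character(1))
    f <- model$metabolites$formula[match(sp, model$metabolites$id)]
    carbon <- vapply(f, function(x) !is.na(x) &&
                       "C" %in% names(parse_formula(x)), logical(1))
    substrates <- sub("\\[e\\]$", "", sp[carbon])
  }
  rows <- lapply(substrates, function(sub) {
    rec <- list(substrate = sub, in_silico = "-", growth_rate = 0,
                transport_reactions = "", utilization_reactions = "",
                note = "")
    # sole nitrogen source too?
    k <- match_species(model, sub)
    nitrogenous <- FALSE
    if (!is.na(k)) {
      f <- model$metabolites$formula[k]
      nitrogenous <- !is.na(f) && "N" %in% names(parse_formula(f))
    }
    med <- tryCatch({
      up <- stats::setNames(uptake_rate, sub)
      if (nitrogenous) up <- c(up, nh3 = 0)
      set_medium(model, up, aerobic = aerobic, mode = "max")
    }, error = function(e) e)
    if (inherits(med, "error")) {
      rec$note <- conditionMessage(med)
      return(rec)
    }
    sol <- solve_fba(model, constraints = med)
    if (sol$status != "optimal") {
      rec$note <- paste("FBA status:", sol$status)
      return(rec)
    }
    rec$growth_rate <- sol$objective_value
    rec$in_silico <- if (sol$objective_value > .growth_threshold) "+" else "-"
    if (rec$in_silico == "+") {
      act <- active_reactions_for(model, sol, sub)
      rec$transport_reactions <- paste(act$transport, collapse = ";")
      rec$utilization_reactions <- paste(act$utilization, collapse = ";")
    }
    rec
  })
  out <- do.call(rbind, lapply(rows, as.data.frame,
                               stringsAsFactors = FALSE))
  if (!is.null(reference)) {
    m <- match(tolower(out$substrate), tolower(reference$substrate))
    out$in_vivo <- reference$in_vivo[m]
    out$concordant <- !is.na(out$in_vivo) & out$in_vivo == out$in_silico
  }
  out
}

# resolve a substrate name to a metabolite row (extracellular preferred)
match_species <- function(model, sub) {
  key <- tolower(sub("\\[[A-Za-z0-9]+\\]$", "", sub))
  bare <- tolower(sub("\\[[A-Za-z0-9]+\\]$", "", model$metabolites$id))
  hit <- which(bare == key | tolower(model$metabolites$name) == tolower(sub))
  if (length(hit) == 0L) return(NA_integer_)
  e <- hit[model$metabolites$compartment[hit] == "e"]
  if (length(e)) e[1] else hit[1]
}

# reactions touching any compartment form of `sub` that carry flux
active_reactions_for <- function(model, solution, sub) {
  key <- tolower(sub("\\[[A-Za-z0-9]+\\]$", "", sub))
  bare <- tolower(sub("\\[[A-Za-z0-9]+\\]$", "", model$metabolites$id))
  species <- model$metabolites$id[bare == key]
  touches <- vapply(model$reactions$stoichiometry, function(st)
    any(names(st) %in% species), logical(1))
  carries <- abs(solution$fluxes) > .flux_threshold
  sel <- touches & carries
  list(transport = model$reactions$id[sel & model$reactions$kind == "transport"],
       utilization = model$reactions$id[sel & model$reactions$kind == "enzymatic"])
}

#' Test whether a reaction can carry flux under a medium
#'
#' Maximizes the absolute flux through the target reaction (both
#' directions for reversible reactions) under the given medium
#' constraints. The verdict is `+` when the attainable |flux| exceeds the
#' threshold — the in-silico analogue of an enzyme activity test
#' (catalase, urease, nitrate reduction, ...).
#'
#' @param model a valid `metabolic_model`.
#' @param reaction_id the target reaction.
#' @param constraints medium bound overrides (see [set_medium()]).
#' @param threshold minimum |flux| counted as active (default 1e-6).
#' @return list with `reaction_id`, `max_flux` (attainable |flux|) and
#'   `verdict` (`+`/`-`).
#' @export
activity_test <- function(model, reaction_id, constraints = NULL,
                          threshold = 1e-6) {
  j <- match(reaction_id, model$reactions$id)
  if (is.na(j)) stop("unknown reaction id: ", reaction_id, call. = FALSE)
  hi <- solve_fba(model, reaction_id, constraints, direction = "max")
  best <- if (hi$status == "optimal") abs(hi$objective_value) else 0
  if (model$reactions$reversible[j] || model$reactions$lower_bound[j] < 0) {
    lo <- solve_fba(model, reaction_id, constraints, direction = "min")
    if (lo$status == "optimal") best <- max(best, abs(lo$objective_value))
  }
  list(reaction_id = reaction_id, max_flux = best,
       verdict = if (best > threshold) "+" else "-")
}

#' Growth as a function of substrate uptake rate
#'
#' Runs FBA across a vector of uptake rates for one substrate (sole
#' carbon source) and returns the growth-response curve. By LP convexity
#' the curve is monotone non-decreasing in the uptake bound.
#'
#' @param model a valid `metabolic_model`.
#' @param substrate substrate name/id.
#' @param uptake_rates positive uptake rates, mmol/gDW/h.
#' @param aerobic logical, default `TRUE`.
#' @return data.frame with columns `uptake_rate` and `growth_rate`.
#' @export
growth_vs_uptake <- function(model, substrate, uptake_rates, aerobic = TRUE) {
  stopifnot(all(uptake_rates >= 0))
  growth <- vapply(uptake_rates, function(r) {
    med <- set_medium(model, stats::setNames(r, substrate), aerobic = aerobic,
                      mode = "max")
    sol <- solve_fba(model, constraints = med)
    if (sol$status != "optimal") {
      stop("FBA not optimal at uptake ", r, ": ", sol$status, call. = FALSE)
    }
    sol$objective_value
  }, numeric(1))
  data.frame(uptake_rate = uptake_rates, growth_rate = growth)
}
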