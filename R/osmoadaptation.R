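# Osmoadaptation case studies: the choline-betaine sweep, the ectoine
# production sweep with yields, the alanine supplementation scenario, and
# pathway-presence audits by EC number.

#' EC numbers of the ectoine and choline-betaine pathways
#'
#' The four-step ectoine branch of aspartate metabolism (aspartate kinase,
#' aspartate-semialdehyde dehydrogenase, the glutamate- and
#' alanine-dependent diaminobutyrate transaminases, diaminobutyrate
#' acetyltransferase, ectoine synthase) and the two-step choline to
#' glycine betaine route (choline dehydrogenase or choline monooxygenase,
#' then betaine aldehyde dehydrogenase).
#'
#' @format character vectors of EC numbers.
#' @export
ectoine_pathway_ecs <- c("2.7.2.4", "1.2.1.11", "2.6.1.76", "2.6.1.46",
                         "2.3.1.178", "4.2.1.108")

#' @rdname ectoine_pathway_ecs
#' @export
betaine_pathway_ecs <- c("1.1.99.1", "1.14.15.7", "1.2.1.8")

# the two step-one choline oxidation enzymes, knocked out when simulating
# absence of exogenous osmoprotectant use
.choline_oxidation_ecs <- c("1.1.99.1", "1.14.15.7")

#' Verify that a pathway's enzymes are present in a model
#'
#' @param model a valid `metabolic_model`.
#' @param ec_list EC numbers to look up, e.g. [ectoine_pathway_ecs].
#' @return data.frame with columns `ec`, `found` (logical) and
#'   `reaction_ids` (";"-collapsed).
#' @examples
#' verify_pathway(make_mini_halophile(), ectoine_pathway_ecs)
#' @export
verify_pathway <- function(model, ec_list) {
  rows <- lapply(ec_list, function(ec) {
    ids <- reactions_by_ec(model, ec)
    data.frame(ec = ec, found = length(ids) > 0,
               reaction_ids = paste(ids, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# summed flux through all reactions carrying an EC number
pathway_flux <- function(model, solution, ec) {
  ids <- reactions_by_ec(model, ec)
  if (length(ids) == 0L) return(0)
  sum(solution$fluxes[ids])
}

# secretion (positive) flux of a species through its exchange reactions
secretion_rate <- function(model, solution, species) {
  -uptake_rate(model, solution, species)
}

#' Choline-to-betaine osmoadaptation sweep
#'
#' Reproduces the choline supplementation experiment in silico: with
#' glucose fixed as the carbon source, choline uptake is restricted to a
#' series of rates; at each rate FBA maximizes biomass and the betaine
#' production flux (the flux through betaine aldehyde dehydrogenase,
#' EC 1.2.1.8) is recorded. An FVA pass certifies whether the reported
#' fluxes are unique or alternate-optima-sensitive.
#'
#' Both betaine-pathway step-one enzymes and the aldehyde dehydrogenase
#' must be present; their absence is a pathway-audit error raised before
#' any LP is solved.
#'
#' @param model a valid `metabolic_model`.
#' @param glucose_rate glucose uptake, mmol/gDW/h (default 3).
#' @param choline_rates choline uptake rates to sweep (default the series
#'   0, 1, 1.2, 1.4, 1.6, 1.8, 2).
#' @param fva attach FVA variability certificates (default `TRUE`).
#' @return data.frame of class `sweep_result`: `choline_uptake`,
#'   `growth_rate`, `betaine_flux`, `betaine_secretion`, and (with FVA)
#'   `growth_variability_pct`, `betaine_variability_pct`.
#' @export
choline_betaine_sweep <- function(model, glucose_rate = 3,
                                  choline_rates = c(0, 1, 1.2, 1.4, 1.6, 1.8, 2),
                                  fva = TRUE) {
  audit_pathway(model, betaine_pathway_ecs, "choline-betaine")
  badh <- reactions_by_ec(model, "1.2.1.8")
  rows <- lapply(choline_rates, function(r) {
    med <- set_medium(model, c(glc = glucose_rate, cho = r), mode = "fixed")
    sol <- solve_fba(model, constraints = med)
    if (sol$status != "optimal") {
      stop("FBA not optimal at choline uptake ", r, ": ", sol$status,
           call. = FALSE)
    }
    out <- data.frame(choline_uptake = r,
                      growth_rate = sol$objective_value,
                      betaine_flux = pathway_flux(model, sol, "1.2.1.8"),
                      betaine_secretion = tryCatch(
                        secretion_rate(model, sol, "bet"),
                        error = function(e) NA_real_),
                      stringsAsFactors = FALSE)
    if (fva) {
      targets <- c(model$objective_id, badh)
      fv <- flux_variability(model, reactions = targets, constraints = med)
      out$growth_variability_pct <- fv$variability_percent[1]
      out$betaine_variability_pct <- max(fv$variability_percent[-1])
    }
    out
  })
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_result", "data.frame")
  out
}

#' Ectoine production sweep over glucose uptake
#'
#' Simulates de-novo ectoine synthesis when no exogenous osmoprotectant is
#' accessible: choline and betaine uptakes are closed and the two choline
#' oxidation reactions (EC 1.1.99.1, EC 1.14.15.7) are knocked out; FBA
#' then maximizes biomass across a series of glucose uptake rates. The
#' ectoine production flux is the flux through ectoine synthase
#' (EC 4.2.1.108); yield is production divided by glucose uptake
#' (mmol/mmol). The stoichiometric ceiling obtained by maximizing ectoine
#' synthase directly at the same glucose rate is reported alongside.
#'
#' @param model a valid `metabolic_model`.
#' @param glucose_rates glucose uptake rates, mmol/gDW/h (default 3:10).
#' @param fva attach FVA variability certificates (default `TRUE`).
#' @return data.frame of class `sweep_result`: `glucose_uptake`,
#'   `growth_rate`, `ectoine_flux`, `ectoine_secretion`, `yield`,
#'   `max_yield` (direct-maximization bound), and (with FVA)
#'   `ectoine_variability_pct`.
#' @export
ectoine_production_sweep <- function(model, glucose_rates = 3:10, fva = TRUE) {
  audit_pathway(model, ectoine_pathway_ecs, "ectoine")
  ko <- unlist(lapply(.choline_oxidation_ecs, reactions_by_ec, model = model))
  m2 <- knock_out(model, ko)
  ects <- reactions_by_ec(m2, "4.2.1.108")
  rows <- lapply(glucose_rates, function(g) {
    med <- set_medium(m2, c(glc = g), mode = "fixed")
    # betaine/choline uptakes are organic-carbon, hence already closed
    sol <- solve_fba(m2, constraints = med)
    if (sol$status != "optimal") {
      stop("FBA not optimal at glucose uptake ", g, ": ", sol$status,
           call. = FALSE)
    }
    prod <- pathway_flux(m2, sol, "4.2.1.108")
    cap <- solve_fba(m2, objective_id = ects[1], constraints = med)
    out <- data.frame(glucose_uptake = g,
                      growth_rate = sol$objective_value,
                      ectoine_flux = prod,
                      ectoine_secretion = tryCatch(
                        secretion_rate(m2, sol, "ect"),
                        error = function(e) NA_real_),
                      yield = if (g > 0) prod / g else 0,
                      max_yield = if (g > 0 && cap$status == "optimal")
                        cap$objective_value / g else NA_real_,
                      stringsAsFactors = FALSE)
    if (fva) {
      fv <- flux_variability(m2, reactions = ects, constraints = med)
      out$ectoine_variability_pct <- max(fv$variability_percent)
    }
    out
  })
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_result", "data.frame")
  out
}

#' Alanine supplementation scenario
#'
#' Compares growth and ectoine production without and with alanine in the
#' medium. Baseline: glucose uptake fixed (default 1 mmol/gDW/h) and NaCl
#' availability capped (default 1.1 mmol/gDW/h); treatment: the same plus
#' alanine uptake fixed at `alanine_rate` (default 1.2 mmol/gDW/h).
#' Percent stimulations are computed on fluxes rounded to 4 decimals, the
#' precision growth rates are conventionally reported at.
#'
#' The NaCl rate is applied as an upper bound on uptake rather than a
#' two-sided pin: salt has no catabolic fate, so forcing a fixed net
#' uptake in excess of the biomass salt demand would make any
#' mass-balanced model infeasible.
#'
#' @param model a valid `metabolic_model` with an alanine uptake route.
#' @param glucose_rate,nacl_rate,alanine_rate uptake rates in mmol/gDW/h.
#' @return list with `without` and `with` (each: `growth_rate`,
#'   `ectoine_flux`) and `stimulation_percent` (named: `growth`,
#'   `ectoine`).
#' @export
alanine_scenario <- function(model, glucose_rate = 1, nacl_rate = 1.1,
                             alanine_rate = 1.2) {
  audit_pathway(model, ectoine_pathway_ecs, "ectoine")
  run <- function(uptake) {
    med <- set_medium(model, uptake, mode = "fixed")
    # cap NaCl availability (uptake direction only)
    k <- match_species(model, "nacl")
    if (!is.na(k)) {
      ex <- which(vapply(model$reactions$stoichiometry, function(st)
        model$metabolites$id[k] %in% names(st), logical(1)) &
          model$reactions$kind == "exchange")
      if (length(ex)) {
        kk <- match(model$reactions$id[ex], med$reaction_id)
        med$lower[kk] <- -nacl_rate
      }
    }
    sol <- solve_fba(model, constraints = med)
    if (sol$status != "optimal") {
      stop("FBA not optimal under medium [",
           paste(names(uptake), uptake, sep = ":", collapse = ", "), "]: ",
           sol$status, call. = FALSE)
    }
    list(growth_rate = sol$objective_value,
         ectoine_flux = pathway_flux(model, sol, "4.2.1.108"))
  }
  base_uptake <- c(glc = glucose_rate)
  without <- run(base_uptake)
  with_ala <- run(c(base_uptake, ala = alanine_rate))
  pct <- function(a, b) {
    a <- round(a, 4); b <- round(b, 4)
    if (a == 0) return(NA_real_)
    100 * (b - a) / a
  }
  list(without = without, with = with_ala,
       stimulation_percent = c(
         growth = pct(without$growth_rate, with_ala$growth_rate),
         ectoine = pct(without$ectoine_flux, with_ala$ectoine_flux)))
}

audit_pathway <- function(model, ecs, label) {
  rep <- verify_pathway(model, ecs)
  # the two step-one choline enzymes are alternatives: one suffices
  if (identical(sort(ecs), sort(betaine_pathway_ecs))) {
    step1 <- rep$found[rep$ec %in% .choline_oxidation_ecs]
    ok <- any(step1) && all(rep$found[!rep$ec %in% .choline_oxidation_ecs])
  } else {
    alt <- rep$ec %in% c("2.6.1.76", "2.6.1.46")  # transaminase isozymes
    ok <- all(rep$found[!alt]) && any(rep$found[alt])
  }
  if (!ok) {
    stop("pathway-audit error: ", label, " pathway incomplete; missing EC(s): ",
         paste(rep$ec[!rep$found], collapse = ", "), call. = FALSE)
  }
  invisible(rep)
}
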