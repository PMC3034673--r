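#' Flux balance analysis
#'
#' Solves the FBA linear program: find a flux vector v maximizing the
#' objective reaction's flux subject to the steady-state mass balance
#' `S v = 0` and the flux bounds `alpha_j <= v_j <= beta_j`. The objective
#' is the biomass reaction by default, in which case its flux is the
#' specific growth rate (h^-1); all other fluxes are in mmol/gDW/h.
#'
#' Infeasible constraint sets and unbounded formulations are reported
#' distinctly via `status`; they are never silently returned as zero
#' growth.
#'
#' @param model a valid `metabolic_model`.
#' @param objective_id reaction to optimize; defaults to the model's
#'   biomass objective.
#' @param constraints optional bound overrides: a data.frame with columns
#'   `reaction_id`, `lower`, `upper` (as produced by [set_medium()]).
#' @param direction `"max"` (default) or `"min"`.
#' @return an object of class `flux_solution`: list with `status`
#'   (`"optimal"`, `"infeasible"` or `"unbounded"`), `objective_value`,
#'   `objective_id` and `fluxes` (named numeric vector over all reactions).
#' @examples
#' m <- make_toy_chain(length = 2, uptake_bound = 5)
#' solve_fba(m)
#' @export
solve_fba <- function(model, objective_id = NULL, constraints = NULL,
                      direction = c("max", "min")) {
  direction <- match.arg(direction)
  if (is.null(objective_id)) objective_id <- model$objective_id
  j <- match(objective_id, model$reactions$id)
  if (is.na(j)) {
    stop("objective reaction '", objective_id, "' not found", call. = FALSE)
  }
  S <- as.matrix(build_stoichiometric_matrix(model))
  lb <- model$reactions$lower_bound
  ub <- model$reactions$upper_bound
  if (!is.null(constraints) && nrow(constraints) > 0) {
    k <- match(constraints$reaction_id, model$reactions$id)
    if (anyNA(k)) {
      stop("constraint references unknown reaction(s): ",
           paste(constraints$reaction_id[is.na(k)], collapse = ", "),
           call. = FALSE)
    }
    lb[k] <- constraints$lower
    ub[k] <- constraints$upper
  }
  obj <- numeric(ncol(S)); obj[j] <- 1
  res <- solve_lp(obj, S, b = numeric(nrow(S)), lower = lb, upper = ub,
                  maximize = direction == "max")
  fluxes <- stats::setNames(res$x, model$reactions$id)
  structure(list(status = res$status,
                 objective_value = if (res$status == "optimal") res$objective else NA_real_,
                 objective_id = objective_id,
                 fluxes = fluxes),
            class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat("<flux_solution> status:", x$status, "\n")
  if (x$status == "optimal") {
    cat("  objective (", x$objective_id, "): ",
        format(round(x$objective_value, 4), nsmall = 4), "\n", sep = "")
    nz <- sum(abs(x$fluxes) > 1e-9)
    cat("  reactions with |flux| > 1e-9:", nz, "of", length(x$fluxes), "\n")
  }
  invisible(x)
}

#' Flux variability analysis
#'
#' With the objective fixed at (a fraction of) its FBA optimum, computes
#' for each reaction the minimum and maximum flux it can carry. The span
#' `v_max - v_min` characterizes the reaction's variability across
#' alternate optimal flux distributions; it is also reported as a
#' percentage of `max(|v_FBA|, eps)` with `eps = 1e-6`.
#'
#' @param model a valid `metabolic_model`.
#' @param objective_id objective reaction; defaults to the model biomass.
#' @param fraction fraction of the FBA optimum the objective must attain,
#'   in `(0, 1]`; default 1 (the optimum itself).
#' @param reactions reaction ids to analyze; default all.
#' @param constraints optional bound overrides (see [solve_fba()]).
#' @return a data.frame of class `fva_result` with columns `reaction_id`,
#'   `flux_fba`, `vmin`, `vmax`, `variability_percent`.
#' @export
flux_variability <- function(model, objective_id = NULL, fraction = 1.0,
                             reactions = NULL, constraints = NULL) {
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      fraction <= 0 || fraction > 1) {
    stop("fraction must lie in (0, 1]", call. = FALSE)
  }
  if (is.null(objective_id)) objective_id <- model$objective_id
  base <- solve_fba(model, objective_id, constraints)
  if (base$status != "optimal") {
    stop("FVA requires an optimal FBA solution; status was: ", base$status,
         call. = FALSE)
  }
  opt <- base$objective_value
  # pin the objective at >= fraction * optimum (tiny slack for LP round-off)
  slack <- 1e-7 * max(1, abs(opt))
  pin <- data.frame(reaction_id = objective_id,
                    lower = fraction * opt - slack,
                    upper = model$reactions$upper_bound[
                      match(objective_id, model$reactions$id)],
                    stringsAsFactors = FALSE)
  constraints <- if (is.null(constraints)) pin else
    rbind(constraints[, c("reaction_id", "lower", "upper")], pin)
  if (is.null(reactions)) reactions <- model$reactions$id
  vmin <- vmax <- numeric(length(reactions))
  for (i in seq_along(reactions)) {
    lo <- solve_fba(model, reactions[i], constraints, direction = "min")
    hi <- solve_fba(model, reactions[i], constraints, direction = "max")
    if (lo$status != "optimal" || hi$status != "optimal") {
      stop("FVA subproblem not optimal for reaction ", reactions[i],
           " (status ", lo$status, "/", hi$status, ")", call. = FALSE)
    }
    vmin[i] <- lo$objective_value
    vmax[i] <- hi$objective_value
  }
  flux <- base$fluxes[reactions]
  out <- data.frame(reaction_id = reactions,
                    flux_fba = unname(flux),
                    vmin = vmin, vmax = vmax,
                    variability_percent =
                      100 * (vmax - vmin) / pmax(abs(flux), 1e-6),
                    stringsAsFactors = FALSE)
  class(out) <- c("fva_result", "data.frame")
  out
}

#' Compose growth-medium bound overrides
#'
#' Builds the constraint set that represents a defined growth medium:
#' each named substrate's exchange reaction is fixed at the given uptake
#' rate, every other organic-carbon uptake is closed, and inorganic /
#' freely exchanged species (water, CO2, O2 when aerobic, ammonia/um,
#' phosphate, sulfate, nitrogen oxides, sodium chloride, protons) are left
#' open. A species is treated as organic carbon when its formula contains
#' carbon and it is not CO2; species without a formula are closed unless
#' their id is on the inorganic whitelist.
#'
#' Exchange reactions follow the convention `x[e] <=>`, so uptake is a
#' negative exchange flux; this function takes and reports uptake as
#' positive rates and translates internally.
#'
#' @param model a valid `metabolic_model`.
#' @param uptake named numeric vector: substrate -> uptake rate in
#'   mmol/gDW/h. Names are matched against extracellular metabolite ids
#'   (with or without the `[e]` tag) and names, case-insensitively. A rate
#'   of 0 closes that uptake.
#' @param aerobic open the O2 exchange (default `TRUE`). Supplying an
#'   explicit `o2` entry in `uptake` overrides this.
#' @param mode `"fixed"` pins each named uptake at its rate
#'   (`alpha = beta = rate`); `"max"` allows any uptake up to the rate.
#' @param open_rate bound magnitude used for open exchanges (default 1000).
#' @return a data.frame with columns `reaction_id`, `lower`, `upper`
#'   suitable for the `constraints` argument of [solve_fba()].
#' @export
set_medium <- function(model, uptake = numeric(0), aerobic = TRUE,
                       mode = c("fixed", "max"), open_rate = 1000) {
  mode <- match.arg(mode)
  ex <- which(model$reactions$kind == "exchange")
  if (length(ex) == 0L) stop("model has no exchange reactions", call. = FALSE)
  # the (single) extracellular species each exchange moves
  species <- vapply(model$reactions$stoichiometry[ex],
                    function(st) names(st)[1], character(1))
  mrow <- match(species, model$metabolites$id)
  bare <- tolower(sub("\\[[A-Za-z0-9]+\\]$", "", species))
  mname <- tolower(model$metabolites$name[mrow])
  formula <- model$metabolites$formula[mrow]

  inorganic_ids <- c("h2o", "h", "o2", "co2", "nh3", "nh4", "pi", "po4",
                     "so4", "no3", "no2", "na", "na1", "cl", "nacl", "hco3")
  has_carbon <- vapply(formula, function(f) {
    if (is.na(f)) return(NA)
    "C" %in% names(parse_formula(f))
  }, logical(1))
  organic <- ifelse(is.na(has_carbon),
                    !(bare %in% inorganic_ids),
                    has_carbon & !(bare %in% c("co2", "hco3")))

  lower <- ifelse(organic, 0, -open_rate)
  upper <- rep(open_rate, length(ex))
  if (!aerobic) lower[bare == "o2"] <- 0

  if (length(uptake)) {
    if (is.null(names(uptake)) || any(!nzchar(names(uptake)))) {
      stop("uptake must be a named vector (substrate -> rate)", call. = FALSE)
    }
    for (sub in names(uptake)) {
      key <- tolower(sub("\\[[A-Za-z0-9]+\\]$", "", sub))
      hit <- which(bare == key | mname == tolower(sub) |
                     tolower(species) == tolower(sub))
      if (length(hit) == 0L) {
        stop("medium error: substrate '", sub,
             "' has no exchange/uptake route in the model", call. = FALSE)
      }
      rate <- uptake[[sub]]
      if (!is.finite(rate) || rate < 0) {
        stop("medium error: uptake rate for '", sub, "' must be >= 0",
             call. = FALSE)
      }
      if (mode == "fixed") {
        lower[hit] <- -rate
        upper[hit] <- if (rate == 0) open_rate else -rate
      } else {
        lower[hit] <- -rate
        upper[hit] <- open_rate
      }
    }
  }
  data.frame(reaction_id = model$reactions$id[ex],
             lower = lower, upper = upper, stringsAsFactors = FALSE)
}

# Uptake rate of a substrate in a solved flux distribution: the negative
# part of its exchange flux, reported positive.
#' Uptake rate of a species in a flux solution
#'
#' @param model the model the solution belongs to.
#' @param solution a `flux_solution`.
#' @param species extracellular metabolite id (with or without `[e]`).
#' @return uptake in mmol/gDW/h (positive = consumed from the medium).
#' @export
uptake_rate <- function(model, solution, species) {
  ex <- which(model$reactions$kind == "exchange")
  sp <- vapply(model$reactions$stoichiometry[ex],
               function(st) names(st)[1], character(1))
  key <- tolower(sub("\\[[A-Za-z0-9]+\\]$", "", species))
  hit <- ex[tolower(sub("\\[[A-Za-z0-9]+\\]$", "", sp)) == key]
  if (length(hit) == 0L) stop("no exchange for species '", species, "'",
                              call. = FALSE)
  -sum(solution$fluxes[model$reactions$id[hit]])
}
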