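# Synthetic network generators: analytic toys with known LP optima, random
# quality-control networks with recorded ground truth, and the curated
# mini-halophile fixture. Everything the test suite and the examples run on
# is generated here, in code, deterministically.

#' Linear toy pathway with analytic FBA optimum
#'
#' Builds the chain `EX -> transport -> (length - 1 conversions) -> biomass`.
#' A single uptake bound limits the whole pathway, so the FBA optimum is
#' exactly `uptake_bound`.
#'
#' @param length number of intracellular species in the chain (>= 1).
#' @param uptake_bound maximal substrate uptake in mmol/gDW/h.
#' @return a `metabolic_model` with objective `BIOMASS`.
#' @examples
#' solve_fba(make_toy_chain(3, uptake_bound = 2))$objective_value  # 2
#' @export
make_toy_chain <- function(length = 1L, uptake_bound = 5) {
  stopifnot(length >= 1, uptake_bound >= 0)
  ids <- paste0("c", seq_len(length), "[c]")
  eqs <- c("s[e] <=>",
           paste0("s[e] -> ", ids[1]))
  if (length > 1) {
    eqs <- c(eqs, paste0(ids[-length], " -> ", ids[-1]))
  }
  eqs <- c(eqs, paste0(ids[length], " ->"))
  rxn <- data.frame(
    id = c("EX_s", "TRANS", if (length > 1) paste0("CONV", seq_len(length - 1)),
           "BIOMASS"),
    equation = eqs,
    kind = c("exchange", "transport",
             rep("enzymatic", max(0, length - 1)), "biomass"),
    stringsAsFactors = FALSE)
  rxn$reversible <- c(TRUE, rep(FALSE, nrow(rxn) - 1L))
  rxn$lower_bound <- c(-uptake_bound, rep(0, nrow(rxn) - 1L))
  rxn$upper_bound <- 1000
  mets <- data.frame(id = c("s[e]", ids), formula = "C",
                     stringsAsFactors = FALSE)
  build_model_from_equations(rxn, mets, objective_id = "BIOMASS")
}

#' Parallel-branch toy with alternate optima
#'
#' Several capacity-limited branches feed one pooled intermediate drained
#' by the biomass sink. The FBA optimum is
#' `min(sum(capacities), sink_bound)`; whenever the branches have spare
#' joint capacity the optimum is degenerate and FVA shows the per-branch
#' spans.
#'
#' @param capacities upper bounds of the parallel branches (>= 2 values).
#' @param sink_bound upper bound of the biomass sink.
#' @return a `metabolic_model` with objective `BIOMASS`.
#' @export
make_branched_toy <- function(capacities = c(5, 5), sink_bound = 5) {
  stopifnot(length(capacities) >= 2, all(capacities >= 0), sink_bound >= 0)
  nb <- length(capacities)
  rxn <- data.frame(
    id = c("EX_src", paste0("BRANCH", seq_len(nb)), "BIOMASS"),
    equation = c("src[e] <=>",
                 rep("src[e] -> mid[c]", nb),
                 "mid[c] ->"),
    kind = c("exchange", rep("transport", nb), "biomass"),
    stringsAsFactors = FALSE)
  rxn$reversible <- c(TRUE, rep(FALSE, nb + 1L))
  rxn$lower_bound <- c(-1000, rep(0, nb + 1L))
  rxn$upper_bound <- c(1000, capacities, sink_bound)
  mets <- data.frame(id = c("src[e]", "mid[c]"), formula = "C",
                     stringsAsFactors = FALSE)
  build_model_from_equations(rxn, mets, objective_id = "BIOMASS")
}

#' Random quality-control network with recorded ground truth
#'
#' Generates a mass-balanced core network (a cycle over the metabolites
#' plus random chords, coefficients in \{1, 2\}, single-element formulas so
#' brute-force balance oracles are exact) and then injects a requested
#' number of defects, recording exactly what was injected:
#' * dead ends: extra metabolites attached as sole substrate
#'   (`no-producer`) or sole product (`no-consumer`) of one new reaction;
#' * elemental imbalances: the coefficient of one participant of a core
#'   reaction is incremented, shifting its elemental deficit.
#'
#' The same seed yields the identical model and ground truth.
#'
#' @param seed integer RNG seed.
#' @param n_metabolites,n_reactions core network size
#'   (`n_reactions >= n_metabolites`).
#' @param dead_end_fraction,unbalanced_fraction fractions in `[0, 1]` of
#'   `n_metabolites` (resp. `n_reactions`) to corrupt.
#' @return list with `model` and `ground_truth` (list with `dead_ends`, a
#'   data.frame like [find_dead_ends()] output, and `unbalanced`, a named
#'   list reaction id -> expected element deficit).
#' @export
make_random_network <- function(seed, n_metabolites = 12L, n_reactions = 18L,
                                dead_end_fraction = 0, unbalanced_fraction = 0) {
  stopifnot(n_metabolites >= 3)
  if (n_reactions < n_metabolites) {
    stop("infeasible spec: n_reactions must be >= n_metabolites ",
         "(the balanced core is a cycle)", call. = FALSE)
  }
  if (dead_end_fraction < 0 || dead_end_fraction > 1 ||
      unbalanced_fraction < 0 || unbalanced_fraction > 1) {
    stop("infeasible spec: fractions must lie in [0, 1]", call. = FALSE)
  }
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  m <- n_metabolites
  w <- sample(c(1L, 2L), m, replace = TRUE)       # elemental weight C_w
  met_ids <- sprintf("m%02d[c]", seq_len(m))
  coeffs_for <- function(wa, wb) {
    # a * wa == b * wb with a, b in {1, 2}
    if (wa == wb) c(1, 1) else if (wa * 2 == wb) c(2, 1) else c(1, 2)
  }
  mk_eq <- function(a, ca, b, cb) {
    paste0(if (ca > 1) paste0(ca, " ") else "", a, " -> ",
           if (cb > 1) paste0(cb, " ") else "", b)
  }
  eqs <- character(0)
  from <- c(seq_len(m))
  to <- c(seq_len(m) %% m + 1L)
  extra <- n_reactions - m
  if (extra > 0) {
    from <- c(from, sample(m, extra, replace = TRUE))
    shift <- sample(m - 1L, extra, replace = TRUE)
    to <- c(to, (from[(m + 1):(m + extra)] + shift - 1L) %% m + 1L)
  }
  for (k in seq_len(n_reactions)) {
    ab <- coeffs_for(w[from[k]], w[to[k]])
    eqs <- c(eqs, mk_eq(met_ids[from[k]], ab[1], met_ids[to[k]], ab[2]))
  }
  rxn <- data.frame(id = sprintf("r%03d", seq_len(n_reactions)),
                    equation = eqs, kind = "enzymatic",
                    reversible = FALSE, stringsAsFactors = FALSE)
  mets <- data.frame(id = met_ids, formula = paste0("C", w),
                     stringsAsFactors = FALSE)
  mets$formula[w == 1] <- "C"

  # inject dead ends: new species hanging off one new reaction each
  k_dead <- round(dead_end_fraction * m)
  dead <- data.frame(metabolite_id = character(0), mode = character(0),
                     stringsAsFactors = FALSE)
  if (k_dead > 0) {
    for (d in seq_len(k_dead)) {
      did <- sprintf("dead%02d[c]", d)
      host <- sample(m, 1)
      mode <- sample(c("no-producer", "no-consumer"), 1)
      ab <- coeffs_for(1L, w[host])
      eq <- if (mode == "no-producer") {
        mk_eq(did, ab[1], met_ids[host], ab[2])
      } else {
        mk_eq(met_ids[host], ab[2], did, ab[1])
      }
      rxn <- rbind(rxn, data.frame(id = sprintf("rdead%02d", d), equation = eq,
                                   kind = "enzymatic", reversible = FALSE,
                                   stringsAsFactors = FALSE))
      mets <- rbind(mets, data.frame(id = did, formula = "C",
                                     stringsAsFactors = FALSE))
      dead <- rbind(dead, data.frame(metabolite_id = did, mode = mode,
                                     stringsAsFactors = FALSE))
    }
  }

  model <- build_model_from_equations(rxn, mets, validate = TRUE)

  # inject imbalances into core reactions by bumping one coefficient
  k_unbal <- round(unbalanced_fraction * n_reactions)
  unbal <- list()
  if (k_unbal > 0) {
    victims <- sample(n_reactions, k_unbal)
    for (v in victims) {
      st <- model$reactions$stoichiometry[[v]]
      p <- sample(length(st), 1)
      bump <- sign(st[p])          # push the existing side further
      st[p] <- st[p] + bump
      model$reactions$stoichiometry[[v]] <- st
      wt <- parse_formula(model$metabolites$formula[
        match(names(st)[p], model$metabolites$id)])
      unbal[[model$reactions$id[v]]] <- wt * bump
    }
  }
  list(model = model,
       ground_truth = list(dead_ends = dead, unbalanced = unbal))
}

#' The curated mini-halophile fixture
#'
#' A deterministic ~45-reaction model emulating the parts of a halophile
#' reconstruction this package analyzes: glucose / choline / alanine /
#' nitrate / O2 / ammonia / NaCl exchanges, a lumped but elementally
#' balanced glycolysis-TCA-oxidative-phosphorylation energy module with
#' lactate fermentation, aspartate and glutamate nodes, the full four-step
#' ectoine branch (aspartate kinase EC 2.7.2.4, ASA dehydrogenase EC
#' 1.2.1.11, both diaminobutyrate transaminases EC 2.6.1.76 / EC 2.6.1.46,
#' DA acetyltransferase EC 2.3.1.178, ectoine synthase EC 4.2.1.108), the
#' two-step choline-betaine pathway with both step-one enzymes (choline
#' dehydrogenase EC 1.1.99.1, choline monooxygenase EC 1.14.15.7, then
#' betaine aldehyde dehydrogenase EC 1.2.1.8), an osmolyte requirement in
#' the biomass reaction satisfiable by either betaine or ectoine, and
#' betaine/ectoine export routes.
#'
#' Every non-boundary reaction with full formula coverage is elementally
#' balanced; redox is carried by an NAD/NADH pair written as an H2
#' carrier. Stoichiometric coefficients are chosen for balance and
#' convenient rational optima, not biological accuracy: the fixture's
#' purpose is contractual testing of the analysis stack.
#'
#' @return a `metabolic_model` with objective `BIOMASS`.
#' @seealso [mini_halophile_phenotypes()] for the fixture's declared
#'   substrate phenotypes.
#' @examples
#' m <- make_mini_halophile()
#' solve_fba(m, constraints = set_medium(m, c(glc = 3)))
#' @export
make_mini_halophile <- function() {
  mets <- data.frame(rbind(
    c("glc",    "D-glucose",              "C6H12O6",        "e,c"),
    c("o2",     "oxygen",                 "O2",             "e,c"),
    c("co2",    "carbon dioxide",         "CO2",            "e,c"),
    c("h2o",    "water",                  "H2O",            "e,c"),
    c("nh3",    "ammonia",                "H3N",            "e,c"),
    c("no3",    "nitrate",                "HNO3",           "e,c"),
    c("no2",    "nitrite",                "HNO2",           "e,c"),
    c("nacl",   "sodium chloride",        "ClNa",           "e,c"),
    c("lac",    "lactate",                "C3H6O3",         "e,c"),
    c("cho",    "choline",                "C5H13NO",        "e,c"),
    c("bet",    "glycine betaine",        "C5H11NO2",       "e,c"),
    c("ect",    "ectoine",                "C6H10N2O2",      "e,c"),
    c("ala",    "L-alanine",              "C3H7NO2",        "e,c"),
    c("atp",    "ATP",                    "C10H16N5O13P3",  "c"),
    c("adp",    "ADP",                    "C10H15N5O10P2",  "c"),
    c("pi",     "phosphate",              "H3O4P",          "c"),
    c("nad",    "NAD",                    "C21H27N7O14P2",  "c"),
    c("nadh",   "NADH (H2 carrier form)", "C21H29N7O14P2",  "c"),
    c("coa",    "coenzyme A",             "C21H36N7O16P3S", "c"),
    c("accoa",  "acetyl-CoA",             "C23H38N7O17P3S", "c"),
    c("pyr",    "pyruvate",               "C3H4O3",         "c"),
    c("cit",    "citrate",                "C6H8O7",         "c"),
    c("akg",    "2-oxoglutarate",         "C5H6O5",         "c"),
    c("oaa",    "oxaloacetate",           "C4H4O5",         "c"),
    c("glu",    "L-glutamate",            "C5H9NO4",        "c"),
    c("asp",    "L-aspartate",            "C4H7NO4",        "c"),
    c("aspp",   "4-phospho-L-aspartate",  "C4H8NO7P",       "c"),
    c("asa",    "aspartate semialdehyde", "C4H7NO3",        "c"),
    c("dab",    "L-2,4-diaminobutyrate",  "C4H10N2O2",      "c"),
    c("nada",   "N-acetyl-diaminobutyrate", "C6H12N2O3",    "c"),
    c("betald", "betaine aldehyde",       "C5H11NO",        "c"),
    c("osm",    "osmoprotectant unit",    NA,               "c")
  ), stringsAsFactors = FALSE)
  names(mets) <- c("base", "name", "formula", "comps")
  expand <- do.call(rbind, lapply(seq_len(nrow(mets)), function(i) {
    comps <- strsplit(mets$comps[i], ",")[[1]]
    data.frame(id = paste0(mets$base[i], "[", comps, "]"),
               name = mets$name[i], compartment = comps,
               formula = mets$formula[i], charge = 0, stringsAsFactors = FALSE)
  }))
  expand$charge[is.na(expand$formula)] <- NA_real_

  R <- function(id, equation, kind = "enzymatic", ec = "", gene = "",
                subsystem = "central metabolism", name = id) {
    data.frame(id = id, name = name, equation = equation, kind = kind,
               ec = ec, gene = gene, subsystem = subsystem,
               stringsAsFactors = FALSE)
  }
  rx <- rbind(
    # boundary
    R("EX_glc",  "glc[e] <=>",  "exchange", subsystem = "exchange"),
    R("EX_o2",   "o2[e] <=>",   "exchange", subsystem = "exchange"),
    R("EX_co2",  "co2[e] <=>",  "exchange", subsystem = "exchange"),
    R("EX_h2o",  "h2o[e] <=>",  "exchange", subsystem = "exchange"),
    R("EX_nh3",  "nh3[e] <=>",  "exchange", subsystem = "exchange"),
    R("EX_no3",  "no3[e] <=>",  "exchange", subsystem = "exchange"),
    R("EX_no2",  "no2[e] <=>",  "exchange", subsystem = "exchange"),
    R("EX_nacl", "nacl[e] <=>", "exchange", subsystem = "exchange"),
    R("EX_lac",  "lac[e] <=>",  "exchange", subsystem = "exchange"),
    R("EX_cho",  "cho[e] <=>",  "exchange", subsystem = "exchange"),
    R("EX_bet",  "bet[e] <=>",  "exchange", subsystem = "exchange"),
    R("EX_ect",  "ect[e] <=>",  "exchange", subsystem = "exchange"),
    R("EX_ala",  "ala[e] <=>",  "exchange", subsystem = "exchange"),
    # transport
    R("T_glc",  "glc[e] -> glc[c]",   "transport", gene = "Csal0010", subsystem = "transport"),
    R("T_o2",   "o2[e] <=> o2[c]",    "transport", subsystem = "transport"),
    R("T_co2",  "co2[c] <=> co2[e]",  "transport", subsystem = "transport"),
    R("T_h2o",  "h2o[c] <=> h2o[e]",  "transport", subsystem = "transport"),
    R("T_nh3",  "nh3[e] <=> nh3[c]",  "transport", subsystem = "transport"),
    R("T_no3",  "no3[e] -> no3[c]",   "transport", subsystem = "transport"),
    R("T_no2",  "no2[c] -> no2[e]",   "transport", subsystem = "transport"),
    R("T_nacl", "nacl[e] -> nacl[c]", "transport", subsystem = "transport"),
    R("T_lac",  "lac[c] -> lac[e]",   "transport", subsystem = "transport"),
    R("T_cho",  "cho[e] -> cho[c]",   "transport", gene = "Csal3001", subsystem = "transport"),
    R("T_bet",  "bet[e] <=> bet[c]",  "transport", gene = "Csal3002", subsystem = "transport"),
    R("T_ect",  "ect[c] -> ect[e]",   "transport", subsystem = "transport"),
    R("T_ala",  "ala[e] -> ala[c]",   "transport", subsystem = "transport"),
    # energy core (lumped, balanced)
    R("GLYC", "glc[c] + 2 adp[c] + 2 pi[c] + 2 nad[c] -> 2 pyr[c] + 2 atp[c] + 2 nadh[c] + 2 h2o[c]",
      ec = "2.7.1.2", gene = "Csal0935", subsystem = "carbohydrate metabolism",
      name = "glycolysis (lumped)"),
    R("PDH", "pyr[c] + coa[c] + nad[c] -> accoa[c] + co2[c] + nadh[c]",
      ec = "1.2.4.1", gene = "Csal0101", name = "pyruvate dehydrogenase"),
    R("CS", "accoa[c] + oaa[c] + h2o[c] -> cit[c] + coa[c]",
      ec = "2.3.3.1", gene = "Csal0102", name = "citrate synthase"),
    R("CITAKG", "cit[c] + nad[c] -> akg[c] + co2[c] + nadh[c]",
      ec = "1.1.1.42", gene = "Csal0103", name = "citrate to 2-oxoglutarate (lumped)"),
    R("AKGOAA", "akg[c] + 3 nad[c] + 2 h2o[c] -> oaa[c] + co2[c] + 3 nadh[c]",
      ec = "1.2.4.2", gene = "Csal0111",
      name = "2-oxoglutarate to oxaloacetate (lumped TCA arm)"),
    R("PC", "pyr[c] + co2[c] + atp[c] + h2o[c] -> oaa[c] + adp[c] + pi[c]",
      ec = "6.4.1.1", gene = "Csal0104", name = "pyruvate carboxylase"),
    R("NADHOX", "2 nadh[c] + o2[c] + 4 adp[c] + 4 pi[c] -> 2 nad[c] + 4 atp[c] + 6 h2o[c]",
      ec = "1.9.3.1", gene = "Csal0105", subsystem = "energy metabolism",
      name = "respiratory chain (lumped)"),
    R("NAR", "nadh[c] + no3[c] + 2 adp[c] + 2 pi[c] -> nad[c] + no2[c] + 2 atp[c] + 3 h2o[c]",
      ec = "1.7.99.4", gene = "Csal0106", subsystem = "energy metabolism",
      name = "nitrate reductase (respiratory)"),
    R("LDH", "pyr[c] + nadh[c] -> lac[c] + nad[c]",
      ec = "1.1.1.27", gene = "Csal0107", name = "lactate dehydrogenase"),
    # amino acid nodes
    R("GDH", "akg[c] + nh3[c] + nadh[c] <=> glu[c] + nad[c] + h2o[c]",
      ec = "1.4.1.2", gene = "Csal0108", subsystem = "amino acid metabolism",
      name = "glutamate dehydrogenase"),
    R("AST", "oaa[c] + glu[c] <=> asp[c] + akg[c]",
      ec = "2.6.1.1", gene = "Csal0109", subsystem = "amino acid metabolism",
      name = "aspartate transaminase"),
    R("ALATA", "pyr[c] + glu[c] <=> ala[c] + akg[c]",
      ec = "2.6.1.2", gene = "Csal0110", subsystem = "amino acid metabolism",
      name = "alanine transaminase"),
    # ectoine branch
    R("ASK", "asp[c] + atp[c] -> aspp[c] + adp[c]",
      ec = "2.7.2.4", gene = "Csal0626", subsystem = "osmolyte biosynthesis",
      name = "aspartate kinase"),
    R("ASD", "aspp[c] + nadh[c] -> asa[c] + nad[c] + pi[c]",
      ec = "1.2.1.11", gene = "Csal2450", subsystem = "osmolyte biosynthesis",
      name = "aspartate-semialdehyde dehydrogenase"),
    R("DATG", "asa[c] + glu[c] -> dab[c] + akg[c]",
      ec = "2.6.1.76", gene = "Csal1877", subsystem = "osmolyte biosynthesis",
      name = "diaminobutyrate-2-oxoglutarate transaminase"),
    R("DATA", "asa[c] + ala[c] -> dab[c] + pyr[c]",
      ec = "2.6.1.46", gene = "Csal1877", subsystem = "osmolyte biosynthesis",
      name = "diaminobutyrate-pyruvate transaminase"),
    R("DAA", "dab[c] + accoa[c] -> nada[c] + coa[c]",
      ec = "2.3.1.178", gene = "Csal1876", subsystem = "osmolyte biosynthesis",
      name = "diaminobutyrate acetyltransferase"),
    R("ECTS", "nada[c] -> ect[c] + h2o[c]",
      ec = "4.2.1.108", gene = "Csal1878", subsystem = "osmolyte biosynthesis",
      name = "ectoine synthase"),
    # choline-betaine branch
    R("CDH", "cho[c] + nad[c] -> betald[c] + nadh[c]",
      ec = "1.1.99.1", gene = "Csal1514", subsystem = "osmolyte biosynthesis",
      name = "choline dehydrogenase"),
    R("CMO", "2 cho[c] + o2[c] -> 2 betald[c] + 2 h2o[c]",
      ec = "1.14.15.7", gene = "Csal2455", subsystem = "osmolyte biosynthesis",
      name = "choline monooxygenase"),
    R("BADH", "betald[c] + nad[c] + h2o[c] -> bet[c] + nadh[c]",
      ec = "1.2.1.8", gene = "Csal1515", subsystem = "osmolyte biosynthesis",
      name = "betaine aldehyde dehydrogenase"),
    # osmoprotectant pooling and growth
    R("OSM_BET", "bet[c] -> osm[c]", subsystem = "osmolyte biosynthesis",
      name = "betaine osmoprotectant commitment"),
    R("OSM_ECT", "ect[c] -> osm[c]", subsystem = "osmolyte biosynthesis",
      name = "ectoine osmoprotectant commitment"),
    R("BIOMASS",
      paste("30 atp[c] + 30 h2o[c] + 2 pyr[c] + asp[c] + glu[c] + ala[c]",
            "+ osm[c] + 0.1 nacl[c] -> 30 adp[c] + 30 pi[c]"),
      kind = "biomass", subsystem = "biomass", name = "biomass drain")
  )
  rxn <- data.frame(id = rx$id, name = rx$name, equation = rx$equation,
                    kind = rx$kind, subsystem = rx$subsystem,
                    gene_association = rx$gene, stringsAsFactors = FALSE)
  rxn$ec_numbers <- lapply(rx$ec, function(e)
    if (nzchar(e)) e else character(0))
  build_model_from_equations(rxn, expand, objective_id = "BIOMASS")
}

#' Declared substrate phenotypes of the mini-halophile fixture
#'
#' The fixture's ground-truth sole-carbon-source verdicts, derived from
#' its construction: glucose and alanine support growth; choline and
#' betaine can satisfy the osmolyte requirement but cannot supply biomass
#' precursors; lactate has an export-only transporter; sorbitol has no
#' transport route at all.
#'
#' @return data.frame with columns `substrate` and `in_vivo` (`"+"`/`"-"`),
#'   the reference column for concordance checks against
#'   [substrate_screen()] verdicts.
#' @export
mini_halophile_phenotypes <- function() {
  data.frame(
    substrate = c("glc", "ala", "cho", "bet", "lac", "sorbitol"),
    in_vivo = c("+", "+", "-", "-", "-", "-"),
    stringsAsFactors = FALSE)
}

#' In-vivo substrate utilization reference table
#'
#' The packaged transcription of the published in-vivo phenotype column
#' for *Chromohalobacter salexigens* (60 substrates plus four enzyme
#' activities), shipped so that concordance between in-silico verdicts and
#' the reported phenotypes can be computed offline against any
#' full-reconstruction model file.
#'
#' @return data.frame with columns `entry`, `type` (`substrate` or
#'   `activity`) and `in_vivo` (`"+"`/`"-"`).
#' @export
table2_reference <- function() {
  path <- system.file("extdata", "table2_invivo.tsv", package = "halofba",
                      mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
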