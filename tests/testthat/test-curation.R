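# brute-force dead-end oracle: double loop over (metabolite, reaction)
dead_end_oracle <- function(model) {
  out <- data.frame(metabolite_id = character(0), mode = character(0),
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(model$metabolites))) {
    id <- model$metabolites$id[i]
    prod <- FALSE
    cons <- FALSE
    for (j in seq_len(nrow(model$reactions))) {
      st <- model$reactions$stoichiometry[[j]]
      if (!id %in% names(st)) next
      c0 <- st[[id]]
      rev <- model$reactions$reversible[j]
      if (c0 > 0 || rev) prod <- TRUE
      if (c0 < 0 || rev) cons <- TRUE
    }
    if (!prod) out <- rbind(out, data.frame(metabolite_id = id,
                                            mode = "no-producer"))
    if (!cons) out <- rbind(out, data.frame(metabolite_id = id,
                                            mode = "no-consumer"))
  }
  out[order(out$metabolite_id, out$mode), , drop = FALSE]
}

test_that("dead-end detection matches the brute-force oracle on random networks", {
  for (seed in 101:110) {
    net <- make_random_network(seed, n_metabolites = 10, n_reactions = 15,
                               dead_end_fraction = runif(1, 0, 0.5))
    got <- find_dead_ends(net$model)
    want <- dead_end_oracle(net$model)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want, info = paste("seed", seed))
  }
})

test_that("injected dead ends are recovered exactly, clean networks are clean", {
  expect_equal(nrow(find_dead_ends(make_toy_chain(3, 5))), 0)
  net0 <- make_random_network(21, dead_end_fraction = 0)
  expect_equal(nrow(find_dead_ends(net0$model)), 0)
  for (seed in 31:35) {
    net <- make_random_network(seed, n_metabolites = 10, n_reactions = 14,
                               dead_end_fraction = 0.4)
    found <- find_dead_ends(net$model)
    truth <- net$ground_truth$dead_ends
    expect_equal(nrow(found), nrow(truth))
    expect_setequal(found$metabolite_id, truth$metabolite_id)
    m <- merge(found, truth, by = "metabolite_id")
    expect_equal(m$mode.x, m$mode.y)
  }
})

test_that("a missing pathway intermediate surfaces as a dead end", {
  # tagatose-like gap: phosphorylation of the 6-phosphate exists but the
  # upstream kinase from the imported sugar is missing
  rxn <- data.frame(
    id = c("EX_tag", "T_tag", "T6PK", "SINK"),
    equation = c("tag[e] <=>", "tag[e] -> tag[c]",
                 "tag6p[c] -> tagbp[c]", "tagbp[c] ->"),
    kind = c("exchange", "transport", "enzymatic", "enzymatic"),
    stringsAsFactors = FALSE)
  m <- halofba:::build_model_from_equations(rxn)
  de <- find_dead_ends(m)
  expect_true("tag[c]" %in% de$metabolite_id[de$mode == "no-consumer"])
  expect_true("tag6p[c]" %in% de$metabolite_id[de$mode == "no-producer"])
  # adding the missing kinase closes the gap
  rxn2 <- rbind(rxn, data.frame(id = "TK", equation = "tag[c] -> tag6p[c]",
                                kind = "enzymatic"))
  expect_equal(nrow(find_dead_ends(halofba:::build_model_from_equations(rxn2))), 0)
})

test_that("glucokinase bookkeeping: one proton missing, fixed by adding h[c]", {
  mets <- data.frame(
    id = c("glc[c]", "atp[c]", "g6p[c]", "adp[c]", "h[c]"),
    compartment = "c",
    formula = c("C6H12O6", "C10H12N5O13P3", "C6H11O9P", "C10H12N5O10P2", "H"),
    charge = c(0, -4, -2, -3, 1),
    stringsAsFactors = FALSE)
  broken <- parse_reaction_equation(
    "glc[c] + atp[c] -> g6p[c] + adp[c]")$stoichiometry
  d <- halofba:::reaction_deficit(broken, mets)
  expect_equal(d$elements, c(H = -1))
  expect_equal(d$charge, -1)
  fixed <- parse_reaction_equation(
    "glc[c] + atp[c] -> g6p[c] + adp[c] + h[c]")$stoichiometry
  d2 <- halofba:::reaction_deficit(fixed, mets)
  expect_equal(length(d2$elements), 0L)
  expect_equal(d2$charge, 0)
})

test_that("balance deficits are antisymmetric under reaction reversal", {
  net <- make_random_network(55, unbalanced_fraction = 0.3)
  m <- net$model
  for (j in seq_len(nrow(m$reactions))) {
    st <- m$reactions$stoichiometry[[j]]
    d_fwd <- halofba:::reaction_deficit(st, m$metabolites)
    d_rev <- halofba:::reaction_deficit(-st, m$metabolites)
    expect_equal(d_fwd$elements, -d_rev$elements[names(d_fwd$elements)])
  }
})

test_that("injected elemental imbalances are flagged exactly, balanced cores pass", {
  for (seed in 61:65) {
    net <- make_random_network(seed, n_metabolites = 10, n_reactions = 16,
                               unbalanced_fraction = 0.3)
    bal <- check_mass_charge_balance(net$model)
    flagged <- bal$reaction_id[bal$status == "unbalanced"]
    expect_setequal(flagged, names(net$ground_truth$unbalanced))
    for (id in flagged) {
      got <- bal$element_deficit[[match(id, bal$reaction_id)]]
      want <- net$ground_truth$unbalanced[[id]]
      expect_equal(got[names(want)], want, info = id)
    }
  }
})

test_that("formula parser handles Hill notation and rejects junk", {
  expect_equal(parse_formula("C6H12O6"), c(C = 6, H = 12, O = 6))
  expect_equal(parse_formula("H2O"), c(H = 2, O = 1))
  expect_equal(parse_formula("ClNa"), c(Cl = 1, Na = 1))
  expect_equal(parse_formula("C10H12N5O13P3"),
               c(C = 10, H = 12, N = 5, O = 13, P = 3))
  expect_error(parse_formula("C6H12O6!"), "formula-syntax")
  expect_error(parse_formula("6CH12"), "formula-syntax")
})

test_that("adjacency matrices are symmetric, zero-diagonal and correct on toys", {
  one <- halofba:::build_model_from_equations(
    data.frame(id = "r", equation = "a[c] -> b[c]", kind = "enzymatic",
               stringsAsFactors = FALSE))
  adj <- adjacency_matrices(one)
  expect_equal(sum(adj$metabolite), 2)  # single off-diagonal pair, both ways
  expect_equal(sum(adj$reaction), 0)

  chain <- make_toy_chain(4, 5)
  adj <- adjacency_matrices(chain)
  A <- as.matrix(adj$reaction)
  # consecutive chain reactions share a metabolite: a path graph
  ids <- chain$reactions$id
  for (k in seq_len(length(ids) - 1)) {
    expect_equal(A[ids[k], ids[k + 1]], 1)
  }
  expect_equal(sum(A), 2 * (length(ids) - 1))

  net <- make_random_network(77)
  adj <- adjacency_matrices(net$model)
  expect_equal(as.matrix(adj$metabolite), t(as.matrix(adj$metabolite)))
  expect_equal(as.matrix(adj$reaction), t(as.matrix(adj$reaction)))
  expect_equal(sum(Matrix::diag(adj$metabolite)), 0)
  expect_equal(sum(Matrix::diag(adj$reaction)), 0)
})

test_that("network statistics count consistently and are permutation-invariant", {
  m <- make_mini_halophile()
  st <- network_statistics(m)
  expect_equal(sum(st$reactions_by_kind), nrow(m$reactions))
  expect_equal(st$n_metabolites, sum(st$metabolites_by_compartment))
  expect_equal(sum(st$subsystem_distribution), 1, tolerance = 1e-12)
  # permute rows: counts identical
  set.seed(1)
  mp <- m
  mp$reactions <- mp$reactions[sample(nrow(mp$reactions)), ]
  mp$metabolites <- mp$metabolites[sample(nrow(mp$metabolites)), ]
  st2 <- network_statistics(mp)
  expect_equal(st2$reactions_by_kind, st$reactions_by_kind)
  expect_equal(st2$monofunctional_fraction, st$monofunctional_fraction)
  expect_equal(st2$subsystem_distribution[names(st$subsystem_distribution)],
               st$subsystem_distribution)
})

test_that("monofunctional fraction counts ECs catalyzing exactly one reaction", {
  rxn <- data.frame(
    id = c("r1", "r2", "r3"),
    equation = c("a[c] -> b[c]", "b[c] -> c[c]", "c[c] -> a[c]"),
    kind = "enzymatic", stringsAsFactors = FALSE)
  rxn$ec_numbers <- list("1.1.1.1", "1.1.1.1", "2.2.2.2")
  m <- halofba:::build_model_from_equations(rxn)
  # 1.1.1.1 catalyzes two reactions, 2.2.2.2 one -> fraction 1/2
  expect_equal(network_statistics(m)$monofunctional_fraction, 0.5)
  rxn$ec_numbers <- list("1.1.1.1", "1.1.1.1", "1.1.1.1")
  m2 <- halofba:::build_model_from_equations(rxn)
  expect_equal(network_statistics(m2)$monofunctional_fraction, 0)
})

test_that("cross-model comparison matches by formula signature, not id", {
  m <- make_mini_halophile()
  self <- compare_models(m, m)
  expect_equal(length(self$unique_a), 0)
  expect_equal(length(self$unique_b), 0)

  # rename every id; formulas unchanged -> all formula-covered reactions
  # are still shared, and the remainder resolves via a curated mapping
  ren <- m
  met_map <- stats::setNames(paste0("X", seq_len(nrow(m$metabolites))),
                             m$metabolites$id)
  ren$metabolites$id <- unname(met_map[m$metabolites$id])
  ren$reactions$id <- paste0("R", seq_len(nrow(m$reactions)))
  ren$reactions$stoichiometry <- lapply(m$reactions$stoichiometry, function(st)
    stats::setNames(unname(st), unname(met_map[names(st)])))
  ren$objective_id <- ren$reactions$id[match("BIOMASS", m$reactions$id)]
  cmp <- compare_models(m, ren)
  # only reactions touching the formula-free osmolyte pseudo-species differ
  osm_rxns <- c("OSM_BET", "OSM_ECT", "BIOMASS")
  expect_setequal(cmp$unique_a, osm_rxns)
  # a mapping override for that species restores full sharing
  cmp_map <- compare_models(m, ren,
                            mapping_b = c(stats::setNames("osm",
                                                          met_map["osm[c]"])))
  expect_equal(length(cmp_map$unique_a), 0)
  expect_equal(length(cmp_map$unique_b), 0)
  # symmetry
  rev_cmp <- compare_models(ren, m)
  expect_equal(nrow(rev_cmp$shared), nrow(cmp$shared))

  # chemically unrelated models share nothing
  cmp2 <- compare_models(make_toy_chain(2, 5), m)
  expect_equal(nrow(cmp2$shared), 0)
})

test_that("audit report on the curated fixture is clean and serializable", {
  m <- make_mini_halophile()
  rep <- audit_model(m)
  expect_equal(nrow(rep$dead_ends), 0)
  expect_equal(nrow(rep$unbalanced), 0)
  # the osmolyte pseudo-species is formula-free by design
  expect_true(all(c("OSM_BET", "OSM_ECT", "BIOMASS") %in% rep$unknown_formula))
  jp <- withr::local_tempfile(fileext = ".json")
  tp <- withr::local_tempfile(fileext = ".tsv")
  write_audit_report(rep, jp, tp)
  doc <- jsonlite::fromJSON(jp)
  expect_equal(doc$stats$n_reactions, nrow(m$reactions))
  expect_true(file.exists(tp))
})
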