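test_that("single-path chain is bound-limited at the uptake rate", {
  m <- make_toy_chain(1, uptake_bound = 5)
  sol <- solve_fba(m)
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objective_value, 5, tolerance = 1e-9)
  expect_equal(solve_fba(make_toy_chain(10, 2))$objective_value, 2,
               tolerance = 1e-9)
  expect_equal(solve_fba(make_toy_chain(3, 0))$objective_value, 0,
               tolerance = 1e-9)
})

test_that("optimal solutions satisfy steady state and bounds", {
  models <- list(make_toy_chain(4, 3), make_branched_toy(c(5, 5), 7),
                 make_mini_halophile())
  constraints <- list(NULL, NULL, set_medium(models[[3]], c(glc = 3)))
  for (k in seq_along(models)) {
    m <- models[[k]]
    sol <- solve_fba(m, constraints = constraints[[k]])
    expect_equal(sol$status, "optimal")
    S <- build_stoichiometric_matrix(m)
    resid <- max(abs(as.vector(S %*% sol$fluxes[colnames(S)])))
    expect_lt(resid, 1e-8)
    lb <- m$reactions$lower_bound
    ub <- m$reactions$upper_bound
    if (!is.null(constraints[[k]])) {
      i <- match(constraints[[k]]$reaction_id, m$reactions$id)
      lb[i] <- constraints[[k]]$lower
      ub[i] <- constraints[[k]]$upper
    }
    v <- sol$fluxes[m$reactions$id]
    expect_true(all(v >= lb - 1e-9 & v <= ub + 1e-9))
  }
})

test_that("infeasible and unbounded problems are reported distinctly", {
  m <- make_toy_chain(2, 5)
  # contradictory constraint: force flux the chain cannot carry
  bad <- data.frame(reaction_id = c("EX_s", "BIOMASS"),
                    lower = c(0, 1), upper = c(0, 2))
  sol <- solve_fba(m, constraints = bad)
  expect_equal(sol$status, "infeasible")
  expect_true(is.na(sol$objective_value))
  # missing bound on an internal cycle: flux can grow without limit
  rxn <- data.frame(
    id = c("r_ab", "r_ba"),
    equation = c("a[c] -> b[c]", "b[c] -> a[c]"),
    kind = "enzymatic", reversible = FALSE,
    lower_bound = 0, upper_bound = Inf, stringsAsFactors = FALSE)
  cyc <- halofba:::build_model_from_equations(rxn)
  sol2 <- solve_fba(cyc, objective_id = "r_ab")
  expect_equal(sol2$status, "unbounded")
})

test_that("solver agrees with vertex enumeration on random toy models", {
  for (seed in 201:240) {
    m <- random_fba_model(seed)
    got <- solve_fba(m)
    want <- fba_oracle(m)
    expect_identical(got$status, want$status, info = paste("seed", seed))
    if (got$status == "optimal") {
      expect_equal(got$objective_value, want$objective, tolerance = 1e-6,
                   info = paste("seed", seed))
    }
  }
})

test_that("relaxing an uptake bound never decreases the optimum", {
  m <- make_mini_halophile()
  rates <- c(1, 2, 3, 5, 8)
  g <- vapply(rates, function(r)
    solve_fba(m, constraints = set_medium(m, c(glc = r), mode = "max"))$objective_value,
    numeric(1))
  expect_true(all(diff(g) >= -1e-9))
})

test_that("growth is linear in a single limiting substrate", {
  m <- make_toy_chain(3, uptake_bound = 1000)
  g1 <- solve_fba(m, constraints = data.frame(reaction_id = "EX_s",
                                              lower = -2, upper = 0))
  g2 <- solve_fba(m, constraints = data.frame(reaction_id = "EX_s",
                                              lower = -4, upper = 0))
  expect_equal(g2$objective_value / g1$objective_value, 2, tolerance = 1e-6)
  mh <- make_mini_halophile()
  h1 <- solve_fba(mh, constraints = set_medium(mh, c(glc = 2)))
  h2 <- solve_fba(mh, constraints = set_medium(mh, c(glc = 4)))
  expect_equal(h2$objective_value / h1$objective_value, 2, tolerance = 1e-6)
})

test_that("FVA collapses on unique optima and spans parallel branches", {
  chain <- make_toy_chain(3, 5)
  fv <- flux_variability(chain)
  expect_true(all(abs(fv$vmax - fv$vmin) < 1e-6))
  expect_true(all(fv$vmin <= fv$flux_fba + 1e-7 &
                    fv$flux_fba <= fv$vmax + 1e-7))

  par2 <- make_branched_toy(c(5, 5), sink_bound = 5)
  fv2 <- flux_variability(par2)
  b <- match(c("BRANCH1", "BRANCH2"), fv2$reaction_id)
  expect_equal(fv2$vmax[b] - fv2$vmin[b], c(5, 5), tolerance = 1e-6)
  expect_equal(fv2$vmin[match("BIOMASS", fv2$reaction_id)], 5,
               tolerance = 1e-6)

  # closing one branch makes the optimum unique again
  par1 <- make_branched_toy(c(5, 0), sink_bound = 5)
  fv3 <- flux_variability(par1)
  expect_true(all(abs(fv3$vmax - fv3$vmin) < 1e-6))
})

test_that("FVA preserves the objective at both extremes (sandwich property)", {
  m <- make_mini_halophile()
  med <- set_medium(m, c(glc = 3))
  base <- solve_fba(m, constraints = med)
  fv <- flux_variability(m, constraints = med,
                         reactions = c("BIOMASS", "ECTS", "GLYC", "NADHOX"))
  expect_true(all(fv$vmin <= fv$flux_fba + 1e-6))
  expect_true(all(fv$flux_fba <= fv$vmax + 1e-6))
  j <- match("BIOMASS", fv$reaction_id)
  expect_equal(fv$vmin[j], base$objective_value, tolerance = 1e-5)
  expect_error(flux_variability(m, fraction = 0), "fraction")
  expect_error(flux_variability(m, fraction = 1.5), "fraction")
})

test_that("set_medium opens inorganics, closes organics, handles anaerobiosis", {
  m <- make_mini_halophile()
  med <- set_medium(m, c(glc = 3))
  row <- function(id) med[match(id, med$reaction_id), ]
  expect_equal(row("EX_glc")$lower, -3)
  expect_equal(row("EX_glc")$upper, -3)     # fixed-rate semantics
  expect_equal(row("EX_o2")$lower, -1000)   # aerobic: O2 open
  expect_equal(row("EX_cho")$lower, 0)      # organic carbon closed
  expect_equal(row("EX_ala")$lower, 0)
  expect_equal(row("EX_nh3")$lower, -1000)  # inorganic N open
  med_ana <- set_medium(m, c(glc = 3, no3 = 1), aerobic = FALSE)
  expect_equal(med_ana[match("EX_o2", med_ana$reaction_id), "lower"], 0)
  sol <- solve_fba(m, constraints = med_ana)
  expect_equal(sol$status, "optimal")
  expect_gt(sol$objective_value, 0)
  expect_lt(sol$objective_value,
            solve_fba(m, constraints = med)$objective_value)
  # empty medium: no carbon, no growth
  zero <- solve_fba(m, constraints = set_medium(m))
  expect_equal(zero$objective_value, 0, tolerance = 1e-9)
  expect_error(set_medium(m, c(unobtainium = 1)), "medium error")
  expect_error(set_medium(m, c(glc = -1)), ">= 0")
})
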