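# Independent oracles and generators used across the suite.
#
# lp_oracle solves max c'x s.t. Ax = b, lb <= x <= ub by exhaustive
# enumeration of basic solutions (all candidate vertices of the bounded
# polytope): every subset of rank(A) columns with the remaining variables
# pinned at a finite bound. Deliberately brute force and entirely separate
# from the package's simplex path.

lp_oracle <- function(obj, A, b = numeric(nrow(A)), lower, upper,
                      maximize = TRUE) {
  A <- as.matrix(A)
  n <- ncol(A)
  r <- if (nrow(A) > 0) qr(A)$rank else 0L
  bestval <- if (maximize) -Inf else Inf
  best <- NULL
  combos <- if (r > 0) utils::combn(n, r, simplify = FALSE) else list(integer(0))
  for (B in combos) {
    if (r > 0 && qr(A[, B, drop = FALSE])$rank < r) next
    qb <- if (r > 0) qr(A[, B, drop = FALSE]) else NULL
    N <- setdiff(seq_len(n), B)
    n_free <- length(N)
    for (mask in seq_len(max(1, 2^n_free)) - 1L) {
      xN <- numeric(n_free)
      ok <- TRUE
      for (k in seq_len(n_free)) {
        at_upper <- bitwAnd(mask, bitwShiftL(1L, k - 1L)) > 0L
        v <- if (at_upper) upper[N[k]] else lower[N[k]]
        if (!is.finite(v)) { ok <- FALSE; break }
        xN[k] <- v
      }
      if (!ok) next
      rhs <- b - if (n_free) as.vector(A[, N, drop = FALSE] %*% xN) else 0 * b
      xB <- if (r > 0) qr.coef(qb, rhs) else numeric(0)
      if (anyNA(xB)) next
      x <- numeric(n)
      x[N] <- xN
      if (r > 0) x[B] <- xB
      if (nrow(A) > 0 && max(abs(as.vector(A %*% x) - b)) > 1e-7) next
      if (any(x < lower - 1e-8) || any(x > upper + 1e-8)) next
      val <- sum(obj * x)
      if ((maximize && val > bestval) || (!maximize && val < bestval)) {
        bestval <- val
        best <- x
      }
    }
  }
  if (is.null(best)) {
    list(status = "infeasible", objective = NA_real_, x = NULL)
  } else {
    list(status = "optimal", objective = bestval, x = best)
  }
}

# FBA through the oracle: same contract as solve_fba for comparison.
fba_oracle <- function(model, objective_id = model$objective_id,
                       constraints = NULL, maximize = TRUE) {
  S <- as.matrix(build_stoichiometric_matrix(model))
  lb <- model$reactions$lower_bound
  ub <- model$reactions$upper_bound
  if (!is.null(constraints)) {
    k <- match(constraints$reaction_id, model$reactions$id)
    lb[k] <- constraints$lower
    ub[k] <- constraints$upper
  }
  obj <- as.numeric(model$reactions$id == objective_id)
  lp_oracle(obj, S, numeric(nrow(S)), lb, ub, maximize = maximize)
}

# Random small FBA toy: 2-4 metabolites, 4-8 reactions, integer
# stoichiometry, finite random bounds. Occasionally infeasible by
# construction (positive lower bounds), which is part of what the
# equivalence test covers.
random_fba_model <- function(seed) {
  set.seed(seed)
  m <- sample(2:4, 1)
  n <- sample(4:8, 1)
  mets <- sprintf("m%d[c]", seq_len(m))
  stoich <- vector("list", n)
  for (j in seq_len(n)) {
    k <- sample(seq_len(min(m, 3)), 1)
    rows <- sample(m, k)
    cf <- sample(c(-2, -1, 1, 2), k, replace = TRUE)
    stoich[[j]] <- stats::setNames(cf, mets[rows])
  }
  lb <- round(ifelse(runif(n) < 0.4, runif(n, -5, 0), 0), 1)
  ub <- round(lb + runif(n, 0.5, 8), 1)
  # rare forced-flux reactions make some toys infeasible on purpose
  force_k <- runif(n) < 0.1
  lb[force_k] <- round(runif(sum(force_k), 0.5, 2), 1)
  ub[force_k] <- lb[force_k] + 1
  rxn <- data.frame(id = sprintf("r%d", seq_len(n)),
                    reversible = lb < 0,
                    lower_bound = lb, upper_bound = ub,
                    kind = c(rep("enzymatic", n - 1), "biomass"),
                    stringsAsFactors = FALSE)
  rxn$stoichiometry <- stoich
  mets_df <- data.frame(id = mets, compartment = "c", stringsAsFactors = FALSE)
  metabolic_model(mets_df, rxn, objective_id = sprintf("r%d", n))
}

# Field-by-field model equality (order-sensitive), used by IO round trips.
expect_models_equal <- function(a, b, tol = 1e-9) {
  expect_equal(a$metabolites$id, b$metabolites$id)
  expect_equal(a$metabolites$compartment, b$metabolites$compartment)
  expect_equal(a$metabolites$formula, b$metabolites$formula)
  expect_equal(a$metabolites$charge, b$metabolites$charge, tolerance = tol)
  expect_equal(a$reactions$id, b$reactions$id)
  expect_equal(a$reactions$reversible, b$reactions$reversible)
  expect_equal(a$reactions$lower_bound, b$reactions$lower_bound, tolerance = tol)
  expect_equal(a$reactions$upper_bound, b$reactions$upper_bound, tolerance = tol)
  expect_equal(a$reactions$kind, b$reactions$kind)
  expect_equal(a$reactions$gene_association, b$reactions$gene_association)
  expect_equal(a$reactions$ec_numbers, b$reactions$ec_numbers)
  for (j in seq_len(nrow(a$reactions))) {
    sa <- a$reactions$stoichiometry[[j]]
    sb <- b$reactions$stoichiometry[[j]]
    expect_equal(sort(names(sa)), sort(names(sb)))
    expect_equal(sa[sort(names(sa))], sb[sort(names(sa))], tolerance = tol)
  }
  expect_equal(sort(a$genes), sort(b$genes))
  expect_equal(a$objective_id, b$objective_id)
}
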