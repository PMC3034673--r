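# Bounded-variable primal simplex.
#
# Solves   max (or min)  c'x
#          s.t.          A x = b,   lower <= x <= upper
#
# Dense two-phase implementation with Bland's anti-cycling rule and simple
# upper-bound handling (nonbasic variables rest at a finite bound; a pivot
# step may end in a bound flip). Problem sizes in this package are tiny
# (tens of variables), so the basis inverse is recomputed from scratch via
# LU each iteration; robustness is preferred over speed.
#
# Every variable must have at least one finite bound. Returns a list with
# status ("optimal" | "infeasible" | "unbounded"), objective and x.
solve_lp <- function(obj, A, b = numeric(nrow(A)), lower, upper,
                     maximize = TRUE, tol = 1e-9, max_iter = NULL) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(obj) == n, length(lower) == n, length(upper) == n,
            length(b) == m)
  if (any(lower > upper)) {
    return(list(status = "infeasible", objective = NA_real_,
                x = rep(NA_real_, n)))
  }
  if (n == 0L) {
    feas <- all(abs(b) <= 1e-7)
    return(list(status = if (feas) "optimal" else "infeasible",
                objective = if (feas) 0 else NA_real_, x = numeric(0)))
  }
  if (any(!is.finite(lower) & !is.finite(upper))) {
    stop("solve_lp: variables with both bounds infinite are not supported",
         call. = FALSE)
  }
  cc <- if (maximize) obj else -obj
  if (m == 0L) {
    # unconstrained box problem: optimum at the bound favoured by the cost
    xs <- ifelse(cc > 0, upper, ifelse(cc < 0, lower,
                                       ifelse(is.finite(lower), lower, upper)))
    if (any(!is.finite(xs) & abs(cc) > tol)) {
      return(list(status = "unbounded",
                  objective = if (maximize) Inf else -Inf,
                  x = rep(NA_real_, n)))
    }
    xs <- ifelse(is.finite(xs), xs, ifelse(is.finite(lower), lower, upper))
    return(list(status = "optimal", objective = sum(obj * xs), x = xs))
  }
  if (is.null(max_iter)) max_iter <- 200L * (n + m + 10L)

  # start: structurals nonbasic at a finite bound, artificials basic
  x <- ifelse(is.finite(lower), lower, upper)
  r <- b - as.vector(A %*% x)
  s <- ifelse(r >= 0, 1, -1)
  Aext <- cbind(A, diag(s, nrow = m))
  lo <- c(lower, rep(0, m))
  hi <- c(upper, rep(Inf, m))
  x <- c(x, abs(r))
  basis <- n + seq_len(m)
  is_basic <- c(rep(FALSE, n), rep(TRUE, m))

  run_phase <- function(cost) {
    it <- 0L
    repeat {
      it <- it + 1L
      if (it > max_iter) stop("solve_lp: iteration limit reached", call. = FALSE)
      B <- Aext[, basis, drop = FALSE]
      y <- tryCatch(solve(t(B), cost[basis]),
                    error = function(e) stop("solve_lp: singular basis",
                                             call. = FALSE))
      nonbasic <- which(!is_basic)
      red <- cost[nonbasic] - as.vector(t(Aext[, nonbasic, drop = FALSE]) %*% y)
      at_lo <- is.finite(lo[nonbasic]) &
        abs(x[nonbasic] - lo[nonbasic]) <= 1e-7 * (1 + abs(lo[nonbasic]))
      # a nonbasic fixed variable (lo == hi) can never improve
      fixed <- hi[nonbasic] - lo[nonbasic] <= tol
      improving <- !fixed & ((at_lo & red > tol) | (!at_lo & red < -tol))
      if (!any(improving)) return("optimal")
      q <- nonbasic[improving][which.min(nonbasic[improving])]  # Bland
      dir <- if (is.finite(lo[q]) &&
                 abs(x[q] - lo[q]) <= 1e-7 * (1 + abs(lo[q]))) 1 else -1
      w <- solve(B, Aext[, q])
      # how far can x[q] move by t*dir before a bound is hit?
      t_own <- hi[q] - lo[q]                     # its own opposite bound
      t_best <- t_own; leave <- 0L               # 0 = bound flip
      for (k in seq_len(m)) {
        d <- dir * w[k]                          # x[basis[k]] changes by -d*t
        if (d > tol) {
          tk <- (x[basis[k]] - lo[basis[k]]) / d
        } else if (d < -tol) {
          tk <- (hi[basis[k]] - x[basis[k]]) / (-d)
        } else next
        if (tk < t_best - tol ||
            (tk < t_best + tol && leave > 0L && basis[k] < basis[leave])) {
          t_best <- tk; leave <- k
        }
      }
      if (!is.finite(t_best)) return("unbounded")
      t_best <- max(t_best, 0)
      x[q] <<- x[q] + dir * t_best
      x[basis] <<- x[basis] - dir * t_best * w
      if (leave > 0L) {
        p <- basis[leave]
        # snap the leaving variable to the bound it hit
        x[p] <<- if (dir * w[leave] > 0) lo[p] else hi[p]
        is_basic[p] <<- FALSE
        is_basic[q] <<- TRUE
        basis[leave] <<- q
      }
      # else: bound flip, basis unchanged
    }
  }

  # phase I: drive the artificials to zero
  if (max(abs(r)) > tol) {
    st <- run_phase(c(rep(0, n), rep(-1, m)))
    if (st != "optimal" || sum(x[n + seq_len(m)]) > 1e-7) {
      return(list(status = "infeasible", objective = NA_real_,
                  x = rep(NA_real_, n)))
    }
  }
  # freeze artificials at zero for phase II
  hi[n + seq_len(m)] <- 0
  x[n + seq_len(m)] <- pmin(x[n + seq_len(m)], 0)
  x[n + seq_len(m)] <- pmax(x[n + seq_len(m)], 0)

  st <- run_phase(c(cc, rep(0, m)))
  if (st == "unbounded") {
    return(list(status = "unbounded", objective = if (maximize) Inf else -Inf,
                x = rep(NA_real_, n)))
  }
  xs <- x[seq_len(n)]
  # clean tiny bound violations from floating point
  xs <- pmin(pmax(xs, lower), upper)
  list(status = "optimal", objective = sum(obj * xs), x = xs)
}
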