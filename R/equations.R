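#' Parse a human-readable reaction equation
#'
#' The equation dialect writes each species as `id[compartment]`, e.g.
#' `"2 A[c] + B[c] -> C[c]"`. The arrow token `->` marks an irreversible
#' reaction, `<=>` a reversible one. Coefficients default to 1 and may be
#' decimal or a rational `p/q`. Either side may be empty, which is how
#' boundary (exchange, demand, biomass drain) reactions are written, e.g.
#' `"glc[e] <=>"`.
#'
#' Left-hand species receive negative coefficients (consumed), right-hand
#' species positive (produced). A species may not appear twice on one side;
#' a species appearing on both sides has its coefficients netted and must
#' not cancel to zero.
#'
#' @param text a single equation string.
#' @return a list with `stoichiometry` (named numeric vector,
#'   metabolite id -> signed coefficient) and `reversible` (logical).
#' @examples
#' parse_reaction_equation("atp[c] + glc[c] -> adp[c] + g6p[c] + h[c]")
#' parse_reaction_equation("A[e] <=> A[c]")
#' @export
parse_reaction_equation <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  arrow <- regexpr("<=>|<->|-->|->|=>", text)
  if (arrow == -1L) {
    stop("equation parse error at column 1: no arrow token ('->' or '<=>') in \"",
         text, "\"", call. = FALSE)
  }
  tok <- regmatches(text, arrow)
  reversible <- tok %in% c("<=>", "<->")
  lhs <- substr(text, 1L, arrow - 1L)
  rhs <- substr(text, arrow + attr(arrow, "match.length"), nchar(text))

  lt <- parse_equation_side(lhs, offset = 0L, text = text)
  rt <- parse_equation_side(rhs, offset = arrow + attr(arrow, "match.length") - 1L,
                            text = text)
  stoich <- c(-lt, rt)
  if (length(stoich) == 0L) {
    stop("equation parse error at column 1: empty stoichiometry in \"", text, "\"",
         call. = FALSE)
  }
  # net species occurring on both sides
  stoich <- tapply(stoich, names(stoich), sum)
  stoich <- stats::setNames(as.numeric(stoich), names(stoich))
  if (any(abs(stoich) < 1e-12)) {
    bad <- names(stoich)[abs(stoich) < 1e-12]
    stop("equation parse error: species cancel to zero coefficient: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  list(stoichiometry = stoich[order(names(stoich))], reversible = reversible)
}

# Parse one side of an equation into a named coefficient vector (all positive).
# `offset` is the 0-based column of the side's start within the full string,
# used to report 1-based column offsets in errors.
parse_equation_side <- function(side, offset, text) {
  if (!nzchar(trimws(side))) return(stats::setNames(numeric(0), character(0)))
  # split on '+' surrounded by whitespace; keep track of term positions
  terms <- strsplit(side, "\\s\\+\\s")[[1]]
  pos <- offset + 1L
  coefs <- numeric(0)
  species_re <- "^([A-Za-z0-9_:'.,()-]+)\\[([A-Za-z0-9]+)\\]$"
  for (term in terms) {
    col <- pos + nchar(term) - nchar(sub("^\\s+", "", term))  # first non-blank
    t <- trimws(term)
    pos <- pos + nchar(term) + 3L  # account for " + "
    if (!nzchar(t)) {
      stop("equation parse error at column ", col, ": empty term in \"", text,
           "\"", call. = FALSE)
    }
    parts <- strsplit(t, "\\s+")[[1]]
    coef <- 1
    if (length(parts) == 2L) {
      coef <- parse_coefficient(parts[1])
      if (is.na(coef)) {
        stop("equation parse error at column ", col, ": malformed coefficient \"",
             parts[1], "\" in \"", text, "\"", call. = FALSE)
      }
      t <- parts[2]
    } else if (length(parts) > 2L) {
      stop("equation parse error at column ", col, ": malformed term \"", t,
           "\" in \"", text, "\"", call. = FALSE)
    }
    if (!grepl(species_re, t)) {
      hint <- if (!grepl("\\[", t)) ": missing compartment tag" else ""
      stop("equation parse error at column ", col, ": malformed species token \"",
           t, "\"", hint, " in \"", text, "\"", call. = FALSE)
    }
    if (coef <= 0) {
      stop("equation parse error at column ", col,
           ": coefficient must be positive in \"", text, "\"", call. = FALSE)
    }
    if (t %in% names(coefs)) {
      stop("equation parse error at column ", col, ": duplicate species \"", t,
           "\" on one side of \"", text, "\"", call. = FALSE)
    }
    coefs[t] <- coef
  }
  coefs
}

parse_coefficient <- function(x) {
  if (grepl("^[0-9]+/[0-9]+$", x)) {
    pq <- as.numeric(strsplit(x, "/")[[1]])
    if (pq[2] == 0) return(NA_real_)
    return(pq[1] / pq[2])
  }
  suppressWarnings(as.numeric(x))
}

#' Format a stoichiometry map back into an equation string
#'
#' Inverse of [parse_reaction_equation()] up to term ordering and coefficient
#' formatting: species are emitted in alphabetical order within each side and
#' coefficients printed with full precision.
#'
#' @param stoichiometry named numeric vector, metabolite id -> signed
#'   coefficient (negative = consumed).
#' @param reversible logical; selects the arrow token.
#' @return a single equation string.
#' @export
format_reaction_equation <- function(stoichiometry, reversible = FALSE) {
  stopifnot(is.numeric(stoichiometry), !is.null(names(stoichiometry)))
  fmt_side <- function(ids, coefs) {
    if (length(ids) == 0L) return("")
    o <- order(ids)
    paste(vapply(o, function(i) {
      if (abs(coefs[i] - 1) < 1e-12) ids[i]
      else paste(format(coefs[i], digits = 15), ids[i])
    }, character(1)), collapse = " + ")
  }
  lhs <- fmt_side(names(stoichiometry)[stoichiometry < 0],
                  -stoichiometry[stoichiometry < 0])
  rhs <- fmt_side(names(stoichiometry)[stoichiometry > 0],
                  stoichiometry[stoichiometry > 0])
  arrow <- if (reversible) "<=>" else "->"
  trimws(paste(lhs, arrow, rhs))
}
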