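.mf_env <- new.env(parent = emptyenv())

#' Standard atomic weights
#'
#' The packaged table of IUPAC standard (average) atomic weights, as a
#' named numeric vector keyed by element symbol. Monoisotopic masses are
#' out of scope; all molecular weights in the package are averages.
#'
#' @return named numeric vector, daltons per atom
#' @examples
#' elementWeights()[c("C", "H", "N", "O")]
#' @export
elementWeights <- function() {
  if (is.null(.mf_env$weights)) {
    path <- system.file("extdata", "atomic_weights.tsv", package = "MacroForms",
      mustWork = TRUE)
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    w <- tab$weight
    names(w) <- tab$symbol
    .mf_env$weights <- w
  }
  .mf_env$weights
}

#' Render an element formula in Hill order
#'
#' Carbon first, then hydrogen, then the remaining elements alphabetically;
#' when no carbon is present all elements (including H) are ordered
#' alphabetically. Counts of one are implicit; zero-count entries are
#' dropped.
#'
#' @param f named integer vector of element counts
#' @return single character string, e.g. `"C2H5NO2"`
#' @examples
#' formulaString(c(C = 2L, H = 5L, N = 1L, O = 2L))
#' @export
formulaString <- function(f) {
  f <- f[f != 0]
  if (length(f) == 0L) return("")
  els <- names(f)
  if ("C" %in% els) {
    ord <- c(intersect(c("C", "H"), els), sort(setdiff(els, c("C", "H"))))
  } else {
    ord <- sort(els)
  }
  f <- f[ord]
  paste0(names(f), ifelse(f == 1L, "", f), collapse = "")
}

#' Parse an element formula string
#'
#' Inverse of [formulaString()] for plain formulas such as `"C9H17N3O4SSe"`.
#'
#' @param s formula string
#' @return named integer vector of element counts
#' @export
parseFormula <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  m <- gregexpr("[A-Z][a-z]?[0-9]*", s)[[1]]
  parts <- regmatches(s, gregexpr("[A-Z][a-z]?[0-9]*", s))[[1]]
  if (sum(nchar(parts)) != nchar(s))
    stop("malformed formula string: ", s)
  f <- integer()
  for (p in parts) {
    el <- sub("[0-9]*$", "", p)
    n <- sub("^[A-Za-z]+", "", p)
    n <- if (nzchar(n)) as.integer(n) else 1L
    f[el] <- (if (el %in% names(f)) f[[el]] else 0L) + n
  }
  f
}

# elementwise sum of two element formulas
addFormulas <- function(f, g) {
  els <- union(names(f), names(g))
  out <- integer(length(els))
  names(out) <- els
  out[names(f)] <- out[names(f)] + f
  out[names(g)] <- out[names(g)] + g
  out[out != 0L]
}

# f - g elementwise (may not go negative for chemically sensible input;
# negative counts are allowed here so callers can detect imbalance)
subtractFormulas <- function(f, g) addFormulas(f, -g)

scaleFormula <- function(f, n) {
  out <- f * as.integer(n)
  out[out != 0L]
}

formulaEqual <- function(f, g) {
  d <- subtractFormulas(f, g)
  length(d) == 0L
}

formulaWeight <- function(f) {
  w <- elementWeights()
  unknown <- setdiff(names(f), names(w))
  if (length(unknown))
    stop("no atomic weight for element(s): ", paste(unknown, collapse = ", "))
  sum(w[names(f)] * f)
}
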