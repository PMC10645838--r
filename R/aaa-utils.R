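#' @keywords internal
"_PACKAGE"

# Canonical keys for the six PMAA linkage classes, in reporting order.
LINKAGE_CLASSES <- c("t_fruf", "b21_fruf", "b26_fruf", "di_fruf",
                     "t_glcp", "i_glcp")

LINKAGE_LABELS <- c(
  t_fruf   = "t-Fruf",
  b21_fruf = "(2->1)-Fruf",
  b26_fruf = "(2->6)-Fruf",
  di_fruf  = "1,6-di-Fruf",
  t_glcp   = "t-Glcp",
  i_glcp   = "i-Glcp"
)

#' Round half away from zero
#'
#' Decimal rounding where a decimal part of exactly 0.5 always rounds up
#' (2.5 -> 3), unlike [round()]'s round-half-even. This is the convention used
#' throughout the molecule-assignment procedure.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 0).
#' @return numeric vector rounded half-up.
#' @examples
#' round_half_up(c(2.5, 2.4, 0.25), 0)
#' round_half_up(6.1333, 1)
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  # small nudge guards against values like 0.285 stored just below .5 ulp
  floor(x * scale + 0.5 + sqrt(.Machine$double.eps)) / scale
}

#' Normalise a census-like vector to the six canonical linkage classes
#'
#' Missing classes are filled with zero; extra names are an error.
#'
#' @param x named numeric vector or list using the canonical keys
#'   (`t_fruf`, `b21_fruf`, `b26_fruf`, `di_fruf`, `t_glcp`, `i_glcp`).
#' @return named numeric vector over all six classes, canonical order.
#' @export
as_census <- function(x) {
  x <- unlist(x)
  if (is.null(names(x)) && length(x) == length(LINKAGE_CLASSES)) {
    names(x) <- LINKAGE_CLASSES
  }
  bad <- setdiff(names(x), LINKAGE_CLASSES)
  if (length(bad)) {
    stop("unknown linkage class name(s): ", paste(bad, collapse = ", "),
         "; expected ", paste(LINKAGE_CLASSES, collapse = ", "))
  }
  out <- stats::setNames(numeric(length(LINKAGE_CLASSES)), LINKAGE_CLASSES)
  out[names(x)] <- as.numeric(x)
  if (any(out < 0)) stop("linkage census values must be non-negative")
  out
}

# Seed handling: run `expr` under a locally-set seed without disturbing the
# caller's RNG state; seed = NULL leaves the stream alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
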