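#' @keywords internal
"_PACKAGE"

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(expr)
}

# Stable, platform-independent integer hash of a string, used to derive
# per-iteration seeds that do not depend on iteration order.
stable_hash <- function(s) {
  codes <- utf8ToInt(s)
  h <- 0
  for (k in codes) h <- (h * 31 + k) %% 1000003L
  as.integer(h)
}

# Seeds must stay within the 32-bit integer range R accepts.
derive_seed <- function(base_seed, offset) {
  as.integer((as.numeric(base_seed) + as.numeric(offset)) %% 2147483647)
}

#' Format a proportion as a printed percentage
#'
#' Renders a proportion on the 0-100 scale to three significant figures, the
#' convention used for maturity and information-fraction percentages in
#' trial reports (e.g. 39/315 prints as "12.4", 171/152 prints as "112").
#'
#' @param p Proportion (events/denominator quotient, may exceed 1).
#' @return Character scalar, percentage without the \code{\%} sign.
#' @examples
#' format_percent(39 / 315)  # "12.4"
#' format_percent(171 / 152) # "112"
#' @export
format_percent <- function(p) {
  stopifnot(is.numeric(p), length(p) >= 1)
  vapply(p, function(pi) {
    if (is.na(pi)) return(NA_character_)
    format(signif(pi * 100, 3), scientific = FALSE, trim = TRUE)
  }, character(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
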