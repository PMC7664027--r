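# Internal helpers: error conditions, facility-name normalization, seeded
# child RNG streams.

config_error <- function(field, msg) {
  rlang::abort(
    sprintf("Invalid configuration: `%s` %s.", field, msg),
    class = "dhisclean_config_error",
    field = field
  )
}

format_error <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "dhisclean_format_error")
}

io_error <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "dhisclean_io_error")
}

domain_error <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "dhisclean_domain_error")
}

#' Normalize a facility name for matching
#'
#' Facility spellings differ between the national master list and DHIS2
#' exports; matching is done on a case-folded, whitespace-collapsed form of
#' the name. The same normalization is applied to county labels.
#'
#' @param x Character vector of names.
#' @return Character vector of normalized names.
#' @export
#' @examples
#' normalize_name(c("  Kijiji   Dispensary ", "KIJIJI dispensary"))
normalize_name <- function(x) {
  x <- tolower(trimws(as.character(x)))
  gsub("[[:space:]]+", " ", x)
}

facility_key <- function(name, county) {
  paste(normalize_name(name), normalize_name(county), sep = "|")
}

# Deterministic child seed derived from a root seed and up to three counters.
# Changing n_facilities must not reshuffle earlier facilities, so every
# (facility, year, area) triple gets its own stream. Arithmetic stays below
# 2^53 so doubles are exact; result is in [0, 2^31 - 2].
child_seed <- function(root, i = 0L, j = 0L, k = 0L) {
  m <- 2147483647
  s <- as.double(root) %% m
  for (ctr in c(i, j, k)) {
    s <- (s * 48271 + (as.double(ctr) + 1) * 506952114) %% m
  }
  as.integer(s)
}

# Evaluate `expr` under a temporary RNG seed, restoring global RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
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
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
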