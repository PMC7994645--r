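#' @keywords internal
"_PACKAGE"

#' Derive a reproducible seed from a master seed and a string key
#'
#' Per-drug and per-stage seeds are derived by stable string hashing so that
#' adding or reordering drugs never perturbs the random streams of the others.
#'
#' @param master Integer master seed.
#' @param key Character key (e.g. a drug id or stage name).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, key) {
  stopifnot(is.numeric(master), length(master) == 1L, length(key) == 1L)
  h <- 0
  for (ch in utf8ToInt(as.character(key))) h <- (h * 31 + ch) %% 2147483647
  as.integer((abs(master) + h) %% 2147483647)
}

#' Stable hash of an R object (for config/manifest fingerprints)
#'
#' Serializes the object to canonical JSON and hashes the string. Not
#' cryptographic; used only to fingerprint run configurations.
#'
#' @param x Any jsonlite-serializable object.
#' @return A character hash.
#' @export
config_hash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null")
  h1 <- 0; h2 <- 0
  for (ch in utf8ToInt(as.character(s))) {
    h1 <- (h1 * 31 + ch) %% 2147483647
    h2 <- (h2 * 131 + ch) %% 2147483629
  }
  sprintf("%08x%08x", h1, h2)
}

# type-7 quartiles used throughout (median and third quartile)
quartiles_q2_q3 <- function(x) {
  x <- x[!is.na(x)]
  stats::quantile(x, probs = c(0.5, 0.75), type = 7, names = FALSE)
}

msg <- function(verbose, ...) if (isTRUE(verbose)) message(sprintf(...))

`%||%` <- function(a, b) if (is.null(a)) b else a
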