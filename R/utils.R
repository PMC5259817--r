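# Internal helpers: seed substreams, alphabets, small validators.

# The 20 standard amino acids; X marks an indeterminate residue.
AA_STANDARD <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)
AA_ALLOWED <- c(AA_STANDARD, "X")
NT_ALLOWED <- c("A", "C", "G", "T", "N")

#' Derive a reproducible sub-seed from a master seed
#'
#' All stochastic steps in the package consume named sub-streams derived from
#' one master seed, so that e.g. the shuffled copies of a simulated target
#' database and its decoy database use disjoint, individually reproducible
#' random streams.
#'
#' @param master Integer master seed.
#' @param role Character label naming the consumer (e.g. `"decoy_shuffle"`).
#' @param index Integer index within the role (e.g. the copy number).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' substream_seed(1, "decoy_shuffle", 3)
substream_seed <- function(master, role = "main", index = 0L) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(role))
  h <- sum(utf8ToInt(role) * seq_along(utf8ToInt(role)))
  as.integer((abs(as.numeric(master)) * 48271 + h * 9973 +
                as.numeric(index) * 7919 + 12345) %% 2147483647)
}

assert_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %d, got %s",
                  name, min, paste(format(x), collapse = ",")))
  }
  invisible(as.integer(x))
}

assert_fraction <- function(x, name, lo = 0, hi = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi) {
    abort(sprintf("`%s` must be a single number in [%g, %g]", name, lo, hi))
  }
  invisible(as.numeric(x))
}

split_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]
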