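#' @keywords internal
"_PACKAGE"

# The 20 canonical amino-acid one-letter codes, alphabetical.
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Ambiguity / non-standard letters excluded from compositions.
AA_NONCANONICAL <- c("B", "J", "O", "U", "X", "Z")

#' Evaluate an expression under a temporary RNG state
#'
#' Seeds the R RNG with `seed`, evaluates `expr`, and restores the previous
#' RNG state so that generators are pure functions of their arguments and
#' never disturb the caller's random stream.
#'
#' @param seed Integer scalar seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive a reproducible child seed from a parent seed and a stream index,
# kept within the positive 32-bit integer range.
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 7919 + 104729 * stream) %% 2147483587) + 1L
}

#' Default background amino-acid composition
#'
#' A 20-entry composition modelled on average vertebrate proteome residue
#' frequencies, constrained so that D + E = 0.117 (D = 0.055, E = 0.062),
#' the acidic-residue background used throughout the charge-enrichment
#' analyses. The remaining 18 residues carry proteome-like proportions
#' rescaled to fill the remaining mass. These are configuration values,
#' not measured results.
#'
#' @return Named numeric vector of length 20 summing to 1.
#' @export
default_background <- function() {
  base <- c(
    A = 0.0826, C = 0.0137, F = 0.0386, G = 0.0708, H = 0.0228,
    I = 0.0593, K = 0.0582, L = 0.0965, M = 0.0241, N = 0.0406,
    P = 0.0472, Q = 0.0393, R = 0.0553, S = 0.0661, T = 0.0535,
    V = 0.0687, W = 0.0110, Y = 0.0292
  )
  base <- base / sum(base) * (1 - 0.117)
  freq <- c(base, D = 0.055, E = 0.062)
  freq <- freq[AA_ALPHABET]
  validate_background(freq)
}

#' Validate a background composition
#'
#' @param freq Named numeric vector over the 20 canonical residues.
#' @return The composition, reordered to the canonical alphabet.
#' @export
validate_background <- function(freq) {
  if (is.null(names(freq)) || !setequal(names(freq), AA_ALPHABET)) {
    stop("background composition must be named over the 20 canonical residues",
         call. = FALSE)
  }
  freq <- freq[AA_ALPHABET]
  if (any(freq < 0) || any(freq > 1)) {
    stop("background proportions must lie in [0, 1]", call. = FALSE)
  }
  if (abs(sum(freq) - 1) > 1e-9) {
    stop("background composition must sum to 1 (within 1e-9)", call. = FALSE)
  }
  structure(freq, class = "pc_background")
}

# Split peptide strings into a character matrix padded with NA (ragged ok).
split_peptides <- function(sequences) {
  strsplit(sequences, "", fixed = TRUE)
}

fmt_num <- function(x) formatC(x, format = "g", digits = 6)
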