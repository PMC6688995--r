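#' @useDynLib toxscan, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif rbinom
#' @importFrom utils read.delim write.table
NULL

#' Canonical amino-acid alphabet
#'
#' The 20 canonical one-letter codes, alphabetical. Ambiguity codes
#' (B, Z, U, O, J) are mapped to X on read; X contributes a score of 0 in
#' every profile column and is excluded from column counts.
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Background amino-acid frequencies
#'
#' Robinson & Robinson (1991) residue frequencies, renormalized to sum to
#' one. Used as the default profile background and as the emission
#' distribution for decoy proteins, which makes decoy scores directly
#' calibratable against the profile's log-odds.
#' @export
BACKGROUND_FREQS <- local({
  q <- c(A = 0.07805, C = 0.01925, D = 0.05364, E = 0.06295, F = 0.03856,
         G = 0.07377, H = 0.02199, I = 0.05142, K = 0.05744, L = 0.09019,
         M = 0.02243, N = 0.04487, P = 0.05203, Q = 0.04264, R = 0.05129,
         S = 0.07120, T = 0.05841, V = 0.06441, W = 0.01330, Y = 0.03216)
  q / sum(q)
})

#' Round half-up
#'
#' Deterministic half-up rounding (base R rounds half-even). All reported
#' percentages use 2 decimals under this rule, e.g. 1389/1546 -> 89.84.
#'
#' @param x non-negative numeric vector
#' @param digits decimal places
#' @export
round_half_up <- function(x, digits = 2) {
  stopifnot(all(x >= 0 | is.na(x)))
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Derive a stage seed from the run seed
#'
#' One global seed fans out to per-stage child seeds so stages are
#' independently re-runnable. The derivation is a fixed affine map modulo
#' a Mersenne prime; results stay below 2^31.
#'
#' @param seed integer run seed
#' @param stage stage name (character) or ordinal
#' @export
derive_seed <- function(seed, stage) {
  k <- if (is.character(stage)) {
    sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  } else {
    as.numeric(stage)
  }
  as.integer((as.numeric(seed) * 48271 + k * 7919) %% 2147483647)
}

# Split a protein string into single characters.
str_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# Map non-canonical residue letters to X (B/Z/U/O/J and anything else
# outside the 20-letter alphabet except the gap character).
canonicalize_aa <- function(x) {
  chartr("BZUOJ", "XXXXX", toupper(x))
}

# Encode residues as 1..20 column indices; X and unknowns become NA
# (scored 0 by the scan kernel).
encode_aa <- function(seq_string) {
  m <- match(str_chars(seq_string), AA_ALPHABET)
  m
}

# Write a data.frame as the package's TSV dialect: tab-separated, UTF-8,
# "." for missing, LF line endings, no quoting.
write_tsv_dialect <- function(df, path) {
  df2 <- df
  for (j in seq_along(df2)) {
    v <- df2[[j]]
    v <- as.character(v)
    v[is.na(v)] <- "."
    df2[[j]] <- v
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  write.table(df2, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}

read_tsv_dialect <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE, quote = "",
                   na.strings = ".", stringsAsFactors = FALSE,
                   check.names = FALSE)
  df
}

# Format a percent with fixed 2 decimals (half-up); NA -> "."
format_percent <- function(x) {
  ifelse(is.na(x), ".", sprintf("%.2f", round_half_up(x, 2)))
}
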