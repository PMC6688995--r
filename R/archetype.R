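#' Reference toxin archetype
#'
#' A fixed 449-residue reference effector used to seed the synthetic domain
#' families. Its layout mirrors the modular effectors the pipeline targets:
#' an N-terminal marker (FIX-like) region at positions 43-121, a C-terminal
#' nuclease (PoNe-like) toxin region at 283-449, and a conserved
#' Kx3GExnGIDx2YxnYx3ExK motif instance spanning positions 294-354 with the
#' catalytic aspartate at position 335. The background residues are drawn
#' once from [BACKGROUND_FREQS] under a fixed internal seed, so the
#' archetype is a package constant.
#'
#' @return An object of class \code{reference_archetype}: a list with
#'   \describe{
#'     \item{sequence}{the 449-residue protein string}
#'     \item{fix_region, pone_region}{1-based inclusive ranges c(43,121),
#'       c(283,449)}
#'     \item{motif_window}{c(294, 354)}
#'     \item{anchors}{named integer vector: reference positions of the ten
#'       motif anchor residues K,G,E,G,I,D,Y,Y,E,K}
#'     \item{catalytic_position}{335L}
#'   }
#' @export
reference_archetype <- function() {
  anchors <- c(K = 294L, G = 298L, E = 299L, G = 333L, I = 334L, D = 335L,
               Y = 338L, Y = 348L, E = 352L, K = 354L)
  seq_chars <- withr::with_seed(960745L, {
    sample(AA_ALPHABET, 449, replace = TRUE, prob = BACKGROUND_FREQS)
  })
  seq_chars[anchors] <- names(anchors)
  structure(
    list(sequence = paste(seq_chars, collapse = ""),
         fix_region = c(43L, 121L),
         pone_region = c(283L, 449L),
         motif_window = c(294L, 354L),
         anchors = anchors,
         catalytic_position = 335L),
    class = "reference_archetype"
  )
}

#' Emit one diverged family member from the archetype
#'
#' Per-site substitution at probability \code{divergence}, except at the ten
#' motif anchor columns where the rate is reduced tenfold
#' (\code{0.1 * divergence}) so the planted conservation signal survives
#' family divergence and the motif remains recoverable by the logo stage.
#' Substitutions replace the residue with a uniform draw from the other 19
#' letters; length is always preserved (the generator plants no indels).
#'
#' @param archetype a [reference_archetype()] object
#' @param divergence per-site substitution probability in [0, 1)
#' @param seed integer seed; identical inputs give identical output
#' @param region optional c(start, end) to emit only a subsequence (anchor
#'   positions outside the region are simply absent); defaults to the full
#'   protein
#' @return a protein string
#' @export
emit_family_member <- function(archetype, divergence, seed,
                               region = NULL) {
  stopifnot(inherits(archetype, "reference_archetype"))
  if (divergence < 0 || divergence >= 1) {
    stop("divergence must lie in [0, 1)")
  }
  full <- str_chars(archetype$sequence)
  if (is.null(region)) region <- c(1L, length(full))
  idx <- seq.int(region[1], region[2])
  chars <- full[idx]
  rate <- rep(divergence, length(idx))
  rate[idx %in% archetype$anchors] <- divergence * 0.1
  withr::with_seed(seed, {
    mut <- runif(length(idx)) < rate
    if (any(mut)) {
      for (i in which(mut)) {
        alt <- setdiff(AA_ALPHABET, chars[i])
        chars[i] <- alt[sample.int(19L, 1L)]
      }
    }
  })
  paste(chars, collapse = "")
}
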