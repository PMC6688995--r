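#' Reference-anchored multiple alignment
#'
#' Star alignment around a reference: each member is globally aligned to
#' the reference (BLOSUM62, gap opening 10, gap extension 0.5) and its
#' residues are projected onto reference columns; member insertions
#' relative to the reference are discarded, matching the downstream logo
#' convention that removes aligned columns not represented in the
#' reference. The result has exactly one column per reference position, and
#' column numbering equals reference numbering.
#'
#' @param reference single named protein string (names() gives the id) or a
#'   plain string
#' @param members named character vector of member proteins
#' @param reference_id id used when \code{reference} is unnamed
#' @return object of class "anchor_msa": list(reference_id, reference,
#'   mat) where mat is a character matrix (members x reference positions;
#'   "-" marks deletions relative to the reference)
#' @export
anchor_msa <- function(reference, members, reference_id = NULL) {
  if (length(members) == 0L) stop("empty member set")
  if (is.null(reference_id)) {
    reference_id <- if (!is.null(names(reference))) names(reference)[1] else
      "reference"
  }
  ref <- unname(canonicalize_aa(reference[1]))
  if (nchar(ref) == 0L) stop("empty reference")
  L <- nchar(ref)
  mat <- matrix("-", nrow = length(members), ncol = L,
                dimnames = list(names(members), NULL))
  for (m in seq_along(members)) {
    mem <- canonicalize_aa(members[[m]])
    if (identical(mem, ref)) {
      mat[m, ] <- str_chars(mem)
      next
    }
    pa <- pairwiseAlignment(mem, ref, substitutionMatrix = blosum62(),
                            gapOpening = 10, gapExtension = 0.5,
                            type = "global")
    p <- str_chars(as.character(Biostrings::alignedPattern(pa)))
    s <- str_chars(as.character(Biostrings::alignedSubject(pa)))
    col <- 0L
    for (j in seq_along(s)) {
      if (s[j] != "-") {
        col <- col + 1L
        mat[m, col] <- p[j]
      }
      # s[j] == "-": member insertion relative to the reference; dropped
    }
  }
  structure(list(reference_id = reference_id, reference = ref, mat = mat),
            class = "anchor_msa")
}

#' Per-column information content (sequence-logo math)
#'
#' Gap characters are excluded: frequencies p_a = c_a / sum(c) are over
#' observed residues only. H = -sum p_a log2 p_a, IC = log2(20) - H - e_n
#' with the optional small-sample correction e_n = 19 / (2 ln2 n), and
#' letter heights p_a * IC sum to IC.
#'
#' @param counts named residue counts for one column (sum >= 1)
#' @param small_sample apply the small-sample correction (default off)
#' @return list(counts, p, H, IC, e_n, heights)
#' @export
column_information <- function(counts, small_sample = FALSE) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n < 1) stop("all-gap column: no observed residues")
  p <- counts / n
  H <- -sum(p * log2(p))
  e_n <- if (small_sample) 19 / (2 * log(2) * n) else 0
  IC <- log2(20) - H - e_n
  list(counts = counts, p = p, H = H, IC = IC, e_n = e_n,
       heights = p * IC)
}

#' Logo table over a reference window
#'
#' One row per reference position within \code{window}: observed counts,
#' entropy H, information content IC (bits) and the dominant residue with
#' its frequency.
#'
#' @param msa an [anchor_msa()] object
#' @param window c(start, end) in reference coordinates; defaults to the
#'   full reference
#' @param small_sample apply the small-sample correction
#' @return data.frame(position, n, H, IC, top_residue, top_freq, gap_freq)
#' @export
logo_table <- function(msa, window = NULL,
                       small_sample = FALSE) {
  stopifnot(inherits(msa, "anchor_msa"))
  L <- ncol(msa$mat)
  if (is.null(window)) window <- c(1L, L)
  if (window[1] < 1L || window[2] > L || window[1] > window[2]) {
    stop("window outside reference length")
  }
  pos <- seq.int(window[1], window[2])
  rows <- lapply(pos, function(j) {
    col <- msa$mat[, j]
    res <- col[col != "-" & col != "X"]
    gap_freq <- mean(col == "-")
    if (!length(res)) {
      return(data.frame(position = j, n = 0L, H = NA_real_, IC = NA_real_,
                        top_residue = NA_character_, top_freq = NA_real_,
                        gap_freq = gap_freq, stringsAsFactors = FALSE))
    }
    counts <- table(res)
    ci <- column_information(c(counts), small_sample = small_sample)
    top <- which.max(ci$p)
    data.frame(position = j, n = sum(counts), H = ci$H, IC = ci$IC,
               top_residue = names(ci$p)[top], top_freq = unname(ci$p[top]),
               gap_freq = gap_freq, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Consensus motif in spacer-token notation
#'
#' Scans a reference window of an anchored MSA and emits one residue token
#' per column whose dominant residue frequency reaches \code{tau}; maximal
#' runs of k non-conserved columns collapse to a fixed spacer "x_k", or to
#' the variable spacer "x_n" when at least \code{gap_run_fraction} of
#' members carry a projected gap somewhere in the run (the run is
#' length-variable across the family). The compact string uses "x3"/"xn"
#' style tokens, e.g. "Kx3GExnGIDx2YxnYx3ExK".
#'
#' @param msa an [anchor_msa()] object
#' @param tau conservation threshold for residue tokens (default 0.5)
#' @param window c(start, end) reference range
#' @param gap_run_fraction member fraction with a gap that marks a spacer
#'   run length-variable (default 0.05)
#' @param small_sample passed to [logo_table()]
#' @return list(tokens = data.frame(token, type, start, end), motif =
#'   compact string, positions = reference positions of residue tokens)
#' @export
consensus_motif <- function(msa, tau = 0.5, window = NULL,
                            gap_run_fraction = 0.05, small_sample = FALSE) {
  lt <- logo_table(msa, window = window, small_sample = small_sample)
  if (nrow(lt) == 0L) stop("empty window")
  conserved <- !is.na(lt$top_freq) & lt$top_freq >= tau
  tokens <- list()
  i <- 1L
  while (i <= nrow(lt)) {
    if (conserved[i]) {
      tokens[[length(tokens) + 1L]] <- data.frame(
        token = lt$top_residue[i], type = "residue",
        start = lt$position[i], end = lt$position[i],
        stringsAsFactors = FALSE)
      i <- i + 1L
    } else {
      j <- i
      while (j < nrow(lt) && !conserved[j + 1L]) j <- j + 1L
      run_cols <- lt$position[i]:lt$position[j]
      gap_any <- mean(apply(
        msa$mat[, run_cols, drop = FALSE] == "-", 1L, any))
      k <- j - i + 1L
      tok <- if (gap_any >= gap_run_fraction) "xn" else paste0("x", k)
      tokens[[length(tokens) + 1L]] <- data.frame(
        token = tok, type = "spacer", start = lt$position[i],
        end = lt$position[j], stringsAsFactors = FALSE)
      i <- j + 1L
    }
  }
  tok_df <- do.call(rbind, tokens)
  list(tokens = tok_df,
       motif = paste(tok_df$token, collapse = ""),
       positions = tok_df$start[tok_df$type == "residue"])
}
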