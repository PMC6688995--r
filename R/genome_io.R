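#' @importFrom Biostrings readAAStringSet writeXStringSet AAStringSet
NULL

FEATURE_COLUMNS <- c("assembly_id", "organism", "contig_id", "feature_index",
                     "start", "end", "strand", "protein_id", "product",
                     "length_aa")

ANNOTATION_COLUMNS <- c("protein_id", "domain_name", "start", "end",
                        "score", "expect", "source")

#' Validate and normalize a feature table
#'
#' Coordinates are 1-based inclusive with start <= end; minus-strand genes
#' carry strand "-" (public feature tables sometimes report minus-strand
#' genes with start > end; \code{permissive = TRUE} normalizes such rows by
#' swapping the coordinates and setting strand to "-"). Rows are sorted by
#' (assembly, contig, start) and \code{feature_index} is (re)assigned as the
#' 1-based ordinal within each contig.
#'
#' @param df data.frame with the 10 documented columns
#' @param permissive normalize start > end rows instead of rejecting them
#' @export
validate_feature_table <- function(df, permissive = FALSE) {
  missing_cols <- setdiff(FEATURE_COLUMNS, names(df))
  if (length(missing_cols)) {
    stop("feature table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df <- df[FEATURE_COLUMNS]
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df$length_aa <- as.integer(df$length_aa)
  swapped <- df$start > df$end
  if (any(swapped)) {
    if (!permissive) {
      stop("start > end in feature table row(s): ",
           paste(which(swapped), collapse = ", "))
    }
    tmp <- df$start[swapped]
    df$start[swapped] <- df$end[swapped]
    df$end[swapped] <- tmp
    df$strand[swapped] <- "-"
  }
  if (!all(df$strand %in% c("+", "-"))) {
    stop("invalid strand: values must be '+' or '-'")
  }
  ord <- order(df$assembly_id, df$contig_id, df$start)
  df <- df[ord, , drop = FALSE]
  idx <- stats::ave(df$start,
                    paste(df$assembly_id, df$contig_id, sep = "\r"),
                    FUN = seq_along)
  df$feature_index <- as.integer(idx)
  prev_end <- stats::ave(df$end,
                         paste(df$assembly_id, df$contig_id, sep = "\r"),
                         FUN = function(e) c(-1L, e[-length(e)]))
  if (any(df$start <= prev_end & df$feature_index > 1L)) {
    stop("overlapping CDS on a contig")
  }
  rownames(df) <- NULL
  df
}

#' Read / write a CDS feature table
#'
#' Tab-separated, UTF-8, "." for missing values, header row required, the
#' 10 documented columns. write then read is the identity.
#'
#' @param path file path
#' @param permissive see [validate_feature_table()]
#' @export
read_feature_table <- function(path, permissive = FALSE) {
  df <- read_tsv_dialect(path)
  validate_feature_table(df, permissive = permissive)
}

#' @rdname read_feature_table
#' @param table validated feature table
#' @export
write_feature_table <- function(table, path) {
  table <- validate_feature_table(table)
  write_tsv_dialect(table, path)
}

#' Read / write domain-annotation tables
#'
#' Houses externally produced domain calls (conserved-domain profiles,
#' DUF1911/DUF1910 immunity domains, T6SS core-component COGs, signal
#' peptide predictors "Phobius"/"SignalP") as well as the package's own
#' scan output. Columns: protein_id, domain_name, start, end, score (bits),
#' expect (E-value), source ("internal-scan" or "external-table").
#'
#' @param path file path
#' @export
read_domain_annotations <- function(path) {
  df <- read_tsv_dialect(path)
  missing_cols <- setdiff(ANNOTATION_COLUMNS, names(df))
  if (length(missing_cols)) {
    stop("annotation table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df <- df[ANNOTATION_COLUMNS]
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df$score <- as.numeric(df$score)
  df$expect <- as.numeric(df$expect)
  bad <- !is.na(df$start) & !is.na(df$end) &
    (df$start < 1L | df$start > df$end)
  if (any(bad)) stop("invalid domain coordinates (need 1 <= start <= end)")
  if (any(!is.na(df$expect) & df$expect < 0)) stop("expect must be >= 0")
  df
}

#' @rdname read_domain_annotations
#' @param annotations annotation data.frame
#' @export
write_domain_annotations <- function(annotations, path) {
  write_tsv_dialect(annotations[ANNOTATION_COLUMNS], path)
}

#' Read / write protein FASTA
#'
#' Headers must be unique; B/Z/U/O/J are mapped to X on read. Sequences are
#' returned as a named character vector. Writing wraps at 60 characters.
#'
#' @param path file path
#' @export
read_fasta <- function(path) {
  ss <- readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA header: ", ids[duplicated(ids)][1])
  }
  seqs <- canonicalize_aa(as.character(ss))
  names(seqs) <- ids
  seqs
}

#' @rdname read_fasta
#' @param proteome named character vector of protein sequences
#' @export
write_fasta <- function(proteome, path) {
  if (anyDuplicated(names(proteome))) stop("duplicate FASTA header")
  ss <- AAStringSet(unlist(proteome))
  names(ss) <- names(proteome)
  writeXStringSet(ss, path, width = 60L)
  invisible(path)
}

#' Read an aligned FASTA (protein or nucleotide)
#'
#' All rows must have equal length; gaps are "-". Returns a named character
#' vector of gapped rows.
#'
#' @param path file path
#' @export
read_aligned_fasta <- function(path) {
  ss <- readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA header: ", ids[duplicated(ids)][1])
  }
  seqs <- toupper(as.character(ss))
  if (length(unique(nchar(seqs))) > 1L) {
    stop("alignment rows differ in length")
  }
  names(seqs) <- ids
  seqs
}

#' Write a tree in Newick format
#'
#' Serializes an \pkg{ape} "phylo" tree with branch lengths printed at a
#' fixed 6-decimal precision so outputs are byte-stable; the result parses
#' in standard Newick readers.
#'
#' @param tree an object of class "phylo"
#' @param path file path
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  n_tip <- length(tree$tip.label)
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  has_len <- !is.null(tree$edge.length)
  rec <- function(node) {
    if (node <= n_tip) return(tree$tip.label[node])
    kids <- children[[as.character(node)]]
    parts <- vapply(kids, function(e) {
      child <- tree$edge[e, 2]
      lab <- rec(child)
      if (has_len) paste0(lab, ":", sprintf("%.6f", tree$edge.length[e]))
      else lab
    }, character(1))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  root <- setdiff(unique(tree$edge[, 1]), tree$edge[, 2])[1]
  txt <- paste0(rec(root), ";")
  writeLines(txt, path, sep = "\n")
  invisible(txt)
}
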