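#' Select conserved alignment sites
#'
#' Conserved sites are columns with no gap and no ambiguity code in any
#' row: every row must carry A, C, G or T (case-insensitive). Complete
#' deletion -- one global conserved-site set -- matches a single printed
#' site count.
#'
#' @param alignment named character vector of equal-length aligned rows
#' @return integer vector of selected column indices
#' @export
select_conserved_sites <- function(alignment) {
  if (length(alignment) == 0L) stop("empty alignment")
  if (length(unique(nchar(alignment))) != 1L) {
    stop("alignment rows differ in length")
  }
  mat <- do.call(rbind, strsplit(toupper(alignment), "", fixed = TRUE))
  ok <- mat %in% c("A", "C", "G", "T")
  dim(ok) <- dim(mat)
  which(colSums(ok) == nrow(mat))
}

#' Jukes-Cantor (JC69) distance
#'
#' d = -(3/4) ln(1 - (4/3) p) for a mismatch proportion p in [0, 0.75);
#' monotone increasing with d(0) = 0 and d >= p. p >= 0.75 is saturated and
#' rejected.
#'
#' @param p proportion of differing sites over compared conserved sites
#' @export
jc69 <- function(p) {
  if (any(p < 0) || any(p >= 0.75)) {
    stop("saturated distance: mismatch proportion must lie in [0, 0.75)")
  }
  -0.75 * log(1 - 4 * p / 3)
}

#' JC69 distance matrix over conserved sites
#'
#' Pairwise mismatch proportions are computed over the selected columns
#' only (complete deletion) and corrected with [jc69()]. A saturated pair
#' (p >= 0.75) aborts with the taxon pair named.
#'
#' @param alignment named character vector of >= 2 aligned rows
#' @param sites conserved-site indices; defaults to
#'   [select_conserved_sites()]
#' @return symmetric numeric matrix with taxa as dimnames
#' @export
mismatch_matrix <- function(alignment, sites = NULL) {
  if (length(alignment) < 2L) stop("need at least 2 rows")
  if (is.null(sites)) sites <- select_conserved_sites(alignment)
  if (length(sites) == 0L) stop("zero conserved sites")
  mat <- do.call(rbind, strsplit(toupper(alignment), "",
                                 fixed = TRUE))[, sites, drop = FALSE]
  n <- nrow(mat)
  taxa <- names(alignment)
  d <- matrix(0, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      p <- mean(mat[i, ] != mat[j, ])
      if (p >= 0.75) {
        stop("saturated distance between ", taxa[i], " and ", taxa[j],
             " (p = ", sprintf("%.3f", p), ")")
      }
      d[i, j] <- d[j, i] <- jc69(p)
    }
  }
  d
}

#' Neighbor-joining tree
#'
#' Standard Saitou-Nei agglomeration (via \pkg{ape}) on a symmetric
#' distance matrix; exact on additive matrices. Negative branch-length
#' estimates are clamped to zero with a warning. The two-taxon case returns
#' a single split whose two pendant branches sum to d(1,2).
#'
#' @param d symmetric distance matrix with taxon dimnames
#' @return an unrooted "phylo" tree
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 2L) stop("need at least 2 taxa")
  if (!isSymmetric(unname(d), tol = 1e-8)) stop("non-symmetric matrix")
  if (nrow(d) == 2L) {
    tree <- structure(list(edge = matrix(c(3L, 1L, 3L, 2L), 2L, 2L,
                                         byrow = TRUE),
                           edge.length = rep(d[1, 2] / 2, 2L),
                           tip.label = rownames(d), Nnode = 1L),
                      class = "phylo")
    return(tree)
  }
  tree <- ape::nj(stats::as.dist(d))
  neg <- tree$edge.length < 0
  if (any(neg)) {
    warning(sum(neg), " negative branch length(s) clamped to 0")
    tree$edge.length[neg] <- 0
  }
  tree
}
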