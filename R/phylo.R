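# Distance-based tree scaffold: Kimura-corrected protein distances from
# pairwise local alignments, neighbor joining, Newick export. This stage
# only has to rank relative placement (for Pog-versus-classic anchoring);
# it makes no claim to model-based phylogenetic inference.

#' Kimura-corrected distance between two protein sequences
#'
#' `p` is the fraction of differing aligned columns of the local
#' alignment; the corrected distance is `-ln(1 - p - 0.2 p^2)`. The
#' correction is undefined for `p >= 0.85`; such pairs are capped at
#' `max_distance` and flagged.
#'
#' @param a,b Single-row `upo_records` or residue strings.
#' @param scheme Scoring scheme for the alignment.
#' @param max_distance Cap for saturated pairs.
#' @return Numeric distance, with attribute `capped = TRUE` when the cap
#'   applied. Zero aligned columns is an error.
#' @export
protein_distance <- function(a, b, scheme = scoring_scheme(),
                             max_distance = 5.0) {
  hit <- local_align(a, b, scheme)
  if (hit$ali_len == 0L) {
    stop("no aligned columns between '", hit$query, "' and '",
         hit$subject, "'")
  }
  p <- 1 - hit$nident / hit$ali_len
  if (p >= 0.85) {
    d <- max_distance
    attr(d, "capped") <- TRUE
    return(d)
  }
  -log(1 - p - 0.2 * p^2)
}

#' All-pairs Kimura-corrected distance matrix
#'
#' @param records A `upo_records` collection (n >= 2).
#' @param scheme Scoring scheme.
#' @param max_distance Saturation cap, see [protein_distance()].
#' @return Symmetric matrix with zero diagonal, dimnames = record ids.
#' @export
distance_matrix <- function(records, scheme = scoring_scheme(),
                            max_distance = 5.0) {
  stopifnot(inherits(records, "upo_records"), nrow(records) >= 2L)
  n <- nrow(records)
  D <- matrix(0, n, n, dimnames = list(records$id, records$id))
  for (i in 1:(n - 1L)) {
    for (j in (i + 1L):n) {
      d <- protein_distance(records[i, , drop = FALSE],
                            records[j, , drop = FALSE], scheme,
                            max_distance)
      D[i, j] <- D[j, i] <- as.numeric(d)
    }
  }
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Taxa are sorted lexicographically before agglomeration so the result
#' is invariant to input order; negative branch-length estimates are
#' clamped to zero and flagged. NJ reconstructs the generating tree
#' exactly whenever the matrix is additive.
#'
#' @param D Symmetric non-negative matrix with zero diagonal and taxon
#'   dimnames (n >= 2).
#' @return An `ape::phylo` tree, unrooted for n >= 3; attribute
#'   `clamped = TRUE` if any branch was clamped.
#' @export
nj_tree <- function(D) {
  D <- as.matrix(D)
  if (is.null(rownames(D))) stop("distance matrix needs taxon dimnames")
  n <- nrow(D)
  if (n < 2L) stop("need at least two taxa")
  if (max(abs(D - t(D))) > 1e-12) stop("distance matrix is not symmetric")
  if (any(D < 0)) stop("negative distances are not allowed")
  if (any(diag(D) != 0)) stop("diagonal must be zero")
  if (any(!is.finite(D))) stop("distances must be finite")
  ord <- order(rownames(D), method = "radix")
  D <- D[ord, ord]
  if (n == 2L) {
    tr <- list(edge = matrix(c(3L, 1L, 3L, 2L), 2, 2, byrow = TRUE),
               edge.length = rep(D[1, 2] / 2, 2),
               tip.label = rownames(D), Nnode = 1L)
    class(tr) <- "phylo"
    return(tr)
  }
  tr <- ape::nj(stats::as.dist(D))
  if (any(tr$edge.length < 0)) {
    tr$edge.length[tr$edge.length < 0] <- 0
    attr(tr, "clamped") <- TRUE
  }
  tr
}

#' Write a tree in Newick format
#'
#' Branch lengths are written with 6 significant digits; tip labels
#' containing whitespace or Newick metacharacters are single-quoted.
#'
#' @param tree An `ape::phylo`.
#' @param path Output path.
#' @return The Newick string, invisibly (also written to `path`).
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  labs <- tree$tip.label
  needs_quote <- grepl("[][\\s(),:;']", labs, perl = TRUE)
  placeholder <- sprintf("UPOTIP%06d", seq_along(labs))
  tree$tip.label <- ifelse(needs_quote, placeholder, labs)
  s <- ape::write.tree(tree, digits = 6)
  for (i in which(needs_quote)) {
    quoted <- paste0("'", gsub("'", "''", labs[i]), "'")
    s <- sub(placeholder[i], quoted, s, fixed = TRUE)
  }
  if (!is.null(path)) writeLines(s, path)
  invisible(s)
}

#' Export a distance matrix as square TSV
#'
#' PHYLIP-like square layout with a header row of taxon ids.
#'
#' @param D Symmetric matrix with taxon dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_distance_tsv <- function(D, path) {
  df <- data.frame(taxon = rownames(D), as.data.frame(D),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a square TSV distance matrix
#'
#' @param path File written by [write_distance_tsv()].
#' @return Numeric matrix with taxon dimnames.
#' @export
read_distance_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  D <- as.matrix(df[, -1, drop = FALSE])
  rownames(D) <- df[[1]]
  storage.mode(D) <- "double"
  D
}
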