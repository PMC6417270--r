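# Two clustering stages of the mining funnel:
#   1. greedy incremental identity clustering (cd-hit style): 90% identity
#      cut-off over the shorter sequence, word length 5;
#   2. Markov clustering (MCL) of the similarity graph at inflation 1.4,
#      keeping only the cluster that contains the seed sequence.

#' Construct a cluster set
#'
#' @param clusters List of character vectors of member ids (a disjoint
#'   cover of the clustered ids).
#' @param representative One member id per cluster.
#' @param method `"greedy"` or `"mcl"`.
#' @param converged Convergence flag (MCL only).
#' @return A `cluster_set`.
#' @export
cluster_set <- function(clusters, representative, method,
                        converged = TRUE) {
  stopifnot(length(clusters) == length(representative))
  structure(list(clusters = clusters, representative = representative,
                 method = method, converged = converged),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  sizes <- lengths(x$clusters)
  cat(sprintf("<cluster_set> %s: %d cluster(s), sizes %s\n", x$method,
              length(x$clusters),
              paste(sort(sizes, decreasing = TRUE), collapse = ",")))
  invisible(x)
}

#' Membership table of a cluster set
#'
#' @param cs A `cluster_set`.
#' @return data.frame with columns `cluster`, `member`,
#'   `is_representative`.
#' @export
cluster_table <- function(cs) {
  stopifnot(inherits(cs, "cluster_set"))
  do.call(rbind, lapply(seq_along(cs$clusters), function(k) {
    data.frame(cluster = k, member = cs$clusters[[k]],
               is_representative = cs$clusters[[k]] == cs$representative[k],
               stringsAsFactors = FALSE)
  }))
}

kmer_set <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  unique(substring(s, 1:(n - k + 1L), k:n))
}

#' Greedy incremental identity clustering
#'
#' Records are sorted by length (descending, ties by id) and processed in
#' order: each record joins the first existing cluster whose
#' representative shares at least `identity_threshold` identity --
#' identical aligned positions of the local alignment divided by the
#' shorter sequence's length -- otherwise it founds a new cluster as its
#' representative. A shared-`word_length`-mer prefilter skips only pairs
#' with zero shared words (and is bypassed for sequences shorter than the
#' word), so it can never change the clustering.
#'
#' @param records A `upo_records` collection.
#' @param identity_threshold Identity cut-off in (0, 1]; default 0.90.
#' @param word_length k-mer length of the prefilter; default 5.
#' @param scheme Scoring scheme for the local alignments.
#' @param use_prefilter Disable to force alignment of every pair (used to
#'   verify the prefilter is inert).
#' @return A `cluster_set` with method `"greedy"`.
#' @export
greedy_identity_cluster <- function(records, identity_threshold = 0.90,
                                    word_length = 5L,
                                    scheme = scoring_scheme(),
                                    use_prefilter = TRUE) {
  stopifnot(inherits(records, "upo_records"))
  if (identity_threshold <= 0 || identity_threshold > 1) {
    stop("identity_threshold must lie in (0, 1]")
  }
  ord <- order(-nchar(records$seq), records$id, method = "radix")
  recs <- records[ord, , drop = FALSE]
  clusters <- list()
  reps <- character(0)
  rep_words <- list()
  for (i in seq_len(nrow(recs))) {
    s <- recs$seq[i]
    words <- kmer_set(s, word_length)
    placed <- FALSE
    for (k in seq_along(clusters)) {
      if (use_prefilter && nchar(s) >= word_length &&
          length(rep_words[[k]]) &&
          !any(words %in% rep_words[[k]])) {
        next
      }
      rep_rec <- records[records$id == reps[k], , drop = FALSE]
      hit <- local_align(recs[i, , drop = FALSE], rep_rec, scheme)
      identity <- hit$nident / min(nchar(s), nchar(rep_rec$seq))
      if (identity >= identity_threshold) {
        clusters[[k]] <- c(clusters[[k]], recs$id[i])
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      clusters[[length(clusters) + 1L]] <- recs$id[i]
      reps <- c(reps, recs$id[i])
      rep_words[[length(rep_words) + 1L]] <- words
    }
  }
  cluster_set(clusters, reps, "greedy")
}

#' Build a weighted similarity graph from pairwise alignments
#'
#' Aligns every pair of records; an undirected edge is added when the
#' pair's E-value (database length = summed residues of the collection)
#' is at most `edge_E`. Weights are bit scores by default, or
#' `-log10(E)` (floored at 0).
#'
#' @param records A `upo_records` collection.
#' @param scheme A calibrated `scoring_scheme`.
#' @param edge_E E-value cut-off for keeping an edge.
#' @param weight `"bit"` or `"logE"`.
#' @return A `similarity_graph`: list with `nodes` and an `edges`
#'   data.frame (`from`, `to`, `weight`).
#' @export
build_similarity_graph <- function(records, scheme, edge_E = 10,
                                   weight = c("bit", "logE")) {
  stopifnot(inherits(records, "upo_records"))
  weight <- match.arg(weight)
  n_db <- sum(nchar(records$seq))
  ids <- records$id
  from <- character(0); to <- character(0); w <- numeric(0)
  if (nrow(records) >= 2L) {
    for (i in 1:(nrow(records) - 1L)) {
      for (j in (i + 1L):nrow(records)) {
        hit <- local_align(records[i, , drop = FALSE],
                           records[j, , drop = FALSE], scheme)
        ev <- evalue(hit$score, nchar(records$seq[i]), n_db, scheme)
        if (ev <= edge_E) {
          from <- c(from, ids[i]); to <- c(to, ids[j])
          w <- c(w, if (weight == "bit") bit_score(hit$score, scheme)
                 else max(0, -log10(ev)))
        }
      }
    }
  }
  similarity_graph(ids, data.frame(from = from, to = to, weight = w,
                                   stringsAsFactors = FALSE))
}

#' Construct a similarity graph from an edge list
#'
#' @param nodes Character vector of node ids.
#' @param edges data.frame with columns `from`, `to`, `weight`
#'   (non-negative; duplicate undirected edges are an error).
#' @return A `similarity_graph`.
#' @export
similarity_graph <- function(nodes, edges) {
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  if (any(edges$weight < 0)) stop("edge weights must be non-negative")
  if (!all(c(edges$from, edges$to) %in% nodes)) {
    stop("edge endpoints must be listed in nodes")
  }
  key <- paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to))
  if (anyDuplicated(key)) stop("duplicate undirected edge(s)")
  structure(list(nodes = as.character(nodes), edges = edges),
            class = "similarity_graph")
}

#' Markov clustering of a similarity graph
#'
#' Dense-matrix MCL: self-loops are added (weight = the node's maximum
#' incident edge weight, or 1 for isolated nodes), columns are normalized
#' to a stochastic matrix, then expansion (matrix squaring) and inflation
#' (elementwise power, column renormalization) alternate, pruning entries
#' below `prune`, until the largest absolute entry change drops below
#' `tol` or `max_iter` is reached (the latter yields a warning and a
#' `converged = FALSE` flag). Clusters are the connected components of
#' the converged matrix's non-zero pattern; cluster representatives are
#' the attractor nodes with the largest converged self-mass (ties broken
#' by id).
#'
#' @param graph A `similarity_graph`.
#' @param inflation Inflation exponent; default 1.4.
#' @param max_iter,tol,prune Iteration controls.
#' @return A `cluster_set` with method `"mcl"`.
#' @export
mcl_cluster <- function(graph, inflation = 1.4, max_iter = 100L,
                        tol = 1e-6, prune = 1e-8) {
  stopifnot(inherits(graph, "similarity_graph"))
  ids <- sort(graph$nodes)
  n <- length(ids)
  if (!n) stop("empty graph")
  M <- matrix(0, n, n, dimnames = list(ids, ids))
  if (nrow(graph$edges)) {
    fi <- match(graph$edges$from, ids)
    ti <- match(graph$edges$to, ids)
    M[cbind(fi, ti)] <- graph$edges$weight
    M[cbind(ti, fi)] <- graph$edges$weight
  }
  loop <- apply(M, 2, max)
  diag(M) <- ifelse(loop > 0, loop, 1)
  normalize <- function(A) sweep(A, 2, colSums(A), "/")
  M <- normalize(M)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    prev <- M
    M <- M %*% M
    M <- M^inflation
    M[M < prune] <- 0
    M <- normalize(M)
    if (max(abs(M - prev)) < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("MCL did not converge in ", max_iter, " iterations")
  }
  adj <- (M > 0) | (t(M) > 0)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  clusters <- split(ids, comp)
  self_mass <- diag(M)
  reps <- vapply(clusters, function(mem) {
    mem[order(-self_mass[mem], mem)][1]
  }, character(1))
  cluster_set(unname(clusters), unname(reps), "mcl",
              converged = converged)
}

#' Members of the cluster containing the seed sequence
#'
#' The MCL stage's purpose in the funnel: everything that does not
#' co-cluster with the seed is discarded as dissimilar.
#'
#' @param cs A `cluster_set`.
#' @param seed_id Id of the seed (query) sequence.
#' @return Character vector of member ids (including the seed).
#' @export
retain_seed_cluster <- function(cs, seed_id) {
  stopifnot(inherits(cs, "cluster_set"))
  for (mem in cs$clusters) {
    if (seed_id %in% mem) return(mem)
  }
  stop("seed '", seed_id, "' not present in the clustering")
}
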