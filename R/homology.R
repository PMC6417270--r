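# Homology screening: Smith-Waterman local alignment under BLOSUM62 with
# affine gaps, scored for significance with Karlin-Altschul extreme-value
# statistics (E = K * m * n * exp(-lambda * S)) and the classic two-tier
# thresholding: a loose reporting E-value and a strict inclusion E-value.
#
# A gap of length k costs gap_open + k * gap_extend (BLAST convention).

#' Build a scoring scheme
#'
#' @param matrix Substitution matrix name (`"BLOSUM62"`, `"BLOSUM50"`,
#'   `"PAM250"`, ...; resolved from Biostrings data) or a numeric matrix
#'   with residue dimnames.
#' @param gap_open,gap_extend Affine gap penalties (positive numbers; a
#'   gap of length k costs `gap_open + k * gap_extend`).
#' @param background Named residue background frequencies; default uniform
#'   over the 20 canonical residues.
#' @param lambda,K Karlin-Altschul parameters. Left `NULL` they are filled
#'   in by [calibrate_lambda()] (analytic, ungapped) or
#'   [calibrate_evalue()] (simulation, gapped).
#' @return A list of class `scoring_scheme`.
#' @export
scoring_scheme <- function(matrix = "BLOSUM62", gap_open = 11,
                           gap_extend = 1, background = NULL,
                           lambda = NULL, K = NULL) {
  if (is.character(matrix)) {
    nm <- matrix
    e <- new.env()
    utils::data(list = nm, package = "Biostrings", envir = e)
    matrix <- get(nm, envir = e)
  } else {
    nm <- "custom"
  }
  canonical <- setdiff(AA_ALPHABET21, "X")
  if (is.null(background)) {
    background <- stats::setNames(rep(1 / 20, 20), canonical)
  }
  background <- background / sum(background)
  if (abs(sum(background) - 1) > 1e-9) stop("background must sum to 1")
  structure(
    list(matrix_name = nm, matrix = matrix, gap_open = gap_open,
         gap_extend = gap_extend, background = background,
         lambda = lambda, K = K, calibration = "none"),
    class = "scoring_scheme"
  )
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cat(sprintf("<scoring_scheme> %s, gap %g/%g, lambda=%s K=%s (%s)\n",
              x$matrix_name, x$gap_open, x$gap_extend,
              if (is.null(x$lambda)) "?" else format(x$lambda, digits = 4),
              if (is.null(x$K)) "?" else format(x$K, digits = 4),
              x$calibration))
  invisible(x)
}

#' Analytic (ungapped) Karlin-Altschul lambda
#'
#' Solves `sum_ij p_i p_j exp(lambda * s_ij) = 1` for its unique positive
#' root, to relative tolerance 1e-9. Defined only for matrices with at
#' least one positive score and a negative expected score under the
#' background frequencies.
#'
#' @param scheme A `scoring_scheme`.
#' @return The scheme with `lambda` set and `calibration = "analytic"`.
#' @export
calibrate_lambda <- function(scheme) {
  stopifnot(inherits(scheme, "scoring_scheme"))
  p <- scheme$background
  res <- names(p)
  s <- scheme$matrix[res, res]
  w <- outer(p, p)
  expected <- sum(w * s)
  if (expected >= 0 || !any(s > 0)) {
    stop("calibration error: matrix needs a negative expected score ",
         "and at least one positive entry")
  }
  f <- function(lam) sum(w * exp(lam * s)) - 1
  hi <- 1
  while (f(hi) < 0) hi <- hi * 2
  lo <- 1e-6
  while (f(lo) > 0) lo <- lo / 2
  root <- stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
  scheme$lambda <- root
  if (is.null(scheme$K)) scheme$K <- 0.1
  scheme$calibration <- "analytic"
  scheme
}

random_seq <- function(n, p) {
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

#' Calibrate gapped E-value statistics by simulation
#'
#' Aligns `nsim` pairs of random sequences drawn from the background
#' frequencies and fits a Gumbel law to the Smith-Waterman scores by
#' maximum likelihood (method-of-moments initialization), then
#' `lambda = 1 / beta` and `K = exp(lambda * mu) / (m * n)`. This is the
#' standard empirical route to gapped-alignment statistics; the analytic
#' ungapped lambda of [calibrate_lambda()] does not apply once gaps are
#' allowed.
#'
#' @param scheme A `scoring_scheme`.
#' @param nsim Number of random pairs.
#' @param m,n Lengths of the simulated query and subject.
#' @param seed Integer seed for the simulation.
#' @return The scheme with `lambda` and `K` set and
#'   `calibration = "simulation"`.
#' @export
calibrate_evalue <- function(scheme, nsim = 600L, m = 200L, n = 200L,
                             seed = 1L) {
  stopifnot(inherits(scheme, "scoring_scheme"))
  p <- scheme$background
  scores <- withr_seed(seed, {
    vapply(seq_len(nsim), function(i) {
      a <- random_seq(m, p)
      b <- random_seq(n, p)
      as.numeric(Biostrings::pairwiseAlignment(
        Biostrings::AAString(a), Biostrings::AAString(b),
        substitutionMatrix = scheme$matrix,
        gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend,
        type = "local", scoreOnly = TRUE))
    }, numeric(1))
  })
  # Gumbel MLE: beta solves beta = mean(x) - sum(x w(x)) / sum(w(x)),
  # w(x) = exp(-x / beta); fixed-point iteration from the moment fit
  beta <- stats::sd(scores) * sqrt(6) / pi
  for (it in 1:200) {
    w <- exp(-(scores - max(scores)) / beta)  # shift for stability
    beta_new <- mean(scores) - sum(scores * w) / sum(w)
    if (abs(beta_new - beta) < 1e-10) break
    beta <- beta_new
  }
  mx <- max(scores)
  mu <- mx - beta * log(mean(exp(-(scores - mx) / beta)))
  lambda <- 1 / beta
  scheme$lambda <- lambda
  scheme$K <- exp(lambda * mu) / (as.numeric(m) * as.numeric(n))
  scheme$calibration <- "simulation"
  scheme
}

# run code under a local RNG seed without disturbing the caller's stream
withr_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

#' Smith-Waterman local alignment of two records
#'
#' @param a,b Single-row `upo_records` (or plain residue strings, in which
#'   case ids default to `"a"`/`"b"`).
#' @param scheme A `scoring_scheme`.
#' @return One-row data.frame: `query`, `subject`, `score`, `nident`,
#'   `ali_len` (aligned residue columns, gaps excluded), `pid_short`
#'   (identical columns over the shorter sequence length, in percent),
#'   `q_start`, `q_end`, `s_start`, `s_end` (1-based inclusive).
#' @export
local_align <- function(a, b, scheme = scoring_scheme()) {
  aid <- if (inherits(a, "upo_records")) a$id[1] else "a"
  bid <- if (inherits(b, "upo_records")) b$id[1] else "b"
  as_ <- if (inherits(a, "upo_records")) a$seq[1] else as.character(a)
  bs <- if (inherits(b, "upo_records")) b$seq[1] else as.character(b)
  if (!nzchar(as_) || !nzchar(bs)) stop("empty sequence in local_align")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(as_), Biostrings::AAString(bs),
    substitutionMatrix = scheme$matrix,
    gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend,
    type = "local")
  sc <- Biostrings::score(pa)
  if (sc <= 0) {
    return(data.frame(query = aid, subject = bid, score = max(0, sc),
                      nident = 0L, ali_len = 0L, pid_short = 0,
                      q_start = NA_integer_, q_end = NA_integer_,
                      s_start = NA_integer_, s_end = NA_integer_,
                      stringsAsFactors = FALSE))
  }
  nid <- Biostrings::nmatch(pa)
  nmm <- Biostrings::nmismatch(pa)
  data.frame(
    query = aid, subject = bid, score = sc,
    nident = nid, ali_len = nid + nmm,
    pid_short = 100 * nid / min(nchar(as_), nchar(bs)),
    q_start = Biostrings::start(Biostrings::pattern(pa)),
    q_end = Biostrings::end(Biostrings::pattern(pa)),
    s_start = Biostrings::start(Biostrings::subject(pa)),
    s_end = Biostrings::end(Biostrings::subject(pa)),
    stringsAsFactors = FALSE
  )
}

#' E-value of an alignment score
#'
#' `E = K * m * n * exp(-lambda * S)`: the expected number of chance
#' alignments scoring at least `S` between a length-`m` query and a
#' length-`n` database.
#'
#' @param score Raw alignment score(s).
#' @param m Query length.
#' @param n Database length (summed residues).
#' @param scheme A calibrated `scoring_scheme`.
#' @return Numeric E-value(s).
#' @export
evalue <- function(score, m, n, scheme) {
  if (is.null(scheme$lambda) || is.null(scheme$K)) {
    stop("scoring scheme is not calibrated; run calibrate_evalue() or ",
         "calibrate_lambda() first")
  }
  scheme$K * as.numeric(m) * as.numeric(n) * exp(-scheme$lambda * score)
}

#' Bit score of a raw alignment score
#'
#' @inheritParams evalue
#' @return `(lambda * S - ln K) / ln 2`.
#' @export
bit_score <- function(score, scheme) {
  (scheme$lambda * score - log(scheme$K)) / log(2)
}

#' Screen a proteome against a query sequence
#'
#' Aligns every proteome sequence to the query and partitions the hits by
#' the two-tier E-value rule: reported at `E <= report_E` (default 10.0)
#' and accepted at the inclusion threshold `E <= accept_E` (default 0.01,
#' i.e. about one chance acceptance per hundred searches). The database
#' length entering the E-value is the summed residue count of the
#' proteome.
#'
#' @param proteome A `upo_records` collection.
#' @param query A single-row `upo_records`.
#' @param scheme A calibrated `scoring_scheme`.
#' @param report_E,accept_E The two E-value tiers.
#' @return List with data.frames `accepted` and `reported` (the accepted
#'   set is a subset of the reported set), each ordered by E-value then
#'   subject id, with columns of [local_align()] plus `bit` and `evalue`.
#' @export
screen_proteome <- function(proteome, query, scheme,
                            report_E = 10.0, accept_E = 0.01) {
  stopifnot(inherits(proteome, "upo_records"))
  if (is.null(scheme$lambda) || is.null(scheme$K)) {
    stop("scoring scheme is not calibrated")
  }
  empty <- data.frame(query = character(0), subject = character(0),
                      score = numeric(0), nident = integer(0),
                      ali_len = integer(0), pid_short = numeric(0),
                      q_start = integer(0), q_end = integer(0),
                      s_start = integer(0), s_end = integer(0),
                      bit = numeric(0), evalue = numeric(0),
                      stringsAsFactors = FALSE)
  if (!nrow(proteome)) return(list(accepted = empty, reported = empty))
  n_db <- sum(nchar(proteome$seq))
  m <- nchar(query$seq[1])
  hits <- do.call(rbind, lapply(seq_len(nrow(proteome)), function(i) {
    local_align(query, proteome[i, , drop = FALSE], scheme)
  }))
  hits$bit <- bit_score(hits$score, scheme)
  hits$evalue <- evalue(hits$score, m, n_db, scheme)
  hits <- hits[order(hits$evalue, hits$subject, method = "radix"), ,
               drop = FALSE]
  rownames(hits) <- NULL
  list(accepted = hits[hits$evalue <= accept_E, , drop = FALSE],
       reported = hits[hits$evalue <= report_E, , drop = FALSE])
}
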