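# From grammar verdicts and motif evidence to the taxonomy: UPO
# subfamilies I-V, the peroxidase-peroxygenase (Pog) superfamily, classic
# CPOs, or unassigned; plus the short/long mass classes (Group-I around
# 29 kDa, Group-II around 44 kDa).

# Average (isotope-weighted) residue masses in Da; X is scored at a mean
# residue mass of 110 Da and flags the result as uncertain.
AA_RESIDUE_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326,
  X = 110.0
)
WATER_MASS <- 18.01528

#' Molecular weight of a protein sequence
#'
#' Sum of average residue masses plus one water for the intact chain
#' termini, in kDa. `X` residues are counted at 110 Da and flagged.
#'
#' @param seq Residue string or single-row `upo_records`.
#' @return Numeric kDa, with attribute `uncertain = TRUE` when the
#'   sequence contains `X`.
#' @examples
#' molecular_weight("G")  # free glycine, 0.07507 kDa
#' @export
molecular_weight <- function(seq) {
  s <- if (inherits(seq, "upo_records")) seq$seq[1] else as.character(seq)
  if (!nzchar(s)) stop("empty sequence has no molecular weight")
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  if (!all(ch %in% names(AA_RESIDUE_MASS))) {
    stop("sequence contains letters outside the 21-letter alphabet")
  }
  kda <- (sum(AA_RESIDUE_MASS[ch]) + WATER_MASS) / 1000
  if (any(ch == "X")) attr(kda, "uncertain") <- TRUE
  kda
}

#' Assign the short/long UPO mass class
#'
#' Group-I collects the short UPOs (average around 29 kDa), Group-II the
#' long ones (average around 44 kDa). The default cut at 35 kDa is the
#' midpoint of the two averages; the boundary is closed on the right
#' (exactly 35 kDa is Group-II).
#'
#' @param weight_kda Molecular weight in kDa.
#' @param threshold Cut-off in kDa.
#' @return `"Group-I"` or `"Group-II"`.
#' @export
assign_group <- function(weight_kda, threshold = 35.0) {
  ifelse(as.numeric(weight_kda) < threshold, "Group-I", "Group-II")
}

# The disulfide evidence rule of Subfamily I: at least two cysteines
# outside the PCP motif. Weak evidence -- the motif has no printed local
# pattern.
cys_pair_rule <- function(seq, grammar) {
  s <- if (inherits(seq, "upo_records")) seq$seq[1] else as.character(seq)
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  cys <- which(ch == "C")
  if (!is.na(grammar$cys_pos)) {
    pcp <- (grammar$cys_pos - 1L):(grammar$cys_pos + 1L)
    cys <- setdiff(cys, pcp)
  }
  length(cys) >= 2L
}

#' Classify a grammar-validated sequence into a UPO subfamily
#'
#' Scores each subfamily as the fraction of its signature motifs with at
#' least one hit; the arg-max subfamily is called when its score reaches
#' `min_score` and at least `min_motifs` of its signatures matched.
#' Ties at the top or sub-threshold scores yield `"unassigned"` (all
#' scores are still reported). Sequences with the chloroperoxidase
#' grammar bypass subfamily scoring and are flagged `"needs-tree"` for
#' Pog-versus-classic placement by [place_cpo()].
#'
#' @param grammar A `grammar_result` with class other than `"none"`.
#' @param hits Registry hit table from [scan_registry()] for the same
#'   sequence.
#' @param registry A `motif_registry`.
#' @param seq The sequence itself (needed for rule motifs such as the
#'   Subfamily-I cysteine-pair evidence and for the mass class).
#' @param min_score Minimum matched-signature fraction; default 0.5.
#' @param min_motifs Minimum number of matched signature motifs;
#'   default 2.
#' @param group_threshold Mass-class cut-off in kDa.
#' @return A list of class `subfamily_call`: `family` (`"I"`..`"V"`,
#'   `"Pog"`, `"classic_CPO"`, `"unassigned"`), `group`, `score`,
#'   `evidence` (matched signature motif names), `scores` (all five),
#'   `grammar_class`, `weight_kda`, `flags`.
#' @export
classify_subfamily <- function(grammar, hits, registry, seq,
                               min_score = 0.5, min_motifs = 2L,
                               group_threshold = 35.0) {
  stopifnot(inherits(grammar, "grammar_result"))
  if (grammar$class == "none") {
    stop("cannot classify a sequence without a core grammar")
  }
  w <- molecular_weight(seq)
  flags <- character(0)
  if (isTRUE(attr(w, "uncertain"))) flags <- c(flags, "weight-uncertain")
  group <- assign_group(w, group_threshold)

  if (grammar$class == "CPO_core") {
    return(structure(
      list(family = "unassigned", group = group, score = NA_real_,
           evidence = character(0), scores = NULL,
           grammar_class = grammar$class, weight_kda = as.numeric(w),
           flags = c(flags, "needs-tree")),
      class = "subfamily_call"))
  }

  sets <- signature_sets(registry)
  matched <- lapply(sets, function(motifs) {
    hit_ok <- vapply(motifs, function(mn) {
      m <- registry[[mn]]
      if (!is.na(m$rule)) {
        switch(m$rule,
               cys_pair = cys_pair_rule(seq, grammar),
               FALSE)
      } else {
        mn %in% hits$motif
      }
    }, logical(1))
    motifs[hit_ok]
  })
  scores <- vapply(seq_along(sets), function(i) {
    length(matched[[i]]) / length(sets[[i]])
  }, numeric(1))
  names(scores) <- names(sets)
  nmatched <- lengths(matched)

  top <- max(scores)
  winners <- names(scores)[scores == top]
  family <- "unassigned"
  evidence <- character(0)
  if (length(winners) == 1L && top >= min_score &&
      nmatched[[winners]] >= min_motifs) {
    family <- winners
    evidence <- matched[[winners]]
    if ("CYS_CYS" %in% evidence) flags <- c(flags, "weak-cys-evidence")
  } else if (length(winners) > 1L && top >= min_score) {
    flags <- c(flags, "tie")
  }
  structure(
    list(family = family, group = group,
         score = if (family == "unassigned") max(scores) else top,
         evidence = evidence, scores = scores,
         grammar_class = grammar$class, weight_kda = as.numeric(w),
         flags = flags),
    class = "subfamily_call")
}

#' @export
print.subfamily_call <- function(x, ...) {
  cat(sprintf("<subfamily_call> %s (%s, %.2f kDa, %s)", x$family,
              x$grammar_class, x$weight_kda, x$group))
  if (length(x$evidence)) {
    cat("  evidence:", paste(x$evidence, collapse = ","))
  }
  if (length(x$flags)) cat("  [", paste(x$flags, collapse = ","), "]")
  cat("\n")
  invisible(x)
}

#' Place a CPO-grammar sequence as Pog superfamily or classic CPO
#'
#' The Pog (peroxidase-peroxygenase) superfamily is a phylogenetic clade,
#' not a motif class, so placement is by tree proximity: the candidate is
#' Pog when its nearest anchor by path length in the tree is a Pog
#' exemplar (an MroUPO homolog), otherwise classic CPO. Exact ties go to
#' Pog with a tie flag (conservative toward the superfamily).
#'
#' @param call A `subfamily_call` for a CPO-grammar candidate.
#' @param tree An `ape::phylo` tree whose tips include the candidate and
#'   all anchors.
#' @param anchors Named list with elements `pog` and `cpo`, each a
#'   character vector of anchor tip labels.
#' @param candidate_id Tip label of the candidate.
#' @return The call with `family` set to `"Pog"` or `"classic_CPO"` and
#'   the `needs-tree` flag cleared.
#' @export
place_cpo <- function(call, tree, anchors, candidate_id) {
  stopifnot(inherits(call, "subfamily_call"), inherits(tree, "phylo"))
  if (length(setdiff(c("pog", "cpo"), names(anchors))) ||
      !length(anchors$pog) || !length(anchors$cpo)) {
    stop("anchors must supply both roles: pog (MroUPO-like exemplar) ",
         "and cpo (classic chloroperoxidase exemplar)")
  }
  tips <- tree$tip.label
  if (!candidate_id %in% tips) stop("candidate not in tree: ", candidate_id)
  if (!all(unlist(anchors[c("pog", "cpo")]) %in% tips)) {
    stop("all anchor tips must be present in the tree")
  }
  D <- stats::cophenetic(tree)
  d_pog <- min(D[candidate_id, anchors$pog])
  d_cpo <- min(D[candidate_id, anchors$cpo])
  call$family <- if (d_pog <= d_cpo) "Pog" else "classic_CPO"
  call$flags <- setdiff(call$flags, "needs-tree")
  if (d_pog == d_cpo) call$flags <- c(call$flags, "anchor-tie")
  call
}
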