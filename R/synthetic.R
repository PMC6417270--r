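# Seeded synthetic proteomes with planted, grammar-conformant UPO/CPO
# sequences and motif-free decoys. Planted sequences follow the printed
# AaeUPO anatomy (proximal Cys near 36, distal triad near 122-124,
# acid-base pair near 189/196) with seed-controlled jitter of up to ten
# positions per segment, so nothing downstream can get away with
# hard-coding coordinates. All planted UPOs descend from one master
# scaffold (the query stand-in), giving the homology stage a realistic
# similarity gradient: distinct subfamilies diverge strongly from the
# scaffold, within-subfamily siblings only mildly.

#' Specification for a synthetic proteome
#'
#' @param n_per_family Named counts of planted UPO sequences per
#'   subfamily (`I`..`V`).
#' @param n_pog_like,n_classic_like Counts of CPO-grammar sequences
#'   derived (by a fixed mutation budget) from the Pog anchor and the
#'   classic-CPO anchor; anchors are emitted whenever either count is
#'   positive.
#' @param n_decoys Number of background decoy sequences.
#' @param decoy_length Length range (min, max) for decoys.
#' @param mutation_rate Within-subfamily substitution rate for planted
#'   siblings, in \[0, 1).
#' @param family_divergence Substitution rate separating each subfamily
#'   template from the master scaffold.
#' @param jitter Maximum absolute per-segment coordinate jitter.
#' @param mutation_budget Exact substitution count for Pog-/classic-like
#'   derivatives.
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @return List of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_per_family = c(I = 6L, II = 6L, III = 6L,
                                            IV = 6L, V = 6L),
                           n_pog_like = 0L, n_classic_like = 0L,
                           n_decoys = 500L, decoy_length = c(200L, 500L),
                           mutation_rate = 0.12,
                           family_divergence = 0.30,
                           jitter = 10L, mutation_budget = 10L,
                           seed = 42L) {
  stopifnot(all(n_per_family >= 0), n_pog_like >= 0, n_classic_like >= 0,
            n_decoys >= 0, mutation_rate >= 0, mutation_rate < 1,
            family_divergence >= 0, family_divergence < 1)
  fams <- c("I", "II", "III", "IV", "V")
  if (!all(fams %in% names(n_per_family))) {
    stop("n_per_family must name all five subfamilies I..V")
  }
  structure(
    list(n_per_family = n_per_family[fams], n_pog_like = n_pog_like,
         n_classic_like = n_classic_like, n_decoys = n_decoys,
         decoy_length = decoy_length, mutation_rate = mutation_rate,
         family_divergence = family_divergence, jitter = jitter,
         mutation_budget = mutation_budget, seed = seed),
    class = "synthetic_spec")
}

BG19 <- setdiff(AA_ALPHABET21, c("X", "C"))  # planted backgrounds avoid Cys
AA20 <- setdiff(AA_ALPHABET21, "X")

sample_bg <- function(n, alphabet = BG19) {
  if (n <= 0L) return(character(0))
  sample(alphabet, n, replace = TRUE)
}

# concrete instance of a registry motif, subfamily variants resolved
motif_instance <- function(name, family = NULL) {
  rnd <- function(k) paste(sample_bg(k), collapse = "")
  switch(name,
         PCP = "PCP", EGD = "EGD", EHD = "EHD",
         SILG = "SIG",
         SXXRXD = paste0("S", rnd(2), "R", rnd(1), "D"),
         NHG_family = switch(family, I = "SHG", IV = "NYG", "NHG"),
         FXD = paste0("F", rnd(1), "D"),
         RGN = "RGN", IDG = "IDG",
         TX6R = paste0("T", rnd(6), "R"),
         VPPLPG = "VPPLPG",
         GMLG = paste0("G", sample(c("M", "L"), 1L), "G"),
         CDA = "CDA",
         FXXXDG = paste0("F", rnd(3), "DG"),
         GAAXXXYE = paste0("GAA", rnd(3), "YE"),
         HXXF = paste0("H", rnd(2), "F"),
         EDXXH = paste0("ED", rnd(2), "H"),
         GXG = paste0("G", rnd(1), "G"),
         stop("no instance rule for motif ", name))
}

# positional signature motifs planted per subfamily (rule motifs such as
# the Subfamily-I Cys pair are handled separately)
family_signature_plan <- list(
  I = c("NHG_family", "FXD"),
  II = c("NHG_family", "RGN", "IDG", "TX6R", "VPPLPG"),
  III = c("NHG_family", "GMLG"),
  IV = c("NHG_family", "CDA", "FXXXDG", "GAAXXXYE", "HXXF"),
  V = c("NHG_family", "EDXXH", "GXG")
)

# assemble a sequence from alternating background gaps and motif blocks;
# returns the string plus 1-based coordinates of every block
assemble_sequence <- function(gaps, blocks, block_names,
                              alphabet = BG19) {
  stopifnot(length(gaps) == length(blocks) + 1L)
  pieces <- character(0)
  coords <- data.frame(motif = character(0), start = integer(0),
                       end = integer(0), stringsAsFactors = FALSE)
  pos <- 0L
  for (i in seq_along(blocks)) {
    g <- paste(sample_bg(gaps[i], alphabet), collapse = "")
    pieces <- c(pieces, g, blocks[i])
    start <- pos + gaps[i] + 1L
    end <- start + nchar(blocks[i]) - 1L
    coords <- rbind(coords, data.frame(motif = block_names[i],
                                       start = start, end = end,
                                       stringsAsFactors = FALSE))
    pos <- end
  }
  pieces <- c(pieces, paste(sample_bg(gaps[length(gaps)], alphabet),
                            collapse = ""))
  list(seq = paste(pieces, collapse = ""), coords = coords)
}

# Core UPO anatomy as background gap lengths between motif blocks,
# reproducing the AaeUPO coordinates at zero jitter:
# PCP 35-37, S[IL]G 60-62, NHG 105-107, EGD 122-124, SXXRXD 130-135,
# Arg 189, Glu 196. The 6-residue pair spacing is never jittered.
UPO_BASE_GAPS <- c(34L, 22L, 42L, 14L, 5L, 53L, 6L, 0L)

# One shared backbone for all planted UPOs: a per-segment pool of
# background residues long enough to accommodate the maximum jitter.
# Each sequence draws a (jittered-length) prefix of every pool, so all
# planted sequences stay alignable to the master scaffold while their
# motif coordinates shift.
upo_scaffold <- function(jitter) {
  lapply(UPO_BASE_GAPS, function(g) sample_bg(g + jitter))
}

# core grammar region of one sequence on the shared scaffold
build_upo_core <- function(family, scaffold, jitter, divergence,
                           silg = "SIG", sxxrxd = NULL) {
  n_seg <- length(UPO_BASE_GAPS)
  deltas <- if (jitter > 0) {
    sample(seq(-jitter, jitter), n_seg, replace = TRUE)
  } else {
    rep(0L, n_seg)
  }
  deltas[7:8] <- 0L  # pair spacing and trailing gap stay fixed
  gaps <- pmax(1L, UPO_BASE_GAPS + deltas)
  gaps[8] <- 0L
  bg <- vapply(seq_len(n_seg), function(i) {
    paste(scaffold[[i]][seq_len(gaps[i])], collapse = "")
  }, character(1))
  if (is.null(sxxrxd)) sxxrxd <- motif_instance("SXXRXD")
  blocks <- c("PCP", silg, motif_instance("NHG_family", family),
              "EGD", sxxrxd, "R", "E")
  names_ <- c("PCP", "SILG", "NHG_family", "EGD", "SXXRXD",
              "stabilizer_R", "catalytic_E")
  pieces <- character(0)
  coords <- data.frame(motif = character(0), start = integer(0),
                       end = integer(0), stringsAsFactors = FALSE)
  pos <- 0L
  for (i in seq_along(blocks)) {
    pieces <- c(pieces, bg[i], blocks[i])
    start <- pos + nchar(bg[i]) + 1L
    end <- start + nchar(blocks[i]) - 1L
    coords <- rbind(coords, data.frame(motif = names_[i], start = start,
                                       end = end,
                                       stringsAsFactors = FALSE))
    pos <- end
  }
  core <- list(seq = paste(pieces, collapse = ""), coords = coords)
  if (divergence > 0) {
    core$seq <- mutate_variant(core$seq, divergence,
                               preserve_motifs = TRUE,
                               preserve = coords_to_positions(coords),
                               alphabet = BG19)
  }
  core
}

append_tail <- function(core, family, spec) {
  sigs <- setdiff(family_signature_plan[[family]],
                  "NHG_family")  # NHG sits in the core region
  blocks <- vapply(sigs, motif_instance, character(1), family = family)
  if (family == "I") {
    blocks <- c(blocks, "C", "C")
    sigs <- c(sigs, "CYS", "CYS")
  }
  gaps <- c(12L, sample(8:15, length(blocks) - 1L, replace = TRUE), 18L)
  tail_part <- assemble_sequence(gaps, blocks, sigs)
  offset <- nchar(core$seq)
  tail_part$coords$start <- tail_part$coords$start + offset
  tail_part$coords$end <- tail_part$coords$end + offset
  list(seq = paste0(core$seq, tail_part$seq),
       coords = rbind(core$coords, tail_part$coords))
}

substitute_positions <- function(chars, idx, alphabet) {
  for (i in idx) {
    chars[i] <- sample(setdiff(alphabet, chars[i]), 1L)
  }
  chars
}

#' Mutate a sequence by random substitutions
#'
#' Each eligible position is substituted with probability `rate`
#' (equivalently: a binomial number of positions is drawn and substituted
#' to a different letter). With `preserve_motifs`, positions listed in
#' `preserve` are exempt.
#'
#' @param seq Residue string or single-row `upo_records`.
#' @param rate Per-position substitution probability in \[0, 1).
#' @param seed Optional integer seed (the caller's RNG stream is left
#'   untouched when given).
#' @param preserve_motifs Exempt the `preserve` positions?
#' @param preserve Integer positions (1-based) to keep fixed.
#' @param alphabet Replacement alphabet.
#' @return The mutated residue string.
#' @export
mutate_variant <- function(seq, rate, seed = NULL,
                           preserve_motifs = FALSE,
                           preserve = integer(0), alphabet = AA20) {
  stopifnot(rate >= 0, rate < 1)
  s <- if (inherits(seq, "upo_records")) seq$seq[1] else as.character(seq)
  run <- function() {
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    eligible <- seq_along(chars)
    if (preserve_motifs) eligible <- setdiff(eligible, preserve)
    k <- stats::rbinom(1L, length(eligible), rate)
    if (k > 0L) {
      idx <- sample(eligible, k)
      chars <- substitute_positions(chars, idx, alphabet)
    }
    paste(chars, collapse = "")
  }
  if (is.null(seed)) run() else withr_seed(seed, run())
}

coords_to_positions <- function(coords) {
  unlist(lapply(seq_len(nrow(coords)), function(i) {
    coords$start[i]:coords$end[i]
  }))
}

coords_to_string <- function(coords) {
  paste(sprintf("%s:%d-%d", coords$motif, coords$start, coords$end),
        collapse = ";")
}

build_cpo_core <- function(jitter) {
  jit <- function(g) max(1L, g + sample(seq(-jitter, jitter), 1L))
  gaps <- c(jit(28L), jit(68L), jit(57L), jit(40L))
  blocks <- c("PCP", "EHD", "E")
  assemble_sequence(gaps, blocks, c("PCP", "EHD", "catalytic_E"))
}

check_upo <- function(s, family, registry) {
  g <- find_core_grammar(s, registry)
  if (g$class != "UPO_core") return(FALSE)
  hits <- scan_registry(s, registry)
  call <- classify_subfamily(g, hits, registry, s)
  call$family == family && call$score == 1
}

#' Generate a synthetic proteome with ground truth
#'
#' Emits the master scaffold as the query stand-in (`QUERY_UPO`), the
#' planted subfamily sequences, optional CPO-grammar anchors and their
#' mutation-derived candidates, and background decoys. Every planted
#' sequence is verified to satisfy the core grammar and classify into its
#' intended subfamily with a full signature score; decoys are verified to
#' lack any complete core grammar. Failed draws are resampled; a spec
#' that cannot host the grammar raises an error.
#'
#' @param spec A `synthetic_spec`.
#' @param registry A `motif_registry` used for verification.
#' @return List of class `synthetic_proteome`: `records` (a
#'   `upo_records`), `truth` (data.frame `id`, `class`, `family`,
#'   `motifs`), and `coords` (per-id coordinate data.frames). The seed is
#'   recorded as an attribute.
#' @export
generate_proteome <- function(spec = synthetic_spec(),
                              registry = load_registry()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr_seed(spec$seed, generate_proteome_impl(spec, registry))
}

generate_proteome_impl <- function(spec, registry) {
  ids <- character(0); seqs <- character(0)
  truth <- data.frame(id = character(0), class = character(0),
                      family = character(0), motifs = character(0),
                      stringsAsFactors = FALSE)
  coords <- list()
  add <- function(id, s, class, family, crd) {
    ids <<- c(ids, id); seqs <<- c(seqs, s)
    truth <<- rbind(truth, data.frame(
      id = id, class = class, family = family,
      motifs = if (is.null(crd)) "" else coords_to_string(crd),
      stringsAsFactors = FALSE))
    coords[[id]] <<- crd
  }
  retry <- function(n, what, f) {
    for (i in seq_len(n)) {
      out <- f()
      if (!is.null(out)) return(out)
    }
    stop("could not generate a valid ", what, " in ", n, " attempts; ",
         "the spec cannot host the grammar")
  }

  # shared backbone, then the master scaffold = query stand-in (core
  # grammar at the unjittered coordinates, no subfamily tail)
  scaffold <- upo_scaffold(spec$jitter)
  master <- retry(100L, "master scaffold", function() {
    m <- build_upo_core("II", scaffold, jitter = 0L, divergence = 0)
    m$seq <- paste0(m$seq, paste(sample_bg(40L), collapse = ""))
    g <- find_core_grammar(m$seq, registry)
    if (g$class == "UPO_core") m else NULL
  })
  add("QUERY_UPO", master$seq, "UPO_core", "query", master$coords)

  for (fam in names(spec$n_per_family)) {
    n <- spec$n_per_family[[fam]]
    if (n == 0L) next
    template <- retry(200L, paste("subfamily", fam, "template"),
                      function() {
      core <- build_upo_core(fam, scaffold, spec$jitter,
                             spec$family_divergence)
      full <- append_tail(core, fam, spec)
      if (check_upo(full$seq, fam, registry)) full else NULL
    })
    for (i in seq_len(n)) {
      keep <- coords_to_positions(template$coords)
      s <- retry(100L, paste("subfamily", fam, "sequence"), function() {
        v <- mutate_variant(template$seq, spec$mutation_rate,
                            preserve_motifs = TRUE, preserve = keep,
                            alphabet = BG19)
        if (check_upo(v, fam, registry)) v else NULL
      })
      add(sprintf("UPO_%s_%02d", fam, i), s, "UPO_core", fam,
          template$coords)
    }
  }

  if (spec$n_pog_like > 0L || spec$n_classic_like > 0L) {
    make_anchor <- function(label) retry(200L, label, function() {
      a <- build_cpo_core(spec$jitter)
      g <- find_core_grammar(a$seq, registry)
      if (g$class == "CPO_core") a else NULL
    })
    pog <- make_anchor("Pog anchor")
    cpo <- make_anchor("classic CPO anchor")
    add("POG_ANCHOR", pog$seq, "CPO_core", "anchor_pog", pog$coords)
    add("CPO_ANCHOR", cpo$seq, "CPO_core", "anchor_cpo", cpo$coords)
    derive <- function(anchor, n, prefix, famlab) {
      keep <- coords_to_positions(anchor$coords)
      for (i in seq_len(n)) {
        s <- retry(100L, paste(famlab, "candidate"), function() {
          chars <- strsplit(anchor$seq, "", fixed = TRUE)[[1]]
          idx <- sample(setdiff(seq_along(chars), keep),
                        spec$mutation_budget)
          v <- paste(substitute_positions(chars, idx, BG19),
                     collapse = "")
          g <- find_core_grammar(v, registry)
          if (g$class == "CPO_core") v else NULL
        })
        add(sprintf("%s_%02d", prefix, i), s, "CPO_core", famlab,
            anchor$coords)
      }
    }
    derive(pog, spec$n_pog_like, "POGLIKE", "Pog_like")
    derive(cpo, spec$n_classic_like, "CPOLIKE", "classic_like")
  }

  if (spec$n_decoys > 0L) {
    lens <- sample(spec$decoy_length[1]:spec$decoy_length[2],
                   spec$n_decoys, replace = TRUE)
    for (i in seq_len(spec$n_decoys)) {
      s <- retry(100L, "decoy", function() {
        v <- paste(sample_bg(lens[i], AA20), collapse = "")
        g <- find_core_grammar(v, registry)
        if (g$class == "none") v else NULL
      })
      add(sprintf("DECOY_%03d", i), s, "none", "decoy", NULL)
    }
  }

  records <- protein_records(ids, seqs, source = "synthetic")
  out <- structure(list(records = records, truth = truth,
                        coords = coords),
                   class = "synthetic_proteome")
  attr(out, "seed") <- spec$seed
  attr(out, "spec") <- spec
  out
}

#' @export
print.synthetic_proteome <- function(x, ...) {
  cat(sprintf("<synthetic_proteome> %d records (seed %d): %s\n",
              nrow(x$records), attr(x, "seed"),
              paste(sprintf("%s=%d", names(table(x$truth$family)),
                            table(x$truth$family)), collapse = " ")))
  invisible(x)
}

#' Write a synthetic proteome and its truth table to disk
#'
#' @param synth A `synthetic_proteome`.
#' @param fasta_path,truth_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_synthetic <- function(synth, fasta_path, truth_path) {
  stopifnot(inherits(synth, "synthetic_proteome"))
  write_fasta(synth$records, fasta_path)
  utils::write.table(synth$truth, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(fasta_path, truth_path))
}
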