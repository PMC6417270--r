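# Motif scanning and the core catalytic grammar.
#
# The grammar of a functional unspecific peroxygenase reads, left to
# right: PCP (proximal Cys), S[IL]G, the distal EGD triad, SXXRXD, then
# the acid-base catalyst pair Arg...Glu with exactly six residues in
# between (Arg189/Glu196 in AaeUPO numbering). Chloroperoxidases carry
# PCP, the EHD triad (whose His is the acid-base partner), and a
# downstream catalytic Glu. A small set of UPO-like CPO sequences follows
# the UPO grammar but with an EAD/ETD distal triad and/or a seven-residue
# pair spacing.

pattern_to_regex <- function(positions) {
  paste(vapply(positions, function(cls) {
    if (length(cls) == 1L && is.na(cls)) "[A-Z]"
    else if (length(cls) == 1L) cls
    else paste0("[", paste(cls, collapse = ""), "]")
  }, character(1)), collapse = "")
}

#' Scan one motif pattern over a sequence
#'
#' Reports every (possibly overlapping) occurrence. A wildcard position
#' matches any letter including `X`; a sequence `X` matches only wildcard
#' positions.
#'
#' @param pattern A `motif_pattern` (positional; rule motifs cannot be
#'   scanned).
#' @param seq A residue string or a single-row `upo_records`.
#' @return data.frame with columns `motif`, `start`, `end`, `match`
#'   (1-based inclusive coordinates), ordered by `start`.
#' @examples
#' reg <- load_registry()
#' scan_motif(reg$SILG, "ASIGK")
#' @export
scan_motif <- function(pattern, seq) {
  stopifnot(inherits(pattern, "motif_pattern"))
  if (!is.na(pattern$rule)) {
    stop("motif '", pattern$name, "' is a rule, not a scannable pattern")
  }
  s <- if (inherits(seq, "upo_records")) seq$seq[1] else as.character(seq)
  len <- length(pattern$positions)
  empty <- data.frame(motif = character(0), start = integer(0),
                      end = integer(0), match = character(0),
                      stringsAsFactors = FALSE)
  if (nchar(s) < len) return(empty)
  rx <- sprintf("(?=(%s))", pattern_to_regex(pattern$positions))
  m <- gregexpr(rx, s, perl = TRUE)[[1]]
  if (m[1] == -1L) return(empty)
  starts <- as.integer(m)
  data.frame(
    motif = pattern$name,
    start = starts,
    end = starts + len - 1L,
    match = substring(s, starts, starts + len - 1L),
    stringsAsFactors = FALSE
  )
}

#' Scan every positional motif of a registry over a sequence
#'
#' @param seq Residue string or single-row `upo_records`.
#' @param registry A `motif_registry`.
#' @return data.frame of hits (as [scan_motif()]), all motifs combined,
#'   ordered by motif name then start.
#' @export
scan_registry <- function(seq, registry) {
  positional <- Filter(function(m) is.na(m$rule), registry)
  hits <- do.call(rbind, lapply(positional, scan_motif, seq = seq))
  if (is.null(hits)) {
    hits <- data.frame(motif = character(0), start = integer(0),
                       end = integer(0), match = character(0),
                       stringsAsFactors = FALSE)
  }
  rownames(hits) <- NULL
  hits[order(hits$motif, hits$start), , drop = FALSE]
}

#' Residue count strictly between the acid-base catalyst pair
#'
#' @param stabilizer_pos 1-based position of the charge stabilizer (Arg in
#'   UPOs).
#' @param glutamate_pos 1-based position of the catalytic Glu; must lie
#'   right of `stabilizer_pos`.
#' @return Integer spacing; 6 for the canonical UPO pair (189, 196).
#' @export
pair_spacing <- function(stabilizer_pos, glutamate_pos) {
  if (any(glutamate_pos <= stabilizer_pos)) {
    stop("glutamate position must lie right of the stabilizer position")
  }
  as.integer(glutamate_pos - stabilizer_pos - 1L)
}

grammar_result <- function(class = "none", cys_pos = NA_integer_,
                           distal_variant = NA_character_,
                           distal_start = NA_integer_,
                           stabilizer_pos = NA_integer_,
                           glutamate_pos = NA_integer_,
                           spacing = NA_integer_,
                           supporting = NULL, flags = character(0)) {
  if (is.null(supporting)) {
    supporting <- data.frame(motif = character(0), start = integer(0),
                             end = integer(0), match = character(0),
                             stringsAsFactors = FALSE)
  }
  structure(
    list(class = class, cys_pos = cys_pos,
         distal_variant = distal_variant, distal_start = distal_start,
         stabilizer_pos = stabilizer_pos, glutamate_pos = glutamate_pos,
         spacing = spacing, supporting = supporting, flags = flags),
    class = "grammar_result"
  )
}

#' @export
print.grammar_result <- function(x, ...) {
  cat(sprintf("<grammar> %s", x$class))
  if (x$class != "none") {
    cat(sprintf("  Cys@%d  %s@%d", x$cys_pos, x$distal_variant,
                x$distal_start))
    if (!is.na(x$stabilizer_pos)) {
      cat(sprintf("  pair %d..%d (spacing %d)", x$stabilizer_pos,
                  x$glutamate_pos, x$spacing))
    } else if (!is.na(x$glutamate_pos)) {
      cat(sprintf("  catalytic E@%d", x$glutamate_pos))
    }
  }
  if (length(x$flags)) cat("  [", paste(x$flags, collapse = ","), "]")
  cat("\n")
  invisible(x)
}

# Left-most R...E pair downstream of `after`, with spacing drawn from
# `spacings` (tried in the given order at each candidate R).
find_pair <- function(chars, after, spacings) {
  n <- length(chars)
  r_pos <- which(chars == "R")
  r_pos <- r_pos[r_pos > after]
  for (r in r_pos) {
    for (s in spacings) {
      e <- r + s + 1L
      if (e <= n && chars[e] == "E") {
        return(list(stabilizer = r, glutamate = e, spacing = s))
      }
    }
  }
  NULL
}

upo_grammar_search <- function(s, chars, registry, distal_names, spacings,
                               require_silg, require_sxxrxd) {
  pcp <- scan_motif(registry$PCP, s)
  if (!nrow(pcp)) return(NULL)
  silg <- scan_motif(registry$SILG, s)
  sxxrxd <- scan_motif(registry$SXXRXD, s)
  distal_hits <- do.call(rbind, lapply(distal_names, function(nm) {
    scan_motif(registry[[nm]], s)
  }))
  if (is.null(distal_hits) || !nrow(distal_hits)) return(NULL)
  distal_hits <- distal_hits[order(distal_hits$start), , drop = FALSE]

  for (pi in seq_len(nrow(pcp))) {
    p_end <- pcp$end[pi]
    for (di in seq_len(nrow(distal_hits))) {
      d <- distal_hits[di, ]
      if (d$start <= p_end) next
      silg_ok <- !require_silg ||
        any(silg$start > p_end & silg$end < d$start)
      if (!silg_ok) next
      if (require_sxxrxd) {
        anc <- sxxrxd[sxxrxd$start > d$end, , drop = FALSE]
        if (!nrow(anc)) next
        anchor_end <- anc$end[1]
      } else {
        anchor_end <- d$end
      }
      pair <- find_pair(chars, anchor_end, spacings)
      if (is.null(pair)) next
      silg_used <- silg[silg$start > p_end & silg$end < d$start, ,
                        drop = FALSE]
      sxx_used <- sxxrxd[sxxrxd$start > d$end, , drop = FALSE]
      return(list(
        cys = pcp$start[pi] + 1L, distal = d, pair = pair,
        supporting = rbind(utils::head(silg_used, 1L),
                           utils::head(sxx_used, 1L))
      ))
    }
  }
  NULL
}

#' Locate the core catalytic grammar of a sequence
#'
#' Tries, in order: the strict UPO grammar (EGD distal triad, pair spacing
#' 6, with S\[IL\]G and SXXRXD required by default -- each requirement can
#' be relaxed, SXXRXD notably being absent in MroUPO); the UPO-like CPO
#' variant grammar (distal EGD/EAD/ETD, spacing 6 or 7); and the CPO
#' grammar (EHD triad followed by a catalytic Glu, no Arg stabilizer).
#' All candidate choices are resolved left-most first, so the result is
#' deterministic.
#'
#' @param seq Residue string or single-row `upo_records`.
#' @param registry A `motif_registry` (default: built-in).
#' @param require_silg,require_sxxrxd Require the two all-UPO supporting
#'   motifs for the UPO-type grammars.
#' @param min_length Sequences shorter than this yield class `"none"`.
#' @return A `grammar_result` with class one of `"UPO_core"`,
#'   `"UPO_like_CPO"`, `"CPO_core"`, `"none"`, the catalytic coordinates
#'   (1-based), the distal variant, the pair spacing, and supporting
#'   motif hits (including any NHG-family hits).
#' @export
find_core_grammar <- function(seq, registry = load_registry(),
                              require_silg = TRUE, require_sxxrxd = TRUE,
                              min_length = 60L) {
  s <- if (inherits(seq, "upo_records")) seq$seq[1] else as.character(seq)
  if (nchar(s) < min_length) {
    return(grammar_result("none", flags = "below-length-floor"))
  }
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  nhg <- scan_motif(registry$NHG_family, s)

  hit <- upo_grammar_search(s, chars, registry, "EGD", 6L,
                            require_silg, require_sxxrxd)
  cls <- "UPO_core"
  if (is.null(hit)) {
    hit <- upo_grammar_search(s, chars, registry, c("EGD", "EAD", "ETD"),
                              c(6L, 7L), require_silg, require_sxxrxd)
    cls <- "UPO_like_CPO"
  }
  if (!is.null(hit)) {
    return(grammar_result(
      class = cls, cys_pos = hit$cys,
      distal_variant = hit$distal$motif, distal_start = hit$distal$start,
      stabilizer_pos = hit$pair$stabilizer,
      glutamate_pos = hit$pair$glutamate, spacing = hit$pair$spacing,
      supporting = rbind(hit$supporting, nhg)
    ))
  }

  # chloroperoxidase grammar: PCP < EHD < catalytic E
  pcp <- scan_motif(registry$PCP, s)
  ehd <- scan_motif(registry$EHD, s)
  if (nrow(pcp) && nrow(ehd)) {
    e_pos <- which(chars == "E")
    for (pi in seq_len(nrow(pcp))) {
      dd <- ehd[ehd$start > pcp$end[pi], , drop = FALSE]
      if (!nrow(dd)) next
      for (di in seq_len(nrow(dd))) {
        glu <- e_pos[e_pos > dd$end[di]]
        if (length(glu)) {
          return(grammar_result(
            class = "CPO_core", cys_pos = pcp$start[pi] + 1L,
            distal_variant = "EHD", distal_start = dd$start[di],
            glutamate_pos = glu[1], supporting = nhg
          ))
        }
      }
    }
  }
  grammar_result("none")
}

#' Count aromatic residues around the distal motif
#'
#' Sequence-level descriptor of the aromatic lining of the substrate
#' channel: counts F/Y/W within `window` residues either side of the
#' distal triad midpoint. Report-only -- this never filters candidates and
#' is not a substitute for structural inspection of the binding cavity.
#'
#' @param seq Residue string or single-row `upo_records`.
#' @param grammar A `grammar_result` with class other than `"none"`.
#' @param window Half-width in residues.
#' @return Integer count.
#' @export
aromatic_context <- function(seq, grammar, window = 15L) {
  stopifnot(inherits(grammar, "grammar_result"))
  if (grammar$class == "none") {
    stop("aromatic_context needs a located grammar")
  }
  s <- if (inherits(seq, "upo_records")) seq$seq[1] else as.character(seq)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  mid <- grammar$distal_start + 1L
  lo <- max(1L, mid - window)
  hi <- min(length(chars), mid + window)
  sum(chars[lo:hi] %in% c("F", "Y", "W"))
}

#' Export motif hits as BED-like intervals
#'
#' The only place the package uses 0-based half-open coordinates, per BED
#' convention; everything else is 1-based inclusive.
#'
#' @param hits Hit data.frame from [scan_registry()] with an `id` column
#'   (or one id supplied via `id`).
#' @param path Output path.
#' @param id Sequence id used when `hits` lacks an `id` column.
#' @return `path`, invisibly.
#' @export
export_bed <- function(hits, path, id = NULL) {
  if (!"id" %in% names(hits)) {
    if (is.null(id)) stop("hits need an 'id' column or an explicit id")
    hits$id <- id
  }
  bed <- data.frame(chrom = hits$id, start = hits$start - 1L,
                    end = hits$end, name = hits$motif)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
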