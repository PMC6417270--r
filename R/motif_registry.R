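# The motif registry: conserved sequence motifs of heme-thiolate
# peroxidases, expressed as fixed-length residue-class patterns.
#
# Pattern language: one position per character, "[...]" for an explicit
# residue class, "X" for a wildcard that matches any letter of the
# 21-letter alphabet (including X). A class such as [IL] matches I or L
# only -- a sequence X never matches a non-wildcard position. There are no
# quantifiers: TXXXXXXR is eight fixed positions.

#' Parse a motif pattern string into residue-class sets
#'
#' @param pattern Pattern string, e.g. `"S[IL]G"` or `"TXXXXXXR"`.
#' @param name Motif name used in error messages.
#' @return A list with one character vector per position; `NA` marks a
#'   wildcard position.
#' @export
parse_pattern <- function(pattern, name = pattern) {
  ch <- strsplit(pattern, "", fixed = TRUE)[[1]]
  canonical <- setdiff(AA_ALPHABET21, "X")
  positions <- list()
  i <- 1L
  while (i <= length(ch)) {
    if (ch[i] == "[") {
      j <- which(ch == "]" & seq_along(ch) > i)[1]
      if (is.na(j)) stop("malformed pattern in motif '", name,
                         "': unclosed '[' in ", pattern)
      cls <- ch[(i + 1L):(j - 1L)]
      if (!length(cls) || j == i + 1L) {
        stop("malformed pattern in motif '", name, "': empty class")
      }
      if (!all(cls %in% canonical)) {
        stop("malformed pattern in motif '", name,
             "': class letters must be canonical residues")
      }
      positions[[length(positions) + 1L]] <- cls
      i <- j + 1L
    } else if (ch[i] == "]") {
      stop("malformed pattern in motif '", name, "': unmatched ']'")
    } else if (ch[i] == "X") {
      positions[[length(positions) + 1L]] <- NA_character_
      i <- i + 1L
    } else if (ch[i] %in% canonical) {
      positions[[length(positions) + 1L]] <- ch[i]
      i <- i + 1L
    } else {
      stop("malformed pattern in motif '", name, "': character '",
           ch[i], "'")
    }
  }
  if (length(positions) < 2L) {
    stop("motif '", name, "': pattern length must be >= 2")
  }
  positions
}

motif_pattern <- function(name, pattern, scope, novel, rule = NA_character_,
                          note = NULL) {
  positions <- if (is.na(rule)) parse_pattern(pattern, name) else NULL
  structure(
    list(name = name, pattern = pattern, positions = positions,
         scope = scope, novel = novel, rule = rule, note = note),
    class = "motif_pattern"
  )
}

#' @export
print.motif_pattern <- function(x, ...) {
  cat(sprintf("<motif> %s  %s  scope=%s  %s\n", x$name,
              if (is.na(x$rule)) x$pattern else paste0("rule:", x$rule),
              paste(x$scope, collapse = ","),
              if (isTRUE(x$novel)) "newly-reported" else "previously-known"))
  invisible(x)
}

# The built-in registry. Scope semantics:
#   "all"  -- expected in (virtually) all UPOs; supports the core grammar
#             but is not a subfamily signature.
#   "core" -- constituent of the core catalytic grammar itself.
#   "CPO"  -- chloroperoxidase-type core motif.
#   "I".."V" -- signature motif of that UPO subfamily.
# Motifs carrying a rule instead of a positional pattern (CYS_CYS) are
# evaluated by the classifier, not the scanner.
default_registry_entries <- function() {
  list(
    # core catalytic grammar (previously known)
    motif_pattern("PCP", "PCP", "core", FALSE,
                  note = "proximal heme ligand; central Cys is the thiolate"),
    motif_pattern("EGD", "EGD", "core", FALSE,
                  note = "distal-side triad of UPOs"),
    motif_pattern("EHD", "EHD", "CPO", FALSE,
                  note = "distal-side triad of CPOs; His replaces Gly"),
    motif_pattern("EAD", "EAD", "core", FALSE,
                  note = "distal variant seen in UPO-like CPO sequences"),
    motif_pattern("ETD", "ETD", "core", FALSE,
                  note = "distal variant seen in UPO-like CPO sequences"),
    # newly-reported motifs: all UPOs
    motif_pattern("SILG", "S[IL]G", "all", TRUE,
                  note = paste("between PCP and the distal triad; Leu instead",
                               "of Ile in three species, so both accepted")),
    motif_pattern("SXXRXD", "SXXRXD", "all", TRUE,
                  note = "downstream of the distal triad; absent in MroUPO"),
    # newly-reported: subfamily signatures
    motif_pattern("NHG_family", "[SN][HY][GN]",
                  c("I", "II", "III", "IV", "V"), TRUE,
                  note = paste("one family covering the per-subfamily",
                               "variants: [SN]HG (I), NHG (II/III/V),",
                               "NH[GN]/NYG (IV); NHN and SHG are also",
                               "reported variants and the family class",
                               "admits them all")),
    motif_pattern("FXD", "FXD", "I", TRUE),
    motif_pattern("CYS_CYS", NA_character_, "I", TRUE, rule = "cys_pair",
                  note = paste("C-terminal disulfide evidence; no printed",
                               "local pattern, operationalized as >= 2 Cys",
                               "outside the PCP motif; weak evidence only")),
    motif_pattern("RGN", "RGN", "II", TRUE,
                  note = paste("signature table places RGN in Subfamily II;",
                               "one narrative passage says Subfamily IV --",
                               "the table assignment is kept")),
    motif_pattern("IDG", "IDG", "II", TRUE),
    motif_pattern("TX6R", "TXXXXXXR", "II", TRUE),
    motif_pattern("VPPLPG", "VPPLPG", "II", TRUE),
    motif_pattern("GMLG", "G[ML]G", "III", TRUE,
                  note = paste("signature table and one passage say",
                               "Subfamily III; another passage says IV --",
                               "the table assignment is kept")),
    motif_pattern("CDA", "CDA", "IV", TRUE),
    motif_pattern("FXXXDG", "FXXXDG", "IV", TRUE),
    motif_pattern("GAAXXXYE", "GAAXXXYE", "IV", TRUE),
    motif_pattern("HXXF", "HXXF", "IV", TRUE,
                  note = paste("signature table lists HXXF under IV only;",
                               "narrative also mentions I and II")),
    motif_pattern("EDXXH", "EDXXH", "V", TRUE),
    motif_pattern("GXG", "GXG", "V", TRUE)
  )
}

#' Load a motif registry
#'
#' With `path = NULL` returns the built-in registry: the core catalytic
#' motifs (PCP; distal EGD with its EHD chloroperoxidase counterpart and
#' the EAD/ETD variants) plus the newly-reported conserved motifs -- two
#' present in virtually all UPOs (S\[IL\]G, SXXRXD) and the per-subfamily
#' signature motifs, 16 newly-reported motifs in total. With a path, reads
#' a YAML registry file of the same structure.
#'
#' @param path Optional YAML registry file.
#' @return A list of `motif_pattern` objects, class `motif_registry`.
#' @export
load_registry <- function(path = NULL) {
  if (is.null(path)) {
    entries <- default_registry_entries()
  } else {
    y <- yaml::read_yaml(path)
    if (is.null(y$motifs)) stop("registry config has no 'motifs' list")
    entries <- lapply(y$motifs, function(m) {
      if (is.null(m$name)) stop("registry entry without a name")
      motif_pattern(
        name = m$name,
        pattern = if (is.null(m$pattern)) NA_character_ else m$pattern,
        scope = unlist(m$scope),
        novel = isTRUE(m$novel),
        rule = if (is.null(m$rule)) NA_character_ else m$rule,
        note = m$note
      )
    })
  }
  nm <- vapply(entries, `[[`, character(1), "name")
  if (anyDuplicated(nm)) {
    stop("duplicate motif name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  names(entries) <- nm
  class(entries) <- "motif_registry"
  entries
}

#' Write a motif registry to a YAML config file
#'
#' @param registry A `motif_registry`.
#' @param path Output path.
#' @return `path`, invisibly; `load_registry(path)` round-trips.
#' @export
write_registry <- function(registry, path) {
  stopifnot(inherits(registry, "motif_registry"))
  motifs <- lapply(unclass(registry), function(m) {
    out <- list(name = m$name)
    if (!is.na(m$rule)) out$rule <- m$rule else out$pattern <- m$pattern
    out$scope <- as.list(m$scope)
    out$novel <- m$novel
    if (!is.null(m$note)) out$note <- m$note
    out
  })
  yaml::write_yaml(list(motifs = unname(motifs)), path)
  invisible(path)
}

#' @export
print.motif_registry <- function(x, ...) {
  cat(sprintf("<motif_registry> %d motifs (%d newly-reported)\n",
              length(x), sum(vapply(x, `[[`, logical(1), "novel"))))
  for (m in x) print(m)
  invisible(x)
}

#' Count newly-reported motifs in a registry
#'
#' @param registry A `motif_registry`.
#' @return Integer count of motifs carrying the newly-reported flag.
#' @export
n_novel_motifs <- function(registry) {
  sum(vapply(registry, `[[`, logical(1), "novel"))
}

#' Signature motif sets per UPO subfamily
#'
#' A motif is a signature of subfamily `f` when it is newly-reported and
#' its scope names `f`. The shared NHG-family motif is scoped to all five
#' subfamilies and therefore contributes to every set.
#'
#' @param registry A `motif_registry`.
#' @return Named list (`I`..`V`) of motif-name vectors.
#' @export
signature_sets <- function(registry) {
  fams <- c("I", "II", "III", "IV", "V")
  out <- lapply(fams, function(f) {
    keep <- vapply(registry, function(m) {
      isTRUE(m$novel) && f %in% m$scope
    }, logical(1))
    names(registry)[keep]
  })
  names(out) <- fams
  out
}
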