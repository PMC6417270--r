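# Protein record collections: the currency every pipeline stage trades in.
# A record set is a data.frame (class "upo_records") with columns
# id / desc / seq / source, one row per sequence.

#' The 21-letter residue alphabet
#'
#' The 20 canonical amino acids plus `X` for unknown or ambiguous residues.
#' Everything read into the pipeline is normalized onto this alphabet.
#'
#' @format Character vector of length 21.
#' @export
AA_ALPHABET21 <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "X"
)

#' Normalize a residue string onto the 21-letter alphabet
#'
#' Uppercases, strips a single terminal stop (`*`), and maps every character
#' outside the 20 canonical letters (ambiguity codes B, Z, J, the rare U/O,
#' internal stops, gap characters, digits, ...) to `X`. Fungal gene models
#' routinely contain `X` runs; records are repaired, never discarded.
#'
#' @param x Character vector of residue strings.
#' @return Character vector of normalized residue strings.
#' @examples
#' normalize_residues("mkv*")  # "MKV"
#' normalize_residues("MBU")   # "MXX"
#' @export
normalize_residues <- function(x) {
  x <- toupper(x)
  x <- sub("\\*$", "", x)
  canonical <- setdiff(AA_ALPHABET21, "X")
  vapply(x, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    ch[!(ch %in% canonical) & ch != "X"] <- "X"
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Construct a protein record collection
#'
#' @param id Character vector of unique sequence identifiers.
#' @param seq Character vector of residue strings (normalized on input).
#' @param desc Free-text descriptions (defaults to empty).
#' @param source Provenance label per record: a file path or `"synthetic"`.
#' @return A data.frame of class `upo_records`.
#' @export
protein_records <- function(id, seq, desc = "", source = "synthetic") {
  id <- as.character(id)
  if (anyDuplicated(id)) {
    stop("duplicate record id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  seq <- normalize_residues(as.character(seq))
  if (length(seq) && any(!nzchar(seq))) {
    stop("empty residue string for record(s): ",
         paste(id[!nzchar(seq)], collapse = ", "))
  }
  out <- data.frame(
    id = id,
    desc = rep_len(as.character(desc), length(id)),
    seq = seq,
    source = rep_len(as.character(source), length(id)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("upo_records", "data.frame")
  out
}

#' @export
print.upo_records <- function(x, ...) {
  cat(sprintf("<upo_records> %d sequence(s), %d..%d residues\n",
              nrow(x),
              if (nrow(x)) min(nchar(x$seq)) else 0L,
              if (nrow(x)) max(nchar(x$seq)) else 0L))
  if (nrow(x)) {
    show <- utils::head(x, 5L)
    for (i in seq_len(nrow(show))) {
      cat(sprintf("  %s  (%d aa)  %s\n", show$id[i], nchar(show$seq[i]),
                  substr(show$seq[i], 1L, 30L)))
    }
    if (nrow(x) > 5L) cat(sprintf("  ... and %d more\n", nrow(x) - 5L))
  }
  invisible(x)
}

#' Read an amino-acid FASTA file
#'
#' Residues are uppercased; a terminal `*` is stripped; characters outside
#' the 21-letter alphabet are mapped to `X`. File order is preserved. The
#' header's first whitespace-delimited token is the id, the remainder the
#' description.
#'
#' @param path Path to a FASTA file.
#' @return A `upo_records` collection; empty (with a warning) for an empty
#'   file.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || all(!nzchar(trimws(lines)))) {
    warning("empty FASTA file: ", path)
    return(protein_records(character(0), character(0), source = path))
  }
  first <- which(nzchar(trimws(lines)))[1]
  if (!startsWith(trimws(lines[first]), ">")) {
    stop(sprintf("not FASTA: expected '>' header at line %d of %s",
                 first, path))
  }
  aa <- Biostrings::readAAStringSet(path)
  headers <- names(aa)
  id <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(id)) {
    stop("duplicate record id(s) in ", path, ": ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  protein_records(id, as.character(aa), desc = desc, source = path)
}

#' Write a protein record collection as 60-column FASTA
#'
#' @param records A `upo_records` collection.
#' @param path Output path.
#' @return `path`, invisibly. `read_fasta(write_fasta(x))` reproduces `x`
#'   up to the `source` column.
#' @export
write_fasta <- function(records, path) {
  stopifnot(inherits(records, "upo_records"))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    hdr <- if (nzchar(records$desc[i])) {
      paste(records$id[i], records$desc[i])
    } else {
      records$id[i]
    }
    writeLines(paste0(">", hdr), con)
    s <- records$seq[i]
    starts <- seq(1L, nchar(s), by = 60L)
    writeLines(substring(s, starts, pmin(starts + 59L, nchar(s))), con)
  }
  invisible(path)
}

#' Write a stage annotation report
#'
#' Rows carry (record_id, stage, key, value) and are emitted in a
#' deterministic order (record_id, then stage, then key) so identical runs
#' produce identical files.
#'
#' @param rows A data.frame with columns `record_id`, `stage`, `key`,
#'   `value`.
#' @param path Output path.
#' @param format `"tsv"` (default) or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(rows, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  need <- c("record_id", "stage", "key", "value")
  if (is.null(rows) || !nrow(rows)) {
    rows <- data.frame(record_id = character(0), stage = character(0),
                       key = character(0), value = character(0),
                       stringsAsFactors = FALSE)
  }
  if (!all(need %in% names(rows))) {
    stop("report rows need columns: ", paste(need, collapse = ", "))
  }
  rows <- rows[need]
  rows$value <- as.character(rows$value)
  ord <- order(rows$record_id, rows$stage, rows$key, rows$value,
               method = "radix")
  rows <- rows[ord, , drop = FALSE]
  if (format == "tsv") {
    utils::write.table(rows, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  } else {
    jsonlite::write_json(rows, path, dataframe = "rows", auto_unbox = TRUE,
                         pretty = TRUE)
  }
  invisible(path)
}
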