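# Orchestration of the mining funnel:
#   homology screen -> greedy identity clustering -> Markov clustering
#   (retain the seed's cluster) -> motif-grammar filter -> subfamily
#   classification
# with per-stage TSV reports and a deterministic, config-hashed run
# directory. One proteome file is treated as one species/strain.

#' Resolved pipeline configuration
#'
#' Defaults mirror the published stage parameters: reporting E-value 10.0,
#' inclusion E-value 0.01, identity cut-off 0.90 with word length 5,
#' MCL inflation 1.4. Resolution order: defaults, then a YAML config
#' file, then direct arguments.
#'
#' @param config_file Optional YAML file of overrides.
#' @param ... Direct overrides of any default (unknown names are an
#'   error).
#' @return Named list of class `pipeline_config`.
#' @export
pipeline_config <- function(config_file = NULL, ...) {
  cfg <- list(
    report_evalue = 10.0,
    accept_evalue = 0.01,
    identity_threshold = 0.90,
    word_length = 5L,
    inflation = 1.4,
    mcl_max_iter = 100L,
    mcl_tol = 1e-6,
    mcl_prune = 1e-8,
    edge_evalue = 10.0,
    edge_weight = "bit",
    group_threshold = 35.0,
    min_score = 0.5,
    min_motifs = 2L,
    require_silg = TRUE,
    require_sxxrxd = TRUE,
    min_length = 60L,
    registry_file = NULL,
    gap_open = 11,
    gap_extend = 1,
    calibration_nsim = 400L,
    calibration_length = 200L,
    seed = 1L
  )
  apply_over <- function(cfg, over, origin) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad)) {
      stop("unknown config parameter(s) from ", origin, ": ",
           paste(bad, collapse = ", "))
    }
    cfg[names(over)] <- over
    cfg
  }
  if (!is.null(config_file)) {
    cfg <- apply_over(cfg, yaml::read_yaml(config_file), config_file)
  }
  cfg <- apply_over(cfg, list(...), "arguments")
  if (cfg$accept_evalue > cfg$report_evalue) {
    stop("inclusion E-value must not exceed the reporting E-value")
  }
  if (cfg$identity_threshold <= 0 || cfg$identity_threshold > 1) {
    stop("identity_threshold must lie in (0, 1]")
  }
  if (cfg$inflation <= 1) stop("inflation must exceed 1")
  structure(cfg, class = c("pipeline_config", "list"))
}

config_hash <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  unname(tools::md5sum(path))
}

calibrated_scheme <- function(cfg) {
  scheme <- scoring_scheme(gap_open = cfg$gap_open,
                           gap_extend = cfg$gap_extend)
  calibrate_evalue(scheme, nsim = cfg$calibration_nsim,
                   m = cfg$calibration_length, n = cfg$calibration_length,
                   seed = cfg$seed)
}

load_proteomes <- function(proteomes) {
  if (inherits(proteomes, "upo_records")) return(list(input = proteomes))
  if (is.character(proteomes)) {
    out <- lapply(proteomes, read_fasta)
    names(out) <- basename(proteomes)
    return(out)
  }
  if (is.list(proteomes)) {
    if (is.null(names(proteomes))) {
      names(proteomes) <- sprintf("proteome_%d", seq_along(proteomes))
    }
    return(proteomes)
  }
  stop("proteomes must be file paths, a upo_records, or a list of them")
}

as_query_record <- function(query) {
  if (inherits(query, "upo_records")) return(query[1, , drop = FALSE])
  if (is.character(query) && file.exists(query)) {
    return(read_fasta(query)[1, , drop = FALSE])
  }
  stop("query must be a upo_records row or a FASTA path")
}

classification_row <- function(id, grammar, call, aromatic) {
  data.frame(
    id = id,
    grammar_class = grammar$class,
    family = call$family,
    group = call$group,
    weight_kda = round(call$weight_kda, 2),
    score = round(call$score, 4),
    evidence = paste(call$evidence, collapse = ","),
    cys_pos = grammar$cys_pos,
    distal_variant = grammar$distal_variant,
    distal_start = grammar$distal_start,
    stabilizer_pos = grammar$stabilizer_pos,
    glutamate_pos = grammar$glutamate_pos,
    pair_spacing = grammar$spacing,
    aromatic_context = aromatic,
    flags = paste(call$flags, collapse = ","),
    stringsAsFactors = FALSE
  )
}

#' Grammar-validate and classify a set of sequences
#'
#' The classification-only entry point for pre-selected candidate sets:
#' no homology or clustering stages. CPO-grammar sequences are flagged
#' `needs-tree` (Pog versus classic CPO requires anchors and a tree; see
#' [place_cpo()]).
#'
#' @param records A `upo_records` collection or FASTA path.
#' @param config A `pipeline_config`.
#' @param registry Optional `motif_registry` (defaults to the config's
#'   registry file, or the built-in registry).
#' @return data.frame with one row per grammar-bearing sequence: grammar
#'   class, family, mass class, catalytic coordinates, pair spacing,
#'   aromatic context, evidence motifs and flags. Sequences without a
#'   core grammar are omitted (use `keep_none = TRUE` to keep them).
#' @param keep_none Keep rows for sequences whose grammar class is
#'   `"none"`.
#' @export
run_classify <- function(records, config = pipeline_config(),
                         registry = NULL, keep_none = FALSE) {
  if (is.character(records)) records <- read_fasta(records)
  if (is.null(registry)) {
    registry <- load_registry(config$registry_file)
  }
  rows <- lapply(seq_len(nrow(records)), function(i) {
    rec <- records[i, , drop = FALSE]
    g <- find_core_grammar(rec, registry,
                           require_silg = config$require_silg,
                           require_sxxrxd = config$require_sxxrxd,
                           min_length = config$min_length)
    if (g$class == "none") {
      if (!keep_none) return(NULL)
      return(data.frame(id = rec$id, grammar_class = "none",
                        family = NA_character_, group = NA_character_,
                        weight_kda = NA_real_, score = NA_real_,
                        evidence = "", cys_pos = NA_integer_,
                        distal_variant = NA_character_,
                        distal_start = NA_integer_,
                        stabilizer_pos = NA_integer_,
                        glutamate_pos = NA_integer_,
                        pair_spacing = NA_integer_,
                        aromatic_context = NA_integer_, flags = "",
                        stringsAsFactors = FALSE))
    }
    hits <- scan_registry(rec, registry)
    call <- classify_subfamily(g, hits, registry, rec,
                               min_score = config$min_score,
                               min_motifs = config$min_motifs,
                               group_threshold = config$group_threshold)
    classification_row(rec$id, g, call, aromatic_context(rec, g))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(invisible(data.frame()))
  rownames(out) <- NULL
  out
}

#' Run the full mining pipeline
#'
#' Executes screen, greedy identity clustering, Markov clustering with
#' seed-cluster retention, grammar filtering and classification, writing
#' per-stage TSVs, the final classification table, per-species putative
#' counts, the resolved config (with hash) and a run log into `out_dir`.
#'
#' @param proteomes FASTA path(s), a `upo_records`, or a named list of
#'   `upo_records` (one entry per species/strain).
#' @param query Seed sequence: single-row `upo_records` or FASTA path.
#' @param config A `pipeline_config`.
#' @param out_dir Run directory (created; must not pre-exist unless
#'   `overwrite`).
#' @param overwrite Allow writing into an existing directory.
#' @return Invisibly, a list with the per-stage tables and `out_dir`.
#' @export
run_mine <- function(proteomes, query, config = pipeline_config(),
                     out_dir = tempfile("upomine_run_"),
                     overwrite = FALSE) {
  if (dir.exists(out_dir) && !overwrite) {
    stop("output directory exists: ", out_dir)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out_dir, "run.log")
  log_line <- function(...) {
    cat(sprintf(...), "\n", sep = "", file = logf, append = TRUE)
  }
  hash <- config_hash(config, file.path(out_dir, "config.yaml"))
  cat(sprintf("run started %s\nconfig md5 %s\n",
              format(Sys.time(), "%Y-%m-%d %H:%M:%S"), hash),
      file = logf)

  registry <- load_registry(config$registry_file)
  prot_list <- load_proteomes(proteomes)
  query <- as_query_record(query)
  scheme <- calibrated_scheme(config)

  # stage 1: homology screen, per proteome (= per species)
  screened <- lapply(names(prot_list), function(sp) {
    res <- screen_proteome(prot_list[[sp]], query, scheme,
                           report_E = config$report_evalue,
                           accept_E = config$accept_evalue)
    if (nrow(res$accepted)) res$accepted$species <- sp
    if (nrow(res$reported)) res$reported$species <- sp
    log_line("screen %s: %d sequences, %d reported, %d accepted", sp,
             nrow(prot_list[[sp]]), nrow(res$reported),
             nrow(res$accepted))
    res
  })
  accepted <- do.call(rbind, lapply(screened, `[[`, "accepted"))
  reported <- do.call(rbind, lapply(screened, `[[`, "reported"))
  all_records <- do.call(rbind, unname(prot_list))
  class(all_records) <- c("upo_records", "data.frame")
  utils::write.table(reported, file.path(out_dir, "screen.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  empty_final <- data.frame()
  if (is.null(accepted) || !nrow(accepted)) {
    log_line("no accepted hits; empty run")
    utils::write.table(empty_final,
                       file.path(out_dir, "classification.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    counts <- data.frame(species = names(prot_list), putative = 0L)
    utils::write.table(counts, file.path(out_dir, "species_counts.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(list(classification = empty_final,
                          species_counts = counts, out_dir = out_dir)))
  }

  cand <- all_records[all_records$id %in% accepted$subject &
                        all_records$id != query$id, , drop = FALSE]
  pool <- rbind(query, cand)
  class(pool) <- c("upo_records", "data.frame")

  # stage 2: greedy identity clustering (redundancy removal)
  greedy <- greedy_identity_cluster(
    pool, identity_threshold = config$identity_threshold,
    word_length = config$word_length, scheme = scheme)
  utils::write.table(cluster_table(greedy),
                     file.path(out_dir, "clusters_greedy.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  log_line("greedy clustering: %d -> %d representatives", nrow(pool),
           length(greedy$clusters))
  reps <- pool[pool$id %in% greedy$representative, , drop = FALSE]
  if (!query$id %in% reps$id) {
    reps <- rbind(query, reps)
    class(reps) <- c("upo_records", "data.frame")
  }

  # stage 3: MCL on the representatives' similarity graph; keep the
  # seed's cluster
  graph <- build_similarity_graph(reps, scheme,
                                  edge_E = config$edge_evalue,
                                  weight = config$edge_weight)
  mcl <- mcl_cluster(graph, inflation = config$inflation,
                     max_iter = config$mcl_max_iter,
                     tol = config$mcl_tol, prune = config$mcl_prune)
  utils::write.table(cluster_table(mcl),
                     file.path(out_dir, "clusters_mcl.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  seed_members <- retain_seed_cluster(mcl, query$id)
  log_line("MCL: %d nodes, %d clusters, %d in the seed cluster",
           length(graph$nodes), length(mcl$clusters),
           length(seed_members))
  survivors <- cand[cand$id %in% seed_members, , drop = FALSE]

  # stages 4+5: grammar filter and classification
  classification <- run_classify(survivors, config, registry)
  utils::write.table(classification,
                     file.path(out_dir, "classification.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  log_line("grammar filter: %d candidates -> %d putative sequences",
           nrow(survivors), NROW(classification))

  # per-species putative counts
  sp_of <- accepted$species[match(classification$id, accepted$subject)]
  counts <- data.frame(species = names(prot_list),
                       putative = vapply(names(prot_list), function(sp) {
                         sum(sp_of == sp)
                       }, integer(1)))
  utils::write.table(counts, file.path(out_dir, "species_counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  log_line("done: %d putative sequences in %d species",
           NROW(classification), sum(counts$putative > 0))

  invisible(list(screen = reported, accepted = accepted,
                 greedy = greedy, mcl = mcl,
                 classification = classification,
                 species_counts = counts, out_dir = out_dir))
}
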