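reg <- load_registry()

test_that("molecular weight follows the residue-mass sum", {
  expect_equal(molecular_weight("G"), 0.07506718, tolerance = 1e-6)
  # mass-sum oracle: 10 x Ala
  expect_equal(1000 * molecular_weight(strrep("A", 10)),
               10 * 71.0788 + 18.01528, tolerance = 1e-6)
  # X counts at the mean residue mass and flags the value
  w <- molecular_weight("GXG")
  expect_true(isTRUE(attr(w, "uncertain")))
  expect_equal(as.numeric(w),
               (2 * 57.0519 + 110 + 18.01528) / 1000, tolerance = 1e-9)
  expect_error(molecular_weight(""), "empty")
})

test_that("mass classes split at the configured threshold", {
  expect_equal(assign_group(29), "Group-I")
  expect_equal(assign_group(44), "Group-II")
  expect_equal(assign_group(35.0), "Group-II")  # boundary closed right
  expect_equal(assign_group(34.999), "Group-I")
  expect_equal(assign_group(36, threshold = 40), "Group-I")
})

fake_hits <- function(motifs) {
  data.frame(motif = motifs, start = seq_along(motifs),
             end = seq_along(motifs) + 2L,
             match = motifs, stringsAsFactors = FALSE)
}

upo_grammar_stub <- function() {
  set.seed(61)
  s <- make_grammar_seq()
  list(seq = s, grammar = find_core_grammar(s, reg))
}

test_that("signature scoring assigns the stated examples", {
  stub <- upo_grammar_stub()
  # all Subfamily-V signatures present
  call <- classify_subfamily(stub$grammar,
                             fake_hits(c("NHG_family", "EDXXH", "GXG")),
                             reg, stub$seq)
  expect_equal(call$family, "V")
  expect_equal(call$score, 1.0)
  expect_setequal(call$evidence, c("NHG_family", "EDXXH", "GXG"))

  # Subfamily III
  call3 <- classify_subfamily(stub$grammar,
                              fake_hits(c("NHG_family", "GMLG")),
                              reg, stub$seq)
  expect_equal(call3$family, "III")

  # no signature hits -> unassigned with all-zero scores (the fixture
  # background contains no Cys, so the Subfamily-I rule cannot fire)
  call0 <- classify_subfamily(stub$grammar, fake_hits(character(0)),
                              reg, stub$seq)
  expect_equal(call0$family, "unassigned")
  expect_true(all(call0$scores == 0))

  # a single matched signature is below the evidence minimum
  call1 <- classify_subfamily(stub$grammar, fake_hits("GMLG"), reg,
                              stub$seq)
  expect_equal(call1$family, "unassigned")
})

test_that("scores stay in [0,1] and CPO-grammar sequences defer to the tree", {
  stub <- upo_grammar_stub()
  set.seed(62)
  for (i in 1:20) {
    motifs <- sample(names(reg), sample(0:8, 1))
    call <- classify_subfamily(stub$grammar, fake_hits(motifs), reg,
                               stub$seq)
    expect_true(all(call$scores >= 0 & call$scores <= 1))
  }
  set.seed(63)
  s_cpo <- make_grammar_seq(distal = "EHD")
  g_cpo <- find_core_grammar(s_cpo, reg)
  call <- classify_subfamily(g_cpo, fake_hits(character(0)), reg, s_cpo)
  expect_equal(call$family, "unassigned")
  expect_true("needs-tree" %in% call$flags)
})

test_that("the subfamily-I cysteine-pair rule needs Cys outside PCP", {
  set.seed(64)
  s <- make_grammar_seq()
  g <- find_core_grammar(s, reg)
  hits <- fake_hits(c("NHG_family", "FXD"))
  # without extra Cys: only 2 of 3 subfamily-I signatures
  call <- classify_subfamily(g, hits, reg, s)
  expect_equal(call$family, "I")
  expect_lt(call$score, 1)
  # append two Cys -> full signature set, flagged weak
  s_cc <- paste0(s, "CAC")
  call2 <- classify_subfamily(g, hits, reg, s_cc)
  expect_equal(call2$score, 1.0)
  expect_true("weak-cys-evidence" %in% call2$flags)
})

test_that("tree placement sides with the nearest anchor", {
  set.seed(65)
  synth <- generate_proteome(
    synthetic_spec(n_per_family = c(I = 0, II = 0, III = 0, IV = 0,
                                    V = 0),
                   n_pog_like = 3, n_classic_like = 3, n_decoys = 0,
                   seed = 19))
  recs <- synth$records
  D <- distance_matrix(recs)
  tree <- nj_tree(D)
  anchors <- list(pog = "POG_ANCHOR", cpo = "CPO_ANCHOR")
  cfg <- pipeline_config()
  for (i in seq_len(nrow(recs))) {
    rec <- recs[i, , drop = FALSE]
    truth_fam <- synth$truth$family[synth$truth$id == rec$id]
    if (!truth_fam %in% c("Pog_like", "classic_like")) next
    g <- find_core_grammar(rec, reg)
    call <- classify_subfamily(g, scan_registry(rec, reg), reg, rec)
    placed <- place_cpo(call, tree, anchors, rec$id)
    expect_equal(placed$family,
                 if (truth_fam == "Pog_like") "Pog" else "classic_CPO",
                 info = rec$id)
    expect_false("needs-tree" %in% placed$flags)
  }
  # identical to an anchor -> that side (path length 0 from itself)
  g <- find_core_grammar(recs[recs$id == "POG_ANCHOR", ], reg)
  call <- classify_subfamily(g, fake_hits(character(0)), reg,
                             recs[recs$id == "POG_ANCHOR", ])
  expect_equal(place_cpo(call, tree, anchors, "POG_ANCHOR")$family,
               "Pog")
  expect_equal(place_cpo(call, tree, anchors, "CPO_ANCHOR")$family,
               "classic_CPO")
  expect_error(place_cpo(call, tree, list(pog = "POG_ANCHOR"),
                         "POG_ANCHOR"),
               "anchor")
})
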