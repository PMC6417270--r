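reg <- load_registry()

test_that("the canonical UPO anatomy is recognized with exact coordinates", {
  set.seed(101)
  s <- make_grammar_seq()
  g <- find_core_grammar(s, reg)
  expect_equal(g$class, "UPO_core")
  expect_equal(g$cys_pos, 36L)
  expect_equal(g$distal_variant, "EGD")
  expect_equal(g$distal_start, 122L)
  expect_equal(g$stabilizer_pos, 189L)
  expect_equal(g$glutamate_pos, 196L)
  expect_equal(g$spacing, 6L)
})

test_that("the chloroperoxidase grammar is recognized", {
  set.seed(102)
  s <- make_grammar_seq(distal = "EHD")
  g <- find_core_grammar(s, reg)
  expect_equal(g$class, "CPO_core")
  expect_equal(g$cys_pos, 36L)
  expect_equal(g$distal_variant, "EHD")
  expect_true(is.na(g$stabilizer_pos))
  expect_true(is.na(g$spacing))
})

test_that("degenerate inputs yield class none", {
  expect_equal(find_core_grammar(strrep("A", 250), reg)$class, "none")
  expect_equal(find_core_grammar("PCP", reg)$class, "none")  # length floor
})

test_that("distal variants and spacing 7 give the UPO-like-CPO class", {
  set.seed(103)
  for (distal in c("EAD", "ETD")) {
    g <- find_core_grammar(make_grammar_seq(distal = distal), reg)
    expect_equal(g$class, "UPO_like_CPO", info = distal)
    expect_equal(g$spacing, 6L)
  }
  g <- find_core_grammar(make_grammar_seq(spacing = 7), reg)
  expect_equal(g$class, "UPO_like_CPO")
  expect_equal(g$spacing, 7L)
})

test_that("supporting-motif requirements are independently relaxable", {
  set.seed(104)
  s_no_sxx <- make_grammar_seq(with_sxxrxd = FALSE)
  expect_equal(find_core_grammar(s_no_sxx, reg)$class, "none")
  expect_equal(find_core_grammar(s_no_sxx, reg,
                                 require_sxxrxd = FALSE)$class,
               "UPO_core")
  s_no_silg <- make_grammar_seq(with_silg = FALSE)
  expect_equal(find_core_grammar(s_no_silg, reg)$class, "none")
  expect_equal(find_core_grammar(s_no_silg, reg,
                                 require_silg = FALSE)$class,
               "UPO_core")
})

test_that("grammar results replay through the scanner", {
  # every claimed supporting hit and catalytic coordinate must be
  # confirmed by direct inspection of the sequence
  set.seed(105)
  for (i in 1:10) {
    s <- make_grammar_seq()
    g <- find_core_grammar(s, reg)
    expect_equal(g$class, "UPO_core")
    chars <- strsplit(s, "")[[1]]
    expect_equal(chars[g$cys_pos], "C")
    expect_equal(paste(chars[(g$cys_pos - 1):(g$cys_pos + 1)],
                       collapse = ""), "PCP")
    expect_equal(paste(chars[g$distal_start:(g$distal_start + 2)],
                       collapse = ""), g$distal_variant)
    expect_equal(chars[g$stabilizer_pos], "R")
    expect_equal(chars[g$glutamate_pos], "E")
    if (nrow(g$supporting)) {
      for (r in seq_len(nrow(g$supporting))) {
        expect_equal(substr(s, g$supporting$start[r], g$supporting$end[r]),
                     g$supporting$match[r])
      }
    }
  }
})

test_that("pair_spacing follows its closed form", {
  expect_equal(pair_spacing(189, 196), 6L)
  expect_equal(pair_spacing(1, 2), 0L)
  expect_equal(pair_spacing(10, 18), 7L)
  expect_error(pair_spacing(5, 5), "right of")
  # translation invariance
  set.seed(8)
  for (i in 1:50) {
    a <- sample(1:500, 1); b <- a + sample(1:60, 1); k <- sample(1:100, 1)
    expect_equal(pair_spacing(a + k, b + k), pair_spacing(a, b))
  }
})

test_that("aromatic context counts F/Y/W around the distal triad", {
  set.seed(106)
  s <- make_grammar_seq()
  g <- find_core_grammar(s, reg)
  # brute-force per-position tally
  chars <- strsplit(s, "")[[1]]
  mid <- g$distal_start + 1L
  for (w in c(5L, 15L, 40L)) {
    manual <- sum(chars[max(1, mid - w):min(length(chars), mid + w)]
                  %in% c("F", "Y", "W"))
    expect_equal(aromatic_context(s, g, window = w), manual)
  }
  # all-alanine context around the triad
  flat <- paste0(strrep("A", 100), "EGD", strrep("A", 100))
  g2 <- find_core_grammar(make_grammar_seq(), reg)
  g2$distal_start <- 101L
  expect_equal(aromatic_context(flat, g2, window = 15), 0L)
  expect_error(aromatic_context(flat, find_core_grammar("AAA", reg)),
               "grammar")
})
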