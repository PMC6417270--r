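# Fixture builders shared by the grammar and acceptance tests.

AA20_T <- setdiff(upominer::AA_ALPHABET21, "X")

rand_seq <- function(n, alphabet = AA20_T) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Background that can never complete a catalytic grammar on its own:
# no Arg, no Glu, no Cys (and no His, so the CPO triad cannot form).
SAFE_BG <- setdiff(AA20_T, c("R", "E", "C", "H"))

safe_bg <- function(n) {
  if (n <= 0) return("")
  paste(sample(SAFE_BG, n, replace = TRUE), collapse = "")
}

# A sequence with the canonical UPO anatomy: PCP at 35-37, S[IL]G at
# 60-62, distal triad at 122-124, SXXRXD at 130-135, stabilizer R at
# 189 and the catalytic E at 189 + spacing + 1. Only the planted R/E
# exist anywhere in the sequence.
make_grammar_seq <- function(spacing = 6, distal = "EGD",
                             with_silg = TRUE, with_sxxrxd = TRUE,
                             tail = 60) {
  silg <- if (with_silg) "SIG" else safe_bg(3)
  sxxrxd <- if (with_sxxrxd) {
    paste0("S", safe_bg(2), "R", safe_bg(1), "D")
  } else {
    safe_bg(6)
  }
  paste0(safe_bg(34), "PCP", safe_bg(22), silg, safe_bg(59), distal,
         safe_bg(5), sxxrxd, safe_bg(53), "R", safe_bg(spacing), "E",
         safe_bg(tail))
}

random_records <- function(n, len_range = c(60, 120), prefix = "r") {
  lens <- sample(len_range[1]:len_range[2], n, replace = TRUE)
  upominer::protein_records(
    sprintf("%s%03d", prefix, seq_len(n)),
    vapply(lens, rand_seq, character(1))
  )
}
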