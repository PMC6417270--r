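scheme <- scoring_scheme()

test_that("analytic lambda solves the Karlin-Altschul root equation", {
  # toy 2-letter matrix: match +1, mismatch -2, uniform background
  # (expected score -0.5 < 0); sum p_i p_j exp(lambda s_ij) = 1 is
  # solved by bisection as an independent oracle
  m <- matrix(c(1, -2, -2, 1), 2, 2, dimnames = list(c("A", "B"),
                                                     c("A", "B")))
  p <- c(A = 0.5, B = 0.5)
  sch <- scoring_scheme(matrix = m, background = p)
  sch <- calibrate_lambda(sch)
  f <- function(lam) sum(outer(p, p) * exp(lam * m)) - 1
  lo <- 1e-8; hi <- 10
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  expect_equal(sch$lambda, (lo + hi) / 2, tolerance = 1e-7)
  expect_lt(abs(f(sch$lambda)), 1e-9)

  # scaling the matrix by 2 halves lambda
  sch2 <- calibrate_lambda(scoring_scheme(matrix = 2 * m, background = p))
  expect_equal(sch2$lambda, sch$lambda / 2, tolerance = 1e-9)

  # all-positive matrix cannot be calibrated
  expect_error(calibrate_lambda(scoring_scheme(matrix = abs(m),
                                               background = p)),
               "calibration")
})

test_that("self-alignment recovers the diagonal self-score", {
  set.seed(21)
  for (i in 1:5) {
    rec <- protein_records("x", rand_seq(80))
    hit <- local_align(rec, rec, scheme)
    chars <- strsplit(rec$seq, "")[[1]]
    expect_equal(hit$score, sum(diag(scheme$matrix)[chars]))
    expect_equal(hit$pid_short, 100)
    expect_equal(hit$q_start, 1L)
    expect_equal(hit$q_end, 80L)
  }
})

test_that("alignment score matches exhaustive enumeration on tiny strings", {
  # every pair of 1..3-mers over a 4-letter alphabet, against the pure
  # enumeration oracle (all start points, all op sequences)
  alpha <- c("A", "C", "G", "L")
  sub <- scheme$matrix[alpha, alpha]
  set.seed(31)
  pool <- unlist(lapply(1:3, function(L) {
    apply(expand.grid(rep(list(alpha), L)), 1, paste, collapse = "")
  }))
  pairs <- expand.grid(a = pool, b = pool, stringsAsFactors = FALSE)
  pairs <- pairs[sample(nrow(pairs), 250), ]
  for (r in seq_len(nrow(pairs))) {
    a <- pairs$a[r]; b <- pairs$b[r]
    expect_equal(local_align(a, b, scheme)$score,
                 enum_local_score(a, b, sub, scheme$gap_open,
                                  scheme$gap_extend),
                 info = paste(a, b))
  }
})

test_that("alignment score matches an independent DP on 4/5-mers and longer", {
  alpha <- c("A", "C", "G", "L")
  set.seed(32)
  for (r in 1:300) {
    a <- rand_seq(sample(4:5, 1), alpha)
    b <- rand_seq(sample(4:5, 1), alpha)
    expect_equal(local_align(a, b, scheme)$score,
                 sw_score_dp(a, b, scheme$matrix, scheme$gap_open,
                             scheme$gap_extend),
                 info = paste(a, b))
  }
  for (r in 1:10) {
    a <- rand_seq(40); b <- rand_seq(40)
    expect_equal(local_align(a, b, scheme)$score,
                 sw_score_dp(a, b, scheme$matrix, scheme$gap_open,
                             scheme$gap_extend),
                 info = paste(a, b))
  }
})

test_that("score is symmetric and self-maximal", {
  set.seed(33)
  a <- protein_records("a", rand_seq(60))
  for (i in 1:10) {
    b <- protein_records("b", rand_seq(sample(30:90, 1)))
    sab <- local_align(a, b, scheme)$score
    sba <- local_align(b, a, scheme)$score
    expect_equal(sab, sba)
    expect_gte(local_align(a, a, scheme)$score, sab)
  }
})

test_that("E-values behave as K m n exp(-lambda S)", {
  sch <- calibrate_lambda(scheme)
  e1 <- evalue(50, 100, 1000, sch)
  expect_equal(evalue(50, 100, 2000, sch), 2 * e1)  # linear in n
  expect_lt(evalue(60, 100, 1000, sch), e1)          # monotone in S
  expect_equal(evalue(1e6, 100, 1000, sch), 0)       # S -> Inf limit
  expect_error(evalue(50, 100, 1000, scoring_scheme()), "calibrated")
})

test_that("screening accepts an exact query copy at minimum E", {
  set.seed(34)
  sch <- calibrate_evalue(scheme, nsim = 150, m = 120, n = 120, seed = 3)
  q <- protein_records("query", rand_seq(120))
  prot <- rbind(random_records(10, c(100, 140), "bgx"),
                protein_records("copy", q$seq))
  class(prot) <- c("upo_records", "data.frame")
  res <- screen_proteome(prot, q, sch)
  expect_true("copy" %in% res$accepted$subject)
  expect_equal(res$reported$subject[1], "copy")  # minimum E first
  expect_true(all(res$accepted$evalue <= 0.01))
  expect_true(all(res$accepted$subject %in% res$reported$subject))

  empty <- screen_proteome(protein_records(character(0), character(0)),
                           q, sch)
  expect_equal(nrow(empty$accepted), 0L)
})

test_that("unrelated decoys are accepted at about the nominal chance rate", {
  sch <- calibrate_evalue(scheme, nsim = 300, m = 150, n = 150, seed = 5)
  set.seed(35)
  fp <- 0L
  n_search <- 100L
  for (i in seq_len(n_search)) {
    q <- protein_records("q", rand_seq(150))
    db <- random_records(4, c(130, 170), "d")
    fp <- fp + nrow(screen_proteome(db, q, sch)$accepted)
  }
  # expected about 0.01 per search; allow a generous binomial band
  expect_lte(fp, stats::qbinom(0.9999, n_search, 0.01) + 2L)
})
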