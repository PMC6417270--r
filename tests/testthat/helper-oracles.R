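# Independent oracles used across the suite. These deliberately take the
# slowest, most literal route: sliding windows, pure recursion, long-run
# fixed points. They share no code with the implementation paths they
# check.

# literal sliding-window motif matcher
naive_scan <- function(positions, s) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  L <- length(positions)
  starts <- integer(0)
  if (length(chars) >= L) {
    for (i in 1:(length(chars) - L + 1L)) {
      ok <- TRUE
      for (k in seq_len(L)) {
        cls <- positions[[k]]
        if (length(cls) == 1L && is.na(cls)) next  # wildcard
        if (!(chars[i + k - 1L] %in% cls)) { ok <- FALSE; break }
      }
      if (ok) starts <- c(starts, i)
    }
  }
  starts
}

# plain-R Gotoh DP for local alignment scores, gap of length k costing
# open + k * ext
sw_score_dp <- function(a, b, mat, open = 11, ext = 1) {
  x <- strsplit(a, "", fixed = TRUE)[[1]]
  y <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(x); m <- length(y)
  H <- matrix(0, n + 1L, m + 1L)
  E <- matrix(-Inf, n + 1L, m + 1L)  # gap in a (consume y)
  F_ <- matrix(-Inf, n + 1L, m + 1L) # gap in b (consume x)
  best <- 0
  for (i in 2:(n + 1L)) {
    for (j in 2:(m + 1L)) {
      E[i, j] <- max(H[i, j - 1L] - open - ext, E[i, j - 1L] - ext)
      F_[i, j] <- max(H[i - 1L, j] - open - ext, F_[i - 1L, j] - ext)
      H[i, j] <- max(0,
                     H[i - 1L, j - 1L] + mat[x[i - 1L], y[j - 1L]],
                     E[i, j], F_[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

# exhaustive enumeration of every local alignment of two tiny strings:
# all start pairs, all op sequences, affine gap costs; returns the best
# score (floored at 0)
enum_local_score <- function(a, b, mat, open = 11, ext = 1) {
  x <- strsplit(a, "", fixed = TRUE)[[1]]
  y <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(x); m <- length(y)
  best <- 0
  rec <- function(i, j, score, last) {
    best <<- max(best, score)
    if (i <= n && j <= m) {
      rec(i + 1L, j + 1L, score + mat[x[i], y[j]], "M")
    }
    if (i <= n) {
      rec(i + 1L, j, score - ext - if (last == "D") 0 else open, "D")
    }
    if (j <= m) {
      rec(i, j + 1L, score - ext - if (last == "I") 0 else open, "I")
    }
  }
  for (i0 in seq_len(n)) {
    for (j0 in seq_len(m)) {
      rec(i0, j0, 0, "M")
    }
  }
  best
}

# independent MCL fixed-point oracle, run to a much tighter tolerance
mcl_oracle_partition <- function(nodes, edges, inflation, tol = 1e-12,
                                 iters = 2000L) {
  ids <- sort(nodes)
  n <- length(ids)
  M <- matrix(0, n, n, dimnames = list(ids, ids))
  if (nrow(edges)) {
    for (r in seq_len(nrow(edges))) {
      M[edges$from[r], edges$to[r]] <- edges$weight[r]
      M[edges$to[r], edges$from[r]] <- edges$weight[r]
    }
  }
  mx <- apply(M, 2, max)
  diag(M) <- ifelse(mx > 0, mx, 1)
  M <- sweep(M, 2, colSums(M), "/")
  for (it in seq_len(iters)) {
    prev <- M
    M <- (M %*% M)^inflation
    M[M < 1e-8] <- 0
    M <- sweep(M, 2, colSums(M), "/")
    if (max(abs(M - prev)) < tol) break
  }
  adj <- (M > 0) | t(M > 0)
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cur
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  unname(split(ids, comp))
}

# canonical form of a partition (for set equality)
canon_partition <- function(clusters) {
  parts <- sort(vapply(clusters, function(cl) {
    paste(sort(cl), collapse = ",")
  }, character(1)))
  paste(parts, collapse = "|")
}

random_graph <- function(n, p_edge = 0.5) {
  nodes <- sprintf("n%02d", seq_len(n))
  from <- character(0); to <- character(0); w <- numeric(0)
  if (n >= 2) {
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        if (stats::runif(1) < p_edge) {
          from <- c(from, nodes[i]); to <- c(to, nodes[j])
          w <- c(w, sample(1:2, 1))
        }
      }
    }
  }
  list(nodes = nodes,
       edges = data.frame(from = from, to = to, weight = w,
                          stringsAsFactors = FALSE))
}
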