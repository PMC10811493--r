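# Independent oracles used across the suite. These re-derive expected
# results by brute force / exhaustive enumeration and deliberately share no
# code with the package internals they check.

# Enumerate ALL optimal global alignments of `read` vs `ref` under affine
# gap scoring (gap of length L costs open + ext * L). Returns a list of
# list(pattern, subject, score). Exponential in co-optimal paths; intended
# for short sequences only.
nw_enumerate <- function(read, ref, match = 2, mismatch = -4,
                         open = 10, ext = 1, max_paths = 20000) {
  x <- strsplit(read, "", fixed = TRUE)[[1]]
  y <- strsplit(ref, "", fixed = TRUE)[[1]]
  n <- length(x); m <- length(y)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); D <- matrix(NEG, n + 1, m + 1)
  I <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (j in seq_len(m)) D[1, j + 1] <- -(open + ext * j)
  for (i in seq_len(n)) I[i + 1, 1] <- -(open + ext * i)
  s <- function(a, b) if (a == b) match else mismatch
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      sc <- s(x[i], y[j])
      M[i + 1, j + 1] <- sc + max(M[i, j], D[i, j], I[i, j])
      D[i + 1, j + 1] <- max(M[i + 1, j] - open - ext, D[i + 1, j] - ext,
                             I[i + 1, j] - open - ext)
      I[i + 1, j + 1] <- max(M[i, j + 1] - open - ext, I[i, j + 1] - ext,
                             D[i, j + 1] - open - ext)
    }
  }
  best <- max(M[n + 1, m + 1], D[n + 1, m + 1], I[n + 1, m + 1])
  paths <- list()
  recurse <- function(i, j, state, pat, sub) {
    if (length(paths) >= max_paths) return()
    if (i == 0 && j == 0 && state == "M") {
      paths[[length(paths) + 1]] <<- list(pattern = paste(rev(pat), collapse = ""),
                                          subject = paste(rev(sub), collapse = ""),
                                          score = best)
      return()
    }
    if (state == "M") {
      if (i == 0 && j == 0) return()
      sc <- s(x[i], y[j])
      tgt <- M[i + 1, j + 1] - sc
      for (st in c("M", "D", "I")) {
        v <- switch(st, M = M[i, j], D = D[i, j], I = I[i, j])
        if (v == tgt) recurse(i - 1, j - 1, st, c(pat, x[i]), c(sub, y[j]))
      }
    } else if (state == "D") {  # gap in read consuming y[j]
      tgt <- D[i + 1, j + 1]
      if (M[i + 1, j] - open - ext == tgt) recurse(i, j - 1, "M", c(pat, "-"), c(sub, y[j]))
      if (D[i + 1, j] - ext == tgt) recurse(i, j - 1, "D", c(pat, "-"), c(sub, y[j]))
      if (I[i + 1, j] - open - ext == tgt) recurse(i, j - 1, "I", c(pat, "-"), c(sub, y[j]))
    } else {                    # gap in ref consuming x[i]
      tgt <- I[i + 1, j + 1]
      if (M[i, j + 1] - open - ext == tgt) recurse(i - 1, j, "M", c(pat, x[i]), c(sub, "-"))
      if (I[i, j + 1] - ext == tgt) recurse(i - 1, j, "I", c(pat, x[i]), c(sub, "-"))
      if (D[i, j + 1] - open - ext == tgt) recurse(i - 1, j, "D", c(pat, x[i]), c(sub, "-"))
    }
  }
  start_states <- c("M", "D", "I")[c(M[n + 1, m + 1], D[n + 1, m + 1],
                                     I[n + 1, m + 1]) == best]
  for (st in start_states) recurse(n, m, st, character(0), character(0))
  paths
}

# Plain column-walk event extraction from a gapped alignment pair, with no
# position normalization: events are reported where the alignment puts them.
oracle_events <- function(pattern, subject) {
  p <- strsplit(pattern, "", fixed = TRUE)[[1]]
  s <- strsplit(subject, "", fixed = TRUE)[[1]]
  out <- data.frame(kind = character(0), start = integer(0),
                    length = integer(0), alt_seq = character(0))
  r <- 0; i <- 1
  while (i <= length(p)) {
    if (p[i] == "-") {
      j <- i
      while (j <= length(p) && p[j] == "-") j <- j + 1
      out <- rbind(out, data.frame(kind = "deletion", start = r,
                                   length = j - i, alt_seq = ""))
      r <- r + (j - i); i <- j
    } else if (s[i] == "-") {
      j <- i
      while (j <= length(p) && s[j] == "-") j <- j + 1
      out <- rbind(out, data.frame(kind = "insertion", start = r, length = j - i,
                                   alt_seq = paste(p[i:(j - 1)], collapse = "")))
      i <- j
    } else if (p[i] != s[i]) {
      j <- i
      while (j <= length(p) && p[j] != "-" && s[j] != "-" && p[j] != s[j]) j <- j + 1
      out <- rbind(out, data.frame(kind = "substitution", start = r, length = j - i,
                                   alt_seq = paste(p[i:(j - 1)], collapse = "")))
      r <- r + (j - i); i <- j
    } else {
      r <- r + 1; i <- i + 1
    }
  }
  out
}

# Brute-force NGG site scan of one sequence (both strands), returning
# forward-window starts per strand; independent of enumerate_sites().
brute_sites <- function(seq) {
  rc1 <- function(s) chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]),
                                                  collapse = ""))
  L <- nchar(seq)
  hits <- list()
  if (L >= 23) {
    for (w in 0:(L - 23)) {
      win <- substr(seq, w + 1, w + 23)
      if (substr(win, 22, 23) == "GG") {
        hits[[length(hits) + 1]] <- data.frame(start = w, strand = "+",
                                               protospacer = substr(win, 1, 20))
      }
      rwin <- rc1(win)
      if (substr(rwin, 22, 23) == "GG") {
        hits[[length(hits) + 1]] <- data.frame(start = w, strand = "-",
                                               protospacer = substr(rwin, 1, 20))
      }
    }
  }
  if (length(hits)) do.call(rbind, hits) else
    data.frame(start = integer(0), strand = character(0),
               protospacer = character(0))
}
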