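# Independent oracles used by the test suite. Each is deliberately written
# with a different algorithmic structure than the package code it checks.

.GC <- Biostrings::GENETIC_CODE

# --- NG86 site oracle: brute enumeration of all 9 single-base neighbours ---
oracle_codon_sites <- function(codon) {
  bases <- c("A", "C", "G", "T")
  ch <- strsplit(codon, "")[[1]]
  neighbours <- character(0)
  for (pos in 1:3) for (b in bases) if (b != ch[pos]) {
    v <- ch; v[pos] <- b
    neighbours <- c(neighbours, paste(v, collapse = ""))
  }
  syn <- sum(.GC[neighbours] != "*" & .GC[neighbours] == .GC[[codon]])
  c(s = syn / 3, n = 3 - syn / 3)
}

# --- NG86 pathway oracle: depth-first path expansion over strings ---
# Walks every ordering of the differing positions by recursion, collecting
# (sd, nd) per stop-free path; falls back to all paths when none is free.
oracle_codon_diffs <- function(a, b) {
  walk <- function(cur, remaining, sd, nd, allow_stop) {
    if (!length(remaining)) return(list(c(sd = sd, nd = nd)))
    out <- list()
    for (pos in remaining) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(b, pos, pos)
      if (!allow_stop && .GC[[nxt]] == "*") next
      step_syn <- .GC[[cur]] == .GC[[nxt]]
      out <- c(out, walk(nxt, setdiff(remaining, pos),
                         sd + step_syn, nd + !step_syn, allow_stop))
    }
    out
  }
  diffpos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  if (!length(diffpos)) return(c(sd = 0, nd = 0))
  res <- walk(a, diffpos, 0, 0, allow_stop = FALSE)
  if (!length(res)) res <- walk(a, diffpos, 0, 0, allow_stop = TRUE)
  m <- do.call(rbind, res)
  c(sd = mean(m[, "sd"]), nd = mean(m[, "nd"]))
}

# --- global-alignment score oracle: enumerate every monotone move path ---
# Scores each complete path with affine gaps (first gap residue costs
# open + extend) and returns the maximum. Exponential; lengths <= 6 only.
oracle_nw_best_score <- function(a, b, submat, gap_open, gap_extend) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  best <- -Inf
  rec <- function(i, j, sc, prev) {
    if (i > length(av) && j > length(bv)) {
      best <<- max(best, sc); return(invisible())
    }
    if (i <= length(av) && j <= length(bv))
      rec(i + 1, j + 1, sc + submat[av[i], bv[j]], "m")
    if (i <= length(av))
      rec(i + 1, j, sc - if (prev == "u") gap_extend else
        gap_open + gap_extend, "u")
    if (j <= length(bv))
      rec(i, j + 1, sc - if (prev == "l") gap_extend else
        gap_open + gap_extend, "l")
  }
  rec(1, 1, 0, "none")
  best
}

# --- plain-R Smith-Waterman (affine) for identity cross-checks ---
oracle_sw <- function(a, b, match = 1, mismatch = -2, gap_open = 5,
                      gap_extend = 2) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  M <- matrix(0, n + 1, m + 1); X <- matrix(-Inf, n + 1, m + 1)
  Y <- matrix(-Inf, n + 1, m + 1)
  gi <- gap_open + gap_extend
  best <- 0
  for (i in 1:n) for (j in 1:m) {
    s <- if (av[i] == bv[j]) match else mismatch
    M[i + 1, j + 1] <- max(0, M[i, j], X[i, j], Y[i, j]) + s
    X[i + 1, j + 1] <- max(M[i, j + 1] - gi, X[i, j + 1] - gap_extend)
    Y[i + 1, j + 1] <- max(M[i + 1, j] - gi, Y[i + 1, j] - gap_extend)
    best <- max(best, M[i + 1, j + 1])
  }
  best
}

# --- Kruskal-Wallis by the direct rank-sum formula ---
oracle_kw_H <- function(groups) {
  x <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  r <- rank(x)
  N <- length(x)
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, g, sum)^2 / lengths(groups)) - 3 * (N + 1)
  ties <- table(r)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# small random protein over the 20 standard residues
random_protein <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n,
               replace = TRUE), collapse = "")
}

# mutate a fraction of positions of a DNA string (never to the same base)
mutate_dna <- function(s, frac) {
  v <- strsplit(s, "")[[1]]
  k <- round(frac * length(v))
  pos <- sample(length(v), k)
  for (p in pos) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
  paste(v, collapse = "")
}
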