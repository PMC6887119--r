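# Independent brute-force oracles. These deliberately re-derive each
# quantity by a different route than the package implementation; they are
# only ever run on small inputs.

random_dna <- function(len, p_g = 0.25) {
  probs <- c(A = (1 - p_g) / 3, C = (1 - p_g) / 3, G = p_g,
             T = (1 - p_g) / 3)
  paste(sample(names(probs), len, replace = TRUE, prob = probs),
        collapse = "")
}

# --- G4 oracle: regex run-finding + global candidate enumeration + greedy
# non-overlap selection (the scanner uses an rle single pass instead).
oracle_g4 <- function(s, g = 3L, lmin = 1L, lmax = 12L, ntr = 4L) {
  s <- chartr("U", "T", toupper(s))
  m <- gregexpr(sprintf("G{%d,}", g), s, perl = TRUE)[[1L]]
  hits <- data.frame(start = integer(), end = integer())
  if (m[1L] == -1L) return(hits)
  rs <- as.integer(m)
  re <- rs + attr(m, "match.length") - 1L
  nr <- length(rs)
  if (nr < ntr) return(hits)
  cand <- integer(0)
  for (i in seq_len(nr - ntr + 1L)) {
    gaps <- rs[(i + 1L):(i + ntr - 1L)] - re[i:(i + ntr - 2L)] - 1L
    if (all(gaps >= lmin & gaps <= lmax)) cand <- c(cand, i)
  }
  next_allowed <- 1L
  for (i in cand) {
    if (i >= next_allowed) {
      hits <- rbind(hits, data.frame(start = rs[i], end = re[i + ntr - 1L]))
      next_allowed <- i + ntr
    }
  }
  hits
}

# --- (GGC/A)n oracle: PCRE leftmost greedy non-overlapping matches.
oracle_ggc <- function(s, min_repeats = 4L) {
  s <- chartr("U", "T", toupper(s))
  m <- gregexpr(sprintf("(?:GG[CA]){%d,}", min_repeats), s, perl = TRUE)[[1L]]
  if (m[1L] == -1L)
    return(data.frame(start = integer(), end = integer(),
                      n_repeats = integer()))
  start <- as.integer(m)
  len <- attr(m, "match.length")
  data.frame(start = start, end = start + len - 1L, n_repeats = len %/% 3L)
}

# --- Nussinov oracle: plain recursion over all pairing decisions (no
# memoization, exponential; inputs <= 12 nt only).
.oracle_pairs <- list(A = "T", T = c("A", "G"), G = c("C", "T"), C = "G")
oracle_nussinov <- function(s, min_loop = 3L) {
  ch <- strsplit(chartr("U", "T", toupper(s)), "")[[1L]]
  rec <- function(i, j) {
    if (j - i <= min_loop) return(0L)
    best <- rec(i, j - 1L)
    for (k in i:(j - min_loop - 1L)) {
      if (ch[j] %in% .oracle_pairs[[ch[k]]]) {
        left <- if (k - 1L >= i) rec(i, k - 1L) else 0L
        inner <- rec(k + 1L, j - 1L)
        best <- max(best, left + 1L + inner)
      }
    }
    best
  }
  if (length(ch) < 2L) return(0L)
  rec(1L, length(ch))
}

# --- Mann-Whitney oracle: U by direct pairwise counting, exact two-sided
# p by enumerating every group assignment of the pooled values.
oracle_mw_u <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
oracle_mw <- function(a, b) {
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  mu <- na * nb / 2
  U_obs <- oracle_mw_u(a, b)
  sets <- combn(na + nb, na)
  Ustar <- apply(sets, 2L, function(ix)
    oracle_mw_u(pooled[ix], pooled[-ix]))
  list(U = U_obs,
       p_value = mean(abs(Ustar - mu) >= abs(U_obs - mu) - 1e-9))
}

# --- Duplex oracle: try every length (descending), every rRNA window and
# every oligo start; first admissible hit wins (ties resolved in the same
# documented order: longest, then smallest rRNA start, then smallest oligo
# start).
oracle_duplex <- function(oligo, rrna, min_pairs = 6L, allow_GU = FALSE) {
  oc <- strsplit(chartr("U", "T", toupper(oligo)), "")[[1L]]
  rc <- strsplit(chartr("U", "T", toupper(rrna)), "")[[1L]]
  ok_pair <- function(r, o) {
    wc <- paste0(r, o) %in% c("AT", "TA", "GC", "CG")
    if (allow_GU) wc | paste0(r, o) %in% c("GT", "TG") else wc
  }
  n <- length(rc); m <- length(oc)
  if (min(n, m) < min_pairs) return(NULL)
  for (l in rev(seq(min_pairs, min(n, m)))) {
    for (i in seq_len(n - l + 1L)) {
      for (j in seq_len(m - l + 1L)) {
        # antiparallel: rRNA i..i+l-1 pairs oligo j+l-1..j
        if (all(ok_pair(rc[i:(i + l - 1L)], oc[(j + l - 1L):j])))
          return(list(rrna_start = i, rrna_end = i + l - 1L,
                      oligo_start = j, oligo_end = j + l - 1L,
                      n_pairs = l))
      }
    }
  }
  NULL
}

# --- RT-stop tally oracle: literal per-read loop.
oracle_rt_tally <- function(pos_5prime, reference_length) {
  counts <- numeric(reference_length)
  for (p in pos_5prime) {
    if (p >= 2 && p <= reference_length) counts[p - 1] <- counts[p - 1] + 1
  }
  counts
}

# --- top-k oracle: exhaustive sort of the full (position, count) table.
oracle_top_sites <- function(counts, k) {
  df <- data.frame(position = seq_along(counts), count = counts)
  df <- df[df$count > 0, , drop = FALSE]
  df <- df[order(-df$count, df$position), , drop = FALSE]
  head(df, k)
}
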