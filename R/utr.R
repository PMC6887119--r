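#' GC content of a sequence
#'
#' @param sequence Single DNA/RNA string over {A, C, G, T, U, N}; N bases
#'   are excluded from the denominator.
#' @return Percent GC in `[0, 100]`.
#' @examples
#' gc_content("GGCATT")  # 50
#' @export
gc_content <- function(sequence) {
  ch <- .seq_chars(sequence)
  if (!length(ch)) stop("empty sequence", call. = FALSE)
  bad <- setdiff(unique(ch), c("A", "C", "G", "T", "N"))
  if (length(bad))
    stop("sequence contains invalid characters: ",
         paste(bad, collapse = ""), call. = FALSE)
  denom <- sum(ch != "N")
  if (denom == 0) stop("sequence is all N", call. = FALSE)
  100 * sum(ch %in% c("G", "C")) / denom
}

#' Motif specification for the G4 / (GGC/A)n scanners
#'
#' Two motif families drive the 5' UTR enrichment analyses: intramolecular
#' G-quadruplexes, `(G_g N_{loop_min..loop_max})_{n_tracts}` with g = 3
#' (classical) or 2 (weak G2 variant), and `(GGC/A)` tandem repeats of at
#' least `min_repeats` units (4 units = the 12-mer, 5 = the 15-mer).
#'
#' @param kind `"g_quadruplex"` or `"ggc_repeat"`.
#' @param tract_length Minimum G-tract length g (default 3).
#' @param loop_min,loop_max Loop length bounds in nt (defaults 1 and 12).
#' @param n_tracts Number of G-tracts (default 4, >= 2).
#' @param min_repeats Minimum tandem units for the repeat family
#'   (default 4, >= 2).
#' @return Object of class `motif_spec`.
#' @export
motif_spec <- function(kind = c("g_quadruplex", "ggc_repeat"),
                       tract_length = 3L, loop_min = 1L, loop_max = 12L,
                       n_tracts = 4L, min_repeats = 4L) {
  kind <- match.arg(kind)
  if (loop_min > loop_max) stop("loop_min must be <= loop_max", call. = FALSE)
  if (n_tracts < 2L) stop("n_tracts must be >= 2", call. = FALSE)
  if (min_repeats < 2L) stop("min_repeats must be >= 2", call. = FALSE)
  if (tract_length < 1L) stop("tract_length must be >= 1", call. = FALSE)
  structure(list(kind = kind, tract_length = as.integer(tract_length),
                 loop_min = as.integer(loop_min),
                 loop_max = as.integer(loop_max),
                 n_tracts = as.integer(n_tracts),
                 min_repeats = as.integer(min_repeats)),
            class = "motif_spec")
}

# maximal G runs of length >= g: data.frame(start, end)
.g_runs <- function(chars, g) {
  r <- rle(chars == "G")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= g
  data.frame(start = starts[keep], end = ends[keep])
}

#' Scan for G-quadruplex motifs
#'
#' Finds `(G_g N_{loop})_{n}` matches: chains of `n_tracts` maximal G-runs
#' of length >= `tract_length` whose successive gaps (loops) are
#' `loop_min..loop_max` nt. Matching is greedy left-to-right and reports
#' non-overlapping hits; G-tracts are extended maximally, so a loop can
#' never begin or end inside a qualifying G-run. Presence/absence per UTR
#' is what the downstream enrichment statistic consumes, so alternative
#' overlapping registers are not enumerated.
#'
#' @param sequence DNA/RNA string (U and T equivalent).
#' @param spec A [motif_spec()] with `kind = "g_quadruplex"`.
#' @return Data frame `(start, end, tract_len, n_tracts)`, 1-based
#'   inclusive; zero rows when no hit.
#' @examples
#' scan_g4("GGGAGGGAGGGAGGG")  # one hit covering 1-15
#' @export
scan_g4 <- function(sequence, spec = motif_spec("g_quadruplex")) {
  stopifnot(inherits(spec, "motif_spec"), spec$kind == "g_quadruplex")
  chars <- .seq_chars(sequence)
  runs <- .g_runs(chars, spec$tract_length)
  hits <- data.frame(start = integer(), end = integer(),
                     tract_len = integer(), n_tracts = integer())
  if (nrow(runs) < spec$n_tracts) return(hits)
  i <- 1L
  while (i <= nrow(runs) - spec$n_tracts + 1L) {
    j <- i + spec$n_tracts - 1L
    gaps <- runs$start[(i + 1L):j] - runs$end[i:(j - 1L)] - 1L
    if (all(gaps >= spec$loop_min & gaps <= spec$loop_max)) {
      hits <- rbind(hits, data.frame(
        start = runs$start[i], end = runs$end[j],
        tract_len = min(runs$end[i:j] - runs$start[i:j] + 1L),
        n_tracts = spec$n_tracts))
      i <- j + 1L  # non-overlapping: resume after the last tract used
    } else {
      i <- i + 1L
    }
  }
  hits
}

#' Scan for (GGC/A)n tandem repeats
#'
#' Finds maximal tandem runs of the trinucleotide unit `GG[C|A]` (mixed C/A
#' units allowed within a run) and reports runs of at least `min_repeats`
#' units. Scanning is greedy left-to-right over non-overlapping runs.
#'
#' @inheritParams scan_g4
#' @param spec A [motif_spec()] with `kind = "ggc_repeat"`.
#' @return Data frame `(start, end, n_repeats)`, 1-based inclusive.
#' @examples
#' scan_ggc_repeats("GGCGGAGGCGGA")  # one hit, 4 mixed units
#' @export
scan_ggc_repeats <- function(sequence, spec = motif_spec("ggc_repeat")) {
  stopifnot(inherits(spec, "motif_spec"), spec$kind == "ggc_repeat")
  chars <- .seq_chars(sequence)
  n <- length(chars)
  hits <- data.frame(start = integer(), end = integer(),
                     n_repeats = integer())
  is_unit <- function(p) p + 2L <= n && chars[p] == "G" &&
    chars[p + 1L] == "G" && (chars[p + 2L] == "C" || chars[p + 2L] == "A")
  p <- 1L
  while (p + 3L * spec$min_repeats - 1L <= n) {
    if (is_unit(p)) {
      q <- p
      while (is_unit(q + 3L)) q <- q + 3L
      reps <- (q - p) %/% 3L + 1L
      if (reps >= spec$min_repeats) {
        hits <- rbind(hits, data.frame(start = p, end = q + 2L,
                                       n_repeats = reps))
        p <- q + 3L
      } else p <- p + 1L
    } else p <- p + 1L
  }
  hits
}

# Watson-Crick + GU wobble pairing on the DNA-normalized alphabet
.can_pair <- function(a, b) {
  (a == "A" & b == "T") | (a == "T" & b == "A") |
    (a == "G" & (b == "C" | b == "T")) |
    (a == "C" & b == "G") | (a == "T" & b == "G")
}

#' Maximum base-pair count by the Nussinov algorithm
#'
#' Dynamic program maximizing the number of nested Watson-Crick + GU wobble
#' pairs with a minimum hairpin loop of `min_loop` unpaired nt between any
#' pair. A proxy for secondary-structure content: it is monotone in how
#' much of the sequence can fold, which is all the downstream group
#' comparisons require (full nearest-neighbor thermodynamics is out of
#' scope; externally computed folding energies can be supplied instead, see
#' [utr_features()]).
#'
#' @param sequence DNA/RNA string.
#' @param min_loop Minimum hairpin loop size (default 3).
#' @return Maximum number of base pairs (>= 0; bounded by
#'   `floor(length/2)`).
#' @examples
#' structure_score("GGGGAAAACCCC")  # 4
#' @export
structure_score <- function(sequence, min_loop = 3L) {
  chars <- .seq_chars(sequence)
  n <- length(chars)
  if (n < 1L) stop("length must be >= 1", call. = FALSE)
  if (n < min_loop + 2L) return(0L)
  dp <- matrix(0L, n, n)
  for (span in (min_loop + 1L):(n - 1L)) {
    for (i in seq_len(n - span)) {
      j <- i + span
      best <- dp[i, j - 1L]  # j unpaired
      ks <- i:(j - min_loop - 1L)
      ks <- ks[.can_pair(chars[ks], chars[j])]
      if (length(ks)) {
        left <- ifelse(ks - 1L >= i, dp[i, pmax(ks - 1L, i)], 0L)
        inner <- ifelse(ks + 1L <= j - 1L, dp[cbind(pmin(ks + 1L, j - 1L),
                                                    j - 1L)], 0L)
        best <- max(best, max(left + 1L + inner))
      }
      dp[i, j] <- best
    }
  }
  as.integer(dp[1L, n])
}

#' Flag a 5' terminal oligopyrimidine (TOP) sequence
#'
#' A transcript is flagged TOP when it starts with C at position +1
#' followed by at least `min_tract` consecutive pyrimidines (C/T/U). The
#' sequence must begin at the annotated transcription start.
#'
#' @param sequence 5' UTR sequence starting at the +1 transcription start.
#' @param min_tract Minimum pyrimidine-tract length after the initial C
#'   (default 4).
#' @return Logical.
#' @examples
#' flag_top("CTTTTCAGG")  # TRUE
#' flag_top("CTTAG")      # FALSE: tract of 2 after the C
#' @export
flag_top <- function(sequence, min_tract = 4L) {
  ch <- .seq_chars(sequence)
  if (!length(ch) || ch[1L] != "C") return(FALSE)
  if (length(ch) < 1L + min_tract) return(FALSE)
  all(ch[2L:(1L + min_tract)] %in% c("C", "T"))
}

#' Per-UTR feature table
#'
#' Computes, for every sequence: length, GC percent, G4 and (GGC/A)n hit
#' counts (G3 default plus the weak G2 variant), TOP flag, and a structure
#' measure — the internal Nussinov pair count (optionally per nt) or an
#' externally computed folding free energy joined by id.
#'
#' @param sequences Named character vector of 5' UTR sequences.
#' @param g4_spec,g2_spec,ggc_spec Motif specifications; set `g2_spec =
#'   NULL` to skip the G2 scan.
#' @param structure `"nussinov"` (default), `"none"`, or `"external"`.
#' @param external_dg Data frame `(id, dG_kcal_per_mol)` when
#'   `structure = "external"`.
#' @param te_table Optional `te_table` to join `class` by id.
#' @return Data frame with one row per UTR: `id`, `length`, `gc_percent`,
#'   `g4_hits`, `g2_hits`, `ggc_hits`, `has_g4`, `has_ggc`, `is_top`,
#'   `structure_score` (and/or `dG_kcal_per_mol`), `te_class` when joined.
#' @export
utr_features <- function(sequences,
                         g4_spec = motif_spec("g_quadruplex"),
                         g2_spec = motif_spec("g_quadruplex",
                                              tract_length = 2L),
                         ggc_spec = motif_spec("ggc_repeat"),
                         structure = c("nussinov", "none", "external"),
                         external_dg = NULL,
                         te_table = NULL) {
  structure <- match.arg(structure)
  ids <- names(sequences)
  if (is.null(ids)) ids <- sprintf("utr_%04d", seq_along(sequences))
  out <- data.frame(
    id = ids,
    length = nchar(sequences),
    gc_percent = vapply(sequences, gc_content, numeric(1)),
    g4_hits = vapply(sequences, function(s) nrow(scan_g4(s, g4_spec)),
                     integer(1)),
    ggc_hits = vapply(sequences,
                      function(s) nrow(scan_ggc_repeats(s, ggc_spec)),
                      integer(1)),
    is_top = vapply(sequences, flag_top, logical(1)),
    stringsAsFactors = FALSE)
  if (!is.null(g2_spec))
    out$g2_hits <- vapply(sequences,
                          function(s) nrow(scan_g4(s, g2_spec)), integer(1))
  out$has_g4 <- out$g4_hits > 0
  out$has_ggc <- out$ggc_hits > 0
  if (structure == "nussinov") {
    out$structure_score <- vapply(sequences, structure_score, integer(1))
  } else if (structure == "external") {
    stopifnot(is.data.frame(external_dg),
              all(c("id", "dG_kcal_per_mol") %in% names(external_dg)))
    out$dG_kcal_per_mol <-
      external_dg$dG_kcal_per_mol[match(out$id, external_dg$id)]
  }
  if (!is.null(te_table))
    out$te_class <- te_table$class[match(out$id, te_table$gene_id)]
  rownames(out) <- NULL
  out
}
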