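#' Linear mRNA path model on the 40S solvent side
#'
#' Models the mRNA 3' of the entry channel as a fully stretched
#' single-stranded RNA threaded along the ES6S region: distance from the
#' channel is `(position - origin) * rise_per_base`. The defaults place
#' mRNA position +11 at the entry channel and use a rise of 4.5 Å per base
#' for a stretched RNA strand.
#'
#' @param origin_position mRNA nt index at the entry channel (default 11).
#' @param rise_per_base Rise per base in Angstrom (> 0, default 4.5).
#' @return Object of class `path_model`.
#' @export
path_model <- function(origin_position = 11L, rise_per_base = 4.5) {
  .assert_scalar_num(rise_per_base, "rise_per_base", lower = 0,
                     strict_lower = TRUE)
  structure(list(origin_position = origin_position,
                 rise_per_base = rise_per_base),
            class = "path_model")
}

#' Distance of an mRNA position from the entry channel
#'
#' Affine in the position: `distance(a) - distance(b) =
#' (a - b) * rise_per_base` exactly. Positions upstream of the origin
#' (inside the channel) return signed negative distances with a warning.
#'
#' @param nt_position mRNA position(s), 1-based.
#' @param model A [path_model()].
#' @return Distance(s) in Angstrom.
#' @examples
#' path_distance(27)  # (27 - 11) * 4.5 = 72
#' @export
path_distance <- function(nt_position, model = path_model()) {
  stopifnot(inherits(model, "path_model"))
  d <- (nt_position - model$origin_position) * model$rise_per_base
  if (any(d < 0))
    warning("position(s) upstream of the entry-channel origin: ",
            "negative (inside-channel) distances returned")
  d
}

#' Project crosslink positions along the solvent-side path
#'
#' Joins [path_distance()] over a set of mRNA positions, optionally
#' annotating a parallel vector of crosslinked rRNA positions against a
#' helix map. Output is ordered by position; duplicated input positions
#' are preserved.
#'
#' @param positions mRNA nt positions (>= 1).
#' @param model A [path_model()].
#' @param rrna_positions Optional rRNA positions (same length) to annotate.
#' @param map [helix_map()] used for the annotation.
#' @return Data frame `(position, distance_A[, rrna_position, helix])`.
#' @export
annotate_path_contacts <- function(positions, model = path_model(),
                                   rrna_positions = NULL,
                                   map = helix_map()) {
  if (!length(positions))
    return(data.frame(position = numeric(), distance_A = numeric()))
  if (any(positions < 1)) stop("positions must be >= 1", call. = FALSE)
  o <- order(positions)
  out <- data.frame(position = positions[o],
                    distance_A = suppressWarnings(
                      path_distance(positions[o], model)))
  if (!is.null(rrna_positions)) {
    stopifnot(length(rrna_positions) == length(positions))
    out$rrna_position <- rrna_positions[o]
    out$helix <- annotate_site(rrna_positions[o], map)
  }
  out
}

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

.revcomp <- function(chars) rev(unname(.COMPLEMENT[chars]))

# pairing predicate between an rRNA base and an oligo base read antiparallel
.duplex_pair <- function(r, o, allow_GU) {
  wc <- (r == "A" & o == "T") | (r == "T" & o == "A") |
    (r == "G" & o == "C") | (r == "C" & o == "G")
  if (allow_GU) wc | (r == "G" & o == "T") | (r == "T" & o == "G") else wc
}

#' Map the longest perfect oligo-rRNA duplex
#'
#' Finds the maximal-length contiguous antiparallel complementary stretch
#' between an oligonucleotide and any window of an rRNA sequence — the
#' region an RNase H protection experiment would identify for a DNA oligo.
#' Only perfect (ungapped, mismatch-free) complementarity is searched.
#' GU wobble pairs are excluded by default (DNA-RNA heteroduplex, the
#' RNase H substrate) and can be enabled for RNA-RNA mode. Ties are broken
#' by the smallest rRNA start.
#'
#' @param oligo_sequence Oligo sequence, 5' to 3'.
#' @param rrna_sequence rRNA (target) sequence, 5' to 3'.
#' @param min_pairs Minimum duplex length to report (default 6).
#' @param allow_GU Allow GU wobble pairs (default FALSE).
#' @return A `duplex_hit` (list with `rrna_start`, `rrna_end`,
#'   `oligo_start`, `oligo_end`, `n_pairs`, `unpaired_5prime_len`,
#'   `unpaired_3prime_len`; oligo coordinates 1-based 5' to 3'), or `NULL`
#'   when no stretch reaches `min_pairs`.
#' @export
map_oligo_duplex <- function(oligo_sequence, rrna_sequence, min_pairs = 6L,
                             allow_GU = FALSE) {
  oc <- .seq_chars(oligo_sequence)
  rc <- .seq_chars(rrna_sequence)
  if (!length(oc) || !length(rc))
    stop("sequences must be nonempty", call. = FALSE)
  n <- length(rc); m <- length(oc)
  # L[i, j]: length of the perfect duplex ending at rRNA position i paired
  # with oligo position j (antiparallel: previous pair is (i-1, j+1))
  L <- matrix(0L, n + 1L, m + 2L)
  best <- 0L; best_i <- 0L; best_j <- 0L
  for (i in seq_len(n)) {
    pair <- .duplex_pair(rc[i], oc, allow_GU)
    js <- which(pair)
    if (length(js)) {
      L[i + 1L, js + 1L] <- L[i, js + 2L] + 1L
      mx <- max(L[i + 1L, js + 1L])
      if (mx > best) {
        best <- mx
        best_i <- i
        best_j <- js[which.max(L[i + 1L, js + 1L])]
      }
    }
  }
  if (best < min_pairs) return(NULL)
  # scan in rRNA order guarantees the FIRST attainment of the maximal
  # length, i.e. the smallest rRNA start among ties
  rrna_end <- best_i; rrna_start <- best_i - best + 1L
  oligo_start <- best_j; oligo_end <- best_j + best - 1L
  structure(list(rrna_start = rrna_start, rrna_end = rrna_end,
                 oligo_start = oligo_start, oligo_end = oligo_end,
                 n_pairs = best,
                 unpaired_5prime_len = oligo_start - 1L,
                 unpaired_3prime_len = m - oligo_end),
            class = "duplex_hit")
}

#' @export
print.duplex_hit <- function(x, ...) {
  cat(sprintf(paste0("duplex: rRNA %d-%d (%d bp), oligo %d-%d; ",
                     "unpaired 5' %d nt, 3' %d nt\n"),
              x$rrna_start, x$rrna_end, x$n_pairs, x$oligo_start,
              x$oligo_end, x$unpaired_5prime_len, x$unpaired_3prime_len))
  invisible(x)
}
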