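#' Per-nucleotide RT-stop (crosslink) profile on an rRNA reference
#'
#' Holds termination-event counts at every 1-based reference position.
#' Because reverse transcription arrests one nucleotide 3' of a crosslink
#' adduct, the site reported at position p was tallied from reads whose 5'
#' ends mapped at p + 1.
#'
#' @param counts Non-negative integer vector, one element per reference
#'   position (1-based).
#' @param reference_name Reference name.
#' @param total_reads Total reads examined (>= sum(counts)).
#' @param skipped Named integer vector describing skipped records (optional
#'   report from ingestion).
#' @return An object of class `rt_stop_profile`.
#' @export
rt_stop_profile <- function(counts, reference_name = "18S",
                            total_reads = sum(counts),
                            skipped = integer(0)) {
  if (any(counts < 0)) stop("counts must be >= 0", call. = FALSE)
  if (sum(counts) > total_reads)
    stop("sum(counts) cannot exceed total_reads", call. = FALSE)
  structure(list(reference_name = reference_name,
                 reference_length = length(counts),
                 counts = as.numeric(counts),
                 total_reads = total_reads,
                 skipped = skipped),
            class = "rt_stop_profile")
}

#' @export
print.rt_stop_profile <- function(x, ...) {
  cat(sprintf("RT-stop profile on %s (%d nt): %g site events from %g reads\n",
              x$reference_name, x$reference_length, sum(x$counts),
              x$total_reads))
  if (length(x$skipped) && sum(x$skipped) > 0)
    cat("  skipped records:",
        paste(names(x$skipped), x$skipped, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Call RT-stop crosslink sites from aligned reads
#'
#' For every sense-strand read whose 5' end maps at 1-based position p >= 2,
#' the crosslink site is the 5'-adjacent nucleotide p - 1 and its count is
#' incremented. Reads starting at p = 1 have no 5'-adjacent nucleotide:
#' they count toward `total_reads` but contribute no site. Reverse-strand
#' records and malformed positions are skipped and tallied in the profile's
#' skip report.
#'
#' @param alignments Data frame with columns `ref` and `pos_5prime`
#'   (1-based), optionally `flag` (SAM flag; records with the 0x10
#'   reverse-strand bit are skipped) — as returned by [gen_rtts_reads()] or
#'   [read_sam_minimal()].
#' @param reference_name Expected reference name; alignments to any other
#'   reference are an error.
#' @param reference_length Reference length in nt.
#' @return An [rt_stop_profile()].
#' @examples
#' aln <- data.frame(ref = "18S", pos_5prime = c(804, 804, 851))
#' prof <- call_rt_stops(aln, "18S", 1869)
#' prof$counts[c(803, 850)]
#' @export
call_rt_stops <- function(alignments, reference_name, reference_length) {
  stopifnot(is.data.frame(alignments), "pos_5prime" %in% names(alignments))
  reference_length <- as.integer(reference_length)
  if ("ref" %in% names(alignments) && nrow(alignments)) {
    bad <- unique(alignments$ref[alignments$ref != reference_name])
    if (length(bad))
      stop("alignment to unknown reference: ", paste(bad, collapse = ", "),
           call. = FALSE)
  }
  pos <- alignments$pos_5prime
  skipped <- c(reverse_strand = 0L, malformed_position = 0L)
  if ("flag" %in% names(alignments)) {
    rev <- bitwAnd(as.integer(alignments$flag), 16L) != 0L
    skipped["reverse_strand"] <- sum(rev)
    pos <- pos[!rev]
  }
  ok <- is.finite(pos) & pos >= 1 & pos <= reference_length & pos == round(pos)
  skipped["malformed_position"] <- sum(!ok)
  pos <- as.integer(pos[ok])
  total <- length(pos)
  sites <- pos[pos >= 2L] - 1L
  counts <- tabulate(sites, nbins = reference_length)
  rt_stop_profile(counts, reference_name = reference_name,
                  total_reads = total, skipped = skipped)
}

#' Parse a minimal SAM text file into an alignment table
#'
#' Reads the mandatory SAM fields QNAME, FLAG, RNAME, POS and returns the
#' sense-strand 5' end as `pos_5prime` (= POS for forward-strand records,
#' after any soft clipping, which the aligner already excluded from POS).
#' Unmapped records (flag 0x4 or RNAME `*`) are dropped.
#'
#' @param path SAM file path.
#' @return Data frame `(read_id, flag, ref, pos_5prime)`.
#' @export
read_sam_minimal <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (!length(lines))
    return(data.frame(read_id = character(), flag = integer(),
                      ref = character(), pos_5prime = integer(),
                      stringsAsFactors = FALSE))
  f <- strsplit(lines, "\t", fixed = TRUE)
  n_fields <- lengths(f)
  if (any(n_fields < 4L))
    stop("malformed SAM record (fewer than 4 fields)", call. = FALSE)
  out <- data.frame(read_id = vapply(f, `[[`, "", 1L),
                    flag = as.integer(vapply(f, `[[`, "", 2L)),
                    ref = vapply(f, `[[`, "", 3L),
                    pos_5prime = as.integer(vapply(f, `[[`, "", 4L)),
                    stringsAsFactors = FALSE)
  mapped <- bitwAnd(out$flag, 4L) == 0L & out$ref != "*"
  out[mapped, , drop = FALSE]
}

#' Top-k most abundant crosslink sites
#'
#' Ranks nonzero positions by count (descending); ties broken by ascending
#' position so output is deterministic. The k = 18 default mirrors the
#' standard display of the 18 most abundant sites on 18S rRNA.
#'
#' @param profile An [rt_stop_profile()].
#' @param k Number of sites to return (>= 0); fewer are returned if fewer
#'   nonzero positions exist.
#' @return Data frame `(position, count)` sorted by the tie rule.
#' @export
top_sites <- function(profile, k = 18L) {
  stopifnot(inherits(profile, "rt_stop_profile"))
  .assert_scalar_num(k, "k", lower = 0)
  nz <- which(profile$counts > 0)
  if (!length(nz) || k == 0)
    return(data.frame(position = integer(), count = numeric()))
  ord <- nz[order(-profile$counts[nz], nz)]
  keep <- head(ord, k)
  data.frame(position = keep, count = profile$counts[keep])
}

#' ES6S helix interval map
#'
#' Named 1-based inclusive intervals on 18S rRNA. The default is the four
#' ES6S helices: A (681–735), B (740–793), C–D (795–864), E (865–910).
#' Gaps between intervals are allowed (e.g. 736–739); overlaps are a
#' configuration error.
#'
#' @param intervals Data frame with columns `label`, `start`, `end`
#'   (1-based inclusive, `start <= end`).
#' @return Object of class `helix_map`.
#' @export
helix_map <- function(intervals = default_es6s_map()) {
  stopifnot(is.data.frame(intervals),
            all(c("label", "start", "end") %in% names(intervals)))
  if (any(intervals$start > intervals$end))
    stop("interval start must be <= end", call. = FALSE)
  o <- order(intervals$start)
  s <- intervals$start[o]; e <- intervals$end[o]
  if (nrow(intervals) > 1L && any(s[-1L] <= e[-length(e)]))
    stop("overlapping intervals in helix map", call. = FALSE)
  structure(intervals, class = c("helix_map", "data.frame"))
}

#' @rdname helix_map
#' @export
default_es6s_map <- function() {
  data.frame(label = c("ES6S_A", "ES6S_B", "ES6S_CD", "ES6S_E"),
             start = c(681L, 740L, 795L, 865L),
             end = c(735L, 793L, 864L, 910L),
             stringsAsFactors = FALSE)
}

#' Annotate a position against a helix interval map
#'
#' @param position 1-based position(s).
#' @param map A [helix_map()].
#' @return Character vector of labels, `NA` where the position falls in a
#'   gap between intervals.
#' @examples
#' annotate_site(802)   # "ES6S_CD" — base of helix C
#' annotate_site(737)   # NA: gap between ES6S_A and ES6S_B
#' @export
annotate_site <- function(position, map = helix_map()) {
  stopifnot(inherits(map, "helix_map"))
  if (any(position < 1)) stop("positions must be >= 1", call. = FALSE)
  vapply(position, function(p) {
    hit <- which(map$start <= p & p <= map$end)
    if (length(hit)) map$label[hit] else NA_character_
  }, character(1))
}

#' Fraction of crosslink events inside a reference region
#'
#' Defaults to nt 700–910, the region concentrating the vast majority of
#' crosslinks in the ES6S channel.
#'
#' @param profile An [rt_stop_profile()].
#' @param start,end 1-based inclusive bounds.
#' @return Fraction in `[0, 1]`; 0 when the profile holds no events.
#' @export
region_fraction <- function(profile, start = 700L, end = 910L) {
  stopifnot(inherits(profile, "rt_stop_profile"))
  if (!(start >= 1 && start <= end && end <= profile$reference_length))
    stop("require 1 <= start <= end <= reference_length", call. = FALSE)
  tot <- sum(profile$counts)
  if (tot == 0) return(0)
  sum(profile$counts[start:end]) / tot
}

#' Compare two RT-stop profiles position by position
#'
#' Normalizes each profile to rates (count / total site events) and reports
#' the per-position log2 rate ratio with a pseudocount of 1 on counts, so
#' disjoint supports stay finite. Positions at zero in both profiles are
#' omitted.
#'
#' @param profile_a,profile_b [rt_stop_profile()]s on the same reference.
#' @param pseudocount Pseudocount added to each count (default 1).
#' @return Data frame `(position, count_a, count_b, rate_a, rate_b,
#'   log2_ratio)` where `log2_ratio` is a over b.
#' @export
compare_profiles <- function(profile_a, profile_b, pseudocount = 1) {
  stopifnot(inherits(profile_a, "rt_stop_profile"),
            inherits(profile_b, "rt_stop_profile"))
  if (profile_a$reference_length != profile_b$reference_length)
    stop("profiles have differing reference lengths", call. = FALSE)
  ca <- profile_a$counts; cb <- profile_b$counts
  keep <- which(ca > 0 | cb > 0)
  ta <- max(sum(ca), 1); tb <- max(sum(cb), 1)
  log2_ratio <- log2((ca[keep] + pseudocount) / ta) -
    log2((cb[keep] + pseudocount) / tb)
  data.frame(position = keep, count_a = ca[keep], count_b = cb[keep],
             rate_a = ca[keep] / ta, rate_b = cb[keep] / tb,
             log2_ratio = log2_ratio)
}

#' Export an RT-stop profile and its top sites as genome-browser tracks
#'
#' Internal coordinates are 1-based inclusive (matching rRNA nt numbering);
#' bedGraph/BED output converts to 0-based half-open.
#'
#' @param profile An [rt_stop_profile()].
#' @param path Output file path.
#' @param k Number of top sites for the BED export.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(profile, path) {
  nz <- which(profile$counts > 0)
  df <- data.frame(chrom = profile$reference_name, start = nz - 1L, end = nz,
                   value = profile$counts[nz])
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_bedgraph
#' @export
write_bed_top_sites <- function(profile, path, k = 18L) {
  ts <- top_sites(profile, k)
  df <- data.frame(chrom = profile$reference_name, start = ts$position - 1L,
                   end = ts$position,
                   name = sprintf("site_%d", ts$position),
                   score = ts$count)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Tabulate an RT-stop profile with helix annotation
#'
#' @param profile An [rt_stop_profile()].
#' @param map A [helix_map()].
#' @return Data frame `(position, count, rate, helix)` over nonzero
#'   positions.
#' @export
site_table <- function(profile, map = helix_map()) {
  nz <- which(profile$counts > 0)
  tot <- max(sum(profile$counts), 1)
  data.frame(position = nz, count = profile$counts[nz],
             rate = profile$counts[nz] / tot,
             helix = annotate_site(nz, map),
             stringsAsFactors = FALSE)
}
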