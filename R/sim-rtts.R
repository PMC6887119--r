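#' Specification for a simulated RT-stop sequencing library
#'
#' Describes a synthetic reverse-transcriptase termination site (RTTS)
#' library on an rRNA-like reference: a set of planted crosslink sites with
#' expected read intensities, plus a uniform background. Signal reads model
#' the pure RT-stop mechanism: reverse transcription arrests one nucleotide
#' 3' of the adduct, so a read whose 5' end maps at position p reports a
#' crosslink at p - 1.
#'
#' @param reference_length Reference length in nt. Default 1869, the length
#'   of mammalian 18S rRNA.
#' @param planted_sites Data frame with columns `position` (1-based nt,
#'   must be in `[2, reference_length]`) and `intensity` (expected signal
#'   reads per site, > 0).
#' @param background_rate Expected background reads per nt (>= 0). Background
#'   read 5' ends are uniform over the reference.
#' @param n_reads Total reads to draw. `NULL` (default) uses the expected
#'   total `sum(intensity) + background_rate * reference_length`, rounded.
#' @param read_length Read length in nt used when writing SAM (default 30).
#' @param readthrough Geometric read-through probability: with probability
#'   `readthrough` per nt, the RT reads past the adduct, shifting the 5' end
#'   further 5'. Default 0 (pure RT-stop, no smearing).
#' @param seed Integer seed; generation is bit-reproducible given the seed.
#' @return An object of class `rtts_sim_spec`.
#' @seealso [gen_rtts_reads()]
#' @export
rtts_sim_spec <- function(reference_length = 1869L,
                          planted_sites = data.frame(position = integer(),
                                                     intensity = numeric()),
                          background_rate = 0,
                          n_reads = NULL,
                          read_length = 30L,
                          readthrough = 0,
                          seed = 1L) {
  .assert_scalar_num(reference_length, "reference_length", lower = 1)
  .assert_scalar_num(background_rate, "background_rate", lower = 0)
  .assert_scalar_num(read_length, "read_length", lower = 1)
  .assert_scalar_num(readthrough, "readthrough", lower = 0, upper = 0.999)
  stopifnot(is.data.frame(planted_sites),
            all(c("position", "intensity") %in% names(planted_sites)))
  if (nrow(planted_sites)) {
    if (any(planted_sites$position < 2L))
      stop("planted site at position 1 rejected: no 5'-adjacent nucleotide exists",
           call. = FALSE)
    if (any(planted_sites$position > reference_length))
      stop("planted positions must lie within the reference", call. = FALSE)
    if (any(planted_sites$intensity <= 0))
      stop("planted intensities must be > 0", call. = FALSE)
    if (anyDuplicated(planted_sites$position))
      stop("planted positions must be unique", call. = FALSE)
  }
  if (is.null(n_reads))
    n_reads <- round(sum(planted_sites$intensity) +
                       background_rate * reference_length)
  .assert_scalar_num(n_reads, "n_reads", lower = 0)
  structure(list(reference_length = as.integer(reference_length),
                 planted_sites = planted_sites,
                 background_rate = background_rate,
                 n_reads = as.integer(n_reads),
                 read_length = as.integer(read_length),
                 readthrough = readthrough,
                 seed = as.integer(seed)),
            class = "rtts_sim_spec")
}

#' Simulate an RT-stop alignment library with known crosslink sites
#'
#' Draws `n_reads` reads, each either a signal read (5' end at
#' `site + 1`, sites chosen multinomially in proportion to their planted
#' intensities) or a background read (5' end uniform over the reference).
#' The returned truth table records each planted site and its expected
#' fraction of total reads.
#'
#' @param spec An [rtts_sim_spec()].
#' @param reference_name Reference sequence name (default `"18S"`).
#' @return A list with
#'   \describe{
#'     \item{alignments}{data frame `(read_id, ref, pos_5prime)`, one row
#'       per read, positions 1-based.}
#'     \item{truth}{data frame `(position, intensity, expected_fraction)`.}
#'     \item{spec}{the input spec.}
#'   }
#' @examples
#' spec <- rtts_sim_spec(planted_sites = data.frame(position = 850,
#'                                                  intensity = 100),
#'                       n_reads = 100, seed = 7)
#' sim <- gen_rtts_reads(spec)
#' all(sim$alignments$pos_5prime == 851)
#' @export
gen_rtts_reads <- function(spec, reference_name = "18S") {
  stopifnot(inherits(spec, "rtts_sim_spec"))
  set.seed(spec$seed)
  sites <- spec$planted_sites
  bg_weight <- spec$background_rate * spec$reference_length
  weights <- c(sites$intensity, bg_weight)
  truth <- data.frame(position = sites$position,
                      intensity = sites$intensity,
                      expected_fraction = if (sum(weights) > 0)
                        sites$intensity / sum(weights) else numeric(nrow(sites)))
  n <- spec$n_reads
  if (n == 0L || sum(weights) == 0) {
    aln <- data.frame(read_id = character(), ref = character(),
                      pos_5prime = integer(), stringsAsFactors = FALSE)
    return(list(alignments = aln, truth = truth, spec = spec))
  }
  draw <- as.vector(rmultinom(1L, n, weights))
  n_bg <- draw[length(draw)]
  pos <- integer(0)
  if (nrow(sites)) {
    pos <- rep.int(sites$position + 1L, draw[seq_len(nrow(sites))])
    if (spec$readthrough > 0 && length(pos)) {
      shift <- rgeom(length(pos), prob = 1 - spec$readthrough)
      pos <- pmax(1L, pos - shift)
    }
  }
  if (n_bg > 0)
    pos <- c(pos, sample.int(spec$reference_length, n_bg, replace = TRUE))
  pos <- sample(pos)  # shuffle so read order carries no signal
  aln <- data.frame(read_id = sprintf("read_%06d", seq_along(pos)),
                    ref = reference_name,
                    pos_5prime = as.integer(pos),
                    stringsAsFactors = FALSE)
  list(alignments = aln, truth = truth, spec = spec)
}

#' Write simulated alignments as a minimal SAM file
#'
#' Emits a valid single-reference SAM with fields QNAME, FLAG (0), RNAME,
#' POS, MAPQ (255), CIGAR (`<len>M`, truncated at the reference end), plus
#' `*`/0 placeholders. The inverse of [read_sam_minimal()].
#'
#' @param alignments Data frame `(read_id, ref, pos_5prime)`.
#' @param path Output file path.
#' @param reference_length Reference length for the `@SQ` header line.
#' @param read_length Read length used for the CIGAR.
#' @return `path`, invisibly.
#' @export
write_alignments_sam <- function(alignments, path, reference_length,
                                 read_length = 30L) {
  refs <- unique(alignments$ref)
  if (length(refs) > 1L) stop("single-reference SAM writer", call. = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  if (length(refs))
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", refs, as.integer(reference_length)),
               con)
  if (nrow(alignments)) {
    len <- pmin(read_length, reference_length - alignments$pos_5prime + 1L)
    writeLines(sprintf("%s\t0\t%s\t%d\t255\t%dM\t*\t0\t0\t*\t*",
                       alignments$read_id, alignments$ref,
                       alignments$pos_5prime, len), con)
  }
  invisible(path)
}
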