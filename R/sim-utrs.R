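#' Specification for simulated 5' UTR sequence sets
#'
#' Describes per-group 5' UTR simulation: log-normal length distribution,
#' target GC fraction (bases drawn i.i.d. with P(G) = P(C) = gc/2), and
#' independent per-sequence planting probabilities for a canonical
#' G-quadruplex motif and a (GGC/A)4 tandem repeat. Planted motifs are
#' written verbatim at a uniformly chosen position and recorded in the
#' truth table. Defaults emulate a translationally repressed ("TE_down",
#' long / GC-rich / motif-rich) versus de-repressed ("TE_up", short /
#' GC-poor) contrast.
#'
#' @param n_sequences Sequences per group (scalar recycled or per group).
#' @param groups Character vector of group labels.
#' @param length_meanlog,length_sdlog Log-normal length parameters per group.
#' @param min_length Lower truncation for lengths (>= 1).
#' @param gc_target GC fraction per group, in `[0, 1]`.
#' @param p_g4,p_ggc Planting probability per group for the G4 motif
#'   (`GGGAGGGAGGGAGGG`) and the (GGC/A)4 repeat (`GGCGGCGGCGGC`).
#' @param g_free If `TRUE`, background bases are drawn from {A, C, T} only
#'   (no G), a negative-control alphabet for G-motif scanners; requires
#'   `p_g4 = p_ggc = 0`.
#' @param seed Integer seed.
#' @return An object of class `utr_sim_spec`.
#' @export
utr_sim_spec <- function(n_sequences = 500L,
                         groups = c("TE_down", "TE_up"),
                         length_meanlog = c(5.2, 4.3),
                         length_sdlog = 0.5,
                         min_length = 20L,
                         gc_target = c(0.65, 0.5),
                         p_g4 = c(0.45, 0.15),
                         p_ggc = c(0.4, 0.1),
                         g_free = FALSE,
                         seed = 1L) {
  k <- length(groups)
  spec <- list(n_sequences = rep_len(as.integer(n_sequences), k),
               groups = groups,
               length_meanlog = rep_len(length_meanlog, k),
               length_sdlog = rep_len(length_sdlog, k),
               min_length = as.integer(min_length),
               gc_target = rep_len(gc_target, k),
               p_g4 = rep_len(p_g4, k),
               p_ggc = rep_len(p_ggc, k),
               g_free = isTRUE(g_free),
               seed = as.integer(seed))
  if (any(spec$gc_target < 0 | spec$gc_target > 1))
    stop("gc_target must be in [0, 1]", call. = FALSE)
  if (any(c(spec$p_g4, spec$p_ggc) < 0 | c(spec$p_g4, spec$p_ggc) > 1))
    stop("planting probabilities must be in [0, 1]", call. = FALSE)
  if (spec$min_length < 1L) stop("lengths must be >= 1", call. = FALSE)
  if (spec$g_free && any(c(spec$p_g4, spec$p_ggc) > 0))
    stop("g_free alphabet is incompatible with G-motif planting",
         call. = FALSE)
  structure(spec, class = "utr_sim_spec")
}

.G4_MOTIF <- "GGGAGGGAGGGAGGG"
.GGC_MOTIF <- "GGCGGCGGCGGC"

.plant_motif <- function(seq_chars, motif) {
  m <- nchar(motif)
  if (m > length(seq_chars))
    stop("motif longer than sequence", call. = FALSE)
  start <- sample.int(length(seq_chars) - m + 1L, 1L)
  seq_chars[start:(start + m - 1L)] <- strsplit(motif, "")[[1L]]
  list(chars = seq_chars, start = start)
}

#' Simulate 5' UTR sequences with planted motifs
#'
#' @param spec A [utr_sim_spec()].
#' @return List with
#'   \describe{
#'     \item{sequences}{named character vector of DNA sequences
#'       (`utr_<group>_<i>`).}
#'     \item{truth}{data frame `(id, group, length, gc_target, g4_planted,
#'       g4_start, ggc_planted, ggc_start)`.}
#'   }
#' @examples
#' sim <- gen_utrs(utr_sim_spec(n_sequences = 5, seed = 3))
#' names(sim$sequences)[1:3]
#' @export
gen_utrs <- function(spec) {
  stopifnot(inherits(spec, "utr_sim_spec"))
  set.seed(spec$seed)
  out_seq <- character(0)
  truth <- list()
  for (g in seq_along(spec$groups)) {
    n <- spec$n_sequences[g]
    if (n == 0L) next
    lens <- pmax(spec$min_length,
                 round(exp(rnorm(n, spec$length_meanlog[g],
                                 spec$length_sdlog[g]))))
    gc <- spec$gc_target[g]
    probs <- if (spec$g_free) {
      # G-free control: keep the GC target on C alone
      c(A = (1 - gc) / 2, C = gc, G = 0, T = (1 - gc) / 2)
    } else {
      c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    }
    plant_g4 <- runif(n) < spec$p_g4[g]
    plant_ggc <- runif(n) < spec$p_ggc[g]
    ids <- sprintf("utr_%s_%04d", spec$groups[g], seq_len(n))
    seqs <- character(n)
    g4_start <- ggc_start <- rep(NA_integer_, n)
    for (i in seq_len(n)) {
      chars <- sample(names(probs), lens[i], replace = TRUE, prob = probs)
      if (plant_ggc[i]) {
        p <- .plant_motif(chars, .GGC_MOTIF)
        chars <- p$chars; ggc_start[i] <- p$start
      }
      if (plant_g4[i]) {
        p <- .plant_motif(chars, .G4_MOTIF)
        chars <- p$chars; g4_start[i] <- p$start
        if (!is.na(ggc_start[i]) &&
            abs(g4_start[i] - ggc_start[i]) < nchar(.G4_MOTIF))
          ggc_start[i] <- NA_integer_  # G4 overwrote the repeat
      }
      seqs[i] <- paste(chars, collapse = "")
    }
    names(seqs) <- ids
    out_seq <- c(out_seq, seqs)
    truth[[g]] <- data.frame(id = ids, group = spec$groups[g],
                             length = lens, gc_target = gc,
                             g4_planted = plant_g4, g4_start = g4_start,
                             ggc_planted = plant_ggc & !is.na(ggc_start),
                             ggc_start = ggc_start,
                             stringsAsFactors = FALSE)
  }
  list(sequences = out_seq, truth = do.call(rbind, truth))
}

#' Write sequences to a FASTA file
#'
#' @param sequences Named character vector of DNA sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_utr_fasta <- function(sequences, path) {
  x <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' @param path FASTA file path (DNA or RNA; U is mapped to T downstream).
#' @return Named character vector.
#' @export
read_utr_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  setNames(toupper(as.character(x)), names(x))
}
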