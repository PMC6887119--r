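#' Median-of-ratios size factors from reference rows
#'
#' The per-sample size factor is the median, over reference rows (spike-ins
#' by default), of `count[i, j] / geometric_mean_i`, where the geometric
#' mean is taken across samples. Rows containing any zero are excluded from
#' the reference set (their geometric mean would be degenerate). Factors
#' are rescaled so their geometric mean is 1, which fixes the arbitrary
#' overall scale.
#'
#' @param counts Numeric matrix, genes x samples.
#' @param reference_rows Row indices or names of the reference set
#'   (e.g. ERCC spike-in rows); `NULL` uses all rows (all-gene fallback).
#' @return Named numeric vector of size factors, one per sample, with
#'   geometric mean 1.
#' @examples
#' m <- rbind(a = c(10, 20), b = c(30, 60))
#' size_factors(m)           # ratio exactly 2, geomean 1
#' @export
size_factors <- function(counts, reference_rows = NULL) {
  counts <- as.matrix(counts)
  ref <- if (is.null(reference_rows)) counts else
    counts[reference_rows, , drop = FALSE]
  usable <- rowSums(ref <= 0) == 0
  if (!any(usable))
    stop(paste("no usable reference row (all contain zeros);",
               "consider the all-gene fallback (reference_rows = NULL)"),
         call. = FALSE)
  ref <- ref[usable, , drop = FALSE]
  logr <- log(ref)
  ratios <- exp(logr - rowMeans(logr))
  f <- apply(ratios, 2L, median)
  f <- f / exp(mean(log(f)))
  setNames(f, colnames(counts))
}

#' Normalize a count matrix by size factors
#'
#' @param counts Genes x samples matrix.
#' @param factors Per-sample size factors (from [size_factors()]).
#' @return Matrix of `counts[, j] / factors[j]`.
#' @export
normalize_counts <- function(counts, factors) {
  counts <- as.matrix(counts)
  if (length(factors) != ncol(counts))
    stop("one size factor per sample required", call. = FALSE)
  sweep(counts, 2L, factors, `/`)
}

.check_design <- function(design, n_samples) {
  stopifnot(is.data.frame(design),
            all(c("sample_id", "fraction", "condition", "replicate") %in%
                  names(design)))
  if (!missing(n_samples) && nrow(design) != n_samples)
    stop("design rows must match count columns", call. = FALSE)
  for (cond in unique(design$condition))
    for (fr in c("monosomal", "polysomal"))
      if (!any(design$condition == cond & design$fraction == fr))
        stop(sprintf("condition '%s' lacks %s samples", cond, fr),
             call. = FALSE)
  invisible(design)
}

#' Per-gene translation efficiency per condition
#'
#' TE is the ratio of mRNA abundance in the polysomal fraction to that in
#' the monosomal fraction. Abundances are replicate means of normalized
#' counts; a pseudocount keeps the ratio finite.
#'
#' @param normalized_counts Genes x samples matrix (>= 0), already
#'   size-factor normalized.
#' @param design Sample design (`sample_id`, `fraction`, `condition`,
#'   `replicate`), rows aligned with the columns of `normalized_counts`.
#' @param pseudocount Added to both means before the ratio (default 0.5,
#'   the half-count convention).
#' @return Matrix genes x conditions of TE values (> 0).
#' @export
compute_te <- function(normalized_counts, design, pseudocount = 0.5) {
  normalized_counts <- as.matrix(normalized_counts)
  .check_design(design, ncol(normalized_counts))
  if (any(normalized_counts < 0))
    stop("normalized counts must be >= 0", call. = FALSE)
  conds <- unique(design$condition)
  te <- vapply(conds, function(cond) {
    p <- rowMeans(normalized_counts[, design$condition == cond &
                                      design$fraction == "polysomal",
                                    drop = FALSE])
    m <- rowMeans(normalized_counts[, design$condition == cond &
                                      design$fraction == "monosomal",
                                    drop = FALSE])
    (p + pseudocount) / (m + pseudocount)
  }, numeric(nrow(normalized_counts)))
  te <- matrix(te, nrow = nrow(normalized_counts))
  dimnames(te) <- list(rownames(normalized_counts), conds)
  te
}

#' Log2 fold change of translation efficiency
#'
#' `log2(te_control / te_treated)`: positive values mean the treatment
#' reduced TE (translation down).
#'
#' @param te_control,te_treated Positive TE values (vectorized).
#' @return log2 FC TE.
#' @export
fc_te <- function(te_control, te_treated) {
  if (any(te_control <= 0) || any(te_treated <= 0))
    stop("TE values must be > 0", call. = FALSE)
  log2(te_control / te_treated)
}

#' Per-gene test for TE change on replicate-level log2 TE
#'
#' Tests, gene by gene, whether per-replicate log2 TE differs between two
#' conditions, then adjusts across genes with Benjamini-Hochberg. The
#' default is an empirical-Bayes moderated t: the pooled two-group variance
#' of each gene is shrunk toward a common prior variance `s0^2` with prior
#' degrees of freedom `d0` estimated from all genes by moment matching on
#' `log s^2` (trigamma inversion), and the statistic is referred to a t
#' distribution on `d0 + d_g` degrees of freedom. With only 2-3 replicates
#' per group, sharing variance information across genes is what gives the
#' test usable power; an unmoderated Welch t on ~4 df cannot resolve even
#' a four-fold TE change at typical count dispersion. Welch's t and a
#' label-permutation test are available as alternatives. Degenerate genes
#' with zero variance and equal means get p = 1.
#'
#' @param log2_te Genes x replicates matrix of per-replicate log2 TE.
#' @param condition_labels Condition label per column (exactly 2 levels,
#'   >= 2 replicates each).
#' @param method `"moderated"` (default), `"welch"`, or `"permutation"`.
#' @param n_perm Permutations for `method = "permutation"`; all distinct
#'   label assignments are enumerated exactly when fewer than `n_perm`
#'   exist.
#' @return Data frame `(p_value, p_adj)`, one row per gene.
#' @export
test_te_change <- function(log2_te, condition_labels,
                           method = c("moderated", "welch", "permutation"),
                           n_perm = 1000L) {
  method <- match.arg(method)
  log2_te <- as.matrix(log2_te)
  labs <- as.factor(condition_labels)
  if (nlevels(labs) != 2L)
    stop("exactly two conditions required", call. = FALSE)
  i1 <- which(labs == levels(labs)[1L]); i2 <- which(labs == levels(labs)[2L])
  if (length(i1) < 2L || length(i2) < 2L)
    stop(">= 2 replicates per condition required", call. = FALSE)
  x1 <- log2_te[, i1, drop = FALSE]; x2 <- log2_te[, i2, drop = FALSE]
  d <- rowMeans(x1) - rowMeans(x2)
  if (method == "moderated") {
    n1 <- length(i1); n2 <- length(i2)
    v1 <- apply(x1, 1L, var); v2 <- apply(x2, 1L, var)
    dg <- n1 + n2 - 2L
    s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / dg
    sq <- .squeeze_var(s2, dg)
    se2 <- sq$var_post * (1 / n1 + 1 / n2)
    tstat <- d / sqrt(se2)
    df_total <- dg + sq$df_prior
    p <- if (is.finite(df_total)) 2 * pt(-abs(tstat), df_total) else
      2 * pnorm(-abs(tstat))
    degenerate <- se2 == 0
    p[degenerate & d == 0] <- 1
    p[degenerate & d != 0] <- .Machine$double.xmin
  } else if (method == "welch") {
    n1 <- length(i1); n2 <- length(i2)
    v1 <- apply(x1, 1L, var); v2 <- apply(x2, 1L, var)
    se2 <- v1 / n1 + v2 / n2
    tstat <- d / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    p <- 2 * pt(-abs(tstat), df)
    # zero variance in both groups: no-signal convention p = 1 on equal
    # means; otherwise the difference is infinitely resolved
    degenerate <- se2 == 0
    p[degenerate & d == 0] <- 1
    p[degenerate & d != 0] <- .Machine$double.xmin
  } else {
    stat_obs <- abs(d)
    n <- ncol(log2_te)
    n_distinct <- choose(n, length(i1))
    if (n_distinct <= n_perm) {
      # enumerate every distinct label assignment (exact permutation p;
      # the observed assignment is one of them, so p >= 1/n_distinct)
      sets <- combn(n, length(i1))
      exceed <- numeric(nrow(log2_te))
      for (b in seq_len(ncol(sets))) {
        take <- sets[, b]
        db <- rowMeans(log2_te[, take, drop = FALSE]) -
          rowMeans(log2_te[, -take, drop = FALSE])
        exceed <- exceed + (abs(db) >= stat_obs - 1e-12)
      }
      p <- exceed / n_distinct
    } else {
      exceed <- numeric(nrow(log2_te))
      for (b in seq_len(n_perm)) {
        take <- sample.int(n, length(i1))
        db <- rowMeans(log2_te[, take, drop = FALSE]) -
          rowMeans(log2_te[, -take, drop = FALSE])
        exceed <- exceed + (abs(db) >= stat_obs - 1e-12)
      }
      p <- (exceed + 1) / (n_perm + 1)
    }
  }
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  data.frame(p_value = p, p_adj = p.adjust(p, method = "BH"))
}

# Empirical-Bayes variance shrinkage (Smyth-style). Fits a scaled inverse
# chi-square prior (s0^2, d0) to the observed per-gene variances s2 on dg
# degrees of freedom by matching moments of log s2: with
# e_g = log s2_g - digamma(dg/2) + log(dg/2),
#   E[e] = log s0^2 - digamma(d0/2) + log(d0/2)
#   Var[e] = trigamma(dg/2) + trigamma(d0/2).
# Returns the posterior variances (d0 s0^2 + dg s2)/(d0 + dg).
.squeeze_var <- function(s2, dg) {
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 2L)
    return(list(var_post = s2, df_prior = 0, var_prior = NA_real_))
  e <- log(s2[ok]) - digamma(dg / 2) + log(dg / 2)
  ev <- var(e) - trigamma(dg / 2)
  if (ev <= 0) {
    d0 <- Inf
    s0 <- exp(mean(e))
  } else {
    # invert trigamma(d0/2) = ev
    f <- function(x) trigamma(x / 2) - ev
    d0 <- tryCatch(uniroot(f, c(1e-4, 1e7))$root, error = function(err) Inf)
    s0 <- if (is.finite(d0))
      exp(mean(e) + digamma(d0 / 2) - log(d0 / 2)) else exp(mean(e))
  }
  var_post <- if (is.finite(d0)) (d0 * s0 + dg * s2) / (d0 + dg) else
    rep(s0, length(s2))
  var_post[!is.finite(var_post)] <- s0
  list(var_post = var_post, df_prior = d0, var_prior = s0)
}

#' Classify genes by TE change
#'
#' A gene is `TE_down` when its log2 FC TE exceeds `down_threshold` with
#' adjusted p below `alpha` (translation reduced by treatment), `TE_up`
#' when below `up_threshold` with adjusted p below `alpha`, otherwise
#' `unchanged`. The default asymmetric thresholds (> 1 down, < -0.7 up at
#' p-adj < 0.05) are the published selection rule.
#'
#' @param log2_fc_te Log2 FC TE per gene.
#' @param p_adj BH-adjusted p per gene.
#' @param down_threshold,up_threshold FC thresholds (down > 0 > up).
#' @param alpha Significance level on adjusted p.
#' @return Character vector in `{"TE_down", "TE_up", "unchanged"}`.
#' @export
classify_te <- function(log2_fc_te, p_adj, down_threshold = 1.0,
                        up_threshold = -0.7, alpha = 0.05) {
  if (!(down_threshold > 0 && up_threshold < 0))
    stop("need down_threshold > 0 > up_threshold", call. = FALSE)
  cls <- rep("unchanged", length(log2_fc_te))
  sig <- !is.na(p_adj) & p_adj < alpha
  cls[sig & log2_fc_te > down_threshold] <- "TE_down"
  cls[sig & log2_fc_te < up_threshold] <- "TE_up"
  cls
}

#' Full TE pipeline: normalize, quantify, test, classify
#'
#' Runs the complete polysome-profiling analysis: median-of-ratios size
#' factors on spike-in rows (or all genes), per-replicate and per-condition
#' TE, log2 FC TE between control and treated, Welch/BH testing, and
#' threshold classification. Genes with fewer than `min_total` raw counts
#' summed across samples are filtered before testing.
#'
#' @param counts Raw count matrix, genes (incl. spike-in rows) x samples.
#' @param design Sample design aligned with columns.
#' @param spike_pattern Regular expression identifying spike-in row names
#'   (default `"^ERCC-"`).
#' @param norm `"spike"` (default) or `"all-genes"` size-factor reference.
#' @param conditions Length-2 character vector (control, treated); `NULL`
#'   uses the design's first two conditions in order of appearance.
#' @param pseudocount Pseudocount for TE ratios (default 0.5).
#' @param min_total Low-count filter on raw row sums (default 10).
#' @param alpha,down_threshold,up_threshold Passed to [classify_te()].
#' @param test_method,n_perm Passed to [test_te_change()].
#' @param keep_spikes Keep spike-in rows in the output table (default TRUE;
#'   they are flagged in the `is_spike` column).
#' @return A `te_table` data frame: `gene_id`, `te_<control>`,
#'   `te_<treated>`, `log2_fc_te`, `p_value`, `p_adj`, `class`, `is_spike`;
#'   size factors in `attr(, "size_factors")`.
#' @export
te_pipeline <- function(counts, design, spike_pattern = "^ERCC-",
                        norm = c("spike", "all-genes"),
                        conditions = NULL, pseudocount = 0.5,
                        min_total = 10, alpha = 0.05,
                        down_threshold = 1.0, up_threshold = -0.7,
                        test_method = "moderated", n_perm = 1000L,
                        keep_spikes = TRUE) {
  norm <- match.arg(norm)
  counts <- as.matrix(counts)
  .check_design(design, ncol(counts))
  if (is.null(conditions)) conditions <- unique(design$condition)[1:2]
  is_spike <- grepl(spike_pattern, rownames(counts))
  if (norm == "spike" && !any(is_spike))
    stop("no spike-in rows match the pattern; use norm = 'all-genes'",
         call. = FALSE)
  sf <- size_factors(counts, if (norm == "spike") which(is_spike) else NULL)
  nc <- normalize_counts(counts, sf)

  keep <- rowSums(counts) >= min_total
  if (!keep_spikes) keep <- keep & !is_spike
  nc <- nc[keep, , drop = FALSE]
  is_spike <- is_spike[keep]

  te <- compute_te(nc, design, pseudocount)
  lfc <- fc_te(te[, conditions[1L]], te[, conditions[2L]])

  # per-replicate log2 TE: pair polysomal with monosomal by replicate index
  rep_te <- list(); rep_cond <- character(0)
  for (cond in conditions) {
    reps <- sort(unique(design$replicate[design$condition == cond]))
    for (r in reps) {
      jp <- which(design$condition == cond & design$replicate == r &
                    design$fraction == "polysomal")
      jm <- which(design$condition == cond & design$replicate == r &
                    design$fraction == "monosomal")
      if (length(jp) != 1L || length(jm) != 1L) next
      rep_te[[length(rep_te) + 1L]] <-
        log2((nc[, jp] + pseudocount) / (nc[, jm] + pseudocount))
      rep_cond <- c(rep_cond, cond)
    }
  }
  log2_te <- do.call(cbind, rep_te)
  test <- test_te_change(log2_te, rep_cond, method = test_method,
                         n_perm = n_perm)
  cls <- classify_te(lfc, test$p_adj, down_threshold, up_threshold, alpha)
  out <- data.frame(gene_id = rownames(nc), stringsAsFactors = FALSE)
  out[[paste0("te_", conditions[1L])]] <- te[, conditions[1L]]
  out[[paste0("te_", conditions[2L])]] <- te[, conditions[2L]]
  out$log2_fc_te <- lfc
  out$p_value <- test$p_value
  out$p_adj <- test$p_adj
  out$class <- cls
  out$is_spike <- is_spike
  rownames(out) <- NULL
  structure(out, size_factors = sf, conditions = conditions,
            class = c("te_table", "data.frame"))
}

#' Read / write a TE table as TSV
#'
#' @param x A `te_table` (or compatible data frame).
#' @param path File path.
#' @return `write_te_table` returns `path` invisibly; `read_te_table`
#'   returns a `te_table` data frame.
#' @export
write_te_table <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_te_table
#' @export
read_te_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  structure(df, class = c("te_table", "data.frame"))
}

#' Read a TSV count matrix (genes x samples, first column gene ids)
#'
#' @param path TSV path.
#' @return Numeric matrix with gene-id row names.
#' @export
read_count_matrix <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "numeric"
  m
}
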