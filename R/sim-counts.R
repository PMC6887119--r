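#' Specification for a simulated polysome-profiling count matrix
#'
#' Describes a gene-by-sample negative-binomial count simulation matching
#' the structure of a monosomal/polysomal polysome-profiling RNA-seq
#' experiment with ERCC-style spike-ins: per-sample size factors, per-gene
#' baseline means, NB dispersion, and a planted log2 fold-change of
#' translation efficiency (FC TE) per gene. A planted `log2_fc_te` of x
#' means the treated condition's TE is 2^-x times the control TE (positive
#' values = translation reduced by treatment), encoded by scaling the
#' treated polysomal mean. Spike-in rows follow size factors only and carry
#' no condition effect.
#'
#' @param n_genes Number of biological genes (spike-ins are extra rows).
#' @param design Data frame with columns `sample_id`, `fraction`
#'   (`"monosomal"`/`"polysomal"`), `condition`, `replicate`. Every
#'   condition must have >= 2 replicates of each fraction. `NULL` builds the
#'   default 12-sample design: 2 conditions x 2 fractions x 3 replicates,
#'   mirroring a 12-library experiment.
#' @param spike_in_count Number of spike-in rows (default 50).
#' @param true_size_factors Per-sample size factors (> 0); default all 1.
#' @param baseline_means Per-gene baseline means; `NULL` draws log-normal
#'   means (meanlog `log(200)`, sdlog 1), a realistic bulk RNA-seq spread.
#' @param dispersion NB dispersion (scalar or per-gene). `0` is the
#'   deterministic limit: counts equal their means exactly (no rounding),
#'   useful for closed-form checks.
#' @param spike_dispersion NB dispersion for spike-in rows (default 0.002).
#'   Spike-ins are added to the purified RNA before library construction,
#'   so their variance is purely technical (near-Poisson with a small
#'   extra-Poisson component), far below the biological dispersion of
#'   genes.
#' @param planted_log2_fc_te Per-gene planted log2 FC TE (0 for null genes);
#'   scalar recycled.
#' @param conditions Character vector of length 2: control first, treated
#'   second (defines the sign of FC TE).
#' @param seed Integer seed.
#' @return An object of class `count_sim_spec`.
#' @export
count_sim_spec <- function(n_genes = 2000L,
                           design = NULL,
                           spike_in_count = 50L,
                           true_size_factors = NULL,
                           baseline_means = NULL,
                           dispersion = 0.05,
                           spike_dispersion = 0.002,
                           planted_log2_fc_te = 0,
                           conditions = c("control", "treated"),
                           seed = 1L) {
  .assert_scalar_num(n_genes, "n_genes", lower = 1)
  .assert_scalar_num(spike_in_count, "spike_in_count", lower = 0)
  if (is.null(design)) design <- default_polysome_design(conditions)
  stopifnot(is.data.frame(design),
            all(c("sample_id", "fraction", "condition", "replicate") %in%
                  names(design)))
  if (!all(design$fraction %in% c("monosomal", "polysomal")))
    stop("fraction must be 'monosomal' or 'polysomal'", call. = FALSE)
  tab <- table(design$condition, design$fraction)
  if (ncol(tab) < 2L || any(tab < 2L))
    stop("every condition needs >= 2 replicates of each fraction",
         call. = FALSE)
  n_samples <- nrow(design)
  if (is.null(true_size_factors)) true_size_factors <- rep(1, n_samples)
  if (length(true_size_factors) != n_samples || any(true_size_factors <= 0))
    stop("true_size_factors must be positive, one per sample", call. = FALSE)
  if (any(dispersion < 0) || any(spike_dispersion < 0))
    stop("dispersion must be >= 0", call. = FALSE)
  if (all(dispersion == 0)) spike_dispersion <- 0  # deterministic limit
  planted <- rep_len(planted_log2_fc_te, n_genes)
  structure(list(n_genes = as.integer(n_genes), design = design,
                 spike_in_count = as.integer(spike_in_count),
                 true_size_factors = true_size_factors,
                 baseline_means = baseline_means,
                 dispersion = dispersion,
                 spike_dispersion = spike_dispersion,
                 planted_log2_fc_te = planted,
                 conditions = conditions,
                 seed = as.integer(seed)),
            class = "count_sim_spec")
}

#' Default 12-sample polysome-profiling design
#'
#' Two conditions x two fractions (monosomal, polysomal) x three replicates.
#'
#' @param conditions Length-2 character vector, control first.
#' @return Design data frame with `sample_id`, `fraction`, `condition`,
#'   `replicate`.
#' @export
default_polysome_design <- function(conditions = c("control", "treated")) {
  d <- expand.grid(replicate = 1:3,
                   fraction = c("monosomal", "polysomal"),
                   condition = conditions,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  d$sample_id <- sprintf("%s_%s_rep%d", d$condition,
                         ifelse(d$fraction == "monosomal", "M", "P"),
                         d$replicate)
  d[, c("sample_id", "fraction", "condition", "replicate")]
}

#' Simulate a polysome-profiling count matrix with planted TE shifts
#'
#' Counts are NB(mean, dispersion) with mean =
#' `size_factor * baseline * te_effect`, where the TE effect multiplies the
#' polysomal mean of the treated condition by `2^-planted_log2_fc_te`.
#' Spike-in rows (`ERCC-...`) carry no condition effect. With
#' `dispersion = 0` the counts equal their means exactly.
#'
#' @param spec A [count_sim_spec()].
#' @return List with
#'   \describe{
#'     \item{counts}{numeric matrix (genes + spike-ins) x samples, row names
#'       `gene_0001...`/`ERCC-0001...`, column names `sample_id`.}
#'     \item{design}{the sample design.}
#'     \item{truth}{data frame `(gene_id, planted_log2_fc_te, is_spike,
#'       baseline_mean)`.}
#'     \item{size_factors}{the planted per-sample size factors.}
#'   }
#' @export
gen_count_matrix <- function(spec) {
  stopifnot(inherits(spec, "count_sim_spec"))
  set.seed(spec$seed)
  ng <- spec$n_genes; ns <- nrow(spec$design); nspk <- spec$spike_in_count
  base <- spec$baseline_means
  if (is.null(base))
    base <- exp(rnorm(ng, log(200), 1))
  base <- pmax(rep_len(base, ng), 1e-8)
  spike_base <- if (nspk) exp(rnorm(nspk, log(500), 0.8)) else numeric(0)
  gene_ids <- sprintf("gene_%04d", seq_len(ng))
  spike_ids <- if (nspk) sprintf("ERCC-%04d", seq_len(nspk)) else character(0)
  means_all <- rep(c(base, spike_base), times = ns)
  dim(means_all) <- c(ng + nspk, ns)

  treated <- spec$conditions[2L]
  fc <- c(spec$planted_log2_fc_te, rep(0, nspk))
  poly_treated <- which(spec$design$fraction == "polysomal" &
                          spec$design$condition == treated)
  for (j in poly_treated)
    means_all[, j] <- means_all[, j] * 2^(-fc)
  means_all <- sweep(means_all, 2L, spec$true_size_factors, `*`)

  disp <- c(rep_len(spec$dispersion, ng),
            rep_len(spec$spike_dispersion, nspk))
  counts <- means_all
  stoch <- disp > 0
  if (any(stoch)) {
    mu <- means_all[stoch, , drop = FALSE]
    counts[stoch, ] <- rnbinom(length(mu), mu = mu,
                               size = rep(1 / disp[stoch], ns))
  }
  dimnames(counts) <- list(c(gene_ids, spike_ids), spec$design$sample_id)
  truth <- data.frame(gene_id = c(gene_ids, spike_ids),
                      planted_log2_fc_te = fc,
                      is_spike = c(rep(FALSE, ng), rep(TRUE, nspk)),
                      baseline_mean = c(base, spike_base),
                      stringsAsFactors = FALSE)
  list(counts = counts, design = spec$design, truth = truth,
       size_factors = spec$true_size_factors)
}
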