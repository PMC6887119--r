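#' Mann-Whitney U test (exact for small samples)
#'
#' U is computed from midrank sums: `U = R_a - n_a(n_a+1)/2` where `R_a` is
#' the rank sum of group a in the pooled midranked data. For
#' `n_a + n_b <= 16` the two-sided p-value is exact: all
#' `choose(n_a+n_b, n_a)` group assignments of the pooled values are
#' enumerated and p is the fraction with `|U* - n_a n_b / 2|` at least the
#' observed deviation (ties handled by enumerating the actual midranks).
#' Larger samples use the normal approximation with tie correction and a
#' 0.5 continuity correction.
#'
#' @param values_a,values_b Non-empty numeric vectors.
#' @param exact_max Largest pooled size for the exact branch (default 16).
#' @return List with `U` (for group a), `p_value` (two-sided), and
#'   `method` (`"exact"` or `"normal"`).
#' @examples
#' mannwhitney_u(c(1, 2), c(3, 4))  # U = 0, exact p = 1/3
#' @export
mannwhitney_u <- function(values_a, values_b, exact_max = 16L) {
  na <- length(values_a); nb <- length(values_b)
  if (na == 0L || nb == 0L) stop("each group must be nonempty", call. = FALSE)
  pooled <- c(values_a, values_b)
  r <- rank(pooled)  # midranks
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * nb / 2
  if (na + nb <= exact_max) {
    idx <- combn(na + nb, na)
    rsums <- colSums(matrix(r[idx], nrow = na))
    Ustar <- rsums - na * (na + 1) / 2
    p <- mean(abs(Ustar - mu) >= abs(U - mu) - 1e-9)
    method <- "exact"
  } else {
    n <- na + nb
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- na * nb / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (abs(U - mu) - 0.5) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-max(z, 0)))
    }
    method <- "normal"
  }
  list(U = U, p_value = p, method = method)
}

#' Pearson chi-square test of motif-class independence
#'
#' Pearson's chi-square without continuity correction on an r x c
#' contingency table (1 df for the 2 x 2 class-by-motif-presence tables
#' used in enrichment analysis). Zero margins are an error.
#'
#' @param table 2 x 2 (or r x c) matrix of non-negative counts,
#'   e.g. rows = TE class, columns = motif presence/absence.
#' @return List with `statistic`, `df`, `p_value`, and `expected`.
#' @examples
#' motif_enrichment(matrix(c(20, 5, 5, 20), 2))  # X^2 = 18
#' @export
motif_enrichment <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0)) stop("counts must be non-negative", call. = FALSE)
  rs <- rowSums(table); cs <- colSums(table)
  if (any(rs == 0) || any(cs == 0))
    stop("zero margin in contingency table", call. = FALSE)
  n <- sum(table)
  expected <- outer(rs, cs) / n
  stat <- sum((table - expected)^2 / expected)
  df <- (nrow(table) - 1L) * (ncol(table) - 1L)
  list(statistic = stat, df = df,
       p_value = pchisq(stat, df, lower.tail = FALSE),
       expected = expected)
}

#' PCA of 5' UTR features
#'
#' Standardizes the feature columns (z-score) and decomposes by singular
#' value decomposition. Zero-variance features are dropped with a warning.
#' Loading signs follow a deterministic convention: within each component
#' the largest-magnitude loading is made positive.
#'
#' @param features Numeric data frame or matrix (UTRs x features), e.g.
#'   length, GC percent, structure score.
#' @return List with `loadings` (features x components, orthonormal),
#'   `variance_explained` (fractions summing to 1), and `scores`.
#' @export
feature_pca <- function(features) {
  x <- as.matrix(features)
  if (nrow(x) < 2L || ncol(x) < 2L)
    stop("need >= 2 rows and >= 2 features", call. = FALSE)
  v <- apply(x, 2L, var)
  if (any(v == 0)) {
    warning("dropping zero-variance feature(s): ",
            paste(colnames(x)[v == 0], collapse = ", "))
    x <- x[, v > 0, drop = FALSE]
    if (ncol(x) < 2L) stop("fewer than 2 informative features", call. = FALSE)
  }
  pc <- prcomp(x, center = TRUE, scale. = TRUE)
  flip <- apply(pc$rotation, 2L, function(l) sign(l[which.max(abs(l))]))
  rot <- sweep(pc$rotation, 2L, flip, `*`)
  scores <- sweep(pc$x, 2L, flip, `*`)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  list(loadings = rot, variance_explained = ve, scores = scores)
}

#' Feature-by-class group statistics
#'
#' For each numeric feature, compares two TE classes with the Mann-Whitney
#' U test and reports group medians.
#'
#' @param features Output of [utr_features()] including a `te_class`
#'   column (or a `group` column named by `group_col`).
#' @param classes Length-2 character vector of class labels to compare.
#' @param columns Feature columns to test; defaults to the standard set
#'   present in the table.
#' @param group_col Name of the grouping column (default `"te_class"`).
#' @return Data frame `(feature, median_a, median_b, U, p_value)`.
#' @export
group_stats <- function(features, classes = c("TE_down", "TE_up"),
                        columns = NULL, group_col = "te_class") {
  stopifnot(group_col %in% names(features))
  if (is.null(columns))
    columns <- intersect(c("length", "gc_percent", "structure_score",
                           "dG_kcal_per_mol"), names(features))
  a <- features[features[[group_col]] == classes[1L], , drop = FALSE]
  b <- features[features[[group_col]] == classes[2L], , drop = FALSE]
  do.call(rbind, lapply(columns, function(col) {
    mw <- mannwhitney_u(a[[col]], b[[col]])
    data.frame(feature = col,
               median_a = median(a[[col]]), median_b = median(b[[col]]),
               U = mw$U, p_value = mw$p_value, stringsAsFactors = FALSE)
  }))
}

#' Build the class x motif-presence contingency table
#'
#' @param features Output of [utr_features()] with a grouping column.
#' @param motif_col Logical presence column (`"has_g4"` or `"has_ggc"`).
#' @param classes Length-2 class labels (rows of the table).
#' @param group_col Grouping column name.
#' @return 2 x 2 integer matrix (rows classes; columns motif present /
#'   absent), ready for [motif_enrichment()].
#' @export
motif_table <- function(features, motif_col = "has_g4",
                        classes = c("TE_down", "TE_up"),
                        group_col = "te_class") {
  stopifnot(motif_col %in% names(features), group_col %in% names(features))
  m <- vapply(classes, function(cl) {
    sel <- features[[group_col]] == cl
    c(sum(features[[motif_col]][sel]), sum(!features[[motif_col]][sel]))
  }, integer(2))
  t(matrix(m, nrow = 2L,
           dimnames = list(c("present", "absent"), classes)))
}
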