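#' Per-sample log-ratio of two feature sets
#'
#' For each sample, the natural log of the summed abundance of the numerator
#' set over the summed abundance of the denominator set. Because the ratio of
#' two amalgamations is scale-invariant, the statistic is unaffected by
#' sequencing depth. Samples where either sum is zero carry no information
#' about the ratio and are dropped (returned as `NA`) and counted, rather
#' than patched with pseudocounts.
#'
#' @param table A [feature_table()].
#' @param numerator,denominator Disjoint, non-empty feature id sets; ids
#'   absent from the table are ignored, but each set must intersect the
#'   table's features.
#' @return An object of class `log_ratio_result` with `numerator_set`,
#'   `denominator_set`, `per_sample_log_ratio` (named, `NA` = dropped) and
#'   `n_dropped`.
#' @export
log_ratio <- function(table, numerator, denominator) {
  stopifnot(inherits(table, "feature_table"))
  if (!length(numerator) || !length(denominator)) {
    stop("numerator and denominator must be non-empty")
  }
  if (length(intersect(numerator, denominator))) {
    stop("numerator and denominator must be disjoint")
  }
  num <- intersect(numerator, rownames(table$values))
  den <- intersect(denominator, rownames(table$values))
  if (!length(num)) stop("no numerator feature found in the table")
  if (!length(den)) stop("no denominator feature found in the table")
  ns <- colSums(table$values[num, , drop = FALSE])
  ds <- colSums(table$values[den, , drop = FALSE])
  lr <- ifelse(ns > 0 & ds > 0, log(ns / ds), NA_real_)
  names(lr) <- colnames(table$values)
  structure(list(numerator_set = num, denominator_set = den,
                 per_sample_log_ratio = lr,
                 n_dropped = sum(is.na(lr)),
                 group_p_value = NA_real_, test = NA_character_),
            class = "log_ratio_result")
}

#' Log-ratio group assessment
#'
#' Computes [log_ratio()] and compares responders against nonresponders with
#' a two-sided Wilcoxon rank-sum test on the per-sample log-ratios.
#'
#' @inheritParams log_ratio
#' @param metadata [sample_metadata()] supplying `R`/`NR` labels.
#' @return A `log_ratio_result` with `group_p_value` and `test` filled in.
#' @export
log_ratio_group_test <- function(table, numerator, denominator, metadata) {
  res <- log_ratio(table, numerator, denominator)
  lr <- res$per_sample_log_ratio
  md <- metadata[match(names(lr), metadata$sample_id), , drop = FALSE]
  a <- lr[!is.na(lr) & md$response %in% "R"]
  b <- lr[!is.na(lr) & md$response %in% "NR"]
  if (!length(a) || !length(b)) {
    warning("a response group has no usable log-ratio samples")
    return(res)
  }
  res$group_p_value <- wilcoxon_rank_sum(a, b)
  res$test <- "wilcoxon_rank_sum"
  res
}

# exact null counts of the rank-sum of a size-n1 subset of ranks 1..N
.rank_sum_counts <- function(n1, N) {
  max_s <- sum((N - n1 + 1):N)
  f <- matrix(0, n1 + 1, max_s + 1)
  f[1, 1] <- 1
  for (v in seq_len(N)) {
    for (k in min(n1, v):1) {
      f[k + 1, (v + 1):(max_s + 1)] <- f[k + 1, (v + 1):(max_s + 1)] +
        f[k, 1:(max_s + 1 - v)]
    }
  }
  f[n1 + 1, ]  # index s+1 = count of subsets with rank sum s
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact enumeration of the rank-sum null distribution when both groups have
#' at most 12 observations and there are no ties (mode `"auto"`); otherwise a
#' normal approximation with tie correction and continuity correction, as in
#' the classical large-sample test.
#'
#' @param a,b Numeric vectors (both non-empty).
#' @param mode `"auto"`, `"exact"` or `"normal"`. `"exact"` with ties is an
#'   error.
#' @return Two-sided p-value.
#' @export
wilcoxon_rank_sum <- function(a, b, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  if (length(unique(c(a, b))) == 1) return(1)
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  ties <- anyDuplicated(c(a, b)) > 0
  if (mode == "auto") {
    mode <- if (n1 <= 12 && n2 <= 12 && !ties) "exact" else "normal"
  }
  if (mode == "exact") {
    if (ties) stop("exact mode requires untied data")
    r <- rank(c(a, b))
    w <- sum(r[seq_len(n1)])
    counts <- .rank_sum_counts(n1, N)
    s <- seq_along(counts) - 1
    mu <- n1 * (N + 1) / 2
    extreme <- abs(s - mu) >= abs(w - mu) - 1e-9
    sum(counts[extreme]) / choose(N, n1)
  } else {
    r <- rank(c(a, b))
    R1 <- sum(r[seq_len(n1)])
    U <- R1 - n1 * (n1 + 1) / 2
    mu <- n1 * n2 / 2
    tab <- table(r)
    tie_term <- sum(tab^3 - tab) / (N * (N - 1))
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) return(1)
    z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
    min(1, 2 * stats::pnorm(-abs(z)))
  }
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate control:
#' `q_(i) = min over j >= i of m p_(j) / j`, clipped to 1 and returned in the
#' input order.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted values in input order.
#' @export
benjamini_hochberg <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]")
  m <- length(p_values)
  if (m == 0) return(numeric(0))
  o <- order(p_values, decreasing = TRUE)
  q <- pmin(1, cummin(m / (m:1) * p_values[o]))
  q[order(o)]
}

#' Aitchison distance between two compositions
#'
#' Euclidean distance between the centered-log-ratio transforms of
#' `x + pseudocount` and `y + pseudocount`. Scale-invariant for positive
#' inputs; zeros require a positive pseudocount.
#'
#' @param x,y Non-negative vectors over the same feature set.
#' @param pseudocount Added before the log transform (default 0).
#' @return Non-negative distance.
#' @export
aitchison_distance <- function(x, y, pseudocount = 0) {
  if (length(x) != length(y)) stop("x and y must share a feature set")
  x <- x + pseudocount
  y <- y + pseudocount
  if (any(x <= 0) || any(y <= 0)) {
    stop("zero entries require a positive pseudocount")
  }
  clr <- function(v) log(v) - mean(log(v))
  sqrt(sum((clr(x) - clr(y))^2))
}

#' Bray-Curtis dissimilarity
#'
#' `1 - 2 * sum(min(x, y)) / (sum(x) + sum(y))`, in \[0, 1\].
#'
#' @param x,y Non-negative vectors of equal length, not both all-zero.
#' @return Dissimilarity.
#' @export
bray_curtis <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (sum(x) + sum(y) == 0) stop("both vectors are all-zero")
  1 - 2 * sum(pmin(x, y)) / (sum(x) + sum(y))
}

#' Pairwise distance matrix for a feature table
#'
#' @param table A [feature_table()].
#' @param method `"aitchison"` or `"bray_curtis"`.
#' @param pseudocount Passed to [aitchison_distance()] (default 1, suited to
#'   count tables with zeros).
#' @return A symmetric matrix of sample-by-sample distances.
#' @export
distance_matrix <- function(table, method = c("aitchison", "bray_curtis"),
                            pseudocount = 1) {
  method <- match.arg(method)
  v <- table$values
  n <- ncol(v)
  d <- matrix(0, n, n, dimnames = list(colnames(v), colnames(v)))
  fun <- if (method == "aitchison") {
    function(x, y) aitchison_distance(x, y, pseudocount)
  } else {
    bray_curtis
  }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- fun(v[, i], v[, j])
    }
  }
  d
}

#' Permutational multivariate analysis of variance
#'
#' One-factor PERMANOVA on a distance matrix via the Gower-centered
#' sum-of-squares decomposition:
#' `SS_total = sum(d_ij^2)/n` over pairs, `SS_within` summed per group, and
#' `pseudo-F = (SS_between/(g-1)) / (SS_within/(n-g))`. The p-value counts
#' permuted pseudo-F values at least as large as the observed one, with the
#' add-one correction, under free label permutation.
#'
#' @param dist Square symmetric matrix (zero diagonal) or `dist` object.
#' @param labels Grouping vector; at least 2 groups with at least 2 members.
#' @param n_permutations Number of label permutations (default 10000).
#' @param seed Integer seed for the permutation stream.
#' @return An object of class `permanova_result` with `r_squared`,
#'   `pseudo_F`, `p_value`, `n_permutations`, `seed`.
#' @export
permanova <- function(dist, labels, n_permutations = 10000, seed = 1) {
  D <- as.matrix(dist)
  n <- nrow(D)
  if (length(labels) != n) stop("labels must match the distance matrix")
  if (max(abs(D - t(D))) > 1e-8 || any(abs(diag(D)) > 1e-12)) {
    stop("distance matrix must be symmetric with zero diagonal")
  }
  labels <- as.character(labels)
  sizes <- table(labels)
  if (length(sizes) < 2) stop("need at least 2 groups")
  if (any(sizes < 2)) {
    stop("singleton group(s): ", paste(names(sizes)[sizes < 2], collapse = ", "))
  }
  D2 <- D^2
  g <- length(sizes)
  ss_total <- sum(D2) / (2 * n)
  ssw <- function(lab) {
    s <- 0
    for (lv in unique(lab)) {
      idx <- which(lab == lv)
      s <- s + sum(D2[idx, idx]) / (2 * length(idx))
    }
    s
  }
  f_stat <- function(lab) {
    w <- ssw(lab)
    b <- ss_total - w
    if (w <= 0) return(Inf)
    (b / (g - 1)) / (w / (n - g))
  }
  f_obs <- f_stat(labels)
  set.seed(seed)
  exceed <- 0L
  for (b in seq_len(n_permutations)) {
    if (f_stat(sample(labels)) >= f_obs - 1e-12) exceed <- exceed + 1L
  }
  structure(list(r_squared = (ss_total - ssw(labels)) / ss_total,
                 pseudo_F = f_obs,
                 p_value = (1 + exceed) / (1 + n_permutations),
                 n_permutations = n_permutations,
                 seed = seed),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("<permanova> R2 = %.3f, pseudo-F = %.3f, p = %.4g (%d permutations)\n",
              x$r_squared, x$pseudo_F, x$p_value, x$n_permutations))
  invisible(x)
}
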