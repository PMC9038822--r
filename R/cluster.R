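#' Pointwise one-sample t statistics across a group time course
#'
#' For each center, the one-sample t statistic of the participants'
#' delta-beta values against zero: `t = mean / (sd / sqrt(n))`, df = n - 1.
#' Centers with zero cross-participant variance have an undefined t; they are
#' returned as 0 (never suprathreshold) with a warning.
#'
#' @param mat Participants x centers matrix of delta-beta values.
#' @return Numeric vector of t values, one per center.
#' @export
t_series <- function(mat) {
  stopifnot(is.matrix(mat), nrow(mat) >= 2)
  n <- nrow(mat)
  m <- colMeans(mat)
  s <- sqrt(colSums(sweep(mat, 2, m)^2) / (n - 1))
  t <- unname(ifelse(s > 0, m / (s / sqrt(n)), 0))
  if (any(s == 0 & m != 0)) {
    warning("centers with zero variance and nonzero mean: t undefined, treated as subthreshold")
  }
  t
}

#' Cluster-forming t threshold
#'
#' Two-tailed Student-t critical value at `df = n_participants - 1`; with the
#' study's 49 participants and alpha 0.05 this is the |t(48)| > 2.01 rule.
#'
#' @param n_participants Number of participants contributing to each t.
#' @param alpha Two-tailed significance level.
#' @return The critical t value.
#' @export
#' @examples
#' round(critical_t(49), 2) # 2.01
critical_t <- function(n_participants, alpha = 0.05) {
  stopifnot(n_participants >= 3)
  stats::qt(1 - alpha / 2, df = n_participants - 1)
}

#' Identify suprathreshold clusters in a t series
#'
#' Maximal runs of consecutive centers with `t > threshold` form positive
#' clusters and runs with `t < -threshold` negative clusters; a sign change
#' breaks adjacency. Each cluster's mass is the sum of its t values.
#'
#' @param t_values Numeric t series.
#' @param threshold Positive cluster-forming threshold.
#' @return A tibble with `start`, `end` (indices into the series, inclusive),
#'   `sign` (`"positive"`/`"negative"`), `mass`. Empty if nothing is
#'   suprathreshold.
#' @export
find_clusters <- function(t_values, threshold) {
  stopifnot(threshold > 0)
  state <- ifelse(t_values > threshold, 1L, ifelse(t_values < -threshold, -1L, 0L))
  r <- rle(state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != 0L
  tibble::tibble(
    start = starts[keep],
    end = ends[keep],
    sign = ifelse(r$values[keep] > 0, "positive", "negative"),
    mass = vapply(which(keep), function(i) sum(t_values[starts[i]:ends[i]]),
                  numeric(1))
  )
}

# Largest absolute cluster mass in a t series (0 if no cluster); the
# max-statistic pooled over both signs that builds the permutation null.
max_cluster_mass <- function(t_values, threshold) {
  cl <- find_clusters(t_values, threshold)
  if (nrow(cl) == 0) 0 else max(abs(cl$mass))
}

# Sign matrices for the permutation null: all 2^n patterns (exhaustive) or
# n_perm random rows.
sign_matrix <- function(n, n_perm, exhaustive) {
  if (exhaustive) {
    patterns <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
    dimnames(patterns) <- NULL
    patterns
  } else {
    matrix(sample(c(1, -1), n * n_perm, replace = TRUE), nrow = n_perm)
  }
}

# t series under every sign pattern at once. Sign flips leave each column's
# sum of squares unchanged, so only the flipped means need recomputing:
# rows of S %*% mat / n give the permuted means.
flipped_t <- function(signs, mat) {
  n <- ncol(signs)
  ss <- colSums(mat^2)
  mns <- signs %*% mat / n
  vars <- sweep(-n * mns^2, 2, ss, "+") / (n - 1)
  tt <- mns / (sqrt(pmax(vars, 0)) / sqrt(n))
  tt[!is.finite(tt)] <- 0
  tt
}

#' Cluster-based permutation test of delta-beta time courses against zero
#'
#' One-sample cluster-mass permutation test with a participant sign-flip
#' null: each permutation negates each participant's entire series
#' independently, the permuted t series is clustered at the same threshold,
#' and the maximum absolute cluster mass is recorded. Each observed cluster's
#' p value is the fraction of the null distribution at or above its absolute
#' mass, using the (B+1)/(N+1) convention for Monte-Carlo sampling. With 12
#' or fewer participants all 2^n sign patterns are enumerated exactly instead
#' of sampled (noted via a message).
#'
#' @param group A [group_timecourse()] list, or a participants x centers
#'   matrix.
#' @param n_perm Number of random permutations (study default 10,000).
#' @param alpha Cluster significance level.
#' @param seed Integer seed for the random sign flips.
#' @param threshold Cluster-forming threshold; default [critical_t()] at the
#'   actual sample size.
#' @param method `"auto"` (exhaustive when n <= 12), `"exhaustive"`, or
#'   `"montecarlo"`.
#' @return A tibble of clusters: `start`, `end`, `start_center`, `end_center`
#'   (trial indices when available), `sign`, `mass`, `p_value`, `significant`.
#'   Attributes: `t_values`, `threshold`, `method`, `n_perm`.
#' @export
permutation_test <- function(group, n_perm = 10000, alpha = 0.05, seed = 1L,
                             threshold = NULL,
                             method = c("auto", "exhaustive", "montecarlo")) {
  method <- match.arg(method)
  mat <- if (is.list(group)) group$mat else group
  centers <- if (is.list(group)) group$centers else seq_len(ncol(mat))
  stopifnot(is.matrix(mat), nrow(mat) >= 2, n_perm >= 1)
  n <- nrow(mat)
  if (is.null(threshold)) threshold <- critical_t(n, alpha)

  obs_t <- t_series(mat)
  clusters <- find_clusters(obs_t, threshold)
  empty <- tibble::tibble(
    start = integer(), end = integer(), start_center = numeric(),
    end_center = numeric(), sign = character(), mass = numeric(),
    p_value = numeric(), significant = logical()
  )
  if (nrow(clusters) == 0) {
    res <- empty
  } else {
    exhaustive <- method == "exhaustive" || (method == "auto" && n <= 12)
    if (exhaustive && method == "auto") {
      message(sprintf("n = %d participants <= 12: using exhaustive 2^%d sign-flip enumeration", n, n))
    }
    null_max <- withr::with_seed(as.integer(seed), {
      signs <- sign_matrix(n, n_perm, exhaustive)
      tt <- flipped_t(signs, mat)
      apply(tt, 1, max_cluster_mass, threshold = threshold)
    })
    p <- vapply(abs(clusters$mass), function(m) {
      # small tolerance so the identity permutation always counts as >= its
      # own observed mass despite floating-point roundoff
      tol <- 1e-8 * max(1, m)
      if (exhaustive) mean(null_max >= m - tol) else
        (1 + sum(null_max >= m - tol)) / (n_perm + 1)
    }, numeric(1))
    res <- tibble::tibble(
      start = clusters$start, end = clusters$end,
      start_center = centers[clusters$start],
      end_center = centers[clusters$end],
      sign = clusters$sign, mass = clusters$mass,
      p_value = p, significant = p < alpha
    )
    attr(res, "method") <- if (exhaustive) "exhaustive" else "montecarlo"
    attr(res, "n_perm") <- if (exhaustive) 2^n else n_perm
  }
  attr(res, "t_values") <- obs_t
  attr(res, "threshold") <- threshold
  res
}

#' Permutation test for an increasing trend in delta-beta time courses
#'
#' Tests whether the delta-beta series increase over time at the group level,
#' using the same participant sign-flip null as [permutation_test()]. The
#' statistic is the mean across participants of each participant's Pearson
#' correlation between their series and center order; negating a
#' participant's series negates their correlation, so the sign-flip null
#' applies exactly. The p value is one-sided (increasing trend).
#'
#' @inheritParams permutation_test
#' @return A list with `statistic` (mean per-participant trend correlation),
#'   `per_participant` (the individual correlations) and `p_value`.
#' @export
permutation_trend_test <- function(group, n_perm = 2000, seed = 1L) {
  mat <- if (is.list(group)) group$mat else group
  stopifnot(is.matrix(mat), nrow(mat) >= 2, ncol(mat) >= 3)
  n <- nrow(mat)
  idx <- seq_len(ncol(mat))
  cors <- apply(mat, 1, stats::cor, y = idx)
  cors[is.na(cors)] <- 0 # flat series carry no trend information
  obs <- mean(cors)
  null <- withr::with_seed(as.integer(seed), {
    signs <- sign_matrix(n, n_perm, exhaustive = FALSE)
    as.vector(signs %*% cors / n)
  })
  list(statistic = obs, per_participant = cors,
       p_value = (1 + sum(null >= obs)) / (n_perm + 1))
}
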