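#' Tukey-Kramer HSD pairwise comparisons
#'
#' All pairwise comparisons of group means via the studentized-range (HSD)
#' procedure with the Kramer correction for unequal group sizes, at a family
#' alpha of 0.05 — the comparison used throughout the original analyses of
#' these assays. Backed by [stats::aov()] + [stats::TukeyHSD()].
#'
#' @param values Numeric observations.
#' @param groups Group labels, same length.
#' @param alpha Family-wise significance threshold.
#' @return list of class `comparison_result`: `groups`, `estimates` (group
#'   means), and `pairwise` data.frame (`pair`, `difference`, `p_adjusted`,
#'   `significant`).
#' @export
hsd_pairwise <- function(values, groups, alpha = 0.05) {
  groups <- as.character(groups)
  stopifnot(length(values) == length(groups))
  tab <- table(groups)
  if (length(tab) < 2) stop_zfsocial("insufficient_data", "need >= 2 groups")
  if (any(tab < 2)) {
    stop_zfsocial("insufficient_data", "group with < 2 observations: ",
                  paste(names(tab)[tab < 2], collapse = ", "))
  }
  df <- data.frame(value = values, group = factor(groups))
  tk <- stats::TukeyHSD(stats::aov(value ~ group, data = df))$group
  pairwise <- data.frame(pair = rownames(tk), difference = tk[, "diff"],
                         p_adjusted = tk[, "p adj"],
                         significant = tk[, "p adj"] < alpha,
                         row.names = NULL)
  structure(list(groups = levels(df$group),
                 estimates = tapply(values, groups, mean),
                 pairwise = pairwise, alpha = alpha),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat("Tukey-Kramer HSD pairwise comparisons (alpha =", x$alpha, ")\n")
  cat("Group means:\n")
  print(round(x$estimates, 4))
  print(x$pairwise, digits = 4)
  invisible(x)
}

#' Two-sided permutation test for a difference in means
#'
#' Distribution-free alternative to the parametric contrasts: the group
#' labels are permuted `n_perm` times and the two-sided p-value computed
#' with the add-one correction, `p = (1 + #{|T*| >= |T|}) / (n_perm + 1)`.
#'
#' @param x,y Numeric observations for the two groups.
#' @param n_perm Number of permutations (>= 999).
#' @param seed Integer seed; same seed, same p-value.
#' @return list: `p_value`, `observed` (mean difference), `n_perm`.
#' @export
permutation_test <- function(x, y, n_perm = 1999, seed = 1) {
  stopifnot(n_perm >= 999, length(x) >= 1, length(y) >= 1)
  obs <- mean(x) - mean(y)
  pool <- c(x, y)
  nx <- length(x)
  n <- length(pool)
  exceed <- withr::with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(n, nx)
      tstar <- mean(pool[idx]) - mean(pool[-idx])
      abs(tstar) >= abs(obs)
    }, logical(1)))
  })
  list(p_value = (1 + exceed) / (n_perm + 1), observed = obs, n_perm = n_perm)
}

#' Paired (sign-flip) permutation test
#'
#' For paired designs (e.g. the same animal's presocial vs social phase):
#' the signs of the paired differences are flipped at random, testing the
#' null that the differences are symmetric about zero. Two-sided, add-one
#' corrected.
#'
#' @param x,y Paired observations (same length), or `y = NULL` to test
#'   differences `x` against zero.
#' @param n_perm Number of sign flips (>= 999).
#' @param seed Integer seed.
#' @return list: `p_value`, `observed` (mean difference), `n_perm`.
#' @export
paired_permutation_test <- function(x, y = NULL, n_perm = 1999, seed = 1) {
  d <- if (is.null(y)) x else {
    stopifnot(length(x) == length(y))
    x - y
  }
  stopifnot(n_perm >= 999, length(d) >= 1)
  obs <- mean(d)
  exceed <- withr::with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i) {
      flips <- sample(c(-1, 1), length(d), replace = TRUE)
      abs(mean(flips * d)) >= abs(obs)
    }, logical(1)))
  })
  list(p_value = (1 + exceed) / (n_perm + 1), observed = obs, n_perm = n_perm)
}
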