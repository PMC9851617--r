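#' Flag outliers at three standard deviations
#'
#' Marks values lying strictly more than three sample standard deviations
#' from the mean.  Flagged values are reported, never removed: downstream
#' analyses keep all observations and the mask is for reporting only.  A
#' constant input (SD = 0) yields no outliers, and a value at exactly three
#' SDs is not flagged (strict inequality).
#'
#' @param values numeric vector of length >= 3.
#' @return logical mask of the same length.
#' @export
flag_outliers <- function(values) {
  if (length(values) < 3) stop("need at least 3 values", call. = FALSE)
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0) return(rep(FALSE, length(values)))
  abs(values - mean(values)) > 3 * s
}

#' Permutation test for a group-by-hemisphere interaction
#'
#' Nonparametric surrogate for a two-group mixed ANOVA interaction: the
#' observed statistic is the between-group difference of the mean
#' within-subject (deprived minus intact) difference, and the null
#' distribution is built by permuting group labels across subjects.  The
#' two-sided p-value is `(1 + #{ |null| >= |observed| }) / (1 + n_perm)`.
#'
#' @param deprived,intact numeric vectors of per-subject hemisphere values
#'   (paired, same order).
#' @param groups group label per subject (exactly two distinct labels).
#' @param n_perm number of label permutations (default 1000; < 100 warns).
#' @param seed integer seed.
#' @param exact enumerate all group-label assignments instead of sampling
#'   (feasible for small groups only).
#' @return object of class `perm_result`: list with `statistic_name`,
#'   `observed`, `null_distribution_size`, `p_value`, `seed`.
#' @export
perm_interaction_test <- function(deprived, intact, groups,
                                  n_perm = 1000, seed = 1, exact = FALSE) {
  stopifnot(length(deprived) == length(intact),
            length(groups) == length(deprived))
  gl <- unique(groups)
  if (length(gl) != 2)
    stop("need exactly two groups", call. = FALSE)
  if (min(table(groups)) < 2)
    stop("each group needs at least two subjects", call. = FALSE)
  if (!exact && n_perm < 100)
    warning("n_perm < 100 gives a very coarse p-value")
  d <- deprived - intact
  stat <- function(g1_idx) {
    mean(d[g1_idx]) - mean(d[-g1_idx])
  }
  i1 <- which(groups == gl[1])
  observed <- stat(i1)
  n <- length(d)
  n1 <- length(i1)
  if (exact) {
    combs <- utils::combn(n, n1)
    null <- apply(combs, 2, stat)
    # exact enumeration: p is the tail proportion over all assignments
    p <- mean(abs(null) >= abs(observed) - 1e-12)
    n_used <- ncol(combs)
  } else {
    old <- .Random.seed_get()
    on.exit(.Random.seed_set(old))
    set.seed(seed)
    null <- vapply(seq_len(n_perm),
                   function(k) stat(sample.int(n, n1)), numeric(1))
    p <- (1 + sum(abs(null) >= abs(observed) - 1e-12)) / (1 + n_perm)
    n_used <- n_perm
  }
  structure(
    list(statistic_name = "group_by_hemisphere_interaction",
         observed = observed, null_distribution_size = n_used,
         p_value = p, seed = seed),
    class = "perm_result"
  )
}

#' @export
print.perm_result <- function(x, ...) {
  cat(sprintf("%s: observed %.4f, p = %.4g (%d permutations)\n",
              x$statistic_name, x$observed, x$p_value,
              x$null_distribution_size))
  invisible(x)
}
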