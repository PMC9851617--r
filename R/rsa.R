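#' Estimate the ROI noise covariance from GLM residuals
#'
#' Run-wise sample covariances of the residual time series are averaged and
#' shrunk toward their diagonal,
#' `Sigma_hat = (1 - lambda) * S + lambda * diag(S)`,
#' which down-weights noisy vertices in the Mahalanobis metric while keeping
#' the estimate positive definite when time points are scarce relative to
#' vertices.  When `lambda` is not supplied it is set by the analytic
#' optimal-shrinkage rule of Schafer-Strimmer (variance of the off-diagonal
#' sample covariances over their squared magnitude), clamped to `[0, 1]`.
#'
#' @param residuals_list list of time x vertex residual matrices, one per
#'   run (columns = ROI vertices, identical across runs).
#' @param lambda optional shrinkage weight in `[0, 1]`.
#' @return object of class `noise_cov`: list with `matrix` (vertex x
#'   vertex), `shrinkage_lambda`, `source_dof`.
#' @export
estimate_noise_cov <- function(residuals_list, lambda = NULL) {
  if (length(residuals_list) < 1)
    stop("need residuals from at least one run", call. = FALSE)
  P <- ncol(residuals_list[[1]])
  S <- matrix(0, P, P)
  lam_num <- 0; lam_den <- 0
  dof <- 0
  for (R in residuals_list) {
    if (ncol(R) != P) stop("runs have different vertex counts", call. = FALSE)
    Tn <- nrow(R)
    if (Tn < 2) stop("need more than one time point", call. = FALSE)
    Rc <- sweep(R, 2, colMeans(R))
    Sr <- crossprod(Rc) / (Tn - 1)
    S <- S + Sr
    if (is.null(lambda)) {
      # var of each off-diagonal sample covariance (Schafer & Strimmer 2005)
      W <- array(0, c(P, P))
      for (t in seq_len(Tn)) {
        wt <- tcrossprod(Rc[t, ])
        W <- W + (wt - Sr * (Tn - 1) / Tn)^2
      }
      v <- W * Tn / ((Tn - 1)^3)
      off <- upper.tri(Sr)
      lam_num <- lam_num + sum(v[off])
      lam_den <- lam_den + sum(Sr[off]^2)
    }
    dof <- dof + (Tn - 1)
  }
  S <- S / length(residuals_list)
  dvar <- diag(S)
  if (any(dvar <= 0)) {
    warning("zero-variance vertex in residuals; flooring its variance")
    floor_v <- max(dvar[dvar > 0], .Machine$double.eps) * 1e-6
    dvar[dvar <= 0] <- floor_v
    diag(S) <- dvar
  }
  if (is.null(lambda)) {
    lambda <- if (lam_den > 0) min(1, max(0, lam_num / lam_den)) else 1
  }
  Sig <- (1 - lambda) * S + lambda * diag(dvar, P)
  structure(list(matrix = Sig, shrinkage_lambda = lambda, source_dof = dof),
            class = "noise_cov")
}

#' Cross-validated Mahalanobis (crossnobis) RDM
#'
#' For every condition pair (A, B) the squared Mahalanobis distance is
#' estimated with cross-validation over runs:
#'
#'   d(A,B) = mean over ordered run pairs m != n of
#'            (b_A^m - b_B^m)' Sigma^-1 (b_A^n - b_B^n) / P
#'
#' where `P` is the ROI vertex count (normalising by P makes RDMs
#' comparable across ROI sizes).  Because the two pattern differences come
#' from independent runs, the estimator is unbiased: its expected value is
#' zero when the two true patterns are identical, and noise can make
#' individual estimates negative.
#'
#' @param betas_list list (one per run, >= 2) of condition x vertex beta
#'   matrices with identical row names.
#' @param cov a `noise_cov` whose dimension matches the vertex count, or
#'   `NULL` for the identity metric.
#' @return object of class `somato_rdm`: list with `conditions` and `d`
#'   (symmetric matrix, zero diagonal).
#' @export
crossnobis_rdm <- function(betas_list, cov = NULL) {
  if (length(betas_list) < 2)
    stop("crossnobis needs at least two runs", call. = FALSE)
  conds <- rownames(betas_list[[1]])
  P <- ncol(betas_list[[1]])
  for (B in betas_list)
    if (!identical(rownames(B), conds) || ncol(B) != P)
      stop("runs have inconsistent conditions or vertex counts",
           call. = FALSE)
  if (!is.null(cov)) {
    stopifnot(inherits(cov, "noise_cov"))
    if (nrow(cov$matrix) != P)
      stop("covariance dimension does not match vertex count", call. = FALSE)
    # whiten once: b -> b Sigma^(-1/2)
    Ci <- chol(solve(cov$matrix))
    betas_list <- lapply(betas_list, function(B) B %*% t(Ci))
  }
  K <- length(conds)
  M <- length(betas_list)
  d <- matrix(0, K, K, dimnames = list(conds, conds))
  pairs <- which(outer(seq_len(M), seq_len(M), `!=`), arr.ind = TRUE)
  for (a in seq_len(K - 1)) {
    for (b in (a + 1):K) {
      acc <- 0
      for (k in seq_len(nrow(pairs))) {
        m <- pairs[k, 1]; n <- pairs[k, 2]
        dm <- betas_list[[m]][a, ] - betas_list[[m]][b, ]
        dn <- betas_list[[n]][a, ] - betas_list[[n]][b, ]
        acc <- acc + sum(dm * dn)
      }
      d[a, b] <- d[b, a] <- acc / (nrow(pairs) * P)
    }
  }
  structure(list(conditions = conds, d = d), class = "somato_rdm")
}

#' @export
print.somato_rdm <- function(x, ...) {
  cat("crossnobis RDM over", length(x$conditions), "conditions\n")
  print(round(x$d, 4))
  invisible(x)
}

#' Mean dissimilarity over selected RDM entries
#'
#' Arithmetic mean of the selected off-diagonal entries; by default all
#' unique face-face pairs (6 pairs for the four facial conditions), the
#' summary used as "amount of facial information" in an ROI.
#'
#' @param rdm a `somato_rdm`.
#' @param pairs optional 2-column matrix (or data frame) of condition-label
#'   pairs; default all unique pairs among the four face conditions present.
#' @return scalar mean dissimilarity.
#' @export
mean_dissimilarity <- function(rdm, pairs = NULL) {
  if (is.null(pairs)) {
    fc <- intersect(FACE_CONDITIONS, rdm$conditions)
    pairs <- t(utils::combn(fc, 2))
  }
  pairs <- as.matrix(pairs)
  if (nrow(pairs) == 0) stop("empty pair subset", call. = FALSE)
  if (any(pairs[, 1] == pairs[, 2]))
    stop("pairs must be off-diagonal", call. = FALSE)
  vals <- rdm$d[cbind(match(pairs[, 1], rdm$conditions),
                      match(pairs[, 2], rdm$conditions))]
  if (any(is.na(vals))) stop("pair labels not in the RDM", call. = FALSE)
  mean(vals)
}

#' Classical multidimensional scaling of an RDM
#'
#' Double-centres the squared-distance matrix, eigendecomposes it, and keeps
#' the top-k non-negative eigenpairs (negative eigenvalues, which crossnobis
#' RDMs can produce, are clipped to zero).  Pairwise distances between the
#' returned coordinates approximate the RDM entries.
#'
#' @param rdm a `somato_rdm` (entries are treated as distances; negative
#'   entries are clipped to 0 before embedding).
#' @param k embedding dimension (`< number of conditions`).
#' @return condition x k coordinate matrix with attribute `eigenvalues`.
#' @export
classical_mds <- function(rdm, k = 2) {
  K <- length(rdm$conditions)
  if (k >= K) stop("k must be smaller than the number of conditions",
                   call. = FALSE)
  D <- pmax(rdm$d, 0)
  D2 <- D^2
  J <- diag(K) - matrix(1 / K, K, K)
  B <- -0.5 * J %*% D2 %*% J
  eg <- eigen((B + t(B)) / 2, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  coords <- eg$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(ev[seq_len(k)]), k)
  rownames(coords) <- rdm$conditions
  attr(coords, "eigenvalues") <- eg$values
  coords
}

#' End-to-end crossnobis RDM for one subject-hemisphere
#'
#' Convenience wrapper: fits nothing, it just wires run-level GLM results to
#' the noise model and crossnobis estimator within a trimmed ROI.
#'
#' @param glm_results list of `glm_result`s (one per run).
#' @param roi integer vertex-index set (use a trimmed ROI).
#' @param conditions conditions to include (default the four face parts).
#' @param lambda optional shrinkage weight passed to
#'   [estimate_noise_cov()].
#' @return a `somato_rdm`.
#' @export
roi_rdm <- function(glm_results, roi, conditions = FACE_CONDITIONS,
                    lambda = NULL) {
  resid <- lapply(glm_results, function(g) g$residuals[, roi, drop = FALSE])
  betas <- lapply(glm_results, function(g)
    g$betas[conditions, roi, drop = FALSE])
  cov <- estimate_noise_cov(resid, lambda = lambda)
  crossnobis_rdm(betas, cov)
}
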