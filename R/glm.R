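#' Canonical double-gamma haemodynamic response function
#'
#' Difference of two gamma densities (response peak near 5-6 s, undershoot
#' near 15-16 s, undershoot ratio 1/6), sampled at the TR and scaled to unit
#' peak.  This is the canonical kernel used to convolve block regressors in
#' the GLM.
#'
#' @param tr sampling interval, s (> 0).
#' @param duration kernel length, s (>= 24).
#' @return numeric vector of kernel samples at `t = 0, tr, 2*tr, ...`.
#' @export
double_gamma_hrf <- function(tr, duration = 32) {
  if (tr <= 0) stop("tr must be > 0", call. = FALSE)
  if (duration < 24) stop("duration must be >= 24 s", call. = FALSE)
  t <- seq(0, duration, by = tr)
  # shape/scale parameterisation: peak = (shape-1)*scale
  h <- stats::dgamma(t, shape = 6, scale = 1) -
    stats::dgamma(t, shape = 16, scale = 1) / 6
  h / max(h)
}

# HRF-convolved condition regressors sampled at the TR.  Convolution is done
# on a fine grid (dt = 0.05 s) so block onsets need not align with volumes.
convolved_regressors <- function(events, conditions, tr, n_volumes,
                                 derivative = FALSE) {
  dt <- 0.05
  total_t <- n_volumes * tr
  if (nrow(events) > 0 &&
      any(events$onset < 0 | events$onset + events$duration > total_t + 1e-9))
    stop("events fall outside the run duration", call. = FALSE)
  fine_t <- seq(0, total_t, by = dt)
  hrf_fine <- stats::dgamma(seq(0, 32, by = dt), shape = 6, scale = 1) -
    stats::dgamma(seq(0, 32, by = dt), shape = 16, scale = 1) / 6
  hrf_fine <- hrf_fine / max(hrf_fine)
  vol_t <- (seq_len(n_volumes) - 1) * tr
  X <- matrix(0, n_volumes, length(conditions),
              dimnames = list(NULL, conditions))
  Xd <- X
  for (j in seq_along(conditions)) {
    box <- numeric(length(fine_t))
    ev <- events[events$condition == conditions[j], , drop = FALSE]
    for (k in seq_len(nrow(ev)))
      box[fine_t >= ev$onset[k] & fine_t < ev$onset[k] + ev$duration[k]] <- 1
    conv <- stats::convolve(box, rev(hrf_fine), type = "open")[seq_along(fine_t)] * dt
    X[, j] <- stats::approx(fine_t, conv, xout = vol_t, rule = 2)$y
    if (derivative) {
      dconv <- c(0, diff(conv)) / dt
      Xd[, j] <- stats::approx(fine_t, dconv, xout = vol_t, rule = 2)$y
    }
  }
  if (derivative) attr(X, "derivatives") <- Xd
  X
}

#' Build a block-design matrix
#'
#' One HRF-convolved boxcar column per condition (in the fixed condition
#' order), followed by nuisance columns: a constant and a linear drift.
#' Temporal-derivative columns can be appended optionally (off by default;
#' at synthetic SNR they change winner maps negligibly).
#'
#' @param events data frame with columns `condition`, `onset` (s),
#'   `duration` (s).
#' @param tr repetition time, s.
#' @param n_volumes number of volumes in the run.
#' @param conditions ordered condition labels; defaults to the conditions
#'   present in `events` (in order of first appearance).
#' @param derivatives append temporal-derivative columns.
#' @return object of class `design_matrix`: list with `matrix`
#'   (time x regressor), `regressor_names`, `conditions`, `tr`.
#' @export
build_design_matrix <- function(events, tr, n_volumes, conditions = NULL,
                                derivatives = FALSE) {
  if (is.null(conditions)) conditions <- unique(events$condition)
  Xc <- convolved_regressors(events, conditions, tr, n_volumes,
                             derivative = derivatives)
  nuis <- cbind(constant = rep(1, n_volumes),
                drift = seq_len(n_volumes) - (n_volumes + 1) / 2)
  X <- cbind(Xc, nuis)
  if (derivatives) {
    Xd <- attr(Xc, "derivatives")
    colnames(Xd) <- paste0(conditions, "_deriv")
    X <- cbind(Xc, Xd, nuis)
  }
  structure(
    list(matrix = X, regressor_names = colnames(X),
         conditions = conditions, tr = tr),
    class = "design_matrix"
  )
}

#' Fit the run-level GLM
#'
#' Ordinary least squares per vertex.  Because rest is the implicit
#' baseline, each condition beta is directly the condition-versus-rest
#' contrast.  Residuals and degrees of freedom are retained for the noise
#' model of the representational analysis, and the diagonal of
#' `(X'X)^-1` for fixed-effects standard errors.
#'
#' @param run a `somato_run` (or any list with `data` vertex x time and
#'   matching `tr`).
#' @param design a `design_matrix` with rows matching the run's time points.
#' @return object of class `glm_result`: list with `betas`
#'   (condition x vertex), `residuals` (time x vertex), `dof`, `sigma2`
#'   (per-vertex residual variance), `xtx_inv_diag` (per condition),
#'   `conditions`, plus `subject_id`/`hemisphere`/`run_index` if present on
#'   the run.
#' @export
fit_glm <- function(run, design) {
  stopifnot(inherits(design, "design_matrix"))
  X <- design$matrix
  Y <- t(run$data)                       # time x vertex
  if (nrow(X) != nrow(Y))
    stop("design rows do not match run time points", call. = FALSE)
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("design matrix is rank deficient", call. = FALSE)
  beta_all <- qr.coef(qrX, Y)            # regressor x vertex
  resid <- Y - X %*% beta_all
  dof <- nrow(Y) - qrX$rank
  xtx_inv <- chol2inv(qr.R(qrX))
  cond <- design$conditions
  ci <- match(cond, colnames(X))
  structure(
    list(betas = beta_all[ci, , drop = FALSE],
         residuals = resid,
         dof = dof,
         sigma2 = colSums(resid^2) / dof,
         xtx_inv_diag = setNames(diag(xtx_inv)[ci], cond),
         conditions = cond,
         subject_id = run$subject_id, hemisphere = run$hemisphere,
         run_index = run$run_index),
    class = "glm_result"
  )
}

#' Fixed-effects averaging of run-level GLM estimates
#'
#' Averages condition betas across runs per vertex and forms a t-like
#' statistic `beta_mean / SE`, where the standard error combines the
#' run-level residual variances with the design-derived beta variance
#' (fixed-effects model).  The t-like statistic is the default winner
#' statistic for winner-takes-all mapping; the plain beta mean is also
#' available.
#'
#' @param results list of `glm_result`s for the same subject/hemisphere.
#' @param kind `"t_like"` (default) or `"beta_mean"`.
#' @return named list of `activation_map` objects, one per condition:
#'   each a list with `values` (per-vertex statistic), `condition`, `kind`.
#' @export
average_runs <- function(results, kind = c("t_like", "beta_mean")) {
  kind <- match.arg(kind)
  if (length(results) < 1) stop("need at least one run", call. = FALSE)
  conds <- results[[1]]$conditions
  for (r in results)
    if (!identical(r$conditions, conds))
      stop("runs have inconsistent condition sets", call. = FALSE)
  R <- length(results)
  beta_mean <- Reduce(`+`, lapply(results, `[[`, "betas")) / R
  if (kind == "t_like") {
    # var(mean beta) = (1/R^2) * sum_r sigma2_rv * (X'X)^-1_cc
    se2 <- 0
    for (r in results) {
      se2 <- se2 + outer(r$xtx_inv_diag, r$sigma2)
    }
    se <- sqrt(se2) / R
    se[se == 0] <- .Machine$double.eps
    stat <- beta_mean / se
  } else stat <- beta_mean
  maps <- lapply(conds, function(cn) {
    structure(list(values = stat[cn, ], condition = cn, kind = kind),
              class = "activation_map")
  })
  names(maps) <- conds
  maps
}
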