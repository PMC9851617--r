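#' @importFrom stats rnorm runif setNames
NULL

# Fixed condition order shared by every stage of the pipeline.
FACE_CONDITIONS <- c("forehead", "nose", "lips", "tongue")

# Deterministic sub-seed derivation (kept below 2^31 - 1).
derive_seed <- function(seed, ...) {
  k <- c(...)
  s <- as.double(seed) %% 2147483647
  for (x in k) s <- (s * 69069 + as.double(abs(x)) + 1) %% 2147483647
  as.integer(s)
}

#' Cohort specification for the synthetic somatotopy study
#'
#' Bundles every parameter of the simulated study: the flat-patch geometry,
#' the three groups and their sizes, the ground-truth somatotopic layout
#' (an upright face map with the forehead nearest the hand border), the
#' group-specific remapping shifts injected into the deprived hemisphere,
#' the block protocol, and the noise model.  The defaults encode the study
#' design being emulated: three groups (22 controls, 17 amputees, 21
#' one-handers), four facial conditions plus an optional thumb, 8 s blocks
#' repeated 4 times per condition (5 baseline blocks) over 3 runs at
#' TR = 1.45 s.
#'
#' Shift parameters are in mm, positive toward the hand border (i.e. the
#' blob centre moves medially in the deprived hemisphere).  The default
#' injects the remapping pattern reported for congenital one-handers
#' (forehead away from, lips and tongue toward the deprived hand area) and
#' no shifts for amputees or controls.
#'
#' @param groups named integer vector of subject counts.
#' @param include_thumb generate a thumb condition as well (excluded from all
#'   face analyses by default).
#' @param n_medial,n_lateral,spacing flat-patch grid parameters (mm).
#' @param hand_extent,face_extent,rsa_gap ROI geometry, mm.
#' @param truth_params data frame with columns `condition`, `centre` (mm,
#'   medial-lateral blob centre), `width` (mm, Gaussian SD), `amplitude`.
#' @param shift_params named list (per group) of named numeric vectors (per
#'   condition) of deprived-hemisphere CoG shifts, mm, + = toward hand.
#' @param block_s,repeats,baseline_blocks,runs,tr block protocol.
#' @param extra_volumes rest volumes appended after the last block (scanner
#'   lead-out); with the six-condition study protocol the total is 172
#'   volumes per run.
#' @param noise_sd temporal noise SD (marginal, a.u.).
#' @param noise_ar1 AR(1) coefficient of the temporal noise.
#' @param noise_fwhm spatial smoothing FWHM of the noise, mm.
#' @param jitter_sd SD of the per-subject Gaussian jitter on blob centres, mm.
#' @param seed master seed; the whole cohort is a pure function of the spec.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(groups = c(controls = 22, amputees = 17, one_handers = 21),
                        include_thumb = FALSE,
                        n_medial = 15, n_lateral = 31, spacing = 2,
                        hand_extent = 20, face_extent = 40, rsa_gap = 10,
                        truth_params = NULL,
                        shift_params = NULL,
                        block_s = 8, repeats = 4, baseline_blocks = 5,
                        runs = 3, tr = 1.45, extra_volumes = 12,
                        noise_sd = 1, noise_ar1 = 0.3, noise_fwhm = 3,
                        jitter_sd = 1,
                        seed = 1) {
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    stop("groups must be a named vector of counts", call. = FALSE)
  if (any(groups < 0)) stop("group counts must be >= 0", call. = FALSE)
  conditions <- c(FACE_CONDITIONS, if (include_thumb) "thumb")
  if (is.null(truth_params)) {
    truth_params <- data.frame(
      condition = conditions,
      # upright map: forehead closest to the hand border (at hand_extent),
      # then nose, lips, tongue at equal steps laterally; thumb inside the
      # hand band.  With the default 20/40 mm bands: 26, 34, 42, 50 mm.
      centre = c(hand_extent + c(0.15, 0.35, 0.55, 0.75) * face_extent,
                 if (include_thumb) hand_extent / 2),
      width = 4,
      amplitude = 1,
      stringsAsFactors = FALSE
    )
  }
  if (!all(conditions %in% truth_params$condition))
    stop("truth_params must cover every condition", call. = FALSE)
  zero <- setNames(numeric(length(conditions)), conditions)
  if (is.null(shift_params)) {
    shift_params <- lapply(names(groups), function(g) zero)
    names(shift_params) <- names(groups)
    if ("one_handers" %in% names(groups)) {
      shift_params$one_handers[c("forehead", "lips", "tongue")] <- c(-5, 5, 5)
    }
  } else {
    given <- shift_params
    shift_params <- lapply(names(groups), function(g) {
      out <- zero
      if (!is.null(given[[g]])) out[names(given[[g]])] <- given[[g]]
      out
    })
    names(shift_params) <- names(groups)
  }
  if (runs < 1 || repeats < 1 || block_s <= 0 || tr <= 0)
    stop("invalid protocol parameters", call. = FALSE)
  structure(
    list(groups = groups, conditions = conditions,
         include_thumb = include_thumb,
         n_medial = n_medial, n_lateral = n_lateral, spacing = spacing,
         hand_extent = hand_extent, face_extent = face_extent,
         rsa_gap = rsa_gap,
         truth_params = truth_params, shift_params = shift_params,
         block_s = block_s, repeats = repeats,
         baseline_blocks = baseline_blocks, runs = runs, tr = tr,
         extra_volumes = extra_volumes,
         noise_sd = noise_sd, noise_ar1 = noise_ar1,
         noise_fwhm = noise_fwhm,
         jitter_sd = jitter_sd, seed = seed),
    class = "cohort_spec"
  )
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("cohort_spec:",
      paste(sprintf("%s=%d", names(x$groups), x$groups), collapse = ", "),
      sprintf("| %d conditions, %d runs, TR %.2f s, %d volumes/run\n",
              length(x$conditions), x$runs, x$tr, n_run_volumes(x)))
  invisible(x)
}

# Number of volumes per run implied by the protocol.
n_run_volumes <- function(spec) {
  n_blocks <- length(spec$conditions) * spec$repeats + spec$baseline_blocks
  as.integer(ceiling(n_blocks * spec$block_s / spec$tr)) + spec$extra_volumes
}

# Mesh and ROI set implied by a cohort_spec.
cohort_geometry <- function(spec) {
  mesh <- build_flat_patch_mesh(spec$n_medial, spec$n_lateral, spec$spacing)
  rois <- define_rois(mesh, spec$hand_extent, spec$face_extent, spec$rsa_gap)
  list(mesh = mesh, rois = rois)
}

#' Ground-truth activation patterns for one subject
#'
#' Each condition's true pattern is an isotropic planar Gaussian bump on the
#' patch, centred at the spec'd medial-lateral offset.  In the deprived
#' hemisphere the centre is displaced by the group's shift parameter
#' (positive = toward the hand border, i.e. medially); both hemispheres then
#' receive independent per-condition Gaussian jitter of SD `spec$jitter_sd`
#' (set it to 0 for exact effect injection: the deprived-minus-intact CoG
#' difference then equals the configured shift exactly).
#'
#' @param spec a [cohort_spec()].
#' @param group group label, one of `names(spec$groups)`.
#' @param subject_seed integer seed for the subject's jitter.
#' @param geometry optional precomputed [cohort_geometry()] (internal).
#' @return list with elements `deprived` and `intact`, each a
#'   condition x vertex matrix of non-negative amplitudes, with the jittered
#'   blob centres attached as attribute `centres`.
#' @export
generate_subject_truth <- function(spec, group, subject_seed,
                                   geometry = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!group %in% names(spec$groups))
    stop("unknown group: ", group, call. = FALSE)
  if (is.null(geometry)) geometry <- cohort_geometry(spec)
  mesh <- geometry$mesh
  x <- mesh$vertices[, 1]
  y <- mesh$vertices[, 2]
  cy <- mean(range(y))
  shifts <- spec$shift_params[[group]]
  tp <- spec$truth_params

  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(subject_seed)

  out <- list()
  for (hemi in c("deprived", "intact")) {
    centres <- numeric(nrow(tp))
    pat <- matrix(0, nrow(tp), length(x),
                  dimnames = list(tp$condition, NULL))
    for (i in seq_len(nrow(tp))) {
      jit <- if (spec$jitter_sd > 0) rnorm(1, 0, spec$jitter_sd) else 0
      ctr <- tp$centre[i] + jit
      if (hemi == "deprived") ctr <- ctr - shifts[[tp$condition[i]]]
      centres[i] <- ctr
      pat[i, ] <- tp$amplitude[i] *
        exp(-((x - ctr)^2 + (y - cy)^2) / (2 * tp$width[i]^2))
    }
    attr(pat, "centres") <- setNames(centres, tp$condition)
    out[[hemi]] <- pat
  }
  out
}

# Save/restore .Random.seed so generators are pure functions of their seeds.
.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_set <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Simulate one block-design run
#'
#' The condition blocks (each condition repeated `spec$repeats` times,
#' plus `spec$baseline_blocks` rest blocks) are ordered uniformly at random,
#' tiled back to back in 8 s (by default) blocks.  The noiseless signal at a
#' vertex is the sum over conditions of the truth amplitude times the
#' condition boxcar convolved with the canonical double-gamma HRF, sampled at
#' the TR.  AR(1) temporal noise (marginal SD `spec$noise_sd`), spatially
#' smoothed on the mesh to `spec$noise_fwhm`, is then added per vertex.
#' Note that spatial smoothing reduces the marginal SD of the noise below
#' `noise_sd`; the SD is defined pre-smoothing.
#'
#' @param truth condition x vertex matrix (one hemisphere of
#'   [generate_subject_truth()]).
#' @param spec a [cohort_spec()].
#' @param run_index 1-based run number (`<= spec$runs`).
#' @param seed integer seed for block order and noise.
#' @param geometry optional precomputed [cohort_geometry()].
#' @return object of class `somato_run`: list with `data` (vertex x time
#'   matrix), `tr`, `events` (data frame: condition, onset, duration),
#'   `run_index`.
#' @export
generate_run_timeseries <- function(truth, spec, run_index, seed,
                                    geometry = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (run_index < 1 || run_index > spec$runs)
    stop("run_index out of range", call. = FALSE)
  if (is.null(geometry)) geometry <- cohort_geometry(spec)
  mesh <- geometry$mesh
  if (ncol(truth) != nrow(mesh$vertices))
    stop("truth is not defined on the spec's mesh", call. = FALSE)

  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)

  labels <- c(rep(spec$conditions, each = spec$repeats),
              rep("baseline", spec$baseline_blocks))
  labels <- sample(labels)
  onsets <- (seq_along(labels) - 1) * spec$block_s
  ev <- data.frame(condition = labels, onset = onsets,
                   duration = spec$block_s, stringsAsFactors = FALSE)
  events <- ev[ev$condition != "baseline", , drop = FALSE]
  rownames(events) <- NULL

  nvol <- n_run_volumes(spec)
  X <- convolved_regressors(events, spec$conditions, spec$tr, nvol)
  signal <- t(truth[spec$conditions, , drop = FALSE]) %*% t(X)  # vertex x time

  if (spec$noise_sd > 0) {
    nv <- nrow(mesh$vertices)
    innov_sd <- spec$noise_sd * sqrt(1 - spec$noise_ar1^2)
    eps <- matrix(rnorm(nv * nvol, 0, innov_sd), nv, nvol)
    if (spec$noise_ar1 != 0) {
      noise <- t(apply(eps, 1, function(e)
        as.numeric(stats::filter(e, spec$noise_ar1, method = "recursive"))))
    } else noise <- eps
    if (spec$noise_fwhm > 0)
      noise <- smooth_matrix_on_mesh(noise, mesh, spec$noise_fwhm)
    signal <- signal + noise
  }

  structure(
    list(data = signal, tr = spec$tr, events = events,
         run_index = run_index),
    class = "somato_run"
  )
}

# Column-wise smoothing of a vertex x k matrix (same kernel as
# smooth_on_mesh, vectorised through an averaging operator).
smooth_matrix_on_mesh <- function(m, mesh, fwhm) {
  if (fwhm == 0) return(m)
  h <- mesh$spacing
  sigma2 <- (fwhm / 2.3548)^2
  n_iter <- max(1L, as.integer(round(sigma2 / (4 * h^2 / 7))))
  e <- mesh_edges(mesh)
  deg <- tabulate(c(e[, 1], e[, 2]), nbins = nrow(mesh$vertices))
  for (it in seq_len(n_iter)) {
    acc <- m
    s1 <- rowsum(m[e[, 2], , drop = FALSE], group = e[, 1])
    i1 <- as.integer(rownames(s1))
    acc[i1, ] <- acc[i1, , drop = FALSE] + s1
    s2 <- rowsum(m[e[, 1], , drop = FALSE], group = e[, 2])
    i2 <- as.integer(rownames(s2))
    acc[i2, ] <- acc[i2, , drop = FALSE] + s2
    m <- acc / (deg + 1)
  }
  m
}

#' Generate a full synthetic cohort
#'
#' Emits, deterministically from `(spec, spec$seed)`: per-subject ground
#' truths, all runs (subject x hemisphere x run), a participant table, and a
#' phantom-sensation questionnaire table for the amputee-like group
#' (intensities and frequency codes drawn from configurable distributions;
#' see [cohort_spec()]).
#'
#' @param spec a [cohort_spec()].
#' @param generate_runs simulate the time series (set `FALSE` to get only
#'   geometry, truths and tables).
#' @return object of class `somato_cohort`: list with `spec`, `mesh`,
#'   `rois`, `subjects` (data frame), `truths` (per subject), `runs`
#'   (`runs[[subject_id]][[hemisphere]][[run]]`), `phantom` (data frame of
#'   questionnaire records for amputee-like subjects).
#' @export
generate_cohort <- function(spec, generate_runs = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  geom <- cohort_geometry(spec)

  prefix <- c(controls = "C", amputees = "A", one_handers = "O")
  subj <- do.call(rbind, lapply(names(spec$groups), function(g) {
    n <- spec$groups[[g]]
    if (n == 0) return(NULL)
    pre <- if (g %in% names(prefix)) prefix[[g]] else toupper(substr(g, 1, 1))
    data.frame(subject_id = sprintf("%s%02d", pre, seq_len(n)),
               group = g, stringsAsFactors = FALSE)
  }))
  if (is.null(subj) || nrow(subj) == 0)
    stop("cohort has no subjects", call. = FALSE)

  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(derive_seed(spec$seed, 1))

  # demographics loosely matched to the emulated study populations
  age_mu <- c(controls = 45.5, amputees = 53.7, one_handers = 42.7)
  age_sd <- c(controls = 9.5, amputees = 11, one_handers = 14)
  p_female <- c(controls = 10 / 22, amputees = 4 / 17, one_handers = 13 / 21)
  p_right <- c(controls = 6 / 22, amputees = 9 / 17, one_handers = 8 / 21)
  gmu <- function(tbl, g, def) if (g %in% names(tbl)) tbl[[g]] else def
  subj$age <- round(pmin(75, pmax(20, rnorm(
    nrow(subj),
    vapply(subj$group, function(g) gmu(age_mu, g, 45), numeric(1)),
    vapply(subj$group, function(g) gmu(age_sd, g, 10), numeric(1))))))
  subj$gender <- ifelse(
    runif(nrow(subj)) < vapply(subj$group, function(g) gmu(p_female, g, .5),
                               numeric(1)), "F", "M")
  subj$affected_side <- ifelse(
    runif(nrow(subj)) < vapply(subj$group, function(g) gmu(p_right, g, .5),
                               numeric(1)), "R", "L")

  # phantom questionnaire for the amputee-like group
  amp <- subj$subject_id[subj$group == "amputees"]
  phantom <- NULL
  if (length(amp)) {
    set.seed(derive_seed(spec$seed, 2))
    n <- length(amp)
    pls_int <- 5 * round(runif(n, 4, 20))
    pls_frq <- sample(0:5, n, replace = TRUE,
                      prob = c(.06, .06, .12, .12, .12, .52))
    has_plp <- runif(n) < 11 / 17
    plp_int <- ifelse(has_plp, 5 * round(runif(n, 2, 20)), 0)
    plp_frq <- ifelse(has_plp, sample(1:5, n, replace = TRUE), 0)
    phantom <- data.frame(
      participant_id = amp,
      pls_intensity = pls_int, pls_freq_code = pls_frq,
      plp_intensity = plp_int, plp_freq_code = plp_frq,
      stringsAsFactors = FALSE)
    phantom$pls_chronic <- chronic_score(phantom$pls_intensity,
                                         phantom$pls_freq_code)$value
    phantom$plp_chronic <- chronic_score(phantom$plp_intensity,
                                         phantom$plp_freq_code)$value
    phantom <- merge(phantom,
                     subj[, c("subject_id", "group", "age", "gender",
                              "affected_side")],
                     by.x = "participant_id", by.y = "subject_id",
                     sort = FALSE)
  }

  truths <- list()
  runs <- list()
  for (i in seq_len(nrow(subj))) {
    sid <- subj$subject_id[i]
    tseed <- derive_seed(spec$seed, 3, i)
    truths[[sid]] <- generate_subject_truth(spec, subj$group[i], tseed,
                                            geometry = geom)
    if (generate_runs) {
      runs[[sid]] <- list()
      for (hemi in c("deprived", "intact")) {
        runs[[sid]][[hemi]] <- lapply(seq_len(spec$runs), function(r) {
          rn <- generate_run_timeseries(
            truths[[sid]][[hemi]], spec, r,
            derive_seed(spec$seed, 4, i, match(hemi, c("deprived", "intact")), r),
            geometry = geom)
          rn$subject_id <- sid
          rn$hemisphere <- hemi
          rn
        })
      }
    }
  }

  structure(
    list(spec = spec, mesh = geom$mesh, rois = geom$rois,
         subjects = subj, truths = truths, runs = runs, phantom = phantom),
    class = "somato_cohort"
  )
}

#' @export
print.somato_cohort <- function(x, ...) {
  cat(sprintf("somato_cohort: %d subjects (%s), %s runs\n",
              nrow(x$subjects),
              paste(sprintf("%s=%d", names(x$spec$groups), x$spec$groups),
                    collapse = ", "),
              if (length(x$runs)) "with" else "without"))
  invisible(x)
}

#' Write the participant/questionnaire table as TSV
#'
#' Columns mirror the demographic table layout of the emulated study
#' (participant, age, gender, affected limb, PLS/PLP intensity, frequency
#' and chronic columns).  Deterministic given the cohort.
#'
#' @param cohort a `somato_cohort`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_participant_tsv <- function(cohort, path) {
  s <- cohort$subjects
  out <- data.frame(
    Participants = s$subject_id, Age = s$age, Gender = s$gender,
    `Affected limb` = s$affected_side, Group = s$group,
    check.names = FALSE, stringsAsFactors = FALSE)
  ph <- cohort$phantom
  for (col in c("PLS intensity", "PLS frequency", "Chronic PLS",
                "PLP intensity", "PLP frequency", "Chronic PLP"))
    out[[col]] <- NA_real_
  if (!is.null(ph)) {
    i <- match(ph$participant_id, out$Participants)
    out[i, "PLS intensity"] <- ph$pls_intensity
    out[i, "PLS frequency"] <- ph$pls_freq_code
    out[i, "Chronic PLS"] <- ph$pls_chronic
    out[i, "PLP intensity"] <- ph$plp_intensity
    out[i, "PLP frequency"] <- ph$plp_freq_code
    out[i, "Chronic PLP"] <- ph$plp_chronic
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
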