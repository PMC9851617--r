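#' Pipeline configuration
#'
#' Bundles the cohort specification with the analysis parameters of every
#' downstream stage.  The whole object is JSON-serializable; a snapshot is
#' written alongside the outputs of [run_pipeline()] so any run can be
#' reproduced from its output directory alone.
#'
#' @param spec a [cohort_spec()].
#' @param wta_threshold winner-takes-all statistic cutoff (default 0:
#'   minimally thresholded maps).
#' @param winner_stat `"t_like"` or `"beta_mean"`.
#' @param derivatives include temporal-derivative regressors in the GLM.
#' @param rsa_lambda optional fixed shrinkage weight for the noise
#'   covariance (`NULL` = analytic rule).
#' @param n_perm number of permutations for the group statistics.
#' @param distance_scale per-subject multiplicative hook for distance
#'   normalisation (e.g. brain-size correction on real data); default 1.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(spec = cohort_spec(),
                            wta_threshold = 0,
                            winner_stat = c("t_like", "beta_mean"),
                            derivatives = FALSE,
                            rsa_lambda = NULL,
                            n_perm = 1000,
                            distance_scale = 1) {
  structure(
    list(spec = spec, wta_threshold = wta_threshold,
         winner_stat = match.arg(winner_stat),
         derivatives = derivatives, rsa_lambda = rsa_lambda,
         n_perm = n_perm, distance_scale = distance_scale),
    class = "pipeline_config"
  )
}

#' Write / read a pipeline configuration as JSON
#' @param config a `pipeline_config`.
#' @param path file path.
#' @return `write_config`: the path, invisibly; `read_config`: a
#'   `pipeline_config`.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass_config(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

unclass_config <- function(config) {
  out <- unclass(config)
  out$spec <- unclass(out$spec)
  # named atomic vectors serialize as bare arrays; lists keep their names
  out$spec$groups <- as.list(out$spec$groups)
  out$spec$shift_params <- lapply(out$spec$shift_params, as.list)
  out
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  sp <- raw$spec
  spec <- cohort_spec(
    groups = unlist(sp$groups), include_thumb = isTRUE(sp$include_thumb),
    n_medial = sp$n_medial, n_lateral = sp$n_lateral, spacing = sp$spacing,
    hand_extent = sp$hand_extent, face_extent = sp$face_extent,
    rsa_gap = sp$rsa_gap,
    truth_params = as.data.frame(sp$truth_params),
    shift_params = lapply(sp$shift_params, unlist),
    block_s = sp$block_s, repeats = sp$repeats,
    baseline_blocks = sp$baseline_blocks, runs = sp$runs, tr = sp$tr,
    extra_volumes = sp$extra_volumes,
    noise_sd = sp$noise_sd, noise_ar1 = sp$noise_ar1,
    noise_fwhm = sp$noise_fwhm, jitter_sd = sp$jitter_sd, seed = sp$seed)
  pipeline_config(
    spec = spec, wta_threshold = raw$wta_threshold,
    winner_stat = raw$winner_stat, derivatives = isTRUE(raw$derivatives),
    rsa_lambda = raw$rsa_lambda,
    n_perm = raw$n_perm, distance_scale = raw$distance_scale)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes simulate -> GLM -> topography -> Jaccard -> RSA -> scores ->
#' permutation statistics, writing all tabular outputs (TSV), GIFTI files
#' (surface mesh and per-subject winner label maps), a config snapshot, and
#' a run log into `out_dir`.  Deterministic: the same `(config, seed)`
#' yields byte-identical TSVs.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if missing); `NULL` skips all
#'   file output and just returns the result tables.
#' @param seed overrides `config$spec$seed` when given.
#' @param stages character vector of stages to run, in pipeline order; any
#'   of `"simulate"`, `"glm"`, `"topography"`, `"jaccard"`, `"rsa"`,
#'   `"scores"`, `"report"`.  Later stages imply earlier ones.
#' @param verbose log progress to stderr.
#' @return (invisibly) a list of the result tables: `subjects`,
#'   `distances`, `laterality`, `jaccard`, `rdm`, `mds`,
#'   `mean_dissimilarity`, `phantom`, `permutation`.
#' @export
run_pipeline <- function(config, out_dir = NULL, seed = NULL,
                         stages = "report", verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  all_stages <- c("simulate", "glm", "topography", "jaccard", "rsa",
                  "scores", "report")
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  last <- max(match(stages, all_stages))
  spec <- config$spec
  if (!is.null(seed)) spec$seed <- seed
  log_lines <- character()
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, msg)
    if (verbose) message(msg)
  }
  fail <- function(stage, e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  }

  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  out <- function(f) file.path(out_dir, f)

  ## -- simulate ----------------------------------------------------------
  say("simulate: generating cohort (seed %d)", spec$seed)
  cohort <- tryCatch(generate_cohort(spec), error = function(e)
    fail("simulate", e))
  res <- list(subjects = cohort$subjects)
  if (!is.null(out_dir)) {
    write_config(config, out("config.json"))
    write_participant_tsv(cohort, out("participants.tsv"))
    write_gifti_surface(cohort$mesh, out("patch.surf.gii"))
  }
  if (last >= match("scores", all_stages) || "scores" %in% stages) {
    if (!is.null(cohort$phantom)) {
      ph <- cohort$phantom
      ph$plp_class <- classify_plp(ph$plp_chronic)
      res$phantom <- ph
      if (!is.null(out_dir)) write_tsv(ph, out("phantom_scores.tsv"))
    }
  }
  if (last < match("glm", all_stages)) {
    if (!is.null(out_dir)) writeLines(log_lines, out("run.log"))
    return(invisible(res))
  }

  ## -- glm ---------------------------------------------------------------
  say("glm: fitting %d subjects x 2 hemispheres x %d runs",
      nrow(cohort$subjects), spec$runs)
  mesh <- cohort$mesh; rois <- cohort$rois
  nvol <- n_run_volumes(spec)
  glms <- list(); maps <- list()
  for (sid in cohort$subjects$subject_id) {
    glms[[sid]] <- list(); maps[[sid]] <- list()
    for (hemi in c("deprived", "intact")) {
      gl <- tryCatch(lapply(cohort$runs[[sid]][[hemi]], function(rn) {
        des <- build_design_matrix(rn$events, rn$tr, nvol,
                                   conditions = spec$conditions,
                                   derivatives = config$derivatives)
        fit_glm(rn, des)
      }), error = function(e) fail("glm", e))
      glms[[sid]][[hemi]] <- gl
      maps[[sid]][[hemi]] <- average_runs(gl, kind = config$winner_stat)
    }
  }

  if (last < match("topography", all_stages)) {
    if (!is.null(out_dir)) writeLines(log_lines, out("run.log"))
    return(invisible(res))
  }

  ## -- topography --------------------------------------------------------
  say("topography: winner maps, CoG distances, laterality")
  wmaps_s1 <- list(); wmaps_hand <- list()
  dist_rows <- list(); lat_rows <- list()
  groups_by_id <- stats::setNames(cohort$subjects$group,
                                  cohort$subjects$subject_id)
  for (sid in cohort$subjects$subject_id) {
    wmaps_s1[[sid]] <- list(); wmaps_hand[[sid]] <- list()
    for (hemi in c("deprived", "intact")) {
      m <- maps[[sid]][[hemi]]
      w_s1 <- winner_takes_all(m, rois$s1_combined, config$wta_threshold)
      w_hand <- winner_takes_all(m, rois$hand, config$wta_threshold)
      wmaps_s1[[sid]][[hemi]] <- w_s1
      wmaps_hand[[sid]][[hemi]] <- w_hand
      for (cn in FACE_CONDITIONS) {
        if (length(winner_vertices(w_s1, cn)) == 0) next
        cog <- weighted_cog(w_s1, mesh, cn)
        sd_ <- signed_distance_to_anchor(cog, rois, mesh)
        dist_rows[[length(dist_rows) + 1L]] <- data.frame(
          subject = sid, group = groups_by_id[[sid]], hemisphere = hemi,
          condition = cn,
          distance_mm = sd_$value * config$distance_scale,
          stringsAsFactors = FALSE)
      }
      if (!is.null(out_dir)) {
        lab <- integer(nrow(mesh$vertices))
        lab[w_s1$roi] <- w_s1$labels
        write_gifti_label(lab, out(sprintf("wta_%s_%s.label.gii", sid, hemi)))
      }
    }
    lat <- coverage_and_laterality(wmaps_hand[[sid]]$deprived,
                                   wmaps_hand[[sid]]$intact, rois,
                                   mesh = mesh)
    lat$subject <- sid; lat$group <- groups_by_id[[sid]]
    lat_rows[[length(lat_rows) + 1L]] <- lat
  }
  res$distances <- do.call(rbind, dist_rows)
  res$laterality <- do.call(rbind, lat_rows)
  if (!is.null(out_dir)) {
    write_tsv(res$distances, out("distances.tsv"))
    write_tsv(res$laterality, out("laterality.tsv"))
  }

  ## -- jaccard -----------------------------------------------------------
  if (last >= match("jaccard", all_stages)) {
    say("jaccard: inter/intra-group map similarity")
    jac <- list()
    for (hemi in c("deprived", "intact")) {
      hm <- lapply(wmaps_s1, `[[`, hemi)
      jac[[hemi]] <- jaccard_table(hm, groups_by_id, hemisphere = hemi)
    }
    res$jaccard <- do.call(rbind, jac)
    rownames(res$jaccard) <- NULL
    if (!is.null(out_dir)) write_tsv(res$jaccard, out("jaccard.tsv"))
  }

  ## -- rsa ---------------------------------------------------------------
  if (last >= match("rsa", all_stages)) {
    say("rsa: crossnobis RDMs in trimmed ROIs")
    rdm_rows <- list(); md_rows <- list(); mds_rows <- list()
    for (sid in cohort$subjects$subject_id) {
      for (hemi in c("deprived", "intact")) {
        for (roi_label in c("hand", "face")) {
          roi <- if (roi_label == "hand") rois$hand_trimmed else
            rois$face_trimmed
          rdm <- tryCatch(
            roi_rdm(glms[[sid]][[hemi]], roi, lambda = config$rsa_lambda),
            error = function(e) fail("rsa", e))
          cc <- t(utils::combn(rdm$conditions, 2))
          rdm_rows[[length(rdm_rows) + 1L]] <- data.frame(
            subject = sid, group = groups_by_id[[sid]], hemisphere = hemi,
            roi = roi_label, cond_a = cc[, 1], cond_b = cc[, 2],
            distance = rdm$d[cc], stringsAsFactors = FALSE)
          md_rows[[length(md_rows) + 1L]] <- data.frame(
            subject = sid, group = groups_by_id[[sid]], hemisphere = hemi,
            roi = roi_label, mean_dissimilarity = mean_dissimilarity(rdm),
            stringsAsFactors = FALSE)
          if (roi_label == "hand" && hemi == "deprived") {
            xy <- classical_mds(rdm, 2)
            mds_rows[[length(mds_rows) + 1L]] <- data.frame(
              subject = sid, group = groups_by_id[[sid]],
              condition = rownames(xy), dim1 = xy[, 1], dim2 = xy[, 2],
              stringsAsFactors = FALSE)
          }
        }
      }
    }
    res$rdm <- do.call(rbind, rdm_rows)
    res$mean_dissimilarity <- do.call(rbind, md_rows)
    res$mds <- do.call(rbind, mds_rows)
    if (!is.null(out_dir)) {
      write_tsv(res$rdm, out("rdm_long.tsv"))
      write_tsv(res$mean_dissimilarity, out("rdm_mean.tsv"))
      write_tsv(res$mds, out("mds.tsv"))
    }
  }

  ## -- report: permutation statistics ------------------------------------
  if (last >= match("report", all_stages)) {
    say("report: permutation interaction tests (%d permutations)",
        config$n_perm)
    perm_rows <- list()
    ref <- "controls"
    test_groups <- setdiff(unique(cohort$subjects$group), ref)
    if (ref %in% cohort$subjects$group) {
      for (tg in test_groups) {
        for (cn in FACE_CONDITIONS) {
          dd <- res$distances
          wide <- merge(
            dd[dd$hemisphere == "deprived" & dd$condition == cn,
               c("subject", "group", "distance_mm")],
            dd[dd$hemisphere == "intact" & dd$condition == cn,
               c("subject", "distance_mm")],
            by = "subject", suffixes = c("_dep", "_int"))
          wide <- wide[wide$group %in% c(ref, tg), ]
          if (length(unique(wide$group)) < 2 || min(table(wide$group)) < 2)
            next
          pr <- perm_interaction_test(
            wide$distance_mm_dep, wide$distance_mm_int, wide$group,
            n_perm = config$n_perm,
            seed = derive_seed(spec$seed, 5, match(tg, test_groups),
                               match(cn, FACE_CONDITIONS)))
          perm_rows[[length(perm_rows) + 1L]] <- data.frame(
            comparison = paste0(tg, "_vs_", ref), condition = cn,
            measure = "signed_distance", observed = pr$observed,
            p_value = pr$p_value, n_perm = pr$null_distribution_size,
            stringsAsFactors = FALSE)
        }
      }
    }
    res$permutation <- if (length(perm_rows)) do.call(rbind, perm_rows) else
      data.frame()
    if (!is.null(out_dir)) write_tsv(res$permutation,
                                     out("permutation_tests.tsv"))
  }

  if (!is.null(out_dir)) writeLines(log_lines, out("run.log"))
  invisible(res)
}
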