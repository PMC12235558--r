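with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage %s] %s", stage, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full parcellation pipeline
#'
#' Denoises every run, extracts group and per-subject component sets with
#' both streams (hierarchical group ICA and iCAP), matches components to
#' the segmental-level atlas, tabulates per-level overlap, compares the
#' methods by matched Dice, and builds individual-level heatmaps. Stage
#' failures are re-raised with the stage name attached.
#'
#' @param config a [pipeline_config()].
#' @param runs list of [bold_run()]s on a shared grid.
#' @param cord,csf cord and CSF masks.
#' @param atlas a [level_atlas()].
#' @param confounds optional list of per-subject confound data.frames.
#' @param raw_runs optional list of unsmoothed runs for CompCor.
#' @param out_dir optional directory; when given, tables (TSV), metadata
#'   (JSON) and component maps (NIfTI) are written there.
#' @return list of class `parcellation_report`: `group` (per-method
#'   component sets, atlas matchings, overlap tables), `subject`
#'   (per-method lists of component sets, overlap summaries, heatmaps),
#'   `cross_method` (Dice matrix, matching, mean), `config`, `dvars`.
#' @export
run_pipeline <- function(config, runs, cord, csf, atlas, confounds = NULL,
                         raw_runs = NULL, out_dir = NULL) {
  stopifnot(length(runs) >= 1)
  cohort <- with_stage("denoise", prepare_cohort(runs, cord, csf, atlas,
                                                 confounds, config,
                                                 raw_runs = raw_runs))
  K <- config$K
  z <- config$z_threshold
  vz <- runs[[1]]$voxel_size[3]

  ica_group <- with_stage("ica", extract_components(cohort, "ica", K, "group"))
  icap_group <- with_stage("icap", extract_components(cohort, "icap", K, "group"))
  ica_subj <- with_stage("ica", extract_components(cohort, "ica", K, "subject"))
  icap_subj <- with_stage("icap", extract_components(cohort, "icap", K, "subject"))

  report <- with_stage("evaluate", {
    group <- list()
    for (method in c("ica", "icap")) {
      cs <- if (method == "ica") ica_group else icap_group
      mt <- match_to_atlas(cs, atlas, z)
      bm <- binarize_components(cs, z)
      overlap <- t(vapply(bm, function(b) {
        if (sum(b$data) == 0) return(rep(NA_real_, atlas$L + 1))
        level_overlap(b, atlas)
      }, numeric(atlas$L + 1)))
      colnames(overlap) <- c(sprintf("level_%d", seq_len(atlas$L)), "outside")
      group[[method]] <- list(components = cs, atlas_matching = mt,
                              overlap = overlap,
                              mean_matched_overlap =
                                as.numeric(matched_level_overlap(cs, atlas, z)))
    }
    b_ica <- binarize_components(ica_group, z)
    b_icap <- binarize_components(icap_group, z)
    D <- dice_matrix(b_ica, b_icap)
    D0 <- D; D0[is.na(D0)] <- 0
    xm <- match_components(D0)
    safe_com <- function(b) {
      if (sum(b$data) == 0) return(NA_real_)   # empty map: extraction failure
      center_of_mass_z(b, voxel_size_z = vz)
    }
    coms <- list(ica = vapply(b_ica, safe_com, numeric(1)),
                 icap = vapply(b_icap, safe_com, numeric(1)))
    com_dist <- abs(coms$ica[xm$pairs$a] - coms$icap[xm$pairs$b])

    subject <- list()
    for (method in c("ica", "icap")) {
      sets <- if (method == "ica") ica_subj else icap_subj
      per_subj <- vapply(sets, function(cs) {
        as.numeric(matched_level_overlap(cs, atlas, z))
      }, numeric(1))
      subject[[method]] <- list(components = sets,
                                level_overlap_pct = per_subj,
                                heatmap = individual_heatmap(sets, z, vz))
    }
    list(group = group,
         cross_method = list(dice = D, matching = xm,
                             mean_matched_dice = mean(xm$pairs$weight),
                             com_distance_mm = com_dist),
         subject = subject)
  })

  report$config <- config
  report$dvars <- lapply(cohort$designs, function(d) {
    if (!is.null(d)) names(d$families)
  })
  report$cohort <- cohort
  class(report) <- "parcellation_report"
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.parcellation_report <- function(x, ...) {
  cat(sprintf("<parcellation_report> K=%d, %d subjects\n", x$config$K,
              x$cohort$n_subjects))
  cat(sprintf("  cross-method mean matched Dice: %.3f\n",
              x$cross_method$mean_matched_dice))
  for (m in c("ica", "icap")) {
    cat(sprintf("  %s: mean atlas Dice %.3f, mean matched overlap %.1f%%\n",
                m, x$group[[m]]$atlas_matching$mean_matched_dice,
                x$group[[m]]$mean_matched_overlap))
  }
  invisible(x)
}

#' Write a parcellation report to disk
#'
#' TSV tables (overlap, Dice, matchings), JSON metadata (config, seed,
#' summary statistics) and NIfTI component maps / heatmaps.
#'
#' @param report a `parcellation_report`.
#' @param out_dir output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  vz <- 1
  for (method in c("ica", "icap")) {
    g <- report$group[[method]]
    write_volume(g$components$maps, file.path(out_dir, sprintf("group_%s_maps.nii.gz", method)))
    ov <- as.data.frame(g$overlap)
    ov <- cbind(component = seq_len(nrow(ov)), ov)
    write.table(format(ov, digits = 10), file.path(out_dir, sprintf("group_%s_overlap.tsv", method)),
                sep = "\t", quote = FALSE, row.names = FALSE)
    mp <- g$atlas_matching$matching$pairs
    names(mp) <- c("component", "level", "dice")
    write.table(format(mp, digits = 10), file.path(out_dir, sprintf("group_%s_atlas_matching.tsv", method)),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write_volume(report$subject[[method]]$heatmap,
                 file.path(out_dir, sprintf("subject_%s_heatmap.nii.gz", method)))
  }
  D <- as.data.frame(report$cross_method$dice)
  names(D) <- sprintf("icap_%d", seq_len(ncol(D)))
  write.table(format(cbind(ica = seq_len(nrow(D)), D), digits = 10),
              file.path(out_dir, "cross_method_dice.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(
    config = unclass(report$config),
    seed = report$config$seed,
    n_subjects = report$cohort$n_subjects,
    cross_method_mean_dice = report$cross_method$mean_matched_dice,
    atlas_mean_dice = list(
      ica = report$group$ica$atlas_matching$mean_matched_dice,
      icap = report$group$icap$atlas_matching$mean_matched_dice),
    mean_matched_overlap_pct = list(
      ica = report$group$ica$mean_matched_overlap,
      icap = report$group$icap$mean_matched_overlap),
    subject_level_overlap_pct = list(
      ica = report$subject$ica$level_overlap_pct,
      icap = report$subject$icap$level_overlap_pct))
  write_json_report(meta, file.path(out_dir, "report.json"))
  invisible(out_dir)
}
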