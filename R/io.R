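# Voxels are embedded in NIfTI volumes in ascending linear index order:
# subcortical voxels occupy linear indices 1..a, cortical voxels a+1..a+b of
# a minimal cubic grid. This ordering contract is shared by every module;
# load_recording() extracts by the same rule.

cohort_grid_dim <- function(a, b) {
  side <- ceiling((a + b)^(1 / 3))
  while (side^3 < a + b) side <- side + 1L
  rep(as.integer(side), 3L)
}

roi_label_table <- function(parcellation) {
  cells <- unique(parcellation[, c("roi", "hemisphere")])
  cells$label <- seq_len(nrow(cells))
  cells
}

#' Write a synthetic cohort to NIfTI + TSV files
#'
#' Writes one 4D NIfTI time-series per subject (subcortical voxels at linear
#' indices `1..a`, cortical at `a+1..a+b` of a minimal cubic grid), an
#' integer-label subcortical parcellation volume, a binary cortical mask, the
#' covariate table and the ground-truth manifest.
#'
#' @param cohort a `gradient_cohort`.
#' @param dir output directory (created if needed).
#' @return invisibly, the list of written paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "gradient_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  a <- cohort$config$a; b <- cohort$config$b; t_n <- cohort$config$t
  gd <- cohort_grid_dim(a, b)
  labels <- roi_label_table(cohort$parcellation)
  lab_vec <- labels$label[match(
    paste(cohort$parcellation$roi, cohort$parcellation$hemisphere),
    paste(labels$roi, labels$hemisphere))]
  sub_vol <- array(0L, gd)
  sub_vol[seq_len(a)] <- lab_vec
  cort_vol <- array(0L, gd)
  cort_vol[a + seq_len(b)] <- 1L
  paths <- list(
    subcortex = file.path(dir, "subcortex_labels.nii"),
    cortex = file.path(dir, "cortex_mask.nii"),
    covariates = file.path(dir, "covariates.tsv"),
    ground_truth = file.path(dir, "ground_truth.tsv"),
    roi_labels = file.path(dir, "roi_labels.tsv")
  )
  RNifti::writeNifti(sub_vol, paths$subcortex)
  RNifti::writeNifti(cort_vol, paths$cortex)
  write.table(cohort$covariates, paths$covariates, sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(cohort$ground_truth$axis, paths$ground_truth, sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(labels, paths$roi_labels, sep = "\t", quote = FALSE,
              row.names = FALSE)
  ts_paths <- character(length(cohort$recordings))
  for (i in seq_along(cohort$recordings)) {
    rec <- cohort$recordings[[i]]
    vol <- array(0, c(gd, t_n))
    flat <- matrix(0, prod(gd), t_n)
    flat[seq_len(a), ] <- t(rec$subcortical_ts)
    flat[a + seq_len(b), ] <- t(rec$cortical_ts)
    vol[] <- flat
    ts_paths[i] <- file.path(dir, paste0(rec$subject_id, "_bold.nii"))
    RNifti::writeNifti(vol, ts_paths[i])
  }
  paths$timeseries <- ts_paths
  invisible(paths)
}

#' Load a subject recording from NIfTI files
#'
#' Extracts the subcortical and cortical voxel time-series from a 4D image
#' using the label/mask volumes, in ascending linear voxel index order
#' within each mask.
#'
#' @param ts_path 4D NIfTI time-series.
#' @param subcortex_mask_path integer-label subcortical parcellation volume.
#' @param cortex_mask_path cortical gray-matter mask (nonzero = cortex).
#' @param covariate_row optional one-row data.frame with `subject_id`,
#'   `group`, `protocol`, `mts`, `btcs`, `duration_years`.
#' @return a `subject_recording` with an attached `parcellation` attribute
#'   (voxel_id, label) when ROI labels are present.
#' @export
load_recording <- function(ts_path, subcortex_mask_path, cortex_mask_path,
                           covariate_row = NULL) {
  ts_img <- RNifti::readNifti(ts_path)
  sub_img <- RNifti::readNifti(subcortex_mask_path)
  cort_img <- RNifti::readNifti(cortex_mask_path)
  d <- dim(ts_img)
  if (length(d) != 4L) stopf("time-series image must be 4D, got %dD",
                             length(d))
  if (!all(dim(sub_img) == d[1:3]) || !all(dim(cort_img) == d[1:3]))
    stopf("mask grid does not match time-series grid")
  x1 <- RNifti::xform(ts_img); x2 <- RNifti::xform(sub_img)
  x3 <- RNifti::xform(cort_img)
  if (max(abs(x1 - x2)) > 1e-4 || max(abs(x1 - x3)) > 1e-4)
    stopf("mask affine does not match time-series affine")
  sub_idx <- which(as.vector(sub_img) > 0)
  cort_idx <- which(as.vector(cort_img) > 0)
  if (!length(sub_idx)) stopf("empty subcortical mask")
  if (!length(cort_idx)) stopf("empty cortical mask")
  overlap <- length(intersect(sub_idx, cort_idx))
  if (overlap > 0)
    stopf("subcortical and cortical masks overlap in %d voxel(s)", overlap)
  t_n <- d[4L]
  flat <- matrix(as.vector(ts_img), prod(d[1:3]), t_n)
  sub_ts <- t(flat[sub_idx, , drop = FALSE])
  cort_ts <- t(flat[cort_idx, , drop = FALSE])
  zv <- which(apply(sub_ts, 2L, sd) == 0)
  if (length(zv))
    warning(sprintf("%d zero-variance subcortical voxel(s): %s",
                    length(zv), paste(head(zv, 10L), collapse = ", ")),
            call. = FALSE)
  rec <- structure(list(
    subject_id = covariate_row$subject_id %||%
      sub("_bold\\.nii(\\.gz)?$", "", basename(ts_path)),
    subcortical_ts = sub_ts, cortical_ts = cort_ts,
    group = covariate_row$group %||% NA_character_,
    protocol = covariate_row$protocol %||% NA_character_,
    covariates = list(mts = covariate_row$mts %||% NA,
                      btcs = covariate_row$btcs %||% NA,
                      duration_years = covariate_row$duration_years %||%
                        NA_real_)
  ), class = "subject_recording")
  attr(rec, "parcellation") <- data.frame(
    voxel_id = seq_along(sub_idx),
    label = as.vector(sub_img)[sub_idx]
  )
  rec
}

#' Write a gradient set as TSV
#'
#' One row per voxel with its parcellation labels and gradient coordinates,
#' plus a sidecar eigenvalue table.
#'
#' @param gradient_set a `gradient_set`.
#' @param parcellation parcellation table.
#' @param path output TSV path; eigenvalues go to `<path>.eigenvalues.tsv`.
#' @return invisibly, the written paths.
#' @export
write_gradients <- function(gradient_set, parcellation, path) {
  k <- ncol(gradient_set$coords)
  df <- cbind(parcellation[, c("voxel_id", "roi", "hemisphere")],
              setNames(as.data.frame(gradient_set$coords),
                       paste0("g", seq_len(k))))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  ev_path <- paste0(path, ".eigenvalues.tsv")
  write.table(data.frame(gradient = seq_len(k),
                         eigenvalue = gradient_set$eigenvalues,
                         eigenvalue_normalized =
                           gradient_set$eigenvalues_normalized),
              ev_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(path, ev_path))
}

#' Pipeline run configuration
#'
#' Validated parameter set for [run_pipeline()]. The seed must be given
#' explicitly — stochastic stages are never silently defaulted.
#'
#' @param density,kernel,method,n_components,alpha,diffusion_time gradient
#'   stage parameters (see [subject_gradients()]).
#' @param n_perm permutation count for the statistical stage.
#' @param seed integer seed; required.
#' @param gradients gradient indices carried through the statistics.
#' @return a `run_config`.
#' @export
run_config <- function(density = 0.10, kernel = "pearson",
                       method = "diffusion", n_components = 250L,
                       alpha = 0.5, diffusion_time = 0, n_perm = 2000L,
                       seed = NULL, gradients = c(1L, 2L)) {
  if (is.null(seed))
    stopf("`seed` is required: stochastic stages are not defaulted silently")
  kernel <- match.arg(kernel, AFFINITY_KERNELS)
  method <- match.arg(method, EMBED_METHODS)
  if (density <= 0 || density > 1) stopf("density must be in (0, 1]")
  structure(list(density = density, kernel = kernel, method = method,
                 n_components = as.integer(n_components), alpha = alpha,
                 diffusion_time = diffusion_time,
                 n_perm = as.integer(n_perm), seed = as.integer(seed),
                 gradients = as.integer(gradients)),
            class = "run_config")
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                              digits = NA), f)
  unname(tools::md5sum(f))
}

#' Run the full cohort pipeline
#'
#' Orchestrates gradients, template construction, Procrustes alignment,
#' protocol harmonization and the statistical battery on a cohort, writing
#' tidy result tables and a provenance sidecar (configuration hash, seed,
#' stage dimensions) to `out_dir`.
#'
#' @param cohort a `gradient_cohort` (simulated or assembled from
#'   [load_recording()] output plus parcellation/covariate tables).
#' @param config a [run_config()].
#' @param out_dir output directory; `NULL` skips writing.
#' @param verbose log each stage.
#' @return `pipeline_result`: list with the aligned `stack`, `roi_stats`
#'   table, `global_variance`, `expansion_tests`, `roi_contrasts`,
#'   `bhattacharyya`, `clinical_models`, `eigenvalue_summary` and `paths`.
#' @export
run_pipeline <- function(cohort, config, out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) tryCatch(expr, error = function(e)
    stopf("pipeline stage [%s] failed: %s", name, conditionMessage(e)))
  cov <- cohort$covariates
  parc <- cohort$parcellation

  say("stage gradients: %d subjects", length(cohort$recordings))
  gsets <- stage("gradients", cohort_gradients(
    cohort, density = config$density, kernel = config$kernel,
    method = config$method, n_components = config$n_components,
    alpha = config$alpha, diffusion_time = config$diffusion_time))
  ev_mat <- vapply(gsets, function(g) g$eigenvalues_normalized[1:5],
                   numeric(5L))
  eigenvalue_summary <- data.frame(
    gradient = 1:5,
    eigenvalue_normalized_mean = rowMeans(ev_mat),
    eigenvalue_normalized_sd = apply(ev_mat, 1L, sd)
  )

  say("stage align")
  stack <- stage("align", align_cohort(gsets, covariates = cov,
                                       k = config$n_components))
  if (length(unique(cov$protocol)) > 1L) {
    say("stage harmonize")
    stack <- stage("harmonize", harmonize_stack(stack))
  }

  say("stage statistics")
  rstats <- stage("roi_stats", roi_stats(stack, parc,
                                         gradients = config$gradients))
  gv <- global_variance(stack, gradient = 1L)
  is_pat <- cov$group != "control"
  controls <- which(!is_pat)
  expansion_tests <- NULL
  roi_contrasts <- NULL
  bhatt <- NULL
  clinical <- NULL
  if (any(is_pat) && length(controls) >= 2L) {
    ex_all <- expansion_test(gv[is_pat], gv[controls])
    expansion_tests <- data.frame(
      contrast = "TLE vs control", statistic = ex_all$statistic,
      p_value = ex_all$p_value, p_corrected = ex_all$p_corrected,
      cohens_d = ex_all$cohens_d
    )
    for (g in c("L-TLE", "R-TLE")) {
      gi <- which(cov$group == g)
      if (length(gi) >= 2L) {
        ex <- expansion_test(gv[gi], gv[controls], bonferroni = 2L)
        expansion_tests <- rbind(expansion_tests, data.frame(
          contrast = paste(g, "vs control"), statistic = ex$statistic,
          p_value = ex$p_value, p_corrected = ex$p_corrected,
          cohens_d = ex$cohens_d
        ))
      }
    }

    # ipsilateral ROI mean contrasts, patients vs side-matched controls
    rois <- unique(parc$roi)
    rows <- list()
    for (g in c("L-TLE", "R-TLE")) {
      gi <- which(cov$group == g)
      if (length(gi) < 2L) next
      side <- if (g == "L-TLE") "L" else "R"
      for (r in rois) {
        pt <- roi_contrast_test(stack, parc, r, gradient = 1L,
                                members_a = gi, members_b = controls,
                                side_a = side, side_b = side,
                                n_perm = config$n_perm, seed = config$seed)
        rows[[length(rows) + 1L]] <- data.frame(
          contrast = paste(g, "vs control"), roi = r, side = "ipsi",
          gradient = 1L, observed = pt$observed, p_perm = pt$p_value,
          p_corrected = min(1, length(rois) * pt$p_value),
          n_perm = config$n_perm, seed = config$seed
        )
      }
    }
    roi_contrasts <- do.call(rbind, rows)

    # Bhattacharyya distance on the hippocampus (g1, g2) cloud,
    # patients vs side-matched controls
    bh_rows <- list()
    for (g in c("L-TLE", "R-TLE")) {
      gi <- which(cov$group == g)
      if (length(gi) < 2L) next
      side <- if (g == "L-TLE") "L" else "R"
      idx <- which(parc$roi == "hippocampus" & parc$hemisphere == side)
      if (!length(idx)) next
      clouds <- function(members) lapply(members, function(i)
        stack$tensor[i, idx, 1:2])
      bp <- bhattacharyya_permutation(clouds(gi), clouds(controls),
                                      n_perm = config$n_perm,
                                      seed = config$seed)
      bh_rows[[length(bh_rows) + 1L]] <- data.frame(
        contrast = paste(g, "vs control"), roi = "hippocampus",
        side = side, distance = bp$observed, p_perm = bp$p_value,
        n_perm = config$n_perm, seed = config$seed
      )
    }
    bhatt <- do.call(rbind, bh_rows)

    # clinical covariate models on per-patient ipsilateral ROI means
    pat_cov <- cov[is_pat, ]
    if (nrow(pat_cov) >= 6L && length(unique(pat_cov$group)) == 2L &&
        all(is.finite(pat_cov$duration_years))) {
      lat <- group_laterality(cov)
      flipped <- flip_to_ipsi_contra(rstats, lat)
      cl_rows <- list()
      for (r in rois) {
        sel <- flipped$roi == r & flipped$side == "ipsi" &
          flipped$gradient == 1L
        sub <- flipped[sel, ]
        sub <- sub[match(pat_cov$subject_id, sub$subject_id), ]
        cm <- tryCatch(fit_clinical_model(
          sub$mean,
          data.frame(laterality = lat[pat_cov$subject_id],
                     mts = pat_cov$mts, btcs = pat_cov$btcs,
                     duration_years = pat_cov$duration_years),
          response_tag = list(roi = r, gradient = 1L, statistic = "mean")),
          error = function(e) NULL)
        if (!is.null(cm)) {
          tab <- cm$coefficients
          tab$roi <- r
          cl_rows[[length(cl_rows) + 1L]] <- tab
        }
      }
      clinical <- do.call(rbind, cl_rows)
    }
  }

  result <- structure(list(
    stack = stack, roi_stats = rstats, global_variance = gv,
    expansion_tests = expansion_tests, roi_contrasts = roi_contrasts,
    bhattacharyya = bhatt, clinical_models = clinical,
    eigenvalue_summary = eigenvalue_summary, config = config,
    paths = NULL
  ), class = "pipeline_result")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list()
    wt <- function(df, name) {
      if (is.null(df)) return(NULL)
      p <- file.path(out_dir, name)
      write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
      p
    }
    paths$roi_stats <- wt(rstats, "roi_stats.tsv")
    paths$global_variance <- wt(
      data.frame(subject_id = names(gv), group = cov$group,
                 global_variance_g1 = unname(gv)),
      "global_variance.tsv")
    paths$expansion <- wt(expansion_tests, "expansion_tests.tsv")
    paths$roi_contrasts <- wt(roi_contrasts, "roi_contrasts.tsv")
    paths$bhattacharyya <- wt(bhatt, "bhattacharyya.tsv")
    paths$clinical <- wt(clinical, "clinical_models.tsv")
    paths$eigenvalues <- wt(eigenvalue_summary, "eigenvalue_summary.tsv")
    for (g in 1:2) {
      wide <- t(stack$tensor[, , g])
      colnames(wide) <- cov$subject_id
      paths[[paste0("gradient", g)]] <- wt(
        cbind(parc, as.data.frame(wide)), sprintf("aligned_gradient%d.tsv", g))
    }
    prov <- list(config = unclass(config), config_hash = config_hash(config),
                 n_subjects = length(cohort$recordings),
                 dims = list(t = nrow(cohort$recordings[[1]]$subcortical_ts),
                             a = dim(stack$tensor)[2L],
                             k = dim(stack$tensor)[3L]),
                 harmonized = stack$harmonized,
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
    pj <- file.path(out_dir, "provenance.json")
    writeLines(jsonlite::toJSON(prov, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE), pj)
    paths$provenance <- pj
    result$paths <- paths
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  d <- dim(x$stack$tensor)
  cat(sprintf("<pipeline_result> %d subjects x %d voxels x %d gradients\n",
              d[1L], d[2L], d[3L]))
  if (!is.null(x$expansion_tests)) {
    cat("Expansion tests (gradient 1 global variance):\n")
    print(x$expansion_tests, digits = 3)
  }
  invisible(x)
}
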