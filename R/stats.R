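#' Per-ROI gradient summaries
#'
#' Sample mean and (unbiased, n-1) variance of the gradient value over the
#' member voxels of every ROI, per subject and gradient.
#'
#' @param stack a `gradient_stack`.
#' @param parcellation data.frame with `voxel_id`, `roi`, `hemisphere`
#'   matching the stack's voxel order.
#' @param gradients gradient indices to summarize (default 1 and 2).
#' @return data.frame: subject_id, group, roi, side, gradient, mean,
#'   variance. Sides are `"L"`/`"R"`; see [flip_to_ipsi_contra()].
#' @export
roi_stats <- function(stack, parcellation, gradients = c(1L, 2L)) {
  stopifnot(inherits(stack, "gradient_stack"))
  if (nrow(parcellation) != dim(stack$tensor)[2L])
    stopf("parcellation rows (%d) must match stack voxels (%d)",
          nrow(parcellation), dim(stack$tensor)[2L])
  ids <- dimnames(stack$tensor)[[1L]] %||%
    sprintf("sub-%03d", seq_len(dim(stack$tensor)[1L]))
  groups <- stack$covariates$group %||% rep(NA_character_, length(ids))
  cells <- unique(parcellation[, c("roi", "hemisphere")])
  out <- list()
  for (ci in seq_len(nrow(cells))) {
    idx <- which(parcellation$roi == cells$roi[ci] &
                 parcellation$hemisphere == cells$hemisphere[ci])
    if (!length(idx)) stopf("empty ROI %s/%s", cells$roi[ci],
                            cells$hemisphere[ci])
    for (g in gradients) {
      vals <- stack$tensor[, idx, g, drop = FALSE]
      dim(vals) <- dim(vals)[1:2]
      out[[length(out) + 1L]] <- data.frame(
        subject_id = ids, group = groups,
        roi = cells$roi[ci], side = cells$hemisphere[ci], gradient = g,
        mean = rowMeans(vals), variance = apply(vals, 1L, var),
        stringsAsFactors = FALSE, row.names = NULL
      )
    }
  }
  do.call(rbind, out)
}

#' Subject-level global gradient variance
#'
#' Variance (n-1) of one gradient over all subcortical voxels, per subject —
#' the expansion/contraction measure of the whole gradient.
#'
#' @param stack a `gradient_stack`.
#' @param gradient gradient index (default 1, the principal gradient).
#' @return named numeric vector, one value per subject.
#' @export
global_variance <- function(stack, gradient = 1L) {
  stopifnot(inherits(stack, "gradient_stack"))
  if (gradient > dim(stack$tensor)[3L])
    stopf("gradient %d not present (stack has %d)", gradient,
          dim(stack$tensor)[3L])
  v <- apply(stack$tensor[, , gradient, drop = FALSE], 1L, var)
  names(v) <- dimnames(stack$tensor)[[1L]]
  v
}

# Cohen's d with the classic pooled standard deviation
cohens_d <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp <- sqrt(((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2))
  if (sp == 0) return(0)
  (mean(x) - mean(y)) / sp
}

#' Gradient expansion test
#'
#' One-tailed Welch two-sample t-test for larger gradient variance
#' (expansion) in patients than controls, with pooled-SD Cohen's d and an
#' optional Bonferroni factor for multiple contrasts.
#'
#' @param patient_vars,control_vars per-subject global variances.
#' @param one_tailed test only the expansion direction (default `TRUE`).
#' @param bonferroni multiple-comparison family size (default 1).
#' @return `expansion_test`: list with `statistic`, `df`, `p_value`,
#'   `p_corrected`, `cohens_d`, `n`.
#' @export
expansion_test <- function(patient_vars, control_vars, one_tailed = TRUE,
                           bonferroni = 1L) {
  if (length(patient_vars) < 2L || length(control_vars) < 2L)
    stopf("need at least 2 subjects per group")
  if (var(patient_vars) == 0 && var(control_vars) == 0)
    stopf("zero pooled variance: expansion test undefined")
  tt <- t.test(patient_vars, control_vars,
               alternative = if (one_tailed) "greater" else "two.sided")
  structure(list(
    statistic = unname(tt$statistic), df = unname(tt$parameter),
    p_value = tt$p.value,
    p_corrected = min(1, bonferroni * tt$p.value),
    cohens_d = cohens_d(patient_vars, control_vars),
    n = c(patients = length(patient_vars), controls = length(control_vars)),
    one_tailed = one_tailed, bonferroni = bonferroni
  ), class = "expansion_test")
}

#' @export
print.expansion_test <- function(x, ...) {
  cat(sprintf("Gradient expansion test (%s-tailed Welch t)\n",
              if (x$one_tailed) "one" else "two"))
  cat(sprintf("  t = %.3f (df = %.1f), p = %.4g%s, Cohen's d = %.2f\n",
              x$statistic, x$df, x$p_value,
              if (x$bonferroni > 1)
                sprintf(" (Bonferroni x%d: %.4g)", x$bonferroni,
                        x$p_corrected) else "",
              x$cohens_d))
  invisible(x)
}

#' Relabel hemispheres relative to the seizure onset zone
#'
#' Maps `L`/`R` ROI sides to `ipsi`/`contra` per patient laterality (L-TLE:
#' left is ipsilateral; R-TLE: right is ipsilateral); control rows are left
#' unchanged. Applying the function to already-flipped labels maps them back,
#' so the operation is an involution.
#'
#' @param stats data.frame from [roi_stats()].
#' @param laterality named character vector (`"L"`/`"R"`) per patient
#'   subject; controls may be `NA` or absent.
#' @return the stats table with `side` relabeled.
#' @export
flip_to_ipsi_contra <- function(stats, laterality) {
  side <- stats$side
  patient <- stats$group %in% c("L-TLE", "R-TLE")
  lat <- laterality[stats$subject_id]
  if (any(patient & (is.na(lat) | !lat %in% c("L", "R"))))
    stopf("missing laterality for patient subject(s): %s",
          paste(unique(stats$subject_id[patient & is.na(lat)]),
                collapse = ", "))
  lr <- patient & side %in% c("L", "R")
  side[lr] <- ifelse(side[lr] == lat[lr], "ipsi", "contra")
  ic <- patient & stats$side %in% c("ipsi", "contra")
  side[ic] <- ifelse(stats$side[ic] == "ipsi", lat[ic],
                     ifelse(lat[ic] == "L", "R", "L"))
  stats$side <- side
  stats
}

# laterality implied by the group labels of a covariate table
group_laterality <- function(covariates) {
  lat <- ifelse(covariates$group == "L-TLE", "L",
                ifelse(covariates$group == "R-TLE", "R", NA_character_))
  setNames(lat, covariates$subject_id)
}

#' Voxel-wise group-average gradients
#'
#' @param stack a `gradient_stack`.
#' @param members subject indices or logical/character selector.
#' @return `a x k` matrix of voxel-wise means over the selected subjects.
#' @export
group_average_gradient <- function(stack, members) {
  stopifnot(inherits(stack, "gradient_stack"))
  if (is.character(members))
    members <- match(members, dimnames(stack$tensor)[[1L]])
  sub <- stack$tensor[members, , , drop = FALSE]
  if (dim(sub)[1L] == 0L) stopf("empty group")
  apply(sub, c(2L, 3L), mean)
}

# subset/size helpers for permutation machinery: rows of a matrix, elements
# of a list or vector
items_n <- function(x) if (is.matrix(x)) nrow(x) else length(x)
items_subset <- function(x, idx) {
  if (is.matrix(x)) x[idx, , drop = FALSE] else x[idx]
}
items_pool <- function(a, b) {
  if (is.matrix(a)) rbind(a, b) else c(a, b)
}

#' Group-shuffling permutation test
#'
#' Computes `stat_fn(group_a, group_b)` on the true labels and on `n_perm`
#' random reassignments of the pooled subjects to two groups of the original
#' sizes. The two-tailed p-value is the exceedance of the observed statistic
#' about the null median, `p = (#\{|null - med| >= |obs - med|\} + 1) /
#' (n_perm + 1)`; `alternative = "greater"` gives the one-sided exceedance
#' used for nonnegative distance statistics.
#'
#' @param stat_fn function of two groups; groups may be vectors, lists or
#'   matrices (rows = subjects).
#' @param group_a,group_b the two groups' data.
#' @param n_perm number of shuffles (default 2000).
#' @param seed RNG seed.
#' @param alternative `"two_tailed"` (default) or `"greater"`.
#' @return `permutation_test`: list with `observed`, `null_sample`,
#'   `p_value`, `n_perm`, `seed`, `alternative`.
#' @export
permutation_test <- function(stat_fn, group_a, group_b, n_perm = 2000L,
                             seed = 1L, alternative = c("two_tailed",
                                                        "greater")) {
  alternative <- match.arg(alternative)
  n_a <- items_n(group_a); n_b <- items_n(group_b)
  if (n_a < 2L || n_b < 2L) stopf("need at least 2 subjects per group")
  observed <- stat_fn(group_a, group_b)
  pool <- items_pool(group_a, group_b)
  n <- n_a + n_b
  null_sample <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(n)
    stat_fn(items_subset(pool, idx[seq_len(n_a)]),
            items_subset(pool, idx[-seq_len(n_a)]))
  }, numeric(1L)))
  p <- if (alternative == "two_tailed") {
    med <- median(null_sample)
    (sum(abs(null_sample - med) >= abs(observed - med)) + 1) / (n_perm + 1)
  } else {
    (sum(null_sample >= observed) + 1) / (n_perm + 1)
  }
  structure(list(observed = observed, null_sample = null_sample,
                 p_value = p, n_perm = n_perm, seed = seed,
                 alternative = alternative),
            class = "permutation_test")
}

#' @export
print.permutation_test <- function(x, ...) {
  cat(sprintf("Permutation test (%s, %d shuffles, seed %d)\n",
              gsub("_", "-", x$alternative), x$n_perm, x$seed))
  cat(sprintf("  observed = %.4g, p = %.4g\n", x$observed, x$p_value))
  invisible(x)
}

#' Average-gradient-space ROI contrast with a permutation null
#'
#' The statistic is the difference of ROI means of the voxel-wise
#' group-average gradient: group A's mean over the ROI on `side_a` minus
#' group B's mean over the ROI on `side_b` (sides may differ, implementing
#' the ipsilateral left-vs-right flip). Shuffled subjects contribute the
#' side of the group they are assigned to, so inherent left-right
#' asymmetries enter the null.
#'
#' @param stack a `gradient_stack`.
#' @param parcellation parcellation table matching the stack.
#' @param roi ROI name.
#' @param gradient gradient index.
#' @param members_a,members_b subject indices of the two groups.
#' @param side_a,side_b hemisphere compared in each group.
#' @param statistic `"mean"` or `"variance"` of the group-average gradient
#'   over the ROI voxels.
#' @param n_perm,seed permutation parameters.
#' @return a `permutation_test`.
#' @export
roi_contrast_test <- function(stack, parcellation, roi, gradient = 1L,
                              members_a, members_b, side_a = "L",
                              side_b = "R", statistic = c("mean", "variance"),
                              n_perm = 2000L, seed = 1L) {
  statistic <- match.arg(statistic)
  idx_a <- which(parcellation$roi == roi & parcellation$hemisphere == side_a)
  idx_b <- which(parcellation$roi == roi & parcellation$hemisphere == side_b)
  if (!length(idx_a) || !length(idx_b)) stopf("ROI %s not found", roi)
  agg <- if (statistic == "mean") mean else var
  # voxels x subjects matrices: what each subject contributes to A resp. B
  grab <- function(idx) {
    m <- stack$tensor[, idx, gradient, drop = FALSE]
    dim(m) <- dim(m)[1:2]
    t(m)
  }
  val_a <- grab(idx_a)
  val_b <- grab(idx_b)
  # rows: voxels; columns: subjects -> group-average then aggregate
  pair_stat <- function(a, b) {
    ga <- rowMeans(val_a[, a, drop = FALSE])
    gb <- rowMeans(val_b[, b, drop = FALSE])
    agg(ga) - agg(gb)
  }
  # represent each subject by its index; shuffle indices
  stat_fn <- function(a_idx, b_idx) pair_stat(unlist(a_idx), unlist(b_idx))
  permutation_test(stat_fn, as.list(members_a), as.list(members_b),
                   n_perm = n_perm, seed = seed)
}

#' Z-score patient ROI statistics against side-matched controls
#'
#' Each patient value is standardized against the control distribution of
#' the same (roi, side, gradient) cell — left ROIs against control left
#' ROIs, right against right — so inherent hemispheric asymmetries do not
#' masquerade as group effects.
#'
#' @param patient_stats,control_stats data.frames from [roi_stats()] with
#'   `L`/`R` side labels.
#' @param value which statistic to standardize: `"mean"` or `"variance"`.
#' @return `patient_stats` with an added column `z`.
#' @export
zscore_to_controls <- function(patient_stats, control_stats,
                               value = c("mean", "variance")) {
  value <- match.arg(value)
  key <- function(d) paste(d$roi, d$side, d$gradient, sep = "|")
  ctrl_split <- split(control_stats[[value]], key(control_stats))
  mu <- vapply(ctrl_split, mean, numeric(1L))
  s <- vapply(ctrl_split, sd, numeric(1L))
  if (any(vapply(ctrl_split, length, integer(1L)) < 2L))
    stopf("need at least 2 control subjects per (roi, side) cell")
  if (any(s == 0)) stopf("zero control SD in cell(s): %s",
                         paste(names(s)[s == 0], collapse = ", "))
  k <- key(patient_stats)
  if (any(!k %in% names(mu)))
    stopf("patient cell(s) missing from controls: %s",
          paste(unique(k[!k %in% names(mu)]), collapse = ", "))
  patient_stats$z <- (patient_stats[[value]] - mu[k]) / s[k]
  patient_stats
}

#' Fit a bivariate normal to a gradient cloud
#'
#' @param g1_values,g2_values coordinates of the ROI voxels on gradients 1
#'   and 2.
#' @return `gaussian_summary`: list with `mu` (length 2), `sigma` (2 x 2),
#'   `n`, and `singular` flag (covariance numerically rank deficient).
#' @export
fit_gaussian2d <- function(g1_values, g2_values) {
  if (length(g1_values) != length(g2_values))
    stopf("coordinate vectors differ in length")
  if (length(g1_values) < 3L) stopf("need at least 3 points")
  x <- cbind(g1 = g1_values, g2 = g2_values)
  mu <- colMeans(x)
  sigma <- cov(x)
  singular <- det(sigma) <= 1e-12 * max(diag(sigma))^2
  structure(list(mu = mu, sigma = sigma, n = nrow(x), singular = singular),
            class = "gaussian_summary")
}

#' @export
print.gaussian_summary <- function(x, ...) {
  cat(sprintf("<gaussian_summary> n = %d, mu = (%.3f, %.3f)%s\n", x$n,
              x$mu[1L], x$mu[2L],
              if (x$singular) " [singular covariance]" else ""))
  invisible(x)
}

# Stabilize a (near-)singular covariance by an epsilon ridge before
# inversion; flagged by the caller through gaussian_summary$singular.
stabilize_cov <- function(sigma) {
  if (det(sigma) <= 1e-12 * max(diag(sigma))^2) {
    eps <- 1e-10 * sum(diag(sigma)) / 2
    sigma <- sigma + diag(max(eps, 1e-300), nrow(sigma))
  }
  sigma
}

#' Bhattacharyya distance between two multivariate normals
#'
#' Closed form: `D = (1/8) (mu1 - mu2)' S^-1 (mu1 - mu2) +
#' (1/2) log(det S / sqrt(det S1 det S2))` with `S = (S1 + S2)/2`.
#' Symmetric, nonnegative, zero iff the distributions coincide.
#'
#' @param p,q `gaussian_summary` objects (or lists with `mu`, `sigma`).
#' @return nonnegative scalar.
#' @export
bhattacharyya_distance <- function(p, q) {
  s1 <- stabilize_cov(p$sigma); s2 <- stabilize_cov(q$sigma)
  ev <- eigen(s1, symmetric = TRUE, only.values = TRUE)$values
  ev2 <- eigen(s2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 0 || min(ev2) < 0)
    stopf("covariance not positive semi-definite")
  sbar <- (s1 + s2) / 2
  dmu <- p$mu - q$mu
  term1 <- as.numeric(dmu %*% solve(sbar, dmu)) / 8
  term2 <- 0.5 * log(det(sbar) / sqrt(det(s1) * det(s2)))
  term1 + term2
}

#' Permutation test on the Bhattacharyya distance of group-average clouds
#'
#' The statistic is the Bhattacharyya distance between the two groups'
#' voxel-wise average (gradient 1, gradient 2) ROI clouds, each summarized
#' as a bivariate normal. The null shuffles subjects between groups; a
#' subject reassigned to the other group contributes the cloud given by the
#' `*_alt` arguments (defaults: its own cloud), which implements the
#' flipped-hemisphere convention when sides differ between groups.
#' One-sided exceedance, since the distance is nonnegative.
#'
#' @param group_a,group_b lists of per-subject `v x 2` coordinate matrices
#'   (identical `v` within a group).
#' @param n_perm,seed permutation parameters.
#' @param group_a_alt,group_b_alt clouds contributed by each subject when
#'   assigned to the other group (defaults to its own cloud).
#' @return a `permutation_test`.
#' @export
bhattacharyya_permutation <- function(group_a, group_b, n_perm = 2000L,
                                      seed = 1L, group_a_alt = NULL,
                                      group_b_alt = NULL) {
  group_a_alt <- group_a_alt %||% group_a
  group_b_alt <- group_b_alt %||% group_b
  n_a <- length(group_a)
  # element i of the pooled list: list(as_a = cloud, as_b = cloud)
  pool_items <- c(
    mapply(function(a, alt) list(as_a = a, as_b = alt),
           group_a, group_a_alt, SIMPLIFY = FALSE),
    mapply(function(b, alt) list(as_a = alt, as_b = b),
           group_b, group_b_alt, SIMPLIFY = FALSE)
  )
  cloud_dist <- function(a_items, b_items) {
    ca <- Reduce(`+`, lapply(a_items, `[[`, "as_a")) / length(a_items)
    cb <- Reduce(`+`, lapply(b_items, `[[`, "as_b")) / length(b_items)
    bhattacharyya_distance(fit_gaussian2d(ca[, 1L], ca[, 2L]),
                           fit_gaussian2d(cb[, 1L], cb[, 2L]))
  }
  permutation_test(cloud_dist, pool_items[seq_len(n_a)],
                   pool_items[-seq_len(n_a)], n_perm = n_perm, seed = seed,
                   alternative = "greater")
}

#' Multivariate dispersion of a gradient cloud
#'
#' Mean squared Euclidean distance of the points to their centroid. In one
#' dimension this equals the biased (n-denominator) variance — the
#' univariate dispersion equivalence; ROI variances elsewhere in the package
#' use the unbiased n-1 convention.
#'
#' @param coords `n x d` matrix (or vector for d = 1).
#' @return nonnegative scalar.
#' @export
multivariate_dispersion <- function(coords) {
  x <- as.matrix(coords)
  ctr <- colMeans(x)
  mean(rowSums(sweep(x, 2L, ctr)^2))
}

#' Linear model of clinical covariates on a gradient statistic
#'
#' Ordinary least squares of a per-patient gradient statistic on laterality,
#' mesial temporal sclerosis, bilateral tonic-clonic seizure history and
#' disease duration, with per-coefficient t-tests and Bonferroni correction
#' across the four covariates.
#'
#' @param y numeric response (per-patient ROI mean or variance).
#' @param covariates data.frame with columns `laterality` (`"L"`/`"R"`),
#'   `mts` (0/1), `btcs` (0/1), `duration_years`.
#' @param response_tag optional label (roi, gradient, statistic) carried in
#'   the output.
#' @return `clinical_model_fit`: coefficient table with estimates, standard
#'   errors, raw and corrected p-values, plus the underlying `lm` fit.
#' @export
fit_clinical_model <- function(y, covariates, response_tag = NULL) {
  need <- c("laterality", "mts", "btcs", "duration_years")
  if (!all(need %in% names(covariates)))
    stopf("covariates must contain: %s", paste(need, collapse = ", "))
  if (length(y) < 6L) stopf("need at least 6 patients, got %d", length(y))
  x_lat <- as.integer(covariates$laterality == "R")
  design <- data.frame(y = y, lat = x_lat, mts = covariates$mts,
                       btcs = covariates$btcs,
                       duration = covariates$duration_years)
  mm <- model.matrix(~ lat + mts + btcs + duration, design)
  if (qr(mm)$rank < ncol(mm)) {
    qr_d <- qr(mm)
    bad <- colnames(mm)[qr_d$pivot[-seq_len(qr_d$rank)]]
    stopf("rank-deficient design; offending column(s): %s",
          paste(bad, collapse = ", "))
  }
  fit <- lm(y ~ lat + mts + btcs + duration, data = design)
  tab <- summary(fit)$coefficients
  out <- data.frame(
    term = c("(Intercept)", "laterality", "mts", "btcs", "duration"),
    estimate = tab[, 1L], std_error = tab[, 2L], t = tab[, 3L],
    p_value = tab[, 4L], row.names = NULL
  )
  out$p_corrected <- c(NA, pmin(1, 4 * out$p_value[-1L]))
  structure(list(coefficients = out, fit = fit,
                 response_tag = response_tag),
            class = "clinical_model_fit")
}

#' @export
print.clinical_model_fit <- function(x, ...) {
  if (!is.null(x$response_tag))
    cat("Clinical covariate model:",
        paste(unlist(x$response_tag), collapse = " / "), "\n")
  else cat("Clinical covariate model\n")
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' @export
coef.clinical_model_fit <- function(object, ...) {
  setNames(object$coefficients$estimate, object$coefficients$term)
}

#' Kernel-by-embedding stability analysis
#'
#' Runs the full gradient pipeline for every combination of the five
#' affinity kernels and three embedding methods (15 variants), aligns and
#' harmonizes each variant internally, averages the first `n_keep` aligned
#' gradients over the patient subjects, and reports the matrix of absolute
#' Pearson correlations between every pair of variants (one matrix per
#' gradient). Magnitudes are used because gradients of different variants
#' are aligned within but not across variants, so signs may invert. Variants
#' that fail leave `NA` entries rather than fabricated values.
#'
#' @param cohort a `gradient_cohort` (or list of recordings plus a
#'   `covariates` table).
#' @param covariates covariate table; defaults to `cohort$covariates`.
#' @param n_keep gradients to compare (default 2).
#' @param density,n_components passed to [subject_gradients()].
#' @return `stability_result`: list with `variants` (kernel x method table),
#'   `correlation` (15 x 15 x n_keep array of absolute correlations) and
#'   `average_gradients`.
#' @export
stability_analysis <- function(cohort, covariates = NULL, n_keep = 2L,
                               density = 0.10, n_components = 10L) {
  recs <- if (inherits(cohort, "gradient_cohort")) cohort$recordings
          else cohort
  covariates <- covariates %||%
    (if (inherits(cohort, "gradient_cohort")) cohort$covariates else NULL)
  variants <- expand.grid(kernel = AFFINITY_KERNELS, method = EMBED_METHODS,
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  vnames <- paste(variants$kernel, variants$method, sep = "+")
  patient_idx <- if (!is.null(covariates))
    which(covariates$group != "control") else seq_along(recs)
  if (!length(patient_idx)) patient_idx <- seq_along(recs)
  avg <- vector("list", nrow(variants))
  names(avg) <- vnames
  for (v in seq_len(nrow(variants))) {
    avg[[v]] <- tryCatch({
      gs <- lapply(recs, subject_gradients, density = density,
                   kernel = variants$kernel[v], method = variants$method[v],
                   n_components = n_components)
      names(gs) <- vapply(recs, `[[`, character(1L), "subject_id")
      stack <- align_cohort(gs, covariates = covariates, k = n_components)
      if (!is.null(covariates) &&
          length(unique(covariates$protocol)) > 1L)
        stack <- harmonize_stack(stack)
      apply(stack$tensor[patient_idx, , seq_len(n_keep), drop = FALSE],
            c(2L, 3L), mean)
    }, error = function(e) {
      warning(sprintf("variant %s failed: %s", vnames[v],
                      conditionMessage(e)), call. = FALSE)
      NULL
    })
  }
  nv <- nrow(variants)
  corr <- array(NA_real_, dim = c(nv, nv, n_keep),
                dimnames = list(vnames, vnames, paste0("g", seq_len(n_keep))))
  for (g in seq_len(n_keep)) {
    for (i in seq_len(nv)) for (j in seq_len(nv)) {
      if (!is.null(avg[[i]]) && !is.null(avg[[j]]))
        corr[i, j, g] <- abs(cor(avg[[i]][, g], avg[[j]][, g]))
    }
  }
  structure(list(variants = variants, correlation = corr,
                 average_gradients = avg),
            class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  nv <- nrow(x$variants)
  cat(sprintf("<stability_result> %d variants (%d kernels x %d methods)\n",
              nv, length(unique(x$variants$kernel)),
              length(unique(x$variants$method))))
  for (g in seq_len(dim(x$correlation)[3L])) {
    m <- x$correlation[, , g]
    cat(sprintf("  gradient %d: median |r| = %.3f (off-diagonal), %d missing\n",
                g, median(m[upper.tri(m)], na.rm = TRUE),
                sum(is.na(m[upper.tri(m)]))))
  }
  invisible(x)
}
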