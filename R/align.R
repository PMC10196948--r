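#' Build the group gradient template
#'
#' Horizontally stacks the gradient coordinates of every subject
#' (`a x (k * n)`) and extracts the first `k` left singular vectors — the
#' principal components in voxel space — as an orthonormal template that
#' every subject is subsequently aligned to.
#'
#' @param gradient_sets list of `gradient_set` (equal `a` and column count).
#' @param k number of template components (capped at the stacked rank).
#' @return `gradient_template`: list with `coords` (`a x k`, orthonormal
#'   columns) and `n_subjects`.
#' @export
build_template <- function(gradient_sets, k = 250L) {
  coords <- lapply(gradient_sets, function(g)
    if (inherits(g, "gradient_set")) g$coords else g)
  dims <- vapply(coords, dim, integer(2L))
  if (any(dims[1L, ] != dims[1L, 1L]) || any(dims[2L, ] != dims[2L, 1L]))
    stopf("gradient sets have inconsistent shapes")
  stacked <- do.call(cbind, coords)
  k <- min(k, dim(stacked))
  sv <- svd(stacked, nu = k, nv = 0)
  keep <- sv$d[seq_len(k)] > max(sv$d) * 1e-12
  u <- fix_column_signs(sv$u[, which(keep), drop = FALSE])
  structure(list(coords = u, n_subjects = length(gradient_sets)),
            class = "gradient_template")
}

#' @export
print.gradient_template <- function(x, ...) {
  cat(sprintf("<gradient_template> %d voxels x %d components (from %d subjects)\n",
              nrow(x$coords), ncol(x$coords), x$n_subjects))
  invisible(x)
}

#' Procrustes alignment of one gradient set to the template
#'
#' Closed-form full Procrustes: the translation, isotropic scaling and
#' orthogonal rotation (reflections permitted) minimizing the Frobenius
#' distance to the template, obtained from the SVD of the cross-covariance
#' of the centered configurations. Alignment never increases the Frobenius
#' distance to the template.
#'
#' @param source `gradient_set` or `a x k` matrix.
#' @param template `gradient_template` or `a x k` matrix.
#' @return aligned `a x k` matrix with attributes `rotation`, `scale`,
#'   `translation` and `residual` (Frobenius distance after alignment).
#' @export
procrustes_align <- function(source, template) {
  x <- if (inherits(source, "gradient_set")) source$coords else source
  y <- if (inherits(template, "gradient_template")) template$coords
       else template
  if (!all(dim(x) == dim(y)))
    stopf("source (%d x %d) and template (%d x %d) dimensions differ",
          nrow(x), ncol(x), nrow(y), ncol(y))
  if (max(abs(x)) == 0) stopf("degenerate all-zero source")
  mx <- colMeans(x); my <- colMeans(y)
  xc <- sweep(x, 2L, mx); yc <- sweep(y, 2L, my)
  sv <- svd(crossprod(xc, yc))
  rot <- sv$u %*% t(sv$v)
  s <- sum(sv$d) / sum(xc^2)
  aligned <- s * (xc %*% rot)
  aligned <- sweep(aligned, 2L, my, `+`)
  structure(aligned, rotation = rot, scale = s,
            translation = my - s * as.numeric(mx %*% rot),
            residual = sqrt(sum((aligned - y)^2)))
}

#' Align every subject to a common template
#'
#' Builds the stacked-PCA template from all subjects' gradients and
#' Procrustes-aligns each subject to it, producing a voxel-comparable
#' gradient stack.
#'
#' @param gradient_sets list of `gradient_set` (one per subject).
#' @param covariates cohort covariate table (row order = subject order);
#'   carried into the stack for downstream statistics.
#' @param k number of template components / aligned gradients.
#' @param template optional pre-built `gradient_template`.
#' @return A `gradient_stack`: list with `tensor` (`n x a x k` array),
#'   `covariates`, `template`, `harmonized = FALSE`.
#' @export
align_cohort <- function(gradient_sets, covariates = NULL, k = 250L,
                         template = NULL) {
  if (is.null(template)) template <- build_template(gradient_sets, k)
  subj_k <- min(vapply(gradient_sets, function(g)
    ncol(if (inherits(g, "gradient_set")) g$coords else g), integer(1L)))
  k_eff <- min(ncol(template$coords), subj_k)
  template$coords <- template$coords[, seq_len(k_eff), drop = FALSE]
  n <- length(gradient_sets)
  a <- nrow(template$coords)
  tensor <- array(NA_real_, dim = c(n, a, k_eff),
                  dimnames = list(names(gradient_sets), NULL, NULL))
  for (i in seq_len(n)) {
    g <- gradient_sets[[i]]
    coords <- if (inherits(g, "gradient_set")) g$coords else g
    tensor[i, , ] <- procrustes_align(coords[, seq_len(k_eff), drop = FALSE],
                                      template)
  }
  structure(list(tensor = tensor, covariates = covariates,
                 template = template, harmonized = FALSE),
            class = "gradient_stack")
}

#' @export
print.gradient_stack <- function(x, ...) {
  d <- dim(x$tensor)
  cat(sprintf("<gradient_stack> %d subjects x %d voxels x %d gradients%s\n",
              d[1L], d[2L], d[3L],
              if (isTRUE(x$harmonized)) " (harmonized)" else ""))
  invisible(x)
}

#' Harmonize an aligned gradient stack across batches
#'
#' Removes batch (acquisition protocol) location/scale effects from each
#' gradient column with the parametric empirical-Bayes batch model of
#' `sva::ComBat`, treating voxels as features and subjects as observations,
#' while preserving the group effects encoded in the design. With a single
#' batch the stack is returned unchanged.
#'
#' @param stack a `gradient_stack` from [align_cohort()].
#' @param batch factor/character of batch labels, one per subject (default:
#'   `covariates$protocol`).
#' @param group factor/character of group labels to preserve (default:
#'   `covariates$group`, encoded as indicator columns against the first
#'   level).
#' @return the stack with batch effects removed and `harmonized = TRUE`.
#' @export
harmonize_stack <- function(stack, batch = NULL, group = NULL) {
  stopifnot(inherits(stack, "gradient_stack"))
  batch <- batch %||% stack$covariates$protocol
  group <- group %||% stack$covariates$group
  n <- dim(stack$tensor)[1L]
  if (length(batch) != n) stopf("need one batch label per subject")
  batch <- factor(batch)
  if (nlevels(batch) == 1L) {
    stack$harmonized <- TRUE
    return(stack)
  }
  if (any(table(batch) < 2L))
    stopf("every batch needs at least 2 subjects (variance inestimable)")
  mod <- NULL
  if (!is.null(group)) {
    group <- factor(group)
    mod <- model.matrix(~group)
    if (qr(mod)$rank < ncol(mod))
      stopf("design matrix (group indicators) is rank deficient")
  }
  k <- dim(stack$tensor)[3L]
  for (j in seq_len(k)) {
    dat <- t(stack$tensor[, , j])      # voxels x subjects
    # ComBat drops zero-variance features; guard by jittering exact constants
    keep_sd <- apply(dat, 1L, sd)
    const <- keep_sd == 0
    h <- dat
    if (!all(const)) {
      sub <- dat[!const, , drop = FALSE]
      res <- suppressMessages(
        sva::ComBat(dat = sub, batch = batch, mod = mod, par.prior = TRUE)
      )
      h[!const, ] <- res
    }
    stack$tensor[, , j] <- t(h)
  }
  stack$harmonized <- TRUE
  stack
}
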