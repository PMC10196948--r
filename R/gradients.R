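#' Compress the cortical time-series by PCA
#'
#' Reduces a `t x b` cortical time-series (typically `t << b`) to its
#' `min(t - 1, b)` principal component score time-series, preserving all
#' pairwise temporal structure up to rank truncation. Computed from the
#' `t x t` Gram matrix of the column-centered data so the cost is independent
#' of `b`.
#'
#' @param cortical_ts numeric matrix, timepoints x cortical voxels.
#' @return `t x p` score matrix (`p = min(t - 1, b)`), columns ordered by
#'   decreasing explained variance, with attribute `"explained_variance"`.
#' @export
reduce_cortex_pca <- function(cortical_ts) {
  if (!is.matrix(cortical_ts) || !is.numeric(cortical_ts))
    stopf("`cortical_ts` must be a numeric matrix")
  t_n <- nrow(cortical_ts)
  if (t_n < 3L) stopf("need at least 3 timepoints, got %d", t_n)
  xc <- scale(cortical_ts, center = TRUE, scale = FALSE)
  g <- tcrossprod(xc)                      # t x t Gram matrix
  if (max(abs(g)) == 0) stopf("all-constant cortical input: no variance")
  eg <- eigen(g, symmetric = TRUE)
  p_max <- min(t_n - 1L, ncol(cortical_ts))
  tol <- max(eg$values) * 1e-12
  keep <- seq_len(min(p_max, sum(eg$values > tol)))
  d <- sqrt(eg$values[keep])
  scores <- eg$vectors[, keep, drop = FALSE] * rep(d, each = t_n)
  scores <- fix_column_signs(scores)
  attr(scores, "explained_variance") <- eg$values[keep] / sum(pmax(eg$values, 0))
  scores
}

# Deterministic sign convention: the largest-magnitude entry of each column
# is made positive (first occurrence breaks ties), so repeated runs and
# different eigensolvers agree up to nothing.
fix_column_signs <- function(x) {
  for (j in seq_len(ncol(x))) {
    i <- which.max(abs(x[, j]))
    if (x[i, j] < 0) x[, j] <- -x[, j]
  }
  x
}

#' Connectivity fingerprints of subcortical voxels
#'
#' Correlates every subcortical voxel's time-series with every cortical
#' principal component score, giving each voxel an `a x p` connectivity
#' fingerprint in component space.
#'
#' @param subcortical_ts `t x a` matrix of subcortical voxel time-series.
#' @param pc_scores `t x p` cortical PC scores from [reduce_cortex_pca()].
#' @return `connectivity_fingerprint`: an `a x p` correlation matrix with
#'   attribute `density` (`NULL` before thresholding).
#' @export
compute_fingerprint <- function(subcortical_ts, pc_scores) {
  if (nrow(subcortical_ts) != nrow(pc_scores))
    stopf("timepoint mismatch: %d vs %d", nrow(subcortical_ts),
          nrow(pc_scores))
  sds <- apply(subcortical_ts, 2L, sd)
  if (any(sds == 0))
    stopf("zero-variance subcortical voxel(s): %s",
          paste(which(sds == 0), collapse = ", "))
  fp <- cor(subcortical_ts, pc_scores)   # a x p
  structure(fp, class = c("connectivity_fingerprint", "matrix", "array"),
            density = NULL)
}

#' Row-threshold a connectivity fingerprint
#'
#' Keeps, per row, the `ceiling(density * p)` largest entries by signed value
#' (the strongest connections) and zeroes the rest. Ties are broken by lowest
#' column index. The input is not modified.
#'
#' @param fingerprint matrix from [compute_fingerprint()].
#' @param density fraction of entries to retain per row, in (0, 1].
#' @return thresholded fingerprint with attribute `density` set.
#' @export
threshold_rows <- function(fingerprint, density = 0.10) {
  if (!is.numeric(density) || length(density) != 1L ||
      density <= 0 || density > 1)
    stopf("`density` must be in (0, 1], got %s", format(density))
  p <- ncol(fingerprint)
  keep_n <- ceiling(density * p)
  out <- matrix(0, nrow(fingerprint), p)
  for (i in seq_len(nrow(fingerprint))) {
    row <- fingerprint[i, ]
    idx <- order(row, decreasing = TRUE)[seq_len(keep_n)]  # stable: ties -> lowest index
    out[i, idx] <- row[idx]
  }
  structure(out, class = c("connectivity_fingerprint", "matrix", "array"),
            density = density)
}

AFFINITY_KERNELS <- c("pearson", "spearman", "cosine", "normalized_angle",
                      "gaussian")

#' Voxel-by-voxel affinity matrix
#'
#' Turns the (thresholded) fingerprint into an `a x a` similarity matrix by
#' comparing rows. Structural zeros introduced by thresholding participate in
#' the comparison like any other coordinate.
#'
#' Kernels: `pearson` and `spearman` row correlations, `cosine` similarity,
#' `normalized_angle` (`1 - acos(cosine)/pi`), and a `gaussian` kernel
#' `exp(-gamma * ||xi - xj||^2)` with the self-tuning bandwidth
#' `gamma = 1 / median(nonzero squared pairwise distance)`.
#'
#' @param fingerprint matrix (rows = subcortical voxels).
#' @param kernel one of `"pearson"`, `"spearman"`, `"cosine"`,
#'   `"normalized_angle"`, `"gaussian"`.
#' @return `affinity_matrix`: symmetric `a x a` matrix with attribute
#'   `kernel`; unit diagonal for the correlation/cosine/angle kernels.
#' @export
compute_affinity <- function(fingerprint, kernel = "pearson") {
  kernel <- match.arg(kernel, AFFINITY_KERNELS)
  x <- unclass(fingerprint)
  attr(x, "density") <- NULL
  if (kernel %in% c("pearson", "spearman")) {
    row_sd <- apply(x, 1L, sd)
    if (any(row_sd == 0))
      stopf("constant fingerprint row(s) under %s kernel: %s", kernel,
            paste(which(row_sd == 0), collapse = ", "))
    aff <- cor(t(x), method = kernel)
  } else if (kernel %in% c("cosine", "normalized_angle")) {
    nrm <- sqrt(rowSums(x^2))
    if (any(nrm == 0))
      stopf("zero fingerprint row(s) under %s kernel: %s", kernel,
            paste(which(nrm == 0), collapse = ", "))
    cosine <- tcrossprod(x / nrm)
    cosine <- pmin(pmax(cosine, -1), 1)
    aff <- if (kernel == "cosine") cosine else 1 - acos(cosine) / pi
  } else {  # gaussian
    sq <- as.matrix(dist(x))^2
    nz <- sq[upper.tri(sq)]
    nz <- nz[nz > 0]
    gamma <- if (length(nz)) 1 / median(nz) else 1
    aff <- exp(-gamma * sq)
  }
  aff <- (aff + t(aff)) / 2
  if (kernel != "gaussian") diag(aff) <- 1 else diag(aff) <- exp(0)
  structure(aff, class = c("affinity_matrix", "matrix", "array"),
            kernel = kernel)
}

EMBED_METHODS <- c("diffusion", "laplacian_eigenmaps", "pca")

# connected components of the nonnegative affinity graph (simple BFS)
n_components <- function(w) {
  n <- nrow(w)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0L) next
    cur <- cur + 1L
    frontier <- s
    comp[s] <- cur
    while (length(frontier)) {
      nb <- which(colSums(w[frontier, , drop = FALSE] > 0) > 0)
      nb <- nb[comp[nb] == 0L]
      comp[nb] <- cur
      frontier <- nb
    }
  }
  cur
}

#' Spectral embedding of an affinity matrix
#'
#' Computes the gradient coordinates of each voxel from the affinity matrix.
#' `diffusion` performs diffusion-map embedding of the alpha-normalized
#' transition operator (anisotropic normalization with exponent `alpha`,
#' trivial stationary eigenvector dropped; `diffusion_time = 0` selects the
#' multi-scale scaling `lambda / (1 - lambda)`, positive values scale by
#' `lambda^diffusion_time`). `laplacian_eigenmaps` returns the smallest
#' nontrivial generalized eigenvectors of the graph Laplacian.
#' `pca` returns principal component scores of the affinity rows.
#'
#' Negative affinity entries are clipped to zero before the diffusion and
#' Laplacian embeddings (both require a nonnegative kernel); the unclipped
#' matrix feeds the PCA variant.
#'
#' @param affinity symmetric matrix from [compute_affinity()].
#' @param method one of `"diffusion"`, `"laplacian_eigenmaps"`, `"pca"`.
#' @param n_components number of gradients to return (capped at `a - 1`).
#' @param alpha diffusion anisotropy exponent (0.5 default).
#' @param diffusion_time diffusion time (0 = multi-scale, the default).
#' @return A `gradient_set`: list with `coords` (`a x k`, columns ordered by
#'   decreasing eigenvalue, deterministic sign convention), `eigenvalues`
#'   (raw, descending), `eigenvalues_normalized` (fraction of their sum),
#'   `method` and `params`.
#' @export
embed_gradients <- function(affinity, method = "diffusion",
                            n_components = 250L, alpha = 0.5,
                            diffusion_time = 0) {
  method <- match.arg(method, EMBED_METHODS)
  if (!is.matrix(affinity) || !all(is.finite(affinity)))
    stopf("affinity must be a finite numeric matrix")
  if (max(abs(affinity - t(affinity))) > 1e-8)
    stopf("affinity must be symmetric")
  a <- nrow(affinity)
  k <- min(n_components, a - 1L)

  if (method == "pca") {
    x <- scale(unclass(affinity), center = TRUE, scale = FALSE)
    sv <- svd(x, nu = k, nv = 0)
    coords <- fix_column_signs(sv$u * rep(sv$d[seq_len(k)], each = a))
    ev <- sv$d[seq_len(k)]^2 / (a - 1L)
  } else {
    w <- pmax(unclass(affinity), 0)
    nc <- n_components(w)
    if (nc > 1L)
      stopf("affinity graph is disconnected (%d components)", nc)
    if (method == "diffusion") {
      d <- rowSums(w)
      w_a <- w / outer(d^alpha, d^alpha)        # anisotropic normalization
      d_a <- rowSums(w_a)
      m_sym <- w_a / outer(sqrt(d_a), sqrt(d_a))  # symmetric conjugate of P
      eg <- eigen(m_sym, symmetric = TRUE)
      lam <- eg$values
      psi <- eg$vectors / sqrt(d_a)   # right eigenvectors of P
      psi <- psi / psi[1L, 1L]        # trivial eigenvector becomes constant 1
      lam_k <- lam[seq_len(k) + 1L]
      scale_k <- if (diffusion_time == 0) lam_k / (1 - lam_k)
                 else lam_k^diffusion_time
      coords <- psi[, seq_len(k) + 1L, drop = FALSE] *
        rep(scale_k, each = a)
      coords <- fix_column_signs(coords)
      ev <- lam_k
    } else {  # laplacian eigenmaps
      d <- rowSums(w)
      m_sym <- w / outer(sqrt(d), sqrt(d))
      eg <- eigen(m_sym, symmetric = TRUE)
      # generalized eigenvectors of L v = mu D v are D^{-1/2} u with
      # mu = 1 - lambda; smallest nontrivial mu = largest lambda below 1
      vecs <- eg$vectors / sqrt(d)
      coords <- vecs[, seq_len(k) + 1L, drop = FALSE]
      coords <- fix_column_signs(coords)
      ev <- eg$values[seq_len(k) + 1L]
    }
  }
  structure(list(
    coords = coords, eigenvalues = ev,
    eigenvalues_normalized = ev / sum(abs(ev)),
    method = method,
    params = list(alpha = alpha, diffusion_time = diffusion_time,
                  n_components = k)
  ), class = "gradient_set")
}

#' @export
print.gradient_set <- function(x, ...) {
  cat(sprintf("<gradient_set> %d voxels x %d gradients (%s embedding)\n",
              nrow(x$coords), ncol(x$coords), x$method))
  ev <- head(x$eigenvalues_normalized, 5L)
  cat("  leading eigenvalues (normalized):",
      paste(sprintf("%.3f", ev), collapse = " "), "\n")
  invisible(x)
}

#' @export
summary.gradient_set <- function(object, ...) {
  k <- min(5L, ncol(object$coords))
  data.frame(
    gradient = seq_len(k),
    eigenvalue = object$eigenvalues[seq_len(k)],
    eigenvalue_normalized = object$eigenvalues_normalized[seq_len(k)],
    coord_sd = apply(object$coords[, seq_len(k), drop = FALSE], 2L, sd)
  )
}

#' @export
plot.gradient_set <- function(x, gradients = c(1L, 2L), col = NULL, ...) {
  g <- x$coords[, gradients, drop = FALSE]
  plot(g[, 1L], g[, 2L], xlab = sprintf("Gradient %d", gradients[1L]),
       ylab = sprintf("Gradient %d", gradients[2L]),
       col = col %||% "grey30", pch = 16, ...)
  invisible(x)
}

#' Per-subject gradient pipeline
#'
#' Runs the full per-subject chain: cortical PCA compression, connectivity
#' fingerprinting, row thresholding, affinity computation and spectral
#' embedding. Deterministic; provenance (kernel, method, density, parameters)
#' is recorded in the result.
#'
#' @param recording a `subject_recording` (see [simulate_subject()] or
#'   [load_recording()]).
#' @param density row-threshold density (default 0.10, i.e. top 10%).
#' @param kernel affinity kernel (default `"pearson"`).
#' @param method embedding method (default `"diffusion"`).
#' @param n_components,alpha,diffusion_time passed to [embed_gradients()].
#' @return A `gradient_set` with `$provenance`.
#' @export
subject_gradients <- function(recording, density = 0.10, kernel = "pearson",
                              method = "diffusion", n_components = 250L,
                              alpha = 0.5, diffusion_time = 0) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("[%s] %s", name, conditionMessage(e)))
  }
  pcs <- stage("reduce_cortex_pca", reduce_cortex_pca(recording$cortical_ts))
  fp <- stage("compute_fingerprint",
              compute_fingerprint(recording$subcortical_ts, pcs))
  fp <- stage("threshold_rows", threshold_rows(fp, density))
  aff <- stage("compute_affinity", compute_affinity(fp, kernel))
  gs <- stage("embed", embed_gradients(aff, method, n_components, alpha,
                                       diffusion_time))
  gs$provenance <- list(subject_id = recording$subject_id, density = density,
                        kernel = kernel, method = method,
                        n_components = gs$params$n_components, alpha = alpha,
                        diffusion_time = diffusion_time)
  gs
}

#' Gradients for every subject of a cohort
#'
#' @param cohort a `gradient_cohort` from [generate_cohort()] or a list of
#'   `subject_recording`s.
#' @param ... passed to [subject_gradients()].
#' @param verbose print one line per subject.
#' @return list of `gradient_set`, named by subject id.
#' @export
cohort_gradients <- function(cohort, ..., verbose = FALSE) {
  recs <- if (inherits(cohort, "gradient_cohort")) cohort$recordings
          else cohort
  out <- vector("list", length(recs))
  for (i in seq_along(recs)) {
    if (verbose) message("gradients: ", recs[[i]]$subject_id)
    out[[i]] <- subject_gradients(recs[[i]], ...)
  }
  names(out) <- vapply(recs, `[[`, character(1L), "subject_id")
  out
}
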