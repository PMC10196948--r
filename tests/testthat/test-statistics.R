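# gradient-space statistical battery

make_stack <- function(tensor, group = NULL, protocol = NULL, ids = NULL) {
  n <- dim(tensor)[1L]
  ids <- ids %||% sprintf("sub-%03d", seq_len(n))
  dimnames(tensor)[[1L]] <- ids
  structure(list(
    tensor = tensor,
    covariates = data.frame(subject_id = ids,
                            group = group %||% rep("control", n),
                            protocol = protocol %||% rep("protocol1", n),
                            stringsAsFactors = FALSE),
    template = NULL, harmonized = FALSE), class = "gradient_stack")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("roi_stats reproduces hand-computed means and variances", {
  tensor <- array(0, c(2L, 4L, 2L))
  tensor[1L, , 1L] <- c(1, 3, 10, 20)
  tensor[2L, , 1L] <- c(2, 2, 5, 5)
  tensor[, , 2L] <- 7
  parc <- data.frame(voxel_id = 1:4,
                     roi = c("hippocampus", "hippocampus", "thalamus",
                             "thalamus"),
                     hemisphere = c("L", "L", "R", "R"))
  st <- roi_stats(make_stack(tensor, group = c("control", "L-TLE")), parc)
  hip1 <- st[st$roi == "hippocampus" & st$gradient == 1L, ]
  expect_equal(hip1$mean, c(2, 2))
  expect_equal(hip1$variance, c(2, 0))
  tha1 <- st[st$roi == "thalamus" & st$gradient == 1L, ]
  expect_equal(tha1$mean, c(15, 5))
  expect_equal(st$variance[st$gradient == 2L], rep(0, 4))
  expect_setequal(unique(st$side), c("L", "R"))
  expect_error(roi_stats(make_stack(tensor), parc[1:3, ]), "must match")
})

test_that("global_variance is the per-subject voxel variance", {
  tensor <- array(rnorm(3 * 20 * 2), c(3, 20, 2))
  gv <- global_variance(make_stack(tensor), gradient = 2L)
  expect_equal(unname(gv), apply(tensor[, , 2L], 1L, var))
  expect_error(global_variance(make_stack(tensor), gradient = 3L),
               "not present")
})

test_that("cohens_d and expansion_test match direct formulas", {
  x <- c(4, 5, 6, 7); y <- c(1, 2, 3)
  sp <- sqrt((3 * var(x) + 2 * var(y)) / 5)
  expect_equal(subgrad:::cohens_d(x, y), (mean(x) - mean(y)) / sp)
  et <- expansion_test(x, y, bonferroni = 2L)
  tt <- t.test(x, y, alternative = "greater")
  expect_equal(et$p_value, tt$p.value)
  expect_equal(et$statistic, unname(tt$statistic))
  expect_equal(et$p_corrected, min(1, 2 * tt$p.value))
  et2 <- expansion_test(x, y, one_tailed = FALSE)
  expect_equal(et2$p_value, t.test(x, y)$p.value)
  expect_error(expansion_test(c(1), y), "at least 2")
  expect_error(expansion_test(c(1, 1), c(1, 1)), "zero pooled variance")
})

test_that("flip_to_ipsi_contra flips per laterality and is an involution", {
  stats <- data.frame(
    subject_id = rep(c("c1", "l1", "r1"), each = 2L),
    group = rep(c("control", "L-TLE", "R-TLE"), each = 2L),
    roi = "hippocampus", side = rep(c("L", "R"), 3L),
    gradient = 1L, mean = 1:6, variance = 1)
  lat <- c(c1 = NA, l1 = "L", r1 = "R")
  fl <- flip_to_ipsi_contra(stats, lat)
  expect_equal(fl$side, c("L", "R", "ipsi", "contra", "contra", "ipsi"))
  back <- flip_to_ipsi_contra(fl, lat)
  expect_equal(back$side, stats$side)
  expect_error(flip_to_ipsi_contra(stats, c(c1 = NA)), "missing laterality")
})

test_that("permutation_test follows the add-one median-centered convention", {
  # deterministic stat on tiny groups: difference of means
  stat <- function(a, b) mean(a) - mean(b)
  pt <- permutation_test(stat, c(10, 11, 12), c(0, 1, 2), n_perm = 200L,
                         seed = 3L)
  med <- median(pt$null_sample)
  expect_equal(pt$p_value,
               (sum(abs(pt$null_sample - med) >= abs(pt$observed - med)) + 1) /
                 201)
  expect_gte(pt$p_value, 1 / 201)
  # identical groups: observed near the null center, large p
  pt0 <- permutation_test(stat, c(1, 2, 3, 4), c(1, 2, 3, 4),
                          n_perm = 200L, seed = 3L)
  expect_gt(pt0$p_value, 0.2)
  # seeded determinism
  pt2 <- permutation_test(stat, c(10, 11, 12), c(0, 1, 2), n_perm = 200L,
                          seed = 3L)
  expect_identical(pt$null_sample, pt2$null_sample)
  # one-sided exceedance for nonnegative statistics
  pt1 <- permutation_test(function(a, b) abs(mean(a) - mean(b)),
                          c(10, 11, 12), c(0, 1, 2), n_perm = 200L,
                          seed = 4L, alternative = "greater")
  expect_equal(pt1$p_value, (sum(pt1$null_sample >= pt1$observed) + 1) / 201)
  expect_error(permutation_test(stat, 1, c(1, 2)), "at least 2")
})

test_that("roi_contrast_test detects a planted ROI mean offset", {
  set.seed(31)
  n <- 12L; a <- 20L
  parc <- data.frame(voxel_id = 1:a,
                     roi = rep(c("hippocampus", "thalamus"), each = a / 2L),
                     hemisphere = rep(c("L", "R"), a / 2L))
  tensor <- array(rnorm(n * a * 2L, sd = 0.3), c(n, a, 2L))
  hipL <- which(parc$roi == "hippocampus" & parc$hemisphere == "L")
  tensor[7:12, hipL, 1L] <- tensor[7:12, hipL, 1L] + 2
  stack <- make_stack(tensor, group = rep(c("control", "L-TLE"), each = 6L))
  pt <- roi_contrast_test(stack, parc, "hippocampus", members_a = 7:12,
                          members_b = 1:6, side_a = "L", side_b = "L",
                          n_perm = 400L, seed = 9L)
  expect_lt(pt$p_value, 0.02)
  # no effect on the thalamus
  pt2 <- roi_contrast_test(stack, parc, "thalamus", members_a = 7:12,
                           members_b = 1:6, side_a = "L", side_b = "L",
                           n_perm = 400L, seed = 9L)
  expect_gt(pt2$p_value, 0.05)
  expect_error(roi_contrast_test(stack, parc, "amygdala",
                                 members_a = 7:12, members_b = 1:6),
               "not found")
})

test_that("zscore_to_controls standardizes against side-matched cells", {
  ctrl <- data.frame(subject_id = rep(c("c1", "c2", "c3"), each = 1L),
                     group = "control", roi = "hippocampus", side = "L",
                     gradient = 1L, mean = c(1, 2, 3), variance = 1)
  pat <- data.frame(subject_id = "p1", group = "L-TLE",
                    roi = "hippocampus", side = "L", gradient = 1L,
                    mean = 4, variance = 1)
  z <- zscore_to_controls(pat, ctrl)
  expect_equal(z$z, (4 - 2) / 1)
  ctrl0 <- ctrl; ctrl0$mean <- 2
  expect_error(zscore_to_controls(pat, ctrl0), "zero control SD")
  pat_bad <- pat; pat_bad$side <- "R"
  expect_error(zscore_to_controls(pat_bad, ctrl), "missing from controls")
})

test_that("fit_gaussian2d summarizes clouds and flags singular fits", {
  set.seed(32)
  x <- rnorm(200); y <- rnorm(200)
  fg <- fit_gaussian2d(x, y)
  expect_equal(unname(fg$mu), c(mean(x), mean(y)))
  expect_equal(unname(fg$sigma), unname(cov(cbind(x, y))))
  expect_false(fg$singular)
  fg2 <- fit_gaussian2d(c(1, 2, 3), c(2, 4, 6))   # perfectly collinear
  expect_true(fg2$singular)
  expect_error(fit_gaussian2d(1:3, 1:2), "differ in length")
  expect_error(fit_gaussian2d(1:2, 1:2), "at least 3")
})

test_that("bhattacharyya distance matches its closed form", {
  p <- list(mu = c(0, 0), sigma = diag(2))
  q <- list(mu = c(1, 0), sigma = diag(2))
  expect_equal(bhattacharyya_distance(p, q), 0.125, tolerance = 1e-12)
  expect_equal(bhattacharyya_distance(p, p), 0, tolerance = 1e-12)
  set.seed(33)
  for (i in 1:20) {
    a <- matrix(rnorm(9), 3); s1 <- crossprod(a) / 3 + diag(3) * 0.1
    b <- matrix(rnorm(9), 3); s2 <- crossprod(b) / 3 + diag(3) * 0.1
    p <- list(mu = rnorm(3), sigma = s1)
    q <- list(mu = rnorm(3), sigma = s2)
    d1 <- bhattacharyya_distance(p, q)
    expect_equal(d1, bhattacharyya_distance(q, p), tolerance = 1e-12)
    expect_gte(d1, 0)
    sbar <- (s1 + s2) / 2
    dmu <- p$mu - q$mu
    ref <- as.numeric(dmu %*% solve(sbar) %*% dmu) / 8 +
      0.5 * log(det(sbar) / sqrt(det(s1) * det(s2)))
    expect_equal(d1, ref, tolerance = 1e-10)
  }
})

test_that("bhattacharyya_permutation separates shifted clouds", {
  set.seed(34)
  cloud <- function(mu) cbind(rnorm(40, mu), rnorm(40))
  ga <- lapply(1:8, function(i) cloud(1.2))
  gb <- lapply(1:8, function(i) cloud(0))
  bp <- bhattacharyya_permutation(ga, gb, n_perm = 300L, seed = 6L)
  expect_lt(bp$p_value, 0.02)
  expect_equal(bp$alternative, "greater")
  # same-distribution clouds: no signal
  gc_ <- lapply(1:8, function(i) cloud(0))
  bp0 <- bhattacharyya_permutation(gb, gc_, n_perm = 300L, seed = 6L)
  expect_gt(bp0$p_value, 0.05)
})

test_that("multivariate dispersion generalizes the biased variance", {
  x <- c(1, 4, 7, 10)
  expect_equal(multivariate_dispersion(x), mean((x - mean(x))^2))
  xy <- cbind(c(0, 2), c(0, 0))
  expect_equal(multivariate_dispersion(xy), 1)   # points at distance 1 each
})

test_that("fit_clinical_model recovers planted coefficients", {
  set.seed(35)
  n <- 60L
  cov <- data.frame(laterality = sample(c("L", "R"), n, TRUE),
                    mts = rbinom(n, 1L, 0.4),
                    btcs = rbinom(n, 1L, 0.5),
                    duration_years = runif(n, 1, 30))
  y <- 2 + 0.8 * (cov$laterality == "R") + 1.5 * cov$mts +
    0.05 * cov$duration_years + rnorm(n, sd = 0.1)
  cm <- fit_clinical_model(y, cov, response_tag = list(roi = "hippocampus"))
  est <- coef(cm)
  expect_equal(unname(est[c("laterality", "mts", "duration")]),
               c(0.8, 1.5, 0.05), tolerance = 0.1)
  tab <- cm$coefficients
  expect_equal(tab$p_corrected[-1L], pmin(1, 4 * tab$p_value[-1L]))
  expect_true(is.na(tab$p_corrected[1L]))
  expect_lt(tab$p_corrected[tab$term == "mts"], 0.001)
  # oracle: identical to lm fit by hand
  ref <- lm(y ~ I(cov$laterality == "R") + cov$mts + cov$btcs +
              cov$duration_years)
  expect_equal(unname(est), unname(coef(ref)), tolerance = 1e-10)
  expect_error(fit_clinical_model(y[1:4], cov[1:4, ]), "at least 6")
  cov_bad <- cov; cov_bad$mts <- 1L
  expect_error(fit_clinical_model(y, cov_bad), "rank-deficient.*mts")
  expect_error(fit_clinical_model(y, cov[, 1:3]), "must contain")
})

test_that("stability_analysis covers all 15 kernel-method variants", {
  cfg <- simulation_config(n_control = 2L, n_ltle = 2L, n_rtle = 0L,
                           t = 50L, a = 24L, b = 100L,
                           roi_layout = data.frame(
                             roi = c("hippocampus", "thalamus"),
                             voxels = c(6L, 6L)),
                           batch_assignment = rep("protocol1", 4L),
                           seed = 17L)
  coh <- suppressWarnings(generate_cohort(cfg))
  sr <- stability_analysis(coh, n_keep = 2L, n_components = 5L)
  expect_equal(dim(sr$correlation), c(15L, 15L, 2L))
  expect_equal(nrow(sr$variants), 15L)
  expect_setequal(unique(sr$variants$kernel), AFFINITY_KERNELS)
  expect_setequal(unique(sr$variants$method), EMBED_METHODS)
  for (g in 1:2) {
    m <- sr$correlation[, , g]
    expect_equal(unname(diag(m))[!is.na(diag(m))],
                 rep(1, sum(!is.na(diag(m)))))
    expect_true(all(m[!is.na(m)] >= 0 & m[!is.na(m)] <= 1 + 1e-12))
    expect_equal(m, t(m))
  }
})
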