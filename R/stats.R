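## Statistical layer: rank tests with Bonferroni-adjusted pairwise
## comparisons, Bray-Curtis PCoA, PAM clustering with silhouette-based k
## selection, envfit-style vector fitting, PERMANOVA, and MaAsLin2-style
## multivariable linear associations with BH FDR control.

#' Two-sided Mann-Whitney U test
#'
#' Exact enumeration when the pooled size is at most 16 and there are no
#' ties; normal approximation with tie and continuity correction
#' otherwise.
#'
#' @param x,y numeric samples.
#' @param m number of comparisons for the Bonferroni adjustment
#'   (default 1, i.e. unadjusted).
#' @return List of class `rank_test`: `statistic` (U for `x`), `p_value`,
#'   `adjusted_p`, `n`.
#' @export
mann_whitney_u <- function(x, y, m = 1L) {
  stopifnot(length(x) > 0L, length(y) > 0L)
  exact <- (length(x) + length(y) <= 16L) &&
    !any(duplicated(c(x, y)))
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = TRUE))
  structure(list(statistic = unname(wt$statistic),
                 p_value = wt$p.value,
                 adjusted_p = min(1, wt$p.value * m),
                 exact = exact,
                 n = c(n_x = length(x), n_y = length(y))),
            class = "rank_test")
}

#' Kruskal-Wallis test with tie correction
#'
#' With fewer than three groups the comparison is routed to
#' [mann_whitney_u()].
#'
#' @param groups list of numeric vectors (>= 3 for Kruskal-Wallis).
#' @return List of class `rank_test`: `statistic` (H), `p_value`, `df`,
#'   `n`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), all(lengths(groups) > 0L))
  if (length(groups) < 3L) {
    if (length(groups) != 2L) stop("need >= 2 groups", call. = FALSE)
    return(mann_whitney_u(groups[[1]], groups[[2]]))
  }
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  kt <- stats::kruskal.test(x, g)
  structure(list(statistic = unname(kt$statistic),
                 p_value = kt$p.value,
                 df = unname(kt$parameter),
                 n = lengths(groups)),
            class = "rank_test")
}

#' Pairwise Mann-Whitney tests with Bonferroni adjustment
#'
#' All pairwise two-sided comparisons among `k` groups; adjusted p-values
#' are `min(1, p * C(k, 2))`.
#'
#' @param groups named list of numeric vectors.
#' @return Data frame: `group_a`, `group_b`, `statistic`, `p_value`,
#'   `adjusted_p`.
#' @export
pairwise_bonferroni <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  nm <- names(groups)
  if (is.null(nm)) nm <- paste0("g", seq_along(groups))
  pr <- utils::combn(seq_along(groups), 2L)
  m <- ncol(pr)
  rows <- lapply(seq_len(m), function(k) {
    res <- mann_whitney_u(groups[[pr[1, k]]], groups[[pr[2, k]]], m = m)
    data.frame(group_a = nm[pr[1, k]], group_b = nm[pr[2, k]],
               statistic = res$statistic, p_value = res$p_value,
               adjusted_p = res$adjusted_p, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Bray-Curtis dissimilarity matrix
#'
#' `d(x, y) = sum |x_i - y_i| / sum (x_i + y_i)`; symmetric, zero
#' diagonal, in \[0, 1\] for non-negative data. A pair of all-zero
#' vectors gets distance 0 with a warning.
#'
#' @param m samples x features non-negative numeric matrix.
#' @return `dist` object.
#' @export
bray_curtis <- function(m) {
  m <- as.matrix(m)
  stopifnot(all(m >= 0))
  n <- nrow(m)
  d <- matrix(0, n, n)
  warned <- FALSE
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      denom <- sum(m[i, ] + m[j, ])
      if (denom == 0) {
        if (!warned) {
          warning("all-zero sample pair; distance set to 0", call. = FALSE)
          warned <- TRUE
        }
        d[i, j] <- d[j, i] <- 0
      } else {
        d[i, j] <- d[j, i] <- sum(abs(m[i, ] - m[j, ])) / denom
      }
    }
  }
  rownames(d) <- colnames(d) <- rownames(m)
  stats::as.dist(d)
}

#' Principal coordinates analysis
#'
#' Gower double-centering of the squared-distance matrix followed by
#' eigendecomposition; coordinates are eigenvectors scaled by the square
#' root of the positive eigenvalues. Negative eigenvalues are reported
#' but not corrected. Axis signs follow a deterministic convention: the
#' largest-magnitude loading on each axis is positive.
#'
#' @param d `dist` or square symmetric matrix with zero diagonal.
#' @param n_axes number of axes to return (default: all positive ones).
#' @return List of class `ordination`: `coordinates` (samples x axes),
#'   `eigenvalues` (all), `pct_variance` (per returned axis, over
#'   positive eigenvalues).
#' @export
pcoa <- function(d, n_axes = NULL) {
  dm <- as.matrix(d)
  if (!isSymmetric(unname(dm), tol = 1e-8)) {
    stop("distance matrix must be symmetric", call. = FALSE)
  }
  n <- nrow(dm)
  a <- -0.5 * dm^2
  centering <- diag(n) - matrix(1 / n, n, n)
  g <- centering %*% a %*% centering
  eig <- eigen((g + t(g)) / 2, symmetric = TRUE)
  values <- eig$values
  pos <- which(values > max(values[1], 0) * 1e-12 & values > 0)
  if (length(pos) == 0L) stop("no positive eigenvalues", call. = FALSE)
  if (is.null(n_axes)) n_axes <- length(pos)
  n_axes <- min(n_axes, length(pos))
  axes <- pos[seq_len(n_axes)]
  coords <- eig$vectors[, axes, drop = FALSE] %*%
    diag(sqrt(values[axes]), nrow = n_axes)
  for (k in seq_len(ncol(coords))) {
    big <- which.max(abs(coords[, k]))
    if (coords[big, k] < 0) coords[, k] <- -coords[, k]
  }
  rownames(coords) <- rownames(dm)
  colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  pct <- 100 * values[axes] / sum(values[values > 0])
  structure(list(coordinates = coords, eigenvalues = values,
                 pct_variance = pct),
            class = "ordination")
}

#' PAM clustering with silhouette-based selection of k
#'
#' Runs partitioning-around-medoids for each k in `k_range` and returns
#' the solution maximizing average silhouette width (ties to the smaller
#' k).
#'
#' @param d `dist` object.
#' @param k_range candidate cluster numbers (subset of 2..n-1).
#' @return List of class `cluster_solution`: `k`, `medoids` (indices),
#'   `assignments`, `avg_silhouette`, `silhouette_by_k`.
#' @export
pam_with_silhouette <- function(d, k_range = 2:6) {
  n <- attr(d, "Size")
  if (is.null(n)) { d <- stats::as.dist(d); n <- attr(d, "Size") }
  if (n < 3L) stop("need at least 3 samples", call. = FALSE)
  if (max(d) == 0) stop("all points identical; silhouette undefined",
                        call. = FALSE)
  k_range <- k_range[k_range >= 2L & k_range <= n - 1L]
  stopifnot(length(k_range) > 0L)
  sil <- numeric(length(k_range))
  fits <- vector("list", length(k_range))
  for (i in seq_along(k_range)) {
    fit <- cluster::pam(d, k = k_range[i], diss = TRUE)
    fits[[i]] <- fit
    sil[i] <- fit$silinfo$avg.width
  }
  best <- which(sil == max(sil))[1L]   # ties -> smaller k (k_range sorted)
  fit <- fits[[best]]
  structure(list(k = k_range[best],
                 medoids = as.integer(fit$id.med),
                 assignments = as.integer(fit$clustering),
                 avg_silhouette = sil[best],
                 silhouette_by_k = stats::setNames(sil, k_range)),
            class = "cluster_solution")
}

#' Fit external variables as vectors onto an ordination
#'
#' For each variable, least-squares regression on the first two
#' ordination axes; R-squared is the fitted variance fraction and the
#' direction cosines are the normalized regression coefficients.
#' Significance by permutation of the variable's rows:
#' `p = (1 + #permuted R2 >= observed) / (n_perm + 1)`.
#'
#' @param ord `ordination` (or samples x axes coordinate matrix).
#' @param variables data frame or matrix of numeric variables aligned to
#'   samples.
#' @param n_perm number of permutations (>= 99; default 999).
#' @param seed RNG seed (required for reproducibility).
#' @return Data frame: `variable`, `dir1`, `dir2`, `r2`, `p_value`.
#' @export
envfit_vectors <- function(ord, variables, n_perm = 999L, seed) {
  coords <- if (inherits(ord, "ordination")) ord$coordinates else ord
  stopifnot(ncol(coords) >= 2L, n_perm >= 99L, !missing(seed))
  ax <- scale(coords[, 1:2], center = TRUE, scale = FALSE)
  variables <- as.data.frame(variables)
  stopifnot(nrow(variables) == nrow(ax))
  n <- nrow(ax)
  qr_ax <- qr(ax)

  r2_of <- function(v) {
    v <- v - mean(v)
    tot <- sum(v^2)
    if (tot == 0) return(0)
    fit <- qr.fitted(qr_ax, v)
    sum(fit^2) / tot
  }
  set.seed(seed)
  rows <- lapply(names(variables), function(nm) {
    v <- variables[[nm]]
    obs <- r2_of(v)
    if (stats::var(v) == 0) {
      return(data.frame(variable = nm, dir1 = NA_real_, dir2 = NA_real_,
                        r2 = 0, p_value = 1, stringsAsFactors = FALSE))
    }
    beta <- qr.coef(qr_ax, v - mean(v))
    dir <- beta / sqrt(sum(beta^2))
    exceed <- 0L
    for (b in seq_len(n_perm)) {
      if (r2_of(v[sample.int(n)]) >= obs - 1e-12) exceed <- exceed + 1L
    }
    data.frame(variable = nm, dir1 = dir[1], dir2 = dir[2], r2 = obs,
               p_value = (1 + exceed) / (n_perm + 1),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' PERMANOVA (one-way) on a distance matrix
#'
#' Pseudo-F from the partition of the total sum of squared distances into
#' within- and between-group components; the p-value comes from seeded
#' permutations of the group labels.
#'
#' @param d `dist` object.
#' @param grouping factor-like group labels, one per sample.
#' @param n_perm number of permutations (>= 99; default 999).
#' @param seed RNG seed.
#' @return List of class `permanova_result`: `pseudo_f`, `r2`, `p_value`,
#'   `df`.
#' @export
permanova <- function(d, grouping, n_perm = 999L, seed) {
  dm <- as.matrix(d)^2
  grouping <- as.factor(grouping)
  n <- nrow(dm)
  stopifnot(length(grouping) == n, n_perm >= 99L, !missing(seed))
  a <- nlevels(droplevels(grouping))
  if (a < 2L) stop("need >= 2 groups", call. = FALSE)

  ss_total <- sum(dm[upper.tri(dm)]) / n
  ss_within <- function(g) {
    s <- 0
    for (lev in levels(g)) {
      idx <- which(g == lev)
      if (length(idx) >= 2L) {
        sub <- dm[idx, idx]
        s <- s + sum(sub[upper.tri(sub)]) / length(idx)
      }
    }
    s
  }
  f_of <- function(g) {
    ssw <- ss_within(g)
    ssa <- ss_total - ssw
    (ssa / (a - 1)) / (ssw / (n - a))
  }
  obs <- f_of(grouping)
  set.seed(seed)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    if (f_of(grouping[sample.int(n)]) >= obs - 1e-12) exceed <- exceed + 1L
  }
  ssw_obs <- ss_within(grouping)
  structure(list(pseudo_f = obs,
                 r2 = (ss_total - ssw_obs) / ss_total,
                 p_value = (1 + exceed) / (n_perm + 1),
                 df = c(between = a - 1L, within = n - a)),
            class = "permanova_result")
}

#' Multivariable linear diet-microbiome associations with BH FDR
#'
#' MaAsLin2-style linear layer: per feature, total-sum-scaled relative
#' abundance with a half-minimum pseudocount and log transform, then
#' ordinary least squares of the transformed abundance on each exposure
#' plus covariates. Features are restricted to non-minor labels (median
#' >= 1% or prevalence >= 10%). BH q-values are computed across all
#' feature x exposure tests and mapped to confidence tiers: high
#' (q < 0.1), moderate (q < 0.25), exploratory (q < 0.3), ns.
#'
#' @param profiles `sample_profiles` or samples x labels relative
#'   abundance matrix.
#' @param cohort data frame with `sample_id`, the exposures and the
#'   covariates; rows are matched to profile samples by `sample_id`.
#' @param exposures character vector of exposure column names.
#' @param covariates character vector of covariate column names
#'   (default `c("BMI", "age", "sex")`).
#' @param th `filter_thresholds` (minor-label rule).
#' @return Data frame of class `association_results`: `feature`,
#'   `exposure`, `coef`, `se`, `p_value`, `q_value`, `tier`.
#' @export
fit_associations <- function(profiles, cohort, exposures,
                             covariates = c("BMI", "age", "sex"),
                             th = filter_thresholds()) {
  rel <- if (inherits(profiles, "sample_profiles")) profiles$rel_abundance
         else as.matrix(profiles)
  stopifnot("sample_id" %in% names(cohort),
            all(exposures %in% names(cohort)),
            all(covariates %in% names(cohort)))
  common <- intersect(rownames(rel), cohort$sample_id)
  stopifnot(length(common) > length(covariates) + 2L)
  rel <- rel[common, , drop = FALSE]
  meta <- cohort[match(common, cohort$sample_id), , drop = FALSE]

  summ <- summarize_cohort(rel, th)
  features <- summ$per_label$label[!summ$per_label$minor]
  features <- setdiff(features, "Others")
  if (length(features) == 0L) stop("no non-minor features", call. = FALSE)

  ## drop exposures collinear with the covariates
  keep_exp <- character()
  for (e in exposures) {
    x <- stats::model.matrix(
      stats::reformulate(c(e, covariates)), data = meta)
    if (qr(x)$rank == ncol(x)) keep_exp <- c(keep_exp, e)
    else warning("exposure dropped (collinear design): ", e, call. = FALSE)
  }
  if (length(keep_exp) == 0L) stop("all exposures collinear", call. = FALSE)

  rows <- list()
  for (f in features) {
    y <- rel[, f]
    nz <- y[y > 0]
    pseudo <- if (length(nz)) min(nz) / 2 else 1e-6
    ly <- log(y + pseudo)
    for (e in keep_exp) {
      dat <- data.frame(.y = ly, meta, check.names = FALSE)
      fit <- stats::lm(stats::reformulate(c(e, covariates),
                                          response = ".y"), data = dat)
      co <- summary(fit)$coefficients
      ## exposure row(s): first non-intercept term(s) belonging to e
      idx <- grep(paste0("^", e), rownames(co))[1]
      rows[[length(rows) + 1L]] <- data.frame(
        feature = f, exposure = e,
        coef = co[idx, 1], se = co[idx, 2], p_value = co[idx, 4],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out$tier <- cut(out$q_value, breaks = c(-Inf, 0.1, 0.25, 0.3, Inf),
                  labels = c("high", "moderate", "exploratory", "ns"),
                  right = FALSE)
  out$tier <- as.character(out$tier)
  class(out) <- c("association_results", "data.frame")
  out
}
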