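# k-means++ seeding: spread initial centers by sampling points with
# probability proportional to squared distance from the nearest chosen center.
kmeansPlusPlusInit <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(NA_real_, k, ncol(X))
  idx <- sample.int(n, 1)
  centers[1, ] <- X[idx, ]
  d2 <- rowSums((X - matrix(centers[1, ], n, ncol(X), byrow = TRUE))^2)
  for (j in seq_len(k - 1)) {
    if (all(d2 == 0)) idx <- sample.int(n, 1)
    else idx <- sample.int(n, 1, prob = d2)
    centers[j + 1, ] <- X[idx, ]
    d2 <- pmin(d2, rowSums((X - matrix(centers[j + 1, ], n, ncol(X),
                                       byrow = TRUE))^2))
  }
  centers
}

#' Cluster expression or allele-frequency trajectories
#'
#' Scales each gene's series (`center_scale`: subtract the mean and divide
#' by the SD, used for combined expression profiles; `center_only`: subtract
#' the mean only, used for allele-frequency profiles) and runs Lloyd's
#' k-means with k-means++ initialization, keeping the best of `nRestarts`
#' restarts by within-cluster sum of squares. Genes with any missing
#' timepoint are removed first (k-means does not handle missing data);
#' zero-variance genes are excluded with a warning under `center_scale`.
#'
#' @param profiles numeric matrix, genes x timepoints.
#' @param k number of clusters (default 12).
#' @param mode `"center_scale"` or `"center_only"`.
#' @param nRestarts independent initializations (default 25).
#' @param seed seed.
#' @param maxIter Lloyd iteration cap per restart.
#' @return list of class `clusterModel`: `k`, `centroids` (k x T),
#'   `assignments` (named integer), `inertia`, `mode`, `removed` (genes
#'   dropped for missingness or zero variance), `scaled` (the matrix
#'   actually clustered).
#' @export
clusterProfiles <- function(profiles, k = 12,
                            mode = c("center_scale", "center_only"),
                            nRestarts = 25, seed = 1, maxIter = 100) {
  mode <- match.arg(mode)
  profiles <- as.matrix(profiles)
  if (is.null(rownames(profiles)))
    rownames(profiles) <- paste0("gene", seq_len(nrow(profiles)))
  complete <- complete.cases(profiles)
  removed <- rownames(profiles)[!complete]
  X <- profiles[complete, , drop = FALSE]
  ctr <- rowMeans(X)
  X <- X - ctr
  if (mode == "center_scale") {
    s <- apply(X, 1, sd)
    zv <- s == 0
    if (any(zv)) {
      warning(sum(zv), " zero-variance gene(s) excluded from scaling")
      removed <- c(removed, rownames(X)[zv])
      X <- X[!zv, , drop = FALSE]
      s <- s[!zv]
    }
    X <- X / s
  }
  if (k > nrow(X)) stop("k exceeds the number of usable genes")
  best <- NULL
  withSeed(childSeed(seed, "kmeans"), {
    for (r in seq_len(nRestarts)) {
      init <- kmeansPlusPlusInit(X, k)
      fit <- suppressWarnings(
        kmeans(X, centers = init, iter.max = maxIter, algorithm = "Lloyd"))
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
  })
  structure(list(k = k, centroids = best$centers,
                 assignments = setNames(best$cluster, rownames(X)),
                 inertia = best$tot.withinss, mode = mode,
                 removed = removed, scaled = X),
            class = "clusterModel")
}

#' @export
print.clusterModel <- function(x, ...) {
  cat("clusterModel: k =", x$k, "(", x$mode, "), ",
      length(x$assignments), "genes, inertia", format(x$inertia), "\n")
  invisible(x)
}

#' Classify an ASE trajectory as transition-extremum or environment-dependent
#'
#' Operates on a centered allele-frequency series: the gene is
#' `transition_extremum` iff the maximum absolute centered ASE inside the
#' shift window strictly exceeds the absolute centered ASE at both series
#' endpoints by at least `margin`; otherwise the ASE difference grows or
#' shrinks toward the ends of the timecourse and the gene is
#' `environment_dependent`.
#'
#' @param series numeric centered ASE series (frequency minus its mean).
#' @param shiftIndex timepoint index (1-based) of glucose depletion.
#' @param window half-width of the shift window in timepoints (default 3).
#' @param margin required excess over the endpoint deviations (default 0).
#' @return `"transition_extremum"` or `"environment_dependent"`.
#' @export
classifyTransition <- function(series, shiftIndex, window = 3, margin = 0) {
  n <- length(series)
  lo <- shiftIndex - window
  hi <- shiftIndex + window
  if (lo < 1 || hi > n) stop("shift window outside the series")
  peak <- max(abs(series[lo:hi]))
  ends <- abs(series[c(1, n)])
  if (peak > max(ends) + margin) "transition_extremum"
  else "environment_dependent"
}
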