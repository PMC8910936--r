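#' Build structural feature vectors for contact pairs
#'
#' Each contact contributes a 6-dimensional feature: the open-form Calpha
#' coordinates of its NBD residue followed by those of its SBD residue.
#' Features are mean-centered per coordinate; only the open conformation is
#' used, since the contacts exist only there.
#'
#' @param contacts data frame with `nbd_res`, `sbd_res` (and optionally
#'   `nbd_aa`, `sbd_aa` for labelling).
#' @param open_model the open-form `structure_model`.
#' @return Numeric matrix (contacts x 6) with contact labels as rownames
#'   and the NBD residue numbers as attribute `nbd_res`.
#' @export
build_features <- function(contacts, open_model) {
  idx_n <- match(contacts$nbd_res, open_model$resno)
  idx_s <- match(contacts$sbd_res, open_model$resno)
  if (anyNA(idx_n) || anyNA(idx_s)) {
    bad <- c(contacts$nbd_res[is.na(idx_n)], contacts$sbd_res[is.na(idx_s)])
    stop("contact residue(s) absent from the open model: ",
         paste(bad, collapse = ", "))
  }
  xyz <- as.matrix(open_model[, c("x", "y", "z")])
  feats <- cbind(xyz[idx_n, , drop = FALSE], xyz[idx_s, , drop = FALSE])
  feats <- scale(feats, center = TRUE, scale = FALSE)
  attr(feats, "scaled:center") <- NULL
  colnames(feats) <- c("nbd_x", "nbd_y", "nbd_z", "sbd_x", "sbd_y", "sbd_z")
  lab_n <- if (!is.null(contacts$nbd_aa)) paste0(contacts$nbd_aa, contacts$nbd_res) else contacts$nbd_res
  lab_s <- if (!is.null(contacts$sbd_aa)) paste0(contacts$sbd_aa, contacts$sbd_res) else contacts$sbd_res
  rownames(feats) <- paste0(lab_n, "-", lab_s)
  attr(feats, "nbd_res") <- contacts$nbd_res
  feats
}

#' Project contact features onto the first principal component
#'
#' The PC1 sign is fixed so that the contact with the smallest NBD residue
#' number scores negative, making runs reproducible across platforms.
#'
#' @param features matrix from [build_features()].
#' @return Named numeric vector of PC1 scores, with the fraction of
#'   variance explained as attribute `var_explained`.
#' @export
pc1_scores <- function(features) {
  if (nrow(features) < 2L) stop("need >= 2 features")
  if (all(apply(features, 2L, stats::sd) == 0))
    stop("zero-variance features: PCA undefined")
  pc <- stats::prcomp(features, center = FALSE, scale. = FALSE)
  scores <- pc$x[, 1L]
  nbd_res <- attr(features, "nbd_res")
  if (!is.null(nbd_res)) {
    anchor <- scores[which.min(nbd_res)]
    if (anchor > 0) scores <- -scores
  }
  attr(scores, "var_explained") <- pc$sdev[1L]^2 / sum(pc$sdev^2)
  scores
}

# Gaussian kernel density on a grid
.kde_eval <- function(x, grid, bw) {
  vapply(grid, function(g) mean(stats::dnorm(g, mean = x, sd = bw)), numeric(1))
}

#' Kernel bandwidth by cost minimization (Shimazaki-Shinomoto)
#'
#' Selects the Gaussian-kernel bandwidth minimising the unbiased
#' integrated-squared-error cost
#' `C(w) = (1/n^2) sum_ij phi(d_ij; 2w^2) - (2/n^2) sum_{i!=j} phi(d_ij; w^2)`
#' over a logarithmic candidate grid. The cost minimum is typically shallow
#' for small samples, where the selector is known to undersmooth; among all
#' candidates within `cost_slack` of the minimum (relative to the cost range
#' on the grid) the largest bandwidth is returned. Falls back to Silverman's
#' rule ([stats::bw.nrd0()]) for tiny or degenerate samples.
#'
#' @param x numeric sample.
#' @param n_candidates size of the candidate grid.
#' @param cost_slack near-optimality fraction of the cost range within which
#'   the smoothest bandwidth is preferred; default 0.05.
#' @return Bandwidth (same units as `x`).
#' @export
kde_bandwidth <- function(x, n_candidates = 100L, cost_slack = 0.05) {
  n <- length(x)
  rng <- diff(range(x))
  if (n < 4L || rng == 0) return(max(stats::bw.nrd0(x), .Machine$double.eps))
  d <- as.matrix(stats::dist(x))
  ws <- exp(seq(log(rng / n / 10), log(rng), length.out = n_candidates))
  cost <- vapply(ws, function(w) {
    term1 <- sum(stats::dnorm(d, sd = sqrt(2) * w)) / n^2
    off <- stats::dnorm(d, sd = w); diag(off) <- 0
    term1 - 2 * sum(off) / n^2
  }, numeric(1))
  thr <- min(cost) + cost_slack * diff(range(cost))
  max(ws[cost <= thr])
}

#' Cluster 1D scores by gaps in their kernel density
#'
#' Estimates a Gaussian kernel density of the PC1 scores on a regular grid
#' spanning the scores plus three bandwidths, then cuts the density at
#' local minima deep enough to separate modes: a valley splits two
#' neighbouring peaks when its density falls below `valley_fraction` times
#' the smaller peak. Shallow satellite modes -- local maxima below
#' `peak_min_fraction` of the highest peak, as arise in the tails of an
#' ISE-optimal (mildly undersmoothed) density -- are never cluster seeds
#' and are absorbed into their neighbour. Cluster labels are contiguous
#' from 1 and ordered by ascending score.
#'
#' @param scores numeric vector (typically [pc1_scores()] output).
#' @param bandwidth `"auto"` (Shimazaki-Shinomoto via [kde_bandwidth()]) or
#'   a positive number.
#' @param valley_fraction depth criterion in (0, 1); default 0.5.
#' @param peak_min_fraction minimum height of a cluster-seeding mode,
#'   relative to the global density maximum; default 0.1.
#' @param grid_size number of grid points; default 512.
#' @param boundary_tol scores within this distance of a cut point are
#'   flagged `is_boundary`; default `bandwidth / 10`.
#' @return List with `assignments` (data frame `id`, `score`, `cluster`,
#'   `is_boundary`), `density` (data frame `x`, `density`), `bandwidth`
#'   and `n_clusters`.
#' @export
kde_clusters <- function(scores, bandwidth = "auto", valley_fraction = 0.5,
                         peak_min_fraction = 0.1, grid_size = 512L,
                         boundary_tol = NULL) {
  ids <- if (is.null(names(scores))) as.character(seq_along(scores)) else names(scores)
  x <- as.numeric(scores)
  if (length(x) < 2L) stop("need >= 2 scores")
  if (diff(range(x)) == 0) {
    warning("all scores identical: single cluster")
    return(list(assignments = data.frame(id = ids, score = x, cluster = 1L,
                                         is_boundary = FALSE,
                                         stringsAsFactors = FALSE),
                density = data.frame(x = x[1L], density = Inf),
                bandwidth = 0, n_clusters = 1L))
  }
  bw <- if (identical(bandwidth, "auto")) kde_bandwidth(x) else as.numeric(bandwidth)
  stopifnot(bw > 0)
  grid <- seq(min(x) - 3 * bw, max(x) + 3 * bw, length.out = grid_size)
  dens <- .kde_eval(x, grid, bw)

  # peaks and the deepest valley between consecutive peaks
  is_peak <- c(FALSE, diff(sign(diff(dens))) < 0, FALSE)
  peaks <- which(is_peak)
  peaks <- peaks[dens[peaks] >= peak_min_fraction * max(dens)]
  if (length(peaks) == 0L) peaks <- which.max(dens)
  repeat {
    if (length(peaks) < 2L) { cuts <- numeric() ; break }
    valleys <- vapply(seq_len(length(peaks) - 1L), function(k) {
      seg <- peaks[k]:peaks[k + 1L]
      seg[which.min(dens[seg])]
    }, integer(1))
    depth_ok <- dens[valleys] < valley_fraction * pmin(dens[peaks[-length(peaks)]],
                                                       dens[peaks[-1L]])
    if (all(depth_ok)) { cuts <- grid[valleys]; break }
    # merge the pair with the shallowest valley: drop its lower peak
    k <- which.max(dens[valleys] / pmin(dens[peaks[-length(peaks)]], dens[peaks[-1L]]))
    drop <- if (dens[peaks[k]] < dens[peaks[k + 1L]]) k else k + 1L
    peaks <- peaks[-drop]
  }
  cluster <- 1L + vapply(x, function(s) sum(s > cuts), integer(1))
  # relabel contiguously in ascending score order
  cluster <- match(cluster, sort(unique(cluster)))
  if (is.null(boundary_tol)) boundary_tol <- bw / 10
  is_boundary <- if (length(cuts)) vapply(x, function(s)
    any(abs(s - cuts) <= boundary_tol), logical(1)) else rep(FALSE, length(x))
  list(assignments = data.frame(id = ids, score = x, cluster = cluster,
                                is_boundary = is_boundary,
                                stringsAsFactors = FALSE),
       density = data.frame(x = grid, density = dens),
       bandwidth = bw, n_clusters = length(unique(cluster)))
}
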