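#' Kimura protein distance between two aligned sequences
#'
#' Counts comparable positions (columns where neither row has a gap), the
#' exact matches among them, and applies the Kimura correction
#' `-ln(1 - D - 0.2 D^2)` to the mismatch fraction `D = 1 - m/npos`. The
#' result is multiplied by `scale` (default 100, the distmat convention).
#' Ambiguity codes X, B and Z never count as matches, not even to
#' themselves. The correction saturates: for `D` above the positive root of
#' `1 - D - 0.2 D^2` (about 0.8541) the distance is undefined and an error
#' is raised rather than returning NaN.
#'
#' @param row_a,row_b aligned sequences (equal-length strings from one MSA).
#' @param scale output multiplier; 100 for the distmat scale, 1 for raw.
#' @return List with `npos`, `m`, `S`, `D` and `distance`.
#' @export
kimura_distance <- function(row_a, row_b, scale = 100) {
  ca <- strsplit(toupper(row_a), "", fixed = TRUE)[[1]]
  cb <- strsplit(toupper(row_b), "", fixed = TRUE)[[1]]
  if (length(ca) != length(cb)) stop("rows differ in aligned length")
  cmp <- ca != "-" & cb != "-"
  npos <- sum(cmp)
  if (npos == 0L) stop("no comparable (gap-free) positions: distance undefined")
  ambig <- c("X", "B", "Z")
  m <- sum(cmp & ca == cb & !(ca %in% ambig))
  S <- m / npos
  D <- 1 - S
  arg <- 1 - D - 0.2 * D^2
  if (arg <= 0)
    stop(sprintf("Kimura correction saturated (D = %.4f): distance undefined", D))
  list(npos = npos, m = m, S = S, D = D, distance = -log(arg) * scale)
}

#' Pairwise Kimura distance matrices per subdomain
#'
#' Slices the alignment into the columns mapping to each subdomain interval
#' (reference numbering) and computes all pairwise Kimura distances within
#' each slice.
#'
#' @param a a [protein_msa()].
#' @param partition a [subdomain_partition()] (or any named list of
#'   reference intervals).
#' @param map [map_to_reference()] coordinate map for `a`.
#' @param scale passed to [kimura_distance()].
#' @return Named list of symmetric distance matrices (ids as dimnames), one
#'   per subdomain, each carrying `mean` and `sd` of the upper triangle as
#'   attributes.
#' @export
subdomain_matrices <- function(a, partition, map, scale = 100) {
  m <- msa_matrix(a)
  out <- list()
  for (nm in names(partition)) {
    iv <- partition[[nm]]
    cols <- map$msa_pos[map$ref_pos >= iv[1] & map$ref_pos <= iv[2]]
    if (length(cols) == 0L)
      stop("subdomain '", nm, "' maps to no alignment columns")
    rows <- apply(m[, cols, drop = FALSE], 1L, paste, collapse = "")
    dmat <- matrix(0, a$n, a$n, dimnames = list(a$ids, a$ids))
    for (i in seq_len(a$n - 1L)) for (j in (i + 1L):a$n) {
      d <- kimura_distance(rows[i], rows[j], scale = scale)$distance
      dmat[i, j] <- dmat[j, i] <- d
    }
    attr(dmat, "mean") <- mean(dmat[upper.tri(dmat)])
    attr(dmat, "sd") <- stats::sd(dmat[upper.tri(dmat)])
    out[[nm]] <- dmat
  }
  out
}

#' Correlate evolutionary distances between two subdomains
#'
#' Pairs the two matrices' upper triangles by sequence pair, fits an
#' ordinary least-squares line and reports Pearson's r; the natural
#' reference for equal per-subdomain rates is slope 1.
#'
#' @param mat_x,mat_y symmetric distance matrices over the same id set.
#' @return List with `pairs` (data frame `id_a`, `id_b`, `x`, `y`), `slope`,
#'   `intercept`, `r`.
#' @export
distance_correlation <- function(mat_x, mat_y) {
  ids <- rownames(mat_x)
  if (!setequal(ids, rownames(mat_y)))
    stop("matrices cover different id sets")
  mat_y <- mat_y[ids, ids]
  ut <- which(upper.tri(mat_x), arr.ind = TRUE)
  if (nrow(ut) < 3L) stop("need >= 3 sequence pairs for a correlation")
  pairs <- data.frame(id_a = ids[ut[, 1]], id_b = ids[ut[, 2]],
                      x = mat_x[ut], y = mat_y[ut], stringsAsFactors = FALSE)
  fit <- stats::lm(y ~ x, data = pairs)
  list(pairs = pairs,
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r = stats::cor(pairs$x, pairs$y))
}
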