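#' Welch's two-sample t-test with a degenerate-variance fast path
#'
#' Standard unequal-variance two-sided t-test via [stats::t.test()]. When
#' both samples are constant, `t.test` cannot run; identical constants give
#' `t = 0, p = 1` and different constants `t = Inf, p = 0` (an exact
#' separation).
#'
#' @param x,y numeric samples.
#' @return List with `t` and `p`.
#' @export
welch_test <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L)
    stop("need >= 2 values per sample")
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    if (mean(x) == mean(y)) return(list(t = 0, p = 1))
    return(list(t = Inf, p = 0))
  }
  ht <- stats::t.test(x, y, var.equal = FALSE)
  list(t = unname(ht$statistic), p = ht$p.value)
}

# label of the IFR containing reference position `ref`, or NA
.ifr_label_at <- function(ref, ifrs) {
  if (is.na(ref) || nrow(ifrs) == 0L) return(NA_character_)
  hit <- which(ifrs$ref_start <= ref & ifrs$ref_end >= ref)
  if (length(hit) == 0L) NA_character_ else ifrs$rank_label[hit[1L]]
}

#' Annotate interdomain contacts with alignment-derived features
#'
#' Maps each contact residue (reference numbering) onto its alignment
#' column and records IFR membership, indel-position status, conservation
#' and Wu-Kabat variability. IFR membership takes precedence: a residue
#' inside an IFR is never flagged as at an indel position (the only indels
#' an IFR may contain are fusion-waived singletons).
#'
#' @param contacts data frame with `nbd_res` and `sbd_res` columns
#'   (output of [extract_contacts()] or a curated list).
#' @param map [map_to_reference()] coordinate map.
#' @param ifrs [find_ifrs()] output.
#' @param profile [indel_probability_profile()] output.
#' @param conserved logical per-column mask from [conservation_mask()].
#' @param wu_kabat_values [wu_kabat()] output.
#' @return Data frame, one row per contact, with per-residue columns
#'   `*_msa_pos`, `*_in_ifr`, `*_at_indel`, `*_conserved`, `*_wu_kabat`.
#' @export
annotate_contacts <- function(contacts, map, ifrs, profile, conserved,
                              wu_kabat_values) {
  msa_of <- stats::setNames(map$msa_pos, map$ref_pos)
  p <- profile$indel_probability
  one <- function(ref) {
    pos <- unname(msa_of[as.character(ref)])
    if (is.na(ref) || is.na(pos)) {
      warning("contact residue ", ref, " outside reference coverage")
      return(list(msa_pos = NA_integer_, in_ifr = NA_character_,
                  at_indel = NA, conserved = NA, wk = NA_real_))
    }
    lab <- .ifr_label_at(ref, ifrs)
    list(msa_pos = pos, in_ifr = lab,
         at_indel = is.na(lab) && p[pos] > 0,
         conserved = conserved[pos],
         wk = wu_kabat_values$variability[pos])
  }
  nbd <- lapply(contacts$nbd_res, one)
  sbd <- lapply(contacts$sbd_res, one)
  out <- data.frame(
    nbd_res = contacts$nbd_res, sbd_res = contacts$sbd_res,
    nbd_msa_pos = vapply(nbd, `[[`, integer(1), "msa_pos"),
    sbd_msa_pos = vapply(sbd, `[[`, integer(1), "msa_pos"),
    nbd_in_ifr = vapply(nbd, `[[`, character(1), "in_ifr"),
    sbd_in_ifr = vapply(sbd, `[[`, character(1), "in_ifr"),
    nbd_at_indel = vapply(nbd, `[[`, logical(1), "at_indel"),
    sbd_at_indel = vapply(sbd, `[[`, logical(1), "at_indel"),
    nbd_conserved = vapply(nbd, `[[`, logical(1), "conserved"),
    sbd_conserved = vapply(sbd, `[[`, logical(1), "conserved"),
    nbd_wu_kabat = vapply(nbd, `[[`, numeric(1), "wk"),
    sbd_wu_kabat = vapply(sbd, `[[`, numeric(1), "wk"),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Summarize contact-residue enrichment against the alignment background
#'
#' Counts unique contact residues by location class (inside an IFR / at an
#' indel position / elsewhere), compares conserved fractions and mean
#' Wu-Kabat variability of contact residues against all other analyzed
#' columns of the same domain, and tests the variability difference with
#' Welch's two-sided t-test.
#'
#' @param annotations [annotate_contacts()] output.
#' @param background data frame with one row per analyzed alignment column:
#'   columns `msa_pos`, `domain` (`"NBD"`/`"SBD"`), `conserved` (logical),
#'   `wu_kabat` (numeric). Contact columns are excluded from the background
#'   side of the comparisons.
#' @return List with `counts` (n_in_ifr, n_at_indel, n_elsewhere,
#'   n_residues) and `by_domain`, a data frame per domain with conserved
#'   fractions, mean variabilities and the Welch statistic/p-value.
#' @export
enrichment_summary <- function(annotations, background) {
  res <- rbind(
    data.frame(domain = "NBD", res = annotations$nbd_res,
               msa_pos = annotations$nbd_msa_pos,
               in_ifr = annotations$nbd_in_ifr,
               at_indel = annotations$nbd_at_indel,
               conserved = annotations$nbd_conserved,
               wu_kabat = annotations$nbd_wu_kabat,
               stringsAsFactors = FALSE),
    data.frame(domain = "SBD", res = annotations$sbd_res,
               msa_pos = annotations$sbd_msa_pos,
               in_ifr = annotations$sbd_in_ifr,
               at_indel = annotations$sbd_at_indel,
               conserved = annotations$sbd_conserved,
               wu_kabat = annotations$sbd_wu_kabat,
               stringsAsFactors = FALSE))
  res <- res[!duplicated(res[, c("domain", "res")]), , drop = FALSE]
  counts <- list(n_in_ifr = sum(!is.na(res$in_ifr)),
                 n_at_indel = sum(is.na(res$in_ifr) & res$at_indel %in% TRUE),
                 n_residues = nrow(res))
  counts$n_elsewhere <- counts$n_residues - counts$n_in_ifr - counts$n_at_indel
  by_domain <- lapply(c("NBD", "SBD"), function(dom) {
    cres <- res[res$domain == dom, , drop = FALSE]
    bg <- background[background$domain == dom &
                       !(background$msa_pos %in% cres$msa_pos), , drop = FALSE]
    if (nrow(cres) < 2L)
      stop("need >= 2 contact residues in ", dom, " for the Welch test")
    wt <- welch_test(cres$wu_kabat[!is.na(cres$wu_kabat)],
                     bg$wu_kabat[!is.na(bg$wu_kabat)])
    data.frame(domain = dom,
               conserved_fraction_contacts = mean(cres$conserved, na.rm = TRUE),
               conserved_fraction_background = mean(bg$conserved, na.rm = TRUE),
               wu_kabat_mean_contacts = mean(cres$wu_kabat, na.rm = TRUE),
               wu_kabat_mean_background = mean(bg$wu_kabat, na.rm = TRUE),
               welch_t = wt$t, welch_p = wt$p,
               stringsAsFactors = FALSE)
  })
  list(counts = counts, by_domain = do.call(rbind, by_domain))
}
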