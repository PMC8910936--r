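#' Describe a synthetic-alignment scenario
#'
#' Defines a star-phylogeny simulation: an ancestor of `reference_length`
#' residues and `n_sequences - 1` descendants mutated independently with
#' region-specific substitution and indel rates. Regions with
#' `indel_rate = 0` are planted indel-free regions. Indel lengths are
#' geometric with the given mean; an event is an insertion with probability
#' `insertion_prob`, a deletion otherwise.
#'
#' @param n_sequences total rows including the unmutated reference row
#'   `"REF"`; default 20.
#' @param reference_length ancestor length in residues.
#' @param regions data frame with columns `start`, `end` (inclusive,
#'   tiling 1..reference_length), `substitution_rate`, `indel_rate`
#'   (per site), `mean_indel_length` (residues).
#' @param seed integer RNG seed.
#' @param insertion_prob probability an indel event is an insertion.
#' @param length_mixture optional data frame `length`, `prob` of point
#'   masses mixed into the geometric length law (to mimic empirical length
#'   spectra with secondary modes); remaining mass stays geometric.
#' @return An `alignment_scenario` list.
#' @export
alignment_scenario <- function(n_sequences = 20L, reference_length = 200L,
                               regions, seed = 1L, insertion_prob = 0.5,
                               length_mixture = NULL) {
  stopifnot(n_sequences >= 2L, reference_length >= 1L)
  regions <- regions[order(regions$start), , drop = FALSE]
  if (regions$start[1] != 1L || regions$end[nrow(regions)] != reference_length ||
      (nrow(regions) > 1L && any(regions$start[-1] != regions$end[-nrow(regions)] + 1L)))
    stop("regions must tile 1..reference_length")
  if (any(regions$substitution_rate < 0) || any(regions$indel_rate < 0))
    stop("rates must be >= 0")
  if (any(regions$indel_rate * regions$mean_indel_length > 0.9))
    stop("scenario refused: expected gap content exceeds 90% in some region")
  structure(list(n_sequences = as.integer(n_sequences),
                 reference_length = as.integer(reference_length),
                 regions = regions, seed = as.integer(seed),
                 insertion_prob = insertion_prob,
                 length_mixture = length_mixture),
            class = "alignment_scenario")
}

.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

.sample_indel_length <- function(scenario, mean_len) {
  mix <- scenario$length_mixture
  if (!is.null(mix) && stats::runif(1) < sum(mix$prob))
    return(as.integer(sample(mix$length, 1L, prob = mix$prob)))
  1L + stats::rgeom(1L, 1 / mean_len)
}

#' Simulate a gapped alignment with planted indels and IFRs
#'
#' Draws a uniform-random ancestor, mutates each descendant independently
#' (substitutions per region rate; indel events started per site at the
#' region indel rate, geometric lengths), and renders all rows against a
#' single shared coordinate system: one column per reference position plus
#' an insertion slot after each position sized to the longest insertion
#' anchored there. Because no re-alignment is performed, the returned truth
#' tables are exact. Deletions are truncated at the boundary of the region
#' they start in, so zero-indel-rate regions are indel-free by construction.
#'
#' @param scenario an [alignment_scenario()].
#' @return List with `alignment` (a [protein_msa()], first row `"REF"` is
#'   the ungapped ancestor), and `truth`: `events` (per-sequence realized
#'   indels, reference coordinates), `ifrs` (maximal zero-indel runs,
#'   reference coordinates, no fusion applied), `conserved` (per-column
#'   strict-identity flags) and `ref_of_col`/`col_of_ref` coordinate
#'   vectors.
#' @export
simulate_alignment <- function(scenario) {
  stopifnot(inherits(scenario, "alignment_scenario"))
  set.seed(scenario$seed)
  L <- scenario$reference_length
  n_desc <- scenario$n_sequences - 1L
  site_region <- integer(L)
  for (k in seq_len(nrow(scenario$regions)))
    site_region[scenario$regions$start[k]:scenario$regions$end[k]] <- k
  sub_rate <- scenario$regions$substitution_rate[site_region]
  indel_rate <- scenario$regions$indel_rate[site_region]
  mean_len <- scenario$regions$mean_indel_length[site_region]

  ancestor <- sample(.AA20, L, replace = TRUE)
  rows <- vector("list", n_desc)
  events <- vector("list", n_desc)
  for (i in seq_len(n_desc)) {
    seqch <- ancestor
    mut <- which(stats::runif(L) < sub_rate)
    for (s in mut) seqch[s] <- sample(setdiff(.AA20, seqch[s]), 1L)
    deleted <- rep(FALSE, L)
    ins <- list()  # anchor (after position) -> residue string
    ev <- list()
    start_ev <- which(stats::runif(L) < indel_rate)
    is_ins <- stats::runif(length(start_ev)) < scenario$insertion_prob
    lens <- vapply(start_ev, function(s)
      .sample_indel_length(scenario, mean_len[s]), integer(1))
    for (k in which(!is_ins)) {
      # deletions stay inside their region of origin so that zero-rate
      # regions are indel-free by construction
      s <- start_ev[k]
      region_end <- scenario$regions$end[site_region[s]]
      deleted[s:min(region_end, s + lens[k] - 1L)] <- TRUE
    }
    for (k in which(is_ins)) {
      s <- start_ev[k]
      # an insertion anchored strictly inside a deletion run of the same
      # sequence would split the rendered run in two; drop it so truth
      # tables stay exact
      if (deleted[s] && s < L && deleted[s + 1L]) next
      key <- as.character(s)
      if (is.null(ins[[key]])) {  # at most one insertion per anchor
        ins[[key]] <- paste(sample(.AA20, lens[k], replace = TRUE), collapse = "")
        ev[[length(ev) + 1L]] <- data.frame(kind = "insertion", anchor = s,
                                            ref_start = NA_integer_,
                                            ref_end = NA_integer_,
                                            length = lens[k])
      }
    }
    # realized (coalesced) deletion runs
    if (any(deleted)) {
      r <- rle(deleted)
      e2 <- cumsum(r$lengths); s2 <- c(1L, utils::head(e2, -1L) + 1L)
      for (k in which(r$values))
        ev[[length(ev) + 1L]] <- data.frame(kind = "deletion", anchor = NA_integer_,
                                            ref_start = s2[k], ref_end = e2[k],
                                            length = e2[k] - s2[k] + 1L)
    }
    seqch[deleted] <- "-"
    rows[[i]] <- list(seq = seqch, ins = ins)
    if (length(ev))
      events[[i]] <- cbind(sequence_id = sprintf("seq%03d", i),
                           do.call(rbind, ev), stringsAsFactors = FALSE)
  }

  # render: slot widths per anchor
  slot <- integer(L + 1L)  # index a+1 = anchor after position a (0..L)
  for (i in seq_len(n_desc)) for (key in names(rows[[i]]$ins))
    slot[as.integer(key) + 1L] <- max(slot[as.integer(key) + 1L],
                                      nchar(rows[[i]]$ins[[key]]))
  width <- L + sum(slot)
  col_of_ref <- integer(L)
  pos <- slot[1L]
  for (s in seq_len(L)) { pos <- pos + 1L; col_of_ref[s] <- pos; pos <- pos + slot[s + 1L] }
  render <- function(seqch, ins) {
    out <- rep("-", width)
    out[col_of_ref] <- seqch
    for (key in names(ins)) {
      a <- as.integer(key)
      base <- if (a == 0L) 0L else col_of_ref[a]
      chs <- strsplit(ins[[key]], "")[[1]]
      out[base + seq_along(chs)] <- chs
    }
    paste(out, collapse = "")
  }
  seqs <- c(render(ancestor, list()),
            vapply(seq_len(n_desc), function(i)
              render(rows[[i]]$seq, rows[[i]]$ins), character(1)))
  ids <- c("REF", sprintf("seq%03d", seq_len(n_desc)))
  aln <- protein_msa(ids, seqs)

  events <- do.call(rbind, events[!vapply(events, is.null, logical(1))])
  if (is.null(events))
    events <- data.frame(sequence_id = character(), kind = character(),
                         anchor = integer(), ref_start = integer(),
                         ref_end = integer(), length = integer(),
                         stringsAsFactors = FALSE)
  rownames(events) <- NULL

  # truth IFRs: reference positions hit by no deletion, boundaries by no insertion
  dirty_pos <- rep(FALSE, L)
  for (k in which(events$kind == "deletion"))
    dirty_pos[events$ref_start[k]:events$ref_end[k]] <- TRUE
  dirty_anchor <- rep(FALSE, L + 1L)
  dirty_anchor[events$anchor[events$kind == "insertion"] + 1L] <- TRUE
  ifr <- list(); r <- 1L
  while (r <= L) {
    if (dirty_pos[r]) { r <- r + 1L; next }
    s <- r
    while (r < L && !dirty_pos[r + 1L] && !dirty_anchor[r + 1L]) r <- r + 1L
    ifr[[length(ifr) + 1L]] <- c(s, r)
    r <- r + 1L
  }
  ifrs <- if (length(ifr))
    data.frame(ref_start = vapply(ifr, `[`, 1L, i = 1L),
               ref_end = vapply(ifr, `[`, 1L, i = 2L))
  else data.frame(ref_start = integer(), ref_end = integer())

  mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  conserved <- apply(mat, 2L, function(col) {
    col <- col[col != "-"]
    length(col) > 0L && length(unique(col)) == 1L
  })
  list(alignment = aln,
       truth = list(events = events, ifrs = ifrs, conserved = conserved,
                    col_of_ref = col_of_ref))
}

#' Describe a synthetic two-conformation structure scenario
#'
#' Bead models of an NBD (residues numbered from 1) and an SBD (numbered
#' from the SBD start of `partition`). `contacts` are planted interdomain
#' pairs hitting their target open/closed distances exactly; `decoys` are
#' pairs constructed to violate exactly one of the two contact conditions.
#' A residue may appear in at most one pair so all targets are
#' simultaneously satisfiable.
#'
#' @param n_nbd,n_sbd beads per domain.
#' @param contacts,decoys data frames with `nbd_res`, `sbd_res`, `d_open`,
#'   `d_closed` (Angstrom).
#' @param partition a [subdomain_partition()].
#' @param contact_threshold,diff_threshold the extraction thresholds the
#'   planted pairs are checked against.
#' @param seed RNG seed (bead amino-acid identities).
#' @return A `structure_scenario` list.
#' @export
structure_scenario <- function(n_nbd = 20L, n_sbd = 20L,
                               contacts,
                               decoys = NULL,
                               partition = subdomain_partition(),
                               contact_threshold = 7, diff_threshold = 2,
                               seed = 1L) {
  empty <- data.frame(nbd_res = integer(), sbd_res = integer(),
                      d_open = numeric(), d_closed = numeric())
  if (is.null(decoys)) decoys <- empty
  if (missing(contacts) || is.null(contacts)) contacts <- empty
  all_pairs <- rbind(contacts, decoys)
  if (any(all_pairs$d_open <= 0) || any(all_pairs$d_closed <= 0))
    stop("scenario infeasible: distance targets must be positive")
  if (anyDuplicated(c(all_pairs$nbd_res)) || anyDuplicated(all_pairs$sbd_res))
    stop("scenario infeasible: a residue may appear in at most one pair")
  ok_open <- contacts$d_open < contact_threshold
  ok_diff <- abs(contacts$d_closed - contacts$d_open) > diff_threshold
  if (!all(ok_open & ok_diff))
    stop("planted contacts must satisfy both thresholds")
  d_ok_open <- decoys$d_open < contact_threshold
  d_ok_diff <- abs(decoys$d_closed - decoys$d_open) > diff_threshold
  if (!all(xor(d_ok_open, d_ok_diff)))
    stop("decoys must violate exactly one threshold")
  nbd_res <- seq_len(n_nbd)
  sbd_res <- partition$SBD[1] + seq_len(n_sbd) - 1L
  if (!all(all_pairs$nbd_res %in% nbd_res) || !all(all_pairs$sbd_res %in% sbd_res))
    stop("pair residues must lie within the generated bead ranges")
  structure(list(n_nbd = n_nbd, n_sbd = n_sbd, contacts = contacts,
                 decoys = decoys, partition = partition, seed = seed),
            class = "structure_scenario")
}

#' Simulate an open/closed bead-structure pair with planted contacts
#'
#' Each planted or decoy pair occupies an isolated spatial slot (slots 60 A
#' apart) with the SBD bead placed at the target open/closed distance from
#' its fixed NBD partner, so targets are hit exactly and no accidental
#' interdomain contacts arise; unpaired beads sit far from everything.
#'
#' @param scenario a [structure_scenario()].
#' @return List with `open` and `closed` `structure_model`s and `truth`
#'   (the planted contact data frame).
#' @export
simulate_structure_pair <- function(scenario) {
  stopifnot(inherits(scenario, "structure_scenario"))
  set.seed(scenario$seed)
  nbd_res <- seq_len(scenario$n_nbd)
  sbd_res <- scenario$partition$SBD[1] + seq_len(scenario$n_sbd) - 1L
  aa <- stats::setNames(sample(.AA20, length(c(nbd_res, sbd_res)), replace = TRUE),
                        c(nbd_res, sbd_res))
  pairs <- rbind(scenario$contacts, scenario$decoys)
  coord <- function(closed = FALSE) {
    xyz <- matrix(NA_real_, length(c(nbd_res, sbd_res)), 3L,
                  dimnames = list(c(nbd_res, sbd_res), NULL))
    if (nrow(pairs) > 0L) for (k in seq_len(nrow(pairs))) {
      base <- c(0, 60 * k, 0)
      d <- if (closed) pairs$d_closed[k] else pairs$d_open[k]
      xyz[as.character(pairs$nbd_res[k]), ] <- base
      xyz[as.character(pairs$sbd_res[k]), ] <- base + c(d, 0, 0)
    }
    free_n <- setdiff(nbd_res, pairs$nbd_res)
    free_s <- setdiff(sbd_res, pairs$sbd_res)
    for (j in seq_along(free_n)) xyz[as.character(free_n[j]), ] <- c(500 + 60 * j, 0, 0)
    for (j in seq_along(free_s)) xyz[as.character(free_s[j]), ] <- c(500 + 60 * j, 3000, 0)
    xyz
  }
  mk <- function(xyz, label) {
    res <- as.integer(rownames(xyz))
    structure_model(data.frame(resno = res, aa = unname(aa[rownames(xyz)]),
                               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                               stringsAsFactors = FALSE), label)
  }
  truth <- scenario$contacts
  if (nrow(truth) > 0L) {
    truth$nbd_aa <- unname(aa[as.character(truth$nbd_res)])
    truth$sbd_aa <- unname(aa[as.character(truth$sbd_res)])
    truth <- truth[order(truth$nbd_res, truth$sbd_res), , drop = FALSE]
    rownames(truth) <- NULL
  }
  list(open = mk(coord(FALSE), "open"), closed = mk(coord(TRUE), "closed"),
       truth = truth)
}

#' Write a structure model as a minimal PDB file
#'
#' One Calpha ATOM record per residue (chain A, occupancy 1), via
#' [bio3d::write.pdb()].
#'
#' @param model a `structure_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(model, path) {
  n <- nrow(model)
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(model[, c("x", "y", "z")]))),
                   resno = model$resno,
                   resid = bio3d::aa123(model$aa),
                   eleno = seq_len(n),
                   elety = rep("CA", n),
                   chain = rep("A", n),
                   o = rep(1, n), b = rep(0, n))
  invisible(path)
}
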