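#' Define a subdomain partition of a two-domain chaperone
#'
#' Hsp70/DnaK splits into a nucleotide-binding domain (NBD) and a
#' substrate-binding domain (SBD); the NBD further splits into lobe I and
#' lobe II, the SBD into a beta-sandwich core (betaSBD) and the helical lid
#' (alphaSBD). Intervals are inclusive and given in reference (E. coli DnaK)
#' residue numbering. Defaults follow the standard DnaK domain boundaries,
#' with the disordered C-terminal tail (residue 604+) excluded.
#'
#' @param NBD,SBD integer length-2 vectors, inclusive residue intervals.
#' @param lobe_I,lobe_II intervals tiling the NBD.
#' @param betaSBD,alphaSBD intervals tiling the SBD.
#' @return An object of class `subdomain_partition`: a named list of
#'   integer intervals.
#' @examples
#' part <- subdomain_partition()
#' part$NBD
#' @export
subdomain_partition <- function(NBD = c(1L, 398L), SBD = c(399L, 603L),
                                lobe_I = c(1L, 183L), lobe_II = c(184L, 398L),
                                betaSBD = c(399L, 507L), alphaSBD = c(508L, 603L)) {
  part <- lapply(list(NBD = NBD, SBD = SBD, lobe_I = lobe_I, lobe_II = lobe_II,
                      betaSBD = betaSBD, alphaSBD = alphaSBD),
                 function(x) as.integer(x))
  for (nm in names(part)) {
    iv <- part[[nm]]
    if (length(iv) != 2L || iv[1] > iv[2])
      stop("interval '", nm, "' must be c(start, end) with start <= end")
  }
  if (part$NBD[2] >= part$SBD[1])
    stop("NBD and SBD intervals must be disjoint (NBD before SBD)")
  if (part$lobe_I[1] != part$NBD[1] || part$lobe_II[2] != part$NBD[2] ||
      part$lobe_II[1] != part$lobe_I[2] + 1L)
    stop("lobe_I and lobe_II must tile the NBD")
  if (part$betaSBD[1] != part$SBD[1] || part$alphaSBD[2] != part$SBD[2] ||
      part$alphaSBD[1] != part$betaSBD[2] + 1L)
    stop("betaSBD and alphaSBD must tile the SBD")
  structure(part, class = "subdomain_partition")
}

#' Read the Calpha trace of one chain of a PDB file
#'
#' Parses standard PDB text via [bio3d::read.pdb()], keeps ATOM records of
#' the requested chain, resolves alternate locations to the highest-occupancy
#' copy (ties broken by altloc identifier order), and returns one record per
#' residue that carries a Calpha atom. Residues lacking a Calpha are skipped
#' with a warning.
#'
#' @param pdb_path path to a PDB file.
#' @param chain_id one-letter chain identifier.
#' @param conformation_label `"open"` or `"closed"` (free-form allowed).
#' @return A `structure_model`: data frame with columns `resno`, `aa`
#'   (one-letter code), `x`, `y`, `z`, ordered by increasing residue number,
#'   with attribute `conformation`.
#' @export
read_structure <- function(pdb_path, chain_id, conformation_label = "open") {
  pdb <- bio3d::read.pdb(pdb_path, rm.alt = FALSE, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM" & at$chain %in% chain_id, , drop = FALSE]
  if (nrow(at) == 0L)
    stop("chain '", chain_id, "' not found in ", pdb_path)
  resnos <- sort(unique(at$resno))
  ca <- at[at$elety == "CA", , drop = FALSE]
  if (nrow(ca) == 0L)
    stop("no Calpha atoms in chain '", chain_id, "' of ", pdb_path)
  # altloc: keep the highest-occupancy copy per residue; ties by altloc order
  if (anyDuplicated(ca$resno)) {
    occ <- ifelse(is.na(ca$o), 1, ca$o)
    alt <- ifelse(is.na(ca$alt) | ca$alt == "", " ", ca$alt)
    ord <- order(ca$resno, -occ, alt)
    ca <- ca[ord, , drop = FALSE]
    ca <- ca[!duplicated(ca$resno), , drop = FALSE]
  }
  missing_ca <- setdiff(resnos, ca$resno)
  if (length(missing_ca) > 0L)
    warning(length(missing_ca), " residue(s) without a Calpha skipped: ",
            paste(utils::head(missing_ca, 5L), collapse = ", "),
            if (length(missing_ca) > 5L) ", ..." else "")
  ca <- ca[order(ca$resno), , drop = FALSE]
  model <- data.frame(resno = as.integer(ca$resno),
                      aa = unname(bio3d::aa321(ca$resid)),
                      x = ca$x, y = ca$y, z = ca$z,
                      stringsAsFactors = FALSE)
  structure_model(model, conformation_label)
}

#' Construct a structure model from a residue table
#'
#' @param residues data frame with columns `resno`, `aa`, `x`, `y`, `z`.
#' @param conformation_label free-form conformation tag.
#' @return A `structure_model` (see [read_structure()]).
#' @export
structure_model <- function(residues, conformation_label = "open") {
  stopifnot(all(c("resno", "aa", "x", "y", "z") %in% names(residues)))
  if (nrow(residues) == 0L) stop("structure model must contain >= 1 residue")
  if (anyDuplicated(residues$resno))
    stop("duplicated residue numbers in structure model")
  residues <- residues[order(residues$resno), , drop = FALSE]
  rownames(residues) <- NULL
  attr(residues, "conformation") <- conformation_label
  class(residues) <- c("structure_model", "data.frame")
  residues
}

#' All-against-all Calpha-Calpha distance matrix
#'
#' @param model a `structure_model`.
#' @return Symmetric numeric matrix (Angstrom) with residue numbers as
#'   dimnames; zero diagonal.
#' @export
ca_distance_matrix <- function(model) {
  xyz <- as.matrix(model[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  dimnames(d) <- list(model$resno, model$resno)
  d
}

#' Mean of a distance or difference matrix over unique residue pairs
#'
#' Means exclude the diagonal. With `block = c("A", "B")` and A != B the mean
#' runs over the full A x B rectangle; with A == B (or a single name) over the
#' unique off-diagonal pairs within that subdomain.
#'
#' @param mat symmetric matrix with residue-number dimnames.
#' @param partition a [subdomain_partition()] (required when `block` given).
#' @param block optional character vector of one or two subdomain names.
#' @return Mean distance in Angstrom.
#' @export
matrix_mean <- function(mat, partition = NULL, block = NULL) {
  res <- as.integer(rownames(mat))
  if (is.null(block)) {
    return(mean(mat[upper.tri(mat)]))
  }
  if (is.null(partition)) stop("'partition' required when 'block' is given")
  if (length(block) == 1L) block <- c(block, block)
  iv <- lapply(block, function(b) {
    if (is.null(partition[[b]])) stop("unknown subdomain '", b, "'")
    partition[[b]]
  })
  sel1 <- res >= iv[[1]][1] & res <= iv[[1]][2]
  sel2 <- res >= iv[[2]][1] & res <= iv[[2]][2]
  if (!any(sel1) || !any(sel2))
    stop("subdomain block '", paste(block, collapse = " x "),
         "' contains no residues of this matrix")
  sub <- mat[sel1, sel2, drop = FALSE]
  if (identical(iv[[1]], iv[[2]])) mean(sub[upper.tri(sub)]) else mean(sub)
}

#' Absolute Calpha-Calpha distance difference map between two conformations
#'
#' Restricted to residue numbers present in both models; entries are
#' `|d_closed - d_open|`.
#'
#' @param open_model,closed_model `structure_model`s of the same protein.
#' @return Symmetric nonnegative matrix with shared residue numbers as
#'   dimnames.
#' @export
difference_map <- function(open_model, closed_model) {
  shared <- intersect(open_model$resno, closed_model$resno)
  if (length(shared) < 2L)
    stop("need >= 2 residues shared between the two conformations")
  d_open <- ca_distance_matrix(open_model[open_model$resno %in% shared, ])
  d_closed <- ca_distance_matrix(closed_model[closed_model$resno %in% shared, ])
  abs(d_closed - d_open)
}

#' Per-residue maximum distance shift
#'
#' Row-wise maxima of a difference map; the pair attaining the global
#' maximum is attached as attribute `max_pair` (residue numbers) together
#' with `max_value`.
#'
#' @param diff a [difference_map()] matrix.
#' @return Named numeric vector (names = residue numbers) of row maxima.
#' @export
max_shift_per_residue <- function(diff) {
  mx <- apply(diff, 1L, max)
  ij <- which(diff == max(diff), arr.ind = TRUE)[1L, ]
  pair <- sort(as.integer(c(rownames(diff)[ij[1]], colnames(diff)[ij[2]])))
  structure(mx, max_pair = pair, max_value = max(diff))
}

#' Residue pairs whose Calpha distance barely changes between conformations
#'
#' @param diff a [difference_map()] matrix.
#' @param tolerance maximum allowed absolute change (Angstrom); default 0.01.
#' @return Data frame `res_i`, `res_j`, `delta` (res_i < res_j), sorted by
#'   ascending delta.
#' @export
invariant_pairs <- function(diff, tolerance = 0.01) {
  stopifnot(tolerance >= 0)
  ut <- upper.tri(diff)
  idx <- which(ut & diff <= tolerance, arr.ind = TRUE)
  out <- data.frame(res_i = as.integer(rownames(diff)[idx[, 1]]),
                    res_j = as.integer(colnames(diff)[idx[, 2]]),
                    delta = diff[idx])
  out[order(out$delta, out$res_i, out$res_j), , drop = FALSE]
}

#' Extract ATP-specific interdomain contacts between two conformations
#'
#' A contact is an NBD x SBD residue pair whose open-form Calpha-Calpha
#' distance is strictly below `contact_threshold` (7 Angstrom by default) and
#' whose distance changes by strictly more than `diff_threshold` (2 Angstrom)
#' between the open and closed forms. The pre-filter list (distance condition
#' only) is attached as attribute `prefilter`.
#'
#' @param open_model,closed_model `structure_model`s.
#' @param partition a [subdomain_partition()].
#' @param contact_threshold open-form distance cutoff, Angstrom (strict `<`).
#' @param diff_threshold conformational-change cutoff, Angstrom (strict `>`).
#' @return Data frame of contacts (`nbd_res`, `nbd_aa`, `sbd_res`, `sbd_aa`,
#'   `d_open`, `d_closed`, `delta`) sorted by NBD then SBD residue, with the
#'   pre-filter data frame as attribute `prefilter`.
#' @export
extract_contacts <- function(open_model, closed_model, partition = subdomain_partition(),
                             contact_threshold = 7, diff_threshold = 2) {
  if (is.null(partition$NBD) || is.null(partition$SBD))
    stop("partition must define NBD and SBD")
  shared <- intersect(open_model$resno, closed_model$resno)
  if (length(shared) < 2L) stop("need >= 2 shared residues")
  om <- open_model[open_model$resno %in% shared, ]
  cm <- closed_model[closed_model$resno %in% shared, ]
  d_open <- ca_distance_matrix(om)
  d_closed <- ca_distance_matrix(cm)
  res <- as.integer(rownames(d_open))
  in_nbd <- res >= partition$NBD[1] & res <= partition$NBD[2]
  in_sbd <- res >= partition$SBD[1] & res <= partition$SBD[2]
  idx <- which(outer(in_nbd, in_sbd, "&") & d_open < contact_threshold,
               arr.ind = TRUE)
  aa_of <- stats::setNames(om$aa, om$resno)
  pre <- data.frame(nbd_res = res[idx[, 1]],
                    nbd_aa = unname(aa_of[as.character(res[idx[, 1]])]),
                    sbd_res = res[idx[, 2]],
                    sbd_aa = unname(aa_of[as.character(res[idx[, 2]])]),
                    d_open = d_open[idx],
                    d_closed = d_closed[idx],
                    stringsAsFactors = FALSE)
  pre$delta <- abs(pre$d_closed - pre$d_open)
  pre <- pre[!duplicated(pre[, c("nbd_res", "sbd_res")]), , drop = FALSE]
  pre <- pre[order(pre$nbd_res, pre$sbd_res), , drop = FALSE]
  rownames(pre) <- NULL
  keep <- pre[pre$delta > diff_threshold, , drop = FALSE]
  rownames(keep) <- NULL
  attr(keep, "prefilter") <- pre
  keep
}
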