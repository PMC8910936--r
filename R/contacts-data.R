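#' Curated ATP-specific interdomain contact list for E. coli DnaK
#'
#' The published set of 31 NBD-SBD contact pairs of E. coli DnaK (open
#' 4B9Q vs closed 2KHO conformations; Calpha-Calpha distance < 7 Angstrom
#' in the open form, change > 2 Angstrom between forms), with their
#' kernel-density cluster labels and per-residue conservation flags,
#' shipped as a plain-text table under `extdata`.
#'
#' @return Data frame with columns `cluster`, `nbd_res`, `nbd_aa`,
#'   `sbd_res`, `sbd_aa`, `nbd_conserved`, `sbd_conserved`.
#' @export
dnak_contact_clusters <- function() {
  path <- system.file("extdata", "dnak_interdomain_contacts.tsv",
                      package = "hsp70ifr", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Count contacts and unique residues per domain in a contact list
#'
#' @param contacts data frame with `nbd_res` and `sbd_res` columns.
#' @param partition a [subdomain_partition()] used to sanity-check domain
#'   membership of the residues.
#' @return List with `n_contacts`, `n_residues` (unique over both domains),
#'   `n_nbd_residues`, `n_sbd_residues`.
#' @export
contact_residue_counts <- function(contacts, partition = subdomain_partition()) {
  nbd <- unique(contacts$nbd_res)
  sbd <- unique(contacts$sbd_res)
  if (!all(nbd >= partition$NBD[1] & nbd <= partition$NBD[2]))
    stop("NBD residue(s) outside the NBD interval")
  if (!all(sbd >= partition$SBD[1] & sbd <= partition$SBD[2]))
    stop("SBD residue(s) outside the SBD interval")
  list(n_contacts = nrow(unique(contacts[, c("nbd_res", "sbd_res")])),
       n_residues = length(nbd) + length(sbd),
       n_nbd_residues = length(nbd),
       n_sbd_residues = length(sbd))
}

#' Locate the two reference DnaK structure files, if present
#'
#' The full structural reproduction (distance-map summaries, contact
#' extraction, PC1/KDE clustering) needs the open (4B9Q) and closed (2KHO)
#' PDB files, which are not distributed with the package. Drop them as
#' `4B9Q.pdb` and `2KHO.pdb` into the directory returned by
#' `system.file("extdata", "pdb", package = "hsp70ifr")` (or pass
#' `dir` explicitly) and the structure-dependent checks become runnable.
#'
#' @param dir directory to look in; defaults to the package `extdata/pdb`.
#' @return Named character vector `c(open = ..., closed = ...)`; entries are
#'   `NA` when a file is absent.
#' @export
dnak_structure_paths <- function(dir = system.file("extdata", "pdb",
                                                   package = "hsp70ifr")) {
  p <- c(open = file.path(dir, "4B9Q.pdb"), closed = file.path(dir, "2KHO.pdb"))
  ifelse(file.exists(p), p, NA_character_)
}
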