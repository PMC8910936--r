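#' Construct a protein multiple sequence alignment object
#'
#' @param ids character vector of unique sequence identifiers.
#' @param seqs character vector of aligned sequences (equal length,
#'   amino acids plus gap `-`; `.` and `~` are normalised to `-`,
#'   lower case to upper case).
#' @return A `protein_msa`: list with `ids`, `seqs`, `n` (rows) and
#'   `width` (columns).
#' @export
protein_msa <- function(ids, seqs) {
  ids <- as.character(ids)
  seqs <- toupper(as.character(seqs))
  seqs <- gsub("[.~]", "-", seqs)
  if (length(ids) != length(seqs)) stop("ids and seqs differ in length")
  if (length(ids) < 2L) stop("alignment needs >= 2 sequences")
  if (anyDuplicated(ids)) stop("duplicate sequence ids")
  w <- unique(nchar(seqs))
  if (length(w) != 1L) stop("ragged alignment: rows differ in length")
  structure(list(ids = ids, seqs = seqs, n = length(ids), width = w),
            class = "protein_msa")
}

#' @export
print.protein_msa <- function(x, ...) {
  cat("protein_msa:", x$n, "sequences x", x$width, "columns\n")
  invisible(x)
}

#' Read an aligned FASTA or Clustal file
#'
#' Thin wrapper over [seqinr::read.alignment()] that validates the result
#' (equal row lengths, unique ids).
#'
#' @param path file path.
#' @param format `"fasta"` or `"clustal"`.
#' @return A [protein_msa()].
#' @export
read_alignment <- function(path, format = c("fasta", "clustal")) {
  format <- match.arg(format)
  aln <- seqinr::read.alignment(path, format = format)
  protein_msa(aln$nam, unlist(aln$seq, use.names = FALSE))
}

# character matrix view (rows = sequences, columns = alignment positions)
msa_matrix <- function(a) {
  m <- do.call(rbind, strsplit(a$seqs, "", fixed = TRUE))
  rownames(m) <- a$ids
  m
}

#' Per-column gap statistics and indel-class assignment
#'
#' A column is classed `insertion` when its gap fraction exceeds 0.5 (most
#' sequences lack a residue there, so the residues present are inserts),
#' `deletion_site` when it has gaps in at most half of the sequences, and
#' `ungapped` otherwise. The consensus is the most frequent character
#' including the gap, ties broken by lexicographic order.
#'
#' @param a a [protein_msa()].
#' @return Data frame with `msa_pos`, `gap_count`, `gap_fraction`,
#'   `consensus`, `column_class`.
#' @export
column_profiles <- function(a) {
  m <- msa_matrix(a)
  gap_count <- colSums(m == "-")
  gap_fraction <- gap_count / a$n
  consensus <- apply(m, 2L, function(col) {
    tab <- table(col)
    names(tab)[which.max(tab)]  # which.max takes the first = lexicographic min
  })
  cls <- ifelse(gap_fraction > 0.5, "insertion",
                ifelse(gap_fraction > 0, "deletion_site", "ungapped"))
  data.frame(msa_pos = seq_len(a$width), gap_count = as.integer(gap_count),
             gap_fraction = unname(gap_fraction), consensus = unname(consensus),
             column_class = cls, stringsAsFactors = FALSE)
}

#' Call per-sequence indel events from an alignment
#'
#' Insertions are maximal runs of residues a sequence carries in
#' insertion-class columns; deletions are maximal runs of gaps in
#' non-insertion columns. A gap in an insertion column carries no signal for
#' that sequence and does not interrupt a deletion run.
#'
#' @param a a [protein_msa()].
#' @param profiles optional precomputed [column_profiles()].
#' @return Data frame `sequence_id`, `kind` (`insertion`/`deletion`),
#'   `msa_start`, `msa_end`, `length` (residues, i.e. informative columns
#'   of the run).
#' @export
call_indel_events <- function(a, profiles = column_profiles(a)) {
  m <- msa_matrix(a)
  ins_col <- profiles$column_class == "insertion"
  out <- vector("list", a$n)
  for (i in seq_len(a$n)) {
    row <- m[i, ]
    gap <- row == "-"
    # state per column: I = inserted residue, D = deleted residue,
    # M = aligned residue, S = silent (gap in an insertion column)
    state <- ifelse(ins_col, ifelse(gap, "S", "I"), ifelse(gap, "D", "M"))
    vis <- which(state != "S")
    if (length(vis) == 0L) next
    r <- rle(state[vis])
    ends <- cumsum(r$lengths)
    starts <- c(1L, utils::head(ends, -1L) + 1L)
    keep <- r$values %in% c("I", "D")
    if (!any(keep)) next
    out[[i]] <- data.frame(
      sequence_id = a$ids[i],
      kind = ifelse(r$values[keep] == "I", "insertion", "deletion"),
      msa_start = vis[starts[keep]],
      msa_end = vis[ends[keep]],
      length = r$lengths[keep],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(sequence_id = character(), kind = character(),
                      msa_start = integer(), msa_end = integer(),
                      length = integer(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Per-position indel probability profile
#'
#' For each alignment column, the fraction of sequences carrying an indel
#' event whose run covers that column. Optionally projected onto reference
#' coordinates.
#'
#' @param events output of [call_indel_events()].
#' @param a the [protein_msa()] the events came from.
#' @param map optional [map_to_reference()] coordinate map; when given, the
#'   reference projection is attached as attribute `ref_profile`.
#' @return Data frame `msa_pos`, `indel_probability`.
#' @export
indel_probability_profile <- function(events, a, map = NULL) {
  counts <- matrix(FALSE, nrow = a$n, ncol = a$width,
                   dimnames = list(a$ids, NULL))
  for (k in seq_len(nrow(events)))
    counts[events$sequence_id[k], events$msa_start[k]:events$msa_end[k]] <- TRUE
  p <- colSums(counts) / a$n
  out <- data.frame(msa_pos = seq_len(a$width), indel_probability = unname(p))
  if (!is.null(map)) {
    attr(out, "ref_profile") <- data.frame(
      ref_pos = map$ref_pos,
      indel_probability = p[map$msa_pos])
  }
  out
}

#' Histogram of indel event lengths
#'
#' @param events output of [call_indel_events()].
#' @return Data frame `length`, `count`, sorted by length.
#' @export
indel_length_distribution <- function(events) {
  if (nrow(events) == 0L)
    return(data.frame(length = integer(), count = integer()))
  tab <- table(events$length)
  data.frame(length = as.integer(names(tab)), count = as.integer(tab))
}

#' Map alignment columns to reference residue numbering
#'
#' @param a a [protein_msa()].
#' @param reference_id id of the reference row (e.g. the E. coli sequence).
#' @return Data frame `msa_pos`, `ref_pos`: a monotone bijection between the
#'   reference's non-gap columns and residue numbers 1..L, with attribute
#'   `reference_id`.
#' @export
map_to_reference <- function(a, reference_id) {
  i <- match(reference_id, a$ids)
  if (is.na(i)) stop("reference id '", reference_id, "' not in alignment")
  chars <- strsplit(a$seqs[i], "", fixed = TRUE)[[1]]
  msa_pos <- which(chars != "-")
  out <- data.frame(msa_pos = msa_pos, ref_pos = seq_along(msa_pos))
  attr(out, "reference_id") <- reference_id
  out
}

# do all events overlapping msa columns `cols` qualify for fusion waiver?
.waivable <- function(events, cols, fuse_max_seqs, fuse_max_len) {
  if (length(cols) == 0L) return(TRUE)
  hit <- events$msa_end >= min(cols) & events$msa_start <= max(cols)
  ev <- events[hit, , drop = FALSE]
  if (nrow(ev) == 0L) return(TRUE)
  length(unique(ev$sequence_id)) <= fuse_max_seqs && all(ev$length <= fuse_max_len)
}

#' Detect indel-free regions (IFRs) in reference coordinates
#'
#' An IFR is a maximal run of reference positions at which no sequence
#' carries an indel, and across which no insertion column (relative to the
#' reference) carries one either. Runs separated only by a waivable breaker
#' -- indel events confined to at most `fuse_max_seqs` sequences, each of
#' length at most `fuse_max_len` -- are fused into one region and flagged.
#' Regions are ranked by reference length (descending) and labelled with
#' roman numerals (IFR-I the longest).
#'
#' @param profile [indel_probability_profile()] of the alignment.
#' @param map [map_to_reference()] coordinate map.
#' @param events [call_indel_events()] output (needed for the fusion waiver).
#' @param min_length drop regions shorter than this many reference residues.
#' @param fuse_max_seqs,fuse_max_len fusion-waiver limits (defaults 1 and 1:
#'   a breaker due to a single length-1 indel in a single sequence is waived).
#' @return Data frame `rank_label`, `ref_start`, `ref_end`, `msa_start`,
#'   `msa_end`, `length`, `fused`, `fusion_note`, sorted by length
#'   descending.
#' @export
find_ifrs <- function(profile, map, events, min_length = 4L,
                      fuse_max_seqs = 1L, fuse_max_len = 1L) {
  p <- profile$indel_probability
  mpos <- map$msa_pos
  L <- nrow(map)
  clean <- p[mpos] == 0
  # a run also breaks between ref r and r+1 when an intervening insertion
  # column (reference gap) carries events
  gap_dirty <- vapply(seq_len(L - 1L), function(r) {
    g <- if (mpos[r + 1L] - mpos[r] > 1L) (mpos[r] + 1L):(mpos[r + 1L] - 1L) else integer()
    length(g) > 0L && any(p[g] > 0)
  }, logical(1))

  # maximal clean runs
  runs <- list()
  r <- 1L
  while (r <= L) {
    if (!clean[r]) { r <- r + 1L; next }
    s <- r
    while (r < L && clean[r + 1L] && !gap_dirty[r]) r <- r + 1L
    runs[[length(runs) + 1L]] <- c(s, r)
    r <- r + 1L
  }
  if (length(runs) == 0L)
    return(data.frame(rank_label = character(), ref_start = integer(),
                      ref_end = integer(), msa_start = integer(),
                      msa_end = integer(), length = integer(),
                      fused = logical(), fusion_note = character(),
                      stringsAsFactors = FALSE))

  segs <- data.frame(ref_start = vapply(runs, `[`, 1L, i = 1L),
                     ref_end = vapply(runs, `[`, 1L, i = 2L),
                     fused = FALSE, fusion_note = "",
                     stringsAsFactors = FALSE)
  # fusion pass: merge neighbours whose whole breaker span is waivable
  repeat {
    merged <- FALSE
    i <- 1L
    while (i < nrow(segs)) {
      span <- (mpos[segs$ref_end[i]] + 1L):(mpos[segs$ref_start[i + 1L]] - 1L)
      if (.waivable(events, span, fuse_max_seqs, fuse_max_len)) {
        note <- sprintf("fused across ref %d/%d", segs$ref_end[i],
                        segs$ref_start[i + 1L])
        old <- c(segs$fusion_note[i], segs$fusion_note[i + 1L])
        note <- paste(c(old[nzchar(old)], note), collapse = "; ")
        segs$ref_end[i] <- segs$ref_end[i + 1L]
        segs$fused[i] <- TRUE
        segs$fusion_note[i] <- note
        segs <- segs[-(i + 1L), , drop = FALSE]
        merged <- TRUE
      } else i <- i + 1L
    }
    if (!merged) break
  }
  segs$msa_start <- mpos[segs$ref_start]
  segs$msa_end <- mpos[segs$ref_end]
  segs$length <- segs$ref_end - segs$ref_start + 1L
  segs <- segs[segs$length >= min_length, , drop = FALSE]
  segs <- segs[order(-segs$length, segs$ref_start), , drop = FALSE]
  segs$rank_label <- if (nrow(segs)) paste0("IFR-", as.roman(seq_len(nrow(segs)))) else character()
  rownames(segs) <- NULL
  segs[, c("rank_label", "ref_start", "ref_end", "msa_start", "msa_end",
           "length", "fused", "fusion_note")]
}

#' Wu-Kabat variability per alignment column
#'
#' Variability is `N * k / n` where `N` is the number of sequences carrying a
#' residue at the column, `k` the number of distinct amino acids there and
#' `n` the count of the most frequent one. Columns whose consensus character
#' is a gap (pure insertion space) are not analyzed and get `NA`.
#'
#' @param a a [protein_msa()].
#' @param profiles optional precomputed [column_profiles()].
#' @return Data frame `msa_pos`, `analyzed` (logical), `variability`.
#' @export
wu_kabat <- function(a, profiles = column_profiles(a)) {
  m <- msa_matrix(a)
  analyzed <- profiles$consensus != "-"
  v <- rep(NA_real_, a$width)
  for (j in which(analyzed)) {
    col <- m[, j]
    col <- col[col != "-"]
    tab <- table(col)
    v[j] <- length(col) * length(tab) / max(tab)
  }
  data.frame(msa_pos = seq_len(a$width), analyzed = analyzed, variability = v)
}

#' Per-column conservation mask
#'
#' A column is conserved when its most frequent residue (gaps excluded from
#' numerator and denominator) reaches `identity_threshold`. All-gap columns
#' are never conserved.
#'
#' @param a a [protein_msa()].
#' @param identity_threshold fraction in (0, 1]; default 1 (strict identity).
#' @return Logical vector of length `a$width`.
#' @export
conservation_mask <- function(a, identity_threshold = 1.0) {
  m <- msa_matrix(a)
  apply(m, 2L, function(col) {
    col <- col[col != "-"]
    if (length(col) == 0L) return(FALSE)
    max(table(col)) / length(col) >= identity_threshold
  })
}

#' Indel events of one aligned sequence relative to another
#'
#' Treats `row_a` as the ancestor: maximal runs where `b` has residues and
#' `a` gaps are insertions, runs where `a` has residues and `b` gaps are
#' deletions. Columns gapped in both rows are silent. Events are assigned to
#' partition intervals via the ancestor's residue numbering (for an
#' insertion, the last preceding ancestor residue).
#'
#' @param row_a,row_b aligned sequences (same MSA, equal length strings).
#' @param partition optional [subdomain_partition()] for per-domain counts;
#'   when omitted everything is counted under domain `"all"`.
#' @return List with `events` (data frame: `kind`, `msa_start`, `msa_end`,
#'   `length`, `ref_pos`, `domain`) and `counts` (data frame: `domain`,
#'   `insertions`, `deletions`).
#' @export
compare_indels <- function(row_a, row_b, partition = NULL) {
  ca <- strsplit(toupper(row_a), "", fixed = TRUE)[[1]]
  cb <- strsplit(toupper(row_b), "", fixed = TRUE)[[1]]
  if (length(ca) != length(cb)) stop("rows differ in aligned length")
  ga <- ca == "-"; gb <- cb == "-"
  state <- ifelse(ga & gb, "S", ifelse(ga & !gb, "I", ifelse(!ga & gb, "D", "M")))
  ref_at <- cumsum(!ga)  # ancestor residue number at or before each column
  vis <- which(state != "S")
  events <- data.frame(kind = character(), msa_start = integer(),
                       msa_end = integer(), length = integer(),
                       ref_pos = integer(), domain = character(),
                       stringsAsFactors = FALSE)
  if (length(vis) > 0L) {
    r <- rle(state[vis])
    ends <- cumsum(r$lengths)
    starts <- c(1L, utils::head(ends, -1L) + 1L)
    keep <- r$values %in% c("I", "D")
    if (any(keep)) {
      ms <- vis[starts[keep]]; me <- vis[ends[keep]]
      events <- data.frame(
        kind = ifelse(r$values[keep] == "I", "insertion", "deletion"),
        msa_start = ms, msa_end = me, length = r$lengths[keep],
        ref_pos = ref_at[ms], stringsAsFactors = FALSE)
    }
  }
  doms <- if (is.null(partition)) "all" else names(partition)
  events$domain <- if (nrow(events) == 0L) character() else if (is.null(partition)) "all" else
    vapply(events$ref_pos, function(rp) {
      hit <- vapply(partition, function(iv) rp >= iv[1] && rp <= iv[2], logical(1))
      if (any(hit)) paste(names(partition)[hit], collapse = ",") else "outside"
    }, character(1))
  in_dom <- function(d) vapply(strsplit(events$domain, ",", fixed = TRUE),
                               function(x) d %in% x, logical(1))
  counts <- data.frame(domain = doms,
                       insertions = vapply(doms, function(d)
                         sum(events$kind == "insertion" & in_dom(d)), integer(1)),
                       deletions = vapply(doms, function(d)
                         sum(events$kind == "deletion" & in_dom(d)), integer(1)),
                       row.names = NULL, stringsAsFactors = FALSE)
  list(events = events, counts = counts)
}
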