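test_that("aligned FASTA and Clustal renderings parse to the same alignment", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">s1", "ACDE-", ">s2", "AC-EF", ">s3", "ACDEF"), fa)
  a <- read_alignment(fa, "fasta")
  expect_s3_class(a, "protein_msa")
  expect_equal(a$n, 3L)
  expect_equal(a$width, 5L)

  cl <- tempfile(fileext = ".aln")
  writeLines(c("CLUSTAL W (1.83) multiple sequence alignment", "",
               "s1              ACD", "s2              AC-", "s3              ACD",
               "                ** ", "",
               "s1              E-", "s2              EF", "s3              EF",
               "                *  "), cl)
  b <- read_alignment(cl, "clustal")
  expect_equal(b$ids, a$ids)
  expect_equal(b$seqs, a$seqs)

  ragged <- tempfile(fileext = ".fasta")
  writeLines(c(">s1", "ACDE", ">s2", "AC"), ragged)
  expect_error(read_alignment(ragged, "fasta"), "ragged")
  expect_error(protein_msa(c("a", "a"), c("AC", "AC")), "duplicate")
  expect_error(protein_msa("a", "AC"), ">= 2")
})

test_that("column classes follow the majority-gap insertion rule", {
  m <- rbind(c("A", "A", "A"), c("A", "-", "A"), c("A", "-", "A"),
             c("A", "-", "A"), c("-", "-", "A"))
  prof <- column_profiles(msa_from_matrix(m))
  expect_equal(prof$gap_fraction, c(0.2, 0.8, 0))
  expect_equal(prof$column_class, c("deletion_site", "insertion", "ungapped"))

  # exactly 50% gaps is still a deletion site (insertions need a majority)
  m2 <- rbind(c("A"), c("A"), c("-"), c("-"))
  expect_equal(column_profiles(msa_from_matrix(m2))$column_class, "deletion_site")

  # classes are exclusive and exhaustive
  sim <- simulate_alignment(planted_ifr_scenario(seed = 5))
  cls <- column_profiles(sim$alignment)$column_class
  expect_true(all(cls %in% c("insertion", "deletion_site", "ungapped")))
})

test_that("indel events are maximal runs split by column class", {
  # one sequence with a 3-column gap run in otherwise gapless columns
  base <- matrix("A", 10, 8)
  base[4, 3:5] <- "-"
  ev <- call_indel_events(msa_from_matrix(base))
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$kind, "deletion")
  expect_equal(c(ev$msa_start, ev$msa_end, ev$length), c(3L, 5L, 3L))

  expect_equal(nrow(call_indel_events(msa_from_matrix(matrix("A", 5, 4)))), 0L)

  # one row carrying residues across two insertion-class columns
  m <- matrix("A", 10, 6)
  m[, 3:4] <- "-"
  m[7, 3:4] <- c("G", "G")
  ev2 <- call_indel_events(msa_from_matrix(m))
  expect_equal(nrow(ev2), 1L)
  expect_equal(ev2$kind, "insertion")
  expect_equal(c(ev2$msa_start, ev2$msa_end, ev2$length), c(3L, 4L, 2L))
  expect_equal(ev2$sequence_id, "s7")
})

test_that("indel probability counts sequences with an overlapping event", {
  m <- matrix("A", 10, 5)
  m[1, 3] <- "-"; m[2, 3] <- "-"
  a <- msa_from_matrix(m)
  p <- indel_probability_profile(call_indel_events(a), a)
  expect_equal(p$indel_probability, c(0, 0, 0.2, 0, 0))

  g <- msa_from_matrix(matrix("C", 4, 6))
  expect_equal(indel_probability_profile(call_indel_events(g), g)$indel_probability,
               rep(0, 6))

  # planted hotspots dominate the profile; values stay in [0, 1] and are
  # zero exactly where no event overlaps
  sim <- simulate_alignment(planted_ifr_scenario(seed = 21))
  a2 <- sim$alignment
  ev <- call_indel_events(a2)
  p2 <- indel_probability_profile(ev, a2, map_to_reference(a2, "REF"))
  expect_true(all(p2$indel_probability >= 0 & p2$indel_probability <= 1))
  covered <- rep(FALSE, a2$width)
  for (k in seq_len(nrow(ev)))
    covered[ev$msa_start[k]:ev$msa_end[k]] <- TRUE
  expect_equal(p2$indel_probability > 0, covered)
  rp <- attr(p2, "ref_profile")
  hot <- rp$ref_pos <= 60 | (rp$ref_pos >= 101 & rp$ref_pos <= 160) |
    (rp$ref_pos >= 241 & rp$ref_pos <= 300) | rp$ref_pos >= 451
  expect_gt(mean(rp$indel_probability[hot]), 0.2)
  expect_equal(max(rp$indel_probability[!hot]), 0)
})

test_that("indel length histograms count events by length", {
  ev <- data.frame(sequence_id = c("a", "b", "c"), kind = "deletion",
                   msa_start = c(1, 4, 8), msa_end = c(1, 4, 9),
                   length = c(1L, 1L, 2L))
  h <- indel_length_distribution(ev)
  expect_equal(h, data.frame(length = c(1L, 2L), count = c(2L, 1L)))
  expect_equal(nrow(indel_length_distribution(ev[0, ])), 0L)

  # realized lengths follow the geometric law of the generator (p = 0.5)
  regions <- data.frame(start = 1, end = 400, substitution_rate = 0.05,
                        indel_rate = 0.15, mean_indel_length = 2)
  sim <- simulate_alignment(alignment_scenario(40, 400, regions, seed = 99))
  lens <- sim$truth$events$length[sim$truth$events$kind == "insertion"]
  n <- length(lens)
  expect_gt(n, 200)
  for (l in 1:4) {
    p_l <- 0.5 * 0.5^(l - 1)
    expect_lt(abs(sum(lens == l) - n * p_l), 3 * sqrt(n * p_l * (1 - p_l)) + 1)
  }
})

test_that("reference coordinate maps are monotone bijections", {
  a <- protein_msa(c("ref", "x"), c("A-CD", "AAAA"))
  map <- map_to_reference(a, "ref")
  expect_equal(map$msa_pos, c(1L, 3L, 4L))
  expect_equal(map$ref_pos, 1:3)

  b <- protein_msa(c("r", "s"), c("ACDEF", "AC-EF"))
  expect_equal(map_to_reference(b, "r")$msa_pos, 1:5)

  set.seed(3)
  chars <- sample(c("A", "C", "-"), 60, TRUE, prob = c(.4, .4, .2))
  c2 <- protein_msa(c("r", "s"),
                    c(paste(chars, collapse = ""), paste(rep("A", 60), collapse = "")))
  map2 <- map_to_reference(c2, "r")
  expect_equal(map2$msa_pos, which(chars != "-"))           # brute-force scan
  expect_equal(map2$ref_pos, cumsum(chars != "-")[chars != "-"])
  expect_true(all(diff(map2$msa_pos) > 0))
  expect_error(map_to_reference(c2, "zz"), "not in alignment")
})

test_that("Wu-Kabat variability equals N*k/n and skips consensus-gap columns", {
  m <- cbind(c("A", "A", "A", "C", "G"),
             rep("A", 5),
             c("A", "C", "D", "E", "F"),
             c("A", "-", "-", "-", "-"))
  wk <- wu_kabat(msa_from_matrix(m))
  expect_equal(wk$variability[1], 5 * 3 / 3)
  expect_equal(wk$variability[2], 1)
  expect_equal(wk$variability[3], 5 * 5 / 1)
  expect_false(wk$analyzed[4])
  expect_true(is.na(wk$variability[4]))

  sim <- simulate_alignment(planted_ifr_scenario(seed = 8))
  wk2 <- wu_kabat(sim$alignment)
  expect_true(all(wk2$variability[wk2$analyzed] >= 1))
})

test_that("conservation masks exclude gaps from both sides of the ratio", {
  m <- rbind(strsplit("AAA", "")[[1]], strsplit("AAA", "")[[1]],
             strsplit("A--", "")[[1]], strsplit("AC-", "")[[1]],
             strsplit("AAA", "")[[1]])
  a <- msa_from_matrix(m)  # cols: AAAAA, AA-CA, AA--A
  expect_equal(conservation_mask(a, 1.0), c(TRUE, FALSE, TRUE))
  expect_equal(conservation_mask(a, 0.75), c(TRUE, TRUE, TRUE))
  allgap <- msa_from_matrix(cbind(c("A", "A"), c("-", "-")))
  expect_equal(conservation_mask(allgap), c(TRUE, FALSE))
})

test_that("pairwise indel comparison is antisymmetric and domain-aware", {
  expect_equal(sum(compare_indels("ACDEF", "ACDEF")$counts[, -1]), 0)

  cmp <- compare_indels("ACDEF", "AC--F")
  expect_equal(cmp$events$kind, "deletion")
  expect_equal(cmp$events$length, 2L)

  # insertions of b vs a are deletions of a vs b
  a <- "AC--DEF-K"
  b <- "ACGG-EFLK"
  ab <- compare_indels(a, b)$events
  ba <- compare_indels(b, a)$events
  expect_equal(ab$kind == "insertion", ba$kind == "deletion")
  expect_equal(ab[, c("msa_start", "msa_end", "length")],
               ba[, c("msa_start", "msa_end", "length")])

  # three planted events land in the right subdomains
  part <- subdomain_partition(NBD = c(1, 4), SBD = c(5, 9),
                              lobe_I = c(1, 2), lobe_II = c(3, 4),
                              betaSBD = c(5, 7), alphaSBD = c(8, 9))
  anc <- "AAAA-AAAAA"
  des <- "A--AGAAA-A"   # deletion at ref 2-3 (NBD), insertion after ref 4,
                        # deletion at ref 8 (SBD)
  cmp3 <- compare_indels(anc, des, part)
  expect_equal(nrow(cmp3$events), 3L)
  counts <- cmp3$counts
  expect_equal(counts$deletions[counts$domain == "NBD"], 1L)
  expect_equal(counts$deletions[counts$domain == "SBD"], 1L)
  expect_equal(sum(counts$insertions[counts$domain %in% c("NBD", "SBD")]), 1L)
  expect_error(compare_indels("AC", "ACD"), "length")
})

test_that("IFR detection recovers planted regions exactly and ranks by length", {
  sim <- simulate_alignment(planted_ifr_scenario(seed = 11))
  pipe <- run_ifr_pipeline(sim$alignment, min_length = 30)
  expect_equal(pipe$ifrs$ref_start, c(301L, 161L, 61L))
  expect_equal(pipe$ifrs$ref_end, c(450L, 240L, 100L))
  expect_equal(pipe$ifrs$length, c(150L, 80L, 40L))
  expect_equal(pipe$ifrs$rank_label, c("IFR-I", "IFR-II", "IFR-III"))
  # intervals are disjoint and consistent with the generator truth
  big_truth <- sim$truth$ifrs[sim$truth$ifrs$ref_end - sim$truth$ifrs$ref_start >= 29, ]
  expect_equal(pipe$ifrs$ref_start[order(pipe$ifrs$ref_start)], big_truth$ref_start)
  expect_true(all(pipe$ifrs$ref_end[order(pipe$ifrs$ref_start)] == big_truth$ref_end))

  # an all-clean profile yields a single IFR spanning the mapped reference
  g <- msa_from_matrix(matrix("A", 5, 12))
  pipe0 <- run_ifr_pipeline(g, "s1")
  expect_equal(nrow(pipe0$ifrs), 1L)
  expect_equal(c(pipe0$ifrs$ref_start, pipe0$ifrs$ref_end), c(1L, 12L))
  expect_false(pipe0$ifrs$fused)
})

test_that("a single-sequence single-residue insertion is fused away", {
  # 20 sequences, 150 reference columns, one extra insertion column after
  # reference position 75 carried by one sequence only
  n <- 20L
  m <- matrix("A", n, 151L)
  m[, 76] <- "-"
  m[2, 76] <- "G"
  a <- msa_from_matrix(m, ids = c("REF", sprintf("seq%02d", 2:n)))
  pipe <- run_ifr_pipeline(a)
  expect_equal(nrow(pipe$ifrs), 1L)
  expect_equal(pipe$ifrs$length, 150L)
  expect_true(pipe$ifrs$fused)
  expect_match(pipe$ifrs$fusion_note, "75/76")

  # with fusion disabled the same alignment splits into two 75-residue IFRs
  strict <- find_ifrs(pipe$profile, pipe$map, pipe$events, fuse_max_seqs = 0)
  expect_equal(strict$length, c(75L, 75L))

  # a two-sequence breaker is not waived under the defaults
  m2 <- m
  m2[3, 76] <- "G"
  pipe2 <- run_ifr_pipeline(msa_from_matrix(m2, ids = a$ids))
  expect_equal(pipe2$ifrs$length, c(75L, 75L))
})
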