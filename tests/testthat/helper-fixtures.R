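# hand-formatted PDB ATOM lines for parser tests (fixed-width per PDB spec)
pdb_line <- function(serial, resno, x, y, z, name = " CA ", alt = " ",
                     resn = "ALA", chain = "A", occ = 1, b = 0) {
  paste0("ATOM  ", sprintf("%5d", serial), " ", name, alt,
         sprintf("%3s", resn), " ", chain, sprintf("%4d", resno), "    ",
         sprintf("%8.3f%8.3f%8.3f", x, y, z), sprintf("%6.2f%6.2f", occ, b),
         "           C")
}

write_pdb_fixture <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

# the collinear 3-residue toy used across the structure tests
collinear_pdb <- function() {
  write_pdb_fixture(c(pdb_line(1, 1, 0, 0, 0),
                      pdb_line(2, 2, 3.8, 0, 0),
                      pdb_line(3, 3, 7.6, 0, 0)))
}

random_model <- function(n, seed, label = "open", resno = seq_len(n)) {
  set.seed(seed)
  structure_model(data.frame(resno = resno,
                             aa = sample(c("A", "G", "L", "S"), n, TRUE),
                             x = runif(n, 0, 50), y = runif(n, 0, 50),
                             z = runif(n, 0, 50)), label)
}

# alignment built column-wise from a character matrix
msa_from_matrix <- function(m, ids = sprintf("s%d", seq_len(nrow(m)))) {
  protein_msa(ids, apply(m, 1L, paste, collapse = ""))
}

# scenario with planted IFRs of 40/80/150 residues amid indel hotspots
planted_ifr_scenario <- function(seed = 11L, hot_rate = 0.3) {
  regions <- data.frame(
    start = c(1, 61, 101, 161, 241, 301, 451),
    end = c(60, 100, 160, 240, 300, 450, 500),
    substitution_rate = 0.1,
    indel_rate = c(hot_rate, 0, hot_rate, 0, hot_rate, 0, hot_rate),
    mean_indel_length = 2)
  alignment_scenario(n_sequences = 20L, reference_length = 500L,
                     regions = regions, seed = seed)
}

planted_ifr_truth <- data.frame(ref_start = c(61L, 161L, 301L),
                                ref_end = c(100L, 240L, 450L))

run_ifr_pipeline <- function(a, reference_id = "REF", ...) {
  prof <- column_profiles(a)
  ev <- call_indel_events(a, prof)
  map <- map_to_reference(a, reference_id)
  p <- indel_probability_profile(ev, a, map)
  list(profiles = prof, events = ev, map = map, profile = p,
       ifrs = find_ifrs(p, map, ev, ...))
}
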