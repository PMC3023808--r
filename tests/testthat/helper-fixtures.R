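# In-code fixtures shared across test files.

# Micro-fixture: 12-pair curated set over proteins A..H, two 4-pair HT
# screens, study levels making {A, B} well-studied at cutoff 125.
# Every intermediate of the estimation pipeline is hand-checkable.
micro_fixture <- function() {
  lc <- interaction_dataset(
    protein_a = c("A", "A", "A", "B", "B", "B", "C", "C", "D", "D", "E", "A"),
    protein_b = c("C", "D", "E", "C", "D", "E", "D", "E", "E", "F", "F", "B"),
    name = "LowBP-LC",
    evidence_codes = list("Two-hybrid", "Two-hybrid", "Biochemical Activity",
                          "Two-hybrid", "Reconstituted Complex", "Two-hybrid",
                          "Two-hybrid", "FRET", "Two-hybrid", "Two-hybrid",
                          "Two-hybrid", "Reconstituted Complex"),
    pub_ids = list(c("P1", "P2"), "P3", "P4", "P5", c("P6", "P7"), "P8",
                   "P9", "P10", "P11", "P12", "P13", "P14"),
    pub_years = list(c(1995L, 2001L), 1998L, 2002L, 1999L, c(2003L, 2004L),
                     1997L, 1996L, 2005L, 1999L, 1995L, 2001L, 1998L)
  )
  ref <- interaction_dataset(c("A", "C", "G", "A"), c("C", "D", "H", "G"),
                             name = "REF")
  x <- interaction_dataset(c("A", "B", "D", "F"), c("D", "C", "E", "G"),
                           name = "X")
  levels <- study_levels(c(A = 200, B = 150, C = 10, D = 10, E = 10,
                           F = 10, G = 10, H = 10))
  list(lc = lc, ref = ref, x = x, levels = levels,
       ht_list = list(REF = ref, X = x))
}

# Raw BioGRID-style records: 10 rows — 2 genetic, 3 from a publication
# exceeding the throughput threshold (here 2), 5 whitelisted low-throughput
# rows over 4 distinct pairs.
raw_filter_fixture <- function() {
  with_keys(data.frame(
    protein_a = c("P1", "P3", "P5", "P1", "P7", "P1", "P1", "P3", "P10", "P7"),
    protein_b = c("P2", "P4", "P6", "P2", "P8", "P2", "P2", "P4", "P9", "P8"),
    evidence = c("Two-hybrid", "Two-hybrid", "Two-hybrid",
                 "Synthetic Lethality", "Synthetic Lethality",
                 "Two-hybrid", "Reconstituted Complex", "Biochemical Activity",
                 "FRET", "PCA"),
    pub_id = c("HT1", "HT1", "HT1", "L1", "L2", "L3", "L4", "L5", "L6", "L7"),
    pub_year = c(2001L, 2001L, 2001L, 1999L, 1999L, 1995L, 1996L, 1997L,
                 1998L, 1999L),
    stringsAsFactors = FALSE
  ))
}

with_keys <- function(df) {
  cp <- canonical_pair(df$protein_a, df$protein_b)
  df$protein_a <- cp[, 1L]
  df$protein_b <- cp[, 2L]
  df$key <- paste(cp[, 1L], cp[, 2L], sep = "|")
  df
}

# Raw records giving publications supporting 5, 100, 101 and 2000 distinct
# pairs respectively.
throughput_fixture <- function() {
  mk <- function(pub, n, prefix) {
    data.frame(protein_a = sprintf("%s%04dA", prefix, seq_len(n)),
               protein_b = sprintf("%s%04dB", prefix, seq_len(n)),
               evidence = "Two-hybrid", pub_id = pub, pub_year = 2000L,
               stringsAsFactors = FALSE)
  }
  with_keys(rbind(mk("PUB5", 5, "V"), mk("PUB100", 100, "W"),
                  mk("PUB101", 101, "X"), mk("PUB2000", 2000, "Y")))
}

random_dataset <- function(n_pairs, n_proteins = 30, prefix = "R") {
  prot <- sprintf("%s%03d", prefix, seq_len(n_proteins))
  a <- sample(prot, n_pairs, replace = TRUE)
  b <- sample(prot, n_pairs, replace = TRUE)
  interaction_dataset(a, b, name = "random")
}

write_micro_biogrid <- function(path) {
  fx <- micro_fixture()
  write_biogrid_tab(fx$lc, path)
  path
}
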