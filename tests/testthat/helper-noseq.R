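# Shared fixtures and independent oracles for the test suite.

BASES <- c("A", "C", "G", "T")

random_reference <- function(len, modified = integer()) {
  seq <- paste(sample(BASES, len, replace = TRUE), collapse = "")
  reference_amplicon(seq, modified_positions = intersect(
    modified, which(strsplit(seq, "")[[1]] == "A")))
}

# Apply the deamination read-out rules to a reference sequence with given
# per-event flags; used to construct reads with known properties.
deaminate_string <- function(seq, a_to_g = TRUE, c_to_t = TRUE) {
  ch <- strsplit(seq, "")[[1]]
  if (a_to_g) ch[ch == "A"] <- "G"
  if (c_to_t) ch[ch == "C"] <- "T"
  paste(ch, collapse = "")
}

# Random plausible read for a reference: partial deamination plus optional
# corruption (point mutations, shifts, truncation) to exercise every
# rejection path.
random_read <- function(reference, p_conv = 0.3, corrupt = TRUE) {
  ch <- strsplit(reference$sequence, "")[[1]]
  a <- which(ch == "A"); cc <- which(ch == "C")
  conv_a <- a[runif(length(a)) < p_conv]
  conv_c <- cc[runif(length(cc)) < p_conv]
  ch[conv_a] <- "G"; ch[conv_c] <- "T"
  if (corrupt) {
    mode <- sample(c("clean", "mutate", "shift", "truncate"), 1,
                   prob = c(.4, .3, .15, .15))
    if (mode == "mutate") {
      i <- sample(length(ch), 1)
      ch[i] <- sample(BASES, 1)
    } else if (mode == "shift") {
      drop <- sample(1:3, 1)
      ch <- ch[-seq_len(drop)]
    } else if (mode == "truncate") {
      keep <- sample(seq_len(length(ch) - 1), 1)
      ch <- ch[seq_len(keep)]
    }
  }
  paste(ch, collapse = "")
}

# Independent brute-force aligner: scores every ungapped placement of the
# read on the reference directly and applies the retention filters, with no
# seeding machinery. Accepts iff some placement starts at 1, is in bounds,
# scores exactly the read length, covers the window, and the read can seed
# at all (length >= k).
brute_force_align <- function(read, reference, k = 11,
                              matrix = substitution_matrix(),
                              window = NULL) {
  refc <- strsplit(reference$sequence, "")[[1]]
  rc <- strsplit(read, "")[[1]]
  Lr <- length(rc); Lref <- length(refc)
  if (is.null(window)) window <- c(1, Lref)
  if (Lr < k || Lr > Lref || any(!rc %in% BASES)) {
    return(list(accepted = FALSE, score = NA_integer_))
  }
  scores <- vapply(seq_len(Lref - Lr + 1), function(s) {
    sum(matrix[cbind(rc, refc[s:(s + Lr - 1)])])
  }, numeric(1))
  acc <- scores[1] == Lr && 1 <= window[1] && Lr >= window[2]
  list(accepted = acc, score = if (acc) scores[1] else NA_integer_,
       all_scores = scores)
}

# Reference-path aligner built from the exported R primitives (seed_matches
# + extend_and_score over seeds in order), for agreement checks against the
# compiled batch path.
r_path_align <- function(read, reference, k = 11,
                         matrix = substitution_matrix(), window = NULL) {
  idx <- build_index(reference, k)
  seeds <- seed_matches(read, idx, matrix)
  if (nrow(seeds) == 0) {
    return(list(accepted = FALSE, reason = "no_seed",
                score = NA_integer_, reference_start = NA_integer_))
  }
  first <- NULL
  for (i in seq_len(nrow(seeds))) {
    res <- extend_and_score(read, c(seeds$read_offset[i],
                                    seeds$reference_offset[i]),
                            reference, matrix, window)
    if (is.null(first)) first <- res
    if (res$accepted) return(res)
  }
  first
}

write_temp_fasta <- function(seq, name = "ref") {
  path <- tempfile(fileext = ".fasta")
  writeLines(c(paste0(">", name), seq), path)
  path
}

# The printed calibration oligo in its native RNA alphabet.
OLIGO_53MER_RNA <- "AUAGGGGAAUGGGCCGUUCAUCUGCUAAAAGGACUGCUUUUGGGGCUUGUAGU"

# Standard chemistry used by the simulation-based acceptance checks:
# conversion at the working point, no G chemistry (full-length reads).
accept_chem <- function() chemistry_model(p_AtoI = 0.30, p_CtoU = 0.35,
                                          p_GtoX = 0)

run_chain <- function(reference, stoichiometry = numeric(), n = 10000L,
                      jitter = 0.15, merip = NULL, seed = 1L,
                      chem = accept_chem(), pcr = 0, threshold = 0.95) {
  p <- sim_params(reference, stoichiometry = stoichiometry, n_molecules = n,
                  position_rate_jitter = jitter, merip = merip,
                  pcr_duplication_rate = pcr, seed = seed)
  sim <- simulate_reads(p, chem)
  aln <- align_all(sim$reads, reference)
  list(sim = sim, aln = aln,
       calls = call_sites(tabulate_rates(aln), threshold = threshold))
}
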