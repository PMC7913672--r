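test_that("the substitution matrix has exactly the deamination +1 entries", {
  m <- substitution_matrix()
  plus <- list(c("A", "A"), c("C", "C"), c("G", "G"), c("T", "T"),
               c("G", "A"), c("A", "G"), c("T", "C"))
  for (p in plus) expect_equal(m[p[1], p[2]], 1L)
  expect_equal(sum(m == 1L), 7L)
  expect_equal(sum(m == -1L), 9L)
  # the load-bearing asymmetry
  expect_equal(m["T", "C"], 1L)
  expect_equal(m["C", "T"], -1L)
})

test_that("a custom matrix round-trips through its TSV representation", {
  m <- substitution_matrix()
  m["C", "T"] <- 1L   # a deliberately different table
  path <- tempfile(fileext = ".tsv")
  write.table(m, path, sep = "\t", quote = FALSE)
  expect_equal(unname(read_substitution_matrix(path)), unname(m))
  expect_error(read_substitution_matrix(write_temp_fasta("x")), "4x4")
})

test_that("the k-mer index covers every reference offset in sorted order", {
  idx <- build_index(oligo_53mer(), k = 11)
  expect_equal(sort(unlist(idx$positions)), 1:43)
  expect_equal(idx$kmers, sort(idx$kmers))
  single <- build_index(reference_amplicon("ACGT"), k = 4)
  expect_equal(single$kmers, "ACGT")
  expect_equal(single$positions[[1]], 1L)
  expect_error(build_index(reference_amplicon("ACGT"), k = 0), "k")
  expect_error(build_index(reference_amplicon("ACGT"), k = 5), "exceeds")
})

test_that("seeding is matrix-compatible, not literal string equality", {
  ref <- reference_amplicon(strrep("A", 11))
  idx <- build_index(ref, 11)
  # a fully deaminated k-mer still seeds on its source
  hit <- seed_matches(strrep("G", 11), idx)
  expect_equal(nrow(hit), 1L)
  expect_equal(unlist(hit), c(read_offset = 1L, reference_offset = 1L))
  # but not under literal seeding
  expect_equal(nrow(seed_matches(strrep("G", 11), idx, mode = "literal")), 0L)
  # incompatible alphabet never seeds
  refc <- reference_amplicon(strrep("C", 11))
  expect_equal(nrow(seed_matches(strrep("A", 11), build_index(refc, 11))), 0L)
  # identity always seeds
  ref53 <- oligo_53mer()
  idx53 <- build_index(ref53, 11)
  sm <- seed_matches(substr(ref53$sequence, 5, 25), idx53)
  expect_true(any(sm$read_offset == 1 & sm$reference_offset == 5))
})

test_that("extension applies the perfect-score, anchor and coverage filters", {
  ref <- oligo_53mer()
  full_deam <- deaminate_string(ref$sequence)
  res <- extend_and_score(full_deam, c(1, 1), ref)
  expect_true(res$accepted)
  expect_equal(res$score, 53L)

  verbatim <- extend_and_score(ref$sequence, c(1, 1), ref)
  expect_true(verbatim$accepted)
  expect_equal(verbatim$score, nchar(ref$sequence))

  # one C over a reference T is a -1 pairing: score < length
  t_pos <- which(strsplit(ref$sequence, "")[[1]] == "T")[1]
  bad <- ref$sequence
  substr(bad, t_pos, t_pos) <- "C"
  res_bad <- extend_and_score(bad, c(1, 1), ref)
  expect_false(res_bad$accepted)
  expect_equal(res_bad$reason, "score")
  expect_equal(res_bad$score, 51L)

  # perfect sub-read starting inside the reference: anchored elsewhere
  sub <- substr(ref$sequence, 5, 53)
  res_sub <- extend_and_score(sub, c(1, 5), ref, window = c(5, 53))
  expect_false(res_sub$accepted)
  expect_equal(res_sub$reason, "anchor")

  # placement running off the reference
  res_oob <- extend_and_score(ref$sequence, c(1, 5), ref)
  expect_equal(res_oob$reason, "coverage")

  # full-score prefix that does not cover the window
  res_cov <- extend_and_score(substr(ref$sequence, 1, 30), c(1, 1), ref)
  expect_equal(res_cov$reason, "coverage")
})

test_that("the asymmetry is load-bearing for acceptance", {
  # read T over reference C is accepted; swapping roles is rejected
  ref_c <- reference_amplicon(strrep("C", 12))
  expect_true(align_all(strrep("T", 12), ref_c, k = 11)$decisions$accepted)
  ref_t <- reference_amplicon(strrep("T", 12))
  dec <- align_all(strrep("C", 12), ref_t, k = 11)$decisions
  expect_false(dec$accepted)
})

test_that("seed-and-extend equals the brute-force all-placements oracle", {
  set.seed(7)
  checked <- 0
  for (rep in 1:200) {
    ref <- random_reference(sample(20:40, 1))
    reads <- replicate(50, random_read(ref))
    aln <- align_all(reads, ref)
    for (i in seq_along(reads)) {
      bf <- brute_force_align(reads[i], ref)
      expect_identical(aln$decisions$accepted[i], bf$accepted)
      if (bf$accepted) {
        expect_identical(aln$decisions$score[i], as.integer(bf$score))
        expect_identical(aln$decisions$reference_start[i], 1L)
      }
      checked <- checked + 1
    }
  }
  expect_equal(checked, 200L * 50L)
})

test_that("the compiled batch path agrees with the R seed/extend primitives", {
  set.seed(8)
  for (rep in 1:25) {
    ref <- random_reference(sample(15:30, 1))
    k <- sample(c(5, 8, 11), 1)
    reads <- replicate(15, random_read(ref))
    aln <- align_all(reads, ref, k = k)
    for (i in seq_along(reads)) {
      rp <- r_path_align(reads[i], ref, k = k)
      expect_identical(aln$decisions$accepted[i], rp$accepted)
      if (!rp$accepted) {
        expect_identical(aln$decisions$reason[i], rp$reason)
      }
    }
  }
})

test_that("extra deamination-compatible conversions never break acceptance", {
  set.seed(9)
  ref <- oligo_53mer()
  for (rep in 1:40) {
    rd <- random_read(ref, p_conv = 0.3, corrupt = FALSE)
    expect_true(align_all(rd, ref)$decisions$accepted)
    # convert one more A->G or C->T (on the read's own remaining A/C)
    ch <- strsplit(rd, "")[[1]]
    refc <- strsplit(ref$sequence, "")[[1]]
    conv <- which((ch == "A" & refc == "A") | (ch == "C" & refc == "C"))
    if (length(conv) > 0) {
      j <- sample(conv, 1)
      ch[j] <- if (ch[j] == "A") "G" else "T"
      expect_true(align_all(paste(ch, collapse = ""), ref)$decisions$accepted)
    }
  }
})

test_that("alignment funnel is conserved and non-increasing", {
  ref <- oligo_53mer()
  p <- sim_params(ref, n_molecules = 2000L, seed = 5)
  sim <- simulate_reads(p, chemistry_model(p_AtoI = 0.3, p_CtoU = 0.3,
                                           p_GtoX = 0.1, p_X_block = 0.8))
  # sprinkle N reads in
  sim$reads$insert[1:10] <- sub("^.", "N", sim$reads$insert[1:10])
  aln <- align_all(sim$reads, ref)
  s <- aln$stats
  expect_equal(sum(s[c("accepted", "rejected_score", "rejected_anchor",
                       "rejected_coverage", "rejected_no_seed",
                       "rejected_n_base")]),
               unname(s["input"]))
  expect_true(all(diff(s[c("input", "usable", "seeded", "accepted")]) <= 0))
})

test_that("clean reads all align and truncated reads are all rejected", {
  ref <- oligo_53mer()
  p0 <- sim_params(ref, n_molecules = 300L, position_rate_jitter = 0,
                   seed = 6)
  clean <- simulate_reads(p0, chemistry_model(p_AtoI = 0, p_CtoU = 0))
  a0 <- align_all(clean$reads, ref)
  expect_equal(unname(a0$stats["accepted"]), 300L)

  pt <- sim_params(ref, n_molecules = 400L, seed = 7)
  tr <- simulate_reads(pt, chemistry_model(p_AtoI = 0.2, p_CtoU = 0.2,
                                           p_GtoX = 0.5, p_X_block = 1))
  at <- align_all(tr$reads, ref)
  truncated <- !is.na(tr$truth$truncated_at)
  expect_true(any(truncated))
  dec <- at$decisions[truncated, ]
  expect_false(any(dec$accepted))
  expect_true(all(dec$reason %in% c("coverage", "no_seed")))
  # seedable truncations specifically fail on coverage
  expect_true(all(dec$reason[dec$length >= 11] == "coverage"))
})

test_that("reads longer than the reference are rejected, not clipped", {
  ref <- oligo_53mer()
  long <- paste0(ref$sequence, "A")
  dec <- align_all(long, ref)$decisions
  expect_false(dec$accepted)
  expect_equal(dec$reason, "coverage")
})

test_that("SAM rendering of accepted reads is well-formed", {
  ref <- oligo_53mer()
  aln <- align_all(c(ref$sequence, deaminate_string(ref$sequence)), ref)
  path <- tempfile(fileext = ".sam")
  write_sam(aln, path)
  lines <- readLines(path)
  expect_equal(sum(startsWith(lines, "@")), 3L)
  body <- strsplit(lines[!startsWith(lines, "@")], "\t")
  expect_equal(length(body), 2L)
  expect_true(all(vapply(body, function(f) f[6] == "53M", logical(1))))
  expect_true(all(vapply(body, function(f) f[4] == "1", logical(1))))
})
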