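test_that("the deamination screening grid enumerates all 72 conditions", {
  g <- condition_grid()
  expect_equal(nrow(g), 72L)
  # ascending order: temperature, then pH, then time
  expect_equal(unlist(g[1, c("temperature_C", "pH", "time_min")]),
               c(temperature_C = 50, pH = 3.5, time_min = 1))
  expect_equal(sum(g$pH == 4.0), 18L)
  expect_false(any(duplicated(g$label)))
})

test_that("chemistry presets respect the published rate constraints", {
  oo <- condition_preset("optimal_oligo")
  expect_true(oo$p_AtoI >= 0.10 && oo$p_AtoI <= 0.50)
  for (preset in c("optimal_oligo", "amplicon")) {
    m <- condition_preset(preset)
    expect_lt(m$p_GtoX, min(m$p_AtoI, m$p_CtoU))
  }
  expect_error(condition_preset("bogus"), "unknown")
  expect_error(chemistry_model(p_AtoI = 1.2, p_CtoU = 0), "\\[0, 1\\]")
})

test_that("zero-rate chemistry reproduces the reference verbatim", {
  ref <- oligo_53mer()
  p <- sim_params(ref, n_molecules = 50L, position_rate_jitter = 0, seed = 1)
  sim <- simulate_reads(p, chemistry_model(p_AtoI = 0, p_CtoU = 0))
  expect_true(all(sim$reads$insert == ref$sequence))
  expect_true(all(nchar(sim$reads$umi) == 7L))
})

test_that("the deterministic limit converts every convertible base", {
  ref <- oligo_53mer()
  p <- sim_params(ref, stoichiometry = c("33" = 1), n_molecules = 30L,
                  position_rate_jitter = 0, seed = 2)
  sim <- simulate_reads(p, chemistry_model(p_AtoI = 1, p_CtoU = 1,
                                           p_GtoX = 0))
  refc <- strsplit(ref$sequence, "")[[1]]
  for (rd in sim$reads$insert) {
    ch <- strsplit(rd, "")[[1]]
    expect_true(all(ch[refc == "A" & seq_along(refc) != 33] == "G"))
    expect_true(all(ch[refc == "C"] == "T"))
    expect_equal(ch[33], "A")                      # protected m6A
    expect_equal(which(ch == "A"), 33L)            # the only A left
  }
})

test_that("empirical conversion frequencies match the generative rates", {
  ref <- oligo_53mer()
  p <- sim_params(ref, n_molecules = 10000L, position_rate_jitter = 0,
                  seed = 3)
  sim <- simulate_reads(p, chemistry_model(p_AtoI = 0.3, p_CtoU = 0.35))
  m <- do.call(rbind, strsplit(sim$reads$insert, ""))
  refc <- strsplit(ref$sequence, "")[[1]]
  se_a <- sqrt(0.3 * 0.7 / 10000)
  for (pos in which(refc == "A")) {
    expect_lt(abs(mean(m[, pos] == "G") - 0.3), 3 * se_a)
  }
  se_c <- sqrt(0.35 * 0.65 / 10000)
  for (pos in which(refc == "C")) {
    expect_lt(abs(mean(m[, pos] == "T") - 0.35), 3 * se_c)
  }
})

test_that("RT blockage at xanthosine biases survivors toward low deamination", {
  ref <- oligo_53mer()
  p <- sim_params(ref, n_molecules = 4000L, position_rate_jitter = 0,
                  seed = 4)
  sim <- simulate_reads(p, chemistry_model(p_AtoI = 0.3, p_CtoU = 0.3,
                                           p_GtoX = 0.15, p_X_block = 0.9))
  full <- is.na(sim$truth$truncated_at)
  expect_true(any(full) && any(!full))
  load <- sim$truth$n_A_conversions + sim$truth$n_C_conversions +
    sim$truth$n_X
  expect_lt(mean(load[full]), mean(load))
  # truncated reads end before their blocking lesion
  expect_true(all(nchar(sim$reads$insert[!full]) <
                    sim$truth$truncated_at[!full]))
})

test_that("MeRIP with unit enrichment and retention is a no-op in distribution", {
  ref <- oligo_53mer()
  frac <- function(merip, seed) {
    p <- sim_params(ref, stoichiometry = c("33" = 0.3), n_molecules = 4000L,
                    position_rate_jitter = 0, merip = merip, seed = seed)
    sim <- simulate_reads(p, accept_chem())
    mean(nchar(sim$truth$methylated_sites) > 0)
  }
  f_plain <- frac(NULL, 11)
  f_unit <- frac(list(enrichment_factor = 1, background_retention = 1), 11)
  se <- sqrt(0.3 * 0.7 / 4000)
  expect_lt(abs(f_plain - 0.3), 3 * se)
  expect_lt(abs(f_unit - 0.3), 4 * se)   # resampling adds a little variance
  # and a 10x enrichment is decidedly not a no-op
  f_enr <- frac(list(enrichment_factor = 10, background_retention = 1), 11)
  expect_gt(f_enr, 0.7)  # 0.3*10/(0.3*10+0.7) ~ 0.81
})

test_that("simulation is byte-identical under a fixed seed", {
  ref <- oligo_53mer()
  mk <- function() {
    p <- sim_params(ref, stoichiometry = c("33" = 0.5), n_molecules = 500L,
                    pcr_duplication_rate = 0.1, seed = 99)
    simulate_reads(p, condition_preset("optimal_oligo"))
  }
  s1 <- mk(); s2 <- mk()
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$truth, s2$truth)
})

test_that("stoichiometry for an unannotated position is rejected", {
  ref <- oligo_53mer()
  expect_error(sim_params(ref, stoichiometry = c("20" = 0.5)), "20")
  expect_error(sim_params(ref, stoichiometry = c("33" = 1.5)), "\\[0, 1\\]")
})
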