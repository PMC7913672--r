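test_that("the probability statistic matches an erf-based normal CDF", {
  z <- c(-8, -3.2, -1, -0.1, 0, 0.5, 1.644853, 2, 6)
  erf_cdf <- 0.5 * (1 + pracma::erf(z / sqrt(2)))
  got <- stats::pnorm(z)
  expect_true(all(abs(got - erf_cdf) < 1e-12))
  # and call_sites uses exactly that transform of its z scores
  res <- run_chain(oligo_53mer(), stoichiometry = c("33" = 1), n = 500L,
                   seed = 31)
  expect_equal(res$calls$probability,
               0.5 * (1 + pracma::erf(res$calls$z / sqrt(2))),
               tolerance = 1e-12)
})

test_that("an identical-rate distribution is a degenerate-distribution error", {
  ref <- oligo_53mer()
  aln <- align_all(rep(ref$sequence, 10), ref)
  expect_error(call_sites(tabulate_rates(aln)), "degenerate")
})

test_that("a fully methylated site is the unique candidate", {
  res <- run_chain(oligo_53mer(), stoichiometry = c("33" = 1), n = 10000L,
                   seed = 32)
  cand <- res$calls[res$calls$is_candidate, ]
  expect_equal(cand$position, 33L)
  expect_gt(cand$probability, 0.95)
  expect_gt(cand$a_rate, 0.99)
})

test_that("50% stoichiometry is detectable de novo (median over seeds)", {
  probs <- sapply(1:5, function(s) {
    res <- run_chain(oligo_53mer(), stoichiometry = c("33" = 0.5),
                     n = 10000L, seed = 40 + s)
    res$calls$probability[res$calls$position == 33]
  })
  expect_gt(median(probs), 0.95)
})

test_that("site probability is non-decreasing in stoichiometry", {
  med <- sapply(c(0, 0.25, 1), function(m) {
    median(sapply(1:5, function(s) {
      res <- run_chain(oligo_53mer(),
                       stoichiometry = setNames(m, "33"),
                       n = 6000L, seed = 50 + s)
      res$calls$probability[res$calls$position == 33]
    }))
  })
  expect_true(all(diff(med) > 0))
  expect_lt(med[1], 0.95)   # unmethylated site is not called
})

test_that("calls are invariant under read reordering", {
  ref <- oligo_53mer()
  p <- sim_params(ref, stoichiometry = c("33" = 0.6), n_molecules = 2000L,
                  seed = 33)
  sim <- simulate_reads(p, accept_chem())
  calls1 <- call_sites(tabulate_rates(align_all(sim$reads, ref)))
  perm <- sim$reads[sample(nrow(sim$reads)), ]
  class(perm) <- class(sim$reads)
  calls2 <- call_sites(tabulate_rates(align_all(perm, ref)))
  expect_equal(as.data.frame(calls1), as.data.frame(calls2))
})

test_that("leave-one-out sharpens the z score of a genuine site", {
  res <- run_chain(oligo_53mer(), stoichiometry = c("33" = 1), n = 5000L,
                   seed = 34)
  rt <- tabulate_rates(res$aln)
  incl <- call_sites(rt)
  loo <- call_sites(rt, leave_one_out = TRUE)
  expect_gt(loo$z[loo$position == 33], incl$z[incl$position == 33])
})

test_that("calibration fits exact lines and validates its inputs", {
  fit <- fit_calibration(data.frame(m6a_content = c(0, 0.5, 1),
                                    a_signal = c(0.3, 0.65, 1.0)))
  expect_equal(fit$slope, 0.7, tolerance = 1e-12)
  expect_equal(fit$intercept, 0.3, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(unname(coef(fit)), c(0.3, 0.7), tolerance = 1e-12)
  # inverse prediction, clipped to [0, 1]
  expect_equal(predict(fit, 0.65, inverse = TRUE), 0.5, tolerance = 1e-12)
  expect_equal(predict(fit, 1.5, inverse = TRUE), 1)
  expect_equal(predict(fit, 0, inverse = TRUE), 0)
  expect_error(fit_calibration(data.frame(m6a_content = c(0, 1),
                                          a_signal = c(0, 1))),
               "3 distinct")
  expect_error(fit_calibration(data.frame(m6a_content = c(1, 1, 1),
                                          a_signal = c(0, 0.5, 1))),
               "3 distinct")
})

test_that("MeRIP enrichment lifts sub-stoichiometric sites over the threshold", {
  ref <- oligo_53mer()
  med <- function(m) {
    reps <- lapply(1:5, function(s)
      merip_detection_experiment(ref, m, n_reads = 3000L,
                                 enrichment_factor = 10, seed = 60 + s))
    do.call(rbind, reps)
  }
  at0 <- med(0)
  expect_lt(median(at0$probability[at0$arm == "merip"]), 0.95)
  expect_lt(median(at0$probability[at0$arm == "non_merip"]), 0.95)

  at10 <- med(0.10)
  expect_gt(median(at10$probability[at10$arm == "merip"]), 0.95)
  expect_gt(median(at10$probability[at10$arm == "merip"]),
            median(at10$probability[at10$arm == "non_merip"]))

  at100 <- med(1)
  expect_true(all(tapply(at100$probability, at100$arm, median) > 0.95))
})
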