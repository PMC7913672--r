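#' Call m6A candidate sites from a rate table
#'
#' At every reference A position the A rate is standardized against the
#' distribution of A rates over all A positions (z = (a - mean) / sd, sample
#' SD) and converted to a probability with the cumulative normal
#' distribution. Positions whose probability exceeds the detection threshold
#' (default 0.95, strict) behave significantly differently from the bulk of
#' A positions -- they resisted deamination -- and are flagged as m6A
#' candidates. The test is one-sided: only abnormally high A rates indicate
#' m6A; abnormally low outliers are reported as QC warnings via an
#' attribute, never as candidates.
#'
#' @param rate_table A \code{\link{tabulate_rates}} result with at least 3 A
#'   positions.
#' @param threshold Detection threshold on the probability (default 0.95).
#' @param leave_one_out If TRUE, the mean and SD for each position are
#'   computed from the other A positions only. Default FALSE: the candidate
#'   is included, which is conservative (a strong site inflates the SD).
#' @return A data.frame of class \code{noseq_calls}, one row per A position,
#'   sorted by position: \code{position}, \code{a_rate}, \code{z},
#'   \code{probability}, \code{is_candidate}. Attribute \code{low_outliers}
#'   lists positions whose probability falls below 1 - threshold.
#' @export
call_sites <- function(rate_table, threshold = 0.95, leave_one_out = FALSE) {
  stopifnot(inherits(rate_table, "noseq_rates"))
  if (threshold <= 0 || threshold >= 1) {
    stop("threshold must lie strictly between 0 and 1", call. = FALSE)
  }
  aidx <- rate_table$ref_base == "A"
  pos <- rate_table$position[aidx]
  a <- rate_table$a_rate[aidx]
  if (length(a) < 3L) {
    stop("need at least 3 A positions to form the rate distribution",
         call. = FALSE)
  }
  if (leave_one_out) {
    n <- length(a)
    mu <- (sum(a) - a) / (n - 1L)
    s2 <- vapply(seq_len(n), function(i) stats::var(a[-i]), numeric(1L))
    sdv <- sqrt(s2)
  } else {
    mu <- mean(a)
    sdv <- stats::sd(a)
  }
  if (any(sdv == 0)) {
    stop("degenerate A-rate distribution (zero variance): no call possible",
         call. = FALSE)
  }
  z <- (a - mu) / sdv
  p <- stats::pnorm(z)
  out <- data.frame(position = pos, a_rate = a, z = z, probability = p,
                    is_candidate = p > threshold)
  out <- out[order(out$position), ]
  rownames(out) <- NULL
  structure(out, class = c("noseq_calls", "data.frame"),
            threshold = threshold,
            leave_one_out = leave_one_out,
            low_outliers = pos[p < 1 - threshold])
}

#' @export
print.noseq_calls <- function(x, ...) {
  thr <- attr(x, "threshold")
  cat("m6A candidate calls over ", nrow(x), " A positions (threshold ",
      thr, ")\n", sep = "")
  cand <- x[x$is_candidate, ]
  if (nrow(cand) == 0L) {
    cat("  no candidate sites\n")
  } else {
    for (i in seq_len(nrow(cand))) {
      cat(sprintf("  position %d: A rate %.3f, probability %.4f\n",
                  cand$position[i], cand$a_rate[i], cand$probability[i]))
    }
  }
  lo <- attr(x, "low_outliers")
  if (length(lo) > 0L) {
    cat("  QC: abnormally LOW A rate at position(s) ",
        paste(lo, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Probability plot of candidate calls
#'
#' Probability of each A position behaving differently from the bulk,
#' with the detection threshold as a red line.
#'
#' @param x A \code{\link{call_sites}} result.
#' @param ... Passed to \code{\link[graphics]{plot}}.
#' @export
#' @method plot noseq_calls
plot.noseq_calls <- function(x, ...) {
  graphics::plot(x$position, x$probability, pch = 19, ylim = c(0, 1),
                 xlab = "reference position (A sites)",
                 ylab = "probability", ...)
  graphics::abline(h = attr(x, "threshold"), col = "red", lwd = 2)
  if (any(x$is_candidate)) {
    graphics::points(x$position[x$is_candidate],
                     x$probability[x$is_candidate],
                     pch = 19, col = "red")
  }
  invisible(x)
}

#' Fit the m6A stoichiometry calibration line
#'
#' Ordinary least-squares fit of the A signal at the modified site against
#' the known m6A content of a calibration titration. Under partial
#' deamination with A-to-I conversion rate p, the expected A signal at the
#' site is m + (1 - m) (1 - p): a line in the m6A content m with slope p and
#' intercept 1 - p, so a clean titration recovers the conversion rate as the
#' slope. Inverse prediction (signal -> estimated content, clipped to [0,1])
#' is available through \code{\link{predict.noseq_calibration}}.
#'
#' @param points A data.frame (or list) with components/columns
#'   \code{m6a_content} (in [0,1]) and \code{a_signal}.
#' @return An object of class \code{noseq_calibration} wrapping the
#'   \code{\link[stats]{lm}} fit, with \code{coef}, \code{predict},
#'   \code{print} and \code{plot} methods.
#' @examples
#' fit <- fit_calibration(data.frame(m6a_content = c(0, .5, 1),
#'                                   a_signal = c(.3, .65, 1)))
#' coef(fit)   # intercept 0.3, slope 0.7
#' @export
fit_calibration <- function(points) {
  points <- as.data.frame(points)
  stopifnot(all(c("m6a_content", "a_signal") %in% names(points)))
  if (length(unique(points$m6a_content)) < 3L) {
    stop("need at least 3 distinct m6a_content values for calibration",
         call. = FALSE)
  }
  fit <- stats::lm(a_signal ~ m6a_content, data = points)
  # direct r^2 (summary.lm warns on exact lines, a legitimate input here)
  sst <- sum((points$a_signal - mean(points$a_signal))^2)
  r2 <- if (sst == 0) 1 else 1 - sum(stats::residuals(fit)^2) / sst
  structure(list(points = points, fit = fit,
                 slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = r2),
            class = "noseq_calibration")
}

#' @export
#' @method coef noseq_calibration
coef.noseq_calibration <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' Predict from a calibration fit
#'
#' Forward prediction maps m6A content to expected A signal; inverse
#' prediction maps an observed A signal to the estimated m6A content,
#' clipped to [0, 1].
#'
#' @param object A \code{\link{fit_calibration}} result.
#' @param newdata Numeric vector: m6A contents (forward) or A signals
#'   (inverse).
#' @param inverse If TRUE, perform inverse prediction (default FALSE).
#' @param ... Unused.
#' @export
#' @method predict noseq_calibration
predict.noseq_calibration <- function(object, newdata, inverse = FALSE, ...) {
  if (inverse) {
    est <- (newdata - object$intercept) / object$slope
    pmin(1, pmax(0, est))
  } else {
    object$intercept + object$slope * newdata
  }
}

#' @export
print.noseq_calibration <- function(x, ...) {
  cat(sprintf(paste0("m6A stoichiometry calibration: a_signal = %.4f + ",
                     "%.4f * m6a_content (r^2 = %.4f, %d points)\n"),
              x$intercept, x$slope, x$r_squared, nrow(x$points)))
  invisible(x)
}

#' @export
#' @method plot noseq_calibration
plot.noseq_calibration <- function(x, ...) {
  graphics::plot(x$points$m6a_content, x$points$a_signal, pch = 19,
                 xlab = "m6A content", ylab = "A signal at site", ...)
  graphics::abline(x$fit, col = "red")
  invisible(x)
}

#' Simulated detection-threshold experiment (MeRIP vs. non-MeRIP)
#'
#' Runs the full simulate -> align -> tabulate -> call chain over a grid of
#' m6A stoichiometries, with and without a MeRIP enrichment stage, and
#' reports the probability statistic at the modified site per condition.
#' Enrichment boosts the methylated-read fraction and thereby lifts
#' low-stoichiometry sites above the detection threshold, at the cost of the
#' linear stoichiometry-to-signal relationship.
#'
#' @param reference A \code{\link{reference_amplicon}} with exactly one
#'   annotated site.
#' @param stoichiometries Numeric vector of m6A fractions to scan.
#' @param chem A \code{\link{chemistry_model}}.
#' @param n_reads Reads per simulated library.
#' @param enrichment_factor MeRIP enrichment weight for methylated molecules.
#' @param background_retention MeRIP retention of unmethylated molecules.
#' @param threshold Calling threshold (default 0.95).
#' @param jitter Per-position rate jitter sigma (default 0.15).
#' @param seed Base RNG seed.
#' @return A data.frame with one row per (stoichiometry, arm): the
#'   probability at the site, its A rate and whether it was called.
#' @export
merip_detection_experiment <- function(reference, stoichiometries,
                                       chem = condition_preset("optimal_oligo"),
                                       n_reads = 10000L,
                                       enrichment_factor = 10,
                                       background_retention = 1,
                                       threshold = 0.95,
                                       jitter = 0.15,
                                       seed = 1L) {
  stopifnot(inherits(reference, "noseq_reference"),
            length(reference$modified_positions) == 1L)
  site <- reference$modified_positions
  merip <- list(enrichment_factor = enrichment_factor,
                background_retention = background_retention)
  rows <- list()
  for (m in stoichiometries) {
    for (arm in c("non_merip", "merip")) {
      p <- sim_params(reference,
                      stoichiometry = setNames(m, site),
                      n_molecules = n_reads,
                      position_rate_jitter = jitter,
                      merip = if (arm == "merip") merip else NULL,
                      seed = seed + round(1000 * m) + (arm == "merip"))
      sim <- simulate_reads(p, chem)
      aln <- align_all(sim$reads, reference)
      calls <- call_sites(tabulate_rates(aln), threshold = threshold)
      hit <- calls[calls$position == site, ]
      rows[[length(rows) + 1L]] <-
        data.frame(stoichiometry = m, arm = arm,
                   a_rate = hit$a_rate, probability = hit$probability,
                   is_candidate = hit$is_candidate)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
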