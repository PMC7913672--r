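#' The deamination condition screening grid
#'
#' Enumerates the full wet-lab screening grid of nitrous-acid deamination
#' conditions: reaction temperature (50, 60, 70 deg C) x buffer pH (3.5,
#' 4.0, 4.5, 5.0) x incubation time (1, 3, 5, 10, 20, 30 min) = 72
#' conditions, in deterministic order (temperature, then pH, then time,
#' each ascending).
#'
#' @return A data.frame with columns \code{temperature_C}, \code{pH},
#'   \code{time_min}, \code{label}; exactly 72 rows.
#' @examples
#' nrow(condition_grid())   # 72
#' @export
condition_grid <- function() {
  g <- expand.grid(time_min = c(1, 3, 5, 10, 20, 30),
                   pH = c(3.5, 4.0, 4.5, 5.0),
                   temperature_C = c(50, 60, 70),
                   KEEP.OUT.ATTRS = FALSE)
  g <- g[, c("temperature_C", "pH", "time_min")]
  g$label <- sprintf("%gC_pH%.1f_%gmin", g$temperature_C, g$pH, g$time_min)
  rownames(g) <- NULL
  g
}

#' Conversion chemistry of a partial deamination treatment
#'
#' Captures the per-base conversion probabilities a deamination condition
#' induces, as seen by the sequencer after reverse transcription (RT):
#' unmethylated A deaminates to inosine and reads as G; C deaminates to U
#' and reads as T; G deaminates (more slowly) to xanthosine (X), which
#' slows/blocks RT and, on read-through, mostly keeps its G signal with a
#' minor A component. m6A resists deamination and keeps a pure A signal;
#' its nitrosation product (NOm6A) is carried as a formation probability
#' with configurable read-out behaviour since its base pairing is not
#' established.
#'
#' @param p_AtoI Per-base probability that an unmethylated A is deaminated
#'   (reads as G).
#' @param p_CtoU Per-base probability that a C is deaminated (reads as T).
#' @param p_GtoX Per-base probability that a G is deaminated to xanthosine.
#' @param p_X_reads_A Given RT reads through an X, probability it is read as
#'   A (else G).
#' @param p_X_block Probability that RT terminates at a given X.
#' @param p_m6A_deaminated Probability that an m6A behaves like an
#'   unmethylated A (default 0: full protection).
#' @param p_NOm6A Probability that a methylated site forms NOm6A.
#' @param nom6a_behavior Read-out behaviour of NOm6A: \code{"reads_A"}
#'   (default; indistinguishable from untouched m6A) or \code{"blocks_RT"}.
#' @param nom6a_block_weight Mixing weight: probability that a formed NOm6A
#'   actually blocks RT when \code{nom6a_behavior = "blocks_RT"}.
#' @param seq_error_rate Optional uniform per-base sequencing error rate
#'   (default 0).
#' @return A list of class \code{noseq_chemistry}.
#' @export
chemistry_model <- function(p_AtoI, p_CtoU, p_GtoX = 0,
                            p_X_reads_A = 0.1, p_X_block = 0,
                            p_m6A_deaminated = 0, p_NOm6A = 0,
                            nom6a_behavior = c("reads_A", "blocks_RT"),
                            nom6a_block_weight = 1,
                            seq_error_rate = 0) {
  nom6a_behavior <- match.arg(nom6a_behavior)
  probs <- c(p_AtoI = p_AtoI, p_CtoU = p_CtoU, p_GtoX = p_GtoX,
             p_X_reads_A = p_X_reads_A, p_X_block = p_X_block,
             p_m6A_deaminated = p_m6A_deaminated, p_NOm6A = p_NOm6A,
             nom6a_block_weight = nom6a_block_weight,
             seq_error_rate = seq_error_rate)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    stop("all chemistry probabilities must lie in [0, 1]", call. = FALSE)
  }
  structure(c(as.list(probs), list(nom6a_behavior = nom6a_behavior)),
            class = "noseq_chemistry")
}

#' Chemistry presets for the documented working conditions
#'
#' Two presets encode the published working regimes. \code{"optimal_oligo"}
#' mirrors the condition used for the synthetic-oligo calibration work
#' (50 deg C, pH 4.0, 20 min): A-to-I conversion in the useful 10--50\%
#' window (default 0.30), C faster than A, G much slower. \code{"amplicon"}
#' mirrors the milder condition used for biological amplicons (60 deg C,
#' pH 5.0, 10 min) with correspondingly lower rates. The published record
#' reports ranges and orderings rather than exact constants; the preset
#' numbers sit mid-range and respect the orderings (see the methods
#' vignette).
#'
#' @param name \code{"optimal_oligo"} or \code{"amplicon"}.
#' @return A \code{\link{chemistry_model}}.
#' @examples
#' condition_preset("optimal_oligo")$p_AtoI   # 0.3
#' @export
condition_preset <- function(name) {
  switch(as.character(name),
    optimal_oligo = chemistry_model(p_AtoI = 0.30, p_CtoU = 0.35,
                                    p_GtoX = 0.03, p_X_reads_A = 0.1,
                                    p_X_block = 0.8, p_NOm6A = 0.30),
    amplicon = chemistry_model(p_AtoI = 0.15, p_CtoU = 0.20,
                               p_GtoX = 0.01, p_X_reads_A = 0.1,
                               p_X_block = 0.8, p_NOm6A = 0.05),
    stop("unknown chemistry preset '", name,
         "'; available: optimal_oligo, amplicon", call. = FALSE)
  )
}

#' Simulation parameters for a synthetic amplicon library
#'
#' @param reference A \code{\link{reference_amplicon}}.
#' @param stoichiometry Named numeric vector: per-site m6A fraction in [0,1],
#'   names are annotated modified positions of the reference. Unnamed sites
#'   default to 0.
#' @param n_molecules Number of reads to emit.
#' @param pcr_duplication_rate Expected fraction of reads that are PCR
#'   re-reads of an earlier molecule (same UMI).
#' @param umi_length UMI length in nt (default 7); 0 disables UMIs.
#' @param position_rate_jitter Log-normal sigma of the per-position
#'   multiplicative noise on p_AtoI and p_CtoU, modelling site-to-site
#'   reactivity variance (default 0.15).
#' @param merip Optional MeRIP enrichment model:
#'   \code{list(enrichment_factor = >=1, background_retention = [0,1])}.
#'   Reads of methylated molecules are retained with weight
#'   \code{enrichment_factor}, unmethylated with \code{background_retention},
#'   renormalized to \code{n_molecules} output reads.
#' @param seed RNG seed (integer) for reproducibility.
#' @return A list of class \code{noseq_sim_params}.
#' @export
sim_params <- function(reference, stoichiometry = numeric(),
                       n_molecules = 10000L, pcr_duplication_rate = 0,
                       umi_length = 7L, position_rate_jitter = 0.15,
                       merip = NULL, seed = NULL) {
  stopifnot(inherits(reference, "noseq_reference"))
  if (length(stoichiometry) > 0L) {
    pos <- as.integer(names(stoichiometry))
    if (anyNA(pos)) {
      stop("stoichiometry must be a named vector keyed by position",
           call. = FALSE)
    }
    bad <- setdiff(pos, reference$modified_positions)
    if (length(bad) > 0L) {
      stop("stoichiometry given for position(s) not annotated as modified: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    if (any(stoichiometry < 0 | stoichiometry > 1)) {
      stop("stoichiometry values must lie in [0, 1]", call. = FALSE)
    }
  }
  if (!is.null(merip)) {
    stopifnot(is.list(merip),
              all(c("enrichment_factor", "background_retention") %in%
                    names(merip)))
    if (merip$enrichment_factor < 1) {
      stop("merip enrichment_factor must be >= 1", call. = FALSE)
    }
    if (merip$background_retention < 0 || merip$background_retention > 1) {
      stop("merip background_retention must lie in [0, 1]", call. = FALSE)
    }
  }
  structure(list(reference = reference,
                 stoichiometry = stoichiometry,
                 n_molecules = as.integer(n_molecules),
                 pcr_duplication_rate = pcr_duplication_rate,
                 umi_length = as.integer(umi_length),
                 position_rate_jitter = position_rate_jitter,
                 merip = merip,
                 seed = seed),
            class = "noseq_sim_params")
}

#' Simulate a partially deaminated amplicon read set
#'
#' Generates reads with the statistical structure of a partially deaminated
#' amplicon library. Per molecule: (1) the methylation state of each
#' annotated site is drawn from its stoichiometry; (2) conversion events are
#' drawn independently per base with position-jittered rates; (3) each
#' xanthosine may terminate reverse transcription (scanning 5'->3' along the
#' read), emitting a truncated read -- such reads are later rejected by the
#' aligner's coverage filter, reproducing the survivor bias toward
#' under-deaminated molecules; (4) read-out follows the deamination rules
#' (converted A -> G, converted C -> T, read-through X -> A or G, m6A -> A);
#' (5) a random UMI is attached; (6) PCR duplicates (same molecule, same
#' UMI) are injected; (7) an optional MeRIP enrichment resamples reads in
#' favour of methylated molecules.
#'
#' @param params A \code{\link{sim_params}} object.
#' @param chem A \code{\link{chemistry_model}}.
#' @return A list of class \code{noseq_sim} with elements \code{reads}
#'   (a \code{\link{structured_reads}} table) and \code{truth} (a data.frame
#'   logging, per emitted read, the source molecule, duplicate status,
#'   per-site methylation state, conversion-event counts, truncation point
#'   and a compact event string).
#' @export
simulate_reads <- function(params, chem) {
  stopifnot(inherits(params, "noseq_sim_params"),
            inherits(chem, "noseq_chemistry"))
  if (!is.null(params$seed)) set.seed(params$seed)

  ref <- params$reference
  refc <- strsplit(ref$sequence, "")[[1L]]
  L <- length(refc)
  n <- params$n_molecules
  if (n < 1L) stop("n_molecules must be >= 1", call. = FALSE)

  a_pos <- which(refc == "A")
  c_pos <- which(refc == "C")
  g_pos <- which(refc == "G")
  sites <- ref$modified_positions
  stoich <- setNames(rep(0, length(sites)), sites)
  if (length(params$stoichiometry) > 0L) {
    stoich[names(params$stoichiometry)] <- params$stoichiometry
  }

  # per-position reactivity jitter (log-normal, multiplicative on the rate)
  sj <- params$position_rate_jitter
  jit <- if (sj > 0) exp(stats::rnorm(L, 0, sj)) else rep(1, L)
  rate_A <- pmin(1, chem$p_AtoI * jit)
  rate_C <- pmin(1, chem$p_CtoU * jit)

  # methylation state per molecule x site
  meth <- matrix(FALSE, n, length(sites))
  for (s in seq_along(sites)) {
    meth[, s] <- stats::runif(n) < stoich[s]
  }

  # conversion events
  out <- matrix(rep(refc, each = n), nrow = n)   # n x L read-out matrix
  convA <- matrix(FALSE, n, length(a_pos))
  for (j in seq_along(a_pos)) {
    p <- a_pos[j]
    convertible <- rep(TRUE, n)
    s <- match(p, sites)
    if (!is.na(s)) {
      behaves_unmeth <- stats::runif(n) < chem$p_m6A_deaminated
      convertible <- !meth[, s] | behaves_unmeth
    }
    convA[, j] <- convertible & (stats::runif(n) < rate_A[p])
  }
  out[, a_pos][convA] <- "G"

  convC <- matrix(stats::runif(n * length(c_pos)), n) <
    matrix(rate_C[c_pos], n, length(c_pos), byrow = TRUE)
  if (length(c_pos) > 0L) out[, c_pos][convC] <- "T"

  # G -> xanthosine; read-through signal and RT blockage
  isX <- matrix(stats::runif(n * length(g_pos)), n) < chem$p_GtoX
  trunc_at <- rep(NA_integer_, n)
  if (length(g_pos) > 0L && any(isX)) {
    blocked <- isX & (matrix(stats::runif(n * length(g_pos)), n) <
                        chem$p_X_block)
    if (any(blocked)) {
      first_block <- apply(blocked, 1L, function(b) {
        w <- which(b)
        if (length(w) == 0L) NA_integer_ else g_pos[w[1L]]
      })
      trunc_at <- as.integer(first_block)
    }
    x_read_A <- isX & (matrix(stats::runif(n * length(g_pos)), n) <
                         chem$p_X_reads_A)
    out[, g_pos][isX] <- "G"
    out[, g_pos][x_read_A] <- "A"
  }

  # NOm6A at methylated sites: optional RT block
  if (length(sites) > 0L && chem$p_NOm6A > 0 &&
      chem$nom6a_behavior == "blocks_RT") {
    for (s in seq_along(sites)) {
      nob <- meth[, s] & (stats::runif(n) < chem$p_NOm6A) &
        (stats::runif(n) < chem$nom6a_block_weight)
      trunc_at <- ifelse(nob & (is.na(trunc_at) | sites[s] < trunc_at),
                         sites[s], trunc_at)
    }
    trunc_at <- as.integer(trunc_at)
  }

  # uniform sequencing error (default off)
  if (chem$seq_error_rate > 0) {
    err <- which(matrix(stats::runif(n * L), n) < chem$seq_error_rate)
    if (length(err) > 0L) {
      cur <- out[err]
      alt <- vapply(cur, function(b) {
        sample(setdiff(c("A", "C", "G", "T"), b), 1L)
      }, character(1L))
      out[err] <- alt
    }
  }

  reads <- do.call(paste0, as.data.frame(out, stringsAsFactors = FALSE))
  # RT termination at a blocking lesion: emit the fragment up to (not
  # including) the blocked position
  tr <- !is.na(trunc_at)
  reads[tr] <- substr(reads[tr], 1L, trunc_at[tr] - 1L)

  umis <- if (params$umi_length > 0L) random_umis(n, params$umi_length)
          else rep(NA_character_, n)

  nAconv <- rowSums(convA)
  nCconv <- if (length(c_pos) > 0L) rowSums(convC) else rep(0L, n)
  nX <- if (length(g_pos) > 0L) rowSums(isX) else rep(0L, n)
  meth_str <- if (length(sites) == 0L) "" else
    apply(meth, 1L, function(m) paste(sites[m], collapse = ","))

  mol <- data.frame(molecule = sprintf("mol%06d", seq_len(n)),
                    sequence = reads,
                    umi = umis,
                    methylated_sites = meth_str,
                    n_A_conversions = nAconv,
                    n_C_conversions = nCconv,
                    n_X = nX,
                    truncated_at = trunc_at,
                    stringsAsFactors = FALSE)

  # PCR duplication: each read after the first is, with probability r, a
  # re-read of an earlier molecule (same sequence and UMI)
  r <- params$pcr_duplication_rate
  src <- seq_len(n)
  is_dup <- rep(FALSE, n)
  if (r > 0 && n > 1L) {
    is_dup <- c(FALSE, stats::runif(n - 1L) < r)
    for (i in which(is_dup)) {
      src[i] <- src[sample.int(i - 1L, 1L)]
    }
  }
  emitted <- mol[src, ]
  emitted$is_duplicate <- is_dup

  # MeRIP enrichment: weight methylated molecules up, renormalize to n reads
  if (!is.null(params$merip)) {
    w <- ifelse(nchar(emitted$methylated_sites) > 0L,
                params$merip$enrichment_factor,
                params$merip$background_retention)
    if (all(w == 0)) {
      stop("MeRIP model retained no reads (all weights zero)", call. = FALSE)
    }
    keep <- sample.int(nrow(emitted), n, replace = TRUE, prob = w)
    emitted <- emitted[keep, ]
  }

  read_id <- sprintf("read%06d", seq_len(nrow(emitted)))
  truth <- data.frame(read_id = read_id,
                      emitted[, c("molecule", "is_duplicate",
                                  "methylated_sites", "n_A_conversions",
                                  "n_C_conversions", "n_X", "truncated_at")],
                      stringsAsFactors = FALSE)
  rownames(truth) <- NULL

  structure(
    list(reads = structured_reads(read_id, emitted$sequence, emitted$umi,
                                  strrep("I", nchar(emitted$sequence))),
         truth = truth,
         site_rates = data.frame(position = seq_len(L), ref_base = refc,
                                 p_AtoI = ifelse(refc == "A", rate_A, NA),
                                 p_CtoU = ifelse(refc == "C", rate_C, NA))),
    class = "noseq_sim")
}

random_umis <- function(n, len) {
  m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE), n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

#' @export
print.noseq_sim <- function(x, ...) {
  cat("Simulated deaminated read set: ", nrow(x$reads), " reads\n", sep = "")
  ntr <- sum(!is.na(x$truth$truncated_at))
  cat("  truncated by RT block: ", ntr, "\n", sep = "")
  cat("  PCR duplicates: ", sum(x$truth$is_duplicate), "\n", sep = "")
  meth <- sum(nchar(x$truth$methylated_sites) > 0L)
  cat("  reads from methylated molecules: ", meth, "\n", sep = "")
  invisible(x)
}
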