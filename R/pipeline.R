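#' Run the full amplicon m6A detection pipeline
#'
#' Orchestrates simulate (or load) -> align -> rates -> call -> UMI
#' assessment with reproducible seeding, writes every stage table as TSV
#' plus a JSON manifest (seed, filtering funnel, candidate list, file
#' checksums), and returns the assembled result object.
#'
#' @param config A named list (or path to a YAML file) with entries:
#'   \describe{
#'     \item{reference}{path to a FASTA file, or a
#'       \code{\link{reference_amplicon}} object.}
#'     \item{modified_positions}{integer vector of annotated m6A positions
#'       (when \code{reference} is a path).}
#'     \item{reads}{path to a FASTQ file of real reads; omit to simulate.}
#'     \item{simulate}{when \code{reads} is absent: list with
#'       \code{preset} (chemistry preset name) or \code{chemistry}
#'       (a \code{\link{chemistry_model}}), plus any \code{\link{sim_params}}
#'       arguments (\code{stoichiometry}, \code{n_molecules}, ...).}
#'     \item{umi}{UMI layout: \code{list(placement=, umi_length=)}; default
#'       trailing 7 nt for simulated data, none for loaded FASTQ.}
#'     \item{k, matrix, window, threshold}{aligner / caller settings.}
#'     \item{output_dir}{where to write tables, plots and the manifest;
#'       omit to skip writing.}
#'     \item{seed}{integer RNG seed, recorded in the manifest.}
#'   }
#' @return An object of class \code{noseq_result} with elements
#'   \code{reference}, \code{sim} (NULL for real data), \code{alignment},
#'   \code{rates}, \code{calls}, \code{redundancy} (NULL without UMIs) and
#'   \code{manifest}.
#' @export
noseq_run <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) {
      stop("config file not found: ", config, call. = FALSE)
    }
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))

  reference <- config$reference
  if (is.character(reference)) {
    if (!file.exists(reference)) {
      stop("reference path not found: ", reference, call. = FALSE)
    }
    reference <- read_reference(reference,
                                as.integer(config$modified_positions))
  }
  stopifnot(inherits(reference, "noseq_reference"))
  if (!is.null(config$reads) && !file.exists(config$reads)) {
    stop("reads path not found: ", config$reads, call. = FALSE)
  }

  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  threshold <- if (is.null(config$threshold)) 0.95 else config$threshold
  k <- if (is.null(config$k)) 11L else as.integer(config$k)
  matrix <- if (is.null(config$matrix)) substitution_matrix()
            else if (is.character(config$matrix))
              read_substitution_matrix(config$matrix)
            else validate_matrix(config$matrix)

  sim <- NULL
  if (is.null(config$reads)) {
    sc <- config$simulate
    if (is.null(sc)) sc <- list()
    chem <- if (!is.null(sc$chemistry)) sc$chemistry
            else condition_preset(if (is.null(sc$preset)) "optimal_oligo"
                                  else sc$preset)
    stoich <- sc$stoichiometry
    if (is.null(stoich) && length(reference$modified_positions) > 0L) {
      stoich <- setNames(rep(1, length(reference$modified_positions)),
                         reference$modified_positions)
    }
    args <- sc[setdiff(names(sc), c("preset", "chemistry", "stoichiometry"))]
    params <- do.call(sim_params,
                      c(list(reference = reference,
                             stoichiometry = if (is.null(stoich)) numeric()
                                             else stoich,
                             seed = seed),
                        args))
    sim <- simulate_reads(params, chem)
    reads <- sim$reads
  } else {
    spec <- if (is.null(config$umi)) umi_spec("none")
            else do.call(umi_spec, config$umi)
    reads <- read_structured_fastq(config$reads, spec)
  }

  alignment <- align_all(reads, reference, k = k, matrix = matrix,
                         window = config$window)
  rates <- tabulate_rates(alignment)
  calls <- call_sites(rates, threshold = threshold)
  redundancy <- if (!anyNA(alignment$accepted$umi) &&
                    nrow(alignment$accepted) > 0L) {
    assess_redundancy(alignment)
  }

  manifest <- list(seed = seed, k = k, threshold = threshold,
                   reference = reference$name,
                   reference_length = nchar(reference$sequence),
                   funnel = as.list(alignment$stats),
                   candidates = calls$position[calls$is_candidate],
                   files = list())

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    manifest$files <- write_outputs(config$output_dir, sim, alignment, rates,
                                    calls, redundancy, manifest)
  }

  structure(list(reference = reference, sim = sim, alignment = alignment,
                 rates = rates, calls = calls, redundancy = redundancy,
                 manifest = manifest),
            class = "noseq_result")
}

write_outputs <- function(dir, sim, alignment, rates, calls, redundancy,
                          manifest) {
  paths <- character()
  wtsv <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths[[name]] <<- p
  }
  if (!is.null(sim)) {
    wtsv(sim$truth, "truth.tsv")
    write_structured_fastq(sim$reads, file.path(dir, "reads.fastq"),
                           umi_spec(if (anyNA(sim$reads$umi)) "none"
                                    else "trailing",
                                    umi_length = if (anyNA(sim$reads$umi)) 7L
                                    else nchar(sim$reads$umi[1L])))
    paths[["reads.fastq"]] <- file.path(dir, "reads.fastq")
  }
  wtsv(alignment$decisions, "alignment_decisions.tsv")
  write_sam(alignment, file.path(dir, "accepted.sam"))
  paths[["accepted.sam"]] <- file.path(dir, "accepted.sam")
  wtsv(as.data.frame(rates), "rates.tsv")
  wtsv(as.data.frame(calls), "calls.tsv")
  if (!is.null(redundancy)) {
    wtsv(data.frame(metric = c("total_reads", "distinct_umis",
                               "duplicate_reads", "redundancy_fraction",
                               "collision_floor"),
                    value = c(redundancy$total_reads,
                              redundancy$distinct_umis,
                              redundancy$duplicate_reads,
                              redundancy$redundancy_fraction,
                              redundancy$collision_floor)),
         "umi_redundancy.tsv")
  }
  for (plt in c("rates", "calls")) {
    p <- file.path(dir, paste0(plt, ".png"))
    grDevices::png(p, width = 900, height = 480)
    if (plt == "rates") plot(rates) else plot(calls)
    grDevices::dev.off()
    paths[[paste0(plt, ".png")]] <- p
  }
  files <- lapply(paths, function(p) {
    list(path = basename(p), md5 = unname(tools::md5sum(p)))
  })
  manifest$files <- files
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files
}

#' @export
print.noseq_result <- function(x, ...) {
  cat("== noseq pipeline result ==\n")
  print(x$reference)
  print(x$alignment)
  print(x$calls)
  if (!is.null(x$redundancy)) print(x$redundancy)
  invisible(x)
}

#' Zero-download demonstration on the built-in 53-mer
#'
#' Simulates a fully methylated, partially deaminated library of the
#' built-in 53-mer calibration oligo under the optimal-oligo chemistry
#' preset and runs the complete pipeline. The expected outcome is a single
#' candidate call at position 33.
#'
#' @param output_dir Optional directory for the stage outputs and manifest.
#' @param n_reads Number of simulated reads (default 5000).
#' @param seed RNG seed.
#' @return A \code{\link{noseq_run}} result.
#' @examples
#' \donttest{
#' res <- noseq_demo()
#' res$calls[res$calls$is_candidate, ]
#' }
#' @export
noseq_demo <- function(output_dir = NULL, n_reads = 5000L, seed = 1L) {
  noseq_run(list(reference = oligo_53mer(),
                 simulate = list(preset = "optimal_oligo",
                                 stoichiometry = c("33" = 1),
                                 n_molecules = n_reads,
                                 pcr_duplication_rate = 0.10),
                 output_dir = output_dir,
                 seed = seed))
}
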