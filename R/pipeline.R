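# End-to-end entry points: each runs a complete analysis from an input
# table (or simulation config) and writes TSV/JSON outputs plus a run
# manifest under an output directory. A thin command-line wrapper over
# these functions ships in inst/scripts/sloanfit.R.

#' Assemble a pipeline run configuration
#'
#' Defaults mirror the standard analysis settings: rarefaction to 1,000
#' reads per sample, headline statistics averaged over R = 100 independent
#' rarefactions, detection threshold d = 1/N (one read) and B = 100
#' bootstrap replicates.
#'
#' @param input path to a delimited OTU table (see [readOtuTable()]), or
#'   NULL when the command generates its own data.
#' @param outdir output directory (created if missing).
#' @param depth rarefaction depth, default 1000.
#' @param rarefactions number of independent rarefactions R, default 100.
#' @param d detection threshold; NULL means 1/depth.
#' @param B bootstrap replicates, default 100.
#' @param seed master seed, default 1.
#' @param sep input field separator.
#' @param orientation input table orientation.
#' @return a `RunConfig` list.
#' @export
runConfig <- function(input = NULL, outdir = tempfile("sloanfit_"),
                      depth = 1000L, rarefactions = 100L, d = NULL,
                      B = 100L, seed = 1L, sep = "\t",
                      orientation = "taxa_rows") {
  structure(list(input = input, outdir = outdir, depth = as.integer(depth),
                 rarefactions = as.integer(rarefactions), d = d,
                 B = as.integer(B), seed = as.integer(seed), sep = sep,
                 orientation = orientation),
            class = "RunConfig")
}

.ensureOutdir <- function(config) {
  if (!dir.exists(config$outdir))
    dir.create(config$outdir, recursive = TRUE)
  config$outdir
}

.writeManifest <- function(config, command, extra = list()) {
  manifest <- c(list(command = command,
                     package_version =
                       as.character(utils::packageVersion("SloanFit")),
                     r_version = as.character(getRversion())),
                unclass(config), extra)
  manifest <- manifest[!vapply(manifest, is.null, logical(1))]
  path <- file.path(config$outdir, paste0(command, "_manifest.json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

.loadInput <- function(config) {
  if (is.null(config$input)) stop("config$input is required", call. = FALSE)
  readOtuTable(config$input, sep = config$sep,
               orientation = config$orientation)
}

#' Run the full neutral-fit analysis on an OTU table
#'
#' Pipeline: R independent rarefactions to the target depth; on each, the
#' occurrence-abundance statistics, the neutral fit, the binomial
#' comparison. Headline numbers (m, R-squared, both AICs) are reported as
#' means over the R rarefactions; the per-taxon table, band
#' classification and plot come from a reference rarefaction (the first
#' substream). Bootstrap CIs over hosts are attached to the reference
#' rarefaction. Outputs under `config$outdir`: `fit_summary.json`,
#' `fit_taxa.tsv`, `fit_plot.pdf`, `drop_log.txt`, and a manifest.
#'
#' @param config a [runConfig()] list.
#' @param plot write the occurrence-abundance figure, default TRUE.
#' @return invisibly, a list with the summary, the reference
#'   [NeutralFit-class] and the bootstrap results.
#' @export
runFit <- function(config, plot = TRUE) {
  .ensureOutdir(config)
  tab <- .loadInput(config)
  seeds <- substreamSeeds(config$seed, config$rarefactions)
  drop_log <- character()
  per_rar <- lapply(seeds, function(s) {
    rar <- withCallingHandlers(
      rarefy(tab, depth = config$depth, seed = s),
      warning = function(w) {
        drop_log <<- unique(c(drop_log, conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    fitNeutral(taxonStats(rar, d = config$d))
  })
  ref <- per_rar[[1L]]
  mean_of <- function(get) mean(vapply(per_rar, get, numeric(1)))
  summary <- list(
    m_hat = mean_of(function(z) z@mHat),
    r_squared = mean_of(function(z) z@rSquared),
    aic_neutral = mean_of(function(z) z@aic),
    aic_binomial = mean_of(function(z) z@aicBinomial),
    delta_aic = mean_of(function(z) z@aicBinomial - z@aic),
    n_taxa = mean_of(function(z) length(z@phi)),
    rarefactions = config$rarefactions,
    depth = config$depth, S = ref@stats@S, d = ref@stats@d)
  rar_ref <- suppressWarnings(rarefy(tab, depth = config$depth,
                                     seed = seeds[1L]))
  bs <- bootstrapFit(rar_ref, B = config$B, d = config$d,
                     seed = config$seed + 1L)
  summary$r_squared_ci <- c(bs$rSquared@lower, bs$rSquared@upper)
  summary$m_hat_ci <- c(bs$mHat@lower, bs$mHat@upper)
  jsonlite::write_json(summary,
                       file.path(config$outdir, "fit_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.table(as.data.frame(ref),
                     file.path(config$outdir, "fit_taxa.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(if (length(drop_log)) drop_log else
               "no samples dropped during rarefaction",
             file.path(config$outdir, "drop_log.txt"))
  if (plot) {
    grDevices::pdf(file.path(config$outdir, "fit_plot.pdf"), width = 6,
                   height = 4.5)
    print(plotFit(ref))
    grDevices::dev.off()
  }
  .writeManifest(config, "fit")
  invisible(list(summary = summary, fit = ref, bootstrap = bs))
}

#' Simulate a neutral metacommunity and write it as an OTU table
#'
#' @param config a [runConfig()] list (`input` ignored).
#' @param S,N,m,steps,D simulation parameters (see
#'   [simulationConfig()]); D is the source-pool richness.
#' @param initMode,k initial condition (see [simulationConfig()]).
#' @param sourceDistribution source-pool shape (see [sourceCommunity()]).
#' @param sequencingDepth optional multinomial read sampling per
#'   community.
#' @return invisibly, the written [OtuExperiment-class].
#' @export
runSimulate <- function(config, S = 50L, N = 1000L, m = 0.05,
                        steps = 1e6, D = 300L, initMode = "source",
                        k = 5L, sourceDistribution = "dirichlet",
                        sequencingDepth = NULL) {
  .ensureOutdir(config)
  src <- sourceCommunity(D, distribution = sourceDistribution,
                         seed = config$seed)
  cfg <- simulationConfig(S = S, N = N, m = m, steps = steps,
                          initMode = initMode, k = k,
                          seed = config$seed + 1L)
  ens <- simulateEnsemble(cfg, src)
  tab <- ensembleToOtuTable(ens, sequencingDepth = sequencingDepth,
                            seed = config$seed + 2L)
  writeOtuTable(tab, file.path(config$outdir, "simulated_otu_table.tsv"))
  .writeManifest(config, "simulate",
                 extra = list(S = S, N = N, m = m, steps = steps, D = D,
                              initMode = initMode, k = k,
                              sourceDistribution = sourceDistribution,
                              sequencingDepth = sequencingDepth))
  invisible(tab)
}

# Rarefy-if-needed guard shared by the resampling commands.
.uniformDepth <- function(tab, config) {
  totals <- colSums(otuCounts(tab))
  if (length(unique(totals)) == 1L && is.null(config$depth)) return(tab)
  if (length(unique(totals)) == 1L && totals[1L] == config$depth)
    return(tab)
  suppressWarnings(rarefy(tab, depth = config$depth, seed = config$seed))
}

#' Bootstrap command: host-resampled CIs for R-squared and m
#' @param config a [runConfig()] list.
#' @return invisibly, the [bootstrapFit()] result.
#' @export
runBootstrap <- function(config) {
  .ensureOutdir(config)
  tab <- .uniformDepth(.loadInput(config), config)
  bs <- bootstrapFit(tab, B = config$B, d = config$d,
                     seed = config$seed)
  reps <- data.frame(replicate = seq_len(config$B),
                     r_squared = bs$rSquared@replicates,
                     m_hat = bs$mHat@replicates)
  utils::write.table(reps,
                     file.path(config$outdir, "bootstrap_replicates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(r_squared = bs$rSquared@point,
         r_squared_ci = c(bs$rSquared@lower, bs$rSquared@upper),
         m_hat = bs$mHat@point,
         m_hat_ci = c(bs$mHat@lower, bs$mHat@upper),
         B = bs$rSquared@B, discarded = bs$rSquared@discarded),
    file.path(config$outdir, "bootstrap_summary.json"),
    auto_unbox = TRUE, digits = NA)
  .writeManifest(config, "bootstrap")
  invisible(bs)
}

#' Subsampling-curve command (goodness of fit vs number of hosts)
#' @param config a [runConfig()] list.
#' @param sizes host counts; default a spread from 4 to all hosts.
#' @param reps resamples per size.
#' @return invisibly, the curve data.frame.
#' @export
runSubsample <- function(config, sizes = NULL, reps = 100L) {
  .ensureOutdir(config)
  tab <- .uniformDepth(.loadInput(config), config)
  S <- ncol(otuCounts(tab))
  if (is.null(sizes))
    sizes <- unique(pmax(2L, round(seq(4L, S, length.out = 8L))))
  curve <- subsampleCurve(tab, sizes = sizes, reps = reps,
                          seed = config$seed, d = config$d)
  utils::write.table(curve,
                     file.path(config$outdir, "subsample_curve.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  .writeManifest(config, "subsample",
                 extra = list(sizes = sizes, reps = reps))
  invisible(curve)
}

#' Read-depth-curve command (goodness of fit vs rarefaction depth)
#' @param config a [runConfig()] list.
#' @param depths read depths to rarefy to.
#' @param reps rarefaction draws per depth.
#' @return invisibly, the curve data.frame.
#' @export
runDepthCurve <- function(config, depths, reps = 10L) {
  .ensureOutdir(config)
  tab <- .loadInput(config)
  curve <- depthCurve(tab, depths = depths, reps = reps,
                      seed = config$seed)
  utils::write.table(curve,
                     file.path(config$outdir, "depth_curve.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  .writeManifest(config, "depthcurve",
                 extra = list(depths = depths, reps = reps))
  invisible(curve)
}

#' Matched-neutral-benchmark command
#' @param config a [runConfig()] list.
#' @param steps events per community for the benchmark simulation.
#' @return invisibly, the [matchedNeutralBenchmark()] result.
#' @export
runBenchmark <- function(config, steps = 1e6) {
  .ensureOutdir(config)
  tab <- .uniformDepth(.loadInput(config), config)
  stats <- taxonStats(tab, d = config$d)
  fit <- fitNeutral(stats)
  bench <- matchedNeutralBenchmark(stats, fit@mHat, steps = steps,
                                   B = config$B, seed = config$seed)
  jsonlite::write_json(
    list(empirical_r_squared = fit@rSquared,
         benchmark_r_squared = bench$fit@rSquared,
         benchmark_ci = c(bench$rSquared@lower, bench$rSquared@upper),
         m_hat = fit@mHat),
    file.path(config$outdir, "benchmark_summary.json"),
    auto_unbox = TRUE, digits = NA)
  .writeManifest(config, "benchmark", extra = list(steps = steps))
  invisible(bench)
}

#' Time-course (transient neutralization) command
#' @param config a [runConfig()] list.
#' @param S,N,m,D,k simulation parameters; communities start from k
#'   random colonizers.
#' @param checkpoints event counts at which the fit is evaluated.
#' @return invisibly, the time-course data.frame (one row per
#'   checkpoint).
#' @export
runTimecourse <- function(config, S = 50L, N = 1000L, m = 0.05,
                          D = 300L, k = 5L,
                          checkpoints = c(0, 1e3, 3e3, 1e4, 3e4, 1e5,
                                          3e5, 6e5, 1e6)) {
  .ensureOutdir(config)
  src <- sourceCommunity(D, seed = config$seed)
  cfg <- simulationConfig(S = S, N = N, m = m, steps = max(checkpoints),
                          initMode = "colonizers", k = k,
                          seed = config$seed + 1L)
  tc <- timeCourseNeutrality(cfg, src, checkpoints, B = config$B)
  utils::write.table(tc, file.path(config$outdir, "timecourse.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  .writeManifest(config, "timecourse",
                 extra = list(S = S, N = N, m = m, D = D, k = k,
                              checkpoints = checkpoints))
  invisible(tc)
}
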