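#' Run the analysis pipeline from a configuration
#'
#' Executes the requested stages in order, writing every product under
#' \code{outDir} and finishing with a \code{manifest.json} that lists each
#' output file with its md5 checksum, the seed, and per-stage status. Valid
#' stages:
#' \describe{
#'   \item{simulate}{generate a transient-absorption surface from a preset or
#'     custom photocycle model; writes \code{surface.csv} +
#'     \code{params.yaml}.}
#'   \item{globalfit}{global multi-exponential fit of the surface (simulated
#'     upstream or read from \code{config$surface}); writes
#'     \code{fit_report.json} and \code{das.tsv}.}
#'   \item{photocycle}{intermediate assignment and turnover from the fit;
#'     writes \code{assignment.json}.}
#'   \item{ephys}{photocurrent metrics of a simulated or supplied trace
#'     (\code{config$trace} CSV + \code{config$epochs}); writes
#'     \code{ephys_metrics.json}.}
#'   \item{pump}{pump-assay metrics of simulated (by \code{config$mode}) or
#'     supplied traces; writes \code{pump_metrics.json}.}
#'   \item{phylo}{NJ + Poisson + bootstrap on \code{config$alignment} (FASTA)
#'     or a simulated alignment; writes \code{tree.nwk}, \code{dist.phy}.}
#' }
#' Rerunning with the same config and seed reproduces byte-identical files
#' (fixed key order, 12 significant digits in JSON).
#'
#' @param config named list, or path to a YAML file with the same content.
#'   Recognized fields: \code{stages} (character vector, required),
#'   \code{protein} (preset name, default "KR2"), \code{n_components}
#'   (default: BIC selection up to \code{max_components}, default 5),
#'   \code{noise_sd}, \code{seed}, \code{surface}, \code{trace},
#'   \code{epochs}, \code{alignment}, \code{mode}, \code{replicates}
#'   (bootstrap, default 1000).
#' @param outDir output directory (created if missing); default
#'   \code{config$out_dir} or "nartools_out".
#' @return the manifest (list) invisibly; on stage failure the manifest is
#'   still written with the failed stage marked, then the error is re-raised.
#' @export
runPipeline <- function(config, outDir = NULL) {
  if (is.character(config) && length(config) == 1L)
    config <- readParamsYAML(config)
  if (!is.list(config) || is.null(config$stages) || !length(config$stages))
    stop("config must be a list (or YAML path) with a non-empty 'stages' field")
  valid <- c("simulate", "globalfit", "photocycle", "ephys", "pump", "phylo")
  bad <- setdiff(config$stages, valid)
  if (length(bad))
    stop("unknown stage(s) ", paste(bad, collapse = ", "),
         "; valid stages: ", paste(valid, collapse = ", "))
  for (f in c("surface", "trace", "alignment"))
    if (!is.null(config[[f]]) && !file.exists(config[[f]]))
      stop("input path does not exist: ", config[[f]])
  if (is.null(outDir)) outDir <- config$out_dir %||% "nartools_out"
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)

  files <- character(0)
  status <- list()
  state <- new.env(parent = emptyenv())
  out <- function(name) file.path(outDir, name)

  stageFuns <- list(
    simulate = function() {
      model <- photocycleModelPreset(config$protein %||% "KR2")
      state$surface <- simulatePhotocycle(model,
        noiseSd = config$noise_sd %||% 0, seed = seed)
      files <<- c(files, writeSurfaceCSV(state$surface, out("surface.csv")),
                  writeParamsYAML(list(
                    protein = config$protein %||% "KR2",
                    noise_sd = config$noise_sd %||% 0, seed = seed,
                    rate_constants_per_s = rateConstants(model),
                    excited_fraction = excitedFraction(model)),
                    out("params.yaml")))
    },
    globalfit = function() {
      if (is.null(state$surface)) {
        if (is.null(config$surface))
          stop("globalfit needs a simulated surface upstream or config$surface")
        state$surface <- readSurfaceCSV(config$surface)
      }
      nc <- config$n_components
      sel <- NULL
      if (is.null(nc)) {
        sel <- selectComponents(state$surface, config$max_components %||% 5L)
        nc <- max(sel$n, 1L)
      }
      state$fit <- fitGlobal(state$surface, nc)
      files <<- c(files,
                  writeFitReport(state$fit, out("fit_report.json"),
                                 bicTable = sel$table),
                  writeDasTSV(state$fit, out("das.tsv")))
    },
    photocycle = function() {
      if (is.null(state$fit)) stop("photocycle needs a globalfit stage first")
      darkMax <- config$dark_lambda_max %||% 525
      asg <- assignIntermediates(state$fit, darkMax)
      jsonlite::write_json(list(
        labels = asg@labels, taus_s = asg@taus,
        peak_nm = asg@peakWavelengths, scheme = asg@schemeString,
        o_detected = asg@oDetected, cycle_time_s = asg@cycleTime,
        turnover_per_min = asg@turnoverPerMin),
        out("assignment.json"), auto_unbox = TRUE, digits = 12)
      files <<- c(files, out("assignment.json"))
    },
    ephys = function() {
      tr <- if (!is.null(config$trace)) {
        df <- readTraceCSV(config$trace)
        ep <- matrix(unlist(config$epochs), ncol = 2L, byrow = TRUE)
        new("PhotocurrentTrace", time = df[[1L]], current = df[[2L]],
            lightEpochs = ep, holdingPotential = 0, irradiance = 0.8)
      } else simulatePhotocurrent(
        peakPa = config$peak_pa %||% 40, steadyPa = config$steady_pa %||% 10,
        tauOffMs = config$tau_off_ms %||% 10,
        lightEpochs = c(50, 350), samplingMs = 0.1,
        noiseSd = config$trace_noise_sd %||% 0.4, seed = seed)
      met <- photocurrentMetrics(tr)
      jsonlite::write_json(list(i_peak_pa = met$iPeak, i_ss_pa = met$iSs,
                                inactivation_ratio = met$inactivationRatio,
                                tau_off_ms = met$tauOff),
                           out("ephys_metrics.json"), auto_unbox = TRUE,
                           digits = 12)
      files <<- c(files, out("ephys_metrics.json"))
    },
    pump = function() {
      mode <- config$mode %||% "na_export"
      tr <- simulatePumpTrace(mode, seed = seed)
      trC <- simulatePumpTrace(mode, cccpPresent = TRUE, seed = seed + 1L)
      met <- pumpMetrics(tr, pairedCccpTrace = trC)
      jsonlite::write_json(list(initial_slope_ph_per_s = met$initialSlope,
                                net_delta_ph = met$netDeltaPH,
                                classification = met$classification,
                                cccp_ratio = met$cccpRatio),
                           out("pump_metrics.json"), auto_unbox = TRUE,
                           digits = 12)
      files <<- c(files, out("pump_metrics.json"))
    },
    phylo = function() {
      aln <- if (!is.null(config$alignment)) readAlignmentFasta(config$alignment)
        else {
          set.seed(seed)
          tr0 <- ape::rtree(8, br = function(n) stats::runif(n, 0.05, 0.3))
          alignment(simulateAlignment(tr0, config$n_sites %||% 500L,
                                      seed = seed))
        }
      d <- poissonCorrect(pDistance(aln))
      tree <- bootstrapSupport(aln, nReplicates = config$replicates %||% 1000L,
                               seed = seed)
      files <<- c(files, writePhylipDist(d, out("dist.phy")),
                  writeNewick(tree, out("tree.nwk")))
    }
  )

  err <- NULL
  for (st in config$stages) {
    res <- tryCatch({ stageFuns[[st]](); "ok" },
                    error = function(e) { err <<- e; conditionMessage(e) })
    status[[st]] <- res
    if (!is.null(err)) break
  }
  manifest <- list(
    seed = seed,
    stages = status,
    failed = !is.null(err),
    files = lapply(files, function(f)
      list(path = f, md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = 12)
  if (!is.null(err))
    stop("pipeline stage failed (see manifest.json): ", conditionMessage(err))
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
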