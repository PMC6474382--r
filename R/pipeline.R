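# Pipeline orchestration: file formats, per-participant simulation of
# active and sham arms, and the aggregated report bundle.

#' Hypnogram CSV input/output
#'
#' Fixed schema: \code{epoch_index} (1-based), \code{start_s},
#' \code{stage} with stage in \{W, N1, N2, N3, R\}.
#'
#' @param hypnogram a [Hypnogram-class].
#' @param path CSV file.
#' @return \code{writeHypnogramCSV}: \code{path} invisibly;
#'   \code{readHypnogramCSV}: a [Hypnogram-class].
#' @export
writeHypnogramCSV <- function(hypnogram, path) {
  df <- data.frame(epoch_index = seq_len(nEpochs(hypnogram)),
                   start_s = (seq_len(nEpochs(hypnogram)) - 1L) *
                     epochLength(hypnogram),
                   stage = stages(hypnogram))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeHypnogramCSV
#' @export
readHypnogramCSV <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("epoch_index", "start_s", "stage") %in% names(df)))
  df <- df[order(df$epoch_index), ]
  epl <- if (nrow(df) > 1L) df$start_s[2] - df$start_s[1] else 30
  Hypnogram(df$stage, epl)
}

#' Pipeline configuration
#'
#' Bundles the per-stage configurations and cohort parameters for
#' [runPipeline()]. The cohort default mirrors a 17-participant
#' within-subject design (every participant has an active and a sham
#' nap); tests and examples use smaller cohorts and shorter naps.
#'
#' @param nParticipants simulated participants.
#' @param duration_s nap length per session, s.
#' @param seed master seed; per-participant generator seeds are derived
#'   from it deterministically.
#' @param outDir output directory for the report bundle.
#' @param sim named list of [simConfig()] overrides applied to every
#'   participant.
#' @param detection a [detectionConfig()].
#' @param closedLoop a [closedLoopConfig()].
#' @param bands a [bandSet()].
#' @param scores optional memory-score table (columns participant,
#'   condition, test, percent) for the performance analysis.
#' @return List of class \code{"PipelineConfig"}.
#' @export
pipelineConfig <- function(nParticipants = 17, duration_s = 5400,
                           seed = 1L, outDir = tempfile("sdrtes_run_"),
                           sim = list(),
                           detection = detectionConfig(),
                           closedLoop = closedLoopConfig(),
                           bands = bandSet(),
                           scores = NULL) {
  stopifnot(nParticipants >= 1, duration_s >= 60)
  structure(list(nParticipants = nParticipants,
                 duration_s = duration_s, seed = as.integer(seed),
                 outDir = outDir, sim = sim, detection = detection,
                 closedLoop = closedLoop, bands = bands,
                 scores = scores),
            class = "PipelineConfig")
}

participantSimConfig <- function(config, p) {
  args <- c(list(duration_s = config$duration_s,
                 seed = config$seed + 1000L * p),
            config$sim)
  do.call(simConfig, args[!duplicated(names(args))])
}

#' Run one participant session (active or sham arm)
#'
#' Simulates the nap, runs the closed loop (threshold, causal detection,
#' scheduling), applies the stimulation response in the active arm, and
#' performs the offline analyses (detection, SO rate, relabeled sleep
#' summary, narrow-band power, spindle energy, pre-stimulation
#' features).
#'
#' @param config a [pipelineConfig()].
#' @param p participant index.
#' @param active logical; \code{FALSE} gives the sham arm (stimulator
#'   powered but no current, recording untouched).
#' @return List with the session's recordings, events and measures.
#' @export
runParticipantSession <- function(config, p, active = TRUE) {
  simc <- participantSimConfig(config, p)
  hyp <- simulateHypnogram(simc)
  sim <- simulateEEG(simc, hyp)
  thr <- computeThreshold(sim$eeg, hyp, config$detection)

  clc <- config$closedLoop
  clc$enabled <- active
  det <- onlineDetect(sim$eeg, "Fz", thr, config$detection)
  sched <- scheduleStimulation(det, hyp, clc,
                               recordingDuration = duration(sim$eeg))
  if (active && nrow(sched$events)) {
    resp <- applyStimulationResponse(sim$eeg, sim$truth, sched$events,
                                     simc)
    eeg <- resp$eeg; truth <- resp$truth
  } else {
    eeg <- sim$eeg; truth <- sim$truth
  }
  hypScored <- relabelStimEpochs(hyp, artifactMask(eeg),
                                 samplingRate(eeg))

  thrOff <- computeThreshold(eeg, hypScored, config$detection)
  events <- detectSOEvents(eeg, hypScored, thrOff, config$detection)
  rates <- soRate(events, hypScored, eeg,
                  channels = channelNames(eeg))
  summary <- sleepSummary(hypScored)
  psd <- psdWelch(eeg, hypScored)
  soPower <- bandPower(psd, config$bands$so_narrow)
  spindleZ <- lapply(c(slow = "slow_spindle", fast = "fast_spindle"),
                     function(b)
                       phaseLockedSpindleEnergy(eeg, events,
                                                config$bands[[b]])$perChannel)

  prest <- NULL
  if (active && nrow(sched$events)) {
    feats <- prestimFeatures(eeg, sched$events, config$bands)
    merged <- mergeEventsAcrossChannels(
      events[events$channel %in% PRESTIM_CHANNELS, , drop = FALSE],
      config$detection)
    counts <- poststimSOCount(merged, sched$events)
    prest <- list(features = feats, counts = counts)
  }

  list(participant = p, active = active, threshold = thrOff,
       hypnogram = hypScored, events = events, rates = rates,
       summary = summary, soNarrowPower = soPower,
       spindleZ = spindleZ, stimLog = sched$log,
       stimEvents = sched$events, prestim = prest, truth = truth)
}

#' Run the full simulated-cohort pipeline
#'
#' Simulates every participant's active and sham nap, runs the complete
#' analysis chain, and writes the report bundle: per-participant event
#' and stimulation-log CSVs, a sleep-architecture comparison table
#' (Wilcoxon + paired Cohen's d per parameter), a per-channel SO-rate
#' topography table with BH-FDR correction, the pooled pre-stimulation
#' efficacy correlations, the memory-performance analysis when scores
#' are supplied, and a JSON run manifest (seed, versions, configuration)
#' sufficient to reproduce the run.
#'
#' @param config a [pipelineConfig()].
#' @return Invisibly, a list with the aggregated tables and the output
#'   directory.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  sessions <- list()
  for (p in seq_len(config$nParticipants)) {
    for (arm in c("active", "sham")) {
      s <- runParticipantSession(config, p, active = arm == "active")
      sessions[[paste0("p", p, "_", arm)]] <- s
      tag <- file.path(config$outDir, sprintf("p%02d_%s", p, arm))
      utils::write.csv(s$events, paste0(tag, "_so_events.csv"),
                       row.names = FALSE)
      utils::write.csv(s$stimLog, paste0(tag, "_stim_log.csv"),
                       row.names = FALSE)
      writeHypnogramCSV(s$hypnogram, paste0(tag, "_hypnogram.csv"))
    }
  }
  act <- sessions[grepl("_active$", names(sessions))]
  shm <- sessions[grepl("_sham$", names(sessions))]

  # sleep architecture table (Wilcoxon + paired d per parameter)
  params <- c("TST", "SOL", "WASO", "SE")
  archRows <- lapply(params, function(pp) {
    a <- vapply(act, function(s) s$summary[[pp]], numeric(1))
    b <- vapply(shm, function(s) s$summary[[pp]], numeric(1))
    dt <- if (length(a) >= 3L) descriptiveTests(b, a) else
      list(wilcoxon = list(V = NA, p = NA), d = cohensDPaired(b, a))
    data.frame(parameter = pp, sham_mean = mean(b), sham_sd = stats::sd(b),
               active_mean = mean(a), active_sd = stats::sd(a),
               wilcoxon_p = dt$wilcoxon$p, cohens_d = dt$d)
  })
  for (stg in c("N1", "N2", "N3", "R")) {
    a <- vapply(act, function(s) s$summary$stage_pct[[stg]], numeric(1))
    b <- vapply(shm, function(s) s$summary$stage_pct[[stg]], numeric(1))
    dt <- if (length(a) >= 3L) descriptiveTests(b, a) else
      list(wilcoxon = list(V = NA, p = NA), d = cohensDPaired(b, a))
    archRows[[length(archRows) + 1L]] <-
      data.frame(parameter = paste0(stg, "_pct"), sham_mean = mean(b),
                 sham_sd = stats::sd(b), active_mean = mean(a),
                 active_sd = stats::sd(a), wilcoxon_p = dt$wilcoxon$p,
                 cohens_d = dt$d)
  }
  architecture <- do.call(rbind, archRows)
  utils::write.csv(architecture,
                   file.path(config$outDir, "sleep_architecture.csv"),
                   row.names = FALSE)

  # SO-rate channel topography (active vs sham, BH-FDR)
  chans <- names(act[[1]]$rates)
  rateA <- do.call(rbind, lapply(act, function(s) s$rates[chans]))
  rateS <- do.call(rbind, lapply(shm, function(s) s$rates[chans]))
  topography <- if (nrow(rateA) >= 3L)
    channelTopographyTest(rateA, rateS) else NULL
  if (!is.null(topography))
    utils::write.csv(topography,
                     file.path(config$outDir, "so_rate_topography.csv"),
                     row.names = FALSE)

  # pooled pre-stimulation efficacy analysis
  featList <- list(); cnts <- integer(); off <- 0L
  for (s in act) {
    if (is.null(s$prestim)) next
    f <- s$prestim$features
    f$stim_id <- f$stim_id + off
    featList[[length(featList) + 1L]] <- f
    cnts <- c(cnts, s$prestim$counts)
    off <- off + length(s$prestim$counts)
  }
  efficacy <- NULL
  if (length(featList)) {
    feats <- do.call(rbind, featList)
    efficacy <- correlateEfficacy(feats, cnts)
    utils::write.csv(efficacy,
                     file.path(config$outDir, "prestim_efficacy.csv"),
                     row.names = FALSE)
  }

  # memory performance (optional input table)
  memory <- NULL
  if (!is.null(config$scores)) {
    pc <- performanceChange(config$scores)
    memory <- list(change = pc)
    if (length(unique(pc$perParticipant$test)) >= 2L) {
      memory$anova <- rmAnovaGG(pc$perParticipant, dv = "change",
                                subject = "participant",
                                factors = c("test", "condition"))
      utils::write.csv(memory$anova,
                       file.path(config$outDir, "memory_anova.csv"),
                       row.names = FALSE)
    }
    utils::write.csv(pc$group,
                     file.path(config$outDir, "memory_change.csv"),
                     row.names = FALSE)
  }

  manifest <- list(
    package = "sdrtes",
    version = as.character(utils::packageVersion("sdrtes")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    nParticipants = config$nParticipants,
    duration_s = config$duration_s,
    sim_overrides = config$sim,
    detection = unclass(config$detection),
    closed_loop = unclass(config$closedLoop))
  jsonlite::write_json(manifest,
                       file.path(config$outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(outDir = config$outDir, sessions = sessions,
                 architecture = architecture, topography = topography,
                 efficacy = efficacy, memory = memory))
}
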