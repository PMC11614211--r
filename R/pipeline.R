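# Orchestration: synthesize or load a recording, preprocess, build features,
# classify every contact x format, cluster-test significant contacts, and
# aggregate group maps, with full seed fan-out and deterministic outputs.

#' Configure a pipeline run
#'
#' @param mode `"synthetic"` (generate a cohort from `synth`) or `"files"`
#'   (read EDF + events + electrodes from the paths).
#' @param synth a [SynthConfig-class] (synthetic mode).
#' @param edfPath,eventsPath,electrodesPath input paths (files mode).
#' @param tfr a [TFRConfig-class].
#' @param nComponents principal components per fold (default 50).
#' @param kFolds cross-validation folds (default 6).
#' @param alpha classifier significance level (default 0.01).
#' @param cost linear-SVM C (default 1).
#' @param clusterAlpha cluster permutation level (default 0.01).
#' @param nPerm sign-flip permutations (default 1000).
#' @param itiGuardS baseline guard in seconds (default 1.99).
#' @param formats contrasts to run: subset of the four modalities plus
#'   `"all"` (default all five).
#' @param doClusters run the cluster permutation test on significant
#'   contacts (default TRUE).
#' @param outDir output directory (`""` = no files written).
#' @param seed master seed; every stage derives its own child seed from it.
#' @return a list of class `RunConfig`.
#' @export
runConfig <- function(mode = c("synthetic", "files"), synth = NULL,
                      edfPath = "", eventsPath = "", electrodesPath = "",
                      tfr = tfrConfig(), nComponents = 50L, kFolds = 6L,
                      alpha = 0.01, cost = 1, clusterAlpha = 0.01,
                      nPerm = 1000L, itiGuardS = 1.99,
                      formats = c(MODALITIES, "all"), doClusters = TRUE,
                      outDir = "", seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "synthetic") {
    if (!is(synth, "SynthConfig")) stopf("synthetic mode needs a SynthConfig in 'synth'")
    validObject(synth)
  } else {
    for (p in c(edfPath, eventsPath, electrodesPath))
      if (!nzchar(p) || !file.exists(p)) stopf("input file not found: '%s'", p)
  }
  stopifnot(is(tfr, "TFRConfig"))
  validObject(tfr)
  bad <- setdiff(formats, c(MODALITIES, "all"))
  if (length(bad)) stopf("unknown format(s): %s", paste(bad, collapse = ", "))
  if (!isNum(alpha) || alpha <= 0 || alpha >= 1) stopf("'alpha' must be in (0, 1)")
  if (!isNum(clusterAlpha) || clusterAlpha <= 0 || clusterAlpha >= 1)
    stopf("'clusterAlpha' must be in (0, 1)")
  structure(list(
    mode = mode, synth = synth, edfPath = edfPath, eventsPath = eventsPath,
    electrodesPath = electrodesPath, tfr = tfr,
    nComponents = as.integer(nComponents), kFolds = as.integer(kFolds),
    alpha = alpha, cost = cost, clusterAlpha = clusterAlpha,
    nPerm = as.integer(nPerm), itiGuardS = itiGuardS, formats = formats,
    doClusters = isTRUE(doClusters), outDir = outDir, seed = as.integer(seed)),
    class = "RunConfig")
}

# deterministic text form of numbers for TSV output
fmtNum <- function(x) vapply(x, function(v) format(v, digits = 15), "")

#' Run the full decoding pipeline
#'
#' Stages, in order: obtain the recording (synthesize or load), common
#' average reference, balanced epoch extraction, cross-validated rejection
#' threshold + trial rejection, per-contact time-frequency features, PCA +
#' linear-SVM classification per contact and format with binomial
#' significance, sign-flip cluster permutation tests on significant
#' contacts, and group-level aggregation (significant counts, region
#' accuracy, feature maps). All randomness derives from the master seed, so
#' identical configurations reproduce every output byte-for-byte.
#'
#' When `outDir` is set the bundle is written there: `summary.tsv` (contact,
#' region, format, accuracy, p, significant), `counts.tsv`,
#' `region_accuracy_<format>.tsv`, `feature_map_<format>_<layer>.tsv`,
#' `bundle.rds` and `provenance.json`.
#'
#' @param config a `RunConfig` from [runConfig()].
#' @param verbose log per-stage counts to stderr (default TRUE).
#' @return a list of class `ResultsBundle`: `summary` (data.frame),
#'   `results` (list of [ContactResult-class]), `clusterSets` (per format,
#'   named by contact), `counts`, `regionMaps`, `featureMaps`, `manifest`,
#'   `electrodes`, `config`, `seed`.
#' @export
runPipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "RunConfig"))
  seed <- config$seed
  note <- function(fmt, ...) if (verbose) message(sprintf(fmt, ...))

  if (config$mode == "synthetic") {
    schedule <- buildSchedule(config$synth, seed = childSeed(seed, "schedule"))
    sim <- simulateRecording(schedule, config$synth,
                             seed = childSeed(seed, "recording"))
    rec <- sim$recording
    manifest <- sim$manifest
    electrodes <- makeElectrodeTable(config$synth)
  } else {
    rec <- readRecordingEDF(config$edfPath)
    schedule <- readEventsTSV(config$eventsPath)
    electrodes <- readElectrodesTSV(config$electrodesPath)
    manifest <- list()
  }
  miss <- setdiff(rec@channelNames, electrodes$name)
  if (length(miss))
    stopf("contact(s) missing from the electrode table: %s",
          paste(miss, collapse = ", "))
  note("recording: %d channels, %.0f s", nrow(rec@data), ncol(rec@data) / rec@sfreqHz)

  rec <- averageReference(rec)
  epochs <- extractEpochs(rec, schedule, itiGuardS = config$itiGuardS,
                          seed = childSeed(seed, "epochs"))
  note("epochs: %d stimulus + %d iti",
       sum(epochs@condition == "stimulus"), sum(epochs@condition == "iti"))
  thr <- estimateRejectionThreshold(epochs, seed = childSeed(seed, "reject"))
  epochs <- dropBadEpochs(epochs, thr, seed = childSeed(seed, "drop"))
  note("rejection threshold %.1f uV p2p; %d epochs kept", thr, sum(epochs@keptMask))

  ppm <- max(table(schedule$modality[!schedule$is_catch]))
  null <- nullSpec(nObs = ppm, alpha = config$alpha)

  contacts <- rec@channelNames
  results <- list()
  clusterSets <- stats::setNames(vector("list", length(config$formats)), config$formats)
  for (f in config$formats) clusterSets[[f]] <- list()

  for (ch in contacts) {
    feats <- contactFeatures(epochs, config$tfr, ch)
    itiIdx <- which(feats@condition == "iti")
    for (fmt in config$formats) {
      if (fmt == "all") {
        sub <- feats
      } else {
        stimIdx <- which(feats@condition == "stimulus" & feats@modality == fmt)
        if (length(stimIdx) < config$kFolds) {
          warnf("contact %s, format %s: only %d stimulus epochs; skipped",
                ch, fmt, length(stimIdx))
          next
        }
        pick <- withSeed(childSeed(seed, "format-iti", fmt), {
          sort(sample(itiIdx, length(stimIdx)))
        })
        sub <- feats[sort(c(stimIdx, pick))]
      }
      res <- crossvalClassify(sub, nComponents = config$nComponents,
                              kFolds = config$kFolds,
                              seed = childSeed(seed, "cv", ch, fmt),
                              cost = config$cost, null = null, format = fmt)
      results[[length(results) + 1L]] <- res
      if (config$doClusters && res@significant && nEpochs(sub) >= 10) {
        maps <- contributionMaps(res, sub)
        # the resolution advisory is config-level information, not per-contact
        clusterSets[[fmt]][[ch]] <- withCallingHandlers(
          oneSampleClusterPerm(maps, alpha = config$clusterAlpha,
                               nPerm = config$nPerm,
                               seed = childSeed(seed, "perm", ch, fmt)),
          warning = function(w) {
            if (grepl("coarse resolution", conditionMessage(w)))
              invokeRestart("muffleWarning")
          })
      }
    }
  }
  summary <- resultsTable(results)
  summary$region <- electrodes$region[match(summary$contact, electrodes$name)]
  summary <- summary[order(summary$contact, summary$format),
                     c("contact", "region", "format", "accuracy", "pValue",
                       "significant")]
  rownames(summary) <- NULL
  counts <- countSignificant(results)
  note("significant contacts: %s; intersection %d",
       paste(sprintf("%s=%d", names(counts$perFormat), counts$perFormat),
             collapse = ", "), counts$intersection)

  regionMaps <- list()
  maps <- list()
  for (fmt in config$formats) {
    sub <- Filter(function(r) r@format == fmt, results)
    if (!length(sub)) next
    regionMaps[[fmt]] <- regionAccuracy(sub, electrodes)
    maps[[fmt]] <- featureMaps(sub, clusterSets[[fmt]], format = fmt)
  }

  bundle <- structure(list(
    summary = summary, results = results, clusterSets = clusterSets,
    counts = counts, regionMaps = regionMaps, featureMaps = maps,
    manifest = manifest, electrodes = electrodes, config = config,
    seed = seed), class = "ResultsBundle")
  if (nzchar(config$outDir)) writeBundle(bundle, config$outDir)
  bundle
}

# write the deterministic TSV summaries plus the serialized bundle
writeBundle <- function(bundle, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  sm <- bundle$summary
  sm$accuracy <- fmtNum(sm$accuracy)
  sm$pValue <- fmtNum(sm$pValue)
  utils::write.table(sm, file.path(outDir, "summary.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cnt <- data.frame(format = names(bundle$counts$perFormat),
                    n_significant = as.integer(bundle$counts$perFormat))
  cnt <- rbind(cnt, data.frame(format = "intersection",
                               n_significant = bundle$counts$intersection))
  utils::write.table(cnt, file.path(outDir, "counts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (fmt in names(bundle$regionMaps)) {
    rm <- bundle$regionMaps[[fmt]]
    rm$accuracy <- fmtNum(rm$accuracy)
    utils::write.table(rm, file.path(outDir, sprintf("region_accuracy_%s.tsv", fmt)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  for (fmt in names(bundle$featureMaps)) {
    fm <- bundle$featureMaps[[fmt]]
    layers <- list(proportion_significant = fm@proportionSignificant,
                   proportion_positive = fm@proportionPositive,
                   classification_value = fm@classificationValue)
    for (ly in names(layers)) {
      m <- layers[[ly]]
      dimnames(m) <- list(c(sprintf("f%.4g", fm@freqsHz), "voltage"),
                          sprintf("t%.4g", fm@timesS))
      utils::write.table(m, file.path(outDir, sprintf("feature_map_%s_%s.tsv", fmt, ly)),
                         sep = "\t", quote = FALSE, row.names = TRUE)
    }
  }
  saveRDS(bundle, file.path(outDir, "bundle.rds"))
  prov <- list(seed = bundle$seed,
               package_version = as.character(utils::packageVersion("seegDecode")),
               config = configToList(bundle$config),
               written_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(prov, file.path(outDir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(outDir)
}

# ---------------------------------------------------------------------------
# Config (de)serialization: YAML round-trip
# ---------------------------------------------------------------------------

configToList <- function(config) {
  out <- list(mode = config$mode,
              edf_path = config$edfPath, events_path = config$eventsPath,
              electrodes_path = config$electrodesPath,
              n_components = config$nComponents, k_folds = config$kFolds,
              alpha = config$alpha, cost = config$cost,
              cluster_alpha = config$clusterAlpha, n_perm = config$nPerm,
              iti_guard_s = config$itiGuardS, formats = config$formats,
              do_clusters = config$doClusters, out_dir = config$outDir,
              seed = config$seed)
  tfr <- config$tfr
  out$tfr <- list(freqs_hz = tfr@freqsHz, n_cycles = tfr@nCycles,
                  decim = tfr@decim, bandpass_hz = tfr@bandpassHz,
                  log_power = tfr@logPower)
  if (!is.null(config$synth)) {
    sc <- config$synth
    out$synth <- list(
      n_contacts = sc@nContacts, sfreq_hz = sc@sfreqHz,
      presentations_per_modality = sc@presentationsPerModality,
      catch_rate = sc@catchRate,
      region_labels = as.list(sc@regionLabels), seed = sc@seed,
      noise = list(one_over_f_exponent = sc@noise@oneOverFExponent,
                   amplitude_uv = sc@noise@amplitudeUv,
                   line_freq_hz = if (length(sc@noise@lineFreqHz))
                     sc@noise@lineFreqHz else NULL),
      effects = lapply(sc@effects, function(ef) list(
        contact = ef@contact, modalities = ef@modalities,
        band_hz = ef@bandHz, window_s = ef@windowS,
        direction = ef@direction, magnitude = ef@magnitude,
        erp_amplitude_uv = ef@erpAmplitude)))
  }
  out
}

listToConfig <- function(x) {
  synth <- NULL
  if (!is.null(x$synth)) {
    s <- x$synth
    effects <- lapply(s$effects, function(ef)
      effectSpec(ef$contact, unlist(ef$modalities), unlist(ef$band_hz),
                 unlist(ef$window_s), ef$direction, ef$magnitude,
                 ef$erp_amplitude_uv))
    labels <- unlist(s$region_labels)
    synth <- synthConfig(
      nContacts = s$n_contacts, sfreqHz = s$sfreq_hz,
      presentationsPerModality = s$presentations_per_modality,
      catchRate = s$catch_rate, effects = effects,
      noise = noiseModel(s$noise$one_over_f_exponent, s$noise$amplitude_uv,
                         s$noise$line_freq_hz),
      regionLabels = labels, seed = s$seed)
  }
  tfr <- tfrConfig(freqsHz = unlist(x$tfr$freqs_hz),
                   nCycles = unlist(x$tfr$n_cycles), decim = x$tfr$decim,
                   bandpassHz = unlist(x$tfr$bandpass_hz),
                   logPower = x$tfr$log_power)
  runConfig(mode = x$mode, synth = synth, edfPath = x$edf_path,
            eventsPath = x$events_path, electrodesPath = x$electrodes_path,
            tfr = tfr, nComponents = x$n_components, kFolds = x$k_folds,
            alpha = x$alpha, cost = x$cost, clusterAlpha = x$cluster_alpha,
            nPerm = x$n_perm, itiGuardS = x$iti_guard_s,
            formats = unlist(x$formats), doClusters = x$do_clusters,
            outDir = x$out_dir, seed = x$seed)
}

#' Write / read a pipeline configuration as YAML
#'
#' `readRunConfig(writeRunConfig(cfg, path))` reproduces the configuration;
#' serialize - parse - serialize is the identity on the YAML text.
#'
#' @param config a `RunConfig`.
#' @param path `.yaml` file path.
#' @return `path` invisibly (writer); a `RunConfig` (reader).
#' @export
writeRunConfig <- function(config, path) {
  stopifnot(inherits(config, "RunConfig"))
  writeLines(yaml::as.yaml(configToList(config)), path)
  invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stopf("config file not found: '%s'", path)
  listToConfig(yaml::read_yaml(path))
}
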