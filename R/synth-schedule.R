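# Task-schedule builder: jittered fixation / 1 s stimulus / jittered ITI.

# fixed task-timing constants (seconds)
FIXATION_RANGE_S <- c(0.5, 1.5)
STIMULUS_DUR_S <- 1.0
ITI_RANGE_S <- c(1.5, 3.5)
SCHEDULE_PAD_S <- 5.0

#' Build a randomized task schedule
#'
#' Generates the trial sequence of the number-recognition task: each trial is
#' a fixation cross jittered uniformly in 0.5-1.5 s, a 1 s number stimulus in
#' one of four modalities (Arabic numeral, dot assortment, spoken number,
#' beep sequence) with a quantity drawn uniformly from 1-9, and an
#' inter-trial period jittered uniformly in 1.5-3.5 s. Exactly
#' `presentationsPerModality` non-catch trials of each modality are
#' delivered, plus catch trials at the configured rate; the full sequence is
#' randomly shuffled.
#'
#' @param config a [SynthConfig-class].
#' @param seed integer seed; identical seeds give identical schedules.
#' @return a `data.frame` with one row per trial and columns `onset_s`
#'   (stimulus onset, seconds from recording start), `modality`, `quantity`,
#'   `is_catch`, `fixation_dur_s`, `iti_dur_s`.
#' @export
#' @examples
#' sched <- buildSchedule(synthConfig(nContacts = 2), seed = 7)
#' all(table(sched$modality[!sched$is_catch]) == 40)
buildSchedule <- function(config, seed = config@seed) {
  stopifnot(is(config, "SynthConfig"))
  validObject(config)
  ppm <- config@presentationsPerModality
  nStim <- 4L * ppm
  # catch trials are additional trials so that they form catchRate of the total
  nCatch <- as.integer(round(config@catchRate * nStim / (1 - config@catchRate)))
  withSeed(seed, {
    modality <- c(rep(MODALITIES, each = ppm),
                  if (nCatch > 0) sample(MODALITIES, nCatch, replace = TRUE))
    isCatch <- c(rep(FALSE, nStim), rep(TRUE, nCatch))
    ord <- sample.int(length(modality))
    modality <- modality[ord]
    isCatch <- isCatch[ord]
    n <- length(modality)
    quantity <- sample.int(9L, n, replace = TRUE)
    fixation <- stats::runif(n, FIXATION_RANGE_S[1], FIXATION_RANGE_S[2])
    iti <- stats::runif(n, ITI_RANGE_S[1], ITI_RANGE_S[2])
    onset <- numeric(n)
    t <- SCHEDULE_PAD_S
    for (i in seq_len(n)) {
      t <- t + fixation[i]
      onset[i] <- t
      t <- t + STIMULUS_DUR_S + iti[i]
    }
    data.frame(onset_s = onset, modality = modality, quantity = quantity,
               is_catch = isCatch, fixation_dur_s = fixation, iti_dur_s = iti,
               stringsAsFactors = FALSE)
  })
}

#' Total duration implied by a schedule
#'
#' @param schedule a schedule `data.frame` from [buildSchedule()].
#' @param padS trailing padding in seconds (default 5).
#' @return duration in whole seconds.
#' @export
scheduleDuration <- function(schedule, padS = SCHEDULE_PAD_S) {
  n <- nrow(schedule)
  ceiling(schedule$onset_s[n] + STIMULUS_DUR_S + schedule$iti_dur_s[n] + padS)
}

# validate that a data.frame is a usable schedule
checkSchedule <- function(schedule) {
  need <- c("onset_s", "modality", "quantity", "is_catch",
            "fixation_dur_s", "iti_dur_s")
  miss <- setdiff(need, names(schedule))
  if (length(miss))
    stopf("schedule is missing column(s): %s", paste(miss, collapse = ", "))
  if (nrow(schedule) == 0) stopf("schedule has no trials")
  if (any(diff(schedule$onset_s) <= 0)) stopf("schedule onsets must be strictly increasing")
  invisible(schedule)
}
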