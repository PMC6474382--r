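# Hypnogram summarisation and the stimulation-epoch relabeling rule.

#' Relabel epochs dominated by stimulation artifact
#'
#' Scoring rule for stimulated sessions: an epoch keeps its label when
#' more than 50% of it is artifact-free; when artifacts cover more than
#' 50% of the epoch, the epoch takes the label of the next epoch whose
#' own masked fraction is at most 50% (skipping chains of artifact
#' epochs). A trailing artifact epoch with no subsequent clean epoch
#' keeps its label, with a warning.
#'
#' @param hypnogram a [Hypnogram-class].
#' @param mask logical artifact mask on the sample grid.
#' @param fs sampling rate of the mask, Hz.
#' @return A relabeled [Hypnogram-class]. The operation is idempotent.
#' @export
relabelStimEpochs <- function(hypnogram, mask, fs) {
  stopifnot(is(hypnogram, "Hypnogram"))
  spe <- round(epochLength(hypnogram) * fs)
  nep <- nEpochs(hypnogram)
  frac <- vapply(seq_len(nep), function(ep) {
    i1 <- (ep - 1L) * spe + 1L
    i2 <- min(ep * spe, length(mask))
    if (i1 > length(mask)) return(0)
    mean(mask[i1:i2])
  }, numeric(1))
  st <- stages(hypnogram)
  dirty <- frac > 0.5
  for (ep in which(dirty)) {
    nxt <- which(!dirty & seq_len(nep) > ep)
    if (length(nxt)) {
      st[ep] <- st[nxt[1]]
    } else {
      warning("epoch ", ep,
              " is artifact-dominated with no subsequent clean epoch; ",
              "label kept")
    }
  }
  Hypnogram(st, epochLength(hypnogram))
}

#' Sleep-architecture summary
#'
#' Standard hypnogram summary: total sleep time (TST, minutes of non-wake
#' epochs), sleep-onset latency (SOL, minutes from start to the first
#' sleep epoch), wake after sleep onset (WASO, wake minutes after the
#' first sleep epoch), sleep efficiency (SE = 100 * TST / time in bed,
#' with time in bed the full hypnogram span) and stage percentages of
#' TST over \{N1, N2, N3, REM\}.
#'
#' @param hypnogram a [Hypnogram-class].
#' @return List with \code{TST}, \code{SOL}, \code{WASO} (minutes),
#'   \code{SE} (percent), \code{stage_pct} (named percents of TST).
#'   With no sleep epochs TST and SE are 0 and SOL/WASO/stage_pct are
#'   NA (flagged undefined).
#' @export
sleepSummary <- function(hypnogram) {
  stopifnot(is(hypnogram, "Hypnogram"))
  st <- stages(hypnogram)
  epMin <- epochLength(hypnogram) / 60
  sleep <- st %in% SLEEP_STAGES
  tib <- length(st) * epMin
  tst <- sum(sleep) * epMin
  if (!any(sleep)) {
    return(list(TST = 0, SOL = NA_real_, WASO = NA_real_, SE = 0,
                stage_pct = stats::setNames(rep(NA_real_, 4),
                                            c("N1", "N2", "N3", "R"))))
  }
  first <- which(sleep)[1]
  sol <- (first - 1L) * epMin
  waso <- sum(st[first:length(st)] == "W") * epMin
  pct <- vapply(c("N1", "N2", "N3", "R"), function(s)
    100 * sum(st == s) * epMin / tst, numeric(1))
  list(TST = tst, SOL = sol, WASO = waso, SE = 100 * tst / tib,
       stage_pct = pct)
}
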