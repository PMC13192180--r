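# Run orchestration: configuration, manifest dispatch, summary assembly,
# condition comparisons.

#' Default run configuration
#'
#' Aggregates every tunable threshold of the pipeline with the
#' slice-culture defaults: the gamma classification rule (> 23 Hz,
#' >= 1e-4 mV^2/Hz), the 85\% burst-prominence cutoff, the particle/soma
#' size cutoffs (400 / 300 px), the 100 px territory dilation and the
#' 0.31 um pixel calibration. Unknown keys are rejected.
#'
#' @param ... overrides of the defaults by name.
#' @return list of class \code{"RunConfig"}.
#' @export
runConfig <- function(...) {
  cfg <- list(gammaFreqMin = 23, powerMin = 1e-4, prominenceFrac = 0.85,
              refractoryS = 0.2, silenceRms = 0.005, minEvents = 3,
              welchWindowLen = 8192L, lowpassCornerHz = 200,
              minParticlePx = 400, minSomaPx = 300, dilationPx = 100,
              attributeAreaPx = 99, pixelUm = 0.31, shollStepUm = 5,
              seed = 1L)
  ov <- list(...)
  bad <- setdiff(names(ov), names(cfg))
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "), call. = FALSE)
  cfg[names(ov)] <- ov
  structure(cfg, class = "RunConfig")
}

configHash <- function(cfg) fnvHash(paste(names(cfg), unlist(cfg),
                                          sep = "=", collapse = ";"))

#' Run an experiment manifest
#'
#' Dispatches each manifest row to the matching analysis: LFP files go
#' through low-pass filtering, Welch PSD, burst detection and state
#' classification; image pairs through counting. Every record carries the
#' config hash and input checksum for provenance. The summary table gives
#' per-condition state counts and gamma peak medians.
#'
#' @param manifest data.frame with columns \code{kind} ("lfp" or "image"),
#'   \code{condition}, \code{path} (for "lfp": a trace file readable by
#'   \code{\link{readTraceText}} or \code{\link{readTraceBinary}}; for
#'   "image": the DAPI TIFF path, with the Iba1 path in \code{path2}).
#' @param config a \code{\link{runConfig}}.
#' @return list: \code{records} (one list per input), \code{stateTable}
#'   (condition x state counts), \code{summary} data.frame.
#' @export
runExperiment <- function(manifest, config = runConfig()) {
  states <- c("Gamma", "LowActivity", "Bursts", "NoActivity")
  if (nrow(manifest) == 0)
    return(list(records = list(),
                stateTable = matrix(0L, 0, 4,
                                    dimnames = list(NULL, states)),
                summary = data.frame()))
  cfgH <- configHash(config)
  records <- lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    rec <- list(condition = row$condition, kind = row$kind,
                path = row$path, config_hash = cfgH,
                input_md5 = unname(tools::md5sum(row$path)))
    if (row$kind == "lfp") {
      tr <- if (grepl("\\.f32$|\\.bin$", row$path)) readTraceBinary(row$path)
            else readTraceText(row$path)
      filt <- lowpassButterworth(tr, cornerHz = config$lowpassCornerHz)
      pk <- findSpectralPeak(welchPsd(filt,
              windowLen = min(config$welchWindowLen, length(filt@samples))))
      bursts <- detectBursts(filt, prominenceFrac = config$prominenceFrac,
                             refractoryS = config$refractoryS)
      call <- classifyState(filt, pk, bursts,
                            gammaFreqMin = config$gammaFreqMin,
                            powerMin = config$powerMin,
                            silenceRms = config$silenceRms,
                            minEvents = config$minEvents)
      rec$state <- callState(call)
      rec$peak_freq <- peakFreq(call@peak)
      rec$peak_power <- peakPower(call@peak)
      rec$n_bursts <- nrow(burstEvents(call))
      rec$subtype <- burstSubtype(call)
    } else if (row$kind == "image") {
      dapi <- readChannelTiff(row$path, pixelUm = config$pixelUm,
                              channel = "DAPI")
      iba1 <- readChannelTiff(row$path2, pixelUm = config$pixelUm,
                              channel = "Iba1")
      cnt <- countMicroglia(dapi, iba1,
                            minParticlePx = config$minParticlePx)
      rec$n_somata <- cnt$nSomata
      rec$density_per_mm2 <- cnt$densityPerMm2
    } else stop("unknown manifest kind: ", row$kind, call. = FALSE)
    rec
  })
  conds <- unique(manifest$condition)
  lfpRec <- Filter(function(r) r$kind == "lfp", records)
  stateTable <- matrix(0L, length(conds), length(states),
                       dimnames = list(conds, states))
  for (r in lfpRec)
    stateTable[r$condition, r$state] <- stateTable[r$condition, r$state] + 1L
  summary <- do.call(rbind, lapply(conds, function(cc) {
    rc <- Filter(function(r) r$condition == cc, lfpRec)
    gam <- Filter(function(r) r$state == "Gamma", rc)
    data.frame(condition = cc, n_lfp = length(rc),
      n_gamma = length(gam),
      gamma_peak_freq_median =
        if (length(gam)) stats::median(vapply(gam, `[[`, 0, "peak_freq"))
        else NA_real_,
      gamma_peak_power_median =
        if (length(gam)) stats::median(vapply(gam, `[[`, 0, "peak_power"))
        else NA_real_)
  }))
  list(records = records, stateTable = stateTable, summary = summary)
}

#' Compare state distributions between conditions
#'
#' For each pair of conditions, collapses the state table to a 2x2 table of
#' the chosen state versus its absence ("Gamma" vs "No Gamma") and applies
#' \code{\link{fisherExact2x2}}. Raw per-pair p-values are reported (no
#' multiplicity correction).
#'
#' @param stateTable condition x state count matrix (rows = conditions).
#' @param state the state to test, e.g. "Gamma".
#' @return data.frame with \code{condition_a}, \code{condition_b},
#'   \code{p_value}.
#' @export
compareConditions <- function(stateTable, state = "Gamma") {
  conds <- rownames(stateTable)
  stopifnot2(length(conds) >= 2, "need at least two conditions")
  stopifnot2(state %in% colnames(stateTable), "unknown state column")
  pairs <- utils::combn(conds, 2)
  out <- apply(pairs, 2, function(pr) {
    has <- stateTable[pr, state]
    tot <- rowSums(stateTable[pr, , drop = FALSE])
    tbl <- cbind(has, tot - has)
    p <- if (all(tbl[, 1] == 0) || all(tbl[, 2] == 0)) {
      warning("degenerate margins; p = 1")
      1
    } else fisherExact2x2(tbl)
    data.frame(condition_a = pr[1], condition_b = pr[2], p_value = p)
  })
  do.call(rbind, out)
}
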