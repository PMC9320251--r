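.RESPONSE_COLS <- c("delta_t", "hr_max", "v_resp", "dhr_wb", "dhr_rw",
                    "dhr_rb")
.HRV_COLS <- c("mean_hr", "mean_rr", "sdnn", "cv", "rmssd", "pnn50",
               "pnn30", "lf_ms2", "hf_ms2", "lf_nu", "hf_nu", "lf_hf",
               "edr", "sd1", "sd2", "sd1_sd2", "apen", "sampen", "alpha1")

# Process one subject end to end; returns list(indices, response, log).
.processSubject <- function(id, group, rr, ecg, settings, maxArtifactFrac) {
  logRow <- function(status, reason = NA_character_, frac = NA_real_,
                     nCorr = NA_integer_) {
    data.frame(subject_id = id, group = group, status = status,
               artifact_fraction = frac, n_corrected = nCorr,
               reason = reason, stringsAsFactors = FALSE)
  }
  tryCatch({
    if (!is.null(ecg)) {
      beats <- detectRPeaks(ecg)
      if (length(beats) < 2) stop("no beats detected in ECG")
      seg <- if (!is.null(rr)) segmentation(rr) else NULL
      rr0 <- extractRR(beats)
      rr0@segmentation <- seg
      rr <- rr0
    } else {
      beats <- NULL
    }
    rr <- suppressMessages(flagAnomalousIntervals(rr))
    dec <- applyExclusionRule(rr, maxArtifactFrac)
    if (!dec$include) {
      return(list(indices = NULL, response = NULL,
                  log = logRow("excluded",
                               sprintf("artifact_fraction > %.3g",
                                       maxArtifactFrac),
                               frac = dec$fraction)))
    }
    nFlagged <- dec$nFlagged
    rr <- suppressWarnings(correctIntervals(rr))
    seg <- segmentation(rr)
    if (is.null(seg)) stop("no phase segmentation available")
    phases <- segmentPhases(rr, seg)
    idx <- do.call(rbind, lapply(c("baseline", "recovery"), function(p) {
      phaseBeats <- if (!is.null(beats)) {
        lims <- switch(p,
                       baseline = c(seg@tBaselineStart, seg@tWalkStart),
                       recovery = c(seg@tWalkEnd, seg@tRecoveryEnd))
        sel <- beats@rTimes > lims[1] & beats@rTimes <= lims[2]
        if (sum(sel) >= 2)
          BeatSeries(beats@rTimes[sel], beats@rAmplitudes[sel]) else NULL
      } else NULL
      cbind(data.frame(subject_id = id, group = group, phase = p,
                       stringsAsFactors = FALSE),
            suppressWarnings(computeHrvIndices(phases[[p]], settings,
                                               beats = phaseBeats)))
    }))
    resp <- cbind(data.frame(subject_id = id, group = group,
                             stringsAsFactors = FALSE),
                  suppressWarnings(computeResponseIndices(rr, seg, settings)))
    list(indices = idx, response = resp,
         log = logRow("included", frac = dec$fraction,
                      nCorr = sum(beatAnnotations(rr) == "corrected")))
  }, error = function(e) {
    list(indices = NULL, response = NULL,
         log = logRow("error", reason = conditionMessage(e)))
  })
}

#' Run the full walking-test analysis pipeline
#'
#' Orchestrates every stage — simulate (or load) the cohort, detect beats
#' when ECG is the input, flag/exclude/correct artifacts, compute 5-min
#' HRV indices for baseline and recovery, compute the chronotropic
#' response, summarize by group and evaluate the frail-vs-non-frail
#' biomarkers. A failing subject is isolated (logged with its error)
#' without aborting the cohort; every input subject appears exactly once
#' in the run log. With a fixed configuration and seed the written CSVs
#' are byte-identical across runs.
#'
#' Output files in `outDir`: `hrv_indices.csv`, `response_indices.csv`,
#' `group_summary.csv`, `roc_auc.csv`, `diagnostic_performance.csv`,
#' `run_log.csv`.
#'
#' @param cohort a [cohortConfig()] list (simulation input), or `NULL`.
#' @param manifest path to a manifest CSV (file input), or `NULL`. Exactly
#'   one of `cohort` / `manifest` must be given.
#' @param settings an [analysisSettings()] list.
#' @param outDir output directory; created if missing. `NULL` skips
#'   writing.
#' @param positive,negative group labels for the biomarker evaluation.
#' @param maxArtifactFrac exclusion threshold on the flagged fraction.
#' @param evalIndices index columns evaluated as biomarkers (baseline
#'   phase) in addition to the response indices.
#' @return (invisibly) a list with `indices`, `response`, `summary`,
#'   `roc`, `performance`, `log` data.frames.
#' @export
runPipeline <- function(cohort = NULL, manifest = NULL,
                        settings = analysisSettings(), outDir = NULL,
                        positive = "F", negative = "nF",
                        maxArtifactFrac = 0.05,
                        evalIndices = c("lf_nu", "hf_nu", "lf_hf", "sampen",
                                        "alpha1", "pnn50", "edr")) {
  .stopIfNot(xor(is.null(cohort), is.null(manifest)),
             "exactly one input source (cohort or manifest) must be given")
  subjects <- list()
  if (!is.null(cohort)) {
    sim <- generateCohort(cohort)
    for (s in sim$subjects)
      subjects[[s$id]] <- list(id = s$id, group = s$group, rr = s$rr,
                               ecg = s$ecg)
  } else {
    m <- readManifest(manifest)
    base <- dirname(manifest)
    resolve <- function(p) if (file.exists(p)) p else file.path(base, p)
    for (i in seq_len(nrow(m))) {
      rr <- readRR(resolve(m$rr_path[i]))
      if (is.null(segmentation(rr)))
        rr@segmentation <- suppressWarnings(PhaseSegmentation(
          tWalkStart = m$t_walk_start_s[i], tWalkEnd = m$t_walk_end_s[i],
          tRecoveryEnd = max(beatTimes(rr))))
      ecg <- if (!is.na(m$ecg_path[i])) readEcg(resolve(m$ecg_path[i]))
        else NULL
      subjects[[m$subject_id[i]]] <- list(id = m$subject_id[i],
                                          group = m$group[i], rr = rr,
                                          ecg = ecg)
    }
  }
  .stopIfNot(length(subjects) >= 1, "empty cohort")

  res <- lapply(subjects, function(s)
    .processSubject(s$id, s$group, s$rr, s$ecg, settings, maxArtifactFrac))
  indices <- do.call(rbind, c(Filter(Negate(is.null),
                                     lapply(res, `[[`, "indices")),
                              list(make.row.names = FALSE)))
  response <- do.call(rbind, c(Filter(Negate(is.null),
                                      lapply(res, `[[`, "response")),
                               list(make.row.names = FALSE)))
  runLog <- do.call(rbind, c(lapply(res, `[[`, "log"),
                             list(make.row.names = FALSE)))
  .stopIfNot(!is.null(indices) && nrow(indices) > 0,
             "empty cohort after exclusions")

  summaryTab <- .groupSummary(indices, response)

  evalTab <- indices[indices$phase == "baseline",
                     c("subject_id", "group", .HRV_COLS)]
  evalTab <- merge(evalTab, response[, c("subject_id", .RESPONSE_COLS)],
                   by = "subject_id", sort = TRUE)
  haveBoth <- sum(evalTab$group == positive) >= 2 &&
    sum(evalTab$group == negative) >= 2
  bm <- if (haveBoth) {
    suppressMessages(evaluateBiomarkers(
      evalTab, intersect(c(evalIndices, .RESPONSE_COLS), names(evalTab)),
      labelCol = "group", positive = positive, negative = negative))
  } else list(roc = NULL, performance = NULL)

  out <- list(indices = indices, response = response, summary = summaryTab,
              roc = bm$roc, performance = bm$performance, log = runLog)
  if (!is.null(outDir)) {
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    wr <- function(df, f) utils::write.csv(
      df, file.path(outDir, f), row.names = FALSE, na = "")
    wr(indices, "hrv_indices.csv")
    wr(response, "response_indices.csv")
    wr(summaryTab, "group_summary.csv")
    wr(bm$roc %||% data.frame(), "roc_auc.csv")
    wr(bm$performance %||% data.frame(), "diagnostic_performance.csv")
    wr(runLog, "run_log.csv")
  }
  invisible(out)
}

# Long-format group summary: one row per (phase, variable, group).
.groupSummary <- function(indices, response) {
  rows <- list()
  addBlock <- function(df, phase, cols) {
    for (v in cols) {
      x <- df[[v]]
      for (gr in sort(unique(df$group))) {
        xs <- x[df$group == gr & is.finite(x)]
        if (!length(xs)) next
        rows[[length(rows) + 1L]] <<- data.frame(
          phase = phase, variable = v, group = gr, n = length(xs),
          median = median(xs), p25 = unname(quantile(xs, 0.25)),
          p75 = unname(quantile(xs, 0.75)), stringsAsFactors = FALSE)
      }
    }
  }
  for (p in unique(indices$phase))
    addBlock(indices[indices$phase == p, ], p, .HRV_COLS)
  addBlock(response, "response", .RESPONSE_COLS)
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

.fmtCell <- function(med, p25, p75, digits = 1) {
  fmt <- function(x) formatC(x, format = "f", digits = digits)
  sprintf("%s (%s–%s)", fmt(med), fmt(p25), fmt(p75))
}

#' Render group summaries as a markdown table
#'
#' Formats the long-form group summary of [runPipeline()] in the study's
#' reporting style: one column per group, cells as
#' `median (p25`&#8211;`p75)`, and a significance marker on groups whose
#' pairwise Mann-Whitney test against the first (reference) group has
#' p <= 0.05 (uncorrected by default, mirroring the source analysis;
#' `pAdjust = "holm"` applies a Holm correction).
#'
#' @param summary the `summary` element of a [runPipeline()] result.
#' @param indices the `indices` element (subject-level values, used for
#'   the pairwise tests); `NULL` skips markers.
#' @param response the `response` element; `NULL` skips response markers.
#' @param phase which phase block to render (`"baseline"`, `"recovery"`
#'   or `"response"`).
#' @param digits decimals in the formatted cells.
#' @param pAdjust p-adjustment for the pairwise tests, default `"none"`.
#' @return a character vector of markdown lines (invisibly printable with
#'   `cat(..., sep = "\n")`).
#' @export
renderTables <- function(summary, indices = NULL, response = NULL,
                         phase = "baseline", digits = 1, pAdjust = "none") {
  .stopIfNot(is.data.frame(summary) && nrow(summary) > 0,
             "summary must be a non-empty data.frame")
  blk <- summary[summary$phase == phase, ]
  .stopIfNot(nrow(blk) > 0, "no such phase in summary: ", phase)
  groups <- sort(unique(blk$group))
  subjData <- if (phase == "response") response else
    if (!is.null(indices)) indices[indices$phase == phase, ] else NULL
  header <- paste0("| variable | ", paste(groups, collapse = " | "), " |")
  sepln <- paste0("|", paste(rep("---", length(groups) + 1L),
                             collapse = "|"), "|")
  lines <- c(header, sepln)
  for (v in unique(blk$variable)) {
    marks <- setNames(rep("", length(groups)), groups)
    if (!is.null(subjData) && v %in% names(subjData) &&
        length(groups) >= 2) {
      ref <- groups[1]
      cmp <- tryCatch(
        compareGroups(subjData, v, "group", pAdjust = pAdjust),
        warning = function(w) NULL, error = function(e) NULL)
      if (!is.null(cmp) && !is.null(cmp$pairwise)) {
        pw <- cmp$pairwise
        hit <- pw[(pw$group1 == ref | pw$group2 == ref) &
                    pw$p_adjusted <= 0.05, ]
        other <- setdiff(unlist(hit[, c("group1", "group2")]), ref)
        marks[other] <- " \\*"
      }
    }
    cells <- vapply(groups, function(gr) {
      r <- blk[blk$variable == v & blk$group == gr, ]
      if (!nrow(r)) return("(absent)")
      paste0(.fmtCell(r$median, r$p25, r$p75, digits), marks[[gr]])
    }, character(1))
    lines <- c(lines, paste0("| ", v, " | ",
                             paste(cells, collapse = " | "), " |"))
  }
  missing <- setdiff(groups, unique(blk$group))
  if (length(missing))
    lines <- c(lines, "", paste0("Missing group column(s): ",
                                 paste(missing, collapse = ", ")))
  lines <- c(lines,
             "", paste0("\\* p <= 0.05 vs ", groups[1],
                        " (pairwise Mann–Whitney)"))
  lines
}
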