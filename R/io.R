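#' Read and write RR-interval files
#'
#' The RR plain-text format stores one interval per line in milliseconds,
#' preceded by `#`-prefixed header lines carrying metadata: `subject_id`
#' and, when known, the phase boundaries in seconds (`t_baseline_start_s`,
#' `t_walk_start_s`, `t_walk_end_s`, `t_recovery_end_s`) and the
#' per-interval annotation string (comma-separated, only written when any
#' interval is non-normal).
#'
#' @param x an [RRSeries-class].
#' @param path file path.
#' @return `readRR()` returns an [RRSeries-class]; `writeRR()` returns
#'   `path` invisibly.
#' @export
writeRR <- function(x, path) {
  .stopIfNot(is(x, "RRSeries"), "x must be an RRSeries")
  hdr <- c(sprintf("# subject_id: %s", x@subjectId))
  if (!is.null(x@segmentation)) {
    s <- x@segmentation
    hdr <- c(hdr,
             sprintf("# t_baseline_start_s: %.6g", s@tBaselineStart),
             sprintf("# t_walk_start_s: %.6g", s@tWalkStart),
             sprintf("# t_walk_end_s: %.6g", s@tWalkEnd),
             sprintf("# t_recovery_end_s: %.6g", s@tRecoveryEnd))
  }
  if (any(x@annotations != "normal"))
    hdr <- c(hdr, paste0("# annotations: ",
                         paste(x@annotations, collapse = ",")))
  writeLines(c(hdr, formatC(x@intervals, format = "f", digits = 6)), path)
  invisible(path)
}

#' @rdname writeRR
#' @export
readRR <- function(path) {
  .stopIfNot(file.exists(path), "no such file: ", path)
  lines <- readLines(path)
  isHdr <- startsWith(lines, "#")
  meta <- list()
  for (h in lines[isHdr]) {
    kv <- sub("^#\\s*", "", h)
    key <- sub(":.*$", "", kv)
    meta[[trimws(key)]] <- trimws(sub("^[^:]*:", "", kv))
  }
  intervals <- as.numeric(lines[!isHdr & nzchar(trimws(lines))])
  .stopIfNot(length(intervals) >= 1 && !anyNA(intervals),
             "no parseable intervals in ", path)
  seg <- NULL
  if (!is.null(meta$t_walk_start_s)) {
    seg <- suppressWarnings(PhaseSegmentation(
      tBaselineStart = as.numeric(meta$t_baseline_start_s %||% "0"),
      tWalkStart = as.numeric(meta$t_walk_start_s),
      tWalkEnd = as.numeric(meta$t_walk_end_s),
      tRecoveryEnd = as.numeric(
        meta$t_recovery_end_s %||% (as.numeric(meta$t_walk_end_s) + 300))))
  }
  ann <- if (!is.null(meta$annotations)) {
    strsplit(meta$annotations, ",")[[1]]
  } else rep("normal", length(intervals))
  beatT <- cumsum(intervals) / 1000
  phases <- if (!is.null(seg)) .assignPhases(beatT, seg) else
    rep(NA_character_, length(intervals))
  RRSeries(intervals = intervals, beatTimes = beatT, annotations = ann,
           phases = phases, segmentation = seg,
           subjectId = meta$subject_id %||% NA_character_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read and write ECG CSV files
#'
#' CSV with columns `sample_index` (0-based) and `mv`; a `#`-prefixed header
#' comment states the sampling rate (`# sampling_rate: 250`).
#'
#' @param x an [ECGRecord-class].
#' @param path file path.
#' @param samplingRate fallback sampling rate (Hz) when the file has no
#'   header comment.
#' @return `readEcg()` returns an [ECGRecord-class]; `writeEcg()` returns
#'   `path` invisibly.
#' @export
writeEcg <- function(x, path) {
  .stopIfNot(is(x, "ECGRecord"), "x must be an ECGRecord")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# sampling_rate: %g", x@samplingRate),
               sprintf("# subject_id: %s", x@subjectId),
               "sample_index,mv"), con)
  writeLines(sprintf("%d,%.6g", seq_along(x@samples) - 1L, x@samples), con)
  invisible(path)
}

#' @rdname writeEcg
#' @export
readEcg <- function(path, samplingRate = NULL) {
  .stopIfNot(file.exists(path), "no such file: ", path)
  lines <- readLines(path)
  isHdr <- startsWith(lines, "#")
  fs <- samplingRate
  sid <- NA_character_
  for (h in lines[isHdr]) {
    if (grepl("sampling_rate", h))
      fs <- as.numeric(sub("^.*:", "", h))
    if (grepl("subject_id", h))
      sid <- trimws(sub("^.*:", "", h))
  }
  .stopIfNot(!is.null(fs) && is.finite(fs) && fs > 0,
             "sampling rate neither in file header nor supplied")
  body <- lines[!isHdr]
  body <- body[nzchar(trimws(body))]
  .stopIfNot(length(body) >= 2, "no samples in ", path)
  dat <- utils::read.csv(text = body, header = TRUE)
  .stopIfNot(all(c("sample_index", "mv") %in% names(dat)),
             "ECG CSV must have columns sample_index, mv")
  ECGRecord(samples = dat$mv, samplingRate = fs, subjectId = sid)
}

#' Read and write cohort manifests
#'
#' CSV with columns `subject_id`, `group`, `rr_path`, `ecg_path` (optional,
#' may be empty), `t_walk_start_s`, `t_walk_end_s`.
#'
#' @param manifest a data.frame with the columns above.
#' @param path file path.
#' @return `readManifest()` returns the manifest data.frame;
#'   `writeManifest()` returns `path` invisibly.
#' @export
writeManifest <- function(manifest, path) {
  .stopIfNot(is.data.frame(manifest), "manifest must be a data.frame")
  utils::write.csv(manifest, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname writeManifest
#' @export
readManifest <- function(path) {
  .stopIfNot(file.exists(path), "no such file: ", path)
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "rr_path", "t_walk_start_s",
            "t_walk_end_s")
  .stopIfNot(all(need %in% names(m)),
             "manifest must have columns: ", paste(need, collapse = ", "))
  if (!"ecg_path" %in% names(m)) m$ecg_path <- NA_character_
  m$ecg_path[!nzchar(trimws(ifelse(is.na(m$ecg_path), "", m$ecg_path)))] <-
    NA_character_
  m
}

#' Read a pipeline configuration file
#'
#' Structured YAML (or JSON, which YAML parses) mirroring the arguments of
#' [runPipeline()]: either a `cohort` block (group sizes, seed, optional
#' per-group profile overrides) or a `manifest` path — exactly one of the
#' two — plus optional `settings`, `evaluation` and `output` blocks. A seed
#' is mandatory when simulating.
#'
#' @param path path to the YAML file.
#' @return a named list of [runPipeline()] arguments.
#' @export
readPipelineConfig <- function(path) {
  .stopIfNot(file.exists(path), "no such file: ", path)
  cfg <- yaml::read_yaml(path)
  hasSim <- !is.null(cfg$cohort)
  hasFiles <- !is.null(cfg$manifest)
  .stopIfNot(xor(hasSim, hasFiles),
             "config must name exactly one input source: 'cohort' or 'manifest'")
  out <- list()
  if (hasSim) {
    .stopIfNot(!is.null(cfg$cohort$seed), "cohort.seed is mandatory")
    # YAML 1.1 parses a bare key "n" as boolean false; accept both spellings
    # plus the explicit alias "sizes"
    nn <- cfg$cohort$n %||% cfg$cohort$sizes %||% cfg$cohort[["FALSE"]]
    .stopIfNot(!is.null(nn), "cohort block must give group sizes (n:)")
    out$cohort <- cohortConfig(
      n = unlist(nn), seed = cfg$cohort$seed,
      ecg = isTRUE(cfg$cohort$ecg), profiles = cfg$cohort$profiles)
  } else {
    out$manifest <- cfg$manifest
  }
  if (!is.null(cfg$settings))
    out$settings <- do.call(analysisSettings, cfg$settings)
  if (!is.null(cfg$evaluation)) {
    out$positive <- cfg$evaluation$positive %||% "F"
    out$negative <- cfg$evaluation$negative %||% "nF"
  }
  if (!is.null(cfg$output)) out$outDir <- cfg$output
  out
}
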