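#' Construct a centroided LC-MS run
#'
#' An `ms_run` holds an ordered scan table (retention times in minutes) and
#' a centroided peak table. Retention times must be strictly increasing and
#' peaks are kept sorted by m/z within each scan; unsorted input is repaired
#' with a warning.
#'
#' @param scans Tibble/data frame with columns `scan` (integer id) and `rt`
#'   (minutes), one row per scan, strictly increasing `rt`.
#' @param peaks Tibble/data frame with columns `scan`, `mz` (Th), `intensity`
#'   (arbitrary units, >= 0). Scans without peaks are allowed.
#' @param metadata Named list of free-form metadata (instrument, source, ...).
#' @return An object of class `ms_run`.
#' @export
ms_run <- function(scans, peaks, metadata = list()) {
  scans <- as_tibble(scans)[, c("scan", "rt")]
  peaks <- as_tibble(peaks)[, c("scan", "mz", "intensity")]
  if (nrow(scans) == 0L) stop_format("empty run: no scans")
  if (is.unsorted(scans$rt, strictly = TRUE)) {
    warn("scan retention times not strictly increasing; reordering scans")
    scans <- dplyr::arrange(scans, .data$rt)
  }
  if (any(peaks$intensity < 0)) stop_validation("peak intensities must be >= 0")
  if (any(!peaks$scan %in% scans$scan)) {
    stop_validation("peaks reference scan ids absent from the scan table")
  }
  peaks <- dplyr::arrange(peaks, .data$scan, .data$mz)
  structure(list(scans = scans, peaks = peaks, metadata = metadata),
            class = "ms_run")
}

#' @export
print.ms_run <- function(x, ...) {
  cat("<ms_run> ", nrow(x$scans), " scans, ", nrow(x$peaks), " peaks, RT ",
      sprintf("%.2f-%.2f", min(x$scans$rt), max(x$scans$rt)), " min\n", sep = "")
  invisible(x)
}

#' Read a centroided LC-MS run
#'
#' Supported formats: `"mzml"` (MS1 centroid subset, read through mzR;
#' profile-mode spectra are rejected with guidance to centroid upstream),
#' `"json"` (the package's fixture format: a list of scans with `rt`, `mz`,
#' `intensity` arrays plus a `metadata` block), and `"csv"` (a flat peak
#' table with columns `scan`, `rt`, `mz`, `intensity`; peak-free scans are
#' not representable). `"auto"` picks by file extension.
#'
#' @param path Input file.
#' @param format One of `"auto"`, `"mzml"`, `"json"`, `"csv"`.
#' @return An [ms_run()].
#' @export
read_ms_run <- function(path, format = c("auto", "mzml", "json", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_format(sprintf("file not found: %s", path))
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, mzml = "mzml", json = "json", csv = "csv",
                     stop_format(sprintf("cannot infer run format from extension '.%s'", ext)))
  }
  switch(format,
         mzml = read_run_mzml(path),
         json = read_run_json(path),
         csv = read_run_csv(path))
}

read_run_mzml <- function(path) {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    stop_config("reading mzML requires the mzR package")
  }
  h <- mzR::openMSfile(path)
  on.exit(mzR::close(h), add = TRUE)
  hdr <- mzR::header(h)
  if (nrow(hdr) == 0L) stop_format("empty run: mzML file contains no spectra")
  ms1 <- hdr$msLevel == 1L
  if (!any(ms1)) stop_format("no MS1 spectra in mzML file")
  if (any(!is.na(hdr$centroided) & !hdr$centroided)) {
    stop_format(paste("profile-mode spectra found; this workflow requires",
                      "centroided data - centroid during conversion (e.g. msconvert peakPicking)"))
  }
  pk <- mzR::peaks(h)
  if (is.matrix(pk)) pk <- list(pk)
  idx <- which(ms1)
  peaks <- dplyr::bind_rows(purrr::map(seq_along(idx), function(i) {
    m <- pk[[idx[i]]]
    tibble(scan = i, mz = m[, 1], intensity = m[, 2])
  }))
  scans <- tibble(scan = seq_along(idx),
                  rt = hdr$retentionTime[idx] / 60)   # mzR reports seconds
  ms_run(scans, peaks, metadata = list(source = path, format = "mzml"))
}

read_run_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$scans) || length(x$scans$rt) == 0L) stop_format("empty run")
  sc <- x$scans
  peaks <- dplyr::bind_rows(purrr::map(seq_along(sc$rt), function(i) {
    tibble(scan = i,
           mz = as.numeric(sc$mz[[i]]),
           intensity = as.numeric(sc$intensity[[i]]))
  }))
  scans <- tibble(scan = seq_along(sc$rt), rt = as.numeric(sc$rt))
  ms_run(scans, peaks, metadata = as.list(x$metadata) %||% list())
}

read_run_csv <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("scan", "rt", "mz", "intensity")
  if (!all(need %in% names(d))) {
    stop_format(sprintf("run CSV must have columns %s", paste(need, collapse = ", ")))
  }
  if (nrow(d) == 0L) stop_format("empty run")
  scans <- dplyr::distinct(d[, c("scan", "rt")])
  ms_run(scans, d[, c("scan", "mz", "intensity")],
         metadata = list(source = path, format = "csv"))
}

#' Write an LC-MS run
#'
#' Inverse of [read_ms_run()] for the three supported formats. mzML output
#' (via mzR) is a minimal MS1 centroid file that round-trips through
#' [read_ms_run()].
#'
#' @param run An [ms_run()].
#' @param path Output file.
#' @param format One of `"auto"`, `"mzml"`, `"json"`, `"csv"`.
#' @return `path`, invisibly.
#' @export
write_ms_run <- function(run, path, format = c("auto", "mzml", "json", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, mzml = "mzml", json = "json", csv = "csv",
                     stop_format(sprintf("cannot infer run format from extension '.%s'", ext)))
  }
  by_scan <- split(run$peaks, factor(run$peaks$scan, levels = run$scans$scan))
  switch(format,
    json = {
      scans <- list(
        rt = run$scans$rt,
        mz = purrr::map(by_scan, function(p) p$mz),
        intensity = purrr::map(by_scan, function(p) p$intensity))
      jsonlite::write_json(list(metadata = run$metadata, scans = scans),
                           path, auto_unbox = TRUE, digits = NA)
    },
    csv = {
      d <- dplyr::left_join(run$peaks, run$scans, by = "scan")
      readr::write_csv(d[, c("scan", "rt", "mz", "intensity")], path)
    },
    mzml = write_run_mzml(run, by_scan, path))
  invisible(path)
}

write_run_mzml <- function(run, by_scan, path) {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    stop_config("writing mzML requires the mzR package")
  }
  pks <- purrr::map(by_scan, function(p) cbind(mz = p$mz, intensity = p$intensity))
  n <- length(pks)
  cnt <- vapply(pks, nrow, integer(1))
  safe_max <- function(x) if (length(x)) max(x) else 0
  safe_min <- function(x) if (length(x)) min(x) else 0
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n), msLevel = 1L,
    polarity = 1L, peaksCount = cnt,
    totIonCurrent = vapply(pks, function(m) sum(m[, 2]), numeric(1)),
    retentionTime = run$scans$rt * 60,
    basePeakMZ = vapply(pks, function(m) if (nrow(m)) m[which.max(m[, 2]), 1] else 0, numeric(1)),
    basePeakIntensity = vapply(pks, function(m) safe_max(m[, 2]), numeric(1)),
    collisionEnergy = 0, ionisationEnergy = 0,
    lowMZ = vapply(pks, function(m) safe_min(m[, 1]), numeric(1)),
    highMZ = vapply(pks, function(m) safe_max(m[, 1]), numeric(1)),
    precursorScanNum = 0L, precursorMZ = 0, precursorCharge = 0L,
    precursorIntensity = 0, mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = NA_character_,
    spectrumId = sprintf("scan=%d", seq_len(n)),
    centroided = TRUE, ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = NA_real_, isolationWindowLowerOffset = NA_real_,
    isolationWindowUpperOffset = NA_real_, scanWindowLowerLimit = NA_real_,
    scanWindowUpperLimit = NA_real_, stringsAsFactors = FALSE)
  mzR::writeMSData(unname(pks), file = path, header = hdr)
  invisible(path)
}
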