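#' Write segments to CSV (samples + sidecar label table)
#'
#' Samples go to `<prefix>_samples.csv`, one column per segment (named by
#' `record_id.start`), one row per sample; metadata to `<prefix>_labels.csv`
#' with columns `segment`, `record_id`, `start`, `fs`, `label`, `rhythm`,
#' `excluded`, `reason`.
#'
#' @param segments list of [ecg_segment()] objects of equal length.
#' @param prefix path prefix for the two files.
#' @return invisibly, the two file paths.
#' @export
write_segments_csv <- function(segments, prefix) {
  stopifnot(length(segments) > 0)
  ids <- vapply(segments, function(s) paste0(s$record_id, ".", s$start),
                character(1))
  mat <- vapply(segments, function(s) s$samples,
                numeric(length(segments[[1]]$samples)))
  colnames(mat) <- ids
  sp <- paste0(prefix, "_samples.csv")
  lp <- paste0(prefix, "_labels.csv")
  utils::write.csv(mat, sp, row.names = FALSE)
  meta <- do.call(rbind, lapply(seq_along(segments), function(i) {
    s <- segments[[i]]
    data.frame(segment = ids[i], record_id = s$record_id, start = s$start,
               fs = s$fs, label = s$label, rhythm = s$rhythm,
               excluded = s$excluded,
               reason = ifelse(is.na(s$reason), "", s$reason))
  }))
  utils::write.csv(meta, lp, row.names = FALSE)
  invisible(c(samples = sp, labels = lp))
}

#' Read segments written by [write_segments_csv()]
#'
#' @param prefix the path prefix used when writing.
#' @return a list of [ecg_segment()] objects.
#' @export
read_segments_csv <- function(prefix) {
  mat <- utils::read.csv(paste0(prefix, "_samples.csv"), check.names = FALSE)
  meta <- utils::read.csv(paste0(prefix, "_labels.csv"),
                          colClasses = c(reason = "character"))
  lapply(seq_len(nrow(meta)), function(i) {
    m <- meta[i, ]
    ecg_segment(m$record_id, m$start, mat[[m$segment]], m$fs, m$label,
                rhythm = m$rhythm, excluded = m$excluded,
                reason = if (nzchar(m$reason)) m$reason else NA_character_)
  })
}

#' Rhythm-annotation code mapping
#'
#' Loads the editable table translating raw annotation codes to the
#' package's rhythm vocabulary (`VF`, `VT`, `VFL`, `N`, `noise`, `asystole`,
#' `transition`). The default table ships in
#' `inst/extdata/rhythm_map.csv`; unknown codes map to `"N"` (other
#' non-shockable) with a message.
#'
#' @param path optional path to a custom two-column CSV (`code`, `rhythm`).
#' @return named character vector mapping code to rhythm.
#' @export
rhythm_map <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "rhythm_map.csv", package = "shockadvice")
  tab <- utils::read.csv(path, colClasses = "character")
  stats::setNames(tab$rhythm, tab$code)
}

#' Write a record as a WFDB-compatible header/signal pair
#'
#' Writes `<record>.hea` and `<record>.dat` (format 16: 16-bit little-endian
#' integers, gain 200 adu/mV) plus, when the record carries annotations, a
#' plain-text `<record>.ann.csv` sidecar with columns `sample`, `rhythm`.
#' This is a deliberate subset of the WFDB family -- single signal, format
#' 16, text annotations -- sufficient for round-tripping records produced by
#' the synthetic generator.
#'
#' @param record an [ecg_record()].
#' @param dir output directory.
#' @return invisibly, the header path.
#' @export
write_wfdb <- function(record, dir) {
  stopifnot(inherits(record, "ecg_record"))
  gain <- 200
  name <- record$record_id
  hea <- file.path(dir, paste0(name, ".hea"))
  dat <- paste0(name, ".dat")
  adu <- as.integer(round(record$samples * gain))
  if (any(abs(adu) > 32767)) stop("signal exceeds 16-bit range at gain 200")
  writeLines(c(sprintf("%s 1 %g %d", name, record$fs, length(adu)),
               sprintf("%s 16 %d/mV 16 0 %d %d 0 ECG",
                       dat, gain, adu[1], sum(adu) %% 65536)),
             hea)
  con <- file(file.path(dir, dat), "wb")
  writeBin(adu, con, size = 2, endian = "little")
  close(con)
  if (nrow(record$annotations))
    utils::write.csv(record$annotations,
                     file.path(dir, paste0(name, ".ann.csv")),
                     row.names = FALSE)
  invisible(hea)
}

#' Read a WFDB record (header + format-16 signal)
#'
#' Parses the `.hea` header, reads the interleaved `.dat` samples, converts
#' to mV by the per-signal gain and returns the requested channel (the
#' first, by default, as multi-channel records are analyzed on channel 1).
#' Annotations are read from a `<record>.ann.csv` sidecar when present
#' (otherwise the record is returned with empty annotations and a warning)
#' and translated through [rhythm_map()].
#'
#' @param path path to the `.hea` file (with or without the extension).
#' @param channel 0-based channel index (default 0, the first channel).
#' @param map rhythm-code mapping, default [rhythm_map()].
#' @return an [ecg_record()].
#' @export
read_wfdb_record <- function(path, channel = 0, map = rhythm_map()) {
  path <- sub("\\.hea$", "", path)
  hea <- readLines(paste0(path, ".hea"))
  hea <- hea[!grepl("^#", hea)]
  top <- strsplit(trimws(hea[1]), "\\s+")[[1]]
  name <- top[1]
  nsig <- as.integer(top[2])
  fs <- as.numeric(top[3])
  nsamp <- if (length(top) >= 4) as.integer(top[4]) else NA_integer_
  if (channel < 0 || channel >= nsig)
    stop(sprintf("channel %d not present (record has %d signal(s))",
                 channel, nsig))
  sig <- strsplit(trimws(hea[2 + channel]), "\\s+")[[1]]
  fmt <- as.integer(sig[2])
  if (fmt != 16) stop("only WFDB format 16 is supported")
  gain <- as.numeric(sub("[(/].*$", "", sig[3]))
  if (!is.finite(gain) || gain <= 0) gain <- 200
  datfile <- file.path(dirname(paste0(path, ".hea")), sig[1])
  raw <- readBin(datfile, integer(), n = file.size(datfile) / 2,
                 size = 2, endian = "little")
  x <- raw[seq(channel + 1, length(raw), by = nsig)] / gain
  if (!is.na(nsamp) && length(x) > nsamp) x <- x[seq_len(nsamp)]
  annfile <- paste0(path, ".ann.csv")
  if (file.exists(annfile)) {
    ann <- utils::read.csv(annfile, colClasses = c(rhythm = "character"))
    mapped <- map[ann$rhythm]
    unknown <- is.na(mapped)
    if (any(unknown)) {
      message("unknown rhythm code(s) mapped to non-shockable: ",
              paste(unique(ann$rhythm[unknown]), collapse = ", "))
      mapped[unknown] <- "N"
    }
    ann$rhythm <- unname(mapped)
  } else {
    warning(sprintf("no annotation sidecar for %s; loading without annotations",
                    name))
    ann <- data.frame(sample = 0L, rhythm = "N")
  }
  ecg_record(name, x, fs, ann)
}

#' Write a reproducibility manifest
#'
#' Records everything needed to rerun a pipeline invocation bit for bit:
#' package and R versions, the seeds, and the full configuration (rather
#' than a hash, so the manifest is self-contained).
#'
#' @param path output JSON path.
#' @param config named list of configuration objects (coerced to plain
#'   lists).
#' @param seeds named list/vector of seeds used.
#' @return invisibly, `path`.
#' @export
write_run_manifest <- function(path, config = list(), seeds = list()) {
  manifest <- list(
    package = "shockadvice",
    version = as.character(utils::packageVersion("shockadvice")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seeds = seeds,
    config = lapply(config, function(x) unclass(x)))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
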