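# BrainVision Core Data Format 1.0 reader/writer.
# A recording is a triplet: .vhdr (INI header), .vmrk (markers), .eeg (binary).
# Writer emits IEEE float32, multiplexed, little-endian; reader additionally
# accepts INT_16 (scaled by the per-channel resolution) and VECTORIZED order.

parse_ini <- function(lines) {
  lines <- sub("﻿", "", lines)
  lines <- lines[!grepl("^\\s*[;#]", lines)]
  sec <- NA_character_
  out <- list()
  for (ln in lines) {
    if (grepl("^\\s*\\[.+\\]\\s*$", ln)) {
      sec <- gsub("^\\s*\\[|\\]\\s*$", "", ln)
      out[[sec]] <- character()
    } else if (grepl("=", ln, fixed = TRUE) && !is.na(sec)) {
      key <- sub("=.*$", "", ln)
      val <- sub("^[^=]*=", "", ln)
      out[[sec]][trimws(key)] <- val
    }
  }
  out
}

#' Read a BrainVision recording
#'
#' Reads the `.vhdr` header, its companion `.eeg` binary data file and
#' `.vmrk` marker file. Data are returned in microvolts (the per-channel
#' resolution declared in the header is applied). Markers of type
#' `"Stimulus"` become event markers; their 1-based positions are converted
#' to 0-based sample indices.
#'
#' @param header_path path to the `.vhdr` file.
#' @param marker_map named character vector mapping marker codes to
#'   conditions; see [default_marker_map()]. Codes absent from the map get
#'   condition `NA`.
#' @return a [continuous_recording()].
#' @export
read_brainvision <- function(header_path, marker_map = default_marker_map()) {
  stop_if_not(file.exists(header_path), "header file not found: %s", header_path)
  hdr <- parse_ini(readLines(header_path, warn = FALSE, encoding = "UTF-8"))
  ci <- hdr[["Common Infos"]]
  stop_if_not(!is.null(ci), "not a BrainVision header (no [Common Infos]): %s", header_path)
  dir <- dirname(header_path)
  data_path <- file.path(dir, ci[["DataFile"]])
  marker_path <- file.path(dir, ci[["MarkerFile"]])
  stop_if_not(file.exists(data_path), "missing companion data file: %s", data_path)
  stop_if_not(file.exists(marker_path), "missing companion marker file: %s", marker_path)

  fmt <- toupper(ci[["DataFormat"]] %||% "BINARY")
  stop_if_not(fmt == "BINARY", "unsupported DataFormat: %s", fmt)
  orient <- toupper(ci[["DataOrientation"]] %||% "MULTIPLEXED")
  stop_if_not(orient %in% c("MULTIPLEXED", "VECTORIZED"),
              "unsupported DataOrientation: %s", orient)
  nchan <- as.integer(ci[["NumberOfChannels"]])
  srate <- 1e6 / as.numeric(ci[["SamplingInterval"]])

  chinfo <- hdr[["Channel Infos"]]
  labels <- character(nchan); resolution <- rep(1, nchan)
  for (k in seq_len(nchan)) {
    parts <- strsplit(chinfo[[paste0("Ch", k)]], ",", fixed = TRUE)[[1]]
    labels[k] <- parts[1]
    if (length(parts) >= 3 && nzchar(parts[3])) resolution[k] <- as.numeric(parts[3])
  }

  binfmt <- toupper(hdr[["Binary Infos"]][["BinaryFormat"]] %||% "IEEE_FLOAT_32")
  sz <- file.size(data_path)
  con <- file(data_path, "rb"); on.exit(close(con))
  if (binfmt == "IEEE_FLOAT_32") {
    nval <- sz / 4
    raw_vals <- readBin(con, "double", n = nval, size = 4, endian = "little")
  } else if (binfmt == "INT_16") {
    nval <- sz / 2
    raw_vals <- readBin(con, "integer", n = nval, size = 2, signed = TRUE,
                        endian = "little")
  } else {
    stop(sprintf("unsupported BinaryFormat: %s", binfmt), call. = FALSE)
  }
  stop_if_not(length(raw_vals) %% nchan == 0,
              "binary length (%d values) is not a multiple of %d channels",
              length(raw_vals), nchan)
  nsamp <- length(raw_vals) / nchan
  data <- if (orient == "MULTIPLEXED") {
    matrix(raw_vals, nrow = nchan, ncol = nsamp)
  } else {
    t(matrix(raw_vals, nrow = nsamp, ncol = nchan))
  }
  data <- data * resolution
  rownames(data) <- labels

  mk <- parse_ini(readLines(marker_path, warn = FALSE, encoding = "UTF-8"))
  mi <- mk[["Marker Infos"]] %||% character()
  ev <- list()
  for (key in names(mi)) {
    parts <- strsplit(mi[[key]], ",", fixed = TRUE)[[1]]
    if (length(parts) < 3 || parts[1] != "Stimulus") next
    pos <- as.integer(parts[3])
    stop_if_not(pos >= 1 && pos <= nsamp,
                "marker %s position %d beyond data length %d", key, pos, nsamp)
    ev[[length(ev) + 1]] <- data.frame(
      sample_index = pos - 1L,
      condition = unname(marker_map[parts[2]]),
      code = parts[2], stringsAsFactors = FALSE)
  }
  events <- if (length(ev)) do.call(rbind, ev) else NULL
  if (!is.null(events)) events <- events[order(events$sample_index), , drop = FALSE]
  continuous_recording(data, srate, events)
}

#' Write a BrainVision recording
#'
#' Emits the `.vhdr`/`.vmrk`/`.eeg` triplet (IEEE float32, multiplexed,
#' little-endian). The marker file contains one `New Segment` marker followed
#' by one `Stimulus` marker per event; [read_brainvision()] inverts the
#' writer up to float32 quantization of the samples.
#'
#' @param rec a [continuous_recording()].
#' @param base_path output path without extension (e.g. `"out/sub-01"`).
#' @return invisibly, the three file paths written.
#' @export
write_brainvision <- function(rec, base_path) {
  stop_if_not(inherits(rec, "continuous_recording"), "`rec` must be a continuous_recording")
  stop_if_not(nrow(rec$data) >= 1, "recording has an empty channel list")
  stop_if_not(all(is.finite(rec$data)), "recording contains non-finite samples")
  base <- basename(base_path)
  paths <- paste0(base_path, c(".vhdr", ".vmrk", ".eeg"))
  labels <- rownames(rec$data)

  hdr <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "",
    "[Common Infos]",
    "Codepage=UTF-8",
    paste0("DataFile=", base, ".eeg"),
    paste0("MarkerFile=", base, ".vmrk"),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", nrow(rec$data)),
    paste0("SamplingInterval=", format(1e6 / rec$sampling_rate, scientific = FALSE)),
    "",
    "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "",
    "[Channel Infos]",
    sprintf("Ch%d=%s,,1,µV", seq_along(labels), labels)
  )
  writeLines(hdr, paths[1], useBytes = FALSE)

  mrk <- c(
    "Brain Vision Data Exchange Marker File, Version 1.0",
    "",
    "[Common Infos]",
    "Codepage=UTF-8",
    paste0("DataFile=", base, ".eeg"),
    "",
    "[Marker Infos]",
    "Mk1=New Segment,,1,1,0,00000000000000000000"
  )
  if (nrow(rec$events)) {
    mrk <- c(mrk, sprintf("Mk%d=Stimulus,%s,%d,1,0",
                          seq_len(nrow(rec$events)) + 1L,
                          rec$events$code,
                          rec$events$sample_index + 1L))
  }
  writeLines(mrk, paths[2])

  con <- file(paths[3], "wb")
  writeBin(as.vector(rec$data), con, size = 4, endian = "little")
  close(con)
  invisible(paths)
}
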