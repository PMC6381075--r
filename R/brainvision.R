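#' Write a recording as a BrainVision triplet
#'
#' Produces `<base>.vhdr`, `<base>.vmrk` and `<base>.eeg` in the BrainVision
#' Core Data Format 1.0 (binary, MULTIPLEXED orientation, little-endian).
#' `"int16"` stores samples as 16-bit integers at a 0.1 microvolt resolution;
#' `"float32"` stores IEEE single-precision microvolt values.
#'
#' @param rec a `wm_raw` recording.
#' @param base output path without extension.
#' @param format `"int16"` or `"float32"`.
#' @param resolution scaling (microvolt per bit) for the int16 dialect.
#' @return Invisibly, `base`.
#' @export
write_brainvision <- function(rec, base, format = c("int16", "float32"),
                              resolution = 0.1) {
  format <- match.arg(format)
  n_ch <- nrow(rec$signal)
  vhdr <- paste0(base, ".vhdr"); vmrk <- paste0(base, ".vmrk")
  eeg <- paste0(base, ".eeg")
  res <- if (format == "int16") resolution else 1
  hdr <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "; Written by wmosc",
    "",
    "[Common Infos]",
    "Codepage=UTF-8",
    paste0("DataFile=", basename(eeg)),
    paste0("MarkerFile=", basename(vmrk)),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", n_ch),
    paste0("SamplingInterval=", format(1e6 / rec$sfreq, scientific = FALSE)),
    "",
    "[Binary Infos]",
    paste0("BinaryFormat=", if (format == "int16") "INT_16" else "IEEE_FLOAT_32"),
    "",
    "[Channel Infos]",
    sprintf("Ch%d=%s,,%s,µV", seq_len(n_ch), rec$channel_names,
            format(res, scientific = FALSE))
  )
  writeLines(hdr, vhdr, useBytes = TRUE)

  mk <- c(
    "Brain Vision Data Exchange Marker File, Version 1.0",
    "",
    "[Common Infos]",
    "Codepage=UTF-8",
    paste0("DataFile=", basename(eeg)),
    "",
    "[Marker Infos]",
    "Mk1=New Segment,,1,1,0,00000000000000000000",
    if (nrow(rec$events) > 0)
      sprintf("Mk%d=Stimulus,%s,%d,1,0", seq_len(nrow(rec$events)) + 1L,
              rec$events$marker, rec$events$sample)
  )
  writeLines(mk, vmrk, useBytes = TRUE)

  con <- file(eeg, "wb"); on.exit(close(con))
  x <- as.vector(rec$signal)                     # multiplexed: channels fastest
  if (format == "int16") {
    v <- as.integer(round(x / res))
    if (any(abs(v) > 32767))
      stop("signal exceeds the int16 range at resolution ", res, " µV")
    writeBin(v, con, size = 2, endian = "little")
  } else {
    writeBin(x, con, size = 4, endian = "little")
  }
  invisible(base)
}

parse_bv_ini <- function(lines) {
  lines <- sub(";.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  section <- ""
  out <- list()
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      out[[section]] <- character(0)
    } else if (grepl("=", ln, fixed = TRUE)) {
      k <- sub("=.*$", "", ln); v <- sub("^[^=]*=", "", ln)
      out[[section]][k] <- v
    }
  }
  out
}

#' Read a BrainVision recording
#'
#' Supports binary MULTIPLEXED data in the INT_16 and IEEE_FLOAT_32 dialects.
#' Stimulus markers become events; the `New Segment` marker is dropped.
#' Channels named VEOG/HEOG (or of type EOG) are reported as ocular.
#'
#' @param vhdr path to the `.vhdr` header file.
#' @return A `wm_raw` object (signal in microvolt).
#' @export
read_brainvision <- function(vhdr) {
  if (!file.exists(vhdr)) stop("no such file: ", vhdr)
  ini <- parse_bv_ini(readLines(vhdr, encoding = "UTF-8", warn = FALSE))
  ci <- ini[["Common Infos"]]
  if (!identical(unname(ci["DataFormat"]), "BINARY") ||
      !identical(unname(ci["DataOrientation"]), "MULTIPLEXED"))
    stop("only binary MULTIPLEXED BrainVision data are supported")
  n_ch <- as.integer(ci["NumberOfChannels"])
  sfreq <- 1e6 / as.numeric(ci["SamplingInterval"])
  binfmt <- unname(ini[["Binary Infos"]]["BinaryFormat"])
  chs <- ini[["Channel Infos"]]
  parts <- strsplit(unname(chs), ",")
  ch_names <- vapply(parts, `[`, "", 1)
  res <- vapply(parts, function(p) {
    r <- suppressWarnings(as.numeric(p[3])); if (is.na(r)) 1 else r
  }, numeric(1))

  eeg <- file.path(dirname(vhdr), unname(ci["DataFile"]))
  sz <- file.info(eeg)$size
  con <- file(eeg, "rb"); on.exit(close(con))
  if (identical(binfmt, "INT_16")) {
    n <- sz / 2
    x <- readBin(con, "integer", n = n, size = 2, endian = "little")
    sig <- matrix(as.numeric(x), nrow = n_ch) * res
  } else if (identical(binfmt, "IEEE_FLOAT_32")) {
    n <- sz / 4
    x <- readBin(con, "numeric", n = n, size = 4, endian = "little")
    sig <- matrix(x, nrow = n_ch) * res
  } else stop("unsupported BinaryFormat: ", binfmt)
  rownames(sig) <- ch_names

  vmrk <- file.path(dirname(vhdr), unname(ci["MarkerFile"]))
  events <- data.frame(sample = integer(0), marker = character(0),
                       trial_id = integer(0))
  if (file.exists(vmrk)) {
    mi <- parse_bv_ini(readLines(vmrk, encoding = "UTF-8", warn = FALSE))[["Marker Infos"]]
    if (!is.null(mi)) {
      p <- strsplit(unname(mi), ",")
      type <- vapply(p, `[`, "", 1)
      desc <- vapply(p, `[`, "", 2)
      pos <- as.integer(vapply(p, `[`, "", 3))
      keep <- type == "Stimulus"
      events <- data.frame(sample = pos[keep], marker = desc[keep],
                           trial_id = seq_len(sum(keep)),
                           stringsAsFactors = FALSE)
    }
  }

  rec <- list(signal = sig, channel_names = ch_names, sfreq = sfreq,
              events = events,
              eog_channels = intersect(c("VEOG", "HEOG"), ch_names),
              subject = NA_integer_, icf = NA_real_)
  class(rec) <- "wm_raw"
  rec
}

#' Read a behaviour CSV
#'
#' Expects at least the columns `trial_id`, `probe_type`, `response`, `rt_s`,
#' `condition`; serial-recognition columns `sp1`..`sp4` are kept if present.
#' The condition column is validated against [derive_condition()].
#'
#' @param path CSV file path.
#' @return A `wm_behavior` data.frame.
#' @export
read_behavior <- function(path) {
  beh <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("trial_id", "probe_type", "response", "rt_s", "condition")
  if (!all(need %in% names(beh)))
    stop("behavior file must contain columns: ", paste(need, collapse = ", "))
  chk <- derive_condition(beh$probe_type, beh$response)
  if (!identical(chk, beh$condition))
    stop("condition column inconsistent with (probe_type, response) mapping")
  class(beh) <- c("wm_behavior", class(beh))
  beh
}
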