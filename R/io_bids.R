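# BIDS-EEG dataset reading and writing:
# sub-<label>/eeg/sub-<label>[_task-<task>]_eeg.{vhdr,vmrk,eeg|edf} plus the
# *_eeg.json, *_channels.tsv and *_electrodes.tsv/_coordsystem.json sidecars.

read_tsv_plain <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                    na.strings = c("n/a", "NA", ""))
}

write_tsv_plain <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "n/a")
}

#' Read one subject's recording from a BIDS-EEG dataset
#'
#' Loads the BrainVision or EDF data file, the required `*_eeg.json`
#' (power-line frequency, reference name) and `*_channels.tsv` sidecars, and
#' the optional `*_electrodes.tsv` with its `*_coordsystem.json`. Electrode
#' coordinates are converted to head RAS in meters; the CTF/ALS convention
#' is rigidly rotated, any other declared system is an error. By default an
#' EEG channel is retained only if it has a standard 10-5 position (from
#' the built-in montage) or a position in `electrodes.tsv`; positionless
#' EEG channels are dropped. Non-EEG channels (EOG, ECG, ...) are kept
#' without positions.
#'
#' @param dataset_root root of the BIDS dataset
#' @param subject_label label without the `sub-` prefix
#' @param task optional task label to disambiguate multiple recordings
#' @return an `eeg_recording` with `line_freq` and `reference` populated
#' @export
read_raw_bids <- function(dataset_root, subject_label, task = NULL) {
  eeg_dir <- file.path(dataset_root, paste0("sub-", subject_label), "eeg")
  if (!dir.exists(eeg_dir)) stop("no eeg/ directory for subject: ", eeg_dir)
  patt <- if (is.null(task)) "_eeg\\.(vhdr|edf)$"
          else sprintf("_task-%s.*_eeg\\.(vhdr|edf)$", task)
  cand <- list.files(eeg_dir, pattern = patt, full.names = TRUE)
  if (!length(cand)) stop("no BrainVision/EDF data file found under ", eeg_dir,
                          " (only BrainVision and EDF are supported)")
  datafile <- cand[1]
  stem <- sub("\\.(vhdr|edf)$", "", datafile)
  sidecar <- paste0(stem, ".json")
  chan_tsv <- paste0(stem, ".json")
  chan_tsv <- sub("_eeg\\.json$", "_channels.tsv", sidecar)
  if (!file.exists(sidecar)) stop("missing required sidecar file: ", sidecar)
  if (!file.exists(chan_tsv)) stop("missing required sidecar file: ", chan_tsv)

  rec <- if (grepl("\\.vhdr$", datafile)) read_brainvision(datafile) else read_edf(datafile)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (!is.null(meta$PowerLineFrequency)) rec$line_freq <- as.numeric(meta$PowerLineFrequency)
  if (!is.null(meta$EEGReference)) rec$reference <- as.character(meta$EEGReference)

  chans <- read_tsv_plain(chan_tsv)
  if (nrow(chans) != n_channels(rec))
    stop("channel count mismatch: data has ", n_channels(rec),
         " channels but ", basename(chan_tsv), " lists ", nrow(chans))
  rec$channels$type <- toupper(chans$type[match(rec$channels$name, chans$name)])
  rec$channels$type[is.na(rec$channels$type)] <- "EEG"
  if (!is.null(chans$status)) {
    st <- chans$status[match(rec$channels$name, chans$name)]
    rec$channels$status <- ifelse(is.na(st), "good", st)
  }

  # electrode positions: explicit electrodes.tsv wins, else standard montage
  el_tsv <- sub("_eeg\\.json$", "_electrodes.tsv", sidecar)
  el_tsv2 <- file.path(eeg_dir, sprintf("sub-%s_electrodes.tsv", subject_label))
  if (!file.exists(el_tsv) && file.exists(el_tsv2)) el_tsv <- el_tsv2
  if (file.exists(el_tsv)) {
    el <- read_tsv_plain(el_tsv)
    cs_json <- sub("_electrodes\\.tsv$", "_coordsystem.json", el_tsv)
    pos <- as.matrix(el[, c("x", "y", "z")])
    if (file.exists(cs_json)) {
      cs <- jsonlite::read_json(cs_json, simplifyVector = TRUE)
      units <- tolower(cs$EEGCoordinateUnits %||% "m")
      mult <- switch(units, m = 1, cm = 1e-2, mm = 1e-3,
                     stop("unsupported coordinate units: ", units))
      pos <- pos * mult
      sys <- toupper(cs$EEGCoordinateSystem %||% "RAS")
      if (sys %in% c("CTF", "ALS")) {
        # ALS (x anterior, y left) -> RAS (x right, y anterior)
        pos <- cbind(-pos[, 2], pos[, 1], pos[, 3])
      } else if (!sys %in% c("RAS", "CAPTRAK", "HEADRAS", "OTHER")) {
        stop("unsupported electrode coordinate system: ", sys)
      }
    }
    m <- match(rec$channels$name, el$name)
    rec$channels$x <- pos[m, 1]; rec$channels$y <- pos[m, 2]; rec$channels$z <- pos[m, 3]
  } else {
    std <- standard_montage()
    m <- match(rec$channels$name, std$name)
    rec$channels$x <- std$x[m]; rec$channels$y <- std$y[m]; rec$channels$z <- std$z[m]
  }
  drop_names <- rec$channels$name[rec$channels$type == "EEG" & is.na(rec$channels$x)]
  if (length(drop_names)) rec <- remove_channels(rec, drop_names)
  rec
}

#' Write a recording as a BIDS-EEG subject (BrainVision + sidecars)
#'
#' @param rec an `eeg_recording`
#' @param dataset_root dataset root (created if needed)
#' @param subject_label label without the `sub-` prefix
#' @param task task label (default "rest")
#' @return invisibly, the subject's eeg directory
#' @export
write_bids_recording <- function(rec, dataset_root, subject_label, task = "rest") {
  eeg_dir <- file.path(dataset_root, paste0("sub-", subject_label), "eeg")
  dir.create(eeg_dir, recursive = TRUE, showWarnings = FALSE)
  dd <- file.path(dataset_root, "dataset_description.json")
  if (!file.exists(dd))
    jsonlite::write_json(list(Name = "resteeg synthetic dataset",
                              BIDSVersion = "1.8.0"),
                         dd, auto_unbox = TRUE, pretty = TRUE)
  stem <- file.path(eeg_dir, sprintf("sub-%s_task-%s_eeg", subject_label, task))
  write_brainvision(rec, stem)
  jsonlite::write_json(list(
    SamplingFrequency = rec$srate,
    PowerLineFrequency = if (is.na(rec$line_freq)) 50 else rec$line_freq,
    EEGReference = rec$reference,
    TaskName = task,
    EEGChannelCount = sum(rec$channels$type == "EEG"),
    RecordingDuration = duration_s(rec)
  ), paste0(stem, ".json"), auto_unbox = TRUE, pretty = TRUE, digits = NA)
  write_tsv_plain(data.frame(name = rec$channels$name,
                             type = rec$channels$type,
                             units = "uV",
                             status = rec$channels$status),
                  sub("_eeg$", "_channels.tsv", stem))
  haspos <- !is.na(rec$channels$x)
  if (any(haspos)) {
    el_stem <- file.path(eeg_dir, sprintf("sub-%s_electrodes.tsv", subject_label))
    write_tsv_plain(data.frame(name = rec$channels$name[haspos],
                               x = rec$channels$x[haspos],
                               y = rec$channels$y[haspos],
                               z = rec$channels$z[haspos]),
                    el_stem)
    jsonlite::write_json(list(EEGCoordinateSystem = "RAS",
                              EEGCoordinateUnits = "m"),
                         sub("_electrodes\\.tsv$", "_coordsystem.json", el_stem),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(eeg_dir)
}

#' Subjects present in a BIDS dataset
#' @param dataset_root dataset root directory
#' @return character vector of subject labels (without the `sub-` prefix)
#' @export
bids_subjects <- function(dataset_root) {
  subs <- list.dirs(dataset_root, recursive = FALSE, full.names = FALSE)
  sub("^sub-", "", subs[grepl("^sub-", subs)])
}
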