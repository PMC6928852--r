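#' Construct an annotated ECG record
#'
#' Bundles a sampled single-lead waveform with its beat annotations
#' (R-peak sample positions plus one annotation symbol per beat). Annotation
#' indices are 0-based, matching the convention of WFDB-style sources;
#' 1-based sources must be shifted at read time.
#'
#' @param record_id Record identifier (e.g. `"100"` or a synthetic id).
#' @param samples Numeric vector, the waveform in millivolts.
#' @param fs Sampling rate in Hz (MIT-BIH records use 360).
#' @param ann_indices Integer vector of 0-based R-peak sample positions,
#'   strictly increasing.
#' @param ann_symbols Character vector of annotation symbols, same length as
#'   `ann_indices`.
#' @return An object of class `ecg_record`.
#' @export
ecg_record <- function(record_id, samples, fs = 360,
                       ann_indices = integer(), ann_symbols = character()) {
  samples <- as.numeric(samples)
  ann_indices <- as.integer(ann_indices)
  ann_symbols <- as.character(ann_symbols)
  if (length(ann_indices) != length(ann_symbols))
    stop("ann_indices and ann_symbols must have the same length")
  if (length(ann_indices) > 1 && any(diff(ann_indices) <= 0))
    stop("ann_indices must be strictly increasing")
  if (length(ann_indices) &&
      (min(ann_indices) < 0 || max(ann_indices) >= length(samples)))
    stop("annotation indices must lie within the record")
  structure(
    list(record_id = as.character(record_id), samples = samples, fs = fs,
         ann_indices = ann_indices, ann_symbols = ann_symbols),
    class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record %s: %d samples @ %g Hz, %d annotations>\n",
              x$record_id, length(x$samples), x$fs, length(x$ann_indices)))
  invisible(x)
}

#' Denoising filter chain settings
#'
#' @param ma_order Moving-average length in samples (uniform, centered).
#' @param hp_cutoff High-pass cut-off in Hz (baseline wander suppression).
#' @param lp_cutoff Low-pass Butterworth cut-off in Hz.
#' @param filter_order Butterworth order for both IIR stages.
#' @return A `filter_config` list.
#' @export
filter_config <- function(ma_order = 5, hp_cutoff = 1, lp_cutoff = 45,
                          filter_order = 4) {
  stopifnot(ma_order >= 1, hp_cutoff > 0, lp_cutoff > hp_cutoff,
            filter_order >= 1)
  structure(list(ma_order = as.integer(ma_order), hp_cutoff = hp_cutoff,
                 lp_cutoff = lp_cutoff, filter_order = as.integer(filter_order)),
            class = "filter_config")
}

# Centered uniform moving average with edge replication so the output keeps
# the input length and the R-peak alignment.
moving_average <- function(x, order) {
  if (order <= 1) return(x)
  half <- (order - 1) %/% 2
  padded <- c(rep(x[1], half), x, rep(x[length(x)], order - 1 - half))
  as.numeric(stats::filter(padded, rep(1 / order, order), sides = 1))[order:(length(x) + order - 1)]
}

#' Denoise an ECG record
#'
#' Applies the standard artifact-suppression chain: remove the sample mean,
#' smooth with a 5-point moving average, suppress baseline wander with a 1 Hz
#' high-pass, and remove residual high-frequency noise with a 45 Hz
#' Butterworth low-pass. Both IIR stages run forward-backward (zero phase) so
#' annotation indices stay valid on the filtered signal.
#'
#' @param record An [ecg_record()].
#' @param config A [filter_config()].
#' @return A new `ecg_record` with filtered samples and unchanged annotations.
#' @export
denoise <- function(record, config = filter_config()) {
  stopifnot(inherits(record, "ecg_record"))
  if (length(record$samples) == 0) stop("empty input: record has no samples")
  if (record$fs <= 2 * config$lp_cutoff)
    stop("invalid sampling rate: fs must exceed twice the low-pass cut-off")
  x <- record$samples - mean(record$samples)
  x <- moving_average(x, config$ma_order)
  nyq <- record$fs / 2
  hp <- signal::butter(config$filter_order, config$hp_cutoff / nyq, type = "high")
  lp <- signal::butter(config$filter_order, config$lp_cutoff / nyq, type = "low")
  x <- signal::filtfilt(hp, x)
  x <- signal::filtfilt(lp, x)
  out <- record
  out$samples <- x
  out
}

#' Map an annotation symbol to its AAMI super-class
#'
#' Beat symbols collapse onto the five AAMI groups: N gets normal plus left
#' and right bundle branch block and atrial/nodal escape beats
#' (`N,L,R,e,j`); S the supraventricular ectopics (`A,a,J,S`); V the
#' ventricular ectopics including flutter and escape (`V,E,!`); F the
#' ventricular/normal fusions (`F`); Q paced, fusion-of-paced and
#' unclassifiable beats (`/,f,Q`). Non-beat annotations (rhythm changes,
#' artifacts, comments) return `NA` and the beat is skipped.
#'
#' @param symbol Character vector of annotation symbols.
#' @return Character vector of the same length with values in
#'   `c("N","S","V","F","Q")` or `NA` for non-beat/unknown symbols.
#' @export
map_aami_label <- function(symbol) {
  mapping <- c(
    "N" = "N", "L" = "N", "R" = "N", "e" = "N", "j" = "N",
    "A" = "S", "a" = "S", "J" = "S", "S" = "S",
    "V" = "V", "E" = "V", "!" = "V",
    "F" = "F",
    "/" = "Q", "f" = "Q", "Q" = "Q")
  non_beat <- c("+", "~", "|", "x", "[", "]", "\"", "=", "s", "T", "*", "@")
  out <- unname(mapping[symbol])
  unknown <- is.na(out) & !(symbol %in% non_beat)
  if (any(unknown))
    warning("unknown beat symbol(s) skipped: ",
            paste(unique(symbol[unknown]), collapse = " "))
  out
}

#' Segment a record into fixed-length beat windows
#'
#' Cuts one `pre_samples + post_samples` window per annotated beat, placed
#' `[r - pre_samples, r + post_samples)` around the R index so the window
#' keeps the P wave before the QRS complex and the full T wave after it.
#' Beats whose symbol has no AAMI class and beats whose window leaves the
#' record are dropped.
#'
#' @param record A (typically denoised) [ecg_record()].
#' @param pre_samples Samples kept before the R peak (default 100).
#' @param post_samples Samples kept from the R peak on (default 200). The sum
#'   must be 300.
#' @return A list of `beat_segment` objects, each with fields `record_id`,
#'   `r_index`, `samples` (length 300) and `aami_class`.
#' @export
segment_beats <- function(record, pre_samples = 100, post_samples = 200) {
  stopifnot(inherits(record, "ecg_record"))
  if (pre_samples + post_samples != 300)
    stop("configuration error: pre_samples + post_samples must equal 300")
  n <- length(record$samples)
  labels <- suppressWarnings(map_aami_label(record$ann_symbols))
  out <- vector("list", length(record$ann_indices))
  kept <- 0L
  for (i in seq_along(record$ann_indices)) {
    if (is.na(labels[i])) next
    r <- record$ann_indices[i]           # 0-based
    lo <- r - pre_samples                # first sample (0-based, inclusive)
    hi <- r + post_samples               # one past last (0-based)
    if (lo < 0 || hi > n) next
    kept <- kept + 1L
    out[[kept]] <- structure(
      list(record_id = record$record_id, r_index = r,
           samples = record$samples[(lo + 1):hi], aami_class = labels[i]),
      class = "beat_segment")
  }
  out[seq_len(kept)]
}

#' Inter-patient DS1/DS2 record split
#'
#' The canonical inter-patient partition of the 44 usable MIT-BIH arrhythmia
#' records: DS1 (22 records) trains the model, DS2 (22 disjoint records)
#' evaluates it, and the four paced-rhythm records 102, 104, 107 and 217 are
#' excluded from both.
#'
#' @param records Optional character vector of available record ids; the
#'   returned lists are intersected with it. Defaults to all 44.
#' @return A list with `ds1_records`, `ds2_records` and `excluded_records`.
#' @export
split_ds1_ds2 <- function(records = NULL) {
  ds1 <- c("101", "106", "108", "109", "112", "114", "115", "116", "118",
           "119", "122", "124", "201", "203", "205", "207", "208", "209",
           "215", "220", "223", "230")
  ds2 <- c("100", "103", "105", "111", "113", "117", "121", "123", "200",
           "202", "210", "212", "213", "214", "219", "221", "222", "228",
           "231", "232", "233", "234")
  excluded <- c("102", "104", "107", "217")
  if (!is.null(records)) {
    records <- as.character(records)
    ds1 <- intersect(ds1, records)
    ds2 <- intersect(ds2, records)
    excluded <- union(excluded, setdiff(records, c(ds1, ds2)))
  }
  list(ds1_records = ds1, ds2_records = ds2, excluded_records = excluded)
}

#' Read / write plain-text ECG records
#'
#' The on-disk fallback format is a CSV of `(sample_index, value)` rows for
#' the waveform and a JSON array of `{index, symbol}` objects for the
#' annotations, both 0-based.
#'
#' @param signal_csv Path to the waveform CSV.
#' @param annotation_json Path to the annotation JSON.
#' @param record_id Record identifier; defaults to the CSV file stem.
#' @param fs Sampling rate in Hz.
#' @return An [ecg_record()].
#' @export
read_ecg_csv <- function(signal_csv, annotation_json = NULL,
                         record_id = NULL, fs = 360) {
  sig <- utils::read.csv(signal_csv)
  if (!all(c("sample_index", "value") %in% names(sig)))
    stop("signal CSV needs columns sample_index,value")
  sig <- sig[order(sig$sample_index), ]
  idx <- integer(); sym <- character()
  if (!is.null(annotation_json)) {
    ann <- jsonlite::fromJSON(annotation_json)
    if (length(ann)) {
      idx <- as.integer(ann$index)
      sym <- as.character(ann$symbol)
    }
  }
  if (is.null(record_id))
    record_id <- sub("\\.csv$", "", basename(signal_csv))
  ecg_record(record_id, sig$value, fs = fs,
             ann_indices = idx, ann_symbols = sym)
}

#' @rdname read_ecg_csv
#' @param record An [ecg_record()] to write.
#' @param dir Output directory; files are named `<record_id>.csv` and
#'   `<record_id>_ann.json`.
#' @return (write) Invisibly, the two file paths.
#' @export
write_ecg_csv <- function(record, dir) {
  stopifnot(inherits(record, "ecg_record"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sig_path <- file.path(dir, paste0(record$record_id, ".csv"))
  ann_path <- file.path(dir, paste0(record$record_id, "_ann.json"))
  utils::write.csv(
    data.frame(sample_index = seq_along(record$samples) - 1L,
               value = record$samples),
    sig_path, row.names = FALSE)
  jsonlite::write_json(
    data.frame(index = record$ann_indices, symbol = record$ann_symbols),
    ann_path, dataframe = "rows")
  invisible(c(signal = sig_path, annotations = ann_path))
}
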