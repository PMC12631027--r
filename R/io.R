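#' Write a wave table to CSV with a JSON manifest
#'
#' Serializes a wave tibble as a long CSV (`wave_id`, `sample_index`,
#' `voltage`; 0-based sample indices, >= 15 significant digits) plus a JSON
#' manifest carrying sampling metadata and the per-wave labels. All waves of
#' one table must share a sample count.
#'
#' @param waves Wave tibble (see [simulate_session()]).
#' @param path CSV output path.
#' @param manifest_path JSON manifest output path.
#' @return Invisibly, a list of the two paths.
#' @export
write_wave_table <- function(waves, path, manifest_path) {
  meta_cols <- c("wave_id", "antenna_id", "odor", "dilution",
                 "acquisition_index", "delivery_id", "is_calibration",
                 "artifact")
  missing <- setdiff(c("wave_id", "samples"), names(waves))
  if (length(missing)) {
    stop("wave table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(waves$wave_id)) {
    stop("duplicate wave_id in table: ",
         waves$wave_id[duplicated(waves$wave_id)][1], call. = FALSE)
  }
  lens <- lengths(waves$samples)
  if (length(unique(lens)) > 1) {
    stop("write refused: inconsistent sample counts across waves (",
         paste(unique(lens), collapse = ", "), ")", call. = FALSE)
  }
  info <- wave_table_info(waves)

  if (nrow(waves) == 0) {
    long <- tibble::tibble(wave_id = character(), sample_index = integer(),
                           voltage = double())
  } else {
    long <- tidyr::unnest(
      dplyr::mutate(
        dplyr::select(waves, "wave_id", "samples"),
        samples = purrr::map(.data$samples, ~ tibble::tibble(
          sample_index = seq_along(.x) - 1L, voltage = .x))),
      "samples")
  }
  # %.17g guarantees bit-exact round trip of doubles through decimal text
  long$voltage <- sprintf("%.17g", long$voltage)
  readr::write_csv(long, path)

  present <- intersect(meta_cols, names(waves))
  manifest <- list(
    format = "long",
    n_waves = nrow(waves),
    n_samples = if (nrow(waves)) unname(lens[[1]]) else 0L,
    sample_rate_hz = info$sample_rate_hz,
    pre_s = info$pre_s,
    post_s = info$post_s,
    waves = as.data.frame(waves[present])
  )
  cfg <- attr(waves, "config")
  if (!is.null(cfg)) manifest$seed <- cfg$seed
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(list(path = path, manifest_path = manifest_path))
}

#' Read a wave table written by [write_wave_table()]
#'
#' Round-trips bit-exactly on voltages and metadata. Validation errors
#' (missing waves, sample-count mismatches against the manifest, duplicate
#' ids) identify the offending wave.
#'
#' @param path CSV wave table path.
#' @param manifest_path JSON manifest path.
#' @return A wave tibble.
#' @export
read_wave_table <- function(path, manifest_path) {
  manifest <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  long <- readr::read_csv(path, col_types = readr::cols(
    wave_id = readr::col_character(),
    sample_index = readr::col_integer(),
    voltage = readr::col_character()))
  # parse via strtod for correctly rounded (bit-exact) doubles
  long$voltage <- as.numeric(long$voltage)

  meta <- tibble::as_tibble(manifest$waves)
  if (manifest$n_waves == 0) {
    out <- tibble::tibble(wave_id = character(), samples = list())
  } else {
    if (anyDuplicated(meta$wave_id)) {
      stop("manifest lists duplicate wave_id: ",
           meta$wave_id[duplicated(meta$wave_id)][1], call. = FALSE)
    }
    extra <- setdiff(unique(long$wave_id), meta$wave_id)
    if (length(extra)) {
      stop("wave table contains wave_id absent from manifest: ", extra[1],
           call. = FALSE)
    }
    split_v <- split(long$voltage, factor(long$wave_id, levels = meta$wave_id))
    lens <- vapply(split_v, length, integer(1))
    bad <- which(lens != manifest$n_samples)
    if (length(bad)) {
      stop("wave '", names(lens)[bad[1]], "' has ", lens[bad[1]],
           " samples; manifest declares ", manifest$n_samples, call. = FALSE)
    }
    out <- meta
    out$samples <- unname(split_v)
  }
  attr(out, "sample_rate_hz") <- manifest$sample_rate_hz
  attr(out, "pre_s") <- manifest$pre_s
  attr(out, "post_s") <- manifest$post_s
  out
}

#' Extract stimulus-aligned windows from a continuous recording
#'
#' Cuts the half-open window `[onset - pre_s, onset + post_s)` around each
#' stimulus onset out of a continuous voltage trace; the onset sample is the
#' first sample of the post-stimulus segment. Times are seconds, indices
#' 0-based.
#'
#' @param trace Numeric vector: the continuous voltage recording.
#' @param sample_rate_hz Sampling rate of `trace`, Hz.
#' @param onsets_s Numeric vector of stimulus onset times (s from trace
#'   start), strictly increasing.
#' @param pre_s,post_s Window extent before/after onset, seconds.
#' @param metadata Optional tibble with one row per onset (labels such as
#'   `antenna_id`, `odor`, `dilution`); carried onto the output.
#' @return A wave tibble with `wave_id`, `acquisition_index`, any metadata
#'   columns, and a `samples` list-column of length
#'   `round(sample_rate_hz * (pre_s + post_s))` per wave.
#' @export
#' @examples
#' tr <- sin(2 * pi * 1 * seq(0, 20, by = 1e-3))
#' w <- extract_windows(tr, 1000, onsets_s = c(5, 12), pre_s = 0.25, post_s = 4.75)
#' lengths(w$samples) # 5000 5000
extract_windows <- function(trace, sample_rate_hz, onsets_s,
                            pre_s = 0.25, post_s = 4.75, metadata = NULL) {
  if (is.unsorted(onsets_s, strictly = TRUE)) {
    stop("`onsets_s` must be strictly increasing", call. = FALSE)
  }
  if (!is.null(metadata) && nrow(metadata) != length(onsets_s)) {
    stop("`metadata` must have one row per onset", call. = FALSE)
  }
  n_win <- as.integer(round(sample_rate_hz * (pre_s + post_s)))
  windows <- vector("list", length(onsets_s))
  for (i in seq_along(onsets_s)) {
    start0 <- as.integer(round((onsets_s[i] - pre_s) * sample_rate_hz))
    if (start0 < 0 || start0 + n_win > length(trace)) {
      stop(sprintf(
        "window for onset %g s exceeds trace bounds [0, %g s)",
        onsets_s[i], length(trace) / sample_rate_hz), call. = FALSE)
    }
    windows[[i]] <- trace[(start0 + 1):(start0 + n_win)]
  }
  out <- tibble::tibble(
    wave_id = sprintf("w%04d", seq_along(onsets_s) - 1L),
    acquisition_index = seq_along(onsets_s) - 1L,
    samples = windows)
  if (!is.null(metadata)) out <- dplyr::bind_cols(metadata, out)
  attr(out, "sample_rate_hz") <- sample_rate_hz
  attr(out, "pre_s") <- pre_s
  attr(out, "post_s") <- post_s
  out
}
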