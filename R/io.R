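#' Read and write recordings
#'
#' A recording is stored as a directory holding `meta.json` (sampling rate,
#' channel ids, geometry, pitch) and `voltage.bin` (channel-major 64-bit
#' little-endian floats), so the voltage round-trips bit-identically.
#' Optionally a `truth_spikes.tsv` (columns `channel_id`, `t_s`) sits next to
#' them for simulated recordings.
#'
#' @param rec a [raw_recording()].
#' @param path directory to write to / read from.
#' @return `write_recording` returns `path` invisibly; `read_recording`
#'   returns a `raw_recording`.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "raw_recording"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(sampling_rate_hz = rec$sampling_rate,
               channel_pitch_um = rec$pitch_um,
               channel_ids = rec$channel_ids,
               n_channels = nrow(rec$voltage),
               n_samples = ncol(rec$voltage),
               geometry = rec$geometry)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  con <- file(file.path(path, "voltage.bin"), "wb")
  on.exit(close(con))
  writeBin(as.vector(t(rec$voltage)), con, size = 8, endian = "little")
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  meta_path <- file.path(path, "meta.json")
  if (!file.exists(meta_path)) stop("missing meta.json in ", path, call. = FALSE)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  for (field in c("sampling_rate_hz", "n_channels", "n_samples")) {
    if (is.null(meta[[field]])) {
      stop(sprintf("recording metadata lacks '%s'", field), call. = FALSE)
    }
  }
  if (meta$n_channels < 1) stop("recording has 0 channels", call. = FALSE)
  con <- file(file.path(path, "voltage.bin"), "rb")
  on.exit(close(con))
  v <- readBin(con, "double", n = meta$n_channels * meta$n_samples,
               size = 8, endian = "little")
  raw_recording(matrix(v, nrow = meta$n_channels, byrow = TRUE),
                sampling_rate = as.numeric(meta$sampling_rate_hz),
                channel_ids = meta$channel_ids,
                pitch_um = meta$channel_pitch_um %||% 200)
}

# Canonical TSV writer: tab-separated, UTF-8, Unix newlines, no quoting of
# numerics, deterministic row order as given.
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}

read_tsv_checked <- function(path, required, label) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("%s table '%s' lacks column(s): %s", label, path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  extra <- setdiff(names(df), required)
  if (length(extra)) {
    warning(sprintf("%s table has extra column(s) (preserved): %s", label,
                    paste(extra, collapse = ", ")))
  }
  df
}

#' Read and write cone-survival tables
#'
#' TSV with columns `animal_id`, `arm`, `eye`, `age_pn`, `position_deg`,
#' `cones_per_100um`. Negative densities are a validation error; unknown
#' extra columns are preserved with a warning.
#'
#' @param records a `cone_counts` data frame.
#' @param path file path.
#' @export
write_survival_table <- function(records, path) {
  write_tsv(records, path)
}

#' @rdname write_survival_table
#' @export
read_survival_table <- function(path) {
  df <- read_tsv_checked(path, c("animal_id", "arm", "eye", "age_pn",
                                 "position_deg", "cones_per_100um"),
                         "survival")
  if (any(df$cones_per_100um < 0)) {
    stop("negative cone density in ", path, call. = FALSE)
  }
  structure(df, class = c("cone_counts", "data.frame"))
}

#' Read and write spike-time tables
#'
#' Long TSV with columns `channel_id`, `t_s`.
#'
#' @param spikes a `spike_train`.
#' @param path file path.
#' @export
write_spike_table <- function(spikes, path) {
  df <- data.frame(
    channel_id = rep(names(spikes), vapply(spikes, length, integer(1))),
    t_s = unlist(spikes, use.names = FALSE)
  )
  write_tsv(df, path)
}

#' @rdname write_spike_table
#' @export
read_spike_table <- function(path) {
  read_tsv_checked(path, c("channel_id", "t_s"), "spike")
}

#' Read and write trial-count tables
#'
#' TSV of per-(channel, intensity, repetition) window counts. The window
#' length travels in a `#window_len_s` comment line so the table alone
#' reconstructs firing rates.
#'
#' @param counts a `trial_counts` table.
#' @param path file path.
#' @export
write_trial_counts <- function(counts, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("#window_len_s\t%.17g", attr(counts, "window_len")), con)
  utils::write.table(as.data.frame(counts), con, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  invisible(path)
}

#' @rdname write_trial_counts
#' @export
read_trial_counts <- function(path) {
  first <- readLines(path, n = 1L)
  window <- if (startsWith(first, "#window_len_s")) {
    as.numeric(strsplit(first, "\t")[[1]][2])
  } else {
    stop("trial-count table lacks the #window_len_s header line", call. = FALSE)
  }
  df <- utils::read.delim(path, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("channel", "intensity", "rep_index", "count_on", "count_off",
            "count_spont")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("trial-count table lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  structure(df, window_len = window, class = c("trial_counts", "data.frame"))
}

#' Read and write counts matrices
#'
#' Genes x samples TSV; first column `gene_id`, remaining columns one per
#' sample. Duplicate gene or sample ids are an error.
#'
#' @param counts genes x samples matrix with dimnames.
#' @param path file path.
#' @export
write_counts_table <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
  write_tsv(df, path)
}

#' @rdname write_counts_table
#' @export
read_counts_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!"gene_id" %in% names(df)) {
    stop("counts table lacks 'gene_id' column", call. = FALSE)
  }
  if (anyDuplicated(df$gene_id)) stop("duplicate gene ids", call. = FALSE)
  if (anyDuplicated(setdiff(names(df), "gene_id"))) {
    stop("duplicate sample ids", call. = FALSE)
  }
  m <- as.matrix(df[setdiff(names(df), "gene_id")])
  rownames(m) <- df$gene_id
  m
}

#' Read and write stimulus protocols
#'
#' JSON array of epochs `{onset_s, duration_s, intensity_photons_cm2_s,
#' rep_index}`.
#'
#' @param protocol a `stim_protocol`.
#' @param path file path.
#' @export
write_protocol <- function(protocol, path) {
  epochs <- data.frame(onset_s = protocol$onset_s,
                       duration_s = protocol$duration_s,
                       intensity_photons_cm2_s = protocol$intensity,
                       rep_index = protocol$rep_index)
  jsonlite::write_json(list(flash_dur = attr(protocol, "flash_dur"),
                            dark_gap = attr(protocol, "dark_gap"),
                            intensities = attr(protocol, "intensities"),
                            epochs = epochs),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_protocol
#' @export
read_protocol <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  reps <- max(obj$epochs$rep_index)
  make_protocol(intensities = obj$intensities, reps = reps,
                flash_dur = obj$flash_dur, dark_gap = obj$dark_gap)
}
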