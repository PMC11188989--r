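EPOCH_MAGIC <- "MEGEPOCHSET\n"
EPOCH_SCHEMA_VERSION <- 1L

#' Write an epoch container to disk
#'
#' Serializes an [epoch_set()] to a single self-describing binary file:
#' a fixed magic string, a schema version, a JSON metadata header
#' (sampling rate, time origin, channel labels, trial table, array
#' dimensions) and the raw signal array as IEEE-754 little-endian
#' doubles.  The round trip through [read_epochs()] is bit-exact for the
#' data and field-for-field for the metadata.
#'
#' @param es an `epoch_set`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [read_epochs()]
#' @export
write_epochs <- function(es, path) {
  validate_epoch_set(es)
  hdr <- list(
    schema_version = EPOCH_SCHEMA_VERSION,
    fs = es$fs, t0 = es$t0,
    dims = dim(es$data),
    channel_ids = es$channel_ids,
    trials = lapply(es$trials, function(col) {
      if (is.factor(col)) as.character(col) else col
    })
  )
  raw_hdr <- charToRaw(jsonlite::toJSON(hdr, auto_unbox = TRUE, digits = NA))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(EPOCH_MAGIC), con)
  writeBin(EPOCH_SCHEMA_VERSION, con, size = 4L, endian = "little")
  writeBin(length(raw_hdr), con, size = 4L, endian = "little")
  writeBin(raw_hdr, con)
  writeBin(as.vector(es$data), con, size = 8L, endian = "little")
  invisible(path)
}

#' Read an epoch container from disk
#'
#' Reads a file produced by [write_epochs()].  Channel order is
#' preserved.  Unknown extra header attributes are ignored with a
#' warning; a schema version mismatch or a truncated file raises an
#' explicit error.
#'
#' @param path file path.
#' @return An `epoch_set`.
#' @export
read_epochs <- function(path) {
  if (!file.exists(path)) stop("no such epoch container: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  nmagic <- nchar(EPOCH_MAGIC)
  magic <- readBin(con, "raw", n = nmagic)
  if (length(magic) < nmagic ||
      !identical(rawToChar(magic), EPOCH_MAGIC)) {
    stop("corrupt epoch container (bad magic): ", path)
  }
  ver <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  if (length(ver) != 1L || is.na(ver))
    stop("corrupt epoch container (truncated header): ", path)
  if (ver != EPOCH_SCHEMA_VERSION) {
    stop(sprintf(
      "epoch container schema version mismatch: file has %s, reader supports %d",
      ver, EPOCH_SCHEMA_VERSION))
  }
  nhdr <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  raw_hdr <- readBin(con, "raw", n = nhdr)
  if (length(raw_hdr) < nhdr)
    stop("corrupt epoch container (truncated header): ", path)
  hdr <- jsonlite::fromJSON(rawToChar(raw_hdr), simplifyVector = TRUE)
  known <- c("schema_version", "fs", "t0", "dims", "channel_ids", "trials")
  extra <- setdiff(names(hdr), known)
  if (length(extra)) {
    warning("ignoring unknown epoch container attributes: ",
            paste(extra, collapse = ", "))
  }
  dims <- as.integer(hdr$dims)
  nvals <- prod(dims)
  vals <- readBin(con, "double", n = nvals, size = 8L, endian = "little")
  if (length(vals) < nvals)
    stop("corrupt epoch container (truncated data): ", path)
  trials <- as.data.frame(hdr$trials, stringsAsFactors = FALSE)
  epoch_set(array(vals, dims), fs = hdr$fs, t0 = hdr$t0,
            channel_ids = hdr$channel_ids, trials = trials)
}

#' Default analysis configuration
#'
#' All tunable parameters of the pipeline with their defaults: the six
#' canonical bands, the covert/overt segment windows, filter settings,
#' the strong-pair correlation threshold (0.5), the per-cell trial cap
#' (60), the amplitude-rejection multiplier, the classifier search
#' grids, and the random seed.
#'
#' @return A named list (class `meg_config`).
#' @export
default_config <- function() {
  structure(list(
    bands = canonical_bands(),
    broadband = "standard",
    segments = default_segments(),
    lowpass = list(cutoff = 250, order = 4),
    notch = list(base = 60, order = 2, bw = 3),
    target_fs = 1000,
    strong_pair_threshold = 0.5,
    trial_cap = 60,
    amp_thresh_mult = 5,
    welch_window_s = 1,
    aec_mode = "single-trial-averaged",
    aec_edge_trim_s = 0.1,
    fisher_z = FALSE,
    log_features = FALSE,
    gamma_grid = c(0, 0.01, 0.1, 0.3, 0.5, 1),
    delta_grid = c(0, 1e-4, 1e-3, 1e-2),
    tune_folds = 10,
    seed = 1
  ), class = "meg_config")
}

#' Load an analysis configuration from a YAML file
#'
#' Absent keys take their defaults from [default_config()]; unknown keys
#' raise an error listing the valid keys; band definitions are validated
#' (`0 < lo < hi`).
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return A `meg_config` list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  if (is.null(user)) return(cfg)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         "; valid keys are: ", paste(names(cfg), collapse = ", "))
  }
  if (!is.null(user$bands)) {
    user$bands <- as_band_list(lapply(names(user$bands), function(nm) {
      b <- user$bands[[nm]]
      if (!is.numeric(b$lo) || !is.numeric(b$hi))
        stop("malformed band '", nm, "': lo/hi must be numbers")
      band_spec(nm, b$lo, b$hi)
    }))
  }
  if (!is.null(user$segments)) {
    user$segments <- lapply(names(user$segments), function(nm) {
      s <- user$segments[[nm]]
      segment_spec(nm, s$start_s, s$end_s)
    })
    names(user$segments) <- vapply(user$segments, `[[`, "", "name")
  }
  cfg[names(user)] <- user
  num_keys <- c("target_fs", "strong_pair_threshold", "trial_cap",
                "amp_thresh_mult", "welch_window_s", "aec_edge_trim_s",
                "tune_folds", "seed")
  for (k in num_keys) {
    if (!is.numeric(cfg[[k]]) || anyNA(cfg[[k]]))
      stop("config key '", k, "' must be numeric")
  }
  if (cfg$seed != round(cfg$seed)) stop("config key 'seed' must be an integer")
  cfg
}

# Short provenance hash of an R object (used in reports/manifests).
config_hash <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(x, tf, version = 2)
  unname(tools::md5sum(tf))
}
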