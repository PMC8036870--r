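#' Write a frame stack as a text frame matrix plus JSON sidecar
#'
#' Portable plain-text dialect: `<prefix>.tsv` holds one frame per row
#' (pixels flattened column-major, `rows * cols` values) and
#' `<prefix>.json` the sidecar `{"timestamps_s": [...], "view_id": k,
#' "rows": r, "cols": c}`.
#'
#' @param stack a [frame_stack()].
#' @param prefix output path without extension.
#' @return `prefix`, invisibly.
#' @export
write_framestack <- function(stack, prefix) {
  stopifnot(inherits(stack, "frame_stack"))
  d <- dim(stack$frames)
  data.table::fwrite(data.table::as.data.table(
    matrix(stack$frames, nrow = d[1L])),
    paste0(prefix, ".tsv"), sep = "\t", col.names = FALSE)
  jsonlite::write_json(
    list(timestamps_s = stack$timestamps, view_id = stack$view_id,
         rows = d[2L], cols = d[3L]),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' Read a frame stack written by [write_framestack()]
#' @param prefix path without extension.
#' @return A [frame_stack()].
#' @export
read_framestack <- function(prefix) {
  side <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  m <- as.matrix(data.table::fread(paste0(prefix, ".tsv"), header = FALSE))
  frame_stack(array(m, c(nrow(m), side$rows, side$cols)),
              side$timestamps_s, side$view_id)
}

#' Write/read the synthetic-recording file bundle
#'
#' Lays a [generate_scene()] / [make_multiview()] result out in the
#' pipeline's input dialects: one frame-stack pair per view
#' (`view<k>.tsv/.json`), `annotations.csv`, `reference.csv`,
#' `truth.csv`.
#'
#' @param recording a `synthetic_recording`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_recording <- function(recording, dir) {
  stopifnot(inherits(recording, "synthetic_recording"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(recording$stacks))
    write_framestack(recording$stacks[[i]],
                     file.path(dir, sprintf("view%d", i)))
  utils::write.csv(recording$annotations,
                   file.path(dir, "annotations.csv"), row.names = FALSE)
  utils::write.csv(recording$reference,
                   file.path(dir, "reference.csv"), row.names = FALSE)
  utils::write.csv(recording$truth,
                   file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_recording
#' @export
read_recording <- function(dir) {
  prefixes <- sort(sub("\\.json$", "",
                       list.files(dir, pattern = "^view[0-9]+\\.json$",
                                  full.names = TRUE)))
  if (length(prefixes) == 0L) stop("no view*.json found in ", dir)
  stacks <- lapply(prefixes, read_framestack)
  read_opt <- function(f) {
    p <- file.path(dir, f)
    if (file.exists(p)) utils::read.csv(p) else NULL
  }
  structure(list(stacks = stacks,
                 annotations = read_opt("annotations.csv"),
                 reference = read_opt("reference.csv"),
                 truth = read_opt("truth.csv"),
                 schedule = NULL, spec = NULL),
            class = "synthetic_recording")
}

#' Load, merge and save pipeline configuration
#'
#' Parameters live in one YAML or JSON file (sniffed by extension);
#' anything not set falls back to the defaults: 9 Hz rate, 8 s / 1 s
#' windows, f1 = 8, thr2 = 0.005, kappa1 = 70, kappa2 = 16,
#' kappa3 = 0.9, band 0.5–1.83 Hz, PR tolerance 3.75 BPM.
#'
#' @param path config file path, or NULL for pure defaults.
#' @param overrides named list applied on top (CLI flags).
#' @return Named list of effective parameters.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  defaults <- list(rate_hz = 9, window_s = 8, slide_s = 1,
                   f1 = 8, thr2 = 0.005,
                   kappa1 = 70, kappa2 = 16, kappa3 = 0.9,
                   lim1_hz = 0.5, lim2_hz = 1.83,
                   pad_factor = 120, tolerance_bpm = 3.75,
                   downscale_factor = 1,
                   grayscale_weights = c(0.299, 0.587, 0.114),
                   seed = 1)
  cfg <- defaults
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
      yaml::read_yaml(path)
    else jsonlite::read_json(path, simplifyVector = TRUE)
    unknown <- setdiff(names(user), names(defaults))
    if (length(unknown))
      stop("unknown config keys: ", paste(unknown, collapse = ", "))
    cfg[names(user)] <- user
  }
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown))
    stop("unknown override keys: ", paste(unknown, collapse = ", "))
  cfg[names(overrides)] <- overrides
  cfg
}

config_context <- function(cfg) {
  spectral_context(rate_hz = cfg$rate_hz, window_s = cfg$window_s,
                   pad_factor = cfg$pad_factor,
                   lim1 = cfg$lim1_hz, lim2 = cfg$lim2_hz)
}

#' Write an STFT matrix with its frequency grid header
#' @param stft an `rr_stft` from [build_stft()].
#' @param path output TSV path; first row holds the bin frequencies.
#' @return `path`, invisibly.
#' @export
write_stft <- function(stft, path) {
  m <- rbind(attr(stft, "freqs_hz"), unclass(stft))
  data.table::fwrite(data.table::as.data.table(m), path, sep = "\t",
                     col.names = FALSE)
  invisible(path)
}
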