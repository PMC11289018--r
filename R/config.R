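# Central configuration: every protocol default lives here, so the earlier
# (lax-SNR) and current screening behaviour is a single profile switch.

.config_defaults <- list(
  snr_threshold = 14,              # dB gate for the recording environment
  arhythmic_note_duration = 0.25,  # s per note of arhythmic items
  long_note_duration = 5.0,        # s of the sustained-note trials
  ngram_n = 3,                     # interval n-gram length for ngrukkon
  n_min = 3,                       # shortest item-bank n-gram (notes)
  n_max = 15,                      # longest item-bank n-gram (notes)
  contour_samples = 64,            # step-contour samples
  harmony_segment_dur = 2.0,       # s per implied-harmony window
  h2_threshold_long_note = 0.75,   # communality floor, long-note composite
  h2_threshold_accuracy = 0.30,    # communality floor, accuracy composite
  long_note_min_voiced = 10,       # voiced-frame floor for long-note scoring
  long_note_smooth_k = 5           # running-median window (frames)
)

#' Package configuration
#'
#' Returns the default configuration, optionally overridden by named
#' arguments. Unknown keys are rejected; values are validated.
#'
#' @param ... named overrides of the defaults (e.g. `snr_threshold = 0` for
#'   the earlier screening mode).
#' @return an object of class `"saa_config"`: a named list of settings.
#' @examples
#' saa_config()$snr_threshold  # 14
#' @export
saa_config <- function(...) {
  overrides <- list(...)
  if (length(overrides)) {
    unknown <- setdiff(names(overrides), names(.config_defaults))
    if (length(unknown) || is.null(names(overrides)) ||
        any(names(overrides) == "")) {
      stop("saa_config(): unknown or unnamed option(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  cfg <- utils::modifyList(.config_defaults, overrides)
  stopifnot(cfg$arhythmic_note_duration > 0, cfg$long_note_duration > 0,
            cfg$ngram_n >= 1, cfg$n_min >= 2, cfg$n_max >= cfg$n_min,
            cfg$contour_samples >= 2, cfg$harmony_segment_dur > 0)
  structure(cfg, class = "saa_config")
}

#' @export
print.saa_config <- function(x, ...) {
  cat("<saa_config>\n")
  for (nm in names(x)) cat(sprintf("  %-26s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
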