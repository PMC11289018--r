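# Readers/writers for the note-track and pitch-track table dialects emitted by
# pYIN / Sonic Annotator style transcription, plus a minimal standard MIDI
# file reader/writer for corpus ingestion.

#' Read a note track into a melody
#'
#' Expects the delimited note-track dialect: header `onset,dur,freq,note`
#' with onset and duration in seconds, `freq` in Hz and `note` the nearest
#' integer MIDI pitch. The real-valued pitch is taken from `freq` when
#' present, otherwise from `note`. Malformed rows are reported with their
#' line number.
#'
#' @param path file path.
#' @param id optional label; defaults to the file name.
#' @param is_rhythmic flag stored on the melody.
#' @return a [melody()].
#' @export
read_note_track <- function(path, id = NULL, is_rhythmic = TRUE) {
  if (!file.exists(path)) stop("read_note_track(): no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("onset", "dur")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("read_note_track(): ", path, " is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (!("freq" %in% names(df)) && !("note" %in% names(df))) {
    stop("read_note_track(): ", path, " needs a 'freq' or 'note' column", call. = FALSE)
  }
  bad <- which(!is.finite(df$onset) | !is.finite(df$dur) | df$dur <= 0)
  if (length(bad)) {
    stop("read_note_track(): malformed row(s) at line(s) ",
         paste(bad + 1L, collapse = ", "), " of ", path, call. = FALSE)
  }
  nonmono <- which(diff(df$onset) < 0)
  if (length(nonmono)) {
    stop("read_note_track(): non-monotone onset at line ", nonmono[1] + 2L,
         " of ", path, call. = FALSE)
  }
  pitch <- if ("freq" %in% names(df) && all(is.finite(df$freq) & df$freq > 0)) {
    hz_to_midi(df$freq)
  } else {
    df$note
  }
  melody(pitch, onset = df$onset, duration = df$dur,
         id = if (is.null(id)) basename(path) else id,
         is_rhythmic = is_rhythmic)
}

#' Write a melody as a note-track table
#'
#' @param m a [melody()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_note_track <- function(m, path) {
  df <- data.frame(onset = note_onsets(m),
                   dur = note_durations(m),
                   freq = midi_to_hz(note_pitches(m)),
                   note = as.integer(round_half_away(note_pitches(m))))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a frame-level pitch track
#'
#' Dialect: header `time,freq` (seconds, Hz); an empty or non-positive `freq`
#' marks an unvoiced frame, which is retained as missing rather than dropped.
#'
#' @param path file path.
#' @return a [pitch_track()].
#' @export
read_pitch_track <- function(path) {
  if (!file.exists(path)) stop("read_pitch_track(): no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("time", "freq"), names(df))
  if (length(miss)) {
    stop("read_pitch_track(): ", path, " is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  bad <- which(!is.finite(df$time))
  if (length(bad)) {
    stop("read_pitch_track(): malformed row(s) at line(s) ",
         paste(bad + 1L, collapse = ", "), " of ", path, call. = FALSE)
  }
  nonmono <- which(diff(df$time) <= 0)
  if (length(nonmono)) {
    stop("read_pitch_track(): non-increasing time at line ", nonmono[1] + 2L,
         " of ", path, call. = FALSE)
  }
  pitch_track(df$time, suppressWarnings(as.numeric(df$freq)))
}

#' Write a pitch track as a `time,freq` table
#'
#' Unvoiced frames are written with an empty `freq` field.
#'
#' @param track a [pitch_track()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pitch_track <- function(track, path) {
  utils::write.csv(track, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

# ---------------------------------------------------------------------------
# Minimal standard MIDI file support (format 0/1, monophonic use).
# Corpus melodies are monophonic by construction; only the first track
# containing notes is read, and overlapping notes are truncated at the next
# onset.

.midi_division <- 480L
.midi_tempo <- 500000L  # microseconds per quarter note (120 bpm)

.vlq_encode <- function(value) {
  bytes <- value %% 128L
  value <- value %/% 128L
  while (value > 0) {
    bytes <- c(value %% 128L + 128L, bytes)
    value <- value %/% 128L
  }
  as.raw(bytes)
}

.u32 <- function(x) as.raw(c(x %/% 16777216L, x %/% 65536L %% 256L,
                             x %/% 256L %% 256L, x %% 256L))
.u16 <- function(x) as.raw(c(x %/% 256L, x %% 256L))

#' Write a melody as a standard MIDI file (format 0)
#'
#' One monophonic track at 120 bpm, 480 ticks per quarter note, channel 1,
#' velocity 64. Pitches are rounded to the nearest integer MIDI number.
#'
#' @param m a [melody()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_midi <- function(m, path) {
  sec_per_tick <- .midi_tempo / 1e6 / .midi_division
  on_t <- as.integer(round(note_onsets(m) / sec_per_tick))
  off_t <- as.integer(round((note_onsets(m) + note_durations(m)) / sec_per_tick))
  pitch <- as.integer(round_half_away(note_pitches(m)))
  ev <- data.frame(tick = c(on_t, off_t),
                   on = rep(c(TRUE, FALSE), each = length(pitch)),
                   pitch = c(pitch, pitch))
  ev <- ev[order(ev$tick, ev$on), ]  # note-offs before note-ons at equal ticks
  body <- raw(0)
  # tempo meta event
  body <- c(body, as.raw(0x00), as.raw(c(0xFF, 0x51, 0x03)),
            as.raw(c(.midi_tempo %/% 65536L, .midi_tempo %/% 256L %% 256L,
                     .midi_tempo %% 256L)))
  last <- 0L
  for (i in seq_len(nrow(ev))) {
    delta <- ev$tick[i] - last
    last <- ev$tick[i]
    status <- if (ev$on[i]) 0x90 else 0x80
    vel <- if (ev$on[i]) 64L else 0L
    body <- c(body, .vlq_encode(delta), as.raw(c(status, ev$pitch[i], vel)))
  }
  body <- c(body, as.raw(c(0x00, 0xFF, 0x2F, 0x00)))  # end of track
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("MThd"), .u32(6L), .u16(0L), .u16(1L),
             .u16(.midi_division),
             charToRaw("MTrk"), .u32(length(body)), body), con)
  invisible(path)
}

.vlq_decode <- function(bytes, pos) {
  value <- 0L
  repeat {
    b <- as.integer(bytes[pos]); pos <- pos + 1L
    value <- value * 128L + b %% 128L
    if (b < 128L) break
  }
  list(value = value, pos = pos)
}

#' Read a monophonic melody from a standard MIDI file
#'
#' Supports format 0 and 1 files. The first track containing note events is
#' read; overlapping notes are truncated at the next onset. Tempo changes
#' before the first note are honoured; a single tempo is assumed thereafter.
#'
#' @param path file path.
#' @param id optional label; defaults to the file name.
#' @param is_rhythmic flag stored on the melody.
#' @return a [melody()].
#' @export
read_midi <- function(path, id = NULL, is_rhythmic = TRUE) {
  if (!file.exists(path)) stop("read_midi(): no such file: ", path, call. = FALSE)
  bytes <- readBin(path, "raw", file.info(path)$size)
  if (length(bytes) < 14 || rawToChar(bytes[1:4]) != "MThd") {
    stop("read_midi(): not a standard MIDI file: ", path, call. = FALSE)
  }
  division <- as.integer(bytes[13]) * 256L + as.integer(bytes[14])
  if (division >= 32768L) {
    stop("read_midi(): SMPTE time division not supported", call. = FALSE)
  }
  pos <- 15L
  tempo <- .midi_tempo
  notes <- NULL
  while (pos + 8L <= length(bytes)) {
    if (rawToChar(bytes[pos:(pos + 3L)]) != "MTrk") break
    len <- sum(as.integer(bytes[(pos + 4L):(pos + 7L)]) * c(16777216, 65536, 256, 1))
    track <- bytes[(pos + 8L):(pos + 7L + len)]
    pos <- pos + 8L + len
    parsed <- .parse_midi_track(track)
    if (!is.null(parsed$tempo)) tempo <- parsed$tempo
    if (is.null(notes) && nrow(parsed$notes) > 0) notes <- parsed$notes
  }
  if (is.null(notes) || nrow(notes) == 0) {
    stop("read_midi(): no note events found in ", path, call. = FALSE)
  }
  sec_per_tick <- tempo / 1e6 / division
  notes <- notes[order(notes$on_tick), ]
  onset <- notes$on_tick * sec_per_tick
  duration <- (notes$off_tick - notes$on_tick) * sec_per_tick
  # truncate overlaps at the next onset (monophonic reading)
  if (nrow(notes) > 1) {
    nxt <- c(onset[-1], Inf)
    duration <- pmin(duration, nxt - onset)
  }
  keep <- duration > 0
  melody(notes$pitch[keep], onset = onset[keep], duration = duration[keep],
         id = if (is.null(id)) basename(path) else id,
         is_rhythmic = is_rhythmic)
}

.parse_midi_track <- function(track) {
  pos <- 1L
  tick <- 0L
  status <- 0L
  tempo <- NULL
  on_tick <- integer(0); off_tick <- integer(0); pitch <- integer(0)
  open <- list()  # pitch -> onset tick
  while (pos <= length(track)) {
    d <- .vlq_decode(track, pos); pos <- d$pos
    tick <- tick + d$value
    b <- as.integer(track[pos])
    if (b >= 128L) { status <- b; pos <- pos + 1L } # else running status
    if (status == 255L) {            # meta event
      type <- as.integer(track[pos]); pos <- pos + 1L
      d <- .vlq_decode(track, pos); pos <- d$pos
      if (type == 0x51) {
        dat <- as.integer(track[pos:(pos + d$value - 1L)])
        tempo <- sum(dat * c(65536L, 256L, 1L))
      }
      pos <- pos + d$value
    } else if (status %/% 16L == 9L || status %/% 16L == 8L) {  # note on/off
      p <- as.integer(track[pos]); v <- as.integer(track[pos + 1L])
      pos <- pos + 2L
      is_on <- status %/% 16L == 9L && v > 0L
      key <- as.character(p)
      if (is_on) {
        open[[key]] <- tick
      } else if (!is.null(open[[key]])) {
        on_tick <- c(on_tick, open[[key]])
        off_tick <- c(off_tick, tick)
        pitch <- c(pitch, p)
        open[[key]] <- NULL
      }
    } else if (status %/% 16L %in% c(10L, 11L, 14L)) {
      pos <- pos + 2L                # two data bytes
    } else if (status %/% 16L %in% c(12L, 13L)) {
      pos <- pos + 1L                # one data byte
    } else if (status == 240L || status == 247L) {  # sysex
      d <- .vlq_decode(track, pos); pos <- d$pos + d$value
    } else {
      stop("read_midi(): unsupported status byte ", status, call. = FALSE)
    }
  }
  list(notes = data.frame(on_tick = on_tick, off_tick = off_tick, pitch = pitch),
       tempo = tempo)
}
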