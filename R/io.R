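# On-disk session format: one directory per participant holding
#   gaze.csv     t,gx,gy,gz,hx,hy,hz,valid
#   driving.csv  t,speed_kmh,brake
#   presses.csv  t,side
#   events.json  list of change-event records
#   aois.json    list of AOI records with track arrays
#   meta.json    participant_id, group, segment_bounds, seed, generator, ...
# The schema is this package's own; raw eye-tracker exports are converted
# upstream.

SESSION_FILES <- c("gaze.csv", "driving.csv", "presses.csv",
  "events.json", "aois.json", "meta.json")

#' Write a session log to a directory
#'
#' Columnar streams go to CSV, structured metadata to JSON, at full double
#' precision: `read_session(write_session(s, path))` reproduces `s` up to a
#' round-trip tolerance of 1e-9.
#'
#' @param session A `cb_session`.
#' @param path Directory to create/write into.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  if (!inherits(session, "cb_session")) {
    abort_argument("session must be a cb_session")
  }
  ok <- dir.exists(path) || dir.create(path, recursive = TRUE,
    showWarnings = FALSE)
  if (!ok || !dir.exists(path)) {
    cb_abort(sprintf("cannot create session directory '%s'", path),
      "cb_io_error")
  }
  wcsv <- function(df, file) {
    df <- as.data.frame(df)
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) sprintf("%.15g", x))
    write.csv(df, file.path(path, file), row.names = FALSE, quote = FALSE)
  }
  wcsv(session$gaze, "gaze.csv")
  wcsv(session$driving, "driving.csv")
  wcsv(session$presses, "presses.csv")
  jsonlite::write_json(as.data.frame(session$events),
    file.path(path, "events.json"),
    dataframe = "rows", digits = NA, auto_unbox = TRUE
  )
  aois <- lapply(unname(session$aois), function(a) {
    list(
      aoi_id = a$aoi_id, kind = a$kind, radius = a$radius,
      track = list(t = a$track$t, x = a$track$x, y = a$track$y,
        z = a$track$z)
    )
  })
  jsonlite::write_json(aois, file.path(path, "aois.json"),
    digits = NA, auto_unbox = TRUE)
  meta <- session$meta
  meta$participant_id <- session$participant_id
  meta$group <- session$group
  meta$segment_bounds <- as.data.frame(session$segment_bounds)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
    dataframe = "rows", digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a session log from a directory
#'
#' Counterpart of [write_session()]. The documented file set must be present
#' (a missing file raises a format error naming it) and the loaded session is
#' fully validated (see [validate_session()]).
#'
#' @param path Session directory.
#' @return A `cb_session`.
#' @export
read_session <- function(path) {
  if (!dir.exists(path)) {
    abort_format(sprintf("session directory '%s' does not exist", path))
  }
  missing <- SESSION_FILES[!file.exists(file.path(path, SESSION_FILES))]
  if (length(missing)) {
    abort_format(sprintf("session at '%s' is missing file %s",
      path, missing[1]))
  }
  gaze <- tibble::as_tibble(read.csv(file.path(path, "gaze.csv"),
    colClasses = c(rep("numeric", 7), "logical")))
  driving <- tibble::as_tibble(read.csv(file.path(path, "driving.csv"),
    colClasses = c("numeric", "numeric", "logical")))
  presses <- tibble::as_tibble(read.csv(file.path(path, "presses.csv"),
    colClasses = c("numeric", "character")))
  ev <- jsonlite::read_json(file.path(path, "events.json"),
    simplifyVector = TRUE)
  events <- tibble::as_tibble(ev)
  if (nrow(events) > 0) {
    events$encounter_index <- as.integer(events$encounter_index)
  }
  araw <- jsonlite::read_json(file.path(path, "aois.json"),
    simplifyVector = TRUE, simplifyDataFrame = FALSE)
  aois <- lapply(araw, function(a) {
    list(
      aoi_id = a$aoi_id, kind = a$kind, radius = a$radius,
      track = tibble::tibble(
        t = unlist(a$track$t), x = unlist(a$track$x),
        y = unlist(a$track$y), z = unlist(a$track$z)
      )
    )
  })
  names(aois) <- vapply(aois, `[[`, character(1), "aoi_id")
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
    simplifyVector = TRUE)
  sb <- tibble::as_tibble(meta$segment_bounds)
  pid <- meta$participant_id
  grp <- meta$group
  meta$participant_id <- NULL
  meta$group <- NULL
  meta$segment_bounds <- NULL
  session_log(pid, grp, gaze, driving, presses, events, aois, sb,
    meta = meta)
}

#' Write a cohort of sessions
#'
#' One subdirectory per participant (named by `participant_id`).
#'
#' @param sessions List of `cb_session` objects.
#' @param path Cohort directory.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(sessions, path) {
  for (s in sessions) write_session(s, file.path(path, s$participant_id))
  invisible(path)
}

#' Read a cohort of sessions
#'
#' @param path Cohort directory holding one session directory per
#'   participant.
#' @return Named list of `cb_session` objects.
#' @export
read_cohort <- function(path) {
  dirs <- list.dirs(path, recursive = FALSE)
  if (length(dirs) == 0) {
    abort_format(sprintf("no session directories found under '%s'", path))
  }
  sessions <- lapply(sort(dirs), read_session)
  names(sessions) <- vapply(sessions, `[[`, character(1), "participant_id")
  sessions
}
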