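# Columnar text formats for sessions and pose tracks.

session_csv_columns <- function() {
  c("mouse_id", "group", "drug", "phase", "trial_index", "entries",
    "choice", "rewarded", "reminder", "latency_s")
}

#' Write sessions to the session CSV format
#'
#' One row per trial with columns `mouse_id, group, drug, phase,
#' trial_index, entries` (semicolon-joined odor indices), `choice` (odor
#' index or `"OM"` for an omission), `rewarded` (0/1), `reminder` (0/1) and
#' `latency_s` (blank allowed). UTF-8 with header.
#'
#' @param sessions list of [session()] objects
#' @param path output file
#' @return `path` invisibly
#' @export
write_sessions <- function(sessions, path) {
  rows <- lapply(sessions, function(sess) {
    tr <- sess$trials
    data.frame(
      mouse_id = sess$mouse_id, group = sess$group,
      drug = unname(sess$drug_by_phase[tr$phase]),
      phase = tr$phase, trial_index = tr$trial_index,
      entries = tr$entries,
      choice = ifelse(is.na(tr$choice), "OM", as.character(tr$choice)),
      rewarded = as.integer(tr$rewarded),
      reminder = as.integer(tr$reminder),
      latency_s = ifelse(is.na(tr$latency_s), "", format(tr$latency_s, digits = 15)),
      stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read sessions from the session CSV format
#'
#' Parses and validates a trial table written by [write_sessions()] (or any
#' table with the same schema). Malformed rows are reported with their file
#' line numbers; unknown group labels, non-contiguous trial indices and
#' choices outside `{1..n_odors, OM}` are schema errors.
#'
#' @param path input file
#' @param config a [task_config()]
#' @param groups allowed group labels (default the study's labels); `NULL`
#'   accepts any non-empty label
#' @param require_criterion enforce criterion termination during validation
#' @return list of sessions with class `choice_cohort`
#' @export
read_sessions <- function(path, config = task_config(),
                          groups = study_groups(),
                          require_criterion = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, colClasses = "character",
                        fileEncoding = "UTF-8")
  miss <- setdiff(session_csv_columns(), names(df))
  if (length(miss))
    stop("invalid header; missing columns: ", paste(miss, collapse = ", "))
  if (nrow(df) == 0L) {
    out <- list()
    class(out) <- "choice_cohort"
    return(out)
  }
  line <- seq_len(nrow(df)) + 1L  # header is line 1
  if (!is.null(groups)) {
    bad <- !df$group %in% groups
    if (any(bad))
      stop("unknown group label '", df$group[bad][1L], "' at line ",
           line[bad][1L])
  } else if (any(!nzchar(df$group))) {
    stop("empty group label at line ", line[!nzchar(df$group)][1L])
  }
  okc <- df$choice == "OM" |
    df$choice %in% as.character(seq_len(config$n_odors))
  if (any(!okc))
    stop("choice must be one of 1..", config$n_odors, " or OM; got '",
         df$choice[!okc][1L], "' at line ", line[!okc][1L])
  okn <- grepl("^[0-9]+$", df$trial_index)
  if (any(!okn))
    stop("non-integer trial_index at line ", line[!okn][1L])
  sessions <- list()
  for (id in unique(df$mouse_id)) {
    sub <- df[df$mouse_id == id, , drop = FALSE]
    sub_line <- line[df$mouse_id == id]
    if (length(unique(sub$group)) != 1L)
      stop("mouse ", id, " appears under multiple groups (line ",
           sub_line[1L], ")")
    trials <- data.frame(
      phase = sub$phase,
      trial_index = as.integer(sub$trial_index),
      entries = sub$entries,
      choice = suppressWarnings(
        ifelse(sub$choice == "OM", NA_integer_, as.integer(sub$choice))),
      rewarded = sub$rewarded == "1",
      reminder = sub$reminder == "1",
      latency_s = suppressWarnings(
        ifelse(nzchar(sub$latency_s), as.numeric(sub$latency_s), NA_real_)),
      stringsAsFactors = FALSE)
    drug <- tapply(sub$drug, sub$phase, function(x) x[1L])
    sess <- session(id, sub$group[1L], trials,
                    drug_by_phase = drug[task_phases()[task_phases() %in% names(drug)]])
    err <- tryCatch({
      validate_session(sess, config, require_criterion = require_criterion)
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(err))
      stop("invalid session for mouse ", id, " (starting line ",
           sub_line[1L], "): ", err)
    sessions[[id]] <- sess
  }
  out <- unname(sessions)
  class(out) <- "choice_cohort"
  out
}

#' Write a pose track as CSV
#'
#' Columns `frame, head_x, head_y, torso_x, torso_y, tail_x, tail_y`; an
#' empty cell marks a missing coordinate.
#'
#' @param track a [pose_track()]
#' @param path output file
#' @return `path` invisibly
#' @export
write_pose_track <- function(track, path) {
  utils::write.csv(as.data.frame(track), path, row.names = FALSE, na = "",
                   quote = FALSE)
  invisible(path)
}

#' Read a pose track from CSV
#'
#' @param path input file
#' @param fps frames per second of the recording; metadata is taken from
#'   the caller, not assumed from frame counts
#' @return a [pose_track()]
#' @export
read_pose_track <- function(path, fps = 15) {
  df <- utils::read.csv(path)
  pose_track(df, fps = fps)
}
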