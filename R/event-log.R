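#' Assemble an event log from its four component tables
#'
#' An event log is the validated record of one diffusion experiment: the
#' individual roster, the sessions run at each group, every bout of
#' interaction with the task, and every observation of another individual's
#' bout.  All downstream analyses (the rate-model likelihood, the Cox bout
#' models, the option-bias test) consume this container.
#'
#' Times are stored in seconds on each session's own clock (bout and
#' observation times must lie inside `[start_time, end_time]` of their
#' session).  Experience carried across sessions is handled downstream by
#' counters, not by absolute time.
#'
#' @param individuals data.frame with columns `id`, `group_id`, `age_class`
#'   (`pup`/`juvenile`/`subadult`/`adult`), `sex` (`F`/`M`), `dominance`
#'   (`dominant`/`subordinate`), `is_demonstrator` (logical),
#'   `trained_option_type` (`flap`/`tube`, `NA` for non-demonstrators).
#' @param sessions data.frame with columns `session_id`, `group_id`,
#'   `index` (integer, unique within group), `start_time`, `end_time`
#'   (seconds), `attendees` (ids separated by `";"`).
#' @param bouts data.frame with columns `bout_id`, `session_id`,
#'   `individual_id`, `option_type` (`flap`/`tube`/`other`), `box_side`,
#'   `t_start`, `t_end`, `entered_box`, `obtained_food`, `outcome`.
#' @param observations data.frame with columns `observer_id`,
#'   `target_bout_id`, `t_start`, `t_end`, `saw_entry`, `saw_feeding`.
#' @param validate check all invariants (default `TRUE`).
#' @return an object of class `smfm_event_log`.
#' @seealso [read_event_log()], [write_event_log()],
#'   [build_experience_timeline()]
#' @export
event_log <- function(individuals, sessions, bouts = NULL,
                      observations = NULL, validate = TRUE) {
  if (is.null(bouts)) bouts <- empty_bouts()
  if (is.null(observations)) observations <- empty_observations()
  canon <- function(df, template) {
    df <- as.data.frame(df, stringsAsFactors = FALSE)
    if (all(names(template) %in% names(df)))
      df <- df[, names(template), drop = FALSE]
    df
  }
  individuals <- canon(individuals, empty_individuals())
  sessions <- canon(sessions, empty_sessions())
  bouts <- canon(bouts, empty_bouts())
  observations <- canon(observations, empty_observations())
  rownames(individuals) <- rownames(sessions) <- NULL
  rownames(bouts) <- rownames(observations) <- NULL
  log <- structure(list(individuals = individuals, sessions = sessions,
                        bouts = bouts, observations = observations),
                   class = "smfm_event_log")
  if (validate) validate_event_log(log)
  log
}

empty_individuals <- function() {
  data.frame(id = character(), group_id = character(),
             age_class = character(), sex = character(),
             dominance = character(), is_demonstrator = logical(),
             trained_option_type = character(),
             stringsAsFactors = FALSE)
}

empty_sessions <- function() {
  data.frame(session_id = character(), group_id = character(),
             index = integer(), start_time = numeric(),
             end_time = numeric(), attendees = character(),
             stringsAsFactors = FALSE)
}

empty_bouts <- function() {
  data.frame(bout_id = character(), session_id = character(),
             individual_id = character(), option_type = character(),
             box_side = character(), t_start = numeric(), t_end = numeric(),
             entered_box = logical(), obtained_food = logical(),
             outcome = character(), stringsAsFactors = FALSE)
}

empty_observations <- function() {
  data.frame(observer_id = character(), target_bout_id = character(),
             t_start = numeric(), t_end = numeric(), saw_entry = logical(),
             saw_feeding = logical(), stringsAsFactors = FALSE)
}

#' Split a `";"`-separated attendee field into individual ids
#' @param x character vector of attendee fields.
#' @return list of character vectors.
#' @export
split_attendees <- function(x) {
  lapply(strsplit(as.character(x), ";", fixed = TRUE),
         function(v) v[nzchar(v)])
}

fail_rule <- function(table, row, rule, detail = "") {
  stop(sprintf("event log validation failed [%s, row %s] rule '%s'%s",
               table, paste(row, collapse = ","), rule,
               if (nzchar(detail)) paste0(": ", detail) else ""),
       call. = FALSE)
}

need_cols <- function(df, cols, table) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(sprintf("event log validation failed [%s] missing columns: %s",
                 table, paste(miss, collapse = ", ")), call. = FALSE)
}

#' Validate an event log against the data-model invariants
#'
#' Checks closed vocabularies, referential integrity, session windows,
#' within-individual bout non-overlap, observation containment, and the
#' demonstrator / observation flag rules.  Stops with an error naming the
#' offending table, row and rule on the first violation.
#'
#' @param log an `smfm_event_log`.
#' @return `log`, invisibly, if valid.
#' @export
validate_event_log <- function(log) {
  ind <- log$individuals; ses <- log$sessions
  bt <- log$bouts; obs <- log$observations

  need_cols(ind, names(empty_individuals()), "individuals")
  need_cols(ses, names(empty_sessions()), "sessions")
  need_cols(bt, names(empty_bouts()), "bouts")
  need_cols(obs, names(empty_observations()), "observations")

  if (anyDuplicated(ind$id))
    fail_rule("individuals", which(duplicated(ind$id))[1], "unique id")
  bad <- which(!ind$age_class %in% AGE_CLASSES)
  if (length(bad)) fail_rule("individuals", bad[1], "age_class vocabulary")
  bad <- which(!ind$sex %in% SEXES)
  if (length(bad)) fail_rule("individuals", bad[1], "sex vocabulary")
  bad <- which(!ind$dominance %in% DOMINANCE)
  if (length(bad)) fail_rule("individuals", bad[1], "dominance vocabulary")
  bad <- which(ind$is_demonstrator & !ind$trained_option_type %in% OPTION_TYPES)
  if (length(bad))
    fail_rule("individuals", bad[1], "demonstrator has trained_option_type")
  bad <- which(!ind$is_demonstrator & !is.na(ind$trained_option_type))
  if (length(bad))
    fail_rule("individuals", bad[1], "non-demonstrator has no trained_option_type")

  if (anyDuplicated(ses$session_id))
    fail_rule("sessions", which(duplicated(ses$session_id))[1],
              "unique session_id")
  bad <- which(!ses$group_id %in% unique(ind$group_id))
  if (length(bad)) fail_rule("sessions", bad[1], "group_id refers to roster")
  bad <- which(!(ses$end_time > ses$start_time))
  if (length(bad)) fail_rule("sessions", bad[1], "end_time > start_time")
  dup <- duplicated(ses[c("group_id", "index")])
  if (any(dup))
    fail_rule("sessions", which(dup)[1], "session index unique within group")
  att <- split_attendees(ses$attendees)
  for (i in seq_along(att)) {
    miss <- setdiff(att[[i]], ind$id)
    if (length(miss))
      fail_rule("sessions", i, "attendees refer to roster",
                paste(miss, collapse = ","))
  }

  if (nrow(bt)) {
    if (anyDuplicated(bt$bout_id))
      fail_rule("bouts", which(duplicated(bt$bout_id))[1], "unique bout_id")
    bad <- which(!bt$session_id %in% ses$session_id)
    if (length(bad)) fail_rule("bouts", bad[1], "session_id refers to sessions")
    bad <- which(!bt$individual_id %in% ind$id)
    if (length(bad)) fail_rule("bouts", bad[1], "individual_id refers to roster")
    bad <- which(!bt$option_type %in% c(OPTION_TYPES, "other"))
    if (length(bad)) fail_rule("bouts", bad[1], "option_type vocabulary")
    bad <- which(!bt$box_side %in% BOX_SIDES)
    if (length(bad)) fail_rule("bouts", bad[1], "box_side vocabulary")
    bad <- which(!bt$outcome %in% OUTCOMES)
    if (length(bad)) fail_rule("bouts", bad[1], "outcome vocabulary")
    bad <- which(!(bt$t_start < bt$t_end))
    if (length(bad)) fail_rule("bouts", bad[1], "t_start < t_end")
    si <- match(bt$session_id, ses$session_id)
    bad <- which(bt$t_start < ses$start_time[si] | bt$t_end > ses$end_time[si])
    if (length(bad)) fail_rule("bouts", bad[1], "bout inside session window")
    bad <- which(xor(bt$outcome == "solved", bt$obtained_food))
    if (length(bad)) fail_rule("bouts", bad[1], "outcome solved <=> obtained_food")
    bad <- which(bt$obtained_food & !bt$entered_box)
    if (length(bad)) fail_rule("bouts", bad[1], "obtained_food => entered_box")
    for (key in unique(paste(bt$session_id, bt$individual_id))) {
      rows <- which(paste(bt$session_id, bt$individual_id) == key)
      if (length(rows) < 2L) next
      o <- rows[order(bt$t_start[rows])]
      overl <- which(bt$t_start[o][-1] < bt$t_end[o][-length(o)])
      if (length(overl))
        fail_rule("bouts", o[overl[1] + 1L],
                  "bouts of one individual never overlap")
    }
    # every actor attends the session of its bout
    att_by_ses <- setNames(split_attendees(ses$attendees), ses$session_id)
    bad <- which(!mapply(function(s, i) i %in% att_by_ses[[s]],
                         bt$session_id, bt$individual_id))
    if (length(bad)) fail_rule("bouts", bad[1], "actor attends session")
  }

  if (nrow(obs)) {
    bad <- which(!obs$target_bout_id %in% bt$bout_id)
    if (length(bad))
      fail_rule("observations", bad[1], "target_bout_id refers to bouts")
    bi <- match(obs$target_bout_id, bt$bout_id)
    bad <- which(!obs$observer_id %in% ind$id)
    if (length(bad))
      fail_rule("observations", bad[1], "observer_id refers to roster")
    bad <- which(obs$observer_id == bt$individual_id[bi])
    if (length(bad))
      fail_rule("observations", bad[1], "observer differs from actor")
    bad <- which(obs$t_start < bt$t_start[bi] | obs$t_end > bt$t_end[bi] |
                   obs$t_start > obs$t_end)
    if (length(bad))
      fail_rule("observations", bad[1],
                "observation interval inside target bout")
    bad <- which(obs$saw_feeding & !obs$saw_entry)
    if (length(bad))
      fail_rule("observations", bad[1], "saw_feeding => saw_entry")
    bad <- which(obs$saw_entry & !bt$entered_box[bi])
    if (length(bad))
      fail_rule("observations", bad[1], "saw_entry only if bout entered_box")
    att_by_ses <- setNames(split_attendees(ses$attendees), ses$session_id)
    bad <- which(!mapply(function(s, i) i %in% att_by_ses[[s]],
                         bt$session_id[bi], obs$observer_id))
    if (length(bad))
      fail_rule("observations", bad[1], "observer attends session")
  }
  invisible(log)
}

#' @export
print.smfm_event_log <- function(x, ...) {
  cat("<smfm_event_log>\n")
  cat(sprintf("  %d individuals in %d groups, %d sessions\n",
              nrow(x$individuals), length(unique(x$individuals$group_id)),
              nrow(x$sessions)))
  cat(sprintf("  %d interaction bouts (%d solved), %d observations\n",
              nrow(x$bouts), sum(x$bouts$outcome == "solved"),
              nrow(x$observations)))
  invisible(x)
}

#' @method all.equal smfm_event_log
#' @export
all.equal.smfm_event_log <- function(target, current, ...) {
  all.equal(unclass(target), unclass(current), ...)
}

SCHEMA_VERSIONS <- "1.0"

#' Write an event log to a directory of four CSV tables
#'
#' Writes `individuals.csv`, `sessions.csv`, `bouts.csv` and
#' `observations.csv` (UTF-8, fixed column order, times in seconds) so that
#' [read_event_log()] round-trips to an equal log.
#'
#' @param log a validated `smfm_event_log`.
#' @param path directory (created if necessary).
#' @return `path`, invisibly.
#' @export
write_event_log <- function(log, path) {
  validate_event_log(log)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  tabs <- list(individuals = log$individuals, sessions = log$sessions,
               bouts = log$bouts, observations = log$observations)
  for (nm in names(tabs)) {
    f <- file.path(path, paste0(nm, ".csv"))
    write.csv(tabs[[nm]], f, row.names = FALSE, na = "NA",
              fileEncoding = "UTF-8")
  }
  invisible(path)
}

#' Read and validate an event log from a directory of CSV tables
#'
#' @param path directory containing `individuals.csv`, `sessions.csv`,
#'   `bouts.csv`, `observations.csv` as written by [write_event_log()].
#' @param schema_version table-dialect version; only `"1.0"` is defined.
#' @return a validated `smfm_event_log`.
#' @export
read_event_log <- function(path, schema_version = "1.0") {
  if (!schema_version %in% SCHEMA_VERSIONS)
    stop("unsupported schema_version: ", schema_version, call. = FALSE)
  rd <- function(nm, classes) {
    f <- file.path(path, paste0(nm, ".csv"))
    if (!file.exists(f)) stop("missing table file: ", f, call. = FALSE)
    read.csv(f, stringsAsFactors = FALSE, na.strings = "NA",
             colClasses = classes, fileEncoding = "UTF-8")
  }
  ind <- rd("individuals", c(id = "character", group_id = "character",
                             age_class = "character", sex = "character",
                             dominance = "character",
                             is_demonstrator = "logical",
                             trained_option_type = "character"))
  ses <- rd("sessions", c(session_id = "character", group_id = "character",
                          index = "integer", start_time = "numeric",
                          end_time = "numeric", attendees = "character"))
  bt <- rd("bouts", c(bout_id = "character", session_id = "character",
                      individual_id = "character", option_type = "character",
                      box_side = "character", t_start = "numeric",
                      t_end = "numeric", entered_box = "logical",
                      obtained_food = "logical", outcome = "character"))
  obs <- rd("observations", c(observer_id = "character",
                              target_bout_id = "character",
                              t_start = "numeric", t_end = "numeric",
                              saw_entry = "logical", saw_feeding = "logical"))
  event_log(ind, ses, bt, obs, validate = TRUE)
}
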