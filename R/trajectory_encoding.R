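#' State alphabet for daily trajectory encoding
#'
#' Maps interval event types to integer day states.  Code 0 is reserved
#' for "no event"; higher codes win when stays overlap, so the default
#' ranks ICU above cardiology/respiratory stays above COPD-exacerbation
#' stays (most acute state wins).
#'
#' @param states character vector of interval event types in increasing
#'   priority order (codes 1, 2, ...).
#' @param ignore event types silently skipped during encoding (point
#'   events such as consultations, which are not part of the clustered
#'   sequence).
#' @return object of class \code{state_alphabet}: data.frame(code, state)
#'   plus the ignore set as an attribute.
#' @export
state_alphabet <- function(states = c("copd_exacerbation_stay",
                                      "cardio_resp_stay", "icu_stay"),
                           ignore = c("niv", "copd_drug", "gp_consult",
                                      "pulmonologist_consult",
                                      "hospital_consult", "pft",
                                      "sleep_study", "oxygen_start")) {
  if (anyDuplicated(states)) stop("duplicate state names")
  ab <- data.frame(code = seq_along(states), state = states,
                   stringsAsFactors = FALSE)
  ab <- rbind(data.frame(code = 0L, state = "none"), ab)
  structure(ab, ignore = ignore, class = c("state_alphabet", "data.frame"))
}

#' Encode one patient's events as a daily state sequence
#'
#' Produces the length-\code{window_days} categorical vector clustered by
#' the TAK procedure: position \code{t} is day \code{t - window_days - 1}
#' relative to the index (the last position is day -1; day 0, the index
#' day itself, is excluded).  Intervals are half-open \code{[start, end)}
#' in days, clipped to the window; each day takes the highest-priority
#' state among the events covering it and 0 when none does.
#'
#' @param events event rows for one patient (event_type, start_day,
#'   end_day).
#' @param alphabet a [state_alphabet()].
#' @param window_days window length T (default 365).
#' @return integer vector of length \code{window_days}.
#' @export
encode_trajectory <- function(events, alphabet = state_alphabet(),
                              window_days = 365L) {
  Tw <- as.integer(window_days)
  seq_states <- integer(Tw)
  if (nrow(events) == 0L) return(seq_states)
  known <- alphabet$state
  ign <- attr(alphabet, "ignore")
  bad <- setdiff(unique(events$event_type), c(known, ign))
  if (length(bad) > 0L)
    stop("event type(s) not in alphabet or ignore list: ",
         paste(bad, collapse = ", "))
  ev <- events[events$event_type %in% known, , drop = FALSE]
  if (nrow(ev) == 0L) return(seq_states)
  codes <- alphabet$code[match(ev$event_type, alphabet$state)]
  for (r in seq_len(nrow(ev))) {
    s <- max(ev$start_day[r], -Tw)
    e <- min(ev$end_day[r], 0L)
    if (e <= s) next
    idx <- (s + Tw + 1L):(e + Tw)      # day d maps to index d + Tw + 1
    seq_states[idx] <- pmax(seq_states[idx], codes[r])
  }
  seq_states
}

#' Encode a cohort into a patients-by-days state matrix
#'
#' @param events long event table for all patients.
#' @param patient_ids patients to encode, in the row order wanted; defaults
#'   to the unique ids present in the table.
#' @param alphabet a [state_alphabet()].
#' @param window_days window length T.
#' @return integer matrix (patients x T) with patient ids as rownames and
#'   the alphabet attached as attribute \code{alphabet}.
#' @export
encode_cohort <- function(events, patient_ids = NULL,
                          alphabet = state_alphabet(), window_days = 365L) {
  if (is.null(patient_ids)) patient_ids <- unique(events$patient_id)
  ev_by_pat <- split(events, events$patient_id)
  empty <- events[0L, , drop = FALSE]
  m <- t(vapply(patient_ids, function(id) {
    ev <- ev_by_pat[[id]]
    if (is.null(ev)) ev <- empty
    encode_trajectory(ev, alphabet, window_days)
  }, integer(window_days)))
  rownames(m) <- patient_ids
  attr(m, "alphabet") <- alphabet
  m
}

#' Write / read a sequence matrix as delimited text
#'
#' Lossless round-trip persistence for daily-state matrices: a TSV with
#' patient ids in the first column and one column per day, plus a sidecar
#' \code{<path>.alphabet.tsv} describing the state codes.
#'
#' @param m sequence matrix from [encode_cohort()].
#' @param path file path for the matrix.
#' @return \code{path}, invisibly (writer); the matrix with alphabet
#'   attribute (reader).
#' @export
write_sequences <- function(m, path) {
  df <- data.frame(patient_id = rownames(m), m, check.names = FALSE)
  colnames(df) <- c("patient_id", paste0("d", seq_len(ncol(m))))
  write_stage_table(df, path)
  ab <- attr(m, "alphabet")
  if (!is.null(ab)) {
    side <- rbind(as.data.frame(ab),
                  data.frame(code = -1L, state = attr(ab, "ignore")))
    write_stage_table(side, paste0(path, ".alphabet.tsv"))
  }
  invisible(path)
}

#' @rdname write_sequences
#' @export
read_sequences <- function(path) {
  df <- read_stage_table(path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "integer"
  dimnames(m) <- list(df$patient_id, NULL)
  ab_path <- paste0(path, ".alphabet.tsv")
  if (file.exists(ab_path)) {
    side <- read_stage_table(ab_path)
    ab <- side[side$code >= 0L, , drop = FALSE]
    rownames(ab) <- NULL
    attr(m, "alphabet") <- structure(
      ab, ignore = side$state[side$code < 0L],
      class = c("state_alphabet", "data.frame"))
  }
  m
}
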