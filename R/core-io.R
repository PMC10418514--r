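# Data model and readers/writers shared by all pipeline stages.
#
# Conventions enforced here and relied on everywhere else:
#   * sentence IDs are 0-based and contiguous (0..P-1) in document order;
#   * criterion indices are 0-based within their side (inclusion/exclusion);
#   * all text is normalized to Unicode NFC; no lowercasing at this level.

#' Segment a free-text note into sentences with stable IDs
#'
#' Deterministic rule-based segmentation: the note is split after runs of
#' sentence-final punctuation (`.`, `!`, `?`) that are followed by
#' whitespace.  Decimal numbers and lab thresholds such as `1.5` are never
#' split because no whitespace follows the period.  Sentence IDs are
#' assigned 0-based in document order, and the concatenation of the
#' sentence texts reproduces the input up to inter-sentence whitespace.
#'
#' @param raw_text A single non-empty character string.
#' @return A data.frame with columns `sentence_id` (integer, 0-based) and
#'   `text` (character).
#' @export
#' @examples
#' segment_note("He is 58. He has diabetes.")
segment_note <- function(raw_text) {
  if (!.is_string(raw_text)) .stopf("raw_text must be a single string")
  raw_text <- .nfc(raw_text)
  if (!nzchar(trimws(raw_text))) .stopf("cannot segment empty or whitespace-only text")
  pieces <- strsplit(trimws(raw_text), "(?<=[.!?])\\s+", perl = TRUE)[[1]]
  pieces <- pieces[nzchar(trimws(pieces))]
  data.frame(
    sentence_id = seq_along(pieces) - 1L,
    text = pieces,
    stringsAsFactors = FALSE
  )
}

#' Construct a patient note
#'
#' @param patient_id Opaque identifier string.
#' @param text Free-text patient summary; segmented with [segment_note()].
#' @return An object of class `patient_note` with fields `patient_id`,
#'   `raw_text` and `sentences` (data.frame of `sentence_id`, `text`).
#' @export
patient_note <- function(patient_id, text) {
  if (!.is_string(patient_id) || !nzchar(patient_id)) {
    .stopf("patient_id must be a non-empty string")
  }
  sentences <- segment_note(text)
  structure(
    list(
      patient_id = .nfc(patient_id),
      raw_text = .nfc(text),
      sentences = sentences
    ),
    class = "patient_note"
  )
}

#' @export
print.patient_note <- function(x, ...) {
  cat(sprintf(
    "<patient_note %s: %d sentence%s>\n", x$patient_id,
    nrow(x$sentences), if (nrow(x$sentences) == 1L) "" else "s"
  ))
  invisible(x)
}

# Strip a leading bullet marker or enumeration from one criterion line.
.strip_bullet <- function(line) {
  trimws(sub("^\\s*(?:[-*•‣·]+|\\(?[0-9]+[.)]|[a-zA-Z][.)])?\\s*", "", line, perl = TRUE))
}

#' Split a free-text eligibility block into criterion lists
#'
#' Lines under a header matching `inclusion criteria` (case-insensitive) go
#' to the inclusion list, lines under `exclusion criteria` to the exclusion
#' list.  Bullet markers (`-`, `*`, bullets, numbering) are stripped, blank
#' lines dropped, and text before any recognized header is ignored.  Lines
#' are never split on sentence punctuation, because criteria routinely
#' contain internal periods in lab thresholds.
#'
#' @param eligibility_text Free text, possibly empty.
#' @return A list with character vectors `inclusion` and `exclusion`.
#' @export
#' @examples
#' split_criteria("Inclusion Criteria:\n- Age > 18\nExclusion Criteria:\n- Pregnancy")
split_criteria <- function(eligibility_text) {
  if (!is.character(eligibility_text) || length(eligibility_text) != 1L) {
    .stopf("eligibility_text must be a single string")
  }
  out <- list(inclusion = character(0), exclusion = character(0))
  if (is.na(eligibility_text) || !nzchar(trimws(eligibility_text))) return(out)
  lines <- strsplit(.nfc(eligibility_text), "\r?\n")[[1]]
  side <- NA_character_
  for (line in lines) {
    if (grepl("inclusion criteria", line, ignore.case = TRUE)) {
      side <- "inclusion"
      next
    }
    if (grepl("exclusion criteria", line, ignore.case = TRUE)) {
      side <- "exclusion"
      next
    }
    if (is.na(side)) next
    item <- .strip_bullet(line)
    if (nzchar(item)) out[[side]] <- c(out[[side]], item)
  }
  out
}

#' Construct a clinical-trial record
#'
#' @param trial_id Registry identifier (e.g. NCT-style); must be non-empty.
#' @param brief_title,brief_summary Free-text background fields.
#' @param conditions,interventions Character vectors.
#' @param inclusion_criteria,exclusion_criteria Ordered character vectors of
#'   criterion statements; bullet markers are stripped and empty entries
#'   dropped.  Supply `eligibility_text` instead to have the lists derived
#'   with [split_criteria()].
#' @param eligibility_text Optional free-text eligibility block used when
#'   pre-split lists are absent.
#' @return An object of class `trial_record`.
#' @export
trial_record <- function(trial_id, brief_title = "", conditions = character(0),
                         interventions = character(0), brief_summary = "",
                         inclusion_criteria = NULL, exclusion_criteria = NULL,
                         eligibility_text = NULL) {
  if (!.is_string(trial_id) || !nzchar(trial_id)) {
    .stopf("trial_id must be a non-empty string")
  }
  if (is.null(inclusion_criteria) && is.null(exclusion_criteria)) {
    if (is.null(eligibility_text)) eligibility_text <- ""
    crit <- split_criteria(eligibility_text)
    inclusion_criteria <- crit$inclusion
    exclusion_criteria <- crit$exclusion
  }
  clean <- function(x) {
    if (is.null(x)) return(character(0))
    x <- vapply(as.character(x), .strip_bullet, character(1), USE.NAMES = FALSE)
    x <- x[nzchar(x)]
    .nfc(x)
  }
  structure(
    list(
      trial_id = .nfc(trial_id),
      background = list(
        brief_title = .nfc(as.character(brief_title)),
        conditions = .nfc(as.character(conditions)),
        interventions = .nfc(as.character(interventions)),
        brief_summary = .nfc(as.character(brief_summary))
      ),
      inclusion_criteria = clean(inclusion_criteria),
      exclusion_criteria = clean(exclusion_criteria)
    ),
    class = "trial_record"
  )
}

#' @export
print.trial_record <- function(x, ...) {
  cat(sprintf(
    "<trial_record %s: %d inclusion / %d exclusion criteria>\n",
    x$trial_id, length(x$inclusion_criteria), length(x$exclusion_criteria)
  ))
  invisible(x)
}

.read_jsonl <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) .stopf("empty file: %s", path)
  lapply(lines, function(l) jsonlite::fromJSON(l, simplifyVector = TRUE))
}

.write_jsonl <- function(records, path) {
  lines <- vapply(
    records,
    function(r) jsonlite::toJSON(r, auto_unbox = TRUE, digits = NA, null = "null"),
    character(1)
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read patient notes from a JSONL file
#'
#' One JSON object per line with fields `patient_id` and `text`.
#'
#' @param path Path to the JSONL file.
#' @return A list of [patient_note()] objects, input order preserved.
#' @export
read_patients <- function(path) {
  recs <- .read_jsonl(path)
  ids <- character(0)
  out <- vector("list", length(recs))
  for (k in seq_along(recs)) {
    r <- recs[[k]]
    if (is.null(r$patient_id) || is.null(r$text)) {
      .stopf("patient record %d is missing patient_id or text", k)
    }
    if (!nzchar(trimws(as.character(r$text)))) {
      .stopf("patient record %s has empty text", as.character(r$patient_id))
    }
    out[[k]] <- patient_note(as.character(r$patient_id), as.character(r$text))
    ids <- c(ids, out[[k]]$patient_id)
  }
  if (anyDuplicated(ids)) {
    .stopf("duplicate patient_id: %s", ids[duplicated(ids)][1])
  }
  out
}

#' Write patient notes to JSONL
#' @param patients List of `patient_note` objects.
#' @param path Output path.
#' @export
write_patients <- function(patients, path) {
  .write_jsonl(
    lapply(patients, function(p) list(patient_id = p$patient_id, text = p$raw_text)),
    path
  )
}

.trial_from_record <- function(r, k) {
  if (is.null(r$trial_id)) .stopf("trial record %d is missing trial_id", k)
  trial_record(
    trial_id = as.character(r$trial_id),
    brief_title = if (is.null(r$brief_title)) "" else r$brief_title,
    conditions = if (is.null(r$conditions)) character(0) else unlist(r$conditions),
    interventions = if (is.null(r$interventions)) character(0) else unlist(r$interventions),
    brief_summary = if (is.null(r$brief_summary)) "" else r$brief_summary,
    inclusion_criteria = if (is.null(r$inclusion_criteria)) NULL else unlist(r$inclusion_criteria),
    exclusion_criteria = if (is.null(r$exclusion_criteria)) NULL else unlist(r$exclusion_criteria),
    eligibility_text = if (is.null(r$eligibility_text)) NULL else r$eligibility_text
  )
}

#' Read trial records
#'
#' JSONL is the canonical corpus format (one trial object per line with
#' fields `trial_id`, `brief_title`, `conditions`, `interventions`,
#' `brief_summary`, and either pre-split `inclusion_criteria` /
#' `exclusion_criteria` arrays or a free-text `eligibility_text` block that
#' is split with [split_criteria()]).  A minimal XML dialect
#' (`<trials><trial><trial_id>...</trial_id>...</trial></trials>`) is also
#' accepted when the `xml2` package is available.
#'
#' @param path Path to the corpus file.
#' @param format `"jsonl"` (default) or `"xml"`.
#' @return A list of [trial_record()] objects; duplicate trial IDs error.
#' @export
read_trials <- function(path, format = c("jsonl", "xml")) {
  format <- match.arg(format)
  if (format == "xml") {
    recs <- .read_trials_xml(path)
  } else {
    recs <- .read_jsonl(path)
  }
  out <- vector("list", length(recs))
  for (k in seq_along(recs)) {
    out[[k]] <- tryCatch(
      .trial_from_record(recs[[k]], k),
      error = function(e) {
        id <- recs[[k]]$trial_id
        .stopf(
          "malformed trial record %s: %s",
          if (is.null(id)) sprintf("#%d", k) else as.character(id),
          conditionMessage(e)
        )
      }
    )
  }
  ids <- vapply(out, function(t) t$trial_id, character(1))
  if (anyDuplicated(ids)) .stopf("duplicate trial_id: %s", ids[duplicated(ids)][1])
  out
}

.read_trials_xml <- function(path) {
  if (!requireNamespace("xml2", quietly = TRUE)) {
    .stopf("the xml2 package is required to read XML trial corpora")
  }
  if (!file.exists(path)) .stopf("file not found: %s", path)
  doc <- xml2::read_xml(path)
  nodes <- xml2::xml_find_all(doc, ".//trial")
  lapply(nodes, function(n) {
    field <- function(name) {
      v <- xml2::xml_find_first(n, name)
      if (inherits(v, "xml_missing")) NULL else xml2::xml_text(v)
    }
    multi <- function(name) {
      v <- xml2::xml_find_all(n, name)
      if (length(v) == 0L) NULL else xml2::xml_text(v)
    }
    list(
      trial_id = field("trial_id"),
      brief_title = field("brief_title"),
      conditions = multi("conditions/condition"),
      interventions = multi("interventions/intervention"),
      brief_summary = field("brief_summary"),
      inclusion_criteria = multi("inclusion_criteria/criterion"),
      exclusion_criteria = multi("exclusion_criteria/criterion"),
      eligibility_text = field("eligibility_text")
    )
  })
}

#' Write trial records to JSONL
#' @param trials List of `trial_record` objects.
#' @param path Output path.
#' @export
write_trials <- function(trials, path) {
  .write_jsonl(lapply(trials, function(t) {
    list(
      trial_id = t$trial_id,
      brief_title = t$background$brief_title,
      conditions = as.list(t$background$conditions),
      interventions = as.list(t$background$interventions),
      brief_summary = t$background$brief_summary,
      inclusion_criteria = as.list(t$inclusion_criteria),
      exclusion_criteria = as.list(t$exclusion_criteria)
    )
  }), path)
}

#' Construct a set of eligibility judgments
#'
#' @param patient_id,trial_id,label Parallel vectors; `label` must be one
#'   of `eligible`, `excluded`, `potential`, `irrelevant`.  Any pair absent
#'   from the set is treated as unlabeled.
#' @return A `qrel_set`: a data.frame with those three columns.
#' @export
qrel_set <- function(patient_id = character(0), trial_id = character(0),
                     label = character(0)) {
  ok <- c("eligible", "excluded", "potential", "irrelevant")
  bad <- setdiff(unique(label), ok)
  if (length(bad)) .stopf("invalid eligibility label(s): %s", paste(bad, collapse = ", "))
  df <- data.frame(
    patient_id = as.character(patient_id),
    trial_id = as.character(trial_id),
    label = as.character(label),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(df[c("patient_id", "trial_id")])) {
    .stopf("duplicate (patient_id, trial_id) pair in qrels")
  }
  class(df) <- c("qrel_set", "data.frame")
  df
}

#' Read TREC-style qrels
#'
#' Four whitespace-separated columns per line: `patient_id 0 trial_id rel`.
#' Integer relevance codes are mapped to eligibility labels through
#' `code_map`; the default is the dialect used by the clinical-trials
#' evaluation campaigns (2 = eligible, 1 = excluded, 0 = irrelevant).
#'
#' @param path Path to the qrels file.
#' @param code_map Named character vector mapping code strings to labels.
#' @return A [qrel_set()].
#' @export
read_qrels <- function(path,
                       code_map = c("0" = "irrelevant", "1" = "excluded", "2" = "eligible")) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  pid <- tid <- lab <- character(length(lines))
  for (k in seq_along(lines)) {
    f <- strsplit(trimws(lines[k]), "\\s+")[[1]]
    if (length(f) != 4L) .stopf("malformed qrels line %d: expected 4 fields", k)
    if (!f[4] %in% names(code_map)) .stopf("malformed qrels line %d: unknown code %s", k, f[4])
    pid[k] <- f[1]; tid[k] <- f[3]; lab[k] <- code_map[[f[4]]]
  }
  qrel_set(pid, tid, lab)
}

#' Write qrels in TREC form
#' @param qrels A [qrel_set()].
#' @param path Output path.
#' @param label_map Named integer vector mapping labels to relevance codes.
#' @export
write_qrels <- function(qrels, path,
                        label_map = c(irrelevant = 0L, excluded = 1L, eligible = 2L,
                                      potential = 3L)) {
  missing <- setdiff(unique(qrels$label), names(label_map))
  if (length(missing)) .stopf("label_map lacks code(s) for: %s", paste(missing, collapse = ", "))
  writeLines(
    sprintf("%s 0 %s %d", qrels$patient_id, qrels$trial_id, label_map[qrels$label]),
    path
  )
  invisible(path)
}

#' Construct a ranked run list
#'
#' @param patient_id,trial_id,score Parallel vectors; within each patient,
#'   scores must be non-increasing in rank.  Ranks are assigned 1-based in
#'   input order within each patient.
#' @return A `run_list`: data.frame with columns `patient_id`, `trial_id`,
#'   `rank`, `score`.
#' @export
run_list <- function(patient_id, trial_id, score) {
  df <- data.frame(
    patient_id = as.character(patient_id),
    trial_id = as.character(trial_id),
    score = as.numeric(score),
    stringsAsFactors = FALSE
  )
  parts <- split(seq_len(nrow(df)), df$patient_id)
  df$rank <- NA_integer_
  for (idx in parts) {
    if (is.unsorted(rev(df$score[idx]))) {
      .stopf("scores must be non-increasing with rank within a patient")
    }
    df$rank[idx] <- seq_along(idx)
  }
  df <- df[c("patient_id", "trial_id", "rank", "score")]
  class(df) <- c("run_list", "data.frame")
  df
}

#' Write a run in 6-column TREC form
#'
#' Lines are `patient_id Q0 trial_id rank score tag`.
#'
#' @param run A [run_list()].
#' @param path Output path.
#' @param tag Run tag written in the sixth column.
#' @export
write_run <- function(run, path, tag = "trialmatchr") {
  writeLines(
    sprintf("%s Q0 %s %d %.6f %s", run$patient_id, run$trial_id, run$rank, run$score, tag),
    path
  )
  invisible(path)
}

#' Read a 6-column TREC run file
#' @param path Path to the run file.
#' @return A [run_list()].
#' @export
read_run <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  pid <- tid <- character(length(lines)); sc <- numeric(length(lines))
  for (k in seq_along(lines)) {
    f <- strsplit(trimws(lines[k]), "\\s+")[[1]]
    if (length(f) != 6L) .stopf("malformed run line %d: expected 6 fields", k)
    pid[k] <- f[1]; tid[k] <- f[3]; sc[k] <- as.numeric(f[5])
    if (is.na(sc[k])) .stopf("malformed run line %d: score not numeric", k)
  }
  run_list(pid, tid, sc)
}
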