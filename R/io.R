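#' Write a cohort to tidy CSV files
#'
#' Serializes a cohort as two plain-text tables: a tidy kinematics file with
#' columns `subject`, `time` (s), `segment`, `x`, `y`, `z` (m), and a
#' metadata file with one row per subject (`subject_id`, `group`, `age`,
#' `sex`, `fs`, plus any clinical score columns; controls carry `NA` clinical
#' scores).
#'
#' @param cohort A cohort as returned by [generate_cohort()] or
#'   [read_cohort()].
#' @param kinematics_path,metadata_path Output CSV paths.
#' @return Invisibly, the two paths.
#' @export
write_cohort <- function(cohort, kinematics_path, metadata_path) {
  recs <- cohort$recordings
  tabs <- lapply(recs, function(rec) {
    t_sec <- seq_len(nrow(rec$series[[1L]])) - 1L
    do.call(rbind, lapply(names(rec$series), function(s) {
      xyz <- rec$series[[s]]
      data.table::data.table(
        subject = rec$subject_id, time = t_sec / rec$fs, segment = s,
        x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L]
      )
    }))
  })
  data.table::fwrite(data.table::rbindlist(tabs), kinematics_path)
  data.table::fwrite(cohort$metadata, metadata_path)
  invisible(c(kinematics_path, metadata_path))
}

#' Read a cohort from tidy CSV files
#'
#' Reads the tidy kinematics and metadata tables written by [write_cohort()]
#' (or produced externally in the same schema) and validates them: required
#' columns must be present, segment names must match the canonical list from
#' [body_segments()] exactly, `(subject, time, segment)` rows must be unique,
#' values must be finite, and every kinematics subject must appear in the
#' metadata (and vice versa).
#'
#' @param kinematics_path,metadata_path Input CSV paths.
#' @return A cohort: list with `recordings` (list of `SegmentRecording`) and
#'   `metadata` (data.frame, one row per subject). Each recording is a list
#'   with `subject_id`, `group`, `age`, `sex`, `clinical` (named list or
#'   `NULL`), `fs`, and `series` (named list of T x 3 position matrices).
#' @export
read_cohort <- function(kinematics_path, metadata_path) {
  kin <- data.table::fread(kinematics_path, colClasses = list(
    character = "segment"))
  need <- c("subject", "time", "segment", "x", "y", "z")
  miss <- setdiff(need, names(kin))
  if (length(miss) > 0L) {
    stop("kinematics file missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  assert_known_segments(kin$segment)
  dup <- duplicated(kin[, c("subject", "time", "segment")])
  if (any(dup)) {
    i <- which(dup)[1L]
    stop(sprintf(
      "duplicate (subject, time, segment) row: (%s, %g, %s) at line %d",
      kin$subject[i], kin$time[i], kin$segment[i], i + 1L), call. = FALSE)
  }
  if (!all(is.finite(kin$x) & is.finite(kin$y) & is.finite(kin$z))) {
    stop("non-finite coordinate values in kinematics file", call. = FALSE)
  }

  meta <- as.data.frame(data.table::fread(metadata_path))
  need_meta <- c("subject_id", "group", "age", "sex")
  miss <- setdiff(need_meta, names(meta))
  if (length(miss) > 0L) {
    stop("metadata file missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  subj_kin <- unique(kin$subject)
  no_meta <- setdiff(subj_kin, meta$subject_id)
  if (length(no_meta) > 0L) {
    stop("subject(s) present in kinematics but missing from metadata: ",
         paste(no_meta, collapse = ", "), call. = FALSE)
  }
  no_kin <- setdiff(meta$subject_id, subj_kin)
  if (length(no_kin) > 0L) {
    stop("subject(s) present in metadata but missing from kinematics: ",
         paste(no_kin, collapse = ", "), call. = FALSE)
  }

  clin_cols <- setdiff(names(meta), c(need_meta, "fs"))
  data.table::setkeyv(kin, c("subject", "segment", "time"))
  recordings <- lapply(meta$subject_id, function(id) {
    sub <- kin[kin$subject == id, ]
    fs <- 1 / median(diff(sort(unique(sub$time))))
    series <- lapply(split(sub, sub$segment), function(d) {
      d <- d[order(d$time), ]
      unname(cbind(d$x, d$y, d$z))
    })
    lens <- vapply(series, nrow, 0L)
    if (length(unique(lens)) != 1L) {
      stop("subject ", id, ": segments have unequal lengths", call. = FALSE)
    }
    mrow <- meta[meta$subject_id == id, , drop = FALSE]
    clinical <- NULL
    if (length(clin_cols) > 0L) {
      vals <- as.list(mrow[1L, clin_cols, drop = FALSE])
      if (any(!is.na(unlist(vals)))) clinical <- vals
    }
    structure(list(
      subject_id = id, group = mrow$group[1L], age = mrow$age[1L],
      sex = mrow$sex[1L], clinical = clinical,
      fs = round(fs, 6), series = series
    ), class = "SegmentRecording")
  })
  names(recordings) <- meta$subject_id
  list(recordings = recordings, metadata = meta)
}
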