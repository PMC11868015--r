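#' Write a cohort to the plain-CSV directory layout
#'
#' Layout: `subjects.csv` (metadata, BP, lactate replicates),
#' `events.csv` (hill start / stop start / stop end, s),
#' `rr/<subject_id>.csv` (`t_ms` cumulative beat time, `rr_ms`),
#' `power/<subject_id>.csv` (`t_s`, `watts`, `speed_mps`; `watts` empty for
#' riders without a meter), and optionally `ground_truth.json` plus
#' `rr_clean/<subject_id>.csv` for the uncorrupted series.
#'
#' @param cohort an `hrv_cohort` with RR series attached.
#' @param dir output directory (created if needed).
#' @param ground_truth also write latents and artifact positions.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, ground_truth = TRUE) {
  stopifnot(inherits(cohort, "hrv_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(cohort$subjects, file.path(dir, "subjects.csv"), row.names = FALSE)
  write.csv(cohort$events, file.path(dir, "events.csv"), row.names = FALSE)
  if (!is.null(cohort$rr)) {
    dir.create(file.path(dir, "rr"), showWarnings = FALSE)
    for (id in names(cohort$rr)) {
      s <- cohort$rr[[id]]
      write.csv(data.frame(t_ms = s$t, rr_ms = s$rr),
                file.path(dir, "rr", paste0(id, ".csv")), row.names = FALSE)
    }
  }
  if (!is.null(cohort$power)) {
    dir.create(file.path(dir, "power"), showWarnings = FALSE)
    for (id in names(cohort$power)) {
      write.csv(cohort$power[[id]],
                file.path(dir, "power", paste0(id, ".csv")), row.names = FALSE)
    }
  }
  if (ground_truth && !is.null(cohort$ground_truth)) {
    gt <- cohort$ground_truth
    jsonlite::write_json(
      list(subject_latents = gt$subject_latents,
           artifact_positions = gt$artifact_positions),
      file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
    if (!is.null(gt$clean_rr)) {
      dir.create(file.path(dir, "rr_clean"), showWarnings = FALSE)
      for (id in names(gt$clean_rr)) {
        s <- gt$clean_rr[[id]]
        write.csv(data.frame(t_ms = s$t, rr_ms = s$rr),
                  file.path(dir, "rr_clean", paste0(id, ".csv")), row.names = FALSE)
      }
    }
  }
  invisible(dir)
}

#' Read a cohort from the plain-CSV directory layout
#'
#' Inverse of [write_cohort()]; ground truth is restored when present.
#'
#' @param dir directory holding `subjects.csv`, `events.csv` and `rr/`.
#' @return An `hrv_cohort`.
#' @export
read_cohort <- function(dir) {
  subj <- read.csv(file.path(dir, "subjects.csv"), stringsAsFactors = FALSE)
  events <- read.csv(file.path(dir, "events.csv"), stringsAsFactors = FALSE)
  read_rr_dir <- function(sub) {
    if (!dir.exists(file.path(dir, sub))) return(NULL)
    out <- list()
    for (id in subj$subject_id) {
      f <- file.path(dir, sub, paste0(id, ".csv"))
      if (!file.exists(f)) next
      d <- read.csv(f)
      out[[id]] <- rr_series(d$rr_ms, t = d$t_ms, provenance = "raw")
    }
    out
  }
  rr <- read_rr_dir("rr")
  power <- NULL
  if (dir.exists(file.path(dir, "power"))) {
    power <- list()
    for (id in subj$subject_id) {
      f <- file.path(dir, "power", paste0(id, ".csv"))
      if (file.exists(f)) power[[id]] <- read.csv(f)
    }
  }
  gt <- NULL
  gtf <- file.path(dir, "ground_truth.json")
  if (file.exists(gtf)) {
    raw <- jsonlite::read_json(gtf, simplifyVector = TRUE)
    gt <- list(subject_latents = as.data.frame(raw$subject_latents),
               artifact_positions = lapply(raw$artifact_positions, as.integer),
               clean_rr = read_rr_dir("rr_clean"))
  }
  structure(list(subjects = subj, events = events, rr = rr, power = power,
                 ground_truth = gt, config = NULL),
            class = "hrv_cohort")
}
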