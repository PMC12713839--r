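## CSV readers/writers for hypnograms, activity series and tidy result
## tables.  Files are plain CSV with a header row; dataset-level metadata
## travels in `#`-prefixed comment lines so the files stay grep-able and
## spreadsheet-friendly.

meta_line <- function(...) {
  kv <- list(...)
  paste0("# ", paste(sprintf("%s=%s", names(kv), unlist(kv)), collapse = " "))
}

parse_meta <- function(path) {
  lines <- readLines(path, n = 10)
  lines <- lines[startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    for (tok in strsplit(trimws(sub("^#", "", ln)), "\\s+")[[1]]) {
      kv <- strsplit(tok, "=", fixed = TRUE)[[1]]
      if (length(kv) == 2) out[[kv[1]]] <- kv[2]
    }
  }
  out
}

#' Write / read hypnogram CSV
#'
#' The on-disk format is a CSV with columns `epoch_index` (0-based,
#' contiguous), `zt_start` (hours) and `label` (`W`/`N`/`R`), preceded by
#' a comment line carrying epoch length, start ZT, subject metadata and
#' light schedule.
#'
#' @param hyp A [hypnogram()].
#' @param path File path.
#' @return `write_hypnogram()` returns `path` invisibly;
#'   `read_hypnogram()` returns a [hypnogram()].
#' @export
write_hypnogram <- function(hyp, path) {
  stopifnot(inherits(hyp, "hypnogram"))
  hdr <- meta_line(epoch_s = hyp$epoch_s, start_zt = hyp$start_zt,
                   subject_id = hyp$subject_id, genotype = hyp$genotype,
                   sex = hyp$sex,
                   sched = if (hyp$schedule$dd) "DD" else "LD")
  df <- data.frame(epoch_index = seq_along(hyp$labels) - 1L,
                   zt_start = round(epoch_zt(hyp), 6),
                   label = hyp$labels)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_hypnogram
#' @export
read_hypnogram <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  meta <- parse_meta(path)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("epoch_index", "zt_start", "label")
  if (!all(need %in% names(df)))
    stop("hypnogram CSV must have columns ", paste(need, collapse = ", "))
  bad <- which(!df$label %in% state_levels())
  if (length(bad))
    stop("invalid vigilance label(s) at row(s) ",
         paste(utils::head(bad, 10), collapse = ", "),
         ": ", paste(unique(df$label[utils::head(bad, 10)]), collapse = ", "))
  if (!identical(as.integer(df$epoch_index), seq_len(nrow(df)) - 1L)) {
    gaps <- which(diff(df$epoch_index) != 1)
    stop("epoch_index must be contiguous from 0; problem near row(s) ",
         paste(utils::head(gaps + 1, 10), collapse = ", "))
  }
  hypnogram(df$label,
            epoch_s = as.numeric(meta$epoch_s %||% 10),
            start_zt = as.numeric(meta$start_zt %||% df$zt_start[1]),
            subject_id = meta$subject_id %||% "s1",
            genotype = meta$genotype %||% "WT",
            sex = meta$sex %||% "M",
            schedule = light_schedule(dd = identical(meta$sched, "DD")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read activity CSV
#'
#' Columns are `timestamp` (hours since recording start) and `counts`;
#' bin width, start ZT and light schedule travel in a comment line.
#'
#' @param act An [activity_series()].
#' @param path File path.
#' @return `write_activity()` returns `path` invisibly;
#'   `read_activity()` returns an [activity_series()].
#' @export
write_activity <- function(act, path) {
  stopifnot(inherits(act, "activity_series"))
  hdr <- meta_line(bin_min = act$bin_min, start_zt = act$start_zt,
                   sched = if (act$schedule$dd) "DD" else "LD")
  df <- data.frame(timestamp = round((seq_along(act$counts) - 1) *
                                       act$bin_min / 60, 6),
                   counts = act$counts)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_activity
#' @export
read_activity <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  meta <- parse_meta(path)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("timestamp", "counts") %in% names(df)))
    stop("activity CSV must have columns timestamp, counts")
  bad <- which(df$counts < 0)
  if (length(bad))
    stop("negative counts at row(s) ",
         paste(utils::head(bad, 10), collapse = ", "))
  activity_series(df$counts,
                  bin_min = as.numeric(meta$bin_min %||% 1),
                  start_zt = as.numeric(meta$start_zt %||% 0),
                  schedule = light_schedule(dd = identical(meta$sched, "DD")))
}

#' Re-bin an activity series to wider bins
#'
#' Sums counts over consecutive bins; the new width must be a multiple of
#' the old and divide 60.  A trailing partial bin is dropped with a
#' warning.
#'
#' @param act An [activity_series()].
#' @param bin_min Target bin width in minutes.
#' @return An [activity_series()] at the new resolution.
#' @export
rebin_activity <- function(act, bin_min) {
  stopifnot(inherits(act, "activity_series"))
  k <- bin_min / act$bin_min
  if (k != round(k) || k < 1)
    stop("target bin width must be a multiple of the current width")
  k <- as.integer(k)
  n <- length(act$counts) %/% k
  if (n * k < length(act$counts))
    warning("dropping trailing partial bin")
  counts <- colSums(matrix(act$counts[seq_len(n * k)], nrow = k))
  activity_series(counts, bin_min = bin_min, start_zt = act$start_zt,
                  schedule = act$schedule)
}
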