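#' Write / read the canonical subject container
#'
#' A subject is stored as two files sharing a stem: `<stem>.tsv`, the
#' regions x samples data matrix (tab-separated, no header, full float64
#' precision), and `<stem>.json`, a sidecar carrying `fs`, `subject_id`,
#' `group`, `region_labels`, `epochs`, `events` and `symptom_score`.
#' `read_subject(write_subject(x))` reproduces the recording bitwise.
#'
#' @param rec a [regional_recording()].
#' @param stem file path without extension.
#' @return `write_subject` invisibly returns `stem`; `read_subject`
#'   returns the recording.
#' @export
write_subject <- function(rec, stem) {
  stopifnot(inherits(rec, "regional_recording"))
  ## %.17g guarantees float64 round-trip through text
  lines <- vapply(seq_len(nrow(rec$data)), function(i)
    paste(sprintf("%.17g", rec$data[i, ]), collapse = "\t"), "")
  writeLines(lines, paste0(stem, ".tsv"))
  meta <- list(subject_id = rec$subject_id, group = rec$group,
               fs = rec$fs, region_labels = rec$region_labels,
               epochs = unname(apply(rec$epochs, 1, as.list)),
               events = rec$events, symptom_score = rec$symptom_score)
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(stem)
}

#' @rdname write_subject
#' @export
read_subject <- function(stem) {
  tsv <- paste0(stem, ".tsv"); js <- paste0(stem, ".json")
  if (!file.exists(tsv)) stop("missing data file: ", tsv)
  if (!file.exists(js)) stop("missing sidecar: ", js)
  meta <- jsonlite::read_json(js, simplifyVector = TRUE)
  for (field in c("fs", "subject_id", "region_labels"))
    if (is.null(meta[[field]]))
      stop("sidecar missing required attribute: ", field)
  X <- as.matrix(data.table::fread(tsv, sep = "\t", header = FALSE))
  dimnames(X) <- NULL
  if (nrow(X) != length(meta$region_labels))
    stop("label count (", length(meta$region_labels),
         ") does not match data rows (", nrow(X), ")")
  epochs <- if (!is.null(meta$epochs) && length(meta$epochs))
    matrix(as.integer(unlist(meta$epochs)), ncol = 2, byrow = TRUE,
           dimnames = list(NULL, c("start", "end"))) else NULL
  regional_recording(X, fs = as.numeric(meta$fs),
                     region_labels = meta$region_labels,
                     subject_id = meta$subject_id,
                     group = meta$group %||% NA_character_,
                     epochs = epochs,
                     events = if (length(meta$events))
                       as.integer(meta$events),
                     symptom_score = if (!is.null(meta$symptom_score))
                       as.numeric(meta$symptom_score))
}

#' Export burst visits as a run-length TSV
#'
#' Columns `region_label`, `start_sample`, `end_sample` (half-open).
#' @param trains list of `burst_train`.
#' @param path output file.
#' @return invisibly, the written data frame.
#' @export
write_visits_tsv <- function(trains, path) {
  rows <- lapply(trains, function(tr) {
    if (nrow(tr$visits) == 0) return(NULL)
    data.frame(region_label = tr$region_id,
               start_sample = tr$visits[, "start"],
               end_sample = tr$visits[, "end"])
  })
  out <- do.call(rbind, rows) %||%
    data.frame(region_label = character(), start_sample = integer(),
               end_sample = integer())
  data.table::fwrite(out, path, sep = "\t")
  invisible(out)
}

#' Export a connectome as a square CSV with label header row and column
#'
#' @param c a `connectome`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_connectome_csv <- function(c, path) {
  stopifnot(inherits(c, "connectome"))
  df <- data.frame(region = c$labels, c$J, check.names = FALSE)
  data.table::fwrite(df, path, sep = ",")
  invisible(path)
}

#' Tidy per-subject metric table from burst summaries
#'
#' @param global_list named list (subject id -> [global_collapse()]
#'   output).
#' @param groups named character vector of group labels.
#' @return data frame `subject`, `group`, `metric`, `value`.
#' @export
metric_table <- function(global_list, groups) {
  rows <- lapply(names(global_list), function(s) {
    g <- global_list[[s]]
    keep <- setdiff(names(g), "n_excluded_amplitude")
    data.frame(subject = s, group = unname(groups[s]), metric = keep,
               value = unlist(g[keep]), row.names = NULL,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
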