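# File adapters: BIDS-style events tables, run matrices with JSON sidecars,
# ROI label files, and tidy result tables.

na_to_token <- function(x) ifelse(is.na(x), "n/a", as.character(x))
token_to_na <- function(x) ifelse(x == "n/a", NA, x)

#' Write a run schedule as a BIDS-style events table
#'
#' Tab-separated with columns `onset`, `duration`, `trial_type`, `trial`,
#' `condition`, `target`, `distractor`, `exemplar`, `probe_match`; missing
#' values are written as `n/a`.
#'
#' @param schedule A `vwm_schedule`.
#' @param path Output path (conventionally `*_events.tsv`).
#' @return `path`, invisibly.
#' @export
write_events_tsv <- function(schedule, path) {
  df <- as.data.frame(schedule)
  for (nm in names(df)) df[[nm]] <- na_to_token(df[[nm]])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BIDS-style events table written by [write_events_tsv()]
#'
#' @param path Input path.
#' @param tr_seconds TR to attach (default 0.8).
#' @return A `vwm_schedule`.
#' @export
read_events_tsv <- function(path, tr_seconds = 0.8) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE)
  need <- c("onset", "duration", "trial_type")
  if (!all(need %in% names(df))) {
    stopf("malformed events file %s: missing columns %s", path,
          paste(setdiff(need, names(df)), collapse = ", "))
  }
  for (nm in names(df)) df[[nm]] <- token_to_na(df[[nm]])
  num <- intersect(c("onset", "duration"), names(df))
  for (nm in num) df[[nm]] <- as.numeric(df[[nm]])
  for (nm in intersect(c("trial", "condition", "exemplar"), names(df))) {
    df[[nm]] <- as.integer(df[[nm]])
  }
  if ("probe_match" %in% names(df)) df$probe_match <- as.logical(df$probe_match)
  structure(df, tr_seconds = tr_seconds, class = c("vwm_schedule", "data.frame"))
}

#' Write a run matrix with a JSON sidecar
#'
#' The matrix is stored as little-endian doubles in column-major (TR-major)
#' order; the sidecar (same path with `.json` in place of `.dat`) records
#' participant, session, run, TR, and dimensions.
#'
#' @param run A `vwm_run` or matrix (vertices x TRs).
#' @param path Output path ending in `.dat`.
#' @param participant,session,run_index Identifiers for the sidecar.
#' @return `path`, invisibly.
#' @export
write_run_matrix <- function(run, path, participant = "sub-01", session = 1L,
                             run_index = 1L) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.vector(unclass(run)), con, size = 8L, endian = "little")
  meta <- list(participant = participant, session = session, run = run_index,
               tr_seconds = attr(run, "tr_seconds") %||% 0.8,
               n_vertices = nrow(run), n_trs = ncol(run))
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

sidecar_path <- function(path) sub("\\.dat$", ".json", path)

#' Read a run matrix written by [write_run_matrix()]
#'
#' @param path Path to the `.dat` file.
#' @param expect_tr If non-`NULL`, error unless the sidecar TR matches.
#' @param expect_vertices If non-`NULL`, error unless the vertex count
#'   matches.
#' @return A `vwm_run` matrix with sidecar metadata attached as `meta`.
#' @export
read_run_matrix <- function(path, expect_tr = NULL, expect_vertices = NULL) {
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  if (!is.null(expect_tr) && abs(meta$tr_seconds - expect_tr) > 1e-9) {
    stopf("TR mismatch in %s: sidecar says %g, expected %g", path,
          meta$tr_seconds, expect_tr)
  }
  if (!is.null(expect_vertices) && meta$n_vertices != expect_vertices) {
    stopf("vertex-count mismatch in %s: sidecar says %d, expected %d", path,
          meta$n_vertices, expect_vertices)
  }
  n <- meta$n_vertices * meta$n_trs
  con <- file(path, "rb")
  on.exit(close(con))
  x <- readBin(con, "double", n = n, size = 8L, endian = "little")
  if (length(x) != n) stopf("truncated run matrix %s", path)
  structure(matrix(x, meta$n_vertices, meta$n_trs),
            tr_seconds = meta$tr_seconds, meta = meta, class = "vwm_run")
}

#' Write an ROI label file
#'
#' Newline-delimited 1-based vertex indices preceded by a sector tag header
#' (`# sector: <name>`).
#'
#' @param vertices Integer vertex indices.
#' @param path Output path.
#' @param sector Sector tag (`NA` allowed).
#' @return `path`, invisibly.
#' @export
write_roi_file <- function(vertices, path, sector = NA_character_) {
  writeLines(c(sprintf("# sector: %s", ifelse(is.na(sector), "none", sector)),
               as.character(as.integer(vertices))), path)
  invisible(path)
}

#' Read an ROI label file
#'
#' @param path Input path.
#' @param n_vertices If non-`NULL`, error when any index falls outside
#'   `1..n_vertices`.
#' @return Integer vector with attribute `sector`.
#' @export
read_roi_file <- function(path, n_vertices = NULL) {
  ln <- readLines(path)
  if (length(ln) == 0L || !grepl("^# sector:", ln[1L])) {
    stopf("malformed ROI file %s: missing '# sector:' header", path)
  }
  sector <- trimws(sub("^# sector:", "", ln[1L]))
  if (sector == "none") sector <- NA_character_
  idx <- as.integer(ln[-1L])
  if (anyNA(idx)) stopf("malformed ROI file %s: non-integer vertex index", path)
  if (!is.null(n_vertices) && any(idx < 1L | idx > n_vertices)) {
    stopf("ROI file %s references vertices outside 1..%d", path, n_vertices)
  }
  structure(idx, sector = sector)
}

write_tidy_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
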