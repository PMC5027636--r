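#' Read a raw Ct study from three CSV files
#'
#' Reads the canonical export layout: a Ct matrix CSV (wells as rows, targets
#' as columns, first column `well_id`), a well-metadata CSV and a
#' target-metadata CSV. Sentinel entries (`999`, `Undetermined`, empty) are
#' mapped to `NA` (undetected).
#'
#' @param path Ct matrix CSV.
#' @param well_meta_path well metadata CSV with columns `well_id`,
#'   `sample_type`, `time_point_hr`, `n_cells_captured`, `dilution_quantity`.
#' @param target_meta_path target metadata CSV with columns `target_id`,
#'   `analyte`, `gene`.
#' @return a validated [ct_table()].
#' @export
read_ct_table <- function(path, well_meta_path, target_meta_path) {
  for (p in c(path, well_meta_path, target_meta_path)) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (!ncol(raw) >= 2) stop("Ct matrix must have well_id plus >= 1 target column",
                            call. = FALSE)
  well_ids <- as.character(raw[[1]])
  target_ids <- colnames(raw)[-1]
  ct <- matrix(NA_real_, nrow(raw), length(target_ids),
               dimnames = list(well_ids, target_ids))
  for (j in seq_along(target_ids)) {
    ct[, j] <- parse_ct_column(raw[[j + 1]], target_ids[j], well_ids)
  }
  wells <- utils::read.csv(well_meta_path, stringsAsFactors = FALSE)
  targets <- utils::read.csv(target_meta_path, stringsAsFactors = FALSE)
  miss_w <- setdiff(well_ids, wells$well_id)
  if (length(miss_w)) {
    stop("well(s) in Ct matrix missing from metadata: ",
         paste(miss_w, collapse = ", "), call. = FALSE)
  }
  miss_t <- setdiff(target_ids, targets$target_id)
  if (length(miss_t)) {
    stop("target(s) in Ct matrix missing from metadata: ",
         paste(miss_t, collapse = ", "), call. = FALSE)
  }
  wells <- wells[match(well_ids, wells$well_id), , drop = FALSE]
  targets <- targets[match(target_ids, targets$target_id), , drop = FALSE]
  ct_table(ct, wells, targets)
}

SENTINELS <- c("999", "999.0", "Undetermined", "undetermined", "NA", "")

parse_ct_column <- function(txt, target_id, well_ids) {
  txt <- trimws(txt)
  out <- rep(NA_real_, length(txt))
  is_sent <- txt %in% SENTINELS
  num <- suppressWarnings(as.numeric(txt[!is_sent]))
  bad <- which(!is_sent)[is.na(num)]
  if (length(bad)) {
    stop(sprintf("non-numeric Ct value '%s' at well %s, target %s",
                 txt[bad[1]], well_ids[bad[1]], target_id), call. = FALSE)
  }
  out[!is_sent] <- num
  # instrument ceilings at/above 999 count as undetected too
  out[!is.na(out) & out >= 999] <- NA_real_
  out
}

#' Write a result table to CSV
#'
#' Writes any of the pipeline's tabular results with a header row and a
#' deterministic column order; `CtTable` matrices encode undetected as 999,
#' `DeltaCtTable` matrices round-trip exactly at 6-decimal formatting.
#'
#' @param table a `CtTable`, `DeltaCtTable`, matrix or data.frame.
#' @param path output CSV path.
#' @export
write_table <- function(table, path) UseMethod("write_table")

#' @export
write_table.data.frame <- function(table, path) {
  if (nrow(table) == 0L) stop("refusing to write an empty table", call. = FALSE)
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
write_table.matrix <- function(table, path) {
  if (length(table) == 0L) stop("refusing to write an empty table", call. = FALSE)
  df <- data.frame(well_id = rownames(table), table, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
write_table.CtTable <- function(table, path) {
  m <- table$ct
  m[is.na(m)] <- 999
  write_table.matrix(m, path)
}

#' @export
write_table.DeltaCtTable <- function(table, path) {
  write_table.matrix(table$dct, path)
}

#' Read a delta-Ct matrix written by [write_table()]
#'
#' @param path delta-Ct CSV (wells as rows, first column `well_id`).
#' @param wells,targets metadata data.frames as for [delta_ct_table()].
#' @return a [delta_ct_table()].
#' @export
read_delta_ct_table <- function(path, wells, targets) {
  raw <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(raw[, -1, drop = FALSE])
  rownames(m) <- as.character(raw[[1]])
  delta_ct_table(m, wells, targets)
}

#' Write a full Ct study (matrix plus both metadata tables)
#'
#' @param table a `CtTable`.
#' @param dir output directory; `ct.csv`, `wells.csv`, `targets.csv` are
#'   written inside it.
#' @return the directory, invisibly.
#' @export
write_ct_study <- function(table, dir) {
  stopifnot(inherits(table, "CtTable"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_table(table, file.path(dir, "ct.csv"))
  write_table(table$wells, file.path(dir, "wells.csv"))
  write_table(table$targets[, c("target_id", "analyte", "gene")],
              file.path(dir, "targets.csv"))
  invisible(dir)
}
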