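#' Raw cycle-threshold table
#'
#' Container for a wells x assays matrix of qPCR cycle-threshold (Ct) values
#' together with well and target metadata. Undetected reactions (no
#' amplification; instrument exports of 999 or "Undetermined") are stored as
#' `NA` so that sentinels can never leak into arithmetic.
#'
#' @param ct numeric matrix, wells x targets, `NA` for undetected. Row names
#'   are well ids and column names target ids; if absent they are taken from
#'   the metadata.
#' @param wells data.frame with columns `well_id`, `sample_type` (one of
#'   `"CELL"`, `"ZERO_CELL"`, `"LYSIS_BUFFER"`, `"DILUTION"`),
#'   `time_point_hr` (nonnegative or `NA`), `n_cells_captured`,
#'   `dilution_quantity` (positive or `NA`).
#' @param targets data.frame with columns `target_id`, `analyte` (`"RNA"` or
#'   `"PROTEIN"`) and `gene`; an optional logical `reliable` column is added
#'   (all `NA`) when missing.
#' @return An object of class `CtTable`: a list with elements `ct`, `wells`,
#'   `targets`.
#' @export
ct_table <- function(ct, wells, targets) {
  wells <- validate_well_meta(wells)
  targets <- validate_target_meta(targets)
  ct <- as.matrix(ct)
  storage.mode(ct) <- "double"
  if (nrow(ct) != nrow(wells)) {
    stop("Ct matrix has ", nrow(ct), " rows but well metadata describes ",
         nrow(wells), " wells", call. = FALSE)
  }
  if (ncol(ct) != nrow(targets)) {
    stop("Ct matrix has ", ncol(ct), " columns but target metadata describes ",
         nrow(targets), " targets", call. = FALSE)
  }
  if (is.null(rownames(ct))) rownames(ct) <- wells$well_id
  if (is.null(colnames(ct))) colnames(ct) <- targets$target_id
  if (!identical(rownames(ct), wells$well_id)) {
    stop("Ct matrix row names do not match well metadata well_id order",
         call. = FALSE)
  }
  if (!identical(colnames(ct), targets$target_id)) {
    stop("Ct matrix column names do not match target metadata target_id order",
         call. = FALSE)
  }
  if (any(ct <= 0, na.rm = TRUE)) {
    stop("Ct values must be positive (undetected is NA, not 0)", call. = FALSE)
  }
  structure(list(ct = ct, wells = wells, targets = targets),
            class = "CtTable")
}

#' Normalized delta-Ct table
#'
#' Container for a wells x targets matrix of nonnegative delta-Ct values on
#' the log2 expression scale; 0 encodes undetected (or at/below background
#' for protein targets).
#'
#' @param dct numeric matrix of delta-Ct values, all `>= 0`.
#' @inheritParams ct_table
#' @return An object of class `DeltaCtTable`.
#' @export
delta_ct_table <- function(dct, wells, targets) {
  wells <- validate_well_meta(wells)
  targets <- validate_target_meta(targets)
  dct <- as.matrix(dct)
  storage.mode(dct) <- "double"
  if (nrow(dct) != nrow(wells) || ncol(dct) != nrow(targets)) {
    stop("dct matrix dimensions do not match metadata", call. = FALSE)
  }
  if (is.null(rownames(dct))) rownames(dct) <- wells$well_id
  if (is.null(colnames(dct))) colnames(dct) <- targets$target_id
  if (anyNA(dct) || any(dct < 0)) {
    stop("delta-Ct values must be nonnegative and non-missing (0 = undetected)",
         call. = FALSE)
  }
  structure(list(dct = dct, wells = wells, targets = targets),
            class = "DeltaCtTable")
}

SAMPLE_TYPES <- c("CELL", "ZERO_CELL", "LYSIS_BUFFER", "DILUTION")
ANALYTES <- c("RNA", "PROTEIN")

validate_well_meta <- function(wells) {
  wells <- as.data.frame(wells, stringsAsFactors = FALSE)
  need <- c("well_id", "sample_type")
  miss <- setdiff(need, names(wells))
  if (length(miss)) {
    stop("well metadata missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!"time_point_hr" %in% names(wells)) wells$time_point_hr <- NA_real_
  if (!"n_cells_captured" %in% names(wells)) {
    wells$n_cells_captured <- ifelse(wells$sample_type == "CELL", 1L, 0L)
  }
  if (!"dilution_quantity" %in% names(wells)) wells$dilution_quantity <- NA_real_
  wells$well_id <- as.character(wells$well_id)
  if (anyDuplicated(wells$well_id)) {
    stop("duplicated well_id: ",
         paste(unique(wells$well_id[duplicated(wells$well_id)]), collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(wells$sample_type), SAMPLE_TYPES)
  if (length(bad)) {
    stop("unknown sample_type: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  wells$time_point_hr <- as.numeric(wells$time_point_hr)
  if (any(wells$time_point_hr < 0, na.rm = TRUE)) {
    stop("time_point_hr must be nonnegative", call. = FALSE)
  }
  wells$n_cells_captured <- as.integer(wells$n_cells_captured)
  wells$dilution_quantity <- as.numeric(wells$dilution_quantity)
  one <- wells$sample_type == "CELL" & wells$n_cells_captured != 1L
  if (any(one, na.rm = TRUE)) {
    stop("CELL wells must have n_cells_captured == 1: ",
         paste(wells$well_id[which(one)], collapse = ", "), call. = FALSE)
  }
  zero <- wells$sample_type == "ZERO_CELL" & wells$n_cells_captured != 0L
  if (any(zero, na.rm = TRUE)) {
    stop("ZERO_CELL wells must have n_cells_captured == 0: ",
         paste(wells$well_id[which(zero)], collapse = ", "), call. = FALSE)
  }
  dil <- wells$sample_type == "DILUTION" &
    (is.na(wells$dilution_quantity) | wells$dilution_quantity <= 0)
  if (any(dil)) {
    stop("DILUTION wells must carry a positive dilution_quantity: ",
         paste(wells$well_id[which(dil)], collapse = ", "), call. = FALSE)
  }
  rownames(wells) <- NULL
  wells
}

validate_target_meta <- function(targets) {
  targets <- as.data.frame(targets, stringsAsFactors = FALSE)
  need <- c("target_id", "analyte", "gene")
  miss <- setdiff(need, names(targets))
  if (length(miss)) {
    stop("target metadata missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  targets$target_id <- as.character(targets$target_id)
  if (anyDuplicated(targets$target_id)) {
    stop("duplicated target_id: ",
         paste(unique(targets$target_id[duplicated(targets$target_id)]),
               collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unique(targets$analyte), ANALYTES)
  if (length(bad)) {
    stop("unknown analyte: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  targets$gene <- as.character(targets$gene)
  if (!"reliable" %in% names(targets)) targets$reliable <- NA
  targets$reliable <- as.logical(targets$reliable)
  rownames(targets) <- NULL
  targets
}

#' @export
print.CtTable <- function(x, ...) {
  cat("CtTable:", nrow(x$ct), "wells x", ncol(x$ct), "targets\n")
  cat("  sample types:",
      paste(sprintf("%s=%d", names(table(x$wells$sample_type)),
                    table(x$wells$sample_type)), collapse = ", "), "\n")
  cat("  analytes:",
      paste(sprintf("%s=%d", names(table(x$targets$analyte)),
                    table(x$targets$analyte)), collapse = ", "), "\n")
  cat("  undetected cells:", sum(is.na(x$ct)), "\n")
  invisible(x)
}

#' @export
print.DeltaCtTable <- function(x, ...) {
  cat("DeltaCtTable:", nrow(x$dct), "wells x", ncol(x$dct), "targets\n")
  cat("  detected (dct > 0):",
      sprintf("%.1f%%", 100 * mean(x$dct > 0)), "\n")
  invisible(x)
}

#' @export
dim.CtTable <- function(x) dim(x$ct)

#' @export
dim.DeltaCtTable <- function(x) dim(x$dct)

#' Subset a table by wells and/or targets
#'
#' @param x a `CtTable` or `DeltaCtTable`
#' @param wells character vector of well ids, logical or integer index
#' @param targets character vector of target ids, logical or integer index
#' @return an object of the same class restricted to the selected axes
#' @export
subset_table <- function(x, wells = NULL, targets = NULL) {
  stopifnot(inherits(x, c("CtTable", "DeltaCtTable")))
  wi <- resolve_index(wells, x$wells$well_id, "well")
  ti <- resolve_index(targets, x$targets$target_id, "target")
  m <- if (inherits(x, "CtTable")) x$ct else x$dct
  m <- m[wi, ti, drop = FALSE]
  w <- x$wells[wi, , drop = FALSE]
  rownames(w) <- NULL
  tg <- x$targets[ti, , drop = FALSE]
  rownames(tg) <- NULL
  if (inherits(x, "CtTable")) {
    structure(list(ct = m, wells = w, targets = tg), class = "CtTable")
  } else {
    structure(list(dct = m, wells = w, targets = tg), class = "DeltaCtTable")
  }
}

resolve_index <- function(idx, ids, what) {
  if (is.null(idx)) return(seq_along(ids))
  if (is.character(idx)) {
    miss <- setdiff(idx, ids)
    if (length(miss)) {
      stop("unknown ", what, " id(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    return(match(idx, ids))
  }
  seq_along(ids)[idx]
}

#' Restrict a delta-Ct table to retained single-cell wells
#'
#' @param x a `DeltaCtTable` or `CtTable`
#' @param time_point_hr optional time point to select
#' @return same class, CELL wells only (optionally one time point)
#' @export
cells_only <- function(x, time_point_hr = NULL) {
  keep <- x$wells$sample_type == "CELL"
  if (!is.null(time_point_hr)) {
    keep <- keep & !is.na(x$wells$time_point_hr) &
      x$wells$time_point_hr == time_point_hr
  }
  subset_table(x, wells = keep)
}

#' Combine two tables over the same wells
#'
#' Joins the target axes of two `DeltaCtTable`s (or `CtTable`s) that share an
#' identical well axis — typically the RNA and protein delta-Ct tables after
#' normalization.
#'
#' @param x,y two tables of the same class with identical well metadata and
#'   disjoint target ids.
#' @return a table of the same class with the targets of both.
#' @export
combine_targets <- function(x, y) {
  stopifnot(inherits(x, c("CtTable", "DeltaCtTable")),
            class(x)[1] == class(y)[1])
  common <- intersect(x$wells$well_id, y$wells$well_id)
  if (!length(common)) stop("tables share no wells", call. = FALSE)
  x <- subset_table(x, wells = common)
  y <- subset_table(y, wells = common)
  if (length(intersect(x$targets$target_id, y$targets$target_id))) {
    stop("target ids overlap between tables", call. = FALSE)
  }
  m <- cbind(if (inherits(x, "CtTable")) x$ct else x$dct,
             if (inherits(y, "CtTable")) y$ct else y$dct)
  tg <- rbind(x$targets, y$targets)
  rownames(tg) <- NULL
  if (inherits(x, "CtTable")) ct_table(m, x$wells, tg)
  else delta_ct_table(m, x$wells, tg)
}

#' Study configuration constants
#'
#' All tunable constants of the pipeline in one validated list. Defaults are
#' the study conditions: a Ct ceiling of 24 cycles, a 35-RNA cell-culling
#' floor, detection confidence 0.01, a linear-range penalty of 0.03 per
#' removed dilution point, a 7-of-8 replicate limit-of-detection rule, 1.3
#' cell equivalents as the single-cell quantity, 10,000 permutations,
#' a correlation-edge threshold of 0.3, a trajectory-clustering cut height of
#' 0.75, and a four-fifths training fraction.
#'
#' @param ct_ceiling Ct ceiling in cycles used for RNA normalization and
#'   protein clipping.
#' @param cull_min_detected_rna minimum detected reliable RNAs per retained cell.
#' @param detection_alpha one-sided tail probability above background that
#'   defines detection.
#' @param range_cost penalty subtracted from a window's R-squared per dilution
#'   level excluded from the window.
#' @param lod_min_detected,lod_replicates detected-replicate rule defining the
#'   limit of detection.
#' @param single_cell_equivalents bulk-lysate quantity regarded as one cell.
#' @param n_permutations label permutations for null correlation distributions.
#' @param edge_rho_threshold Spearman rho above which a network edge is drawn.
#' @param trajectory_cut dendrogram cut height (1 - rho scale) partitioning
#'   gene trajectories.
#' @param train_fraction fraction of cells drawn (with replacement) as the
#'   classifier training set.
#' @param rng_seed integer seed recorded with stochastic results.
#' @return a list of class `study_config`.
#' @export
study_config <- function(ct_ceiling = 24,
                         cull_min_detected_rna = 35,
                         detection_alpha = 0.01,
                         range_cost = 0.03,
                         lod_min_detected = 7,
                         lod_replicates = 8,
                         single_cell_equivalents = 1.3,
                         n_permutations = 10000,
                         edge_rho_threshold = 0.3,
                         trajectory_cut = 0.75,
                         train_fraction = 0.8,
                         rng_seed = 1L) {
  cfg <- list(ct_ceiling = ct_ceiling,
              cull_min_detected_rna = as.integer(cull_min_detected_rna),
              detection_alpha = detection_alpha,
              range_cost = range_cost,
              lod_min_detected = as.integer(lod_min_detected),
              lod_replicates = as.integer(lod_replicates),
              single_cell_equivalents = single_cell_equivalents,
              n_permutations = as.integer(n_permutations),
              edge_rho_threshold = edge_rho_threshold,
              trajectory_cut = trajectory_cut,
              train_fraction = train_fraction,
              rng_seed = as.integer(rng_seed))
  stopifnot(cfg$ct_ceiling > 0,
            cfg$detection_alpha > 0, cfg$detection_alpha < 1,
            cfg$train_fraction > 0, cfg$train_fraction < 1,
            cfg$lod_min_detected <= cfg$lod_replicates,
            cfg$range_cost >= 0,
            cfg$n_permutations >= 1)
  class(cfg) <- "study_config"
  cfg
}
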