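#' Run the full analysis pipeline from one configuration
#'
#' Orchestrates the stages in the order normalize -> calibrate (when a
#' dilution plate is supplied) -> cull -> correlate -> gate -> network ->
#' classify -> trajectory, writing each stage's CSV outputs and a YAML
#' manifest under `out_dir`.
#'
#' The configuration is a YAML file (or an equivalent R list) with keys:
#' \describe{
#'   \item{ct, wells, targets}{paths to the three study CSVs
#'     (see [read_ct_table()]); required.}
#'   \item{dilution_ct, dilution_wells, dilution_targets}{optional dilution
#'     plate CSVs for calibration.}
#'   \item{seed_targets}{optional character vector for network growth.}
#'   \item{config}{optional overrides of [study_config()] fields.}
#' }
#'
#' @param config path to a YAML config file, or a list.
#' @param out_dir output directory.
#' @return invisibly, the manifest list (also written to
#'   `manifest.yaml`): config snapshot, input digests, per-stage outputs,
#'   seeds and package version.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  for (key in c("ct", "wells", "targets")) {
    if (is.null(config[[key]])) {
      stop("config missing required key: ", key, call. = FALSE)
    }
    if (!file.exists(config[[key]])) {
      stop("input file missing: ", config[[key]], call. = FALSE)
    }
  }
  cfg <- do.call(study_config, as.list(config$config))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = config,
                   study_config = unclass(cfg),
                   inputs = lapply(config[c("ct", "wells", "targets")],
                                   function(p) unname(tools::md5sum(p))),
                   package_version = as.character(utils::packageVersion("peasta")),
                   stages = list(), failed_stage = NULL)
  outputs <- character(0)
  stage <- function(name, fn) {
    res <- tryCatch(fn(), error = function(e) e)
    if (inherits(res, "error")) {
      manifest$failed_stage <<- name
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(res))
      write_manifest(manifest, out_dir)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(res),
           call. = FALSE)
    }
    manifest$stages[[name]] <<- list(status = "ok")
    res
  }

  ct <- stage("load", function() {
    read_ct_table(config$ct, config$wells, config$targets)
  })

  norm <- stage("normalize", function() {
    bg <- estimate_protein_background(ct, ct_ceiling = cfg$ct_ceiling)
    dct <- combine_targets(rna_delta_ct(ct, cfg$ct_ceiling),
                           protein_delta_ct(ct, bg, cfg$ct_ceiling))
    write_table(as.data.frame(bg), file.path(out_dir, "background.csv"))
    write_table(dct, file.path(out_dir, "dct.csv"))
    list(bg = bg, dct = dct)
  })
  thresholds <- detection_threshold(norm$bg, cfg$detection_alpha)
  write_table(thresholds, file.path(out_dir, "thresholds.csv"))

  calib <- NULL
  if (!is.null(config$dilution_ct)) {
    calib <- stage("calibrate", function() {
      dil <- read_ct_table(config$dilution_ct, config$dilution_wells,
                           config$dilution_targets)
      ddct <- dilution_delta_ct(dil, cfg$ct_ceiling)
      res <- calibrate_assays(
        ddct, thresholds, range_cost = cfg$range_cost,
        single_cell_equivalents = cfg$single_cell_equivalents,
        min_detected = cfg$lod_min_detected,
        replicates = cfg$lod_replicates)
      write_table(res, file.path(out_dir, "calibration.csv"))
      res
    })
  }

  culled <- stage("cull", function() {
    rna_ids <- norm$dct$targets$target_id[norm$dct$targets$analyte == "RNA"]
    if (!is.null(calib)) {
      rel <- calib$target_id[calib$reliable]
      keep <- intersect(rna_ids, rel)
      if (length(keep)) rna_ids <- keep
    }
    res <- cull_cells(norm$dct, rna_ids,
                      min_detected = cfg$cull_min_detected_rna)
    write_table(res$qc, file.path(out_dir, "qc_report.csv"))
    res
  })
  dct <- culled$dct

  stage("correlate", function() {
    recs <- paired_correlations(dct)
    write_table(recs, file.path(out_dir, "correlations.csv"))
    recs
  })

  stage("gate", function() {
    gt <- in_silico_gate_all(dct, thresholds)
    write_table(gt, file.path(out_dir, "gate_tests.csv"))
    gt
  })

  if (!is.null(config$seed_targets)) {
    stage("network", function() {
      tps <- sort(unique(dct$wells$time_point_hr[dct$wells$sample_type == "CELL"]))
      rows <- lapply(tps, function(tp) {
        net <- grow_seed_network(dct, config$seed_targets, tp,
                                 cfg$edge_rho_threshold)
        if (nrow(net$edges)) cbind(time_point_hr = tp, net$edges)
        else NULL
      })
      edges <- do.call(rbind, rows)
      if (!is.null(edges) && nrow(edges)) {
        write_table(edges, file.path(out_dir, "network_edges.csv"))
      }
      edges
    })
  }

  stage("classify", function() {
    prot <- dct$targets$target_id[dct$targets$analyte == "PROTEIN"]
    pca <- pca_standardized(dct, prot)
    ev <- rf_timepoint_classifier(pca, train_fraction = cfg$train_fraction,
                                  seed = cfg$rng_seed)
    write_table(data.frame(class = names(ev$auc), auc = unname(ev$auc)),
                file.path(out_dir, "auc.csv"))
    ev
  })

  stage("trajectory", function() {
    prof <- quadrant_profiles(dct, thresholds = thresholds)
    cl <- cluster_trajectories(prof, cut_height = cfg$trajectory_cut)
    write_table(prof, file.path(out_dir, "quadrants.csv"))
    write_table(data.frame(gene = names(cl$cluster),
                           cluster = unname(cl$cluster)),
                file.path(out_dir, "trajectory_clusters.csv"))
    cl
  })

  write_manifest(manifest, out_dir)
  invisible(manifest)
}

write_manifest <- function(manifest, out_dir) {
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
}
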