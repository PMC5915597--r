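#' Read a pipeline run configuration from YAML
#'
#' The configuration names either existing inputs (`atlas_labels`,
#' `atlas_names`, `scans` directory of per-subject NIfTI files named
#' `<subject_id>.nii.gz`, `phenotypes` TSV) or a `synthetic: true` block, in
#' which case the bundled two-site demonstration cohort is simulated from
#' `seed`. Remaining keys: `roi_id`, `contrast` (two labels), `covariates`,
#' `mode` (threshold string such as `"fdr:0.05"`), `chunk_size`, `seed`,
#' `output_dir`.
#'
#' @param path YAML file.
#' @return A named list (class `run_config`).
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  defaults <- list(roi_id = 1L, contrast = c("patient", "control"),
                   covariates = c("age", "sex", "mean_fd", "education"),
                   mode = "fdr:0.05", chunk_size = 65536L, seed = 1L,
                   synthetic = FALSE, min_table_cluster_voxels = 10L,
                   n_timepoints = 120L, n_controls = 20L, n_patients = 20L,
                   delta_z = 0.25)
  for (nm in names(defaults)) if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  if (is.null(cfg$output_dir)) stop("run config needs `output_dir`", call. = FALSE)
  if (!isTRUE(cfg$synthetic)) {
    for (nm in c("atlas_labels", "atlas_names", "scans", "phenotypes")) {
      if (is.null(cfg[[nm]])) {
        stop("run config needs `", nm, "` (or synthetic: true)", call. = FALSE)
      }
      if (!file.exists(cfg[[nm]])) {
        stop("run config path does not exist: ", cfg[[nm]], call. = FALSE)
      }
    }
  }
  parse_threshold_mode(cfg$mode)  # validate early
  structure(cfg, class = "run_config")
}

#' Run the full association pipeline
#'
#' Orchestrates simulate/load, connectivity, association and clinical
#' correlation, writing every artifact under `output_dir`: the Fisher-z
#' store (`fc_store.h5`), per-voxel MA and signed-sum maps (NIfTI), the
#' cluster table and clinical correlations (TSV), a plain-text log, and a
#' machine-readable `summary.json` with subject counts, pair count, the
#' attained significance threshold, significant-link count and the top
#' cluster rows. Deterministic given the seed and inputs.
#'
#' @param cfg A [read_run_config()] list (or a named list with the same
#'   fields, validated on entry).
#' @return The summary list, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(cfg) {
  cfg <- validate_run_config(unclass(cfg))
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(cfg$output_dir, "run.log")
  cat("", file = logf)
  say <- function(stage, ...) {
    line <- paste0("[", stage, "] ", paste0(..., collapse = ""))
    cat(line, "\n", file = logf, append = TRUE, sep = "")
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      say(name, "ERROR: ", conditionMessage(e))
      stop("[", name, "] ", conditionMessage(e), call. = FALSE)
    })
  }

  inputs <- stage("input", {
    if (isTRUE(cfg$synthetic)) {
      say("input", "simulating demo cohort, seed ", cfg$seed)
      cohort <- generate_cohort(demo_config(
        seed = cfg$seed, n_controls = cfg$n_controls,
        n_patients = cfg$n_patients, n_timepoints = cfg$n_timepoints,
        delta_z = cfg$delta_z))
      cohort
    } else {
      atlas <- load_atlas(cfg$atlas_labels, cfg$atlas_names)
      ph <- read_phenotypes(cfg$phenotypes)
      scans <- lapply(ph$subject_id, function(id) {
        f <- file.path(cfg$scans, paste0(id, ".nii.gz"))
        if (!file.exists(f)) f <- file.path(cfg$scans, paste0(id, ".nii"))
        load_scan(f, atlas, id)
      })
      say("input", nrow(ph), " subjects loaded")
      list(atlas = atlas, scans = scans, phenotypes = ph)
    }
  })

  store <- stage("fc", {
    pairs <- enumerate_pairs(inputs$atlas, cfg$roi_id)
    say("fc", nrow(pairs), " voxel pairs, chunk size ", cfg$chunk_size)
    st <- compute_fc_store(inputs$scans, pairs, cfg$chunk_size)
    if (length(st$zero_variance)) {
      say("fc", "zero-variance voxels in ",
          length(st$zero_variance), " subject(s); pairs excluded")
    }
    write_fc_store(st, file.path(cfg$output_dir, "fc_store.h5"))
    st
  })

  result <- stage("associate", {
    res <- associate(store, inputs$phenotypes, inputs$atlas,
                     contrast = cfg$contrast, covariates = cfg$covariates,
                     mode = cfg$mode,
                     min_table_cluster_voxels = cfg$min_table_cluster_voxels)
    say("associate", sum(res$links$significant), " significant links at ",
        format(res$mode), "; attained p cutoff ",
        format(res$threshold, digits = 4))
    write_voxel_map(res$voxels$ma, inputs$atlas,
                    file.path(cfg$output_dir, "ma.nii.gz"))
    write_voxel_map(res$voxels$s * ifelse(res$voxels$sign < 0, -1, 1),
                    inputs$atlas,
                    file.path(cfg$output_dir, "signed_sum_z.nii.gz"))
    readr::write_tsv(
      dplyr::select(res$clusters, -"voxels"),
      file.path(cfg$output_dir, "clusters.tsv"))
    res
  })

  clinical <- stage("correlate", {
    if (nrow(result$clusters)) {
      prof <- roiwise_mean_fc(store, result)
      cc <- clinical_correlates(prof, inputs$phenotypes)
      write_clinical_correlates(cc, file.path(cfg$output_dir, "clinical.tsv"))
      say("correlate", nrow(cc), " cluster x score x site rows")
      cc
    } else {
      say("correlate", "no clusters; skipped")
      NULL
    }
  })

  summary <- stage("report", {
    ph <- inputs$phenotypes
    counts <- dplyr::count(ph, .data$site, .data$group)
    top <- utils::head(dplyr::select(result$clusters, -"voxels"), 5)
    s <- list(
      seed = cfg$seed,
      subjects = stats::setNames(
        lapply(split(counts, counts$site),
               function(d) stats::setNames(as.list(d$n), d$group)), unique(counts$site)),
      n_pairs = nrow(result$links),
      mode = format(result$mode),
      threshold_attained = result$threshold,
      n_significant_links = sum(result$links$significant),
      top_clusters = top
    )
    jsonlite::write_json(s, file.path(cfg$output_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    s
  })
  invisible(list(summary = summary, result = result, clinical = clinical,
                 store = store, inputs = inputs))
}
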