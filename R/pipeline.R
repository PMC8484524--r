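#' Pipeline run configuration
#'
#' Bundles every stage parameter with its default: 10 discarded volumes,
#' 0.01-0.08 Hz band, 6 mm FWHM, 3 mm / 3 degree motion limits, 40-TR windows
#' in steps of 2, 1000 permutations and the 20-voxel (ANCOVA) / "> 9 voxel"
#' (post-hoc) extent rules. Any field can be overridden; the configuration is
#' serialised verbatim into the run manifest.
#'
#' @param design A [cohort_design()] (default: the scaled-down design).
#' @param discard Leading volumes to drop.
#' @param band Passband in Hz.
#' @param fwhm Smoothing FWHM in mm.
#' @param motion_limits Translation (mm) and rotation (deg) exclusion limits.
#' @param width,step Sliding-window width and step in TRs.
#' @param template_nperm Permutations for the network-template stage.
#' @param template_alpha FWE alpha for the template stage.
#' @param inference An [inference_config()].
#' @param contrasts List of group pairs for post-hoc tests and classification.
#' @param domain_map Mapping of cognitive domains to raw score columns.
#' @param seed Global RNG seed for the run.
#' @return A list of class `run_config`.
#' @export
run_config <- function(design = small_cohort_design(),
                       discard = 10, band = c(0.01, 0.08), fwhm = 6,
                       motion_limits = c(3, 3), width = 40, step = 2,
                       template_nperm = 1000, template_alpha = 0.05,
                       inference = inference_config(),
                       contrasts = list(c("HC", "SCD"), c("HC", "aMCI"),
                                        c("SCD", "aMCI")),
                       domain_map = list(EM = "EM", EF = "EF",
                                         IPS = "IPS", VF = "VF"),
                       seed = 1L) {
  stopifnot(discard >= 0, band[1] < band[2], fwhm >= 0, width >= 2, step >= 1)
  if (design$n_volumes - discard < width)
    stop("retained volumes do not cover one window")
  structure(list(design = design, discard = discard, band = band, fwhm = fwhm,
                 motion_limits = motion_limits, width = width, step = step,
                 template_nperm = template_nperm, template_alpha = template_alpha,
                 inference = inference, contrasts = contrasts,
                 domain_map = domain_map, seed = as.integer(seed)),
            class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Scalar stage parameters may be overridden from a YAML file; the `design`
#' section (if present) is passed to [small_cohort_design()] or
#' [cohort_design()] according to its `scale` field.
#'
#' @param path YAML file path.
#' @return A [run_config()].
#' @export
load_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  design <- NULL
  if (!is.null(y$design)) {
    scale <- y$design$scale %||% "small"
    args <- y$design[setdiff(names(y$design), "scale")]
    design <- if (identical(scale, "full")) do.call(cohort_design, args)
      else do.call(small_cohort_design, args)
    y$design <- NULL
  }
  if (!is.null(y$inference)) {
    y$inference <- do.call(inference_config, y$inference)
  }
  args <- y[names(y) %in% names(formals(run_config))]
  if (!is.null(design)) args$design <- design
  do.call(run_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full synthetic-cohort analysis pipeline
#'
#' Executes simulate, preprocess, network templates, DFC variability, group
#' inference (ANCOVA + post-hoc contrasts per network), brain-behavior
#' correlation and diagnostic classification, writing stage outputs and a
#' manifest under `out_dir`. No stage reads the generator's ground truth.
#'
#' @param config A [run_config()].
#' @param out_dir Run directory (created if needed).
#' @param write_dataset Also write the raw synthetic dataset (NIfTI + motion
#'   tables) under `out_dir/dataset`? Default FALSE.
#' @return Invisibly, a list with all stage results and the `manifest`.
#' @export
run_pipeline <- function(config, out_dir = tempfile("tripledfc_run_"),
                         write_dataset = FALSE) {
  stopifnot(inherits(config, "run_config"))
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop("stage [setup]: cannot create run directory")
  design <- config$design
  design$rng_seed <- config$seed
  masks <- tissue_masks(design)

  ## stage: simulate
  sim <- simulate_cohort(design,
                         out_dir = if (write_dataset) file.path(out_dir, "dataset") else NULL,
                         keep_data = TRUE)
  cohort <- sim$cohort

  ## stage: preprocess (motion exclusion, then the fixed pipeline)
  excluded <- vapply(sim$subjects, function(s)
    exclude_by_motion(s$motion, config$motion_limits[1], config$motion_limits[2]),
    logical(1))
  keep <- which(!excluded)
  if (length(keep) < 6) stop("stage [preprocess]: fewer than 6 subjects retained")
  pp <- lapply(keep, function(i)
    preprocess_bold(sim$subjects[[i]]$bold, sim$subjects[[i]]$motion,
                    discard = config$discard, band = config$band,
                    fwhm = config$fwhm, wm_mask = masks$wm,
                    csf_mask = masks$csf))
  cohort <- cohort[keep, , drop = FALSE]
  T_ret <- n_volumes(pp[[1]])
  scheme <- make_windows(T_ret, config$width, config$step)
  hc <- which(cohort$group == "HC")

  networks <- names(design$seeds)
  net_results <- list()
  all_extract <- list()
  for (ni in seq_along(networks)) {
    net <- networks[ni]
    seed_obj <- design$seeds[[net]]
    seed_masks <- lapply(pp, function(img)
      make_seed_mask(seed_obj, dim(img$data)[1:3], img$affine))

    ## stage: templates (HC static FC, one-sample TFCE-FWE)
    zmaps <- lapply(hc, function(i)
      static_fc_zmap(pp[[i]], seed_timeseries(pp[[i]], seed_masks[[i]]),
                     mask = masks$gm))
    template <- one_sample_template(zmaps, mask = masks$gm,
                                    n_perm = config$template_nperm,
                                    alpha = config$template_alpha,
                                    seed = config$seed + 1000L + ni)
    write_map(template, design$affine,
              file.path(out_dir, sprintf("template_%s.nii.gz", net)),
              sidecar = attr(template, "provenance"))
    res <- list(template_voxels = sum(template))
    if (!any(template)) {
      net_results[[net]] <- c(res, list(note = "empty template; network skipped"))
      next
    }

    ## stage: dfc (per-subject variability maps)
    varmaps <- lapply(seq_along(pp), function(i)
      variability_map(pp[[i]], seed_masks[[i]], scheme, mask = masks$gm))

    ## stage: inference
    dmx <- design_matrix(cohort)
    ancova <- permutation_cluster_threshold(varmaps, dmx, template,
                                            design$affine, config$inference,
                                            seed = config$seed + 2000L + ni)
    write_map(ancova$f_map, design$affine,
              file.path(out_dir, sprintf("ancova_F_%s.nii.gz", net)))
    res$ancova <- ancova$clusters
    posthoc <- list()
    if (any(ancova$cluster_mask)) {
      for (ci in seq_along(config$contrasts)) {
        pair <- config$contrasts[[ci]]
        ph <- posthoc_pairwise(varmaps, cohort, pair, ancova$cluster_mask,
                               design$affine, config$inference,
                               seed = config$seed + 3000L + 10L * ni + ci)
        key <- paste(pair, collapse = "_vs_")
        posthoc[[key]] <- ph$clusters
        if (nrow(ph$clusters) > 0) {
          ext <- extract_cluster_means(varmaps, ph$labels)
          names(ext) <- paste(net, key, names(ext), sep = ".")
          all_extract[[length(all_extract) + 1]] <- ext
        }
      }
    }
    res$posthoc <- posthoc
    net_results[[net]] <- res
  }

  ## stage: behavior
  composites <- composite_z(cohort, config$domain_map,
                            ref_rows = cohort$group == "HC")
  behavior <- NULL
  extracts <- if (length(all_extract)) do.call(cbind, all_extract) else NULL
  if (!is.null(extracts)) {
    patients <- cohort$group %in% c("SCD", "aMCI")
    covs <- cbind(age = cohort$age, sex = cohort$sex, education = cohort$education)
    behavior <- behavior_correlations(extracts[patients, , drop = FALSE],
                                      composites[patients, , drop = FALSE],
                                      covs[patients, , drop = FALSE])
    write.table(behavior, file.path(out_dir, "behavior_correlations.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  ## stage: classify
  cls_data <- cbind(cohort["group"], composites)
  if (!is.null(extracts)) cls_data <- cbind(cls_data, extracts)
  predictors <- setdiff(names(cls_data), "group")
  names(cls_data) <- make.names(names(cls_data))
  predictors <- make.names(predictors)
  classification <- lapply(config$contrasts, function(pair) {
    set.seed(config$seed + 4000L)
    classify_contrast(cls_data, pair, predictors)
  })
  names(classification) <- vapply(config$contrasts, paste, "", collapse = "_vs_")

  manifest <- list(
    package_version = as.character(packageVersion("tripledfc")),
    seed = config$seed,
    parameters = list(discard = config$discard, band = config$band,
                      fwhm = config$fwhm, width = config$width,
                      step = config$step, n_windows = scheme$n_windows,
                      template_nperm = config$template_nperm,
                      inference_nperm = config$inference$n_perm),
    n_subjects = nrow(cohort), n_excluded = sum(excluded),
    group_sizes = as.list(table(cohort$group)),
    templates = lapply(net_results, `[[`, "template_voxels"),
    ancova_clusters = lapply(net_results, function(r)
      if (!is.null(r$ancova)) r$ancova else NULL),
    posthoc_clusters = lapply(net_results, function(r) r$posthoc),
    behavior = behavior,
    auc = lapply(classification, function(cl) cl$multivariable$roc$auc))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(list(cohort = cohort, scheme = scheme, networks = net_results,
                 composites = composites, extracts = extracts,
                 behavior = behavior, classification = classification,
                 manifest = manifest, out_dir = out_dir))
}
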