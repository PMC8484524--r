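#' Synthetic cohort design
#'
#' Generating conditions for a fully synthetic three-group resting-state
#' cohort with known ground-truth static and dynamic coupling. Defaults match
#' the cohort the analysis targets: 58/44/49 subjects (HC/SCD/aMCI), 8-minute
#' runs of 240 volumes at TR = 2 s on a 3 mm MNI-like grid, four seed-driven
#' networks whose seed-target coupling `c(t) = mu + A * m(t)` fluctuates under
#' a two-state Markov modulator `m(t)` (mean dwell 40 s), group-dependent
#' fluctuation amplitudes `A` in designated target regions, and cognitive
#' domain scores generated as linear functions of the subject's injected
#' ECN-target amplitude (negative coupling for EM/EF).
#'
#' @param group_sizes Named counts per group.
#' @param n_volumes Volumes per run.
#' @param tr Repetition time, seconds.
#' @param grid_shape Grid dimensions.
#' @param voxel_size_mm Isotropic voxel edge, mm.
#' @param affine Voxel-to-mm affine; default is the 3 mm MNI-like affine for
#'   the default grid, or a centred affine otherwise.
#' @param seeds Named list of [seed_spec()] network generators.
#' @param regions Named list of [seed_spec()]-style target regions, one per
#'   network (names must match `seeds`).
#' @param effect_table Data frame `(group, network, mu, amplitude)`: static
#'   coupling mean and fluctuation amplitude per group and target region.
#' @param noise_sd Thermal noise standard deviation.
#' @param motion_sd Random-walk step sd of the simulated motion (mm / deg).
#' @param motion_bound Reflecting bound on simulated motion.
#' @param modulator `"markov"` (two-state +/-1 switching) or `"sinusoid"`.
#' @param dwell_s Mean dwell time of the modulator, seconds.
#' @param hrf Convolve latent signals with a canonical double-gamma HRF?
#' @param amp_jitter_sd Log-normal sd of the per-subject amplitude jitter.
#' @param cog_region Network whose target amplitude drives cognition.
#' @param cog_base,cog_coef,cog_noise_sd Generating model of the four raw
#'   domain scores: `score = base + coef * A_subject + N(0, noise)`.
#' @param discard Leading volumes the downstream pipeline will drop (used for
#'   the window-feasibility invariant).
#' @param window_width Downstream window width (for the same invariant).
#' @param rng_seed Integer seed making the whole cohort reproducible.
#' @return A list of class `cohort_design`.
#' @export
cohort_design <- function(group_sizes = c(HC = 58, SCD = 44, aMCI = 49),
                          n_volumes = 240, tr = 2.0,
                          grid_shape = c(61, 73, 61), voxel_size_mm = 3,
                          affine = NULL,
                          seeds = default_seeds(),
                          regions = default_target_regions(),
                          effect_table = default_effect_table(),
                          noise_sd = 1, motion_sd = 0.05, motion_bound = 2.5,
                          modulator = c("markov", "sinusoid"), dwell_s = 40,
                          hrf = FALSE, amp_jitter_sd = 0.1,
                          cog_region = "ECN",
                          cog_base = c(EM = 0.5, EF = 0.5, IPS = 0.3, VF = 0.3),
                          cog_coef = c(EM = -1.6, EF = -1.3, IPS = -0.6, VF = -0.4),
                          cog_noise_sd = 0.3,
                          discard = 10, window_width = 40,
                          rng_seed = 42L) {
  modulator <- match.arg(modulator)
  if (any(group_sizes <= 0)) stop("group sizes must all be positive")
  if (voxel_size_mm <= 0) stop("voxel size must be positive")
  if (n_volumes - discard < window_width)
    stop("n_volumes minus discard must cover at least one window")
  if (is.null(affine)) {
    affine <- if (identical(as.integer(grid_shape), c(61L, 73L, 61L)) &&
                  voxel_size_mm == 3) mni_affine_3mm()
      else centered_affine(grid_shape, voxel_size_mm)
  }
  stopifnot(identical(sort(names(seeds)), sort(names(regions))),
            all(effect_table$network %in% names(regions)),
            all(names(group_sizes) %in% unique(effect_table$group)) ||
              all(unique(effect_table$group) %in% names(group_sizes)))
  # every seed and target region must voxelize inside the grid
  for (s in c(seeds, regions)) make_seed_mask(s, grid_shape, affine)
  structure(list(group_sizes = group_sizes, n_volumes = n_volumes, tr = tr,
                 grid_shape = as.integer(grid_shape), voxel_size_mm = voxel_size_mm,
                 affine = affine, seeds = seeds, regions = regions,
                 effect_table = effect_table, noise_sd = noise_sd,
                 motion_sd = motion_sd, motion_bound = motion_bound,
                 modulator = modulator, dwell_s = dwell_s, hrf = hrf,
                 amp_jitter_sd = amp_jitter_sd, cog_region = cog_region,
                 cog_base = cog_base, cog_coef = cog_coef,
                 cog_noise_sd = cog_noise_sd,
                 discard = discard, window_width = window_width,
                 rng_seed = as.integer(rng_seed)),
            class = "cohort_design")
}

#' Default target regions for the four networks
#'
#' One designated 9-mm spherical target region per network, placed at
#' locations consistent with the group-effect literature the generator
#' emulates: right angular gyrus (aDMN), right middle temporal gyrus (pDMN),
#' left putamen (SN) and left inferior frontal gyrus (ECN).
#'
#' @return Named list of [seed_spec()] objects.
#' @export
default_target_regions <- function() {
  list(
    aDMN = seed_spec("R angular", c(42, -51, 24), 9, "aDMN"),
    pDMN = seed_spec("R MTG", c(60, -45, 0), 9, "pDMN"),
    SN   = seed_spec("L putamen", c(-27, 3, -3), 9, "SN"),
    ECN  = seed_spec("L IFG", c(-39, 9, 24), 9, "ECN")
  )
}

#' Default group-by-region effect table
#'
#' Static coupling mean `mu` and fluctuation amplitude `A` per group and
#' network target: aDMN variability reduced in aMCI, pDMN reduced in SCD,
#' SN elevated in SCD/aMCI, ECN elevated in aMCI (the largest injected
#' contrast, aMCI vs HC).
#'
#' @return Data frame with columns `group`, `network`, `mu`, `amplitude`.
#' @export
default_effect_table <- function() {
  data.frame(
    group = rep(c("HC", "SCD", "aMCI"), each = 4),
    network = rep(c("aDMN", "pDMN", "SN", "ECN"), times = 3),
    mu = 0.4,
    amplitude = c(0.45, 0.45, 0.10, 0.10,   # HC
                  0.40, 0.15, 0.50, 0.20,   # SCD
                  0.15, 0.40, 0.40, 0.60)   # aMCI
  )
}

#' Scaled-down design for fast tests and calibration studies
#'
#' A miniature 12^3 grid at 3 mm with the four seeds and four target regions
#' remapped to disjoint corners of the grid (radius 4 mm), and small group
#' sizes. All other generating conditions are unchanged.
#'
#' @param n_per_group Subjects per group (default 8/8/8).
#' @param n_volumes Volumes per run (default 240, as in the full design).
#' @param ... Passed on to [cohort_design()].
#' @return A `cohort_design`.
#' @export
small_cohort_design <- function(n_per_group = c(HC = 8, SCD = 8, aMCI = 8),
                                n_volumes = 240, ...) {
  seeds <- list(
    aDMN = seed_spec("vmPFC", c(-7.5, -7.5, 7.5), 4, "aDMN"),
    pDMN = seed_spec("PCC", c(7.5, -7.5, 7.5), 4, "pDMN"),
    SN   = seed_spec("rAI", c(-7.5, 7.5, 7.5), 4, "SN"),
    ECN  = seed_spec("DLPFC", c(7.5, 7.5, 7.5), 4, "ECN")
  )
  regions <- list(
    aDMN = seed_spec("aDMN target", c(-7.5, -7.5, -7.5), 4, "aDMN"),
    pDMN = seed_spec("pDMN target", c(7.5, -7.5, -7.5), 4, "pDMN"),
    SN   = seed_spec("SN target", c(-7.5, 7.5, -7.5), 4, "SN"),
    ECN  = seed_spec("ECN target", c(7.5, 7.5, -7.5), 4, "ECN")
  )
  cohort_design(group_sizes = n_per_group, n_volumes = n_volumes,
                grid_shape = c(12, 12, 12), voxel_size_mm = 3,
                seeds = seeds, regions = regions, ...)
}

# Canonical double-gamma HRF sampled at TR (peak 6 s, undershoot 16 s).
hrf_kernel <- function(tr, duration = 32) {
  t <- seq(0, duration, by = tr)
  h <- stats::dgamma(t, shape = 6, scale = 1) -
    stats::dgamma(t, shape = 16, scale = 1) / 6
  h / sum(h)
}

# Latent band-limited (0.01-0.08 Hz) unit-variance signal.
latent_signal <- function(T, tr, hrf = FALSE) {
  x <- rnorm(T)
  x <- bandpass(x, tr, 0.01, 0.08)
  if (hrf) {
    k <- hrf_kernel(tr)
    x <- stats::convolve(x, rev(k), type = "open")[seq_len(T)]
  }
  s <- sd(x)
  if (s > 0) x / s else x
}

# Two-state (+1/-1) modulator: Markov switching with per-TR switch
# probability tr/dwell_s, or a deterministic sinusoid with half-period dwell.
modulator_trace <- function(T, tr, dwell_s, kind) {
  if (kind == "sinusoid")
    return(sin(2 * pi * tr * (seq_len(T) - 1) / (2 * dwell_s)))
  p <- min(1, tr / dwell_s)
  state <- sample(c(-1, 1), 1)
  out <- numeric(T)
  for (t in seq_len(T)) {
    out[t] <- state
    if (runif(1) < p) state <- -state
  }
  out
}

#' Simulate one synthetic subject
#'
#' BOLD model: each network has a latent band-limited seed signal `s(t)` added
#' to its seed sphere; its target region receives `c(t) * s(t)` with coupling
#' `c(t) = mu + A_subj * m(t)`; every voxel receives independent Gaussian
#' noise. `A_subj` is the group amplitude with multiplicative log-normal
#' jitter. Motion is a bounded random walk in 6 parameters. The output is a
#' pure function of `(design, group, subject_seed)`.
#'
#' @param design A [cohort_design()].
#' @param group Group label (must appear in `design$group_sizes`).
#' @param subject_seed Integer seed for this subject.
#' @return List with `bold` ([bold_image()]), `motion` (T x 6 matrix) and
#'   `truth` (latent couplings, amplitudes, modulators).
#' @export
simulate_subject <- function(design, group, subject_seed) {
  if (!group %in% names(design$group_sizes)) stop("unknown group label")
  set.seed(as.integer(subject_seed))
  T <- design$n_volumes
  dims <- design$grid_shape
  nets <- names(design$seeds)

  flat <- matrix(rnorm(prod(dims) * T, sd = design$noise_sd), prod(dims), T)
  truth <- list(group = group, subject_seed = subject_seed,
                mu = numeric(0), amplitude = numeric(0),
                coupling = matrix(0, 0, T), modulator = matrix(0, 0, T))
  for (net in nets) {
    s <- latent_signal(T, design$tr, design$hrf)
    m <- modulator_trace(T, design$tr, design$dwell_s, design$modulator)
    eff <- design$effect_table[design$effect_table$group == group &
                                 design$effect_table$network == net, ]
    if (nrow(eff) != 1) stop(sprintf("effect table needs one row for (%s, %s)", group, net))
    A <- eff$amplitude * exp(rnorm(1, 0, design$amp_jitter_sd))
    c_t <- eff$mu + A * m

    seed_vox <- which(as.vector(make_seed_mask(design$seeds[[net]], dims, design$affine)))
    tgt_vox <- which(as.vector(make_seed_mask(design$regions[[net]], dims, design$affine)))
    flat[seed_vox, ] <- flat[seed_vox, ] + rep(s, each = length(seed_vox))
    flat[tgt_vox, ] <- flat[tgt_vox, ] + rep(c_t * s, each = length(tgt_vox))

    truth$mu[net] <- eff$mu
    truth$amplitude[net] <- A
    truth$coupling <- rbind(truth$coupling, c_t)
    truth$modulator <- rbind(truth$modulator, m)
  }
  rownames(truth$coupling) <- rownames(truth$modulator) <- nets
  data <- array(flat, c(dims, T))

  steps <- matrix(rnorm(T * 6, sd = design$motion_sd), T, 6)
  steps[1, ] <- 0
  motion <- apply(steps, 2, cumsum)
  motion <- pmin(pmax(motion, -design$motion_bound), design$motion_bound)

  bold <- bold_image(data, affine = design$affine, tr = design$tr)
  list(bold = bold, motion = motion, truth = truth)
}

#' Simulate a full synthetic cohort
#'
#' Draws per-subject seeds deterministically from `design$rng_seed`, simulates
#' every subject, generates demographics (identical distributions across
#' groups) and raw cognitive domain scores coupled to the subject's injected
#' amplitude in `design$cog_region`, and optionally writes the dataset to disk
#' (one NIfTI + one motion table per subject, a TSV cohort table, tissue
#' masks, and the ground truth as JSON).
#'
#' @param design A [cohort_design()].
#' @param out_dir Output directory, or `NULL` to keep everything in memory.
#' @param keep_data Keep the per-subject images in the returned list? Default
#'   `TRUE` when `out_dir` is `NULL`.
#' @return List with `cohort` (the subject table), `truth` (per-subject ground
#'   truth; never consumed by the analysis stages), `design`, and — when
#'   retained — `subjects` (list of `bold`/`motion` pairs).
#' @export
simulate_cohort <- function(design, out_dir = NULL, keep_data = is.null(out_dir)) {
  set.seed(design$rng_seed)
  N <- sum(design$group_sizes)
  subject_seeds <- sample.int(.Machine$integer.max - 1L, N)
  groups <- rep(names(design$group_sizes), design$group_sizes)
  age <- round(pmin(pmax(rnorm(N, 64, 7), 50), 85), 1)
  sex <- rbinom(N, 1, 0.6)
  education <- round(pmin(pmax(rnorm(N, 12, 2.7), 6), 20), 1)
  cog_noise <- matrix(rnorm(N * 4, 0, design$cog_noise_sd), N, 4)

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
      stop("cannot create output directory")
    write_tissue_masks(design, out_dir)
  }
  subjects <- vector("list", N)
  truth <- vector("list", N)
  scores <- matrix(NA_real_, N, 4, dimnames = list(NULL, names(design$cog_base)))
  ids <- sprintf("sub-%03d", seq_len(N))
  for (i in seq_len(N)) {
    sub <- simulate_subject(design, groups[i], subject_seeds[i])
    truth[[i]] <- sub$truth
    truth[[i]]$subject_id <- ids[i]
    A_cog <- sub$truth$amplitude[design$cog_region]
    scores[i, ] <- design$cog_base + design$cog_coef * A_cog + cog_noise[i, ]
    if (!is.null(out_dir)) {
      write_bold(sub$bold, file.path(out_dir, paste0(ids[i], "_bold.nii.gz")))
      write_motion(sub$motion, file.path(out_dir, paste0(ids[i], "_motion.txt")))
    }
    if (keep_data) subjects[[i]] <- sub[c("bold", "motion")]
  }
  cohort <- data.frame(subject_id = ids, group = groups, age = age, sex = sex,
                       education = education, scores,
                       stringsAsFactors = FALSE)
  if (!is.null(out_dir)) {
    write.table(cohort, file.path(out_dir, "cohort.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    gt <- list(design_seed = design$rng_seed,
               effect_table = design$effect_table,
               cog_coef = as.list(design$cog_coef),
               subjects = lapply(truth, function(tt)
                 list(subject_id = tt$subject_id, group = tt$group,
                      mu = as.list(tt$mu), amplitude = as.list(tt$amplitude))))
    jsonlite::write_json(gt, file.path(out_dir, "ground_truth.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  out <- list(cohort = cohort, truth = truth, design = design)
  if (keep_data) out$subjects <- subjects
  invisible(out)
}

# GM mask = whole grid minus the WM/CSF corner blocks; WM and CSF are small
# noise-only blocks at opposite grid corners (synthetic stand-ins so the
# nuisance stage has tissue signals to regress).
#' Tissue masks for a synthetic design
#'
#' @param design A [cohort_design()].
#' @return List of logical arrays: `brain`, `gm`, `wm`, `csf`.
#' @export
tissue_masks <- function(design) {
  dims <- design$grid_shape
  wm <- csf <- array(FALSE, dims)
  b <- pmin(3L, dims)
  wm[seq_len(b[1]), seq_len(b[2]), seq_len(b[3])] <- TRUE
  csf[dims[1] - seq_len(b[1]) + 1L, dims[2] - seq_len(b[2]) + 1L,
      dims[3] - seq_len(b[3]) + 1L] <- TRUE
  brain <- array(TRUE, dims)
  list(brain = brain, gm = brain & !wm & !csf, wm = wm, csf = csf)
}

write_tissue_masks <- function(design, out_dir) {
  masks <- tissue_masks(design)
  for (nm in names(masks))
    write_map(masks[[nm]], design$affine,
              file.path(out_dir, paste0("mask_", nm, ".nii.gz")))
}
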