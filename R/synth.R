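#' Construct a ROI time-series object
#'
#' Light container used throughout the pipeline: a T x N matrix of regional
#' signals plus the sampling interval (repetition time), region labels and a
#' per-volume retention mask (FALSE = scrubbed).
#'
#' @param values T x N numeric matrix (rows = volumes, columns = regions).
#' @param tr sampling interval in seconds.
#' @param region_labels character vector of N region names; defaults to
#'   column names or R1..RN.
#' @param volume_mask logical vector of length T; defaults to all TRUE.
#' @return an object of class `conn_ts`.
#' @export
timeseries_matrix <- function(values, tr, region_labels = NULL,
                              volume_mask = NULL) {
  values <- as.matrix(values)
  if (ncol(values) < 2L) stop("need at least 2 regions")
  if (anyNA(values)) stop("time series must not contain missing values")
  if (tr <= 0) stop("tr must be positive")
  if (is.null(region_labels)) {
    region_labels <- colnames(values)
    if (is.null(region_labels)) region_labels <- paste0("R", seq_len(ncol(values)))
  }
  if (length(region_labels) != ncol(values)) {
    stop("region_labels length must match the number of columns")
  }
  if (is.null(volume_mask)) volume_mask <- rep(TRUE, nrow(values))
  if (length(volume_mask) != nrow(values)) {
    stop("volume_mask length must match the number of rows")
  }
  colnames(values) <- region_labels
  structure(list(values = values, tr = tr, region_labels = region_labels,
                 volume_mask = volume_mask), class = "conn_ts")
}

#' @export
print.conn_ts <- function(x, ...) {
  cat(sprintf("ROI time series: %d volumes x %d regions, TR = %g s, %d scrubbed\n",
              nrow(x$values), ncol(x$values), x$tr, sum(!x$volume_mask)))
  invisible(x)
}

#' Partial correlations implied by a precision matrix
#'
#' For precision matrix O, the partial correlation between nodes i and j
#' given all other nodes is -O\[i,j\] / sqrt(O\[i,i\] O\[j,j\]). The diagonal of
#' the returned matrix is set to zero.
#'
#' @param precision symmetric positive-definite matrix.
#' @return matrix of implied partial correlations.
#' @export
implied_partial_correlation <- function(precision) {
  assert_square_symmetric(precision, tol = 1e-8, what = "precision")
  d <- diag(precision)
  if (any(d <= 0)) stop("precision diagonal must be positive")
  p <- -precision / sqrt(outer(d, d))
  diag(p) <- 0
  p
}

#' Build a modular ground-truth precision matrix
#'
#' Generates the precision (inverse covariance) matrix of one group's
#' ground-truth connectivity model. Regions are organised into modules;
#' within each module the nodes are joined in a ring lattice of strong
#' conditional dependencies (magnitude scaled by `base_strength`), all other
#' within-module pairs carry a weak background dependency, and sparse
#' between-module shortcuts (weaker than the lattice edges) give the implied
#' network its small-world character. Off-diagonal entries incident to
#' `dmn_indices` are multiplied by `1 - attenuation`, which strictly shrinks
#' every implied partial correlation at those nodes; the diagonal is loaded
#' to strict diagonal dominance so the matrix is positive definite by
#' construction (still verified by a Cholesky factorisation, and an error is
#' raised if that fails rather than repairing the matrix).
#'
#' @param n_regions number of nodes (default 90).
#' @param module_partition list of integer vectors partitioning
#'   `1:n_regions`; default 6 equal modules.
#' @param base_strength magnitude of the strong within-module lattice
#'   entries before diagonal normalisation.
#' @param dmn_indices integer indices of the seeded (attenuated) nodes.
#' @param attenuation factor in \[0, 1\]; 0 leaves the model untouched.
#' @param seed integer seed; the random structure is fully reproducible.
#' @param lattice_k even number of ring-lattice neighbours per node within a
#'   module.
#' @param background_frac magnitude of remaining within-module entries as a
#'   fraction of `base_strength`.
#' @param shortcut_prob probability that a between-module pair carries a
#'   shortcut dependency.
#' @param shortcut_frac magnitude of between-module shortcuts as a fraction
#'   of `base_strength`.
#' @param dmn_clique_frac weight of every within-DMN pair as a fraction of
#'   `base_strength`; the default-mode regions form a densely connected hub
#'   community, as they do in real functional connectomes, so group
#'   attenuation has a visible global footprint.
#' @param dmn_extra number of extra strong edges from each DMN node to
#'   random non-DMN nodes of its home module.
#' @param global_attenuation factor in \[0, 1) applied to every off-diagonal
#'   entry (before the DMN-specific attenuation); emulates the diffuse,
#'   whole-brain connectivity weakening of the patient groups on top of the
#'   focal default-mode effect.
#' @param dominance_margin relative diagonal-dominance margin; the diagonal
#'   is `(1 + margin) * sum(|row|)` (plus a small absolute floor).
#' @return an N x N symmetric positive-definite precision matrix.
#' @examples
#' omega <- build_group_precision(n_regions = 30,
#'   module_partition = split(1:30, rep(1:3, each = 10)),
#'   dmn_indices = c(1, 2), attenuation = 0.4, seed = 1)
#' max(abs(implied_partial_correlation(omega)))
#' @export
build_group_precision <- function(n_regions = 90,
                                  module_partition = NULL,
                                  base_strength = 1,
                                  dmn_indices = integer(0),
                                  attenuation = 0,
                                  seed = 1,
                                  lattice_k = 4,
                                  background_frac = 0.08,
                                  shortcut_prob = 0.02,
                                  shortcut_frac = 0.5,
                                  dmn_clique_frac = 2,
                                  dmn_extra = 14,
                                  global_attenuation = 0,
                                  dominance_margin = 0.1) {
  if (is.null(module_partition)) {
    module_partition <- split(seq_len(n_regions),
                              rep(seq_len(6), each = ceiling(n_regions / 6),
                                  length.out = n_regions))
  }
  idx <- as.integer(sort(unname(unlist(module_partition))))
  if (!identical(idx, seq_len(n_regions))) {
    stop("module_partition must partition 1:", n_regions)
  }
  if (attenuation < 0 || attenuation > 1) stop("attenuation must be in [0, 1]")
  if (length(dmn_indices) && (min(dmn_indices) < 1 || max(dmn_indices) > n_regions)) {
    stop("dmn_indices out of range")
  }
  set.seed(seed)
  w <- matrix(0, n_regions, n_regions)
  jitter <- function(n) runif(n, 0.8, 1.2)
  for (mod in module_partition) {
    m <- length(mod)
    if (m < 2) next
    # ring lattice of strong edges within the module
    for (d in seq_len(min(lattice_k %/% 2, (m - 1) %/% 2))) {
      for (a in seq_len(m)) {
        b <- ((a + d - 1) %% m) + 1
        i <- mod[a]; j <- mod[b]
        if (i != j && w[i, j] == 0) {
          v <- base_strength * jitter(1)
          w[i, j] <- v; w[j, i] <- v
        }
      }
    }
    # weak dense background within the module
    for (a in seq_len(m - 1)) for (b in (a + 1):m) {
      i <- mod[a]; j <- mod[b]
      if (w[i, j] == 0) {
        v <- base_strength * background_frac * jitter(1)
        w[i, j] <- v; w[j, i] <- v
      }
    }
  }
  # sparse between-module shortcuts, weaker than the lattice edges
  mod_id <- integer(n_regions)
  for (k in seq_along(module_partition)) mod_id[module_partition[[k]]] <- k
  for (i in seq_len(n_regions - 1)) for (j in (i + 1):n_regions) {
    if (mod_id[i] != mod_id[j] && runif(1) < shortcut_prob) {
      v <- base_strength * shortcut_frac * jitter(1)
      w[i, j] <- v; w[j, i] <- v
    }
  }
  if (length(dmn_indices) >= 2 && dmn_clique_frac > 0) {
    # the seeded (default-mode) regions form a hub community
    for (a in seq_along(dmn_indices)[-1]) for (b in seq_len(a - 1)) {
      i <- dmn_indices[a]; j <- dmn_indices[b]
      v <- base_strength * dmn_clique_frac * jitter(1)
      w[i, j] <- v; w[j, i] <- v
    }
  }
  if (length(dmn_indices) && dmn_extra > 0) {
    for (i in dmn_indices) {
      own <- setdiff(module_partition[[mod_id[i]]], dmn_indices)
      if (!length(own)) next
      pick <- own[sample.int(length(own), min(dmn_extra, length(own)))]
      for (j in pick) {
        v <- base_strength * jitter(1)
        w[i, j] <- v; w[j, i] <- v
      }
    }
  }
  if (global_attenuation < 0 || global_attenuation >= 1) {
    stop("global_attenuation must be in [0, 1)")
  }
  if (global_attenuation > 0) w <- w * (1 - global_attenuation)
  if (length(dmn_indices)) {
    fac <- 1 - attenuation
    w[dmn_indices, ] <- w[dmn_indices, ] * fac
    w[, dmn_indices] <- w[, dmn_indices] * fac
    # doubly scaled entries between two seeded nodes: restore single factor
    w[dmn_indices, dmn_indices] <- w[dmn_indices, dmn_indices] / ifelse(fac > 0, fac, 1)
  }
  omega <- -w
  diag(omega) <- (1 + dominance_margin) * rowSums(abs(w)) + 0.5 * base_strength
  res <- tryCatch(chol(omega), error = function(e) NULL)
  if (is.null(res)) {
    stop("constructed precision matrix is not positive definite")
  }
  omega
}

#' Simulate a subject's ROI time series from a precision matrix
#'
#' Draws Gaussian innovations with covariance equal to the inverse of
#' `precision` and passes them through a first-order autoregression to give
#' the signal BOLD-like temporal smoothness. The AR(1) scaling preserves the
#' partial-correlation structure (the stationary covariance is proportional
#' to the innovation covariance). Identical seeds give bit-identical output.
#'
#' @param precision N x N symmetric positive-definite matrix.
#' @param n_volumes number of time points (rows), >= 2.
#' @param tr repetition time in seconds.
#' @param ar_coeff AR(1) coefficient in \[0, 1).
#' @param seed integer seed.
#' @param region_labels optional column labels.
#' @return a `conn_ts` object with `n_volumes` rows.
#' @export
simulate_subject_timeseries <- function(precision, n_volumes = 240, tr = 2,
                                        ar_coeff = 0.3, seed = 1,
                                        region_labels = NULL) {
  if (n_volumes < 2) stop("n_volumes must be at least 2")
  if (ar_coeff < 0 || ar_coeff >= 1) stop("ar_coeff must be in [0, 1)")
  assert_square_symmetric(precision, tol = 1e-8, what = "precision")
  n <- nrow(precision)
  ch <- tryCatch(chol(precision), error = function(e) NULL)
  if (is.null(ch)) stop("precision matrix is singular or not positive definite")
  sigma <- chol2inv(ch)
  l_sigma <- chol((sigma + t(sigma)) / 2)
  set.seed(seed)
  innov <- matrix(rnorm(n_volumes * n), n_volumes, n) %*% l_sigma
  x <- matrix(0, n_volumes, n)
  x[1, ] <- innov[1, ] / sqrt(1 - ar_coeff^2)
  for (t in 2:n_volumes) x[t, ] <- ar_coeff * x[t - 1, ] + innov[t, ]
  timeseries_matrix(x, tr = tr, region_labels = region_labels)
}

#' Default synthetic-cohort configuration
#'
#' Returns the configuration that the generator treats as the emulated study
#' conditions: 36 / 30 / 48 subjects in the cognitively impaired (CI),
#' non-impaired (NCI) and healthy-control (HC) groups, 240 volumes at TR 2 s
#' over 90 regions, default-mode connectivity attenuated in the patient
#' groups (HC < NCI < CI attenuation, i.e. connectivity ordered
#' HC > NCI > CI), and cognitive scores linearly coupled to each subject's
#' true default-mode nodal strength. Score means and standard deviations
#' follow the published group summaries; exact distributional forms are
#' generator choices.
#'
#' @param ... named overrides of any default listed below.
#' @return a list of generator settings.
#' @export
cohort_config <- function(...) {
  cfg <- list(
    group_sizes = c(CI = 36L, NCI = 30L, HC = 48L),
    n_regions = 90L,
    n_volumes = 240L,
    tr = 2,
    ar_coeff = 0.3,
    n_modules = 6L,
    base_strength = 1,
    attenuation = c(HC = 0, NCI = 0.2, CI = 0.9),
    global_attenuation = c(HC = 0, NCI = 0.25, CI = 0.55),
    attenuation_sd = 0.05,
    # within-group target correlation between true DMN strength and scores
    coupling = c(moca = 0.3, sdmt = 0.45, tmt_a = -0.45, tmt_b = -0.35),
    score_means = list(
      moca  = c(CI = 21.00, NCI = 27.27, HC = 27.54),
      sdmt  = c(CI = 37.03, NCI = 44.50, HC = 48.21),
      tmt_a = c(CI = 51.69, NCI = 43.23, HC = 38.19),
      tmt_b = c(CI = 71.42, NCI = 63.17, HC = 58.19)),
    score_sds = list(
      moca  = c(CI = 4.57, NCI = 0.91, HC = 1.11),
      sdmt  = c(CI = 11.24, NCI = 10.28, HC = 10.15),
      tmt_a = c(CI = 16.56, NCI = 13.27, HC = 9.32),
      tmt_b = c(CI = 16.50, NCI = 12.64, HC = 9.83)),
    age_mean = 31.5, age_sd = 7.5, age_range = c(18, 45),
    male_prob = c(CI = 23 / 36, NCI = 20 / 30, HC = 30 / 48),
    edu_mean = 11.3, edu_sd = 2.7, edu_range = c(5, 20),
    egfr_patient = c(mean = 8, sd = 3, lo = 3, hi = 15),
    egfr_hc = c(mean = 102, sd = 13, lo = 70, hi = 140),
    motion_sd = 0.1,            # marginal sd of baseline motion (mm / deg)
    motion_ar = 0.95,
    motion_clip = 0.25,
    spike_prob = 0.3,           # fraction of subjects given FD spikes
    spike_size = 0.7,           # mm, single-volume translation excursion
    max_spikes = 3L,
    discard = 10L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config fields: ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  cfg
}

truncnorm1 <- function(n, mean, sd, lo, hi) {
  x <- rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  while (length(bad)) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- which(x < lo | x > hi)
  }
  x
}

#' Generate a complete synthetic cohort
#'
#' Samples phenotypes and ROI time series for all subjects of the three
#' groups. Every subject shares the same random modular structure (drawn
#' from a structure seed derived from `master_seed`); subjects differ by an
#' individual default-mode attenuation equal to their group's mean
#' attenuation plus jitter, so default-mode connectivity varies within each
#' group and is ordered HC > NCI > CI on average. Cognitive scores are
#' linear functions of each subject's true default-mode nodal strength plus
#' noise, with coupling targeting the configured within-group correlations.
#' Motion traces are small enough to pass the 1.0 mm / 1.0 degree QC rule;
#' a configurable fraction of subjects receives single-volume translation
#' spikes to exercise framewise-displacement scrubbing, and the flagged
#' volume indices are recorded in the ground truth.
#'
#' @param config list from [cohort_config()].
#' @param master_seed integer; all randomness derives from it through
#'   [derive_seed()], so per-subject output is independent of cohort order.
#' @param out_dir optional directory; when given, writes one
#'   `<id>_roits.tsv` and `<id>_motion.tsv` per subject, `cohort.csv`, and
#'   `ground_truth.json`.
#' @return a list with elements `cohort` (phenotype data.frame), `timeseries`
#'   (named list of `conn_ts`), `motion` (named list of T x 6 matrices),
#'   `model` (group-level ground-truth precisions) and `ground_truth`
#'   (per-subject seeds, attenuations, DMN strengths, planted scrub volumes).
#' @export
generate_cohort <- function(config = cohort_config(), master_seed = 1,
                            out_dir = NULL) {
  cfg <- config
  if (any(cfg$group_sizes < 3)) {
    stop("group sizes below 3 leave the statistics stage undefined")
  }
  n_reg <- cfg$n_regions
  atlas <- if (n_reg == 90L) load_atlas_labels() else NULL
  labels <- if (is.null(atlas)) paste0("R", seq_len(n_reg)) else atlas$abbreviation
  dmn_idx <- if (is.null(atlas)) {
    seq_len(min(7L, n_reg))
  } else {
    unname(dmn_region_indices())
  }
  partition <- split(seq_len(n_reg),
                     rep(seq_len(cfg$n_modules),
                         each = ceiling(n_reg / cfg$n_modules),
                         length.out = n_reg))
  structure_seed <- derive_seed(master_seed, "structure")

  build <- function(att, g_att) {
    build_group_precision(n_regions = n_reg, module_partition = partition,
                          base_strength = cfg$base_strength,
                          dmn_indices = dmn_idx, attenuation = att,
                          global_attenuation = g_att,
                          seed = structure_seed)
  }
  model <- list(
    n_regions = n_reg, region_labels = labels, dmn_indices = dmn_idx,
    precision_by_group = lapply(c("HC", "NCI", "CI"), function(g) {
      build(cfg$attenuation[[g]], cfg$global_attenuation[[g]])
    }),
    attenuation_by_group = cfg$attenuation
  )
  names(model$precision_by_group) <- c("HC", "NCI", "CI")

  groups <- rep(names(cfg$group_sizes), cfg$group_sizes)
  ids <- unlist(lapply(names(cfg$group_sizes), function(g) {
    sprintf("%s%02d", g, seq_len(cfg$group_sizes[[g]]))
  }))
  n_sub <- length(ids)
  t_total <- cfg$n_volumes

  subj_att <- numeric(n_sub)
  dmn_strength <- matrix(NA_real_, n_sub, length(dmn_idx),
                         dimnames = list(ids, labels[dmn_idx]))
  ts_list <- vector("list", n_sub); names(ts_list) <- ids
  motion_list <- vector("list", n_sub); names(motion_list) <- ids
  planted <- vector("list", n_sub); names(planted) <- ids

  for (s in seq_len(n_sub)) {
    id <- ids[s]; g <- groups[s]
    seed_s <- derive_seed(master_seed, id)
    set.seed(seed_s)
    a <- cfg$attenuation[[g]] + rnorm(1, 0, cfg$attenuation_sd)
    a <- min(max(a, 0), 0.95)
    subj_att[s] <- a
    omega <- build(a, cfg$global_attenuation[[g]])
    pc <- implied_partial_correlation(omega)
    dmn_strength[s, ] <- rowSums(abs(pc[dmn_idx, , drop = FALSE]))
    ts_list[[s]] <- simulate_subject_timeseries(
      omega, n_volumes = t_total, tr = cfg$tr, ar_coeff = cfg$ar_coeff,
      seed = derive_seed(master_seed, paste0(id, "_ts")),
      region_labels = labels)

    # motion: smooth AR(1) baseline, clipped well inside the QC bound
    set.seed(derive_seed(master_seed, paste0(id, "_motion")))
    innov_sd <- cfg$motion_sd * sqrt(1 - cfg$motion_ar^2)
    m <- matrix(0, t_total, 6)
    for (k in 1:6) {
      v <- numeric(t_total)
      v[1] <- rnorm(1, 0, cfg$motion_sd)
      for (t in 2:t_total) v[t] <- cfg$motion_ar * v[t - 1] + rnorm(1, 0, innov_sd)
      m[, k] <- pmin(pmax(v, -cfg$motion_clip), cfg$motion_clip)
    }
    colnames(m) <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
    spike_vols <- integer(0)
    if (runif(1) < cfg$spike_prob) {
      n_spike <- sample.int(cfg$max_spikes, 1)
      cand <- seq(cfg$discard + 3L, t_total - 2L)
      vols <- integer(0)
      for (k in seq_len(n_spike)) {
        ok <- cand[vapply(cand, function(v) all(abs(v - vols) > 3), logical(1))]
        if (!length(ok)) break
        vols <- c(vols, ok[sample.int(length(ok), 1)])
      }
      spike_vols <- sort(vols)
      m[spike_vols, 1] <- m[spike_vols, 1] + cfg$spike_size
    }
    motion_list[[s]] <- m
    # a single-volume excursion flags that volume and the return volume
    planted[[s]] <- sort(unique(c(spike_vols, spike_vols + 1L))) - cfg$discard
  }

  # phenotypes (one seeded block so score coupling can standardise per group)
  set.seed(derive_seed(master_seed, "phenotypes"))
  age <- truncnorm1(n_sub, cfg$age_mean, cfg$age_sd, cfg$age_range[1], cfg$age_range[2])
  sex <- ifelse(runif(n_sub) < cfg$male_prob[groups], "M", "F")
  edu <- truncnorm1(n_sub, cfg$edu_mean, cfg$edu_sd, cfg$edu_range[1], cfg$edu_range[2])
  egfr <- numeric(n_sub)
  pat <- groups %in% c("CI", "NCI")
  ep <- cfg$egfr_patient; eh <- cfg$egfr_hc
  egfr[pat] <- truncnorm1(sum(pat), ep["mean"], ep["sd"], ep["lo"], ep["hi"])
  egfr[!pat] <- truncnorm1(sum(!pat), eh["mean"], eh["sd"], eh["lo"], eh["hi"])

  strength_overall <- rowMeans(dmn_strength)
  score <- function(name) {
    out <- numeric(n_sub)
    rho <- cfg$coupling[[name]]
    for (g in names(cfg$group_sizes)) {
      i <- which(groups == g)
      z_s <- as.numeric(scale(strength_overall[i]))
      z <- rho * z_s + sqrt(1 - rho^2) * rnorm(length(i))
      out[i] <- cfg$score_means[[name]][[g]] + cfg$score_sds[[name]][[g]] * z
    }
    out
  }
  moca <- round(score("moca"))
  moca[groups == "CI"] <- pmin(pmax(moca[groups == "CI"], 5L), 25L)
  moca[groups != "CI"] <- pmin(pmax(moca[groups != "CI"], 26L), 30L)
  sdmt <- pmax(round(score("sdmt")), 1L)
  tmt_a <- pmax(score("tmt_a"), 5)
  tmt_b <- pmax(score("tmt_b"), 8)

  cohort <- data.frame(
    subject_id = ids, group = groups, age = round(age, 1), sex = sex,
    education = round(edu, 1), egfr = round(egfr, 1), moca = as.integer(moca),
    tmt_a = round(tmt_a, 1), tmt_b = round(tmt_b, 1), sdmt = as.integer(sdmt),
    seed = vapply(ids, function(id) derive_seed(master_seed, id), integer(1)),
    stringsAsFactors = FALSE)

  ground_truth <- list(
    master_seed = master_seed,
    structure_seed = structure_seed,
    group_attenuation = as.list(cfg$attenuation),
    coupling = as.list(cfg$coupling),
    fd_spike_size = cfg$spike_size,
    discard = cfg$discard,
    subjects = data.frame(
      subject_id = ids, group = groups, seed = cohort$seed,
      attenuation = subj_att, dmn_strength = strength_overall,
      n_planted_scrub = vapply(planted, length, integer(1)),
      stringsAsFactors = FALSE),
    dmn_strength_by_region = dmn_strength,
    planted_scrub_volumes = planted
  )

  out <- list(cohort = cohort, timeseries = ts_list, motion = motion_list,
              model = model, ground_truth = ground_truth, config = cfg)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (id in ids) {
      write.table(ts_list[[id]]$values,
                  file.path(out_dir, paste0(id, "_roits.tsv")),
                  sep = "\t", row.names = FALSE, quote = FALSE)
      write.table(motion_list[[id]],
                  file.path(out_dir, paste0(id, "_motion.tsv")),
                  sep = "\t", row.names = FALSE, quote = FALSE)
    }
    write.csv(cohort, file.path(out_dir, "cohort.csv"), row.names = FALSE)
    gt <- ground_truth
    gt$dmn_strength_by_region <- as.data.frame(gt$dmn_strength_by_region)
    jsonlite::write_json(gt, file.path(out_dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "columns")
  }
  invisible(out)
}

#' Read a subject's ROI time-series TSV written by the generator
#'
#' @param path TSV with a header row of region labels.
#' @param tr sampling interval in seconds.
#' @return a `conn_ts` object.
#' @export
read_timeseries_tsv <- function(path, tr = 2) {
  m <- as.matrix(read.delim(path, check.names = FALSE))
  timeseries_matrix(m, tr = tr, region_labels = colnames(m))
}

#' Read a motion-parameter TSV (3 translations mm, 3 rotations degrees)
#'
#' @param path TSV with 6 columns.
#' @return T x 6 numeric matrix.
#' @export
read_motion_tsv <- function(path) {
  m <- as.matrix(read.delim(path, check.names = FALSE))
  if (ncol(m) != 6) stop("motion table must have 6 columns")
  m
}
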