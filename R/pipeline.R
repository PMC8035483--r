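#' Pipeline run configuration
#'
#' Collects every tunable of the end-to-end run. All stochastic elements
#' derive from `master_seed` through [derive_seed()], so a config + seed
#' pair reproduces a run exactly.
#'
#' @param master_seed integer master seed.
#' @param candidate_grid grid searched by the sparsity-range rule.
#' @param n_null null networks per subject and grid point.
#' @param swaps_per_edge double-edge swaps per edge in each null.
#' @param shrinkage covariance shrinkage for partial correlations
#'   (`"auto"` = analytic intensity, or a fixed value in \[0, 1)).
#' @param fd_threshold framewise-displacement scrub cutoff (mm).
#' @param discard initial volumes dropped.
#' @param band band-pass edges (Hz).
#' @param t_variant "pooled" or "welch" for two-group summary t tests.
#' @param corr_covariates phenotype columns partialled out of the
#'   score-metric correlations.
#' @param cohort a [cohort_config()] used when generating data.
#' @return list of class `conn_config`.
#' @export
run_config <- function(master_seed = 1,
                       candidate_grid = sparsity_grid(0.10, 0.34, 0.01),
                       n_null = 100,
                       swaps_per_edge = 10,
                       shrinkage = 0.9,
                       fd_threshold = 0.5,
                       discard = 10,
                       band = c(0.01, 0.08),
                       t_variant = "pooled",
                       corr_covariates = c("age", "sex01", "education"),
                       cohort = cohort_config()) {
  cfg <- as.list(environment())
  class(cfg) <- "conn_config"
  cfg
}

load_cohort_dir <- function(input_dir, tr) {
  cohort <- read.csv(file.path(input_dir, "cohort.csv"),
                     stringsAsFactors = FALSE)
  ts <- lapply(cohort$subject_id, function(id) {
    read_timeseries_tsv(file.path(input_dir, paste0(id, "_roits.tsv")), tr = tr)
  })
  names(ts) <- cohort$subject_id
  motion <- lapply(cohort$subject_id, function(id) {
    p <- file.path(input_dir, paste0(id, "_motion.tsv"))
    if (file.exists(p)) read_motion_tsv(p) else NULL
  })
  names(motion) <- cohort$subject_id
  list(cohort = cohort, timeseries = ts, motion = motion)
}

summarise_by_group <- function(x, group) {
  t(vapply(split(x, group), function(v) c(n = length(v), mean = mean(v),
                                          sd = sd(v)), numeric(3)))
}

#' Run the full analysis pipeline
#'
#' Stages: (1) generate a synthetic cohort (or load one from `input_dir`);
#' (2) clean every subject's time series and exclude subjects failing the
#' 1.0 mm / 1.0 degree motion rule; (3) build partial-correlation
#' connectivity matrices; (4) select the sparsity range on which sigma > 1
#' for all subjects and compute metric curves and their AUCs; (5) group
#' statistics: demographic tests, ANCOVA (age, sex, eGFR covariates) with
#' Bonferroni post hoc on global and nodal AUCs, and FDR-corrected partial
#' correlations between cognitive scores and default-mode nodal AUCs in the
#' impaired group.
#'
#' @param config a [run_config()].
#' @param input_dir optional directory of generator-format files; when NULL
#'   a cohort is generated in memory from `config$cohort`.
#' @param out_dir optional directory for CSV outputs.
#' @param verbose print stage progress.
#' @return a run-report list; see Details in the package vignette.
#' @export
run_pipeline <- function(config = run_config(), input_dir = NULL,
                         out_dir = NULL, verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  cfg <- config

  # -- stage 1: data ---------------------------------------------------
  if (is.null(input_dir)) {
    say("generating synthetic cohort (master seed %d)", cfg$master_seed)
    gen <- generate_cohort(cfg$cohort, master_seed = cfg$master_seed)
    cohort <- gen$cohort; ts <- gen$timeseries; motion <- gen$motion
    ground_truth <- gen$ground_truth
  } else {
    say("loading cohort from %s", input_dir)
    dat <- load_cohort_dir(input_dir, tr = cfg$cohort$tr)
    cohort <- dat$cohort; ts <- dat$timeseries; motion <- dat$motion
    ground_truth <- NULL
  }

  # -- stage 2: preprocessing + QC ------------------------------------
  say("preprocessing %d subjects", nrow(cohort))
  qc_fail <- character(0)
  clean <- list()
  for (id in cohort$subject_id) {
    m <- motion[[id]]
    if (!is.null(m) && !qc_motion(m)$pass) {
      qc_fail <- c(qc_fail, id)
      next
    }
    clean[[id]] <- clean_timeseries(ts[[id]], motion = m,
                                    discard = cfg$discard, band = cfg$band,
                                    fd_threshold = cfg$fd_threshold)
  }
  cohort <- cohort[!cohort$subject_id %in% qc_fail, , drop = FALSE]
  if (any(table(cohort$group) < 1) || length(unique(cohort$group)) < 3) {
    stop("a group is empty after motion QC")
  }
  n_scrubbed <- vapply(clean, function(x) attr(x, "n_scrubbed"), integer(1))

  # -- stage 3: connectivity ------------------------------------------
  say("estimating partial-correlation matrices")
  conns <- lapply(clean, partial_correlation_matrix, shrinkage = cfg$shrinkage)

  # -- stage 4: sparsity sweep ----------------------------------------
  say("selecting sparsity range")
  grid <- determine_sparsity_range(conns, cfg$candidate_grid,
                                   n_null = cfg$n_null,
                                   swaps_per_edge = cfg$swaps_per_edge,
                                   seed = cfg$master_seed)
  say("selected range %.2f-%.2f (%d points)", grid$s_min, grid$s_max,
      length(grid$points))
  curves <- lapply(cohort$subject_id, function(id) {
    metric_curves(conns[[id]], grid, n_null = cfg$n_null,
                  swaps_per_edge = cfg$swaps_per_edge,
                  seed = derive_seed(cfg$master_seed, id))
  })
  names(curves) <- cohort$subject_id
  aucs <- lapply(curves, auc_summary)
  glob_auc <- t(vapply(aucs, function(a) a$global,
                       numeric(length(aucs[[1]]$global))))
  nodal_auc <- lapply(c(degree = "degree", nodal_efficiency = "nodal_efficiency",
                        betweenness = "betweenness"), function(m) {
    t(vapply(aucs, function(a) a$nodal[, m], numeric(nrow(aucs[[1]]$nodal))))
  })

  # -- stage 5: statistics --------------------------------------------
  say("group statistics")
  group <- factor(cohort$group, levels = c("CI", "NCI", "HC"))
  cohort$sex01 <- as.integer(cohort$sex == "M")
  n_reg <- ncol(conns[[1]])
  atlas <- if (n_reg == 90L) load_atlas_labels() else generic_atlas(n_reg)

  # demographic / clinical table (summary-statistic tests)
  demo <- list()
  sex_tab <- table(cohort$group, cohort$sex)[levels(group), , drop = FALSE]
  cs <- chi_square_test(sex_tab)
  demo[["sex"]] <- data.frame(variable = "sex", test = "chi-square",
                              statistic = cs$statistic, p = cs$p)
  for (v in c("age", "education", "moca", "tmt_a", "tmt_b", "sdmt")) {
    sm <- summarise_by_group(cohort[[v]], group)
    av <- one_way_anova_from_summary(sm)
    demo[[v]] <- data.frame(variable = v, test = "anova",
                            statistic = av$statistic, p = av$p)
  }
  pat <- cohort$group %in% c("CI", "NCI")
  sm <- summarise_by_group(cohort$egfr[pat], droplevels(group[pat]))
  tt <- two_sample_t_from_summary(sm[1, 1], sm[1, 2], sm[1, 3],
                                  sm[2, 1], sm[2, 2], sm[2, 3],
                                  variant = cfg$t_variant)
  demo[["egfr"]] <- data.frame(variable = "egfr",
                               test = paste0("t-", cfg$t_variant),
                               statistic = tt$statistic, p = tt$p)
  table1 <- do.call(rbind, demo)

  covs <- cbind(age = cohort$age, sex01 = cohort$sex01, egfr = cohort$egfr)
  table2 <- do.call(rbind, lapply(colnames(glob_auc), function(m) {
    res <- ancova_group_test(glob_auc[, m], group, covs)
    data.frame(metric = m, F = res$statistic, p = res$p,
               p_CI_vs_NCI = res$posthoc$p_adjusted[
                 res$posthoc$contrast == "CI vs NCI"],
               p_CI_vs_HC = res$posthoc$p_adjusted[
                 res$posthoc$contrast == "CI vs HC"],
               p_NCI_vs_HC = res$posthoc$p_adjusted[
                 res$posthoc$contrast == "NCI vs HC"],
               mean_CI = res$adjusted_means["CI"],
               mean_NCI = res$adjusted_means["NCI"],
               mean_HC = res$adjusted_means["HC"],
               stringsAsFactors = FALSE, row.names = NULL)
  }))

  table3 <- do.call(rbind, lapply(seq_len(nrow(atlas)), function(i) {
    row <- lapply(names(nodal_auc), function(m) {
      res <- ancova_group_test(nodal_auc[[m]][, i], group, covs)
      dir <- paste(names(sort(res$adjusted_means, decreasing = TRUE)),
                   collapse = " > ")
      data.frame(region = atlas$abbreviation[i], metric = m,
                 F = res$statistic, p = res$p, direction = dir,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, row)
  }))
  table3$significant <- table3$p < 0.05

  # score correlations within the impaired group, DMN nodal AUCs
  ci_rows <- which(cohort$group == "CI")
  dmn_idx <- atlas$index[atlas$dmn == 1]
  cc <- as.matrix(cohort[ci_rows, cfg$corr_covariates, drop = FALSE])
  if (length(ci_rows) < ncol(cc) + 3) {
    warning("CI group too small for the covariate-adjusted correlations; ",
            "skipping the correlation stage")
    corr <- data.frame(score = character(0), metric = character(0),
                       region = character(0), r = numeric(0), p = numeric(0))
  } else {
  corr <- do.call(rbind, lapply(c("moca", "tmt_a", "tmt_b", "sdmt"),
                                function(sc) {
    do.call(rbind, lapply(names(nodal_auc), function(m) {
      do.call(rbind, lapply(dmn_idx, function(i) {
        pr <- partial_correlation_test(cohort[[sc]][ci_rows],
                                       nodal_auc[[m]][ci_rows, i], cc)
        data.frame(score = sc, metric = m,
                   region = atlas$abbreviation[i], r = pr$r, p = pr$p,
                   stringsAsFactors = FALSE)
      }))
    }))
  }))
  }
  corr$q <- bh_fdr(corr$p)

  group_auc_summary <- lapply(colnames(glob_auc), function(m) {
    summarise_by_group(glob_auc[, m], group)
  })
  names(group_auc_summary) <- colnames(glob_auc)

  report <- list(
    config = cfg,
    n_subjects = nrow(cohort),
    qc_failures = qc_fail,
    n_scrubbed = n_scrubbed,
    selected_grid = grid,
    cohort = cohort,
    connectivity = conns,
    global_auc = glob_auc,
    nodal_auc = nodal_auc,
    group_auc_summary = group_auc_summary,
    table1 = table1,
    table2 = table2,
    table3 = table3,
    correlations = corr,
    ground_truth = ground_truth
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(table1, file.path(out_dir, "table1_style.csv"), row.names = FALSE)
    write.csv(table2, file.path(out_dir, "table2_style.csv"), row.names = FALSE)
    write.csv(table3, file.path(out_dir, "table3_style.csv"), row.names = FALSE)
    write.csv(corr, file.path(out_dir, "correlations.csv"), row.names = FALSE)
    write.csv(data.frame(subject_id = rownames(glob_auc), glob_auc),
              file.path(out_dir, "metrics_auc.csv"), row.names = FALSE)
  }
  report
}
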