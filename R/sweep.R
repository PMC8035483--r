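#' Construct a sparsity grid
#'
#' @param s_min,s_max grid endpoints in (0, 1).
#' @param step grid spacing.
#' @return list with `s_min`, `s_max`, `step`, `points`.
#' @export
sparsity_grid <- function(s_min = 0.10, s_max = 0.34, step = 0.01) {
  if (s_min <= 0 || s_max >= 1 || s_min >= s_max) {
    stop("need 0 < s_min < s_max < 1")
  }
  pts <- seq(s_min, s_max, by = step)
  # guard against floating-point shortfall of the final point
  if (s_max - pts[length(pts)] > step / 2) pts <- c(pts, s_max)
  list(s_min = s_min, s_max = s_max, step = step, points = round(pts, 10))
}

#' Per-subject metric curves over a sparsity grid
#'
#' Binarizes the connectivity matrix at every grid point and computes the
#' global metrics with small-world normalisation plus the nodal centrality
#' metrics. The null-model seed at each grid point is derived from `seed`
#' and the point index, so curves are reproducible regardless of how
#' subjects or points are scheduled.
#'
#' @param conn N x N partial-correlation matrix.
#' @param grid a [sparsity_grid()].
#' @param n_null null networks per grid point.
#' @param swaps_per_edge swaps per edge for each null.
#' @param seed integer seed for this subject.
#' @param nodal compute nodal metrics too (default TRUE).
#' @return list of class `conn_curves`: per-metric numeric vectors (`cp`,
#'   `lp`, `gamma`, `lambda`, `sigma`, `eglob`, `eloc`, `n_components`) and,
#'   if `nodal`, node x point matrices `degree`, `nodal_efficiency`,
#'   `betweenness`.
#' @export
metric_curves <- function(conn, grid, n_null = 100, swaps_per_edge = 10,
                          seed = 1, nodal = TRUE) {
  pts <- grid$points
  np <- length(pts)
  n <- nrow(conn)
  glob <- matrix(NA_real_, np, 8,
                 dimnames = list(NULL, c("cp", "lp", "gamma", "lambda",
                                         "sigma", "eglob", "eloc",
                                         "n_components")))
  nod <- if (nodal) {
    list(degree = matrix(NA_real_, n, np),
         nodal_efficiency = matrix(NA_real_, n, np),
         betweenness = matrix(NA_real_, n, np))
  }
  for (k in seq_len(np)) {
    net <- binarize_at_sparsity(conn, pts[k])
    gm <- global_metrics(net)
    sw <- tryCatch(
      small_world_normalization(net, n_null = n_null,
                                swaps_per_edge = swaps_per_edge,
                                seed = derive_seed(seed, paste0("S", k))),
      error = function(e) {
        stop("at sparsity ", pts[k], ": ", conditionMessage(e), call. = FALSE)
      })
    glob[k, ] <- c(gm$cp, gm$lp, sw$gamma, sw$lambda, sw$sigma, gm$eglob,
                   gm$eloc, gm$n_components)
    if (nodal) {
      nm <- nodal_metrics(net)
      nod$degree[, k] <- nm$degree
      nod$nodal_efficiency[, k] <- nm$nodal_efficiency
      nod$betweenness[, k] <- nm$betweenness
    }
  }
  out <- c(as.list(as.data.frame(glob)), nod)
  out$grid <- grid
  class(out) <- "conn_curves"
  out
}

#' Sigma curve only (cheap variant used by the range-selection rule)
#' @noRd
sigma_at_points <- function(conn, pts, n_null, swaps_per_edge, seed) {
  vapply(seq_along(pts), function(k) {
    net <- binarize_at_sparsity(conn, pts[k])
    sw <- tryCatch(
      small_world_normalization(net, n_null = n_null,
                                swaps_per_edge = swaps_per_edge,
                                seed = derive_seed(seed, paste0("S", k))),
      error = function(e) NULL)
    if (is.null(sw)) NA_real_ else sw$sigma
  }, numeric(1))
}

#' Select the sparsity range by the small-world estimability rule
#'
#' Returns the largest contiguous sub-grid of `candidate_grid` on which,
#' for every subject, the small-worldness sigma is estimable and exceeds
#' 1.0. Ties between equally long runs go to the lower-sparsity run. Errors
#' if no grid point satisfies the rule for all subjects, listing the
#' subjects that fail most often.
#'
#' @param conns named list of connectivity matrices (one per subject).
#' @param candidate_grid a [sparsity_grid()] to search within.
#' @param n_null,swaps_per_edge null-model settings.
#' @param seed master seed; per-subject seeds are derived from it.
#' @return a [sparsity_grid()] restricted to the selected range, with
#'   attribute `sigma_ok` (subject x point logical matrix).
#' @export
determine_sparsity_range <- function(conns, candidate_grid, n_null = 100,
                                     swaps_per_edge = 10, seed = 1) {
  pts <- candidate_grid$points
  if (!length(pts)) stop("candidate grid is empty")
  ids <- names(conns)
  if (is.null(ids)) ids <- paste0("subj", seq_along(conns))
  ok <- matrix(FALSE, length(conns), length(pts), dimnames = list(ids, NULL))
  for (s in seq_along(conns)) {
    sig <- sigma_at_points(conns[[s]], pts, n_null, swaps_per_edge,
                           derive_seed(seed, ids[s]))
    ok[s, ] <- !is.na(sig) & sig > 1.0
  }
  all_ok <- apply(ok, 2, all)
  if (!any(all_ok)) {
    worst <- names(sort(rowSums(!ok), decreasing = TRUE))
    stop("no sparsity satisfies sigma > 1 for all subjects; worst subjects: ",
         paste(utils::head(worst, 5), collapse = ", "))
  }
  r <- rle(all_ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]
  sel <- starts[best]:ends[best]
  out <- list(s_min = pts[sel[1]], s_max = pts[sel[length(sel)]],
              step = candidate_grid$step, points = pts[sel])
  attr(out, "sigma_ok") <- ok
  out
}

#' AUC summary of all metric curves
#'
#' Reduces each global-metric curve (and each node's curve for each nodal
#' metric) to its trapezoidal area under the curve over the sparsity grid.
#'
#' @param curves a `conn_curves` object from [metric_curves()].
#' @return list with `global` (named numeric vector) and, when nodal curves
#'   are present, `nodal` (node x metric matrix).
#' @export
auc_summary <- function(curves) {
  grid <- curves$grid
  gnames <- c("cp", "lp", "gamma", "lambda", "sigma", "eglob", "eloc")
  glob <- vapply(gnames, function(m) curve_auc(curves[[m]], grid), numeric(1))
  out <- list(global = glob)
  if (!is.null(curves$degree)) {
    nodal <- sapply(c("degree", "nodal_efficiency", "betweenness"),
                    function(m) apply(curves[[m]], 1,
                                      function(v) curve_auc(v, grid)))
    out$nodal <- nodal
  }
  out
}
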