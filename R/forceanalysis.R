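# Analysis surfaces: rupture forces, force vs COM distance, replica
# mean/SD aggregation, geometric hydrogen-bond counting, and the
# per-direction anisotropy table.

#' Centered running mean
#'
#' Window is forced odd; ends use the available (shrinking) window. Intended
#' for plotting only - rupture forces are computed on the raw series unless
#' the caller opts in.
#'
#' @param x numeric vector.
#' @param window window width in samples; `window <= 1` returns `x`.
#' @return smoothed numeric vector, same length.
#' @export
running_mean <- function(x, window = 0) {
  if (window <= 1L) return(x)
  half <- floor(window / 2)
  n <- length(x)
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    mean(x[lo:hi])
  }, numeric(1))
}

#' Maximum rupture force of a trace
#'
#' The global maximum of the projected pulling force - the mechanical
#' stability along that pulling direction. Ties report the earliest time.
#'
#' @param trace a [force_trace()].
#' @param smooth_window optional centered running-mean window applied before
#'   taking the maximum (default 0 = off; the raw series is standard).
#' @return list with `f_max` (pN), `t_at_max` (ps) and `index`.
#' @export
max_rupture_force <- function(trace, smooth_window = 0) {
  stopifnot(inherits(trace, "force_trace"))
  if (length(trace$force) == 0L) pf_stop_input("empty force trace")
  f <- running_mean(trace$force, smooth_window)
  i <- which.max(f)  # first index on ties
  list(f_max = f[i], t_at_max = trace$time[i], index = i)
}

#' Pair forces with center-of-mass distances
#'
#' Orders by time, never by distance: non-monotone COM distance is physical
#' (recoil, slack) and must stay visible.
#'
#' @param trace a [force_trace()].
#' @param distances numeric vector of COM distances (Angstrom) aligned 1:1
#'   with the trace samples.
#' @return data frame with `time`, `distance`, `force`.
#' @export
force_vs_distance <- function(trace, distances) {
  stopifnot(inherits(trace, "force_trace"))
  if (length(distances) != length(trace$time))
    pf_stop_input(sprintf("distance series length (%d) does not match trace length (%d)",
                          length(distances), length(trace$time)))
  data.frame(time = trace$time, distance = as.numeric(distances), force = trace$force)
}

#' Aggregate replica force traces
#'
#' Each trace is linearly interpolated onto a uniform grid spanning the
#' intersection of the replica time ranges (no extrapolation beyond any
#' trace's span); the ensemble is summarized by the pointwise mean and
#' sample standard deviation (n-1 denominator; 0 when n = 1).
#'
#' @param traces list of [force_trace()] objects for one direction.
#' @param grid_dt grid spacing in ps; default: the smallest native sampling
#'   interval among the replicas.
#' @return an object of class `replica_ensemble`: list with `traces`,
#'   `common_time`, `mean_force`, `sd_force`, `n_replicas`.
#' @export
aggregate_replicas <- function(traces, grid_dt = NULL) {
  if (length(traces) == 0L) pf_stop_input("no traces to aggregate")
  stopifnot(all(vapply(traces, inherits, logical(1), "force_trace")))
  t0 <- max(vapply(traces, function(tr) min(tr$time), numeric(1)))
  t1 <- min(vapply(traces, function(tr) max(tr$time), numeric(1)))
  if (t1 <= t0) pf_stop_input("replica time ranges do not overlap")
  if (is.null(grid_dt)) {
    grid_dt <- min(vapply(traces, function(tr) min(diff(tr$time)), numeric(1)))
  }
  grid <- seq(t0, t1, by = grid_dt)
  interp <- vapply(traces, function(tr) approx(tr$time, tr$force, xout = grid)$y,
                   numeric(length(grid)))
  interp <- matrix(interp, nrow = length(grid))
  mean_f <- rowMeans(interp)
  sd_f <- if (length(traces) > 1L) apply(interp, 1, sd) else rep(0, length(grid))
  structure(list(traces = traces, common_time = grid, mean_force = mean_f,
                 sd_force = sd_f, n_replicas = length(traces)),
            class = "replica_ensemble")
}

#' @export
print.replica_ensemble <- function(x, ...) {
  cat(sprintf("replica_ensemble: %d replica(s), %d grid points, peak mean force %.4g pN\n",
              x$n_replicas, length(x$common_time), max(x$mean_force)))
  invisible(x)
}

## ---- hydrogen bonds -------------------------------------------------------

#' Geometric hydrogen-bond criterion
#'
#' A donor-acceptor pair is hydrogen bonded when the donor-acceptor distance
#' is at most `d_max` and the donor-hydrogen-acceptor angle is at least
#' `angle_min`. Defaults (3.5 Angstrom, 150 degrees) are the de-facto
#' standard geometric definition.
#'
#' @param d_max donor-acceptor distance cutoff in Angstrom (> 0).
#' @param angle_min D-H...A angle cutoff in degrees, in (0, 180].
#' @return an object of class `hbond_criterion`.
#' @export
hbond_criterion <- function(d_max = 3.5, angle_min = 150) {
  if (d_max <= 0) pf_stop_config("d_max must be > 0")
  if (angle_min <= 0 || angle_min > 180) pf_stop_config("angle_min must be in (0, 180]")
  structure(list(d_max = d_max, angle_min = angle_min), class = "hbond_criterion")
}

normalize_donors <- function(donors) {
  d <- as.data.frame(donors)
  if (is.null(d$frag)) d$frag <- 1L
  names(d)[1:2] <- c("d", "h")
  d
}

normalize_acceptors <- function(acceptors) {
  if (is.atomic(acceptors) && is.null(dim(acceptors)))
    return(data.frame(a = as.integer(acceptors), frag = 2L))
  a <- as.data.frame(acceptors)
  if (is.null(a$frag)) a$frag <- 2L
  names(a)[1] <- "a"
  a
}

#' Count inter-fragment hydrogen bonds in one frame
#'
#' Counts donor/acceptor combinations satisfying the geometric criterion,
#' restricted to pairs whose fragment tags differ (bonds within one fragment
#' are never counted) and with acceptor distinct from donor.
#'
#' @param frame n x 3 coordinate matrix (Angstrom).
#' @param donors data frame or matrix with columns `d` (donor heavy atom),
#'   `h` (its hydrogen) and optionally `frag` (fragment tag, default 1).
#' @param acceptors integer vector of acceptor atoms (fragment tag 2), or a
#'   data frame with columns `a` and optionally `frag`.
#' @param crit an [hbond_criterion()].
#' @return integer bond count.
#' @export
count_hbonds <- function(frame, donors, acceptors, crit = hbond_criterion()) {
  frame <- as.matrix(frame)
  donors <- normalize_donors(donors)
  acceptors <- normalize_acceptors(acceptors)
  idx <- c(donors$d, donors$h, acceptors$a)
  if (any(idx < 1L | idx > nrow(frame))) pf_stop_input("H-bond atom index out of range")
  cos_min <- cospi(crit$angle_min / 180)  # angle >= angle_min <=> cos <= cos_min
  count <- 0L
  for (i in seq_len(nrow(donors))) {
    D <- frame[donors$d[i], ]; H <- frame[donors$h[i], ]
    for (j in seq_len(nrow(acceptors))) {
      if (donors$frag[i] == acceptors$frag[j]) next
      if (acceptors$a[j] == donors$d[i]) next
      A <- frame[acceptors$a[j], ]
      if (sum((D - A)^2) > crit$d_max^2) next
      u <- D - H; v <- A - H
      nn <- sqrt(sum(u^2) * sum(v^2))
      if (nn < 1e-12) next  # degenerate geometry: angle undefined
      cosang <- sum(u * v) / nn
      if (cosang <= cos_min) count <- count + 1L
    }
  }
  count
}

#' Hydrogen-bond count along a trajectory
#'
#' @param traj a `trajectory` (see [read_trajectory()]).
#' @inheritParams count_hbonds
#' @return integer vector, one count per frame, frame order preserved.
#' @export
hbond_series <- function(traj, donors, acceptors, crit = hbond_criterion()) {
  stopifnot(inherits(traj, "trajectory"))
  vapply(seq_along(traj$frames), function(k) {
    tryCatch(count_hbonds(traj$frames[[k]], donors, acceptors, crit),
             pullfan_error = function(e) pf_stop_input(sprintf("frame %d: %s", k, conditionMessage(e))))
  }, integer(1))
}

## ---- rupture summaries and anisotropy -------------------------------------

#' Summarize rupture forces for one pulling direction
#'
#' @param traces list of [force_trace()] replicas for this direction.
#' @param label direction label.
#' @param theta,phi direction angles in degrees.
#' @param distances optional list of per-replica COM-distance vectors
#'   aligned with each trace (records the distance at rupture).
#' @param smooth_window passed to [max_rupture_force()].
#' @return an object of class `rupture_summary`: per-replica `f_max` (pN),
#'   `t_at_max` (ps), optional `distance_at_max` (Angstrom), and the
#'   ensemble `mean_f_max` / `sd_f_max` (n-1 denominator).
#' @export
rupture_summary <- function(traces, label, theta = NA_real_, phi = NA_real_,
                            distances = NULL, smooth_window = 0) {
  if (length(traces) == 0L) pf_stop_input("no traces for rupture summary")
  per <- lapply(seq_along(traces), function(i) {
    mx <- max_rupture_force(traces[[i]], smooth_window)
    dist_at <- if (!is.null(distances)) distances[[i]][mx$index] else NA_real_
    data.frame(replica = traces[[i]]$replica_id, f_max = mx$f_max,
               t_at_max = mx$t_at_max, distance_at_max = dist_at)
  })
  per <- do.call(rbind, per)
  structure(list(label = label, theta = theta, phi = phi, replicas = per,
                 mean_f_max = mean(per$f_max),
                 sd_f_max = if (nrow(per) > 1L) sd(per$f_max) else 0),
            class = "rupture_summary")
}

#' @export
print.rupture_summary <- function(x, ...) {
  cat(sprintf("rupture_summary %s: mean Fmax %.4g +/- %.4g pN (%d replica(s))\n",
              x$label, x$mean_f_max, x$sd_f_max, nrow(x$replicas)))
  invisible(x)
}

#' Anisotropy table over pulling directions
#'
#' One row per direction: the mean and SD of the per-replica maximum rupture
#' force - the package's central readout of direction-dependent mechanical
#' stability.
#'
#' @param summaries list of [rupture_summary()] objects, in direction-set
#'   order.
#' @return data frame with columns `label`, `theta`, `phi`, `n_replicas`,
#'   `mean_f_max`, `sd_f_max`.
#' @export
anisotropy_table <- function(summaries) {
  if (length(summaries) == 0L) pf_stop_input("no rupture summaries")
  labels <- vapply(summaries, function(s) s$label, character(1))
  if (anyDuplicated(labels)) pf_stop_input("duplicate direction labels in anisotropy table")
  do.call(rbind, lapply(summaries, function(s) {
    data.frame(label = s$label, theta = s$theta, phi = s$phi,
               n_replicas = nrow(s$replicas),
               mean_f_max = s$mean_f_max, sd_f_max = s$sd_f_max,
               stringsAsFactors = FALSE)
  }))
}

#' Write an analysis table as tab-separated text
#'
#' @param df data frame.
#' @param path output path.
#' @param units optional character noted in a `#` header line.
#' @return invisibly, the path.
#' @export
write_tsv_table <- function(df, path, units = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(units)) writeLines(sprintf("# units: %s", units), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## ---- plots ----------------------------------------------------------------

#' Plot a replica ensemble force-time curve
#'
#' Mean force with an SD ribbon, the convention for replica-averaged SMD
#' force profiles.
#'
#' @param ensemble a `replica_ensemble`.
#' @param smooth_window plotting-only running-mean window (default 51).
#' @param title plot title.
#' @return a ggplot object.
#' @export
plot_force_time <- function(ensemble, smooth_window = 51, title = "Pulling force vs time") {
  df <- data.frame(time = ensemble$common_time,
                   mean = running_mean(ensemble$mean_force, smooth_window),
                   sd = running_mean(ensemble$sd_force, smooth_window))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         fill = "lightblue", alpha = 0.6) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::labs(x = "time (ps)", y = "force (pN)", title = title) +
    ggplot2::theme_minimal()
}

#' Plot force versus center-of-mass distance
#'
#' @param fd data frame from [force_vs_distance()].
#' @param title plot title.
#' @return a ggplot object.
#' @export
plot_force_distance <- function(fd, title = "Force vs COM distance") {
  ggplot2::ggplot(fd, ggplot2::aes(x = .data$distance, y = .data$force)) +
    ggplot2::geom_path(color = "steelblue") +
    ggplot2::labs(x = "COM distance (Å)", y = "force (pN)", title = title) +
    ggplot2::theme_minimal()
}

#' Plot a hydrogen-bond count series
#'
#' @param counts integer vector from [hbond_series()].
#' @param time optional time axis (ps); defaults to the frame index.
#' @param smooth_window plotting-only running-mean window.
#' @return a ggplot object.
#' @export
plot_hbond_series <- function(counts, time = seq_along(counts), smooth_window = 0) {
  df <- data.frame(time = time, count = running_mean(as.numeric(counts), smooth_window))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$count)) +
    ggplot2::geom_step(color = "steelblue") +
    ggplot2::labs(x = "time (ps)", y = "hydrogen bonds") +
    ggplot2::theme_minimal()
}

#' Plot the rupture-force anisotropy across directions
#'
#' @param tab data frame from [anisotropy_table()].
#' @return a ggplot object (bar chart with SD error bars).
#' @export
plot_anisotropy <- function(tab) {
  tab$label <- factor(tab$label, levels = tab$label)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$label, y = .data$mean_f_max)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_f_max - .data$sd_f_max,
                                        ymax = .data$mean_f_max + .data$sd_f_max),
                           width = 0.3) +
    ggplot2::labs(x = "pulling direction", y = "max rupture force (pN)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
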