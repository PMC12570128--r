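# Direction-fan generation: an orthonormal frame around the principal axis
# and a deduplicated, labelled set of unit pulling vectors on a (theta, phi)
# grid. Default grid: theta in {0, 45, 90} deg, phi in {0, 90, 180, 270} deg,
# nine distinct directions covering the hemisphere around the axis.

normalize3 <- function(v) {
  len <- sqrt(sum(v^2))
  if (!is.finite(len) || len == 0) pf_stop_input("cannot normalize a zero vector")
  v / len
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Build the local orthonormal frame around a pulling axis
#'
#' Returns a right-handed orthonormal triple `(e1, e2, axis)` with
#' `e1 x e2 = axis`. `e1` fixes the phi = 0 azimuthal reference: it is the
#' normalized `z x axis` unless the axis is within ~2.6 degrees of z
#' (`|axis . z| > 0.999`), in which case `e1` is the unit x direction
#' orthogonalized against the axis (so for axis = z exactly, `e1 = x` and
#' `e2 = y`). The choice is deterministic and continuous almost everywhere;
#' the azimuthal origin is a package convention, not a physical feature.
#'
#' @param axis numeric length-3 unit vector.
#' @return list with unit vectors `e1`, `e2`, `axis`.
#' @export
build_frame <- function(axis) {
  if (length(axis) != 3L || !all(is.finite(axis))) pf_stop_input("axis must be a finite 3-vector")
  axis <- normalize3(axis)
  if (abs(axis[3]) > 0.999) {
    e1 <- normalize3(c(1, 0, 0) - axis[1] * axis)
  } else {
    e1 <- normalize3(cross3(c(0, 0, 1), axis))
  }
  e2 <- cross3(axis, e1)
  list(e1 = e1, e2 = e2, axis = axis)
}

#' Unit pulling vector at spherical angles (theta, phi)
#'
#' `v = cos(theta) axis + sin(theta) (cos(phi) e1 + sin(phi) e2)`, with theta
#' the polar angle from the axis and phi the azimuth in the transverse plane.
#' Angles in degrees; `cospi`/`sinpi` are used so right angles are exact.
#'
#' @param frame frame from [build_frame()].
#' @param theta polar angle in degrees, in \[0, 180\].
#' @param phi azimuth in degrees.
#' @return unit numeric length-3 vector.
#' @export
direction_vector <- function(frame, theta, phi) {
  if (theta < 0 || theta > 180) pf_stop_input("theta must be in [0, 180] degrees")
  ct <- cospi(theta / 180); st <- sinpi(theta / 180)
  cp <- cospi(phi / 180); sp <- sinpi(phi / 180)
  ct * frame$axis + st * (cp * frame$e1 + sp * frame$e2)
}

fmt_angle <- function(a) {
  ifelse(abs(a - round(a)) < 1e-9, sprintf("%d", as.integer(round(a))), sprintf("%.1f", a))
}

direction_label <- function(theta, phi) {
  sprintf("theta_%s_phi_%s", fmt_angle(theta), fmt_angle(phi))
}

angular_distance <- function(u, v) {
  d <- sum(u * v)
  acos(max(-1, min(1, d)))
}

#' Generate the fan of pulling directions
#'
#' Takes the Cartesian product of the theta and phi grids, drops duplicate
#' vectors (angular distance < 1e-6 rad; the theta = 0 pole keeps the single
#' label `theta_0_phi_0`), and orders directions by theta then phi ascending.
#' With 0 in the theta grid the count is `1 + (|thetas| - 1) * |phis|`; the
#' defaults yield nine distinct directions covering the hemisphere around
#' the axis.
#'
#' @param axis unit 3-vector (the principal pulling axis).
#' @param thetas,phis numeric vectors of angles in degrees.
#' @return an object of class `direction_set`: list with `axis`, `frame`,
#'   `thetas`, `phis` and `directions` (data frame: label, theta, phi,
#'   vx, vy, vz).
#' @examples
#' dset <- generate_directions(c(0, 0, 1))
#' nrow(dset$directions)  # 9
#' @export
generate_directions <- function(axis, thetas = c(0, 45, 90), phis = c(0, 90, 180, 270)) {
  if (length(thetas) == 0L || length(phis) == 0L) pf_stop_config("theta and phi grids must be non-empty")
  if (!all(is.finite(thetas)) || !all(is.finite(phis))) pf_stop_config("angles must be finite")
  frame <- build_frame(axis)
  thetas <- sort(unique(thetas)); phis <- sort(unique(phis))
  grid <- expand.grid(phi = phis, theta = thetas)[, c("theta", "phi")]
  vecs <- t(mapply(function(th, ph) direction_vector(frame, th, ph), grid$theta, grid$phi))
  keep <- logical(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    dup <- FALSE
    for (j in which(keep)) {
      if (angular_distance(vecs[i, ], vecs[j, ]) < 1e-6) { dup <- TRUE; break }
    }
    keep[i] <- !dup
  }
  d <- data.frame(
    label = direction_label(grid$theta[keep], grid$phi[keep]),
    theta = grid$theta[keep], phi = grid$phi[keep],
    vx = vecs[keep, 1], vy = vecs[keep, 2], vz = vecs[keep, 3],
    stringsAsFactors = FALSE
  )
  structure(list(axis = frame$axis, frame = frame, thetas = thetas, phis = phis,
                 directions = d),
            class = "direction_set")
}

#' @export
print.direction_set <- function(x, ...) {
  cat(sprintf("direction_set: %d directions (theta: %s; phi: %s)\n",
              nrow(x$directions), paste(fmt_angle(x$thetas), collapse = ","),
              paste(fmt_angle(x$phis), collapse = ",")))
  invisible(x)
}

#' @export
as.data.frame.direction_set <- function(x, ...) x$directions

direction_row_vector <- function(dset, i) {
  as.numeric(dset$directions[i, c("vx", "vy", "vz")])
}

#' Write the direction table
#'
#' Serializes a direction set to tab-separated text (label, theta, phi,
#' vx, vy, vz with six decimals); the same format is used as the campaign
#' manifest.
#'
#' @param dset a `direction_set`.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_direction_table <- function(dset, path) {
  d <- dset$directions
  lines <- c("label\ttheta\tphi\tvx\tvy\tvz",
             sprintf("%s\t%s\t%s\t%.6f\t%.6f\t%.6f",
                     d$label, fmt_angle(d$theta), fmt_angle(d$phi), d$vx, d$vy, d$vz))
  writeLines(lines, path)
  invisible(path)
}

read_direction_table <- function(path) {
  if (!file.exists(path)) pf_stop_input(sprintf("manifest not found: %s", path))
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Render a VMD Tcl script drawing the pulling directions
#'
#' One arrow (cylinder plus cone, labelled with the direction name) per
#' direction, drawn from the given origin (typically the pulled group's
#' center of mass) to `origin + scale * vector`.
#'
#' @param dset a `direction_set`.
#' @param origin numeric 3-vector, arrow base in Angstrom.
#' @param scale arrow length in Angstrom.
#' @return the Tcl script as a single character string.
#' @export
render_vmd_arrows <- function(dset, origin = c(0, 0, 0), scale = 10) {
  d <- dset$directions
  if (nrow(d) == 0L) pf_stop_input("empty direction set")
  fmt3 <- function(v) sprintf("%.3f %.3f %.3f", v[1], v[2], v[3])
  blocks <- vapply(seq_len(nrow(d)), function(i) {
    v <- direction_row_vector(dset, i)
    base <- origin
    mid <- origin + 0.8 * scale * v
    tip <- origin + scale * v
    paste(
      sprintf("# arrow %s", d$label[i]),
      sprintf("draw cylinder {%s} {%s} radius 0.30 resolution 16", fmt3(base), fmt3(mid)),
      sprintf("draw cone {%s} {%s} radius 0.60 resolution 16", fmt3(mid), fmt3(tip)),
      sprintf("draw text {%s} \"%s\" size 0.8", fmt3(tip), d$label[i]),
      sep = "\n")
  }, character(1))
  paste(c("# pulling-direction arrows",
          "draw delete all",
          "draw color orange",
          blocks), collapse = "\n")
}
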