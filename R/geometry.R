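# Per-frame geometric metrics: principal-axis alignment, residue
# orientation angle, side-chain centre-of-mass distances, channel-length
# proxy, and their per-replicate time series.

# Atom pairs defining the side-chain reference point of the orientation
# angle. Extensible: any residue type can be added by the caller.
DEFAULT_PAIR_MAP <- list(HIS = c("ND1", "NE2"), ASN = c("OD1", "ND2"))

#' Principal (major) axis of a frame
#'
#' The axis is the eigenvector of the Calpha coordinate covariance with
#' the largest eigenvalue, anchored at the selection centroid. Its sign is
#' fixed so that a named reference residue (by default His67, at the apex
#' of the extracellular CAP) has positive projection, making "toward the
#' CAP" the positive direction.
#'
#' @param frame `StructureFrame`.
#' @param selection atom name(s) used for the covariance (default `"CA"`).
#' @param reference_residue `c(chain_id, resseq)` of the sign reference.
#' @return Object of class `AxisFrame`: list with unit `axis` and
#'   `origin` (both length-3).
#' @export
principal_axis <- function(frame, selection = "CA",
                           reference_residue = c("A", 67)) {
  sel <- select_atoms(frame, atom_name = selection)
  if (nrow(sel) < 3L) stop("need at least 3 atoms for a principal axis")
  xyz <- atom_xyz(sel)
  ctr <- colMeans(xyz)
  cv <- stats::cov(xyz)
  eg <- eigen(cv, symmetric = TRUE)
  if (any(!is.finite(eg$values)) || eg$values[1] <= 0) {
    stop("degenerate atom selection: no principal axis")
  }
  if ((eg$values[1] - eg$values[2]) <= 1e-6 * eg$values[1]) {
    stop("ambiguous principal axis: two leading eigenvalues are equal")
  }
  ax <- eg$vectors[, 1]
  ax <- ax / sqrt(sum(ax^2))
  ref <- select_atoms(frame, chain_id = reference_residue[1],
                      resseq = as.integer(reference_residue[2]),
                      atom_name = "CA")
  if (nrow(ref) == 0L) {
    stop(sprintf("reference residue (%s, %s) has no CA atom",
                 reference_residue[1], reference_residue[2]))
  }
  if (sum((atom_xyz(ref)[1, ] - ctr) * ax) < 0) ax <- -ax
  structure(list(axis = ax, origin = ctr), class = "AxisFrame")
}

pair_point <- function(frame, chain_id, resseq, pair_map) {
  res <- get_residue(frame, chain_id, resseq)
  resname <- res$resname[1]
  pair <- pair_map[[resname]]
  if (is.null(pair)) {
    stop(sprintf("no side-chain atom pair defined for residue type %s",
                 resname))
  }
  pts <- lapply(pair, function(an) {
    row <- res[res$atom_name == an, , drop = FALSE]
    if (nrow(row) == 0L) {
      stop(sprintf("residue (%s, %d, %s) lacks atom %s",
                   chain_id, as.integer(resseq), resname, an))
    }
    as.numeric(row[1, c("x", "y", "z")])
  })
  # unweighted midpoint (equal-mass centre) of the two named atoms
  (pts[[1]] + pts[[2]]) / 2
}

#' Orientation angle of a residue side chain relative to the channel axis
#'
#' The angle between the oriented principal axis and the vector from the
#' residue's Calpha to the midpoint of its two side-chain reference atoms
#' (ND1/NE2 for histidine, OD1/ND2 for asparagine). 0 degrees means the
#' side chain points along the axis toward the extracellular CAP; 90
#' degrees means perpendicular to the pore axis.
#'
#' @param frame `StructureFrame`.
#' @param axisframe `AxisFrame` from [principal_axis()].
#' @param chain_id,resseq residue to measure (e.g. the residue-122 pH
#'   sensor).
#' @param pair_map named list: residue type -> the two side-chain atom
#'   names whose midpoint defines the side-chain direction.
#' @return Angle in degrees, in `[0, 180]`.
#' @export
residue_orientation_angle <- function(frame, axisframe, chain_id, resseq,
                                      pair_map = DEFAULT_PAIR_MAP) {
  res <- get_residue(frame, chain_id, resseq)
  ca <- res[res$atom_name == "CA", , drop = FALSE]
  if (nrow(ca) == 0L) {
    stop(sprintf("residue (%s, %d) lacks a CA atom",
                 chain_id, as.integer(resseq)))
  }
  v <- pair_point(frame, chain_id, resseq, pair_map) -
    as.numeric(ca[1, c("x", "y", "z")])
  nv <- sqrt(sum(v^2))
  if (nv == 0) stop("zero-length side-chain vector")
  cosang <- sum(v * axisframe$axis) / nv
  cosang <- min(1, max(-1, cosang))
  acos(cosang) * 180 / pi
}

sidechain_com <- function(frame, chain_id, resseq) {
  res <- get_residue(frame, chain_id, resseq)
  sc <- sidechain_atoms(res)
  if (nrow(sc) == 0L) {
    stop(sprintf("residue (%s, %d, %s) has no side-chain heavy atoms",
                 chain_id, as.integer(resseq), res$resname[1]))
  }
  m <- ATOMIC_MASSES[sc$element]
  if (anyNA(m)) {
    stop("unknown element(s): ",
         paste(unique(sc$element[is.na(m)]), collapse = ", "))
  }
  colSums(atom_xyz(sc) * m) / sum(m)
}

#' Distance between side-chain centres of mass
#'
#' Euclidean distance between the mass-weighted centres of mass of the
#' side-chain heavy atoms (heavy atoms excluding backbone N, CA, C, O) of
#' two residues. Intra- vs inter-subunit pairs are selected through the
#' chain identifiers.
#'
#' @param frame `StructureFrame`.
#' @param resA,resB `c(chain_id, resseq)` of the two residues.
#' @return Distance in Angstrom.
#' @export
sidechain_com_distance <- function(frame, resA, resB) {
  a <- sidechain_com(frame, resA[1], as.integer(resA[2]))
  b <- sidechain_com(frame, resB[1], as.integer(resB[2]))
  sqrt(sum((a - b)^2))
}

#' Channel-length proxy
#'
#' Calpha-Calpha distance between two residues spanning the structure
#' (by default His67 at the CAP apex and Arg171 in the intracellular
#' TM2-TM3 loop of chain A), used as a proxy for channel length along the
#' principal axis.
#'
#' @param frame `StructureFrame`.
#' @param resI,resJ `c(chain_id, resseq)` anchors.
#' @return Distance in Angstrom.
#' @export
channel_length_proxy <- function(frame, resI = c("A", 67),
                                 resJ = c("A", 171)) {
  ca_of <- function(rr) {
    row <- select_atoms(frame, chain_id = rr[1],
                        resseq = as.integer(rr[2]), atom_name = "CA")
    if (nrow(row) == 0L) {
      stop(sprintf("residue (%s, %s) lacks a CA atom", rr[1], rr[2]))
    }
    as.numeric(row[1, c("x", "y", "z")])
  }
  sqrt(sum((ca_of(resI) - ca_of(resJ))^2))
}

#' Per-frame metric series over a trajectory
#'
#' Evaluates a per-frame metric for every frame of a trajectory, once per
#' subunit for subunit-level metrics. The result carries the trajectory's
#' condition metadata, replicate labels and an equilibration cutoff
#' (frames before the cutoff are excluded from replicate averages; default
#' 50 ns).
#'
#' @param traj `Trajectory`.
#' @param metric one of the built-ins `"angle122"`, `"length"`, or a
#'   function. For `per_subunit = TRUE` the function signature is
#'   `f(frame, chain_id)`; otherwise `f(frame)`.
#' @param per_subunit evaluate once per chain (`TRUE`, replicate =
#'   subunit) or once per frame (`FALSE`, replicate = whole channel).
#' @param equilibration_cutoff_ns frames strictly before this time are
#'   masked out of averages.
#' @param pair_map passed to [residue_orientation_angle()] for
#'   `"angle122"`.
#' @return Object of class `MetricSeries`: data.frame with columns
#'   `time_ns`, `value`, `subunit`, plus attributes `condition` and
#'   `equilibration_cutoff_ns`.
#' @export
metric_series <- function(traj, metric, per_subunit = TRUE,
                          equilibration_cutoff_ns = 50,
                          pair_map = DEFAULT_PAIR_MAP) {
  stopifnot(equilibration_cutoff_ns >= 0)
  chains <- unique(traj$frames[[1]]$atoms$chain_id)
  fn <- metric
  if (is.character(metric)) {
    fn <- switch(metric,
      angle122 = function(frame, chain) {
        ax <- principal_axis(frame)
        residue_orientation_angle(frame, ax, chain, 122L,
                                  pair_map = pair_map)
      },
      length = function(frame) channel_length_proxy(frame),
      stop("unknown built-in metric: ", metric)
    )
    if (metric == "length") per_subunit <- FALSE
  }
  times <- frame_times(traj)
  if (per_subunit) {
    vals <- lapply(chains, function(ch) {
      vapply(traj$frames, fn, numeric(1), ch)
    })
    df <- data.frame(
      time_ns = rep(times, times = length(chains)),
      value = unlist(vals),
      subunit = rep(chains, each = length(times))
    )
  } else {
    df <- data.frame(
      time_ns = times,
      value = vapply(traj$frames, fn, numeric(1)),
      subunit = "channel"
    )
  }
  structure(df,
            condition = traj$condition,
            equilibration_cutoff_ns = equilibration_cutoff_ns,
            class = c("MetricSeries", "data.frame"))
}

#' Equilibrated (post-cutoff) rows of a metric series
#'
#' @param series `MetricSeries`.
#' @return The rows with `time_ns >=` the equilibration cutoff.
#' @export
equilibrated <- function(series) {
  cutoff <- attr(series, "equilibration_cutoff_ns")
  out <- series[series$time_ns >= cutoff, , drop = FALSE]
  if (nrow(out) == 0L) {
    stop("all frames fall before the equilibration cutoff")
  }
  out
}

#' Replicate averages of a metric series
#'
#' Averages the post-cutoff values of a metric series into replicates:
#' one average per subunit (`pooling = "subunit"`, the convention for
#' angles and pairwise distances) or one per trajectory with both
#' subunits pooled (`pooling = "channel"`, the convention for
#' whole-channel metrics such as the length proxy).
#'
#' @param series `MetricSeries`.
#' @param pooling `"subunit"` or `"channel"`.
#' @return data.frame with columns `replicate` and `mean_value`, carrying
#'   the series' condition as an attribute.
#' @export
replicate_averages <- function(series, pooling = c("subunit", "channel")) {
  pooling <- match.arg(pooling)
  eq <- equilibrated(series)
  cond <- attr(series, "condition")
  rep_id <- if (is.null(cond$replicate_id) || is.na(cond$replicate_id))
    "traj" else as.character(cond$replicate_id)
  if (pooling == "subunit") {
    agg <- stats::aggregate(value ~ subunit, data = eq, FUN = mean)
    out <- data.frame(replicate = paste0(rep_id, ".", agg$subunit),
                      mean_value = agg$value)
  } else {
    out <- data.frame(replicate = rep_id, mean_value = mean(eq$value))
  }
  attr(out, "condition") <- cond
  out
}
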