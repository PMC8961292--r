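# Rigid-body and helix geometry.

#' Least-squares rigid superposition (Kabsch algorithm)
#'
#' Finds the proper rotation R (det = +1) and translation t minimising
#' ||mobile %*% R + t - target||^2 over paired coordinates.
#'
#' @param mobile,target n x 3 numeric matrices of paired coordinates
#'   (n >= 3, non-collinear).
#' @return list with `rotation` (3 x 3, applied as `x %*% R`), `translation`
#'   (length-3), `rmsd` after superposition, and `transform(x)`, a function
#'   applying the fit to any n x 3 matrix.
#' @export
kabsch_superpose <- function(mobile, target) {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  if (!all(dim(mobile) == dim(target)) || ncol(mobile) != 3)
    stop("mobile and target must be equal-size n x 3 matrices")
  n <- nrow(mobile)
  if (n < 3) stop("at least 3 paired points are required")
  cm <- colMeans(mobile); ct <- colMeans(target)
  P <- sweep(mobile, 2, cm); Q <- sweep(target, 2, ct)
  # collinearity check: second singular value of the centred cloud
  if (svd(P)$d[2] < 1e-8 * max(1, svd(P)$d[1]))
    stop("points are collinear; rotation is not determined")
  H <- t(P) %*% Q
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$u %*% D %*% t(s$v)   # applied as x %*% R
  t_vec <- ct - as.numeric(cm %*% R)
  fitted <- sweep(mobile %*% R, 2, t_vec, "+")
  rmsd <- sqrt(mean(rowSums((fitted - target)^2)))
  list(rotation = R, translation = t_vec, rmsd = rmsd,
       transform = function(x) sweep(as.matrix(x) %*% R, 2, t_vec, "+"))
}

#' Fit the axis of an alpha-helix from consecutive C-alpha positions
#'
#' Centroids of a sliding window of `window` consecutive C-alpha atoms lie on
#' the helix axis; a least-squares 3-D line (first principal component)
#' through those centroids gives the axis. The direction points from the
#' N-terminal towards the C-terminal (distal) end. Each residue is assigned
#' an azimuthal phase about the axis, measured in a fixed orthonormal frame
#' (`e1`, `e2`) so that phases of different point sets about the same axis are
#' directly comparable.
#'
#' @param ca_coords n x 3 matrix of ordered C-alpha coordinates (n >= 6).
#' @param window sliding-window length for axis centroids (default 4).
#' @return object of class `helix_axis`: `direction` (unit, N->C), `centroid`,
#'   `e1`, `e2`, and `phases` (degrees in \[0, 360)).
#' @export
fit_helix_axis <- function(ca_coords, window = 4) {
  x <- as.matrix(ca_coords)
  if (ncol(x) != 3) stop("ca_coords must be an n x 3 matrix")
  n <- nrow(x)
  if (n < 6) stop("at least 6 consecutive C-alpha positions are required")
  nw <- n - window + 1
  cents <- t(vapply(seq_len(nw), function(i) colMeans(x[i:(i + window - 1), , drop = FALSE]),
                    numeric(3)))
  centroid <- colMeans(cents)
  pc <- prcomp(cents, center = TRUE)
  dir <- pc$rotation[, 1]
  # orient N -> C
  if (sum((cents[nw, ] - cents[1, ]) * dir) < 0) dir <- -dir
  dir <- unit(dir)
  ax <- new_helix_axis(dir, centroid)
  ax$phases <- axis_phases(ax, x)
  ax
}

new_helix_axis <- function(direction, centroid) {
  direction <- unit(direction)
  # reference frame perpendicular to the axis; seeded from the global axis
  # least aligned with the helix so the frame is well conditioned
  seed <- diag(3)[, which.min(abs(direction))]
  e1 <- unit(seed - sum(seed * direction) * direction)
  e2 <- cross3(direction, e1)
  structure(list(direction = direction, centroid = centroid, e1 = e1, e2 = e2),
            class = "helix_axis")
}

#' Azimuthal phases of points about a helix axis
#'
#' @param axis a `helix_axis`.
#' @param coords n x 3 matrix.
#' @return numeric vector of phases in degrees, \[0, 360).
#' @export
axis_phases <- function(axis, coords) {
  x <- as.matrix(coords)
  v <- sweep(x, 2, axis$centroid)
  along <- v %*% axis$direction
  perp <- v - along %*% t(axis$direction)
  wrap360(rad2deg(atan2(perp %*% axis$e2, perp %*% axis$e1)))
}

# Representative side-chain direction point for a residue: C-beta, falling
# back to C-alpha (glycine). Used for rotational phase comparisons, because
# the relevant alignment is of side-chain positions, not backbone.
residue_cb_point <- function(model, chain, resno) {
  a <- model$atoms
  r <- a[a$chain == chain & a$resno == resno, , drop = FALSE]
  if (nrow(r) == 0) return(NULL)
  cb <- r[r$atom == "CB", c("x", "y", "z"), drop = FALSE]
  if (nrow(cb) == 1) return(as.numeric(cb))
  ca <- r[r$atom == "CA", c("x", "y", "z"), drop = FALSE]
  if (nrow(ca) == 1) return(as.numeric(ca))
  NULL
}

residue_ca_point <- function(model, chain, resno) {
  a <- model$atoms
  r <- a[a$chain == chain & a$resno == resno & a$atom == "CA", , drop = FALSE]
  if (nrow(r) == 0) return(NULL)
  as.numeric(r[1, c("x", "y", "z")])
}

#' Rotation of helix 8 that aligns it with the EH-domain alpha-C helix
#'
#' The EH-domain model is first rigidly superposed onto the receptor using the
#' alpha-B <-> TM1/ICL1 C-alpha pairs of the correspondence map. The axis of
#' helix 8 is then fitted from receptor C-alpha atoms, and the rotation about
#' that axis which minimises the summed azimuthal offset between each H8-side
#' position and its (superposed) alpha-C partner is reported. Side-chain
#' facing is represented by C-beta azimuths (C-alpha for glycine).
#'
#' Sign convention: positive angles are clockwise as seen from the distal
#' (C-terminal) end of helix 8, the viewpoint used when describing the
#' TM1/ICL1/H8 pocket.
#'
#' @param gpcr receptor [structure_model()].
#' @param eh2 EH-domain [structure_model()].
#' @param cmap correspondence map, see [eh2_gpcr_correspondence()].
#' @param gpcr_chain,eh2_chain chain identifiers (default: first chain).
#' @param bw_map named integer vector mapping Ballesteros-Weinstein labels to
#'   author residue numbers in `gpcr`. Defaults to the packaged rhodopsin
#'   annotation.
#' @param h8_resnos author residue numbers of the helix-8 C-alpha trace used
#'   for axis fitting; default: all segment-8 residues of `bw_map`.
#' @return list: `angle_deg` (clockwise-positive from the distal end of H8,
#'   in \[0, 360)), `per_pair` offsets, `rmsd_tm1` of the anchoring
#'   superposition.
#' @export
h8_rotation_angle <- function(gpcr, eh2, cmap = eh2_gpcr_correspondence(),
                              gpcr_chain = NULL, eh2_chain = NULL,
                              bw_map = NULL, h8_resnos = NULL) {
  stopifnot(inherits(gpcr, "structure_model"), inherits(eh2, "structure_model"))
  if (is.null(gpcr_chain)) gpcr_chain <- gpcr$atoms$chain[1]
  if (is.null(eh2_chain)) eh2_chain <- eh2$atoms$chain[1]
  if (is.null(bw_map)) bw_map <- rhodopsin_bw_resno_map()
  cmap <- cmap[!cmap$unverified & !is.na(cmap$eh2_resno), , drop = FALSE]
  seg <- sub("\\..*$", "", cmap$bw)
  tm1 <- cmap[seg %in% c("1", "12"), , drop = FALSE]
  h8 <- cmap[seg == "8", , drop = FALSE]
  if (nrow(tm1) < 3) stop("need at least 3 TM1/ICL1-side correspondence pairs")
  if (nrow(h8) < 1) stop("no H8-side correspondence pairs")

  resno_of_bw <- function(bw) {
    if (!bw %in% names(bw_map)) return(NA_integer_)
    as.integer(bw_map[[bw]])
  }
  # anchoring superposition: alpha-B CA -> TM1/ICL1 CA
  pull_pairs <- function(rows) {
    g <- lapply(rows$bw, function(b) {
      rn <- resno_of_bw(b)
      if (is.na(rn)) NULL else residue_ca_point(gpcr, gpcr_chain, rn)
    })
    e <- lapply(rows$eh2_resno, function(rn) residue_ca_point(eh2, eh2_chain, rn))
    ok <- !vapply(g, is.null, logical(1)) & !vapply(e, is.null, logical(1))
    if (any(!ok))
      stop("missing correspondence residues: ",
           paste(rows$bw[!ok], collapse = ", "))
    list(g = do.call(rbind, g[ok]), e = do.call(rbind, e[ok]))
  }
  anchor <- pull_pairs(tm1)
  fit <- kabsch_superpose(anchor$e, anchor$g)

  # helix-8 axis from receptor C-alpha trace
  if (is.null(h8_resnos)) {
    segs <- sub("\\..*$", "", names(bw_map))
    h8_resnos <- sort(as.integer(bw_map[segs == "8"]))
  }
  h8_ca <- do.call(rbind, lapply(h8_resnos, function(rn)
    residue_ca_point(gpcr, gpcr_chain, rn)))
  if (is.null(h8_ca) || nrow(h8_ca) < 6)
    stop("need at least 6 helix-8 C-alpha positions to fit the axis")
  axis <- fit_helix_axis(h8_ca)

  offsets <- vapply(seq_len(nrow(h8)), function(k) {
    rn_g <- resno_of_bw(h8$bw[k])
    p_g <- residue_cb_point(gpcr, gpcr_chain, rn_g)
    p_e_raw <- residue_cb_point(eh2, eh2_chain, h8$eh2_resno[k])
    if (is.null(p_g) || is.null(p_e_raw))
      stop("missing correspondence residues: ", h8$bw[k])
    p_e <- as.numeric(fit$transform(matrix(p_e_raw, 1)))
    ph_g <- axis_phases(axis, matrix(p_g, 1))
    ph_e <- axis_phases(axis, matrix(p_e, 1))
    as.numeric(ph_e - ph_g)
  }, numeric(1))
  # rotation about the N->C axis carrying H8 side chains onto alpha-C partners
  ccw <- circ_mean_deg(offsets)
  angle_cw <- wrap360(-ccw)   # clockwise viewed from the distal (+axis) end
  list(angle_deg = angle_cw,
       per_pair = data.frame(bw = h8$bw, eh2_resno = h8$eh2_resno,
                             offset_ccw_deg = wrap360(offsets)),
       rmsd_tm1 = fit$rmsd)
}
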