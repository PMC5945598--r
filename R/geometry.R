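# Least-squares superposition (Kabsch), rigid transforms, and screw-axis
# decomposition between rigid bodies of two conformers.

#' Rigid transforms
#'
#' A `rigid_transform` maps a point `p` to `R p + t`, with `R` a proper
#' rotation (det = +1) and `t` a translation in angstrom.
#'
#' @param R 3x3 proper orthogonal matrix.
#' @param t translation 3-vector.
#' @param rmsd,n_atoms optional fit diagnostics attached by [superpose()].
#' @return a `rigid_transform` object.
#' @export
rigid_transform <- function(R = diag(3), t = c(0, 0, 0), rmsd = NA_real_,
                            n_atoms = NA_integer_) {
  R <- unname(as.matrix(R)); t <- as.numeric(t)
  stopifnot(all(dim(R) == c(3, 3)), length(t) == 3)
  if (max(abs(R %*% t(R) - diag(3))) > 1e-9 || abs(det(R) - 1) > 1e-9) {
    abort("R is not a proper rotation matrix (orthogonality/determinant tolerance 1e-9)")
  }
  structure(list(R = R, t = t, rmsd = rmsd, n_atoms = n_atoms),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform>")
  if (!is.na(x$rmsd)) cat(sprintf(" rmsd %.4f A over %d atoms", x$rmsd, x$n_atoms))
  cat("\n rotation:\n")
  print(round(x$R, 6))
  cat(" translation:", paste(sprintf("%.4f", x$t), collapse = " "), "\n")
  invisible(x)
}

#' Apply a rigid transform to a model or coordinate matrix
#' @param x a `struct_tbl` or an n x 3 coordinate matrix.
#' @param tf a [rigid_transform()].
#' @return object of the same type with transformed coordinates.
#' @export
apply_transform <- function(x, tf) {
  if (is.matrix(x)) return(sweep(x %*% t(tf$R), 2, tf$t, "+"))
  set_coords(x, apply_transform(coords(x), tf))
}

#' Compose two rigid transforms
#' @param tf2,tf1 transforms; the result applies `tf1` first, then `tf2`.
#' @return a [rigid_transform()].
#' @export
compose_transform <- function(tf2, tf1) {
  rigid_transform(tf2$R %*% tf1$R, as.vector(tf2$R %*% tf1$t) + tf2$t)
}

#' Invert a rigid transform
#' @param tf a [rigid_transform()].
#' @return the inverse [rigid_transform()].
#' @export
invert_transform <- function(tf) {
  rigid_transform(t(tf$R), as.vector(-t(tf$R) %*% tf$t))
}

# core Kabsch: optimal proper rotation + translation carrying P onto Q
kabsch <- function(P, Q) {
  pbar <- colMeans(P); qbar <- colMeans(Q)
  Pc <- sweep(P, 2, pbar); Qc <- sweep(Q, 2, qbar)
  H <- t(Pc) %*% Qc
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t <- qbar - as.vector(R %*% pbar)
  fitted <- sweep(Pc %*% t(R), 2, qbar, "+")
  rmsd <- sqrt(mean(rowSums((fitted - Q)^2)))
  list(R = R, t = t, rmsd = rmsd, singular = sv$d)
}

match_atoms <- function(mobile, reference, selection, atom_set, match_by) {
  sel <- if (is.null(selection)) NULL else residue_selection(selection)
  pick <- function(m) {
    m <- filter(as_struct(m), !.data$het)
    if (!is.null(sel)) m <- select_residues(m, sel)
    if (atom_set == "CA") m <- filter(m, .data$atom == "CA")
    else m <- filter(m, .data$element != "H")
    m
  }
  a <- pick(mobile); b <- pick(reference)
  if (nrow(a) == 0 || nrow(b) == 0) abort("selection resolves to no atoms")
  keys <- if (match_by == "resno_atom") c("resno", "insert", "atom")
          else c("chain", "resno", "insert", "atom")
  ka <- do.call(paste, c(as_tibble(a)[keys], sep = "|"))
  kb <- do.call(paste, c(as_tibble(b)[keys], sep = "|"))
  if (anyDuplicated(ka) || anyDuplicated(kb)) {
    abort(paste0("ambiguous atom matching (duplicate keys) under match_by = '",
                 match_by, "'"))
  }
  # residues present on one side only
  rk <- if (match_by == "resno_atom") c("resno", "insert") else c("chain", "resno", "insert")
  ra <- unique(do.call(paste, c(as_tibble(a)[rk], sep = "|")))
  rb <- unique(do.call(paste, c(as_tibble(b)[rk], sep = "|")))
  lost <- c(setdiff(ra, rb), setdiff(rb, ra))
  idx <- match(ka, kb)
  if (all(is.na(idx)) || sum(!is.na(idx)) < 3) {
    abort(paste0("fewer than 3 matched atom pairs in selection",
                 if (length(lost) > 0) paste0("; unmatched residues: ",
                                              paste(utils::head(lost, 10), collapse = ", "))))
  }
  if (length(lost) > 0) {
    warn(paste0("residues unmatched between models (ignored): ",
                paste(utils::head(lost, 10), collapse = ", "),
                if (length(lost) > 10) " ..."))
  }
  list(P = coords(a)[!is.na(idx), , drop = FALSE],
       Q = coords(b)[idx[!is.na(idx)], , drop = FALSE])
}

#' Optimal superposition of one model onto another
#'
#' Computes the least-squares optimal proper rotation and translation (no
#' reflection; Kabsch algorithm via SVD) carrying the selected atoms of
#' `mobile` onto the matching atoms of `reference`, together with the
#' post-fit RMSD over the selection. Atoms are matched by
#' `(chain, resno, insert, atom name)`, or without the chain id when
#' `match_by = "resno_atom"` (useful across filament subunits whose chains
#' differ but whose numbering is shared).
#'
#' @param mobile,reference `struct_tbl` models.
#' @param selection residues used for the fit (string, tibble, or `NULL` for
#'   all residues).
#' @param atom_set `"CA"` (default) or `"all_heavy"`.
#' @param match_by `"chain_resno_atom"` (default) or `"resno_atom"`.
#' @return a [rigid_transform()] with `rmsd` and `n_atoms` filled in.
#' @export
superpose <- function(mobile, reference, selection = NULL,
                      atom_set = c("CA", "all_heavy"),
                      match_by = c("chain_resno_atom", "resno_atom")) {
  atom_set <- match.arg(atom_set)
  match_by <- match.arg(match_by)
  m <- match_atoms(mobile, reference, selection, atom_set, match_by)
  if (nrow(m$P) < 3) abort("superposition needs at least 3 matched atom pairs")
  k <- kabsch(m$P, m$Q)
  # collinear/degenerate: centered coordinates must span at least 2 dimensions
  if (k$singular[2] < 1e-8 * max(k$singular[1], 1)) {
    abort("degenerate (collinear) atom configuration: superposition is not unique")
  }
  rigid_transform(k$R, k$t, rmsd = k$rmsd, n_atoms = nrow(m$P))
}

#' Fit RMSD between matched atoms without refitting
#' @noRd
transform_rmsd <- function(P, Q, tf) {
  sqrt(mean(rowSums((apply_transform(P, tf) - Q)^2)))
}

# ---- screw axes --------------------------------------------------------------

#' Screw axes
#'
#' A `screw_axis` describes a rigid motion as a rotation of `angle_deg`
#' degrees about a directed line (unit `direction` through `point`) plus a
#' translation of `translation_along_axis` angstrom along that line. For an
#' identity rotation the motion has no defined axis: `no_rotation` is set and
#' [axis_direction()] raises an error.
#'
#' @param direction unit 3-vector.
#' @param point a point on the axis (angstrom).
#' @param angle_deg rotation magnitude in degrees, in (0, 180].
#' @param translation_along_axis angstrom.
#' @param no_rotation flag for the degenerate identity case.
#' @return a `screw_axis` object.
#' @export
screw_axis <- function(direction, point, angle_deg, translation_along_axis,
                       no_rotation = FALSE) {
  if (!no_rotation) {
    direction <- as.numeric(direction)
    if (abs(sqrt(sum(direction^2)) - 1) > 1e-9) {
      abort("screw axis direction must be a unit vector (tolerance 1e-9)")
    }
    if (angle_deg <= 0) abort("angle_deg must be > 0 for a non-identity screw motion")
  }
  structure(list(direction = if (no_rotation) rep(NA_real_, 3) else direction,
                 point = as.numeric(point), angle_deg = angle_deg,
                 translation_along_axis = translation_along_axis,
                 no_rotation = no_rotation),
            class = "screw_axis")
}

#' @export
print.screw_axis <- function(x, ...) {
  if (x$no_rotation) {
    cat("<screw_axis> no rotation (identity)\n")
  } else {
    cat(sprintf("<screw_axis> %.1f deg about (%.4f, %.4f, %.4f), axial shift %.2f A\n",
                x$angle_deg, x$direction[1], x$direction[2], x$direction[3],
                x$translation_along_axis))
    cat(sprintf("  through point (%.2f, %.2f, %.2f)\n",
                x$point[1], x$point[2], x$point[3]))
  }
  invisible(x)
}

#' Direction of a screw axis
#'
#' Errors on the degenerate "no rotation" case, where the direction is
#' undefined.
#' @param sa a [screw_axis()].
#' @return unit 3-vector.
#' @export
axis_direction <- function(sa) {
  if (isTRUE(sa$no_rotation)) abort("no rotation: axis direction is undefined")
  sa$direction
}

#' @export
tidy.screw_axis <- function(x, ...) {
  tibble(angle_deg = x$angle_deg,
         dir_x = x$direction[1], dir_y = x$direction[2], dir_z = x$direction[3],
         point_x = x$point[1], point_y = x$point[2], point_z = x$point[3],
         translation_along_axis = x$translation_along_axis,
         no_rotation = x$no_rotation)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

#' Screw (axis-angle) decomposition of a rigid transform
#'
#' Every non-identity rigid motion is a rotation about a unique axis plus a
#' translation along it (Chasles' theorem). The returned `point` is the axis
#' point closest to the origin; see [screw_point_near()] to slide it along
#' the axis.
#'
#' @param tf a [rigid_transform()].
#' @param tol rotation angle (radians) below which the motion is treated as
#'   a pure translation ("no rotation").
#' @return a [screw_axis()].
#' @export
rotation_to_axis_angle <- function(tf, tol = 1e-9) {
  R <- tf$R; t <- tf$t
  ctheta <- (sum(diag(R)) - 1) / 2
  ctheta <- min(1, max(-1, ctheta))
  theta <- acos(ctheta)
  if (theta < tol) {
    return(screw_axis(NULL, c(0, 0, 0), 0, sqrt(sum(t^2)), no_rotation = TRUE))
  }
  v <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  if (sqrt(sum(v^2)) > 1e-6) {
    a <- v / sqrt(sum(v^2))
  } else {
    # theta near pi: use the symmetric part, pick the dominant column of R + I
    B <- R + diag(3)
    j <- which.max(colSums(B^2))
    a <- B[, j] / sqrt(sum(B[, j]^2))
    # fix sign so that the antisymmetric part (however small) agrees
    if (sum(v * a) < 0) a <- -a
  }
  d_axial <- sum(t * a)
  t_perp <- t - d_axial * a
  # axis point: solves (I - R) p = t_perp with p orthogonal to a
  p <- 0.5 * (t_perp + cross3(a, t_perp) / tan(theta / 2))
  screw_axis(a, p, angle_deg = theta * 180 / pi,
             translation_along_axis = d_axial)
}

#' Rebuild the rigid transform encoded by a screw axis
#' @param sa a [screw_axis()].
#' @return a [rigid_transform()].
#' @export
screw_to_transform <- function(sa) {
  if (sa$no_rotation) {
    return(rigid_transform(diag(3), c(0, 0, 0)))
  }
  R <- rotation_about_axis(sa$direction, sa$angle_deg)
  t <- sa$point - as.vector(R %*% sa$point) + sa$translation_along_axis * sa$direction
  rigid_transform(R, t)
}

#' Rotation matrix about an arbitrary axis
#' @param direction axis direction (normalized internally).
#' @param angle_deg rotation angle in degrees (right-handed about `direction`).
#' @return 3x3 rotation matrix.
#' @export
rotation_about_axis <- function(direction, angle_deg) {
  a <- direction / sqrt(sum(direction^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Slide the anchor point of a screw axis to the point nearest `x`
#' @param sa a [screw_axis()].
#' @param x a 3-vector (e.g. a domain centroid).
#' @return the [screw_axis()] with `point` replaced by the nearest axis point.
#' @export
screw_point_near <- function(sa, x) {
  if (sa$no_rotation) return(sa)
  a <- sa$direction
  sa$point <- sa$point + sum((x - sa$point) * a) * a
  sa
}

#' Inter-domain rotation axis between two conformers
#'
#' Determines the screw axis describing how `moving_body` reorients relative
#' to `fixed_body` between two conformers: (1) `conf_b` is superposed onto
#' `conf_a` over the fixed body; (2) the residual transform carrying
#' `conf_a`'s moving body onto the fixed-body-aligned `conf_b` moving body is
#' computed; (3) its screw decomposition is returned, with the anchor point
#' slid to the position nearest the moving body's centroid so that rendered
#' axes pass through the molecule. This is the operation behind inter-domain
#' rotation angles such as the 15.0 degree G-to-F and 6.0 degree G-to-C
#' outer-domain rotations of actin.
#'
#' @param conf_a,conf_b conformer models (`struct_tbl`).
#' @param fixed_body,moving_body residue selections for the two rigid bodies.
#' @param atom_set `"CA"` (default) or `"all_heavy"`.
#' @param match_by atom matching rule, see [superpose()].
#' @return a [screw_axis()] with extra fields `rmsd_fixed` and `rmsd_moving`.
#' @export
screw_axis_between <- function(conf_a, conf_b, fixed_body, moving_body,
                               atom_set = c("CA", "all_heavy"),
                               match_by = c("chain_resno_atom", "resno_atom")) {
  atom_set <- match.arg(atom_set)
  match_by <- match.arg(match_by)
  tf_fix <- superpose(conf_b, conf_a, fixed_body, atom_set, match_by)
  b_aligned <- apply_transform(as_struct(conf_b), tf_fix)
  tf_res <- superpose(conf_a, b_aligned, moving_body, atom_set, match_by)
  sa <- rotation_to_axis_angle(tf_res)
  mov <- select_residues(as_struct(conf_a), moving_body)
  mov <- filter(mov, if (atom_set == "CA") .data$atom == "CA" else .data$element != "H")
  sa <- screw_point_near(sa, colMeans(coords(mov)))
  sa$rmsd_fixed <- tf_fix$rmsd
  sa$rmsd_moving <- tf_res$rmsd
  sa
}

#' Write a two-pseudo-atom PDB trace of a screw axis for visualisation
#' @param sa a [screw_axis()].
#' @param path output PDB path.
#' @param half_length half-length of the traced segment in angstrom.
#' @return `path`, invisibly.
#' @export
write_axis_trace <- function(sa, path, half_length = 40) {
  p1 <- sa$point - half_length * axis_direction(sa)
  p2 <- sa$point + half_length * axis_direction(sa)
  m <- struct_tbl(tibble(atom = "CA", chain = "X", resno = c(1L, 2L),
                         resid = "AXS", element = "C",
                         x = c(p1[1], p2[1]), y = c(p1[2], p2[2]),
                         z = c(p1[3], p2[3])), id = "axis")
  write_structure(m, path)
}
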