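# Seed-deterministic synthetic structure generators with planted ground
# truth: two-domain hinge ensembles, (decorated) helical filaments, and
# contact/collision fixtures. These stand in for cryo-EM-derived atomic
# models in tests: every generator returns coordinates plus a machine-
# readable truth record of what was planted.

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  }
  force(code)
}

# idealized Calpha helix trace: n residues, ~1.5 A rise and 100 deg turn per
# residue about `axis` starting at `origin`; returns n x 3 matrix
ca_helix <- function(n, origin = c(0, 0, 0), axis = c(1, 0, 0), radius = 2.3,
                     phase = 0) {
  a <- axis / sqrt(sum(axis^2))
  ref <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- cross3(a, ref); u <- u / sqrt(sum(u^2))
  v <- cross3(a, u)
  k <- seq_len(n) - 1
  th <- phase + k * 100 * pi / 180
  t(vapply(seq_len(n), function(i) {
    origin + 1.5 * k[i] * a + radius * (cos(th[i]) * u + sin(th[i]) * v)
  }, numeric(3)))
}

# Calpha trace + pseudo side-chain (CB) atoms for a chain of residues at the
# given Calpha positions; CB is offset 1.5 A in a residue-specific direction
chain_atoms <- function(ca, chain = "A", resno = seq_len(nrow(ca)),
                        element = "C", with_cb = TRUE) {
  n <- nrow(ca)
  rows <- list(tibble(atom = "CA", chain = chain, resno = resno, resid = "ALA",
                      element = element, x = ca[, 1], y = ca[, 2], z = ca[, 3]))
  if (with_cb) {
    dirs <- t(vapply(seq_len(n), function(i) {
      d <- if (i < n) ca[i + 1, ] - ca[i, ]
           else if (n > 1) ca[i, ] - ca[i - 1, ]
           else c(1, 0, 0)
      ref <- c(0.3, 0.5, 0.81)
      o <- cross3(d, ref)
      nrm <- sqrt(sum(o^2))
      if (nrm < 1e-8) o <- c(0, 0, 1) else o <- o / nrm
      o
    }, numeric(3)))
    rows[[2]] <- tibble(atom = "CB", chain = chain, resno = resno, resid = "ALA",
                        element = element,
                        x = ca[, 1] + 1.5 * dirs[, 1],
                        y = ca[, 2] + 1.5 * dirs[, 2],
                        z = ca[, 3] + 1.5 * dirs[, 3])
  }
  bind_rows(rows) |> arrange(.data$resno, .data$atom)
}

#' Synthetic two-domain hinge ensemble
#'
#' Generates `length(angles_deg)` conformers of a two-domain protein with a
#' planted rigid core: body A (residues `1..n_res_a`) is fixed, body B
#' (`n_res_a+1 .. n_res_a+n_res_b`) is rotated by the conformer-specific
#' planted angle about `hinge_axis` through `hinge_point`, and an optional
#' flexible tail (`n_flexible` residues) receives 5x the coordinate noise,
#' mimicking disordered loops. Every atom then receives isotropic Gaussian
#' noise of SD `noise_sd` per coordinate. Body B is laid out so that its
#' residues stay at least ~10 angstrom from the hinge axis, which makes the
#' planted rotations resolvable from positional SDs. Output is
#' seed-deterministic (same seed, bitwise-identical coordinates).
#'
#' @param n_res_a,n_res_b,n_flexible residue counts of body A, body B and
#'   the flexible tail.
#' @param angles_deg planted per-conformer hinge angles (degrees).
#' @param hinge_axis planted rotation axis (unit vector; normalized).
#' @param noise_sd per-coordinate Gaussian noise SD in angstrom.
#' @param seed integer seed.
#' @param absent optional named list: member name (or index as `"m3"`) to
#'   residue numbers deleted from that member, emulating unmodelled regions.
#' @param dir optional directory; when given, each member is written as a
#'   PDB file and the ground truth as JSON.
#' @return list with `members` (named list of `struct_tbl`) and `truth`
#'   (list: body memberships, hinge axis/point, angles, noise, seed).
#' @export
make_two_domain_ensemble <- function(n_res_a = 120, n_res_b = 40,
                                     n_flexible = 0,
                                     angles_deg = c(0, 6, 15),
                                     hinge_axis = c(0, 0, 1),
                                     noise_sd = 0, seed = 1,
                                     absent = list(), dir = NULL) {
  hinge_axis <- hinge_axis / sqrt(sum(hinge_axis^2))
  hinge_point <- c(0, 0, 0)
  # frame: body B extends away from the hinge axis, starting 10 A out,
  # perpendicular to the axis
  perp <- if (abs(hinge_axis[1]) < 0.9) cross3(hinge_axis, c(1, 0, 0)) else cross3(hinge_axis, c(0, 1, 0))
  perp <- perp / sqrt(sum(perp^2))
  base_a <- ca_helix(n_res_a, origin = hinge_point - 6 * perp - 3 * hinge_axis,
                     axis = -perp)
  base_b <- ca_helix(n_res_b + n_flexible, origin = hinge_point + 10 * perp,
                     axis = perp)
  n_total <- n_res_a + n_res_b + n_flexible
  body_a <- seq_len(n_res_a)
  body_b <- n_res_a + seq_len(n_res_b)
  flexible <- if (n_flexible > 0) n_res_a + n_res_b + seq_len(n_flexible) else integer()

  members <- with_seed(seed, {
    purrr::imap(setNames(angles_deg, paste0("m", seq_along(angles_deg))),
                function(angle, nm) {
      R <- rotation_about_axis(hinge_axis, angle)
      xb <- sweep(sweep(base_b, 2, hinge_point) %*% t(R), 2, hinge_point, "+")
      ca <- rbind(base_a, xb)
      at <- chain_atoms(ca, chain = "A")
      sd_per_atom <- ifelse(at$resno %in% flexible, 5 * noise_sd, noise_sd)
      if (noise_sd > 0) {
        at$x <- at$x + rnorm(nrow(at), 0, sd_per_atom)
        at$y <- at$y + rnorm(nrow(at), 0, sd_per_atom)
        at$z <- at$z + rnorm(nrow(at), 0, sd_per_atom)
      }
      gone <- absent[[nm]]
      if (!is.null(gone)) at <- filter(at, !(.data$resno %in% gone))
      struct_tbl(at, id = nm)
    })
  })
  truth <- list(body_a = body_a, body_b = body_b, flexible = flexible,
                hinge_axis = hinge_axis, hinge_point = hinge_point,
                angles_deg = angles_deg, noise_sd = noise_sd, seed = seed,
                n_members = length(angles_deg), absent = absent)
  if (!is.null(dir)) write_fixture(members, truth, dir)
  list(members = members, truth = truth)
}

#' Synthetic (optionally decorated) helical filament
#'
#' Builds a dummy-protomer filament under exact helical symmetry and, when
#' `decorated = TRUE`, adds one compact cofilin-like chain bridging each
#' same-strand subunit pair `(k, k+2)`. The default decorated symmetry is
#' the cofilin-decorated filament geometry (twist -162.1 deg, rise 27.6 A);
#' undecorated filaments default to the canonical actin filament values
#' (-166.6 deg, 27.5 A). Each cofilin-like chain is placed radially outside
#' the filament with two deliberate near-contacts (3.2 angstrom, inside the
#' interface cut but outside the collision cut for carbon) to its two
#' partner subunits, so interface detection and barbed/pointed pairing have
#' a planted ground truth and the decorated filament is collision-free at
#' the default radii. Optional isotropic noise perturbs all coordinates
#' after construction.
#'
#' @param protomer_size residues per dummy protomer.
#' @param twist_deg,rise genetic helical parameters; `NULL` picks the
#'   decorated/undecorated default.
#' @param n_subunits number of actin-like subunits.
#' @param decorated add cofilin-like bridging chains.
#' @param cofilin_size residues per cofilin-like chain.
#' @param noise_sd per-coordinate Gaussian noise SD (applied to everything).
#' @param seed integer seed.
#' @param dir optional output directory (PDB + truth JSON).
#' @return list with `filament` (`struct_tbl` with `subunit` column, cofilin
#'   chains `subunit = NA`, `decoration` attribute) and `truth`.
#' @export
make_decorated_filament <- function(protomer_size = 20, twist_deg = NULL,
                                    rise = NULL, n_subunits = 6,
                                    decorated = TRUE, cofilin_size = 12,
                                    noise_sd = 0, seed = 1, dir = NULL) {
  twist_deg <- twist_deg %||% if (decorated) -162.1 else -166.6
  rise <- rise %||% if (decorated) 27.6 else 27.5
  sym <- helical_symmetry(twist_deg, rise)
  # protomer: compact helical blob with its centroid ~12 A off the z axis,
  # plus a radially protruding "handle" CB used as the cofilin anchor
  ca <- ca_helix(protomer_size, origin = c(12, -2, 0), axis = c(0.2, 1, 0.25))
  prot <- chain_atoms(ca, chain = "A")
  mid <- ceiling(protomer_size / 2)
  # make the handle atom stick out radially from the axis
  hrow <- which(prot$atom == "CB" & prot$resno == mid)
  p <- c(prot$x[hrow], prot$y[hrow], prot$z[hrow])
  rad <- c(p[1], p[2], 0); rad <- rad / sqrt(sum(rad^2))
  rmax <- max(sqrt(prot$x^2 + prot$y^2))
  pout <- rad * (rmax + 2.0); pout[3] <- p[3]
  prot$x[hrow] <- pout[1]; prot$y[hrow] <- pout[2]; prot$z[hrow] <- pout[3]
  protomer <- struct_tbl(prot, id = "synthprot")

  fil <- build_filament(protomer, sym, n_subunits)
  dec <- NULL
  if (decorated && n_subunits >= 3) {
    pairs <- tibble(b_subunit = seq_len(n_subunits - 2L),
                    p_subunit = seq_len(n_subunits - 2L) + 2L)
    taken <- unique(fil$chain)
    cof_chains <- next_free_chains(taken, nrow(pairs))
    handle_of <- function(k) {
      s <- filter(fil, .data$subunit == k, .data$atom == "CB", .data$resno == mid)
      c(s$x[1], s$y[1], s$z[1])
    }
    cofs <- purrr::map(seq_len(nrow(pairs)), function(i) {
      h1 <- handle_of(pairs$b_subunit[i])
      h2 <- handle_of(pairs$p_subunit[i])
      out1 <- c(h1[1], h1[2], 0); out1 <- out1 / sqrt(sum(out1^2))
      out2 <- c(h2[1], h2[2], 0); out2 <- out2 / sqrt(sum(out2^2))
      # interface (< 1.1*3.4 = 3.74) but no collision (> 0.5*3.4 = 1.7); the
      # +-1.6 A axial offsets keep symmetry-related cofilin termini apart
      q1 <- h1 + 3.2 * out1 + c(0, 0, -1.6)
      q2 <- h2 + 3.2 * out2 + c(0, 0, 1.6)
      tt <- seq(0, 1, length.out = cofilin_size)
      # arc bulging outward so intermediate atoms stay clear of the filament
      bulge <- 4 * sin(pi * tt)
      pos <- t(vapply(seq_along(tt), function(j) {
        base <- (1 - tt[j]) * q1 + tt[j] * q2
        o <- c(base[1], base[2], 0); o <- o / max(sqrt(sum(o^2)), 1e-9)
        base + bulge[j] * o
      }, numeric(3)))
      pos[1, ] <- q1; pos[cofilin_size, ] <- q2
      tibble(atom = "CA", chain = cof_chains[i], resno = seq_len(cofilin_size),
             resid = "COF", element = "C",
             x = pos[, 1], y = pos[, 2], z = pos[, 3],
             subunit = NA_integer_, chain_orig = NA_character_)
    })
    dec <- tibble(cofilin_chain = cof_chains, b_subunit = pairs$b_subunit,
                  p_subunit = pairs$p_subunit)
    fil <- struct_tbl(bind_rows(as_tibble(fil), bind_rows(cofs)),
                      id = paste0("synthfil_dec", n_subunits))
  }
  if (noise_sd > 0) {
    fil <- with_seed(seed, {
      fil$x <- fil$x + rnorm(nrow(fil), 0, noise_sd)
      fil$y <- fil$y + rnorm(nrow(fil), 0, noise_sd)
      fil$z <- fil$z + rnorm(nrow(fil), 0, noise_sd)
      fil
    })
  }
  attr(fil, "symmetry") <- sym
  attr(fil, "decoration") <- dec
  truth <- list(twist_deg = twist_deg, rise = rise, n_subunits = n_subunits,
                decorated = decorated, protomer_size = protomer_size,
                cofilin_size = cofilin_size, noise_sd = noise_sd, seed = seed,
                decoration = dec, axis_point = c(0, 0, 0),
                axis_direction = c(0, 0, 1))
  if (!is.null(dir)) write_fixture(list(filament = fil), truth, dir)
  list(filament = fil, truth = truth)
}

#' Synthetic two-chain contact/collision fixture
#'
#' Places `n_interface` carbon-atom pairs across two chains such that, at
#' the default contact configuration, the interface pair count is exactly
#' `n_interface`, of which exactly `n_collide` are collisions (and the
#' colliding-atom counts per chain equal `n_collide` as well). Anchor atoms
#' are spaced 10 angstrom apart so no cross-pair contacts arise; each
#' partner sits at 1.2 angstrom (collision) or 3.0 angstrom (interface
#' only) from its anchor, in a seed-dependent direction.
#'
#' @param n_interface total interface pair count (>= 0).
#' @param n_collide collision pair count; must not exceed `n_interface`.
#' @param seed integer seed.
#' @param dir optional output directory (PDB + truth JSON).
#' @return list with `model` (two-chain `struct_tbl`) and `truth`.
#' @export
make_clash_fixture <- function(n_interface, n_collide, seed = 1, dir = NULL) {
  if (n_collide > n_interface) {
    abort("infeasible request: n_collide must not exceed n_interface")
  }
  n <- max(n_interface, 1L)
  model <- with_seed(seed, {
    phi <- runif(n, 0, 2 * pi)
    dists <- c(rep(1.2, n_collide), rep(3.0, n_interface - n_collide))
    if (n_interface == 0) dists <- rep(100, n)   # far apart: empty report
    a <- tibble(atom = "CA", chain = "A", resno = seq_len(n), resid = "FIX",
                element = "C", x = 10 * seq_len(n), y = 0, z = 0)
    b <- tibble(atom = "CA", chain = "B", resno = seq_len(n), resid = "FIX",
                element = "C",
                x = 10 * seq_len(n),
                y = dists * cos(phi),
                z = dists * sin(phi))
    struct_tbl(bind_rows(a, b), id = paste0("clash_", n_interface, "_", n_collide))
  })
  truth <- list(n_interface = n_interface, n_collide = n_collide, seed = seed)
  if (!is.null(dir)) write_fixture(list(model = model), truth, dir)
  list(model = model, truth = truth)
}

write_fixture <- function(models, truth, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in names(models)) {
    write_structure(models[[nm]], file.path(dir, paste0(nm, ".pdb")))
  }
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
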