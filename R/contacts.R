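# Interface and steric-collision determination between two molecules using
# van der Waals distance criteria.

#' Bondi van der Waals radii
#'
#' The default radii table (Bondi 1964): C 1.70, N 1.55, O 1.52, S 1.80,
#' P 1.80, Mg 1.73, H 1.20 angstrom.
#'
#' @return named numeric vector, element symbol to radius in angstrom.
#' @export
bondi_radii <- function() {
  c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, MG = 1.73)
}

#' Contact-analysis configuration
#'
#' An atom pair (one atom from each molecule) is part of the interface when
#' its distance is strictly less than `interface_factor` times the sum of the
#' two van der Waals radii, and a steric collision when the distance is
#' strictly less than `collision_factor` times that sum (non-hydrogen atoms
#' only, unless `collision_excludes_hydrogen = FALSE`). The defaults, 1.1 and
#' 0.5, are the interface and collision criteria used for cofilactin/F-actin
#' model analysis.
#'
#' @param radii named vector of vdW radii (angstrom) keyed by element symbol.
#' @param interface_factor dimensionless multiplier for the interface cut.
#' @param collision_factor dimensionless multiplier for the collision cut;
#'   must satisfy `0 < collision_factor < interface_factor`.
#' @param collision_excludes_hydrogen restrict collisions to heavy atoms.
#' @param default_radius radius used for elements absent from `radii`
#'   (`NULL` = error on unknown elements).
#' @return a `contact_config` object.
#' @export
contact_config <- function(radii = bondi_radii(), interface_factor = 1.1,
                           collision_factor = 0.5,
                           collision_excludes_hydrogen = TRUE,
                           default_radius = NULL) {
  if (!(collision_factor > 0 && collision_factor < interface_factor)) {
    abort("need 0 < collision_factor < interface_factor")
  }
  if (is.null(names(radii)) || any(!nzchar(names(radii)))) {
    abort("radii must be a named vector keyed by element symbol")
  }
  structure(list(radii = setNames(as.numeric(radii), toupper(names(radii))),
                 interface_factor = interface_factor,
                 collision_factor = collision_factor,
                 collision_excludes_hydrogen = collision_excludes_hydrogen,
                 default_radius = default_radius),
            class = "contact_config")
}

atom_radii <- function(m, config) {
  r <- config$radii[toupper(m$element)]
  if (anyNA(r)) {
    if (is.null(config$default_radius)) {
      i <- which(is.na(r))[1]
      abort(paste0("no van der Waals radius for element '", m$element[i],
                   "' (atom ", m$chain[i], ":", m$resno[i], " ", m$atom[i],
                   "); supply it in the radii table or set default_radius"))
    }
    r[is.na(r)] <- config$default_radius
  }
  unname(r)
}

#' Find interface and collision atom pairs between two molecules
#'
#' All inter-molecular atom pairs closer than the interface criterion are
#' reported, with collisions flagged. The default method prunes the pair
#' search with a uniform cell grid (cell edge = the largest possible
#' interface cutoff), which returns results identical to the exhaustive
#' all-pairs scan (`method = "all_pairs"`).
#'
#' @param mol_a,mol_b the two molecules (`struct_tbl`); their atom sets must
#'   be disjoint.
#' @param config a [contact_config()].
#' @param method `"grid"` (default) or `"all_pairs"`.
#' @return a `contact_report`: list with `pairs` (tibble of interface pairs,
#'   one row per pair, with `distance`, `vdw_sum` and `collision` columns and
#'   `_a`/`_b` suffixed atom identifiers) and `counts`
#'   (`n_interface_pairs`, `n_collision_pairs`, `n_colliding_atoms_a`,
#'   `n_colliding_atoms_b`).
#' @export
find_contacts <- function(mol_a, mol_b, config = contact_config(),
                          method = c("grid", "all_pairs")) {
  method <- match.arg(method)
  a <- as_struct(mol_a); b <- as_struct(mol_b)
  if (nrow(a) == 0 || nrow(b) == 0) abort("both molecules must be non-empty")
  ra <- atom_radii(a, config); rb <- atom_radii(b, config)
  cutoff <- config$interface_factor * (max(ra) + max(rb))

  idx <- if (method == "grid") {
    grid_candidate_pairs(coords(a), coords(b), cutoff)
  } else {
    as.matrix(expand.grid(i = seq_len(nrow(a)), j = seq_len(nrow(b))))
  }

  pa <- coords(a)[idx[, 1], , drop = FALSE]
  pb <- coords(b)[idx[, 2], , drop = FALSE]
  d <- sqrt(rowSums((pa - pb)^2))
  vdw <- ra[idx[, 1]] + rb[idx[, 2]]
  keep <- d < config$interface_factor * vdw
  if (!any(keep)) {
    return(new_contact_report(empty_pairs(), a, b, config))
  }
  i <- idx[keep, 1]; j <- idx[keep, 2]
  hyd <- a$element[i] == "H" | b$element[j] == "H"
  coll <- d[keep] < config$collision_factor * vdw[keep]
  if (config$collision_excludes_hydrogen) coll <- coll & !hyd
  pairs <- bind_cols(
    setNames(as_tibble(a)[i, c("chain", "resno", "insert", "resid", "atom", "element")],
             paste0(c("chain", "resno", "insert", "resid", "atom", "element"), "_a")),
    setNames(as_tibble(b)[j, c("chain", "resno", "insert", "resid", "atom", "element")],
             paste0(c("chain", "resno", "insert", "resid", "atom", "element"), "_b")),
    tibble(distance = d[keep], vdw_sum = vdw[keep], collision = coll))
  pairs <- arrange(pairs, .data$chain_a, .data$resno_a, .data$atom_a,
                   .data$chain_b, .data$resno_b, .data$atom_b)
  new_contact_report(pairs, a, b, config)
}

empty_pairs <- function() {
  tibble(chain_a = character(), resno_a = integer(), insert_a = character(),
         resid_a = character(), atom_a = character(), element_a = character(),
         chain_b = character(), resno_b = integer(), insert_b = character(),
         resid_b = character(), atom_b = character(), element_b = character(),
         distance = numeric(), vdw_sum = numeric(), collision = logical())
}

new_contact_report <- function(pairs, a, b, config) {
  cp <- pairs[pairs$collision, , drop = FALSE]
  counts <- list(
    n_interface_pairs = nrow(pairs),
    n_collision_pairs = nrow(cp),
    n_colliding_atoms_a = nrow(distinct(cp[, c("chain_a", "resno_a", "insert_a", "atom_a")])),
    n_colliding_atoms_b = nrow(distinct(cp[, c("chain_b", "resno_b", "insert_b", "atom_b")])))
  structure(list(pairs = pairs, counts = counts, config = config,
                 id_a = struct_id(a), id_b = struct_id(b)),
            class = "contact_report")
}

# cell-grid candidate pruning: returns a 2-column index matrix of (i, j)
# candidates whose cells are within one cell of each other
grid_candidate_pairs <- function(A, B, cutoff) {
  org <- pmin(apply(A, 2, min), apply(B, 2, min))
  ca <- floor(sweep(A, 2, org) / cutoff)
  cb <- floor(sweep(B, 2, org) / cutoff)
  keyb <- paste(cb[, 1], cb[, 2], cb[, 3], sep = ",")
  bmap <- split(seq_len(nrow(B)), keyb)
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  out_i <- vector("list", 27L); out_j <- vector("list", 27L)
  for (o in seq_len(27L)) {
    ka <- paste(ca[, 1] + off[o, 1], ca[, 2] + off[o, 2], ca[, 3] + off[o, 3],
                sep = ",")
    hits <- bmap[ka]
    ns <- lengths(hits)
    out_i[[o]] <- rep(seq_len(nrow(A)), ns)
    out_j[[o]] <- unlist(hits, use.names = FALSE)
  }
  cbind(i = unlist(out_i), j = unlist(out_j))
}

#' @export
print.contact_report <- function(x, ...) {
  cat("<contact_report> ", x$id_a, " vs ", x$id_b, "\n", sep = "")
  cat("  interface pairs:", x$counts$n_interface_pairs,
      " collision pairs:", x$counts$n_collision_pairs, "\n")
  cat("  colliding atoms:", x$counts$n_colliding_atoms_a, "(a) /",
      x$counts$n_colliding_atoms_b, "(b)\n")
  invisible(x)
}

#' @describeIn find_contacts the interface-pair tibble.
#' @param x a `contact_report`.
#' @param ... unused.
#' @export
tidy.contact_report <- function(x, ...) x$pairs

#' @describeIn find_contacts one-row tibble of pair/atom counts.
#' @export
glance.contact_report <- function(x, ...) as_tibble(x$counts)

#' @describeIn find_contacts residue-level contact map (interface pairs per
#'   residue pair, collisions highlighted).
#' @param object a `contact_report`.
#' @export
autoplot.contact_report <- function(object, ...) {
  df <- object$pairs |>
    group_by(.data$chain_a, .data$resno_a, .data$chain_b, .data$resno_b) |>
    summarise(n_pairs = dplyr::n(), any_collision = any(.data$collision),
              .groups = "drop") |>
    mutate(res_a = paste0(.data$chain_a, .data$resno_a),
           res_b = paste0(.data$chain_b, .data$resno_b))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$res_a, y = .data$res_b,
                                   fill = .data$n_pairs,
                                   colour = .data$any_collision)) +
    ggplot2::geom_tile(linewidth = 0.6) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = NA, `TRUE` = "red")) +
    ggplot2::labs(x = "molecule A residue", y = "molecule B residue",
                  fill = "atom pairs", colour = "collision") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Per-residue interface rollup
#'
#' Lists every residue of each molecule participating in at least one
#' interface pair, with its partner residues and pair counts.
#'
#' @param report a `contact_report` from [find_contacts()].
#' @return tibble with `molecule` (`"a"`/`"b"`), `chain`, `resno`, `insert`,
#'   `resid`, `n_pairs`, `n_collision_pairs`, `partners` (comma-separated
#'   partner residues).
#' @export
interface_residue_table <- function(report) {
  stopifnot(inherits(report, "contact_report"))
  p <- report$pairs
  roll <- function(side, other) {
    if (nrow(p) == 0) {
      return(tibble(molecule = character(), chain = character(),
                    resno = integer(), insert = character(), resid = character(),
                    n_pairs = integer(), n_collision_pairs = integer(),
                    partners = character()))
    }
    p |>
      mutate(partner = paste0(.data[[paste0("chain_", other)]],
                              .data[[paste0("resno_", other)]])) |>
      group_by(chain = .data[[paste0("chain_", side)]],
               resno = .data[[paste0("resno_", side)]],
               insert = .data[[paste0("insert_", side)]],
               resid = .data[[paste0("resid_", side)]]) |>
      summarise(n_pairs = dplyr::n(),
                n_collision_pairs = sum(.data$collision),
                partners = paste(sort(unique(.data$partner)), collapse = ","),
                .groups = "drop") |>
      mutate(molecule = side, .before = 1)
  }
  bind_rows(roll("a", "b"), roll("b", "a")) |>
    arrange(.data$molecule, .data$chain, .data$resno)
}

#' Minimum Calpha-Calpha distance over listed residue pairs
#'
#' Used, for instance, to verify that long-range salt-bridge/hydrogen-bond
#' pairs bridge their backbones at over 10 angstrom.
#'
#' @param model a `struct_tbl` containing all listed residues.
#' @param pairs tibble with columns `chain_a`, `resno_a`, `chain_b`,
#'   `resno_b` (insertion codes assumed blank).
#' @return the minimum distance in angstrom; the full per-pair table is
#'   attached as attribute `"distances"`.
#' @export
min_ca_distance <- function(model, pairs) {
  model <- as_struct(model)
  if (nrow(pairs) == 0) abort("empty residue pair list")
  ca <- filter(model, .data$atom == "CA", !.data$het)
  get_ca <- function(ch, rn) {
    hit <- which(ca$chain == ch & ca$resno == rn)
    if (length(hit) == 0) abort(paste0("missing CA atom for residue ", ch, ":", rn))
    coords(ca)[hit[1], ]
  }
  d <- purrr::pmap_dbl(pairs[, c("chain_a", "resno_a", "chain_b", "resno_b")],
                       function(chain_a, resno_a, chain_b, resno_b) {
                         sqrt(sum((get_ca(chain_a, resno_a) - get_ca(chain_b, resno_b))^2))
                       })
  out <- min(d)
  attr(out, "distances") <- mutate(pairs, ca_distance = d)
  out
}
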