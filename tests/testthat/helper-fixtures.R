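# Shared helpers: random rigid motions, tiny hand-built models, and the
# locator for released coordinate files (used by the deposited-model checks).

# uniform random rotation matrix (quaternion method)
random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

random_transform <- function(t_scale = 10) {
  rigid_transform(random_rotation(), rnorm(3, 0, t_scale))
}

# small single-chain model from a coordinate matrix
toy_model <- function(xyz, chain = "A", atom = "CA", element = "C",
                      resno = seq_len(nrow(xyz)), id = "toy") {
  struct_tbl(tibble::tibble(atom = atom, chain = chain, resno = resno,
                            resid = "GLY", element = element,
                            x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]), id = id)
}

set_coords <- function(x, m) { x$x <- m[, 1]; x$y <- m[, 2]; x$z <- m[, 3]; x }

# non-degenerate 10-atom cloud
toy_cloud <- function(n = 10, seed = 42) {
  withr::with_seed(seed, matrix(rnorm(n * 3, 0, 3), ncol = 3))
}

# released coordinate files (1J6Z, 5JLF, 5YU8) are looked for here; they are
# not redistributed with the package, so these checks fail cleanly when the
# files have not been placed under the accession directory.
accession_file <- function(id) {
  dir <- getOption("actifil.accession_dir",
                   system.file("extdata", "accessions", package = "actifil"))
  candidates <- file.path(dir, paste0(tolower(id), c(".pdb", ".cif")))
  hit <- candidates[file.exists(candidates)]
  if (length(hit) == 0) candidates[1] else hit[1]
}

expect_accessions <- function(ids) {
  paths <- vapply(ids, accession_file, character(1))
  ok <- file.exists(paths)
  expect_true(all(ok),
              info = paste0("released coordinate files required but not found: ",
                            paste(ids[!ok], collapse = ", "),
                            " (place them under getOption('actifil.accession_dir'))"))
  all(ok)
}

# actin chains of a deposited model: polymer chains with > 250 residues
actin_chains <- function(model) {
  tab <- model |>
    dplyr::filter(!het, atom == "CA") |>
    dplyr::count(chain)
  tab$chain[tab$n > 250]
}

# tag each listed chain as one filament subunit, ordered axially by the
# projection of the chain centroids onto their principal axis
tag_subunits <- function(model, chains) {
  ctrs <- t(vapply(chains, function(ch) {
    m <- dplyr::filter(model, chain == ch, !het)
    colMeans(cbind(m$x, m$y, m$z))
  }, numeric(3)))
  pc <- prcomp(ctrs)$x[, 1]
  ord <- chains[order(pc)]
  model$subunit <- match(model$chain, ord)
  model
}
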