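# Atomic models as atom-level tibbles ("struct_tbl"), plus PDB/mmCIF IO,
# residue selections and conformer-ensemble correspondence.

STRUCT_COLS <- c("eleno", "atom", "resid", "chain", "resno", "insert",
                 "x", "y", "z", "occ", "b", "element", "het")

#' Construct an atomic-model tibble
#'
#' A `struct_tbl` is a tibble with one row per atom and columns
#' `eleno` (atom serial), `atom` (atom name, e.g. `"CA"`), `resid`
#' (residue name), `chain`, `resno` (author residue number), `insert`
#' (insertion code, `""` when none), `x`, `y`, `z` (coordinates in
#' angstrom), `occ`, `b`, `element` (element symbol) and `het`
#' (`TRUE` for HETATM records such as ADP or Mg). Optional columns
#' (e.g. `subunit` for filaments) are preserved by all verbs.
#'
#' @param atoms data frame with at least `atom`, `chain`, `resno`, `x`, `y`,
#'   `z`, `element`; missing bookkeeping columns are filled with defaults.
#' @param id model identifier string.
#' @param source_format `"pdb"`, `"cif"` or `"r"` (built in code).
#' @return a `struct_tbl` tibble.
#' @export
struct_tbl <- function(atoms, id = "model", source_format = "r") {
  atoms <- as_tibble(atoms)
  if (nrow(atoms) == 0L) abort("empty model: no atoms")
  defaults <- list(eleno = seq_len(nrow(atoms)), resid = "ALA", insert = "",
                   occ = 1, b = 0, het = FALSE)
  for (nm in names(defaults)) {
    if (!nm %in% names(atoms)) atoms[[nm]] <- defaults[[nm]]
  }
  miss <- setdiff(STRUCT_COLS, names(atoms))
  if (length(miss) > 0) {
    abort(paste0("missing atom columns: ", paste(miss, collapse = ", ")))
  }
  atoms$resno <- as.integer(atoms$resno)
  atoms$insert[is.na(atoms$insert)] <- ""
  atoms <- atoms[, c(STRUCT_COLS, setdiff(names(atoms), STRUCT_COLS))]
  out <- new_tibble(atoms, class = "struct_tbl")
  attr(out, "struct_id") <- id
  attr(out, "source_format") <- source_format
  validate_struct(out)
  out
}

#' @exportS3Method dplyr::dplyr_reconstruct
dplyr_reconstruct.struct_tbl <- function(data, template) {
  out <- NextMethod()
  if (all(STRUCT_COLS %in% names(out))) {
    class(out) <- class(template)
    attr(out, "struct_id") <- attr(template, "struct_id")
    attr(out, "source_format") <- attr(template, "source_format")
  }
  out
}

#' Model identifier of a structure
#' @param x a `struct_tbl`.
#' @return the identifier string.
#' @export
struct_id <- function(x) attr(x, "struct_id") %||% "model"

validate_struct <- function(x) {
  if (any(!is.finite(x$x) | !is.finite(x$y) | !is.finite(x$z))) {
    abort("non-finite coordinates in model")
  }
  if (any(is.na(x$element) | x$element == "")) {
    bad <- which(is.na(x$element) | x$element == "")[1]
    abort(paste0("atom without element symbol (row ", bad, ")"))
  }
  # one residue name per residue identifier
  rid <- residue_ids(x)
  multi <- rid |> group_by(.data$chain, .data$resno, .data$insert) |>
    summarise(k = dplyr::n_distinct(.data$resid), .groups = "drop") |>
    filter(.data$k > 1)
  if (nrow(multi) > 0) {
    abort(paste0("duplicate residue identifier with conflicting residue names: ",
                 multi$chain[1], ":", multi$resno[1]))
  }
  dup <- x |> filter(!.data$het) |>
    count(.data$chain, .data$resno, .data$insert, .data$atom) |>
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(paste0("duplicate atom record: ", dup$chain[1], ":", dup$resno[1],
                 " ", dup$atom[1]))
  }
  invisible(x)
}

#' Residue identifiers of a model
#' @param x a `struct_tbl`.
#' @return tibble with one row per residue: `chain`, `resno`, `insert`, `resid`.
#' @export
residue_ids <- function(x) {
  distinct(as_tibble(x)[, c("chain", "resno", "insert", "resid")])
}

res_key <- function(x) paste(x$chain, x$resno, x$insert, sep = "|")

#' Coordinate matrix of a model
#' @param x a `struct_tbl`.
#' @return n x 3 numeric matrix of x, y, z in angstrom.
#' @export
coords <- function(x) cbind(x$x, x$y, x$z)

set_coords <- function(x, m) {
  x$x <- m[, 1]; x$y <- m[, 2]; x$z <- m[, 3]
  x
}

#' Read an atomic model from a PDB or mmCIF file
#'
#' Parsing is delegated to \pkg{bio3d}. HETATM records (ADP, Mg, waters) are
#' retained and flagged in the `het` column. When alternate locations are
#' present, only the highest-occupancy conformer of each atom is kept, so
#' downstream geometry always sees a single conformer.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"pdb"` or `"cif"`.
#' @return a [struct_tbl()].
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (format == "auto") {
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "cif" else "pdb"
  }
  parsed <- tryCatch(
    if (format == "cif") bio3d::read.cif(path, rm.alt = FALSE, verbose = FALSE)
    else bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE),
    error = function(e) {
      abort(paste0("could not parse ", format, " file '", path, "': ",
                   conditionMessage(e)))
    })
  at <- as_tibble(parsed$atom)
  if (nrow(at) == 0L) abort(paste0("empty model in ", path))
  at$insert[is.na(at$insert)] <- ""
  at$chain[is.na(at$chain)] <- " "
  element <- at$elesy
  if (is.null(element)) element <- rep(NA_character_, nrow(at))
  guess <- toupper(substr(gsub("[^A-Za-z].*$", "", at$elety), 1, 1))
  element <- ifelse(is.na(element) | element == "", guess, element)
  atoms <- tibble(
    eleno = at$eleno, atom = at$elety, resid = at$resid, chain = at$chain,
    resno = at$resno, insert = at$insert, x = at$x, y = at$y, z = at$z,
    occ = ifelse(is.na(at$o), 1, at$o), b = ifelse(is.na(at$b), 0, at$b),
    element = toupper(element), het = at$type == "HETATM",
    alt = ifelse(is.na(at$alt), "", at$alt))
  # duplicate records that are not alternate locations are real errors
  plain <- atoms[atoms$alt == "" & !atoms$het, , drop = FALSE]
  dup <- plain |>
    count(.data$chain, .data$resno, .data$insert, .data$atom) |>
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(paste0("duplicate residue identifier in ", path, ": ",
                 dup$chain[1], ":", dup$resno[1], " ", dup$atom[1]))
  }
  # highest-occupancy alternate location only
  atoms <- atoms |>
    arrange(.data$chain, .data$resno, .data$insert, .data$atom,
            dplyr::desc(.data$occ), .data$alt) |>
    distinct(.data$chain, .data$resno, .data$insert, .data$atom, .data$het,
             .keep_all = TRUE) |>
    arrange(.data$eleno) |>
    select(-"alt")
  struct_tbl(atoms, id = sub("\\.[^.]+$", "", basename(path)),
             source_format = format)
}

#' Write an atomic model to a PDB file
#'
#' @param x a `struct_tbl`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(x, path) {
  x <- as_struct(x)
  long <- nchar(x$chain) != 1L
  if (any(long)) {
    abort(paste0("chain identifiers must be single characters for PDB output: ",
                 paste(unique(x$chain[long]), collapse = ", ")))
  }
  bio3d::write.pdb(
    file = path,
    xyz = as.vector(t(coords(x))),
    type = ifelse(x$het, "HETATM", "ATOM"),
    resno = x$resno, resid = x$resid, eleno = seq_len(nrow(x)),
    elety = x$atom, chain = x$chain, insert = ifelse(x$insert == "", NA, x$insert),
    o = x$occ, b = x$b, elesy = x$element)
  invisible(path)
}

as_struct <- function(x) {
  if (inherits(x, "struct_tbl")) return(x)
  struct_tbl(x)
}

# ---- residue selections ------------------------------------------------------

#' Residue selections
#'
#' A selection is a tibble of inclusive residue-number ranges, one row per
#' `(chain, start, end)`. `chain = NA` matches any chain, which is the
#' convenient form for proteins that share author numbering across chains
#' (as the actin structures do). Overlapping or abutting ranges on the same
#' chain are merged. The string form is `"A:138-336,A:7-35"`; a bare range
#' `"138-336"` (no chain) matches all chains.
#'
#' @param spec a selection string, an integer vector of residue numbers, a
#'   tibble with columns `chain`, `start`, `end`, or an existing selection.
#' @param chain optional chain id applied when `spec` is numeric.
#' @return a tibble with columns `chain`, `start`, `end`.
#' @export
#' @examples
#' residue_selection("A:138-336")
#' residue_selection(c(7:35, 68:137, 337:372))
residue_selection <- function(spec, chain = NA_character_) {
  if (is.null(spec)) return(NULL)
  if (is.data.frame(spec)) {
    sel <- as_tibble(spec)
    if (!all(c("start", "end") %in% names(sel))) {
      abort("selection data frame needs columns start, end (and optionally chain)")
    }
    if (!"chain" %in% names(sel)) sel$chain <- NA_character_
    sel <- sel[, c("chain", "start", "end")]
  } else if (is.character(spec)) {
    parts <- unlist(strsplit(spec, ",", fixed = TRUE))
    parts <- trimws(parts[nzchar(trimws(parts))])
    if (length(parts) == 0) abort("empty selection string")
    sel <- purrr::map(parts, function(p) {
      ch <- NA_character_
      if (grepl(":", p, fixed = TRUE)) {
        bits <- strsplit(p, ":", fixed = TRUE)[[1]]
        ch <- bits[1]
        p <- bits[2]
      }
      m <- regmatches(p, regexec("^(-?[0-9]+)(?:-(-?[0-9]+))?$", p))[[1]]
      if (length(m) == 0) abort(paste0("cannot parse selection range: '", p, "'"))
      s <- as.integer(m[2])
      e <- if (m[3] == "") s else as.integer(m[3])
      tibble(chain = ch, start = s, end = e)
    }) |> bind_rows()
  } else if (is.numeric(spec)) {
    spec <- sort(unique(as.integer(spec)))
    if (length(spec) == 0) abort("empty selection")
    brk <- c(0L, which(diff(spec) != 1L), length(spec))
    sel <- tibble(chain = chain,
                  start = spec[brk[-length(brk)] + 1L],
                  end = spec[brk[-1L]])
  } else {
    abort("unsupported selection specification")
  }
  if (any(is.na(sel$start) | is.na(sel$end))) abort("selection range with NA bound")
  if (any(sel$end < sel$start)) abort("selection range with end < start")
  merge_ranges(sel)
}

merge_ranges <- function(sel) {
  sel |>
    mutate(.chain = ifelse(is.na(.data$chain), "\r*", .data$chain)) |>
    arrange(.data$.chain, .data$start, .data$end) |>
    group_by(.data$.chain) |>
    mutate(grp = cumsum(.data$start > dplyr::lag(cummax(.data$end + 1L),
                                                 default = -.Machine$integer.max))) |>
    group_by(.data$.chain, .data$grp) |>
    summarise(chain = first(.data$chain), start = min(.data$start),
              end = max(.data$end), .groups = "drop") |>
    select("chain", "start", "end") |>
    arrange(is.na(.data$chain), .data$chain, .data$start)
}

#' Convert a selection to its string form
#' @param sel a selection tibble.
#' @return a string such as `"A:7-35,A:68-137"`.
#' @export
selection_string <- function(sel) {
  paste0(ifelse(is.na(sel$chain), "", paste0(sel$chain, ":")),
         sel$start, ifelse(sel$end == sel$start, "", paste0("-", sel$end)),
         collapse = ",")
}

#' Subset a model to a residue selection
#'
#' @param x a `struct_tbl`.
#' @param sel a selection ([residue_selection()] or string); `NULL` selects
#'   everything.
#' @param exclude optional selection removed after `sel` is applied.
#' @return the filtered `struct_tbl`.
#' @export
select_residues <- function(x, sel = NULL, exclude = NULL) {
  x <- as_struct(x)
  if (!is.null(sel)) x <- x[selection_mask(x, residue_selection(sel)), ]
  if (!is.null(exclude)) x <- x[!selection_mask(x, residue_selection(exclude)), ]
  x
}

selection_mask <- function(x, sel) {
  m <- rep(FALSE, nrow(x))
  for (i in seq_len(nrow(sel))) {
    hit <- x$resno >= sel$start[i] & x$resno <= sel$end[i]
    if (!is.na(sel$chain[i])) hit <- hit & x$chain == sel$chain[i]
    m <- m | hit
  }
  m
}

#' Residue numbers covered by a selection
#' @param sel a selection tibble.
#' @return sorted integer vector of residue numbers (chains ignored).
#' @export
selection_resnos <- function(sel) {
  sort(unique(unlist(purrr::map2(sel$start, sel$end, seq))))
}

# ---- conformer ensembles -----------------------------------------------------

#' Build a conformer ensemble with residue correspondence
#'
#' Correspondence between members is established by author residue numbering
#' within matching chain ids (`mode = "by_author_number"`); `chain_map` can
#' rename member chains onto a canonical lettering first. The shared core is
#' the set of residues present in every member with a Calpha atom; residues
#' missing from any member are excluded and reported.
#'
#' @param models list of `struct_tbl` (length >= 2), optionally named.
#' @param mode correspondence mode; only `"by_author_number"` is defined.
#' @param chain_map optional list, one element per member, each a named
#'   character vector `c(old_chain = "new_chain")`.
#' @return a `conformer_ensemble`: list with `members` (named list of
#'   `struct_tbl`), `core` (tibble `chain`, `resno`, `insert`) and
#'   `excluded` (tibble of residues absent from at least one member, with a
#'   `missing_from` column).
#' @export
build_ensemble <- function(models, mode = "by_author_number", chain_map = NULL) {
  mode <- match.arg(mode, "by_author_number")
  if (length(models) < 2L) abort("an ensemble needs at least 2 models")
  models <- purrr::map(models, as_struct)
  if (is.null(names(models)) || any(!nzchar(names(models)))) {
    names(models) <- purrr::imap_chr(models, function(m, i) {
      paste0("m", i, "_", struct_id(m))
    })
  }
  if (!is.null(chain_map)) {
    models <- purrr::map2(models, chain_map, function(m, cm) {
      if (is.null(cm)) return(m)
      hit <- m$chain %in% names(cm)
      m$chain[hit] <- unname(cm[m$chain[hit]])
      m
    })
  }
  per_member <- purrr::map(models, function(m) {
    distinct(as_tibble(filter(m, .data$atom == "CA", !.data$het))[,
             c("chain", "resno", "insert")])
  })
  all_res <- distinct(bind_rows(per_member))
  present <- purrr::map(per_member, function(r) {
    !is.na(match(res_key(all_res), res_key(r)))
  })
  pmat <- do.call(cbind, present)
  keep <- rowSums(pmat) == length(models)
  core <- tibble(chain = all_res$chain[keep], resno = all_res$resno[keep],
                 insert = all_res$insert[keep]) |>
    arrange(.data$chain, .data$resno, .data$insert)
  if (nrow(core) == 0L) abort("empty shared core: no residue with a CA atom is present in all members")
  excl <- all_res[rowSums(pmat) < length(models), , drop = FALSE]
  excl$missing_from <- apply(!pmat[rowSums(pmat) < length(models), , drop = FALSE],
                             1, function(row) paste(names(models)[row], collapse = ","))
  out <- list(members = models, core = as_tibble(core), excluded = as_tibble(excl))
  class(out) <- "conformer_ensemble"
  out
}

#' @export
print.conformer_ensemble <- function(x, ...) {
  cat("<conformer_ensemble> ", length(x$members), " members, shared core ",
      nrow(x$core), " residues (", nrow(x$excluded), " excluded)\n", sep = "")
  invisible(x)
}

# intersect the shared core with a selection; returns core subset tibble
core_in_selection <- function(ensemble, sel) {
  sel <- residue_selection(sel)
  core <- ensemble$core
  keep <- rep(FALSE, nrow(core))
  for (i in seq_len(nrow(sel))) {
    hit <- core$resno >= sel$start[i] & core$resno <= sel$end[i]
    if (!is.na(sel$chain[i])) hit <- hit & core$chain == sel$chain[i]
    keep <- keep | hit
  }
  core[keep, , drop = FALSE]
}
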