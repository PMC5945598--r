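# Per-residue positional variability across an aligned conformer ensemble and
# the two-pass rigid-body search.

#' Per-residue Calpha positional standard deviation across an ensemble
#'
#' All members are superposed (Calpha) onto the first member over `align_on`;
#' for every shared-core residue the positional SD is the root-mean-square
#' distance of the member Calpha positions from their mean,
#' `sd = sqrt( (1/N) * sum_i |r_i - rbar|^2 )`. This pools the three
#' coordinates into a single scalar per residue. The default divisor is the
#' population size `N` (`divisor = "n"`); set `divisor = "n-1"` for the
#' sample form. The SD is invariant (up to numerical noise) to which member
#' serves as the alignment reference, since all members end up in a common
#' frame.
#'
#' @param ensemble a [build_ensemble()] result.
#' @param align_on residue selection used for the superposition.
#' @param divisor `"n"` (population, default) or `"n-1"`.
#' @return tibble with `chain`, `resno`, `insert`, `sd` (angstrom) and
#'   `n_members`.
#' @export
per_residue_sd <- function(ensemble, align_on, divisor = c("n", "n-1")) {
  divisor <- match.arg(divisor)
  stopifnot(inherits(ensemble, "conformer_ensemble"))
  members <- ensemble$members
  N <- length(members)
  core <- ensemble$core
  ck <- res_key(core)
  ca_of <- function(m) {
    ca <- filter(m, .data$atom == "CA", !.data$het)
    ca[match(ck, res_key(ca)), c("x", "y", "z")]
  }
  ref <- members[[1]]
  mats <- vector("list", N)
  mats[[1]] <- as.matrix(ca_of(ref))
  for (i in seq_len(N)[-1]) {
    tf <- superpose(members[[i]], ref, align_on, atom_set = "CA")
    mats[[i]] <- apply_transform(as.matrix(ca_of(members[[i]])), tf)
  }
  arr <- simplify2array(mats)              # n_res x 3 x N
  mean_pos <- apply(arr, c(1, 2), mean)
  dev2 <- apply((arr - array(mean_pos, dim = dim(arr)))^2, 1, sum)
  denom <- if (divisor == "n") N else N - 1
  tibble(chain = core$chain, resno = core$resno, insert = core$insert,
         sd = sqrt(dev2 / denom), n_members = N)
}

#' Two-pass rigid-body search over a conformer ensemble
#'
#' Pass 1: the ensemble is aligned on `initial_region` and residues within
#' that region with Calpha positional SD strictly below `pass1_threshold`
#' form a putative rigid body. Pass 2: the ensemble is re-aligned on the
#' putative body and residues with SD strictly below `pass2_threshold` form
#' the final body. Final-pass SDs are reported for all shared-core residues,
#' so body membership outside the initial region is visible. Residues whose
#' final SD falls within `borderline_margin` of the pass-2 threshold are
#' flagged (`borderline`), mirroring how residues sitting essentially on the
#' threshold (e.g. SDs of 0.72 and 0.62 angstrom against a 0.7 cut) deserve
#' case-by-case judgement.
#'
#' With `iterate = TRUE` the pass-2 re-align/re-threshold step is repeated
#' until the membership is a fixed point (the default is the plain two-pass
#' scheme).
#'
#' @param ensemble a [build_ensemble()] result.
#' @param initial_region residue selection seeding pass 1 (for actin, the
#'   inner domain 138-336).
#' @param pass1_threshold,pass2_threshold SD cutoffs in angstrom (defaults
#'   1.0 and 0.7); membership uses strict `<`.
#' @param iterate repeat pass 2 to convergence.
#' @param borderline_margin half-width of the borderline flag band.
#' @param divisor passed to [per_residue_sd()].
#' @return a `rigid_body` object: list with `member_residues` (merged-range
#'   selection tibble), `residues` (per-residue final SD table with
#'   `in_body` and `borderline` flags), `thresholds`, `converged`, `n_pass`.
#' @export
rigid_body_search <- function(ensemble, initial_region,
                              pass1_threshold = 1.0, pass2_threshold = 0.7,
                              iterate = FALSE, borderline_margin = 0.05,
                              divisor = "n") {
  initial_region <- residue_selection(initial_region)
  seed_core <- core_in_selection(ensemble, initial_region)
  if (nrow(seed_core) == 0) abort("initial_region contains no shared-core residues")

  sd1 <- per_residue_sd(ensemble, initial_region, divisor = divisor)
  in_init <- !is.na(match(res_key(sd1), res_key(seed_core)))
  putative <- sd1[in_init & sd1$sd < pass1_threshold, , drop = FALSE]
  if (nrow(putative) == 0) {
    abort(paste0("rigid-body search pass 1: no residue below the ",
                 pass1_threshold, " A threshold"))
  }

  body <- putative[, c("chain", "resno", "insert")]
  n_pass <- 1L
  converged <- FALSE
  repeat {
    n_pass <- n_pass + 1L
    sd2 <- per_residue_sd(ensemble, residues_to_selection(body), divisor = divisor)
    new_body <- sd2[sd2$sd < pass2_threshold, c("chain", "resno", "insert")]
    if (nrow(new_body) == 0) {
      abort(paste0("rigid-body search pass ", n_pass, ": no residue below the ",
                   pass2_threshold, " A threshold"))
    }
    same <- identical(res_key(new_body), res_key(body))
    body <- new_body
    if (!iterate || same || n_pass > 50L) {
      converged <- same || !iterate && n_pass == 2L
      if (iterate && !same && n_pass > 50L) {
        warn("rigid-body search did not reach a fixed point within 50 iterations")
        converged <- FALSE
      }
      break
    }
  }

  residues <- sd2 |>
    mutate(in_body = .data$sd < pass2_threshold,
           in_initial_region = !is.na(match(res_key(sd2), res_key(seed_core))),
           borderline = abs(.data$sd - pass2_threshold) <= borderline_margin)
  pass1_tbl <- sd1 |> select("chain", "resno", "insert", pass1_sd = "sd")
  residues <- left_join(residues, pass1_tbl, by = c("chain", "resno", "insert"))

  structure(list(member_residues = residues_to_selection(body),
                 residues = residues,
                 thresholds = c(pass1 = pass1_threshold, pass2 = pass2_threshold),
                 converged = converged, n_pass = n_pass,
                 initial_region = initial_region),
            class = "rigid_body")
}

# collapse a residue-id tibble into a merged-range selection
residues_to_selection <- function(res) {
  res |>
    distinct(.data$chain, .data$resno) |>
    group_by(.data$chain) |>
    arrange(.data$resno, .by_group = TRUE) |>
    mutate(grp = cumsum(c(1L, diff(.data$resno) != 1L))) |>
    group_by(.data$chain, .data$grp) |>
    summarise(start = min(.data$resno), end = max(.data$resno), .groups = "drop") |>
    select("chain", "start", "end")
}

#' @export
print.rigid_body <- function(x, ...) {
  cat("<rigid_body> ", sum(x$residues$in_body), " residues (",
      selection_string(x$member_residues), ")\n", sep = "")
  cat(sprintf("  thresholds: pass1 < %.2f A, pass2 < %.2f A; passes: %d\n",
              x$thresholds["pass1"], x$thresholds["pass2"], x$n_pass))
  nb <- sum(x$residues$borderline)
  if (nb > 0) cat("  borderline residues (|sd - threshold| <= margin):", nb, "\n")
  invisible(x)
}

#' @describeIn rigid_body_search per-residue SD table (one row per
#'   shared-core residue, with `in_body` and `borderline` flags).
#' @param x a `rigid_body` object.
#' @param ... unused.
#' @export
tidy.rigid_body <- function(x, ...) x$residues

#' @describeIn rigid_body_search one-row summary (body size, thresholds,
#'   convergence).
#' @export
glance.rigid_body <- function(x, ...) {
  tibble(n_body = sum(x$residues$in_body),
         n_core = nrow(x$residues),
         n_borderline = sum(x$residues$borderline),
         pass1_threshold = unname(x$thresholds["pass1"]),
         pass2_threshold = unname(x$thresholds["pass2"]),
         n_pass = x$n_pass, converged = x$converged,
         selection = selection_string(x$member_residues))
}

#' @describeIn rigid_body_search SD profile plot with threshold lines.
#' @param object a `rigid_body` object.
#' @export
autoplot.rigid_body <- function(object, ...) {
  df <- object$residues
  ggplot2::ggplot(df, ggplot2::aes(x = .data$resno, y = .data$sd,
                                   colour = .data$in_body)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = unname(object$thresholds["pass2"]),
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = unname(object$thresholds["pass1"]),
                        linetype = "dotted") +
    ggplot2::facet_wrap(~chain, scales = "free_x") +
    ggplot2::labs(x = "residue number", y = "Calpha positional SD (A)",
                  colour = "in rigid body") +
    ggplot2::theme_minimal()
}

#' Selection of the final rigid-body residues
#' @param x a `rigid_body` object.
#' @return selection tibble (`chain`, `start`, `end`).
#' @export
body_selection <- function(x) x$member_residues
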