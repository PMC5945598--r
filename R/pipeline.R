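# End-to-end driver: rigid-body search -> rotation axes -> filament grafts
# and hybrids -> contact reports -> helical measurements, on synthetic
# inputs by default or on user-supplied coordinate files.

#' Run the full structural-analysis pipeline
#'
#' Executes every stage of the analysis in order on one configuration:
#' rigid-body search over a conformer ensemble, inter-domain screw-axis
#' determination, helical symmetry fitting and centroid-axis measurements,
#' cofilin grafts through the F-, Gi- and Go-sites, hybrid two-strand
#' models over the requested spans, and contact/collision reports for every
#' constructed model. With no inputs it generates its own synthetic system
#' (planted hinge ensemble + decorated and bare filaments) from `seed`, so
#' the whole pipeline is runnable download-free; pass real conformers and
#' filaments through `config` to analyse deposited models instead.
#'
#' Any stage failure is rethrown with the stage name; results computed up to
#' that point are preserved in the condition's `partial` field and, when
#' `out_dir` is set, on disk.
#'
#' @param config optional list overriding inputs and parameters:
#'   `ensemble` (a [build_ensemble()] result), `conf_pairs` (named list of
#'   `list(a =, b =)` conformer pairs for axis determination), `cofilactin`
#'   and `factin` (filaments with `subunit` columns), `initial_region`,
#'   `id_body`, `sd1_body` (selections), `pass1_threshold`,
#'   `pass2_threshold`, `contact_config`, `spans`, `centroid_exclude`.
#' @param out_dir optional directory: JSON/TSV summaries, PDB models and the
#'   run configuration are written there.
#' @param seed seed for the synthetic inputs.
#' @return a `pipeline_result` list with elements `rigid_body`, `axes`,
#'   `helical`, `grafts`, `hybrids`, `contacts` and `config`.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL, seed = 1) {
  stage <- function(name, expr, partial) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)),
            class = "pipeline_stage_error", partial = partial)
    })
  }
  res <- list()
  cfg <- config

  # ---- inputs ----------------------------------------------------------------
  res$config <- cfg[setdiff(names(cfg), c("ensemble", "cofilactin", "factin", "conf_pairs"))]
  if (is.null(cfg$ensemble)) {
    ens_raw <- make_two_domain_ensemble(
      n_res_a = 120, n_res_b = 40, angles_deg = seq(0, 20, length.out = 8),
      noise_sd = 0.2, seed = seed)
    cfg$ensemble <- build_ensemble(ens_raw$members)
    cfg$initial_region <- cfg$initial_region %||%
      residue_selection(ens_raw$truth$body_a)
    pair <- make_two_domain_ensemble(n_res_a = 120, n_res_b = 40,
                                     angles_deg = c(0, 6, 15), noise_sd = 0,
                                     seed = seed + 1)
    cfg$conf_pairs <- cfg$conf_pairs %||% list(
      g_to_c = list(a = pair$members$m1, b = pair$members$m2),
      g_to_f = list(a = pair$members$m1, b = pair$members$m3))
    cfg$moving_body <- residue_selection(ens_raw$truth$body_b)
  }
  if (is.null(cfg$cofilactin)) {
    cfg$cofilactin <- make_decorated_filament(n_subunits = 11, decorated = TRUE,
                                              seed = seed)$filament
    cfg$factin <- make_decorated_filament(n_subunits = 11, decorated = FALSE,
                                          seed = seed)$filament
    cfg$id_body <- cfg$id_body %||% residue_selection(1:10)
    cfg$sd1_body <- cfg$sd1_body %||% residue_selection(11:20)
  }
  if (is.null(cfg$initial_region)) abort("config$initial_region is required")
  ctc <- cfg$contact_config %||% contact_config()
  spans <- cfg$spans %||% 2:5

  # ---- rigid-body search -----------------------------------------------------
  res$rigid_body <- stage("rigid_body_search", rigid_body_search(
    cfg$ensemble, cfg$initial_region,
    pass1_threshold = cfg$pass1_threshold %||% 1.0,
    pass2_threshold = cfg$pass2_threshold %||% 0.7), res)

  # ---- rotation axes ---------------------------------------------------------
  moving <- cfg$moving_body %||% body_selection(res$rigid_body)
  res$axes <- stage("screw_axes", purrr::map(cfg$conf_pairs, function(p) {
    screw_axis_between(p$a, p$b, fixed_body = body_selection(res$rigid_body),
                       moving_body = moving)
  }), res)

  # ---- helical measurements --------------------------------------------------
  res$helical <- stage("helical", {
    fits <- list(cofilactin = fit_helical_axis(cfg$cofilactin),
                 factin = fit_helical_axis(cfg$factin))
    tibble(model = names(fits),
           twist_deg = unname(purrr::map_dbl(fits, "twist_deg")),
           rise = unname(purrr::map_dbl(fits, "rise")),
           strand_rotation_deg = unname(purrr::map_dbl(fits, function(f) {
             strand_rotation_from_genetic(f$twist_deg)
           })),
           centroid_axis_dist = purrr::map2_dbl(
             list(cfg$cofilactin, cfg$factin), fits, function(m, fit) {
               sub <- filter(m, !is.na(.data$subunit),
                             .data$subunit == min(.data$subunit, na.rm = TRUE))
               centroid_axis_distance(sub, fit, exclude = cfg$centroid_exclude)
             }))
  }, res)

  # ---- grafts ----------------------------------------------------------------
  mid_sub <- floor(max(cfg$factin$subunit, na.rm = TRUE) / 2)
  res$grafts <- stage("grafts", purrr::map(
    setNames(c("F", "Gi", "Go"), c("F", "Gi", "Go")), function(site) {
      g <- graft_cofilin(cfg$factin, cfg$cofilactin, site = site,
                         target_subunit = mid_sub,
                         id_body = cfg$id_body, sd1_body = cfg$sd1_body)
      info <- attr(g, "graft")
      ct <- find_contacts(filter(g, .data$chain == info$cofilin_chain),
                          filter(g, .data$chain != info$cofilin_chain), ctc)
      list(model = g, rmsd = info$rmsd, contacts = glance(ct))
    }), res)

  # ---- hybrids ---------------------------------------------------------------
  res$hybrids <- stage("hybrids", purrr::map(setNames(spans, paste0("span", spans)),
    function(s) {
      h <- build_hybrid_filament(cfg$cofilactin, cfg$factin, span = s,
                                 id_body = cfg$id_body)
      info <- attr(h, "hybrid")
      repl <- filter(h, .data$subunit %in% info$replaced_subunits |
                       .data$chain %in% info$cofilins$cofilin_chain)
      other <- anti_join(as_tibble(h), as_tibble(repl),
                         by = c("chain", "resno", "atom"))
      ct <- find_contacts(repl, struct_tbl(other, id = "opposite"), ctc)
      list(model = h, rmsd = info$rmsd, interstrand_contacts = glance(ct))
    }), res)

  # ---- summary + outputs -----------------------------------------------------
  res$summary <- tibble(
    quantity = c("rigid_body_size",
                 paste0("axis_angle_", names(res$axes)),
                 paste0("strand_rotation_", res$helical$model),
                 paste0("graft_collisions_", names(res$grafts))),
    value = c(sum(res$rigid_body$residues$in_body),
              purrr::map_dbl(res$axes, "angle_deg"),
              res$helical$strand_rotation_deg,
              purrr::map_dbl(res$grafts, function(g) {
                g$contacts$n_colliding_atoms_a + g$contacts$n_colliding_atoms_b
              })))
  class(res) <- "pipeline_result"

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    jsonlite::write_json(res$config, file.path(out_dir, "run_config.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    utils::write.table(tidy(res$rigid_body),
                       file.path(out_dir, "rigid_body_sd.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(res$helical, file.path(out_dir, "helical.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(
      list(summary = res$summary,
           axes = purrr::map(res$axes, function(a) tidy(a)),
           rigid_body = glance(res$rigid_body)),
      file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA,
      dataframe = "rows")
    for (nm in names(res$grafts)) {
      write_structure(res$grafts[[nm]]$model,
                      file.path(out_dir, paste0("graft_", nm, ".pdb")))
    }
    for (nm in names(res$hybrids)) {
      write_structure(res$hybrids[[nm]]$model,
                      file.path(out_dir, paste0("hybrid_", nm, ".pdb")))
    }
  }
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  print(x$summary, n = Inf)
  invisible(x)
}
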