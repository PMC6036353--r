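# End-to-end orchestration: per beam, (split ->) collimate -> deposit ->
# convert to Gy -> cumulate, with a run manifest capturing every seed and
# the collimation counters, so a run can be reproduced bit for bit.

#' Run the full FAJT dose pipeline for a plan
#'
#' For each beam: VMAT arcs are split into per-control-point-pair
#' sub-fields, each collimated and deposited at its own gantry span and
#' converted with its own Sb factor; static/IMRT fields are collimated
#' whole (dynamically when they have >= 2 control points) and converted
#' with the MU-weighted Sb. Beam doses are cumulated into the plan dose.
#'
#' @param plan a `fajt_plan` (see [load_plan()]) or list of [beam()]s.
#' @param source a `phsp_store` (PhspA), or a [source_model()] from which
#'   `n_source` particles are generated.
#' @param geom a [collimator_geometry()].
#' @param calib a [calibration_config()], or `NULL` to skip absolute
#'   conversion (the per-history grids are summed with MU weights).
#' @param sb_table a [read_sb()] table (required with `calib`).
#' @param phantom a [voxel_phantom()].
#' @param n_requested collimated particles per beam (per sub-field share
#'   for VMAT, proportional to MU).
#' @param n_recycle APR copies per source particle.
#' @param seed master seed; every stage seed is derived from it.
#' @param n_source particles to generate when `source` is a model.
#' @param atten an [attenuation_model()].
#' @param reference optional reference [dose_grid()] to compare against.
#' @param criteria [comparison_criteria()] for the comparison.
#' @param out_dir optional directory: writes `manifest.json`, the plan
#'   dose (text dump), and the comparison report.
#' @return list: `dose` (plan [dose_grid()]), `beam_doses`, `reports`
#'   (collimation counters), `manifest`, and `comparison` when a reference
#'   was given.
#' @export
run_pipeline <- function(plan, source, geom, calib = NULL, sb_table = NULL,
                         phantom = make_water_cube(), n_requested = 1e5,
                         n_recycle = 20, seed = 1L, n_source = 5e5,
                         atten = attenuation_model(), reference = NULL,
                         criteria = comparison_criteria(), out_dir = NULL) {
  t_start <- Sys.time()
  beams <- if (inherits(plan, "fajt_plan")) plan$beams else plan
  if (inherits(source, "source_model")) {
    source <- generate_phspA(source, n_source)
  }
  stopifnot(inherits(source, "phsp_store"))
  if (!is.null(calib) && is.null(sb_table)) {
    stop("absolute conversion needs an Sb table")
  }

  beam_doses <- list()
  reports <- list()
  seeds_used <- list(master = seed)

  for (bi in seq_along(beams)) {
    bm <- beams[[bi]]
    pieces <- if (bm$modality == "vmat_arc" && bm$n_cp > 2) {
      split_vmat_subfields(bm)
    } else {
      list(bm)
    }
    sub_grids <- list()
    for (si in seq_along(pieces)) {
      sub <- pieces[[si]]
      sd <- derive_seed(seed, bi * 1000L + si)
      seeds_used[[paste0("beam", bi, "_sub", si)]] <- sd
      n_req <- if (!is.null(sub$mu_share)) {
        max(1L, round(n_requested * sub$mu_share / bm$total_mu))
      } else {
        n_requested
      }
      rmax <- default_r_max(beam_max_opening(sub), attr(source, "z_plane"),
                            geom$sad)
      reader <- cyclic_reader(source, sd, r_max = rmax)
      cfg <- collimation_config(n_req, n_recycle, seed = sd)
      res <- if (sub$n_cp >= 2) {
        collimate_dynamic(reader, geom, cfg, sub)
      } else {
        collimate_static(reader, geom, cfg,
                         list(jaws = sub$jaws[1, ],
                              mlc = if (!is.null(sub$mlc_boundaries)) {
                                list(boundaries = sub$mlc_boundaries,
                                     bankA = sub$bankA[1, ],
                                     bankB = sub$bankB[1, ])
                              }))
      }
      reports[[paste0("beam", bi, "_sub", si)]] <- res$report
      grid <- deposit(res$store, phantom, atten,
                      gantry_deg = if (sub$n_cp >= 2) NULL else
                        sub$gantry[1],
                      sad = geom$sad)
      if (!is.null(calib)) {
        sb <- if (sub$n_cp >= 2) {
          sb_weighted_imrt(sub, sb_table)
        } else {
          sz <- c(sub$jaws[1, 2] - sub$jaws[1, 1],
                  sub$jaws[1, 4] - sub$jaws[1, 3])
          sb_lookup(sb_table, sz[1], sz[2])
        }
        mu_piece <- if (!is.null(sub$mu_share)) sub$mu_share else bm$total_mu
        grid <- to_gray(grid, calib, mu_piece, sb)
      }
      sub_grids[[si]] <- grid
    }
    beam_doses[[bi]] <- if (length(sub_grids) == 1) {
      sub_grids[[1]]
    } else if (is.null(calib)) {
      sum_dose(sub_grids, "histories")
    } else {
      sum_dose(sub_grids, rep(1, length(sub_grids)))
    }
  }

  plan_dose <- if (length(beam_doses) == 1) {
    beam_doses[[1]]
  } else if (is.null(calib)) {
    mus <- vapply(beams, `[[`, numeric(1), "total_mu")
    sum_dose(beam_doses, mus / sum(mus))
  } else {
    sum_dose(beam_doses, rep(1, length(beam_doses)))
  }

  comparison <- NULL
  if (!is.null(reference)) {
    comparison <- list(
      gamma = gamma3d(reference, plan_dose, criteria),
      chi = chi3d(reference, plan_dose, criteria),
      rmsd = rmsd_percent(reference, plan_dose, criteria$threshold)
    )
  }

  manifest <- list(
    tool = paste("fajtrace",
                 as.character(utils::packageVersion("fajtrace"))),
    created = format(t_start, "%Y-%m-%dT%H:%M:%S%z"),
    seeds = seeds_used,
    n_requested = n_requested, n_recycle = n_recycle,
    source = list(n = nrow(source), z_plane = attr(source, "z_plane")),
    geometry = unclass(geom)[c("mlc_plane_z", "sad", "phspB_z")],
    counters = lapply(reports, unclass),
    wall_time_s = as.numeric(difftime(Sys.time(), t_start, units = "secs"))
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_dose_text(plan_dose, file.path(out_dir, "plan"))
    if (!is.null(comparison)) {
      jsonlite::write_json(
        list(gamma_pass = comparison$gamma$pass_rate,
             chi_pass = comparison$chi$pass_rate,
             rmsd_percent = comparison$rmsd,
             n_evaluated = comparison$gamma$n_evaluated),
        file.path(out_dir, "comparison.json"),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
  }

  list(dose = plan_dose, beam_doses = beam_doses, reports = reports,
       manifest = manifest, comparison = comparison)
}
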