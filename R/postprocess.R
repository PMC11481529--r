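# Post-processing: volume averages, mean superficial speeds, Peclet numbers,
# intercompartmental flow totals, transmantle pressure difference, and the
# experiment suite driving the base model and the five parameter variations.

#' Volume average of a nodal field over a subdomain
#'
#' @param field Nodal values (one per mesh vertex).
#' @param mesh A `brain_mesh`.
#' @param region `"all"`, `"gray"`, `"white"` or `"stem"`.
#' @export
volume_average <- function(field, mesh, region = "all") {
  stopifnot(inherits(mesh, "brain_mesh"), length(field) == nrow(mesh$vertices))
  geom <- tet_geometry(mesh$vertices, mesh$cells)
  sel <- if (identical(region, "all")) rep(TRUE, nrow(mesh$cells)) else {
    lbl <- mesh$legend$subdomain[region]
    if (is.na(lbl)) stop("unknown region: ", region)
    mesh$cell_label == lbl
  }
  if (!any(sel)) stop("region '", region, "' contains no cells")
  vol <- geom$vol[sel]
  cellmean <- rowMeans(matrix(field[mesh$cells[sel, ]], nrow = sum(sel)))
  sum(vol * cellmean) / sum(vol)
}

#' Volume-averaged magnitude of a cellwise velocity field
#'
#' @param velocity Cellwise field (ncell x 3), m/s.
#' @param mesh A `brain_mesh`.
#' @return Mean speed in nm/s.
#' @export
mean_speed <- function(velocity, mesh) {
  stopifnot(nrow(velocity) == nrow(mesh$cells))
  vol <- tet_geometry(mesh$vertices, mesh$cells)$vol
  (sum(vol * sqrt(rowSums(velocity^2))) / sum(vol)) * 1e9
}

#' Intercompartmental flow totals ("flowchart")
#'
#' Domain-integrated transfer rates `int omega_ij (p_j - p_i) dV` for every
#' connected pair, plus per-compartment net boundary inflow, all in ml/min.
#' The pair entries are antisymmetric by construction: `rate` is the flow
#' received by `to` from `from`.
#'
#' @param fields Nodal pressure matrix (nodes x 7, Pa).
#' @param sys An assembled `mpet_system`.
#' @param p_csf_mmHg Lumped SAS pressure (mmHg) for the boundary expressions.
#' @return List with data.frame `pairs` (from, to, rate_ml_min) and named
#'   vector `boundary` (net influx per compartment).
#' @export
intercompartment_totals <- function(fields, sys, p_csf_mmHg) {
  stopifnot(inherits(sys, "mpet_system"))
  prs <- .transfer_pairs()
  rate <- vapply(seq_len(nrow(prs)), function(k) {
    i <- prs[k, 1]; j <- prs[k, 2]
    m3s_to_mlmin(sys$omega[i, j] *
                 sum(sys$w_node * (fields[, i] - fields[, j])))
  }, numeric(1))
  pairs <- data.frame(from = prs[, 1], to = prs[, 2], rate_ml_min = rate,
                      stringsAsFactors = FALSE)
  list(pairs = pairs,
       boundary = .boundary_influx(fields, sys, mmhg_to_pa(p_csf_mmHg)))
}

#' Transmantle pressure difference
#'
#' Area-averaged extracellular pressure over the ventricular wall minus the
#' area average over the pial (cortical) surface, in mmHg.
#'
#' @param p_e Nodal extracellular pressures (Pa).
#' @param mesh A `brain_mesh`.
#' @export
transmantle_dp <- function(p_e, mesh) {
  stopifnot(length(p_e) == nrow(mesh$vertices))
  leg <- mesh$legend$boundary
  area_avg <- function(label) {
    f <- mesh$facets[mesh$facet_label == label, , drop = FALSE]
    if (nrow(f) == 0L) stop("mesh lacks facets with label ", label)
    a <- tri_areas(mesh$vertices, f)
    sum(a * rowMeans(matrix(p_e[f], nrow = nrow(f)))) / sum(a)
  }
  pa_to_mmhg(area_avg(leg[["ventricular"]]) - area_avg(leg[["pial"]]))
}

# sample a result at an absolute time (s); returns the nearest grid index
.result_index <- function(result, time_s) which.min(abs(result$time_s - time_s))

#' Summary row of one simulation at the reporting times
#'
#' Volume-averaged pressures (mmHg) and mean speeds (nm/s) per compartment at
#' one minute before infusion and at end of infusion, Peclet number of the
#' extracellular flow, transmantle pressure difference, Q_pvs and the Davson
#' R_out implied by the lumped trace.
#'
#' @param result An `mpet_result`.
#' @param constants [transport_constants()] for the Peclet numbers.
#' @export
summarize_result <- function(result, constants = transport_constants()) {
  pr <- result$protocol
  k_pre <- .result_index(result, pr$t_pre - 60)
  k_end <- .result_index(result, pr$t_pre + pr$t_inf)
  mesh <- result$sys$mesh
  snap_end <- result$snapshots[[which.min(abs(result$snapshot_times -
                                              (pr$t_pre + pr$t_inf)))]]
  dp <- transmantle_dp(snap_end[, "e"], mesh)
  rout <- (result$p_csf[k_end] - result$subject$p_ref) / pr$Q_inf
  row <- data.frame(
    scenario = result$scenario_name,
    alpha = result$alpha,
    p_csf_pre = result$p_csf[k_pre], p_csf_end = result$p_csf[k_end],
    q_pvs_end = result$q_pvs[k_end],
    peak_pvs_inflow = max(result$boundary[, "pa"]),
    transmantle_dp_end = dp,
    R_out_model = rout,
    stringsAsFactors = FALSE
  )
  for (ci in colnames(result$pbar)) {
    row[[paste0("p_", ci, "_pre")]] <- result$pbar[k_pre, ci]
    row[[paste0("p_", ci, "_end")]] <- result$pbar[k_end, ci]
    row[[paste0("v_", ci, "_pre")]] <- signif(result$speed[k_pre, ci], 2)
    row[[paste0("v_", ci, "_end")]] <- signif(result$speed[k_end, ci], 2)
  }
  row$Pe_e_end <- peclet_number(result$speed[k_end, "e"] * 1e-9, constants)
  row
}

#' Run the experiment suite
#'
#' Executes the requested scenarios on one mesh (generated from
#' [geometry_spec()] defaults when not supplied) with the given subject
#' boundary data, collecting one summary row per run plus flowcharts at one
#' minute before infusion and at the end of infusion. Per-run failures are
#' recorded and the suite continues.
#'
#' @param scenarios Character vector of scenario names (default: base plus
#'   all variations).
#' @param mesh Optional `brain_mesh` shared by all runs.
#' @param subject [subject_boundary_data()].
#' @param protocol,config,bcs Passed to [run_infusion_simulation()].
#' @param outdir Optional directory: writes `summary.csv`, per-run
#'   `trace_<scenario>.csv` and `flowchart_<scenario>_<clock>.csv`.
#' @return List with `summary` (data.frame), `flowcharts`, `results`,
#'   `failures`.
#' @export
run_experiment_suite <- function(scenarios = scenario_names(),
                                 mesh = NULL,
                                 subject = subject_boundary_data(),
                                 protocol = infusion_protocol(),
                                 config = solver_config(),
                                 bcs = mpet_bcs(),
                                 outdir = NULL) {
  if (is.null(mesh)) mesh <- generate_synthetic_brain(geometry_spec())
  if (!is.null(outdir) && !dir.exists(outdir)) {
    dir.create(outdir, recursive = TRUE)
  }
  rows <- list(); flowcharts <- list(); results <- list(); failures <- list()
  for (sc in scenarios) {
    res <- tryCatch(
      run_infusion_simulation(mesh, sc, subject, protocol, config, bcs),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      failures[[sc]] <- conditionMessage(res)
      message("suite: scenario '", sc, "' failed: ", conditionMessage(res))
      next
    }
    results[[sc]] <- res
    rows[[sc]] <- summarize_result(res)
    fc <- list()
    for (clock in c("pre", "end")) {
      tt <- if (clock == "pre") protocol$t_pre - 60 else protocol$t_pre + protocol$t_inf
      k <- which.min(abs(res$snapshot_times - tt))
      fc[[clock]] <- intercompartment_totals(res$snapshots[[k]], res$sys,
                                             res$p_csf[.result_index(res, tt)])
    }
    flowcharts[[sc]] <- fc
    if (!is.null(outdir)) {
      utils::write.csv(data.frame(time_s = res$time_s, p_csf_mmHg = res$p_csf,
                                  q_pvs_ml_min = res$q_pvs, res$pbar,
                                  check.names = FALSE),
                       file.path(outdir, paste0("trace_", sc, ".csv")),
                       row.names = FALSE)
      for (clock in names(fc)) {
        utils::write.csv(fc[[clock]]$pairs,
                         file.path(outdir, sprintf("flowchart_%s_%s.csv", sc, clock)),
                         row.names = FALSE)
      }
    }
  }
  summary <- do.call(rbind, rows)
  if (!is.null(outdir) && !is.null(summary)) {
    utils::write.csv(summary, file.path(outdir, "summary.csv"), row.names = FALSE)
  }
  list(summary = summary, flowcharts = flowcharts, results = results,
       failures = failures)
}
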