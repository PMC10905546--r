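#' Default run configuration
#'
#' The full set of tunable parameters driving the pipeline, as a nested
#' list: `chamber` (Ussing geometry and fluids), `cohort` (synthetic
#' cohort spec), `geometry`, `transport`, `drug`, `grid`, and `study`
#' (the K parameter study: three homogeneous anchor conductivities from
#' the measured tumor set, plus two heterogeneous slice-derived maps;
#' the map anchor values are synthetic stand-ins chosen inside the
#' measured tumor envelope, the second map having the larger
#' edge-to-core contrast). Any subset can be overridden through
#' [run_config()]; unknown keys are rejected.
#'
#' @return A named list of class `run_config`.
#' @export
default_run_config <- function() {
  structure(list(
    seed = 1L,
    chamber = list(w = 1e-3, d = 5.05e-3, b = 1e-3, rho = 998,
                   h = 0.16, g = 9.81, temperature_C = 21, mu_if = 3.5e-3),
    cohort = list(n_samples = 29L, collagen_range = c(10, 50),
                  k_collagen_slope = -0.025, k_intercept = -13.85,
                  noise_sd = 0.15, cell_range = c(5, 40),
                  fibroblast_range = c(2, 40)),
    geometry = list(R_t = 5e-3, R_n = 2.5e-3, hypoxic_thickness = 2.5e-3,
                    R_domain = 2e-2),
    transport = list(Lp = 2.1e-11, SV = 2e4, p_v = 2080, sigma = 0.82,
                     pi_v = 2666, pi_i = 2000,
                     Lp_normal = 2.7e-12, SV_normal = 7000,
                     sigma_normal = 0.91, pi_i_normal = 1330,
                     LpL = 1.33e-11, SLVL = 1e4, p_L = 0,
                     vascular_on = list(necrotic = FALSE, hypoxic = TRUE,
                                        viable = TRUE, normal = TRUE),
                     lymphatic_on = list(necrotic = FALSE, hypoxic = FALSE,
                                         viable = FALSE, normal = TRUE)),
    drug = list(Ld = 5e-7, sigma_d = 0.1, c_p = 0, C_boundary = 0.17,
                duration = 3600, dt = 10, Deff_ref = 3e-10,
                K_ref = 8.8e-15, exponent = 1 / 3, threshold_frac = 0.01),
    grid = list(n_cells = 800L),
    study = list(
      anchors = c(low = 9.4e-16, mid = 8.8e-15, high = 1.6e-14),
      maps = list(T1 = c(K1 = 6.0e-15, K2 = 2.0e-15),
                  T2 = c(K1 = 1.4e-14, K2 = 1.5e-15)),
      K_normal_factor = 5, transition_width = 5e-4)
  ), class = "run_config")
}

# recursively reject keys absent from the template
.check_keys <- function(user, template, path = "") {
  if (!is.list(user)) return(invisible(NULL))
  bad <- setdiff(names(user), names(template))
  if (length(bad)) {
    stop("unknown config key(s): ",
         paste0(path, bad, collapse = ", "), call. = FALSE)
  }
  for (k in names(user)) {
    if (is.list(template[[k]]) && !is.null(names(template[[k]]))) {
      .check_keys(user[[k]], template[[k]], paste0(path, k, "/"))
    }
  }
  invisible(NULL)
}

#' Load and validate a run configuration
#'
#' Reads a YAML file (or takes a list of overrides), validates every key
#' against the schema of [default_run_config()], and merges onto the
#' defaults. Precedence: explicit `overrides` > file > defaults.
#'
#' @param path Optional YAML file path.
#' @param overrides Optional named list of overrides.
#' @return A validated `run_config` list.
#' @export
run_config <- function(path = NULL, overrides = NULL) {
  cfg <- unclass(default_run_config())
  for (layer in list(
    if (!is.null(path)) yaml::read_yaml(path) else NULL,
    overrides)) {
    if (is.null(layer)) next
    .check_keys(layer, cfg)
    cfg <- utils::modifyList(cfg, layer)
    # anchors and maps are replaced wholesale, not merged elementwise
    if (!is.null(layer$study)) {
      for (k in intersect(c("anchors", "maps"), names(layer$study))) {
        cfg$study[[k]] <- layer$study[[k]]
      }
    }
  }
  g <- cfg$geometry
  if (!(g$R_n > 0 && g$R_n + g$hypoxic_thickness <= g$R_t &&
        g$R_t < g$R_domain)) {
    stop("config error in geometry: require 0 < R_n, ",
         "R_n + hypoxic_thickness <= R_t < R_domain", call. = FALSE)
  }
  structure(cfg, class = "run_config")
}

#' Provenance hash of a configuration
#'
#' MD5 of the canonical YAML serialization, embedded in every output file
#' so results can be traced back to their exact parameter set.
#'
#' @param config A `run_config`.
#' @return Character MD5 hash.
#' @export
config_hash <- function(config) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  writeLines(yaml::as.yaml(unclass(config)), tf)
  unname(tools::md5sum(tf))
}

#' Write a table with a provenance header
#'
#' Prepends a `#` comment line carrying the package version and the
#' config hash; the CSV body follows. Read back with
#' `read.csv(, comment.char = "#")`.
#'
#' @param df Data frame to write.
#' @param path Output path.
#' @param config The `run_config` that produced the table.
#' @export
write_provenance_csv <- function(df, path, config) {
  hdr <- sprintf("# tumorflow %s config_md5=%s",
                 as.character(utils::packageVersion("tumorflow")),
                 config_hash(config))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

# build the solver inputs shared by all study cases
.study_context <- function(config) {
  geometry <- do.call(tumor_geometry, config$geometry)
  grid <- radial_grid(geometry, n_cells = config$grid$n_cells)
  params <- do.call(transport_params, config$transport)
  dparams <- do.call(drug_params, config$drug)
  list(geometry = geometry, grid = grid, params = params,
       dparams = dparams)
}

#' Run one flow + drug simulation case
#'
#' @param config A `run_config`.
#' @param profile A [k_profile()].
#' @return List with elements `flow` ([solve_steady_ifp()] result) and
#'   `drug` ([simulate_drug()] result).
#' @export
simulate_case <- function(config, profile) {
  ctx <- .study_context(config)
  flow <- solve_steady_ifp(ctx$grid, profile, ctx$geometry, ctx$params)
  drug <- simulate_drug(flow, ctx$dparams)
  list(flow = flow, drug = drug)
}

#' K parameter study: homogeneous anchors and heterogeneous maps
#'
#' Reproduces the study design around the measured conductivity range:
#' three homogeneous tumor K values (with `K_normal` =
#' `K_normal_factor` x the tumor value) and two heterogeneous
#' slice-derived radial maps, each solved for steady interstitial
#' pressure/velocity and transient drug concentration.
#'
#' @param config A `run_config` (default configuration if omitted).
#' @param outdir Optional output directory; when given, a tidy
#'   `study_summary.csv` plus one radial-profile CSV per case are written,
#'   each carrying the config hash and package version.
#' @return Invisibly, a list with `summary` (one row per case: maximum
#'   IFP and its radius, mean intratumoral IFP, maximum IFV, non-zero IFV
#'   extent, penetration depth) and `profiles` (named list of per-case
#'   radial data frames with columns `r`, `region`, `K`, `p_i`, `u_i`,
#'   `J_V`, `J_L`, `C_final`).
#' @export
run_parameter_study <- function(config = run_config(), outdir = NULL) {
  stopifnot(inherits(config, "run_config"))
  st <- config$study
  cases <- list()
  for (nm in names(st$anchors)) {
    cases[[paste0("hom_", nm)]] <- k_profile(
      "homogeneous", K_tumor = st$anchors[[nm]],
      K_normal = st$K_normal_factor * st$anchors[[nm]],
      transition_width = st$transition_width)
  }
  for (nm in names(st$maps)) {
    m <- st$maps[[nm]]
    cases[[paste0("het_", nm)]] <- profile_from_slices(
      m[["K1"]], m[["K2"]], K_normal_factor = st$K_normal_factor,
      transition_width = st$transition_width)
  }

  ctx <- .study_context(config)
  rows <- list()
  profiles <- list()
  for (case in names(cases)) {
    profile <- cases[[case]]
    flow <- solve_steady_ifp(ctx$grid, profile, ctx$geometry, ctx$params)
    drug <- simulate_drug(flow, ctx$dparams)
    u_c <- (flow$u_faces[-1] + flow$u_faces[-length(flow$u_faces)]) / 2
    in_tumor <- flow$r <= ctx$geometry$R_t
    ifv_thr <- 0.01 * max(abs(flow$u_faces))
    rows[[case]] <- data.frame(
      case = case, shape = profile$shape,
      K_edge = profile$K1, K_core = profile$K_necrotic,
      max_ifp_Pa = max(flow$p_i),
      r_max_ifp_m = flow$r[which.max(flow$p_i)],
      mean_tumor_ifp_Pa = mean(flow$p_i[in_tumor]),
      edge_ifp_Pa = flow$p_i[which.min(abs(flow$r - ctx$geometry$R_t))],
      max_ifv_m_s = max(abs(flow$u_faces)),
      r_max_ifv_m = flow$r_faces[which.max(abs(flow$u_faces))],
      ifv_extent_m = ctx$grid$dr * sum(abs(flow$u_faces) > ifv_thr),
      penetration_depth_m = drug$penetration_depth,
      mass_balance_defect = flow$residual,
      drug_budget_defect = drug$budget_residual)
    profiles[[case]] <- data.frame(
      case = case, r = flow$r, region = as.character(flow$region),
      K = flow$K, p_i = flow$p_i, u_i = u_c,
      J_V = flow$J_V, J_L = flow$J_L,
      C_final = drug$C[nrow(drug$C), ])
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_provenance_csv(summary, file.path(outdir, "study_summary.csv"),
                         config)
    for (case in names(profiles)) {
      write_provenance_csv(profiles[[case]],
                           file.path(outdir, paste0("profile_", case,
                                                    ".csv")),
                           config)
    }
  }
  invisible(list(summary = summary, profiles = profiles))
}
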