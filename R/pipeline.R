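# Tabular I/O and pipeline orchestration: CSV readers/writers with schema
# checks, YAML configuration, and the end-to-end domain-size analysis that
# turns trajectory tables into fitted hydrodynamic parameters, viscosities,
# and derived quantities.

.check_columns <- function(df, need, what) {
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("%s: missing required column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  if (nrow(df) == 0) stop(sprintf("%s: no data rows", what), call. = FALSE)
  invisible(df)
}

#' Read a trajectory table from CSV
#'
#' Expects columns `track_id`, `frame`, `t_s`, `x_um`, `y_um` and optionally
#' `d_a_um`, `phase`; they are renamed to the internal convention (`time`,
#' `x`, `y`, `d_a`).
#'
#' @param path CSV file path.
#' @return A tibble of trajectories.
#' @export
read_trajectory_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  .check_columns(df, c("track_id", "frame", "t_s", "x_um", "y_um"),
                 "trajectory CSV")
  out <- dplyr::rename(df, time = "t_s", x = "x_um", y = "y_um")
  if ("d_a_um" %in% names(out)) out <- dplyr::rename(out, d_a = "d_a_um")
  if (!"phase" %in% names(out)) out$phase <- "unknown"
  out
}

#' Write a trajectory table to CSV
#'
#' @param tracks tibble with internal columns `track_id`, `frame`, `time`,
#'   `x`, `y`, and optionally `d_a`, `phase`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(tracks, path) {
  .check_columns(tracks, c("track_id", "frame", "time", "x", "y"),
                 "trajectory table")
  out <- dplyr::rename(tracks, t_s = "time", x_um = "x", y_um = "y")
  if ("d_a" %in% names(out)) out <- dplyr::rename(out, d_a_um = "d_a")
  readr::write_csv(out, path)
  invisible(path)
}

#' Read a per-domain observation table from CSV
#'
#' Expects columns `d_a_um`, `D_um2_s`, optional `sigma_D`, `phase`.
#'
#' @param path CSV file path.
#' @return A tibble with internal columns `d_a`, `D`, `sigma_D`, `phase`.
#' @export
read_observations_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  .check_columns(df, c("d_a_um", "D_um2_s"), "observations CSV")
  out <- dplyr::rename(df, d_a = "d_a_um", D = "D_um2_s")
  if (!"phase" %in% names(out)) out$phase <- "unknown"
  out
}

#' Write a per-domain observation table to CSV
#'
#' @param obs tibble with columns `d_a`, `D` and optionally `sigma_D`,
#'   `phase`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_observations_csv <- function(obs, path) {
  .check_columns(obs, c("d_a", "D"), "observation table")
  out <- dplyr::rename(obs, d_a_um = "d_a", D_um2_s = "D")
  readr::write_csv(out, path)
  invisible(path)
}

#' Read an FCS autocorrelation curve from CSV
#'
#' Expects columns `tau_s`, `G`, optional `sigma_G`.
#'
#' @param path CSV file path.
#' @return A tibble with columns `tau`, `G` (and `sigma_G` if present).
#' @export
read_fcs_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  .check_columns(df, c("tau_s", "G"), "FCS CSV")
  dplyr::rename(df, tau = "tau_s")
}

#' Read a two-channel image pair from TIFF or PNG files
#'
#' @param path1,path2 per-channel grayscale image files (`.tif`/`.tiff` or
#'   `.png`).
#' @param pixel_size pixel size, um/px.
#' @return A list `channel1`, `channel2`, `pixel_size` (matrices).
#' @export
read_channel_pair <- function(path1, path2, pixel_size) {
  read_one <- function(p) {
    ext <- tolower(tools::file_ext(p))
    img <- if (ext %in% c("tif", "tiff")) {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        stop("reading TIFF requires the 'tiff' package", call. = FALSE)
      }
      tiff::readTIFF(p)
    } else if (ext == "png") {
      if (!requireNamespace("png", quietly = TRUE)) {
        stop("reading PNG requires the 'png' package", call. = FALSE)
      }
      png::readPNG(p)
    } else {
      stop("unsupported image format: .", ext, call. = FALSE)
    }
    if (length(dim(img)) == 3) img <- img[, , 1]
    img
  }
  ch1 <- read_one(path1)
  ch2 <- read_one(path2)
  if (!identical(dim(ch1), dim(ch2))) {
    stop("channel images differ in shape", call. = FALSE)
  }
  list(channel1 = ch1, channel2 = ch2, pixel_size = pixel_size)
}

#' Read an analysis configuration from YAML
#'
#' Unknown keys are rejected; missing keys fall back to the defaults of
#' [sim_config()] and the fitting functions.
#'
#' @param path YAML file path.
#' @return A named list of configuration blocks.
#' @export
read_config_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("seed", "simulation", "tracking", "fit", "energetics", "fcs",
             "registration")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    stop("unknown configuration block(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg
}

#' Fit both phases and derive the headline quantities
#'
#' Runs the full size-from-mobility analysis on an observation table: fits
#' the offset generalized Saffman-Delbruck law per phase, converts the
#' fitted parameters to membrane viscosities by both routes
#' ([viscosity_from_A()] and [viscosity_from_beta()]), checks the implied
#' bulk viscosity, extrapolates to single-lipid mobility (`d = 0.9` nm),
#' and reports the smallest true domain size per phase.
#'
#' Tracked domains of one phase move through the *other* phase, so the
#' viscosity obtained from a phase's fit characterizes the surrounding
#' phase (e.g. the LOD-tracking fit probes the disordered-phase viscosity).
#'
#' @param obs observation table with columns `d_a`, `D`, optional `sigma_D`,
#'   and `phase` (values `"LOD"`/`"LDD"`).
#' @param d_lipid single-lipid diameter for the extrapolation, um.
#' @param seed seed for the fit restarts.
#' @param weighting `"none"` (default) ignores any `sigma_D` column;
#'   `"sigma"` passes it through so [fit_gsd()] weights by `1/sigma_D^2`.
#'   Tracking-derived bootstrap sigmas correlate with the realized estimation
#'   error of each `D`, and weighting by them biases the fit, so they are
#'   ignored unless explicitly requested.
#' @param ... passed to [fit_gsd()].
#' @return A list of class `domain_analysis`: per-phase `gsd_fit` objects
#'   (`fits`) and a tidy `summary` tibble of derived quantities.
#' @export
run_domain_analysis <- function(obs, d_lipid = 0.9e-3, seed = 1,
                                weighting = c("none", "sigma"), ...) {
  .check_columns(obs, c("d_a", "D", "phase"), "observation table")
  weighting <- match.arg(weighting)
  if (weighting == "none" && "sigma_D" %in% names(obs)) {
    obs <- dplyr::select(obs, -"sigma_D")
  }
  phases <- intersect(c("LOD", "LDD"), unique(obs$phase))
  if (length(phases) == 0) stop("no LOD/LDD phase labels found", call. = FALSE)
  fits <- purrr::map(rlang::set_names(phases), function(ph) {
    fit_gsd(dplyr::filter(obs, .data$phase == ph), seed = seed, ...)
  })
  summary <- purrr::map_dfr(phases, function(ph) {
    f <- fits[[ph]]
    sm <- smallest_domain(f)
    tibble::tibble(
      phase = ph,
      A = f$estimates[["A"]], se_A = f$se[["A"]],
      beta = f$estimates[["beta"]], se_beta = f$se[["beta"]],
      delta = f$estimates[["delta"]], se_delta = f$se[["delta"]],
      eta_from_A = viscosity_from_A(f$params),
      eta_from_beta = viscosity_from_beta(f$params),
      eta3d_implied = eta3d_consistency(f$params),
      D_single_lipid = gsd_diffusion(d_lipid, f$params, f$consts),
      d_min = sm$d_min, sigma_d_min = sm$sigma,
      d_min_physical = sm$physical,
      n_obs = f$n_obs
    )
  })
  structure(list(fits = fits, summary = summary, d_lipid = d_lipid),
            class = "domain_analysis")
}

#' @export
print.domain_analysis <- function(x, ...) {
  cat("<domain_analysis>\n")
  print(x$summary)
  invisible(x)
}

#' Write an analysis report as JSON and Markdown
#'
#' @param analysis a `domain_analysis` object.
#' @param energetics optional tibble from [energy_table()].
#' @param json_path,md_path output paths (either may be `NULL` to skip).
#' @return Invisibly, the report list that was serialized.
#' @export
write_report <- function(analysis, energetics = NULL, json_path = NULL,
                         md_path = NULL) {
  stopifnot(inherits(analysis, "domain_analysis"))
  rep <- list(
    summary = analysis$summary,
    parameters = purrr::map(analysis$fits, function(f) {
      list(estimates = as.list(f$estimates), se = as.list(f$se),
           ci95 = list(lower = as.list(f$ci95[, "lower"]),
                       upper = as.list(f$ci95[, "upper"])),
           n_obs = f$n_obs)
    }),
    d_lipid_um = analysis$d_lipid
  )
  if (!is.null(energetics)) rep$energetics <- energetics
  if (!is.null(json_path)) {
    jsonlite::write_json(rep, json_path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  }
  if (!is.null(md_path)) {
    s <- analysis$summary
    lines <- c(
      "# Domain size-from-mobility analysis", "",
      "| phase | A (um^2/s) | beta | delta (um) | eta_A (Pa s) | eta_beta (Pa s) | D(0.9 nm) (um^2/s) | d_min (um) |",
      "|---|---|---|---|---|---|---|---|",
      sprintf("| %s | %.3g ± %.2g | %.3g ± %.2g | %.3g ± %.2g | %.3g | %.3g | %.3g | %.3g ± %.2g |",
              s$phase, s$A, s$se_A, s$beta, s$se_beta, s$delta, s$se_delta,
              s$eta_from_A, s$eta_from_beta, s$D_single_lipid,
              s$d_min, s$sigma_d_min)
    )
    if (!is.null(energetics)) {
      ds <- dplyr::distinct(energetics, .data$state, .data$d_star)
      lines <- c(lines, "", "## Registration energetics", "",
                 sprintf("- d* (%s) = %.3g nm", ds$state, ds$d_star))
    }
    writeLines(lines, md_path)
  }
  invisible(rep)
}
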