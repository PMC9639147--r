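# Plain-text readers/writers (model, pulse, spectrum), run configuration,
# and the end-to-end driver.

#' Short content hash of an R object
#'
#' FNV-1a hash of the serialized object, reported as 8 hex digits;
#' embedded in output headers so runs can be traced to their inputs.
#'
#' @param x any R object.
#' @return character scalar.
#' @export
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  n <- length(bytes)
  if (n > 5000L) bytes <- c(n %% 251L, bytes[as.integer(seq(1, n, length.out = 5000L))])
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

.parse_err <- function(path, lineno, msg) {
  stop(sprintf("%s:%d: %s", path, lineno, msg), call. = FALSE)
}

#' Read / write a vibronic model file
#'
#' Sectioned plain-text format (INI-style).  Sections:
#' `[electronic]` with `gap_eV`; `[modes]` with one line per mode
#' `k freq_g_cm1 freq_e_cm1 displacement`; `[dipole]` with `mu0 x y z` and
#' one `dmu k x y z` line per mode (a.u.); optional `[fc_table]`
#' (`e_state g_state value`) and `[ht_table]` (`e_state g_state mode value`)
#' sections of explicit integrals, indexed on the default basis ordering,
#' which override the analytic per-mode computation (the import path for
#' externally computed, e.g. Duschinsky-mixed, integrals; the convention of
#' the normal coordinates used for the derivatives must be stated by the
#' producing code - this package uses dimensionless ground-surface
#' coordinates).  Lines starting with `#` are comments.  Malformed content
#' is rejected with the offending line number.
#'
#' @param path file path.
#' @param max_quanta basis truncation passed to [vibronic_model()].
#' @return a [vibronic_model()].
#' @export
read_model <- function(path, max_quanta = 1L) {
  lines <- readLines(path)
  section <- ""
  gap <- NULL
  mode_rows <- list(); mu0 <- NULL; dmu_rows <- list()
  fc_rows <- list(); ht_rows <- list()
  for (i in seq_along(lines)) {
    ln <- trimws(sub("#.*", "", lines[i]))
    if (ln == "") next
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("[][]", "", ln)
      next
    }
    toks <- strsplit(ln, "\\s+")[[1]]
    num <- suppressWarnings(as.numeric(toks[-1]))
    if (section == "electronic") {
      if (toks[1] != "gap_eV" || length(toks) != 2 || is.na(num))
        .parse_err(path, i, "expected 'gap_eV <value>'")
      gap <- num
    } else if (section == "modes") {
      v <- suppressWarnings(as.numeric(toks))
      if (length(v) != 4 || any(is.na(v)))
        .parse_err(path, i, "expected 'k freq_g_cm1 freq_e_cm1 displacement'")
      if (v[2] <= 0 || v[3] <= 0)
        .parse_err(path, i, "mode frequencies must be strictly positive")
      mode_rows[[length(mode_rows) + 1L]] <- v
    } else if (section == "dipole") {
      if (toks[1] == "mu0") {
        if (length(num) != 3 || any(is.na(num)))
          .parse_err(path, i, "expected 'mu0 x y z'")
        mu0 <- num
      } else if (toks[1] == "dmu") {
        if (length(num) != 4 || any(is.na(num)))
          .parse_err(path, i, "expected 'dmu k x y z'")
        dmu_rows[[length(dmu_rows) + 1L]] <- num
      } else .parse_err(path, i, "unknown dipole entry")
    } else if (section == "fc_table") {
      v <- suppressWarnings(as.numeric(toks))
      if (length(v) != 3 || any(is.na(v)))
        .parse_err(path, i, "expected 'e_state g_state value'")
      fc_rows[[length(fc_rows) + 1L]] <- v
    } else if (section == "ht_table") {
      v <- suppressWarnings(as.numeric(toks))
      if (length(v) != 4 || any(is.na(v)))
        .parse_err(path, i, "expected 'e_state g_state mode value'")
      ht_rows[[length(ht_rows) + 1L]] <- v
    } else .parse_err(path, i, "content outside a known section")
  }
  if (is.null(gap)) stop(path, ": missing [electronic] gap_eV")
  if (is.null(mu0)) stop(path, ": missing [dipole] mu0")
  n <- length(mode_rows)
  ord <- order(vapply(mode_rows, `[`, numeric(1), 1))
  modes <- lapply(mode_rows[ord], function(v)
    normal_mode(v[2], v[3], v[4], unit = "cm-1"))
  dmu <- matrix(0, 3, n)
  for (v in dmu_rows) {
    if (v[1] < 1 || v[1] > n) stop(path, ": dmu mode index out of range")
    dmu[, v[1]] <- v[2:4]
  }
  fc_table <- ht_table <- NULL
  if (length(fc_rows) || length(ht_rows)) {
    ns <- nrow(build_basis(modes, max_quanta))
    fc_table <- matrix(0, ns, ns)
    for (v in fc_rows) fc_table[v[1], v[2]] <- v[3]
    ht_table <- array(0, c(ns, ns, max(n, 1L)))
    for (v in ht_rows) ht_table[v[1], v[2], v[3]] <- v[4]
  }
  vibronic_model(modes, gap = gap, mu0 = mu0, dmu = dmu,
                 max_quanta = max_quanta,
                 fc_table = fc_table, ht_table = ht_table)
}

#' @rdname read_model
#' @param model a [vibronic_model()] (analytic-integral models only; models
#'   carrying imported tables are written back with their tables).
#' @export
write_model <- function(model, path) {
  fmt <- function(x) sprintf("%.17g", x)
  lines <- c("# tdraman vibronic model",
             "[electronic]",
             paste("gap_eV", fmt(model$gap * au$hartree_eV)),
             "[modes]")
  for (k in seq_len(model$n_modes)) {
    m <- model$modes[[k]]
    lines <- c(lines, paste(k, fmt(au_to_cm1(m$freq_g)),
                            fmt(au_to_cm1(m$freq_e)), fmt(m$displacement)))
  }
  lines <- c(lines, "[dipole]",
             paste("mu0", paste(fmt(model$mu0), collapse = " ")))
  for (k in seq_len(model$n_modes))
    lines <- c(lines, paste("dmu", k, paste(fmt(model$dmu[, k]), collapse = " ")))
  if (!is.null(model$fc_table)) {
    lines <- c(lines, "[fc_table]")
    idx <- which(model$fc_table != 0, arr.ind = TRUE)
    for (r in seq_len(nrow(idx)))
      lines <- c(lines, paste(idx[r, 1], idx[r, 2],
                              fmt(model$fc_table[idx[r, 1], idx[r, 2]])))
    if (!is.null(model$ht_table)) {
      lines <- c(lines, "[ht_table]")
      idx <- which(model$ht_table != 0, arr.ind = TRUE)
      for (r in seq_len(nrow(idx)))
        lines <- c(lines, paste(idx[r, 1], idx[r, 2], idx[r, 3],
                                fmt(model$ht_table[idx[r, 1], idx[r, 2], idx[r, 3]])))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a tabulated pulse file
#'
#' Two-column whitespace-separated text (time in fs, field value); a header
#' comment line `# unit: au` or `# unit: V/m` declares the field unit and an
#' optional `# polarization: x y z` line sets the direction (default x).
#'
#' @param path file path.
#' @return a [tabulated_pulse()].
#' @export
read_pulse <- function(path) {
  lines <- readLines(path)
  unit <- "au"; pol <- c(1, 0, 0)
  rows <- list()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "") next
    if (startsWith(ln, "#")) {
      if (grepl("unit:", ln))
        unit <- trimws(sub(".*unit:", "", ln))
      if (grepl("polarization:", ln))
        pol <- as.numeric(strsplit(trimws(sub(".*polarization:", "", ln)),
                                   "\\s+")[[1]])
      next
    }
    v <- suppressWarnings(as.numeric(strsplit(ln, "\\s+")[[1]]))
    if (length(v) != 2 || any(is.na(v)))
      .parse_err(path, i, "expected 'time_fs field'")
    rows[[length(rows) + 1L]] <- v
  }
  if (!unit %in% c("au", "V/m"))
    stop(path, ": field unit must be 'au' or 'V/m'")
  m <- do.call(rbind, rows)
  tabulated_pulse(m[, 1], m[, 2], polarization = pol, amplitude_unit = unit)
}

#' Write / read a spectrum file
#'
#' Tab-separated text: comment header with the content hash, incident
#' frequency, observation times and units, then columns `omega_au`,
#' `shift_cm1` and one cross-section column per observation time.
#'
#' @param spectrum a `spectrum_series`.
#' @param path file path.
#' @param seed optional seed to record in the header.
#' @export
write_spectrum <- function(spectrum, path, seed = NULL) {
  hdr <- c("# tdraman cumulative scattering cross-section",
           paste("# hash:", config_hash(spectrum)),
           paste("# omega_I_au:", sprintf("%.17g", spectrum$omega_I)),
           paste("# t_obs_fs:", paste(sprintf("%.17g", au_to_fs(spectrum$t_obs)),
                                      collapse = " ")),
           if (!is.null(seed)) paste("# seed:", seed),
           "# units: atomic units of d^2 sigma / (d omega_S d Omega)")
  tab <- cbind(spectrum$omega, spectrum$shift_cm1, spectrum$sigma)
  colnames(tab) <- c("omega_au", "shift_cm1",
                     sprintf("sigma_t%d", seq_along(spectrum$t_obs)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(format(tab, digits = 17, trim = TRUE), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  getv <- function(key) {
    ln <- hdr[grepl(paste0("# ", key, ":"), hdr, fixed = TRUE)]
    if (!length(ln)) return(NULL)
    as.numeric(strsplit(trimws(sub(paste0(".*", key, ":"), "", ln[1])),
                        "\\s+")[[1]])
  }
  tab <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  omega_I <- getv("omega_I_au")
  structure(list(
    omega = tab$omega_au,
    shift_cm1 = tab$shift_cm1,
    t_obs = fs_to_au(getv("t_obs_fs")),
    per_state = NULL,
    sigma = as.matrix(tab[, -(1:2), drop = FALSE]),
    omega_I = omega_I, fluence = NA_real_
  ), class = "spectrum_series")
}

#' Export a quantum-jump log
#'
#' @param trajectories list of SSE `coef_trajectory` objects.
#' @param path CSV output path.
#' @export
write_jump_log <- function(trajectories, path) {
  rows <- do.call(rbind, lapply(seq_along(trajectories), function(i) {
    tr <- trajectories[[i]]
    if (!length(tr$jump_times)) return(NULL)
    data.frame(trajectory = i, time_fs = au_to_fs(tr$jump_times),
               channel = tr$jump_channels)
  }))
  if (is.null(rows))
    rows <- data.frame(trajectory = integer(0), time_fs = numeric(0),
                       channel = integer(0))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

# ---- run configuration ------------------------------------------------

.default_config <- function() {
  list(
    model = NULL,
    synthesize = list(n_modes = 2, seed = 1),
    pulse = list(eps0_Vm = 5.14e5, sigma_fs = 256, t0_fs = 968,
                 omega_eV = 2.04, phase = 0),
    grid = list(dt_fs = 0.024, duration_fs = 2400, stride = 4),
    observation_times_fs = c(484, 968, 1451, 1936, 2400),
    shift_window_cm1 = NULL,
    pad = 8,
    relaxation = list(enabled = FALSE, lifetime_ps = 1.8, surfaces = "both"),
    ensemble = list(n_traj = 1, seed = 1),
    output = list(spectrum = "spectrum.tsv", log = NULL)
  )
}

# recursive merge that keeps NULL-valued keys (unlike modifyList), so a
# configuration round-trips through YAML identically
.merge_config <- function(base, new) {
  for (k in names(new)) {
    if (is.list(base[[k]]) && is.list(new[[k]]))
      base[[k]] <- .merge_config(base[[k]], new[[k]])
    else base[k] <- list(new[[k]])
  }
  base
}

#' Read and validate a run configuration
#'
#' YAML run configuration; unspecified keys take the defaults of a
#' porphyrin-like nonresonant demo run.  Validation reports every offending
#' key at once.  A parsed configuration serializes back to YAML and
#' re-parses identically.
#'
#' @param x path to a YAML file, or a configuration list.
#' @return validated configuration list (class `run_config`).
#' @export
read_run_config <- function(x) {
  cfg <- if (is.character(x)) yaml::read_yaml(x) else x
  base <- .merge_config(.default_config(), cfg)
  bad <- character(0)
  if (!is.null(base$model) && !file.exists(base$model))
    bad <- c(bad, "model (file does not exist)")
  p <- base$pulse
  if (!is.numeric(p$sigma_fs) || p$sigma_fs <= 0) bad <- c(bad, "pulse.sigma_fs")
  if (!is.numeric(p$eps0_Vm) || p$eps0_Vm < 0) bad <- c(bad, "pulse.eps0_Vm")
  if (!is.numeric(p$omega_eV) || p$omega_eV <= 0) bad <- c(bad, "pulse.omega_eV")
  g <- base$grid
  if (!is.numeric(g$dt_fs) || g$dt_fs <= 0) bad <- c(bad, "grid.dt_fs")
  if (!is.numeric(g$duration_fs) || g$duration_fs <= 0) bad <- c(bad, "grid.duration_fs")
  if (g$stride < 1) bad <- c(bad, "grid.stride")
  if (!length(base$observation_times_fs) ||
        any(base$observation_times_fs > g$duration_fs))
    bad <- c(bad, "observation_times_fs (beyond duration)")
  if (base$ensemble$n_traj < 1) bad <- c(bad, "ensemble.n_traj (must be >= 1)")
  if (base$relaxation$lifetime_ps <= 0) bad <- c(bad, "relaxation.lifetime_ps")
  if (length(bad))
    stop("invalid run configuration: ", paste(bad, collapse = ", "),
         call. = FALSE)
  structure(base, class = "run_config")
}

#' @rdname read_run_config
#' @param cfg a validated configuration.
#' @param path YAML output path.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Run the full simulation pipeline from a configuration
#'
#' Loads or synthesizes the model, runs the three incident-field directions
#' (x, y, z) through the propagation, scattered-field and averaging stages
#' (closed-system, or an SSE trajectory ensemble when relaxation is
#' enabled), writes the spectrum file and an optional plain-text log, and
#' returns the spectrum.  Deterministic for a fixed configuration and seed.
#'
#' @param config a configuration list, path, or [read_run_config()] result.
#' @return the `spectrum_series`, invisibly.
#' @export
run_simulation <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else read_run_config(config)
  t_start <- Sys.time()
  model <- if (!is.null(cfg$model)) read_model(cfg$model)
  else do.call(synthesize_model, cfg$synthesize)
  pulse <- gaussian_pulse(cfg$pulse$eps0_Vm, cfg$pulse$sigma_fs,
                          cfg$pulse$t0_fs, cfg$pulse$omega_eV,
                          phase = cfg$pulse$phase, amplitude_unit = "V/m")
  grid <- propagation_grid(cfg$grid$duration_fs, cfg$grid$dt_fs,
                           cfg$grid$stride)
  if (isTRUE(cfg$relaxation$enabled)) {
    channels <- decay_channels(model, cfg$relaxation$lifetime_ps,
                               cfg$relaxation$surfaces)
    spec <- sse_spectrum_ensemble(model, pulse, grid,
                                  cfg$observation_times_fs, channels,
                                  n_traj = cfg$ensemble$n_traj,
                                  seed = cfg$ensemble$seed,
                                  shift_window_cm1 = cfg$shift_window_cm1,
                                  pad = cfg$pad)
  } else {
    spec <- scattering_spectrum(model, pulse, grid,
                                cfg$observation_times_fs,
                                shift_window_cm1 = cfg$shift_window_cm1,
                                pad = cfg$pad)
  }
  if (!is.null(cfg$output$spectrum))
    write_spectrum(spec, cfg$output$spectrum, seed = cfg$ensemble$seed)
  if (!is.null(cfg$output$log)) {
    writeLines(c(
      "tdraman run log",
      paste("version:", as.character(utils::packageVersion("tdraman"))),
      paste("R:", R.version.string),
      paste("config hash:", config_hash(unclass(cfg))),
      paste("seed:", cfg$ensemble$seed),
      paste("model hash:", config_hash(model)),
      paste("wall clock (s):",
            sprintf("%.1f", as.numeric(difftime(Sys.time(), t_start,
                                                units = "secs")))),
      "config:",
      utils::capture.output(utils::str(unclass(cfg)))
    ), cfg$output$log)
  }
  invisible(spec)
}
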