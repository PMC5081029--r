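PARAM_KEYS_REQUIRED <- c("gamma", "K_BC", "k_BC_ref", "f_ref", "delta",
                         "lam", "k_Ca_on", "k_Ca_off")
PARAM_KEYS_OPTIONAL <- c("RT", "angles", "label")
ANGLE_KEYS <- c("phi_B", "phi_C", "phi_M")

#' Read / write a parameter set as YAML
#'
#' The YAML schema mirrors the [tm_params()] fields, with angles given in
#' degrees under an `angles:` block.  Unknown keys are rejected and missing
#' required keys are reported by name.
#'
#' @param path file path.
#' @param params a [tm_params()] object.
#' @return `load_params()` returns a [tm_params()]; `write_params()`
#'   returns the path invisibly.
#' @export
load_params <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  y <- yaml::read_yaml(path)
  if (!is.list(y)) stop("malformed parameter file: ", path)
  known <- c(PARAM_KEYS_REQUIRED, PARAM_KEYS_OPTIONAL)
  extra <- setdiff(names(y), known)
  if (length(extra))
    stop("unknown key(s) in ", basename(path), ": ",
         paste(extra, collapse = ", "))
  missing <- setdiff(PARAM_KEYS_REQUIRED, names(y))
  if (length(missing))
    stop("missing required key(s) in ", basename(path), ": ",
         paste(missing, collapse = ", "))
  angles <- if (!is.null(y$angles)) {
    bad <- setdiff(names(y$angles), ANGLE_KEYS)
    if (length(bad))
      stop("unknown angle key(s): ", paste(bad, collapse = ", "))
    do.call(tm_angles, y$angles)
  } else tm_angles()
  tm_params(gamma = y$gamma, K_BC = y$K_BC, k_BC_ref = y$k_BC_ref,
            f_ref = y$f_ref, delta = y$delta, lam = y$lam,
            k_Ca_on = y$k_Ca_on, k_Ca_off = y$k_Ca_off,
            RT = if (is.null(y$RT)) 2.577 else y$RT,
            angles = angles,
            label = if (is.null(y$label)) "" else y$label)
}

#' @rdname load_params
#' @export
write_params <- function(params, path) {
  validate_params(params)
  a <- params$angles
  y <- list(label = params$label, gamma = params$gamma, K_BC = params$K_BC,
            k_BC_ref = params$k_BC_ref, f_ref = params$f_ref,
            delta = params$delta, lam = params$lam,
            k_Ca_on = params$k_Ca_on, k_Ca_off = params$k_Ca_off,
            RT = params$RT,
            angles = list(phi_B = a$phi_B * 180 / pi,
                          phi_C = a$phi_C * 180 / pi,
                          phi_M = a$phi_M * 180 / pi))
  yaml::write_yaml(y, path, precision = 15)
  invisible(path)
}

#' Read / write a force-pCa curve as CSV
#'
#' Plain CSV with columns `pca`, `force`, `force_sem` and an optional
#' leading metadata block of `# key: value` comment lines.  Values are
#' written with full double precision so that a write/read cycle is
#' lossless.
#'
#' @param curve a `force_pca_curve`.
#' @param path file path.
#' @return `read_curve()` returns a `force_pca_curve`; `write_curve()`
#'   returns the path invisibly.
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "force_pca_curve"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n_runs: %s", curve$n_runs), con)
  writeLines("pca,force,force_sem", con)
  writeLines(sprintf("%.17g,%.17g,%.17g", curve$pca, curve$force,
                     curve$force_sem), con)
  invisible(path)
}

#' @rdname write_curve
#' @export
read_curve <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  if (!length(lines)) stop("parse error: ", basename(path), " is empty")
  meta <- grep("^#", lines)
  n_runs <- NA_integer_
  for (i in meta) {
    m <- regmatches(lines[i], regexec("^#\\s*n_runs:\\s*(\\S+)", lines[i]))[[1]]
    if (length(m) == 2) n_runs <- suppressWarnings(as.integer(m[2]))
  }
  body <- lines[setdiff(seq_along(lines), meta)]
  if (length(body) < 2)
    stop("parse error in ", basename(path), ": no data rows")
  df <- tryCatch(
    utils::read.csv(text = body, stringsAsFactors = FALSE),
    error = function(e) stop("parse error in ", basename(path), ": ",
                             conditionMessage(e)))
  need <- c("pca", "force", "force_sem")
  if (!all(need %in% names(df)))
    stop("parse error in ", basename(path), ": columns must be ",
         paste(need, collapse = ", "))
  for (cn in need) {
    if (!is.numeric(df[[cn]])) {
      v <- suppressWarnings(as.numeric(df[[cn]]))
      bad <- which(is.na(v) & !is.na(df[[cn]]))
      if (length(bad))
        stop("parse error in ", basename(path), " at data line ", bad[1],
             ": non-numeric ", cn)
      df[[cn]] <- v
    }
  }
  bad <- which(!stats::complete.cases(df[need]))
  if (length(bad))
    stop("parse error in ", basename(path), " at data line ", bad[1])
  new_force_pca_curve(df$pca, df$force, df$force_sem, params = NULL,
                      n_runs = n_runs)
}

#' Read / write a calcium transient as 2-column CSV
#'
#' Columns `time_ms` and `ca_uM`, the dialect used for measured-transient
#' input files.
#'
#' @param transient a [calcium_transient()].
#' @param path file path.
#' @return `read_transient()` returns a [calcium_transient()].
#' @export
write_transient <- function(transient, path) {
  stopifnot(inherits(transient, "calcium_transient"))
  utils::write.csv(data.frame(time_ms = transient$times,
                              ca_uM = transient$ca),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_transient
#' @export
read_transient <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time_ms", "ca_uM") %in% names(df)))
    stop("parse error in ", basename(path),
         ": columns must be time_ms, ca_uM")
  calcium_transient(df$time_ms, df$ca_uM)
}

#' Run a named multi-step study end to end
#'
#' Executes one of the packaged pipeline recipes, writing all artifacts
#' plus a JSON run manifest (configuration snapshot, package version,
#' seeds, chosen time steps, runtime) sufficient to reproduce the outputs.
#'
#' * `"reproduce-table2"`: simulates the wild-type skinned (Set 1) and
#'   reconstituted (Set 2) steady-state force-pCa curves and writes their
#'   Hill statistics.
#' * `"mutant-twitch"`: simulates wild-type (Set 3), E180G (Set 4) and
#'   D175N (Set 5) twitches under one shared synthetic calcium transient
#'   and writes the twitch metric table.
#'
#' @param recipe `"reproduce-table2"` or `"mutant-twitch"`.
#' @param out_dir output directory (created if needed).
#' @param seed top-level seed from which every stochastic stage derives.
#' @param n_runs replicates per condition.
#' @param duration steady-state activation length in ms
#'   (`reproduce-table2` only).
#' @return Invisibly, a list with the computed results and the manifest.
#' @export
run_pipeline <- function(recipe = c("reproduce-table2", "mutant-twitch"),
                         out_dir = ".", seed = 1, n_runs = 200,
                         duration = 7500) {
  recipe <- match.arg(recipe)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()[["elapsed"]]
  manifest <- list(recipe = recipe, seed = seed, n_runs = n_runs,
                   package_version = as.character(utils::packageVersion("tmcoop")),
                   stages = list())
  results <- list()
  if (recipe == "reproduce-table2") {
    grids <- list(set1_skinned = seq(6.4, 4.8, by = -0.1),
                  set2_reconstituted = seq(7.0, 4.5, by = -0.25))
    stats_rows <- list()
    for (set in names(grids)) {
      p <- param_set(set)
      cfg <- sim_config(n_runs = n_runs, duration = duration, seed = seed)
      curve <- force_pca_curve(grids[[set]], p, cfg)
      hf <- fit_hill(curve)
      write_curve(curve, file.path(out_dir, paste0(set, "_fpca.csv")))
      stats_rows[[set]] <- data.frame(set = set, n_H = hf$n_H,
                                      pCa50 = hf$pCa50, F_max = hf$F_max,
                                      n_H_lower = hf$n_H_lower,
                                      n_H_upper = hf$n_H_upper)
      manifest$stages[[set]] <- list(
        pca_grid = grids[[set]],
        dt = choose_dt(p, pca_to_ca(min(grids[[set]]))),
        completed = TRUE)
      results[[set]] <- hf
    }
    tab <- do.call(rbind, stats_rows)
    utils::write.csv(tab, file.path(out_dir, "hill_stats.csv"),
                     row.names = FALSE)
    results$table <- tab
  } else {
    tr <- make_transient()
    write_transient(tr, file.path(out_dir, "transient.csv"))
    rows <- list()
    for (set in c("set3_intact", "set4_intact_E180G", "set5_intact_D175N")) {
      p <- param_set(set)
      cfg <- sim_config(n_runs = n_runs, seed = seed, record_dt = 1)
      tw <- twitch(tr, p, cfg)
      mt <- twitch_metrics(tw)
      rows[[set]] <- data.frame(set = set, peak = mt$peak_force,
                                diastolic = mt$diastolic_force,
                                ttp = mt$ttp, rt50 = mt$rt50,
                                tti = mt$tension_time_integral)
      manifest$stages[[set]] <- list(dt = tw$dt, completed = TRUE)
      results[[set]] <- mt
    }
    tab <- do.call(rbind, rows)
    utils::write.csv(tab, file.path(out_dir, "twitch_metrics.csv"),
                     row.names = FALSE)
    results$table <- tab
  }
  manifest$runtime_s <- proc.time()[["elapsed"]] - t0
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(results = results, manifest = manifest))
}
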