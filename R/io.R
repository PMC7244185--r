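#' Load a simulation configuration from a file or preset
#'
#' Accepts a flat key-value configuration in JSON or in a minimal flat YAML
#' dialect (`key: value` lines, `#` comments; no nesting). Recognized keys:
#' `a`, `b`, `c`, `alpha`, `beta`, `L`, `d`, `N`, `dt`, `T`, `record_every`,
#' `init_mode`, `seed`, `epsilon`. Alternatively `preset` may name one of the
#' published parameter tables (see [preset_params()]); explicit keys override
#' preset values.
#'
#' @param path path to a `.json`/`.yaml`/`.yml` file, or `NULL` when only a
#'   preset is wanted
#' @param preset optional preset name (`"table1"`, `"table2"`, `"table3"`)
#' @return list with `params` ([model_params]), `sim` ([sim_config]) and `N`
#' @export
load_config <- function(path = NULL, preset = NULL) {
  vals <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
      jsonlite::read_json(path, simplifyVector = TRUE)
    } else {
      read_flat_yaml(path)
    }
  }
  if (!is.null(vals$preset)) preset <- vals$preset
  defaults <- list(c = 10, alpha = 40, beta = 1, L = 300, d = 2, N = 1000,
                   dt = 0.02, T = 1000, record_every = 10,
                   init_mode = "random", seed = 1, epsilon = 1e-6,
                   descent = "per_cell")
  if (!is.null(preset)) {
    pp <- preset_params(preset)
    defaults[c("a", "b", "c", "alpha", "beta", "L", "d")] <-
      pp$params[c("a", "b", "c", "alpha", "beta", "L", "d")]
    defaults$N <- pp$N
  }
  known <- c(names(defaults), "a", "b", "preset")
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  for (k in setdiff(names(vals), "preset")) defaults[[k]] <- vals[[k]]
  missing <- setdiff(c("a", "b"), names(defaults))
  if (length(missing))
    stop("missing required config keys: ", paste(missing, collapse = ", "))
  params <- model_params(a = defaults$a, b = defaults$b, c = defaults$c,
                         alpha = defaults$alpha, beta = defaults$beta,
                         L = defaults$L, d = defaults$d,
                         descent = defaults$descent)
  sim <- sim_config(dt = defaults$dt, T_final = defaults$T,
                    record_every = defaults$record_every,
                    seed = defaults$seed, init_mode = defaults$init_mode,
                    epsilon = defaults$epsilon)
  list(params = params, sim = sim, N = as.integer(defaults$N))
}

# minimal flat YAML: "key: value" scalar lines only (no yaml package in the
# supported environment)
read_flat_yaml <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*:\\s*(.*)$", ln))[[1]]
    if (length(m) != 3) stop("cannot parse config line: ", ln)
    val <- trimws(m[3])
    num <- suppressWarnings(as.numeric(val))
    out[[m[2]]] <- if (!is.na(num)) num else gsub("^['\"]|['\"]$", "", val)
  }
  out
}

#' Write a trajectory as a tidy per-snapshot table
#'
#' Plain tab-separated text with a header row and columns `time`, `cell_id`,
#' `x`, `y`\[, `z`\], `wx`, `wy`\[, `wz`\]. Values are written with 17
#' significant digits so that reading the file back reproduces every double
#' bit-exactly.
#'
#' @param traj a `trajectory`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_trajectory <- function(traj, path) {
  d <- traj$params$d
  nrec <- length(traj$times)
  cols <- if (d == 2L) c("x", "y", "wx", "wy") else c("x", "y", "z", "wx", "wy", "wz")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("time", "cell_id", cols), collapse = "\t"), con)
  for (k in seq_len(nrec)) {
    pos <- array_slab(traj$positions, k)
    ori <- array_slab(traj$orientations, k)
    block <- cbind(pos, ori)
    txt <- sprintf("%.17g", block)
    dim(txt) <- dim(block)
    lines <- apply(cbind(sprintf("%.17g", rep(traj$times[k], traj$N)),
                         as.character(seq_len(traj$N)), txt), 1L,
                   paste, collapse = "\t")
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read a trajectory table written by [write_trajectory()]
#'
#' @param path file path
#' @param params the [model_params] of the run (carried for provenance; `L`
#'   and `d` must match the file)
#' @param sim optional [sim_config] for provenance
#' @return a `trajectory`
#' @export
read_trajectory <- function(path, params, sim = NULL) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  d <- if ("z" %in% names(tab)) 3L else 2L
  if (d != params$d) stop("trajectory dimension does not match params$d")
  times <- unique(tab$time)
  N <- sum(tab$time == times[1])
  poscols <- if (d == 2L) c("x", "y") else c("x", "y", "z")
  oricols <- if (d == 2L) c("wx", "wy") else c("wx", "wy", "wz")
  nrec <- length(times)
  pos <- array(NA_real_, c(N, d, nrec))
  ori <- array(NA_real_, c(N, d, nrec))
  for (k in seq_len(nrec)) {
    blk <- tab[tab$time == times[k], ]
    blk <- blk[order(blk$cell_id), ]
    pos[, , k] <- as.matrix(blk[, poscols])
    ori[, , k] <- as.matrix(blk[, oricols])
  }
  structure(list(times = times, positions = pos, orientations = ori,
                 params = params,
                 sim = if (is.null(sim)) sim_config(T_final = max(times, 1)) else sim,
                 N = N),
            class = "trajectory")
}

#' Write a run manifest
#'
#' A small JSON record sufficient to reproduce a run: model and simulation
#' parameters, cell count, package version, wall-clock interval and output
#' paths.
#'
#' @param params a [model_params]
#' @param sim a [sim_config]
#' @param N cell count
#' @param outputs character vector of file paths produced by the run
#' @param path manifest destination (JSON)
#' @param started,finished POSIXct wall-clock stamps
#' @return `path`, invisibly
#' @export
write_manifest <- function(params, sim, N, outputs, path,
                           started = Sys.time(), finished = Sys.time()) {
  man <- list(
    package = "oncostream",
    version = as.character(utils::packageVersion("oncostream")),
    params = unclass(params)[c("a", "b", "c", "alpha", "beta", "L", "d",
                               "descent")],
    sim = unclass(sim),
    N = N,
    started = format(started, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(finished, "%Y-%m-%dT%H:%M:%S%z"),
    outputs = as.list(outputs))
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Re-run a simulation from a manifest
#'
#' @param path manifest JSON written by [write_manifest()]
#' @return a `trajectory` reproducing the original run
#' @export
replay_manifest <- function(path) {
  man <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- man$params
  params <- model_params(a = p$a, b = p$b, c = p$c, alpha = p$alpha,
                         beta = p$beta, L = p$L, d = p$d, descent = p$descent)
  s <- man$sim
  sim <- sim_config(dt = s$dt, T_final = s$T_final,
                    record_every = s$record_every, seed = s$seed,
                    init_mode = s$init_mode, epsilon = s$epsilon)
  simulate_cells(params, sim, as.integer(man$N))
}

#' Draw a configuration as ellipse glyphs colored by travel direction
#'
#' Each cell is drawn as an ellipse with semi-axes `a` (along its
#' orientation) and `b`, colored by the sign of its inner product with the
#' nematic mean direction (blue with the flow, red against it). In 3D the
#' glyphs are the projections onto the first two coordinates. The periodic
#' box is drawn to scale.
#'
#' @param config a [cell_configuration]
#' @param params a [model_params]
#' @param n_vertices polygon resolution per glyph
#' @return a ggplot object
#' @export
render_snapshot <- function(config, params, n_vertices = 24L) {
  w <- config$orientations
  lab <- color_by_nematic(w)
  tau <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  ex <- params$a * cos(tau)
  ey <- params$b * sin(tau)
  N <- config$N
  polys <- lapply(seq_len(N), function(i) {
    cx <- w[i, 1]; cy <- w[i, 2]
    nrm <- sqrt(cx^2 + cy^2)
    if (nrm < 1e-12) { cx <- 1; cy <- 0 } else { cx <- cx / nrm; cy <- cy / nrm }
    data.frame(id = i,
               x = config$positions[i, 1] + ex * cx - ey * cy,
               y = config$positions[i, 2] + ex * cy + ey * cx,
               side = factor(ifelse(lab[i] > 0, "with flow", "against flow"),
                             levels = c("with flow", "against flow")))
  })
  df <- do.call(rbind, polys)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   group = .data$id, fill = .data$side)) +
    ggplot2::geom_polygon(colour = NA, alpha = 0.8) +
    ggplot2::scale_fill_manual(values = c("with flow" = "#3366cc",
                                          "against flow" = "#cc3333"),
                               name = NULL, drop = FALSE) +
    ggplot2::coord_fixed(xlim = c(0, params$L), ylim = c(0, params$L),
                         expand = FALSE) +
    ggplot2::labs(x = "x (um)", y = "y (um)",
                  title = sprintf("t = %g h", config$time)) +
    ggplot2::theme_minimal()
}
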