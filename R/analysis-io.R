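#' Enrichment summary over a record stream
#'
#' Means of the slow type's relative abundance in patches and in dispersing
#' hosts over the cycles where both are defined, and their difference
#' \code{f_host - f_patch} - the host-enrichment statistic.
#'
#' @param records A data.frame of per-cycle records with columns
#'   \code{f_patch} and \code{f_host} (e.g. [run_simulation()] output).
#' @return A list with \code{mean_f_patch}, \code{mean_f_host},
#'   \code{mean_difference}, and \code{n_cycles} (cycles used).  All
#'   \code{NA} when no cycle has both quantities defined.
#' @examples
#' r <- run_simulation(sim_params(M = 5, K = 200, tau = 50, D = 20),
#'                     n_cycles = 5, invader = "all", seed = 1)
#' enrichment_summary(r)
#' @export
enrichment_summary <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) >= 1,
            all(c("f_patch", "f_host") %in% names(records)))
  ok <- !is.na(records$f_patch) & !is.na(records$f_host)
  if (!any(ok)) {
    return(list(mean_f_patch = NA_real_, mean_f_host = NA_real_,
                mean_difference = NA_real_, n_cycles = 0L))
  }
  list(mean_f_patch = mean(records$f_patch[ok]),
       mean_f_host = mean(records$f_host[ok]),
       mean_difference = mean(records$f_host[ok] - records$f_patch[ok]),
       n_cycles = sum(ok))
}

#' @export
summary.mp_records <- function(object, ...) {
  s <- enrichment_summary(object)
  structure(s, class = "mp_records_summary")
}

#' @export
print.mp_records_summary <- function(x, ...) {
  cat("Slow-type enrichment over", x$n_cycles, "cycles:\n")
  cat(sprintf("  mean f_patch      = %s\n", format(x$mean_f_patch, digits = 4)))
  cat(sprintf("  mean f_host       = %s\n", format(x$mean_f_host, digits = 4)))
  cat(sprintf("  mean (f_host - f_patch) = %s\n",
              format(x$mean_difference, digits = 4)))
  invisible(x)
}

#' Specify a one-parameter sweep
#'
#' @param param Swept parameter, one of \code{"b"}, \code{"D"}, \code{"c"},
#'   \code{"m"}, \code{"tau"}, \code{"delta_s"}.
#' @param grid Non-empty vector of parameter values.
#' @param replicates Fixation replicates per grid point.
#' @param base A [sim_params()] object supplying all other parameters.
#' @param seed Master seed; grid point \code{j}, replicate \code{i} runs on
#'   the stream \code{derive_seed(derive_seed(seed, j - 1) , i - 1)}.
#' @param invader Invader placement passed to [initialize_metapop()].
#' @return An object of class \code{"sweep_spec"}.
#' @export
sweep_spec <- function(param, grid, replicates, base = sim_params(),
                       seed = 1L, invader = TRUE) {
  param <- match.arg(param, c("b", "D", "c", "m", "tau", "delta_s"))
  stopifnot(length(grid) >= 1, replicates >= 1, inherits(base, "sim_params"))
  structure(list(param = param, grid = grid, replicates = as.integer(replicates),
                 base = base, seed = as.integer(seed), invader = invader),
            class = "sweep_spec")
}

#' Run a fixation-probability parameter sweep
#'
#' For each grid point, rebuilds the parameter set with the swept value,
#' estimates the slow type's fixation probability over independent
#' replicates ([estimate_fixation_probability()]), and records the mean slow
#' fractions in patches and hosts.  Every grid point gets its own derived,
#' logged seed so any row can be re-run in isolation.
#'
#' @param spec A [sweep_spec()].
#' @return An object of class \code{"mp_sweep"}: a data.frame with one row
#'   per grid point and columns \code{param}, \code{value}, \code{fixation},
#'   \code{ci_lo}, \code{ci_hi}, \code{mean_f_patch}, \code{mean_f_host},
#'   \code{censored}, \code{replicates}, \code{seed}.
#' @examples
#' sp <- sweep_spec("b", c(1, 5), replicates = 5,
#'                  base = sim_params(M = 5, K = 200, tau = 50, D = 20,
#'                                    max_cycles = 50))
#' run_sweep(sp)
#' @export
run_sweep <- function(spec) {
  stopifnot(inherits(spec, "sweep_spec"))
  rows <- vector("list", length(spec$grid))
  for (j in seq_along(spec$grid)) {
    value <- spec$grid[j]
    args <- unclass(spec$base)
    args[[spec$param]] <- value
    params <- do.call(sim_params, args)
    point_seed <- derive_seed(spec$seed, j - 1L)
    est <- tryCatch(
      estimate_fixation_probability(params, replicates = spec$replicates,
                                    seed = point_seed, invader = spec$invader,
                                    record = TRUE),
      error = function(e) {
        stop(sprintf("sweep point %s = %s (seed %d) failed: %s",
                     spec$param, format(value), point_seed,
                     conditionMessage(e)), call. = FALSE)
      })
    rows[[j]] <- data.frame(param = spec$param, value = value,
                            fixation = est$estimate, ci_lo = est$ci[1],
                            ci_hi = est$ci[2],
                            mean_f_patch = est$mean_f_patch,
                            mean_f_host = est$mean_f_host,
                            censored = est$censored,
                            replicates = spec$replicates, seed = point_seed)
  }
  structure(do.call(rbind, rows), class = c("mp_sweep", "data.frame"),
            spec = spec)
}

#' Read and write record streams and sweep results
#'
#' Headered comma-delimited text with a stable column schema; a write/read
#' round trip reproduces the values exactly (fractions serialised at full
#' precision).
#'
#' @param records,result A data.frame of per-cycle records or a sweep
#'   result.
#' @param path File path.
#' @return The written path (writers, invisibly) or the data.frame
#'   (readers).
#' @name records_io
#' @export
write_records <- function(records, path) {
  stopifnot(is.data.frame(records))
  write_csv_checked(as.data.frame(records), path)
}

#' @rdname records_io
#' @export
read_records <- function(path) {
  df <- read_csv_checked(path)
  structure(df, class = c("mp_records", "data.frame"))
}

#' @rdname records_io
#' @export
write_sweep <- function(result, path) {
  stopifnot(is.data.frame(result))
  write_csv_checked(as.data.frame(result), path)
}

#' @rdname records_io
#' @export
read_sweep <- function(path) {
  df <- read_csv_checked(path)
  structure(df, class = c("mp_sweep", "data.frame"))
}

write_csv_checked <- function(df, path) {
  tryCatch(utils::write.csv(df, path, row.names = FALSE),
           error = function(e) stop(sprintf("cannot write '%s': %s", path,
                                            conditionMessage(e)),
                                    call. = FALSE))
  invisible(path)
}

read_csv_checked <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: '%s'", path), call. = FALSE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Run manifests
#'
#' A manifest is a flat key-value text file (\code{key = value} lines)
#' capturing the fully resolved parameter set, seed and package version of a
#' run - sufficient to reproduce it bit-exactly.
#'
#' @param params A [sim_params()] object.
#' @param path File path.
#' @param extra Named list of additional entries (command, output path, ...).
#' @return The path (writer, invisibly); a named character vector (reader).
#' @name manifest
#' @export
write_manifest <- function(params, path, extra = list()) {
  stopifnot(inherits(params, "sim_params"))
  fields <- unclass(params)
  fields$version <- as.character(utils::packageVersion("micropatch"))
  fields <- c(fields, extra)
  lines <- sprintf("%s = %s", names(fields),
                   vapply(fields, function(v) format(v, digits = 17), ""))
  tryCatch(writeLines(lines, path),
           error = function(e) stop(sprintf("cannot write '%s': %s", path,
                                            conditionMessage(e)),
                                    call. = FALSE))
  invisible(path)
}

#' @rdname manifest
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: '%s'", path), call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  bad <- !grepl("=", lines, fixed = TRUE)
  if (any(bad)) {
    stop(sprintf("malformed manifest line in '%s': %s", path,
                 lines[bad][1]), call. = FALSE)
  }
  keys <- trimws(sub("=.*$", "", lines))
  vals <- trimws(sub("^[^=]*=", "", lines))
  if (any(!nzchar(keys))) {
    stop(sprintf("malformed manifest line in '%s': %s", path,
                 lines[!nzchar(keys)][1]), call. = FALSE)
  }
  stats::setNames(vals, keys)
}
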