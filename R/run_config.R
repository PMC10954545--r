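#' Run configuration with study-standard defaults
#'
#' Bundles the tunable parameters of every pipeline stage with their
#' conventional values: volcano fudge constant `s0 = 2` and `fdr = 0.2`,
#' profile bin width 0.5 um and width 7 px, colocalization region size
#' 25 um, tip exclusion 100 um and top-10 averaging for root diameter, and
#' `alpha = 0.05` for post-hoc tests. Round-trips losslessly through JSON.
#'
#' @param s0 Volcano fudge constant (default 2).
#' @param fdr Volcano FDR threshold (default 0.2).
#' @param n_perm Maximum permutations for the volcano null (default 1000).
#' @param bin_width_um Edge-profile bin width, um (default 0.5).
#' @param width_px Edge-profile width, pixels (default 7).
#' @param region_um Colocalization region edge, um (default 25).
#' @param tip_exclude_um Root-diameter tip exclusion, um (default 100).
#' @param top_k Largest distances averaged for root diameter (default 10).
#' @param alpha Post-hoc significance level (default 0.05).
#' @param seed Integer seed for all stochastic stages (default 1).
#' @param out_dir Output directory (default ".").
#' @return Object of class `run_config` (a named list).
#' @export
run_config <- function(s0 = 2, fdr = 0.2, n_perm = 1000L,
                       bin_width_um = 0.5, width_px = 7L, region_um = 25,
                       tip_exclude_um = 100, top_k = 10L, alpha = 0.05,
                       seed = 1L, out_dir = ".") {
  cfg <- list(s0 = s0, fdr = fdr, n_perm = as.integer(n_perm),
              bin_width_um = bin_width_um, width_px = as.integer(width_px),
              region_um = region_um, tip_exclude_um = tip_exclude_um,
              top_k = as.integer(top_k), alpha = alpha,
              seed = as.integer(seed), out_dir = out_dir)
  structure(cfg, class = "run_config")
}

#' Read / write a run configuration as JSON
#'
#' @param path JSON path.
#' @return [run_config()] for the reader; `path` invisibly for the writer.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, raw[intersect(names(raw),
                                    names(formals(run_config)))])
}

#' @rdname read_run_config
#' @param config A [run_config()].
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' Machine-readable provenance record for an output artifact
#'
#' @param inputs Named list or character vector of input paths.
#' @param params Named list of parameters used.
#' @param seed Integer seed used.
#' @return List with `inputs`, `params`, `seed`, `software` (package name
#'   and version) and `timestamp`.
#' @export
provenance_record <- function(inputs, params, seed) {
  list(inputs = inputs, params = params, seed = seed,
       software = list(package = "edgesense",
                       version = as.character(
                         utils::packageVersion("edgesense"))),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

#' Write an artifact's provenance next to it
#'
#' @param prov A [provenance_record()].
#' @param artifact_path Path of the artifact the record describes; the
#'   record is written to `<artifact_path>.provenance.json`.
#' @return The provenance path, invisibly.
#' @export
write_provenance <- function(prov, artifact_path) {
  p <- paste0(artifact_path, ".provenance.json")
  jsonlite::write_json(prov, p, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(p)
}

# CSV writer with the package's dialect: UTF-8, comma, '.' decimal,
# header, 9 significant digits for doubles
write_csv9 <- function(df, path) {
  num <- vapply(df, is.double, TRUE)
  df[num] <- lapply(df[num], function(x) signif(x, 9))
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
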