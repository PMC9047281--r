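#' Write a JSON run manifest
#'
#' Records what produced a set of output files: package version, the RNG
#' seed, an MD5 digest of the configuration, digests of input and output
#' files, and a timestamp. Identical configuration and seed give an
#' identical digest chain (the timestamp is informational only).
#'
#' @param path manifest output path.
#' @param seed RNG seed used for the run.
#' @param outputs named character vector of output file paths.
#' @param inputs named character vector of input file paths.
#' @param config optional list of configuration values to digest.
#' @return invisibly, the manifest list.
#' @export
write_run_manifest <- function(path, seed = NA_integer_,
                               outputs = character(),
                               inputs = character(), config = NULL) {
  digest_files <- function(paths) {
    if (length(paths) == 0) return(NULL)
    existing <- paths[file.exists(paths)]
    as.list(tools::md5sum(existing))
  }
  config_digest <- if (!is.null(config)) {
    tmp <- tempfile()
    on.exit(unlink(tmp), add = TRUE)
    writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA), tmp)
    unname(tools::md5sum(tmp))
  }
  manifest <- list(
    tool = "tebench",
    version = as.character(utils::packageVersion("tebench")),
    seed = seed,
    config_digest = config_digest,
    inputs = digest_files(inputs),
    outputs = digest_files(outputs),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(manifest)
}
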