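# Reproducibility metadata for pipeline runs.

#' Write a run manifest
#'
#' Records the command, seed, parameter list, input file digests (size plus a
#' content checksum), package version and timestamp as JSON, so a run can be
#' matched to its outputs and reproduced.
#'
#' @param path Output JSON path.
#' @param command Command or function name being recorded.
#' @param seed Random seed used (or `NA`).
#' @param params Named list of parameters.
#' @param inputs Character vector of input file paths to digest.
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(path, command, seed = NA, params = list(),
                           inputs = character()) {
  digest_file <- function(f) {
    if (!file.exists(f)) return(list(path = f, exists = FALSE))
    raw <- readBin(f, "raw", file.info(f)$size)
    list(path = f, exists = TRUE, size = length(raw),
         checksum = sum(as.integer(raw) * (seq_along(raw) %% 997)) %% 2^31)
  }
  manifest <- list(
    command = command,
    seed = seed,
    params = params,
    inputs = map(inputs, digest_file),
    package_version = as.character(utils::packageVersion("kinfolk")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
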