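#' Write a run manifest (JSON) describing one analysis stage
#'
#' Records the stage name, parameters, seed, input-file checksums, package
#' version and timestamp so any output directory documents how it was
#' produced.
#'
#' @param path Output JSON path.
#' @param stage Stage name (e.g. "classify", "simulate", "synth").
#' @param config Named list of parameters used.
#' @param seed RNG seed, if any.
#' @param inputs Character vector of input file paths; sizes and md5-style
#'   content hashes are recorded for files that exist.
#' @return Invisibly, the manifest list.
#' @export
runManifest <- function(path, stage, config = list(), seed = NULL,
                        inputs = character(0)) {
  fileInfo <- lapply(inputs, function(f) {
    if (!file.exists(f)) return(list(path = f, exists = FALSE))
    list(path = f, exists = TRUE, bytes = file.size(f),
         checksum = unname(tools::md5sum(f)))
  })
  manifest <- list(
    stage = stage,
    config = config,
    seed = seed,
    inputs = fileInfo,
    package = "MCMfootprints",
    version = as.character(utils::packageVersion("MCMfootprints")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(manifest)
}
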