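#' Write a run manifest
#'
#' Records MD5 checksums of a run's artifact files plus the seed and package
#' version, as JSON. Two runs of a seeded pipeline are reproducible iff their
#' manifests' checksums are equal.
#'
#' @param files Paths of the artifacts to fingerprint.
#' @param path Output JSON path.
#' @param seed Seed used by the run (recorded, may be NULL).
#' @return Invisibly, the manifest list.
#' @export
write_manifest <- function(files, path, seed = NULL) {
  files <- files[file.exists(files)]
  sums <- tools::md5sum(files)
  names(sums) <- basename(files)
  manifest <- list(
    checksums = as.list(sums),
    seed = seed,
    package_version = as.character(utils::packageVersion("mtgblup"))
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Read a run manifest
#' @param path Manifest JSON path.
#' @return Manifest list.
#' @export
read_manifest <- function(path) {
  jsonlite::read_json(path)
}
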