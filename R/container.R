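CONTAINER_FORMAT <- "qusac-container"
CONTAINER_VERSION <- 1L

#' Write a dataset container
#'
#' Single-file container for simulated datasets: feature arrays and truths
#' (`acq`), optional raw phantom maps (`phantoms`), the split table
#' (`splits`), and metadata (`meta`: format version, seeds, spec/config
#' hashes). Round-trips all arrays and attributes losslessly.
#'
#' @param path Output file path.
#' @param dataset An [build_dataset()] result.
#' @param phantoms Optional named list of [tissue_map()] objects.
#' @param extra_meta Optional named list merged into `meta`.
#' @return `path`, invisibly.
#' @export
write_container <- function(path, dataset, phantoms = NULL, extra_meta = list()) {
  stopifnot(inherits(dataset, "ac_dataset"))
  obj <- list(
    meta = c(
      list(
        format = CONTAINER_FORMAT,
        version = CONTAINER_VERSION,
        created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
        seed = dataset$seed,
        spec_hash = dataset$spec_hash,
        n_records = length(dataset$ids)
      ),
      extra_meta
    ),
    acq = dataset,
    phantoms = phantoms,
    splits = dataset$splits
  )
  saveRDS(obj, path)
  invisible(path)
}

#' Read a dataset container
#'
#' Validates the format marker and version before returning the contents.
#'
#' @param path Container path.
#' @return A list with `meta`, `acq` (the `ac_dataset`), `phantoms`, `splits`.
#' @export
read_container <- function(path) {
  if (!file.exists(path)) stop_input("container '%s' not found", path)
  obj <- readRDS(path)
  if (!identical(obj$meta$format, CONTAINER_FORMAT)) {
    stop_input("not a dataset container (missing format marker)")
  }
  if (is.null(obj$meta$version)) {
    stop_input("container has no version field; cannot migrate")
  }
  if (obj$meta$version != CONTAINER_VERSION) {
    stop_input(
      "container version %s not supported (expected %d); migration required",
      obj$meta$version, CONTAINER_VERSION
    )
  }
  ids <- obj$acq$ids
  sp <- obj$splits
  if (!setequal(sp$id, ids) || anyDuplicated(sp$id) > 0) {
    stop_input("split ids do not partition the record ids")
  }
  obj
}
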