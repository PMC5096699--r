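#' Save arrays and metadata to a plain-text archive
#'
#' An archive is a directory with a `meta.json` file (schema version, array
#' shapes, object metadata) and one CSV file per array. Integer counts round
#' trip bit-exactly; doubles are written with 17 significant digits, which
#' round trips IEEE values exactly.
#'
#' @param x a [trial_tensor()], a decomposition object (`st_decomp`,
#'   `sbt_decomp`, `space_decomp`), or a named list of numeric
#'   arrays/matrices plus optional `meta` list.
#' @param path directory to create (overwritten if it exists).
#' @return `path`, invisibly.
#' @export
write_archive <- function(x, path) {
  arrays <- list()
  meta <- list(schema_version = 1L, class = class(x)[1])
  if (inherits(x, "trial_tensor")) {
    arrays$counts <- x$counts
    meta$bin_width <- x$bin_width
    meta$window <- x$window
    meta$labels <- as.character(x$labels)
  } else if (inherits(x, "sbt_decomp")) {
    arrays$temporal_modules <- x$temporal_modules
    arrays$spatial_modules <- x$spatial_modules
    arrays$core <- x$core
    meta$method <- x$method
    meta$reconstruction_error <- x$reconstruction_error
  } else if (inherits(x, "st_decomp")) {
    arrays$modules <- do.call(rbind, lapply(x$modules, module_to_row))
    arrays$activations <- x$activations
    meta$method <- x$method
    meta$n_bins <- nrow(x$modules[[1]])
    meta$n_neurons <- ncol(x$modules[[1]])
    meta$reconstruction_error <- x$reconstruction_error
  } else if (is.list(x)) {
    meta <- c(meta, x$meta)
    arrays <- x[setdiff(names(x), "meta")]
  } else {
    abort("unsupported object for archiving.")
  }
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta$arrays <- lapply(arrays, function(a) as.integer(dim(a) %||% length(a)))
  jsonlite::write_json(
    meta, file.path(path, "meta.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  for (nm in names(arrays)) {
    a <- arrays[[nm]]
    flat <- format(as.vector(a), digits = 17, scientific = TRUE, trim = TRUE)
    writeLines(flat, file.path(path, paste0(nm, ".csv")))
  }
  invisible(path)
}

#' Load an archive written by [write_archive()]
#'
#' @param path archive directory.
#' @return the reconstructed object (class recorded in the archive metadata),
#'   or a plain list of arrays plus `meta` for generic archives.
#' @export
read_archive <- function(path) {
  meta_file <- file.path(path, "meta.json")
  if (!file.exists(meta_file)) abort("not an archive: meta.json is missing.")
  meta <- jsonlite::read_json(meta_file, simplifyVector = TRUE)
  if (is.null(meta$schema_version)) {
    abort("archive lacks required metadata key: schema_version")
  }
  if (meta$schema_version != 1L) {
    abort(sprintf("unsupported archive schema version: %s", meta$schema_version))
  }
  arrays <- lapply(names(meta$arrays), function(nm) {
    v <- as.numeric(readLines(file.path(path, paste0(nm, ".csv"))))
    dims <- meta$arrays[[nm]]
    if (length(dims) > 1) array(v, dim = dims) else v
  })
  names(arrays) <- names(meta$arrays)
  cls <- meta$class %||% "list"
  if (cls == "trial_tensor") {
    for (key in c("bin_width", "window", "labels")) {
      if (is.null(meta[[key]])) {
        abort(paste0("archive lacks required metadata key: ", key))
      }
    }
    return(trial_tensor(arrays$counts, meta$bin_width, meta$window, meta$labels))
  }
  if (cls == "sbt_decomp") {
    return(new_sbt_decomp(
      arrays$temporal_modules, arrays$spatial_modules, arrays$core,
      method = meta$method, reconstruction_error = meta$reconstruction_error
    ))
  }
  if (cls == "st_decomp") {
    mods <- lapply(seq_len(nrow(arrays$modules)), function(i) {
      row_to_module(arrays$modules[i, ], meta$n_bins, meta$n_neurons)
    })
    return(new_st_decomp(
      mods, arrays$activations,
      method = meta$method, reconstruction_error = meta$reconstruction_error
    ))
  }
  c(arrays, list(meta = meta))
}
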