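## HDF5 results archive.
##
## Layout (versioned; original to this package):
##   /metadata                 group with string datasets `format_version`,
##                             `chrom`, `parameters` (JSON) and numeric
##                             `length`, `resolution`, `n_bins`
##   /<chrom>/<triangle>/      `pseudodistribution`, `raw_marginal` (double
##                             vectors), `seeds` and `stripes` (tables)

ARCHIVE_FORMAT_VERSION <- "1.0"

#' Write a stripe call to an HDF5 archive
#'
#' Stores the full result -- pseudo-distributions, seeds, stripe geometry and
#' descriptors -- together with the exact parameter set, so that the archive
#' round-trips losslessly through [read_archive()] and suffices to rerun the
#' call deterministically.
#'
#' @param result A `stripe_call` from [call_stripes()].
#' @param path Output `.h5`/`.hdf5` path (overwritten if present).
#' @return `path`, invisibly.
#' @export
write_archive <- function(result, path) {
  stopifnot(inherits(result, "stripe_call"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)

  rhdf5::h5createGroup(path, "metadata")
  h5w <- function(obj, name) rhdf5::h5write(obj, path, name)
  h5w(ARCHIVE_FORMAT_VERSION, "metadata/format_version")
  h5w(result$chrom, "metadata/chrom")
  h5w(result$bins$length, "metadata/length")
  h5w(result$bins$resolution, "metadata/resolution")
  h5w(result$bins$n_bins, "metadata/n_bins")
  h5w(as.character(jsonlite::toJSON(unclass(result$parameters),
                                    auto_unbox = TRUE, digits = NA,
                                    null = "null")),
      "metadata/parameters")

  rhdf5::h5createGroup(path, result$chrom)
  for (tri in names(result$triangles)) {
    g <- paste0(result$chrom, "/", tri)
    rhdf5::h5createGroup(path, g)
    t <- result$triangles[[tri]]
    h5w(t$pseudodistribution, paste0(g, "/pseudodistribution"))
    h5w(t$raw_marginal, paste0(g, "/raw_marginal"))
    ## zero-row tables are represented by the dataset's absence
    if (nrow(t$seeds)) {
      seeds <- t$seeds
      seeds$essential <- as.integer(seeds$essential)
      h5w(seeds, paste0(g, "/seeds"))
    }
    if (nrow(t$stripes)) {
      stripes <- t$stripes
      ## HDF5 fixed-width strings cannot be empty; "." marks "no peaks"
      stripes$interior_peaks <- ifelse(nzchar(stripes$interior_peaks),
                                       stripes$interior_peaks, ".")
      h5w(stripes, paste0(g, "/stripes"))
    }
  }
  invisible(path)
}

#' Read a stripe call back from an HDF5 archive
#'
#' Reconstructs the `stripe_call` object written by [write_archive()].
#' Archives written with a different format version are rejected with an
#' error naming both versions.
#'
#' @param path Archive path.
#' @return A `stripe_call` object.
#' @export
read_archive <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  ver <- tryCatch(as.character(rhdf5::h5read(path, "metadata/format_version")),
                  error = function(e) NA_character_)
  if (is.na(ver)) stop(sprintf("not a stripe archive: %s", path))
  if (!identical(ver, ARCHIVE_FORMAT_VERSION)) {
    stop(sprintf("archive format version '%s' is not supported (expected '%s')",
                 ver, ARCHIVE_FORMAT_VERSION))
  }
  chrom <- as.character(rhdf5::h5read(path, "metadata/chrom"))
  bins <- bin_table(chrom,
                    as.numeric(rhdf5::h5read(path, "metadata/length")),
                    as.numeric(rhdf5::h5read(path, "metadata/resolution")))
  pj <- jsonlite::fromJSON(as.character(rhdf5::h5read(path, "metadata/parameters")))
  params <- do.call(call_parameters, pj)

  ls <- rhdf5::h5ls(path)
  has <- function(group, name) any(ls$group == paste0("/", group) & ls$name == name)
  triangles <- list()
  for (tri in c("lower", "upper")) {
    g <- paste0(chrom, "/", tri)
    if (has(g, "seeds")) {
      seeds <- as.data.frame(rhdf5::h5read(path, paste0(g, "/seeds")))
      seeds[] <- lapply(seeds, as.vector)  # drop 1-d array dims
      seeds$bin <- as.integer(seeds$bin)
      seeds$essential <- as.logical(seeds$essential)
    } else {
      seeds <- data.frame(bin = integer(), persistence = numeric(),
                          essential = logical())
    }
    if (has(g, "stripes")) {
      stripes <- as.data.frame(rhdf5::h5read(path, paste0(g, "/stripes")))
      stripes[] <- lapply(stripes, as.vector)
      for (col in c("seed_bin", "left_bin", "right_bin", "top_bin", "bottom_bin")) {
        stripes[[col]] <- as.integer(stripes[[col]])
      }
      stripes$interior_peaks <- sub("^\\.$", "",
                                    as.character(stripes$interior_peaks))
    } else {
      stripes <- empty_stripe_frame()
    }
    triangles[[tri]] <- list(
      triangle = tri,
      pseudodistribution = as.numeric(rhdf5::h5read(path, paste0(g, "/pseudodistribution"))),
      raw_marginal = as.numeric(rhdf5::h5read(path, paste0(g, "/raw_marginal"))),
      seeds = seeds,
      stripes = stripes
    )
  }
  structure(list(chrom = chrom, bins = bins, parameters = params,
                 triangles = triangles),
            class = "stripe_call")
}
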