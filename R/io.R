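#' Write a 3-D grid (WER map or dose grid) as MetaImage (MHD + raw)
#'
#' Writes the ASCII `.mhd` header and a little-endian `MET_FLOAT` raw
#' payload next to it. Voxel ordering is x-fastest, matching the in-memory
#' array layout.
#'
#' @param x A [wer_map()] or a `dose_grid` from [run_simulation()].
#' @param path Path of the `.mhd` header file.
#' @return The header path, invisibly.
#' @export
write_mhd <- function(x, path) {
  g <- x$grid
  vals <- if (inherits(x, "wer_map")) x$wer else x$dose
  raw_path <- sub("\\.mhd$", ".raw", path)
  if (identical(raw_path, path)) raw_path <- paste0(path, ".raw")
  hdr <- c("ObjectType = Image",
           "NDims = 3",
           "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           sprintf("DimSize = %d %d %d", g$n[1], g$n[2], g$n[3]),
           sprintf("ElementSpacing = %g %g %g",
                   g$spacing[1], g$spacing[2], g$spacing[3]),
           sprintf("Offset = %g %g %g",
                   g$origin[1], g$origin[2], g$origin[3]),
           "ElementType = MET_FLOAT",
           sprintf("ElementDataFile = %s", basename(raw_path)))
  writeLines(hdr, path)
  con <- file(raw_path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(vals), con, size = 4, endian = "little")
  invisible(path)
}

#' Read a MetaImage (MHD + raw) grid written by [write_mhd()]
#'
#' @param path Path of the `.mhd` header.
#' @param as `"wer_map"` to wrap the payload as a [wer_map()], `"array"` for
#'   a bare list of grid + values.
#' @return A [wer_map()] or a list `(grid, values)`.
#' @export
read_mhd <- function(path, as = c("wer_map", "array")) {
  as <- match.arg(as)
  lines <- readLines(path)
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[`, character(1), 1)
  vals <- vapply(kv, function(p) paste(p[-1], collapse = " "), character(1))
  get <- function(k) vals[match(k, keys)]
  if (!identical(get("ElementType"), "MET_FLOAT")) {
    stop("only MET_FLOAT MetaImage payloads are supported")
  }
  n <- as.integer(strsplit(get("DimSize"), "\\s+")[[1]])
  spacing <- as.numeric(strsplit(get("ElementSpacing"), "\\s+")[[1]])
  origin <- as.numeric(strsplit(get("Offset"), "\\s+")[[1]])
  raw_path <- file.path(dirname(path), get("ElementDataFile"))
  con <- file(raw_path, "rb")
  on.exit(close(con))
  v <- readBin(con, numeric(), n = prod(n), size = 4, endian = "little")
  arr <- array(v, dim = n)
  grid <- voxel_grid(n, spacing, origin)
  if (as == "wer_map") wer_map(grid, arr) else list(grid = grid, values = arr)
}

#' Read / write a phantom specification as YAML
#'
#' @param path File path.
#' @param spec A [phantom_spec()].
#' @export
read_phantom_spec <- function(path) {
  y <- yaml::read_yaml(path)
  inserts <- lapply(y$inserts, function(i)
    list(lo = as.numeric(i$lo), hi = as.numeric(i$hi),
         wer = as.numeric(i$wer)))
  phantom_spec(as.numeric(y$extents), inserts, kind = y$kind)
}

#' @rdname read_phantom_spec
#' @export
write_phantom_spec <- function(spec, path) {
  yaml::write_yaml(list(kind = spec$kind, extents = spec$extents,
                        inserts = spec$inserts), path)
  invisible(path)
}

#' Write a run manifest JSON sidecar
#'
#' Records seed, history count, mode and cutoff of a finished run in a
#' minimal JSON file (no external JSON dependency).
#'
#' @param dose A `dose_grid`.
#' @param path File path.
#' @export
write_run_manifest <- function(dose, path) {
  txt <- sprintf(
    '{"mode": "%s", "seed": %d, "n_particles": %d, "cutoff": %g, "dims": [%d, %d, %d]}',
    dose$mode, dose$seed, dose$n_particles, dose$cutoff,
    dose$grid$n[1], dose$grid$n[2], dose$grid$n[3])
  writeLines(txt, path)
  invisible(path)
}

#' Export a profile as CSV
#'
#' @param profile A `profile_sample`.
#' @param path File path.
#' @export
write_profile_csv <- function(profile, path) {
  utils::write.csv(data.frame(coordinate = profile$coordinates,
                              value = profile$values),
                   path, row.names = FALSE)
  invisible(path)
}
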