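#' Construct a 3D free-energy grid
#'
#' A ligand-migration free-energy field sampled on a regular rectangular
#' grid, as produced by implicit ligand sampling over an MD trajectory.
#' Energies are kcal/mol; `+Inf` marks sterically forbidden voxels. Voxel
#' indices are 1-based in R; the physical coordinate of voxel (i, j, k) is
#' `origin + (c(i, j, k) - 1) * spacing`.
#'
#' @param values numeric 3D array of free energies, kcal/mol (finite or +Inf).
#' @param origin numeric length-3, grid origin in Angstrom.
#' @param spacing positive scalar or length-3 voxel spacing in Angstrom.
#' @param bulk_reference the bulk free energy the grid is referenced to;
#'   `NA` until [normalize_to_bulk()] has been applied, 0 afterwards.
#' @return An object of class `energy_grid`.
#' @seealso [read_dx()], [normalize_to_bulk()], [extract_minimax_path()]
#' @export
energy_grid <- function(values, origin = c(0, 0, 0), spacing = 1,
                        bulk_reference = NA_real_) {
  if (!is.array(values) || length(dim(values)) != 3)
    stop_data("`values` must be a 3D array")
  if (any(dim(values) < 2))
    stop_data("grid must have at least 2 voxels on every axis")
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0))
    stop_data("`spacing` must be a positive scalar or 3-vector")
  if (length(origin) != 3 || any(!is.finite(origin)))
    stop_data("`origin` must be a finite 3-vector")
  v <- values
  storage.mode(v) <- "double"
  if (any(is.na(v)) || any(v == -Inf))
    stop_data("grid energies must be finite or +Inf")
  structure(list(values = v, origin = as.numeric(origin),
                 spacing = as.numeric(spacing),
                 dims = dim(v), bulk_reference = bulk_reference),
            class = "energy_grid")
}

#' @export
print.energy_grid <- function(x, ...) {
  cat("<energy_grid> ", paste(x$dims, collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = "/"), " A\n", sep = "")
  fin <- is.finite(x$values)
  cat("  energies [", signif(min(x$values[fin]), 4), ", ",
      signif(max(x$values[fin]), 4), "] kcal/mol; ",
      sum(!fin), " forbidden voxels; bulk ref ",
      ifelse(is.na(x$bulk_reference), "unset", x$bulk_reference), "\n", sep = "")
  invisible(x)
}

#' Read an OpenDX scalar field as an energy grid
#'
#' Parses the OpenDX "gridpositions / gridconnections / array" scalar-field
#' dialect used by ILS tools. Value ordering in the file follows the OpenDX
#' convention: the *last* (z) index varies fastest, so for counts nx ny nz
#' the file lists values in order (1,1,1), (1,1,2), ..., (1,1,nz), (1,2,1),
#' ... The in-memory array is indexed `values[ix, iy, iz]`.
#'
#' @param path file path.
#' @param steric_cap energies above this value (kcal/mol) are mapped to +Inf
#'   (steric exclusion); `Inf` disables the cap.
#' @return An [energy_grid()] (no bulk normalization applied).
#' @export
read_dx <- function(path, steric_cap = Inf) {
  if (!file.exists(path)) stop_data(paste0("grid file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines)]
  lines <- lines[nzchar(trimws(lines))]
  want <- function(pat, what) {
    i <- grep(pat, lines)[1]
    if (is.na(i))
      stop_data(paste0("malformed OpenDX header: missing ", what,
                       " (no line matching '", pat, "')"))
    i
  }
  nums <- function(line, n, what) {
    x <- suppressWarnings(as.numeric(strsplit(trimws(line), "\\s+")[[1]]))
    x <- x[!is.na(x)]
    if (length(x) < n)
      stop_data(paste0("malformed OpenDX header line ('", line,
                       "'): expected ", n, " numbers for ", what))
    x[seq_len(n)]
  }
  ip <- want("^object\\s+\\S+\\s+class\\s+gridpositions\\s+counts", "gridpositions")
  dims <- as.integer(nums(sub(".*counts", "", lines[ip]), 3, "counts"))
  if (any(dims < 2)) stop_data("grid counts must be >= 2 on every axis")
  io <- want("^origin", "origin")
  origin <- nums(sub("^origin", "", lines[io]), 3, "origin")
  id <- grep("^delta", lines)
  if (length(id) < 3) stop_data("malformed OpenDX header: need 3 delta lines")
  deltas <- t(vapply(lines[id[1:3]],
                     function(l) nums(sub("^delta", "", l), 3, "delta"),
                     numeric(3)))
  if (any(abs(deltas[row(deltas)[, ] != col(deltas)[, ]]) > 1e-12))
    stop_data("only axis-aligned (diagonal delta) grids are supported")
  spacing <- diag(deltas)
  ia <- want("class\\s+array.*items", "data array")
  items <- as.integer(sub(".*items\\s+(\\d+).*", "\\1", lines[ia]))
  if (is.na(items))
    stop_data(paste0("malformed OpenDX header line ('", lines[ia],
                     "'): cannot parse item count"))
  data_lines <- lines[(ia + 1):length(lines)]
  data_lines <- data_lines[!grepl("^(attribute|component|object|end)", data_lines)]
  vals <- suppressWarnings(as.numeric(unlist(strsplit(trimws(data_lines), "\\s+"))))
  if (any(is.na(vals))) stop_data("non-numeric token in OpenDX data section")
  if (items != prod(dims))
    stop_data(paste0("OpenDX structural error: items (", items,
                     ") != product of counts (", prod(dims), ")"))
  if (length(vals) != items)
    stop_data(paste0("OpenDX structural error: ", length(vals),
                     " values for declared ", items, " items"))
  # file order is z-fastest; fill an [iz, iy, ix] array then transpose
  arr <- aperm(array(vals, dim = rev(dims)), c(3, 2, 1))
  if (is.finite(steric_cap)) arr[arr > steric_cap] <- Inf
  energy_grid(arr, origin = origin, spacing = spacing)
}

#' Write an energy grid as an OpenDX scalar field
#'
#' Inverse of [read_dx()]; values are written z-fastest per the OpenDX
#' convention. `+Inf` voxels are written as a large sentinel (1e6).
#'
#' @param grid an [energy_grid()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dx <- function(grid, path) {
  stopifnot(inherits(grid, "energy_grid"))
  d <- grid$dims
  vals <- aperm(grid$values, c(3, 2, 1))  # z-fastest on disk
  v <- as.vector(vals)
  v[!is.finite(v)] <- 1e6
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %.6f %.6f %.6f", grid$origin[1], grid$origin[2], grid$origin[3]),
    sprintf("delta %.6f 0 0", grid$spacing[1]),
    sprintf("delta 0 %.6f 0", grid$spacing[2]),
    sprintf("delta 0 0 %.6f", grid$spacing[3]),
    sprintf("object 2 class gridconnections counts %d %d %d", d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows", prod(d))
  ), con)
  idx <- seq(1, length(v), by = 3)
  body <- vapply(idx, function(i)
    paste(formatC(v[i:min(i + 2, length(v))], format = "g", digits = 10),
          collapse = " "), character(1))
  writeLines(body, con)
  writeLines('attribute "dep" string "positions"', con)
  invisible(path)
}

# logical mask of the outer shell of width w voxels
bulk_shell_mask <- function(dims, w) {
  ix <- slice.index(array(0, dims), 1)
  iy <- slice.index(array(0, dims), 2)
  iz <- slice.index(array(0, dims), 3)
  (ix <= w) | (ix > dims[1] - w) |
    (iy <= w) | (iy > dims[2] - w) |
    (iz <= w) | (iz > dims[3] - w)
}

#' Reference a grid to the bulk solvent
#'
#' Subtracts a constant so that the mean free energy over the finite voxels
#' of the outer shell (the bulk solvent region surrounding the protein) is
#' exactly zero. Infinite (sterically forbidden) voxels are untouched.
#'
#' @param grid an [energy_grid()].
#' @param shell_width shell width in voxels (>= 1 and less than half the
#'   smallest grid dimension).
#' @return The normalized grid with `bulk_reference = 0`. Idempotent.
#' @examples
#' g <- energy_grid(array(4.2, c(4, 4, 4)))
#' all(normalize_to_bulk(g)$values == 0)
#' @export
normalize_to_bulk <- function(grid, shell_width = 2L) {
  stopifnot(inherits(grid, "energy_grid"))
  w <- as.integer(shell_width)
  if (w < 1) stop_config("`shell_width` must be >= 1 voxel")
  if (w >= min(grid$dims) / 2)
    stop_config("`shell_width` must be smaller than half the smallest grid dimension")
  shell <- bulk_shell_mask(grid$dims, w)
  sv <- grid$values[shell]
  sv <- sv[is.finite(sv)]
  if (!length(sv))
    stop_data("cannot normalize: bulk shell contains no finite voxel")
  off <- mean(sv)
  v <- grid$values
  fin <- is.finite(v)
  v[fin] <- v[fin] - off
  out <- grid
  out$values <- v
  out$bulk_reference <- 0
  out
}
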