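#' Structural positions defining the active site and each tunnel
#'
#' Topological residue labels (globin helix notation) whose occupants
#' determine the active-site hydrogen-bond network and the free-energy
#' profile of each ligand tunnel: the Long Tunnel (LT), the Short Tunnel at
#' G8 (STG8) and the E7 gate (E7G).
#'
#' @param which one of `"active_site"`, `"LT"`, `"STG8"`, `"E7G"`.
#' @return Character vector of structural position labels, in fixed order.
#' @export
tunnel_positions <- function(which = c("active_site", "LT", "STG8", "E7G")) {
  which <- match.arg(which)
  switch(which,
         active_site = c("B10", "CD1", "E7", "E11", "G8"),
         LT   = c("H5", "B2", "H9", "E15", "E11", "G8"),
         STG8 = c("H9", "G8", "G9"),
         E7G  = c("B10", "CD1", "E7", "E11"))
}

# normalize an MSA argument to a named character vector of aligned strings
as_msa_chars <- function(msa) {
  if (inherits(msa, "AAStringSet") || inherits(msa, "AAMultipleAlignment")) {
    msa <- as.character(msa)
  }
  if (!is.character(msa) || is.null(names(msa)))
    stop_data("MSA must be a named character vector or Biostrings AAStringSet")
  if (!length(msa)) stop_data("MSA is empty")
  if (length(unique(nchar(msa))) != 1)
    stop_data("MSA sequences must all have the same aligned width")
  msa
}

#' Read a multiple sequence alignment
#'
#' FASTA alignments are read with Biostrings; Stockholm via
#' `Biostrings::readAAMultipleAlignment`.
#'
#' @param path file path.
#' @param format `"fasta"` or `"stockholm"`; guessed from the extension by
#'   default (`.sto`/`.stk` = Stockholm).
#' @return A named character vector of aligned sequences.
#' @export
read_msa <- function(path, format = NULL) {
  if (!file.exists(path)) stop_data(paste0("MSA file not found: ", path))
  if (is.null(format)) {
    format <- if (grepl("\\.(sto|stk|stockholm)$", path, ignore.case = TRUE))
      "stockholm" else "fasta"
  }
  x <- if (format == "stockholm")
    Biostrings::readAAMultipleAlignment(path, format = "stockholm")
  else Biostrings::readAAStringSet(path)
  as_msa_chars(x)
}

#' Map structural position labels to alignment columns
#'
#' Anchors the globin topological numbering on an annotated reference
#' sequence present in the alignment: the annotation gives, for each
#' ungapped residue index of the reference, its structural label; the map
#' follows the reference's gaps to alignment columns.
#'
#' @param msa alignment (see [read_msa()]).
#' @param reference_id name of the annotated reference sequence.
#' @param annotation a data frame with columns `ref_index` (1-based ungapped
#'   residue index in the reference) and `label` (structural position).
#' @return Named integer vector label -> 1-based alignment column, of class
#'   `structural_map`.
#' @export
map_structural_positions <- function(msa, reference_id, annotation) {
  msa <- as_msa_chars(msa)
  if (!reference_id %in% names(msa))
    stop_data(paste0("reference '", reference_id, "' not found in the MSA"))
  if (!all(c("ref_index", "label") %in% names(annotation)))
    stop_data("annotation needs columns ref_index and label")
  ref <- strsplit(msa[[reference_id]], "")[[1]]
  cols_of_residue <- which(!ref %in% c("-", "."))
  idx <- as.integer(annotation$ref_index)
  if (any(idx < 1 | idx > length(cols_of_residue)))
    stop_data("annotation ref_index outside the reference's ungapped length")
  map <- setNames(cols_of_residue[idx], as.character(annotation$label))
  if (anyDuplicated(names(map)))
    stop_data("duplicate structural labels in annotation")
  if (anyDuplicated(map))
    stop_data("two labels map to the same alignment column")
  if (!"F8" %in% names(map))
    stop_config("structural map must include F8 (the family hallmark position)")
  structure(map, class = "structural_map")
}

msa_residues_at <- function(msa, column) {
  substr(msa, column, column)
}

#' Curate an alignment with the family's filtering rules
#'
#' Retains sequences whose ungapped length is strictly below `max_length`
#' and (optionally) that carry the family hallmark, the proximal histidine
#' at F8. Every rejection is reported with its reason.
#'
#' @param msa alignment (see [read_msa()]).
#' @param position_map a [map_structural_positions()] result (must resolve
#'   F8 when `require_his_f8` is TRUE).
#' @param max_length sequences must be shorter than this many residues.
#' @param require_his_f8 drop sequences without His at the F8 column.
#' @return A list: `msa` (the retained alignment) and `report`, a tibble of
#'   rejections with columns `id` and `reason`.
#' @export
filter_sequences <- function(msa, position_map, max_length = 160,
                             require_his_f8 = TRUE) {
  msa <- as_msa_chars(msa)
  if (require_his_f8 && !"F8" %in% names(position_map))
    stop_config("position map does not resolve F8")
  ulen <- nchar(gsub("[-.]", "", msa))
  reasons <- lapply(seq_along(msa), function(i) {
    r <- character()
    if (ulen[i] >= max_length)
      r <- c(r, sprintf("length %d >= %d", ulen[i], max_length))
    if (require_his_f8 &&
        msa_residues_at(msa[i], position_map[["F8"]]) != "H")
      r <- c(r, "missing HisF8 hallmark")
    r
  })
  bad <- lengths(reasons) > 0
  report <- tibble(id = rep(names(msa)[bad], lengths(reasons)[bad]),
                   reason = unlist(reasons[bad]) %||% character())
  list(msa = msa[!bad], report = report)
}

#' Catalog the residue combinations at active-site or tunnel positions
#'
#' Extracts, for every sequence, the ordered residues at the positions
#' defining the chosen site ([tunnel_positions()]), and tallies the distinct
#' combinations. Sequences with a gap at any needed column carry missing
#' data and are excluded from the catalog (listed in the `excluded`
#' attribute with the offending position).
#'
#' @param msa alignment (see [read_msa()]).
#' @param position_map a [map_structural_positions()] result.
#' @param which `"active_site"`, `"LT"`, `"STG8"` or `"E7G"`.
#' @return A tibble of class `combo_catalog` with columns `combo` (dash-
#'   separated residues in position order), one column per position, `count`
#'   and `freq`; attributes `which`, `positions`, `total` (sequences
#'   catalogued) and `excluded` (tibble id/position of gapped sequences).
#' @export
extract_combos <- function(msa, position_map,
                           which = c("active_site", "LT", "STG8", "E7G")) {
  which <- match.arg(which)
  msa <- as_msa_chars(msa)
  pos <- tunnel_positions(which)
  miss <- setdiff(pos, names(position_map))
  if (length(miss))
    stop_config(paste0("position map does not resolve: ",
                       paste(miss, collapse = ", ")))
  cols <- position_map[pos]
  resmat <- vapply(cols, function(cc) msa_residues_at(msa, cc),
                   character(length(msa)))
  resmat <- matrix(resmat, ncol = length(cols),
                   dimnames = list(names(msa), pos))
  gap <- resmat %in% c("-", ".")
  dim(gap) <- dim(resmat)
  has_gap <- rowSums(gap) > 0
  excluded <- if (any(has_gap)) {
    ij <- which(gap & has_gap, arr.ind = TRUE)
    tibble(id = rownames(resmat)[ij[, 1]], position = pos[ij[, 2]])
  } else tibble(id = character(), position = character())
  keep <- resmat[!has_gap, , drop = FALSE]
  combos <- apply(keep, 1, paste, collapse = "-")
  tab <- sort(table(combos), decreasing = TRUE)
  cat_tbl <- tibble(combo = names(tab), count = as.integer(tab))
  if (nrow(cat_tbl)) {
    parts <- do.call(rbind, strsplit(cat_tbl$combo, "-", fixed = TRUE))
    colnames(parts) <- pos
    cat_tbl <- bind_cols(cat_tbl, as_tibble(parts))
  }
  cat_tbl$freq <- if (nrow(keep)) cat_tbl$count / nrow(keep) else numeric(0)
  cat_tbl <- cat_tbl |> arrange(desc(.data$count), .data$combo)
  structure(cat_tbl,
            class = c("combo_catalog", class(cat_tbl)),
            which = which, positions = pos,
            total = nrow(keep), excluded = excluded)
}

#' Default amino-acid similarity classes
#'
#' Physicochemical classes used when merging near-equivalent residue
#' combinations: aliphatic, aromatic, hydroxyl, amide, acidic, basic, and
#' singleton classes for Gly, Pro and Cys.
#'
#' @return A list of character vectors partitioning the 20 amino acids.
#' @export
default_similarity_classes <- function() {
  list(aliphatic = c("L", "I", "V", "M", "A"),
       aromatic  = c("F", "Y", "W"),
       hydroxyl  = c("S", "T"),
       amide     = c("N", "Q"),
       acidic    = c("D", "E"),
       basic     = c("K", "R", "H"),
       gly = "G", pro = "P", cys = "C")
}

#' Merge similar residue combinations and flag a representative set
#'
#' Combos whose residues belong position-wise to the same similarity class
#' are merged (the merged combo is written with each class's first member);
#' merged combos are sorted by descending count (ties lexicographically) and
#' the smallest prefix whose cumulative frequency reaches `coverage_target`
#' is flagged representative. Fully deterministic.
#'
#' @param catalog an [extract_combos()] result.
#' @param similarity_classes a partition of the amino acids
#'   ([default_similarity_classes()]).
#' @param coverage_target fraction of catalogued sequences the
#'   representative set must cover, in (0, 1].
#' @return A `combo_catalog` tibble with columns `combo`, per-position
#'   residues (class representatives), `count`, `freq`, `coverage`
#'   (cumulative) and `representative`.
#' @export
reduce_combos <- function(catalog,
                          similarity_classes = default_similarity_classes(),
                          coverage_target = 0.9) {
  if (!is.numeric(coverage_target) || coverage_target <= 0 || coverage_target > 1)
    stop_config("`coverage_target` must lie in (0, 1]")
  aa <- unlist(similarity_classes)
  if (anyDuplicated(aa))
    stop_config("similarity classes must partition the amino acids (duplicate found)")
  rep_of <- setNames(rep(vapply(similarity_classes, `[`, character(1), 1),
                         lengths(similarity_classes)), aa)
  pos <- attr(catalog, "positions")
  total <- attr(catalog, "total")
  to_rep <- function(r) ifelse(r %in% names(rep_of), rep_of[r], r)
  merged_parts <- lapply(pos, function(p) to_rep(catalog[[p]]))
  names(merged_parts) <- pos
  merged_combo <- do.call(paste, c(merged_parts, sep = "-"))
  d <- tibble(combo = merged_combo, count = catalog$count) |>
    bind_cols(as_tibble(merged_parts)) |>
    group_by(across(all_of(c("combo", pos)))) |>
    summarise(count = sum(.data$count), .groups = "drop") |>
    arrange(desc(.data$count), .data$combo)
  d$freq <- d$count / total
  d$coverage <- cumsum(d$freq)
  k <- if (nrow(d)) which(d$coverage >= coverage_target - 1e-12)[1] else 0L
  if (is.na(k)) k <- nrow(d)  # target unreachable only if rounding; take all
  d$representative <- seq_len(nrow(d)) <= k
  structure(d, class = c("combo_catalog", class(d)),
            which = attr(catalog, "which"), positions = pos,
            total = total, excluded = attr(catalog, "excluded"))
}

#' Default hydrogen-bond donor table
#'
#' Which residues, when placed at one of the five distal positions, can
#' donate a strong hydrogen bond to the heme-bound water (and the bound
#' ligand): Tyr, Trp, His, Gln, Asn, Ser, Thr, Arg and Lys count as donors
#' at any distal position; the hydrophobics do not. Shipped as a
#' tab-separated data file so it can be overridden.
#'
#' @param path optional path to an alternative table (columns `position`,
#'   `residue`, `donor`).
#' @return A tibble with columns `position`, `residue`, `donor` (logical).
#' @export
default_donor_table <- function(path = NULL) {
  path <- path %||% system.file("extdata", "donor_table.tsv", package = "trhbkin")
  if (!file.exists(path)) stop_config(paste0("donor table not found: ", path))
  d <- as_tibble(read.delim(path, sep = "\t", stringsAsFactors = FALSE))
  d$donor <- as.logical(d$donor)
  d
}

#' Count hydrogen-bond donors in an active-site combination
#'
#' @param residues named character vector of residues at the five distal
#'   positions (names B10, CD1, E7, E11, G8), or a dash-separated combo
#'   string in that order.
#' @param donor_table a donor table ([default_donor_table()]).
#' @return Integer count of donor-capable residues.
#' @examples
#' \dontrun{
#' count_hbond_donors(c(B10 = "Y", CD1 = "F", E7 = "L", E11 = "Q", G8 = "V"))
#' }
#' @export
count_hbond_donors <- function(residues, donor_table = default_donor_table()) {
  pos <- tunnel_positions("active_site")
  if (is.character(residues) && length(residues) == 1 && grepl("-", residues))
    residues <- setNames(strsplit(residues, "-", fixed = TRUE)[[1]], pos)
  if (is.null(names(residues))) names(residues) <- pos[seq_along(residues)]
  key_tab <- paste(donor_table$position, donor_table$residue)
  is_donor <- setNames(donor_table$donor, key_tab)
  keys <- paste(names(residues), residues)
  sum(is_donor[keys], na.rm = TRUE)
}

#' Annotate an active-site catalog with donor counts
#'
#' @param catalog an active-site [extract_combos()] catalog.
#' @param donor_table a donor table ([default_donor_table()]).
#' @return The catalog with an added integer `n_hbonds` column.
#' @export
add_hbond_counts <- function(catalog, donor_table = default_donor_table()) {
  catalog$n_hbonds <- vapply(catalog$combo, count_hbond_donors,
                             integer(1), donor_table = donor_table,
                             USE.NAMES = FALSE)
  catalog
}

#' Detect potential heme hexacoordination
#'
#' His or Lys at position E10 can occupy the sixth iron coordination site;
#' for such proteins the predicted kon is an upper bound.
#'
#' @param msa alignment (see [read_msa()]); may be a single sequence.
#' @param position_map a [map_structural_positions()] result resolving E10.
#' @param watch_residues residues treated as potential sixth ligands.
#' @return Named logical vector, one value per sequence.
#' @export
detect_hexacoordination <- function(msa, position_map,
                                    watch_residues = c("H", "K")) {
  msa <- as_msa_chars(msa)
  if (!"E10" %in% names(position_map))
    stop_config("position map does not resolve E10")
  r <- msa_residues_at(msa, position_map[["E10"]])
  setNames(r %in% watch_residues, names(msa))
}

#' Write / read a combination catalog as a tab-separated table
#'
#' @param catalog a `combo_catalog`.
#' @param path file path.
#' @return `write_catalog` returns `path` invisibly; `read_catalog` returns
#'   the catalog tibble with its `which`/`positions`/`total` attributes
#'   restored from the header comment.
#' @export
write_catalog <- function(catalog, path) {
  hdr <- sprintf("# which=%s positions=%s total=%d",
                 attr(catalog, "which"),
                 paste(attr(catalog, "positions"), collapse = ","),
                 attr(catalog, "total"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  write.table(as.data.frame(catalog), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_catalog
#' @export
read_catalog <- function(path) {
  if (!file.exists(path)) stop_data(paste0("catalog not found: ", path))
  hdr <- readLines(path, n = 1)
  m <- regmatches(hdr, regexec("which=(\\S+) positions=(\\S+) total=(\\d+)", hdr))[[1]]
  if (length(m) != 4) stop_data("catalog header is malformed")
  d <- as_tibble(read.delim(path, sep = "\t", skip = 1,
                            stringsAsFactors = FALSE))
  structure(d, class = c("combo_catalog", class(d)),
            which = m[2], positions = strsplit(m[3], ",")[[1]],
            total = as.integer(m[4]),
            excluded = tibble(id = character(), position = character()))
}
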