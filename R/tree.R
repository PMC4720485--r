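#' Attach per-protein predictions to a phylogeny
#'
#' Joins a table of rate predictions (and optional group labels) onto the
#' leaves of a Newick tree. Every prediction must match exactly one leaf;
#' duplicated or orphan prediction ids are an error that lists the
#' offenders. Leaves without a prediction are kept and flagged. The original
#' Newick text is retained so that exporting the tree is byte-faithful.
#'
#' @param tree an `ape::phylo` object, a Newick string, or a path to a
#'   Newick file.
#' @param predictions a tibble as returned by [predict_rates()] (must have
#'   an `id` column); extra columns (e.g. `species`, tunnel classes) are
#'   carried along.
#' @param group_labels optional named character vector or two-column data
#'   frame (`id`, `group`) assigning each leaf a family group (N/O/P/Q).
#' @return An object of class `annotated_trhb_tree`: list with `tree`
#'   (phylo), `newick` (original text, if available), and `data` (per-leaf
#'   tibble with `annotated` flag).
#' @export
annotate_tree <- function(tree, predictions, group_labels = NULL) {
  newick <- NULL
  if (inherits(tree, "phylo")) {
    phy <- tree
  } else if (is.character(tree) && length(tree) == 1) {
    if (file.exists(tree)) {
      newick <- paste(readLines(tree, warn = FALSE), collapse = "\n")
      phy <- ape::read.tree(text = newick)
    } else {
      newick <- tree
      phy <- ape::read.tree(text = tree)
    }
    if (is.null(phy)) stop_data("could not parse Newick input")
  } else stop_data("`tree` must be a phylo object, Newick string, or file path")

  if (!"id" %in% names(predictions))
    stop_data("`predictions` must have an `id` column")
  dup <- unique(predictions$id[duplicated(predictions$id)])
  if (length(dup))
    stop_data(paste0("duplicated prediction ids: ", paste(dup, collapse = ", ")))
  orphan <- setdiff(predictions$id, phy$tip.label)
  if (length(orphan))
    stop_data(paste0("predictions with no matching leaf: ",
                     paste(orphan, collapse = ", ")))

  leaf <- tibble(id = phy$tip.label)
  data <- left_join(leaf, as_tibble(predictions), by = "id")
  data$annotated <- data$id %in% predictions$id
  if (!is.null(group_labels)) {
    gl <- if (is.data.frame(group_labels)) {
      setNames(group_labels$group, group_labels$id)
    } else group_labels
    data$group <- unname(gl[data$id])
  }
  structure(list(tree = phy, newick = newick, data = data),
            class = "annotated_trhb_tree")
}

#' @export
print.annotated_trhb_tree <- function(x, ...) {
  cat("<annotated_trhb_tree> ", length(x$tree$tip.label), " leaves, ",
      sum(x$data$annotated), " annotated\n", sep = "")
  invisible(x)
}

#' Export an annotated tree
#'
#' Writes the tree (byte-identical to the original Newick text when the
#' input was textual) and a per-leaf annotation table suitable for
#' tree-viewer imports.
#'
#' @param x an [annotate_tree()] result.
#' @param newick_path,table_path output paths (either may be `NULL` to
#'   skip).
#' @return Invisibly, a list of the paths written.
#' @export
export_annotated_tree <- function(x, newick_path = NULL, table_path = NULL) {
  stopifnot(inherits(x, "annotated_trhb_tree"))
  if (!is.null(newick_path)) {
    if (!is.null(x$newick)) writeLines(x$newick, newick_path)
    else ape::write.tree(x$tree, file = newick_path)
  }
  if (!is.null(table_path))
    write.table(as.data.frame(x$data), table_path, sep = "\t",
                quote = FALSE, row.names = FALSE)
  invisible(list(newick = newick_path, table = table_path))
}

#' Rough functional typing from predicted kinetics and tunnel openness
#'
#' A rule table distilled from the family's leading cases: proteins with a
#' tightly stabilized oxy complex (low koff) and an open polar E7 gate look
#' like catalase-peroxidases (the E7 gate admits polar/charged substrates
#' and takes precedence); low koff with two or more open tunnels suits
#' NO/O2 multiligand chemistry (the NO-detoxifying type); moderate-to-fast
#' koff with at least one open tunnel suits oxygen transport/storage;
#' anything else is unassigned.
#'
#' @param koff_class character vector, `"low"`, `"moderate"` or `"fast"`.
#' @param lt_class,stg8_class,e7g_class per-tunnel classes
#'   (`"open"`/`"intermediate"`/`"closed"`), vectorized.
#' @return Character vector with levels `catalase_peroxidase`,
#'   `NO_O2_chemistry`, `oxygen_transport`, `unassigned`.
#' @export
functional_type <- function(koff_class, lt_class, stg8_class, e7g_class) {
  n_open <- (lt_class == "open") + (stg8_class == "open") + (e7g_class == "open")
  low <- koff_class == "low"
  modfast <- koff_class %in% c("moderate", "fast")
  out <- rep("unassigned", length(koff_class))
  out[modfast & n_open >= 1] <- "oxygen_transport"
  out[low & n_open >= 2] <- "NO_O2_chemistry"
  out[low & e7g_class == "open"] <- "catalase_peroxidase"  # precedence
  out
}

#' Group composition of an annotated tree
#'
#' @param x an [annotate_tree()] result whose data has a `group` column.
#' @return A tibble `group`, `n`, `fraction`; fractions sum to 1.
#' @export
group_composition <- function(x) {
  d <- x$data
  if (!"group" %in% names(d)) stop_data("tree has no group labels")
  d <- d[!is.na(d$group), , drop = FALSE]
  if (!nrow(d)) stop_data("no leaf carries a group label")
  d |> count(.data$group) |> mutate(fraction = n / sum(n))
}

#' Per-organism co-occurrence of trHb paralogs
#'
#' Summarizes how many distinct trHbs each species carries and which family
#' groups co-occur: the per-species table, the aggregate shares of species
#' with one, two, or more than two trHbs, and the pairwise group
#' combinations among two-trHb species.
#'
#' @param predictions a tibble with columns `id`, `species` and optionally
#'   `group`.
#' @return A list of tibbles: `per_species`, `shares` (categories `one`,
#'   `two`, `more`), and `group_pairs` (among two-trHb species; empty
#'   without group labels).
#' @export
organism_cooccurrence <- function(predictions) {
  if (!"species" %in% names(predictions))
    stop_data("`predictions` must have a `species` column")
  per <- predictions |>
    group_by(.data$species) |>
    summarise(n_trhbs = dplyr::n_distinct(.data$id),
              groups = paste(sort(unique(stats::na.omit(.data$group))),
                             collapse = "+"),
              .groups = "drop")
  cat3 <- cut(per$n_trhbs, c(0, 1, 2, Inf), labels = c("one", "two", "more"))
  shares <- tibble(category = c("one", "two", "more"),
                   n_species = as.integer(table(cat3)[c("one", "two", "more")]))
  shares$share <- shares$n_species / sum(shares$n_species)
  pairs <- per |>
    filter(.data$n_trhbs == 2, nzchar(.data$groups)) |>
    count(.data$groups, name = "n_species")
  if (nrow(pairs)) pairs$share <- pairs$n_species / sum(pairs$n_species)
  list(per_species = per, shares = shares, group_pairs = pairs)
}

#' Distribution summaries of a prediction table
#'
#' Log10-binned kon/koff histograms and the categorical class counts, as
#' tibbles ready for plotting.
#'
#' @param predictions a [predict_rates()] result.
#' @param binwidth log10 bin width for the rate histograms.
#' @return A list of tibbles: `kon_hist`, `koff_hist`, `affinity_classes`,
#'   `koff_classes`, and `tunnel_classes` if columns `lt_class`,
#'   `stg8_class`, `e7g_class` are present.
#' @export
summarize_predictions <- function(predictions, binwidth = 1) {
  if (!nrow(predictions)) stop_data("empty prediction table")
  lbin <- function(x) {
    lx <- log10(x[x > 0 & is.finite(x)])
    b <- floor(lx / binwidth) * binwidth
    tibble(log10_bin = sort(unique(b))) |>
      left_join(tibble(log10_bin = b) |> count(.data$log10_bin),
                by = "log10_bin")
  }
  out <- list(kon_hist = lbin(predictions$kon),
              koff_hist = lbin(predictions$koff),
              affinity_classes = predictions |> count(.data$affinity_class),
              koff_classes = predictions |> count(.data$koff_class))
  tc <- intersect(c("lt_class", "stg8_class", "e7g_class"), names(predictions))
  if (length(tc) == 3) {
    out$tunnel_classes <- predictions |>
      select(all_of(tc)) |>
      tidyr::pivot_longer(dplyr::everything(), names_to = "tunnel",
                          values_to = "class") |>
      count(.data$tunnel, .data$class)
  }
  out
}

#' Plot log-binned rate distributions
#'
#' @param predictions a [predict_rates()] result.
#' @return A ggplot with kon and koff log10 histograms.
#' @export
plot_rate_distributions <- function(predictions) {
  d <- tibble(rate = c(rep("kon (M-1 s-1)", nrow(predictions)),
                       rep("koff (s-1)", nrow(predictions))),
              value = c(predictions$kon, predictions$koff)) |>
    filter(.data$value > 0)
  ggplot2::ggplot(d, ggplot2::aes(x = log10(.data$value))) +
    ggplot2::geom_histogram(binwidth = 1, boundary = 0,
                            fill = "steelblue", colour = "white") +
    ggplot2::facet_wrap(~rate, scales = "free") +
    ggplot2::labs(x = "log10 rate", y = "proteins") +
    ggplot2::theme_minimal()
}
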