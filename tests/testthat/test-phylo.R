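toy_predictions <- function(ids, seed = 3) {
  n <- length(ids)
  withr::with_seed(seed, tibble::tibble(
    id = ids,
    k_LT = runif(n, 0, 0.5), k_STG8 = runif(n, 0, 0.5), k_E7G = 0,
    n_hbonds = sample(0:2, n, TRUE), ddE_O2 = runif(n, 0, 10))) |>
    predict_rates()
}

test_that("predictions join onto tree leaves; orphans and duplicates fail loudly", {
  nwk <- make_tree(c("a", "b", "c"), seed = 1)
  pred <- toy_predictions(c("a", "b", "c"))
  at <- annotate_tree(nwk, pred)
  expect_true(all(at$data$annotated))

  expect_error(annotate_tree(nwk, toy_predictions(c("a", "zzz"))),
               "zzz", class = "trhbkin_data_error")
  dup <- toy_predictions(c("a", "a"))
  expect_error(annotate_tree(nwk, dup), "duplicated",
               class = "trhbkin_data_error")
})

test_that("partially annotated trees flag exactly the uncovered leaves", {
  ids <- sprintf("L%02d", 1:8)
  nwk <- make_tree(ids, seed = 2)
  pred <- toy_predictions(ids[c(1, 3, 5)])
  at <- annotate_tree(nwk, pred)
  expect_setequal(at$data$id[!at$data$annotated], setdiff(ids, pred$id))
})

test_that("Newick round trip preserves topology, branch lengths and bytes", {
  ids <- sprintf("t%d", 1:12)
  nwk <- make_tree(ids, seed = 9)
  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines(nwk, f)
  at <- annotate_tree(f, toy_predictions(ids))
  out <- withr::local_tempfile(fileext = ".nwk")
  export_annotated_tree(at, newick_path = out)
  expect_identical(readLines(out), readLines(f))
  phy1 <- ape::read.tree(text = nwk)
  phy2 <- ape::read.tree(out)
  expect_true(ape::all.equal.phylo(phy1, phy2, use.edge.length = TRUE))
})

test_that("functional typing follows the rule table with E7G precedence", {
  # NO/O2 chemistry: tight oxy complex + multiple open apolar tunnels
  expect_equal(functional_type("low", "open", "open", "closed"),
               "NO_O2_chemistry")
  # catalase-peroxidase: tight oxy complex + open polar E7 gate
  expect_equal(functional_type("low", "closed", "closed", "open"),
               "catalase_peroxidase")
  # precedence: both rules fire, the E7G-open reading wins
  expect_equal(functional_type("low", "open", "open", "open"),
               "catalase_peroxidase")
  # transport: moderate koff and at least one open tunnel
  expect_equal(functional_type("moderate", "open", "closed", "closed"),
               "oxygen_transport")
  expect_equal(functional_type("fast", "closed", "closed", "closed"),
               "unassigned")
  expect_equal(functional_type("low", "open", "closed", "closed"),
               "unassigned")
  # vectorized and a partition: exactly one label each
  out <- functional_type(c("low", "fast"), c("open", "open"),
                         c("open", "closed"), c("closed", "closed"))
  expect_equal(length(out), 2)
  expect_true(all(out %in% c("NO_O2_chemistry", "oxygen_transport",
                             "catalase_peroxidase", "unassigned")))
})

test_that("group composition reproduces a planted 24/45/27/4 split", {
  n <- 100
  ids <- sprintf("g%03d", 1:n)
  groups <- rep(c("N", "O", "P", "Q"), times = c(24, 45, 27, 4))
  nwk <- make_tree(ids, seed = 4)
  at <- annotate_tree(nwk, toy_predictions(ids),
                      group_labels = setNames(groups, ids))
  comp <- group_composition(at)
  expect_equal(sum(comp$fraction), 1, tolerance = 1e-12)
  expect_equal(comp$fraction[match(c("N", "O", "P", "Q"), comp$group)],
               c(0.24, 0.45, 0.27, 0.04))
})

test_that("organism co-occurrence shares are exact on a constructed fixture", {
  pred <- toy_predictions(sprintf("p%02d", 1:10))
  pred$species <- c("s1", "s2", "s2", "s3", "s3", "s4", "s5", "s5", "s5", "s6")
  pred$group <- c("N", "N", "O", "O", "P", "O", "N", "O", "P", "O")
  oc <- organism_cooccurrence(pred)
  expect_equal(nrow(oc$per_species), 6)
  sh <- setNames(oc$shares$share, oc$shares$category)
  expect_equal(unname(sh["one"]), 3 / 6)
  expect_equal(unname(sh["two"]), 2 / 6)
  expect_equal(unname(sh["more"]), 1 / 6)
  expect_equal(sum(oc$shares$share), 1, tolerance = 1e-12)
  # both 2-trHb species have an N+O and an O+P pairing respectively
  expect_setequal(oc$group_pairs$groups, c("N+O", "O+P"))
  expect_equal(sum(oc$group_pairs$share), 1, tolerance = 1e-12)
  # single-protein dataset: the "one" share is everything
  oc1 <- organism_cooccurrence(tibble::tibble(id = "x", species = "s",
                                              group = "N"))
  expect_equal(setNames(oc1$shares$share, oc1$shares$category)[["one"]], 1)
})

test_that("prediction summaries bin rates and count classes", {
  pred <- toy_predictions(sprintf("q%02d", 1:20))
  sm <- summarize_predictions(pred)
  expect_equal(sum(sm$kon_hist$n), sum(pred$kon > 0))
  expect_equal(sum(sm$koff_hist$n), nrow(pred))
  expect_equal(sum(sm$affinity_classes$n), nrow(pred))
  expect_error(summarize_predictions(pred[0, ]), class = "trhbkin_data_error")
  # single protein: one bin of occupancy one
  sm1 <- summarize_predictions(pred[1, ])
  expect_equal(sm1$kon_hist$n, 1L)
})
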