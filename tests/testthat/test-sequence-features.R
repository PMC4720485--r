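test_that("structural positions map through the reference's gaps", {
  # ungapped reference: columns equal residue indices
  mm <- fixture_msa()
  ann <- mm$annotation
  expect_equal(unname(mm$map[ann$label]), ann$ref_index)

  # a leading gap column shifts every mapped column by one
  msa2 <- c(REF = paste0("-", mm$msa[["REF"]]),
            S2 = paste0("A", mm$msa[[2]]))
  map2 <- map_structural_positions(msa2, "REF", ann)
  expect_equal(unname(map2[ann$label]), ann$ref_index + 1L)

  # internal insertion relative to the reference: hand-computed columns
  ref <- "AC-DEF"
  oth <- "ACXDEF"
  map3 <- map_structural_positions(
    c(REF = ref, O = oth), "REF",
    data.frame(ref_index = c(2, 3, 5), label = c("B10", "F8", "G8")))
  expect_equal(unname(map3[c("B10", "F8", "G8")]), c(2L, 4L, 6L))
})

test_that("position-map validation catches misuse", {
  mm <- fixture_msa()
  expect_error(map_structural_positions(mm$msa, "nope", mm$annotation),
               "not found", class = "trhbkin_data_error")
  expect_error(
    map_structural_positions(mm$msa, "REF",
                             data.frame(ref_index = 999, label = "F8")),
    "outside", class = "trhbkin_data_error")
  expect_error(
    map_structural_positions(mm$msa, "REF",
                             data.frame(ref_index = 5, label = "B10")),
    "F8", class = "trhbkin_config_error")
})

test_that("curation drops over-length and non-His-F8 sequences with reasons", {
  mm <- make_msa(12, c("Y-F-L-Q-V" = 1), n_reject_hallmark = 2,
                 n_reject_length = 3, seed = 5)
  map <- map_structural_positions(mm$msa, "REF", mm$annotation)
  flt <- filter_sequences(mm$msa, map)
  planted_bad <- mm$truth$id[mm$truth$planted_violation != "none"]
  expect_setequal(unique(flt$report$id), planted_bad)
  expect_equal(length(flt$msa), 12)
  expect_true(any(grepl("HisF8", flt$report$reason)))
  expect_true(any(grepl(">= 160", flt$report$reason)))
  # boundary: exactly 160 residues is rejected ("shorter than 160" is strict)
  msa_b <- c(REF = mm$msa[["REF"]],
             LONG = paste(rep("A", nchar(mm$msa[["REF"]])), collapse = ""))
  long_seq <- paste(c(rep("A", 40), "H", rep("A", 119)), collapse = "")
  map_b <- map_structural_positions(
    c(REF = long_seq, X = long_seq), "REF",
    data.frame(ref_index = 41, label = "F8"))
  flt_b <- filter_sequences(c(REF = long_seq, X = long_seq), map_b)
  expect_equal(length(flt_b$msa), 0)
  expect_true(all(grepl("length 160 >= 160", flt_b$report$reason)))
})

test_that("combination catalogs recover planted frequencies exactly", {
  mm <- fixture_msa()
  cat_as <- extract_combos(mm$msa, mm$map, "active_site")
  expect_s3_class(cat_as, "combo_catalog")
  # generator ground truth: catalog counts equal the planted draws
  truth_counts <- mm$combo_counts
  expect_equal(cat_as$combo, truth_counts$combo)
  expect_equal(cat_as$count, truth_counts$count)
  expect_equal(sum(cat_as$count), attr(cat_as, "total"))
  expect_equal(sum(cat_as$freq), 1)
})

test_that("catalog conservation holds for every position set", {
  mm <- fixture_msa()
  for (w in c("active_site", "LT", "STG8", "E7G")) {
    ct <- extract_combos(mm$msa, mm$map, w)
    expect_equal(sum(ct$count),
                 attr(ct, "total") )
    expect_equal(attr(ct, "total") +
                   length(unique(attr(ct, "excluded")$id)),
                 length(mm$msa))
  }
})

test_that("gapped sequences are excluded from catalogs with the position logged", {
  mm <- fixture_msa()
  msa <- mm$msa
  gcol <- mm$map[["B10"]]
  substr(msa[[3]], gcol, gcol) <- "-"
  ct <- extract_combos(msa, mm$map, "active_site")
  expect_equal(attr(ct, "total"), length(msa) - 1L)
  exc <- attr(ct, "excluded")
  expect_equal(exc$id, names(msa)[3])
  expect_equal(exc$position, "B10")
})

test_that("similar residues merge and the representative prefix matches greedy", {
  mm <- make_msa(60, c("Y-F-L-Q-V" = 0.4, "Y-F-I-Q-V" = 0.2,
                       "Y-H-H-Q-W" = 0.25, "L-F-L-V-V" = 0.15), seed = 21)
  map <- map_structural_positions(mm$msa, "REF", mm$annotation)
  ct <- extract_combos(mm$msa, map, "active_site")
  red <- reduce_combos(ct, coverage_target = 0.87)
  # Leu/Ile are one aliphatic class: the first two combos merged, written
  # with each class's first member (F for aromatics, N for amides, L for
  # aliphatics)
  expect_lt(nrow(red), nrow(ct))
  expect_true("F-F-L-N-L" %in% red$combo)
  merged_count <- red$count[red$combo == "F-F-L-N-L"]
  expect_equal(merged_count,
               sum(ct$count[ct$combo %in% c("Y-F-L-Q-V", "Y-F-I-Q-V")]))
  expect_equal(sum(red$count), attr(ct, "total"))
  # representative prefix equals the greedy oracle
  k <- oracle_greedy_prefix(red$count, attr(ct, "total"), 0.87)
  expect_equal(sum(red$representative), k)
  expect_gte(max(red$coverage[red$representative]), 0.87)
  # full coverage flags everything
  red1 <- reduce_combos(ct, coverage_target = 1.0)
  expect_true(all(red1$representative))
  expect_error(reduce_combos(ct, coverage_target = 0),
               class = "trhbkin_config_error")
  expect_error(reduce_combos(ct, coverage_target = 1.5),
               class = "trhbkin_config_error")
})

test_that("catalogs round-trip through their tab-separated form", {
  mm <- fixture_msa()
  ct <- add_hbond_counts(extract_combos(mm$msa, mm$map, "active_site"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_catalog(ct, f)
  back <- read_catalog(f)
  expect_equal(back$combo, ct$combo)
  expect_equal(back$count, ct$count)
  expect_equal(back$n_hbonds, ct$n_hbonds)
  expect_equal(attr(back, "total"), attr(ct, "total"))
  expect_equal(attr(back, "positions"), attr(ct, "positions"))
})

test_that("hydrogen-bond donor counting follows the donor table", {
  expect_equal(count_hbond_donors(c(B10 = "Y", CD1 = "F", E7 = "L",
                                    E11 = "Q", G8 = "V")), 2)
  expect_equal(count_hbond_donors("L-F-L-V-V"), 0)
  expect_equal(count_hbond_donors("Y-H-H-Q-W"), 5)
  # table overrides change the verdict
  tab <- default_donor_table()
  tab$donor[tab$residue == "Q"] <- FALSE
  expect_equal(count_hbond_donors("Y-F-L-Q-V", tab), 1)
})

test_that("hexacoordination is flagged for His or Lys at E10", {
  mm <- fixture_msa()
  msa <- mm$msa[1:3]
  e10 <- mm$map[["E10"]]
  substr(msa[[1]], e10, e10) <- "H"
  substr(msa[[2]], e10, e10) <- "K"
  substr(msa[[3]], e10, e10) <- "L"
  flags <- detect_hexacoordination(msa, mm$map)
  expect_equal(unname(flags), c(TRUE, TRUE, FALSE))
})

test_that("alignments read from FASTA and Stockholm files identically", {
  mm <- fixture_msa()
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(paste0(">", names(mm$msa), "\n", mm$msa), fa)
  m1 <- read_msa(fa)
  expect_equal(unname(m1), unname(mm$msa))
  sto <- withr::local_tempfile(fileext = ".sto")
  writeLines(c("# STOCKHOLM 1.0",
               paste(names(mm$msa), mm$msa), "//"), sto)
  m2 <- read_msa(sto)
  expect_equal(unname(m2[names(mm$msa)]), unname(mm$msa))
})
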