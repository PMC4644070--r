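mk_pred <- function(species, molecule, position, srna_id = "sR1",
                    guide_kind = "D", productive = TRUE) {
  data.frame(species = species, srna_id = srna_id, guide_kind = guide_kind,
             molecule = molecule, position = as.integer(position),
             productive = productive, mode = "strict", site_class = "WC",
             wc_run = 11L, n_gu = 0L, n_mm = 0L, target_start = 1L,
             target_end = 11L, target_id = NA_character_, flag = "",
             column = NA_integer_, stringsAsFactors = FALSE)
}

test_that("alignment projection maps positions through the column map", {
  maps <- list(Sp1 = list(rRNA_16S = build_column_map("A--CG", "Sp1", "rRNA_16S")))
  p <- mk_pred("Sp1", "rRNA_16S", 3)
  mapped <- map_to_alignment(p, maps)
  expect_equal(mapped$column, 5L)

  expect_warning(un <- map_to_alignment(mk_pred("Sp1", "rRNA_16S", 9), maps),
                 "could not be mapped")
  expect_equal(nrow(attr(un, "unmappable")), 1L)
  expect_true(is.na(un$column))

  maps2 <- list(Sp1 = list(rRNA_16S = build_column_map("ACGUA", "Sp1", "rRNA_16S")))
  expect_equal(map_to_alignment(mk_pred("Sp1", "rRNA_16S", 4), maps2)$column, 4L)
})

test_that("conservation summary aggregates per column with exact totals", {
  pred <- rbind(mk_pred("Sp1", "rRNA_16S", 1), mk_pred("Sp2", "rRNA_16S", 1),
                mk_pred("Sp3", "rRNA_16S", 1), mk_pred("Sp1", "rRNA_16S", 2))
  pred$column <- c(10L, 10L, 10L, 20L)
  cs <- conservation_summary(pred)
  expect_equal(cs$totals$n_events, 4L)
  expect_equal(cs$totals$n_positions, 2L)
  expect_equal(cs$totals$n_single, 1L)
  expect_equal(cs$totals$n_multi, 1L)
  expect_equal(cs$sites$n_species[cs$sites$column == 10], 3L)
  expect_equal(cs$sites$species_hits[cs$sites$column == 10], "Sp1,Sp2,Sp3")

  empty <- conservation_summary(mk_pred("Sp1", "rRNA_16S", 1)[0, ])
  expect_equal(nrow(empty$sites), 0L)
  expect_equal(nrow(empty$totals), 0L)

  # non-productive interactions are excluded by default
  pred$productive[1] <- FALSE
  cs2 <- conservation_summary(pred)
  expect_equal(cs2$totals$n_events, 3L)
})

test_that("hotspot profile is a truncated moving window sum and is linear", {
  ev <- data.frame(molecule = "rRNA_16S", column = 50L, n_events = 1L)
  prof <- hotspot_profile(ev, window = 9, length_out = list(rRNA_16S = 100))
  expect_equal(prof$density[prof$column %in% 46:54], rep(1, 9))
  expect_equal(sum(prof$density), 9)

  ev2 <- data.frame(molecule = "rRNA_16S", column = c(50L, 50L), n_events = 1L)
  prof2 <- hotspot_profile(ev2, window = 9, length_out = list(rRNA_16S = 100))
  expect_equal(max(prof2$density), 2)

  flat <- data.frame(molecule = "rRNA_16S", column = 1:50, n_events = 1L)
  proff <- hotspot_profile(flat, window = 9)
  expect_true(all(proff$density[5:46] == 9))

  # linearity on disjoint event sets
  set.seed(9)
  a <- data.frame(molecule = "rRNA_16S", column = sample(1:100, 20, TRUE), n_events = 1L)
  b <- data.frame(molecule = "rRNA_16S", column = sample(1:100, 20, TRUE), n_events = 1L)
  pa <- hotspot_profile(a, 9, list(rRNA_16S = 100))
  pb <- hotspot_profile(b, 9, list(rRNA_16S = 100))
  pab <- hotspot_profile(rbind(a, b), 9, list(rRNA_16S = 100))
  expect_equal(pab$density, pa$density + pb$density)

  expect_error(hotspot_profile(a, window = 8), "odd")
})

test_that("redundant sites group sRNAs targeting one position within a species", {
  pred <- rbind(mk_pred("Mka", "rRNA_16S", 250, "sR24"),
                mk_pred("Mka", "rRNA_16S", 250, "sR25"),
                mk_pred("Mka", "rRNA_16S", 400, "sR30"))
  red <- find_redundant_sites(pred)
  expect_equal(nrow(red), 1L)
  expect_equal(red$srna_ids, "sR24/sR25")
  expect_equal(red$position, 250L)

  expect_equal(nrow(find_redundant_sites(rbind(mk_pred("Mka", "rRNA_16S", 1, "a"),
                                               mk_pred("Mka", "rRNA_16S", 2, "b")))), 0L)

  pred3 <- rbind(mk_pred("Mka", "rRNA_16S", 660, "sR41"),
                 mk_pred("Mka", "rRNA_16S", 660, "sR52"),
                 mk_pred("Mka", "rRNA_16S", 660, "sR92"))
  red3 <- find_redundant_sites(pred3)
  expect_equal(red3$n_srnas, 3L)
  expect_equal(red3$srna_ids, "sR41/sR52/sR92")
})

test_that("guide pairs are classified by primary-sequence separation", {
  mk2 <- function(pd, pdp, mol_d = "rRNA_16S", mol_dp = "rRNA_16S") {
    rbind(mk_pred("Neq", mol_d, pd, "sR17", "D"),
          mk_pred("Neq", mol_dp, pdp, "sR17", "Dprime"))
  }
  expect_equal(classify_guide_pairs(mk2(100, 150))$classification, "double_local")
  far <- classify_guide_pairs(mk2(915, 1371))
  expect_equal(far$classification, "double_distant")
  expect_equal(far$primary_distance, 456L)
  cross <- classify_guide_pairs(mk2(100, 150, mol_dp = "rRNA_23S"))
  expect_equal(cross$classification, "cross_molecule")
  expect_true(is.na(cross$primary_distance))
  # inclusive threshold
  expect_equal(classify_guide_pairs(mk2(100, 200))$classification, "double_local")
  expect_equal(classify_guide_pairs(mk2(100, 201))$classification, "double_distant")
})

test_that("dot-bracket parsing and structure distances behave as a graph metric", {
  pt <- parse_dotbracket("((((....))))")
  expect_equal(pt[1], 12L)
  expect_equal(structure_distance(pt, 1, 12), 1L)

  lin <- parse_dotbracket(strrep(".", 10))
  expect_equal(structure_distance(lin, 1, 10), 9L)

  expect_error(parse_dotbracket("(()"), "unbalanced")
  expect_error(parse_dotbracket("())"), "unbalanced")
  expect_error(parse_dotbracket("(.x)"), "character")

  set.seed(19)
  for (k in 1:30) {
    pt <- parse_dotbracket(random_structure(sample(30:70, 1)))
    n <- length(pt)
    ab <- sample(n, 2)
    d <- structure_distance(pt, ab[1], ab[2])
    expect_equal(d, oracle_bfs(pt, ab[1], ab[2]))
    expect_equal(d, structure_distance(pt, ab[2], ab[1]))  # symmetry
    c3 <- sample(n, 1)
    expect_lte(d, structure_distance(pt, ab[1], c3) + structure_distance(pt, c3, ab[2]))
  }
})

test_that("CT files round-trip the pairing table", {
  pt <- parse_dotbracket("((..((...))..))")
  f <- withr::local_tempfile(fileext = ".ct")
  n <- length(pt)
  writeLines(c(sprintf("%d synthetic", n),
               sprintf("%d %s %d %d %d %d", 1:n, "N", 0:(n - 1), c(2:n, 0), pt, 1:n)),
             f)
  expect_equal(read_ct(f), pt)
})

test_that("chaperone candidates are distant pairs close in structure space", {
  # helix between 10..14 and 60..64: crossing strands are one edge apart
  db <- paste0(strrep(".", 9), "(((((", strrep(".", 45), ")))))", strrep(".", 40))
  pt <- parse_dotbracket(db)
  calls <- rbind(
    data.frame(species = "Neq", srna_id = "sR17", molecule_d = "rRNA_16S",
               position_d = 10L, molecule_dprime = "rRNA_16S",
               position_dprime = 64L, primary_distance = 54L,
               classification = "double_distant", stringsAsFactors = FALSE),
    data.frame(species = "Neq", srna_id = "sR99", molecule_d = "rRNA_16S",
               position_d = 2L, molecule_dprime = "rRNA_16S",
               position_dprime = 104L, primary_distance = 102L,
               classification = "double_distant", stringsAsFactors = FALSE))
  out <- chaperone_candidates(calls, list(rRNA_16S = pt), max_struct_dist = 10)
  expect_equal(out$srna_id, "sR17")
  expect_equal(out$structure_distance, 1L)

  expect_warning(deg <- chaperone_candidates(calls, NULL), "no secondary structure")
  expect_equal(nrow(deg), 2L)
  expect_true(all(is.na(deg$structure_distance)))
})
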