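test_that("consensus matching honours the R purine code", {
  expect_equal(match_consensus("AUGAUGA", "RUGAUGA"), 0L)
  expect_equal(match_consensus("GUGAUGA", "RUGAUGA"), 0L)
  expect_equal(match_consensus("CUGAUGA", "RUGAUGA"), 1L)
  expect_equal(match_consensus("CUGA", "CUGA"), 0L)
  expect_error(match_consensus("CUG", "CUGA"), "length")
})

test_that("box motif search finds exact and mismatched windows in order", {
  hits <- find_box_motifs("GGCUGAGG", "D", max_mm = 0L)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 3L)
  expect_equal(hits$end, 6L)
  expect_equal(hits$sequence, "CUGA")

  expect_equal(nrow(find_box_motifs("AAAAAAAAAA", "D", max_mm = 0L)), 0L)
})

test_that("box motif search equals brute-force enumeration on random sequences", {
  set.seed(7)
  for (k in 1:30) {
    s <- random_rna(60)
    for (kind in c("C", "D")) {
      for (mm in 0:2) {
        consensus <- if (kind == "C") "RUGAUGA" else "CUGA"
        got <- find_box_motifs(s, kind, mm)
        want <- oracle_find_boxes(s, consensus, mm)
        if (is.null(want)) {
          expect_equal(nrow(got), 0L)
        } else {
          got <- got[order(got$start), ]
          expect_equal(got$start, want$start)
          expect_equal(got$mismatches, want$mismatches)
        }
      }
    }
  }
})

test_that("k-turn check requires the sheared-pair residues", {
  cbox <- data.frame(kind = "C", sequence = "AUGAUGA")
  dbox <- data.frame(kind = "D", sequence = "CUGA")
  expect_true(check_kturn(cbox, dbox))
  expect_false(check_kturn(cbox, data.frame(kind = "D", sequence = "CCCA")))
  expect_false(check_kturn(data.frame(kind = "Cprime", sequence = "AUGACGA"),
                           data.frame(kind = "Dprime", sequence = "CUGA")))
  expect_error(check_kturn(dbox, cbox), "kind")
})

test_that("annotation recovers a planted arrangement exactly", {
  set.seed(11)
  rrnas <- list(rRNA_16S = generate_rrna(500, 0.5))
  p <- plant_srna(rrnas,
                  site_spec_d = list(molecule = "rRNA_16S", site = 120),
                  site_spec_dprime = list(molecule = "rRNA_16S", site = 170),
                  guide_len = 12, id = "sRX")
  ann <- annotate_cd_srna(p$srna, id = "sRX")
  expect_false(is_rejected(ann))
  expect_equal(ann$boxes$start, p$boxes$start)
  expect_equal(ann$boxes$end, p$boxes$end)
  expect_equal(ann$score, 0L)
  expect_true(all(ann$kturn))
  expect_equal(sort(ann$guides$sequence),
               sort(p$truth$guide_seq))
})

test_that("sequences without a D box are rejected with a reason", {
  set.seed(5)
  repeat {
    s <- random_rna(60)
    if (nrow(find_box_motifs(s, "D", 0L)) == 0L) break
  }
  rej <- annotate_cd_srna(s, id = "noD")
  expect_true(is_rejected(rej))
  expect_match(rej$reason, "box|arrangement")
  expect_true(is_rejected(annotate_cd_srna(strrep("A", 150))))
})

test_that("a mismatched C' box is tolerated and its mismatch count recorded", {
  set.seed(13)
  rrnas <- list(rRNA_16S = generate_rrna(500, 0.5))
  p <- plant_srna(rrnas,
                  site_spec_d = list(molecule = "rRNA_16S", site = 120),
                  site_spec_dprime = list(molecule = "rRNA_16S", site = 180),
                  guide_len = 11, id = "sRY")
  ann0 <- annotate_cd_srna(p$srna)
  cp <- ann0$boxes[ann0$boxes$kind == "Cprime", ]
  s <- p$srna
  substr(s, cp$start + 2L, cp$start + 2L) <- "C"  # G3 -> C, one mismatch
  ann <- annotate_cd_srna(s, id = "sRY")
  expect_false(is_rejected(ann))
  expect_equal(ann$boxes$start, ann0$boxes$start)
  expect_equal(ann$score, 1L)
  expect_equal(ann$boxes$mismatches[ann$boxes$kind == "Cprime"], 1L)
})

test_that("guide extraction arithmetic follows the box geometry", {
  residues <- paste(rep("A", 30), collapse = "")
  srna <- list(id = "g", residues = residues,
               boxes = data.frame(
                 kind = c("C", "Dprime", "Cprime", "D"),
                 start = c(1L, 20L, 22L, 29L), end = c(7L, 23L, 28L, 30L),
                 stringsAsFactors = FALSE))
  g <- extract_guides(srna)
  dp <- g[g$kind == "Dprime", ]
  expect_equal(c(dp$start, dp$end, dp$length, dp$plus5_offset), c(8L, 20L, 13L, 8L))

  # guide of length 12 has +5 offset 7
  srna$boxes$start[2] <- 19L
  g <- extract_guides(srna)
  expect_equal(g$plus5_offset[g$kind == "Dprime"], 7L)

  # a 5-nt guide cannot host the +5 position and is dropped
  srna$boxes$start[2] <- 12L
  g <- extract_guides(srna)
  expect_false("Dprime" %in% g$kind)
})

test_that("boxes and guides tile the annotated span without gaps", {
  set.seed(17)
  rrnas <- list(rRNA_16S = generate_rrna(400, 0.5))
  p <- plant_srna(rrnas,
                  site_spec_d = list(molecule = "rRNA_16S", site = 100),
                  site_spec_dprime = list(molecule = "rRNA_16S", site = 150),
                  guide_len = 10, id = "sRZ")
  ann <- annotate_cd_srna(p$srna)
  b <- ann$boxes; g <- ann$guides
  gd <- g[g$kind == "D", ]; gdp <- g[g$kind == "Dprime", ]
  span <- paste0(
    b$sequence[b$kind == "C"],
    substr(gdp$sequence, 1, gdp$length - 1),
    b$sequence[b$kind == "Dprime"],
    substr(ann$residues, b$end[b$kind == "Dprime"] + 1, b$start[b$kind == "Cprime"] - 1),
    b$sequence[b$kind == "Cprime"],
    substr(gd$sequence, 1, gd$length - 1),
    b$sequence[b$kind == "D"]
  )
  expect_equal(span, substr(ann$residues, b$start[b$kind == "C"], b$end[b$kind == "D"]))
})
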