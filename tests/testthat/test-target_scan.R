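test_that("pair classification is symmetric and matches the taxonomy", {
  expect_equal(classify_pair("A", "U"), "WC")
  expect_equal(classify_pair("U", "G"), "GU")
  expect_equal(classify_pair("C", "U"), "MM")
  bases <- c("A", "C", "G", "U")
  for (a in bases) for (b in bases) {
    expect_equal(classify_pair(a, b), oracle_classify(a, b))
    expect_equal(classify_pair(a, b), classify_pair(b, a))
  }
  expect_error(classify_pair("A", "T"), "A/C/G/U")
})

test_that("guide-window pairing uses the antiparallel register and +5 rule", {
  d <- pair_guide_window("UUAGGACUGAUCC", "GGAUCAGUCCUAA")
  expect_equal(d$pair_classes, rep("WC", 13))
  expect_equal(d$site_window_index, 6L)
  expect_equal(d$site_class, "WC")

  # substitution at the +5 partner: 12 WC, MM at the site
  win <- strsplit("GGAUCAGUCCUAA", "")[[1]]
  win[6] <- "C"  # partner of guide position 8 (= 13 - 5)
  d2 <- pair_guide_window("UUAGGACUGAUCC", paste(win, collapse = ""))
  expect_equal(sum(d2$pair_classes == "WC"), 12L)
  expect_equal(d2$site_class, "MM")
  expect_equal(d2$pair_classes[8], "MM")

  # antiparallel endpoint identity: guide position L pairs window position 1
  set.seed(3)
  g <- random_rna(11); w <- random_rna(11)
  d3 <- pair_guide_window(g, w)
  expect_equal(d3$pair_classes[11],
               classify_pair(substr(g, 11, 11), substr(w, 1, 1)))
  expect_error(pair_guide_window("ACGU", "ACG"), "length")
})

test_that("strict significance needs a 9-pair run covering the +5 column", {
  rules <- scan_rules()
  # 9 consecutive WC covering +5 (position 6 of 11)
  d <- make_duplex(c("WC", rep("WC", 9), "MM"), p5 = 6L)
  expect_true(call_significance(d, rules, "strict"))
  # 8 consecutive WC only
  d <- make_duplex(c("MM", rep("WC", 8), "MM", "MM"), p5 = 6L)
  expect_false(call_significance(d, rules, "strict"))
  # run of 9 WC that does not cover the +5 column
  d <- make_duplex(c(rep("WC", 9), "MM", "MM"), p5 = 11L)
  expect_false(call_significance(d, rules, "strict"))
  # mismatch exactly at the site: flanking WC pairs still carry significance
  d <- make_duplex(c(rep("WC", 5), "MM", rep("WC", 5)), p5 = 6L)
  expect_true(call_significance(d, rules, "strict"))
  expect_false(classify_productive(d, significant = TRUE))
  # G:U inside the run breaks it in strict mode but not in relaxed mode
  d <- make_duplex(c(rep("WC", 3), "GU", rep("WC", 7)), p5 = 6L)
  expect_false(call_significance(d, rules, "strict"))
  expect_true(call_significance(d, rules, "relaxed"))
})

test_that("productivity requires a Watson-Crick pair at the site", {
  expect_true(classify_productive(list(significant = TRUE, site_class = "WC")))
  expect_false(classify_productive(list(significant = TRUE, site_class = "MM")))
  expect_false(classify_productive(list(significant = TRUE, site_class = "GU")))
  expect_false(classify_productive(list(significant = FALSE, site_class = "WC")))
})

test_that("scanning finds a planted complement at the +5-consistent site", {
  set.seed(23)
  rrna <- random_rna(400)
  g <- "UUAGGACUGAUCC"
  rrna <- plant_window(rrna, g, 101)
  hits <- scan_guide(g, rrna)
  planted <- hits[hits$target_start == 101, ]
  expect_equal(nrow(planted), 1L)
  expect_equal(planted$position, 106L)
  expect_true(planted$productive)

  expect_equal(nrow(scan_guide(strrep("A", 10), strrep("A", 200))), 0L)
})

test_that("scan_guide equals the brute-force oracle on random instances", {
  set.seed(31)
  rules <- scan_rules()
  for (k in 1:60) {
    L <- sample(10:14, 1)
    g <- random_rna(L)
    rrna <- random_rna(240)
    if (k %% 2 == 0) {
      s <- sample(seq_len(240 - L), 1)
      rrna <- plant_window(rrna, g, s,
                           perturb = sample(seq_len(L), sample(0:2, 1)))
    }
    p5 <- L - 5L
    mode <- if (k %% 5 == 0) "relaxed" else "strict"
    got <- scan_guide(list(srna_id = "g", kind = "D", sequence = g,
                           plus5_offset = p5), rrna, rules, mode = mode)
    want <- oracle_scan(g, p5, rrna, mode = mode)
    got <- got[order(got$target_start), ]
    expect_equal(got$target_start, want$target_start)
    expect_equal(got$position, want$position)
    expect_equal(got$wc_run, want$wc_run)
    expect_equal(got$n_mm, want$n_mm)
    expect_equal(got$n_gu, want$n_gu)
    expect_equal(got$site_class, want$site_class)
  }
})

test_that("scanning the reverse complement mirrors coordinates", {
  set.seed(37)
  for (k in 1:15) {
    L <- 12L
    g <- random_rna(L)
    rrna <- random_rna(300)
    s <- sample(seq_len(300 - L), 1)
    rrna <- plant_window(rrna, g, s, perturb = sample(seq_len(L), sample(0:1, 1)))
    p5 <- L - 5L
    fwd <- scan_guide(list(srna_id = "g", kind = "D", sequence = g,
                           plus5_offset = p5), rrna)
    rev <- scan_guide(list(srna_id = "g", kind = "D", sequence = revcomp_rna(g),
                           plus5_offset = L - p5 + 1L), revcomp_rna(rrna))
    N <- 300L
    expect_setequal(N - fwd$target_end + 1L, rev$target_start)
    expect_setequal(N - fwd$position + 1L, rev$position)
    expect_equal(sort(fwd$wc_run), sort(rev$wc_run))
  }
})

test_that("tightening the rules never enlarges the hit set", {
  set.seed(41)
  for (k in 1:25) {
    L <- 12L
    g <- random_rna(L)
    rrna <- random_rna(300)
    rrna <- plant_window(rrna, g, sample(seq_len(300 - L), 1),
                         perturb = sample(seq_len(L), sample(0:2, 1)))
    guide <- list(srna_id = "g", kind = "D", sequence = g, plus5_offset = L - 5L)
    base <- scan_guide(guide, rrna, scan_rules(min_consecutive_wc = 8))
    for (tighter in list(scan_rules(min_consecutive_wc = 9),
                         scan_rules(min_consecutive_wc = 8, max_gu = 1),
                         scan_rules(min_consecutive_wc = 8, max_mismatch = 0))) {
      tight <- scan_guide(guide, rrna, tighter)
      expect_true(all(tight$target_start %in% base$target_start))
    }
  }
})

test_that("prediction recovers planted targets and classifies sRNAs", {
  spec <- synthetic_spec(seed = 91, n_species = 2, rrna_16s_len = 600,
                         rrna_23s_len = 900, n_srnas_per_species = 10,
                         frac_decoy = 0, frac_empty_guide = 0,
                         frac_site_mismatch = 0, frac_site_gu = 0,
                         frac_shared_sites = 0)
  ds <- generate_dataset(spec)
  for (sp in ds$species) {
    ann <- lapply(names(ds$srnas[[sp]]), function(id) {
      annotate_cd_srna(ds$srnas[[sp]][[id]], id = id, species = sp)
    })
    res <- predict_targets(ann, ds$rrnas[[sp]], species = sp)
    truth <- ds$truth_guides[ds$truth_guides$species == sp, ]
    got <- res$predictions[order(res$predictions$srna_id, res$predictions$guide_kind), ]
    want <- truth[order(truth$srna_id, truth$guide_kind), ]
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$molecule, want$molecule)
    expect_equal(got$position, want$site)
    expect_true(all(got$productive))
    expect_equal(res$summary$n_double_guide, 10L)
    expect_equal(res$summary$n_significant,
                 res$summary$n_productive + res$summary$n_nonproductive)
  }
})

test_that("decoy sRNAs land in the no-target class per generator truth", {
  spec <- synthetic_spec(seed = 97, n_species = 1, rrna_16s_len = 600,
                         rrna_23s_len = 900, n_srnas_per_species = 12,
                         frac_decoy = 0.5, frac_empty_guide = 0,
                         frac_site_mismatch = 0, frac_site_gu = 0,
                         frac_shared_sites = 0)
  ds <- generate_dataset(spec)
  sp <- ds$species[1]
  ann <- lapply(names(ds$srnas[[sp]]), function(id) {
    annotate_cd_srna(ds$srnas[[sp]][[id]], id = id, species = sp)
  })
  res <- predict_targets(ann, ds$rrnas[[sp]], species = sp)
  want <- table(ds$truth_srnas$expected_call)
  got <- table(res$srna_classes$class)
  expect_equal(as.vector(got[names(want)]), as.vector(want))
  expect_true(res$summary$n_no_target >= 1L)
})

test_that("an empty guide is rescued in relaxed mode near its partner site", {
  set.seed(53)
  rrnas <- list(rRNA_16S = generate_rrna(600, 0.5))
  p <- plant_srna(rrnas,
                  site_spec_d = list(molecule = "rRNA_16S", site = 200),
                  site_spec_dprime = list(molecule = "rRNA_16S", site = 240),
                  guide_len = 12, id = "sRR")
  ann0 <- annotate_cd_srna(p$srna)
  gdp <- ann0$guides[ann0$guides$kind == "Dprime", ]
  gchars <- strsplit(gdp$sequence, "")[[1]]
  L <- gdp$length; p5 <- gdp$plus5_offset
  rrna_chars <- strsplit(p$rrnas$rRNA_16S, "")[[1]]
  # make one pair inside the strict run a G:U so the strict 9-WC run is lost
  mutated <- NULL
  for (i in setdiff(seq(p5 - 3L, p5 - 1L), p5)) {
    partner <- rrna_chars[240L + L - 5L - i]
    if (partner %in% c("G", "U")) {
      g2 <- gchars
      g2[i] <- if (partner == "G") "U" else "G"
      s2 <- p$srna
      substr(s2, gdp$start + i - 1L, gdp$start + i - 1L) <- g2[i]
      ann2 <- annotate_cd_srna(s2, id = "sRR")
      if (!is_rejected(ann2) && identical(ann2$boxes$start, ann0$boxes$start)) {
        mutated <- ann2
        break
      }
    }
  }
  expect_false(is.null(mutated))
  res <- predict_targets(list(mutated), p$rrnas)
  pred <- res$predictions
  expect_equal(nrow(pred), 2L)
  dprow <- pred[pred$guide_kind == "Dprime", ]
  expect_equal(dprow$mode, "relaxed")
  expect_equal(dprow$position, 240L)
  expect_equal(pred$position[pred$guide_kind == "D"], 200L)
})
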