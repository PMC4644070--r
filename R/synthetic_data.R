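# Seeded synthetic-data generator with planted ground truth.
#
# The generator emits rRNA-like sequences, C/D box sRNAs whose guides are
# antiparallel complements of planted rRNA windows (positioned so the +5 rule
# yields a chosen site), decoy sRNAs with shuffled/random guides, controlled
# mismatch-at-site / G:U-at-site perturbations, and a multi-species rRNA
# alignment with per-species substitutions and indels.  Same seed, same bytes.

#' Specification for a synthetic dataset
#'
#' Defaults emulate a seven-species pan-archaeal survey: 16S/23S lengths of
#' 1500/3000 nt, roughly 70 sRNAs per species, guide lengths 10--12 nt, about
#' a third of sRNAs without any rRNA target (`frac_decoy`), 13% with a single
#' functional guide (`frac_empty_guide`), a 2.2% per-guide rate of a mismatch
#' exactly at the predicted site (`frac_site_mismatch`, the non-productive
#' class) and a rare G:U-at-site class.
#'
#' @param seed integer RNG seed; part of the public contract (same seed, same
#'   dataset).
#' @param n_species number of species.
#' @param rrna_16s_len,rrna_23s_len rRNA lengths (nt).
#' @param gc_fraction G+C fraction of the ancestral rRNAs.
#' @param n_srnas_per_species sRNAs emitted per species.
#' @param guide_len_range inclusive guide-length range, within 6--20.
#' @param frac_decoy fraction of sRNAs whose two guides are random
#'   (no planted target).
#' @param frac_empty_guide fraction of sRNAs with exactly one functional
#'   guide.
#' @param frac_site_mismatch per-guide probability of a mismatch at the +5
#'   site (significant but non-productive).
#' @param frac_site_gu per-guide probability of a G:U pair at the +5 site.
#' @param n_gu_in_duplex number of G:U pairs (0--2) planted at the duplex ends
#'   of clean guides.
#' @param frac_shared_sites fraction controlling how many cross-species
#'   conserved target sites are planted (shared by two or more species).
#' @param sub_rate per-site substitution rate of each species against the
#'   ancestor.
#' @param per_species_indel_rate per-site indel rate (split evenly between
#'   insertions and deletions).
#' @return An object of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(seed = 1L, n_species = 7L,
                           rrna_16s_len = 1500L, rrna_23s_len = 3000L,
                           gc_fraction = 0.55, n_srnas_per_species = 70L,
                           guide_len_range = c(10L, 12L),
                           frac_decoy = 0.33, frac_empty_guide = 0.13,
                           frac_site_mismatch = 0.022, frac_site_gu = 0.002,
                           n_gu_in_duplex = 0L, frac_shared_sites = 0.17,
                           sub_rate = 0.05, per_species_indel_rate = 0.01) {
  fracs <- c(frac_decoy, frac_empty_guide, frac_site_mismatch, frac_site_gu,
             frac_shared_sites, gc_fraction, sub_rate, per_species_indel_rate)
  stopifnot(all(fracs >= 0 & fracs <= 1), frac_decoy + frac_empty_guide <= 1,
            guide_len_range[1] >= 6L, guide_len_range[2] <= 20L,
            guide_len_range[1] <= guide_len_range[2],
            n_gu_in_duplex <= 2L, rrna_16s_len >= 300L, rrna_23s_len >= 300L,
            n_species >= 1L, n_srnas_per_species >= 1L)
  structure(list(
    seed = as.integer(seed), n_species = as.integer(n_species),
    rrna_16s_len = as.integer(rrna_16s_len), rrna_23s_len = as.integer(rrna_23s_len),
    gc_fraction = gc_fraction, n_srnas_per_species = as.integer(n_srnas_per_species),
    guide_len_range = as.integer(guide_len_range),
    frac_decoy = frac_decoy, frac_empty_guide = frac_empty_guide,
    frac_site_mismatch = frac_site_mismatch, frac_site_gu = frac_site_gu,
    n_gu_in_duplex = as.integer(n_gu_in_duplex),
    frac_shared_sites = frac_shared_sites,
    sub_rate = sub_rate, per_species_indel_rate = per_species_indel_rate
  ), class = "synthetic_spec")
}

#' Generate a random rRNA-like sequence
#'
#' Residues are i.i.d. with P(G) = P(C) = gc_fraction/2 and
#' P(A) = P(U) = (1 - gc_fraction)/2.
#'
#' @param length sequence length (>= 100).
#' @param gc_fraction G+C fraction in [0, 1].
#' @param seed optional seed (otherwise the current RNG stream is used).
#' @return An RNA sequence string.
#' @export
generate_rrna <- function(length, gc_fraction = 0.5, seed = NULL) {
  stopifnot(length >= 100L, gc_fraction >= 0, gc_fraction <= 1)
  if (!is.null(seed)) set.seed(seed)
  p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
         G = gc_fraction / 2, U = (1 - gc_fraction) / 2)
  paste(sample(names(p), length, replace = TRUE, prob = p), collapse = "")
}

pick1 <- function(v) v[sample.int(length(v), 1L)]

rand_chars <- function(n) if (n > 0L) sample(RNA_BASES, n, replace = TRUE) else character(0L)

random_guide_chars <- function(L) {
  g <- rand_chars(L)
  g[L] <- "C"  # the guide 3' nt is the first nucleotide of the downstream box
  g
}

# residue planted opposite the +5 site to create a mismatch (never WC, never GU)
MM_AT_SITE <- c(A = "G", C = "A", G = "A", U = "C")

# --- mutable per-species sequence state ------------------------------------
# st$seqs[[mol]]: ungapped residue char vector; st$rows[[mol]]: gapped row
# char vector (optional); st$maps[[mol]]: column_map (optional).

force_residue <- function(st, mol, pos, nt) {
  st$seqs[[mol]][pos] <- nt
  if (!is.null(st$rows[[mol]])) {
    st$rows[[mol]][st$maps[[mol]]$col_of_pos[pos]] <- nt
  }
  st
}

# Build one guide complementary to the window whose +5 partner is `site`.
# Returns the updated state and the guide characters.
build_guide_chars <- function(st, mol, site, L, gclass = "clean", n_gu = 0L) {
  len <- length(st$seqs[[mol]])
  if (site - 5L < 1L || site + L - 6L > len) {
    stop("site ", site, " too close to the rRNA end for a ", L, "-nt guide",
         call. = FALSE)
  }
  st <- force_residue(st, mol, site - 5L, "G")  # guide 3' nt becomes C (box start)
  if (gclass == "site_gu") st <- force_residue(st, mol, site, "G")
  n_gu_eff <- 0L
  if (gclass == "clean" && n_gu > 0L) {
    n_gu_eff <- min(n_gu, if (L >= 11L) 2L else 1L)
    st <- force_residue(st, mol, site + L - 6L, "G")         # partner of guide pos 1
    if (n_gu_eff >= 2L) st <- force_residue(st, mol, site + L - 7L, "G")
  }
  window <- st$seqs[[mol]][(site - 5L):(site + L - 6L)]
  guide <- rev(unname(RNA_COMPLEMENT[window]))
  p5 <- L - 5L
  if (gclass == "site_mismatch") guide[p5] <- MM_AT_SITE[[st$seqs[[mol]][site]]]
  if (gclass == "site_gu") guide[p5] <- "U"
  if (n_gu_eff >= 1L) guide[1L] <- "U"
  if (n_gu_eff >= 2L) guide[2L] <- "U"
  list(state = st, guide = guide)
}

# Wobble one rRNA residue inside the offending guide motif (never the +5
# partner or the forced box-start partner), so the rebuilt guide loses it.
break_guide_motif <- function(st, mol, site, L, guide) {
  gstr <- paste(guide, collapse = "")
  hit <- regexpr("CUGA", substr(gstr, 1L, L - 1L), fixed = TRUE)
  if (hit < 0L) hit <- regexpr("[AG]UGAUGA", gstr)
  if (hit < 0L && startsWith(gstr, "UGA")) {
    # a guide starting UGA recreates a C-box motif at the junction with the
    # upstream box (which ends ...AUGA); wobble one of its first residues
    hit <- 1L
    attr(hit, "match.length") <- 3L
  }
  if (hit < 0L) return(st)
  idx <- setdiff(hit:(hit + attr(hit, "match.length") - 1L), c(L - 5L, L))
  i <- pick1(idx)
  pos <- site + L - 5L - i  # rRNA partner of guide position i
  force_residue(st, mol, pos, pick1(setdiff(RNA_BASES, st$seqs[[mol]][pos])))
}

# guides must not themselves contain exact box motifs, or the planted
# arrangement would no longer be the unique zero-mismatch annotation
guide_motif_free <- function(g) {
  L <- length(g)
  body <- paste(g[-L], collapse = "")
  full <- paste(g, collapse = "")
  !grepl("CUGA", body, fixed = TRUE) &&
    !grepl("AUGAUGA", full, fixed = TRUE) &&
    !grepl("GUGAUGA", full, fixed = TRUE) &&
    !startsWith(full, "UGA")  # would recreate a C box across the junction
}

# all (overlapping) start positions of a fixed pattern
find_exact <- function(seq, pattern) {
  n <- nchar(seq); L <- nchar(pattern)
  if (n < L) return(integer(0L))
  starts <- seq_len(n - L + 1L)
  which(substring(seq, starts, starts + L - 1L) == pattern)
}

find_cbox_exact <- function(seq) {
  sort(unique(c(find_exact(seq, "AUGAUGA"), find_exact(seq, "GUGAUGA"))))
}

# Assemble lead + C + (D' guide - last nt) + D' + spacer + C' + (D guide -
# last nt) + D + tail, retrying flanks (and resampleable random guides) until
# the exact box motifs occur only at their planted positions.
assemble_srna <- function(g_dprime, g_d, resample_dprime = FALSE, resample_d = FALSE,
                          max_try = 25L) {
  for (try in seq_len(max_try)) {
    lead <- rand_chars(pick1(0:3))
    spacer <- rand_chars(pick1(0:2))
    tail <- rand_chars(pick1(0:3))
    cbox <- c(pick1(c("A", "G")), strsplit("UGAUGA", "")[[1L]])
    cpbox <- c(pick1(c("A", "G")), strsplit("UGAUGA", "")[[1L]])
    dbox <- strsplit("CUGA", "")[[1L]]
    L1 <- length(g_dprime); L2 <- length(g_d)
    chars <- c(lead, cbox, g_dprime[-L1], dbox, spacer, cpbox, g_d[-L2], dbox)
    chars <- c(chars, tail)
    srna <- paste(chars, collapse = "")
    c_start <- length(lead) + 1L
    c_end <- c_start + 6L
    dp_start <- c_end + L1
    dp_end <- dp_start + 3L
    cp_start <- dp_end + length(spacer) + 1L
    cp_end <- cp_start + 6L
    d_start <- cp_end + L2
    d_end <- d_start + 3L
    ok <- setequal(find_exact(srna, "CUGA"), c(dp_start, d_start)) &&
      setequal(find_cbox_exact(srna), c(c_start, cp_start))
    if (ok) {
      return(list(srna = srna,
                  boxes = data.frame(
                    kind = c("C", "Dprime", "Cprime", "D"),
                    start = c(c_start, dp_start, cp_start, d_start),
                    end = c(c_end, dp_end, cp_end, d_end),
                    stringsAsFactors = FALSE),
                  guide_spans = data.frame(
                    kind = c("D", "Dprime"),
                    start = c(cp_end + 1L, c_end + 1L),
                    end = c(d_start, dp_start), stringsAsFactors = FALSE)))
    }
    if (resample_dprime) g_dprime <- random_guide_chars(L1)
    if (resample_d) g_d <- random_guide_chars(L2)
  }
  NULL
}

#' Plant a single C/D box sRNA against a set of rRNAs
#'
#' Builds an sRNA 5'->3' as [C box][D' guide][D' box][C' box][D guide][D box]
#' (with short random flanks) where each functional guide is the antiparallel
#' complement of the rRNA window positioned so the +5 rule maps exactly onto
#' the requested site.  The rRNA residue opposite the guide's 3'-terminal
#' nucleotide is set to G so that the guide ends on the C that opens the
#' downstream box; the (possibly) modified rRNAs are returned.  A `NULL` site
#' spec produces a random guide with no planted target.
#'
#' @param rrnas named list/vector of rRNA residue strings (names are molecule
#'   labels such as `"rRNA_16S"`).
#' @param site_spec_d,site_spec_dprime `NULL`, or a list with `molecule`,
#'   `site` (1-based rRNA position to methylate) and optional `class`
#'   (`"clean"`, `"site_mismatch"`, `"site_gu"`).
#' @param guide_len guide length (one value for both guides, 6--20).
#' @param n_gu number of G:U pairs (0--2) planted at the duplex ends of clean
#'   guides.
#' @param id,species labels for the truth rows.
#' @param seed optional seed.
#' @return A list with `id`, `srna` (sequence string), `boxes`, `truth`
#'   (one row per guide: kind, class, molecule, site, expected site class,
#'   expected significance/productivity) and `rrnas` (modified set).
#' @export
plant_srna <- function(rrnas, site_spec_d = NULL, site_spec_dprime = NULL,
                       guide_len = 11L, n_gu = 0L, id = "sR1",
                       species = NA_character_, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(guide_len >= 6L, guide_len <= 20L)
  st <- list(seqs = lapply(as.list(rrnas), function(x) strsplit(x, "", fixed = TRUE)[[1L]]),
             rows = NULL, maps = NULL)
  build_one <- function(spec) {
    if (is.null(spec)) {
      return(list(guide = random_guide_chars(guide_len), molecule = NA_character_,
                  site = NA_integer_, class = "empty"))
    }
    cls <- spec$class %||% "clean"
    for (try in seq_len(30L)) {
      res <- build_guide_chars(st, spec$molecule, spec$site, guide_len, cls, n_gu)
      if (guide_motif_free(res$guide)) {
        st <<- res$state
        return(list(guide = res$guide, molecule = spec$molecule,
                    site = as.integer(spec$site), class = cls))
      }
      # motif inside the guide: wobble a window residue inside it and rebuild
      st <<- break_guide_motif(res$state, spec$molecule, spec$site, guide_len,
                               res$guide)
    }
    stop("could not build a box-motif-free guide at site ", spec$site, call. = FALSE)
  }
  gd <- build_one(site_spec_d)
  gdp <- build_one(site_spec_dprime)
  asm <- assemble_srna(gdp$guide, gd$guide,
                       resample_dprime = is.null(site_spec_dprime),
                       resample_d = is.null(site_spec_d))
  if (is.null(asm)) stop("could not assemble an sRNA with unique box motifs", call. = FALSE)
  truth <- do.call(rbind, lapply(list(D = gd, Dprime = gdp), function(g) {
    data.frame(
      species = species, srna_id = id,
      guide_kind = if (identical(g, gd)) "D" else "Dprime",
      class = g$class, molecule = g$molecule, site = g$site,
      site_class = switch(g$class, clean = "WC", site_mismatch = "MM",
                          site_gu = "GU", NA_character_),
      expect_significant = g$class != "empty",
      expect_productive = g$class == "clean",
      guide_seq = paste(g$guide, collapse = ""),
      stringsAsFactors = FALSE)
  }))
  truth$guide_kind <- c("D", "Dprime")
  rownames(truth) <- NULL
  list(id = id, srna = asm$srna, boxes = asm$boxes, truth = truth,
       rrnas = lapply(st$seqs, paste, collapse = ""))
}

# per-species divergence from an ancestor; returns named gapped rows
diverge_species <- function(anc, species, sub_rate, indel_rate) {
  a <- strsplit(anc, "", fixed = TRUE)[[1L]]
  n <- length(a)
  ns <- length(species)
  del <- matrix(stats::runif(ns * n) < indel_rate / 2, ns, n)
  ins <- matrix(stats::runif(ns * n) < indel_rate / 2, ns, n)
  subs <- matrix(stats::runif(ns * n) < sub_rate, ns, n)
  ncols <- n + sum(ins)
  mat <- matrix("-", ns, ncols)
  col <- 0L
  for (i in seq_len(n)) {
    col <- col + 1L
    for (s in seq_len(ns)) {
      if (del[s, i]) next
      ch <- a[i]
      if (subs[s, i]) ch <- pick1(setdiff(RNA_BASES, ch))
      mat[s, col] <- ch
    }
    for (s in which(ins[, i])) {
      col <- col + 1L
      mat[s, col] <- pick1(RNA_BASES)
    }
  }
  rows <- apply(mat, 1L, paste, collapse = "")
  names(rows) <- species
  rows
}

#' Generate a complete multi-species synthetic dataset with ground truth
#'
#' Ancestral 16S/23S rRNAs are mutated per species (substitutions and indels)
#' with the true alignment retained; C/D box sRNAs are planted per species
#' with guides complementary to chosen rRNA windows; a configurable fraction
#' of target sites is shared between two or more species (conserved sites).
#' Every functional guide is verified during generation to recover its
#' planted site as the unique best strict-scan hit; decoy and empty guides
#' record the actual scan outcome (including accidental hits) in the truth
#' table, so downstream comparisons are exact.
#'
#' @param spec a [synthetic_spec()].
#' @return An object of class `"cd_synthetic_dataset"`: `species`, `rrnas`
#'   (per species named list of residue strings), `srnas` (per species named
#'   vector of sRNA sequences), `alignments` (per molecule named gapped
#'   rows), `column_maps`, `truth_guides`, `truth_srnas`, `spec`.
#' @export
generate_dataset <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  ns <- spec$n_species
  species <- sprintf("Sp%d", seq_len(ns))
  mol_len <- c(rRNA_16S = spec$rrna_16s_len, rRNA_23S = spec$rrna_23s_len)
  mols <- names(mol_len)
  aln_rows <- list()
  state <- list()
  for (m in mols) {
    anc <- generate_rrna(mol_len[[m]], spec$gc_fraction)
    aln_rows[[m]] <- diverge_species(anc, species, spec$sub_rate,
                                     spec$per_species_indel_rate)
  }
  for (sp in species) {
    st <- list(seqs = list(), rows = list(), maps = list())
    for (m in mols) {
      st$rows[[m]] <- strsplit(aln_rows[[m]][[sp]], "", fixed = TRUE)[[1L]]
      st$maps[[m]] <- build_column_map(aln_rows[[m]][[sp]], sp, m)
      st$seqs[[m]] <- st$rows[[m]][st$rows[[m]] != "-"]
    }
    state[[sp]] <- st
  }
  used <- lapply(species, function(sp) list(rRNA_16S = integer(0L), rRNA_23S = integer(0L)))
  names(used) <- species

  margin <- 40L
  # planted duplex windows must never overlap (forcing one would corrupt
  # another); window span <= guide length, so this separation is sufficient
  min_sep <- max(spec$guide_len_range) + 2L
  mol_prob <- mol_len / sum(mol_len)
  pick_mol <- function() sample(mols, 1L, prob = mol_prob)
  pick_site <- function(sp, mol) {
    len <- length(state[[sp]]$seqs[[mol]])
    for (try in seq_len(200L)) {
      s <- pick1(margin:(len - margin))
      if (all(abs(s - used[[sp]][[mol]]) >= min_sep)) {
        used[[sp]][[mol]] <<- c(used[[sp]][[mol]], s)
        return(s)
      }
    }
    stop("could not place a target site; lower n_srnas_per_species", call. = FALSE)
  }
  pick_site_near <- function(sp, mol, anchor) {
    len <- length(state[[sp]]$seqs[[mol]])
    for (try in seq_len(200L)) {
      s <- anchor + pick1(c(-1L, 1L)) * pick1(min_sep:90L)  # double guides target within ~100 nt
      if (s >= margin && s <= len - margin &&
          all(abs(s - used[[sp]][[mol]]) >= min_sep)) {
        used[[sp]][[mol]] <<- c(used[[sp]][[mol]], s)
        return(s)
      }
    }
    pick_site(sp, mol)  # fall back to an unlinked site
  }

  # shared (conserved) target sites: anchor an alignment column, take every
  # species where the column is occupied and placeable, keep >= 2 of them
  shared_queue <- lapply(species, function(sp) list())
  names(shared_queue) <- species
  K <- max(0L, as.integer(round(spec$frac_shared_sites * spec$n_srnas_per_species)))
  if (K > 0L && ns >= 2L) {
    for (k in seq_len(K)) {
      mol <- pick_mol()
      for (try in seq_len(100L)) {
        anchor_sp <- pick1(species)
        len_a <- length(state[[anchor_sp]]$seqs[[mol]])
        col <- state[[anchor_sp]]$maps[[mol]]$col_of_pos[pick1(margin:(len_a - margin))]
        members <- list()
        for (sp in species) {
          p <- state[[sp]]$maps[[mol]]$pos_of_col[col]
          if (is.na(p)) next
          len_sp <- length(state[[sp]]$seqs[[mol]])
          if (p < margin || p > len_sp - margin) next
          if (!all(abs(p - used[[sp]][[mol]]) >= min_sep)) next
          members[[sp]] <- p
        }
        if (length(members) >= 2L) {
          take <- sample(names(members), pick1(2:length(members)))
          for (sp in take) {
            used[[sp]][[mol]] <- c(used[[sp]][[mol]], members[[sp]])
            shared_queue[[sp]][[length(shared_queue[[sp]]) + 1L]] <-
              list(molecule = mol, site = members[[sp]], shared_id = k)
          }
          break
        }
      }
    }
  }

  guide_class <- function() {
    u <- stats::runif(1L)
    if (u < spec$frac_site_mismatch) "site_mismatch"
    else if (u < spec$frac_site_mismatch + spec$frac_site_gu) "site_gu"
    else "clean"
  }
  lens <- spec$guide_len_range[1L]:spec$guide_len_range[2L]

  srnas <- list(); truth_g <- list(); truth_s <- list()
  for (sp in species) {
    sp_srnas <- character(0L)
    sp_truth <- list()
    sp_specs <- list()
    n_shared_used <- 0L
    for (j in seq_len(spec$n_srnas_per_species)) {
      id <- paste0("sR", j)
      u <- stats::runif(1L)
      cls <- if (u < spec$frac_decoy) "decoy"
             else if (u < spec$frac_decoy + spec$frac_empty_guide) "empty_guide"
             else "functional"
      empty_kind <- if (cls == "empty_guide") pick1(c("D", "Dprime")) else NA_character_
      sp_specs[[j]] <- list(id = id, class = cls, empty_kind = empty_kind,
                            L_d = pick1(lens), L_dp = pick1(lens))
    }

    # build one sRNA; site specs may be forced (rebuild path) or drawn fresh
    build_srna <- function(sinfo, allow_shared = TRUE) {
      g_spec <- list(D = NULL, Dprime = NULL)
      if (sinfo$class != "decoy") {
        functional_kinds <- setdiff(c("D", "Dprime"),
                                    if (sinfo$class == "empty_guide") sinfo$empty_kind else NULL)
        anchor <- NULL
        for (kind in functional_kinds) {
          gcls <- guide_class()
          if (kind == "D" && allow_shared && sinfo$class == "functional" &&
              length(shared_queue[[sp]]) > 0L) {
            sh <- shared_queue[[sp]][[1L]]
            shared_queue[[sp]][[1L]] <<- NULL
            g_spec[[kind]] <- list(molecule = sh$molecule, site = sh$site,
                                   class = gcls, shared_id = sh$shared_id)
          } else if (!is.null(anchor)) {
            g_spec[[kind]] <- list(molecule = anchor$molecule,
                                   site = pick_site_near(sp, anchor$molecule, anchor$site),
                                   class = gcls, shared_id = NA_integer_)
          } else {
            mol <- pick_mol()
            g_spec[[kind]] <- list(molecule = mol, site = pick_site(sp, mol),
                                   class = gcls, shared_id = NA_integer_)
          }
          if (is.null(anchor)) anchor <- g_spec[[kind]]
        }
      }
      guides <- list()
      for (kind in c("D", "Dprime")) {
        L <- if (kind == "D") sinfo$L_d else sinfo$L_dp
        gs <- g_spec[[kind]]
        if (is.null(gs)) {
          guides[[kind]] <- list(guide = random_guide_chars(L), spec = NULL)
          next
        }
        built <- NULL
        for (try in seq_len(30L)) {
          res <- build_guide_chars(state[[sp]], gs$molecule, gs$site, L,
                                   gs$class, spec$n_gu_in_duplex)
          if (guide_motif_free(res$guide)) { built <- res; break }
          state[[sp]] <<- break_guide_motif(res$state, gs$molecule, gs$site, L,
                                            res$guide)
        }
        if (is.null(built)) stop("could not build motif-free guide", call. = FALSE)
        state[[sp]] <<- built$state
        guides[[kind]] <- list(guide = built$guide, spec = gs)
      }
      asm <- assemble_srna(guides$Dprime$guide, guides$D$guide,
                           resample_dprime = is.null(g_spec$Dprime),
                           resample_d = is.null(g_spec$D))
      if (is.null(asm)) stop("could not assemble sRNA with unique boxes", call. = FALSE)
      list(asm = asm, guides = guides)
    }

    verify_guide <- function(guide_chars, L, gs, id, kind) {
      grow <- data.frame(srna_id = id, kind = kind,
                         sequence = paste(guide_chars, collapse = ""),
                         plus5_offset = L - 5L, stringsAsFactors = FALSE)
      hits <- do.call(rbind, lapply(mols, function(m) {
        scan_guide(grow, paste(state[[sp]]$seqs[[m]], collapse = ""),
                   scan_rules(), mode = "strict", molecule = m)
      }))
      if (is.null(hits) || !nrow(hits)) return(FALSE)
      hits <- hits[order_hits(hits), , drop = FALSE]
      top <- hits[1L, ]
      if (top$molecule != gs$molecule || top$position != gs$site) return(FALSE)
      if (nrow(hits) >= 2L) {
        second <- hits[2L, ]
        if (second$wc_run == top$wc_run &&
            second$n_mm + second$n_gu == top$n_mm + top$n_gu) return(FALSE)
      }
      TRUE
    }

    built <- vector("list", spec$n_srnas_per_species)
    for (j in seq_along(sp_specs)) built[[j]] <- build_srna(sp_specs[[j]])
    for (round in seq_len(8L)) {
      all_ok <- TRUE
      for (j in seq_along(built)) {
        sinfo <- sp_specs[[j]]
        for (kind in c("D", "Dprime")) {
          g <- built[[j]]$guides[[kind]]
          if (is.null(g$spec)) next
          L <- if (kind == "D") sinfo$L_d else sinfo$L_dp
          if (!verify_guide(g$guide, L, g$spec, sinfo$id, kind)) {
            built[[j]] <- build_srna(sinfo, allow_shared = FALSE)
            all_ok <- FALSE
            break
          }
        }
      }
      if (all_ok) break
      if (round == 8L) stop("planted sites could not be made uniquely recoverable",
                            call. = FALSE)
    }

    for (j in seq_along(built)) {
      sinfo <- sp_specs[[j]]
      sp_srnas[[sinfo$id]] <- built[[j]]$asm$srna
      for (kind in c("D", "Dprime")) {
        g <- built[[j]]$guides[[kind]]
        gs <- g$spec
        gcls <- if (is.null(gs)) {
          if (sinfo$class == "decoy") "decoy" else "empty_guide"
        } else gs$class
        sp_truth[[length(sp_truth) + 1L]] <- data.frame(
          species = sp, srna_id = sinfo$id, guide_kind = kind, class = gcls,
          molecule = if (is.null(gs)) NA_character_ else gs$molecule,
          site = if (is.null(gs)) NA_integer_ else gs$site,
          column = if (is.null(gs)) NA_integer_ else
            state[[sp]]$maps[[gs$molecule]]$col_of_pos[gs$site],
          shared_id = if (is.null(gs)) NA_integer_ else gs$shared_id,
          site_class = if (is.null(gs)) NA_character_ else
            switch(gs$class, clean = "WC", site_mismatch = "MM", site_gu = "GU"),
          expect_significant = !is.null(gs),
          expect_productive = !is.null(gs) && gs$class == "clean",
          accidental = FALSE,
          guide_seq = paste(g$guide, collapse = ""),
          stringsAsFactors = FALSE)
      }
      truth_s[[length(truth_s) + 1L]] <- data.frame(
        species = sp, srna_id = sinfo$id, class = sinfo$class,
        expected_call = NA_character_, stringsAsFactors = FALSE)
    }
    srnas[[sp]] <- sp_srnas
    truth_g[[sp]] <- do.call(rbind, sp_truth)
  }

  truth_guides <- do.call(rbind, truth_g)
  rownames(truth_guides) <- NULL
  truth_srnas <- do.call(rbind, truth_s)
  rownames(truth_srnas) <- NULL

  # rebuild final sequences/rows after all forcings
  rrnas <- lapply(state, function(st) lapply(st$seqs, paste, collapse = ""))
  alignments <- lapply(mols, function(m) {
    rows <- vapply(species, function(sp) paste(state[[sp]]$rows[[m]], collapse = ""),
                   character(1L))
    names(rows) <- species
    rows
  })
  names(alignments) <- mols
  column_maps <- lapply(state, function(st) st$maps)

  ds <- structure(list(
    spec = spec, species = species, rrnas = rrnas, srnas = srnas,
    alignments = alignments, column_maps = column_maps,
    truth_guides = truth_guides, truth_srnas = truth_srnas
  ), class = "cd_synthetic_dataset")
  finalize_truth(ds)
}

# Run the pipeline once over the emitted data to (a) assert that every
# planted guide is recovered and (b) record the actual outcome for decoy and
# empty guides (accidental hits included), so truth-based tests are exact.
finalize_truth <- function(ds) {
  tg <- ds$truth_guides
  ts <- ds$truth_srnas
  for (sp in ds$species) {
    ann <- lapply(names(ds$srnas[[sp]]), function(id) {
      annotate_cd_srna(ds$srnas[[sp]][[id]], id = id, species = sp)
    })
    bad <- vapply(ann, is_rejected, logical(1L))
    if (any(bad)) stop("internal: planted sRNA rejected by annotation", call. = FALSE)
    res <- predict_targets(ann, ds$rrnas[[sp]], scan_rules(), species = sp)
    pred <- res$predictions
    for (i in which(tg$species == sp)) {
      hit <- pred[pred$srna_id == tg$srna_id[i] & pred$guide_kind == tg$guide_kind[i], ,
                  drop = FALSE]
      if (tg$class[i] %in% c("decoy", "empty_guide")) {
        if (nrow(hit)) {
          tg$accidental[i] <- TRUE
          tg$molecule[i] <- hit$molecule[1L]
          tg$site[i] <- hit$position[1L]
          tg$column[i] <- ds$column_maps[[sp]][[hit$molecule[1L]]]$col_of_pos[hit$position[1L]]
          tg$site_class[i] <- hit$site_class[1L]
          tg$expect_significant[i] <- TRUE
          tg$expect_productive[i] <- hit$productive[1L]
        } else {
          tg$expect_significant[i] <- FALSE
          tg$expect_productive[i] <- FALSE
        }
      } else {
        if (!nrow(hit) || hit$molecule[1L] != tg$molecule[i] ||
            hit$position[1L] != tg$site[i]) {
          stop("internal: planted guide not recovered (", sp, " ",
               tg$srna_id[i], " ", tg$guide_kind[i], ")", call. = FALSE)
        }
      }
    }
    cls <- res$srna_classes
    for (i in which(ts$species == sp)) {
      ts$expected_call[i] <- cls$class[cls$srna_id == ts$srna_id[i]]
    }
  }
  ds$truth_guides <- tg
  ds$truth_srnas <- ts
  ds
}

#' @export
print.cd_synthetic_dataset <- function(x, ...) {
  cat(sprintf("<cd_synthetic_dataset> %d species x %d sRNAs (seed %d)\n",
              length(x$species), x$spec$n_srnas_per_species, x$spec$seed))
  cat(sprintf("  guide classes: %s\n",
              paste(sprintf("%s=%d", names(table(x$truth_guides$class)),
                            as.integer(table(x$truth_guides$class))), collapse = ", ")))
  invisible(x)
}

#' Write a synthetic dataset to disk (FASTA, alignments, truth, config)
#'
#' Emits per-species sRNA and rRNA FASTA files, the true multi-species
#' alignments, the truth tables (TSV) and a ready-to-run pipeline config
#' (`config.yaml`) referencing them with paths relative to `dir`.
#'
#' @param ds a `"cd_synthetic_dataset"` from [generate_dataset()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "cd_synthetic_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg_species <- list()
  for (sp in ds$species) {
    write_rna_fasta(ds$srnas[[sp]], file.path(dir, paste0(sp, "_srna.fasta")))
    entry <- list(abbreviation = sp, srna = paste0(sp, "_srna.fasta"))
    for (m in names(ds$rrnas[[sp]])) {
      f <- paste0(sp, "_", m, ".fasta")
      seqs <- ds$rrnas[[sp]][[m]]
      names(seqs) <- paste0(sp, "_", sub("rRNA_", "", m))
      write_rna_fasta(seqs, file.path(dir, f))
      entry[[tolower(m)]] <- f
    }
    cfg_species[[length(cfg_species) + 1L]] <- entry
  }
  aln_files <- list()
  for (m in names(ds$alignments)) {
    f <- paste0("alignment_", m, ".fasta")
    write_rna_fasta(ds$alignments[[m]], file.path(dir, f))
    aln_files[[m]] <- f
  }
  utils::write.table(ds$truth_guides, file.path(dir, "truth_guides.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(ds$truth_srnas, file.path(dir, "truth_srnas.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- list(species = cfg_species, alignment = aln_files,
              output_dir = "results", seed = ds$spec$seed)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}
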