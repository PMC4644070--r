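# Guide-rRNA duplex scanning under the N+5 rule.
#
# A guide of length L paired bulge-free and antiparallel against an rRNA
# window [target_start, target_end] (target_end - target_start + 1 = L) pairs
# guide position i (1-based, 5'->3') with rRNA position target_end - i + 1.
# The methylation site is the rRNA partner of the guide +5 position
# (plus5_offset = L - 5), i.e. site = target_start + (L - plus5_offset).

#' Duplex scanning rules
#'
#' Strict significance requires a run of at least `min_consecutive_wc`
#' consecutive Watson-Crick pairs covering the +5 pairing column, with at most
#' `max_mismatch` mismatches and `max_gu` G:U pairs in the whole duplex.  In
#' relaxed mode (used for double-guide rescue) G:U pairs count as pairing
#' inside the run when `relaxed_run_counts_gu` is `TRUE`, and at most
#' `relaxed_max_mismatch` mismatches are allowed in the whole duplex.  In both
#' modes the +5 column itself is exempt from the pairing requirement: a
#' mismatch or G:U pair exactly at the site leaves the duplex significant
#' (if the flanking run is long enough) but non-productive.  Bulges are never
#' allowed.
#'
#' @param min_consecutive_wc minimum pairing-run length covering the +5
#'   column (>= 6 so the run can reach the site).
#' @param max_mismatch,max_gu strict-mode whole-duplex limits.
#' @param relaxed_run_counts_gu should G:U count as pairing inside the relaxed
#'   run?
#' @param relaxed_max_mismatch relaxed-mode whole-duplex mismatch limit.
#' @return An object of class `"scan_rules"`.
#' @export
scan_rules <- function(min_consecutive_wc = 9L, max_mismatch = 1L, max_gu = 2L,
                       relaxed_run_counts_gu = TRUE, relaxed_max_mismatch = 1L) {
  stopifnot(min_consecutive_wc >= 6L)
  structure(list(
    min_consecutive_wc = as.integer(min_consecutive_wc),
    max_mismatch = as.integer(max_mismatch),
    max_gu = as.integer(max_gu),
    allow_bulges = FALSE,
    relaxed_run_counts_gu = isTRUE(relaxed_run_counts_gu),
    relaxed_max_mismatch = as.integer(relaxed_max_mismatch)
  ), class = "scan_rules")
}

#' Classify a base pair as Watson-Crick, wobble or mismatch
#'
#' Vectorized and symmetric: A:U and G:C are `"WC"`, G:U is `"GU"`, anything
#' else is `"MM"`.
#'
#' @param a,b residue vectors over A/C/G/U.
#' @return Character vector of `"WC"`, `"GU"`, `"MM"`.
#' @export
classify_pair <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must have equal length", call. = FALSE)
  if (any(!a %in% RNA_BASES) || any(!b %in% RNA_BASES)) {
    stop("residues must be A/C/G/U", call. = FALSE)
  }
  wc <- (a == "A" & b == "U") | (a == "U" & b == "A") |
    (a == "G" & b == "C") | (a == "C" & b == "G")
  gu <- (a == "G" & b == "U") | (a == "U" & b == "G")
  ifelse(wc, "WC", ifelse(gu, "GU", "MM"))
}

#' Reverse complement of an RNA sequence
#' @param x RNA sequence string (A/C/G/U).
#' @return The reverse complement string.
#' @export
revcomp_rna <- function(x) {
  chartr("ACGU", "UGCA", paste(rev(strsplit(x, "", fixed = TRUE)[[1L]]), collapse = ""))
}

as_guide <- function(guide, plus5_offset = NULL) {
  if (is.character(guide)) {
    L <- nchar(guide)
    return(list(srna_id = "<guide>", kind = "D", sequence = guide,
                plus5_offset = plus5_offset %||% (L - 5L), length = L))
  }
  g <- if (is.data.frame(guide)) {
    as.list(guide[1L, , drop = FALSE][c("srna_id", "kind", "sequence", "plus5_offset")])
  } else {
    guide[c("srna_id", "kind", "sequence", "plus5_offset")]
  }
  g$length <- nchar(g$sequence)
  g
}

#' Pair a guide against an rRNA window (bulge-free, antiparallel)
#'
#' @param guide a guide row from [extract_guides()] or a sequence string
#'   (then `plus5_offset` defaults to length - 5).
#' @param window rRNA window, same length as the guide, 5'->3'.
#' @param plus5_offset override for character guides.
#' @return An object of class `"duplex_alignment"`: `pair_classes` (one class
#'   per guide position, 5'->3' along the guide), `plus5_offset`,
#'   `site_window_index` (window position paired with the +5 guide position),
#'   `site_class`.
#' @examples
#' d <- pair_guide_window("UUAGGACUGAUCC", "GGAUCAGUCCUAA")
#' d$site_window_index  # 6
#' @export
pair_guide_window <- function(guide, window, plus5_offset = NULL) {
  g <- as_guide(guide, plus5_offset)
  L <- g$length
  if (nchar(window) != L) {
    stop("window length (", nchar(window), ") != guide length (", L, ")", call. = FALSE)
  }
  if (g$plus5_offset < 1L) stop("guide too short to host the +5 position", call. = FALSE)
  gc <- strsplit(g$sequence, "", fixed = TRUE)[[1L]]
  wcRes <- strsplit(window, "", fixed = TRUE)[[1L]]
  partner <- wcRes[L - seq_len(L) + 1L]  # antiparallel register
  classes <- classify_pair(gc, partner)
  structure(list(
    guide = g, window = window, pair_classes = classes,
    plus5_offset = g$plus5_offset,
    site_window_index = L - g$plus5_offset + 1L,
    site_class = classes[[g$plus5_offset]]
  ), class = "duplex_alignment")
}

# run of consecutive pairing positions around the +5 column; the +5 column is
# exempt from the pairing requirement and is counted only if it pairs itself.
site_run <- function(pairing, p5) {
  l <- 0L; i <- p5 - 1L
  while (i >= 1L && pairing[i]) { l <- l + 1L; i <- i - 1L }
  r <- 0L; i <- p5 + 1L
  while (i <= length(pairing) && pairing[i]) { r <- r + 1L; i <- i + 1L }
  l + r + as.integer(isTRUE(pairing[p5]))
}

duplex_stats <- function(classes, p5, rules, mode) {
  n_mm <- sum(classes == "MM")
  n_gu <- sum(classes == "GU")
  pairing <- if (mode == "strict") classes == "WC"
             else classes == "WC" | (rules$relaxed_run_counts_gu & classes == "GU")
  run <- site_run(pairing, p5)
  significant <- if (mode == "strict") {
    run >= rules$min_consecutive_wc && n_mm <= rules$max_mismatch && n_gu <= rules$max_gu
  } else {
    run >= rules$min_consecutive_wc && n_mm <= rules$relaxed_max_mismatch
  }
  list(wc_run = run, n_mm = n_mm, n_gu = n_gu, significant = significant,
       site_class = classes[[p5]])
}

#' Call significance of a guide-target duplex
#'
#' @param d a `"duplex_alignment"` from [pair_guide_window()].
#' @param rules a [scan_rules()] object.
#' @param mode `"strict"` or `"relaxed"`.
#' @return Logical: is the duplex significant under the rules?
#' @export
call_significance <- function(d, rules = scan_rules(), mode = c("strict", "relaxed")) {
  mode <- match.arg(mode)
  stopifnot(inherits(d, "duplex_alignment"))
  duplex_stats(d$pair_classes, d$plus5_offset, rules, mode)$significant
}

#' Call productivity of a significant duplex
#'
#' A significant duplex directs methylation only if the +5 pairing column is a
#' canonical Watson-Crick pair.  A mismatch at the site makes the interaction
#' non-productive; a G:U pair at the site is also treated as non-productive
#' but flagged `"uncertain_site_GU"` since such cases are borderline.
#'
#' @param d a `"duplex_alignment"`, or a list with `significant` and
#'   `site_class` fields.
#' @param significant significance override for duplexes built with
#'   [pair_guide_window()] (which carry no significance call of their own).
#' @return Logical.
#' @export
classify_productive <- function(d, significant = NULL) {
  sig <- significant %||% d$significant
  if (is.null(sig)) stop("significance not known; pass `significant`", call. = FALSE)
  isTRUE(sig) && identical(d$site_class, "WC")
}

#' Scan a guide against an rRNA for significant duplexes
#'
#' Evaluates every bulge-free antiparallel register (offsets 1 ..
#' rRNA length - guide length + 1) and returns those passing
#' [call_significance()], sorted by decreasing pairing-run length, then
#' increasing mismatch + G:U count, then 5'-most target start.
#'
#' @param guide a guide row from [extract_guides()] or a sequence string.
#' @param rrna rRNA residues string, or a one-row data.frame from
#'   [read_rna_fasta()] (its `molecule`/`id` are carried into the result).
#' @param rules a [scan_rules()] object.
#' @param mode `"strict"` or `"relaxed"`.
#' @param molecule,target_id labels for the result (defaults taken from
#'   `rrna` when it is a data.frame).
#' @return A data.frame of significant hits with columns `srna_id`,
#'   `guide_kind`, `molecule`, `target_id`, `target_start`, `target_end`,
#'   `position` (the predicted methylation site), `site_class`, `wc_run`,
#'   `n_mm`, `n_gu`, `mode`, `significant`, `productive`, `flag`.
#' @export
scan_guide <- function(guide, rrna, rules = scan_rules(),
                       mode = c("strict", "relaxed"),
                       molecule = NULL, target_id = NULL) {
  mode <- match.arg(mode)
  g <- as_guide(guide)
  if (is.data.frame(rrna)) {
    molecule <- molecule %||% rrna$molecule[[1L]]
    target_id <- target_id %||% rrna$id[[1L]]
    residues <- rrna$residues[[1L]]
  } else {
    residues <- rrna
  }
  molecule <- molecule %||% "other"
  target_id <- target_id %||% NA_character_
  L <- g$length
  p5 <- g$plus5_offset
  if (p5 < 1L) stop("guide too short to host the +5 position", call. = FALSE)
  r <- strsplit(residues, "", fixed = TRUE)[[1L]]
  N <- length(r)
  if (N < L) stop("rRNA shorter than guide", call. = FALSE)
  M <- N - L + 1L
  gc <- strsplit(g$sequence, "", fixed = TRUE)[[1L]]
  wc <- matrix(FALSE, nrow = L, ncol = M)
  gu <- matrix(FALSE, nrow = L, ncol = M)
  for (i in seq_len(L)) {
    part <- r[(L - i + 1L):(N - i + 1L)]  # partner residues across all offsets
    wc[i, ] <- part == RNA_COMPLEMENT[[gc[i]]]
    gu[i, ] <- (gc[i] == "G" & part == "U") | (gc[i] == "U" & part == "G")
  }
  pairing <- if (mode == "strict") wc else (wc | (rules$relaxed_run_counts_gu & gu))
  left <- integer(M); ok <- rep(TRUE, M)
  if (p5 > 1L) for (i in (p5 - 1L):1L) { ok <- ok & pairing[i, ]; left <- left + ok }
  right <- integer(M); ok <- rep(TRUE, M)
  if (p5 < L) for (i in (p5 + 1L):L) { ok <- ok & pairing[i, ]; right <- right + ok }
  run <- left + right + as.integer(pairing[p5, ])
  n_mm <- colSums(!wc & !gu)
  n_gu <- colSums(gu)
  sig <- if (mode == "strict") {
    run >= rules$min_consecutive_wc & n_mm <= rules$max_mismatch & n_gu <= rules$max_gu
  } else {
    run >= rules$min_consecutive_wc & n_mm <= rules$relaxed_max_mismatch
  }
  hits <- which(sig)
  if (!length(hits)) {
    out <- empty_scan_frame()
    return(out)
  }
  site_class <- ifelse(wc[p5, hits], "WC", ifelse(gu[p5, hits], "GU", "MM"))
  out <- data.frame(
    srna_id = g$srna_id, guide_kind = g$kind, molecule = molecule,
    target_id = target_id,
    target_start = hits, target_end = hits + L - 1L,
    position = hits + (L - p5),
    site_class = site_class,
    wc_run = run[hits], n_mm = as.integer(n_mm[hits]), n_gu = as.integer(n_gu[hits]),
    mode = mode, significant = TRUE,
    productive = site_class == "WC",
    flag = ifelse(site_class == "GU", "uncertain_site_GU",
                  ifelse(site_class == "MM", "site_mismatch", "")),
    stringsAsFactors = FALSE
  )
  out[order(-out$wc_run, out$n_mm + out$n_gu, out$target_start), , drop = FALSE]
}

empty_scan_frame <- function() {
  data.frame(
    srna_id = character(), guide_kind = character(), molecule = character(),
    target_id = character(), target_start = integer(), target_end = integer(),
    position = integer(), site_class = character(), wc_run = integer(),
    n_mm = integer(), n_gu = integer(), mode = character(),
    significant = logical(), productive = logical(), flag = character(),
    stringsAsFactors = FALSE
  )
}

# order used to pick the single retained prediction per guide
order_hits <- function(h) {
  mol_rank <- match(h$molecule, MOLECULE_LEVELS, nomatch = length(MOLECULE_LEVELS) + 1L)
  order(-h$wc_run, h$n_mm + h$n_gu, mol_rank, h$target_start)
}

#' Predict methylation targets for a set of annotated sRNAs
#'
#' Two-pass procedure over the D and D' guides of every annotated sRNA of one
#' species.  Pass 1: strict scan of every guide against both rRNAs, keeping
#' the best hit per guide (or all passing hits with `multi_target = TRUE`).
#' Pass 2 (double-guide rescue): a guide with no strict hit whose partner
#' guide has a kept hit is rescanned in relaxed mode; a relaxed hit is kept
#' only if its site lies within `double_guide_window` nucleotides of the
#' partner's site on the same molecule (the closest qualifying hit under the
#' standard ordering is kept).  Guides of rejected sRNAs are skipped.
#'
#' @param srnas list of [annotate_cd_srna()] results (`cd_srna` or
#'   `cd_rejection` objects).
#' @param rrnas named list/vector of rRNA residue strings with names
#'   `rRNA_16S` and/or `rRNA_23S`, or a data.frame from [read_rna_fasta()]
#'   with a `molecule` column.
#' @param rules a [scan_rules()] object.
#' @param multi_target keep all passing strict hits per guide instead of the
#'   best one.
#' @param double_guide_window maximum site separation (nt, inclusive) for
#'   relaxed rescue of a partner guide.
#' @param species species label for the output (defaults to the first sRNA's).
#' @return A list with elements
#'   \describe{
#'     \item{predictions}{prediction data.frame (one row per kept guide hit).}
#'     \item{srna_classes}{data.frame `srna_id`, `class` in
#'       `double_guide` / `single_guide` / `no_target` / `rejected`.}
#'     \item{summary}{named list of counts: `n_srnas`, `n_annotated`,
#'       `n_rejected`, `n_guides`, `n_significant`, `n_productive`,
#'       `n_nonproductive`, `n_empty_guides`, `n_double_guide`,
#'       `n_single_guide`, `n_no_target`.}
#'   }
#' @export
predict_targets <- function(srnas, rrnas, rules = scan_rules(),
                            multi_target = FALSE, double_guide_window = 100L,
                            species = NULL) {
  if (inherits(srnas, "cd_srna") || inherits(srnas, "cd_rejection")) srnas <- list(srnas)
  rr <- normalize_rrna_set(rrnas)
  preds <- list()
  guide_tab <- list()
  classes <- list()
  n_rejected <- 0L
  n_guides_with_hit <- 0L
  for (s in srnas) {
    if (is_rejected(s)) {
      n_rejected <- n_rejected + 1L
      classes[[length(classes) + 1L]] <-
        data.frame(srna_id = s$id, class = "rejected", stringsAsFactors = FALSE)
      next
    }
    if (is.null(species)) species <- s$species
    kept <- list()
    for (k in seq_len(nrow(s$guides))) {
      gd <- s$guides[k, ]
      hits <- do.call(rbind, lapply(names(rr$seqs), function(mol) {
        scan_guide(gd, rr$seqs[[mol]], rules, mode = "strict",
                   molecule = mol, target_id = rr$ids[[mol]])
      }))
      if (!is.null(hits) && nrow(hits)) {
        hits <- hits[order_hits(hits), , drop = FALSE]
        kept[[gd$kind]] <- if (multi_target) hits else hits[1L, , drop = FALSE]
      }
      guide_tab[[length(guide_tab) + 1L]] <-
        data.frame(srna_id = s$id, kind = gd$kind, stringsAsFactors = FALSE)
    }
    # pass 2: relaxed rescue of an empty guide next to its partner's site
    kinds <- s$guides$kind
    if (length(kinds) == 2L && length(kept) == 1L) {
      have <- names(kept)[[1L]]
      need <- setdiff(kinds, have)
      partner <- kept[[have]][1L, ]
      gd <- s$guides[s$guides$kind == need, ]
      rel <- scan_guide(gd, rr$seqs[[partner$molecule]], rules, mode = "relaxed",
                        molecule = partner$molecule,
                        target_id = rr$ids[[partner$molecule]])
      if (nrow(rel)) {
        rel <- rel[abs(rel$position - partner$position) <= double_guide_window, ,
                   drop = FALSE]
        if (nrow(rel)) {
          rel <- rel[order_hits(rel), , drop = FALSE]
          kept[[need]] <- rel[1L, , drop = FALSE]
        }
      }
    }
    n_hit_guides <- length(kept)
    n_guides_with_hit <- n_guides_with_hit + n_hit_guides
    cls <- if (n_hit_guides >= 2L) "double_guide"
           else if (n_hit_guides == 1L) "single_guide" else "no_target"
    classes[[length(classes) + 1L]] <-
      data.frame(srna_id = s$id, class = cls, stringsAsFactors = FALSE)
    if (n_hit_guides) preds[[length(preds) + 1L]] <- do.call(rbind, kept)
  }
  predictions <- if (length(preds)) do.call(rbind, preds) else empty_scan_frame()
  rownames(predictions) <- NULL
  if (nrow(predictions)) predictions$species <- species %||% NA_character_
  else predictions$species <- character()
  predictions <- as_prediction_frame(predictions)
  classes <- if (length(classes)) do.call(rbind, classes) else
    data.frame(srna_id = character(), class = character(), stringsAsFactors = FALSE)
  n_guides <- length(guide_tab)
  summary <- list(
    n_srnas = length(srnas),
    n_annotated = length(srnas) - n_rejected,
    n_rejected = n_rejected,
    n_guides = n_guides,
    n_significant = nrow(predictions),
    n_productive = sum(predictions$productive),
    n_nonproductive = sum(!predictions$productive),
    n_empty_guides = n_guides - n_guides_with_hit,
    n_double_guide = sum(classes$class == "double_guide"),
    n_single_guide = sum(classes$class == "single_guide"),
    n_no_target = sum(classes$class == "no_target")
  )
  list(predictions = predictions, srna_classes = classes, summary = summary)
}

normalize_rrna_set <- function(rrnas) {
  if (is.data.frame(rrnas)) {
    seqs <- as.list(rrnas$residues)
    names(seqs) <- rrnas$molecule
    ids <- as.list(rrnas$id)
    names(ids) <- rrnas$molecule
  } else {
    seqs <- as.list(rrnas)
    ids <- as.list(rep(NA_character_, length(seqs)))
    names(ids) <- names(seqs)
  }
  bad <- setdiff(names(seqs), c("rRNA_16S", "rRNA_23S", "other"))
  if (length(bad)) stop("unknown rRNA molecule name(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  list(seqs = seqs, ids = ids)
}
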