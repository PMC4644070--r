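# Box motif detection, k-turn plausibility and guide extraction.

BOX_CONSENSUS <- c(C = "RUGAUGA", Cprime = "RUGAUGA", D = "CUGA", Dprime = "CUGA")
BOX_KINDS <- names(BOX_CONSENSUS)

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", U = "U",
  R = c("A", "G")
)

#' Default box-annotation parameters
#'
#' Mismatch tolerances default to 1 for C/C' and D', and 0 for D (the D box is
#' the best-conserved element).  Guide lengths of 6--20 nt are accepted; guides
#' outside 9--13 nt are annotated with a note (10--12 nt is typical, not a
#' rule).  Sequences longer than `max_len` (default 100 nt) are rejected.
#'
#' @param max_mm_c,max_mm_cprime,max_mm_d,max_mm_dprime maximum mismatches to
#'   the box consensus for each box kind.
#' @param guide_min,guide_max hard guide-length bounds (nt).  `guide_min` must
#'   be at least 6 so the +5 position exists.
#' @param guide_warn length band outside which a note is recorded.
#' @param max_len maximum sRNA length considered.
#' @return A named list of parameters.
#' @export
cd_params <- function(max_mm_c = 1L, max_mm_dprime = 1L, max_mm_cprime = 1L,
                      max_mm_d = 0L, guide_min = 6L, guide_max = 20L,
                      guide_warn = c(9L, 13L), max_len = 100L) {
  stopifnot(guide_min >= 6L, guide_max >= guide_min, max_len >= 22L)
  list(max_mm_c = max_mm_c, max_mm_dprime = max_mm_dprime,
       max_mm_cprime = max_mm_cprime, max_mm_d = max_mm_d,
       guide_min = as.integer(guide_min), guide_max = as.integer(guide_max),
       guide_warn = as.integer(guide_warn), max_len = as.integer(max_len))
}

#' Count mismatches of a window against an IUPAC consensus
#'
#' The consensus may use A/C/G/U plus R (= A or G).  A window residue matches
#' when it is in the consensus set at that position.
#'
#' @param window sequence window (same length as `consensus`).
#' @param consensus consensus string.
#' @return Integer mismatch count.
#' @examples
#' match_consensus("AUGAUGA", "RUGAUGA")  # 0
#' match_consensus("CUGAUGA", "RUGAUGA")  # 1
#' @export
match_consensus <- function(window, consensus) {
  if (nchar(window) != nchar(consensus)) {
    stop("window length (", nchar(window), ") != consensus length (",
         nchar(consensus), ")", call. = FALSE)
  }
  w <- strsplit(window, "", fixed = TRUE)[[1L]]
  k <- strsplit(consensus, "", fixed = TRUE)[[1L]]
  bad <- which(!k %in% names(IUPAC_SETS))
  if (length(bad)) stop("unsupported consensus code(s): ", paste(k[bad], collapse = ","),
                        call. = FALSE)
  sum(!mapply(function(wi, ki) wi %in% IUPAC_SETS[[ki]], w, k))
}

#' Find all box motif candidates in a sequence
#'
#' Slides the consensus of the requested box kind over the sequence and
#' returns every window with at most `max_mm` mismatches, sorted by
#' (mismatches, start).
#'
#' @param seq an RNA sequence string, or a one-row data.frame from
#'   [read_rna_fasta()].
#' @param kind one of `"C"`, `"Dprime"`, `"Cprime"`, `"D"`.
#' @param max_mm maximum mismatches against the consensus.
#' @return A data.frame with columns `kind`, `start`, `end`, `sequence`,
#'   `mismatches` (possibly zero rows).
#' @export
find_box_motifs <- function(seq, kind = BOX_KINDS, max_mm = 1L) {
  kind <- match.arg(kind)
  residues <- if (is.data.frame(seq)) seq$residues[[1L]] else seq
  consensus <- BOX_CONSENSUS[[kind]]
  L <- nchar(consensus)
  n <- nchar(residues)
  out <- data.frame(kind = character(), start = integer(), end = integer(),
                    sequence = character(), mismatches = integer(),
                    stringsAsFactors = FALSE)
  if (n < L) return(out)
  starts <- seq_len(n - L + 1L)
  win <- substring(residues, starts, starts + L - 1L)
  mm <- vapply(win, match_consensus, integer(1L), consensus = consensus,
               USE.NAMES = FALSE)
  keep <- which(mm <= max_mm)
  if (!length(keep)) return(out)
  out <- data.frame(kind = kind, start = starts[keep], end = starts[keep] + L - 1L,
                    sequence = win[keep], mismatches = mm[keep],
                    stringsAsFactors = FALSE)
  out[order(out$mismatches, out$start), , drop = FALSE]
}

#' Sequence-level kink-turn plausibility for a C/D box pair
#'
#' When a C box (RUGAUGA) and a D box (CUGA) juxtapose, the k-turn is capped by
#' two tandem sheared pairs.  Under the consensus register the check requires
#' C-box G3 opposite D-box A4 (G.A), C-box A4 opposite D-box G3 (A.G), and the
#' neighbouring C-box position 5 / D-box position 2 pair to be U.U or
#' Watson-Crick.  This is a sequence-only proxy for k-turn formation.
#'
#' @param cbox a box motif (one-row data.frame or list with `kind` and
#'   `sequence`); kind must be `"C"` or `"Cprime"`.
#' @param dbox a box motif with kind `"D"` or `"Dprime"`.
#' @return `TRUE` if the sheared-pair residues are present.
#' @export
check_kturn <- function(cbox, dbox) {
  ck <- as.character(cbox$kind[[1L]]); dk <- as.character(dbox$kind[[1L]])
  if (!ck %in% c("C", "Cprime")) stop("cbox kind must be C or Cprime, got ", ck, call. = FALSE)
  if (!dk %in% c("D", "Dprime")) stop("dbox kind must be D or Dprime, got ", dk, call. = FALSE)
  cs <- strsplit(as.character(cbox$sequence[[1L]]), "", fixed = TRUE)[[1L]]
  ds <- strsplit(as.character(dbox$sequence[[1L]]), "", fixed = TRUE)[[1L]]
  if (length(cs) != 7L || length(ds) != 4L) {
    stop("box lengths must be 7 (C/C') and 4 (D/D')", call. = FALSE)
  }
  sheared1 <- cs[3L] == "G" && ds[4L] == "A"
  sheared2 <- cs[4L] == "A" && ds[3L] == "G"
  cap <- (cs[5L] == "U" && ds[2L] == "U") ||
    classify_pair(cs[5L], ds[2L]) == "WC"
  isTRUE(sheared1 && sheared2 && cap)
}

cd_rejection <- function(id, reason) {
  structure(list(id = id, reason = reason), class = "cd_rejection")
}

#' Test whether an annotation result is a rejection
#' @param x result of [annotate_cd_srna()].
#' @return Logical scalar.
#' @export
is_rejected <- function(x) inherits(x, "cd_rejection")

#' Annotate a small RNA as a C/D box sRNA
#'
#' Searches exhaustively over candidate box quadruples (C, D', C', D in strictly
#' increasing, non-overlapping order, both guides within the configured length
#' bounds) and returns the best-scoring consistent arrangement.  The score is
#' the total number of box mismatches; ties are broken by guide lengths closest
#' to 11 nt, then by the leftmost C box.  Kink-turn plausibility of the C/D and
#' C'/D' pairs is recorded but is advisory: it never rejects an sRNA.
#'
#' @param seq an RNA sequence string or a one-row data.frame from
#'   [read_rna_fasta()] (its `id`/`species` are carried through).
#' @param params parameters from [cd_params()].
#' @param id,species overrides for the sequence id and species label.
#' @return An object of class `"cd_srna"` (list with `id`, `species`,
#'   `residues`, `boxes`, `kturn`, `guides`, `score`, `notes`), or a
#'   `"cd_rejection"` (list with `id`, `reason`) when no arrangement exists.
#' @export
annotate_cd_srna <- function(seq, params = cd_params(), id = NULL, species = NA_character_) {
  if (is.data.frame(seq)) {
    if (is.null(id)) id <- seq$id[[1L]]
    if (is.na(species) && !is.null(seq$species)) species <- seq$species[[1L]]
    residues <- seq$residues[[1L]]
  } else {
    residues <- seq
    if (is.null(id)) id <- "<srna>"
  }
  n <- nchar(residues)
  if (n > params$max_len) {
    return(cd_rejection(id, sprintf("sequence length %d exceeds max_len %d", n, params$max_len)))
  }
  cands <- list(
    C = find_box_motifs(residues, "C", params$max_mm_c),
    Dprime = find_box_motifs(residues, "Dprime", params$max_mm_dprime),
    Cprime = find_box_motifs(residues, "Cprime", params$max_mm_cprime),
    D = find_box_motifs(residues, "D", params$max_mm_d)
  )
  for (k in BOX_KINDS) {
    if (nrow(cands[[k]]) == 0L) {
      return(cd_rejection(id, sprintf("no %s box within %d mismatch(es) of consensus",
                                      sub("prime", "'", k),
                                      params[[paste0("max_mm_", tolower(k))]])))
    }
  }
  gmin <- params$guide_min; gmax <- params$guide_max
  best <- NULL
  for (ci in seq_len(nrow(cands$C))) {
    cbox <- cands$C[ci, ]
    for (di in seq_len(nrow(cands$Dprime))) {
      dp <- cands$Dprime[di, ]
      g1 <- dp$start - cbox$end  # D' guide length (includes D' box first nt)
      if (g1 < gmin || g1 > gmax) next
      for (cpi in seq_len(nrow(cands$Cprime))) {
        cp <- cands$Cprime[cpi, ]
        if (cp$start <= dp$end) next
        for (ddi in seq_len(nrow(cands$D))) {
          dd <- cands$D[ddi, ]
          g2 <- dd$start - cp$end  # D guide length (includes D box first nt)
          if (g2 < gmin || g2 > gmax) next
          if (dd$end > n) next
          score <- cbox$mismatches + dp$mismatches + cp$mismatches + dd$mismatches
          tie1 <- abs(g1 - 11L) + abs(g2 - 11L)
          key <- c(score, tie1, cbox$start, dp$start, cp$start, dd$start)
          if (is.null(best) || lex_less(key, best$key)) {
            best <- list(key = key, C = cbox, Dprime = dp, Cprime = cp, D = dd,
                         score = score)
          }
        }
      }
    }
  }
  if (is.null(best)) {
    return(cd_rejection(id, "no consistent C / D' / C' / D arrangement with guides in bounds"))
  }
  boxes <- rbind(best$C, best$Dprime, best$Cprime, best$D)
  rownames(boxes) <- NULL
  srna <- structure(
    list(id = id, species = species, residues = residues, boxes = boxes,
         kturn = c(CD = check_kturn(best$C, best$D),
                   CpDp = check_kturn(best$Cprime, best$Dprime)),
         guides = NULL, score = best$score, notes = character()),
    class = "cd_srna"
  )
  srna$guides <- extract_guides(srna)
  warn <- params$guide_warn
  odd <- srna$guides$length < warn[1L] | srna$guides$length > warn[2L]
  if (any(odd)) {
    srna$notes <- c(srna$notes, sprintf(
      "%s guide length %d outside typical band %d-%d",
      srna$guides$kind[odd], srna$guides$length[odd], warn[1L], warn[2L]
    ))
  }
  srna
}

`%||%` <- function(a, b) if (is.null(a)) b else a

lex_less <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  FALSE
}

#' Extract the D and D' guide regions of an annotated sRNA
#'
#' The D' guide spans (C box end + 1) .. (D' box start) and the D guide spans
#' (C' box end + 1) .. (D box start); each guide therefore ends on the first
#' nucleotide of its downstream box, which may participate in the duplex.
#' `plus5_offset = length - 5` is the 1-based guide index (from the 5' end)
#' of the nucleotide sitting five nucleotides upstream of the downstream box
#' start; methylation is directed to its base-pairing partner.  A guide
#' shorter than 6 nt cannot host the +5 position and is dropped with a note.
#'
#' @param srna a `"cd_srna"` object from [annotate_cd_srna()].
#' @return A data.frame with columns `srna_id`, `kind` (`"D"`, `"Dprime"`),
#'   `start`, `end`, `length`, `sequence`, `plus5_offset` (D guide first).
#' @export
extract_guides <- function(srna) {
  stopifnot(inherits(srna, "cd_srna") || (is.list(srna) && !is.null(srna$boxes)))
  b <- srna$boxes
  row_of <- function(kind) b[b$kind == kind, , drop = FALSE][1L, ]
  cb <- row_of("C"); dpb <- row_of("Dprime"); cpb <- row_of("Cprime"); db <- row_of("D")
  mk <- function(kind, start, end) {
    len <- end - start + 1L
    data.frame(srna_id = srna$id, kind = kind, start = start, end = end,
               length = len,
               sequence = substr(srna$residues, start, end),
               plus5_offset = len - 5L, stringsAsFactors = FALSE)
  }
  guides <- rbind(mk("D", cpb$end + 1L, db$start),
                  mk("Dprime", cb$end + 1L, dpb$start))
  short <- guides$length < 6L
  if (any(short)) {
    guides <- guides[!short, , drop = FALSE]
  }
  rownames(guides) <- NULL
  guides
}

#' @export
print.cd_srna <- function(x, ...) {
  cat(sprintf("<cd_srna> %s (%s), %d nt, box mismatches %d\n",
              x$id, x$species, nchar(x$residues), x$score))
  cat(sprintf("  boxes: %s\n",
              paste(sprintf("%s@%d-%d(%s)", x$boxes$kind, x$boxes$start,
                            x$boxes$end, x$boxes$sequence), collapse = "  ")))
  cat(sprintf("  k-turn C/D: %s, C'/D': %s\n", x$kturn[["CD"]], x$kturn[["CpDp"]]))
  for (i in seq_len(nrow(x$guides))) {
    g <- x$guides[i, ]
    cat(sprintf("  %s guide %d-%d (%d nt, +5 offset %d): %s\n",
                g$kind, g$start, g$end, g$length, g$plus5_offset, g$sequence))
  }
  invisible(x)
}

#' @export
print.cd_rejection <- function(x, ...) {
  cat(sprintf("<cd_rejection> %s: %s\n", x$id, x$reason))
  invisible(x)
}
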