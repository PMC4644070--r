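# Reading/writing external formats and alignment coordinate maps.
# Coordinates are 1-based and inclusive everywhere (TSV, GFF3, internal).

#' Normalize a nucleotide string to the RNA alphabet
#'
#' Upper-cases the sequence and maps T to U.  Any residue outside
#' A/C/G/U/T (either case) is a validation error reporting the offending
#' positions.
#'
#' @param x character scalar, the sequence.
#' @param id identifier used in error messages.
#' @return The normalized sequence (A/C/G/U only).
#' @examples
#' normalize_rna("acgT")  # "ACGU"
#' @export
normalize_rna <- function(x, id = "<sequence>") {
  stopifnot(is.character(x), length(x) == 1L)
  x <- chartr("t", "u", x)
  x <- toupper(x)
  x <- chartr("T", "U", x)
  chars <- strsplit(x, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% RNA_BASES)
  if (length(bad)) {
    stop(sprintf(
      "sequence '%s' contains %d residue(s) outside A/C/G/U/T at position(s): %s",
      id, length(bad),
      paste(utils::head(bad, 10L), collapse = ", ")
    ), call. = FALSE)
  }
  x
}

#' Read RNA sequences from a FASTA file
#'
#' Reads a (possibly DNA) FASTA file and returns normalized RNA sequences
#' (T mapped to U, upper case).  Record order is preserved; the record id is
#' the first whitespace-delimited token of the header.
#'
#' @param path path to a FASTA file.
#' @param species species abbreviation attached to every record (e.g. "Mka").
#' @param molecule one of `"sRNA"`, `"rRNA_16S"`, `"rRNA_23S"`, `"other"`.
#' @return A data.frame with columns `id`, `species`, `molecule`, `residues`.
#'   An empty FASTA file yields a zero-row data.frame.
#' @export
read_rna_fasta <- function(path, species = NA_character_,
                           molecule = c("other", "sRNA", "rRNA_16S", "rRNA_23S")) {
  molecule <- match.arg(molecule)
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    return(data.frame(id = character(), species = character(),
                      molecule = character(), residues = character(),
                      stringsAsFactors = FALSE))
  }
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1L), 1L)
  res <- as.character(set)
  res <- vapply(seq_along(res), function(i) normalize_rna(res[[i]], ids[[i]]),
                character(1L))
  data.frame(id = ids, species = species, molecule = molecule,
             residues = unname(res), stringsAsFactors = FALSE)
}

#' Write RNA sequences to a FASTA file
#'
#' @param x a data.frame as returned by [read_rna_fasta()], or a named
#'   character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rna_fasta <- function(x, path) {
  if (is.data.frame(x)) {
    seqs <- x$residues
    names(seqs) <- x$id
  } else {
    seqs <- x
    if (is.null(names(seqs))) stop("sequences must be named", call. = FALSE)
  }
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), filepath = path)
  invisible(path)
}

#' Read a multi-FASTA alignment
#'
#' All rows must have equal (gapped) length; the gap character is `-`.
#' A `.` gap is an error unless `dot_as_gap = TRUE`, in which case dots are
#' mapped to `-`.
#'
#' @param path path to an aligned multi-FASTA file.
#' @param dot_as_gap map `.` to `-` instead of erroring.
#' @return A named character vector of gapped, RNA-normalized rows.
#' @export
read_rna_alignment <- function(path, dot_as_gap = FALSE) {
  if (!file.exists(path)) stop("alignment file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("alignment file contains no records: ", path, call. = FALSE)
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1L), 1L)
  rows <- as.character(set)
  widths <- nchar(rows)
  if (length(unique(widths)) != 1L) {
    stop(sprintf(
      "ragged alignment in '%s': row lengths %s",
      path, paste(unique(widths), collapse = ", ")
    ), call. = FALSE)
  }
  rows <- vapply(seq_along(rows), function(i) {
    r <- rows[[i]]
    if (dot_as_gap) r <- chartr(".", "-", r)
    if (grepl(".", r, fixed = TRUE)) {
      stop(sprintf("alignment row '%s' uses '.' gaps; set dot_as_gap = TRUE", ids[[i]]),
           call. = FALSE)
    }
    ungapped <- gsub("-", "", r, fixed = TRUE)
    if (nzchar(ungapped)) normalize_rna(ungapped, ids[[i]])  # validate residues
    chartr("t", "u", chartr("T", "U", toupper(r)))
  }, character(1L))
  names(rows) <- ids
  rows
}

#' Build a coordinate map between an ungapped sequence and alignment columns
#'
#' `col_of_pos[i]` is the alignment column of the i-th non-gap residue of the
#' gapped row; `pos_of_col` is the inverse partial map (NA at gap columns).
#' An all-gap row is permitted and produces an empty map with a warning.
#'
#' @param gapped a gapped alignment row (gap character `-`).
#' @param species,molecule labels stored in the map.
#' @return An object of class `"column_map"` with elements `species`,
#'   `molecule`, `col_of_pos` (integer vector) and `pos_of_col`
#'   (integer vector of alignment length, NA at gaps).
#' @examples
#' m <- build_column_map("A--CG")
#' m$col_of_pos  # 1 4 5
#' @export
build_column_map <- function(gapped, species = NA_character_, molecule = "other") {
  stopifnot(is.character(gapped), length(gapped) == 1L)
  chars <- strsplit(gapped, "", fixed = TRUE)[[1L]]
  col_of_pos <- which(chars != "-")
  pos_of_col <- rep(NA_integer_, length(chars))
  pos_of_col[col_of_pos] <- seq_along(col_of_pos)
  if (length(col_of_pos) == 0L) {
    warning("all-gap alignment row for ", species, "/", molecule,
            "; column map is empty", call. = FALSE)
  }
  structure(
    list(species = species, molecule = molecule,
         col_of_pos = as.integer(col_of_pos), pos_of_col = pos_of_col),
    class = "column_map"
  )
}

#' @export
print.column_map <- function(x, ...) {
  cat(sprintf("<column_map> %s/%s: %d residues over %d columns\n",
              x$species, x$molecule, length(x$col_of_pos), length(x$pos_of_col)))
  invisible(x)
}

# canonical prediction-table columns, in output order
PREDICTION_COLUMNS <- c(
  "species", "srna_id", "guide_kind", "molecule", "position", "productive",
  "mode", "site_class", "wc_run", "n_gu", "n_mm", "target_start", "target_end",
  "target_id", "flag", "column"
)

empty_predictions <- function() {
  data.frame(
    species = character(), srna_id = character(), guide_kind = character(),
    molecule = character(), position = integer(), productive = logical(),
    mode = character(), site_class = character(), wc_run = integer(),
    n_gu = integer(), n_mm = integer(), target_start = integer(),
    target_end = integer(), target_id = character(), flag = character(),
    column = integer(), stringsAsFactors = FALSE
  )
}

as_prediction_frame <- function(pred) {
  base <- empty_predictions()
  for (nm in setdiff(names(base), names(pred))) pred[[nm]] <- base[[nm]][NA_integer_][seq_len(nrow(pred))]
  pred[, PREDICTION_COLUMNS]
}

#' Write methylation predictions to TSV, GFF3 or JSON
#'
#' TSV columns: species, sRNA id, guide kind, molecule, 1-based position,
#' productive flag, significance mode, length of the Watson-Crick run covering
#' the +5 column, G:U and mismatch counts, duplex window, and the alignment
#' column when available.  GFF3 rows are 1-based inclusive point features of
#' type `2prime_O_methylation_site` on the target rRNA sequence id.  JSON
#' mirrors the TSV.
#'
#' @param predictions a prediction data.frame (see [predict_targets()]).
#' @param path output path.
#' @param format one of `"tsv"`, `"gff3"`, `"json"`.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path, format = c("tsv", "gff3", "json")) {
  format <- match.arg(format)
  pred <- as_prediction_frame(predictions)
  if (format == "tsv") {
    utils::write.table(pred, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
  } else if (format == "json") {
    jsonlite::write_json(pred, path, dataframe = "rows", na = "null",
                         auto_unbox = FALSE, digits = NA, pretty = TRUE)
  } else {
    con <- file(path, open = "wt")
    on.exit(close(con))
    writeLines("##gff-version 3", con)
    if (nrow(pred)) {
      seqid <- ifelse(is.na(pred$target_id) | !nzchar(pred$target_id),
                      paste(pred$species, pred$molecule, sep = "|"),
                      pred$target_id)
      attrs <- sprintf(
        "ID=%s;srna=%s;guide=%s;productive=%s;mode=%s;site_class=%s",
        paste0(pred$srna_id, ":", pred$guide_kind, ":", pred$position),
        pred$srna_id, pred$guide_kind,
        tolower(as.character(pred$productive)), pred$mode, pred$site_class
      )
      writeLines(sprintf(
        "%s\tcdguide\t2prime_O_methylation_site\t%d\t%d\t.\t+\t.\t%s",
        seqid, pred$position, pred$position, attrs
      ), con)
    }
  }
  invisible(path)
}

#' Read a prediction TSV written by [write_predictions()]
#'
#' @param path path to the TSV file.
#' @return A prediction data.frame with canonical column types.
#' @export
read_predictions <- function(path) {
  pred <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
  int_cols <- c("position", "wc_run", "n_gu", "n_mm",
                "target_start", "target_end", "column")
  for (nm in intersect(int_cols, names(pred))) pred[[nm]] <- as.integer(pred[[nm]])
  if ("productive" %in% names(pred)) pred$productive <- as.logical(pred$productive)
  chr_cols <- c("species", "srna_id", "guide_kind", "molecule", "mode",
                "site_class", "target_id", "flag")
  for (nm in intersect(chr_cols, names(pred))) pred[[nm]] <- as.character(pred[[nm]])
  if ("flag" %in% names(pred)) pred$flag[is.na(pred$flag)] <- ""
  as_prediction_frame(pred)
}
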