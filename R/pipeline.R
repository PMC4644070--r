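# Pipeline orchestration: annotate -> scan -> conserve, with config
# validation and a machine-readable summary report.

#' Validate a pipeline configuration
#'
#' The configuration is a YAML file (or an equivalent list) with:
#' \preformatted{
#' species:
#'   - abbreviation: Sp1
#'     srna: Sp1_srna.fasta
#'     rrna_16s: Sp1_rRNA_16S.fasta
#'     rrna_23s: Sp1_rRNA_23S.fasta
#' alignment:            # optional
#'   rRNA_16S: alignment_rRNA_16S.fasta
#'   rRNA_23S: alignment_rRNA_23S.fasta
#' structure:            # optional; dot-bracket (first line) or .ct files
#'   rRNA_16S: 16s.dbn
#' rules: {min_consecutive_wc: 9, max_mismatch: 1, max_gu: 2}   # optional
#' boxes: {max_mm_c: 1, max_mm_d: 0}                            # optional
#' output_dir: results
#' seed: 1
#' }
#' Relative paths are resolved against the directory of the config file.
#' All validation errors are collected and reported together.
#'
#' @param config path to a YAML config file, or a list of the same shape.
#' @param base_dir base directory for relative paths (defaults to the config
#'   file's directory, or the working directory for list input).
#' @return The validated config (list) with resolved paths, a `rules`
#'   [scan_rules()] object and a `box_params` [cd_params()] list.
#' @export
validate_config <- function(config, base_dir = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config, call. = FALSE)
    base_dir <- base_dir %||% dirname(normalizePath(config))
    cfg <- yaml::read_yaml(config)
  } else {
    cfg <- config
    base_dir <- base_dir %||% getwd()
  }
  errors <- character(0L)
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (!file.exists(p)) p <- file.path(base_dir, p)
    p
  }
  if (is.null(cfg$species) || !length(cfg$species)) {
    errors <- c(errors, "config has no species entries")
    cfg$species <- list()
  }
  abbrs <- character(0L)
  for (i in seq_along(cfg$species)) {
    entry <- cfg$species[[i]]
    ab <- entry$abbreviation
    if (is.null(ab) || !nzchar(ab)) {
      errors <- c(errors, sprintf("species entry %d: missing abbreviation", i))
      ab <- sprintf("<entry %d>", i)
    }
    if (ab %in% abbrs) errors <- c(errors, "duplicate species abbreviation: ", ab)
    abbrs <- c(abbrs, ab)
    if (is.null(entry$srna)) {
      errors <- c(errors, sprintf("species %s: missing field 'srna'", ab))
    } else {
      entry$srna <- resolve(entry$srna)
      if (!file.exists(entry$srna)) {
        errors <- c(errors, sprintf("species %s: sRNA FASTA not found: %s", ab, entry$srna))
      }
    }
    has_rrna <- FALSE
    for (f in c("rrna_16s", "rrna_23s")) {
      if (!is.null(entry[[f]])) {
        has_rrna <- TRUE
        entry[[f]] <- resolve(entry[[f]])
        if (!file.exists(entry[[f]])) {
          errors <- c(errors, sprintf("species %s: %s FASTA not found: %s", ab, f, entry[[f]]))
        }
      }
    }
    if (!has_rrna) errors <- c(errors, sprintf("species %s: no rRNA FASTA given", ab))
    cfg$species[[i]] <- entry
  }
  for (m in names(cfg$alignment)) {
    cfg$alignment[[m]] <- resolve(cfg$alignment[[m]])
    if (!file.exists(cfg$alignment[[m]])) {
      errors <- c(errors, sprintf("alignment %s not found: %s", m, cfg$alignment[[m]]))
    }
  }
  for (m in names(cfg$structure)) {
    cfg$structure[[m]] <- resolve(cfg$structure[[m]])
    if (!file.exists(cfg$structure[[m]])) {
      errors <- c(errors, sprintf("structure %s not found: %s", m, cfg$structure[[m]]))
    }
  }
  if (length(errors)) {
    stop("invalid pipeline config:\n  - ", paste(errors, collapse = "\n  - "),
         call. = FALSE)
  }
  cfg$rules <- do.call(scan_rules, as.list(cfg$rules))
  cfg$box_params <- do.call(cd_params, as.list(cfg$boxes))
  cfg$output_dir <- cfg$output_dir %||% "cdguide_out"
  if (!grepl("^(/|[A-Za-z]:)", cfg$output_dir)) {
    cfg$output_dir <- file.path(base_dir, cfg$output_dir)
  }
  cfg
}

read_structure_file <- function(path) {
  if (grepl("\\.ct$", path, ignore.case = TRUE)) return(read_ct(path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  db <- lines[grepl("^[.()]+$", trimws(lines))][1L]
  if (is.na(db)) stop("no dot-bracket line found in ", path, call. = FALSE)
  parse_dotbracket(trimws(db))
}

#' Run the full annotate -> scan -> conserve pipeline
#'
#' Deterministic given identical inputs and config.  Per species, every input
#' sRNA is either annotated (and its guides scanned) or written to the
#' rejected report; predictions are written as TSV, GFF3 and JSON.  When
#' alignments are configured, predictions are projected onto alignment
#' columns and the conservation, hotspot, redundancy and distant-target
#' summaries are written; otherwise the conservation stage is skipped with a
#' warning and per-species outputs are still produced.
#'
#' @param config path to a YAML config, or a config list (see
#'   [validate_config()]).
#' @param output_dir override for the configured output directory.
#' @return Invisibly, a list: `report` (summary counts; see below),
#'   `predictions` (all species), `conservation`, `guide_pairs`,
#'   `redundant_sites`, `chaperone_candidates`.  The report satisfies
#'   `n_significant = n_productive + n_nonproductive` and, per molecule,
#'   `n_positions = n_single + n_multi`.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  cfg <- validate_config(config)
  out <- output_dir %||% cfg$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  per_species <- list()
  all_preds <- list()
  all_classes <- list()
  column_maps <- list()
  for (entry in cfg$species) {
    sp <- entry$abbreviation
    srna_df <- read_rna_fasta(entry$srna, species = sp, molecule = "sRNA")
    rrnas <- list()
    if (!is.null(entry$rrna_16s)) {
      rrnas[["rRNA_16S"]] <- read_rna_fasta(entry$rrna_16s, sp, "rRNA_16S")$residues[[1L]]
    }
    if (!is.null(entry$rrna_23s)) {
      rrnas[["rRNA_23S"]] <- read_rna_fasta(entry$rrna_23s, sp, "rRNA_23S")$residues[[1L]]
    }
    ann <- lapply(seq_len(nrow(srna_df)), function(i) {
      annotate_cd_srna(srna_df[i, , drop = FALSE], params = cfg$box_params)
    })
    res <- predict_targets(ann, rrnas, cfg$rules, species = sp)
    rejected <- do.call(rbind, lapply(ann[vapply(ann, is_rejected, logical(1L))],
                                      function(r) data.frame(srna_id = r$id,
                                                             reason = r$reason,
                                                             stringsAsFactors = FALSE)))
    if (is.null(rejected)) {
      rejected <- data.frame(srna_id = character(), reason = character(),
                             stringsAsFactors = FALSE)
    }
    annotated <- do.call(rbind, lapply(ann[!vapply(ann, is_rejected, logical(1L))],
                                       function(s) {
      data.frame(srna_id = s$id, length = nchar(s$residues),
                 box_mismatches = s$score,
                 kturn_CD = s$kturn[["CD"]], kturn_CpDp = s$kturn[["CpDp"]],
                 boxes = paste(sprintf("%s:%d-%d", s$boxes$kind, s$boxes$start,
                                       s$boxes$end), collapse = ","),
                 stringsAsFactors = FALSE)
    }))
    utils::write.table(rejected, file.path(out, paste0(sp, "_rejected.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(annotated)) {
      utils::write.table(annotated, file.path(out, paste0(sp, "_annotated.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    write_predictions(res$predictions, file.path(out, paste0(sp, "_predictions.tsv")), "tsv")
    write_predictions(res$predictions, file.path(out, paste0(sp, "_predictions.gff3")), "gff3")
    write_predictions(res$predictions, file.path(out, paste0(sp, "_predictions.json")), "json")
    per_species[[sp]] <- res$summary
    all_preds[[sp]] <- res$predictions
    all_classes[[sp]] <- cbind(species = sp, res$srna_classes)
  }
  predictions <- do.call(rbind, all_preds)
  rownames(predictions) <- NULL

  conservation <- NULL
  hotspots <- NULL
  if (length(cfg$alignment)) {
    for (m in names(cfg$alignment)) {
      rows <- read_rna_alignment(cfg$alignment[[m]])
      for (sp in names(rows)) column_maps[[sp]][[m]] <- build_column_map(rows[[sp]], sp, m)
    }
    mapped <- map_to_alignment(predictions, column_maps)
    conservation <- conservation_summary(mapped)
    hotspots <- hotspot_profile(conservation$sites)
    utils::write.table(conservation$sites, file.path(out, "conservation_sites.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(hotspots, file.path(out, "hotspot_profile.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    predictions <- mapped
  } else {
    warning("no alignment configured; conservation stage skipped", call. = FALSE)
  }
  redundant <- find_redundant_sites(predictions)
  pairs <- classify_guide_pairs(predictions)
  utils::write.table(redundant, file.path(out, "redundant_sites.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(pairs, file.path(out, "guide_pairs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  chap <- NULL
  if (length(cfg$structure)) {
    structures <- lapply(cfg$structure, read_structure_file)
    chap <- chaperone_candidates(pairs, structures)
    utils::write.table(chap, file.path(out, "chaperone_candidates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  global <- Reduce(function(a, b) Map(`+`, a, b), per_species)
  report <- list(
    per_species = per_species,
    global = global,
    per_molecule = if (!is.null(conservation)) conservation$totals else NULL,
    ratios = if (!is.null(conservation)) conservation$ratios else NULL,
    n_double_distant = sum(pairs$classification == "double_distant"),
    identities_ok = with(global, n_significant == n_productive + n_nonproductive) &&
      (is.null(conservation) ||
         all(conservation$totals$n_positions ==
               conservation$totals$n_single + conservation$totals$n_multi))
  )
  jsonlite::write_json(report, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  invisible(list(report = report, predictions = predictions,
                 srna_classes = do.call(rbind, all_classes),
                 conservation = conservation, hotspots = hotspots,
                 redundant_sites = redundant, guide_pairs = pairs,
                 chaperone_candidates = chap))
}
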