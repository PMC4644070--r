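# Cross-species conservation mapping, hotspot profiling, within-species
# redundancy, and distant-target (chaperone candidate) detection.

#' Project predictions onto alignment columns
#'
#' Annotates each prediction with the alignment column of its species rRNA
#' position.  Predictions whose species/molecule has no map, or whose position
#' falls outside the map, get an `NA` column and are reported in the
#' `"unmappable"` attribute (with a warning); they are never silently dropped.
#'
#' @param predictions a prediction data.frame.
#' @param column_maps nested list `column_maps[[species]][[molecule]]` of
#'   [build_column_map()] objects.
#' @return The predictions with a filled `column` field; unmappable rows are
#'   attached as `attr(, "unmappable")`.
#' @export
map_to_alignment <- function(predictions, column_maps) {
  pred <- predictions
  pred$column <- NA_integer_
  for (i in seq_len(nrow(pred))) {
    m <- column_maps[[pred$species[i]]][[pred$molecule[i]]]
    if (!is.null(m) && pred$position[i] >= 1L &&
        pred$position[i] <= length(m$col_of_pos)) {
      pred$column[i] <- m$col_of_pos[[pred$position[i]]]
    }
  }
  un <- pred[is.na(pred$column), , drop = FALSE]
  if (nrow(un)) {
    warning(nrow(un), " prediction(s) could not be mapped to the alignment",
            call. = FALSE)
  }
  attr(pred, "unmappable") <- un
  pred
}

#' Per-column conservation summary of mapped predictions
#'
#' Aggregates alignment-mapped predictions per (molecule, column): the set of
#' species predicted modified there, the number of distinct species, and the
#' total number of guide interactions mapped there.  By default only
#' productive interactions are counted (non-productive site-mismatch duplexes
#' are excluded from conservation totals).
#'
#' @param mapped predictions with a `column` field (see [map_to_alignment()]).
#' @param productive_only count productive interactions only.
#' @return A list with
#'   \describe{
#'     \item{sites}{data.frame `molecule`, `column`, `species_hits`
#'       (comma-joined), `n_species`, `n_events`.}
#'     \item{totals}{data.frame per molecule: `n_events`, `n_positions`,
#'       `n_single` (columns hit in one species), `n_multi` (columns hit in
#'       two or more species); `n_positions = n_single + n_multi` always.}
#'     \item{ratios}{`multi_site_to_event_pct` (multi-species columns over
#'       total events, in percent) and `multi_site_pct` (multi-species columns
#'       over distinct columns).}
#'   }
#' @export
conservation_summary <- function(mapped, productive_only = TRUE) {
  pred <- mapped
  if (productive_only && nrow(pred)) pred <- pred[pred$productive, , drop = FALSE]
  dropped <- sum(is.na(pred$column))
  if (dropped) {
    message(dropped, " unmapped prediction(s) excluded from conservation totals")
    pred <- pred[!is.na(pred$column), , drop = FALSE]
  }
  if (!nrow(pred)) {
    sites <- data.frame(molecule = character(), column = integer(),
                        species_hits = character(), n_species = integer(),
                        n_events = integer(), stringsAsFactors = FALSE)
    totals <- data.frame(molecule = character(), n_events = integer(),
                         n_positions = integer(), n_single = integer(),
                         n_multi = integer(), stringsAsFactors = FALSE)
    return(list(sites = sites, totals = totals,
                ratios = list(multi_site_to_event_pct = NA_real_,
                              multi_site_pct = NA_real_)))
  }
  key <- interaction(pred$molecule, pred$column, drop = TRUE)
  sites <- do.call(rbind, lapply(split(pred, key), function(g) {
    sp <- sort(unique(g$species))
    data.frame(molecule = g$molecule[[1L]], column = g$column[[1L]],
               species_hits = paste(sp, collapse = ","),
               n_species = length(sp), n_events = nrow(g),
               stringsAsFactors = FALSE)
  }))
  sites <- sites[order(sites$molecule, sites$column), , drop = FALSE]
  rownames(sites) <- NULL
  totals <- do.call(rbind, lapply(split(sites, sites$molecule), function(g) {
    data.frame(molecule = g$molecule[[1L]],
               n_events = sum(g$n_events),
               n_positions = nrow(g),
               n_single = sum(g$n_species == 1L),
               n_multi = sum(g$n_species >= 2L),
               stringsAsFactors = FALSE)
  }))
  rownames(totals) <- NULL
  n_events_all <- sum(totals$n_events)
  n_multi_all <- sum(totals$n_multi)
  list(
    sites = sites, totals = totals,
    ratios = list(
      multi_site_to_event_pct = 100 * n_multi_all / n_events_all,
      multi_site_pct = 100 * n_multi_all / sum(totals$n_positions)
    )
  )
}

#' Windowed methylation-density (hotspot) profile
#'
#' For every alignment column, the density is the total number of methylation
#' events within a centred window (default 9 columns), truncated at the
#' alignment ends (no wraparound).  The profile is linear in the event set.
#'
#' @param x a `sites` data.frame from [conservation_summary()] (columns
#'   `molecule`, `column`, `n_events`), or mapped predictions (each row one
#'   event).
#' @param window odd window width in columns.
#' @param length_out named vector/list of profile lengths per molecule
#'   (defaults to the maximum observed column).
#' @return A data.frame `molecule`, `column`, `density`.
#' @export
hotspot_profile <- function(x, window = 9L, length_out = NULL) {
  if (window %% 2L != 1L) stop("window must be odd", call. = FALSE)
  if (!all(c("molecule", "column") %in% names(x))) {
    stop("x must have molecule and column fields", call. = FALSE)
  }
  ev <- x[!is.na(x$column), , drop = FALSE]
  if (!"n_events" %in% names(ev)) ev$n_events <- 1L
  h <- (window - 1L) %/% 2L
  out <- lapply(split(ev, ev$molecule), function(g) {
    len <- if (!is.null(length_out) && !is.null(length_out[[g$molecule[[1L]]]])) {
      as.integer(length_out[[g$molecule[[1L]]]])
    } else max(g$column)
    counts <- numeric(len)
    for (i in seq_len(nrow(g))) {
      counts[g$column[i]] <- counts[g$column[i]] + g$n_events[i]
    }
    cs <- c(0, cumsum(counts))
    cols <- seq_len(len)
    dens <- cs[pmin(cols + h, len) + 1L] - cs[pmax(cols - h - 1L, 0L) + 1L]
    data.frame(molecule = g$molecule[[1L]], column = cols, density = dens,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Find within-species redundant target sites
#'
#' Groups predictions of one or more species by (species, molecule, position)
#' in species coordinates and reports every site targeted by two or more
#' distinct sRNAs.
#'
#' @param predictions a prediction data.frame.
#' @param productive_only consider productive interactions only.
#' @return A data.frame `species`, `molecule`, `position`, `srna_ids`
#'   (slash-joined, sorted), `n_srnas`, sorted by molecule then position.
#' @export
find_redundant_sites <- function(predictions, productive_only = TRUE) {
  pred <- predictions
  if (productive_only && nrow(pred)) pred <- pred[pred$productive, , drop = FALSE]
  empty <- data.frame(species = character(), molecule = character(),
                      position = integer(), srna_ids = character(),
                      n_srnas = integer(), stringsAsFactors = FALSE)
  if (!nrow(pred)) return(empty)
  key <- interaction(pred$species, pred$molecule, pred$position, drop = TRUE)
  groups <- lapply(split(pred, key), function(g) {
    ids <- sort(unique(g$srna_id))
    if (length(ids) < 2L) return(NULL)
    data.frame(species = g$species[[1L]], molecule = g$molecule[[1L]],
               position = g$position[[1L]],
               srna_ids = paste(ids, collapse = "/"), n_srnas = length(ids),
               stringsAsFactors = FALSE)
  })
  groups <- do.call(rbind, groups)
  if (is.null(groups)) return(empty)
  groups <- groups[order(groups$species, groups$molecule, groups$position), ,
                   drop = FALSE]
  rownames(groups) <- NULL
  groups
}

#' Classify the two kept targets of double-guide sRNAs
#'
#' For every sRNA with two kept predictions, classifies the pair as
#' `double_local` (same molecule, site separation <= `threshold` nt,
#' inclusive), `double_distant` (same molecule, separation > `threshold`) or
#' `cross_molecule`.
#'
#' @param predictions a prediction data.frame.
#' @param threshold separation threshold in nucleotides (default 100).
#' @return A data.frame `species`, `srna_id`, `molecule_d`, `position_d`,
#'   `molecule_dprime`, `position_dprime`, `primary_distance` (NA across
#'   molecules), `classification`.
#' @export
classify_guide_pairs <- function(predictions, threshold = 100L) {
  empty <- data.frame(species = character(), srna_id = character(),
                      molecule_d = character(), position_d = integer(),
                      molecule_dprime = character(), position_dprime = integer(),
                      primary_distance = integer(), classification = character(),
                      stringsAsFactors = FALSE)
  if (!nrow(predictions)) return(empty)
  key <- interaction(predictions$species, predictions$srna_id, drop = TRUE)
  rows <- lapply(split(predictions, key), function(g) {
    d <- g[g$guide_kind == "D", , drop = FALSE]
    dp <- g[g$guide_kind == "Dprime", , drop = FALSE]
    if (!nrow(d) || !nrow(dp)) return(NULL)
    d <- d[1L, ]; dp <- dp[1L, ]
    if (d$molecule != dp$molecule) {
      dist <- NA_integer_; cls <- "cross_molecule"
    } else {
      dist <- abs(d$position - dp$position)
      cls <- if (dist <= threshold) "double_local" else "double_distant"
    }
    data.frame(species = d$species, srna_id = d$srna_id,
               molecule_d = d$molecule, position_d = d$position,
               molecule_dprime = dp$molecule, position_dprime = dp$position,
               primary_distance = dist, classification = cls,
               stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows)) return(empty)
  rows <- rows[order(rows$species, rows$srna_id), , drop = FALSE]
  rownames(rows) <- NULL
  rows
}

#' Parse a dot-bracket secondary structure into a pairing table
#'
#' @param db dot-bracket string over `.`, `(`, `)`.
#' @return Integer vector `pt` with `pt[i] = j` if i pairs j, 0 if unpaired.
#' @examples
#' parse_dotbracket("((((....))))")
#' @export
parse_dotbracket <- function(db) {
  chars <- strsplit(db, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% c(".", "(", ")"))
  if (length(bad)) {
    stop("unsupported dot-bracket character(s) at position(s): ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  pt <- integer(length(chars))
  stack <- integer(0L)
  for (i in seq_along(chars)) {
    if (chars[i] == "(") {
      stack <- c(stack, i)
    } else if (chars[i] == ")") {
      if (!length(stack)) stop("unbalanced dot-bracket: unmatched ')' at position ", i,
                               call. = FALSE)
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pt[i] <- j; pt[j] <- i
    }
  }
  if (length(stack)) stop("unbalanced dot-bracket: unmatched '(' at position(s) ",
                          paste(stack, collapse = ", "), call. = FALSE)
  pt
}

#' Read a CT (connectivity table) secondary-structure file
#'
#' Standard CT layout: a header line starting with the sequence length,
#' followed by one row per nucleotide whose fifth column is the pairing
#' partner (0 if unpaired).
#'
#' @param path path to a CT file.
#' @return Integer pairing vector as in [parse_dotbracket()].
#' @export
read_ct <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  n <- as.integer(strsplit(trimws(lines[[1L]]), "\\s+")[[1L]][[1L]])
  if (is.na(n) || length(lines) < n + 1L) stop("malformed CT file: ", path, call. = FALSE)
  body <- utils::read.table(text = lines[2:(n + 1L)], stringsAsFactors = FALSE)
  pt <- as.integer(body[[5L]])
  if (length(pt) != n) stop("malformed CT file: ", path, call. = FALSE)
  pt
}

structure_graph <- function(pt) {
  n <- length(pt)
  backbone <- cbind(seq_len(n - 1L), seq.int(2L, n))
  paired <- which(pt > seq_along(pt))
  edges <- rbind(backbone, cbind(paired, pt[paired]))
  igraph::graph_from_edgelist(edges, directed = FALSE)
}

#' Graph distance between two nucleotides in a secondary structure
#'
#' Shortest path length in the graph whose nodes are nucleotides and whose
#' edges are backbone adjacencies (i, i+1) and base pairs (i, j).  This is a
#' metric on the molecule: positions on the two strands of one helix are one
#' edge apart however far they sit in the primary sequence.
#'
#' @param pt pairing vector from [parse_dotbracket()] or [read_ct()].
#' @param pos_a,pos_b 1-based nucleotide positions.
#' @return Integer path length.
#' @export
structure_distance <- function(pt, pos_a, pos_b) {
  n <- length(pt)
  if (any(c(pos_a, pos_b) < 1L) || any(c(pos_a, pos_b) > n)) {
    stop("positions must lie in 1..", n, call. = FALSE)
  }
  g <- structure_graph(pt)
  as.integer(igraph::distances(g, v = pos_a, to = pos_b)[1L, 1L])
}

#' Filter distant-target calls to RNA chaperone candidates
#'
#' A chaperone candidate is a `double_distant` call (two targets far apart in
#' the primary sequence) whose two sites are nevertheless close in secondary
#' structure space.  Without a structure for the molecule, all
#' `double_distant` calls are returned with `structure_distance = NA` and a
#' warning (degraded mode).
#'
#' @param calls output of [classify_guide_pairs()].
#' @param structures named list of pairing vectors per molecule
#'   (e.g. `list(rRNA_16S = pt)`), or `NULL`.
#' @param max_struct_dist maximum structure-graph distance (edges) for a
#'   candidate.
#' @return The `double_distant` subset of `calls` with a `structure_distance`
#'   column, filtered to `structure_distance <= max_struct_dist` where a
#'   structure is available.
#' @export
chaperone_candidates <- function(calls, structures = NULL, max_struct_dist = 10L) {
  dd <- calls[calls$classification == "double_distant", , drop = FALSE]
  dd$structure_distance <- NA_integer_
  if (!nrow(dd)) return(dd)
  keep <- rep(TRUE, nrow(dd))
  missing_structure <- FALSE
  for (i in seq_len(nrow(dd))) {
    pt <- structures[[dd$molecule_d[i]]]
    if (is.null(pt)) {
      missing_structure <- TRUE
      next
    }
    dd$structure_distance[i] <-
      structure_distance(pt, dd$position_d[i], dd$position_dprime[i])
    keep[i] <- dd$structure_distance[i] <= max_struct_dist
  }
  if (missing_structure) {
    warning("no secondary structure for one or more molecules; ",
            "returning those double_distant calls unfiltered", call. = FALSE)
  }
  out <- dd[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
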