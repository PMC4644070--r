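# Independent oracle implementations used to cross-check the package.
# These deliberately use different code paths (rle-based run finding,
# queue-based BFS, naive window enumeration) from the implementation.

oracle_classify <- function(a, b) {
  if ((a == "A" && b == "U") || (a == "U" && b == "A") ||
      (a == "G" && b == "C") || (a == "C" && b == "G")) return("WC")
  if ((a == "G" && b == "U") || (a == "U" && b == "G")) return("GU")
  "MM"
}

# brute-force duplex scan: enumerate every window, classify every pair,
# find the maximal pairing run containing the +5 column via rle (the +5
# column acts as a wildcard; run length counts actual pairing positions)
oracle_scan <- function(guide, p5, rrna, min_run = 9L, max_mm = 1L, max_gu = 2L,
                        mode = "strict", gu_in_run = TRUE, relaxed_max_mm = 1L) {
  g <- strsplit(guide, "")[[1]]
  r <- strsplit(rrna, "")[[1]]
  L <- length(g)
  out <- NULL
  for (s in seq_len(length(r) - L + 1L)) {
    cls <- vapply(seq_len(L), function(i) oracle_classify(g[i], r[s + L - i]),
                  character(1))
    n_mm <- sum(cls == "MM"); n_gu <- sum(cls == "GU")
    pairing <- if (mode == "strict") cls == "WC" else
      cls == "WC" | (gu_in_run & cls == "GU")
    q <- pairing
    q[p5] <- TRUE  # site column is exempt from the pairing requirement
    rl <- rle(q)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    k <- which(rl$values & starts <= p5 & ends >= p5)
    run <- if (length(k)) sum(pairing[starts[k]:ends[k]]) else 0L
    sig <- if (mode == "strict") {
      run >= min_run && n_mm <= max_mm && n_gu <= max_gu
    } else {
      run >= min_run && n_mm <= relaxed_max_mm
    }
    if (sig) {
      out <- rbind(out, data.frame(
        target_start = s, target_end = s + L - 1L, position = s + (L - p5),
        site_class = cls[p5], wc_run = run, n_mm = n_mm, n_gu = n_gu,
        stringsAsFactors = FALSE))
    }
  }
  if (is.null(out)) {
    out <- data.frame(target_start = integer(), target_end = integer(),
                      position = integer(), site_class = character(),
                      wc_run = integer(), n_mm = integer(), n_gu = integer(),
                      stringsAsFactors = FALSE)
  }
  out
}

# naive box-motif enumeration
oracle_find_boxes <- function(seq, consensus, max_mm) {
  sets <- list(A = "A", C = "C", G = "G", U = "U", R = c("A", "G"))
  k <- strsplit(consensus, "")[[1]]
  s <- strsplit(seq, "")[[1]]
  L <- length(k)
  res <- NULL
  if (length(s) < L) return(res)
  for (i in seq_len(length(s) - L + 1L)) {
    mm <- 0L
    for (j in seq_len(L)) if (!s[i + j - 1L] %in% sets[[k[j]]]) mm <- mm + 1L
    if (mm <= max_mm) res <- rbind(res, data.frame(start = i, mismatches = mm))
  }
  res
}

# queue-based breadth-first search on the nucleotide graph
oracle_bfs <- function(pt, a, b) {
  n <- length(pt)
  adj <- vector("list", n)
  for (i in seq_len(n)) {
    nb <- integer(0)
    if (i > 1L) nb <- c(nb, i - 1L)
    if (i < n) nb <- c(nb, i + 1L)
    if (pt[i] > 0L) nb <- c(nb, pt[i])
    adj[[i]] <- nb
  }
  dist <- rep(NA_integer_, n)
  dist[a] <- 0L
  queue <- a
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    if (v == b) return(dist[v])
    for (w in adj[[v]]) {
      if (is.na(dist[w])) {
        dist[w] <- dist[v] + 1L
        queue <- c(queue, w)
      }
    }
  }
  dist[b]
}

# random nested secondary structure (grammar: S -> .S | (S)S | "")
random_structure <- function(n) {
  build <- function(m) {
    if (m <= 0L) return("")
    if (m == 1L || stats::runif(1) < 0.5) return(paste0(".", build(m - 1L)))
    k <- sample(0:(m - 2L), 1L)
    paste0("(", build(k), ")", build(m - 2L - k))
  }
  build(n)
}

# random RNA string
random_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n, replace = TRUE),
                                collapse = "")

# plant revcomp(guide) into rrna at offset s, optionally perturbing positions
plant_window <- function(rrna, guide, s, perturb = integer(0)) {
  win <- strsplit(revcomp_rna(guide), "")[[1]]
  for (p in perturb) win[p] <- sample(setdiff(c("A", "C", "G", "U"), win[p]), 1L)
  r <- strsplit(rrna, "")[[1]]
  r[s:(s + length(win) - 1L)] <- win
  paste(r, collapse = "")
}

# duplex with prescribed pair classes: guide all G, window chosen per class
# (WC -> C, GU -> U, MM -> G), used to exercise significance calls directly
make_duplex <- function(classes, p5) {
  L <- length(classes)
  window_rev <- vapply(classes, function(cl) switch(cl, WC = "C", GU = "U", MM = "G"),
                       character(1))
  window <- paste(rev(window_rev), collapse = "")
  pair_guide_window(strrep("G", L), window, plus5_offset = p5)
}
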