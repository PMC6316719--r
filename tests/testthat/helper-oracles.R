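# Independent brute-force oracles used by the tests. These deliberately do
# not share code with the package scanners.

random_dna <- function(n, prob = rep(0.25, 4)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
        collapse = "")
}

# every (start, stop) ORF on the forward strand of a LINEAR sequence by
# walking every position and frame
oracle_orfs_linear <- function(s, min_aa = 45, starts = c("ATG", "GTG", "TTG")) {
  n <- nchar(s)
  stops <- c("TAA", "TAG", "TGA")
  hits <- list()
  for (i in seq_len(n - 2)) {
    if (!substr(s, i, i + 2) %in% starts) next
    j <- i + 3
    while (j + 2 <= n) {
      cod <- substr(s, j, j + 2)
      if (cod %in% stops) {
        aa <- (j - i) / 3
        if (aa >= min_aa) {
          hits[[length(hits) + 1]] <- data.frame(start = i, end = j + 2,
                                                 length_aa = aa)
        }
        break
      }
      j <- j + 3
    }
  }
  if (!length(hits)) {
    return(data.frame(start = integer(), end = integer(),
                      length_aa = integer()))
  }
  h <- do.call(rbind, hits)
  # maximal ORF per stop: the most-upstream qualifying start
  h <- h[order(h$end, h$start), ]
  h[!duplicated(h$end), ]
}

# best RBS placement by brute force: every offset of the template over the
# window, every contiguous stretch bounded by matches with <= max_mm internal
# mismatches; ranked by net pairing, then mismatches, then spacing
oracle_rbs <- function(win, model = sd_model()) {
  tmpl <- strsplit(model$template_dna, "")[[1]]
  m <- length(tmpl)
  wc <- strsplit(win, "")[[1]]
  W <- length(wc)
  best <- NULL
  for (o in seq_len(W - m + 1)) {
    seg <- wc[o:(o + m - 1)]
    matched <- seg == tmpl
    spacing <- W - (o + model$anchor_index - 1) - 1
    if (spacing < model$spacing_range[1] ||
        spacing > model$spacing_range[2]) next
    idx <- which(matched)
    for (i in idx) for (j in idx[idx >= i]) {
      mm <- sum(!matched[i:j])
      if (mm > model$max_mismatch) next
      np <- sum(matched[i:j])
      core_hit <- sum(intersect(which(matched), model$core) %in% i:j)
      if (core_hit < model$min_core_paired) next
      if (np < model$weak_min_paired) next
      cand <- list(net = np - mm, np = np, mm = mm, spacing = spacing,
                   o = o, i = i, j = j)
      if (is.null(best) || cand$net > best$net ||
          (cand$net == best$net && cand$mm < best$mm) ||
          (cand$net == best$net && cand$mm == best$mm &&
           cand$spacing < best$spacing)) {
        best <- cand
      }
    }
  }
  best
}

# exhaustive hairpin + U-tract enumeration on a short linear sequence
oracle_hairpins <- function(s, min_stem = 4, max_stem = 15,
                            loop_range = c(3, 10), max_mismatch = 1,
                            min_u = 3, u_window = 8, allow_gu = TRUE) {
  ch <- strsplit(chartr("T", "U", s), "")[[1]]
  n <- length(ch)
  pairs <- function(x, y) {
    wc <- c(A = "U", C = "G", G = "C", U = "A")[x] == y
    if (allow_gu) wc | (x == "G" & y == "U") | (x == "U" & y == "G") else wc
  }
  out <- list()
  for (a in seq_len(n)) {
    for (stem in min_stem:max_stem) {
      for (loop in loop_range[1]:loop_range[2]) {
        e <- a + 2 * stem + loop - 1
        if (e + u_window > n) next
        arm5 <- ch[a:(a + stem - 1)]
        arm3 <- ch[(e - stem + 1):e]
        p <- pairs(arm5, rev(arm3))
        if (!p[1] || !p[stem] || sum(!p) > max_mismatch) next
        tract <- paste(ch[(e + 1):(e + u_window)], collapse = "")
        if (u_tract_score(tract, u_window) < min_u) next
        dg <- hairpin_energy(paste(arm5, collapse = ""),
                             paste(arm3, collapse = ""), loop)
        if (dg >= 0) next
        out[[length(out) + 1]] <- data.frame(start = a, end = e,
                                             stem_len = stem,
                                             loop_len = loop, dg = dg)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(), end = integer(),
                      stem_len = integer(), loop_len = integer(),
                      dg = numeric()))
  }
  do.call(rbind, out)
}

# longest U-run with at most one single-base interruption, by enumerating
# every substring
oracle_u_tract <- function(seq, window = 8) {
  s <- strsplit(chartr("U", "T", toupper(substr(seq, 1, window))), "")[[1]]
  n <- length(s)
  best <- 0
  for (i in seq_len(n)) for (j in i:n) {
    sub <- s[i:j]
    if (sub[1] != "T" || sub[length(sub)] != "T") next
    non_t <- which(sub != "T")
    if (length(non_t) > 1) next
    best <- max(best, sum(sub == "T"))
  }
  best
}

# per-base walk of a circular span
oracle_span <- function(start, end, L) {
  p <- start
  n <- 1
  while (p != end) {
    p <- if (p == L) 1 else p + 1
    n <- n + 1
  }
  n
}

# coverage of a set of (possibly wrapping) intervals via a position bitmap
oracle_coverage <- function(starts, ends, L) {
  hit <- logical(L)
  for (k in seq_along(starts)) {
    s <- starts[k]; e <- ends[k]
    pos <- if (s <= e) s:e else c(s:L, 1:e)
    hit[pos] <- TRUE
  }
  100 * sum(hit) / L
}
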