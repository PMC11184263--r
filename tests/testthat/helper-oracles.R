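# Independent brute-force oracles. These deliberately avoid the code
# paths (and where possible the libraries) used by the implementation:
# plain string ops, explicit loops and textbook definitions only.

# N50 by definition: the largest length L present such that sequences of
# length >= L hold at least half the total bases.
oracle_n50 <- function(lens) {
  total <- sum(lens)
  sorted <- sort(lens, decreasing = TRUE)
  cum <- 0
  for (l in sorted) {
    cum <- cum + l
    if (cum >= total / 2) return(l)
  }
}

.codon_table <- local({
  bases <- c("T", "C", "A", "G")
  aas <- strsplit(paste0(
    "FFLLSSSSYY**CC*W", "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR", "VVVVAAAADDEEGGGG"), "")[[1]]
  # codon order: first base slowest, third fastest, bases in TCAG order
  codons <- c(sapply(bases, function(b1)
    sapply(bases, function(b2) paste0(b1, b2, bases))))
  setNames(aas, codons)
})

oracle_revcomp <- function(s) {
  comp <- chartr("ACGTN", "TGCAN", s)
  paste(rev(strsplit(comp, "")[[1]]), collapse = "")
}

oracle_translate_frame <- function(s, frame) {
  str <- if (frame > 0) s else oracle_revcomp(s)
  off <- abs(frame)
  n <- nchar(str)
  ncod <- (n - off + 1) %/% 3
  if (ncod < 1) return("")
  out <- character(ncod)
  for (i in seq_len(ncod)) {
    codon <- substr(str, off + 3 * (i - 1), off + 3 * i - 1)
    out[i] <- if (grepl("N", codon)) "X" else .codon_table[[codon]]
  }
  paste(out, collapse = "")
}

oracle_six_frames <- function(s) {
  fr <- c(1, 2, 3, -1, -2, -3)
  setNames(vapply(fr, function(f) oracle_translate_frame(s, f),
                  character(1)),
           c("+1", "+2", "+3", "-1", "-2", "-3"))
}

# Exhaustive ORF enumeration over the six frames.
oracle_longest_orf <- function(s, allow_partial = TRUE, min_codons = 30) {
  L <- nchar(s)
  best <- NULL
  rank <- 0
  for (f in c(1, 2, 3, -1, -2, -3)) {
    rank <- rank + 1
    pep <- oracle_translate_frame(s, f)
    aa <- strsplit(pep, "")[[1]]
    if (length(aa) == 0) next
    stops <- c(which(aa == "*"), length(aa) + 1)
    run_start <- 1
    for (st in stops) {
      if (st > run_start) {
        run <- run_start:(st - 1)
        starts <- c()
        m <- which(aa[run] == "M")
        if (length(m) > 0) starts <- run[m[1]]
        if (allow_partial && run_start == 1) starts <- unique(c(1, starts))
        for (a0 in starts) {
          plen <- st - a0
          if (plen < min_codons) next
          off <- abs(f)
          nt_s_local <- off + 3 * (a0 - 1)
          nt_e_local <- off + 3 * (st - 1) - 1
          if (f > 0) { nt_s <- nt_s_local; nt_e <- nt_e_local }
          else { nt_s <- L - nt_e_local + 1; nt_e <- L - nt_s_local + 1 }
          cand <- list(frame = f, nt_start = nt_s, nt_end = nt_e,
                       peptide = paste(aa[a0:(st - 1)], collapse = ""),
                       has_start_codon = aa[a0] == "M",
                       len = plen, rank = rank)
          if (is.null(best) || cand$len > best$len ||
              (cand$len == best$len && cand$rank < best$rank) ||
              (cand$len == best$len && cand$rank == best$rank &&
               cand$nt_start < best$nt_start))
            best <- cand
        }
      }
      run_start <- st + 1
    }
  }
  if (is.null(best)) return(NULL)
  best$len <- NULL; best$rank <- NULL
  best
}

# Double-loop reciprocal-best-hit oracle.
oracle_rbh <- function(ab, ba) {
  best_of <- function(hits, q) {
    rows <- hits[hits$qseqid == q, , drop = FALSE]
    if (nrow(rows) == 0) return(NA_character_)
    rows <- rows[order(-rows$bitscore, rows$evalue, rows$sseqid), ,
                 drop = FALSE]
    rows$sseqid[1]
  }
  pairs <- list()
  for (a in sort(unique(ab$qseqid))) {
    b <- best_of(ab, a)
    if (!is.na(b) && identical(best_of(ba, b), a))
      pairs[[length(pairs) + 1]] <- c(a, b)
  }
  if (length(pairs) == 0)
    return(data.frame(gene_a = character(), gene_b = character(),
                      stringsAsFactors = FALSE))
  data.frame(gene_a = vapply(pairs, `[`, character(1), 1),
             gene_b = vapply(pairs, `[`, character(1), 2),
             stringsAsFactors = FALSE)
}

# Exact one-sided hypergeometric upper-tail probability via choose().
oracle_hyper_upper <- function(q, m, n, k) {
  i <- q:min(m, k)
  sum(choose(m, i) * choose(n, k - i)) / choose(m + n, k)
}

# Textbook Benjamini-Hochberg step-up rejections at level alpha.
oracle_bh_reject <- function(p, alpha) {
  n <- length(p)
  ord <- order(p)
  thresh <- alpha * seq_len(n) / n
  below <- which(p[ord] <= thresh)
  reject <- logical(n)
  if (length(below) > 0) reject[ord[seq_len(max(below))]] <- TRUE
  reject
}

# All-pairs leaf distances on a phylo by DFS over the edge list.
oracle_tip_distances <- function(tree) {
  n <- length(tree$tip.label)
  nn <- max(tree$edge)
  adj <- vector("list", nn)
  for (e in seq_len(nrow(tree$edge))) {
    a <- tree$edge[e, 1]; b <- tree$edge[e, 2]
    w <- tree$edge.length[e]
    adj[[a]] <- rbind(adj[[a]], c(b, w))
    adj[[b]] <- rbind(adj[[b]], c(a, w))
  }
  dist_from <- function(src) {
    d <- rep(NA_real_, nn)
    d[src] <- 0
    queue <- src
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      for (r in seq_len(nrow(adj[[v]] %||% matrix(nrow = 0, ncol = 2)))) {
        u <- adj[[v]][r, 1]; w <- adj[[v]][r, 2]
        if (is.na(d[u])) { d[u] <- d[v] + w; queue <- c(queue, u) }
      }
    }
    d
  }
  out <- matrix(0, n, n)
  for (i in seq_len(n)) out[i, ] <- dist_from(i)[seq_len(n)]
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random fixture builders ---------------------------------------------

random_hit_tables <- function(n_a = 5, n_b = 5, n_hits = 12) {
  a_ids <- paste0("a", seq_len(n_a))
  b_ids <- paste0("b", seq_len(n_b))
  mk <- function(qs, ss) {
    hit_table(qseqid = sample(qs, n_hits, replace = TRUE),
              sseqid = sample(ss, n_hits, replace = TRUE),
              bitscore = sample(50:300, n_hits, replace = TRUE),
              evalue = 10^-sample(5:50, n_hits, replace = TRUE))
  }
  list(ab = mk(a_ids, b_ids), ba = mk(b_ids, a_ids))
}

random_tree <- function(n_tips) {
  tr <- ape::rtree(n_tips, rooted = FALSE,
                   tip.label = paste0("S", seq_len(n_tips), "_g",
                                      seq_len(n_tips)))
  tr$edge.length <- round(runif(nrow(tr$edge), 0.1, 5), 3)
  tr
}
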