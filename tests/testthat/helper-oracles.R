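# Independent brute-force oracles used by the property and acceptance
# tests.  These deliberately re-derive every quantity with naive loops,
# not by calling the implementation under test.

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

# every window on both strands with Hamming distance <= max_mm
oracle_scan <- function(query, contig_name, contig, max_mm) {
  m <- nchar(query)
  L <- nchar(contig)
  rows <- list()
  gch <- strsplit(contig, "")[[1]]
  for (strand in c("+", "-")) {
    q <- if (strand == "+") query else oracle_revcomp(query)
    qch <- strsplit(q, "")[[1]]
    for (s in seq_len(L - m + 1)) {
      mm <- sum(gch[s:(s + m - 1)] != qch)
      if (mm <= max_mm)
        rows[[length(rows) + 1]] <- data.frame(
          contig = contig_name, start = s - 1L, end = s - 1L + m,
          strand = strand, mismatches = mm, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(contig = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      mismatches = integer(0)))
  out <- do.call(rbind, rows)
  out[order(out$contig, out$start, out$strand), , drop = FALSE]
}

# naive per-position expectation of one alignment column layout
oracle_col_pen <- function(mb, tb, pos) {
  base <- if (tb == chartr("ACGT", "TGCA", mb)) 0
  else if ((mb == "G" && tb == "T") || (mb == "T" && tb == "G")) 0.5
  else 1.0
  if (pos >= 2 && pos <= 13) base * 2 else base
}

# exhaustive enumeration of all ungapped and single-gap duplexes with
# expectation <= max_exp; same conventions as the documented interface
oracle_duplexes <- function(mirna, cds, max_exp) {
  mch <- strsplit(mirna, "")[[1]]
  cch <- strsplit(cds, "")[[1]]
  m <- length(mch); n <- length(cch)
  rows <- list()
  add <- function(start, end, n_gaps, pen) {
    if (pen <= max_exp)
      rows[[length(rows) + 1]] <<- data.frame(
        start = start, end = end, n_gaps = n_gaps, expectation = pen)
  }
  gap_pen <- function(pos) if (pos >= 2 && pos <= 13) 4.0 else 2.0
  # ungapped
  for (s in 0:(n - m)) {
    pen <- 0
    for (i in 1:m) pen <- pen + oracle_col_pen(mch[i], cch[s + m - i + 1], i)
    add(s, s + m, 0L, pen)
  }
  # gap on the target side at miRNA position g (window m-1)
  if (n >= m - 1) for (s in 0:(n - (m - 1))) {
    for (g in 1:m) {
      pen <- gap_pen(g)
      t <- s + m - 1          # 1-based index of window's 3'-most base
      for (i in 1:m) {
        if (i == g) next
        pen <- pen + oracle_col_pen(mch[i], cch[t], i)
        t <- t - 1
      }
      add(s, s + m - 1, 1L, pen)
    }
  }
  # inserted target base between miRNA positions g and g+1 (window m+1)
  if (n >= m + 1) for (s in 0:(n - (m + 1))) {
    for (g in 1:(m - 1)) {
      pen <- gap_pen(g + 1)
      t <- s + m + 1
      for (i in 1:m) {
        pen <- pen + oracle_col_pen(mch[i], cch[t], i)
        t <- t - 1
        if (i == g) t <- t - 1       # skip the inserted base
      }
      add(s, s + m + 1, 1L, pen)
    }
  }
  if (!length(rows))
    return(data.frame(start = integer(0), end = integer(0),
                      n_gaps = integer(0), expectation = numeric(0)))
  do.call(rbind, rows)
}

# documented locus selection: best expectation first (ties: smaller
# start, fewer gaps), greedily non-overlapping
oracle_select <- function(dups) {
  dups <- dups[order(dups$expectation, dups$start, dups$n_gaps), ,
               drop = FALSE]
  chosen <- dups[0, ]
  for (i in seq_len(nrow(dups))) {
    ok <- TRUE
    if (nrow(chosen)) {
      for (j in seq_len(nrow(chosen))) {
        if (dups$start[i] < chosen$end[j] && chosen$start[j] < dups$end[i]) {
          ok <- FALSE
          break
        }
      }
    }
    if (ok) chosen <- rbind(chosen, dups[i, ])
  }
  chosen <- chosen[order(chosen$start), , drop = FALSE]
  rownames(chosen) <- NULL
  chosen
}

# MRCA ages by explicit root paths
oracle_pair_times <- function(tree) {
  ntip <- length(tree$tip.label)
  parent <- integer(max(tree$edge))
  elen <- numeric(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  elen[tree$edge[, 2]] <- tree$edge.length
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  path <- function(node) {
    p <- node
    while (node != root) {
      node <- parent[node]
      p <- c(p, node)
    }
    p
  }
  depth <- function(node) {
    d <- 0
    while (node != root) {
      d <- d + elen[node]
      node <- parent[node]
    }
    d
  }
  h <- max(vapply(seq_len(ntip), depth, numeric(1)))
  tm <- matrix(0, ntip, ntip,
               dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(ntip)) for (j in seq_len(ntip)) {
    if (i == j) next
    anc <- intersect(path(i), path(j))[1]
    tm[i, j] <- h - depth(anc)
  }
  tm
}

# all permutations of 1..n (n small)
all_perms <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- all_perms(n - 1)
  out <- NULL
  for (k in 1:n) {
    block <- cbind(k, matrix((1:n)[-k][sub], nrow(sub)))
    out <- rbind(out, block)
  }
  out
}

oracle_spearman_p <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  obs <- abs(cor(rx, ry))
  P <- all_perms(length(y))
  r <- apply(P, 1, function(p) cor(rx, ry[p]))
  mean(abs(r) >= obs - 1e-12)
}

# brute-force network statistics from raw tables
oracle_incoming <- function(targeting, gene_ids) {
  sapply(gene_ids, function(g)
    list(unique(targeting$mirna_id[targeting$gene_id == g])))
}

oracle_unique_shared <- function(targeting, gene_ids, mirnas) {
  inc <- oracle_incoming(targeting, gene_ids)
  do.call(rbind, lapply(mirnas, function(m) {
    targ <- unique(targeting$gene_id[targeting$mirna_id == m])
    data.frame(mirna_id = m,
               n_unique = sum(vapply(targ, function(g)
                 length(inc[[g]]) == 1, logical(1))),
               n_shared = sum(vapply(targ, function(g)
                 length(inc[[g]]) >= 2, logical(1))),
               stringsAsFactors = FALSE)
  }))
}

oracle_sharing <- function(targeting, genes, relation) {
  inc <- oracle_incoming(targeting, genes$gene_id)
  share <- c(); ident <- c()
  n_pairs <- 0L
  for (i in seq_len(nrow(genes) - 1)) for (j in (i + 1):nrow(genes)) {
    if (genes$family_id[i] != genes$family_id[j]) next
    rel <- if (genes$species[i] == genes$species[j]) "paralog" else "ortholog"
    if (rel != relation) next
    a <- inc[[genes$gene_id[i]]]; b <- inc[[genes$gene_id[j]]]
    if (length(a) == 0 && length(b) == 0) next
    n_pairs <- n_pairs + 1L
    share <- c(share, length(intersect(a, b)) > 0)
    ident <- c(ident, setequal(a, b) && length(a) > 0)
  }
  list(n_pairs = n_pairs,
       frac_share_any = if (n_pairs) mean(share) else NA_real_,
       frac_identical = if (n_pairs) mean(ident) else NA_real_)
}

# longest colinear homologous run between two ordered gene lists, by
# explicit diagonal extension from every start pair
oracle_max_run <- function(la, lb, homset) {
  best <- 0L
  for (i in seq_along(la)) for (j in seq_along(lb)) {
    run <- 0L
    while (i + run <= length(la) && j + run <= length(lb) &&
           paste(la[i + run], lb[j + run]) %in% homset)
      run <- run + 1L
    best <- max(best, run)
  }
  best
}

# random ultrametric tree helper (coalescent times rescaled to depth)
random_chronogram <- function(ntip, depth) {
  tr <- ape::rcoal(ntip)
  tr$edge.length <- tr$edge.length / max(ape::node.depth.edgelength(tr)) * depth
  tr
}

# random targeting-network fixture (<= 30 nodes)
random_network_tables <- function() {
  n_mir <- sample(2:4, 1)
  n_fam <- sample(2:4, 1)
  mirnas <- sprintf("m%d", seq_len(n_mir))
  genes <- do.call(rbind, lapply(seq_len(n_fam), function(f) {
    sz <- sample(1:3, 1)
    do.call(rbind, lapply(seq_len(sz), function(g)
      data.frame(gene_id = sprintf("%s_f%d_g%d", c("spA", "spB"), f, g),
                 species = c("spA", "spB"),
                 family_id = sprintf("f%d", f), stringsAsFactors = FALSE)))
  }))
  edges <- expand.grid(mirna_id = mirnas, gene_id = genes$gene_id,
                       stringsAsFactors = FALSE)
  edges <- edges[runif(nrow(edges)) < 0.3, , drop = FALSE]
  edges$expectation <- round(runif(nrow(edges), 0, 3) * 2) / 2
  list(genes = genes, sites = edges, mirnas = mirnas)
}
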