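# In-silico identification of family loci: mismatch genome scan, flanking
# window extraction, folding + deterministic trimming, structural
# validation, and miR* localisation.

#' Scan a genome for mature miRNA matches
#'
#' Reports every window on both strands whose Hamming distance to the
#' query is at most `max_mismatches` (ungapped matches only).
#'
#' @param query mature miRNA sequence(s), 20-24 nt; a named character
#'   vector (names become `query_id`).  U is treated as T.
#' @param genome named character vector of contig sequences.
#' @param max_mismatches maximum Hamming distance per hit (default 3).
#' @return data.frame (`query_id`, `contig`, `start`, `end`, `strand`,
#'   `mismatches`), 0-based half-open forward-strand spans, sorted by
#'   (contig, start, strand).
#' @export
scan_genome <- function(query, genome, max_mismatches = 3) {
  if (is.null(names(query)))
    names(query) <- sprintf("query%d", seq_along(query))
  query <- vapply(query, norm_seq, character(1), what = "query")
  qlen <- nchar(query)
  if (any(qlen < 20 | qlen > 24))
    stop("query length must be 20-24 nt", call. = FALSE)
  if (length(genome) == 0) return(empty_hits())
  if (is.null(names(genome)))
    names(genome) <- sprintf("contig%d", seq_along(genome))
  genome <- vapply(genome, norm_seq, character(1), what = "genome")
  out <- list()
  for (ctg in names(genome)) {
    g <- utf8ToInt(genome[[ctg]])
    L <- length(g)
    for (qid in names(query)) {
      m <- qlen[[qid]]
      if (L < m) next
      n_win <- L - m + 1L
      for (strand in c("+", "-")) {
        qs <- if (strand == "+") query[[qid]] else revcomp(query[[qid]])
        qi <- utf8ToInt(qs)
        mm <- integer(n_win)
        for (i in seq_len(m))
          mm <- mm + (g[i:(i + n_win - 1L)] != qi[i])
        keep <- which(mm <= max_mismatches)
        if (length(keep))
          out[[length(out) + 1]] <- data.frame(
            query_id = qid, contig = ctg, start = keep - 1L,
            end = keep - 1L + m, strand = strand,
            mismatches = mm[keep], stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) return(empty_hits())
  hits <- do.call(rbind, out)
  hits <- hits[order(hits$contig, hits$start, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

empty_hits <- function() {
  data.frame(query_id = character(0), contig = character(0),
             start = integer(0), end = integer(0), strand = character(0),
             mismatches = integer(0), stringsAsFactors = FALSE)
}

# merge hits of different queries that map to the same locus (identical
# contig/span/strand), keeping the query with fewest mismatches
merge_duplicate_loci <- function(hits) {
  if (nrow(hits) == 0) return(hits)
  key <- paste(hits$contig, hits$start, hits$end, hits$strand)
  hits <- hits[order(key, hits$mismatches), , drop = FALSE]
  hits <- hits[!duplicated(paste(hits$contig, hits$start, hits$end,
                                 hits$strand)), , drop = FALSE]
  hits <- hits[order(hits$contig, hits$start, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Extract the flanking candidate window around a genome hit
#'
#' Takes `flank` nt on each side of the hit (clipped at contig bounds).
#' For minus-strand hits the window sequence is reverse-complemented so it
#' is always query-oriented; `mature_offset` locates the hit within the
#' window and maps back exactly onto the genomic span.
#'
#' @param hit one row of [scan_genome()] output (or an equivalent list).
#' @param genome named character vector of contigs.
#' @param flank flank length in nt (default 450).
#' @return object of class `"candidate_window"`: list with `hit`,
#'   `window_span` (forward-strand genomic), `sequence` (query-oriented),
#'   `mature_offset` (span within `sequence`).
#' @export
extract_candidate <- function(hit, genome, flank = 450) {
  hit <- as.list(hit)
  if (!hit$contig %in% names(genome))
    stop("contig ", hit$contig, " not in genome", call. = FALSE)
  ctg <- genome[[hit$contig]]
  L <- nchar(ctg)
  ws <- span(max(0L, hit$start - flank), min(L, hit$end + flank))
  seq <- span_seq(ctg, ws)
  W <- span_len(ws)
  if (identical(hit$strand, "-")) {
    seq <- revcomp(seq)
    mo <- span(W - (hit$end - ws[1]), W - (hit$start - ws[1]))
  } else {
    mo <- span(hit$start - ws[1], hit$end - ws[1])
  }
  structure(list(hit = hit, window_span = ws, sequence = seq,
                 mature_offset = mo), class = "candidate_window")
}

# validation core shared by validate_hairpin and fold_and_trim; works on a
# dot-bracket structure and a mature span within it
validate_structure <- function(struct, mature_span, min_paired = 15,
                               max_bulge = 4) {
  pm <- pairing_map(struct)
  mpos <- (mature_span[1] + 1L):mature_span[2]
  partners <- pm[mpos]
  paired_idx <- which(!is.na(partners))
  fail <- function(reason, n_paired = length(paired_idx))
    list(valid = FALSE, reason = reason, n_paired = n_paired)
  if (length(paired_idx) == 0L) return(fail("no_stem"))
  # (a) mature entirely in one arm: partners all on one side and never
  # inside the mature itself
  if (any(partners[paired_idx] %in% mpos)) return(fail("mature_in_loop"))
  side <- sign(partners[paired_idx] - mpos[paired_idx])
  if (length(unique(side)) > 1L) return(fail("mature_in_loop"))
  # (b) enough of the mature paired to the opposite arm
  if (length(paired_idx) < min_paired) return(fail("duplex_too_weak"))
  pp <- partners[paired_idx]
  # (d.1) antiparallel helix: partners strictly decreasing, no crossing
  if (any(diff(pp) >= 0)) return(fail("multiloop"))
  # (c) asymmetric bulges within the miR/miR* duplex
  dm <- diff(mpos[paired_idx])
  dp <- -diff(pp)
  if (any(abs(dm - dp) > max_bulge)) return(fail("duplex_too_weak"))
  # (d.2) single hairpin: no base pair strictly between the duplex's
  # loop-proximal ends
  if (side[1] > 0) {            # partners downstream: mature on 5' arm
    inner_m <- mpos[paired_idx][length(paired_idx)]
    inner_p <- pp[length(pp)]
  } else {                      # mature on 3' arm
    inner_m <- mpos[paired_idx][1]
    inner_p <- pp[1]
  }
  lo <- min(inner_m, inner_p)
  hi <- max(inner_m, inner_p)
  if (hi - lo > 1L) {
    # the stem may continue inward, but it must close a single terminal
    # loop: a bifurcation (two sibling hairpins) is a multiloop
    inner_str <- substr(struct, lo + 1L, hi - 1L)
    n_loops <- length(gregexpr("\\(\\.*\\)", inner_str)[[1]])
    if (attr(gregexpr("\\(\\.*\\)", inner_str)[[1]], "match.length")[1] == -1)
      n_loops <- 0L
    if (n_loops > 1L) return(fail("multiloop"))
  }
  list(valid = TRUE, reason = NA_character_, n_paired = length(paired_idx),
       arm = if (side[1] > 0) "five_prime" else "three_prime")
}

#' Validate a precursor hairpin
#'
#' A hairpin is accepted iff (a) the mature lies entirely in one arm, (b)
#' at least `min_paired` of its positions pair to the opposite arm, (c)
#' no asymmetric bulge longer than `max_bulge` nt interrupts the
#' miR/miR* duplex, and (d) the mature-containing stem is a single
#' hairpin with no multiloop between miR and miR*.  Thresholds follow
#' common plant-miRNA annotation practice and are configurable.
#'
#' @param p a [precursor].
#' @param min_paired minimum paired mature positions (default 15).
#' @param max_bulge maximum asymmetric bulge within the duplex (default 4).
#' @return list with `valid` (logical), `reason` (NA or one of
#'   `no_stem`, `mature_in_loop`, `duplex_too_weak`, `multiloop`) and
#'   `n_paired`.
#' @export
validate_hairpin <- function(p, min_paired = 15, max_bulge = 4) {
  validate_structure(p$structure, p$mature_span, min_paired, max_bulge)
}

#' Locate the miR* span of a validated precursor
#'
#' The star is the block pairing with the mature under the structure's
#' pairing map, shifted to leave a 2-nt 3' overhang on each duplex end
#' (Dicer convention).  Bulges shift coordinates via the pairing map.
#'
#' @param p a [precursor] that passes [validate_hairpin()].
#' @return 0-based half-open star span on the precursor sequence.
#' @export
locate_mir_star <- function(p) {
  star_from_pairing(pairing_map(p$structure), p$mature_span,
                    nchar(p$sequence))
}

hairpin_rejection <- function(reason, window = NULL) {
  structure(list(reason = reason, window = window),
            class = "hairpin_rejection")
}

#' @export
print.hairpin_rejection <- function(x, ...) {
  cat("<rejected candidate>", x$reason, "\n")
  invisible(x)
}

#' Is an object a rejected candidate?
#' @param x object returned by [fold_and_trim()].
#' @return logical.
#' @export
is_rejected <- function(x) inherits(x, "hairpin_rejection")

#' Fold a candidate window and trim it to a minimal valid hairpin
#'
#' Folds progressively larger sub-windows centred on the mature (the
#' engine returns the maximum-pairing structure plus alternative
#' co-optimal tracebacks standing in for suboptimal structures).  The
#' first structure passing [validate_hairpin()] is trimmed to the minimal
#' span covering mature and star plus `flank_keep` nt on each side,
#' refolded and re-validated.  Rejections carry a machine-readable reason.
#'
#' @param window a `"candidate_window"` from [extract_candidate()].
#' @param n_suboptimal alternative structures to sample per fold
#'   (default 10).
#' @param min_paired,max_bulge validation thresholds (see
#'   [validate_hairpin()]).
#' @param flank_keep nt of flank retained around the trimmed duplex
#'   (default 5).
#' @return a [precursor] (with provenance attributes `contig`, `strand`,
#'   `genome_span`) or an object of class `"hairpin_rejection"` with a
#'   `reason` in `window_too_short`, `no_stem`, `mature_in_loop`,
#'   `duplex_too_weak`, `multiloop`.
#' @export
fold_and_trim <- function(window, n_suboptimal = 10, min_paired = 15,
                          max_bulge = 4, flank_keep = 5) {
  seq <- window$sequence
  n <- nchar(seq)
  mo <- window$mature_offset
  if (n < 50) return(hairpin_rejection("window_too_short", window))
  cap <- max(mo[1], n - mo[2])
  ladder <- unique(pmin(c(60L, 90L, 130L, 180L, 250L, 350L, 450L), cap))
  last_reason <- "no_stem"
  for (hw in ladder) {
    sub_span <- span(max(0L, mo[1] - hw), min(n, mo[2] + hw))
    subseq <- span_seq(seq, sub_span)
    sub_mo <- mo - sub_span[1]
    folds <- fold_candidate(subseq, n_suboptimal)
    for (k in seq_len(nrow(folds))) {
      st <- folds$structure[k]
      v <- validate_structure(st, sub_mo, min_paired, max_bulge)
      if (!v$valid) {
        if (k == 1L) last_reason <- v$reason
        next
      }
      pm <- pairing_map(st)
      star <- star_from_pairing(pm, sub_mo, nchar(subseq))
      lo <- max(0L, min(sub_mo[1], star[1]) - flank_keep)
      hi <- min(nchar(subseq), max(sub_mo[2], star[2]) + flank_keep)
      trimmed <- substr(subseq, lo + 1L, hi)
      t_mo <- sub_mo - lo
      refold <- fold_candidate(trimmed, n_suboptimal)
      for (j in seq_len(nrow(refold))) {
        v2 <- validate_structure(refold$structure[j], t_mo, min_paired,
                                 max_bulge)
        if (!v2$valid) next
        pm2 <- pairing_map(refold$structure[j])
        star2 <- star_from_pairing(pm2, t_mo, nchar(trimmed))
        # genomic span of the trimmed precursor (forward strand)
        off <- sub_span[1] + lo
        len_t <- nchar(trimmed)
        gspan <- if (identical(window$hit$strand, "-"))
          span(window$window_span[1] + (n - (off + len_t)),
               window$window_span[1] + (n - off))
        else
          span(window$window_span[1] + off,
               window$window_span[1] + off + len_t)
        p <- precursor(
          id = sprintf("%s_%s_%d", window$hit$query_id, window$hit$contig,
                       window$hit$start),
          sequence = trimmed, structure = refold$structure[j],
          mature_span = t_mo, star_span = star2,
          arm = v2$arm, fold_energy = -refold$pairs[j])
        attr(p, "contig") <- window$hit$contig
        attr(p, "strand") <- window$hit$strand
        attr(p, "genome_span") <- gspan
        return(p)
      }
    }
  }
  hairpin_rejection(last_reason, window)
}

#' Discover precursors for a set of mature queries
#'
#' End-to-end discovery: genome scan, merging of duplicate loci (queries
#' mapping to an identical span are collapsed, keeping the fewest-mismatch
#' query), window extraction, folding/trimming and validation.
#'
#' @inheritParams scan_genome
#' @param flank flank length for [extract_candidate()].
#' @param ... passed to [fold_and_trim()].
#' @return list with `precursors` (list of [precursor]), `hits`
#'   (accepted hits data.frame) and `rejections` (data.frame of rejected
#'   loci with reasons).
#' @export
discover_precursors <- function(query, genome, max_mismatches = 3,
                                flank = 450, ...) {
  hits <- merge_duplicate_loci(scan_genome(query, genome, max_mismatches))
  precursors <- list()
  acc <- integer(0)
  rej <- list()
  for (i in seq_len(nrow(hits))) {
    w <- extract_candidate(hits[i, ], genome, flank)
    res <- fold_and_trim(w, ...)
    if (is_rejected(res)) {
      rej[[length(rej) + 1]] <- data.frame(
        query_id = hits$query_id[i], contig = hits$contig[i],
        start = hits$start[i], end = hits$end[i], strand = hits$strand[i],
        reason = res$reason, stringsAsFactors = FALSE)
    } else {
      precursors[[length(precursors) + 1]] <- res
      acc <- c(acc, i)
    }
  }
  list(precursors = precursors,
       hits = hits[acc, , drop = FALSE],
       rejections = if (length(rej)) do.call(rbind, rej) else
         data.frame(query_id = character(0), contig = character(0),
                    start = integer(0), end = integer(0),
                    strand = character(0), reason = character(0)))
}
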