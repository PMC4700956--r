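# Expectation-scored target prediction.  The score is an additive penalty
# over duplex positions read from the miRNA 5' end: Watson-Crick match 0,
# G.U wobble 0.5, mismatch 1.0, gap 2.0, with every per-position penalty
# doubled at seed positions 2-13.  Strict predictions keep expectation
# <= 2.0, relaxed <= 3.0 (the two published cutoffs); the scoring
# constants themselves are configurable.

default_scoring <- function() {
  list(seed_lo = 2L, seed_hi = 13L, w_gu = 0.5, w_mm = 1.0, w_gap = 2.0,
       seed_mult = 2.0)
}

#' Expectation penalty of an ungapped miRNA/target duplex
#'
#' The target window is scored antiparallel: miRNA position 1 (5') faces
#' the window's 3'-most base.
#'
#' @param mirna miRNA sequence, 5'->3'.
#' @param window target-sense window of the same length.
#' @param seed_span inclusive 1-based miRNA positions with doubled
#'   penalties (default `c(2, 13)`).
#' @param scoring list of scoring constants (see `default_scoring`).
#' @return expectation score; the per-position pairing string (one char
#'   per miRNA position: `|` match, `o` G.U, `x` mismatch) is attached as
#'   attribute `"pairing"`.
#' @export
duplex_penalty <- function(mirna, window, seed_span = c(2L, 13L),
                           scoring = default_scoring()) {
  mirna <- norm_seq(mirna, "mirna")
  window <- norm_seq(window, "window")
  m <- nchar(mirna)
  if (m == 0 || nchar(window) == 0) stop("empty input", call. = FALSE)
  if (nchar(window) != m)
    stop("window length must equal miRNA length (ungapped scoring)",
         call. = FALSE)
  mb <- strsplit(mirna, "")[[1]]
  wb <- rev(strsplit(window, "")[[1]])     # wb[i] faces miRNA position i
  comp <- chartr("ACGT", "TGCA", mb)
  is_match <- wb == comp
  is_gu <- (mb == "G" & wb == "T") | (mb == "T" & wb == "G")
  pen <- ifelse(is_match, 0, ifelse(is_gu, scoring$w_gu, scoring$w_mm))
  mult <- ifelse(seq_len(m) >= seed_span[1] & seq_len(m) <= seed_span[2],
                 scoring$seed_mult, 1)
  out <- sum(pen * mult)
  attr(out, "pairing") <- paste(
    ifelse(is_match, "|", ifelse(is_gu, "o", "x")), collapse = "")
  out
}

#' Scan a CDS for miRNA target duplexes
#'
#' Evaluates every ungapped window plus all single-gap variants (a gap on
#' either strand at any position) and reports, per non-overlapping locus,
#' the minimum-expectation duplex with expectation `<= max_expectation`.
#' Ties are broken by smaller offset, then fewer gaps.  A gap on the
#' target side (`-` in the pairing string) leaves a miRNA position
#' unpaired; an insertion on the target side (`^`) sits between two miRNA
#' positions and is penalised at the index of the following position.
#'
#' @param mirna miRNA sequence.
#' @param cds coding sequence (>= miRNA length).
#' @param max_expectation report duplexes up to this score (default 3.0).
#' @param max_gaps at most this many gaps per duplex (0 or 1; default 1).
#' @param scoring scoring constants (see [duplex_penalty()]).
#' @return data.frame (`start`, `end`, `n_gaps`, `expectation`,
#'   `pairing`, `translation_inhibition`), 0-based half-open spans on the
#'   CDS, sorted by start.
#' @export
scan_cds <- function(mirna, cds, max_expectation = 3.0, max_gaps = 1,
                     scoring = default_scoring()) {
  mirna <- norm_seq(mirna, "mirna")
  cds <- norm_seq(cds, "cds")
  if (nchar(cds) < nchar(mirna))
    stop("cds shorter than miRNA", call. = FALSE)
  cand <- .scan_duplexes_cpp(mirna, cds, max_expectation,
                             as.integer(max_gaps),
                             scoring$seed_lo, scoring$seed_hi,
                             scoring$w_gu, scoring$w_mm, scoring$w_gap,
                             scoring$seed_mult)
  if (nrow(cand) == 0) return(empty_duplexes())
  # best duplex per non-overlapping locus, deterministic tie-breaks
  cand <- cand[order(cand$expectation, cand$start, cand$n_gaps), ,
               drop = FALSE]
  keep <- logical(nrow(cand))
  taken <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(nrow(cand))) {
    sp <- c(cand$start[i], cand$end[i])
    if (nrow(taken) == 0 ||
        !any(taken[, 1] < sp[2] & sp[1] < taken[, 2])) {
      keep[i] <- TRUE
      taken <- rbind(taken, sp)
    }
  }
  res <- cand[keep, , drop = FALSE]
  res$translation_inhibition <- vapply(res$pairing, central_mismatch,
                                       logical(1), USE.NAMES = FALSE)
  res <- res[order(res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

empty_duplexes <- function() {
  data.frame(start = integer(0), end = integer(0), n_gaps = integer(0),
             expectation = numeric(0), pairing = character(0),
             translation_inhibition = logical(0), stringsAsFactors = FALSE)
}

# central mismatch (miRNA positions 9-11) flags translation inhibition;
# reported but never used to filter (cleavage-site scoring only)
central_mismatch <- function(pairing) {
  ch <- strsplit(pairing, "")[[1]]
  pos <- cumsum(ch != "^")                 # miRNA position per column
  central <- ch[pos >= 9 & pos <= 11]
  any(central %in% c("x", "-", "^"))
}

#' Predict miRNA targets across a CDS set
#'
#' Runs [scan_cds()] for every miRNA/CDS combination and classifies sites
#' by stringency: strict keeps expectation <= 2.0, relaxed <= 3.0.  A
#' gene counts once per miRNA via its best site, but all sites are
#' retained in the detailed table.
#'
#' @param mirnas named character vector of miRNA sequences (unique ids).
#' @param cds_set named character vector of CDS (unique ids).
#' @param mode `"strict"` or `"relaxed"`.
#' @param strict_cutoff,relaxed_cutoff expectation cutoffs (2.0 / 3.0).
#' @param scoring scoring constants.
#' @return object of class `"target_prediction"`: list with `sites` (all
#'   sites at the mode's cutoff), `best` (best site per miRNA-gene pair)
#'   and `mode`.
#' @export
predict_targets <- function(mirnas, cds_set, mode = c("relaxed", "strict"),
                            strict_cutoff = 2.0, relaxed_cutoff = 3.0,
                            scoring = default_scoring()) {
  mode <- match.arg(mode)
  if (anyDuplicated(names(mirnas)) || anyDuplicated(names(cds_set)))
    stop("duplicate ids in mirnas or cds_set", call. = FALSE)
  cutoff <- if (mode == "strict") strict_cutoff else relaxed_cutoff
  rows <- list()
  for (mn in names(mirnas)) {
    for (gn in names(cds_set)) {
      d <- scan_cds(mirnas[[mn]], cds_set[[gn]],
                    max_expectation = relaxed_cutoff, scoring = scoring)
      d <- d[d$expectation <= cutoff, , drop = FALSE]
      if (nrow(d) == 0) next
      d$mirna_id <- mn
      d$gene_id <- gn
      rows[[length(rows) + 1]] <- d
    }
  }
  sites <- if (length(rows)) do.call(rbind, rows) else
    cbind(empty_duplexes(),
          data.frame(mirna_id = character(0), gene_id = character(0)))
  sites$stringency <- ifelse(sites$expectation <= strict_cutoff,
                             "strict", "relaxed")
  sites <- sites[, c("mirna_id", "gene_id", "start", "end", "n_gaps",
                     "expectation", "pairing", "stringency",
                     "translation_inhibition")]
  rownames(sites) <- NULL
  # best site per (miRNA, gene): lowest expectation, then smallest start
  o <- order(sites$mirna_id, sites$gene_id, sites$expectation, sites$start)
  best <- sites[o, , drop = FALSE]
  best <- best[!duplicated(paste(best$mirna_id, best$gene_id)), ,
               drop = FALSE]
  rownames(best) <- NULL
  structure(list(sites = sites, best = best, mode = mode,
                 cutoff = cutoff), class = "target_prediction")
}

#' @export
print.target_prediction <- function(x, ...) {
  cat(sprintf("<target_prediction mode=%s> %d sites, %d miRNA-gene pairs\n",
              x$mode, nrow(x$sites), nrow(x$best)))
  invisible(x)
}

#' Gene x miRNA best-expectation matrix
#' @param pred a [predict_targets()] result.
#' @return numeric matrix (genes in rows, miRNAs in columns) of best
#'   expectations; `NA` where no site passes the cutoff.
#' @export
best_score_matrix <- function(pred) {
  b <- pred$best
  genes <- sort(unique(b$gene_id))
  mirnas <- sort(unique(b$mirna_id))
  m <- matrix(NA_real_, length(genes), length(mirnas),
              dimnames = list(genes, mirnas))
  for (i in seq_len(nrow(b)))
    m[b$gene_id[i], b$mirna_id[i]] <- b$expectation[i]
  m
}
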