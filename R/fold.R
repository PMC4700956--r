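# Folding backend and precursor objects.
#
# The folding interface is deliberately narrow: sequence in, a table of
# (structure, pairs) out.  The built-in engine is a Nussinov-style
# maximum-base-pairing fold (minimum hairpin loop 3 nt, G.U wobble allowed);
# its objective is the pair count and the reported "energy" is -pairs.
# Alternative co-optimal tracebacks stand in for suboptimal structures.

#' Fold a candidate sequence
#'
#' Returns the maximum-pairing structure plus up to `n_suboptimal`
#' alternative co-optimal structures from distinct tracebacks.
#'
#' @param seq nucleotide string (ACGT/U).
#' @param n_suboptimal number of additional structures to sample.
#' @return data.frame with columns `structure` (dot-bracket) and `pairs`
#'   (pair count of the optimum; the engine's objective).
#' @export
fold_candidate <- function(seq, n_suboptimal = 10) {
  seq <- norm_seq(seq)
  res <- .fold_engine_cpp(seq, as.integer(n_suboptimal))
  data.frame(structure = as.character(res$structure),
             pairs = as.integer(res$pairs),
             stringsAsFactors = FALSE)
}

#' Construct a precursor record
#'
#' @param id precursor identifier.
#' @param sequence nucleotide string.
#' @param structure dot-bracket string of equal length.
#' @param mature_span,star_span 0-based half-open spans on `sequence`.
#' @param arm `"five_prime"` or `"three_prime"`: arm carrying the mature.
#' @param fold_energy engine units (built-in engine: minus the pair count).
#' @return object of class `"precursor"`.
#' @export
precursor <- function(id, sequence, structure, mature_span, star_span,
                      arm = c("three_prime", "five_prime"),
                      fold_energy = NA_real_) {
  arm <- match.arg(arm)
  if (nchar(sequence) != nchar(structure))
    stop("sequence and structure lengths differ", call. = FALSE)
  if (!db_balanced(structure))
    stop("structure is not balanced", call. = FALSE)
  n <- nchar(sequence)
  for (sp in list(mature_span, star_span))
    if (sp[1] < 0 || sp[2] > n)
      stop("span outside [0, len)", call. = FALSE)
  if (spans_overlap(mature_span, star_span))
    stop("mature and star spans overlap", call. = FALSE)
  structure(list(id = id, sequence = sequence, structure = structure,
                 mature_span = as.integer(mature_span),
                 star_span = as.integer(star_span),
                 arm = arm, fold_energy = fold_energy),
            class = "precursor")
}

#' @export
print.precursor <- function(x, ...) {
  cat(sprintf("<precursor %s> %d nt, mature [%d,%d) on %s arm, star [%d,%d)\n",
              x$id, nchar(x$sequence), x$mature_span[1], x$mature_span[2],
              sub("_prime", "'", x$arm), x$star_span[1], x$star_span[2]))
  cat(x$sequence, "\n")
  cat(x$structure, "\n")
  invisible(x)
}

# miR* span from a pairing map under the Dicer 2-nt 3'-overhang convention:
# the star starts at the partner of the mature position 2 nt in from its 3'
# end and runs to 2 nt past the partner of the mature 5' end.  Bulges shift
# coordinates implicitly because partners are read off the pairing map.
# Unpaired edge positions fall back to the nearest paired mature position.
# The result is clipped to [0, len).  All spans 0-based half-open.
star_from_pairing <- function(partner, mature_span, len = length(partner)) {
  mpos <- (mature_span[1] + 1L):mature_span[2]        # 1-based
  paired <- mpos[!is.na(partner[mpos])]
  if (length(paired) == 0L)
    stop("mature is fully unpaired; no star can be located", call. = FALSE)
  # mature 5' end partner (fallback: first paired position)
  p5 <- partner[paired[1]]
  # position 2 nt in from the mature 3' end (index mature_end - 3 0-based,
  # i.e. mature_span[2] - 2 1-based); fallback: last paired position <= it
  want <- mature_span[2] - 2L
  cand <- paired[paired <= want]
  p3 <- partner[if (length(cand)) cand[length(cand)] else paired[length(paired)]]
  lo <- min(p3, p5)
  hi <- max(p3, p5)
  # 2-nt 3' overhang extends the star past the partner of the mature 5' end
  if (p5 > p3) hi <- hi + 2L else lo <- lo - 2L
  span(max(0L, lo - 1L), min(len, hi))
}
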