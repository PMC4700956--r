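# Flanking-gene synteny: the k nearest protein-coding genes on either
# side of each miRNA locus, conserved flanking runs (segmental
# duplication) and tandem pairs (no intervening coding gene, identical
# flanking sets).

#' Flanking protein-coding genes of a locus
#'
#' The `k` nearest genes strictly upstream and strictly downstream of the
#' locus by interval-midpoint distance (ties broken by lower start
#' coordinate); fewer than `k` near chromosome ends.
#'
#' @param locus list or one-row data.frame with `locus_id`, `chrom`,
#'   `start`, `end`.
#' @param annotation data.frame of gene intervals (`gene_id`, `chrom`,
#'   `start`, `end`, optional `type`); rows whose `type` is not a coding
#'   gene (anything containing "miRNA"/"MIR") are excluded.
#' @param k flank size (default 10).
#' @return object of class `"synteny_context"`: list with `locus_id`,
#'   `chrom`, `upstream` and `downstream` gene-id vectors (nearest
#'   first).
#' @export
flanking_context <- function(locus, annotation, k = 10) {
  locus <- as.list(locus)
  ann <- annotation
  if ("type" %in% names(ann))
    ann <- ann[!grepl("miRNA|MIR", ann$type), , drop = FALSE]
  ann <- ann[ann$chrom == locus$chrom, , drop = FALSE]
  if (!locus$chrom %in% annotation$chrom)
    stop("locus chromosome ", locus$chrom, " absent from annotation",
         call. = FALSE)
  mid_l <- (locus$start + locus$end) / 2
  mid_g <- (ann$start + ann$end) / 2
  d <- abs(mid_g - mid_l)
  up <- ann[mid_g < mid_l, , drop = FALSE]
  dn <- ann[mid_g > mid_l, , drop = FALSE]
  pick <- function(df, dd) {
    o <- order(dd, df$start)
    head(df$gene_id[o], k)
  }
  structure(list(locus_id = locus$locus_id, chrom = locus$chrom,
                 upstream = pick(up, abs((up$start + up$end) / 2 - mid_l)),
                 downstream = pick(dn, abs((dn$start + dn$end) / 2 - mid_l))),
            class = "synteny_context")
}

#' @export
print.synteny_context <- function(x, ...) {
  cat(sprintf("<synteny_context %s> chrom %s: %d upstream, %d downstream\n",
              x$locus_id, x$chrom, length(x$upstream), length(x$downstream)))
  invisible(x)
}

duplication_call <- function(locus_a, locus_b, kind, evidence) {
  structure(list(locus_a = locus_a, locus_b = locus_b, kind = kind,
                 evidence = evidence), class = "duplication_call")
}

#' @export
print.duplication_call <- function(x, ...) {
  cat(sprintf("<duplication_call %s> %s -- %s\n", x$kind, x$locus_a,
              x$locus_b))
  invisible(x)
}

#' Call a tandem duplication between two loci
#'
#' Tandem iff the loci share a chromosome, no protein-coding gene lies
#' between them, and the union of the flanking-gene sets of the two loci
#' is identical.
#'
#' @param a,b loci (lists/rows with `locus_id`, `chrom`, `start`, `end`).
#' @param annotation gene intervals as in [flanking_context()].
#' @param contexts named list of [flanking_context()] results (same `k`),
#'   keyed by `locus_id`.
#' @return a `"duplication_call"` of kind `"tandem"`, or `NULL`.
#' @export
call_tandem <- function(a, b, annotation, contexts) {
  a <- as.list(a); b <- as.list(b)
  if (!identical(a$chrom, b$chrom)) return(NULL)
  ann <- annotation
  if ("type" %in% names(ann))
    ann <- ann[!grepl("miRNA|MIR", ann$type), , drop = FALSE]
  ann <- ann[ann$chrom == a$chrom, , drop = FALSE]
  mid_a <- (a$start + a$end) / 2
  mid_b <- (b$start + b$end) / 2
  mid_g <- (ann$start + ann$end) / 2
  if (any(mid_g > min(mid_a, mid_b) & mid_g < max(mid_a, mid_b)))
    return(NULL)
  ca <- contexts[[a$locus_id]]
  cb <- contexts[[b$locus_id]]
  fa <- union(ca$upstream, ca$downstream)
  fb <- union(cb$upstream, cb$downstream)
  if (!setequal(fa, fb)) return(NULL)
  duplication_call(a$locus_id, b$locus_id, "tandem",
                   list(shared_flanks = sort(fa)))
}

#' Call a segmental duplication from two flanking contexts
#'
#' The flanking genes of each locus are laid out in chromosomal order
#' (upstream reversed, then downstream).  A conserved run is a maximal
#' block of consecutive positions, at some alignment offset, where the
#' ordered genes are homologous (e-value below the cutoff); colinear
#' order is required, inversions are not matched.  A call requires a run
#' of at least `min_run` genes.
#'
#' @param ctx_a,ctx_b [flanking_context()] results.
#' @param homology data.frame (`gene_a`, `gene_b`, `evalue`); closed
#'   under symmetry internally.
#' @param max_evalue e-value cutoff (default 1e-4).
#' @param min_run minimum conserved run length (default 3).
#' @return a `"duplication_call"` of kind `"segmental"` (evidence: run
#'   length and matched gene pairs), or `NULL`.
#' @export
call_segmental <- function(ctx_a, ctx_b, homology, max_evalue = 1e-4,
                           min_run = 3) {
  need <- c("gene_a", "gene_b", "evalue")
  if (!is.data.frame(homology) || !all(need %in% names(homology)))
    stop("malformed homology table: need gene_a, gene_b, evalue",
         call. = FALSE)
  hom <- homology[homology$evalue < max_evalue, , drop = FALSE]
  key <- unique(c(paste(hom$gene_a, hom$gene_b),
                  paste(hom$gene_b, hom$gene_a)))   # symmetric closure
  ord_a <- c(rev(ctx_a$upstream), ctx_a$downstream)
  ord_b <- c(rev(ctx_b$upstream), ctx_b$downstream)
  na <- length(ord_a); nb <- length(ord_b)
  if (na == 0 || nb == 0) return(NULL)
  best_len <- 0L
  best_pairs <- NULL
  for (d in (-(nb - 1L)):(na - 1L)) {
    run <- 0L
    pairs <- list()
    for (j in seq_len(nb)) {
      i <- j + d
      match_ij <- i >= 1 && i <= na &&
        paste(ord_a[i], ord_b[j]) %in% key
      if (match_ij) {
        run <- run + 1L
        pairs[[length(pairs) + 1]] <- c(ord_a[i], ord_b[j])
        if (run > best_len) {
          best_len <- run
          best_pairs <- pairs[(length(pairs) - run + 1):length(pairs)]
        }
      } else {
        run <- 0L
        pairs <- list()
      }
    }
  }
  if (best_len < min_run) return(NULL)
  duplication_call(ctx_a$locus_id, ctx_b$locus_id, "segmental",
                   list(run_length = best_len,
                        matched = do.call(rbind, best_pairs)))
}
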