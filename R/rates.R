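# Structure-partitioned substitution rates: the precursor is tiled into
# five regions (5'-stem, miR*, loop, miR, 3'-stem); pairwise raw
# differences within an orthologous precursor group are normalised by the
# longer region length and twice the divergence time (Myr), then averaged
# per group.  Divergence times come from a chronogram or a supplied table.

#' Partition a precursor into its five structural regions
#'
#' The loop is the span strictly between the two duplex spans; the 5'
#' region is everything before the first and the 3' region everything
#' after the last.  The five spans tile `[0, len)` exactly.
#'
#' @param p a [precursor] with mature and star spans set.
#' @return object of class `"region_partition"`: list with `spans`, a
#'   named list of 0-based half-open spans ordered along the sequence.
#' @export
partition_regions <- function(p) {
  m <- p$mature_span
  s <- p$star_span
  if (spans_overlap(m, s))
    stop("mature and star spans overlap", call. = FALSE)
  n <- nchar(p$sequence)
  mature_first <- m[1] < s[1]
  first <- if (mature_first) m else s
  second <- if (mature_first) s else m
  spans <- list(
    five_prime = span(0L, first[1]),
    loop = span(first[2], second[1]),
    three_prime = span(second[2], n))
  spans[[if (mature_first) "mir" else "mir_star"]] <- first
  spans[[if (mature_first) "mir_star" else "mir"]] <- second
  ord <- if (mature_first) c("five_prime", "mir", "loop", "mir_star",
                             "three_prime")
         else c("five_prime", "mir_star", "loop", "mir", "three_prime")
  structure(list(spans = spans[ord]), class = "region_partition")
}

#' @export
print.region_partition <- function(x, ...) {
  for (r in names(x$spans))
    cat(sprintf("%-12s [%d,%d)\n", r, x$spans[[r]][1], x$spans[[r]][2]))
  invisible(x)
}

#' Project a region partition onto alignment columns
#'
#' Each alignment column is labelled with the region of the reference
#' member's base in that column; columns where the reference carries a
#' gap inherit the region of the nearest preceding reference base
#' (leading gap columns get the first region).
#'
#' @param ref_row aligned reference sequence (with `-` gaps).
#' @param partition [partition_regions()] result for the ungapped
#'   reference.
#' @return character vector, one region label per alignment column.
#' @export
project_partition <- function(ref_row, partition) {
  ch <- strsplit(ref_row, "")[[1]]
  is_base <- ch != "-"
  refpos <- cumsum(is_base)              # 1-based ref position per column
  refpos[refpos == 0L] <- 1L             # leading gaps -> first base
  lab_of_pos <- character(sum(is_base))
  for (r in names(partition$spans)) {
    sp <- partition$spans[[r]]
    if (span_len(sp) > 0) lab_of_pos[(sp[1] + 1L):sp[2]] <- r
  }
  lab_of_pos[refpos]
}

#' Count per-region fixed differences between two aligned rows
#'
#' A column contributes 1 to its region iff both rows carry a non-gap
#' base and the bases differ; any column with a gap in either row
#' contributes 0 (substitutions only).
#'
#' @param rowA,rowB aligned sequences of equal length (`-` gaps).
#' @param mask per-column region labels from [project_partition()].
#' @return named integer vector over the five regions.
#' @export
count_region_differences <- function(rowA, rowB, mask) {
  a <- strsplit(toupper(rowA), "")[[1]]
  b <- strsplit(toupper(rowB), "")[[1]]
  if (length(a) != length(b))
    stop("aligned rows have different lengths", call. = FALSE)
  if (length(mask) != length(a))
    stop("mask length does not match alignment width", call. = FALSE)
  diff <- a != b & a != "-" & b != "-"
  regions <- c("five_prime", "mir_star", "loop", "mir", "three_prime")
  counts <- setNames(integer(5), regions)
  tab <- table(factor(mask[diff], levels = regions))
  counts[names(tab)] <- as.integer(tab)
  counts
}

#' Pairwise substitution rate per site per Myr
#'
#' `rate = diffs / max(lenA, lenB) / (2 * T)`: fixed differences divided
#' by the longer of the two (ungapped) region lengths and by twice the
#' divergence time.  With `correct = TRUE` the raw proportion is first
#' converted to a Jukes-Cantor distance (`-3/4 log(1 - 4/3 p)`), which
#' removes the saturation bias of raw differences (used by the simulation
#' recovery tests; the default matches the raw estimator).
#'
#' @param diffs number of fixed differences.
#' @param lenA,lenB ungapped region lengths of the two members.
#' @param T divergence time in Myr (> 0).
#' @param correct apply the Jukes-Cantor correction (default FALSE).
#' @return substitution rate (substitutions/site/Myr).
#' @export
pairwise_rate <- function(diffs, lenA, lenB, T, correct = FALSE) {
  if (T <= 0) stop("divergence time must be > 0", call. = FALSE)
  p <- diffs / max(lenA, lenB)
  if (correct) {
    if (p >= 0.75) return(NA_real_)
    p <- -0.75 * log(1 - 4 / 3 * p)
  }
  p / (2 * T)
}

#' Assemble a precursor group
#'
#' @param group_id identifier.
#' @param alignment named character vector of aligned member sequences
#'   (equal widths, `-` gaps).
#' @param species named character vector: species label per member.
#' @param partitions named list of [partition_regions()] results on the
#'   ungapped member sequences.
#' @param times either a member-by-member matrix of divergence times in
#'   Myr, or a species-by-species matrix (e.g. from
#'   [times_from_chronogram()]) which is expanded through `species`.
#' @param reference member used to project the region mask (default: the
#'   longest ungapped member).
#' @return object of class `"precursor_group"`.
#' @export
precursor_group <- function(group_id, alignment, species, partitions,
                            times, reference = NULL) {
  members <- names(alignment)
  if (is.null(members)) stop("alignment must be named", call. = FALSE)
  w <- nchar(alignment)
  if (length(unique(w)) != 1)
    stop("alignment rows have unequal widths", call. = FALSE)
  if (!all(members %in% names(species)))
    stop("species labels missing for some members", call. = FALSE)
  if (!all(members %in% names(partitions)))
    stop("partitions missing for some members", call. = FALSE)
  if (!all(members %in% rownames(times))) {
    sp <- unname(species[members])
    if (!all(sp %in% rownames(times)))
      stop("times matrix covers neither members nor species", call. = FALSE)
    times <- times[sp, sp, drop = FALSE]
    dimnames(times) <- list(members, members)
  } else {
    times <- times[members, members, drop = FALSE]
  }
  if (any(times != t(times)))
    stop("times matrix must be symmetric", call. = FALSE)
  if (is.null(reference)) {
    ungapped <- nchar(gsub("-", "", alignment))
    reference <- members[which.max(ungapped)]
  }
  structure(list(group_id = group_id, alignment = alignment,
                 species = species[members], partitions = partitions[members],
                 times = times, reference = reference),
            class = "precursor_group")
}

#' Per-region mean substitution rates for a precursor group
#'
#' Computes [pairwise_rate()] for every member pair with positive
#' divergence time (T = 0 pairs, e.g. same-species duplicates, are
#' excluded and counted) and averages per region.  The region mask is projected from
#' the reference member; per-member partitions supply the region lengths.
#'
#' @param g a [precursor_group()].
#' @param correct Jukes-Cantor correction flag (see [pairwise_rate()]).
#' @param cross_species_only restrict to pairs from different species.
#' @return data.frame (`group_id`, `region`, `mean_rate`, `sd`,
#'   `n_pairs`, `n_excluded`).
#' @export
group_region_rates <- function(g, correct = FALSE,
                               cross_species_only = FALSE) {
  members <- names(g$alignment)
  regions <- c("five_prime", "mir_star", "loop", "mir", "three_prime")
  mask <- project_partition(g$alignment[[g$reference]],
                            g$partitions[[g$reference]])
  region_len <- function(m)
    vapply(regions, function(r) span_len(g$partitions[[m]]$spans[[r]]),
           integer(1))
  lens <- vapply(members, region_len, integer(5))
  rates <- matrix(NA_real_, nrow = 0, ncol = 5,
                  dimnames = list(NULL, regions))
  n_excluded <- 0L
  if (length(members) >= 2) {
    prs <- combn(members, 2)
    for (k in seq_len(ncol(prs))) {
      a <- prs[1, k]; b <- prs[2, k]
      T <- g$times[a, b]
      if (T <= 0) { n_excluded <- n_excluded + 1L; next }
      if (cross_species_only && g$species[[a]] == g$species[[b]]) {
        n_excluded <- n_excluded + 1L
        next
      }
      d <- count_region_differences(g$alignment[[a]], g$alignment[[b]], mask)
      r <- vapply(regions, function(rg)
        pairwise_rate(d[[rg]], lens[rg, a], lens[rg, b], T, correct),
        numeric(1))
      rates <- rbind(rates, r)
    }
  }
  n_pairs <- nrow(rates)
  data.frame(
    group_id = g$group_id, region = regions,
    mean_rate = if (n_pairs) colMeans(rates, na.rm = TRUE) else NA_real_,
    sd = if (n_pairs > 1) apply(rates, 2, sd, na.rm = TRUE) else NA_real_,
    n_pairs = n_pairs, n_excluded = n_excluded,
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Pairwise divergence times from a chronogram
#'
#' The divergence time of two tips is the age (Myr) of their most recent
#' common ancestor in an ultrametric tree.
#'
#' @param tree `ape::phylo`, a Newick string, or a path to a Newick file.
#' @param tol ultrametricity tolerance (relative, default 1e-6).
#' @return symmetric matrix of times with tip labels as dimnames and a
#'   zero diagonal.
#' @export
times_from_chronogram <- function(tree, tol = 1e-6) {
  if (is.character(tree)) {
    tree <- if (file.exists(tree)) ape::read.tree(tree)
            else ape::read.tree(text = tree)
  }
  if (!inherits(tree, "phylo")) stop("not a phylogenetic tree", call. = FALSE)
  ages <- node_ages(tree, tol)
  tips <- tree$tip.label
  mrca <- ape::mrca(tree)
  tm <- matrix(0, length(tips), length(tips), dimnames = list(tips, tips))
  for (i in seq_along(tips))
    for (j in seq_along(tips))
      if (i != j) tm[i, j] <- ages[[mrca[tips[i], tips[j]]]]
  tm
}

#' Global pairwise alignment (fixtures only)
#'
#' Needleman-Wunsch with match 1, mismatch -1, gap -2.  A convenience
#' for building small aligned fixtures; real analyses consume alignments
#' produced elsewhere.
#'
#' @param a,b nucleotide strings.
#' @param match,mismatch,gap scoring parameters.
#' @return list with aligned strings `a` and `b` and the `score`.
#' @export
align_pair <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  S <- matrix(0, n + 1, m + 1)
  S[, 1] <- gap * (0:n)
  S[1, ] <- gap * (0:m)
  for (i in seq_len(n))
    for (j in seq_len(m))
      S[i + 1, j + 1] <- max(
        S[i, j] + if (x[i] == y[j]) match else mismatch,
        S[i, j + 1] + gap,
        S[i + 1, j] + gap)
  ai <- character(0); bi <- character(0)
  i <- n; j <- m
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        S[i + 1, j + 1] == S[i, j] + (if (x[i] == y[j]) match else mismatch)) {
      ai <- c(x[i], ai); bi <- c(y[j], bi); i <- i - 1; j <- j - 1
    } else if (i > 0 && S[i + 1, j + 1] == S[i, j + 1] + gap) {
      ai <- c(x[i], ai); bi <- c("-", bi); i <- i - 1
    } else {
      ai <- c("-", ai); bi <- c(y[j], bi); j <- j - 1
    }
  }
  list(a = paste(ai, collapse = ""), b = paste(bi, collapse = ""),
       score = S[n + 1, m + 1])
}
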