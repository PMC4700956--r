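# Synthetic-data generators: every input the pipeline consumes, with known
# ground truth.  All generators are pure functions of their seed and
# arguments (RNG state is saved and restored).

#' Construct a hairpin precursor template
#'
#' Builds a stem-loop with a designed pairing: the 3' arm is the reverse
#' complement of the 5' arm except at wobble positions (converted to G.U,
#' still paired in the dot-bracket) and bulge positions (single unpaired
#' bases inserted into the arm opposite the mature, so the mature duplex
#' stays intact).  A 22-nt mature span is centred in the requested arm and
#' the miR* span is derived from the designed pairing under the Dicer
#' 2-nt 3'-overhang convention.  Loop bases are drawn from {A, C} only so
#' that the designed structure is also the maximum-pairing structure.
#'
#' @param stem_len stem length in base pairs (>= 22 so the mature fits).
#' @param loop_len terminal loop length (>= 3).
#' @param n_wobbles number of G.U pairs to place in the stem.
#' @param n_bulges number of 1-nt bulges on the arm opposite the mature.
#' @param mature_arm `"3p"` or `"5p"`.
#' @param seed integer seed fixing all randomness.
#' @return a [precursor] object.
#' @export
make_hairpin <- function(stem_len, loop_len, n_wobbles = 0, n_bulges = 0,
                         mature_arm = c("3p", "5p"), seed = 1) {
  mature_arm <- match.arg(mature_arm)
  if (stem_len < 22) stop("mature cannot fit in arm", call. = FALSE)
  if (loop_len < 3) stop("loop_len must be >= 3", call. = FALSE)
  if (n_wobbles > stem_len) stop("too many wobbles", call. = FALSE)
  with_seed(seed, {
    arm5 <- sample(c("A", "C", "G", "T"), stem_len, replace = TRUE)
    arm3 <- strsplit(chartr("ACGT", "TGCA", paste(rev(arm5), collapse = "")), "")[[1]]
    # wobbles: pair index p couples arm5[p] with arm3[stem_len - p + 1]
    if (n_wobbles > 0) {
      wpos <- sample.int(stem_len, n_wobbles)
      for (p in wpos) {
        if (runif(1) < 0.5) {
          arm5[p] <- "G"; arm3[stem_len - p + 1] <- "T"
        } else {
          arm5[p] <- "T"; arm3[stem_len - p + 1] <- "G"
        }
      }
    }
    loop <- sample(c("A", "C"), loop_len, replace = TRUE)
    s5 <- rep("(", stem_len)
    s3 <- rep(")", stem_len)
    # bulges: single unpaired bases inserted into the arm opposite the
    # mature, strictly inside the stem
    if (n_bulges > 0) {
      ins_at <- sample(seq_len(stem_len - 1), min(n_bulges, stem_len - 1))
      ins_base <- sample(c("A", "C"), length(ins_at), replace = TRUE)
      target_arm <- if (mature_arm == "3p") "5p" else "3p"
      for (i in order(ins_at, decreasing = TRUE)) {
        at <- ins_at[i]
        if (target_arm == "5p") {
          arm5 <- append(arm5, ins_base[i], after = at)
          s5 <- append(s5, ".", after = at)
        } else {
          arm3 <- append(arm3, ins_base[i], after = at)
          s3 <- append(s3, ".", after = at)
        }
      }
    }
    seq <- paste(c(arm5, loop, arm3), collapse = "")
    struct <- paste(c(s5, rep(".", loop_len), s3), collapse = "")
    n <- nchar(seq)
    # mature: 22 nt centred in its arm (paired positions only)
    off <- (stem_len - 22L) %/% 2L
    if (mature_arm == "5p") {
      arm_pair_pos <- which(strsplit(struct, "")[[1]] == "(")
      mstart <- arm_pair_pos[off + 1L] - 1L
      mend <- arm_pair_pos[off + 22L]
    } else {
      arm_pair_pos <- which(strsplit(struct, "")[[1]] == ")")
      mstart <- arm_pair_pos[off + 1L] - 1L
      mend <- arm_pair_pos[off + 22L]
    }
    mature_span <- span(mstart, mend)
    pm <- pairing_map(struct)
    star_span <- star_from_pairing(pm, mature_span, n)
    precursor(id = sprintf("hairpin_s%d", as.integer(seed)),
              sequence = seq, structure = struct,
              mature_span = mature_span, star_span = star_span,
              arm = if (mature_arm == "5p") "five_prime" else "three_prime",
              fold_energy = -sum(!is.na(pm)) / 2)
  })
}

#' Mature miRNA sequence of a precursor
#' @param p a [precursor].
#' @return 5'->3' mature sequence (DNA alphabet). For a 3'-arm mature the
#'   genomic slice already reads 5'->3'.
#' @export
mature_seq <- function(p) span_seq(p$sequence, p$mature_span)

#' Evolve a hairpin family along an ultrametric tree
#'
#' Jukes-Cantor substitution process, independent per site, with the rate
#' of each site set by its structural region (5'-stem, miR*, loop, miR,
#' 3'-stem).  Along a branch of length `t` Myr a site substitutes with
#' probability `3/4 * (1 - exp(-4/3 * k * t))` and the new base is uniform
#' over the three alternatives.  No indels.
#'
#' @param ancestor a [precursor] used as root sequence; its region
#'   partition assigns a rate to every site.
#' @param tree an `ape::phylo` ultrametric tree with branch lengths in Myr
#'   (or a Newick string).
#' @param region_rates named numeric: substitutions/site/Myr for exactly
#'   `five_prime`, `mir_star`, `loop`, `mir`, `three_prime`.
#' @param seed integer seed.
#' @return list with `tips` (named character, one sequence per tip) and
#'   `truth` (list: `true_region_rates`, `tree_ages`, `site_regions`).
#' @export
evolve_family <- function(ancestor, tree, region_rates, seed = 1) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  if (!inherits(tree, "phylo")) stop("tree must be an ape phylo", call. = FALSE)
  if (length(tree$tip.label) < 2) stop("tree needs >= 2 tips", call. = FALSE)
  want <- c("five_prime", "mir_star", "loop", "mir", "three_prime")
  if (!setequal(names(region_rates), want))
    stop("region_rates must name exactly the five regions", call. = FALSE)
  if (any(region_rates < 0)) stop("negative rate", call. = FALSE)
  ages <- node_ages(tree)                      # errors if non-ultrametric
  part <- partition_regions(ancestor)
  n <- nchar(ancestor$sequence)
  site_region <- character(n)
  for (r in names(part$spans)) {
    sp <- part$spans[[r]]
    if (span_len(sp) > 0) site_region[(sp[1] + 1L):sp[2]] <- r
  }
  k_site <- unname(unlist(region_rates)[site_region])
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    nnode <- max(tree$edge)
    seqs <- vector("list", nnode)
    root <- length(tree$tip.label) + 1L
    seqs[[root]] <- strsplit(ancestor$sequence, "")[[1]]
    # preorder: ape edges from root outward after reorder
    tr <- ape::reorder.phylo(tree, "cladewise")
    for (e in seq_len(nrow(tr$edge))) {
      par <- tr$edge[e, 1]; child <- tr$edge[e, 2]
      t_br <- tr$edge.length[e]
      s <- seqs[[par]]
      p_sub <- 0.75 * (1 - exp(-4 / 3 * k_site * t_br))
      hit <- runif(n) < p_sub
      if (any(hit)) {
        for (i in which(hit)) s[i] <- sample(setdiff(bases, s[i]), 1)
      }
      seqs[[child]] <- s
    }
    tips <- vapply(seq_along(tree$tip.label),
                   function(i) paste(seqs[[i]], collapse = ""), character(1))
    names(tips) <- tree$tip.label
    list(tips = tips,
         truth = list(true_region_rates = unlist(region_rates)[want],
                      tree_ages = ages,
                      site_regions = site_region))
  })
}

# node ages (Myr before present) of an ultrametric tree; errors otherwise
node_ages <- function(tree, tol = 1e-6) {
  depths <- ape::node.depth.edgelength(tree)
  ntip <- length(tree$tip.label)
  tip_depth <- depths[seq_len(ntip)]
  h <- max(tip_depth)
  if (max(tip_depth) - min(tip_depth) > tol * max(1, h))
    stop("tree is not ultrametric", call. = FALSE)
  ages <- h - depths
  names(ages) <- c(tree$tip.label,
                   as.character((ntip + 1):(ntip + tree$Nnode)))
  ages
}

#' Dinucleotide shuffle (Altschul-Erickson)
#'
#' Random Eulerian-path shuffle that preserves the exact dinucleotide
#' composition (and therefore mononucleotide composition, first and last
#' base) while destroying longer-range structure such as stems.
#'
#' @param seq nucleotide string.
#' @return shuffled string.
#' @export
dinuc_shuffle <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  if (n < 3) return(seq)
  verts <- unique(ch)
  succ <- split(ch[-1], factor(ch[-n], levels = verts))
  first <- ch[1]; last <- ch[n]
  # choose a random last-edge per non-terminal vertex such that following
  # last-edges always reaches the terminal vertex
  repeat {
    last_edge <- list()
    for (v in verts) {
      if (v == last) next
      s <- succ[[v]]
      if (length(s) == 0) next
      last_edge[[v]] <- s[sample.int(length(s), 1)]
    }
    ok <- TRUE
    for (v in verts) {
      if (v == last || length(succ[[v]]) == 0) next
      cur <- v; steps <- 0L
      while (!identical(cur, last) && steps <= length(verts)) {
        cur <- last_edge[[cur]]
        steps <- steps + 1L
        if (is.null(cur)) break
      }
      if (is.null(cur) || !identical(cur, last)) { ok <- FALSE; break }
    }
    if (ok) break
  }
  # per-vertex edge order: shuffle, forcing the chosen last edge last
  order_for <- list()
  for (v in verts) {
    s <- succ[[v]]
    if (length(s) == 0) { order_for[[v]] <- character(0); next }
    if (v != last && !is.null(last_edge[[v]])) {
      idx <- which(s == last_edge[[v]])[1]
      rest <- s[-idx]
      order_for[[v]] <- c(if (length(rest)) sample(rest) else character(0),
                          s[idx])
    } else {
      order_for[[v]] <- if (length(s) > 1) sample(s) else s
    }
  }
  ptr <- setNames(rep(1L, length(verts)), verts)
  out <- character(n)
  out[1] <- first
  cur <- first
  for (i in 2:n) {
    nxt <- order_for[[cur]][ptr[[cur]]]
    ptr[[cur]] <- ptr[[cur]] + 1L
    out[i] <- nxt
    cur <- nxt
  }
  paste(out, collapse = "")
}

#' Plant hairpin loci in a random genome background
#'
#' The background is i.i.d. uniform ACGT.  Planted loci are the template
#' hairpins plus mutated copies (substitutions restricted to the mature
#' span); half of all planted loci are inserted reverse-complemented.
#' Decoys are dinucleotide-shuffled hairpin sequences: same composition,
#' no stem.
#'
#' @param templates list of [precursor] templates.
#' @param mutated_copies list of `list(template = <precursor>,
#'   n_mismatches = <int>)`; mismatches are placed inside the mature span.
#' @param n_decoys number of shuffled decoy inserts.
#' @param bg_len background genome length (nt).
#' @param seed integer seed.
#' @param contig contig name.
#' @return list with `genome` (named character) and `truth` (list with
#'   data.frames `planted_loci` and `decoy_loci`).
#' @export
plant_genome <- function(templates, mutated_copies = list(), n_decoys = 0,
                         bg_len = 10000, seed = 1, contig = "ctg1") {
  if (inherits(templates, "precursor")) templates <- list(templates)
  with_seed(seed, {
    inserts <- list()
    for (i in seq_along(templates)) {
      p <- templates[[i]]
      inserts[[length(inserts) + 1]] <-
        list(seq = p$sequence, kind = "planted", template_id = p$id,
             n_mismatches = 0L)
    }
    for (mc in mutated_copies) {
      p <- mc$template
      k <- mc$n_mismatches
      ch <- strsplit(p$sequence, "")[[1]]
      mpos <- (p$mature_span[1] + 1L):p$mature_span[2]
      hit <- sample(mpos, k)
      for (j in hit) ch[j] <- sample(setdiff(c("A", "C", "G", "T"), ch[j]), 1)
      inserts[[length(inserts) + 1]] <-
        list(seq = paste(ch, collapse = ""), kind = "planted",
             template_id = p$id, n_mismatches = as.integer(k))
    }
    n_planted <- length(inserts)
    if (n_decoys > 0) {
      for (d in seq_len(n_decoys)) {
        p <- templates[[(d - 1L) %% length(templates) + 1L]]
        inserts[[length(inserts) + 1]] <-
          list(seq = dinuc_shuffle(p$sequence), kind = "decoy",
               template_id = p$id, n_mismatches = NA_integer_)
      }
    }
    lens <- vapply(inserts, function(x) nchar(x$seq), integer(1))
    free <- bg_len - sum(lens)
    if (free < 0)
      stop("cannot place inserts without overlap: background too short",
           call. = FALSE)
    n_ins <- length(inserts)
    # gap sizes between inserts (n_ins + 1 gaps summing to `free`)
    cuts <- sort(sample.int(free + 1L, n_ins, replace = TRUE) - 1L)
    gaps <- c(cuts, free) - c(0L, cuts)
    # strand: half of the planted loci reverse-complemented
    strands <- rep("+", n_ins)
    if (n_planted > 1) {
      neg <- sample.int(n_planted, n_planted %/% 2L)
      strands[neg] <- "-"
    }
    ord <- sample.int(n_ins)                      # random genomic order
    pieces <- character(0)
    pos <- 0L
    rec <- list()
    for (k in seq_len(n_ins)) {
      g <- gaps[k]
      if (g > 0) { pieces <- c(pieces, rand_seq(g)); pos <- pos + g }
      i <- ord[k]
      s <- inserts[[i]]$seq
      placed <- if (strands[i] == "-") revcomp(s) else s
      pieces <- c(pieces, placed)
      rec[[length(rec) + 1]] <- data.frame(
        contig = contig, start = pos, end = pos + nchar(s),
        strand = strands[i], n_mismatches = inserts[[i]]$n_mismatches,
        template_id = inserts[[i]]$template_id, kind = inserts[[i]]$kind,
        stringsAsFactors = FALSE)
      pos <- pos + nchar(s)
    }
    if (gaps[n_ins + 1L] > 0) pieces <- c(pieces, rand_seq(gaps[n_ins + 1L]))
    genome <- setNames(paste(pieces, collapse = ""), contig)
    loci <- do.call(rbind, rec)
    loci <- loci[order(loci$start), , drop = FALSE]
    rownames(loci) <- NULL
    list(genome = genome,
         truth = list(
           planted_loci = loci[loci$kind == "planted", , drop = FALSE],
           decoy_loci = loci[loci$kind == "decoy", , drop = FALSE]))
  })
}

#' Design a target window with an exact expectation score
#'
#' Starting from the perfect reverse complement of the miRNA, edits are
#' introduced to reach exactly `penalty` under the expectation scoring
#' rule (match 0, G.U 0.5, mismatch 1, doubled at seed positions 2-13):
#' integer parts >= 2 use one seed mismatch, remaining integer units use
#' non-seed mismatches, and a half unit uses a non-seed G.U wobble (which
#' requires a G or U in the miRNA at a non-seed position).
#'
#' @param mirna mature miRNA sequence (5'->3', >= 20 nt).
#' @param penalty designed expectation, a non-negative multiple of 0.5.
#' @param seed_span inclusive 1-based miRNA positions forming the seed.
#' @return target-sense window (same length as the miRNA) whose duplex
#'   expectation equals `penalty` exactly.
#' @export
design_target_window <- function(mirna, penalty, seed_span = c(2L, 13L)) {
  mirna <- norm_seq(mirna, "mirna")
  m <- nchar(mirna)
  mb <- strsplit(mirna, "")[[1]]
  nonseed <- setdiff(seq_len(m), seed_span[1]:seed_span[2])
  wobble_ok <- nonseed[mb[nonseed] %in% c("G", "T")]
  achievable <- function(x) {
    x >= 0 && abs(x * 2 - round(x * 2)) < 1e-9 &&
      (abs(x - round(x)) < 1e-9 || length(wobble_ok) > 0)
  }
  if (!achievable(penalty)) {
    closest <- if (penalty < 0) 0 else round(penalty)
    stop(sprintf("designed penalty %s not achievable; closest achievable is %s",
                 format(penalty), format(closest)), call. = FALSE)
  }
  # perfect complement window: miRNA position i faces window position m+1-i
  comp <- chartr("ACGT", "TGCA", mb)
  win <- rev(comp)
  used <- logical(m)
  set_col <- function(i, base) win[m + 1L - i] <<- base
  r <- penalty
  if (abs(r - floor(r) - 0.5) < 1e-9) {
    i <- wobble_ok[length(wobble_ok)]             # prefer 3'-most slot
    set_col(i, if (mb[i] == "G") "T" else "G")    # G.U wobble
    used[i] <- TRUE
    r <- r - 0.5
  }
  r <- round(r)
  seed_free <- setdiff(seed_span[1]:seed_span[2], which(used))
  while (r >= 2 && length(seed_free) > 0) {
    i <- seed_free[4L]                            # position 5 by default
    if (is.na(i)) i <- seed_free[1L]
    set_col(i, mb[i])                             # same base = mismatch
    used[i] <- TRUE
    seed_free <- setdiff(seed_free, i)
    r <- r - 2
  }
  ns_free <- setdiff(nonseed, which(used))
  while (r >= 1) {
    if (length(ns_free) == 0)
      stop("designed penalty too large for available positions", call. = FALSE)
    i <- ns_free[length(ns_free)]
    set_col(i, mb[i])
    used[i] <- TRUE
    ns_free <- setdiff(ns_free, i)
    r <- r - 1
  }
  window <- paste(win, collapse = "")
  got <- duplex_penalty(mirna, window, seed_span = seed_span)
  if (abs(got - penalty) > 1e-9)
    stop("internal error: designed window scores ", got, call. = FALSE)
  window
}

#' Generate a two-species CDS set with planted miRNA target sites
#'
#' Each gene family has orthologous members in species `"spA"` and
#' `"spB"`.  Planted sites are edited reverse-complement windows of the
#' designed penalty (see [design_target_window()]), inserted into the
#' member's CDS in both species.  Background CDS regions are verified by
#' the scorer to contain no window with expectation <= 3.0 for any of the
#' supplied miRNAs (offending windows are resampled).
#'
#' @param n_families number of gene families.
#' @param family_sizes integer vector, one size per family (members per
#'   species).
#' @param mirnas named character vector of mature miRNA sequences.
#' @param planted data.frame (or list of lists) with columns/fields
#'   `mirna_idx`, `family_idx`, `member_idx`, `designed_penalty`.
#' @param cds_len CDS length in nt (>= miRNA length).
#' @param seed integer seed.
#' @return list with `cds` (named character, both species), `families`
#'   (data.frame gene_id/species/family_id) and `truth` (data.frame
#'   `planted_sites`: mirna_id, gene_id, start, end, designed_penalty).
#' @export
make_target_set <- function(n_families, family_sizes, mirnas, planted = NULL,
                            cds_len = 300, seed = 1) {
  if (length(family_sizes) != n_families)
    stop("family_sizes must have one entry per family", call. = FALSE)
  if (is.null(names(mirnas)))
    names(mirnas) <- sprintf("miR%02d", seq_along(mirnas))
  mirnas <- vapply(mirnas, norm_seq, character(1))
  if (cds_len < max(nchar(mirnas)))
    stop("cds_len must be >= miRNA length", call. = FALSE)
  if (is.list(planted) && !is.data.frame(planted) && length(planted))
    planted <- do.call(rbind, lapply(planted, as.data.frame))
  with_seed(seed, {
    genes <- do.call(rbind, lapply(seq_len(n_families), function(f) {
      do.call(rbind, lapply(seq_len(family_sizes[f]), function(g) {
        data.frame(gene_id = sprintf("%s_fam%d_g%d", c("spA", "spB"), f, g),
                   species = c("spA", "spB"), family_id = sprintf("fam%d", f),
                   member = g, stringsAsFactors = FALSE)
      }))
    }))
    cds <- setNames(vapply(seq_len(nrow(genes)),
                           function(i) rand_seq(cds_len), character(1)),
                    genes$gene_id)
    sites <- list()
    occupied <- setNames(vector("list", nrow(genes)), genes$gene_id)
    if (!is.null(planted) && nrow(planted) > 0) {
      for (k in seq_len(nrow(planted))) {
        mi <- planted$mirna_idx[k]; fi <- planted$family_idx[k]
        gi <- planted$member_idx[k]; pen <- planted$designed_penalty[k]
        win <- design_target_window(mirnas[[mi]], pen)
        w <- nchar(win)
        for (sp in c("spA", "spB")) {
          gid <- sprintf("%s_fam%d_g%d", sp, fi, gi)
          if (!gid %in% genes$gene_id)
            stop("planted site refers to non-existent gene ", gid,
                 call. = FALSE)
          # deterministic-random non-overlapping offset
          occ <- occupied[[gid]]
          for (try in 1:200) {
            st <- sample.int(cds_len - w + 1L, 1) - 1L
            if (!length(occ) ||
                !any(vapply(occ, function(o) spans_overlap(o, c(st, st + w)),
                            logical(1)))) break
            if (try == 200) stop("cannot place planted sites", call. = FALSE)
          }
          occupied[[gid]] <- c(occ, list(span(st, st + w)))
          cds[[gid]] <- paste0(substr(cds[[gid]], 1, st), win,
                               substr(cds[[gid]], st + w + 1L, cds_len))
          sites[[length(sites) + 1]] <- data.frame(
            mirna_id = names(mirnas)[mi], gene_id = gid,
            start = st, end = st + w, designed_penalty = pen,
            stringsAsFactors = FALSE)
        }
      }
    }
    truth_sites <- if (length(sites)) do.call(rbind, sites) else
      data.frame(mirna_id = character(0), gene_id = character(0),
                 start = integer(0), end = integer(0),
                 designed_penalty = numeric(0))
    # scrub background: no non-planted window may reach expectation <= 3.0
    for (gid in names(cds)) {
      planted_here <- truth_sites[truth_sites$gene_id == gid, , drop = FALSE]
      for (iter in 1:50) {
        dirty <- FALSE
        for (mn in names(mirnas)) {
          hits <- scan_cds(mirnas[[mn]], cds[[gid]], max_expectation = 3.0)
          if (nrow(hits) == 0) next
          for (h in seq_len(nrow(hits))) {
            hs <- c(hits$start[h], hits$end[h])
            is_planted <- nrow(planted_here) > 0 &&
              any(vapply(seq_len(nrow(planted_here)), function(j)
                spans_overlap(hs, c(planted_here$start[j],
                                    planted_here$end[j])), logical(1)))
            if (!is_planted) {
              dirty <- TRUE
              repl <- rand_seq(hs[2] - hs[1])
              cds[[gid]] <- paste0(substr(cds[[gid]], 1, hs[1]), repl,
                                   substr(cds[[gid]], hs[2] + 1L, cds_len))
            }
          }
        }
        if (!dirty) break
        if (iter == 50) stop("could not scrub background", call. = FALSE)
      }
    }
    list(cds = cds,
         families = genes[, c("gene_id", "species", "family_id")],
         truth = list(planted_sites = truth_sites))
  })
}
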