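# End-to-end pipeline on the default synthetic scenario, plus the plain
# text writers shared by the CLI: simulate -> discover -> rates ->
# targets -> network -> synteny, emitting FASTA/BED/TSV/Newick/GraphML.

#' Write a dot-bracket structure file
#'
#' FASTA-like: a header line, the sequence line, then the structure line
#' annotated with the mature and star spans.
#'
#' @param precursors list of [precursor] objects.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_structure_file <- function(precursors, path) {
  lines <- unlist(lapply(precursors, function(p) c(
    sprintf(">%s mature=%d-%d star=%d-%d arm=%s energy=%g",
            p$id, p$mature_span[1], p$mature_span[2],
            p$star_span[1], p$star_span[2], p$arm, p$fold_energy),
    p$sequence, p$structure)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a dot-bracket structure file written by [write_structure_file()]
#' @param path file path.
#' @return list of [precursor] objects.
#' @export
read_structure_file <- function(path) {
  lines <- readLines(path)
  stopifnot(length(lines) %% 3 == 0)
  out <- list()
  for (i in seq(1, length(lines), by = 3)) {
    hdr <- sub("^>", "", lines[i])
    fields <- strsplit(hdr, " ")[[1]]
    kv <- strsplit(fields[-1], "=")
    vals <- setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
    msp <- as.integer(strsplit(vals[["mature"]], "-")[[1]])
    ssp <- as.integer(strsplit(vals[["star"]], "-")[[1]])
    out[[length(out) + 1]] <- precursor(
      id = fields[1], sequence = lines[i + 1], structure = lines[i + 2],
      mature_span = msp, star_span = ssp, arm = vals[["arm"]],
      fold_energy = as.numeric(vals[["energy"]]))
  }
  out
}

#' Write genome hits as BED6
#' @param hits [scan_genome()] output.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_bed <- function(hits, path) {
  bed <- data.frame(hits$contig, hits$start, hits$end, hits$query_id,
                    hits$mismatches, hits$strand)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a BED6 hits file written by [write_bed()]
#' @param path file path.
#' @return data.frame in [scan_genome()] layout.
#' @export
read_bed <- function(path) {
  bed <- read.table(path, sep = "\t", stringsAsFactors = FALSE)
  data.frame(query_id = bed[[4]], contig = bed[[1]], start = bed[[2]],
             end = bed[[3]], strand = bed[[6]], mismatches = bed[[5]],
             stringsAsFactors = FALSE)
}

# the default chronogram: 8 tips, depth 50 Myr, with a shallow 8-Myr
# split mirroring the tomato/potato divergence
default_chronogram <- function() {
  paste0("((((t1:8,t2:8):12,t3:20):15,t4:35):15,",
         "(((t5:10,t6:10):15,t7:25):15,t8:40):10);")
}

# the default region rates (substitutions/site/Myr): miR and miR* most
# constrained, loop fastest
default_region_rates <- function() {
  c(five_prime = 0.001, mir_star = 0.0005, loop = 0.01, mir = 0.0005,
    three_prime = 0.001)
}

# synthetic annotation + homology fixture for the synteny stage: a tandem
# pair on chr1 (adjacent loci, no gene between, shared flanks) and a
# segmental pair chr1/chr2 with a colinear homologous 4-gene block
synteny_fixture <- function() {
  gene <- function(id, chrom, start)
    data.frame(gene_id = id, chrom = chrom, start = start,
               end = start + 800L, type = "gene", stringsAsFactors = FALSE)
  ann <- do.call(rbind, c(
    lapply(1:24, function(i) gene(sprintf("c1g%02d", i), "chr1",
                                  i * 2000L + ifelse(i > 12, 5000L, 0L))),
    lapply(1:14, function(i) gene(sprintf("c2g%02d", i), "chr2",
                                  i * 2000L))))
  loci <- data.frame(
    locus_id = c("mirA", "mirB", "mirC"),
    chrom = c("chr1", "chr1", "chr2"),
    start = c(26000L, 27000L, 15000L),
    end = c(26150L, 27150L, 15150L), stringsAsFactors = FALSE)
  # mirA/mirB: adjacent between c1g12 (24000) and c1g13 (31000) -> tandem
  # mirC on chr2; c2g05..c2g08 homologous to c1g09..c1g12 (colinear run 4)
  homology <- data.frame(
    gene_a = sprintf("c1g%02d", 9:12),
    gene_b = sprintf("c2g%02d", 5:8),
    evalue = 1e-10, stringsAsFactors = FALSE)
  list(annotation = ann, loci = loci, homology = homology)
}

#' Run the full pipeline on the default synthetic scenario
#'
#' simulate -> discover -> rates -> targets -> network -> synteny, with
#' every declared output written under `out_dir` as plain text (FASTA,
#' BED, TSV, Newick, JSON, GraphML, SIF).
#'
#' @param out_dir output directory (created if needed).
#' @param seed integer master seed; all stage seeds derive from it.
#' @param bg_len background genome length for the discovery stage.
#' @return invisibly, a list with the in-memory stage results and a
#'   `files` vector of all written paths.
#' @export
run_pipeline <- function(out_dir, seed = 1, bg_len = 50000) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(x) file.path(out_dir, x)
  seed <- as.integer(seed)

  ## simulate -----------------------------------------------------------
  templates <- list(
    make_hairpin(30, 6, n_wobbles = 2, n_bulges = 0, mature_arm = "3p",
                 seed = seed * 100L + 1L),
    make_hairpin(26, 5, n_wobbles = 1, n_bulges = 1, mature_arm = "5p",
                 seed = seed * 100L + 2L),
    make_hairpin(34, 8, n_wobbles = 3, n_bulges = 1, mature_arm = "3p",
                 seed = seed * 100L + 3L))
  for (i in seq_along(templates))
    templates[[i]]$id <- sprintf("tmpl%d", i)
  mirnas <- setNames(vapply(templates, mature_seq, character(1)),
                     sprintf("miR%02d", seq_along(templates)))
  tree <- ape::read.tree(text = default_chronogram())
  fam <- evolve_family(templates[[1]], tree, default_region_rates(),
                       seed = seed * 100L + 4L)
  gen <- plant_genome(
    templates,
    mutated_copies = list(
      list(template = templates[[1]], n_mismatches = 1),
      list(template = templates[[2]], n_mismatches = 2),
      list(template = templates[[3]], n_mismatches = 3)),
    n_decoys = 5, bg_len = bg_len, seed = seed * 100L + 5L)
  # redundant targeting: several genes carry sites for two miRNAs, as in
  # the real network where most R-genes are hit by >= 2 family members
  planted <- data.frame(
    mirna_idx = c(1, 2, 1, 2, 3, 2, 3, 1),
    family_idx = c(1, 1, 1, 2, 2, 3, 4, 2),
    member_idx = c(1, 1, 2, 1, 1, 1, 1, 2),
    designed_penalty = c(0, 1.0, 1.5, 2.0, 1.0, 2.5, 3.0, 0.5))
  ts <- make_target_set(5, c(4, 3, 2, 2, 1), mirnas, planted,
                        cds_len = 300, seed = seed * 100L + 6L)
  write_fasta(gen$genome, fp("genome.fasta"))
  write_fasta(mirnas, fp("mature.fasta"))
  write_fasta(fam$tips, fp("family_tips.fasta"))
  # per-tip structure records (no indels: the ancestor's structure and
  # spans hold for every tip)
  anc <- templates[[1]]
  tip_precs <- lapply(names(fam$tips), function(tp)
    precursor(tp, fam$tips[[tp]], anc$structure, anc$mature_span,
              anc$star_span, anc$arm, anc$fold_energy))
  write_structure_file(tip_precs, fp("family_structures.txt"))
  write_fasta(ts$cds, fp("cds.fasta"))
  write_tsv(ts$families, fp("families.tsv"))
  ape::write.tree(tree, fp("chronogram.nwk"))
  jsonlite::write_json(
    list(planted_loci = gen$truth$planted_loci,
         decoy_loci = gen$truth$decoy_loci,
         planted_sites = ts$truth$planted_sites,
         true_region_rates = as.list(default_region_rates())),
    fp("truth.json"), auto_unbox = TRUE, digits = NA)

  ## discover -----------------------------------------------------------
  disc <- discover_precursors(mirnas, gen$genome)
  write_fasta(setNames(vapply(disc$precursors, `[[`, "", "sequence"),
                       vapply(disc$precursors, `[[`, "", "id")),
              fp("precursors.fasta"))
  write_structure_file(disc$precursors, fp("structures.txt"))
  write_bed(disc$hits, fp("hits.bed"))

  ## rates --------------------------------------------------------------
  part <- partition_regions(templates[[1]])
  tips <- fam$tips
  grp <- precursor_group(
    "grp1", alignment = tips,
    species = setNames(names(tips), names(tips)),
    partitions = setNames(rep(list(part), length(tips)), names(tips)),
    times = times_from_chronogram(tree))
  rates <- group_region_rates(grp)
  write_tsv(rates, fp("rates.tsv"))

  ## targets ------------------------------------------------------------
  pred <- predict_targets(mirnas, ts$cds, mode = "relaxed")
  write_tsv(pred$sites, fp("sites.tsv"))
  mat <- best_score_matrix(pred)
  write.table(cbind(gene_id = rownames(mat), as.data.frame(mat)),
              fp("score_matrix.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  ## network ------------------------------------------------------------
  net <- build_network(pred, ts$families)
  us <- unique_shared_counts(net)
  sh_o <- homolog_sharing(net, "ortholog")
  sh_p <- homolog_sharing(net, "paralog")
  corr <- family_size_vs_mirna_count(net)
  tf <- lapply(c(spA = "spA", spB = "spB"), function(sp)
    targeted_fraction(net, sp))
  write_tsv(us, fp("unique_shared.tsv"))
  export_network(net, fp("network.tsv"), "tsv")
  export_network(net, fp("network.graphml"), "graphml")
  export_network(net, fp("network.sif"), "sif")
  jsonlite::write_json(
    list(ortholog = unclass(sh_o)[c("n_pairs", "frac_share_any",
                                    "frac_identical")],
         paralog = unclass(sh_p)[c("n_pairs", "frac_share_any",
                                   "frac_identical")],
         family_size_correlation = corr[c("rho", "p_value", "n")],
         targeted_fraction = tf),
    fp("network_summary.json"), auto_unbox = TRUE, digits = NA)

  ## synteny ------------------------------------------------------------
  syn <- synteny_fixture()
  ctx <- lapply(seq_len(nrow(syn$loci)), function(i)
    flanking_context(syn$loci[i, ], syn$annotation))
  names(ctx) <- syn$loci$locus_id
  calls <- list()
  prs <- combn(syn$loci$locus_id, 2)
  for (k in seq_len(ncol(prs))) {
    a <- syn$loci[syn$loci$locus_id == prs[1, k], ]
    b <- syn$loci[syn$loci$locus_id == prs[2, k], ]
    tc <- call_tandem(a, b, syn$annotation, ctx)
    if (!is.null(tc))
      calls[[length(calls) + 1]] <- data.frame(
        locus_a = tc$locus_a, locus_b = tc$locus_b, kind = "tandem",
        evidence = length(tc$evidence$shared_flanks))
    scall <- call_segmental(ctx[[prs[1, k]]], ctx[[prs[2, k]]],
                            syn$homology)
    if (!is.null(scall))
      calls[[length(calls) + 1]] <- data.frame(
        locus_a = scall$locus_a, locus_b = scall$locus_b,
        kind = "segmental", evidence = scall$evidence$run_length)
  }
  calls <- if (length(calls)) do.call(rbind, calls) else
    data.frame(locus_a = character(0), locus_b = character(0),
               kind = character(0), evidence = integer(0))
  write_tsv(calls, fp("synteny_calls.tsv"))

  files <- list.files(out_dir, full.names = TRUE)
  invisible(list(templates = templates, mirnas = mirnas, genome = gen,
                 family = fam, target_set = ts, discovery = disc,
                 rates = rates, prediction = pred, network = net,
                 unique_shared = us, sharing = list(ortholog = sh_o,
                                                    paralog = sh_p),
                 correlation = corr, targeted = tf, synteny = calls,
                 files = files))
}
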